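# Shared fixture builders. Feature maps follow the public convention
# (batch, channel, row, col); all fixtures are generated in code.

rand_fm <- function(B = 2, C = 3, H = 4, W = 5, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(B * C * H * W, sd = sd), c(B, C, H, W))
}

# double-loop reference for per-sample per-channel moments
loop_channel_stats <- function(f, eps = 1e-5) {
  d <- dim(f)
  mu <- matrix(0, d[1], d[2])
  sigma <- matrix(0, d[1], d[2])
  for (b in seq_len(d[1])) for (ch in seq_len(d[2])) {
    v <- 0; m <- 0; n <- d[3] * d[4]
    for (i in seq_len(d[3])) for (j in seq_len(d[4])) m <- m + f[b, ch, i, j]
    m <- m / n
    for (i in seq_len(d[3])) for (j in seq_len(d[4]))
      v <- v + (f[b, ch, i, j] - m)^2
    mu[b, ch] <- m
    sigma[b, ch] <- sqrt(v / n + eps^2)
  }
  list(mu = mu, sigma = sigma)
}

# per-pixel enumeration oracle for all segmentation metrics
loop_metrics <- function(pred, gt, n_classes, weed_ids) {
  tp <- fp <- fn <- numeric(n_classes)
  wtp <- wfp <- wfn <- 0
  for (i in seq_along(pred)) {
    g <- gt[i]; p <- pred[i]
    if (g == 255) next
    for (k in 0:(n_classes - 1)) {
      if (g == k && p == k) tp[k + 1] <- tp[k + 1] + 1
      if (g != k && p == k) fp[k + 1] <- fp[k + 1] + 1
      if (g == k && p != k) fn[k + 1] <- fn[k + 1] + 1
    }
    gw <- g %in% weed_ids; pw <- p %in% weed_ids
    if (gw && pw) wtp <- wtp + 1
    if (!gw && pw) wfp <- wfp + 1
    if (gw && !pw) wfn <- wfn + 1
  }
  denom <- tp + fp + fn
  use <- denom > 0
  fg <- setdiff(seq_len(n_classes), 1L)
  TP <- sum(tp[fg]); FP <- sum(fp[fg]); FN <- sum(fn[fg])
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  list(miou = 100 * mean(tp[use] / denom[use]),
       precision = 100 * P, recall = 100 * R,
       f1 = 100 * F1,
       weed_iou = if (wtp + wfp + wfn > 0)
         100 * wtp / (wtp + wfp + wfn) else NA_real_)
}

# small in-memory two-domain benchmark for pipeline tests
tiny_benchmark <- function(seed = 1, n_lab = 12, n_field = 6, size = 32) {
  generate_benchmark(seed = seed, n_lab = n_lab, n_field = n_field,
                     image_size = size)
}

tiny_config <- function(...) {
  seg_config(n_iterations = 30L, vae_iterations = 15L, batch_size = 4L,
             ...)
}
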