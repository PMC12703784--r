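# Adversarial feature normalization. A learnable pair of per-channel
# statistics (mu_adv, sigma_adv) replaces the instance statistics of the
# incoming feature map. The statistics are trained through a gradient
# reversal layer: the forward pass is the identity, the backward pass flips
# (and scales) the gradient, so a single optimization loop simultaneously
# descends the task loss in the model parameters and ascends it in the
# adversarial statistics -- pushing the normalization toward feature styles
# the segmenter finds hard.

#' Learnable adversarial normalization statistics
#'
#' `sigma_adv` is stored as a log so positivity is structural.
#'
#' @param n_channels number of feature channels.
#' @param init_mu,init_log_sigma initial values (recycled over channels).
#' @return An object of class `"adversarial_stats"` with numeric vectors
#'   `mu_adv` and `log_sigma_adv` of length `n_channels`.
#' @export
adversarial_stats <- function(n_channels, init_mu = 0, init_log_sigma = 0) {
  structure(list(mu_adv = rep_len(as.numeric(init_mu), n_channels),
                 log_sigma_adv = rep_len(as.numeric(init_log_sigma),
                                         n_channels)),
            class = "adversarial_stats")
}

#' @export
print.adversarial_stats <- function(x, ...) {
  cat(sprintf("Adversarial statistics over %d channels\n", length(x$mu_adv)))
  cat(sprintf("  mu_adv in [%.4g, %.4g], sigma_adv in [%.4g, %.4g]\n",
              min(x$mu_adv), max(x$mu_adv),
              min(exp(x$log_sigma_adv)), max(exp(x$log_sigma_adv))))
  invisible(x)
}

#' Gradient reversal configuration
#'
#' @param lambda_grl nonnegative gradient reversal coefficient.
#' @param phi positive step size of the adversarial-statistics update (the
#'   style perturbation rate). Default 0.01.
#' @param schedule `"constant"` keeps `lambda_grl` fixed; `"linear-ramp"`
#'   ramps it from 0 to its value over the first 10% of iterations.
#' @param normalized when `TRUE` (default) the update moves a fixed
#'   distance `phi * lambda_grl` along the task-gradient direction, so the
#'   style perturbation rate controls the speed of the distribution shift
#'   independently of the loss scale; `FALSE` uses the raw gradient.
#' @return An object of class `"grl_config"`.
#' @export
grl_config <- function(lambda_grl = 1, phi = 0.01,
                       schedule = c("constant", "linear-ramp"),
                       normalized = TRUE) {
  schedule <- match.arg(schedule)
  if (!is.finite(lambda_grl) || lambda_grl < 0)
    stop("`lambda_grl` must be nonnegative", call. = FALSE)
  if (!is.finite(phi) || phi <= 0)
    stop("`phi` must be positive", call. = FALSE)
  structure(list(lambda_grl = lambda_grl, phi = phi, schedule = schedule,
                 normalized = isTRUE(normalized)),
            class = "grl_config")
}

# effective reversal coefficient at a given iteration
grl_coefficient <- function(cfg, iter, n_total) {
  if (cfg$schedule == "constant") return(cfg$lambda_grl)
  ramp <- max(1, ceiling(0.1 * n_total))
  cfg$lambda_grl * min(1, iter / ramp)
}

#' Gradient reversal layer
#'
#' The forward pass is the exact identity on any numeric array. The backward
#' contract is that a downstream gradient `g` arrives upstream as
#' `-lambda_grl * g`; [grl_backward()] applies it. Training loops in this
#' package realize the contract by routing the task gradient of the
#' adversarial statistics through [grl_backward()] before the optimizer, so
#' the statistics ascend the task loss while everything else descends it.
#'
#' @param x any numeric array.
#' @param lambda_grl nonnegative reversal coefficient.
#' @return `x`, unchanged.
#' @export
grl <- function(x, lambda_grl = 1) {
  if (!is.finite(lambda_grl) || lambda_grl < 0)
    stop("`lambda_grl` must be nonnegative", call. = FALSE)
  x
}

#' @param grad downstream gradient array.
#' @rdname grl
#' @export
grl_backward <- function(grad, lambda_grl = 1) {
  if (!is.finite(lambda_grl) || lambda_grl < 0)
    stop("`lambda_grl` must be nonnegative", call. = FALSE)
  -lambda_grl * grad
}

#' Normalize a feature map with adversarial statistics
#'
#' Replaces each sample's per-channel moments with the learnable adversarial
#' pair: `x_t = sigma_adv * (x - mu(x)) / sigma(x) + mu_adv`. The same
#' algebra as [moment_inject()], with one target shared across the batch.
#'
#' @param x feature map `(B, C, H, W)`.
#' @param adv an [adversarial_stats()] object with `C` channels.
#' @param eps moment stabilizer.
#' @return Feature map shaped like `x` whose channel statistics equal
#'   `(mu_adv, sigma_adv)` up to the stabilizer.
#' @export
adversarial_normalize <- function(x, adv, eps = 1e-5) {
  fm_check(x, "x")
  stopifnot(inherits(adv, "adversarial_stats"))
  d <- dim(x)
  if (length(adv$mu_adv) != d[2])
    stop(sprintf("adversarial statistics have %d channels but the map has %d",
                 length(adv$mu_adv), d[2]), call. = FALSE)
  to_bchw(adv_normalize_fwd(to_hwbc(x), adv, eps)$out)
}

# internal fwd/bwd on (h, w, batch, channel) maps; the target is broadcast
# over the batch, so parameter gradients are summed over samples
adv_normalize_fwd <- function(x, adv, eps) {
  d <- dim(x)
  mu_t <- matrix(adv$mu_adv, d[3], d[4], byrow = TRUE)
  sg_t <- matrix(exp(adv$log_sigma_adv), d[3], d[4], byrow = TRUE)
  inject_fwd(x, mu_t, sg_t, eps)
}

adv_normalize_bwd <- function(dout, adv, cache) {
  ib <- inject_bwd(dout, cache)
  sigma_adv <- exp(adv$log_sigma_adv)
  list(dx = ib$dx,
       dmu_adv = colSums(ib$dmu_t),
       dlog_sigma_adv = colSums(ib$dsigma_t) * sigma_adv)
}

# Sample-relative adversarial restyling used by the training loop: the
# adversarial statistics of a sample are its own moments moved by the
# learnable shifts, mu_adv = mu(x) + delta_mu and
# sigma_adv = sigma(x) * exp(delta_log_sigma), so the transform realizes
# the iterative shift of the feature-style distribution while preserving
# per-sample style diversity. Algebraically
#   x_t = e^d * (x - mu(x)) + mu(x) + delta_mu     (per channel c).
adv_shift_fwd <- function(x, adv, eps) {
  st <- cs_fwd(x, eps)
  d <- dim(x); n <- st$n; B <- d[3]; C <- d[4]
  scale <- exp(adv$log_sigma_adv)
  sc_full <- rep(rep(scale, each = B), each = n)
  mu_full <- rep(as.vector(st$mu), each = n)
  out <- sc_full * (as.vector(x) - mu_full) + mu_full +
    rep(rep(adv$mu_adv, each = B), each = n)
  dim(out) <- d
  list(out = out, cache = list(x = x, stats = st, scale = scale, dims = d))
}

adv_shift_bwd <- function(dout, adv, cache) {
  d <- cache$dims; n <- d[1] * d[2]; B <- d[3]; C <- d[4]
  dmat <- dout; dim(dmat) <- c(n, B * C)
  xm <- cache$x; dim(xm) <- c(n, B * C)
  mu <- as.vector(cache$stats$mu)
  centered <- xm - rep(mu, each = n)
  col_d <- colSums(dmat)                       # per (b, c)
  dmu_adv <- colSums(matrix(col_d, B, C))
  dlog_sigma_adv <- cache$scale *
    colSums(matrix(colSums(dmat * centered), B, C))
  sc_full <- rep(rep(cache$scale, each = B), each = n)
  # x_t = a x + (1 - a) mu + delta: dx = a dout + (1 - a) mean(dout)
  dx <- sc_full * as.vector(dout) +
    rep((1 - rep(cache$scale, each = B)) * col_d / n, each = n)
  dim(dx) <- d
  list(dx = dx, dmu_adv = dmu_adv, dlog_sigma_adv = dlog_sigma_adv)
}

#' Adversarial-statistics update step
#'
#' Applies the reversed-gradient update: the statistics move *up* the task
#' loss (direction `lambda_grl * task_grad`), realizing the iterative
#' feature-style distribution shift. When `task_grad` carries a `consist`
#' component (the gradient of the weighted consistency loss with respect
#' to the statistics), that component is *descended* -- the consistency
#' term is the stabilizer that keeps the adversarial excursion bounded.
#' With the default normalized configuration the statistics move a fixed
#' distance `phi * lambda_grl` along the combined direction. A zero
#' gradient (or a vanishing step size) leaves the statistics unchanged.
#'
#' @param adv an [adversarial_stats()] object.
#' @param task_grad list with finite numeric vectors `mu_adv` and
#'   `log_sigma_adv`: the gradient of the task loss with respect to the
#'   statistics (in the stored parameterization); optionally a `consist`
#'   list holding the stabilizer gradient in the same shape.
#' @param cfg a [grl_config()] object.
#' @param lambda_grl optional override of the reversal coefficient (used by
#'   schedules); defaults to `cfg$lambda_grl`.
#' @return The updated `"adversarial_stats"` object.
#' @export
dgb_step <- function(adv, task_grad, cfg = grl_config(),
                     lambda_grl = NULL) {
  stopifnot(inherits(adv, "adversarial_stats"), inherits(cfg, "grl_config"))
  lam <- if (is.null(lambda_grl)) cfg$lambda_grl else lambda_grl
  g_mu <- task_grad$mu_adv; g_ls <- task_grad$log_sigma_adv
  if (any(!is.finite(g_mu)) || any(!is.finite(g_ls)))
    stop(sprintf(
      "non-finite adversarial gradient (first offending channel: %d)",
      which(!is.finite(c(g_mu, g_ls)))[1L] %% length(g_mu)), call. = FALSE)
  dir_mu <- lam * g_mu
  dir_ls <- lam * g_ls
  if (!is.null(task_grad$consist)) {
    dir_mu <- dir_mu - task_grad$consist$mu_adv
    dir_ls <- dir_ls - task_grad$consist$log_sigma_adv
  }
  if (isTRUE(cfg$normalized)) {
    nrm <- sqrt(sum(dir_mu^2) + sum(dir_ls^2))
    if (nrm > 0) {
      dir_mu <- lam * dir_mu / nrm
      dir_ls <- lam * dir_ls / nrm
    }
  }
  adv$mu_adv <- adv$mu_adv + cfg$phi * dir_mu
  adv$log_sigma_adv <- adv$log_sigma_adv + cfg$phi * dir_ls
  adv
}

#' Batch feature-consistency loss
#'
#' Mean squared distance of the batch feature vectors from their batch
#' mean: `(1/N) * sum_i || z_i - z_bar ||^2`. Nonnegative, zero iff all
#' vectors coincide, and invariant to reordering. Equals the per-coordinate
#' population variance summed over coordinates.
#'
#' @param z numeric matrix `(N, D)`, one feature vector per row.
#' @return Nonnegative scalar.
#' @export
consistency_loss <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 1L) stop("`z` must contain at least one vector", call. = FALSE)
  zbar <- colMeans(z)
  mean(rowSums(sweep(z, 2, zbar)^2))
}

# gradient of consistency_loss wrt z (the mean-dependence cancels)
consistency_grad <- function(z) {
  zbar <- colMeans(z)
  2 * sweep(z, 2, zbar) / nrow(z)
}
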