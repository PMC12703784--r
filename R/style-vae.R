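# Stochastic style transfer in feature space. A small variational
# autoencoder is trained over style vectors (channel mean/sd descriptors);
# sampling its latent space yields novel plausible styles which are injected
# into content feature maps by moment injection. The four-term objective
# combines a content term, a style term, the KL regularizer and a style
# reconstruction term.

#' Construct a style variational autoencoder
#'
#' The encoder maps a style vector of width `2 * n_channels` to the mean and
#' log-variance of a Gaussian latent posterior; the decoder maps a latent
#' code back to a reconstructed style vector whose standard-deviation block
#' is forced nonnegative through a softplus. Both maps are two-hidden-layer
#' fully connected networks.
#'
#' @param n_channels number of feature channels the style vectors describe.
#' @param latent_dim latent dimensionality. Default 64.
#' @param hidden_width width of the hidden layers. Default 256.
#' @param seed integer seed for parameter initialization.
#' @return An object of class `"style_vae"`.
#' @export
style_vae <- function(n_channels, latent_dim = 64L, hidden_width = 256L,
                      seed = 1L) {
  s_dim <- 2L * as.integer(n_channels)
  params <- with_seed(seed, function() list(
    enc1 = linear_init(s_dim, hidden_width),
    enc2 = linear_init(hidden_width, hidden_width),
    enc_mu = linear_init(hidden_width, latent_dim, gain = 1),
    enc_lv = linear_init(hidden_width, latent_dim, gain = 1e-2),
    dec1 = linear_init(latent_dim, hidden_width),
    dec2 = linear_init(hidden_width, hidden_width),
    dec_out = linear_init(hidden_width, s_dim, gain = 1)
  ))
  structure(list(params = params, n_channels = as.integer(n_channels),
                 latent_dim = as.integer(latent_dim),
                 hidden_width = as.integer(hidden_width)),
            class = "style_vae")
}

#' @export
print.style_vae <- function(x, ...) {
  cat(sprintf(
    "Style VAE: style width %d (C = %d), latent %d, hidden %d\n",
    2L * x$n_channels, x$n_channels, x$latent_dim, x$hidden_width))
  invisible(x)
}

vae_flat_params <- function(vae) {
  out <- list()
  for (ly in names(vae$params)) {
    out[[paste0(ly, ".W")]] <- vae$params[[ly]]$W
    out[[paste0(ly, ".b")]] <- vae$params[[ly]]$b
  }
  out
}

vae_set_flat <- function(vae, flat) {
  for (ly in names(vae$params)) {
    vae$params[[ly]]$W <- flat[[paste0(ly, ".W")]]
    vae$params[[ly]]$b <- flat[[paste0(ly, ".b")]]
  }
  vae
}

# encoder forward with caches (internal)
enc_fwd <- function(vae, s) {
  p <- vae$params
  l1 <- linear_fwd(s, p$enc1); r1 <- relu_fwd(l1$out)
  l2 <- linear_fwd(r1$out, p$enc2); r2 <- relu_fwd(l2$out)
  mu <- linear_fwd(r2$out, p$enc_mu)
  lv <- linear_fwd(r2$out, p$enc_lv)
  list(xi = mu$out, log_var = lv$out,
       cache = list(l1 = l1, r1 = r1, l2 = l2, r2 = r2, mu = mu, lv = lv))
}

dec_fwd <- function(vae, z) {
  p <- vae$params
  l1 <- linear_fwd(z, p$dec1); r1 <- relu_fwd(l1$out)
  l2 <- linear_fwd(r1$out, p$dec2); r2 <- relu_fwd(l2$out)
  o <- linear_fwd(r2$out, p$dec_out)
  C <- vae$n_channels
  mu_hat <- o$out[, seq_len(C), drop = FALSE]
  sp <- softplus_fwd(o$out[, C + seq_len(C), drop = FALSE])
  list(mu_hat = mu_hat, sigma_hat = sp$out,
       cache = list(l1 = l1, r1 = r1, l2 = l2, r2 = r2, o = o, sp = sp))
}

#' Encode a style vector to its latent posterior
#'
#' Deterministic given the VAE parameters: returns the latent Gaussian
#' `N(xi, psi^2)`. Positivity of `psi` is structural -- the encoder emits a
#' log-variance and `psi = exp(log_var / 2)`.
#'
#' @param vae a [style_vae()] object.
#' @param s style-vector matrix `(batch, 2 * n_channels)`.
#' @return An object of class `"latent_style"`: list with matrices `xi`,
#'   `psi` and `log_var`, each `(batch, latent_dim)`.
#' @export
encode_style <- function(vae, s) {
  stopifnot(inherits(vae, "style_vae"))
  s <- as.matrix(s)
  if (ncol(s) != 2L * vae$n_channels)
    stop(sprintf("style vector width %d does not match the encoder input width %d",
                 ncol(s), 2L * vae$n_channels), call. = FALSE)
  e <- enc_fwd(vae, s)
  structure(list(xi = e$xi, log_var = e$log_var, psi = exp(e$log_var / 2)),
            class = "latent_style")
}

#' Draw a latent style code by the reparameterization trick
#'
#' Computes `z = xi + psi * noise` elementwise. With standard-normal noise
#' this is a draw from the latent posterior through which gradients flow.
#'
#' @param dist a `"latent_style"` object from [encode_style()].
#' @param noise numeric matrix `(batch, latent_dim)`; drawn i.i.d. standard
#'   normal when `NULL`.
#' @return Numeric matrix `(batch, latent_dim)`.
#' @export
sample_latent <- function(dist, noise = NULL) {
  stopifnot(inherits(dist, "latent_style"))
  if (is.null(noise))
    noise <- matrix(stats::rnorm(length(dist$xi)), nrow(dist$xi), ncol(dist$xi))
  noise <- as.matrix(noise)
  if (!identical(dim(noise), dim(dist$xi)))
    stop("`noise` must match the latent dimensions (batch, latent_dim)",
         call. = FALSE)
  dist$xi + dist$psi * noise
}

#' Decode a latent code to a reconstructed style vector
#'
#' Deterministic given the VAE parameters; the standard-deviation block of
#' the output is passed through a softplus so it is nonnegative for any
#' latent input.
#'
#' @param vae a [style_vae()] object.
#' @param z latent matrix `(batch, latent_dim)`.
#' @return Reconstructed style-vector matrix `(batch, 2 * n_channels)`.
#' @export
decode_style <- function(vae, z) {
  stopifnot(inherits(vae, "style_vae"))
  z <- as.matrix(z)
  if (ncol(z) != vae$latent_dim)
    stop(sprintf("latent width %d does not match the decoder input width %d",
                 ncol(z), vae$latent_dim), call. = FALSE)
  d <- dec_fwd(vae, z)
  cbind(d$mu_hat, d$sigma_hat)
}

## ---- loss terms ------------------------------------------------------------

#' Kullback-Leibler loss of the latent posterior
#'
#' Closed-form `D_KL(N(xi, psi^2) || N(0, I))`, summed over latent
#' dimensions and averaged over the batch:
#' `0.5 * sum(psi^2 + xi^2 - 1 - 2 log psi)`. Always nonnegative.
#'
#' @param dist a `"latent_style"` object (or a list with `xi` and `psi`).
#' @return Nonnegative scalar.
#' @export
kl_loss <- function(dist) {
  xi <- as.matrix(dist$xi); psi <- as.matrix(dist$psi)
  if (any(psi <= 0)) stop("`psi` must be strictly positive", call. = FALSE)
  mean(rowSums(0.5 * (psi^2 + xi^2 - 1 - 2 * log(psi))))
}

#' Style-vector reconstruction loss
#'
#' Squared Euclidean distance between the original and reconstructed style
#' vectors, averaged over the batch. Symmetric, and zero iff the two agree.
#'
#' @param s,s_hat style-vector matrices of equal shape.
#' @return Nonnegative scalar.
#' @export
reconstruction_loss <- function(s, s_hat) {
  s <- as.matrix(s); s_hat <- as.matrix(s_hat)
  if (!identical(dim(s), dim(s_hat)))
    stop("`s` and `s_hat` must have identical dimensions", call. = FALSE)
  mean(rowSums((s - s_hat)^2))
}

#' Content-preservation loss
#'
#' Mean squared error between the instance-normalized versions of the
#' stylized and the content feature maps. Because moment injection is an
#' affine per-channel map, this is zero (to numerical tolerance) whenever
#' `f_styl` is any moment injection of `f_content` -- the term measures
#' structural, style-invariant disagreement only.
#'
#' @param f_styl,f_content feature maps of equal shape.
#' @param eps stabilizer for the instance normalizations.
#' @return Nonnegative scalar.
#' @export
content_loss <- function(f_styl, f_content, eps = 1e-5) {
  fm_check(f_styl, "f_styl"); fm_check(f_content, "f_content")
  if (!identical(dim(f_styl), dim(f_content)))
    stop("`f_styl` and `f_content` must have identical shapes", call. = FALSE)
  d <- dim(f_styl)
  zeros <- matrix(0, d[1], d[2]); ones <- matrix(1, d[1], d[2])
  a <- inject_fwd(to_hwbc(f_styl), zeros, ones, eps)$out
  b <- inject_fwd(to_hwbc(f_content), zeros, ones, eps)$out
  mean((a - b)^2)
}

#' Style-approximation loss
#'
#' Mean squared error between the channel statistics of the stylized map and
#' the target statistics, over both the mean and the standard-deviation
#' blocks. Zero after an exact moment injection of the target.
#'
#' @param f_styl feature map.
#' @param target a `"channel_stats"` object with matching `(batch, channel)`.
#' @param eps stabilizer for the stylized map's statistics.
#' @return Nonnegative scalar.
#' @export
style_loss <- function(f_styl, target, eps = 1e-5) {
  fm_check(f_styl, "f_styl")
  stopifnot(inherits(target, "channel_stats"))
  d <- dim(f_styl)
  if (!identical(dim(target$mu), d[1:2]))
    stop("target statistics do not match the stylized map's (batch, channel)",
         call. = FALSE)
  st <- cs_fwd(to_hwbc(f_styl), eps)
  mean(c((st$mu - target$mu)^2, (st$sigma - target$sigma)^2))
}

#' Loss weights for the style-transfer objective
#'
#' Defaults are the grid-searched values: content weight `2e-4`, style
#' weight `1`, KL weight `1`, reconstruction weight `5`.
#'
#' @param lambda_content,lambda_s,lambda_KL,lambda_Rec nonnegative weights.
#' @return An object of class `"rain_weights"`.
#' @export
rain_weights <- function(lambda_content = 2e-4, lambda_s = 1,
                         lambda_KL = 1, lambda_Rec = 5) {
  w <- c(lambda_content = lambda_content, lambda_s = lambda_s,
         lambda_KL = lambda_KL, lambda_Rec = lambda_Rec)
  if (any(!is.finite(w)) || any(w < 0))
    stop("all loss weights must be finite and nonnegative", call. = FALSE)
  structure(as.list(w), class = "rain_weights")
}

#' Combined style-transfer training loss
#'
#' `lambda_content * L_c + lambda_s * L_s + lambda_KL * L_KL +
#'  lambda_Rec * L_Rec`.
#'
#' @param lc,ls,lkl,lrec finite scalar loss components.
#' @param w a [rain_weights()] object.
#' @return Scalar.
#' @export
rain_total_loss <- function(lc, ls, lkl, lrec, w = rain_weights()) {
  stopifnot(inherits(w, "rain_weights"))
  comps <- c(lc, ls, lkl, lrec)
  if (any(!is.finite(comps)))
    stop("all loss components must be finite", call. = FALSE)
  w$lambda_content * lc + w$lambda_s * ls + w$lambda_KL * lkl +
    w$lambda_Rec * lrec
}

#' Stochastic stylization of a content feature map
#'
#' The three-stage pipeline: summarize the style map into a style vector,
#' encode it to a latent Gaussian and sample a code by reparameterization,
#' decode the code to new channel statistics, and inject those statistics
#' into the content map. With fresh noise on every call the injected style
#' scatters around the decoded posterior mean.
#'
#' @param vae a [style_vae()] object.
#' @param content_f content feature map `(B, C, H, W)`.
#' @param style_f style feature map with the same channel count (spatial
#'   size may differ).
#' @param noise optional `(B, latent_dim)` matrix; standard normal draws
#'   when `NULL`.
#' @param eps moment stabilizer.
#' @return A list: `stylized` (feature map shaped like `content_f`),
#'   `dist` (the latent posterior), `z`, `s` (input style vectors), `s_hat`
#'   (decoded style vectors).
#' @export
rain_forward <- function(vae, content_f, style_f, noise = NULL, eps = 1e-5) {
  stopifnot(inherits(vae, "style_vae"))
  fm_check(content_f, "content_f"); fm_check(style_f, "style_f")
  if (dim(content_f)[2] != dim(style_f)[2])
    stop("content and style maps must have the same channel count",
         call. = FALSE)
  if (dim(content_f)[1] != dim(style_f)[1])
    stop("content and style maps must have the same batch size", call. = FALSE)
  s <- make_style_vector(compute_channel_stats(style_f, eps))
  dist <- encode_style(vae, s)
  z <- sample_latent(dist, noise)
  s_hat <- decode_style(vae, z)
  tgt <- split_style_vector(s_hat, eps)
  stylized <- moment_inject(content_f, tgt, eps)
  list(stylized = stylized, dist = dist, z = z, s = s, s_hat = s_hat)
}

## ---- exact gradients of the objective wrt the VAE parameters ---------------

# One forward/backward pass. `s` is the (batch, 2C) style-vector matrix;
# `content_f` is an internal-layout (h, w, batch, C) feature array or NULL,
# in which case the content and style terms are dropped (the VAE-only
# objective: KL + reconstruction). Returns the loss components and exact
# gradients for every VAE parameter.
vae_loss_grad <- function(vae, s, content_f = NULL, noise,
                          w = rain_weights(), eps = 1e-5) {
  C <- vae$n_channels
  B <- nrow(s)
  enc <- enc_fwd(vae, s)
  psi <- exp(enc$log_var / 2)
  z <- enc$xi + psi * noise
  dec <- dec_fwd(vae, z)
  s_hat <- cbind(dec$mu_hat, dec$sigma_hat)

  lkl <- mean(rowSums(0.5 * (psi^2 + enc$xi^2 - 1 - enc$log_var)))
  lrec <- mean(rowSums((s - s_hat)^2))

  lc <- 0; ls <- 0
  inj <- NULL; in_c <- NULL; st_out <- NULL
  mu_s <- s[, seq_len(C), drop = FALSE]
  sg_s <- s[, C + seq_len(C), drop = FALSE]
  if (!is.null(content_f)) {
    inj <- inject_fwd(content_f, dec$mu_hat, dec$sigma_hat, eps)
    st_out <- cs_fwd(inj$out, eps)
    ls <- mean(c((st_out$mu - mu_s)^2, (st_out$sigma - sg_s)^2))
    d <- dim(content_f)
    zeros <- matrix(0, d[3], d[4]); ones <- matrix(1, d[3], d[4])
    in_c <- inject_fwd(content_f, zeros, ones, eps)
    in_o <- inject_fwd(inj$out, zeros, ones, eps)
    lc <- mean((in_o$out - in_c$out)^2)
  }
  total <- rain_total_loss(lc, ls, lkl, lrec, w)

  ## backward
  ds_hat <- w$lambda_Rec * 2 * (s_hat - s) / B
  dmu_hat <- ds_hat[, seq_len(C), drop = FALSE]
  dsg_hat <- ds_hat[, C + seq_len(C), drop = FALSE]

  if (!is.null(content_f)) {
    # style term through the statistics of the injected map
    nst <- 2 * B * C
    dmu_o <- w$lambda_s * 2 * (st_out$mu - mu_s) / nst
    dsg_o <- w$lambda_s * 2 * (st_out$sigma - sg_s) / nst
    d_out <- cs_bwd(dmu_o, dsg_o, inj$out, st_out)
    # content term through the instance normalization of the injected map
    if (w$lambda_content > 0) {
      d <- dim(content_f)
      in_o <- inject_fwd(inj$out, matrix(0, d[3], d[4]),
                         matrix(1, d[3], d[4]), eps)
      dg <- w$lambda_content * 2 * (in_o$out - in_c$out) / length(in_o$out)
      d_out <- d_out + inject_bwd(dg, in_o$cache)$dx
    }
    ib <- inject_bwd(d_out, inj$cache)
    dmu_hat <- dmu_hat + ib$dmu_t
    dsg_hat <- dsg_hat + ib$dsigma_t
  }

  # decoder backward
  do_raw <- cbind(dmu_hat, softplus_bwd(dsg_hat, dec$cache$sp$cache))
  g <- list()
  bo <- linear_bwd(do_raw, vae$params$dec_out, dec$cache$o$cache)
  g[["dec_out.W"]] <- bo$dW; g[["dec_out.b"]] <- bo$db
  d2 <- relu_bwd(bo$dx, dec$cache$r2$cache)
  b2 <- linear_bwd(d2, vae$params$dec2, dec$cache$l2$cache)
  g[["dec2.W"]] <- b2$dW; g[["dec2.b"]] <- b2$db
  d1 <- relu_bwd(b2$dx, dec$cache$r1$cache)
  b1 <- linear_bwd(d1, vae$params$dec1, dec$cache$l1$cache)
  g[["dec1.W"]] <- b1$dW; g[["dec1.b"]] <- b1$db
  dz <- b1$dx

  # reparameterization + KL backward
  dxi <- dz + w$lambda_KL * enc$xi / B
  dpsi <- dz * noise + w$lambda_KL * psi / B
  dlv <- dpsi * psi / 2 - w$lambda_KL * 0.5 / B

  bmu <- linear_bwd(dxi, vae$params$enc_mu, enc$cache$mu$cache)
  g[["enc_mu.W"]] <- bmu$dW; g[["enc_mu.b"]] <- bmu$db
  blv <- linear_bwd(dlv, vae$params$enc_lv, enc$cache$lv$cache)
  g[["enc_lv.W"]] <- blv$dW; g[["enc_lv.b"]] <- blv$db
  dh2 <- relu_bwd(bmu$dx + blv$dx, enc$cache$r2$cache)
  be2 <- linear_bwd(dh2, vae$params$enc2, enc$cache$l2$cache)
  g[["enc2.W"]] <- be2$dW; g[["enc2.b"]] <- be2$db
  dh1 <- relu_bwd(be2$dx, enc$cache$r1$cache)
  be1 <- linear_bwd(dh1, vae$params$enc1, enc$cache$l1$cache)
  g[["enc1.W"]] <- be1$dW; g[["enc1.b"]] <- be1$db

  list(total = total, lc = lc, ls = ls, lkl = lkl, lrec = lrec,
       grads = g, s_hat = s_hat)
}

#' Train the style VAE
#'
#' Optimizes the style-transfer objective with Adam. `style_vectors` holds
#' one style descriptor per row; when `content_features` is supplied, each
#' step also routes the decoded statistics through a moment injection into a
#' random content batch so the content and style terms participate,
#' otherwise only the KL and reconstruction terms are active.
#'
#' @param vae a [style_vae()] object.
#' @param style_vectors matrix `(n, 2 * n_channels)` of style descriptors.
#' @param content_features optional 4-d array `(n_content, C, h, w)` of
#'   content feature maps.
#' @param weights a [rain_weights()] object.
#' @param n_iter number of optimization steps.
#' @param lr Adam learning rate.
#' @param batch_size rows sampled per step.
#' @param seed integer seed controlling batch order and sampling noise.
#' @param eps moment stabilizer.
#' @return The trained `"style_vae"` with a `trace` data frame (per-step
#'   loss components) attached.
#' @export
train_style_vae <- function(vae, style_vectors, content_features = NULL,
                            weights = rain_weights(), n_iter = 1000L,
                            lr = 1e-3, batch_size = 16L, seed = 1L,
                            eps = 1e-5) {
  stopifnot(inherits(vae, "style_vae"))
  style_vectors <- as.matrix(style_vectors)
  if (ncol(style_vectors) != 2L * vae$n_channels)
    stop("style vector width does not match the encoder input", call. = FALSE)
  n <- nrow(style_vectors)
  if (!is.null(content_features))
    content_features <- to_hwbc(content_features)
  nc <- if (is.null(content_features)) 0L else dim(content_features)[3]
  flat <- vae_flat_params(vae)
  st <- opt_adam_init(flat)
  trace <- matrix(NA_real_, n_iter, 5,
                  dimnames = list(NULL, c("total", "lc", "ls", "lkl", "lrec")))
  with_seed(seed, function() {
    for (it in seq_len(n_iter)) {
      idx <- if (n > batch_size) sample.int(n, batch_size) else seq_len(n)
      s <- style_vectors[idx, , drop = FALSE]
      cf <- NULL
      if (nc > 0L) {
        ci <- sample.int(nc, length(idx), replace = nc < length(idx))
        cf <- content_features[, , ci, , drop = FALSE]
      }
      noise <- matrix(stats::rnorm(length(idx) * vae$latent_dim),
                      length(idx), vae$latent_dim)
      vae_now <- vae_set_flat(vae, flat)
      res <- vae_loss_grad(vae_now, s, cf, noise, weights, eps)
      if (!is.finite(res$total))
        stop(sprintf("style VAE training diverged at step %d", it),
             call. = FALSE)
      trace[it, ] <<- c(res$total, res$lc, res$ls, res$lkl, res$lrec)
      upd <- opt_adam_step(flat, res$grads, st, lr)
      flat <<- upd$params; st <<- upd$state
    }
  })
  out <- vae_set_flat(vae, flat)
  out$trace <- as.data.frame(trace)
  out
}
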