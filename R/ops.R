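# Internal array primitives. Feature maps travel internally as
# (row, col, batch, channel): with R's column-major storage the spatial
# block of every (batch, channel) pair is contiguous, so im2col patches,
# per-pixel matrices for the classifier head / cross-entropy, and
# channel-moment reductions are all plain `dim<-` reshapes with no data
# movement. The public API speaks (batch, channel, row, col); adapters at
# the boundary convert. All layers come as fwd/bwd pairs so the training
# loops chain exact gradients without an autodiff framework.

fm_check <- function(f, arg = "f") {
  if (!is.array(f) || length(dim(f)) != 4L)
    stop(sprintf("`%s` must be a 4-d array (batch, channel, row, col)", arg),
         call. = FALSE)
  if (anyNA(f) || !all(is.finite(f))) {
    bad <- which(!is.finite(f))[1L]
    idx <- arrayInd(bad, dim(f))
    stop(sprintf("`%s` has a non-finite value at (b=%d, c=%d, i=%d, j=%d)",
                 arg, idx[1], idx[2], idx[3], idx[4]), call. = FALSE)
  }
  invisible(f)
}

# public (B, C, H, W)  <->  internal (H, W, B, C)
to_hwbc <- function(f) aperm(f, c(3, 4, 1, 2))
to_bchw <- function(f) aperm(f, c(3, 4, 1, 2))

# run `fn()` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

## ---- 3x3 convolution (pad 1) via im2col + one GEMM -------------------------
## weights: (c_out, c_in * 9), kernel-offset-major / channel-minor columns

conv_init <- function(c_in, c_out, stride = 1L, gain = sqrt(2)) {
  fan_in <- c_in * 9L
  list(W = matrix(stats::rnorm(c_out * fan_in, sd = gain / sqrt(fan_in)),
                  c_out, fan_in),
       b = numeric(c_out),
       stride = as.integer(stride))
}

# Training loops pass a workspace environment `ws`: the large im2col,
# gradient-column and input-gradient intermediates are then allocated once
# (with their final shapes) and refilled in place each iteration, which
# keeps the garbage collector out of the hot loop. The same BLAS kernels
# run in both modes, so workspace and plain calls are bitwise identical.
ws_buf <- function(ws, name, dims) {
  b <- ws[[name]]
  if (is.null(b)) {
    b <- array(0, dims)
    ws[[name]] <- b
  }
  b
}

conv_fwd <- function(x, par, ws = NULL, key = NULL) {
  d <- dim(x); H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  s <- par$stride
  Ho <- (H - 1L) %/% s + 1L
  Wo <- (W - 1L) %/% s + 1L
  N <- Ho * Wo * B
  Cout <- nrow(par$W)
  if (is.null(ws)) {
    M <- matrix(0, N, C * 9L)
    out <- array(0, c(Ho, Wo, B, Cout))
  } else {
    M <- ws_buf(ws, paste0(key, ".M"), c(N, C * 9L))
    out <- ws_buf(ws, paste0(key, ".out"), c(Ho, Wo, B, Cout))
  }
  cpp_im2col_into(M, x, H, W, B, C, s)
  cpp_gemm_abt_into(M, N, C * 9L, par$W, par$b, out)
  list(out = out,
       cache = list(M = M, dims = c(H, W, B, C, Ho, Wo), stride = s))
}

conv_bwd <- function(dout, par, cache, want_dx = TRUE, want_dW = TRUE,
                     ws = NULL, key = NULL) {
  dm <- cache$dims
  H <- dm[1]; W <- dm[2]; B <- dm[3]; C <- dm[4]; Ho <- dm[5]; Wo <- dm[6]
  N <- Ho * Wo * B
  Cout <- nrow(par$W)
  dW <- if (want_dW) cpp_gemm_atb(dout, N, Cout, cache$M, C * 9L) else NULL
  db <- if (want_dW) cpp_colsums(dout, N, Cout) else NULL
  dx <- NULL
  if (want_dx) {
    if (is.null(ws)) {
      dM <- matrix(0, N, C * 9L)
      dx <- array(0, c(H, W, B, C))
    } else {
      dM <- ws_buf(ws, paste0(key, ".dM"), c(N, C * 9L))
      dx <- ws_buf(ws, paste0(key, ".dx"), c(H, W, B, C))
    }
    cpp_gemm_ab_into(dout, N, Cout, par$W, dM)
    cpp_col2im_into(dx, dM, H, W, B, C, cache$stride)
  }
  list(dx = dx, dW = dW, db = db)
}

## ---- 1x1 convolution (channel mixing) -------------------------------------

conv1x1_init <- function(c_in, c_out, gain = 1) {
  list(W = matrix(stats::rnorm(c_out * c_in, sd = gain / sqrt(c_in)),
                  c_out, c_in),
       b = numeric(c_out))
}

conv1x1_fwd <- function(x, par) {
  d <- dim(x)
  N <- d[1] * d[2] * d[3]
  xm <- x
  dim(xm) <- c(N, d[4])
  out <- xm %*% t(par$W) + rep(par$b, each = N)
  dim(out) <- c(d[1], d[2], d[3], nrow(par$W))
  list(out = out, cache = list(xm = xm, dims = d))
}

conv1x1_bwd <- function(dout, par, cache) {
  d <- cache$dims
  N <- d[1] * d[2] * d[3]
  dmat <- dout
  dim(dmat) <- c(N, nrow(par$W))
  dx <- dmat %*% par$W
  dim(dx) <- d
  list(dx = dx, dW = crossprod(dmat, cache$xm), db = colSums(dmat))
}

## ---- pointwise and pooling layers -----------------------------------------

relu_fwd <- function(x) {
  out <- cpp_relu_fwd(x)
  dim(out) <- dim(x)
  list(out = out, cache = x)
}
relu_bwd <- function(dout, cache) {
  dx <- cpp_relu_bwd(dout, cache)
  dim(dx) <- dim(dout)
  dx
}

softplus_fwd <- function(x) {
  out <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  list(out = out, cache = x)
}
softplus_bwd <- function(dout, cache) dout * stats::plogis(cache)

upsample_nearest <- function(x, factor) {
  d <- dim(x)
  out <- cpp_upsample(x, d[1], d[2], d[3] * d[4], factor)
  dim(out) <- c(d[1] * factor, d[2] * factor, d[3], d[4])
  out
}

upsample_nearest_bwd <- function(dout, factor) {
  d <- dim(dout)
  out <- cpp_upsample_bwd(dout, d[1], d[2], d[3] * d[4], factor)
  dim(out) <- c(d[1] %/% factor, d[2] %/% factor, d[3], d[4])
  out
}

# (H, W, B, C) -> (B, C) spatial means
global_avgpool <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

global_avgpool_bwd <- function(dz, spatial) {
  n <- spatial[1] * spatial[2]
  array(rep(as.vector(dz), each = n),
        c(spatial[1], spatial[2], dim(dz))) / n
}

## ---- per-sample per-channel moments and moment injection -------------------
## moment arrays are (B, C); feature maps (H, W, B, C)

# population variance over spatial positions; eps enters inside the sqrt so
# constant channels get sigma = eps instead of zero
cs_fwd <- function(f, eps) {
  d <- dim(f); n <- d[1] * d[2]
  m <- f
  dim(m) <- c(n, d[3] * d[4])
  mu <- colMeans(m)
  v <- colMeans(m * m) - mu * mu
  v[v < 0] <- 0
  sigma <- sqrt(v + eps * eps)
  list(mu = matrix(mu, d[3], d[4]), sigma = matrix(sigma, d[3], d[4]),
       n = n)
}

# backward of (mu, sigma) with respect to f
cs_bwd <- function(dmu, dsigma, f, stats) {
  d <- dim(f); n <- stats$n
  mu_f <- rep(as.vector(stats$mu), each = n)
  adj <- rep(as.vector(dsigma / (n * stats$sigma)), each = n)
  out <- rep(as.vector(dmu / n), each = n) + adj * (as.vector(f) - mu_f)
  dim(out) <- d
  out
}

# out = sigma_t * (f - mu(f)) / sigma(f) + mu_t, target stats (B, C)
inject_fwd <- function(f, mu_t, sigma_t, eps) {
  d <- dim(f); n <- d[1] * d[2]; BC <- d[3] * d[4]
  r <- cpp_inject_fwd(f, n, BC, as.numeric(mu_t), as.numeric(sigma_t), eps)
  out <- r$out
  dim(out) <- d
  list(out = out,
       cache = list(xhat = r$xhat,
                    stats = list(mu = matrix(r$mu, d[3], d[4]),
                                 sigma = matrix(r$sigma, d[3], d[4]),
                                 n = n),
                    sigma_t = sigma_t, dims = d))
}

# gradients wrt the content map and the injected target statistics
inject_bwd <- function(dout, cache) {
  d <- cache$dims; n <- d[1] * d[2]; BC <- d[3] * d[4]
  r <- cpp_inject_bwd(dout, cache$xhat, n, BC,
                      as.numeric(cache$stats$sigma),
                      as.numeric(cache$sigma_t))
  dx <- r$dx
  dim(dx) <- d
  list(dx = dx, dmu_t = matrix(r$dmu_t, d[3], d[4]),
       dsigma_t = matrix(r$dsigma_t, d[3], d[4]))
}

## ---- dense layers ----------------------------------------------------------

linear_init <- function(n_in, n_out, gain = sqrt(2)) {
  list(W = matrix(stats::rnorm(n_out * n_in, sd = gain / sqrt(n_in)),
                  n_out, n_in),
       b = numeric(n_out))
}

linear_fwd <- function(x, par) {
  out <- x %*% t(par$W) + rep(par$b, each = nrow(x))
  list(out = out, cache = x)
}

linear_bwd <- function(dout, par, cache) {
  list(dx = dout %*% par$W, dW = crossprod(dout, cache), db = colSums(dout))
}

## ---- softmax cross-entropy over pixels with an ignore label ----------------
## scores (H, W, B, K), labels (H, W, B)

ce_fwd <- function(scores, labels, ignore = 255L) {
  d <- dim(scores); K <- d[4]
  N <- d[1] * d[2] * d[3]
  sm <- scores
  dim(sm) <- c(N, K)
  r <- cpp_ce(sm, as.integer(labels) + 1L, ignore + 1L)
  if (is.na(r$loss))
    stop("task loss undefined: every pixel carries the ignore label",
         call. = FALSE)
  list(loss = r$loss, cache = list(grad = r$grad, dims = d))
}

ce_bwd <- function(cache) {
  g <- cache$grad
  dim(g) <- cache$dims
  g
}

## ---- optimizers over flat named lists of parameter arrays ------------------

opt_adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

opt_adam_step <- function(params, grads, st, lr,
                          b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

opt_sgd_step <- function(params, grads, lr) {
  for (nm in names(grads)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  params
}
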