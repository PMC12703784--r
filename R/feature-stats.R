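#' Per-sample, per-channel feature moments
#'
#' Computes instance-normalization statistics of a batched feature map: for
#' every sample `b` and channel `c`, the mean and standard deviation of the
#' activations over the spatial positions only (never across the batch).
#' The variance uses the population convention (divide by `H * W`) and the
#' stabilizer enters inside the square root, `sigma = sqrt(var + eps^2)`,
#' so a constant channel gets `sigma = eps` rather than zero. Degenerate
#' `1 x 1` spatial maps are allowed; their sigma is `eps` by construction.
#'
#' @param f numeric 4-d array `(batch, channel, row, col)`; all values must
#'   be finite.
#' @param eps small positive stabilizer added inside the square root.
#'   Default `1e-5`.
#' @return An object of class `"channel_stats"`: a list with matrices `mu`
#'   and `sigma`, each `(batch, channel)`, and the `eps` used.
#' @examples
#' f <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
#' st <- compute_channel_stats(f)
#' dim(st$mu)
#' @seealso [moment_inject()], [make_style_vector()]
#' @export
compute_channel_stats <- function(f, eps = 1e-5) {
  fm_check(f, "f")
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("`eps` must be a single positive number", call. = FALSE)
  st <- cs_fwd(to_hwbc(f), eps)
  structure(list(mu = st$mu, sigma = st$sigma, eps = eps),
            class = "channel_stats")
}

#' @export
print.channel_stats <- function(x, ...) {
  cat(sprintf("Channel statistics: %d sample(s) x %d channel(s)\n",
              nrow(x$mu), ncol(x$mu)))
  cat(sprintf("  mu in [%.4g, %.4g], sigma in [%.4g, %.4g]\n",
              min(x$mu), max(x$mu), min(x$sigma), max(x$sigma)))
  invisible(x)
}

#' Build channel statistics from explicit moment matrices
#'
#' @param mu,sigma numeric `(batch, channel)` matrices; `sigma` must be
#'   nonnegative.
#' @param eps stabilizer recorded on the object.
#' @return A `"channel_stats"` object.
#' @export
as_channel_stats <- function(mu, sigma, eps = 1e-5) {
  mu <- as.matrix(mu); sigma <- as.matrix(sigma)
  if (!identical(dim(mu), dim(sigma)))
    stop("`mu` and `sigma` must have identical dimensions", call. = FALSE)
  if (any(sigma < 0)) stop("`sigma` must be nonnegative", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, eps = eps), class = "channel_stats")
}

#' Concatenate channel moments into a style vector
#'
#' Builds the per-sample style descriptor `s = [mu; sigma]`: for each sample
#' the channel means followed by the channel standard deviations, giving a
#' `(batch, 2 * channels)` matrix. The operation is inverted losslessly by
#' [split_style_vector()].
#'
#' @param stats a `"channel_stats"` object from [compute_channel_stats()].
#' @return Numeric matrix `(batch, 2 * channels)`.
#' @export
make_style_vector <- function(stats) {
  stopifnot(inherits(stats, "channel_stats"))
  cbind(stats$mu, stats$sigma)
}

#' Split a style vector back into channel moments
#'
#' @param s numeric matrix `(batch, 2 * channels)`; the first half of each
#'   row is the mean block, the second half the (nonnegative) standard
#'   deviation block.
#' @param eps stabilizer recorded on the resulting object.
#' @return A `"channel_stats"` object.
#' @rdname make_style_vector
#' @export
split_style_vector <- function(s, eps = 1e-5) {
  s <- as.matrix(s)
  if (ncol(s) %% 2L != 0L)
    stop("a style vector must have an even number of columns", call. = FALSE)
  C <- ncol(s) %/% 2L
  as_channel_stats(s[, seq_len(C), drop = FALSE],
                   s[, C + seq_len(C), drop = FALSE], eps)
}

#' Inject target channel moments into a content feature map
#'
#' The adaptive-instance-normalization transform: the content map is
#' instance-normalized with its own per-channel moments and re-scaled and
#' re-centered with the target statistics,
#' `out = sigma_t * (f - mu(f)) / sigma(f) + mu_t`, channel by channel.
#' When the content's per-channel variance is well above `eps^2`, the output's
#' channel statistics equal the target statistics to numerical tolerance, and
#' the operation is idempotent for a fixed target.
#'
#' @param content numeric 4-d array `(batch, channel, row, col)`.
#' @param target a `"channel_stats"` object whose `(batch, channel)` shape
#'   matches the content map.
#' @param eps stabilizer for the content normalization. Default `1e-5`.
#' @return A 4-d array shaped like `content`.
#' @examples
#' f <- array(rnorm(1 * 2 * 8 * 8), c(1, 2, 8, 8))
#' tgt <- as_channel_stats(matrix(10, 1, 2), matrix(2, 1, 2))
#' out <- moment_inject(f, tgt)
#' compute_channel_stats(out)$mu     # ~10
#' @export
moment_inject <- function(content, target, eps = 1e-5) {
  fm_check(content, "content")
  stopifnot(inherits(target, "channel_stats"))
  d <- dim(content)
  if (!identical(dim(target$mu), d[1:2]))
    stop(sprintf(
      "target statistics are (%d, %d) but the content map has (batch=%d, channel=%d)",
      nrow(target$mu), ncol(target$mu), d[1], d[2]), call. = FALSE)
  to_bchw(inject_fwd(to_hwbc(content), target$mu, target$sigma, eps)$out)
}
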