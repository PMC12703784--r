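make_vae <- function(C = 4, D = 6, hidden = 32, seed = 1)
  style_vae(C, latent_dim = D, hidden_width = hidden, seed = seed)

test_that("encoding is deterministic with structurally positive psi", {
  vae <- make_vae()
  s <- matrix(rnorm(3 * 8), 3, 8)
  d1 <- encode_style(vae, s)
  d2 <- encode_style(vae, s)
  expect_identical(d1, d2)
  expect_true(all(d1$psi > 0))
  # stays finite for large inputs
  big <- matrix(runif(2 * 8, -1e3, 1e3), 2, 8)
  db <- encode_style(vae, big)
  expect_true(all(is.finite(db$xi)) && all(is.finite(db$psi)))
  expect_error(encode_style(vae, matrix(0, 1, 6)), "width")
})

test_that("reparameterized sampling is z = xi + psi * noise exactly", {
  vae <- make_vae()
  dist <- encode_style(vae, matrix(rnorm(2 * 8), 2, 8))
  expect_equal(sample_latent(dist, matrix(0, 2, 6)), dist$xi)
  unit <- structure(list(xi = matrix(0, 2, 6), psi = matrix(1, 2, 6)),
                    class = "latent_style")
  eps <- matrix(rnorm(12), 2, 6)
  expect_equal(sample_latent(unit, eps), eps)
  expect_error(sample_latent(dist, matrix(0, 2, 5)), "latent")
  # Monte-Carlo: empirical moments track (xi, psi) within 3 standard errors
  set.seed(9)
  n <- 1e4
  one <- structure(list(xi = matrix(1.5, 1, 1), psi = matrix(0.7, 1, 1)),
                   class = "latent_style")
  z <- vapply(seq_len(n), function(i)
    sample_latent(one, matrix(rnorm(1), 1, 1))[1, 1], numeric(1))
  expect_lt(abs(mean(z) - 1.5), 3 * 0.7 / sqrt(n))
  expect_lt(abs(sd(z) - 0.7), 3 * 0.7 / sqrt(2 * n))
})

test_that("decoded style vectors always carry a nonnegative sigma block", {
  vae <- make_vae()
  z <- matrix(rnorm(5 * 6, sd = 5), 5, 6)
  s_hat <- decode_style(vae, z)
  expect_identical(dim(s_hat), c(5L, 8L))
  expect_true(all(s_hat[, 5:8] >= 0))
  expect_identical(decode_style(vae, z), s_hat)
  expect_error(decode_style(vae, matrix(0, 1, 3)), "width")
})

test_that("KL loss matches its closed form and is nonnegative", {
  mk <- function(xi, psi)
    structure(list(xi = as.matrix(xi), psi = as.matrix(psi)),
              class = "latent_style")
  expect_equal(kl_loss(mk(0, 1)), 0)
  expect_equal(kl_loss(mk(1, 1)), 0.5)
  expect_error(kl_loss(mk(0, -1)), "positive")
  set.seed(10)
  for (i in 1:10) {
    d <- mk(matrix(rnorm(6), 2), matrix(exp(rnorm(6)), 2))
    expect_gte(kl_loss(d), 0)
  }
})

test_that("reconstruction loss is a symmetric batch-averaged squared distance", {
  expect_equal(reconstruction_loss(matrix(c(1, 2), 1), matrix(c(1, 4), 1)), 4)
  s <- matrix(rnorm(6), 2, 3); sh <- matrix(rnorm(6), 2, 3)
  expect_equal(reconstruction_loss(s, sh), reconstruction_loss(sh, s))
  expect_equal(reconstruction_loss(s, s), 0)
  expect_error(reconstruction_loss(s, matrix(0, 2, 2)), "dimensions")
})

test_that("content loss vanishes under moment injection and matches a loop oracle", {
  set.seed(12)
  f <- rand_fm(1, 2, 6, 6)
  expect_equal(content_loss(f, f), 0)
  tgt <- as_channel_stats(matrix(rnorm(2), 1), matrix(exp(rnorm(2)), 1))
  expect_lt(content_loss(moment_inject(f, tgt), f), 1e-8)
  # hand loop on 2x2 instance-normalized maps
  a <- rand_fm(1, 1, 2, 2); b <- rand_fm(1, 1, 2, 2)
  innorm <- function(x) {
    v <- as.vector(x)
    (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-10)
  }
  expect_equal(content_loss(a, b), mean((innorm(a) - innorm(b))^2),
               tolerance = 1e-6)
})

test_that("style loss measures the gap to the target moments", {
  set.seed(13)
  f <- rand_fm(1, 3, 5, 5)
  expect_lt(style_loss(f, compute_channel_stats(f)), 1e-12)
  tgt <- as_channel_stats(matrix(rnorm(3), 1), matrix(exp(rnorm(3)), 1))
  expect_lt(style_loss(moment_inject(f, tgt), tgt), 1e-8)
  # scalar case: mu gap 1, sigma gap 2, C = 1 -> (1 + 4) / 2
  g <- array(c(0, 0, 0, 0), c(1, 1, 2, 2))
  st <- compute_channel_stats(g)
  tg <- as_channel_stats(st$mu + 1, st$sigma + 2)
  expect_equal(style_loss(g, tg), (1 + 4) / 2, tolerance = 1e-12)
})

test_that("the combined objective weights its four terms as specified", {
  expect_equal(rain_total_loss(3, 9, 9, 9, rain_weights(1, 0, 0, 0)), 3)
  expect_equal(rain_total_loss(1, 1, 1, 1, rain_weights(1, 1, 1, 1)), 4)
  # grid-searched weights (2e-4, 1, 1, 5) on unit components
  expect_equal(rain_total_loss(1, 1, 1, 1, rain_weights()), 7.0002)
  expect_error(rain_weights(lambda_s = -1), "nonnegative")
  expect_error(rain_total_loss(NaN, 0, 0, 0), "finite")
})

test_that("the stylization pipeline is stochastic with well-formed outputs", {
  set.seed(14)
  vae <- make_vae(C = 3)
  content <- rand_fm(2, 3, 8, 8)
  style <- rand_fm(2, 3, 6, 6)
  r1 <- rain_forward(vae, content, style)
  expect_identical(dim(r1$stylized), dim(content))
  # zero noise is deterministic; fresh noise disperses the injected moments
  z0 <- rain_forward(vae, content, style, noise = matrix(0, 2, 6))
  z0b <- rain_forward(vae, content, style, noise = matrix(0, 2, 6))
  expect_identical(z0$stylized, z0b$stylized)
  sig_draws <- replicate(20, {
    r <- rain_forward(vae, content, style)
    compute_channel_stats(r$stylized)$sigma[1, 1]
  })
  expect_gt(var(sig_draws), 0)
  expect_error(rain_forward(vae, content, rand_fm(2, 2, 6, 6)), "channel")
})

test_that("objective gradients flow to the VAE parameters and feature inputs", {
  set.seed(15)
  vae <- make_vae(C = 2, D = 3, hidden = 8)
  s <- matrix(rnorm(2 * 4), 2, 4); s[, 3:4] <- abs(s[, 3:4]) + 0.3
  cf <- array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2))   # internal layout
  noise <- matrix(rnorm(6), 2, 3)
  res <- weedseg:::vae_loss_grad(vae, s, cf, noise, rain_weights())
  expect_true(all(vapply(res$grads, function(g) all(is.finite(g)), TRUE)))
  expect_gt(sum(vapply(res$grads, function(g) sum(abs(g)), 0)), 0)
  # finite differences on two random parameters
  flat <- weedseg:::vae_flat_params(vae)
  h <- 1e-5
  for (nm in c("dec_out.W", "enc1.W")) {
    i <- sample(length(flat[[nm]]), 1)
    f2 <- flat; f2[[nm]][i] <- f2[[nm]][i] + h
    up <- weedseg:::vae_loss_grad(weedseg:::vae_set_flat(vae, f2), s, cf,
                                  noise, rain_weights())$total
    f2[[nm]][i] <- f2[[nm]][i] - 2 * h
    dn <- weedseg:::vae_loss_grad(weedseg:::vae_set_flat(vae, f2), s, cf,
                                  noise, rain_weights())$total
    expect_equal(res$grads[[nm]][i], (up - dn) / (2 * h), tolerance = 1e-4)
  }
  # content/style losses respond to their feature inputs at generic points
  fs <- rand_fm(1, 2, 4, 4); fc <- rand_fm(1, 2, 4, 4)
  g_fd <- (content_loss(fs + 1e-4, fc) - content_loss(fs - 1e-4, fc)) / 2e-4
  expect_true(is.finite(g_fd))
})

test_that("VAE training reduces its objective on a small style pool", {
  set.seed(16)
  sv <- cbind(matrix(rnorm(20 * 4), 20, 4),
              matrix(exp(rnorm(20 * 4)), 20, 4))
  vae <- style_vae(4, latent_dim = 6, hidden_width = 32, seed = 2)
  fit <- train_style_vae(vae, sv, n_iter = 300, lr = 3e-3, batch_size = 8,
                         seed = 3)
  tr <- fit$trace$total
  expect_lt(mean(tail(tr, 30)), mean(head(tr, 30)))
  # fixed seed reproducibility of the trained parameters
  fit2 <- train_style_vae(vae, sv, n_iter = 300, lr = 3e-3, batch_size = 8,
                          seed = 3)
  expect_identical(fit$params, fit2$params)
})
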