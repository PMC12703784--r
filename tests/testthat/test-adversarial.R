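test_that("adversarial normalization shares the moment-injection algebra", {
  set.seed(21)
  x <- rand_fm(2, 3, 5, 5)
  adv <- adversarial_stats(3, init_mu = c(1, -1, 0),
                           init_log_sigma = c(0, 0.5, -0.5))
  tgt <- as_channel_stats(
    matrix(c(1, -1, 0), 2, 3, byrow = TRUE),
    matrix(exp(c(0, 0.5, -0.5)), 2, 3, byrow = TRUE))
  expect_equal(adversarial_normalize(x, adv), moment_inject(x, tgt))
  # identity when the statistics equal the sample's own moments (B = 1)
  x1 <- rand_fm(1, 2, 6, 6)
  st <- compute_channel_stats(x1)
  advi <- adversarial_stats(2, init_mu = st$mu[1, ],
                            init_log_sigma = log(st$sigma[1, ]))
  expect_equal(adversarial_normalize(x1, advi), x1, tolerance = 1e-6)
  # whitening defaults produce unit moments
  st0 <- compute_channel_stats(adversarial_normalize(x, adversarial_stats(3)))
  expect_equal(st0$mu, matrix(0, 2, 3), tolerance = 1e-10)
  expect_equal(st0$sigma, matrix(1, 2, 3), tolerance = 1e-4)
  expect_error(adversarial_normalize(x, adversarial_stats(5)), "channels")
})

test_that("the gradient reversal layer is identity forward and flips gradients", {
  x <- rand_fm(1, 2, 3, 3, seed = 22)
  expect_identical(grl(x, 0.7), x)                # bitwise identity forward
  g <- array(rnorm(length(x)), dim(x))
  expect_equal(grl_backward(g, 0), 0 * g)         # lambda 0 kills the signal
  expect_equal(grl_backward(g, 1), -g)
  expect_error(grl(x, -1), "nonnegative")

  # contract against central finite differences: for a scalar loss of the
  # adversarially normalized features, the gradient through the reversal
  # equals minus lambda times the plain gradient
  set.seed(23)
  adv <- adversarial_stats(2, init_mu = rnorm(2), init_log_sigma = rnorm(2) / 4)
  wts <- array(rnorm(length(x)), dim(x))
  loss_of <- function(a) sum(wts * adversarial_normalize(x, a))
  fwd <- weedseg:::adv_normalize_fwd(weedseg:::to_hwbc(x), adv, 1e-5)
  bwd <- weedseg:::adv_normalize_bwd(weedseg:::to_hwbc(wts), adv, fwd$cache)
  h <- 1e-3
  for (lam in c(0.5, 1, 2)) {
    for (i in 1:2) {
      a2 <- adv; a2$mu_adv[i] <- a2$mu_adv[i] + h; up <- loss_of(a2)
      a2$mu_adv[i] <- a2$mu_adv[i] - 2 * h; dn <- loss_of(a2)
      fd <- (up - dn) / (2 * h)
      expect_equal(grl_backward(bwd$dmu_adv, lam)[i], -lam * fd,
                   tolerance = 1e-5)
    }
  }
})

test_that("the adversarial update ascends the task loss", {
  cfg <- grl_config(lambda_grl = 1, phi = 0.05)
  adv <- adversarial_stats(2, init_mu = c(0.2, -0.1))
  # zero gradient (or a vanishing step) leaves the statistics unchanged
  zero <- list(mu_adv = c(0, 0), log_sigma_adv = c(0, 0))
  expect_identical(dgb_step(adv, zero, cfg), adv)
  tiny <- grl_config(lambda_grl = 1, phi = 1e-12)
  g <- list(mu_adv = c(1, 1), log_sigma_adv = c(1, 1))
  expect_equal(dgb_step(adv, g, tiny)$mu_adv, adv$mu_adv, tolerance = 1e-10)
  # quadratic toy loss L(mu) = sum((mu - a)^2): one reversed step must
  # strictly increase it
  a <- c(1, 2)
  L <- function(s) sum((s$mu_adv - a)^2)
  grad <- list(mu_adv = 2 * (adv$mu_adv - a), log_sigma_adv = c(0, 0))
  expect_gt(L(dgb_step(adv, grad, cfg)), L(adv))
  expect_error(dgb_step(adv, list(mu_adv = c(NaN, 0),
                                  log_sigma_adv = c(0, 0)), cfg),
               "non-finite")
})

test_that("the reversal schedule ramps over the first tenth of training", {
  cfg <- grl_config(lambda_grl = 2, schedule = "linear-ramp")
  expect_equal(weedseg:::grl_coefficient(cfg, 50, 1000), 1)    # halfway up
  expect_equal(weedseg:::grl_coefficient(cfg, 100, 1000), 2)
  expect_equal(weedseg:::grl_coefficient(cfg, 900, 1000), 2)
  cfg2 <- grl_config(lambda_grl = 2)
  expect_equal(weedseg:::grl_coefficient(cfg2, 1, 1000), 2)
})

test_that("consistency loss is the spread around the batch mean", {
  expect_equal(consistency_loss(rbind(c(0, 0), c(2, 0))), 1)
  z <- matrix(rnorm(40), 8, 5)
  expect_equal(consistency_loss(z[sample(8), ]), consistency_loss(z))
  expect_equal(consistency_loss(matrix(3, 4, 2)), 0)
  # algebraic identity: equals the summed per-coordinate population variance
  pv <- sum(apply(z, 2, function(v) mean((v - mean(v))^2)))
  expect_equal(consistency_loss(z), pv, tolerance = 1e-12)
  expect_error(consistency_loss(matrix(0, 0, 2)), "at least one")
})
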