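test_that("channel statistics follow the population convention with eps inside the root", {
  eps <- 1e-5
  # constant map: variance 0, sigma collapses to eps
  f <- array(7, c(1, 1, 3, 3))
  st <- compute_channel_stats(f, eps)
  expect_equal(st$mu[1, 1], 7)
  expect_equal(st$sigma[1, 1], eps)

  # single channel [1, 2, 3, 4]: mean 2.5, population variance 1.25
  f <- array(c(1, 2, 3, 4), c(1, 1, 2, 2))
  st <- compute_channel_stats(f, eps)
  expect_equal(st$mu[1, 1], 2.5)
  expect_equal(st$sigma[1, 1]^2 - eps^2, 1.25, tolerance = 1e-12)

  # 1x1 spatial maps are legal and degenerate to sigma = eps
  st <- compute_channel_stats(array(3, c(2, 2, 1, 1)), eps)
  expect_true(all(st$sigma == eps))
})

test_that("statistics are invariant to spatial permutation and match a loop oracle", {
  set.seed(11)
  f <- rand_fm(2, 3, 4, 5)
  st <- compute_channel_stats(f)
  # any spatial permutation leaves the moments unchanged
  perm <- sample(20)
  fp <- f
  for (b in 1:2) for (ch in 1:3) {
    v <- as.vector(f[b, ch, , ])[perm]
    fp[b, ch, , ] <- array(v, c(4, 5))
  }
  stp <- compute_channel_stats(fp)
  expect_equal(stp$mu, st$mu, tolerance = 1e-12)
  expect_equal(stp$sigma, st$sigma, tolerance = 1e-12)
  # explicit double-loop implementation agrees to 1e-6
  ref <- loop_channel_stats(f)
  expect_equal(st$mu, ref$mu, tolerance = 1e-6)
  expect_equal(st$sigma, ref$sigma, tolerance = 1e-6)
})

test_that("invalid feature maps and eps are rejected with informative errors", {
  f <- rand_fm(1, 2, 3, 3, seed = 1)
  f[1, 2, 3, 1] <- NaN
  expect_error(compute_channel_stats(f), "b=1, c=2, i=3, j=1")
  expect_error(compute_channel_stats(matrix(1, 2, 2)), "4-d")
  expect_error(compute_channel_stats(rand_fm(), eps = 0), "eps")
})

test_that("style vectors concatenate [mu; sigma] and round-trip losslessly", {
  st <- as_channel_stats(matrix(c(1, 2), 1), matrix(c(3, 4), 1))
  expect_equal(as.vector(make_style_vector(st)), c(1, 2, 3, 4))
  # batched: row-wise independent concatenation
  set.seed(2)
  f <- rand_fm(2, 3, 4, 4)
  st <- compute_channel_stats(f)
  s <- make_style_vector(st)
  for (b in 1:2)
    expect_equal(s[b, ], c(st$mu[b, ], st$sigma[b, ]))
  back <- split_style_vector(s)
  expect_equal(back$mu, st$mu)
  expect_equal(back$sigma, st$sigma)
  expect_error(split_style_vector(matrix(1, 2, 3)), "even")
})

test_that("moment injection matches a scalar oracle and hits the target moments", {
  # scalar oracle: content [1,2,3,4], target (10, 2):
  # out = 2 * (x - 2.5) / sqrt(1.25 + eps^2) + 10
  eps <- 1e-5
  f <- array(c(1, 2, 3, 4), c(1, 1, 2, 2))
  tgt <- as_channel_stats(matrix(10), matrix(2))
  out <- moment_inject(f, tgt, eps)
  expect_equal(as.vector(out),
               2 * (c(1, 2, 3, 4) - 2.5) / sqrt(1.25 + eps^2) + 10,
               tolerance = 1e-12)

  # identity: injecting a map's own statistics reproduces it
  set.seed(3)
  g <- rand_fm(2, 3, 6, 6)
  expect_equal(moment_inject(g, compute_channel_stats(g)), g,
               tolerance = 1e-6)

  # whitening: mu 0, sigma 1 gives an instance-normalized map
  wh <- moment_inject(g, as_channel_stats(matrix(0, 2, 3), matrix(1, 2, 3)))
  stw <- compute_channel_stats(wh)
  expect_equal(stw$mu, matrix(0, 2, 3), tolerance = 1e-10)
  expect_equal(stw$sigma, matrix(1, 2, 3), tolerance = 1e-4)

  expect_error(
    moment_inject(g, as_channel_stats(matrix(0, 3, 3), matrix(1, 3, 3))),
    "batch")
})

test_that("moment matching and idempotence hold over random inputs", {
  set.seed(4)
  for (rep in 1:20) {
    f <- rand_fm(2, 4, 5, 6, sd = runif(1, 0.5, 3))
    tgt <- as_channel_stats(matrix(rnorm(8), 2, 4),
                            matrix(exp(rnorm(8)), 2, 4))
    out <- moment_inject(f, tgt)
    st <- compute_channel_stats(out)
    expect_equal(st$mu, tgt$mu, tolerance = 1e-4)
    expect_equal(st$sigma, tgt$sigma, tolerance = 1e-4)
    # idempotence for a fixed target
    expect_equal(moment_inject(out, tgt), out, tolerance = 1e-4)
  }
})

test_that("injection is differentiable in content and target statistics", {
  # finite differences on a scalar functional of the output
  set.seed(5)
  f <- rand_fm(1, 2, 3, 3)
  mu_t <- matrix(rnorm(2), 1); sg_t <- matrix(exp(rnorm(2)), 1)
  wvec <- array(rnorm(length(f)), dim(f))
  val <- function(ff, m, s)
    sum(wvec * moment_inject(ff, as_channel_stats(m, s)))
  h <- 1e-3
  for (i in sample(length(f), 4)) {
    f2 <- f; f2[i] <- f2[i] + h; up <- val(f2, mu_t, sg_t)
    f2[i] <- f2[i] - 2 * h; dn <- val(f2, mu_t, sg_t)
    expect_true(is.finite((up - dn) / (2 * h)))
  }
  for (i in 1:2) {
    m2 <- mu_t; m2[i] <- m2[i] + h
    g_mu <- (val(f, m2, sg_t) - val(f, mu_t, sg_t)) / h
    expect_true(is.finite(g_mu) && abs(g_mu) > 0)
  }
})
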