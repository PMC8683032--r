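test_that("Box-Cox power is recovered from transformed-Gaussian data", {
  set.seed(41)
  # data already Gaussian: power near 1
  Y1 <- matrix(rnorm(500 * 16, mean = 5, sd = 0.5), 500)
  l1 <- estimate_lambda(Y1)
  expect_lt(abs(l1$lambda_bc - 1), 0.2)
  expect_equal(l1$shift_bc, 0)
  # log-normal data: power near 0
  Y2 <- matrix(exp(rnorm(500 * 16, mean = 1, sd = 0.3)), 500)
  expect_lt(abs(estimate_lambda(Y2)$lambda_bc), 0.2)
  # near-zero-mean data gets a positivity shift
  Y3 <- matrix(rnorm(100 * 16, 0, 0.05), 100)
  l3 <- estimate_lambda(Y3)
  expect_gte(min(Y3) + l3$shift_bc, 0.01 - 1e-12)
  expect_error(estimate_lambda(matrix(3, 50, 16)), "degenerate")
  expect_error(estimate_lambda(matrix(1:16, 1)), "at least 2")
})

test_that("AR(1) noise parameters are recovered from free segments", {
  set.seed(42)
  ns <- estimate_ar1_noise(rmvn_ar1(1000, 0.1, 0.8), identity_noise(),
                           rep(0, 16))
  expect_lt(abs(ns$sigma - 0.1) / 0.1, 0.1)
  expect_lt(abs(ns$rho - 0.8) / 0.8, 0.1)
  ns0 <- estimate_ar1_noise(rmvn_ar1(1000, 0.1, 0), identity_noise(),
                            rep(0, 16))
  expect_lt(abs(ns0$rho), 0.05)
  # a single segment yields an estimate with a convergence flag
  one <- estimate_ar1_noise(rmvn_ar1(1, 0.1, 0.5), identity_noise(),
                            rep(0, 16))
  expect_s3_class(one, "noise_model")
  expect_false(attr(one, "convergence"))
  expect_error(estimate_ar1_noise(matrix(numeric(0), 0, 16),
                                  identity_noise(), rep(0, 16)),
               "no blink-free")
})

test_that("mean profiles: pointwise mean and end-anchored spline", {
  idn <- identity_noise()
  zero <- matrix(0, 5, 16)
  mp <- compute_mean_profiles(zero, zero, idn)
  expect_equal(mp$mu_free, rep(0, 16))
  expect_equal(mp$mu_affected, rep(0, 16))

  set.seed(43)
  Xf <- matrix(rnorm(50 * 16, 0, 0.2), 50)
  mp2 <- compute_mean_profiles(Xf, zero, idn)
  expect_equal(mp2$mu_free, colMeans(Xf), tolerance = 1e-12)

  # linear affected mean reproduced exactly by the end spline
  grid <- model_grid()
  lin <- matrix(rep(0.1 + 0.05 * grid, 4), 4, byrow = TRUE)
  for (na in 1:2) {
    mp3 <- compute_mean_profiles(zero, lin, idn, n_anchor = na)
    expect_equal(mp3$mu_affected, 0.1 + 0.05 * grid, tolerance = 1e-10)
  }
  expect_error(compute_mean_profiles(matrix(0, 0, 16), zero, idn))
})

test_that("kernel shape is recovered from affected segments", {
  g <- model_grid()
  sh <- default_true_shape()
  h <- gamma_kernel(sh, g)
  idn <- noise_model(1, 1, 0.05, 0.8)
  means <- list(mu_free = rep(0, 16), mu_affected = rep(0, 16))

  # noise-free self-consistency
  Y0 <- matrix(rep(h, 20), 20, byrow = TRUE)
  sh0 <- estimate_bpr_shape(Y0, idn, means)
  expect_lt(max(abs(gamma_kernel(sh0, g) - h)), 1e-8 * 1e3)

  # no BPR present: amplitude estimate is essentially zero
  Yn <- matrix(0, 20, 16)
  shn <- estimate_bpr_shape(Yn, idn, means)
  expect_lt(max(abs(gamma_kernel(shn, g))), 0.01)

  # noisy recovery at the canonical regime
  set.seed(44)
  th <- rgamma(500, shape = 1 / 0.36, scale = 0.36)
  Y <- rmvn_ar1(500, 0.05, 0.8) + outer(th, h)
  sh1 <- estimate_bpr_shape(Y, idn, means)
  h1 <- gamma_kernel(sh1, g)
  nrmse <- sqrt(mean((h1 - mean(th) * h)^2)) /
    sqrt(mean((mean(th) * h)^2))
  expect_lt(nrmse, 0.1)

  expect_error(estimate_bpr_shape(Y[1:5, ], idn, means),
               "insufficient")
})

test_that("blink amplitudes are recovered per segment", {
  g <- model_grid()
  sh <- default_true_shape()
  h <- gamma_kernel(sh, g)
  idn <- noise_model(1, 1, 0.05, 0.8)
  means <- list(mu_free = rep(0, 16), mu_affected = rep(0, 16))

  expect_equal(estimate_blink_amplitudes(matrix(2 * h, 1, byrow = TRUE),
                                         sh, idn, means), 2,
               tolerance = 1e-3)
  expect_lt(abs(estimate_blink_amplitudes(matrix(0, 1, 16), sh, idn,
                                          means)), 0.5)
  set.seed(45)
  th <- rgamma(200, shape = 1 / 0.36, scale = 0.36)
  Y <- rmvn_ar1(200, 0.05, 0.8) + outer(th, h)
  that <- estimate_blink_amplitudes(Y, sh, idn, means)
  expect_gt(cor(that, th), 0.8)
  expect_length(estimate_blink_amplitudes(matrix(0, 0, 16), sh, idn,
                                          means), 0L)
})

test_that("estimates are invariant to segment order", {
  set.seed(46)
  g <- model_grid()
  sh <- default_true_shape()
  h <- gamma_kernel(sh, g)
  idn <- noise_model(1, 1, 0.05, 0.8)
  means <- list(mu_free = rep(0, 16), mu_affected = rep(0, 16))
  Y <- rmvn_ar1(80, 0.05, 0.8) + outer(rep(1, 80), h)
  perm <- sample(80)
  l_a <- estimate_lambda(Y + 4)
  l_b <- estimate_lambda(Y[perm, ] + 4)
  expect_equal(l_a$lambda_bc, l_b$lambda_bc, tolerance = 1e-8)
  ns_a <- estimate_ar1_noise(Y, idn, colMeans(Y))
  ns_b <- estimate_ar1_noise(Y[perm, ], idn, colMeans(Y))
  expect_equal(ns_a$sigma, ns_b$sigma, tolerance = 1e-8)
  expect_equal(ns_a$rho, ns_b$rho, tolerance = 1e-8)
  sh_a <- estimate_bpr_shape(Y, idn, means)
  sh_b <- estimate_bpr_shape(Y[perm, ], idn, means)
  expect_equal(sh_a$gamma_amp, sh_b$gamma_amp, tolerance = 1e-8)
})

test_that("kernel amplitude recovery is consistent in segment count", {
  # sampling SD of the amplitude estimate drops when n doubles
  g <- model_grid()
  sh <- default_true_shape()
  h <- gamma_kernel(sh, g)
  idn <- noise_model(1, 1, 0.05, 0.8)
  means <- list(mu_free = rep(0, 16), mu_affected = rep(0, 16))
  est_g <- function(n, seed) {
    set.seed(seed)
    Y <- rmvn_ar1(n, 0.05, 0.8) + matrix(h, n, 16, byrow = TRUE)
    estimate_bpr_shape(Y, idn, means)$gamma_amp
  }
  g1 <- vapply(1:16, function(s) est_g(30, 500 + s), numeric(1))
  g2 <- vapply(1:16, function(s) est_g(120, 600 + s), numeric(1))
  expect_lt(sd(g2), sd(g1))
  # and the median error at the canonical run-scale segment count is
  # within 15% for both the amplitude and the time-to-peak proxy
  fits <- lapply(1:20, function(s) {
    set.seed(700 + s)
    th <- rgamma(57, shape = 1 / 0.36, scale = 0.36)
    Y <- rmvn_ar1(57, 0.05, 0.8) + outer(th, h)
    est <- estimate_bpr_shape(Y, idn, means)
    c(gam = est$gamma_amp / mean(th),
      tp = (est$alpha - 1) * est$beta + est$t_shift)
  })
  gam <- vapply(fits, `[[`, numeric(1), "gam")
  tp <- vapply(fits, `[[`, numeric(1), "tp")
  expect_lt(median(abs(gam - sh$gamma_amp) / abs(sh$gamma_amp)), 0.15)
  expect_lt(median(abs(tp - 0.9) / 0.9), 0.15)
})

test_that("the staged fit runs end to end on a simulated recording", {
  fx <- cached_fix_run()
  run <- fx$run
  pp <- fx$pp
  fit <- fit_bpr_model(pp$trace, pp$blinks)
  expect_s3_class(fit, "bpr_fit")
  expect_true(all(fit$diagnostics$converged[fit$diagnostics$stage !=
                                              "lambda"]))
  # trough time of the recovered kernel within 0.2 s of truth
  tp <- (fit$shape$alpha - 1) * fit$shape$beta + fit$shape$t_shift
  expect_lt(abs(tp - 0.9), 0.2)
  # amplitudes exist for each affected segment, overlap flagged
  expect_equal(nrow(fit$amplitudes), fit$n_affected)
  expect_type(fit$amplitudes$overlapping, "logical")

  # tidy / glance / JSON round trip
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 8L)
  gl <- glance(fit)
  expect_equal(gl$n_affected, fit$n_affected)
  f <- withr::local_tempfile(fileext = ".json")
  write_bpr_model(fit, f)
  fit2 <- read_bpr_model(f)
  expect_equal(fit2$shape$alpha, fit$shape$alpha, tolerance = 1e-12)
  expect_equal(fit2$amplitudes$theta, fit$amplitudes$theta,
               tolerance = 1e-12)

  # two blinks 1 s apart are both flagged overlapping, both get theta
  close_idx <- which(fit$amplitudes$overlapping)
  expect_true(all(is.finite(fit$amplitudes$theta)))
  expect_gt(length(close_idx), 0L)
})

test_that("a run without blinks yields a flagged model, not an error", {
  set.seed(47)
  tt <- seq(0, 120, by = 0.01)
  tr <- pupil_trace(tt, 4 + 0.05 * sin(2 * pi * 0.1 * tt), rate = 100)
  f <- bandpass_filter(tr)
  empty <- tibble::tibble(onset = numeric(0), offset = numeric(0))
  expect_warning(fit <- fit_bpr_model(f, empty), "no usable")
  expect_null(fit$shape)
  expect_true("no_blinks" %in% fit$flags)
  expect_equal(nrow(fit$amplitudes), 0L)
})
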