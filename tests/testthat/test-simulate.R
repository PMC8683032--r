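test_that("blink trains follow the rate profile with refractoriness", {
  cfg0 <- sim_config(n_trials = 50, trial_length = 2, rate = 100,
                     conditions = list(sim_condition("z", 1, 0, 0)),
                     pad_rate = 0, seed = 3)
  expect_equal(nrow(sample_blink_trains(cfg0)), 0L)

  cfg <- sim_config(n_trials = 500, trial_length = 2, rate = 100,
                    conditions = list(sim_condition("c", 1, 0, 0.3)),
                    pad_rate = 0.3, seed = 4)
  bl <- sample_blink_trains(cfg)
  # renewal-theory count: each blink blocks ~(mean duration +
  # refractory) of dead time, so the effective rate is
  # lambda / (1 + lambda * dead); Poisson 3-sd band around that
  dead <- mean(cfg$blink_duration) + cfg$refractory
  expected <- 0.3 / (1 + 0.3 * dead) * cfg$duration
  expect_lt(abs(nrow(bl) - expected), 3 * sqrt(expected))
  # refractory gap between offset and next onset
  expect_true(all(bl$onset[-1] - bl$offset[-nrow(bl)] >=
                    cfg$refractory - 1e-12))
  expect_true(all(bl$offset - bl$onset >= 0.1 - 1e-12 &
                    bl$offset - bl$onset <= 0.4 + 1e-12))

  # reproducibility: same seed identical, different seed different
  expect_identical(sample_blink_trains(cfg), bl)
  cfg2 <- cfg
  cfg2$seed <- 5L
  expect_false(identical(sample_blink_trains(cfg2)$onset, bl$onset))
})

test_that("the synthetic trace decomposes exactly into its parts", {
  run <- synthesize_trace(sim_config_fixation(n_trials = 60, seed = 6))
  expect_equal(run$trace$pupil,
               run$config$baseline_mm + run$truth$sf + run$truth$pr +
                 run$truth$bpr,
               tolerance = 1e-12)
  # blink gaps are stamped invalid
  expect_gt(sum(!run$trace$valid), 0L)
  for (j in seq_len(min(5, nrow(run$blinks)))) {
    mid <- (run$blinks$onset[j] + run$blinks$offset[j]) / 2
    expect_false(run$trace$valid[which.min(abs(run$trace$time - mid))])
  }
  # theta constant zero removes the BPR component entirely
  cfg0 <- sim_config_fixation(n_trials = 30, seed = 6)
  cfg0$theta_dist <- list(family = "constant", mean = 0, cv = 0)
  run0 <- synthesize_trace(cfg0)
  expect_equal(run0$truth$bpr, numeric(nrow(run0$trace)))
  expect_equal(run0$trace$pupil,
               run0$config$baseline_mm + run0$truth$sf + run0$truth$pr)
})

test_that("spontaneous fluctuation has the configured autocorrelation", {
  cfg <- sim_config(n_trials = 1000, trial_length = 3, rate = 50,
                    conditions = list(sim_condition("f", 1, 0, 0)),
                    pad_rate = 0, seed = 8)
  run <- synthesize_trace(cfg)
  # sample the spontaneous component on the 5-Hz model grid
  sf5 <- run$truth$sf[seq(1, nrow(run$trace), by = 10)]
  r1 <- cor(sf5[-1], sf5[-length(sf5)])
  expect_lt(abs(r1 - cfg$true_noise$rho), 0.05)
})

test_that("blink-locked averages reproduce the mean kernel", {
  cfg <- sim_config(n_trials = 3200, trial_length = 3, rate = 50,
                    conditions = list(sim_condition("f", 1, 0, 0.15)),
                    pad_rate = 0.15, seed = 9)
  run <- synthesize_trace(cfg)
  tr_bpr <- run$trace
  tr_bpr$pupil <- run$truth$bpr
  bl <- run$blinks
  gap_prev <- c(Inf, bl$onset[-1] - bl$offset[-nrow(bl)])
  gap_next <- c(bl$onset[-1] - bl$offset[-nrow(bl)], Inf)
  iso <- which(gap_prev > 3 & gap_next > 3 &
                 bl$offset + 3 < max(run$trace$time))
  expect_gt(length(iso), 500L)
  M <- vapply(bl$offset[iso], function(o) resample_window(tr_bpr, o),
              numeric(16))
  avg <- rowMeans(M)
  sem <- apply(M, 1, sd) / sqrt(length(iso))
  # the grid values are block means, so compare against the
  # block-averaged kernel, not its pointwise values
  g <- model_grid()
  expected <- mean(bl$theta[iso]) * vapply(seq_along(g), function(i) {
    lo <- max(g[i] - 0.1, 0)
    hi <- min(g[i] + 0.1, 3)
    x <- seq(lo, hi, by = 1e-3)
    mean(gamma_kernel(cfg$true_shape, x))
  }, numeric(1))
  expect_true(all(abs(avg - expected) <= 2 * sem + 1e-4))
})

test_that("the confound predictor matches convolution identities", {
  L <- 100
  rate <- 50
  cog <- 0.2 * dilation_profile((0:(L - 1)) / rate)
  kern <- gamma_kernel(default_true_shape(), (0:(3 * rate)) / rate)

  # zero blink rate: prediction is the tiled, baselined profile
  p0 <- predict_confound(rep(0, L), kern, cog, n_trials_span = 3,
                         rate = rate)
  expect_equal(p0$predicted, rep(cog - cog[1], 3), tolerance = 1e-12)

  # unit rate impulse: prediction minus cognitive is the shifted
  # kernel (the impulse recurs each tiled trial, so compare up to the
  # next trial's impulse only)
  r <- rep(0, L)
  r[11] <- rate  # discrete unit impulse (integrates to 1)
  p1 <- predict_confound(r, kern, cog, n_trials_span = 3, rate = rate,
                         baseline = FALSE)
  d <- p1$predicted - p1$cognitive
  expect_equal(d[11:110], kern[1:100], tolerance = 1e-9)
  expect_equal(d[1:10], rep(0, 10), tolerance = 1e-12)

  expect_error(predict_confound(rep(0, 10), kern, cog, 2, rate),
               "trial grid")
})

test_that("the predictor agrees with trial-averaged simulation", {
  cfg <- sim_config(
    n_trials = 800, trial_length = 2, rate = 100,
    conditions = list(sim_condition(
      "tone", 1,
      cognitive = function(p) 0.2 * dilation_profile(p),
      blink_rate = function(p) 0.1 + 0.9 * exp(-(p - 0.75)^2 /
                                                 (2 * 0.2^2)))),
    seed = 71)
  run <- synthesize_trace(cfg)
  rate <- 100
  L <- 200
  x <- run$trace$pupil - mean(run$trace$pupil)
  M <- vapply(seq_len(nrow(run$events)), function(i) {
    i0 <- round(run$events$onset[i] * rate) + 1L
    v <- x[i0:(i0 + L - 1L)]
    v - v[1]
  }, numeric(L))
  avg <- rowMeans(M)
  sem <- apply(M, 1, sd) / sqrt(ncol(M))
  br <- blink_rate_timecourse(run$blinks, run$events, rate = rate)
  kern <- gamma_kernel(cfg$true_shape, (0:(3 * rate)) / rate)
  cog <- 0.2 * dilation_profile((0:(L - 1)) / rate)
  pred <- predict_confound(br$rate_hz, kern, cog, n_trials_span = 8,
                           rate = rate)
  pr <- pred$predicted[pred$trial == 4]
  expect_gt(mean(abs(pr - avg) <= 2 * sem), 0.9)
})

test_that("trial sequences are selected by exact blink history", {
  trials <- tibble::tibble(onset = seq(0, 18, by = 2), duration = 2)
  none <- tibble::tibble(onset = numeric(0), offset = numeric(0))
  expect_equal(select_trial_sequences(none, trials, c(0, 0, 0, 0)), 4:10)
  expect_length(select_trial_sequences(none, trials, c(0, 0, 0, 1)), 0L)

  one <- tibble::tibble(onset = 8.5, offset = 8.8)  # inside trial 5
  expect_true(5 %in% select_trial_sequences(one, trials, c(0, 0, 0, 1)))
  expect_true(6 %in% select_trial_sequences(one, trials, c(0, 0, 1, 0)))
  expect_false(5 %in% select_trial_sequences(one, trials, c(0, 0, 0, 0)))

  # counts match a brute-force scan on random trains
  set.seed(10)
  for (rep in 1:5) {
    bl <- tibble::tibble(onset = sort(runif(12, 0, 20)))
    bl$offset <- bl$onset + 0.2
    hit <- vapply(seq_len(nrow(trials)), function(i) {
      any(bl$onset >= trials$onset[i] &
            bl$onset < trials$onset[i] + trials$duration[i])
    }, logical(1))
    for (pat in list(c(0, 0, 0, 1), c(0, 0, 1, 0), c(1, 0, 0, 0))) {
      brute <- which(vapply(4:10, function(t) {
        all(as.integer(hit[(t - 3):t]) == pat)
      }, logical(1))) + 3L
      expect_equal(select_trial_sequences(bl, trials, pat), brute)
    }
  }
})

test_that("blink-history contrasts show the breakpoint confound signature", {
  # blink-in-current-trial sequences dip late; blink-in-previous-trial
  # sequences start inflated (baselined on the recovery limb)
  okA <- okB <- 0L
  n_seeds <- 10L
  rate <- 100
  L <- 200
  for (sd in seq_len(n_seeds)) {
    cfg <- sim_config(
      n_trials = 300, trial_length = 2, rate = rate,
      conditions = list(sim_condition(
        "tone", 1,
        cognitive = function(p) 0.2 * dilation_profile(p),
        blink_rate = function(p) 0.1 + 0.9 * exp(-(p - 0.75)^2 /
                                                   (2 * 0.2^2)))),
      seed = 100 + sd)
    run <- synthesize_trace(cfg)
    x <- run$trace$pupil - mean(run$trace$pupil)
    prof <- function(idx) {
      rowMeans(vapply(idx, function(i) {
        i0 <- round(run$events$onset[i] * rate) + 1L
        v <- x[i0:(i0 + L - 1L)]
        v - v[1]
      }, numeric(L)))
    }
    s0 <- select_trial_sequences(run$blinks, run$events, c(0, 0, 0, 0))
    s1 <- select_trial_sequences(run$blinks, run$events, c(0, 0, 0, 1))
    s2 <- select_trial_sequences(run$blinks, run$events, c(0, 0, 1, 0))
    if (min(lengths(list(s0, s1, s2))) < 4) next
    p0 <- prof(s0)
    late <- (L / 2 + 1):L
    early <- 1:(L / 2)
    okA <- okA + (mean(prof(s1)[late]) < mean(p0[late]))
    okB <- okB + (mean(prof(s2)[early]) > mean(p0[early]))
  }
  expect_gte(okA, 8L)
  expect_gte(okB, 8L)
})
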