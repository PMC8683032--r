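make_flat_trace <- function(dur = 40, rate = 100, level = 4) {
  tt <- seq(0, dur, by = 1 / rate)
  pupil_trace(tt, rep(level, length(tt)), rate = rate)
}

test_that("segment extraction follows the isolation and chunking rules", {
  tr <- make_flat_trace(dur = 40)
  # two blinks 2 s apart: both affected, neither isolated
  bl <- tibble::tibble(onset = c(10, 12), offset = c(10.2, 12.2))
  segs <- extract_segments(tr, bl, edge_sec = 0)
  aff <- segs[segs$kind == "blink_affected", ]
  expect_equal(nrow(aff), 2L)
  expect_false(any(aff$isolated))
  expect_true(all(lengths(aff$values) == 16L))

  # a 13-s inter-blink interval yields floor((13 - 3) / 3) = 3 free
  # segments
  bl2 <- tibble::tibble(onset = c(5, 18.2), offset = c(5.2, 18.4))
  segs2 <- extract_segments(tr, bl2, edge_sec = 0)
  free2 <- segs2[segs2$kind == "blink_free" & segs2$anchor > 5 &
                   segs2$anchor < 18.2, ]
  expect_equal(nrow(free2), 3L)
  expect_equal(free2$anchor, c(8.2, 11.2, 14.2), tolerance = 1e-9)

  # a single blink with > 3-s gaps on both sides is isolated
  bl3 <- tibble::tibble(onset = 20, offset = 20.2)
  segs3 <- extract_segments(tr, bl3, edge_sec = 0)
  expect_true(segs3$isolated[segs3$kind == "blink_affected"])
})

test_that("trial classification uses the 2-back blink history", {
  trials <- tibble::tibble(onset = seq(0, 18, by = 2), duration = 2,
                           condition = "x")
  bl <- tibble::tibble(onset = 6.5, offset = 6.8)  # trial 4
  cl <- classify_trials(trials, bl)
  expect_true(all(is.na(cl$label[1:2])))
  expect_equal(cl$label[4], "blink_affected")   # current
  expect_equal(cl$label[5], "blink_affected")   # 1-back
  expect_equal(cl$label[6], "blink_affected")   # 2-back
  expect_equal(cl$label[7], "blink_free")       # 3-back only
  expect_equal(cl$label[3], "blink_free")
  # counts equal the brute-force history scan on random trains
  set.seed(11)
  for (rep in 1:5) {
    blr <- tibble::tibble(onset = sort(runif(8, 0, 20)))
    blr$offset <- blr$onset + 0.2
    expect_equal(classify_trials(trials, blr)$label,
                 oracle_classify(trials, blr))
  }
})

test_that("blink-rate time courses scale to blinks per second", {
  trials <- tibble::tibble(onset = seq(0, 38, by = 2), duration = 2)
  none <- tibble::tibble(onset = numeric(0), offset = numeric(0))
  br0 <- blink_rate_timecourse(none, trials, rate = 100)
  expect_equal(br0$rate_hz, rep(0, 200))

  # one offset at the same latency every trial: 1/boxcar Hz there
  bl <- tibble::tibble(onset = trials$onset + 0.8,
                       offset = trials$onset + 1.0)
  br <- blink_rate_timecourse(bl, trials, rate = 100)
  expect_equal(max(br$rate_hz), 10, tolerance = 1e-9)
  expect_equal(br$rate_hz[br$phase < 0.9 | br$phase > 1.1],
               rep(0, sum(br$phase < 0.9 | br$phase > 1.1)))

  # uniform offsets average to M / T blinks per second
  set.seed(12)
  nt <- 400
  trials2 <- tibble::tibble(onset = seq(0, by = 2, length.out = nt),
                            duration = 2)
  offs <- sort(unlist(lapply(seq_len(nt), function(i) {
    trials2$onset[i] + runif(rpois(1, 0.8), 0, 2)
  })))
  bl2 <- tibble::tibble(onset = offs - 0.2, offset = offs)
  br2 <- blink_rate_timecourse(bl2, trials2, rate = 100)
  expect_lt(abs(mean(br2$rate_hz) - length(offs) / (2 * nt)) /
              (length(offs) / (2 * nt)), 0.1)
})

test_that("response magnitudes are baselined window averages", {
  rate <- 100
  trials <- tibble::tibble(onset = seq(0, 18, by = 2), duration = 2,
                           condition = rep(c("a", "b"), 5))
  flat <- make_flat_trace(dur = 25)
  m0 <- response_magnitudes(trials, flat)
  expect_equal(m0$magnitude, rep(0, 10))
  expect_equal(m0$condition, trials$condition)

  # a known ramp inside the window integrates analytically
  tt <- flat$time
  ramp <- flat
  ramp$pupil <- 4 + 0.1 * (tt %% 2)
  m1 <- response_magnitudes(trials, ramp, window = list(fixed = c(0.5, 2)))
  phase <- (0:199) / rate
  sel <- phase >= 0.5 & phase <= 2
  expect_equal(m1$magnitude, rep(mean(0.1 * phase[sel]), 10),
               tolerance = 1e-9)

  # auto window bounds equal a brute-force threshold scan
  tri <- flat
  tri$pupil <- 4 + pmax(0, 1 - abs((tt %% 2) - 1)) * 0.2
  m2 <- response_magnitudes(trials, tri, window = list(auto_frac = 0.75))
  grand <- pmax(0, 1 - abs(phase - 1)) * 0.2
  grand <- grand - grand[1]
  above <- which(grand >= 0.75 * max(grand))
  sel2 <- seq(min(above), max(above))
  expect_equal(m2$magnitude, rep(mean(grand[sel2]), 10),
               tolerance = 1e-9)

  expect_error(response_magnitudes(trials, flat,
                                   window = list(auto_frac = 0.75)),
               "flat")
})

test_that("quantile profiles sort amplitudes within the trough window", {
  g <- model_grid()
  # identical segments: five identical quantile profiles
  same <- tibble::tibble(values = replicate(25, sin(g), simplify = FALSE))
  qp <- quantile_bpr_profiles(same)
  expect_equal(nrow(qp), 5L)
  for (b in 2:5) expect_equal(qp$profile[[b]], qp$profile[[1]])

  # known amplitudes: pre-smoothing profiles match a brute-force
  # sort-bin-average oracle
  set.seed(13)
  amp <- runif(50, -0.4, -0.05)
  segs <- tibble::tibble(values = lapply(amp, function(a) {
    a * gamma_kernel(default_true_shape(), g) / -0.2
  }))
  qp2 <- quantile_bpr_profiles(segs)
  X <- do.call(rbind, segs$values)
  tw <- g >= 0.5 & g <= 1.2
  o_amp <- apply(X[, tw], 1, min)
  q <- dplyr::ntile(-o_amp, 5)
  for (b in 1:5) {
    expect_equal(qp2$profile[[b]], colMeans(X[q == b, , drop = FALSE]),
                 tolerance = 1e-10)
  }
  # deepest quantile has the larger trough
  expect_lt(qp2$peak_amplitude[5], qp2$peak_amplitude[1])

  # the trough search never reads outside 0.5-1.2 s: a huge dip at
  # 2.0 s must not drive the binning
  spike <- tibble::tibble(values = lapply(1:10, function(i) {
    v <- rep(0, 16)
    v[g == 2] <- -i  # monotone dip outside the window
    v[g == 1] <- -0.1 * (11 - i)  # opposite order inside
    v
  }))
  qp3 <- quantile_bpr_profiles(spike)
  # binning must follow the in-window dip: the deepest bin holds
  # segments 1 and 2 (in-window troughs -1.0 and -0.9)
  expect_equal(qp3$profile[[5]][g == 1], -0.95, tolerance = 1e-12)
})

test_that("Euclidean distance and AUC match brute-force oracles", {
  expect_equal(compare_to_blink_free(rep(1, 16), rep(1, 16)), 0)
  expect_equal(compare_to_blink_free(rep(0.3, 16), rep(0.05, 16)),
               4 * 0.25, tolerance = 1e-12)
  set.seed(14)
  a <- rnorm(16)
  b <- rnorm(16)
  expect_equal(compare_to_blink_free(a, b), sqrt(sum((a - b)^2)))
  expect_error(compare_to_blink_free(a, b[1:5]), "equal length")

  x <- c(1, 2, 3, 4)
  expect_equal(discriminability(x, x)$auc, 0.5)
  expect_equal(discriminability(c(5, 6, 7), c(1, 2, 3))$auc, 1)
  for (rep in 1:5) {
    a <- sample(1:10, 12, replace = TRUE)
    b <- sample(1:10, 9, replace = TRUE)
    d <- discriminability(a, b)
    expect_equal(d$auc, oracle_auc(a, b), tolerance = 1e-12)
    expect_equal(d$mean_diff, mean(a) - mean(b))
    # AUC is invariant under strictly monotone transforms
    expect_equal(discriminability(exp(a / 3), exp(b / 3))$auc, d$auc)
  }
  expect_error(discriminability(1, c(1, 2)), "at least 2")
})

test_that("bootstrap power behaves like power", {
  set.seed(15)
  # strong effect: rejection near 1 even at small n
  recs <- tibble::tibble(
    condition = rep(c("a", "b"), each = 100),
    magnitude = c(rnorm(100, 0, 0.1), rnorm(100, 2, 0.1)))
  pw <- power_bootstrap(recs, c(a = -0.5, b = 0.5),
                        n_grid = c(10, 20, 40), reps = 500, seed = 2)
  expect_gt(pw$results$rejection_frac[1], 0.95)
  expect_equal(pw$min_n, 10)

  # moderate effect: non-decreasing in n up to Monte-Carlo error
  recs2 <- tibble::tibble(
    condition = rep(c("a", "b"), each = 200),
    magnitude = c(rnorm(200, 0, 1), rnorm(200, 0.4, 1)))
  pw2 <- power_bootstrap(recs2, c(a = -0.5, b = 0.5),
                         n_grid = c(25, 50, 100, 200), reps = 2000,
                         seed = 3)
  fr <- pw2$results$rejection_frac
  mc <- 2 * sqrt(0.25 / 2000)
  expect_true(all(diff(fr) > -mc))

  # degenerate resamples (single regressor value) are not significant
  recs3 <- tibble::tibble(condition = c(rep("a", 99), "b"),
                          magnitude = rnorm(100))
  pw3 <- power_bootstrap(recs3, c(a = 0, b = 1), n_grid = 3,
                         reps = 200, seed = 4)
  expect_lt(pw3$results$rejection_frac, 0.2)
  expect_error(power_bootstrap(recs3[1:99, ], c(a = 0, b = 1), 10),
               "distinct")
})
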