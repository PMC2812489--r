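test_that("the 3-parameter logistic has the stated geometry", {
  lnK <- log(10000)
  # at t = m log abundance is lnK / 2, i.e. abundance sqrt(K) = 100
  expect_equal(exp(logistic3(5, lnK, 5, 2)), 100)
  # asymptote
  expect_lt(abs(logistic3(5 + 50 * 2, lnK, 5, 2) - lnK), 1e-10)
  # tail e-folding: deviation from the asymptote shrinks by e per phi years
  d1 <- lnK - logistic3(5 + 10 * 2, lnK, 5, 2)
  d2 <- lnK - logistic3(5 + 11 * 2, lnK, 5, 2)
  expect_equal(d1 / d2, exp(1), tolerance = 1e-4)
  d1 <- lnK - logistic3(5 + 20 * 2, lnK, 5, 2)
  d2 <- lnK - logistic3(5 + 21 * 2, lnK, 5, 2)
  expect_equal(d1 / d2, exp(1), tolerance = 1e-6)
  expect_true(all(diff(logistic3(1:40, lnK, 5, 2)) > 0))
  expect_error(logistic3(1, lnK, 5, 0), "phi")
})

test_that("the 4-parameter logistic reduces to and extends the 3-parameter", {
  t <- seq(0, 30, by = 0.5)
  expect_equal(logistic4(t, 0, log(500), 4, 1.5), logistic3(t, log(500), 4, 1.5))
  expect_lt(abs(logistic4(4 - 50 * 1.5, 2, log(500), 4, 1.5) - 2), 1e-10)
  expect_equal(logistic4(4, 2, log(500), 4, 1.5), (2 + log(500)) / 2)
  expect_error(logistic4(1, 7, log(500), 4, 1.5), "lower asymptote")
})

test_that("the synthetic segment generator is exact, seeded and calibrated", {
  s0 <- simulate_logistic_trajectory(K = 1000, m = 5, phi = 2, sigma_e = 0,
                                     sigma_b = 0, seed = 1)
  expect_equal(s0$lnN, logistic3(s0$t, log(1000), 5, 2))
  expect_identical(simulate_logistic_trajectory(seed = 3),
                   simulate_logistic_trajectory(seed = 3))
  s1 <- simulate_logistic_trajectory(K = 1000, m = 5, phi = 2, sigma_e = 0.3,
                                     sigma_b = 0, seed = 4)
  res <- s1$lnN - logistic3(s1$t, log(1000), 5, 2)
  expect_lt(abs(var(res) - 0.09) / 0.09, 0.10)
})

test_that("noiseless logistic data are recovered exactly", {
  seg <- simulate_logistic_trajectory(K = 1000, m = 5, phi = 2, sigma_e = 0,
                                      sigma_b = 0, seed = 1)
  f <- fit_recovery(seg, form = 3, n_boot = 0)
  expect_true(f$converged)
  expect_lt(abs(f$K - 1000) / 1000, 1e-4)
  expect_lt(abs(f$m - 5) / 5, 1e-4)
  expect_lt(abs(f$phi - 2) / 2, 1e-4)

  t <- rep(1:17, 10); y <- landrec::weather_label(seq_along(t))
  seg4 <- data.frame(t = t, lnN = logistic4(t, 1.5, log(5000), 6, 2.5), y = y)
  f4 <- fit_recovery(seg4, form = 4, n_boot = 0)
  expect_lt(abs(f4$K - 5000) / 5000, 1e-4)
  expect_lt(abs(f4$A - 1.5) / 1.5, 1e-4)
  expect_lt(abs(f4$phi - 2.5) / 2.5, 1e-4)
})

test_that("degenerate inputs yield flags or instructions, not crashes", {
  flat <- data.frame(t = rep(1:17, 2), lnN = log(1000),
                     y = rep(1:2, each = 17))
  f <- fit_recovery(flat, n_boot = 0)
  expect_false(f$converged)
  expect_match(f$diagnostic, "no growth signal")
  one_label <- data.frame(t = 1:17, lnN = logistic3(1:17, log(100), 4, 2),
                          y = 1)
  expect_error(fit_recovery(one_label, n_boot = 0), "weather label")
  expect_error(fit_recovery(flat[1:5, ], n_boot = 0), "at least 8")
})

test_that("fits are invariant to segment order and label renaming", {
  seg <- simulate_logistic_trajectory(seed = 10)
  f1 <- fit_recovery(seg, n_boot = 0)
  shuffled <- seg[sample(nrow(seg)), ]
  attr(shuffled, "segment_length") <- attr(seg, "segment_length")
  f2 <- fit_recovery(shuffled, n_boot = 0)
  expect_equal(f1$K, f2$K, tolerance = 1e-8)
  expect_equal(f1$phi, f2$phi, tolerance = 1e-8)
  relabeled <- seg
  relabeled$y <- c(10, 1:9)[seg$y]    # permute label names
  f3 <- fit_recovery(relabeled, n_boot = 0)
  expect_equal(f3$K, f1$K, tolerance = 1e-8)
  expect_equal(sort(unname(f3$b_y)), sort(unname(f1$b_y)), tolerance = 1e-8)
})

test_that("the fitted curve keeps the tail e-folding (return-time) property", {
  seg <- simulate_logistic_trajectory(seed = 12)
  f <- fit_recovery(seg, n_boot = 0)
  lnK <- unname(coef(f)["lnK"])
  dev <- function(t) lnK - predict(f, data.frame(t = t))
  expect_equal(dev(f$m + 10 * f$phi) / dev(f$m + 11 * f$phi), exp(1),
               tolerance = 1e-4)
})

test_that("estimates agree with an independent nonlinear mixed model fit", {
  seg <- simulate_logistic_trajectory(K = 2000, m = 5, phi = 2,
                                      sigma_e = 0.1, sigma_b = 0.2, seed = 21)
  ours <- fit_recovery(seg, n_boot = 0)
  ctrl <- nlme::nlmeControl(maxIter = 200, returnObject = TRUE)
  ref <- nlme::nlme(lnN ~ lnK / (1 + exp((m - t) / phi)),
                    fixed = lnK + m + phi ~ 1, random = lnK ~ 1 | y,
                    data = seg, start = c(lnK = max(seg$lnN), m = 4, phi = 1),
                    control = ctrl)
  fx <- nlme::fixef(ref)
  expect_lt(abs(ours$K - exp(fx[["lnK"]])) / exp(fx[["lnK"]]), 0.05)
  expect_lt(abs(ours$phi - fx[["phi"]]) / fx[["phi"]], 0.05)
})

test_that("recovery-fit methods are coherent", {
  seg <- simulate_logistic_trajectory(seed = 14)
  f <- fit_recovery(seg, n_boot = 50, seed = 2)
  expect_s3_class(f, "recovery_fit")
  expect_named(coef(f), c("lnK", "m", "phi"))
  expect_equal(length(residuals(f)), f$n_obs)
  expect_equal(fitted(f) + residuals(f), f$data$lnN)
  expect_true(all(f$ci[, "lower"] <= c(f$K, f$phi)))
  expect_true(all(f$ci[, "upper"] >= c(f$K, f$phi)))
  sim <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(f$n_obs, 3L))
  expect_output(print(f), "logistic recovery fit")
  # prediction with label offsets uses b_y (asymptotically additive)
  tt <- f$m + 60 * f$phi
  pr <- predict(f, data.frame(t = c(tt, tt), y = names(f$b_y)[1:2]))
  expect_equal(unname(diff(pr)), unname(diff(f$b_y[1:2])), tolerance = 1e-8)
})

test_that("the unperturbed equilibrium fit matches closed forms", {
  mk <- function(N) {
    tr <- data.frame(year = 1:181, N = N, weather = landrec::weather_label(1:181),
                     perturbed = FALSE, analyzed = 1:181 > 11,
                     segment = NA_integer_, t = NA_integer_)
    class(tr) <- c("trajectory", "data.frame")
    attr(tr, "schedule") <- make_schedule(removal_fraction = 0)
    tr
  }
  f <- fit_unperturbed(mk(rep(500, 181)))
  expect_equal(unname(f$K), 500)
  expect_true(all(abs(f$intercepts - log(500)) < 1e-12))

  # labels alternating 100/200 (odd labels see 100, even see 200)
  N <- ifelse(landrec::weather_label(1:181) %% 2 == 1, 100, 200)
  f2 <- fit_unperturbed(mk(N))
  expect_equal(f2$K, sqrt(100 * 200), tolerance = 1e-12)

  # residual SD of label-shifted white noise recovered within 10% at n = 170
  set.seed(3)
  lab <- landrec::weather_label(1:181)
  N3 <- round(exp(log(1000) + 0.3 * (lab %% 3) + rnorm(181, 0, 0.2)))
  f3 <- fit_unperturbed(mk(N3))
  expect_lt(abs(f3$sigma_e - 0.2) / 0.2, 0.10)
  expect_error(fit_unperturbed(mk(rep(0, 181))), "no usable")
})

test_that("per-segment asymptotes resolve stepped declines", {
  mk_step <- function(seed) {
    segs <- lapply(1:9, function(k) {
      K <- 1000 * 2^(-((k - 1) %/% 3))
      s <- simulate_logistic_trajectory(K = K, m = 4, phi = 1.5,
                                        sigma_e = 0.08, sigma_b = 0,
                                        n_segments = 1, seed = seed * 100 + k)
      s$segment <- k
      s
    })
    out <- do.call(rbind, segs)
    attr(out, "segment_length") <- 17L
    out
  }
  sk <- segmentwise_K(mk_step(1))
  truth <- 1000 * 2^(-((1:9 - 1) %/% 3))
  expect_true(all(abs(sk$K - truth) / truth < 0.15))

  null <- simulate_logistic_trajectory(K = 1000, m = 4, phi = 1.5,
                                       sigma_e = 0.08, sigma_b = 0,
                                       n_segments = 8, seed = 5)
  sk0 <- segmentwise_K(null)
  ci <- recovery_decline_test(sk0)$ci
  expect_true(ci[1] <= 0 && 0 <= ci[2])

  one <- simulate_logistic_trajectory(n_segments = 1, seed = 2)
  expect_error(segmentwise_K(one), "at least 2")
})
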