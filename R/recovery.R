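# Logistic recovery fitting on log abundance.
#
# The recovery model is ln N(t) = ln(K) / (1 + exp((m - t) / phi)), where K
# is the equilibrium population size, m the inflection time (log abundance
# equals ln(K)/2 there, i.e. abundance equals sqrt(K)), and phi the shape
# parameter: the log-scale deviation from the asymptote decays by a factor e
# per phi years, so phi is the return time (reciprocal of return rate).
# Among-weather-year variation enters as a random asymptote: ln(K)_y =
# ln(K) + b_y with b_y ~ N(0, sigma_b^2).

#' Three-parameter logistic on log abundance
#'
#' `lnK / (1 + exp((m - t) / phi))`: strictly increasing in t with upper
#' asymptote `lnK`; at `t = m` the predicted log abundance is `lnK / 2`
#' (abundance `sqrt(K)`).
#'
#' @param t time since perturbation (years).
#' @param lnK log equilibrium population size.
#' @param m inflection time.
#' @param phi shape parameter / return time (> 0).
#' @return predicted log abundance.
#' @export
logistic3 <- function(t, lnK, m, phi) {
  if (any(phi <= 0)) stop("phi must be > 0")
  lnK / (1 + exp((m - t) / phi))
}

#' Four-parameter logistic on log abundance
#'
#' `A + (lnK - A) / (1 + exp((m - t) / phi))`: lower asymptote `A`, upper
#' asymptote `lnK`; reduces to [logistic3()] when `A = 0`. Used where
#' growth rate initially increases with time after disturbance (the skylark
#' archetype).
#'
#' @param t time since perturbation (years).
#' @param A lower asymptote on the log scale (`A < lnK`).
#' @inheritParams logistic3
#' @return predicted log abundance.
#' @export
logistic4 <- function(t, A, lnK, m, phi) {
  if (any(phi <= 0)) stop("phi must be > 0")
  if (any(lnK <= A)) stop("lnK must exceed the lower asymptote A")
  A + (lnK - A) / (1 + exp((m - t) / phi))
}

#' Simulate logistic recovery segments
#'
#' Synthetic generator for fitting tests: `lnN(t) = logistic3(t; lnK + b_y,
#' m, phi) + e` with `b_y ~ N(0, sigma_b^2)` fixed per weather label across
#' the run and `e ~ N(0, sigma_e^2)`. Labels cycle with the calendar year,
#' as in the simulation protocol.
#'
#' @param K,m,phi logistic parameters (natural scale K).
#' @param sigma_e residual SD on the log scale.
#' @param sigma_b SD of the per-label asymptote deviations.
#' @param n_segments,segment_length design shape (default: the study's 10
#'   segments of 17 years).
#' @param n_labels number of weather labels (default 10).
#' @param seed integer seed.
#' @return segments data.frame (segment, t, N, lnN, y) with attribute `b_y`.
#' @export
simulate_logistic_trajectory <- function(K = 1000, m = 5, phi = 2,
                                         sigma_e = 0.1, sigma_b = 0.2,
                                         n_segments = 10L,
                                         segment_length = 17L,
                                         n_labels = 10L, seed = NULL) {
  stopifnot(K > 0, phi > 0, sigma_e >= 0, sigma_b >= 0,
            n_segments >= 1, segment_length >= 1, n_labels >= 1)
  local_seed(seed, {
    b <- stats::rnorm(n_labels, 0, sigma_b)
    seg <- rep(seq_len(n_segments), each = segment_length)
    t <- rep(seq_len(segment_length), n_segments)
    year <- (seg - 1L) * segment_length + t
    y <- weather_label(year, n_labels)
    lnN <- logistic3(t, log(K) + b[y], m, phi) +
      stats::rnorm(length(t), 0, sigma_e)
    out <- data.frame(segment = seg, t = t, N = exp(lnN), lnN = lnN, y = y)
    attr(out, "b_y") <- b
    attr(out, "segment_length") <- segment_length
    out
  })
}

# Pooled nonlinear least squares (stage 1). Returns list(par, fitted,
# converged, at_bound) or NULL on failure.
fit_stage1 <- function(t, lnN, form, segment_length, start = NULL) {
  phi_lo <- 0.05
  phi_hi <- 10 * segment_length
  if (is.null(start)) {
    lnK0 <- max(lnN)
    cross <- t[lnN >= lnK0 / 2]
    m0 <- if (length(cross)) min(cross) else stats::median(t)
    phi0 <- segment_length / 8
    start <- if (form == 3L) c(lnK = lnK0, m = m0, phi = phi0)
             else c(A = min(lnN), lnK = lnK0, m = m0, phi = phi0)
  }
  d <- data.frame(t = t, lnN = lnN)
  fml <- if (form == 3L) lnN ~ lnK / (1 + exp((m - t) / phi))
         else lnN ~ A + (lnK - A) / (1 + exp((m - t) / phi))
  lower <- if (form == 3L) c(lnK = 1e-8, m = -Inf, phi = phi_lo)
           else c(A = -Inf, lnK = 1e-8, m = -Inf, phi = phi_lo)
  upper <- if (form == 3L) c(lnK = Inf, m = Inf, phi = phi_hi)
           else c(A = Inf, lnK = Inf, m = Inf, phi = phi_hi)
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = d, start = as.list(start),
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  par <- stats::coef(fit)
  at_bound <- par["phi"] <= phi_lo * (1 + 1e-6) ||
    par["phi"] >= phi_hi * (1 - 1e-6)
  list(par = par, fitted = stats::fitted(fit), converged = TRUE,
       at_bound = at_bound)
}

predict_curve <- function(par, t, form, b = 0) {
  out <- if (form == 3L) logistic3(t, par[["lnK"]] + b, par[["m"]], par[["phi"]])
         else logistic4(t, par[["A"]], par[["lnK"]] + b, par[["m"]], par[["phi"]])
  as.vector(out)
}

empty_fit <- function(form, n_obs, diagnostic) {
  structure(list(coefficients = NULL, K = NA_real_, phi = NA_real_,
                 A = if (form == 4L) NA_real_, m = NA_real_,
                 b_y = NULL, sigma_b = NA_real_, sigma_e = NA_real_,
                 ci = NULL, converged = FALSE, n_obs = n_obs,
                 form = form, diagnostic = diagnostic),
            class = "recovery_fit")
}

#' Fit a logistic recovery model with weather-year random asymptotes
#'
#' Pools all post-perturbation segments and fits log abundance against time
#' since perturbation. Estimation is two-stage: (1) pooled nonlinear least
#' squares for the fixed parameters (lnK, m, phi, and the lower asymptote A
#' for the 4-parameter form); (2) per-weather-label asymptote deviations
#' b_y estimated from label means of late-window residuals (t >= m) with
#' empirical-Bayes shrinkage `lambda_y = sigma_b^2 / (sigma_b^2 +
#' sigma_e^2 / n_y)`, the variance components by method of moments. 95%
#' confidence intervals for K and phi come from a parametric bootstrap of
#' the full two-level model. When the optimizer fails, phi hits its bounds,
#' or the data carry no growth signal, the fit is returned with
#' `converged = FALSE` and no intervals rather than an exception.
#'
#' @param segments data.frame with columns `t` (time since perturbation),
#'   `lnN` (log abundance, NA for zero counts) and `y` (weather label), as
#'   produced by [segment_trajectory()] or
#'   [simulate_logistic_trajectory()].
#' @param form 3 or 4 (the 4-parameter form adds a lower asymptote).
#' @param n_boot parametric bootstrap replicates for the intervals.
#' @param seed integer seed for the bootstrap.
#' @param level confidence level.
#' @return object of class `recovery_fit`: estimates `K`, `m`, `phi`
#'   (and `A`), per-label deviations `b_y`, variance components `sigma_b`,
#'   `sigma_e`, bootstrap `ci`, `converged`, `n_obs`.
#' @export
fit_recovery <- function(segments, form = 3, n_boot = 200L, seed = NULL,
                         level = 0.95) {
  form <- as.integer(form)
  stopifnot(form %in% c(3L, 4L),
            all(c("t", "lnN", "y") %in% names(segments)))
  use <- is.finite(segments$lnN)
  d <- segments[use, ]
  if (nrow(d) < 8L)
    stop("need at least 8 usable (t, lnN, y) points")
  if (length(unique(d$y)) < 2L)
    stop("fewer than 2 weather labels: fit the pooled model without ",
         "random asymptotes instead")
  seg_len <- attr(segments, "segment_length")
  if (is.null(seg_len)) seg_len <- max(d$t)
  if (stats::sd(d$lnN) < 1e-10)
    return(empty_fit(form, nrow(d), "no growth signal"))

  s1 <- fit_stage1(d$t, d$lnN, form, seg_len)
  if (is.null(s1)) return(empty_fit(form, nrow(d), "optimizer failed"))
  if (s1$at_bound) return(empty_fit(form, nrow(d), "phi at bounds"))
  par <- s1$par

  ## stage 2: random-asymptote deviations from late-window residuals
  res <- d$lnN - predict_curve(par, d$t, form)
  late <- d$t >= par["m"]
  if (sum(late) < max(4L, 2L * length(unique(d$y))))
    late <- d$t >= stats::median(d$t)
  rl <- res[late]; yl <- d$y[late]
  n_y <- tapply(rl, yl, length)
  rbar <- tapply(rl, yl, mean)
  within <- tapply(rl, yl, function(z) if (length(z) > 1) stats::var(z) else NA)
  sigma_e2 <- stats::weighted.mean(within, w = pmax(n_y - 1, 0), na.rm = TRUE)
  if (!is.finite(sigma_e2)) sigma_e2 <- stats::var(rl)
  between <- if (length(rbar) > 1) stats::var(rbar) else 0
  sigma_b2 <- max(0, between - sigma_e2 * mean(1 / n_y))
  lambda <- sigma_b2 / (sigma_b2 + sigma_e2 / n_y)
  b_y <- lambda * rbar

  out <- structure(list(
    coefficients = par,
    K = unname(exp(par["lnK"])), phi = unname(par["phi"]),
    m = unname(par["m"]), A = if (form == 4L) unname(par["A"]),
    b_y = b_y, sigma_b = sqrt(sigma_b2), sigma_e = sqrt(max(sigma_e2, 0)),
    ci = NULL, converged = TRUE, n_obs = nrow(d), form = form,
    diagnostic = NULL, data = d, fitted = predict_curve(par, d$t, form),
    segment_length = seg_len, n_boot = n_boot, level = level
  ), class = "recovery_fit")
  out$residuals <- d$lnN - out$fitted

  ## parametric bootstrap for K and phi
  if (n_boot > 0L) {
    labs <- sort(unique(d$y))
    boot <- local_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        bs <- stats::rnorm(length(labs), 0, sqrt(sigma_b2))
        names(bs) <- labs
        lnN_b <- predict_curve(par, d$t, form, b = bs[as.character(d$y)]) +
          stats::rnorm(nrow(d), 0, sqrt(max(sigma_e2, 0)))
        s <- fit_stage1(d$t, lnN_b, form, seg_len, start = par)
        if (is.null(s)) c(NA_real_, NA_real_)
        else c(exp(s$par[["lnK"]]), s$par[["phi"]])
      }, numeric(2))
    })
    a <- (1 - level) / 2
    out$ci <- rbind(
      K   = stats::quantile(boot[1L, ], c(a, 1 - a), na.rm = TRUE),
      phi = stats::quantile(boot[2L, ], c(a, 1 - a), na.rm = TRUE))
    colnames(out$ci) <- c("lower", "upper")
  }
  out
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(x$form, "-parameter logistic recovery fit\n", sep = "")
  if (!x$converged) {
    cat("  did not converge:", x$diagnostic, "\n")
    return(invisible(x))
  }
  cat(sprintf("  K = %.4g, m = %.3g, phi = %.3g years", x$K, x$m, x$phi))
  if (!is.null(x$A)) cat(sprintf(", A = %.3g", x$A))
  cat("\n")
  if (!is.null(x$ci))
    cat(sprintf("  95%% CI: K [%.4g, %.4g], phi [%.3g, %.3g]\n",
                x$ci["K", 1], x$ci["K", 2], x$ci["phi", 1], x$ci["phi", 2]))
  cat(sprintf("  sigma_b = %.3g, sigma_e = %.3g, n = %d\n",
              x$sigma_b, x$sigma_e, x$n_obs))
  invisible(x)
}

#' @export
summary.recovery_fit <- function(object, ...) {
  print(object)
  if (object$converged && !is.null(object$b_y)) {
    cat("  weather-year asymptote deviations (b_y):\n")
    print(round(object$b_y, 4))
  }
  invisible(object)
}

#' @export
coef.recovery_fit <- function(object, ...) object$coefficients

#' @export
fitted.recovery_fit <- function(object, ...) object$fitted

#' @export
residuals.recovery_fit <- function(object, ...) object$residuals

#' Predict log abundance from a recovery fit
#'
#' @param object a converged `recovery_fit`.
#' @param newdata data.frame with column `t` and optionally `y` (weather
#'   label, adds the fitted b_y); defaults to the fitting data.
#' @param ... unused.
#' @return numeric vector of predicted log abundance.
#' @export
predict.recovery_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("fit did not converge")
  if (is.null(newdata)) return(object$fitted)
  b <- 0
  if (!is.null(newdata$y) && !is.null(object$b_y)) {
    b <- object$b_y[as.character(newdata$y)]
    b[is.na(b)] <- 0
  }
  predict_curve(object$coefficients, newdata$t, object$form, b = b)
}

#' Simulate from a fitted recovery model
#'
#' Parametric draws at the fitting design points: fresh b_y ~ N(0,
#' sigma_b^2) per label and residual noise N(0, sigma_e^2) around the
#' fitted curve.
#'
#' @param object a converged `recovery_fit`.
#' @param nsim number of simulated response vectors.
#' @param seed integer seed.
#' @param ... unused.
#' @return data.frame with one column per simulation.
#' @export
simulate.recovery_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("fit did not converge")
  d <- object$data
  labs <- sort(unique(d$y))
  local_seed(seed, {
    out <- replicate(nsim, {
      bs <- stats::setNames(stats::rnorm(length(labs), 0, object$sigma_b), labs)
      predict_curve(object$coefficients, d$t, object$form,
                    b = bs[as.character(d$y)]) +
        stats::rnorm(nrow(d), 0, object$sigma_e)
    })
    as.data.frame(out)
  })
}

#' @export
plot.recovery_fit <- function(x, ...) {
  if (!x$converged) stop("fit did not converge")
  d <- x$data
  graphics::plot(d$t, d$lnN, xlab = "years since perturbation",
                 ylab = "ln N", col = "grey40", ...)
  tt <- seq(min(d$t), max(d$t), length.out = 200)
  graphics::lines(tt, predict_curve(x$coefficients, tt, x$form), lwd = 2)
  invisible(x)
}

#' Equilibrium fit for an unperturbed trajectory
#'
#' Intercept-only model on log abundance whose intercept varies among
#' weather years: per-label intercepts are the label means of ln N over the
#' analyzed window, the grand equilibrium is `K = exp(mean of intercepts)`,
#' and the residual SD is pooled across labels (homogeneous variance).
#'
#' @param trajectory an unperturbed `trajectory`.
#' @return object of class `equilibrium_fit` with fields `intercepts`, `K`,
#'   `sigma_e`, `n_obs`.
#' @export
fit_unperturbed <- function(trajectory) {
  sched <- attr(trajectory, "schedule")
  if (!is.null(sched) && sched$removal_fraction > 0)
    stop("trajectory is perturbed; use segment_trajectory() + fit_recovery()")
  d <- trajectory[trajectory$analyzed & trajectory$N > 0, ]
  if (!nrow(d)) stop("no usable records in the analyzed window")
  lnN <- log(d$N)
  intercepts <- tapply(lnN, d$weather, mean)
  res <- lnN - intercepts[as.character(d$weather)]
  n_lab <- tapply(lnN, d$weather, length)
  df <- sum(n_lab - 1)
  structure(list(intercepts = intercepts,
                 K = unname(exp(mean(intercepts))),
                 sigma_e = if (df > 0) sqrt(sum(res^2) / df) else NA_real_,
                 n_obs = nrow(d)),
            class = "equilibrium_fit")
}

#' @export
print.equilibrium_fit <- function(x, ...) {
  cat("equilibrium (intercept-only) fit:",
      sprintf("K = %.4g, sigma_e = %.3g, n = %d\n", x$K, x$sigma_e, x$n_obs))
  invisible(x)
}

#' @export
coef.equilibrium_fit <- function(object, ...) object$intercepts

#' Per-segment asymptote estimates
#'
#' Fits a logistic with shared inflection and shape (m, phi) but a free
#' asymptote per segment: for fixed (m, phi) each segment's lnK has the
#' closed form `sum(g * lnN) / sum(g^2)` with `g(t) = 1 / (1 + exp((m - t) /
#' phi))`, and (m, phi) are profiled out numerically. Standard errors are
#' conditional on (m, phi). Enables inspection of equilibrium decline under
#' repeated perturbation.
#'
#' @param segments segments data.frame (>= 2 segments).
#' @return data.frame (segment, lnK, se_lnK, K, se_K) with attributes `m`,
#'   `phi`, `sigma`.
#' @export
segmentwise_K <- function(segments) {
  use <- is.finite(segments$lnN)
  d <- segments[use, ]
  segs <- sort(unique(d$segment))
  if (length(segs) < 2L) stop("need at least 2 segments")
  si <- match(d$segment, segs)
  seg_len <- attr(segments, "segment_length")
  if (is.null(seg_len)) seg_len <- max(d$t)

  profile_lnK <- function(m, phi) {
    g <- 1 / (1 + exp((m - d$t) / phi))
    num <- tapply(g * d$lnN, si, sum)
    den <- tapply(g * g, si, sum)
    list(lnK = num / den, g = g, den = den)
  }
  rss <- function(p) {
    phi <- exp(p[2L])
    pr <- profile_lnK(p[1L], phi)
    sum((d$lnN - pr$lnK[si] * pr$g)^2)
  }
  lnK0 <- max(d$lnN)
  cross <- d$t[d$lnN >= lnK0 / 2]
  m0 <- if (length(cross)) min(cross) else stats::median(d$t)
  opt <- stats::optim(c(m0, log(seg_len / 8)), rss, method = "Nelder-Mead")
  m <- opt$par[1L]; phi <- exp(opt$par[2L])
  pr <- profile_lnK(m, phi)
  dof <- nrow(d) - (2L + length(segs))
  sigma2 <- opt$value / max(dof, 1L)
  se_lnK <- sqrt(sigma2 / pr$den)
  out <- data.frame(segment = segs, lnK = as.numeric(pr$lnK),
                    se_lnK = as.numeric(se_lnK),
                    K = exp(as.numeric(pr$lnK)))
  out$se_K <- out$K * out$se_lnK
  attr(out, "m") <- m
  attr(out, "phi") <- phi
  attr(out, "sigma") <- sqrt(sigma2)
  out
}
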