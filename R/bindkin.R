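#' Fit a Hill binding curve to an EMSA titration
#'
#' Unweighted least-squares fit of
#' `fraction_bound = conc^H / (K_D^H + conc^H)` with a multi-start over a
#' log-spaced K_D grid (EMSA titrations are sparse and the Hill surface
#' can hold shallow local minima).  95% confidence intervals are computed
#' by profile likelihood, falling back to asymptotic (Wald) intervals
#' when profiling fails; R-squared is `1 - SS_res / SS_tot`.
#'
#' Free enzyme is approximated by total enzyme (no ligand-depletion
#' correction), the standard treatment for Hill fits of EMSA titrations;
#' see the methods vignette for the caveat.
#'
#' @param curve A titration tibble with columns `concentration` (nM) and
#'   `fraction_bound`; replicate rows are simply pooled.
#' @param level Confidence level (default 0.95).
#' @return A `hill_fit` object with elements `kd`, `h`, `se_kd`, `se_h`,
#'   `ci_kd`, `ci_h`, `r_squared`, `converged`, `ci_method`, `n_points`
#'   and the data; see [tidy.hill_fit()] / [glance.hill_fit()].
#' @export
fit_hill <- function(curve, level = 0.95) {
  stopifnot(all(c("concentration", "fraction_bound") %in% names(curve)))
  conc <- curve$concentration
  fb <- curve$fraction_bound
  if (dplyr::n_distinct(conc) < 4) {
    stop("need at least 4 distinct concentrations to fit a Hill curve",
         call. = FALSE)
  }
  if (stats::sd(fb) < 1e-12) {
    stop("flat titration: fraction bound does not vary", call. = FALSE)
  }
  pos <- conc[conc > 0]
  kd_grid <- exp(seq(log(max(min(pos), 1e-3)), log(max(conc)), length.out = 7))
  dat <- data.frame(conc = conc, fb = fb)
  best <- NULL
  for (kd0 in kd_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fb ~ ifelse(conc <= 0, 0, conc^h / (kd^h + conc^h)),
        data = dat, start = list(kd = kd0, h = 1),
        lower = c(kd = 1e-6, h = 0.05), upper = c(kd = 1e6, h = 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(kd = NA_real_, h = NA_real_, se_kd = NA_real_,
                          se_h = NA_real_, ci_kd = c(NA_real_, NA_real_),
                          ci_h = c(NA_real_, NA_real_), r_squared = NA_real_,
                          converged = FALSE, ci_method = NA_character_,
                          n_points = nrow(curve), level = level, data = curve),
                     class = "hill_fit"))
  }
  fit <- best$fit
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  ss_tot <- sum((fb - mean(fb))^2)
  r2 <- 1 - best$rss / ss_tot
  ci <- tryCatch(
    suppressWarnings(suppressMessages(stats::confint(fit, level = level))),
    error = function(e) NULL
  )
  if (!is.null(ci) && !anyNA(ci)) {
    ci_method <- "profile"
  } else {
    tq <- stats::qt(1 - (1 - level) / 2, df = nrow(dat) - 2)
    ci <- rbind(kd = est["kd"] + c(-1, 1) * tq * se["kd"],
                h = est["h"] + c(-1, 1) * tq * se["h"])
    ci_method <- "asymptotic"
  }
  structure(
    list(kd = unname(est["kd"]), h = unname(est["h"]),
         se_kd = unname(se["kd"]), se_h = unname(se["h"]),
         ci_kd = unname(ci["kd", ]), ci_h = unname(ci["h", ]),
         r_squared = r2, converged = TRUE, ci_method = ci_method,
         n_points = nrow(curve), level = level, data = curve),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> K_D = %.3g nM [%.3g, %.3g], H = %.3g [%.3g, %.3g], R^2 = %.4g (%s CI, n = %d)\n",
              x$kd, x$ci_kd[1], x$ci_kd[2], x$h, x$ci_h[1], x$ci_h[2],
              x$r_squared, x$ci_method, x$n_points))
  invisible(x)
}

#' Tidy a Hill fit
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd", "h"),
    estimate = c(x$kd, x$h),
    std.error = c(x$se_kd, x$se_h),
    conf.low = c(x$ci_kd[1], x$ci_h[1]),
    conf.high = c(x$ci_kd[2], x$ci_h[2])
  )
}

#' One-row summary of a Hill fit
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return A tibble: `r.squared`, `converged`, `ci.method`, `nobs`.
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, converged = x$converged,
                 ci.method = x$ci_method, nobs = x$n_points)
}

#' Estimate the initial rate of a remodeling or ATPase time course
#'
#' Default (`"exponential"`): fits the saturating exponential
#' `A * (1 - exp(-k * t))` and reports the analytic initial slope
#' `v0 = A * k` with a delta-method standard error.  If the exponential
#' fit does not converge (e.g. the course is still linear over the
#' sampled times), falls back to `"linear-early"` with a warning flag:
#' an ordinary regression over the early points whose signal is below
#' `early_fraction` of the maximum.
#'
#' @param tc A time-course tibble with columns `time` (s, including 0)
#'   and `signal` (nM).
#' @param method `"exponential"` or `"linear-early"`.
#' @param early_fraction Signal cutoff (fraction of max) defining the
#'   early linear phase.
#' @return A `rate_fit` object: `v0`, `se`, `plateau`, `k`, `method`,
#'   `fallback`, `n_points`, plus the data.
#' @export
fit_initial_rate <- function(tc, method = c("exponential", "linear-early"),
                             early_fraction = 0.3) {
  method <- match.arg(method)
  stopifnot(all(c("time", "signal") %in% names(tc)))
  if (nrow(tc) < 4 || !any(tc$time == 0)) {
    stop("need at least 4 time points including t = 0", call. = FALSE)
  }
  if (method == "exponential") {
    f <- fit_rate_exponential(tc)
    if (!is.null(f)) return(f)
    warning("exponential fit did not converge; falling back to linear-early")
    f <- fit_rate_linear(tc, early_fraction)
    f$fallback <- TRUE
    return(f)
  }
  fit_rate_linear(tc, early_fraction)
}

fit_rate_exponential <- function(tc) {
  dat <- data.frame(t = tc$time, y = tc$signal)
  a0 <- max(dat$y)
  if (a0 <= 0) a0 <- 1
  pos <- dat$t > 0 & dat$y > 0
  k0 <- if (any(pos)) {
    stats::median(-log(pmax(1e-6, 1 - pmin(dat$y[pos] / (a0 * 1.05), 0.999))) /
                    dat$t[pos])
  } else 0.01
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)), data = dat,
                      start = list(A = a0, k = max(k0, 1e-4)),
                      lower = c(A = 1e-9, k = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  est <- stats::coef(fit)
  # a fit pinned near the k lower bound means the curve never saturates
  if (est["k"] <= 2e-9) return(NULL)
  V <- stats::vcov(fit)
  v0 <- unname(est["A"] * est["k"])
  grad <- c(est["k"], est["A"])  # d(Ak)/dA, d(Ak)/dk
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  structure(list(v0 = v0, se = se, plateau = unname(est["A"]),
                 k = unname(est["k"]), method = "exponential",
                 fallback = FALSE, n_points = nrow(tc), data = tc),
            class = "rate_fit")
}

fit_rate_linear <- function(tc, early_fraction) {
  cutoff <- early_fraction * max(tc$signal)
  early <- tc[tc$signal < cutoff | tc$time == 0, , drop = FALSE]
  if (nrow(early) < 2) early <- tc[order(tc$time), ][1:3, ]
  fit <- stats::lm(signal ~ time, data = early)
  sm <- summary(fit)$coefficients
  structure(list(v0 = unname(stats::coef(fit)["time"]),
                 se = unname(sm["time", "Std. Error"]),
                 plateau = NA_real_, k = NA_real_, method = "linear-early",
                 fallback = FALSE, n_points = nrow(tc), data = tc),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> v0 = %.3g +/- %.3g nM/s (%s%s, n = %d)\n",
              x$v0, x$se, x$method, if (x$fallback) ", fallback" else "",
              x$n_points))
  invisible(x)
}

#' Tidy a rate fit
#' @param x A `rate_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `term = "v0"`, `estimate`, `std.error`.
#' @export
tidy.rate_fit <- function(x, ...) {
  tibble::tibble(term = "v0", estimate = x$v0, std.error = x$se)
}

#' One-row summary of a rate fit
#' @param x A `rate_fit`.
#' @param ... Unused.
#' @return A tibble: `plateau`, `k`, `method`, `fallback`, `nobs`.
#' @export
glance.rate_fit <- function(x, ...) {
  tibble::tibble(plateau = x$plateau, k = x$k, method = x$method,
                 fallback = x$fallback, nobs = x$n_points)
}

#' Fold ratio between two rates with reporting-style rounding
#'
#' Computes `a / b` exactly and also rounded the way such comparisons are
#' conventionally printed: to the nearest integer for large ratios
#' (>= `integer_from`), to one decimal place below that.
#'
#' @param a,b `rate_fit` objects or positive scalars (numerator,
#'   denominator); a `rate_fit` contributes its `v0`.
#' @param integer_from Ratio magnitude from which rounding switches to
#'   whole numbers (default 10).
#' @return A one-row tibble: `exact`, `rounded`.
#' @export
#' @examples
#' fold_ratio(0.77, 0.060)  # exact 12.83, rounded 13
fold_ratio <- function(a, b, integer_from = 10) {
  num <- if (inherits(a, "rate_fit")) a$v0 else a
  den <- if (inherits(b, "rate_fit")) b$v0 else b
  if (!is.numeric(num) || !is.numeric(den)) stop("inputs must be rates or numbers")
  if (den == 0) stop("fold ratio undefined for a zero denominator", call. = FALSE)
  exact <- num / den
  rounded <- if (abs(exact) >= integer_from) round(exact) else round(exact, 1)
  tibble::tibble(exact = exact, rounded = rounded)
}
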