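#' Boundary sigmoid
#'
#' `y(x) = ymin + ymax * exp((x - xc)/b) / (1 + exp((x - xc)/b))`: `ymin`
#' is the lower saturation level, `ymax` the amplitude of the step, `xc`
#' the abscissa of the central point (where `y = ymin + ymax/2`) and `b`
#' sets the slope at the central point (its sign sets the orientation).
#'
#' @param x abscissa (cm for distance curves, ms of touch delay for
#'   behavioral curves).
#' @param ymin,ymax,xc,b parameters; `b != 0`.
#' @return y values.
#' @export
boundary_sigmoid <- function(x, ymin, ymax, xc, b) {
  stopifnot(b != 0)
  # plogis((x - xc)/b) = e^((x-xc)/b) / (1 + e^((x-xc)/b)), overflow-safe
  ymin + ymax * stats::plogis((x - xc) / b)
}

#' Fit the boundary sigmoid by nonlinear least squares
#'
#' Levenberg-Marquardt least squares of the four parameters (ymin, ymax,
#' xc, b) on (x, y) pairs, optionally weighted. Repetition-level data are
#' fitted pooled. Initialization: `ymin = min(y)`, `ymax = range(y)`, `xc`
#' at the steepest local slope of a 3-point moving average, `b` a tenth of
#' the x-range with the sign of the observed trend; five jittered restarts
#' are tried on failure and the best converged fit (lowest residual sum of
#' squares) is kept.
#'
#' The 95 percent confidence interval of `xc` is t-based from the
#' asymptotic parameter covariance at the optimum. When the transition is
#' steeper than the sampling grid the Jacobian in `b` degenerates and the
#' asymptotic interval is meaningless; with `ci_method = "auto"` (default)
#' such fits fall back to a stratified bootstrap (repetitions resampled
#' within each x, percentile interval over refits), which can also be
#' requested explicitly. The fit report also
#' records the abscissa at which the fitted curve crosses the midpoint of
#' its own saturation levels, `(ymin + (ymin + ymax))/2`, which for this
#' parameterization coincides with `xc`; both are kept because the two
#' midpoint conventions circulating for this curve differ when `ymin` is
#' treated as part of the upper level.
#'
#' @param x,y data vectors (`length >= 4`); `x` need not be unique
#'   (pooled repetitions) but must span a nondegenerate range.
#' @param weights optional nonnegative weights.
#' @param ci_method `"auto"`, `"asymptotic"` or `"bootstrap"`.
#' @param n_boot bootstrap replicates (only used when bootstrapping).
#' @return a `boundary_fit` object: estimates, covariance, `ci95_xc`,
#'   residual sum of squares, convergence flag.
#' @examples
#' x <- seq(0, 140, 10)
#' y <- boundary_sigmoid(x, 100, 50, 60, 5)
#' fit <- fit_sigmoid(x, y)
#' fit$coef["xc"]  # 60
#' @export
fit_sigmoid <- function(x, y, weights = NULL,
                        ci_method = c("auto", "asymptotic", "bootstrap"),
                        n_boot = 200) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (diff(range(x)) == 0) stop("degenerate fit: x has no range")
  if (stats::sd(y) == 0 || diff(range(y)) < 1e-12 * max(1, abs(mean(y))))
    stop("degenerate fit: flat response, no boundary to locate")
  if (is.null(weights)) weights <- rep(1, length(x))
  dat <- data.frame(x = x, y = y, w = weights)

  # initialization from the pooled per-x means
  mx <- sort(unique(x))
  my <- tapply(y, x, mean)[as.character(mx)]
  sm <- if (length(my) >= 3) stats::filter(my, rep(1 / 3, 3), sides = 2) else my
  sm[is.na(sm)] <- my[is.na(sm)]
  slopes <- diff(as.numeric(sm)) / diff(mx)
  i_st <- which.max(abs(slopes))
  xc0 <- mean(mx[c(i_st, i_st + 1)])
  rising <- stats::cor(x, y) >= 0
  b0 <- diff(range(x)) / 10 * (if (rising) 1 else -1)
  start0 <- c(ymin = min(my), ymax = diff(range(my)), xc = xc0, b = b0)

  # slope magnitude bounded below at a quarter grid step: transitions
  # sharper than the sampling cannot be resolved and break the Jacobian
  grid_step <- min(diff(mx))
  b_floor <- grid_step / 4
  one_fit <- function(st) {
    sgn <- if (st[["b"]] >= 0) 1 else -1
    st[["b"]] <- sgn * max(abs(st[["b"]]), b_floor)
    lo <- c(ymin = -Inf, ymax = -Inf, xc = -Inf,
            b = if (sgn > 0) b_floor else -Inf)
    hi <- c(ymin = Inf, ymax = Inf, xc = Inf,
            b = if (sgn > 0) Inf else -b_floor)
    tryCatch(
      minpack.lm::nlsLM(
        y ~ boundary_sigmoid(x, ymin, ymax, xc, b),
        data = dat, start = as.list(st), weights = dat$w,
        lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  }
  # deterministic starts first (slope tempered both ways), then jitters
  starts <- list(start0)
  for (fac in c(0.25, 4)) {
    st <- start0; st["b"] <- st["b"] * fac; starts <- c(starts, list(st))
  }
  for (off in c(-grid_step, grid_step)) {
    st <- start0; st["xc"] <- st["xc"] + off; starts <- c(starts, list(st))
  }
  fit <- NULL
  for (st in starts) {
    cand <- one_fit(st)
    if (!is.null(cand) &&
        (is.null(fit) || sum(stats::resid(cand)^2) < sum(stats::resid(fit)^2)))
      fit <- cand
  }
  tries <- 0
  while (tries < 5 && (is.null(fit) || !fit$convInfo$isConv)) {
    tries <- tries + 1
    jit <- start0 * stats::runif(4, 0.7, 1.3)
    jit["xc"] <- start0["xc"] + stats::runif(1, -0.25, 0.25) * diff(range(x))
    cand <- one_fit(jit)
    if (!is.null(cand) &&
        (is.null(fit) || sum(stats::resid(cand)^2) < sum(stats::resid(fit)^2)))
      fit <- cand
  }
  if (is.null(fit))
    return(structure(list(converged = FALSE, coef = NULL, vcov = NULL,
                          ci95_xc = c(NA_real_, NA_real_), rss = NA_real_,
                          df = NA_integer_, n = length(x)),
                     class = "boundary_fit"))
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 4, 4))
  dfree <- length(x) - 4L
  tq <- if (dfree > 0) stats::qt(0.975, dfree) else NA_real_
  se_xc <- sqrt(vc["xc", "xc"])
  ci <- unname(cf["xc"] + c(-1, 1) * tq * se_xc)
  ci_used <- "asymptotic"
  degenerate <- !is.finite(se_xc) || se_xc > diff(range(x))
  if (ci_method == "bootstrap" || (ci_method == "auto" && degenerate)) {
    bci <- bootstrap_xc_ci(dat, cf, n_boot)
    if (!is.null(bci)) { ci <- bci; ci_used <- "bootstrap" }
  }
  structure(list(converged = isTRUE(fit$convInfo$isConv),
                 coef = cf, vcov = vc, ci95_xc = ci,
                 ci_method = ci_used,
                 se_xc = unname(se_xc),
                 rss = sum(stats::resid(fit)^2), df = dfree, n = length(x),
                 midpoint_level = unname(cf["ymin"] + cf["ymax"] / 2),
                 fitted_at = function(x) boundary_sigmoid(x, cf["ymin"],
                                                          cf["ymax"], cf["xc"],
                                                          cf["b"])),
            class = "boundary_fit")
}

# stratified bootstrap over repetitions: resample y within each unique x,
# refit starting from the full-data optimum, percentile interval of xc
bootstrap_xc_ci <- function(dat, cf, n_boot) {
  groups <- split(seq_len(nrow(dat)), dat$x)
  grid_step <- min(diff(sort(unique(dat$x))))
  b_floor <- grid_step / 4
  st <- cf
  sgn <- if (st[["b"]] >= 0) 1 else -1
  st[["b"]] <- sgn * max(abs(st[["b"]]), grid_step)
  lo <- c(ymin = -Inf, ymax = -Inf, xc = -Inf,
          b = if (sgn > 0) b_floor else -Inf)
  hi <- c(ymin = Inf, ymax = Inf, xc = Inf,
          b = if (sgn > 0) Inf else -b_floor)
  xcs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(groups, function(g) g[sample.int(length(g),
                                                          replace = TRUE)]))
    db <- dat[idx, ]
    fb <- tryCatch(
      minpack.lm::nlsLM(y ~ boundary_sigmoid(x, ymin, ymax, xc, b),
                        data = db, start = as.list(st), weights = db$w,
                        lower = lo, upper = hi,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fb)) xcs[b] <- stats::coef(fb)["xc"]
  }
  xcs <- xcs[is.finite(xcs)]
  if (length(xcs) < n_boot / 2) return(NULL)
  unname(stats::quantile(xcs, c(0.025, 0.975)))
}

#' @export
print.boundary_fit <- function(x, ...) {
  if (is.null(x$coef)) { cat("boundary fit: FAILED to converge\n"); return(invisible(x)) }
  cat(sprintf("boundary sigmoid fit (n = %d, rss = %.4g%s)\n", x$n, x$rss,
              if (x$converged) "" else ", NOT converged"))
  cat(sprintf("  ymin = %.3f  ymax = %.3f  xc = %.3f  b = %.3f\n",
              x$coef["ymin"], x$coef["ymax"], x$coef["xc"], x$coef["b"]))
  cat(sprintf("  central point xc = %.2f, 95%% CI [%.2f, %.2f]\n",
              x$coef["xc"], x$ci95_xc[1], x$ci95_xc[2]))
  invisible(x)
}

#' Compare two boundary fits
#'
#' Reports the shift of the central point between two fitted curves and
#' whether their 95 percent confidence intervals are disjoint.
#'
#' @param fit_a,fit_b converged `boundary_fit` objects (e.g. before and
#'   after training).
#' @return list with `xc_a`, `xc_b`, `shift` (`xc_b - xc_a`), `ci_a`,
#'   `ci_b`, and `disjoint` (logical).
#' @export
compare_boundaries <- function(fit_a, fit_b) {
  if (is.null(fit_a$coef) || is.null(fit_b$coef) ||
      !fit_a$converged || !fit_b$converged)
    stop("both fits must have converged")
  disjoint <- fit_a$ci95_xc[2] < fit_b$ci95_xc[1] ||
    fit_b$ci95_xc[2] < fit_a$ci95_xc[1]
  list(xc_a = unname(fit_a$coef["xc"]), xc_b = unname(fit_b$coef["xc"]),
       shift = unname(fit_b$coef["xc"] - fit_a$coef["xc"]),
       ci_a = fit_a$ci95_xc, ci_b = fit_b$ci95_xc, disjoint = disjoint)
}

#' Fit the boundary sigmoid to a reaction-time curve
#'
#' Convenience wrapper pooling the repetition-level reaction times of a
#' [rt_vs_distance()] result.
#'
#' @param curve a `pps_rtcurve`.
#' @return a `boundary_fit`.
#' @export
fit_rt_curve <- function(curve) {
  reps <- curve$reps[!curve$reps$censored, ]
  fit_sigmoid(reps$distance, reps$rt)
}
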