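# Doubling times are estimated by ordinary least squares on ln(OD) versus
# time over the contiguous window that maximizes r^2, restricted to readings
# inside an OD band that excludes the noise-dominated start of the curve and
# the plateau. The window search is exhaustive over all contiguous runs of
# in-bounds readings, using running sums so each candidate window costs O(1).

#' Fit the exponential-phase growth rate of one OD series
#'
#' Restricts the series to readings with `od_low <= OD <= od_high`
#' (`od_high = NA` means half the observed maximum), then finds the
#' contiguous window of at least `min_points` readings whose ordinary
#' least-squares fit of `ln(OD)` against time has the highest r^2. Ties are
#' broken toward the earlier window, then toward the longer one. The slope
#' is the specific growth rate mu (1/h).
#'
#' @param time Numeric vector of times in hours, strictly increasing.
#' @param od Numeric vector of OD600 readings, same length.
#' @param min_points Minimum number of readings in the fit window.
#' @param od_low,od_high OD bounds for in-bounds readings.
#' @param sample_id Label used in error messages.
#' @return A list with `mu` (1/h), `window` = c(t_start, t_end), `r2`, `n`.
#' @export
fit_exponential_window <- function(time, od, min_points = 4,
                                   od_low = 0.04, od_high = NA,
                                   sample_id = "series") {
  stopifnot(length(time) == length(od), length(time) >= 2)
  if (any(diff(time) <= 0)) {
    stop("times must be strictly increasing for ", sample_id, call. = FALSE)
  }
  if (is.na(od_high)) od_high <- max(od) / 2
  keep <- !is.na(od) & od >= od_low & od <= od_high & od > 0
  if (sum(keep) < min_points) {
    stop("fewer than ", min_points, " in-bounds OD readings for ", sample_id,
         call. = FALSE)
  }
  idx <- which(keep)
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  best <- NULL
  eps <- 1e-12
  for (run in runs) {
    if (length(run) < min_points) next
    x <- time[run]
    y <- log(od[run])
    n_run <- length(run)
    cx <- cumsum(x);  cy <- cumsum(y)
    cxx <- cumsum(x * x); cyy <- cumsum(y * y); cxy <- cumsum(x * y)
    at <- function(c, i) if (i == 0) 0 else c[i]
    for (i in seq_len(n_run - min_points + 1)) {
      for (j in seq(i + min_points - 1, n_run)) {
        n <- j - i + 1
        sx <- at(cx, j) - at(cx, i - 1)
        sy <- at(cy, j) - at(cy, i - 1)
        sxx <- at(cxx, j) - at(cxx, i - 1)
        syy <- at(cyy, j) - at(cyy, i - 1)
        sxy <- at(cxy, j) - at(cxy, i - 1)
        ssxx <- n * sxx - sx * sx
        ssyy <- n * syy - sy * sy
        ssxy <- n * sxy - sx * sy
        slope <- ssxy / ssxx
        # constant ln(OD): the flat line fits exactly; define r^2 = 1
        r2 <- if (ssyy <= eps * max(1, syy)) 1 else (ssxy * ssxy) / (ssxx * ssyy)
        cand <- list(mu = slope, window = c(x[i], x[j]), r2 = r2, n = n)
        if (is.null(best) ||
            r2 > best$r2 + eps ||
            (abs(r2 - best$r2) <= eps &&
             (x[i] < best$window[1] - eps ||
              (abs(x[i] - best$window[1]) <= eps && n > best$n)))) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) {
    stop("no contiguous in-bounds window of >= ", min_points,
         " readings for ", sample_id, call. = FALSE)
  }
  best
}

#' Doubling time from a specific growth rate
#'
#' @param mu Specific growth rate in 1/h; must be positive.
#' @return Doubling time `ln(2)/mu` in hours.
#' @export
#' @examples
#' doubling_time(log(2))  # 1 hour
doubling_time <- function(mu) {
  if (any(mu <= 0)) stop("mu must be > 0 to define a doubling time", call. = FALSE)
  log(2) / mu
}

#' Mean and standard error of per-replicate maximum density
#'
#' @param series A tibble with `sample_id`, `time`, `od` covering one or
#'   more replicate series.
#' @return A list with `max_od` (mean of per-replicate maxima), `se`
#'   (sd/sqrt(n); `NA` for a single replicate), `n`, and the per-replicate
#'   maxima.
#' @export
max_density_summary <- function(series) {
  if (nrow(series) == 0) stop("no OD readings supplied", call. = FALSE)
  maxima <- series |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(max_od = max(.data$od), .groups = "drop")
  n <- nrow(maxima)
  list(
    max_od = mean(maxima$max_od),
    se = if (n >= 2) stats::sd(maxima$max_od) / sqrt(n) else NA_real_,
    n = n,
    maxima = maxima
  )
}

#' Compare maximum densities across conditions
#'
#' One-way ANOVA on per-replicate maximum OD with Tukey HSD post-hoc
#' comparisons; pairs are flagged at adjusted p < 0.05. With zero variance
#' between and within groups (degenerate identical inputs) the ANOVA p is
#' reported as 1 and no pair is flagged.
#'
#' @param maxima A tibble with columns `condition` and `max_od`, one row per
#'   replicate.
#' @param alpha Flagging threshold.
#' @return A list with `anova_f`, `anova_p`, and `tukey` (tibble: pair,
#'   diff, padj, flag).
#' @export
compare_max_density <- function(maxima, alpha = 0.05) {
  counts <- table(maxima$condition)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need >= 2 conditions with >= 2 replicates each", call. = FALSE)
  }
  if (stats::var(maxima$max_od) == 0) {
    pairs <- utils::combn(names(counts), 2, paste, collapse = "-")
    return(list(
      anova_f = 0, anova_p = 1,
      tukey = tibble::tibble(pair = pairs, diff = 0, padj = 1, flag = FALSE)
    ))
  }
  maxima$condition <- factor(maxima$condition)
  fit <- stats::aov(max_od ~ condition, data = maxima)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$condition
  tukey <- tibble::tibble(
    pair = rownames(tk),
    diff = tk[, "diff"],
    padj = tk[, "p adj"],
    flag = tk[, "p adj"] < alpha
  )
  list(anova_f = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1], tukey = tukey)
}

#' Fit a logistic growth model to one OD series
#'
#' Nonlinear least squares on the three-parameter logistic
#' `OD(t) = K / (1 + ((K - OD0)/OD0) exp(-mu t))` via the self-starting
#' parametrization `Asym / (1 + exp((xmid - t)/scal))`, where `mu = 1/scal`
#' and `K = Asym`. Batch cultures monitored to saturation are fit whole;
#' no window selection is needed and the plateau pins down `K`.
#'
#' @param time,od Numeric vectors (hours, OD600).
#' @param sample_id Label used in error messages.
#' @return A list with `mu` (1/h), `K`, `td` (hours).
#' @export
fit_logistic_curve <- function(time, od, sample_id = "series") {
  dat <- data.frame(time = time, od = od)
  fit <- tryCatch(
    stats::nls(od ~ stats::SSlogis(time, Asym, xmid, scal), data = dat,
               control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) {
      stop("logistic fit failed for ", sample_id, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  cf <- stats::coef(fit)
  mu <- 1 / cf[["scal"]]
  list(mu = mu, K = cf[["Asym"]], td = log(2) / mu)
}

#' Summarize growth kinetics per condition
#'
#' Estimates the specific growth rate of every replicate series, converts
#' to doubling times, and aggregates per condition: mean and standard
#' error (sd/sqrt(n)) of the doubling time and of the maximum observed
#' density.
#'
#' Two estimators are available. `"logistic"` (default) fits the full
#' logistic model ([fit_logistic_curve()]), which is unbiased for batch
#' curves monitored into stationary phase; a series on which the nonlinear
#' fit fails falls back to the window estimator. `"window"` uses the
#' log-linear sliding-window fit ([fit_exponential_window()]); note that
#' on saturating curves the r-squared-selected window absorbs logistic
#' curvature and underestimates mu, so it is best reserved for series
#' truncated within the exponential phase.
#'
#' @param od A tibble with `sample_id`, `time`, `od`.
#' @param design The sample design, as from [design_samples()].
#' @param method `"logistic"` (default) or `"window"`.
#' @param min_points,od_low,od_high Window-fit settings; see
#'   [fit_exponential_window()].
#' @return A tibble with one row per condition: `condition`, `mu`, `td`,
#'   `td_se`, `max_od`, `max_od_se`, `n_reps`.
#' @export
growth_summary <- function(od, design = design_samples(),
                           method = c("logistic", "window"),
                           min_points = 4, od_low = 0.04, od_high = NA) {
  method <- match.arg(method)
  dat <- dplyr::inner_join(od, design, by = "sample_id")
  if (nrow(dat) == 0) stop("no OD samples match the design", call. = FALSE)
  fit_mu <- function(time, od, id) {
    if (method == "logistic") {
      tryCatch(fit_logistic_curve(time, od, sample_id = id)$mu,
               error = function(e) {
                 fit_exponential_window(time, od, min_points = min_points,
                                        od_low = od_low, od_high = od_high,
                                        sample_id = id)$mu
               })
    } else {
      fit_exponential_window(time, od, min_points = min_points,
                             od_low = od_low, od_high = od_high,
                             sample_id = id)$mu
    }
  }
  per_rep <- dat |>
    dplyr::group_by(.data$condition, .data$sample_id) |>
    dplyr::summarise(
      mu = fit_mu(.data$time, .data$od, .data$sample_id[1]),
      max_od = max(.data$od),
      .groups = "drop"
    ) |>
    dplyr::mutate(td = doubling_time(.data$mu))
  per_rep |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      td_se = if (dplyr::n() >= 2) stats::sd(.data$td) / sqrt(dplyr::n()) else NA_real_,
      td = mean(.data$td),
      mu = log(2) / td,
      max_od_se = if (dplyr::n() >= 2) stats::sd(.data$max_od) / sqrt(dplyr::n()) else NA_real_,
      max_od = mean(.data$max_od),
      n_reps = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("condition", "mu", "td", "td_se", "max_od", "max_od_se", "n_reps")
}
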