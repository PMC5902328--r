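#' Growth curve
#'
#' An OD600 time series for one culture replicate.
#'
#' @param times Strictly increasing sampling times (h).
#' @param od600 Non-negative optical densities (dimensionless), same
#'   length as `times`.
#' @param replicate_id Replicate label.
#' @param condition Condition label (e.g. the sugar supplement).
#' @return An object of class `GrowthCurve`.
#' @export
growth_curve <- function(times, od600, replicate_id = 1L, condition = "") {
  stopifnot(length(times) == length(od600),
            all(diff(times) > 0), all(od600 >= 0))
  structure(list(times = as.numeric(times), od600 = as.numeric(od600),
                 replicate_id = replicate_id, condition = condition),
            class = "GrowthCurve")
}

# All simple linear regressions y ~ t over contiguous fixed-length
# windows, by prefix sums: slope and R^2 in O(1) per window.
window_regressions <- function(t, y, len) {
  n <- length(t)
  ct <- cumsum(t); ct2 <- cumsum(t^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2); cty <- cumsum(t * y)
  seg <- function(cs, i, j) cs[j] - if (i > 1) cs[i - 1] else 0
  out <- list()
  for (i in seq_len(n - len + 1L)) {
    j <- i + len - 1L
    St <- seg(ct, i, j); Stt <- seg(ct2, i, j)
    Sy <- seg(cy, i, j); Syy <- seg(cy2, i, j); Sty <- seg(cty, i, j)
    sxx <- Stt - St^2 / len
    sst <- Syy - Sy^2 / len
    slope <- (Sty - St * Sy / len) / sxx
    sse <- max(0, sst - slope^2 * sxx)
    r2 <- if (sst > 0) 1 - sse / sst else 0
    out[[length(out) + 1L]] <- c(i = i, j = j, slope = slope, r2 = r2)
  }
  do.call(rbind, out)
}

fit_one_curve <- function(curve, r2_min, window_points, floor_od, blank,
                          min_rise) {
  od <- curve$od600 - blank
  keep_all <- which(od > floor_od)        # above the detection floor
  keep <- keep_all[keep_all <= which.max(od)]  # and before the OD peak
  t <- curve$times[keep]; y <- log(od[keep])
  none <- data.frame(replicate_id = curve$replicate_id, mu = 0,
                     t_start = NA_real_, t_end = NA_real_,
                     r_squared = NA_real_, flag = "no_growth")
  if (length(keep_all) < 3) return(none)
  if (length(t) >= window_points) {
    w <- window_regressions(t, y, window_points)
    rise <- w[, "slope"] * (t[w[, "j"]] - t[w[, "i"]])
    ok <- w[w[, "r2"] >= r2_min & rise >= min_rise, , drop = FALSE]
    if (nrow(ok)) {
      best <- ok[which.max(ok[, "slope"]), ]
      return(data.frame(replicate_id = curve$replicate_id,
                        mu = best[["slope"]],
                        t_start = t[best[["i"]]], t_end = t[best[["j"]]],
                        r_squared = best[["r2"]], flag = "ok"))
    }
  }
  # No window shows a clean exponential rise: either growth too slow to
  # clear min_rise within a window (near the detection limit) or no growth
  # at all. Fall back to the slope over the whole curve (no peak
  # truncation, which would bias a noisy flat curve upward) and keep it
  # only when significantly positive.
  t <- curve$times[keep_all]; y <- log(od[keep_all])
  fit <- stats::lm(y ~ t)
  sm <- summary(fit)$coefficients
  slope <- sm["t", "Estimate"]
  p_one_sided <- stats::pt(sm["t", "t value"], df = length(t) - 2,
                           lower.tail = FALSE)
  if (is.finite(p_one_sided) && slope > 0 && p_one_sided < 0.01) {
    data.frame(replicate_id = curve$replicate_id, mu = slope,
               t_start = t[1], t_end = t[length(t)],
               r_squared = summary(fit)$r.squared, flag = "whole_curve")
  } else {
    none
  }
}

#' Specific growth rate from OD600 curves
#'
#' Per replicate, the specific growth rate mu (h^-1) is the slope of
#' `ln(OD600)` versus time over an automatically selected exponential
#' window. After blank subtraction, points at or below the detection floor
#' and points after the OD maximum are excluded; every contiguous window
#' of exactly `window_points` samples is fitted by OLS and the steepest
#' window satisfying `R^2 >= r2_min` and a total log-rise of at least
#' `min_rise` is selected (the max-slope rule keeps the estimate in early
#' exponential phase, before saturation flattens the curve; the rise
#' requirement stops noise-aligned windows from faking growth). When no
#' window qualifies, a whole-curve log-linear slope is kept only if
#' significantly positive (one-sided p < 0.01) and flagged
#' `"whole_curve"` — the regime of very slow growth near the detection
#' limit; otherwise the replicate is an explicit no-growth result
#' (`mu = 0`, flag `"no_growth"`). Replicates are pooled as mean with
#' across-replicate SD.
#'
#' @param curves List of [growth_curve()] replicates (at least one), each
#'   with at least 4 points.
#' @param r2_min R-squared gate for the exponential window (default 0.98).
#' @param window_points Window length in samples (default 5).
#' @param floor_od Detection floor on blank-subtracted OD (default 0.01).
#' @param blank Blank OD subtracted before the log transform (default 0).
#' @param min_rise Minimum fitted increase of `ln(OD)` across the window
#'   (default 0.3, i.e. ~35% OD increase).
#' @return A `RateEstimate`: list with pooled `mu` (h^-1), `sd` across
#'   replicates, `window` (earliest start, latest end over replicates, h),
#'   `r_squared` (mean over fitted replicates), `flag` (`"ok"`,
#'   `"no_growth"` when every replicate is flagged no-growth, else
#'   `"mixed"`), and the per-replicate table in `$replicates`.
#' @export
estimate_growth_rate <- function(curves, r2_min = 0.98, window_points = 5,
                                 floor_od = 0.01, blank = 0,
                                 min_rise = 0.3) {
  if (inherits(curves, "GrowthCurve")) curves <- list(curves)
  stopifnot(length(curves) >= 1, window_points >= 4)
  for (cu in curves) {
    stopifnot(inherits(cu, "GrowthCurve"))
    if (length(cu$times) < 4) stop("growth curve needs at least 4 points")
  }
  reps <- do.call(rbind, lapply(curves, fit_one_curve, r2_min = r2_min,
                                window_points = window_points,
                                floor_od = floor_od, blank = blank,
                                min_rise = min_rise))
  flags <- reps$flag
  flag <- if (all(flags == "no_growth")) "no_growth" else
    if (all(flags == "ok")) "ok" else "mixed"
  fitted <- reps[reps$flag != "no_growth", , drop = FALSE]
  structure(list(
    mu = if (flag == "no_growth") 0 else mean(reps$mu),
    sd = if (nrow(reps) > 1) stats::sd(reps$mu) else NA_real_,
    window = c(t_start = suppressWarnings(min(fitted$t_start)),
               t_end = suppressWarnings(max(fitted$t_end))),
    r_squared = if (nrow(fitted)) mean(fitted$r_squared) else NA_real_,
    flag = flag, replicates = reps), class = "RateEstimate")
}

#' @export
print.RateEstimate <- function(x, ...) {
  cat(sprintf("RateEstimate: mu = %.4g h^-1 (sd %.2g, %d replicates, %s)\n",
              x$mu, x$sd, nrow(x$replicates), x$flag))
  invisible(x)
}

#' Metabolite time series
#'
#' HPLC-style concentration time series for one growth condition.
#'
#' @param times Strictly increasing sampling times (h).
#' @param concentrations Data frame (or named list) of non-negative
#'   concentrations (mM), one column per analyte, `length(times)` rows.
#' @param condition Condition label.
#' @return An object of class `MetaboliteTimeSeries`.
#' @export
metabolite_timeseries <- function(times, concentrations, condition = "") {
  conc <- as.data.frame(concentrations)
  stopifnot(all(diff(times) > 0), nrow(conc) == length(times),
            all(as.matrix(conc) >= 0))
  structure(list(times = as.numeric(times), concentrations = conc,
                 condition = condition),
            class = "MetaboliteTimeSeries")
}

#' Acetate:propionate production ratio
#'
#' Endpoint production of each short-chain fatty acid (final minus initial
#' concentration, floored at 0) and their ratio. When no propionate is
#' produced the ratio is undefined (`defined = FALSE`, `ratio = NA`) — the
#' situation of a substrate that is degraded without SCFA production. The
#' ratio is invariant to a shared dilution factor.
#'
#' @param ts A [metabolite_timeseries()] containing `acetate` and
#'   `propionate` columns.
#' @param detection_limit Production (mM) below which an acid counts as
#'   not produced (default 0.05 mM, an HPLC-scale quantification floor).
#' @return A `ScfaRatio`: list with `acetate_produced`,
#'   `propionate_produced` (mM), `ratio`, `defined`.
#' @export
scfa_ratio <- function(ts, detection_limit = 0.05) {
  stopifnot(inherits(ts, "MetaboliteTimeSeries"))
  for (a in c("acetate", "propionate")) {
    if (!a %in% names(ts$concentrations)) stop("missing analyte: ", a)
  }
  produced <- function(a) {
    x <- ts$concentrations[[a]]
    p <- max(0, x[length(x)] - x[1])
    if (p < detection_limit) 0 else p
  }
  ac <- produced("acetate"); pr <- produced("propionate")
  structure(list(acetate_produced = ac, propionate_produced = pr,
                 ratio = if (pr > 0) ac / pr else NA_real_,
                 defined = pr > 0),
            class = "ScfaRatio")
}

#' Linear consumption rates of sugars
#'
#' Per analyte, the consumption rate (mM/h) is minus the OLS slope of
#' concentration versus time over the depletion phase: from the first
#' sample until the first sample below 5% of the initial concentration
#' (inclusive), or the whole series when the analyte is never depleted.
#' When exactly two analytes are requested, their rates are declared equal
#' when the 95% confidence intervals of the slopes overlap — the test
#' behind "consumed at the same rate".
#'
#' @param ts A [metabolite_timeseries()].
#' @param analytes Character vector of analyte names present in `ts`.
#' @return Data frame with columns `analyte`, `rate` (mM/h), `ci_lower`,
#'   `ci_upper`; with exactly two analytes the attribute `"equal"` holds
#'   the equality verdict.
#' @export
consumption_rates <- function(ts, analytes) {
  stopifnot(inherits(ts, "MetaboliteTimeSeries"), length(ts$times) >= 3)
  missing <- setdiff(analytes, names(ts$concentrations))
  if (length(missing)) stop("missing analyte(s): ",
                            paste(missing, collapse = ", "))
  rows <- lapply(analytes, function(a) {
    x <- ts$concentrations[[a]]
    below <- which(x < 0.05 * x[1])
    last <- if (length(below)) below[1] else length(x)
    last <- max(last, 3L)
    fit <- stats::lm(conc ~ time, data = data.frame(
      time = ts$times[1:last], conc = x[1:last]))
    # noise-free series give an exactly collinear fit; the CI is then [x, x]
    ci <- suppressWarnings(stats::confint(fit)["time", ])
    ci[is.na(ci)] <- stats::coef(fit)[["time"]]
    data.frame(analyte = a, rate = -stats::coef(fit)[["time"]],
               ci_lower = -ci[2], ci_upper = -ci[1], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (length(analytes) == 2L) {
    overlap <- out$ci_lower[1] <= out$ci_upper[2] &&
      out$ci_lower[2] <= out$ci_upper[1]
    attr(out, "equal") <- overlap
  }
  out
}

#' Read growth curves from CSV
#'
#' Expected columns: `condition`, `replicate`, `time_h`, `od600`. One
#' [growth_curve()] per (condition, replicate).
#'
#' @param path CSV file path.
#' @return List of `GrowthCurve`s.
#' @export
read_growth_curves <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "replicate", "time_h", "od600")
  missing <- setdiff(need, names(d))
  if (length(missing)) stop("growth CSV lacks column(s): ",
                            paste(missing, collapse = ", "))
  keys <- interaction(d$condition, d$replicate, drop = TRUE)
  lapply(split(d, keys), function(g) {
    g <- g[order(g$time_h), ]
    growth_curve(g$time_h, g$od600, replicate_id = g$replicate[1],
                 condition = g$condition[1])
  })
}

#' Write growth curves to CSV
#'
#' @param curves List of `GrowthCurve`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_growth_curves <- function(curves, path) {
  d <- do.call(rbind, lapply(curves, function(cu) {
    data.frame(condition = cu$condition, replicate = cu$replicate_id,
               time_h = cu$times, od600 = cu$od600)
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read metabolite time series from CSV
#'
#' Expected (long-format HPLC) columns: `condition`, `time_h`, `analyte`,
#' `conc_mM`. One [metabolite_timeseries()] per condition.
#'
#' @param path CSV file path.
#' @return List of `MetaboliteTimeSeries`.
#' @export
read_hplc <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "time_h", "analyte", "conc_mM")
  missing <- setdiff(need, names(d))
  if (length(missing)) stop("HPLC CSV lacks column(s): ",
                            paste(missing, collapse = ", "))
  lapply(split(d, d$condition), function(g) {
    wide <- stats::reshape(g[, c("time_h", "analyte", "conc_mM")],
                           idvar = "time_h", timevar = "analyte",
                           direction = "wide")
    wide <- wide[order(wide$time_h), ]
    names(wide) <- sub("^conc_mM\\.", "", names(wide))
    metabolite_timeseries(wide$time_h, wide[, -1, drop = FALSE],
                          condition = g$condition[1])
  })
}

#' Write a metabolite time series to CSV
#'
#' @param ts_list List of `MetaboliteTimeSeries`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hplc <- function(ts_list, path) {
  d <- do.call(rbind, lapply(ts_list, function(ts) {
    do.call(rbind, lapply(names(ts$concentrations), function(a) {
      data.frame(condition = ts$condition, time_h = ts$times,
                 analyte = a, conc_mM = ts$concentrations[[a]])
    }))
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
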