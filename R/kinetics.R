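#' Assay series
#'
#' Initial-rate measurements for one replicate of an enzyme assay: a set of
#' substrate concentrations and the corresponding initial rates, with the
#' co-substrate (when present) held saturating.
#'
#' @param substrate_id Substrate varied in the assay (e.g. `"Fru6P"`,
#'   `"NH4"`, `"GlcN6P"`).
#' @param concentrations Strictly positive, strictly increasing substrate
#'   concentrations (mM).
#' @param rates Non-negative initial rates (absorbance-derived units/min),
#'   same length as `concentrations`.
#' @param replicate_id Replicate label.
#' @param activator_conc Concentration (mM) of the candidate allosteric
#'   activator GlcNAc6P present during the assay (0 = none).
#' @return An object of class `AssaySeries`.
#' @export
assay_series <- function(substrate_id, concentrations, rates,
                         replicate_id = 1L, activator_conc = 0) {
  stopifnot(length(concentrations) == length(rates),
            all(concentrations > 0),
            all(diff(concentrations) > 0),
            all(rates >= 0))
  structure(list(substrate_id = substrate_id,
                 concentrations = as.numeric(concentrations),
                 rates = as.numeric(rates),
                 replicate_id = replicate_id,
                 activator_conc = activator_conc),
            class = "AssaySeries")
}

check_series <- function(series, need_positive_rates = TRUE) {
  stopifnot(is.list(series), length(series) >= 1)
  for (s in series) {
    stopifnot(inherits(s, "AssaySeries"))
    if (length(unique(s$concentrations)) < 3) {
      stop("fewer than 3 distinct concentrations in replicate ",
           s$replicate_id)
    }
    if (need_positive_rates && any(s$rates == 0)) {
      stop("zero rate in replicate ", s$replicate_id,
           ": reciprocal transform undefined")
    }
  }
  invisible(TRUE)
}

pool_fits <- function(per_rep, method) {
  valid <- per_rep[per_rep$valid, , drop = FALSE]
  n <- nrow(valid)
  if (n == 0L) {
    return(structure(list(Km = NA_real_, Vmax = NA_real_,
                          Km_se = NA_real_, Vmax_se = NA_real_,
                          n_replicates = 0L, method = method,
                          replicate_fits = per_rep, valid = FALSE),
                     class = "KineticFit"))
  }
  se <- function(x) if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
  structure(list(Km = mean(valid$Km), Vmax = mean(valid$Vmax),
                 Km_se = se(valid$Km), Vmax_se = se(valid$Vmax),
                 n_replicates = n, method = method,
                 replicate_fits = per_rep, valid = TRUE),
            class = "KineticFit")
}

#' @export
print.KineticFit <- function(x, ...) {
  cat(sprintf("KineticFit (%s): Km = %.4g +/- %.2g mM, Vmax = %.4g +/- %.2g (n = %d)\n",
              x$method, x$Km, x$Km_se, x$Vmax, x$Vmax_se, x$n_replicates))
  invisible(x)
}

#' Km and Vmax by double-reciprocal (Lineweaver-Burk) regression
#'
#' Per replicate, unweighted ordinary least squares of `1/v` on `1/[S]`:
#' with intercept `1/Vmax` and slope `Km/Vmax`, so `Km = slope/intercept`
#' and `Vmax = 1/intercept`. Replicates are fitted separately and pooled as
#' mean with standard error `sd/sqrt(n)` across replicates, so the pooled
#' estimate carries a spread comparable to a reported mean +/- SD over
#' n = 2-3 assays. A replicate with non-positive intercept is flagged
#' invalid and excluded from the pool.
#'
#' The double-reciprocal transform is exact on noiseless Michaelis-Menten
#' data but statistically fragile under noise (low-concentration points
#' dominate); [fit_michaelis_nonlinear()] is the robust cross-check.
#'
#' @param series List of [assay_series()] replicates (at least one), each
#'   with at least 3 distinct concentrations and strictly positive rates.
#' @return A `KineticFit`: pooled `Km` (mM), `Vmax`, standard errors,
#'   `n_replicates`, `method = "lineweaver_burk"` and the per-replicate
#'   table in `$replicate_fits`.
#' @export
fit_lineweaver_burk <- function(series) {
  if (inherits(series, "AssaySeries")) series <- list(series)
  check_series(series, need_positive_rates = TRUE)
  per_rep <- do.call(rbind, lapply(series, function(s) {
    fit <- stats::lm(y ~ x, data = data.frame(x = 1 / s$concentrations,
                                              y = 1 / s$rates))
    ic <- stats::coef(fit)[[1]]; sl <- stats::coef(fit)[[2]]
    data.frame(replicate_id = s$replicate_id,
               Km = if (ic > 0) sl / ic else NA_real_,
               Vmax = if (ic > 0) 1 / ic else NA_real_,
               valid = ic > 0)
  }))
  pool_fits(per_rep, "lineweaver_burk")
}

#' Km and Vmax by nonlinear Michaelis-Menten least squares
#'
#' Per replicate, direct least-squares fit of `v = Vmax [S] / (Km + [S])`
#' (Levenberg-Marquardt, started from a double-reciprocal or heuristic
#' guess), pooled across replicates as in [fit_lineweaver_burk()]. Zero
#' rates are permitted. A replicate is flagged invalid when the optimizer
#' fails to converge, the estimates are non-positive, or the fit explains
#' less than half the rate variance (`R^2 < 0.5` — the model-mismatch
#' guard, e.g. for monotone-decreasing rates).
#'
#' @param series List of [assay_series()] replicates.
#' @return A `KineticFit` with `method = "michaelis_nls"`.
#' @export
fit_michaelis_nonlinear <- function(series) {
  if (inherits(series, "AssaySeries")) series <- list(series)
  check_series(series, need_positive_rates = FALSE)
  per_rep <- do.call(rbind, lapply(series, function(s) {
    d <- data.frame(S = s$concentrations, v = s$rates)
    start <- list(Vmax = max(d$v) * 1.2 + 1e-9, Km = stats::median(d$S))
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = d, start = start,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(replicate_id = s$replicate_id, Km = NA_real_,
                        Vmax = NA_real_, valid = FALSE))
    }
    co <- stats::coef(fit)
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((d$v - mean(d$v))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    ok <- is.finite(co[["Km"]]) && co[["Km"]] > 0 && co[["Vmax"]] > 0 &&
      r2 >= 0.5
    data.frame(replicate_id = s$replicate_id,
               Km = if (ok) co[["Km"]] else NA_real_,
               Vmax = if (ok) co[["Vmax"]] else NA_real_,
               valid = ok)
  }))
  fit <- pool_fits(per_rep, "michaelis_nls")
  if (!fit$valid) stop("nonlinear Michaelis-Menten fit failed for all replicates")
  fit
}

#' Compare Km between two conditions
#'
#' Welch two-sample t-test on replicate-level Km estimates — the test
#' behind the "activator has no influence" conclusion (no influence iff
#' p > 0.05). Degenerate zero-variance inputs are handled explicitly:
#' identical constant samples give p = 1, different constant samples p = 0.
#'
#' @param km_a,km_b Numeric vectors of per-replicate Km estimates (each of
#'   length at least 2).
#' @return A `KmComparison`: list with `Km_a`, `Km_b` (means), `p_value`
#'   and `conclusion` (`"no influence"` or `"differs"`).
#' @export
compare_km <- function(km_a, km_b) {
  if (length(km_a) < 2 || length(km_b) < 2) {
    stop("compare_km needs at least 2 replicates per condition")
  }
  if (stats::sd(km_a) == 0 && stats::sd(km_b) == 0) {
    p <- if (isTRUE(all.equal(mean(km_a), mean(km_b)))) 1 else 0
  } else {
    p <- stats::t.test(km_a, km_b, var.equal = FALSE)$p.value
  }
  structure(list(Km_a = mean(km_a), Km_b = mean(km_b), p_value = p,
                 conclusion = if (p > 0.05) "no influence" else "differs"),
            class = "KmComparison")
}

#' Test activity above a no-enzyme blank
#'
#' One-sided Welch t-test of measured rates against blank (no-enzyme or
#' no-substrate control) rates. Used to represent the
#' glutamine-dependent-amination assay outcome: an enzyme with no activity
#' on a substrate pair gives rates indistinguishable from the blank.
#'
#' @param rates Numeric vector of assay rates.
#' @param blank_rates Numeric vector of control rates.
#' @param alpha Significance level (default 0.05).
#' @return List with `active` (logical), `p_value`, `mean_rate`,
#'   `mean_blank`.
#' @export
activity_above_blank <- function(rates, blank_rates, alpha = 0.05) {
  stopifnot(length(rates) >= 2, length(blank_rates) >= 2)
  if (stats::sd(rates) == 0 && stats::sd(blank_rates) == 0) {
    p <- if (mean(rates) > mean(blank_rates)) 0 else 1
  } else {
    p <- stats::t.test(rates, blank_rates, alternative = "greater",
                       var.equal = FALSE)$p.value
  }
  list(active = p < alpha, p_value = p,
       mean_rate = mean(rates), mean_blank = mean(blank_rates))
}

#' Read assay series from CSV
#'
#' Expected columns: `replicate`, `substrate`, `conc_mM`, `rate`,
#' `activator_mM`. Rows are grouped into one [assay_series()] per
#' (substrate, replicate, activator) combination.
#'
#' @param path CSV file path.
#' @return List of `AssaySeries`.
#' @export
read_assays <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("replicate", "substrate", "conc_mM", "rate", "activator_mM")
  missing <- setdiff(need, names(d))
  if (length(missing)) stop("assay CSV lacks column(s): ",
                            paste(missing, collapse = ", "))
  keys <- interaction(d$substrate, d$replicate, d$activator_mM, drop = TRUE)
  lapply(split(d, keys), function(g) {
    g <- g[order(g$conc_mM), ]
    assay_series(g$substrate[1], g$conc_mM, g$rate,
                 replicate_id = g$replicate[1],
                 activator_conc = g$activator_mM[1])
  })
}

#' Write assay series to CSV
#'
#' @param series List of `AssaySeries`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assays <- function(series, path) {
  d <- do.call(rbind, lapply(series, function(s) {
    data.frame(replicate = s$replicate_id, substrate = s$substrate_id,
               conc_mM = s$concentrations, rate = s$rates,
               activator_mM = s$activator_conc)
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
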