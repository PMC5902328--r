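# Flux balance analysis via linear programming.
#
# The LP core is a dense two-phase primal simplex with Bland's
# anti-cycling rule. The FBA problem is shifted to standard form first:
# x = v - lb >= 0, equalities S x = -S lb, upper-bound rows x_i + s_i =
# ub_i - lb_i, and (for FVA) an objective-pinning row c'x - t = r with a
# surplus variable t. Phase 1 minimizes artificials on the equality rows;
# phase 2 optimizes the objective with artificial columns removed.

# Minimize obj'z over the current tableau (A z = b, z >= 0, basis given).
simplex_core <- function(obj, A, b, basis, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A)
  for (it in seq_len(max_iter)) {
    red <- obj - as.numeric(crossprod(obj[basis], A))
    enter <- which(red < -tol)
    if (!length(enter)) {
      return(list(status = "optimal", A = A, b = b, basis = basis))
    }
    j <- min(enter)                     # Bland's rule: smallest index enters
    col <- A[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratios <- b[pos] / col[pos]
    cand <- pos[ratios <= min(ratios) + tol]
    i <- cand[which.min(basis[cand])]   # Bland's rule: smallest index leaves
    piv <- A[i, j]
    A[i, ] <- A[i, ] / piv
    b[i] <- b[i] / piv
    upd <- which(abs(A[, j]) > 0)
    upd <- upd[upd != i]
    if (length(upd)) {
      f <- A[upd, j]
      A[upd, ] <- A[upd, , drop = FALSE] - outer(f, A[i, ])
      b[upd] <- pmax(b[upd] - f * b[i], 0)
    }
    basis[i] <- j
  }
  stop("LP solver failure: simplex iteration limit reached")
}

# Minimize (or maximize) cvec'x s.t. Aeq x = beq, 0 <= x <= u (u may be Inf).
lp_standard <- function(cvec, Aeq, beq, u, maximize = TRUE, tol = 1e-9) {
  n <- length(cvec)
  Aeq <- as.matrix(Aeq)
  neg <- beq < 0
  if (any(neg)) {
    Aeq[neg, ] <- -Aeq[neg, , drop = FALSE]
    beq[neg] <- -beq[neg]
  }
  fin <- which(is.finite(u))
  m1 <- nrow(Aeq); nf <- length(fin)
  # columns: x (n) | bound slacks (nf) | artificials (m1)
  Eb <- matrix(0, nf, n); Eb[cbind(seq_len(nf), fin)] <- 1
  A <- rbind(cbind(Aeq, matrix(0, m1, nf), diag(m1)),
             cbind(Eb, diag(nf), matrix(0, nf, m1)))
  b <- c(beq, u[fin])
  basis <- c(n + nf + seq_len(m1), n + seq_len(nf))
  obj1 <- c(rep(0, n + nf), rep(1, m1))
  ph1 <- simplex_core(obj1, A, b, basis, tol = tol)
  if (ph1$status != "optimal") stop("LP solver failure in phase 1")
  art_level <- sum(ph1$b[ph1$basis > n + nf])
  if (art_level > 1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  A <- ph1$A; b <- ph1$b; basis <- ph1$basis
  # pivot residual zero-level artificials out of the basis, or drop rows
  keep <- rep(TRUE, nrow(A))
  for (i in which(basis > n + nf)) {
    piv_j <- which(abs(A[i, seq_len(n + nf)]) > tol)
    if (length(piv_j)) {
      j <- piv_j[1]
      piv <- A[i, j]
      A[i, ] <- A[i, ] / piv; b[i] <- b[i] / piv
      upd <- setdiff(which(abs(A[, j]) > 0), i)
      if (length(upd)) {
        f <- A[upd, j]
        A[upd, ] <- A[upd, , drop = FALSE] - outer(f, A[i, ])
        b[upd] <- pmax(b[upd] - f * b[i], 0)
      }
      basis[i] <- j
    } else {
      keep[i] <- FALSE                 # redundant constraint row
    }
  }
  A <- A[keep, seq_len(n + nf), drop = FALSE]
  b <- b[keep]; basis <- basis[keep]
  obj2 <- c(if (maximize) -cvec else cvec, rep(0, nf))
  ph2 <- simplex_core(obj2, A, b, basis, tol = tol)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  x <- numeric(n + nf)
  x[ph2$basis] <- ph2$b
  x <- x[seq_len(n)]
  list(status = "optimal", x = x, objective = sum(cvec * x))
}

solve_lp <- function(S, lb, ub, obj_coef, direction = "max",
                     extra = NULL) {
  n <- length(lb)
  stopifnot(ncol(S) == n, length(ub) == n, length(obj_coef) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("FBA requires finite flux bounds")
  }
  Aeq <- as.matrix(S)
  beq <- as.numeric(-S %*% lb)
  u <- ub - lb
  cvec <- obj_coef
  if (!is.null(extra)) {
    for (con in extra) {  # list(coef (length n, v-space), rhs, dir=">=")
      if (con$dir != ">=") stop("only >= extra constraints supported")
      Aeq <- rbind(cbind(Aeq, 0), c(con$coef, -1))
      beq <- c(beq, con$rhs - sum(con$coef * lb))
      u <- c(u, Inf)
      cvec <- c(cvec, 0)
    }
  }
  res <- lp_standard(cvec, Aeq, beq, u, maximize = direction == "max")
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, v = NULL))
  }
  v <- res$x[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj_coef * v), v = v)
}

model_lp_parts <- function(model) {
  S <- as.matrix(stoichiometric_matrix(model))
  list(S = S,
       lb = vapply(model$reactions, `[[`, 0, "lower_bound"),
       ub = vapply(model$reactions, `[[`, 0, "upper_bound"),
       ids = reaction_ids(model))
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through an objective reaction subject
#' to the steady-state constraint `S v = 0` and the per-reaction flux
#' bounds. At steady state the production of every internal metabolite
#' equals its consumption; exchange reactions carry uptake as negative and
#' secretion as positive flux. All quantities are in the model's arbitrary
#' units (a.u.).
#'
#' The objective value is deterministic for fixed input; the returned flux
#' vector is one optimal vertex and may not be unique — use
#' [flux_variability()] for per-reaction ranges.
#'
#' @param model A `MetabolicModel` with finite bounds.
#' @param objective_id Reaction to optimize; defaults to the model's
#'   objective (biomass).
#' @param direction `"max"` or `"min"`.
#' @return An `FBAResult`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_value` (a.u.; `NA` when
#'   not optimal) and `fluxes` (named numeric vector over reaction ids,
#'   `NULL` when not optimal). A solver that fails numerically raises an
#'   error rather than returning a silent zero.
#' @export
fba_optimize <- function(model, objective_id = model$objective_id,
                         direction = c("max", "min")) {
  direction <- match.arg(direction)
  validate_model(model)
  p <- model_lp_parts(model)
  if (!objective_id %in% p$ids) stop("unknown objective reaction: ", objective_id)
  obj <- as.numeric(p$ids == objective_id)
  sol <- solve_lp(p$S, p$lb, p$ub, obj, direction)
  structure(list(status = sol$status,
                 objective_value = sol$objective,
                 fluxes = if (is.null(sol$v)) NULL else
                   stats::setNames(sol$v, p$ids)),
            class = "FBAResult")
}

#' @export
print.FBAResult <- function(x, ...) {
  cat(sprintf("FBAResult: %s, objective = %s a.u.\n", x$status,
              format(x$objective_value, digits = 6)))
  invisible(x)
}

#' Flux variability analysis
#'
#' For every reaction, the minimal and maximal flux compatible with the
#' objective held at (at least) `fraction_of_optimum` times its optimum —
#' at fraction 1.0 the ranges are those compatible with maximal growth.
#' The objective is pinned from below with a `1e-9` slack to avoid spurious
#' infeasibility at the vertex.
#'
#' @param model A `MetabolicModel`.
#' @param objective_id Objective reaction id (defaults to the biomass
#'   objective).
#' @param fraction_of_optimum Number in `[0, 1]`.
#' @return Data frame with columns `reaction_id`, `min_flux`, `max_flux`
#'   (a.u.), one row per reaction.
#' @export
flux_variability <- function(model, objective_id = model$objective_id,
                             fraction_of_optimum = 1.0) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  base <- fba_optimize(model, objective_id)
  if (base$status != "optimal") {
    stop("FVA undefined: base FBA problem is ", base$status)
  }
  p <- model_lp_parts(model)
  obj <- as.numeric(p$ids == objective_id)
  pin <- list(list(coef = obj,
                   rhs = fraction_of_optimum * base$objective_value - 1e-9,
                   dir = ">="))
  n <- length(p$ids)
  mins <- numeric(n); maxs <- numeric(n)
  for (k in seq_len(n)) {
    ck <- as.numeric(seq_len(n) == k)
    lo <- solve_lp(p$S, p$lb, p$ub, ck, "min", extra = pin)
    hi <- solve_lp(p$S, p$lb, p$ub, ck, "max", extra = pin)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem infeasible for reaction ", p$ids[k])
    }
    mins[k] <- lo$objective; maxs[k] <- hi$objective
  }
  data.frame(reaction_id = p$ids, min_flux = pmin(mins, maxs),
             max_flux = pmax(mins, maxs), row.names = NULL)
}

#' Knock out a reaction
#'
#' Returns a copy of the model with both bounds of `reaction_id` set to
#' zero — the in-silico equivalent of removing the catalyzing enzyme (used
#' e.g. for the hypothetical glucosamine transporter mutant). Idempotent;
#' the input model is unmodified.
#'
#' @param model A `MetabolicModel`.
#' @param reaction_id Reaction to disable.
#' @return The modified model copy.
#' @export
knockout <- function(model, reaction_id) {
  if (!reaction_id %in% reaction_ids(model)) {
    stop("unknown reaction: ", reaction_id)
  }
  set_bounds(model, reaction_id, lower_bound = 0, upper_bound = 0)
}
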