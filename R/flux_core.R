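# LP assembly shared by FBA, pFBA, FVA, deletions and the samplers.
# The steady-state constraint S v = 0 plus per-reaction bounds define the
# flux polytope; the objective is the model's objective coefficient vector.
build_lp <- function(model, bounds = NULL) {
  bs <- as_bounds(model, bounds)
  list(S = as.matrix(model$stoichiometry),
       lb = bs$lower_bound,
       ub = bs$upper_bound,
       obj = model$reactions$objective_coefficient,
       rxn = model$reactions$id)
}

check_finite_bounds <- function(lp) {
  if (any(!is.finite(lp$lb)) || any(!is.finite(lp$ub)))
    stop(paste0("model has infinite bounds; close open exchange bounds ",
                "(e.g. apply a medium) before flux analysis"))
}

flux_vector <- function(lp, res, label = "fba") {
  fl <- if (res$status == "optimal") stats::setNames(res$x, lp$rxn)
        else stats::setNames(rep(NA_real_, length(lp$rxn)), lp$rxn)
  structure(list(label = label,
                 fluxes = fl,
                 objective_value = if (res$status == "optimal")
                   sum(lp$obj * res$x) else NA_real_,
                 status = res$status),
            class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, ...) {
  cat(sprintf("flux_vector '%s': status %s, objective %s\n", x$label,
              x$status, format(x$objective_value)))
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the model objective `c'v` subject to the steady-state
#' constraint `S v = 0` and the reaction bounds. When the optimum is
#' degenerate (alternative optima) the individual fluxes returned are one
#' arbitrary optimal vertex; only the objective value is unique (use
#' [pfba()] when a reproducible representative distribution matters).
#'
#' @param model a `metabolic_model` with at least one nonzero objective
#'   coefficient.
#' @param bounds optional per-sample bounds data.frame (see
#'   [apply_ras_to_bounds()]); defaults to the model's bounds.
#' @return A `flux_vector`: list with `fluxes` (named, mmol/gDW/h),
#'   `objective_value` and `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"` — never an error for these states).
#' @export
fba <- function(model, bounds = NULL) {
  lp <- build_lp(model, bounds)
  check_finite_bounds(lp)
  if (all(lp$obj == 0)) stop("model has no objective coefficient set")
  res <- solve_lp(lp$S, rep(0, nrow(lp$S)), lp$obj, lp$lb, lp$ub, "max")
  flux_vector(lp, res, "fba")
}

# threshold for the "objective >= fraction of optimum" side constraint,
# relaxed by 1e-6 (relative) to absorb solver round-off
opt_threshold <- function(opt, fraction) {
  fraction * opt - 1e-6 * max(1, abs(opt))
}

# append a constraint obj'v >= thr via a slack column
with_objective_floor <- function(lp, thr) {
  big <- max(1e6, 10 * sum(abs(lp$ub)) + 10 * sum(abs(lp$lb)))
  list(S = rbind(cbind(lp$S, 0), c(lp$obj, -1)),
       b = c(rep(0, nrow(lp$S)), 0),
       lb = c(lp$lb, thr), ub = c(lp$ub, big))
}

#' Parsimonious flux balance analysis
#'
#' First finds the FBA optimum, then minimizes the total absolute flux
#' `sum(|v|)` subject to the original constraints plus
#' `c'v >= fraction_of_optimum * optimum`. Each flux is split into
#' non-negative forward and reverse parts so the L1 objective is linear.
#' The returned `objective_value` is the original objective's value at the
#' parsimonious solution.
#'
#' @inheritParams fba
#' @param fraction_of_optimum fraction in `(0, 1]` of the FBA optimum that
#'   the parsimonious solution must retain (default 1).
#' @return A `flux_vector` with an extra element `total_flux` =
#'   `sum(|v|)`.
#' @export
pfba <- function(model, bounds = NULL, fraction_of_optimum = 1) {
  stopifnot(fraction_of_optimum > 0, fraction_of_optimum <= 1)
  lp <- build_lp(model, bounds)
  check_finite_bounds(lp)
  if (all(lp$obj == 0)) stop("model has no objective coefficient set")
  base <- solve_lp(lp$S, rep(0, nrow(lp$S)), lp$obj, lp$lb, lp$ub, "max")
  if (base$status != "optimal") return(flux_vector(lp, base, "pfba"))
  thr <- opt_threshold(base$objective, fraction_of_optimum)

  n <- length(lp$rxn); m <- nrow(lp$S)
  # v = f - r, f,r >= 0; bounds chosen so f - r spans exactly [lb, ub]
  lf <- pmax(lp$lb, 0); uf <- pmax(lp$ub, 0)
  lr <- pmax(-lp$ub, 0); ur <- pmax(-lp$lb, 0)
  big <- max(1e6, 10 * sum(abs(lp$ub)) + 10 * sum(abs(lp$lb)))
  A <- rbind(cbind(lp$S, -lp$S, 0),
             c(lp$obj, -lp$obj, -1))
  lbs <- c(lf, lr, thr); ubs <- c(uf, ur, big)
  objmin <- c(rep(1, 2L * n), 0)
  res <- solve_lp(A, rep(0, m + 1L), objmin, lbs, ubs, "min")
  if (res$status != "optimal")
    return(flux_vector(lp, list(status = res$status, x = NULL), "pfba"))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  out <- flux_vector(lp, list(status = "optimal", x = v), "pfba")
  out$total_flux <- sum(abs(v))
  out
}

#' Flux variability analysis
#'
#' Per reaction, the minimum and maximum flux achievable subject to the
#' model constraints plus `c'v >= fraction_of_optimum * optimum`. With
#' `fraction_of_optimum = 0` the objective constraint is omitted entirely
#' and the ranges describe the raw flux polytope.
#'
#' @inheritParams fba
#' @param fraction_of_optimum fraction in `[0, 1]` (default 1).
#' @param reactions reaction ids to analyze (default: all).
#' @return data.frame with columns `reaction_id`, `min`, `max`, `status`
#'   (per-reaction solver status; a failed reaction is flagged, the others
#'   are still returned).
#' @export
fva <- function(model, bounds = NULL, fraction_of_optimum = 1,
                reactions = NULL) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  lp <- build_lp(model, bounds)
  check_finite_bounds(lp)
  if (is.null(reactions)) reactions <- lp$rxn
  idx <- match(reactions, lp$rxn)
  if (anyNA(idx)) stop("unknown reaction id(s): ",
                       paste(reactions[is.na(idx)], collapse = ", "))

  if (fraction_of_optimum > 0) {
    if (all(lp$obj == 0)) stop("model has no objective coefficient set")
    base <- solve_lp(lp$S, rep(0, nrow(lp$S)), lp$obj, lp$lb, lp$ub, "max")
    if (base$status != "optimal")
      stop("base FBA is ", base$status, "; cannot run FVA")
    cl <- with_objective_floor(lp, opt_threshold(base$objective,
                                                 fraction_of_optimum))
    nv <- ncol(cl$S)
  } else {
    cl <- list(S = lp$S, b = rep(0, nrow(lp$S)), lb = lp$lb, ub = lp$ub)
    nv <- ncol(lp$S)
  }

  out <- data.frame(reaction_id = reactions, min = NA_real_, max = NA_real_,
                    status = "optimal", stringsAsFactors = FALSE)
  for (q in seq_along(idx)) {
    ee <- numeric(nv); ee[idx[q]] <- 1
    lo <- solve_lp(cl$S, cl$b, ee, cl$lb, cl$ub, "min")
    hi <- solve_lp(cl$S, cl$b, ee, cl$lb, cl$ub, "max")
    if (lo$status == "optimal" && hi$status == "optimal") {
      out$min[q] <- lo$objective
      out$max[q] <- hi$objective
    } else {
      out$status[q] <- paste(unique(c(lo$status, hi$status))[
        unique(c(lo$status, hi$status)) != "optimal"], collapse = "/")
    }
  }
  out
}

# FVA extreme *solutions* (not just values): one optimal vertex per
# direction per reaction; used as sampler warmup points
fva_warmup_points <- function(lp) {
  n <- length(lp$rxn)
  pts <- matrix(NA_real_, 2L * n, n)
  keep <- logical(2L * n)
  for (j in seq_len(n)) {
    ee <- numeric(n); ee[j] <- 1
    lo <- solve_lp(lp$S, rep(0, nrow(lp$S)), ee, lp$lb, lp$ub, "min")
    hi <- solve_lp(lp$S, rep(0, nrow(lp$S)), ee, lp$lb, lp$ub, "max")
    if (lo$status == "optimal") { pts[2L * j - 1L, ] <- lo$x; keep[2L * j - 1L] <- TRUE }
    if (hi$status == "optimal") { pts[2L * j, ] <- hi$x; keep[2L * j] <- TRUE }
  }
  if (!any(keep)) stop("flux polytope is empty; cannot generate warmup points")
  pts[keep, , drop = FALSE]
}

#' Single-reaction deletion scan
#'
#' Re-solves the FBA problem once per reaction with that reaction's bounds
#' forced to `(0, 0)`. Knockouts that make the problem infeasible are
#' reported with objective 0 and status `"infeasible"`.
#'
#' @inheritParams fba
#' @param reactions reaction ids to knock out (default: all).
#' @return data.frame with columns `reaction_id`, `objective`, `status`.
#' @export
single_reaction_deletion <- function(model, bounds = NULL, reactions = NULL) {
  lp <- build_lp(model, bounds)
  check_finite_bounds(lp)
  if (all(lp$obj == 0)) stop("model has no objective coefficient set")
  if (is.null(reactions)) reactions <- lp$rxn
  idx <- match(reactions, lp$rxn)
  if (anyNA(idx)) stop("unknown reaction id(s): ",
                       paste(reactions[is.na(idx)], collapse = ", "))
  out <- data.frame(reaction_id = reactions, objective = NA_real_,
                    status = "optimal", stringsAsFactors = FALSE)
  for (q in seq_along(idx)) {
    lb2 <- lp$lb; ub2 <- lp$ub
    lb2[idx[q]] <- 0; ub2[idx[q]] <- 0
    res <- solve_lp(lp$S, rep(0, nrow(lp$S)), lp$obj, lb2, ub2, "max")
    if (res$status == "optimal") out$objective[q] <- res$objective
    else { out$objective[q] <- 0; out$status[q] <- res$status }
  }
  out
}

#' Steady-state residual of a flux vector
#' @param model a `metabolic_model`.
#' @param v named flux vector (or `flux_vector` object).
#' @return `max |S v|` over metabolites.
#' @export
steady_state_residual <- function(model, v) {
  if (inherits(v, "flux_vector")) v <- v$fluxes
  S <- as.matrix(model$stoichiometry)
  max(abs(S %*% v[colnames(S)]))
}
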