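#' Solve a bounded-variable linear program
#'
#' Maximizes (or minimizes) `obj %*% x` subject to `A %*% x = b` and
#' `lb <= x <= ub`, with a two-phase primal simplex on bounded variables.
#' Phase 1 drives artificial variables out of an auxiliary basis; phase 2
#' optimizes the requested objective from the feasible basis found.
#' Redundant (rank-deficient) equality rows are tolerated: their artificial
#' variables simply stay basic at zero. Dantzig pricing is used, with a
#' switch to Bland's rule after a streak of degenerate steps so the method
#' cannot cycle. Optimal solutions are basic, i.e. vertices of the feasible
#' polytope: at least `ncol(A) - rank(A)` variables sit exactly on a bound.
#'
#' This solver is the package's optimization backbone (flux balance
#' analysis and everything built on it); tests validate it against an
#' independent vertex-enumeration oracle on small problems.
#'
#' @param A numeric constraint matrix (m x n).
#' @param b numeric right-hand side (length m).
#' @param obj numeric objective coefficients (length n).
#' @param lb,ub finite numeric bounds (length n), `lb <= ub`.
#' @param sense `"max"` or `"min"`.
#' @param tol pivoting / feasibility tolerance.
#' @param max_iter iteration cap (defensive; an error past it).
#' @return list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `x` (length n, `NA` unless optimal) and `objective`.
#' @export
solve_lp <- function(A, b, obj, lb, ub, sense = c("max", "min"),
                     tol = 1e-9, max_iter = 20000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite variable bounds")
  if (any(lb > ub + tol)) return(list(status = "infeasible", x = rep(NA_real_, n),
                                      objective = NA_real_))
  cc <- if (sense == "min") -obj else obj

  # start nonbasic structural variables at the bound nearest zero
  start_upper <- abs(ub) < abs(lb)
  x <- ifelse(start_upper, ub, lb)
  resid <- b - as.vector(A %*% x)
  sgn <- ifelse(resid >= 0, 1, -1)
  big <- max(1, abs(b), abs(lb), abs(ub)) * 1e3 + sum(abs(resid))
  Af <- cbind(A, diag(sgn, m, m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(big, m))
  xf <- c(x, abs(resid))
  basis <- n + seq_len(m)
  at_upper <- c(start_upper, rep(FALSE, m))

  run <- function(cost, xf, basis, at_upper, phase) {
    nfull <- ncol(Af)
    bland <- FALSE
    degen <- 0L
    for (it in seq_len(max_iter)) {
      B <- Af[, basis, drop = FALSE]
      nonbasic <- setdiff(seq_len(nfull), basis)
      xN <- xf[nonbasic]
      xB <- tryCatch(solve(B, b - as.vector(Af[, nonbasic, drop = FALSE] %*% xN)),
                     error = function(e) NULL)
      if (is.null(xB)) stop("simplex basis became singular")
      xf[basis] <- xB
      y <- solve(t(B), cost[basis])
      d <- cost[nonbasic] - as.vector(t(Af[, nonbasic, drop = FALSE]) %*% y)
      up <- at_upper[nonbasic]
      improving <- (!up & d > tol) | (up & d < -tol)
      if (!any(improving))
        return(list(status = "optimal", xf = xf, basis = basis,
                    at_upper = at_upper))
      cand <- which(improving)
      pick <- if (bland) cand[which.min(nonbasic[cand])] else cand[which.max(abs(d[cand]))]
      j <- nonbasic[pick]
      dir <- if (at_upper[j]) -1 else 1
      w <- solve(B, Af[, j])
      delta <- -dir * w
      tmax <- ubf[j] - lbf[j]
      leave <- 0L; leave_to_upper <- FALSE
      for (i in seq_len(m)) {
        if (delta[i] > tol) {
          ti <- (ubf[basis[i]] - xf[basis[i]]) / delta[i]
          if (ti < tmax - tol * max(1, abs(tmax))) { tmax <- ti; leave <- i; leave_to_upper <- TRUE }
          else if (leave == 0L && ti <= tmax + tol) { tmax <- min(tmax, ti); leave <- i; leave_to_upper <- TRUE }
        } else if (delta[i] < -tol) {
          ti <- (lbf[basis[i]] - xf[basis[i]]) / delta[i]
          if (ti < tmax - tol * max(1, abs(tmax))) { tmax <- ti; leave <- i; leave_to_upper <- FALSE }
          else if (leave == 0L && ti <= tmax + tol) { tmax <- min(tmax, ti); leave <- i; leave_to_upper <- FALSE }
        }
      }
      tmax <- max(tmax, 0)
      if (!is.finite(tmax))
        return(list(status = "unbounded", xf = xf, basis = basis,
                    at_upper = at_upper))
      if (tmax <= tol) { degen <- degen + 1L; if (degen > 2L * nfull) bland <- TRUE }
      else { degen <- 0L; bland <- FALSE }
      xf[j] <- xf[j] + dir * tmax
      xf[basis] <- xf[basis] + delta * tmax
      if (leave == 0L) {
        at_upper[j] <- !at_upper[j]     # bound flip, basis unchanged
        xf[j] <- if (at_upper[j]) ubf[j] else lbf[j]
      } else {
        out <- basis[leave]
        xf[out] <- if (leave_to_upper) ubf[out] else lbf[out]
        at_upper[out] <- leave_to_upper
        basis[leave] <- j
      }
    }
    stop("simplex iteration limit reached")
  }

  # phase 1: maximize -(sum of artificials)
  cost1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run(cost1, xf, basis, at_upper, 1L)
  if (ph1$status != "optimal" || sum(ph1$xf[n + seq_len(m)]) > 1e-7 * max(1, max(abs(b))))
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))

  # phase 2: lock artificials at zero and optimize the real objective
  ubf[n + seq_len(m)] <- 0
  lbf[n + seq_len(m)] <- 0
  xf <- ph1$xf
  xf[n + seq_len(m)] <- 0
  environment(run)$ubf <- ubf
  environment(run)$lbf <- lbf
  cost2 <- c(cc, rep(0, m))
  ph2 <- run(cost2, xf, ph1$basis, ph1$at_upper, 2L)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_))
  xs <- ph2$xf[seq_len(n)]
  # snap round-off onto the bounds
  xs <- pmin(pmax(xs, lb), ub)
  list(status = "optimal", x = xs, objective = sum(obj * xs))
}
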