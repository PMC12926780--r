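# Independent oracles used across the suite. These deliberately share no
# code with the package internals: the LP oracle enumerates basic solutions
# by brute force, the GPR oracle evaluates randomly generated rule trees
# recursively on its own representation, and the KS oracle counts lattice
# paths for the exact small-sample null distribution.

# ---- LP oracle: brute-force enumeration of basic solutions -----------------
# optimum of obj'x over {A x = b, lb <= x <= ub} by trying every choice of
# n - rank(A) variables fixed at a bound and solving for the rest
oracle_lp <- function(A, b, obj, lb, ub, sense = "max", tol = 1e-8) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  r <- qr(A)$rank
  free <- n - r
  best <- if (sense == "max") -Inf else Inf
  bestx <- NULL
  consider <- function(x) {
    if (all(x >= lb - tol) && all(x <= ub + tol) &&
        max(abs(A %*% x - b)) < 1e-6) {
      val <- sum(obj * x)
      better <- if (sense == "max") val > best else val < best
      if (better) { best <<- val; bestx <<- x }
    }
  }
  if (free == 0L) {
    x <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (!is.null(x)) consider(x)
  } else {
    combs <- utils::combn(n, free)
    for (j in seq_len(ncol(combs))) {
      nb <- combs[, j]
      bs <- setdiff(seq_len(n), nb)
      Ab <- A[, bs, drop = FALSE]
      if (qr(Ab)$rank < r) next
      for (mask in 0:(2^free - 1)) {
        at_ub <- bitwAnd(mask, 2^(seq_len(free) - 1L)) > 0
        xN <- ifelse(at_ub, ub[nb], lb[nb])
        xB <- tryCatch(qr.solve(Ab, b - A[, nb, drop = FALSE] %*% xN),
                       error = function(e) NULL)
        if (is.null(xB)) next
        x <- numeric(n); x[nb] <- xN; x[bs] <- xB
        consider(x)
      }
    }
  }
  list(value = best, x = bestx)
}

# pFBA oracle: minimum total absolute flux at (near-)optimal objective,
# via enumeration on the forward/reverse-split polytope
oracle_pfba_total <- function(S, obj, lb, ub, opt, fraction = 1) {
  n <- ncol(S); m <- nrow(S)
  thr <- fraction * opt - 1e-6 * max(1, abs(opt))
  lf <- pmax(lb, 0); uf <- pmax(ub, 0)
  lr <- pmax(-ub, 0); ur <- pmax(-lb, 0)
  big <- 10 * sum(abs(ub)) + 10 * sum(abs(lb)) + 1e3
  A <- rbind(cbind(S, -S, 0), c(obj, -obj, -1))
  res <- oracle_lp(A, rep(0, m + 1), c(rep(1, 2 * n), 0),
                   c(lf, lr, thr), c(uf, ur, big), "min")
  res$value
}

# ---- GPR oracle: independent random trees + recursive evaluator ------------
# trees are generated in their own list form (op/args), serialized to rule
# text with full parentheses for the code under test
oracle_random_gpr <- function(depth, genes) {
  if (depth <= 0L || (depth < 3L && stats::runif(1) < 0.35)) {
    return(list(op = "leaf", gene = sample(genes, 1L)))
  }
  op <- sample(c("and", "or"), 1L)
  k <- sample(2:3, 1L)
  list(op = op, args = lapply(seq_len(k), function(i)
    oracle_random_gpr(depth - 1L, genes)))
}

oracle_gpr_text <- function(tr) {
  if (tr$op == "leaf") return(tr$gene)
  # mix the operator keyword case to exercise case-insensitivity
  kw <- sample(c(tr$op, toupper(tr$op)), 1L)
  paste0("(", paste(vapply(tr$args, oracle_gpr_text, ""),
                    collapse = paste0(" ", kw, " ")), ")")
}

oracle_gpr_eval <- function(tr, values) {
  if (tr$op == "leaf") {
    if (tr$gene %in% names(values)) return(unname(values[tr$gene]))
    return(NA_real_)
  }
  vs <- vapply(tr$args, oracle_gpr_eval, numeric(1L), values = values)
  vs <- vs[!is.na(vs)]
  if (!length(vs)) return(NA_real_)
  if (tr$op == "or") sum(vs) else min(vs)
}

# ---- exact two-sample KS oracle (no ties) ----------------------------------
# P(D >= d) under H0 by counting monotone lattice paths from (0,0) to
# (m, n) that stay strictly inside |i/m - j/n| < d, divided by C(m+n, m)
oracle_ks_pvalue <- function(x, y) {
  m <- length(x); n <- length(y)
  stopifnot(!anyDuplicated(c(x, y)))
  cdfx <- stats::ecdf(x); cdfy <- stats::ecdf(y)
  zs <- sort(c(x, y))
  d <- max(abs(cdfx(zs) - cdfy(zs)))
  inside <- function(i, j) abs(i / m - j / n) < d - 1e-12
  cnt <- matrix(0, m + 1L, n + 1L)
  cnt[1L, 1L] <- 1
  for (i in 0:m) for (j in 0:n) {
    if (i == 0L && j == 0L) next
    if (!(i == m && j == n) && !inside(i, j)) { cnt[i + 1L, j + 1L] <- 0; next }
    acc <- 0
    if (i > 0L) acc <- acc + cnt[i, j + 1L]
    if (j > 0L) acc <- acc + cnt[i + 1L, j]
    cnt[i + 1L, j + 1L] <- acc
  }
  1 - cnt[m + 1L, n + 1L] / choose(m + n, m)
}

# ---- shared toy fixtures ---------------------------------------------------
chain_model <- function(uptake = 10) {
  make_toy_model(1L, 1L, uptake)$model
}

parallel_model <- function(uptake = 10, path_ub = 10, gprs = NULL) {
  make_toy_model(2L, c(1L, 1L), uptake, path_ub = path_ub,
                 gpr_assignment = gprs)$model
}

random_network <- function(n_rxn, n_met, seed) {
  withr::with_seed(seed, {
    repeat {
      S <- matrix(sample(-2:2, n_met * n_rxn, TRUE), n_met, n_rxn)
      if (all(colSums(S != 0) > 0)) break
    }
    dimnames(S) <- list(sprintf("m%d", seq_len(n_met)),
                        sprintf("r%d", seq_len(n_rxn)))
    lb <- ifelse(stats::runif(n_rxn) < 0.5, -10, 0)
    ub <- sample(c(5, 10), n_rxn, TRUE)
    obj <- round(stats::runif(n_rxn, -1, 1), 2)
    mets <- data.frame(id = rownames(S), compartment = "c",
                       stringsAsFactors = FALSE)
    rxns <- data.frame(id = colnames(S), lower_bound = lb, upper_bound = ub,
                       objective_coefficient = obj, stringsAsFactors = FALSE)
    metabolic_model(mets, rxns, S)
  })
}
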