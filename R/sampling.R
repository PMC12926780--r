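#' Corner-based flux sampling (CBS)
#'
#' Draws vertices of the flux polytope `{S v = 0, lb <= v <= ub}` by
#' repeatedly maximizing a random linear objective. Each draw's objective
#' coefficients are i.i.d. uniform on `[-1, 1]` (the cost distribution is a
#' package choice; the method only prescribes random objectives), so the
#' sampler lands on corners of the feasible region — the characteristic of
#' corner-based sampling. Identical seeds give identical output.
#'
#' @param model a `metabolic_model`.
#' @param bounds optional per-sample bounds data.frame.
#' @param n_samples number of flux vectors to draw.
#' @param seed integer seed; every random draw derives from it.
#' @return A `flux_frame`: numeric matrix (samples x reactions) with
#'   attributes `provenance = "cbs"` and `seed`.
#' @export
sample_cbs <- function(model, bounds = NULL, n_samples = 100L, seed = 1L) {
  lp <- build_lp(model, bounds)
  check_finite_bounds(lp)
  n <- length(lp$rxn)
  objs <- withr::with_seed(seed, matrix(stats::runif(n_samples * n, -1, 1),
                                        n_samples, n))
  pts <- matrix(NA_real_, n_samples, n,
                dimnames = list(sprintf("cbs_%d", seq_len(n_samples)), lp$rxn))
  for (k in seq_len(n_samples)) {
    res <- solve_lp(lp$S, rep(0, nrow(lp$S)), objs[k, ], lp$lb, lp$ub, "max")
    if (res$status == "unbounded")
      stop(paste0("flux region is unbounded; close open exchange bounds ",
                  "before sampling"))
    if (res$status != "optimal")
      stop("flux region is empty (infeasible); cannot sample")
    pts[k, ] <- res$x
  }
  flux_frame(pts, "cbs", seed)
}

#' Artificial-centering hit-and-run flux sampling
#'
#' A single-chain artificial-centering hit-and-run walk over the flux
#' polytope. Warmup points are the flux-variability extreme solutions
#' (one optimal vertex per reaction per direction, no objective
#' constraint); chord directions are drawn from a stored point minus the
#' running center, so the walk self-tunes to the polytope's shape; the
#' step along each chord is uniform on the feasible segment. Every
#' `thinning`-th iterate is kept until `n_samples` points are collected.
#' Identical seeds give identical output.
#'
#' @inheritParams sample_cbs
#' @param thinning keep every `thinning`-th point (default 100).
#' @return A `flux_frame` with `provenance = "hit_and_run"`.
#' @export
sample_hit_and_run <- function(model, bounds = NULL, n_samples = 100L,
                               thinning = 100L, seed = 1L) {
  stopifnot(thinning >= 1L)
  lp <- build_lp(model, bounds)
  check_finite_bounds(lp)
  n <- length(lp$rxn)
  warm <- fva_warmup_points(lp)
  # orthonormal basis of the null space of S: directions are projected onto
  # it every step so rounding noise cannot push the walk off S v = 0
  qrS <- qr(t(lp$S))
  rk <- qrS$rank
  NS <- if (rk < n) qr.Q(qrS, complete = TRUE)[, (rk + 1L):n, drop = FALSE]
        else matrix(0, n, 0)
  if (ncol(NS) == 0L)
    stop("the steady-state constraint leaves no degree of freedom to sample")
  pts <- matrix(NA_real_, n_samples, n,
                dimnames = list(sprintf("hr_%d", seq_len(n_samples)), lp$rxn))
  withr::with_seed(seed, {
    pool <- warm
    center <- colMeans(pool)
    x <- center
    n_seen <- nrow(pool)
    kept <- 0L
    iter <- 0L
    max_iter <- n_samples * thinning * 50L
    while (kept < n_samples && iter < max_iter) {
      iter <- iter + 1L
      src <- pool[sample.int(nrow(pool), 1L), ]
      d <- src - center
      d <- as.vector(NS %*% crossprod(NS, d))
      nd <- sqrt(sum(d * d))
      if (nd < 1e-8) next
      d <- d / nd
      # feasible segment along the chord (S d = 0 by construction, so only
      # the box bounds cut it)
      tmin <- -Inf; tmax <- Inf
      for (i in seq_len(n)) {
        if (abs(d[i]) < 1e-12) next
        a <- (lp$lb[i] - x[i]) / d[i]
        b <- (lp$ub[i] - x[i]) / d[i]
        if (d[i] > 0) { tmin <- max(tmin, a); tmax <- min(tmax, b) }
        else { tmin <- max(tmin, b); tmax <- min(tmax, a) }
      }
      if (!is.finite(tmin) || !is.finite(tmax) || tmax < tmin) next
      tt <- stats::runif(1L, tmin, tmax)
      x <- x + tt * d
      x <- pmin(pmax(x, lp$lb), lp$ub)
      n_seen <- n_seen + 1L
      center <- center + (x - center) / n_seen
      if (iter %% thinning == 0L) {
        kept <- kept + 1L
        pts[kept, ] <- x
        pool <- rbind(pool, x)
      }
    }
    if (kept < n_samples)
      stop("hit-and-run failed to collect the requested samples ",
           "(degenerate polytope?)")
  })
  flux_frame(pts, "hit_and_run", seed)
}

flux_frame <- function(values, provenance, seed) {
  structure(values, provenance = provenance, seed = seed,
            class = c("flux_frame", class(values)))
}

#' @export
print.flux_frame <- function(x, ...) {
  cat(sprintf("flux_frame: %d samples x %d reactions (%s, seed %s)\n",
              nrow(x), ncol(x), attr(x, "provenance"),
              format(attr(x, "seed"))))
  invisible(x)
}

#' Summary statistics of sampled fluxes
#'
#' @param frame a `flux_frame` (or any samples-by-reactions matrix).
#' @param quantiles quantile levels to report besides mean and median.
#' @return data.frame with one row per reaction: `reaction_id`, `mean`,
#'   `median` and one `q<level>` column per requested quantile.
#' @export
summarize_fluxes <- function(frame, quantiles = c(0.25, 0.75)) {
  stopifnot(nrow(frame) >= 1L)
  out <- data.frame(reaction_id = colnames(frame),
                    mean = colMeans(frame),
                    median = apply(frame, 2L, stats::median),
                    stringsAsFactors = FALSE)
  for (q in quantiles)
    out[[sprintf("q%g", 100 * q)]] <- apply(frame, 2L, stats::quantile, probs = q)
  rownames(out) <- NULL
  out
}

#' Draw flux samples in reproducible batches
#'
#' Splits `n_samples` over `n_batches` (sizes differing by at most one,
#' larger batches first); batch `i` (0-based) is drawn with seed
#' `seed + i`, so batches are independent streams and a single batch
#' reproduces the direct call.
#'
#' @inheritParams sample_cbs
#' @param n_batches number of batches (>= 1).
#' @param method `"cbs"` or `"hit_and_run"`.
#' @param thinning for `method = "hit_and_run"`.
#' @return list of `flux_frame`s, one per batch.
#' @export
batch_samples <- function(model, bounds = NULL, n_samples = 100L,
                          n_batches = 1L, seed = 1L,
                          method = c("cbs", "hit_and_run"), thinning = 100L) {
  method <- match.arg(method)
  stopifnot(n_batches >= 1L, n_samples >= n_batches)
  base <- n_samples %/% n_batches
  sizes <- rep(base, n_batches) + as.integer(seq_len(n_batches) <= n_samples %% n_batches)
  lapply(seq_len(n_batches), function(i) {
    s <- seed + i - 1L
    if (method == "cbs") sample_cbs(model, bounds, sizes[i], s)
    else sample_hit_and_run(model, bounds, sizes[i], thinning, s)
  })
}

#' Write / read a flux table (samples x reactions, tab-separated)
#' @param frame matrix to write (sample labels in the first column).
#' @param path file path.
#' @export
write_fluxes <- function(frame, path) {
  df <- data.frame(sample = rownames(frame), as.data.frame(unclass(frame)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fluxes
#' @export
read_fluxes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}
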