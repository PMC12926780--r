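#' Signed, bounded flux fold change
#'
#' `(avg1 - avg2) / (|avg1| + |avg2|)`: a symmetric effect size in
#' `[-1, 1]`. It is 0 when the group means are equal, +/-1 when they have
#' equal magnitude and opposite signs (a reversed reversible reaction), and
#' 0 by convention when both means are exactly 0. Antisymmetric in its
#' arguments.
#'
#' @param avg1,avg2 group mean fluxes (vectorized).
#' @return Numeric in `[-1, 1]`.
#' @examples
#' fold_change(3, 1)   # 0.5
#' fold_change(1, -1)  # 1: opposite direction of use
#' @export
fold_change <- function(avg1, avg2) {
  den <- abs(avg1) + abs(avg2)
  ifelse(den == 0, 0, (avg1 - avg2) / den)
}

#' Two-sample test of a reaction's flux distributions
#'
#' Two-sided p-value of the chosen test between the two groups' flux
#' values. The default is the Kolmogorov-Smirnov test (exact small-sample
#' distribution when sizes permit and there are no ties, as in
#' [stats::ks.test()]). Two identical constant samples give p = 1 by
#' convention.
#'
#' @param values1,values2 numeric flux vectors, each of length >= 2.
#' @param test `"ks"`, `"mannwhitney"` or `"ttest"`.
#' @return p-value in `[0, 1]`.
#' @export
test_reaction <- function(values1, values2, test = c("ks", "mannwhitney", "ttest")) {
  test <- match.arg(test)
  stopifnot(length(values1) >= 2L, length(values2) >= 2L)
  v1c <- stats::var(values1) == 0
  v2c <- stats::var(values2) == 0
  if (v1c && v2c) {
    if (values1[1L] == values2[1L]) return(1)
    if (test == "ttest") return(0)  # disjoint constants: t-test degenerates
  }
  p <- switch(test,
              ks = suppressWarnings(stats::ks.test(values1, values2))$p.value,
              mannwhitney = suppressWarnings(
                stats::wilcox.test(values1, values2))$p.value,
              ttest = stats::t.test(values1, values2)$p.value)
  min(max(p, 0), 1)
}

#' Welch two-sample z-score of a flux difference
#'
#' `(mean1 - mean2) / sqrt(var1/n1 + var2/n2)` with n-1 sample variances:
#' the standardized group-mean difference reported alongside the fold
#' change. When both variances are zero the score is undefined and `NA` is
#' returned.
#'
#' @param values1,values2 numeric flux vectors, each of length >= 2.
#' @return A single numeric, or `NA` when undefined.
#' @export
z_score <- function(values1, values2) {
  stopifnot(length(values1) >= 2L, length(values2) >= 2L)
  se2 <- stats::var(values1) / length(values1) +
         stats::var(values2) / length(values2)
  if (se2 == 0) return(NA_real_)
  (mean(values1) - mean(values2)) / sqrt(se2)
}

style_classes <- c("up", "down", "sign_flip_up", "sign_flip_down",
                   "not_significant")

# significance gate and style class for one reaction.
# The user-facing fold-change threshold t (default 1.2, "at least 20%
# difference") is a ratio criterion: |avg1 - avg2| >= (t-1) * min(|avg1|,
# |avg2|) (equivalently max/min ratio >= t for same-sign means). The
# Eq.-style bounded fold change is what gets *reported*; with
# fc_on_eq1 = TRUE the threshold is applied to it directly as
# |fc| >= (t-1)/(t+1). Sign-discordant mean pairs that pass the p-value
# gate are always classified as a sign flip: a direction reversal is
# qualitatively significant whatever the ratio.
classify_reaction <- function(p, avg1, avg2, p_threshold, fc_threshold,
                              fc_on_eq1 = FALSE) {
  if (is.na(p) || p > p_threshold) return("not_significant")
  fc <- fold_change(avg1, avg2)
  if (avg1 * avg2 < 0)
    return(if (fc > 0) "sign_flip_up" else "sign_flip_down")
  pass <- if (fc_on_eq1) {
    abs(fc) >= (fc_threshold - 1) / (fc_threshold + 1) && avg1 != avg2
  } else {
    abs(avg1 - avg2) >= (fc_threshold - 1) * min(abs(avg1), abs(avg2)) &&
      avg1 != avg2
  }
  if (!pass) return("not_significant")
  if (fc > 0) "up" else "down"
}

#' Compare flux distributions between sample groups
#'
#' Per-reaction two-sample test, fold change, z-score and style class for
#' each requested pair of groups. A reaction is significant iff its
#' p-value passes `p_threshold` *and* the fold-change criterion holds
#' (both gates, as in the defaults p <= 0.05 and ratio >= 1.2); only those
#' reactions get an `up`/`down`/`sign_flip_*` class for map highlighting.
#'
#' @param fluxes either a named list of samples-by-reactions flux matrices
#'   (one per group, identical reaction columns), or a single matrix
#'   together with `groups`.
#' @param groups when `fluxes` is a single matrix: named character vector
#'   or data.frame (`sample`, `group`) assigning each row to a group.
#' @param mode `"one_vs_one"` (all pairs), `"one_vs_all"` (each group
#'   against all other samples pooled) or `"one_vs_control"`.
#' @param control control group name (required for `"one_vs_control"`).
#' @param test passed to [test_reaction()].
#' @param p_threshold p-value gate (default 0.05).
#' @param fc_threshold fold-change ratio gate (default 1.2 = at least 20%
#'   difference between the group means).
#' @param fc_on_eq1 apply the threshold to the bounded fold-change
#'   statistic instead of the ratio (see [fold_change()]).
#' @param correction `"none"` (default, raw thresholding) or `"bh"` for
#'   Benjamini-Hochberg adjustment of each comparison's p-values before
#'   gating.
#' @return Named list of comparison data.frames (`"A_vs_B"`, ...), each
#'   with columns `reaction_id`, `p_value`, `fold_change`, `z_score`,
#'   `avg1`, `avg2`, `style_class`.
#' @export
compare_groups <- function(fluxes, groups = NULL,
                           mode = c("one_vs_one", "one_vs_all", "one_vs_control"),
                           control = NULL, test = "ks",
                           p_threshold = 0.05, fc_threshold = 1.2,
                           fc_on_eq1 = FALSE, correction = c("none", "bh")) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  gf <- as_grouped_fluxes(fluxes, groups)
  gnames <- names(gf)
  if (length(gnames) < 2L) stop("need at least two groups to compare")
  if (mode == "one_vs_control") {
    if (is.null(control)) stop("mode 'one_vs_control' requires a control group")
    if (!control %in% gnames)
      stop("unknown control group '", control, "'; available: ",
           paste(gnames, collapse = ", "))
  }

  pairs <- switch(mode,
    one_vs_one = {
      cb <- utils::combn(gnames, 2L)
      lapply(seq_len(ncol(cb)), function(i)
        list(label = paste0(cb[1L, i], "_vs_", cb[2L, i]),
             m1 = gf[[cb[1L, i]]], m2 = gf[[cb[2L, i]]]))
    },
    one_vs_all = lapply(gnames, function(g)
      list(label = paste0(g, "_vs_all"),
           m1 = gf[[g]],
           m2 = do.call(rbind, unname(gf[setdiff(gnames, g)])))),
    one_vs_control = lapply(setdiff(gnames, control), function(g)
      list(label = paste0(g, "_vs_", control),
           m1 = gf[[g]], m2 = gf[[control]])))

  out <- lapply(pairs, function(pr) {
    rxns <- colnames(pr$m1)
    p <- vapply(rxns, function(r)
      test_reaction(pr$m1[, r], pr$m2[, r], test), 0)
    if (correction == "bh") p <- stats::p.adjust(p, "BH")
    a1 <- colMeans(pr$m1); a2 <- colMeans(pr$m2)
    zero_var <- apply(pr$m1, 2L, stats::var) == 0 &
                apply(pr$m2, 2L, stats::var) == 0
    cls <- vapply(seq_along(rxns), function(i) {
      if (zero_var[i]) "not_significant"
      else classify_reaction(p[i], a1[i], a2[i], p_threshold, fc_threshold,
                             fc_on_eq1)
    }, "")
    data.frame(reaction_id = rxns,
               p_value = unname(p),
               fold_change = unname(fold_change(a1, a2)),
               z_score = vapply(rxns, function(r)
                 z_score(pr$m1[, r], pr$m2[, r]), 0, USE.NAMES = FALSE),
               avg1 = unname(a1), avg2 = unname(a2),
               style_class = factor(cls, levels = style_classes),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(out) <- vapply(pairs, `[[`, "", "label")
  out
}

as_grouped_fluxes <- function(fluxes, groups) {
  if (is.list(fluxes) && !is.data.frame(fluxes)) {
    gf <- lapply(fluxes, function(m) {
      m <- as.matrix(m)
      storage.mode(m) <- "double"
      m
    })
    rx <- colnames(gf[[1L]])
    for (m in gf) if (!identical(colnames(m), rx))
      stop("all groups must share the same reaction columns")
  } else {
    m <- as.matrix(fluxes)
    storage.mode(m) <- "double"
    if (is.null(groups))
      stop("a single flux matrix needs a 'groups' sample-to-group assignment")
    if (is.data.frame(groups)) {
      stopifnot(all(c("sample", "group") %in% names(groups)))
      groups <- stats::setNames(as.character(groups$group),
                                as.character(groups$sample))
    }
    miss <- setdiff(rownames(m), names(groups))
    if (length(miss)) stop("sample(s) with no group assignment: ",
                           paste(miss, collapse = ", "))
    gl <- groups[rownames(m)]
    gf <- lapply(split(seq_len(nrow(m)), factor(gl, levels = unique(gl))),
                 function(ix) m[ix, , drop = FALSE])
  }
  if (any(vapply(gf, nrow, 0L) < 2L))
    stop("every group needs at least two samples")
  gf
}

#' Read / write group assignments (tab-separated: sample, group)
#' @param path file path.
#' @param groups named character vector (names = samples) or data.frame.
#' @export
read_groups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group") %in% names(df)))
  stats::setNames(as.character(df$group), as.character(df$sample))
}

#' @rdname read_groups
#' @export
write_groups <- function(groups, path) {
  if (!is.data.frame(groups))
    groups <- data.frame(sample = names(groups), group = unname(groups),
                         stringsAsFactors = FALSE)
  utils::write.table(groups, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write one comparison table (tab-separated)
#' @param record a comparison data.frame from [compare_groups()].
#' @param path file path.
#' @export
write_comparison <- function(record, path) {
  utils::write.table(record, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
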