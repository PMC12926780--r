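#' Normalize Reaction Activity Scores across samples
#'
#' Each reaction's scores are divided by that reaction's maximum across all
#' samples, so every non-missing normalized score lies in `[0, 1]` and the
#' most active sample scores 1. Missing scores (`NA`) propagate. A reaction
#' whose maximum is 0 carries no usable signal: by default its whole row
#' becomes `NA` (downstream, bounds stay unchanged) rather than 0, which
#' would close the reaction in every sample and often make models
#' infeasible; set `zero_ras_closes = TRUE` for the harsher reading where
#' the row normalizes to 0.
#'
#' @param ras reactions-by-samples numeric matrix (see
#'   [expression_to_ras()]).
#' @param zero_ras_closes how to treat all-zero rows (see above).
#' @return Matrix of the same shape with values in `[0, 1]` or `NA`.
#' @examples
#' normalize_ras(matrix(c(2, 4, 8), 1, 3,
#'                      dimnames = list("R1", c("s1", "s2", "s3"))))
#' @export
normalize_ras <- function(ras, zero_ras_closes = FALSE) {
  stopifnot(is.matrix(ras), ncol(ras) >= 1L)
  out <- ras
  for (i in seq_len(nrow(ras))) {
    row <- ras[i, ]
    if (all(is.na(row))) next
    mx <- max(row, na.rm = TRUE)
    if (mx == 0) {
      out[i, ] <- if (zero_ras_closes) ifelse(is.na(row), NA_real_, 0) else NA_real_
    } else {
      out[i, ] <- row / mx
    }
  }
  out
}

#' Scale reaction bounds by normalized activity scores
#'
#' For each reaction with a (non-missing) normalized score `r` in `[0, 1]`,
#' both bounds are multiplied by `r`, shrinking the allowed flux range while
#' preserving the reversibility direction; reactions with a missing score or
#' no GPR keep their original bounds. Exchange reactions are exempt by
#' default (the growth medium, not enzyme expression, governs uptake);
#' `scale_exchanges = TRUE` overrides.
#'
#' @param model a `metabolic_model`.
#' @param norm_ras named numeric vector (one sample's column of a
#'   normalized RAS matrix): reaction id -> score in `[0, 1]` or `NA`.
#' @param scale_exchanges also scale exchange reactions carrying a score.
#' @param bounds optional starting bounds (a data.frame as returned by this
#'   function or [apply_medium()]); defaults to the model's own bounds.
#' @return data.frame with columns `reaction_id`, `lower_bound`,
#'   `upper_bound` covering every model reaction.
#' @export
apply_ras_to_bounds <- function(model, norm_ras, scale_exchanges = FALSE,
                                bounds = NULL) {
  bs <- as_bounds(model, bounds)
  r <- norm_ras[bs$reaction_id]
  ok <- !is.na(r)
  if (any(r[ok] < -1e-12 | r[ok] > 1 + 1e-12))
    stop("normalized RAS values must lie in [0, 1]")
  if (!scale_exchanges) ok <- ok & !is_exchange(model)
  bs$lower_bound[ok] <- bs$lower_bound[ok] * r[ok]
  bs$upper_bound[ok] <- bs$upper_bound[ok] * r[ok]
  bs
}

as_bounds <- function(model, bounds = NULL) {
  if (is.null(bounds))
    return(data.frame(reaction_id = model$reactions$id,
                      lower_bound = model$reactions$lower_bound,
                      upper_bound = model$reactions$upper_bound,
                      stringsAsFactors = FALSE))
  stopifnot(all(c("reaction_id", "lower_bound", "upper_bound") %in% names(bounds)))
  if (!setequal(bounds$reaction_id, model$reactions$id))
    stop("bounds must cover exactly the model's reactions")
  bounds[match(model$reactions$id, bounds$reaction_id), , drop = FALSE]
}

#' Constrain exchange reactions to a growth medium
#'
#' Exchange reactions transporting a metabolite listed in the medium get
#' their lower bound set to minus the metabolite's maximal uptake rate
#' (negative flux is uptake); exchange reactions for metabolites absent
#' from the medium get lower bound 0 (no uptake). Upper bounds (secretion)
#' and non-exchange reactions are untouched. Medium metabolites with no
#' matching exchange reaction trigger a warning listing the ids.
#'
#' @param model a `metabolic_model`.
#' @param medium data.frame with columns `metabolite_id` and `uptake_rate`
#'   (both rates >= 0), or a named non-negative numeric vector.
#' @param bounds optional starting bounds (default: the model's).
#' @return data.frame of per-reaction bounds (see [apply_ras_to_bounds()]).
#' @export
apply_medium <- function(model, medium, bounds = NULL) {
  med <- as_medium(medium)
  bs <- as_bounds(model, bounds)
  ex <- is_exchange(model)
  exmet <- exchange_metabolites(model)
  missing_ex <- setdiff(names(med), exmet)
  if (length(missing_ex))
    warning("medium metabolite(s) with no exchange reaction in the model: ",
            paste(missing_ex, collapse = ", "))
  for (i in which(ex)) {
    met <- exmet[[bs$reaction_id[i]]]
    new_lb <- if (met %in% names(med)) -med[[met]] else 0
    bs$lower_bound[i] <- min(new_lb, bs$upper_bound[i])
  }
  bs
}

as_medium <- function(medium) {
  if (is.data.frame(medium)) {
    stopifnot(all(c("metabolite_id", "uptake_rate") %in% names(medium)))
    med <- stats::setNames(as.numeric(medium$uptake_rate),
                           as.character(medium$metabolite_id))
  } else {
    med <- medium
    stopifnot(is.numeric(med), !is.null(names(med)) || length(med) == 0L)
  }
  if (any(med < 0)) stop("medium uptake rates must be >= 0")
  med
}

#' Read a medium table (tab-separated: metabolite_id, uptake_rate)
#' @param path file path.
#' @return data.frame with columns `metabolite_id`, `uptake_rate`.
#' @export
read_medium <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite_id", "uptake_rate") %in% names(df)))
  df
}

#' Build per-sample transcriptionally constrained bounds
#'
#' The full RAS-to-bounds pipeline for a cohort: the medium (if any) is
#' applied first to the exchange reactions, then each sample's normalized
#' RAS column scales the GPR-bearing reactions, yielding one bounds table
#' per sample. Optionally each constrained model is exported via
#' [export_model()].
#'
#' @param model a `metabolic_model`.
#' @param norm_ras normalized RAS matrix (reactions x samples), e.g. from
#'   [normalize_ras()].
#' @param medium optional medium (see [apply_medium()]).
#' @param scale_exchanges passed to [apply_ras_to_bounds()].
#' @param export_dir,export_format when `export_dir` is given, each
#'   per-sample model is written there as `<sample>.<ext>` in
#'   `export_format` (`"sbml"` or `"json"`).
#' @return Named list (one entry per sample) of bounds data.frames.
#' @export
build_sample_models <- function(model, norm_ras, medium = NULL,
                                scale_exchanges = FALSE,
                                export_dir = NULL, export_format = c("sbml", "json")) {
  export_format <- match.arg(export_format)
  stopifnot(is.matrix(norm_ras))
  base <- if (is.null(medium)) as_bounds(model) else apply_medium(model, medium)
  out <- lapply(colnames(norm_ras), function(s) {
    apply_ras_to_bounds(model, norm_ras[, s], scale_exchanges = scale_exchanges,
                        bounds = base)
  })
  names(out) <- colnames(norm_ras)
  if (!is.null(export_dir)) {
    if (!dir.exists(export_dir)) dir.create(export_dir, recursive = TRUE)
    ext <- if (export_format == "sbml") "xml" else "json"
    for (s in names(out)) {
      m2 <- model
      m2$reactions$lower_bound <- out[[s]]$lower_bound
      m2$reactions$upper_bound <- out[[s]]$upper_bound
      export_model(m2, export_format, file.path(export_dir, paste0(s, ".", ext)))
    }
  }
  out
}

#' Write / read a bounds table (tab-separated)
#' @param bounds data.frame with `reaction_id`, `lower_bound`, `upper_bound`.
#' @param path file path.
#' @export
write_bounds <- function(bounds, path) {
  utils::write.table(bounds, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bounds
#' @export
read_bounds <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
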