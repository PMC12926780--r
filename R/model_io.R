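#' Import a metabolic model from a standard file format
#'
#' Reads SBML (Level 3 + fbc, `.xml`), COBRA-style JSON (`.json`), YAML
#' mirroring the JSON schema (`.yml`/`.yaml`) or the package's flat tabular
#' schema (`.tsv`/`.tab`/`.txt`), optionally compressed as `.gz`, `.bz2` or
#' `.zip` (a zip must contain exactly one model file). The format is chosen
#' from the (inner) file extension unless `format` overrides it.
#'
#' MATLAB `.mat` models are a binary format with no reader in this package's
#' dependency set and are rejected with an explanatory error; convert them
#' to SBML or JSON first.
#'
#' @param path path to the model file.
#' @param format one of `"auto"`, `"sbml"`, `"json"`, `"yaml"`, `"tabular"`,
#'   `"mat"`.
#' @return A [metabolic_model()].
#' @export
import_model <- function(path,
                         format = c("auto", "sbml", "json", "mat", "yaml", "tabular")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  got <- read_model_text(path)
  if (format == "auto") {
    format <- format_from_extension(got$ext)
    if (is.na(format))
      stop(sprintf("cannot determine model format from extension '.%s'; pass format=",
                   got$ext))
  }
  switch(format,
         sbml = sbml_to_model(got$text),
         json = json_to_model(got$text),
         yaml = yaml_to_model(got$text),
         tabular = table_to_model(read_model_table(textConnection(got$text))),
         mat = stop(paste0("MATLAB .mat models are not supported ",
                           "(binary format); export the model to SBML or ",
                           "JSON and re-import")))
}

format_from_extension <- function(ext) {
  switch(tolower(ext),
         xml = "sbml", sbml = "sbml",
         json = "json",
         yml = "yaml", yaml = "yaml",
         tsv = "tabular", tab = "tabular", txt = "tabular", csv = "tabular",
         mat = "mat",
         NA_character_)
}

# decompress if needed and return list(text, ext) where ext is the inner
# (uncompressed) file extension
read_model_text <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gz", "bz2")) {
    inner <- tolower(tools::file_ext(sub("\\.(gz|bz2)$", "", path, ignore.case = TRUE)))
    con <- if (ext == "gz") gzfile(path, "rb") else bzfile(path, "rb")
    on.exit(close(con))
    list(text = paste(readLines(con, warn = FALSE), collapse = "\n"), ext = inner)
  } else if (ext == "zip") {
    entries <- utils::unzip(path, list = TRUE)$Name
    entries <- entries[!grepl("/$", entries)]
    if (length(entries) != 1L)
      stop("zip archive must contain exactly one model file, found ",
           length(entries))
    con <- unz(path, entries[1L])
    on.exit(close(con))
    list(text = paste(readLines(con, warn = FALSE), collapse = "\n"),
         ext = tolower(tools::file_ext(entries[1L])))
  } else {
    list(text = paste(readLines(path, warn = FALSE), collapse = "\n"), ext = ext)
  }
}

#' Flatten a model to the tabular schema
#'
#' One row per reaction with a human-readable equation string, the bounds,
#' the GPR text, the objective coefficient, a medium flag and the pathway.
#' `in_medium` is `TRUE` for an exchange reaction whose transported
#' metabolite appears in `medium`; when no medium is given, for an exchange
#' reaction whose lower bound is negative (i.e. uptake is open). The column
#' set of this schema is this package's own reconstruction of a flat
#' model-exchange table and is documented as such.
#'
#' @param model a `metabolic_model`.
#' @param medium optional medium (see [read_medium()]): data.frame with
#'   `metabolite_id`/`uptake_rate` columns or a named numeric vector.
#' @return data.frame with columns `reaction_id`, `equation_string`,
#'   `lower_bound`, `upper_bound`, `gpr_text`, `objective_coefficient`,
#'   `in_medium`, `pathway`.
#' @export
model_to_table <- function(model, medium = NULL) {
  rx <- model$reactions
  ex <- is_exchange(model)
  exmet <- exchange_metabolites(model)
  in_medium <- rep(FALSE, nrow(rx))
  if (is.null(medium)) {
    in_medium[ex] <- rx$lower_bound[ex] < 0
  } else {
    med <- as_medium(medium)
    in_medium[ex] <- exmet[rx$id[ex]] %in% names(med)
  }
  data.frame(reaction_id = rx$id,
             equation_string = vapply(seq_len(nrow(rx)), function(i)
               equation_string(model, i), ""),
             lower_bound = rx$lower_bound,
             upper_bound = rx$upper_bound,
             gpr_text = rx$gpr,
             objective_coefficient = rx$objective_coefficient,
             in_medium = in_medium,
             pathway = rx$pathway,
             stringsAsFactors = FALSE)
}

equation_string <- function(model, i) {
  S <- model$stoichiometry
  co <- as.numeric(S[, i])
  ids <- rownames(S)
  term <- function(idx) {
    vapply(idx, function(k) {
      a <- abs(co[k])
      if (a == 1) ids[k] else paste(format(a, digits = 10), ids[k])
    }, "")
  }
  lhs <- paste(term(which(co < 0)), collapse = " + ")
  rhs <- paste(term(which(co > 0)), collapse = " + ")
  arrow <- if (model$reactions$lower_bound[i] < 0) "<=>" else "-->"
  trimws(paste(lhs, arrow, rhs))
}

parse_equation <- function(eq, row_label = "") {
  m <- regexpr("-->|<=>", eq)
  if (m < 0)
    stop("unparsable equation string", row_label, ": no '-->' or '<=>' arrow")
  arrow <- regmatches(eq, m)
  sides <- strsplit(eq, "-->|<=>")[[1L]]
  lhs <- if (length(sides) >= 1L) trimws(sides[1L]) else ""
  rhs <- if (length(sides) >= 2L) trimws(sides[2L]) else ""
  parse_side <- function(side, sign) {
    if (!nzchar(side)) return(NULL)
    terms <- trimws(strsplit(side, "\\s\\+\\s|^\\+\\s|\\s\\+$")[[1L]])
    terms <- terms[nzchar(terms)]
    out <- lapply(terms, function(tm) {
      parts <- strsplit(tm, "\\s+")[[1L]]
      if (length(parts) == 1L) c(coef = sign, met = parts)
      else {
        co <- suppressWarnings(as.numeric(parts[1L]))
        if (is.na(co))
          stop("unparsable equation term '", tm, "'", row_label)
        c(coef = sign * co, met = paste(parts[-1L], collapse = " "))
      }
    })
    do.call(rbind, out)
  }
  tab <- rbind(parse_side(lhs, -1), parse_side(rhs, +1))
  if (is.null(tab))
    stop("equation string has no metabolites", row_label)
  data.frame(metabolite = tab[, "met"],
             coef = as.numeric(tab[, "coef"]),
             stringsAsFactors = FALSE)
}

#' Rebuild a model from the tabular schema
#'
#' Inverse of [model_to_table()]: parses the equation strings back into a
#' stoichiometric matrix and re-assembles a [metabolic_model()].
#' Compartments are taken from a trailing `[x]` suffix on metabolite ids
#' when present, else `"c"`.
#'
#' @param table data.frame in the [model_to_table()] schema.
#' @return A `metabolic_model`.
#' @export
table_to_model <- function(table) {
  need <- c("reaction_id", "equation_string", "lower_bound", "upper_bound")
  if (!all(need %in% names(table)))
    stop("model table must have columns: ", paste(need, collapse = ", "))
  bad <- which(table$lower_bound > table$upper_bound)
  if (length(bad))
    stop("lower_bound > upper_bound in row(s) for reaction(s): ",
         paste(table$reaction_id[bad], collapse = ", "))
  stoich <- list()
  for (i in seq_len(nrow(table))) {
    eqd <- parse_equation(table$equation_string[i],
                          paste0(" in row for reaction '", table$reaction_id[i], "'"))
    eqd$reaction <- table$reaction_id[i]
    stoich[[i]] <- eqd
  }
  stoich <- do.call(rbind, stoich)
  mets <- unique(stoich$metabolite)
  comp <- sub("^.*\\[([^]]+)\\]$", "\\1", mets)
  comp[comp == mets] <- "c"
  S <- Matrix::sparseMatrix(i = match(stoich$metabolite, mets),
                            j = match(stoich$reaction, table$reaction_id),
                            x = stoich$coef,
                            dims = c(length(mets), nrow(table)),
                            dimnames = list(mets, table$reaction_id))
  metabolic_model(
    metabolites = data.frame(id = mets, compartment = comp,
                             stringsAsFactors = FALSE),
    reactions = data.frame(
      id = table$reaction_id,
      lower_bound = table$lower_bound,
      upper_bound = table$upper_bound,
      gpr = if (is.null(table$gpr_text)) "" else ifelse(is.na(table$gpr_text), "", table$gpr_text),
      objective_coefficient = if (is.null(table$objective_coefficient)) 0
                              else table$objective_coefficient,
      pathway = if (is.null(table$pathway)) NA_character_ else table$pathway,
      stringsAsFactors = FALSE),
    stoichiometry = S)
}

#' Read / write the tabular model schema as a tab-separated file
#' @param path file path (or connection for `read_model_table`).
#' @param table data.frame in the [model_to_table()] schema.
#' @return `read_model_table`: the data.frame.
#' @export
read_model_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA"))
}

#' @rdname read_model_table
#' @export
write_model_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a model (or model table) to a standard format
#'
#' @param x a `metabolic_model` or a data.frame in the tabular schema.
#' @param format `"sbml"`, `"json"`, `"yaml"` or `"tabular"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_model <- function(x, format = c("sbml", "json", "yaml", "tabular"), path) {
  format <- match.arg(format)
  if (is.data.frame(x)) {
    if (format == "tabular") return(write_model_table(x, path))
    x <- table_to_model(x)
  }
  stopifnot(inherits(x, "metabolic_model"))
  switch(format,
         sbml = writeLines(model_to_sbml(x), path),
         json = writeLines(model_to_json(x), path),
         yaml = yaml::write_yaml(model_to_cobra_list(x), path),
         tabular = write_model_table(model_to_table(x), path))
  invisible(path)
}

# ---- COBRA-style JSON / YAML ------------------------------------------------

model_to_cobra_list <- function(model) {
  S <- model$stoichiometry
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    co <- as.numeric(S[, i])
    nz <- which(co != 0)
    mets <- as.list(co[nz])
    names(mets) <- rownames(S)[nz]
    out <- list(id = r$id, metabolites = mets,
                lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                gene_reaction_rule = r$gpr,
                objective_coefficient = r$objective_coefficient)
    if (!is.na(r$pathway)) out$subsystem <- r$pathway
    out
  })
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i)
    list(id = model$metabolites$id[i],
         compartment = model$metabolites$compartment[i]))
  genes <- lapply(model_genes(model), function(g) list(id = g))
  list(id = "model", metabolites = mets, reactions = rxns, genes = genes,
       compartments = as.list(stats::setNames(
         unique(model$metabolites$compartment),
         unique(model$metabolites$compartment))))
}

model_to_json <- function(model) {
  jsonlite::toJSON(model_to_cobra_list(model), auto_unbox = TRUE, digits = NA,
                   pretty = TRUE)
}

cobra_list_to_model <- function(lst) {
  if (is.null(lst$reactions) || is.null(lst$metabolites))
    stop("model document lacks 'reactions'/'metabolites' sections")
  mets <- data.frame(
    id = vapply(lst$metabolites, function(m) as.character(m$id), ""),
    compartment = vapply(lst$metabolites, function(m)
      if (is.null(m$compartment)) "c" else as.character(m$compartment), ""),
    stringsAsFactors = FALSE)
  n <- length(lst$reactions)
  rid <- character(n); lb <- numeric(n); ub <- numeric(n)
  gpr <- character(n); oc <- numeric(n); pw <- rep(NA_character_, n)
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (k in seq_len(n)) {
    r <- lst$reactions[[k]]
    rid[k] <- as.character(r$id)
    lb[k] <- if (is.null(r$lower_bound)) -1000 else as.numeric(r$lower_bound)
    ub[k] <- if (is.null(r$upper_bound)) 1000 else as.numeric(r$upper_bound)
    gpr[k] <- if (is.null(r$gene_reaction_rule)) "" else as.character(r$gene_reaction_rule)
    oc[k] <- if (is.null(r$objective_coefficient)) 0 else as.numeric(r$objective_coefficient)
    if (!is.null(r$subsystem) && nzchar(r$subsystem)) pw[k] <- as.character(r$subsystem)
    if (length(r$metabolites)) {
      midx <- match(names(r$metabolites), mets$id)
      if (anyNA(midx))
        stop("reaction '", rid[k], "' references undeclared metabolite(s): ",
             paste(names(r$metabolites)[is.na(midx)], collapse = ", "))
      ii <- c(ii, midx); jj <- c(jj, rep(k, length(midx)))
      xx <- c(xx, vapply(r$metabolites, as.numeric, 0))
    }
  }
  for (k in seq_len(n)) {
    if (nzchar(gpr[k]))
      tryCatch(parse_gpr(gpr[k]), error = function(e)
        stop("GPR of reaction '", rid[k], "' fails to parse: ",
             conditionMessage(e)))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(mets), n),
                            dimnames = list(mets$id, rid))
  metabolic_model(mets,
                  data.frame(id = rid, lower_bound = lb, upper_bound = ub,
                             gpr = gpr, objective_coefficient = oc,
                             pathway = pw, stringsAsFactors = FALSE),
                  S)
}

json_to_model <- function(text) {
  cobra_list_to_model(jsonlite::fromJSON(text, simplifyVector = FALSE))
}

yaml_to_model <- function(text) {
  cobra_list_to_model(yaml::yaml.load(text))
}
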