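#' Parse a gene-protein-reaction (GPR) boolean rule
#'
#' GPR rules link genes to reactions through boolean expressions such as
#' `"(g1 and g2) or g3"`. `and`/`or` are case-insensitive, `and` binds
#' tighter than `or`, and parentheses override precedence. The result is an
#' abstract syntax tree of nested lists: leaves are
#' `list(kind = "gene", gene = <id>)`, internal nodes are
#' `list(kind = "and"|"or", children = <list of >= 2 nodes>)`. Consecutive
#' applications of the same operator are flattened into one n-ary node.
#'
#' @param text GPR rule text; must be non-empty.
#' @return A `gpr_node` list as described above.
#' @examples
#' parse_gpr("g1 and g2 or g3")   # OR(AND(g1, g2), g3)
#' parse_gpr("(g1 or g2) and g3") # AND(OR(g1, g2), g3)
#' @export
parse_gpr <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("GPR text must be a single non-empty string")
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  node <- gpr_parse_or(st)
  if (st$pos <= length(st$toks))
    stop(sprintf("GPR parse error at token %d ('%s'): unexpected trailing input",
                 st$pos, st$toks[st$pos]))
  node
}

gpr_tokenize <- function(text) {
  # split on parentheses and whitespace; keep parentheses as tokens
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1L]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  children <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_and(st)))
  }
  if (length(children) == 1L) children[[1L]]
  else structure(list(kind = "or", children = gpr_flatten(children, "or")),
                 class = "gpr_node")
}

gpr_parse_and <- function(st) {
  children <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_atom(st)))
  }
  if (length(children) == 1L) children[[1L]]
  else structure(list(kind = "and", children = gpr_flatten(children, "and")),
                 class = "gpr_node")
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk))
    stop(sprintf("GPR parse error at token %d: expected gene or '(' but input ended",
                 st$pos))
  if (tk == "(") {
    st$pos <- st$pos + 1L
    node <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")")
      stop(sprintf("GPR parse error at token %d: unbalanced parentheses", st$pos))
    st$pos <- st$pos + 1L
    return(node)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or"))
    stop(sprintf("GPR parse error at token %d ('%s'): expected gene or '('",
                 st$pos, tk))
  st$pos <- st$pos + 1L
  structure(list(kind = "gene", gene = tk), class = "gpr_node")
}

gpr_flatten <- function(children, kind) {
  out <- list()
  for (ch in children) {
    if (identical(ch$kind, kind)) out <- c(out, ch$children)
    else out <- c(out, list(ch))
  }
  out
}

#' @export
print.gpr_node <- function(x, ...) {
  cat(gpr_canonical(x), "\n")
  invisible(x)
}

#' Deparse a GPR node back to rule text
#'
#' `gpr_canonical` produces a fully parenthesized, sorted form used to
#' compare rules for boolean-semantics equality; `gpr_text` a readable form
#' with minimal parentheses.
#'
#' @param node a `gpr_node`.
#' @return A single string.
#' @export
gpr_text <- function(node) {
  if (node$kind == "gene") return(node$gene)
  sep <- if (node$kind == "and") " and " else " or "
  parts <- vapply(node$children, function(ch) {
    t <- gpr_text(ch)
    # parenthesize an OR inside an AND; everything else is unambiguous
    if (node$kind == "and" && ch$kind == "or") paste0("(", t, ")") else t
  }, "")
  paste(parts, collapse = sep)
}

#' @rdname gpr_text
#' @export
gpr_canonical <- function(node) {
  if (node$kind == "gene") return(node$gene)
  parts <- sort(vapply(node$children, gpr_canonical, ""))
  paste0(node$kind, "(", paste(parts, collapse = ","), ")")
}

#' All gene ids referenced by a GPR node
#' @param node a `gpr_node`.
#' @return character vector (duplicates removed).
#' @export
gpr_genes <- function(node) {
  if (node$kind == "gene") return(node$gene)
  unique(unlist(lapply(node$children, gpr_genes)))
}

#' Evaluate a GPR rule to a Reaction Activity Score
#'
#' The score of a rule under an expression vector follows the RAS semantics:
#' `or` is the sum of its operands (isoenzyme redundancy adds capacity),
#' `and` is the minimum (complex subunits are co-limiting). Genes missing
#' from `expr` are dropped from sums and minima; a node whose operands are
#' all missing evaluates to `NA` (the missing marker), and so does a gene
#' absent from `expr`.
#'
#' @param node a `gpr_node` from [parse_gpr()].
#' @param expr named numeric vector of non-negative expression values; genes
#'   not present in `names(expr)` count as missing. An `NA` value is treated
#'   the same as an absent gene.
#' @return A single numeric score, or `NA` when every gene in the rule is
#'   missing.
#' @examples
#' eval_ras(parse_gpr("(g1 and g2) or g3"), c(g1 = 2, g2 = 6, g3 = 3)) # 5
#' eval_ras(parse_gpr("(g1 and g2) or g3"), c(g1 = 2, g2 = 6))        # 2
#' @export
eval_ras <- function(node, expr) {
  if (node$kind == "gene") {
    v <- expr[node$gene]
    return(if (length(v) == 0L || is.na(v)) NA_real_ else as.numeric(v))
  }
  vals <- vapply(node$children, eval_ras, numeric(1L), expr = expr)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  if (node$kind == "or") sum(vals) else min(vals)
}

#' Compute Reaction Activity Scores for every reaction and sample
#'
#' Applies [eval_ras()] to each reaction's GPR rule under each sample column
#' of an expression matrix, producing a reactions-by-samples RAS matrix.
#' Reactions without a GPR get `NA` (missing) in every sample. Gene ids are
#' matched by exact string equality after trimming surrounding whitespace;
#' no case folding or alias mapping is applied.
#'
#' @param model a `metabolic_model` whose GPR texts parse.
#' @param expr numeric matrix (genes x samples) with gene ids as row names
#'   and sample names as column names, all values non-negative; or a
#'   data.frame whose first column holds gene ids (as produced by
#'   [read_expression()]).
#' @return A numeric matrix (reactions x samples) with an attribute
#'   `gene_coverage`: the fraction of the model's GPR genes found in the
#'   expression data. Missing scores are `NA`.
#' @export
expression_to_ras <- function(model, expr) {
  expr <- as_expression_matrix(expr)
  genes <- model_genes(model)
  if (!length(genes)) stop("model has no GPR rules; nothing to score")
  found <- intersect(genes, rownames(expr))
  if (!length(found))
    stop("no overlap between model GPR genes and expression gene ids")
  coverage <- length(found) / length(genes)

  rxns <- model$reactions
  out <- matrix(NA_real_, nrow(rxns), ncol(expr),
                dimnames = list(rxns$id, colnames(expr)))
  asts <- lapply(rxns$gpr, function(g) if (nzchar(g)) parse_gpr(g) else NULL)
  for (j in seq_len(ncol(expr))) {
    ev <- expr[, j]
    names(ev) <- rownames(expr)
    for (i in seq_len(nrow(rxns))) {
      if (!is.null(asts[[i]])) out[i, j] <- eval_ras(asts[[i]], ev)
    }
  }
  attr(out, "gene_coverage") <- coverage
  out
}

as_expression_matrix <- function(expr) {
  if (is.data.frame(expr)) {
    ids <- trimws(as.character(expr[[1L]]))
    m <- as.matrix(expr[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    expr <- m
  }
  if (!is.matrix(expr) || is.null(rownames(expr)))
    stop("expression data must be a matrix with gene-id row names")
  rownames(expr) <- trimws(rownames(expr))
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene ids in expression data: ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))]), collapse = ", "))
  if (any(expr < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  expr
}

#' Read / write tab-separated expression and RAS tables
#'
#' Both layouts are genes-or-reactions in rows and samples in columns, a
#' header row, and the id in the first column. Missing RAS values are
#' serialized as the string `"None"`.
#'
#' @param path file path.
#' @param x matrix to write (row names used as the id column).
#' @param id_col header of the first column on write.
#' @return `read_expression` / `read_ras`: numeric matrix with row names.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_expression_matrix(df)
}

#' @rdname read_expression
#' @export
read_ras <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "None"))
  ids <- trimws(as.character(df[[1L]]))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @rdname read_expression
#' @export
write_ras <- function(x, path, id_col = "reaction_id") {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) ifelse(is.na(col), "None", format(col, digits = 12))
    else col
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
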