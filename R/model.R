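#' Construct a constraint-based metabolic model
#'
#' The central container of the package: a set of metabolites, a set of
#' reactions with flux bounds (mmol/gDW/h), gene-protein-reaction (GPR)
#' boolean rules and objective coefficients, and a sparse stoichiometric
#' matrix linking the two. Exchange (boundary) reactions are detected
#' structurally: a reaction is an exchange iff it touches exactly one
#' metabolite with nonzero stoichiometry, regardless of its id.
#'
#' @param metabolites data.frame with columns `id` and `compartment`.
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`; optional `gpr` (boolean rule text, `""` or `NA` when
#'   absent), `objective_coefficient` (default 0) and `pathway`
#'   (default `NA`).
#' @param stoichiometry numeric matrix (or `Matrix` sparse matrix) with one
#'   row per metabolite and one column per reaction; dimnames must match the
#'   metabolite and reaction ids (any order).
#' @return An object of class `metabolic_model`.
#' @examples
#' mets <- data.frame(id = c("A[e]", "B[e]"), compartment = c("e", "e"))
#' rxns <- data.frame(id = c("EX_A", "R1", "EX_B"),
#'                    lower_bound = c(-10, 0, 0),
#'                    upper_bound = c(1000, 1000, 1000),
#'                    objective_coefficient = c(0, 0, 1))
#' S <- matrix(c(-1, -1, 0,
#'                0,  1, -1), 2, 3, byrow = TRUE,
#'             dimnames = list(c("A[e]", "B[e]"), c("EX_A", "R1", "EX_B")))
#' m <- metabolic_model(mets, rxns, S)
#' exchange_reactions(m)
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "compartment") %in% names(metabolites)),
            all(c("id", "lower_bound", "upper_bound") %in% names(reactions)))
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (anyDuplicated(reactions$id))
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$objective_coefficient)) reactions$objective_coefficient <- 0
  if (is.null(reactions$pathway)) reactions$pathway <- NA_character_
  bad <- reactions$lower_bound > reactions$upper_bound
  if (any(bad))
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(reactions$id[bad], collapse = ", "))

  S <- Matrix::Matrix(stoichiometry, sparse = TRUE)
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop("stoichiometry must carry metabolite row names and reaction column names")
  if (!setequal(rownames(S), metabolites$id))
    stop("stoichiometry rows do not match declared metabolite ids")
  if (!setequal(colnames(S), reactions$id))
    stop("stoichiometry columns do not match declared reaction ids")
  S <- S[metabolites$id, reactions$id, drop = FALSE]

  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL
  structure(list(metabolites = metabolites, reactions = reactions,
                 stoichiometry = S),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  nex <- sum(is_exchange(x))
  genes <- model_genes(x)
  cat(sprintf(paste0("metabolic_model: %d metabolites, %d reactions ",
                     "(%d exchange), %d genes in GPRs\n"),
              nrow(x$metabolites), nrow(x$reactions), nex, length(genes)))
  obj <- x$reactions$id[x$reactions$objective_coefficient != 0]
  if (length(obj)) cat("objective:", paste(obj, collapse = " + "), "\n")
  invisible(x)
}

#' Structural exchange-reaction test
#'
#' A reaction is an exchange reaction iff exactly one metabolite has nonzero
#' stoichiometry in it (boundary uptake/secretion under the COBRA sign
#' convention: negative flux is uptake).
#'
#' @param model a `metabolic_model`.
#' @return `is_exchange`: logical vector along `model$reactions`;
#'   `exchange_reactions`: the ids of the exchange reactions.
#' @export
is_exchange <- function(model) {
  Matrix::colSums(model$stoichiometry != 0) == 1
}

#' @rdname is_exchange
#' @export
exchange_reactions <- function(model) {
  model$reactions$id[is_exchange(model)]
}

#' For each exchange reaction, the single metabolite it transports.
#' @param model a `metabolic_model`.
#' @return named character vector: names are exchange reaction ids, values
#'   metabolite ids.
#' @export
exchange_metabolites <- function(model) {
  ex <- which(is_exchange(model))
  S <- model$stoichiometry
  out <- vapply(ex, function(j) rownames(S)[which(S[, j] != 0)[1L]], "")
  names(out) <- model$reactions$id[ex]
  out
}

#' All gene ids appearing in the model's GPR rules
#' @param model a `metabolic_model`.
#' @return character vector of distinct gene ids.
#' @export
model_genes <- function(model) {
  gprs <- model$reactions$gpr
  gprs <- gprs[!is.na(gprs) & nzchar(gprs)]
  if (!length(gprs)) return(character())
  sort(unique(unlist(lapply(gprs, function(g) gpr_genes(parse_gpr(g))))))
}

# equality helper used by round-trip tests: same ids, bounds, stoichiometry,
# objective, and GPR truth semantics (compared on canonicalized ASTs)
model_equivalent <- function(a, b, tol = 1e-9) {
  if (!setequal(a$reactions$id, b$reactions$id)) return(FALSE)
  if (!setequal(a$metabolites$id, b$metabolites$id)) return(FALSE)
  ra <- a$reactions[match(b$reactions$id, a$reactions$id), ]
  if (max(abs(ra$lower_bound - b$reactions$lower_bound)) > tol) return(FALSE)
  if (max(abs(ra$upper_bound - b$reactions$upper_bound)) > tol) return(FALSE)
  if (max(abs(ra$objective_coefficient - b$reactions$objective_coefficient)) > tol)
    return(FALSE)
  Sa <- as.matrix(a$stoichiometry)[b$metabolites$id, b$reactions$id, drop = FALSE]
  if (max(abs(Sa - as.matrix(b$stoichiometry))) > tol) return(FALSE)
  for (i in seq_along(b$reactions$id)) {
    ga <- ra$gpr[i]; gb <- b$reactions$gpr[i]
    ea <- if (nzchar(ga)) gpr_canonical(parse_gpr(ga)) else ""
    eb <- if (nzchar(gb)) gpr_canonical(parse_gpr(gb)) else ""
    if (!identical(ea, eb)) return(FALSE)
  }
  TRUE
}
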