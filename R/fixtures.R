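# Deterministic toy-scale generators: models with chain/parallel topology,
# matching SVG maps, expression matrices with planted group effects, and
# ground-truth tables derived symbolically from the GPR structure. Every
# downstream stage of the package is testable on these with no external
# data.

#' Generate a toy metabolic model (chains/parallel paths) plus an SVG map
#'
#' Builds a source metabolite `A[e]`, a sink metabolite `B[e]`, an uptake
#' exchange `EX_A` (lower bound `-uptake_limit`), a secretion exchange
#' `EX_B` (the objective), and `n_parallel_paths` paths from A to B, path
#' `p` consisting of `path_lengths[p]` internal reactions `P<p>_<k>`
#' (intermediates in compartment `c`). GPR rules are attached from
#' `gpr_assignment`. The matching SVG carries one `<path>` element per
#' reaction with element id `R_<reaction id>`.
#'
#' @param n_parallel_paths number of parallel A-to-B routes.
#' @param path_lengths integer vector (recycled) of reactions per route.
#' @param uptake_limit maximal uptake of A (flux units, > 0 for a nonzero
#'   optimum).
#' @param path_ub upper bound of each internal path reaction.
#' @param gpr_assignment named character vector / list: reaction id -> GPR
#'   text.
#' @return list with `model` (a [metabolic_model()]) and `svg` (map text).
#' @export
make_toy_model <- function(n_parallel_paths = 1L, path_lengths = 1L,
                           uptake_limit = 10, path_ub = 1000,
                           gpr_assignment = NULL) {
  stopifnot(n_parallel_paths >= 1L)
  path_lengths <- rep_len(path_lengths, n_parallel_paths)
  mets <- data.frame(id = c("A[e]", "B[e]"), compartment = c("e", "e"),
                     stringsAsFactors = FALSE)
  rxn <- list(); st <- list()
  add_rxn <- function(id, lb, ub, stoich, pathway) {
    rxn[[length(rxn) + 1L]] <<- data.frame(
      id = id, lower_bound = lb, upper_bound = ub, pathway = pathway,
      stringsAsFactors = FALSE)
    st[[length(st) + 1L]] <<- data.frame(
      metabolite = names(stoich), reaction = id, coef = unname(stoich),
      stringsAsFactors = FALSE)
  }
  add_rxn("EX_A", -uptake_limit, 1000, c("A[e]" = -1), "exchange")
  for (p in seq_len(n_parallel_paths)) {
    len <- path_lengths[p]
    nodes <- c("A[e]",
               if (len > 1L) sprintf("I%d_%d[c]", p, seq_len(len - 1L)),
               "B[e]")
    for (k in seq_len(len)) {
      add_rxn(sprintf("P%d_%d", p, k), 0, path_ub,
              stats::setNames(c(-1, 1), c(nodes[k], nodes[k + 1L])),
              sprintf("path%d", p))
    }
    if (len > 1L)
      mets <- rbind(mets, data.frame(id = nodes[2:len], compartment = "c",
                                     stringsAsFactors = FALSE))
  }
  add_rxn("EX_B", 0, 1000, c("B[e]" = -1), "exchange")
  rxns <- do.call(rbind, rxn)
  rxns$objective_coefficient <- as.numeric(rxns$id == "EX_B")
  rxns$gpr <- ""
  if (!is.null(gpr_assignment)) {
    for (id in names(gpr_assignment)) {
      if (!id %in% rxns$id) stop("gpr_assignment names unknown reaction: ", id)
      rxns$gpr[rxns$id == id] <- gpr_assignment[[id]]
    }
  }
  stoich <- do.call(rbind, st)
  S <- Matrix::sparseMatrix(i = match(stoich$metabolite, mets$id),
                            j = match(stoich$reaction, rxns$id),
                            x = stoich$coef,
                            dims = c(nrow(mets), nrow(rxns)),
                            dimnames = list(mets$id, rxns$id))
  model <- metabolic_model(mets, rxns, S)
  list(model = model, svg = make_map_svg(model))
}

#' Minimal SVG metabolic map for a model
#'
#' One horizontal `<path>` stroke per reaction, stacked vertically, each
#' with element id `R_<reaction id>` and a text label; enough structure for
#' map-styling round trips.
#'
#' @param model a `metabolic_model`.
#' @return SVG document as a single string.
#' @export
make_map_svg <- function(model) {
  ids <- model$reactions$id
  h <- 20 * length(ids) + 30
  rows <- vapply(seq_along(ids), function(i) {
    y <- 20 * i
    paste0(sprintf('  <path id="R_%s" d="M 120 %d L 260 %d" stroke="#999999" stroke-width="2" fill="none"/>',
                   ids[i], y, y),
           "\n",
           sprintf('  <text id="label_%s" x="10" y="%d" font-size="10">%s</text>',
                   ids[i], y + 4, ids[i]))
  }, "")
  paste0('<svg xmlns="http://www.w3.org/2000/svg" width="300" height="',
         h, '">\n', paste(rows, collapse = "\n"), "\n</svg>\n")
}

#' Generate an expression matrix with planted group effects
#'
#' Samples gene expression as `baseline_mean * factor * noise`, with
#' multiplicative lognormal noise of coefficient of variation `noise_cv`
#' (non-negative by construction, a realistic shape for expression data)
#' and `factor` taken from `planted_effects` for (group, gene) pairs and 1
#' otherwise. Alongside the matrix, a ground-truth table states which
#' reactions' activity scores are expected to shift between each pair of
#' groups and in which direction; it is computed *symbolically* by
#' evaluating each GPR at the noise-free group means (the RAS semantics is
#' monotone in every gene, so the noise-free comparison gives the expected
#' direction), independent of any code under test.
#'
#' @param model a `metabolic_model` (planted genes must appear in its
#'   GPRs).
#' @param groups character vector of group names.
#' @param n_samples_per_group samples per group.
#' @param baseline_mean baseline expression level (arbitrary units).
#' @param planted_effects data.frame (`group`, `gene`, `factor`) of
#'   multiplicative effects; `NULL` for a null dataset.
#' @param noise_cv lognormal coefficient of variation (default 0.2).
#' @param seed integer seed (identical seed, identical matrix).
#' @return list with `expression` (genes x samples matrix), `groups`
#'   (named vector sample -> group) and `truth` (data.frame
#'   `group1`, `group2`, `reaction_id`, `direction` in
#'   `c("up", "down", "none")` comparing group1 to group2).
#' @export
make_expression <- function(model, groups = c("g1", "g2"),
                            n_samples_per_group = 5L, baseline_mean = 100,
                            planted_effects = NULL, noise_cv = 0.2,
                            seed = 1L) {
  genes <- model_genes(model)
  if (!length(genes)) stop("model has no GPR genes to simulate")
  if (!is.null(planted_effects)) {
    stopifnot(all(c("group", "gene", "factor") %in% names(planted_effects)))
    missing_g <- setdiff(planted_effects$gene, genes)
    if (length(missing_g))
      stop("planted gene(s) not in any GPR: ", paste(missing_g, collapse = ", "))
  }
  mean_of <- function(group, gene) {
    f <- 1
    if (!is.null(planted_effects)) {
      hit <- planted_effects$group == group & planted_effects$gene == gene
      if (any(hit)) f <- prod(planted_effects$factor[hit])
    }
    baseline_mean * f
  }
  sdlog <- sqrt(log(1 + noise_cv^2))
  samples <- unlist(lapply(groups, function(g)
    sprintf("%s_s%d", g, seq_len(n_samples_per_group))))
  gvec <- stats::setNames(rep(groups, each = n_samples_per_group), samples)
  expr <- withr::with_seed(seed, {
    m <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    for (s in samples) {
      for (gn in genes) {
        mu <- mean_of(gvec[[s]], gn)
        # lognormal with mean mu and cv noise_cv
        m[gn, s] <- mu * stats::rlnorm(1L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      }
    }
    m
  })

  # symbolic ground truth: GPR value at noise-free means, per group pair
  rx <- model$reactions
  truth <- list()
  asts <- lapply(rx$gpr, function(g) if (nzchar(g)) parse_gpr(g) else NULL)
  if (length(groups) >= 2L) {
    cb <- utils::combn(groups, 2L)
    for (j in seq_len(ncol(cb))) {
      g1 <- cb[1L, j]; g2 <- cb[2L, j]
      e1 <- stats::setNames(vapply(genes, function(gn) mean_of(g1, gn), 0), genes)
      e2 <- stats::setNames(vapply(genes, function(gn) mean_of(g2, gn), 0), genes)
      for (i in seq_len(nrow(rx))) {
        if (is.null(asts[[i]])) next
        v1 <- eval_ras(asts[[i]], e1); v2 <- eval_ras(asts[[i]], e2)
        dir <- if (is.na(v1) || is.na(v2) || v1 == v2) "none"
               else if (v1 > v2) "up" else "down"
        truth[[length(truth) + 1L]] <- data.frame(
          group1 = g1, group2 = g2, reaction_id = rx$id[i], direction = dir,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(expression = expr, groups = gvec,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(group1 = character(), group2 = character(),
                    reaction_id = character(), direction = character()))
}

# model of n disjoint gene-gated linear chains: EX_in_i -> Ci -> EX_out_i,
# every Ci capped at path_ub with a single-gene GPR, all sinks in the
# objective; chains are stoichiometrically independent, so their fluxes
# are independent test statistics downstream
disjoint_chains_model <- function(n_chains, path_ub = 10, uptake = 20) {
  mets <- data.frame(
    id = c(sprintf("S%d[e]", seq_len(n_chains)),
           sprintf("T%d[e]", seq_len(n_chains))),
    compartment = "e", stringsAsFactors = FALSE)
  rxns <- do.call(rbind, lapply(seq_len(n_chains), function(i) data.frame(
    id = c(sprintf("EX_in%d", i), sprintf("C%d", i), sprintf("EX_out%d", i)),
    lower_bound = c(-uptake, 0, 0),
    upper_bound = c(1000, path_ub, 1000),
    gpr = c("", sprintf("gene%d", i), ""),
    objective_coefficient = c(0, 0, 1),
    pathway = sprintf("chain%d", i),
    stringsAsFactors = FALSE)))
  S <- matrix(0, 2L * n_chains, 3L * n_chains,
              dimnames = list(mets$id, rxns$id))
  for (i in seq_len(n_chains)) {
    S[sprintf("S%d[e]", i), sprintf("EX_in%d", i)] <- -1
    S[sprintf("S%d[e]", i), sprintf("C%d", i)] <- -1
    S[sprintf("T%d[e]", i), sprintf("C%d", i)] <- 1
    S[sprintf("T%d[e]", i), sprintf("EX_out%d", i)] <- -1
  }
  metabolic_model(mets, rxns, S)
}

#' Null fixture: independent gene-gated chains with exchangeable groups
#'
#' A no-effect counterpart to [make_twogroup_fixture()] for type-I-error
#' checks: `n_chains` stoichiometrically independent chains, each capped
#' by its own single-gene GPR, and an expression matrix with no planted
#' effects, so the two groups are exchangeable and every chain contributes
#' an independent null test statistic downstream.
#'
#' @param n_chains number of independent chains (default 6).
#' @param n_samples_per_group expression samples per group (default 20).
#' @param noise_cv lognormal noise CV.
#' @param seed integer seed.
#' @return list with `model`, `expression`, `groups`, `truth` (all
#'   directions `"none"`).
#' @export
make_null_fixture <- function(n_chains = 6L, n_samples_per_group = 20L,
                              noise_cv = 0.2, seed = 1L) {
  model <- disjoint_chains_model(n_chains)
  ex <- make_expression(model, groups = c("g1", "g2"),
                        n_samples_per_group = n_samples_per_group,
                        planted_effects = NULL, noise_cv = noise_cv,
                        seed = seed)
  c(list(model = model), ex)
}

#' Two-group planted-effect fixture over two independent chains
#'
#' The workhorse end-to-end fixture: a model of two *disjoint* chains
#' (`EX_A -> C1 -> EX_B` and `EX_C -> C2 -> EX_D`, both contributing to
#' the objective), each chain's internal reaction capped at `path_ub` and
#' carrying a single-gene GPR, with uptake generous enough that the
#' GPR-scaled cap is always the binding constraint. Genes of chain 1 are
#' up-scaled by `effect_size` in the first group, so after RAS
#' normalization and bound scaling the whole of chain 1 (including its
#' exchanges, which carry the same flux) shifts up in group 1 while chain
#' 2 is exchangeable between groups. The expected flux-level significant
#' set is therefore chain 1's reactions, recorded in `$flux_truth`.
#'
#' @param n_samples_per_group expression samples per group.
#' @param effect_size multiplicative up-effect on chain 1's gene in group
#'   1 (default 3).
#' @param noise_cv lognormal noise CV (default 0.2).
#' @param seed integer seed.
#' @return list: `model`, `svg`, `expression`, `groups`, `truth` (RAS
#'   level), `flux_truth` (data.frame `reaction_id`, `direction` expected
#'   for group1 vs group2 at the flux level).
#' @export
make_twogroup_fixture <- function(n_samples_per_group = 25L, effect_size = 3,
                                  noise_cv = 0.2, seed = 1L) {
  mets <- data.frame(id = c("A[e]", "B[e]", "C[e]", "D[e]"),
                     compartment = "e", stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_A", "C1", "EX_B", "EX_C", "C2", "EX_D"),
    lower_bound = c(-20, 0, 0, -20, 0, 0),
    upper_bound = c(1000, 10, 1000, 1000, 10, 1000),
    gpr = c("", "gA1 or gA2", "", "", "gC1", ""),
    objective_coefficient = c(0, 0, 1, 0, 0, 1),
    pathway = c("chain1", "chain1", "chain1", "chain2", "chain2", "chain2"),
    stringsAsFactors = FALSE)
  S <- matrix(0, 4, 6, dimnames = list(mets$id, rxns$id))
  S["A[e]", "EX_A"] <- -1
  S["A[e]", "C1"] <- -1; S["B[e]", "C1"] <- 1
  S["B[e]", "EX_B"] <- -1
  S["C[e]", "EX_C"] <- -1
  S["C[e]", "C2"] <- -1; S["D[e]", "C2"] <- 1
  S["D[e]", "EX_D"] <- -1
  model <- metabolic_model(mets, rxns, S)
  eff <- data.frame(group = "g1", gene = c("gA1", "gA2"),
                    factor = effect_size, stringsAsFactors = FALSE)
  ex <- make_expression(model, groups = c("g1", "g2"),
                        n_samples_per_group = n_samples_per_group,
                        planted_effects = eff, noise_cv = noise_cv,
                        seed = seed)
  # signed-flux expectations for group1 vs group2: chain 1 carries more
  # flux in group 1, so its forward reactions shift up while its uptake
  # exchange (negative flux = uptake) becomes more negative, i.e. "down"
  # on the signed scale
  flux_truth <- data.frame(
    reaction_id = rxns$id,
    direction = c("down", "up", "up", "none", "none", "none"),
    stringsAsFactors = FALSE)
  c(list(model = model, svg = make_map_svg(model)), ex,
    list(flux_truth = flux_truth))
}
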