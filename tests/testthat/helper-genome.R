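# synthetic genome-scale model generator (stand-in for a published
# human-metabolism reconstruction of 395 metabolites / 469 reactions /
# 498 GPR genes): random sparse stoichiometry, boundary exchanges, and
# GPR rules distributing a fixed gene census across the reactions
make_synthetic_genome_model <- function(n_mets = 395L, n_rxns = 469L,
                                        n_genes = 498L, seed = 2024L) {
  withr::with_seed(seed, {
    mets <- data.frame(id = sprintf("met%03d[%s]", seq_len(n_mets),
                                    sample(c("c", "m", "e"), n_mets, TRUE)),
                       compartment = "c", stringsAsFactors = FALSE)
    mets$compartment <- sub("^.*\\[([a-z])\\]$", "\\1", mets$id)
    n_ex <- 60L
    rid <- c(sprintf("EX_%03d", seq_len(n_ex)),
             sprintf("RXN%03d", seq_len(n_rxns - n_ex)))
    ii <- integer(); jj <- integer(); xx <- numeric()
    for (j in seq_len(n_ex)) {
      ii <- c(ii, j); jj <- c(jj, j); xx <- c(xx, -1)
    }
    for (j in (n_ex + 1L):n_rxns) {
      k <- sample(2:4, 1L)
      who <- sample(n_mets, k)
      coef <- sample(c(-2, -1, 1, 2), k, TRUE)
      coef[1L] <- -abs(coef[1L]); coef[k] <- abs(coef[k])
      ii <- c(ii, who); jj <- c(jj, rep(j, k)); xx <- c(xx, coef)
    }
    S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(n_mets, n_rxns),
                              dimnames = list(mets$id, rid))
    genes <- sprintf("HGNC:%d", seq_len(n_genes) + 1000L)
    gpr <- character(n_rxns)
    gi <- 1L
    for (j in seq((n_ex + 1L), n_rxns)) {
      if (gi > n_genes) break
      k <- min(sample(1:3, 1L), n_genes - gi + 1L)
      gs <- genes[gi:(gi + k - 1L)]
      gi <- gi + k
      gpr[j] <- if (k == 1L) gs
                else if (stats::runif(1) < 0.5) paste(gs, collapse = " or ")
                else paste(gs, collapse = " and ")
    }
    rxns <- data.frame(id = rid,
                       lower_bound = ifelse(stats::runif(n_rxns) < 0.3, -1000, 0),
                       upper_bound = 1000,
                       gpr = gpr,
                       objective_coefficient = as.numeric(rid == "RXN001"),
                       stringsAsFactors = FALSE)
    metabolic_model(mets, rxns, S)
  })
}
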