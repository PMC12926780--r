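test_that("FBA solves textbook chain and bottleneck cases", {
  m <- chain_model(uptake = 10)
  r <- fba(m)
  expect_equal(r$status, "optimal")
  expect_equal(r$objective_value, 10)
  expect_lt(steady_state_residual(m, r), 1e-6)

  bs <- as.data.frame(model_to_table(m)[, c("reaction_id", "lower_bound",
                                            "upper_bound")])
  bs$upper_bound[bs$reaction_id == "P1_1"] <- 4
  expect_equal(fba(m, bs)$objective_value, 4)

  bs2 <- bs
  bs2$upper_bound[bs2$reaction_id == "P1_1"] <- 1000
  bs2$lower_bound[bs2$reaction_id == "EX_A"] <- 0
  expect_equal(fba(m, bs2)$objective_value, 0)
})

test_that("FBA never throws for infeasible or unbounded state", {
  m <- chain_model()
  bs <- data.frame(reaction_id = m$reactions$id,
                   lower_bound = m$reactions$lower_bound,
                   upper_bound = m$reactions$upper_bound)
  # force uptake (positive lower bound on EX_B secretion while blocking it)
  bs$lower_bound[bs$reaction_id == "EX_B"] <- 5
  bs$upper_bound[bs$reaction_id == "P1_1"] <- 0
  r <- fba(m, bs)
  expect_equal(r$status, "infeasible")
  expect_true(is.na(r$objective_value))
})

test_that("FBA / FVA optima match the vertex-enumeration oracle on random nets", {
  for (seed in 1:12) {
    m <- random_network(n_rxn = sample(5:8, 1), n_met = sample(2:4, 1),
                        seed = 4000 + seed)
    lp <- list(S = as.matrix(m$stoichiometry),
               lb = m$reactions$lower_bound, ub = m$reactions$upper_bound,
               obj = m$reactions$objective_coefficient)
    oc <- oracle_lp(lp$S, rep(0, nrow(lp$S)), lp$obj, lp$lb, lp$ub, "max")
    r <- fba(m)
    expect_equal(r$status, "optimal")
    expect_equal(r$objective_value, oc$value, tolerance = 1e-6)
    expect_lt(steady_state_residual(m, r), 1e-6)

    # FVA at fraction 0 on two random reactions
    pick <- sample(m$reactions$id, 2)
    fv <- fva(m, fraction_of_optimum = 0, reactions = pick)
    for (k in 1:2) {
      j <- match(pick[k], m$reactions$id)
      ee <- numeric(ncol(lp$S)); ee[j] <- 1
      lo <- oracle_lp(lp$S, rep(0, nrow(lp$S)), ee, lp$lb, lp$ub, "min")$value
      hi <- oracle_lp(lp$S, rep(0, nrow(lp$S)), ee, lp$lb, lp$ub, "max")$value
      expect_equal(fv$min[k], lo, tolerance = 1e-6)
      expect_equal(fv$max[k], hi, tolerance = 1e-6)
    }
  }
})

test_that("pFBA picks the shortest route and matches the split-LP oracle", {
  # one 1-reaction route vs one 2-reaction route: all flux takes the short one
  m <- make_toy_model(2L, c(1L, 2L), 10)$model
  p <- pfba(m)
  expect_equal(p$objective_value, 10, tolerance = 1e-4)
  expect_equal(unname(p$fluxes["P1_1"]), 10, tolerance = 1e-4)
  expect_equal(unname(p$fluxes["P2_1"]), 0, tolerance = 1e-4)

  # chain: pFBA flux equals FBA flux (unique solution)
  mc <- chain_model()
  expect_equal(pfba(mc)$fluxes, fba(mc)$fluxes, tolerance = 1e-4)

  # 5-reaction fixtures: total |v| equals an independently enumerated
  # minimum over the forward/reverse-split polytope
  for (seed in 1:4) {
    m5 <- random_network(n_rxn = 5, n_met = 3, seed = 970 + seed)
    base <- fba(m5)
    if (base$status != "optimal") next
    p5 <- pfba(m5)
    expect_equal(p5$status, "optimal")
    oracle <- oracle_pfba_total(as.matrix(m5$stoichiometry),
                                m5$reactions$objective_coefficient,
                                m5$reactions$lower_bound,
                                m5$reactions$upper_bound,
                                base$objective_value)
    expect_equal(p5$total_flux, oracle, tolerance = 1e-6)
    # pFBA dominance and objective retention
    expect_lte(p5$total_flux, sum(abs(base$fluxes)) + 1e-6)
    expect_gte(p5$objective_value,
               base$objective_value - 1e-5 * max(1, abs(base$objective_value)))
  }
})

test_that("FVA brackets the FBA flux and degenerates on unique solutions", {
  # two identical parallel routes: either can carry anything in [0, 10]
  m <- parallel_model(uptake = 10, path_ub = 10)
  fv <- fva(m, fraction_of_optimum = 1)
  expect_equal(fv$min[fv$reaction_id == "P1_1"], 0, tolerance = 1e-5)
  expect_equal(fv$max[fv$reaction_id == "P1_1"], 10, tolerance = 1e-5)

  r <- fba(m)
  for (i in seq_len(nrow(fv))) {
    expect_gte(r$fluxes[fv$reaction_id[i]], fv$min[i] - 1e-6)
    expect_lte(r$fluxes[fv$reaction_id[i]], fv$max[i] + 1e-6)
  }

  # chain model: every reaction's range collapses at fraction 1
  mc <- chain_model()
  fvc <- fva(mc, fraction_of_optimum = 1)
  expect_true(all(fvc$max - fvc$min < 1e-4))
  # fraction 0 frees the objective: EX_B spans [0, 10]
  fv0 <- fva(mc, fraction_of_optimum = 0, reactions = "EX_B")
  expect_equal(c(fv0$min, fv0$max), c(0, 10), tolerance = 1e-6)
})

test_that("single-reaction deletions report redundancy and lethality", {
  mc <- chain_model()
  ko <- single_reaction_deletion(mc)
  expect_equal(ko$objective[ko$reaction_id == "P1_1"], 0, tolerance = 1e-6)

  m <- parallel_model(uptake = 10, path_ub = 1000)
  ko2 <- single_reaction_deletion(m, reactions = "P1_1")
  expect_equal(ko2$objective, 10, tolerance = 1e-6)  # P2_1 carries all

  # deleting an already-closed reaction changes nothing
  bs <- data.frame(reaction_id = m$reactions$id,
                   lower_bound = m$reactions$lower_bound,
                   upper_bound = m$reactions$upper_bound)
  bs[bs$reaction_id == "P2_1", c("lower_bound", "upper_bound")] <- 0
  expect_equal(single_reaction_deletion(m, bs, reactions = "P2_1")$objective,
               fba(m, bs)$objective_value, tolerance = 1e-6)
})
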