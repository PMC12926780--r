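test_that("sampled points satisfy steady state, bounds and FVA containment", {
  m <- parallel_model(uptake = 10, path_ub = 10,
                      gprs = list(P1_1 = "g1", P2_1 = "g2"))
  S <- as.matrix(m$stoichiometry)
  fv <- fva(m, fraction_of_optimum = 0)

  for (frame in list(sample_cbs(m, n_samples = 200, seed = 11),
                     sample_hit_and_run(m, n_samples = 200, thinning = 10,
                                        seed = 11))) {
    expect_equal(nrow(frame), 200L)
    expect_lt(max(abs(S %*% t(frame))), 1e-6)
    lbv <- m$reactions$lower_bound[match(colnames(frame), m$reactions$id)]
    ubv <- m$reactions$upper_bound[match(colnames(frame), m$reactions$id)]
    expect_true(all(t(frame) >= lbv - 1e-6))
    expect_true(all(t(frame) <= ubv + 1e-6))
    for (i in seq_len(nrow(fv))) {
      v <- frame[, fv$reaction_id[i]]
      expect_gte(min(v), fv$min[i] - 1e-6)
      expect_lte(max(v), fv$max[i] + 1e-6)
    }
  }
})

test_that("samplers are deterministic under a fixed seed", {
  m <- parallel_model()
  a <- sample_cbs(m, n_samples = 50, seed = 7)
  b <- sample_cbs(m, n_samples = 50, seed = 7)
  expect_identical(unclass(a), unclass(b))
  h1 <- sample_hit_and_run(m, n_samples = 100, thinning = 5, seed = 3)
  h2 <- sample_hit_and_run(m, n_samples = 100, thinning = 5, seed = 3)
  expect_identical(unclass(h1), unclass(h2))
  expect_false(identical(unclass(a),
                         unclass(sample_cbs(m, n_samples = 50, seed = 8))))
})

test_that("CBS points are vertices: enough active bounds for a certificate", {
  m <- parallel_model(uptake = 10, path_ub = 10)
  S <- as.matrix(m$stoichiometry)
  need <- ncol(S) - qr(S)$rank
  frame <- sample_cbs(m, n_samples = 100, seed = 5)
  lbv <- m$reactions$lower_bound[match(colnames(frame), m$reactions$id)]
  ubv <- m$reactions$upper_bound[match(colnames(frame), m$reactions$id)]
  for (k in seq_len(nrow(frame))) {
    active <- sum(abs(frame[k, ] - lbv) < 1e-6 | abs(frame[k, ] - ubv) < 1e-6)
    expect_gte(active, need)
  }
})

test_that("CBS on a 1-D feasible segment concentrates on its two vertices", {
  # chain with free uptake in [0, 10]: the only corners are flux 0 and 10,
  # picked according to the sign of the random objective along the line
  m <- chain_model(uptake = 10)
  frame <- sample_cbs(m, n_samples = 500, seed = 123)
  v <- frame[, "EX_B"]
  expect_true(all(abs(v) < 1e-6 | abs(v - 10) < 1e-6))
  # share at the upper vertex ~ Binomial(500, 1/2) by symmetry: 3-sigma band
  share <- mean(abs(v - 10) < 1e-6)
  expect_gt(share, 0.5 - 3 * sqrt(0.25 / 500))
  expect_lt(share, 0.5 + 3 * sqrt(0.25 / 500))
})

test_that("hit-and-run mean on the 1-D uniform fixture approaches the midpoint", {
  m <- chain_model(uptake = 10)
  frame <- sample_hit_and_run(m, n_samples = 2000, thinning = 10, seed = 42)
  v <- frame[, "EX_B"]
  # flux is uniform on [0, 10]: mean 5, sd sqrt(100/12)
  se <- sqrt(100 / 12) / sqrt(length(v))
  expect_lt(abs(mean(v) - 5), 3 * se)
})

test_that("flux summaries are exact sample statistics", {
  frame <- matrix(4, 10, 2, dimnames = list(NULL, c("R1", "R2")))
  sm <- summarize_fluxes(frame, quantiles = c(0.1, 0.9))
  expect_true(all(sm$mean == 4 & sm$median == 4 & sm$q10 == 4 & sm$q90 == 4))

  f2 <- matrix(c(0, 10), 2, 1, dimnames = list(NULL, "R"))
  expect_equal(summarize_fluxes(f2, quantiles = 0.5)$q50, 5)

  # independent streaming recomputation on a random frame
  m <- parallel_model()
  fr <- sample_cbs(m, n_samples = 200, seed = 31)
  sm2 <- summarize_fluxes(fr, quantiles = c(0.25, 0.75))
  for (j in seq_len(ncol(fr))) {
    acc <- 0
    for (k in seq_len(nrow(fr))) acc <- acc + fr[k, j]
    expect_equal(sm2$mean[j], acc / nrow(fr), tolerance = 1e-12)
    expect_equal(sm2$median[j], stats::quantile(fr[, j], 0.5, names = FALSE))
  }
  expect_true(all(sm2$q25 <= sm2$median & sm2$median <= sm2$q75))
})

test_that("batching splits sizes evenly and stays reproducible", {
  m <- parallel_model()
  bt <- batch_samples(m, n_samples = 100, n_batches = 4, seed = 2,
                      method = "cbs")
  expect_equal(vapply(bt, nrow, 0L), rep(25L, 4))

  bt2 <- batch_samples(m, n_samples = 10, n_batches = 3, seed = 2,
                       method = "cbs")
  expect_equal(sort(vapply(bt2, nrow, 0L), decreasing = TRUE), c(4L, 3L, 3L))
  expect_equal(sum(vapply(bt2, nrow, 0L)), 10L)

  one <- batch_samples(m, n_samples = 30, n_batches = 1, seed = 9,
                       method = "cbs")[[1]]
  expect_identical(unclass(one), unclass(sample_cbs(m, n_samples = 30, seed = 9)))
  # consecutive batches differ (independent streams)
  expect_false(identical(unclass(bt[[1]])[1:25, ], unclass(bt[[2]])[1:25, ]))
})

test_that("sampling refuses unbounded or infinite-bound regions", {
  m <- chain_model()
  bs <- data.frame(reaction_id = m$reactions$id,
                   lower_bound = m$reactions$lower_bound,
                   upper_bound = m$reactions$upper_bound)
  bs$upper_bound[bs$reaction_id == "EX_B"] <- Inf
  expect_error(sample_cbs(m, bs, n_samples = 5, seed = 1), "infinite bounds")
})

test_that("flux frames round-trip through files", {
  m <- parallel_model()
  fr <- sample_cbs(m, n_samples = 10, seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fluxes(fr, f)
  back <- read_fluxes(f)
  expect_equal(back, unclass(fr)[, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(fr))
})
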