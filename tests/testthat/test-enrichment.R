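test_that("fold change follows the bounded signed formula", {
  expect_equal(fold_change(1, 1), 0)
  expect_equal(fold_change(3, 1), 0.5)
  expect_equal(fold_change(1, -1), 1)
  expect_equal(fold_change(0, 0), 0)   # degenerate case by convention
  expect_equal(fold_change(0, 2), -1)

  withr::with_seed(15, {
    a <- stats::rnorm(500, sd = 10)
    b <- stats::rnorm(500, sd = 10)
    fc <- fold_change(a, b)
    expect_true(all(fc >= -1 & fc <= 1))
    expect_equal(fc, -fold_change(b, a))   # antisymmetry
  })
})

test_that("two-sample tests return two-sided p-values with sane degenerate cases", {
  expect_equal(test_reaction(c(1, 1, 1), c(1, 1, 1)), 1)
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  expect_equal(test_reaction(x, y, "ks"), 1)

  # disjoint supports, n = 20 each: D = 1
  withr::with_seed(8, {
    lo <- stats::runif(20, 0, 1); hi <- stats::runif(20, 2, 3)
    ks <- suppressWarnings(stats::ks.test(lo, hi))
    expect_equal(unname(ks$statistic), 1)
    expect_equal(test_reaction(lo, hi, "ks"), ks$p.value)
  })

  # exact small-sample KS distribution against the path-counting oracle
  withr::with_seed(501, {
    for (i in 1:5) {
      v1 <- round(stats::rnorm(15, 0, 1), 6)
      v2 <- round(stats::rnorm(15, 0.6, 1), 6)
      expect_equal(test_reaction(v1, v2, "ks"), oracle_ks_pvalue(v1, v2),
                   tolerance = 1e-12)
    }
  })

  withr::with_seed(52, {
    v1 <- stats::rnorm(12); v2 <- stats::rnorm(12, 1)
    expect_equal(test_reaction(v1, v2, "mannwhitney"),
                 stats::wilcox.test(v1, v2)$p.value)
    expect_equal(test_reaction(v1, v2, "ttest"),
                 stats::t.test(v1, v2)$p.value)
  })
})

test_that("z-score is the Welch standardized mean difference", {
  expect_equal(z_score(c(1, 2, 3), c(1, 2, 3)), 0)
  # mean difference s with var s^2 in both groups of size 2 gives z = 1
  s <- 3
  v1 <- c(10, 10 + s * sqrt(2))
  v2 <- v1 - s
  expect_equal(z_score(v1, v2), 1)
  expect_true(is.na(z_score(c(2, 2), c(5, 5))))

  withr::with_seed(99, {
    a <- stats::rnorm(30); b <- stats::rnorm(25, 0.4)
    manual <- (sum(a) / 30 - sum(b) / 25) /
      sqrt(sum((a - mean(a))^2) / 29 / 30 + sum((b - mean(b))^2) / 24 / 25)
    expect_equal(z_score(a, b), manual)
  })
})

make_grouped <- function(shift = 0, n = 15, seed = 1, rxns = c("R1", "R2")) {
  withr::with_seed(seed, {
    g1 <- matrix(stats::rnorm(n * length(rxns), 5 + shift), n,
                 dimnames = list(sprintf("a%d", 1:n), rxns))
    g2 <- matrix(stats::rnorm(n * length(rxns), 5), n,
                 dimnames = list(sprintf("b%d", 1:n), rxns))
    list(g1 = g1, g2 = g2)
  })
}

test_that("comparison modes emit the right pairs and labels", {
  gf <- c(make_grouped(seed = 2), list(g3 = make_grouped(seed = 3)$g1))
  rownames(gf$g3) <- sprintf("c%d", seq_len(nrow(gf$g3)))

  cmp <- compare_groups(gf, mode = "one_vs_one")
  expect_named(cmp, c("g1_vs_g2", "g1_vs_g3", "g2_vs_g3"))
  cmp_all <- compare_groups(gf, mode = "one_vs_all")
  expect_named(cmp_all, c("g1_vs_all", "g2_vs_all", "g3_vs_all"))
  cmp_ctl <- compare_groups(gf, mode = "one_vs_control", control = "g2")
  expect_named(cmp_ctl, c("g1_vs_g2", "g3_vs_g2"))
  expect_error(compare_groups(gf, mode = "one_vs_control", control = "zz"),
               "g1, g2, g3")

  # single matrix + group assignment equals the grouped-list route
  big <- rbind(gf$g1, gf$g2)
  groups <- stats::setNames(rep(c("g1", "g2"), each = nrow(gf$g1)),
                            rownames(big))
  cmp2 <- compare_groups(big, groups, mode = "one_vs_one")
  expect_equal(cmp2$g1_vs_g2, cmp$g1_vs_g2)
})

test_that("identical groups yield no significant reactions; swaps flip direction", {
  gf <- make_grouped(shift = 0, seed = 5)
  same <- compare_groups(list(a = gf$g1, b = gf$g1), mode = "one_vs_one")[[1]]
  expect_true(all(same$style_class == "not_significant"))
  expect_true(all(same$p_value == 1))

  gf2 <- make_grouped(shift = 4, seed = 6)
  ab <- compare_groups(list(a = gf2$g1, b = gf2$g2))[[1]]
  ba <- compare_groups(list(b = gf2$g2, a = gf2$g1))[[1]]
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$fold_change, -ba$fold_change)
  expect_true(all(ab$style_class == "up" & ba$style_class == "down"))
})

test_that("significance needs both the p-value and the fold-change gate", {
  # large n, tiny shift: p passes but the 20%-difference ratio gate fails
  withr::with_seed(71, {
    g1 <- matrix(stats::rnorm(200, 10.3, 0.5), 200, 1,
                 dimnames = list(NULL, "R"))
    g2 <- matrix(stats::rnorm(200, 10.0, 0.5), 200, 1,
                 dimnames = list(NULL, "R"))
  })
  rec <- compare_groups(list(a = g1, b = g2))[[1]]
  expect_lt(rec$p_value, 0.05)
  expect_equal(as.character(rec$style_class), "not_significant")
  # applying the threshold on the bounded statistic is even stricter here
  rec2 <- compare_groups(list(a = g1, b = g2), fc_on_eq1 = TRUE)[[1]]
  expect_equal(as.character(rec2$style_class), "not_significant")
  # the same shift passes once the means differ by > 20%
  rec3 <- compare_groups(list(a = g1 + 3, b = g2))[[1]]
  expect_equal(as.character(rec3$style_class), "up")
})

test_that("sign-discordant significant reactions are classed as flips", {
  withr::with_seed(13, {
    g1 <- matrix(stats::rnorm(15, 4, 0.3), 15, 1, dimnames = list(NULL, "R"))
    g2 <- matrix(stats::rnorm(15, -4, 0.3), 15, 1, dimnames = list(NULL, "R"))
  })
  rec <- compare_groups(list(a = g1, b = g2))[[1]]
  expect_equal(as.character(rec$style_class), "sign_flip_up")
  rec2 <- compare_groups(list(b = g2, a = g1))[[1]]
  expect_equal(as.character(rec2$style_class), "sign_flip_down")
})

test_that("threshold monotonicity: relaxing gates never shrinks the significant set", {
  withr::with_seed(200, {
    rxns <- sprintf("R%d", 1:12)
    g1 <- matrix(stats::rnorm(15 * 12, 5, 1), 15, dimnames = list(NULL, rxns))
    g2 <- matrix(stats::rnorm(15 * 12, 5 * stats::runif(12, 0.5, 1.6), 1),
                 15, dimnames = list(NULL, rxns), byrow = TRUE)
  })
  sig_set <- function(p_thr, fc_thr) {
    rec <- compare_groups(list(a = g1, b = g2), p_threshold = p_thr,
                          fc_threshold = fc_thr)[[1]]
    rec$reaction_id[rec$style_class != "not_significant"]
  }
  s0 <- sig_set(0.05, 1.2)
  expect_true(all(s0 %in% sig_set(0.2, 1.2)))
  expect_true(all(s0 %in% sig_set(0.05, 1.05)))
  expect_true(all(sig_set(0.01, 1.5) %in% s0))
})

test_that("planted pathway effects are recovered end to end", {
  fx <- make_twogroup_fixture(n_samples_per_group = 25, effect_size = 3,
                              seed = 77)
  ras <- expression_to_ras(fx$model, fx$expression)
  bss <- build_sample_models(fx$model, normalize_ras(ras))
  fl <- t(vapply(names(bss), function(s) pfba(fx$model, bss[[s]])$fluxes,
                 numeric(nrow(fx$model$reactions))))
  cmp <- compare_groups(fl, fx$groups, mode = "one_vs_one")[["g1_vs_g2"]]
  got_sig <- cmp$reaction_id[cmp$style_class != "not_significant"]
  want_sig <- fx$flux_truth$reaction_id[fx$flux_truth$direction != "none"]
  expect_setequal(got_sig, want_sig)
  # directions match the construction: chain-1 forward up, uptake down
  for (i in seq_len(nrow(cmp))) {
    want <- fx$flux_truth$direction[fx$flux_truth$reaction_id ==
                                      cmp$reaction_id[i]]
    if (want == "up") expect_equal(as.character(cmp$style_class[i]), "up")
    if (want == "down") expect_equal(as.character(cmp$style_class[i]), "down")
  }
})

test_that("group files and comparison tables round-trip", {
  g <- c(s1 = "a", s2 = "a", s3 = "b")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_groups(g, f)
  expect_equal(read_groups(f), g)

  gf <- make_grouped(shift = 4, seed = 30)
  rec <- compare_groups(gf, mode = "one_vs_one")[[1]]
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_comparison(rec, f2)
  back <- utils::read.delim(f2)
  expect_equal(back$p_value, rec$p_value, tolerance = 1e-9)
  expect_equal(back$style_class, as.character(rec$style_class))
})
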