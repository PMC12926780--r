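toy_with_gprs <- function() {
  make_toy_model(2L, c(1L, 2L), 10,
                 gpr_assignment = list(P1_1 = "g1 and (g2 or g3)",
                                       P2_1 = "g4 or g5",
                                       P2_2 = "g1"))$model
}

test_that("exchange detection is structural: exactly one metabolite touched", {
  m <- chain_model()
  expect_setequal(exchange_reactions(m), c("EX_A", "EX_B"))
  # renaming does not change detection
  m2 <- m
  m2$reactions$id <- sub("EX_", "boundary", m2$reactions$id)
  colnames(m2$stoichiometry) <- m2$reactions$id
  expect_setequal(exchange_reactions(m2), c("boundaryA", "boundaryB"))
  expect_equal(unname(exchange_metabolites(m)["EX_A"]), "A[e]")
})

test_that("model invariants are enforced at construction", {
  m <- chain_model()
  bad <- m$reactions
  bad$lower_bound[2] <- 5000
  expect_error(metabolic_model(m$metabolites, bad, m$stoichiometry),
               "lower_bound > upper_bound.*P1_1")
  dup <- rbind(m$metabolites, m$metabolites[1, ])
  expect_error(metabolic_model(dup, m$reactions, m$stoichiometry),
               "duplicate metabolite")
})

test_that("models round-trip through every text format", {
  m <- toy_with_gprs()
  for (fmt in c("sbml", "json", "yaml", "tabular")) {
    ext <- switch(fmt, sbml = "xml", json = "json", yaml = "yml",
                  tabular = "tsv")
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    export_model(m, fmt, f)
    m2 <- import_model(f)
    expect_true(model_equivalent(m, m2), info = fmt)
    # second hop: export the re-import again (import o export is identity)
    f2 <- withr::local_tempfile(fileext = paste0(".", ext))
    export_model(m2, fmt, f2)
    expect_true(model_equivalent(m, import_model(f2)), info = fmt)
  }
})

test_that("compressed model files dispatch on the inner extension", {
  m <- toy_with_gprs()
  plain <- withr::local_tempfile(fileext = ".json")
  export_model(m, "json", plain)

  gz <- withr::local_tempfile(fileext = ".json.gz")
  con <- gzfile(gz, "w"); writeLines(readLines(plain), con); close(con)
  expect_true(model_equivalent(m, import_model(gz)))

  bz <- withr::local_tempfile(fileext = ".json.bz2")
  con <- bzfile(bz, "w"); writeLines(readLines(plain), con); close(con)
  expect_true(model_equivalent(m, import_model(bz)))

  zipf <- withr::local_tempfile(fileext = ".zip")
  write_stored_zip(zipf, basename(plain), readLines(plain))
  expect_true(model_equivalent(m, import_model(zipf)))
})

test_that("format errors are informative", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines("nonsense", f)
  expect_error(import_model(f), "\\.xyz")
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<html><body/></html>", f2)
  expect_error(import_model(f2), "not an SBML")
  f3 <- withr::local_tempfile(fileext = ".mat")
  writeLines("", f3)
  expect_error(import_model(f3), "not supported")
  expect_error(import_model(file.path(tempdir(), "nope.xml")), "not found")
})

test_that("SBML import accepts legacy notes GPRs; fbc wins when both present", {
  m <- toy_with_gprs()
  f <- withr::local_tempfile(fileext = ".xml")
  export_model(m, "sbml", f)
  doc <- readLines(f)
  # graft a conflicting legacy GPR note into P2_2 (fbc rule says "g1")
  i <- grep('name="P2_2"', doc)
  doc[i] <- sub(">$", paste0("><notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
                             "<p>GENE_ASSOCIATION: g9 or g8</p></body></notes>"),
                doc[i])
  writeLines(doc, f)
  m2 <- import_model(f)
  expect_equal(m2$reactions$gpr[m2$reactions$id == "P2_2"], "g1")

  # strip the fbc association entirely -> the notes rule is used
  drop <- grep("geneProductAssociation|geneProductRef|fbc:and|fbc:or", doc)
  block <- range(intersect(drop, (i - 1):(i + 20)))
  writeLines(doc[-(seq(block[1], block[2]))], f)
  m3 <- import_model(f)
  expect_equal(gpr_canonical(parse_gpr(m3$reactions$gpr[m3$reactions$id == "P2_2"])),
               "or(g8,g9)")
})

test_that("model_to_table flags the medium per the exchange/medium rules", {
  m <- chain_model()
  t0 <- model_to_table(m)
  expect_equal(t0$in_medium, c(TRUE, FALSE, FALSE))  # EX_A has lb < 0

  t1 <- model_to_table(m, medium = c("B[e]" = 5))
  expect_equal(t1$in_medium[t1$reaction_id == "EX_B"], TRUE)
  expect_equal(sum(t1$in_medium), 1L)

  t2 <- model_to_table(m, medium = stats::setNames(numeric(), character()))
  expect_false(any(t2$in_medium))
})

test_that("tabular export catches invalid rows by reaction name", {
  m <- chain_model()
  tab <- model_to_table(m)
  tab$lower_bound[tab$reaction_id == "P1_1"] <- 50
  tab$upper_bound[tab$reaction_id == "P1_1"] <- 2
  expect_error(table_to_model(tab), "P1_1")
  tab2 <- model_to_table(m)
  tab2$equation_string[2] <- "A[e] ~~> B[e]"
  expect_error(table_to_model(tab2), "P1_1")
})

test_that("equation strings preserve stoichiometric coefficients", {
  mets <- data.frame(id = c("A[c]", "B[c]", "C[c]"), compartment = "c")
  rxns <- data.frame(id = c("R1", "EX_A", "EX_C"),
                     lower_bound = c(-5, -10, 0),
                     upper_bound = c(5, 10, 10),
                     objective_coefficient = c(0, 0, 1))
  # rows A, B, C x cols R1 (A + 2B <=> 1.5C), EX_A, EX_C
  S <- matrix(c(-1, -1, 0,
                -2, 0, 0,
                1.5, 0, -1), 3, 3, byrow = TRUE,
              dimnames = list(mets$id, rxns$id))
  m <- metabolic_model(mets, rxns, S)
  tab <- model_to_table(m)
  expect_match(tab$equation_string[1], "A\\[c\\] \\+ 2 B\\[c\\] <=> 1.5 C\\[c\\]")
  expect_true(model_equivalent(m, table_to_model(tab)))
})
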