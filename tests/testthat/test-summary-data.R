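test_that("summary files round-trip through the canonical schema", {
  df <- data.frame(snp = c("rs1", "rs2", "rs3"),
                   effect_allele = c("A", "T", "C"),
                   other_allele = c("G", "C", "A"),
                   beta = c(0.1, -0.2, 0.05),
                   se = c(0.01, 0.02, 0.015),
                   pvalue = c(1e-10, 1e-8, 0.2),
                   eaf = c(0.1, 0.5, 0.9),
                   n = c(1000, 1000, 1000))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_gwas_summary(path, trait = "iron")
  expect_equal(nrow(rec), 3)
  for (col in names(df)) expect_equal(rec[[col]], df[[col]])
  expect_equal(unique(rec$trait), "iron")
})

test_that("validation rejects rows violating the schema invariants", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\teffect_allele\tother_allele\tbeta\tse",
               "rs1\tA\tG\t0.1\t0",
               "rs2\tA\tG\t0.1\t0.01"), path)
  expect_error(read_gwas_summary(path, trait = "x"),
               class = "validation_error")
  expect_error(read_gwas_summary(path, trait = "x"), "row")

  expect_error(assoc1("rs1", "A", "A", 0.1, 0.01), class = "validation_error")
  expect_error(association_table("rs1", "A", "G", 0.1, 0.01, pvalue = 1.2),
               class = "validation_error")
  expect_error(association_table("rs1", "A", "G", 0.1, 0.01, eaf = 1.0),
               class = "validation_error")
})

test_that("a column map reproduces the canonical-header parse", {
  canon <- withr::local_tempfile(fileext = ".tsv")
  alt <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(snp = c("rs10", "rs11"), effect_allele = c("A", "C"),
                   other_allele = c("G", "T"), beta = c(0.3, -0.1),
                   se = c(0.05, 0.04), pvalue = c(1e-9, 0.01),
                   eaf = c(0.2, 0.6), n = 500)
  write.table(df, canon, sep = "\t", quote = FALSE, row.names = FALSE)
  alt_df <- df
  names(alt_df) <- c("MarkerName", "Allele1", "Allele2", "Effect", "StdErr",
                     "P.value", "Freq1", "N")
  write.table(alt_df, alt, sep = ",", quote = FALSE, row.names = FALSE)
  map <- c(snp = "MarkerName", effect_allele = "Allele1",
           other_allele = "Allele2", beta = "Effect", se = "StdErr",
           pvalue = "P.value", eaf = "Freq1", n = "N")
  expect_identical(read_gwas_summary(alt, "x", column_map = map),
                   read_gwas_summary(canon, "x"))
  expect_error(read_gwas_summary(alt, "x"), class = "configuration_error")
})

test_that("strict selection recovers the three concordant genome-wide loci", {
  tabs <- fixture_biomarker_tables()
  strict <- select_instruments(tabs, mode = "strict")
  expect_setequal(strict$snp, c("rs1800562", "rs1799945", "rs855791"))
  # oriented to the iron-increasing allele: all iron betas positive,
  # all transferrin betas negative
  expect_true(all(strict$beta_iron > 0))
  expect_true(all(strict$beta_transferrin < 0))
  # rs855791 was stored with the iron-lowering allele as effect allele
  r <- strict[strict$snp == "rs855791", ]
  expect_equal(r$effect_allele, "G")
  expect_equal(r$beta_iron, 0.181)
  expect_equal(r$beta_transferrin, -0.046)
})

test_that("relaxed selection adds the three single-biomarker loci", {
  tabs <- fixture_biomarker_tables()
  relaxed <- select_instruments(tabs, mode = "relaxed")
  expect_setequal(relaxed$snp,
                  c("rs1800562", "rs1799945", "rs855791",
                    "rs9990333", "rs7385804", "rs411988"))
  # discordant loci are excluded in both modes, e.g. transferrin rising
  # with serum iron
  expect_false("rs174577" %in% relaxed$snp)
  expect_false("rs8177240" %in% relaxed$snp)
})

test_that("strict-mode output is always a subset of relaxed-mode output", {
  for (seed in 1:5) {
    tabs <- random_biomarker_tables(20, seed)
    strict <- select_instruments(tabs, mode = "strict", gw_threshold = 1e-3)
    relaxed <- select_instruments(tabs, mode = "relaxed", gw_threshold = 1e-3)
    expect_true(all(strict$snp %in% relaxed$snp))
  }
})

test_that("selection requires all four biomarker tables", {
  tabs <- fixture_biomarker_tables()
  expect_error(select_instruments(tabs[c("iron", "ferritin")]),
               class = "configuration_error")
})

test_that("harmonization keeps, flips and complements alleles correctly", {
  exp_rec <- assoc1("rs1", "A", "G", 0.2, 0.01)

  same <- harmonize(exp_rec, assoc1("rs1", "A", "G", 0.05, 0.02))
  expect_equal(same$beta_outcome, 0.05)
  expect_false(same$flipped)

  swapped <- harmonize(exp_rec, assoc1("rs1", "G", "A", 0.05, 0.02))
  expect_equal(swapped$beta_outcome, -0.05)
  expect_true(swapped$flipped)

  # strand complements: A/G on the other strand reads T/C
  comp <- harmonize(exp_rec, assoc1("rs1", "T", "C", 0.05, 0.02))
  expect_equal(comp$beta_outcome, 0.05)
  expect_false(comp$flipped)
  comp_sw <- harmonize(exp_rec, assoc1("rs1", "C", "T", 0.05, 0.02))
  expect_equal(comp_sw$beta_outcome, -0.05)
  expect_true(comp_sw$flipped)

  expect_error(harmonize(exp_rec, assoc1("rs1", "A", "C", 0.05, 0.02)),
               class = "harmonization_error")
})

test_that("palindrome frequency policy follows its decision table", {
  pal_exp <- function(eaf) assoc1("rs9", "A", "T", 0.2, 0.01, eaf = eaf)
  pal_out <- function(eaf) assoc1("rs9", "A", "T", 0.05, 0.02, eaf = eaf)

  # both clearly minor: orientation kept
  kept <- harmonize(pal_exp(0.10), pal_out(0.12))
  expect_equal(kept$beta_outcome, 0.05)
  expect_false(kept$flipped)
  # both clearly major: kept as well
  expect_false(is.null(harmonize(pal_exp(0.90), pal_out(0.88))))
  # straddling or inside the ambiguity band: dropped with a warning
  for (pair in list(c(0.10, 0.88), c(0.45, 0.45), c(0.10, 0.50),
                    c(0.41, 0.43))) {
    expect_warning(res <- harmonize(pal_exp(pair[1]), pal_out(pair[2])),
                   "dropped")
    expect_null(res)
  }
  # missing frequency: dropped, never guessed
  expect_warning(res <- harmonize(pal_exp(NA_real_), pal_out(0.1)), "dropped")
  expect_null(res)
  # drop policy drops even unambiguous pairs
  expect_warning(
    res <- harmonize(pal_exp(0.1), pal_out(0.1), palindrome_policy = "drop"),
    "dropped")
  expect_null(res)
})

test_that("harmonization is idempotent and neutral to double label flips", {
  exp_rec <- assoc1("rs2", "T", "G", 0.31, 0.012, eaf = 0.2)
  out_rec <- assoc1("rs2", "G", "T", -0.04, 0.03, eaf = 0.75)
  h1 <- harmonize(exp_rec, out_rec)

  # idempotence: re-harmonizing the already-aligned pair changes nothing
  aligned_out <- assoc1("rs2", "T", "G", h1$beta_outcome, h1$se_outcome,
                        eaf = 0.25)
  h2 <- harmonize(exp_rec, aligned_out)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$beta_exposure, h1$beta_exposure)

  # double flip: relabelling both studies' alleles with negated betas
  exp_flip <- assoc1("rs2", "G", "T", -0.31, 0.012, eaf = 0.8)
  out_flip <- assoc1("rs2", "T", "G", 0.04, 0.03, eaf = 0.25)
  h3 <- harmonize(exp_flip, out_flip)
  expect_equal(h3$beta_outcome / h3$beta_exposure,
               h1$beta_outcome / h1$beta_exposure)
})

test_that("proxy search honours the strict r2 bound and breaks ties stably", {
  cand <- association_table(
    snp = c("rsB", "rsA", "rsC"), effect_allele = "A", other_allele = "G",
    beta = c(0.1, 0.2, 0.3), se = 0.01, trait = "stroke")
  ld <- data.frame(snp_a = c("rsT", "rsT", "rsC"),
                   snp_b = c("rsB", "rsA", "rsT"),
                   r2 = c(0.9, 0.5, 0.4))

  expect_message(hit <- find_proxy("rsT", cand, ld), "rsB")
  expect_equal(hit$snp, "rsB")

  # exactly at the bound: strictly-greater is required
  ld_edge <- data.frame(snp_a = "rsT", snp_b = "rsB", r2 = 0.3)
  expect_message(expect_null(find_proxy("rsT", cand, ld_edge)), "no proxy")

  # ties resolved to the lexicographically smallest rsID, whatever the
  # input order of candidates or LD rows
  ld_tie <- data.frame(snp_a = "rsT", snp_b = c("rsC", "rsA", "rsB"),
                       r2 = 0.8)
  set.seed(99)
  for (i in 1:5) {
    perm <- sample(nrow(cand))
    permld <- sample(nrow(ld_tie))
    suppressMessages(
      hit <- find_proxy("rsT", cand[perm, ], ld_tie[permld, ]))
    expect_equal(hit$snp, "rsA")
  }
})
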