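test_that("generated cohort has the configured size and group structure", {
  cfg <- cohort_config(n_cases = 990, n_controls = 1094, seed = 11)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort$phenotypes), 2084)
  expect_equal(as.integer(table(cohort$phenotypes$status)[c("case", "control")]),
               c(990L, 1094L))
  expect_true(all(cohort$variants$subject_id %in%
                    cohort$phenotypes$subject_id |
                    grepl("^S", cohort$variants$subject_id)))
  # controls carry no receptor data; cases are partially typed
  ctrl <- cohort$phenotypes[cohort$phenotypes$status == "control", ]
  expect_true(all(is.na(ctrl$er) & is.na(ctrl$pr) & is.na(ctrl$her2)))
  cases <- cohort$phenotypes[cohort$phenotypes$status == "case", ]
  expect_gt(sum(!is.na(cases$er)), 0)
  # ages live inside the banded range
  expect_true(all(cohort$phenotypes$age_years >= 25 &
                    cohort$phenotypes$age_years <= 75))
})

test_that("identical seeds give identical tables and different seeds differ", {
  cfg1 <- cohort_config(n_cases = 120, n_controls = 140, seed = 5)
  a <- generate_cohort(cfg1)
  b <- generate_cohort(cfg1)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$variants, b$variants)
  expect_identical(a$carriers, b$carriers)
  c3 <- generate_cohort(cohort_config(n_cases = 120, n_controls = 140,
                                      seed = 6))
  expect_false(identical(a$carriers, c3$carriers) &&
                 identical(a$phenotypes, c3$phenotypes))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(n_cases = 0, seed = 1), "n_cases")
  expect_error(cohort_config(fh_prob_cases = 1.4, seed = 1), "fh_prob_cases")
  expect_error(gene_spec("G", carrier_freq_controls = 1), "carrier_freq")
  expect_error(gene_spec("G", 0.01, founder_fraction = -0.2),
               "founder_fraction")
  expect_error(cohort_config(seed = 1, genes = list(
    gene_spec("A", 0.01), gene_spec("A", 0.02)
  )), "duplicated")
  # age-varying effects require the model-age mode
  expect_error(
    cohort_config(seed = 1, genes = list(
      gene_spec("A", 0.01, log_or_age = log(0.94))
    )),
    "age_mode"
  )
  expect_error(cohort_config(seed = 1)$genes, NA)
})

test_that("null genes show symmetric carrier frequencies in cases and controls", {
  cfg <- cohort_config(
    n_cases = 5000, n_controls = 5000,
    genes = list(gene_spec("NULLG", 0.02, log_or = 0)),
    decoys = FALSE, seed = 21
  )
  cohort <- generate_cohort(cfg)
  ph <- cohort$phenotypes
  carr <- cohort$carriers$NULLG
  p_case <- mean(carr[ph$status == "case"])
  p_ctrl <- mean(carr[ph$status == "control"])
  se <- sqrt(0.02 * 0.98 * (1 / 5000 + 1 / 5000))
  expect_lt(abs(p_case - p_ctrl), 3 * se)
})

test_that("configured marginals are recovered at large n", {
  cfg <- cohort_config(
    n_cases = 25000, n_controls = 25000,
    genes = list(gene_spec("G1", 0.01, log_or = log(3))),
    decoys = FALSE, seed = 31
  )
  cohort <- generate_cohort(cfg)
  ph <- cohort$phenotypes
  is_ctrl <- ph$status == "control"
  # family-history marginal among controls
  fh_ctrl <- mean(ph$family_history[is_ctrl], na.rm = TRUE)
  se_fh <- sqrt(cfg$fh_prob_controls * (1 - cfg$fh_prob_controls) / 25000)
  expect_lt(abs(fh_ctrl - cfg$fh_prob_controls), 3 * se_fh)
  # control carrier frequency matches the configured value
  p_ctrl <- mean(cohort$carriers$G1[is_ctrl])
  se_g <- sqrt(0.01 * 0.99 / 25000)
  expect_lt(abs(p_ctrl - 0.01), 3 * se_g)
})

test_that("variant tables exercise every classification rule", {
  cohort <- generate_cohort(cohort_config(n_cases = 400, n_controls = 400,
                                          seed = 41))
  cl <- classify_variants(cohort$variants)
  reasons <- unique(cl$exclusion_reason[!is.na(cl$exclusion_reason)])
  expect_setequal(
    reasons,
    c("gene_excluded", "consequence_out_of_scope", "last_exon",
      "penultimate_splice", "uncertain_splice", "benign", "common")
  )
  expect_true(any(cl$category == "PTV"))
  expect_true(any(cl$category == "RARE_MISSENSE"))
})

test_that("founder fraction concentrates carriers on one designated variant", {
  cfg <- cohort_config(
    n_cases = 3000, n_controls = 3000,
    genes = list(gene_spec("BRCA2", 0.01, log_or = log(5),
                           founder_fraction = 0.55, n_exons = 27)),
    decoys = FALSE, seed = 51
  )
  cohort <- generate_cohort(cfg)
  ptv <- cohort$variants[grepl("BRCA2", cohort$variants$gene), ]
  share <- mean(ptv$variant_id == "BRCA2:founder")
  expect_gt(share, 0.4)
  expect_lt(share, 0.7)
  expect_true(all(ptv$hgvs_c[ptv$variant_id == "BRCA2:founder"] ==
                    "c.8756delG"))
})

test_that("incidence presets have the stated shape", {
  inc <- generate_incidence_table("constant", scale = 0.001, age_max = 80)
  expect_equal(nrow(inc), 16)
  expect_true(all(inc$rate_per_py == 0.001))
  expect_equal(inc$age_start[1], 0)
  expect_equal(inc$age_end[16], 80)

  bc <- generate_incidence_table("bc_like")
  cum_risk <- 1 - exp(-sum(bc$rate_per_py * (bc$age_end - bc$age_start)))
  expect_gt(cum_risk, 0.05)
  expect_lt(cum_risk, 0.15)

  expect_error(generate_incidence_table("constant", scale = 0), "scale")
  expect_error(generate_incidence_table("constant", scale = -1), "scale")
})

test_that("cohort tables round-trip through disk", {
  cohort <- generate_cohort(cohort_config(n_cases = 60, n_controls = 60,
                                          seed = 61))
  dm <- generate_domain_map(cohort$config$genes)
  dir <- withr::local_tempdir()
  paths <- write_cohort(cohort, dir, domain_map = dm)
  ph <- read_phenotypes(paths[["phenotypes"]])
  expect_equal(nrow(ph), 120)
  v <- read_variants(paths[["variants"]])
  expect_equal(nrow(v), nrow(cohort$variants))
  expect_equal(v$variant_id, cohort$variants$variant_id)
  dm2 <- read_domain_map(file.path(dir, "domains.tsv"))
  expect_equal(dm2$domain, dm$domain)
})
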