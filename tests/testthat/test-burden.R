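test_that("carrier indicators collapse multiplicity and zygosity to 0/1", {
  ph <- tibble::tibble(subject_id = c("A", "B", "C"),
                       status = c("case", "case", "control"))
  cl <- tibble::tibble(
    subject_id = c("A", "A", "B"), gene = "BRCA2",
    variant_id = c("v1", "v2", "v1"),
    category = "PTV", exclusion_reason = NA_character_,
    domain = NA_character_, zygosity = c("het", "het", "hom")
  )
  cm <- build_carrier_matrix(cl, ph, "PTV")
  expect_equal(cm$BRCA2, c(1L, 1L, 0L))  # two variants still score 1; hom == het
  expect_equal(cm$subject_id, ph$subject_id)
})

test_that("orphan subject ids are rejected with their ids listed", {
  ph <- tibble::tibble(subject_id = "A", status = "case")
  cl <- tibble::tibble(subject_id = c("A", "GHOST"), gene = "ATM",
                       variant_id = c("v1", "v2"), category = "PTV",
                       exclusion_reason = NA_character_,
                       domain = NA_character_)
  expect_error(build_carrier_matrix(cl, ph, "PTV"), "GHOST")
})

test_that("the published carrier-count fixture reproduces the printed prevalences", {
  fx <- published_counts_fixture()
  ph <- fx$phenotypes
  cm <- fx$cm
  # per-gene column sums by status
  is_case <- ph$status == "case"
  expect_equal(sum(cm$BRCA2[is_case]), 18)
  expect_equal(sum(cm$BRCA2[!is_case]), 1)
  expect_equal(sum(cm$ATM[is_case]), 9)

  prev <- tabulate_prevalence(cm, ph, classified = fx$classified)
  est <- prev[prev$unit == "established", ]
  expect_equal(est$n_case_carriers, 35)
  expect_equal(round(est$case_prevalence, 2), 3.54)
  expect_equal(est$n_control_carriers, 4)
  expect_equal(round(est$control_prevalence, 2), 0.37)
  tot <- prev[prev$unit == "any_unit", ]
  expect_equal(tot$n_case_carriers, 45)
  expect_equal(round(tot$case_prevalence, 2), 4.55)
  expect_equal(tot$n_control_carriers, 16)
  expect_equal(round(tot$control_prevalence, 2), 1.46)
  # unique variant count for BRCA2 (founder + 5 others)
  expect_equal(prev$n_variants[prev$unit == "BRCA2"], 6)
})

test_that("founder breakdown reports prevalence and carrier share", {
  fx <- published_counts_fixture()
  fb <- founder_breakdown(fx$classified, fx$phenotypes,
                          "BRCA2", "BRCA2:c.8756delG")
  expect_equal(fb$n_case_founder, 10)
  expect_equal(round(fb$case_prevalence, 2), 1.01)
  expect_equal(round(fb$share_of_case_carriers, 2), 55.56)
  expect_equal(fb$n_control_founder, 1)
  expect_equal(round(fb$share_of_control_carriers, 2), 100)
})

test_that("aggregate carrier counts never exceed the member-gene sum", {
  cohort <- generate_cohort(cohort_config(n_cases = 500, n_controls = 500,
                                          seed = 71))
  cl <- classify_variants(cohort$variants)
  cm <- build_carrier_matrix(cl, cohort$phenotypes, "PTV")
  prev <- tabulate_prevalence(cm, cohort$phenotypes)
  units <- setdiff(prev$unit, c("established", "any_unit"))
  est_members <- intersect(units, established_genes())
  est_row <- prev[prev$unit == "established", ]
  member_sum <- sum(prev$n_case_carriers[prev$unit %in% est_members])
  expect_lte(est_row$n_case_carriers, member_sum)
  # percentages recompute exactly from stored counts
  expect_equal(prev$case_prevalence,
               100 * prev$n_case_carriers / 500)
})

test_that("stratification reproduces the study's partition sizes", {
  fx <- published_counts_fixture()
  cases <- fx$phenotypes[fx$phenotypes$status == "case", ]
  fh <- stratify(cases, "family_history")
  expect_length(fh$fh_yes, 158)
  expect_length(fh$fh_no, 815)
  expect_length(attr(fh, "dropped"), 17)

  sub <- stratify(cases, "subtype")
  expect_length(sub$fully_typed, 576)
  expect_length(sub$triple_negative, 66)
  expect_equal(round(100 * length(sub$triple_negative) /
                       length(sub$fully_typed), 1), 11.5)
  expect_length(sub$er_pos, 628 - 66)  # fixture: all typed non-TN are ER+
})

test_that("age dichotomy at 50 is exhaustive and boundary-configurable", {
  ph <- tibble::tibble(subject_id = as.character(1:5), status = "case",
                       age_years = c(30, 49.9, 50, 50.1, 70))
  parts <- stratify(ph, "age_cut", cut = 50)
  expect_equal(sort(c(parts$age_lt_50, parts$age_ge_50)),
               sort(ph$subject_id))
  expect_true("3" %in% parts$age_ge_50)
  left <- stratify(ph, "age_cut", cut = 50, boundary = "left")
  expect_true("3" %in% left$age_lt_50)
  expect_error(stratify(ph, "histology"))
})

test_that("location comparison matches small-sample hand computations", {
  # identical groups: rank-sum p of 1
  r <- compare_group_location(c(1, 2, 3), c(1, 2, 3), "rank_sum")
  expect_equal(r$p_value, 1, tolerance = 1e-9)
  # n=2 vs n=2 fully separated: W = 0, exact p = 2 * (1 / choose(4,2))
  r <- compare_group_location(c(1, 2), c(3, 4), "rank_sum")
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 2 / choose(4, 2), tolerance = 1e-9)
  # large shift is detected by both tests
  x <- withr::with_seed(3, rnorm(200, 50, 9))
  r1 <- compare_group_location(x, x + 10, "rank_sum")
  r2 <- compare_group_location(x, x + 10, "t_test")
  expect_lt(r1$p_value, 1e-3)
  expect_lt(r2$p_value, 1e-3)
  expect_equal(r2$mean_y - r2$mean_x, 10)
  expect_error(compare_group_location(1, c(1, 2), "t_test"), "at least 2")
  expect_error(compare_group_location(numeric(0), 1:3), "nonempty")
})

test_that("proportion comparison matches exact hypergeometric behaviour", {
  expect_equal(compare_two_proportions(5, 10, 5, 10)$p_value, 1)
  # 0/10 vs 10/10 is as extreme as a 2x2 gets
  expect_lt(compare_two_proportions(0, 10, 10, 10)$p_value, 1e-3)
  # the study's family-history contrast is significant under a supported test
  p_fisher <- compare_two_proportions(13, 158, 29, 815)$p_value
  p_chisq <- compare_two_proportions(13, 158, 29, 815, "chisq")$p_value
  expect_lte(min(p_fisher, p_chisq), 0.05)
  expect_error(compare_two_proportions(11, 10, 1, 10), "k <= n")
})
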