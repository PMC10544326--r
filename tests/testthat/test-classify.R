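vrow <- function(gene = "CHEK2", consequence = "nonsynonymous_SNV",
                 exon_index = 4L, n_exons = 15L, af = 5e-4,
                 clinical_class = "vus", hgvs_c = "c.100A>G",
                 protein_pos = 150L) {
  tibble::tibble(
    subject_id = "S1", gene = gene, variant_id = paste0(gene, ":x"),
    hgvs_c = hgvs_c, consequence = consequence,
    exon_index = exon_index, n_exons = n_exons, af_gnomad_nfe = af,
    clinical_class = clinical_class, protein_pos = protein_pos,
    zygosity = "het"
  )
}

cat1 <- function(v) {
  cl <- classify_variants(v)
  list(category = cl$category[1], reason = cl$exclusion_reason[1],
       af_unknown = cl$af_unknown[1])
}

test_that("the rule list classifies each archetype correctly", {
  # named uncertain BRCA1 splice variant
  r <- cat1(vrow("BRCA1", "splicing", 9L, 23L, NA, "vus", "c.594-2A>C"))
  expect_equal(r$category, "EXCLUDED")
  expect_equal(r$reason, "uncertain_splice")
  # penultimate-exon splice in an exception gene is retained as PTV
  r <- cat1(vrow("PALB2", "splicing", 12L, 13L, NA, "unclassified"))
  expect_equal(r$category, "PTV")
  # ... but excluded in a non-exception gene
  r <- cat1(vrow("BRCA2", "splicing", 26L, 27L, NA, "unclassified"))
  expect_equal(r$reason, "penultimate_splice")
  # last-exon PTVs of any flavour are excluded
  r <- cat1(vrow("CHEK2", "stopgain", 15L, 15L, NA, "pathogenic"))
  expect_equal(r$reason, "last_exon")
  r <- cat1(vrow("PALB2", "splicing", 13L, 13L, NA, "unclassified"))
  expect_equal(r$reason, "last_exon")
  # rare missense kept, common excluded; the threshold is >= 0.001
  expect_equal(cat1(vrow(af = 5e-4))$category, "RARE_MISSENSE")
  expect_equal(cat1(vrow(af = 2e-3))$reason, "common")
  expect_equal(cat1(vrow(af = 1e-3))$reason, "common")
  expect_equal(cat1(vrow(af = 0.000999))$category, "RARE_MISSENSE")
  # (likely) benign missense removed even when rare
  expect_equal(cat1(vrow(af = 1e-5, clinical_class = "likely_benign"))$reason,
               "benign")
  expect_equal(cat1(vrow(af = 1e-5, clinical_class = "benign"))$reason,
               "benign")
  # excluded gene trumps everything
  expect_equal(cat1(vrow("PPM1D", "stopgain", 3L, 6L))$reason, "gene_excluded")
  # out-of-scope consequences
  for (cons in c("nonframeshift_deletion", "intronic", "UTR5", "UTR3",
                 "synonymous_SNV")) {
    expect_equal(cat1(vrow(consequence = cons))$reason,
                 "consequence_out_of_scope")
  }
  # unknown-AF missense kept but flagged
  r <- cat1(vrow(af = NA))
  expect_equal(r$category, "RARE_MISSENSE")
  expect_true(r$af_unknown)
  # interior frameshift is a PTV
  expect_equal(cat1(vrow("ATM", "frameshift_deletion", 10L, 63L))$category,
               "PTV")
})

test_that("unknown vocabulary and missing exon information are errors", {
  expect_error(classify_variants(vrow(consequence = "missense_variant")),
               "missense_variant")
  expect_error(
    classify_variants(vrow("ATM", "stopgain", NA_integer_, 63L)),
    "exon_index"
  )
})

test_that("classification partitions rows and is order-independent", {
  v <- random_variant_fixture(n = 200L, seed = 7L)
  cl <- classify_variants(v)
  expect_equal(nrow(cl), 200L)
  expect_equal(sum(cl$category == "PTV") +
                 sum(cl$category == "RARE_MISSENSE") +
                 sum(cl$category == "EXCLUDED"), 200L)
  expect_true(all(is.na(cl$exclusion_reason) == (cl$category != "EXCLUDED")))
  # shuffling rows permutes the classification identically
  perm <- withr::with_seed(1, sample.int(200L))
  cl2 <- classify_variants(v[perm, ])
  expect_equal(cl2$category, cl$category[perm])
  expect_equal(cl2$exclusion_reason, cl$exclusion_reason[perm])
})

test_that("classification agrees with the independent rule oracle on every row", {
  v <- random_variant_fixture(n = 200L, seed = 13L)
  cl <- classify_variants(v)
  for (i in seq_len(nrow(v))) {
    expected <- oracle_classify_row(v$gene[i], v$consequence[i],
                                    v$exon_index[i], v$n_exons[i],
                                    v$af_gnomad_nfe[i], v$clinical_class[i],
                                    v$hgvs_c[i])
    expect_equal(cl$category[i], expected[1],
                 info = sprintf("row %d (%s %s)", i, v$gene[i],
                                v$consequence[i]))
    expect_equal(cl$exclusion_reason[i], unname(expected[2]),
                 info = sprintf("row %d reason", i))
  }
})

test_that("domain assignment uses inclusive 1-based bounds", {
  dm <- tibble::tibble(
    gene = c("PALB2", "PALB2"), domain = c("ChAM", "WD1"),
    residue_start = c(100L, 850L), residue_end = c(130L, 1186L)
  )
  mk <- function(pos) {
    classify_variants(vrow("PALB2", protein_pos = pos, af = 1e-5))
  }
  expect_equal(assign_domains(mk(900L), dm)$domain, "WD1")
  expect_equal(assign_domains(mk(100L), dm)$domain, "ChAM")  # start inclusive
  expect_equal(assign_domains(mk(130L), dm)$domain, "ChAM")  # end inclusive
  expect_true(is.na(assign_domains(mk(500L), dm)$domain))    # outside all
  # PTVs pass through unchanged
  ptv <- classify_variants(vrow("PALB2", "stopgain", 5L, 13L))
  expect_identical(assign_domains(ptv, dm), ptv)
})

test_that("overlapping domain intervals are rejected at load time", {
  bad <- tibble::tibble(
    gene = "ATM", domain = c("A", "B"),
    residue_start = c(10L, 50L), residue_end = c(60L, 90L)
  )
  expect_error(validate_domain_map(bad), "overlap")
  expect_error(assign_domains(classify_variants(vrow()), bad), "overlap")
  ok <- tibble::tibble(
    gene = c("ATM", "ATM", "BRCA1"), domain = c("A", "B", "A"),
    residue_start = c(10L, 61L, 40L), residue_end = c(60L, 90L, 80L)
  )
  expect_silent(validate_domain_map(ok))
})

test_that("rare pathogenic missense stays in the rare-missense scan set", {
  r <- cat1(vrow(af = 1e-5, clinical_class = "pathogenic"))
  expect_equal(r$category, "RARE_MISSENSE")
})
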