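# Fixtures built in code: a carrier/phenotype fixture reproducing the
# published per-gene carrier counts of the emulated study, and a randomized
# variant fixture exercising every classification rule.

# Per-gene PTV carrier counts (cases of 990, controls of 1094)
PUBLISHED_CASE_PTV_COUNTS <- c(
  ATM = 9, BRCA1 = 3, BRCA2 = 18, PALB2 = 5, ABRAXAS1 = 1,
  FANCC = 3, MUTYH = 1, RAD50 = 4, RECQL = 1
)
PUBLISHED_CONTROL_PTV_COUNTS <- c(
  ATM = 1, BRCA1 = 1, BRCA2 = 1, CHEK2 = 1, CDH1 = 1, FANCM = 1,
  GEN1 = 1, MRE11 = 1, MUTYH = 1, RAD50 = 1, RINT1 = 1, RECQL = 3, FANCC = 2
)

published_counts_fixture <- function() {
  n_cases <- 990L
  n_controls <- 1094L
  case_ids <- sprintf("CASE%04d", seq_len(n_cases))
  ctrl_ids <- sprintf("CTRL%04d", seq_len(n_controls))

  # disjoint carrier assignment: consecutive case/control indices per gene
  genes <- union(names(PUBLISHED_CASE_PTV_COUNTS), names(PUBLISHED_CONTROL_PTV_COUNTS))
  case_carr <- list()
  i <- 1L
  for (g in names(PUBLISHED_CASE_PTV_COUNTS)) {
    k <- PUBLISHED_CASE_PTV_COUNTS[[g]]
    case_carr[[g]] <- case_ids[i:(i + k - 1L)]
    i <- i + k
  }
  ctrl_carr <- list()
  i <- 1L
  for (g in names(PUBLISHED_CONTROL_PTV_COUNTS)) {
    k <- PUBLISHED_CONTROL_PTV_COUNTS[[g]]
    ctrl_carr[[g]] <- ctrl_ids[i:(i + k - 1L)]
    i <- i + k
  }

  ind <- tibble::tibble(subject_id = c(case_ids, ctrl_ids))
  for (g in genes) {
    ind[[g]] <- as.integer(ind$subject_id %in% c(case_carr[[g]],
                                                 ctrl_carr[[g]]))
  }
  cm <- as_carrier_matrix(ind, category = "PTV")

  all_case_carriers <- unlist(case_carr, use.names = FALSE)  # 45 subjects

  # family history: 158/973 observed-yes cases (13 carriers among them),
  # 29 carrier cases FH-no, 3 carrier cases FH missing; 14 more cases
  # missing FH; controls 87/1091 yes, 3 missing
  fh_case <- rep(0L, n_cases)
  names(fh_case) <- case_ids
  fh_case[all_case_carriers[1:13]] <- 1L
  fh_case[all_case_carriers[43:45]] <- NA_integer_
  noncarr <- setdiff(case_ids, all_case_carriers)
  fh_case[noncarr[1:145]] <- 1L            # 13 + 145 = 158 FH-yes
  fh_case[noncarr[146:159]] <- NA_integer_ # 3 + 14 = 17 missing
  fh_ctrl <- rep(0L, n_controls)
  fh_ctrl[1:87] <- 1L
  fh_ctrl[1088:1090] <- NA_integer_

  # receptors: cases 1..576 fully typed (1..66 triple-negative), cases
  # 577..628 ER-typed only, the rest untyped
  er <- pr <- her2 <- rep(NA_character_, n_cases)
  er[1:66] <- "neg"; pr[1:66] <- "neg"; her2[1:66] <- "neg"
  er[67:576] <- "pos"; pr[67:576] <- "pos"; her2[67:576] <- "neg"
  er[577:628] <- "pos"

  phenotypes <- tibble::tibble(
    subject_id = c(case_ids, ctrl_ids),
    status = rep(c("case", "control"), c(n_cases, n_controls)),
    age_years = 50,
    family_history = c(unname(fh_case), fh_ctrl),
    er = c(er, rep(NA_character_, n_controls)),
    pr = c(pr, rep(NA_character_, n_controls)),
    her2 = c(her2, rep(NA_character_, n_controls))
  )

  # classified variant rows, one per carrier; BRCA2 has 6 unique variants,
  # 10 case carriers and the single control carrier share the founder
  classified <- list()
  for (g in genes) {
    subs <- c(case_carr[[g]], ctrl_carr[[g]])
    vid <- if (g == "BRCA2") {
      c(rep("BRCA2:c.8756delG", 10),
        paste0("BRCA2:v", c(1, 1, 2, 2, 3, 4, 5, 5)),
        "BRCA2:c.8756delG")
    } else {
      paste0(g, ":v", seq_along(subs))
    }
    classified[[g]] <- tibble::tibble(
      subject_id = subs, gene = g, variant_id = vid,
      category = "PTV", exclusion_reason = NA_character_,
      domain = NA_character_
    )
  }
  classified <- dplyr::bind_rows(classified)

  list(phenotypes = phenotypes, cm = cm, classified = classified)
}

# Missense carrier fixture reproducing the study's aggregate missense
# prevalences: 195/990 cases and 188/1094 controls carry a rare missense
# variant in an established gene; 499 and 457 in any panel gene.
missense_fixture <- function() {
  n_cases <- 990L
  n_controls <- 1094L
  case_ids <- sprintf("CASE%04d", seq_len(n_cases))
  ctrl_ids <- sprintf("CTRL%04d", seq_len(n_controls))
  ind <- tibble::tibble(subject_id = c(case_ids, ctrl_ids))
  ind$BRCA1 <- as.integer(ind$subject_id %in% c(case_ids[1:195],
                                                ctrl_ids[1:188]))
  ind$FANCM <- as.integer(ind$subject_id %in% c(case_ids[196:499],
                                                ctrl_ids[189:457]))
  phenotypes <- tibble::tibble(
    subject_id = c(case_ids, ctrl_ids),
    status = rep(c("case", "control"), c(n_cases, n_controls))
  )
  list(cm = as_carrier_matrix(ind, category = "RARE_MISSENSE"),
       phenotypes = phenotypes)
}

# One variant-table row with explicit rule-relevant fields.
vrow_acc <- function(gene, consequence, exon_index, n_exons, af,
                     clinical_class, hgvs_c = "c.1A>G",
                     protein_pos = 100L) {
  tibble::tibble(
    subject_id = "SX", gene = gene,
    variant_id = paste0(gene, ":", hgvs_c),
    hgvs_c = hgvs_c, consequence = consequence,
    exon_index = exon_index, n_exons = n_exons, af_gnomad_nfe = af,
    clinical_class = clinical_class, protein_pos = protein_pos,
    zygosity = "het"
  )
}

# Randomized 200-row variant fixture exercising every classification rule.
random_variant_fixture <- function(n = 200L, seed = 7L) {
  withr::with_seed(seed, {
    genes <- c("ATM", "BARD1", "BRCA1", "BRCA2", "CHEK2", "PALB2", "RAD51C",
               "RAD51D", "TP53", "CDH1", "FANCC", "PPM1D")
    cons <- c("stopgain", "frameshift_insertion", "frameshift_deletion",
              "splicing", "nonsynonymous_SNV", "nonframeshift_insertion",
              "nonframeshift_deletion", "intronic", "UTR5", "UTR3",
              "synonymous_SNV")
    n_exons <- sample(c(10L, 15L, 23L, 27L), n, replace = TRUE)
    v <- tibble::tibble(
      subject_id = sprintf("S%03d", sample.int(80L, n, replace = TRUE)),
      gene = sample(genes, n, replace = TRUE),
      variant_id = sprintf("v%03d", seq_len(n)),
      hgvs_c = sprintf("c.%dA>G", seq_len(n)),
      consequence = sample(cons, n, replace = TRUE,
                           prob = c(rep(2, 4), 6, rep(1, 6))),
      exon_index = NA_integer_,
      n_exons = n_exons,
      af_gnomad_nfe = sample(c(NA, 0, 1e-5, 5e-4, 0.001, 0.002, 0.01),
                             n, replace = TRUE),
      clinical_class = sample(c("pathogenic", "likely_pathogenic", "vus",
                                "likely_benign", "benign", "unclassified"),
                              n, replace = TRUE),
      protein_pos = sample.int(1000L, n, replace = TRUE),
      zygosity = sample(c("het", "hom"), n, replace = TRUE, prob = c(0.97, 0.03))
    )
    # exon positions hitting boundary cases: last, penultimate, interior
    v$exon_index <- pmax(1L, v$n_exons - sample(0:5, n, replace = TRUE))
    # sprinkle the named uncertain BRCA1 splice variants
    six <- c("c.594-2A>C", "c.4096+1G>A", "c.4096+2T>C", "c.4186-2A>G",
             "c.4358-1G>C", "c.4358-2del")
    idx <- sample.int(n, 12L)
    v$gene[idx] <- "BRCA1"
    v$consequence[idx] <- "splicing"
    v$hgvs_c[idx] <- sample(six, 12L, replace = TRUE)
    v$exon_index[idx] <- pmin(v$exon_index[idx], v$n_exons[idx] - 2L)
    v
  })
}
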