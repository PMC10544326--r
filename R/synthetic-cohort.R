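## Synthetic case-control cohort generator.
##
## Emulates the design of a population-based breast cancer case-control panel
## study: a source population with per-gene carrier indicators and a logistic
## disease model, from which fixed numbers of cases and controls are sampled
## (retrospective design, so logistic odds ratios are the estimand). Marginal
## structure (age bands, family history, receptor status and its missingness)
## follows the study population the package emulates by default.

# Age bands used for the banded age distributions: [25,30), [30,40), [40,50),
# [50,60), [60,75). Probabilities default to the emulated study's case and
# control age tables.
AGE_BAND_START <- c(25, 30, 40, 50, 60)
AGE_BAND_END <- c(30, 40, 50, 60, 75)
AGE_PROBS_CASES <- c(5, 87, 349, 344, 205) / 990
AGE_PROBS_CONTROLS <- c(2, 8, 178, 566, 337) / 1091

# Receptor-status model for cases (controls are never typed). ER is drawn
# first; PR and HER2 are drawn conditionally on ER so that the marginal
# positivity rates and the triple-negative fraction approximate the emulated
# study (ER+ 75.8%, PR+ 61.6%, HER2+ 16.1%, TN ~11.5%).
RECEPTOR_DEFAULTS <- list(
  er_obs = 628 / 990, pr_obs = 619 / 990, her2_obs = 584 / 990,
  er_pos = 476 / 628,
  pr_pos_er_pos = 0.78, pr_pos_er_neg = 0.10,
  her2_pos_er_pos = 0.085, her2_pos_er_neg = 0.40
)

#' Per-gene simulation specification
#'
#' Describes one gene's contribution to the synthetic cohort: the control
#' carrier frequency of qualifying protein-truncating variants (PTVs), the
#' log odds ratio on disease, an optional ER-negative-specific effect, an
#' optional per-year change of the log odds ratio with age, and a founder
#' fraction (the share of PTV carriers who all carry one designated founder
#' variant, emulating founder effects such as BRCA2 c.8756delG).
#'
#' @param gene Gene symbol.
#' @param carrier_freq_controls PTV carrier frequency among non-diseased
#'   subjects, in `[0, 1)`.
#' @param log_or Log odds ratio of disease for PTV carriers.
#' @param subtype_log_or Optional ER-negative-specific log odds ratio; when
#'   supplied, carriers' tumours are shifted towards ER-negative disease so
#'   that the ER-negative-specific effect equals this value.
#' @param log_or_age Per-year change in the carrier log odds ratio, centred
#'   at age 50 (0 = no age trend). Requires `age_mode = "model"` in
#'   [cohort_config()].
#' @param n_exons Number of exons of the simulated transcript (>= 4).
#' @param founder_fraction Fraction of PTV carriers assigned the designated
#'   founder variant, in `[0, 1]`.
#' @param missense_freq Carrier frequency of rare missense (VUS) variants,
#'   simulated independently of PTV carriership.
#' @param missense_log_or Log odds ratio of disease for rare-missense carriers.
#' @param protein_length Protein length in residues (for missense positions).
#' @return A `gene_spec` list.
#' @export
gene_spec <- function(gene, carrier_freq_controls, log_or = 0,
                      subtype_log_or = NULL, log_or_age = 0,
                      n_exons = 20L, founder_fraction = 0,
                      missense_freq = 0, missense_log_or = 0,
                      protein_length = 1000L) {
  if (!is.character(gene) || length(gene) != 1L || !nzchar(gene)) {
    pb_abort("`gene` must be a single non-empty gene symbol", "pb_config_error")
  }
  check_prob(carrier_freq_controls, "carrier_freq_controls")
  if (carrier_freq_controls >= 1) {
    pb_abort("`carrier_freq_controls` must be < 1", "pb_config_error")
  }
  check_prob(founder_fraction, "founder_fraction")
  check_prob(missense_freq, "missense_freq")
  n_exons <- check_count(n_exons, "n_exons")
  if (n_exons < 4L) pb_abort("`n_exons` must be >= 4", "pb_config_error")
  structure(
    list(
      gene = gene, carrier_freq_controls = carrier_freq_controls,
      log_or = log_or, subtype_log_or = subtype_log_or,
      log_or_age = log_or_age, n_exons = n_exons,
      founder_fraction = founder_fraction, missense_freq = missense_freq,
      missense_log_or = missense_log_or,
      protein_length = as.integer(protein_length)
    ),
    class = "gene_spec"
  )
}

#' Synthetic cohort configuration
#'
#' @param n_cases,n_controls Numbers of cases and controls to sample.
#' @param genes List of [gene_spec()] objects (names must be unique).
#' @param fh_prob_cases,fh_prob_controls Marginal probabilities of positive
#'   first-degree family history among cases and controls.
#' @param fh_missing_cases,fh_missing_controls Probabilities that family
#'   history is unobserved.
#' @param base_prevalence Baseline disease probability in the source
#'   population (sets the logistic intercept).
#' @param age_mode `"table"` (default) draws ages per group from the banded
#'   age distributions after case/control sampling, reproducing the emulated
#'   study's marginal age structure; `"model"` draws age in the source
#'   population and enters it (and any carrier-by-age interaction) in the
#'   disease model, as needed for age-trend simulations.
#' @param age_log_or Per-year effect of age on the disease log odds
#'   (`"model"` mode only), centred at 50.
#' @param fh_log_or Effect of family history on the disease log odds
#'   (`"model"` mode only).
#' @param age_probs_cases,age_probs_controls Band probabilities over the five
#'   age bands `[25,30), [30,40), [40,50), [50,60), [60,75)`.
#' @param receptor Receptor-status model parameters; see Details of
#'   [generate_cohort()].
#' @param decoys Add non-qualifying variant rows (last-exon PTVs, penultimate
#'   splice variants, named uncertain splice variants, common and benign
#'   missense, in-frame indels, UTR/intronic/synonymous rows, and rows in the
#'   excluded gene PPM1D) so that every classification rule is exercised.
#'   Decoys never alter carrier status for qualifying categories.
#' @param seed Master seed (required); each generated table uses its own
#'   derived RNG stream.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_cases = 990L, n_controls = 1094L,
                          genes = default_gene_specs(),
                          fh_prob_cases = 158 / 973,
                          fh_prob_controls = 87 / 1091,
                          fh_missing_cases = 17 / 990,
                          fh_missing_controls = 3 / 1094,
                          base_prevalence = 0.05,
                          age_mode = c("table", "model"),
                          age_log_or = 0, fh_log_or = 0,
                          age_probs_cases = AGE_PROBS_CASES,
                          age_probs_controls = AGE_PROBS_CONTROLS,
                          receptor = RECEPTOR_DEFAULTS,
                          decoys = TRUE,
                          seed) {
  if (missing(seed)) pb_abort("`seed` is required", "pb_config_error")
  n_cases <- check_count(n_cases, "n_cases")
  n_controls <- check_count(n_controls, "n_controls")
  check_prob(fh_prob_cases, "fh_prob_cases")
  check_prob(fh_prob_controls, "fh_prob_controls")
  check_prob(fh_missing_cases, "fh_missing_cases")
  check_prob(fh_missing_controls, "fh_missing_controls")
  check_prob(base_prevalence, "base_prevalence")
  if (base_prevalence <= 0 || base_prevalence >= 1) {
    pb_abort("`base_prevalence` must be in (0, 1)", "pb_config_error")
  }
  age_mode <- match.arg(age_mode)
  if (!is.list(genes) || !all(vapply(genes, inherits, TRUE, "gene_spec"))) {
    pb_abort("`genes` must be a list of gene_spec objects", "pb_config_error")
  }
  gene_names <- vapply(genes, `[[`, character(1), "gene")
  if (anyDuplicated(gene_names)) {
    pb_abort("`genes` contains duplicated gene names", "pb_config_error")
  }
  names(genes) <- gene_names
  has_trend <- any(vapply(genes, function(g) g$log_or_age != 0, logical(1)))
  if (has_trend && age_mode != "model") {
    pb_abort(
      "`log_or_age` effects require `age_mode = \"model\"`",
      "pb_config_error"
    )
  }
  for (p in c("age_probs_cases", "age_probs_controls")) {
    v <- get(p)
    if (length(v) != length(AGE_BAND_START) || any(v < 0) ||
        abs(sum(v) - 1) > 1e-6) {
      pb_abort(sprintf("`%s` must be %d non-negative probabilities summing to 1",
                       p, length(AGE_BAND_START)), "pb_config_error")
    }
  }
  structure(
    list(
      n_cases = n_cases, n_controls = n_controls, genes = genes,
      fh_prob_cases = fh_prob_cases, fh_prob_controls = fh_prob_controls,
      fh_missing_cases = fh_missing_cases,
      fh_missing_controls = fh_missing_controls,
      base_prevalence = base_prevalence, age_mode = age_mode,
      age_log_or = age_log_or, fh_log_or = fh_log_or,
      age_probs_cases = age_probs_cases,
      age_probs_controls = age_probs_controls,
      receptor = receptor, decoys = isTRUE(decoys),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Default gene specifications emulating the study cohort
#'
#' Control carrier frequencies and odds ratios follow the per-gene carrier
#' counts and association estimates of the emulated study: BRCA2 (OR 9.75,
#' founder fraction 0.55), ATM (7.61), PALB2 (ER-negative-skewed), BRCA1
#' (ER-negative-skewed), CHEK2 and RAD50, plus missense carrier channels in
#' the established genes.
#'
#' @return Named list of [gene_spec()] objects.
#' @export
default_gene_specs <- function() {
  specs <- list(
    gene_spec("BRCA2", carrier_freq_controls = 9e-4, log_or = log(9.75),
              founder_fraction = 0.55, n_exons = 27L,
              missense_freq = 0.02, protein_length = 3418L),
    gene_spec("ATM", carrier_freq_controls = 9e-4, log_or = log(7.61),
              n_exons = 63L, missense_freq = 0.05, protein_length = 3056L),
    gene_spec("BRCA1", carrier_freq_controls = 9e-4, log_or = log(3.18),
              subtype_log_or = log(20.73), n_exons = 23L,
              missense_freq = 0.01, missense_log_or = log(2.4),
              protein_length = 1863L),
    gene_spec("PALB2", carrier_freq_controls = 3e-4, log_or = log(16.14),
              subtype_log_or = log(44.23), n_exons = 13L,
              missense_freq = 0.01, protein_length = 1186L),
    gene_spec("CHEK2", carrier_freq_controls = 9e-4, log_or = 0,
              n_exons = 15L, missense_freq = 0.02, protein_length = 543L),
    gene_spec("RAD50", carrier_freq_controls = 9e-4, log_or = log(3.83),
              n_exons = 25L, missense_freq = 0.01, protein_length = 1312L)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "gene")
  specs
}

draw_banded_ages <- function(n, probs) {
  band <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  AGE_BAND_START[band] +
    runif(n) * (AGE_BAND_END[band] - AGE_BAND_START[band])
}

## Convert a configured carrier frequency among controls (non-diseased
## subjects) into the source-population frequency it implies: with disease
## odds multiplied by exp(log_or) for carriers, carriers are depleted among
## the non-diseased, so odds_pop = odds_controls * (1 + o0 * OR) / (1 + o0)
## with o0 the baseline disease odds.
population_freq <- function(freq_controls, log_or, base_prevalence) {
  if (freq_controls == 0) return(0)
  o0 <- base_prevalence / (1 - base_prevalence)
  odds <- freq_controls / (1 - freq_controls) *
    (1 + o0 * exp(log_or)) / (1 + o0)
  odds / (1 + odds)
}

## Source-population block: carriers, (model-mode) age/FH, disease status.
simulate_pool_block <- function(n, cfg) {
  genes <- cfg$genes
  ptv <- vapply(genes, function(g) {
    rbinom(n, 1L, population_freq(g$carrier_freq_controls, g$log_or,
                                  cfg$base_prevalence))
  }, integer(n))
  mis <- vapply(genes, function(g) {
    rbinom(n, 1L, population_freq(g$missense_freq, g$missense_log_or,
                                  cfg$base_prevalence))
  }, integer(n))
  if (!is.matrix(ptv)) ptv <- matrix(ptv, nrow = n)
  if (!is.matrix(mis)) mis <- matrix(mis, nrow = n)
  eta <- rep(qlogis(cfg$base_prevalence), n)
  age <- fh <- NULL
  if (cfg$age_mode == "model") {
    age <- draw_banded_ages(n, cfg$age_probs_controls)
    fh <- rbinom(n, 1L, cfg$fh_prob_controls)
    eta <- eta + cfg$age_log_or * (age - 50) + cfg$fh_log_or * fh
  }
  for (j in seq_along(genes)) {
    g <- genes[[j]]
    b <- g$log_or
    if (cfg$age_mode == "model" && g$log_or_age != 0) {
      eta <- eta + ptv[, j] * (b + g$log_or_age * (age - 50))
    } else if (b != 0) {
      eta <- eta + ptv[, j] * b
    }
    if (g$missense_log_or != 0) eta <- eta + mis[, j] * g$missense_log_or
  }
  y <- rbinom(n, 1L, plogis(eta))
  list(ptv = ptv, mis = mis, age = age, fh = fh, y = y)
}

#' Generate a synthetic case-control cohort
#'
#' Simulates a source population with per-gene carrier indicators and a
#' logistic disease model, samples the configured numbers of cases and
#' controls (retrospective design), and emits the phenotype table, the
#' annotated variant table, and ground-truth carrier indicator tables.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `phenotypes` (tibble: subject_id, status,
#'   age_years, family_history, er, pr, her2), `variants` (tibble in the
#'   annotated variant-table schema; see [classify_variants()]), `carriers`
#'   and `missense_carriers` (tibbles of true 0/1 carrier indicators,
#'   subject_id plus one column per gene), and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_cases = 200, n_controls = 200,
#'   genes = list(gene_spec("BRCA2", 0.01, log_or = log(5))),
#'   seed = 1
#' ))
#' nrow(cohort$phenotypes)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    pb_abort("`config` must be a cohort_config object", "pb_config_error")
  }
  cfg <- config
  genes <- cfg$genes
  n_genes <- length(genes)
  gene_names <- names(genes)

  pool <- with_seed(derive_seed(cfg$seed, "population"), {
    p0 <- cfg$base_prevalence
    block_n <- ceiling(1.5 * max(cfg$n_cases / p0, cfg$n_controls / (1 - p0)))
    acc <- simulate_pool_block(block_n, cfg)
    tries <- 1L
    while ((sum(acc$y == 1L) < cfg$n_cases ||
            sum(acc$y == 0L) < cfg$n_controls) && tries < 20L) {
      nxt <- simulate_pool_block(block_n, cfg)
      acc$ptv <- rbind(acc$ptv, nxt$ptv)
      acc$mis <- rbind(acc$mis, nxt$mis)
      acc$y <- c(acc$y, nxt$y)
      if (cfg$age_mode == "model") {
        acc$age <- c(acc$age, nxt$age)
        acc$fh <- c(acc$fh, nxt$fh)
      }
      tries <- tries + 1L
    }
    if (sum(acc$y == 1L) < cfg$n_cases || sum(acc$y == 0L) < cfg$n_controls) {
      pb_abort("source population did not yield enough cases/controls; raise `base_prevalence`",
               "pb_generation_error")
    }
    acc
  })

  case_idx <- which(pool$y == 1L)[seq_len(cfg$n_cases)]
  ctrl_idx <- which(pool$y == 0L)[seq_len(cfg$n_controls)]
  sel <- c(case_idx, ctrl_idx)
  n_total <- length(sel)
  status <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
  subject_id <- sprintf("S%05d", seq_len(n_total))

  ptv <- pool$ptv[sel, , drop = FALSE]
  mis <- pool$mis[sel, , drop = FALSE]
  colnames(ptv) <- colnames(mis) <- gene_names

  is_case <- status == "case"
  pheno <- with_seed(derive_seed(cfg$seed, "phenotypes"), {
    if (cfg$age_mode == "model") {
      age <- pool$age[sel]
      fh <- pool$fh[sel]
    } else {
      age <- numeric(n_total)
      age[is_case] <- draw_banded_ages(sum(is_case), cfg$age_probs_cases)
      age[!is_case] <- draw_banded_ages(sum(!is_case), cfg$age_probs_controls)
      fh <- integer(n_total)
      fh[is_case] <- rbinom(sum(is_case), 1L, cfg$fh_prob_cases)
      fh[!is_case] <- rbinom(sum(!is_case), 1L, cfg$fh_prob_controls)
    }
    fh_miss <- runif(n_total) <
      ifelse(is_case, cfg$fh_missing_cases, cfg$fh_missing_controls)
    fh[fh_miss] <- NA_integer_
    tibble::tibble(
      subject_id = subject_id, status = status,
      age_years = round(age, 1), family_history = fh
    )
  })

  receptors <- with_seed(derive_seed(cfg$seed, "receptors"), {
    draw_receptors(is_case, ptv, genes, cfg$receptor)
  })
  pheno <- dplyr::bind_cols(pheno, receptors)

  variants <- with_seed(derive_seed(cfg$seed, "variants"), {
    build_variant_table(subject_id, ptv, mis, genes, decoys = cfg$decoys)
  })

  list(
    phenotypes = pheno,
    variants = variants,
    carriers = tibble::as_tibble(cbind(
      tibble::tibble(subject_id = subject_id), as.data.frame(ptv)
    )),
    missense_carriers = tibble::as_tibble(cbind(
      tibble::tibble(subject_id = subject_id), as.data.frame(mis)
    )),
    config = cfg
  )
}

## ER drawn first; PR/HER2 conditional on ER. Carriers of genes with an
## ER-negative-specific effect have their ER-negative odds multiplied by
## exp(subtype_log_or - log_or), the retrospective consequence of a larger
## effect on ER-negative disease.
draw_receptors <- function(is_case, ptv, genes, rc) {
  n <- length(is_case)
  er <- pr <- her2 <- rep(NA_character_, n)
  nc <- sum(is_case)
  if (nc > 0) {
    er_neg_odds <- rep((1 - rc$er_pos) / rc$er_pos, n)
    for (j in seq_along(genes)) {
      g <- genes[[j]]
      if (!is.null(g$subtype_log_or)) {
        shift <- exp(g$subtype_log_or - g$log_or)
        er_neg_odds <- er_neg_odds * ifelse(ptv[, j] == 1L, shift, 1)
      }
    }
    p_neg <- er_neg_odds / (1 + er_neg_odds)
    er_neg <- rbinom(n, 1L, p_neg) == 1L
    er_v <- ifelse(er_neg, "neg", "pos")
    pr_pos_p <- ifelse(er_neg, rc$pr_pos_er_neg, rc$pr_pos_er_pos)
    pr_v <- ifelse(rbinom(n, 1L, pr_pos_p) == 1L, "pos", "neg")
    h_pos_p <- ifelse(er_neg, rc$her2_pos_er_neg, rc$her2_pos_er_pos)
    h_v <- ifelse(rbinom(n, 1L, h_pos_p) == 1L, "pos", "neg")
    sel_er <- is_case & runif(n) < rc$er_obs
    sel_pr <- is_case & runif(n) < rc$pr_obs
    sel_h <- is_case & runif(n) < rc$her2_obs
    er[sel_er] <- er_v[sel_er]
    pr[sel_pr] <- pr_v[sel_pr]
    her2[sel_h] <- h_v[sel_h]
  }
  tibble::tibble(er = er, pr = pr, her2 = her2)
}

BRCA1_UNCERTAIN_SPLICE <- c(
  "c.594-2A>C", "c.4096+1G>A", "c.4096+2T>C",
  "c.4186-2A>G", "c.4358-1G>C", "c.4358-2del"
)

PTV_CONSEQUENCES <- c("stopgain", "frameshift_insertion",
                      "frameshift_deletion", "splicing")

## Candidate qualifying PTVs for one gene: fixed per-gene pool so that
## carriers sharing a variant share its annotation. Founder carriers all get
## candidate 0. Qualifying candidates avoid the last and penultimate exons.
gene_ptv_candidates <- function(g, n_candidates = 6L) {
  k <- n_candidates
  cons <- sample(PTV_CONSEQUENCES, k, replace = TRUE)
  exon <- sample.int(max(1L, g$n_exons - 2L), k, replace = TRUE)
  tibble::tibble(
    gene = g$gene,
    variant_id = sprintf("%s:ptv%d", g$gene, seq_len(k)),
    hgvs_c = sprintf("c.%ddelA", 100L * seq_len(k) + 1L),
    consequence = cons,
    exon_index = exon,
    n_exons = g$n_exons,
    af_gnomad_nfe = ifelse(runif(k) < 0.3, NA_real_, runif(k) * 1e-4),
    clinical_class = sample(c("pathogenic", "likely_pathogenic"), k,
                            replace = TRUE, prob = c(0.8, 0.2)),
    protein_pos = NA_integer_
  )
}

gene_missense_candidates <- function(g, n_candidates = 12L) {
  k <- n_candidates
  tibble::tibble(
    gene = g$gene,
    variant_id = sprintf("%s:mis%d", g$gene, seq_len(k)),
    hgvs_c = sprintf("c.%dG>A", 50L * seq_len(k) + 3L),
    consequence = "nonsynonymous_SNV",
    exon_index = sample.int(g$n_exons, k, replace = TRUE),
    n_exons = g$n_exons,
    af_gnomad_nfe = ifelse(runif(k) < 0.25, NA_real_, runif(k) * 9e-4),
    clinical_class = sample(c("vus", "unclassified"), k, replace = TRUE),
    protein_pos = sample.int(g$protein_length, k, replace = TRUE)
  )
}

build_variant_table <- function(subject_id, ptv, mis, genes, decoys) {
  n <- length(subject_id)
  rows <- list()
  for (j in seq_along(genes)) {
    g <- genes[[j]]
    carriers <- which(ptv[, j] == 1L)
    if (length(carriers) > 0) {
      cand <- gene_ptv_candidates(g)
      founder <- tibble::tibble(
        gene = g$gene, variant_id = sprintf("%s:founder", g$gene),
        hgvs_c = if (g$gene == "BRCA2") "c.8756delG" else "c.8756delG",
        consequence = "frameshift_deletion",
        exon_index = min(21L, g$n_exons - 2L), n_exons = g$n_exons,
        af_gnomad_nfe = NA_real_, clinical_class = "pathogenic",
        protein_pos = NA_integer_
      )
      is_founder <- runif(length(carriers)) < g$founder_fraction
      pick <- sample.int(nrow(cand), length(carriers), replace = TRUE)
      ann <- cand[pick, ]
      if (any(is_founder)) {
        ann[is_founder, ] <- founder[rep(1L, sum(is_founder)), ]
      }
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = subject_id[carriers]), ann
      )
    }
    mcar <- which(mis[, j] == 1L)
    if (length(mcar) > 0) {
      cand <- gene_missense_candidates(g)
      pick <- sample.int(nrow(cand), length(mcar), replace = TRUE)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = subject_id[mcar]), cand[pick, ]
      )
    }
  }
  if (decoys) rows[[length(rows) + 1L]] <- decoy_rows(subject_id, genes)
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      subject_id = character(), gene = character(), variant_id = character(),
      hgvs_c = character(), consequence = character(),
      exon_index = integer(), n_exons = integer(),
      af_gnomad_nfe = double(), clinical_class = character(),
      protein_pos = integer()
    )
  }
  out$zygosity <- ifelse(runif(nrow(out)) < 0.01, "hom", "het")
  dplyr::arrange(out, .data$subject_id, .data$gene, .data$variant_id)
}

## Non-qualifying rows exercising every exclusion rule without altering
## qualifying carrier status.
decoy_rows <- function(subject_id, genes, rate = 0.01) {
  n <- length(subject_id)
  g1 <- genes[[1L]]
  mk <- function(k, gene, variant_id, hgvs_c, consequence, exon_index,
                 n_exons, af, cls, ppos = NA_integer_) {
    who <- sample(subject_id, k, replace = FALSE)
    tibble::tibble(
      subject_id = who, gene = gene, variant_id = variant_id,
      hgvs_c = hgvs_c, consequence = consequence,
      exon_index = exon_index, n_exons = n_exons,
      af_gnomad_nfe = af, clinical_class = cls, protein_pos = ppos
    )
  }
  k <- max(2L, round(rate * n))
  out <- list(
    mk(k, g1$gene, sprintf("%s:lastexon", g1$gene), "c.9000G>T", "stopgain",
       g1$n_exons, g1$n_exons, NA_real_, "unclassified"),
    mk(k, g1$gene, sprintf("%s:penult", g1$gene), "c.8900+2T>C", "splicing",
       g1$n_exons - 1L, g1$n_exons, NA_real_, "unclassified"),
    mk(k, g1$gene, sprintf("%s:common_mis", g1$gene), "c.1234A>G",
       "nonsynonymous_SNV", 5L, g1$n_exons, 0.004, "vus",
       as.integer(min(411L, g1$protein_length))),
    mk(k, g1$gene, sprintf("%s:benign_mis", g1$gene), "c.2345C>T",
       "nonsynonymous_SNV", 6L, g1$n_exons, 2e-4, "likely_benign",
       as.integer(min(782L, g1$protein_length))),
    mk(k, g1$gene, sprintf("%s:inframe", g1$gene), "c.3000_3002del",
       "nonframeshift_deletion", 7L, g1$n_exons, NA_real_, "unclassified"),
    mk(k, g1$gene, sprintf("%s:intronic", g1$gene), "c.300-15T>C",
       "intronic", 3L, g1$n_exons, 0.2, "benign"),
    mk(k, g1$gene, sprintf("%s:utr", g1$gene), "c.-12C>T", "UTR5",
       1L, g1$n_exons, 0.1, "unclassified"),
    mk(k, g1$gene, sprintf("%s:syn", g1$gene), "c.51G>A", "synonymous_SNV",
       2L, g1$n_exons, 0.05, "benign"),
    mk(k, "PPM1D", "PPM1D:ptv1", "c.1420C>T", "stopgain", 5L, 6L,
       NA_real_, "unclassified")
  )
  if ("BRCA1" %in% names(genes)) {
    b1 <- genes[["BRCA1"]]
    out[[length(out) + 1L]] <- dplyr::bind_rows(lapply(
      seq_along(BRCA1_UNCERTAIN_SPLICE),
      function(i) mk(1L, "BRCA1", sprintf("BRCA1:usplice%d", i),
                     BRCA1_UNCERTAIN_SPLICE[i], "splicing",
                     min(9L + i, b1$n_exons - 3L), b1$n_exons,
                     NA_real_, "vus")
    ))
  }
  dplyr::bind_rows(out)
}

#' Generate a protein-domain map
#'
#' Emits a functional-domain interval table (gene, domain, residue start/end,
#' 1-based inclusive) for the supplied gene specifications, using recognised
#' domain names for the well-characterised genes (e.g., PALB2 WD40 repeats,
#' CHEK2 FHA, ATM FAT and PI3K/PI4K-like kinase domains).
#'
#' @param genes Named list of [gene_spec()] objects, or a character vector of
#'   gene symbols (protein length then defaults to 1000 residues).
#' @return Tibble with columns gene, domain, residue_start, residue_end.
#' @export
generate_domain_map <- function(genes = default_gene_specs()) {
  if (is.character(genes)) {
    genes <- lapply(genes, function(g) gene_spec(g, 0))
    names(genes) <- vapply(genes, `[[`, character(1), "gene")
  }
  named <- list(
    ATM = c("FAT", "PI3K_PI4K"),
    BRCA1 = c("RING_Zinc_Finger", "BRCT"),
    BRCA2 = c("BRC_repeats", "DNA_binding"),
    CHEK2 = c("FHA", "Kinase"),
    PALB2 = c("ChAM", "WD1"),
    TP53 = c("DNA_binding", "Tetramerisation")
  )
  dplyr::bind_rows(lapply(genes, function(g) {
    L <- g$protein_length
    nm <- named[[g$gene]] %||% paste0(g$gene, c("_Nterm", "_Cterm"))
    tibble::tibble(
      gene = g$gene,
      domain = nm,
      residue_start = as.integer(round(c(0.10, 0.55) * L)),
      residue_end = as.integer(round(c(0.35, 0.90) * L))
    )
  }))
}

# Age-increasing per-band rates (per person-year) whose cumulative risk to 80
# is ~8%, i.e. within the 5-15% band typical of female breast cancer.
BC_LIKE_RATES <- c(
  0, 0, 0, 0,                      # 0-19
  1e-5, 5e-5, 1e-4, 2e-4,          # 20-39
  5e-4, 1e-3, 1.5e-3, 2e-3,        # 40-59
  2.5e-3, 3e-3, 3e-3, 3e-3         # 60-79
)

#' Generate a population incidence table
#'
#' Piecewise-constant incidence on contiguous 5-year age bands from 0 to
#' `age_max`.
#'
#' @param shape `"constant"` (every band has rate `scale`) or `"bc_like"`
#'   (an age-increasing breast-cancer-like preset, multiplied by `scale`,
#'   with cumulative risk to 80 of about 8 percent at `scale = 1`).
#' @param scale Positive rate (constant shape) or multiplier (bc_like).
#' @param age_max Upper age bound; must be a multiple of 5.
#' @return Tibble with columns age_start, age_end, rate_per_py.
#' @examples
#' inc <- generate_incidence_table("bc_like")
#' 1 - exp(-sum(inc$rate_per_py * 5))  # population cumulative risk to 80
#' @export
generate_incidence_table <- function(shape = c("constant", "bc_like"),
                                     scale = 1, age_max = 80) {
  shape <- match.arg(shape)
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0) {
    pb_abort("`scale` must be a single positive number", "pb_config_error")
  }
  if (age_max <= 0 || age_max %% 5 != 0) {
    pb_abort("`age_max` must be a positive multiple of 5", "pb_config_error")
  }
  starts <- seq(0, age_max - 5, by = 5)
  rate <- switch(shape,
    constant = rep(scale, length(starts)),
    bc_like = {
      base <- rep_len(BC_LIKE_RATES, length(starts))
      if (age_max > 80) base[starts >= 80] <- BC_LIKE_RATES[16]
      base * scale
    }
  )
  tibble::tibble(age_start = starts, age_end = starts + 5, rate_per_py = rate)
}

#' Write a synthetic cohort's tables to disk
#'
#' Phenotypes as CSV; variants and the domain map as TSV.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param domain_map Optional domain map tibble to write alongside.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir, domain_map = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    phenotypes = file.path(dir, "phenotypes.csv"),
    variants = file.path(dir, "variants.tsv")
  )
  readr::write_csv(cohort$phenotypes, paths[["phenotypes"]])
  readr::write_tsv(cohort$variants, paths[["variants"]])
  if (!is.null(domain_map)) {
    paths <- c(paths, domain_map = file.path(dir, "domains.tsv"))
    readr::write_tsv(domain_map, paths[["domain_map"]])
  }
  invisible(paths)
}
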