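# Independent oracles: a naive per-row reimplementation of the variant
# classification rule list, direct numerical maximization of the penalized
# likelihood, and a discrete-time population simulation for the risk
# recursion. These deliberately share no code with the package internals.

oracle_classify_row <- function(gene, consequence, exon_index, n_exons,
                                af, clinical_class, hgvs_c) {
  exception_genes <- c("ATM", "BARD1", "BRCA1", "RAD51C", "RAD51D", "PALB2")
  six_brca1 <- c("c.594-2A>C", "c.4096+1G>A", "c.4096+2T>C", "c.4186-2A>G",
                 "c.4358-1G>C", "c.4358-2del")
  if (gene == "PPM1D") return(c("EXCLUDED", "gene_excluded"))
  if (consequence %in% c("nonframeshift_insertion", "nonframeshift_deletion",
                         "intronic", "UTR5", "UTR3", "synonymous_SNV")) {
    return(c("EXCLUDED", "consequence_out_of_scope"))
  }
  if (consequence %in% c("stopgain", "frameshift_insertion",
                         "frameshift_deletion", "splicing")) {
    if (exon_index == n_exons) return(c("EXCLUDED", "last_exon"))
    if (consequence == "splicing" && exon_index == n_exons - 1 &&
        !(gene %in% exception_genes)) {
      return(c("EXCLUDED", "penultimate_splice"))
    }
    if (gene == "BRCA1" && hgvs_c %in% six_brca1) {
      return(c("EXCLUDED", "uncertain_splice"))
    }
    return(c("PTV", NA))
  }
  # missense
  if (clinical_class %in% c("benign", "likely_benign")) {
    return(c("EXCLUDED", "benign"))
  }
  if (!is.na(af) && af >= 0.001) return(c("EXCLUDED", "common"))
  c("RARE_MISSENSE", NA)
}

# Direct numerical maximization of the penalized log-likelihood
# l(beta) + 1/2 log det X'WX, gradient-free BFGS from zero.
oracle_firth <- function(X, y, reltol = 1e-15) {
  negpll <- function(beta) {
    eta <- drop(X %*% beta)
    pi <- 1 / (1 + exp(-eta))
    w <- pi * (1 - pi)
    info <- t(X) %*% (X * w)
    ld <- determinant(info, logarithm = TRUE)$modulus
    ll <- sum(ifelse(y == 1, log(pi), log(1 - pi)))
    -(ll + 0.5 * as.numeric(ld))
  }
  fit <- optim(rep(0, ncol(X)), negpll, method = "BFGS",
               control = list(maxit = 2000, reltol = reltol))
  # polish with Newton steps on numerical derivatives of the same objective
  par <- fit$par
  for (i in 1:5) {
    g <- pracma::grad(negpll, par)
    H <- pracma::hessian(negpll, par)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || max(abs(step)) > 1) break
    par <- par - step
    if (max(abs(step)) < 1e-10) break
  }
  par
}

# Discrete-time population simulation: n individuals, carrier w.p. f,
# per-band event probability 1 - exp(-hazard * width) among those still
# disease-free. Returns realized cumulative risks by group with MC
# standard errors. Counts are simulated with binomial draws, which is
# equivalent to individual-level simulation.
oracle_risk_sim <- function(hazards, f, n) {
  n1 <- rbinom(1, n, f)
  n0 <- n - n1
  at_risk1 <- n1
  at_risk0 <- n0
  width <- hazards$age_end - hazards$age_start
  for (b in seq_len(nrow(hazards))) {
    at_risk1 <- at_risk1 -
      rbinom(1, at_risk1, 1 - exp(-hazards$hazard_carrier[b] * width[b]))
    at_risk0 <- at_risk0 -
      rbinom(1, at_risk0, 1 - exp(-hazards$hazard_noncarrier[b] * width[b]))
  }
  F1 <- 1 - at_risk1 / n1
  F0 <- 1 - at_risk0 / n0
  list(
    F1 = F1, F0 = F0,
    se1 = sqrt(F1 * (1 - F1) / n1),
    se0 = sqrt(F0 * (1 - F0) / n0),
    n_carriers = n1
  )
}

# Shared simulation settings for calibration studies at the emulated
# study's scale (990 cases / 1094 controls).
sim_single_gene_cohort <- function(seed, log_or = 0, freq = 0.01,
                                   n_cases = 990, n_controls = 1094,
                                   founder_fraction = 0) {
  cfg <- cohort_config(
    n_cases = n_cases, n_controls = n_controls,
    genes = list(gene_spec("GENE1", freq, log_or = log_or,
                           founder_fraction = founder_fraction)),
    decoys = FALSE, seed = seed
  )
  generate_cohort(cfg)
}

# One adjusted Firth fit of the true carrier indicator for GENE1.
sim_fit_gene <- function(cohort) {
  cm <- as_carrier_matrix(cohort$carriers)
  association_scan(cm, cohort$phenotypes, outcomes = "overall",
                   adjustment = c("age_years", "family_history"))
}
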