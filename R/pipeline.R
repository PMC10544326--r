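## End-to-end pipeline: generate/load -> validate -> classify -> tabulate ->
## associate -> risk, with deterministic outputs and a run manifest.

#' Run the full analysis pipeline
#'
#' Executes the stages in order on either a synthesized cohort or the four
#' input tables, writes the prevalence, association and risk tables plus a
#' run manifest to the output directory, and returns the in-memory results.
#' Identical config and seed give byte-identical output tables.
#'
#' @param config A list, or the path of a YAML file, with entries:
#'   \describe{
#'     \item{seed}{Master seed (required).}
#'     \item{output_dir}{Output directory.}
#'     \item{synthesize}{Arguments for [cohort_config()]; `genes` may be a
#'       named list of [gene_spec()] argument lists. Mutually exclusive with
#'       `inputs`.}
#'     \item{inputs}{Paths `phenotypes`, `variants`, and optionally
#'       `domain_map`, `incidence`. Mutually exclusive with `synthesize`.}
#'     \item{classification}{Arguments for [classification_config()].}
#'     \item{analysis}{`outcomes` (default `"overall"`), `domain_scan`
#'       (default TRUE), `fh_stratified` (default TRUE).}
#'     \item{risk}{`enabled` (default TRUE), `threshold` (default 0.30),
#'       `p_max` (default 0.05: units given risk curves).}
#'   }
#' @param seed Optional override of `config$seed`.
#' @param out_dir Optional override of `config$output_dir`.
#' @return A list: `manifest` plus the stage results (`cohort` tables,
#'   `classified`, `prevalence_ptv`, `prevalence_missense`, `associations`,
#'   `risk_curves`, `threshold_report`).
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) {
    pb_abort("`config` must be a list or a YAML file path", "pb_config_error")
  }
  has_syn <- !is.null(config$synthesize)
  has_inp <- !is.null(config$inputs)
  if (has_syn == has_inp) {
    pb_abort("config must contain exactly one of `synthesize` or `inputs`",
             "pb_config_error")
  }
  seed <- seed %||% config$seed
  if (is.null(seed)) pb_abort("`seed` is required", "pb_config_error")
  out_dir <- out_dir %||% config$output_dir %||% "panelburden-run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  analysis <- config$analysis %||% list()
  outcomes <- analysis$outcomes %||% "overall"
  domain_scan <- analysis$domain_scan %||% TRUE
  fh_strat <- analysis$fh_stratified %||% TRUE
  risk_cfg <- config$risk %||% list()
  risk_on <- risk_cfg$enabled %||% TRUE

  counts <- list()

  ## stage: acquire inputs
  if (has_syn) {
    syn <- config$synthesize
    if (!is.null(syn$genes) && !all(vapply(syn$genes, inherits, TRUE,
                                           "gene_spec"))) {
      syn$genes <- lapply(names(syn$genes), function(nm) {
        do.call(gene_spec, c(list(gene = nm), syn$genes[[nm]]))
      })
    }
    ccfg <- do.call(cohort_config, c(syn, list(seed = seed)))
    cohort <- generate_cohort(ccfg)
    phenotypes <- cohort$phenotypes
    variants <- cohort$variants
    domain_map <- generate_domain_map(ccfg$genes)
    incidence <- generate_incidence_table("bc_like")
  } else {
    cohort <- NULL
    phenotypes <- read_phenotypes(config$inputs$phenotypes)
    variants <- read_variants(config$inputs$variants)
    domain_map <- if (!is.null(config$inputs$domain_map)) {
      read_domain_map(config$inputs$domain_map)
    } else NULL
    incidence <- if (!is.null(config$inputs$incidence)) {
      read_incidence(config$inputs$incidence)
    } else generate_incidence_table("bc_like")
  }
  validate_inputs(phenotypes, variants, domain_map, incidence, strict = TRUE)
  counts$subjects <- nrow(phenotypes)
  counts$variant_rows <- nrow(variants)

  ## stage: classify
  clf_cfg <- do.call(classification_config, config$classification %||% list())
  classified <- classify_variants(variants, clf_cfg)
  if (!is.null(domain_map)) {
    classified <- assign_domains(classified, domain_map)
  }
  report <- classification_report(classified)
  readr::write_tsv(report, file.path(out_dir, "classification_report.tsv"))
  counts$classified <- lapply(
    setNames(nm = c("PTV", "RARE_MISSENSE", "EXCLUDED")),
    function(k) sum(classified$category == k)
  )

  ## stage: burden
  cm_ptv <- build_carrier_matrix(classified, phenotypes, "PTV", "gene")
  cm_mis <- build_carrier_matrix(classified, phenotypes, "RARE_MISSENSE", "gene")
  gene_sets <- list(established = clf_cfg$established_genes)
  prev_ptv <- tabulate_prevalence(cm_ptv, phenotypes, gene_sets, classified)
  prev_mis <- tabulate_prevalence(cm_mis, phenotypes, gene_sets, classified)
  readr::write_tsv(prev_ptv, file.path(out_dir, "prevalence_ptv.tsv"))
  readr::write_tsv(prev_mis, file.path(out_dir, "prevalence_missense.tsv"))

  ## stage: association
  scans <- list(
    ptv = association_scan(cm_ptv, phenotypes, outcomes = outcomes),
    missense = association_scan(cm_mis, phenotypes, outcomes = outcomes)
  )
  if (domain_scan && !is.null(domain_map)) {
    cm_dom <- build_carrier_matrix(classified, phenotypes, "RARE_MISSENSE",
                                   "domain")
    if (length(carrier_units(cm_dom)) > 0) {
      scans$missense_domain <- association_scan(cm_dom, phenotypes,
                                                outcomes = outcomes)
    }
  }
  if (fh_strat) {
    fh <- stratify(phenotypes, "family_history")
    ctrl <- phenotypes$subject_id[phenotypes$status == "control"]
    for (s in c("fh_yes", "fh_no")) {
      ids <- union(fh[[s]], ctrl)
      scans[[paste0("ptv_", s)]] <- association_scan(
        cm_ptv, phenotypes, outcomes = "overall",
        stratum_ids = ids, stratum = s
      )
    }
  }
  associations <- dplyr::bind_rows(lapply(names(scans), function(nm) {
    dplyr::mutate(tibble::as_tibble(scans[[nm]]), scan = nm,
                  .before = 1)
  }))
  readr::write_tsv(associations, file.path(out_dir, "associations.tsv"))
  counts$association_fits <- nrow(associations)

  ## stage: cumulative risk for significant overall PTV units
  risk_curves <- list()
  thr_report <- NULL
  if (risk_on) {
    p_max <- risk_cfg$p_max %||% 0.05
    sig <- scans$ptv[scans$ptv$outcome == "overall" &
                       scans$ptv$converged &
                       !is.na(scans$ptv$p_wald) &
                       scans$ptv$p_wald < p_max &
                       scans$ptv$or > 1, ]
    n_ctrl <- sum(phenotypes$status == "control")
    for (i in seq_len(nrow(sig))) {
      u <- sig$unit[i]
      f <- sig$n_control_carriers[i] / n_ctrl
      risk_curves[[u]] <- cumulative_risk_curve(
        sig$or[i], sig$ci_low[i], sig$ci_high[i],
        incidence = incidence, f = f
      )
    }
    if (length(risk_curves) > 0) {
      thr_report <- threshold_report(risk_curves,
                                     threshold = risk_cfg$threshold %||% 0.30)
      readr::write_tsv(thr_report, file.path(out_dir, "risk_threshold.tsv"))
      risk_tbl <- dplyr::bind_rows(lapply(names(risk_curves), function(u) {
        dplyr::mutate(tibble::as_tibble(risk_curves[[u]]), unit = u,
                      .before = 1)
      }))
      readr::write_tsv(risk_tbl, file.path(out_dir, "risk_curves.tsv"))
    }
  }
  counts$risk_curves <- length(risk_curves)

  # hash the analysis-relevant config: output location must not change it
  hash_cfg <- config
  hash_cfg$output_dir <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("panelburden")),
    seed = as.integer(seed),
    config_hash = rlang::hash(hash_cfg),
    mode = if (has_syn) "synthesize" else "inputs",
    counts = counts,
    outputs = setdiff(list.files(out_dir), "manifest.json")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  list(
    manifest = manifest,
    cohort = cohort,
    phenotypes = phenotypes,
    classified = classified,
    prevalence_ptv = prev_ptv,
    prevalence_missense = prev_mis,
    associations = associations,
    risk_curves = risk_curves,
    threshold_report = thr_report
  )
}
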