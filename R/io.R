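## Readers and input validation for the four input tables.

PHENOTYPE_COLS <- c("subject_id", "status", "age_years", "family_history",
                    "er", "pr", "her2")
VARIANT_COLS <- c("subject_id", "gene", "variant_id", "hgvs_c", "consequence",
                  "exon_index", "n_exons", "af_gnomad_nfe", "clinical_class",
                  "protein_pos", "zygosity")

#' Read a phenotype table (CSV)
#' @param path File path.
#' @return Tibble with the phenotype schema.
#' @export
read_phenotypes <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject_id = "c", status = "c", age_years = "d",
                    family_history = "i", er = "c", pr = "c", her2 = "c"
                  ))
}

#' Read an annotated variant table (TSV)
#' @param path File path.
#' @return Tibble with the variant schema.
#' @export
read_variants <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject_id = "c", gene = "c", variant_id = "c",
                    hgvs_c = "c", consequence = "c", exon_index = "i",
                    n_exons = "i", af_gnomad_nfe = "d", clinical_class = "c",
                    protein_pos = "i", zygosity = "c"
                  ))
}

#' Read a protein-domain map (TSV)
#' @param path File path.
#' @return Validated tibble (gene, domain, residue_start, residue_end).
#' @export
read_domain_map <- function(path) {
  validate_domain_map(readr::read_tsv(path, show_col_types = FALSE))
}

#' Read a population incidence table (CSV)
#' @param path File path.
#' @return Validated tibble (age_start, age_end, rate_per_py).
#' @export
read_incidence <- function(path) {
  check_incidence(readr::read_csv(path, show_col_types = FALSE))
}

issue <- function(table, problem, rows = NA_integer_) {
  tibble::tibble(table = table, problem = problem,
                 rows = paste(head(rows, 10), collapse = ","))
}

#' Validate the input tables
#'
#' Schema, range, duplicate-id and cross-reference checks for the phenotype,
#' variant, domain-map and incidence tables. Returns a tibble of issues,
#' empty when everything is valid; `strict = TRUE` turns any issue into an
#' error.
#'
#' @param phenotypes,variants Tibbles (or paths) in the package schemas.
#' @param domain_map,incidence Optional tibbles (or paths).
#' @param strict Error on the first report instead of returning it.
#' @return Tibble: table, problem, rows (first offending rows).
#' @export
validate_inputs <- function(phenotypes, variants, domain_map = NULL,
                            incidence = NULL, strict = FALSE) {
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  if (is.character(variants)) variants <- read_variants(variants)
  issues <- list()
  add <- function(x) issues[[length(issues) + 1L]] <<- x

  miss <- setdiff(PHENOTYPE_COLS, names(phenotypes))
  if (length(miss) > 0) {
    add(issue("phenotypes", paste("missing columns:",
                                  paste(miss, collapse = ", "))))
  } else {
    dup <- which(duplicated(phenotypes$subject_id))
    if (length(dup) > 0) add(issue("phenotypes", "duplicate subject_id", dup))
    bad <- which(!phenotypes$status %in% c("case", "control"))
    if (length(bad) > 0) add(issue("phenotypes", "status not case/control", bad))
    bad <- which(!is.na(phenotypes$age_years) &
                   (phenotypes$age_years < 0 | phenotypes$age_years > 120))
    if (length(bad) > 0) add(issue("phenotypes", "age_years out of range", bad))
    bad <- which(!is.na(phenotypes$family_history) &
                   !phenotypes$family_history %in% c(0L, 1L))
    if (length(bad) > 0) add(issue("phenotypes", "family_history not 0/1", bad))
  }

  miss <- setdiff(VARIANT_COLS, names(variants))
  if (length(miss) > 0) {
    add(issue("variants", paste("missing columns:",
                                paste(miss, collapse = ", "))))
  } else {
    bad <- which(!is.na(variants$af_gnomad_nfe) &
                   (variants$af_gnomad_nfe < 0 | variants$af_gnomad_nfe > 1))
    if (length(bad) > 0) add(issue("variants", "af_gnomad_nfe outside [0,1]", bad))
    bad <- which(!variants$consequence %in% CONSEQ_VOCAB)
    if (length(bad) > 0) add(issue("variants", "unknown consequence term", bad))
    bad <- which(!is.na(variants$exon_index) & !is.na(variants$n_exons) &
                   (variants$exon_index < 1 |
                      variants$exon_index > variants$n_exons))
    if (length(bad) > 0) add(issue("variants", "exon_index outside 1..n_exons", bad))
    bad <- which(!variants$clinical_class %in% CLINICAL_CLASSES)
    if (length(bad) > 0) add(issue("variants", "unknown clinical_class", bad))
    if (all(c("subject_id") %in% names(phenotypes))) {
      bad <- which(!variants$subject_id %in% phenotypes$subject_id)
      if (length(bad) > 0) {
        add(issue("variants", "subject_id absent from phenotypes", bad))
      }
    }
  }

  if (!is.null(domain_map)) {
    if (is.character(domain_map)) domain_map <- readr::read_tsv(domain_map, show_col_types = FALSE)
    res <- tryCatch({
      validate_domain_map(domain_map)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) add(issue("domain_map", res))
  }
  if (!is.null(incidence)) {
    if (is.character(incidence)) incidence <- readr::read_csv(incidence, show_col_types = FALSE)
    res <- tryCatch({
      check_incidence(incidence)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) add(issue("incidence", res))
  }

  out <- if (length(issues) == 0) {
    tibble::tibble(table = character(), problem = character(),
                   rows = character())
  } else {
    dplyr::bind_rows(issues)
  }
  if (strict && nrow(out) > 0) {
    pb_abort(paste0("input validation failed:\n",
                    paste(sprintf("- %s: %s (rows %s)", out$table, out$problem,
                                  out$rows), collapse = "\n")),
             "pb_validation_error")
  }
  out
}
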