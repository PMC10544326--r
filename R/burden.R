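## Carrier-burden tabulation and descriptive stratification.

#' Build a subject-by-unit carrier matrix
#'
#' Collapses classified variants to binary carrier indicators: a subject
#' carrying at least one qualifying variant of the chosen category in a unit
#' (gene, or gene:domain for missense) scores 1 regardless of zygosity or the
#' number of distinct variants; heterozygous and homozygous carriers are not
#' distinguished. Subjects without qualifying variants appear as all-zero
#' rows, so the matrix always covers the full phenotype table.
#'
#' @param classified Output of [classify_variants()] (after
#'   [assign_domains()] if `unit_level = "domain"`).
#' @param phenotypes Phenotype tibble with a `subject_id` column.
#' @param category `"PTV"` or `"RARE_MISSENSE"`.
#' @param unit_level `"gene"` or `"domain"` (domain-level units are labelled
#'   `gene:domain` and restricted to missense rows with a mapped domain).
#' @return A tibble (class `pb_carrier_matrix`) with `subject_id` plus one
#'   0/1 column per unit; attributes `category` and `unit_level`.
#' @export
build_carrier_matrix <- function(classified, phenotypes,
                                 category = c("PTV", "RARE_MISSENSE"),
                                 unit_level = c("gene", "domain")) {
  category <- match.arg(category)
  unit_level <- match.arg(unit_level)
  check_cols(phenotypes, "subject_id", "phenotype table")
  orphans <- setdiff(unique(classified$subject_id), phenotypes$subject_id)
  if (length(orphans) > 0) {
    pb_abort(sprintf("variant table has subject_id(s) absent from phenotypes: %s",
                     paste(head(orphans, 10), collapse = ", ")),
             "pb_id_error")
  }
  keep <- classified[classified$category == category, , drop = FALSE]
  if (unit_level == "domain") {
    keep <- keep[!is.na(keep$domain), , drop = FALSE]
    keep$unit <- paste(keep$gene, keep$domain, sep = ":")
  } else {
    keep$unit <- keep$gene
  }
  units <- sort(unique(keep$unit))
  out <- tibble::tibble(subject_id = phenotypes$subject_id)
  for (u in units) {
    out[[u]] <- as.integer(
      out$subject_id %in% keep$subject_id[keep$unit == u]
    )
  }
  structure(out,
            class = c("pb_carrier_matrix", class(out)),
            category = category, unit_level = unit_level)
}

#' Construct a carrier matrix from a ready indicator table
#'
#' Wraps a tibble of 0/1 indicators (subject_id plus one column per unit) as
#' a carrier matrix, e.g. ground-truth carriers from [generate_cohort()] or
#' indicators reconstructed from published per-gene carrier counts.
#'
#' @param indicators Tibble: subject_id plus 0/1 unit columns.
#' @param category `"PTV"` or `"RARE_MISSENSE"`.
#' @param unit_level `"gene"` or `"domain"`.
#' @return A `pb_carrier_matrix` tibble.
#' @export
as_carrier_matrix <- function(indicators, category = "PTV",
                              unit_level = "gene") {
  indicators <- tibble::as_tibble(indicators)
  check_cols(indicators, "subject_id", "indicator table")
  vals <- unlist(indicators[setdiff(names(indicators), "subject_id")])
  if (length(vals) > 0 && !all(vals %in% c(0L, 1L))) {
    pb_abort("carrier indicators must be 0/1", "pb_schema_error")
  }
  structure(indicators,
            class = c("pb_carrier_matrix", class(indicators)),
            category = category, unit_level = unit_level)
}

carrier_units <- function(cm) setdiff(names(cm), "subject_id")

#' Tabulate carrier prevalence by unit and gene set
#'
#' Produces the per-unit prevalence table (unique variant count, case and
#' control carrier counts and percentages) plus one aggregate row per named
#' gene set, in which a subject carrying variants in several member genes is
#' counted once. Percentages are 100 * carriers / group size.
#'
#' @param cm A carrier matrix from [build_carrier_matrix()].
#' @param phenotypes Phenotype tibble with subject_id and status
#'   (`"case"`/`"control"`).
#' @param gene_sets Named list of character vectors; defaults to the
#'   `established` set restricted to units present in the matrix.
#' @param classified Optional classified variant table used to fill the
#'   unique-variant count per unit (keyed on gene and variant_id, pooled over
#'   cases and controls); NA when omitted.
#' @return Tibble: unit, n_variants, n_case_carriers, case_prevalence,
#'   n_control_carriers, control_prevalence (percentages to full precision;
#'   round at presentation).
#' @export
tabulate_prevalence <- function(cm, phenotypes,
                                gene_sets = list(established = ESTABLISHED_GENES),
                                classified = NULL) {
  check_cols(phenotypes, c("subject_id", "status"), "phenotype table")
  ph <- phenotypes[match(cm$subject_id, phenotypes$subject_id), ]
  is_case <- ph$status == "case"
  n_case <- sum(is_case)
  n_ctrl <- sum(!is_case)
  if (n_case == 0 || n_ctrl == 0) {
    pb_abort("both cases and controls must be present", "pb_group_error")
  }
  units <- carrier_units(cm)
  variant_counts <- NULL
  if (!is.null(classified)) {
    keep <- classified[classified$category == attr(cm, "category"), ]
    variant_counts <- keep |>
      dplyr::distinct(.data$gene, .data$variant_id) |>
      dplyr::count(.data$gene, name = "n_variants")
  }
  one_row <- function(unit, ind) {
    kc <- sum(ind[is_case])
    kk <- sum(ind[!is_case])
    tibble::tibble(
      unit = unit,
      n_variants = if (is.null(variant_counts)) NA_integer_ else {
        m <- variant_counts$n_variants[variant_counts$gene == unit]
        if (length(m) == 1) m else NA_integer_
      },
      n_case_carriers = kc,
      case_prevalence = 100 * kc / n_case,
      n_control_carriers = kk,
      control_prevalence = 100 * kk / n_ctrl
    )
  }
  per_unit <- dplyr::bind_rows(lapply(units, function(u) one_row(u, cm[[u]])))
  set_rows <- dplyr::bind_rows(lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], units)
    ind <- if (length(members) == 0) rep(0L, nrow(cm)) else {
      as.integer(rowSums(as.data.frame(cm[members])) > 0)
    }
    r <- one_row(nm, ind)
    r$n_variants <- if (is.null(variant_counts)) NA_integer_ else {
      sum(variant_counts$n_variants[variant_counts$gene %in% members])
    }
    r
  }))
  all_ind <- if (length(units) == 0) rep(0L, nrow(cm)) else {
    as.integer(rowSums(as.data.frame(cm[units])) > 0)
  }
  total <- one_row("any_unit", all_ind)
  total$n_variants <- if (is.null(variant_counts)) NA_integer_ else {
    sum(variant_counts$n_variants)
  }
  dplyr::bind_rows(per_unit, set_rows, total)
}

#' Founder-variant carrier breakdown
#'
#' For a designated founder variant (a single ancestral variant shared by
#' many carriers), reports its carrier prevalence among cases and controls
#' and its share of the gene's carriers in each group.
#'
#' @param classified Classified variant table.
#' @param phenotypes Phenotype tibble (subject_id, status).
#' @param gene Gene symbol.
#' @param variant_id The founder variant's id.
#' @param category Variant category to count (default PTV).
#' @return One-row tibble: gene, variant_id, founder carrier counts and
#'   percentages by group, and the founder's percentage share of the gene's
#'   carriers by group.
#' @export
founder_breakdown <- function(classified, phenotypes, gene, variant_id,
                              category = "PTV") {
  check_cols(phenotypes, c("subject_id", "status"), "phenotype table")
  keep <- classified[classified$category == category &
                       classified$gene == gene, ]
  carriers <- unique(keep$subject_id)
  fcarriers <- unique(keep$subject_id[keep$variant_id == variant_id])
  is_case <- phenotypes$status == "case"
  case_ids <- phenotypes$subject_id[is_case]
  ctrl_ids <- phenotypes$subject_id[!is_case]
  n_fc <- sum(fcarriers %in% case_ids)
  n_fk <- sum(fcarriers %in% ctrl_ids)
  n_gc <- sum(carriers %in% case_ids)
  n_gk <- sum(carriers %in% ctrl_ids)
  tibble::tibble(
    gene = gene, variant_id = variant_id,
    n_case_founder = n_fc,
    case_prevalence = 100 * n_fc / length(case_ids),
    n_control_founder = n_fk,
    control_prevalence = 100 * n_fk / length(ctrl_ids),
    share_of_case_carriers = if (n_gc > 0) 100 * n_fc / n_gc else NA_real_,
    share_of_control_carriers = if (n_gk > 0) 100 * n_fk / n_gk else NA_real_
  )
}

#' Partition subjects into strata
#'
#' Supported stratifiers: `"family_history"` (with/without a first-degree
#' relative with breast cancer), `"age_cut"` (below versus at-or-above the
#' cut, default 50 years; the boundary side is configurable), and
#' `"subtype"` (ER/PR/HER2 partitions among cases, plus the triple-negative
#' subset defined only for cases with all three markers observed). Subjects
#' missing the stratifier are dropped and reported in the `dropped`
#' attribute.
#'
#' @param phenotypes Phenotype tibble.
#' @param by One of `"family_history"`, `"age_cut"`, `"subtype"`.
#' @param cut Age cut in years (age_cut only).
#' @param boundary `"right"` assigns age == cut to the upper stratum
#'   (default, i.e. `<50` vs `>=50`); `"left"` to the lower.
#' @return Named list of subject-id character vectors; attribute `dropped`
#'   holds ids with a missing stratifier.
#' @export
stratify <- function(phenotypes, by = c("family_history", "age_cut", "subtype"),
                     cut = 50, boundary = c("right", "left")) {
  by <- match.arg(by)
  boundary <- match.arg(boundary)
  ph <- phenotypes
  if (by == "family_history") {
    check_cols(ph, c("subject_id", "family_history"), "phenotype table")
    dropped <- ph$subject_id[is.na(ph$family_history)]
    out <- list(
      fh_yes = ph$subject_id[!is.na(ph$family_history) & ph$family_history == 1],
      fh_no = ph$subject_id[!is.na(ph$family_history) & ph$family_history == 0]
    )
  } else if (by == "age_cut") {
    check_cols(ph, c("subject_id", "age_years"), "phenotype table")
    dropped <- ph$subject_id[is.na(ph$age_years)]
    a <- ph$age_years
    lower <- if (boundary == "right") !is.na(a) & a < cut else !is.na(a) & a <= cut
    upper <- !is.na(a) & !lower
    out <- setNames(
      list(ph$subject_id[lower], ph$subject_id[upper]),
      paste0(c("age_lt_", "age_ge_"), cut)
    )
  } else {
    check_cols(ph, c("subject_id", "status", "er", "pr", "her2"),
               "phenotype table")
    cases <- ph[ph$status == "case", ]
    dropped <- cases$subject_id[is.na(cases$er) & is.na(cases$pr) &
                                  is.na(cases$her2)]
    full <- !is.na(cases$er) & !is.na(cases$pr) & !is.na(cases$her2)
    out <- list(
      er_pos = cases$subject_id[!is.na(cases$er) & cases$er == "pos"],
      er_neg = cases$subject_id[!is.na(cases$er) & cases$er == "neg"],
      pr_pos = cases$subject_id[!is.na(cases$pr) & cases$pr == "pos"],
      pr_neg = cases$subject_id[!is.na(cases$pr) & cases$pr == "neg"],
      her2_pos = cases$subject_id[!is.na(cases$her2) & cases$her2 == "pos"],
      her2_neg = cases$subject_id[!is.na(cases$her2) & cases$her2 == "neg"],
      fully_typed = cases$subject_id[full],
      triple_negative = cases$subject_id[full & cases$er == "neg" &
                                           cases$pr == "neg" &
                                           cases$her2 == "neg"]
    )
  }
  structure(out, dropped = dropped)
}

#' Compare the location of two age distributions
#'
#' Two-sided Wilcoxon rank-sum or two-sample t test, with group means and
#' standard deviations echoed.
#'
#' @param x,y Numeric vectors (e.g. ages of two carrier groups).
#' @param method `"rank_sum"` or `"t_test"`.
#' @return One-row tibble: method, statistic, p_value, mean_x, sd_x, n_x,
#'   mean_y, sd_y, n_y.
#' @export
compare_group_location <- function(x, y, method = c("rank_sum", "t_test")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    pb_abort("both groups must be nonempty", "pb_group_error")
  }
  if (method == "t_test" && (length(x) < 2 || length(y) < 2)) {
    pb_abort("t test needs at least 2 observations per group", "pb_group_error")
  }
  fit <- if (method == "rank_sum") {
    suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  } else {
    t.test(x, y, alternative = "two.sided")
  }
  tibble::tibble(
    method = method,
    statistic = unname(fit$statistic),
    p_value = fit$p.value,
    mean_x = mean(x), sd_x = sd(x), n_x = length(x),
    mean_y = mean(y), sd_y = sd(y), n_y = length(y)
  )
}

#' Compare two proportions
#'
#' Two-sided test of k1/n1 versus k2/n2; the default is Fisher's exact
#' (conditional hypergeometric) test, with the chi-square test optional.
#'
#' @param k1,n1,k2,n2 Successes and totals in the two groups.
#' @param method `"fisher"` or `"chisq"`.
#' @return One-row tibble: method, p_value, prop1, prop2.
#' @export
compare_two_proportions <- function(k1, n1, k2, n2,
                                    method = c("fisher", "chisq")) {
  method <- match.arg(method)
  if (k1 > n1 || k2 > n2 || any(c(k1, n1, k2, n2) < 0)) {
    pb_abort("need 0 <= k <= n in both groups", "pb_group_error")
  }
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  p <- if (method == "fisher") {
    fisher.test(tab)$p.value
  } else {
    suppressWarnings(chisq.test(tab, correct = FALSE))$p.value
  }
  tibble::tibble(method = method, p_value = p,
                 prop1 = k1 / n1, prop2 = k2 / n2)
}
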