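## Rule-based variant classification.
##
## Maps each annotated variant row to PTV, RARE_MISSENSE or EXCLUDED(reason),
## following the filtering rules of panel burden studies: PTVs are frameshift
## indels, canonical +/-2 splice variants and nonsense variants, excluding
## last-exon PTVs and penultimate-exon splice variants (except in genes where
## the truncated protein is still expected to be pathogenic) and a named set
## of splice variants of uncertain significance; missense variants are kept
## when rare (gnomAD NFE allele frequency below a threshold) and not (likely)
## benign.

# ANNOVAR-style consequence vocabulary
CONSEQ_PTV <- c("stopgain", "frameshift_insertion", "frameshift_deletion",
                "splicing")
CONSEQ_MISSENSE <- "nonsynonymous_SNV"
CONSEQ_OUT_OF_SCOPE <- c("nonframeshift_insertion", "nonframeshift_deletion",
                         "intronic", "UTR5", "UTR3", "synonymous_SNV")
CONSEQ_VOCAB <- c(CONSEQ_PTV, CONSEQ_MISSENSE, CONSEQ_OUT_OF_SCOPE)

CLINICAL_CLASSES <- c("pathogenic", "likely_pathogenic", "vus",
                      "likely_benign", "benign", "unclassified")

#' Classification configuration
#'
#' @param established_genes Genes treated as established susceptibility genes
#'   (used for gene-set aggregation downstream).
#' @param excluded_genes Genes removed from analysis entirely (default PPM1D,
#'   whose truncating variants arise as somatic mosaicism).
#' @param penultimate_exception_genes Genes whose penultimate-exon splice
#'   variants are retained as PTVs because the truncated protein may still be
#'   pathogenic. Default ATM, BARD1, BRCA1, RAD51C, RAD51D, PALB2.
#' @param excluded_splice_hgvs Data frame (gene, hgvs_c) of named splice
#'   variants of uncertain significance to exclude; defaults to six BRCA1
#'   canonical splice variants.
#' @param missense_af_threshold Missense variants with gnomAD non-Finnish
#'   European allele frequency at or above this are excluded as common.
#' @return A `classification_config` list.
#' @export
classification_config <- function(
    established_genes = ESTABLISHED_GENES,
    excluded_genes = "PPM1D",
    penultimate_exception_genes = c("ATM", "BARD1", "BRCA1", "RAD51C",
                                    "RAD51D", "PALB2"),
    excluded_splice_hgvs = default_excluded_splice(),
    missense_af_threshold = 0.001) {
  if (missense_af_threshold <= 0 || missense_af_threshold >= 1) {
    pb_abort("`missense_af_threshold` must be in (0, 1)", "pb_config_error")
  }
  if (length(intersect(excluded_genes, established_genes)) > 0) {
    pb_abort("`excluded_genes` must not overlap `established_genes`",
             "pb_config_error")
  }
  excluded_splice_hgvs <- tibble::as_tibble(excluded_splice_hgvs)
  check_cols(excluded_splice_hgvs, c("gene", "hgvs_c"), "excluded_splice_hgvs")
  structure(
    list(
      established_genes = established_genes,
      excluded_genes = excluded_genes,
      penultimate_exception_genes = penultimate_exception_genes,
      excluded_splice_hgvs = excluded_splice_hgvs,
      missense_af_threshold = missense_af_threshold
    ),
    class = "classification_config"
  )
}

#' Default excluded splice variants
#'
#' The six canonical BRCA1 splice variants excluded as being of uncertain
#' clinical significance under ENIGMA classification.
#'
#' @return Tibble with columns gene, hgvs_c.
#' @export
default_excluded_splice <- function() {
  tibble::tibble(gene = "BRCA1", hgvs_c = BRCA1_UNCERTAIN_SPLICE)
}

#' Classify annotated variants
#'
#' Applies the rule list, in order, to every row of an annotated variant
#' table: (1) excluded gene; (2) out-of-scope consequence (in-frame indels,
#' intronic, UTR, synonymous); (3) PTV-class consequences — last-exon
#' variants excluded, penultimate-exon splice variants excluded unless the
#' gene is on the exception list, named uncertain splice variants excluded,
#' the rest are PTVs; (4) missense — (likely) benign excluded, allele
#' frequency at or above the threshold excluded as common, the rest are
#' RARE_MISSENSE. Missense rows with unknown allele frequency are kept
#' (absence from gnomAD implies rarity) and flagged via `af_unknown`.
#'
#' @param variants Variant table (tibble) with columns subject_id, gene,
#'   variant_id, hgvs_c, consequence, exon_index, n_exons, af_gnomad_nfe,
#'   clinical_class, protein_pos (zygosity optional).
#' @param config A [classification_config()].
#' @return The input tibble with added columns `category` (PTV,
#'   RARE_MISSENSE, EXCLUDED), `exclusion_reason` (NA unless EXCLUDED),
#'   `af_unknown`, and `domain` (NA until [assign_domains()]).
#' @examples
#' v <- tibble::tibble(
#'   subject_id = "S1", gene = "CHEK2", variant_id = "CHEK2:1",
#'   hgvs_c = "c.470T>C", consequence = "nonsynonymous_SNV",
#'   exon_index = 4L, n_exons = 15L, af_gnomad_nfe = 5e-4,
#'   clinical_class = "vus", protein_pos = 157L
#' )
#' classify_variants(v, classification_config())$category
#' @export
classify_variants <- function(variants, config = classification_config()) {
  variants <- tibble::as_tibble(variants)
  check_cols(variants, c("subject_id", "gene", "variant_id", "hgvs_c",
                         "consequence", "exon_index", "n_exons",
                         "af_gnomad_nfe", "clinical_class", "protein_pos"),
             "variant table")
  if (nrow(variants) == 0) {
    return(dplyr::mutate(variants,
                         category = character(), exclusion_reason = character(),
                         af_unknown = logical(), domain = character()))
  }
  unknown <- setdiff(unique(variants$consequence), CONSEQ_VOCAB)
  if (length(unknown) > 0) {
    pb_abort(sprintf("unknown consequence term(s): %s",
                     paste(unknown, collapse = ", ")),
             "pb_vocab_error")
  }
  ptv_class <- variants$consequence %in% CONSEQ_PTV
  if (any(ptv_class & (is.na(variants$exon_index) | is.na(variants$n_exons)))) {
    bad <- variants$variant_id[ptv_class & (is.na(variants$exon_index) |
                                              is.na(variants$n_exons))]
    pb_abort(sprintf("missing exon_index/n_exons for PTV-class variant(s): %s",
                     paste(unique(bad), collapse = ", ")),
             "pb_schema_error")
  }

  named_excl <- dplyr::mutate(config$excluded_splice_hgvs, .named_excl = TRUE)
  v <- dplyr::left_join(variants, named_excl, by = c("gene", "hgvs_c"))
  v$.named_excl <- !is.na(v$.named_excl)

  v <- dplyr::mutate(
    v,
    .ptv_class = .data$consequence %in% CONSEQ_PTV,
    .is_missense = .data$consequence %in% CONSEQ_MISSENSE,
    af_unknown = .data$.is_missense & is.na(.data$af_gnomad_nfe),
    exclusion_reason = dplyr::case_when(
      .data$gene %in% config$excluded_genes ~ "gene_excluded",
      .data$consequence %in% CONSEQ_OUT_OF_SCOPE ~ "consequence_out_of_scope",
      .data$.ptv_class & .data$exon_index == .data$n_exons ~ "last_exon",
      .data$.ptv_class & .data$consequence == "splicing" &
        .data$exon_index == .data$n_exons - 1L &
        !(.data$gene %in% config$penultimate_exception_genes) ~
        "penultimate_splice",
      .data$.ptv_class & .data$.named_excl ~ "uncertain_splice",
      .data$.is_missense &
        .data$clinical_class %in% c("benign", "likely_benign") ~ "benign",
      .data$.is_missense & !is.na(.data$af_gnomad_nfe) &
        .data$af_gnomad_nfe >= config$missense_af_threshold ~ "common",
      TRUE ~ NA_character_
    ),
    category = dplyr::case_when(
      !is.na(.data$exclusion_reason) ~ "EXCLUDED",
      .data$.ptv_class ~ "PTV",
      TRUE ~ "RARE_MISSENSE"
    ),
    domain = NA_character_
  )
  dplyr::select(v, -".ptv_class", -".is_missense", -".named_excl")
}

#' Summarise classification attrition
#'
#' Per-category and per-exclusion-reason row counts for a classified variant
#' table, for run reports.
#'
#' @param classified Output of [classify_variants()].
#' @return Tibble with columns category, exclusion_reason, n.
#' @export
classification_report <- function(classified) {
  dplyr::count(classified, .data$category, .data$exclusion_reason, name = "n")
}

#' Validate a domain map
#'
#' @param domain_map Tibble (gene, domain, residue_start, residue_end).
#' @return The validated tibble, invisibly usable downstream.
#' @export
validate_domain_map <- function(domain_map) {
  domain_map <- tibble::as_tibble(domain_map)
  check_cols(domain_map, c("gene", "domain", "residue_start", "residue_end"),
             "domain map")
  if (any(domain_map$residue_start > domain_map$residue_end)) {
    pb_abort("domain map has residue_start > residue_end", "pb_schema_error")
  }
  overlaps <- domain_map |>
    dplyr::group_by(.data$gene) |>
    dplyr::arrange(.data$residue_start, .by_group = TRUE) |>
    dplyr::summarise(
      bad = any(.data$residue_start[-1] <=
                  .data$residue_end[-dplyr::n()]) && dplyr::n() > 1,
      .groups = "drop"
    )
  if (any(overlaps$bad)) {
    pb_abort(sprintf("overlapping domain intervals in gene(s): %s",
                     paste(overlaps$gene[overlaps$bad], collapse = ", ")),
             "pb_schema_error")
  }
  domain_map
}

#' Assign protein domains to rare missense variants
#'
#' Labels each RARE_MISSENSE row with the unique domain interval (1-based,
#' inclusive bounds) containing its protein residue, or NA when the residue
#' lies outside all mapped domains. PTV and EXCLUDED rows pass through
#' unchanged.
#'
#' @param classified Output of [classify_variants()].
#' @param domain_map Tibble (gene, domain, residue_start, residue_end);
#'   validated for non-overlap.
#' @return `classified` with the `domain` column filled for missense rows.
#' @export
assign_domains <- function(classified, domain_map) {
  domain_map <- validate_domain_map(domain_map)
  is_mis <- classified$category == "RARE_MISSENSE" &
    !is.na(classified$protein_pos)
  if (!any(is_mis)) return(classified)
  mis <- classified[is_mis, c("gene", "protein_pos")]
  mis$.row <- which(is_mis)
  hit <- dplyr::inner_join(mis, domain_map, by = "gene",
                           relationship = "many-to-many") |>
    dplyr::filter(.data$protein_pos >= .data$residue_start,
                  .data$protein_pos <= .data$residue_end)
  classified$domain[hit$.row] <- hit$domain
  classified
}
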