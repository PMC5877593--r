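SOMATIC_EFFECTS <- c("coding_nonsilent", "splice_site_pm3")

#' Somatic / germline / undetermined status from matched-normal counts
#'
#' Vectorised decision rule on the matched normal: a variant is `somatic`
#' when the normal is well covered (total depth > 5) and essentially clean
#' of the alternate allele — zero alternate reads, or one alternate read
#' tolerated at total depth >= 15, or two at total depth >= 30. It is
#' `undetermined` when the normal is too shallow to be informative (the
#' boundary depth of exactly 5 is conservatively treated as uninformative).
#' Everything else — genuine alternate support in a covered normal — is
#' `germline`.
#'
#' @param normal_total_depth Integer vector of normal total depths.
#' @param normal_alt_depth Integer vector of alternate-supporting reads in
#'   the normal, for the exact alternate allele of the tumor variant.
#' @param min_normal_depth Depth below-or-at which the normal is
#'   uninformative (default 5).
#' @param alt1_min_depth,alt2_min_depth Total depths from which 1 and 2
#'   alternate reads are still compatible with a somatic call (defaults 15
#'   and 30).
#' @return Character vector: `"somatic"`, `"germline"` or `"undetermined"`.
#' @export
#' @examples
#' somatic_status(c(20, 16, 4, 30), c(0, 1, 0, 3))
somatic_status <- function(normal_total_depth, normal_alt_depth,
                           min_normal_depth = 5,
                           alt1_min_depth = 15, alt2_min_depth = 30) {
  stopifnot(length(normal_total_depth) == length(normal_alt_depth))
  td <- normal_total_depth
  ad <- normal_alt_depth
  dplyr::case_when(
    is.na(td) | is.na(ad) ~ "undetermined",
    td <= min_normal_depth ~ "undetermined",
    ad == 0 ~ "somatic",
    ad == 1 & td >= alt1_min_depth ~ "somatic",
    ad == 2 & td >= alt2_min_depth ~ "somatic",
    .default = "germline"
  )
}

# normal-side read count for the tumor's alternate allele: the exact base
# for SNVs, the indel tally for length-changing alleles; other non-reference
# bases do not count against somatic status
pileup_alt_count <- function(pileup, ref, alt) {
  n <- length(ref)
  out <- integer(n)
  is_indel <- nchar(ref) > 1 | nchar(alt) > 1
  for (b in BASES) {
    sel <- !is_indel & alt == b
    out[sel] <- pileup[[b]][sel]
  }
  out[is_indel] <- pileup$indel[is_indel]
  out
}

#' Classify a cohort's filtered variants against matched-normal pileups
#'
#' Joins each tumor variant to its patient's normal pileup (via the sample
#' map) and applies [somatic_status()]. Loci missing from the pileup are
#' `undetermined` and flagged in `pileup_missing`; the missing fraction is
#' attached as the `missing_pileup_fraction` attribute. Duplicate pileup
#' rows for one locus are an input error.
#'
#' @param variants Filtered variant tibble.
#' @param pileups Normal pileup tibble (`patient_id`, `chrom`, `pos`,
#'   `ref`, `A`, `C`, `G`, `T`, `indel`, `total_depth`).
#' @param sample_map Tibble `sample_id`, `patient_id`; every variant sample
#'   must be present.
#' @inheritParams somatic_status
#' @return The variant tibble with `patient_id`, `normal_total_depth`,
#'   `normal_alt_depth`, `pileup_missing` and `status` columns.
#' @export
classify_cohort <- function(variants, pileups, sample_map,
                            min_normal_depth = 5,
                            alt1_min_depth = 15, alt2_min_depth = 30) {
  missing_samples <- setdiff(unique(variants$sample_id),
                             sample_map$sample_id)
  if (length(missing_samples) > 0) {
    abort(sprintf("sample(s) missing from sample map: %s",
                  paste(missing_samples, collapse = ", ")))
  }
  dup <- pileups |>
    count(.data$patient_id, .data$chrom, .data$pos) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate pileup rows for %d locus/loci (first: %s %s:%d)",
                  nrow(dup), dup$patient_id[1], dup$chrom[1], dup$pos[1]))
  }
  out <- variants |>
    left_join(sample_map, by = "sample_id") |>
    left_join(
      pileups |>
        select("patient_id", "chrom", "pos",
               all_of(BASES), "indel",
               normal_total_depth = "total_depth"),
      by = c("patient_id", "chrom", "pos")
    )
  out$pileup_missing <- is.na(out$normal_total_depth)
  out$normal_alt_depth <- ifelse(
    out$pileup_missing, NA_integer_,
    pileup_alt_count(out, out$ref, out$alt)
  )
  out$status <- somatic_status(out$normal_total_depth, out$normal_alt_depth,
                               min_normal_depth, alt1_min_depth,
                               alt2_min_depth)
  out <- out |> select(-all_of(BASES), -"indel")
  attr(out, "missing_pileup_fraction") <-
    if (nrow(out) == 0) 0 else mean(out$pileup_missing)
  out
}

#' Gene-level recurrence of somatic variants
#'
#' Counts, per gene, the distinct samples and distinct patients carrying a
#' somatic variant. Genes mutated in several samples that all belong to one
#' patient are flagged `same_patient_only`: recurrence driven entirely by
#' multiple lesions of one individual, which is not cohort-level
#' recurrence.
#'
#' @param somatic_variants Tibble of somatic variants (needs `gene`,
#'   `sample_id`).
#' @param sample_map Tibble `sample_id`, `patient_id`.
#' @return Tibble per gene: `n_samples`, `n_patients`, `samples`,
#'   `recurrent` (>= 2 samples), `same_patient_only`.
#' @export
recurrent_genes <- function(somatic_variants, sample_map) {
  if (nrow(somatic_variants) == 0) {
    return(tibble(gene = character(0), n_samples = integer(0),
                  n_patients = integer(0), samples = character(0),
                  recurrent = logical(0), same_patient_only = logical(0)))
  }
  missing <- setdiff(unique(somatic_variants$sample_id),
                     sample_map$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("sample(s) missing from sample map: %s",
                  paste(missing, collapse = ", ")))
  }
  somatic_variants |>
    select(-any_of("patient_id")) |>
    left_join(sample_map, by = "sample_id") |>
    distinct(.data$gene, .data$sample_id, .data$patient_id) |>
    group_by(gene = .data$gene) |>
    summarise(
      n_samples = n_distinct(.data$sample_id),
      n_patients = n_distinct(.data$patient_id),
      samples = paste(sort(unique(.data$sample_id)), collapse = ","),
      .groups = "drop"
    ) |>
    mutate(
      recurrent = .data$n_samples >= 2,
      same_patient_only = .data$recurrent & .data$n_patients == 1
    ) |>
    arrange(desc(.data$n_patients), desc(.data$n_samples), .data$gene)
}

#' Fraction of mutated genes expressed in the mutated sample
#'
#' A mutated gene counts as expressed when its expression is at least
#' `min_expr` in at least one of the samples in which it is mutated; genes
#' absent from the expression table count as not expressed.
#'
#' @param somatic_variants Tibble of somatic variants (`gene`, `sample_id`).
#' @param expression Long tibble `gene`, `sample_id`, `expr`.
#' @param min_expr Expression threshold, in the units of the table
#'   (default 1).
#' @return Fraction in \[0, 1\] (NA if there are no mutated genes).
#' @export
expressed_fraction <- function(somatic_variants, expression, min_expr = 1) {
  mutated <- somatic_variants |> distinct(.data$gene, .data$sample_id)
  if (nrow(mutated) == 0) return(NA_real_)
  if (nrow(expression) == 0) return(0)
  hits <- mutated |>
    left_join(expression, by = c("gene", "sample_id")) |>
    group_by(.data$gene) |>
    summarise(expressed = any(!is.na(.data$expr) & .data$expr >= min_expr),
              .groups = "drop")
  mean(hits$expressed)
}

#' Match somatic variants against an actionable-gene list
#'
#' Symbol matching is case-insensitive and whitespace-stripped. The
#' package ships a small illustrative list
#' (`system.file("extdata", "actionable_genes.tsv", package = "somaticflow")`);
#' supply a licensed clinical database for real use.
#'
#' @param somatic_variants Tibble of somatic variants (needs `gene`).
#' @param actionable Tibble with columns `gene` and (optionally)
#'   `annotation`, or a character vector of symbols.
#' @return The matching variants with an `actionable_annotation` column.
#' @export
match_actionable <- function(somatic_variants, actionable) {
  if (is.character(actionable)) {
    actionable <- tibble(gene = actionable, annotation = NA_character_)
  }
  if (!"annotation" %in% names(actionable)) {
    actionable$annotation <- NA_character_
  }
  norm <- function(x) str_to_upper(str_trim(x))
  key <- norm(actionable$gene)
  idx <- match(norm(somatic_variants$gene), key)
  out <- somatic_variants[!is.na(idx), ]
  out$actionable_annotation <- actionable$annotation[idx[!is.na(idx)]]
  out
}
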