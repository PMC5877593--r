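#' Partition a patient's somatic variants by lesion sharing
#'
#' For a patient with several sequenced lesions, each somatic variant is
#' assigned to exactly one of three disjoint, exhaustive categories by the
#' number of lesions carrying it: `truncal` (all lesions — on the trunk of
#' the clonal tree), `partial` (more than one but not all) or `private`
#' (exactly one). Variant identity across lesions is the exact
#' (chrom, pos, ref, alt) key; lesions are called against the same
#' reference, so no fuzzy matching is applied.
#'
#' @param somatic_variants Tibble of somatic variants of one patient's
#'   lesions, with `sample_id`, `chrom`, `pos`, `ref`, `alt` and
#'   optionally `gene`.
#' @param lesions Optional character vector naming (and ordering) the
#'   lesions; defaults to the sorted samples present. At least two lesions
#'   are required — sharing is undefined for a single lesion.
#' @param patient_id Optional label carried on the result.
#' @return An object of class `clonal_partition`: list with `patient_id`,
#'   `lesions` and `assignments` (tibble: variant key columns, `gene`,
#'   `n_lesions`, `lesions`, `category`). `tidy()` returns the
#'   assignments, `glance()` the category counts.
#' @export
#' @examples
#' v <- tibble::tibble(
#'   sample_id = c("L1", "L2", "L1"), chrom = "chr1",
#'   pos = c(100L, 100L, 200L), ref = "A", alt = "T", gene = "G1"
#' )
#' glance(clonal_partition(v))
clonal_partition <- function(somatic_variants, lesions = NULL,
                             patient_id = NULL) {
  if (is.null(lesions)) lesions <- sort(unique(somatic_variants$sample_id))
  if (length(lesions) < 2) {
    abort("clonal partition requires >= 2 lesions")
  }
  extra <- setdiff(unique(somatic_variants$sample_id), lesions)
  if (length(extra) > 0) {
    abort(sprintf("sample(s) not in the lesion list: %s",
                  paste(extra, collapse = ", ")))
  }
  if (!"gene" %in% names(somatic_variants)) {
    somatic_variants$gene <- NA_character_
  }
  n_total <- length(lesions)
  assignments <- somatic_variants |>
    distinct(.data$sample_id, .data$chrom, .data$pos, .data$ref,
             .data$alt, .data$gene) |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt, .data$gene) |>
    summarise(
      n_lesions = n_distinct(.data$sample_id),
      lesions = paste(intersect(lesions, unique(.data$sample_id)),
                      collapse = ","),
      .groups = "drop"
    ) |>
    mutate(category = dplyr::case_when(
      .data$n_lesions == n_total ~ "truncal",
      .data$n_lesions == 1L ~ "private",
      .default = "partial"
    )) |>
    arrange(desc(.data$n_lesions), .data$chrom, .data$pos, .data$alt)
  structure(list(patient_id = patient_id, lesions = lesions,
                 assignments = assignments),
            class = "clonal_partition")
}

#' @export
print.clonal_partition <- function(x, ...) {
  cat(sprintf("<clonal_partition>%s %d lesions, %d variants\n",
              if (is.null(x$patient_id)) "" else paste0(" ", x$patient_id),
              length(x$lesions), nrow(x$assignments)))
  print(glance(x))
  invisible(x)
}

#' @rdname clonal_partition
#' @param x A `clonal_partition`.
#' @param ... Unused.
#' @method tidy clonal_partition
#' @export
tidy.clonal_partition <- function(x, ...) x$assignments

#' @rdname clonal_partition
#' @method glance clonal_partition
#' @export
glance.clonal_partition <- function(x, ...) {
  tibble(
    patient_id = x$patient_id %||% NA_character_,
    n_lesions = length(x$lesions),
    n_variants = nrow(x$assignments),
    n_truncal = sum(x$assignments$category == "truncal"),
    n_partial = sum(x$assignments$category == "partial"),
    n_private = sum(x$assignments$category == "private")
  )
}

#' Lesion-by-gene mutation matrix
#'
#' Builds the presence/absence matrix behind multi-lesion sharing plots: a
#' cell is `TRUE` when the lesion carries at least one somatic variant in
#' the gene. Genes are ordered truncal-first, then by decreasing number of
#' carrying lesions.
#'
#' @param partition A [clonal_partition()].
#' @param lesions Optional lesion (row) order; defaults to the partition's.
#' @return Tibble with `sample_id` and one logical column per gene.
#' @export
clonal_matrix <- function(partition, lesions = NULL) {
  if (is.null(lesions)) lesions <- partition$lesions
  a <- partition$assignments
  gene_order <- a |>
    mutate(gene = dplyr::coalesce(.data$gene, "intergenic")) |>
    group_by(.data$gene) |>
    summarise(truncal = any(.data$category == "truncal"),
              max_n = max(.data$n_lesions), .groups = "drop") |>
    arrange(desc(.data$truncal), desc(.data$max_n), .data$gene) |>
    pull("gene")
  cells <- a |>
    mutate(gene = dplyr::coalesce(.data$gene, "intergenic")) |>
    tidyr::separate_rows("lesions", sep = ",") |>
    distinct(sample_id = .data$lesions, .data$gene) |>
    mutate(present = TRUE)
  tidyr::crossing(sample_id = lesions, gene = gene_order) |>
    left_join(cells, by = c("sample_id", "gene")) |>
    mutate(present = dplyr::coalesce(.data$present, FALSE),
           gene = factor(.data$gene, levels = gene_order)) |>
    arrange(.data$gene) |>
    tidyr::pivot_wider(names_from = "gene", values_from = "present") |>
    (\(d) d[match(lesions, d$sample_id), ])()
}
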