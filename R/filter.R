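#' Depth and allele-fraction filter
#'
#' Keeps variants with `total_depth` strictly greater than
#' `min_total_depth` and alternate-allele ratio (VAF) strictly greater than
#' `min_ratio`. Both comparators are strict, so boundary values are
#' removed; a record with zero total depth has no defined ratio and is
#' removed. Input order is preserved.
#'
#' @param variants Variant tibble with `total_depth` and `alt_depth`
#'   columns (`ratio` is recomputed if absent).
#' @param min_total_depth Depth threshold (default 10).
#' @param min_ratio VAF threshold (default 0.2).
#' @return The surviving rows, in input order.
#' @export
filter_depth_vaf <- function(variants, min_total_depth = 10,
                             min_ratio = 0.2) {
  if (nrow(variants) == 0) return(variants)
  ratio <- ifelse(variants$total_depth > 0,
                  variants$alt_depth / variants$total_depth, NA_real_)
  keep <- !is.na(ratio) & variants$total_depth > min_total_depth &
    ratio > min_ratio
  variants[keep, ]
}

#' Functional-consequence filter
#'
#' Keeps variants within coding exons with a non-silent protein effect and
#' variants at +/-3 of splice sites (`effect_class` of `coding_nonsilent`
#' or `splice_site_pm3`); silent and non-coding records are removed.
#' Records with a missing `effect_class` are rejected with a warning and
#' counted in the `n_missing_effect` attribute of the result.
#'
#' @param variants Variant tibble with an `effect_class` column.
#' @return The surviving rows, in input order.
#' @export
filter_functional <- function(variants) {
  if (nrow(variants) == 0) return(variants)
  missing <- is.na(variants$effect_class) | variants$effect_class == ""
  if (any(missing)) {
    warn(sprintf("%d record(s) without effect_class rejected", sum(missing)))
  }
  out <- variants[!missing &
                    variants$effect_class %in%
                    c("coding_nonsilent", "splice_site_pm3"), ]
  attr(out, "n_missing_effect") <- sum(missing)
  out
}

#' Population-rarity filter
#'
#' Keeps novel variants (no frequency in any database) and variants whose
#' frequency is strictly below `max_freq` in every database that reports
#' one. A variant common in even a single database is a likely polymorphism
#' and is removed. Frequency columns are those named `freq_*`.
#'
#' @param variants Variant tibble.
#' @param max_freq Frequency threshold (default 0.01, strict).
#' @return The surviving rows, in input order.
#' @export
filter_rarity <- function(variants, max_freq = 0.01) {
  if (nrow(variants) == 0) return(variants)
  fc <- grep("^freq_", names(variants), value = TRUE)
  if (length(fc) == 0) return(variants)
  fm <- as.matrix(variants[, fc])
  if (any(fm < 0 | fm > 1, na.rm = TRUE)) {
    abort("population frequency outside [0, 1]")
  }
  keep <- apply(fm, 1, function(r) all(is.na(r)) || all(r[!is.na(r)] < max_freq))
  variants[keep, ]
}

#' The full variant selection cascade
#'
#' Applies the three selection stages in order — depth/VAF, functional
#' consequence, population rarity — and records how many variants survive
#' each stage. Each stage is idempotent and the functional and rarity
#' stages commute, so the composition equals a single per-record predicate.
#'
#' @param variants Variant tibble.
#' @param min_total_depth,min_ratio,max_freq Stage thresholds (all strict);
#'   defaults 10, 0.2 and 0.01.
#' @return An object of class `variant_cascade`: list with `variants` (the
#'   survivors) and `counts` (tibble of per-stage surviving counts).
#'   `tidy()` returns the survivors, `glance()` the counts in one row.
#' @export
#' @examples
#' v <- tibble::tibble(
#'   sample_id = "S1", chrom = "chr1", pos = 1:3, ref = "A", alt = "T",
#'   total_depth = c(50L, 8L, 60L), alt_depth = c(20L, 4L, 30L),
#'   gene = "G1", effect_class = c("coding_nonsilent", "coding_nonsilent", "silent"),
#'   freq_dbsnp = c(NA, NA, NA)
#' )
#' glance(filter_cascade(v))
filter_cascade <- function(variants, min_total_depth = 10, min_ratio = 0.2,
                           max_freq = 0.01) {
  s1 <- filter_depth_vaf(variants, min_total_depth, min_ratio)
  s2 <- filter_functional(s1)
  s3 <- filter_rarity(s2, max_freq)
  attr(s3, "n_missing_effect") <- NULL
  counts <- tibble(
    stage = c("input", "depth_vaf", "functional", "rarity"),
    n = c(nrow(variants), nrow(s1), nrow(s2), nrow(s3))
  )
  structure(list(variants = as_tibble(s3), counts = counts,
                 params = list(min_total_depth = min_total_depth,
                               min_ratio = min_ratio, max_freq = max_freq)),
            class = "variant_cascade")
}

#' @export
print.variant_cascade <- function(x, ...) {
  cat("<variant_cascade>\n")
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-10s %d\n", x$counts$stage[i], x$counts$n[i]))
  }
  invisible(x)
}

#' @rdname filter_cascade
#' @param x A `variant_cascade`.
#' @param ... Unused.
#' @method tidy variant_cascade
#' @export
tidy.variant_cascade <- function(x, ...) x$variants

#' @rdname filter_cascade
#' @method glance variant_cascade
#' @export
glance.variant_cascade <- function(x, ...) {
  x$counts |> tidyr::pivot_wider(names_from = "stage", values_from = "n",
                                 names_prefix = "n_")
}
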