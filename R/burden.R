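#' Size of the merged capture target in megabases
#'
#' Overlapping or duplicated intervals are merged (union semantics) before
#' summing, so no base is counted twice.
#'
#' @param targets Tibble `chrom`, `start`, `end`, 1-based inclusive (as
#'   returned by [read_bed()]).
#' @return Total merged length / 1e6.
#' @export
target_size_mb <- function(targets) {
  if (nrow(targets) == 0) abort("empty target interval set")
  if (any(targets$end < targets$start)) {
    abort("invalid target interval: end < start")
  }
  total <- targets |>
    group_by(.data$chrom) |>
    group_map(function(d, key) {
      sum(IRanges::width(IRanges::reduce(IRanges::IRanges(d$start, d$end))))
    }) |>
    unlist() |>
    sum()
  total / 1e6
}

#' Somatic mutational burden per Mb of captured target
#'
#' Burden is the count of somatic variants in the burden scope — status
#' `somatic` and effect class in the coding/splice universe
#' (`coding_nonsilent`, `splice_site_pm3`) — divided by the merged capture
#' size in Mb. Undetermined variants are excluded from the numerator.
#'
#' @param classified Classified variant tibble (from [classify_cohort()]).
#' @param targets Capture target tibble (1-based inclusive).
#' @param samples Optional character vector of the sample universe, so that
#'   samples with zero somatic variants still get a row; defaults to the
#'   samples present in `classified`.
#' @return Tibble `sample_id`, `n_somatic`, `target_mb`, `burden`.
#' @export
#' @examples
#' cls <- tibble::tibble(
#'   sample_id = "T01", status = "somatic",
#'   effect_class = "coding_nonsilent", n = 1
#' )[rep(1, 17), ]
#' targets <- tibble::tibble(chrom = "chr1", start = 1, end = 34e6)
#' compute_burden(cls, targets)  # 17 / 34 Mb = 0.5 per Mb
compute_burden <- function(classified, targets, samples = NULL) {
  mb <- target_size_mb(targets)
  if (is.null(samples)) samples <- sort(unique(classified$sample_id))
  classified |>
    filter(.data$status == "somatic",
           .data$effect_class %in% SOMATIC_EFFECTS) |>
    count(.data$sample_id, name = "n_somatic") |>
    right_join(tibble(sample_id = samples), by = "sample_id") |>
    mutate(
      n_somatic = as.integer(dplyr::coalesce(.data$n_somatic, 0L)),
      target_mb = mb,
      burden = .data$n_somatic / mb
    ) |>
    arrange(.data$sample_id)
}
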