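#' Two-caller consensus over copy-number segments
#'
#' A consensus region is the intersection of a same-state segment pair
#' (one segment from each caller, same chromosome) whose reciprocal
#' overlap reaches `min_overlap` — the intersection must cover at least
#' that fraction of *each* segment — and whose uncertainty, where a
#' segment carries one, is strictly below `max_uncertainty`. A segment may
#' pair with several segments of the other caller; qualifying
#' intersections of the same state are merged when they overlap or touch.
#' Coordinates are 1-based inclusive on input and output; the interval
#' arithmetic is 0-based half-open internally.
#'
#' @param segs_a,segs_b Segment tibbles from the two callers: `sample_id`,
#'   `chrom`, `start`, `end` (1-based inclusive), `state` (`gain`/`loss`),
#'   optional `uncertainty` (percentage in \[0, 100\]). All rows must
#'   belong to one sample.
#' @param min_overlap Reciprocal overlap fraction (default 0.8, inclusive).
#' @param max_uncertainty Uncertainty ceiling (default 80, strict).
#' @return Tibble `sample_id`, `chrom`, `start`, `end`, `state`, sorted and
#'   non-overlapping within a state.
#' @export
#' @examples
#' a <- tibble::tibble(sample_id = "S", chrom = "chr1", start = 1001,
#'                     end = 2000, state = "loss", uncertainty = 10)
#' b <- tibble::tibble(sample_id = "S", chrom = "chr1", start = 1101,
#'                     end = 2100, state = "loss")
#' cnv_consensus(a, b)  # intersection 1101-2000
cnv_consensus <- function(segs_a, segs_b, min_overlap = 0.8,
                          max_uncertainty = 80) {
  samples <- unique(c(segs_a$sample_id, segs_b$sample_id))
  if (length(samples) > 1) {
    abort(sprintf("segments from several samples in one call: %s (use cnv_consensus_cohort())",
                  paste(samples, collapse = ", ")))
  }
  empty <- tibble(sample_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), state = character(0))
  if (nrow(segs_a) == 0 || nrow(segs_b) == 0) return(empty)

  prep <- function(s, tag) {
    out <- s |>
      mutate(s0 = .data$start - 1, e0 = .data$end, len = .data$end - .data$start + 1)
    if (!"uncertainty" %in% names(out)) out$uncertainty <- NA_real_
    out |> select("chrom", "state", "s0", "e0", "len",
                  uncertainty = "uncertainty") |>
      rename_with(~ paste0(.x, "_", tag), c("s0", "e0", "len", "uncertainty"))
  }
  pairs <- inner_join(prep(segs_a, "a"), prep(segs_b, "b"),
                      by = c("chrom", "state"),
                      relationship = "many-to-many") |>
    mutate(
      ov = pmin(.data$e0_a, .data$e0_b) - pmax(.data$s0_a, .data$s0_b)
    ) |>
    filter(
      .data$ov > 0,
      .data$ov >= min_overlap * .data$len_a,
      .data$ov >= min_overlap * .data$len_b,
      is.na(.data$uncertainty_a) | .data$uncertainty_a < max_uncertainty,
      is.na(.data$uncertainty_b) | .data$uncertainty_b < max_uncertainty
    )
  if (nrow(pairs) == 0) return(empty)
  pairs |>
    transmute(
      chrom = .data$chrom, state = .data$state,
      start = as.integer(pmax(.data$s0_a, .data$s0_b) + 1),
      end = as.integer(pmin(.data$e0_a, .data$e0_b))
    ) |>
    group_by(.data$chrom, .data$state) |>
    group_modify(function(d, key) {
      r <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
      tibble(start = IRanges::start(r), end = IRanges::end(r))
    }) |>
    ungroup() |>
    mutate(sample_id = samples, .before = 1) |>
    arrange(.data$chrom, .data$start, .data$state)
}

#' Per-sample consensus over a whole cohort
#'
#' @inheritParams cnv_consensus
#' @return Row-bound [cnv_consensus()] results for every sample present in
#'   either caller's table.
#' @export
cnv_consensus_cohort <- function(segs_a, segs_b, min_overlap = 0.8,
                                 max_uncertainty = 80) {
  samples <- sort(unique(c(segs_a$sample_id, segs_b$sample_id)))
  purrr::map(samples, function(sid) {
    cnv_consensus(segs_a |> filter(.data$sample_id == sid),
                  segs_b |> filter(.data$sample_id == sid),
                  min_overlap, max_uncertainty)
  }) |> list_rbind()
}

#' Remove consensus segments on polymorphic copy-number regions
#'
#' A segment is discarded when the union of its overlaps with the
#' polymorphic catalog covers at least `max_frac` of its length — such a
#' segment is most likely a population copy-number polymorphism, not a
#' somatic event.
#'
#' @param consensus Consensus segment tibble.
#' @param polymorphic Tibble of polymorphic regions (`chrom`, `start`,
#'   `end`, 1-based inclusive).
#' @param max_frac Covered-fraction threshold (default 0.5, inclusive
#'   removal).
#' @return The surviving segments.
#' @export
filter_polymorphic <- function(consensus, polymorphic, max_frac = 0.5) {
  if (nrow(consensus) == 0 || nrow(polymorphic) == 0) return(consensus)
  covered <- vapply(seq_len(nrow(consensus)), function(i) {
    p <- polymorphic |> filter(.data$chrom == consensus$chrom[i])
    if (nrow(p) == 0) return(0)
    seg <- IRanges::IRanges(consensus$start[i], consensus$end[i])
    hits <- IRanges::reduce(IRanges::restrict(
      IRanges::IRanges(p$start, p$end),
      start = consensus$start[i], end = consensus$end[i]))
    sum(IRanges::width(hits))
  }, numeric(1))
  frac <- covered / (consensus$end - consensus$start + 1)
  consensus[frac < max_frac, ]
}

#' Per-chromosome fraction of samples with gains and losses
#'
#' A sample counts at most once per (chromosome, state), whatever the
#' number of its segments there.
#'
#' @param consensus Consensus segments across the cohort.
#' @param samples Character vector: the full sample universe (denominator).
#' @param chromosomes Chromosomes to report; defaults to those seen in
#'   `consensus`.
#' @return Tibble `chrom`, `gain_fraction`, `loss_fraction`.
#' @export
chromosome_summary <- function(consensus, samples,
                               chromosomes = NULL) {
  if (is.null(chromosomes)) chromosomes <- sort(unique(consensus$chrom))
  base <- tidyr::crossing(chrom = chromosomes, state = c("gain", "loss"))
  counts <- consensus |>
    distinct(.data$chrom, .data$state, .data$sample_id) |>
    count(.data$chrom, .data$state)
  base |>
    left_join(counts, by = c("chrom", "state")) |>
    mutate(fraction = dplyr::coalesce(.data$n, 0L) / length(samples)) |>
    select("chrom", "state", "fraction") |>
    tidyr::pivot_wider(names_from = "state", values_from = "fraction",
                       names_glue = "{state}_fraction") |>
    arrange(.data$chrom)
}

#' Samples with a focal deletion overlapping a gene
#'
#' Focality is a declared length ceiling (default 3 Mb): whole-chromosome
#' or arm-level losses covering the gene do not qualify.
#'
#' @param consensus Consensus segments across the cohort.
#' @param gene_model Gene model tibble (`chrom`, `start`, `end`, `gene`).
#' @param gene Gene symbol (case-insensitive).
#' @param max_focal_len Maximum segment length, bp (default 3e6).
#' @return The qualifying loss segments, one row per (sample, segment).
#' @export
focal_gene_deletion <- function(consensus, gene_model, gene,
                                max_focal_len = 3e6) {
  g <- gene_model[str_to_upper(gene_model$gene) ==
                    str_to_upper(str_trim(gene)), ]
  if (nrow(g) == 0) abort(sprintf("gene `%s` absent from the gene model", gene))
  consensus |>
    filter(
      .data$state == "loss",
      .data$chrom == g$chrom[1],
      .data$start <= g$end[1],
      .data$end >= g$start[1],
      .data$end - .data$start + 1 <= max_focal_len
    ) |>
    mutate(gene = g$gene[1])
}
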