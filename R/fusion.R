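#' Do two fusion calls describe the same event?
#'
#' Matching is by sample and ordered gene pair: the 5'/3' orientation is
#' preserved (a swapped pair is a different event) and breakpoint
#' coordinates are deliberately ignored, since callers report different
#' breakpoint conventions for the same fusion.
#'
#' @param x,y One-row fusion-call tibbles (or lists) with `sample_id`,
#'   `gene5`, `gene3`.
#' @return Logical scalar; symmetric in its arguments.
#' @export
match_fusion_calls <- function(x, y) {
  isTRUE(x$sample_id == y$sample_id &&
           x$gene5 == y$gene5 && x$gene3 == y$gene3)
}

#' Multi-caller fusion consensus
#'
#' Keeps one record per (sample, gene5, gene3) supported by at least
#' `min_callers` *distinct* callers; duplicate calls within one caller
#' count once. The representative breakpoints come from the
#' best-supported call (ties broken by caller name, deterministically).
#'
#' @param calls Fusion-call tibble: `sample_id`, `caller`, `gene5`,
#'   `gene3`, `chrom5`, `pos5`, `chrom3`, `pos3`, `strand5`, `strand3`,
#'   `supporting_reads`.
#' @param min_callers Minimum distinct supporting callers (default 2).
#' @param callers The configured caller identifiers; an unknown `caller`
#'   value is an error.
#' @return Tibble with `n_callers`, the supporting `callers` string and
#'   representative breakpoint columns, one row per consensus fusion.
#' @export
consensus_fusions <- function(calls, min_callers = 2,
                              callers = FUSION_CALLERS) {
  unknown <- setdiff(unique(calls$caller), callers)
  if (length(unknown) > 0) {
    abort(sprintf("unknown fusion caller id(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  if (nrow(calls) == 0) {
    return(tibble(sample_id = character(0), gene5 = character(0),
                  gene3 = character(0), n_callers = integer(0),
                  callers = character(0), chrom5 = character(0),
                  pos5 = integer(0), chrom3 = character(0),
                  pos3 = integer(0), strand5 = character(0),
                  strand3 = character(0), supporting_reads = integer(0)))
  }
  calls |>
    group_by(.data$sample_id, .data$gene5, .data$gene3) |>
    arrange(desc(.data$supporting_reads), .data$caller, .by_group = TRUE) |>
    summarise(
      n_callers = n_distinct(.data$caller),
      callers = paste(sort(unique(.data$caller)), collapse = ","),
      chrom5 = first(.data$chrom5), pos5 = first(.data$pos5),
      chrom3 = first(.data$chrom3), pos3 = first(.data$pos3),
      strand5 = first(.data$strand5), strand3 = first(.data$strand3),
      supporting_reads = max(.data$supporting_reads),
      .groups = "drop"
    ) |>
    filter(.data$n_callers >= min_callers) |>
    arrange(.data$sample_id, .data$gene5, .data$gene3)
}

#' Structural triage of consensus fusions
#'
#' A fusion is `readthrough_or_conjoined` when both partners lie on the
#' same chromosome and strand and the 3' partner is the next same-strand
#' gene downstream of the 5' partner — or starts within
#' `max_readthrough_gap` of its end, in transcriptional orientation.
#' Same-chromosome events that are not read-through candidates are
#' `intra_chromosomal`; partners on different chromosomes are
#' `inter_chromosomal`. Read-through chimeras arise from transcription
#' running past a gene end into its neighbour and do not imply a genomic
#' rearrangement.
#'
#' @param consensus Consensus fusion tibble (from [consensus_fusions()]).
#' @param gene_model Gene model tibble (`chrom`, `start`, `end`, `gene`,
#'   `strand`); both partners must be present.
#' @param max_readthrough_gap Maximum 5'-end to 3'-start distance for the
#'   gap-based read-through call, bp (default 1e5).
#' @return `consensus` with a `category` column.
#' @export
classify_fusions <- function(consensus, gene_model,
                             max_readthrough_gap = 1e5) {
  if (nrow(consensus) == 0) {
    consensus$category <- character(0)
    return(consensus)
  }
  missing <- setdiff(unique(c(consensus$gene5, consensus$gene3)),
                     gene_model$gene)
  if (length(missing) > 0) {
    abort(sprintf("gene(s) absent from the gene model: %s",
                  paste(missing, collapse = ", ")))
  }
  gm <- gene_model
  i5 <- match(consensus$gene5, gm$gene)
  i3 <- match(consensus$gene3, gm$gene)

  next_downstream <- function(i) {
    same <- which(gm$chrom == gm$chrom[i] & gm$strand == gm$strand[i])
    if (gm$strand[i] == "+") {
      cand <- same[gm$start[same] > gm$end[i]]
      if (length(cand) == 0) return(NA_character_)
      gm$gene[cand[which.min(gm$start[cand])]]
    } else {
      cand <- same[gm$end[same] < gm$start[i]]
      if (length(cand) == 0) return(NA_character_)
      gm$gene[cand[which.max(gm$end[cand])]]
    }
  }

  consensus$category <- vapply(seq_len(nrow(consensus)), function(k) {
    a <- i5[k]; b <- i3[k]
    if (gm$chrom[a] != gm$chrom[b]) return("inter_chromosomal")
    if (gm$strand[a] == gm$strand[b]) {
      gap <- if (gm$strand[a] == "+") gm$start[b] - gm$end[a]
             else gm$start[a] - gm$end[b]
      is_next <- identical(next_downstream(a), gm$gene[b])
      if (is_next || (gap >= 0 && gap <= max_readthrough_gap)) {
        return("readthrough_or_conjoined")
      }
    }
    "intra_chromosomal"
  }, character(1))
  consensus
}

#' Fusions recurring across samples
#'
#' @param consensus Consensus fusion tibble (with or without `category`).
#' @return Gene pairs seen in at least two distinct samples, with their
#'   sample count and the categories observed.
#' @export
recurrent_fusions <- function(consensus) {
  if (nrow(consensus) == 0) {
    return(tibble(gene5 = character(0), gene3 = character(0),
                  n_samples = integer(0), samples = character(0),
                  categories = character(0)))
  }
  if (!"category" %in% names(consensus)) {
    consensus$category <- NA_character_
  }
  consensus |>
    group_by(.data$gene5, .data$gene3) |>
    summarise(
      n_samples = n_distinct(.data$sample_id),
      samples = paste(sort(unique(.data$sample_id)), collapse = ","),
      categories = paste(sort(unique(.data$category)), collapse = ","),
      .groups = "drop"
    ) |>
    filter(.data$n_samples >= 2) |>
    arrange(desc(.data$n_samples), .data$gene5, .data$gene3)
}
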