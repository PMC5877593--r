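CHROMOSOMES <- c(paste0("chr", 1:22), "chrX", "chrY")

# Well-known symbols pinned to fixed chromosomes so that narrative queries
# (driver recurrence, focal DMD deletion, actionable matching) have stable
# coordinates in every simulated cohort.
SPECIAL_GENES <- c(
  PDGFRA = "chr4", DMD = "chrX", TP53 = "chr17",
  IDH1 = "chr2", FBXW7 = "chr4", SDHB = "chr1"
)

#' Synthetic gene model
#'
#' Lays out equally sized genes on 24 named chromosomes, 1-based inclusive
#' coordinates, alternating gene bodies and intergenic gaps. Most genes are
#' on the plus strand with every seventh gene flipped, so adjacent
#' same-strand pairs (read-through candidates) are common. The total gene
#' span equals `target_size_mb` and the capture target is exactly the gene
#' bodies. A handful of well-known symbols (PDGFRA, DMD, TP53, IDH1, FBXW7,
#' SDHB) are assigned to fixed chromosomes; all other genes carry synthetic
#' `G####` symbols.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `chrom`, `start`, `end`, `gene`, `strand`.
#' @export
sim_gene_model <- function(config) {
  n_genes <- max(length(SPECIAL_GENES) + 24L,
                 round(config$target_size_mb * 1e6 / config$gene_length_bp))
  per_chrom <- distribute_evenly(n_genes, length(CHROMOSOMES))
  step <- config$gene_length_bp + config$gene_gap_bp
  model <- purrr::map2(CHROMOSOMES, per_chrom, function(chrom, k) {
    if (k == 0) return(NULL)
    idx <- seq_len(k)
    tibble(
      chrom = chrom,
      start = (idx - 1L) * step + 1L,
      end = (idx - 1L) * step + config$gene_length_bp,
      strand = ifelse(idx %% 7L == 0L, "-", "+")
    )
  }) |> list_rbind()
  model$gene <- sprintf("G%04d", seq_len(nrow(model)))
  # pin the named symbols to the first free slot of their chromosome
  for (sym in names(SPECIAL_GENES)) {
    i <- which(model$chrom == SPECIAL_GENES[[sym]])[1]
    while (model$gene[i] %in% names(SPECIAL_GENES)) i <- i + 1L
    model$gene[i] <- sym
  }
  model[, c("chrom", "start", "end", "gene", "strand")]
}

distribute_evenly <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

#' Capture target of the synthetic genome
#'
#' @param gene_model Output of [sim_gene_model()].
#' @return Tibble `chrom`, `start`, `end` (1-based inclusive), the gene
#'   bodies themselves.
#' @export
sim_targets <- function(gene_model) {
  gene_model[, c("chrom", "start", "end")]
}

#' Sample sheet of the synthetic cohort
#'
#' @param config A [sim_config()].
#' @return Tibble `sample_id` (`T01`, `T02`, ...), `patient_id`.
#' @export
sim_sample_map <- function(config) {
  pid <- rep(names(config$lesions_per_patient), config$lesions_per_patient)
  tibble(
    sample_id = sprintf("T%02d", seq_along(pid)),
    patient_id = pid
  )
}
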