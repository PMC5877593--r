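# shared fixtures: all built in code, deterministically

# minimal variant tibble; every argument is recycled to the longest
mk_variants <- function(total_depth, alt_depth,
                        effect_class = "coding_nonsilent",
                        freq = NA_real_, sample_id = "S1",
                        chrom = "chr1", gene = "G1") {
  n <- max(lengths(list(total_depth, alt_depth, effect_class, freq,
                        sample_id, chrom, gene)))
  tibble::tibble(
    sample_id = rep_len(sample_id, n),
    chrom = rep_len(chrom, n),
    pos = seq_len(n) * 100L,
    ref = "A", alt = "T",
    total_depth = as.integer(rep_len(total_depth, n)),
    alt_depth = as.integer(rep_len(alt_depth, n)),
    gene = rep_len(gene, n),
    effect_class = rep_len(effect_class, n),
    freq_dbsnp = rep_len(freq, n),
    freq_1kg = NA_real_
  )
}

# random annotated variants for oracle checks
random_variants <- function(n, seed) {
  withr::with_seed(seed, {
    v <- mk_variants(
      total_depth = sample(0:40, n, replace = TRUE),
      alt_depth = 0L,
      effect_class = sample(c("coding_nonsilent", "splice_site_pm3",
                              "silent", "noncoding"), n, replace = TRUE),
      freq = ifelse(runif(n) < 0.4, runif(n, 0, 0.05), NA_real_)
    )
    v$alt_depth <- vapply(v$total_depth,
                          function(d) as.integer(sample(0:d, 1)), integer(1))
    v$freq_1kg <- ifelse(runif(n) < 0.4, runif(n, 0, 0.05), NA_real_)
    v
  })
}

# tiny simulation config: fast but structurally complete
tiny_config <- function(seed = 101L, ...) {
  defaults <- list(
    n_patients = 3L,
    lesions_per_patient = c(P01 = 1L, P02 = 2L, P03 = 1L),
    target_size_mb = 5,
    germline_rate_per_mb = 2,
    common_rate_per_mb = 1,
    silent_rate_per_mb = 1,
    artifact_rate_per_mb = 1,
    n_true_cnvs = 2L,
    n_polymorphic_cnvs = 1L,
    n_true_fusions = 2L,
    n_readthrough_events = 1L,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# toy gene model with controllable geometry (1-based inclusive)
toy_gene_model <- function() {
  tibble::tibble(
    chrom  = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr14", "chr14"),
    start  = c(1000L, 11000L, 30000L, 200000L, 1000L, 500000L, 1000L, 41000000L),
    end    = c(6000L, 16000L, 35000L, 205000L, 6000L, 505000L, 6000L, 41005000L),
    gene   = c("GA", "GB", "GC", "GD", "GE", "GF", "GH", "GI"),
    strand = c("+", "+", "-", "+", "+", "+", "+", "+")
  )
}
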