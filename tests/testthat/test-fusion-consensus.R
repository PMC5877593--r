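mk_call <- function(sample_id, caller, gene5, gene3, reads = 10L) {
  tibble::tibble(
    sample_id = sample_id, caller = caller, gene5 = gene5, gene3 = gene3,
    chrom5 = "chr1", pos5 = 100L, chrom3 = "chr2", pos3 = 200L,
    strand5 = "+", strand3 = "+", supporting_reads = as.integer(reads))
}

CALLERS <- c("tophat_fusion", "defuse", "chimerascan", "fusionmap")

# brute force: count distinct callers per (sample, ordered gene pair)
consensus_brute <- function(calls, min_callers = 2) {
  key <- paste(calls$sample_id, calls$gene5, calls$gene3, sep = "|")
  tab <- tapply(calls$caller, key, function(x) length(unique(x)))
  sort(names(tab)[tab >= min_callers])
}

test_that("voting needs two distinct callers; within-caller duplicates collapse", {
  calls <- dplyr::bind_rows(
    mk_call("S1", "defuse", "GX", "GY"),
    mk_call("S1", "fusionmap", "GX", "GY"),
    mk_call("S1", "defuse", "GA", "GB"),        # single caller
    mk_call("S1", "chimerascan", "GC", "GD"),
    mk_call("S1", "chimerascan", "GC", "GD"),   # duplicate within caller
    mk_call("S1", "defuse", "GY", "GX")         # swapped pair: different event
  )
  out <- consensus_fusions(calls)
  expect_equal(nrow(out), 1)
  expect_equal(out$gene5, "GX")
  expect_equal(out$n_callers, 2L)
  expect_equal(out$callers, "defuse,fusionmap")

  expect_equal(nrow(consensus_fusions(calls, min_callers = 5)), 0)
  expect_error(consensus_fusions(mk_call("S1", "mystery", "GX", "GY")),
               "unknown fusion caller")
})

test_that("ordered gene-pair matching ignores breakpoint coordinates", {
  x <- mk_call("S1", "defuse", "GX", "GY")
  y <- mk_call("S1", "fusionmap", "GX", "GY")
  y$pos5 <- 2100L  # 2 kb away
  expect_true(match_fusion_calls(x, y))
  expect_true(match_fusion_calls(y, x))
  expect_false(match_fusion_calls(x, mk_call("S1", "defuse", "GY", "GX")))
  expect_false(match_fusion_calls(x, mk_call("S2", "defuse", "GX", "GY")))
})

test_that("consensus equals distinct-caller brute force on random calls", {
  calls <- withr::with_seed(15, {
    n <- 500
    tibble::tibble(
      sample_id = sample(sprintf("S%d", 1:5), n, replace = TRUE),
      caller = sample(CALLERS, n, replace = TRUE),
      gene5 = sample(sprintf("G%02d", 1:15), n, replace = TRUE),
      gene3 = sample(sprintf("H%02d", 1:15), n, replace = TRUE),
      chrom5 = "chr1", pos5 = sample.int(1e6, n), chrom3 = "chr2",
      pos3 = sample.int(1e6, n), strand5 = "+", strand3 = "+",
      supporting_reads = sample.int(50, n, replace = TRUE))
  })
  out <- consensus_fusions(calls)
  got <- sort(paste(out$sample_id, out$gene5, out$gene3, sep = "|"))
  expect_identical(got, consensus_brute(calls))

  # permuting input order changes nothing
  shuffled <- withr::with_seed(1, calls[sample.int(nrow(calls)), ])
  expect_identical(as.data.frame(consensus_fusions(shuffled)),
                   as.data.frame(out))
})

test_that("structural triage separates read-through from rearrangements", {
  gm <- toy_gene_model()
  cons <- consensus_fusions(dplyr::bind_rows(
    mk_call("S1", "defuse", "GA", "GB"),
    mk_call("S1", "fusionmap", "GA", "GB"),     # adjacent, same strand, 5 kb
    mk_call("S1", "defuse", "GA", "GD"),
    mk_call("S1", "fusionmap", "GA", "GD"),     # same chrom, far, not next
    mk_call("S1", "defuse", "GA", "GE"),
    mk_call("S1", "fusionmap", "GA", "GE"),     # different chromosomes
    mk_call("S1", "defuse", "GA", "GC"),
    mk_call("S1", "fusionmap", "GA", "GC")      # strand mismatch
  ))
  out <- classify_fusions(cons, gm)
  cat_of <- function(g3) out$category[out$gene3 == g3]
  expect_equal(cat_of("GB"), "readthrough_or_conjoined")
  expect_equal(cat_of("GD"), "intra_chromosomal")
  expect_equal(cat_of("GE"), "inter_chromosomal")
  expect_equal(cat_of("GC"), "intra_chromosomal")

  # next same-strand downstream neighbour qualifies beyond the gap too
  cons_gd <- consensus_fusions(dplyr::bind_rows(
    mk_call("S1", "defuse", "GB", "GD"),
    mk_call("S1", "fusionmap", "GB", "GD")))
  expect_equal(classify_fusions(cons_gd, gm)$category,
               "readthrough_or_conjoined")

  expect_error(classify_fusions(
    consensus_fusions(dplyr::bind_rows(
      mk_call("S1", "defuse", "NOPE", "GB"),
      mk_call("S1", "fusionmap", "NOPE", "GB"))), gm), "absent")
})

test_that("recurrence requires at least two distinct samples", {
  cons <- dplyr::bind_rows(
    consensus_fusions(dplyr::bind_rows(
      mk_call("S1", "defuse", "GX", "GY"),
      mk_call("S1", "fusionmap", "GX", "GY"))),
    consensus_fusions(dplyr::bind_rows(
      mk_call("S2", "defuse", "GX", "GY"),
      mk_call("S2", "fusionmap", "GX", "GY"))),
    consensus_fusions(dplyr::bind_rows(
      mk_call("S1", "defuse", "GA", "GB"),
      mk_call("S1", "fusionmap", "GA", "GB")))
  )
  cons$category <- c("readthrough_or_conjoined", "readthrough_or_conjoined",
                     "intra_chromosomal")
  rec <- recurrent_fusions(cons)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$gene5, "GX")
  expect_equal(rec$n_samples, 2L)
  expect_equal(rec$categories, "readthrough_or_conjoined")
  expect_equal(nrow(recurrent_fusions(cons[0, ])), 0)
})

test_that("simulated true fusions are recovered and caller-private calls removed", {
  co <- simulate_cohort(tiny_config(seed = 55L))
  cons <- consensus_fusions(co$fusions)
  got <- paste(cons$sample_id, cons$gene5, cons$gene3, sep = "|")
  want <- paste(co$truth$true_fusions$sample_id,
                co$truth$true_fusions$gene5,
                co$truth$true_fusions$gene3, sep = "|")
  expect_setequal(got, want)

  # triage recovers the generator's structural category
  cat_got <- classify_fusions(cons, co$gene_model)
  joined <- dplyr::inner_join(
    cat_got, co$truth$true_fusions,
    by = c("sample_id", "gene5", "gene3"), suffix = c("", ".true"))
  expect_equal(joined$category, joined$category.true)
})
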