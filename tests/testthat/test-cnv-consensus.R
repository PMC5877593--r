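test_that("worked examples of the pairing rule behave as specified", {
  a <- tibble::tibble(sample_id = "S", chrom = "chr1", start = 1001L,
                      end = 2000L, state = "loss", uncertainty = 10)
  b <- tibble::tibble(sample_id = "S", chrom = "chr1", start = 1101L,
                      end = 2100L, state = "loss")
  # 900 bp intersection, 90% of both 1 kb segments
  out <- cnv_consensus(a, b)
  expect_equal(out[, c("start", "end", "state")],
               tibble::tibble(start = 1101L, end = 2000L, state = "loss"))

  # state disagreement: no consensus even with full overlap
  b_gain <- dplyr::mutate(b, state = "gain", start = 1001L, end = 2000L)
  expect_equal(nrow(cnv_consensus(a, b_gain)), 0)

  # uncertainty at/above the ceiling removes the pair
  a85 <- dplyr::mutate(a, uncertainty = 85)
  expect_equal(nrow(cnv_consensus(a85, b)), 0)
  a80 <- dplyr::mutate(a, uncertainty = 80)
  expect_equal(nrow(cnv_consensus(a80, b)), 0)  # strict "< 80"

  # identical segments: consensus is the segment itself
  ident <- cnv_consensus(a, dplyr::select(a, -"uncertainty"))
  expect_equal(ident$start, 1001L)
  expect_equal(ident$end, 2000L)

  expect_error(
    cnv_consensus(a, dplyr::mutate(b, sample_id = "OTHER")),
    "several samples")
})

test_that("consensus equals per-base brute force on random toy chromosomes", {
  withr::with_seed(99, {
    n_nonempty <- 0
    for (rep in 1:100) {
      p <- random_seg_pair()
      got <- consensus_bases_pkg(cnv_consensus(p$a, p$b))
      want <- consensus_bases_brute(p$a, p$b)
      expect_identical(got, want)
      if (length(want$gain) + length(want$loss) > 0) {
        n_nonempty <- n_nonempty + 1
      }
    }
    expect_gt(n_nonempty, 30)  # the check is not vacuous
  })
})

test_that("swapping caller roles leaves the consensus unchanged", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      p <- random_seg_pair()
      fwd <- cnv_consensus(p$a, p$b)
      rev <- cnv_consensus(p$b, p$a)
      expect_identical(as.data.frame(fwd), as.data.frame(rev))
    }
  })
})

test_that("consensus bases never extend outside either caller's coverage", {
  withr::with_seed(7, {
    n_rows <- 0
    for (rep in 1:20) {
      pair <- random_seg_pair()
      a <- pair$a
      b <- pair$b
      cons <- cnv_consensus(a, b)
      n_rows <- n_rows + nrow(cons)
      for (i in seq_len(nrow(cons))) {
        bases <- cons$start[i]:cons$end[i]
        cov_a <- unlist(lapply(which(a$state == cons$state[i]),
                               function(k) a$start[k]:a$end[k]))
        cov_b <- unlist(lapply(which(b$state == cons$state[i]),
                               function(k) b$start[k]:b$end[k]))
        expect_true(all(bases %in% cov_a) && all(bases %in% cov_b))
      }
    }
    expect_gt(n_rows, 0)
  })
})

test_that("polymorphic-region filter removes mostly-covered segments", {
  cons <- tibble::tibble(
    sample_id = "S", chrom = "chr1",
    start = c(1000L, 5000L, 9000L), end = c(1999L, 5999L, 9999L),
    state = "loss")
  poly <- tibble::tibble(chrom = "chr1",
                         start = c(900L, 5000L), end = c(2100L, 5399L))
  out <- filter_polymorphic(cons, poly)
  # first: fully inside -> removed; second: 40% covered -> kept
  expect_equal(out$start, c(5000L, 9000L))
  expect_identical(filter_polymorphic(cons, poly[0, ]), cons)
})

test_that("chromosome summary counts each sample once per state", {
  segs <- tibble::tibble(
    sample_id = sprintf("T%02d", 1:8), chrom = "chrX",
    start = 1000L, end = 2000L, state = "loss")
  segs <- dplyr::bind_rows(segs, dplyr::mutate(segs[1, ], start = 5000L,
                                               end = 6000L))
  samples <- sprintf("T%02d", 1:19)
  s <- chromosome_summary(segs, samples)
  expect_equal(s$loss_fraction, 8 / 19)
  expect_equal(s$gain_fraction, 0)

  all14 <- tibble::tibble(sample_id = samples, chrom = "chr14",
                          start = 1L, end = 100L, state = "loss")
  expect_equal(chromosome_summary(all14, samples)$loss_fraction, 1)
  empty <- chromosome_summary(all14[0, ], samples, chromosomes = "chr1")
  expect_equal(empty$gain_fraction, 0)
})

test_that("focal deletion query respects overlap, state and length", {
  gm <- toy_gene_model()
  cons <- tibble::tibble(
    sample_id = c("T1", "T2", "T3", "T4"), chrom = "chr14",
    start = c(40900000L, 1L, 39000000L, 41000100L),
    end = c(41400000L, 50000000L, 39500000L, 41001000L),
    state = c("loss", "loss", "loss", "gain"))
  hit <- focal_gene_deletion(cons, gm, "GI")
  # 500 kb loss over the gene qualifies; a 50 Mb chromosome-scale loss is
  # not focal; a loss elsewhere does not overlap; a gain never qualifies
  expect_equal(hit$sample_id, "T1")
  expect_error(focal_gene_deletion(cons, gm, "NOSUCH"), "absent")
})

test_that("simulated true CNVs are recovered and caller-private segments are not", {
  co <- simulate_cohort(tiny_config(seed = 47L, n_true_cnvs = 4L))
  cons <- filter_polymorphic(
    cnv_consensus_cohort(co$cnv_a, co$cnv_b),
    co$polymorphic_regions)
  tr <- co$truth$true_cnvs
  reciprocal_hit <- function(seg, pool, frac) {
    cand <- pool[pool$sample_id == seg$sample_id &
                   pool$chrom == seg$chrom & pool$state == seg$state, ]
    if (nrow(cand) == 0) return(FALSE)
    ov <- pmin(cand$end, seg$end) - pmax(cand$start, seg$start) + 1
    any(ov >= frac * (seg$end - seg$start + 1) &
          ov >= frac * (cand$end - cand$start + 1))
  }
  for (i in seq_len(nrow(tr))) {
    expect_true(reciprocal_hit(tr[i, ], cons, 0.8))
  }
  # no consensus segment without substantial same-state truth support
  for (i in seq_len(nrow(cons))) {
    seg <- cons[i, ]
    cand <- tr[tr$sample_id == seg$sample_id & tr$chrom == seg$chrom &
                 tr$state == seg$state, ]
    ov <- if (nrow(cand) == 0) 0 else
      max(pmin(cand$end, seg$end) - pmax(cand$start, seg$start) + 1)
    expect_gte(ov, 0.5 * (seg$end - seg$start + 1))
  }
})
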