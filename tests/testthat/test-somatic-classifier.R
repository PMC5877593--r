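# independent oracle: the matched-normal decision rule written as explicit
# branching over a single (total, alt) pair
status_oracle <- function(total, alt) {
  if (total < 5) return("undetermined")
  if (total == 5) return("undetermined")  # boundary treated as uninformative
  if (alt == 0) return("somatic")
  if (alt == 1 && total >= 15) return("somatic")
  if (alt == 2 && total >= 30) return("somatic")
  "germline"
}

test_that("canonical normal-count patterns classify as documented", {
  expect_equal(somatic_status(20, 0), "somatic")
  expect_equal(somatic_status(16, 1), "somatic")
  expect_equal(somatic_status(30, 2), "somatic")
  expect_equal(somatic_status(4, 0), "undetermined")
  expect_equal(somatic_status(30, 3), "germline")
  expect_equal(somatic_status(14, 1), "germline")
  expect_equal(somatic_status(29, 2), "germline")
  expect_equal(somatic_status(5, 0), "undetermined")  # boundary depth
  expect_equal(somatic_status(NA, 0), "undetermined")
})

test_that("classifier agrees with exhaustive truth-table evaluation", {
  grid <- do.call(rbind, lapply(0:40, function(td)
    data.frame(total = td, alt = 0:td)))
  expected <- mapply(status_oracle, grid$total, grid$alt)
  got <- somatic_status(grid$total, grid$alt)
  expect_identical(got, unname(expected))
})

test_that("more alternate reads never turn a germline call somatic", {
  for (td in 6:40) {
    s <- somatic_status(rep(td, td + 1), 0:td)
    first_germline <- match("germline", s)
    if (!is.na(first_germline)) {
      expect_false("somatic" %in% s[first_germline:length(s)])
    }
  }
})

test_that("cohort classification joins pileups and flags missing loci", {
  v <- mk_variants(total_depth = 50L, alt_depth = 25L)
  v <- v[rep(1, 3), ]
  v$pos <- c(100L, 200L, 300L)
  smap <- tibble::tibble(sample_id = "S1", patient_id = "P1")
  pu <- tibble::tibble(
    patient_id = "P1", chrom = "chr1", pos = c(100L, 200L), ref = "A",
    A = c(20L, 10L), C = 0L, G = 0L, T = c(0L, 10L), indel = 0L,
    total_depth = c(20L, 20L)
  )
  out <- classify_cohort(v, pu, smap)
  expect_equal(out$status, c("somatic", "germline", "undetermined"))
  expect_equal(out$pileup_missing, c(FALSE, FALSE, TRUE))
  expect_equal(attr(out, "missing_pileup_fraction"), 1 / 3)

  # empty pileup: everything undetermined
  empty <- classify_cohort(v, pu[0, ], smap)
  expect_true(all(empty$status == "undetermined"))

  expect_error(classify_cohort(v, dplyr::bind_rows(pu, pu[1, ]), smap),
               "duplicate pileup")
  expect_error(classify_cohort(v, pu, smap[0, ]), "missing from sample map")
})

test_that("indel alternates are counted from the indel column", {
  v <- mk_variants(total_depth = 50L, alt_depth = 25L)
  v$ref <- "AT"
  v$alt <- "A"
  pu <- tibble::tibble(
    patient_id = "P1", chrom = "chr1", pos = 100L, ref = "AT",
    A = 22L, C = 0L, G = 0L, T = 0L, indel = 8L, total_depth = 30L
  )
  out <- classify_cohort(v, pu,
                         tibble::tibble(sample_id = "S1", patient_id = "P1"))
  expect_equal(out$normal_alt_depth, 8L)
  expect_equal(out$status, "germline")
})

test_that("gene recurrence separates sample- and patient-level counts", {
  v <- mk_variants(total_depth = 50L, alt_depth = 25L,
                   sample_id = c("T07", "T08", "T09", "T10", "T11"))
  smap <- tibble::tibble(
    sample_id = c("T07", "T08", "T09", "T10", "T11", "T01"),
    patient_id = c(rep("P06", 5), "P01"))
  rep1 <- recurrent_genes(v, smap)
  expect_equal(rep1$n_samples, 5L)
  expect_equal(rep1$n_patients, 1L)
  expect_true(rep1$same_patient_only)

  v2 <- dplyr::bind_rows(v, mk_variants(50L, 25L, sample_id = "T01"))
  rep2 <- recurrent_genes(v2, smap)
  expect_equal(rep2$n_patients, 2L)
  expect_false(rep2$same_patient_only)

  expect_equal(nrow(recurrent_genes(v[0, ], smap)), 0)
  expect_error(recurrent_genes(mk_variants(50L, 25L, sample_id = "ZZ"),
                               smap), "missing from sample map")
})

test_that("expressed fraction counts mutated genes expressed in their sample", {
  v <- mk_variants(50L, 25L, gene = c("GA", "GB", "GC"))
  v$pos <- c(1L, 2L, 3L)
  expr <- tibble::tibble(
    gene = c("GA", "GB", "GC"), sample_id = "S1", expr = c(10, 0.2, 0))
  expect_equal(expressed_fraction(v, expr), 1 / 3)
  expr$expr <- c(10, 5, 2)
  expect_equal(expressed_fraction(v, expr), 1)
  expect_equal(expressed_fraction(v, expr[0, ]), 0)
})

test_that("actionable matching is case-insensitive on symbols", {
  v <- mk_variants(50L, 25L, gene = c("tp53 ", "PDGFRA", "G999"))
  lst <- tibble::tibble(gene = c("TP53", "pdgfra"),
                        annotation = c("a", "b"))
  out <- match_actionable(v, lst)
  expect_equal(nrow(out), 2)
  expect_equal(out$actionable_annotation, c("a", "b"))
  expect_equal(nrow(match_actionable(v, lst[0, ])), 0)
})
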