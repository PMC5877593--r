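test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(truncal_fraction = 1.5), "truncal_fraction")
  expect_error(sim_config(somatic_rate_per_mb = -1), "somatic_rate_per_mb")
  expect_error(sim_config(n_patients = 2,
                          lesions_per_patient = c(P01 = 1L)),
               "lesions_per_patient")
  expect_error(sim_config(n_true_fusions = 1, n_readthrough_events = 2),
               "n_readthrough_events")
  expect_error(generate_patient_lesions("P01", 0, tiny_config()),
               "n_lesions")
})

test_that("zero mutation rates leave only the driver locus per sample", {
  cfg <- tiny_config(somatic_rate_per_mb = 0, germline_rate_per_mb = 0,
                     common_rate_per_mb = 0, silent_rate_per_mb = 0,
                     artifact_rate_per_mb = 0)
  co <- simulate_cohort(cfg)
  drv <- co$truth$driver_locus
  expect_equal(nrow(co$variants), nrow(co$sample_map))
  expect_true(all(co$variants$chrom == drv$chrom &
                    co$variants$pos == drv$pos &
                    co$variants$gene == drv$gene))
  expect_setequal(co$variants$sample_id, co$sample_map$sample_id)
})

test_that("truncal_fraction at the extremes controls lesion sharing", {
  cfg <- tiny_config(truncal_fraction = 1, artifact_rate_per_mb = 0)
  pl <- withr::with_seed(5, generate_patient_lesions("P", 3, cfg))
  sets <- split(paste0(pl$variants$chrom, ":", pl$variants$pos),
                pl$variants$sample_id)
  expect_length(unique(lapply(sets, sort)), 1)
  expect_true(all(pl$clonal$category == "truncal"))

  cfg0 <- tiny_config(truncal_fraction = 0, partial_fraction = 0)
  pl0 <- withr::with_seed(5, generate_patient_lesions("P", 3, cfg0))
  truncal <- pl0$clonal[pl0$clonal$category == "truncal", ]
  expect_equal(nrow(truncal), 1)
  expect_true(truncal$is_driver)
})

test_that("identical seeds give bit-identical cohorts and file trees", {
  cfg <- tiny_config(seed = 77L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$variants, c2$variants)
  expect_identical(c1$truth, c2$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
})

test_that("every emitted record is labeled except depth/VAF-failing artifacts", {
  co <- simulate_cohort(tiny_config(seed = 31L))
  unlabeled <- dplyr::anti_join(
    co$variants, co$truth$variant_labels,
    by = c("sample_id", "chrom", "pos", "ref", "alt"))
  expect_true(all(unlabeled$total_depth <= 10 | unlabeled$ratio <= 0.2))
  # and all labels point at emitted records
  dangling <- dplyr::anti_join(
    co$truth$variant_labels, co$variants,
    by = c("sample_id", "chrom", "pos", "ref", "alt"))
  expect_equal(nrow(dangling), 0)
})

test_that("somatic counts are calibrated to rate x target size", {
  # 200 single-lesion samples at 0.5/Mb on a 30 Mb target: mean true
  # somatic count per sample ~ 15 within 3 standard errors
  cfg <- sim_config(
    n_patients = 200L,
    lesions_per_patient = setNames(rep(1L, 200), sprintf("P%03d", 1:200)),
    germline_rate_per_mb = 0, common_rate_per_mb = 0,
    silent_rate_per_mb = 0, artifact_rate_per_mb = 0,
    n_true_cnvs = 0L, n_polymorphic_cnvs = 0L, focal_deletion_frac = 0,
    n_true_fusions = 0L, n_readthrough_events = 0L, caller_fp_rate = 0,
    seed = 404L
  )
  co <- simulate_cohort(cfg)
  counts <- dplyr::count(co$truth$variant_labels, sample_id)
  expect_equal(nrow(counts), 200)
  expected <- cfg$somatic_rate_per_mb * cfg$target_size_mb
  se <- sd(counts$n) / sqrt(nrow(counts))
  expect_lt(abs(mean(counts$n) - expected), 3 * se + 1 / nrow(counts))
})

test_that("the driver is somatic and truncal everywhere", {
  co <- simulate_cohort(tiny_config(seed = 13L))
  drv <- co$truth$driver_locus
  lab <- dplyr::filter(co$truth$variant_labels,
                       chrom == drv$chrom, pos == drv$pos)
  expect_setequal(lab$sample_id, co$sample_map$sample_id)
  expect_true(all(lab$label == "somatic"))
  cl <- dplyr::filter(co$truth$clonal_assignment,
                      chrom == drv$chrom, pos == drv$pos)
  expect_true(all(cl$category == "truncal"))
})
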