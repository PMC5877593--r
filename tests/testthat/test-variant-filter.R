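# independent per-record predicate: the cascade re-expressed as plain
# if/else logic, used as the oracle
cascade_predicate <- function(v, min_depth = 10, min_ratio = 0.2,
                              max_freq = 0.01) {
  vapply(seq_len(nrow(v)), function(i) {
    if (v$total_depth[i] <= min_depth) return(FALSE)
    if (v$total_depth[i] == 0) return(FALSE)
    if (v$alt_depth[i] / v$total_depth[i] <= min_ratio) return(FALSE)
    if (!(v$effect_class[i] %in% c("coding_nonsilent", "splice_site_pm3"))) {
      return(FALSE)
    }
    for (f in c(v$freq_dbsnp[i], v$freq_1kg[i])) {
      if (!is.na(f) && f >= max_freq) return(FALSE)
    }
    TRUE
  }, logical(1))
}

test_that("depth/VAF thresholds are strict, boundaries excluded", {
  v <- mk_variants(total_depth = c(11L, 10L, 50L, 50L, 0L),
                   alt_depth = c(3L, 9L, 10L, 11L, 0L))
  kept <- filter_depth_vaf(v)
  # 11x with ratio 0.27 survives; depth exactly 10 fails however high the
  # ratio; ratio exactly 0.2 fails; zero depth fails
  expect_equal(kept$pos, c(100L, 400L))
  expect_identical(filter_depth_vaf(v[0, ]), v[0, ])
})

test_that("functional filter keeps non-silent coding and splice-region records", {
  v <- mk_variants(total_depth = 50L, alt_depth = 20L,
                   effect_class = c("silent", "splice_site_pm3",
                                    "coding_nonsilent", "noncoding"))
  expect_equal(filter_functional(v)$effect_class,
               c("splice_site_pm3", "coding_nonsilent"))
  v$effect_class[1] <- NA
  expect_warning(out <- filter_functional(v), "without effect_class")
  expect_equal(attr(out, "n_missing_effect"), 1L)
})

test_that("rarity keeps novel records and those rare in every database", {
  v <- mk_variants(total_depth = 50L, alt_depth = 20L,
                   freq = c(NA, 0.05, 0.009, 0.009))
  v$freq_1kg <- c(NA, NA, 0.009, 0.02)
  out <- filter_rarity(v)
  expect_equal(out$pos, c(100L, 300L))  # novel and all-rare survive
  v$freq_dbsnp[1] <- 1.5
  expect_error(filter_rarity(v), "outside")
})

test_that("the cascade composes the three stages with monotone counts", {
  v <- dplyr::bind_rows(
    mk_variants(9L, 5L),                                  # fails depth
    mk_variants(50L, 5L),                                 # fails ratio
    mk_variants(50L, 25L, effect_class = "silent"),       # fails effect
    mk_variants(50L, 25L, freq = 0.2),                    # fails rarity
    mk_variants(50L, 25L)                                 # survives
  )
  v$pos <- seq_len(nrow(v)) * 10L
  res <- filter_cascade(v)
  expect_s3_class(res, "variant_cascade")
  expect_equal(res$counts$n, c(5L, 3L, 2L, 1L))
  expect_true(all(diff(res$counts$n) <= 0))
  expect_equal(tidy(res)$pos, 50L)
  expect_named(glance(res),
               c("n_input", "n_depth_vaf", "n_functional", "n_rarity"))

  all_pass <- mk_variants(rep(50L, 4), rep(25L, 4))
  expect_equal(tidy(filter_cascade(all_pass)), all_pass)
})

test_that("filters are idempotent and functional/rarity commute", {
  v <- random_variants(400, seed = 20)
  f1 <- filter_depth_vaf(v)
  expect_identical(filter_depth_vaf(f1), f1)
  f2 <- suppressWarnings(filter_functional(v))
  expect_identical(as.data.frame(suppressWarnings(filter_functional(f2))),
                   as.data.frame(f2))
  f3 <- filter_rarity(v)
  expect_identical(filter_rarity(f3), f3)
  ab <- filter_rarity(filter_functional(v))
  ba <- filter_functional(filter_rarity(v))
  expect_identical(as.data.frame(ab), as.data.frame(ba))
  expect_identical(as.data.frame(filter_depth_vaf(filter_rarity(v))),
                   as.data.frame(filter_rarity(filter_depth_vaf(v))))
})

test_that("cascade equals independent per-record predicate on random input", {
  v <- random_variants(1000, seed = 7)
  res <- filter_cascade(v)
  expect_identical(as.data.frame(tidy(res)),
                   as.data.frame(v[cascade_predicate(v), ]))
  counts_brute <- c(
    nrow(v),
    sum(v$total_depth > 10 & v$alt_depth / v$total_depth > 0.2, na.rm = TRUE)
  )
  expect_equal(res$counts$n[1:2], counts_brute)
})
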