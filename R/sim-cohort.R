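FREQ_COLS <- c("freq_dbsnp", "freq_1kg", "freq_evs", "freq_exac")
FUSION_CALLERS <- c("tophat_fusion", "defuse", "chimerascan", "fusionmap")

# negative-binomial depth truncated below at `min`
rdepth <- function(n, mean, size, min = 0L) {
  if (n == 0) return(integer(0))
  x <- rnbinom(n, mu = mean, size = size)
  while (any(bad <- x < min)) {
    x[bad] <- rnbinom(sum(bad), mu = mean, size = size)
  }
  as.integer(x)
}

# Beta VAF centred on `mean` with concentration k, truncated below at `min`
rvaf <- function(n, mean, k, min = 0) {
  if (n == 0) return(numeric(0))
  x <- rbeta(n, mean * k, (1 - mean) * k)
  while (any(bad <- x < min)) {
    x[bad] <- rbeta(sum(bad), mean * k, (1 - mean) * k)
  }
  x
}

# alt-read draw conditioned on exceeding a ratio floor (caller detectability)
ralt_detectable <- function(depth, vaf, min_ratio) {
  alt <- rbinom(length(depth), depth, vaf)
  while (any(bad <- alt / depth <= min_ratio | alt == 0)) {
    alt[bad] <- rbinom(sum(bad), depth[bad], vaf[bad])
  }
  as.integer(alt)
}

# distinct loci inside gene bodies, avoiding `exclude` (chrom:pos keys)
sample_loci <- function(n, gene_model, exclude = character(0)) {
  out <- NULL
  while (n > 0) {
    gi <- sample.int(nrow(gene_model), n, replace = TRUE)
    pos <- gene_model$start[gi] +
      floor(runif(n) * (gene_model$end[gi] - gene_model$start[gi] + 1))
    cand <- tibble(
      chrom = gene_model$chrom[gi],
      pos = as.integer(pos),
      gene = gene_model$gene[gi]
    )
    cand <- cand[!duplicated(paste0(cand$chrom, ":", cand$pos)), ]
    cand <- cand[!(paste0(cand$chrom, ":", cand$pos) %in% exclude), ]
    out <- bind_rows(out, cand)
    exclude <- c(exclude, paste0(cand$chrom, ":", cand$pos))
    n <- n - nrow(cand)
  }
  out
}

BASES <- c("A", "C", "G", "T")

draw_alleles <- function(n, indel_frac = 0.05) {
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
  is_indel <- runif(n) < indel_frac
  ins <- is_indel & runif(n) < 0.5
  alt[ins] <- paste0(ref[ins], sample(BASES, sum(ins), replace = TRUE))
  del <- is_indel & !ins
  ref[del] <- paste0(ref[del], sample(BASES, sum(del), replace = TRUE))
  alt[del] <- substr(ref[del], 1, 1)
  list(ref = unname(ref), alt = unname(alt))
}

driver_locus_of <- function(gene_model) {
  row <- gene_model[gene_model$gene == "PDGFRA", ]
  list(gene = "PDGFRA", chrom = row$chrom, pos = row$start + 1000L,
       ref = "A", alt = "T")
}

#' Generate the variant tables of one patient's lesions
#'
#' Draws the patient's germline background and somatic variants, assigns
#' each somatic variant a clonal category (truncal in all lesions, partial
#' in a strict subset, or private to one lesion), and emits per-lesion
#' tumor caller records plus one matched-normal pileup. The designated
#' driver locus (PDGFRA) is truncal in every patient. Caller false-positive
#' records (which fail the depth/VAF filter by construction) carry no truth
#' label.
#'
#' Uses the current RNG state; seed externally (or via [simulate_cohort()],
#' which seeds from its config) for reproducibility.
#'
#' @param patient_id Patient identifier.
#' @param n_lesions Number of lesions (>= 1).
#' @param config A [sim_config()].
#' @param gene_model Gene model from [sim_gene_model()]; built from `config`
#'   if omitted.
#' @param sample_ids Optional sample ids for the lesions (default
#'   `<patient>_L1`, ...).
#' @return List with `variants` (tumor caller records, all lesions),
#'   `pileup` (matched-normal allele counts per locus), `labels`
#'   (somatic/germline truth per emitted labeled record) and `clonal`
#'   (per-variant clonal category; non-empty only for n_lesions >= 2).
#' @export
generate_patient_lesions <- function(patient_id, n_lesions, config,
                                     gene_model = NULL, sample_ids = NULL) {
  if (n_lesions < 1) abort("n_lesions must be >= 1")
  if (is.null(gene_model)) gene_model <- sim_gene_model(config)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("%s_L%d", patient_id, seq_len(n_lesions))
  }
  stopifnot(length(sample_ids) == n_lesions)
  tmb <- config$target_size_mb
  drv <- driver_locus_of(gene_model)
  used <- paste0(drv$chrom, ":", drv$pos)

  ## ---- patient-level loci -------------------------------------------------
  n_rare <- rpois(1, config$germline_rate_per_mb * tmb)
  n_common <- rpois(1, config$common_rate_per_mb * tmb)
  n_silent <- rpois(1, config$silent_rate_per_mb * tmb)

  mk_germline <- function(n, kind) {
    if (n == 0) return(NULL)
    loci <- sample_loci(n, gene_model, used)
    used <<- c(used, paste0(loci$chrom, ":", loci$pos))
    al <- draw_alleles(n)
    eff <- switch(kind,
      rare = sample(c("coding_nonsilent", "splice_site_pm3"), n, TRUE,
                    prob = c(0.85, 0.15)),
      common = rep("coding_nonsilent", n),
      silent = sample(c("silent", "noncoding"), n, TRUE)
    )
    fq <- switch(kind,
      rare = matrix(ifelse(runif(n * 4) < 0.7, runif(n * 4, 0, 0.0095), NA),
                    nrow = n),
      common = matrix(runif(n * 4, 0.02, 0.5), nrow = n),
      silent = matrix(NA_real_, nrow = n, ncol = 4)
    )
    colnames(fq) <- FREQ_COLS
    bind_cols(loci, tibble(ref = al$ref, alt = al$alt, effect_class = eff),
              as_tibble(fq)) |>
      mutate(vaf_normal = rvaf(n, 0.5, 40), label = "germline")
  }
  germ <- bind_rows(
    mk_germline(n_rare, "rare"),
    mk_germline(n_common, "common"),
    mk_germline(n_silent, "silent")
  )

  ## somatic budget: each *lesion* sees an expected somatic_rate_per_mb x
  ## target_mb variants; the truncal/partial/private split preserves that
  ## per-lesion expectation, and the driver occupies one truncal slot
  lam <- config$somatic_rate_per_mb * tmb
  t_frac <- config$truncal_fraction
  p_frac <- if (n_lesions >= 3) min(config$partial_fraction, 1 - t_frac) else 0
  priv_frac <- max(0, 1 - t_frac - p_frac)
  n_truncal <- max(rpois(1, t_frac * lam) - 1L, 0L)
  n_private <- rpois(n_lesions, priv_frac * lam)
  kbar <- if (n_lesions >= 3) mean(2:(n_lesions - 1)) else 1
  n_partial <- if (p_frac > 0) rpois(1, p_frac * lam * n_lesions / kbar) else 0L

  lesion_sets <- c(
    list(seq_len(n_lesions)),                                   # driver
    rep(list(seq_len(n_lesions)), n_truncal),
    unlist(lapply(seq_len(n_lesions), function(li)
      rep(list(li), n_private[li])), recursive = FALSE),
    lapply(seq_len(n_partial), function(i) {
      k <- if (n_lesions == 3) 2L else sample(2:(n_lesions - 1), 1)
      sort(sample.int(n_lesions, k))
    })
  )
  n_som <- length(lesion_sets) - 1L
  som_loci <- if (n_som > 0) sample_loci(n_som, gene_model, used) else NULL
  if (!is.null(som_loci)) {
    used <- c(used, paste0(som_loci$chrom, ":", som_loci$pos))
  }
  som <- bind_rows(
    tibble(chrom = drv$chrom, pos = drv$pos, gene = drv$gene,
           ref = drv$ref, alt = drv$alt, effect_class = "coding_nonsilent",
           is_driver = TRUE),
    if (!is.null(som_loci)) {
      al <- draw_alleles(n_som)
      bind_cols(som_loci,
                tibble(ref = al$ref, alt = al$alt,
                       effect_class = sample(
                         c("coding_nonsilent", "splice_site_pm3"),
                         n_som, TRUE, prob = c(0.9, 0.1)),
                       is_driver = FALSE))
    }
  )
  for (fc in FREQ_COLS) som[[fc]] <- NA_real_
  som$vaf_tumor <- rvaf(nrow(som), config$tumor_vaf_mean,
                        config$vaf_concentration, config$somatic_min_emit_vaf)
  som$lesion_set <- lesion_sets
  som$category <- vapply(som$lesion_set, function(s) {
    if (length(s) == n_lesions) "truncal"
    else if (length(s) == 1L) "private" else "partial"
  }, character(1))

  ## ---- per-lesion tumor records -------------------------------------------
  lesion_tbl <- function(li) {
    sid <- sample_ids[li]
    g <- NULL
    if (!is.null(germ) && nrow(germ) > 0) {
      dp <- rdepth(nrow(germ), config$tumor_depth_mean,
                   config$depth_dispersion, min = 1L)
      ad <- as.integer(rbinom(nrow(germ), dp, germ$vaf_normal))
      g <- germ |>
        select(-"vaf_normal", -"label") |>
        mutate(sample_id = sid, total_depth = dp, alt_depth = ad)
    }
    s_idx <- which(vapply(som$lesion_set, function(s) li %in% s, logical(1)))
    s <- NULL
    if (length(s_idx) > 0) {
      dp <- rdepth(length(s_idx), config$tumor_depth_mean,
                   config$depth_dispersion,
                   min = config$somatic_min_emit_depth)
      ad <- ralt_detectable(dp, som$vaf_tumor[s_idx],
                            config$somatic_min_emit_vaf)
      s <- som[s_idx, c("chrom", "pos", "gene", "ref", "alt",
                        "effect_class", FREQ_COLS)] |>
        mutate(sample_id = sid, total_depth = dp, alt_depth = ad)
    }
    ## caller false positives: always fail the depth/VAF stage
    n_art <- rpois(1, config$artifact_rate_per_mb * tmb)
    a <- NULL
    if (n_art > 0) {
      loci <- sample_loci(n_art, gene_model, used)
      used <<- c(used, paste0(loci$chrom, ":", loci$pos))
      al <- draw_alleles(n_art)
      shallow <- runif(n_art) < 0.5
      dp <- ifelse(shallow, sample(1:10, n_art, TRUE),
                   rdepth(n_art, config$tumor_depth_mean,
                          config$depth_dispersion, min = 20L))
      ad <- ifelse(shallow, pmax(1L, rbinom(n_art, dp, 0.3)),
                   floor(runif(n_art) * 0.2 * dp))
      a <- bind_cols(loci, tibble(ref = al$ref, alt = al$alt)) |>
        mutate(effect_class = "coding_nonsilent", sample_id = sid,
               total_depth = as.integer(dp), alt_depth = as.integer(ad))
      for (fc in FREQ_COLS) a[[fc]] <- NA_real_
    }
    bind_rows(g, s, a)
  }
  variants <- purrr::map(seq_len(n_lesions), lesion_tbl) |>
    list_rbind() |>
    mutate(
      ratio = ifelse(.data$total_depth > 0,
                     .data$alt_depth / .data$total_depth, NA_real_),
      caller = "snv_caller"
    ) |>
    select("sample_id", "chrom", "pos", "ref", "alt", "total_depth",
           "alt_depth", "ratio", "gene", "effect_class",
           all_of(FREQ_COLS), "caller") |>
    arrange(.data$sample_id, .data$chrom, .data$pos, .data$alt)

  ## ---- matched-normal pileup (one normal per patient) ---------------------
  loci <- variants |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt)
  has_germ <- !is.null(germ) && nrow(germ) > 0
  germ_keys <- if (has_germ) paste0(germ$chrom, ":", germ$pos) else character(0)
  som_keys <- paste0(som$chrom, ":", som$pos)
  key <- paste0(loci$chrom, ":", loci$pos)
  is_germ <- key %in% germ_keys
  is_som <- key %in% som_keys
  nl <- nrow(loci)
  ## the driver is a molecularly confirmed locus: its normal coverage is
  ## never left uninformative
  low <- runif(nl) < config$low_depth_frac &
    !(key == paste0(drv$chrom, ":", drv$pos))
  dp <- ifelse(low, rdepth(nl, 3, 5), rdepth(nl, config$normal_depth_mean,
                                             config$depth_dispersion))
  ad <- integer(nl)
  if (has_germ) {
    vafg <- germ$vaf_normal[match(key, germ_keys)]
    ad[is_germ] <- rbinom(sum(is_germ), dp[is_germ], vafg[is_germ])
  }
  contam <- is_som & runif(nl) < config$normal_contam_frac
  ad[contam] <- pmin(dp[contam], sample(1:2, sum(contam), TRUE))
  pileup <- build_pileup(loci, as.integer(dp), as.integer(ad)) |>
    mutate(patient_id = patient_id, .before = 1) |>
    arrange(.data$chrom, .data$pos)

  ## ---- truth --------------------------------------------------------------
  labels <- bind_rows(
    if (!is.null(germ) && nrow(germ) > 0) {
      tidyr::crossing(sample_id = sample_ids,
                      germ[, c("chrom", "pos", "ref", "alt")]) |>
        mutate(label = "germline")
    },
    purrr::map(seq_len(n_lesions), function(li) {
      s_idx <- which(vapply(som$lesion_set, function(s) li %in% s,
                            logical(1)))
      som[s_idx, c("chrom", "pos", "ref", "alt")] |>
        mutate(sample_id = sample_ids[li], label = "somatic")
    }) |> list_rbind()
  ) |>
    select("sample_id", "chrom", "pos", "ref", "alt", "label") |>
    arrange(.data$sample_id, .data$chrom, .data$pos, .data$alt)

  clonal <- if (n_lesions >= 2) {
    som |>
      mutate(
        patient_id = patient_id,
        lesions = vapply(.data$lesion_set, function(s)
          paste(sample_ids[s], collapse = ","), character(1))
      ) |>
      select("patient_id", "chrom", "pos", "ref", "alt", "gene",
             "category", "lesions", "is_driver") |>
      arrange(.data$chrom, .data$pos)
  } else {
    tibble(patient_id = character(0), chrom = character(0),
           pos = integer(0), ref = character(0), alt = character(0),
           gene = character(0), category = character(0),
           lesions = character(0), is_driver = logical(0))
  }

  list(variants = variants, pileup = pileup, labels = labels,
       clonal = clonal)
}

# pileup rows (A/C/G/T/indel counts) from per-locus normal depth/alt counts
build_pileup <- function(loci, depth, alt_count) {
  n <- nrow(loci)
  m <- matrix(0L, nrow = n, ncol = 4, dimnames = list(NULL, BASES))
  is_indel <- nchar(loci$ref) > 1 | nchar(loci$alt) > 1
  refbase <- substr(loci$ref, 1, 1)
  indel <- integer(n)
  for (i in seq_len(n)) {
    if (is_indel[i]) {
      indel[i] <- alt_count[i]
      m[i, refbase[i]] <- depth[i] - alt_count[i]
    } else {
      m[i, loci$alt[i]] <- alt_count[i]
      m[i, refbase[i]] <- depth[i] - alt_count[i]
    }
  }
  bind_cols(loci[, c("chrom", "pos", "ref")], as_tibble(m)) |>
    mutate(indel = indel, total_depth = as.integer(depth))
}
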