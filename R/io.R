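VCF_INFO_KEYS <- c(
  DP = "total_depth", VD = "alt_depth", GENE = "gene", EFF = "effect_class",
  DBSNP_AF = "freq_dbsnp", KG_AF = "freq_1kg", EVS_AF = "freq_evs",
  EXAC_AF = "freq_exac"
)

#' Write a simulated cohort to disk as caller-style files
#'
#' Materialises a [simulate_cohort()] result as the file tree a downstream
#' analysis would consume: one VCF v4.2 per tumor sample, one pileup TSV per
#' patient (the matched normal), two CNV segment TSVs per sample (caller A
#' carries an uncertainty column), four fusion TSVs per sample, gene-model
#' and capture-target BEDs, the sample map, a wide expression table, a
#' polymorphic-region BED, the ground truth as JSON, and the generating
#' configuration as YAML. Identical cohorts produce byte-identical trees.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create output directory `%s`", dir))
  write_bed(cohort$gene_model |>
              mutate(score = 0L) |>
              select("chrom", "start", "end", "gene", "score", "strand"),
            file.path(dir, "genes.bed"))
  write_bed(cohort$targets, file.path(dir, "targets.bed"))
  write_bed(cohort$polymorphic_regions,
            file.path(dir, "polymorphic_regions.bed"))
  readr::write_tsv(cohort$sample_map, file.path(dir, "sample_map.tsv"))
  cohort$expression |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "expr") |>
    readr::write_tsv(file.path(dir, "expression.tsv"))

  for (sid in cohort$sample_map$sample_id) {
    write_variants_vcf(cohort$variants |> filter(.data$sample_id == sid),
                       file.path(dir, sprintf("%s.tumor.vcf", sid)))
    cohort$cnv_a |> filter(.data$sample_id == sid) |>
      readr::write_tsv(file.path(dir, sprintf("%s.cnv_callerA.tsv", sid)))
    cohort$cnv_b |> filter(.data$sample_id == sid) |>
      readr::write_tsv(file.path(dir, sprintf("%s.cnv_callerB.tsv", sid)))
    for (cl in FUSION_CALLERS) {
      cohort$fusions |>
        filter(.data$sample_id == sid, .data$caller == cl) |>
        readr::write_tsv(file.path(dir, sprintf("%s.fusions.%s.tsv", sid, cl)))
    }
  }
  for (pid in unique(cohort$sample_map$patient_id)) {
    cohort$pileups |> filter(.data$patient_id == pid) |>
      readr::write_tsv(file.path(dir, sprintf("%s.normal_pileup.tsv", pid)))
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- unclass(cohort$config)
  cfg$lesions_per_patient <- as.list(cfg$lesions_per_patient)
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory holding the cohort files.
#' @return A list shaped like a `sim_cohort` (class `sim_cohort`), with the
#'   truth tables when `truth.json` is present.
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("cohort directory `%s` does not exist", dir))
  sample_map <- readr::read_tsv(file.path(dir, "sample_map.tsv"),
                                show_col_types = FALSE)
  gene_model <- read_bed(file.path(dir, "genes.bed"),
                         c("chrom", "start", "end", "gene", "score", "strand")) |>
    select(-"score")
  targets <- read_bed(file.path(dir, "targets.bed"))
  poly <- read_bed(file.path(dir, "polymorphic_regions.bed"),
                   c("chrom", "start", "end", "region_id"))
  expression <- readr::read_tsv(file.path(dir, "expression.tsv"),
                                show_col_types = FALSE) |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "expr")

  variants <- purrr::map(sample_map$sample_id, function(sid) {
    read_variants_vcf(file.path(dir, sprintf("%s.tumor.vcf", sid)), sid)
  }) |> list_rbind()
  cnv_a <- purrr::map(sample_map$sample_id, function(sid) {
    readr::read_tsv(file.path(dir, sprintf("%s.cnv_callerA.tsv", sid)),
                    show_col_types = FALSE)
  }) |> list_rbind()
  cnv_b <- purrr::map(sample_map$sample_id, function(sid) {
    readr::read_tsv(file.path(dir, sprintf("%s.cnv_callerB.tsv", sid)),
                    show_col_types = FALSE)
  }) |> list_rbind()
  fusions <- purrr::map(sample_map$sample_id, function(sid) {
    purrr::map(FUSION_CALLERS, function(cl) {
      f <- file.path(dir, sprintf("%s.fusions.%s.tsv", sid, cl))
      readr::read_tsv(f, show_col_types = FALSE,
                      col_types = readr::cols(
                        sample_id = "c", caller = "c", gene5 = "c",
                        gene3 = "c", chrom5 = "c", chrom3 = "c"))
    }) |> list_rbind()
  }) |> list_rbind()
  pileups <- purrr::map(unique(sample_map$patient_id), function(pid) {
    readr::read_tsv(file.path(dir, sprintf("%s.normal_pileup.tsv", pid)),
                    show_col_types = FALSE)
  }) |> list_rbind()

  truth <- NULL
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    raw <- jsonlite::fromJSON(truth_path)
    as_tbl <- function(x) if (length(x) == 0) tibble() else as_tibble(x)
    truth <- list(
      variant_labels = as_tbl(raw$variant_labels),
      clonal_assignment = as_tbl(raw$clonal_assignment),
      true_cnvs = as_tbl(raw$true_cnvs),
      true_fusions = as_tbl(raw$true_fusions),
      driver_locus = raw$driver_locus
    )
  }
  config <- NULL
  cfg_path <- file.path(dir, "sim_config.yaml")
  if (file.exists(cfg_path)) {
    cfg <- yaml::read_yaml(cfg_path)
    cfg$lesions_per_patient <- unlist(cfg$lesions_per_patient)
    cfg$seed <- as.integer(cfg$seed)
    config <- structure(cfg, class = "sim_config")
  }
  structure(list(
    config = config, gene_model = gene_model, targets = targets,
    sample_map = sample_map, variants = variants, pileups = pileups,
    cnv_a = cnv_a, cnv_b = cnv_b, polymorphic_regions = poly,
    fusions = fusions, expression = expression, truth = truth
  ), class = "sim_cohort")
}

#' Write tumor variant records as VCF v4.2
#'
#' Depths, gene, effect class and per-database population frequencies are
#' carried as INFO keys (`DP`, `VD`, `GENE`, `EFF`, `DBSNP_AF`, `KG_AF`,
#' `EVS_AF`, `EXAC_AF`); absent frequencies are omitted.
#'
#' @param variants Variant tibble (one sample).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=somaticflow_simulator",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total tumor depth">',
    '##INFO=<ID=VD,Number=1,Type=Integer,Description="Alternate-supporting tumor depth">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=EFF,Number=1,Type=String,Description="Effect class">',
    '##INFO=<ID=DBSNP_AF,Number=1,Type=Float,Description="dbSNP-like population frequency">',
    '##INFO=<ID=KG_AF,Number=1,Type=Float,Description="1000G-like population frequency">',
    '##INFO=<ID=EVS_AF,Number=1,Type=Float,Description="EVS-like population frequency">',
    '##INFO=<ID=EXAC_AF,Number=1,Type=Float,Description="ExAC-like population frequency">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  info <- vapply(seq_len(nrow(variants)), function(i) {
    parts <- c(
      sprintf("DP=%d", variants$total_depth[i]),
      sprintf("VD=%d", variants$alt_depth[i]),
      sprintf("GENE=%s", variants$gene[i]),
      sprintf("EFF=%s", variants$effect_class[i])
    )
    for (k in c("DBSNP_AF", "KG_AF", "EVS_AF", "EXAC_AF")) {
      col <- VCF_INFO_KEYS[[k]]
      if (!col %in% names(variants)) next
      v <- variants[[col]][i]
      if (!is.na(v)) parts <- c(parts, sprintf("%s=%.6g", k, v))
    }
    paste(parts, collapse = ";")
  }, character(1))
  body <- if (nrow(variants) == 0) character(0) else {
    paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
          ".", "PASS", info, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an annotated tumor VCF into the canonical variant tibble
#'
#' Parses with `vcfR` and lifts the INFO annotations written by
#' [write_variants_vcf()] (or an equivalently annotated VCF) into columns.
#' Multi-allelic rows are split into per-alternate records before any
#' filtering, since the depth/VAF rule applies per alternate allele.
#'
#' @param path VCF file.
#' @param sample_id Sample identifier to stamp on the records.
#' @return Variant tibble with depths, `ratio`, `gene`, `effect_class` and
#'   `freq_*` columns.
#' @export
read_variants_vcf <- function(path, sample_id) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) {
    return(tibble(sample_id = character(0), chrom = character(0),
                  pos = integer(0), ref = character(0), alt = character(0),
                  total_depth = integer(0), alt_depth = integer(0),
                  ratio = numeric(0), gene = character(0),
                  effect_class = character(0), freq_dbsnp = numeric(0),
                  freq_1kg = numeric(0), freq_evs = numeric(0),
                  freq_exac = numeric(0), caller = character(0)))
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  out <- tibble(
    sample_id = sample_id,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    total_depth = as.integer(vcfR::extract.info(vcf, "DP", as.numeric = TRUE)),
    alt_depth = as.integer(vcfR::extract.info(vcf, "VD", as.numeric = TRUE)),
    gene = vcfR::extract.info(vcf, "GENE"),
    effect_class = vcfR::extract.info(vcf, "EFF"),
    freq_dbsnp = vcfR::extract.info(vcf, "DBSNP_AF", as.numeric = TRUE),
    freq_1kg = vcfR::extract.info(vcf, "KG_AF", as.numeric = TRUE),
    freq_evs = vcfR::extract.info(vcf, "EVS_AF", as.numeric = TRUE),
    freq_exac = vcfR::extract.info(vcf, "EXAC_AF", as.numeric = TRUE),
    caller = "snv_caller"
  )
  out <- split_multiallelic(out)
  out$ratio <- ifelse(out$total_depth > 0,
                      out$alt_depth / out$total_depth, NA_real_)
  out |> select("sample_id", "chrom", "pos", "ref", "alt", "total_depth",
                "alt_depth", "ratio", everything())
}

#' Split multi-allelic variant records into per-alternate rows
#'
#' Rows whose `alt` holds a comma-separated allele list become one row per
#' allele. A comma-separated `alt_depth` is distributed across the alleles;
#' a scalar `alt_depth` is kept only for the first allele (the others get
#' `NA`, there being no per-allele evidence to carry).
#'
#' @param variants Variant tibble.
#' @return Variant tibble with one alternate allele per row.
#' @export
split_multiallelic <- function(variants) {
  multi <- str_detect(variants$alt, ",")
  if (!any(multi)) return(variants)
  keep <- variants[!multi, ]
  expanded <- purrr::map(which(multi), function(i) {
    alts <- strsplit(variants$alt[i], ",", fixed = TRUE)[[1]]
    ads <- if (is.character(variants$alt_depth[i]) &&
               str_detect(as.character(variants$alt_depth[i]), ",")) {
      as.integer(strsplit(as.character(variants$alt_depth[i]), ",")[[1]])
    } else {
      c(as.integer(variants$alt_depth[i]),
        rep(NA_integer_, length(alts) - 1))
    }
    rows <- variants[rep(i, length(alts)), ]
    rows$alt <- alts
    rows$alt_depth <- ads
    rows
  }) |> list_rbind()
  bind_rows(keep, expanded) |>
    arrange(.data$sample_id, .data$chrom, .data$pos, .data$alt)
}

#' Read a BED file into 1-based inclusive coordinates
#'
#' BED input is 0-based half-open; the returned tibble is 1-based inclusive
#' (`start = bed_start + 1`), the convention used throughout the package.
#'
#' @param path BED file.
#' @param col_names Column names (first three must be chrom/start/end).
#' @return Tibble with at least `chrom`, `start`, `end`.
#' @export
read_bed <- function(path, col_names = c("chrom", "start", "end")) {
  x <- readr::read_tsv(path, col_names = col_names, show_col_types = FALSE)
  if (any(x$end <= x$start)) {
    abort(sprintf("invalid interval in `%s`: end <= start", path))
  }
  x$start <- as.integer(x$start + 1L)
  x$end <- as.integer(x$end)
  x
}

#' Write 1-based inclusive intervals as BED (0-based half-open)
#'
#' @param x Tibble whose first three columns are chrom, start, end
#'   (1-based inclusive); extra columns are carried through.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x$start <- x$start - 1L
  readr::write_tsv(x, path, col_names = FALSE)
  invisible(path)
}
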