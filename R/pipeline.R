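#' Assemble a pipeline run configuration
#'
#' Collects every threshold of the downstream analysis in one place, with
#' the documented defaults: variant selection `total depth > 10`,
#' `ratio > 0.2`, `population frequency < 0.01`; matched-normal rule
#' thresholds 5/15/30; CNV consensus reciprocal `overlap >= 0.8` with
#' `uncertainty < 80`; fusion consensus `>= 2` distinct callers. Every
#' parameter can be overridden, and a configuration can equally be read
#' from YAML via [run_pipeline()].
#'
#' @param input_dir Directory of cohort files ([write_cohort()] layout).
#'   Leave `NULL` when `sim` is given.
#' @param out_dir Output directory for the consolidated report.
#' @param sim Optional list of [sim_config()] overrides; when present the
#'   cohort is simulated (with `seed`) into `out_dir/cohort` and analysed.
#' @param seed Integer seed for a simulated run.
#' @param min_total_depth,min_ratio,max_freq Variant-filter thresholds.
#' @param min_normal_depth,alt1_min_depth,alt2_min_depth Somatic-rule
#'   thresholds.
#' @param cnv_min_overlap,cnv_max_uncertainty,polymorphic_max_frac CNV
#'   consensus thresholds.
#' @param fusion_min_callers,max_readthrough_gap Fusion thresholds.
#' @param focal_gene,max_focal_len Focal-deletion query.
#' @param min_expr Expression threshold for the expressed-gene cross-check.
#' @param actionable_path TSV of actionable genes (`gene`, `annotation`);
#'   defaults to the small illustrative list shipped with the package.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, out_dir = tempfile("somaticflow_"),
                       sim = NULL, seed = 1L,
                       min_total_depth = 10, min_ratio = 0.2,
                       max_freq = 0.01,
                       min_normal_depth = 5, alt1_min_depth = 15,
                       alt2_min_depth = 30,
                       cnv_min_overlap = 0.8, cnv_max_uncertainty = 80,
                       polymorphic_max_frac = 0.5,
                       fusion_min_callers = 2, max_readthrough_gap = 1e5,
                       focal_gene = "DMD", max_focal_len = 3e6,
                       min_expr = 1,
                       actionable_path = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Range and existence checks only; the configuration is never modified.
#'
#' @param config A [run_config()] (or plain list with its fields).
#' @return Tibble of violations (`field`, `problem`); zero rows when the
#'   configuration is valid.
#' @export
validate_run_config <- function(config) {
  v <- list()
  bad <- function(field, problem) v[[length(v) + 1]] <<-
    tibble(field = field, problem = problem)
  in01 <- function(f) {
    x <- config[[f]]
    if (!is.numeric(x) || length(x) != 1 || x < 0 || x > 1) {
      bad(f, "must be a single number in [0, 1]")
    }
  }
  for (f in c("min_ratio", "max_freq", "cnv_min_overlap",
              "polymorphic_max_frac")) in01(f)
  pos <- function(f) {
    x <- config[[f]]
    if (!is.numeric(x) || length(x) != 1 || x < 0) {
      bad(f, "must be a single non-negative number")
    }
  }
  for (f in c("min_total_depth", "min_normal_depth", "alt1_min_depth",
              "alt2_min_depth", "cnv_max_uncertainty", "fusion_min_callers",
              "max_readthrough_gap", "max_focal_len", "min_expr")) pos(f)
  if (is.numeric(config$fusion_min_callers) &&
      length(config$fusion_min_callers) == 1 &&
      config$fusion_min_callers < 1) {
    bad("fusion_min_callers", "must be >= 1")
  }
  if (is.null(config$input_dir) && is.null(config$sim)) {
    bad("input_dir", "either input_dir or sim must be given")
  }
  if (!is.null(config$input_dir) && !dir.exists(config$input_dir)) {
    bad("input_dir", sprintf("directory `%s` does not exist",
                             config$input_dir))
  }
  if (!is.null(config$actionable_path) &&
      !file.exists(config$actionable_path)) {
    bad("actionable_path", sprintf("file `%s` does not exist",
                                   config$actionable_path))
  }
  if (length(v) == 0) {
    tibble(field = character(0), problem = character(0))
  } else {
    list_rbind(v)
  }
}

default_actionable <- function() {
  system.file("extdata", "actionable_genes.tsv", package = "somaticflow")
}

#' Run the whole downstream analysis
#'
#' Orchestrates the full run on a cohort directory (or a freshly simulated
#' cohort): variant filter cascade, somatic classification against the
#' matched normals, mutational burden, gene recurrence, expression
#' cross-check, actionable-gene matching, CNV consensus with polymorphism
#' filtering and chromosome summary, focal-deletion query, fusion
#' consensus with structural triage and recurrence, and clonal
#' partitioning of every multi-lesion patient. Writes a consolidated
#' `report.json` plus per-table TSVs under `out_dir`; runs with the same
#' configuration and seed are byte-identical.
#'
#' @param config A [run_config()], a plain list of its fields, or the path
#'   to a YAML file holding them.
#' @return The report (class `somaticflow_report`), invisibly a list of
#'   all result tables and summary scalars.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(run_config, yaml::read_yaml(config))
  }
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  violations <- validate_run_config(config)
  if (nrow(violations) > 0) {
    abort(paste0("invalid run configuration:\n", paste(
      sprintf("  %s: %s", violations$field, violations$problem),
      collapse = "\n")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (!is.null(config$sim)) {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    ch <- simulate_cohort(do.call(sim_config, sim_args))
    write_cohort(ch, file.path(config$out_dir, "cohort"))
    ch
  } else {
    read_cohort(config$input_dir)
  }
  samples <- cohort$sample_map$sample_id

  ## variant cascade and somatic classification
  cascade <- filter_cascade(cohort$variants, config$min_total_depth,
                            config$min_ratio, config$max_freq)
  classified <- classify_cohort(tidy(cascade), cohort$pileups,
                                cohort$sample_map,
                                config$min_normal_depth,
                                config$alt1_min_depth,
                                config$alt2_min_depth)
  somatic <- classified |> filter(.data$status == "somatic")
  status_counts <- classified |> count(.data$status)

  burden <- compute_burden(classified, cohort$targets, samples)
  recurrence <- recurrent_genes(somatic, cohort$sample_map)
  expressed <- if (!is.null(cohort$expression)) {
    expressed_fraction(somatic, cohort$expression, config$min_expr)
  } else NA_real_
  actionable_tbl <- readr::read_tsv(
    config$actionable_path %||% default_actionable(),
    show_col_types = FALSE)
  actionable <- match_actionable(somatic, actionable_tbl)

  ## copy number
  consensus <- cnv_consensus_cohort(cohort$cnv_a, cohort$cnv_b,
                                    config$cnv_min_overlap,
                                    config$cnv_max_uncertainty)
  consensus_f <- filter_polymorphic(consensus, cohort$polymorphic_regions,
                                    config$polymorphic_max_frac)
  cnv_summary <- chromosome_summary(consensus_f, samples,
                                    sort(unique(cohort$gene_model$chrom)))
  focal <- if (any(str_to_upper(cohort$gene_model$gene) ==
                   str_to_upper(config$focal_gene))) {
    focal_gene_deletion(consensus_f, cohort$gene_model, config$focal_gene,
                        config$max_focal_len)
  } else NULL

  ## fusions
  fusions <- consensus_fusions(cohort$fusions, config$fusion_min_callers) |>
    classify_fusions(cohort$gene_model, config$max_readthrough_gap)
  fusion_recurrent <- recurrent_fusions(fusions)

  ## clonal partitions for multi-lesion patients
  multi <- cohort$sample_map |>
    count(.data$patient_id) |>
    filter(.data$n >= 2) |>
    pull("patient_id")
  partitions <- purrr::map(multi, function(pid) {
    sids <- cohort$sample_map$sample_id[cohort$sample_map$patient_id == pid]
    clonal_partition(
      somatic |> filter(.data$sample_id %in% sids,
                        .data$effect_class %in% SOMATIC_EFFECTS),
      lesions = sids, patient_id = pid)
  }) |> setNames(multi)

  report <- structure(list(
    seed = config$seed,
    params = config[c("min_total_depth", "min_ratio", "max_freq",
                      "min_normal_depth", "alt1_min_depth",
                      "alt2_min_depth", "cnv_min_overlap",
                      "cnv_max_uncertainty", "polymorphic_max_frac",
                      "fusion_min_callers", "max_readthrough_gap",
                      "focal_gene", "max_focal_len", "min_expr")],
    stage_counts = cascade$counts,
    status_counts = status_counts,
    missing_pileup_fraction = attr(classified, "missing_pileup_fraction"),
    burden = burden,
    mean_burden = mean(burden$burden),
    recurrence = recurrence,
    expressed_fraction = expressed,
    actionable = actionable,
    cnv_consensus = consensus_f,
    n_cnv_consensus = nrow(consensus),
    n_cnv_after_polymorphic = nrow(consensus_f),
    cnv_summary = cnv_summary,
    focal_deletions = focal,
    fusions = fusions,
    fusion_recurrent = fusion_recurrent,
    clonal = partitions
  ), class = "somaticflow_report")

  write_report(report, classified, config$out_dir)
  report
}

write_report <- function(report, classified, out_dir) {
  readr::write_tsv(classified, file.path(out_dir, "variant_status.tsv"))
  readr::write_tsv(report$burden, file.path(out_dir, "burden.tsv"))
  readr::write_tsv(report$recurrence, file.path(out_dir, "recurrence.tsv"))
  readr::write_tsv(report$cnv_consensus,
                   file.path(out_dir, "cnv_consensus.tsv"))
  readr::write_tsv(report$cnv_summary, file.path(out_dir, "cnv_summary.tsv"))
  readr::write_tsv(report$fusions, file.path(out_dir, "fusions.tsv"))
  for (pid in names(report$clonal)) {
    readr::write_tsv(tidy(report$clonal[[pid]]),
                     file.path(out_dir, sprintf("clonal_%s.tsv", pid)))
  }
  json <- list(
    seed = report$seed,
    params = report$params,
    stage_counts = report$stage_counts,
    status_counts = report$status_counts,
    missing_pileup_fraction = report$missing_pileup_fraction,
    burden = report$burden,
    mean_burden = report$mean_burden,
    expressed_fraction = report$expressed_fraction,
    n_actionable = nrow(report$actionable),
    n_cnv_consensus = report$n_cnv_consensus,
    n_cnv_after_polymorphic = report$n_cnv_after_polymorphic,
    cnv_summary = report$cnv_summary,
    n_focal_deletion_samples = if (is.null(report$focal_deletions)) 0L
      else dplyr::n_distinct(report$focal_deletions$sample_id),
    n_consensus_fusions = nrow(report$fusions),
    fusion_categories = report$fusions |> count(.data$category),
    n_recurrent_fusions = nrow(report$fusion_recurrent),
    clonal = purrr::map(report$clonal, glance)
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.somaticflow_report <- function(x, ...) {
  cat("<somaticflow_report>\n")
  cat(sprintf("  variants: %s\n",
              paste(sprintf("%s=%d", x$stage_counts$stage,
                            x$stage_counts$n), collapse = " -> ")))
  cat(sprintf("  status: %s\n",
              paste(sprintf("%s=%d", x$status_counts$status,
                            x$status_counts$n), collapse = ", ")))
  cat(sprintf("  mean burden: %.3f /Mb; consensus CNVs: %d; consensus fusions: %d\n",
              x$mean_burden, x$n_cnv_after_polymorphic, nrow(x$fusions)))
  cat(sprintf("  clonal partitions: %s\n",
              paste(names(x$clonal), collapse = ", ")))
  invisible(x)
}
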