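#' Simulation configuration for a synthetic tumor/normal cohort
#'
#' Builds the parameter set that drives [simulate_cohort()]. The defaults
#' describe a desk-scale whole-exome cohort: 14 patients (two of them with
#' multiple metastatic lesions, 19 tumor samples in all), a 30 Mb capture
#' target sequenced at a mean depth of 60x, roughly 0.5 somatic mutations
#' per Mb, and one designated driver locus (PDGFRA) shared by every tumor.
#'
#' Rates are per megabase of capture target and are expectations of Poisson
#' counts. Sequencing depths are negative-binomial around the configured
#' means (capture data is over-dispersed relative to Poisson); variant
#' allele fractions are Beta-distributed around `tumor_vaf_mean` for clonal
#' somatic variants and around 0.5 for germline variants.
#'
#' Emitted somatic records are drawn conditional on caller-style
#' detectability (`somatic_min_emit_depth`, `somatic_min_emit_vaf`):
#' a variant appears in a lesion's call table only if it would have been
#' called there, which mirrors real caller output and keeps shared variants
#' observable in every lesion that carries them.
#'
#' @param n_patients Number of patients.
#' @param lesions_per_patient Named integer vector mapping patient id to its
#'   lesion count. Default: one lesion each, except the fourth patient (2
#'   lesions) and the sixth (5 lesions), emulating a cohort with two
#'   multi-metastasis cases.
#' @param target_size_mb Megabases of capture target (gene bodies of the
#'   synthetic gene model).
#' @param somatic_rate_per_mb Expected somatic mutations per Mb per sample.
#' @param germline_rate_per_mb Expected rare (population frequency < 1%)
#'   non-silent germline variants per Mb per patient.
#' @param common_rate_per_mb Expected common polymorphisms per Mb (rarity
#'   filter fodder; population frequency well above 1%).
#' @param silent_rate_per_mb Expected silent/non-coding germline records per
#'   Mb (functional-filter fodder).
#' @param artifact_rate_per_mb Expected caller false-positive records per Mb
#'   per lesion; these fail the depth/VAF filter by construction and carry
#'   no truth label.
#' @param truncal_fraction Probability that a somatic variant of a
#'   multi-lesion patient is truncal (shared by all lesions). The driver is
#'   always truncal.
#' @param partial_fraction Probability that a non-truncal somatic variant of
#'   a patient with >= 3 lesions is shared by a strict subset (>1) of
#'   lesions.
#' @param tumor_depth_mean,normal_depth_mean Mean sequencing depths.
#' @param depth_dispersion Negative-binomial size parameter for depths.
#' @param tumor_vaf_mean Mean VAF of clonal somatic variants (< 0.5 reflects
#'   tumor purity below 1).
#' @param vaf_concentration Beta concentration (a+b) for VAF draws.
#' @param somatic_min_emit_depth,somatic_min_emit_vaf Caller-style
#'   detectability floor for emitted somatic records (see Details).
#' @param normal_contam_frac Fraction of somatic loci whose matched normal
#'   receives 1-2 alternate reads (tumor-in-normal contamination); default 0.
#' @param low_depth_frac Fraction of loci with a poorly covered normal
#'   (mean depth 3), exercising the "undetermined" branch.
#' @param n_true_cnvs True copy-number segments per sample.
#' @param cnv_boundary_jitter_bp Per-caller uniform jitter applied to true
#'   segment boundaries.
#' @param n_polymorphic_cnvs Polymorphic (population) CNVs per sample; they
#'   sit on shared polymorphic regions and are not somatic truth.
#' @param focal_deletion_frac Fraction of samples given a focal deletion of
#'   `focal_deletion_gene` (rounded to a whole number of samples).
#' @param focal_deletion_gene Gene symbol targeted by the focal deletion.
#' @param n_true_fusions True fusion events per sample.
#' @param n_readthrough_events How many of the true fusions are read-through
#'   transcripts between adjacent same-strand genes (must be <=
#'   `n_true_fusions`).
#' @param caller_fp_rate Expected caller-private false-positive calls per
#'   caller per sample (fusions and CNV segments).
#' @param expressed_gene_frac Probability that a gene is expressed in a
#'   sample (drives the expression cross-check).
#' @param gene_length_bp,gene_gap_bp Geometry of the synthetic gene model.
#' @param seed Integer seed; identical configurations (including the seed)
#'   produce bit-identical cohorts and output files.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 2, seed = 7)
#' cfg$target_size_mb
sim_config <- function(n_patients = 14,
                       lesions_per_patient = NULL,
                       target_size_mb = 30,
                       somatic_rate_per_mb = 0.5,
                       germline_rate_per_mb = 3,
                       common_rate_per_mb = 2,
                       silent_rate_per_mb = 1,
                       artifact_rate_per_mb = 1,
                       truncal_fraction = 0.3,
                       partial_fraction = 0.1,
                       tumor_depth_mean = 60,
                       normal_depth_mean = 60,
                       depth_dispersion = 10,
                       tumor_vaf_mean = 0.4,
                       vaf_concentration = 60,
                       somatic_min_emit_depth = 12,
                       somatic_min_emit_vaf = 0.22,
                       normal_contam_frac = 0,
                       low_depth_frac = 0.02,
                       n_true_cnvs = 6,
                       cnv_boundary_jitter_bp = 5000,
                       n_polymorphic_cnvs = 2,
                       focal_deletion_frac = 0.42,
                       focal_deletion_gene = "DMD",
                       n_true_fusions = 3,
                       n_readthrough_events = 2,
                       caller_fp_rate = 1,
                       expressed_gene_frac = 1 / 3,
                       gene_length_bp = 25000,
                       gene_gap_bp = 25000,
                       seed = 1L) {
  if (is.null(lesions_per_patient)) {
    lesions_per_patient <- default_lesion_map(n_patients)
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    lesions_per_patient = lesions_per_patient,
    target_size_mb = target_size_mb,
    somatic_rate_per_mb = somatic_rate_per_mb,
    germline_rate_per_mb = germline_rate_per_mb,
    common_rate_per_mb = common_rate_per_mb,
    silent_rate_per_mb = silent_rate_per_mb,
    artifact_rate_per_mb = artifact_rate_per_mb,
    truncal_fraction = truncal_fraction,
    partial_fraction = partial_fraction,
    tumor_depth_mean = tumor_depth_mean,
    normal_depth_mean = normal_depth_mean,
    depth_dispersion = depth_dispersion,
    tumor_vaf_mean = tumor_vaf_mean,
    vaf_concentration = vaf_concentration,
    somatic_min_emit_depth = somatic_min_emit_depth,
    somatic_min_emit_vaf = somatic_min_emit_vaf,
    normal_contam_frac = normal_contam_frac,
    low_depth_frac = low_depth_frac,
    n_true_cnvs = as.integer(n_true_cnvs),
    cnv_boundary_jitter_bp = cnv_boundary_jitter_bp,
    n_polymorphic_cnvs = as.integer(n_polymorphic_cnvs),
    focal_deletion_frac = focal_deletion_frac,
    focal_deletion_gene = focal_deletion_gene,
    n_true_fusions = as.integer(n_true_fusions),
    n_readthrough_events = as.integer(n_readthrough_events),
    caller_fp_rate = caller_fp_rate,
    expressed_gene_frac = expressed_gene_frac,
    gene_length_bp = as.integer(gene_length_bp),
    gene_gap_bp = as.integer(gene_gap_bp),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default patient -> lesion-count map
#'
#' One lesion per patient, except the fourth patient (2 lesions) and the
#' sixth (5 lesions) when the cohort is large enough to have them.
#'
#' @param n_patients Number of patients.
#' @return Named integer vector (names `P01`, `P02`, ...).
#' @export
default_lesion_map <- function(n_patients) {
  ids <- sprintf("P%02d", seq_len(n_patients))
  n <- rep(1L, n_patients)
  if (n_patients >= 4) n[4] <- 2L
  if (n_patients >= 6) n[6] <- 5L
  setNames(n, ids)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) abort(sprintf("invalid sim_config: field `%s` %s", field, why))
  }
  rate_fields <- c(
    "target_size_mb", "somatic_rate_per_mb", "germline_rate_per_mb",
    "common_rate_per_mb", "silent_rate_per_mb", "artifact_rate_per_mb",
    "tumor_depth_mean", "normal_depth_mean", "depth_dispersion",
    "cnv_boundary_jitter_bp", "caller_fp_rate"
  )
  for (f in rate_fields) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] >= 0,
        f, "must be a single non-negative number")
  }
  frac_fields <- c(
    "truncal_fraction", "partial_fraction", "tumor_vaf_mean",
    "somatic_min_emit_vaf", "normal_contam_frac", "low_depth_frac",
    "focal_deletion_frac", "expressed_gene_frac"
  )
  for (f in frac_fields) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 &&
          cfg[[f]] >= 0 && cfg[[f]] <= 1,
        f, "must lie in [0, 1]")
  }
  chk(cfg$n_patients >= 1, "n_patients", "must be >= 1")
  chk(cfg$target_size_mb > 0, "target_size_mb", "must be > 0")
  chk(length(cfg$lesions_per_patient) == cfg$n_patients,
      "lesions_per_patient", "must have one entry per patient")
  chk(all(cfg$lesions_per_patient >= 1), "lesions_per_patient",
      "entries must be >= 1")
  chk(cfg$n_readthrough_events <= cfg$n_true_fusions,
      "n_readthrough_events", "must be <= n_true_fusions")
  chk(is.integer(cfg$seed) && length(cfg$seed) == 1 && !is.na(cfg$seed),
      "seed", "must be a single integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  patients: %d (%d samples), target %.1f Mb, depth %gx\n",
              x$n_patients, sum(x$lesions_per_patient), x$target_size_mb,
              x$tumor_depth_mean))
  cat(sprintf("  somatic %.2f/Mb, germline %.2f/Mb, truncal fraction %.2f\n",
              x$somatic_rate_per_mb, x$germline_rate_per_mb,
              x$truncal_fraction))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
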