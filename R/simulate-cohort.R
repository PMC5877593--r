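#' Simulate a matched tumor/normal cohort with known truth
#'
#' Generates caller-style output tables for a whole cohort — tumor variant
#' calls, matched-normal pileups, copy-number segments from two
#' pseudo-callers (one carrying an uncertainty score), fusion calls from
#' four pseudo-callers, a gene model, a capture target and an expression
#' table — together with the ground truth needed to score every downstream
#' stage: somatic/germline labels, clonal assignments, true CNVs and true
#' fusions. All randomness is governed by `config$seed`; identical
#' configurations produce identical cohorts.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_cohort`: a list with the simulated
#'   tables (`variants`, `pileups`, `cnv_a`, `cnv_b`, `fusions`,
#'   `expression`, `gene_model`, `targets`, `sample_map`,
#'   `polymorphic_regions`) and a `truth` list (`variant_labels`,
#'   `clonal_assignment`, `true_cnvs`, `true_fusions`, `driver_locus`).
#' @seealso [write_cohort()] to materialise the cohort as files,
#'   [generate_patient_lesions()] for a single patient.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 2, seed = 42))
#' nrow(cohort$variants)
simulate_cohort <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    gene_model <- sim_gene_model(config)
    targets <- sim_targets(gene_model)
    sample_map <- sim_sample_map(config)

    n_focal <- round(config$focal_deletion_frac * nrow(sample_map))
    focal_samples <- sort(sample(sample_map$sample_id, n_focal))

    per_patient <- purrr::imap(
      as.list(config$lesions_per_patient),
      function(n_les, pid) {
        sids <- sample_map$sample_id[sample_map$patient_id == pid]
        generate_patient_lesions(pid, n_les, config, gene_model, sids)
      }
    )
    variants <- list_rbind(purrr::map(per_patient, "variants"))
    pileups <- list_rbind(purrr::map(per_patient, "pileup"))
    labels <- list_rbind(purrr::map(per_patient, "labels"))
    clonal <- list_rbind(purrr::map(per_patient, "clonal"))

    cnv <- sim_cnvs(config, gene_model, sample_map$sample_id, focal_samples)
    fus <- sim_fusions(config, gene_model, sample_map$sample_id)
    expression <- sim_expression(config, gene_model, sample_map$sample_id)

    structure(list(
      config = config,
      gene_model = gene_model,
      targets = targets,
      sample_map = sample_map,
      variants = variants,
      pileups = pileups,
      cnv_a = cnv$caller_a,
      cnv_b = cnv$caller_b,
      polymorphic_regions = cnv$polymorphic_regions,
      fusions = fus$calls,
      expression = expression,
      truth = list(
        variant_labels = labels,
        clonal_assignment = clonal,
        true_cnvs = cnv$truth,
        true_fusions = fus$truth,
        driver_locus = driver_locus_of(gene_model)
      )
    ), class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>\n")
  cat(sprintf("  %d samples / %d patients, %.1f Mb target\n",
              nrow(x$sample_map), x$config$n_patients,
              x$config$target_size_mb))
  cat(sprintf("  %d tumor variant records (%d labeled), %d CNV truth segments, %d true fusions\n",
              nrow(x$variants), nrow(x$truth$variant_labels),
              nrow(x$truth$true_cnvs), nrow(x$truth$true_fusions)))
  invisible(x)
}

chrom_lengths <- function(gene_model, gap) {
  gene_model |>
    group_by(chrom = .data$chrom) |>
    summarise(length = max(.data$end) + gap, .groups = "drop")
}

overlaps_any <- function(segs, chrom, start, end) {
  if (is.null(segs) || nrow(segs) == 0) return(FALSE)
  any(segs$chrom == chrom & segs$start <= end & segs$end >= start)
}

## ---- copy number ----------------------------------------------------------

sim_cnvs <- function(config, gene_model, sample_ids, focal_samples) {
  clen <- chrom_lengths(gene_model, config$gene_gap_bp)
  draw_on <- function(chroms, len_lo, len_hi) {
    repeat {
      ch <- sample(chroms, 1)
      L <- clen$length[clen$chrom == ch]
      len <- round(runif(1, len_lo, min(len_hi, L - 1)))
      if (len < 1) next
      start <- floor(runif(1, 1, L - len))
      return(list(chrom = ch, start = as.integer(start),
                  end = as.integer(start + len - 1L)))
    }
  }

  jit <- function(x, j) as.integer(x + round(runif(length(x), -j, j)))
  gene_row <- gene_model[gene_model$gene == config$focal_deletion_gene, ]
  if (nrow(gene_row) == 0) {
    abort(sprintf("focal_deletion_gene `%s` absent from the gene model",
                  config$focal_deletion_gene))
  }

  ## polymorphic catalog: kept clear of the focal-deletion gene so the
  ## designated somatic aberration is never mistaken for a polymorphism
  n_poly_regions <- 5L
  focal_zone <- tibble(chrom = gene_row$chrom,
                       start = gene_row$start - 1000000L,
                       end = gene_row$end + 1000000L)
  poly_regions <- purrr::map(seq_len(n_poly_regions), function(i) {
    repeat {
      s <- draw_on(clen$chrom, 2e5, 8e5)
      if (!overlaps_any(focal_zone, s$chrom, s$start, s$end)) break
    }
    tibble(chrom = s$chrom, start = s$start, end = s$end,
           region_id = sprintf("DGVlike_%d", i))
  }) |> list_rbind()

  empty_segs <- tibble(chrom = character(0), start = integer(0),
                       end = integer(0), state = character(0),
                       kind = character(0))
  per_sample <- purrr::map(sample_ids, function(sid) {
    segs <- empty_segs
    add <- function(seg) segs <<- bind_rows(segs, seg)

    if (sid %in% focal_samples) {
      len <- round(runif(1, 3e5, 8e5))
      lo <- max(1, gene_row$end - len + 1)
      start <- floor(runif(1, lo, gene_row$start))
      add(tibble(chrom = gene_row$chrom, start = as.integer(start),
                 end = as.integer(start + len - 1L), state = "loss",
                 kind = "focal"))
    }
    ## somatic truth avoids the polymorphic catalog: a segment on a known
    ## polymorphic locus would be removed by design downstream
    for (i in seq_len(config$n_true_cnvs)) {
      for (try in 1:50) {
        s <- draw_on(clen$chrom, 2e5, 1.2e6)
        if (!overlaps_any(segs, s$chrom, s$start, s$end) &&
            !overlaps_any(poly_regions, s$chrom, s$start, s$end)) {
          add(tibble(chrom = s$chrom, start = s$start, end = s$end,
                     state = sample(c("gain", "loss"), 1), kind = "true"))
          break
        }
      }
    }
    for (i in seq_len(config$n_polymorphic_cnvs)) {
      for (try in 1:20) {
        r <- poly_regions[sample.int(nrow(poly_regions), 1), ]
        st <- max(1L, jit(r$start, 1e4))
        en <- jit(r$end, 1e4)
        if (en > st && !overlaps_any(segs, r$chrom, st, en)) {
          add(tibble(chrom = r$chrom, start = st, end = en,
                     state = sample(c("gain", "loss"), 1),
                     kind = "polymorphic"))
          break
        }
      }
    }
    segs$sample_id <- sid

    emit <- function(base, fp_chroms, with_uncertainty) {
      j <- config$cnv_boundary_jitter_bp
      out <- base |>
        mutate(start = pmax(1L, jit(.data$start, j)),
               end = pmax(.data$start + 1000L, jit(.data$end, j)))
      if (with_uncertainty) out$uncertainty <- runif(nrow(out), 5, 75)
      n_fp <- rpois(1, config$caller_fp_rate)
      for (i in seq_len(n_fp)) {
        for (try in 1:50) {
          s <- draw_on(fp_chroms, 2e5, 1.2e6)
          if (!overlaps_any(out, s$chrom, s$start, s$end)) {
            fp <- tibble(chrom = s$chrom, start = s$start, end = s$end,
                         state = sample(c("gain", "loss"), 1),
                         kind = "false_positive", sample_id = sid)
            if (with_uncertainty) fp$uncertainty <- runif(1, 5, 95)
            out <- bind_rows(out, fp)
            break
          }
        }
      }
      out |> arrange(.data$chrom, .data$start)
    }
    # each pseudo-caller has its own characteristic artifact territory
    # (disjoint chromosome sets), mirroring algorithm-specific biases and
    # keeping false segments caller-private
    even <- clen$chrom[seq_along(clen$chrom) %% 2 == 0]
    odd <- clen$chrom[seq_along(clen$chrom) %% 2 == 1]
    list(
      truth = segs |> filter(.data$kind != "polymorphic") |>
        transmute(sample_id = sid, chrom = .data$chrom,
                  start = .data$start, end = .data$end,
                  state = .data$state, focal = .data$kind == "focal"),
      a = emit(segs, even, TRUE) |>
        transmute(sample_id = sid, chrom = .data$chrom,
                  start = .data$start, end = .data$end,
                  state = .data$state, uncertainty = .data$uncertainty,
                  caller = "callerA"),
      b = emit(segs, odd, FALSE) |>
        transmute(sample_id = sid, chrom = .data$chrom,
                  start = .data$start, end = .data$end,
                  state = .data$state, caller = "callerB")
    )
  })

  list(
    truth = list_rbind(purrr::map(per_sample, "truth")),
    caller_a = list_rbind(purrr::map(per_sample, "a")),
    caller_b = list_rbind(purrr::map(per_sample, "b")),
    polymorphic_regions = poly_regions
  )
}

## ---- fusions --------------------------------------------------------------

# ordered (gene5, gene3) pairs where gene3 is the next same-strand gene
# downstream of gene5 within `max_gap` — read-through candidates
readthrough_candidates <- function(gene_model, max_gap = 1e5) {
  gene_model |>
    group_by(.data$chrom, .data$strand) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(
      next_gene = lead(.data$gene), next_start = lead(.data$start),
      prev_gene = lag(.data$gene), prev_end = lag(.data$end)
    ) |>
    ungroup() |>
    (\(d) bind_rows(
      d |> filter(.data$strand == "+",
                  !is.na(.data$next_gene),
                  .data$next_start - .data$end <= max_gap) |>
        transmute(gene5 = .data$gene, gene3 = .data$next_gene),
      d |> filter(.data$strand == "-",
                  !is.na(.data$prev_gene),
                  .data$start - .data$prev_end <= max_gap) |>
        transmute(gene5 = .data$gene, gene3 = .data$prev_gene)
    ))()
}

fusion_breakpoint <- function(gene_model, gene, side) {
  g <- gene_model[gene_model$gene == gene, ]
  donor <- (side == 5) == (g$strand == "+")
  list(chrom = g$chrom, pos = if (donor) g$end else g$start,
       strand = g$strand)
}

sim_fusions <- function(config, gene_model, sample_ids) {
  rt_pool <- readthrough_candidates(gene_model)
  n_other <- config$n_true_fusions - config$n_readthrough_events

  by_chrom <- split(seq_len(nrow(gene_model)), gene_model$chrom)

  per_sample <- purrr::map(sample_ids, function(sid) {
    events <- NULL
    used_pairs <- character(0)
    add_event <- function(g5, g3, category) {
      key <- paste0(g5, "|", g3)
      if (key %in% used_pairs || g5 == g3) return(FALSE)
      used_pairs <<- c(used_pairs, key)
      events <<- bind_rows(events, tibble(gene5 = g5, gene3 = g3,
                                          category = category))
      TRUE
    }
    k <- 0
    while (k < config$n_readthrough_events) {
      r <- rt_pool[sample.int(nrow(rt_pool), 1), ]
      if (add_event(r$gene5, r$gene3, "readthrough_or_conjoined")) k <- k + 1
    }
    k <- 0
    while (k < n_other) {
      if (runif(1) < 0.5) {
        ch <- sample(names(by_chrom)[lengths(by_chrom) >= 6], 1)
        idx <- sort(sample(by_chrom[[ch]], 2))
        if (idx[2] - idx[1] < 4) next  # keep well apart: no read-through
        ok <- add_event(gene_model$gene[idx[1]], gene_model$gene[idx[2]],
                        "intra_chromosomal")
      } else {
        idx <- sample.int(nrow(gene_model), 2)
        if (gene_model$chrom[idx[1]] == gene_model$chrom[idx[2]]) next
        ok <- add_event(gene_model$gene[idx[1]], gene_model$gene[idx[2]],
                        "inter_chromosomal")
      }
      if (ok) k <- k + 1
    }
    if (is.null(events)) {
      events <- tibble(gene5 = character(0), gene3 = character(0),
                       category = character(0))
    }
    events$n_callers <- sample(2:4, nrow(events), replace = TRUE)

    calls <- purrr::pmap(events, function(gene5, gene3, category,
                                          n_callers) {
      b5 <- fusion_breakpoint(gene_model, gene5, 5)
      b3 <- fusion_breakpoint(gene_model, gene3, 3)
      callers <- sample(FUSION_CALLERS, n_callers)
      tibble(
        sample_id = sid, caller = callers, gene5 = gene5, gene3 = gene3,
        chrom5 = b5$chrom,
        pos5 = as.integer(b5$pos + round(runif(n_callers, -500, 500))),
        chrom3 = b3$chrom,
        pos3 = as.integer(b3$pos + round(runif(n_callers, -500, 500))),
        strand5 = b5$strand, strand3 = b3$strand,
        supporting_reads = rnbinom(n_callers, mu = 20, size = 5) + 2L
      )
    }) |> list_rbind()

    fp_calls <- purrr::map(FUSION_CALLERS, function(cl) {
      n_fp <- rpois(1, config$caller_fp_rate)
      out <- NULL
      k <- 0
      while (k < n_fp) {
        idx <- sample.int(nrow(gene_model), 2)
        g5 <- gene_model$gene[idx[1]]; g3 <- gene_model$gene[idx[2]]
        key <- paste0(g5, "|", g3)
        if (g5 == g3 || key %in% used_pairs) next
        used_pairs <<- c(used_pairs, key)
        b5 <- fusion_breakpoint(gene_model, g5, 5)
        b3 <- fusion_breakpoint(gene_model, g3, 3)
        out <- bind_rows(out, tibble(
          sample_id = sid, caller = cl, gene5 = g5, gene3 = g3,
          chrom5 = b5$chrom, pos5 = as.integer(b5$pos),
          chrom3 = b3$chrom, pos3 = as.integer(b3$pos),
          strand5 = b5$strand, strand3 = b3$strand,
          supporting_reads = rnbinom(1, mu = 6, size = 5) + 2L
        ))
        k <- k + 1
      }
      out
    }) |> list_rbind()

    all_calls <- bind_rows(calls, fp_calls)
    if (is.null(all_calls) || nrow(all_calls) == 0) {
      all_calls <- tibble(
        sample_id = character(0), caller = character(0),
        gene5 = character(0), gene3 = character(0), chrom5 = character(0),
        pos5 = integer(0), chrom3 = character(0), pos3 = integer(0),
        strand5 = character(0), strand3 = character(0),
        supporting_reads = integer(0))
    }
    list(
      calls = all_calls |>
        arrange(.data$caller, .data$gene5, .data$gene3),
      truth = events |> mutate(sample_id = sid, .before = 1)
    )
  })

  list(
    calls = list_rbind(purrr::map(per_sample, "calls")),
    truth = list_rbind(purrr::map(per_sample, "truth"))
  )
}

## ---- expression -----------------------------------------------------------

sim_expression <- function(config, gene_model, sample_ids) {
  tidyr::crossing(gene = gene_model$gene, sample_id = sample_ids) |>
    mutate(expr = ifelse(runif(n()) < config$expressed_gene_frac,
                         round(runif(n(), 1, 100), 2), 0))
}
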