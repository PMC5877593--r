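# brute-force CNV oracles shared by the consensus tests

# per-base brute force: a base is consensus iff some same-state pair of
# segments (one per caller) passes the reciprocal-overlap and uncertainty
# tests and covers it
consensus_bases_brute <- function(segs_a, segs_b, min_overlap = 0.8,
                                  max_uncertainty = 80) {
  unc_of <- function(s, i) {
    if (!"uncertainty" %in% names(s)) return(NA_real_)
    s$uncertainty[i]
  }
  out <- list(gain = integer(0), loss = integer(0))
  for (i in seq_len(nrow(segs_a))) {
    for (j in seq_len(nrow(segs_b))) {
      if (segs_a$chrom[i] != segs_b$chrom[j]) next
      if (segs_a$state[i] != segs_b$state[j]) next
      ua <- unc_of(segs_a, i)
      ub <- unc_of(segs_b, j)
      if (!is.na(ua) && ua >= max_uncertainty) next
      if (!is.na(ub) && ub >= max_uncertainty) next
      lo <- max(segs_a$start[i], segs_b$start[j])
      hi <- min(segs_a$end[i], segs_b$end[j])
      ov <- hi - lo + 1
      if (ov <= 0) next
      if (ov < min_overlap * (segs_a$end[i] - segs_a$start[i] + 1)) next
      if (ov < min_overlap * (segs_b$end[j] - segs_b$start[j] + 1)) next
      st <- segs_a$state[i]
      out[[st]] <- union(out[[st]], lo:hi)
    }
  }
  lapply(out, sort)
}

consensus_bases_pkg <- function(consensus) {
  out <- list(gain = integer(0), loss = integer(0))
  for (i in seq_len(nrow(consensus))) {
    st <- consensus$state[i]
    out[[st]] <- union(out[[st]], consensus$start[i]:consensus$end[i])
  }
  lapply(out, sort)
}

# a correlated pair of caller outputs: caller B re-detects a subset of
# caller A's segments with boundary jitter (so reciprocal-overlap pairs
# actually occur) plus private segments of its own
random_seg_pair <- function() {
  a <- random_segs("callerA", with_uncertainty = TRUE)
  reuse <- a[runif(nrow(a)) < 0.7, ]
  b_shared <- NULL
  if (nrow(reuse) > 0) {
    len <- reuse$end - reuse$start + 1
    j <- pmax(1L, as.integer(0.09 * len))
    b_shared <- tibble::tibble(
      sample_id = "S", chrom = "c1",
      start = pmax(1L, as.integer(reuse$start +
                                    vapply(j, function(x)
                                      sample(-x:x, 1), integer(1)))),
      end = pmin(10000L, as.integer(reuse$end +
                                      vapply(j, function(x)
                                        sample(-x:x, 1), integer(1)))),
      state = reuse$state, caller = "callerB")
    b_shared <- b_shared[b_shared$end > b_shared$start, ]
  }
  list(a = a,
       b = dplyr::bind_rows(b_shared, random_segs("callerB", FALSE)))
}

random_segs <- function(caller, with_uncertainty) {
  n <- sample(1:4, 1)
  start <- sample(1:9000, n)
  len <- sample(50:3000, n)
  out <- tibble::tibble(
    sample_id = "S", chrom = "c1", start = start,
    end = pmin(start + len - 1L, 10000L),
    state = sample(c("gain", "loss"), n, replace = TRUE),
    caller = caller
  )
  if (with_uncertainty) {
    out$uncertainty <- ifelse(runif(n) < 0.8, runif(n, 0, 100), NA)
  }
  out
}
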