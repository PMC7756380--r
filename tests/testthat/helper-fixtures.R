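# Shared fixtures and independent oracles, all built in code.

# deterministic toy sequence of a given length
toy_seq <- function(n, id = "toy") {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mature_sequence(id, paste(aa[(seq_len(n) - 1L) %% 20L + 1L], collapse = ""))
}

toy_layout <- function(n = 60, channels = "IgE", blank_count = 10,
                       replicate_count = 3) {
  build_layout(tile_sequence(toy_seq(n)), replicate_count = replicate_count,
               blank_count = blank_count, channels = channels)
}

# z table over the full probe grid of a layout, for one patient/channel
z_table_for <- function(layout, z, patient_id = "P1", channel = "IgE") {
  p <- layout$probes
  stopifnot(length(z) == nrow(p))
  data.frame(patient_id = patient_id, channel = channel,
             probe_id = p$probe_id, start = p$start, end = p$end, z = z,
             stringsAsFactors = FALSE)
}

# --- independent oracle for epitope calling ("all peptides reactive") ---
# Enumerates maximal runs of consecutive reactive peptides with a plain
# scan (no rle, no shared code with call_epitopes) and applies the
# bounded-window reduction: windows of 4 left to right, remainder kept
# when >= 2, a remainder of 1 rebalanced into final windows 3 + 2.
oracle_calls <- function(starts, ends, z, threshold, offset = 3) {
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]; z <- z[ord]
  runs <- list()
  cur <- integer()
  for (i in seq_along(z)) {
    contiguous <- length(cur) > 0 &&
      starts[i] - starts[cur[length(cur)]] == offset
    if (is.finite(z[i]) && z[i] >= threshold) {
      if (contiguous) cur <- c(cur, i)
      else {
        if (length(cur) >= 2) runs[[length(runs) + 1]] <- cur
        cur <- i
      }
    } else {
      if (length(cur) >= 2) runs[[length(runs) + 1]] <- cur
      cur <- integer()
    }
  }
  if (length(cur) >= 2) runs[[length(runs) + 1]] <- cur
  out <- list()
  for (run in runs) {
    n <- length(run)
    q <- n %/% 4L; r <- n %% 4L
    lens <- if (n <= 4L) n
    else if (r == 0L) rep(4L, q)
    else if (r == 1L) c(rep(4L, q - 1L), 3L, 2L)
    else c(rep(4L, q), r)
    pos <- 1L
    for (len in lens) {
      w <- run[pos:(pos + len - 1L)]
      pos <- pos + len
      out[[length(out) + 1]] <- data.frame(
        region_start = max(starts[w]), region_end = min(ends[w]),
        n_peptides = len, median_z = median(z[w])
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(region_start = integer(), region_end = integer(),
                      n_peptides = integer(), median_z = numeric()))
  }
  df <- do.call(rbind, out)
  df[order(df$region_start), , drop = FALSE]
}

# brute-force residue coverage of a probe set
covered_residues <- function(probes) {
  sort(unique(unlist(Map(seq.int, probes$start, probes$end))))
}

# spot rows for one probe/blank unit
spot_rows <- function(patient, probe, reps_total, reps_bg,
                      channel = "IgE") {
  data.frame(patient_id = patient, probe_id = probe,
             replicate = seq_along(reps_total), channel = channel,
             total_fluorescence = reps_total,
             background_fluorescence = reps_bg, stringsAsFactors = FALSE)
}

# minimal cohort for pipeline-level tests: planted recognition with
# fixed counts at saturated effect size
saturated_config <- function(n_allergic = 6, n_tolerant = 2, k_allergic = 6,
                             k_tolerant = 1, region = c(31L, 42L),
                             effect = 10, seed = 1) {
  pe <- data.frame(start = region[1], end = region[2],
                   prob_allergic = 0, prob_tolerant = 0,
                   n_allergic = k_allergic, n_tolerant = k_tolerant,
                   effect_z = effect)
  cohort_config(n_allergic = n_allergic, n_tolerant = n_tolerant,
                planted_epitopes = pe, seed = seed)
}
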