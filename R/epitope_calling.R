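# Epitope calling: runs of 2-4 contiguous reactive peptides, named by
# the consensus interval (intersection) of the run's peptides.

#' Consensus region of a run of contiguous probes
#'
#' The consensus amino-acid interval of a run is the intersection of the
#' peptide intervals: `start = max(starts)`, `end = min(ends)`. For the
#' default 15mer/offset-3 design this gives regions of 12/9/6 residues
#' for runs of 2/3/4 peptides, matching the conventional 12-residue
#' epitope names of two-peptide runs.
#'
#' @param run_probes Data frame with columns `start` and `end` (one row
#'   per probe in the run).
#' @return Integer vector `c(start, end)`.
#' @export
consensus_region <- function(run_probes) {
  stopifnot(is.data.frame(run_probes), nrow(run_probes) >= 1L)
  s <- max(run_probes$start)
  e <- min(run_probes$end)
  if (s > e) {
    stop("probe run has an empty intersection (run too long for this geometry)")
  }
  c(start = as.integer(s), end = as.integer(e))
}

# Split a run of n contiguous reactive peptides into windows of length
# 2..4, left to right: windows of 4 with the remainder appended; a
# remainder of 1 is avoided by rebalancing the final two windows to
# lengths 3 and 2.
split_run_lengths <- function(n) {
  if (n <= 4L) return(n)
  lens <- rep(4L, n %/% 4L)
  r <- n %% 4L
  if (r >= 2L) {
    lens <- c(lens, r)
  } else if (r == 1L) {
    lens[length(lens)] <- 3L
    lens <- c(lens, 2L)
  }
  lens
}

#' Call linear epitopes from a z-score table
#'
#' An epitope is a run of 2-4 contiguous peptides (consecutive starts
#' differing by exactly the tiling offset) whose median z-score meets
#' the threshold. Under the default `run_rule = "all_above"` every
#' peptide of the run must itself have `z >= threshold` (the run median
#' then trivially passes; it is still checked explicitly). Maximal
#' reactive runs longer than 4 peptides are split left-to-right into
#' windows of at most 4 (no window of length 1 or 5) and flagged
#' `"split-from-long-run"`. A missing z-score breaks contiguity.
#'
#' @param z `zscore_table` (or compatible data.frame with columns
#'   `patient_id`, `channel`, `probe_id`, `start`, `end`, `z`).
#' @param layout `array_layout` providing the tiling grid.
#' @param threshold Reactivity threshold on the z-score scale
#'   (default 3).
#' @param run_rule `"all_above"` (default): each peptide of a run must
#'   pass the threshold. `"median_only"`: only the window median must
#'   pass; windows are chosen greedily left-to-right, longest (4) first.
#' @return Data frame of epitope calls with columns `patient_id`,
#'   `channel`, `antigen_id`, `region_start`, `region_end`, `region`,
#'   `n_peptides`, `probe_run`, `median_z`, `flag`.
#' @export
call_epitopes <- function(z, layout, threshold = 3,
                          run_rule = c("all_above", "median_only")) {
  run_rule <- match.arg(run_rule)
  stopifnot(inherits(layout, "array_layout"))
  if (threshold <= 0) stop("threshold must be > 0")
  empty <- data.frame(
    patient_id = character(), channel = character(), antigen_id = character(),
    region_start = integer(), region_end = integer(), region = character(),
    n_peptides = integer(), probe_run = character(), median_z = numeric(),
    flag = character(), stringsAsFactors = FALSE
  )
  if (is.null(z) || nrow(z) == 0L) return(empty)

  probes <- layout$probes
  z$antigen_id <- probes$antigen_id[match(z$probe_id, probes$probe_id)]
  z <- z[!is.na(z$antigen_id), , drop = FALSE]
  if (nrow(z) == 0L) return(empty)
  offset <- layout$offset

  groups <- split(z, list(z$patient_id, z$channel, z$antigen_id), drop = TRUE)
  calls <- list()
  for (g in groups) {
    g <- g[order(g$start), , drop = FALSE]
    g <- g[is.finite(g$z), , drop = FALSE]  # missing z breaks contiguity
    if (nrow(g) == 0L) next
    reactive <- g$z >= threshold
    # contiguity breaks where the grid step is not exactly the offset
    new_block <- c(TRUE, diff(g$start) != offset)
    block_id <- cumsum(new_block)

    if (run_rule == "all_above") {
      run_id <- cumsum(new_block | c(TRUE, diff(reactive) != 0L))
      for (rid in unique(run_id[reactive])) {
        idx <- which(run_id == rid & reactive)
        n <- length(idx)
        if (n < 2L) next
        lens <- split_run_lengths(n)
        flag <- if (n > 4L) "split-from-long-run" else ""
        pos <- 1L
        for (len in lens) {
          w <- idx[pos:(pos + len - 1L)]
          pos <- pos + len
          calls[[length(calls) + 1L]] <-
            make_call(g[w, , drop = FALSE], threshold, flag)
        }
      }
    } else {
      for (bid in unique(block_id)) {
        idx <- which(block_id == bid)
        i <- 1L
        while (i <= length(idx)) {
          found <- FALSE
          for (len in 4L:2L) {
            if (i + len - 1L > length(idx)) next
            w <- idx[i:(i + len - 1L)]
            if (median(g$z[w]) >= threshold) {
              calls[[length(calls) + 1L]] <-
                make_call(g[w, , drop = FALSE], threshold, "", check = FALSE)
              i <- i + len
              found <- TRUE
              break
            }
          }
          if (!found) i <- i + 1L
        }
      }
    }
  }
  if (length(calls) == 0L) return(empty)
  out <- do.call(rbind, calls)
  out <- out[order(out$patient_id, out$channel, out$antigen_id, out$region_start), ]
  rownames(out) <- NULL
  out
}

make_call <- function(run, threshold, flag, check = TRUE) {
  med <- median(run$z)
  if (check && med < threshold) {
    stop("internal error: run median below threshold")  # cannot occur for all_above
  }
  region <- consensus_region(run)
  data.frame(
    patient_id = run$patient_id[1], channel = run$channel[1],
    antigen_id = run$antigen_id[1],
    region_start = region[["start"]], region_end = region[["end"]],
    region = sprintf("aa%d-%d", region[["start"]], region[["end"]]),
    n_peptides = nrow(run),
    probe_run = paste(run$probe_id, collapse = ","),
    median_z = med, flag = flag, stringsAsFactors = FALSE
  )
}

regions_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

#' Cross-reference epitope calls between detection channels
#'
#' Labels each called region as recognized by IgE only, IgG4 only, or
#' both, per patient and antigen. Two regions are taken as the same
#' epitope when they share at least one residue.
#'
#' @param calls_ige,calls_igg4 Call tables from [call_epitopes()] for
#'   the two channels of the same cohort.
#' @return Data frame with columns `patient_id`, `antigen_id`,
#'   `channel`, `region_start`, `region_end`, `region`, `label`.
#' @export
cross_reference_channels <- function(calls_ige, calls_igg4) {
  both <- rbind(calls_ige, calls_igg4)
  if (nrow(both) == 0L) {
    return(data.frame(patient_id = character(), antigen_id = character(),
                      channel = character(), region_start = integer(),
                      region_end = integer(), region = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  label <- character(nrow(both))
  for (i in seq_len(nrow(both))) {
    this <- both[i, ]
    other_chan <- if (this$channel == "IgE") "IgG4" else "IgE"
    other <- both[both$patient_id == this$patient_id &
                    both$antigen_id == this$antigen_id &
                    both$channel == other_chan, , drop = FALSE]
    hit <- any(regions_overlap(this$region_start, this$region_end,
                               other$region_start, other$region_end))
    label[i] <- if (hit) "both" else paste0(this$channel, "-only")
  }
  out <- both[, c("patient_id", "antigen_id", "channel",
                  "region_start", "region_end", "region")]
  out$label <- label
  rownames(out) <- NULL
  out
}

#' Epitope-by-patient recognition matrix
#'
#' Binary matrix (patients in rows, epitope regions in columns) suitable
#' for heatmaps and PCA. Columns are the distinct called regions in
#' coordinate order; an entry is 1 when the patient has a call for that
#' exact region.
#'
#' @param calls Call table from [call_epitopes()] (typically one
#'   channel).
#' @param patient_ids Optional character vector fixing row order (and
#'   including patients with no calls).
#' @return Integer matrix with dimnames.
#' @export
epitope_patient_matrix <- function(calls, patient_ids = NULL) {
  if (is.null(patient_ids)) patient_ids <- sort(unique(calls$patient_id))
  regs <- unique(calls[, c("antigen_id", "region_start", "region_end", "region")])
  regs <- regs[order(regs$antigen_id, regs$region_start), , drop = FALSE]
  cols <- if (nrow(regs) > 0L) paste0(regs$antigen_id, ":", regs$region) else character()
  m <- matrix(0L, nrow = length(patient_ids), ncol = length(cols),
              dimnames = list(patient_ids, cols))
  if (nrow(calls) > 0L) {
    key <- paste0(calls$antigen_id, ":", calls$region)
    keep <- calls$patient_id %in% patient_ids
    m[cbind(match(calls$patient_id[keep], patient_ids),
            match(key[keep], cols))] <- 1L
  }
  m
}

#' Write epitope calls to TSV
#'
#' @param calls Call table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
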