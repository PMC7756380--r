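# Per-spot log2 signal-to-noise, replicate aggregation, and robust
# z-score normalization against blank spots.

#' Log2 signal-to-noise ratio of a spot
#'
#' `S = log2(total / background)`. S is strictly increasing in the
#' total and strictly decreasing in the background fluorescence.
#'
#' @param total_fluorescence Nonnegative total fluorescence.
#' @param background_fluorescence Positive local background, same units.
#' @return Numeric vector of S values (log2 units).
#' @examples
#' compute_snr(1600, 100)  # 4
#' compute_snr(100, 400)   # -2
#' @export
compute_snr <- function(total_fluorescence, background_fluorescence) {
  if (any(background_fluorescence <= 0)) {
    stop("background_fluorescence must be > 0; flag such spots invalid upstream")
  }
  if (any(total_fluorescence < 0)) {
    stop("total_fluorescence must be >= 0")
  }
  log2(total_fluorescence / background_fluorescence)
}

#' Aggregate replicate S values of one probe
#'
#' The replicate aggregator is the median of the per-spot S values,
#' computed after the log2 transform; it is permutation-invariant and
#' robust to one failed spot in a triplicate.
#'
#' @param s Numeric vector of replicate S values (length >= 1).
#' @return Scalar aggregated S.
#' @export
aggregate_replicates <- function(s) {
  s <- s[is.finite(s)]
  if (length(s) == 0L) return(NA_real_)
  median(s)
}

#' Reduce spot measurements to per-probe aggregated S values
#'
#' Spots with background <= 0 or negative/missing total fluorescence are
#' flagged invalid and excluded from aggregation (never imputed); a
#' message reports how many were dropped. Blank units are aggregated
#' exactly like probes.
#'
#' @param spots Spot data frame (see [read_spot_table()]).
#' @param layout `array_layout`.
#' @return Object of class `signal_table`: a data.frame with columns
#'   `patient_id`, `channel`, `probe_id`, `S`, `n_replicates`,
#'   `is_blank`; invalid spots are attached as attribute
#'   `invalid_spots`.
#' @export
spots_to_signal <- function(spots, layout) {
  spots <- validate_spots(spots, layout)
  ok <- is.finite(spots$background_fluorescence) &
    spots$background_fluorescence > 0 &
    is.finite(spots$total_fluorescence) &
    spots$total_fluorescence >= 0
  invalid <- spots[!ok, , drop = FALSE]
  if (nrow(invalid) > 0L) {
    message(nrow(invalid), " spot(s) flagged invalid (background <= 0 or ",
            "bad total) and excluded from aggregation")
  }
  spots <- spots[ok, , drop = FALSE]
  if (nrow(spots) == 0L) stop("no valid spots left after sanitation")
  spots$S <- compute_snr(spots$total_fluorescence, spots$background_fluorescence)

  key <- interaction(spots$patient_id, spots$channel, spots$probe_id,
                     drop = TRUE, sep = "\r")
  agg_s <- tapply(spots$S, key, aggregate_replicates)
  n_rep <- tapply(spots$S, key, function(x) sum(is.finite(x)))
  parts <- do.call(rbind, strsplit(names(agg_s), "\r", fixed = TRUE))
  out <- data.frame(
    patient_id = parts[, 1], channel = parts[, 2], probe_id = parts[, 3],
    S = as.numeric(agg_s), n_replicates = as.integer(n_rep),
    stringsAsFactors = FALSE
  )
  out$is_blank <- is_blank_id(out$probe_id)
  out <- out[order(out$patient_id, out$channel, out$is_blank, out$probe_id), ]
  rownames(out) <- NULL
  attr(out, "invalid_spots") <- invalid
  class(out) <- c("signal_table", "data.frame")
  out
}

#' Normalize aggregated S values into robust z-scores against blanks
#'
#' Per patient x channel (each serum incubation is its own array), the
#' blank-spot S values define the null location and scale:
#' `z = (S - median(S_blank)) / MedianDeviation(S_blank)`, where the
#' median deviation is the unscaled median absolute deviation about the
#' median (`mad_scale = 1`, no Gaussian consistency factor). Setting
#' `mad_scale = 1.4826` gives the Gaussian-consistent variant; this only
#' rescales the z >= 3 epitope threshold uniformly.
#'
#' @param signal `signal_table` from [spots_to_signal()].
#' @param layout `array_layout`; used to attach probe coordinates.
#' @param mad_scale Consistency constant of the median deviation
#'   (default 1, unscaled).
#' @return Object of class `zscore_table`: data.frame with columns
#'   `patient_id`, `channel`, `probe_id`, `start`, `end`, `z`, with the
#'   per-array normalization statistics attached as attribute `stats`
#'   (a data.frame with `blank_median`, `blank_mad`, `n_blanks`).
#' @export
compute_zscores <- function(signal, layout, mad_scale = 1) {
  stopifnot(inherits(signal, "data.frame"))
  stopifnot(inherits(layout, "array_layout"))
  if (!all(c("patient_id", "channel", "probe_id", "S") %in% names(signal))) {
    stop("signal must have columns patient_id, channel, probe_id, S")
  }
  if (is.null(signal$is_blank)) signal$is_blank <- is_blank_id(signal$probe_id)

  groups <- split(signal, list(signal$patient_id, signal$channel), drop = TRUE)
  z_list <- vector("list", length(groups))
  stat_list <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    blank_s <- g$S[g$is_blank & is.finite(g$S)]
    if (length(blank_s) < 2L) {
      stop("fewer than 2 blank S values for patient '", g$patient_id[1],
           "' channel '", g$channel[1], "'")
    }
    m <- median(blank_s)
    md <- mad(blank_s, constant = mad_scale)
    if (md == 0) {
      stop("median deviation of blanks is zero for patient '", g$patient_id[1],
           "' channel '", g$channel[1],
           "': all blanks identical; inspect the blank spots before normalizing")
    }
    probes <- g[!g$is_blank, , drop = FALSE]
    z_list[[i]] <- data.frame(
      patient_id = probes$patient_id, channel = probes$channel,
      probe_id = probes$probe_id, z = (probes$S - m) / md,
      stringsAsFactors = FALSE
    )
    stat_list[[i]] <- data.frame(
      patient_id = g$patient_id[1], channel = g$channel[1],
      blank_median = m, blank_mad = md, n_blanks = length(blank_s),
      stringsAsFactors = FALSE
    )
  }
  z <- do.call(rbind, z_list)
  idx <- match(z$probe_id, layout$probes$probe_id)
  z$start <- layout$probes$start[idx]
  z$end <- layout$probes$end[idx]
  z <- z[order(z$patient_id, z$channel, z$start),
         c("patient_id", "channel", "probe_id", "start", "end", "z")]
  rownames(z) <- NULL
  attr(z, "stats") <- do.call(rbind, stat_list)
  attr(z, "mad_scale") <- mad_scale
  class(z) <- c("zscore_table", "data.frame")
  z
}

#' Write a z-score table with its normalization audit trail
#'
#' Writes a TSV (`patient_id channel probe_id start end z`) and a JSON
#' sidecar `<path>.stats.json` with the per-array blank median, median
#' deviation and blank count.
#'
#' @param z `zscore_table` from [compute_zscores()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_zscore_table <- function(z, path) {
  write.table(as.data.frame(z), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  stats_df <- attr(z, "stats")
  if (!is.null(stats_df)) {
    jsonlite::write_json(stats_df, paste0(path, ".stats.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
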