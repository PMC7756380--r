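# Spot-level fluorescence tables and patient metadata.
#
# Spot-table dialect: tab-separated, UTF-8, header
#   patient_id probe_id replicate channel total_fluorescence background_fluorescence
# BLANK is a reserved probe_id token; numbered blank units BLANK_01, ...
# identify physical blank spots across replicates.

SPOT_COLUMNS <- c("patient_id", "probe_id", "replicate", "channel",
                  "total_fluorescence", "background_fluorescence")

#' Read a spot-level fluorescence table
#'
#' Validates every row against the array layout: unknown probe ids are
#' rejected, channels must be layout channels, replicate indices must
#' not exceed the layout replicate count, and total fluorescence must be
#' nonnegative. Row order is preserved; no row is silently dropped.
#'
#' @param path Path to a tab-separated table in the documented dialect.
#' @param layout `array_layout` the table must conform to.
#' @return `data.frame` of validated spot measurements (one row per
#'   spot) in input order.
#' @export
read_spot_table <- function(path, layout) {
  stopifnot(inherits(layout, "array_layout"))
  if (!file.exists(path)) stop("spot table not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing_cols <- setdiff(SPOT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("spot table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, SPOT_COLUMNS]
  if (nrow(df) == 0L) {
    warning("spot table has an empty data section: ", path)
    return(df)
  }
  validate_spots(df, layout)
}

#' Validate an in-memory spot table against a layout
#'
#' @param df Data frame with the spot-table columns.
#' @param layout `array_layout`.
#' @return The validated data frame (row order preserved).
#' @export
validate_spots <- function(df, layout) {
  stopifnot(inherits(layout, "array_layout"))
  df$replicate <- as.integer(df$replicate)
  df$total_fluorescence <- as.numeric(df$total_fluorescence)
  df$background_fluorescence <- as.numeric(df$background_fluorescence)

  bad <- which(is.na(df$total_fluorescence) | df$total_fluorescence < 0)
  if (length(bad) > 0L) {
    stop("negative or missing total_fluorescence at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  known <- df$probe_id %in% layout$probes$probe_id | is_blank_id(df$probe_id)
  if (!all(known)) {
    stop("probe_id not in layout and not BLANK: ",
         paste(unique(df$probe_id[!known]), collapse = ", "))
  }
  bad_chan <- setdiff(unique(df$channel), layout$channels)
  if (length(bad_chan) > 0L) {
    stop("channel(s) not in layout: ", paste(bad_chan, collapse = ", "))
  }
  if (any(is.na(df$replicate) | df$replicate < 1L)) {
    stop("replicate indices must be integers >= 1")
  }
  if (any(df$replicate > layout$replicate_count)) {
    stop("replicate index exceeds layout replicate_count (",
         layout$replicate_count, ")")
  }
  df
}

#' Write a spot table in the package dialect
#'
#' @param spots Spot data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  missing_cols <- setdiff(SPOT_COLUMNS, names(spots))
  if (length(missing_cols) > 0L) {
    stop("spot table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  write.table(spots[, SPOT_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Import a GenePix results (GPR) file as spot measurements
#'
#' Convenience reader for GenePix-style scanner exports: an ATF header
#' (first line `ATF <version>`, second line `<n_header> <n_cols>`)
#' followed by a tab-separated data block. The probe id is taken from
#' the `Name` column; foreground and background are mapped from the
#' median columns at the requested wavelength (e.g. `F635 Median`,
#' `B635 Median`).
#'
#' @param path GPR file path.
#' @param patient_id Patient the scan belongs to.
#' @param channel Channel label to assign (e.g. `"IgE"`).
#' @param wavelength Wavelength tag used in the column names (default
#'   `"635"`).
#' @return Spot data frame in the package dialect. Replicates are
#'   numbered in file order within each probe id.
#' @export
read_gpr <- function(path, patient_id, channel, wavelength = "635") {
  if (!file.exists(path)) stop("GPR file not found: ", path)
  lines <- readLines(path, n = 2L)
  if (!grepl("^ATF", lines[1])) stop("not an ATF/GPR file: ", path)
  n_header <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]][1])
  df <- read.delim(path, skip = 2L + n_header, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  fg_col <- paste0("F", wavelength, " Median")
  bg_col <- paste0("B", wavelength, " Median")
  for (col in c("Name", fg_col, bg_col)) {
    if (!col %in% names(df)) stop("GPR file lacks column '", col, "'")
  }
  out <- data.frame(
    patient_id = patient_id,
    probe_id = df$Name,
    replicate = stats::ave(seq_len(nrow(df)), df$Name, FUN = seq_along),
    channel = channel,
    total_fluorescence = as.numeric(df[[fg_col]]),
    background_fluorescence = as.numeric(df[[bg_col]]),
    stringsAsFactors = FALSE
  )
  out
}

#' Read a patient metadata table
#'
#' CSV with header `patient_id,group,symptom_class,challenge,...` where
#' the remaining columns are component intensities (`*_ige_ru`,
#' `*_igg4_ru`, response units) and extract titres (`*_kul`, kU/L).
#' Group/symptom consistency is enforced: tolerant patients must have
#' `symptom_class == "none"` and allergic patients must not.
#'
#' @param path CSV path.
#' @return Validated `data.frame`, one row per patient.
#' @export
read_patient_table <- function(path) {
  if (!file.exists(path)) stop("patient table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_patients(df)
}

#' Validate an in-memory patient table
#'
#' @param df Data frame with at least `patient_id`, `group`,
#'   `symptom_class`, `challenge`.
#' @return The validated data frame.
#' @export
validate_patients <- function(df) {
  req <- c("patient_id", "group", "symptom_class", "challenge")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("patient table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$patient_id)) {
    stop("duplicated patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))
  }
  if (!all(df$group %in% c("allergic", "tolerant"))) {
    stop("group must be 'allergic' or 'tolerant'")
  }
  if (!all(df$symptom_class %in% c("objective", "subjective", "none"))) {
    stop("symptom_class must be 'objective', 'subjective' or 'none'")
  }
  bad_tol <- df$group == "tolerant" & df$symptom_class != "none"
  if (any(bad_tol)) {
    stop("tolerant patient(s) with symptom_class != 'none': ",
         paste(df$patient_id[bad_tol], collapse = ", "))
  }
  bad_all <- df$group == "allergic" & df$symptom_class == "none"
  if (any(bad_all)) {
    stop("allergic patient(s) with symptom_class 'none': ",
         paste(df$patient_id[bad_all], collapse = ", "))
  }
  df$challenge <- as.logical(df$challenge)
  num_cols <- grep("(_ru|_kul)$", names(df), value = TRUE)
  for (col in num_cols) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      stop("negative values in patient column '", col, "'")
    }
  }
  df
}

#' Write a patient metadata table
#'
#' @param patients Patient data frame.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(patients, path) {
  write.csv(patients, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
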