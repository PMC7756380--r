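#' Construct a mature antigen sequence
#'
#' A mature sequence is the protein sequence after signal-peptide
#' removal; all residue coordinates in the pipeline (probe intervals,
#' epitope names such as "aa30-41") are 1-based positions on this
#' sequence.
#'
#' @param antigen_id Short label, e.g. `"Gal_d_1"`. Used as prefix for
#'   probe ids, so it should contain no whitespace.
#' @param residues Amino-acid string restricted to the 20 standard
#'   one-letter codes (upper case).
#' @param accession Optional database accession recorded as metadata.
#' @return An object of class `mature_sequence` with fields
#'   `antigen_id`, `accession`, `residues`.
#' @examples
#' seq <- mature_sequence("toy", paste(rep("ACDEFGHIKL", 3), collapse = ""))
#' nchar(seq$residues)
#' @export
mature_sequence <- function(antigen_id, residues, accession = NA_character_) {
  stopifnot(is.character(antigen_id), length(antigen_id) == 1L, nzchar(antigen_id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  letters <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(letters), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("non-standard residue letter(s) in sequence '", antigen_id, "': ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(antigen_id = antigen_id, accession = accession, residues = residues),
    class = "mature_sequence"
  )
}

#' @export
print.mature_sequence <- function(x, ...) {
  cat("<mature_sequence> ", x$antigen_id,
      if (!is.na(x$accession)) paste0(" (", x$accession, ")"), ": ",
      nchar(x$residues), " aa\n", sep = "")
  invisible(x)
}

#' Read mature antigen sequences from a FASTA file
#'
#' The first whitespace-delimited token of each description line is the
#' antigen id; an accession is taken from a token of the form
#' `accession=XXX` or, failing that, the second token.
#'
#' @param path Path to a FASTA file (one or more records).
#' @return A list of [mature_sequence()] objects, named by antigen id.
#' @export
read_mature_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no sequences in FASTA file: ", path)
  out <- lapply(seq_along(aa), function(i) {
    desc <- names(aa)[i]
    tokens <- strsplit(trimws(desc), "\\s+")[[1]]
    id <- tokens[1]
    acc <- NA_character_
    hit <- grep("^accession=", tokens, value = TRUE)
    if (length(hit) > 0L) {
      acc <- sub("^accession=", "", hit[1])
    } else if (length(tokens) >= 2L) {
      acc <- tokens[2]
    }
    mature_sequence(id, as.character(aa[[i]]), acc)
  })
  names(out) <- vapply(out, function(s) s$antigen_id, character(1))
  out
}

#' Tile a mature sequence into overlapping peptide probes
#'
#' Probes of `peptide_length` residues start at positions 1, 1+offset,
#' 1+2*offset, ... Consecutive regularly spaced probes overlap by
#' `peptide_length - offset` residues (12 for the default 15/3 design).
#' When the regular grid does not end exactly at the C-terminus, one
#' additional probe ending at the last residue is appended so that every
#' residue is covered by at least one probe.
#'
#' @param seq A [mature_sequence()].
#' @param peptide_length Probe length in residues (default 15).
#' @param offset Start-to-start spacing in residues (default 3).
#' @param linker Linker peptide recorded as layout metadata only; it
#'   never enters coordinates or scoring. The default is two beta-alanine
#'   residues and one aspartic acid, written `"bAbAD"`.
#' @return A `data.frame` with columns `probe_id`, `antigen_id`,
#'   `start`, `end`, `sequence`, `linker`, carrying attributes
#'   `peptide_length` and `offset`.
#' @examples
#' seq <- mature_sequence("toy", strrep("ACDEFGHIKLMNPQRSTVWY", 2))
#' probes <- tile_sequence(seq, peptide_length = 15, offset = 3)
#' probes[, c("probe_id", "start", "end")]
#' @export
tile_sequence <- function(seq, peptide_length = 15L, offset = 3L,
                          linker = "bAbAD") {
  stopifnot(inherits(seq, "mature_sequence"))
  peptide_length <- as.integer(peptide_length)
  offset <- as.integer(offset)
  L <- nchar(seq$residues)
  if (peptide_length < 1L) stop("peptide_length must be >= 1")
  if (L < peptide_length) {
    stop("sequence '", seq$antigen_id, "' (", L,
         " aa) is shorter than the peptide length (", peptide_length, ")")
  }
  if (offset < 1L || offset > peptide_length) {
    stop("offset must satisfy 1 <= offset <= peptide_length")
  }
  starts <- seq.int(1L, L - peptide_length + 1L, by = offset)
  if (starts[length(starts)] + peptide_length - 1L < L) {
    starts <- c(starts, L - peptide_length + 1L)
  }
  ends <- starts + peptide_length - 1L
  pad <- max(3L, nchar(L))
  probes <- data.frame(
    probe_id = sprintf("%s_%0*d", seq$antigen_id, pad, starts),
    antigen_id = seq$antigen_id,
    start = starts,
    end = ends,
    sequence = substring(seq$residues, starts, ends),
    linker = linker,
    stringsAsFactors = FALSE
  )
  attr(probes, "peptide_length") <- peptide_length
  attr(probes, "offset") <- offset
  probes
}

#' Assemble a validated array layout
#'
#' @param probes Probe table from [tile_sequence()]; probe tables from
#'   several antigens may be row-bound (attributes are taken from the
#'   first, pass `peptide_length`/`offset` explicitly if they differ).
#' @param replicate_count Number of printed replicates per probe
#'   (default 3, i.e. triplicate printing).
#' @param blank_count Number of blank spot units on the array (default
#'   60); at least 2 so that the median deviation of blank signals is
#'   computable. The blank count sets the stability of the per-array
#'   normalization: the blank median deviation is estimated from these
#'   units, and too few blanks inflate the null z-score tail.
#' @param channels Detection channel labels (default IgE and IgG4).
#' @param peptide_length,offset Tiling geometry; defaults read from the
#'   probe table attributes.
#' @return An object of class `array_layout`.
#' @export
build_layout <- function(probes, replicate_count = 3L, blank_count = 60L,
                         channels = c("IgE", "IgG4"),
                         peptide_length = attr(probes, "peptide_length"),
                         offset = attr(probes, "offset")) {
  if (!is.data.frame(probes) || nrow(probes) == 0L) {
    stop("probes must be a nonempty data.frame")
  }
  req <- c("probe_id", "antigen_id", "start", "end", "sequence", "linker")
  missing_cols <- setdiff(req, names(probes))
  if (length(missing_cols) > 0L) {
    stop("probe table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(probes$probe_id)) {
    stop("duplicate probe_id: ",
         paste(unique(probes$probe_id[duplicated(probes$probe_id)]), collapse = ", "))
  }
  replicate_count <- as.integer(replicate_count)
  blank_count <- as.integer(blank_count)
  if (is.na(replicate_count) || replicate_count < 1L) {
    stop("replicate_count must be >= 1")
  }
  if (is.na(blank_count) || blank_count < 2L) {
    stop("blank_count must be >= 2 (median deviation of blanks must be computable)")
  }
  if (length(channels) < 1L) stop("at least one channel is required")
  for (ag in unique(probes$antigen_id)) {
    s <- probes$start[probes$antigen_id == ag]
    if (any(diff(s) <= 0L)) {
      stop("probe starts must be strictly increasing within antigen '", ag, "'")
    }
  }
  structure(
    list(
      probes = probes[, req],
      replicate_count = replicate_count,
      blank_count = blank_count,
      channels = as.character(channels),
      peptide_length = as.integer(peptide_length %||% (probes$end[1] - probes$start[1] + 1L)),
      offset = as.integer(offset %||% if (nrow(probes) > 1L) diff(probes$start)[1] else 1L)
    ),
    class = "array_layout"
  )
}

#' @export
print.array_layout <- function(x, ...) {
  cat("<array_layout> ", nrow(x$probes), " probes (",
      paste(unique(x$probes$antigen_id), collapse = ", "), "), ",
      x$peptide_length, "mers offset ", x$offset, ", ",
      x$replicate_count, " replicates, ", x$blank_count, " blank units, channels: ",
      paste(x$channels, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Blank spot unit ids for a layout
#'
#' Blank spots carry the reserved probe-id token `BLANK`; distinct
#' physical blank units are distinguished as `BLANK_01`, `BLANK_02`, ...
#' so that replicate aggregation treats each unit like a probe.
#'
#' @param layout An `array_layout`.
#' @return Character vector of blank unit ids.
#' @export
blank_ids <- function(layout) {
  stopifnot(inherits(layout, "array_layout"))
  sprintf("BLANK_%02d", seq_len(layout$blank_count))
}

#' Test whether probe ids denote blank spots
#'
#' @param probe_id Character vector.
#' @return Logical vector; `TRUE` for the reserved token `BLANK` or a
#'   numbered blank unit `BLANK_<nn>`.
#' @export
is_blank_id <- function(probe_id) {
  grepl("^BLANK(_[0-9]+)?$", probe_id)
}

#' Write an array layout probe table to TSV
#'
#' Columns: `probe_id`, `antigen_id`, `start`, `end`, `sequence`,
#' `linker`.
#'
#' @param layout An `array_layout`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "array_layout"))
  write.table(layout$probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
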