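# End-to-end orchestration: tiling -> signal stats -> epitope calls ->
# optional surface exposure -> diagnostics, with a machine-readable run
# manifest.

#' Pipeline run configuration
#'
#' All defaults are the design constants of the assay: 15mer peptides at
#' offset 3, z-score threshold 3.0 with the unscaled median deviation,
#' residue exposure at ratio > 0.5 with epitope fraction >= 0.25, and
#' the three discriminative regions aa30-41/aa39-50/aa84-95 for the
#' classifier. Every parameter is echoed into the run manifest.
#'
#' @param fasta Path to the mature antigen FASTA.
#' @param spots Path to the spot table (package dialect).
#' @param patients Path to the patient metadata CSV (optional; without
#'   it the diagnostics stage is skipped).
#' @param structure Optional PDB path for surface exposure.
#' @param outdir Output directory.
#' @param peptide_length,offset Tiling geometry.
#' @param replicate_count,blank_count,channels Layout parameters.
#' @param z_threshold Epitope-calling threshold.
#' @param mad_scale Median-deviation consistency constant.
#' @param run_rule Epitope run rule (see [call_epitopes()]).
#' @param exposure_ratio,exposure_fraction Surface-exposure thresholds.
#' @param regions Discriminative regions for the classifier.
#' @param titre_cutoff Extract-titre cutoff (kU/L) for the comparison
#'   classifier.
#' @return List of class `run_config`.
#' @export
run_config <- function(fasta, spots, patients = NULL, structure = NULL,
                       outdir = "epimapr_out",
                       peptide_length = 15L, offset = 3L,
                       replicate_count = 3L, blank_count = 20L,
                       channels = c("IgE", "IgG4"),
                       z_threshold = 3.0, mad_scale = 1.0,
                       run_rule = "all_above",
                       exposure_ratio = 0.5, exposure_fraction = 0.25,
                       regions = list(c(30, 41), c(39, 50), c(84, 95)),
                       titre_cutoff = 5) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full epitope-mapping pipeline
#'
#' Executes tiling, signal statistics, epitope calling, optional
#' surface exposure and diagnostics, writing every stage output plus a
#' manifest (`manifest.json`) recording package version, parameters and
#' input digests. A stage failure aborts with the stage name and cause.
#'
#' @param config [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  seqs <- stage("tiling", read_mature_fasta(config$fasta))
  probes <- stage("tiling", {
    do.call(rbind, lapply(seqs, tile_sequence,
                          peptide_length = config$peptide_length,
                          offset = config$offset))
  })
  attr(probes, "peptide_length") <- config$peptide_length
  attr(probes, "offset") <- config$offset
  layout <- stage("tiling", build_layout(
    probes, replicate_count = config$replicate_count,
    blank_count = config$blank_count, channels = config$channels
  ))
  write_layout(layout, file.path(config$outdir, "layout.tsv"))

  spots <- stage("signal", read_spot_table(config$spots, layout))
  signal <- stage("signal", spots_to_signal(spots, layout))
  z <- stage("signal", compute_zscores(signal, layout,
                                       mad_scale = config$mad_scale))
  write_zscore_table(z, file.path(config$outdir, "zscores.tsv"))

  calls <- stage("calling", call_epitopes(z, layout,
                                          threshold = config$z_threshold,
                                          run_rule = config$run_rule))
  write_calls(calls, file.path(config$outdir, "epitope_calls.tsv"))
  mat <- epitope_patient_matrix(calls[calls$channel == "IgE", , drop = FALSE],
                                sort(unique(spots$patient_id)))
  write.csv(mat, file.path(config$outdir, "epitope_matrix.csv"))

  exposure <- NULL
  if (!is.null(config$structure)) {
    exposure <- stage("surface", compute_residue_accessibility(config$structure))
    write_exposure(exposure, file.path(config$outdir, "exposure.tsv"))
    verdicts <- lapply(split(calls, calls$region), function(g) {
      v <- classify_epitope_exposure(
        c(g$region_start[1], g$region_end[1]), exposure,
        min_fraction = config$exposure_fraction
      )
      as.data.frame(v)
    })
    if (length(verdicts) > 0L) {
      write.table(do.call(rbind, verdicts),
                  file.path(config$outdir, "exposure_verdicts.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  report <- NULL
  if (!is.null(config$patients)) {
    patients <- stage("diagnostics", read_patient_table(config$patients))
    report <- stage("diagnostics",
                    diagnostic_report(calls, patients, regions = config$regions))
    jsonlite::write_json(
      list(
        counts = report$performance[c("tp", "fp", "tn", "fn")],
        sensitivity = round(report$performance$sensitivity, 2),
        specificity = round(report$performance$specificity, 2),
        recognition = lapply(report$recognition, function(r) {
          list(region = r$region, allergic_percent = r$allergic$percent,
               tolerant_percent = r$tolerant$percent)
        })
      ),
      file.path(config$outdir, "diagnostics.json"),
      auto_unbox = TRUE, digits = NA
    )
  }

  inputs <- c(fasta = config$fasta, spots = config$spots,
              patients = config$patients, structure = config$structure)
  manifest <- list(
    package = "epimapr",
    version = as.character(utils::packageVersion("epimapr")),
    parameters = unclass(config)[setdiff(names(config),
                                c("fasta", "spots", "patients", "structure", "outdir"))],
    inputs = lapply(inputs[!vapply(inputs, is.null, logical(1))], function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(layout = layout, zscores = z, calls = calls,
                 matrix = mat, exposure = exposure, report = report,
                 manifest = manifest))
}
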