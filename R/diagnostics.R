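# Serological and diagnostic statistics: EAST classes, sIgE/sIgG4
# ratios, sensitivity/specificity, Mann-Whitney group comparison, PCA
# variable contributions.

#' Map EUROLINE intensities (RU) to EAST classes
#'
#' Step mapping: <3 -> 0, 3-6 -> 1, 7-15 -> 2, 16-30 -> 3, 31-50 -> 4,
#' 51-100 -> 5, >100 -> 6. The published bands have integer bounds, so
#' non-integer intensities inside the open gaps between bands (e.g.
#' 6.5 RU, between the 3-6 and 7-15 bands) are rounded to the nearest
#' integer first; everywhere else the bands apply literally.
#'
#' @param el_intensity Numeric vector of band intensities in response
#'   units (RU), nonnegative.
#' @return Integer vector of EAST classes (0-6).
#' @examples
#' el_to_east_class(c(0, 67, 110))  # 0 5 6
#' @export
el_to_east_class <- function(el_intensity) {
  if (any(is.na(el_intensity)) || any(el_intensity < 0)) {
    stop("EL intensities must be nonnegative")
  }
  uppers <- c(6, 15, 30, 50, 100)
  x <- el_intensity
  in_gap <- Reduce(`|`, lapply(uppers, function(u) x > u & x < u + 1))
  x[in_gap] <- round(x[in_gap])
  findInterval(x, c(3, 7, 16, 31, 51, 101))
}

#' sIgE/sIgG4 ratios with log transform
#'
#' The ratio is defined only when the IgG4 intensity is positive;
#' undefined ratios are flagged (`defined = FALSE`) and should be
#' excluded from medians. The log transform is base 10 and is `NA` for
#' a zero ratio.
#'
#' @param ige_ru,igg4_ru Nonnegative intensities (response units).
#' @param patient_id,component Optional identifiers carried through.
#' @return Data frame with columns `patient_id`, `component`, `ige_ru`,
#'   `igg4_ru`, `ratio`, `log_ratio`, `defined`.
#' @export
ige_igg4_ratio <- function(ige_ru, igg4_ru, patient_id = NA_character_,
                           component = NA_character_) {
  if (any(ige_ru < 0, na.rm = TRUE) || any(igg4_ru < 0, na.rm = TRUE)) {
    stop("intensities must be nonnegative")
  }
  defined <- !is.na(igg4_ru) & igg4_ru > 0 & !is.na(ige_ru)
  ratio <- ifelse(defined, ige_ru / igg4_ru, NA_real_)
  log_ratio <- ifelse(defined & ratio > 0, log10(ratio), NA_real_)
  data.frame(patient_id = patient_id, component = component,
             ige_ru = ige_ru, igg4_ru = igg4_ru, ratio = ratio,
             log_ratio = log_ratio, defined = defined,
             stringsAsFactors = FALSE)
}

#' Diagnostic performance of a binary classifier against group truth
#'
#' Sensitivity is the fraction of allergic patients predicted positive,
#' specificity the fraction of tolerant patients predicted negative.
#'
#' @param predictions Named logical vector (patient -> positive).
#' @param truth Named character vector (patient -> `"allergic"` or
#'   `"tolerant"`); names must match `predictions`.
#' @return Object of class `diagnostic_counts`: list with `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `specificity`.
#' @examples
#' pred <- setNames(c(rep(TRUE, 6), rep(FALSE, 7), TRUE, rep(FALSE, 14)),
#'                  paste0("P", 1:28))
#' truth <- setNames(rep(c("allergic", "tolerant"), c(13, 15)),
#'                   paste0("P", 1:28))
#' diagnostic_performance(pred, truth)
#' @export
diagnostic_performance <- function(predictions, truth) {
  if (length(predictions) == 0L) stop("empty cohort")
  if (is.null(names(predictions)) || is.null(names(truth)) ||
      !setequal(names(predictions), names(truth))) {
    stop("predictions and truth must be named over the same patient set")
  }
  truth <- truth[names(predictions)]
  if (!all(truth %in% c("allergic", "tolerant"))) {
    stop("truth values must be 'allergic' or 'tolerant'")
  }
  pos <- as.logical(predictions)
  allergic <- truth == "allergic"
  out <- list(
    tp = sum(pos & allergic), fn = sum(!pos & allergic),
    fp = sum(pos & !allergic), tn = sum(!pos & !allergic)
  )
  out$sensitivity <- if (out$tp + out$fn > 0) out$tp / (out$tp + out$fn) else NA_real_
  out$specificity <- if (out$tn + out$fp > 0) out$tn / (out$tn + out$fp) else NA_real_
  class(out) <- "diagnostic_counts"
  out
}

#' @export
print.diagnostic_counts <- function(x, ...) {
  cat("tp=", x$tp, " fp=", x$fp, " tn=", x$tn, " fn=", x$fn,
      "  sensitivity=", sprintf("%.2f", x$sensitivity),
      "  specificity=", sprintf("%.2f", x$specificity), "\n", sep = "")
  invisible(x)
}

#' Recognition fraction with report rounding
#'
#' Percentages are rounded to whole numbers for summaries (38% for
#' 5/13, 7% for 1/15).
#'
#' @param k Number of recognizing patients.
#' @param n Group size.
#' @return List with `fraction` and integer `percent`.
#' @export
recognition_fraction <- function(k, n) {
  stopifnot(n > 0, k >= 0, k <= n)
  list(fraction = k / n, percent = as.integer(round(100 * k / n)))
}

#' Titre threshold classifier
#'
#' @param titres Named numeric vector (patient -> kU/L or ratio).
#' @param cutoff Positive cutoff; positive at `titre >= cutoff`
#'   (inclusive, the default) or `titre > cutoff`.
#' @param inclusive Use `>=` (default) rather than `>`.
#' @return Named logical predictions.
#' @export
threshold_classifier <- function(titres, cutoff, inclusive = TRUE) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (inclusive) titres >= cutoff else titres > cutoff
}

#' Classify patients by recognition of discriminative epitopes
#'
#' A patient is positive when at least one of their epitope calls (in
#' `channel`) matches any of the designated discriminative regions. A
#' call matches a region when it covers more than `min_overlap` of the
#' region's residues (default: a strict majority). On an offset-3
#' tiling, adjacent but distinct epitopes share a boundary stretch of
#' up to half a region, so a 1-residue overlap rule would conflate a
#' neighbouring non-discriminative epitope with a discriminative one;
#' the majority rule keeps them apart while tolerating small boundary
#' shifts of a true call. Set `min_overlap = 0` for the permissive
#' any-shared-residue rule.
#'
#' @param calls Call table from [call_epitopes()].
#' @param patient_ids All patients of the cohort (so patients with no
#'   calls are negative rather than absent).
#' @param regions List of `c(start, end)` regions; default the three
#'   discriminative ovomucoid regions aa30-41, aa39-50, aa84-95.
#' @param channel Channel the rule applies to (default `"IgE"`).
#' @param antigen_id Optional antigen restriction.
#' @param min_overlap Fraction of the discriminative region that must
#'   be covered (strictly more than) for a call to count (default 0.5).
#' @return Named logical predictions over `patient_ids`.
#' @export
classify_by_epitopes <- function(calls, patient_ids,
                                 regions = list(c(30, 41), c(39, 50), c(84, 95)),
                                 channel = "IgE", antigen_id = NULL,
                                 min_overlap = 0.5) {
  calls <- calls[calls$channel == channel, , drop = FALSE]
  if (!is.null(antigen_id)) {
    calls <- calls[calls$antigen_id == antigen_id, , drop = FALSE]
  }
  pos <- setNames(rep(FALSE, length(patient_ids)), patient_ids)
  for (r in regions) {
    ov <- pmin(calls$region_end, r[2]) - pmax(calls$region_start, r[1]) + 1
    hit <- ov > min_overlap * (r[2] - r[1] + 1)
    pos[unique(calls$patient_id[hit])] <- TRUE
  }
  pos
}

#' Mann-Whitney U test with exact permutation p for small samples
#'
#' For combined sample size up to `exact_max_n` the two-sided p-value
#' is computed by exact enumeration of the rank-sum permutation
#' distribution (ties handled through midranks; the distribution is
#' counted by dynamic programming, equivalent to full enumeration of
#' all group assignments). The two-sided p is twice the smaller tail
#' probability, capped at 1. For larger samples the normal
#' approximation with tie correction is used (no continuity
#' correction).
#'
#' @param values_a,values_b Numeric vectors, both nonempty.
#' @param exact_max_n Largest combined n for the exact mode
#'   (default 25).
#' @return List with `statistic` (U of group a), `p.value`, `method`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))$p.value  # 0.1 by enumeration
#' @export
compare_groups <- function(values_a, values_b, exact_max_n = 25L) {
  na <- length(values_a); nb <- length(values_b)
  if (na == 0L || nb == 0L) stop("both groups must be nonempty")
  n <- na + nb
  r <- rank(c(values_a, values_b))
  w <- sum(r[seq_len(na)])
  U <- w - na * (na + 1) / 2

  if (length(unique(c(values_a, values_b))) == 1L) {
    return(list(statistic = U, p.value = 1,
                method = "identical values in both groups"))
  }

  if (n <= exact_max_n) {
    r2 <- as.integer(round(2 * r))  # midranks doubled -> integers
    total <- sum(r2)
    # dp[k+1, s+1] = number of size-k subsets with doubled rank sum s
    dp <- matrix(0, nrow = na + 1L, ncol = total + 1L)
    dp[1L, 1L] <- 1
    seen <- 0L
    for (v in r2) {
      seen <- seen + 1L
      for (k in seq.int(min(na, seen), 1L)) {
        nz <- which(dp[k, ] > 0)
        if (length(nz) > 0L) dp[k + 1L, nz + v] <- dp[k + 1L, nz + v] + dp[k, nz]
      }
    }
    counts <- dp[na + 1L, ]
    total_subsets <- sum(counts)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[seq_len(w2 + 1L)]) / total_subsets
    p_ge <- sum(counts[seq.int(w2 + 1L, total + 1L)]) / total_subsets
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = U, p.value = p,
                method = "exact permutation (rank-sum enumeration)"))
  }

  mu <- na * nb / 2
  ties <- table(r)
  sigma2 <- (na * nb / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = U, p.value = 1,
                method = "normal approximation (degenerate)"))
  }
  zstat <- (U - mu) / sqrt(sigma2)
  list(statistic = U, p.value = min(1, 2 * pnorm(-abs(zstat))),
       method = "normal approximation with tie correction")
}

#' PCA with variable contribution percentages
#'
#' Principal component analysis (centered; scaled to unit variance by
#' default) of a patients x features matrix. The contribution of a
#' feature to a component is `100 * loading^2` (loadings are unit-norm
#' eigenvectors, so contributions sum to 100 per component). Sign
#' convention: the largest-magnitude loading of each component is made
#' positive, which fixes the eigenvector sign deterministically.
#' Constant features are dropped with a warning.
#'
#' @param mat Numeric matrix, patients in rows, features in columns
#'   (z-scores or epitope mean z). More features than patients is
#'   allowed.
#' @param scale Scale features to unit variance (default `TRUE`).
#' @return List with `contributions` (features x components, percent),
#'   `coordinates` (patient scores), `sdev`, `var_explained` (percent
#'   per component), `dropped` (names of constant features).
#' @export
pca_contributions <- function(mat, scale = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    stop("need at least 2 patients and 2 features")
  }
  if (is.null(colnames(mat))) colnames(mat) <- paste0("V", seq_len(ncol(mat)))
  v <- apply(mat, 2L, stats::var)
  constant <- v == 0 | is.na(v)
  dropped <- colnames(mat)[constant]
  if (any(constant)) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
    mat <- mat[, !constant, drop = FALSE]
  }
  if (ncol(mat) < 2L) stop("fewer than 2 non-constant features")
  p <- prcomp(mat, center = TRUE, scale. = scale)
  for (k in seq_len(ncol(p$rotation))) {
    j <- which.max(abs(p$rotation[, k]))
    if (p$rotation[j, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  contrib <- 100 * p$rotation^2
  list(
    contributions = contrib,
    coordinates = p$x,
    sdev = p$sdev,
    var_explained = 100 * p$sdev^2 / sum(p$sdev^2),
    dropped = dropped
  )
}

#' Cohort diagnostic report
#'
#' Bundles the headline diagnostic statistics for a cohort: the
#' epitope-recognition classifier's 2x2 counts and rates, per-region
#' recognition fractions by group, EAST classes of component
#' intensities, and sIgE/sIgG4 ratio medians by group.
#'
#' @param calls Epitope call table (IgE channel used for the
#'   classifier).
#' @param patients Patient metadata table (see
#'   [read_patient_table()]).
#' @param regions Discriminative regions for the classifier.
#' @param component Metadata column prefix holding the component
#'   intensities used for ratios/EAST classes (default `"gal_d_1"`).
#' @return List of class `diagnostic_report`.
#' @export
diagnostic_report <- function(calls, patients,
                              regions = list(c(30, 41), c(39, 50), c(84, 95)),
                              component = "gal_d_1") {
  truth <- setNames(patients$group, patients$patient_id)
  pred <- classify_by_epitopes(calls, patients$patient_id, regions = regions)
  perf <- diagnostic_performance(pred, truth)

  n_all <- sum(patients$group == "allergic")
  n_tol <- sum(patients$group == "tolerant")
  rec <- lapply(regions, function(r) {
    p <- classify_by_epitopes(calls, patients$patient_id, regions = list(r))
    k_all <- sum(p[patients$patient_id[patients$group == "allergic"]])
    k_tol <- sum(p[patients$patient_id[patients$group == "tolerant"]])
    list(region = sprintf("aa%d-%d", r[1], r[2]),
         allergic = recognition_fraction(k_all, n_all),
         tolerant = recognition_fraction(k_tol, n_tol))
  })

  ige_col <- paste0(component, "_ige_ru")
  igg4_col <- paste0(component, "_igg4_ru")
  east <- ratios <- NULL
  if (all(c(ige_col, igg4_col) %in% names(patients))) {
    east <- data.frame(
      patient_id = patients$patient_id, group = patients$group,
      el_intensity = patients[[ige_col]],
      east_class = el_to_east_class(patients[[ige_col]]),
      stringsAsFactors = FALSE
    )
    ratios <- ige_igg4_ratio(patients[[ige_col]], patients[[igg4_col]],
                             patients$patient_id, component)
    ratios$group <- patients$group
  }
  out <- list(performance = perf, recognition = rec, east = east,
              ratios = ratios,
              n_allergic = n_all, n_tolerant = n_tol)
  class(out) <- "diagnostic_report"
  out
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("Cohort: ", x$n_allergic, " allergic, ", x$n_tolerant, " tolerant\n",
      sep = "")
  cat("Discriminative-epitope classifier: ")
  print(x$performance)
  for (r in x$recognition) {
    cat("  ", r$region, ": allergic ", r$allergic$percent, "%, tolerant ",
        r$tolerant$percent, "%\n", sep = "")
  }
  if (!is.null(x$ratios)) {
    med <- tapply(x$ratios$ratio[x$ratios$defined],
                  x$ratios$group[x$ratios$defined], median)
    cat("median sIgE/sIgG4 ratio: ",
        paste(names(med), sprintf("%.2f", med), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
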