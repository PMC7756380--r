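test_that("EL intensities map onto EAST classes per the step bands", {
  expect_equal(el_to_east_class(67), 5L)   # median allergic ovomucoid band
  expect_equal(el_to_east_class(0), 0L)
  expect_equal(el_to_east_class(110), 6L)
  expect_equal(el_to_east_class(c(2.9, 3, 6, 7, 15, 16, 30, 31, 50, 51, 100, 101)),
               c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L))
  # a value in the open gap between bands is rounded to the nearest integer
  expect_equal(el_to_east_class(6.5), 1L)
  expect_equal(el_to_east_class(6.9), 2L)
  expect_error(el_to_east_class(-1), "nonnegative")
})

test_that("the EAST mapping is a total monotone nondecreasing step function", {
  x <- seq(0, 150, by = 0.25)
  cls <- el_to_east_class(x)
  expect_true(all(diff(cls) >= 0))
  expect_true(all(cls %in% 0:6))
})

test_that("sIgE/sIgG4 ratios and their log transform handle degenerate inputs", {
  r <- ige_igg4_ratio(50, 100)
  expect_equal(r$ratio, 0.5)
  expect_equal(r$log_ratio, log10(0.5))
  expect_equal(ige_igg4_ratio(100, 100)$log_ratio, 0)
  u <- ige_igg4_ratio(10, 0)
  expect_false(u$defined)
  expect_true(is.na(u$ratio))
  z <- ige_igg4_ratio(0, 100)
  expect_equal(z$ratio, 0)
  expect_true(is.na(z$log_ratio))
  expect_error(ige_igg4_ratio(-1, 5), "nonnegative")
})

test_that("diagnostic performance reproduces the 2x2 arithmetic", {
  ids <- paste0("P", 1:28)
  truth <- setNames(rep(c("allergic", "tolerant"), c(13, 15)), ids)
  pred <- setNames(c(rep(TRUE, 6), rep(FALSE, 7), TRUE, rep(FALSE, 14)), ids)
  perf <- diagnostic_performance(pred, truth)
  expect_equal(perf$tp, 6); expect_equal(perf$fn, 7)
  expect_equal(perf$fp, 1); expect_equal(perf$tn, 14)
  expect_equal(perf$sensitivity, 6 / 13)
  expect_equal(perf$specificity, 14 / 15)

  all_neg <- diagnostic_performance(setNames(rep(FALSE, 28), ids), truth)
  expect_equal(all_neg$sensitivity, 0)
  expect_equal(all_neg$specificity, 1)

  oracle_pred <- setNames(truth == "allergic", ids)
  exact <- diagnostic_performance(oracle_pred, truth)
  expect_equal(exact$sensitivity, 1)
  expect_equal(exact$specificity, 1)

  # order invariance and marginal identities
  shuffle <- sample(ids)
  perf2 <- diagnostic_performance(pred[shuffle], truth)
  expect_equal(perf2, perf)
  expect_equal(perf$tp + perf$fn, 13)
  expect_equal(perf$tn + perf$fp, 15)

  expect_error(diagnostic_performance(logical(0), truth), "empty")
})

test_that("recognition fractions round to the reported whole percentages", {
  expect_equal(recognition_fraction(5, 13)$percent, 38L)
  expect_equal(recognition_fraction(4, 15)$percent, 27L)
  expect_equal(recognition_fraction(9, 28)$percent, 32L)
  expect_equal(recognition_fraction(1, 15)$percent, 7L)
  expect_equal(recognition_fraction(6, 13)$percent, 46L)
})

test_that("titre threshold classification is inclusive at the cutoff", {
  titres <- c(a = 4.9, b = 5.0, c = 5.1)
  expect_equal(unname(threshold_classifier(titres, 5)), c(FALSE, TRUE, TRUE))
  expect_equal(unname(threshold_classifier(titres, 5, inclusive = FALSE)),
               c(FALSE, FALSE, TRUE))
  expect_true(all(!threshold_classifier(titres, 100)))
  expect_true(all(threshold_classifier(titres, 0.35)))
  expect_error(threshold_classifier(titres, 0), "cutoff")
})

test_that("epitope-based classification requires majority overlap of a region", {
  mk_call <- function(patient, s, e) data.frame(
    patient_id = patient, channel = "IgE", antigen_id = "toy",
    region_start = s, region_end = e, region = sprintf("aa%d-%d", s, e),
    n_peptides = 2, probe_run = "x,y", median_z = 5, flag = "",
    stringsAsFactors = FALSE
  )
  ids <- c("P1", "P2", "P3", "P4")
  calls <- rbind(
    mk_call("P1", 31, 42),  # 11/12 of aa30-41 -> positive
    mk_call("P2", 45, 56),  # 6/12 of aa39-50 -> not a majority -> negative
    mk_call("P3", 100, 111) # elsewhere -> negative
  )
  pred <- classify_by_epitopes(calls, ids)
  expect_equal(unname(pred), c(TRUE, FALSE, FALSE, FALSE))
  # permissive any-shared-residue rule flips the adjacent epitope
  loose <- classify_by_epitopes(calls, ids, min_overlap = 0)
  expect_equal(unname(loose), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("Mann-Whitney exact p-values agree with enumeration and wilcox.test", {
  # full-enumeration example: all 20 assignments, one extreme -> p = 0.1
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 0.1)

  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_equal(compare_groups(c(7, 7), c(7, 7, 7))$p.value, 1)

  # symmetry under group swap
  set.seed(31)
  for (i in 1:10) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1))
    expect_equal(compare_groups(a, b)$p.value, compare_groups(b, a)$p.value)
  }

  # tie-free exact mode agrees with wilcox.test's exact p
  for (i in 1:15) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    ours <- compare_groups(a, b)
    ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }

  # with ties: agrees with a direct combn enumeration for combined n <= 8
  rank_sum_p <- function(a, b) {
    x <- c(a, b); na <- length(a)
    r <- rank(x)
    w_obs <- sum(r[seq_len(na)])
    sets <- combn(length(x), na)
    w_all <- apply(sets, 2, function(idx) sum(r[idx]))
    min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
  }
  set.seed(8)
  for (i in 1:10) {
    a <- sample(1:4, sample(2:4, 1), replace = TRUE)
    b <- sample(1:4, sample(2:4, 1), replace = TRUE)
    expect_equal(compare_groups(a, b)$p.value, rank_sum_p(a, b))
  }

  # large samples drop to the tie-corrected normal approximation
  set.seed(44)
  big <- compare_groups(rnorm(20), rnorm(20, 1))
  expect_match(big$method, "normal approximation")
  expect_lt(big$p.value, 0.05)
})

test_that("PCA contributions are percentages that sum to 100 per component", {
  set.seed(13)
  mat <- matrix(rnorm(10 * 6), 10, 6,
                dimnames = list(paste0("P", 1:10), paste0("f", 1:6)))
  p <- pca_contributions(mat)
  expect_true(all(abs(colSums(p$contributions) - 100) < 1e-9))
  expect_true(all(p$contributions >= 0))
  expect_equal(sum(p$var_explained), 100)
  # deterministic output including the sign convention
  expect_identical(p, pca_contributions(mat))
})

test_that("a dominant-variance feature drives the first component", {
  set.seed(21)
  n <- 30
  mat <- cbind(big = rnorm(n, sd = 10), matrix(rnorm(n * 5, sd = 0.1), n, 5))
  colnames(mat) <- c("big", paste0("s", 1:5))
  p <- pca_contributions(mat, scale = FALSE)
  expect_gt(p$contributions["big", 1], 95)
})

test_that("duplicating a patient row leaves loadings unchanged up to convention", {
  set.seed(2)
  mat <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(paste0("P", 1:8), paste0("f", 1:5)))
  # duplicating every patient row leaves the covariance eigenvectors,
  # hence the per-component contributions, unchanged
  expect_equal(pca_contributions(rbind(mat, mat), scale = FALSE)$contributions[, 1],
               pca_contributions(mat, scale = FALSE)$contributions[, 1],
               tolerance = 1e-8)
})

test_that("constant features are dropped with a warning; degenerate matrices error", {
  set.seed(6)
  mat <- cbind(matrix(rnorm(12), 6, 2), const = rep(3, 6))
  colnames(mat) <- c("a", "b", "const")
  expect_warning(p <- pca_contributions(mat), "constant")
  expect_equal(p$dropped, "const")
  expect_error(suppressWarnings(pca_contributions(matrix(1, 5, 3))), "non-constant")
})

test_that("the cohort diagnostic report assembles counts, fractions and ratios", {
  ids <- c(sprintf("A%02d", 1:13), sprintf("T%02d", 1:15))
  patients <- data.frame(
    patient_id = ids, group = rep(c("allergic", "tolerant"), c(13, 15)),
    symptom_class = rep(c("objective", "none"), c(13, 15)),
    challenge = FALSE, gal_d_1_ige_ru = 67, gal_d_1_igg4_ru = 46,
    stringsAsFactors = FALSE
  )
  mk_call <- function(patient) data.frame(
    patient_id = patient, channel = "IgE", antigen_id = "toy",
    region_start = 31, region_end = 42, region = "aa31-42",
    n_peptides = 2, probe_run = "x,y", median_z = 8, flag = "",
    stringsAsFactors = FALSE
  )
  calls <- do.call(rbind, lapply(c(sprintf("A%02d", 1:6), "T01"), mk_call))
  rep <- diagnostic_report(calls, patients)
  expect_equal(rep$performance$tp, 6)
  expect_equal(rep$performance$fp, 1)
  expect_equal(round(rep$performance$specificity, 2), 0.93)
  expect_equal(rep$recognition[[1]]$allergic$percent, 46L)
  expect_equal(rep$recognition[[1]]$tolerant$percent, 7L)
  expect_true(all(rep$east$east_class[rep$east$group == "allergic"] == 5L))
  expect_equal(unique(rep$ratios$ratio), 67 / 46)
})
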