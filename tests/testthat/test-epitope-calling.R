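test_that("consensus regions are the intersection of the run's peptides", {
  expect_equal(consensus_region(data.frame(start = c(42, 45), end = c(56, 59))),
               c(start = 45, end = 56))
  expect_equal(consensus_region(data.frame(start = 1, end = 15)),
               c(start = 1, end = 15))
  expect_equal(consensus_region(data.frame(start = c(1, 4, 7, 10),
                                           end = c(15, 18, 21, 24))),
               c(start = 10, end = 15))
  expect_error(consensus_region(data.frame(start = c(1, 20), end = c(15, 34))),
               "empty intersection")
})

test_that("two-peptide runs reproduce the canonical 12-residue epitope names", {
  # reactive pairs at starts {27,30}, {36,39}, {42,45}, {81,84} on a
  # 15/3 tiling give regions aa30-41, aa39-50, aa45-56, aa84-95
  for (case in list(c(27, 30, 41), c(36, 39, 50), c(42, 45, 56), c(81, 84, 95))) {
    probes <- data.frame(
      probe_id = paste0("toy_", sprintf("%03d", c(case[1], case[2]))),
      antigen_id = "toy", start = c(case[1], case[2]),
      end = c(case[1], case[2]) + 14,
      sequence = "X", linker = "bAbAD", stringsAsFactors = FALSE
    )
    probes$sequence <- substring(toy_seq(186)$residues, probes$start, probes$end)
    lay2 <- build_layout(probes, peptide_length = 15, offset = 3)
    ztab <- data.frame(patient_id = "P1", channel = "IgE",
                       probe_id = probes$probe_id, start = probes$start,
                       end = probes$end, z = c(5, 4))
    calls <- call_epitopes(ztab, lay2)
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$region, sprintf("aa%d-%d", case[2], case[3]))
    expect_equal(calls$median_z, 4.5)
  }
})

test_that("singletons never call and three-peptide runs give 9-residue regions", {
  layout <- toy_layout(186)
  grid <- layout$probes$start
  z1 <- ifelse(grid == 31, 10, 0)
  expect_equal(nrow(call_epitopes(z_table_for(layout, z1), layout)), 0L)

  # three contiguous reactive 15mers: region length 15 - 2*3 = 9
  z3 <- ifelse(grid %in% c(82, 85, 88), 5, 0)
  calls <- call_epitopes(z_table_for(layout, z3), layout)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$region_start, 88)
  expect_equal(calls$region_end, 96)
  expect_equal(calls$region_end - calls$region_start + 1, 9)
})

test_that("region length follows peptide_length - offset*(k-1)", {
  layout <- toy_layout(186)
  grid <- layout$probes$start
  for (k in 2:4) {
    z <- ifelse(grid %in% grid[10:(9 + k)], 6, 0)
    calls <- call_epitopes(z_table_for(layout, z), layout)
    expect_equal(calls$region_end - calls$region_start + 1, 15 - 3 * (k - 1))
  }
})

test_that("long reactive runs split into flagged windows of length 2-4", {
  layout <- toy_layout(186)
  grid <- layout$probes$start
  for (n_run in 5:11) {
    z <- ifelse(grid %in% grid[5:(4 + n_run)], 6, 0)
    calls <- call_epitopes(z_table_for(layout, z), layout)
    expect_true(all(calls$n_peptides >= 2 & calls$n_peptides <= 4))
    expect_equal(sum(calls$n_peptides), n_run)
    expect_true(all(calls$flag == "split-from-long-run"))
    # windows are consecutive and non-overlapping on the grid
    expect_true(all(diff(calls$region_start) > 0))
  }
})

test_that("call_epitopes matches the brute-force window oracle on random inputs", {
  layout <- toy_layout(186)
  p <- layout$probes
  set.seed(202)
  for (i in 1:150) {
    z <- rnorm(nrow(p), mean = 1.2, sd = 2)
    calls <- call_epitopes(z_table_for(layout, z), layout, threshold = 3)
    oracle <- oracle_calls(p$start, p$end, z, threshold = 3)
    expect_equal(calls$region_start, oracle$region_start)
    expect_equal(calls$region_end, oracle$region_end)
    expect_equal(calls$n_peptides, oracle$n_peptides)
    expect_equal(calls$median_z, oracle$median_z)
  }
})

test_that("raising the threshold never adds reactive peptides to the call set", {
  layout <- toy_layout(120)
  p <- layout$probes
  set.seed(17)
  for (i in 1:30) {
    z <- rnorm(nrow(p), 1.5, 2)
    lo <- call_epitopes(z_table_for(layout, z), layout, threshold = 3)
    hi <- call_epitopes(z_table_for(layout, z), layout, threshold = 4)
    peptides_of <- function(calls) unlist(strsplit(calls$probe_run, ","))
    expect_true(all(peptides_of(hi) %in% peptides_of(lo)))
    expect_lte(sum(hi$n_peptides), sum(lo$n_peptides))
  }
})

test_that("a missing probe z breaks contiguity", {
  layout <- toy_layout(186)
  p <- layout$probes
  z <- ifelse(p$start %in% c(28, 31, 34), 8, 0)
  ztab <- z_table_for(layout, z)
  full <- call_epitopes(ztab, layout)
  expect_equal(nrow(full), 1L)
  # drop the middle probe's row entirely: the run is no longer contiguous
  gap <- ztab[ztab$start != 31, ]
  expect_equal(nrow(call_epitopes(gap, layout)), 0L)
})

test_that("call order is independent of input row order", {
  layout <- toy_layout(186)
  set.seed(5)
  z <- rnorm(nrow(layout$probes), 1.5, 2)
  ztab <- z_table_for(layout, z)
  shuffled <- ztab[sample(nrow(ztab)), ]
  expect_equal(call_epitopes(ztab, layout), call_epitopes(shuffled, layout))
})

test_that("invalid thresholds and empty tables are handled", {
  layout <- toy_layout(60)
  expect_error(call_epitopes(z_table_for(layout, rep(0, nrow(layout$probes))),
                             layout, threshold = 0), "threshold")
  empty <- call_epitopes(z_table_for(layout, rep(0, nrow(layout$probes)))[0, ],
                         layout)
  expect_equal(nrow(empty), 0L)
})

test_that("channel cross-referencing labels shared regions by residue overlap", {
  mk_calls <- function(channel, regions) {
    if (length(regions) == 0) {
      return(call_epitopes(NULL, toy_layout(60)))
    }
    do.call(rbind, lapply(regions, function(r) data.frame(
      patient_id = "P1", channel = channel, antigen_id = "toy",
      region_start = r[1], region_end = r[2],
      region = sprintf("aa%d-%d", r[1], r[2]), n_peptides = 2,
      probe_run = "x,y", median_z = 5, flag = "", stringsAsFactors = FALSE
    )))
  }
  ige <- mk_calls("IgE", list(c(30, 41)))
  igg4 <- mk_calls("IgG4", list(c(39, 50)))
  out <- cross_reference_channels(ige, igg4)
  expect_true(all(out$label == "both"))  # overlap at 39-41

  disjoint <- cross_reference_channels(mk_calls("IgE", list(c(1, 12))),
                                       mk_calls("IgG4", list(c(100, 111))))
  expect_setequal(disjoint$label, c("IgE-only", "IgG4-only"))

  same <- cross_reference_channels(mk_calls("IgE", list(c(1, 12))),
                                   mk_calls("IgG4", list(c(1, 12))))
  expect_true(all(same$label == "both"))
})

test_that("the epitope-by-patient matrix is binary with patients preserved", {
  calls <- data.frame(
    patient_id = c("P1", "P1", "P3"), channel = "IgE", antigen_id = "toy",
    region_start = c(30, 84, 30), region_end = c(41, 95, 41),
    region = c("aa30-41", "aa84-95", "aa30-41"), n_peptides = 2,
    probe_run = "x,y", median_z = 5, flag = "", stringsAsFactors = FALSE
  )
  m <- epitope_patient_matrix(calls, patient_ids = c("P1", "P2", "P3"))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(unname(m["P1", ]), c(1L, 1L))
  expect_equal(unname(m["P2", ]), c(0L, 0L))
  expect_equal(unname(m["P3", ]), c(1L, 0L))
})
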