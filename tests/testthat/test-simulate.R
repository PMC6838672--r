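test_that("kinome generation is seed-deterministic", {
  k1 <- generate_kinome(5, seed = 7)
  k2 <- generate_kinome(5, seed = 7)
  expect_identical(k1$sequence, k2$sequence)
  expect_identical(attr(k1, "truth"), attr(k2, "truth"))
  fa1 <- withr::local_tempfile(fileext = ".fasta")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_kinome_fasta(k1, fa1)
  write_kinome_fasta(k2, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  k3 <- generate_kinome(5, seed = 8)
  expect_false(identical(k1$sequence, k3$sequence))
})

test_that("generated kinomes round-trip through FASTA", {
  k <- generate_kinome(4, seed = 19)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_kinome_fasta(k, fa)
  back <- read_kinome(fa)
  expect_equal(back$kinase_id, k$kinase_id)
  expect_equal(back$gene, k$gene)
  expect_equal(back$sequence, k$sequence)
})

test_that("every generated record locates at its truth span", {
  k <- generate_kinome(20, seed = 13)
  truth <- attr(k, "truth")
  for (i in seq_len(nrow(k))) {
    hit <- locate_activation_segment(k$sequence[i])
    expect_equal(
      unname(hit), c(truth$segment_start[i], truth$segment_end[i])
    )
    # truth sites are S/T/Y at the stated protein positions
    pos <- as.integer(strsplit(truth$sites[i], ";")[[1]])
    chars <- strsplit(k$sequence[i], "")[[1]]
    expect_true(all(chars[pos] %in% c("S", "T", "Y")))
    expect_true(all(pos >= truth$segment_start[i] &
                      pos <= truth$segment_end[i]))
  }
})

test_that("shared segments produce exactly one kinase group", {
  k <- generate_kinome(6, seed = 7, shared_groups = c(3))
  targets <- design_targets(k, max_missed = 0, multiplicities = 1)
  m <- build_peptide_kinase_map(targets)
  truth <- attr(k, "truth")
  shared_pep <- truth$target_peptide[1]
  det <- m[m$backbone == shared_pep, c("backbone", "phospho_positions")]
  groups <- resolve_groups(det, m)
  # identical kinase sets merge: every site of the shared peptide lands in
  # the same single group of 3
  expect_equal(nrow(groups), 1)
  expect_equal(groups$n_evidence_peptides, nrow(det))
  expect_true(all(groups$n_kinases == 3))
  expect_setequal(
    strsplit(groups$kinase_ids[1], ";")[[1]],
    truth$kinase_id[1:3]
  )
})

test_that("chromatogram simulation is deterministic and recovers ratios", {
  k <- generate_kinome(3, seed = 23)
  targets <- design_targets(k, max_missed = 0, multiplicities = 1)
  a <- build_assays(targets[targets$multiplicity == 1, ][1:3, ],
                    mode = "quantification")
  peps <- unique(paste0(a$backbone, "[", a$phospho_positions, "]"))
  ratios <- tibble::tibble(peptide = peps, condition = "c1", ratio = 2)
  ch1 <- simulate_chromatograms(a, ratios, seed = 5, noise_sd = 0)
  ch2 <- simulate_chromatograms(a, ratios, seed = 5, noise_sd = 0)
  expect_identical(ch1, ch2)
  truth <- attr(ch1, "truth")
  q <- quantify_peptides(
    ch1,
    expected_rt = dplyr::distinct(truth, peptide, expected_rt = rt)
  )
  expect_true(all(q$status == "accepted"))
  expect_true(all(abs(q$ratio - 2) / 2 < 0.01))
})

test_that("dilution-series simulation honours its parameters", {
  s1 <- simulate_dilution_series(2, 0.5, 0.1, seed = 42)
  s2 <- simulate_dilution_series(2, 0.5, 0.1, seed = 42)
  expect_identical(s1, s2)
  expect_equal(sort(unique(s1$amount_fmol)), c(0.01, 0.1, 1, 5, 10, 50, 100))
  expect_equal(dplyr::n_distinct(s1$replicate), 3)
  # zero noise -> exact line, LOD 0
  s0 <- simulate_dilution_series(2, 0, 0, seed = 1)
  suppressWarnings(fit <- fit_calibration(s0))
  expect_equal(fit$lod, 0, tolerance = 1e-9)
  expect_equal(fit$b, 2, tolerance = 1e-9)
  # noise floor substitution lifts sub-floor responses
  sf <- simulate_dilution_series(2, 0, 0.01, seed = 2, noise_floor = 0.5)
  low <- sf$response[sf$amount_fmol == 0.01]
  expect_true(all(low > 0.2))
  expect_error(simulate_dilution_series(-1, 0.5, 0.1, seed = 1), "> 0")
})
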