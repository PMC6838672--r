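test_that("site-determining ions discriminate positional isomers", {
  # candidates S4 and T9 of GHLSEGLVTK: b4..b8 hold only position 4,
  # y2..y6 hold only position 9 (exhaustive span enumeration)
  sdi <- site_determining_ions("GHLSEGLVTK", c(4, 9))
  expect_setequal(
    paste0(sdi$ion_type, sdi$ion_index),
    c(paste0("b", 4:8), paste0("y", 2:6))
  )
  # single candidate: nothing to discriminate
  expect_equal(nrow(site_determining_ions("GHLSEGLVTK", 4)), 0)
  # adjacent candidates: only the cleavage between them discriminates
  sdi2 <- site_determining_ions("GHLSTGLVAK", c(4, 5))
  expect_setequal(paste0(sdi2$ion_type, sdi2$ion_index), c("b4", "y6"))
  expect_error(site_determining_ions("GHLSEGLVTK", 5), "not on S/T/Y")
})

test_that("survey mode emits exactly 3 transitions per precursor channel", {
  a <- build_assay("GHLSEGLVTK", 4, mode = "survey")
  counts <- dplyr::count(a, precursor_charge, label)
  expect_true(all(counts$n == 3))
  expect_equal(sort(unique(a$label)), c("heavy", "light"))
  # light and heavy share identical annotation lists
  split_ann <- split(a$annotation, a$label)
  expect_setequal(split_ann$light, split_ann$heavy)
})

test_that("quantification mode caps at 7 and force-includes site-determining ions", {
  a <- build_assay("GHLSEGLVTK", 4, mode = "quantification")
  counts <- dplyr::count(a, precursor_charge, label)
  expect_true(all(counts$n <= 7))
  one <- a[a$precursor_charge == 2 & a$label == "light", ]
  expect_gte(sum(one$site_determining), 1)
  # default ranking without a library: y ions over b ions, longer first
  surv <- build_assay("GHLAEGLVTK", 9, mode = "survey")
  expect_true(all(grepl("^y", surv$annotation)))
})

test_that("library intensities override the default ion ranking", {
  lib <- tibble::tibble(
    annotation = c("b4", "y3", "y7-98"),
    intensity = c(100, 80, 60)
  )
  a <- build_assay("GHLSEGLVTK", 4, mode = "survey", library_ranks = lib)
  one <- a[a$precursor_charge == 2 & a$label == "light", ]
  expect_setequal(one$annotation, c("b4", "y3", "y7-98"))
})

test_that("assay masses satisfy channel and neutral-loss relationships", {
  a <- build_assay("GHLSEGLVTK", 4, mode = "quantification")
  wide <- tidyr::pivot_wider(
    a, id_cols = c("precursor_charge", "annotation"),
    names_from = "label",
    values_from = c("precursor_mz", "product_mz")
  )
  expect_equal(
    wide$precursor_mz_heavy - wide$precursor_mz_light,
    8.014199 / wide$precursor_charge,
    tolerance = 1e-9
  )
  yions <- wide[grepl("^y", wide$annotation), ]
  prod_z <- ifelse(grepl("\\^2", yions$annotation), 2, 1)
  expect_equal(
    yions$product_mz_heavy - yions$product_mz_light,
    8.014199 / prod_z, tolerance = 1e-9
  )
  bions <- wide[grepl("^b", wide$annotation), ]
  expect_equal(bions$product_mz_heavy, bions$product_mz_light)
})

test_that("short peptides warn and emit what exists", {
  expect_warning(a <- build_assay("SK", 1, mode = "survey"), "candidate")
  expect_lte(nrow(a[a$label == "light", ]), 3)
  expect_error(build_assay("GHLSEGLVTA", 4), "C-terminal K or R")
})

test_that("build_assays skips unlabelable targets and exports a transition list", {
  targets <- design_targets(fixture_kinome(), max_missed = 0,
                            multiplicities = 1)
  a <- build_assays(targets, mode = "survey")
  expect_true(nrow(a) > 0)
  path <- withr::local_tempfile(fileext = ".csv")
  a$expected_rt <- 30
  a$window <- 4
  export_transition_list(a, path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_true(all(c(
    "proteins", "modified_sequence", "precursor_mz", "precursor_charge",
    "product_mz", "product_charge", "ion", "ce", "expected_rt", "window"
  ) %in% names(out)))
  expect_true(any(grepl("S[+80]", out$modified_sequence, fixed = TRUE)))
  expect_true(any(grepl("K[+8]", out$modified_sequence, fixed = TRUE)))
})
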