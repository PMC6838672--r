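demo_targets <- function() {
  tibble::tibble(
    backbone = c("VSEPTYAK", "VSEPTYAK", "VSEPTYAK",
                 "TATQGQLK", "TATQGQLK", "LGQGSFGK"),
    phospho_positions = c("6", "6", "6", "1", "1", "5"),
    multiplicity = 1L,
    kinase_ids = c("EPHA3", "EPHA4", "EPHA5", "HCK", "LYN", "GSK3B"),
    genes = c("EPHA3", "EPHA4", "EPHA5", "HCK", "LYN", "GSK3B"),
    site_labels = c("EPHA3_Y6", "EPHA4_Y6", "EPHA5_Y6",
                    "HCK_T1", "LYN_T1", "GSK3B_S5")
  )
}

test_that("the peptide-kinase map is the exact inverse of the target list", {
  m <- build_peptide_kinase_map(demo_targets())
  expect_equal(nrow(m), 3)
  expect_equal(
    m$kinase_ids[m$backbone == "VSEPTYAK"], "EPHA3;EPHA4;EPHA5"
  )
  expect_equal(m$kinase_ids[m$backbone == "LGQGSFGK"], "GSK3B")
  expect_error(build_peptide_kinase_map(demo_targets()[0, ]), "Empty")
  # conflicting site labels for the same peptide+kinase
  bad <- demo_targets()
  bad$site_labels[2] <- "EPHA4_Y6"
  bad$kinase_ids[2] <- "EPHA3" # same kinase, different label than row 1
  expect_error(build_peptide_kinase_map(bad), "Conflicting site labels")
})

test_that("shared peptides collapse into named kinase groups", {
  m <- build_peptide_kinase_map(demo_targets())
  detected <- m[, c("backbone", "phospho_positions")]
  groups <- resolve_groups(detected, m)
  expect_setequal(
    groups$group_id, c("EPHA3-EPHA4-EPHA5", "HCK-LYN", "GSK3B")
  )
  s <- glance(groups)
  expect_equal(s$n_sites, 3)
  expect_equal(s$n_groups, 3)
  expect_equal(s$n_kinases, 6)
})

test_that("identical kinase sets merge evidence; unique peptides stay singletons", {
  targets <- tibble::tibble(
    backbone = c("AAASK", "CCCTK", "DDDYK"),
    phospho_positions = c("4", "4", "4"),
    multiplicity = 1L,
    kinase_ids = c("A;B", "A;B", "C"),
    genes = c("A;B", "A;B", "C"),
    site_labels = c("A_S4;B_S4", "A_T4;B_T4", "C_Y4")
  )
  m <- build_peptide_kinase_map(targets)
  groups <- resolve_groups(m[, 1:2], m)
  s <- glance(groups)
  expect_equal(s$n_sites, 3)
  expect_equal(s$n_groups, 2)
  expect_equal(s$n_kinases, 3)
  ab <- groups[groups$group_id == "A-B", ]
  expect_equal(ab$n_evidence_peptides, 2)

  # three unique peptides -> three groups
  uniq <- targets
  uniq$kinase_ids <- c("A", "B", "C")
  uniq$genes <- uniq$kinase_ids
  uniq$site_labels <- c("A_S4", "B_T4", "C_Y4")
  mu <- build_peptide_kinase_map(uniq)
  su <- glance(resolve_groups(mu[, 1:2], mu))
  expect_equal(unlist(su), c(n_sites = 3, n_groups = 3, n_kinases = 3))
})

test_that("grouping is order-independent and idempotent", {
  kin <- generate_kinome(12, seed = 21, shared_groups = c(3, 2))
  targets <- design_targets(kin, max_missed = 0, multiplicities = 1)
  m <- build_peptide_kinase_map(targets)
  detected <- m[, c("backbone", "phospho_positions")]
  g1 <- resolve_groups(detected, m)
  set.seed(1)
  g2 <- resolve_groups(detected[sample(nrow(detected)), ], m)
  expect_identical(g1$group_id, g2$group_id)
  expect_identical(glance(g1), glance(g2))
  s <- glance(g1)
  expect_lte(s$n_groups, s$n_sites)
  expect_gte(s$n_kinases, s$n_groups)
  # re-resolving the evidence of the groups is a fixed point
  evidence <- tibble::tibble(
    key = unlist(strsplit(g1$evidence, ";"))
  )
  evidence$backbone <- sub("\\[.*", "", evidence$key)
  evidence$phospho_positions <- sub(".*\\[(.*)\\]", "\\1", evidence$key)
  g3 <- resolve_groups(evidence[, c("backbone", "phospho_positions")], m)
  expect_identical(g1$group_id, g3$group_id)
  expect_identical(g1$kinase_ids, g3$kinase_ids)
})

test_that("detections missing from the map raise a listing error", {
  m <- build_peptide_kinase_map(demo_targets())
  bad <- tibble::tibble(backbone = "NOPEPTIDEK", phospho_positions = "3")
  expect_error(resolve_groups(bad, m), "NOPEPTIDEK")
})
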