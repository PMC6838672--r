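ratio_table <- function(values_by_cond, n_bio = 3, n_tech = 2,
                        peptide = "P1") {
  tidyr::expand_grid(
    condition = names(values_by_cond),
    bio_rep = seq_len(n_bio), tech_rep = seq_len(n_tech)
  ) |>
    dplyr::mutate(
      peptide = peptide,
      ratio = purrr::pmap_dbl(
        list(condition, bio_rep, tech_rep),
        function(cond, b, t) {
          v <- values_by_cond[[cond]]
          if (length(v) == 1) v
          else if (length(v) == n_bio) v[b]
          else v[(b - 1) * n_tech + t]
        }
      )
    )
}

test_that("normalization rescales to the reference mean and is idempotent", {
  d <- tibble::tibble(
    peptide = rep(c("P1", "P2"), each = 4),
    condition = rep(c("ctrl", "ctrl", "stim", "stim"), 2),
    ratio = c(2, 2, 4, 6, 1, 3, 2, 2)
  )
  n1 <- normalize_to_reference(d, "ctrl")
  expect_equal(n1$ratio[n1$peptide == "P1"], c(1, 1, 2, 3))
  expect_equal(n1$ratio[n1$peptide == "P2"], c(0.5, 1.5, 1, 1))
  # reference means are now 1 -> renormalizing changes nothing
  n2 <- normalize_to_reference(n1, "ctrl")
  expect_equal(n2$ratio, n1$ratio)
  # all-equal values collapse to 1
  flat <- normalize_to_reference(
    dplyr::mutate(d, ratio = 5), "ctrl"
  )
  expect_true(all(flat$ratio == 1))
})

test_that("a peptide with no reference ratio is flagged, not normalized", {
  d <- tibble::tibble(
    peptide = c("P1", "P1", "P2", "P2"),
    condition = c("ctrl", "stim", "ctrl", "stim"),
    ratio = c(2, 4, NA, 6)
  )
  expect_warning(out <- normalize_to_reference(d, "ctrl"), "P2")
  expect_false(any(out$normalized[out$peptide == "P2"]))
  expect_equal(out$ratio[out$peptide == "P2" & out$condition == "stim"], 6)
  expect_error(normalize_to_reference(d, "nope"), "not present")
})

test_that("identical conditions give zero fold change and no significance", {
  set.seed(3)
  base <- exp(rnorm(3, 0, 0.1))
  d <- ratio_table(list(A = rep(base, 2), B = rep(base, 2)))
  res <- differential_test(d, reference = "A")
  expect_equal(res$log2fc, 0, tolerance = 1e-9)
  expect_gt(res$p, 0.05)
  expect_false(res$significant)
})

test_that("two conditions reduce to the pooled two-sample t-test", {
  set.seed(14)
  d <- ratio_table(list(A = exp(rnorm(6, 0, 0.2)),
                        B = exp(rnorm(6, 0.5, 0.2))))
  res <- differential_test(d, reference = "A")
  means <- d |>
    dplyr::mutate(y = log2(ratio)) |>
    dplyr::summarise(y = mean(y), .by = c(condition, bio_rep))
  tt <- t.test(y ~ condition, data = means, var.equal = TRUE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$log2fc,
               -diff(tt$estimate)[[1]] * -1, tolerance = 1e-12)
})

test_that("single biological replicates yield fold changes without p-values", {
  d <- ratio_table(list(A = 2, B = 4), n_bio = 1, n_tech = 2)
  expect_warning(res <- differential_test(d, reference = "A"), "replicates")
  expect_equal(res$log2fc, 1, tolerance = 1e-9)
  expect_true(is.na(res$p))
})

test_that("a simulated 2-fold change is recovered with high power", {
  n_sim <- 60
  hits <- purrr::map_dfr(seq_len(n_sim), function(i) {
    set.seed(500 + i)
    d <- ratio_table(list(
      A = exp(rnorm(6, 0, 0.05)),
      B = 2 * exp(rnorm(6, 0, 0.05))
    ))
    differential_test(d, reference = "A")
  })
  expect_true(all(hits$log2fc > 0.8 & hits$log2fc < 1.2))
  expect_gte(mean(hits$significant), 0.95)
})

test_that("technical replicates are averaged before testing", {
  # inflate one technical replicate wildly: averaging keeps bio_rep means
  d <- ratio_table(list(A = c(1, 1, 1), B = c(2, 2, 2)), n_tech = 1)
  d2 <- dplyr::bind_rows(
    dplyr::mutate(d, tech_rep = 1),
    dplyr::mutate(d, tech_rep = 2, ratio = ratio^3)
  )
  res <- differential_test(d2, reference = "A")
  # mean of log2 over tech reps: (x + 3x)/2 = 2x -> log2fc doubles
  expect_equal(res$log2fc, 2, tolerance = 1e-9)
})

test_that("multi-condition designs contrast each level against the reference", {
  set.seed(6)
  d <- ratio_table(list(
    naive = exp(rnorm(6, 0, 0.1)),
    sensitive = exp(rnorm(6, 0.3, 0.1)),
    resistant = 2 * exp(rnorm(6, 0, 0.1))
  ))
  res <- differential_test(d, reference = "naive")
  expect_setequal(res$condition, c("sensitive", "resistant"))
  expect_true(all(res$reference == "naive"))
  adj <- differential_test(d, reference = "naive", adjust = TRUE)
  expect_true("p_adj" %in% names(adj))
  expect_true(all(adj$p_adj >= adj$p, na.rm = TRUE))
})
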