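test_that("integration recovers the closed-form Gaussian area", {
  # area of A * exp(-t^2 / (2 sigma^2)) is A * sigma * sqrt(2*pi)
  tr <- gaussian_trace(c("y7", "y6"), c(1e5, 5e4), rt = 30, sigma_s = 5)
  out <- integrate_peak(tr, window = c(29.5, 30.5))
  expected <- c(1e5, 5e4) * 5 * sqrt(2 * pi)
  got <- out$areas$area[match(c("y7", "y6"), out$areas$ion)]
  # the 1%-of-apex boundary rule plus linear baseline subtraction trims
  # ~2.7% of the analytic Gaussian area
  expect_equal(got, expected, tolerance = 0.03)
  expect_equal(out$apex_rt, 30, tolerance = 0.01)
  expect_false(out$no_signal)
})

test_that("all-zero traces yield zero areas with a no-signal flag", {
  tr <- gaussian_trace(c("y7", "y6"), c(0, 0))
  out <- integrate_peak(tr)
  expect_true(out$no_signal)
  expect_equal(out$summed_area, 0)
  expect_error(integrate_peak(tr, window = c(100, 101)), "Empty")
})

test_that("boundaries exclude a separated second peak", {
  grid <- seq(29, 31, by = 0.005)
  sig <- 4 / 60
  tall <- 1e5 * exp(-(grid - 29.6)^2 / (2 * sig^2))
  short <- 4e4 * exp(-(grid - 30.5)^2 / (2 * sig^2))
  tr <- tibble::tibble(ion = "y7", time = grid, intensity = tall + short)
  out <- integrate_peak(tr)
  expect_equal(out$apex_rt, 29.6, tolerance = 0.01)
  expect_lt(out$right, 30.3) # boundary stops before the second peak
  # area close to the tall peak alone
  expect_equal(out$summed_area, 1e5 * 4 * sqrt(2 * pi), tolerance = 0.03)
})

test_that("integration is linear and ratios are scale-invariant", {
  set.seed(5)
  tr <- gaussian_trace(c("y7", "y6", "b4"), c(8e4, 5e4, 2e4))
  a1 <- integrate_peak(tr)
  tr2 <- dplyr::mutate(tr, intensity = intensity * 3.7)
  a2 <- integrate_peak(tr2)
  expect_equal(a2$areas$area, 3.7 * a1$areas$area, tolerance = 1e-9)
})

test_that("rdotp measures pattern similarity with scale invariance", {
  expect_equal(rdotp(c(a = 1, b = 2, c = 2), c(a = 1, b = 2, c = 2)), 1)
  expect_equal(rdotp(c(a = 1, b = 2, c = 2), c(a = 2, b = 4, c = 4)), 1)
  expect_equal(rdotp(c(a = 1, b = 0, c = 0), c(a = 0, b = 1, c = 0)), 0)
  expect_equal(rdotp(c(a = 0, b = 0), c(a = 1, b = 1)), 0) # zero vector
  # symmetry and rescaling invariance on random vectors
  set.seed(8)
  for (i in 1:20) {
    l <- setNames(runif(4), letters[1:4])
    h <- setNames(runif(4), letters[1:4])
    expect_equal(rdotp(l, h), rdotp(h, l))
    expect_equal(rdotp(l * 13, h), rdotp(l, h), tolerance = 1e-12)
  }
  expect_error(rdotp(c(a = 1, b = 1), c(a = 1, x = 1)), "do not match")
  expect_error(rdotp(c(a = 1), c(a = 1)), "At least 2")
})

test_that("the acceptance rule applies rdotp, co-elution and noise thresholds", {
  good <- list(apex_rt = 30.0, summed_area = 1e5, no_signal = FALSE)
  heavy <- list(apex_rt = 30.05, summed_area = 2e5, no_signal = FALSE)
  expect_equal(assess_signal(good, heavy, 0.95, noise_area = 10), "accepted")
  expect_equal(assess_signal(good, heavy, 0.85, noise_area = 10), "rejected")
  # rdotp exactly at the threshold is not enough (strict inequality)
  expect_equal(assess_signal(good, heavy, 0.9, noise_area = 10), "rejected")
  late <- list(apex_rt = 30.5, summed_area = 1e5, no_signal = FALSE)
  expect_equal(assess_signal(late, heavy, 0.95, noise_area = 10), "rejected")
  absent <- list(apex_rt = NA_real_, summed_area = 0, no_signal = TRUE)
  expect_equal(
    assess_signal(absent, heavy, NA_real_, noise_area = 50,
                  accepted_elsewhere = TRUE),
    "on_off"
  )
  expect_error(
    assess_signal(good, list(no_signal = TRUE), 0.95),
    "mandatory"
  )
})

test_that("ratio readout follows status", {
  expect_equal(quantify_ratio(2000, 1000, "accepted")$ratio, 2)
  r <- quantify_ratio(NA, 1000, "on_off", noise_area = 50)
  expect_equal(r$ratio, 0.05)
  expect_true(r$censored)
  expect_true(is.na(quantify_ratio(2000, 1000, "rejected")$ratio))
  expect_error(quantify_ratio(2000, 0, "accepted"), "positive")
})

test_that("full quantification recovers ratios and flags on/off states", {
  set.seed(31)
  ions <- c("y7", "y6", "b4")
  amps <- c(8e4, 5e4, 2e4)
  make_chrom <- function(cond, ratio) {
    dplyr::bind_rows(
      dplyr::mutate(
        gaussian_trace(ions, amps, rt = 30, noise_sd = 100),
        channel = "heavy"
      ),
      dplyr::mutate(
        gaussian_trace(ions, amps * ratio, rt = 30, noise_sd = 100),
        channel = "light"
      )
    ) |> dplyr::mutate(peptide = "PEPK[1]", condition = cond)
  }
  chrom <- dplyr::bind_rows(make_chrom("ctrl", 2), make_chrom("stim", 0))
  q <- quantify_peptides(
    chrom,
    expected_rt = tibble::tibble(peptide = "PEPK[1]", expected_rt = 30)
  )
  ctrl <- q[q$condition == "ctrl", ]
  stim <- q[q$condition == "stim", ]
  expect_equal(ctrl$status, "accepted")
  expect_gt(ctrl$rdotp, 0.99)
  expect_equal(ctrl$ratio, 2, tolerance = 0.02)
  # light absent in stim but accepted in ctrl -> on/off with noise readout
  expect_equal(stim$status, "on_off")
  expect_true(stim$censored)
  expect_lt(stim$ratio, 0.1)
})

test_that("an interfering light pattern is rejected by rdotp", {
  set.seed(32)
  ions <- c("y7", "y6", "b4")
  chrom <- dplyr::bind_rows(
    dplyr::mutate(gaussian_trace(ions, c(8e4, 5e4, 2e4), rt = 30),
                  channel = "heavy"),
    # inverted pattern: same total signal, different shape
    dplyr::mutate(gaussian_trace(ions, c(2e4, 1e4, 9e4), rt = 30),
                  channel = "light")
  ) |> dplyr::mutate(peptide = "PEPK[1]")
  q <- quantify_peptides(chrom)
  expect_equal(q$status, "rejected")
  expect_lt(q$rdotp, 0.9)
  expect_true(is.na(q$ratio))
})
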