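#' Fit a dilution-series calibration with LOD/LOQ
#'
#' Ordinary least squares of response on spiked amount, pooled over all
#' replicates, gives the sensitivity (slope) `b`; per-replicate regressions
#' give one intercept each, whose spread estimates `S_a`, the standard
#' deviation of the intercept. Detection limits follow
#' `LOD = 3 S_a / b` and `LOQ = 10 S_a / b`, so `LOQ = (10/3) LOD` exactly.
#' Because responses below the detection limit sit on the noise floor and
#' would flatten the regression, sub-LOD levels are excluded iteratively:
#' among the levels below the current LOD all but the highest are dropped,
#' the fit is repeated, and the procedure stops when the excluded set is
#' stable (at most one pass per level).
#'
#' With a handful of replicates the sample standard deviation of the
#' intercepts is biased low; by default it is divided by the finite-sample
#' normal-consistency constant c4(n) to give an unbiased estimate of the
#' intercept sigma (`sa_correct = FALSE` restores the raw SD). The
#' alternative reading of `S_a` — the standard error of the intercept of
#' the pooled fit — is available via `sa_method = "fit_se"`.
#'
#' @param series Tibble with columns `amount_fmol`, `replicate`,
#'   `response`; at least 4 levels and 2 replicates.
#' @param sa_method `"replicate_sd"` (default) or `"fit_se"`.
#' @param sa_correct Apply the c4 unbiasedness correction to the
#'   replicate-SD estimate (default `TRUE`).
#' @return An object of class `calibration_fit`: `b` (slope), `intercept`,
#'   `intercepts` (per replicate), `s_a`, `lod`, `loq` (fmol),
#'   `excluded_levels`, `valid` (slope > 0), `r_squared`, `data`.
#' @examples
#' series <- simulate_dilution_series(
#'   b_true = 2, intercept_sd = 0.5, noise_sd = 0.05, seed = 1
#' )
#' fit <- fit_calibration(series)
#' glance(fit)
#' @export
fit_calibration <- function(series, sa_method = c("replicate_sd", "fit_se"),
                            sa_correct = TRUE) {
  sa_method <- arg_match(sa_method)
  need <- c("amount_fmol", "replicate", "response")
  if (!all(need %in% names(series))) {
    abort("`series` needs columns amount_fmol, replicate, response.")
  }
  levels_all <- sort(unique(series$amount_fmol))
  if (length(levels_all) < 4L) abort("At least 4 dilution levels required.")
  if (length(unique(series$replicate)) < 2L) {
    abort("At least 2 replicates required for S_a estimation.")
  }
  if (length(unique(series$amount_fmol)) < 2L ||
        sd(series$amount_fmol) == 0) {
    abort("Degenerate series: no variance in amounts.")
  }

  excluded <- numeric()
  fit <- NULL
  for (iter in seq_len(length(levels_all) + 1L)) {
    fit <- calibration_pass(series, excluded, sa_method, sa_correct)
    below <- levels_all[levels_all < fit$lod]
    new_excluded <- setdiff(below, max(below, -Inf)) # keep highest sub-LOD
    if (setequal(new_excluded, excluded)) break
    excluded <- new_excluded
  }
  fit$excluded_levels <- sort(excluded)
  fit$n_levels <- length(levels_all)
  fit$n_replicates <- length(unique(series$replicate))
  fit$data <- series %>%
    mutate(excluded = .data$amount_fmol %in% fit$excluded_levels)
  class(fit) <- "calibration_fit"
  if (!fit$valid) {
    warn("Non-positive slope: calibration fit flagged invalid.")
  }
  fit
}

calibration_pass <- function(series, excluded, sa_method, sa_correct) {
  use <- filter(series, !.data$amount_fmol %in% excluded)
  pooled <- lm(response ~ amount_fmol, data = use)
  b <- unname(coef(pooled)[2])
  a <- unname(coef(pooled)[1])
  intercepts <- use %>%
    group_by(.data$replicate) %>%
    summarise(
      intercept = unname(coef(lm(response ~ amount_fmol,
                                 data = dplyr::pick(dplyr::everything())))[1]),
      .groups = "drop"
    )
  psum <- suppressWarnings(summary(pooled)) # exact fits warn harmlessly
  s_a <- if (sa_method == "fit_se") {
    psum$coefficients[1, "Std. Error"]
  } else {
    raw <- sd(intercepts$intercept)
    if (sa_correct) raw / c4_constant(nrow(intercepts)) else raw
  }
  valid <- is.finite(b) && b > 0
  lod <- if (valid) 3 * s_a / b else NA_real_
  loq <- if (valid) 10 * s_a / b else NA_real_
  list(
    b = b, intercept = a, intercepts = intercepts, s_a = s_a,
    lod = lod, loq = loq, valid = valid,
    r_squared = psum$r.squared
  )
}

# E[sd] = c4(n) * sigma for iid normal samples.
c4_constant <- function(n) {
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Calibration fit%s: b = %.4g, S_a = %.4g\n",
      "  LOD = %.4g fmol, LOQ = %.4g fmol",
      " (%d levels, %d replicates; excluded: %s)\n"
    ),
    if (x$valid) "" else " [INVALID: non-positive slope]",
    x$b, x$s_a, x$lod, x$loq, x$n_levels, x$n_replicates,
    if (length(x$excluded_levels) == 0) {
      "none"
    } else {
      paste(x$excluded_levels, collapse = ", ")
    }
  ))
  invisible(x)
}

#' Tidy a calibration fit
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return Tibble of terms: slope, intercept, s_a, lod, loq.
#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble(
    term = c("slope", "intercept", "s_a", "lod_fmol", "loq_fmol"),
    estimate = c(x$b, x$intercept, x$s_a, x$lod, x$loq)
  )
}

#' Summarise a calibration fit
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble(
    b = x$b, s_a = x$s_a, lod_fmol = x$lod, loq_fmol = x$loq,
    r_squared = x$r_squared, valid = x$valid,
    n_levels = x$n_levels, n_replicates = x$n_replicates,
    n_excluded = length(x$excluded_levels)
  )
}

#' Plot a dilution-series calibration
#'
#' Response vs spiked amount on log10 axes with the pooled fit and LOD/LOQ
#' markers; excluded sub-LOD points are hollow.
#'
#' @param object A `calibration_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_fit <- function(object, ...) {
  dat <- object$data
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$amount_fmol, y = .data$response)
  ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$excluded)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::geom_abline(
      slope = object$b, intercept = object$intercept, colour = "steelblue"
    ) +
    ggplot2::geom_vline(
      xintercept = c(object$lod, object$loq),
      linetype = c("dashed", "dotted"), colour = "firebrick"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Spiked amount (fmol)", y = "Response",
      shape = "Excluded (< LOD)",
      title = sprintf(
        "LOD = %.3g fmol, LOQ = %.3g fmol", object$lod, object$loq
      )
    )
}
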