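#' Calibrate retention time against reference standards
#'
#' Least-squares map from an indexed retention-time (iRT-style) reference
#' scale to observed minutes on the current chromatographic setup, used to
#' adapt scheduling windows to the instrument state.
#'
#' @param observed Observed retention times (minutes) of the standards.
#' @param reference Their reference-scale values (same length, >= 2
#'   distinct values).
#' @return An object of class `rt_map` with elements `slope`, `intercept`,
#'   `residual_sd`, `n`. Use `predict(map, reference)` to convert.
#' @examples
#' m <- calibrate_rt(c(10, 20, 40), c(0, 50, 150))
#' predict(m, 100)
#' @export
calibrate_rt <- function(observed, reference) {
  if (length(observed) != length(reference)) {
    abort("`observed` and `reference` must have the same length.")
  }
  if (length(observed) < 2L) {
    abort("At least 2 paired RT standards are required.")
  }
  if (length(unique(reference)) < 2L) {
    abort("Reference values are degenerate (all identical).")
  }
  fit <- lm(observed ~ reference)
  out <- list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    residual_sd = suppressWarnings(summary(fit))$sigma,
    n = length(observed)
  )
  class(out) <- "rt_map"
  out
}

#' @export
predict.rt_map <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata
}

#' @export
print.rt_map <- function(x, ...) {
  cat(sprintf(
    "RT map: minutes = %.4f + %.4f * reference (residual SD %.3f, n = %d)\n",
    x$intercept, x$slope, x$residual_sd, x$n
  ))
  invisible(x)
}

#' Tidy an RT calibration
#' @param x An `rt_map`.
#' @param ... Unused.
#' @export
tidy.rt_map <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

mode_schedule_defaults <- function(mode) {
  if (identical(mode, "survey")) {
    list(window = 4, cycle_time = 4)
  } else {
    list(window = 6, cycle_time = 2.75)
  }
}

#' Schedule an SRM acquisition method
#'
#' Assigns each assay a retention-time window centred on its expected RT
#' and checks acquisition feasibility: at the worst point of the gradient,
#' the instrument must divide the cycle time over all concurrently
#' scheduled transitions, and the resulting dwell time must stay above the
#' dwell floor. Mode presets follow the survey (4 min windows / 4 s cycles)
#' vs quantification (6-10 min windows / 2.5-3 s cycles) conventions.
#'
#' @param transitions Transition tibble from [build_assays()] with an
#'   `expected_rt` column in minutes, or an `irt` column plus `rt_map`.
#' @param rt_map Optional [calibrate_rt()] object converting `irt` to
#'   minutes.
#' @param window Scheduling-window width in minutes (default by mode).
#' @param cycle_time Cycle time in seconds (default by mode).
#' @param dwell_floor_ms Minimum acceptable dwell time in ms (default 10).
#' @return An object of class `srm_schedule`: list with `transitions`
#'   (input plus `window`, `window_start`, `window_end`), `cycle_time`,
#'   `dwell_floor_ms`, and `report` (max concurrent transitions, worst RT,
#'   dwell in ms, feasibility). Infeasibility is reported, never raised.
#' @export
schedule_method <- function(transitions, rt_map = NULL, window = NULL,
                            cycle_time = NULL, dwell_floor_ms = 10) {
  mode <- if ("mode" %in% names(transitions) && nrow(transitions) > 0) {
    transitions$mode[1]
  } else {
    "quantification"
  }
  defaults <- mode_schedule_defaults(mode)
  window <- window %||% defaults$window
  cycle_time <- cycle_time %||% defaults$cycle_time

  if (!"expected_rt" %in% names(transitions)) {
    if (!is.null(rt_map) && "irt" %in% names(transitions)) {
      transitions$expected_rt <- predict(rt_map, transitions$irt)
    } else {
      abort("Transitions need `expected_rt` (or `irt` plus an `rt_map`).")
    }
  }
  transitions <- transitions %>%
    mutate(
      window = window,
      window_start = .data$expected_rt - window / 2,
      window_end = .data$expected_rt + window / 2
    )

  report <- concurrency_report(transitions, cycle_time, dwell_floor_ms)
  out <- list(
    transitions = transitions,
    cycle_time = cycle_time,
    dwell_floor_ms = dwell_floor_ms,
    report = report
  )
  class(out) <- "srm_schedule"
  out
}

# Concurrency is piecewise constant between window endpoints, so evaluating
# the count at every window start (plus a point inside each maximal
# overlap) is exact.
concurrency_report <- function(transitions, cycle_time, dwell_floor_ms) {
  if (nrow(transitions) == 0) {
    return(tibble(
      max_concurrent = 0L, worst_rt = NA_real_, dwell_ms = Inf,
      feasible = TRUE, assays_at_worst = ""
    ))
  }
  probes <- sort(unique(c(
    transitions$window_start,
    (transitions$window_start + transitions$window_end) / 2
  )))
  counts <- purrr::map_int(probes, function(t) {
    sum(transitions$window_start <= t & t < transitions$window_end)
  })
  k <- which.max(counts)
  max_conc <- counts[k]
  worst <- probes[k]
  active <- transitions$window_start <= worst & worst < transitions$window_end
  dwell <- cycle_time / max_conc * 1000
  tibble(
    max_concurrent = max_conc,
    worst_rt = worst,
    dwell_ms = dwell,
    feasible = dwell >= dwell_floor_ms,
    assays_at_worst = paste(
      sort(unique(paste0(
        transitions$backbone[active], "[",
        transitions$phospho_positions[active], "]"
      ))),
      collapse = ";"
    )
  )
}

#' @export
print.srm_schedule <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0(
      "SRM schedule: %d transitions, cycle %.2f s\n",
      "  max concurrent %d at RT %.2f min -> dwell %.1f ms (floor %.0f ms): %s\n"
    ),
    nrow(x$transitions), x$cycle_time, r$max_concurrent, r$worst_rt,
    r$dwell_ms, x$dwell_floor_ms,
    if (r$feasible) "feasible" else "INFEASIBLE"
  ))
  invisible(x)
}

#' Summarise a scheduled method
#' @param x An `srm_schedule`.
#' @param ... Unused.
#' @return One-row tibble: transitions, cycle time, max concurrency, dwell,
#'   feasibility.
#' @export
glance.srm_schedule <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      n_transitions = nrow(x$transitions),
      cycle_time_s = x$cycle_time,
      dwell_floor_ms = x$dwell_floor_ms
    ),
    x$report
  )
}

#' Plot scheduled acquisition windows
#'
#' Transition count over the gradient, with the dwell-implied capacity.
#'
#' @param object An `srm_schedule`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.srm_schedule <- function(object, ...) {
  tr <- object$transitions
  grid <- seq(
    min(tr$window_start), max(tr$window_end),
    length.out = 400
  )
  counts <- purrr::map_int(grid, function(t) {
    sum(tr$window_start <= t & t < tr$window_end)
  })
  capacity <- object$cycle_time / (object$dwell_floor_ms / 1000)
  ggplot2::ggplot(
    tibble(rt = grid, concurrent = counts),
    ggplot2::aes(x = .data$rt, y = .data$concurrent)
  ) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(
      yintercept = capacity, linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "Retention time (min)", y = "Concurrent transitions",
      title = "Scheduled transition concurrency",
      subtitle = sprintf(
        "cycle %.2f s; dashed line = capacity at %.0f ms dwell floor",
        object$cycle_time, object$dwell_floor_ms
      )
    )
}
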