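#' Read a chromatogram table
#'
#' Tidy tab-separated chromatograms: one row per sampled point, columns
#' `peptide`, `channel` (`light`/`heavy`), `ion`, `time` (minutes),
#' `intensity` (counts), plus any extra annotation columns (e.g.
#' `condition`, `replicate`).
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_chromatograms <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Integrate a chromatographic peak
#'
#' Locates the peak apex as the maximum of the transition-summed trace
#' inside the search window, walks outward to the nearest flanking local
#' minima — or to the points where the summed trace drops below 1% of the
#' apex, whichever comes first — and integrates each transition between
#' those boundaries by the trapezoidal rule after subtracting a straight
#' baseline (the mean of that transition's boundary intensities).
#'
#' Apex and boundary detection run on a lightly smoothed (9-point moving
#' average) summed trace with a noise tolerance estimated from the
#' raw-minus-smoothed residuals, so baseline noise does not spawn spurious
#' local minima next to the apex; integration itself uses the raw trace.
#'
#' @param chrom Tibble with columns `ion`, `time` (minutes, identical grid
#'   across ions), `intensity` for one peptide and channel.
#' @param window Numeric `c(start, end)` in minutes bounding the apex
#'   search; defaults to the full trace.
#' @param apex_fraction Boundary stop fraction of apex height (default
#'   0.01).
#' @param bounds Optional fixed integration boundaries `c(left, right)` in
#'   minutes (e.g. taken from the internal-standard channel); skips
#'   boundary detection.
#' @return List: `apex_rt`, `left`, `right` (minutes), `areas` (tibble
#'   `ion`, `area` in counts * s), `summed_area`, `no_signal`.
#' @export
integrate_peak <- function(chrom, window = NULL, apex_fraction = 0.01,
                           bounds = NULL) {
  wide <- chrom %>%
    arrange(.data$time) %>%
    tidyr::pivot_wider(
      id_cols = "time", names_from = "ion", values_from = "intensity"
    )
  times <- wide$time
  mat <- as.matrix(wide[, -1, drop = FALSE])
  if (any(mat < 0, na.rm = TRUE)) abort("Negative intensities.")
  summed <- rowSums(mat)
  if (is.null(window)) window <- range(times)
  in_win <- which(times >= window[1] & times <= window[2])
  if (length(in_win) == 0) abort("Empty integration window.")

  if (!is.null(bounds)) {
    idx <- which(times >= bounds[1] & times <= bounds[2])
    if (length(idx) < 2) abort("Empty integration window.")
    in_win <- idx
  }
  if (all(summed[in_win] == 0)) {
    return(list(
      apex_rt = NA_real_, left = times[in_win[1]],
      right = times[in_win[length(in_win)]],
      areas = tibble(ion = colnames(mat), area = 0),
      summed_area = 0, no_signal = TRUE
    ))
  }
  smooth <- moving_average(summed, 9L)
  noise_tol <- 3 * stats::mad(summed - smooth, na.rm = TRUE)
  if (!is.null(bounds)) {
    left <- in_win[1]
    right <- in_win[length(in_win)]
    apex <- in_win[which.max(smooth[in_win])]
  } else {
    apex <- in_win[which.max(smooth[in_win])]
    floor_val <- apex_fraction * smooth[apex]
    left <- apex
    while (left > 1) {
      if (smooth[left - 1] < floor_val) { left <- left - 1L; break }
      if (smooth[left - 1] > smooth[left] + noise_tol) break # rising again
      left <- left - 1L
    }
    right <- apex
    n <- length(summed)
    while (right < n) {
      if (smooth[right + 1] < floor_val) { right <- right + 1L; break }
      if (smooth[right + 1] > smooth[right] + noise_tol) break
      right <- right + 1L
    }
  }

  idx <- left:right
  areas <- purrr::map_dbl(seq_len(ncol(mat)), function(j) {
    y <- mat[idx, j]
    base <- mean(y[c(1, length(y))])
    trap <- trapz(times[idx], y) - base * (times[idx[length(idx)]] - times[idx[1]])
    max(trap, 0) * 60 # minutes -> seconds
  })
  areas <- tibble(ion = colnames(mat), area = areas)
  list(
    apex_rt = times[apex], left = times[left], right = times[right],
    areas = areas, summed_area = sum(areas$area), no_signal = FALSE
  )
}

moving_average <- function(x, k) {
  k <- min(k, length(x))
  if (k < 3L) return(x)
  if (k %% 2L == 0L) k <- k - 1L
  sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Light/heavy transition-pattern similarity (rdotp)
#'
#' Normalized dot product between the per-transition area patterns of the
#' endogenous (light) and internal-standard (heavy) peptide. Values near 1
#' indicate the two channels carry the same analyte; the acceptance rule is
#' rdotp > 0.9.
#'
#' @param light_areas,heavy_areas Named numeric vectors (names = ion
#'   annotations) or tibbles with columns `ion`, `area`; at least two
#'   matched transitions.
#' @return Value in `[0, 1]`; 0 when either vector is all-zero.
#' @examples
#' rdotp(c(y7 = 1, y6 = 2, b4 = 2), c(y7 = 2, y6 = 4, b4 = 4))
#' @export
rdotp <- function(light_areas, heavy_areas) {
  l <- as_area_vector(light_areas)
  h <- as_area_vector(heavy_areas)
  if (length(l) != length(h) || !setequal(names(l), names(h))) {
    abort("Light and heavy transition annotations do not match.")
  }
  if (length(l) < 2L) abort("At least 2 matched transitions are required.")
  h <- h[names(l)]
  nl <- sqrt(sum(l^2))
  nh <- sqrt(sum(h^2))
  if (nl == 0 || nh == 0) return(0)
  min(sum(l * h) / (nl * nh), 1)
}

as_area_vector <- function(x) {
  if (is.data.frame(x)) {
    setNames(x$area, x$ion)
  } else {
    if (is.null(names(x))) abort("Area vectors must be named by ion.")
    x
  }
}

#' Accept, reject or flag a light/heavy signal pair
#'
#' Acceptance mimics expert review of co-elution: the light signal is
#' accepted when the transition patterns agree (rdotp above threshold), the
#' apexes co-elute within an RT tolerance, and the light summed area
#' exceeds the noise floor. Failing signals are rejected — unless the
#' replicate context shows a clear on/off state (the peptide accepted in at
#' least one other condition while absent here), in which case the status
#' is `on_off` and the noise area becomes the quantitative readout.
#'
#' @param light,heavy Results of [integrate_peak()] for each channel.
#' @param rdotp_value Pattern similarity from [rdotp()].
#' @param noise_area Estimated noise area (counts * s), used both as floor
#'   and as the censored readout for on/off peptides.
#' @param rdotp_min rdotp acceptance threshold (default 0.9, exclusive).
#' @param rt_tolerance Maximum |light - heavy| apex difference in minutes
#'   (default 0.2).
#' @param accepted_elsewhere Logical: was this peptide accepted in another
#'   condition of the same experiment?
#' @return Character status: `"accepted"`, `"rejected"` or `"on_off"`.
#' @export
assess_signal <- function(light, heavy, rdotp_value, noise_area = 0,
                          rdotp_min = 0.9, rt_tolerance = 0.2,
                          accepted_elsewhere = FALSE) {
  if (is.null(heavy) || isTRUE(heavy$no_signal)) {
    abort("Heavy (internal standard) channel is mandatory.")
  }
  rt_delta <- light$apex_rt - heavy$apex_rt
  ok <- !isTRUE(light$no_signal) &&
    !is.na(rdotp_value) && rdotp_value > rdotp_min &&
    !is.na(rt_delta) && abs(rt_delta) <= rt_tolerance &&
    light$summed_area > noise_area
  if (ok) return("accepted")
  if (isTRUE(accepted_elsewhere)) return("on_off")
  "rejected"
}

#' Analyte/internal-standard ratio readout
#'
#' @param light_area Light summed area (counts * s).
#' @param heavy_area Heavy summed area (> 0 unless rejected).
#' @param status Status from [assess_signal()].
#' @param noise_area Noise area used for the censored on/off readout.
#' @return One-row tibble `ratio`, `censored`.
#' @export
quantify_ratio <- function(light_area, heavy_area, status, noise_area = 0) {
  if (status == "rejected") {
    return(tibble(ratio = NA_real_, censored = FALSE))
  }
  if (is.na(heavy_area) || heavy_area <= 0) {
    abort("Heavy area must be positive for accepted/on_off signals.")
  }
  if (status == "on_off") {
    return(tibble(ratio = noise_area / heavy_area, censored = TRUE))
  }
  tibble(ratio = light_area / heavy_area, censored = FALSE)
}

#' Quantify peptides from tidy chromatograms
#'
#' Full quantification pass over a chromatogram table: per peptide (and
#' condition/replicate, if present) the heavy internal-standard channel
#' fixes the peak boundaries, both channels are integrated on them, the
#' light apex is located independently for the co-elution check, rdotp is
#' computed on matched transition areas, and the acceptance rule of
#' [assess_signal()] is applied. When a `condition` column is present, a
#' second pass re-labels rejected no-signal peptides as `on_off` wherever
#' the same peptide was accepted in another condition, substituting the
#' noise area as readout.
#'
#' The noise floor is estimated as the median summed intensity outside the
#' peak boundaries (within the search window) times the peak width.
#'
#' @param chrom Chromatogram tibble (see [read_chromatograms()]).
#' @param expected_rt Optional tibble `peptide`, `expected_rt` (minutes)
#'   restricting the apex search to `expected_rt +/- window/2`.
#' @param window Search-window width in minutes (default 2).
#' @param rdotp_min,rt_tolerance Acceptance thresholds (see
#'   [assess_signal()]).
#' @return Tibble with one row per peptide x condition/replicate:
#'   apex RTs, `rt_delta`, `rdotp`, `light_area`, `heavy_area`,
#'   `noise_area`, `status`, `ratio`, `censored`.
#' @export
quantify_peptides <- function(chrom, expected_rt = NULL, window = 2,
                              rdotp_min = 0.9, rt_tolerance = 0.2) {
  extra <- intersect(c("condition", "replicate"), names(chrom))
  keys <- c("peptide", extra)
  nested <- chrom %>%
    group_by(across(all_of(keys))) %>%
    tidyr::nest() %>%
    ungroup()

  res <- purrr::pmap(
    list(nested$peptide, nested$data),
    function(pep, data) {
      win <- NULL
      if (!is.null(expected_rt)) {
        rt0 <- expected_rt$expected_rt[match(pep, expected_rt$peptide)]
        if (!is.na(rt0)) win <- c(rt0 - window / 2, rt0 + window / 2)
      }
      quantify_one(data, win, rdotp_min, rt_tolerance)
    }
  ) %>% bind_rows()
  out <- bind_cols(nested[keys], res)

  if ("condition" %in% names(out)) {
    out <- out %>%
      group_by(.data$peptide) %>%
      mutate(
        accepted_elsewhere = purrr::map_lgl(
          row_number(),
          function(i) any(.data$status[-i] == "accepted")
        ),
        status = ifelse(
          .data$status == "rejected" & .data$no_signal &
            .data$accepted_elsewhere,
          "on_off", .data$status
        )
      ) %>%
      ungroup() %>%
      select(-"accepted_elsewhere")
    redo <- out$status == "on_off"
    if (any(redo)) {
      requant <- purrr::pmap(
        list(out$light_area[redo], out$heavy_area[redo],
             out$status[redo], out$noise_area[redo]),
        quantify_ratio
      ) %>% bind_rows()
      out$ratio[redo] <- requant$ratio
      out$censored[redo] <- requant$censored
    }
  }
  select(out, -"no_signal")
}

quantify_one <- function(data, win, rdotp_min, rt_tolerance) {
  heavy_tr <- filter(data, .data$channel == "heavy") %>%
    select("ion", "time", "intensity")
  light_tr <- filter(data, .data$channel == "light") %>%
    select("ion", "time", "intensity")
  if (nrow(heavy_tr) == 0) abort("Heavy channel missing for a peptide.")

  heavy <- integrate_peak(heavy_tr, win)
  bounds <- c(heavy$left, heavy$right)
  # integrate light on the standard's boundaries (shared peak model)
  light <- integrate_peak(light_tr, bounds = bounds)
  # independent light apex within the search window for the co-elution check
  light_apex <- integrate_peak(light_tr, win)$apex_rt

  r <- tryCatch(
    rdotp(light$areas, heavy$areas),
    error = function(e) NA_real_
  )
  noise <- noise_area_estimate(light_tr, win, bounds)
  light$apex_rt <- light_apex
  status <- assess_signal(
    light, heavy, r, noise, rdotp_min, rt_tolerance,
    accepted_elsewhere = FALSE
  )
  rq <- quantify_ratio(light$summed_area, heavy$summed_area, status, noise)
  tibble(
    apex_rt_light = light_apex, apex_rt_heavy = heavy$apex_rt,
    rt_delta = light_apex - heavy$apex_rt,
    rdotp = r,
    light_area = light$summed_area, heavy_area = heavy$summed_area,
    noise_area = noise,
    status = status,
    ratio = rq$ratio, censored = rq$censored,
    # "absent" for the on/off pass: nothing above the local noise level
    no_signal = light$no_signal || light$summed_area <= noise
  )
}

# Median summed intensity outside the peak boundaries, scaled by the peak
# width in seconds: an area-equivalent noise readout.
noise_area_estimate <- function(traces, win, bounds) {
  summed <- traces %>%
    group_by(.data$time) %>%
    summarise(intensity = sum(.data$intensity), .groups = "drop")
  if (!is.null(win)) {
    summed <- filter(summed, .data$time >= win[1], .data$time <= win[2])
  }
  outside <- filter(summed, .data$time < bounds[1] | .data$time > bounds[2])
  if (nrow(outside) == 0) return(0)
  median(abs(outside$intensity)) * (bounds[2] - bounds[1]) * 60
}

#' Plot light/heavy SRM traces for one peptide
#'
#' @param chrom Chromatogram tibble filtered to one peptide (and one
#'   condition).
#' @param title Optional plot title.
#' @return A ggplot object, heavy channel on top.
#' @export
plot_chromatogram <- function(chrom, title = NULL) {
  ggplot2::ggplot(
    chrom,
    ggplot2::aes(x = .data$time, y = .data$intensity, colour = .data$ion)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(
      ggplot2::vars(.data$channel), ncol = 1, scales = "free_y"
    ) +
    ggplot2::labs(
      x = "Retention time (min)", y = "Intensity (counts)",
      colour = "Transition", title = title
    )
}
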