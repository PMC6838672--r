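#' Normalize ratios to a reference condition
#'
#' Divides each peptide's analyte/standard ratios by that peptide's mean
#' ratio in the reference (control) condition, so the reference mean
#' becomes 1. Peptides with no non-missing reference ratio are flagged and
#' left unnormalized. The operation is idempotent.
#'
#' @param ratios Tidy tibble with columns `peptide`, `condition`, `ratio`
#'   (plus any replicate columns, carried through).
#' @param reference Name of the reference condition.
#' @return Input tibble with `ratio` rescaled and a logical `normalized`
#'   column.
#' @export
normalize_to_reference <- function(ratios, reference) {
  if (!reference %in% ratios$condition) {
    abort(paste0("Reference condition '", reference, "' not present."))
  }
  ref_means <- ratios %>%
    filter(.data$condition == reference) %>%
    group_by(.data$peptide) %>%
    summarise(ref_mean = mean(.data$ratio, na.rm = TRUE), .groups = "drop")
  out <- ratios %>%
    left_join(ref_means, by = "peptide") %>%
    mutate(
      normalized = !is.na(.data$ref_mean) & .data$ref_mean > 0,
      ratio = ifelse(.data$normalized, .data$ratio / .data$ref_mean,
                     .data$ratio)
    ) %>%
    select(-"ref_mean")
  flagged <- unique(out$peptide[!out$normalized])
  if (length(flagged) > 0) {
    warn(paste0(
      "No usable reference ratio for: ", paste(flagged, collapse = ", "),
      " (left unnormalized)."
    ))
  }
  out
}

#' Test kinase-activation differences between conditions
#'
#' Log2-transforms analyte/standard ratios, averages technical replicates
#' within each biological replicate, and fits, per peptide, a fixed-effect
#' condition model on the biological-replicate means — for two conditions
#' this is the pooled-variance two-sample t-test. Each non-reference
#' condition is contrasted against the reference; the log2 fold change is
#' the difference of condition means. With fewer than two biological
#' replicates in a condition the fold change is still reported but the
#' p-value is missing (with a warning).
#'
#' @param ratios Tidy tibble with columns `peptide`, `condition`,
#'   `bio_rep`, `ratio`, and optionally `tech_rep`.
#' @param reference Reference condition; defaults to the first condition in
#'   sort order.
#' @param alpha Significance cutoff on the (unadjusted) p-value, default
#'   0.05.
#' @param adjust Apply Benjamini-Hochberg adjustment across peptides within
#'   each contrast (default `FALSE`; significance is then called on the
#'   adjusted value).
#' @return Tibble of class `differential_results`: `peptide`, `condition`,
#'   `reference`, `log2fc`, `p`, `p_adj` (if `adjust`), `significant`.
#' @export
differential_test <- function(ratios, reference = NULL, alpha = 0.05,
                              adjust = FALSE) {
  need <- c("peptide", "condition", "bio_rep", "ratio")
  if (!all(need %in% names(ratios))) {
    abort("`ratios` needs columns peptide, condition, bio_rep, ratio.")
  }
  conditions <- sort(unique(ratios$condition))
  if (length(conditions) < 2L) abort("At least 2 conditions are required.")
  reference <- reference %||% conditions[1]
  if (!reference %in% conditions) {
    abort(paste0("Reference condition '", reference, "' not present."))
  }

  means <- ratios %>%
    filter(!is.na(.data$ratio), .data$ratio > 0) %>%
    mutate(log2_ratio = log2(.data$ratio)) %>%
    group_by(.data$peptide, .data$condition, .data$bio_rep) %>%
    summarise(log2_ratio = mean(.data$log2_ratio), .groups = "drop")

  out <- means %>%
    group_by(.data$peptide) %>%
    tidyr::nest() %>%
    ungroup() %>%
    mutate(res = purrr::map(.data$data, contrast_conditions,
                            reference = reference)) %>%
    select("peptide", "res") %>%
    tidyr::unnest("res")

  if (any(is.na(out$p))) {
    warn("p-values missing where a condition has < 2 biological replicates.")
  }
  if (adjust) {
    out <- out %>%
      group_by(.data$condition) %>%
      mutate(p_adj = p.adjust(.data$p, method = "BH")) %>%
      ungroup() %>%
      mutate(significant = !is.na(.data$p_adj) & .data$p_adj <= alpha)
  } else {
    out <- mutate(out,
                  significant = !is.na(.data$p) & .data$p <= alpha)
  }
  class(out) <- c("differential_results", class(out))
  attr(out, "alpha") <- alpha
  out
}

# Fixed-effect one-way model on biological-replicate means; contrasts of
# every condition against the reference share the pooled residual variance.
contrast_conditions <- function(data, reference) {
  data$condition <- factor(
    data$condition,
    levels = c(reference, setdiff(sort(unique(data$condition)), reference))
  )
  others <- setdiff(levels(data$condition), reference)
  n_per <- table(data$condition)
  ref_mean <- mean(data$log2_ratio[data$condition == reference])

  estimable <- length(others) > 0 && reference %in% data$condition
  fit <- NULL
  if (estimable && sum(n_per >= 2) >= 2 &&
        nrow(data) > length(unique(data$condition))) {
    fit <- lm(log2_ratio ~ condition, data = data)
    coefs <- suppressWarnings(summary(fit))$coefficients
  }
  purrr::map(others, function(cond) {
    sub <- data$condition == cond
    if (!any(sub)) return(NULL)
    log2fc <- mean(data$log2_ratio[sub]) - ref_mean
    p <- NA_real_
    if (!is.null(fit) && n_per[[cond]] >= 2 && n_per[[reference]] >= 2) {
      term <- paste0("condition", cond)
      if (term %in% rownames(coefs)) p <- coefs[term, "Pr(>|t|)"]
    }
    tibble(condition = cond, reference = reference, log2fc = log2fc, p = p)
  }) %>% bind_rows()
}

#' Volcano plot of differential kinase activation
#'
#' @param object A `differential_results` tibble.
#' @param label_top Number of most significant peptides to label.
#' @param ... Unused.
#' @return A ggplot object, one facet per contrast.
#' @export
autoplot.differential_results <- function(object, label_top = 5, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  dat <- filter(object, !is.na(.data$p))
  lab <- dat %>%
    arrange(.data$p) %>%
    head(label_top)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                 colour = .data$significant)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      yintercept = -log10(alpha), linetype = "dashed"
    ) +
    ggplot2::geom_text(
      data = lab, ggplot2::aes(label = .data$peptide),
      vjust = -0.6, size = 3, show.legend = FALSE
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick")
    ) +
    ggplot2::labs(
      x = "log2 fold change (vs reference)", y = "-log10 p",
      colour = sprintf("p <= %.2g", alpha)
    )
}
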