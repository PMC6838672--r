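#' Invert a target list into a peptide-to-kinase map
#'
#' Builds the exact inverse index of [design_targets()] output: each
#' distinct (backbone, phosphosite set) maps to the set of kinases whose
#' digest produces it. This is the lookup used for kinase-group resolution.
#'
#' @param targets Target tibble with columns `backbone`,
#'   `phospho_positions`, `kinase_ids`, `genes`, `site_labels`
#'   (semicolon-joined sets).
#' @return Tibble keyed by `backbone` + `phospho_positions` with
#'   semicolon-joined, lexicographically sorted `kinase_ids`, `genes`,
#'   `site_labels`.
#' @export
build_peptide_kinase_map <- function(targets) {
  if (is.null(targets) || nrow(targets) == 0) {
    abort("Empty target list: nothing to map.")
  }
  join_sets <- function(x) {
    paste(sort(unique(unlist(strsplit(x, ";", fixed = TRUE)))), collapse = ";")
  }
  # same peptide + same kinase appearing with disjoint site labels would be
  # an inconsistent (conflicting) index
  per_kinase <- targets %>%
    tidyr::separate_rows("kinase_ids", sep = ";") %>%
    group_by(.data$backbone, .data$phospho_positions, .data$kinase_ids) %>%
    summarise(n_label_sets = dplyr::n_distinct(.data$site_labels),
              .groups = "drop")
  conflict <- per_kinase %>% filter(.data$n_label_sets > 1L)
  if (nrow(conflict) > 0) {
    abort(paste0(
      "Conflicting site labels for the same peptide and kinase: ",
      paste(unique(conflict$backbone), collapse = ", ")
    ))
  }
  targets %>%
    group_by(.data$backbone, .data$phospho_positions) %>%
    summarise(
      kinase_ids = join_sets(.data$kinase_ids),
      genes = join_sets(.data$genes),
      site_labels = join_sets(.data$site_labels),
      .groups = "drop"
    ) %>%
    arrange(.data$backbone, .data$phospho_positions)
}

#' Resolve detected peptides into kinase groups
#'
#' Applies the protein-grouping principle at the kinase level: a detected
#' T-loop phosphopeptide whose sequence is shared by several kinases cannot
#' distinguish them, so those kinases are reported as one "kinase group".
#' Group identity is the exact kinase set of the peptide; detections with
#' identical kinase sets merge into one group, pooling their evidence
#' peptides. Group names are the member gene symbols, sorted
#' lexicographically and hyphen-joined, so ids are deterministic.
#'
#' @param detected Tibble of detected peptides with columns `backbone` and
#'   `phospho_positions` (semicolon-joined peptide-local sites).
#' @param mapping Peptide-to-kinase map from [build_peptide_kinase_map()].
#' @return A tibble of class `kinase_groups`, sorted by `group_id`, with
#'   columns `group_id`, `kinase_ids`, `genes`, `n_kinases`,
#'   `n_evidence_peptides`, `evidence`. Summary counts are available via
#'   [glance.kinase_groups()].
#' @examples
#' targets <- tibble::tibble(
#'   backbone = c("VSEPTYAK", "VSEPTYAK", "LGQGSFGK"),
#'   phospho_positions = c("6", "6", "5"),
#'   multiplicity = 1L,
#'   kinase_ids = c("EPHA3", "EPHA4", "GSK3B"),
#'   genes = c("EPHA3", "EPHA4", "GSK3B"),
#'   site_labels = c("EPHA3_Y6", "EPHA4_Y6", "GSK3B_S5")
#' )
#' m <- build_peptide_kinase_map(targets)
#' resolve_groups(m[, c("backbone", "phospho_positions")], m)
#' @export
resolve_groups <- function(detected, mapping) {
  need <- c("backbone", "phospho_positions")
  if (!all(need %in% names(detected))) {
    abort("`detected` needs columns backbone and phospho_positions.")
  }
  detected <- detected %>%
    mutate(phospho_positions = as.character(.data$phospho_positions)) %>%
    distinct(.data$backbone, .data$phospho_positions)
  hit <- left_join(detected, mapping, by = need)
  missing <- hit %>% filter(is.na(.data$kinase_ids))
  if (nrow(missing) > 0) {
    abort(paste0(
      "Detected peptide(s) absent from the map: ",
      paste(
        paste0(missing$backbone, "[", missing$phospho_positions, "]"),
        collapse = ", "
      )
    ))
  }
  groups <- hit %>%
    mutate(
      group_id = purrr::map_chr(.data$genes, function(g) {
        paste(sort(unlist(strsplit(g, ";", fixed = TRUE))), collapse = "-")
      }),
      evidence_key = paste0(.data$backbone, "[", .data$phospho_positions, "]")
    ) %>%
    group_by(.data$group_id, .data$kinase_ids, .data$genes) %>%
    summarise(
      n_evidence_peptides = n(),
      evidence = paste(sort(.data$evidence_key), collapse = ";"),
      .groups = "drop"
    ) %>%
    mutate(n_kinases = purrr::map_int(.data$kinase_ids, function(k) {
      length(strsplit(k, ";", fixed = TRUE)[[1]])
    })) %>%
    select("group_id", "kinase_ids", "genes", "n_kinases",
           "n_evidence_peptides", "evidence") %>%
    arrange(.data$group_id)

  all_kinases <- unique(unlist(strsplit(groups$kinase_ids, ";", fixed = TRUE)))
  attr(groups, "summary") <- tibble(
    n_sites = nrow(detected),
    n_groups = nrow(groups),
    n_kinases = length(all_kinases)
  )
  class(groups) <- c("kinase_groups", class(groups))
  groups
}

#' Summarise a kinase-group resolution
#'
#' @param x A `kinase_groups` tibble from [resolve_groups()].
#' @param ... Unused.
#' @return One-row tibble with `n_sites` (distinct detected peptides),
#'   `n_groups`, and `n_kinases` (union of all group members).
#' @export
glance.kinase_groups <- function(x, ...) {
  attr(x, "summary")
}

#' @export
print.kinase_groups <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "Kinase groups: %d sites -> %d groups (%d kinases)\n",
    s$n_sites, s$n_groups, s$n_kinases
  ))
  NextMethod()
}
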