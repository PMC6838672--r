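#' Design T-loop target phosphopeptides
#'
#' The computational assay-design step: for every kinase with an activation
#' segment, digest the protein in silico, keep peptides that cover at least
#' one T-loop S/T/Y and fall within SRM-measurable length bounds
#' ("accessible"), and emit one target per distinct combination of peptide
#' backbone and phosphosite set. Identical backbones arising from different
#' kinases (conserved T-loops) are merged, pooling their kinase ids — these
#' shared peptides are what later forces kinase grouping. Doubly
#' phosphorylated forms are emitted when two sites co-occur on one backbone
#' and multiplicity 2 is allowed.
#'
#' @param kinome Kinase tibble; segments are located on the fly for rows
#'   lacking annotation (see [locate_segments()]).
#' @param max_missed Maximum missed cleavages for the digest (default 2).
#' @param length_bounds Inclusive peptide length bounds, default `c(6, 30)`.
#' @param multiplicities Allowed phosphate counts per peptide, default
#'   `c(1, 2)`.
#' @param enzymes Enzymes for [digest()], default trypsin.
#' @param ... Passed to [locate_segments()] (motifs, loop bounds).
#' @return Tibble with one row per target: `backbone`, `phospho_positions`
#'   (peptide-local 1-based, semicolon-joined), `multiplicity`,
#'   `kinase_ids`, `genes`, `site_labels` (semicolon-joined),
#'   `missed_cleavages` (minimum over source peptides), and `cterm_kr`
#'   (whether the C-terminal residue is K/R and hence heavy-labelable).
#'   Attribute `"skipped"` lists kinases without segment or accessible
#'   peptide.
#' @export
design_targets <- function(kinome, max_missed = 2L, length_bounds = c(6L, 30L),
                           multiplicities = c(1L, 2L), enzymes = "trypsin",
                           ...) {
  kinome <- locate_segments(kinome, ...)
  skipped <- attr(kinome, "skipped")
  sites <- tloop_sites(kinome)

  per_kinase <- purrr::pmap(
    list(kinome$kinase_id, kinome$gene, kinome$sequence,
         kinome$segment_start),
    function(id, gene, seq, seg_start) {
      if (is.na(seg_start)) return(NULL)
      ksites <- filter(sites, .data$kinase_id == id)
      if (nrow(ksites) == 0) return(NULL)
      peps <- digest(seq, enzymes = enzymes, max_missed = max_missed) %>%
        filter(
          nchar(.data$peptide) >= length_bounds[1],
          nchar(.data$peptide) <= length_bounds[2]
        )
      if (nrow(peps) == 0) return(NULL)
      purrr::pmap(
        list(peps$peptide, peps$start, peps$missed_cleavages),
        function(pep, start, mc) {
          inside <- ksites$position >= start &
            ksites$position <= start + nchar(pep) - 1L
          if (!any(inside)) return(NULL)
          hit <- ksites[inside, ]
          local <- hit$position - start + 1L
          combos <- site_combinations(local, hit$site_label, multiplicities)
          if (is.null(combos)) return(NULL)
          combos %>% mutate(
            kinase_id = id, gene = gene, backbone = pep,
            missed_cleavages = mc
          )
        }
      ) %>% bind_rows()
    }
  ) %>% bind_rows()

  if (nrow(per_kinase) == 0) {
    targets <- tibble(
      backbone = character(), phospho_positions = character(),
      multiplicity = integer(), kinase_ids = character(),
      genes = character(), site_labels = character(),
      missed_cleavages = integer(), cterm_kr = logical()
    )
    no_access <- setdiff(
      kinome$kinase_id[!is.na(kinome$segment_start)], character()
    )
  } else {
    targets <- per_kinase %>%
      group_by(.data$backbone, .data$phospho_positions) %>%
      summarise(
        multiplicity = .data$multiplicity[1],
        kinase_ids = paste(sort(unique(.data$kinase_id)), collapse = ";"),
        genes = paste(sort(unique(.data$gene)), collapse = ";"),
        site_labels = paste(sort(unique(unlist(
          strsplit(.data$site_labels, ";", fixed = TRUE)
        ))), collapse = ";"),
        missed_cleavages = min(.data$missed_cleavages),
        .groups = "drop"
      ) %>%
      mutate(
        cterm_kr = stringr::str_detect(.data$backbone, "[KR]$")
      ) %>%
      arrange(.data$backbone, .data$phospho_positions)
    covered <- unique(unlist(strsplit(targets$kinase_ids, ";", fixed = TRUE)))
    no_access <- setdiff(
      kinome$kinase_id[!is.na(kinome$segment_start)], covered
    )
  }
  if (length(no_access) > 0) {
    skipped <- bind_rows(skipped, tibble(
      kinase_id = no_access,
      gene = kinome$gene[match(no_access, kinome$kinase_id)],
      reason = "no accessible T-loop peptide"
    ))
  }
  attr(targets, "skipped") <- skipped
  targets
}

site_combinations <- function(local_positions, site_labels, multiplicities) {
  out <- list()
  if (1L %in% multiplicities) {
    out <- c(out, purrr::map(seq_along(local_positions), function(i) {
      tibble(
        phospho_positions = as.character(local_positions[i]),
        multiplicity = 1L, site_labels = site_labels[i]
      )
    }))
  }
  if (2L %in% multiplicities && length(local_positions) >= 2L) {
    idx <- utils::combn(seq_along(local_positions), 2L, simplify = FALSE)
    out <- c(out, purrr::map(idx, function(ij) {
      ord <- order(local_positions[ij])
      ij <- ij[ord]
      tibble(
        phospho_positions = paste(local_positions[ij], collapse = ";"),
        multiplicity = 2L,
        site_labels = paste(site_labels[ij], collapse = ";")
      )
    }))
  }
  if (length(out) == 0) return(NULL)
  bind_rows(out)
}

#' Write / read a target-peptide table
#'
#' Comma-separated round-trip of the [design_targets()] output.
#'
#' @param targets Target tibble.
#' @param path File path.
#' @return `path` invisibly; `read_targets()` returns the tibble.
#' @export
write_targets <- function(targets, path) {
  readr::write_csv(targets, path)
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, col_types = readr::cols(
    backbone = "c", phospho_positions = "c", kinase_ids = "c",
    genes = "c", site_labels = "c"
  ))
}
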