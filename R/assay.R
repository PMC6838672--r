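#' Site-determining fragment ions
#'
#' For a peptide with several candidate phosphosites, a fragment ion
#' localizes the phosphate only if its residue span contains some but not
#' all of the candidates: its mass then differs between positional isomers.
#' Returns every such y/b ion; with a single candidate no ion discriminates
#' and the result is empty.
#'
#' @param backbone Peptide sequence.
#' @param candidate_positions 1-based peptide positions of the candidate
#'   phosphosites (each must be S/T/Y).
#' @return Tibble with columns `ion_type`, `ion_index`.
#' @examples
#' site_determining_ions("GHLSEGLVTK", c(4, 9))
#' @export
site_determining_ions <- function(backbone, candidate_positions) {
  res <- .check_backbone(backbone)
  candidate_positions <- .check_phospho(res, candidate_positions)
  n <- length(res)
  k <- length(candidate_positions)
  if (k < 1L) abort("At least one candidate position is required.")
  out <- purrr::map(c("y", "b"), function(type) {
    idx <- purrr::keep(seq_len(n - 1L), function(i) {
      span <- if (type == "y") (n - i + 1L):n else 1:i
      m <- sum(candidate_positions %in% span)
      m > 0L && m < k
    })
    if (length(idx) == 0) return(NULL)
    tibble(ion_type = type, ion_index = as.integer(idx))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    tibble(ion_type = character(), ion_index = integer())
  } else {
    out
  }
}

default_assay_params <- function() {
  list(
    min_ion_index = 2L,
    product_charge2_min_length = 6L,
    charge3_length = 14L,
    n_survey = 3L,
    n_quant = 7L,
    ce_offset = 0
  )
}

precursor_charges <- function(backbone, params) {
  charges <- 2L
  internal <- substr(backbone, 1, nchar(backbone) - 1L)
  if (nchar(backbone) > params$charge3_length ||
        stringr::str_detect(internal, "[HKR]")) {
    charges <- c(charges, 3L)
  }
  charges
}

# All theoretical y/b candidates (plus neutral-loss variants on
# phospho-containing ions) for one backbone + phosphosite set, light channel
# m/z; ranked by library intensity when given, else y-over-b then longer
# ions first, neutral-loss variants after their regular counterparts.
candidate_ions <- function(backbone, phospho, library_ranks = NULL,
                           params = default_assay_params()) {
  n <- nchar(backbone)
  idx <- if (n - 1L >= params$min_ion_index) {
    params$min_ion_index:(n - 1L)
  } else {
    integer()
  }
  base <- tidyr::expand_grid(
    ion_type = c("y", "b"),
    ion_index = idx
  ) %>%
    mutate(product_charge = 1L)
  two <- base %>%
    filter(.data$ion_index >= params$product_charge2_min_length) %>%
    mutate(product_charge = 2L)
  cand <- bind_rows(base, two) %>%
    mutate(n_phos = purrr::map2_int(
      .data$ion_type, .data$ion_index,
      function(type, i) {
        span <- if (type == "y") (n - i + 1L):n else 1:i
        sum(phospho %in% span)
      }
    ))
  nl <- cand %>% filter(.data$n_phos > 0L) %>% mutate(neutral_loss = TRUE)
  cand <- bind_rows(mutate(cand, neutral_loss = FALSE), nl) %>%
    mutate(annotation = paste0(
      .data$ion_type, .data$ion_index,
      ifelse(.data$neutral_loss, "-98", ""),
      ifelse(.data$product_charge > 1L,
             paste0("^", .data$product_charge), "")
    ))
  sdi <- site_determining_ions(
    backbone, all_sty_positions(backbone)
  )
  cand <- cand %>%
    left_join(mutate(sdi, site_determining = TRUE),
              by = c("ion_type", "ion_index")) %>%
    mutate(site_determining = !is.na(.data$site_determining))

  if (!is.null(library_ranks)) {
    cand <- cand %>%
      left_join(library_ranks, by = "annotation") %>%
      arrange(desc(!is.na(.data$intensity)), desc(.data$intensity),
              .data$neutral_loss, .data$ion_type != "y",
              desc(.data$ion_index), .data$product_charge) %>%
      select(-"intensity")
  } else {
    cand <- cand %>%
      arrange(.data$neutral_loss, .data$ion_type != "y",
              desc(.data$ion_index), .data$product_charge)
  }
  cand %>% mutate(rank = row_number())
}

all_sty_positions <- function(backbone) {
  which(strsplit(backbone, "")[[1]] %in% c("S", "T", "Y"))
}

#' Build an SRM assay for one target peptide
#'
#' Generates the light + heavy transition set for a target phosphopeptide.
#' Candidate ions are all theoretical y/b ions (index >= 2) plus
#' neutral-loss (-H3PO4) variants of phospho-containing ions, ranked by
#' spectral-library intensity when one is supplied and otherwise by the
#' default priority (y over b, longer fragments first). Survey mode keeps
#' the top 3 ions per precursor; quantification mode keeps up to 7 with
#' site-determining ions force-included (best-ranked first). Light and
#' heavy channels carry identical ion annotations; collision energy follows
#' [collision_energy()].
#'
#' @param backbone Peptide sequence (C-terminal K/R required for the heavy
#'   channel).
#' @param phospho_positions Integer vector (or semicolon-joined string) of
#'   peptide-local phosphosites.
#' @param mode `"survey"` or `"quantification"`.
#' @param library_ranks Optional tibble (`annotation`, `intensity`) of
#'   relative library intensities, e.g. `"y7"`, `"y7-98"`, `"b4"`.
#' @param kinase_ids,genes Optional identifiers carried through to the
#'   output.
#' @param params Assay parameters from `default_assay_params()`.
#' @return Tibble of transitions: one row per (precursor charge, channel,
#'   ion) with columns `backbone`, `phospho_positions`, `kinase_ids`,
#'   `genes`, `mode`, `label`, `precursor_charge`, `precursor_mz`,
#'   `ion_type`, `ion_index`, `product_charge`, `neutral_loss`,
#'   `annotation`, `product_mz`, `ce`, `rank`, `site_determining`.
#' @export
build_assay <- function(backbone, phospho_positions,
                        mode = c("survey", "quantification"),
                        library_ranks = NULL, kinase_ids = NA_character_,
                        genes = NA_character_,
                        params = default_assay_params()) {
  mode <- arg_match(mode)
  phospho <- parse_positions(phospho_positions)
  res <- .check_backbone(backbone)
  .check_phospho(res, phospho)
  if (!res[length(res)] %in% c("K", "R")) {
    abort("Heavy labeling requires a C-terminal K or R.")
  }
  cand <- candidate_ions(backbone, phospho, library_ranks, params)
  n_keep <- if (mode == "survey") params$n_survey else params$n_quant
  if (nrow(cand) < params$n_survey) {
    warn(paste0(
      "Only ", nrow(cand), " candidate ions for '", backbone,
      "'; emitting all."
    ))
  }
  if (mode == "quantification") {
    sel <- bind_rows(
      cand %>% filter(.data$site_determining, !.data$neutral_loss),
      cand %>% filter(!.data$site_determining | .data$neutral_loss)
    ) %>% head(n_keep) %>% arrange(.data$rank)
  } else {
    sel <- head(arrange(cand, .data$rank), n_keep)
  }

  pkey <- paste(phospho, collapse = ";")
  bb <- backbone
  out <- tidyr::expand_grid(
    precursor_charge = precursor_charges(backbone, params),
    label = c("light", "heavy"),
    sel
  ) %>%
    mutate(
      backbone = bb,
      phospho_positions = pkey,
      kinase_ids = .env$kinase_ids,
      genes = .env$genes,
      mode = .env$mode,
      precursor_mz = purrr::map2_dbl(
        .data$precursor_charge, .data$label,
        function(z, lab) precursor_mz(bb, phospho, z, lab)
      ),
      product_mz = purrr::pmap_dbl(
        list(.data$ion_type, .data$ion_index, .data$product_charge,
             .data$neutral_loss, .data$label),
        function(type, i, z, nl, lab) {
          fragment_mz(bb, phospho, type, i, z, nl, lab)
        }
      ),
      ce = collision_energy(.data$precursor_mz, .data$precursor_charge,
                            params$ce_offset)
    ) %>%
    select(
      "backbone", "phospho_positions", "kinase_ids", "genes", "mode",
      "label", "precursor_charge", "precursor_mz", "ion_type", "ion_index",
      "product_charge", "neutral_loss", "annotation", "product_mz", "ce",
      "rank", "site_determining"
    )
  out
}

parse_positions <- function(x) {
  if (is.character(x)) {
    x <- unlist(strsplit(x, ";", fixed = TRUE))
  }
  sort(as.integer(x))
}

#' Build assays for a whole target table
#'
#' Vectorised [build_assay()] over the rows of a [design_targets()] table.
#' Targets without a C-terminal K/R (protein C-terminus) cannot receive the
#' heavy label and are skipped with a message.
#'
#' @param targets Target tibble.
#' @inheritParams build_assay
#' @return Transition tibble (rows from all targets combined), with a
#'   `"skipped"` attribute naming unlabelable backbones.
#' @export
build_assays <- function(targets, mode = c("survey", "quantification"),
                         library_ranks = NULL,
                         params = default_assay_params()) {
  mode <- arg_match(mode)
  ok <- stringr::str_detect(targets$backbone, "[KR]$")
  if (any(!ok)) {
    inform(paste0(
      sum(!ok), " target(s) without C-terminal K/R skipped (no heavy label)."
    ))
  }
  kept <- targets[ok, ]
  out <- purrr::pmap(
    list(kept$backbone, kept$phospho_positions, kept$kinase_ids, kept$genes),
    function(bb, pp, kid, g) {
      build_assay(bb, pp, mode, library_ranks, kid, g, params)
    }
  ) %>% bind_rows()
  attr(out, "skipped") <- unique(targets$backbone[!ok])
  out
}

#' Export a transition list
#'
#' Writes transitions as a comma-separated list importable by vendor or
#' scheduling software. The modified sequence encodes phosphosites as
#' `[+80]` after the residue and the heavy label as `[+8]`/`[+10]` after
#' the C-terminal K/R.
#'
#' @param transitions Transition tibble from [build_assays()], optionally
#'   with `expected_rt`/`window` columns (minutes) added by scheduling.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_transition_list <- function(transitions, path) {
  out <- transitions %>%
    mutate(
      modified_sequence = purrr::pmap_chr(
        list(.data$backbone, .data$phospho_positions, .data$label),
        modified_sequence_string
      )
    ) %>%
    select(
      proteins = "kinase_ids", genes = "genes",
      "modified_sequence", "precursor_mz", "precursor_charge",
      "product_mz", "product_charge", ion = "annotation", "ce",
      any_of(c("expected_rt", "window"))
    )
  readr::write_csv(out, path)
  invisible(path)
}

#' @importFrom dplyr any_of
modified_sequence_string <- function(backbone, phospho_positions, label) {
  res <- strsplit(backbone, "")[[1]]
  phospho <- parse_positions(phospho_positions)
  res[phospho] <- paste0(res[phospho], "[+80]")
  if (identical(label, "heavy")) {
    n <- length(res)
    shift <- if (substr(backbone, nchar(backbone), nchar(backbone)) == "K") {
      "[+8]"
    } else {
      "[+10]"
    }
    res[n] <- paste0(res[n], shift)
  }
  paste(res, collapse = "")
}
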