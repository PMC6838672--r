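#' Read a kinome FASTA into a kinase table
#'
#' Parses a FASTA of kinase (or synthetic) protein sequences into a tibble,
#' one row per entry. The first whitespace-separated token of each header is
#' taken as `kinase_id` (the accession for `sp|ACC|NAME`-style headers); a
#' `GN=` tag, when present, supplies the gene symbol, otherwise the id is
#' reused. An optional sidecar annotation table can supply kinase-domain and
#' activation-segment coordinates.
#'
#' @param fasta_path Path to a FASTA file of amino-acid sequences.
#' @param annotation_path Optional path to a tab-separated table with columns
#'   `kinase_id`, `domain_start`, `domain_end`, `segment_start`,
#'   `segment_end` (1-based inclusive; missing values allowed).
#' @return A tibble with columns `kinase_id`, `gene`, `sequence`, `length`,
#'   `domain_start`, `domain_end`, `segment_start`, `segment_end`.
#' @export
read_kinome <- function(fasta_path, annotation_path = NULL) {
  if (!file.exists(fasta_path)) {
    abort(paste0("FASTA file not found: ", fasta_path))
  }
  seqs <- tryCatch(
    Biostrings::readAAStringSet(fasta_path),
    error = function(e) {
      abort(paste0("Malformed FASTA '", fasta_path, "': ", conditionMessage(e)))
    }
  )
  if (length(seqs) == 0) {
    warn(paste0("FASTA '", fasta_path, "' contains no sequences."))
    kin <- tibble(
      kinase_id = character(), gene = character(), sequence = character(),
      length = integer()
    )
  } else {
    headers <- names(seqs)
    ids <- stringr::str_split_i(headers, "\\s+", 1)
    ids <- ifelse(
      stringr::str_detect(ids, "^\\w+\\|[^|]+\\|"),
      stringr::str_split_i(ids, "\\|", 2), ids
    )
    gene <- stringr::str_match(headers, "GN=([^\\s]+)")[, 2]
    kin <- tibble(
      kinase_id = ids,
      gene = dplyr::coalesce(gene, ids),
      sequence = unname(toupper(as.character(seqs))),
      length = nchar(.data$sequence)
    )
    # Biostrings silently drops invalid letters, so validate the raw
    # record text to report offending entries by name
    raw <- readLines(fasta_path)
    rec <- cumsum(stringr::str_detect(raw, "^>"))
    seq_raw <- vapply(
      split(raw[!stringr::str_detect(raw, "^>")],
            rec[!stringr::str_detect(raw, "^>")]),
      paste, character(1), collapse = ""
    )
    ok <- stringr::str_detect(
      toupper(seq_raw), "^[ACDEFGHIKLMNPQRSTVWY]*$"
    )
    if (any(!ok)) {
      abort(paste0(
        "Non-amino-acid characters in sequence(s): ",
        paste(kin$kinase_id[!ok], collapse = ", ")
      ))
    }
  }

  ann <- NULL
  if (!is.null(annotation_path)) {
    ann <- readr::read_tsv(annotation_path, show_col_types = FALSE)
    if (!"kinase_id" %in% names(ann)) {
      abort("Annotation table must have a `kinase_id` column.")
    }
  }
  for (col in c("domain_start", "domain_end", "segment_start", "segment_end")) {
    if (is.null(ann) || !col %in% names(ann)) {
      kin[[col]] <- NA_integer_
    }
  }
  if (!is.null(ann)) {
    keep <- intersect(
      c("kinase_id", "domain_start", "domain_end",
        "segment_start", "segment_end"),
      names(ann)
    )
    kin <- left_join(kin, ann[keep], by = "kinase_id")
  }
  validate_spans(kin)
  kin
}

validate_spans <- function(kin) {
  chk <- function(s, e, what) {
    ok <- is.na(s) | is.na(e) | (s >= 1L & s <= e & e <= kin$length)
    if (!all(ok)) {
      abort(paste0(
        "Invalid ", what, " span for: ",
        paste(kin$kinase_id[!ok], collapse = ", ")
      ))
    }
  }
  chk(kin$domain_start, kin$domain_end, "domain")
  chk(kin$segment_start, kin$segment_end, "segment")
  invisible(kin)
}

#' Write a kinase table to FASTA
#'
#' @param kinome Kinase tibble as from [read_kinome()] or
#'   [generate_kinome()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_kinome_fasta <- function(kinome, path) {
  seqs <- Biostrings::AAStringSet(setNames(kinome$sequence, paste0(
    kinome$kinase_id, " GN=", kinome$gene
  )))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Locate the kinase activation segment (DFG..APE)
#'
#' Finds the activation segment of a kinase sequence as the interval from
#' the first residue of the DFG motif to the last residue of the APE motif,
#' requiring the intervening stretch to fall within length bounds. Motifs
#' are regular expressions; if no exact DFG/APE pair satisfies the bounds,
#' the relaxed fallback patterns are tried. Scanning is left-to-right: the
#' first DFG occurrence with a downstream APE within bounds wins, and for
#' that DFG the nearest such APE is used.
#'
#' @param sequence Amino-acid string.
#' @param motif_dfg,motif_ape Primary motif regular expressions.
#' @param fallback_dfg,fallback_ape Relaxed motifs tried when the primary
#'   pair yields no hit.
#' @param min_loop,max_loop Bounds (inclusive) on the number of residues
#'   strictly between the two motifs. Default 15-40.
#' @return Integer vector `c(start, end)` (1-based inclusive) or `NULL`
#'   when no motif pair satisfies the bounds.
#' @examples
#' locate_activation_segment("AAADFGLARTSAPEAAA", min_loop = 0)
#' @export
locate_activation_segment <- function(sequence,
                                      motif_dfg = "DFG", motif_ape = "APE",
                                      fallback_dfg = "D[FWL]G",
                                      fallback_ape = "AP[ED]",
                                      min_loop = 15L, max_loop = 40L) {
  sequence <- toupper(sequence)
  hit <- segment_scan(sequence, motif_dfg, motif_ape, min_loop, max_loop)
  if (is.null(hit)) {
    hit <- segment_scan(sequence, fallback_dfg, fallback_ape,
                        min_loop, max_loop)
  }
  hit
}

segment_scan <- function(sequence, pat_dfg, pat_ape, min_loop, max_loop) {
  dfg <- stringr::str_locate_all(sequence, pat_dfg)[[1]]
  ape <- stringr::str_locate_all(sequence, pat_ape)[[1]]
  if (nrow(dfg) == 0 || nrow(ape) == 0) return(NULL)
  for (i in seq_len(nrow(dfg))) {
    gap <- ape[, "start"] - dfg[i, "end"] - 1L
    ok <- which(gap >= min_loop & gap <= max_loop)
    if (length(ok) > 0) {
      j <- ok[which.min(gap[ok])]
      return(c(start = unname(dfg[i, "start"]), end = unname(ape[j, "end"])))
    }
  }
  NULL
}

#' Annotate activation segments across a kinase table
#'
#' Applies [locate_activation_segment()] to every kinase lacking an external
#' segment annotation; externally supplied spans are kept unchanged. Kinases
#' in which no segment is found are retained with `NA` spans and listed in
#' the `"skipped"` attribute of the result.
#'
#' @param kinome Kinase tibble (see [read_kinome()]).
#' @inheritParams locate_activation_segment
#' @return The input tibble with `segment_start`/`segment_end` filled in;
#'   attribute `"skipped"` holds a tibble of kinases without a segment.
#' @export
locate_segments <- function(kinome, motif_dfg = "DFG", motif_ape = "APE",
                            fallback_dfg = "D[FWL]G", fallback_ape = "AP[ED]",
                            min_loop = 15L, max_loop = 40L) {
  spans <- purrr::pmap(
    list(kinome$sequence, kinome$segment_start, kinome$segment_end),
    function(seq, s, e) {
      if (!is.na(s) && !is.na(e)) return(c(s, e))
      hit <- locate_activation_segment(
        seq, motif_dfg, motif_ape, fallback_dfg, fallback_ape,
        min_loop, max_loop
      )
      if (is.null(hit)) c(NA_integer_, NA_integer_) else hit
    }
  )
  kinome$segment_start <- purrr::map_int(spans, function(x) as.integer(x[1]))
  kinome$segment_end <- purrr::map_int(spans, function(x) as.integer(x[2]))
  skipped <- kinome %>%
    filter(is.na(.data$segment_start)) %>%
    select("kinase_id", "gene") %>%
    mutate(reason = "segment not found")
  if (nrow(skipped) > 0) {
    inform(paste0(
      "No activation segment found for ", nrow(skipped), " kinase(s): ",
      paste(skipped$kinase_id, collapse = ", ")
    ))
  }
  attr(kinome, "skipped") <- skipped
  kinome
}

#' Enumerate phosphorylatable T-loop residues
#'
#' Lists every S/T/Y inside the annotated activation segment of each kinase.
#'
#' @param kinome Kinase tibble with `segment_start`/`segment_end` filled
#'   (see [locate_segments()]).
#' @return Tibble with columns `kinase_id`, `gene`, `position` (1-based in
#'   the protein), `residue`, and `site_label` (e.g. `"RIPK1_S161"`).
#' @export
tloop_sites <- function(kinome) {
  with_seg <- filter(kinome, !is.na(.data$segment_start))
  purrr::pmap(
    list(with_seg$kinase_id, with_seg$gene, with_seg$sequence,
         with_seg$segment_start, with_seg$segment_end),
    function(id, gene, seq, s, e) {
      res <- strsplit(seq, "")[[1]][s:e]
      pos <- s:e
      sty <- res %in% c("S", "T", "Y")
      if (!any(sty)) return(NULL)
      tibble(
        kinase_id = id, gene = gene, position = pos[sty],
        residue = res[sty],
        site_label = paste0(gene, "_", res[sty], pos[sty])
      )
    }
  ) %>% bind_rows()
}
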