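#' In-silico proteolytic digestion
#'
#' Cleaves a protein sequence with trypsin (after K/R, suppressed before
#' proline) and/or Lys-C (after K regardless of the next residue). When both
#' enzymes are given, the union of their cleavage points is used. All
#' peptides with up to `max_missed` internal (missed) cleavage sites are
#' returned.
#'
#' @param sequence Protein sequence (uppercase amino-acid string).
#' @param enzymes Character subset of `c("trypsin", "lysC")`.
#' @param max_missed Maximum number of missed cleavages (>= 0).
#' @return A tibble with columns `peptide`, `start` (1-based position in the
#'   parent), `end`, and `missed_cleavages`, ordered by start then length.
#' @examples
#' digest("GHLSEGLVTKR")
#' digest("AKPR", enzymes = c("trypsin", "lysC"))
#' @export
digest <- function(sequence, enzymes = "trypsin", max_missed = 0L) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    abort("`sequence` must be a single non-empty string.")
  }
  unknown <- setdiff(enzymes, c("trypsin", "lysC"))
  if (length(unknown) > 0) {
    abort(paste0("Unknown enzyme(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(enzymes) == 0) abort("At least one enzyme is required.")
  max_missed <- as.integer(max_missed)
  if (max_missed < 0L) abort("`max_missed` must be >= 0.")

  res <- strsplit(toupper(sequence), "")[[1]]
  n <- length(res)
  cuts <- cleavage_sites(res, enzymes)
  bounds <- c(0L, cuts, n) # peptide k spans (bounds[k]+1) .. bounds[k+1]

  out <- purrr::map(0:max_missed, function(mc) {
    k <- seq_len(max(length(bounds) - 1L - mc, 0L))
    if (length(k) == 0) return(NULL)
    tibble(
      start = bounds[k] + 1L,
      end = bounds[k + 1L + mc],
      missed_cleavages = mc
    )
  })
  out <- bind_rows(out) %>%
    mutate(peptide = substr_vec(sequence, .data$start, .data$end)) %>%
    select("peptide", "start", "end", "missed_cleavages") %>%
    arrange(.data$start, .data$end - .data$start)
  out
}

# Positions i such that cleavage occurs between residue i and i+1.
cleavage_sites <- function(res, enzymes) {
  n <- length(res)
  if (n < 2L) return(integer())
  i <- seq_len(n - 1L)
  cut <- rep(FALSE, n - 1L)
  if ("trypsin" %in% enzymes) {
    cut <- cut | (res[i] %in% c("K", "R") & res[i + 1L] != "P")
  }
  if ("lysC" %in% enzymes) {
    cut <- cut | (res[i] == "K")
  }
  which(cut)
}

substr_vec <- function(x, start, end) {
  purrr::map2_chr(start, end, function(s, e) substr(x, s, e))
}
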