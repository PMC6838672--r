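# Shared fixtures and independent oracles.

# Independent residue-mass table (literature monoisotopic values), kept
# separate from the package internals so mass tests have their own ground
# truth.
ORACLE_AA <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
ORACLE_PROTON <- 1.007276
ORACLE_WATER <- 18.010565
ORACLE_PHOSPHO <- 79.966331

oracle_neutral_mass <- function(backbone, n_phospho = 0) {
  res <- strsplit(backbone, "")[[1]]
  sum(ORACLE_AA[res]) + ORACLE_WATER + ORACLE_PHOSPHO * n_phospho
}

# Brute-force digestion oracle: enumerate every pair of cleavage boundaries
# with at most max_missed internal cleavage points.
oracle_digest <- function(sequence, enzymes = "trypsin", max_missed = 0L) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cut <- logical(n - 1)
  for (i in seq_len(max(n - 1, 0))) {
    if ("trypsin" %in% enzymes && res[i] %in% c("K", "R") &&
          res[i + 1] != "P") {
      cut[i] <- TRUE
    }
    if ("lysC" %in% enzymes && res[i] == "K") cut[i] <- TRUE
  }
  bounds <- c(0L, which(cut), n)
  out <- character()
  for (a in seq_along(bounds)) {
    for (b in seq_along(bounds)) {
      if (b <= a) next
      internal <- b - a - 1L
      if (internal <= max_missed) {
        out <- c(out, substr(sequence, bounds[a] + 1L, bounds[b]))
      }
    }
  }
  sort(out)
}

random_peptide <- function(n, cterm_kr = TRUE) {
  aa <- names(ORACLE_AA)
  body <- sample(aa[!aa %in% c("K", "R")], n - 1, replace = TRUE)
  tail <- if (cterm_kr) sample(c("K", "R"), 1) else sample(aa, 1)
  paste(c(body, tail), collapse = "")
}

random_sequence <- function(n) {
  paste(sample(names(ORACLE_AA), n, replace = TRUE), collapse = "")
}

# A two-kinase fixture whose activation segments are fully known. The
# designed tryptic T-loop peptide of KINA is GHLSEGLVTK (sites S4, T9
# peptide-local).
fixture_kinome <- function() {
  # segment: DFG + (AQWNC R GHLSEGLVT K MVWQH) + APE; loop length 15-40 ok
  seg <- "DFGAQWNCRGHLSEGLVTKMVWQHAPE"
  tibble::tibble(
    kinase_id = c("KINA", "KINB"),
    gene = c("KINA", "KINB"),
    sequence = c(
      paste0("MAAVNLCQW", seg, "LVNQCW"),
      paste0("MQQCVNW", seg, "AANNW")
    ),
    length = nchar(sequence),
    domain_start = NA_integer_, domain_end = NA_integer_,
    segment_start = NA_integer_, segment_end = NA_integer_
  )
}

write_fasta <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# Gaussian chromatogram for one channel: shared grid, one peak per ion.
gaussian_trace <- function(ions, amps, rt = 30, sigma_s = 5,
                           span = 0.6, step = 0.005, noise_sd = 0,
                           baseline = 0) {
  grid <- seq(rt - span, rt + span, by = step)
  sig <- sigma_s / 60
  purrr::map2(ions, amps, function(ion, a) {
    tibble::tibble(
      ion = ion, time = grid,
      intensity = pmax(
        a * exp(-(grid - rt)^2 / (2 * sig^2)) + baseline +
          stats::rnorm(length(grid), 0, noise_sd),
        0
      )
    )
  }) |> dplyr::bind_rows()
}
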