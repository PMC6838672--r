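# Seed-deterministic generators for every input the pipeline consumes:
# synthetic kinomes with known activation segments, SRM chromatograms with
# Gaussian peaks + noise, and dilution series with known slope/intercept
# structure. Each generator attaches its ground truth so downstream results
# can be checked without rerunning it.

.aa20 <- names(.aa_mono)
.aa_filler <- setdiff(.aa20, c("S", "T", "Y", "K", "R", "P", "D"))
.aa_flank <- .aa20

#' Generate a synthetic kinome with known activation segments
#'
#' Random protein sequences, each embedding one DFG..APE activation segment
#' whose loop carries a designed tryptic target peptide (C-terminal K,
#' preceded by an R cleavage point) containing 1-3 phosphorylatable S/T/Y
#' residues. Optionally, subsets of kinases share an identical segment so
#' that their target peptides are indistinguishable, creating kinase
#' groups. Loop residues outside the target core avoid S/T/Y (so the truth
#' enumerates all sites exactly), P (so tryptic cleavage is never
#' suppressed) and D (so no spurious DFG arises); any DFG occurring by
#' chance elsewhere in the protein is mutated away, making the designed
#' segment the unique match.
#'
#' @param n_kinases Number of kinases (>= 1).
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param length_range Protein length range, default `c(300, 600)`.
#' @param loop_range Bounds for residues between DFG and APE, default
#'   `c(15, 40)`.
#' @param n_sites_range Sites per target peptide, default `c(1, 3)`.
#' @param peptide_length_range Target tryptic peptide length, default
#'   `c(8, 12)`.
#' @param shared_groups Optional integer vector of group sizes; the first
#'   `sum(shared_groups)` kinases are assigned shared segments accordingly
#'   (e.g. `c(3, 2)` makes kinases 1-3 share one segment and 4-5 another).
#' @return Kinase tibble (as [read_kinome()]) with attribute `"truth"`: a
#'   tibble of `kinase_id`, `gene`, `segment_start`, `segment_end`,
#'   `sites` (protein positions, semicolon-joined), `target_peptide`,
#'   `shared_group`.
#' @export
generate_kinome <- function(n_kinases, seed, length_range = c(300L, 600L),
                            loop_range = c(15L, 40L),
                            n_sites_range = c(1L, 3L),
                            peptide_length_range = c(8L, 12L),
                            shared_groups = NULL) {
  if (n_kinases < 1L) abort("`n_kinases` must be >= 1.")
  if (loop_range[2] + 6L > length_range[1]) {
    abort("Segment longer than the shortest allowed protein.")
  }
  if (!is.null(shared_groups) && sum(shared_groups) > n_kinases) {
    abort("`shared_groups` assigns more kinases than exist.")
  }
  set.seed(seed)

  group_of <- rep(NA_integer_, n_kinases)
  if (!is.null(shared_groups)) {
    group_of[seq_len(sum(shared_groups))] <-
      rep(seq_along(shared_groups), shared_groups)
  }
  segments <- list()

  rows <- purrr::map(seq_len(n_kinases), function(i) {
    g <- group_of[i]
    if (!is.na(g) && !is.null(segments[[as.character(g)]])) {
      seg <- segments[[as.character(g)]]
    } else {
      seg <- random_segment(loop_range, n_sites_range, peptide_length_range)
      if (!is.na(g)) segments[[as.character(g)]] <<- seg
    }
    total_len <- sample(length_range[1]:length_range[2], 1L)
    seg_len <- nchar(seg$segment)
    flank_total <- total_len - seg_len
    pre_len <- sample(seq(20L, flank_total - 20L), 1L)
    pre <- paste(sample(.aa_flank, pre_len, replace = TRUE), collapse = "")
    post <- paste(
      sample(.aa_flank, flank_total - pre_len, replace = TRUE),
      collapse = ""
    )
    seq_full <- scrub_spurious_dfg(
      paste0(pre, seg$segment, post),
      keep_start = pre_len + 1L
    )
    tibble(
      kinase_id = sprintf("SYNK%03d", i),
      gene = sprintf("SYNK%d", i),
      sequence = seq_full,
      length = nchar(seq_full),
      domain_start = NA_integer_, domain_end = NA_integer_,
      segment_start = NA_integer_, segment_end = NA_integer_,
      truth_segment_start = pre_len + 1L,
      truth_segment_end = pre_len + seg_len,
      truth_sites = paste(pre_len + seg$site_offsets, collapse = ";"),
      target_peptide = seg$target_peptide,
      shared_group = g
    )
  }) %>% bind_rows()

  truth <- rows %>%
    select(
      "kinase_id", "gene",
      segment_start = "truth_segment_start",
      segment_end = "truth_segment_end",
      sites = "truth_sites", "target_peptide", "shared_group"
    )
  kinome <- rows %>%
    select("kinase_id", "gene", "sequence", "length", "domain_start",
           "domain_end", "segment_start", "segment_end")
  attr(kinome, "truth") <- truth
  kinome
}

# One DFG..APE segment: DFG | prefix R core K suffix | APE, with the target
# tryptic peptide = core + K. Site offsets are 1-based within the segment.
random_segment <- function(loop_range, n_sites_range, peptide_length_range) {
  pep_len <- sample(peptide_length_range[1]:peptide_length_range[2], 1L)
  core_len <- pep_len - 1L
  loop_min <- max(loop_range[1], core_len + 2L)
  loop_len <- sample(loop_min:loop_range[2], 1L)
  spare <- loop_len - core_len - 2L
  pre_len <- sample(0:spare, 1L)
  post_len <- spare - pre_len

  n_sites <- sample(n_sites_range[1]:n_sites_range[2], 1L)
  n_sites <- min(n_sites, core_len)
  core <- sample(.aa_filler, core_len, replace = TRUE)
  site_pos <- sort(sample(core_len, n_sites))
  core[site_pos] <- sample(c("S", "T", "Y"), n_sites, replace = TRUE)

  loop <- c(
    sample(.aa_filler, pre_len, replace = TRUE), "R", core, "K",
    sample(.aa_filler, post_len, replace = TRUE)
  )
  segment <- paste0("DFG", paste(loop, collapse = ""), "APE")
  # segment-local 1-based offsets of the sites: DFG(3) + pre + R + position
  offsets <- 3L + pre_len + 1L + site_pos
  list(
    segment = segment,
    site_offsets = offsets,
    target_peptide = paste0(paste(core, collapse = ""), "K")
  )
}

# Mutate every DFG whose start is not the designed one (F -> A).
scrub_spurious_dfg <- function(sequence, keep_start) {
  repeat {
    hits <- stringr::str_locate_all(sequence, "DFG")[[1]]
    spurious <- hits[hits[, "start"] != keep_start, , drop = FALSE]
    if (nrow(spurious) == 0) return(sequence)
    i <- spurious[1, "start"] + 1L
    substr(sequence, i, i) <- "A"
  }
}

#' Simulate SRM chromatograms for a transition set
#'
#' One Gaussian peak per transition on a shared time grid around a random
#' elution time, with per-transition amplitudes following a geometric
#' intensity pattern over transition rank, heavy channel at a fixed
#' amplitude and light = heavy x true ratio, plus additive Gaussian
#' baseline noise. A ratio of 0 encodes an off state (no light signal).
#'
#' @param transitions Transition tibble from [build_assays()]; one peptide
#'   key is `backbone[phospho_positions]`. Only the lowest precursor charge
#'   per peptide is traced.
#' @param true_ratios Tibble `peptide`, `condition`, `ratio` giving the
#'   light/heavy ratio per condition (use a single condition for plain
#'   runs).
#' @param seed Integer RNG seed.
#' @param heavy_amplitude Apex intensity of the strongest heavy transition
#'   (counts), default 1e5.
#' @param noise_sd Baseline noise SD in counts (default 50).
#' @param rt_range Elution-time range (minutes) peptides are scattered
#'   over, default `c(15, 85)`.
#' @param peak_sigma_s Range of Gaussian peak SD in seconds, default
#'   `c(3, 8)`.
#' @param time_step Grid step in minutes (default 0.005).
#' @return Chromatogram tibble (`peptide`, `condition`, `channel`, `ion`,
#'   `time`, `intensity`) with attribute `"truth"` (`peptide`, `rt`,
#'   `sigma_s`, per-condition ratios).
#' @export
simulate_chromatograms <- function(transitions, true_ratios, seed,
                                   heavy_amplitude = 1e5, noise_sd = 50,
                                   rt_range = c(15, 85),
                                   peak_sigma_s = c(3, 8),
                                   time_step = 0.005) {
  set.seed(seed)
  tr <- transitions %>%
    mutate(peptide = paste0(.data$backbone, "[", .data$phospho_positions, "]"))
  tr <- tr %>%
    group_by(.data$peptide) %>%
    filter(.data$precursor_charge == min(.data$precursor_charge)) %>%
    ungroup()
  peptides <- unique(tr$peptide)
  if (!all(true_ratios$peptide %in% peptides)) {
    abort("`true_ratios` refers to peptides absent from `transitions`.")
  }

  truth <- tibble(
    peptide = peptides,
    rt = stats::runif(length(peptides), rt_range[1], rt_range[2]),
    sigma_s = stats::runif(length(peptides), peak_sigma_s[1], peak_sigma_s[2])
  )

  out <- purrr::map(peptides, function(pep) {
    ions <- tr %>%
      filter(.data$peptide == pep, .data$label == "heavy") %>%
      distinct(.data$annotation, .data$rank)
    pat <- 0.6^(rank(ions$rank) - 1)
    rt0 <- truth$rt[truth$peptide == pep]
    sig_min <- truth$sigma_s[truth$peptide == pep] / 60
    grid <- seq(rt0 - 0.6, rt0 + 0.6, by = time_step)
    conds <- filter(true_ratios, .data$peptide == pep)
    purrr::map2(conds$condition, conds$ratio, function(cond, ratio) {
      purrr::map2(ions$annotation, pat, function(ann, w) {
        shape <- exp(-(grid - rt0)^2 / (2 * sig_min^2))
        heavy_sig <- heavy_amplitude * w * shape
        light_sig <- heavy_sig * ratio
        bind_rows(
          tibble(
            peptide = pep, condition = cond, channel = "heavy", ion = ann,
            time = grid,
            intensity = pmax(
              heavy_sig + stats::rnorm(length(grid), 0, noise_sd), 0
            )
          ),
          tibble(
            peptide = pep, condition = cond, channel = "light", ion = ann,
            time = grid,
            intensity = pmax(
              light_sig + stats::rnorm(length(grid), 0, noise_sd), 0
            )
          )
        )
      }) %>% bind_rows()
    }) %>% bind_rows()
  }) %>% bind_rows()

  attr(out, "truth") <- left_join(truth, true_ratios, by = "peptide")
  out
}

#' Simulate a dilution-series response table
#'
#' `response = b_true * amount + intercept_rep + noise`, with one
#' intercept per replicate drawn from `Normal(0, intercept_sd)` and
#' point noise from `Normal(0, noise_sd)`. When a positive noise floor is
#' given, responses falling below it are replaced by draws around the
#' floor, emulating the representative noise areas read off for sub-LOD
#' spike-ins.
#'
#' @param b_true True slope (response per fmol, > 0).
#' @param intercept_sd SD of the per-replicate intercepts.
#' @param noise_sd SD of the per-point noise.
#' @param seed Integer RNG seed.
#' @param levels Spike amounts in fmol; default the 7-level series
#'   `c(0.01, 0.1, 1, 5, 10, 50, 100)` (10 amol to 100 fmol).
#' @param n_replicates Replicates per level (default 3).
#' @param noise_floor Response floor; 0 disables substitution.
#' @return Tibble `amount_fmol`, `replicate`, `response` with attribute
#'   `"truth"` listing the generating parameters.
#' @export
simulate_dilution_series <- function(b_true, intercept_sd, noise_sd, seed,
                                     levels = c(0.01, 0.1, 1, 5, 10, 50, 100),
                                     n_replicates = 3L, noise_floor = 0) {
  if (b_true <= 0) abort("`b_true` must be > 0.")
  set.seed(seed)
  intercepts <- stats::rnorm(n_replicates, 0, intercept_sd)
  out <- tidyr::expand_grid(
    replicate = seq_len(n_replicates),
    amount_fmol = sort(levels)
  ) %>%
    mutate(
      response = b_true * .data$amount_fmol +
        intercepts[.data$replicate] +
        stats::rnorm(n(), 0, noise_sd)
    )
  if (noise_floor > 0) {
    low <- out$response < noise_floor
    out$response[low] <- abs(stats::rnorm(
      sum(low), noise_floor, 0.1 * noise_floor
    ))
  }
  attr(out, "truth") <- tibble(
    b_true = b_true, intercept_sd = intercept_sd, noise_sd = noise_sd,
    noise_floor = noise_floor, seed = seed
  )
  out
}
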