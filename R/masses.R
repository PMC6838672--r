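# Monoisotopic masses. Residue masses are the standard amino-acid residue
# (i.e., water-free) monoisotopic values; constants follow SRM convention:
# phospho +79.966331, phosphoric-acid neutral loss 97.976896, and
# SILAC-style C-terminal labels 13C6,15N2-K (+8.014199) / 13C6,15N4-R
# (+10.008269).

.aa_mono <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.mass_proton <- 1.007276
.mass_water <- 18.010565
.mass_phospho <- 79.966331
.mass_h3po4 <- 97.976896
.mass_heavy_k <- 8.014199
.mass_heavy_r <- 10.008269

.check_backbone <- function(backbone) {
  if (!is.character(backbone) || length(backbone) != 1L || !nzchar(backbone)) {
    abort("`backbone` must be a single non-empty peptide string.")
  }
  res <- strsplit(toupper(backbone), "")[[1]]
  bad <- setdiff(unique(res), names(.aa_mono))
  if (length(bad) > 0) {
    abort(paste0(
      "Non-amino-acid characters in peptide '", backbone, "': ",
      paste(bad, collapse = ", ")
    ))
  }
  res
}

.check_phospho <- function(res, phospho_positions) {
  phospho_positions <- as.integer(phospho_positions)
  if (any(phospho_positions < 1L | phospho_positions > length(res))) {
    abort("Phospho positions outside the peptide.")
  }
  not_sty <- phospho_positions[!res[phospho_positions] %in% c("S", "T", "Y")]
  if (length(not_sty) > 0) {
    abort(paste0(
      "Phospho position(s) ", paste(not_sty, collapse = ", "),
      " are not on S/T/Y."
    ))
  }
  phospho_positions
}

.label_mass <- function(res, label) {
  if (identical(label, "light")) return(0)
  cterm <- res[length(res)]
  if (cterm == "K") return(.mass_heavy_k)
  if (cterm == "R") return(.mass_heavy_r)
  abort("Heavy label requires a C-terminal K or R.")
}

#' Monoisotopic precursor m/z of a (phospho)peptide
#'
#' Computes the precursor m/z of a light or heavy-labelled peptide carrying
#' zero or more phosphate groups. Heavy labels are stable-isotope
#' substitutions of the C-terminal K (+8.014199 Da) or R (+10.008269 Da),
#' the standard chemistry for SRM internal standards.
#'
#' @param backbone Peptide sequence (uppercase single-letter amino acids).
#' @param phospho_positions Integer vector of 1-based peptide positions
#'   carrying a phosphate; each must be S, T or Y.
#' @param charge Precursor charge (>= 1).
#' @param label `"light"` or `"heavy"`; heavy requires a C-terminal K/R.
#' @return Precursor m/z in Thomson.
#' @examples
#' precursor_mz("GHLSEGLVTK", phospho_positions = 4, charge = 2)
#' @export
precursor_mz <- function(backbone, phospho_positions = integer(),
                         charge = 2L, label = c("light", "heavy")) {
  label <- arg_match(label)
  res <- .check_backbone(backbone)
  phospho_positions <- .check_phospho(res, phospho_positions)
  if (charge < 1L) abort("`charge` must be >= 1.")
  neutral <- sum(.aa_mono[res]) + .mass_water +
    .mass_phospho * length(phospho_positions) + .label_mass(res, label)
  (neutral + charge * .mass_proton) / charge
}

#' Monoisotopic fragment-ion m/z
#'
#' m/z of a y- or b-ion of a modified peptide, optionally after neutral loss
#' of phosphoric acid (-97.976896 Da), which is only defined for fragments
#' that retain at least one phosphate. The heavy label sits on the C-terminal
#' residue, so it shifts y ions only.
#'
#' @inheritParams precursor_mz
#' @param ion_type `"y"` or `"b"`.
#' @param ion_index Fragment length, `1 <= ion_index <= nchar(backbone) - 1`.
#' @param product_charge Product-ion charge (>= 1).
#' @param neutral_loss If `TRUE`, subtract one H3PO4 from the fragment.
#' @return Product m/z in Thomson.
#' @examples
#' fragment_mz("GHLSEGLVTK", 4, ion_type = "y", ion_index = 7)
#' @export
fragment_mz <- function(backbone, phospho_positions = integer(),
                        ion_type = c("y", "b"), ion_index,
                        product_charge = 1L, neutral_loss = FALSE,
                        label = c("light", "heavy")) {
  ion_type <- arg_match(ion_type)
  label <- arg_match(label)
  res <- .check_backbone(backbone)
  phospho_positions <- .check_phospho(res, phospho_positions)
  n <- length(res)
  ion_index <- as.integer(ion_index)
  if (ion_index < 1L || ion_index > n - 1L) {
    abort("`ion_index` must lie in [1, peptide length - 1].")
  }
  if (product_charge < 1L) abort("`product_charge` must be >= 1.")

  span <- if (ion_type == "y") (n - ion_index + 1L):n else 1:ion_index
  n_phos <- sum(phospho_positions %in% span)
  mass <- sum(.aa_mono[res[span]]) + .mass_phospho * n_phos
  if (ion_type == "y") {
    mass <- mass + .mass_water + .label_mass(res, label)
  }
  if (neutral_loss) {
    if (n_phos == 0L) {
      abort("Neutral loss requested on a fragment with no phosphate.")
    }
    mass <- mass - .mass_h3po4
  }
  (mass + product_charge * .mass_proton) / product_charge
}

#' Triple-quadrupole collision energy
#'
#' Charge-dependent linear collision-energy ramp:
#' `CE = 0.03 m/z + 2.905` for 2+ precursors and `CE = 0.038 m/z + 2.281`
#' for precursors of charge three and higher, plus an optional empirical
#' per-transition offset.
#'
#' @param precursor_mz Precursor m/z in Thomson (vectorised).
#' @param precursor_charge Precursor charge (>= 2, vectorised).
#' @param offset Additive CE offset in volts (default 0).
#' @return Collision energy in volts.
#' @examples
#' collision_energy(500, 2)
#' collision_energy(700, 3)
#' @export
collision_energy <- function(precursor_mz, precursor_charge, offset = 0) {
  if (any(precursor_charge < 2L)) {
    abort("Collision energy is defined for precursor charges >= 2.")
  }
  ce <- ifelse(precursor_charge == 2L,
    0.03 * precursor_mz + 2.905,
    0.038 * precursor_mz + 2.281
  )
  ce + offset
}
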