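# Independent atomic-composition oracle. Masses are rebuilt from isotope
# masses and elemental formulas, so agreement with the package's residue
# and monosaccharide tables is a genuine cross-check, not a tautology.

.atom_mono <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
                O = 15.9949146196, S = 31.97207100)

oracle_formula_mass <- function(counts) {
  sum(.atom_mono[names(counts)] * counts)
}

# residue (monomer) elemental formulas
.residue_formula <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

.water_formula <- c(H = 2, O = 1)
.h2_formula <- c(H = 2)

oracle_residue_mass <- function(code) {
  oracle_formula_mass(.residue_formula[[code]])
}

oracle_peptide_mass <- function(sequence) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sum(vapply(res, oracle_residue_mass, numeric(1))) +
    oracle_formula_mass(.water_formula)
}

# monosaccharide residue formulas (glycosidic, minus water)
.glycan_formula <- list(
  hex = c(C = 6, H = 10, O = 5),
  hexnac = c(C = 8, H = 13, N = 1, O = 5),
  deoxyhexose = c(C = 6, H = 10, O = 4),
  neuac = c(C = 11, H = 17, N = 1, O = 8)
)

oracle_glycan_mass <- function(hex = 0, hexnac = 0, deoxyhexose = 0, neuac = 0,
                               core = TRUE, label_2aa = FALSE) {
  if (core) { hex <- hex + 3; hexnac <- hexnac + 2 }
  m <- hex * oracle_formula_mass(.glycan_formula$hex) +
    hexnac * oracle_formula_mass(.glycan_formula$hexnac) +
    deoxyhexose * oracle_formula_mass(.glycan_formula$deoxyhexose) +
    neuac * oracle_formula_mass(.glycan_formula$neuac) +
    oracle_formula_mass(.water_formula)
  if (label_2aa) {
    # anthranilic acid C7H7NO2, reductive amination: -H2O +H2
    m <- m + oracle_formula_mass(c(C = 7, H = 7, N = 1, O = 2)) -
      oracle_formula_mass(.water_formula) + oracle_formula_mass(.h2_formula)
  }
  m
}

oracle_disulfide_mass <- function(member_masses, n_bonds) {
  sum(member_masses) - n_bonds * oracle_formula_mass(.h2_formula)
}

# brute-force all-pairs matcher used as the oracle for match_peaks
oracle_match <- function(neutral_peaks, candidates, tol_da) {
  vapply(neutral_peaks, function(m) {
    err <- abs(m - candidates$mono_mass)
    ok <- which(err <= tol_da)
    if (length(ok) == 0) return(NA_integer_)
    ord <- order(err[ok], candidates$n_mods[ok], candidates$sequence[ok])
    ok[ord[1]]
  }, integer(1))
}
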