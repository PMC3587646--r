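# Mass constants and residue tables. Monoisotopic values follow standard
# IUPAC atomic masses; average values follow the conventional elemental
# average weights. All peptide arithmetic in the package goes through
# these tables so the two scales can never be mixed silently.

#' Fundamental mass constants
#'
#' Named constants used throughout the package, in daltons.
#'
#' @format A named numeric vector with elements:
#' \describe{
#'   \item{water_mono, water_avg}{mass of H2O, added once per free peptide}
#'   \item{proton}{mass of a proton; converts neutral mass to MH+}
#'   \item{h2_mono, h2_avg}{mass of H2, lost once per disulfide bond}
#'   \item{isotope_spacing}{C13-C12 spacing, the +1 isotope mis-pick offset}
#' }
#' @export
mass_constants <- c(
  water_mono      = 18.010565,
  water_avg       = 18.01528,
  proton          = 1.007276,
  h2_mono         = 2.015650,
  h2_avg          = 2.01588,
  isotope_spacing = 1.003355
)

# monomer (residue) masses: amino acid minus water
.residue_mono <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.residue_avg <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.check_scale <- function(scale) {
  match.arg(scale, c("monoisotopic", "average"))
}

.residue_table <- function(scale) {
  if (scale == "monoisotopic") .residue_mono else .residue_avg
}

.water <- function(scale) {
  unname(if (scale == "monoisotopic") mass_constants["water_mono"] else mass_constants["water_avg"])
}

#' Mass of a single amino-acid residue
#'
#' Returns the monomer (amino acid minus water) mass of one of the 20
#' canonical residues.
#'
#' @param residue Single-letter residue code.
#' @param scale `"monoisotopic"` (default) or `"average"`.
#' @return Mass in daltons.
#' @examples
#' residue_mass("G")
#' residue_mass("R", scale = "average")
#' @export
residue_mass <- function(residue, scale = c("monoisotopic", "average")) {
  scale <- .check_scale(scale)
  tab <- .residue_table(scale)
  bad <- setdiff(unique(residue), names(tab))
  if (length(bad) > 0) {
    stop("unknown residue code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(tab[residue])
}

#' Modification registry
#'
#' The built-in table of supported covalent modifications. `target` is the
#' set of residue codes a modification may sit on; `mode` records whether
#' the modification is normally applied to every eligible residue
#' (`fixed`, e.g. cysteine blocking in a reduced workflow) or enumerated
#' combinatorially (`variable`, e.g. spontaneous deamidation/oxidation).
#' PNGase F deglycosylation leaves the same +0.98402 Da deamidation
#' signature but only at occupied sequon asparagines, so it is applied by
#' [apply_pngasef()] rather than listed as fixed.
#'
#' @return A tibble with columns `name`, `target`, `mono_delta`,
#'   `avg_delta`, `mode`.
#' @export
modifications <- function() {
  tibble::tribble(
    ~name,              ~target, ~mono_delta, ~avg_delta, ~mode,
    "carbamidomethyl",  "C",        57.02146,    57.0513, "fixed",
    "deamidation",      "NQ",        0.98402,     0.9848, "variable",
    "oxidation",        "M",        15.99491,    15.9994, "variable"
  )
}

.mod_lookup <- function(names_vec, registry = modifications()) {
  idx <- match(names_vec, registry$name)
  if (anyNA(idx)) {
    stop("unknown modification(s): ",
         paste(unique(names_vec[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  registry[idx, ]
}

# fast vectorised raw chain/peptide mass (no mods)
.sequence_mass <- function(sequences, scale) {
  tab <- .residue_table(scale)
  water <- .water(scale)
  vapply(strsplit(sequences, "", fixed = TRUE), function(res) {
    m <- tab[res]
    if (anyNA(m)) {
      stop("unknown residue code(s): ",
           paste(unique(res[is.na(m)]), collapse = ", "), call. = FALSE)
    }
    sum(m) + water
  }, numeric(1))
}

#' Neutral mass of a peptide with applied modifications
#'
#' Computes residue-mass sum plus one water plus the deltas of the applied
#' modifications. `mods` lists applied instances: to apply a modification
#' twice, name it twice. Each application requires an eligible target
#' residue in the sequence; requesting more applications of a modification
#' than there are eligible residues is an error.
#'
#' @param sequence Peptide sequence(s), single-letter codes.
#' @param mods Character vector of modification names from
#'   [modifications()] (applied to every sequence given), or `NULL`.
#' @param scale `"monoisotopic"` (default) or `"average"`.
#' @param registry Modification registry, by default [modifications()].
#' @return Neutral peptide mass(es) in daltons.
#' @examples
#' peptide_mass("GR")
#' peptide_mass("LVLNCTAR", mods = c("carbamidomethyl", "deamidation"))
#' @export
peptide_mass <- function(sequence, mods = NULL,
                         scale = c("monoisotopic", "average"),
                         registry = modifications()) {
  scale <- .check_scale(scale)
  if (any(!nzchar(sequence))) stop("empty peptide sequence", call. = FALSE)
  base <- .sequence_mass(sequence, scale)
  if (is.null(mods) || length(mods) == 0) return(base)
  rows <- .mod_lookup(mods, registry)
  delta_col <- if (scale == "monoisotopic") rows$mono_delta else rows$avg_delta
  # each application needs its own eligible residue
  for (i in seq_along(sequence)) {
    res <- strsplit(sequence[[i]], "", fixed = TRUE)[[1]]
    need <- table(rows$name)
    for (nm in names(need)) {
      targets <- strsplit(rows$target[match(nm, rows$name)], "", fixed = TRUE)[[1]]
      avail <- sum(res %in% targets)
      if (avail < need[[nm]]) {
        stop(sprintf("modification '%s' applied %d time(s) but only %d eligible residue(s) in '%s'",
                     nm, need[[nm]], avail, sequence[[i]]), call. = FALSE)
      }
    }
  }
  base + sum(delta_col)
}

#' Singly protonated mass (MH+)
#'
#' @param mass Neutral mass in daltons.
#' @return `mass + 1.007276`.
#' @export
mh_plus <- function(mass) {
  stopifnot(all(mass >= 0))
  mass + unname(mass_constants["proton"])
}

#' Mass-to-charge ratio for a given charge state
#'
#' @param mass Neutral mass in daltons.
#' @param z Positive integer charge.
#' @return `(mass + z * 1.007276) / z`; `mz(m, 1)` equals [mh_plus()].
#' @export
mz <- function(mass, z) {
  if (any(z < 1)) stop("charge must be >= 1", call. = FALSE)
  (mass + z * unname(mass_constants["proton"])) / z
}

#' Neutral mass back-calculated from an m/z observation
#'
#' Inverse of [mz()]: `mass_from_mz(mz(m, z), z) == m`.
#'
#' @param mz_obs Observed m/z.
#' @param z Positive integer charge.
#' @return Neutral mass in daltons.
#' @export
mass_from_mz <- function(mz_obs, z) {
  if (any(z < 1)) stop("charge must be >= 1", call. = FALSE)
  mz_obs * z - z * unname(mass_constants["proton"])
}
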