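# Glycan composition arithmetic. Compositions are held exactly as the
# field writes them: antenna counts (Hex/HexNAc/Deoxyhexose/NeuAc) kept
# separate from the constant (Man)3(GlcNAc)2 core, with an optional 2-AA
# label on released glycans. Deoxyhexose is fucose mass-wise; NeuAc is
# sialic acid and contributes one acidic group to the pI model.

# monosaccharide residue masses (glycosidic, i.e. minus water)
.glycan_mono <- c(hex = 162.05282, hexnac = 203.07937,
                  deoxyhexose = 146.05791, neuac = 291.09542)
.glycan_avg <- c(hex = 162.1406, hexnac = 203.1925,
                 deoxyhexose = 146.1412, neuac = 291.2546)

# 2-AA reductive amination: + anthranilic acid (C7H7NO2) - H2O + H2
.label_2aa_mono <- 121.052764
.label_2aa_avg <- 121.1366

#' Construct glycan compositions
#'
#' @param hex,hexnac,deoxyhexose,neuac Antenna monosaccharide counts
#'   (the core is counted separately).
#' @param core Logical; add the constant (Man)3(GlcNAc)2 core (3 Hex +
#'   2 HexNAc).
#' @param label `"none"` or `"2AA"`.
#' @return A tibble of compositions with a `composition` notation column
#'   like `"(Hex)2(HexNAc)2(Deoxyhexose)1(NeuAc)2 + (Man)3(GlcNAc)2"`.
#' @export
glycan_composition <- function(hex = 0, hexnac = 0, deoxyhexose = 0, neuac = 0,
                               core = TRUE, label = "none") {
  out <- tibble::tibble(hex = as.integer(hex), hexnac = as.integer(hexnac),
                        deoxyhexose = as.integer(deoxyhexose),
                        neuac = as.integer(neuac), core = core, label = label)
  if (any(out$hex < 0 | out$hexnac < 0 | out$deoxyhexose < 0 | out$neuac < 0)) {
    stop("monosaccharide counts must be >= 0", call. = FALSE)
  }
  if (any(!out$label %in% c("none", "2AA"))) stop("label must be 'none' or '2AA'", call. = FALSE)
  out$composition <- glycan_notation(out)
  out
}

#' Compositional notation for glycans
#'
#' @param comps Composition tibble.
#' @return Character vector like
#'   `"(Hex)2(HexNAc)2(NeuAc)1 + (Man)3(GlcNAc)2"`.
#' @export
glycan_notation <- function(comps) {
  part <- function(name, n) ifelse(n > 0, sprintf("(%s)%d", name, n), "")
  antenna <- paste0(part("Hex", comps$hex), part("HexNAc", comps$hexnac),
                    part("Deoxyhexose", comps$deoxyhexose), part("NeuAc", comps$neuac))
  out <- ifelse(comps$core,
                ifelse(nzchar(antenna), paste0(antenna, " + (Man)3(GlcNAc)2"),
                       "(Man)3(GlcNAc)2"),
                antenna)
  ifelse(nzchar(out), out, "(empty)")
}

#' Parse compositional glycan notation
#'
#' Reads strings such as
#' `"(Hex)2(HexNAc)2(Deoxyhexose)1(NeuAc)2+(Man)3(GlcNAc)2"`; a trailing
#' `+(Man)3(GlcNAc)2` sets the core flag.
#'
#' @param x Character vector of notations.
#' @return Composition tibble as from [glycan_composition()].
#' @export
parse_glycan <- function(x) {
  purrr::map_dfr(x, function(s) {
    s0 <- gsub("\\s", "", s)
    core <- grepl("\\+?\\(Man\\)3\\(GlcNAc\\)2$", s0)
    s0 <- sub("\\+?\\(Man\\)3\\(GlcNAc\\)2$", "", s0)
    count_of <- function(name) {
      m <- stringr::str_match(s0, sprintf("\\(%s\\)(\\d+)", name))[, 2]
      ifelse(is.na(m), 0L, as.integer(m))
    }
    # HexNAc must be counted before Hex is matched standalone
    hexnac <- count_of("HexNAc")
    s1 <- gsub("\\(HexNAc\\)\\d+", "", s0)
    hx <- stringr::str_match(s1, "\\(Hex\\)(\\d+)")[, 2]
    glycan_composition(
      hex = ifelse(is.na(hx), 0L, as.integer(hx)),
      hexnac = hexnac,
      deoxyhexose = count_of("Deoxyhexose"),
      neuac = count_of("NeuAc"),
      core = core
    )
  })
}

#' Mass of a free reducing glycan
#'
#' Sum of monosaccharide residue masses over antenna counts, plus the
#' (Man)3(GlcNAc)2 core when `core` is set, plus one water for the free
#' reducing end, plus the 2-AA label delta when labelled.
#'
#' @param comps Composition tibble.
#' @param scale `"monoisotopic"` or `"average"`.
#' @return Numeric vector of masses in daltons.
#' @export
composition_mass <- function(comps, scale = c("monoisotopic", "average")) {
  scale <- .check_scale(scale)
  tab <- if (scale == "monoisotopic") .glycan_mono else .glycan_avg
  lab <- if (scale == "monoisotopic") .label_2aa_mono else .label_2aa_avg
  if (any(comps$hex < 0 | comps$hexnac < 0 | comps$deoxyhexose < 0 | comps$neuac < 0)) {
    stop("monosaccharide counts must be >= 0", call. = FALSE)
  }
  core_mass <- 3 * tab[["hex"]] + 2 * tab[["hexnac"]]
  comps$hex * tab[["hex"]] + comps$hexnac * tab[["hexnac"]] +
    comps$deoxyhexose * tab[["deoxyhexose"]] + comps$neuac * tab[["neuac"]] +
    ifelse(comps$core, core_mass, 0) +
    .water(scale) +
    ifelse(comps$label == "2AA", lab, 0)
}

#' Apply the 2-AA fluorescent label
#'
#' Reductive amination of the reducing end with anthranilic acid
#' (2-aminobenzoic acid): net +121.052764 Da monoisotopic, identical for
#' every composition. Labelling an already-labelled glycan is an error.
#'
#' @param comps Composition tibble.
#' @return The tibble with `label = "2AA"`.
#' @export
label_2aa <- function(comps) {
  if (any(comps$label != "none")) stop("glycan is already labelled", call. = FALSE)
  comps$label <- "2AA"
  comps
}

#' Glycopeptide mass
#'
#' Mass of a peptide with a glycan attached at its sequon asparagine:
#' peptide mass (Asn unmodified, i.e. not deamidated) plus the glycan
#' *residue* mass (composition mass minus water; glycosidic attachment
#' adds no water). The peptide must contain a sequon and the glycan must
#' be unlabelled.
#'
#' @param peptide Peptide sequence (or a vector matched to `comps`
#'   row-wise).
#' @param comps Composition tibble.
#' @param scale Mass scale.
#' @return Numeric vector of glycopeptide masses.
#' @export
glycopeptide_mass <- function(peptide, comps, scale = c("monoisotopic", "average")) {
  scale <- .check_scale(scale)
  if (any(comps$label != "none")) stop("glycopeptide glycans must be unlabelled", call. = FALSE)
  has_sequon <- vapply(peptide, function(s) nrow(find_sequons(c(x = s))) > 0, logical(1))
  if (any(!has_sequon)) {
    stop("peptide(s) without a sequon: ",
         paste(unique(peptide[!has_sequon]), collapse = ", "), call. = FALSE)
  }
  peptide_mass(peptide, mods = NULL, scale = scale) +
    (composition_mass(comps, scale) - .water(scale))
}

#' Built-in glycan composition library
#'
#' The complex biantennary, core-fucosylated and sialylated compositions
#' typical of CHO-produced Fc-fusion proteins, plus the truncated Fc
#' glycoforms; all carry the (Man)3(GlcNAc)2 core.
#'
#' @return Composition tibble.
#' @export
glycan_library <- function() {
  dplyr::bind_rows(
    glycan_composition(2, 2, 1, 2),  # A2G2F S2
    glycan_composition(2, 2, 1, 1),  # A2G2F S1
    glycan_composition(2, 2, 1, 0),  # A2G2F
    glycan_composition(2, 2, 0, 2),  # A2G2 S2 (afucosyl)
    glycan_composition(2, 2, 0, 1),  # A2G2 S1
    glycan_composition(2, 2, 0, 0),  # A2G2
    glycan_composition(2, 0, 0, 0),  # Man5-like (core + 2 Hex)
    glycan_composition(1, 2, 1, 0),  # A2G1F
    glycan_composition(0, 2, 1, 0),  # A2G0F
    glycan_composition(0, 2, 0, 0)   # A2G0
  )
}

#' Read a glycan library from TSV
#'
#' Columns `hex`, `hexnac`, `deoxyhexose`, `neuac` and optional `core`
#' (default `TRUE`).
#'
#' @param path TSV file path.
#' @return Composition tibble.
#' @export
read_glycan_library <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"core" %in% names(df)) df$core <- TRUE
  glycan_composition(df$hex, df$hexnac, df$deoxyhexose, df$neuac, core = df$core)
}

#' Search glycan compositions matching an observed mass
#'
#' Exhaustive enumeration over the bounded composition lattice; every
#' composition whose mass lies within `tol` of `observed` is returned,
#' sorted by absolute error (ties by counts, lexicographically), so the
#' result equals a brute-force search by construction.
#'
#' @param observed Observed neutral mass in Da (free glycan, labelled or
#'   not according to `label`).
#' @param tol_da Tolerance in Da.
#' @param bounds Named list of upper bounds for `hex`, `hexnac`,
#'   `deoxyhexose`, `neuac`.
#' @param core Require the core (default `TRUE`).
#' @param label Label state of the observed mass.
#' @param scale Mass scale.
#' @return Composition tibble with `mass` and `error_da`, best first.
#' @export
composition_search <- function(observed, tol_da = 0.5,
                               bounds = list(hex = 10, hexnac = 8, deoxyhexose = 3, neuac = 4),
                               core = TRUE, label = "none",
                               scale = c("monoisotopic", "average")) {
  scale <- .check_scale(scale)
  grid <- tidyr::expand_grid(hex = 0:bounds$hex, hexnac = 0:bounds$hexnac,
                             deoxyhexose = 0:bounds$deoxyhexose, neuac = 0:bounds$neuac)
  comps <- glycan_composition(grid$hex, grid$hexnac, grid$deoxyhexose, grid$neuac,
                              core = core, label = label)
  comps$mass <- composition_mass(comps, scale)
  comps$error_da <- comps$mass - observed
  comps <- comps[abs(comps$error_da) <= tol_da, , drop = FALSE]
  dplyr::arrange(comps, abs(.data$error_da), .data$hex, .data$hexnac,
                 .data$deoxyhexose, .data$neuac)
}

#' Assign per-site glycoforms from glycopeptide peak groups
#'
#' Each peak group references one sequon-bearing tryptic peptide.
#' Observed glycopeptide MH+ values are matched against the library of
#' compositions attached to that peptide; per site the matches are ranked
#' by intensity when intensities are present, otherwise by absolute
#' error, and the top `top_k` retained (the "most abundant structures per
#' site" table).
#'
#' @param peak_groups Tibble with columns `site` (identifier), `peptide`
#'   (sequon-bearing sequence), `observed` (MH+), optional `charge`,
#'   `intensity`.
#' @param library Composition tibble (default [glycan_library()]).
#' @param tol_da Tolerance in Da.
#' @param top_k Glycoforms reported per site (default 3).
#' @return A `site_glycoforms` tibble: `site`, `peptide`, `rank`,
#'   `composition`, counts, `theoretical_mh`, `observed`, `error_da`,
#'   `intensity`.
#' @export
assign_site_glycoforms <- function(peak_groups, library = glycan_library(),
                                   tol_da = 0.5, top_k = 3) {
  peak_groups <- tibble::as_tibble(peak_groups)
  bad <- vapply(unique(peak_groups$peptide),
                function(s) nrow(find_sequons(c(x = s))) == 0, logical(1))
  if (any(bad)) {
    stop("peak group(s) reference sequon-free peptide(s): ",
         paste(unique(peak_groups$peptide)[bad], collapse = ", "), call. = FALSE)
  }
  empty <- tibble::tibble(site = peak_groups$site[0], peptide = character(),
                          composition = character(), hex = integer(),
                          hexnac = integer(), deoxyhexose = integer(),
                          neuac = integer(), theoretical_mh = numeric(),
                          observed = numeric(), error_da = numeric(),
                          intensity = numeric(), rank = integer())
  if (nrow(peak_groups) == 0) {
    class(empty) <- c("site_glycoforms", class(empty))
    return(empty)
  }
  out <- peak_groups |>
    dplyr::group_by(.data$site, .data$peptide) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) == 0) return(empty[0, setdiff(names(empty), c("site", "peptide"))])
      cand <- library
      cand$theoretical_mh <- mh_plus(glycopeptide_mass(rep(key$peptide, nrow(cand)), cand))
      hits <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
        err <- g$observed[i] - cand$theoretical_mh
        j <- which(abs(err) <= tol_da)
        if (length(j) == 0) return(NULL)
        j <- j[which.min(abs(err[j]))]
        tibble::tibble(
          composition = cand$composition[j],
          hex = cand$hex[j], hexnac = cand$hexnac[j],
          deoxyhexose = cand$deoxyhexose[j], neuac = cand$neuac[j],
          theoretical_mh = cand$theoretical_mh[j],
          observed = g$observed[i], error_da = err[j],
          intensity = if ("intensity" %in% names(g)) g$intensity[i] else NA_real_
        )
      })
      if (nrow(hits) == 0) return(hits)
      hits <- hits |> dplyr::distinct(.data$composition, .keep_all = TRUE)
      if (all(!is.na(hits$intensity))) {
        hits <- dplyr::arrange(hits, dplyr::desc(.data$intensity))
      } else {
        hits <- dplyr::arrange(hits, abs(.data$error_da))
      }
      hits <- utils::head(hits, top_k)
      hits$rank <- seq_len(nrow(hits))
      hits
    }) |>
    dplyr::ungroup()
  class(out) <- c("site_glycoforms", class(out))
  out
}
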