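# Theory-vs-observation matching: PNGase F simulation, variable
# modification expansion, tolerance matching against observed peak lists,
# sequence coverage, and b/y fragment prediction for CID confirmation.
# Peaks may be given as MH+ or as (m/z, z); the canonical internal form is
# the neutral monoisotopic mass.

#' Simulate PNGase F treatment on a peptide table
#'
#' PNGase F releases N-glycans and converts each occupied sequon
#' asparagine to aspartate, a +0.98402 Da (monoisotopic) deamidation
#' signature. Every peptide whose coordinates overlap an occupied sequon
#' gains one deamidation per overlapped site; peptides without sequons
#' are returned unchanged. This is how site occupancy is read out of a
#' peptide map: the deamidated tryptic peptide appears only in the
#' treated sample.
#'
#' @param peptides A peptide table from [theoretical_peptide_table()].
#' @param sequon_sites Tibble from [find_sequons()]; only rows with
#'   `occupied` `TRUE` (or `NA`, treated as occupied) are applied.
#' @param registry Modification registry.
#' @return The peptide table with deamidation applied at overlapped
#'   sequons and masses recomputed; adds column `n_deamidated`.
#' @export
apply_pngasef <- function(peptides, sequon_sites, registry = modifications()) {
  occ <- sequon_sites[is.na(sequon_sites$occupied) | sequon_sites$occupied, ]
  orphan <- !purrr::map2_lgl(occ$chain_id, occ$position, function(cid, pos) {
    any(peptides$chain_id == cid & peptides$start <= pos & peptides$end >= pos)
  })
  if (any(orphan)) {
    warning(sum(orphan), " occupied sequon site(s) fall outside every peptide",
            call. = FALSE)
  }
  n_deam <- purrr::pmap_int(peptides[c("chain_id", "start", "end")],
    function(chain_id, start, end) {
      sum(occ$chain_id == chain_id & occ$position >= start & occ$position <= end)
    })
  deam <- .mod_lookup("deamidation", registry)
  peptides$mods <- purrr::map2(peptides$mods, n_deam,
                               function(m, k) c(m, rep("deamidation", k)))
  peptides$n_mods <- peptides$n_mods + n_deam
  peptides$n_deamidated <- n_deam
  peptides$mono_mass <- peptides$mono_mass + n_deam * deam$mono_delta
  peptides$avg_mass <- peptides$avg_mass + n_deam * deam$avg_delta
  peptides$mh_plus <- mh_plus(peptides$mono_mass)
  peptides
}

#' Expand variable-modification candidates
#'
#' For each peptide, enumerates every placement of at most `max_mods`
#' variable modifications on eligible residues (each residue carries at
#' most one), always including the unmodified form. Masses are updated
#' per candidate.
#'
#' @param peptides Peptide table with mass columns (fixed mods already
#'   applied).
#' @param variable_mods Character vector of variable modification names.
#' @param max_mods Maximum number of variable modifications per peptide.
#' @param registry Modification registry.
#' @return A candidate tibble: the peptide columns plus `var_mods`
#'   (list-column of `name@position` strings) and `n_var_mods`.
#' @export
expand_variants <- function(peptides, variable_mods = c("deamidation", "oxidation"),
                            max_mods = 2, registry = modifications()) {
  stopifnot(max_mods >= 0)
  mod_rows <- .mod_lookup(variable_mods, registry)
  purrr::map_dfr(seq_len(nrow(peptides)), function(i) {
    p <- peptides[i, ]
    res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
    # eligible (mod, position) pairs
    sites <- purrr::map_dfr(seq_len(nrow(mod_rows)), function(j) {
      targets <- strsplit(mod_rows$target[j], "", fixed = TRUE)[[1]]
      tibble::tibble(name = mod_rows$name[j],
                     position = which(res %in% targets),
                     mono_delta = mod_rows$mono_delta[j],
                     avg_delta = mod_rows$avg_delta[j])
    })
    combos <- list(integer(0))
    if (nrow(sites) > 0 && max_mods > 0) {
      for (k in seq_len(min(max_mods, nrow(sites)))) {
        cmb <- utils::combn(nrow(sites), k, simplify = FALSE)
        # a residue position can carry at most one modification
        cmb <- purrr::keep(cmb, function(ix) !anyDuplicated(sites$position[ix]))
        combos <- c(combos, cmb)
      }
    }
    purrr::map_dfr(combos, function(ix) {
      out <- p
      out$var_mods <- list(sprintf("%s@%d", sites$name[ix], sites$position[ix]))
      out$n_var_mods <- length(ix)
      out$n_mods <- p$n_mods + length(ix)
      out$mono_mass <- p$mono_mass + sum(sites$mono_delta[ix])
      out$avg_mass <- p$avg_mass + sum(sites$avg_delta[ix])
      out$mh_plus <- mh_plus(out$mono_mass)
      out
    })
  })
}

# canonical neutral mass from a peak table (observed is MH+ when charge
# is absent/NA, otherwise m/z at that charge)
.peak_neutral <- function(peaks) {
  z <- if ("charge" %in% names(peaks)) peaks$charge else rep(NA_real_, nrow(peaks))
  z[is.na(z)] <- 1
  if (any(z < 1)) stop("charge must be >= 1", call. = FALSE)
  mass_from_mz(peaks$observed, z)
}

#' Match observed peaks against theoretical candidates
#'
#' Assigns each peak its best candidate within tolerance: smallest
#' absolute mass error, ties broken by fewer modifications, then by
#' lexicographic sequence. Identical to a brute-force all-pairs search by
#' construction. Optionally also tests the hypothesis that a peak is a +1
#' isotope mis-pick (observed 1.00336 Da above the monoisotopic peak, a
#' known ion-trap artifact); such assignments are flagged
#' `isotope_offset` and only used when no direct match exists.
#'
#' @param peaks Tibble with column `observed` (MH+, or m/z when a
#'   `charge` column is present) and optional `charge`, `intensity`.
#' @param candidates Tibble with columns `mono_mass`, `sequence`,
#'   `n_mods` (e.g. from [theoretical_peptide_table()], [apply_pngasef()]
#'   or [expand_variants()]).
#' @param tol_da Absolute tolerance in Da on the neutral-mass scale.
#' @param tol_ppm Optional ppm tolerance; when given, a match must also
#'   satisfy it.
#' @param check_isotope Also test the -1 isotope-offset hypothesis.
#' @return A `match_results` tibble, one row per peak: peak columns,
#'   `matched`, candidate columns (`NA` when unmatched), `error_da`
#'   (observed - theoretical, neutral scale), `error_ppm`,
#'   `isotope_offset`.
#' @export
match_peaks <- function(peaks, candidates, tol_da = 0.5, tol_ppm = NULL,
                        check_isotope = FALSE) {
  stopifnot(tol_da > 0 || (!is.null(tol_ppm) && tol_ppm > 0))
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) > 0 && any(peaks$observed <= 0)) stop("observed mass must be > 0", call. = FALSE)
  neutral <- .peak_neutral(peaks)
  cand_cols <- c("chain_id", "start", "end", "sequence", "missed_cleavages",
                 "n_mods", "mono_mass", "mh_plus")
  cand_cols <- intersect(cand_cols, names(candidates))

  pick <- function(target) {
    if (nrow(candidates) == 0) return(NA_integer_)
    err <- target - candidates$mono_mass
    ok <- abs(err) <= tol_da
    if (!is.null(tol_ppm)) ok <- ok & abs(err) / candidates$mono_mass * 1e6 <= tol_ppm
    if (!any(ok)) return(NA_integer_)
    ix <- which(ok)
    ord <- order(abs(err[ix]), candidates$n_mods[ix], candidates$sequence[ix])
    ix[ord[1]]
  }

  if (nrow(peaks) == 0) {
    rows <- peaks
    rows$peak <- integer()
    rows$neutral_mass <- numeric()
    rows$matched <- logical()
    for (cc in cand_cols) rows[[cc]] <- candidates[[cc]][0]
    rows$error_da <- numeric()
    rows$error_ppm <- numeric()
    rows$isotope_offset <- logical()
    class(rows) <- c("match_results", class(rows))
    return(rows)
  }

  rows <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    j <- pick(neutral[i])
    iso <- FALSE
    if (is.na(j) && check_isotope) {
      j <- pick(neutral[i] - unname(mass_constants["isotope_spacing"]))
      iso <- !is.na(j)
    }
    base <- peaks[i, ]
    base$peak <- i
    base$neutral_mass <- neutral[i]
    if (is.na(j)) {
      base$matched <- FALSE
      for (cc in cand_cols) base[[cc]] <- candidates[[cc]][NA_integer_]
      base$error_da <- NA_real_; base$error_ppm <- NA_real_
      base$isotope_offset <- FALSE
    } else {
      base$matched <- TRUE
      for (cc in cand_cols) base[[cc]] <- candidates[[cc]][j]
      eff <- neutral[i] - if (iso) unname(mass_constants["isotope_spacing"]) else 0
      base$error_da <- eff - candidates$mono_mass[j]
      base$error_ppm <- base$error_da / candidates$mono_mass[j] * 1e6
      base$isotope_offset <- iso
    }
    base
  })
  class(rows) <- c("match_results", class(rows))
  rows
}

#' Propagate matches across identical homodimer chains
#'
#' The chains of a homodimer are indistinguishable in a peptide map: a
#' peak matched to a peptide of one chain is equally evidence for every
#' chain with that sequence. This replicates each matched row onto all
#' sequence-identical chains so coverage and occupancy are credited
#' symmetrically.
#'
#' @param matches A `match_results` tibble.
#' @param chains Chain table.
#' @return The matches with matched rows replicated across twin chains.
#' @export
expand_homodimer_matches <- function(matches, chains) {
  chains <- as_chain_tbl(chains)
  if (anyDuplicated(chains$sequence) == 0 || !any(matches$matched)) return(matches)
  hit <- matches[matches$matched, , drop = FALSE]
  out <- purrr::map_dfr(seq_len(nrow(hit)), function(i) {
    seq_i <- chains$sequence[match(hit$chain_id[i], chains$chain_id)]
    twins <- chains$chain_id[chains$sequence == seq_i]
    o <- hit[rep(i, length(twins)), ]
    o$chain_id <- twins
    o
  })
  out <- dplyr::bind_rows(out, matches[!matches$matched, , drop = FALSE])
  class(out) <- c("match_results", class(out))
  out
}

#' Sequence coverage from matched peptides
#'
#' Unions the chain intervals of all matched peptides and reports the
#' covered fraction per chain.
#'
#' @param matches A `match_results` tibble whose candidates carry
#'   `chain_id`, `start`, `end`.
#' @param chains Chain table (or named character vector).
#' @return A `coverage_report` tibble: `chain_id`, `length`,
#'   `covered_residues`, `fraction`, `intervals` (list-column of
#'   two-column matrices).
#' @export
coverage <- function(matches, chains) {
  chains <- as_chain_tbl(chains)
  hits <- matches[matches$matched & !is.na(matches$start), , drop = FALSE]
  out <- purrr::pmap_dfr(chains[c("chain_id", "sequence")], function(chain_id, sequence) {
    n <- nchar(sequence)
    mask <- logical(n)
    h <- hits[hits$chain_id == chain_id, , drop = FALSE]
    if (nrow(h) > 0) {
      if (any(h$start < 1 | h$end > n)) stop("matched interval outside chain bounds", call. = FALSE)
      for (i in seq_len(nrow(h))) mask[h$start[i]:h$end[i]] <- TRUE
    }
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    iv <- cbind(start = starts[r$values], end = ends[r$values])
    tibble::tibble(chain_id = chain_id, length = n,
                   covered_residues = sum(mask), fraction = sum(mask) / n,
                   intervals = list(iv))
  })
  class(out) <- c("coverage_report", class(out))
  out
}

#' b/y fragment ion series for CID confirmation
#'
#' Singly charged b and y ions: `b_i` is the sum of the first `i` residue
#' masses (plus any per-residue modification deltas) plus a proton; `y_j`
#' is the sum of the last `j` residues plus water plus a proton. The
#' complementarity identity `b_i + y_(n-i) = M + 2 * 1.007276` holds for
#' every cut position.
#'
#' @param sequence Peptide sequence (length >= 2).
#' @param mod_deltas Optional numeric vector of per-residue monoisotopic
#'   modification deltas (length = peptide length).
#' @param series Which series to return.
#' @return A tibble `series`, `index`, `mz`, ordered by series then
#'   index.
#' @export
fragment_ions <- function(sequence, mod_deltas = NULL, series = c("b", "y")) {
  series <- match.arg(series, several.ok = TRUE)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n < 2) stop("fragment ions require a peptide of length >= 2", call. = FALSE)
  m <- residue_mass(res, "monoisotopic")
  if (!is.null(mod_deltas)) {
    stopifnot(length(mod_deltas) == n)
    m <- m + mod_deltas
  }
  proton <- unname(mass_constants["proton"])
  water <- unname(mass_constants["water_mono"])
  out <- list()
  if ("b" %in% series) {
    out$b <- tibble::tibble(series = "b", index = seq_len(n - 1),
                            mz = cumsum(m)[seq_len(n - 1)] + proton)
  }
  if ("y" %in% series) {
    out$y <- tibble::tibble(series = "y", index = seq_len(n - 1),
                            mz = cumsum(rev(m))[seq_len(n - 1)] + water + proton)
  }
  dplyr::bind_rows(out)
}
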