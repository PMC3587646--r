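# End-to-end characterization: digestion -> (PNGase F) -> matching ->
# coverage & sequon occupancy; non-reduced digestion -> disulfide mapping
# with scrambling check; per-site glycoform assignment; pI summary.
# Everything in the report is traceable to a match row.

#' Characterize a fusion protein from observed peak lists
#'
#' Runs the whole in-silico characterization pipeline against up to three
#' observed peak lists (reduced/PNGase F peptide map, non-reduced digest,
#' glycopeptide groups) and assembles a report.
#'
#' @param chains Chain tibble or named character vector.
#' @param peaks_peptide_map Peak tibble for the reduced + PNGase F
#'   peptide map (`observed` as MH+ or with a `charge` column), or
#'   `NULL`.
#' @param peaks_nonreduced Peak tibble from the non-reduced digest, or
#'   `NULL`.
#' @param peak_groups_glyco Glycopeptide peak groups (`site`, `peptide`,
#'   `observed`, optional `intensity`), or `NULL`.
#' @param bonds Disulfide topology tibble, or `NULL` to skip disulfide
#'   mapping.
#' @param glycan_lib Glycan composition library.
#' @param tol_da Matching tolerance in Da.
#' @param max_missed Missed cleavages for the reduced digest.
#' @param nonreduced_missed Missed cleavages for the non-reduced digest.
#' @param pngasef Model the PNGase F-treated sample (sequon Asn -> Asp).
#' @param check_isotope Test the +1 isotope mis-pick hypothesis for
#'   otherwise unmatched peaks.
#' @param pka pKa set for the pI summary.
#' @param glycan_pool_fraction Fraction of each site's glycan pool that
#'   the reported top-k glycoforms are taken to account for when
#'   estimating the sialic-acid load for the pI summary; the unreported
#'   remainder of the pool is taken as asialo. A released-glycan
#'   chromatogram of CHO material shows a long tail of neutral species
#'   beyond the few most abundant glycoforms, so treating the top-k as
#'   the whole pool overstates sialylation.
#' @param seed Seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return A `characterization_report` list with elements `coverage`,
#'   `sequons`, `matches`, `disulfide`, `glycoforms`, `pi_summary`,
#'   `provenance`.
#' @export
characterize <- function(chains,
                         peaks_peptide_map = NULL,
                         peaks_nonreduced = NULL,
                         peak_groups_glyco = NULL,
                         bonds = NULL,
                         glycan_lib = glycan_library(),
                         tol_da = 0.5, max_missed = 0, nonreduced_missed = 1,
                         pngasef = TRUE, check_isotope = TRUE,
                         pka = pka_bjellqvist(), glycan_pool_fraction = 0.6,
                         seed = 1) {
  stopifnot(tol_da > 0)
  chains <- as_chain_tbl(chains)
  sequons <- find_sequons(chains)

  candidates <- theoretical_peptide_table(chains, max_missed = max_missed,
                                          fixed_mods = "carbamidomethyl")
  if (pngasef) {
    occ <- sequons; occ$occupied <- TRUE
    candidates <- apply_pngasef(candidates, occ)
  }

  matches <- NULL
  cov <- NULL
  if (!is.null(peaks_peptide_map)) {
    matches <- match_peaks(peaks_peptide_map, candidates, tol_da = tol_da,
                           check_isotope = check_isotope)
    cov_matches <- expand_homodimer_matches(matches, chains)
    cov <- coverage(cov_matches, chains)
    # a sequon is confirmed occupied when a deamidated peptide covering it
    # was observed in the treated sample
    sequons$occupied <- purrr::map2_lgl(sequons$chain_id, sequons$position,
      function(cid, pos) {
        any(cov_matches$matched & cov_matches$chain_id == cid &
              cov_matches$start <= pos & cov_matches$end >= pos &
              cov_matches$n_mods > 0, na.rm = TRUE)
      })
  }

  disulfide <- NULL
  if (!is.null(bonds)) {
    assembly <- dimer_assembly(chains, bonds)
    pool <- nonreduced_digest(assembly, missed_cleavages = nonreduced_missed)
    expected <- build_linked_species(pool, bonds)
    hypothetical <- enumerate_hypothetical_pairs(pool)
    disulfide <- if (is.null(peaks_nonreduced)) {
      list(expected = expected, hypothetical = hypothetical)
    } else {
      detect_mispairing(peaks_nonreduced, expected, hypothetical, tol_da)
    }
  }

  glycoforms <- NULL
  if (!is.null(peak_groups_glyco)) {
    glycoforms <- assign_site_glycoforms(peak_groups_glyco, glycan_lib, tol_da)
  }

  n_chains <- nrow(chains)
  n_sites <- nrow(sequons)
  sialic_total <- sialic_load(glycoforms) * glycan_pool_fraction * n_sites
  seqs <- chains$sequence
  g_glyc <- ionizable_groups(seqs, n_sialic = sialic_total)
  g_deglyc <- ionizable_groups(seqs)
  g_deglyc[["D"]] <- g_deglyc[["D"]] + n_sites
  pi_summary <- tibble::tibble(
    state = c("glycosylated", "deglycosylated"),
    n_acidic_glycan_groups = c(sialic_total, 0),
    n_new_asp = c(0, n_sites),
    pi = c(isoelectric_point(g_glyc, pka), isoelectric_point(g_deglyc, pka))
  )

  params <- list(tol_da = tol_da, max_missed = max_missed,
                 nonreduced_missed = nonreduced_missed, pngasef = pngasef,
                 check_isotope = check_isotope, pka = as.list(pka),
                 glycan_pool_fraction = glycan_pool_fraction, seed = seed)
  provenance <- list(
    package_version = as.character(utils::packageVersion("massmapr")),
    parameters = params,
    config_hash = rlang::hash(params),
    seed = seed
  )

  structure(list(coverage = cov, sequons = sequons, matches = matches,
                 disulfide = disulfide, glycoforms = glycoforms,
                 pi_summary = pi_summary, provenance = provenance),
            class = "characterization_report")
}

#' @export
print.characterization_report <- function(x, ...) {
  cat("Characterization report\n")
  if (!is.null(x$coverage)) {
    cat(sprintf("  coverage: %s\n",
                paste(sprintf("%s %.1f%%", x$coverage$chain_id,
                              100 * x$coverage$fraction), collapse = ", ")))
  }
  cat(sprintf("  sequons: %d (%d confirmed occupied)\n",
              nrow(x$sequons), sum(x$sequons$occupied %in% TRUE)))
  if (inherits(x$disulfide, "disulfide_report")) {
    cat(sprintf("  disulfide species matched: %d / %d; scrambling hits: %d\n",
                sum(x$disulfide$expected$matched), nrow(x$disulfide$expected),
                nrow(x$disulfide$scrambling)))
  }
  if (!is.null(x$glycoforms)) {
    cat(sprintf("  glycoforms assigned: %d across %d sites\n",
                nrow(x$glycoforms), length(unique(x$glycoforms$site))))
  }
  cat(sprintf("  pI: %.2f glycosylated -> %.2f deglycosylated\n",
              x$pi_summary$pi[1], x$pi_summary$pi[2]))
  invisible(x)
}

#' Strict anomaly check on a report
#'
#' Returns `TRUE` when the report is clean: full coverage of every chain,
#' all sequons occupied, all expected disulfide species found and no
#' scrambling hits. Used by the command-line `characterize` to set a
#' nonzero exit status under `--strict`.
#'
#' @param report A `characterization_report`.
#' @return Logical.
#' @export
report_clean <- function(report) {
  ok <- TRUE
  if (!is.null(report$coverage)) ok <- ok && all(report$coverage$fraction == 1)
  ok <- ok && all(report$sequons$occupied %in% TRUE)
  if (inherits(report$disulfide, "disulfide_report")) {
    ok <- ok && all(report$disulfide$expected$matched) &&
      nrow(report$disulfide$scrambling) == 0
  }
  ok
}

#' Write a report bundle to disk
#'
#' TSV per table plus one JSON bundle with the provenance block.
#'
#' @param report A `characterization_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(dir, paste0(name, ".tsv"))
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.list),
                                          ~purrr::map_chr(.x, paste, collapse = ";")))
    readr::write_tsv(df, p)
    paths <<- c(paths, p)
  }
  wr(report$coverage, "coverage")
  wr(report$sequons, "sequons")
  wr(report$matches, "matches")
  if (inherits(report$disulfide, "disulfide_report")) {
    wr(report$disulfide$expected, "disulfide_expected")
    wr(report$disulfide$scrambling, "disulfide_scrambling")
  }
  wr(report$glycoforms, "glycoforms")
  wr(report$pi_summary, "pi_summary")
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(list(
    glance = as.list(glance(report)),
    provenance = report$provenance
  ), jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, jp)
  invisible(paths)
}
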