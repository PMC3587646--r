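# Rule-based in-silico protease digestion. Cleavage happens after every
# residue in the rule's cut_after set unless the next residue is in
# blocked_by_next; peptides carry 1-based inclusive coordinates on their
# parent chain so downstream stages (coverage, sequon overlap, disulfide
# link points) can reason in chain space.

#' Built-in protease rules
#'
#' @param name Rule name: `"trypsin"` (cut after K or R, blocked by a
#'   following P) or `"none"` (no cleavage; one peptide per chain).
#' @return A list with elements `name`, `cut_after`, `blocked_by_next`.
#' @export
protease_rule <- function(name = c("trypsin", "none")) {
  name <- match.arg(name)
  switch(name,
    trypsin = list(name = "trypsin", cut_after = c("K", "R"), blocked_by_next = "P"),
    none = list(name = "none", cut_after = character(), blocked_by_next = character())
  )
}

# cut points for one chain: positions after which the backbone is cleaved
.cut_sites <- function(res, rule) {
  n <- length(res)
  if (n <= 1 || length(rule$cut_after) == 0) return(integer())
  i <- seq_len(n - 1)
  i[res[i] %in% rule$cut_after & !(res[i + 1] %in% rule$blocked_by_next)]
}

#' Digest protein chains in silico
#'
#' Applies a protease rule to every chain and returns all peptides with
#' `0..missed_cleavages` internal missed cut sites. The zero-missed
#' peptides tile each chain exactly (contiguous, non-overlapping, full
#' coverage).
#'
#' @param chains A tibble with columns `chain_id`, `sequence`, or a named
#'   character vector.
#' @param rule A protease rule from [protease_rule()] or a compatible
#'   list.
#' @param missed_cleavages Maximum number of missed cleavages (>= 0).
#' @param min_length Drop peptides shorter than this (default 1, i.e. no
#'   filter).
#' @return A tibble with columns `chain_id`, `start`, `end`, `sequence`,
#'   `missed_cleavages`.
#' @examples
#' digest(c(x = "AKRPGKR"))
#' @export
digest <- function(chains, rule = protease_rule("trypsin"),
                   missed_cleavages = 0, min_length = 1) {
  stopifnot(missed_cleavages >= 0)
  chains <- as_chain_tbl(chains)
  purrr::pmap_dfr(chains[c("chain_id", "sequence")], function(chain_id, sequence) {
    res <- strsplit(sequence, "", fixed = TRUE)[[1]]
    n <- length(res)
    bounds <- c(0L, .cut_sites(res, rule), n)
    bounds <- unique(bounds)
    starts <- bounds[-length(bounds)] + 1L
    ends <- bounds[-1]
    k <- length(starts)
    out <- purrr::map_dfr(0:min(missed_cleavages, k - 1), function(m) {
      i <- seq_len(k - m)
      tibble::tibble(
        chain_id = chain_id,
        start = starts[i],
        end = ends[i + m],
        missed_cleavages = m
      )
    })
    out$sequence <- stringr::str_sub(sequence, out$start, out$end)
    out[nchar(out$sequence) >= min_length,
        c("chain_id", "start", "end", "sequence", "missed_cleavages")]
  })
}

#' Theoretical peptide table from a simulated digestion
#'
#' Digests the chains and computes monoisotopic and average neutral
#' masses plus MH+ for every peptide, with fixed modifications applied to
#' every eligible residue (the standard reduced-and-blocked workflow uses
#' carbamidomethyl on all cysteines).
#'
#' @inheritParams digest
#' @param max_missed Maximum missed cleavages.
#' @param fixed_mods Character vector of fixed modification names applied
#'   to every eligible residue, or `NULL`.
#' @param registry Modification registry, default [modifications()].
#' @return A tibble: `chain_id`, `start`, `end`, `sequence`,
#'   `missed_cleavages`, `mods` (list-column of applied modification
#'   names), `n_mods`, `mono_mass`, `avg_mass`, `mh_plus`.
#' @export
theoretical_peptide_table <- function(chains, rule = protease_rule("trypsin"),
                                      max_missed = 0, fixed_mods = "carbamidomethyl",
                                      min_length = 1, registry = modifications()) {
  peps <- digest(chains, rule, max_missed, min_length)
  add_peptide_masses(peps, fixed_mods = fixed_mods, registry = registry)
}

# apply fixed mods per eligible residue and compute both-scale masses
add_peptide_masses <- function(peps, fixed_mods = "carbamidomethyl",
                               registry = modifications()) {
  if (nrow(peps) == 0) {
    peps$mods <- list(); peps$n_mods <- integer()
    peps$mono_mass <- peps$avg_mass <- peps$mh_plus <- numeric()
    return(peps)
  }
  mod_rows <- if (is.null(fixed_mods)) registry[0, ] else .mod_lookup(fixed_mods, registry)
  applied <- purrr::map(peps$sequence, function(s) {
    res <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- character()
    for (j in seq_len(nrow(mod_rows))) {
      targets <- strsplit(mod_rows$target[j], "", fixed = TRUE)[[1]]
      out <- c(out, rep(mod_rows$name[j], sum(res %in% targets)))
    }
    out
  })
  mono_delta <- vapply(applied, function(m) {
    if (length(m) == 0) 0 else sum(.mod_lookup(m, registry)$mono_delta)
  }, numeric(1))
  avg_delta <- vapply(applied, function(m) {
    if (length(m) == 0) 0 else sum(.mod_lookup(m, registry)$avg_delta)
  }, numeric(1))
  peps$mods <- applied
  peps$n_mods <- lengths(applied)
  peps$mono_mass <- .sequence_mass(peps$sequence, "monoisotopic") + mono_delta
  peps$avg_mass <- .sequence_mass(peps$sequence, "average") + avg_delta
  peps$mh_plus <- mh_plus(peps$mono_mass)
  peps
}
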