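# Disulfide mapping from a non-reduced digest. Peptides become nodes,
# disulfide bonds become edges between the peptides containing the bonded
# cysteines, and each connected component with at least one bond is a
# linked species whose mass obeys M = sum(member masses) - 2H per bond.
# Scrambling is detected by matching observed peaks against the exhaustive
# enumeration of hypothetical cysteine-linked di-peptides.

#' Construct a homodimeric (or heterodimeric) assembly with disulfide topology
#'
#' @param chains Chain table (`chain_id`, `sequence`) or named character
#'   vector; two chains for a dimer.
#' @param bonds Tibble of cysteine pairs: `chain_a`, `pos_a`, `chain_b`,
#'   `pos_b`, 1-based positions. Every bonded position must be a cysteine
#'   and no cysteine may appear in more than one bond.
#' @return A `dimer_assembly` list with elements `chains` and `bonds`.
#' @export
dimer_assembly <- function(chains, bonds) {
  chains <- as_chain_tbl(chains)
  bonds <- tibble::as_tibble(bonds)
  stopifnot(all(c("chain_a", "pos_a", "chain_b", "pos_b") %in% names(bonds)))
  res_at <- function(cid, pos) {
    s <- chains$sequence[match(cid, chains$chain_id)]
    if (anyNA(s)) stop("bond references unknown chain: ", paste(unique(cid[is.na(s)]), collapse = ", "), call. = FALSE)
    substring(s, pos, pos)
  }
  ra <- res_at(bonds$chain_a, bonds$pos_a)
  rb <- res_at(bonds$chain_b, bonds$pos_b)
  if (any(ra != "C") || any(rb != "C")) {
    stop("bonded position(s) are not cysteine", call. = FALSE)
  }
  ends <- c(paste(bonds$chain_a, bonds$pos_a), paste(bonds$chain_b, bonds$pos_b))
  if (anyDuplicated(ends)) stop("a cysteine appears in more than one bond", call. = FALSE)
  structure(list(chains = chains, bonds = bonds), class = "dimer_assembly")
}

#' Non-reduced digest with cysteine link points retained
#'
#' Digests every chain of the assembly and annotates each peptide with
#' the global (chain, position) coordinates of the cysteines it carries.
#' Masses are computed with no cysteine blocking (non-reduced workflow).
#'
#' @param assembly A [dimer_assembly()].
#' @param rule Protease rule.
#' @param missed_cleavages Maximum missed cleavages (default 1; linked
#'   peptides frequently retain missed sites).
#' @return Peptide pool tibble with mass columns and a `cys_positions`
#'   list-column of integer chain positions.
#' @export
nonreduced_digest <- function(assembly, rule = protease_rule("trypsin"),
                              missed_cleavages = 1) {
  stopifnot(inherits(assembly, "dimer_assembly"))
  pool <- theoretical_peptide_table(assembly$chains, rule, missed_cleavages,
                                    fixed_mods = NULL)
  pool$cys_positions <- purrr::pmap(pool[c("sequence", "start")], function(sequence, start) {
    which(strsplit(sequence, "", fixed = TRUE)[[1]] == "C") + start - 1L
  })
  pool
}

# peptide id string for graph nodes
.pep_key <- function(pool) paste(pool$chain_id, pool$start, pool$end, sep = ":")

# locate the pool row (zero-missed tile) containing a cysteine
.containing_peptide <- function(pool, chain_id, pos) {
  hit <- which(pool$chain_id == chain_id & pool$start <= pos & pool$end >= pos &
                 pool$missed_cleavages == 0)
  if (length(hit) == 0) return(NA_integer_)
  hit[1]
}

#' Linked species expected under a disulfide topology
#'
#' Builds the peptide-bond graph from the zero-missed-cleavage pool and
#' the stated topology, takes connected components with at least one
#' bond, and computes each species mass by the -2H-per-bond rule
#' (monoisotopic 2.015650, average 2.01588). Species identical up to the
#' chain relabelling of a homodimer (same member-sequence multiset and
#' bond count) are collapsed to one row with `n_copies` recording the
#' multiplicity, matching how a mass spectrum counts them: the two
#' symmetric hinge peptides joined by the two inter-chain bonds form a
#' single homo-di-peptide species with `bond_count` 2.
#'
#' @param pool Pool from [nonreduced_digest()].
#' @param bonds Bond table as in [dimer_assembly()].
#' @return A tibble: `species_id`, `members` (list of member sequences),
#'   `member_coords` (list of `chain:start:end` keys), `n_members`,
#'   `bond_count`, `n_copies`, `mono_mass`, `avg_mass`, `mh_plus`.
#' @export
build_linked_species <- function(pool, bonds) {
  bonds <- tibble::as_tibble(bonds)
  if (nrow(bonds) == 0) {
    return(tibble::tibble(species_id = character(), members = list(),
                          member_coords = list(), n_members = integer(),
                          bond_count = integer(), n_copies = integer(),
                          mono_mass = numeric(), avg_mass = numeric(),
                          mh_plus = numeric()))
  }
  tiles <- pool[pool$missed_cleavages == 0, , drop = FALSE]
  key <- .pep_key(tiles)
  ia <- purrr::map2_int(bonds$chain_a, bonds$pos_a, ~.containing_peptide(tiles, .x, .y))
  ib <- purrr::map2_int(bonds$chain_b, bonds$pos_b, ~.containing_peptide(tiles, .x, .y))
  if (anyNA(ia) || anyNA(ib)) {
    bad <- which(is.na(ia) | is.na(ib))
    stop("bond endpoint(s) not found in the peptide pool: bond row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = key[ia], to = key[ib]),
    directed = FALSE,
    vertices = data.frame(name = key)
  )
  comp <- igraph::components(g)
  edge_member <- comp$membership[key[ia]]  # both endpoints share a component
  species <- purrr::map_dfr(sort(unique(edge_member)), function(cmp) {
    nodes <- which(comp$membership == cmp)
    rows <- tiles[nodes, , drop = FALSE]
    b <- sum(edge_member == cmp)
    tibble::tibble(
      members = list(sort(rows$sequence)),
      member_coords = list(sort(key[nodes])),
      n_members = nrow(rows),
      bond_count = b,
      mono_mass = sum(rows$mono_mass) - b * unname(mass_constants["h2_mono"]),
      avg_mass = sum(rows$avg_mass) - b * unname(mass_constants["h2_avg"])
    )
  })
  # collapse homodimer-symmetric duplicates
  sig <- paste(purrr::map_chr(species$members, paste, collapse = "+"),
               species$bond_count, sep = "|b=")
  species <- species |>
    dplyr::mutate(.sig = sig) |>
    dplyr::group_by(.data$.sig) |>
    dplyr::summarise(
      members = members[1], member_coords = member_coords[1],
      n_members = n_members[1], bond_count = bond_count[1],
      n_copies = dplyr::n(),
      mono_mass = mono_mass[1], avg_mass = avg_mass[1],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mono_mass) |>
    dplyr::select(-".sig")
  species$species_id <- sprintf("DS%02d", seq_len(nrow(species)))
  species$mh_plus <- mh_plus(species$mono_mass)
  species[c("species_id", "members", "member_coords", "n_members",
            "bond_count", "n_copies", "mono_mass", "avg_mass", "mh_plus")]
}

#' Exhaustively enumerate hypothetical cysteine-linked di-peptides
#'
#' Every unordered pair of distinct cysteine-bearing peptide species in
#' the pool, including self-pairs (the same tryptic peptide from the two
#' chains of a homodimer), with the single-bond mass
#' `m1 + m2 - 2.01565`; pairs in which both members carry at least two
#' cysteines are additionally listed with `bond_count` 2. For k distinct
#' cysteine-bearing peptide sequences this yields `choose(k, 2) + k`
#' single-bond pairs. Matching observed peaks against this enumeration
#' (minus the expected topology) is the disulfide scrambling check.
#'
#' @param pool Pool from [nonreduced_digest()] (zero-missed tiles are
#'   used).
#' @return A tibble: `seq_a`, `seq_b`, `bond_count`, `mono_mass`,
#'   `mh_plus`.
#' @export
enumerate_hypothetical_pairs <- function(pool) {
  tiles <- pool[pool$missed_cleavages == 0 & lengths(pool$cys_positions) > 0, ]
  specs <- tiles |>
    dplyr::distinct(.data$sequence, .keep_all = TRUE) |>
    dplyr::arrange(.data$sequence)
  k <- nrow(specs)
  if (k < 1) {
    return(tibble::tibble(seq_a = character(), seq_b = character(),
                          bond_count = integer(), mono_mass = numeric(),
                          mh_plus = numeric()))
  }
  idx <- expand.grid(a = seq_len(k), b = seq_len(k))
  idx <- idx[idx$a <= idx$b, ]
  h2 <- unname(mass_constants["h2_mono"])
  out <- tibble::tibble(
    seq_a = specs$sequence[idx$a],
    seq_b = specs$sequence[idx$b],
    bond_count = 1L,
    mono_mass = specs$mono_mass[idx$a] + specs$mono_mass[idx$b] - h2
  )
  ncys_a <- lengths(specs$cys_positions)[idx$a]
  ncys_b <- lengths(specs$cys_positions)[idx$b]
  two <- ncys_a >= 2 & ncys_b >= 2
  if (any(two)) {
    extra <- out[two, ]
    extra$bond_count <- 2L
    extra$mono_mass <- extra$mono_mass - h2
    out <- dplyr::bind_rows(out, extra)
  }
  out$mh_plus <- mh_plus(out$mono_mass)
  dplyr::arrange(out, .data$mono_mass)
}

#' Detect disulfide scrambling in an observed peak list
#'
#' Two-sided report: (a) which expected linked species are matched by an
#' observed peak within tolerance, and (b) which peaks match a
#' hypothetical cysteine pairing that is *not* an expected species —
#' evidence of non-native disulfide scrambling.
#'
#' @param peaks Peak tibble (`observed` as MH+, optional `charge`).
#' @param expected Species table from [build_linked_species()].
#' @param hypothetical Enumeration from [enumerate_hypothetical_pairs()].
#' @param tol_da Tolerance in Da.
#' @return A `disulfide_report` list with tibbles `expected` (adds
#'   `matched`, `observed`, `error_da`) and `scrambling` (one row per
#'   scrambling hit: peak, offending pair, error).
#' @export
detect_mispairing <- function(peaks, expected, hypothetical, tol_da = 0.5) {
  stopifnot(tol_da > 0)
  peaks <- tibble::as_tibble(peaks)
  neutral <- if (nrow(peaks) > 0) .peak_neutral(peaks) else numeric()

  exp_match <- purrr::map_dfr(seq_len(nrow(expected)), function(i) {
    err <- neutral - expected$mono_mass[i]
    j <- which(abs(err) <= tol_da)
    if (length(j) == 0) {
      tibble::tibble(matched = FALSE, observed = NA_real_, error_da = NA_real_)
    } else {
      j <- j[which.min(abs(err[j]))]
      tibble::tibble(matched = TRUE, observed = peaks$observed[j], error_da = err[j])
    }
  })
  expected_out <- dplyr::bind_cols(expected, exp_match)

  is_expected_mass <- function(m) {
    nrow(expected) > 0 && any(abs(m - expected$mono_mass) <= tol_da)
  }
  scrambling <- purrr::map_dfr(seq_along(neutral), function(i) {
    if (is_expected_mass(neutral[i])) return(NULL)
    err <- neutral[i] - hypothetical$mono_mass
    j <- which(abs(err) <= tol_da)
    if (length(j) == 0) return(NULL)
    j <- j[order(abs(err[j]))]
    tibble::tibble(peak = i, observed = peaks$observed[i],
                   seq_a = hypothetical$seq_a[j], seq_b = hypothetical$seq_b[j],
                   bond_count = hypothetical$bond_count[j], error_da = err[j])
  })
  if (nrow(scrambling) == 0) {
    scrambling <- tibble::tibble(peak = integer(), observed = numeric(),
                                 seq_a = character(), seq_b = character(),
                                 bond_count = integer(), error_da = numeric())
  }
  structure(list(expected = expected_out, scrambling = scrambling,
                 tol_da = tol_da),
            class = "disulfide_report")
}

#' @export
print.disulfide_report <- function(x, ...) {
  cat(sprintf("Disulfide mapping report (tol %.3g Da)\n", x$tol_da))
  cat(sprintf("  expected species matched: %d / %d\n",
              sum(x$expected$matched), nrow(x$expected)))
  cat(sprintf("  scrambling hits: %d\n", nrow(x$scrambling)))
  invisible(x)
}
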