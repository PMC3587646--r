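# Charge-vs-pH model and isoelectric point. The net charge of a protein
# is a Henderson-Hasselbalch sum over its ionizable groups; the pI is the
# root of that curve. Sialic acids on N-glycans are modelled as extra
# acidic groups, which is what links glycan occupancy to the acidic shift
# seen by capillary electrophoresis after PNGase F treatment.

#' Bjellqvist pKa set
#'
#' The default pKa values used by [charge_at_ph()] and
#' [isoelectric_point()]. `sialic` is the carboxylic acid of
#' N-acetylneuraminic acid, contributed by sialylated glycans. Override
#' any entry by passing a modified copy.
#'
#' @return Named numeric vector of pKa values.
#' @export
pka_bjellqvist <- function() {
  c(n_term = 7.5, c_term = 3.55,
    D = 4.05, E = 4.45, C = 9.0, Y = 10.0,
    H = 5.98, K = 10.0, R = 12.0,
    sialic = 2.6)
}

.acidic_groups <- c("c_term", "D", "E", "C", "Y", "sialic")
.basic_groups  <- c("n_term", "H", "K", "R")

#' Count ionizable groups of a sequence
#'
#' Tallies the side chains and termini that carry charge, optionally with
#' extra acidic groups from sialylated glycans.
#'
#' @param sequence Protein or peptide sequence (one chain).
#' @param n_chains Number of identical chains (2 for a homodimer doubles
#'   every count including termini).
#' @param n_sialic Number of sialic-acid carboxyl groups carried by the
#'   attached glycans (per assembly, not per chain).
#' @return Named numeric vector of group counts suitable for
#'   [charge_at_ph()].
#' @export
ionizable_groups <- function(sequence, n_chains = 1, n_sialic = 0) {
  res <- strsplit(paste(sequence, collapse = ""), "", fixed = TRUE)[[1]]
  counts <- c(
    n_term = length(sequence) * n_chains,
    c_term = length(sequence) * n_chains,
    D = sum(res == "D") * n_chains, E = sum(res == "E") * n_chains,
    C = sum(res == "C") * n_chains, Y = sum(res == "Y") * n_chains,
    H = sum(res == "H") * n_chains, K = sum(res == "K") * n_chains,
    R = sum(res == "R") * n_chains,
    sialic = n_sialic
  )
  counts
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch sum over N-terminus, C-terminus, D, E, C, Y, K,
#' R, H and any extra acidic groups (e.g. sialic acids). Basic groups
#' contribute `+n / (1 + 10^(pH - pKa))`, acidic groups
#' `-n / (1 + 10^(pKa - pH))`.
#'
#' @param groups Named counts as from [ionizable_groups()]; names absent
#'   from the pKa set are rejected.
#' @param ph pH value(s) in `[0, 14]`.
#' @param pka pKa set, by default [pka_bjellqvist()].
#' @return Signed net charge (vectorised over `ph`).
#' @export
charge_at_ph <- function(groups, ph, pka = pka_bjellqvist()) {
  stopifnot(all(ph >= 0 & ph <= 14))
  bad <- setdiff(names(groups), names(pka))
  if (length(bad) > 0) stop("unknown ionizable group(s): ", paste(bad, collapse = ", "), call. = FALSE)
  vapply(ph, function(p) {
    pos <- sum(vapply(intersect(names(groups), .basic_groups), function(g) {
      groups[[g]] / (1 + 10^(p - pka[[g]]))
    }, numeric(1)))
    neg <- sum(vapply(intersect(names(groups), .acidic_groups), function(g) {
      groups[[g]] / (1 + 10^(pka[[g]] - p))
    }, numeric(1)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which [charge_at_ph()] crosses zero, by bisection on
#' `[0, 14]` until `|charge| < tol`. The charge curve is strictly
#' decreasing in pH, so the root is unique when it exists; with at least
#' one acidic and one basic group (the two termini suffice) a sign change
#' is guaranteed.
#'
#' @inheritParams charge_at_ph
#' @param tol Convergence tolerance on the net charge.
#' @return The pI.
#' @export
isoelectric_point <- function(groups, pka = pka_bjellqvist(), tol = 1e-4) {
  lo <- 0; hi <- 14
  q_lo <- charge_at_ph(groups, lo, pka)
  q_hi <- charge_at_ph(groups, hi, pka)
  if (q_lo <= 0 || q_hi >= 0) {
    stop("charge curve does not change sign on [0, 14]; need at least one acidic and one basic group",
         call. = FALSE)
  }
  repeat {
    mid <- (lo + hi) / 2
    q <- charge_at_ph(groups, mid, pka)
    if (abs(q) < tol || (hi - lo) < 1e-12) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Isoelectric point of a sequence
#'
#' Convenience wrapper: counts groups with [ionizable_groups()] and calls
#' [isoelectric_point()].
#'
#' @inheritParams ionizable_groups
#' @inheritParams isoelectric_point
#' @return The pI.
#' @examples
#' sequence_pi("KKKK") > sequence_pi("KKKD")
#' @export
sequence_pi <- function(sequence, n_chains = 1, n_sialic = 0,
                        pka = pka_bjellqvist(), tol = 1e-4) {
  isoelectric_point(ionizable_groups(sequence, n_chains, n_sialic), pka, tol)
}
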