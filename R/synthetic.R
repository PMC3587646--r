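# Seeded synthetic-data generators. The "vegf_trap" preset emulates the
# architecture of a homodimeric VEGF-receptor/Fc fusion protein: seven
# N-glycosylation sequons each on its own tryptic peptide, two adjacent
# inter-chain hinge cysteines sharing one tryptic peptide per chain, and
# one intra-chain disulfide pair spanning two peptides in each of two
# receptor-like domains plus two pairs in the Fc-like region. The real
# molecule's sequence is proprietary/unpublished, so fixture sequences are
# generated; the preset reproduces the printed feature counts (7 sequons,
# 10 bonds per homodimer, 5 distinct linked di-peptide species) without
# claiming sequence identity.

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# filler alphabet: no K/R (would add cut sites), no C (link points are
# designed), no N (sequons are designed); segments never start with P
# (would block the preceding cleavage)
.filler_alphabet <- c("A", "D", "E", "F", "G", "H", "I", "L", "M",
                      "P", "Q", "S", "T", "V", "W", "Y")

.rand_run <- function(len, first_not_p = FALSE) {
  s <- sample(.filler_alphabet, len, replace = TRUE)
  if (first_not_p && s[1] == "P") {
    s[1] <- sample(setdiff(.filler_alphabet, "P"), 1)
  }
  paste(s, collapse = "")
}

.seg_filler <- function() paste0(.rand_run(sample(6:11, 1), TRUE), sample(c("K", "R"), 1))

.seg_sequon <- function() {
  x <- sample(setdiff(.filler_alphabet, "P"), 1)
  paste0(.rand_run(sample(2:4, 1), TRUE), "N", x, sample(c("S", "T"), 1),
         .rand_run(sample(2:6, 1)), sample(c("K", "R"), 1))
}

.seg_cys <- function() {
  paste0(.rand_run(sample(2:4, 1), TRUE), "C", .rand_run(sample(2:6, 1)),
         sample(c("K", "R"), 1))
}

# hinge-like peptide carrying two cysteines (CPPCP motif as in an IgG1
# hinge; the P after each C never blocks cleavage since C is not a cut site)
.seg_hinge <- function() {
  paste0(.rand_run(sample(2:3, 1), TRUE), "CPPCP", .rand_run(sample(2:4, 1)), "K")
}

# default per-site glycoform truth: complex biantennary with core fucose
# and sialylation on the receptor-domain sites, afucosylated forms on one
# site, truncated glycans on the Fc site. fraction_of_pool records how
# much of each site's glycan pool a listed form accounts for; the three
# listed forms cover 60% of the pool, the unlisted remainder being the
# long tail of mostly neutral species a released-glycan chromatogram of
# CHO material always shows. The remainder is what keeps the
# site-averaged sialic load below one NeuAc per site, and with it the
# acidic (not basic) pI shift on deglycosylation.
.default_glycoforms <- function() {
  pool_frac <- c(0.33, 0.18, 0.09)
  set_for <- function(site, triplets) {
    purrr::imap_dfr(triplets, function(tr, rank) {
      cbind(tibble::tibble(site = site, rank = rank,
                           fraction_of_pool = pool_frac[rank]),
            glycan_composition(tr[1], tr[2], tr[3], tr[4]))
    })
  }
  fucosyl <- list(c(2, 2, 1, 2), c(2, 2, 1, 1), c(2, 2, 1, 0))
  dplyr::bind_rows(
    set_for(1, fucosyl),
    set_for(2, fucosyl),
    set_for(3, list(c(2, 2, 0, 1), c(2, 0, 0, 0), c(2, 2, 0, 2))),
    set_for(4, list(c(2, 2, 0, 1), c(2, 2, 1, 1), c(2, 2, 0, 0))),
    set_for(5, fucosyl),
    set_for(6, fucosyl),
    set_for(7, list(c(1, 2, 1, 0), c(0, 2, 1, 0), c(0, 2, 0, 0)))
  )
}

#' Generate a synthetic homodimeric fusion-protein fixture
#'
#' Builds a two-chain assembly with the `"vegf_trap"` preset topology
#' (see the module comment), the per-site glycoform truth table, and
#' ground-truth peptide, disulfide and glycopeptide tables against which
#' every pipeline stage can be checked. Deterministic under `seed`.
#'
#' @param seed Integer seed.
#' @param preset Only `"vegf_trap"` currently.
#' @param glycoforms Per-site glycoform table (`site`, `rank`, counts);
#'   defaults to the built-in complex-biantennary pattern.
#' @return A `trap_fixture` list: `assembly` ([dimer_assembly()]),
#'   `sequons` (occupied sites, both chains), `annotations` (domain
#'   intervals), `glycoforms`, `truth` (list of `peptides`, `disulfides`,
#'   `glycopeptides` tibbles), `seed`.
#' @export
make_fixture <- function(seed = 1, preset = "vegf_trap", glycoforms = NULL) {
  preset <- match.arg(preset)
  if (is.null(glycoforms)) glycoforms <- .default_glycoforms()
  .with_seed(seed, {
    for (attempt in 1:25) {
      segs <- list(
        filler1 = .seg_filler(),
        seq1    = .seg_sequon(),
        vr1_a   = .seg_cys(),
        filler2 = .seg_filler(),
        vr1_b   = .seg_cys(),
        seq2    = .seg_sequon(),
        vr2_a   = .seg_cys(),
        seq3    = .seg_sequon(),
        vr2_b   = .seg_cys(),
        seq4    = .seg_sequon(),
        filler3 = .seg_filler(),
        hinge   = .seg_hinge(),
        seq5    = .seg_sequon(),
        ch2_a   = .seg_cys(),
        filler4 = .seg_filler(),
        ch2_b   = .seg_cys(),
        seq6    = .seg_sequon(),
        ch3_a   = .seg_cys(),
        filler5 = .seg_filler(),
        ch3_b   = .seg_cys(),
        seq7    = .seg_sequon(),
        tail    = .rand_run(sample(6:10, 1), TRUE)
      )
      sequence <- paste(unlist(segs), collapse = "")
      lens <- nchar(unlist(segs))
      offsets <- c(0, cumsum(lens))[seq_along(lens)]
      names(offsets) <- names(segs)
      ok <- all(lens >= 5 & lens <= 20)
      if (ok) break
    }
    if (!ok) stop("could not place fixture segments within length bounds", call. = FALSE)

    cys_at <- function(seg) {
      offsets[[seg]] + which(strsplit(segs[[seg]], "", fixed = TRUE)[[1]] == "C")
    }
    hinge_cys <- cys_at("hinge")
    intra <- purrr::map_dfr(
      list(c("vr1_a", "vr1_b"), c("vr2_a", "vr2_b"),
           c("ch2_a", "ch2_b"), c("ch3_a", "ch3_b")),
      function(pr) tibble::tibble(pos_a = cys_at(pr[1]), pos_b = cys_at(pr[2]))
    )
    bonds <- dplyr::bind_rows(
      tibble::tibble(chain_a = "A", pos_a = hinge_cys,
                     chain_b = "B", pos_b = hinge_cys),
      purrr::map_dfr(c("A", "B"), function(ch) {
        tibble::tibble(chain_a = ch, pos_a = intra$pos_a,
                       chain_b = ch, pos_b = intra$pos_b)
      })
    )
    chains <- tibble::tibble(chain_id = c("A", "B"), sequence = sequence)
    assembly <- dimer_assembly(chains, bonds)

    sequons <- find_sequons(chains)
    sequons$occupied <- TRUE
    sequons$site <- rep(seq_len(nrow(sequons) / 2), 2)

    domain_of <- c(filler1 = "linker", seq1 = "VR1 D2", vr1_a = "VR1 D2",
                   filler2 = "VR1 D2", vr1_b = "VR1 D2", seq2 = "VR2 D3",
                   vr2_a = "VR2 D3", seq3 = "VR2 D3", vr2_b = "VR2 D3",
                   seq4 = "VR2 D4", filler3 = "VR2 D4", hinge = "Fc hinge",
                   seq5 = "Fc CH2", ch2_a = "Fc CH2", filler4 = "Fc CH2",
                   ch2_b = "Fc CH2", seq6 = "Fc CH3", ch3_a = "Fc CH3",
                   filler5 = "Fc CH3", ch3_b = "Fc CH3", seq7 = "Fc CH3",
                   tail = "tail")
    annotations <- tibble::tibble(
      segment = names(segs),
      domain = unname(domain_of[names(segs)]),
      start = offsets + 1L,
      end = offsets + lens
    )

    fx <- structure(list(assembly = assembly, sequons = sequons,
                         annotations = annotations, glycoforms = glycoforms,
                         seed = seed),
                    class = "trap_fixture")
    fx$truth <- .fixture_truth(fx)
    fx
  })
}

# ground-truth tables for every pipeline stage
.fixture_truth <- function(fx) {
  chain_a <- fx$assembly$chains[1, ]
  occ_a <- fx$sequons[fx$sequons$chain_id == "A", ]

  peptides <- theoretical_peptide_table(chain_a, max_missed = 0,
                                        fixed_mods = "carbamidomethyl") |>
    apply_pngasef(occ_a)

  pool <- nonreduced_digest(fx$assembly, missed_cleavages = 0)
  disulfides <- build_linked_species(pool, fx$assembly$bonds)

  tiles <- digest(chain_a)
  glyco <- fx$glycoforms |>
    dplyr::rowwise() |>
    dplyr::mutate(
      peptide = tiles$sequence[tiles$start <= occ_a$position[.data$site] &
                                 tiles$end >= occ_a$position[.data$site]][1],
      theoretical_mh = mh_plus(glycopeptide_mass(.data$peptide,
        glycan_composition(.data$hex, .data$hexnac, .data$deoxyhexose, .data$neuac))),
      intensity = 300 * .data$fraction_of_pool
    ) |>
    dplyr::ungroup()

  list(peptides = peptides, disulfides = disulfides, glycopeptides = glyco)
}

#' @export
print.trap_fixture <- function(x, ...) {
  cat("Synthetic homodimeric fusion-protein fixture\n")
  cat(sprintf("  chain length: %d residues x 2 chains\n",
              nchar(x$assembly$chains$sequence[1])))
  cat(sprintf("  sequons: %d per chain; disulfide bonds: %d; expected linked species: %d\n",
              sum(x$sequons$chain_id == "A"), nrow(x$assembly$bonds),
              nrow(x$truth$disulfides)))
  invisible(x)
}

#' Simulate an observed peak list from ground-truth species
#'
#' Emulates ion-trap observation of a list of species: each non-dropped
#' species emits one MH+ peak with Gaussian mass error, occasionally
#' shifted +1.00336 Da (a +1 isotope mis-pick), plus uniform contaminant
#' peaks over the scan range.
#'
#' @param truth Tibble with an `mh_plus` column (and optionally
#'   `intensity`); any id columns are carried into `species`.
#' @param mass_sigma Gaussian mass error SD in Da (default 0.2,
#'   ion-trap scale).
#' @param isotope_pick_prob Probability of a +1 isotope mis-pick.
#' @param dropout_prob Probability a species emits no peak.
#' @param contaminant_rate Expected number of contaminant peaks
#'   (Poisson).
#' @param scan_range m/z window for contaminants (default 500-2000).
#' @param seed Optional seed.
#' @return Peak tibble: `observed` (MH+ scale), `intensity`, `species`
#'   (truth row index, `NA` for contaminants), `isotope_shifted`.
#' @export
simulate_peaklist <- function(truth, mass_sigma = 0.2, isotope_pick_prob = 0.1,
                              dropout_prob = 0, contaminant_rate = 0,
                              scan_range = c(500, 2000), seed = NULL) {
  stopifnot(nrow(truth) > 0, mass_sigma >= 0,
            isotope_pick_prob >= 0, isotope_pick_prob <= 1,
            dropout_prob >= 0, dropout_prob <= 1)
  run <- function() {
    keep <- stats::runif(nrow(truth)) >= dropout_prob
    n <- sum(keep)
    shift <- stats::runif(n) < isotope_pick_prob
    obs <- truth$mh_plus[keep] + stats::rnorm(n, 0, mass_sigma) +
      shift * unname(mass_constants["isotope_spacing"])
    peaks <- tibble::tibble(
      observed = obs,
      intensity = if ("intensity" %in% names(truth)) truth$intensity[keep]
                  else stats::runif(n, 10, 100),
      species = which(keep),
      isotope_shifted = shift
    )
    n_cont <- if (contaminant_rate > 0) stats::rpois(1, contaminant_rate) else 0L
    if (n_cont > 0) {
      peaks <- dplyr::bind_rows(peaks, tibble::tibble(
        observed = stats::runif(n_cont, scan_range[1], scan_range[2]),
        intensity = stats::runif(n_cont, 1, 20),
        species = NA_integer_,
        isotope_shifted = FALSE
      ))
    }
    dplyr::arrange(peaks, .data$observed)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Average sialic-acid load per glycosylation site
#'
#' Pool-fraction-weighted NeuAc count summed within each site, averaged
#' over sites. When no `fraction_of_pool` column is present the
#' glycoforms at a site are weighted by `intensity` if available,
#' equally otherwise, and taken to describe the whole pool.
#'
#' @param glycoforms A per-site glycoform tibble with columns `site`,
#'   `neuac` and one of `fraction_of_pool` / `intensity`.
#' @return Average NeuAc per site (scalar).
#' @export
sialic_load <- function(glycoforms) {
  if (is.null(glycoforms) || nrow(glycoforms) == 0) return(0)
  per_site <- glycoforms |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(load = if ("fraction_of_pool" %in% names(glycoforms)) {
      sum(.data$fraction_of_pool * .data$neuac)
    } else if ("intensity" %in% names(glycoforms) && all(!is.na(.data$intensity))) {
      sum(.data$intensity * .data$neuac) / sum(.data$intensity)
    } else {
      mean(.data$neuac)
    }, .groups = "drop")
  mean(per_site$load)
}

#' Simulate a PNGase F deglycosylation time course and its pI profile
#'
#' Site occupancy decays as first-order release (`exp(-rate * hours)`).
#' Each site is, independently, either released (its Asn converted to
#' Asp, one new acidic group, no glycan) or still occupied, in which case
#' it carries a glycoform drawn from that site's pool (the listed forms
#' at their pool fractions, the unlisted remainder asialo) and
#' contributes that form's sialic acids as extra acidic groups. The
#' charge-state distribution of the whole assembly is the convolution of
#' the per-site distributions; the pI of every (released, sialic) state
#' is computed with [isoelectric_point()]. The untreated sample is a
#' heterogeneous multi-peak pI profile (sialylation heterogeneity), the
#' mean pI strictly decreases with treatment time — the acidic shift
#' seen by capillary electrophoresis — and at long times the profile
#' collapses to the single fully deamidated species.
#'
#' @param fixture A `trap_fixture` (or any list with `assembly`,
#'   `sequons`, `glycoforms` of the same shape).
#' @param hours Time points in hours.
#' @param rate First-order release rate per hour.
#' @param pka pKa set.
#' @param prune Mixture components below this weight are dropped before
#'   the pI evaluation.
#' @return A `pngasef_timecourse` tibble: `hours`,
#'   `fraction_deglycosylated`, `n_released`, `n_sialic`, `weight`,
#'   `pi`; per-time-point summary (`mean_pi`, `n_major_species`) in
#'   attribute `"summary"`.
#' @export
simulate_pngasef_timecourse <- function(fixture, hours = c(0, 7, 48), rate = 0.1,
                                        pka = pka_bjellqvist(), prune = 1e-6) {
  stopifnot(rate > 0)
  n_chains <- nrow(fixture$assembly$chains)
  seq1 <- fixture$assembly$chains$sequence[1]
  sites <- sort(unique(fixture$glycoforms$site))
  base <- ionizable_groups(seq1, n_chains = n_chains)

  # per-site sialic-count pmf of the occupied state
  site_pmf <- purrr::map(sites, function(s) {
    g <- fixture$glycoforms[fixture$glycoforms$site == s, ]
    frac <- if ("fraction_of_pool" %in% names(g)) g$fraction_of_pool
            else rep(1 / nrow(g), nrow(g))
    pmf <- tapply(frac, g$neuac, sum)
    rest <- 1 - sum(frac)
    out <- tibble::tibble(n_sialic = as.integer(names(pmf)), w = as.numeric(pmf))
    if (rest > 1e-12) {
      out <- dplyr::bind_rows(out, tibble::tibble(n_sialic = 0L, w = rest)) |>
        dplyr::count(.data$n_sialic, wt = .data$w, name = "w")
    }
    out
  })

  convolve_sites <- function(p_occ) {
    states <- tibble::tibble(n_released = 0L, n_sialic = 0L, w = 1)
    for (pmf in rep(site_pmf, n_chains)) {
      occupied <- purrr::map_dfr(seq_len(nrow(pmf)), function(j) {
        tibble::tibble(n_released = states$n_released,
                       n_sialic = states$n_sialic + pmf$n_sialic[j],
                       w = states$w * p_occ * pmf$w[j])
      })
      released <- tibble::tibble(n_released = states$n_released + 1L,
                                 n_sialic = states$n_sialic,
                                 w = states$w * (1 - p_occ))
      states <- dplyr::bind_rows(occupied, released) |>
        dplyr::count(.data$n_released, .data$n_sialic, wt = .data$w, name = "w") |>
        dplyr::filter(.data$w > prune)
    }
    states$w <- states$w / sum(states$w)
    states
  }

  out <- purrr::map_dfr(hours, function(t) {
    p_occ <- exp(-rate * t)
    states <- convolve_sites(p_occ)
    states$pi <- purrr::map2_dbl(states$n_released, states$n_sialic, function(d, s) {
      g <- base
      g[["D"]] <- g[["D"]] + d
      g[["sialic"]] <- s
      isoelectric_point(g, pka)
    })
    tibble::tibble(hours = t, fraction_deglycosylated = 1 - p_occ,
                   n_released = states$n_released, n_sialic = states$n_sialic,
                   weight = states$w, pi = states$pi)
  })
  summary <- out |>
    dplyr::group_by(.data$hours) |>
    dplyr::summarise(
      fraction_deglycosylated = .data$fraction_deglycosylated[1],
      mean_pi = sum(.data$weight * .data$pi),
      n_major_species = sum(.data$weight > 0.01),
      pi_min = min(.data$pi[.data$weight > 0.01]),
      pi_max = max(.data$pi[.data$weight > 0.01]),
      .groups = "drop"
    )
  attr(out, "summary") <- summary
  class(out) <- c("pngasef_timecourse", class(out))
  out
}
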