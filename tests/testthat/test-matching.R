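# PNGase F simulation, variant expansion, tolerance matching, coverage,
# fragment ions.

test_that("apply_pngasef adds one deamidation per occupied overlapped sequon", {
  chains <- c(x = "GGKNSTFVRAANISNVTKGGR")
  tab <- theoretical_peptide_table(chains)
  sites <- find_sequons(chains)
  sites$occupied <- TRUE
  out <- apply_pngasef(tab, sites)
  # NSTFVR carries one sequon; AANISNVTK carries two
  expect_equal(out$n_deamidated[out$sequence == "NSTFVR"], 1L)
  expect_equal(out$n_deamidated[out$sequence == "AANISNVTK"], 2L)
  expect_equal(out$n_deamidated[out$sequence == "GGK"], 0L)
  expect_equal(out$mono_mass - tab$mono_mass, out$n_deamidated * 0.98402,
               tolerance = 1e-9)
  # a site outside every peptide warns but does not fail
  sites2 <- tibble::tibble(chain_id = "y", position = 5L, motif = "NAS",
                           occupied = TRUE)
  expect_warning(apply_pngasef(tab, sites2), "outside")
})

test_that("expand_variants enumerates placements combinatorially", {
  tab <- theoretical_peptide_table(c(x = "AAAK"), fixed_mods = NULL)
  v <- expand_variants(tab, "oxidation", 2)
  expect_equal(nrow(v), 1L)                       # no eligible residue
  expect_equal(v$n_var_mods, 0L)

  tab2 <- theoretical_peptide_table(c(x = "MAMK"), fixed_mods = NULL)
  v2 <- expand_variants(tab2, "oxidation", 2)
  expect_equal(nrow(v2), 4L)                      # 0, 1a, 1b, 2 oxidations
  expect_equal(sort(v2$n_var_mods), c(0L, 1L, 1L, 2L))
  expect_equal(sort(unique(v2$mono_mass - tab2$mono_mass)),
               c(0, 15.99491, 2 * 15.99491), tolerance = 1e-6)

  tab3 <- theoretical_peptide_table(c(x = "NGK"), fixed_mods = NULL)
  v3 <- expand_variants(tab3, "deamidation", 1)
  expect_equal(nrow(v3), 2L)
  expect_equal(diff(sort(v3$mono_mass)), 0.98402, tolerance = 1e-6)
})

test_that("match_peaks equals the brute-force all-pairs oracle", {
  set.seed(42)
  aa <- c("A", "G", "L", "S", "T", "V", "E", "D", "F", "Y", "K", "R")
  for (rep in 1:20) {
    candidates <- tibble::tibble(
      sequence = replicate(200, paste(sample(aa, sample(4:15, 1), TRUE), collapse = "")),
      n_mods = sample(0:3, 200, TRUE)
    )
    candidates$mono_mass <- peptide_mass(candidates$sequence)
    peaks <- tibble::tibble(
      observed = mh_plus(sample(candidates$mono_mass, 50)) + rnorm(50, 0, 0.3)
    )
    res <- match_peaks(peaks, candidates, tol_da = 0.5)
    want <- oracle_match(mass_from_mz(peaks$observed, 1), candidates, 0.5)
    got <- ifelse(res$matched, match(paste(res$sequence, res$n_mods),
                                     paste(candidates$sequence, candidates$n_mods)),
                  NA_integer_)
    expect_equal(
      candidates$mono_mass[got][!is.na(want)],
      candidates$mono_mass[want][!is.na(want)]
    )
    expect_equal(is.na(got), is.na(want))
  }
})

test_that("matching respects charge states, exact hits and empty candidate sets", {
  cand <- tibble::tibble(sequence = "PEPTIDE", n_mods = 0L,
                         mono_mass = peptide_mass("PEPTIDE"))
  # MH+ peak exactly on theory -> error 0
  r1 <- match_peaks(tibble::tibble(observed = mh_plus(cand$mono_mass)), cand)
  expect_true(r1$matched)
  expect_equal(r1$error_da, 0, tolerance = 1e-10)
  # same species observed at z = 2
  r2 <- match_peaks(tibble::tibble(observed = mz(cand$mono_mass, 2), charge = 2), cand)
  expect_true(r2$matched)
  expect_equal(r2$error_da, 0, tolerance = 1e-10)
  # empty candidate set: unmatched, not an error
  r3 <- match_peaks(tibble::tibble(observed = 500), cand[0, ])
  expect_false(r3$matched)
})

test_that("isotope-offset hypothesis recovers +1 mis-picked peaks and is flagged", {
  cand <- tibble::tibble(sequence = c("NGIPLESNHTIK", "DTGNYTVILTNPISK"),
                         n_mods = 0L)
  cand$mono_mass <- peptide_mass(cand$sequence)
  peaks <- tibble::tibble(observed = mh_plus(cand$mono_mass) + 1.003355)
  plain <- match_peaks(peaks, cand, tol_da = 0.5)
  expect_false(any(plain$matched))
  iso <- match_peaks(peaks, cand, tol_da = 0.5, check_isotope = TRUE)
  expect_true(all(iso$matched))
  expect_true(all(iso$isotope_offset))
  expect_equal(iso$error_da, c(0, 0), tolerance = 1e-9)
})

test_that("coverage unions matched intervals", {
  chains <- c(x = paste(rep("A", 40), collapse = ""))
  fake <- tibble::tibble(matched = TRUE, chain_id = "x",
                         start = c(1L, 5L), end = c(10L, 20L))
  cov <- coverage(fake, chains)
  expect_equal(cov$fraction, 0.5)
  expect_equal(cov$covered_residues, 20L)
  expect_equal(unname(cov$intervals[[1]][, "start"]), 1L)
  expect_equal(unname(cov$intervals[[1]][, "end"]), 20L)
  cov0 <- coverage(fake[0, ], chains)
  expect_equal(cov0$fraction, 0)
  # a fully matched zero-missed digest covers everything
  fx <- make_fixture(seed = 6)
  truth <- fx$truth$peptides
  peaks <- tibble::tibble(observed = truth$mh_plus)
  m <- match_peaks(peaks, truth, tol_da = 0.01)
  expect_equal(coverage(m, fx$assembly$chains[1, ])$fraction, 1)
})

test_that("b/y fragment series obey the complementarity identity", {
  b <- fragment_ions("GG", series = "b")
  y <- fragment_ions("GG", series = "y")
  expect_equal(b$mz[1], 57.02146 + 1.007276, tolerance = 1e-6)
  expect_equal(y$mz[1], 57.02146 + 18.010565 + 1.007276, tolerance = 1e-6)
  expect_error(fragment_ions("G"), "length")
  set.seed(9)
  aa <- names(.residue_formula)
  for (i in 1:10) {
    s <- paste(sample(aa, sample(2:20, 1), TRUE), collapse = "")
    n <- nchar(s)
    deltas <- ifelse(runif(n) < 0.2, 15.99491, 0)
    fr <- fragment_ions(s, mod_deltas = deltas)
    M <- peptide_mass(s) + sum(deltas)
    bi <- fr$mz[fr$series == "b"]
    yj <- fr$mz[fr$series == "y"]
    expect_equal(bi + rev(yj), rep(M + 2 * 1.007276, n - 1), tolerance = 1e-8,
                 label = s)
  }
})
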