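# Fixture generator, peak-list simulator, PNGase F time course.

test_that("the preset fixture reproduces the expected architecture, deterministically", {
  fx <- make_fixture(seed = 123)
  expect_equal(sum(fx$sequons$chain_id == "A"), 7L)          # seven sequons
  expect_equal(nrow(fx$truth$disulfides), 5L)                # five linked species
  expect_equal(nrow(fx$assembly$bonds), 10L)
  # each sequon sits on its own tryptic peptide
  tiles <- digest(fx$assembly$chains[1, ])
  host <- vapply(fx$sequons$position[fx$sequons$chain_id == "A"], function(p) {
    which(tiles$start <= p & tiles$end >= p)
  }, integer(1))
  expect_equal(anyDuplicated(host), 0L)
  # tryptic peptides around designed features are 5-20 residues long
  expect_true(all(nchar(tiles$sequence[host]) >= 5 & nchar(tiles$sequence[host]) <= 20))
  # determinism
  fx2 <- make_fixture(seed = 123)
  expect_identical(fx$assembly$chains, fx2$assembly$chains)
  expect_identical(fx$truth, fx2$truth)
  # different seeds give different sequences
  expect_false(identical(fx$assembly$chains$sequence[1],
                         make_fixture(seed = 124)$assembly$chains$sequence[1]))
})

test_that("noiseless simulation emits peaks exactly at theoretical MH+", {
  fx <- make_fixture(seed = 2)
  truth <- fx$truth$peptides
  pk <- simulate_peaklist(truth, mass_sigma = 0, isotope_pick_prob = 0,
                          dropout_prob = 0, contaminant_rate = 0, seed = 1)
  expect_equal(sort(pk$observed), sort(truth$mh_plus), tolerance = 1e-12)
  # total dropout gives an empty list
  pk0 <- simulate_peaklist(truth, dropout_prob = 1, seed = 1)
  expect_equal(nrow(pk0), 0L)
  # determinism under seed
  a <- simulate_peaklist(truth, mass_sigma = 0.2, contaminant_rate = 5, seed = 99)
  b <- simulate_peaklist(truth, mass_sigma = 0.2, contaminant_rate = 5, seed = 99)
  expect_identical(a, b)
})

test_that("parameter recovery: >=95% of species assigned at sigma 0.2, tol 0.5", {
  fx <- make_fixture(seed = 10)
  truth <- fx$truth$peptides
  rates <- vapply(1:20, function(r) {
    pk <- simulate_peaklist(truth, mass_sigma = 0.2, isotope_pick_prob = 0,
                            dropout_prob = 0, contaminant_rate = 0, seed = 1000 + r)
    m <- match_peaks(pk, truth, tol_da = 0.5)
    # recovered: the peak's assigned mass is its generating species' mass
    ok <- m$matched &
      abs(truth$mh_plus[pk$species] - m$mh_plus) < 1e-9
    mean(ok)
  }, numeric(1))
  expect_gte(mean(rates), 0.95)
})

test_that("the PNGase F time course shows the acidic shift and homogenization", {
  fx <- make_fixture(seed = 3)
  tc <- simulate_pngasef_timecourse(fx, hours = c(0, 7, 48, 168))
  s <- attr(tc, "summary")
  expect_true(all(diff(s$mean_pi) < 0))                 # strictly acid-ward
  expect_gt(s$n_major_species[s$hours == 0], 3)         # heterogeneous untreated
  expect_equal(s$n_major_species[s$hours == 168], 1L)   # collapsed at long times
  expect_equal(s$fraction_deglycosylated[1], 0)
  # the terminal species is the fully deamidated one with the lowest pI
  last <- tc[tc$hours == 168, ]
  expect_equal(last$n_released[which.max(last$weight)],
               2L * sum(fx$sequons$chain_id == "A"))
  # doubling the rate increases the deglycosylated fraction at fixed t
  s2 <- attr(simulate_pngasef_timecourse(fx, hours = 7, rate = 0.2), "summary")
  expect_gt(s2$fraction_deglycosylated, s$fraction_deglycosylated[s$hours == 7])
})
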