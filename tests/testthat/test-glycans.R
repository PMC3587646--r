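# Glycan composition arithmetic, 2-AA labeling, glycopeptide masses,
# lattice search, per-site assignment.

test_that("composition masses agree with the atomic-composition oracle", {
  core <- glycan_composition(0, 0, 0, 0, core = TRUE)
  expect_equal(composition_mass(core), oracle_glycan_mass(), tolerance = 1e-5)
  expect_equal(composition_mass(core), 910.32776, tolerance = 1e-4)
  empty <- glycan_composition(0, 0, 0, 0, core = FALSE)
  expect_equal(composition_mass(empty), 18.010565, tolerance = 1e-6)
  # the fully decorated disialylated core-fucosylated biantennary glycan
  big <- glycan_composition(2, 2, 1, 2)
  expect_equal(composition_mass(big),
               oracle_glycan_mass(2, 2, 1, 2), tolerance = 1e-5)
  expect_error(glycan_composition(-1, 0, 0, 0), ">= 0")
})

test_that("composition mass is linear in counts", {
  a <- glycan_composition(1, 2, 0, 1, core = FALSE)
  b <- glycan_composition(3, 0, 1, 1, core = FALSE)
  ab <- glycan_composition(4, 2, 1, 2, core = FALSE)
  water <- 18.010565
  expect_equal(composition_mass(ab) - water,
               (composition_mass(a) - water) + (composition_mass(b) - water),
               tolerance = 1e-9)
})

test_that("2-AA labeling adds one constant, once", {
  comps <- glycan_library()
  lab <- label_2aa(comps)
  delta <- composition_mass(lab) - composition_mass(comps)
  expect_true(all(abs(delta - delta[1]) < 1e-12))   # same constant everywhere
  expect_gt(delta[1], 0)
  expect_equal(composition_mass(label_2aa(glycan_composition(0, 0, 0, 0))),
               oracle_glycan_mass(label_2aa = TRUE), tolerance = 1e-5)
  expect_error(label_2aa(lab), "already")
})

test_that("glycan notation round-trips through the parser", {
  lib <- glycan_library()
  reparsed <- parse_glycan(lib$composition)
  expect_equal(reparsed[c("hex", "hexnac", "deoxyhexose", "neuac", "core")],
               lib[c("hex", "hexnac", "deoxyhexose", "neuac", "core")])
  # the field's compact notation with no spaces parses too
  p <- parse_glycan("(Hex)2(HexNAc)2(Deoxyhexose)1(NeuAc)2+(Man)3(GlcNAc)2")
  expect_equal(unlist(p[c("hex", "hexnac", "deoxyhexose", "neuac")]),
               c(hex = 2L, hexnac = 2L, deoxyhexose = 1L, neuac = 2L))
  expect_true(p$core)
})

test_that("glycopeptide mass = peptide + glycan residue mass, with guards", {
  comp <- glycan_composition(0, 2, 0, 0)      # truncated Fc glycoform
  gm <- glycopeptide_mass("EEQYNSTYR", comp)
  expect_equal(gm, oracle_peptide_mass("EEQYNSTYR") +
                 oracle_glycan_mass(0, 2, 0, 0) - 18.010565, tolerance = 1e-5)
  # attaching the empty no-core glycan changes nothing
  expect_equal(glycopeptide_mass("EEQYNSTYR", glycan_composition(0, 0, 0, 0, core = FALSE)),
               peptide_mass("EEQYNSTYR"), tolerance = 1e-9)
  # the glycan increment is peptide-independent
  d1 <- glycopeptide_mass("NSTFVR", comp) - peptide_mass("NSTFVR")
  d2 <- glycopeptide_mass("EEQYNSTYR", comp) - peptide_mass("EEQYNSTYR")
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_error(glycopeptide_mass("GAGAK", comp), "sequon")
  expect_error(glycopeptide_mass("EEQYNSTYR", label_2aa(comp)), "unlabelled")
})

test_that("glycopeptide and deamidated-peptide masses are mutually consistent", {
  # (glycopeptide) - (deglycosylated deamidated peptide) = glycan residue
  # mass - deamidation delta, for every composition and sequon peptide
  lib <- glycan_library()
  for (pep in c("NSTFVR", "EEQYNSTYR", "VTSPNITVTLK")) {
    glyco <- glycopeptide_mass(rep(pep, nrow(lib)), lib)
    deam <- peptide_mass(pep, "deamidation")
    expect_equal(glyco - deam,
                 (composition_mass(lib) - 18.010565) - 0.98402,
                 tolerance = 1e-9, label = pep)
  }
})

test_that("composition_search round-trips every library composition rank-1", {
  lib <- glycan_library()
  for (i in seq_len(nrow(lib))) {
    hits <- composition_search(composition_mass(lib[i, ]), tol_da = 0.01)
    expect_gte(nrow(hits), 1L)
    expect_equal(hits[1, c("hex", "hexnac", "deoxyhexose", "neuac")],
                 lib[i, c("hex", "hexnac", "deoxyhexose", "neuac")],
                 ignore_attr = TRUE)
    expect_lt(abs(hits$error_da[1]), 0.01)
  }
  # zero tolerance on a non-matching mass returns nothing
  expect_equal(nrow(composition_search(1234.5678, tol_da = 1e-9)), 0L)
  # near-degenerate compositions within tol are all reported, deterministically
  m <- composition_mass(glycan_composition(2, 2, 0, 1))
  wide <- composition_search(m, tol_da = 30)
  expect_gt(nrow(wide), 1L)
  expect_equal(wide, composition_search(m, tol_da = 30))  # deterministic order
  expect_true(all(diff(abs(wide$error_da)) >= -1e-12))    # sorted by |error|
})

test_that("per-site glycoform assignment recovers the fixture truth table", {
  fx <- make_fixture(seed = 8)
  truth <- fx$truth$glycopeptides
  groups <- tibble::tibble(site = truth$site, peptide = truth$peptide,
                           observed = truth$theoretical_mh,
                           intensity = truth$intensity)
  got <- assign_site_glycoforms(groups, tol_da = 0.5)
  expect_equal(nrow(got), nrow(truth))                       # all 21 recovered
  expect_equal(length(unique(got$site)),
               sum(fx$sequons$chain_id == "A"))              # one table per site
  key <- function(df) paste(df$site, df$hex, df$hexnac, df$deoxyhexose, df$neuac)
  expect_setequal(key(got), key(truth))
  # intensity ranking reproduces the truth ranks
  ranks <- got |> dplyr::arrange(site, rank)
  tru <- truth |> dplyr::arrange(site, rank)
  expect_equal(ranks$neuac, tru$neuac)
  # an empty group yields an empty table; sequon-free peptides are rejected
  expect_equal(nrow(assign_site_glycoforms(groups[0, ])), 0L)
  expect_error(assign_site_glycoforms(tibble::tibble(site = 1, peptide = "GAGAK",
                                                     observed = 1000)),
               "sequon-free")
})
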