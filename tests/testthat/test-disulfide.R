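# Disulfide-linked species construction, exhaustive pairing enumeration,
# scrambling detection.

test_that("assembly validation enforces cysteine endpoints and single bonding", {
  chains <- c(A = "ACKGCR", B = "ACKGCR")
  ok <- dimer_assembly(chains, tibble::tibble(chain_a = "A", pos_a = 2,
                                              chain_b = "B", pos_b = 2))
  expect_s3_class(ok, "dimer_assembly")
  expect_error(dimer_assembly(chains, tibble::tibble(chain_a = "A", pos_a = 1,
                                                     chain_b = "B", pos_b = 2)),
               "not cysteine")
  expect_error(dimer_assembly(chains, tibble::tibble(chain_a = c("A", "A"),
                                                     pos_a = c(2, 2),
                                                     chain_b = c("B", "B"),
                                                     pos_b = c(2, 5))),
               "more than one bond")
})

test_that("non-reduced digest retains global cysteine coordinates", {
  fx <- make_fixture(seed = 5)
  pool <- nonreduced_digest(fx$assembly, missed_cleavages = 0)
  # conservation: cysteines in the pool equal cysteines in the chains
  n_pool <- sum(lengths(pool$cys_positions))
  n_chain <- sum(stringr::str_count(fx$assembly$chains$sequence, "C"))
  expect_equal(n_pool, n_chain)
  # every recorded position is a C in its chain
  for (i in which(lengths(pool$cys_positions) > 0)) {
    s <- fx$assembly$chains$sequence[match(pool$chain_id[i], fx$assembly$chains$chain_id)]
    expect_true(all(substring(s, pool$cys_positions[[i]],
                              pool$cys_positions[[i]]) == "C"))
  }
  # a chain without cysteines yields no linkable peptides
  a2 <- dimer_assembly(c(A = "GGKAAR", B = "GGKAAR"),
                       tibble::tibble(chain_a = character(), pos_a = integer(),
                                      chain_b = character(), pos_b = integer()))
  p2 <- nonreduced_digest(a2)
  expect_equal(sum(lengths(p2$cys_positions)), 0L)
})

test_that("linked-species masses follow the -2H-per-bond rule (oracle checked)", {
  chains <- c(A = "ACKGGCTR", B = "ACKGGCTR")
  bonds <- tibble::tibble(chain_a = "A", pos_a = 2, chain_b = "A", pos_b = 6)
  assembly <- dimer_assembly(chains, bonds)
  pool <- nonreduced_digest(assembly, missed_cleavages = 0)
  sp <- build_linked_species(pool, bonds)
  expect_equal(nrow(sp), 1L)
  expect_equal(sort(sp$members[[1]]), c("ACK", "GGCTR"))
  expect_equal(sp$mono_mass,
               oracle_disulfide_mass(c(oracle_peptide_mass("ACK"),
                                       oracle_peptide_mass("GGCTR")), 1),
               tolerance = 1e-5)
  # two identical peptides joined by two bonds: 2M - 2 x 2.01565
  chains2 <- c(A = "GGKTCPPCPAK", B = "GGKTCPPCPAK")
  bonds2 <- tibble::tibble(chain_a = c("A", "A"), pos_a = c(5, 8),
                           chain_b = c("B", "B"), pos_b = c(5, 8))
  a2 <- dimer_assembly(chains2, bonds2)
  sp2 <- build_linked_species(nonreduced_digest(a2, missed_cleavages = 0), bonds2)
  expect_equal(nrow(sp2), 1L)
  expect_equal(sp2$bond_count, 2L)
  expect_equal(sp2$n_members, 2L)
  expect_equal(sp2$mono_mass,
               2 * oracle_peptide_mass("TCPPCPAK") - 2 * 2.015650,
               tolerance = 1e-5)
  # bond endpoint outside the pool is rejected by name
  expect_error(build_linked_species(nonreduced_digest(a2, missed_cleavages = 0),
                                    tibble::tibble(chain_a = "Z", pos_a = 5,
                                                   chain_b = "B", pos_b = 5)),
               "bond")
})

test_that("the homodimer fixture yields exactly five species, one with two bonds", {
  fx <- make_fixture(seed = 1)
  sp <- fx$truth$disulfides
  expect_equal(nrow(sp), 5L)
  expect_equal(sum(sp$bond_count == 2), 1L)        # the hinge homo-di-peptide
  expect_equal(sp$n_members[sp$bond_count == 2], 2L)
  expect_true(all(sp$n_members == 2))
  # relabelling the chains leaves the species multiset invariant
  swapped <- fx$assembly
  swapped$chains$chain_id <- rev(swapped$chains$chain_id)
  pool_sw <- nonreduced_digest(dimer_assembly(swapped$chains, fx$assembly$bonds),
                               missed_cleavages = 0)
  sp_sw <- build_linked_species(pool_sw, fx$assembly$bonds)
  expect_equal(sort(sp_sw$mono_mass), sort(sp$mono_mass), tolerance = 1e-9)
})

test_that("hypothetical pair enumeration has C(k,2)+k members and contains the topology", {
  fx <- make_fixture(seed = 1)
  pool <- nonreduced_digest(fx$assembly, missed_cleavages = 0)
  hyp <- enumerate_hypothetical_pairs(pool)
  k <- length(unique(unlist(
    pool$sequence[pool$missed_cleavages == 0 & lengths(pool$cys_positions) > 0])))
  expect_equal(sum(hyp$bond_count == 1), choose(k, 2) + k)
  # expected topology masses are a subset of the enumeration
  expected <- fx$truth$disulfides
  for (m in expected$mono_mass) {
    expect_true(any(abs(hyp$mono_mass - m) < 1e-9))
  }
  # a single cys-peptide gives exactly its self-pair
  one <- nonreduced_digest(dimer_assembly(c(A = "ACKGGR", B = "ACKGGR"),
                                          tibble::tibble(chain_a = "A", pos_a = 2,
                                                         chain_b = "B", pos_b = 2)),
                           missed_cleavages = 0)
  h1 <- enumerate_hypothetical_pairs(one)
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$mono_mass, 2 * oracle_peptide_mass("ACK") - 2.015650,
               tolerance = 1e-5)
})

test_that("scrambling detection separates native from non-native pairings", {
  fx <- make_fixture(seed = 1)
  pool <- nonreduced_digest(fx$assembly, missed_cleavages = 0)
  expected <- fx$truth$disulfides
  hyp <- enumerate_hypothetical_pairs(pool)

  # noiseless native peaks: everything matched, zero scrambling
  peaks <- tibble::tibble(observed = expected$mh_plus)
  rep1 <- detect_mispairing(peaks, expected, hyp, tol_da = 0.5)
  expect_true(all(rep1$expected$matched))
  expect_equal(nrow(rep1$scrambling), 0L)

  # inject one non-native pair mass: exactly one scrambling hit naming it
  nonnative <- hyp[!vapply(hyp$mono_mass,
                           function(m) any(abs(m - expected$mono_mass) < 1e-6),
                           logical(1)), ]
  peaks2 <- dplyr::bind_rows(peaks, tibble::tibble(observed = nonnative$mh_plus[1]))
  rep2 <- detect_mispairing(peaks2, expected, hyp, tol_da = 0.2)
  expect_gte(nrow(rep2$scrambling), 1L)
  expect_true(any(abs(rep2$scrambling$error_da) < 1e-9))
  hit <- rep2$scrambling[which.min(abs(rep2$scrambling$error_da)), ]
  expect_equal(c(hit$seq_a, hit$seq_b),
               c(nonnative$seq_a[1], nonnative$seq_b[1]))

  # empty peak list: nothing matched
  rep3 <- detect_mispairing(peaks[0, ], expected, hyp)
  expect_false(any(rep3$expected$matched))
})
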