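# Data model: free-energy aggregation, rank preference, balance validation,
# parameter assembly.

test_that("hps_total sums the five free-energy components", {
  expect_equal(hps_total(c(E_elec = -500, dG_vib = 10, dG_rot = 5,
                           dG_trans = 3, dG_solv = -8)), -490)
  expect_equal(hps_total(c(E_elec = 0, dG_vib = 0, dG_rot = 0,
                           dG_trans = 0, dG_solv = 0)), 0)
  # order of the components is irrelevant
  expect_equal(hps_total(c(dG_solv = -8, dG_trans = 3, E_elec = -500,
                           dG_rot = 5, dG_vib = 10)), -490)
  expect_error(hps_total(c(E_elec = NaN, dG_vib = 0, dG_rot = 0,
                           dG_trans = 0, dG_solv = 0)), "non-finite")
  expect_error(hps_total(c(E_elec = 1, dG_vib = 2)), "missing")
})

test_that("species free energy is the minimum at the highest available rank", {
  one <- rn_species("x", c(C = 1), structures = list(
    structure_energy("s1", 1L, E_elec = -100)))
  expect_equal(as.numeric(species_free_energy(one)), -100)

  two <- rn_species("x", c(C = 1), structures = list(
    structure_energy("s1", 1L, E_elec = -100),
    structure_energy("s2", 1L, E_elec = -105)))
  expect_equal(as.numeric(species_free_energy(two)), -105)

  # the higher rank wins even when a lower-rank structure lies lower
  mixed <- rn_species("x", c(C = 1), structures = list(
    structure_energy("s1", 1L, E_elec = -110),
    structure_energy("s2", 2L, E_elec = -100)))
  g <- species_free_energy(mixed)
  expect_equal(as.numeric(g), -100)
  expect_equal(attr(g, "rank"), 2L)

  none <- rn_species("ghost", c(C = 1))
  expect_error(species_free_energy(none), "ghost")
})

test_that("rank preference is monotone under added higher-rank structures", {
  sp <- rn_species("x", c(C = 1), structures = list(
    structure_energy("s1", 1L, E_elec = -50)))
  r0 <- attr(species_free_energy(sp), "rank")
  sp$structures <- c(sp$structures,
                     list(structure_energy("s2", 2L, E_elec = -10)))
  expect_gte(attr(species_free_energy(sp), "rank"), r0)
})

test_that("activation free energies follow the TS-minimum and barrierless rules", {
  rx <- rn_reaction("R", c(A = 1L), c(B = 1L), ts_structures = list(
    structure_energy("t1", 1L, E_elec = -80),
    structure_energy("t2", 1L, E_elec = -75)))
  act <- activation_free_energy(rx, G_lhs = -120, G_rhs = -110)
  expect_equal(act$dG_fwd, 40)
  expect_equal(act$dG_bwd, act$dG_fwd - (-110 - -120))

  bl <- rn_reaction("R", c(A = 1L), c(B = 1L))
  up <- activation_free_energy(bl, G_lhs = -100, G_rhs = -90)
  expect_equal(up$dG_fwd, 10)
  expect_equal(up$dG_bwd, 0)
  down <- activation_free_energy(bl, G_lhs = -90, G_rhs = -100)
  expect_equal(down$dG_fwd, 0)
  expect_equal(down$dG_bwd, 10)
})

test_that("backward barriers of barrierless reactions are never negative", {
  bl <- rn_reaction("R", c(A = 1L), c(B = 1L))
  for (dg in seq(-50, 50, by = 10)) {
    act <- activation_free_energy(bl, G_lhs = 0, G_rhs = dg)
    expect_gte(act$dG_bwd, 0)
    expect_equal(act$dG_bwd, act$dG_fwd - dg)
  }
})

test_that("network validation rejects unbalanced and inconsistent reactions", {
  a <- rn_species("a", c(C = 2, H = 6), structures = st1("a", 0))
  b <- rn_species("b", c(C = 2, H = 4), structures = st1("b", 0))
  expect_error(
    rn_network(list(a, b), list(
      rn_reaction("bad", c(a = 1L), c(b = 1L),
                  ts_structures = ts1("bad", 50)))),
    "bad.*not elementally balanced")
  cat1 <- rn_species("cat1", c(C = 1, H = 3), charge = 1L,
                     structures = st1("cat1", 0))
  neu <- rn_species("neu", c(C = 1, H = 3), structures = st1("neu", 0))
  expect_error(
    rn_network(list(cat1, neu), list(
      rn_reaction("chg", c(cat1 = 1L), c(neu = 1L),
                  ts_structures = ts1("chg", 50)))),
    "charge")
  expect_error(rn_network(list(), list()), "no species")
  expect_error(rn_reaction("r", c(a = 1L), c(b = 1L),
                           ts_structures = list(), barrierless = FALSE),
               "inconsistent")
})

test_that("assembled parameters carry rank-based uncertainties", {
  net <- chain3_network()
  # chain3 has rank-2 species and rank-3 TS (delta_pno = 0)
  p <- assemble_parameters(net)
  expect_equal(nrow(p), length(net$species) + length(net$reactions))
  expect_equal(unname(p[p$kind == "G", "u"]), rep(5, 3))
  expect_equal(unname(p[p$kind == "dGa", "u"]), rep(5, 2))  # PNO floor

  # rank-1 entries get 10 / 15
  net1 <- rn_network(
    list(rn_species("A", c(C = 1), c0 = 1, structures = st1("A", 0, 1L)),
         rn_species("B", c(C = 1), structures = st1("B", -5, 1L))),
    list(rn_reaction("R", c(A = 1L), c(B = 1L),
                     ts_structures = ts1("R", 40, 1L))))
  p1 <- assemble_parameters(net1)
  expect_equal(p1["G:A", "u"], 10)
  expect_equal(p1["dGa:R", "u"], 15)

  # rank-3 barrier uncertainty resolves through the PNO rule
  net3 <- rn_network(
    list(rn_species("A", c(C = 1), c0 = 1, structures = st1("A", 0)),
         rn_species("B", c(C = 1), structures = st1("B", -5))),
    list(rn_reaction("R", c(A = 1L), c(B = 1L),
                     ts_structures = ts1("R", 40), delta_pno = 8)))
  expect_equal(assemble_parameters(net3)["dGa:R", "u"], 8)
})

test_that("the PNO uncertainty rule floors at 5 kJ/mol", {
  expect_equal(pno_uncertainty(3), 5)
  expect_equal(pno_uncertainty(8), 8)
  expect_equal(pno_uncertainty(5), 5)
  expect_error(pno_uncertainty(-1), "non-negative")
})

test_that("barrierless parameter entries are derived and re-derived on clamp", {
  net <- rn_network(
    list(rn_species("A", c(C = 1), c0 = 1, structures = st1("A", 0)),
         rn_species("B", c(C = 1), structures = st1("B", 12))),
    list(rn_reaction("R", c(A = 1L), c(B = 1L))))
  p <- assemble_parameters(net)
  expect_equal(p["dGa:R", "value"], 12)  # endergonic: barrier = dG_r
  expect_equal(p["dGa:R", "u"], 0)
  # lowering the product below the reactant re-derives the barrier to zero
  p$value[p$id == "G:B"] <- -8
  p2 <- clamp_parameters(net, p)
  expect_equal(p2["dGa:R", "value"], 0)
})
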