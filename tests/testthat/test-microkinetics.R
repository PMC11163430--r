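# Rate constants, ODE integration, fluxes.

test_that("Eyring rate constants are exact at zero barrier and verified at 100 kJ/mol", {
  for (T in c(298.15, 423.15)) {
    expect_equal(eyring_rate(0, T), KBOLTZ * T / HPLANCK)
  }
  # direct one-line evaluation of the rate expression
  T <- 423.15
  expect_equal(eyring_rate(100, T),
               KBOLTZ * T / HPLANCK * exp(-1e5 / (RGAS * T)),
               tolerance = 1e-12)
  # strict monotone decrease in the barrier
  ks <- eyring_rate(seq(0, 200, by = 5), 350)
  expect_true(all(diff(ks) < 0))
  expect_error(eyring_rate(-3, 300), "clamp")
  expect_error(eyring_rate(10, -1), "positive")
})

test_that("equilibrium constants invert free-energy differences", {
  T <- 310
  expect_equal(equilibrium_constant(-50, -50, T), 1)
  # closed-form inversion: dG_r = -RT ln 2 gives K = 2
  dg <- -(RGAS * T / 1000) * log(2)
  expect_equal(equilibrium_constant(0, dg, T), 2, tolerance = 1e-12)
  # antisymmetry
  expect_equal(equilibrium_constant(-10, 25, T) *
                 equilibrium_constant(25, -10, T), 1, tolerance = 1e-12)
})

test_that("mass-action rates follow the stoichiometric power law", {
  rx <- rn_reaction("R", c(A = 2L), c(B = 1L),
                    ts_structures = ts1("R", 50), delta_pno = 0)
  r <- reaction_rates(c(A = 0.5, B = 0.2), rx, k_plus = 4, k_minus = 1)
  expect_equal(r$f_plus, 4 * 0.5^2)
  expect_equal(r$f_minus, 1 * 0.2)
  r0 <- reaction_rates(c(A = 0, B = 0.2), rx, 4, 1)
  expect_equal(r0$f_plus, 0)
  expect_true(r0$f_minus >= 0 && r$f_plus >= 0)
  expect_error(reaction_rates(c(A = -1, B = 0), rx, 4, 1), "negative")
})

test_that("a network without reactions stays at its initial concentrations", {
  net <- rn_network(
    list(rn_species("A", c(C = 1), c0 = 0.3, structures = st1("A", 0))),
    list())
  sim <- simulate_network(net, assemble_parameters(net),
                          simulation_settings(T = 300, t_max = 10))
  expect_true(all(sim$c["A", ] == 0.3))
  expect_equal(sim$c_flux[["A"]], 0)
})

test_that("reversible first-order kinetics matches the closed form", {
  net <- ab_network(k = 1, T = 298.15)
  p <- assemble_parameters(net)
  s <- simulation_settings(T = 298.15, t_max = 5, times = c(0.5, 1, 5))
  sim <- simulate_network(net, p, s)
  exact <- function(t) 0.5 * (1 + exp(-2 * t))
  for (t in c(0.5, 1, 5)) {
    i <- which(sim$times == t)
    expect_equal(unname(sim$c["A", i]), exact(t), tolerance = 1e-6)
    expect_equal(unname(sim$c["B", i]), 1 - exact(t), tolerance = 1e-6)
  }
})

test_that("long-time concentration ratios reach the equilibrium constant", {
  T <- 298.15
  net <- ab_network(k = 1, T = T, dG_r = -(RGAS * T / 1000) * log(3))
  p <- assemble_parameters(net)
  sim <- simulate_network(net, p, simulation_settings(T = T, t_max = 200))
  K <- sim$rates_meta$K[["R1"]]
  expect_equal(K, 3, tolerance = 1e-12)
  nt <- length(sim$times)
  expect_equal(unname(sim$c["B", nt] / sim$c["A", nt]), K, tolerance = 1e-6)
})

test_that("detailed balance holds exactly as constructed", {
  net <- chain3_network()
  p <- assemble_parameters(net)
  sim <- simulate_network(net, p, simulation_settings(T = 400, t_max = 10))
  rm <- sim$rates_meta
  expect_equal(rm$k_plus / rm$k_minus, rm$K, tolerance = 1e-14)
})

test_that("elements are conserved along trajectories", {
  gen <- generate_network(9, 9, seed = 11, path_barriers = c(60, 70),
                          side_barriers = c(75, 95))
  net <- gen$net
  p <- assemble_parameters(net)
  sim <- simulate_network(net, p, simulation_settings(T = 320, t_max = 50))
  comp <- sapply(net$species, function(sp) {
    v <- c(C = 0, H = 0, O = 0)
    v[names(sp$composition)] <- sp$composition
    v
  })
  totals <- comp %*% sim$c  # element x time
  for (el in rownames(totals))
    expect_equal(max(abs(totals[el, ] - totals[el, 1])), 0,
                 tolerance = 1e-6)
})

test_that("integration agrees with an independent fixed-step RK4 oracle", {
  net <- chain3_network(bAB = 78, bBC = 82)
  p <- assemble_parameters(net)
  T <- 330; t_max <- 40
  sim <- simulate_network(net, p, simulation_settings(T = T, t_max = t_max))
  ref <- rk4_simulate(net, p, T, t_max, n_steps = 40000)
  nt <- length(sim$times)
  for (sp in c("A", "B", "C"))
    expect_equal(unname(sim$c[sp, nt]), ref$c_final[[sp]], tolerance = 1e-4)
})

test_that("flux integrals capture total conversion of an irreversible step", {
  # A -> B driven hard downhill: F equals the converted amount (1 mol/L)
  T <- 298.15
  net <- ab_network(k = 0.5, T = T, dG_r = -80)
  p <- assemble_parameters(net)
  sim <- simulate_network(net, p, simulation_settings(T = T, t_max = 60))
  expect_equal(sim$F[["R1"]], 1, tolerance = 1e-3)
  expect_equal(sim$c_flux[["A"]], sim$F[["R1"]])
  expect_equal(sim$c_flux[["B"]], sim$F[["R1"]])
})

test_that("flux keeps growing for a mixture held at equilibrium", {
  T <- 298.15
  net <- ab_network(k = 1, T = T, cA0 = 0.5, cB0 = 0.5)
  p <- assemble_parameters(net)
  F_at <- vapply(c(5, 10, 20), function(tm) {
    simulate_network(net, p,
                     simulation_settings(T = T, t_max = tm))$F[["R1"]]
  }, 0)
  expect_true(all(diff(F_at) > 0))
})

test_that("c_max bounds c_flux for species starting at zero concentration", {
  gen <- generate_network(8, 8, seed = 4, path_barriers = c(60, 70),
                          side_barriers = c(70, 90))
  p <- assemble_parameters(gen$net)
  sim <- simulate_network(gen$net, p,
                          simulation_settings(T = 320, t_max = 100))
  for (sp in names(gen$net$species)) {
    expect_gte(sim$c_max[[sp]], sim$c[sp, 1])
    if (gen$net$species[[sp]]$c0 == 0)
      expect_gte(sim$c_flux[[sp]] + 1e-9, sim$c_max[[sp]])
  }
})

test_that("trajectory and flux CSV exports round-trip their values", {
  net <- ab_network()
  p <- assemble_parameters(net)
  sim <- simulate_network(net, p, simulation_settings(T = 298.15, t_max = 2))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trajectories_csv(sim, f1)
  traj <- utils::read.csv(f1, check.names = FALSE)
  expect_equal(names(traj), c("time_s", "A", "B"))
  expect_equal(traj$A, unname(sim$c["A", ]))
  write_flux_report_csv(sim, f2)
  rep <- utils::read.csv(f2)
  expect_equal(rep$F[rep$kind == "reaction"], unname(sim$F))
  unlink(c(f1, f2))
})
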