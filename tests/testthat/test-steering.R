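# Exploration steering: target selection, refinement selection, rank
# upgrades, and the rolling loop.

mk_sim_stub <- function(c_max, c_flux) {
  structure(list(c_max = c_max, c_flux = c_flux), class = "rn_sim")
}

mk_morris_stub <- function(cmax_mean, cmax_sd, cflux_mean, cflux_sd) {
  structure(list(
    cmax_stats = data.frame(id = names(cmax_mean), mean = cmax_mean,
                            sd = cmax_sd),
    cflux_stats = data.frame(id = names(cflux_mean), mean = cflux_mean,
                             sd = cflux_sd)), class = "rn_morris")
}

test_that("classic criteria select high-flux species and high-c_max pairs", {
  cfg <- steering_config("classic", "oat")
  expect_equal(cfg$tau_flux, 1e-2)
  expect_equal(cfg$tau_max, 1e-3)
  sim <- mk_sim_stub(c_max = c(a = 0.04, b = 0.04, c = 1e-4),
                     c_flux = c(a = 2e-2, b = 5e-3, c = 0))
  sel <- select_exploration_targets(sim, cfg)
  expect_equal(as.character(sel$unimolecular), "a")
  # 0.04 * 0.04 = 1.6e-3 > 1e-3: pairs among {a, b} incl. self-pairs
  keys <- paste(sel$bimolecular$a, sel$bimolecular$b)
  expect_setequal(keys, c("a a", "a b", "b b"))
})

test_that("uncertainty-aware criteria add one standard deviation", {
  cfg <- steering_config("uncertainty_aware")
  expect_equal(cfg$tau_flux, 1e-1)
  expect_equal(cfg$tau_max, 1e-2)
  st <- mk_morris_stub(cmax_mean = c(a = 0.09, b = 0.02),
                       cmax_sd = c(a = 0.02, b = 0),
                       cflux_mean = c(a = 8e-2, b = 1e-3),
                       cflux_sd = c(a = 3e-2, b = 0))
  sel <- select_exploration_targets(st, cfg)
  # mean + sd = 0.11 > 0.1 selects a
  expect_equal(as.character(sel$unimolecular), "a")
  # (0.09 + 0.02)^2 = 0.0121 > 1e-2 selects only the (a, a) self-pair
  expect_equal(nrow(sel$bimolecular), 1L)
  expect_equal(sel$bimolecular$a, "a")

  # with zero spread the criteria reduce exactly to the classic rule
  cfg0 <- steering_config("classic", "morris", tau_flux = 1e-1,
                          tau_max = 1e-2)
  st0 <- mk_morris_stub(cmax_mean = c(a = 0.09, b = 0.02),
                        cmax_sd = c(a = 0, b = 0),
                        cflux_mean = c(a = 8e-2, b = 1e-3),
                        cflux_sd = c(a = 0, b = 0))
  sim0 <- mk_sim_stub(c_max = c(a = 0.09, b = 0.02),
                      c_flux = c(a = 8e-2, b = 1e-3))
  ua <- select_exploration_targets(st0, steering_config("uncertainty_aware"))
  cl <- select_exploration_targets(sim0, cfg0)
  expect_identical(as.character(ua$unimolecular),
                   as.character(cl$unimolecular))
  expect_identical(ua$bimolecular[, c("a", "b")],
                   cl$bimolecular[, c("a", "b")])
  # uncertainty-aware selection refuses plain simulation results
  expect_error(select_exploration_targets(sim0,
                                          steering_config("uncertainty_aware")),
               "Morris")
})

test_that("refinement selection applies thresholds and top-rank exclusion", {
  net <- rn_network(
    list(rn_species("A", c(C = 1), c0 = 1, structures = st1("A", 0, 1L)),
         rn_species("B", c(C = 1), structures = st1("B", -5, 1L))),
    list(rn_reaction("R", c(A = 1L), c(B = 1L),
                     ts_structures = ts1("R", 40, 1L))))
  p <- assemble_parameters(net)
  cfg <- steering_config("classic", "oat")
  oat <- structure(list(report = data.frame(
    id = p$id, kind = p$kind, target = p$target,
    delta_cmax = c(2e-2, 5e-3, 2e-2),
    screened = TRUE, failed = FALSE)), class = "rn_oat")
  expect_setequal(select_refinement(oat, p, cfg), c("G:A", "dGa:R"))

  # Morris route: mu*max per grid step against tau_ref
  mor <- structure(list(
    mu_star_max = c("G:A" = 6e-3, "G:B" = 1e-3, "dGa:R" = 4e-3),
    step_kj = c("G:A" = 10, "G:B" = 10, "dGa:R" = 10)),
    class = "rn_morris")
  cfgm <- steering_config("uncertainty_aware", tau_ref = 5e-2)
  expect_equal(select_refinement(mor, p, cfgm), "G:A")  # 6e-2 > 5e-2

  # parameters already at their top rank are excluded with a warning
  p_top <- p; p_top$rank <- c(2L, 2L, 3L)
  expect_warning(out <- select_refinement(oat, p_top, cfg), "top rank")
  expect_length(out, 0)
})

test_that("refinement upgrades ranks through the oracle and records refusals", {
  gen <- generate_network(8, 8, seed = 2)
  orc <- synthetic_oracle(gen, seed = 2)
  net1 <- noisy_network(gen$net, rank = 1L, seed = 2)
  p1 <- assemble_parameters(net1)
  expect_true(all(p1$rank[p1$kind == "G"] == 1L))
  upd <- apply_refinement(net1, c("G:P1", "dGa:Rassoc", "G:nonexistent"),
                          orc)
  expect_setequal(upd$refined, c("G:P1", "dGa:Rassoc"))
  expect_equal(upd$refused, "G:nonexistent")
  p2 <- assemble_parameters(upd$net)
  expect_equal(p2["G:P1", "rank"], 2L)     # species -> rank 2
  expect_equal(p2["G:P1", "u"], 5)
  expect_equal(p2["dGa:Rassoc", "rank"], 3L)  # barriers jump to rank 3
  expect_equal(p2["dGa:Rassoc", "u"], 5)      # PNO floor
  # empty refinement set leaves the network unchanged
  same <- apply_refinement(net1, character(0), orc)
  expect_identical(same$net, net1)
})

test_that("an exact zero-uncertainty oracle explores without refinements", {
  gen <- generate_network(8, 8, seed = 6, path_barriers = c(80, 88),
                          side_barriers = c(95, 110))
  # degenerate fidelity ladder: no rank differences, no uncertainty
  gen$net$ranks <- list(
    fidelity_rank(1L, u_G = 0, u_barrier = 0),
    fidelity_rank(2L, u_G = 0, u_barrier = 0),
    fidelity_rank(3L, u_G = 0, u_barrier = 0))
  zero_err <- list(G = data.frame(rank = 1:3, bias = 0, spread = 0),
                   barrier = data.frame(rank = 1:3, bias = 0, spread = 0))
  orc <- synthetic_oracle(gen, errors = zero_err, seed = 1)
  cfg <- steering_config("classic", "oat", max_iterations = 8L)
  res <- explore_network(orc, cfg,
                         simulation_settings(T = 298.15, t_max = 3600))
  expect_true(res$converged)
  expect_length(res$state$refined_parameters, 0)
  # every rank-1 energy equals the truth
  truth_p <- assemble_parameters(gen$net)
  expl_p <- res$params
  shared <- intersect(truth_p$id, expl_p$id)
  expect_equal(setNames(expl_p[shared, "value"], shared),
               setNames(truth_p[shared, "value"], shared))
  # the explored-species set grows monotonically
  log <- res$state$iteration_log
  expect_true(all(diff(log$n_species) >= 0))
  expect_true(all(diff(log$n_reactions) >= 0))
})

test_that("delta_pno on refined barriers feeds the assembled uncertainty", {
  net <- rn_network(
    list(rn_species("A", c(C = 1), c0 = 1, structures = st1("A", 0)),
         rn_species("B", c(C = 1), structures = st1("B", -10))),
    list(rn_reaction("R", c(A = 1L), c(B = 1L),
                     ts_structures = ts1("R", 60), delta_pno = 7.5)))
  p <- assemble_parameters(net)
  expect_equal(p["dGa:R", "u"], 7.5)
})
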