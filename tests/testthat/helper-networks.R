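# Shared fixtures and independent reference implementations.

RGAS <- 8.314462618     # J mol^-1 K^-1
KBOLTZ <- 1.380649e-23  # J K^-1
HPLANCK <- 6.62607015e-34

# Barrier (kJ/mol) giving rate constant k at temperature T (inverse Eyring).
barrier_for_rate <- function(k, T) {
  (RGAS * T / 1000) * log(KBOLTZ * T / HPLANCK / k)
}

st1 <- function(id, G, rank = 2L)
  list(structure_energy(paste0(id, "_s"), rank, E_elec = G))
ts1 <- function(id, G, rank = 3L)
  list(structure_energy(paste0(id, "_ts"), rank, E_elec = G))

# Reversible isomerization A <-> B with k+ = k- = k at temperature T.
ab_network <- function(k = 1, T = 298.15, cA0 = 1, cB0 = 0, dG_r = 0) {
  dg <- barrier_for_rate(k, T)
  rn_network(
    list(rn_species("A", c(C = 1, H = 2, O = 1), c0 = cA0,
                    structures = st1("A", 0)),
         rn_species("B", c(C = 1, H = 2, O = 1), c0 = cB0,
                    structures = st1("B", dG_r))),
    list(rn_reaction("R1", c(A = 1L), c(B = 1L),
                     ts_structures = ts1("R1", dg), delta_pno = 0)))
}

# Three-isomer chain A -> B -> C with configurable barriers (kJ/mol).
chain3_network <- function(bAB = 80, bBC = 85, GB = -10, GC = -40) {
  rn_network(
    list(rn_species("A", c(C = 2, H = 4, O = 1), c0 = 1,
                    structures = st1("A", 0)),
         rn_species("B", c(C = 2, H = 4, O = 1), structures = st1("B", GB)),
         rn_species("C", c(C = 2, H = 4, O = 1), structures = st1("C", GC))),
    list(rn_reaction("RAB", c(A = 1L), c(B = 1L),
                     ts_structures = ts1("RAB", bAB), delta_pno = 0),
         rn_reaction("RBC", c(B = 1L), c(C = 1L),
                     ts_structures = ts1("RBC", max(GB, GC) + bBC),
                     delta_pno = 0)))
}

# Independent fixed-step RK4 mass-action integrator (reference oracle).
# Rebuilds rates straight from the Eyring formula and the network lists.
rk4_simulate <- function(net, params, T, t_max, n_steps = 20000) {
  G <- setNames(params$value[params$kind == "G"],
                params$target[params$kind == "G"])
  RT <- RGAS * T / 1000
  kp <- numeric(length(net$reactions)); km <- kp
  for (j in seq_along(net$reactions)) {
    rx <- net$reactions[[j]]
    dG_r <- sum(G[names(rx$rhs)] * rx$rhs) - sum(G[names(rx$lhs)] * rx$lhs)
    raw <- params$value[params$id == paste0("dGa:", rx$id)]
    if (rx$barrierless) raw <- 0
    eff <- max(raw, 0, dG_r)
    kp[j] <- KBOLTZ * T / HPLANCK * exp(-eff * 1000 / (RGAS * T))
    km[j] <- KBOLTZ * T / HPLANCK * exp(-(eff - dG_r) * 1000 / (RGAS * T))
  }
  sp <- names(net$species)
  y <- vapply(net$species, `[[`, 0, "c0")
  f <- function(y) {
    dy <- setNames(numeric(length(sp)), sp)
    for (j in seq_along(net$reactions)) {
      rx <- net$reactions[[j]]
      fp <- kp[j] * prod(pmax(y[names(rx$lhs)], 0)^rx$lhs)
      fm <- km[j] * prod(pmax(y[names(rx$rhs)], 0)^rx$rhs)
      for (s in names(rx$lhs)) dy[s] <- dy[s] - rx$lhs[[s]] * (fp - fm)
      for (s in names(rx$rhs)) dy[s] <- dy[s] + rx$rhs[[s]] * (fp - fm)
    }
    dy
  }
  h <- t_max / n_steps
  cmax <- y
  for (i in seq_len(n_steps)) {
    k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    cmax <- pmax(cmax, y)
  }
  list(c_final = y, c_max = cmax)
}

# Independent brute-force OAT: manual bound perturbation + manual clamp,
# naive re-simulation, delta over species and directions.
brute_force_oat <- function(net, params, settings, ids = params$id) {
  base <- simulate_network(net, params, settings)
  manual_clamp <- function(p) {
    G <- setNames(p$value[p$kind == "G"], p$target[p$kind == "G"])
    for (j in seq_along(net$reactions)) {
      rx <- net$reactions[[j]]
      dg_r <- sum(G[names(rx$rhs)] * rx$rhs) - sum(G[names(rx$lhs)] * rx$lhs)
      pid <- paste0("dGa:", rx$id)
      v <- if (rx$barrierless) 0 else p$value[p$id == pid]
      p$value[p$id == pid] <- max(v, 0, dg_r)
    }
    p
  }
  out <- setNames(numeric(length(ids)), ids)
  for (pid in ids) {
    d <- 0
    for (sgn in c(-1, 1)) {
      p2 <- params
      i <- which(p2$id == pid)
      p2$value[i] <- p2$value[i] + sgn * p2$u[i]
      p2 <- manual_clamp(p2)
      sim <- simulate_network(net, p2, settings)
      d <- max(d, max(abs(sim$c_max - base$c_max)))
    }
    out[pid] <- d
  }
  out
}

# Exhaustive simple-path enumeration oracle for find_path(): DFS over the
# species graph, recomputing edge weights independently.
enumerate_paths <- function(net, params, from, to, T = 298.15,
                            compound_costs = NULL, default_cost = 10) {
  G <- setNames(params$value[params$kind == "G"],
                params$target[params$kind == "G"])
  RT <- RGAS * T / 1000
  cost_of <- function(sp) {
    if (!is.null(compound_costs) && sp %in% names(compound_costs))
      compound_costs[[sp]]
    else if (net$species[[sp]]$c0 > 0) 1 else default_cost
  }
  barrier <- function(rx, fwd) {
    dg_r <- sum(G[names(rx$rhs)] * rx$rhs) - sum(G[names(rx$lhs)] * rx$lhs)
    raw <- if (rx$barrierless) 0 else
      params$value[params$id == paste0("dGa:", rx$id)]
    eff <- max(raw, 0, dg_r)
    if (fwd) eff else eff - dg_r
  }
  best <- Inf
  recurse <- function(sp, visited, w) {
    if (w >= best) return()
    if (sp == to) { best <<- w; return() }
    for (rx in net$reactions) {
      for (fwd in c(TRUE, FALSE)) {
        lhs <- if (fwd) rx$lhs else rx$rhs
        rhs <- if (fwd) rx$rhs else rx$lhs
        if (!sp %in% names(lhs)) next
        co <- setdiff(names(lhs), sp)
        w_in <- max(barrier(rx, fwd), 0) / RT +
          sum(vapply(co, function(s) cost_of(s) * lhs[[s]], 0)) +
          cost_of(sp) * (lhs[[sp]] - 1L)
        for (nxt in names(rhs)) {
          if (nxt %in% visited) next
          recurse(nxt, c(visited, nxt), w + w_in)
        }
      }
    }
  }
  recurse(from, from, 0)
  best
}
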