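# Synthetic-data machinery: ground-truth network generator with a planted
# dominant path, multi-rank noisy energy oracle calibrated to cross-rank
# error statistics, network delta statistics, and the hand-coded
# Eschenmoser-Claisen example networks.

#' Default per-rank error models of the synthetic oracle
#'
#' Bias and normal spread (kJ mol^-1) of the rank-r energies relative to
#' the ground truth, for species free energies (`G`) and activation free
#' energies (`barrier`).  The sign convention matches the cross-rank delta
#' statistics (`Delta = reference - approximate`): a positive barrier bias
#' means the rank overestimates barriers.  Defaults are calibrated so the
#' simulated rank-1 barrier errors reproduce mean -4.5 / MAD 15.1 kJ mol^-1
#' and the rank-2 barrier errors mean +9.1 / MAD 10.3 (the spread is solved
#' numerically from the folded-normal expected MAD); rank-1 free-energy
#' errors reproduce mean 12.0 / MAD 15.8.  The top rank is the reference
#' (zero error).
#'
#' @return List with data.frames `G` and `barrier` (columns `rank`, `bias`,
#'   `spread`).
#' @export
rank_error_defaults <- function() {
  list(
    G = data.frame(
      rank = 1:2,
      bias = c(-12.0, 0),
      spread = c(spread_for_mad(-12.0, 15.8), 0)),
    barrier = data.frame(
      rank = 1:3,
      bias = c(4.5, -9.1, 0),
      spread = c(spread_for_mad(4.5, 15.1),
                 spread_for_mad(-9.1, 10.3), 0)))
}

#' Normal spread matching a target mean absolute deviation
#'
#' For `X ~ N(bias, sigma)`, solves `E|X| = mad` for `sigma` (folded-normal
#' mean).  Requires `mad >= |bias|`.
#'
#' @param bias Mean of the error distribution (kJ mol^-1).
#' @param mad Target mean absolute deviation (kJ mol^-1).
#' @return The spread `sigma`.
#' @export
spread_for_mad <- function(bias, mad) {
  b <- abs(bias)
  if (mad < b) stop_kinsteer("target MAD ", mad, " below |bias| ", b)
  if (mad == b) return(0)
  f <- function(s) folded_mean(b, s) - mad
  stats::uniroot(f, lower = 1e-9, upper = 10 * (mad + b),
                 tol = 1e-12)$root
}

# E|X| for X ~ N(m, s).
folded_mean <- function(m, s) {
  if (s == 0) return(abs(m))
  s * sqrt(2 / pi) * exp(-m^2 / (2 * s^2)) +
    m * (1 - 2 * stats::pnorm(-m / s))
}

#' Rank-noisy energy drawn from the oracle's error model
#'
#' Returns `truth + bias_rank + N(0, spread_rank)`, deterministic in
#' `(id, rank, seed)`: the same entity queried twice at the same rank gets
#' the same energy.
#'
#' @param truth Ground-truth energy (kJ mol^-1).
#' @param rank Fidelity rank level.
#' @param errors Error model, see [rank_error_defaults()].
#' @param seed Base seed of the oracle.
#' @param id Entity identifier (species or reaction id).
#' @param kind `"G"` or `"barrier"`.
#' @return Noisy energy in kJ mol^-1.
#' @export
noisy_rank_energy <- function(truth, rank, errors = rank_error_defaults(),
                              seed = 1L, id = "x", kind = "barrier") {
  if (!is.finite(truth)) stop_kinsteer("truth energy must be finite")
  tab <- errors[[kind]]
  if (is.null(tab)) stop_kinsteer("unknown energy kind ", kind)
  row <- tab[tab$rank == rank, ]
  if (nrow(row) != 1L)
    stop_kinsteer("no error model for rank ", rank, " (", kind, ")")
  noise <- if (row$spread > 0)
    with_seed(child_seed(seed, paste(kind, id, rank)),
              stats::rnorm(1, 0, row$spread))
  else 0
  truth + row$bias + noise
}

# ---------------------------------------------------------------------------
# Ground-truth network generator

#' Generate a ground-truth network with a planted dominant path
#'
#' Builds a mass-balanced reaction network around a planted reactant ->
#' product path: two seed fragments associate to the first path species, a
#' chain of low-barrier exergonic isomerizations leads to the planted
#' product, and the remaining species/reactions are higher-barrier side
#' isomerizations.  All reactions are elementally balanced by construction
#' and the network is bit-identical for a given seed.
#'
#' @param n_species Total species (>= 2 seeds + path length).
#' @param n_reactions Total reactions (>= path length).
#' @param seed Integer seed.
#' @param path_length Number of species on the planted path (>= 2).
#' @param path_barriers Range (kJ mol^-1) for planted-path barriers.
#' @param side_barriers Range for side-reaction barriers.  Side reactions
#'   never connect two path species directly, and the default ranges keep
#'   any detour (at least two side steps) heavier than the planted route,
#'   so the planted path is the lowest-cost route by construction.
#' @param path_drop Free-energy drop per planted step (kJ mol^-1).
#' @return List with `net` (the ground-truth [rn_network()], species free
#'   energies at rank 2 and barriers at rank 3), `seeds` (ids of the two
#'   starting fragments), `path_species`, `path_reactions` and `product`.
#' @export
generate_network <- function(n_species, n_reactions, seed = 1L,
                             path_length = 4L,
                             path_barriers = c(45, 60),
                             side_barriers = c(95, 130),
                             path_drop = 20) {
  if (n_species < 2L) stop_kinsteer("need at least 2 species")
  path_length <- as.integer(path_length)
  n_side <- n_species - 2L - path_length
  n_side_rxn <- n_reactions - path_length  # assoc + (path_length - 1) steps
  if (n_side < 0L)
    stop_kinsteer("n_species too small for seeds + path of length ",
                  path_length)
  if (n_side_rxn < 0L)
    stop_kinsteer("n_reactions smaller than the planted path")
  iso_n <- path_length + n_side
  max_side_rxn <- iso_n * (iso_n - 1) / 2 -
    path_length * (path_length - 1) / 2
  if (n_side_rxn > max_side_rxn)
    stop_kinsteer("cannot place ", n_side_rxn,
                  " side reactions among ", iso_n, " isomers")

  with_seed(as.integer(seed), {
    frag1 <- c(C = 3L, H = 6L, O = 1L)
    frag2 <- c(C = 1L, H = 2L, O = 1L)
    base <- frag1 + frag2

    mk_struct <- function(id, rank, G)
      structure_energy(paste0(id, "_s1"), rank, E_elec = G)

    species <- list(
      rn_species("F1", frag1, c0 = 1,
                 structures = list(mk_struct("F1", 2L, 0))),
      rn_species("F2", frag2, c0 = 1,
                 structures = list(mk_struct("F2", 2L, 0))))
    # planted path: P1 ... P<L>, G decreasing
    G_path <- -path_drop * seq_len(path_length) +
      stats::runif(path_length, -2, 2)
    for (i in seq_len(path_length))
      species <- c(species, list(
        rn_species(paste0("P", i), base, c0 = 0,
                   structures = list(mk_struct(paste0("P", i), 2L,
                                               G_path[i])))))
    # side isomers
    G_side <- stats::runif(n_side, -30, 10)
    for (i in seq_len(n_side))
      species <- c(species, list(
        rn_species(paste0("I", i), base, c0 = 0,
                   structures = list(mk_struct(paste0("I", i), 2L,
                                               G_side[i])))))
    names(species) <- vapply(species, `[[`, "", "id")

    G_of <- function(id) species[[id]]$structures[[1]]$total
    mk_ts <- function(id, G_lhs, G_rhs, barrier)
      structure_energy(paste0(id, "_ts1"), 3L,
                       E_elec = max(G_lhs, G_rhs) + barrier)

    reactions <- list()
    # entry association F1 + F2 -> P1
    b0 <- stats::runif(1, path_barriers[1], path_barriers[2])
    reactions <- c(reactions, list(
      rn_reaction("Rassoc", c(F1 = 1L, F2 = 1L), c(P1 = 1L),
                  ts_structures = list(mk_ts("Rassoc", G_of("F1") + G_of("F2"),
                                             G_of("P1"), b0)),
                  delta_pno = 0)))
    # planted chain
    for (i in seq_len(path_length - 1L)) {
      id <- paste0("Rpath", i)
      b <- stats::runif(1, path_barriers[1], path_barriers[2])
      reactions <- c(reactions, list(
        rn_reaction(id, setNames(1L, paste0("P", i)),
                    setNames(1L, paste0("P", i + 1L)),
                    ts_structures = list(mk_ts(id, G_of(paste0("P", i)),
                                               G_of(paste0("P", i + 1L)), b)),
                    delta_pno = 0)))
    }
    # side isomerizations among {P*, I*} pairs; pairs of two path species
    # are excluded so no side reaction can shortcut the planted chain
    iso_ids <- c(paste0("P", seq_len(path_length)),
                 if (n_side > 0) paste0("I", seq_len(n_side)))
    cand <- t(utils::combn(iso_ids, 2))
    both_path <- startsWith(cand[, 1], "P") & startsWith(cand[, 2], "P")
    cand <- cand[!both_path, , drop = FALSE]
    pick <- sample.int(nrow(cand), n_side_rxn)
    for (j in seq_along(pick)) {
      a <- cand[pick[j], 1]; b <- cand[pick[j], 2]
      id <- paste0("Rside", j)
      bb <- stats::runif(1, side_barriers[1], side_barriers[2])
      reactions <- c(reactions, list(
        rn_reaction(id, setNames(1L, a), setNames(1L, b),
                    ts_structures = list(mk_ts(id, G_of(a), G_of(b), bb)),
                    delta_pno = 0)))
    }

    net <- rn_network(species, reactions)
    list(net = net, seeds = c("F1", "F2"),
         path_species = c("F1", "F2", paste0("P", seq_len(path_length))),
         path_reactions = c("Rassoc",
                            if (path_length > 1)
                              paste0("Rpath", seq_len(path_length - 1L))),
         product = paste0("P", path_length))
  })
}

# ---------------------------------------------------------------------------
# Noisy oracle over a ground-truth network

# Rank-g noisy free energy of a species (plain number).  Ranks without a
# G error model (e.g. the coupled-cluster rank, where species free energies
# are not recomputed) return the truth.
noisy_species_G <- function(truth_net, id, grank, errors, seed) {
  truth <- as.numeric(species_free_energy(truth_net$species[[id]]))
  if (is.null(errors$G) || !grank %in% errors$G$rank) return(truth)
  noisy_rank_energy(truth, grank, errors, seed, id, "G")
}

# Noisy copy of a species' free energy as a rank-r structure record.
noisy_species_structure <- function(truth_net, id, rank, errors, seed) {
  structure_energy(paste0(id, "_r", rank), rank,
                   E_elec = noisy_species_G(truth_net, id, rank, errors,
                                            seed))
}

# Noisy copy of a reaction's TS free energy (absolute) at rank r.  The
# barrier error model acts on the *activation* free energy: the TS total is
# anchored at the same rank's noisy LHS free energy, so the realized
# forward barrier is exactly truth + error when species and barrier sit at
# matching ranks.  Barriers above the top species rank anchor at the
# reference (rank-2) free energies.
noisy_ts_structure <- function(truth_net, id, rank, errors, seed,
                               overrides = NULL) {
  rx <- truth_net$reactions[[id]]
  if (rx$barrierless) return(NULL)
  ts_truth <- min(vapply(rx$ts_structures, `[[`, 0, "total"))
  G_lhs_truth <- sum(vapply(names(rx$lhs), function(sp)
    as.numeric(species_free_energy(truth_net$species[[sp]])) * rx$lhs[[sp]],
    0))
  fwd_truth <- ts_truth - G_lhs_truth
  err <- if (!is.null(overrides) && id %in% names(overrides) && rank == 1L)
    overrides[[id]]
  else
    noisy_rank_energy(0, rank, errors, seed, id, "barrier")
  grank <- min(rank, 2L)
  G_lhs_noisy <- sum(vapply(names(rx$lhs), function(sp)
    noisy_species_G(truth_net, sp, grank, errors, seed) * rx$lhs[[sp]], 0))
  structure(structure_energy(paste0(id, "_ts_r", rank), rank,
                             E_elec = G_lhs_noisy + fwd_truth + err),
            delta_pno = rx$delta_pno %||% 0)
}

#' Synthetic multi-fidelity energy and discovery oracle
#'
#' Wraps a ground-truth network behind the oracle interface consumed by
#' [explore_network()]: reaction discovery reveals the truth reactions
#' incident to an explored species (unimolecular: reactions whose LHS is
#' one unit of that species) or pair (bimolecular: LHS equal to the pair,
#' self-pairs meaning two units), together with any species they introduce;
#' energies at rank r are the ground truth plus the rank's bias and noise
#' (deterministic per entity, rank and seed).
#'
#' The returned oracle is a list with fields `seed_species` (rank-1
#' structures, truth `c0`), `ranks`, and functions
#' `discover(type, target)`, `refine_species(id)` (rank-2 structure),
#' `refine_barrier(id)` (rank-3 TS structure with `delta_pno` attribute),
#' `truth` (the wrapped network).
#'
#' @param truth List from [generate_network()] or a bare [rn_network()]
#'   plus `seeds` ids.
#' @param errors Per-rank error models ([rank_error_defaults()]); set all
#'   biases/spreads to zero for an exact oracle.
#' @param seed Base seed making all noise reproducible.
#' @param barrier_overrides Named numeric vector of fixed rank-1 barrier
#'   errors (kJ mol^-1) overriding the random model for specific reactions.
#' @return The oracle list.
#' @export
synthetic_oracle <- function(truth, errors = rank_error_defaults(),
                             seed = 1L, barrier_overrides = NULL) {
  net <- if (inherits(truth, "rn_network")) truth else truth$net
  seeds <- if (inherits(truth, "rn_network")) {
    ids <- names(net$species)[vapply(net$species, function(s) s$c0 > 0, NA)]
    if (!length(ids)) stop_kinsteer("no seed species (c0 > 0) in network")
    ids
  } else truth$seeds

  noisy_species <- function(id) {
    sp <- net$species[[id]]
    rn_species(sp$id, sp$composition, sp$charge, sp$role,
               structures = list(noisy_species_structure(net, id, 1L,
                                                         errors, seed)),
               c0 = sp$c0, constituents = sp$constituents)
  }
  noisy_reaction <- function(id) {
    rx <- net$reactions[[id]]
    if (rx$barrierless)
      return(rn_reaction(rx$id, rx$lhs, rx$rhs))
    rn_reaction(rx$id, rx$lhs, rx$rhs,
                ts_structures = list(
                  noisy_ts_structure(net, id, 1L, errors, seed,
                                     barrier_overrides)),
                delta_pno = rx$delta_pno)
  }

  discover <- function(type, target) {
    hits <- Filter(function(rx) {
      if (type == "unimolecular")
        length(rx$lhs) == 1L && sum(rx$lhs) == 1L && names(rx$lhs) == target
      else {
        want <- sort(rep(target, length.out = 2))
        have <- sort(rep(names(rx$lhs), rx$lhs))
        length(have) == 2L && all(have == want)
      }
    }, net$reactions)
    sp_ids <- unique(unlist(lapply(hits, function(rx)
      c(names(rx$lhs), names(rx$rhs)))))
    list(species = lapply(sp_ids, noisy_species),
         reactions = lapply(names(hits), noisy_reaction))
  }

  list(
    seed_species = lapply(seeds, noisy_species),
    ranks = net$ranks,
    discover = discover,
    refine_species = function(id) {
      if (is.null(net$species[[id]])) return(NULL)
      noisy_species_structure(net, id, 2L, errors, seed)
    },
    refine_barrier = function(id) {
      if (is.null(net$reactions[[id]])) return(NULL)
      noisy_ts_structure(net, id, 3L, errors, seed)
    },
    truth = net, seeds = seeds, seed = as.integer(seed), errors = errors)
}

#' Build a rank-1 noisy copy of an entire network
#'
#' Applies the oracle's rank-`rank` error model to every species free
#' energy and reaction barrier of a ground-truth network, returning a
#' network with the same topology.  Used for cross-rank error-statistic
#' calibration.
#'
#' @param net Ground-truth [rn_network()].
#' @param rank Rank level of the noisy copy.
#' @param errors Error model.
#' @param seed Seed.
#' @return The noisy network.
#' @export
noisy_network <- function(net, rank = 1L, errors = rank_error_defaults(),
                          seed = 1L) {
  species <- lapply(net$species, function(sp) {
    rn_species(sp$id, sp$composition, sp$charge, sp$role,
               structures = list(noisy_species_structure(net, sp$id, rank,
                                                         errors, seed)),
               c0 = sp$c0, constituents = sp$constituents)
  })
  reactions <- lapply(net$reactions, function(rx) {
    if (rx$barrierless) return(rn_reaction(rx$id, rx$lhs, rx$rhs))
    rn_reaction(rx$id, rx$lhs, rx$rhs,
                ts_structures = list(
                  noisy_ts_structure(net, rx$id, rank, errors, seed)),
                delta_pno = rx$delta_pno)
  })
  rn_network(species, reactions, ranks = net$ranks, validate = FALSE)
}

# ---------------------------------------------------------------------------
# Cross-rank delta statistics

# Raw (unclamped) forward/backward activation energies of every reaction,
# straight from the assembled parameters: the cross-rank statistics compare
# the activation energies themselves, not the clamped rate-effective
# barriers.
raw_barriers <- function(net, params) {
  dG_r <- reaction_dG_r(net, params)
  idx <- params$kind == "dGa"
  fwd <- setNames(params$value[idx], params$target[idx])[names(net$reactions)]
  list(fwd = fwd, bwd = fwd - dG_r, dG_r = dG_r)
}

# Species reachable from `seeds` crossing only barriers below `cutoff`
# (either direction of a reaction, provided all required reactants on the
# crossed side have been reached).
reachable_species <- function(net, params, seeds, cutoff) {
  rb <- raw_barriers(net, params)
  reached <- seeds
  repeat {
    grew <- FALSE
    for (j in seq_along(net$reactions)) {
      rx <- net$reactions[[j]]
      if (all(names(rx$lhs) %in% reached) && rb$fwd[j] < cutoff) {
        new <- setdiff(names(rx$rhs), reached)
        if (length(new)) { reached <- c(reached, new); grew <- TRUE }
      }
      if (all(names(rx$rhs) %in% reached) && rb$bwd[j] < cutoff) {
        new <- setdiff(names(rx$lhs), reached)
        if (length(new)) { reached <- c(reached, new); grew <- TRUE }
      }
    }
    if (!grew) break
  }
  reached
}

#' Cross-rank free-energy and barrier differences between two networks
#'
#' Matches species and reactions by id, restricts to entities reachable
#' from the seed species by crossing barriers below `barrier_cutoff` in the
#' reference network, and reports `Delta G_n = G_n(A) - G_n(B)` and
#' `DeltaDelta G‡ = dG‡(A) - dG‡(B)` for forward and backward barriers
#' (network A is the reference rank).
#'
#' @param net_a Reference network.
#' @param net_b Comparison (approximate-rank) network with matching ids.
#' @param seeds Seed species for the reachability restriction; defaults to
#'   species with positive initial concentration.
#' @param barrier_cutoff Accessibility cutoff in kJ mol^-1.
#' @return Object of class `rn_deltas`: data.frames `species`
#'   (`id`, `delta_G`) and `reactions` (`id`, `ddG_fwd`, `ddG_bwd`), plus
#'   `summary` (mean and MAD of each difference).
#' @export
network_deltas <- function(net_a, net_b, seeds = NULL,
                           barrier_cutoff = 400) {
  if (is.null(seeds))
    seeds <- names(net_a$species)[vapply(net_a$species,
                                         function(s) s$c0 > 0, NA)]
  pa <- assemble_parameters(net_a, resolve_uncertainty = FALSE)
  pb <- assemble_parameters(net_b, resolve_uncertainty = FALSE)
  reach <- reachable_species(net_a, pa, seeds, barrier_cutoff)
  sp_match <- intersect(intersect(names(net_a$species),
                                  names(net_b$species)), reach)
  rx_match <- intersect(names(net_a$reactions), names(net_b$reactions))
  rx_keep <- vapply(rx_match, function(id) {
    rx <- net_a$reactions[[id]]
    all(c(names(rx$lhs), names(rx$rhs)) %in% reach)
  }, NA)
  rx_match <- rx_match[rx_keep]
  if (!length(sp_match) && !length(rx_match))
    stop_kinsteer("no matching reachable species or reactions")

  Ga <- setNames(pa$value[pa$kind == "G"], pa$target[pa$kind == "G"])
  Gb <- setNames(pb$value[pb$kind == "G"], pb$target[pb$kind == "G"])
  ra <- raw_barriers(net_a, pa)
  rb <- raw_barriers(net_b, pb)

  species <- data.frame(id = sp_match,
                        delta_G = Ga[sp_match] - Gb[sp_match],
                        row.names = NULL)
  reactions <- data.frame(
    id = rx_match,
    ddG_fwd = ra$fwd[rx_match] - rb$fwd[rx_match],
    ddG_bwd = ra$bwd[rx_match] - rb$bwd[rx_match],
    row.names = NULL)
  summ <- data.frame(
    quantity = c("delta_G", "ddG_fwd", "ddG_bwd"),
    mean = c(mean(species$delta_G), mean(reactions$ddG_fwd),
             mean(reactions$ddG_bwd)),
    mad = c(mean(abs(species$delta_G)), mean(abs(reactions$ddG_fwd)),
            mean(abs(reactions$ddG_bwd))))
  structure(list(species = species, reactions = reactions, summary = summ),
            class = "rn_deltas")
}

#' @export
print.rn_deltas <- function(x, ...) {
  cat("cross-rank deltas: ", nrow(x$species), " species, ",
      nrow(x$reactions), " reactions matched\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Eschenmoser-Claisen example networks

#' Eschenmoser-Claisen rearrangement example networks
#'
#' Hand-coded minimal networks for the [3,3]-sigmatropic rearrangement of
#' allyl alcohol (`"allyl"`) and furfuryl alcohol (`"furfuryl"`) with an
#' amide acetal reagent.  The main-path energetics reproduce the refined
#' free-energy profile: for the allyl variant, cumulative transition-state
#' heights of 132.9, 138.8 and 140.8 kJ mol^-1 relative to the reactants
#' for the two methanol eliminations and the Claisen rearrangement step,
#' and an overall reaction free energy of -122.7 kJ mol^-1; for the
#' furfuryl variant 147.1 (elimination) and 127.8 (Claisen) with the
#' ring-rearomatizing H-shift at 101.7 relative to the reactants (183.7
#' relative to the post-Claisen species at -82.0) and an overall reaction
#' free energy of -170.4 kJ mol^-1.  Intermediate well depths not fixed by
#' these values are chosen shallow enough to be kinetically non-binding.
#'
#' @param variant `"allyl"` or `"furfuryl"`.
#' @return An [rn_network()] with species free energies at rank 2 and
#'   transition states at rank 3.
#' @export
eschenmoser_network <- function(variant = c("allyl", "furfuryl")) {
  variant <- match.arg(variant)
  st <- function(id, G) list(structure_energy(paste0(id, "_s1"), 2L,
                                              E_elec = G))
  ts <- function(id, G) list(structure_energy(paste0(id, "_ts1"), 3L,
                                              E_elec = G))
  if (variant == "allyl") {
    species <- list(
      rn_species("amide_acetal", c(C = 6, H = 15, N = 1, O = 2), c0 = 1,
                 structures = st("amide_acetal", 0)),
      rn_species("allyl_alcohol", c(C = 3, H = 6, O = 1), c0 = 1,
                 structures = st("allyl_alcohol", 0)),
      rn_species("methanol", c(C = 1, H = 4, O = 1),
                 structures = st("methanol", 0)),
      rn_species("methoxy_enamine", c(C = 5, H = 11, N = 1, O = 1),
                 structures = st("methoxy_enamine", 20)),
      rn_species("mixed_acetal", c(C = 8, H = 17, N = 1, O = 2),
                 structures = st("mixed_acetal", 15)),
      rn_species("ketene_aminal", c(C = 7, H = 13, N = 1, O = 1),
                 structures = st("ketene_aminal", 18)),
      rn_species("amide_product", c(C = 7, H = 13, N = 1, O = 1),
                 structures = st("amide_product", -122.7)))
    reactions <- list(
      # MeOH elimination from the reagent (alcohol-catalyzed); TS height
      # 132.9 relative to the reactants
      rn_reaction("elim1", c(amide_acetal = 1L),
                  c(methoxy_enamine = 1L, methanol = 1L),
                  ts_structures = ts("elim1", 132.9), delta_pno = 0),
      # alcohol addition to the enamine double bond
      rn_reaction("addition", c(methoxy_enamine = 1L, allyl_alcohol = 1L),
                  c(mixed_acetal = 1L),
                  ts_structures = ts("addition", 100), delta_pno = 0),
      # second MeOH elimination; TS cumulative 138.8 (one MeOH spectator)
      rn_reaction("elim2", c(mixed_acetal = 1L),
                  c(ketene_aminal = 1L, methanol = 1L),
                  ts_structures = ts("elim2", 138.8), delta_pno = 0),
      # Claisen rearrangement; TS cumulative 140.8 (two MeOH spectators)
      rn_reaction("claisen", c(ketene_aminal = 1L), c(amide_product = 1L),
                  ts_structures = ts("claisen", 140.8), delta_pno = 0))
  } else {
    species <- list(
      rn_species("furfuryl_alcohol", c(C = 5, H = 6, O = 2), c0 = 1,
                 structures = st("furfuryl_alcohol", 0)),
      rn_species("methoxy_enamine", c(C = 5, H = 11, N = 1, O = 1), c0 = 1,
                 structures = st("methoxy_enamine", 0)),
      rn_species("methanol", c(C = 1, H = 4, O = 1),
                 structures = st("methanol", 0)),
      rn_species("mixed_acetal_f", c(C = 10, H = 17, N = 1, O = 3),
                 structures = st("mixed_acetal_f", 10)),
      rn_species("ketene_aminal_f", c(C = 9, H = 13, N = 1, O = 2),
                 structures = st("ketene_aminal_f", 5)),
      rn_species("post_claisen", c(C = 9, H = 13, N = 1, O = 2),
                 structures = st("post_claisen", -82.0)),
      rn_species("furan_amide", c(C = 9, H = 13, N = 1, O = 2),
                 structures = st("furan_amide", -170.4)))
    reactions <- list(
      rn_reaction("addition_f",
                  c(furfuryl_alcohol = 1L, methoxy_enamine = 1L),
                  c(mixed_acetal_f = 1L),
                  ts_structures = ts("addition_f", 100), delta_pno = 0),
      # MeOH elimination; TS cumulative 147.1
      rn_reaction("elim_f", c(mixed_acetal_f = 1L),
                  c(ketene_aminal_f = 1L, methanol = 1L),
                  ts_structures = ts("elim_f", 147.1), delta_pno = 0),
      # Claisen step; TS cumulative 127.8 (one MeOH spectator)
      rn_reaction("claisen_f", c(ketene_aminal_f = 1L),
                  c(post_claisen = 1L),
                  ts_structures = ts("claisen_f", 127.8), delta_pno = 0),
      # rearomatizing H-shift; TS cumulative 101.7 = 183.7 above the
      # post-Claisen species
      rn_reaction("h_shift", c(post_claisen = 1L), c(furan_amide = 1L),
                  ts_structures = ts("h_shift", 101.7), delta_pno = 0))
  }
  rn_network(species, reactions)
}
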