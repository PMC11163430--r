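# Core data model: fidelity ranks, structure free energies, species
# (compounds and flasks), reactions, and the aggregation of structure-level
# free energies into the kinetic parameter vector (G_n, dG‡_I).

#' Fidelity rank of an energy model
#'
#' A fidelity rank is one rung of the ladder of electronic-structure model
#' combinations, ordered from cheap/uncertain (level 1) to accurate/expensive
#' (level 3).  Each rank carries the uncertainty assigned to species free
#' energies (`u_G`) and to activation free energies (`u_barrier`) computed at
#' that rank, in kJ mol^-1.  A rank may leave either uncertainty `NA` when
#' parameters of that kind are never used at that rank; the top-rank barrier
#' uncertainty is usually resolved per reaction from the PNO-truncation
#' difference via [pno_uncertainty()].
#'
#' @param level Integer ordinal in `{1, 2, 3}`.
#' @param label Free-text label of the method combination.
#' @param u_G Uncertainty of species free energies at this rank (kJ mol^-1),
#'   or `NA` if species free energies are not used at this rank.
#' @param u_barrier Uncertainty of activation free energies (kJ mol^-1), `NA`
#'   if barriers are not used at this rank, or the string `"pno"` to resolve
#'   it per reaction via [pno_uncertainty()].
#' @return An object of class `fidelity_rank`.
#' @export
fidelity_rank <- function(level, label = paste0("rank-", level),
                          u_G = NA_real_, u_barrier = NA_real_) {
  level <- as.integer(level)
  if (!level %in% 1:3) stop_kinsteer("fidelity rank level must be 1, 2 or 3")
  if (is.numeric(u_G) && !is.na(u_G) && u_G < 0)
    stop_kinsteer("u_G must be non-negative")
  if (is.numeric(u_barrier) && !is.na(u_barrier) && u_barrier < 0)
    stop_kinsteer("u_barrier must be non-negative or the token \"pno\"")
  structure(list(level = level, label = label, u_G = u_G,
                 u_barrier = u_barrier),
            class = "fidelity_rank")
}

#' Default three-rank fidelity ladder
#'
#' The default uncertainty assignments, in kJ mol^-1: rank 1 (semi-empirical
#' structures, hybrid-DFT energies) u(G) = 10, u(dG‡) = 15; rank 2 (DFT
#' structures) u(G) = 5, barriers unused; rank 3 (local coupled cluster)
#' species free energies unused, barrier uncertainty resolved per reaction as
#' `max(delta_pno, 5)` kJ mol^-1.
#'
#' @return List of three [fidelity_rank()] objects, indexed by level.
#' @export
default_ranks <- function() {
  list(fidelity_rank(1L, "semiempirical//hybrid-DFT", u_G = 10, u_barrier = 15),
       fidelity_rank(2L, "DFT//hybrid-DFT", u_G = 5, u_barrier = NA_real_),
       fidelity_rank(3L, "DFT//local-CC", u_G = NA_real_, u_barrier = "pno"))
}

#' Sum the free-energy components of a stationary-point structure
#'
#' Total free energy of a structure in the harmonic-oscillator /
#' particle-in-a-box / static-rotor approximation: electronic energy plus
#' vibrational, rotational, translational and solvation free-energy
#' corrections.
#'
#' @param components Named numeric vector (or list) with entries `E_elec`,
#'   `dG_vib`, `dG_rot`, `dG_trans`, `dG_solv`, all in kJ mol^-1.
#' @return Total free energy in kJ mol^-1.
#' @export
hps_total <- function(components) {
  need <- c("E_elec", "dG_vib", "dG_rot", "dG_trans", "dG_solv")
  components <- unlist(components)
  missing <- setdiff(need, names(components))
  if (length(missing))
    stop_kinsteer("missing free-energy component(s): ",
                  paste(missing, collapse = ", "))
  vals <- as.numeric(components[need])
  if (any(!is.finite(vals)))
    stop_kinsteer("non-finite free-energy component(s): ",
                  paste(need[!is.finite(vals)], collapse = ", "))
  sum(vals)
}

#' Create a structure free-energy record
#'
#' @param structure_id Opaque structure identifier.
#' @param rank Integer fidelity-rank level at which the energies were
#'   computed.
#' @param E_elec,dG_vib,dG_rot,dG_trans,dG_solv Free-energy components in
#'   kJ mol^-1 (corrections default to 0).
#' @param total Optional total; must agree with the component sum to within
#'   `tol`.
#' @param tol Consistency tolerance in kJ mol^-1.
#' @return Object of class `structure_energy`.
#' @export
structure_energy <- function(structure_id, rank, E_elec,
                             dG_vib = 0, dG_rot = 0, dG_trans = 0,
                             dG_solv = 0, total = NULL, tol = 1e-6) {
  comps <- c(E_elec = E_elec, dG_vib = dG_vib, dG_rot = dG_rot,
             dG_trans = dG_trans, dG_solv = dG_solv)
  tot <- hps_total(comps)
  if (!is.null(total) && abs(total - tot) > tol)
    stop_kinsteer("structure ", structure_id, ": stored total ", total,
                  " differs from component sum ", tot)
  structure(list(structure_id = as.character(structure_id),
                 rank = as.integer(rank),
                 components = comps, total = tot),
            class = "structure_energy")
}

#' Create a kinetic species (compound or flask)
#'
#' A species is a compound (single molecule) or a flask (a multi-molecule
#' reactive complex treated as one kinetic species).  Flask internal
#' composition is metadata only; the kinetics treats both roles identically.
#'
#' @param id Species identifier.
#' @param composition Named integer vector of element counts, e.g.
#'   `c(C = 3, H = 6, O = 1)`.
#' @param charge Total charge.
#' @param role `"compound"` or `"flask"`.
#' @param structures List of [structure_energy()] records (any ranks).
#' @param c0 Initial concentration in mol L^-1.
#' @param constituents For flasks, character vector (length >= 2) naming the
#'   molecular constituents; metadata only.
#' @return Object of class `rn_species`.
#' @export
rn_species <- function(id, composition, charge = 0L, role = "compound",
                       structures = list(), c0 = 0,
                       constituents = NULL) {
  role <- match.arg(role, c("compound", "flask"))
  composition <- composition[composition != 0]
  storage.mode(composition) <- "integer"
  if (any(composition < 0))
    stop_kinsteer("species ", id, ": negative element counts")
  if (c0 < 0) stop_kinsteer("species ", id, ": negative c0")
  if (role == "flask" && !is.null(constituents) && length(constituents) < 2)
    stop_kinsteer("flask ", id, " must list >= 2 molecular constituents")
  structure(list(id = as.character(id), role = role,
                 composition = composition, charge = as.integer(charge),
                 structures = structures, c0 = c0,
                 constituents = constituents),
            class = "rn_species")
}

#' Create a reaction
#'
#' @param id Reaction identifier.
#' @param lhs,rhs Named integer vectors mapping species id to stoichiometric
#'   coefficient (positive) on the left/right-hand side.
#' @param ts_structures List of transition-state [structure_energy()]
#'   records; empty if and only if the reaction is barrierless.
#' @param barrierless Flag; defaults to `TRUE` when `ts_structures` is empty.
#' @param delta_pno Optional PNO-truncation energy difference (kJ mol^-1)
#'   used to resolve the top-rank barrier uncertainty.
#' @return Object of class `rn_reaction`.
#' @export
rn_reaction <- function(id, lhs, rhs, ts_structures = list(),
                        barrierless = length(ts_structures) == 0L,
                        delta_pno = NULL) {
  for (side in list(lhs, rhs))
    if (is.null(names(side)) || any(side <= 0) || any(side != round(side)))
      stop_kinsteer("reaction ", id,
                    ": stoichiometries must be named positive integers")
  if (barrierless != (length(ts_structures) == 0L))
    stop_kinsteer("reaction ", id,
                  ": barrierless flag inconsistent with TS structure list")
  storage.mode(lhs) <- "integer"; storage.mode(rhs) <- "integer"
  structure(list(id = as.character(id), lhs = lhs, rhs = rhs,
                 ts_structures = ts_structures, barrierless = barrierless,
                 delta_pno = delta_pno),
            class = "rn_reaction")
}

#' Assemble a reaction network
#'
#' @param species List of [rn_species()] objects.
#' @param reactions List of [rn_reaction()] objects.
#' @param ranks Fidelity ladder, see [default_ranks()].
#' @param validate Run [validate_network()] on construction.
#' @return Object of class `rn_network` with named `species` and `reactions`
#'   lists.
#' @export
rn_network <- function(species, reactions = list(), ranks = default_ranks(),
                       validate = TRUE) {
  names(species) <- vapply(species, `[[`, "", "id")
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  net <- structure(list(species = species, reactions = reactions,
                        ranks = ranks),
                   class = "rn_network")
  if (validate) validate_network(net)
  net
}

# Elemental content of one side of a reaction, as a named count vector.
side_composition <- function(net, side) {
  tab <- list()
  for (sp in names(side)) {
    comp <- net$species[[sp]]$composition * side[[sp]]
    for (el in names(comp)) tab[[el]] <- (tab[[el]] %||% 0L) + comp[[el]]
  }
  out <- unlist(tab) %||% integer(0)
  out[out != 0L]
}

side_charge <- function(net, side) {
  sum(vapply(names(side),
             function(sp) net$species[[sp]]$charge * side[[sp]], 0))
}

#' Validate a reaction network
#'
#' Checks that every reaction references known species, is elementally and
#' charge balanced, and is barrierless exactly when it has no transition-state
#' structures; and that every species carries at least one structure.
#'
#' @param net An [rn_network()].
#' @param require_structures Demand >= 1 structure per species (disable for
#'   bare topologies).
#' @return `net`, invisibly; errors name the offending entity.
#' @export
validate_network <- function(net, require_structures = TRUE) {
  if (length(net$species) == 0L) stop_kinsteer("network has no species")
  for (sp in net$species) {
    if (require_structures && length(sp$structures) == 0L)
      stop_kinsteer("species ", sp$id, " has no structures")
  }
  for (rx in net$reactions) {
    unknown <- setdiff(c(names(rx$lhs), names(rx$rhs)), names(net$species))
    if (length(unknown))
      stop_kinsteer("reaction ", rx$id, " references unknown species: ",
                    paste(unknown, collapse = ", "))
    cl <- side_composition(net, rx$lhs)
    cr <- side_composition(net, rx$rhs)
    els <- union(names(cl), names(cr))
    cl_f <- vapply(els, function(e) if (is.na(cl[e])) 0L else cl[[e]], 0L)
    cr_f <- vapply(els, function(e) if (is.na(cr[e])) 0L else cr[[e]], 0L)
    if (any(cl_f != cr_f))
      stop_kinsteer("reaction ", rx$id, " is not elementally balanced (",
                    paste0(els[cl_f != cr_f], collapse = ", "), ")")
    if (side_charge(net, rx$lhs) != side_charge(net, rx$rhs))
      stop_kinsteer("reaction ", rx$id, " is not charge balanced")
    if (rx$barrierless != (length(rx$ts_structures) == 0L))
      stop_kinsteer("reaction ", rx$id,
                    ": barrierless flag inconsistent with TS structures")
  }
  invisible(net)
}

#' Species free energy under the rank-preference policy
#'
#' Returns the minimum structure free energy at the *highest* fidelity rank
#' for which the species has structures.  A higher-rank structure always
#' wins, even when a lower-rank structure lies lower in energy (the ranks are
#' not energetically comparable).
#'
#' @param species An [rn_species()].
#' @return Free energy in kJ mol^-1, with attribute `"rank"` giving the
#'   selected rank level.
#' @export
species_free_energy <- function(species) {
  if (length(species$structures) == 0L)
    stop_kinsteer("species ", species$id, " has no structures")
  rks <- vapply(species$structures, `[[`, 0L, "rank")
  best <- max(rks)
  tot <- vapply(species$structures[rks == best], `[[`, 0, "total")
  structure(min(tot), rank = best)
}

#' Forward and backward activation free energies of a reaction
#'
#' For a reaction with transition-state structures, the forward barrier is
#' the minimum TS free energy at the best available rank minus the summed
#' left-hand-side free energy.  For barrierless reactions the transition
#' "state" is taken at the higher of the two side free energies, so the
#' forward barrier is `max(0, G_rhs - G_lhs)`.  In all cases the backward
#' barrier is `dG_fwd - (G_rhs - G_lhs)`.
#'
#' @param reaction An [rn_reaction()].
#' @param G_lhs,G_rhs Summed side free energies (stoichiometry-weighted sums
#'   of species free energies), kJ mol^-1.
#' @return List with `dG_fwd`, `dG_bwd` (kJ mol^-1) and `rank` (TS rank
#'   level, `NA` for barrierless reactions).
#' @export
activation_free_energy <- function(reaction, G_lhs, G_rhs) {
  dG_r <- G_rhs - G_lhs
  if (reaction$barrierless) {
    dG_fwd <- max(0, dG_r)
    return(list(dG_fwd = dG_fwd, dG_bwd = dG_fwd - dG_r, rank = NA_integer_))
  }
  if (length(reaction$ts_structures) == 0L)
    stop_kinsteer("reaction ", reaction$id,
                  " has neither TS structures nor a barrierless flag")
  rks <- vapply(reaction$ts_structures, `[[`, 0L, "rank")
  best <- max(rks)
  Gts <- min(vapply(reaction$ts_structures[rks == best], `[[`, 0, "total"))
  dG_fwd <- Gts - G_lhs
  list(dG_fwd = dG_fwd, dG_bwd = dG_fwd - dG_r, rank = best)
}

#' Top-rank barrier uncertainty from the PNO-truncation difference
#'
#' The uncertainty assigned to a barrier computed at the coupled-cluster rank
#' is the absolute free-energy difference between normal and tight PNO
#' truncation settings, floored at 5.0 kJ mol^-1 to cover unquantified error
#' sources.
#'
#' @param delta_pno Non-negative energy difference in kJ mol^-1.
#' @return `max(delta_pno, 5.0)` kJ mol^-1.
#' @export
pno_uncertainty <- function(delta_pno) {
  if (any(delta_pno < 0)) stop_kinsteer("delta_pno must be non-negative")
  pmax(delta_pno, 5.0)
}

rank_u <- function(ranks, level, what) {
  if (is.na(level)) return(NA_real_)
  rk <- ranks[[level]]
  u <- rk[[what]]
  if (identical(u, "pno")) return(NA_real_)  # resolved per reaction
  as.numeric(u)
}

#' Assemble the kinetic parameter vector of a network
#'
#' Builds one free-energy parameter per species (`G`) and one forward
#' activation free energy per reaction (`dGa`), each taken at the best
#' available fidelity rank, together with the per-entry uncertainty from the
#' rank's assignment (top-rank barriers via [pno_uncertainty()]).
#'
#' Barrierless reactions get a parameter entry whose value is the derived
#' effective barrier `max(0, dG_r)`; it carries zero uncertainty and the top
#' rank, because it is fully determined by the endpoint free energies and is
#' re-derived from them at every model evaluation.
#'
#' @param net An [rn_network()].
#' @param resolve_uncertainty Demand that every entry's rank provides an
#'   uncertainty (disable for value-only uses such as cross-rank
#'   comparisons, where `u` is reported `NA`).
#' @return A `data.frame` of class `rn_params` with columns `id`, `kind`
#'   (`"G"` or `"dGa"`), `target` (species/reaction id), `value`, `u`,
#'   `rank`, `barrierless`.
#' @export
assemble_parameters <- function(net, resolve_uncertainty = TRUE) {
  n_sp <- length(net$species); n_rx <- length(net$reactions)
  sp_ids <- names(net$species)
  G <- numeric(n_sp); G_rank <- integer(n_sp); G_u <- numeric(n_sp)
  offenders <- character(0)
  for (i in seq_len(n_sp)) {
    g <- species_free_energy(net$species[[i]])
    G[i] <- g; G_rank[i] <- attr(g, "rank")
    G_u[i] <- rank_u(net$ranks, G_rank[i], "u_G")
    if (is.na(G_u[i]))
      offenders <- c(offenders, paste0("G:", sp_ids[i], " (rank ",
                                       G_rank[i], " has no u_G)"))
  }
  names(G) <- sp_ids
  rx_ids <- names(net$reactions)
  dGa <- numeric(n_rx); A_rank <- integer(n_rx); A_u <- numeric(n_rx)
  bl <- logical(n_rx)
  for (j in seq_len(n_rx)) {
    rx <- net$reactions[[j]]
    G_lhs <- sum(G[names(rx$lhs)] * rx$lhs)
    G_rhs <- sum(G[names(rx$rhs)] * rx$rhs)
    act <- activation_free_energy(rx, G_lhs, G_rhs)
    dGa[j] <- act$dG_fwd; bl[j] <- rx$barrierless
    if (rx$barrierless) {
      A_rank[j] <- length(net$ranks); A_u[j] <- 0
    } else {
      A_rank[j] <- act$rank
      rk <- net$ranks[[act$rank]]
      if (identical(rk$u_barrier, "pno")) {
        A_u[j] <- pno_uncertainty(rx$delta_pno %||% 0)
      } else {
        A_u[j] <- rank_u(net$ranks, act$rank, "u_barrier")
        if (is.na(A_u[j]))
          offenders <- c(offenders, paste0("dGa:", rx_ids[j], " (rank ",
                                           act$rank, " has no u_barrier)"))
      }
    }
  }
  if (resolve_uncertainty && length(offenders))
    stop_kinsteer("unresolvable parameter entries: ",
                  paste(offenders, collapse = "; "))
  params <- data.frame(
    id = c(sprintf("G:%s", sp_ids), sprintf("dGa:%s", rx_ids)),
    kind = rep(c("G", "dGa"), c(n_sp, n_rx)),
    target = c(sp_ids, rx_ids),
    value = c(G, dGa),
    u = c(G_u, A_u),
    rank = c(G_rank, A_rank),
    barrierless = c(rep(FALSE, n_sp), bl),
    stringsAsFactors = FALSE)
  rownames(params) <- params$id
  class(params) <- c("rn_params", "data.frame")
  params
}

# Reaction free energies dG_r implied by the G entries of a parameter table.
reaction_dG_r <- function(net, params) {
  G <- params$value[params$kind == "G"]
  names(G) <- params$target[params$kind == "G"]
  vapply(net$reactions, function(rx) {
    sum(G[names(rx$rhs)] * rx$rhs) - sum(G[names(rx$lhs)] * rx$lhs)
  }, 0)
}

#' Clamp barrier parameters to physically admissible values
#'
#' Applies two rules given the current species free energies: (i) a negative
#' forward barrier is raised to zero (capping the rate constant at kB*T/h);
#' (ii) a forward barrier below the reaction free energy (which would imply a
#' negative backward barrier) is raised to make the backward barrier exactly
#' zero.  Barrierless entries are re-derived as `max(0, dG_r)`.
#'
#' @param net An [rn_network()].
#' @param params An `rn_params` table, possibly perturbed.
#' @return The clamped parameter table.
#' @export
clamp_parameters <- function(net, params) {
  if (!length(net$reactions)) return(params)
  dG_r <- reaction_dG_r(net, params)
  idx <- which(params$kind == "dGa")
  tgt <- params$target[idx]
  cur <- params$value[idx]
  cur[params$barrierless[idx]] <- 0  # re-derive: lower bound only
  params$value[idx] <- pmax(cur, 0, dG_r[tgt])
  params
}

#' @export
print.rn_network <- function(x, ...) {
  n_fl <- sum(vapply(x$species, function(s) s$role == "flask", NA))
  cat("reaction network: ", length(x$species), " species (",
      n_fl, " flasks), ", length(x$reactions), " reactions, ",
      length(x$ranks), " fidelity ranks\n", sep = "")
  invisible(x)
}

#' @export
print.rn_params <- function(x, ...) {
  cat("kinetic parameters: ", sum(x$kind == "G"), " species free energies, ",
      sum(x$kind == "dGa"), " activation free energies\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}
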