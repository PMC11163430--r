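# Serialization of networks to the structured-text schema (YAML, sections
# `ranks`, `species`, `reactions`), lossless to 12+ significant digits.

structure_to_list <- function(st) {
  list(structure_id = st$structure_id, rank = st$rank,
       components = as.list(st$components))
}

structure_from_list <- function(x) {
  cmp <- x$components
  structure_energy(x$structure_id, x$rank,
                   E_elec = cmp$E_elec, dG_vib = cmp$dG_vib %||% 0,
                   dG_rot = cmp$dG_rot %||% 0,
                   dG_trans = cmp$dG_trans %||% 0,
                   dG_solv = cmp$dG_solv %||% 0)
}

#' Write a network to the structured-text schema
#'
#' One YAML document per network with sections `ranks`, `species` and
#' `reactions`.  Energies are emitted with 15 significant digits, so a
#' write/read round trip is the identity on the data model (12 significant
#' digits guaranteed).
#'
#' @param net An [rn_network()].
#' @param path Output file.
#' @export
write_network <- function(net, path) {
  doc <- list(
    ranks = lapply(net$ranks, function(rk)
      list(level = rk$level, label = rk$label,
           u_G = if (is.na(rk$u_G)) NULL else rk$u_G,
           u_barrier = if (is.character(rk$u_barrier)) rk$u_barrier
                       else if (is.na(rk$u_barrier)) NULL else rk$u_barrier)),
    species = lapply(unname(net$species), function(sp)
      list(id = sp$id, role = sp$role,
           composition = as.list(sp$composition),
           charge = sp$charge, c0 = sp$c0,
           constituents = sp$constituents,
           structures = lapply(sp$structures, structure_to_list))),
    reactions = lapply(unname(net$reactions), function(rx)
      list(id = rx$id, lhs = as.list(rx$lhs), rhs = as.list(rx$rhs),
           barrierless = rx$barrierless,
           delta_pno = rx$delta_pno,
           ts_structures = lapply(rx$ts_structures, structure_to_list))))
  writeLines(yaml::as.yaml(doc, precision = 15L), path)
  invisible(path)
}

#' Read a network from the structured-text schema
#'
#' Parses and validates a network file written by [write_network()];
#' schema violations raise errors naming the offending entity.
#'
#' @param path Input file.
#' @return An [rn_network()].
#' @export
read_network <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$species) || length(doc$species) == 0L)
    stop_kinsteer(path, ": network has no species")
  ranks <- if (is.null(doc$ranks)) default_ranks() else
    lapply(doc$ranks, function(rk)
      fidelity_rank(rk$level, rk$label %||% paste0("rank-", rk$level),
                    u_G = rk$u_G %||% NA_real_,
                    u_barrier = rk$u_barrier %||% NA_real_))
  species <- lapply(doc$species, function(sp) {
    comp <- unlist(sp$composition)
    rn_species(sp$id, comp, charge = sp$charge %||% 0L,
               role = sp$role %||% "compound",
               structures = lapply(sp$structures, structure_from_list),
               c0 = sp$c0 %||% 0,
               constituents = unlist(sp$constituents))
  })
  reactions <- lapply(doc$reactions %||% list(), function(rx) {
    rn_reaction(rx$id, unlist(rx$lhs), unlist(rx$rhs),
                ts_structures = lapply(rx$ts_structures,
                                       structure_from_list),
                barrierless = rx$barrierless %||%
                  (length(rx$ts_structures) == 0L),
                delta_pno = rx$delta_pno)
  })
  rn_network(species, reactions, ranks = ranks)
}
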