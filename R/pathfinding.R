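# Shortest-path extraction from reactants to a target species over the
# bipartite species/reaction digraph, with barrier-derived edge weights and
# compound costs for required co-reactants.

#' Shortest reaction path between two species
#'
#' Builds a bipartite directed graph with species nodes and one node per
#' reaction direction, and runs Dijkstra's algorithm
#' (`igraph::shortest_paths`).  The edge from species `n` into a reaction
#' direction is weighted by `max(dG‡, 0) / (R*T)` (dimensionless barrier)
#' plus the compound costs of every other reactant the step consumes
#' (additional units of `n` included); edges from a reaction to its
#' products carry no weight.  Compound costs express how available a
#' co-reactant is: by default 1.0 for species with a positive starting
#' concentration and `default_cost` otherwise, overridable per species.
#'
#' The report traces cumulative free energies along the path relative to
#' the source: entering co-reactants add their free energy, each step adds
#' its reaction free energy, and each transition state sits at the
#' cumulative level of its left-hand side plus the forward barrier.
#'
#' @param net An [rn_network()].
#' @param params Parameter table ([assemble_parameters()]).
#' @param from,to Source and target species ids.
#' @param compound_costs Named numeric vector of per-species costs
#'   (dimensionless, > 0) overriding the default policy.
#' @param T Temperature (K) used to scale barriers into weights.
#' @param default_cost Cost assigned to co-reactants with zero starting
#'   concentration and no explicit cost.
#' @return Object of class `rn_path`: `found` flag, `species` and
#'   `reactions` sequences, `weight`, and a `steps` data.frame with
#'   per-step barriers, reaction free energies, and cumulative/transition-
#'   state energies relative to the source side (kJ mol^-1).
#' @export
find_path <- function(net, params, from, to, compound_costs = NULL,
                      T = 298.15, default_cost = 10) {
  if (is.null(net$species[[from]]) || is.null(net$species[[to]]))
    stop_kinsteer("unknown source or target species")
  if (any(compound_costs <= 0)) stop_kinsteer("compound costs must be > 0")
  rates <- derive_rates(net, params, T)
  G <- setNames(params$value[params$kind == "G"],
                params$target[params$kind == "G"])
  RT <- .Rgas * T / 1000  # kJ/mol

  cost_of <- function(sp) {
    if (!is.null(compound_costs) && sp %in% names(compound_costs))
      compound_costs[[sp]]
    else if (net$species[[sp]]$c0 > 0) 1.0
    else default_cost
  }

  sp_ids <- names(net$species)
  edges <- character(0); w <- numeric(0)
  rx_nodes <- character(0)
  for (j in seq_along(net$reactions)) {
    rx <- net$reactions[[j]]
    for (dir in c("f", "b")) {
      lhs <- if (dir == "f") rx$lhs else rx$rhs
      rhs <- if (dir == "f") rx$rhs else rx$lhs
      barrier <- if (dir == "f") rates$dG_fwd[j] else rates$dG_bwd[j]
      node <- paste0("rx:", rx$id, ":", dir)
      rx_nodes <- c(rx_nodes, node)
      for (sp in names(lhs)) {
        co <- setdiff(names(lhs), sp)
        w_in <- max(barrier, 0) / RT +
          sum(vapply(co, function(s) cost_of(s) * lhs[[s]], 0)) +
          cost_of(sp) * (lhs[[sp]] - 1L)
        edges <- c(edges, sp, node); w <- c(w, w_in)
      }
      for (sp in names(rhs)) {
        edges <- c(edges, node, sp); w <- c(w, 0)
      }
    }
  }
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(c(sp_ids, rx_nodes))
  if (length(edges)) g <- g + igraph::edges(edges, weight = w)
  sp_res <- suppressWarnings(
    igraph::shortest_paths(g, from = from, to = to, mode = "out",
                           weights = igraph::E(g)$weight,
                           output = "both"))
  vpath <- sp_res$vpath[[1]]
  if (length(vpath) == 0L)
    return(structure(list(found = FALSE, from = from, to = to),
                     class = "rn_path"))
  node_names <- igraph::V(g)$name[as.integer(vpath)]
  weight <- sum(igraph::E(g)$weight[as.integer(sp_res$epath[[1]])])

  is_rx <- startsWith(node_names, "rx:")
  rx_seq <- sub("^rx:(.*):(f|b)$", "\\1", node_names[is_rx])
  rx_dir <- sub("^rx:.*:(f|b)$", "\\1", node_names[is_rx])
  sp_seq <- node_names[!is_rx]

  # cumulative energy bookkeeping
  cum <- 0
  steps <- NULL
  for (s in seq_along(rx_seq)) {
    j <- match(rx_seq[s], names(net$reactions))
    rx <- net$reactions[[j]]
    fwd <- rx_dir[s] == "f"
    lhs <- if (fwd) rx$lhs else rx$rhs
    entered <- sp_seq[s]
    co_G <- sum(G[names(lhs)] * lhs) - G[entered]
    barrier <- if (fwd) rates$dG_fwd[j] else rates$dG_bwd[j]
    dG_r <- if (fwd) rates$dG_r[j] else -rates$dG_r[j]
    ts_cum <- cum + co_G + barrier
    cum <- cum + co_G + dG_r
    steps <- rbind(steps, data.frame(
      step = s, reaction = rx_seq[s],
      direction = if (fwd) "forward" else "backward",
      from = entered, to = sp_seq[s + 1L],
      barrier = barrier, dG_r = dG_r,
      ts_energy = ts_cum, cumulative = cum))
  }
  structure(list(found = TRUE, from = from, to = to,
                 species = sp_seq, reactions = rx_seq,
                 weight = weight, steps = steps),
            class = "rn_path")
}

#' @export
print.rn_path <- function(x, ...) {
  if (!x$found) {
    cat("no path from ", x$from, " to ", x$to, "\n", sep = "")
    return(invisible(x))
  }
  cat("path ", x$from, " -> ", x$to, " (weight ", signif(x$weight, 5),
      ")\n", sep = "")
  cat(sprintf("  %-14s %s\n", "", x$from))
  if (is.null(x$steps)) return(invisible(x))
  for (s in seq_len(nrow(x$steps))) {
    st <- x$steps[s, ]
    cat(sprintf("  %-14s %s  [TS %+.1f, cumulative %+.1f kJ/mol]\n",
                paste0(st$reaction, " (", substr(st$direction, 1, 1), ")"),
                st$to, st$ts_energy, st$cumulative))
  }
  invisible(x)
}
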