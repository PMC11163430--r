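# The rolling exploration loop: select which species/pairs to explore next
# (classic and uncertainty-aware criteria), which parameters to refine,
# invoke the energy oracle for refinements, and iterate to convergence.

#' Steering configuration
#'
#' Thresholds and mode switches for the exploration loop.  Defaults follow
#' the two operating points used in practice: classic steering with local
#' OAT sensitivities (`tau_max = 1e-3 mol^2 L^-2`, `tau_flux = 1e-2 mol
#' L^-1`, OAT refinement threshold `1e-2 mol L^-1`) and uncertainty-aware
#' steering with Morris sensitivities (`tau_max = 1e-2`, `tau_flux = 1e-1`,
#' `tau_ref = 5e-2 mol L^-1`).
#'
#' @param mode `"classic"` (point estimates) or `"uncertainty_aware"`
#'   (ensemble mean + standard deviation).
#' @param sensitivity `"oat"` or `"morris"`.
#' @param tau_flux Unimolecular exploration threshold on the concentration
#'   flux (mol L^-1).
#' @param tau_max Bimolecular exploration threshold on the product of
#'   maximum concentrations (mol^2 L^-2).
#' @param tau_ref Morris refinement threshold on mu*max expressed as a
#'   concentration change per full grid step (mol L^-1).
#' @param oat_refine_threshold OAT refinement threshold on delta c_max
#'   (mol L^-1).
#' @param tau_flux_kin OAT flux-screening threshold; defaults to `tau_flux`.
#' @param morris_screen_threshold Morris flux-screening threshold
#'   (mol L^-1), active above `morris_screen_size` parameters.
#' @param morris_screen_size Parameter count activating Morris screening.
#' @param max_iterations Iteration cap for the loop.
#' @param requeue_gain Relative criterion increase required to re-queue an
#'   already-explored target (guards against thrashing).
#' @return Object of class `steering_config`.
#' @export
steering_config <- function(mode = c("classic", "uncertainty_aware"),
                            sensitivity = c("oat", "morris"),
                            tau_flux = NULL, tau_max = NULL,
                            tau_ref = 5e-2, oat_refine_threshold = 1e-2,
                            tau_flux_kin = NULL,
                            morris_screen_threshold = 1e-9,
                            morris_screen_size = 1000L,
                            max_iterations = 10L,
                            requeue_gain = 0.1) {
  mode <- match.arg(mode)
  sensitivity <- if (missing(sensitivity) && mode == "uncertainty_aware")
    "morris" else match.arg(sensitivity)
  if (mode == "uncertainty_aware" && sensitivity != "morris")
    stop_kinsteer("uncertainty-aware steering needs Morris ensemble ",
                  "statistics; set sensitivity = \"morris\"")
  if (is.null(tau_flux)) tau_flux <- if (mode == "classic") 1e-2 else 1e-1
  if (is.null(tau_max)) tau_max <- if (mode == "classic") 1e-3 else 1e-2
  if (is.null(tau_flux_kin)) tau_flux_kin <- tau_flux
  stopifnot(tau_flux > 0, tau_max > 0, tau_ref > 0,
            oat_refine_threshold > 0, tau_flux_kin > 0)
  structure(list(mode = mode, sensitivity = sensitivity,
                 tau_flux = tau_flux, tau_max = tau_max, tau_ref = tau_ref,
                 oat_refine_threshold = oat_refine_threshold,
                 tau_flux_kin = tau_flux_kin,
                 morris_screen_threshold = morris_screen_threshold,
                 morris_screen_size = as.integer(morris_screen_size),
                 max_iterations = as.integer(max_iterations),
                 requeue_gain = requeue_gain),
            class = "steering_config")
}

#' Select exploration targets from a simulation or ensemble statistics
#'
#' Classic criteria: explore species `n` unimolecularly when
#' `c_flux_n > tau_flux`, and the unordered pair `(n, m)` (self-pairs
#' allowed) bimolecularly when `c_max_n * c_max_m > tau_max`.
#' Uncertainty-aware criteria replace each point value by the ensemble mean
#' plus one standard deviation from a Morris analysis:
#' `(mean + sd)(c_flux_n) > tau_flux` and
#' `(mean + sd)(c_max_n) * (mean + sd)(c_max_m) > tau_max`.
#' With all spreads zero the two modes select identically.
#'
#' @param x An `rn_sim` (classic mode) or `rn_morris` (uncertainty-aware
#'   mode).
#' @param config A [steering_config()].
#' @return List with `unimolecular` (character vector of species ids,
#'   with attribute `"criterion"`), and `bimolecular` (data.frame `a`, `b`,
#'   `criterion` of unordered pairs).
#' @export
select_exploration_targets <- function(x, config) {
  if (config$mode == "uncertainty_aware") {
    if (!inherits(x, "rn_morris"))
      stop_kinsteer("uncertainty-aware selection needs Morris ensemble ",
                    "statistics (an rn_morris object)")
    flux <- setNames(x$cflux_stats$mean + x$cflux_stats$sd,
                     x$cflux_stats$id)
    cmax <- setNames(x$cmax_stats$mean + x$cmax_stats$sd, x$cmax_stats$id)
  } else {
    if (!inherits(x, "rn_sim"))
      stop_kinsteer("classic selection needs a simulation result")
    flux <- x$c_flux
    cmax <- x$c_max
  }
  uni <- names(flux)[flux > config$tau_flux]
  crit_uni <- flux[uni]
  ids <- names(cmax)
  pairs <- NULL
  if (length(ids)) {
    idx <- which(outer(cmax, cmax) > config$tau_max, arr.ind = TRUE)
    idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
    pairs <- data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]],
                        criterion = cmax[idx[, 1]] * cmax[idx[, 2]],
                        stringsAsFactors = FALSE)
  }
  list(unimolecular = structure(uni, criterion = unname(crit_uni)),
       bimolecular = pairs %||%
         data.frame(a = character(0), b = character(0),
                    criterion = numeric(0)))
}

# Highest rank at which a parameter of the given kind can exist.
top_rank_for <- function(kind, n_ranks = 3L) {
  if (kind == "G") 2L else n_ranks
}

#' Select parameters for refinement from a sensitivity report
#'
#' OAT reports: refine parameters with `delta_cmax >= oat_refine_threshold`.
#' Morris reports: refine parameters whose `mu*max`, expressed as a
#' concentration change per full grid step (`mu*max * step_kj`), exceeds
#' `tau_ref`.  Parameters already at the top rank of their kind (species
#' free energies at rank 2, barriers at rank 3) are excluded, with a
#' warning when their sensitivity is large.
#'
#' @param report An `rn_oat` or `rn_morris`.
#' @param params The parameter table the report refers to.
#' @param config A [steering_config()].
#' @return Character vector of parameter ids to refine.
#' @export
select_refinement <- function(report, params, config) {
  if (inherits(report, "rn_oat")) {
    r <- report$report
    flagged <- r$id[r$screened & !r$failed &
                      !is.na(r$delta_cmax) &
                      r$delta_cmax >= config$oat_refine_threshold]
  } else if (inherits(report, "rn_morris")) {
    per_step <- report$mu_star_max * report$step_kj
    flagged <- names(per_step)[per_step > config$tau_ref]
  } else stop_kinsteer("unknown sensitivity report type")
  at_top <- vapply(flagged, function(pid) {
    row <- params[params$id == pid, ]
    row$barrierless || row$rank >= top_rank_for(row$kind)
  }, NA)
  if (any(at_top))
    warning("sensitive but unrefinable (already at top rank): ",
            paste(flagged[at_top], collapse = ", "))
  flagged[!at_top]
}

#' Apply refinements through the energy oracle
#'
#' Upgrades flagged species free energies to rank 2 and flagged activation
#' free energies directly to rank 3 (barriers skip rank 2), appending the
#' oracle-provided structures to the network.  A refusal by the oracle
#' leaves the parameter at its old rank and is recorded.
#'
#' @param net An [rn_network()].
#' @param refine_ids Parameter ids from [select_refinement()].
#' @param oracle An energy oracle, see [synthetic_oracle()] for the
#'   contract.
#' @return List with the updated `net`, `refined` and `refused` id vectors.
#' @export
apply_refinement <- function(net, refine_ids, oracle) {
  refined <- character(0); refused <- character(0)
  for (pid in refine_ids) {
    kind <- sub(":.*$", "", pid)
    target <- sub("^[^:]+:", "", pid)
    if (kind == "G") {
      st <- oracle$refine_species(target)
      if (is.null(st)) { refused <- c(refused, pid); next }
      sp <- net$species[[target]]
      sp$structures <- c(sp$structures, list(st))
      net$species[[target]] <- sp
    } else {
      st <- oracle$refine_barrier(target)
      if (is.null(st)) { refused <- c(refused, pid); next }
      rx <- net$reactions[[target]]
      rx$ts_structures <- c(rx$ts_structures, list(st))
      dp <- attr(st, "delta_pno")
      if (!is.null(dp)) rx$delta_pno <- dp
      net$reactions[[target]] <- rx
    }
    refined <- c(refined, pid)
  }
  list(net = net, refined = refined, refused = refused)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Kinetics-steered exploration with sensitivity-driven refinement
#'
#' The rolling loop: (1) ask the oracle to reveal reactions incident to the
#' current frontier (unimolecular targets and bimolecular pairs);
#' (2) assemble parameters and run the microkinetic simulation; (3) run the
#' configured sensitivity analysis; (4) refine flagged parameters through
#' the oracle's fidelity ladder; (5) recompute exploration targets
#' (classic or uncertainty-aware criteria) and iterate.  The loop stops when
#' an iteration produces no new exploration targets and no refinements, or
#' at `max_iterations` (flagged unconverged).
#'
#' Already-explored targets are only re-queued when their criterion value
#' has grown by more than `requeue_gain` (default 10 %) since they were
#' last explored.
#'
#' @param oracle Energy/discovery oracle; see [synthetic_oracle()] for the
#'   interface contract.
#' @param config A [steering_config()].
#' @param settings [simulation_settings()] for the inner simulations.
#' @param morris List of extra arguments for [morris_sensitivity()] (e.g.
#'   `trajectories`, `levels`, `seed`, `method`).
#' @return Object of class `rn_exploration`: final `net`, `params`,
#'   `result` (last baseline simulation), `state` (explored sets, refined
#'   parameters with rank history, iteration log) and `converged` flag.
#' @export
explore_network <- function(oracle, config, settings, morris = list()) {
  net <- rn_network(oracle$seed_species, list(), ranks = oracle$ranks,
                    validate = FALSE)
  explored_uni <- character(0); explored_pairs <- character(0)
  crit_uni <- numeric(0); crit_pair <- numeric(0)
  refined_all <- character(0)
  refused_all <- character(0)
  log <- list()
  seeds <- names(net$species)
  seed_pairs <- expand.grid(a = seeds, b = seeds, stringsAsFactors = FALSE)
  seed_pairs <- seed_pairs[seed_pairs$a <= seed_pairs$b, , drop = FALSE]
  seed_pairs$criterion <- Inf
  targets <- list(
    unimolecular = structure(seeds, criterion = rep(Inf, length(seeds))),
    bimolecular = seed_pairs)
  converged <- FALSE
  sim <- NULL; params <- NULL

  for (iter in seq_len(config$max_iterations)) {
    # -- discover ---------------------------------------------------------
    n_new_species <- 0L; n_new_reactions <- 0L
    add_discovery <- function(found) {
      for (sp in found$species) if (is.null(net$species[[sp$id]])) {
        net$species[[sp$id]] <<- sp
        n_new_species <<- n_new_species + 1L
      }
      for (rx in found$reactions) if (is.null(net$reactions[[rx$id]])) {
        net$reactions[[rx$id]] <<- rx
        n_new_reactions <<- n_new_reactions + 1L
      }
    }
    for (tg in targets$unimolecular) {
      add_discovery(oracle$discover("unimolecular", tg))
      explored_uni <- union(explored_uni, tg)
    }
    if (nrow(targets$bimolecular)) {
      for (r in seq_len(nrow(targets$bimolecular))) {
        ab <- c(targets$bimolecular$a[r], targets$bimolecular$b[r])
        add_discovery(oracle$discover("bimolecular", ab))
        explored_pairs <- union(explored_pairs, pair_key(ab[1], ab[2]))
      }
    }
    crit_uni[targets$unimolecular] <- attr(targets$unimolecular, "criterion")
    if (nrow(targets$bimolecular))
      crit_pair[pair_key(targets$bimolecular$a, targets$bimolecular$b)] <-
        targets$bimolecular$criterion
    validate_network(net)

    # -- simulate + sensitivity ------------------------------------------
    params <- assemble_parameters(net)
    sim <- simulate_network(net, params, settings)
    n_evals <- 1L
    if (config$sensitivity == "oat") {
      report <- oat_sensitivity(net, params, settings,
                                tau_flux_kin = config$tau_flux_kin,
                                baseline = sim)
      n_evals <- report$n_model_evals
    } else {
      margs <- c(list(net = net, params = params, settings = settings,
                      screen_threshold = config$morris_screen_threshold,
                      screen_size = config$morris_screen_size,
                      baseline = sim),
                 morris)
      report <- do.call(morris_sensitivity, margs)
      n_evals <- report$n_model_evals + 1L
    }

    # -- refine -----------------------------------------------------------
    flagged <- select_refinement(report, params, config)
    flagged <- setdiff(flagged, refined_all)  # never re-refine at same rank
    upd <- apply_refinement(net, flagged, oracle)
    net <- upd$net
    refined_all <- c(refined_all, upd$refined)
    refused_all <- union(refused_all, upd$refused)
    if (length(upd$refined)) {
      params <- assemble_parameters(net)
      sim <- simulate_network(net, params, settings)
      n_evals <- n_evals + 1L
    }

    # -- next targets ------------------------------------------------------
    sel_input <- if (config$mode == "uncertainty_aware") {
      if (length(upd$refined)) {
        margs <- c(list(net = net, params = params, settings = settings,
                        screen_threshold = config$morris_screen_threshold,
                        screen_size = config$morris_screen_size,
                        baseline = sim),
                   morris)
        report2 <- do.call(morris_sensitivity, margs)
        n_evals <- n_evals + report2$n_model_evals
        report2
      } else report
    } else sim
    sel <- select_exploration_targets(sel_input, config)

    fresh_uni <- vapply(seq_along(sel$unimolecular), function(ii) {
      id <- sel$unimolecular[ii]
      cr <- attr(sel$unimolecular, "criterion")[ii]
      !(id %in% explored_uni) ||
        (is.finite(crit_uni[id]) && cr > (1 + config$requeue_gain) * crit_uni[id])
    }, NA)
    new_uni <- sel$unimolecular[fresh_uni]
    attr(new_uni, "criterion") <- attr(sel$unimolecular, "criterion")[fresh_uni]
    bp <- sel$bimolecular
    if (nrow(bp)) {
      keys <- pair_key(bp$a, bp$b)
      fresh_bi <- !(keys %in% explored_pairs) |
        (is.finite(crit_pair[keys]) &
           bp$criterion > (1 + config$requeue_gain) * crit_pair[keys])
      fresh_bi[is.na(fresh_bi)] <- TRUE
      bp <- bp[fresh_bi, , drop = FALSE]
    }
    targets <- list(unimolecular = new_uni, bimolecular = bp)

    log[[iter]] <- data.frame(
      iteration = iter, n_species = length(net$species),
      n_reactions = length(net$reactions),
      n_new_species = n_new_species, n_new_reactions = n_new_reactions,
      n_model_evals = n_evals,
      n_flagged = length(flagged), n_refined = length(upd$refined),
      n_new_targets = length(new_uni) + nrow(bp))
    if (length(new_uni) == 0L && nrow(bp) == 0L &&
        length(upd$refined) == 0L) {
      converged <- TRUE
      break
    }
  }

  structure(list(net = net, params = params, result = sim,
                 state = list(explored_species = explored_uni,
                              explored_pairs = explored_pairs,
                              refined_parameters = refined_all,
                              refused_parameters = refused_all,
                              iteration_log = do.call(rbind, log)),
                 converged = converged,
                 config = config),
            class = "rn_exploration")
}

#' @export
print.rn_exploration <- function(x, ...) {
  cat("exploration (", x$config$mode, " / ", x$config$sensitivity, "): ",
      nrow(x$state$iteration_log), " iterations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  print(x$state$iteration_log, row.names = FALSE)
  invisible(x)
}
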