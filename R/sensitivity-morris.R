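# Morris elementary-effects sensitivity analysis over the free-energy
# parameter space: level grids, trajectory sampling (random and
# spread-maximizing), elementary effects, mu* aggregation, and ensemble
# statistics of c_max and c_flux.

#' Per-parameter level grid for a Morris design
#'
#' Builds `p` equally spaced values spanning the uncertainty interval
#' `[x - u, x + u]` (inclusive) of each parameter.  Parameters with `u = 0`
#' have a degenerate grid and are excluded from the design.
#'
#' @param params An `rn_params` table (or any data.frame with `value`, `u`,
#'   `id`).
#' @param levels Number of grid levels `p >= 2`.
#' @return List with `grid` (named list of level vectors), `lower`, `upper`
#'   (named numeric) and `excluded` (ids with zero uncertainty).
#' @export
morris_grid <- function(params, levels = 4L) {
  levels <- as.integer(levels)
  if (levels < 2L) stop_kinsteer("need at least 2 grid levels")
  active <- params$u > 0
  lo <- params$value[active] - params$u[active]
  hi <- params$value[active] + params$u[active]
  names(lo) <- names(hi) <- params$id[active]
  grid <- lapply(seq_along(lo),
                 function(i) seq(lo[i], hi[i], length.out = levels))
  names(grid) <- params$id[active]
  list(grid = grid, lower = lo, upper = hi,
       excluded = params$id[!active], levels = levels)
}

#' Morris design: trajectories through the parameter grid
#'
#' Samples `trajectories` one-at-a-time trajectories of `k + 1` points in
#' the normalized unit hypercube discretized to `levels` levels per axis.
#' Each trajectory starts at a random grid point and changes every parameter
#' exactly once, in random order, by the normalized step
#' `delta = levels / (2 (levels - 1))`; changed parameters are not returned
#' to their initial values.  `method = "spread_maximizing"` draws a pool of
#' `pool_factor * trajectories` random candidates and greedily selects the
#' subset with maximal summed squared pairwise trajectory distance
#' (Euclidean point-pair distances); the exact combinatorial selection is
#' infeasible for realistic sizes.
#'
#' @param params An `rn_params` table.
#' @param levels Grid levels `p` (default 4).
#' @param trajectories Number of trajectories `N` (default 20).
#' @param method `"random"` or `"spread_maximizing"`.
#' @param seed Integer seed; the design is fully reproducible from it.
#' @param pool_factor Candidate pool multiplier for the spread-maximizing
#'   variant.
#' @param include Optional character vector of parameter ids to restrict the
#'   design to (after dropping zero-uncertainty parameters).
#' @return Object of class `morris_design`: normalized trajectory point
#'   matrices, step bookkeeping, bounds and metadata.
#' @export
morris_design <- function(params, levels = 4L, trajectories = 20L,
                          method = c("random", "spread_maximizing"),
                          seed = 1L, pool_factor = 50L, include = NULL) {
  method <- match.arg(method)
  g <- morris_grid(params, levels)
  ids <- names(g$lower)
  if (!is.null(include)) ids <- intersect(ids, include)
  k <- length(ids)
  if (k < 1L) stop_kinsteer("no parameters with positive uncertainty")
  N <- as.integer(trajectories)
  if (N < 1L) stop_kinsteer("need at least one trajectory")
  p <- g$levels
  delta <- p / (2 * (p - 1))
  lev <- seq(0, 1, length.out = p)

  sample_one <- function() {
    # per-axis: random step sign, then a start level from which that step
    # stays inside [0, 1]
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    start <- numeric(k)
    for (i in seq_len(k)) {
      ok <- lev[lev + sgn[i] * delta >= -1e-12 &
                lev + sgn[i] * delta <= 1 + 1e-12]
      start[i] <- ok[sample.int(length(ok), 1)]
    }
    ord <- sample.int(k)
    pts <- matrix(0, k + 1L, k)
    pts[1L, ] <- start
    x <- start
    for (s in seq_len(k)) {
      x[ord[s]] <- x[ord[s]] + sgn[ord[s]] * delta
      pts[s + 1L, ] <- x
    }
    list(points = pmin(pmax(pts, 0), 1), order = ord, sign = sgn)
  }

  trajs <- with_seed(as.integer(seed), {
    if (method == "random") {
      lapply(seq_len(N), function(r) sample_one())
    } else {
      M <- max(N, as.integer(pool_factor) * N)
      pool <- lapply(seq_len(M), function(r) sample_one())
      if (M == N) pool else select_spread(pool, N)
    }
  })

  structure(list(trajectories = trajs, param_ids = ids,
                 excluded = union(g$excluded, setdiff(names(g$lower), ids)),
                 lower = g$lower[ids], upper = g$upper[ids],
                 levels = p, delta = delta, n_trajectories = N,
                 method = method, seed = as.integer(seed)),
            class = "morris_design")
}

# Greedy spread-maximizing subset selection: start from the trajectory
# farthest from the pool centroid, then repeatedly add the candidate with
# the largest summed squared distance to the already-selected set.
select_spread <- function(pool, N) {
  M <- length(pool)
  flat <- vapply(pool, function(tr) as.vector(tr$points),
                 numeric(length(pool[[1]]$points)))
  centroid <- rowMeans(flat)
  d0 <- colSums((flat - centroid)^2)
  sel <- which.max(d0)
  acc <- numeric(M)  # running sum of squared distances to selected
  repeat {
    last <- sel[length(sel)]
    for (m in seq_len(M)) {
      if (m %in% sel) next
      acc[m] <- acc[m] + traj_distance(pool[[m]], pool[[last]])^2
    }
    if (length(sel) >= N) break
    cand <- setdiff(seq_len(M), sel)
    sel <- c(sel, cand[which.max(acc[cand])])
    if (length(sel) == N) break
  }
  pool[sel]
}

# Campolongo trajectory distance: sum of Euclidean distances between all
# point pairs of two trajectories.
traj_distance <- function(a, b) {
  A <- a$points; B <- b$points
  cross <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sum(sqrt(pmax(cross, 0)))
}

# Denormalize a trajectory point to parameter units.
denorm_point <- function(z, design) {
  design$lower + z * (design$upper - design$lower)
}

#' Evaluate a model along a Morris design
#'
#' Runs `model_fn` at every trajectory point.  `model_fn(x)` receives the
#' full named parameter vector in original units (design parameters set to
#' the trajectory point, all others at baseline) and must return a named
#' numeric vector of outputs (or a list of such vectors).
#'
#' @param model_fn Model evaluator.
#' @param design A [morris_design()].
#' @return List (one per trajectory) of lists of model outputs, for
#'   [elementary_effects()].
#' @keywords internal
morris_evaluate <- function(model_fn, design) {
  lapply(design$trajectories, function(tr) {
    lapply(seq_len(nrow(tr$points)), function(s) {
      x <- denorm_point(tr$points[s, ], design)
      names(x) <- design$param_ids
      model_fn(x)
    })
  })
}

#' Elementary effects and mu* from Morris model evaluations
#'
#' For the step of trajectory `r` that changes parameter `i`, the elementary
#' effect on output `n` is
#' `EE_nir = (y_n(after) - y_n(before)) / Delta_i`, with `Delta_i` the
#' signed step in original parameter units (kJ mol^-1).  `mu*_ni` is the
#' mean of `|EE_nir|` over trajectories; `mu*max_i = max_n mu*_ni`.
#'
#' @param evals Evaluations from [morris_evaluate()]: per trajectory, a list
#'   of named output vectors (one per trajectory point).
#' @param design The [morris_design()] that generated them.
#' @return List with `mu_star` (outputs x parameters matrix),
#'   `mu_star_max` (per parameter), `ee` (per-trajectory effects array) and
#'   `step_kj` (unsigned grid step per parameter in original units).
#' @export
elementary_effects <- function(evals, design) {
  ids <- design$param_ids
  k <- length(ids)
  N <- length(evals)
  if (N != design$n_trajectories)
    stop_kinsteer("evaluation list does not match design: ", N,
                  " trajectories, expected ", design$n_trajectories)
  out_names <- names(evals[[1]][[1]])
  n_out <- length(out_names)
  range_kj <- design$upper - design$lower
  step_kj <- design$delta * range_kj
  abs_ee <- array(NA_real_, dim = c(n_out, k, N),
                  dimnames = list(out_names, ids, NULL))
  for (r in seq_len(N)) {
    tr <- design$trajectories[[r]]
    ys <- evals[[r]]
    if (length(ys) != k + 1L)
      stop_kinsteer("trajectory ", r, " has ", length(ys),
                    " evaluations, expected ", k + 1L)
    for (s in seq_len(k)) {
      i <- tr$order[s]
      d_signed <- tr$sign[i] * step_kj[i]
      ee <- (ys[[s + 1L]] - ys[[s]]) / d_signed
      abs_ee[, i, r] <- abs(ee[out_names])
    }
  }
  mu_star <- apply(abs_ee, c(1, 2), mean)
  mu_star_max <- apply(mu_star, 2, max)
  list(mu_star = mu_star, mu_star_max = mu_star_max,
       ee = abs_ee, step_kj = step_kj)
}

#' Flux-based screening for large Morris designs
#'
#' For models with more than `activation_size` parameters, restricts the
#' Morris analysis to parameters of species and reactions whose baseline
#' fluxes exceed `threshold` (default 1e-9 mol L^-1); smaller models are
#' analyzed in full.
#'
#' @param baseline Baseline `rn_sim`.
#' @param params An `rn_params` table.
#' @param threshold Flux threshold in mol L^-1.
#' @param activation_size Parameter count above which screening activates.
#' @return Character vector of retained parameter ids.
#' @export
morris_screen <- function(baseline, params, threshold = 1e-9,
                          activation_size = 1000L) {
  if (nrow(params) <= activation_size) return(params$id)
  oat_screen(baseline, params, threshold)
}

#' Ensemble statistics over Morris model evaluations
#'
#' Arithmetic mean and sample standard deviation, per output, over all
#' `N * (k + 1)` model evaluations of a Morris analysis.  These spreads are
#' the uncertainty measure used by the uncertainty-aware exploration
#' criteria.
#'
#' @param values Numeric matrix, evaluations in rows, outputs in columns.
#' @return data.frame with columns `id`, `mean`, `sd`.
#' @export
ensemble_statistics <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2L)
    stop_kinsteer("ensemble statistics require at least 2 model evaluations")
  data.frame(id = colnames(values),
             mean = colMeans(values),
             sd = apply(values, 2, stats::sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Morris sensitivity analysis of a reaction network
#'
#' Builds a Morris design over the kinetic parameters (grid spanning each
#' parameter's uncertainty interval), simulates the network at every
#' trajectory point (barrier clamps applied at each point), and aggregates
#' elementary effects on the maximum concentrations plus ensemble statistics
#' of `c_max` and `c_flux`.
#'
#' @param net An [rn_network()].
#' @param params Parameter table.
#' @param settings [simulation_settings()].
#' @param levels,trajectories,method,seed,pool_factor Design controls, see
#'   [morris_design()].
#' @param screen_threshold,screen_size Screening controls, see
#'   [morris_screen()].
#' @param baseline Optional precomputed baseline `rn_sim`.
#' @return Object of class `rn_morris`: `mu_star` (species x parameter),
#'   `mu_star_max`, `step_kj`, `cmax_stats`, `cflux_stats`, `design`,
#'   `n_model_evals`, `baseline`.
#' @export
morris_sensitivity <- function(net, params, settings,
                               levels = 4L, trajectories = 20L,
                               method = c("random", "spread_maximizing"),
                               seed = 1L, pool_factor = 50L,
                               screen_threshold = 1e-9,
                               screen_size = 1000L,
                               baseline = NULL) {
  method <- match.arg(method)
  if (is.null(baseline)) baseline <- simulate_network(net, params, settings)
  keep <- morris_screen(baseline, params, screen_threshold, screen_size)
  design <- morris_design(params, levels = levels,
                          trajectories = trajectories, method = method,
                          seed = seed, pool_factor = pool_factor,
                          include = keep)
  idx <- match(design$param_ids, params$id)
  cmax_acc <- NULL; cflux_acc <- NULL
  model_fn <- function(x) {
    p <- params
    p$value[idx] <- x
    p <- clamp_parameters(net, p)
    sim <- simulate_network(net, p, settings)
    cmax_acc[[length(cmax_acc) + 1L]] <<- sim$c_max
    cflux_acc[[length(cflux_acc) + 1L]] <<- sim$c_flux
    sim$c_max
  }
  evals <- morris_evaluate(model_fn, design)
  ee <- elementary_effects(evals, design)
  cmax_mat <- do.call(rbind, cmax_acc)
  cflux_mat <- do.call(rbind, cflux_acc)
  structure(list(mu_star = ee$mu_star, mu_star_max = ee$mu_star_max,
                 step_kj = ee$step_kj,
                 cmax_stats = ensemble_statistics(cmax_mat),
                 cflux_stats = ensemble_statistics(cflux_mat),
                 design = design,
                 n_model_evals = nrow(cmax_mat),
                 baseline = baseline),
            class = "rn_morris")
}

#' @export
print.rn_morris <- function(x, ...) {
  cat("Morris sensitivity: ", length(x$design$param_ids), " parameters, ",
      x$design$n_trajectories, " trajectories (", x$design$method, "), ",
      x$n_model_evals, " model evaluations\n", sep = "")
  ord <- order(-x$mu_star_max)
  top <- data.frame(id = names(x$mu_star_max)[ord],
                    mu_star_max = x$mu_star_max[ord])
  print(utils::head(top, 8), row.names = FALSE)
  invisible(x)
}

#' Export a Morris report as CSV files
#'
#' Writes the mu* matrix and the ensemble statistics next to each other:
#' `<stem>_mu_star.csv`, `<stem>_cmax_stats.csv`, `<stem>_cflux_stats.csv`.
#'
#' @param morris An `rn_morris`.
#' @param stem Output path stem.
#' @export
write_morris_csv <- function(morris, stem) {
  utils::write.csv(as.data.frame(morris$mu_star),
                   paste0(stem, "_mu_star.csv"))
  utils::write.csv(morris$cmax_stats, paste0(stem, "_cmax_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(morris$cflux_stats, paste0(stem, "_cflux_stats.csv"),
                   row.names = FALSE)
  invisible(stem)
}

#' Dump a Morris design as JSON for reproducibility
#'
#' @param design A [morris_design()].
#' @param path Output file.
#' @export
write_morris_design_json <- function(design, path) {
  obj <- list(param_ids = design$param_ids, levels = design$levels,
              delta = design$delta, n_trajectories = design$n_trajectories,
              method = design$method, seed = design$seed,
              lower = as.list(design$lower), upper = as.list(design$upper),
              trajectories = lapply(design$trajectories, function(tr)
                list(points = tr$points, order = tr$order, sign = tr$sign)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
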