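# Local one-at-a-time (OAT) sensitivity analysis: perturb each kinetic
# parameter to its uncertainty bounds, re-run the microkinetics, and score
# the largest change in any species' maximum concentration.

#' Perturb one kinetic parameter to an uncertainty bound
#'
#' Replaces `x_i` by `x_i - u(x_i)` (`direction = "lower"`) or
#' `x_i + u(x_i)` (`"upper"`), then re-applies the barrier clamps via
#' [clamp_parameters()]: any reaction whose backward barrier became negative
#' has its forward barrier raised so the backward barrier is exactly zero,
#' and negative forward barriers are raised to zero.
#'
#' @param net The network (needed to re-derive reaction free energies for
#'   the clamp).
#' @param params An `rn_params` table.
#' @param i Parameter index or id.
#' @param direction `"lower"` or `"upper"`.
#' @return The perturbed, clamped parameter table.
#' @export
perturb_parameter <- function(net, params, i, direction = c("lower", "upper")) {
  direction <- match.arg(direction)
  if (is.character(i)) i <- match(i, params$id)
  if (is.na(i) || i < 1 || i > nrow(params))
    stop_kinsteer("invalid parameter index")
  shift <- if (direction == "lower") -params$u[i] else params$u[i]
  params$value[i] <- params$value[i] + shift
  clamp_parameters(net, params)
}

#' Flux-based screening of OAT parameters
#'
#' Returns the ids of the free-energy parameters of species whose
#' concentration flux exceeds `tau_flux_kin`, plus the activation-energy
#' parameters of reactions whose flux exceeds the same threshold, based on a
#' baseline simulation.  Parameters of inert species/reactions cannot change
#' the steering outcome and are skipped.
#'
#' @param baseline An `rn_sim` from [simulate_network()].
#' @param params An `rn_params` table.
#' @param tau_flux_kin Screening threshold in mol L^-1.
#' @return Character vector of screened-in parameter ids.
#' @export
oat_screen <- function(baseline, params, tau_flux_kin) {
  keep_G <- params$kind == "G" &
    baseline$c_flux[params$target] > tau_flux_kin
  keep_A <- params$kind == "dGa" &
    baseline$F[params$target] > tau_flux_kin
  params$id[which(keep_G | keep_A)]
}

#' Local OAT sensitivity analysis
#'
#' For each screened parameter, evaluates the model at the lower and upper
#' uncertainty bounds and records
#' `delta_c_max_i = max_{n, l/u} |c_max_n(perturbed) - c_max_n(baseline)|`.
#'
#' @param net An [rn_network()].
#' @param params Parameter table ([assemble_parameters()]).
#' @param settings [simulation_settings()].
#' @param tau_flux_kin Screening threshold (mol L^-1); see [oat_screen()].
#' @param baseline Optional precomputed baseline `rn_sim` (re-simulated if
#'   missing).
#' @return Object of class `rn_oat`: data.frame `report` (parameter id,
#'   kind, `delta_cmax`, `screened`, `failed`), `baseline`, `n_model_evals`.
#' @export
oat_sensitivity <- function(net, params, settings, tau_flux_kin,
                            baseline = NULL) {
  n_evals <- 0L
  if (is.null(baseline)) {
    baseline <- simulate_network(net, params, settings)
    n_evals <- n_evals + 1L
  } else n_evals <- n_evals + 1L
  screened <- oat_screen(baseline, params, tau_flux_kin)
  delta <- setNames(rep(NA_real_, nrow(params)), params$id)
  failed <- setNames(rep(FALSE, nrow(params)), params$id)
  base_cmax <- baseline$c_max
  for (pid in screened) {
    d <- 0; ok <- TRUE
    for (dir in c("lower", "upper")) {
      pert <- perturb_parameter(net, params, pid, dir)
      sim <- tryCatch(simulate_network(net, pert, settings),
                      error = function(e) e)
      n_evals <- n_evals + 1L
      if (inherits(sim, "error")) { ok <- FALSE; next }
      d <- max(d, max(abs(sim$c_max - base_cmax)))
    }
    if (ok) delta[pid] <- d else failed[pid] <- TRUE
  }
  report <- data.frame(id = params$id, kind = params$kind,
                       target = params$target,
                       delta_cmax = as.numeric(delta),
                       screened = params$id %in% screened,
                       failed = as.logical(failed),
                       stringsAsFactors = FALSE)
  report$delta_cmax[!report$screened] <- NA_real_
  structure(list(report = report, baseline = baseline,
                 n_model_evals = n_evals),
            class = "rn_oat")
}

#' @export
print.rn_oat <- function(x, ...) {
  sc <- x$report[x$report$screened & !x$report$failed, ]
  cat("OAT sensitivity: ", sum(x$report$screened), "/", nrow(x$report),
      " parameters screened in, ", x$n_model_evals, " model evaluations\n",
      sep = "")
  sc <- sc[order(-sc$delta_cmax), ]
  print(utils::head(sc[, c("id", "delta_cmax")], 8), row.names = FALSE)
  invisible(x)
}

#' Export an OAT report as CSV
#'
#' @param oat An `rn_oat`.
#' @param path Output file.
#' @export
write_oat_csv <- function(oat, path) {
  utils::write.csv(oat$report, path, row.names = FALSE)
  invisible(path)
}
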