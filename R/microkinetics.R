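# Mass-action microkinetics: Eyring rate constants, equilibrium constants,
# stiff ODE integration (deSolve), reaction and species concentration fluxes.

#' Eyring rate constant
#'
#' Transition-state-theory rate constant
#' `k = (kB*T/h) * exp(-dG_fwd / (R*T))` with transmission coefficient 1.
#' Under the 1 mol L^-1 standard state, bimolecular constants carry implicit
#' L mol^-1 s^-1 units; no conversion is applied.
#'
#' @param dG_fwd Activation free energy in kJ mol^-1, must be >= 0 (clamp
#'   negative barriers before calling).
#' @param T Temperature in K.
#' @return Rate constant (s^-1 times the implicit concentration units).
#' @export
eyring_rate <- function(dG_fwd, T) {
  if (T <= 0) stop_kinsteer("temperature must be positive")
  if (any(dG_fwd < -1e-9))
    stop_kinsteer("negative activation free energy passed to eyring_rate(); ",
                  "clamp barriers first")
  (.kB * T / .h) * exp(-pmax(dG_fwd, 0) * 1000 / (.Rgas * T))
}

#' Equilibrium constant of a reaction
#'
#' `K = exp(-(G_rhs - G_lhs) / (R*T))`, dimensionless under the 1 mol L^-1
#' standard state.
#'
#' @param G_lhs,G_rhs Summed side free energies in kJ mol^-1.
#' @param T Temperature in K.
#' @return Equilibrium constant.
#' @export
equilibrium_constant <- function(G_lhs, G_rhs, T) {
  if (T <= 0) stop_kinsteer("temperature must be positive")
  exp(-(G_rhs - G_lhs) * 1000 / (.Rgas * T))
}

#' Forward and backward mass-action rates of a reaction
#'
#' `f+ = k+ * prod(c_n^S-_nI)`, `f- = k- * prod(c_n^S+_nI)`.
#'
#' @param c Named concentration vector (mol L^-1, >= 0).
#' @param reaction An [rn_reaction()].
#' @param k_plus,k_minus Rate constants.
#' @return List with `f_plus` and `f_minus`.
#' @export
reaction_rates <- function(c, reaction, k_plus, k_minus) {
  if (any(c < 0)) stop_kinsteer("negative concentrations")
  list(f_plus = k_plus * prod(c[names(reaction$lhs)]^reaction$lhs),
       f_minus = k_minus * prod(c[names(reaction$rhs)]^reaction$rhs))
}

#' Simulation settings
#'
#' @param T Temperature in K.
#' @param t_max End time in s.
#' @param t0 Start time in s.
#' @param c0 Named initial concentrations (mol L^-1); defaults to the
#'   species' `c0` fields.
#' @param rel_tol,abs_tol Solver tolerances (abs_tol in mol L^-1).
#' @param n_out Minimum number of output-grid points (log-spaced after the
#'   first second, so that fluxes of fast transients are resolved).
#' @param times Optional explicit output times overriding the default grid.
#' @param max_steps Maximum internal solver steps.
#' @return Object of class `sim_settings`.
#' @export
simulation_settings <- function(T, t_max, t0 = 0, c0 = NULL,
                                rel_tol = 1e-8, abs_tol = 1e-12,
                                n_out = 512L, times = NULL,
                                max_steps = 100000L) {
  if (T <= 0) stop_kinsteer("T must be > 0")
  if (!(t_max > t0 && t0 >= 0)) stop_kinsteer("need t_max > t0 >= 0")
  if (!is.null(c0) && any(c0 < 0)) stop_kinsteer("c0 must be >= 0")
  structure(list(T = T, t0 = t0, t_max = t_max, c0 = c0,
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 n_out = as.integer(n_out), times = times,
                 max_steps = as.integer(max_steps)),
            class = "sim_settings")
}

# Output grid: linear over the first second, log-spaced beyond, always
# containing t0 and t_max.
output_grid <- function(settings) {
  if (!is.null(settings$times)) {
    tt <- sort(unique(c(settings$t0, settings$times, settings$t_max)))
    return(tt[tt >= settings$t0 & tt <= settings$t_max])
  }
  t0 <- settings$t0; t1 <- settings$t_max; n <- max(settings$n_out, 16L)
  span <- t1 - t0
  if (span <= 1) return(seq(t0, t1, length.out = n))
  n_head <- max(16L, n %/% 8L)
  head <- seq(t0, t0 + 1, length.out = n_head)
  tail <- t0 + 10^seq(0, log10(span), length.out = n - n_head + 1L)
  sort(unique(c(head, tail, t1)))
}

# Derive per-reaction rate data from a parameter table: effective forward
# barrier (clamped), backward barrier, k+, k-, K.  k- is constructed as k+/K
# so detailed balance holds by construction; for reactions whose K over- or
# underflows, k- falls back to the (equivalent) Eyring form of the backward
# barrier.
derive_rates <- function(net, params, T) {
  dG_r <- reaction_dG_r(net, params)
  idx <- which(params$kind == "dGa")
  stored <- params$value[idx]
  stored[params$barrierless[idx]] <- 0
  names(stored) <- params$target[idx]
  stored <- stored[names(net$reactions)]
  dG_eff <- pmax(stored, 0, dG_r)
  dG_bwd <- dG_eff - dG_r
  k_plus <- eyring_rate(dG_eff, T)
  K <- equilibrium_constant(0, dG_r, T)
  k_minus <- k_plus / K
  bad <- !is.finite(k_minus)
  if (any(bad)) k_minus[bad] <- eyring_rate(dG_bwd[bad], T)
  list(dG_fwd = dG_eff, dG_bwd = dG_bwd, dG_r = dG_r,
       k_plus = k_plus, k_minus = k_minus, K = K)
}

# Stoichiometry matrices (species x reactions).
stoich_matrices <- function(net) {
  sp <- names(net$species); rx <- names(net$reactions)
  Sm <- matrix(0, length(sp), length(rx), dimnames = list(sp, rx))
  Sp <- Sm
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    Sm[names(r$lhs), j] <- r$lhs
    Sp[names(r$rhs), j] <- r$rhs
  }
  list(Sm = Sm, Sp = Sp)
}

# Forward/backward rate matrices evaluated on a concentration matrix
# (species x time); returns reactions x time matrices.
eval_rates <- function(cmat, net, k_plus, k_minus) {
  cp <- pmax(cmat, 0)
  sp <- rownames(cmat)
  n_t <- ncol(cmat); n_rx <- length(net$reactions)
  fp <- matrix(0, n_rx, n_t); fm <- matrix(0, n_rx, n_t)
  for (j in seq_len(n_rx)) {
    r <- net$reactions[[j]]
    v <- rep(k_plus[j], n_t)
    for (s in names(r$lhs)) v <- v * cp[s, ]^r$lhs[[s]]
    fp[j, ] <- v
    v <- rep(k_minus[j], n_t)
    for (s in names(r$rhs)) v <- v * cp[s, ]^r$rhs[[s]]
    fm[j, ] <- v
  }
  list(f_plus = fp, f_minus = fm)
}

#' Integrate the mass-action ODE system of a network
#'
#' Solves `dc_n/dt = sum_I (S+_nI - S-_nI) (f+_I - f-_I)` from the initial
#' concentrations with a stiff-capable solver (`deSolve::lsoda`), on an
#' output grid dense enough (log-spaced after the first second) that maximum
#' concentrations and flux integrals are resolved.
#'
#' @param net An [rn_network()].
#' @param params Parameter table from [assemble_parameters()] (possibly
#'   perturbed).
#' @param settings A [simulation_settings()] object.
#' @return Object of class `rn_sim`: `times`, concentration matrix `c`
#'   (species x time), `c_max`, `c_flux`, per-reaction flux `F`, and
#'   `rates_meta` (k+, k-, K, effective barriers).
#' @export
simulate_network <- function(net, params, settings) {
  sp <- names(net$species)
  c0 <- vapply(net$species, `[[`, 0, "c0")
  if (!is.null(settings$c0)) c0[names(settings$c0)] <- settings$c0
  names(c0) <- sp
  times <- output_grid(settings)

  if (length(net$reactions) == 0L) {
    cmat <- matrix(rep(c0, length(times)), nrow = length(sp),
                   dimnames = list(sp, NULL))
    res <- list(times = times, c = cmat, c_max = c0,
                c_flux = setNames(numeric(length(sp)), sp),
                F = setNames(numeric(0), character(0)),
                rates_meta = NULL, settings = settings)
    class(res) <- "rn_sim"
    return(res)
  }

  rates <- derive_rates(net, params, settings$T)
  S <- stoich_matrices(net)
  Snet <- S$Sp - S$Sm
  kp <- rates$k_plus; km <- rates$k_minus

  rx_lhs <- lapply(net$reactions, function(r) match(names(r$lhs), sp))
  rx_rhs <- lapply(net$reactions, function(r) match(names(r$rhs), sp))
  rx_ls <- lapply(net$reactions, function(r) as.numeric(r$lhs))
  rx_rs <- lapply(net$reactions, function(r) as.numeric(r$rhs))
  n_rx <- length(net$reactions)

  deriv <- function(t, y, p) {
    cp <- pmax(y, 0)
    fp <- numeric(n_rx); fm <- numeric(n_rx)
    for (j in seq_len(n_rx)) {
      fp[j] <- kp[j] * prod(cp[rx_lhs[[j]]]^rx_ls[[j]])
      fm[j] <- km[j] * prod(cp[rx_rhs[[j]]]^rx_rs[[j]])
    }
    list(as.vector(Snet %*% (fp - fm)))
  }

  out <- deSolve::lsoda(y = c0, times = times, func = deriv, parms = NULL,
                        rtol = settings$rel_tol, atol = settings$abs_tol,
                        maxsteps = settings$max_steps)
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    worst <- names(net$reactions)[order(-pmax(kp, km))][1:min(3, n_rx)]
    stop_kinsteer("ODE integration failed (istate ", istate,
                  "); stiffest reactions (largest rate constants): ",
                  paste(worst, collapse = ", "))
  }
  cmat <- t(out[, sp, drop = FALSE])
  worst_neg <- min(cmat, 0)
  if (worst_neg < -10 * settings$abs_tol)
    stop_kinsteer("negative concentration excursion ", worst_neg,
                  " exceeds 10*abs_tol")
  cmat[cmat < 0] <- 0

  fl <- eval_rates(cmat, net, kp, km)
  Fband <- fl$f_plus + fl$f_minus
  Fint <- apply(Fband, 1, function(y) trapz(times, y))
  names(Fint) <- names(net$reactions)
  c_flux <- as.vector((S$Sp + S$Sm) %*% Fint)
  names(c_flux) <- sp

  res <- list(times = times, c = cmat,
              c_max = apply(cmat, 1, max),
              c_flux = c_flux, F = Fint,
              rates_meta = rates, settings = settings)
  class(res) <- "rn_sim"
  res
}

#' Reaction and species concentration fluxes of a completed simulation
#'
#' The per-reaction flux `F_I` is the time integral of `f+_I + f-_I` over
#' the simulation horizon (trapezoidal quadrature on the solver output
#' grid); the per-species flux is `c_flux_n = sum_I (S+_nI + S-_nI) F_I`.
#'
#' @param result An `rn_sim` from [simulate_network()].
#' @param net The network it was computed on.
#' @return List with `F` (per reaction) and `c_flux` (per species), both in
#'   mol L^-1.
#' @export
fluxes <- function(result, net) {
  list(F = result$F, c_flux = result$c_flux)
}

#' @export
print.rn_sim <- function(x, ...) {
  cat("microkinetic simulation: ", nrow(x$c), " species, ",
      length(x$F), " reactions, t in [", x$times[1], ", ",
      x$times[length(x$times)], "] s\n", sep = "")
  top <- sort(x$c_max, decreasing = TRUE)
  top <- top[seq_len(min(5, length(top)))]
  cat("top c_max (mol/L):\n")
  print(signif(top, 4))
  invisible(x)
}

#' Export concentration trajectories as CSV
#'
#' @param result An `rn_sim`.
#' @param path Output file; first column `time_s`, one column per species.
#' @export
write_trajectories_csv <- function(result, path) {
  df <- data.frame(time_s = result$times, t(result$c), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export maximum concentrations and fluxes as CSV
#'
#' Writes one row per species (`c_max`, `c_flux`) and one per reaction
#' (`F`), keyed by id.
#'
#' @param result An `rn_sim`.
#' @param path Output file.
#' @export
write_flux_report_csv <- function(result, path) {
  df <- rbind(
    data.frame(id = names(result$c_max), kind = "species",
               c_max = as.numeric(result$c_max),
               c_flux = as.numeric(result$c_flux), F = NA_real_),
    if (length(result$F))
      data.frame(id = names(result$F), kind = "reaction",
                 c_max = NA_real_, c_flux = NA_real_,
                 F = as.numeric(result$F)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
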