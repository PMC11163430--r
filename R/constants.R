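# Physical constants (CODATA 2018).  Energies are kJ mol^-1 package-wide;
# conversion to J happens only inside Boltzmann exponents.

.kB <- 1.380649e-23      # J K^-1
.h  <- 6.62607015e-34    # J s
.Rgas <- 8.314462618     # J mol^-1 K^-1

#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  Used to make oracles and designs
# reproducible without clobbering user RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic 31-bit hash of a string, for deriving per-entity RNG streams
# from a base seed.  Polynomial rolling hash mod (2^31 - 1).
str_hash31 <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  m <- 2147483647
  for (cc in codes) h <- (h * 131 + cc) %% m
  as.integer(h)
}

# Combine a base seed with an entity label into a reproducible child seed.
child_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 2654435761 + str_hash31(label)) %% 2147483647)
}

# Trapezoidal quadrature on a (sorted) grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

stop_kinsteer <- function(..., class = "kinsteer_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
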