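## Internal validation and unit helpers shared across modules.

# Assert that `x` is a single finite number, optionally strictly positive.
check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be strictly positive (got %g).", name, x))
  }
  if (nonneg && x < 0) {
    abort(sprintf("`%s` must be non-negative (got %g).", name, x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name)
  if (x < min || x != round(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Pa.s -> centipoise and back
pas_to_cp <- function(x) x * 1e3
cp_to_pas <- function(x) x * 1e-3

# Pa -> dyn/cm^2 (1 Pa = 10 dyn/cm^2)
pa_to_dyn_cm2 <- function(x) x * 10

# Stokes-Einstein diffusivity (m^2/s) for a sphere of radius `a` (m) in a
# Newtonian fluid of viscosity `eta` (Pa.s) at temperature `temp` (K).
stokes_einstein_D <- function(eta, a, temp) {
  .kB * temp / (6 * pi * eta * a)
}

# Deterministic per-stage seed derived from a user seed; keeps independent
# stages decoupled while remaining reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
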