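# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("rtopmap_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_invalid(...)
  invisible(TRUE)
}

#' @keywords internal
unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}

vec_norm <- function(v) sqrt(sum(v^2))

normalize_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop_invalid("cannot normalize a (near-)zero vector")
  v / n
}

# Angle between two vectors, radians.
angle_between <- function(a, b) {
  ca <- sum(normalize_vec(a) * normalize_vec(b))
  acos(max(-1, min(1, ca)))
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Uniform random unit vectors on S^2 (n x 3).
random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  unit_rows(m)
}
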