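# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`,
#' then restores the previous RNG state so callers' random streams are not
#' disturbed. With `seed = NULL` the code runs against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Derive per-stage seeds from a single run seed
#'
#' All randomness in a pipeline run flows from one seed; each stage gets an
#' independent derived seed so partial reruns reproduce exactly.
#'
#' @param seed Integer master seed.
#' @param n Number of derived seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seeds(1, 3)
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(n), length(n) == 1L, n >= 1)
  with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, as.integer(n)))
}

# Scalar validation with a readable message.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %s (got %s)", name, lower, x), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %s (got %s)", name, lower, x), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %s (got %s)", name, upper, x), call. = FALSE)
  }
  invisible(x)
}

# The four quadrant subgroup labels, in a fixed factor order.
quadrant_levels <- function() {
  c("MVD-high/Tcell_inf_GEP-high",
    "MVD-high/Tcell_inf_GEP-low",
    "MVD-low/Tcell_inf_GEP-high",
    "MVD-low/Tcell_inf_GEP-low")
}
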