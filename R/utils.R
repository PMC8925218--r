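# Internal helpers: argument checks, seed derivation, unit conversion.

stopf <- function(fmt, ..., class = "heelpad_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "heelpad_error")))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name, class = "invalid_config_error")
  if (x < lower || (strict_lower && x <= lower) ||
      x > upper || (strict_upper && x >= upper))
    stopf("'%s' = %g is outside its valid range", name, x,
          class = "invalid_config_error")
  invisible(x)
}

#' Derive a reproducible integer sub-seed
#'
#' Hashes an arbitrary key (e.g. master seed, subject id, side, condition)
#' into an integer in `[1, 2^31 - 2]` with a polynomial rolling hash, so that
#' every random draw in the package flows deterministically from one master
#' seed without correlated streams between heels.
#'
#' @param ... key components; coerced to character and concatenated.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "S01", "left", "time_zero")
derive_seed <- function(...) {
  parts <- vapply(list(...), function(x) paste(as.character(x), collapse = "|"),
                  character(1))
  s <- paste(parts, collapse = "::")
  h <- 17
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(max(h, 1))
}

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# N over cm^2 -> kPa. 1 N / 1 cm^2 = 10 kPa.
force_to_stress_kpa <- function(force_n, area_cm2) 10 * force_n / area_cm2
stress_to_force_n <- function(stress_kpa, area_cm2) stress_kpa * area_cm2 / 10

# Truncated normal by rejection; deterministic under the active seed.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}
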