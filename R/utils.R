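#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive k reproducible child seeds (< 2^31) from one parent seed.
child_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Significance bands for post-hoc p-values
#'
#' Maps two-sided p-values onto the bands used in the discriminant reports:
#' `"**"` for p < 0.01, `"*"` for p < 0.05, `"§"` (section sign) for
#' p < 0.1 and `"ns"` otherwise. The most significant applicable band is
#' returned.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return character vector of bands, same length as `p`.
#' @examples
#' significance_band(c(0.005, 0.03, 0.07, 0.5))
#' @export
significance_band <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep("ns", length(p))
  out[p < 0.1] <- "§"
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[is.na(p)] <- NA_character_
  out
}
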