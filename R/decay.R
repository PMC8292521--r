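#' Physical decay factor
#'
#' Fraction of Tc-99m activity remaining after \code{t} hours,
#' \code{exp(-ln(2) t / T_phys)}.
#'
#' @param t Time post-injection in hours (vectorised, must be >= 0).
#' @param T_phys Physical half-life in hours. Default 6.0 h for Tc-99m.
#' @return Numeric vector of decay factors in (0, 1].
#' @examples
#' decay_factor(0)            # 1
#' decay_factor(6)            # 0.5
#' decay_factor(3)            # 2^-0.5
#' @export
decay_factor <- function(t, T_phys = 6.0) {
  if (!is.numeric(t) || !is.numeric(T_phys)) stop("t and T_phys must be numeric")
  if (any(T_phys <= 0)) stop("T_phys must be positive")
  if (any(t < 0)) stop("negative time post-injection is not allowed")
  exp(-log(2) * t / T_phys)
}

# Run an expression with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  expr
}
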