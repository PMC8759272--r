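## Internal helpers shared across modules.

#' Min-max rescale onto [0, 1]
#'
#' Rescales a numeric vector linearly so its minimum maps to 0 and its
#' maximum to 1. A constant vector (no spread) maps to 0.5 everywhere so
#' that downstream composite scores stay defined when a stage yields a
#' single module or tied statistics.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length in [0, 1].
#' @examples
#' rescale01(c(2, 4, 6))
#' rescale01(c(3, 3, 3))  # degenerate: all 0.5
#' @export
rescale01 <- function(x) {
  stopifnot(is.numeric(x))
  rng <- range(x)
  if (!all(is.finite(rng))) stop("rescale01: non-finite values")
  if (rng[1] == rng[2]) return(rep(0.5, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

## Run code under a temporary RNG state; restores the caller's .Random.seed.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

## Canonical ordering of conditions through disease progression.
CONDITION_LEVELS <- c("normal", "I", "II", "III", "IV")

checkConditions <- function(x) {
  bad <- setdiff(unique(as.character(x)), CONDITION_LEVELS)
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  factor(as.character(x), levels = CONDITION_LEVELS)
}

## Symmetry check with a numerical tolerance.
isSymmetricMat <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}
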