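#' @keywords internal
#' @useDynLib scoutreid, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Seed plumbing: every stochastic operation takes an explicit seed and runs
## inside a local RNG scope, so no call mutates the caller's .Random.seed and
## identical seeds always reproduce identical draws.

#' Evaluate an expression under a local RNG seed
#'
#' Saves the caller's random-number state, seeds the generator with `seed`,
#' evaluates `expr`, and restores the previous state on exit. All stochastic
#' code in the package runs through this scope so that results depend only on
#' the seeds passed in, never on hidden global state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

## 32-bit modular multiply on doubles (exact: operands kept below 2^53).
mul32 <- function(a, b) {
  a_lo <- a %% 65536
  a_hi <- (a - a_lo) / 65536
  (((a_hi * b) %% 65536) * 65536 + a_lo * b) %% 4294967296
}

## 32-bit xor on doubles via 16-bit halves (bitwXor needs < 2^31).
xor32 <- function(a, b) {
  a_lo <- a %% 65536; a_hi <- (a - a_lo) / 65536
  b_lo <- b %% 65536; b_hi <- (b - b_lo) / 65536
  bitwXor(as.integer(a_hi), as.integer(b_hi)) * 65536 +
    bitwXor(as.integer(a_lo), as.integer(b_lo))
}

#' Derive a child seed from a master seed and a label path
#'
#' FNV-1a hash of the master seed and any number of labels, reduced to a
#' valid `set.seed()` integer. Used to give every patient, exam and training
#' stage its own reproducible stream from one master seed.
#'
#' @param master Integer master seed.
#' @param ... Character or numeric labels identifying the stream.
#' @return Integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "patient", "P001")
derive_seed <- function(master, ...) {
  key <- paste(c(format(master, scientific = FALSE), vapply(list(...), function(x)
    paste(format(x, scientific = FALSE), collapse = ","), character(1))),
    collapse = "\x1f")
  h <- 2166136261
  for (byte in utf8ToInt(key)) {
    h <- xor32(h, byte)
    h <- mul32(h, 16777619)
  }
  as.integer(h %% 2147483646)
}
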