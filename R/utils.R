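#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft kruskal.test median p.adjust pnorm predict quantile
#'   rbeta rnorm rpois runif sd var
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic stream of child seeds from a master seed.  Linear
# congruential step kept in double precision; values stay below 2^31 so
# they are valid R integer seeds.
derive_seed <- function(master, k) {
  stopifnot(is.numeric(master), is.numeric(k))
  as.integer((abs(master) * 69069 + k * 104729 + 12345) %% 2147483629 + 1)
}

# Run code with a local RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed %% 2147483629))
  force(code)
}

stop_fusion <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_fusion(msg)
  invisible(TRUE)
}
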