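#' @keywords internal
"_PACKAGE"

#' @useDynLib netmoa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cmdscale p.adjust wilcox.test fisher.test phyper dist
#' @importFrom utils head read.delim write.table
NULL

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards, so generators are pure functions of their
# arguments.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
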