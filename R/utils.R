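#' @importFrom methods new validObject is
#' @importFrom stats pnorm rnorm runif rnbinom rpois rlnorm cor sd t.test
#'   fisher.test p.adjust setNames oneway.test dnorm
#' @importFrom utils head read.delim write.table
NULL

# Deterministic sub-stream seed so that the synchrony, count and read stages
# are independently reproducible from one master seed.
.subSeed <- function(seed, stream) {
  m <- 2147483647
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% m
  as.integer((as.numeric(seed) %% m + h) %% m)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
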