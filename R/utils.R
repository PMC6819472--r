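#' @keywords internal
"_PACKAGE"

#' @importFrom stats rpois rbinom rbeta rnorm runif optimize pchisq pbinom
#'   dbinom quantile median var pt p.adjust fisher.test setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed for a named output stream
#'
#' Each kind of simulated output draws from its own stream derived from the
#' master seed, so adding a new output kind never perturbs existing ones.
#'
#' @param seed master integer seed.
#' @param kind character stream name.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, kind) {
  h <- 0
  for (u in utf8ToInt(kind)) h <- (h * 131 + u) %% 2147480009
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480009)
}

# Run code under a named RNG stream, restoring global RNG state afterwards.
with_stream <- function(seed, kind, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, kind))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# require columns in a data.frame, error naming the missing ones
check_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  }
  invisible(df)
}
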