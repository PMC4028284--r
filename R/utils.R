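#' @importFrom stats dhyper qnorm pnorm plogis rbinom rnorm rpois runif
#'   median quantile sd cor uniroot setNames qchisq
#' @importFrom utils head tail
#' @importFrom methods is
#' @importFrom data.table := .SD data.table as.data.table fread fwrite
#'   rbindlist setkeyv
NULL

utils::globalVariables(c("r2", "id_a", "id_b", "_index", "."))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards so that seeded
#' operations do not perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
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
  set.seed(as.integer(seed))
  expr
}

# Accepted chromosome names: autosomes 1-22 plus X/Y, with or without a
# "chr" prefix. Anything else is rejected by name so bad input surfaces early.
norm_chrom <- function(chrom, ids = NULL) {
  ch <- sub("^chr", "", as.character(chrom))
  ok <- ch %in% c(as.character(1:22), "X", "Y")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    offender <- if (!is.null(ids)) ids[bad] else chrom[bad]
    stopf("unknown chromosome name '%s' (record '%s')", chrom[bad], offender)
  }
  ch
}

as_id_vector <- function(x) {
  if (is.data.frame(x)) {
    if (!"id" %in% names(x)) stopf("expected an 'id' column")
    as.character(x$id)
  } else as.character(x)
}
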