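## Logging to stderr with timestamps.  The quiet flag suppresses "info"
## messages but never warnings.

.cfState <- new.env(parent = emptyenv())
.cfState$quiet <- FALSE

#' Toggle informational logging
#'
#' @param quiet logical; when `TRUE`, suppress `info`-level log lines
#'   (warnings are always emitted).
#' @return The previous setting, invisibly.
#' @export
cfQuiet <- function(quiet = TRUE) {
  old <- .cfState$quiet
  .cfState$quiet <- isTRUE(quiet)
  invisible(old)
}

#' @rdname cfQuiet
#' @param msg message text.
#' @param level `"info"` or `"warn"`.
#' @export
cfLog <- function(msg, level = c("info", "warn")) {
  level <- match.arg(level)
  if (level == "info" && .cfState$quiet) return(invisible(NULL))
  cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              toupper(level), msg), file = stderr())
  invisible(NULL)
}

## Seed hygiene: run an expression under a local RNG state.  With seed = NULL
## the current RNG stream is used (and advanced), so pipelines can derive all
## randomness from one top-level seed.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Pearson r without cor()'s NA ceremony; errors on constant input.
.pearson <- function(x, y, what = "correlation") {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop(sprintf("%s undefined: at least one vector is constant", what),
         call. = FALSE)
  stats::cor(x, y, method = "pearson")
}
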