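# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{code} under \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so package functions never clobber the session RNG.
#'
#' @param seed Integer seed, or \code{NULL} to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize a RNG state so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# stop() without the call, with sprintf-style formatting
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# check a scalar is one of a fixed set
match_enum <- function(x, choices, what) {
  if (length(x) != 1L || !x %in% choices) {
    fail("%s must be one of {%s}, got '%s'", what,
         paste(choices, collapse = ", "), paste(x, collapse = ","))
  }
  x
}

# uppercase and convert RNA to DNA alphabet; validate characters
normalize_sequence <- function(s, what = "sequence") {
  s <- toupper(s)
  bad <- grepl("[^ACGTU]", s)
  if (any(bad)) {
    fail("%s contains characters outside {A,C,G,T,U}: %s", what,
         paste(utils::head(s[bad], 3L), collapse = ", "))
  }
  gsub("U", "T", s, fixed = TRUE)
}
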