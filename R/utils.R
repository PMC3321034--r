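`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize gene/sample identifiers for matching
#'
#' Identifiers are compared case-insensitively after trimming whitespace.
#' @param x character vector of identifiers.
#' @return normalized character vector.
#' @keywords internal
norm_id <- function(x) toupper(trimws(as.character(x)))

#' Match query identifiers against a target set (case-insensitive, trimmed)
#' @keywords internal
match_ids <- function(query, targets) match(norm_id(query), norm_id(targets))

## The four transcriptional glioblastoma subtypes.
GBM_SUBTYPES <- c("Mesenchymal", "Classical", "Neural", "Proneural")

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
## RNG state afterwards so seeded helpers do not perturb the session stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
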