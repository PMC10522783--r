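#' @keywords internal
"_PACKAGE"

#' Logit and inverse-logit
#'
#' Thin wrappers over [stats::qlogis()] and [stats::plogis()] used throughout
#' the package; the area-level model operates on the logit scale.
#'
#' @param p proportion in (0, 1).
#' @param x real number.
#' @return `logit()` returns log(p / (1 - p)); `expit()` its inverse.
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
expit <- function(x) stats::plogis(x)

## Deterministic per-stage seed derivation: keeps stages reproducible in
## isolation while a single master seed drives a whole run. Result stays
## within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1009 * as.numeric(offset)) %% 2147483646L) + 1L
}

## Evaluate an expression under a local RNG state (restores caller's state).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

## md5 of an in-memory object via its canonical JSON serialisation
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}
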