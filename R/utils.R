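#' @keywords internal
"_PACKAGE"

# Logging goes through one gate so pipelines can silence or capture it.
ptml_log <- function(...) {
  if (isTRUE(getOption("nanoptml.quiet", FALSE))) return(invisible(NULL))
  message("[nanoptml] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a private RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  expr
}

stop_contract <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
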