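#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so every generator and permutation routine is a pure
#' function of its inputs.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
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

#' Derive a per-stage child seed from a global seed
#'
#' Deterministic mixing keeps stage sub-streams distinct while staying within
#' the 32-bit integer range R requires of `set.seed`.
#'
#' @param seed integer global seed.
#' @param offset small integer distinguishing the stage.
#' @keywords internal
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 8191) %% 2147483587) + 1L
}

# Internal event log: routines that silently repair degenerate input (zero
# variance genes, homolog collisions, disconnected subgraphs) record what they
# did; the pipeline copies these notes into its manifest.
log_event <- function(...) {
  msg <- paste0(...)
  ev <- getOption("ewdms.events", character())
  options(ewdms.events = c(ev, msg))
  if (isTRUE(getOption("ewdms.verbose", FALSE))) message("[ewdms] ", msg)
  invisible(msg)
}

clear_events <- function() options(ewdms.events = character())
get_events <- function() getOption("ewdms.events", character())

`%||%` <- function(a, b) if (is.null(a)) b else a
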