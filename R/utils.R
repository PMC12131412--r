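#' @importFrom stats cor dist quantile rnbinom rnorm runif sd var setNames
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom methods as is
NULL

stop_stmap <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "stmap_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so package internals never clobber a user's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

# Deterministic child seed: double arithmetic, folded into 32-bit range.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 2654435 + sum(utf8ToInt(stage)) * 97) %%
               2147483562) + 1L
}

msg_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}
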