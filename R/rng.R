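# Seed plumbing: every sampler is a pure function of its arguments including
# the seed, and never disturbs the caller's RNG state.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the global `.Random.seed`, seeds the RNG, evaluates `code`, and
#' restores the previous state so callers see no side effect.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive named sub-seeds from a master seed
#'
#' A master seed splits deterministically into independent streams (interaction
#' matrix, diffusion rates, initial conditions, ...) so any component can be
#' regenerated on its own.  All derived seeds stay below 2^31.
#'
#' @param master single integer master seed.
#' @param labels character vector naming the streams.
#' @return named integer vector of sub-seeds.
#' @export
#' @examples
#' derive_seeds(42, c("matrix", "diffusion", "ic"))
derive_seeds <- function(master, labels) {
  local_seed(master, {
    setNames(sample.int(2147483646L, length(labels)), labels)
  })
}
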