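# Small internal utilities.

#' Rejection sentinel
#'
#' Returned by filtering operations that can reject their input (e.g.
#' [filter_cluster()], [build_ortholog_group()]) instead of returning a
#' group; carries the reason.
#'
#' @param reason Human-readable rejection reason.
#' @return An object of class `curation_reject`.
#' @export
rejected <- function(reason) {
  structure(list(reason = reason), class = "curation_reject")
}

#' @rdname rejected
#' @param x An object.
#' @export
is_rejected <- function(x) inherits(x, "curation_reject")

#' Evaluate code under a local RNG seed, restoring the caller's RNG state
#' @noRd
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a stream of sub-seeds from one master seed (kept below 2^31)
#' @noRd
.sub_seeds <- function(seed, n) {
  # capped at 1e9 so callers can add small offsets without overflow
  .with_seed(seed, sample.int(1000000000L, n))
}
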