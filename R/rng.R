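#' Derive a reproducible substream seed from a root seed and labels
#'
#' All randomness in the package flows from one root seed through named
#' substreams, so that e.g. adding participants to a cohort does not
#' perturb the draws of existing ones. The derivation is a 32-bit FNV-1a
#' hash of the concatenated labels, mixed with the root seed and reduced
#' below 2^31.
#'
#' @param root integer root seed.
#' @param ... labels (coerced to character) naming the substream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @examples
#' substream_seed(1, "participant", 7, "trial_log")
#' @export
substream_seed <- function(root, ...) {
  stopifnot(is.numeric(root), length(root) == 1, is.finite(root))
  lab <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 2166136261
  for (b in utf8ToInt(lab)) {
    h <- bitwXor(as.integer(h %% 2147483648), b) +
      (if (h >= 2147483648) 2147483648 else 0)
    # 32-bit multiply by the FNV prime 16777619 = 403 + 256 * 2^16,
    # split so intermediates stay below 2^53
    h <- (h * 403 + (h %% 65536) * 16777216) %% 4294967296
  }
  h <- (h + as.numeric(root) * 2654435761) %% 4294967296
  as.integer(h %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
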