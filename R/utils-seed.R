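#' Derive a reproducible child seed from a master seed and a label
#'
#' Stage and subject seeds are derived by hashing `(master_seed, label)` with a
#' small FNV-1a-style string hash, so that every stage of a run draws from an
#' independent, stable stream. The result always lies in `[1, 2^31 - 2]` and
#' is therefore a valid R integer seed.
#'
#' @param master_seed Integer master seed.
#' @param ... Character or numeric labels identifying the consumer
#'   (e.g. stage name, subject id). Coerced to character and concatenated.
#' @return A single integer seed.
#' @examples
#' derive_seed(1, "bold", 3)
#' @export
derive_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.finite(master_seed))
  key <- paste(c(format(master_seed, scientific = FALSE),
                 vapply(list(...), function(x) paste(format(x), collapse = "|"),
                        character(1))),
               collapse = "::")
  bytes <- utf8ToInt(key)
  # FNV-1a over a 2^31-1 modulus; plain doubles are exact well below 2^53
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
    h <- (h * 16777619) %% 2147483629
  }
  as.integer(h %% 2147483645L) + 1L
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
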