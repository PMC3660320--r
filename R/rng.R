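#' Derive a child seed from a root seed and a stage label
#'
#' All randomness in the package flows from one root seed; each pipeline
#' stage (and each subject, day, experiment within a stage) derives its own
#' child seed by hashing the root together with string labels.  Children are
#' stable under reordering or addition of other stages.
#'
#' @param root integer root seed.
#' @param ... stage labels (coerced to character), e.g. `"simulate"`,
#'   subject id, day index.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "simulate", "s01", 3)
#' @export
derive_seed <- function(root, ...) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root))
  m <- 2147483647 # 2^31 - 1; products below stay < 2^53
  h <- abs(as.double(root)) %% m
  for (part in unlist(lapply(list(...), as.character))) {
    for (cp in utf8ToInt(part)) h <- (h * 69069 + cp) %% m
  }
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}
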