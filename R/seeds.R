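#' Derive a reproducible per-stage seed from a global seed
#'
#' Every stochastic stage of the pipeline (imputation, permutation nulls,
#' fold assignment, simulation) draws its own seed from the single global
#' seed in [run_config()], so that changing the number of permutations in
#' one stage never perturbs another stage's random stream.
#'
#' The substream seed is a deterministic hash of the global seed and a
#' stage label, reduced modulo 2^31 - 1 so it is always a valid R integer.
#'
#' @param seed Integer global seed.
#' @param label Character stage label, e.g. `"impute"` or `"fdr"`.
#' @return A single integer seed.
#' @export
#' @examples
#' substream_seed(1, "impute")
#' substream_seed(1, "fdr")
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  codes <- utf8ToInt(label)
  h <- as.double(seed %% 2147483647)
  for (k in codes) {
    # 31-based polynomial rolling hash, kept in double-safe range
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
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
  force(expr)
}
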