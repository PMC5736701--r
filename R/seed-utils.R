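#' Derive a component seed from a master seed
#'
#' Stable string-hash combination of a master seed with a component name, so
#' that every randomised stage of a pipeline gets its own reproducible stream
#' without seed collisions between stages.
#'
#' @param seed Master integer seed.
#' @param component Character scalar naming the consumer (e.g. `"cohort"`,
#'   `"train"`, `"mc"`).
#' @return An integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' derive_seed(1, "cohort")
#' derive_seed(1, "train")
#' @export
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component),
            length(component) == 1L)
  h <- as.double(abs(seed) %% 2147483647)
  for (v in utf8ToInt(component)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Write a data frame as CSV with numeric columns at full double precision
# (round-trips exactly through %.17g).
write_numeric_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}
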