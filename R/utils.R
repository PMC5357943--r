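# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic entry points funnel through
# this so that a seed argument fully determines their output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
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

# Standardize rows to zero mean, unit (sample) sd. Errors on flat rows.
standardize_rows <- function(values) {
  mu <- rowMeans(values)
  centred <- values - mu
  sds <- sqrt(rowSums(centred^2) / (ncol(values) - 1L))
  if (any(sds == 0))
    stop("zero-variance profile(s): ",
         paste(utils::head(rownames(values)[sds == 0], 5L), collapse = ", "))
  centred / sds
}
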