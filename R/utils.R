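# internal helpers shared across modules

# run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never clobbers the
# session RNG. seed = NULL runs in the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# per-stage seeds derived from a master seed; double arithmetic keeps the
# result exact and below 2^31
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %%
               2147483587)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("features must be a numeric matrix or data frame", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

manhattan_to_rows <- function(x, centers) {
  # n x k matrix of L1 distances from rows of x to rows of centers
  n <- nrow(x)
  k <- nrow(centers)
  d <- matrix(0, n, k)
  for (c in seq_len(k))
    d[, c] <- rowSums(abs(sweep(x, 2L, centers[c, ], "-")))
  d
}
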