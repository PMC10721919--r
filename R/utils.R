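# Internal helpers shared across the pipeline.

#' Derive an independent sub-seed
#'
#' All randomness flows from one user-facing integer seed. Sub-streams are
#' derived deterministically so every pipeline stage is replayable in
#' isolation; the derived value stays within 32-bit integer range.
#'
#' @param seed top-level integer seed.
#' @param offset integer stream index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset) {
  s <- (abs(as.numeric(seed)) %% 2147483647) * 7919 + as.numeric(offset) * 104729
  as.integer(s %% 2147483646) + 1L
}

# Evaluate expr under a temporary RNG state; NULL seed uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Sum `values` into an n-vector by integer index (vectorised scatter-add).
accumulate_at <- function(index, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, group = index)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

row_norms <- function(m) sqrt(rowSums(m * m))

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

as_point3 <- function(x, what = "point") {
  x <- as.numeric(x)
  if (length(x) != 3L || anyNA(x)) stop(what, " must be a finite 3D point", call. = FALSE)
  x
}
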