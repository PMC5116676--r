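# internal helpers

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

.assert <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

# nearest-peak lookup: for each query m/z, index of nearest peak in sorted
# `mz` within tol_ppm of `query`, or NA
.nearest_peak <- function(mz, query, tol_ppm) {
  if (length(mz) == 0L || length(query) == 0L) {
    return(rep(NA_integer_, length(query)))
  }
  idx <- findInterval(query, mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(mz))
  d_lo <- abs(mz[lo] - query)
  d_hi <- abs(mz[hi] - query)
  best <- ifelse(d_lo <= d_hi, lo, hi)
  dist <- pmin(d_lo, d_hi)
  best[dist > query * tol_ppm * 1e-6] <- NA_integer_
  best
}
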