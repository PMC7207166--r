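# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Trapezoid-rule integral of y over (possibly non-uniform) grid x.
trapz <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

# Per-label mean of `values` for labels 1..k (0 = background ignored).
label_means <- function(labels, values, k) {
  if (k == 0L) return(numeric(0L))
  keep <- labels > 0L
  sums <- rowsum(values[keep], labels[keep])
  out <- rep(NA_real_, k)
  idx <- as.integer(rownames(sums))
  cnt <- tabulate(labels[keep], nbins = k)
  out[idx] <- sums[, 1L] / cnt[idx]
  out
}

# Clamp to the 16-bit unsigned range and round, emulating sCMOS digitisation.
quantize_u16 <- function(m) {
  m[m < 0] <- 0
  m[m > 65535] <- 65535
  round(m)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
}
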