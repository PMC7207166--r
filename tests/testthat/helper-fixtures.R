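# Shared fixture builders: everything is generated in code at test time.

# A small field with both a DNA and a signal channel.
small_field <- function(n_cells = 10L, planted_inhibition = 0, seed = 1L,
                        noise_frac = 0.01, ...) {
  make_field(field_spec(
    n_cells = n_cells,
    channels = list(
      dna = c(background = 100, level = 2000, noise_sd = noise_frac * 2000),
      signal = c(background = 100, level = 1500, noise_sd = noise_frac * 1500)),
    planted_inhibition = planted_inhibition,
    seed = seed, ...))
}

# Wrap a label matrix as the package's mask class (for hand-built masks).
as_label_mask <- function(m) {
  structure(matrix(as.integer(m), nrow(m), ncol(m)),
            n_objects = length(unique(m[m > 0])),
            class = "label_mask")
}

# Independent brute-force overlap count (oracle for soc()).
brute_soc <- function(a, b) {
  inter <- 0L; un <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (a[i, j] && b[i, j]) inter <- inter + 1L
      if (a[i, j] || b[i, j]) un <- un + 1L
    }
  }
  inter / un
}
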