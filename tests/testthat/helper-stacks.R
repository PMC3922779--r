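# Shared fixtures, all generated in code.

# small, fast synthetic stack for unit tests
small_spec <- function(seed = 1L, ...) {
  args <- list(n_frames = 9L, frame_shape = c(64L, 64L), n_cells = 3L,
               radius_px_range = c(4, 7), min_separation_px = 8,
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_spec, args)
}

# stack of two-level random frames with a low-entropy (nearly uniform) frame
# planted at `focus`; every frame has >= 2 intensities so Otsu is defined
two_level_stack <- function(n = 21L, focus = 12L, nr = 24L, nc = 24L,
                            spacing_um = 10, seed = 1L) {
  set.seed(seed)
  frames <- lapply(seq_len(n), function(k) {
    p <- if (k == focus) 0.02 else 0.5
    matrix(sample(c(0L, 4000L), nr * nc, replace = TRUE,
                  prob = c(1 - p, p)), nr, nc)
  })
  zstack(frames, spacing_um = spacing_um,
         stack_id = sprintf("twolevel-%d", seed))
}

# independently coded exhaustive quad enumeration (the selection oracle):
# explicit double loop over 2-below x 2-above index tuples, Psi evaluated
# by a literal translation of the set-complexity formula
brute_force_quad <- function(c_sizes, D, i0, n) {
  best_psi <- -Inf
  best <- NULL
  for (i in 1:(i0 - 2L)) for (j in (i + 1L):(i0 - 1L)) {
    for (k in (i0 + 1L):(n - 1L)) for (l in (k + 1L):n) {
      pos <- c(i, j, k, l)
      acc <- 0
      for (a in 1:4) for (b in 1:4) if (a != b) {
        d <- D[pos[a], pos[b]]
        acc <- acc + c_sizes[pos[a]] * d * (1 - d)
      }
      psi <- acc / 12
      if (psi > best_psi) {
        best_psi <- psi
        best <- pos
      }
    }
  }
  list(indices = best, psi = best_psi)
}

# jaccard overlap of two binary masks
jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
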