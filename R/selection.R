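# Frame selection: in-focus detection by minimum histogram entropy, then
# either the adaptive maximal-information search (argmax of set complexity
# over all 2-below x 2-above frame combinations) or the classical
# fixed-offset baseline.

#' Binarize a frame with Otsu's method
#'
#' The threshold maximizes between-class variance on a 256-level histogram
#' spanning the frame's own intensity range; pixels strictly above the
#' threshold map to 1.
#'
#' @param pixels Numeric matrix with at least two distinct intensities.
#' @return Integer matrix of 0/1 values with the dimensions of `pixels`.
#' @export
binarize_otsu <- function(pixels) {
  rng <- range(pixels)
  if (rng[1L] == rng[2L])
    stop("degenerate histogram: frame has a single intensity")
  thr <- EBImage::otsu(pixels, range = rng, levels = 256L)
  out <- (pixels > thr) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Linearize a binary image into a string
#'
#' Columns are traversed left to right, each column top to bottom, and the
#' 0/1 pixels concatenated into one '0'/'1' character string. Column
#' concatenation preserves vertical runs, which block compressors exploit.
#'
#' @param binary Non-empty matrix of 0/1 values.
#' @return Character scalar of length `nrow(binary) * ncol(binary)`.
#' @export
linearize <- function(binary) {
  if (length(binary) == 0L) stop("empty grid")
  intToUtf8(48L + as.integer(binary))
}

#' Encode every frame of a stack for complexity analysis
#'
#' Each frame is Otsu-binarized, column-linearized, and compressed once;
#' the compressed size C(s) is cached on the encoding, so downstream NCD
#' computations never recompress single frames.
#'
#' @param stack A [zstack()].
#' @param compressor Passed to [compression_size()].
#' @return List of encodings, each a list with `frame_index`, `binary`,
#'   `string`, `c_size`.
#' @export
frame_encodings <- function(stack, compressor = c("bzip2", "gzip")) {
  compressor <- match.arg(compressor)
  lapply(seq_len(n_frames(stack)), function(k) {
    b <- binarize_otsu(stack$frames[[k]])
    s <- linearize(b)
    list(frame_index = k, binary = b, string = s,
         c_size = compression_size(s, compressor))
  })
}

#' Detect the in-focus frame of a z-stack
#'
#' Returns the index of the frame minimizing histogram Shannon entropy
#' (ties broken by the lowest index). The full entropy profile is attached
#' as attribute `"profile"` for reporting.
#'
#' @param stack A [zstack()].
#' @param bins Histogram bins for [shannon_entropy()].
#' @return Integer frame index (1-based) with attribute `profile`.
#' @export
find_in_focus <- function(stack, bins = 256L) {
  profile <- entropy_profile(stack, bins = bins)
  i0 <- which.min(profile)
  structure(i0, profile = profile)
}

# In-focus index constrained to leave >= 2 frames on each side; falls back
# to the entropy-minimizing interior index (with a warning) when the global
# minimum sits too close to a stack boundary.
interior_in_focus <- function(stack, bins = 256L) {
  i0 <- find_in_focus(stack, bins = bins)
  profile <- attr(i0, "profile")
  n <- n_frames(stack)
  if (i0 < 3L || i0 > n - 2L) {
    interior <- 3L:(n - 2L)
    new_i0 <- interior[which.min(profile[interior])]
    warning(sprintf(paste0("in-focus frame %d too close to stack boundary; ",
                           "using interior entropy minimum %d"), i0, new_i0))
    i0 <- structure(new_i0, profile = profile)
  }
  i0
}

frame_quad <- function(idx, i0, psi, strategy) {
  stopifnot(length(idx) == 4L, all(diff(c(idx[1:2], i0, idx[3:4])) > 0))
  structure(
    list(i_minus_minus = idx[1L], i_minus = idx[2L], i0 = as.integer(i0),
         i_plus = idx[3L], i_plus_plus = idx[4L],
         psi = psi, strategy = strategy),
    class = "frame_quad")
}

#' @export
print.frame_quad <- function(x, ...) {
  cat(sprintf(
    "<frame_quad [%s]: I--=%d I-=%d (I0=%d) I+=%d I++=%d, psi=%.4f>\n",
    x$strategy, x$i_minus_minus, x$i_minus, x$i0, x$i_plus, x$i_plus_plus,
    x$psi))
  invisible(x)
}

#' Frame indices of a quad, in z order
#' @param quad A frame quad from [select_frames_maxinfo()] or
#'   [select_frames_fixed()].
#' @return Integer vector `(I--, I-, I+, I++)`.
#' @export
quad_indices <- function(quad) {
  c(quad$i_minus_minus, quad$i_minus, quad$i_plus, quad$i_plus_plus)
}

# Psi of the four defocused frames addressed by positions `pos` in D.
quad_psi <- function(c_sizes, D, pos) {
  set_complexity(c_sizes[pos], D[pos, pos])
}

#' Select the four most informative defocused frames (adaptive strategy)
#'
#' Enumerates every combination of two frames strictly below and two
#' strictly above the in-focus frame, scores each four-frame set by its set
#' complexity Psi over the binarized/linearized/compressed encodings, and
#' returns the maximizing quad. The in-focus frame itself is excluded from
#' the scored set. All single-frame and pairwise-concatenation compressions
#' are computed once and cached, so an n-frame stack costs exactly n +
#' n(n-1)/2 compressor calls. Ties on Psi are broken by the
#' lexicographically smallest index tuple, making the result deterministic.
#'
#' @param stack A [zstack()].
#' @param bins Histogram bins for focus detection.
#' @param compressor Passed to [compression_size()].
#' @param encodings,D Optional precomputed [frame_encodings()] and
#'   [ncd_matrix()] over the whole stack, to share work between strategies.
#' @return A `frame_quad` with elements `i_minus_minus`, `i_minus`, `i0`,
#'   `i_plus`, `i_plus_plus`, `psi`, `strategy = "maxinfo"`.
#' @export
select_frames_maxinfo <- function(stack, bins = 256L,
                                  compressor = c("bzip2", "gzip"),
                                  encodings = NULL, D = NULL) {
  compressor <- match.arg(compressor)
  i0 <- interior_in_focus(stack, bins = bins)
  n <- n_frames(stack)
  if (is.null(encodings)) encodings <- frame_encodings(stack, compressor)
  if (is.null(D)) D <- ncd_matrix(encodings, compressor)
  c_sizes <- vapply(encodings, function(e) e$c_size, numeric(1))
  below <- utils::combn(seq_len(i0 - 1L), 2L)
  above <- utils::combn((i0 + 1L):n, 2L)
  best_psi <- -Inf
  best <- NULL
  for (b in seq_len(ncol(below))) {
    for (a in seq_len(ncol(above))) {
      pos <- c(below[, b], above[, a])
      psi <- quad_psi(c_sizes, D, pos)
      if (psi > best_psi) {           # strict: first (lexicographic) wins ties
        best_psi <- psi
        best <- pos
      }
    }
  }
  frame_quad(best, as.integer(i0), best_psi, "maxinfo")
}

# round half away from zero, so 2.5 frame-spacings become 3 frames
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Select defocused frames at fixed physical offsets (baseline strategy)
#'
#' The classical non-adaptive strategy: weakly defocused frames at
#' `+-weak_um` and strongly defocused frames at `+-strong_um` from the
#' in-focus frame. Offsets are converted to frame counts by rounding half
#' away from zero (at 10 um spacing a 25 um offset becomes 3 frames, i.e.
#' +-30 um), with a minimum of one frame; if weak and strong round to the
#' same count, the strong offset is pushed one frame further out. The Psi
#' of the resulting quad is computed for comparison with the adaptive
#' strategy.
#'
#' @param stack A [zstack()].
#' @param weak_um,strong_um Physical offsets in micrometres,
#'   `weak_um < strong_um`. Defaults 10 and 25.
#' @inheritParams select_frames_maxinfo
#' @return A `frame_quad` with `strategy = "fixed"`.
#' @export
select_frames_fixed <- function(stack, weak_um = 10, strong_um = 25,
                                bins = 256L, compressor = c("bzip2", "gzip"),
                                encodings = NULL, D = NULL) {
  compressor <- match.arg(compressor)
  stopifnot(weak_um > 0, strong_um > weak_um)
  i0 <- interior_in_focus(stack, bins = bins)
  n <- n_frames(stack)
  d_weak <- max(1L, as.integer(round_half_away(weak_um / stack$spacing_um)))
  d_strong <- max(1L, as.integer(round_half_away(strong_um / stack$spacing_um)))
  if (d_strong == d_weak) d_strong <- d_weak + 1L
  idx <- as.integer(i0) + c(-d_strong, -d_weak, d_weak, d_strong)
  if (idx[1L] < 1L || idx[4L] > n)
    stop("fixed offsets exceed stack extent (frames ", idx[1L], "..",
         idx[4L], " of ", n, ")")
  if (is.null(D)) {
    enc <- if (is.null(encodings)) {
      lapply(idx, function(k) {
        b <- binarize_otsu(stack$frames[[k]])
        s <- linearize(b)
        list(frame_index = k, binary = b, string = s,
             c_size = compression_size(s, compressor))
      })
    } else encodings[idx]
    Dq <- ncd_matrix(enc, compressor)
    c_sizes <- vapply(enc, function(e) e$c_size, numeric(1))
    psi <- set_complexity(c_sizes, Dq)
  } else {
    c_sizes <- vapply(encodings, function(e) e$c_size, numeric(1))
    psi <- quad_psi(c_sizes, D, idx)
  }
  frame_quad(as.integer(idx), as.integer(i0), psi, "fixed")
}
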