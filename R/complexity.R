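# Kolmogorov-style information measures over binarized frames: compression
# size C(s) as the complexity proxy, pairwise normalized compression
# distance (NCD), and set complexity (Psi) over frame sets.

.compress_stats <- new.env(parent = emptyenv())
.compress_stats$calls <- 0L

#' Number of real compressor invocations performed so far
#'
#' Every call of [compression_size()] that actually runs the compressor
#' (i.e. is not served from a cache) increments this process-wide counter.
#' Used to audit the pairwise compression cache: selecting frames on an
#' n-frame stack must cost exactly `n` single-string plus `n(n-1)/2`
#' pair-concatenation compressions.
#'
#' @return Integer count since the last [reset_compression_calls()].
#' @export
compression_calls <- function() .compress_stats$calls

#' Reset the compressor invocation counter
#' @return `NULL`, invisibly.
#' @export
reset_compression_calls <- function() {
  .compress_stats$calls <- 0L
  invisible(NULL)
}

#' Compressed size of a string
#'
#' Approximates the Kolmogorov complexity C(s) of a string by its
#' compressed byte length. The default compressor is bzip2 at its maximum
#' (900 kB) block size; compression runs fully in memory.
#'
#' @param s Non-empty character scalar.
#' @param compressor `"bzip2"` (default) or `"gzip"`.
#' @param cache Optional environment used to memoize results by string
#'   identity; cache hits do not invoke the compressor (and do not count in
#'   [compression_calls()]).
#' @return Positive integer: compressed length in bytes.
#' @export
compression_size <- function(s, compressor = c("bzip2", "gzip"), cache = NULL) {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    stop("s must be a single string")
  if (!nzchar(s)) stop("s must be non-empty")
  compressor <- match.arg(compressor)
  if (!is.null(cache)) {
    hit <- get0(s, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
  }
  .compress_stats$calls <- .compress_stats$calls + 1L
  out <- length(memCompress(charToRaw(s), type = compressor))
  if (!is.null(cache)) assign(s, out, envir = cache)
  out
}

#' Normalized compression distance between two strings
#'
#' NCD(s_i, s_j) = (C(s_i s_j) - min(C(s_i), C(s_j))) / max(C(s_i), C(s_j)),
#' where `s_i s_j` is concatenation. Near-identical strings score ~0,
#' unrelated (e.g. independent random) strings score ~1; real compressors
#' may slightly exceed 1. The concatenation order is canonicalized (the
#' lexicographically smaller string first, byte-wise), so the function is
#' exactly symmetric in its arguments.
#'
#' @param s_i,s_j Non-empty strings.
#' @param c_i,c_j Optional precomputed `C(s_i)`, `C(s_j)` (skips
#'   recompression when sizes are already cached at a higher level).
#' @param compressor Passed to [compression_size()].
#' @param cache Optional memoization environment, see [compression_size()].
#' @return Non-negative real, typically in [0, ~1.1].
#' @export
ncd <- function(s_i, s_j, c_i = NULL, c_j = NULL,
                compressor = c("bzip2", "gzip"), cache = NULL) {
  compressor <- match.arg(compressor)
  if (is.null(c_i)) c_i <- compression_size(s_i, compressor, cache)
  if (is.null(c_j)) c_j <- compression_size(s_j, compressor, cache)
  # byte-wise (radix) comparison keeps the canonical order locale-independent
  swap <- s_i != s_j && sort(c(s_i, s_j), method = "radix")[1L] == s_j
  pair <- if (swap) paste0(s_j, s_i) else paste0(s_i, s_j)
  c_ij <- compression_size(pair, compressor, cache)
  (c_ij - min(c_i, c_j)) / max(c_i, c_j)
}

#' Pairwise NCD matrix over a set of frame encodings
#'
#' Computes every off-diagonal NCD once per unordered pair (the
#' concatenation compression is never repeated) and stores the diagonal as
#' exactly 0 by convention, since self-distance never enters the set
#' complexity (which sums over j != i).
#'
#' @param encodings List of frame encodings from [frame_encodings()] (each
#'   has `string` and `c_size`).
#' @param compressor Passed to [compression_size()].
#' @return A symmetric numeric matrix of class `"ncd_matrix"` with
#'   attribute `indices` (the frame indices of its rows/columns).
#' @export
ncd_matrix <- function(encodings, compressor = c("bzip2", "gzip")) {
  compressor <- match.arg(compressor)
  k <- length(encodings)
  if (k < 2L) stop("need at least 2 encodings")
  D <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      D[i, j] <- D[j, i] <- ncd(encodings[[i]]$string, encodings[[j]]$string,
                                c_i = encodings[[i]]$c_size,
                                c_j = encodings[[j]]$c_size,
                                compressor = compressor)
    }
  }
  idx <- vapply(encodings, function(e) e$frame_index, integer(1))
  dimnames(D) <- list(idx, idx)
  structure(D, indices = idx, class = c("ncd_matrix", "matrix", "array"))
}

#' Export an NCD matrix as CSV
#' @param D An [ncd_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ncd_matrix <- function(D, path) {
  utils::write.csv(as.data.frame(unclass(D)), path, row.names = TRUE)
  invisible(path)
}

#' Plot an NCD matrix as a heatmap
#'
#' Lowest z frame in the lower left, highest in the upper right; low NCD in
#' blue, high NCD in red.
#'
#' @param D An [ncd_matrix()].
#' @param main Plot title.
#' @return `NULL`, invisibly.
#' @export
plot_ncd_heatmap <- function(D, main = "pairwise NCD") {
  k <- nrow(D)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  graphics::image(seq_len(k), seq_len(k), t(unclass(D)), col = pal,
                  xlab = "frame", ylab = "frame", main = main, useRaster = TRUE)
  invisible(NULL)
}

#' Set complexity of a set of strings
#'
#' Psi(S) = 1/(n(n-1)) * sum_i C(s_i) * sum_{j != i} d_ij (1 - d_ij), with
#' d_ij the pairwise NCD. The measure discounts pairs that are nearly
#' identical (d ~ 0: redundant) or mutually random (d ~ 1: unrelated) and
#' is maximized when strings are individually complex and roughly
#' half-similar (d ~ 0.5). NCD values above 1 contribute negatively exactly
#' as the formula dictates; no clamping is applied.
#'
#' @param c_sizes Positive numeric vector of per-string compression sizes,
#'   aligned with the rows of `ncd_values`.
#' @param ncd_values Square symmetric matrix of pairwise NCD values with a
#'   zero diagonal (e.g. an [ncd_matrix()] or a submatrix of one).
#' @return Non-negative real (negative only if some NCD exceeds 1).
#' @export
set_complexity <- function(c_sizes, ncd_values) {
  n <- length(c_sizes)
  if (n < 2L) stop("set complexity needs at least 2 strings")
  ncd_values <- unclass(ncd_values)
  if (!is.matrix(ncd_values) || nrow(ncd_values) != n || ncol(ncd_values) != n)
    stop("dimension mismatch between c_sizes and ncd_values")
  M <- ncd_values * (1 - ncd_values)
  diag(M) <- 0
  sum(c_sizes * rowSums(M)) / (n * (n - 1))
}

#' Shannon entropy of a frame's intensity histogram
#'
#' Bins intensities into `bins` equal-width bins spanning the full
#' representable range `[0, 2^bit_depth)` and returns
#' `-sum(p * log2(p))` over occupied bins, in bits. This is the standard
#' histogram Shannon entropy; `method = "integral"` instead evaluates the
#' pixel-summed variant `-sum_pixels p(I(x,y)) log2 p(I(x,y))`
#' (= `-N * sum_v p(v)^2 log2 p(v)`), which weights each intensity by its
#' own frequency. Both are minimized by low-diversity histograms; the
#' histogram form is the default and the one used for focus detection.
#'
#' @param pixels Non-empty numeric matrix of intensities.
#' @param bit_depth Bit depth defining the representable range.
#' @param bins Number of histogram bins (default 256; robust across 8/12/16
#'   bit data).
#' @param method `"histogram"` (default) or `"integral"`.
#' @return Non-negative real, bits.
#' @export
shannon_entropy <- function(pixels, bit_depth = 12L, bins = 256L,
                            method = c("histogram", "integral")) {
  method <- match.arg(method)
  if (length(pixels) == 0L) stop("empty frame")
  if (bins < 2L) stop("bins must be >= 2")
  width <- 2^bit_depth / bins
  idx <- pmin(floor(as.numeric(pixels) / width), bins - 1L) + 1L
  counts <- tabulate(idx, nbins = bins)
  p <- counts[counts > 0] / length(pixels)
  if (method == "histogram") {
    -sum(p * log2(p))
  } else {
    -length(pixels) * sum(p^2 * log2(p))
  }
}

#' Entropy profile of a z-stack
#'
#' Per-frame histogram Shannon entropy along the stack; blur spreads the
#' histogram, so entropy is expected to be minimal at the focal plane and to
#' grow with defocus (noise and banding can break the monotonicity).
#'
#' @param stack A [zstack()].
#' @inheritParams shannon_entropy
#' @return Numeric vector of entropies (bits), one per frame.
#' @export
entropy_profile <- function(stack, bins = 256L,
                            method = c("histogram", "integral")) {
  method <- match.arg(method)
  vapply(stack$frames, shannon_entropy, numeric(1),
         bit_depth = stack$bit_depth, bins = bins, method = method)
}
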