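# Segmentation: the absolute difference of the two strongly defocused
# frames seeds initial cell regions (Otsu + 8-connected components + size
# filter); the difference of the two weakly defocused frames then guides a
# region-based morphological active contour that expands each seed.
# Bright-field cells invert contrast across focus, so cross-focus
# differences are large inside cells and small in background.

#' Segmentation parameters
#'
#' @param min_object_px Minimum connected-component size (pixels) kept by
#'   the artifact filter of [initial_mask()]. Default `NULL` resolves at
#'   use to `round(100 * rows*cols / 1024^2)` (at least 1), i.e. 100 px at
#'   the reference 1024x1024 frame size, scaled by image area.
#' @param max_iterations Upper bound on contour-evolution iterations.
#' @param smoothing Regularization passes per iteration: newly added
#'   boundary pixels are kept only while at least 3 of their 8 neighbours
#'   share their label.
#' @param expansion_bias Outward balloon pressure; 0 evolves purely by the
#'   region statistics, positive values let fronts advance through weak
#'   guidance (units of guidance-image squared intensity, scaled by 0.01).
#' @return An object of class `"seg_params"`.
#' @export
seg_params <- function(min_object_px = NULL, max_iterations = 200L,
                       smoothing = 1L, expansion_bias = 1) {
  if (!is.null(min_object_px) && min_object_px < 1)
    stop("min_object_px must be positive")
  if (max_iterations < 1) stop("max_iterations must be positive")
  if (smoothing < 0) stop("smoothing must be non-negative")
  structure(list(min_object_px = min_object_px,
                 max_iterations = as.integer(max_iterations),
                 smoothing = as.integer(smoothing),
                 expansion_bias = as.numeric(expansion_bias)),
            class = "seg_params")
}

resolve_min_object_px <- function(params, dims) {
  if (!is.null(params$min_object_px)) return(as.integer(params$min_object_px))
  max(1L, as.integer(round(100 * prod(dims) / 1024^2)))
}

#' Normalized absolute difference of two frames
#'
#' Per-pixel absolute intensity difference of two frames of the same stack,
#' min-max normalized to [0, 1]. Identical frames yield an all-zero image
#' (the degenerate normalization is guarded). Absolute difference is used
#' because contrast inversion across focus makes cells bright in one frame
#' and dark in the other regardless of halo polarity.
#'
#' @param stack A [zstack()].
#' @param k1,k2 Distinct frame indices.
#' @return Object of class `"difference_image"`: list with `values`
#'   (numeric matrix in [0,1]) and source indices `k1`, `k2`.
#' @export
difference_image <- function(stack, k1, k2) {
  n <- n_frames(stack)
  if (k1 == k2) stop("k1 and k2 must differ")
  if (k1 < 1L || k2 < 1L || k1 > n || k2 > n)
    stop("frame index out of bounds")
  v <- abs(stack$frames[[k1]] - stack$frames[[k2]])
  rng <- range(v)
  v <- if (rng[2L] > rng[1L]) (v - rng[1L]) / (rng[2L] - rng[1L])
       else matrix(0, nrow(v), ncol(v))
  structure(list(values = v, k1 = as.integer(k1), k2 = as.integer(k2)),
            class = "difference_image")
}

diff_values <- function(x) {
  if (inherits(x, "difference_image")) x$values else x
}

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

NEIGH8 <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

#' Label 8-connected components of a binary image
#'
#' Pure-R vectorized min-label propagation: every foreground pixel starts
#' with a unique id and repeatedly adopts the minimum id in its 8-
#' neighbourhood until a fixed point, then labels are renumbered 1..K in
#' raster order of their minimum id. Deterministic.
#'
#' @param binary Matrix; non-zero entries are foreground.
#' @return Integer label matrix (0 background, 1..K objects).
#' @export
label_components <- function(binary) {
  fg <- binary != 0
  nr <- nrow(binary); nc <- ncol(binary)
  m <- matrix(Inf, nr, nc)
  m[fg] <- which(fg)
  repeat {
    nb <- m
    for (k in seq_len(nrow(NEIGH8)))
      nb <- pmin(nb, shift_mat(m, NEIGH8[k, 1L], NEIGH8[k, 2L], Inf))
    nb[!fg] <- Inf
    new <- pmin(m, nb)
    if (identical(new, m)) break
    m <- new
  }
  lab <- matrix(0L, nr, nc)
  if (any(fg)) {
    ids <- m[fg]
    lab[fg] <- match(ids, sort(unique(ids)))
  }
  lab
}

#' Initial cell regions from a strong-difference image
#'
#' Otsu-binarizes the difference image, labels 8-connected components, and
#' removes components smaller than `min_object_px` pixels (camera and
#' debris artifacts), renumbering the survivors 1..K. A constant
#' (degenerate) difference image yields an empty mask rather than an error.
#'
#' @param diff A [difference_image()] or a plain numeric matrix.
#' @param params [seg_params()].
#' @return Integer label mask.
#' @export
initial_mask <- function(diff, params = seg_params()) {
  v <- diff_values(diff)
  if (length(unique(as.vector(v))) < 2L)
    return(matrix(0L, nrow(v), ncol(v)))
  bin <- binarize_otsu(v)
  lab <- label_components(bin)
  min_px <- resolve_min_object_px(params, dim(v))
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_px)
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  lab
}

#' Expand labeled regions with a guided morphological active contour
#'
#' Region-based (Chan–Vese-style) front propagation on the weak-difference
#' guidance image. Each iteration, background pixels 8-adjacent to exactly
#' one region are annexed when their guidance intensity is closer to the
#' foreground mean than to the background mean, relaxed by the outward
#' `expansion_bias`; `smoothing` passes then drop newly added pixels with
#' fewer than 3 same-label neighbours (curvature regularization). Pixels
#' adjacent to two different regions are never annexed, so colliding fronts
#' freeze at first contact and labels never merge — the property that keeps
#' adherent cells separate. Evolution is expansion-only and stops at the
#' first iteration with no accepted pixel or after `max_iterations`.
#'
#' @param init Integer label mask of seed regions.
#' @param guide A [difference_image()] (or matrix) of the weakly defocused
#'   pair, same dimensions as `init`.
#' @param params [seg_params()].
#' @return Integer label mask with the same label set as `init`.
#' @export
evolve_contours <- function(init, guide, params = seg_params()) {
  g <- diff_values(guide)
  if (!all(dim(init) == dim(g)))
    stop("init and guide dimensions differ")
  L <- init
  storage.mode(L) <- "integer"
  if (max(L) == 0L) return(L)
  tau <- 0.01
  for (it in seq_len(params$max_iterations)) {
    fg <- L > 0L
    if (all(fg)) break
    c_fg <- mean(g[fg]); c_bg <- mean(g[!fg])
    # per-pixel max neighbour label, and min over positive neighbour labels
    nmax <- matrix(0L, nrow(L), ncol(L))
    pos <- matrix(Inf, nrow(L), ncol(L))
    Lp <- ifelse(fg, as.numeric(L), Inf)
    for (k in seq_len(nrow(NEIGH8))) {
      nmax <- pmax(nmax, shift_mat(L, NEIGH8[k, 1L], NEIGH8[k, 2L], 0L))
      pos <- pmin(pos, shift_mat(Lp, NEIGH8[k, 1L], NEIGH8[k, 2L], Inf))
    }
    cand <- !fg & nmax > 0L & (pos == nmax)   # touching exactly one region
    if (!any(cand)) break
    score <- (g - c_bg)^2 - (g - c_fg)^2
    acc <- cand & (score > -params$expansion_bias * tau)
    if (!any(acc)) break
    newL <- L
    newL[acc] <- as.integer(nmax[acc])
    for (s in seq_len(params$smoothing)) {
      same <- matrix(0L, nrow(L), ncol(L))
      for (k in seq_len(nrow(NEIGH8))) {
        sh <- shift_mat(newL, NEIGH8[k, 1L], NEIGH8[k, 2L], 0L)
        same <- same + ((sh == newL) & (newL > 0L))
      }
      drop <- acc & (same < 3L)
      if (!any(drop)) break
      newL[drop] <- 0L
      acc <- acc & !drop
    }
    if (all(newL == L)) break
    L <- newL
  }
  L
}

#' Segment a z-stack given a selected frame quad
#'
#' Composes the pipeline: the strong difference `|I-- - I++|` is
#' binarized and size-filtered into seed regions ([initial_mask()]), which
#' then expand under guidance of the weak difference `|I- - I+|`
#' ([evolve_contours()]). Fully deterministic.
#'
#' @param stack A [zstack()].
#' @param quad A frame quad from [select_frames_maxinfo()] or
#'   [select_frames_fixed()].
#' @param params [seg_params()].
#' @return Integer label mask of segmented cells.
#' @export
segment_stack <- function(stack, quad, params = seg_params()) {
  n <- n_frames(stack)
  idx <- quad_indices(quad)
  if (any(idx < 1L) || any(idx > n))
    stop("quad indices out of bounds for this stack")
  strong <- difference_image(stack, quad$i_minus_minus, quad$i_plus_plus)
  init <- initial_mask(strong, params)
  weak <- difference_image(stack, quad$i_minus, quad$i_plus)
  evolve_contours(init, weak, params)
}
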