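# Synthetic bright-field defocused z-stacks with known ground truth.
# The generator reproduces the phenomena that make frame selection hard on
# real stacks: blur growing with distance from focus, bright/dark contrast
# inversion of cells on opposite sides of focus, per-cell focal offsets
# (cells do not sit on a flat plane), camera stripe banding on selected
# frames, and additive pixel noise.

#' Specification of a synthetic z-stack
#'
#' Defaults describe the reference study conditions: 21 frames at 10 um
#' spacing, 256x256 12-bit frames on a mid-gray (2048) background, 15
#' well-separated elliptical cells of 7-13 px semi-axis.
#'
#' @param n_frames Number of frames (>= 5).
#' @param spacing_um Physical spacing between frames (um).
#' @param frame_shape Integer `(rows, cols)`.
#' @param n_cells Number of cells to place (>= 0).
#' @param radius_px_range `(min, max)` ellipse semi-axis range in pixels.
#' @param cell_z_jitter_um Per-cell focal offset drawn uniformly from
#'   `[-cell_z_jitter_um, +cell_z_jitter_um]`; emulates cells at different
#'   heights. 0 puts every cell exactly on the stack's focal plane.
#' @param blur_per_um Gaussian blur growth rate: a cell `d` um from its own
#'   focus is rendered with blur sigma `blur_per_um * d` pixels.
#' @param halo_gain Amplitude of the contrast inversion: a cell's additive
#'   intensity at height z is `halo_gain * tanh((z - z_cell)/spacing_um) *
#'   exp(-((z - z_cell)/halo_decay_um)^2)`, near zero at the cell's own
#'   focus and oppositely signed (bright/dark) above versus below it.
#' @param halo_decay_um Scale of the Gaussian envelope over which defocus
#'   contrast fades: bright-field halo contrast peaks at moderate defocus
#'   and decays toward extreme defocus as light spreads.
#' @param noise_sigma Additive Gaussian pixel noise (intensity units).
#' @param stripe_noise_frames Integer frame indices receiving horizontal
#'   sinusoidal camera banding.
#' @param stripe_amplitude,stripe_period_px Banding amplitude (intensity
#'   units) and period (pixel rows).
#' @param min_separation_px Minimum gap between cell bounding circles, so
#'   defocus halos of neighbouring cells stay separable.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_frames = 21L, spacing_um = 10,
                           frame_shape = c(256L, 256L), n_cells = 15L,
                           radius_px_range = c(7, 13),
                           cell_z_jitter_um = 0, blur_per_um = 0.05,
                           halo_gain = 700, halo_decay_um = 100,
                           noise_sigma = 30,
                           stripe_noise_frames = integer(0),
                           stripe_amplitude = 400, stripe_period_px = 64L,
                           min_separation_px = 14, seed = 1L) {
  stopifnot(n_frames >= 5L, spacing_um > 0, length(frame_shape) == 2L,
            all(frame_shape >= 16L), n_cells >= 0L,
            length(radius_px_range) == 2L, all(radius_px_range > 0),
            radius_px_range[1L] <= radius_px_range[2L],
            cell_z_jitter_um >= 0, blur_per_um > 0, halo_gain > 0,
            halo_decay_um > 0, noise_sigma >= 0, stripe_amplitude >= 0,
            stripe_period_px >= 2L)
  if (length(stripe_noise_frames) > 0 &&
      (any(stripe_noise_frames < 1L) || any(stripe_noise_frames > n_frames)))
    stop("stripe_noise_frames out of bounds")
  structure(
    list(n_frames = as.integer(n_frames), spacing_um = spacing_um,
         frame_shape = as.integer(frame_shape), n_cells = as.integer(n_cells),
         radius_px_range = radius_px_range,
         cell_z_jitter_um = cell_z_jitter_um, blur_per_um = blur_per_um,
         halo_gain = halo_gain, halo_decay_um = halo_decay_um,
         noise_sigma = noise_sigma,
         stripe_noise_frames = as.integer(stripe_noise_frames),
         stripe_amplitude = stripe_amplitude,
         stripe_period_px = as.integer(stripe_period_px),
         min_separation_px = min_separation_px, seed = as.integer(seed)),
    class = "synthetic_spec")
}

with_fixed_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# ellipse membership grid for a cell, within the window rows/cols given
ellipse_mask <- function(rows, cols, cx, cy, a, b, theta) {
  dx <- outer(rep(1, length(rows)), cols - cx)
  dy <- outer(rows - cy, rep(1, length(cols)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# signed, envelope-decayed halo contrast of a cell dz um from its own focus
halo_amp <- function(spec, dz) {
  spec$halo_gain * tanh(dz / spec$spacing_um) *
    exp(-(dz / spec$halo_decay_um)^2)
}

# Horizontal banding: a sinusoid down the rows whose phase drifts as a
# random walk, as camera strip noise does; the drift makes the band
# pattern of each frame individual (binarized stripes of two frames look
# mutually random, so set complexity discounts striped frames instead of
# rewarding their shared regularity). Consumes RNG draws.
add_stripes <- function(pixels, amplitude, period_px, phase,
                        drift_sd = 0.3) {
  nr <- nrow(pixels)
  drift <- cumsum(stats::rnorm(nr, 0, drift_sd))
  band <- amplitude * sin(2 * pi * (seq_len(nr) - 1) / period_px +
                            phase + drift)
  pixels + matrix(band, nr, ncol(pixels))
}

clip_to_depth <- function(pixels, bit_depth = 12L) {
  out <- pmin(pmax(round(pixels), 0), 2^bit_depth - 1)
  # coerce back to a plain integer matrix (blur may return an EBImage Image)
  matrix(as.integer(out), dim(pixels)[1L], dim(pixels)[2L])
}

# Gaussian blur with the kernel clipped to fit the (possibly small) window
gaussian_blur <- function(x, sigma) {
  radius <- 2L * ceiling(3 * sigma) + 1L
  fit <- min(dim(x))
  fit <- if (fit %% 2L == 0L) fit - 1L else fit
  radius <- min(radius, fit)
  if (radius < 3L) return(x)
  out <- EBImage::gblur(x, sigma = sigma, radius = radius)
  matrix(as.numeric(out), nrow(x), ncol(x))
}

#' Inject camera stripe banding into a frame
#'
#' Adds a horizontal sinusoidal banding pattern (constant along rows,
#' varying down the image) with a seed-determined random phase, then clips
#' to the bit depth. Banding spreads the intensity histogram, so the
#' frame's Shannon entropy increases — the artifact that breaks naive
#' entropy-based focus reasoning on real cameras.
#'
#' @param pixels Integer intensity matrix.
#' @param amplitude Banding amplitude (intensity units); 0 returns the
#'   frame unchanged.
#' @param period_px Banding period in rows (>= 2).
#' @param seed Integer seed for the random phase.
#' @param bit_depth Clipping range.
#' @return Integer matrix of the same dimensions.
#' @export
inject_stripe_noise <- function(pixels, amplitude, period_px = 64L, seed = 1L,
                                bit_depth = 12L) {
  if (period_px < 2L) stop("period_px must be >= 2")
  if (amplitude == 0) return(pixels)
  clip_to_depth(
    with_fixed_rng(seed,
      add_stripes(pixels, amplitude, period_px,
                  phase = stats::runif(1, 0, 2 * pi))),
    bit_depth)
}

#' Generate a synthetic defocused z-stack with ground truth
#'
#' Cells are ellipses with rejection-sampled non-overlapping centers,
#' random semi-axes and orientation, and a per-cell focal height
#' `z_focus + U(-jitter, +jitter)`. The frame at height z renders each cell
#' as its ellipse indicator blurred with a Gaussian of sigma
#' `blur_per_um * |z - z_cell|` and scaled by
#' `halo_gain * tanh((z - z_cell)/spacing_um)`, added to a mid-gray
#' background — near-zero contrast at the cell's own focus and
#' opposite-signed (bright/dark) halos above versus below it. Gaussian
#' pixel noise is added everywhere and sinusoidal banding to the frames
#' listed in the spec; intensities are clipped to 12 bits.
#'
#' Ground truth records each cell's center, its sharp ellipse footprint
#' (the in-focus mask, regardless of the cell's own z offset), the planted
#' global focus index (the middle frame), and the per-cell focal offsets.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `stack` (a [zstack()]) and `truth` (list:
#'   `centers` data frame with `label`, `x`, `y`; `masks` label matrix;
#'   `focus_index`; `per_cell_z_um`).
#' @export
generate_zstack <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nr <- spec$frame_shape[1L]; nc <- spec$frame_shape[2L]
  n <- spec$n_frames
  focus_index <- (n + 1L) %/% 2L
  z_focus <- (focus_index - 1L) * spec$spacing_um
  bg <- 2048

  with_fixed_rng(spec$seed, {
    # --- place cells by rejection sampling ---------------------------------
    cells <- list()
    if (spec$n_cells > 0L) {
      for (i in seq_len(spec$n_cells)) {
        placed <- FALSE
        for (attempt in seq_len(1000L)) {
          a <- stats::runif(1, spec$radius_px_range[1L], spec$radius_px_range[2L])
          b <- stats::runif(1, spec$radius_px_range[1L], spec$radius_px_range[2L])
          theta <- stats::runif(1, 0, pi)
          r <- max(a, b)
          margin <- r + 4
          if (nc - margin <= margin + 1 || nr - margin <= margin + 1)
            next
          cx <- stats::runif(1, margin + 1, nc - margin)
          cy <- stats::runif(1, margin + 1, nr - margin)
          ok <- TRUE
          for (cell in cells) {
            gap <- sqrt((cx - cell$cx)^2 + (cy - cell$cy)^2) -
              (r + max(cell$a, cell$b))
            if (gap < spec$min_separation_px) { ok <- FALSE; break }
          }
          if (ok) {
            cells[[i]] <- list(cx = cx, cy = cy, a = a, b = b, theta = theta)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("arena too crowded: could not place cell ", i,
               " after 1000 attempts")
      }
    }
    k_cells <- length(cells)
    z_cell <- z_focus + if (k_cells > 0L)
      stats::runif(k_cells, -spec$cell_z_jitter_um, spec$cell_z_jitter_um)
    else numeric(0)

    # --- ground-truth masks and centers ------------------------------------
    masks <- matrix(0L, nr, nc)
    for (i in seq_len(k_cells)) {
      cell <- cells[[i]]
      masks[ellipse_mask(seq_len(nr), seq_len(nc), cell$cx, cell$cy,
                         cell$a, cell$b, cell$theta)] <- i
    }
    centers <- data.frame(
      label = seq_len(k_cells),
      x = vapply(cells, function(c) round(c$cx), numeric(1)),
      y = vapply(cells, function(c) round(c$cy), numeric(1)))

    # --- render frames ------------------------------------------------------
    stripe_phase <- stats::runif(n, 0, 2 * pi)
    noise <- if (spec$noise_sigma > 0)
      lapply(seq_len(n), function(k)
        matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma), nr, nc))
    else NULL

    frames <- vector("list", n)
    shared_focus <- k_cells > 0L && length(unique(z_cell)) == 1L
    for (k in seq_len(n)) {
      z <- (k - 1L) * spec$spacing_um
      img <- matrix(bg, nr, nc)
      if (shared_focus) {
        # all cells at one height: one blur of the summed indicator per frame
        dz <- z - z_cell[1L]
        amp <- halo_amp(spec, dz)
        if (amp != 0) {
          ind <- matrix(0, nr, nc)
          ind[masks > 0L] <- 1
          sigma <- spec$blur_per_um * abs(dz)
          blurred <- if (sigma >= 0.3) gaussian_blur(ind, sigma) else ind
          img <- img + amp * blurred
        }
      } else if (k_cells > 0L) {
        for (i in seq_len(k_cells)) {
          cell <- cells[[i]]
          dz <- z - z_cell[i]
          amp <- halo_amp(spec, dz)
          if (amp == 0) next
          sigma <- spec$blur_per_um * abs(dz)
          r <- max(cell$a, cell$b)
          h <- ceiling(r + 3 * sigma + 2)
          rows <- max(1L, floor(cell$cy - h)):min(nr, ceiling(cell$cy + h))
          cols <- max(1L, floor(cell$cx - h)):min(nc, ceiling(cell$cx + h))
          win <- ellipse_mask(rows, cols, cell$cx, cell$cy,
                              cell$a, cell$b, cell$theta) * 1
          if (sigma >= 0.3) win <- gaussian_blur(win, sigma)
          img[rows, cols] <- img[rows, cols] + amp * win
        }
      }
      if (!is.null(noise)) img <- img + noise[[k]]
      if (k %in% spec$stripe_noise_frames)
        img <- add_stripes(img, spec$stripe_amplitude, spec$stripe_period_px,
                           stripe_phase[k])
      frames[[k]] <- clip_to_depth(img, 12L)
    }

    stack <- zstack(frames, spacing_um = spec$spacing_um,
                    stack_id = sprintf("synthetic-seed%d", spec$seed),
                    bit_depth = 12L)
    list(stack = stack,
         truth = list(centers = centers, masks = masks,
                      focus_index = focus_index,
                      per_cell_z_um = z_cell - z_focus))
  })
}

#' Reference noisy study conditions for strategy comparison
#'
#' The default [synthetic_spec()] with the two disturbance phenomena turned
#' on: per-cell focal jitter and camera strip banding on a seed-determined
#' random subset of off-focus frames. These are the conditions under which
#' a fixed frame-selection strategy has no way to adapt, while the
#' information-maximizing strategy can route around corrupted frames.
#'
#' @param seed Integer seed (also seeds the choice of striped frames, via
#'   an independent stream).
#' @param cell_z_jitter_um Per-cell focal jitter (um), default 8.
#' @param n_stripe_frames How many off-focus frames receive banding.
#' @param ... Further overrides passed to [synthetic_spec()].
#' @return A [synthetic_spec()].
#' @export
noisy_synthetic_spec <- function(seed, cell_z_jitter_um = 8,
                                 n_stripe_frames = 3L, ...) {
  spec <- synthetic_spec(seed = seed, cell_z_jitter_um = cell_z_jitter_um,
                         ...)
  candidates <- setdiff(seq_len(spec$n_frames), (spec$n_frames + 1L) %/% 2L)
  spec$stripe_noise_frames <- with_fixed_rng(
    (spec$seed %% 100000L) * 7919L + 13L,
    as.integer(sort(sample(candidates, n_stripe_frames))))
  spec
}
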