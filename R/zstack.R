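#' Construct a z-stack of bright-field frames
#'
#' A z-stack is an ordered set of grayscale frames of the same field of view
#' acquired at equally spaced focal depths. Frames are stored as integer
#' matrices (rows = image rows, columns = image columns); the frame at list
#' position `k` sits at height `(k - 1) * spacing_um` micrometres above the
#' first frame.
#'
#' @param frames List of non-empty integer matrices, all with identical
#'   dimensions. At least 5 frames are required: downstream selection needs
#'   one in-focus frame plus four defocused frames.
#' @param spacing_um Positive physical distance between consecutive frames,
#'   in micrometres.
#' @param stack_id Text label identifying the stack.
#' @param bit_depth Intensity bit depth, one of 8, 12 or 16. If `NULL` it is
#'   inferred from the maximum observed intensity (< 256 gives 8, < 4096
#'   gives 12, otherwise 16). The inference is advisory: entropy and Otsu
#'   thresholding operate on observed intensity ranges, so a misdetected
#'   depth cannot change selection or segmentation results.
#' @return An object of class `"zstack"`: a list with elements `frames`,
#'   `spacing_um`, `stack_id`, `bit_depth`.
#' @seealso [read_zstack()] to load one from disk, [generate_zstack()] to
#'   simulate one.
#' @export
zstack <- function(frames, spacing_um, stack_id = "stack", bit_depth = NULL) {
  if (!is.list(frames) || length(frames) < 5L)
    stop("stack too small: a z-stack needs at least 5 frames")
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L || spacing_um <= 0)
    stop("spacing_um must be a single positive number")
  dims <- lapply(frames, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("every frame must be a matrix")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("inconsistent frame geometry: all frames must share dimensions")
  if (nrow(frames[[1L]]) == 0L || ncol(frames[[1L]]) == 0L)
    stop("frames must be non-empty")
  maxv <- max(vapply(frames, max, numeric(1)))
  minv <- min(vapply(frames, min, numeric(1)))
  if (minv < 0) stop("negative intensities are not allowed")
  if (is.null(bit_depth)) {
    bit_depth <- if (maxv < 256) 8L else if (maxv < 4096) 12L else 16L
  }
  if (!bit_depth %in% c(8L, 12L, 16L))
    stop("bit_depth must be 8, 12 or 16")
  if (maxv >= 2^bit_depth)
    stop("intensities exceed the stated bit depth")
  frames <- lapply(frames, function(f) {
    storage.mode(f) <- "integer"
    f
  })
  structure(
    list(frames = frames, spacing_um = as.numeric(spacing_um),
         stack_id = as.character(stack_id), bit_depth = as.integer(bit_depth)),
    class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<zstack '%s': %d frames of %dx%d, %d-bit, %.3g um spacing>\n",
              x$stack_id, length(x$frames), d[1L], d[2L], x$bit_depth,
              x$spacing_um))
  invisible(x)
}

#' Number of frames in a z-stack
#' @param stack A [zstack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) length(stack$frames)

#' Physical heights of the frames of a z-stack
#' @param stack A [zstack()].
#' @return Numeric vector, `(k - 1) * spacing_um` for frame `k`.
#' @export
frame_heights <- function(stack) (seq_len(n_frames(stack)) - 1) * stack$spacing_um

# Locale-independent numeric-aware ordering of file names, so "frame2" sorts
# before "frame10" the way microscope exports expect.
natural_order <- function(x) {
  padded <- vapply(x, function(s) {
    m <- gregexpr("\\d+", s)
    regmatches(s, m) <- lapply(regmatches(s, m), formatC,
                               width = 20L, flag = "0")
    s
  }, character(1), USE.NAMES = FALSE)
  order(padded, method = "radix")
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    } else if (ext == "png") {
      v <- png::readPNG(path)
      iv <- round(v * 65535)
      # 8-bit PNG samples land on multiples of 257 after the [0,1] scaling
      if (all(iv %% 257 == 0)) {
        iv <- iv / 257
        attr(iv, "bits.per.sample") <- 8L
      } else {
        attr(iv, "bits.per.sample") <- 16L
      }
      iv
    } else {
      stop("unsupported image format: ", ext)
    }
  }, error = function(e) stop("failed to read '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] >= 3L &&
        all(img[, , 1L] == img[, , 2L]) && all(img[, , 1L] == img[, , 3L])) {
      a <- attributes(img)
      img <- img[, , 1L]
      attr(img, "bits.per.sample") <- a$bits.per.sample
    } else {
      stop("'", path, "' is not grayscale")
    }
  }
  img
}

#' Read a z-stack from disk
#'
#' Accepts either a multi-page TIFF or a directory of single-frame TIFF/PNG
#' grayscale images. Directory entries are ordered by numeric-aware
#' (natural-sort) file name, so `frame2.tif` precedes `frame10.tif`
#' regardless of filesystem enumeration order.
#'
#' 12-bit data stored in 16-bit containers is detected when the maximum
#' intensity stays below 4096 and reported as bit depth 12; the detection is
#' advisory only (see [zstack()]).
#'
#' @param path Multi-page TIFF file, or directory containing at least 5
#'   TIFF/PNG frames.
#' @param spacing_um Physical z-spacing between consecutive frames (um).
#' @param stack_id Optional label; defaults to the base name of `path`.
#' @return A [zstack()].
#' @export
read_zstack <- function(path, spacing_um, stack_id = NULL) {
  if (is.null(stack_id)) stack_id <- basename(path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[natural_order(basename(files))]
    if (length(files) < 5L)
      stop("stack too small: found ", length(files), " image files in '",
           path, "'")
    imgs <- lapply(files, read_one_image)
  } else if (file.exists(path)) {
    imgs <- tryCatch(
      tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
      error = function(e) stop("failed to read '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    if (!is.list(imgs)) imgs <- list(imgs)
    if (length(imgs) < 5L)
      stop("stack too small: '", path, "' has ", length(imgs), " pages")
  } else {
    stop("failed to read '", path, "': no such file or directory")
  }
  container_bits <- vapply(imgs, function(im) {
    b <- attr(im, "bits.per.sample")
    if (is.null(b)) 16L else as.integer(b)
  }, integer(1))
  frames <- lapply(imgs, function(im) {
    attributes(im)[setdiff(names(attributes(im)), "dim")] <- NULL
    im
  })
  dims <- vapply(frames, function(f) paste(dim(f), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L)
    stop("inconsistent frame geometry: pages/files differ in size")
  maxv <- max(vapply(frames, max, numeric(1)))
  bit_depth <- if (max(container_bits) <= 8L) 8L
               else if (maxv < 4096) 12L else 16L
  zstack(frames, spacing_um = spacing_um, stack_id = stack_id,
         bit_depth = bit_depth)
}

#' Validate a label mask
#'
#' A label mask is an integer matrix in which 0 marks background and each
#' value `k > 0` marks the pixels of cell object `k`; positive labels must
#' form the contiguous set `1..K`.
#'
#' @param mask Integer matrix of non-negative labels.
#' @return `mask`, invisibly, after validation.
#' @export
validate_label_mask <- function(mask) {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop("mask must be a numeric matrix")
  if (any(mask < 0) || any(mask != floor(mask)))
    stop("mask labels must be non-negative integers")
  pos <- sort(unique(mask[mask > 0]))
  if (length(pos) > 0 && !identical(as.integer(pos), seq_len(length(pos))))
    stop("mask labels must form a contiguous set 1..K")
  invisible(mask)
}

#' Write a label mask as a 16-bit TIFF
#'
#' Label values are preserved exactly: reading the file back yields a
#' bit-identical grid.
#'
#' @param mask A label mask (see [validate_label_mask()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  validate_label_mask(mask)
  if (max(mask) > 65535)
    stop("label overflow for 16-bit container (max label ",
         max(mask), ")")
  ok <- tryCatch(tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L),
                 error = function(e) stop("failed to write '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a label mask written by [write_label_mask()]
#' @param path TIFF file path.
#' @return Integer label matrix.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Read expert cell-center ground truth
#'
#' Parses a delimited text table (CSV, or TSV detected from a tab in the
#' header line) with columns `stack_id`, `x`, `y`, where `x` is the pixel
#' column and `y` the pixel row of one expert-marked cell center (1-based).
#'
#' @param path CSV/TSV file path.
#' @return Named list, one data frame of centers (`x`, `y`) per `stack_id`,
#'   row order preserved.
#' @export
read_ground_truth <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("stack_id", "x", "y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "))
  parse_num <- function(v, col) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) | out < 0)
    if (length(bad) > 0)
      stop("parse error at row ", bad[1L], ": column '", col,
           "' has value '", v[bad[1L]], "'")
    out
  }
  df$x <- parse_num(df$x, "x")
  df$y <- parse_num(df$y, "y")
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  split(df[c("x", "y")], factor(df$stack_id, levels = unique(df$stack_id)))
}

#' Write a z-stack to a directory of single-frame TIFF files
#'
#' Frames are written as `frame_001.tif`, `frame_002.tif`, ... in 16-bit
#' containers, so [read_zstack()] recovers the stack (with 12-bit data
#' redetected from the intensity range).
#'
#' @param stack A [zstack()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_zstack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in seq_len(n_frames(stack))) {
    tiff::writeTIFF(stack$frames[[k]] / 65535,
                    file.path(dir, sprintf("frame_%03d.tif", k)),
                    bits.per.sample = 16L)
  }
  invisible(dir)
}
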