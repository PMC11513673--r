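# Rendering QR symbols to 100x100 single-channel images and materialising
# the labeled image dataset that feeds the classifier.

#' Render a QR matrix as a binary image
#'
#' Adds a light quiet zone of `quiet_zone` modules around the symbol
#' (57 -> 65 logical modules with the default 4), then resamples to
#' `size` x `size` pixels by nearest-neighbour indexing: pixel (r, c)
#' (0-indexed) takes the module at (floor(r * L / size),
#' floor(c * L / size)) where L is the logical side. Dark modules map to
#' intensity 0, light to 255, so the output contains exactly two values —
#' no anti-aliasing, keeping the image as binary as the symbol itself.
#'
#' @param matrix A `qr_matrix`.
#' @param size Output side in pixels (default 100).
#' @param quiet_zone Light border width in modules (default 4, the
#'   standard minimum).
#' @return A `qr_image`: integer matrix `size` x `size` with values in
#'   \{0, 255\}, plus label/subject metadata attributes when available.
#' @export
render <- function(matrix, size = 100L, quiet_zone = 4L) {
  m <- if (inherits(matrix, "qr_matrix")) matrix$modules else matrix
  side <- nrow(m)
  logical_side <- side + 2L * as.integer(quiet_zone)
  if (size < logical_side)
    stop(sprintf("size %d is smaller than the %d-module logical side (symbol + quiet zone)",
                 size, logical_side))
  grid <- matrix(0L, logical_side, logical_side)
  grid[quiet_zone + seq_len(side), quiet_zone + seq_len(side)] <- m
  idx <- as.integer(floor((0:(size - 1L)) * logical_side / size)) + 1L
  px <- ifelse(grid[idx, idx] == 1L, 0L, 255L)
  structure(px, class = c("qr_image", class(px)))
}

#' @export
print.qr_image <- function(x, ...) {
  cat(sprintf("<qr_image> %dx%d pixels, %d dark\n",
              nrow(x), ncol(x), sum(x == 0L)))
  invisible(x)
}

qr_image_filename <- function(subject_id, record_index, label)
  sprintf("%s_%04d_%s.png", subject_id, record_index, label)

#' Build the QR image dataset from feature vectors
#'
#' Encodes each 12-feature record as a version-10 level-M symbol, renders
#' it at 100x100, writes one 8-bit grayscale PNG per record with a
#' deterministic filename, and writes a `manifest.csv`
#' (`path,label,subject_id,record_index`) describing the dataset. The
#' whole construction is deterministic: rebuilding from the same inputs
#' reproduces identical files.
#'
#' @param vectors Feature data frame from [to_feature_vectors()] (rows
#'   from several subjects may be concatenated with `rbind`).
#' @param out_dir Output directory (created if needed).
#' @param size,quiet_zone,precision Rendering and serialization options.
#' @param mask_id Mask policy passed to [qr_encode()].
#' @return The manifest data frame (with per-label counts as the
#'   `"counts"` attribute), invisibly.
#' @export
build_dataset <- function(vectors, out_dir, size = 100L, quiet_zone = 4L,
                          precision = 4L, mask_id = "auto") {
  stopifnot(is.data.frame(vectors), nrow(vectors) >= 1L)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, showWarnings = FALSE, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  rows <- vector("list", nrow(vectors))
  for (i in seq_len(nrow(vectors))) {
    fv <- vectors[i, ]
    img <- render(qr_encode(serialize_features(fv, precision), mask_id),
                  size = size, quiet_zone = quiet_zone)
    fname <- qr_image_filename(fv$subject_id, fv$record_index, fv$label)
    path <- file.path(out_dir, fname)
    png::writePNG(matrix(img / 255, nrow(img), ncol(img)), path)
    rows[[i]] <- data.frame(path = path, label = fv$label,
                            subject_id = fv$subject_id,
                            record_index = fv$record_index,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (anyDuplicated(manifest$path))
    stop("duplicate image paths in manifest (subject_id/record_index collision)")
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  counts <- table(manifest$label)
  message(sprintf("wrote %d images: %s", nrow(manifest),
                  paste(names(counts), as.integer(counts),
                        sep = "=", collapse = ", ")))
  attr(manifest, "counts") <- counts
  invisible(manifest)
}

#' Read a dataset manifest
#' @param path Path to a `manifest.csv` or to the directory holding one.
#' @return Manifest data frame.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  manifest <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "label", "subject_id", "record_index")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  manifest
}

#' Load manifest images into an array
#'
#' @param manifest Manifest data frame.
#' @return Numeric array `side x side x n` with values in \[0, 1\]
#'   (dark = 0).
#' @export
load_images <- function(manifest) {
  n <- nrow(manifest)
  first <- png::readPNG(manifest$path[1L])
  if (length(dim(first)) > 2L) first <- first[, , 1L]
  side <- nrow(first)
  x <- array(0, c(side, side, n))
  x[, , 1L] <- first
  for (i in seq_len(n)[-1L]) {
    img <- png::readPNG(manifest$path[i])
    if (length(dim(img)) > 2L) img <- img[, , 1L]
    x[, , i] <- img
  }
  x
}
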