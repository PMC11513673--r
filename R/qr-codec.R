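# QR version 10, error-correction level M, byte mode: 57x57 modules,
# 216 data + 130 EC codewords in 5 interleaved blocks. The codec is
# version-parametric internally but only V10-M is exercised and supported.

QR_VERSION <- 10L
QR_SIDE <- 17L + 4L * QR_VERSION            # 57
QR_DATA_CODEWORDS <- 216L
QR_TOTAL_CODEWORDS <- 346L
QR_BLOCK_SIZES <- c(43L, 43L, 43L, 43L, 44L) # data octets per RS block
QR_EC_PER_BLOCK <- 26L
# byte-mode capacity: (216*8 - 4 mode bits - 16 count bits) %/% 8
QR_BYTE_CAPACITY <- 213L
QR_ALIGNMENT_CENTERS <- c(6L, 28L, 50L)      # 0-indexed

#' Construct a QR payload
#'
#' Wraps text (Latin-1) or raw octets destined for a version-10, level-M
#' byte-mode symbol, enforcing the 213-octet capacity.
#'
#' @param x Character scalar or integer/raw vector of octets.
#' @return A `qr_payload` with fields `text` and `bytes`.
#' @export
qr_payload <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    bytes <- as.integer(charToRaw(iconv(x, to = "latin1")))
    text <- x
  } else {
    bytes <- as.integer(x)
    if (length(bytes) && any(bytes < 0L | bytes > 255L))
      stop("octets must be in 0..255")
    if (length(bytes) && any(bytes == 0L)) {
      text <- NA_character_  # NUL octets have no R string rendering
    } else {
      text <- rawToChar(as.raw(bytes))
      Encoding(text) <- "latin1"
    }
  }
  if (length(bytes) > QR_BYTE_CAPACITY)
    stop(sprintf("payload of %d octets exceeds the %d-octet capacity of a version-10 level-M symbol",
                 length(bytes), QR_BYTE_CAPACITY))
  structure(list(text = text, bytes = bytes), class = "qr_payload")
}

#' Serialize a feature vector to a QR payload
#'
#' Renders the 12 gait features as comma-joined fixed-point decimals with
#' `precision` fraction digits (no whitespace) — a human-readable,
#' capacity-safe text that a stock QR scanner displays directly.
#'
#' @param values Numeric vector of 12 finite values, or a one-row feature
#'   data frame from [to_feature_vectors()].
#' @param precision Fraction digits (default 4).
#' @return A `qr_payload`.
#' @export
serialize_features <- function(values, precision = 4L) {
  if (is.data.frame(values)) {
    stopifnot(nrow(values) == 1L)
    values <- as.numeric(values[1L, feature_names()])
  }
  values <- as.numeric(values)
  if (length(values) != 12L || !all(is.finite(values)))
    stop("expected exactly 12 finite feature values")
  text <- paste(sprintf(paste0("%.", precision, "f"), values), collapse = ",")
  if (nchar(text) > QR_BYTE_CAPACITY)
    stop(sprintf("serialized payload has %d octets, exceeding the %d-octet capacity",
                 nchar(text), QR_BYTE_CAPACITY))
  qr_payload(text)
}

#' Assemble the 216 data codewords of a symbol
#'
#' Byte-mode bitstream: mode indicator 0100, 16-bit character count, the
#' payload octets, a terminator of at most 4 zero bits, zero padding to an
#' octet boundary, then alternating pad octets 0xEC/0x11 up to the 216
#' data codewords of version 10-M.
#'
#' @param payload A [qr_payload()] (or text coercible to one).
#' @return Integer vector of 216 octets.
#' @export
make_data_codewords <- function(payload) {
  if (!inherits(payload, "qr_payload")) payload <- qr_payload(payload)
  n <- length(payload$bytes)
  bits <- c(
    int_to_bits(4L, 4L),          # byte mode 0100
    int_to_bits(n, 16L),          # character count, 16 bits for V10
    unlist(lapply(payload$bytes, int_to_bits, width = 8L), use.names = FALSE)
  )
  capacity_bits <- QR_DATA_CODEWORDS * 8L
  if (length(bits) > capacity_bits)
    stop("payload exceeds data capacity")
  bits <- c(bits, integer(min(4L, capacity_bits - length(bits)))) # terminator
  if (length(bits) %% 8L != 0L)
    bits <- c(bits, integer(8L - length(bits) %% 8L))             # octet align
  cw <- bits_to_ints(bits, 8L)
  pad <- rep(c(0xECL, 0x11L), length.out = QR_DATA_CODEWORDS - length(cw))
  c(cw, pad)
}

int_to_bits <- function(x, width) {
  x <- as.integer(x)
  rev(as.integer(bitwAnd(bitwShiftR(x, 0:(width - 1L)), 1L)))
}

bits_to_ints <- function(bits, width) {
  stopifnot(length(bits) %% width == 0L)
  m <- matrix(bits, nrow = width)
  as.integer(colSums(m * 2L^((width - 1L):0)))
}

#' Split data codewords into RS blocks and interleave
#'
#' Version 10-M structure: the 216 data octets split in order into five
#' blocks of (43, 43, 43, 43, 44); each block gets 26 Reed-Solomon
#' error-correction octets; the transmitted sequence interleaves the data
#' blocks column-wise, then the EC blocks column-wise (346 octets total).
#'
#' @param data Integer vector of 216 octets.
#' @return List with `data_blocks`, `ec_blocks`, and the interleaved
#'   `final_sequence`.
#' @export
block_and_interleave <- function(data) {
  data <- as.integer(data)
  if (length(data) != QR_DATA_CODEWORDS)
    stop("expected ", QR_DATA_CODEWORDS, " data codewords")
  ends <- cumsum(QR_BLOCK_SIZES)
  starts <- c(1L, head(ends, -1L) + 1L)
  data_blocks <- Map(function(s, e) data[s:e], starts, ends)
  ec_blocks <- lapply(data_blocks, rs_encode_block, n_ec = QR_EC_PER_BLOCK)
  final <- c(interleave_blocks(data_blocks), interleave_blocks(ec_blocks))
  stopifnot(length(final) == QR_TOTAL_CODEWORDS)
  list(data_blocks = data_blocks, ec_blocks = ec_blocks,
       final_sequence = final)
}

interleave_blocks <- function(blocks) {
  out <- integer(0)
  for (j in seq_len(max(lengths(blocks))))
    for (b in blocks)
      if (j <= length(b)) out <- c(out, b[j])
  out
}

# inverse of block_and_interleave's ordering (error-free path)
deinterleave_sequence <- function(final) {
  stopifnot(length(final) == QR_TOTAL_CODEWORDS)
  sizes <- QR_BLOCK_SIZES
  data_blocks <- lapply(sizes, integer)
  pos <- 1L
  for (j in seq_len(max(sizes)))
    for (b in seq_along(sizes))
      if (j <= sizes[b]) { data_blocks[[b]][j] <- final[pos]; pos <- pos + 1L }
  ec_blocks <- lapply(seq_along(sizes), integer)
  for (j in seq_len(QR_EC_PER_BLOCK))
    for (b in seq_along(sizes)) {
      ec_blocks[[b]][j] <- final[pos]; pos <- pos + 1L
    }
  list(data_blocks = data_blocks, ec_blocks = ec_blocks)
}

## ---- module matrix construction -------------------------------------------

# Cache of geometry shared by every symbol: the function-pattern base, the
# zigzag coordinate order of the data modules, and each mask's bit values
# at those coordinates.
.qr_geom <- new.env(parent = emptyenv())

# 0-indexed mask predicate of the eight standard patterns
mask_value <- function(mask_id, i, j) {
  switch(as.character(mask_id),
    "0" = (i + j) %% 2L == 0L,
    "1" = i %% 2L == 0L,
    "2" = j %% 3L == 0L,
    "3" = (i + j) %% 3L == 0L,
    "4" = ((i %/% 2L) + (j %/% 3L)) %% 2L == 0L,
    "5" = (i * j) %% 2L + (i * j) %% 3L == 0L,
    "6" = ((i * j) %% 2L + (i * j) %% 3L) %% 2L == 0L,
    "7" = (((i + j) %% 2L) + ((i * j) %% 3L)) %% 2L == 0L,
    stop("mask_id must be 0..7")
  )
}

qr_geometry <- function() {
  if (!is.null(.qr_geom$base)) return(.qr_geom)
  side <- QR_SIDE
  modules <- matrix(NA_integer_, side, side)   # 1 dark, 0 light, NA = data
  fmap <- matrix(FALSE, side, side)

  put <- function(r, c, v) {                    # 0-indexed
    modules[r + 1L, c + 1L] <<- as.integer(v)
    fmap[r + 1L, c + 1L] <<- TRUE
  }

  place_finder <- function(r0, c0) {
    for (r in -1:7) for (c in -1:7) {
      rr <- r0 + r; cc <- c0 + c
      if (rr < 0L || rr >= side || cc < 0L || cc >= side) next
      dark <- (r >= 0 && r <= 6 && (c == 0 || c == 6)) ||
              (c >= 0 && c <= 6 && (r == 0 || r == 6)) ||
              (r >= 2 && r <= 4 && c >= 2 && c <= 4)
      put(rr, cc, dark)                        # -1 ring = light separator
    }
  }
  place_finder(0L, 0L)
  place_finder(0L, side - 7L)
  place_finder(side - 7L, 0L)

  # alignment patterns (5x5), centers on the grid, skipping finder corners
  for (r0 in QR_ALIGNMENT_CENTERS) for (c0 in QR_ALIGNMENT_CENTERS) {
    if (!is.na(modules[r0 + 1L, c0 + 1L])) next   # overlaps a finder corner
    for (r in -2:2) for (c in -2:2) {
      dark <- max(abs(r), abs(c)) != 1L
      put(r0 + r, c0 + c, dark)
    }
  }

  # timing patterns along row 6 and column 6
  for (k in 8:(side - 9L)) {
    if (is.na(modules[7L, k + 1L])) put(6L, k, k %% 2L == 0L)
    if (is.na(modules[k + 1L, 7L])) put(k, 6L, k %% 2L == 0L)
  }

  # dark module
  put(4L * QR_VERSION + 9L, 8L, TRUE)

  # reserve format-information areas (filled per symbol)
  for (i in 0:5) { put(i, 8L, FALSE); put(8L, i, FALSE) }
  put(7L, 8L, FALSE); put(8L, 8L, FALSE); put(8L, 7L, FALSE)
  for (i in 0:7) put(8L, side - 1L - i, FALSE)
  for (i in 0:6) put(side - 7L + i, 8L, FALSE)

  # version information (static for version 10), both copies
  vbits <- version_information(QR_VERSION)
  for (i in 0:17) {
    bit <- bitwAnd(bitwShiftR(vbits, i), 1L) == 1L
    put(i %/% 3L, side - 11L + i %% 3L, bit)
    put(side - 11L + i %% 3L, i %/% 3L, bit)
  }

  # zigzag order of data modules: two-column ribbons from the right edge,
  # alternating upward/downward, skipping the timing column
  coords <- matrix(0L, sum(!fmap), 2L)
  n <- 0L
  upward <- TRUE
  col <- side - 1L
  while (col > 0L) {
    if (col == 6L) col <- col - 1L
    rows <- if (upward) (side - 1L):0 else 0:(side - 1L)
    for (r in rows) for (c in c(col, col - 1L)) {
      if (!fmap[r + 1L, c + 1L]) {
        n <- n + 1L
        coords[n, ] <- c(r, c)
      }
    }
    upward <- !upward
    col <- col - 2L
  }
  stopifnot(n == nrow(coords), n == QR_TOTAL_CODEWORDS * 8L) # V10: 0 remainder bits

  mask_bits <- lapply(0:7, function(m)
    as.integer(mask_value(m, coords[, 1L], coords[, 2L])))

  # format-information positions (0-indexed), bit index 0 = LSB of the
  # 15-bit string; copy A around the top-left finder, copy B split between
  # the top-right and bottom-left finders
  fmt_a <- rbind(
    cbind(0:5, 8L), c(7L, 8L), c(8L, 8L), c(8L, 7L), cbind(8L, 5:0)
  )
  fmt_b <- rbind(
    cbind(8L, (side - 1L):(side - 8L)), cbind((side - 7L):(side - 1L), 8L)
  )

  .qr_geom$base <- modules
  .qr_geom$fmap <- fmap
  .qr_geom$coords <- coords
  .qr_geom$coord_idx <- coords[, 1L] + 1L + nrow(modules) * coords[, 2L]
  .qr_geom$mask_bits <- mask_bits
  .qr_geom$fmt_a <- fmt_a
  .qr_geom$fmt_b <- fmt_b
  .qr_geom
}

write_format_info <- function(modules, mask_id) {
  g <- qr_geometry()
  bits <- format_information("M", mask_id)
  for (i in 0:14) {
    v <- bitwAnd(bitwShiftR(bits, i), 1L)
    modules[g$fmt_a[i + 1L, 1L] + 1L, g$fmt_a[i + 1L, 2L] + 1L] <- v
    modules[g$fmt_b[i + 1L, 1L] + 1L, g$fmt_b[i + 1L, 2L] + 1L] <- v
  }
  modules
}

new_qr_matrix <- function(modules, mask_id) {
  g <- qr_geometry()
  structure(list(modules = modules, function_map = g$fmap,
                 version = QR_VERSION, ec_level = "M",
                 mask_id = as.integer(mask_id)),
            class = "qr_matrix")
}

#' Place an interleaved codeword sequence into a symbol
#'
#' Lays out the function patterns of a version-10 symbol, writes the 2768
#' data bits in the standard two-column zigzag (skipping the timing
#' column), applies the requested mask to the non-function modules, and
#' writes the BCH-protected format information (level M + mask) and the
#' version-10 version information in both of their locations.
#'
#' @param final_sequence Integer vector of 346 octets from
#'   [block_and_interleave()].
#' @param mask_id 0..7, or `"auto"` to select the mask with the lowest
#'   penalty score ([choose_mask()]).
#' @return A `qr_matrix`.
#' @export
build_symbol <- function(final_sequence, mask_id = "auto") {
  final_sequence <- as.integer(final_sequence)
  if (length(final_sequence) != QR_TOTAL_CODEWORDS)
    stop("expected ", QR_TOTAL_CODEWORDS, " codewords")
  g <- qr_geometry()
  bits <- unlist(lapply(final_sequence, int_to_bits, width = 8L),
                 use.names = FALSE)
  if (identical(mask_id, "auto")) {
    mask_id <- choose_mask(bits)
  } else {
    mask_id <- as.integer(mask_id)
    if (mask_id < 0L || mask_id > 7L) stop("mask_id must be 0..7 or 'auto'")
  }
  modules <- g$base
  modules[g$coord_idx] <- bitwXor(bits, g$mask_bits[[mask_id + 1L]])
  modules <- write_format_info(modules, mask_id)
  new_qr_matrix(modules, mask_id)
}

#' Mask evaluation penalty of a module grid
#'
#' The four standard penalty rules: N1, same-colour runs of length >= 5 in
#' rows and columns score 3 + (length - 5); N2, each 2x2 same-colour block
#' scores 3; N3, each finder-like 1:1:3:1:1 run flanked by 4 light modules
#' (in either orientation) scores 40; N4, 10 points per full 5% deviation
#' of the dark-module proportion from 50%.
#'
#' @param matrix A `qr_matrix`, or a 0/1 integer matrix.
#' @return Named integer vector `c(n1, n2, n3, n4, total)`.
#' @export
penalty <- function(matrix) {
  m <- if (inherits(matrix, "qr_matrix")) matrix$modules else matrix
  storage.mode(m) <- "integer"
  n1 <- 0L
  run_score <- function(v) {
    r <- rle(v)$lengths
    sum(pmax(r - 2L, 0L) * (r >= 5L))        # 3 + (len-5) == len - 2
  }
  for (i in seq_len(nrow(m))) n1 <- n1 + run_score(m[i, ])
  for (j in seq_len(ncol(m))) n1 <- n1 + run_score(m[, j])

  a <- m[-nrow(m), -ncol(m)]
  same <- (a == m[-1, -ncol(m)]) & (a == m[-nrow(m), -1]) & (a == m[-1, -1])
  n2 <- 3L * sum(same)

  pat <- c(1L, 0L, 1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L, 0L)
  n3 <- 0L
  count_pat <- function(v) {
    if (length(v) < 11L) return(0L)
    w <- stats::embed(v, 11L)[, 11:1, drop = FALSE]
    sum(colSums(t(w) == pat) == 11L) + sum(colSums(t(w) == rev(pat)) == 11L)
  }
  for (i in seq_len(nrow(m))) n3 <- n3 + count_pat(m[i, ])
  for (j in seq_len(ncol(m))) n3 <- n3 + count_pat(m[, j])
  n3 <- 40L * n3

  dark_pct <- 100 * sum(m) / length(m)
  n4 <- 10L * (abs(dark_pct - 50) %/% 5)

  out <- c(n1 = n1, n2 = n2, n3 = as.integer(n3), n4 = as.integer(n4))
  c(out, total = sum(out))
}

#' Select the mask with minimal penalty
#'
#' Builds the symbol under each of the eight mask patterns (format
#' information included, as the penalty is scored on the final grid) and
#' returns the mask id attaining the lowest total penalty; ties go to the
#' lowest id.
#'
#' @param data_bits Integer vector of the 2768 unmasked data bits in
#'   placement order (as produced inside [build_symbol()]).
#' @return Integer mask id in 0..7.
#' @export
choose_mask <- function(data_bits) {
  g <- qr_geometry()
  totals <- vapply(0:7, function(mid) {
    modules <- g$base
    modules[g$coord_idx] <- bitwXor(data_bits, g$mask_bits[[mid + 1L]])
    modules <- write_format_info(modules, mid)
    penalty(modules)[["total"]]
  }, numeric(1))
  as.integer(which.min(totals) - 1L)   # which.min takes the first minimum
}

#' Encode a payload as a version-10 level-M QR symbol
#'
#' Composition of [make_data_codewords()], [block_and_interleave()] and
#' [build_symbol()] with automatic mask selection.
#'
#' @param payload A [qr_payload()], or text/octets coercible to one.
#' @param mask_id Mask override (default `"auto"`).
#' @return A `qr_matrix`.
#' @export
qr_encode <- function(payload, mask_id = "auto") {
  if (!inherits(payload, "qr_payload")) payload <- qr_payload(payload)
  blocks <- block_and_interleave(make_data_codewords(payload))
  build_symbol(blocks$final_sequence, mask_id = mask_id)
}

#' Decode an undistorted QR symbol matrix
#'
#' The verification path for symbols produced by this codec: reads and
#' BCH-checks the format information, removes the mask, extracts the
#' zigzag bitstream, de-interleaves the codeword blocks, verifies that
#' every Reed-Solomon syndrome is zero (detection only — error correction
#' is not implemented), and parses the byte-mode bitstream back to text.
#'
#' @param matrix A `qr_matrix` (module grid as encoded; no geometric
#'   distortion handling).
#' @return A `qr_payload`.
#' @export
qr_decode <- function(matrix) {
  g <- qr_geometry()
  m <- if (inherits(matrix, "qr_matrix")) matrix$modules else matrix
  if (!all(dim(m) == QR_SIDE)) stop("expected a ", QR_SIDE, "x", QR_SIDE, " module grid")

  fmt <- 0L
  for (i in 0:14)
    fmt <- bitwOr(fmt, bitwShiftL(m[g$fmt_a[i + 1L, 1L] + 1L,
                                    g$fmt_a[i + 1L, 2L] + 1L], i))
  unmasked <- bitwXor(fmt, 0x5412L)
  ec_code <- bitwShiftR(unmasked, 13L)
  mask_id <- bitwAnd(bitwShiftR(unmasked, 10L), 7L)
  if (format_information(c("1" = "L", "0" = "M", "3" = "Q", "2" = "H")[[as.character(ec_code)]],
                         mask_id) != fmt)
    stop("format information fails its BCH check")
  if (ec_code != 0L) stop("symbol is not error-correction level M")

  bits <- bitwXor(m[g$coord_idx], g$mask_bits[[mask_id + 1L]])
  final <- bits_to_ints(bits, 8L)
  blocks <- deinterleave_sequence(final)
  for (b in seq_along(blocks$data_blocks)) {
    synd <- rs_syndromes(c(blocks$data_blocks[[b]], blocks$ec_blocks[[b]]),
                         QR_EC_PER_BLOCK)
    if (any(synd != 0L))
      stop("corrupted symbol: nonzero Reed-Solomon syndrome in block ", b,
           " (detection only; correction is not implemented)")
  }
  data <- unlist(blocks$data_blocks, use.names = FALSE)
  dbits <- unlist(lapply(data, int_to_bits, width = 8L), use.names = FALSE)
  mode <- bits_to_ints(dbits[1:4], 4L)
  if (mode == 0L) return(qr_payload(integer(0)))  # bare terminator
  if (mode != 4L)
    stop(sprintf("malformed mode indicator 0x%X (only byte mode is supported)", mode))
  count <- bits_to_ints(dbits[5:20], 16L)
  if (count > QR_BYTE_CAPACITY) stop("malformed character count")
  payload_bits <- dbits[20L + seq_len(8L * count)]
  qr_payload(if (count == 0L) integer(0) else bits_to_ints(payload_bits, 8L))
}

## ---- debug text dump -------------------------------------------------------

#' Render a module grid as text
#'
#' One character per module: `#` dark, `.` light. The inverse,
#' [qr_from_text()], reads the same format (used for plain-text fixtures).
#'
#' @param matrix A `qr_matrix` or 0/1 matrix.
#' @return Character vector, one element per row.
#' @export
qr_to_text <- function(matrix) {
  m <- if (inherits(matrix, "qr_matrix")) matrix$modules else matrix
  apply(m, 1L, function(r) paste(ifelse(r == 1L, "#", "."), collapse = ""))
}

#' @rdname qr_to_text
#' @param lines Character vector of `#`/`.` rows (or a file path).
#' @export
qr_from_text <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  lines <- lines[!startsWith(lines, "%")]      # comment/provenance lines
  lines <- lines[nzchar(lines)]
  t(vapply(strsplit(lines, ""), function(ch) as.integer(ch == "#"),
           integer(nchar(lines[1L]))))
}

#' @export
print.qr_matrix <- function(x, ...) {
  cat(sprintf("<qr_matrix> version %d-%s, mask %d, %dx%d modules\n",
              x$version, x$ec_level, x$mask_id, nrow(x$modules), ncol(x$modules)))
  invisible(x)
}

#' @export
print.qr_payload <- function(x, ...) {
  cat(sprintf("<qr_payload> %d octets: %s\n", length(x$bytes),
              substr(x$text, 1L, 60L)))
  invisible(x)
}
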