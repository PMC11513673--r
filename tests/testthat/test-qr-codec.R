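test_that("feature serialization is fixed-point, comma-joined, capacity-safe", {
  p <- serialize_features(rep(0, 12))
  expect_equal(p$text, paste(rep("0.0000", 12), collapse = ","))
  expect_equal(nchar(p$text), 83L)
  expect_length(strsplit(p$text, ",")[[1]], 12L)

  p2 <- serialize_features(c(1.1, 0.6, rep(0.5, 10)))
  expect_equal(strsplit(p2$text, ",")[[1]][1:2], c("1.1000", "0.6000"))

  # worst case for values in [0, 1000): 12 x 8 digits + 11 commas = 119
  p3 <- serialize_features(rep(999.9999, 12))
  expect_equal(nchar(p3$text), 12L * 8L + 11L)
  expect_lte(nchar(p3$text), 213L)

  expect_error(serialize_features(rep(1, 11)), "12")
  expect_error(serialize_features(c(rep(1, 11), Inf)), "finite")
})

test_that("the byte-mode bitstream has mode, count, terminator and pad octets", {
  cw <- make_data_codewords(qr_payload(integer(0)))
  expect_length(cw, 216L)
  # 0100 + 16 zero count bits + 4-bit terminator = 0x40 0x00 0x00
  expect_equal(cw[1:3], c(0x40L, 0x00L, 0x00L))
  expect_equal(cw[4:216], rep(c(0xECL, 0x11L), length.out = 213L))

  full <- make_data_codewords(qr_payload(rep(65L, 213L)))
  expect_length(full, 216L)
  expect_false(any(full == 0xECL))              # no pad codewords at capacity
  # mode nibble + the 16 count bits of 213 straddle the first three octets
  expect_equal(full[1:2], c(0x40L, bitwAnd(bitwShiftR(213L, 4L), 255L)))
  expect_equal(full[3], bitwOr(bitwShiftL(bitwAnd(213L, 15L), 4L),
                               bitwShiftR(65L, 4L)))  # count low nibble + data

  expect_error(qr_payload(rep(0L, 214L)), "capacity")
})

test_that("GF(256) arithmetic matches shift-and-add reduction", {
  expect_equal(gf_mul(0x02L, 0x80L), 0x1DL)  # 0x100 reduced by 0x11D
  set.seed(900)
  for (k in 1:50) {
    a <- sample(0:255, 1); b <- sample(0:255, 1)
    expect_equal(gf_mul(a, b), oracle_gf_mul(a, b))
  }
})

test_that("Reed-Solomon parity agrees with brute-force polynomial division", {
  expect_equal(rs_encode_block(rep(0L, 43L)), rep(0L, 26L))
  set.seed(123)
  data <- sample(0:255, 43L, replace = TRUE)
  ec <- rs_encode_block(data, 26L)
  expect_equal(ec, oracle_rs_remainder(data, 26L))
  # and the full codeword vanishes at every generator root
  cw <- c(data, ec)
  expect_true(all(vapply(0:25, function(i) oracle_poly_eval_alpha(cw, i),
                         integer(1)) == 0L))
  expect_error(rs_encode_block(data, 0L), "n_ec")
})

test_that("codewords split into the 10-M block structure and interleave invertibly", {
  data <- 0:215
  b <- block_and_interleave(data)
  expect_equal(lengths(b$data_blocks), c(43L, 43L, 43L, 43L, 44L))
  expect_equal(b$data_blocks[[5]][1], 172L)
  expect_equal(lengths(b$ec_blocks), rep(26L, 5L))
  expect_length(b$final_sequence, 346L)
  # column-wise interleave: first five octets are the block heads
  expect_equal(b$final_sequence[1:5], c(0L, 43L, 86L, 129L, 172L))
  # the 44th data column only exists in block 5
  expect_equal(b$final_sequence[216], 215L)
  rt <- gaitqr:::deinterleave_sequence(b$final_sequence)
  expect_identical(rt$data_blocks, b$data_blocks)
  expect_identical(rt$ec_blocks, b$ec_blocks)
})

test_that("format and version information match independent BCH oracles", {
  fmt <- gaitqr:::format_information("M", 0L)
  expect_equal(fmt, 0x5412L)
  expect_equal(fmt, int_of_bits(oracle_format_bits(c(0L, 0L), 0L)))
  for (mask in 0:7)
    expect_equal(gaitqr:::format_information("M", mask),
                 int_of_bits(oracle_format_bits(c(0L, 0L), mask)))
  ver <- gaitqr:::version_information(10L)
  expect_equal(ver, 0x0A4D3L)
  expect_equal(ver, int_of_bits(oracle_version_bits(10L)))
})

test_that("symbols carry the fixed function patterns of version 10", {
  m <- qr_encode(serialize_features(rep(1.5, 12)))
  g <- m$modules
  expect_equal(dim(g), c(57L, 57L))
  expect_equal(sort(unique(c(g))), c(0L, 1L))
  # finder centers dark at all three corners
  expect_equal(g[4, 4], 1L); expect_equal(g[4, 54], 1L); expect_equal(g[54, 4], 1L)
  # alignment pattern centers (excluding finder overlaps) are dark with light ring
  for (rc in list(c(29, 7), c(7, 29), c(29, 29), c(29, 51), c(51, 29), c(51, 51))) {
    expect_equal(g[rc[1], rc[2]], 1L)
    expect_equal(g[rc[1] - 1, rc[2]], 0L)
  }
  # timing patterns alternate along row/column 7 (1-indexed)
  expect_equal(g[7, 9:49], rep_len(c(1L, 0L), 41L))
  expect_equal(g[9:49, 7], rep_len(c(1L, 0L), 41L))
  # the fixed dark module at (4*version + 9, 8), 0-indexed
  expect_equal(g[4 * 10 + 9 + 1, 9], 1L)
  expect_true(m$function_map[4 * 10 + 9 + 1, 9])
  expect_equal(sum(!m$function_map), 346L * 8L)
})

test_that("penalty components reproduce hand-enumerated toy grids", {
  expect_equal(penalty(matrix(1L, 4, 4)),
               c(n1 = 0L, n2 = 27L, n3 = 0L, n4 = 100L, total = 127L))
  # exactly half dark, no runs >= 5, no 2x2 blocks, no finder-like pattern
  checker <- outer(1:4, 1:4, function(i, j) (i + j) %% 2L)
  expect_equal(penalty(checker)[["n4"]], 0L)
  expect_equal(penalty(checker)[["total"]], 0L)
  # a 10-module checkerboard row contributes nothing to N1
  row10 <- matrix(rep_len(c(1L, 0L), 10L), nrow = 1)
  expect_equal(penalty(row10)[["n1"]], 0L)
  # runs: a 7-run scores 3 + 2
  run7 <- matrix(c(rep(1L, 7), rep(0L, 4)), nrow = 1)
  expect_equal(penalty(run7)[["n1"]], 5L)
  # N3: the 1:1:3:1:1 pattern with a 4-light flank scores 40 once per orientation
  n3row <- matrix(c(1L,0L,1L,1L,1L,0L,1L,0L,0L,0L,0L), nrow = 1)
  expect_equal(penalty(n3row)[["n3"]], 40L)
})

test_that("automatic masking attains the minimum penalty over all eight masks", {
  for (vals in list(rep(0, 12), c(1.1, 0.6, 110.5, 37.8, rep(2.5, 8)))) {
    p <- serialize_features(vals)
    auto <- qr_encode(p)
    totals <- vapply(0:7, function(k) penalty(qr_encode(p, mask_id = k))[["total"]],
                     numeric(1))
    expect_equal(penalty(auto)[["total"]], min(totals))
    expect_equal(auto$mask_id, which.min(totals) - 1L)
  }
})

test_that("decode inverts encode, including degenerate and random payloads", {
  fixed <- serialize_features(rep(0, 12))
  expect_equal(qr_decode(qr_encode(fixed))$text, fixed$text)
  expect_equal(qr_decode(qr_encode(qr_payload("")))$text, "")

  set.seed(77)
  for (k in 1:30) {
    n <- sample(0:213, 1)
    bytes <- sample(0:255, n, replace = TRUE)
    p <- qr_payload(bytes)
    expect_equal(qr_decode(qr_encode(p))$bytes, as.integer(bytes))
  }
})

test_that("a one-digit payload change yields a different module grid", {
  a <- qr_encode(serialize_features(c(1.1000, rep(0.5, 11))))
  b <- qr_encode(serialize_features(c(1.1001, rep(0.5, 11))))
  expect_false(identical(a$modules, b$modules))
})

test_that("a single flipped data module is detected as corruption", {
  m <- qr_encode(serialize_features(rep(0.25, 12)))
  idx <- which(!m$function_map, arr.ind = TRUE)[10, ]
  m$modules[idx[1], idx[2]] <- 1L - m$modules[idx[1], idx[2]]
  expect_error(qr_decode(m), "syndrome")
})

test_that("encoder output is bit-exact against frozen reference symbols", {
  for (fix in sort(list.files(test_path(), pattern = "^ref-qr-v10m-.*\\.txt$",
                              full.names = TRUE))) {
    lines <- readLines(fix)
    mask <- as.integer(sub(".*mask ([0-7]).*", "\\1",
                           lines[grepl("mask [0-7]$", lines)][1]))
    payload <- sub("^% payload: ", "", lines[startsWith(lines, "% payload:")])
    ref <- qr_from_text(fix)
    mine <- qr_encode(qr_payload(payload), mask_id = mask)
    expect_identical(mine$modules, ref)
    # and the text dump round-trips
    expect_identical(qr_from_text(qr_to_text(mine)), mine$modules)
  }
})
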