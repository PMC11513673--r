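# Independent oracles used by the tests. These deliberately share no code
# with the package: field arithmetic is Russian-peasant (no log tables),
# polynomial division is written directly, and the shape/pixel oracles are
# step-by-step simulations.

# GF(256) multiply by shift-and-add reduction with 0x11D
oracle_gf_mul <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  r <- 0L
  while (b > 0L) {
    if (bitwAnd(b, 1L) == 1L) r <- bitwXor(r, a)
    a <- bitwShiftL(a, 1L)
    if (a >= 256L) a <- bitwXor(a, 0x11DL)
    b <- bitwShiftR(b, 1L)
  }
  r
}

oracle_alpha_pow <- function(i) {
  r <- 1L
  for (k in seq_len(i)) r <- oracle_gf_mul(r, 2L)
  r
}

# brute-force polynomial long division over GF(256):
# remainder of data(x) * x^n_ec mod prod_{i=0}^{n_ec-1}(x - alpha^i)
oracle_rs_remainder <- function(data, n_ec) {
  gen <- 1L
  for (i in 0:(n_ec - 1L)) {
    a <- oracle_alpha_pow(i)
    nxt <- integer(length(gen) + 1L)
    for (k in seq_along(gen)) {
      nxt[k] <- bitwXor(nxt[k], gen[k])                       # x * gen
      nxt[k + 1L] <- bitwXor(nxt[k + 1L], oracle_gf_mul(gen[k], a))
    }
    gen <- nxt
  }
  rem <- c(as.integer(data), integer(n_ec))
  for (i in seq_along(data)) {
    lead <- rem[i]
    if (lead == 0L) next
    for (k in seq_along(gen))
      rem[i + k - 1L] <- bitwXor(rem[i + k - 1L], oracle_gf_mul(gen[k], lead))
  }
  rem[length(data) + seq_len(n_ec)]
}

# evaluate a GF polynomial (coefficients highest degree first) at alpha^i
oracle_poly_eval_alpha <- function(coefs, i) {
  a <- oracle_alpha_pow(i)
  acc <- 0L
  for (c in coefs) acc <- bitwXor(oracle_gf_mul(acc, a), as.integer(c))
  acc
}

# BCH code over GF(2) as explicit bit vectors (index 1 = highest degree):
# appends the remainder of data * x^(n-k) mod generator
oracle_bch <- function(data_bits, generator_bits, total_len) {
  padded <- c(data_bits, integer(total_len - length(data_bits)))
  work <- padded
  g <- length(generator_bits)
  for (i in seq_len(total_len - g + 1L)) {
    if (work[i] == 1L)
      work[i:(i + g - 1L)] <- bitwXor(work[i:(i + g - 1L)], generator_bits)
  }
  rem <- work[(total_len - g + 2L):total_len]
  c(data_bits, rem)
}

bits_of <- function(x, width) rev(as.integer(bitwAnd(bitwShiftR(as.integer(x), 0:(width - 1L)), 1L)))
int_of_bits <- function(bits) sum(bits * 2L^((length(bits) - 1L):0))

# format information oracle: 5 data bits, generator x^10+x^8+x^5+x^4+x^2+x+1
# (10100110111), then XOR with 101010000010010
oracle_format_bits <- function(ec_bits2, mask_id) {
  data5 <- c(ec_bits2, bits_of(mask_id, 3L))
  code <- oracle_bch(data5, c(1L,0L,1L,0L,0L,1L,1L,0L,1L,1L,1L), 15L)
  bitwXor(code, c(1L,0L,1L,0L,1L,0L,0L,0L,0L,0L,1L,0L,0L,1L,0L))
}

# version information oracle: 6 version bits, generator
# x^12+x^11+x^10+x^9+x^8+x^5+x^2+1 (1111100100101)
oracle_version_bits <- function(version) {
  oracle_bch(bits_of(version, 6L),
             c(1L,1L,1L,1L,1L,0L,0L,1L,0L,0L,1L,0L,1L), 18L)
}

# step-by-step simulator of the layer dimension chain
oracle_shape_chain <- function(input_side, filters, kernel, pool, stride,
                               pad1 = "same", pad2 = "valid") {
  ops <- list(c("conv", pad1), c("pool", ""), c("conv", pad2), c("pool", ""))
  s <- input_side
  sides <- integer(0)
  for (op in ops) {
    if (op[1] == "conv") {
      s <- if (op[2] == "same") s else s - kernel + 1L
    } else {
      n <- 0L; pos <- 0L
      while (pos + pool <= s) { n <- n + 1L; pos <- pos + stride }
      s <- n
    }
    sides <- c(sides, s)
  }
  list(sides = sides, flatten = filters * s * s)
}

# per-pixel nearest-neighbour mapping oracle for the renderer
oracle_render <- function(modules, size, quiet_zone) {
  side <- nrow(modules)
  L <- side + 2L * quiet_zone
  out <- matrix(0L, size, size)
  for (r in 0:(size - 1L)) for (c in 0:(size - 1L)) {
    mr <- (r * L) %/% size - quiet_zone
    mc <- (c * L) %/% size - quiet_zone
    dark <- mr >= 0L && mr < side && mc >= 0L && mc < side &&
      modules[mr + 1L, mc + 1L] == 1L
    out[r + 1L, c + 1L] <- if (dark) 0L else 255L
  }
  out
}

# brute-force recount of the four metrics from raw label vectors
# (one-vs-rest, macro averaging; report-level F1 from averaged P and S)
oracle_metrics <- function(true, pred, classes, positive = NULL) {
  prec <- sens <- numeric(length(classes))
  names(prec) <- names(sens) <- classes
  for (cl in classes) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    prec[cl] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    sens[cl] <- if (tp + fn == 0) 0 else tp / (tp + fn)
  }
  if (is.null(positive)) { p <- mean(prec); s <- mean(sens) }
  else { p <- prec[[positive]]; s <- sens[[positive]] }
  list(accuracy = 100 * mean(true == pred),
       precision = 100 * p, sensitivity = 100 * s,
       f1 = if (p + s == 0) 0 else 100 * 2 * p * s / (p + s))
}

# small synthetic image dataset of two trivially separable classes
toy_separable_images <- function(n, side = 100L) {
  x <- array(0, c(side, side, n))
  lab <- rep(c("dark", "light"), length.out = n)
  for (i in which(lab == "light")) x[, , i] <- 1
  list(x = x, labels = lab)
}

# a consistent 3-row stride table fixture (swing+stance=stride, pcts exact)
consistent_fixture_lines <- function() {
  make_row <- function(et, L, R, fL, fR) {
    ls <- fL * L; rs <- fR * R
    ds <- L - ls - rs
    vals <- c(et, L, R, ls, rs, 100 * ls / L, 100 * rs / R,
              L - ls, R - rs, 100 * (L - ls) / L, 100 * (R - rs) / R,
              ds, 100 * ds / L)
    paste(sprintf("%.6f", vals), collapse = "\t")
  }
  c(make_row(1.10, 1.10, 1.08, 0.38, 0.37),
    make_row(2.21, 1.11, 1.09, 0.39, 0.38),
    make_row(3.33, 1.12, 1.10, 0.38, 0.39))
}
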