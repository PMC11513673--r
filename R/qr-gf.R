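# Arithmetic over GF(2^8) with the QR primitive polynomial x^8+x^4+x^3+x^2+1
# (0x11D), plus Reed-Solomon systematic encoding. Tables are built once at
# load time.

.gf_tables <- local({
  exp <- integer(512L)
  log <- integer(256L)
  x <- 1L
  for (i in 0:254) {
    exp[i + 1L] <- x
    log[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwXor(x, 0x11DL)
  }
  exp[256:512] <- exp[(256:512) - 255L]
  list(exp = exp, log = log)
})

#' Multiply two elements of GF(256)
#'
#' Field arithmetic uses the QR-standard primitive polynomial 0x11D.
#' Exposed mainly so the error-correction layer can be inspected and
#' cross-checked.
#'
#' @param a,b Integers in 0..255.
#' @return Integer in 0..255.
#' @export
gf_mul <- function(a, b) {
  if (a == 0L || b == 0L) return(0L)
  .gf_tables$exp[(.gf_tables$log[a + 1L] + .gf_tables$log[b + 1L]) %% 255L + 1L]
}

# alpha^i
gf_pow_alpha <- function(i) .gf_tables$exp[(i %% 255L) + 1L]

# product of GF polynomials, coefficients highest degree first
gf_poly_mul <- function(p, q) {
  r <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    for (j in seq_along(q)) {
      if (q[j] == 0L) next
      k <- i + j - 1L
      r[k] <- bitwXor(r[k], gf_mul(p[i], q[j]))
    }
  }
  r
}

# Reed-Solomon generator polynomial prod_{i=0}^{n-1} (x - alpha^i),
# coefficients highest degree first; cached per degree.
.rs_gen_cache <- new.env(parent = emptyenv())
rs_generator <- function(n_ec) {
  key <- as.character(n_ec)
  if (!is.null(.rs_gen_cache[[key]])) return(.rs_gen_cache[[key]])
  g <- 1L
  for (i in 0:(n_ec - 1L)) g <- gf_poly_mul(g, c(1L, gf_pow_alpha(i)))
  .rs_gen_cache[[key]] <- g
  g
}

#' Reed-Solomon error-correction codewords for one block
#'
#' Computes the `n_ec` parity octets appended to a data block: the
#' remainder of the data polynomial times x^n_ec divided by the generator
#' polynomial prod (x - alpha^i), i = 0..n_ec-1, over GF(256).
#'
#' @param data Integer vector of data octets (0..255), non-empty.
#' @param n_ec Number of error-correction octets (26 for the version-10,
#'   level-M blocks used here).
#' @return Integer vector of length `n_ec`.
#' @export
rs_encode_block <- function(data, n_ec = 26L) {
  if (n_ec < 1L) stop("n_ec must be >= 1")
  data <- as.integer(data)
  if (length(data) == 0L) stop("data block must be non-empty")
  if (any(data < 0L | data > 255L)) stop("octets must be in 0..255")
  gen <- rs_generator(n_ec)
  rem <- c(data, integer(n_ec))
  for (i in seq_along(data)) {
    coef <- rem[i]
    if (coef == 0L) next
    for (j in 2:length(gen)) {
      idx <- i + j - 1L
      rem[idx] <- bitwXor(rem[idx], gf_mul(gen[j], coef))
    }
  }
  rem[(length(data) + 1L):(length(data) + n_ec)]
}

# Syndromes S_i = C(alpha^i), i = 0..n_ec-1, of a received codeword
# (data followed by parity, highest-degree coefficient first). All zero
# for an uncorrupted block.
rs_syndromes <- function(codeword, n_ec) {
  vapply(0:(n_ec - 1L), function(i) {
    a <- gf_pow_alpha(i)
    acc <- 0L
    for (c in codeword) acc <- bitwXor(gf_mul(acc, a), as.integer(c))
    acc
  }, integer(1))
}

# Remainder of a GF(2) polynomial division, operands as integers
# (bit i = coefficient of x^i). Used for the BCH format/version strings.
bch_remainder <- function(value, generator) {
  bitlen <- function(v) if (v == 0) 0L else floor(log2(v)) + 1L
  gdeg <- bitlen(generator) - 1L
  while (bitlen(value) - 1L >= gdeg)
    value <- bitwXor(value, bitwShiftL(generator, bitlen(value) - 1L - gdeg))
  value
}

# 15-bit format information: 2 EC-level bits + 3 mask bits, BCH(15,5)
# remainder with generator 0x537, XOR-masked with 0x5412.
format_information <- function(ec_level = "M", mask_id = 0L) {
  ec_bits <- c(L = 1L, M = 0L, Q = 3L, H = 2L)[[ec_level]]
  data5 <- bitwOr(bitwShiftL(ec_bits, 3L), as.integer(mask_id))
  shifted <- bitwShiftL(data5, 10L)
  bitwXor(bitwOr(shifted, bch_remainder(shifted, 0x537L)), 0x5412L)
}

# 18-bit version information: 6 version bits + BCH(18,6) remainder with
# generator 0x1F25. Defined for versions >= 7.
version_information <- function(version = 10L) {
  shifted <- bitwShiftL(as.integer(version), 12L)
  bitwOr(shifted, bch_remainder(shifted, 0x1F25L))
}
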