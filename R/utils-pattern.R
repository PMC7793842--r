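# Bit-pattern helpers. Feature vectors are represented throughout as strings
# of "0"/"1" characters aligned to a catalog; string identity == vector
# identity, which makes deduplication and hashing trivial.

# radix sort: locale-independent, so serialized output is byte-stable
sort_c <- function(x) sort(x, method = "radix")

pat_bits <- function(pattern) {
  as.integer(charToRaw(pattern)) == 49L
}

bits_to_pat <- function(bits) {
  rawToChar(as.raw(48L + as.integer(bits)))
}

pat_popcount <- function(patterns) {
  vapply(patterns, function(p) sum(charToRaw(p) == as.raw(49L)), integer(1),
         USE.NAMES = FALSE)
}

pat_and <- function(a, b) {
  bits_to_pat(pat_bits(a) & pat_bits(b))
}

# is a's feature set a subset (not necessarily strict) of b's?
pat_is_subset <- function(a, b) {
  ra <- charToRaw(a) == as.raw(49L)
  rb <- charToRaw(b) == as.raw(49L)
  !any(ra & !rb)
}

pats_to_matrix <- function(patterns) {
  n <- length(patterns)
  if (n == 0L) return(matrix(FALSE, 0L, 0L))
  nb <- nchar(patterns[[1L]])
  stopifnot(all(nchar(patterns) == nb))
  matrix(as.integer(charToRaw(paste(patterns, collapse = ""))) == 49L,
         nrow = n, ncol = nb, byrow = TRUE)
}

matrix_to_pats <- function(m) {
  n <- nrow(m)
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i) bits_to_pat(m[i, ]), character(1))
}

# Stable content-derived node identifier: the bit pattern packed into hex
# (left-to-right nibbles, zero-padded on the right). Injective, so identity
# survives file round-trips and rebuilds.
pattern_to_hex <- function(pattern) {
  vapply(pattern, function(p) {
    bits <- pat_bits(p)
    pad <- (4L - length(bits) %% 4L) %% 4L
    bits <- c(bits, rep(FALSE, pad))
    nib <- matrix(as.integer(bits), nrow = 4L)
    vals <- as.integer(c(8L, 4L, 2L, 1L) %*% nib)
    paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
            "a", "b", "c", "d", "e", "f")[vals + 1L], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

hex_to_pattern <- function(hex, n_bits) {
  vapply(hex, function(h) {
    vals <- strtoi(strsplit(h, "")[[1L]], base = 16L)
    bits <- as.logical(vapply(vals, function(v) {
      c(bitwAnd(v, 8L) > 0L, bitwAnd(v, 4L) > 0L,
        bitwAnd(v, 2L) > 0L, bitwAnd(v, 1L) > 0L)
    }, logical(4)))
    bits_to_pat(bits[seq_len(n_bits)])
  }, character(1), USE.NAMES = FALSE)
}

node_id_for <- function(pattern) {
  if (length(pattern) == 0L) return(character(0))
  paste0("n", pattern_to_hex(pattern))
}

hgpm_stop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "hgpm_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1L))))
}
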