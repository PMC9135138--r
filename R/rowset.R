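# Packed row sets: one bit per table row, 8 rows per byte in a raw vector.
# `&` and `|` on raw vectors run vectorised at C level, so a single call
# evaluates a logical connective over the whole table word by word instead of
# row by row. Cardinalities come from a 256-entry popcount table. Bits past
# n_rows are kept at zero by construction (AND/OR preserve that invariant).

.pop8 <- vapply(0:255, function(i) {
  sum(bitwAnd(bitwShiftR(i, 0:7), 1L))
}, integer(1))

rowset_from_logical <- function(x) {
  n <- length(x)
  pad <- (-n) %% 8L
  if (pad > 0L) x <- c(x, rep(FALSE, pad))
  r <- packBits(x, type = "raw")
  attr(r, "n") <- n
  r
}

rowset_full <- function(n) rowset_from_logical(rep(TRUE, n))

rowset_empty <- function(n) rowset_from_logical(rep(FALSE, n))

rowset_and <- function(a, b) {
  r <- unclass(a) & unclass(b)
  attr(r, "n") <- attr(a, "n")
  r
}

rowset_or <- function(a, b) {
  r <- unclass(a) | unclass(b)
  attr(r, "n") <- attr(a, "n")
  r
}

rowset_count <- function(a) {
  sum(.pop8[as.integer(a) + 1L])
}

rowset_members <- function(a) {
  n <- attr(a, "n")
  which(as.logical(rawToBits(a))[seq_len(n)])
}

rowset_as_logical <- function(a) {
  as.logical(rawToBits(a))[seq_len(attr(a, "n"))]
}
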