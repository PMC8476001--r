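#' @keywords internal
"_PACKAGE"

#' Canonical amino-acid alphabet (20 residues) and gap symbol
#'
#' The 20 canonical amino acids in alphabetical one-letter order, and the
#' 21-state alphabet used by aligned models (residues plus the gap '-').
#' The gap is always the last (21st) state.
#'
#' @format Character vectors.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_ALPHABET
#' @export
GAP_CHAR <- "-"

#' @rdname AA_ALPHABET
#' @export
AA_GAP_ALPHABET <- c(AA_ALPHABET, GAP_CHAR)

# fast residue -> index lookup (gap = 21); unknown symbols map to NA
.aa_index <- local({
  idx <- rep(NA_integer_, 128)
  idx[utf8ToInt("-")] <- 21L
  for (k in seq_along(AA_ALPHABET)) idx[utf8ToInt(AA_ALPHABET[k])] <- k
  idx
})

# Convert character sequences to a list of integer index vectors (1..21).
# Errors on unknown symbols, naming symbol and position.
seq_to_indices <- function(seqs) {
  lapply(seqs, function(s) {
    ints <- utf8ToInt(s)
    bad <- ints > 127L
    ii <- ifelse(bad, NA_integer_, .aa_index[pmax(ints, 1L)])
    if (anyNA(ii)) {
      pos <- which(is.na(ii))[1]
      stop(sprintf("unknown symbol '%s' at position %d of '%s'",
                   substr(s, pos, pos), pos, s), call. = FALSE)
    }
    ii
  })
}

# Fixed-width sequences -> integer matrix (n x width)
seqs_to_index_matrix <- function(seqs, width) {
  nc <- nchar(seqs)
  if (any(nc != width)) {
    stop(sprintf("all sequences must have width %d (found width %d)",
                 width, nc[which(nc != width)[1]]), call. = FALSE)
  }
  idx <- seq_to_indices(seqs)
  matrix(unlist(idx), nrow = length(seqs), ncol = width, byrow = TRUE)
}

indices_to_seq <- function(idx) {
  vapply(idx, function(v) paste(AA_GAP_ALPHABET[v], collapse = ""), "")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# vectorized two-argument log(exp(a) + exp(b))
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(-abs(a - b)))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
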