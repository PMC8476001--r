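# Model input encodings: aligned one-hot (21 states x n sites) and
# Left+Right binary features (distance from each CDR3 anchor).

#' One-hot encoding of an aligned CDR3
#'
#' Each of the `n_sites` alignment columns becomes a row with a single 1 in
#' the column of its symbol; the gap maps to the last (21st) state.
#'
#' @param aligned an `aligned_cdr3` or a gapped string of fixed width.
#' @return `n_sites` x 21 binary matrix (class `aligned_encoding`).
#' @export
one_hot_aligned <- function(aligned) {
  s <- if (inherits(aligned, "aligned_cdr3")) aligned$aligned else aligned
  idx <- seq_to_indices(s)[[1]]
  m <- matrix(0L, nrow = length(idx), ncol = 21L,
              dimnames = list(NULL, AA_GAP_ALPHABET))
  m[cbind(seq_along(idx), idx)] <- 1L
  structure(m, class = c("aligned_encoding", class(m)))
}

#' Decode a one-hot aligned encoding back to its string
#' @param encoding matrix from [one_hot_aligned()].
#' @return The gapped string.
#' @export
decode_one_hot <- function(encoding) {
  idx <- apply(unclass(encoding), 1, which.max)
  paste(AA_GAP_ALPHABET[idx], collapse = "")
}

# integer index matrix (n x width) for a set of aligned strings
encode_aligned_matrix <- function(aligned_seqs, width = NULL) {
  width <- width %||% nchar(aligned_seqs[1])
  seqs_to_index_matrix(aligned_seqs, width)
}

# sparse one-hot matrix n x (width * 21); visible index v = (site-1)*21 + a
aligned_onehot_sparse <- function(S, n_states = 21L) {
  n <- nrow(S)
  width <- ncol(S)
  j <- as.vector(t(sweep(S, 2, (seq_len(width) - 1L) * n_states, "+")))
  Matrix::sparseMatrix(i = rep(seq_len(n), each = width), j = j, x = 1,
                       dims = c(n, width * n_states))
}

#' Left+Right binary encoding of a CDR3
#'
#' A binary vector of length `ref_length * 20 * 2`: entry (L, d, A) is 1 iff
#' residue A sits at distance d (0-based) from the left anchor, d <
#' `ref_length`, and symmetrically for the right block. The first residue
#' has left distance 0 and the last residue right distance 0. Feature order
#' is the left block (position-major, residues in `AA_ALPHABET` order) then
#' the right block. For sequences longer than `ref_length`, middle residues
#' whose distance from an end reaches `ref_length` contribute no feature on
#' that side; residues within `ref_length` of both ends contribute to both
#' blocks, and such sequences are flagged via attribute `over_ref_length`.
#'
#' @param cdr3 a CDR3 string (20-letter alphabet).
#' @param ref_length maximum anchored distance (default 19, giving a
#'   vector of length 19 * 20 * 2 = 760).
#' @return Integer 0/1 vector of length `ref_length * 40` (class
#'   `left_right_encoding`), attributes `ref_length`, `source` and
#'   `over_ref_length`.
#' @export
left_right_encode <- function(cdr3, ref_length = 19L) {
  idx <- seq_to_indices(cdr3)[[1]]
  if (any(idx == 21L)) stop("gap character not allowed", call. = FALSE)
  l <- length(idx)
  if (l < 1) stop("cdr3 length must be >= 1", call. = FALSE)
  v <- integer(ref_length * 40L)
  pos <- seq_len(l)
  dl <- pos - 1L                 # distance from left anchor
  dr <- l - pos                  # distance from right anchor
  sel_l <- dl < ref_length
  sel_r <- dr < ref_length
  v[dl[sel_l] * 20L + idx[sel_l]] <- 1L
  v[ref_length * 20L + dr[sel_r] * 20L + idx[sel_r]] <- 1L
  structure(v, class = "left_right_encoding", ref_length = ref_length,
            source = cdr3, over_ref_length = l > ref_length)
}

#' Decode a Left+Right encoding (sequences up to the reference length)
#'
#' For a CDR3 of length `l <= ref_length` the left block determines the
#' sequence exactly; the right block is used to recover `l`.
#'
#' @param encoding a `left_right_encoding`.
#' @return The CDR3 string.
#' @export
left_right_decode <- function(encoding) {
  ref_length <- attr(encoding, "ref_length")
  v <- as.integer(encoding)
  left <- matrix(v[seq_len(ref_length * 20L)], nrow = 20L)
  right <- matrix(v[ref_length * 20L + seq_len(ref_length * 20L)],
                  nrow = 20L)
  l <- sum(colSums(right) > 0)
  if (sum(colSums(left) > 0) != l) {
    stop("encoding is not decodable: sequence exceeded the reference length",
         call. = FALSE)
  }
  res <- apply(left[, seq_len(l), drop = FALSE], 2, which.max)
  paste(AA_ALPHABET[res], collapse = "")
}

# sparse Left+Right feature matrix for many sequences (n x ref_length*40)
left_right_sparse <- function(seqs, ref_length = 19L) {
  idx <- seq_to_indices(seqs)
  lens <- lengths(idx)
  if (any(unlist(idx) == 21L)) stop("gap character not allowed",
                                    call. = FALSE)
  res <- unlist(idx)
  row <- rep(seq_along(seqs), lens)
  pos <- unlist(lapply(lens, seq_len))
  dl <- pos - 1L
  dr <- rep(lens, lens) - pos
  sel_l <- dl < ref_length
  sel_r <- dr < ref_length
  i <- c(row[sel_l], row[sel_r])
  j <- c(dl[sel_l] * 20L + res[sel_l],
         ref_length * 20L + dr[sel_r] * 20L + res[sel_r])
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(length(seqs),
                                                     ref_length * 40L))
}

#' Export an encoding matrix as MatrixMarket or TSV for inspection
#' @param x a matrix or sparse Matrix.
#' @param path output path.
#' @param format "mtx" or "tsv".
#' @return `path`, invisibly.
#' @export
write_encoding <- function(x, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                                            "CsparseMatrix"), "generalMatrix"),
                    path)
  } else {
    utils::write.table(as.matrix(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
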