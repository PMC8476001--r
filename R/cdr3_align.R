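# Fixed-length CDR3 multiple sequence alignment.
#
# Variable-length CDR3s (anchored by the conserved C ... F/V residues) are
# reduced to a fixed number of columns in four steps:
#   1. a position weight matrix (PWM) per observed length;
#   2. progressive profile-profile alignment from the shortest to the longest
#      length, inserting one gap column into the shorter profile per step
#      (expected-BLOSUM62 column score), yielding a seed alignment of width
#      l_max;
#   3. a profile HMM of n_match match states estimated from the seed (match
#      columns = lowest gap fraction, Laplace pseudocounts);
#   4. Viterbi alignment of every sequence to the HMM; deletions emit '-',
#      residues routed through insert states are dropped and flagged.

#' Per-length position weight matrices
#'
#' One L x 20 residue-frequency matrix per CDR3 length in `[l_min, l_max]`
#' with at least one sequence.
#'
#' @param seqs character vector of CDR3s (20-letter alphabet).
#' @param l_min,l_max length range considered (defaults 5 and 23).
#' @param pseudocount added to every residue count before normalizing
#'   (default 0: plain maximum-likelihood frequencies).
#' @return Named list (by length) of objects with fields `columns`
#'   (L x 20 matrix, rows sum to 1), `length` and `support`.
#' @export
build_length_profiles <- function(seqs, l_min = 5L, l_max = 23L,
                                  pseudocount = 0) {
  if (length(seqs) == 0) stop("no sequences supplied", call. = FALSE)
  len <- nchar(seqs)
  keep <- len >= l_min & len <= l_max
  if (!any(keep)) {
    stop(sprintf("no sequences with length in [%d, %d]", l_min, l_max),
         call. = FALSE)
  }
  seqs <- seqs[keep]
  len <- len[keep]
  profiles <- list()
  for (l in sort(unique(len))) {
    sub <- seqs[len == l]
    m <- seqs_to_index_matrix(sub, l)
    if (any(m == 21L)) stop("gap character not allowed in input CDR3s",
                            call. = FALSE)
    counts <- matrix(pseudocount, nrow = l, ncol = 20,
                     dimnames = list(NULL, AA_ALPHABET))
    for (i in seq_len(l)) {
      tab <- tabulate(m[, i], nbins = 20)
      counts[i, ] <- counts[i, ] + tab
    }
    cols <- counts / rowSums(counts)
    profiles[[as.character(l)]] <- list(columns = cols, length = l,
                                        support = length(sub))
  }
  profiles
}

# expected substitution score between two residue-frequency columns
.profile_col_score <- function(col_a, col_b, substitution) {
  as.numeric(col_a %*% substitution %*% col_b)
}

#' Progressive profile-profile alignment of per-length PWMs
#'
#' Starting from the shortest length, the cumulative profile is aligned
#' against the PWM of the next length (one residue longer); exactly one gap
#' column is inserted into the shorter (cumulative) profile at the position
#' maximizing the summed expected substitution score between the aligned
#' columns — the optimum of a global profile alignment restricted to the
#' one-indel case implied by the unit length difference. The procedure
#' yields a gap pattern per input length and a seed alignment of width
#' `l_max` for any set of sequences.
#'
#' @param profiles output of [build_length_profiles()] for a contiguous
#'   length range.
#' @param substitution 20 x 20 substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap penalties on the substitution-matrix
#'   scale; with one gap per step only `gap_open` enters (as a constant) and
#'   the values are kept for interface compatibility.
#' @param seqs optional character vector; when supplied, the returned object
#'   contains the gapped rows for these sequences.
#' @return A `seed_alignment`: list with `width`, `maps` (per length, the
#'   target column of each residue), and `rows` (gapped strings, when `seqs`
#'   given).
#' @export
progressive_profile_align <- function(profiles,
                                      substitution = BLOSUM62_MATRIX,
                                      gap_open = 8, gap_extend = 1,
                                      seqs = NULL) {
  lens <- sort(as.integer(names(profiles)))
  if (length(lens) > 1 && any(diff(lens) != 1L)) {
    stop(paste("non-contiguous profile lengths:",
               paste(lens, collapse = ","),
               "- pool more sequences or bridge the missing lengths"),
         call. = FALSE)
  }
  l_min <- lens[1]
  l_max <- lens[length(lens)]
  # cumulative profile starts as the shortest PWM; maps[[as.character(l)]]
  # gives, for each of the l residues, its column in the current frame
  cum <- profiles[[as.character(l_min)]]$columns
  cum_support <- profiles[[as.character(l_min)]]$support
  maps <- list()
  maps[[as.character(l_min)]] <- seq_len(l_min)
  if (length(lens) > 1) {
    for (l in lens[-1]) {
      nxt <- profiles[[as.character(l)]]$columns    # width l
      w <- nrow(cum)                                # = l - 1
      # score of inserting the gap column before position k (k = 1..w+1)
      best_k <- 1L
      best_s <- -Inf
      for (k in seq_len(w + 1L)) {
        # columns j of cum align to columns of nxt skipping position k
        tgt <- if (k == 1L) 2:(w + 1L)
               else if (k == w + 1L) seq_len(w)
               else c(seq_len(k - 1L), (k + 1L):(w + 1L))
        s <- 0
        for (j in seq_len(w)) {
          s <- s + .profile_col_score(cum[j, ], nxt[tgt[j], ], substitution)
        }
        if (s > best_s + 1e-12) {
          best_s <- s
          best_k <- k
        }
      }
      # update maps: positions >= best_k shift right by one
      for (nm in names(maps)) {
        mp <- maps[[nm]]
        maps[[nm]] <- mp + (mp >= best_k)
      }
      maps[[as.character(l)]] <- seq_len(l)
      # merge profiles (support-weighted), gap column contributes nothing
      merged <- matrix(0, nrow = l, ncol = 20,
                       dimnames = list(NULL, AA_ALPHABET))
      gapped_cum <- matrix(0, nrow = l, ncol = 20)
      keep_rows <- setdiff(seq_len(l), best_k)
      gapped_cum[keep_rows, ] <- cum
      sup_n <- profiles[[as.character(l)]]$support
      merged <- (gapped_cum * cum_support + nxt * sup_n) /
        (cum_support + sup_n)
      # renormalize rows (gap row of gapped_cum diluted the mass)
      rs <- rowSums(merged)
      merged <- merged / ifelse(rs > 0, rs, 1)
      cum <- merged
      cum_support <- cum_support + sup_n
    }
  }
  out <- structure(list(width = nrow(cum), maps = maps, l_min = l_min,
                        l_max = l_max, profile = cum),
                   class = "seed_alignment")
  if (!is.null(seqs)) out$rows <- seed_rows(out, seqs)
  out
}

#' Gapped seed-alignment rows for a set of sequences
#'
#' Places each sequence's residues at the columns given by its length's gap
#' pattern; de-gapping any row recovers the input CDR3 exactly.
#'
#' @param seed a `seed_alignment` from [progressive_profile_align()].
#' @param seqs CDR3s whose lengths are covered by the seed.
#' @return Character vector of gapped strings of width `seed$width`.
#' @export
seed_rows <- function(seed, seqs) {
  len <- nchar(seqs)
  out <- character(length(seqs))
  for (l in unique(len)) {
    mp <- seed$maps[[as.character(l)]]
    if (is.null(mp)) {
      stop(sprintf("length %d not covered by the seed alignment", l),
           call. = FALSE)
    }
    sel <- which(len == l)
    chars <- matrix(GAP_CHAR, length(sel), seed$width)
    src <- matrix(unlist(strsplit(seqs[sel], "")), nrow = length(sel),
                  byrow = TRUE)
    chars[, mp] <- src
    out[sel] <- do.call(paste0, lapply(seq_len(seed$width),
                                       function(c) chars[, c]))
  }
  out
}

#' Profile HMM estimated from a seed alignment
#'
#' Match states are the `n_match` seed columns with the lowest gap fraction
#' (ties resolved leftmost). Emissions and transitions are counted from the
#' seed rows with Laplace pseudocounts. Insert emissions are pooled across
#' positions. States follow the standard match/insert/delete plan.
#'
#' @param seed a `seed_alignment` with `rows`, or a character vector of
#'   equal-width gapped strings.
#' @param n_match number of match states (default 19).
#' @param pseudocount Laplace pseudocount for emissions and transitions.
#' @return A `profile_hmm`: match emissions (n_match x 20), pooled insert
#'   emissions, log-space transition tables, and the match-column indices.
#' @export
build_hmm_profile <- function(seed, n_match = 19L, pseudocount = 1) {
  rows <- if (inherits(seed, "seed_alignment")) seed$rows else seed
  if (is.null(rows)) stop("seed alignment has no rows", call. = FALSE)
  width <- nchar(rows[1])
  if (any(nchar(rows) != width)) stop("seed rows differ in width",
                                      call. = FALSE)
  if (n_match > width) {
    stop(sprintf("n_match (%d) exceeds seed width (%d)", n_match, width),
         call. = FALSE)
  }
  M <- seqs_to_index_matrix(rows, width)   # n x width, 21 = gap
  gap_frac <- colMeans(M == 21L)
  match_cols <- sort(order(gap_frac, seq_len(width))[seq_len(n_match)])

  # emissions
  me <- matrix(pseudocount, nrow = n_match, ncol = 20,
               dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(n_match)) {
    v <- M[, match_cols[j]]
    tab <- tabulate(v[v <= 20L], nbins = 20)
    me[j, ] <- me[j, ] + tab
  }
  me <- me / rowSums(me)
  ins_cols <- setdiff(seq_len(width), match_cols)
  ie <- rep(pseudocount, 20)
  names(ie) <- AA_ALPHABET
  if (length(ins_cols) > 0) {
    v <- as.vector(M[, ins_cols, drop = FALSE])
    ie <- ie + tabulate(v[v <= 20L], nbins = 20)
  }
  ie <- ie / sum(ie)

  # transition counts; node j = between match state j and j+1 (0 = begin)
  # states per node: M, I, D; allowed moves: {M,I,D} -> {M(next), I(same),
  # D(next)}; node 0 has M=begin, no D. Counted with one vectorized pass
  # per column: prev_state/node are vectors over the seed rows.
  is_match <- seq_len(width) %in% match_cols
  trans <- array(pseudocount, dim = c(n_match + 1L, 3L, 3L),
                 dimnames = list(NULL, c("M", "I", "D"), c("M", "I", "D")))
  n <- nrow(M)
  prev_state <- rep(1L, n)   # M (begin)
  node <- rep(0L, n)
  add_counts <- function(rows, to_state) {
    # rows: logical selector; accumulate (node, prev_state, to) triples
    code <- (node[rows]) * 9L + (prev_state[rows] - 1L) * 3L + to_state
    tab <- tabulate(code, nbins = (n_match + 1L) * 9L)
    idx <- which(tab > 0)
    nd <- (idx - 1L) %/% 9L + 1L
    fr <- ((idx - 1L) %% 9L) %/% 3L + 1L
    trans[cbind(nd, fr, to_state)] <<- trans[cbind(nd, fr, to_state)] +
      tab[idx]
  }
  for (c in seq_len(width)) {
    sym <- M[, c]
    if (is_match[c]) {
      is_res <- sym <= 20L
      if (any(is_res)) add_counts(is_res, 1L)
      if (any(!is_res)) add_counts(!is_res, 3L)
      node <- node + 1L
      prev_state <- ifelse(is_res, 1L, 3L)
    } else {
      is_res <- sym <= 20L
      if (any(is_res)) {
        add_counts(is_res, 2L)
        prev_state[is_res] <- 2L
      }
    }
  }
  # exit to end counted as a move to M at the final node
  add_counts(rep(TRUE, n), 1L)
  # delete state cannot exist at node 0 entry side; normalize per (node, from)
  log_trans <- trans
  for (nd in seq_len(n_match + 1L)) {
    for (fr in 1:3) {
      tot <- sum(trans[nd, fr, ])
      log_trans[nd, fr, ] <- log(trans[nd, fr, ] / tot)
    }
  }
  structure(list(n_match = n_match, match_emissions = me,
                 insert_emissions = ie, log_trans = log_trans,
                 match_cols = match_cols, width = width,
                 log_match_emissions = log(me),
                 log_insert_emissions = log(ie)),
            class = "profile_hmm")
}

#' Align one CDR3 to a profile HMM (Viterbi)
#'
#' Returns a string of exactly `n_match` symbols: deletions emit '-';
#' residues emitted by insert states are dropped from the output and set the
#' `insert_flag` (truncation policy for sequences longer than the number of
#' match states). Ties in the dynamic program are broken toward match
#' states, making the decoding deterministic.
#'
#' @param seq a CDR3 string.
#' @param hmm a `profile_hmm`.
#' @return An `aligned_cdr3`: list(aligned, source, score, insert_flag,
#'   low_score_flag).
#' @export
align_to_profile <- function(seq, hmm) {
  if (nchar(seq) == 0) stop("empty sequence", call. = FALSE)
  res <- .viterbi_batch(seq, hmm)
  structure(list(aligned = res$aligned, source = seq, score = res$score,
                 insert_flag = res$insert_flag,
                 low_score_flag = res$low_score_flag),
            class = "aligned_cdr3")
}

# Viterbi over a batch of equal-length sequences, vectorized across the
# batch. States per node j: M_j (j = 1..m), I_j (j = 0..m), D_j (j = 1..m);
# D consumes no residue and is filled by a sequential scan over j after M
# and I (which depend only on the previous residue layer). Ties resolve
# with priority M > I > D.
.viterbi_batch <- function(seqs, hmm) {
  X <- seqs_to_index_matrix(seqs, nchar(seqs[1]))
  if (any(X == 21L)) stop("gap character not allowed in input",
                          call. = FALSE)
  n <- nrow(X)
  L <- ncol(X)
  m <- hmm$n_match
  NEG <- -1e30
  lt <- hmm$log_trans
  lme_t <- t(hmm$log_match_emissions)      # 20 x m
  lie <- hmm$log_insert_emissions
  # transition vectors indexed by target node
  ltMM <- lt[seq_len(m), 1L, 1L]
  ltIM <- lt[seq_len(m), 2L, 1L]
  ltDM <- lt[seq_len(m), 3L, 1L]
  ltMI <- lt[seq_len(m + 1L), 1L, 2L]
  ltII <- lt[seq_len(m + 1L), 2L, 2L]
  ltDI <- lt[seq_len(m + 1L), 3L, 2L]
  ltMD <- lt[seq_len(m), 1L, 3L]
  ltID <- lt[seq_len(m), 2L, 3L]
  ltDD <- lt[seq_len(m), 3L, 3L]
  rbm_ <- function(v) rep(v, each = n)     # broadcast over batch rows
  pick3 <- function(c1, c2, c3) {
    # elementwise max with priority 1 > 2 > 3 on ties
    val <- c1
    ptr <- array(1L, dim = dim(c1))
    upd <- c2 > val
    val[upd] <- c2[upd]
    ptr[upd] <- 2L
    upd <- c3 > val
    val[upd] <- c3[upd]
    ptr[upd] <- 3L
    list(val = val, ptr = ptr)
  }
  PM <- array(0L, dim = c(n, m, L + 1L))
  PI <- array(0L, dim = c(n, m + 1L, L + 1L))
  PD <- array(0L, dim = c(n, m, L + 1L))
  # i = 0 layer: only begin and the delete chain are reachable
  VM <- matrix(NEG, n, m)
  VI <- matrix(NEG, n, m + 1L)
  VD <- matrix(NEG, n, m)
  VD[, 1L] <- lt[1L, 1L, 3L]               # begin -> D_1
  PD[, 1L, 1L] <- 1L
  if (m >= 2L) {
    for (j in 2:m) {
      VD[, j] <- VD[, j - 1L] + ltDD[j]
      PD[, j, 1L] <- 3L
    }
  }
  for (i in seq_len(L)) {
    resi <- X[, i]
    emM <- lme_t[resi, , drop = FALSE]     # n x m
    emI <- lie[resi]                       # n
    b_prev <- if (i == 1L) 0 else NEG      # begin value at i-1 consumed
    VMaug <- cbind(rep(b_prev, n), VM)     # node 0..m at previous layer
    VDaug <- cbind(rep(NEG, n), VD)
    # M_j from node j-1 at i-1
    mm <- pick3(VMaug[, seq_len(m), drop = FALSE] + rbm_(ltMM),
                VI[, seq_len(m), drop = FALSE] + rbm_(ltIM),
                VDaug[, seq_len(m), drop = FALSE] + rbm_(ltDM))
    VM_new <- mm$val + emM
    PM[, , i + 1L] <- mm$ptr
    # I_j from node j at i-1
    ii <- pick3(VMaug + rbm_(ltMI), VI + rbm_(ltII), VDaug + rbm_(ltDI))
    VI_new <- ii$val + emI
    PI[, , i + 1L] <- ii$ptr
    # D_j from node j-1 at this layer (sequential in j)
    VD_new <- matrix(NEG, n, m)
    dd <- pick3(matrix(NEG, n, 1L), VI_new[, 1L, drop = FALSE] + ltID[1L],
                matrix(NEG, n, 1L))
    VD_new[, 1L] <- dd$val
    PD[, 1L, i + 1L] <- dd$ptr
    if (m >= 2L) {
      for (j in 2:m) {
        dd <- pick3(VM_new[, j - 1L, drop = FALSE] + ltMD[j],
                    VI_new[, j, drop = FALSE] + ltID[j],
                    VD_new[, j - 1L, drop = FALSE] + ltDD[j])
        VD_new[, j] <- dd$val
        PD[, j, i + 1L] <- dd$ptr
      }
    }
    VM <- VM_new
    VI <- VI_new
    VD <- VD_new
  }
  ee <- pick3(VM[, m, drop = FALSE] + lt[m + 1L, 1L, 1L],
              VI[, m + 1L, drop = FALSE] + lt[m + 1L, 2L, 1L],
              VD[, m, drop = FALSE] + lt[m + 1L, 3L, 1L])
  score <- as.numeric(ee$val)
  endptr <- as.integer(ee$ptr)
  # traceback per sequence
  aligned <- character(n)
  insert_flag <- logical(n)
  chars <- matrix(GAP_CHAR, n, m)
  for (r in seq_len(n)) {
    state <- endptr[r]
    j <- m
    i <- L
    ins <- FALSE
    repeat {
      if (state == 1L && j == 0L) break
      if (state == 1L) {
        chars[r, j] <- AA_ALPHABET[X[r, i]]
        state <- PM[r, j, i + 1L]
        i <- i - 1L
        j <- j - 1L
      } else if (state == 2L) {
        ins <- TRUE
        state <- PI[r, j + 1L, i + 1L]
        i <- i - 1L
      } else {
        state <- PD[r, j, i + 1L]
        j <- j - 1L
      }
    }
    insert_flag[r] <- ins
  }
  aligned <- do.call(paste0, lapply(seq_len(m), function(c) chars[, c]))
  list(aligned = aligned, score = score, insert_flag = insert_flag,
       low_score_flag = score / max(L, 1) < -10)
}

#' Align a set of CDR3s to a fixed number of columns
#'
#' Composes the four alignment steps (per-length PWMs, progressive profile
#' alignment, profile HMM, Viterbi). Deterministic given inputs and
#' configuration; the result does not depend on input order.
#'
#' @param seqs character vector of CDR3s.
#' @param n_match output width (default 19).
#' @param l_min,l_max length range used to build profiles (defaults 5, 23);
#'   sequences outside the range are still aligned in step 4.
#' @param gap_open,gap_extend profile-alignment gap penalties.
#' @param pseudocount HMM Laplace pseudocount.
#' @return A data.frame (class `cdr3_alignment`) with columns source,
#'   aligned, score, insert_flag, low_score_flag; the fitted HMM is attached
#'   as attribute `hmm`.
#' @export
align_all <- function(seqs, n_match = 19L, l_min = 5L, l_max = 23L,
                      gap_open = 8, gap_extend = 1, pseudocount = 1) {
  if (length(seqs) == 0) stop("no sequences", call. = FALSE)
  uniq <- sort(unique(seqs))
  profiles <- build_length_profiles(uniq, l_min = l_min, l_max = l_max)
  # the progressive step needs a contiguous length range; seed it from the
  # largest contiguous block of observed lengths containing the modal
  # length — sequences at outlying lengths are still aligned in step 4
  lens <- sort(as.integer(names(profiles)))
  support <- vapply(as.character(lens),
                    function(k) profiles[[k]]$support, 0)
  runs <- split(lens, cumsum(c(1, diff(lens) != 1L)))
  run_weight <- vapply(runs, function(r) {
    sum(support[as.character(r)])
  }, 0)
  block <- runs[[which.max(run_weight)]]
  if (max(block) < n_match) {
    stop(sprintf(paste("the contiguous length block %d-%d cannot seed %d",
                       "match states; supply more sequences or lower",
                       "n_match"), min(block), max(block), n_match),
         call. = FALSE)
  }
  profiles <- profiles[as.character(block)]
  in_range <- uniq[nchar(uniq) %in% block]
  seed <- progressive_profile_align(profiles, gap_open = gap_open,
                                    gap_extend = gap_extend, seqs = in_range)
  hmm <- build_hmm_profile(seed, n_match = n_match, pseudocount = pseudocount)
  # align unique sequences, batched by length (chunked to bound memory)
  aligned_u <- character(length(uniq))
  score_u <- numeric(length(uniq))
  ins_u <- logical(length(uniq))
  low_u <- logical(length(uniq))
  len_u <- nchar(uniq)
  for (l in unique(len_u)) {
    sel <- which(len_u == l)
    for (chunk in split(sel, ceiling(seq_along(sel) / 8000))) {
      res <- .viterbi_batch(uniq[chunk], hmm)
      aligned_u[chunk] <- res$aligned
      score_u[chunk] <- res$score
      ins_u[chunk] <- res$insert_flag
      low_u[chunk] <- res$low_score_flag
    }
  }
  lut <- stats::setNames(seq_along(uniq), uniq)
  idx <- lut[seqs]
  out <- data.frame(source = seqs,
                    aligned = aligned_u[idx],
                    score = score_u[idx],
                    insert_flag = ins_u[idx],
                    low_score_flag = low_u[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cdr3_alignment", "data.frame")
  attr(out, "hmm") <- hmm
  out
}

#' Write an alignment as FASTA or TSV
#' @param alignment a `cdr3_alignment` from [align_all()].
#' @param path output path.
#' @param format "tsv" (source, aligned, flags) or "fasta" (gapped rows).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(alignment), path, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  } else {
    s <- alignment$aligned
    names(s) <- alignment$source
    write_fasta(s, path)
  }
  invisible(path)
}
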