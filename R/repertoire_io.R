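# Clonotype table input/output, productive filtering, CDR3 collapsing and
# count-weighted training datasets.
#
# A clonotype table is a data.frame with columns
#   cdr3 (character), v_gene, j_gene (character or NA), count (integer >= 0),
#   productive (logical)
# plus attributes sample_id, timepoint ("day0"/"day21") and antigen, carrying
# the S3 class "clonotype_table". Clones are defined by the CDR3 amino-acid
# sequence alone; V/J genes are provenance only and never used by the models.

# column maps for the supported TSV dialects
.dialects <- list(
  adaptive = list(cdr3 = "aminoAcid", count = "count",
                  v_gene = "vGeneName", j_gene = "jGeneName",
                  productive = "sequenceStatus",
                  required = c("aminoAcid", "count")),
  airr = list(cdr3 = "junction_aa", count = "duplicate_count",
              v_gene = "v_call", j_gene = "j_call",
              productive = "productive",
              required = c("junction_aa", "duplicate_count")),
  simple_tsv = list(cdr3 = "cdr3", count = "count",
                    v_gene = "v_gene", j_gene = "j_gene",
                    productive = "productive",
                    required = c("cdr3", "count"))
)

#' Construct a clonotype table
#'
#' @param cdr3 character vector of CDR3 amino-acid sequences.
#' @param count non-negative integer read counts (recycled if length 1).
#' @param v_gene,j_gene optional gene calls (NA allowed).
#' @param productive logical productive flags (default TRUE).
#' @param sample_id,timepoint,antigen sample metadata attributes.
#' @return A `clonotype_table` (data.frame subclass).
#' @export
clonotype_table <- function(cdr3, count = 1L, v_gene = NA_character_,
                            j_gene = NA_character_, productive = TRUE,
                            sample_id = "sample", timepoint = "day0",
                            antigen = NA_character_) {
  n <- length(cdr3)
  count <- as.integer(rep_len(count, n))
  if (n > 0 && any(is.na(count) | count < 0)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  df <- data.frame(cdr3 = as.character(cdr3),
                   v_gene = as.character(rep_len(v_gene, n)),
                   j_gene = as.character(rep_len(j_gene, n)),
                   count = count,
                   productive = rep_len(as.logical(productive), n),
                   stringsAsFactors = FALSE)
  structure(df, class = c("clonotype_table", "data.frame"),
            sample_id = sample_id, timepoint = timepoint, antigen = antigen)
}

#' @exportS3Method base::print
print.clonotype_table <- function(x, ...) {
  cat(sprintf("clonotype_table: %d records, %d reads (sample %s, %s)\n",
              nrow(x), total_reads(x), attr(x, "sample_id"),
              attr(x, "timepoint")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Total number of reads in a clonotype table
#' @param table a clonotype_table.
#' @return Integer sum of counts.
#' @export
total_reads <- function(table) sum(as.integer(table$count))

# carry table attributes through a data.frame transformation
.rewrap <- function(df, template) {
  structure(df, class = c("clonotype_table", "data.frame"),
            sample_id = attr(template, "sample_id"),
            timepoint = attr(template, "timepoint"),
            antigen = attr(template, "antigen"))
}

#' Read a clonotype table from a TSV file
#'
#' Supports three tab-separated dialects: `"adaptive"` (ImmunoSEQ-style
#' columns aminoAcid/count/vGeneName/jGeneName/sequenceStatus), `"airr"`
#' (junction_aa/duplicate_count/v_call/j_call/productive) and
#' `"simple_tsv"` (cdr3/count, optional v_gene/j_gene/productive).
#'
#' @param path TSV file with a header row.
#' @param dialect one of "adaptive", "airr", "simple_tsv".
#' @param sample_id,timepoint,antigen metadata attached to the result.
#' @return A `clonotype_table`, one record per input row.
#' @export
read_clonotype_table <- function(path, dialect = c("simple_tsv", "adaptive",
                                                   "airr"),
                                 sample_id = basename(path),
                                 timepoint = "day0",
                                 antigen = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- .dialects[[dialect]]
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(map$required, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("format error: dialect '%s' requires missing column(s): %s",
                 dialect, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  n <- nrow(raw)
  get_col <- function(key, default) {
    nm <- map[[key]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else rep(default, n)
  }
  counts_chr <- trimws(get_col("count", "1"))
  ok <- grepl("^[+-]?[0-9]+$", counts_chr)
  counts <- suppressWarnings(as.integer(counts_chr))
  bad <- which(!ok | is.na(counts))
  if (length(bad) > 0) {
    stop(sprintf("parse error: non-integer count '%s' at row %d",
                 counts_chr[bad[1]], bad[1]), call. = FALSE)
  }
  prod_raw <- get_col("productive", "TRUE")
  productive <- if (dialect == "adaptive") {
    toupper(prod_raw) %in% c("IN", "PRODUCTIVE", "TRUE", "T")
  } else {
    toupper(prod_raw) %in% c("TRUE", "T", "YES", "1")
  }
  clonotype_table(cdr3 = toupper(get_col("cdr3", NA_character_)),
                  count = counts,
                  v_gene = get_col("v_gene", NA_character_),
                  j_gene = get_col("j_gene", NA_character_),
                  productive = productive,
                  sample_id = sample_id, timepoint = timepoint,
                  antigen = antigen)
}

#' Write a clonotype table in the canonical simple TSV dialect
#'
#' @param table a clonotype_table.
#' @param path output path (UTF-8, tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(table, path) {
  df <- as.data.frame(table)[, c("cdr3", "count", "v_gene", "j_gene",
                                 "productive")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read CDR3 sequences from a FASTA file
#'
#' Sequence-only input; every record gets count 1.
#'
#' @param path FASTA file of amino-acid CDR3s.
#' @inheritParams read_clonotype_table
#' @return A `clonotype_table` with one record per FASTA entry.
#' @export
read_cdr3_fasta <- function(path, sample_id = basename(path),
                            timepoint = "day0", antigen = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(trimws(x), collapse = "")), "")
  clonotype_table(cdr3 = unname(seqs), count = 1L, sample_id = sample_id,
                  timepoint = timepoint, antigen = antigen)
}

#' Write sequences to FASTA
#' @param seqs character vector (names used as headers when present).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  nm <- names(seqs) %||% paste0("seq", seq_along(seqs))
  if (is.null(names(seqs))) nm <- paste0("seq", seq_along(seqs))
  writeLines(as.vector(rbind(paste0(">", nm), unname(seqs))), path)
  invisible(path)
}

#' Filter to productive, anchored clonotypes
#'
#' Retains records flagged productive whose CDR3 starts with the conserved
#' cysteine and ends with phenylalanine or valine, and (when gene calls are
#' present) whose V/J genes do not match a pseudogene pattern.
#'
#' @param table a clonotype_table.
#' @param pseudogene_patterns character vector of substrings flagging a gene
#'   call as a pseudogene (default "OR", the orphon naming convention).
#' @return Filtered `clonotype_table`; logs counts removed per criterion.
#' @export
filter_productive <- function(table, pseudogene_patterns = c("OR")) {
  if (nrow(table) == 0) return(table)
  keep_prod <- table$productive %in% TRUE
  first <- substr(table$cdr3, 1L, 1L)
  last <- substr(table$cdr3, nchar(table$cdr3), nchar(table$cdr3))
  keep_anchor <- first == "C" & last %in% c("F", "V") & nchar(table$cdr3) >= 2
  is_pseudo <- function(g) {
    hit <- rep(FALSE, length(g))
    for (p in pseudogene_patterns) {
      hit <- hit | (!is.na(g) & grepl(p, g, fixed = TRUE))
    }
    hit
  }
  keep_gene <- !(is_pseudo(table$v_gene) | is_pseudo(table$j_gene))
  keep <- keep_prod & keep_anchor & keep_gene
  message(sprintf(
    "filter_productive: removed %d non-productive, %d anchor-violating, %d pseudogene records",
    sum(!keep_prod), sum(keep_prod & !keep_anchor),
    sum(keep_prod & keep_anchor & !keep_gene)))
  .rewrap(as.data.frame(table)[keep, , drop = FALSE], table)
}

#' Collapse records sharing the same CDR3
#'
#' Sums read counts over all records with an identical CDR3 amino-acid
#' sequence (including records with different V-J genes). The collapsed
#' record keeps the V/J genes of the highest-count contributing row (ties
#' broken to the lexicographically smallest V gene, then J gene); this is
#' provenance only. Also reports the fraction of reads whose CDR3 had more
#' than one distinct V-J combination, as attribute `multi_vj_read_fraction`.
#'
#' @param table a clonotype_table.
#' @return Collapsed `clonotype_table`: each cdr3 appears exactly once and
#'   the total read count is conserved exactly.
#' @export
collapse_by_cdr3 <- function(table) {
  df <- as.data.frame(table)
  if (nrow(df) == 0) {
    out <- .rewrap(df, table)
    attr(out, "multi_vj_read_fraction") <- 0
    return(out)
  }
  key <- df$cdr3
  ord <- order(key, -df$count, df$v_gene, df$j_gene, method = "radix")
  df <- df[ord, , drop = FALSE]
  first_row <- !duplicated(df$cdr3)
  counts <- rowsum(df$count, df$cdr3, reorder = FALSE)[, 1]
  vj <- paste(df$v_gene, df$j_gene, sep = "|")
  nvj <- vapply(split(vj, factor(df$cdr3, levels = unique(df$cdr3))),
                function(x) length(unique(x)), 0L)
  multi <- nvj > 1
  total <- sum(df$count)
  frac <- if (total > 0) sum(counts[multi]) / total else 0
  out <- df[first_row, , drop = FALSE]
  out$count <- as.integer(counts)
  out$productive <- vapply(
    split(df$productive, factor(df$cdr3, levels = unique(df$cdr3))),
    any, TRUE)
  rownames(out) <- NULL
  out <- .rewrap(out, table)
  attr(out, "multi_vj_read_fraction") <- unname(frac)
  out
}

#' Convert a clonotype table to a count-weighted dataset
#'
#' Sequences with count >= `min_count` paired with their counts as weights.
#' Weighting is mathematically equivalent to replicating each sequence by
#' its multiplicity for every downstream likelihood.
#'
#' @param table a clonotype_table (normally already collapsed).
#' @param min_count minimum read count to retain (>= 1).
#' @return A `count_weighted` dataset: list(sequences, weights).
#' @export
to_count_weighted <- function(table, min_count = 1L) {
  if (min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  keep <- table$count >= min_count
  if (!any(keep)) {
    stop("empty dataset: no sequences with count >= ", min_count,
         call. = FALSE)
  }
  structure(list(sequences = table$cdr3[keep],
                 weights = as.numeric(table$count[keep])),
            class = "count_weighted")
}

#' @exportS3Method base::print
print.count_weighted <- function(x, ...) {
  cat(sprintf("count_weighted dataset: %d sequences, total weight %g\n",
              length(x$sequences), sum(x$weights)))
  invisible(x)
}

#' Weighted single-site residue frequencies of a count-weighted dataset
#'
#' Frequencies are computed over left-aligned positions 1..max length; used
#' mainly by tests against the explicit-replication oracle.
#'
#' @param dataset a count_weighted dataset (or list with sequences/weights).
#' @return Matrix positions x 21 states of weighted frequencies.
#' @export
weighted_site_frequencies <- function(dataset) {
  idx <- seq_to_indices(dataset$sequences)
  lmax <- max(lengths(idx))
  freq <- matrix(0, nrow = lmax, ncol = 21,
                 dimnames = list(NULL, AA_GAP_ALPHABET))
  denom <- numeric(lmax)
  for (k in seq_along(idx)) {
    v <- idx[[k]]
    w <- dataset$weights[k]
    for (i in seq_along(v)) freq[i, v[i]] <- freq[i, v[i]] + w
    denom[seq_along(v)] <- denom[seq_along(v)] + w
  }
  sweep(freq, 1, pmax(denom, 1e-300), "/")
}
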