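# Fold change, expansion calling (Fisher exact + Storey q-values),
# probabilistic response and specificity scores, AUROC and correlation
# evaluation, and the read-split / k-fold validation protocols.

#' Pseudo-counted clonal fold change
#'
#' `(n21 + 1/2) / (n0 + 1/2)`; the 1/2 pseudo-count keeps the ratio defined
#' at zero counts.
#'
#' @param n21,n0 non-negative read counts at day 21 and day 0 (vectorized).
#' @return Positive fold changes.
#' @export
fold_change <- function(n21, n0) {
  if (any(n21 < 0) || any(n0 < 0)) stop("counts must be non-negative",
                                        call. = FALSE)
  (n21 + 0.5) / (n0 + 0.5)
}

# one-sided Fisher exact p-value (enrichment at day 21) via the
# hypergeometric tail; identical to fisher.test(alternative="greater")
.fisher_one_sided <- function(n21, n0, total21, total0) {
  stats::phyper(n21 - 1L, n21 + n0, (total21 - n21) + (total0 - n0),
                total21, lower.tail = FALSE)
}

#' Storey q-values
#'
#' The standard Storey false-discovery-rate q-values: pi0 is estimated on a
#' lambda grid 0.05-0.95 with a cubic smoothing spline evaluated at the
#' largest lambda (falling back to 1 for small inputs), and q-values are the
#' running minimum of `pi0 * m * p / rank`.
#'
#' @param p vector of p-values.
#' @param lambda grid for the pi0 estimate.
#' @return list(qvalues, pi0).
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  if (m == 0) return(list(qvalues = numeric(0), pi0 = 1))
  pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
  pi0 <- if (m >= 100 && stats::var(p) > 0) {
    fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
    stats::predict(fit, x = max(lambda))$y
  } else {
    min(pi0_lambda[length(pi0_lambda)], 1)
  }
  pi0 <- min(max(pi0, 1e-8), 1)
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  running <- 1
  ranks <- rank(p, ties.method = "max")
  q_raw <- pmin(pi0 * m * p / ranks, 1)
  for (i in ord) {
    running <- min(running, q_raw[i])
    q[i] <- running
  }
  list(qvalues = q, pi0 = pi0)
}

#' Call expanded clones between two timepoints
#'
#' For every clone in the union of the two tables (absent clones counted 0),
#' computes the pseudo-counted fold change, a one-sided Fisher exact test of
#' enrichment at day 21 (clone reads vs all other reads), and Storey
#' q-values across all tested clones. A clone is expanded iff fold change >
#' `fc_threshold` and q < `q_threshold`.
#'
#' @param day0,day21 `clonotype_table`s from the same sample lineage.
#' @param fc_threshold fold-change cutoff (default 2).
#' @param q_threshold q-value cutoff (default 0.05).
#' @return data.frame (class `expansion_calls`): cdr3, n0, n21, fold_change,
#'   p_value, q_value, expanded.
#' @export
call_expanded <- function(day0, day21, fc_threshold = 2, q_threshold = 0.05) {
  if (nrow(day0) == 0 && nrow(day21) == 0) stop("empty tables",
                                                call. = FALSE)
  cdr3 <- sort(union(day0$cdr3, day21$cdr3))
  n0 <- integer(length(cdr3))
  n21 <- integer(length(cdr3))
  n0[match(day0$cdr3, cdr3)] <- day0$count
  n21[match(day21$cdr3, cdr3)] <- day21$count
  total0 <- sum(n0)
  total21 <- sum(n21)
  fc <- fold_change(n21, n0)
  p <- .fisher_one_sided(n21, n0, total21, total0)
  q <- storey_qvalue(p)$qvalues
  out <- data.frame(cdr3 = cdr3, n0 = n0, n21 = n21, fold_change = fc,
                    p_value = p, q_value = q,
                    expanded = fc > fc_threshold & q < q_threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("expansion_calls", "data.frame")
  out
}

# generic scoring: normalized log-probability of CDR3s under any model
.model_log_prob <- function(model, seqs) {
  if (inherits(model, "rbm_model")) {
    s <- seqs
    need_align <- nchar(seqs) != model$n_sites
    if (any(need_align)) {
      if (is.null(model$hmm)) {
        stop("raw CDR3s supplied but the RBM has no attached alignment HMM",
             call. = FALSE)
      }
      s[need_align] <- vapply(seqs[need_align], function(x) {
        align_to_profile(x, model$hmm)$aligned
      }, "", USE.NAMES = FALSE)
    }
    lz <- if (!is.null(model$log_z)) model$log_z$value else {
      warning("RBM log Z not estimated; returning unnormalized log-scores")
      0
    }
    log_score(model, s) - lz
  } else if (inherits(model, "selection_model")) {
    sonia_log_prob(model, seqs)
  } else if (inherits(model, "background_model")) {
    lp <- model$log_prob(seqs)
    lp[!is.finite(lp)] <- NA_real_
    lp
  } else if (is.function(model)) {
    model(seqs)
  } else {
    stop("unsupported scoring model", call. = FALSE)
  }
}

#' Response score of clones to an antigen stimulation
#'
#' `S_resp = log P21(sigma) - log P_background(sigma)` per sequence, where
#' the background is the pre-stimulation model (or any background
#' distribution: generation-probability providers, built-in backgrounds).
#' Computed in natural log; set `log10 = TRUE` for display scale.
#'
#' @param model21 scoring model of the post-stimulation repertoire
#'   (`rbm_model` with log Z resolved, `selection_model`,
#'   `background_model`, or a function seqs -> log-probabilities).
#' @param background background scoring model (same accepted types).
#' @param seqs CDR3s (raw; RBM models with an attached `hmm` align them).
#' @param log10 report in log base 10 (default FALSE: natural log).
#' @return Numeric scores (NA where the background does not support a
#'   sequence).
#' @export
response_score <- function(model21, background, seqs, log10 = FALSE) {
  s <- .model_log_prob(model21, seqs) - .model_log_prob(background, seqs)
  if (log10) s / log(10) else s
}

#' Specificity score across antigens
#'
#' For each sequence, the response score under the focal antigen minus the
#' maximum response score over the other antigens. With two antigens this
#' difference is antisymmetric between them. With a background shared across
#' antigens the background cancels exactly.
#'
#' @param resp_scores_by_antigen named list of aligned numeric vectors, one
#'   per antigen (same clone order).
#' @param focal name of the focal antigen.
#' @return Numeric vector of specificity scores.
#' @export
specificity_score <- function(resp_scores_by_antigen, focal) {
  nms <- names(resp_scores_by_antigen)
  if (length(nms) < 2) stop("need >= 2 antigens", call. = FALSE)
  if (!focal %in% nms) stop("unknown focal antigen: ", focal, call. = FALSE)
  others <- resp_scores_by_antigen[setdiff(nms, focal)]
  lens <- vapply(resp_scores_by_antigen, length, 0L)
  if (length(unique(lens)) != 1) stop("score vectors differ in length",
                                      call. = FALSE)
  max_other <- do.call(pmax, others)
  resp_scores_by_antigen[[focal]] - max_other
}

#' ROC curve and AUROC of a specificity score
#'
#' Exact rank-statistic AUROC with midranks for ties (equal to the
#' Mann-Whitney U statistic divided by n1*n0) plus the threshold-swept ROC
#' points.
#'
#' @param s_spec numeric scores.
#' @param labels logical (or 0/1): TRUE = specific responder.
#' @return list (class `evaluation_report`): auroc, roc (data.frame fpr,
#'   tpr), n_positive, n_negative.
#' @export
specificity_auroc <- function(s_spec, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(s_spec) & !is.na(labels)
  s <- s_spec[keep]
  y <- labels[keep]
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both label classes must be present",
                               call. = FALSE)
  r <- rank(s, ties.method = "average")
  auroc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(s, decreasing = TRUE)
  tp <- cumsum(y[ord])
  fp <- cumsum(!y[ord])
  roc <- data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  structure(list(auroc = auroc, roc = roc, n_positive = n1,
                 n_negative = n0),
            class = "evaluation_report")
}

#' @exportS3Method base::print
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: AUROC %.4f (%d specific vs %d unspecific)\n",
              x$auroc, x$n_positive, x$n_negative))
  invisible(x)
}

#' Pairwise specificity AUROC matrix for more than two antigens
#'
#' Entry (p, p') is the AUROC of the two-antigen specificity score between
#' antigens p and p', with clones labeled specific to whichever of the two
#' has the higher fold change (ties dropped).
#'
#' @param resp_scores_by_antigen named list of aligned score vectors.
#' @param fc_by_antigen named list of aligned fold-change vectors.
#' @return Square matrix of AUROCs (NA on the diagonal).
#' @export
pairwise_auroc_matrix <- function(resp_scores_by_antigen, fc_by_antigen) {
  nms <- names(resp_scores_by_antigen)
  k <- length(nms)
  out <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      s <- resp_scores_by_antigen[[a]] - resp_scores_by_antigen[[b]]
      fa <- fc_by_antigen[[a]]
      fb <- fc_by_antigen[[b]]
      keep <- fa != fb
      if (sum(keep & fa > fb) == 0 || sum(keep & fa < fb) == 0) next
      out[a, b] <- specificity_auroc(s[keep], (fa > fb)[keep])$auroc
    }
  }
  out
}

#' Correlation between scores and expansion as low-count clones are removed
#'
#' For each retained-N, keeps the N most-abundant clones (count ties broken
#' by CDR3 lexicographic order, independent of the scores) and reports the
#' Pearson and Spearman correlation between score and target (log fold
#' change or log count).
#'
#' @param scores numeric scores per clone.
#' @param counts clone abundances used for filtering.
#' @param target values to correlate against (default `log(counts + 0.5)`).
#' @param retain_ns decreasing vector of clone numbers to retain.
#' @param cdr3 optional CDR3s for the deterministic tie-break.
#' @return data.frame (retained_n, pearson, spearman); `retained_n` is
#'   truncated (with a warning) where it exceeds the number of clones, and
#'   degenerate sizes (< 3) are flagged by NA correlations.
#' @export
correlation_vs_abundance_filter <- function(scores, counts,
                                            target = log(counts + 0.5),
                                            retain_ns = c(1000, 500, 250,
                                                          125),
                                            cdr3 = NULL) {
  n <- length(scores)
  stopifnot(length(counts) == n, length(target) == n)
  if (any(retain_ns > n)) {
    warning("retain_ns exceeding the number of clones truncated to ", n)
    retain_ns[retain_ns > n] <- n
  }
  retain_ns <- sort(unique(retain_ns), decreasing = TRUE)
  tie <- cdr3 %||% as.character(seq_len(n))
  ord <- order(-counts, tie)
  rows <- lapply(retain_ns, function(N) {
    idx <- ord[seq_len(N)]
    ok <- is.finite(scores[idx]) & is.finite(target[idx])
    if (sum(ok) < 3) {
      return(data.frame(retained_n = N, pearson = NA_real_,
                        spearman = NA_real_))
    }
    data.frame(retained_n = N,
               pearson = stats::cor(scores[idx][ok], target[idx][ok]),
               spearman = stats::cor(scores[idx][ok], target[idx][ok],
                                     method = "spearman"))
  })
  do.call(rbind, rows)
}

#' Random read split into training and testing tables
#'
#' Each read is assigned to the training set independently with probability
#' `fraction` (binomial per clone); per-clone counts are conserved exactly
#' across the two outputs.
#'
#' @param table a `clonotype_table`.
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed.
#' @return list(train, test) of `clonotype_table`s (zero-count records
#'   dropped).
#' @export
split_reads_train_test <- function(table, fraction = 0.8, seed = 1L) {
  set.seed(seed)
  n_train <- stats::rbinom(nrow(table), table$count, fraction)
  n_test <- table$count - n_train
  mk <- function(counts) {
    df <- as.data.frame(table)
    df$count <- as.integer(counts)
    .rewrap(df[df$count > 0, , drop = FALSE], table)
  }
  list(train = mk(n_train), test = mk(n_test))
}

#' Disjoint k-folds of unique clones
#'
#' Shuffles the unique CDR3s (seeded) and splits them into k folds whose
#' sizes differ by at most one; the same sequence never appears in two
#' folds. Supports leave-one-out validation and spike-in protocols that mix
#' held-out responders with generated background sequences.
#'
#' @param clones character vector of CDR3s (deduplicated internally).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of k character vectors.
#' @export
kfold_unique_clones <- function(clones, k = 5L, seed = 1L) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  u <- unique(clones)
  if (length(u) < k) stop("fewer unique clones than folds", call. = FALSE)
  set.seed(seed)
  u <- sample(u)
  split(u, rep_len(seq_len(k), length(u)))
}

#' Replicate-split null control for specificity scoring
#'
#' The end-to-end negative control: simulate one baseline repertoire (no
#' responders), split its reads binomially into two technical replicates,
#' train one RBM per replicate on the count-weighted aligned sequences,
#' compute per-clone specificity scores between the two replicate models
#' (AIS-normalized log-probability difference), label each clone by which
#' replicate holds the higher count (ties dropped), and return the AUROC.
#' Two statistically indistinguishable samples should give AUROC ~ 0.5.
#'
#' @param seed integer seed driving the whole pipeline.
#' @param n_clones,depth repertoire size and read depth (defaults 2000 and
#'   1e5).
#' @param n_hidden,l1sq RBM architecture (defaults 10 and 0.1, the
#'   responding-only model defaults).
#' @param epochs training epochs per replicate model (default 40, a reduced
#'   desk-scale schedule; the null does not require full convergence, only
#'   that both models receive identical treatment).
#' @param ais_temps,ais_chains reduced AIS settings for the per-model log Z
#'   (the AUROC is invariant to these per-model constants).
#' @param batch_size training minibatch size (larger batches keep big
#'   repertoires affordable).
#' @return list(auroc, n_scored, n_clones).
#' @export
replicate_null_specificity <- function(seed, n_clones = 2000L, depth = 1e5,
                                       n_hidden = 10L, l1sq = 0.1,
                                       epochs = 40L, ais_temps = 200L,
                                       ais_chains = 10L,
                                       batch_size = 128L) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 5L)
  cfg <- sim_config(n_clones = n_clones, depth = depth)
  clones <- generate_repertoire(cfg, seed = sub[1])
  day0 <- simulate_counts(clones, rep(1, n_clones), depth,
                          seed = sub[2])$day0
  reps <- make_replicates(day0, seed = sub[3])
  ali <- align_all(day0$cdr3)
  aligned_of <- stats::setNames(ali$aligned, ali$source)
  fit_one <- function(tab, s) {
    cw <- to_count_weighted(tab)
    m <- train_rbm(list(sequences = unname(aligned_of[cw$sequences]),
                        weights = cw$weights),
                   n_hidden = n_hidden, l1sq = l1sq, epochs = epochs,
                   batch_size = batch_size, seed = s)
    m <- log_partition(m, "ais", n_temps = ais_temps,
                       n_chains = ais_chains, seed = s)
    m
  }
  m1 <- fit_one(reps$rep1, sub[4])
  m2 <- fit_one(reps$rep2, sub[5])
  n1 <- reps$rep1$count[match(day0$cdr3, reps$rep1$cdr3)]
  n2 <- reps$rep2$count[match(day0$cdr3, reps$rep2$cdr3)]
  n1[is.na(n1)] <- 0L
  n2[is.na(n2)] <- 0L
  keep <- n1 != n2
  aligned <- unname(aligned_of[day0$cdr3[keep]])
  s_spec <- (log_score(m1, aligned) - m1$log_z$value) -
    (log_score(m2, aligned) - m2$log_z$value)
  rep1_wins <- fold_change(n1[keep], 0) > fold_change(n2[keep], 0)
  ev <- specificity_auroc(s_spec, rep1_wins)
  list(auroc = ev$auroc, n_scored = sum(keep), n_clones = n_clones)
}

#' Write a per-clone score report as TSV
#' @param report data.frame of per-clone results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
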