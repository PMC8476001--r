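# Independent-site selection-factor model over Left+Right features with a
# pluggable background distribution:
#   P(sigma) = Q(sigma) * P_bg(sigma),  Q = (1/Z) prod_i q_{i,l}(sigma_i),
# where each position factor is the product of a left term (distance from
# the left anchor) and a right term (distance from the right anchor),
# out-of-range distances (>= ref_length) contributing factor 1. Factors are
# learned in log space by maximum likelihood with an L2 penalty on log q;
# model expectations are estimated over background samples importance-
# weighted by the unnormalized Q.

# ---- background models --------------------------------------------------

#' Built-in background distributions over CDR3s
#'
#' Simple self-contained generative models standing in for an external
#' generation-probability provider. Kinds:
#' \describe{
#'   \item{empirical_day0}{the weighted empirical distribution of the fit
#'     data; sequences outside the support are unsupported (NA log-prob).}
#'   \item{positionwise_independent}{length distribution times per-length,
#'     per-position residue frequencies (anchors inherited from the data).}
#'   \item{markov1}{length distribution times a first-residue law and a
#'     homogeneous order-1 residue transition matrix.}
#' }
#' Any object with elements `log_prob(seqs)` and `sample(n, seed)` can be
#' used wherever a background model is accepted (the adapter point for
#' external generation-probability providers).
#'
#' @param kind background family.
#' @param fit_data a `count_weighted` dataset or character vector of CDR3s
#'   (weights default to 1).
#' @param pseudocount smoothing for fitted frequencies (default 0.5).
#' @return A `background_model` with functions `log_prob` and `sample`.
#' @export
builtin_background <- function(kind = c("positionwise_independent",
                                        "empirical_day0", "markov1"),
                               fit_data, pseudocount = 0.5) {
  kind <- match.arg(kind)
  if (is.character(fit_data)) {
    fit_data <- list(sequences = fit_data, weights = rep(1, length(fit_data)))
  }
  seqs <- fit_data$sequences
  w <- fit_data$weights %||% rep(1, length(seqs))
  if (length(seqs) < 2) stop("insufficient fit data", call. = FALSE)
  lens <- nchar(seqs)
  len_levels <- sort(unique(lens))
  len_prob <- vapply(len_levels, function(l) sum(w[lens == l]), 0)
  len_prob <- len_prob / sum(len_prob)
  names(len_prob) <- len_levels

  if (kind == "empirical_day0") {
    tot <- sum(w)
    tab <- tapply(w, seqs, sum) / tot
    log_tab <- log(tab)
    model <- list(
      kind = kind,
      log_prob = function(x) {
        out <- unname(log_tab[x])
        out[is.na(out)] <- NA_real_
        out
      },
      sample = function(n, seed = 1L) {
        set.seed(seed)
        sample(names(tab), n, replace = TRUE, prob = as.numeric(tab))
      })
  } else if (kind == "positionwise_independent") {
    # anchor positions (first and last) are fit unsmoothed so the
    # constructed anchor constraint is exact; interior positions are
    # smoothed over the full alphabet
    pwms <- lapply(len_levels, function(l) {
      sel <- lens == l
      m <- seqs_to_index_matrix(seqs[sel], l)
      ww <- w[sel]
      cnt <- matrix(0, nrow = l, ncol = 20)
      for (i in seq_len(l)) {
        cnt[i, ] <- vapply(seq_len(20), function(a) {
          sum(ww[m[, i] == a])
        }, 0)
        if (i > 1 && i < l) cnt[i, ] <- cnt[i, ] + pseudocount
      }
      log(cnt / rowSums(cnt))
    })
    names(pwms) <- len_levels
    model <- list(
      kind = kind,
      log_prob = function(x) {
        vapply(x, function(s) {
          l <- nchar(s)
          key <- as.character(l)
          if (!key %in% names(pwms)) return(NA_real_)
          idx <- seq_to_indices(s)[[1]]
          if (any(idx > 20L)) return(NA_real_)
          lp <- pwms[[key]]
          log(len_prob[key]) + sum(lp[cbind(seq_len(l), idx)])
        }, 0, USE.NAMES = FALSE)
      },
      sample = function(n, seed = 1L) {
        set.seed(seed)
        ls <- sample(len_levels, n, replace = TRUE, prob = len_prob)
        out <- character(n)
        for (l in unique(ls)) {
          sel <- which(ls == l)
          lp <- exp(pwms[[as.character(l)]])
          cols <- lapply(seq_len(l), function(i) {
            sample(AA_ALPHABET, length(sel), replace = TRUE, prob = lp[i, ])
          })
          out[sel] <- do.call(paste0, cols)
        }
        out
      })
  } else {  # markov1
    m_idx <- seq_to_indices(seqs)
    first <- vapply(m_idx, `[`, 0L, 1L)
    # first-residue law unsmoothed: the anchor constraint is exact
    p1 <- numeric(20)
    for (a in seq_len(20)) p1[a] <- sum(w[first == a])
    p1 <- p1 / sum(p1)
    trans <- matrix(pseudocount, 20, 20)
    for (k in seq_along(m_idx)) {
      v <- m_idx[[k]]
      if (length(v) >= 2) {
        for (t in seq_len(length(v) - 1L)) {
          trans[v[t], v[t + 1L]] <- trans[v[t], v[t + 1L]] + w[k]
        }
      }
    }
    trans <- trans / rowSums(trans)
    model <- list(
      kind = kind,
      log_prob = function(x) {
        vapply(x, function(s) {
          l <- nchar(s)
          key <- as.character(l)
          if (!key %in% names(len_prob)) return(NA_real_)
          idx <- seq_to_indices(s)[[1]]
          if (any(idx > 20L)) return(NA_real_)
          lp <- log(len_prob[key]) + log(p1[idx[1]])
          if (l >= 2) {
            lp <- lp + sum(log(trans[cbind(idx[-l], idx[-1])]))
          }
          unname(lp)
        }, 0, USE.NAMES = FALSE)
      },
      sample = function(n, seed = 1L) {
        set.seed(seed)
        ls <- sample(len_levels, n, replace = TRUE, prob = len_prob)
        lmax <- max(ls)
        # vectorized chain across sequences: cumulative-probability lookup
        cum_trans <- t(apply(trans, 1, cumsum))
        M <- matrix(0L, n, lmax)
        M[, 1] <- sample.int(20, n, replace = TRUE, prob = p1)
        for (t in 2:lmax) {
          u <- stats::runif(n)
          rows <- cum_trans[M[, t - 1L], , drop = FALSE]
          M[, t] <- max.col(rows >= u, ties.method = "first")
        }
        out <- character(n)
        for (l in unique(ls)) {
          sel <- which(ls == l)
          out[sel] <- do.call(paste0, lapply(seq_len(l), function(t) {
            AA_ALPHABET[M[sel, t]]
          }))
        }
        out
      })
  }
  structure(model, class = "background_model")
}

#' @exportS3Method base::print
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: kind '%s'\n", x$kind))
  invisible(x)
}

# ---- selection model ----------------------------------------------------

#' Construct a selection model
#'
#' @param qL,qR ref_length x 20 matrices of positive selection factors for
#'   the left- and right-anchored distances.
#' @param background a `background_model`.
#' @param log_z normalization of Q (default 0, i.e. unnormalized).
#' @param ref_length maximum anchored distance (default 19).
#' @return A `selection_model`.
#' @export
selection_model <- function(qL = NULL, qR = NULL, background = NULL,
                            log_z = 0, ref_length = 19L) {
  qL <- qL %||% matrix(1, ref_length, 20, dimnames = list(NULL, AA_ALPHABET))
  qR <- qR %||% matrix(1, ref_length, 20, dimnames = list(NULL, AA_ALPHABET))
  if (any(qL <= 0) || any(qR <= 0)) stop("q-factors must be positive",
                                         call. = FALSE)
  structure(list(qL = qL, qR = qR, background = background, log_z = log_z,
                 ref_length = as.integer(ref_length), version = 1L),
            class = "selection_model")
}

#' @exportS3Method base::print
print.selection_model <- function(x, ...) {
  cat(sprintf(
    "selection_model: ref_length %d, log Z %.4f, background %s\n",
    x$ref_length, x$log_z,
    if (is.null(x$background)) "none" else x$background$kind))
  invisible(x)
}

#' Position-specific selection factor
#'
#' The factor for residue `residue` at 0-based `position_from_left` in a
#' CDR3 of length `length`: product of the left factor at the left distance
#' and the right factor at the right distance, sides at distance >=
#' ref_length contributing factor 1.
#'
#' @param model a `selection_model`.
#' @param position_from_left 0-based position (0 <= position < length).
#' @param length CDR3 length.
#' @param residue one-letter residue.
#' @return Positive scalar.
#' @export
q_factor <- function(model, position_from_left, length, residue) {
  if (position_from_left < 0 || position_from_left >= length) {
    stop("position out of range", call. = FALSE)
  }
  a <- .aa_index[utf8ToInt(residue)]
  if (is.na(a) || a > 20L) stop("invalid residue: ", residue, call. = FALSE)
  dl <- position_from_left
  dr <- length - 1L - position_from_left
  f <- 1
  if (dl < model$ref_length) f <- f * model$qL[dl + 1L, a]
  if (dr < model$ref_length) f <- f * model$qR[dr + 1L, a]
  unname(f)
}

# unnormalized log Q for a set of sequences: feature-sparse dot product
.log_q_tilde <- function(model, seqs) {
  X <- left_right_sparse(seqs, model$ref_length)
  lam <- c(as.numeric(t(log(model$qL))), as.numeric(t(log(model$qR))))
  as.numeric(X %*% lam)
}

#' Log-probability under a selection model
#'
#' `log P = sum_i log q_factor - log Z + log P_bg`. Sequences with zero or
#' unavailable background probability yield NA with a warning (the
#' unsupported-sequence signal), never a silent -Inf.
#'
#' @param model a `selection_model` with a background supporting log_prob.
#' @param seqs character vector of CDR3s.
#' @return Numeric vector of log-probabilities (NA where unsupported).
#' @export
sonia_log_prob <- function(model, seqs) {
  if (is.null(model$background) || is.null(model$background$log_prob)) {
    stop("selection model has no background log_prob", call. = FALSE)
  }
  bg <- model$background$log_prob(seqs)
  if (anyNA(bg) || any(!is.finite(bg))) {
    warning(sum(!is.finite(bg) | is.na(bg)),
            " sequence(s) unsupported by the background model (NA returned)")
    bg[!is.finite(bg)] <- NA_real_
  }
  .log_q_tilde(model, seqs) - model$log_z + bg
}

#' Fit a selection model by penalized maximum likelihood
#'
#' Gradient ascent in log-factor space on the weighted likelihood of the
#' data under `P = Q P_bg`, with an L2 penalty on log q (zero penalty at
#' q = 1). Each epoch draws fresh background samples (seeded); model feature
#' expectations are computed over those samples importance-weighted by the
#' unnormalized Q, and log Z is re-estimated as the importance-sampling mean
#' of Q.
#'
#' @param data a `count_weighted` dataset (or character vector of CDR3s).
#' @param background a `background_model`.
#' @param l2 penalty strength on log q (default 0.01).
#' @param n_background_samples background sample size per epoch.
#' @param epochs,learning_rate optimization schedule.
#' @param ref_length maximum anchored distance (default 19).
#' @param seed integer seed.
#' @param verbose print progress.
#' @return A fitted `selection_model` (log Z set from the final epoch).
#' @export
train_sonia <- function(data, background, l2 = 0.01,
                        n_background_samples = 5000L, epochs = 150L,
                        learning_rate = 0.5, ref_length = 19L, seed = 1L,
                        verbose = FALSE) {
  if (is.character(data)) {
    data <- list(sequences = data, weights = rep(1, length(data)))
  }
  seqs <- data$sequences
  w <- data$weights / sum(data$weights)
  if (length(seqs) == 0) stop("empty training data", call. = FALSE)
  bg_lp <- background$log_prob(seqs)
  supported <- is.finite(bg_lp)
  if (!any(supported)) {
    stop("all training sequences have zero background probability",
         call. = FALSE)
  }
  if (!all(supported)) {
    warning(sum(!supported),
            " training sequence(s) outside the background support dropped")
    seqs <- seqs[supported]
    w <- w[supported]
    w <- w / sum(w)
  }
  X <- left_right_sparse(seqs, ref_length)
  f_data <- as.numeric(Matrix::crossprod(X, w))
  n_feat <- ref_length * 40L
  lam <- numeric(n_feat)
  set.seed(seed)
  bg_seeds <- sample.int(.Machine$integer.max - 1L, epochs)
  log_z <- 0
  for (ep in seq_len(epochs)) {
    bs <- background$sample(n_background_samples, seed = bg_seeds[ep])
    Xb <- left_right_sparse(bs, ref_length)
    log_qt <- as.numeric(Xb %*% lam)
    lw <- log_qt - logsumexp(log_qt)      # normalized importance weights
    iw <- exp(lw)
    f_model <- as.numeric(Matrix::crossprod(Xb, iw))
    grad <- f_data - f_model - l2 * lam
    lam <- lam + learning_rate * grad
    log_z <- logsumexp(log_qt) - log(length(bs))
    if (verbose && ep %% 25L == 0L) {
      message(sprintf("epoch %d: logZ %.4f, max|grad| %.4g", ep, log_z,
                      max(abs(grad))))
    }
  }
  qL <- matrix(exp(lam[seq_len(ref_length * 20L)]), nrow = ref_length,
               ncol = 20, byrow = TRUE, dimnames = list(NULL, AA_ALPHABET))
  qR <- matrix(exp(lam[ref_length * 20L + seq_len(ref_length * 20L)]),
               nrow = ref_length, ncol = 20, byrow = TRUE,
               dimnames = list(NULL, AA_ALPHABET))
  m <- selection_model(qL = qL, qR = qR, background = background,
                       log_z = log_z, ref_length = ref_length)
  m$l2 <- l2
  m$seed <- seed
  m
}

#' Write / read a selection model (JSON archive, background not serialized)
#' @param model a `selection_model`.
#' @param path file path.
#' @return `path` invisibly; `read_sonia` returns the model (background must
#'   be re-attached by the caller).
#' @export
write_sonia <- function(model, path) {
  obj <- list(format = "tcrboltz_sonia", version = model$version %||% 1L,
              ref_length = model$ref_length, qL = model$qL, qR = model$qR,
              log_z = model$log_z, l2 = model$l2, seed = model$seed,
              background_kind = model$background$kind %||% NA)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_sonia
#' @export
read_sonia <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "tcrboltz_sonia")) {
    stop("not a tcrboltz selection-model archive: ", path, call. = FALSE)
  }
  m <- selection_model(qL = matrix(obj$qL, obj$ref_length, 20,
                                   dimnames = list(NULL, AA_ALPHABET)),
                       qR = matrix(obj$qR, obj$ref_length, 20,
                                   dimnames = list(NULL, AA_ALPHABET)),
                       log_z = obj$log_z, ref_length = obj$ref_length)
  m$l2 <- obj$l2
  m$seed <- obj$seed
  m
}
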