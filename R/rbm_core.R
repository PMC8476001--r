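# Restricted Boltzmann Machine with dReLU hidden units over aligned
# categorical sequences (q = 21 states: 20 residues + gap).
#
# Joint distribution:
#   P(sigma, h) ~ exp( sum_i g_i(sigma_i) - sum_mu U_mu(h_mu)
#                      + sum_{i,mu} h_mu w_{i,mu}(sigma_i) )
# with the double rectified linear (dReLU) hidden potential
#   U(h) = gamma_plus/2 h_+^2 + gamma_minus/2 h_-^2
#          + theta_plus h_+ + theta_minus h_-,   h_+ = max(h,0), h_- = min(h,0).
# Marginalizing h gives log P(sigma) = sum_i g_i + sum_mu Gamma_mu(I_mu) - log Z
# with I_mu(sigma) = sum_i w_{i,mu}(sigma_i) and Gamma the log partition of
# the conditional hidden integral, available in closed form via Gaussian
# tails (evaluated with pnorm(log.p = TRUE) for stability).
#
# Weights are stored as a (n_sites * n_states) x n_hidden matrix with
# visible index v = (site - 1) * n_states + state.

#' Construct an RBM model
#'
#' @param n_sites number of aligned sites (default 19).
#' @param n_states number of visible states per site (default 21).
#' @param n_hidden number of dReLU hidden units.
#' @param g optional n_sites x n_states local potential matrix (default 0).
#' @param W optional (n_sites*n_states) x n_hidden weight matrix (default 0).
#' @param hidden optional list with numeric vectors gamma_plus, gamma_minus,
#'   theta_plus, theta_minus of length n_hidden (defaults: curvatures 1,
#'   thresholds 0).
#' @param alphabet visible-state symbols (default residues + gap).
#' @return An object of class `rbm_model`. `log_z` is unset until
#'   [log_partition()] is called.
#' @export
new_rbm <- function(n_sites = 19L, n_states = 21L, n_hidden = 10L,
                    g = NULL, W = NULL, hidden = NULL,
                    alphabet = AA_GAP_ALPHABET[seq_len(n_states)]) {
  g <- g %||% matrix(0, n_sites, n_states)
  W <- W %||% matrix(0, n_sites * n_states, n_hidden)
  hidden <- hidden %||% list(gamma_plus = rep(1, n_hidden),
                             gamma_minus = rep(1, n_hidden),
                             theta_plus = rep(0, n_hidden),
                             theta_minus = rep(0, n_hidden))
  stopifnot(nrow(g) == n_sites, ncol(g) == n_states,
            nrow(W) == n_sites * n_states, ncol(W) == n_hidden,
            all(hidden$gamma_plus > 0), all(hidden$gamma_minus > 0))
  structure(list(n_sites = as.integer(n_sites),
                 n_states = as.integer(n_states),
                 n_hidden = as.integer(n_hidden),
                 g = g, W = W, hidden = hidden, alphabet = alphabet,
                 log_z = NULL, version = 1L),
            class = "rbm_model")
}

#' @exportS3Method base::print
print.rbm_model <- function(x, ...) {
  cat(sprintf("rbm_model: %d sites x %d states, %d dReLU hidden units\n",
              x$n_sites, x$n_states, x$n_hidden))
  if (!is.null(x$log_z)) {
    cat(sprintf("  log Z = %.4f (%s, stderr %.4g)\n", x$log_z$value,
                x$log_z$method, x$log_z$stderr))
  }
  invisible(x)
}

# coerce input sequences to an integer state matrix for a model
.rbm_states <- function(model, seqs) {
  if (is.matrix(seqs) && is.numeric(seqs)) {
    S <- seqs
  } else if (inherits(seqs, "aligned_encoding")) {
    S <- matrix(apply(unclass(seqs), 1, which.max), nrow = 1)
  } else if (is.character(seqs)) {
    S <- seqs_to_index_matrix(seqs, model$n_sites)
  } else if (inherits(seqs, "cdr3_alignment")) {
    S <- seqs_to_index_matrix(seqs$aligned, model$n_sites)
  } else {
    stop("unsupported sequence input", call. = FALSE)
  }
  if (ncol(S) != model$n_sites) {
    stop(sprintf("shape mismatch: %d columns, model has %d sites",
                 ncol(S), model$n_sites), call. = FALSE)
  }
  if (max(S) > model$n_states) stop("state index exceeds model n_states",
                                    call. = FALSE)
  storage.mode(S) <- "integer"
  S
}

# visible linear indices for a state matrix: v = (site-1)*q + state
.visible_index <- function(S, q) {
  sweep(S, 2, (seq_len(ncol(S)) - 1L) * q, "+")
}

#' Input to the hidden units for one or more sequences
#'
#' I_mu(sigma) = sum_i w_{i,mu}(sigma_i), computed exactly.
#'
#' @param model an `rbm_model`.
#' @param seqs aligned sequences: character vector of gapped strings, an
#'   `aligned_encoding`, a `cdr3_alignment`, or an integer state matrix.
#' @return n x n_hidden matrix of hidden inputs.
#' @export
hidden_input <- function(model, seqs) {
  S <- .rbm_states(model, seqs)
  V <- .visible_index(S, model$n_states)
  n <- nrow(S)
  I <- matrix(0, n, model$n_hidden)
  for (i in seq_len(ncol(V))) {
    I <- I + model$W[V[, i], , drop = FALSE]
  }
  I
}

# ---- dReLU closed forms ------------------------------------------------

# log of the two half-Gaussian integrals and the mixture bookkeeping for a
# single hidden unit at inputs I (vectorized over I)
.drelu_parts <- function(gamma_plus, gamma_minus, theta_plus, theta_minus,
                         I) {
  sp <- 1 / sqrt(gamma_plus)
  sm <- 1 / sqrt(gamma_minus)
  mp <- (I - theta_plus) / gamma_plus
  mm <- (I - theta_minus) / gamma_minus
  zp <- mp / sp
  zm <- mm / sm
  log_zplus <- 0.5 * log(2 * pi) + log(sp) + 0.5 * zp^2 +
    stats::pnorm(zp, log.p = TRUE)
  log_zminus <- 0.5 * log(2 * pi) + log(sm) + 0.5 * zm^2 +
    stats::pnorm(-zm, log.p = TRUE)
  list(log_zplus = log_zplus, log_zminus = log_zminus,
       mp = mp, mm = mm, sp = sp, sm = sm, zp = zp, zm = zm)
}

#' Closed-form dReLU log-integral Gamma(I)
#'
#' Gamma(I) = log integral dh exp(-U(h) + h I) for the dReLU potential,
#' evaluated in the log domain via Gaussian tail probabilities; stable for
#' |I| well beyond 1e3.
#'
#' @param params list with scalars gamma_plus, gamma_minus, theta_plus,
#'   theta_minus (curvatures must be positive).
#' @param I numeric vector of hidden inputs.
#' @return Numeric vector Gamma(I).
#' @export
gamma_drelu <- function(params, I) {
  if (params$gamma_plus <= 0 || params$gamma_minus <= 0) {
    stop("curvatures gamma_plus and gamma_minus must be positive",
         call. = FALSE)
  }
  p <- .drelu_parts(params$gamma_plus, params$gamma_minus,
                    params$theta_plus, params$theta_minus, I)
  logaddexp(p$log_zplus, p$log_zminus)
}

# inverse Mills ratio phi(z)/Phi(z), stable in the far tail
.mills <- function(z) {
  exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
}

# Conditional moments of h | I for one hidden unit (vectorized over I):
# mixture weight of the positive branch, E[h^+], E[(h^+)^2] conditional on
# branch, same for the negative branch, plus E[h | I] and Gamma(I).
drelu_moments <- function(gamma_plus, gamma_minus, theta_plus, theta_minus,
                          I) {
  p <- .drelu_parts(gamma_plus, gamma_minus, theta_plus, theta_minus, I)
  gamma_v <- logaddexp(p$log_zplus, p$log_zminus)
  w_plus <- exp(p$log_zplus - gamma_v)
  w_minus <- exp(p$log_zminus - gamma_v)
  # positive branch: N(mp, sp^2) truncated to h > 0; lower bound z = -zp
  lam_p <- .mills(p$zp)            # phi(-zp)/Phi(zp) = phi(zp)/Phi(zp)
  e_p <- p$mp + p$sp * lam_p
  var_p <- p$sp^2 * (1 - p$zp * lam_p - lam_p^2)
  e2_p <- pmax(var_p, 0) + e_p^2
  # negative branch: N(mm, sm^2) truncated to h < 0; upper bound z = -zm
  lam_m <- .mills(-p$zm)
  e_m <- p$mm - p$sm * lam_m
  var_m <- p$sm^2 * (1 + p$zm * lam_m - lam_m^2)
  e2_m <- pmax(var_m, 0) + e_m^2
  list(gamma = gamma_v, w_plus = w_plus, w_minus = w_minus,
       e_plus = e_p, e2_plus = e2_p, e_minus = e_m, e2_minus = e2_m,
       mean = w_plus * e_p + w_minus * e_m,
       parts = p)
}

# matrix version of .drelu_parts: I is n x n_hidden, params vectors of
# length n_hidden broadcast over rows; one vectorized pnorm call per branch
.drelu_parts_mat <- function(hidden, I) {
  n <- nrow(I)
  rb <- function(v) rep(v, each = n)    # row-broadcast over the n rows
  sqp <- sqrt(hidden$gamma_plus)
  sqm <- sqrt(hidden$gamma_minus)
  mp <- (I - rb(hidden$theta_plus)) / rb(hidden$gamma_plus)
  mm <- (I - rb(hidden$theta_minus)) / rb(hidden$gamma_minus)
  zp <- mp * rb(sqp)
  zm <- mm * rb(sqm)
  plp <- stats::pnorm(zp, log.p = TRUE)
  plm <- stats::pnorm(-zm, log.p = TRUE)
  log_zplus <- 0.5 * zp^2 + plp + rb(0.5 * log(2 * pi) - log(sqp))
  log_zminus <- 0.5 * zm^2 + plm + rb(0.5 * log(2 * pi) - log(sqm))
  list(log_zplus = log_zplus, log_zminus = log_zminus, mp = mp, mm = mm,
       zp = zp, zm = zm, sp = 1 / sqp, sm = 1 / sqm, plp = plp, plm = plm,
       n = n)
}

# model-wide moments: I is n x n_hidden; returns matrices n x n_hidden
.rbm_hidden_moments <- function(model, I) {
  p <- .drelu_parts_mat(model$hidden, I)
  gamma_v <- logaddexp(p$log_zplus, p$log_zminus)
  w_plus <- exp(p$log_zplus - gamma_v)
  w_minus <- exp(p$log_zminus - gamma_v)
  rb <- function(v) rep(v, each = p$n)
  lam_p <- .mills(p$zp)
  e_p <- p$mp + lam_p * rb(p$sp)
  var_p <- (1 - p$zp * lam_p - lam_p^2) * rb(p$sp^2)
  e2_p <- pmax(var_p, 0) + e_p^2
  lam_m <- .mills(-p$zm)
  e_m <- p$mm - lam_m * rb(p$sm)
  var_m <- (1 + p$zm * lam_m - lam_m^2) * rb(p$sm^2)
  e2_m <- pmax(var_m, 0) + e_m^2
  list(gamma = gamma_v, mean = w_plus * e_p + w_minus * e_m,
       w_plus = w_plus, w_minus = w_minus,
       e_plus = e_p, e2_plus = e2_p, e_minus = e_m, e2_minus = e2_m,
       parts = p)
}

#' Unnormalized log-probability of aligned sequences under an RBM
#'
#' Returns sum_i g_i(sigma_i) + sum_mu Gamma_mu(I_mu(sigma)). The normalized
#' log-likelihood is `log_score - log_z` once [log_partition()] has been
#' evaluated.
#'
#' @inheritParams hidden_input
#' @return Numeric vector of unnormalized log-probabilities.
#' @export
log_score <- function(model, seqs) {
  S <- .rbm_states(model, seqs)
  V <- .visible_index(S, model$n_states)
  gv <- as.vector(t(model$g))       # g indexed by v = (site-1)*q + state
  gsum <- rowSums(matrix(gv[V], nrow = nrow(V)))
  I <- hidden_input(model, S)
  gam <- .rbm_hidden_moments(model, I)$gamma
  gsum + rowSums(gam)
}

#' Latent projection of sequences onto the hidden units
#'
#' Rows are sequences, columns the hidden inputs I_mu (Eq-4-style), the
#' model's low-dimensional representation space.
#'
#' @inheritParams hidden_input
#' @return n x n_hidden matrix.
#' @export
rbm_project <- function(model, seqs) hidden_input(model, seqs)

# enumerate all state matrices for small models (q^N rows)
.enumerate_states <- function(n_sites, n_states) {
  grid <- do.call(expand.grid, rep(list(seq_len(n_states)), n_sites))
  as.matrix(grid[, rev(seq_len(n_sites)), drop = FALSE])
}

#' Log partition function of an RBM
#'
#' `exact_enum` sums the unnormalized marginal over all q^N sequences
#' (guarded to q^N <= 1e7). `ais` runs annealed importance sampling from the
#' factorized model (W = 0, whose log Z is closed-form) to the full model,
#' scaling the weights by a temperature ladder; returns the estimate and a
#' bootstrap standard error over chains.
#'
#' @param model an `rbm_model`.
#' @param method "exact_enum" or "ais".
#' @param n_temps,n_chains AIS ladder length and number of chains.
#' @param seed integer seed for AIS.
#' @param cache if TRUE (default) returns the model with `log_z` set;
#'   otherwise returns the estimate list.
#' @return Model with `log_z = list(value, stderr, method)` (or that list).
#' @export
log_partition <- function(model, method = c("exact_enum", "ais"),
                          n_temps = 1000L, n_chains = 20L, seed = 1L,
                          cache = TRUE) {
  method <- match.arg(method)
  if (method == "exact_enum") {
    if (model$n_states^model$n_sites > 1e7) {
      stop("state space too large for exact enumeration", call. = FALSE)
    }
    S <- .enumerate_states(model$n_sites, model$n_states)
    est <- list(value = logsumexp(log_score(model, S)), stderr = 0,
                method = "exact_enum")
  } else {
    est <- .ais_log_z(model, n_temps = n_temps, n_chains = n_chains,
                      seed = seed)
  }
  if (cache) {
    model$log_z <- est
    model
  } else {
    est
  }
}

# log Z of the factorized model (W = 0): sites decouple and each hidden unit
# contributes Gamma_mu(0)
.log_z_independent <- function(model) {
  site_terms <- apply(model$g, 1, logsumexp)
  h <- model$hidden
  gamma0 <- vapply(seq_len(model$n_hidden), function(mu) {
    gamma_drelu(list(gamma_plus = h$gamma_plus[mu],
                     gamma_minus = h$gamma_minus[mu],
                     theta_plus = h$theta_plus[mu],
                     theta_minus = h$theta_minus[mu]), 0)
  }, 0)
  sum(site_terms) + sum(gamma0)
}

# sample visible states from the factorized model, n chains
.sample_independent <- function(model, n) {
  S <- matrix(0L, n, model$n_sites)
  for (i in seq_len(model$n_sites)) {
    p <- exp(model$g[i, ] - logsumexp(model$g[i, ]))
    S[, i] <- sample.int(model$n_states, n, replace = TRUE, prob = p)
  }
  S
}

# sample hidden units given inputs I (n x n_hidden): dReLU conditional is a
# two-sided truncated-Gaussian mixture, sampled by stable inverse CDF
.sample_hidden <- function(model, I) {
  mom <- .rbm_hidden_moments(model, I)
  p <- mom$parts
  n <- nrow(I)
  nh <- model$n_hidden
  pos <- stats::runif(n * nh) < mom$w_plus
  u <- stats::runif(n * nh)
  # positive branch: h = mp + sp*z with z in the upper tail of mass Phi(zp);
  # negative branch: h = mm + sm*z with z in the lower tail of mass Phi(-zm)
  zpos <- -stats::qnorm(pmax(u * exp(p$plp), 1e-300))
  zneg <- stats::qnorm(pmax(u * exp(p$plm), 1e-300))
  hp <- pmax(p$mp + zpos * rep(p$sp, each = n), 0)
  hm <- pmin(p$mm + zneg * rep(p$sm, each = n), 0)
  H <- hm
  H[pos] <- hp[pos]
  H
}

# sample visible states given hidden values H (n x n_hidden) with weights
# scaled by beta; Gumbel-max over the q states per site
.sample_visible <- function(model, H, beta = 1) {
  n <- nrow(H)
  q <- model$n_states
  logits <- tcrossprod(H, model$W) * beta            # n x (sites*q)
  logits <- logits + rep(as.vector(t(model$g)), each = n)
  # Gumbel-max categorical sampling per site, one noise draw for everything
  logits <- logits - log(-log(stats::runif(n * model$n_sites * q)))
  S <- matrix(0L, n, model$n_sites)
  for (i in seq_len(model$n_sites)) {
    S[, i] <- max.col(logits[, (i - 1L) * q + seq_len(q), drop = FALSE],
                      ties.method = "first")
  }
  S
}

# one Gibbs sweep at inverse temperature beta (scales W only)
.gibbs_sweep <- function(model, S, beta = 1) {
  V <- .visible_index(S, model$n_states)
  I <- matrix(0, nrow(S), model$n_hidden)
  for (i in seq_len(ncol(V))) I <- I + model$W[V[, i], , drop = FALSE]
  H <- .sample_hidden_beta(model, I * beta)
  .sample_visible(model, H, beta = beta)
}

# hidden sampling helper shared by AIS (weights scaled by beta enter via I)
.sample_hidden_beta <- function(model, I) .sample_hidden(model, I)

# unnormalized log p at inverse temperature beta: g + sum Gamma(beta * I)
.log_score_beta <- function(model, S, beta) {
  V <- .visible_index(S, model$n_states)
  gv <- as.vector(t(model$g))
  gsum <- rowSums(matrix(gv[V], nrow = nrow(V)))
  I <- matrix(0, nrow(S), model$n_hidden)
  for (i in seq_len(ncol(V))) I <- I + model$W[V[, i], , drop = FALSE]
  gam <- .rbm_hidden_moments(model, I * beta)$gamma
  gsum + rowSums(gam)
}

.ais_log_z <- function(model, n_temps = 1000L, n_chains = 20L, seed = 1L) {
  set.seed(seed)
  betas <- seq(0, 1, length.out = n_temps + 1L)
  S <- .sample_independent(model, n_chains)
  logw <- numeric(n_chains)
  for (k in seq_len(n_temps)) {
    b_prev <- betas[k]
    b_next <- betas[k + 1L]
    logw <- logw + .log_score_beta(model, S, b_next) -
      .log_score_beta(model, S, b_prev)
    S <- .gibbs_sweep(model, S, beta = b_next)
  }
  log_z0 <- .log_z_independent(model)
  est <- log_z0 + logsumexp(logw) - log(n_chains)
  boot <- vapply(seq_len(200), function(b) {
    idx <- sample.int(n_chains, n_chains, replace = TRUE)
    log_z0 + logsumexp(logw[idx]) - log(n_chains)
  }, 0)
  list(value = est, stderr = stats::sd(boot), method = "ais",
       n_temps = n_temps, n_chains = n_chains)
}

#' Model single-site and pairwise moments by Rao-Blackwellized Gibbs
#'
#' Runs Gibbs chains and averages the conditional visible probabilities
#' p(sigma_i = a | h) instead of the sampled states: given the hidden
#' values the sites are independent, so single-site moments are the mean of
#' the conditional probabilities and pairwise moments the mean of their
#' outer products — a much lower-variance estimator than empirical counts
#' on the sampled sequences.
#'
#' @param model an `rbm_model`.
#' @param n_samples number of Gibbs chains (default 5000).
#' @param gibbs_steps burn-in sweeps per chain (default 100).
#' @param seed integer seed.
#' @return list(f = visible marginal vector of length n_sites*n_states,
#'   ff = second-moment matrix, cc = connected correlations ff - f f^T).
#' @export
rbm_model_moments <- function(model, n_samples = 5000L, gibbs_steps = 100L,
                              seed = 1L) {
  set.seed(seed)
  S <- .sample_independent(model, n_samples)
  for (k in seq_len(gibbs_steps)) S <- .gibbs_sweep(model, S, beta = 1)
  # one more hidden draw, then use conditional visible probabilities
  V <- .visible_index(S, model$n_states)
  I <- matrix(0, n_samples, model$n_hidden)
  for (i in seq_len(ncol(V))) I <- I + model$W[V[, i], , drop = FALSE]
  H <- .sample_hidden(model, I)
  logits <- tcrossprod(H, model$W) +
    rep(as.vector(t(model$g)), each = n_samples)
  q <- model$n_states
  P <- matrix(0, n_samples, model$n_sites * q)
  for (i in seq_len(model$n_sites)) {
    cols <- (i - 1L) * q + seq_len(q)
    block <- logits[, cols, drop = FALSE]
    block <- exp(block - apply(block, 1, max))
    P[, cols] <- block / rowSums(block)
  }
  f <- colMeans(P)
  ff <- crossprod(P) / n_samples
  # same-site blocks: E[1_ia 1_ib] = delta_ab E[p_ia] exactly
  for (i in seq_len(model$n_sites)) {
    cols <- (i - 1L) * q + seq_len(q)
    ff[cols, cols] <- diag(f[cols], nrow = q)
  }
  list(f = f, ff = ff, cc = ff - tcrossprod(f))
}

#' Sample sequences from an RBM by Gibbs sampling
#'
#' Chains start from the factorized (W = 0) model and alternate the
#' categorical visible conditional with the dReLU hidden conditional.
#'
#' @param model an `rbm_model`.
#' @param n number of sequences.
#' @param gibbs_steps sweeps per chain (default 100).
#' @param seed integer seed (reproducible).
#' @param as_strings return gapped strings (default) or a state matrix.
#' @return Character vector (or integer matrix) of n sampled sequences.
#' @export
sample_rbm <- function(model, n, gibbs_steps = 100L, seed = 1L,
                       as_strings = TRUE) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  S <- .sample_independent(model, n)
  for (k in seq_len(gibbs_steps)) S <- .gibbs_sweep(model, S, beta = 1)
  if (!as_strings) return(S)
  vapply(seq_len(n), function(r) {
    paste(model$alphabet[S[r, ]], collapse = "")
  }, "")
}

# ---- training ----------------------------------------------------------

# gradient of the L1^2 penalty  lambda1^2/(2 q N) * sum_mu (sum_v |w_v,mu|)^2
.l1sq_gradient <- function(W, l1sq, n_sites, n_states) {
  colnorm <- colSums(abs(W))
  sweep(sign(W), 2, l1sq / (n_states * n_sites) * colnorm, "*")
}

.l1sq_penalty <- function(W, l1sq, n_sites, n_states) {
  l1sq / (2 * n_states * n_sites) * sum(colSums(abs(W))^2)
}

# sufficient statistics of a batch: visible one-hot means and
# cross-moments <onehot * E[h|I]>; X sparse n x (sites*q)
.rbm_data_stats <- function(model, X, weights = NULL) {
  n <- nrow(X)
  w <- weights %||% rep(1, n)
  w <- w / sum(w)
  I <- as.matrix(X %*% model$W)
  mom <- .rbm_hidden_moments(model, I)
  list(v_mean = as.numeric(Matrix::crossprod(X, w)),
       vh_mean = as.matrix(Matrix::crossprod(X, mom$mean * w)),
       hplus_mean = colSums(mom$w_plus * mom$e_plus * w),
       hminus_mean = colSums(mom$w_minus * mom$e_minus * w),
       h2plus_mean = colSums(mom$w_plus * mom$e2_plus * w),
       h2minus_mean = colSums(mom$w_minus * mom$e2_minus * w))
}

#' Train a dReLU RBM on a count-weighted aligned dataset
#'
#' Maximizes the weighted average log-likelihood penalized by the squared-L1
#' weight regularizer (strength `l1sq`, scaled by 2 q N as in the model
#' definition) using persistent contrastive divergence: the data term uses
#' exact conditional hidden moments; the model term is estimated from
#' persistent Gibbs chains. Minibatches are drawn with probability
#' proportional to sequence weight, which is equivalent to replicating
#' sequences by their multiplicity. Plain SGD with a step-decayed learning
#' rate; hidden curvatures are optimized as log(gamma) for positivity.
#'
#' @param data a `count_weighted` dataset of aligned strings (all the same
#'   width), or a list(sequences, weights).
#' @param n_hidden hidden units (default 25, the count-weighted default;
#'   use 10 for responding-only datasets).
#' @param l1sq regularization strength lambda_1^2 (default 0.1).
#' @param epochs,batch_size,learning_rate,n_chains,gibbs_steps training
#'   schedule (defaults 200, 128, 5e-3, 100, 10); the learning rate is
#'   halved after each third of the epochs.
#' @param seed integer seed; training is deterministic given the seed.
#' @param n_states visible states (default 21).
#' @param init_model optional `rbm_model` to continue training from (shapes
#'   must match); used for staged schedules.
#' @param verbose print progress every 10 epochs.
#' @return A trained `rbm_model` with a `training_log` data.frame attached
#'   (epoch, weighted pseudo-objective proxy, mean |W|).
#' @export
train_rbm <- function(data, n_hidden = 25L, l1sq = 0.1, epochs = 200L,
                      batch_size = 128L, learning_rate = 5e-3,
                      n_chains = 100L, gibbs_steps = 10L, seed = 1L,
                      n_states = 21L, init_model = NULL, verbose = FALSE) {
  if (n_hidden < 1 || l1sq < 0 || epochs < 1 || batch_size < 1 ||
      learning_rate <= 0 || n_chains < 1 || gibbs_steps < 1) {
    stop("non-positive training hyperparameter", call. = FALSE)
  }
  seqs <- data$sequences
  weights <- data$weights %||% rep(1, length(seqs))
  if (length(seqs) == 0) stop("empty training data", call. = FALSE)
  width <- nchar(seqs[1])
  S <- seqs_to_index_matrix(seqs, width)
  X <- aligned_onehot_sparse(S, n_states)
  n <- nrow(S)
  set.seed(seed)

  # init: g at smoothed weighted empirical frequencies, small random W
  wnorm <- weights / sum(weights)
  vfreq <- as.numeric(Matrix::crossprod(X, wnorm))
  if (is.null(init_model)) {
    gmat <- matrix(log(vfreq + 1e-4), nrow = width, ncol = n_states,
                   byrow = TRUE)
    gmat <- gmat - apply(gmat, 1, logsumexp)
    model <- new_rbm(n_sites = width, n_states = n_states,
                     n_hidden = n_hidden, g = gmat,
                     W = matrix(stats::rnorm(width * n_states * n_hidden,
                                             sd = 0.01),
                                width * n_states, n_hidden))
  } else {
    stopifnot(init_model$n_sites == width,
              init_model$n_states == n_states,
              init_model$n_hidden == n_hidden)
    model <- init_model
    model$log_z <- NULL
  }
  chains <- .sample_independent(model, n_chains)
  log_theta_lr_scale <- 0.1   # slower updates for hidden potentials
  n_batches <- max(1L, ceiling(n / batch_size))
  log_rows <- list()
  lr <- learning_rate
  for (epoch in seq_len(epochs)) {
    if (epochs >= 3 && epoch %in% (1L + round(epochs * c(1, 2) / 3))) {
      lr <- lr * 0.5
    }
    for (b in seq_len(n_batches)) {
      idx <- sample.int(n, min(batch_size, n), replace = TRUE,
                        prob = weights)
      ds <- .rbm_data_stats(model, X[idx, , drop = FALSE])
      for (k in seq_len(gibbs_steps)) {
        chains <- .gibbs_sweep(model, chains, beta = 1)
      }
      Xc <- aligned_onehot_sparse(chains, n_states)
      ms <- .rbm_data_stats(model, Xc)
      # parameter updates (gradient ascent on penalized likelihood)
      grad_g <- matrix(ds$v_mean - ms$v_mean, nrow = width,
                       ncol = n_states, byrow = TRUE)
      grad_W <- (ds$vh_mean - ms$vh_mean) -
        .l1sq_gradient(model$W, l1sq, width, n_states)
      grad_theta_p <- -(ds$hplus_mean - ms$hplus_mean)
      grad_theta_m <- -(ds$hminus_mean - ms$hminus_mean)
      grad_log_gp <- -0.5 * (ds$h2plus_mean - ms$h2plus_mean) *
        model$hidden$gamma_plus
      grad_log_gm <- -0.5 * (ds$h2minus_mean - ms$h2minus_mean) *
        model$hidden$gamma_minus
      if (any(!is.finite(grad_W)) || any(!is.finite(grad_g))) {
        stop(sprintf("NaN in gradients at epoch %d; reduce learning rate",
                     epoch), call. = FALSE)
      }
      model$g <- model$g + lr * grad_g
      model$W <- model$W + lr * grad_W
      hlr <- lr * log_theta_lr_scale
      model$hidden$theta_plus <- model$hidden$theta_plus + hlr * grad_theta_p
      model$hidden$theta_minus <- model$hidden$theta_minus +
        hlr * grad_theta_m
      model$hidden$gamma_plus <- exp(pmin(pmax(
        log(model$hidden$gamma_plus) + hlr * grad_log_gp, -4), 4))
      model$hidden$gamma_minus <- exp(pmin(pmax(
        log(model$hidden$gamma_minus) + hlr * grad_log_gm, -4), 4))
    }
    if (epoch %% 10L == 0L || epoch == epochs) {
      proxy <- sum(log_score(model, S) * wnorm)
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(epoch = epoch, score_proxy = proxy,
                   mean_abs_w = mean(abs(model$W)))
      if (verbose) {
        message(sprintf("epoch %d: score proxy %.4f, mean|W| %.4f",
                        epoch, proxy, mean(abs(model$W))))
      }
    }
  }
  model$training_log <- do.call(rbind, log_rows)
  model$l1sq <- l1sq
  model$seed <- seed
  model
}

# ---- exact-gradient machinery (small models; used by tests) -----------

# penalized weighted mean log-likelihood with exact log Z
rbm_exact_objective <- function(model, S, weights = NULL) {
  w <- weights %||% rep(1, nrow(S))
  w <- w / sum(w)
  lz <- log_partition(model, "exact_enum", cache = FALSE)$value
  sum(log_score(model, S) * w) - lz -
    .l1sq_penalty(model$W, model$l1sq %||% 0, model$n_sites, model$n_states)
}

# analytic gradient of rbm_exact_objective in a flat parameter vector,
# ordered (g, W, theta_plus, theta_minus, log_gamma_plus, log_gamma_minus)
rbm_exact_gradient <- function(model, S, weights = NULL) {
  w <- weights %||% rep(1, nrow(S))
  w <- w / sum(w)
  X <- aligned_onehot_sparse(.rbm_states(model, S), model$n_states)
  ds <- .rbm_data_stats(model, X, w)
  Sall <- .enumerate_states(model$n_sites, model$n_states)
  lz <- log_partition(model, "exact_enum", cache = FALSE)$value
  p <- exp(log_score(model, Sall) - lz)
  Xall <- aligned_onehot_sparse(Sall, model$n_states)
  ms <- .rbm_data_stats(model, Xall, p)
  grad_g <- ds$v_mean - ms$v_mean
  grad_W <- (ds$vh_mean - ms$vh_mean) -
    .l1sq_gradient(model$W, model$l1sq %||% 0, model$n_sites,
                   model$n_states)
  c(grad_g, as.numeric(grad_W),
    -(ds$hplus_mean - ms$hplus_mean),
    -(ds$hminus_mean - ms$hminus_mean),
    -0.5 * (ds$h2plus_mean - ms$h2plus_mean) * model$hidden$gamma_plus,
    -0.5 * (ds$h2minus_mean - ms$h2minus_mean) * model$hidden$gamma_minus)
}

# pack/unpack the flat parameter vector used by the gradient check
rbm_get_params <- function(model) {
  c(.flat_g(model),
    as.numeric(model$W),
    model$hidden$theta_plus, model$hidden$theta_minus,
    log(model$hidden$gamma_plus), log(model$hidden$gamma_minus))
}

.flat_g <- function(model) as.numeric(t(model$g))

rbm_set_params <- function(model, par) {
  nv <- model$n_sites * model$n_states
  nw <- nv * model$n_hidden
  nh <- model$n_hidden
  model$g <- matrix(par[seq_len(nv)], nrow = model$n_sites,
                    ncol = model$n_states, byrow = TRUE)
  model$W <- matrix(par[nv + seq_len(nw)], nrow = nv, ncol = nh)
  o <- nv + nw
  model$hidden$theta_plus <- par[o + seq_len(nh)]
  model$hidden$theta_minus <- par[o + nh + seq_len(nh)]
  model$hidden$gamma_plus <- exp(par[o + 2 * nh + seq_len(nh)])
  model$hidden$gamma_minus <- exp(par[o + 3 * nh + seq_len(nh)])
  model
}

# ---- persistence and exports ------------------------------------------

#' Write / read an RBM model (JSON archive)
#'
#' Lossless round-trip of all parameter arrays plus metadata (shapes,
#' alphabet, regularization, seed, cached log Z).
#'
#' @param model an `rbm_model`.
#' @param path file path.
#' @return `path` invisibly; `read_rbm` returns the model.
#' @export
write_rbm <- function(model, path) {
  obj <- list(format = "tcrboltz_rbm", version = model$version %||% 1L,
              n_sites = model$n_sites, n_states = model$n_states,
              n_hidden = model$n_hidden, alphabet = model$alphabet,
              g = model$g, W = model$W, hidden = model$hidden,
              log_z = model$log_z, l1sq = model$l1sq, seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_rbm
#' @export
read_rbm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "tcrboltz_rbm")) {
    stop("not a tcrboltz RBM archive: ", path, call. = FALSE)
  }
  if (obj$version > 1L) stop("unsupported RBM archive version ", obj$version,
                             call. = FALSE)
  m <- new_rbm(n_sites = obj$n_sites, n_states = obj$n_states,
               n_hidden = obj$n_hidden,
               g = matrix(obj$g, obj$n_sites, obj$n_states),
               W = matrix(obj$W, obj$n_sites * obj$n_states, obj$n_hidden),
               hidden = lapply(obj$hidden, as.numeric),
               alphabet = obj$alphabet)
  if (!is.null(obj$log_z)) m$log_z <- obj$log_z
  m$l1sq <- obj$l1sq
  m$seed <- obj$seed
  m
}

#' PWM-style export of the local potentials exp(g)
#'
#' Normalized exp(g) per site (columns sum to 1 over the states), the
#' logo representation of the single-site biases; plus the weights per
#' hidden unit for weight-logo display.
#'
#' @param model an `rbm_model`.
#' @return list(pwm = n_sites x n_states matrix with rows summing to 1,
#'   weights = list of n_sites x n_states matrices, one per hidden unit).
#' @export
export_rbm_logos <- function(model) {
  pwm <- exp(model$g - apply(model$g, 1, logsumexp))
  dimnames(pwm) <- list(NULL, model$alphabet)
  weights <- lapply(seq_len(model$n_hidden), function(mu) {
    matrix(model$W[, mu], nrow = model$n_sites, ncol = model$n_states,
           byrow = TRUE, dimnames = list(NULL, model$alphabet))
  })
  list(pwm = pwm, weights = weights)
}
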