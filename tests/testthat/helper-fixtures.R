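# Shared fixtures: tiny toy models and anchored sequence sets built in code.

# a small random dReLU RBM for exactness checks (q = 2, 3 sites, 1-2 hidden)
toy_rbm <- function(n_sites = 3L, n_states = 2L, n_hidden = 1L, seed = 7L,
                    l1sq = 0) {
  set.seed(seed)
  m <- new_rbm(n_sites = n_sites, n_states = n_states, n_hidden = n_hidden,
               g = matrix(stats::rnorm(n_sites * n_states, sd = 0.6),
                          n_sites, n_states),
               W = matrix(stats::rnorm(n_sites * n_states * n_hidden,
                                       sd = 0.7),
                          n_sites * n_states, n_hidden),
               hidden = list(
                 gamma_plus = stats::runif(n_hidden, 0.6, 1.8),
                 gamma_minus = stats::runif(n_hidden, 0.6, 1.8),
                 theta_plus = stats::rnorm(n_hidden, sd = 0.4),
                 theta_minus = stats::rnorm(n_hidden, sd = 0.4)))
  m$l1sq <- l1sq
  m
}

# anchored toy CDR3 set with a conserved core and mixed lengths
anchored_toy_set <- function(n_per_len = 30L, lengths = 12:16, seed = 3L) {
  set.seed(seed)
  unlist(lapply(lengths, function(l) {
    vapply(seq_len(n_per_len), function(k) {
      mid <- paste(sample(c("A", "S", "G", "L", "R", "Q", "T"), l - 4,
                          replace = TRUE), collapse = "")
      paste0("CAS", mid, if (k %% 2 == 0) "F" else "V")
    }, "")
  }))
}

# quadrature oracle for the dReLU integral: the two half-lines are
# integrated separately with mode-centered scaling, then log-added
gamma_drelu_quadrature <- function(params, I) {
  expo_pos <- function(h) -0.5 * params$gamma_plus * h^2 +
    (I - params$theta_plus) * h
  expo_neg <- function(h) -0.5 * params$gamma_minus * h^2 +
    (I - params$theta_minus) * h
  half <- function(expo, sgn, gamma) {
    s <- 1 / sqrt(gamma)
    opt <- stats::optimize(function(h) expo(sgn * h), c(0, 1e4),
                           maximum = TRUE)
    m <- opt$objective
    v <- stats::integrate(function(h) exp(expo(sgn * h) - m), 0, Inf,
                          rel.tol = 1e-13, abs.tol = 0)$value
    log(v) + m
  }
  lp <- half(expo_pos, 1, params$gamma_plus)
  lm <- half(expo_neg, -1, params$gamma_minus)
  mx <- max(lp, lm)
  mx + log(exp(lp - mx) + exp(lm - mx))
}

logsumexp_test <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# replicate-null AUROC of a pure PWM (independent-site frequency) score:
# the reference statistic for the finite-size memorization bias analysis
pwm_replicate_null <- function(n_clones, depth, seed) {
  cfg <- sim_config(n_clones = n_clones, depth = depth)
  clones <- generate_repertoire(cfg, seed = seed + 1)
  day0 <- simulate_counts(clones, rep(1, n_clones), depth,
                          seed = seed + 2)$day0
  reps <- make_replicates(day0, seed = seed + 3)
  ali <- align_all(day0$cdr3)
  S <- tcrboltz:::seqs_to_index_matrix(ali$aligned, 19)
  X <- tcrboltz:::aligned_onehot_sparse(S, 21)
  n1 <- reps$rep1$count[match(day0$cdr3, reps$rep1$cdr3)]
  n2 <- reps$rep2$count[match(day0$cdr3, reps$rep2$cdr3)]
  n1[is.na(n1)] <- 0
  n2[is.na(n2)] <- 0
  f1 <- as.numeric(Matrix::crossprod(X, n1 / sum(n1))) + 1e-6
  f2 <- as.numeric(Matrix::crossprod(X, n2 / sum(n2))) + 1e-6
  s <- as.numeric(X %*% (log(f1) - log(f2)))
  keep <- n1 != n2
  specificity_auroc(s[keep], (n1 > n2)[keep])$auroc
}

# small simulated experiment used by several tests
small_experiment <- function(seed = 11L, n_clones = 400L, depth = 2e4,
                             antigens = NULL) {
  cfg <- if (is.null(antigens)) {
    sim_config(n_clones = n_clones, depth = depth)
  } else {
    sim_config(n_clones = n_clones, depth = depth, antigens = antigens)
  }
  simulate_experiment(cfg, seed = seed)
}
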