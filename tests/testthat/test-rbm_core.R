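# dReLU RBM: closed forms, exact normalization, partition function,
# training gradients, sampling, projection, persistence.

test_that("hidden_input matches the brute-force site loop", {
  m <- toy_rbm(n_sites = 4, n_states = 3, n_hidden = 2, seed = 2)
  S <- tcrboltz:::.enumerate_states(4, 3)
  I <- hidden_input(m, S)
  brute <- t(vapply(seq_len(nrow(S)), function(r) {
    vapply(seq_len(2), function(mu) {
      sum(vapply(1:4, function(i) m$W[(i - 1) * 3 + S[r, i], mu], 0))
    }, 0)
  }, numeric(2)))
  expect_equal(I, brute, tolerance = 1e-12)

  # zero weights -> zero inputs; single targeted weight
  m0 <- new_rbm(n_sites = 3, n_states = 21, n_hidden = 2)
  expect_true(all(hidden_input(m0, "CAF") == 0))
  m0$W[(1 - 1) * 21 + match("C", AA_GAP_ALPHABET), 1] <- 2
  expect_equal(hidden_input(m0, "CAF")[1, ], c(2, 0))
  expect_error(hidden_input(m0, "CASSF"), "width|shape|sites")
})

test_that("gamma_drelu matches quadrature to 1e-8 relative and closed forms", {
  # symmetric quadratic case: Gamma(I) = I^2/(2 gamma) + log(2 pi / gamma)/2
  for (g in c(0.5, 1, 2.5)) {
    p <- list(gamma_plus = g, gamma_minus = g, theta_plus = 0,
              theta_minus = 0)
    for (I in c(-3, 0, 1.2)) {
      expect_equal(gamma_drelu(p, I), I^2 / (2 * g) + 0.5 * log(2 * pi / g),
                   tolerance = 1e-12)
    }
  }
  expect_equal(gamma_drelu(list(gamma_plus = 1, gamma_minus = 1,
                                theta_plus = 0, theta_minus = 0), 0),
               0.5 * log(2 * pi), tolerance = 1e-14)

  # arbitrary parameters vs adaptive quadrature around the mode
  set.seed(5)
  for (k in 1:20) {
    p <- list(gamma_plus = stats::runif(1, 0.2, 3),
              gamma_minus = stats::runif(1, 0.2, 3),
              theta_plus = stats::rnorm(1, sd = 1.5),
              theta_minus = stats::rnorm(1, sd = 1.5))
    I <- stats::rnorm(1, sd = 20)
    expect_equal(gamma_drelu(p, I), gamma_drelu_quadrature(p, I),
                 tolerance = 1e-8)
  }
  # stability far out
  pbig <- list(gamma_plus = 1, gamma_minus = 1, theta_plus = 0.5,
               theta_minus = -0.5)
  expect_true(is.finite(gamma_drelu(pbig, 1e3)))
  expect_true(is.finite(gamma_drelu(pbig, -1e3)))
  expect_error(gamma_drelu(list(gamma_plus = -1, gamma_minus = 1,
                                theta_plus = 0, theta_minus = 0), 0),
               "positive")
})

test_that("normalized likelihood matches exact enumeration on toy models", {
  m <- toy_rbm(n_sites = 3, n_states = 2, n_hidden = 1, seed = 7)
  m <- log_partition(m, "exact_enum")
  S <- tcrboltz:::.enumerate_states(3, 2)
  probs <- exp(log_score(m, S) - m$log_z$value)
  expect_equal(sum(probs), 1, tolerance = 1e-10)

  # brute-force oracle: P(sigma) via 1-D quadrature of the joint over h
  joint_prob <- function(model, s_row) {
    gsum <- sum(vapply(1:3, function(i) model$g[i, s_row[i]], 0))
    I <- sum(vapply(1:3, function(i) {
      model$W[(i - 1) * 2 + s_row[i], 1]
    }, 0))
    h <- model$hidden
    p <- list(gamma_plus = h$gamma_plus, gamma_minus = h$gamma_minus,
              theta_plus = h$theta_plus, theta_minus = h$theta_minus)
    gsum + gamma_drelu_quadrature(p, I)
  }
  brute <- vapply(seq_len(nrow(S)), function(r) joint_prob(m, S[r, ]), 0)
  brute <- exp(brute - logsumexp_test(brute))
  expect_equal(probs, brute, tolerance = 1e-8)

  # zero-weight model: log_score decomposes over sites and Gamma(0)
  m0 <- toy_rbm(n_sites = 3, n_states = 2, n_hidden = 2, seed = 3)
  m0$W[] <- 0
  gamma0 <- sum(vapply(1:2, function(mu) {
    gamma_drelu(list(gamma_plus = m0$hidden$gamma_plus[mu],
                     gamma_minus = m0$hidden$gamma_minus[mu],
                     theta_plus = m0$hidden$theta_plus[mu],
                     theta_minus = m0$hidden$theta_minus[mu]), 0)
  }, 0))
  s <- c(1L, 2L, 1L)
  expect_equal(log_score(m0, matrix(s, 1)),
               m0$g[1, 1] + m0$g[2, 2] + m0$g[3, 1] + gamma0,
               tolerance = 1e-12)
  # one-site difference = difference of g entries when W = 0
  s2 <- c(2L, 2L, 1L)
  expect_equal(log_score(m0, matrix(s2, 1)) - log_score(m0, matrix(s, 1)),
               m0$g[1, 2] - m0$g[1, 1], tolerance = 1e-12)
})

test_that("log_partition: factorized closed form and AIS agreement", {
  m0 <- toy_rbm(n_sites = 3, n_states = 2, n_hidden = 2, seed = 13)
  m0$W[] <- 0
  closed <- sum(apply(m0$g, 1, logsumexp_test)) +
    sum(vapply(1:2, function(mu) {
      gamma_drelu(list(gamma_plus = m0$hidden$gamma_plus[mu],
                       gamma_minus = m0$hidden$gamma_minus[mu],
                       theta_plus = m0$hidden$theta_plus[mu],
                       theta_minus = m0$hidden$theta_minus[mu]), 0)
    }, 0))
  expect_equal(log_partition(m0, "exact_enum", cache = FALSE)$value, closed,
               tolerance = 1e-10)
  ais0 <- log_partition(m0, "ais", n_temps = 50, n_chains = 10, seed = 2,
                        cache = FALSE)
  expect_equal(ais0$value, closed, tolerance = 1e-6)   # W = 0: no annealing

  # full toy model: AIS within 3 stderr of enumeration, variance shrinks
  m <- toy_rbm(n_sites = 3, n_states = 2, n_hidden = 1, seed = 7)
  exact <- log_partition(m, "exact_enum", cache = FALSE)$value
  a1 <- log_partition(m, "ais", n_temps = 100, n_chains = 30, seed = 5,
                      cache = FALSE)
  expect_lt(abs(a1$value - exact), 3 * max(a1$stderr, 0.02))
  reps <- function(n_temps) {
    vapply(1:6, function(s) {
      log_partition(m, "ais", n_temps = n_temps, n_chains = 10, seed = s,
                    cache = FALSE)$value
    }, 0)
  }
  expect_lt(stats::sd(reps(200)), stats::sd(reps(10)) + 0.05)
  expect_error(log_partition(new_rbm(19, 21, 1), "exact_enum"),
               "too large")
})

test_that("analytic gradient matches finite differences to 1e-5 relative", {
  m <- toy_rbm(n_sites = 3, n_states = 2, n_hidden = 2, seed = 11,
               l1sq = 0.1)
  set.seed(31)
  S <- matrix(sample(1:2, 18, replace = TRUE), 6, 3)
  w <- c(3, 1, 2, 1, 1, 4)
  g_an <- tcrboltz:::rbm_exact_gradient(m, S, w)
  par0 <- tcrboltz:::rbm_get_params(m)
  obj <- function(p) {
    tcrboltz:::rbm_exact_objective(tcrboltz:::rbm_set_params(m, p), S, w)
  }
  h <- 1e-5
  g_fd <- vapply(seq_along(par0), function(k) {
    e <- par0
    e[k] <- e[k] + h
    up <- obj(e)
    e[k] <- par0[k] - h
    (up - obj(e)) / (2 * h)
  }, 0)
  expect_lt(max(abs(g_an - g_fd) / pmax(abs(g_fd), 1e-4)), 1e-5)
})

test_that("training is seeded-deterministic and regularization is monotone", {
  set.seed(42)
  seqs <- sample_rbm(toy_rbm(6, 4, 2, seed = 1), 150, gibbs_steps = 20,
                     seed = 3)
  data <- list(sequences = seqs, weights = rep(1, length(seqs)))
  m1 <- train_rbm(data, n_hidden = 3, epochs = 8, seed = 5, n_states = 4)
  m2 <- train_rbm(data, n_hidden = 3, epochs = 8, seed = 5, n_states = 4)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$g, m2$g)

  norms <- vapply(c(0.01, 0.1, 1.0), function(l1) {
    mt <- train_rbm(data, n_hidden = 3, l1sq = l1, epochs = 15, seed = 5,
                    n_states = 4, learning_rate = 0.02)
    sum(abs(mt$W))
  }, 0)
  expect_true(all(diff(norms) <= 1e-8))
  expect_error(train_rbm(data, n_hidden = 0), "hyperparameter")
})

test_that("sampling: factorized frequencies, determinism, motif enrichment", {
  # W = 0 model: sampled single-site frequencies converge to softmax(g)
  g <- matrix(c(1.5, 0, 0, 0, 0, 1), 2, 3, byrow = TRUE)
  m0 <- new_rbm(n_sites = 2, n_states = 3, n_hidden = 1, g = g,
                W = matrix(0, 6, 1))
  s <- sample_rbm(m0, 8000, gibbs_steps = 3, seed = 4, as_strings = FALSE)
  emp <- tabulate(s[, 1], 3) / 8000
  theo <- exp(g[1, ]) / sum(exp(g[1, ]))
  expect_lt(max(abs(emp - theo)), 4 * sqrt(max(theo * (1 - theo) / 8000)) +
              0.01)

  expect_identical(sample_rbm(m0, 50, gibbs_steps = 5, seed = 9),
                   sample_rbm(m0, 50, gibbs_steps = 5, seed = 9))

  # planted-motif enrichment: train on data where half the sequences carry
  # a 3-residue motif; model samples must be enriched >= 5x over a
  # background model trained on motif-free data
  set.seed(8)
  base <- anchored_toy_set(n_per_len = 120, lengths = c(12, 12), seed = 14)
  motif <- base
  pick <- seq_len(length(base) / 2)
  for (k in pick) {
    s <- strsplit(motif[k], "")[[1]]
    s[4:6] <- c("W", "W", "W")
    motif[k] <- paste(s, collapse = "")
  }
  ali_m <- align_all(motif, n_match = 12)
  ali_b <- align_all(base, n_match = 12)
  dm <- list(sequences = ali_m$aligned, weights = rep(1, length(motif)))
  db <- list(sequences = ali_b$aligned, weights = rep(1, length(base)))
  mm <- train_rbm(dm, n_hidden = 3, epochs = 60, seed = 2,
                  learning_rate = 0.02)
  mb <- train_rbm(db, n_hidden = 3, epochs = 60, seed = 2,
                  learning_rate = 0.02)
  has_motif <- function(x) grepl("WWW", gsub("-", "", x), fixed = TRUE)
  fm <- mean(has_motif(sample_rbm(mm, 1500, gibbs_steps = 30, seed = 6)))
  fb <- mean(has_motif(sample_rbm(mb, 1500, gibbs_steps = 30, seed = 6)))
  expect_gte(fm, 5 * max(fb, 1 / 1500))
})

test_that("projection stacks hidden inputs and separates planted groups", {
  m <- toy_rbm(4, 3, 2, seed = 9)
  S <- tcrboltz:::.enumerate_states(4, 3)
  P <- rbm_project(m, S)
  expect_equal(P, hidden_input(m, S))
  m$W[] <- 0
  expect_true(all(rbm_project(m, S) == 0))

  # two disjoint motif groups separate in the top-weight coordinates
  set.seed(10)
  grp <- anchored_toy_set(n_per_len = 100, lengths = c(12, 12), seed = 15)
  labels <- rep(c(TRUE, FALSE), each = length(grp) / 2)
  for (k in seq_along(grp)) {
    s <- strsplit(grp[k], "")[[1]]
    s[4:6] <- if (labels[k]) c("W", "W", "W") else c("P", "P", "P")
    grp[k] <- paste(s, collapse = "")
  }
  ali <- align_all(grp, n_match = 12)
  mt <- train_rbm(list(sequences = ali$aligned,
                       weights = rep(1, length(grp))),
                  n_hidden = 3, epochs = 60, seed = 4,
                  learning_rate = 0.02)
  proj <- rbm_project(mt, ali$aligned)
  best <- which.max(vapply(seq_len(3), function(mu) {
    abs(mean(proj[labels, mu]) - mean(proj[!labels, mu]))
  }, 0))
  sep <- specificity_auroc(proj[, best], labels)$auroc
  expect_gte(max(sep, 1 - sep), 0.95)
})

test_that("parameter export/import round-trips and logos normalize", {
  m <- toy_rbm(5, 4, 3, seed = 17)
  m <- log_partition(m, "ais", n_temps = 20, n_chains = 5, seed = 1)
  p <- tempfile(fileext = ".json")
  write_rbm(m, p)
  m2 <- read_rbm(p)
  set.seed(33)
  S <- matrix(sample.int(4, 100 * 5, replace = TRUE), 100, 5)
  expect_equal(log_score(m, S), log_score(m2, S), tolerance = 1e-12)
  expect_equal(m2$log_z$value, m$log_z$value)

  logos <- export_rbm_logos(m)
  expect_equal(unname(rowSums(logos$pwm)), rep(1, 5), tolerance = 1e-12)
  # weight logo preserves sign and magnitude ordering per site
  W1 <- logos$weights[[1]]
  expect_equal(as.numeric(t(W1)), as.numeric(m$W[, 1]))

  # version guard
  bad <- jsonlite::read_json(p, simplifyVector = TRUE)
  bad$format <- "other"
  p2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, p2, auto_unbox = TRUE, digits = NA)
  expect_error(read_rbm(p2), "archive")
})
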