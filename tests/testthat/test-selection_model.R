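# Selection-factor model: backgrounds, q-factors, likelihood, training.

test_that("builtin backgrounds are normalized and respect anchors", {
  set.seed(2)
  seqs <- anchored_toy_set(n_per_len = 40, lengths = c(8, 9, 10))
  for (kind in c("positionwise_independent", "markov1")) {
    bg <- builtin_background(kind, seqs)
    s <- bg$sample(300, seed = 4)
    expect_true(all(substr(s, 1, 1) == "C"))
    expect_true(all(is.finite(bg$log_prob(s))))
  }
  # degenerate fit: 1000 copies of one sequence -> that sequence has
  # probability ~ 1 (log prob ~ 0) under the positionwise model
  bg1 <- builtin_background("positionwise_independent",
                            rep("CASSF", 1000), pseudocount = 1e-6)
  expect_gt(bg1$log_prob("CASSF"), -1e-3)

  # enumeration oracle: total probability over an enumerable toy support
  # (two lengths, tiny alphabet usage) sums to 1
  toy <- c(rep("CAF", 6), rep("CGF", 2), rep("CAAF", 4), rep("CGGF", 4))
  bg <- builtin_background("positionwise_independent", toy,
                           pseudocount = 0.5)
  # anchors carry no smoothing, so the support is exactly C?F and C??F
  # with smoothed interior columns; enumerating it must give total mass 1
  enum <- c(vapply(AA_ALPHABET, function(a) paste0("C", a, "F"), ""),
            apply(expand.grid(AA_ALPHABET, AA_ALPHABET), 1,
                  function(x) paste0("C", x[1], x[2], "F")))
  lp <- bg$log_prob(enum)
  expect_equal(sum(exp(lp[is.finite(lp)])), 1, tolerance = 1e-9)

  # empirical background: unseen sequences are unsupported (NA)
  bge <- builtin_background("empirical_day0", toy)
  expect_true(is.na(bge$log_prob("CWWF")))
  expect_equal(sum(exp(bge$log_prob(unique(toy)))), 1, tolerance = 1e-12)
  expect_error(builtin_background("markov1", "CASSF"), "insufficient")
})

test_that("q_factor composes left and right terms with out-of-range = 1", {
  m <- selection_model()
  expect_equal(q_factor(m, 0, 12, "C"), 1)
  m$qL[1, match("C", AA_ALPHABET)] <- 2
  expect_equal(q_factor(m, 0, 12, "C"), 2)
  # both sides in range multiply; right distance l-1-i
  m$qR[3, match("C", AA_ALPHABET)] <- 5   # right distance 2
  expect_equal(q_factor(m, 0, 3, "C"), 10)
  # table-lookup oracle on random factor tables
  set.seed(6)
  m2 <- selection_model(qL = matrix(stats::runif(19 * 20, 0.5, 2), 19, 20),
                        qR = matrix(stats::runif(19 * 20, 0.5, 2), 19, 20))
  for (k in 1:25) {
    l <- sample(5:25, 1)
    i <- sample(0:(l - 1), 1)
    a <- sample(20, 1)
    expected <- 1
    if (i < 19) expected <- expected * m2$qL[i + 1, a]
    if ((l - 1 - i) < 19) expected <- expected * m2$qR[l - i, a]
    expect_equal(q_factor(m2, i, l, AA_ALPHABET[a]), expected,
                 tolerance = 1e-12)
  }
  expect_error(q_factor(m, 5, 3, "C"), "position")
  expect_error(q_factor(m, 0, 3, "B"), "invalid residue")
})

test_that("sonia_log_prob: identity at q = 1, factor doubling, normalization", {
  seqs <- anchored_toy_set(n_per_len = 50, lengths = c(8, 9))
  bg <- builtin_background("positionwise_independent", seqs)
  m <- selection_model(background = bg)
  test_seqs <- bg$sample(20, seed = 3)
  expect_equal(sonia_log_prob(m, test_seqs), bg$log_prob(test_seqs),
               tolerance = 1e-12)
  # doubling one matched factor raises log-prob by log 2
  m2 <- m
  m2$qL[1, match("C", AA_ALPHABET)] <- 2
  expect_equal(sonia_log_prob(m2, test_seqs) - sonia_log_prob(m, test_seqs),
               rep(log(2), 20), tolerance = 1e-12)
  # unsupported sequences signal NA with warning
  expect_warning(out <- sonia_log_prob(m, "CWWWWWWWWWWWWWWWWWWWWWWWWWF"),
                 "unsupported")
  expect_true(is.na(out))

  # normalization oracle: with exact log Z (computed by enumeration over
  # the background support) probabilities sum to 1
  toy <- c(rep("CAF", 3), rep("CGF", 1), rep("CLF", 2))
  bgt <- builtin_background("empirical_day0", toy)
  mt <- selection_model(background = bgt)
  mt$qL[2, match("A", AA_ALPHABET)] <- 3
  support <- unique(toy)
  qt <- tcrboltz:::.log_q_tilde(mt, support)
  mt$log_z <- logsumexp_test(qt + bgt$log_prob(support))
  expect_equal(sum(exp(sonia_log_prob(mt, support))), 1, tolerance = 1e-6)
})

test_that("train_sonia: null recovery, planted-factor recovery, marginals", {
  set.seed(9)
  # base set with fully variable interiors so every interior position
  # carries signal for the planted-enrichment recovery below
  base <- vapply(seq_len(2500), function(k) {
    l <- sample(10:14, 1)
    paste0("C", paste(sample(AA_ALPHABET, l - 2, TRUE), collapse = ""), "F")
  }, "")
  bg <- builtin_background("positionwise_independent", base)

  # data drawn from the background -> log-factors shrink to ~0 for
  # well-sampled features
  data_null <- bg$sample(4000, seed = 7)
  m_null <- train_sonia(data_null, bg, epochs = 60, seed = 1,
                        n_background_samples = 4000)
  seen <- as.numeric(Matrix::colMeans(
    tcrboltz:::left_right_sparse(data_null))) > 0.01
  log_q <- c(as.numeric(t(log(m_null$qL))), as.numeric(t(log(m_null$qR))))
  expect_lt(stats::median(abs(log_q[seen])), 0.05)
  expect_lt(stats::quantile(abs(log_q[seen]), 0.95), 0.35)

  # normalization invariant: E_bg[Q] = 1 within Monte-Carlo error
  bs <- bg$sample(20000, seed = 99)
  qtil <- exp(tcrboltz:::.log_q_tilde(m_null, bs) - m_null$log_z)
  expect_equal(mean(qtil), 1, tolerance = 0.1)

  # planted 3x enrichment of residue A at left distance 2 (3rd residue),
  # generated by rejection from the background, recovered within +-20%
  data_sel <- bg$sample(40000, seed = 13)
  third <- substr(data_sel, 3, 3)
  keep <- stats::runif(length(data_sel)) < ifelse(third == "A", 1, 1 / 3)
  sel <- utils::head(data_sel[keep], 5000)
  expect_length(sel, 5000)
  m_sel <- train_sonia(sel, bg, epochs = 100, seed = 2,
                       n_background_samples = 5000)
  iA <- match("A", AA_ALPHABET)
  ratio_hat <- m_sel$qL[3, iA] / exp(mean(log(m_sel$qL[3, -iA])))
  expect_gt(ratio_hat, 3 * 0.8)
  expect_lt(ratio_hat, 3 * 1.2)

  # model feature marginals match data marginals at convergence
  f_data <- as.numeric(Matrix::colMeans(tcrboltz:::left_right_sparse(sel)))
  bs2 <- bg$sample(20000, seed = 55)
  Xb <- tcrboltz:::left_right_sparse(bs2)
  lw <- as.numeric(Xb %*% c(as.numeric(t(log(m_sel$qL))),
                            as.numeric(t(log(m_sel$qR)))))
  iw <- exp(lw - logsumexp_test(lw))
  f_model <- as.numeric(Matrix::crossprod(Xb, iw))
  common <- f_data > 0.01
  expect_lt(stats::median(abs(f_model[common] - f_data[common]) /
                            f_data[common]), 0.05)
  expect_lt(unname(stats::quantile(abs(f_model[common] - f_data[common]) /
                                     f_data[common], 0.95)), 0.25)
})

test_that("selection model persistence round-trips", {
  m <- selection_model(qL = matrix(stats::runif(380, 0.5, 2), 19, 20,
                                   dimnames = list(NULL, AA_ALPHABET)),
                       qR = matrix(stats::runif(380, 0.5, 2), 19, 20,
                                   dimnames = list(NULL, AA_ALPHABET)),
                       log_z = 0.3)
  p <- tempfile(fileext = ".json")
  write_sonia(m, p)
  m2 <- read_sonia(p)
  expect_equal(m2$qL, m$qL, tolerance = 1e-12)
  expect_equal(m2$qR, m$qR, tolerance = 1e-12)
  expect_equal(m2$log_z, m$log_z)
  suppressWarnings(expect_error(read_sonia(tempfile())))
})
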