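# Synthetic repertoire experiments: anchored baseline CDR3 repertoires with
# heavy-tailed clone frequencies, planted-motif responder clones, clone-
# specific fold-change expansion, multinomial read sampling per timepoint,
# and technical replicates for null controls. Every other module is
# testable end-to-end on these simulations without external data.

# default interior residue composition: VDJ-junction-like usage with
# glycine/serine enrichment (a realistic fixed choice, documented in the
# methods vignette)
.default_residue_freqs <- local({
  f <- c(A = 0.055, C = 0.010, D = 0.040, E = 0.045, F = 0.030, G = 0.110,
         S = 0.120, T = 0.060, W = 0.015, Y = 0.045, H = 0.020, I = 0.030,
         K = 0.035, L = 0.065, M = 0.015, N = 0.040, P = 0.045, Q = 0.050,
         R = 0.065, V = 0.105)
  f <- f[AA_ALPHABET]
  f / sum(f)
})

# default CDR3 length law: discretized normal over 5..23, mode ~ 14-15
.default_length_probs <- local({
  lens <- 5:23
  p <- stats::dnorm(lens, mean = 14.5, sd = 2.2)
  stats::setNames(p / sum(p), lens)
})

#' Simulation configuration
#'
#' The stated world of the synthetic experiments: number of clones, CDR3
#' length law on 5-23, anchor rule (start C, end F with probability
#' `p_end_f` else V), interior residue model, the antigen panel (motif,
#' responder fraction, log-normal fold-change law), sequencing depth per
#' timepoint, and the clone-frequency power law.
#'
#' @param n_clones number of unique baseline clones (default 2000).
#' @param length_probs named numeric vector of length probabilities
#'   (names = lengths; default discretized normal on 5-23, mode 14-15).
#' @param residue_freqs interior residue frequencies (20-vector).
#' @param residue_model "positionwise" (iid interior residues) or "markov1".
#' @param p_end_f probability the right anchor is F rather than V
#'   (default 0.9).
#' @param antigens list of antigen specs, each a list(name, motif = named
#'   character vector: 1-based left-anchored position -> residue,
#'   responder_fraction, fc_meanlog, fc_sdlog). Default: one antigen "A1"
#'   with motif VVV at positions 3-5, responder fraction 0.1, fold factors
#'   log-normal(meanlog = log 10, sdlog = 0.5).
#' @param depth reads per timepoint (default 1e5).
#' @param freq_exponent power-law exponent of the baseline clone-size
#'   distribution (default 2: frequencies proportional to 1/rank).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_clones = 2000L,
                       length_probs = .default_length_probs,
                       residue_freqs = .default_residue_freqs,
                       residue_model = c("positionwise", "markov1"),
                       p_end_f = 0.9,
                       antigens = list(list(name = "A1",
                                            motif = c("3" = "V", "4" = "V",
                                                      "5" = "V"),
                                            responder_fraction = 0.1,
                                            fc_meanlog = log(10),
                                            fc_sdlog = 0.5)),
                       depth = 1e5,
                       freq_exponent = 2) {
  residue_model <- match.arg(residue_model)
  stopifnot(n_clones >= 2, depth >= 1, freq_exponent > 1,
            abs(sum(length_probs) - 1) < 1e-8,
            all(vapply(antigens, function(a) {
              a$responder_fraction > 0 && a$responder_fraction < 1
            }, TRUE)))
  structure(list(n_clones = as.integer(n_clones),
                 length_probs = length_probs,
                 residue_freqs = residue_freqs,
                 residue_model = residue_model,
                 p_end_f = p_end_f, antigens = antigens,
                 depth = depth, freq_exponent = freq_exponent),
            class = "sim_config")
}

# draw n interior strings of the given lengths from the residue model
.draw_interiors <- function(lengths, config) {
  total <- sum(lengths)
  if (total == 0) return(rep("", length(lengths)))
  if (config$residue_model == "positionwise") {
    res <- sample(AA_ALPHABET, total, replace = TRUE,
                  prob = config$residue_freqs)
  } else {
    # order-1 Markov chain biased toward repeating the previous residue
    res <- character(total)
    stay <- 0.15
    trans <- matrix(rep(config$residue_freqs * (1 - stay), each = 20),
                    20, 20, byrow = TRUE) + diag(stay, 20)
    trans <- trans / rowSums(trans)
    starts <- cumsum(c(1, lengths[-length(lengths)]))
    prev <- sample.int(20, length(lengths), replace = TRUE,
                       prob = config$residue_freqs)
    for (k in seq_along(lengths)) {
      if (lengths[k] == 0) next
      v <- integer(lengths[k])
      v[1] <- prev[k]
      if (lengths[k] >= 2) {
        for (t in 2:lengths[k]) v[t] <- sample.int(20, 1,
                                                   prob = trans[v[t - 1], ])
      }
      res[starts[k] + seq_len(lengths[k]) - 1L] <- AA_ALPHABET[v]
    }
  }
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  vapply(seq_along(lengths), function(k) {
    if (lengths[k] == 0) "" else
      paste(res[starts[k]:ends[k]], collapse = "")
  }, "")
}

# n anchored CDR3s with the configured length law
.draw_cdr3 <- function(n, config) {
  lens <- as.integer(sample(names(config$length_probs), n, replace = TRUE,
                            prob = config$length_probs))
  right <- ifelse(stats::runif(n) < config$p_end_f, "F", "V")
  paste0("C", .draw_interiors(lens - 2L, config), right)
}

#' Generate a baseline repertoire
#'
#' Unique anchored CDR3s with the configured length law and power-law clone
#' frequencies (frequency of the rank-r clone proportional to
#' r^(-1/(exponent-1))).
#'
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @return data.frame (class `sim_repertoire`): cdr3, baseline_freq.
#' @export
generate_repertoire <- function(config, seed = 1L) {
  set.seed(seed)
  n <- config$n_clones
  space_guard <- sum(config$length_probs *
                     20^(as.integer(names(config$length_probs)) - 2))
  if (n > space_guard / 10) {
    stop("n_clones too large for the sequence space", call. = FALSE)
  }
  seqs <- character(0)
  tries <- 0L
  while (length(seqs) < n) {
    tries <- tries + 1L
    if (tries > 50L) stop("could not generate enough unique sequences",
                          call. = FALSE)
    seqs <- unique(c(seqs, .draw_cdr3(2L * (n - length(seqs)), config)))
  }
  seqs <- seqs[seq_len(n)]
  freq <- seq_len(n)^(-1 / (config$freq_exponent - 1))
  freq <- freq / sum(freq)
  out <- data.frame(cdr3 = seqs, baseline_freq = freq,
                    stringsAsFactors = FALSE)
  class(out) <- c("sim_repertoire", "data.frame")
  out
}

#' Plant responder motifs into a repertoire
#'
#' Rewrites a `responder_fraction` of clones per antigen so that they carry
#' the antigen's motif (residues at the specified 1-based left-anchored
#' positions). Responder sets are disjoint across antigens when
#' `disjoint = TRUE` (required when motifs overlap in position). Rewritten
#' sequences that collide with existing ones get their non-motif interior
#' resampled.
#'
#' @param clones a `sim_repertoire` (or data.frame with cdr3).
#' @param antigens antigen specs (see [sim_config()]).
#' @param config the `sim_config` (residue model for resampling).
#' @param seed integer seed.
#' @param disjoint enforce disjoint responder sets (default TRUE).
#' @return The input data.frame plus one logical column
#'   `responder_<name>` per antigen.
#' @export
plant_responders <- function(clones, antigens, config, seed = 1L,
                             disjoint = TRUE) {
  set.seed(seed)
  n <- nrow(clones)
  if (!disjoint) {
    pos_sets <- lapply(antigens, function(a) names(a$motif))
    if (length(antigens) > 1) {
      for (a in seq_along(antigens)) {
        for (b in seq_along(antigens)) {
          if (a < b && length(intersect(pos_sets[[a]], pos_sets[[b]])) > 0) {
            stop("conflicting motifs at the same positions require disjoint responder sets",
                 call. = FALSE)
          }
        }
      }
    }
  }
  available <- seq_len(n)
  existing <- new.env(hash = TRUE)
  for (s in clones$cdr3) assign(s, TRUE, envir = existing)
  for (a in antigens) {
    motif_pos <- as.integer(names(a$motif))
    if (any(motif_pos < 1)) stop("motif positions must be >= 1",
                                 call. = FALSE)
    n_resp <- max(1L, round(a$responder_fraction * n))
    min_len <- max(motif_pos) + 1L   # keep the right anchor intact
    len_ok <- nchar(clones$cdr3) >= min_len
    pool <- intersect(available, which(len_ok))
    if (length(pool) < n_resp) stop("motif positions exceed length support",
                                    call. = FALSE)
    chosen <- sample(pool, n_resp)
    if (disjoint) available <- setdiff(available, chosen)
    flag <- rep(FALSE, n)
    flag[chosen] <- TRUE
    for (i in chosen) {
      s <- strsplit(clones$cdr3[i], "")[[1]]
      rm(list = paste(s, collapse = ""), envir = existing)
      s[motif_pos] <- a$motif
      cand <- paste(s, collapse = "")
      tries <- 0L
      while (exists(cand, envir = existing) && tries < 100L) {
        # resample non-motif interior positions to restore uniqueness
        free <- setdiff(2:(length(s) - 1L), motif_pos)
        if (length(free) == 0) break
        s[free] <- sample(AA_ALPHABET, length(free), replace = TRUE,
                          prob = config$residue_freqs)
        cand <- paste(s, collapse = "")
        tries <- tries + 1L
      }
      clones$cdr3[i] <- cand
      assign(cand, TRUE, envir = existing)
    }
    clones[[paste0("responder_", a$name)]] <- flag
  }
  clones
}

#' Sample day-0 / day-21 read counts for one antigen stimulation
#'
#' Day-0 counts are multinomial at the baseline frequencies; day-21
#' frequencies are the baseline times the per-clone fold factor
#' (renormalized) and day-21 counts multinomial at that law. Total reads per
#' table equal `depth` exactly.
#'
#' @param clones data.frame with cdr3 and baseline_freq.
#' @param fold_factors positive per-clone factors (non-responders 1).
#' @param depth reads per timepoint.
#' @param seed integer seed.
#' @param antigen label attached to the day-21 table.
#' @return list(day0, day21) of `clonotype_table`s (zero-count clones
#'   dropped).
#' @export
simulate_counts <- function(clones, fold_factors, depth, seed = 1L,
                            antigen = NA_character_) {
  stopifnot(depth >= 1, length(fold_factors) == nrow(clones),
            all(fold_factors > 0))
  set.seed(seed)
  p0 <- clones$baseline_freq
  n0 <- as.integer(stats::rmultinom(1, depth, p0))
  p21 <- p0 * fold_factors
  p21 <- p21 / sum(p21)
  n21 <- as.integer(stats::rmultinom(1, depth, p21))
  mk <- function(counts, timepoint, antigen) {
    keep <- counts > 0
    clonotype_table(cdr3 = clones$cdr3[keep], count = counts[keep],
                    sample_id = "sim", timepoint = timepoint,
                    antigen = antigen)
  }
  list(day0 = mk(n0, "day0", NA_character_),
       day21 = mk(n21, "day21", antigen))
}

#' Simulate a complete stimulation experiment
#'
#' Baseline repertoire, planted responders per antigen, per-antigen
#' log-normal fold factors, and one day-0 plus per-antigen day-21 count
#' tables. Ground truth (responder labels and true fold factors) is
#' returned alongside.
#'
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @return list (class `sim_experiment`): config, clones (with responder
#'   flags and per-antigen true fold factors), day0, day21 (named list per
#'   antigen).
#' @export
simulate_experiment <- function(config, seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L,
                      2L + 2L * length(config$antigens))
  clones <- generate_repertoire(config, seed = seeds[1])
  clones <- plant_responders(clones, config$antigens, config,
                             seed = seeds[2])
  day21 <- list()
  day0 <- NULL
  for (k in seq_along(config$antigens)) {
    a <- config$antigens[[k]]
    resp <- clones[[paste0("responder_", a$name)]]
    ff <- rep(1, nrow(clones))
    set.seed(seeds[2L + 2L * k - 1L])
    ff[resp] <- stats::rlnorm(sum(resp), meanlog = a$fc_meanlog,
                              sdlog = a$fc_sdlog)
    clones[[paste0("fold_", a$name)]] <- ff
    tabs <- simulate_counts(clones, ff, config$depth,
                            seed = seeds[2L + 2L * k], antigen = a$name)
    if (k == 1L) day0 <- tabs$day0
    day21[[a$name]] <- tabs$day21
  }
  structure(list(config = config, clones = clones, day0 = day0,
                 day21 = day21),
            class = "sim_experiment")
}

#' Split a table into two technical replicates
#'
#' Each clone's reads are split binomially (p = 0.5) into two statistically
#' indistinguishable samples — the null control for specificity analyses.
#'
#' @param table a `clonotype_table`.
#' @param seed integer seed.
#' @return list(rep1, rep2) of `clonotype_table`s; per-clone reads are
#'   conserved exactly across the pair.
#' @export
make_replicates <- function(table, seed = 1L) {
  set.seed(seed)
  n1 <- stats::rbinom(nrow(table), table$count, 0.5)
  n2 <- table$count - n1
  mk <- function(counts) {
    df <- as.data.frame(table)
    df$count <- as.integer(counts)
    .rewrap(df[df$count > 0, , drop = FALSE], table)
  }
  list(rep1 = mk(n1), rep2 = mk(n2))
}
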