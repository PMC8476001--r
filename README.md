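# tcrboltz

Sequence-based probabilistic modeling of T-cell receptor (TRB CDR3)
repertoires sampled before and after antigen stimulation.

When a repertoire is stimulated with an antigen, responding T-cell clones
expand; their read counts rise between the pre-stimulation ("day 0") and
post-stimulation ("day 21") samples. `tcrboltz` is for immunology groups
who have such longitudinal clonotype tables (ImmunoSEQ-style or AIRR
rearrangement TSVs) and want to go beyond count thresholds: it learns
probability models of the CDR3 amino-acid composition of each repertoire,
weighted by clone abundance, and turns ratios of model probabilities into
interpretable scores of response and specificity, plus sequence motifs of
the responding clones.

## Models and statistics

* **Restricted Boltzmann Machine (RBM)** over aligned CDR3s
  (19 columns x 21 states including the gap) with double-rectified
  (dReLU) hidden units:
  `P(σ,h) ∝ exp( Σᵢ gᵢ(σᵢ) − Σ_μ U_μ(h_μ) + Σᵢμ h_μ wᵢμ(σᵢ) )`,
  `U(h) = ½γ₊h₊² + ½γ₋h₋² + θ₊h₊ + θ₋h₋`.
  Trained by persistent contrastive divergence on count-weighted data with
  a squared-L1 weight penalty; supports exact scoring, annealed-importance
  partition estimates, Gibbs sampling, and latent projection onto the
  hidden-unit inputs `I_μ(σ) = Σᵢ wᵢμ(σᵢ)` (the package's
  dimensionality-reduction view).
* **CDR3 alignment**: per-length position weight matrices, progressive
  profile-profile alignment (expected BLOSUM62 column score, one interior
  gap per length step), a 19-match-state profile HMM, and batched Viterbi
  decoding. Anchors (C ... F/V) stay in the outer columns; gaps
  concentrate mid-sequence.
* **Selection-factor model**: independent-site Left+Right features
  (19 x 20 x 2 = 760 binary entries; each residue indexed by its distance
  from each anchor), positive factors learned by importance-sampled
  maximum likelihood against a pluggable background distribution, with an
  L2 penalty on log-factors.
* **Scores**: pseudo-counted fold change `(n21+½)/(n0+½)`; expansion
  calls by one-sided Fisher exact test + Storey q-values; response score
  `S_resp = log P21(σ) − log P_bg(σ)`; specificity score
  `S_spec = S_resp(focal) − max over other antigens`; exact midrank AUROC.
* **Diversity**: dissimilarity index `1/f` with
  `f = mean over pairs of exp(−(d/δ)²)`, Levenshtein `d`, default
  `δ = 5.7`.
* **Synthetic data**: anchored repertoires with a realistic length law,
  Zipf-like clone sizes, planted position-anchored motifs, log-normal
  clonal expansion, multinomial read sampling and technical replicates —
  ground truth for every end-to-end test.

## Worked example

Two antigens with disjoint planted motifs (VVV vs WSA at CDR3 positions
3-5), 10% responders each, expanded ~10-fold:

```r
library(tcrboltz)

cfg <- sim_config(
  n_clones = 1200, depth = 5e4,
  antigens = list(
    list(name = "NA1", motif = c("3" = "V", "4" = "V", "5" = "V"),
         responder_fraction = 0.10, fc_meanlog = log(10), fc_sdlog = 0.5),
    list(name = "CR1", motif = c("3" = "W", "4" = "S", "5" = "A"),
         responder_fraction = 0.10, fc_meanlog = log(10), fc_sdlog = 0.5)))
exp1 <- simulate_experiment(cfg, seed = 7)

# which clones expanded under NA1 stimulation?
calls <- call_expanded(exp1$day0, exp1$day21$NA1)
#> expanded clones (NA1): 112 of 1200 tested

# align and train an RBM on the count-weighted day-21 repertoire
cw  <- to_count_weighted(collapse_by_cdr3(exp1$day21$NA1))
ali <- align_all(cw$sequences)
rbm <- train_rbm(list(sequences = ali$aligned, weights = cw$weights),
                 n_hidden = 10, l1sq = 0.1, epochs = 60,
                 learning_rate = 0.02, seed = 1)
rbm$hmm <- attr(ali, "hmm")
rbm <- log_partition(rbm, "ais", n_temps = 200, n_chains = 10, seed = 1)
rbm
#> rbm_model: 19 sites x 21 states, 10 dReLU hidden units
#>   log Z = 11.6870 (ais, stderr 0.08255)
```

Response scores against a day-0 background correlate with measured fold
change, and the correlation sharpens as noisy low-count clones are
filtered out (all clones vs the 125 most abundant):

```r
bg <- builtin_background("positionwise_independent",
                         to_count_weighted(exp1$day0))
common <- intersect(calls$cdr3, cw$sequences)
s_resp <- response_score(rbm, bg, common, log10 = TRUE)
fc  <- calls$fold_change[match(common, calls$cdr3)]
cts <- calls$n21[match(common, calls$cdr3)]
correlation_vs_abundance_filter(s_resp, cts, target = log10(fc),
                                retain_ns = c(length(common), 125),
                                cdr3 = common)
#>   retained_n   pearson  spearman
#> 1       1195 0.2929298 0.2411350
#> 2        125 0.6730151 0.6815464
```

Specificity scores between the two antigen models separate NA1-specific
from CR1-specific responders essentially perfectly on this planted world,
and the expanded pool's sequence heterogeneity is summarized by the
dissimilarity index:

```r
#> evaluation_report: AUROC 0.9998 (112 specific vs 109 unspecific)
#> dissimilarity_result: index 12.2873 (f = 0.08139, M = 112,
#>                       exact over 6216 pairs, delta = 5.7)
```

(The AUROC here reads: ranking clones by `S_spec` almost perfectly
recovers which of the two stimulations each responder expanded under. The
dissimilarity index 12.3 says the expanded pool behaves like ~12
effectively dissimilar sequence neighborhoods at scale δ = 5.7.)

A command-line interface wraps the same operations
(`simulate`, `align`, `encode`, `train-rbm`, `train-sonia`, `expand`,
`score`, `specificity`, `diversity`, `evaluate`); see `run_cli()` or the
`inst/cli/tcrboltz` wrapper. Every run writes a reproducibility manifest.

## Further reading

The methods vignette (`vignettes/tcrboltz-methods.Rmd`) documents the
model definitions, training estimators, numerical stability choices,
what the synthetic generator does and does not emulate, and known
limitations.
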