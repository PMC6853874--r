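# flowdecon

Single-cell fluorescence measurements of a transcriptional reporter never
show the reporter alone: each event records the reporter signal *plus* the
cell's autofluorescence.  For dim, noisy promoters — exactly the ones whose
rare high-expressing "outlier" cells matter for phenotypes like antibiotic
tolerance — the background can dominate the measurement, and comparisons
between genotypes or between pre/post-treatment populations become
unreliable unless the background is removed.

flowdecon is an R package for that analysis chain, aimed at
quantitative microbiologists and systems biologists working with
flow-cytometry event data (CSV/TSV tables, or FCS 3.x files):

1. **Moment-matching deconvolution.**  Under the additive
   independent-noise model `R = S + N`,

   `⟨S⟩ = ⟨R⟩ − ⟨N⟩`  and  `Var(S) = Var(R) − Var(N)`,

   with the noise moments measured on a non-fluorescent control.  The
   autofluorescence-free signal is then modeled as
   Gamma(k, θ) — the standard description of protein copy-number
   statistics in bacteria — with `k = ⟨S⟩²/Var(S)`, `θ = Var(S)/⟨S⟩`.
2. **Re-convolution validation.**  The fitted Gamma is convolved back with
   the measured control by direct resampling (no smoothing) and compared
   to the raw data with a two-sample Kolmogorov–Smirnov distance; a
   moment-matched lognormal alternative can be ranked the same way.
3. **Enrichment / survival analysis.**  Paired pre/post-selection fits are
   related by `f_a(s) = C·f_b(s)·p(s)`; the package computes enrichment
   factors `EF(s) = f_a(s)/f_b(s)` in log space, the log-linear selection
   strength `β = 1/θ_b − 1/θ_a`, and C-free survival ratios
   `p(s₁)/p(s₂)` at sorting-gate values (defaults 4.1 and 779.5 A.U.).
4. **Population statistics.**  Control normalization, fixed-threshold
   outlier percentages (default 1250 normalized A.U.), fold effects,
   coefficients of variation, dual-reporter Pearson/Spearman correlations,
   and an exact small-sample two-sample KS test (exhaustive permutation
   enumeration) for comparing replicate outlier frequencies.
5. **Synthetic data.**  A generator producing populations with exactly the
   structure the analysis assumes — Gamma signal, additive noise,
   shared-factor dual reporters, expression-dependent survival thinning —
   so the full pipeline is verifiable without instrument data.

## Worked example

Deconvolve a synthetic population whose truth is known (signal
Gamma(k = 1, θ = 50) on top of Gamma autofluorescence with mean 100,
variance 225), validate the fit, and recover an expression-dependent
survival from a thinning experiment:

```r
library(flowdecon)

nm   <- noise_model("gamma", mean = 100, variance = 225)
pop  <- synthesize_population(signal_params(shape = 1, scale = 50), nm,
                              n = 3e4, seed = 7)
ctrl <- sample_noise(nm, 3e4, seed = 8)
fit  <- deconvolve(pop, ctrl)
fit
#> Autofluorescence deconvolution (moment matching)
#>   raw:     n = 30000, mean = 149.6, var = 2673
#>   control: n = 30000, mean = 99.98, var = 223.8
#>   signal:  mean = 49.63, var = 2449  ->  k = 1.006, theta = 49.35

validate_reconvolution(fit$raw, simulate(fit, seed = 9))
#> Re-convolution check: KS D = 0.0052 (n = 30000 vs 30000), max ECDF gap at 115.4 A.U.
```

The recovered `(k, θ) = (1.006, 49.35)` sits within ~1% of the generating
`(1, 50)`, and the re-convolved data set is statistically almost
indistinguishable from the measured one (`D ≈ 0.005` on 3×10⁴ events).

Survival inference: thin a Gamma(2, 1) population with
`p(s) = min(1, 3e-4·e^{0.5 s})`, deconvolve the pre- and post-selection
populations, and read the selection strength back off the enrichment
model:

```r
nm2  <- noise_model("gamma", mean = 1, variance = 0.25)
pool <- synthesize_population(signal_params(2, 1), nm2, n = 3e6, seed = 10)
post <- apply_survival_thinning(pool, survival_model(3e-4, 0.5), seed = 11)
pre  <- synthesize_population(signal_params(2, 1), nm2, n = 3e4, seed = 12)
ctr2 <- sample_noise(nm2, 3e4, seed = 13)

em <- enrichment_model(deconvolve(pre, ctr2), deconvolve(post, ctr2))
infer_survival(em)
#> Relative survival p(s) ~ exp(beta s), beta = 0.509898 per A.U.
#>   note: Gamma shapes differ by 0.05667; ln p(s) also carries a
#>   0.05667*ln(s) term, beta is a least-squares slope over [0.3517, 4.732] A.U.

predict_gate_survival(em, gates = c(low = 2, high = 10))$ratio
#> [1] 51.89999
```

The inferred `β ≈ 0.51`/A.U. recovers the generating 0.5 within 2%, and
cells at signal level 10 are predicted to survive ~52× more often than
cells at level 2 (close to the closed form `e^{0.5·8} ≈ 54.6`; the small
gap is the estimated shape mismatch of 0.057 between the two fits).

A command-line interface wrapping these functions
(`simulate` / `deconvolve` / `enrich` / `outliers` / `report`) is
installed at `system.file("cli/flowdecon", package = "flowdecon")`; an
example scenario file lives in
`system.file("extdata/example_scenario.yaml", package = "flowdecon")`.

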