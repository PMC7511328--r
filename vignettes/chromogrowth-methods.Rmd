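---
title: "Methods: growth fitness, expression, and chromosomal periodicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth fitness, expression, and chromosomal periodicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chromogrowth` analyses the joint structure of three quantities measured
on a bacterium with a circular genome: the exponential growth rate of
every single-gene knockout strain (one non-essential gene deleted per
strain), the wild-type expression level of every gene, and the genomic
position of every gene. This vignette documents the models and the
conventions behind each stage, the synthetic-data generator used to test
them, and the choices made where several defensible options existed.

## Growth rates from OD600 curves

The instantaneous exponential rate between two consecutive plate-reader
readings $C_i$ at $t_i$ and $C_{i+1}$ at $t_{i+1}$ (blank-corrected OD600)
is

$$\mu_i = \frac{\ln(C_{i+1}/C_i)}{t_{i+1}-t_i} \quad [h^{-1}].$$

`interval_rates()` computes these for every pair and masks intervals whose
endpoints sit below a positivity floor (blank + 0.003 OD by default): the
logarithm of reader noise carries no growth information. The strain's rate
is the mean of one window of five consecutive valid interval rates. "Best
window" is a two-objective notion (large mean, small spread) that needs a
total order to be reproducible; `estimate_growth_rate()` uses:

1. maximal window mean (growth rate is the headline quantity);
2. among windows whose mean is within 5% of that maximum, minimal
   standard deviation (stability breaks near-ties robustly);
3. remaining ties go to the earliest window.

A curve with no valid window, or whose best window mean is not positive,
is flagged no-growth and excluded from replicate aggregation (with a
count), mirroring the laboratory practice of re-scoring wells that show no
growth. The growth maximum `max_od` is the largest blank-corrected
reading, deliberately unsmoothed — the simplest defensible convention.
Replicates aggregate to mean, SE $= s/\sqrt{n}$, and replicate count; a
single surviving replicate reports SE 0 with a `degenerate_n` flag rather
than NA, so downstream joins stay total.

On a noise-free exponential the estimator is exact to rounding (the
log-ratio of $C_0e^{\mu t}$ is $\mu$ on any grid), and it is invariant to
positive rescaling of the OD values. On a logistic curve it underestimates
$\mu$ by a factor $\approx 1-\bar{OD}/K$ over the selected window, which
is why the selection rule's preference for the earliest, lowest-OD window
matters; the tests verify convergence to the true rate as $OD_0/K \to 0$.

**Well-location bias.** Plate-reader assays show a reproducible gradient
of the growth *maximum* across well positions, while rates stay trendless.
`well_bias_diagnostic()` averages both quantities per well across strains
and reports Spearman trends against a serpentine well index (A1..A12,
B12..B1, ...). The serpentine order is a fixed documented convention — any
fixed order detects a monotone spatial gradient; serpentine keeps adjacent
indices physically adjacent.

## Five fitness classes and enrichment

Within one medium, the knockout rate distribution is summarized by its
quartiles $Q_1, Q_3$ (linear-interpolation "type 7" quantiles — the R
default, declared so that the fences are reproducible) and the box-plot
fences $Q_1 - 1.5\,\mathrm{IQR}$ and $Q_3 + 1.5\,\mathrm{IQR}$. Class
semantics invert the rate because a fast-growing knockout marks a costly
gene: above the upper fence is `very_negative` (gene contribution), the
box is `neutral`, below the lower fence `very_positive`. Boundary values
are assigned inward (toward neutral), making the five classes an exact
partition; when IQR = 0 the fences collapse onto the quartiles and
everything off the point mass becomes an outlier class.

Category enrichment of a selection of $n$ genes uses the one-sided
binomial tail $P(X \ge x)$, $X \sim \mathrm{Bin}(n, m/M)$, per category
($m$ of $M$ background genes), Bonferroni-corrected over the categories
tested. The background matches the selection's sampling frame: all
annotated non-essential genes for fitness classes (essential genes cannot
be in a knockout library), all annotated genes for expression-based
selections. Only over-representation is tested.

`reevaluate_by_replicates()` demotes a non-neutral call to neutral unless
a two-sided one-sample t test of the strain's replicate rates against the
medium's median rate rejects at $\alpha = 0.05$. The underlying published
procedure is not specified in detail anywhere we could follow, so this
rule is a declared stand-in; strains with fewer than two grown replicates
are exempt and flagged rather than silently demoted.

## Rank-product differential analysis

Expression tables are first put on a common scale by a constant per-dataset
shift that equalizes the median log10 RPKM across datasets (target = mean
of the input medians). A constant shift preserves within-dataset ranks
exactly, which is all the rank product consumes.

For two conditions with replicates, every replicate pairing $(i,j)$
yields a comparison column $A_i - B_j$; by default all $R_A \times R_B$
pairs are used. Items are ranked per column (mid-ranks on ties; rank 1 =
most extreme in the direction under test) and the rank product is the
geometric mean of an item's ranks. Both directions are scored separately.

Significance uses a pooled Monte-Carlo null,
$p = (\#\{RP_{null} \le RP_{obs}\} + 1)/(n_{perm} G + 1)$. The choice of
null matters more than is usually acknowledged:

- **`iid_reference` (default).** Draw iid noise matrices with the same
  dimensions and pairing and recompute the rank products. Because the
  statistic is rank-based this is *exactly* its null law under iid
  sampling — including the dependence among all-pairs columns that share
  a replicate — and observed effects cannot leak into the null.
- **`column_shuffle`.** The classical scheme: shuffle each column's ranks
  independently. Exact when columns are independent (paired design), but
  for all-pairs columns it ignores the shared-replicate dependence and is
  anti-conservative: in our calibration runs it selected ~8% of pure-null
  genes at pfp q < 0.05 instead of ≤5%.
- **`label_permutation`.** Relabel the pooled replicates (one relabelling
  for all items) and recompute. Valid and dependence-preserving, but with
  3+3 replicates only 20 distinct relabellings exist and strong effects
  re-enter the null tables, costing power.

The reported q is pfp ($p \cdot G / \mathrm{rank}(p)$, made monotone
non-decreasing in p), the rank product's native expected-false-positive
ratio; Benjamini–Hochberg is emitted alongside so the choice is auditable.
Selection thresholds should match the FDR being claimed: the DEG/DGG
analysis uses q < 0.05; the package's planted-signal validation selects at
q < 0.1 because that is the FDR bound it asserts.

DGG input is the replicate-level growth rates (the statistic needs
replicate columns), not strain means.

## Growth–expression association

The join is an inner join on gene id between a rate table and an
expression table for one medium; duplicates are errors, unmatched ids are
counted. The headline statistic is Spearman's $\rho$ with the tie-corrected
asymptotic p. The randomization test shuffles one column (growth and
expression each, by default), recomputes $\rho$ per shuffle, and reports
the add-one empirical two-sided p, $(\#\{|\rho_{null}| \ge |\rho_{obs}|\}
+ 1)/(n_{shuffles}+1)$ — never exactly zero, conservative by construction.
Category-level analysis keeps categories with more than 30 genes, averages
both variables within category, and correlates across category means as
well as within each category.

One attenuation effect deserves note: the generator calibrates the
correlation on *true* knockout rates, so the correlation measured on
plate-estimated rates is diluted toward zero by replicate and estimation
noise (classical regression attenuation). With the default noise settings
the true-rate $\rho = -0.37$ reads out at roughly $-0.18$ through the
full plate path. Measured correlations in any real screen are attenuated
the same way relative to the latent biology.

## Chromosomal periodicity

`positional_signal()` converts per-gene values into a circular series: at
every 1-kb anchor $a$, the mean of the values of genes whose midpoint lies
in the half-open window $[a, a+100\,\mathrm{kb})$, wrapping modulo the
genome length. Gene position is the interval midpoint (computed modulo L
for origin-wrapping genes) — one representative point per gene. Windows
are left-anchored; the alternative centred convention only rotates the
series, and rotation provably changes nothing but the fitted phase (a
tested invariant), so the choice is immaterial to powers, g, and dominant
wavelengths. Empty windows are filled with the global mean of non-empty
windows, which is neutral once the series is mean-centred for the
transform. Three modes: `essential_zero` includes essential genes at value
0 (deleting them means no growth), `nonessential_only` drops them, and
`density` counts genes per window (e.g. essential-gene density).

The periodogram of the mean-centred series assigns harmonic $k$ the power
$|c_k|^2/N$ from the discrete Fourier transform; wavelength $= L/k$. Any
consistent scaling would do — Fisher's g and the argmax are scale-free —
so the scaling is pinned by a tested Parseval identity (twice the summed
half-spectrum, minus the Nyquist term for even N, equals the sum of
squares of the centred series). The spectrum is computed on the smoothed
window-mean series, the same series the genomic profiles plot; the 100-kb
moving average multiplies a k-harmonic's amplitude by the Dirichlet factor
$\left|\sin(\pi k W/L) / (W \sin(\pi k/L))\right|$ (window $W$ = 100 bins),
verified against the closed form to 1e-6. Smoothing attenuates but never
relocates a harmonic, so dominant wavelengths are unaffected.

Fisher's g is the largest ordinate over the sum of ordinates, with the
exact null tail
$p = \sum_{j=1}^{\lfloor 1/g \rfloor} (-1)^{j-1}\binom{n}{j}(1-jg)^{n-1}$.
Terms are accumulated via log-magnitudes with early truncation when the
remainder is negligible, and the result is clipped to [0, 1]; a saturating
term sum returns p = 1. Monte-Carlo calibration on white noise (rejection
rate at p < 0.05 within [0.04, 0.06] over 2,000 simulated spectra) is part
of the acceptance checks.

`dominant_period()` takes the argmax of power with the full-genome
harmonic k = 1 excluded by default — that peak reflects the genome's own
length, not a periodicity within it — and reports g and its p over the
ordinates actually considered. Ties go to the smaller k. The sinusoid at
the dominant harmonic is the least-squares fit
$m + A\cos(2\pi k x/L + \phi)$, closed-form from the k-th Fourier
coefficient ($A = 2|c_k|/N$, $\phi = \arg c_k$) because the harmonics are
orthogonal on the circular grid.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with defaults describing the study conditions: a 4,632-kb circular genome,
4,200 genes (~7% essential, leaving ~3,900 knockout strains), a
six-period positional harmonic, and a target growth–expression Spearman
correlation of −0.37.

| parameter | default | units | role |
|---|---|---|---|
| `genome_length_kb` | 4632 | kb | circular coordinate system |
| `n_genes` / `essential_fraction` | 4200 / 0.072 | — | ~3,900 non-essential strains |
| `n_periods` | 6 | cycles/genome | positional harmonic (772-kb wavelength) |
| `positional_amplitude_expr` | 0.15 | log10 RPKM | expression positional cosine |
| `positional_amplitude_growth` | 0.02 | h⁻¹ | growth positional cosine, sign-reversed |
| `target_rho` | −0.37 | — | growth–expression Spearman target |
| `media` | LB: μ=1.2, K=1.0; M63: μ=0.45, K=0.5 | h⁻¹, OD | wild-type kinetics per medium |
| `well_bias_slope` | 0.002 | OD/well index | carrying-capacity bias only |
| `gene_effect_sd` / `expression_sd` | 0.6 / 0.2 | log10 RPKM | gene-specific spread, replicate noise |
| `growth_residual_sd` | 0.05 | h⁻¹ | gene-level rate residual |
| `growth_replicate_sd` | 0.02 | h⁻¹ | replicate spread (free parameter; no published value to match) |
| `od_sd` / `blank` / `od0` | 0.003 / 0.08 / 0.01 | OD | reader noise, blank floor, inoculum |
| `interval_h` / `duration_h` | 0.5 / 24 | h | 49-point sampling grid |

Expression is baseline + positional cosine + gene effect + replicate
noise. The true knockout rate is
$\mu_g = \mu_{wt} - A_g\cos(2\pi k x_g/L + \phi) - \beta\,\tilde e_g +
\varepsilon_g$, with the positional term locked in antiphase with the
expression one and $\tilde e_g$ the centred observed mean expression.
$\beta$ is solved by bisection on the realized Spearman correlation over
the non-essential genes (Spearman under a mixed signal has no closed
form); the bisection stops within ±0.02 of the target, comfortably inside
the ±0.05 contract, and raises an error naming the feasible range when the
target is unreachable (e.g. constant expression). Plate curves are
logistic with the well bias on the carrying capacity only, additive
Gaussian reader noise truncated at the blank floor (plate readers bottom
out at blank), and replicates of a strain placed in different wells by a
37-slot rotation (37 is coprime with 96). All stages derive their own
substreams from the master seed, so outputs are byte-identical given a
config.

**What the generator does not emulate.** Essential genes are scattered
uniformly, whereas in real genomes their placement is itself periodic —
which is exactly why, at default amplitudes, the `essential_zero`
whole-genome spectrum of synthetic data is dominated by random
essential-density fluctuations rather than the planted harmonic, while
`nonessential_only` recovers it cleanly. Also absent: lag/diauxie phases,
read-level RNAseq counts, plate edge effects beyond the monotone gradient,
and any causal structure between expression and fitness. Passing tests on
synthetic data therefore validate the estimators and conventions, not the
biology of any particular genome.

## Problem sizes and determinism

The test-suite simulations are sized to exercise each property at the
scale where it is informative: growth-rate exactness on single curves;
well-bias diagnostics on 192 strains over two plates at 15-min sampling;
rank-product calibration on 100–200 items over 20 seeds; Fisher's g
calibration on 2,000 white-noise spectra of 500–1,000 bins; correlation
recovery at the full ~3,900-strain scale over 10 seeds; classification and
enrichment on 100-run planted-category simulations. All randomness flows
through named seeds; reruns are byte-identical.

## Known limitations

- The rank product's `iid_reference` null assumes exchangeable items with
  iid replicates under the null; strongly heteroscedastic null genes would
  make it optimistic (a limitation shared with the classical scheme).
- Fisher's g assumes Gaussian white noise under the null; heavy-tailed
  positional noise inflates g.
- The window-selection rule's 5% mean band is a convention; any fixed
  band in the 2–10% range gives the same estimates on clean curves but
  may pick different windows on pathological ones.
- Empirical randomization p-values are bounded below by
  $1/(n_{shuffles}+1)$.
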