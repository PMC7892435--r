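---
title: "Dating a founder allele from STR haplotype decay: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating a founder allele from STR haplotype decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderage)
```

# The model

All estimators in this package share one generative picture, the *star
genealogy*: every sampled carrier chromosome descends from the founder
chromosome through `g` independent meioses, with no shared internal branches.
Along each meiosis, a marker at recombination fraction $\theta_k$ from the
disease mutation keeps the founder allele with probability $1 - \theta_k$,
and a retained STR allele mutates by $\pm 1$ repeat unit with probability
$\mu_k$. After `g` generations the founder allele therefore survives at a
marker with probability

$$a_k(g) = \left[(1 - \theta_k)(1 - \mu_k)\right]^g ,$$

and a chromosome can still *match* the ancestral state without carrying the
founder copy — identity by state — with the control-population frequency
$f_k$ of the ancestral allele set:

$$s_k(g) = a_k(g) + \bigl(1 - a_k(g)\bigr) f_k .$$

The four estimators consume this decay differently:

* **Risch moment**: the LD index $\delta = (p_D - p_N)/(1 - p_N)$ has
  expectation $(1-\theta)^g$ (the IBS floor cancels in $\delta$), so
  $g = \log\delta / \log(1-\theta)$ per marker, averaged as mean $\pm$ SD.
* **Markov iteration**: replaces the closed form with the explicit
  per-generation transition $K = \theta R + \mu M + (1-\theta-\mu) I$ and
  counts iterations until the ancestral mass reaches the observed carrier
  proportion; unlike the Risch formula it corrects for marker mutation.
* **MRCA composite likelihood**: reduces each chromosome side to the index
  of the first marker discordant with the ancestral haplotype and scores it
  with $P(j) = (1 - s_j)\prod_{k<j} s_k$ (and $\prod_k s_k$ for fully shared
  sides), summed over chromosomes and maximized on an integer grid.
* **Bayesian posterior**: the same likelihood times a prior on `g`, either
  uniform or growth-informed, $\pi(g) \propto e^{-rg}$, reflecting that a
  mutation entering an exponentially growing population is a priori more
  likely to have entered when the population was recent and large.

## Assumptions worth stating

* Inputs are **phased** chromosomes; carrier records are the
  mutation-bearing chromosome only. The package does no phasing.
* Markers are treated as independent given `g` — a *composite* likelihood.
  In reality marker survival is nested within a side (a single crossover
  removes all markers beyond it), which makes the composite likelihood a
  deliberate approximation; its calibration is therefore established by
  simulation (below), not assumed.
* The star genealogy ignores the shared genealogy of carriers within the
  population; for a rare allele in a growing population this is the standard
  first-order approximation and matches what the moment estimators
  implicitly assume.

# Parameters, units, defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `dist_cM` | marker–mutation genetic distance (cM) | panel-specific | from physical distance × 1.17 cM/Mb (`bp_to_cm()`) |
| map function | cM → θ | `linear` (θ = cM/100) | the convention under which the packaged LD table reproduces its published mean age of 11.5 g; Haldane/Kosambi offered (`cm_to_theta()`); linear is used as-is even for the 54.8 cM marker (θ = 0.548) |
| `mu` | per-meiosis stepwise mutation rate | 5.6×10⁻⁴ (dinucleotide), 2.1×10⁻³ (tetranucleotide) | per-repeat-class rates used in the source analysis; overridable per marker |
| `f` | IBS floor per marker | estimated from control chromosomes | overridable, e.g. with published population frequencies |
| `g_grid` | likelihood search grid | 1–200 generations | exhaustive and deterministic; cheap likelihood makes continuous optimization pointless |
| `years_per_generation` | calendar conversion | 25 y | conventional human generation time used in the source analysis |
| `anchor_year` | year the count runs back from | 1990 | average birth year of sampled carriers in the fixture study |
| `f` (Bayes config) | assumed carrier chromosome proportion | 0.012 | recorded for reporting; the composite likelihood uses per-marker `f_k` |
| `r` | growth rate per generation | 0.079 | `growth_rate(3.5e6, 9.8e6, 13)`: population growth from the founder era to the present |

# Numerical choices

* **Years round before date subtraction**: 11.5 g → 287 y → year 1703 (not
  1702.5); interval endpoints convert the same way.
* **SD uses the n−1 denominator** (sample SD across markers).
* **Markov state space** is the observed repeat range padded by 2 states on
  each side; the mutation matrix reflects at the boundaries (mass that
  would step out of range steps inward). The padding makes results
  insensitive to the boundary convention — property-tested by comparing
  pads of 2 and 5.
* **Multi-allele ancestral sets** (e.g. the bi-allelic 24/25 state at the
  closest marker of the packaged panel) start the Markov chain with mass
  split equally across the set, and count as matches in δ, carrier
  proportions and discordance scans (frequencies over a set are sums of
  member frequencies).
* **Ancestral inference tie-breaks**: the modal carrier allele per marker;
  an exact tie or a runner-up within 0.8× of the modal count yields a
  two-allele set (never silently dropping data); `strict = TRUE` resolves
  ties toward the smaller repeat number for deterministic pipelines.
* **Degenerate LD**: markers with $p_N = 1$ have undefined δ (returned `NA`
  with a warning); δ ≤ 0 markers are flagged non-informative and excluded
  from age estimation with a warning. In the MRCA likelihood, markers with
  $f_k = 1$ can never be discordant and contribute exactly zero, so they
  are excluded from the scan (warning), which makes the MLE invariant to
  their presence.
* **Posterior normalization** uses log-sum-exp; the 95% credible set is the
  smallest contiguous grid interval holding ≥ 0.95 mass (ties resolved
  toward younger ages). The profile-likelihood interval uses the
  $\chi^2_1$ cutoff of 1.92 log-likelihood units.
* **Likelihood boundary hits** (flat or monotone likelihood, e.g. fully
  shared haplotypes with $f \approx 0$) return the grid edge with a
  warning rather than failing.

# The synthetic-data generator

`simulate_haplotypes()` draws carrier chromosomes forward in time under the
star genealogy. Two crossover modes exist, and the difference matters:

* **Default (independent survival)**: marker `k` retains the founder allele
  with probability $(1-\theta_k)^g$, independently across markers. This is
  the *exact* null model of every estimator in the package, which is
  deliberate: recovery experiments then measure estimator error alone, not
  model misspecification.
* **`positional = TRUE` (nested survival)**: each meiosis places a single
  crossover at an exponential genetic distance (Poisson crossover process),
  so survival is nested within a side — the biologically faithful picture.
  Under this mode the composite likelihood is misspecified by construction
  (long shared runs are more probable than independence implies, biasing
  $\hat g$ downward); use it to probe robustness, not calibration.

Stepwise mutations are applied only to retained founder alleles (a
recombined-in allele already carries population variation through the
control frequency draw). Control allele distributions default to a
discretized triangular shape over seven repeat numbers whose mode sits two
steps off the founder allele, giving the founder allele a realistic IBS
frequency of 0.125; empirical distributions can be supplied per marker.

What a green recovery test does **not** establish: robustness to nested
crossovers (run `positional = TRUE` for that), to mis-specified maps or
mutation rates, to unphased or errorful genotypes, or to correlated
genealogies — none of which the generator emulates by default.

# Recovery calibration and an information limit

The acceptance suite simulates ~200 panels (30 carriers, 100 controls, the
packaged 8-marker map) with true ages spanning 5–40 generations and requires
the MLE and posterior mode to track the truth (pooled median absolute error
≤ 3 generations) with pooled interval coverage ≥ 0.85.

One honest caveat, quantified rather than hidden: at `g_true = 40` *alone*
the per-side first-discordance statistic carries little information on this
map — its expected Fisher information bounds the MLE's standard deviation at
about 6.3 generations for 30 carriers, so the per-age median error there is
around 4–5 generations even though coverage stays near nominal. More
carriers, closer markers, or a statistic using the full sharing pattern
(not just the first discordance) would be needed to do better; the package
reports the per-age numbers alongside the pooled ones.

# Known limitations

* The MRCA likelihood is a documented stand-in for published closed-source
  tools (the ESTIAGE likelihood and the DMLE+ intra-allelic coalescent
  MCMC); it reproduces their *kind* of inference, validated against the
  simulator's truth, and is not expected to match their printed estimates
  on the original data to the generation.
* δ-based methods need the ancestral allele set; with few independent
  carriers the modal inference itself is noisy, and that uncertainty is not
  propagated into the age intervals.
* PED/MAP import trusts the file to be phased; genuine PED genotype data
  must be phased upstream.
* Simulation/recovery CLI configs are JSON (no YAML dependency in the
  supported environment).
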