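---
title: "Detecting mutation hotspots in protein functional domains by bootstrap resampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mutation hotspots in protein functional domains by bootstrap resampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhf)
```

## The problem

Disease-associated missense variants are rarely spread evenly along a
protein. When a catalog of single amino acid mutations concentrates inside
particular functional domains — a voltage sensor, a pore loop, a
calmodulin-binding helix — that concentration is itself evidence about
mechanism. The question this package answers is whether an observed
concentration is larger than chance placement would produce, domain by
domain, for a pre-specified set of domain annotations.

The motivating application is the voltage-gated potassium channel subunit
Kv7.2 (KCNQ2), in which hundreds of epilepsy variants have been described,
ranging from mild benign familial neonatal epilepsy (BFNE) to severe
epileptic encephalopathy (EE). The package, however, only sees three
inputs: a protein sequence (or a residue interval of one), an ordered table
of non-overlapping domain intervals, and a variant catalog.

## The resampling model

Let $X$ be the analysis region, $L_X$ its residue count, and let the domain
map contain $J$ non-overlapping intervals with lengths $L_j$. Let $S$ be
the multiset of observed single amino acid mutation positions with
$|S| = n$ (distinct substitutions at one codon count separately; identical
duplicates are collapsed upstream). $D_j$ counts members of $S$ inside
domain $j$.

The null hypothesis is that mutations are equally likely at every residue
of $X$. Under it we draw $K$ bootstrapped sets $\tilde S(k)$ of size $n$,
each position sampled independently and uniformly with replacement from the
$L_X$ residues, and tally $\tilde D_j(k)$. The empirical expectation is

$$\hat E_j = \frac{1}{K} \sum_k \tilde D_j(k),$$

and the right-tailed empirical p-value takes the add-one permutation form

$$\hat P_j = \frac{1 + \#\{k : \tilde D_j(k) \ge D_j\}}{K + 1},$$

whose range $[1/(K+1),\, 1]$ matches the $K+1$ denominator and guarantees
super-uniformity under the null ($P(\hat P_j \le \alpha) \le \alpha$): the
test can only be conservative, never anti-conservative, and never reports
an exact zero. We adopt this form deliberately; the arithmetically
degenerate variant in which the $+1$ sits inside the sum over $k$ evaluates
to approximately 1 for every input and cannot be what any working
implementation computes. The p-values are corrected for the $J$ comparisons
of one analysis by Bonferroni's rule, $p_{adj} = \min(1, J\,\hat P_j)$, and
a domain is called a hotspot when $p_{adj}$ falls below the significance
level (default 0.05; textual output stars the conventional 0.05 / 0.01 /
0.005 thresholds).

Because the null places each mutation in domain $j$ independently with
probability $L_j / L_X$, the null count is exactly
$\mathrm{Binomial}(n, L_j/L_X)$. `exact_binomial_pvalue()` computes this
tail by direct summation and serves as an analytic oracle: the resampling
p-value must agree with $(1 + K b)/(K+1)$, where $b$ is the binomial tail,
within Monte-Carlo error. The test suite checks this over random
configurations, and the convergence of $\hat E_j$ to $n L_j / L_X$ over
$K \in \{100, 1000, 10000\}$.

### Parameters and conventions

* `K` — resampling iterations, default 10,000. At this depth the smallest
  attainable raw p-value is $1/10{,}001$, so the smallest corrected value
  is $J/10{,}001$ (about 0.0014 for $J = 14$), comfortably below the 0.005
  reporting threshold.
* `seed` — one master integer seed; a run is bit-reproducible from
  `(seed, K, n, region)` regardless of how iterations are chunked, because
  all $K \times n$ draws come from a single vectorized stream.
* Sampling is with replacement (the bootstrap). Sampling without
  replacement is available behind `replace = FALSE` for sensitivity
  analysis only; it is not the published procedure.
* Coordinates are 1-based and inclusive on both ends throughout.
* Residues outside every domain stay in the sampling space but carry no
  hypothesis: the null draws from the region, not from the union of
  domains. Domain maps are required non-overlapping so the $D_j$ form a
  clean tally; overlapping inputs are rejected loudly rather than
  double-counted.

### Which variants enter $S$

The test is defined for single amino acid changes only. `select_mhf_input()`
keeps missense and single-residue deletions (plus silent variants for
control runs), and excludes nonsense, frameshift, splice-site, whole- or
partial-gene deletion and non-initiation records, because a truncating or
non-coding event removes one or more domains and has no single residue
position under the null. Substitutions of the initiator methionine are also
excluded: loss of the start codon is a translation defect, not a
domain-level missense event. Distinct substitutions at one codon count
separately in $|S|$; exact duplicates (same position, reference and
alternate) collapse to one record. In the Kv7.2-style catalog this
arithmetic gives $|S| = 126$ missense $+\,4$ deletions $= 130$.

## Severity association

Whether hotspot membership tracks clinical severity is tested with an
exact 2×2 test: rows are variant-in-hotspot-domains vs elsewhere, columns
severe-EE vs the other pathogenic severities. `fisher_exact_2x2()` computes
the hypergeometric exact p-value directly; the two-sided value follows the
minimum-likelihood convention (summing all margin-consistent tables whose
point probability does not exceed the observed one, with the customary
$10^{-7}$ tie tolerance), which is the dominant convention in standard
statistical software, and the suite verifies agreement with both a
brute-force enumeration oracle (to $10^{-12}$ for all tables with total
$\le 30$) and `stats::fisher.test()`. Because published analyses of this
kind rarely print the exact stratification behind their association
p-value, `build_contingency()` exposes the hotspot set and severity split
as explicit parameters instead of hard-coding one canonical form.

## The synthetic-data harness

Every statistical claim in the package is testable without external data
through `simulation_design()` / `simulate_clustered_catalog()`. Each
simulated mutation falls with probability $\pi$ uniformly inside a
designated hotspot set (domains chosen proportionally to length, so $\pi$
is interpretable as total excess hotspot mass and the expected hotspot
count has the closed form $n(\pi + (1-\pi) L_{hot}/L_X)$), and otherwise
uniformly over the region; $\pi = 0$ is exactly the null. Severity labels
are Bernoulli with rate $\rho$ inside hotspots and a stated baseline
elsewhere. Tokens are emitted in parseable one-letter notation with
distinct alternates at repeated positions, so a simulated catalog survives
the duplicate-collapsing rule; one residue supports at most 19 distinct
substitutions, which bounds usable $n$ per residue and is why the
uniformity tests use regions much longer than $n/19$.

`run_calibration()` runs the full pipeline on independently seeded
replicate catalogs and reports per-domain rejection rates. The shipped
checks use the study-scale conditions: $n = 130$, $K = 10{,}000$, 500
uniform-null replicates for the type-I check (raw rejection at
$\alpha = 0.05$ must stay within $0.05 + 3\,\mathrm{SE}$; the add-one form
keeps it below nominal) and 200 replicates at $\pi = 0.4$ into a 5%-length
hotspot for power (corrected $p \le 0.005$ in $\ge 95\%$ of sets; observed
rate is 1). A monotonicity check runs a smaller common-random-numbers grid
over $\pi$, reusing the same design seeds at each $\pi$ to cancel
simulation noise at desk scale.

## The worked example

The package ships a deterministic synthetic Kv7.2-like worked example
(`kv72_synthetic_fixture()` and the `kv72_*_synthetic.*` files under
`inst/extdata`). It mirrors the published aggregate structure of the KCNQ2
epilepsy compilation — 194 records splitting into 10 gene deletions, 17
splice-site, 10 nonsense, 25 frameshift, 2 non-initiation, 126 missense and
4 single-residue deletions, hence $|S| = 130$; a 14-domain full-length map
and a 9-domain C-terminal map; clustering designed into S4, the pore loop
and S6 (full-length) and into helix B and the helix B-C linker (C-terminal
tail), with severe-EE enrichment in those domains and uniformly placed
silent/nonpathogenic controls. It is synthetic: the sequence is generated,
the domain boundaries are literature-plausible rather than transcribed, and
the individual variant records are constructed, not compiled from patient
reports. Tests against it therefore demonstrate that the pipeline detects
the designed pattern at the designed sample sizes — including that the
control catalogs trigger nothing — not that it reproduces any particular
clinical dataset. The distribution-level guarantees come from the oracle
and calibration suites above, which use no fixture at all.

## Electrophysiology analysis equations

Functional follow-up of hotspot variants in this field rests on a small set
of analysis equations, implemented here so their numerics are tested:

* **Leak subtraction** — pointwise subtraction of a control recording
  (e.g. cells without the channel) at matched voltages and time base.
* **Conductance** — chord conductance $G(V) = I_{peak}(V)/(V - V_{rev})$
  from steady-state peak currents and a supplied reversal potential,
  normalized to $G/G_{max}$. Steps at the reversal potential are excluded
  with a warning (zero driving force). Tail-current analysis is out of
  scope; steady-state is the documented default.
* **Boltzmann activation** —
  $G/G_{max} = 1/\{1 + \exp((V_{1/2} - V)/k)\}$, fitted by
  Levenberg-Marquardt with data-driven starting values. The argument of
  the exponential is the full ratio $(V_{1/2} - V)/k$; $k$ is the slope
  factor in mV and the fitted curve equals 0.5 at $V = V_{1/2}$ by
  construction.
* **Activation time constant** — a single exponential
  $I(t) = A(1 - e^{-t/\tau}) + C$ from stimulus onset, one $\tau$ per
  voltage; published reports of this quantity rarely state the functional
  form, so the single-exponential convention is documented here rather
  than assumed silently.
* **Phosphatase-driven decay** — for a $\ge 10$ s depolarization that
  activates a voltage-sensitive phosphatase (depleting PIP$_2$), the ratio
  $I(10\,\mathrm{s})/I_{peak}$ per voltage and its percent decay. The
  ratio is invariant to uniform current scaling and undefined for
  non-positive peaks.

Recovery is verified on forward-simulated traces
(`simulate_step_currents()`): noiseless fits recover parameters to
numerical precision; with Gaussian noise of $\sigma = 0.03$ on $G/G_{max}$
over 13 voltages and 200 replicates the median absolute $V_{1/2}$ error
stays under 1 mV with bias under 0.5 mV, and $\tau$ is recovered within
10% at 5% amplitude noise. Wet-lab reference values for this channel
family (wild-type $V_{1/2} \approx -26.8$ mV, maximal decay
$\approx 53$% at +100 mV) are context for interpreting real recordings,
not targets the synthetic harness can or should reproduce.

## Numerical and design notes

* The hot path tallies all $K \times n$ uniform draws through an integer
  residue-to-domain lookup and a single `tabulate()`, so a full-length
  run at $K = 10{,}000$, $n = 130$ takes well under a second.
* p-values exactly at a threshold: hotspot flags use $p_{adj} \le \alpha$,
  stars use strict `<` at 0.05/0.01/0.005, matching the usual reporting
  conventions.
* Degenerate inputs fail loudly: empty mutation sets refuse to run
  (a $|S| = 0$ "result" would be vacuous), all-zero contingency tables are
  undefined, flat traces cannot yield a time constant, and a Boltzmann fit
  reports non-convergence with the optimizer's diagnostics instead of
  returning garbage.
* Fisher tie tolerance: the $(1 + 10^{-7})$ relative tolerance on point
  probabilities mirrors the convention of the standard implementation so
  that two-sided values agree to enumeration *and* to `fisher.test`.
* Known limitations: the null is uniform per residue by construction —
  no trinucleotide/CpG mutability weighting, no constraint scores, no
  transcript-level coordinate lifting, and no nucleotide-level HGVS
  parsing. These are deliberate non-goals; the hypothesis being tested is
  placement given occurrence, under the stated null.

## A short session

```{r example, fig.width = 9, fig.height = 3.5}
fx <- kv72_synthetic_fixture()
res <- run_mhf(fx$catalog, fx$map_full,
               config = bootstrap_config(K = 10000, seed = 1))
print(res)

tab <- build_contingency(fx$catalog, fx$map_full, fx$hotspots)
fisher_exact_2x2(tab)

plot_lollipop(fx$catalog, fx$map_full)
```
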