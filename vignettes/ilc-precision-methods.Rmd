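---
title: "Interlaboratory precision for compound-specific δ13C: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interlaboratory precision for compound-specific δ13C: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilcprec)
```

## The statistical model

An interlaboratory comparison (ILC) asks how precise an analytical method is
when `p` laboratories measure the same test items. For every cell — one
(analyte, sample) combination — `ilcprec` assumes the classical one-way
random-effects model

$$y_{ij} = m + B_i + e_{ij}, \qquad
  B_i \sim N(0, s_L^2), \quad e_{ij} \sim N(0, s_r^2),$$

where $B_i$ is laboratory $i$'s systematic bias under reproducibility
conditions and $e_{ij}$ its replicate error under repeatability conditions.
The quantities reported per cell are

* $s_r$ — **repeatability SD**, the pooled within-laboratory SD;
* $s_L$ — **between-laboratory SD**, from the between-laboratory mean square
  $MS_B$ via $s_L^2 = (MS_B - s_r^2)/\bar n$, with the standard effective
  replicate number $\bar n = (N - \sum_i n_i^2/N)/(p-1)$, which equals $n$
  exactly for balanced cells;
* $s_R = \sqrt{s_r^2 + s_L^2}$ — **reproducibility SD**;
* relative SDs $100\,s/|\text{mean}|$ in percent (the mean δ13C of honey
  sugars is negative, hence the absolute value);
* the **repeatability and reproducibility limits** $r = 2.80\,s_r$ and
  $R = 2.80\,s_R$: the largest absolute difference to expect (at ~95%
  probability) between two results obtained under repeatability or
  reproducibility conditions. The factor is exactly 2.80, the convention
  used in printed precision tables, not a recomputed
  $1.96\sqrt2 \approx 2.77$.

Measurement uncertainty follows the reproducibility route: the standard
uncertainty of a single laboratory's result is $u = s_R$ and the expanded
uncertainty $U = k\,s_R$ with coverage factor $k = 2$ by default
(`expanded_uncertainty()`).

### Degenerate cells

When $MS_B \le MS_W$ the method-of-moments estimate $s_L^2$ is not positive.
The estimate is then truncated at zero, $s_R$ is **set equal to** $s_r$
(exactly, not approximately), the result carries an `sL_degenerate` flag and
a warning states that between-laboratory reproducibility is understated. The
comparison $MS_B \le MS_W$ uses a relative guard of $10^{-9}$ so that cells
constructed to sit exactly on the boundary are classified as degenerate
rather than left to floating-point representation luck. A perfectly constant
cell (all values identical) reports $s_r = s_L = s_R = 0$ without the flag.
This situation is not hypothetical: a cell in which two laboratories report
large duplicate differences that mask each other in the Cochran test can
easily push $MS_W$ above $MS_B$.

### Unbalanced cells

Laboratories that report a single replicate are retained, not dropped; the
$\bar n$ formulation above handles unequal $n_i$ after outlier removal or
incomplete reporting. A cell in which *every* laboratory is a singleton has
no repeatability information and is reported as a per-cell failure. The
report metadata records this choice.

## Outlier screening

Per cell, three classical tests are applied to whole laboratories:

* **Cochran**: $C = s_\max^2 / \sum_i s_i^2$ on within-laboratory variances —
  flags a laboratory with outlying replicate scatter;
* **single Grubbs** (two-sided): $G = \max_i |\bar y_i - \bar y| / s$ on
  laboratory means;
* **double Grubbs**: the reduced-sum-of-squares ratio for the two lowest /
  two highest laboratory means jointly, for the masking situation where two
  similar extremes hide each other from the single test.

The tests run on **laboratory means** (Grubbs) rather than raw replicates:
with duplicate designs the laboratory mean is the natural unit of
between-laboratory comparison, and removal is always of the entire
laboratory for that cell. The screening policy follows the straggler/outlier
convention: significant at 5% → flagged, kept; significant at 1% → removed.
Both levels are configurable (`screening_policy()`); the 1%/5% defaults are
the classical choice. Tests run in the order Cochran → single Grubbs →
double Grubbs (variances before means; the pair test only when the single
test finds nothing), the sequence restarting after every removal. Removal is
capped at 2/9 of the cell's initial laboratories so screening cannot consume
the dataset. Masking in the Cochran test (second-largest within-laboratory
variance ≥ 0.8 × largest) is detected and *warned about*, never "fixed":
masked values stay in the evaluation.

Every screening event — removal, flag, skip, stop, masking warning — is an
append-only audit record; `replay_screening()` applied to the raw cell and
the records reproduces the cleaned cell exactly, which the test suite checks
on randomized outlier-injected cells.

### Critical values

Critical values are computed, never hard-coded, so any $(p, n, \alpha)$
works:

* **Cochran** — for one fixed laboratory,
  $s_i^2/\sum_j s_j^2 > c \iff F_{\nu,(p-1)\nu} > (p-1)c/(1-c)$ with
  $\nu = n - 1$, so a union bound over laboratories gives
  $c = Q/(Q + p - 1)$ with $Q = F^{-1}(1-\alpha/p;\ \nu, (p-1)\nu)$. The
  bound is exact for $c \ge 1/2$ (two shares cannot both exceed one half)
  and agrees with a 500 000-draw Monte-Carlo quantile to ~0.001 at the
  study design $(p = 14, n = 2)$; a seeded Monte-Carlo method is available
  and is what the self-calibration checks use.
* **single Grubbs** — closed form via Student's $t$:
  $G_{crit} = \frac{p-1}{\sqrt p}\sqrt{t^2/(p-2+t^2)}$,
  $t = t^{-1}(1 - \alpha/(2p);\ p-2)$.
* **double Grubbs** — no convenient closed form; lower quantiles of the null
  ratio are tabulated by Monte Carlo (500 000 draws) under an internal fixed
  seed derived only from $(p, \alpha)$, cached per session. Critical values
  are therefore reproducible constants independent of user seeds.

The suite verifies that all three tests hold their nominal size at
$\alpha \in \{0.01, 0.05\}$ within the 99% binomial envelope over 10 000
simulated null cells of the study design.

## The synthetic ILC generator

The study's raw per-laboratory data were never published; only the per-cell
summary table is available (shipped as `honey_saccharide_precision()`). All
pipeline testing therefore runs on synthetic data from `simulate_ilc()`,
which draws exactly the model above: normal laboratory biases plus normal
replicate errors, with outliers injected *explicitly* (`bias_shift` adds an
offset to one laboratory's bias; `variance_inflation` multiplies its
replicate-error SD) so ground truth stays known. Heavy-tailed contamination
is representable only through such injections — that is deliberate, keeping
every simulated dataset's truth auditable.

Choices worth stating:

* **Bias sharing.** By default one bias per (laboratory, analyte) is shared
  across samples: laboratories are systematically biased, which is what a
  between-laboratory reproducibility component means. `shared_bias = FALSE`
  decouples cells.
* **Determinism.** One master seed; every draw comes from a substream seeded
  by a stable hash of its coordinates (lab, analyte, sample), so the same
  seed is byte-identical and adding an analyte never perturbs existing
  cells. The suite asserts both properties.
* **The study-design preset** (`honey_ilc_spec()`): 14 laboratories, 6
  samples, 5 analytes, duplicates. True means and per-analyte $(s_r, s_L)$
  for fructose, glucose, di- and trisaccharides are taken from the built-in
  published summary (medians across samples; $s_L$ as the median of
  $\sqrt{s_R^2 - s_r^2}$). Oligosaccharides were reported in the study
  design but have no published precision table; the preset uses
  $\mu = -25$‰, $s_r = 0.25$‰, $s_L = 0.45$‰ — slightly noisier than
  trisaccharides, as the hardest fraction to separate and integrate.
* **Inter-analyte independence.** Real within-laboratory errors are likely
  correlated across analytes (shared chromatography and interface); the
  generator defaults to independence because no published estimate of that
  correlation exists. Precision statistics are computed per cell, so this
  affects only joint-behaviour questions, not the per-cell estimates.

What passing simulation tests does and does not show: they validate the
estimators and tests *under the model the evaluation assumes* (normality,
independence, additive lab bias). Real LC–IRMS data add drift,
integration-window and background-correction artefacts and non-normal lab
effects; no synthetic test certifies behaviour under those.

## Numerical and reporting conventions

* **Rounding happens only at render time** (`precision_summary()`): means
  and SDs to 2 decimals, relative SDs to 1, limits to 2 — half-up
  ("commercial") rounding as in printed tables, with a tiny relative guard
  against binary representation just under a .5 boundary. All statistics and
  all test comparisons run at full precision.
* Published tables derive limits and relative SDs from *unrounded* SDs and
  print everything afterwards; recomputing $2.80\,s$ from a printed
  2-decimal $s$ can therefore legitimately differ from the printed limit by
  up to $2.80 \times 0.005$. `recompute_derived()` documents and the
  acceptance tests enforce exactly this propagated-rounding agreement; about
  two thirds of the published derived entries reproduce digit-for-digit.
* Relative SDs at a zero mean are undefined and flagged, never `Inf`.
* δ-notation conversions take the reference 13C/12C ratio as an explicit
  parameter (IAEA consensus VPDB value as default); every statistic in the
  pipeline operates purely on δ values and is independent of it.

## Problem sizes in the test suite

The suite simulates at the sizes the statistics are designed for: 14
laboratories × duplicates per cell; 2 000 simulated studies for
parameter recovery (means of $\hat s_r^2$ and $\hat s_R^2$ within two
Monte-Carlo standard errors of their truths); 10 000 null cells per test and
level for size calibration; 500 random cells for oracle equivalence
(ANOVA = duplicate-shortcut = two-pass brute force to $10^{-10}$ relative);
100 randomized injected cells for audit replay. Critical-value tabulations
use 500 000 draws and are cached.

## Known limitations

* Only the classical remove-and-reestimate evaluation is implemented; robust
  alternatives (ISO 5725-5 Algorithm A, Q/Hampel) are out of scope.
* The Horwitz ratio benchmark is deliberately absent: the Horwitz function
  was fitted for mass-ratio measurands and does not apply to isotope-ratio
  results.
* Conformity assessment against honey purity criteria (to which these
  precision figures would feed) is not part of the package.
* The wide "reporting template" importer uses this package's own column
  convention (`<analyte>_<replicate>`); there is no universal template
  standard.
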