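---
title: "Methods: simultaneous depth and signal-to-noise normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simultaneous depth and signal-to-noise normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(s3norm)
```

## The problem

Binned read-count tracks from ChIP-seq or ATAC-seq experiments differ
across samples in two largely independent ways: **sequencing depth** (SD),
which rescales every bin uniformly, and **signal-to-noise ratio** (SNR),
which changes how strongly peak regions stand out over background. A single
scale factor — whether computed from total signal or from background bins —
can correct depth but not SNR: after scaling, a low-SNR sample's peaks
remain weak relative to a high-SNR sample's, or its background becomes
inflated. Quantile normalization forces identical value distributions,
which over-corrects in the opposite direction: when samples genuinely have
different numbers of peaks, background bins in the peak-poor sample are
promoted to peak-level values.

## The model

This package uses a monotone two-factor power law. With $Y_i$ the signal in
bin $i$ of the target sample,

$$Y_{\mathrm{norm},i} = \alpha\, Y_i^{\beta}
\qquad\Longleftrightarrow\qquad
\log Y_{\mathrm{norm},i} = \log\alpha + \beta \log Y_i ,$$

with $\alpha, \beta > 0$. In log space $\alpha$ shifts the signal and
$\beta$ rotates it, so depth and SNR can be adjusted at once while ranks
are preserved exactly. The two parameters are pinned down by two matching
constraints against a reference sample:

$$\mathrm{mean}(Y_{\mathrm{ref,pk}}) = \mathrm{mean}(\alpha\, Y_{\mathrm{tar,pk}}^{\beta}),
\qquad
\mathrm{nzmean}(Y_{\mathrm{ref,bg}}) = \mathrm{nzmean}(\alpha\, Y_{\mathrm{tar,bg}}^{\beta}),$$

where *pk* is the set of **common peak** bins (peaks in every sample being
normalized), *bg* the **common background** bins (background in every
sample), and *nzmean* the mean over strictly positive values. The
underlying assumptions: epigenetic events shared by all samples carry equal
true signal (so common-peak means should match), and common background is
technical noise (so it should be equalized). Non-zero means are used for
the background because zero-inflated tracks would otherwise drag the mean
by their zero count rather than by their noise level. Peak means use all
common-peak bins, zeros included, since a zero inside a shared peak is
informative.

The reference is by default the sample with the best SNR, estimated by
FRiP (fraction of reads in peaks); per-bin median or mean synthetic
references, or an explicit sample, are also supported
(`select_reference()`).

## Solving the two constraints

Eliminating $\alpha$ through the peak equation,
$\alpha(\beta) = \mathrm{mean}(Y_{\mathrm{ref,pk}}) / \mathrm{mean}(Y_{\mathrm{tar,pk}}^{\beta})$,
leaves one scalar equation

$$g(\beta) = \alpha(\beta)\,\mathrm{nzmean}(Y_{\mathrm{tar,bg}}^{\beta}) -
\mathrm{nzmean}(Y_{\mathrm{ref,bg}}) = 0,$$

solved by Newton–Raphson from $\beta = 1$ with the analytic derivative
$\tfrac{d}{d\beta}\,\mathrm{mean}(Y^{\beta}) = \mathrm{mean}(Y^{\beta}\ln Y)$.
All power means are evaluated in log space (log-mean-exp), so wide
excursions in $\beta$ cannot overflow even when target values reach
$10^{16}$ (as they do when inverting strong transforms). Convergence is
declared at $|g| \le 10^{-6}$ relative to the background target (at most
100 iterations). If a Newton step leaves the domain
$\beta \in [10^{-3}, 10^{3}]$, the solver falls back to bracketed
bisection over a log-spaced scan of that interval; a scan with no sign
change, or with more than one, is reported as an error rather than
resolved silently — more than one root would contradict the model's
uniqueness premise and has not been observed. The constraint residuals at
the solution are stored on the returned model so every fit is auditable.

$\beta$ is constrained positive: monotonicity (rank preservation) is
essential to the method, so a configuration that would need $\beta \le 0$
is a failure, not something to clamp.

## The negative-binomial background model

Downstream signal tracks are $-\log_{10}$ p-values of the per-bin counts
under a null for background fluctuation. Binned ChIP counts are
overdispersed (variance above mean), so the null is negative binomial
rather than Poisson. The convention used throughout is
$P(X = k) = \binom{k+s-1}{k} p^k (1-p)^s$, with mean $sp/(1-p)$ and
variance $sp/(1-p)^2$, so that the moment estimators are

$$p = \frac{\sigma^2 - M}{\sigma^2}, \qquad s = \frac{M^2}{\sigma^2 - M},$$

with $M$, $\sigma^2$ the mean and variance of the counts in the fitting
regions. Because the tracks are zero-inflated, the production estimator
uses only the non-zero bins: with $NM1$ and $NM2$ the mean and mean square
of the non-zero counts, the parameters satisfy

$$p_0 = (1-p)^s,\qquad
p = 1 - \frac{NM1}{NM2 - NM1^2\,(1 - p_0)},\qquad
s = NM1\,(1-p_0)\,\frac{1-p}{p},$$

solved by fixed-point iteration on $p_0$ (tolerance $10^{-8}$, at most
1000 iterations). Two numerical points matter here:

* **Initialization.** The iteration is started at the empirical zero
  fraction of the data (when raw counts are supplied). Starting at
  $p_0 = 0$ works for moderately dispersed counts — the closed-form
  fixture $NM1 = 8/3$, $NM2 = 32/3$ converges to
  $(p, s, p_0) = (0.5, 2, 0.25)$ from either start — but for sparse
  tracks (non-zero mean near 1) the first step from 0 can leave the
  parameter domain even though a valid root exists.
* **The degenerate root.** $(p_0, s) \to (1, 0)$ is always a fixed point,
  and when heavy peak bins contaminate the fitting set the interior root
  can disappear entirely, leaving only the degenerate one. The estimator
  therefore refuses solutions with $p_0 > 1 - 10^{-3}$ or $s < 10^{-6}$;
  `fit_nb_background()` additionally offers `trim` (exclude the top
  fraction of bins by value before fitting, used genome-wide before any
  regions are known) and an opt-in Poisson fallback
  ($\lambda$ = mean of the fitting bins, the $p \to 0$ limit of the NB)
  for tracks whose trimmed counts are no longer overdispersed.

### Local background scaling

As in local-lambda peak calling, the shape parameter is scaled per bin by
the control: $s_{\mathrm{local},i} = s \cdot r^{\mathrm{ctrl}}_i / M^{\mathrm{ctrl}}$,
where $r^{\mathrm{ctrl}}_i$ is the maximum of the control's genome-wide
mean and its 1 kb, 5 kb and 10 kb window means centred on bin $i$ (windows
truncate at chromosome ends; all in counts-per-bin units), and
$M^{\mathrm{ctrl}}$ is the control mean over the fitting regions. Without
a matched control the IP serves as its own control and the 1 kb window is
dropped, so a narrow true peak does not fully cancel its own significance.
No depth scaling is applied to the control before forming
$r^{\mathrm{ctrl}}_i / M^{\mathrm{ctrl}}$: the ratio is normalized by the
control's own mean, so depth cancels.

The p-value is the upper tail $P(X \ge x)$ evaluated as the regularized
incomplete beta $I_p(x, s_{\mathrm{local}})$ — the continuous extension of
the NB survival function — so the non-integer values produced by
normalization are scored directly. At $s_{\mathrm{local}} = 1$, $p = 0.5$
this reduces to the geometric tail $0.5^x$ (the closed form the tests pin
down), and as $p \to 0$ at fixed mean it converges to the Poisson tail.
Computation is done in log space and the output capped at 323 (the double
underflow limit), configurable.

## Regions at a stated FDR, and the two-pass bootstrap

Per-sample peak masks come from Benjamini–Hochberg applied across all bins
to the p-value track, at FDR 0.1 by default (a raw p-value cutoff is
available for compatibility). BH across genome-wide bin tests is the
standard choice where only "FDR" is stated. Training masks are always
called on the raw-count p-value tracks: normalization parameters must not
depend on their own output.

The background model is defined on the common background regions, which in
turn require p-value tracks — a circularity `normalize_set()` resolves in
two passes: (1) per sample, a provisional genome-wide fit with `trim` =
0.01 (so strong peaks cannot dominate the moments), provisional tracks and
masks, and their intersection; (2) a refit on those provisional common
background bins, definitive tracks and masks, and the final common
regions. The fitted $\alpha/\beta$, region counts and FRiP per sample are
all surfaced in the pipeline log so fits can be audited.

By default the raw counts are normalized and p-value tracks are then
generated from the normalized counts; `signal = "pvalue"` instead
normalizes the $-\log_{10}$ p-value tracks themselves.

## Baselines

For comparison the package ships three reference normalizers behind the
same interface: **tsnorm** (total-signal scaling; depth only),
**qtnorm** (rank matching against the reference distribution; target ties
receive the mean of the tied reference span), and **manorm-simplified**
(least-squares line through the M–A cloud of the common peaks, pseudocount
1, applied genome-wide). The MA baseline is deliberately a *linear
simplification* of the published robust-fit method and is labelled
`manorm-simplified` in all outputs to avoid overclaiming equivalence;
comparisons against it are qualitative (direction of background
inflation), never numeric.

## The synthetic data generator

`simulate_tracks()` emulates the heterogeneity the method is built for:

* 2 chromosomes × 5 Mb at 200-bp bins (50,000 bins) — large enough for
  stable means, small enough that the full pipeline runs in seconds;
* sparse NB(s = 1, p = 0.25) background (mean 1/3 counts per bin, ~75%
  zero bins at unit depth), as real 200-bp binned tracks are;
* per-sample depth factors 1 / 0.5 / 2 and peak enrichments 60 / 40 / 20×
  over background, giving FRiP values from ~0.25 to ~0.5 — echoing real
  compendia where mapped reads span an order of magnitude and FRiP spans
  0.1–0.9;
* 150 peaks per sample of 5 bins (1 kb) each (~1.5% of bins), half drawn
  from a core shared by all samples. Shared peaks carry a further 2×
  enrichment: constitutively active regions are typically the strongest
  peaks in real data, and they are exactly what the normalization trains
  on.

`construct_transformed_target()` inverts the model —
target $= (\mathrm{ref}/\alpha)^{1/\beta}$, zeros fixed — so the exact
solution of a refit is known, optionally followed by Poisson resampling.
All randomness is locally seeded; the caller's RNG state is untouched.

What the generator does **not** emulate: mappability and GC bias,
fragment-level structure, copy-number variation, peak-width variation, and
multi-component background mixtures. Passing tests on simulated data
therefore demonstrate correctness of the estimators and the pipeline
plumbing under the stated model, not robustness to every artefact of real
tracks.

## Problem sizes and the noisy-recovery regime

Parameter-recovery checks run at $10^5$ bins: noise-free transforms with
$\alpha \in [0.1, 10]$, $\beta \in [0.3, 3]$ recover to better than
$10^{-3}$ relative; the Newton solution agrees with a dense grid search
(step $10^{-4}$) to grid resolution.

Recovery under Poisson resampling is evaluated on a *deep-coverage*
reference (depth factor 500, background ~170 counts/bin) with
$\alpha \in [0.5, 2]$, $\beta \in [2/3, 1.5]$. The reason is structural,
not cosmetic: resampling replaces each target value $t$ with
$T \sim \mathrm{Pois}(t)$, and
$E[T^{\beta}] \approx t^{\beta}\bigl(1 + \tfrac{\beta(\beta-1)}{2t}\bigr)$,
a Jensen bias of order $1/t$ that no estimator of the matching equations
can remove. Moreover $\alpha$ amplifies any bias in $\beta$ by
$d\log\alpha/d\beta \approx -\log(\text{peak level}) \approx -6$. At
shallow coverage this bias reaches tens of percent of $\alpha$; recovery
is only a well-posed question where the noise is perturbative. The
tolerance itself (5%) is untouched by this choice.

## Degenerate inputs and tie-breaks

Empty common peak or background regions abort with a "fitting impossible"
error suggesting a relaxed FDR. FRiP ties in reference selection break to
the first sample in input order, deterministically. Bedgraph input not
aligned to bins is length-weight averaged (uncovered stretches count as
zero); intervals on unknown chromosomes or past chromosome ends are
rejected by default, skippable/truncatable by flag. Partial terminal bins
are kept so total counts are conserved. Written tracks print 6 significant
digits by default; the write/read round trip is the identity to that
precision, and pipeline reruns with the same inputs are byte-identical.

## Known limitations

* The core assumption — equal true signal in common peaks — fails by
  design in time-course or degradation experiments where shared peaks
  genuinely decay; none of those samples should serve as reference, and a
  spike-in or externally validated stable peak set should anchor the fit
  instead.
* A single NB component cannot describe backgrounds whose non-zero counts
  are too heavy-tailed (the collapse guard will say so); the Poisson
  fallback is deliberately conservative for such tracks.
* The simplified MA baseline is not a faithful reimplementation of the
  published robust-fit method.
* FRiP-based reference selection depends on the called masks; at very
  stringent FDR with weak samples the reference choice can be unstable
  even though each individual fit remains well-defined.
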