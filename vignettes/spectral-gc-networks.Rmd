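---
title: "Spectral Granger-causality brain networks: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral Granger-causality brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcnet)
```

## The analysis in one paragraph

`gcnet` implements a resting-state directed-connectivity analysis for
source-level EEG: per subject, the frequency-domain (Geweke) Granger
causality between every ordered pair of cortical regions is estimated from
bivariate autoregressive models and averaged into the theta (4–8 Hz),
alpha (8–12 Hz), beta (14–30 Hz) and gamma (30–40 Hz) bands. The resulting
weighted directed networks are sparsified by edgewise group-contrast
permutation t-tests, summarised by global/local efficiency and
outdegree/indegree centrality, reduced to directional fronto-posterior
connectivity indices, and compared between groups with linear mixed models
and Bonferroni-corrected planned contrasts. A vector-autoregressive
cohort simulator with an analytic spectral-GC oracle makes every stage
testable without any real recordings.

## The spectral Granger-causality model

For a region pair $(x_i, x_j)$ we fit the bivariate VAR($p$) model

$$
\begin{pmatrix} x_i[n] \\ x_j[n] \end{pmatrix}
 = \sum_{k=1}^{p} A_k
\begin{pmatrix} x_i[n-k] \\ x_j[n-k] \end{pmatrix} + e[n],
\qquad \operatorname{Cov}(e) = \Sigma,
$$

by ordinary least squares on lagged regressors (series are mean-centered;
the residual covariance uses denominator $T - p$). OLS rather than
Levinson/Burg recursion was chosen because it is the standard GC practice,
is exactly reproducible, and lets all $R(R-1)/2$ pairs of one subject
share a single Gram matrix of lagged cross-moments, so each pair costs
only a small linear solve.

With transfer function
$H(f) = \left(I - \sum_k A_k e^{-i 2 \pi f k / f_s}\right)^{-1}$ and
spectrum $S(f) = H(f)\, \Sigma\, H(f)^*$, the spectral GC from $i$ to $j$
is the log ratio of the target's total power to its intrinsic power,

$$
GC_{i \to j}(f) \;=\;
\ln \frac{S_{jj}(f)}
   {S_{jj}(f) - \left(\Sigma_{ii} - \Sigma_{ij}^2 / \Sigma_{jj}\right)
    \left| H_{ji}(f) \right|^2 },
$$

which follows from attributing the correlated part of the innovations to
the target: writing $e_i = \tilde e_i + (\Sigma_{ij}/\Sigma_{jj}) e_j$
with $\tilde e_i \perp e_j$ decomposes $S_{jj}$ exactly into
$(\Sigma_{ii} - \Sigma_{ij}^2/\Sigma_{jj})\,|H_{ji}|^2$ (causal) plus
$|H_{jj} + (\Sigma_{ij}/\Sigma_{jj}) H_{ji}|^2 \Sigma_{jj}$ (intrinsic).
Values are clamped at zero against round-off; clamp events are counted in
the run report, never silently discarded.

Defaults mirror the reference acquisition/analysis settings: $f_s = 500$
Hz, $p = 30$ (GC is stable for $p \ge 30$; a regression test checks
band-averaged GC moves by less than 15% between $p = 30$ and $p = 40$),
frequency resolution $0.1$ Hz, giving 2501 grid samples from DC to
Nyquist. Band edges are inclusive at both ends: 8 Hz contributes to both
theta and alpha, 30 Hz to both beta and gamma, and the 12–14 Hz gap
belongs to no band. Only bivariate (pairwise) GC is implemented —
conditional/multivariate GC is a known limitation, not an option.

### The integral identity and when it holds

For a fitted pair, the time-domain measure
$\ln(\sigma^2_{\text{reduced}} / \sigma^2_{\text{full}})$ (univariate
versus bivariate innovation variance) should equal
$\frac{1}{\pi}\int_0^{\pi} GC(\lambda)\, d\lambda$. The package tests
this identity — but it is a conditional identity: equality requires the
intrinsic spectral factor to be minimum-phase. A randomly drawn stable
VAR whose channel-own lag polynomial is unstable (the channel is
stabilised only by the coupling) violates the condition, and the integral
then genuinely exceeds or falls short of the time-domain value by tens of
percent at any fitting order. The test-model family therefore draws
coefficients until both channel-own polynomials are stable, which
guarantees the condition; the instantaneous-causality gate
($\ln(\Sigma_{ii}\Sigma_{jj}/\det\Sigma) < 0.01$) additionally removes
fits where the decomposition is ambiguous between the two channels.

## The synthetic cohort generator

No recordings ship with the package; the generator defines the study
conditions instead. Each *source* region carries one rhythm as a damped
oscillator: a complex pole pair at radius $r = e^{-\pi\, bw / f_s}$ and
angle $2\pi f_0 / f_s$ (lag-1/2 self coefficients $2r\cos\theta$, $-r^2$),
placing the −3 dB resonance width at $bw$. Band centers/bandwidths are
theta 6/3, alpha 10/3, beta 22/6, gamma 35/5 Hz — typical resting-state
peak locations with physiological widths. Directed influence is a lag-1
cross coefficient. The motif sends slow-band coupling frontal → posterior
(top-down) and fast-band coupling posterior → frontal (bottom-up), plus
feed-forward coupling among same-band sources so that group-difference
networks contain triangles — without them the difference network is
bipartite and neighbourhood-based segregation measures (local efficiency)
are degenerately zero on sparse matrices.

Two calibration rules keep the generator stationary at every scale
without retuning:

* **Resonance-relative strength.** A raw coefficient that is harmless for
  a broad resonance destabilises a narrow one, because the source's
  resonance amplifies the loop by roughly $1/(1-r)$. Coupling is
  therefore specified as `strength` × $(1 - r)$.
* **In-degree normalisation.** Parallel feedback paths add; a per-edge
  gain that is safe in a 6-region toy makes the 68-region motif
  non-stationary. Each edge is divided by its target's in-degree, fixing
  every region's total incoming coupling budget (the directed analogue of
  synaptic scaling).
* Same-band source pairs are coupled acyclically (lower index → higher
  index): a feedback loop between two resonators at the same frequency is
  amplified by both resonances and cannot be made both stationary and
  appreciably coupled.

The default `strength = 0.8` yields single-pair spectral GC peaks of a
few tenths of a nat. Every constructed model must pass the companion
spectral-radius gate ($< 1$) or construction fails loudly; simulation
discards a 1000-sample burn-in. The true generative order (default 3) is
deliberately far below the analysis order $p = 30$, so the estimator is
exercised in the over-fitting-tolerant regime it claims to handle.

The group effect is purely multiplicative on cross-coefficients
(`default_effect_profile()`, 30% attenuation), with the innovation
covariance shared between groups: the high group differs in connectivity,
never in channel power. The 30% figure is a calibration choice — no
effect size for real cohorts is available — picked as a moderate,
detectable-at-$n{=}25$/group effect.

`demo_cohort()` freezes the desk-scale conditions used by the worked
examples and recovery checks: 25 + 25 subjects, 10 regions (4 frontal /
3 posterior / 3 excluded), 30 s at 250 Hz, theta top-down and gamma
bottom-up coupling attenuated by 30%. Alpha- and beta-band group effects
then arise only through the oscillators' spectral tails — deliberately,
so the recovery check does not merely read back a planted per-band flag.

### What the generator does *not* emulate

Linear Gaussian dynamics only: no source leakage or volume conduction, no
1/f background, no artifacts, no nonstationarity, no inter-subject
anatomical variability (groups share one model up to noise realisation).
Passing recovery checks therefore show the *pipeline* recovers planted
directed coupling under its own assumptions — they say nothing about
inverse-solution quality or leakage-induced spurious GC in real source
space.

## The analytic oracle

`analytic_spectral_gc()` computes GC from *true* coefficients, never from
data. For 2-region models the Geweke formula applies directly and
exactly. For larger models the pairwise marginal is a VARMA process; it
is represented by its exact autocovariance sequence (companion-form
Lyapunov equation, solved by doubling) and reduced to a high-order
bivariate AR model via Yule–Walker, after which the same formula applies.
The truncation order (default 200) leaves errors far below test
tolerances for spectral radii up to ~0.96; pairs with no direct or
indirect path short-circuit to exactly zero. Because the oracle shares
only the final Geweke formula with the estimator — coefficients come from
exact moments, not regression — estimator-vs-oracle agreement is a
genuine two-route check.

## Sparsification and inference

Edgewise two-tailed permutation t-tests (pooled-variance Student t;
Welch available) with one shared shuffle sequence across edges — valid
because each edge is compared only against its own permutation
distribution — and the exact-test convention
$p = (1 + \#\{|t_{\pi}| \ge |t_{obs}|\})/(n_{\pi} + 1)$, so $p > 0$
always. Degenerate edges (zero variance at working precision) get
$t = 0$, $p = 1$. Edges with uncorrected $p < .05$ are retained, all
others zeroed in every subject — deliberately uncorrected, as specified
for this noise-reduction step, and deliberately circular (the same cohort
defines mask and downstream statistics); the `sparsify = FALSE`
configuration reproduces the complete-matrix control analysis.

Graph metrics use the reciprocal length transform $L_{ij} = 1/A_{ij}$
(stronger edges are shorter; shortest paths maximise summed weight, the
convention of the standard brain-connectivity toolboxes), directed
shortest paths, and $1/\infty = 0$ for disconnected pairs. Local
efficiency follows the verbal definition — mean over nodes of the global
efficiency of the neighbour subgraph with the node removed — not the
cube-root weighted variant found in some toolbox versions; the
neighbourhood is the union of in- and out-neighbours (the choice is not
standardised; it is stated here and isolated in one helper). Nodes with
fewer than two neighbours contribute zero. Node-level inference reuses
the permutation machinery on centrality vectors with Bonferroni factor =
number of nodes, per band and per metric.

## Directional indices

With frontal ($N_f = 22$) and posterior ($N_p = 18$) clusters from the
packaged 68-region table, four subnetwork averages are formed per subject
and band, e.g. OutFP = (sum of connections from Outdegree-significant
frontal regions into all posterior regions) / $(N_p \times N_{fo})$, and
combined as CI = mean of the defined Out/In components. Three choices
needed a decision:

* An index whose significant-node set is empty is **undefined** (`NA`),
  never zero — zero would fabricate an absent-connectivity observation;
  group contrasts drop and count the missing subjects.
* A combined index with exactly one defined component equals that
  component (averaging over available components preserves scale).
* The packaged posterior cluster is a reconstruction: the source table's
  posterior column is truncated in the available text, so the 9 bilateral
  parieto-occipital labels were chosen from the atlas's parietal and
  occipital rows excluding insula, isthmus cingulate and postcentral to
  satisfy $N_p = 18$. The file (`inst/extdata/dk68_partition.tsv`) is
  plain TSV and user-replaceable.

The InPF subnetwork size uses $N_p$ = all *posterior* regions, consistent
with the symmetric definition (the source text's "frontal" there is an
evident typo).

## Group-level statistics

Planned contrasts are classical pooled-variance two-sample t-tests,
Bonferroni-corrected with family sizes 4 (bands, for GE/LE) and 8
(band × direction cells, for CI). The omnibus test delegates to `lme4`
(`value ~ group * band (* direction) + (1 | subject)`, ML) with Wald
type-II chi-squares from `car`; a singular fit warns and defers to the
per-band contrasts. These are off-the-shelf components by design — the
package's contribution is the connectivity pipeline, not the mixed model.

## Numerical choices

* GC denominators are clamped at $10^{-12} S_{jj}$ and negative round-off
  GC at 0; both are counted and reported.
* Band selection uses a $10^{-9}$ Hz tolerance on edge comparisons so the
  0.1 Hz grid's floating-point representation cannot drop an endpoint.
* Permutation label shuffles are drawn in blocks of 500 to bound memory
  at the 68-region, 5000-permutation scale.
* Per-pair fit failures inside a subject mark the edge missing (`NA`),
  never zero, and are listed in the completeness report.

## Problem sizes used in checks

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own validation conditions: 2-region estimator checks at
$T = 60\,000$ samples and $p = 30$; the Geweke identity on 20 random
minimum-phase models at $T = 30\,000$, $p = 20$; graph-metric oracles on
50 random digraphs of 5–8 nodes against exhaustive path enumeration;
permutation calibration on 20 null cohorts of 20 + 20 subjects with 1000
shuffles; and the end-to-end recovery on `demo_cohort()` (25 + 25
subjects, 10 regions, 30 s at 250 Hz) over 10 seeds, requiring the full
qualitative signature — lower high-group theta/alpha GE and LE, lower
theta CI$_{fp}$, lower gamma CI$_{pf}$ — in at least 90% of seeds. The
full-scale configuration (68 regions, 109 subjects, 2-minute recordings,
5000 permutations) runs through exactly the same code paths.

## Known limitations

Pairwise GC cannot distinguish direct from mediated influence (the chain
test documents this: indirect 1→3 GC is positive by construction).
Sparsification reuses the cohort that defines the mask; inference on the
sparse matrices is descriptive of that cohort, with the no-threshold
variant as the control. The simulator's linearity means estimator
robustness to nonlinear or nonstationary dynamics is untested. Real-EEG
preprocessing (filtering, re-referencing, ICA) and source reconstruction
are out of scope: the pipeline starts at regional time series.
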