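---
title: "Network pharmacology for multi-herb prescriptions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network pharmacology for multi-herb prescriptions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
library(dplyr)
```

herbnet implements the inference chain used to predict which phytochemicals
in a multi-herb prescription drive a pharmacological activity — here,
inhibition of platelet aggregation — and the two downstream experimental
checks: mass-spectrometric identity confirmation and dose-response IC50
analysis. This vignette explains each stage's model, the tunable parameters
and their defaults, the synthetic-data generator used to validate the
pipeline, and the numerical and design choices that were genuinely open.

## The inference chain

The pipeline is a funnel. Each stage filters or re-scores the output of the
previous one:

1. **Drug-likeness screen.** Every collected compound is scored with the
   quantitative estimate of drug-likeness (QED) and with Veber's oral
   bioavailability rule. QED maps eight physicochemical descriptors — MW,
   ALOGP, HBA, HBD, PSA (Å²), ROTB, AROM, ALERT — through asymmetric
   double-sigmoid desirability functions $d_i(x)$ and combines them as

   $$\mathrm{QED} = \exp\!\left(\frac{\sum_i w_i \ln d_i}{\sum_i w_i}\right),$$

   the geometric mean when the weights are equal. The desirability
   parameters are the published fitted constants, shipped in the package and
   never refit; each $d_i$ is normalized by its published maximum so the
   most drug-like value scores 1, and floored at 0.003 before the logarithm
   so QED is strictly positive. Veber's rule passes a compound iff
   ROTB ≤ 10, HBA + HBD ≤ 12 and PSA ≤ 140, all inclusive. The *expected
   active compounds* (EAC) are those with QED ≥ `qed_min` (default 0.3) and
   a Veber pass. The printed rule text reads "sum of HAB and HBD"; we read
   HAB as a typo for HBA. The QED variant (unweighted vs the published
   mean-optimal weights) is selectable; unweighted is the default because
   the source procedure names only the eight properties, not a weight set.

2. **Target intersection.** Predicted compound targets (gene symbol +
   prediction probability) are intersected with a disease gene list carrying
   relevance scores. "False-positive" predictions are removed with a
   probability filter (`min_probability`, default 0: only zero-probability
   rows drop — the natural reading when the upstream predictor emits a
   probability). Potential targets are the intersected genes with relevance
   score at or above a cutoff; with `cutoff = "mean"` the arithmetic mean of
   the intersected genes' scores is used. Because relevance scores are
   right-skewed in practice, a mean cutoff retains a minority of genes. The
   boundary is inclusive: a gene scoring exactly the cutoff stays.

3. **PPI topology.** A scored protein–protein interaction edge list
   (STRING-style; the 0–1000 integer dialect is auto-detected) becomes an
   undirected simple graph after dropping self-loops, collapsing duplicate
   orientations (keeping the maximum score) and thresholding at
   `min_score` (default 0.7, "high confidence"). On the subgraph induced by
   the potential targets we compute degree, betweenness and closeness with
   Cytoscape-compatible conventions: betweenness excludes endpoints and is
   normalized by $(n-1)(n-2)/2$; closeness is the reciprocal mean distance
   to *reachable* nodes (component-restricted), 0 for isolated nodes, so
   disconnected graphs are legal. *Key targets* satisfy degree ≥ 10,
   betweenness ≥ 0.001 and closeness ≥ 0.430, all inclusive. The published
   key-target table reports centralities recomputed on the induced
   key-target subnetwork (its degree column satisfies the handshake lemma
   for the reported edge count, and several rows sit below the selection
   threshold), so both stages — selection on the potential-target network,
   recomputation on the subnetwork — are exposed separately.

4. **Pathway enrichment.** Key targets are tested for over-representation
   against GMT gene sets with the one-sided hypergeometric tail
   $P[X \ge k]$, $X \sim \mathrm{Hypergeom}(N, K, n)$, adjusted across
   tested pathways by Benjamini–Hochberg. The default background is
   $N = 20{,}000$ (protein-coding genome order of magnitude) because ORA
   tools rarely disclose theirs; it is configurable, as is the conservative
   EASE variant ($P[X \ge k-1]$). Results are ranked by ascending p-value
   (the phrase "highest p-value" in informal write-ups means most
   significant), ties broken by descending overlap then pathway id, and the
   top `top_k` (default 20) are retained. Gene ratio is $k/n$.

5. **Integrated network.** Herbs, EAC, key targets and retained pathways
   form a multipartite graph with edges only between adjacent layers.
   EAC with no key-target link are dropped — they carry no information at
   this stage (and this is why a 95-compound screen can yield a 94-compound
   network). Compounds are ranked by total degree, counting herb links as
   well as target links (a compound with 1 herb and 13 targets has degree
   14); ranking by target links only is available. The *key components* are
   the maximal-degree tie class by default (`"max-tie"`), or a top-k.

6. **Mass identification.** Candidate formulas are parsed (Hill notation),
   monoisotopic masses summed from a packaged isotope-mass table, and the
   deprotonated ion's m/z computed as $M - m_\mathrm{H}$ with
   $m_\mathrm{H} = 1.0078250319$ Da — the neutral-hydrogen convention,
   which reproduces vendor-style "calculated m/z" columns to four decimals.
   The physically complete form (adding the electron mass, +0.00054858 Da)
   is available via `electron_correction = TRUE`. Peaks are matched to all
   candidates within a ppm tolerance; unmatched peaks are reported, not
   dropped.

7. **Dose-response.** Replicate aggregation percentages across
   concentrations are fitted with the four-parameter logistic

   $$y(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
   {1 + (c/\mathrm{IC}_{50})^{s}},$$

   by Levenberg–Marquardt least squares on the log-concentration scale. No
   published fitting procedure accompanies typical IC50 tables, so the 4PL
   is used as the field default. Treated-versus-control comparisons use
   Welch's two-sample test by default (a rank test is available), with
   significance stars at the conventional printed thresholds 0.05 and
   0.001.

## Numerical choices in the 4PL fitter

Initialization is deterministic: bottom/top from the per-concentration mean
extrema, IC50 from the geometric mean of the two grid concentrations
bracketing the half-maximal response, slope 1. Parameters are
box-constrained (bottom ≥ 0, top ≤ 110 %, slope ∈ [0.1, 10]); if the
constrained solver rejects a start (which can happen on perfect-fit data
whose solution lies exactly on a bound) a fixed ladder of fallback starts is
tried, ending with an unconstrained fit that is accepted only if its
solution respects the box. Fits require ≥ 4 distinct positive
concentrations; flat data (no dynamic range) raise an error rather than
returning a spurious IC50, and the `converged` flag reports the optimizer's
own verdict. The estimate is equivariant under rescaling of the
concentration axis, and refitting the fitted values reproduces the
parameters (a fixed point), both of which are tested.

## The synthetic study generator

Because the original analysis depends on 2022 snapshots of several
databases and unpublished raw assay traces, the package validates itself on
seeded synthetic studies with planted, recorded ground truth
(`generate_study()`). Defaults mirror the study design the pipeline targets:

| parameter | default | emulates |
|---|---|---|
| `n_herbs` / `n_compounds` | 9 / 119 | prescription size and collected compounds |
| `frac_fail_qed` / `frac_fail_veber` | 0.1 / 0.1 | 24 of 119 compounds fail the screen → 95 EAC |
| `n_disease_genes` | 400 | disease gene list (~397 intersected genes) |
| `relevance_dist` | lognormal(0.5, 1) | right-skewed relevance scores, so a mean cutoff keeps a minority |
| `n_pathways`, sizes | 110, 10–80 | the pathway collection with one planted enriched set |
| planted key compounds / hub targets | 4 / 4 | the key-component and hub-target signal |
| dose-response | 6-point log grid 1–100 µM, n = 4, SD 2.4 % | replicate aggregometry with vehicle-level noise, top ≈ 83 % |

The disease gene list size is not published anywhere we can check, so the
default is an order-of-magnitude choice and fully configurable.

Planting works as follows. Descriptors are drawn from a drug-like box whose
worst corner still passes both screens (desirability is separable and
unimodal per coordinate, so corner enumeration bounds the box); QED-failures
are forced out of range on MW/ALOGP/ALERT while remaining Veber-passing, and
Veber-failures exceed only the ROTB bound while keeping QED ≥ 0.3 — the two
failure sets are disjoint and never overlap the planted key compounds. The
PPI is a preferential-attachment backbone plus an Erdős–Rényi block over the
top-relevance disease genes (the dense disease module that makes a degree
threshold meaningful); each planted hub is then wired to more neighbours
than the maximum backbone degree, biased toward high-relevance disease
genes, which guarantees the hubs occupy the top of the degree distribution
and stay central in the potential-target subnetwork. All planted key
compounds share one identical target set (the hubs plus a shared
high-relevance block), so they form the exact maximal-degree tie class of
the integrated network. The planted pathway contains every hub plus the
shared block. Dose-response series are 4PL curves with IC50 drawn log-
uniformly in 15–60 µM and truncated Gaussian noise.

All randomness flows from one root seed through named substreams (one per
table), so regenerating a bundle is byte-identical and changing one
component leaves the others' draws untouched.

What the generator does *not* emulate: real chemistry (SMILES are absent;
descriptors are not derivable from structures), real gene nomenclature,
correlated descriptor distributions, literature-biased target prediction,
or assay artifacts such as drift and heteroscedastic noise. Passing the
planted-recovery tests therefore demonstrates that the pipeline's *logic*
recovers a known signal under realistic sizes and noise — not that any
particular biological conclusion is correct.

## Problem sizes in the test suite

The suite exercises: exhaustive hypergeometric enumeration for all
parameterizations with N ≤ 25; brute-force centrality oracles on 200 random
graphs of ≤ 8 nodes; 100 synthetic end-to-end runs for enrichment ranking
(the planted pathway must rank first in ≥ 95), with key-component recovery
scored on 20 of them (≥ 90 % required); 50 noisy IC50 recoveries (median
relative error ≤ 5 %); and 10,000 null simulations of the Welch comparison
(empirical size within [0.035, 0.065] at nominal 0.05). These sizes were
chosen to make the Monte-Carlo bounds comfortably stable under the fixed
seeds.

## Known limitations

* The Benjamini–Hochberg adjustment is the standard step-up; adjusted
  values are *not* a fixed point of re-adjustment (a second application
  re-multiplies by $m/i$), which the test suite documents explicitly.
* Centrality conventions follow one tool family (component-restricted
  closeness); the global $(n-1)/\sum d$ closeness is not currently exposed.
* Only the deprotonated adduct is registered; the registry is extensible
  but positive-mode adducts are out of scope.
* The 4PL fitter assumes monotone dose-response; biphasic curves will
  either fail to converge or be summarized misleadingly, and the IC50 of a
  curve whose plateau lies outside the tested range is an extrapolation.
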