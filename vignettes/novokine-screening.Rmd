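---
title: "Models and methods behind the novokine screening pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the novokine screening pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novoscreen)
```

`novoscreen` implements the analysis side of a combinatorial agonist
screen: fusing pairs of receptor-binding protein domains with flexible
linkers, screening the resulting library by phospho-flow in primary human
immune cells, and triaging hits by dose-response shape and receptor
knockouts. Because the quantitative raw data of such screens are rarely
redistributable, the package pairs every analysis stage with a seeded
synthetic generator that emulates the data-generating process; all
statistical guarantees quoted below are verified by the test suite on that
generator. This vignette records the models, the statistics, and the
numerical design choices.

## The registry and the combinatorics

A binder registry maps each binding domain to one receptor subunit.
Receptors carry a *chain class*: `common` chains (γcommon, βcommon, gp130,
IL10Rβ, IL12Rβ1, and — following its behaviour in pairing screens —
IFNAR1) are shared assembly platforms, `private` chains carry the
specificity and the STAT identity, and `non_cytokine` covers TNF-family,
checkpoint, and growth-factor receptors with no intrinsic pSTAT output.

An ordered all-by-all library over *n* binders has exactly *n²* constructs
(both orientations of each heterotypic pair, one orientation of each
homotypic fusion) and *n(n+1)/2* unordered receptor pairings when targets
are distinct: 1,089 constructs and 561 pairings for the packaged 33-binder
set, 576 for a 24-binder pilot. Orientation is tracked because signaling
output depends on it in practice; the default linker is the medium 2×GGS
used at library scale, with repeats configurable. Rigid constructs are
metadata only — no geometry is computed.

Three registry fields are packaged *placeholders*, flagged as such: the
affinities of the nine newly designed binders (drawn once from the
plausible 1–200 nM design range; per-binder values are not tabulated
anywhere reusable), the `binder_sequences_synthetic.fasta` sequences
(random, length-matched; real sequences are not redistributable), and the
cell-panel receptor densities (round literature-scale numbers encoding who
expresses what, not measured copy numbers). Prior-work binders carry `NA`
affinity rather than an invented number; the ternary model substitutes a
neutral 50 nM for missing values.

## The signal models

**Ternary (dual-receptor) mechanism.** Signaling is driven by the bridged
receptor₁–ligand–receptor₂ complex. We use the closed-form bridging
approximation

$$T(d) = \alpha\, r_1 r_2\, \frac{d}{(K_1 + d)(K_2 + d)},
\qquad S(d) = E \cdot \frac{T}{T + K_{1/2}},$$

with $d$ the dose, $K_i$ the arm affinities, $r_i$ the receptor surface
densities, $\alpha$ a bridging-efficiency scale (default 1), and
$K_{1/2} = 50$ in bridging units at densities of order 1000. This is not a
full mass-balance solve; it is the simplest form with the properties the
analysis relies on, each of which is an analytic oracle in the tests:
$T$ is symmetric in the two arms, zero when either density is zero
(knockouts are exact interventions), single-peaked in dose with maximum at
$d = \sqrt{K_1 K_2}$, saturable below the peak, and declining beyond it
(the high-dose hook, where excess ligand occupies each receptor with
separate molecules). At the 250 nM screening dose with nanomolar binders
and densities ≥ a few hundred, $T \gg K_{1/2}$, so the screen operates near
saturation and planted efficacy $E$ is approximately the realized
fold-signal.

**Clustering mechanism.** Some constructs signal by self-association of a
single domain aggregating one receptor. We model this as
$S(d) = s \cdot (r/1000) \cdot \mathrm{occ}(d) \cdot \log(1 + d/K)$ —
occupancy times logarithmic growth — which is strictly increasing on any
bounded dose range and depends on one receptor only. The log-growth form
is a stand-in chosen for its qualitative non-saturation; no data constrain
its exact shape, and only the saturating/non-saturating distinction is
used downstream. The aggregated receptor is taken to be the
signaling-competent arm (the one with nonzero canonical pSTAT weights):
aggregating a receptor with no STAT output produces no phospho-flow
readout and would make the planted truth untestable.

**STAT signature.** Private chains dictate the pSTAT profile: the
signature of a pairing is the sum of the canonical weight vectors of its
private receptor(s), falling back to both receptors' weights for pairings
without a private STAT-competent chain (common–common fusions,
cytokine–growth-factor hybrids). The profile is scaled so its dominant
weight is 1, and flexible (non-rigid) constructs receive an additive
pSTAT5 leak λ (default 0.15, configurable) — relaxed dimer geometries bias
output toward STAT5, which is how IL-4-like and IL-21-like fusions pick up
pSTAT5 beyond their canonical pathways. Pairings with no STAT-competent
receptor stay at zero regardless of λ. Canonical weights are a packaged,
editable catalogue of textbook assignments (IL4Rα→pSTAT6, IL7Rα/IL2Rβ/
TSLPR→pSTAT5, IL21Rα/IL10Rα/gp130→pSTAT3, IFNAR/IFNLR→pSTAT1,
IL12Rβ1→pSTAT4, zero vectors for non-STAT receptors).

## The synthetic screen

A screen table is one row per well: three unstimulated control replicates
per donor × cell type × pSTAT stratum, one stimulated record per construct
(`mfi = baseline · (1 + S·w) · noise`), and one inactive record per
single-binder control. Defaults mirror standard screen practice: a
six-population PBMC panel (CD4/CD8 T, NK, B, monocytes, DCs; common chains
broad, private chains lineage-restricted; a `U937_like` engineered line
expressing everything is available for knockout work), three donors with
lognormal per-receptor density multipliers (sdlog 0.3), multiplicative
lognormal well noise at CV 0.15, a 250 nM single-point dose, and a 4-plex
pSTAT1/3/5/6 readout. Dose-response experiments report the mean of
triplicate wells per dose, the conventional replication for a targeted
assay.

Ground truth plants, per construct, a mechanism (ternary, clustering,
inactive), an efficacy (lognormal, median 3, sdlog 0.5 — a spectrum from
marginal to strong responders), and a pSTAT profile. Only *detectable*
constructs are eligible to be active: their dominant pSTAT output must lie
on a measured pathway and the receptor pair must be co-expressed somewhere
in the panel. Planting rates are per-receptor (γcommon 0.42; gp130,
IL7Rα, IL10Rα, IL21Rα, βcommon, TrkA, IFNAR1 at 0.20; 0.02 otherwise),
with exact rounded counts so planted fractions are stable across seeds,
and a 14:4 ternary:clustering split among actives. All of this emulates
the screening outcome structure the analysis stages must recover; it does
not reproduce any real construct's behaviour.

What the generator deliberately does **not** model: kinetics (the assay is
a 15-minute snapshot), event-level flow data (input is per-well summarized
MFI), plate/batch effects, receptor competition with endogenous cytokines,
endotoxin artifacts, and trimolecular (three-receptor) fusions. Passing
tests therefore demonstrate that the analysis recovers truth *under this
noise model*, not that it is robust to every artifact of real screens.

## Hit calling: normalization, the 6×SEM rule, reproducibility

Intensities are log-transformed and then normalized to 0–1 per donor ×
cell type × pSTAT stratum over all conditions including controls (minimum
→ 0, maximum → 1). The log step is standard flow-cytometry practice —
fold changes are the meaningful signal and multiplicative well noise is
symmetric on the log scale; it also makes the calling statistic's null
behaviour match its Gaussian closed form. The call itself is invariant to
any affine transformation of the (log) intensities within a stratum, so
normalization convention does not affect error rates.

A condition is *signaling* when its normalized score exceeds the mean of
the stratum's three unstimulated controls by more than $k = 6$ standard
errors. Under a Gaussian null this rule has an exact reduction: with $n=3$
controls, $(x - \bar{x}) / (s\sqrt{4/3}) \sim t_2$ and the threshold sits
at $t = k/2 = 3$, so the per-test false-positive rate is
$P(t_2 > 3) \approx 0.0477$ — verified by Monte Carlo in the tests and the
acceptance script. A result is *reproducible* when called in at least 2 of
3 donors, which drives the per-case false rate to
$3p^2(1-p) + p^3 \approx 0.65\%$.

Two guards complete the rule. First, the control SEM is floored at 0.025
normalized units (≈ 2.5% of the stratum range): with only three
replicates the sample SEM occasionally collapses by chance, and an
unfloored mean + 6×SEM rule then calls *every* condition in that stratum a
hit — measured on planted-inactive screens, such bursts dominate the false
calls and, accumulated over a construct's ~24 cell × pathway strata,
inflate per-receptor activation rates by 10–15 percentage points. The
floor converts the rule into "6×SEM, and in any case a minimal effect of
0.15 normalized units", a conventional minimal-effect requirement; real
responses clear 0.3–0.5 units, so sensitivity is unaffected, while the
per-case false rate drops to ~10⁻⁴. Second, for strata where natural-
cytokine positive controls respond weakly, an adaptive cutoff escalates
$k$ by a factor γ (default 1.5 at effect threshold θ = 0.2 normalized
units; both configurable, as no canonical values exist) so that noise in
unresponsive strata is not misread as signal.

Per-receptor activation rates count constructs (not strata): a construct
is active when any cell × pathway combination is reproducible, and the
rate for receptor *R* is the active fraction of constructs involving *R*.
Single-binder controls are scored like constructs but never counted. In
the restricted-expression PBMC panel, weak actives (efficacy ≲ 1) are
sometimes missed, so recovered rates sit 3–5 points below planted ones;
in a uniformly expressing context recovery of a planted 42% γcommon rate
is within ±5 points (verified at fixed seed).

## Dose-response classification

`fit_hill()` fits the four-parameter Hill model
$r(d) = e_0 + (e_{max}-e_0)\, d^h / (d^h + EC_{50}^h)$ by bounded
Levenberg–Marquardt least squares (Hill coefficient in [0.5, 4], EC50
within the positive dose range × [10⁻², 10²]), multi-started from five
EC50 values spread geometrically across the dose range, best residual
wins; a bounded quasi-Newton fallback covers LM failures, and failure from
all starts is flagged rather than guessed.

`classify_dose_response()` reproduces the saturable / non-saturating /
no-signal triage with a deterministic, unit-free rule:

1. **No-signal gate** — the amplitude read from the two highest versus two
   lowest doses (two points at each end so single wells cannot decide)
   must exceed a noise floor, supplied by the caller as 3× the control
   spread on the response scale.
2. **Model comparison** — the bounded Hill competes by AIC against a
   monotone *unbounded* alternative, $r = a + b\log(1 + d/K)$ with its own
   fitted dose scale $K$ (profiled over a geometric grid; linear least
   squares given $K$). Giving the alternative a dose-scale parameter
   matters: a fixed log-dose line misfits the low-dose knee of genuinely
   non-saturating data and hands the AIC to the Hill for the wrong reason.
3. **Plateau check** — the slope of the *fitted* Hill between the two top
   doses, relative to fitted amplitude per natural-log dose unit, must be
   below ε = 0.1. Using the fitted monotone curve makes the check robust
   to well noise and to the high-dose hook: observed post-peak decline
   cannot drag the slope estimate upward.

Saturable = Hill wins AIC *and* plateaus; otherwise non-saturating. The
rule is invariant to affine response rescaling. On 60 generator-produced
series (20 per mechanism, the active panels drawn from top-scoring screen
hits, as triage panels are in practice) accuracy is 92–97% across seeds
with zero saturable↔no-signal confusions; residual errors are strong
clustering series whose last-decade growth is within noise of a plateau.

## Knockout dependence

`knockout_test()` simulates a targeted validation in a cell context
expressing both receptors (default the `U937_like` line): wild-type assay,
then one assay per single-receptor knockout, each with three stimulated
replicates and three controls per donor. A donor is positive when the
majority of its replicates pass the 6×SEM call; positivity must be
reproducible in ≥2 of 3 donors. A receptor is *required* when its knockout
abolishes the call, and knockouts are exact interventions on the signal
model (density set to zero), so ternary constructs are dual-dependent and
clustering constructs lose signal only with their aggregated receptor.
The replicate-majority rule keeps the probability of a false "knockout
still signals" verdict (which would wrongly mark a receptor dispensable)
at ~10⁻⁴ per receptor. The wild type must signal for a verdict to exist —
knockouts are only interpretable in a signaling parental line — and a
non-signaling wild type raises an error rather than returning a verdict.

## Determinism and problem sizes

Every stochastic stage takes an explicit seed and derives per-stage
substreams from it; identical configuration and seed reproduce every
output file byte for byte, and all internal ordering is locale-independent
(radix sorts) so results do not depend on the session's collation.
The test suite and acceptance script run the full 1,089-construct,
three-donor, six-cell-type, 4-plex screen (~81,000 wells, a few seconds),
a 2×10⁵-draw Monte Carlo of the calling statistic, 60 nine-dose
classifier series, and pilot-scale (576) end-to-end pipeline runs — sizes
chosen so that every statistical check has comfortable power while the
whole suite completes in well under a minute per stage.

## Known limitations

- The bridging signal is an equilibrium approximation; absolute EC50s and
  hook positions are not calibrated to any measured construct.
- The clustering dose-response form is qualitative; only its
  non-saturation is meaningful.
- Planted activation rates and efficacy distributions are structural
  emulations of a screening outcome, not estimates from data; recovered
  hit counts should be read as self-consistency checks of the calling
  chain.
- The hit-calling rule inherits the paper-style design of three controls
  per stratum; with so few replicates the SEM floor is load-bearing, and
  analyses that remove it should expect bursty false calls.
- Multikine-style trimolecular fusions, rigid-geometry potency modeling,
  and event-level flow analysis are out of scope.
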