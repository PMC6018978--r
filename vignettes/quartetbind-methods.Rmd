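---
title: "Quantifying floral-quartet formation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying floral-quartet formation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetbind)
```

## The cooperative two-site binding model

MIKC-type MADS-domain transcription factors such as SEP3 bind CArG-box
elements as dimers; proteins that tetramerize recruit a second dimer to a
nearby second box far more readily than the first dimer bound. On a
two-site probe the equilibrium populations of free probe ($Y_0$), probe
with one dimer ($Y_2$) and probe with two dimers ($Y_4$) follow a
partition function in the applied dimer amount $[P_2]$:

$$Z = 1 + \frac{2[P_2]}{k_{d1}} + \frac{[P_2]^2}{k_{d1} k_{d2}},$$

with $Y_0 = 1/Z$, $Y_2 = (2[P_2]/k_{d1})/Z$ and
$Y_4 = ([P_2]^2/(k_{d1}k_{d2}))/Z$. The statistical factor 2 reflects the
two equivalent empty sites available to the first dimer. The model assumes
the two boxes are intrinsically identical, that binding is at equilibrium
in each lane, and that band intensities report probe fractions linearly.

Because in vitro translation yields unknown absolute protein
concentrations, applied volume stands in for $[P_2]$, and $k_{d1}$,
$k_{d2}$ are relative quantities. Their ratio
$k_{coop} = k_{d1}/k_{d2}$ is invariant under any rescaling of the
protein axis — the package's scale-invariance test asserts this property
directly on fitted values.

### Fitting

`fit_cooperative()` minimizes the unweighted sum of squared residuals of
all three fraction curves jointly over all lanes. Equal weighting is the
natural choice when all three bands are quantified by the same
densitometry and no per-band error estimates exist. Optimization is over
$(\log_{10} k_{d1}, \log_{10} k_{d2})$, which enforces positivity without
constraints, using Levenberg–Marquardt (`minpack.lm::nls.lm`). The
objective can have local minima when the intermediate band is nearly
flat, so the optimizer is multi-started from a $3 \times 3$ grid of
log-spaced values spanning the observed protein range; the lowest-RSS
start wins. MINPACK termination codes 1–4 are reported as converged
(code 4, gradient orthogonal to the residual, is what an exact
zero-residual fit returns); anything else sets `converged = FALSE` rather
than failing silently.

Lanes are ingested as measured fractions and renormalized to sum to 1
when the raw sum is within 0.05 of 1 (a typical densitometry wobble);
larger deviations indicate a quantification problem and are rejected.
Lanes whose intermediate band was undetectable are retained as zeros: the
alternative — dropping them — would discard exactly the observations that
drive high-cooperativity estimates toward the censoring ceiling.

### Censoring at the detectability ceiling

Strong cooperativity empties the intermediate band: its peak height is
$\frac{2/\sqrt{k_{coop}}}{2 + 2/\sqrt{k_{coop}}}$, about 0.09 at
$k_{coop} = 100$ and 0.03 at 1000. Once the fitted $Y_2$ never exceeds
the detection threshold $\delta$ (default 0.02) at any observed lane, or
the fitted ratio exceeds the ceiling (default 200), the fit reports
`censored = TRUE` with `kcoop` pinned at the ceiling, to be read as a
lower bound. The ceiling of 200 reflects the practical determinability
limit of gel-based assays of this design; both $\delta$ and the ceiling
are arguments.

### Saturation binding

Dimer affinity for a single box is modeled as
$[PD] = P_t [D]/(k_d + [D])$ with free probe $[D]$ as the independent
variable; `free_probe_from_total()` converts applied (total) probe where
only that is recorded. A series flat at the plateau carries no
information on $k_d$; the fit then runs into the small-$k_d$ boundary and
is flagged (`boundary = TRUE`, `converged = FALSE`).

## What the synthetic data emulate — and what they do not

`simulate_titration()` and `simulate_saturation()` draw from the forward
models and perturb with additive Gaussian noise per band (sd 0.05 by
default, in fraction units; for saturation series, in units of the
plateau), clip to $[0,1]$, zero values under a configurable detection
floor, and renormalize each lane. With `sd = 0` the simulators return the
model values bitwise, so zero-noise simulations are exact fixed points of
the predictors. All generators are pure functions of their parameters and
seed (`withr::with_seed`, leaving the session RNG untouched). Default
ladders mirror the underlying assays: 12 log-spaced protein amounts from
0.05 to 3 volume units, probe amounts from 0.05 to 32.

`simulate_family()` draws alignment columns independently from per-column
residue distributions. `preset_profiles()` encodes the conservation
structure the statistics assume: a SEP3-like preset with near-invariant
leucine (probability 0.95) at the 12 interface leucines
(101, 108, 115, 120, 123, 128, 131, 135, 154, 157, 164, 171), an AP3-like
preset with threonine/glutamine replacing the leucines at positions
157/164 of the tetramerization interface, a PI-like polar variant, and a
diffuse background. What the generator does **not** emulate: phylogenetic
correlation between sequences, covariation between columns, alignment
error, and indels. Passing tests therefore validate the per-column
statistics and the pipeline plumbing, not robustness to tree structure or
misalignment in real collections.

The 0.05 noise sd is a modeling choice (lane-to-lane quantification error
is not published); at that level the median relative error of recovered
$k_{coop}$ over 50 seeded replicates is about 6% at $k_{coop}=1$, 11% at
10, 26% at 50 and 34% at 100 — the growth with $k_{coop}$ is intrinsic,
because the informative intermediate band shrinks toward the noise floor,
the same physics that imposes the ≈200 ceiling. Exhaustive grid search
over the two log-parameters confirms the least-squares surface has its
global optimum at the reported estimates, so this spread is an
information limit, not an optimizer artifact.

## Conservation scoring

`column_similarity()` scores every unordered residue pair of a column
with BLOSUM40 normalized by row maxima. "Dividing by the maximum value of
the respective amino acid" is ambiguous for a pair $(a,b)$ with different
row maxima, so the default is the symmetric mean

$$s(a,b) = \tfrac12\Big(\frac{B(a,b)}{\max_x B(a,x)} +
  \frac{B(a,b)}{\max_x B(b,x)}\Big),$$

which makes the score independent of pair order; both one-sided variants
remain available via `normalization=`. Row maxima are taken over the 20
canonical residues, where they coincide with the diagonal, so identical
columns score exactly 1. Negative normalized scores are kept: the column
statistic is a mean, and flooring at 0 would compress exactly the
variable columns the interacting/non-interacting comparison needs to
distinguish. Gaps and `X` are excluded pair-wise rather than column-wise,
so columns overlapping the four-residue deletion common in PI-subfamily
K-domains remain analysable from their non-gap residues. BLOSUM40 (over
BLOSUM62 and relatives) matches the ~40% average identity of K-domains
across subfamilies.

The interacting-site class defaults to 15 positions: the 12 leucines plus
V104, I111 and M150. Only the leucines are unambiguous; the remaining
three are a documented default (hydrophobic heptad-core positions, with
M150 part of the tetramerization interface's hydrophobic stripe) that
users with structural interface assignments should replace via
`site_partition()`.

### Mann–Whitney U

Similarity profiles are heavily tied (many invariant columns at exactly
1), and standard exact U tests do not handle ties. `mann_whitney_u()`
therefore enumerates the full permutation distribution of U whenever the
smaller class has ≤ 8 members — exact also under ties, with the two-sided
p-value $P(|U' - n_1 n_2/2| \ge |U - n_1 n_2/2|)$ — and otherwise uses
the tie-corrected normal approximation with continuity correction, which
matches `wilcox.test(exact = FALSE)` to near machine precision in the
tie-free case. Tests cross-check both branches against independent
enumeration and against `wilcox.test`.

## Heptad registers, wheels, periodicity

Heptad phases cannot be derived from sequence alone, so
`default_heptad_anchors()` fixes one anchor per subdomain — K1: 101 → a
(span 94–121), K2: 145 → d (122–149), K3: 161 → a (150–181) — chosen so
that all documented assignments follow arithmetically: 145 and 164 at d,
161 and 168 at a, and the tetramerization stripe M150/L157/L164/L171
uniformly at d. The spans are replaceable inputs; positions outside every
span raise an error rather than guessing a phase across the interhelical
kink.

`helical_wheel()` uses the coiled-coil projection of 3.5 residues per
turn (102.857° per residue), first residue at angle 0 by convention, so
the a/d core positions of one heptad sit ~51.4° apart and residues seven
apart coincide. `heptad_periodicity_score()` is a deliberately simple
substitute for full coiled-coil prediction: per window (14/21/28), the
best over the 7 phases of the fraction of a/d positions occupied by
hydrophobic residues (L, I, V, M, F, A, W, Y), maximized over windows
covering each position. It ranks heptad-periodic hydrophobicity and
reproduces the qualitative K1/K2/K3 structure on ideal sequences; it is
not a calibrated coiled-coil probability.

## Constructs and probes

Substitution specs use 1-based full-protein coordinates and the
field's naming (`L164P`, `E161L-N168L`); applying a spec validates the
source residue at every position and reports position/expected/found on
mismatch, so coordinate systems can never silently slip. Specs invert
exactly. Chimeras replace an inclusive host region by a donor region
(defaults: the K3 subdomain, residues 150–181, equal length in the
bundled synthetic references, so the swap is length-preserving). The
bundled reference proteins are synthetic stand-ins that carry the
documented residues at the documented coordinates — sufficient for
coordinate-faithful construct tests, not for structural inference.

The probe fixtures store the printed sequences letter-for-letter. The
151-nt two-site probe carries its two exact CArG-boxes at 0-based offsets
25 and 88 — 63 bp start-to-start, six turns at 10.5 bp/turn. Start-to-start
equals center-to-center here because both motifs are 10 nt; for
unequal-length motifs the distinction matters and the `bp_per_turn` and
definition are explicit in `spacing()`. The 51-nt single-site probe's
printed 3′/5′ end labels are inconsistent with its own CArG cassette
(which matches the two-site probe's cassette letter-for-letter in the
5′→3′ reading); the fixture therefore interprets the printed letters as
the 5′→3′ sense strand and records that decision in its FASTA header.
Consensus scanning (`CC(A/T)6GG` via IUPAC `CCWWWWWWGG`) finds exactly
the two exact boxes on the forward strand of the two-site probe and, on
both strands, four hits — each box's reverse complement `CCTTATTTGG` is
itself a valid CArG consensus.

## Problem sizes and numerical choices

The shipped tests run the recovery studies at 50 replicates per
condition, 12 lanes each, and the conservation pipeline on 78-sequence
families over the 85-column K-domain span — sizes at which the seeded
medians and test decisions are stable from run to run. Fits use relative
tolerances of the optimizer defaults; identity-level assertions use
1e-3 relative tolerance on recovered parameters; renormalization leaves
lanes whose fractions already sum to 1 within 1e-9 bitwise untouched so
that zero-noise paths stay exact.

## Known limitations

- The model ignores the monomer–dimer equilibrium upstream of DNA binding
  and assumes identical, independent lane equilibria.
- Absolute affinities are out of reach by design; only $k_{coop}$ and
  ratios are interpretable across experiments.
- High cooperativity estimates are intrinsically imprecise near the
  ceiling (see above); treat values above ~100 as order-of-magnitude.
- The conservation statistics treat sequences as independent draws;
  phylogenetic autocorrelation in real families inflates effective
  significance.
- The heptad periodicity score is a ranking heuristic, not a coiled-coil
  predictor.
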