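---
title: "Direct conformational analysis of 1,3-diols in MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct conformational analysis of 1,3-diols in MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dioltraj)
```

## The method

Small flexible molecules such as 1,3-propanediol visit many conformations in
solution, and the usual indirect probe — a radial distribution function
(RDF) over characteristic intramolecular distances — cannot separate
conformations whose distance ranges overlap, and says nothing about how long
any conformation lives. `dioltraj` implements the direct alternative: read
the atomic coordinates of every target molecule at a short fixed stride
(1 ps by default), measure the four conformation-defining torsions, bin them
into gauche/trans letters, and work with the resulting discrete state series.

The four torsions of the seven-site chain H1–O1–C1–C2–C3–O2–H2 are
H1−O1−C1−C2, O1−C1−C2−C3, C1−C2−C3−O2 and C2−C3−O2−H2. Each torsion angle
$\chi \in [0^\circ, 360^\circ)$ is binned into three equal segments:

* $[0^\circ, 120^\circ)$ → G (gauche),
* $[120^\circ, 240^\circ)$ → T (trans),
* $[240^\circ, 360^\circ)$ → G′ (gauche-prime, i.e. $-60^\circ$ region).

Letters for the two torsions that involve hydroxyl hydrogens (positions 1
and 4) are written lowercase; the two main-chain letters are uppercase. A
molecule's conformation is thus a four-letter word such as `tTTg` or
`gGGg′`. Boundary angles (exactly 120° or 240°) fall into the upper
interval; the choice is deterministic and has measure zero under any
continuous torsion distribution.

## Symmetry reduction and the 25 unique conformations

Sequential variation of three letters over four torsions gives $3^4 = 81$
raw words, but the molecule has an end-for-end exchange symmetry (reversing
the word) and a mirror symmetry (exchanging G and G′ at every position,
leaving T fixed). These two commuting involutions generate a group of order
four; its orbits on the 81 raw words are the physically distinct
conformations. Burnside's lemma gives the count: the identity fixes all 81
words, reversal fixes the $3^2 = 9$ palindromic words, the mirror fixes
only the all-T word (G and G′ are never fixed), and their composition fixes
9 words, so the orbit count is $(81 + 9 + 1 + 9)/4 = 25$. `enumerate_unique()`
materializes this: 25 labels partitioned into four families by their
main-chain letter pair — TT (4 labels), TG (9), GG (6), GG′ (6).

The choice of which orbit member names the orbit is a convention. The plain
whole-word lexicographic minimum is *not* the convention used in the
field's published tables (it would pick `gG′G′g` over the customary
`g′GGg′`), so `canonicalize()` applies a two-stage rule:

1. keep the orbit members whose main-chain pair is the family-canonical one
   (TT; TG among {TG, GT, TG′, G′T}; GG among {GG, G′G′}; GG′ among
   {GG′, G′G}) — formally, the lexicographic minimum of the chain word's
   own orbit;
2. among those, take the whole-word lexicographic minimum under the letter
   order t < g < g′.

This rule is idempotent, constant on orbits, and reproduces every
customarily printed conformer name. Registry indices `c_1`…`c_25` follow
family-major order (TT, TG, GG, GG′) with lexicographic order inside a
family, which is the order used in the published conformer tables, so all
outputs are directly comparable with them.

```{r}
reg <- enumerate_unique()
head(as.data.frame(reg)[, c("index", "label", "family", "orbit_size")])
table(reg$family)
```

Primes are rendered as U+2032 (′) in reports; shell-unfriendly contexts can
use the ASCII aliases `gp`/`Gp`, which every parser in the package accepts.

## Geometry conventions

Dihedrals are measured with the right-handed (IUPAC-sign) convention,
$\varphi = \operatorname{atan2}\big((\mathbf{n}_1 \times \mathbf{n}_2)
\cdot \hat{\mathbf{b}}_2,\ \mathbf{n}_1 \cdot \mathbf{n}_2\big)$, mapped
from $(-180^\circ, 180^\circ]$ to $[0^\circ, 360^\circ)$. The convention is
pinned by the crystal-structure worked example: the published torsions
(67.6°, 61.5°, 69.4°, −82.5°) must label as `gGGg′`, which requires −82.5°
→ 277.5° → g′. Coordinate inversion negates all dihedrals, so a mirror
image of a molecule maps its label through the mirror symmetry operation —
a cross-module invariant the test suite checks explicitly.

All intramolecular geometry applies the minimum-image convention along the
bonded chain before measuring, so wrapped and unwrapped trajectories give
identical labels. Only orthorhombic boxes are supported; triclinic box
bounds are rejected loudly rather than silently mishandled. Collinear bond
triples (cross-product norm below $10^{-10}\,Å^2$, far below thermal
geometry noise) make a molecule-frame degenerate: it is marked missing,
excluded from the configuration count $N_\mathrm{conf}$, and never
interpolated — lifetimes must not bridge fabricated states.

## Occupancies and lifetimes

For a series of $N_\mathrm{conf}$ labeled molecule-frame configurations,
the content of a conformation is
$\varphi = 100 \cdot n(\text{label}) / N_\mathrm{conf}$ (percent), and
family contents are sums over member labels; totals conserve to 100 % minus
the separately reported missing fraction.

A lifetime is the duration of a maximal run of identical consecutive
canonical labels for one molecule: a run of $k$ frames at stride $\Delta t$
lives $k \Delta t$, so the minimum resolvable lifetime equals the stride.
`lifetime_table()` reports the mean $t_\mathrm{av}$ and maximum
$t_\mathrm{max}$ per label and per family. Three reporting conventions
matter:

* lifetimes attach to *canonical* labels, so a flip between two raw
  symmetry variants of the same conformation does not break a run —
  matching the pooled convention of the published tables;
* family-level runs are computed on the family sequence, so fast hydroxyl
  rotation inside a family does not break a family run. This is what makes
  family lifetimes an order of magnitude longer than label lifetimes when
  main-chain rearrangement is slow;
* runs touching the first or last frame are kept by default
  (`truncation_policy("include")`), which preserves the exact conservation
  property $\sum \text{durations} = n_\mathrm{frames} \Delta t$ per
  molecule; `exclude_boundary` is available, and the two policies converge
  as the trajectory grows.

Summary exports round $t_\mathrm{av}$ to 0.1 ps — the precision customary
in published tables — while the returned objects keep full precision.

## The RDF contrast

`compute_rdf()` histograms the minimum-image distances among hydroxyl
oxygens, normalized by shell volume and the pair density of the *selected*
pair set (all pairs, intermolecular only, or intramolecular only), so an
ideal gas gives $g(r) = 1$ for every selection and the three curves are
mutually comparable. Defaults: 0.05 Å bins and
$r_\mathrm{max} = \min(10\,Å, \text{half the smallest box edge})$, which
resolves the ≈0.6 Å spacing between neighbouring family peaks with stable
statistics.

`decompose_peaks()` fits a sum of Gaussians or Lorentzians by
Levenberg–Marquardt least squares, with initial centers at local maxima of
the lightly smoothed curve (or user-supplied), each center confined between
the midpoints to its neighbours (components stay ordered and local), and
analytic per-component areas normalized to fractions summing to 100 %. The
default fit window runs from the first non-empty bin to the first local
minimum after the last component, excluding the long-range $g \approx 1$
plateau; when narrow structural peaks sit on the flat intermolecular
background, `baseline = "constant"` adds a free offset that is excluded
from the areas. Non-convergence is an error with diagnostics, never a
silent fallback.

The scientific point of carrying the RDF at all: the short-distance
$g_{OO}(r)$ peak near 2.6–2.9 Å collects intramolecular O…O distances of
GG′-family conformations *and* intermolecular hydrogen-bond contacts, so
the naive family-fraction estimate `rdf_conformer_estimate()` overstates
the GG′ family whenever intermolecular contacts exist. The package
reproduces this bias constructively: `inject_intermolecular_contacts()`
rigidly repositions molecule pairs to an exact O…O contact distance without
touching any torsion, which inflates the first-peak area fraction
monotonically while the direct labels are bit-for-bit unchanged. The
control case (no injected contacts) agrees with the direct GG′ fraction
within fit tolerance.

## The synthetic generator as a test instrument

Because the reference systems require nanosecond all-atom MD, every
analysis stage is instead validated against the package's own generator,
whose ground truth is analytic:

* each torsion slot evolves as a three-state Markov chain (states T, G, G′)
  with a user-specified per-step transition matrix; the default test
  instrument is the symmetric stay/switch matrix `stay_transition(p)` whose
  stationary distribution is uniform and whose dwell time is geometric with
  mean $1/(1-p)$ steps. Slots are independent by default (ground truth
  stays analytic); an 81 × 81 joint-matrix mode exists for correlated
  dynamics;
* generated angles sit at the bin center plus truncated-Gaussian jitter
  (s.d. 10°, truncated at ±30° by default). Truncation — not wrapping —
  means a generated angle can never cross a bin boundary, so analyzer-label
  agreement with ground truth is an exact test, not a statistical one;
* `build_coordinates()` realizes each molecule by sequential
  internal-to-Cartesian chain extension from standard bond lengths and
  angles (only torsions carry conformational signal), then applies a random
  rigid pose per frame with a minimum-separation placement; measured
  torsions equal prescribed ones within $10^{-6}$ degrees.

What the generator deliberately does *not* emulate: water, energetics,
forces, realistic translational diffusion (poses are resampled
independently per frame), or correlated torsion kinetics. Passing tests
therefore demonstrate the correctness of the *analysis* — binning,
canonicalization, run-length statistics, RDF normalization and
decomposition — on trajectories with known answers, not the physical
accuracy of any force field. The stay probability 0.75 used across the
tests gives 4 ps mean slot dwells, the same few-picosecond scale as the
hydroxyl-rotation lifetimes seen in the reference solutions.

Test problem sizes were chosen to keep every statistical check at three
Monte-Carlo standard errors: $10^5$ steps for occupancy/dwell recovery, an
8-molecule × 5000-frame box (40,000 configurations, the smallest reference
system's bookkeeping) for the end-to-end pipeline oracle, and 600–1000
frames for RDF demonstrations.

## Reference configuration

`md_reference_systems()` records the exact analysis configuration of the
six dilute aqueous solution systems the method targets (box sizes 800,
2700, 6400 molecules; 8–64 target diols; 2–15 ns analyzed at 1 ps stride;
$N_\mathrm{conf}$ from 40,000 to 135,000). Given equivalent trajectories
(OPLS-AA diol in TIP4P-Ew water, NPT, 298.15 K, 1 atm), running
`label_trajectory()` with that configuration reproduces the published
composition and lifetime tables; those numbers cannot be computed from
this package alone and no test pretends otherwise.

## Known limitations

* Orthorhombic boxes only; binary trajectory formats (DCD/XTC/TRR) are out
  of scope — convert to LAMMPS text dumps or extended XYZ first.
* The trajectory readers validate a constant recording stride and refuse
  drifting time steps rather than resampling.
* No hydrogen-bond geometric criterion is implemented: the O…O distance
  analysis deliberately stops where the published analysis stops.
* Peak decomposition is a generic mixture fit; strongly overlapping peaks
  (closer than roughly one width) need user-supplied centers or a window.
* `occupancy()` reports no block-averaged error bars; replicate
  trajectories are the intended route to uncertainty.
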