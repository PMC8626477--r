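---
title: "Methods: enclosure statistics, volumetrics and interface analysis for hollow core scaffolds"
author: "corescaffold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enclosure statistics, volumetrics and interface analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corescaffold)
```

# The scientific setting

Icosahedral multienzyme cores such as the pyruvate dehydrogenase complex
(PDHc) E2 scaffold are hollow shells of 60 identical subunits with further
components bound inside (in fungi, twelve E3BP copies arranged as four
trimers with tetrahedral symmetry) and several flexible elements that appear
only partially in cryo-EM maps. Three quantitative questions recur when such
assemblies are analysed from a density map plus an atomic model, and this
package implements the full chain for each:

1. *Is a flexible element present in the density of a given subunit copy?*
   Answered by contour-sweep enclosure statistics over the symmetry-related
   copies.
2. *How full is the interior of the shell?* Answered by solvent-excluded
   volumes inside a spherical interior mask, with ensemble averages for
   disordered segments.
3. *Which interfaces hold the assembly together, and which docked poses of a
   mobile domain are plausible?* Answered by buried surface areas, contact
   maps, a simplified energy decomposition, a reach restraint and clash
   screening.

Supporting stages (Michaelis–Menten kinetics of the complex's activity and
alignment-column conservation of active-site residues) complete the
pipeline.

# Enclosure statistics

## Model

For subunit $i$ of $M$ symmetry-related copies, and a contour level $L$, the
uncovered count $c_i(L)$ is the number of element atoms whose trilinearly
interpolated map value lies **strictly below** $L$ (a value exactly at the
level counts as covered). Levels are swept from 0.015 to 0.052 in steps of
0.0005, giving $N = \lfloor (0.052-0.015)/0.0005 \rfloor + 1 = 75$ levels;
all three numbers are configurable. $c_i(L)$ is non-decreasing in $L$ by
construction and the profile container enforces this as a validity
invariant.

Across subunits the per-level confidence band is

$$ CI(L) = \mu(L) \pm z\,\frac{\sigma(L)}{\sqrt{M}} $$

with $\mu$ the mean, $\sigma$ the sample standard deviation (denominator
$M-1$) and $z = 3.291$ by default. The per-subunit enclosure probability is

$$ p_i = n_i / N, \qquad n_i = \#\{L : c_i(L) < CI_{\text{lower}}(L)\}. $$

A subunit whose element is covered by density has *fewer* uncovered atoms
than the cohort expectation, falls below the band, and scores high $p$.

## Reading choices and their rationale

- **"Below the confidence range"** is read as *strictly below the lower
  bound*. This makes $p$ a probability of enclosure, matching the
  interpretation of the grouped comparison (proximal subunits have lower
  probability of extra density). An `"outside"` mode counting both tails is
  provided for sensitivity analysis; `"below"` is the default.
- **$z = 3.291$** is the band default. Note that 3.291 is the
  two-sided 99.9% normal quantile although such bands are sometimes called
  99% intervals; the formula wins and the quantile is configurable.
- **Coverage is point-sampled at atom centres** via trilinear interpolation,
  not by a volumetric inside-the-isosurface test. The two differ at the
  surface of the contour; centre sampling is reproducible and
  implementation-independent.
- **Equal element sizes are required** (the analysis evaluates one element
  model per symmetry copy). Unequal sizes are a hard error unless
  `normalize = TRUE` converts counts to fractions.
- Atoms outside the map box count as uncovered and are flagged separately by
  `mapValuesAt()`.

## Cohort size matters

The band half-width is $z\sigma/\sqrt{M}$. At the native scale
($M = 60$) this is $0.42\,\sigma$; on a 12-subunit toy it is $0.95\,\sigma$,
so a cohort with more than half of its copies fully enclosed drives the
lower bound below zero and $p$ degenerates to 0 for everyone. Consequently:
the synthetic recovery scenarios always carry both enclosed and absent
elements (see below), and the proximity-grouped pipeline demonstration uses
24 subunits. This is a property of the statistic, not of the
implementation.

## Map–model correlation

`mapModelCC()` simulates a map from the model on the experimental grid — a
sum of normalised Gaussians with $\sigma = \text{resolution}/(\pi\sqrt2)$,
one common cryo-EM convention, recorded here so all tests are
self-consistent — and reports the Pearson correlation over voxels within a
mask radius of any atom. Against the very model and convention that
generated a noise-free map the CC is 1 to numerical precision, which is the
self-consistency oracle the tests pin down.

# Proximity grouping

Anchors are centres of mass of each shell subunit and each interior
component (for real structures, single-residue C$\alpha$ anchors can be
selected instead; anchor definitions of this kind usually name a residue
without an atom, and C$\alpha$ is the conventional reading).
`nearestPartnerDistances()` takes the minimum over partners with
lexicographic tie-breaking, `classifyGroups()` applies the default
bounds — group 1 at 55–70 Å inclusive, group 2 strictly above 75 Å — and
deliberately leaves the (70, 75] gap unassigned rather than inventing a
cut; unassigned subunits are reported and counted.
`compareGroupProbabilities()` summarises each group (median, quartiles) and
runs a two-sided Mann–Whitney test (normal approximation with tie
correction; an all-tied degenerate input returns $p = 1$ since there is no
evidence of difference).

# Volumetrics

Solvent-accessible surface areas use Shrake–Rupley sampling with a
deterministic golden-spiral point set (default 960 points/atom, probe
1.4 Å, Bondi-style radii; unknown elements are an error, never a default).
Solvent-excluded (SES) volumes use boolean-lattice morphology: dilate each
atom by the probe (a ball of radius $r_i + 1.4$ Å), erode by the digital
ball of radius 1.4 Å, count voxel centres. Digital morphology carries
$O(h)$ boundary error at lattice spacing $h$ (an isolated atom's SES
volume at $h = 0.4$ is ~20% above its vdW ball, falling to ~4% at
$h = 0.15$); probe-free volumes converge much faster (~0.3% for a 10 Å
ball at $h = 0.5$). The tests assert exactly these behaviours rather than
pretending grid morphology is exact. Interior occupancy intersects
component SES regions with an 80 Å sphere (default; spacing must be at most
radius/20) on a single shared lattice anchored at the mask centre, counts
union volume once, splits multiply-claimed voxels equally among claiming
components so that component fractions plus the empty fraction sum to
exactly 1, and uses the analytic sphere volume as the denominator.

Disordered segments are represented by C$\alpha$-only chains with a 3.0 Å
per-residue sphere (configurable), and `ensembleVolume()` reports the mean
and sd of per-model volumes: the *expected* occupancy of the flexible
segment. Aggregating by mean (not union, not maximum) is a deliberate
choice — the union over a large ensemble grows without bound and the
maximum is an extreme statistic, while the mean is what an occupancy
fraction of a fluctuating chain means physically.

# Interfaces and pose screening

BSA is computed as $\sum_k \mathrm{SASA}(\text{partner}_k) -
\mathrm{SASA}(\text{complex})$, the multi-body total for more than two
partners. Interface residues are those with at least one cross-partner
heavy-atom pair within 5.0 Å (inclusive). The energy decomposition is a
**clearly simplified stand-in** for docking-refinement energetics, intended
for relative comparisons only: Lennard-Jones 12-6 with generic per-element
well depths and $r_{min} = r_i + r_j$; Coulomb with distance-dependent
dielectric $\varepsilon(r) = r$ (332.06 kcal mol⁻¹ Å e⁻²) over a coarse
charge template (Asp/Glu carboxylate −1 split over the two oxygens, Lys +1
on NZ, Arg +1 split over NH1/NH2, His neutral, backbone dipoles ignored);
desolvation as Eisenberg–McLachlan-style atomic solvation parameters times
the SASA change on binding. Absolute values are not comparable to any full
force field and the output carries a parameter-set identifier saying so.

The reach restraint defaults to 10–25 Å between a lipoylated-lysine
C$\alpha$ and an active-site alanine C$\beta$, inclusive at both bounds
(the physical reach of the swinging lipoyllysine arm). Clashes are
cross-partner heavy-atom pairs with overlap $r_i + r_j - d$ strictly
greater than 0.4 Å, computed with spatial binning that the tests hold equal
to the all-pairs scan. `rankPoses()` sorts stably by restraint satisfaction,
then clash count, then BSA, so full ties preserve input order.

# Kinetics

Absorbance converts by Lambert–Beer $c = A/(\varepsilon l)$ with
$\varepsilon = 3.07 \times 10^4\ \mathrm{L\,mol^{-1}\,cm^{-1}}$ (the
formazan read-out of the coupled activity assay) and $l = 1$ cm by default.
Michaelis–Menten fits use `nls` (port algorithm, positivity bounds), with
starting values $V_{max} = \max v$ and $K_M$ at the interpolated
half-maximal substrate concentration; standard errors come from the
Jacobian at the optimum. With replicated concentrations the default fits
per-concentration means — the error-bar design of a triplicate assay — with
a pooled mode available. Negative measured rates are accepted (5% noise at
low substrate produces them); noiseless data are recovered to at least six
significant digits, and a 1000-run Monte-Carlo in the acceptance suite
checks that the 95% Wald interval ($t_{n-2}$ quantile) covers the truth
93–99% of the time.

# Conservation

`mapReferencePosition()` maps an ungapped reference position to its
alignment column by counting non-gap reference characters;
`columnConservation()` reports residue frequencies over the non-gap
characters of that column (case-insensitive, `X` its own category), with
the gap fraction reported separately — identity percentages are what the
field quotes, so gaps stay out of the denominator by default
(`includeGaps = TRUE` reverses this). Kingdom-wide surveys of thousands of sequences are not reproducible
without their underlying databases, so exact survey percentages are
exercised only through planted synthetic alignments.

# The synthetic world

The generators state one fixed world, chosen at design time:

- **Toy assembly**: 12 (default) shell subunits on a 100 Å sphere via a
  deterministic golden-spiral layout, four interior trimers at 50 Å on
  exact tetrahedron vertices (trimer centre-of-mass spacing equal by
  construction), 30 pseudo-atoms per rigid cluster, and a 20-atom flexible
  element displaced 12 Å outward from each subunit. With these radii the
  nearest-partner distances span ~50–96 Å and straddle the 55–70/75 Å
  grouping bounds.
- **Element spread 2.5 Å**: sized so that a full-weight element's atom
  densities clear the top of the 0.015–0.052 sweep window while partial
  occupancies land inside it — the sweep must actually probe the element
  for the statistic to carry information.
- **Maps**: resolution 6 Å, voxel 2 Å, additive white noise of sd 0.002 map
  units (a small fraction of the ~0.07–0.16 element peak values), seeded.
- **Recovery scenarios** (`randomOccupancyScenario()`): half the subunits
  at weight 0, half at uniform(0.4, 1) occupancy, mirroring the balanced
  presence/absence structure of the biological phenomenon; as derived
  above, the cohort-relative band requires both classes to be present.
- **Disordered chains**: fixed 3.8 Å C$\alpha$ steps, uniform random
  directions, rejection at a 2.0 Å self-avoidance radius; end-anchoring by
  rejecting steps that would leave the anchor unreachable, which guarantees
  termination within one step of the anchor.
- **Kinetics truth**: $K_M = 148\ \mu$M, $V_{max} = 5$, an 8-point
  5–1000 µM grid, triplicates, 5% $V_{max}$ noise — a realistic titration
  design for this assay.

What the generators do **not** emulate: real protein shapes (subunits are
pseudo-atom blobs), map artefacts other than white noise (no CTF envelope,
no resolution anisotropy, no masking artefacts), rotamers or force fields
in the chains, and sequence evolution beyond per-column identity. A green
test therefore establishes that the statistics recover planted truth under
the stated idealisations — not that any specific biological conclusion is
reproduced from deposited data. The functions accept real maps and models
through the same interfaces when those are available.

# Numerical choices

- Grids are stored `[x, y, z]` (x fastest, R's column-major order); MRC
  files in any axis order are permuted on read, and lookup is tested to be
  invariant under the stored order.
- MRC origin: the ORIGIN header fields win; when all zero but start indices
  are not, origin = starts × voxel, and the object records which rule
  fired.
- Alternate locations: highest occupancy wins, ties keep the first record.
  Hydrogens are kept on read and excluded by geometry operations through
  heavy-atom selections.
- Strictness: uncovered means value < level; restraint bounds inclusive;
  clash overlap strictly > tolerance; group 2 strictly > 75 Å.
- The Gaussian splat truncates at 6σ (relative error < 2 × 10⁻⁸ of a peak).
- Seeds: every generator is a pure function of its config including the
  seed; rerunning a pipeline stage with the same config is byte-identical.

# Known limitations

- Digital SES morphology is accurate to grid resolution, not exact;
  fine-grained cavity semantics at coarse spacing inherit that error.
- The energy decomposition is for ranking and sign structure only.
- The enclosure statistic needs a mixed cohort (see above); it cannot
  certify an element present in *all* copies of a small assembly.
- Recomputations on deposited entries (maps, models, parameter archives)
  require those files locally; no network access is attempted by any
  function, script or test.
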