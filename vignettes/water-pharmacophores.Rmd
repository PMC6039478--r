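---
title: "Water-based pharmacophore models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-based pharmacophore models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Structure-based virtual screening usually needs either known active
ligands (for ligand-based pharmacophores) or a docking engine. When a
binding site is known but no binders are, the water molecules that visit
the pocket during an explicit-solvent molecular dynamics simulation are
an unbiased probe of its interaction preferences: where water binds
tightly and donates hydrogen bonds, a ligand donor would too; where water
is retained but makes no polar contacts, a hydrophobic group fits.
`waterpharm` turns a pocket water trajectory into a typed pharmacophore
model — with **no ligand knowledge** — and provides the screening and
enrichment machinery to use and validate that model.

```{r, eval = FALSE}
library(waterpharm)
scene  <- generate_trajectory(scene_spec(list(
  planted_site(c(0, 0, 0), type = "D"),
  planted_site(c(8, 0, 0), type = "A"),
  planted_site(c(0, 8, 0), type = "H")), n_frames = 400, seed = 42))
sites  <- analyze_hydration_sites(scene$frames, scene$protein, scene$reference)
model  <- build_model(classify_sites(sites, scene$protein), scene$protein)
lib    <- generate_library(model, n_active = 27, n_decoy = 1041, seed = 1)
hits   <- screen_library(model, lib$ligands)
enrichment_report(hits, lib$labels)
```

## Hydration-site analysis

**Pocket selection.** Waters whose oxygen lies within 5 Å (inclusive) of
any reference-ligand heavy atom are pocket waters; the reference only
defines the region, it contributes no chemistry.

**Clustering.** Hydration sites are 1 Å spheres of maximal time-averaged
water-oxygen density. The algorithm is a greedy argmax over *observed*
oxygen positions: the candidate whose sphere holds the most
not-yet-excluded oxygens becomes a site, its members are excluded, and
the loop continues while the best count reaches the retention threshold

\[
n_{\min} = m \, \rho_{\mathrm{bulk}} \tfrac{4}{3}\pi r^3 N_{\mathrm{frames}},
\]

with multiplier \(m = 2\) (twice bulk), \(\rho_{\mathrm{bulk}} =
0.0334\,\text{Å}^{-3}\) and \(r = 1\) Å — about 2,800 observations for a
10,000-frame trajectory. Using observed positions (not a continuous grid)
makes the argmax finite and deterministic; ties break on the lowest
(frame, molecule id) of the candidate, so the result is independent of
input row order. The retained-count comparison uses
`max(2, ceiling(threshold))`: a single observation is never a density
excess, so degenerate one-frame inputs cannot spawn sites.

**Energy.** Each site's enthalpy is the mean, over member observations,
of the water's Lennard-Jones 12-6 (Lorentz–Berthelot mixing) plus Coulomb
(332.0636 kcal·Å/(mol·e²)) interaction with (i) all protein atoms and
(ii) all other waters whose oxygen lies within the 8 Å cutoff. The
water–water term is counted once, in full, from the site water's
perspective — this directly implements "system energy with and without
the water". A `ww_half_factor` toggle divides it by two for users who
prefer the shared-pair convention; it defaults to off.

**Translational entropy** uses the histogram estimator on a 0.25 Å cubic
grid over the site sphere, referenced to bulk density: with
\(g_k = n_k / (N_{\mathrm{frames}}\rho V_k)\),

\[
S_{\mathrm{trans}} = -k_B \rho \sum_k g_k \ln g_k \, V_k ,
\]

so uniform occupation at bulk density scores exactly zero and any
concentration scores negative.

**Orientational entropy** uses the nearest-neighbour estimator on unit
quaternions (body frame: H–O–H bisector = +z, H1–H2 axis = x), identified
under the quaternion double cover and, by default, the water C2 symmetry
(which halves the reference volume \(\pi^2\)). With \(\theta_i\) the
geodesic distance to the nearest other member and \(V(\theta) = \pi(2
\theta - \sin 2\theta)\) the exact rotation-space ball volume,

\[
S_{\mathrm{orient}} = k_B\left[\gamma + \tfrac{1}{N}\sum_i \ln \frac{N
V(\theta_i)}{V_{\mathrm{ref}}}\right].
\]

Because the exact ball volume is used there is no curvature bias: on
uniformly random orientations the estimator is centred on zero (the test
suite checks \(|S|/k_B < 0.05\) at \(N = 10^4\)), and it diverges to
\(-\infty\) as orientations lock. Sites with fewer than two members
report the descriptor as `NA` rather than failing.

**Hydrogen bonds.** The geometric criterion — donor–acceptor heavy-atom
distance ≤ 3.5 Å and ≤ 30° between the donor X–H bond and the
donor–acceptor axis — has no single field-standard value, so it is a
declared, config-exposed choice, as are the bulk references (1.8 donated
and 1.8 accepted bonds per frame) that normalise the donor/acceptor
*ratios*. Ratios are percentages of bulk and can exceed 100%; the
decision-tree gates below depend on these conventions, which is exactly
why they are configuration, not constants.

## Feature assignment

Sites map to features through a strict decision tree (all inequalities
strict; boundary equality falls through):

1. **Donor branch** — enthalpy < −8.0 kcal/mol, acceptor ratio < 50%,
   donor ratio > 100%: a donor (`D`) when the mean donated H···acceptor
   distance exceeds 1.5 Å, else a positive (`P`). The 1.5 Å split is
   implemented exactly as printed even though it is a physically unusual
   threshold for an H···X distance.
2. **Acceptor branch** — enthalpy < −8.0, acceptor ratio > 100%, donor
   ratio < 50%: an acceptor (`A`).
3. **Apolar branch** — both ratios < 100%: an aromatic feature (`R`) when
   a protein ring centroid lies within 5 Å and the centroid-to-site
   vector is within 30° of the ring normal; otherwise hydrophobic (`H`)
   when at least 6 nonpolar protein atoms sit within 4 Å. The
   contact-count proxy replaces a proprietary hydrophobic-surface-area
   tool; both thresholds are exposed in `feature_rules()`.
4. Anything else produces no feature — a legal outcome (a strongly
   hydrophobic, poorly hydrated pocket can yield an empty model, which
   the screening layer reports as "no feature was generated, and thus no
   compound was screened").

Polar branches are evaluated before the apolar branch; the ordering is
this package's contract for descriptor vectors that satisfy several
guards at once. Pairs of acceptors within 3.5 Å merge, closest pair
first, into one negative feature (`N`) at their midpoint; each acceptor
merges at most once.

## Model generation

Candidates reduce to at most 8 features (screening degrades beyond
that): ionic/polar features (`N`, `P`, `A`, `D`) first, then rings, then
hydrophobes by ascending enthalpy, with hydrophobes inside 2 Å of an
already-kept feature dropped as redundant before the cap applies. The
priority ordering (ionic and polar over apolar) is this package's
contract for realising the goal of pruning redundant hydrophobes.

Feature positions are polished by **rigid chemical probes**: acetate for
`N`; water for `D` when the site enthalpy is above (weaker than) −9.0
kcal/mol; methane for `H` above −8.2 kcal/mol. Stronger sites — and the
strongly bound hydrophobes the gates exclude — keep their raw
hydration-site position, on the reading that "favourable" sites skip
refinement entirely. Refinement is a deterministic local L-BFGS-B
minimisation of the probe's LJ+Coulomb energy over translation and
rotation, started at the feature position, with the interaction-center
displacement clamped to 1.5 Å; a step that fails to lower the energy (or
diverges) is rejected with a warning. This replaces hydrogen-bond
constrained docking with a method of identical intent (a local position
polish, not a pose search); probe parameters ship as a data file
(`inst/extdata/probes.tsv`), not code.

## Screening

Ligand conformers are typed by deterministic structural rules (charged
groups, implicit-hydrogen donors, lone-pair acceptors, aromatic
centroids with normals, connected carbon/halogen clusters), then matched
to the model by backtracking over type-compatible correspondences
(`N`↔`N`/`A`, `P`↔`P`/`D`, others exact) pruned by the 1.5 Å
inter-feature distance-matching tolerance. Surviving correspondences are
superposed by Kabsch SVD; a hit must pass alignment RMSD ≤ 1.2 Å, vector
score ≥ −1 and volume score ≥ 0 — the last two defaults never exclude
anything (the scores are bounded by construction), so post-fit RMSD is
the only active gate under default settings. The vector score is
the mean cosine of matched directions after rotation (directionless
pairs contribute 1; ring normals compare sign-blind). The volume score
is the Monte-Carlo fraction (10,000 fixed-seed points, sampled in the
fitted frame so rigid motions of the input change nothing) of the ligand
vdW volume inside the union of model-feature spheres of radius 1.5 Å;
it is defined against the model because a ligand-free method has no
reference ligand to overlap. Score parity with proprietary screening
engines is explicitly not claimed.

## Enrichment

\[
\mathrm{EF} = \frac{\mathrm{Hits}_{\mathrm{sampled}} / N_{\mathrm{sampled}}}
                   {\mathrm{Hits}_{\mathrm{total}} / N_{\mathrm{total}}}
\]

at 1%, 5% and 10% of the full labelled library, with
\(N_{\mathrm{sampled}} = \lceil f N_{\mathrm{total}} \rceil\) (ceiling, so
a 1% cut always samples at least one compound). Ligands the screen did
not retrieve rank below every hit and are never counted as retrieved
actives — hence an empty hit list scores EF = 0 and an empty model
reports "—". Libraries with no actives leave EF undefined.

## The synthetic-scene generator

`generate_trajectory()` emulates exactly what the analysis consumes: per
frame, each planted site emits (with its occupancy probability) a water
whose oxygen is Gaussian about the site mean and whose orientation is
uniform or concentrated; a uniform bulk band surrounds the pocket; and
the "protein" consists of the partner atoms that realise each intended
feature type — acceptor oxygens down the O–H vectors for `D` (2.90 Å;
2.30 Å anionic partners for `P`, putting the donated H···X distance on
the positive side of the 1.5 Å split), three amine-like N–H donors for
`A`, an eight-carbon apolar shell for `H`, an idealised aromatic ring
3.5 Å below the site for `R`. An `N` plant expands into two acceptor
sub-sites 3 Å apart whose donor shells point away from each other; the
downstream merge recovers the negative feature. Positive-ionizable
plants default to tighter spreads (σ = 0.2 Å, 6° angular jitter),
emulating the near-locked geometry of a strongly bound water; all other
sites default to σ = 0.3 Å.

What the generator does **not** emulate: water–water correlation
structure, periodic boundaries (analysis assumes pre-imaged frames far
from box edges), protein flexibility, and force-field-quality ensembles.
The bulk band keeps a 4 Å clearance from the planted sites, as
pre-equilibrated solvent would — uniform insertion right against a
planted water would create steric clashes no simulation frame contains.
Passing tests on these scenes therefore demonstrate the correctness of
the estimators, the decision tree and the screening engine, not the
field accuracy of any force field.

Active/decoy libraries are rigid multi-fragment molecules whose
perceived features reproduce the model positions up to 0.3 Å jitter;
decoys carry the same feature multiset with all pairwise distances
scaled by 2.1–2.5×, which perturbs every inter-feature distance by more
than twice the matching tolerance whenever model features are ≥ 3 Å
apart. This "distance-scrambled" decoy philosophy exercises the EF
machinery; it does not reproduce property-matched decoy sets, and a
one-feature model has no pairwise distances to scramble.

## Numerical choices and problem sizes

- Strict inequalities throughout the decision tree; ties in clustering
  break canonically on (frame, molecule id); ties in acceptor merging on
  candidate order.
- Water geometry is validated to O–H ∈ [0.7, 1.3] Å, accommodating
  flexible-water models.
- Exact duplicate oxygen positions are collapsed with multiplicity
  before clustering, so a σ = 0 planted site costs O(1), not O(n²).
- Test and example trajectories use 250–800 frames with
  occupancy-proportional thresholds; the estimator contracts are
  scale-free, and the closed-form threshold is asserted at the full
  10,000-frame production size.
- The orientational-entropy nearest-neighbour search is chunked (512
  rows) to bound memory at large occupancies.

## Limitations

- Electrostatics are plain Coulomb sums within a cutoff: no Ewald, no
  periodicity. Pocket-scale analysis only.
- Hydrophobic assignment is a contact-count proxy; sites at the rim of a
  pocket can under-count contacts and yield no feature.
- Ring detection in proteins is template-based (PHE/TYR/TRP/HIS);
  ligand aromaticity comes from SDF aromatic bond flags, not electronic
  structure.
- The screening scores are re-specified, not reverse-engineered;
  absolute score values are not comparable with proprietary engines,
  only the accept/reject semantics are aligned.
- Empty or near-empty pockets (strongly hydrophobic sites) legitimately
  produce empty models; downstream tooling must handle the explicit
  "nothing screened" status rather than an error.
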