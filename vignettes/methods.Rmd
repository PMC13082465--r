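---
title: "Methods: interface scoring, hydration, the screening funnel and placement congruence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface scoring, hydration, the screening funnel and placement congruence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rpiglue` implements the bespoke computational layer of a virtual-screening
workflow for protein–RNA interaction stabilizers. This vignette documents
the models and procedures, the tunable parameters and their defaults, the
numerical choices, what the synthetic-fixture generator does and does not
emulate, and the design decisions taken where the problem left them open.

## Complex screening

A candidate complex passes screening when four structural criteria hold
simultaneously (`screen_complex()`):

* RNA:protein heavy-atom ratio within **[0.1, 20]** — excludes complexes
  where one partner is vestigial;
* at least **25 interface atoms** on each side;
* an interface fraction of at least **2%** of each side's heavy atoms;
* maximum spatial extent below **70 Å**.

Two parameters are deliberately exposed because the criteria do not pin
them down. The *contact cutoff* defining "interface atom" defaults to
5.0 Å between heavy atoms, the common contact convention; it is an argument
of `interface_atoms()` and `screening_criteria()`. The *interface fraction*
bound is quoted as a 2%–5% range in the screening protocol this package
follows; we apply a single configurable threshold defaulting to the
permissive 0.02 and report the measured per-side fractions, so a stricter
bound can be applied downstream without recomputation. Hydrogens are
excluded from ratio, interface and extent computations by default (crystal
structures mostly lack them); both choices are arguments.

Chains are typed by majority vote over residue names, with a small alias
table mapping common modified residues (MSE, PSU, …) to their parent type.
The maximum extent is computed exactly over the 3-D convex hull vertices —
the diameter endpoints are necessarily hull vertices — with a brute-force
fallback for degenerate point sets.

## Solvent-accessible and buried surface area

`shrake_rupley()` re-implements the classic sphere-sampling SASA algorithm:
each atom is covered with a deterministic golden-spiral point set on its
solvent-expanded sphere (radius $r_\mathrm{vdw} + r_\mathrm{probe}$); a
point is accessible when it lies outside every neighbor's expanded sphere,
and the atom's area is the accessible fraction times the sphere area.
Defaults: Bondi van der Waals radii with a 1.7 Å fallback for unknown
elements, probe 1.4 Å (water), 960 sphere points. The defaults mirror what
general-purpose SASA libraries ship; the test suite checks the isolated
atom against the closed form $4\pi(r+p)^2$ and overlapping configurations
against an independent Monte-Carlo surface-point oracle.

Buried surface area follows the inclusion–exclusion identity
$\mathrm{BSA}(A,B) = \mathrm{SASA}(A) + \mathrm{SASA}(B) -
\mathrm{SASA}(A \cup B)$, with all three terms evaluated under identical
probe/point settings. Values in $(-10^{-6}, 0)$ arising from numerical
noise are clamped to zero. Pocket point clouds enter as pseudo-atoms using
their stored per-point radius (their alpha-sphere radius when the detector
provides one) and 1.7 Å otherwise — the parameterization of pocket SASA is
not standardized anywhere, so it is an explicit argument.

The **second-rank BSA** of a pocket or ligand is the smaller of its BSAs
with the protein and with the RNA. `rank_pockets()` sorts by it in
descending order (ties broken by detector drug score, then input order,
so runs are reproducible) and drops pockets below a floor: 50 Å² by
default, with 20 Å² as the conventional counting floor; both are plain
arguments. Pocket deduplication across detectors (`dedup_pocket()`) calls
a candidate *already identified* when ≥ 50% of its points lie within 3 Å
of a selected pocket's points; the source protocol only says "not already
identified", so the threshold is configurable. Docking boxes are the
axis-aligned pocket bounding box with a 5 Å margin on every face.

## Hydration descriptors

`hydration_profile()` selects $n$ equidistant frames (default 10, indices
$\mathrm{round}(k(N-1)/(n-1))$, first and last always included) and, per
frame:

1. counts water oxygens strictly inside or on the pocket's convex hull
   (containment tolerance $10^{-9}$ relative to the cloud diameter; facet
   points count as inside);
2. converts the count to an absolute density (count / hull volume) and a
   relative density against bulk water at standard conditions,
   0.0334 Å⁻³;
3. evaluates the translational order parameter for each enclosed water,
   $S_k = 1 - \frac{1}{12\bar r^2}\sum_{i=1}^{4}(r_i-\bar r)^2$, from the
   distances to its four nearest *enclosed* water oxygens.

$S_k \le 1$ always, with equality exactly at zero spread. Restricting the
neighborhood to in-hull waters is a design decision: the feature of
interest is pocket-local ordering, and bulk neighbors would dilute it.
Waters with fewer than four in-hull neighbors are skipped rather than
padded. Because it is unspecified whether $S_k$ should be averaged per
frame or pooled across frames, both summaries are emitted (`frame_mean_sk`
and `sk` rows of the summary table).

The representative frame of a trajectory (`representative_frame()`) aligns
every frame to the first on a backbone selection — protein N, CA, C, O
plus RNA P, O5′, C5′, C4′, C3′, O3′, itself a choice since the alignment
atom set is conventionally left implicit — computes the time-averaged
structure, and returns the frame with minimum RMSD to that mean, earliest
frame on ties.

The 3-D convex hull is built in-package by an incremental algorithm with
tolerance-based visibility tests (no hull library is among the package's
dependencies); volume follows from the divergence theorem over the
consistently wound facets. The test suite cross-checks membership against
an independent linear-feasibility (non-negative least squares) oracle and
volumes against closed forms.

## The screening funnel and stabilizer classes

`funnel_stage1()` retains, per pocket, the 100 records with the lowest
docking score; `funnel_stage2()` then keeps the 5 with the largest
second-rank BSA. Tie-breaks are deterministic (score, then compound id) —
the ordering within ties is otherwise undefined and would make runs
irreproducible. Undersized pockets keep all their records with a warning,
so the count chain ($n_\mathrm{pockets} \times 100$ then $\times 5$) is
exact whenever every pocket is fully populated.

Compound physicochemical pre-filtering (`physchem_filter()`) applies ten
inclusive ranges (LogP 1–3, mass 250–450 Da, N+O count 2–9, NH+OH 0–3,
TPSA 19–70 Å², rotatable bonds 1–8, aromatic carbocycles 0–2, aromatic
heterocycles 0–1, aromatic rings 1–3, fraction C(sp³) 0.2–0.6); boundary
values pass, and failing properties are reported by name.

`classify_stabilizer()` reads "lower than" strictly: a compound is an
*elevated* stabilizer candidate when both interaction free energies are
$< -10$ kcal·mol⁻¹, *basic* when both are $< -7$, *regular* otherwise, so
a boundary value of exactly $-7$ demotes. The literal reading is a
documented choice and the thresholds are arguments. When replicate
energies are provided, their mean is classified (triplicate averages are
the convention for MMGB/SA end-point estimates).

## The druggability model

The 77-entry feature registry (`feature_registry()`) groups docking-score
statistics (all records, top-100 and top-5 subsets: min/max/mean/sd/
quartiles), ligand-BSA statistics over the retained sets, static pocket
geometry (point count, hull volume/area, radii, box half-diagonal and
volume, detector scores), pocket-volume fluctuation over frames, and
hydration statistics (counts, densities, $S_k$). The exact feature list of
the original 77-dimension design is not fully published, so the registry is
reconstructed from the described feature families — anchored by the
individually named members (docking-score minimum and standard deviation,
maximum second-rank BSA, minimum $S_k$, pocket-volume standard deviation
and minimum) — and versioned in one place: `assemble_features()` is
validated against it, and swapping the registry swaps the model inputs.

`train_druggability()` runs a nested cross-validation: five stratified
outer folds estimate generalization (sensitivity, ROC-AUC, balanced
accuracy), and an inner three-fold grid search selects the configuration,
jointly over forest hyperparameters (tree count 200/500, mtry default or
$p/3$) and a superimposed preprocessing grid of three imbalance strategies
(none / majority-downsampling / inverse-frequency case weights) × two
scalings (none / z-score). The grid is intentionally smaller than an
exhaustive preprocessing search — twelve cells rather than the hundreds a
production sweep might use — and is fully configurable via `cv_config()`.
Missing features are imputed with training-fold medians. Importance is the
forest's mean impurity decrease, normalized to sum to one per model and
averaged over every fitted model (all folds and grid cells), so a feature
must be consistently informative to rank highly.

## Fragment chemistry

ECFP-style fragments are the circular environments of every heavy atom at
radii 1–5 bonds, exported as canonical SMILES, with a 3-atom size floor
and set-level deduplication. "A fragment maps a compound" means a
substructure match — this is implied but never defined in the protocols
this package follows, so it is stated here as the operative definition,
with compound-level (not occurrence-level) frequency counting. The
discrimination score is implemented exactly as specified,
$\mathrm{score} = (f_g - f_{\bar g})\,e^{f_{\bar g}}$; a plausible
alternative with $e^{-f_{\bar g}}$ (penalizing background frequency
instead of boosting contested fragments) exists but is not used. Covering
sets are greedy in descending score with cumulative on- and off-target
coverage reported per step.

BRICS decomposition delegates to RDKit. Recombination applies the inverted
cleavage rules level-wise to join exactly $k$ fragments (default 3),
hydrogen-caps any remaining attachment points, sanitizes, and
deduplicates by canonical SMILES. A hard product cap (default $10^5$) with
seeded uniform sampling controls combinatorial explosion; full-scale
de novo libraries (millions of products) are out of scope for in-memory
enumeration and would be built by sharding the fragment set. The bridge to
RDKit is a subprocess running a bundled helper script; no R-native
implementation of BRICS or Morgan environments exists, and re-deriving the
cleavage-rule chemistry in R would be re-implementing a well-tested
standard.

## Placement congruence

$\Delta L_\mathrm{macro}$ superposes the mobile complex onto the reference
by least-squares (Kabsch) alignment of the matched macromolecule backbone
atoms, then measures the distance between the ligands' strictly
mass-weighted centers of mass. A COM measure is used because ligand atom
sets may differ between sources. Backbone correspondence matches on
(chain kind, residue index, atom name), dropping the chain label when the
sources label chains differently; the mapping is a design decision since
prediction outputs rarely preserve chain naming.

The pocket is every macromolecular backbone atom within 6 Å of a heavy
ligand atom of the reference; the interface adds the heavy ligand atoms.
`rmsd_pocket()` and `rmsd_interface()` align on those sets (requiring a
one-to-one ligand atom match) and report the ligand-only RMSD;
`rmsd_interface_traj()` takes the minimum over trajectory frames with
per-frame realignment — re-aligning per frame matches the per-frame
reference term in the definition, and is the conservative reading of the
ambiguous notation. When several mobile models are available, evaluating
all and keeping the minimum metric reproduces best-of-$k$ comparison;
prediction confidence scores are deliberately ignored.

Gating: a metric whose alignment RMSD reaches the cutoff (default 3 Å for
the COM metric — 2 Å is the stricter variant also in use — and 5 Å for
the RMSD metrics) is `rejected_alignment`; otherwise values below 5 Å are
`agreeing`, above 10 Å `disagreeing`, in between `accepted`. The COM
metric is additionally compared against the mean docking-box half-diagonal
when supplied, the yardstick for calling a placement safely outside the
pocket.

## The synthetic-fixture generator

`make_complex()` builds an idealized protein helix (1.5 Å rise, 100°
twist, five atoms per residue) and an extended RNA strand (4.5 Å rise,
nine atoms per nucleotide), slides the RNA toward the protein until the
requested interface patch holds, and adds a small seeded jitter (0.02 Å)
that distinguishes seeds and breaks exact geometric degeneracies.
`make_trajectory()` adds per-frame Gaussian jitter and places waters
uniformly inside a declared pocket hull — at an exact target density when
requested, e.g. the bulk 0.0334 Å⁻³. `make_screen_tables()` draws Gaussian
docking scores (mean −7, sd 1.5 kcal·mol⁻¹) and log-normal BSA pairs, runs
the real funnel, and plants MMGB/SA energies so that exactly
$\mathrm{round}(f \cdot n)$ of the survivors satisfy each class definition
(defaults $f_\mathrm{basic} = 0.17$, $f_\mathrm{elevated} = 0.07$, the
fraction structure of the workflow's published outcome), emitting
ground-truth labels. `make_placement_pair()` displaces/rotates a ligand
with optional global rigid motion and noise, so
$\Delta L_\mathrm{macro}$ has a known exact value.

All fixture randomness derives from one seed through independent named
streams, making every artifact byte-reproducible. What the generator does
**not** emulate: real force-field energetics, water structure beyond
uniform occupancy, realistic docking-score/BSA correlations, or chemical
plausibility of the toy geometry. Tests passing on fixtures therefore
demonstrate correctness of the computations and selection logic — counts,
closed forms, invariances, recoveries — not predictive performance on
experimental structures.

## Numerical choices and problem sizes

Containment and degeneracy tolerances are $10^{-9}$ (relative to the point
cloud diameter); BSA clamping $10^{-6}$ Å²; Kabsch rejects fewer than
three points or collinear sets and corrects the reflection branch to a
proper rotation. Deterministic tie-breaks: earliest frame
(representative frame), compound id (funnel), drug score then input order
(pocket ranking).

The shipped test and acceptance runs use desk-scale sizes chosen to keep
the full suite in minutes on a single core: 87 × 3 pocket manifests with
200 docked compounds per pocket for the funnel chain (the 200,000-per-
pocket docking campaign is *counted*, never materialized), 10-frame
trajectories with tens of pocket waters, 960 sphere points for SASA with
$10^5$–$10^6$-point Monte-Carlo oracles, and $n = 260$ pockets × 77
features for the classifier. These sizes are the package's own validation
design; every quantity they produce is recomputed at run time by the test
suite or `scripts/acceptance.R`, and nothing in this vignette reports a
number those runs do not compute.

## Known limitations

* Pocket detection, docking, MD and MMGB/SA evaluation are consumed as
  inputs, never performed; garbage in, garbage out.
* The 77-feature registry is a faithful reconstruction of the described
  families, not a published list; models trained on it are comparable to
  each other, not bit-identical to any external model.
* Visual-inspection steps of the original pocket-selection protocol cannot
  be encoded; ranking here is purely metric-based.
* PQR/PDB parsing covers the fixed-width v3.3 dialect; mmCIF and assembly
  generation are out of scope, and structures are assumed complete.
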