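---
title: "Re-engineering TCR-mimic antibodies and counting antigens: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Re-engineering TCR-mimic antibodies and counting antigens: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrmtools)
```

## The problem

TCR-mimic (TCRm) antibodies bind peptide--MHC class I complexes the way T
cell receptors do: CDR1/CDR2 loops grip the MHC helices while CDR3 (and
neighbouring) loops read the peptide lying in the groove.  An antibody with
such a "canonical" diagonal footprint can be *repurposed*: if only the
CDR positions that touch the peptide are randomized, while every
MHC-contacting position is left intact, the resulting library inherits the
MHC bias of the template and can be selected against new peptides on the
same allele.  Validating a re-engineered binder then calls for the reverse
analysis: classify its residue contacts (peptide vs MHC vs both), compare
its docking geometry with the template's, and decompose the buried surface.

A second, independent arm quantifies how many antigen copies sit on a tumor
cell surface, from single-molecule TIRF microscopy of fluorescently labeled
antibodies: localize and track molecules, discard the immobile
surface-adsorbed background, extrapolate the initial mobile count through
photobleaching, and convert to a density and a per-cell copy number:

* density: `rho = N0 / vCSA` (visible cell surface area),
* dual-color correction: `N = A + B - 0.5 * AB` (molecules seen in channel
  1, channel 2, and cotracked in both),
* per-cell count: `N_cell = rho * tCSA` (total cell surface area,
  3900 um^2 by default, obtained as twice the segmented 2D contour area).

`tcrmtools` implements both arms, each with a synthetic-data generator so
every stage is testable against known ground truth.

## Structural footprint analysis

**Contacts.**  A contact is an antibody-atom/target-atom pair within a
cutoff, 4.0 Å by default and compared inclusively ("within 4 Å").
Residue-level statements are distinct-residue projections of the atom-pair
set; this convention reproduces both atom-contact tallies ("26 contacts")
and residue tallies ("seven contacted MHC residues") from one definition.
Hydrogens are excluded (deposited crystal structures at typical resolution
carry none); waters and heteroatoms never count; alternate locations are
resolved upstream to the highest-occupancy conformer (ties broken
alphabetically).  `side_chain_only` removes the *peptide's* backbone atoms
(N, CA, C, O, OXT) from the target set -- used for library designs that
target "peptide side chains" -- with the glycine alpha-carbon counting as a
side chain; antibody atoms are always all-atom.  Published contact counts
in this field were produced with CCP4 `Contact` or PyMOL, whose conventions
differ in detail; integer deviations of 1--2 atom pairs between conventions
are expected and should be reported as such rather than absorbed by cutoff
changes.

**Classification.**  Antibody residues partition into `P` (peptide only),
`M` (MHC only) and `PM` (both); residues with no contacts are absent from
the footprint table.  The classification drives the design rule below.

**Buried surface.**  Shrake--Rupley solvent-accessible surface area with a
1.4 Å probe and a fixed 960-point Fibonacci lattice per atom (deterministic,
so results are identical run to run; the lattice density sets an ~1%
sampling tolerance).  Van der Waals radii follow the common Bondi-style
table (C 1.70, N 1.55, O 1.52, S 1.80 Å; 1.80 Å fallback).  BSA of an
entity is its summed SASA loss between the pMHC alone and the full complex,
reported separately for peptide and MHC heavy chain.

**CDR annotation.**  The package operates on author numbering as deposited
and never renumbers: published residue labels (Q32, R65, K146, H151, ...)
are author numbers.  Kabat and Chothia interval tables are provided, but
since depositions rarely state their numbering scheme the scheme is a
user-facing choice, recorded in the annotation; `manual` ranges are accepted
verbatim and win over any table.

## Docking geometry

The groove frame is built from the alpha-carbons of the two groove helices
(author residues 50--86 and 138--176, configurable for numbering drift
between alleles): the groove axis is their first principal component,
oriented from peptide N- to C-terminus; the normal is the least-variance
component, oriented toward the antibody; the origin is the helix-CA
centroid (the groove rim, within a few Å of the peptide).  The antibody
axis joins the V-domain CA centroids (first 115 residues of each chain),
directed VL to VH.  The docking angle is measured between the antibody axis
*projected into the groove plane* and the groove axis -- an in-plane notion,
matching how footprint rotations are drawn -- and reported in [0, 180).

The rotation between two complexes sharing an MHC scaffold superposes the
query's helix CAs onto the reference's by a Kabsch least-squares fit
(refusing fits with RMSD > 3 Å), then measures the signed in-plane angle
between the two antibody axes.  The sign convention is fixed and documented
-- positive = clockwise viewed from the antibody down the groove normal,
with the groove axis running peptide N to C -- because published "clockwise"
statements do not define their viewpoint; the magnitude is the
convention-free quantity.

## Library design

The design rule is the repurposing strategy itself: randomize
peptide-contacting CDR positions, preserve MHC-contacting positions.
Dual-contact (`PM`) positions are a genuine policy choice -- the mouse
template design randomized all nine positions within 4 Å of the peptide
(some of which also touch MHC), while the human design ignored
MHC-contacting residues -- so `include_PM` is an explicit flag (default
`TRUE`).  Theoretical diversity is the exact integer
`alphabet^positions`, computed in big-integer arithmetic (20^20 already
exceeds double precision); reports always label it as theoretical sequence
space, distinct from realized transformant counts, which are limited by
transformation efficiency and were the figures quoted for the actual
libraries (~5e8 and ~2e8).

## Synthetic complexes with designed contact geometry

Deposited coordinates are an external resource; the package instead ships a
generator of toy five-chain complexes (`build_synthetic_complex()`) whose
antibody/target contact set is *exactly* a user-supplied plan.  Peptide,
helices and domain bulks are idealized point clouds; "contact clusters" of
antibody side-chain atoms are planted 3.4 Å from designated target atoms
while every other cross pair stays above 4 Å, and the generator verifies
the realized pair multiset against the plan by an exhaustive distance scan,
failing loudly on any accidental contact.  `synthetic_tcrm_complex()`
instantiates three stand-ins whose designed footprints equal the published
interface statistics of the mouse template (nine peptide-proximal CDR
residues), the human template (seven side-chain-proximal residues, 14
contacted MHC residues with a 50% three-residue hotspot share, 30% of MHC
contacts from CDRH-1/2) and the re-engineered MART1 binder (26 peptide
contacts, 12 from CDRL-1, 11 via light-chain Q32; 7 MHC residues with an
80% hotspot share; no CDRH-1/2 MHC contacts; docked 9 degrees clockwise of
the template on the same scaffold).

What passing tests on these stand-ins shows: the measurement pipeline
(parsing, role assignment, contact detection, classification, shares,
geometry, design selection) recovers designed ground truth exactly, and the
published statistics are internally consistent under the package's contact
convention.  What it does not show: agreement with the deposited
coordinates themselves -- the toys are labeled synthetic everywhere, and
running the same functions on the real PDB entries (a one-line
`fetch_structure()` + `load_structure()` + `assign_roles()` chain for users
with network access) is the corresponding real-data check.

## Synthetic single-molecule data

The generator mirrors the acquisition used for antigen counting: 32 ms per
frame, 150-frame stacks.  Mobile molecules are Poisson-seeded at the target
density on a rectangular field (default 12 x 12 um -- a realistic visible
basal membrane area, and large enough that ~115 molecules populate the
highest condition, 0.8 um^-2), diffuse with per-axis steps
Normal(0, sqrt(2 D dt)) at D = 0.1 um^2/s (a typical plasma-membrane
protein mobility), reflect at the field edge (molecules are confined to the
cell), and carry tags that bleach independently with per-frame probability
0.02 and are detected with probability 0.9.  Localizations get isotropic
Gaussian error (sigma 20 nm).  An immobile adsorbed background (default
0.1 um^-2 in the study conditions used by the tests) reproduces the
population that the analysis must remove.  Dual-color mode assigns each of
(default) two tags a color independently at 50/50 -- an IgG carries two tag
epitopes; tag valence is configurable since it is not a measured quantity.
Same-color tags on one molecule are optically unresolvable, so a molecule
emits at most one localization per channel per frame, detected when any of
its live tags is.  Everything is driven by one integer seed through R's
default Mersenne-Twister generator; a fixed seed reproduces the tables
byte for byte.

Not modeled: blinking photophysics beyond single-step bleaching, 3D
membrane topology, anomalous diffusion, and spatially varying illumination.
Recovery results on this generator therefore demonstrate correctness of the
estimators under their own assumptions, not robustness to those effects.

## Quantification pipeline: numerical choices

**Tracking** is a simplified multiple-target tracker: per frame, candidate
track/localization pairs are gated at `max_disp` (0.5 um) per elapsed
frame, and assignments are resolved globally by minimal total displacement
(Hungarian algorithm, `clue::solve_LSAP`); gaps up to `max_gap = 2` frames
are bridged.  Ties are resolved deterministically given input order.

**Immobile removal** is a track-level median-radius rule: a track is
immobile when >= 80% of its localizations lie within 0.1 um of its median
position.  This replaces the cited spatiotemporal clustering with the same
contract (remove stationary adsorbed emitters); parameters are exposed.
Single-frame tracks are immobile under this rule, which also sweeps up
mobile molecules that bleach within their first frames -- an unavoidable
confusion that produces a small (<~5%) downward bias in mobile counts,
measured in the tests.

**Bleach extrapolation** fits `N(t) = N0 exp(-k t)` by Levenberg--Marquardt
(initialized from a log-linear regression) to per-frame mobile-molecule
counts.  Counts are taken from tracks alive at each frame (default
`counts_source = "tracks"`): with detection probability < 1, raw per-frame
localization counts estimate `p_det * N(t)` and would bias N0 low by
`1 - p_det`, whereas track spans bridge missed detections.  Because a
molecule missed in the opening frames starts its track late, the first few
frames are biased low; the fit therefore starts at frame `max_gap + 1` and
extrapolates to frame 0.  Non-decreasing series return the mean with a
warning flag; the first-frame count is always reported alongside N0.

**Dual-color correction** implements the printed formula
`A + B - 0.5 AB` exactly.  Under the two-tag labeling model it is known to
over-count: with equal color odds half the molecules are dual-labeled, and
subtracting only half of AB leaves `N (1 + 0.5 * f_mixed)` even at perfect
cotrack recovery (ratio 1.25 at f_mixed = 0.5); cotracks missed because a
tag bleaches before 10 consecutive joint steps push the measured ratio near
1.5 under the default conditions.  The package measures and reports this
bias on synthetic truth (`analysis/06_dual_color_correction.R`) rather than
silently replacing the published formula.

**Cotracking** declares same-frame cross-channel localizations within
150 nm colocalized (one-to-one per frame by minimal total distance) and
counts a track pair once when it colocalizes over at least 10 consecutive
frame-to-frame steps, i.e. 11 consecutive frames (= 320 ms at 32 ms/frame).

**vCSA segmentation** is Otsu's threshold on the smoothed background
fluorescence, keeping the largest connected component; **channel
registration** is a closed-form (Umeyama) least-squares similarity fit to
calibration bead pairs, cross-checked in the tests against an independent
Procrustes implementation; sub-5 nm residuals on >= 100 bead pairs are the
acceptance bar for the round trip.

## Enrichment profiling

Per-position amino-acid frequencies are computed over *unique* peptides
(selection output is clone-redundant), columns normalized after an optional
pseudocount.  The proteome scan scores every length-L window by
`sum(log(freq + 1e-6))`, optionally masking anchor positions; it is a
deliberately simple log-likelihood ranking for locating a motif's source
protein (the published pipeline's prediction scripts are external and not
reproduced here).  The cytotoxicity formula,
`(1 - treated/control) * 100`, is implemented exactly, with negative values
flagged rather than clipped.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated data:
three ~900-atom synthetic complexes, 20-seed recovery batches at densities
0.05/0.2/0.8 um^-2 on a 144 um^2 field, 20-seed photobleach and
planted-consensus batches, and small rendered image stacks.  These sizes
give 2 standard errors of a few percent on the recovered quantities while
keeping the full suite under a minute of compute.  All stochastic stages
take explicit integer seeds; geometry and SASA are fully deterministic.

## Known limitations

* The structural stand-ins are idealized geometry; chemistry (bond lengths,
  rotamers, packing) is not modeled, so SASA/BSA magnitudes are
  toy-specific even though the decomposition logic is general.
* Kabat/Chothia interval tables assume Kabat-compatible author numbering;
  structures deposited with sequential numbering need `manual` ranges.
* The tracker is greedy-per-frame with global per-frame assignment; it does
  not re-float past links (no multiple-hypothesis smoothing), so identity
  swaps are possible at high density, which matters for cotrack counts but
  not for alive-track counts.
* Eq. (2)'s 0.5 coefficient is reproduced as printed; its measured bias
  under the two-tag model is reported, not corrected.
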