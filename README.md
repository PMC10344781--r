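# tcrmtools

Structure-guided repurposing of TCR-mimic (TCRm) antibodies, and
single-molecule quantification of the antigens they target.

TCRm antibodies recognize peptide–MHC class I complexes the way T cell
receptors do: CDR1/CDR2 loops engage the MHC helices, CDR3-proximal loops
read the peptide in the groove. An antibody with such a canonical docking
footprint can be re-engineered for new peptide specificities by randomizing
**only** the CDR positions that contact the peptide while preserving every
MHC-contacting position. `tcrmtools` is for structural immunologists and
protein engineers who want to

1. **map the interface** of an antibody–pMHC complex: atom contacts within a
   cutoff (4 Å default, inclusive), residue classification as peptide (P),
   MHC (M) or both (P/M), per-CDR contact shares, hydrogen-bond/salt-bridge
   labels, and a Shrake–Rupley buried-surface decomposition into peptide and
   MHC portions;
2. **measure docking geometry**: a groove-fixed frame from the α1/α2 helix
   Cα (residues 50–86 and 138–176), the in-plane docking angle of the
   antibody axis, and the signed clockwise rotation between two complexes
   superposed (Kabsch) on a shared MHC scaffold;
3. **design the focused library**: randomized vs preserved positions from
   the footprint, with exact theoretical diversity `alphabet ^ positions`
   (big-integer arithmetic, clearly labelled as theoretical sequence space
   vs realized transformant counts);
4. **count antigens on cells** from single-molecule TIRF localization data
   (32 ms/frame, 150-frame stacks): trajectory linking (Hungarian
   assignment, gap closing), immobile-background removal, photobleaching
   extrapolation of the initial mobile count `N0`, and the density
   equations

   - `ρ = N0 / vCSA` (visible cell surface area),
   - dual-color correction `N = A + B − 0.5·AB` (counts in each spectral
     channel, minus cotracked molecules: colocalized within 150 nm over
     ≥ 10 consecutive steps),
   - `N_cell = ρ × tCSA` (total cell surface area, default 3900 µm²,
     estimated as 2 × the segmented contour area);
5. **profile enriched peptides**: per-position amino-acid frequencies over
   unique peptides and a simple log-likelihood proteome scan, plus the
   cytotoxicity formula `(1 − treated/control) × 100`.

Both arms ship **synthetic-data generators** — toy antibody–pMHC complexes
whose contact geometry is exact by construction (verified by an exhaustive
distance scan at build time), and simulated single-molecule movies/tables
(Brownian diffusion, exponential photobleaching, stochastic dual-color
labeling, immobile adsorbed background) — so every stage is testable against
known ground truth without any external data. The shipped stand-in
complexes (`synthetic_tcrm_complex()`) realize the published interface
statistics of the two engineering templates and one re-engineered binder as
*designed* geometry; they are labelled synthetic throughout. With network
access, `fetch_structure("7TR4")` + `load_structure()` + `assign_roles()`
runs the same pipeline on deposited coordinates.

## Worked example

Footprint of the re-engineered MART1/HLA-A\*02:01 binder (synthetic
stand-in):

```r
library(tcrmtools)
cx <- synthetic_tcrm_complex("ma2-mart1-a2")
footprint_report(cx)
#> Interface footprint (cutoff 4.0 A)
#>   56 atom contacts: 26 to peptide, 30 to MHC
#>   8 antibody residues contact the peptide; 7 distinct MHC residues contacted
#>   buried surface: peptide 295 A^2, MHC 236 A^2
#>
#> Per-residue classification (P = peptide, M = MHC, PM = both):
#>  chain resno resid    cdr n_contacts_peptide n_contacts_mhc peptide_positions class
#>      H    31   ALA CDRH-1                  2              0                P3     P
#>      ...
#>      L    32   GLN CDRL-1                 11              0       P4,P5,P7,P8     P
#>      ...
```

Light-chain Q32 alone makes 11 of the 26 peptide contacts (positions
P4/P5/P7/P8), CDRL-1 makes 12, heavy-chain CDR1/CDR2 make no MHC contacts,
and R65/K146/H151 carry 80% of the antibody–MHC contacts
(`mhc_residue_share(find_contacts(cx), c("R65","K146","H151"))`). The
docking rotation relative to the template on the same scaffold:

```r
docking_rotation(synthetic_tcrm_complex("3m4e5-nyeso-a2"), cx)
#> [1] 9      # degrees, clockwise viewed from the antibody
```

Antigen counting on a simulated high-density acquisition:

```r
sim <- simulate_smlm(sim_config(true_density = 0.8, field = c(12, 12),
                                immobile_density = 0.1, seed = 7))
quantify_density(sim$table, quant_config(vCSA = 144))
#> Antigen density result
#>   initial mobile count N0: 143.67 (first frame: 119)
#>   vCSA: 144.0 um^2  ->  rho = 0.9977 um^-2
#>   per cell (tCSA 3900 um^2): 3891 molecules
sim$truth$n_mobile
#> [1] 139
```

The extrapolated `N0` recovers the simulated 139 mobile molecules within a
few percent despite per-frame bleaching (2%/frame) and imperfect detection
(90%/frame); `ρ` and the per-cell count follow by the exact identities
above.

## Analysis workflow

Numbered drivers under `analysis/` narrate the full study flow and write
their tables under `results/`:

| script | what it computes |
|---|---|
| `01_structural_footprints.R` | P/M/PM footprint tables, MHC-residue shares, BSA split for the three complexes |
| `02_library_design.R` | randomized/preserved positions and theoretical diversities for both templates |
| `03_docking_geometry.R` | docking angles and the template→re-engineered rotation |
| `04_simulate_imaging.R` | synthetic TIRF acquisitions (localization CSVs) |
| `05_quantify_antigen_density.R` | density recovery across 0.05–0.8 µm⁻² and per-cell counts |
| `06_dual_color_correction.R` | measured bias of the `A + B − 0.5·AB` correction vs ground truth |
| `07_enrichment_profiling.R` | position frequency matrix, proteome scan, cytotoxicity titration |

Run any of them from the repository root, e.g.
`Rscript analysis/05_quantify_antigen_density.R`.

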