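#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by sphere sampling with a fixed deterministic Fibonacci
#' lattice, so results are identical run to run.
#'
#' @param xyz n x 3 coordinate matrix (A) or a structure-like object.
#' @param radii Per-atom van der Waals radii (A); derived from the element
#'   column when `xyz` is a structure.
#' @param probe Probe radius, default 1.4 A (water).
#' @param n_points Sample points per atom (>= 960 by default).
#' @return Numeric vector of per-atom SASA values, A^2.
#' @export
sasa_atoms <- function(xyz, radii = NULL, probe = 1.4, n_points = 960) {
  if (!is.matrix(xyz)) {
    at <- atom_table(xyz)
    at <- at[!at$is_water & at$elesy != "H", , drop = FALSE]
    radii <- vdw_radius(at$elesy)
    xyz <- as.matrix(at[, c("x", "y", "z")])
  }
  stopifnot(ncol(xyz) == 3, length(radii) == nrow(xyz))
  .sasa_cpp(xyz, radii, probe = probe, n_points = as.integer(n_points))
}

#' Buried surface area of the pMHC upon antibody binding, split by entity
#'
#' Computes per-atom SASA of the pMHC (peptide + MHC heavy chain + beta-2-
#' microglobulin) alone and within the full complex; the buried area of an
#' entity is the summed SASA loss over its atoms.
#'
#' @param complex A `tcrm_complex` with roles assigned.
#' @param probe Probe radius (A).
#' @param n_points Sample points per atom.
#' @return List with `bsa_peptide`, `bsa_mhc` (A^2), plus `bsa_total` and the
#'   parameters used.
#' @export
buried_surface <- function(complex, probe = 1.4, n_points = 960) {
  stopifnot(inherits(complex, "tcrm_complex"))
  at <- complex$atoms
  at <- at[!at$is_water & !at$is_het & at$elesy != "H", , drop = FALSE]
  roles <- complex$roles
  pmhc_ch <- names(roles)[roles %in% c("PEPTIDE", "MHC_HEAVY", "B2M")]
  ab_ch <- names(roles)[roles %in% c("AB_HEAVY", "AB_LIGHT")]

  keep <- at$chain %in% c(pmhc_ch, ab_ch)
  at <- at[keep, , drop = FALSE]
  radii <- vdw_radius(at$elesy)
  xyz <- as.matrix(at[, c("x", "y", "z")])

  s_complex <- sasa_atoms(xyz, radii, probe, n_points)
  ispmhc <- at$chain %in% pmhc_ch
  s_alone <- sasa_atoms(xyz[ispmhc, , drop = FALSE], radii[ispmhc],
                        probe, n_points)

  dsasa <- s_alone - s_complex[ispmhc]
  sub <- at[ispmhc, ]
  pep_ch <- role_chain(complex, "PEPTIDE")
  mhc_ch <- role_chain(complex, "MHC_HEAVY")
  list(bsa_peptide = max(0, sum(dsasa[sub$chain == pep_ch])),
       bsa_mhc = max(0, sum(dsasa[sub$chain == mhc_ch])),
       bsa_total = max(0, sum(dsasa)),
       probe = probe, n_points = n_points)
}
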