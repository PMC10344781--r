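# Synthetic antibody-pMHC complexes with designed ground-truth contact
# geometry.
#
# These are geometric toys, not physical models: chains are idealized point
# clouds, and "contact clusters" of antibody side-chain atoms are planted at
# 3.4 A from designated target atoms while every other antibody/target atom
# pair is kept > 4 A apart (verified at build time by an exhaustive distance
# scan; construction fails loudly if the designed contact multiset is not
# realized exactly).  They exist so that the footprint, geometry and library
# design stages can be tested against known ground truth without deposited
# coordinates.

PEP_SPACING <- 4.5       # peptide CA spacing, A (extended toy conformation)
TIP_Z <- 5.0             # z of raised side-chain target atoms
CONTACT_DIST <- 3.4      # planted antibody-target atom distance

SIDECHAIN_NAMES <- c("CB", "CG", "CG1", "CG2", "CD", "CD1", "CD2", "CE",
                     "CE1", "CE2", "CZ", "NZ", "NE", "NH1", "NH2", "OH")

#' Build a synthetic antibody-pMHC complex with designed contacts
#'
#' Constructs a five-chain toy complex (MHC heavy chain `A` with two groove
#' helices at author residues 50-86 and 138-176, beta-2-microglobulin `B`,
#' peptide `C`, antibody heavy `H` and light `L`) in which the set of
#' antibody/target atom pairs within 4 A is exactly the supplied contact
#' plan.  The antibody variable-domain bulk is placed above the groove along
#' a docking axis at `alpha_deg` from the groove axis, rotated clockwise (as
#' seen from the antibody) by `rotation_deg` about the groove normal.
#'
#' @param peptide One-letter peptide sequence (8-11 residues).
#' @param pep_plan Data frame `ab_chain`, `ab_resno`, `pos` (peptide position
#'   index, 1-based), `n` (atom pairs): designed side-chain contacts (for
#'   glycine positions the alpha carbon serves as the side chain).
#' @param mhc_plan Data frame `ab_chain`, `ab_resno`, `mhc_resno`, `n`:
#'   designed contacts to MHC helix residues (must lie in the helix windows,
#'   no two contacted MHC residues adjacent in sequence).
#' @param bb_plan Optional data frame `ab_chain`, `ab_resno`, `pos`, `n`:
#'   contacts to the peptide backbone carbonyl oxygen.
#' @param ab_resid Optional named character vector of residue identities for
#'   antibody positions, names like `"H95"`/`"L32"`, values 3-letter codes.
#' @param mhc_resid Same for MHC residues, names like `"65"`.
#' @param alpha_deg Docking axis angle, degrees from the groove axis.
#' @param rotation_deg Clockwise rotation of the antibody bulk about the
#'   groove normal, viewed from the antibody.
#' @return A `tcrm_complex` with roles assigned, Kabat CDRs annotated, and a
#'   `$truth` element echoing the design (contact plans, docking parameters).
#' @export
build_synthetic_complex <- function(peptide,
                                    pep_plan = NULL,
                                    mhc_plan = NULL,
                                    bb_plan = NULL,
                                    ab_resid = NULL,
                                    mhc_resid = NULL,
                                    alpha_deg = 50,
                                    rotation_deg = 0) {
  pep <- strsplit(peptide, "")[[1]]
  npep <- length(pep)
  stopifnot(all(pep %in% names(AA1)))
  empty_plan <- function(cols) as.data.frame(setNames(
    rep(list(integer(0)), length(cols)), cols))
  if (is.null(pep_plan)) pep_plan <- empty_plan(c("ab_chain", "ab_resno", "pos", "n"))
  if (is.null(bb_plan))  bb_plan  <- empty_plan(c("ab_chain", "ab_resno", "pos", "n"))
  if (is.null(mhc_plan)) mhc_plan <- empty_plan(c("ab_chain", "ab_resno", "mhc_resno", "n"))

  rows <- list()
  add <- function(chain, resno, resid, elety, x, y, z) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = as.integer(resno), insert = "", resid = resid,
      elety = elety, elesy = guess_element(elety), x = x, y = y, z = z,
      o = 1, alt = "", is_het = FALSE, is_water = FALSE,
      stringsAsFactors = FALSE)
  }

  ## ---- peptide chain C ------------------------------------------------
  pep_x <- (seq_len(npep) - (npep + 1) / 2) * PEP_SPACING
  sc_contacted <- sort(unique(pep_plan$pos))
  bb_contacted <- sort(unique(bb_plan$pos))
  pep_target <- list()   # position -> target atom coordinates
  for (i in seq_len(npep)) {
    aa3 <- AA1[[pep[i]]]
    ca <- c(pep_x[i], 0, 0)
    add("C", i, aa3, "N", ca[1] - 1.2, 0.8, -0.8)
    add("C", i, aa3, "CA", ca[1], 0, 0)
    add("C", i, aa3, "C", ca[1] + 1.2, 0.8, -0.8)
    o_up <- i %in% bb_contacted
    add("C", i, aa3, "O", ca[1] + 1.2, if (o_up) 0.8 else 2.0,
        if (o_up) 3.0 else -0.8)
    if (pep[i] != "G") {
      zb <- if (i %in% sc_contacted) TIP_Z else 1.5
      add("C", i, aa3, "CB", ca[1], -0.4, zb)
      pep_target[[i]] <- c(ca[1], -0.4, zb)
    } else {
      pep_target[[i]] <- ca  # glycine: CA is the side chain
    }
  }
  bb_target <- lapply(seq_len(npep), function(i)
    c(pep_x[i] + 1.2, if (i %in% bb_contacted) 0.8 else 2.0,
      if (i %in% bb_contacted) 3.0 else -0.8))

  ## ---- MHC heavy chain A ----------------------------------------------
  helix <- function(r) {
    if (r >= 50 && r <= 86) c((r - 68) * 2.5, 8, 1)
    else if (r >= 138 && r <= 176) c((r - 157) * 2.5, -8, 1)
    else NULL
  }
  mhc_contacted <- sort(unique(mhc_plan$mhc_resno))
  if (length(mhc_contacted) > 1 && any(diff(mhc_contacted) < 2))
    stop("contacted MHC residues must not be sequence-adjacent in the toy")
  tip_name <- function(resid) switch(resid, ARG = "NH1", LYS = "NZ",
                                     HIS = "NE2", GLN = "NE2", GLU = "OE1",
                                     ASP = "OD1", "CG")
  mhc_target <- list()
  for (r in 1:275) {
    hx <- helix(r)
    resid <- if (!is.null(mhc_resid) && as.character(r) %in% names(mhc_resid))
      mhc_resid[[as.character(r)]] else "ALA"
    if (!is.null(hx)) {
      add("A", r, resid, "CA", hx[1], hx[2], hx[3])
      if (r %in% mhc_contacted) {
        tp <- c(hx[1], hx[2] - sign(hx[2]) * 2, TIP_Z)
        add("A", r, resid, tip_name(resid), tp[1], tp[2], tp[3])
        mhc_target[[as.character(r)]] <- tp
      }
    } else {
      k <- sum(sapply(1:r, function(q) is.null(helix(q)))) - 1L
      add("A", r, resid, "CA", (k %% 30 - 15) * 3, (k %/% 30 - 3) * 3.2, -6 - (k %% 2))
    }
  }

  ## ---- beta-2-microglobulin chain B ------------------------------------
  for (r in 1:99)
    add("B", r, "ALA", "CA", ((r - 1) %% 12 - 6) * 3, ((r - 1) %/% 12 - 4) * 3, -20)

  ## ---- antibody bulk (chains H, L) -------------------------------------
  alpha <- (alpha_deg - rotation_deg) * pi / 180
  u <- c(cos(alpha), sin(alpha), 0)
  d <- 9
  v_cloud <- function(chain, len, centroid, z0) {
    for (j in seq_len(len)) {
      if (j <= 115) {
        dx <- ((j - 1) %% 10 - 4.5) * 1.5
        dy <- ((j - 1) %/% 10 - 5.5) * 1.5
        dz <- ((j - 1) %% 3 - 1) * 0.8
        add(chain, j, ab_res(chain, j, ab_resid), "CA",
            centroid[1] + dx, centroid[2] + dy, z0 + dz)
      } else {
        k <- j - 116L
        add(chain, j, ab_res(chain, j, ab_resid), "CA",
            centroid[1] + (k %% 10 - 4.5) * 1.5,
            centroid[2] + (k %/% 10 - 4.5) * 1.5, z0 + 12)
      }
    }
  }
  v_cloud("H", 220, d * u, 14)
  v_cloud("L", 214, -d * u, 14)

  ## ---- planted contact clusters ----------------------------------------
  # Group all planned pairs by target atom, lay out one cluster per target.
  plan <- rbind(
    if (nrow(pep_plan)) data.frame(ab_chain = pep_plan$ab_chain,
      ab_resno = pep_plan$ab_resno, n = pep_plan$n,
      tkey = paste0("P", pep_plan$pos), kind = "peptide_sidechain",
      stringsAsFactors = FALSE),
    if (nrow(bb_plan)) data.frame(ab_chain = bb_plan$ab_chain,
      ab_resno = bb_plan$ab_resno, n = bb_plan$n,
      tkey = paste0("O", bb_plan$pos), kind = "peptide_backbone",
      stringsAsFactors = FALSE),
    if (nrow(mhc_plan)) data.frame(ab_chain = mhc_plan$ab_chain,
      ab_resno = mhc_plan$ab_resno, n = mhc_plan$n,
      tkey = paste0("M", mhc_plan$mhc_resno), kind = "mhc",
      stringsAsFactors = FALSE))
  target_pos <- function(tkey) {
    kind <- substr(tkey, 1, 1)
    id <- as.integer(substring(tkey, 2))
    switch(kind, P = pep_target[[id]], O = bb_target[[id]],
           M = mhc_target[[as.character(id)]])
  }
  used_names <- list()  # per antibody residue, which side-chain names taken
  if (!is.null(plan) && nrow(plan)) {
    for (tk in unique(plan$tkey)) {
      sub <- plan[plan$tkey == tk, , drop = FALSE]
      tp <- target_pos(tk)
      ktot <- sum(sub$n)
      m <- 0L
      for (r in seq_len(nrow(sub))) {
        for (q in seq_len(sub$n[r])) {
          m <- m + 1L
          rho <- if (ktot == 1L) 0 else 0.75
          phi <- 2 * pi * (m - 1) / ktot
          dir <- c(rho * cos(phi), rho * sin(phi), 3.25)
          dir <- dir / sqrt(sum(dir^2))
          at <- tp + CONTACT_DIST * dir
          key <- paste0(sub$ab_chain[r], sub$ab_resno[r])
          nm <- setdiff(SIDECHAIN_NAMES, used_names[[key]])[1]
          if (is.na(nm)) stop("too many planted atoms on residue ", key)
          used_names[[key]] <- c(used_names[[key]], nm)
          add(sub$ab_chain[r], sub$ab_resno[r],
              ab_res(sub$ab_chain[r], sub$ab_resno[r], ab_resid),
              nm, at[1], at[2], at[3])
        }
      }
    }
  }

  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(match(atoms$chain, c("A", "B", "C", "H", "L")),
                       atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL

  validate_synthetic_contacts(atoms, plan, npep)

  cx <- assign_roles(structure(list(atoms = atoms, path = "<synthetic>",
                                    format = "synthetic"),
                               class = "raw_structure"))
  cx <- annotate_cdrs(cx, "kabat")
  cx$meta$source <- "synthetic"
  cx$truth <- list(pep_plan = pep_plan, mhc_plan = mhc_plan, bb_plan = bb_plan,
                   alpha_deg = alpha_deg, rotation_deg = rotation_deg)
  cx
}

# Residue identity of an antibody position: overrides, then planted J motifs,
# then alanine.
ab_res <- function(chain, resno, overrides) {
  key <- paste0(chain, resno)
  if (!is.null(overrides) && key %in% names(overrides)) return(overrides[[key]])
  if (chain == "H" && resno %in% 103:106)
    return(c("TRP", "GLY", "GLN", "GLY")[resno - 102])
  if (chain == "L" && resno %in% 98:101)
    return(c("PHE", "GLY", "GLY", "GLY")[resno - 97])
  "ALA"
}

# Exhaustive check that the antibody/target pairs within 4 A are exactly the
# designed plan (count per antibody residue x target residue).
validate_synthetic_contacts <- function(atoms, plan, npep) {
  ab <- atoms[atoms$chain %in% c("H", "L"), ]
  tg <- atoms[atoms$chain %in% c("A", "C"), ]
  d2 <- outer(ab$x, tg$x, "-")^2 + outer(ab$y, tg$y, "-")^2 +
    outer(ab$z, tg$z, "-")^2
  hit <- which(d2 <= 4.0^2, arr.ind = TRUE)
  got <- table(paste(ab$chain[hit[, 1]], ab$resno[hit[, 1]],
                     tg$chain[hit[, 2]], tg$resno[hit[, 2]]))
  want <- integer(0)
  if (!is.null(plan) && nrow(plan)) {
    tchain <- ifelse(substr(plan$tkey, 1, 1) == "M", "A", "C")
    tres <- as.integer(substring(plan$tkey, 2))
    want <- tapply(plan$n, paste(plan$ab_chain, plan$ab_resno, tchain, tres), sum)
  }
  g <- as.integer(got[sort(names(got))])
  w <- as.integer(want[sort(names(want))])
  if (!identical(sort(names(got)), sort(names(want))) || !identical(g, w))
    stop("synthetic complex failed contact validation: designed and realized ",
         "contact sets differ")
  invisible(TRUE)
}

#' Synthetic stand-ins for the study's three antibody-pMHC complexes
#'
#' Builds a toy complex whose designed contact footprint reproduces the
#' published interface statistics of one of three TCR-mimic antibody
#' complexes: `"25d116-ova-kb"` (mouse template; nine CDR residues within 4 A
#' of the SIINFEKL peptide), `"3m4e5-nyeso-a2"` (human template; seven CDR
#' residues within 4 A of SLLMWITQV side chains, 14 contacted MHC helix
#' residues of which R65/Q72/Q155 carry 50% of the antibody-MHC atom
#' contacts, 30% of MHC contacts from CDRH-1/2, light-chain Y32 making a
#' single peptide contact), and `"ma2-mart1-a2"` (re-engineered antibody;
#' 26 antibody-peptide atom contacts of which 12 from CDRL-1 and 11 from
#' light-chain Q32 toward P4/P5/P7/P8 of ELAGIGILTV, 7 contacted MHC residues
#' with R65/K146/H151 carrying 80%, CDRH-1/2 making no MHC contacts, and the
#' antibody docked 9 degrees clockwise relative to the `"3m4e5"` template on
#' the same scaffold).
#'
#' These are *synthetic* complexes: the published statistics are the designed
#' ground truth the generator realizes geometrically, not re-measurements of
#' the deposited coordinates.
#'
#' @param template One of `"25d116-ova-kb"`, `"3m4e5-nyeso-a2"`,
#'   `"ma2-mart1-a2"`.
#' @return A `tcrm_complex` with a `$truth` design record.
#' @export
synthetic_tcrm_complex <- function(template = c("25d116-ova-kb",
                                                "3m4e5-nyeso-a2",
                                                "ma2-mart1-a2")) {
  template <- match.arg(template)
  df <- function(...) data.frame(..., stringsAsFactors = FALSE)
  if (template == "25d116-ova-kb") {
    build_synthetic_complex(
      peptide = "SIINFEKL",
      pep_plan = df(ab_chain = c("H", "H", "H", "H", "H", "H", "L", "L", "L"),
                    ab_resno = c(31, 33, 50, 95, 97, 99, 32, 91, 93),
                    pos      = c(1, 3, 4, 5, 6, 7, 4, 5, 8),
                    n        = c(2, 2, 2, 3, 3, 2, 2, 2, 2)),
      mhc_plan = df(ab_chain  = c("H", "H", "H", "L"),
                    ab_resno  = c(52, 96, 33, 50),
                    mhc_resno = c(65, 146, 62, 151),
                    n         = c(3, 2, 2, 2)),
      alpha_deg = 45)
  } else if (template == "3m4e5-nyeso-a2") {
    build_synthetic_complex(
      peptide = "SLLMWITQV",
      pep_plan = df(ab_chain = c("L", "L", "L", "L", "H", "H", "H"),
                    ab_resno = c(32, 91, 93, 96, 95, 97, 99),
                    pos      = c(5, 4, 7, 5, 6, 5, 3),
                    n        = c(1, 3, 2, 2, 3, 4, 2)),
      bb_plan = df(ab_chain = "H", ab_resno = 100, pos = 9, n = 2),
      mhc_plan = df(
        ab_chain  = c("H", "H", "H", "H", "H", "H", "H", "H", "H", "H",
                      "L", "L", "L", "L", "L", "L", "L", "L"),
        ab_resno  = c(31, 33, 35, 52, 54, 58, 95, 97, 99, 100,
                      30, 32, 50, 53, 55, 91, 93, 96),
        mhc_resno = c(58, 62, 65, 65, 68, 143, 65, 72, 76, 80,
                      151, 146, 72, 155, 158, 155, 162, 166),
        n         = c(2, 2, 2, 3, 2, 1, 3, 3, 2, 2,
                      2, 2, 3, 3, 2, 3, 2, 1)),
      ab_resid = c(L32 = "TYR"),
      mhc_resid = c("65" = "ARG", "72" = "GLN", "155" = "GLN",
                    "146" = "LYS", "151" = "HIS"),
      alpha_deg = 50)
  } else {
    build_synthetic_complex(
      peptide = "ELAGIGILTV",
      pep_plan = df(ab_chain = c("L", "L", "L", "L", "L",
                                 "H", "H", "H", "H", "H", "H"),
                    ab_resno = c(32, 32, 32, 32, 30, 31, 33, 50, 95, 97, 99),
                    pos      = c(4, 5, 7, 8, 5, 3, 5, 6, 6, 5, 7),
                    n        = c(2, 3, 3, 3, 1, 2, 2, 2, 3, 3, 2)),
      mhc_plan = df(ab_chain  = c("H", "H", "H", "L", "L", "L",
                                  "L", "L", "L", "L"),
                    ab_resno  = c(95, 97, 99, 30, 50, 53, 91, 93, 94, 96),
                    mhc_resno = c(65, 65, 146, 146, 151, 151, 72, 155, 158, 166),
                    n         = c(4, 4, 4, 4, 4, 4, 2, 2, 1, 1)),
      ab_resid = c(L32 = "GLN"),
      mhc_resid = c("65" = "ARG", "146" = "LYS", "151" = "HIS",
                    "72" = "GLN", "155" = "GLN"),
      alpha_deg = 50, rotation_deg = 9)
  }
}

#' Apply a rigid motion to every atom of a complex
#'
#' @param complex A `tcrm_complex` or `raw_structure`.
#' @param R 3x3 rotation matrix.
#' @param t Length-3 translation vector.
#' @return The object with transformed coordinates.
#' @export
transform_complex <- function(complex, R = diag(3), t = c(0, 0, 0)) {
  at <- atom_table(complex)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  complex$atoms$x <- xyz[, 1] + t[1]
  complex$atoms$y <- xyz[, 2] + t[2]
  complex$atoms$z <- xyz[, 3] + t[3]
  complex
}

#' Rotation matrix about an arbitrary axis
#' @param axis Length-3 axis vector (normalized internally).
#' @param angle_deg Rotation angle, degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
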