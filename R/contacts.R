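#' Atom-level contacts between antibody and peptide/MHC
#'
#' Emits every antibody-atom / target-atom pair with Euclidean distance at or
#' below `cutoff` (inclusive, matching the "within 4 A" convention).  The
#' target is the peptide chain plus the MHC heavy chain; hydrogens are always
#' excluded, waters and heteroatoms never count.
#'
#' @param complex A `tcrm_complex` with roles assigned.
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @param side_chain_only If `TRUE`, backbone atoms (N, CA, C, O, OXT) of the
#'   *peptide* are excluded from the target set; for glycine the alpha carbon
#'   counts as side chain.  Antibody atoms are always all-atom, and MHC
#'   target atoms are unaffected.
#' @param restrict_to_cdrs If `TRUE`, only antibody atoms belonging to CDR
#'   residues (per [annotate_cdrs()]) are considered.
#' @return A `contact_table` data frame, one row per atom pair: `ab_chain`,
#'   `ab_resno`, `ab_insert`, `ab_resid`, `ab_atom`, `ab_cdr`, `target_role`
#'   (`"PEPTIDE"`/`"MHC"`), `target_chain`, `target_resno`, `target_resid`,
#'   `target_atom`, `peptide_position`, `distance`, `polar_class` (all
#'   `"vdw"` until [polar_contacts()] relabels).
#' @export
find_contacts <- function(complex, cutoff = 4.0, side_chain_only = FALSE,
                          restrict_to_cdrs = FALSE) {
  stopifnot(inherits(complex, "tcrm_complex"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a positive number")
  at <- complex$atoms
  at <- at[!at$is_water & !at$is_het & at$elesy != "H", , drop = FALSE]
  roles <- complex$roles

  ab_ch <- names(roles)[roles %in% c("AB_HEAVY", "AB_LIGHT")]
  if (length(ab_ch) < 1L) stop("no antibody chain roles assigned")
  pep_ch <- role_chain(complex, "PEPTIDE")
  mhc_ch <- role_chain(complex, "MHC_HEAVY")

  ab <- at[at$chain %in% ab_ch, , drop = FALSE]
  if (restrict_to_cdrs) {
    if (is.null(complex$cdr)) stop("restrict_to_cdrs requires annotate_cdrs()")
    keep <- vapply(seq_len(nrow(ab)), function(i)
      cdr_of(complex, ab$chain[i], ab$resno[i]) != "FR", logical(1))
    ab <- ab[keep, , drop = FALSE]
  }
  tg <- at[at$chain %in% c(pep_ch, mhc_ch), , drop = FALSE]
  if (side_chain_only) {
    drop <- tg$chain == pep_ch & tg$elety %in% BACKBONE_ATOMS &
      !(tg$resid == "GLY" & tg$elety == "CA")
    tg <- tg[!drop, , drop = FALSE]
  }
  if (!nrow(ab) || !nrow(tg)) return(empty_contacts(complex))

  abm <- as.matrix(ab[, c("x", "y", "z")])
  tgm <- as.matrix(tg[, c("x", "y", "z")])
  cut2 <- cutoff^2

  # blocked all-pairs scan to bound memory on full-size structures
  pairs <- list()
  bs <- 2000L
  for (s in seq(1L, nrow(abm), by = bs)) {
    e <- min(s + bs - 1L, nrow(abm))
    blk <- abm[s:e, , drop = FALSE]
    d2 <- outer(blk[, 1], tgm[, 1], "-")^2 +
      outer(blk[, 2], tgm[, 2], "-")^2 +
      outer(blk[, 3], tgm[, 3], "-")^2
    hit <- which(d2 <= cut2, arr.ind = TRUE)
    if (nrow(hit))
      pairs[[length(pairs) + 1L]] <-
        cbind(hit[, 1] + s - 1L, hit[, 2], d2[hit])
  }
  if (!length(pairs)) return(empty_contacts(complex))
  pr <- do.call(rbind, pairs)

  ai <- pr[, 1]; ti <- pr[, 2]
  pep_pos <- rep(NA_character_, length(ti))
  is_pep <- tg$chain[ti] == pep_ch
  pos_lookup <- setNames(names(complex$peptide_positions),
                         complex$peptide_positions)
  pep_pos[is_pep] <- pos_lookup[as.character(tg$resno[ti][is_pep])]

  out <- data.frame(
    ab_chain = ab$chain[ai], ab_resno = ab$resno[ai],
    ab_insert = ab$insert[ai], ab_resid = ab$resid[ai],
    ab_atom = ab$elety[ai],
    ab_cdr = if (is.null(complex$cdr)) NA_character_ else
      vapply(seq_along(ai), function(k)
        cdr_of(complex, ab$chain[ai[k]], ab$resno[ai[k]]), character(1)),
    target_role = ifelse(is_pep, "PEPTIDE", "MHC"),
    target_chain = tg$chain[ti], target_resno = tg$resno[ti],
    target_resid = tg$resid[ti], target_atom = tg$elety[ti],
    peptide_position = pep_pos,
    distance = sqrt(pr[, 3]),
    polar_class = "vdw",
    stringsAsFactors = FALSE)
  out <- out[order(out$ab_chain, out$ab_resno, out$target_chain,
                   out$target_resno, out$ab_atom, out$target_atom), ]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "side_chain_only") <- side_chain_only
  attr(out, "restrict_to_cdrs") <- restrict_to_cdrs
  attr(out, "complex_id") <- complex_id(complex)
  class(out) <- c("contact_table", "data.frame")
  out
}

empty_contacts <- function(complex) {
  out <- data.frame(ab_chain = character(0), ab_resno = integer(0),
                    ab_insert = character(0), ab_resid = character(0),
                    ab_atom = character(0), ab_cdr = character(0),
                    target_role = character(0), target_chain = character(0),
                    target_resno = integer(0), target_resid = character(0),
                    target_atom = character(0),
                    peptide_position = character(0),
                    distance = numeric(0), polar_class = character(0),
                    stringsAsFactors = FALSE)
  attr(out, "complex_id") <- complex_id(complex)
  class(out) <- c("contact_table", "data.frame")
  out
}

complex_id <- function(complex) {
  paste0(complex$meta$source %||% "unknown", ":",
         paste(names(complex$roles), complex$roles, sep = "=", collapse = ","),
         ":", nrow(complex$atoms))
}

#' Classify antibody residues by P / M / P-M contact footprint
#'
#' Projects atom-pair contacts onto antibody residues: class `P` if the
#' residue contacts only the peptide, `M` if only the MHC, `PM` if both.
#' Residues with zero contacts do not appear.
#'
#' @param contacts A `contact_table` from one complex.
#' @return A `footprint_table` data frame sorted by chain then residue
#'   number: `chain`, `resno`, `resid`, `cdr`, `n_contacts_peptide`,
#'   `n_contacts_mhc`, `peptide_positions` (comma-separated `P#` labels),
#'   `class`.
#' @export
classify_ab_residues <- function(contacts) {
  stopifnot(inherits(contacts, "contact_table"))
  ids <- attr(contacts, "complex_id")
  if (length(unique(ids)) > 1L)
    stop("contacts must come from a single complex")
  if (!nrow(contacts)) {
    out <- data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), cdr = character(0),
                      n_contacts_peptide = integer(0),
                      n_contacts_mhc = integer(0),
                      peptide_positions = character(0), class = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("footprint_table", "data.frame")
    return(out)
  }
  key <- paste(contacts$ab_chain, contacts$ab_resno, contacts$ab_insert,
               sep = "\r")
  split_idx <- split(seq_len(nrow(contacts)), key)
  rows <- lapply(split_idx, function(ix) {
    sub <- contacts[ix, ]
    np <- sum(sub$target_role == "PEPTIDE")
    nm <- sum(sub$target_role == "MHC")
    pp <- unique(sub$peptide_position[!is.na(sub$peptide_position)])
    pp <- pp[order(as.integer(substring(pp, 2)))]
    data.frame(chain = sub$ab_chain[1], resno = sub$ab_resno[1],
               resid = sub$ab_resid[1], cdr = sub$ab_cdr[1],
               n_contacts_peptide = np, n_contacts_mhc = nm,
               peptide_positions = paste(pp, collapse = ","),
               class = if (np > 0 && nm > 0) "PM" else if (np > 0) "P" else "M",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chain, out$resno), ]
  rownames(out) <- NULL
  attr(out, "complex_id") <- ids
  attr(out, "cutoff") <- attr(contacts, "cutoff")
  attr(out, "side_chain_only") <- attr(contacts, "side_chain_only")
  attr(out, "restrict_to_cdrs") <- attr(contacts, "restrict_to_cdrs")
  class(out) <- c("footprint_table", "data.frame")
  out
}

#' Fraction of antibody-MHC atom contacts carried by an MHC residue subset
#'
#' @param contacts A `contact_table`.
#' @param residue_subset MHC residue numbers; either integers or strings with
#'   a one-letter residue prefix (`"R65"`).
#' @return Fraction in `[0, 1]`.
#' @export
mhc_residue_share <- function(contacts, residue_subset) {
  stopifnot(inherits(contacts, "contact_table"))
  resnos <- vapply(residue_subset, function(r) {
    if (is.numeric(r)) return(as.integer(r))
    as.integer(sub("^[A-Za-z]", "", r))
  }, integer(1))
  mhc <- contacts[contacts$target_role == "MHC", , drop = FALSE]
  if (!nrow(mhc))
    stop("no antibody-MHC contacts present; share undefined")
  sum(mhc$target_resno %in% resnos) / nrow(mhc)
}

#' Relabel contacts as hydrogen bonds or salt bridges
#'
#' Geometric criteria on heavy atoms only: a hydrogen bond is any N/O-N/O
#' pair within `donor_acceptor_cutoff`; a salt bridge is a pair of side-chain
#' charged-group nitrogen/oxygen atoms of opposite formal charge (Arg/Lys/His
#' vs Asp/Glu) within `saltbridge_cutoff`.  Salt-bridge labels take precedence
#' over hydrogen bonds, which take precedence over `vdw`.
#'
#' @param complex A `tcrm_complex`.
#' @param contacts Optional precomputed `contact_table`; computed at
#'   `max(saltbridge_cutoff, donor_acceptor_cutoff)` if missing.
#' @param donor_acceptor_cutoff Hydrogen-bond distance cutoff (A).
#' @param saltbridge_cutoff Salt-bridge distance cutoff (A).
#' @return The `contact_table` with `polar_class` in
#'   `{"vdw","hbond","saltbridge"}`.
#' @export
polar_contacts <- function(complex, contacts = NULL,
                           donor_acceptor_cutoff = 3.5,
                           saltbridge_cutoff = 4.0) {
  if (is.null(contacts))
    contacts <- find_contacts(complex,
                              cutoff = max(donor_acceptor_cutoff,
                                           saltbridge_cutoff))
  no <- c("N", "O")
  ab_el <- guess_element(contacts$ab_atom)
  tg_el <- guess_element(contacts$target_atom)
  both_no <- ab_el %in% no & tg_el %in% no
  hb <- both_no & contacts$distance <= donor_acceptor_cutoff

  pos_atoms <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                    HIS = c("ND1", "NE2"))
  neg_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  charged <- function(resid, atom, table) {
    ok <- logical(length(resid))
    for (r in names(table)) ok <- ok | (resid == r & atom %in% table[[r]])
    ok
  }
  ab_pos <- charged(contacts$ab_resid, contacts$ab_atom, pos_atoms)
  ab_neg <- charged(contacts$ab_resid, contacts$ab_atom, neg_atoms)
  tg_pos <- charged(contacts$target_resid, contacts$target_atom, pos_atoms)
  tg_neg <- charged(contacts$target_resid, contacts$target_atom, neg_atoms)
  sb <- ((ab_pos & tg_neg) | (ab_neg & tg_pos)) &
    contacts$distance <= saltbridge_cutoff

  contacts$polar_class[hb] <- "hbond"
  contacts$polar_class[sb] <- "saltbridge"
  contacts
}
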