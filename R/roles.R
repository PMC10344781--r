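#' Assign biological roles to the chains of an antibody-pMHC complex
#'
#' Roles are inferred from chain length and sequence content:
#' \describe{
#'   \item{PEPTIDE}{shortest polymer chain of length 8-12 residues}
#'   \item{B2M}{~95-105 residues}
#'   \item{MHC_HEAVY}{~270-290 residues (class I ectodomain)}
#'   \item{AB_HEAVY / AB_LIGHT}{the two remaining V-domain-containing chains,
#'     separated by the J-segment motifs `WG.G` (heavy) vs `FG.G` (light)
#'     within the variable domain}
#' }
#' Explicit `hints` override the heuristics verbatim.
#'
#' @param structure A `raw_structure` (or `tcrm_complex` to re-assign).
#' @param hints Optional named character vector or list, `chain id -> role`
#'   with roles among `r paste(ROLE_LEVELS, collapse = ", ")`.
#' @return A `tcrm_complex`: list with `atoms`, `roles` (named chain -> role),
#'   `peptide_positions` (named integer vector, `P1..Pn` -> author resno),
#'   `cdr` (filled by [annotate_cdrs()]) and `meta`.
#' @export
assign_roles <- function(structure, hints = NULL) {
  atoms <- atom_table(structure)
  poly <- atoms[!atoms$is_het & !atoms$is_water & atoms$resid %in% names(AA3), ,
                drop = FALSE]
  chains <- sort(unique(poly$chain))
  lens <- vapply(chains, function(ch) {
    sub <- poly[poly$chain == ch, ]
    length(unique(paste(sub$resno, sub$insert)))
  }, integer(1))
  names(lens) <- chains

  roles <- setNames(rep(NA_character_, length(chains)), chains)
  hints <- unlist(hints)
  if (!is.null(hints)) {
    bad <- setdiff(unname(hints), ROLE_LEVELS)
    if (length(bad)) stop("unknown role in hints: ", paste(bad, collapse = ", "))
    roles[names(hints)] <- unname(hints)
  }
  if (length(chains) < 4L && !all(!is.na(roles)))
    stop("structure has fewer than 4 polymer chains; supply hints for all chains")

  free <- names(roles)[is.na(roles)]

  take <- function(cand, role) {
    cand <- intersect(cand, free)
    if (role %in% roles[!is.na(roles)]) return(character(0))  # hinted already
    if (length(cand) > 1L && role == "PEPTIDE")
      stop("two chains match PEPTIDE (", paste(cand, collapse = ", "),
           "); supply hints")
    cand
  }

  pep <- take(names(lens)[lens >= 8 & lens <= 12], "PEPTIDE")
  if (length(pep) == 1L) { roles[pep] <- "PEPTIDE"; free <- setdiff(free, pep) }
  b2m <- take(names(lens)[lens >= 95 & lens <= 105], "B2M")
  if (length(b2m) > 1L) stop("ambiguous B2M assignment among chains: ",
                             paste(b2m, collapse = ", "), "; supply hints")
  if (length(b2m) == 1L) { roles[b2m] <- "B2M"; free <- setdiff(free, b2m) }
  mhc <- take(names(lens)[lens >= 270 & lens <= 290], "MHC_HEAVY")
  if (length(mhc) > 1L) stop("ambiguous MHC_HEAVY assignment among chains: ",
                             paste(mhc, collapse = ", "), "; supply hints")
  if (length(mhc) == 1L) { roles[mhc] <- "MHC_HEAVY"; free <- setdiff(free, mhc) }

  # Remaining antibody-sized chains: split heavy/light by J-motif
  ab_cand <- free[lens[free] >= 95 & lens[free] <= 260]
  for (ch in ab_cand) {
    sq <- chain_sequence(poly, ch)
    v <- substr(sq, 1, 130)
    hy <- grepl("WG.G", v)
    lt <- grepl("FG.G", v)
    if (hy && !lt) roles[ch] <- "AB_HEAVY"
    else if (lt && !hy) roles[ch] <- "AB_LIGHT"
  }
  und <- names(roles)[is.na(roles)]
  if (length(und))
    stop("ambiguous assignment for chain(s) ", paste(und, collapse = ", "),
         " (lengths ", paste(lens[und], collapse = ", "),
         "); supply hints")
  for (r in c("AB_HEAVY", "AB_LIGHT"))
    if (sum(roles == r) > 1L)
      stop("ambiguous assignment: multiple chains assigned ", r,
           " (", paste(names(roles)[roles == r], collapse = ", "),
           "); supply hints")

  if (sum(roles == "PEPTIDE") != 1L)
    stop("exactly one PEPTIDE chain required, got ", sum(roles == "PEPTIDE"))
  if (sum(roles == "MHC_HEAVY") != 1L)
    stop("exactly one MHC_HEAVY chain required, got ", sum(roles == "MHC_HEAVY"))

  pep_chain <- names(roles)[roles == "PEPTIDE"]
  psub <- poly[poly$chain == pep_chain, ]
  pres <- unique(psub[order(psub$resno, psub$insert), c("resno", "insert")])
  npep <- nrow(pres)
  if (npep < 8 || npep > 11)
    warning("peptide length ", npep, " outside the class I range 8-11")
  peptide_positions <- setNames(pres$resno, paste0("P", seq_len(npep)))

  structure(list(atoms = atoms, roles = roles,
                 peptide_positions = peptide_positions,
                 cdr = NULL,
                 meta = list(source = if (inherits(structure, "raw_structure"))
                   structure$path else attr(structure, "source"))),
            class = "tcrm_complex")
}

# One-letter sequence of a chain (ordered by author numbering)
chain_sequence <- function(atoms, chain) {
  sub <- atoms[atoms$chain == chain & atoms$resid %in% names(AA3) &
                 !atoms$is_het, , drop = FALSE]
  sub <- sub[order(sub$resno, sub$insert), ]
  res <- sub[!duplicated(paste(sub$resno, sub$insert)), "resid"]
  paste(AA3[res], collapse = "")
}

#' Peptide sequence of an annotated complex
#' @param complex A `tcrm_complex`.
#' @return One-letter peptide sequence.
#' @export
peptide_sequence <- function(complex) {
  stopifnot(inherits(complex, "tcrm_complex"))
  chain_sequence(complex$atoms, role_chain(complex, "PEPTIDE"))
}

role_chain <- function(complex, role) {
  ch <- names(complex$roles)[complex$roles == role]
  if (!length(ch)) stop("no chain with role ", role, " assigned")
  ch
}

#' @export
print.tcrm_complex <- function(x, ...) {
  cat("Annotated antibody-pMHC complex\n")
  for (ch in names(x$roles))
    cat(sprintf("  chain %s: %-9s (%d atoms)\n", ch, x$roles[ch],
                sum(x$atoms$chain == ch)))
  cat("  peptide:", peptide_sequence(x), "\n")
  if (!is.null(x$cdr))
    cat("  CDRs annotated (", x$cdr$scheme, " scheme)\n", sep = "")
  invisible(x)
}
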