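# CDR interval tables on author (Kabat-compatible) numbering.
# Ranges are inclusive [start, end] of author residue numbers.
CDR_SCHEMES <- list(
  kabat = list(
    heavy = list(CDR1 = c(31, 35), CDR2 = c(50, 65), CDR3 = c(95, 102)),
    light = list(CDR1 = c(24, 34), CDR2 = c(50, 56), CDR3 = c(89, 97))),
  chothia = list(
    heavy = list(CDR1 = c(26, 32), CDR2 = c(52, 56), CDR3 = c(95, 102)),
    light = list(CDR1 = c(24, 34), CDR2 = c(50, 56), CDR3 = c(89, 97)))
)

#' Annotate the six CDR loops of an antibody-pMHC complex
#'
#' Records CDR1/2/3 residue-number intervals for the antibody heavy and light
#' chains.  Intervals are interpreted on author numbering as deposited (no
#' renumbering is performed); the `kabat` and `chothia` tables therefore only
#' make sense for structures deposited with Kabat-style numbering, which is
#' the common case for Fab entries.  Use `scheme = "manual"` to supply ranges
#' verbatim.
#'
#' @param complex A `tcrm_complex` with `AB_HEAVY` and `AB_LIGHT` assigned.
#' @param scheme `"kabat"`, `"chothia"` or `"manual"`.
#' @param ranges For `scheme = "manual"`: a named list with elements among
#'   `H1`, `H2`, `H3`, `L1`, `L2`, `L3`, each a length-2 integer vector
#'   `c(start, end)`.  Loops not supplied fall back to the kabat table.
#' @return The complex with `$cdr = list(scheme, heavy = list(CDR1..3),
#'   light = list(CDR1..3))`.
#' @export
annotate_cdrs <- function(complex, scheme = c("kabat", "chothia", "manual"),
                          ranges = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(complex, "tcrm_complex"))
  for (role in c("AB_HEAVY", "AB_LIGHT")) {
    ch <- role_chain(complex, role)
    n <- length(unique(complex$atoms$resno[complex$atoms$chain == ch &
                                             !complex$atoms$is_het]))
    if (n < 95)
      stop("chain ", ch, " (", role, ") has ", n,
           " residues, shorter than an antibody V domain")
  }

  cdr <- CDR_SCHEMES[["kabat"]]
  if (scheme %in% names(CDR_SCHEMES)) cdr <- CDR_SCHEMES[[scheme]]
  if (scheme == "manual") {
    if (is.null(ranges) || !length(ranges)) stop("manual scheme requires ranges")
    for (nm in names(ranges)) {
      rg <- ranges[[nm]]
      if (length(rg) != 2L || any(is.na(rg)) || rg[1] > rg[2])
        stop("empty or invalid manual range for ", nm)
      side <- if (startsWith(nm, "H")) "heavy" else if (startsWith(nm, "L"))
        "light" else stop("manual range names must be H1..H3/L1..L3, got ", nm)
      cdr[[side]][[paste0("CDR", substr(nm, 2, 2))]] <- as.integer(rg)
    }
  }
  for (side in c("heavy", "light")) {
    iv <- do.call(rbind, cdr[[side]])
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      stop("overlapping CDR ranges on ", side, " chain")
  }
  complex$cdr <- c(list(scheme = scheme), cdr)
  complex
}

#' CDR membership of an antibody residue
#'
#' @param complex An annotated `tcrm_complex` (after [annotate_cdrs()]).
#' @param chain Chain id.
#' @param resno Author residue number(s).
#' @return Character vector: `"CDRH-1"`, `"CDRL-3"`, ... or `"FR"` for
#'   framework.
#' @export
cdr_of <- function(complex, chain, resno) {
  if (is.null(complex$cdr)) stop("call annotate_cdrs() first")
  side <- if (chain == role_chain(complex, "AB_HEAVY")) "heavy"
          else if (chain == role_chain(complex, "AB_LIGHT")) "light"
          else return(rep("FR", length(resno)))
  lab <- toupper(substr(side, 1, 1))
  out <- rep("FR", length(resno))
  for (k in 1:3) {
    rg <- complex$cdr[[side]][[paste0("CDR", k)]]
    out[resno >= rg[1] & resno <= rg[2]] <- paste0("CDR", lab, "-", k)
  }
  out
}
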