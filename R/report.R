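#' Full interface footprint report for an antibody-pMHC complex
#'
#' Runs the contact, classification, polar-labelling and buried-surface
#' stages and assembles the per-residue table plus interface summary
#' (distinct contacted MHC residues, per-CDR contact counts and fractions for
#' peptide- and MHC-directed contacts separately, buried surface split).
#'
#' @param complex An annotated `tcrm_complex`.
#' @param cutoff Contact cutoff (A).
#' @param side_chain_only Passed to [find_contacts()].
#' @param restrict_to_cdrs Passed to [find_contacts()].
#' @param bsa If `TRUE` (default) compute the buried-surface decomposition.
#' @return A `footprint_report`: list with `table` (the
#'   [classify_ab_residues()] output), `contacts`, `summary` (list described
#'   above).  `print()` renders the table; `as_record()` returns a
#'   JSON-serializable list mirroring it.
#' @export
footprint_report <- function(complex, cutoff = 4.0, side_chain_only = FALSE,
                             restrict_to_cdrs = FALSE, bsa = TRUE) {
  contacts <- find_contacts(complex, cutoff = cutoff,
                            side_chain_only = side_chain_only,
                            restrict_to_cdrs = restrict_to_cdrs)
  contacts <- polar_contacts(complex, contacts)
  tab <- classify_ab_residues(contacts)

  mhc <- contacts[contacts$target_role == "MHC", , drop = FALSE]
  pep <- contacts[contacts$target_role == "PEPTIDE", , drop = FALSE]
  cdr_levels <- c("CDRH-1", "CDRH-2", "CDRH-3", "CDRL-1", "CDRL-2", "CDRL-3",
                  "FR")
  per_cdr <- function(sub) {
    n <- table(factor(sub$ab_cdr, levels = cdr_levels))
    data.frame(cdr = cdr_levels, n_contacts = as.integer(n),
               fraction = if (nrow(sub)) as.numeric(n) / nrow(sub) else
                 rep(NA_real_, length(cdr_levels)),
               stringsAsFactors = FALSE)
  }
  mhc_res <- sort(unique(mhc$target_resno))
  mhc_counts <- if (nrow(mhc)) table(mhc$target_resno) else table(integer(0))

  summary <- list(
    cutoff = cutoff, side_chain_only = side_chain_only,
    restrict_to_cdrs = restrict_to_cdrs,
    n_contacts_total = nrow(contacts),
    n_contacts_peptide = nrow(pep),
    n_contacts_mhc = nrow(mhc),
    n_residues_contacting_peptide = sum(tab$n_contacts_peptide > 0),
    n_mhc_residues_contacted = length(mhc_res),
    mhc_residues_contacted = data.frame(
      resno = as.integer(names(mhc_counts)),
      n_contacts = as.integer(mhc_counts), stringsAsFactors = FALSE),
    per_cdr_peptide = per_cdr(pep),
    per_cdr_mhc = per_cdr(mhc),
    n_hbonds = sum(contacts$polar_class == "hbond"),
    n_saltbridges = sum(contacts$polar_class == "saltbridge"))
  if (bsa) summary <- c(summary, buried_surface(complex)[c("bsa_peptide",
                                                           "bsa_mhc")])
  structure(list(table = tab, contacts = contacts, summary = summary),
            class = "footprint_report")
}

#' @export
print.footprint_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Interface footprint (cutoff %.1f A%s%s)\n", s$cutoff,
              if (s$side_chain_only) ", peptide side chains only" else "",
              if (s$restrict_to_cdrs) ", CDR residues only" else ""))
  cat(sprintf("  %d atom contacts: %d to peptide, %d to MHC\n",
              s$n_contacts_total, s$n_contacts_peptide, s$n_contacts_mhc))
  cat(sprintf("  %d antibody residues contact the peptide; %d distinct MHC residues contacted\n",
              s$n_residues_contacting_peptide, s$n_mhc_residues_contacted))
  if (!is.null(s$bsa_peptide))
    cat(sprintf("  buried surface: peptide %.0f A^2, MHC %.0f A^2\n",
                s$bsa_peptide, s$bsa_mhc))
  cat("\nPer-residue classification (P = peptide, M = MHC, PM = both):\n")
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' Machine-readable record of a footprint report
#' @param report A `footprint_report`.
#' @return A plain list (data frames converted) suitable for
#'   `jsonlite::toJSON()`.
#' @export
as_record <- function(report) {
  stopifnot(inherits(report, "footprint_report"))
  list(table = as.data.frame(report$table),
       summary = lapply(report$summary, function(v)
         if (is.data.frame(v)) v else unname(v)))
}
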