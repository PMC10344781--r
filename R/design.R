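# Focused CDR randomization library design: randomize peptide-contacting
# antibody positions, preserve MHC-contacting positions.

#' Design policy for a focused randomization library
#'
#' @param contact_cutoff Contact cutoff (A) the footprint was computed at.
#' @param side_chain_only Whether the footprint counted peptide side-chain
#'   atoms only.
#' @param include_PM Randomize residues contacting both peptide and MHC
#'   (`PM` class).  Default `TRUE`: the mouse-template library randomized all
#'   residues within 4 A of peptide including dual-contact ones, while the
#'   human-template design ignored MHC-contacting residues; the flag is
#'   exposed because the two designs differ.
#' @param restrict_to_cdrs Restrict the randomized set to CDR residues.
#' @param alphabet Amino-acid alphabet used at randomized positions.
#' @return A `design_policy` list.
#' @export
design_policy <- function(contact_cutoff = 4.0, side_chain_only = FALSE,
                          include_PM = TRUE, restrict_to_cdrs = TRUE,
                          alphabet = unname(AA3)) {
  stopifnot(contact_cutoff > 0, length(alphabet) >= 1)
  structure(list(contact_cutoff = contact_cutoff,
                 side_chain_only = side_chain_only,
                 include_PM = include_PM,
                 restrict_to_cdrs = restrict_to_cdrs,
                 alphabet = alphabet), class = "design_policy")
}

#' Select randomization and preserved positions from a contact footprint
#'
#' The core design rule: positions whose residues contact the peptide are
#' randomized; positions contacting only the MHC are preserved.  Dual
#' (P/M-class) positions go to the randomized set when `include_PM` is `TRUE`
#' and to the preserved set otherwise.
#'
#' @param footprint A `footprint_table` from [classify_ab_residues()],
#'   computed under the policy's cutoff/side-chain settings.
#' @param policy A [design_policy()].
#' @return A `library_design`: list with `randomized` and `preserved` data
#'   frames (`chain`, `resno`, `resid`, `cdr`, `class`),
#'   `theoretical_diversity` (exact, as a character big integer) and
#'   `policy`.
#' @export
select_positions <- function(footprint, policy = design_policy()) {
  stopifnot(inherits(footprint, "footprint_table"),
            inherits(policy, "design_policy"))
  fp <- as.data.frame(footprint)
  if (policy$restrict_to_cdrs && nrow(fp))
    fp <- fp[!is.na(fp$cdr) & fp$cdr != "FR", , drop = FALSE]

  rand_cls <- if (policy$include_PM) c("P", "PM") else "P"
  rand <- fp[fp$class %in% rand_cls, , drop = FALSE]
  pres <- fp[!(fp$class %in% rand_cls), , drop = FALSE]
  if (!nrow(rand))
    stop("no peptide-contacting residues found; nothing to randomize")

  cols <- c("chain", "resno", "resid", "cdr", "class")
  structure(list(randomized = rand[, cols],
                 preserved = pres[, cols],
                 n_randomized = nrow(rand),
                 theoretical_diversity =
                   theoretical_diversity(nrow(rand),
                                         length(policy$alphabet)),
                 policy = policy),
            class = "library_design")
}

#' Theoretical diversity of a randomized library
#'
#' Exact `alphabet_size ^ n_positions`, computed with big-integer arithmetic
#' so counts beyond double precision stay exact.  Note the distinction from
#' *realized* library sizes (transformant counts), which are bounded by
#' transformation efficiency, not by this product.
#'
#' @param n_positions Number of randomized positions (>= 1).
#' @param alphabet_size Number of amino acids per position (>= 1).
#' @return Exact integer as a character string, with attribute `"numeric"`
#'   carrying the double approximation.
#' @export
theoretical_diversity <- function(n_positions, alphabet_size = 20L) {
  stopifnot(n_positions >= 1, alphabet_size >= 1)
  out <- bigint_pow(as.integer(alphabet_size), as.integer(n_positions))
  attr(out, "numeric") <- alphabet_size^n_positions
  out
}

# Exact non-negative integer power via base-1e4 limb arithmetic.
bigint_pow <- function(base, exp) {
  limbs <- c(1L)                       # little-endian, base 1e4
  mul <- function(a, m) {
    carry <- 0
    out <- integer(length(a) + 8L)
    for (i in seq_along(a)) {
      v <- a[i] * m + carry
      out[i] <- v %% 10000L
      carry <- v %/% 10000L
    }
    i <- length(a)
    while (carry > 0) {
      i <- i + 1L
      out[i] <- carry %% 10000L
      carry <- carry %/% 10000L
    }
    out[seq_len(max(i, length(a)))]
  }
  for (k in seq_len(exp)) limbs <- mul(limbs, base)
  n <- length(limbs)
  paste0(limbs[n], paste(sprintf("%04d", rev(limbs[-n])), collapse = ""))
}

#' Render a library design as text and a machine-readable record
#'
#' @param design A `library_design`.
#' @return Invisibly, a list record mirroring the printed output.
#' @export
design_report <- function(design) {
  stopifnot(inherits(design, "library_design"))
  p <- design$policy
  lines <- c(
    sprintf("Focused randomization library design (cutoff %.1f A%s, PM positions %s)",
            p$contact_cutoff,
            if (p$side_chain_only) ", peptide side chains only" else "",
            if (p$include_PM) "randomized" else "preserved"),
    "",
    sprintf("Randomized positions (%d):", nrow(design$randomized)))
  fmt <- function(df) sprintf("  %s%-4d %s  %-6s class %s",
                              df$chain, df$resno, df$resid, df$cdr, df$class)
  lines <- c(lines, if (nrow(design$randomized)) fmt(design$randomized))
  lines <- c(lines, "", sprintf("Preserved MHC-contacting positions (%d):",
                                nrow(design$preserved)),
             if (nrow(design$preserved)) fmt(design$preserved) else "  none")
  lines <- c(lines, "",
             sprintf("Theoretical diversity: %d^%d = %s",
                     length(p$alphabet), nrow(design$randomized),
                     as.character(design$theoretical_diversity)),
             "(theoretical sequence space; realized library sizes are transformant counts and will be smaller)")
  cat(lines, sep = "\n")
  invisible(list(randomized = design$randomized,
                 preserved = design$preserved,
                 theoretical_diversity = as.character(design$theoretical_diversity),
                 alphabet_size = length(p$alphabet),
                 policy = unclass(p)))
}
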