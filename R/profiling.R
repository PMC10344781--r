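# Peptide-enrichment profiling of selection outputs and a simple proteome
# scan, plus the cytotoxicity formula used in killing assays.

#' Per-position amino-acid frequency matrix of enriched peptides
#'
#' Computed over *unique* peptides (duplicates counted once); each column is
#' normalized to sum to 1 after adding the pseudocount.
#'
#' @param peptides Character vector of equal-length peptide sequences
#'   (standard 20-letter alphabet).
#' @param pseudocount Added to every cell before normalization.
#' @return A `pfm`: 20 x L numeric matrix (rows = amino acids), with
#'   attributes `n_unique` and `pseudocount`.
#' @export
frequency_matrix <- function(peptides, pseudocount = 0.0) {
  stopifnot(length(peptides) >= 1)
  lens <- nchar(peptides)
  if (length(unique(lens)) != 1L)
    stop("mixed peptide lengths; first offending row: ",
         which(lens != lens[1])[1])
  bad <- grepl(paste0("[^", paste(unname(AA3), collapse = ""), "]"), peptides)
  if (any(bad))
    stop("non-standard letters in row ", which(bad)[1], ": ",
         peptides[which(bad)[1]])
  uniq <- unique(peptides)
  L <- lens[1]
  m <- matrix(pseudocount, nrow = 20, ncol = L,
              dimnames = list(unname(AA3), paste0("P", seq_len(L))))
  for (p in uniq) {
    aa <- strsplit(p, "")[[1]]
    for (j in seq_len(L)) m[aa[j], j] <- m[aa[j], j] + 1
  }
  m <- sweep(m, 2, colSums(m), "/")
  attr(m, "n_unique") <- length(uniq)
  attr(m, "pseudocount") <- pseudocount
  class(m) <- c("pfm", class(m))
  m
}

#' Scan a proteome for windows matching a position frequency matrix
#'
#' Scores every length-L window as the sum of `log(freq + eps)` over
#' positions (optionally excluding anchor positions), a simple
#' log-likelihood under the enrichment profile.  This is a deliberately
#' simple scorer for ranking candidate source proteins of an enriched motif,
#' not a reimplementation of any published prediction pipeline.
#'
#' @param matrix A [frequency_matrix()] result.
#' @param proteome Named character vector of protein sequences, or a FASTA
#'   file path (read with `Biostrings` when installed, otherwise a minimal
#'   parser).
#' @param anchor_mask Optional integer positions excluded from scoring
#'   (e.g. MHC anchor positions fixed by the library design).
#' @param eps Floor inside the logarithm.
#' @param top Number of hits to return (`Inf` for all).
#' @return Data frame `protein`, `start` (0-based, half-open window),
#'   `window`, `score`, sorted by descending score with ties broken by
#'   protein id then offset.
#' @export
proteome_scan <- function(matrix, proteome, anchor_mask = NULL, eps = 1e-6,
                          top = 50) {
  if (is.character(proteome) && length(proteome) == 1L &&
      file.exists(proteome)) proteome <- read_fasta(proteome)
  stopifnot(length(proteome) >= 1)
  if (is.null(names(proteome)))
    names(proteome) <- paste0("seq", seq_along(proteome))
  L <- ncol(matrix)
  use <- setdiff(seq_len(L), anchor_mask)
  lw <- log(unclass(matrix) + eps)

  hits <- list()
  for (id in names(proteome)) {
    s <- proteome[[id]]
    n <- nchar(s)
    if (n < L) next
    aa <- strsplit(s, "")[[1]]
    idx <- match(aa, rownames(lw))
    for (st in 0:(n - L)) {
      cols <- st + use
      ri <- idx[cols]
      if (anyNA(ri)) next  # windows with non-standard letters skipped
      hits[[length(hits) + 1L]] <- data.frame(
        protein = id, start = st,
        window = substr(s, st + 1, st + L),
        score = sum(lw[cbind(ri, use)]), stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    warning("proteome shorter than the matrix everywhere; no windows scored")
    return(data.frame(protein = character(0), start = integer(0),
                      window = character(0), score = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(-out$score, out$protein, out$start), ]
  rownames(out) <- NULL
  head(out, top)
}

read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    return(setNames(as.character(ss), sub("\\s.*", "", names(ss))))
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, character(1),
                 collapse = "")
  setNames(toupper(gsub("\\s", "", seqs)), sub("^>(\\S+).*", "\\1",
                                               lines[hdr]))
}

#' Percent cytotoxicity relative to an untreated control
#'
#' `(1 - treated/control) * 100`; negative values (treated above control) are
#' returned as-is with a `"negative"` attribute flag.
#'
#' @param treated_units Signal from treated wells (e.g. live-cell units).
#' @param control_units Signal from control wells (> 0).
#' @return Cytotoxicity in percent.
#' @export
cytotoxicity_percent <- function(treated_units, control_units) {
  if (any(control_units <= 0)) stop("control_units must be > 0")
  out <- (1 - treated_units / control_units) * 100
  if (any(out < 0)) attr(out, "flag") <- "negative"
  out
}
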