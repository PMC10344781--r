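#' Load a macromolecular structure from PDB or mmCIF
#'
#' Reads all ATOM/HETATM records with author residue numbering and insertion
#' codes.  Alternate locations are resolved to the highest-occupancy conformer
#' (ties broken alphabetically by alt-loc identifier).  Waters and other
#' non-polymer heteroatoms are flagged (`is_water`, `is_het`) but kept.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format One of `"auto"`, `"pdb"`, `"cif"`. `"auto"` dispatches on the
#'   file extension (`.cif`/`.mmcif` vs anything else).
#' @return An object of class `raw_structure`: a list with `atoms` (data frame
#'   with columns `chain`, `resno`, `insert`, `resid`, `elety`, `elesy`,
#'   `x`, `y`, `z`, `o`, `alt`, `is_het`, `is_water`), `path` and `format`.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop("unparsable ", format, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty model in ", path)

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  if (any(!is.finite(as.matrix(at[, c("x", "y", "z")]))))
    stop("non-finite coordinates in record(s): ",
         paste(which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)),
               collapse = ", "))

  # Resolve alternate locations: per (chain, resno, insert, atom name) keep
  # the conformer with the highest occupancy, ties alphabetical by alt id.
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  if (anyDuplicated(key)) {
    at$.idx <- seq_len(nrow(at))
    at <- at[order(key, -at$o, at$alt), , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "\r")), , drop = FALSE]
    at <- at[order(at$.idx), , drop = FALSE]
    at$.idx <- NULL
  }

  if (is.null(at$elesy) || all(is.na(at$elesy)))
    at$elesy <- guess_element(at$elety)
  at$elesy[is.na(at$elesy) | at$elesy == ""] <- guess_element(
    at$elety[is.na(at$elesy) | at$elesy == ""])

  atoms <- data.frame(
    chain = as.character(at$chain), resno = as.integer(at$resno),
    insert = as.character(at$insert), resid = as.character(at$resid),
    elety = as.character(at$elety), elesy = toupper(as.character(at$elesy)),
    x = at$x, y = at$y, z = at$z, o = at$o, alt = as.character(at$alt),
    is_het = at$type == "HETATM",
    is_water = at$resid %in% c("HOH", "WAT", "DOD"),
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, path = path, format = format),
            class = "raw_structure")
}

guess_element <- function(elety) {
  e <- toupper(sub("^[0-9]*", "", elety))
  two <- substr(e, 1, 2)
  out <- substr(e, 1, 1)
  out[two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "MN", "NA")] <-
    two[two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "MN", "NA")]
  out
}

#' Write a structure or annotated complex to a PDB file
#'
#' Round-trips atom count, chain partition and author numbering exactly.
#'
#' @param x A `raw_structure` or `tcrm_complex`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  at <- atom_table(x)
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(at$is_het, "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resid,
                   insert = ifelse(at$insert == "", NA, at$insert),
                   chain = at$chain, elety = at$elety,
                   o = at$o, b = rep(0, nrow(at)), elesy = at$elesy)
  invisible(path)
}

#' Fetch a structure from the PDB by accession (cached)
#'
#' Downloads `<accession>.cif` (or `.pdb`) from RCSB into `dest_dir` unless a
#' cached copy already exists.  This is the only function in the package that
#' touches the network.
#'
#' @param accession 4-character PDB id, e.g. `"7TR4"`.
#' @param dest_dir Cache directory.
#' @param format `"cif"` or `"pdb"`.
#' @return Path to the cached file.
#' @export
fetch_structure <- function(accession, dest_dir = tools::R_user_dir("tcrmtools", "cache"),
                            format = c("cif", "pdb")) {
  format <- match.arg(format)
  stopifnot(grepl("^[0-9][A-Za-z0-9]{3}$", accession))
  dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE)
  dest <- file.path(dest_dir, paste0(toupper(accession), ".", format))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.%s",
                   toupper(accession), format)
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  }
  dest
}

# Extract the atom data frame from any structure-like object
atom_table <- function(x) {
  if (inherits(x, "raw_structure") || inherits(x, "tcrm_complex")) return(x$atoms)
  if (is.data.frame(x)) return(x)
  stop("cannot extract atoms from object of class ", paste(class(x), collapse = "/"))
}
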