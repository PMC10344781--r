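# Groove-fixed coordinate frame, antibody docking axis, docking angle and the
# signed in-plane rotation between two complexes sharing an MHC scaffold.

#' Groove-fixed coordinate frame of a class I pMHC
#'
#' The groove axis is the first principal component of the alpha-carbon
#' coordinates of the two groove helices (author-numbering windows 50-86 and
#' 138-176 by default), oriented from the peptide N- to C-terminus; the
#' normal is the least-variance principal component, oriented toward the
#' antibody centroid; the origin is the centroid of the helix alpha-carbons
#' (the groove rim).
#'
#' @param complex A `tcrm_complex`.
#' @param helix_windows List of two `c(start, end)` author-numbering windows.
#' @return A `groove_frame`: list with `origin`, `groove_axis`,
#'   `normal_axis`, `third_axis` (orthonormal, right-handed with
#'   `third = normal x groove`).
#' @export
groove_frame <- function(complex,
                         helix_windows = list(c(50, 86), c(138, 176))) {
  stopifnot(inherits(complex, "tcrm_complex"))
  at <- complex$atoms
  mhc_ch <- role_chain(complex, "MHC_HEAVY")
  ca <- at[at$chain == mhc_ch & at$elety == "CA" & !at$is_het, , drop = FALSE]
  sel <- rep(FALSE, nrow(ca))
  expected <- 0L
  for (w in helix_windows) {
    sel <- sel | (ca$resno >= w[1] & ca$resno <= w[2])
    expected <- expected + (w[2] - w[1] + 1L)
  }
  hx <- ca[sel, , drop = FALSE]
  if (nrow(hx) < 0.8 * expected)
    stop("more than 20% of groove helix residues missing (",
         nrow(hx), "/", expected, ")")
  X <- as.matrix(hx[, c("x", "y", "z")])
  ctr <- colMeans(X)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  g <- pc$rotation[, 1]
  n <- pc$rotation[, 3]

  # orient groove axis from peptide N- to C-terminus
  pep_ch <- role_chain(complex, "PEPTIDE")
  pep_ca <- at[at$chain == pep_ch & at$elety == "CA", , drop = FALSE]
  pep_ca <- pep_ca[order(pep_ca$resno, pep_ca$insert), ]
  pep_dir <- as.numeric(pep_ca[nrow(pep_ca), c("x", "y", "z")]) -
    as.numeric(pep_ca[1, c("x", "y", "z")])
  if (sum(g * pep_dir) < 0) g <- -g

  # orient normal toward the antibody centroid
  ab_ch <- names(complex$roles)[complex$roles %in% c("AB_HEAVY", "AB_LIGHT")]
  ab <- at[at$chain %in% ab_ch, c("x", "y", "z")]
  if (nrow(ab) && sum(n * (colMeans(as.matrix(ab)) - ctr)) < 0) n <- -n

  n <- n - sum(n * g) * g
  n <- n / sqrt(sum(n^2))
  structure(list(origin = ctr, groove_axis = unname(g),
                 normal_axis = unname(n),
                 third_axis = unname(cross3(n, g))),
            class = "groove_frame")
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Antibody docking axis
#'
#' The line through the alpha-carbon centroids of the two variable domains
#' (first `v_len` residues, in author-numbering order, of each antibody
#' chain), directed from VL to VH.
#'
#' @param complex A `tcrm_complex` with both antibody chains assigned.
#' @param v_len Number of leading residues forming the V domain.
#' @return List with `point` (midpoint) and `direction` (unit vector VL->VH).
#' @export
ab_axis <- function(complex, v_len = 115) {
  stopifnot(inherits(complex, "tcrm_complex"))
  cent <- function(role) {
    ch <- role_chain(complex, role)
    ca <- complex$atoms[complex$atoms$chain == ch &
                          complex$atoms$elety == "CA", , drop = FALSE]
    ca <- ca[order(ca$resno, ca$insert), , drop = FALSE]
    ca <- ca[!duplicated(paste(ca$resno, ca$insert)), , drop = FALSE]
    if (nrow(ca) < 0.5 * v_len)
      stop("V domain of ", role, " missing or too short (",
           nrow(ca), " CA atoms)")
    colMeans(as.matrix(head(ca, v_len)[, c("x", "y", "z")]))
  }
  ch_h <- cent("AB_HEAVY")
  ch_l <- cent("AB_LIGHT")
  dir <- ch_h - ch_l
  dir <- dir / sqrt(sum(dir^2))
  list(point = (ch_h + ch_l) / 2, direction = unname(dir))
}

#' Docking angle of the antibody over the MHC groove
#'
#' Angle between the antibody axis, projected into the groove plane, and the
#' groove axis; reported in `[0, 180)` degrees.
#'
#' @param complex A `tcrm_complex`.
#' @param frame Optional precomputed [groove_frame()].
#' @param axis Optional precomputed [ab_axis()].
#' @return Angle in degrees.
#' @export
docking_angle <- function(complex, frame = NULL, axis = NULL) {
  frame <- frame %||% groove_frame(complex)
  axis <- axis %||% ab_axis(complex)
  v <- axis$direction
  proj <- v - sum(v * frame$normal_axis) * frame$normal_axis
  nv <- sqrt(sum(proj^2))
  if (nv < 1e-8)
    stop("antibody axis is parallel to the groove normal; projection degenerate")
  proj <- proj / nv
  ang <- acos(max(-1, min(1, sum(proj * frame$groove_axis)))) * 180 / pi
  if (ang >= 180) ang <- ang - 180
  ang
}

#' Signed in-plane docking rotation between two complexes on one MHC scaffold
#'
#' Superposes the query's groove-helix alpha-carbons onto the reference's by
#' least-squares rigid fit (Kabsch), then reports the signed angle between
#' the two antibody axes projected into the reference groove plane.
#' Positive = clockwise as seen from the antibody looking down the groove
#' normal (with the groove axis running peptide N- to C-terminus).
#'
#' @param reference,query `tcrm_complex` objects with homologous MHC chains.
#' @param helix_windows Passed to [groove_frame()]; the fit uses the
#'   alpha-carbons of matching author residue numbers in these windows.
#' @param max_rmsd Superposition RMSD above which the frames are declared
#'   non-comparable (error).
#' @return Signed rotation in degrees; attribute `"rmsd"` carries the fit
#'   RMSD.
#' @export
docking_rotation <- function(reference, query,
                             helix_windows = list(c(50, 86), c(138, 176)),
                             max_rmsd = 3.0) {
  get_helix_ca <- function(cx) {
    ch <- role_chain(cx, "MHC_HEAVY")
    ca <- cx$atoms[cx$atoms$chain == ch & cx$atoms$elety == "CA", ,
                   drop = FALSE]
    sel <- rep(FALSE, nrow(ca))
    for (w in helix_windows) sel <- sel | (ca$resno >= w[1] & ca$resno <= w[2])
    ca <- ca[sel, , drop = FALSE]
    ca[order(ca$resno), c("resno", "x", "y", "z")]
  }
  ra <- get_helix_ca(reference)
  qa <- get_helix_ca(query)
  common <- intersect(ra$resno, qa$resno)
  if (length(common) < 12)
    stop("fewer than 12 matched helix residues between the complexes")
  A <- as.matrix(ra[match(common, ra$resno), c("x", "y", "z")])
  B <- as.matrix(qa[match(common, qa$resno), c("x", "y", "z")])

  fit <- kabsch(A, B)
  if (fit$rmsd > max_rmsd)
    stop(sprintf("superposition RMSD %.2f A exceeds %.1f A; frames not comparable",
                 fit$rmsd, max_rmsd))

  fr <- groove_frame(reference, helix_windows)
  a <- ab_axis(reference)$direction
  b <- fit$R %*% ab_axis(query)$direction  # rotate query axis into ref frame
  pr <- function(v) {
    p <- v - sum(v * fr$normal_axis) * fr$normal_axis
    p / sqrt(sum(p^2))
  }
  a <- pr(a); b <- pr(as.numeric(b))
  ccw <- atan2(sum(fr$normal_axis * cross3(a, b)), sum(a * b)) * 180 / pi
  out <- -ccw  # clockwise positive as seen from the antibody side
  attr(out, "rmsd") <- fit$rmsd
  out
}

# Least-squares rigid superposition (Kabsch): returns rotation R and
# translation t such that B %*% t(R) + t approximates A, plus the RMSD.
kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(B, 2, cb)) %*% sweep(A, 2, ca)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Bf <- sweep(B, 2, cb) %*% t(R)
  Bf <- sweep(Bf, 2, ca, "+")
  list(R = R, t = ca - as.numeric(R %*% cb),
       rmsd = sqrt(mean(rowSums((Bf - A)^2))), fitted = Bf)
}
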