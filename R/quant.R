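# Antigen-density quantification: photobleaching extrapolation, surface
# density, dual-color correction and per-cell scaling.

#' Extrapolate the initial mobile-molecule count through photobleaching
#'
#' Least-squares fit of `N(t) = N0 * exp(-k * t)` (t in frames, 0-based) to
#' per-frame molecule counts, initialized from a log-linear regression and
#' refined by Levenberg-Marquardt nonlinear least squares.
#'
#' @param counts Per-frame molecule counts (>= 10 frames).
#' @param frame_interval Optional seconds per frame, to also report `k_per_s`.
#' @param fit_start First (0-based) frame included in the fit.  Track-based
#'   counts are biased low near the start of the acquisition (a molecule
#'   missed in the first frames starts its track late), so the pipeline fits
#'   from just past the gap-closing horizon and extrapolates to frame 0.
#' @return List with `N0` (count extrapolated to frame 0), `k` (per frame),
#'   `k_per_s` (if interval given), `residuals`, and `flag` (`"ok"` or
#'   `"non_decreasing"`, in which case `N0 = mean(counts)`, `k = 0`).
#' @export
estimate_initial_count <- function(counts, frame_interval = NULL,
                                   fit_start = 0L) {
  counts <- as.numeric(counts)
  if (length(counts) < 10) stop("need at least 10 frames of counts")
  if (all(counts == 0)) stop("all-zero counts; nothing to extrapolate")
  t <- seq_along(counts) - 1
  keep <- t >= fit_start
  counts <- counts[keep]
  t <- t[keep]

  pos <- counts > 0
  sl <- coef(lm(log(counts[pos]) ~ t[pos]))
  if (is.na(sl[2]) || sl[2] >= 0) {
    warning("counts are non-decreasing; returning the mean as N0")
    return(list(N0 = mean(counts), k = 0,
                k_per_s = if (!is.null(frame_interval)) 0,
                residuals = counts - mean(counts), flag = "non_decreasing"))
  }
  start <- list(N0 = exp(unname(sl[1])), k = -unname(sl[2]))
  fit <- minpack.lm::nlsLM(counts ~ N0 * exp(-k * t), start = start,
                           lower = c(0, 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  list(N0 = unname(cf["N0"]), k = unname(cf["k"]),
       k_per_s = if (!is.null(frame_interval)) unname(cf["k"]) / frame_interval,
       residuals = unname(residuals(fit)), flag = "ok")
}

#' Surface density of molecules
#'
#' `rho = N0 / vCSA`: the initial mobile-molecule count divided by the
#' visible cell surface area.
#'
#' @param N0 Molecule count (>= 0).
#' @param vCSA Visible cell surface area, um^2 (> 0).
#' @return Density, molecules per um^2.
#' @export
density_per_um2 <- function(N0, vCSA) {
  if (!is.numeric(vCSA) || vCSA <= 0) stop("vCSA must be > 0")
  N0 / vCSA
}

#' Dual-color corrected molecule count
#'
#' `A + B - 0.5 * AB`, where `A` and `B` are the molecule counts in the two
#' spectral channels and `AB` the number of cotrajectories; molecules carrying
#' both labels are otherwise counted in both channels.
#'
#' @param A,B Per-channel molecule counts (>= 0).
#' @param AB Cotrajectory count (0 <= AB <= min(A, B)).
#' @return Corrected count.
#' @export
dual_color_count <- function(A, B, AB) {
  stopifnot(A >= 0, B >= 0, AB >= 0)
  if (AB > min(A, B)) stop("AB exceeds min(A, B); counts inconsistent")
  A + B - 0.5 * AB
}

#' Per-cell molecule count and total-surface estimation
#'
#' `per_cell_count()` scales a surface density to a whole cell:
#' `density * tCSA`.  `estimate_tcsa()` applies the factor-2 rule converting
#' a segmented two-dimensional cell contour area to total surface area.
#'
#' @param rho Surface density, um^-2 (>= 0).
#' @param tCSA Total cell surface area, um^2 (default 3900).
#' @return Molecules per cell.
#' @export
per_cell_count <- function(rho, tCSA = 3900) {
  stopifnot(rho >= 0)
  rho * tCSA
}

#' @rdname per_cell_count
#' @param contour_area Segmented 2D contour area, um^2 (> 0).
#' @export
estimate_tcsa <- function(contour_area) {
  stopifnot(contour_area > 0)
  2 * contour_area
}

#' Segment the visible cell surface area from background fluorescence
#'
#' Gaussian smoothing, Otsu global threshold, largest connected foreground
#' component; area in um^2.
#'
#' @param image Numeric matrix (single channel).
#' @param pixel_size Pixel size, um.
#' @param smooth_sigma Smoothing SD in pixels.
#' @return vCSA in um^2; attribute `"mask"` carries the logical component
#'   mask.
#' @export
segment_vcsa <- function(image, pixel_size, smooth_sigma = 2) {
  stopifnot(is.matrix(image), pixel_size > 0)
  rng <- range(image)
  if (diff(rng) == 0) stop("empty foreground: image is constant")
  norm <- (image - rng[1]) / diff(rng)
  sm <- EBImage::gblur(EBImage::Image(norm), sigma = smooth_sigma)
  th <- EBImage::otsu(sm)
  fg <- sm > th
  if (!any(fg)) stop("empty foreground after thresholding")
  lab <- EBImage::bwlabel(fg)
  sizes <- table(as.integer(lab)[as.integer(lab) > 0])
  big <- as.integer(names(sizes)[which.max(sizes)])
  area <- sum(lab == big) * pixel_size^2
  attr(area, "mask") <- as.matrix(lab == big)
  area
}

#' Least-squares similarity registration from matched point pairs
#'
#' Fits translation + rotation + scale mapping `moving` onto `reference`
#' (Umeyama closed form) from calibration bead pairs.
#'
#' @param reference,moving n x 2 matrices of matched coordinates (n >= 3,
#'   non-collinear).
#' @return List with `rotation_deg`, `scale`, `translation`,
#'   `residual_rms` and `apply(xy)` mapping moving-channel coordinates into
#'   the reference frame.
#' @export
register_channels <- function(reference, moving) {
  reference <- as.matrix(reference); moving <- as.matrix(moving)
  stopifnot(ncol(reference) == 2, ncol(moving) == 2,
            nrow(reference) == nrow(moving))
  if (nrow(reference) < 3) stop("need at least 3 matched point pairs")
  mr <- colMeans(reference); mm <- colMeans(moving)
  X <- sweep(moving, 2, mm); Y <- sweep(reference, 2, mr)
  sv <- svd(t(Y) %*% X / nrow(X))
  if (sv$d[2] / max(sv$d[1], .Machine$double.eps) < 1e-10)
    stop("degenerate (collinear) calibration points")
  S <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% S %*% t(sv$v)
  varX <- mean(rowSums(X^2))
  scale <- sum(diag(diag(sv$d) %*% S)) / varX
  t_vec <- mr - scale * as.numeric(R %*% mm)
  apply_fun <- function(xy) {
    xy <- as.matrix(xy)
    sweep(scale * xy %*% t(R), 2, t_vec, "+")
  }
  fitted <- apply_fun(moving)
  list(rotation_deg = atan2(R[2, 1], R[1, 1]) * 180 / pi,
       scale = scale, translation = t_vec,
       residual_rms = sqrt(mean(rowSums((fitted - reference)^2))),
       apply = apply_fun)
}

#' Count dual-color cotrajectories
#'
#' Same-frame localizations from the two channels within `coloc_threshold`
#' are colocalization events (one-to-one, resolved by minimal total
#' distance); events are grouped by the underlying track pair and a pair
#' counts as a cotrajectory when it colocalizes over at least
#' `min_cotrack_steps` consecutive frame-to-frame steps (i.e. spans
#' `min_cotrack_steps + 1` consecutive frames).  Each track pair is counted
#' once.
#'
#' @param tracksA,tracksB `track_set` objects for the two channels
#'   (channel B already registered onto channel A).
#' @param config A [quant_config()].
#' @return Integer cotrajectory count; attribute `"pairs"` lists the
#'   qualifying track-id pairs.
#' @export
cotrack <- function(tracksA, tracksB, config = quant_config()) {
  if (!nrow(tracksA) || !nrow(tracksB)) return(structure(0L, pairs = NULL))
  events <- list()
  frames <- intersect(unique(tracksA$frame), unique(tracksB$frame))
  for (f in frames) {
    a <- tracksA[tracksA$frame == f, , drop = FALSE]
    b <- tracksB[tracksB$frame == f, , drop = FALSE]
    d <- sqrt(outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2)
    gate <- d <= config$coloc_threshold
    if (!any(gate)) next
    sol <- gated_assignment(d, gate)
    if (length(sol$row))
      events[[length(events) + 1L]] <- data.frame(
        frame = f, idA = a$track_id[sol$row], idB = b$track_id[sol$col])
  }
  if (!length(events)) return(structure(0L, pairs = NULL))
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$idA, ev$idB, ev$frame), ]
  qual <- list()
  for (key in unique(paste(ev$idA, ev$idB))) {
    sub <- ev[paste(ev$idA, ev$idB) == key, ]
    # longest run of consecutive frames
    best <- 1L
    cur <- 1L
    fr <- sub$frame
    if (length(fr) > 1) for (i in 2:length(fr)) {
      cur <- if (fr[i] == fr[i - 1] + 1) cur + 1L else 1L
      best <- max(best, cur)
    }
    if (best - 1L >= config$min_cotrack_steps)
      qual[[length(qual) + 1L]] <- sub[1, c("idA", "idB")]
  }
  structure(length(qual),
            pairs = if (length(qual)) do.call(rbind, qual) else NULL)
}

#' Detect single-molecule spots in an image stack
#'
#' Per frame: difference-of-Gaussians bandpass, local maxima above a robust
#' intensity threshold, sub-pixel refinement by least-squares Gaussian fit in
#' a local window.
#'
#' @param movie Numeric array `ny x nx x n_frames` (or matrix for one frame),
#'   with `attr(movie, "pixel_size")` or `pixel_size` given.
#' @param pixel_size Pixel size, um.
#' @param psf_sigma Expected PSF sigma, um.
#' @param threshold_sd Detection threshold in robust SDs of the bandpassed
#'   frame.
#' @param saturation_level Pixel value above which a frame is flagged
#'   saturated (attribute `"saturated_frames"` of the result).
#' @return Localization data frame (`frame` 0-based, `x_um`, `y_um`,
#'   `channel = "ch1"`, `intensity`).
#' @export
detect_spots <- function(movie, pixel_size = attr(movie, "pixel_size"),
                         psf_sigma = 0.13, threshold_sd = 5,
                         saturation_level = Inf) {
  if (is.null(pixel_size)) stop("pixel_size required")
  if (is.matrix(movie)) movie <- array(movie, c(dim(movie), 1))
  nf <- dim(movie)[3]
  s_px <- psf_sigma / pixel_size
  out <- list()
  saturated <- integer(0)
  for (f in seq_len(nf)) {
    img <- movie[, , f]
    if (any(img >= saturation_level)) saturated <- c(saturated, f - 1L)
    im <- EBImage::Image(img / max(img, 1))
    bp <- EBImage::gblur(im, sigma = max(s_px, 0.8)) -
      EBImage::gblur(im, sigma = 3 * max(s_px, 0.8))
    bp <- as.matrix(bp)
    thr <- median(bp) + threshold_sd * max(stats::mad(bp), 1e-12)
    ny <- nrow(bp); nx <- ncol(bp)
    cand <- which(bp > thr)
    for (idx in cand) {
      r <- (idx - 1) %% ny + 1; c <- (idx - 1) %/% ny + 1
      if (r < 2 || r > ny - 1 || c < 2 || c > nx - 1) next
      nb <- bp[(r - 1):(r + 1), (c - 1):(c + 1)]
      if (bp[r, c] < max(nb)) next
      # sub-pixel position: least-squares Gaussian fit in a local window,
      # initialized from the intensity-weighted centroid
      h <- max(3L, ceiling(3 * s_px))
      ry <- max(1, r - h):min(ny, r + h); rx <- max(1, c - h):min(nx, c + h)
      w <- img[ry, rx] - min(img[ry, rx])
      if (sum(w) <= 0) next
      cy <- sum(ry * rowSums(w)) / sum(w)
      cx <- sum(rx * colSums(w)) / sum(w)
      df <- data.frame(v = as.vector(w),
                       yy = rep(ry, times = length(rx)),
                       xx = rep(rx, each = length(ry)))
      fit <- tryCatch(minpack.lm::nlsLM(
        v ~ A * exp(-((xx - x0)^2 + (yy - y0)^2) / (2 * s^2)) + b,
        data = df,
        start = list(A = max(df$v), x0 = cx, y0 = cy, s = s_px, b = 0),
        control = minpack.lm::nls.lm.control(maxiter = 50)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- coef(fit)
        # accept the refined position only if it stays inside the window
        if (cf["x0"] >= min(rx) && cf["x0"] <= max(rx) &&
            cf["y0"] >= min(ry) && cf["y0"] <= max(ry)) {
          cx <- unname(cf["x0"]); cy <- unname(cf["y0"])
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        frame = f - 1L, x_um = (cx - 0.5) * pixel_size,
        y_um = (cy - 0.5) * pixel_size, channel = "ch1",
        intensity = sum(w))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
               channel = character(0), intensity = numeric(0))
  attr(res, "saturated_frames") <- saturated
  res
}

#' Full antigen-density quantification pipeline
#'
#' Runs trajectory linking, immobile-background removal, photobleaching
#' extrapolation of the initial mobile count, surface density,
#' dual-color correction (when a second channel is present) and per-cell
#' scaling.
#'
#' @param table Localization data frame (one or two channels in the
#'   `channel` column).
#' @param config A [quant_config()]; `config$vCSA` must be set (um^2).
#' @param n_frames Number of frames in the acquisition (default: max frame
#'   index + 1).
#' @return A `density_result` list: `N0_mobile`, `first_frame_mobile_count`,
#'   `vCSA`, `rho` (= N0/vCSA exactly), `per_cell` (= rho * tCSA exactly),
#'   for dual color also `A`, `B`, `AB`, `dual_corrected_count`, plus
#'   `diagnostics`.
#' @export
quantify_density <- function(table, config = quant_config(vCSA = NULL),
                             n_frames = NULL) {
  if (is.null(config$vCSA) || config$vCSA <= 0)
    stop("config$vCSA must be a positive area in um^2")
  n_frames <- n_frames %||% (max(table$frame) + 1L)
  channels <- sort(unique(table$channel))
  if (!length(channels)) stop("empty localization table")

  per_channel <- lapply(channels, function(ch) {
    tr <- link_tracks(table[table$channel == ch, , drop = FALSE], config)
    mob <- remove_immobile(tr, config)
    cnt <- counts_per_frame(mob, n_frames, config$counts_source)
    fit <- estimate_initial_count(cnt, fit_start = config$max_gap + 1L)
    list(tracks = mob, counts = cnt, fit = fit,
         n_immobile = attr(mob, "n_immobile"),
         first_frame = cnt[1])
  })
  names(per_channel) <- channels

  if (length(channels) == 1L) {
    N0 <- per_channel[[1]]$fit$N0
    AB <- NULL
  } else if (length(channels) == 2L) {
    A <- per_channel[[1]]$fit$N0
    B <- per_channel[[2]]$fit$N0
    AB <- as.integer(cotrack(per_channel[[1]]$tracks,
                             per_channel[[2]]$tracks, config))
    AB <- min(AB, floor(min(A, B)))  # extrapolation can undershoot raw AB
    N0 <- dual_color_count(A, B, AB)
  } else stop("at most two channels supported")

  rho <- density_per_um2(N0, config$vCSA)
  res <- list(N0_mobile = N0,
              first_frame_mobile_count = sum(vapply(per_channel,
                                                    `[[`, numeric(1),
                                                    "first_frame")),
              vCSA = config$vCSA, rho = rho,
              per_cell = per_cell_count(rho, config$tCSA),
              tCSA = config$tCSA,
              diagnostics = list(
                channels = channels,
                bleach_k = vapply(per_channel, function(p) p$fit$k, numeric(1)),
                counts_per_frame = lapply(per_channel, `[[`, "counts"),
                n_immobile_removed = vapply(per_channel, `[[`, integer(1),
                                            "n_immobile"),
                flags = vapply(per_channel, function(p) p$fit$flag,
                               character(1))))
  if (length(channels) == 2L) {
    res$A <- A; res$B <- B; res$AB <- AB
    res$dual_corrected_count <- N0
  }
  stopifnot(isTRUE(all.equal(res$rho, res$N0_mobile / res$vCSA)),
            isTRUE(all.equal(res$per_cell, res$rho * res$tCSA)))
  class(res) <- "density_result"
  res
}

#' @export
print.density_result <- function(x, ...) {
  cat("Antigen density result\n")
  cat(sprintf("  initial mobile count N0: %.2f (first frame: %d)\n",
              x$N0_mobile, x$first_frame_mobile_count))
  if (!is.null(x$AB))
    cat(sprintf("  dual-color: A = %.2f, B = %.2f, AB = %d -> corrected %.2f\n",
                x$A, x$B, x$AB, x$dual_corrected_count))
  cat(sprintf("  vCSA: %.1f um^2  ->  rho = %.4f um^-2\n", x$vCSA, x$rho))
  cat(sprintf("  per cell (tCSA %.0f um^2): %.0f molecules\n",
              x$tCSA, x$per_cell))
  invisible(x)
}
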