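# Synthetic single-molecule TIRF data: diffusing, photobleaching,
# stochastically labeled molecules on a cell surface with an immobile
# surface-adsorbed background.

#' Simulation configuration for synthetic single-molecule data
#'
#' Defaults mirror the acquisition used for antigen counting: 32 ms frame
#' interval, stacks of 150 frames, molecules diffusing in the plasma membrane
#' with immobile adsorbed background emitters.
#'
#' @param true_density Mobile molecules per square micron.
#' @param diffusion_coeff Diffusion coefficient, um^2/s.
#' @param frame_interval Seconds per frame (default 0.032).
#' @param n_frames Frames per stack (default 150).
#' @param field `c(width, height)` of the rectangular cell mask, um.
#' @param localization_sigma Localization error SD per axis, um.
#' @param bleach_prob Per-tag, per-frame bleaching probability.
#' @param detection_prob Per-tag, per-frame detection probability.
#' @param label_model `"single_color"` or `"dual_color"`.
#' @param tags_per_molecule Tags per molecule (dual-color default 2,
#'   reflecting an IgG carrying two tag epitopes).
#' @param color_probs Length-2 probabilities that a tag is channel 1 vs 2
#'   (dual-color only).
#' @param immobile_density Immobile adsorbed molecules per square micron.
#' @param false_positive_rate Spurious localizations per frame per um^2.
#' @param seed Integer RNG seed; fixed seed gives byte-identical output
#'   (R's default Mersenne-Twister generator).
#' @return A `sim_config` list.
#' @export
sim_config <- function(true_density = 0.2, diffusion_coeff = 0.1,
                       frame_interval = 0.032, n_frames = 150L,
                       field = c(12, 12), localization_sigma = 0.02,
                       bleach_prob = 0.02, detection_prob = 0.9,
                       label_model = c("single_color", "dual_color"),
                       tags_per_molecule = NULL, color_probs = c(0.5, 0.5),
                       immobile_density = 0, false_positive_rate = 0,
                       seed = 1L) {
  label_model <- match.arg(label_model)
  if (is.null(tags_per_molecule))
    tags_per_molecule <- if (label_model == "dual_color") 2L else 1L
  cfg <- list(true_density = true_density, diffusion_coeff = diffusion_coeff,
              frame_interval = frame_interval, n_frames = as.integer(n_frames),
              field = field, localization_sigma = localization_sigma,
              bleach_prob = bleach_prob, detection_prob = detection_prob,
              label_model = label_model,
              tags_per_molecule = as.integer(tags_per_molecule),
              color_probs = color_probs / sum(color_probs),
              immobile_density = immobile_density,
              false_positive_rate = false_positive_rate,
              seed = as.integer(seed))
  for (f in c("bleach_prob", "detection_prob"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("invalid config field: ", f)
  for (f in c("true_density", "immobile_density", "false_positive_rate",
              "localization_sigma", "diffusion_coeff"))
    if (cfg[[f]] < 0) stop("invalid config field: ", f)
  if (cfg$frame_interval <= 0) stop("invalid config field: frame_interval")
  if (length(cfg$field) != 2 || any(cfg$field <= 0))
    stop("invalid config field: field")
  if (cfg$tags_per_molecule < 1) stop("invalid config field: tags_per_molecule")
  structure(cfg, class = "sim_config")
}

#' Simulate single-molecule localizations with ground truth
#'
#' Mobile molecules perform 2D Brownian motion (per-axis displacement
#' `Normal(0, sqrt(2 D dt))`, reflective at the field boundary); each tag
#' photobleaches independently with geometric lifetime; a localization is
#' emitted per frame per unbleached tag with probability `detection_prob`, at
#' the true position plus isotropic Gaussian localization error.  Immobile
#' adsorbed molecules and uniform false positives are added per the config.
#'
#' @param config A [sim_config()].
#' @return List with `truth` (per-molecule data frame `id`, `mobility`,
#'   per-tag channels/bleach frames, plus `trajectories`, an
#'   `n_frames x n_molecules x 2` array of true positions) and `table`, the
#'   localization data frame (`frame` 0-based, `x_um`, `y_um`, `channel`,
#'   `intensity`, `molecule_id`; id `NA` for false positives).
#' @export
simulate_smlm <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  W <- config$field[1]; H <- config$field[2]
  area <- W * H
  nf <- config$n_frames

  n_mob <- rpois(1, config$true_density * area)
  n_imm <- rpois(1, config$immobile_density * area)
  n_mol <- n_mob + n_imm
  mobility <- rep(c("mobile", "immobile"), c(n_mob, n_imm))

  # trajectories: reflective Brownian motion (immobile: constant)
  step_sd <- sqrt(2 * config$diffusion_coeff * config$frame_interval)
  traj <- array(NA_real_, c(nf, max(n_mol, 1L), 2))
  if (n_mol > 0) {
    pos <- cbind(runif(n_mol, 0, W), runif(n_mol, 0, H))
    traj[1, seq_len(n_mol), ] <- pos
    if (nf > 1) for (f in 2:nf) {
      if (n_mob > 0) {
        stepm <- matrix(rnorm(2 * n_mob, 0, step_sd), n_mob, 2)
        pos[seq_len(n_mob), ] <- pos[seq_len(n_mob), , drop = FALSE] + stepm
        pos[, 1] <- reflect_into(pos[, 1], W)
        pos[, 2] <- reflect_into(pos[, 2], H)
      }
      traj[f, seq_len(n_mol), ] <- pos
    }
  }

  tpm <- config$tags_per_molecule
  ntags <- n_mol * tpm
  tag_channel <- if (config$label_model == "dual_color") {
    matrix(1L + (runif(ntags) > config$color_probs[1]), n_mol, tpm)
  } else matrix(1L, max(n_mol, 1L), max(tpm, 1L))[seq_len(max(n_mol, 0)), ,
                                                  drop = FALSE]
  # bleach frame: first frame at which the tag is dark (0-based); tags emit in
  # frames 0 .. bleach_frame-1
  tag_bleach <- if (config$bleach_prob > 0)
    matrix(rgeom(ntags, config$bleach_prob) + 1L, n_mol, tpm)
  else matrix(nf + 1L, max(n_mol, 1L), tpm)[seq_len(max(n_mol, 0)), ,
                                            drop = FALSE]

  n_channels <- if (config$label_model == "dual_color") 2L else 1L
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    loc <- list()
    if (n_mol > 0) {
      for (ch in seq_len(n_channels)) {
        # tags of this color on one molecule are optically unresolvable: a
        # molecule emits at most one localization per channel per frame, and
        # is detected when at least one of its unbleached tags of that color
        # is detected
        k_alive <- rowSums(tag_bleach >= f & tag_channel == ch)
        cand <- which(k_alive > 0)
        if (!length(cand)) next
        p_det <- 1 - (1 - config$detection_prob)^k_alive[cand]
        det <- cand[runif(length(cand)) <= p_det]
        if (!length(det)) next
        loc[[length(loc) + 1L]] <- data.frame(
          frame = f - 1L,
          x_um = traj[f, det, 1] + rnorm(length(det), 0, config$localization_sigma),
          y_um = traj[f, det, 2] + rnorm(length(det), 0, config$localization_sigma),
          channel = paste0("ch", ch),
          intensity = 1000 * k_alive[det] + rnorm(length(det), 0, 50),
          molecule_id = det)
      }
    }
    nfp <- rpois(1, config$false_positive_rate * area)
    if (nfp > 0) {
      fp_ch <- if (config$label_model == "dual_color")
        paste0("ch", 1L + (runif(nfp) > config$color_probs[1])) else "ch1"
      loc[[length(loc) + 1L]] <- data.frame(
        frame = f - 1L, x_um = runif(nfp, 0, W), y_um = runif(nfp, 0, H),
        channel = fp_ch, intensity = 1000 + rnorm(nfp, 0, 50),
        molecule_id = NA_integer_)
    }
    rows[[f]] <- if (length(loc)) do.call(rbind, loc) else NULL
  }
  table <- do.call(rbind, rows)
  if (is.null(table))
    table <- data.frame(frame = integer(0), x_um = numeric(0),
                        y_um = numeric(0), channel = character(0),
                        intensity = numeric(0), molecule_id = integer(0))
  rownames(table) <- NULL

  truth <- list(
    molecules = if (n_mol > 0) data.frame(
      id = seq_len(n_mol), mobility = mobility,
      channels = apply(tag_channel, 1, paste, collapse = ","),
      bleach_frames = apply(tag_bleach, 1, paste, collapse = ","))
    else data.frame(id = integer(0), mobility = character(0),
                    channels = character(0), bleach_frames = character(0)),
    trajectories = traj, n_mobile = n_mob, n_immobile = n_imm,
    config = config)
  list(truth = truth, table = table)
}

reflect_into <- function(x, L) {
  x <- x %% (2 * L)
  ifelse(x > L, 2 * L - x, x)
}

#' Apply a similarity misalignment to the second channel of a table
#'
#' Used to exercise [register_channels()]: channel-2 coordinates are mapped
#' through `scale * R(theta) x + shift`.
#'
#' @param table A localization table with a `channel` column.
#' @param shift Length-2 translation, um.
#' @param theta_deg Rotation, degrees.
#' @param scale Scale factor (non-zero).
#' @return The table with transformed ch2 rows.
#' @export
misalign_channels <- function(table, shift = c(0, 0), theta_deg = 0,
                              scale = 1) {
  if (scale == 0) stop("non-invertible transform: scale is zero")
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  i <- table$channel == "ch2"
  if (any(i)) {
    xy <- as.matrix(table[i, c("x_um", "y_um")]) %*% t(R) * scale
    table$x_um[i] <- xy[, 1] + shift[1]
    table$y_um[i] <- xy[, 2] + shift[2]
  }
  table
}

#' Render a localization ground truth as a synthetic image stack
#'
#' Gaussian spots of fixed integrated intensity on a constant background with
#' optional Poisson shot noise and Gaussian read noise.
#'
#' @param truth The `truth` element of [simulate_smlm()] output (or a
#'   localization table).
#' @param psf_sigma PSF standard deviation, um.
#' @param pixel_size Pixel size, um (> 0).
#' @param field Field of view `c(width, height)`, um.
#' @param photons Integrated photons per spot per frame.
#' @param background Background level per pixel.
#' @param shot_noise,read_noise_sd Camera noise model.
#' @return Numeric array `ny x nx x n_frames`.
#' @export
render_movie <- function(truth, psf_sigma = 0.13, pixel_size = 0.1,
                         field = NULL, photons = 500, background = 10,
                         shot_noise = FALSE, read_noise_sd = 0) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (is.data.frame(truth)) {
    tab <- truth
    nf <- max(tab$frame) + 1L
  } else {
    traj <- truth$trajectories
    nf <- dim(traj)[1]
    nmol <- if (length(dim(traj)) == 3) dim(traj)[2] else 0
    tab <- do.call(rbind, lapply(seq_len(nf), function(f)
      if (nmol > 0) data.frame(frame = f - 1L, x_um = traj[f, , 1],
                               y_um = traj[f, , 2]) else NULL))
    field <- field %||% truth$config$field
  }
  if (is.null(field)) field <- c(max(tab$x_um) + 1, max(tab$y_um) + 1)
  nx <- ceiling(field[1] / pixel_size)
  ny <- ceiling(field[2] / pixel_size)
  stack <- array(background, c(ny, nx, nf))
  s_px <- psf_sigma / pixel_size
  half <- ceiling(4 * s_px)
  for (r in seq_len(nrow(tab))) {
    f <- tab$frame[r] + 1L
    cx <- tab$x_um[r] / pixel_size + 0.5
    cy <- tab$y_um[r] / pixel_size + 0.5
    ix <- max(1, floor(cx - half)):min(nx, ceiling(cx + half))
    iy <- max(1, floor(cy - half)):min(ny, ceiling(cy + half))
    if (!length(ix) || !length(iy)) next
    gx <- exp(-((ix - cx)^2) / (2 * s_px^2))
    gy <- exp(-((iy - cy)^2) / (2 * s_px^2))
    spot <- photons * outer(gy, gx) / (2 * pi * s_px^2)
    stack[iy, ix, f] <- stack[iy, ix, f] + spot
  }
  if (shot_noise) stack[] <- rpois(length(stack), stack)
  if (read_noise_sd > 0) stack[] <- stack + rnorm(length(stack), 0, read_noise_sd)
  attr(stack, "pixel_size") <- pixel_size
  stack
}

#' Write / read a localization table as CSV
#'
#' Fixed header `frame,x_um,y_um,channel,intensity`.
#' @param table Localization data frame.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_localizations <- function(table, path) {
  write.csv(table[, c("frame", "x_um", "y_um", "channel", "intensity")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "x_um", "y_um", "channel", "intensity")
  if (!all(need %in% names(tab)))
    stop("localization CSV must have columns ", paste(need, collapse = ","))
  tab
}
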