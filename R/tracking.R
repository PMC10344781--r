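# Simplified multiple-target tracking: frame-to-frame assignment by minimal
# total displacement (Hungarian), gap closing, and immobile-track removal.

#' Quantification configuration
#'
#' @param max_disp Maximum displacement per frame for linking, um.
#' @param max_gap Maximum number of missed frames bridged by gap closing.
#' @param coloc_threshold Colocalization distance threshold, um (default
#'   0.150 = 150 nm).
#' @param min_cotrack_steps Minimum consecutive frame-to-frame steps for a
#'   cotrajectory to count (default 10; at 32 ms per frame, 320 ms).
#' @param immobile_radius Radius around the track median position, um.
#' @param immobile_min_fraction A track is immobile when at least this
#'   fraction of its localizations lies within `immobile_radius` of its
#'   median position.
#' @param tCSA Total cell surface area, um^2 (default 3900).
#' @param vCSA Visible cell surface area, um^2 (`NULL`: derive from the data
#'   source, e.g. [segment_vcsa()] or the simulation field).
#' @param counts_source `"tracks"` (default): per-frame molecule counts for
#'   the bleach fit are the number of mobile tracks alive at each frame
#'   (missed detections bridged by gap closing); `"localizations"`: raw
#'   per-frame localization counts of mobile tracks.
#' @return A `quant_config` list.
#' @export
quant_config <- function(max_disp = 0.5, max_gap = 2, coloc_threshold = 0.150,
                         min_cotrack_steps = 10L, immobile_radius = 0.1,
                         immobile_min_fraction = 0.8, tCSA = 3900,
                         vCSA = NULL,
                         counts_source = c("tracks", "localizations")) {
  stopifnot(max_disp > 0, max_gap >= 0, coloc_threshold > 0,
            min_cotrack_steps >= 1, immobile_radius > 0,
            immobile_min_fraction > 0, immobile_min_fraction <= 1, tCSA > 0)
  structure(list(max_disp = max_disp, max_gap = as.integer(max_gap),
                 coloc_threshold = coloc_threshold,
                 min_cotrack_steps = as.integer(min_cotrack_steps),
                 immobile_radius = immobile_radius,
                 immobile_min_fraction = immobile_min_fraction,
                 tCSA = tCSA, vCSA = vCSA,
                 counts_source = match.arg(counts_source)),
            class = "quant_config")
}

#' Link localizations into trajectories
#'
#' Frame-by-frame linking: candidate track/localization pairs are gated at
#' `max_disp` per elapsed frame, and each frame's assignments are resolved
#' globally by minimal total displacement (Hungarian algorithm).  Tracks not
#' seen for more than `max_gap` frames are closed; unassigned localizations
#' start new tracks.
#'
#' @param table Localization data frame (`frame` 0-based, `x_um`, `y_um`) for
#'   a single channel.
#' @param config A [quant_config()].
#' @return A `track_set` data frame: `track_id`, `frame`, `x_um`, `y_um`,
#'   plus any extra columns of `table`.
#' @export
link_tracks <- function(table, config = quant_config()) {
  stopifnot(inherits(config, "quant_config"))
  if (!nrow(table)) {
    out <- cbind(data.frame(track_id = integer(0)), table)
    class(out) <- c("track_set", "data.frame")
    return(out)
  }
  if ("channel" %in% names(table) && length(unique(table$channel)) > 1L)
    stop("link_tracks expects a single channel; split the table first")
  table <- table[order(table$frame), , drop = FALSE]
  frames <- sort(unique(table$frame))
  by_frame <- split(seq_len(nrow(table)), table$frame)

  track_id <- integer(nrow(table))
  # active tracks: id, last row index, last frame
  act_id <- integer(0); act_row <- integer(0); act_frame <- integer(0)
  next_id <- 1L

  for (f in frames) {
    rows <- by_frame[[as.character(f)]]
    px <- table$x_um[rows]; py <- table$y_um[rows]
    keep <- act_frame >= f - 1L - config$max_gap
    act_id <- act_id[keep]; act_row <- act_row[keep]; act_frame <- act_frame[keep]

    assigned_track <- rep(NA_integer_, length(rows))
    if (length(act_id)) {
      dt <- f - act_frame
      dx <- outer(table$x_um[act_row], px, "-")
      dy <- outer(table$y_um[act_row], py, "-")
      cost <- sqrt(dx^2 + dy^2)
      gate <- cost <= config$max_disp * dt
      if (any(gate)) {
        sol <- gated_assignment(cost, gate)
        assigned_track[sol$col] <- sol$row
      }
    }
    new_act_id <- integer(length(rows)); new_act_row <- integer(length(rows))
    for (j in seq_along(rows)) {
      if (!is.na(assigned_track[j])) {
        tid <- act_id[assigned_track[j]]
      } else {
        tid <- next_id; next_id <- next_id + 1L
      }
      track_id[rows[j]] <- tid
      new_act_id[j] <- tid; new_act_row[j] <- rows[j]
    }
    # updated actives: tracks extended this frame replace their old entry
    stale <- !(act_id %in% new_act_id)
    act_id <- c(act_id[stale], new_act_id)
    act_row <- c(act_row[stale], new_act_row)
    act_frame <- c(act_frame[stale], rep(f, length(rows)))
  }
  out <- cbind(data.frame(track_id = track_id), table)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("track_set", "data.frame")
  out
}

# Minimal-total-distance one-to-one assignment restricted to gated pairs.
# Returns row (track) and col (point) indices of accepted assignments.
gated_assignment <- function(cost, gate) {
  BIG <- 1e6
  c2 <- ifelse(gate, cost, BIG)
  nr <- nrow(c2); nc <- ncol(c2)
  transposed <- FALSE
  if (nr > nc) { c2 <- t(c2); transposed <- TRUE; tmp <- nr; nr <- nc; nc <- tmp }
  sol <- clue::solve_LSAP(c2)
  rows <- seq_len(nr); cols <- as.integer(sol)
  if (transposed) { tmp <- rows; rows <- cols; cols <- tmp }
  ok <- gate[cbind(rows, cols)]
  list(row = rows[ok], col = cols[ok])
}

#' Split a track set into mobile and immobile tracks
#'
#' A track is immobile when at least `immobile_min_fraction` of its
#' localizations lie within `immobile_radius` of the track's median position
#' (surface-adsorbed emitters jitter only by the localization error).
#' Single-localization tracks are immobile by this rule.
#'
#' @param tracks A `track_set`.
#' @param config A [quant_config()].
#' @return The mobile `track_set`; attributes `n_immobile`, `n_mobile`, and
#'   `immobile` (the removed subset).
#' @export
remove_immobile <- function(tracks, config = quant_config()) {
  if (!nrow(tracks)) {
    attr(tracks, "n_immobile") <- 0L; attr(tracks, "n_mobile") <- 0L
    return(tracks)
  }
  imm_ids <- vapply(split(seq_len(nrow(tracks)), tracks$track_id),
                    function(ix) {
    mx <- median(tracks$x_um[ix]); my <- median(tracks$y_um[ix])
    r <- sqrt((tracks$x_um[ix] - mx)^2 + (tracks$y_um[ix] - my)^2)
    mean(r <= config$immobile_radius) >= config$immobile_min_fraction
  }, logical(1))
  imm <- as.integer(names(imm_ids))[imm_ids]
  mobile <- tracks[!(tracks$track_id %in% imm), , drop = FALSE]
  immobile <- tracks[tracks$track_id %in% imm, , drop = FALSE]
  class(mobile) <- class(tracks)
  attr(mobile, "n_immobile") <- length(imm)
  attr(mobile, "n_mobile") <- length(unique(mobile$track_id))
  attr(mobile, "immobile") <- immobile
  mobile
}

# Per-frame molecule counts from a track set.
counts_per_frame <- function(tracks, n_frames,
                             source = c("tracks", "localizations")) {
  source <- match.arg(source)
  counts <- integer(n_frames)
  if (!nrow(tracks)) return(counts)
  if (source == "localizations") {
    tb <- table(factor(tracks$frame, levels = 0:(n_frames - 1)))
    return(as.integer(tb))
  }
  spans <- do.call(rbind, lapply(split(tracks$frame, tracks$track_id), range))
  for (i in seq_len(nrow(spans)))
    counts[(spans[i, 1]:spans[i, 2]) + 1L] <-
      counts[(spans[i, 1]:spans[i, 2]) + 1L] + 1L
  counts
}
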