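#' Electrode montage
#'
#' A montage holds channel labels, 2-D positions in normalized head
#' coordinates (nose up, unit head radius), and named channel groups used
#' by downstream stages: \code{frontal} (the four channels screened by the
#' amplitude-rejection rule), \code{mastoids} (reference channels) and
#' \code{seeds} (parieto-occipital seed electrodes for the seed-based
#' connectivity maps).
#'
#' @param preset_name name of a shipped preset; currently \code{"study32"},
#'   a 32-channel extended 10-05 layout including the seed electrodes POO1
#'   and POO2 and the frontal channels AFp1, AFp2, AFF5h, AFF6h.
#' @return an object of class \code{eeg_montage} with elements
#'   \code{labels}, \code{pos2d} (n x 2 matrix) and \code{groups}.
#' @examples
#' m <- make_montage("study32")
#' m$groups$seeds
#' @export
make_montage <- function(preset_name = "study32") {
  presets <- c("study32")
  if (!is.character(preset_name) || length(preset_name) != 1 ||
      !(preset_name %in% presets)) {
    stop_config("unknown montage preset %s; available: %s",
                deparse1(preset_name), paste(presets, collapse = ", "))
  }
  pos <- .study32_positions()
  groups <- list(
    frontal = c("AFp1", "AFp2", "AFF5h", "AFF6h"),
    mastoids = c("TP9", "TP10"),
    seeds = c("POO1", "POO2"),
    parieto_occipital = c("P7", "P3", "P4", "P8", "PPO1h", "PPO2h",
                          "POO1", "POO2"),
    motor = c("FC5", "FC3", "FC4", "FC6", "FFC3h", "FFC4h",
              "C3", "C1", "C2", "C4", "CP3", "CP4")
  )
  m <- structure(list(labels = rownames(pos), pos2d = pos, groups = groups),
                 class = "eeg_montage")
  validate_montage(m)
  m
}

.study32_positions <- function() {
  # Hand-placed on an evenly spaced extended 10-05 grid so that the default
  # distance-threshold neighbourhood is connected (every electrode has >= 2
  # neighbours); mastoids are projected slightly dorsal of their anatomical
  # location, as is usual for 2-D layouts.
  p <- rbind(
    AFp1  = c(-0.15,  0.90), AFp2  = c( 0.15,  0.90),
    F7    = c(-0.75,  0.62), AFF5h = c(-0.45,  0.70),
    F1    = c(-0.15,  0.62), F2    = c( 0.15,  0.62),
    AFF6h = c( 0.45,  0.70), F8    = c( 0.75,  0.62),
    FC5   = c(-0.75,  0.32), FC3   = c(-0.45,  0.36),
    FFC3h = c(-0.15,  0.36), FFC4h = c( 0.15,  0.36),
    FC4   = c( 0.45,  0.36), FC6   = c( 0.75,  0.32),
    C3    = c(-0.60,  0.04), C1    = c(-0.30,  0.04),
    C2    = c( 0.30,  0.04), C4    = c( 0.60,  0.04),
    TP9   = c(-0.82, -0.22), CP3   = c(-0.45, -0.26),
    CP4   = c( 0.45, -0.26), TP10  = c( 0.82, -0.22),
    P7    = c(-0.75, -0.56), P3    = c(-0.42, -0.52),
    Pz    = c( 0.00, -0.52), P4    = c( 0.42, -0.52),
    P8    = c( 0.75, -0.56),
    PPO1h = c(-0.15, -0.76), PPO2h = c( 0.15, -0.76),
    POO1  = c(-0.15, -0.95), POO2  = c( 0.15, -0.95),
    Oz    = c( 0.00, -1.02)
  )
  colnames(p) <- c("x", "y")
  p
}

validate_montage <- function(m) {
  stopifnot(inherits(m, "eeg_montage"))
  if (anyDuplicated(m$labels))
    stop_config("montage labels must be unique")
  if (nrow(m$pos2d) != length(m$labels))
    stop_config("pos2d must have one row per label")
  d <- stats::dist(m$pos2d)
  if (any(d <= 0))
    stop_config("montage positions must be pairwise distinct")
  for (g in names(m$groups)) {
    missing <- setdiff(m$groups[[g]], m$labels)
    if (length(missing))
      stop_config("group '%s' names channels absent from montage: %s",
                  g, paste(missing, collapse = ", "))
  }
  invisible(m)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels; groups: %s\n",
              length(x$labels), paste(names(x$groups), collapse = ", ")))
  invisible(x)
}

#' Resolve a channel group or label vector to indices
#' @keywords internal
match_channels <- function(labels, channels, what = "channel") {
  idx <- match(channels, labels)
  if (anyNA(idx))
    stop_data("unknown %s(s): %s", what,
              paste(channels[is.na(idx)], collapse = ", "))
  idx
}
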