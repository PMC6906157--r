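#' Idealized spherical 10/5 electrode montage
#'
#' Builds an idealized electrode layout on the unit sphere for up to 72
#' channels of the extended 10/5 system. Each site is placed by its
#' anterior-posterior arc angle (degrees from the vertex towards the nasion,
#' negative towards the inion) and its lateral arc angle (negative left),
#' combined through an azimuthal-equidistant rule: the inclination from the
#' vertex is the Euclidean norm of the two arc angles. Sites labelled 9/10
#' (and Iz) fall below the head equator, as on real extended montages.
#'
#' The layout is used for distance-weighted channel interpolation and for
#' generating spatially smooth synthetic topographies; it is an idealization,
#' not a digitized head model.
#'
#' @param n_channels Number of channels (4--72). The first 32 follow a
#'   conventional 32-channel cap ordering; further channels extend the grid.
#' @return A tibble with columns `channel`, `x`, `y`, `z` (unit-sphere
#'   coordinates; x right, y anterior, z superior).
#' @export
#' @examples
#' standard_montage(32)
standard_montage <- function(n_channels = 32) {
  if (!is.numeric(n_channels) || n_channels < 4 || n_channels > 72) {
    stop("`n_channels` must be between 4 and 72", call. = FALSE)
  }
  tab <- montage_table()
  tab[seq_len(as.integer(n_channels)), , drop = FALSE]
}

# Full 72-channel table in a curated ordering (32-channel cap first).
montage_table <- function() {
  # label, anterior-posterior arc (deg), lateral arc (deg, negative = left)
  def <- list(
    # --- standard 32-channel cap ---
    c("Fp1", 72, -18), c("Fp2", 72, 18),
    c("F7", 36, -72), c("F3", 36, -36), c("Fz", 36, 0),
    c("F4", 36, 36), c("F8", 36, 72),
    c("FC5", 18, -54), c("FC1", 18, -18), c("FC2", 18, 18), c("FC6", 18, 54),
    c("T7", 0, -72), c("C3", 0, -36), c("Cz", 0, 0), c("C4", 0, 36),
    c("T8", 0, 72),
    c("CP5", -18, -54), c("CP1", -18, -18), c("CP2", -18, 18),
    c("CP6", -18, 54),
    c("P7", -36, -72), c("P3", -36, -36), c("Pz", -36, 0), c("P4", -36, 36),
    c("P8", -36, 72),
    c("PO7", -54, -36), c("PO3", -54, -18), c("POz", -54, 0),
    c("PO4", -54, 18), c("PO8", -54, 36),
    c("O1", -72, -18), c("O2", -72, 18),
    # --- 10/10 extension ---
    c("Fpz", 72, 0), c("Oz", -72, 0), c("AFz", 54, 0), c("FCz", 18, 0),
    c("CPz", -18, 0),
    c("AF7", 54, -36), c("AF3", 54, -18), c("AF4", 54, 18), c("AF8", 54, 36),
    c("F5", 36, -54), c("F1", 36, -18), c("F2", 36, 18), c("F6", 36, 54),
    c("FT7", 18, -72), c("FC3", 18, -36), c("FC4", 18, 36), c("FT8", 18, 72),
    c("C5", 0, -54), c("C1", 0, -18), c("C2", 0, 18), c("C6", 0, 54),
    c("TP7", -18, -72), c("CP3", -18, -36), c("CP4", -18, 36),
    c("TP8", -18, 72),
    c("P5", -36, -54), c("P1", -36, -18), c("P2", -36, 18), c("P6", -36, 54),
    # --- below-equator ring ---
    c("F9", 36, -90), c("F10", 36, 90),
    c("FT9", 18, -90), c("FT10", 18, 90),
    c("TP9", -18, -90), c("TP10", -18, 90),
    c("P9", -36, -90), c("P10", -36, 90),
    c("PO9", -54, -72), c("PO10", -54, 72),
    c("Iz", -90, 0)
  )
  lab <- vapply(def, `[`, character(1), 1L)
  ap <- as.numeric(vapply(def, `[`, character(1), 2L))
  lat <- as.numeric(vapply(def, `[`, character(1), 3L))
  inc <- sqrt(ap^2 + lat^2) * pi / 180
  az <- atan2(ap, lat) # angle in tangent plane: 0 = right, pi/2 = anterior
  tibble::tibble(
    channel = lab,
    x = sin(inc) * cos(az),
    y = sin(inc) * sin(az),
    z = cos(inc)
  )
}

# Positions for a set of channel names; errors on unknown labels.
montage_positions <- function(channels) {
  tab <- montage_table()
  idx <- match(channels, tab$channel)
  if (anyNA(idx)) {
    stop("unknown channel label(s): ",
         paste(channels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  as.matrix(tab[idx, c("x", "y", "z")])
}
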