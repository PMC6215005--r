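#' Idealized spherical 10/20 (extended 10/10) electrode positions
#'
#' Builds unit-sphere coordinates for extended 10/20 labels by the standard
#' constructive rule: midline electrodes sit on the nasion-inion great
#' circle, the outermost electrodes of each row sit on the equatorial
#' (circumference) ring, and intermediate electrodes are placed at
#' proportional fractions along the arc joining the two. Inferior "9/10"
#' electrodes (e.g. PO9/PO10, TP9/TP10) extend the same arc 10% below the
#' equator. This is an idealized spherical head, not a digitized cap; it is
#' what spherical-spline current source density estimation assumes.
#'
#' Coordinate frame: x towards nasion, y towards the left ear, z towards the
#' vertex; all electrodes on the unit sphere.
#'
#' @param labels character vector of 10/20-style labels (e.g. "C3", "FCz",
#'   "PO10"). Case sensitive in the conventional spelling.
#' @return data.frame with columns `label`, `x`, `y`, `z`.
#' @examples
#' electrode_positions(c("Cz", "C3", "T7", "PO9"))
#' @export
electrode_positions <- function(labels) {
  stopifnot(is.character(labels), length(labels) >= 1)
  if (anyDuplicated(labels))
    stop("duplicate electrode labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  pos <- t(vapply(labels, electrode_xyz, numeric(3)))
  data.frame(label = labels, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

# row letter -> (midline polar angle deg from vertex towards nasion,
#                equatorial-ring azimuth deg from nasion)
.row_geometry <- list(
  Fp = c(90, 18), AF = c(67.5, 36), F = c(45, 54), FC = c(22.5, 72),
  C = c(0, 90), CP = c(-22.5, 108), P = c(-45, 126), PO = c(-67.5, 144),
  O = c(-90, 162)
)

# alias rows: T -> C, FT -> FC, TP -> CP at full lateral extent
.row_alias <- c(T = "C", FT = "FC", TP = "CP")

electrode_xyz <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]+)$", label))[[1]]
  if (length(m) != 3)
    stop("cannot parse electrode label: ", label)
  row <- m[2]
  suf <- m[3]
  lateral_base <- 0L
  if (row %in% names(.row_alias)) {
    lateral_base <- 4L       # T7 == lateral slot 4 of the C row, etc.
    row <- .row_alias[[row]]
  }
  geom <- .row_geometry[[row]]
  if (is.null(geom)) stop("unknown electrode row in label: ", label)
  alpha <- geom[1] * pi / 180
  phi <- geom[2] * pi / 180
  midline <- c(sin(alpha), 0, cos(alpha))
  if (suf == "z") return(midline)
  num <- as.integer(suf)
  side <- if (num %% 2L == 1L) 1 else -1   # odd = left (+y), even = right
  slot <- if (lateral_base > 0L) {
    if (num >= 9L) 5L else lateral_base
  } else {
    ceiling(num / 2)         # 1,2 -> 1; 3,4 -> 2; 5,6 -> 3; 7,8 -> 4; 9,10 -> 5
  }
  # frontal-polar and occipital rows only have the ring electrodes
  if (row %in% c("Fp", "O")) slot <- 4L
  frac <- slot / 4           # slot 4 = equatorial ring, 5 = 10% below it
  ring <- c(cos(phi), side * sin(phi), 0)
  slerp(midline, ring, frac)
}

# spherical linear interpolation; frac > 1 extrapolates beyond `b`
slerp <- function(a, b, frac) {
  omega <- acos(max(-1, min(1, sum(a * b))))
  if (omega < 1e-12) return(a)
  (sin((1 - frac) * omega) * a + sin(frac * omega) * b) / sin(omega)
}

#' Default 64-channel extended 10/20 montage labels
#'
#' The channel set emulated by the cohort generator: a standard 64-channel
#' cap including FCz (after reference interpolation) and the inferior
#' PO9/PO10, TP9/TP10 sites.
#'
#' @return character vector of 64 labels.
#' @export
montage64 <- function() {
  c("Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "TP10",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10",
    "O1", "Oz", "O2")
}

#' Reduced 16-channel montage used at demo scale
#'
#' Keeps every electrode that carries a default planted component or a
#' classical ERP quantification site (PO9/PO10, Cz, FC1, P1, C3, T7, FCz).
#'
#' @return character vector of 16 labels.
#' @export
montage16 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "FC1", "FCz", "Cz", "C3", "C4",
    "T7", "T8", "P1", "P3", "P4", "PO9", "PO10")
}
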