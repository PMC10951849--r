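## 64-channel extended 10/20 montage on a unit sphere.
##
## Coordinate frame: x = right, y = anterior, z = superior, head centre at the
## origin, sensor sphere radius 1 (dimensionless; multiply by ~0.09 m for a
## physical scalp). Positions are constructed geometrically from the 10/10
## nomenclature: the outer 10% ring sits at 72 deg inclination, rows (F, FC,
## C, ...) are arcs from the left outer-ring anchor through the midline point
## to the right anchor, with intermediate electrodes at equal arc fractions,
## and the 9/10 electrodes (FT9, TP10, ...) sit on the ear-level circle.

sph_point <- function(incl_deg, az_deg) {
  i <- incl_deg * pi / 180
  a <- az_deg * pi / 180
  c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## point at fraction `frac` along the spherical arc from A to M, on the circle
## through A, M, B (all on the sphere, so the circle lies on the sphere)
arc_point <- function(A, M, B, frac) {
  v1 <- M - A
  v2 <- B - A
  n <- cross3(v1, v2)
  n2 <- sum(n^2)
  if (n2 < 1e-14) { # collinear fallback: slerp A->M
    ang <- acos(pmin(pmax(sum(A * M), -1), 1))
    u <- M - sum(A * M) * A
    u <- u / sqrt(sum(u^2))
    return(cos(frac * ang) * A + sin(frac * ang) * u)
  }
  centre <- A + (sum(v1^2) * cross3(cross3(v1, v2), v1) +
                 sum(v2^2) * cross3(v2, cross3(v1, v2))) / (2 * n2)
  a <- A - centre
  m <- M - centre
  axis <- cross3(a, m)
  axis <- axis / sqrt(sum(axis^2))
  ang <- atan2(sqrt(sum(cross3(a, m)^2)), sum(a * m)) * frac
  # Rodrigues rotation of a about axis
  rot <- a * cos(ang) + cross3(axis, a) * sin(ang) + axis * sum(axis * a) * (1 - cos(ang))
  p <- centre + rot
  p / sqrt(sum(p^2))
}

#' Standard 64-channel EEG montage
#'
#' Channel labels and unit-sphere positions for a 64-electrode extended 10/20
#' cap (actiCAP-64 label set, FCz used as recording reference and therefore
#' absent). Positions are derived geometrically from the 10/10 naming scheme.
#'
#' @return data.frame with columns `label`, `x`, `y`, `z` (unit sphere,
#'   x right / y anterior / z superior)
#' @export
#' @examples
#' m <- standard_montage_64()
#' nrow(m) # 64
standard_montage_64 <- function() {
  pos <- list()
  add <- function(label, p) pos[[label]] <<- p

  ring <- c(Fp1 = -18, Fp2 = 18, AF7 = -36, AF8 = 36, F7 = -54, F8 = 54,
            FT7 = -72, FT8 = 72, T7 = -90, T8 = 90, TP7 = -108, TP8 = 108,
            P7 = -126, P8 = 126, PO7 = -144, PO8 = 144, O1 = -162, O2 = 162,
            Oz = 180)
  for (lb in names(ring)) add(lb, sph_point(72, ring[[lb]]))

  lower <- c(FT9 = -72, FT10 = 72, TP9 = -108, TP10 = 108, PO9 = -144, PO10 = 144)
  for (lb in names(lower)) add(lb, sph_point(90, lower[[lb]]))

  mid <- list(AFz = sph_point(54, 0), Fz = sph_point(36, 0), FCz = sph_point(18, 0),
              Cz = sph_point(0, 0), CPz = sph_point(18, 180), Pz = sph_point(36, 180),
              POz = sph_point(54, 180))
  # midline electrodes present in the cap (AFz, FCz are anchors only)
  for (lb in c("Fz", "Cz", "CPz", "Pz", "POz")) add(lb, mid[[lb]])

  row_arc <- function(prefix, left_anchor, mid_label, members) {
    A <- pos[[left_anchor]]
    B <- pos[[sub("7$", "8", left_anchor)]]
    M <- mid[[mid_label]]
    for (nm in names(members)) {
      f <- members[[nm]]
      if (f > 0) add(paste0(prefix, nm), arc_point(A, M, B, f))
      else add(paste0(prefix, nm), arc_point(B, M, A, -f))
    }
  }
  quarters <- c(`5` = 0.25, `3` = 0.5, `1` = 0.75, `2` = -0.75, `4` = -0.5, `6` = -0.25)
  row_arc("AF", "AF7", "AFz", c(`3` = 0.5, `4` = -0.5))
  row_arc("F",  "F7",  "Fz",  quarters)
  row_arc("FC", "FT7", "FCz", quarters)
  row_arc("C",  "T7",  "Cz",  quarters)
  row_arc("CP", "TP7", "CPz", quarters)
  row_arc("P",  "P7",  "Pz",  quarters)
  row_arc("PO", "PO7", "POz", c(`3` = 0.5, `4` = -0.5))

  m <- do.call(rbind, pos)
  df <- data.frame(label = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3],
                   row.names = NULL, stringsAsFactors = FALSE)
  df[order(-df$z, df$y, df$x), , drop = FALSE][seq_len(nrow(df)), ] -> df
  rownames(df) <- NULL
  df
}

#' Azimuthal-equidistant 2-D projection of sensor positions
#'
#' Projects unit-sphere positions to the plane with the vertex at the origin;
#' arc length from the vertex is preserved. Used for neighbour-graph
#' triangulation and topographic plots.
#'
#' @param positions matrix or data.frame with columns x, y, z on the unit sphere
#' @return matrix with columns x2d (right), y2d (anterior)
#' @export
montage_projection <- function(positions) {
  p <- as.matrix(positions[, c("x", "y", "z")])
  r <- sqrt(rowSums(p^2))
  incl <- acos(pmin(pmax(p[, 3] / r, -1), 1))
  az <- atan2(p[, 1], p[, 2])
  cbind(x2d = incl * sin(az), y2d = incl * cos(az))
}
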