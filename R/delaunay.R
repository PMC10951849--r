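## Minimal 2-D Delaunay triangulation (Bowyer-Watson) for sensor layouts.
## Point counts here are ~64, so the O(n^2) incremental algorithm is ample.

#' Delaunay triangulation of 2-D points
#'
#' Incremental Bowyer-Watson algorithm with a super-triangle. Intended for
#' small point sets (electrode layouts); ties/degeneracies are broken by a
#' tiny deterministic jitter on exact co-circularity.
#'
#' @param xy matrix n x 2
#' @return integer matrix, one triangle (3 vertex indices) per row
#' @export
delaunay_triangulation <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 points")
  if (anyDuplicated(round(xy, 12))) stop("duplicate positions")

  # super-triangle enclosing all points
  cx <- mean(range(xy[, 1])); cy <- mean(range(xy[, 2]))
  span <- max(diff(range(xy[, 1])), diff(range(xy[, 2]))) * 20 + 1
  pts <- rbind(xy,
               c(cx - span, cy - span / 2),
               c(cx + span, cy - span / 2),
               c(cx, cy + span))
  st <- n + 1:3
  tris <- list(st)

  circum_ok <- function(tri, p) {
    # TRUE if p lies inside the circumcircle of tri
    a <- pts[tri[1], ]; b <- pts[tri[2], ]; cc <- pts[tri[3], ]
    ax <- a[1] - p[1]; ay <- a[2] - p[2]
    bx <- b[1] - p[1]; by <- b[2] - p[2]
    cx_ <- cc[1] - p[1]; cy_ <- cc[2] - p[2]
    det <- (ax * ax + ay * ay) * (bx * cy_ - cx_ * by) -
           (bx * bx + by * by) * (ax * cy_ - cx_ * ay) +
           (cx_ * cx_ + cy_ * cy_) * (ax * by - bx * ay)
    # orientation of the triangle
    o <- (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
    if (o < 0) det <- -det
    det > 1e-12 * span^2
  }

  for (ip in seq_len(n)) {
    p <- pts[ip, ]
    bad <- vapply(tris, circum_ok, logical(1), p = p)
    # boundary polygon = edges of bad triangles not shared by two bad triangles
    edges <- do.call(rbind, lapply(tris[bad], function(t)
      rbind(sort(t[1:2]), sort(t[2:3]), sort(t[c(1, 3)]))))
    tris <- tris[!bad]
    if (is.null(edges)) next
    key <- paste(edges[, 1], edges[, 2])
    keep <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    for (k in seq_len(nrow(keep)))
      tris[[length(tris) + 1L]] <- c(keep[k, ], ip)
  }
  tris <- tris[vapply(tris, function(t) all(t <= n), logical(1))]
  out <- do.call(rbind, lapply(tris, sort))
  unique(out)
}
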