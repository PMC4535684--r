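# Polygon geometry for closed probe-signal contours.
#
# Contours live in continuous 1-based pixel-center coordinates: vertex
# (row, col) = (1, 1) is the center of the top-left pixel. All polygons are
# implicitly closed (last vertex connects back to the first).

#' Create a contour object
#'
#' A closed polygonal boundary in continuous pixel coordinates, as produced
#' by [initialize_contour()] and [evolve_snake()].
#'
#' @param vertices Numeric matrix with columns `row`, `col` (>= 8 rows).
#' @param closed Logical flag; contours are always closed here.
#' @param converged Logical; whether the producing iteration converged.
#' @return An object of class `"contour"`.
#' @export
contour <- function(vertices, closed = TRUE, converged = NA) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) {
    fishda_stop("contour vertices must be an n x 2 (row, col) matrix",
                "fishda_error_contour")
  }
  if (nrow(vertices) < 8L) {
    fishda_stop("a contour needs at least 8 vertices", "fishda_error_contour")
  }
  if (!all(is.finite(vertices))) {
    fishda_stop("contour vertices must be finite", "fishda_error_contour")
  }
  colnames(vertices) <- c("row", "col")
  structure(list(vertices = vertices, closed = closed, converged = converged),
            class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d vertices, area %.2f px^2, centroid (%.2f, %.2f)\n",
              nrow(x$vertices), polygon_area(x$vertices),
              polygon_centroid(x$vertices)[1], polygon_centroid(x$vertices)[2]))
  invisible(x)
}

#' Shoelace area of a closed polygon (absolute value, px^2)
#' @param vertices n x 2 matrix (row, col).
#' @return Numeric scalar.
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  r <- v[, 1]; c <- v[, 2]
  rn <- c(r[-1], r[1]); cn <- c(c[-1], c[1])
  abs(sum(c * rn - cn * r)) / 2
}

#' @noRd
polygon_perimeter <- function(vertices) {
  v <- as.matrix(vertices)
  d <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]) - v
  sum(sqrt(rowSums(d^2)))
}

#' @noRd
polygon_centroid <- function(vertices) {
  colMeans(as.matrix(vertices))
}

#' Even-odd point-in-polygon test, vectorized over points
#'
#' @param points n x 2 matrix (row, col) of query points.
#' @param vertices m x 2 polygon vertex matrix.
#' @return Logical vector of length n.
#' @export
point_in_polygon <- function(points, vertices) {
  p <- as.matrix(points)
  v <- as.matrix(vertices)
  n <- nrow(v)
  inside <- rep(FALSE, nrow(p))
  j <- n
  px <- p[, 1]; py <- p[, 2]
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

#' Rasterize a contour to a pixel mask (pixel-center membership)
#'
#' A pixel belongs to the mask when its center falls inside the polygon;
#' no partial-pixel weighting is applied.
#'
#' @param contour A [contour] or vertex matrix.
#' @param nrow,ncol Dimensions of the target image.
#' @return Logical matrix.
#' @export
polygon_mask <- function(contour, nrow, ncol) {
  v <- if (inherits(contour, "contour")) contour$vertices else as.matrix(contour)
  mask <- matrix(FALSE, nrow, ncol)
  r0 <- max(1L, floor(min(v[, 1])))
  r1 <- min(nrow, ceiling(max(v[, 1])))
  c0 <- max(1L, floor(min(v[, 2])))
  c1 <- min(ncol, ceiling(max(v[, 2])))
  if (r0 > r1 || c0 > c1) return(mask)
  grid <- as.matrix(expand.grid(row = r0:r1, col = c0:c1))
  inside <- point_in_polygon(grid, v)
  mask[grid[inside, , drop = FALSE]] <- TRUE
  mask
}

#' @noRd
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#' @param vertices n x 2 vertex matrix.
#' @return Logical scalar.
#' @export
polygon_is_simple <- function(vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (shared endpoint)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (segments_intersect(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Resample a closed contour to n points at uniform arc length
#' @noRd
resample_closed <- function(vertices, n) {
  v <- as.matrix(vertices)
  vc <- rbind(v, v[1, , drop = FALSE])
  seg <- sqrt(rowSums((vc[-1, , drop = FALSE] - vc[-nrow(vc), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) return(v[rep(1L, n), , drop = FALSE])
  s <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  out <- matrix(0, n, 2)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(vc)] <- nrow(vc) - 1L
  frac <- (s - cum[idx]) / pmax(seg[idx], .Machine$double.eps)
  out[, 1] <- vc[idx, 1] + frac * (vc[idx + 1L, 1] - vc[idx, 1])
  out[, 2] <- vc[idx, 2] + frac * (vc[idx + 1L, 2] - vc[idx, 2])
  colnames(out) <- c("row", "col")
  out
}

#' Convert a contour to a data frame of vertices
#'
#' @param x A [contour].
#' @param cell_id,homolog Optional identifiers carried into the table.
#' @return A data.frame with columns cell_id, homolog, vertex_index, row, col.
#' @export
contour_to_df <- function(x, cell_id = NA_character_, homolog = NA_character_) {
  v <- x$vertices
  data.frame(
    cell_id = cell_id, homolog = homolog,
    vertex_index = seq_len(nrow(v)),
    row = v[, 1], col = v[, 2],
    stringsAsFactors = FALSE
  )
}
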