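#' Fields of interest for spatial analysis
#'
#' A field of interest delimits the region of space in which cells were
#' observed; all ring counts and random reference points are confined to it,
#' which avoids boundary artifacts without an analytic edge correction.
#' Three representations are supported: an axis-aligned rectangle, a simple
#' polygon, and a rasterized binary mask (the output of
#' [build_field_of_interest()]).
#'
#' @param width,height Rectangle dimensions in micrometres.
#' @return An object of class `erk_field`.
#' @name fields
NULL

#' @rdname fields
#' @export
field_rect <- function(width, height) {
  if (width <= 0 || height <= 0)
    stop_cfg("field must have positive area")
  structure(list(type = "rect", width = width, height = height,
                 area = width * height),
            class = "erk_field")
}

#' @rdname fields
#' @param vertices Two-column matrix of polygon vertices (micrometres), in
#'   order, not self-intersecting; the polygon is closed implicitly.
#' @export
field_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop_cfg("polygon needs a 2-column matrix with >= 3 vertices")
  x <- vertices[, 1]; y <- vertices[, 2]
  # shoelace
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (area <= 0) stop_cfg("field must have positive area")
  structure(list(type = "polygon", vertices = vertices, area = area,
                 bbox = c(min(x), min(y), max(x), max(y))),
            class = "erk_field")
}

#' @rdname fields
#' @param mask Logical matrix (rows = y cells, columns = x cells).
#' @param xmin,ymin Coordinates of the lower-left corner of the mask grid.
#' @param res Grid cell edge length in micrometres.
#' @export
field_mask <- function(mask, xmin = 0, ymin = 0, res = 2) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_cfg("mask must be a logical matrix")
  area <- sum(mask) * res^2
  if (area <= 0) stop_cfg("field must have positive area")
  structure(list(type = "mask", mask = mask, xmin = xmin, ymin = ymin,
                 res = res, area = area),
            class = "erk_field")
}

#' @export
print.erk_field <- function(x, ...) {
  cat(sprintf("<erk_field (%s): area %.0f um^2>\n", x$type, x$area))
  invisible(x)
}

# Even-odd ray casting; `pts` n x 2, returns logical vector.
points_in_polygon <- function(pts, vertices) {
  n <- nrow(pts)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  m <- length(vx)
  inside <- rep(FALSE, n)
  j <- m
  for (i in seq_len(m)) {
    crosses <- ((vy[i] > pts[, 2]) != (vy[j] > pts[, 2])) &
      (pts[, 1] < (vx[j] - vx[i]) * (pts[, 2] - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Is each point inside the field?
field_contains <- function(field, pts) {
  pts <- as.matrix(pts)
  switch(field$type,
    rect = pts[, 1] >= 0 & pts[, 1] <= field$width &
           pts[, 2] >= 0 & pts[, 2] <= field$height,
    polygon = points_in_polygon(pts, field$vertices),
    mask = {
      ix <- floor((pts[, 1] - field$xmin) / field$res) + 1
      iy <- floor((pts[, 2] - field$ymin) / field$res) + 1
      ok <- ix >= 1 & ix <= ncol(field$mask) & iy >= 1 & iy <= nrow(field$mask)
      out <- rep(FALSE, nrow(pts))
      out[ok] <- field$mask[cbind(iy[ok], ix[ok])]
      out
    })
}

# Uniform random points inside the field (uses the current RNG stream).
sample_in_field <- function(field, n) {
  if (n <= 0) return(matrix(numeric(0), ncol = 2))
  switch(field$type,
    rect = cbind(stats::runif(n, 0, field$width),
                 stats::runif(n, 0, field$height)),
    polygon = {
      bb <- field$bbox
      out <- matrix(NA_real_, n, 2)
      got <- 0L
      while (got < n) {
        m <- max(2L * (n - got), 16L)
        cand <- cbind(stats::runif(m, bb[1], bb[3]),
                      stats::runif(m, bb[2], bb[4]))
        keep <- cand[points_in_polygon(cand, field$vertices), , drop = FALSE]
        take <- min(nrow(keep), n - got)
        if (take > 0) {
          out[(got + 1):(got + take), ] <- keep[seq_len(take), ]
          got <- got + take
        }
      }
      out
    },
    mask = {
      cells <- which(field$mask)
      pick <- cells[sample.int(length(cells), n, replace = TRUE)]
      iy <- (pick - 1) %% nrow(field$mask) + 1
      ix <- (pick - 1) %/% nrow(field$mask) + 1
      cbind(field$xmin + (ix - 1 + stats::runif(n)) * field$res,
            field$ymin + (iy - 1 + stats::runif(n)) * field$res)
    })
}

#' Build a field of interest from observed cell positions
#'
#' Rasterizes the union of discs of radius `dilation_radius` around every
#' observed cell, giving the region of space where cells were seen. Using
#' this mask both for the observed counts and for the random reference
#' points prevents boundary artifacts in the radial distribution function.
#'
#' @param points Two-column matrix or data frame of positions (micrometres).
#' @param dilation_radius Disc radius in micrometres (> 0).
#' @param res Raster resolution in micrometres (default 2).
#' @return A mask-type `erk_field` with its `area` in square micrometres.
#' @export
build_field_of_interest <- function(points, dilation_radius, res = 2) {
  pts <- as.matrix(points[, 1:2])
  if (nrow(pts) < 3) stop_cfg("need at least 3 points to build a field")
  if (dilation_radius <= 0) stop_cfg("dilation_radius must be > 0")
  xmin <- min(pts[, 1]) - dilation_radius
  ymin <- min(pts[, 2]) - dilation_radius
  nx <- ceiling((max(pts[, 1]) + dilation_radius - xmin) / res)
  ny <- ceiling((max(pts[, 2]) + dilation_radius - ymin) / res)
  mask <- matrix(FALSE, ny, nx)
  half <- ceiling(dilation_radius / res)
  # grid-cell centres
  cx <- xmin + (seq_len(nx) - 0.5) * res
  cy <- ymin + (seq_len(ny) - 0.5) * res
  for (i in seq_len(nrow(pts))) {
    jx <- floor((pts[i, 1] - xmin) / res) + 1
    jy <- floor((pts[i, 2] - ymin) / res) + 1
    sx <- max(1, jx - half):min(nx, jx + half)
    sy <- max(1, jy - half):min(ny, jy + half)
    dx2 <- (cx[sx] - pts[i, 1])^2
    dy2 <- (cy[sy] - pts[i, 2])^2
    hit <- outer(dy2, dx2, "+") <= dilation_radius^2
    mask[sy, sx] <- mask[sy, sx] | hit
  }
  field_mask(mask, xmin = xmin, ymin = ymin, res = res)
}
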