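# Light-spot geometry: signed distance, scatter expansion, exposure.

#' Light-spot geometry
#'
#' Represents the light region of the arena, either as a circle (the
#' canonical 2-cm-diameter spot: radius `10 * px_per_mm` px) or as a simple
#' closed polygon extracted from images. An `expansion` margin (pixels)
#' records outward offsets applied by [expand_spot()].
#'
#' @param center length-2 numeric, circle centre in px (circle only).
#' @param radius circle radius in px, > 0 (circle only).
#' @param vertices n x 2 matrix of polygon vertices in px (polygon only);
#'   the polygon is closed implicitly (last vertex connects to the first).
#' @return object of class `light_spot`.
#' @export
light_spot <- function(center = NULL, radius = NULL, vertices = NULL) {
  if (!is.null(vertices)) {
    vertices <- as.matrix(vertices)
    stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
    spot <- list(shape = "polygon", vertices = vertices, expansion = 0)
  } else {
    stopifnot(length(center) == 2, is.numeric(radius), radius > 0)
    spot <- list(shape = "circle", center = as.numeric(center),
                 radius = as.numeric(radius), expansion = 0)
  }
  structure(spot, class = "light_spot")
}

#' @export
print.light_spot <- function(x, ...) {
  if (x$shape == "circle") {
    cat(sprintf("<light_spot> circle, center (%.1f, %.1f) px, radius %.2f px",
                x$center[1], x$center[2], x$radius))
  } else {
    cat(sprintf("<light_spot> polygon, %d vertices", nrow(x$vertices)))
  }
  if (x$expansion > 0) cat(sprintf(" (expanded %+g px)", x$expansion))
  cat("\n")
  invisible(x)
}

#' Signed distance from points to the light-spot boundary
#'
#' Euclidean distance to the nearest point of the spot boundary, positive
#' outside the spot, negative inside, 0 on the boundary (the sign
#' convention used for larval head-to-spot distances).
#'
#' @param p n x 2 matrix (or length-2 vector) of points, px.
#' @param spot a [light_spot()].
#' @return numeric vector of signed distances in px.
#' @export
signed_distance <- function(p, spot) {
  stopifnot(inherits(spot, "light_spot"))
  p <- rbind2cols(p)
  if (spot$shape == "circle") {
    d <- sqrt((p[, 1] - spot$center[1])^2 + (p[, 2] - spot$center[2])^2) -
      spot$radius
  } else {
    d <- polygon_signed_distance(p, spot$vertices) - spot$expansion
  }
  d
}

# Unsigned min distance to polygon edges, sign flipped inside.
polygon_signed_distance <- function(p, v) {
  n <- nrow(v)
  mind <- rep(Inf, nrow(p))
  for (i in seq_len(n)) {
    a <- v[i, ]
    b <- v[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- (p[, 1] - a[1])^2 + (p[, 2] - a[2])^2
    } else {
      tt <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
      tt <- pmin(pmax(tt, 0), 1)
      d2 <- (p[, 1] - (a[1] + tt * ab[1]))^2 +
            (p[, 2] - (a[2] + tt * ab[2]))^2
    }
    mind <- pmin(mind, d2)
  }
  inside <- pracma::inpolygon(p[, 1], p[, 2], v[, 1], v[, 2],
                              boundary = TRUE)
  ifelse(inside, -sqrt(mind), sqrt(mind))
}

#' Expand a light spot outward
#'
#' Offsets the spot boundary outward by `margin` px (Minkowski sum with a
#' disc). For circles the radius grows by `margin` exactly; for polygons
#' the offset is carried as an `expansion` field so that the signed
#' distance to the expanded spot equals the nominal signed distance minus
#' `margin`. The canonical use is the 10-px light-scatter allowance applied
#' when scoring light-avoidance success.
#'
#' @param spot a [light_spot()].
#' @param margin outward offset in px, >= 0.
#' @return the expanded `light_spot`.
#' @export
expand_spot <- function(spot, margin) {
  stopifnot(inherits(spot, "light_spot"), is.numeric(margin),
            length(margin) == 1)
  if (margin < 0) stop("negative expansion margins are not allowed")
  if (spot$shape == "circle") {
    spot$radius <- spot$radius + margin
  }
  spot$expansion <- spot$expansion + margin
  spot
}

#' Is a point in the light?
#'
#' TRUE iff the point lies strictly inside the spot expanded outward by
#' `margin` px. A point exactly on the (expanded) boundary counts as out
#' of the light.
#'
#' @inheritParams signed_distance
#' @param margin outward scatter allowance in px (default 10).
#' @return logical vector.
#' @export
head_in_light <- function(p, spot, margin = 10) {
  signed_distance(p, expand_spot(spot, margin)) < 0
}

#' Cumulative light-exposure series
#'
#' Per-frame cumulative seconds during which the larval head has been in
#' the light since trial start. "In the light" uses the same
#' margin-expanded spot as success scoring, so one membership definition
#' holds throughout; exposure accumulates across multiple entries and
#' never resets ("total" exposure).
#'
#' @param traj a [trajectory()].
#' @param spot a [light_spot()].
#' @param margin scatter allowance in px (default 10).
#' @return numeric vector, nondecreasing, increments of 0 or 1/frame_rate.
#' @export
cumulative_exposure <- function(traj, spot, margin = 10) {
  stopifnot(inherits(traj, "larva_trajectory"))
  inlight <- head_in_light(point_matrix(traj, "head"), spot, margin)
  cumsum(as.numeric(inlight)) / traj$frame_rate
}

#' Savitzky-Golay smoothing of a spot boundary
#'
#' Smooths an ordered closed boundary point sequence with a
#' Savitzky-Golay polynomial filter applied periodically to the x and y
#' coordinate sequences (polynomial order 12 by default, matching the
#' smoothing applied to image-extracted spot edges).
#'
#' @param boundary n x 2 matrix of ordered boundary points.
#' @param order polynomial order (default 12).
#' @param window odd filter window, must exceed `order` (default 25).
#' @return smoothed n x 2 matrix.
#' @export
smooth_spot_edge <- function(boundary, order = 12, window = 25) {
  boundary <- rbind2cols(boundary)
  n <- nrow(boundary)
  if (window %% 2 == 0 || window <= order) {
    stop("window must be odd and greater than the polynomial order")
  }
  if (window > n) stop("window exceeds boundary point count")
  h <- (window - 1L) %/% 2L
  pad <- function(x) c(x[(n - h + 1L):n], x, x[1:h])
  sm <- function(x) {
    y <- signal::sgolayfilt(pad(x), p = order, n = window)
    y[(h + 1L):(h + n)]
  }
  cbind(sm(boundary[, 1]), sm(boundary[, 2]))
}

#' Read / write arena geometry JSON
#'
#' Format: `{"shape":"circle","center_px":[x,y],"radius_px":r}` or
#' `{"shape":"polygon","vertices_px":[[x,y],...]}`.
#'
#' @param path file path.
#' @return a [light_spot()] (`read_arena_json`) or `path` invisibly.
#' @export
read_arena_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(j$shape, "circle")) {
    light_spot(center = j$center_px, radius = j$radius_px)
  } else if (identical(j$shape, "polygon")) {
    light_spot(vertices = j$vertices_px)
  } else {
    stop("unknown arena shape: ", j$shape)
  }
}

#' @rdname read_arena_json
#' @param spot a [light_spot()] to serialise.
#' @export
write_arena_json <- function(spot, path) {
  stopifnot(inherits(spot, "light_spot"))
  j <- if (spot$shape == "circle") {
    list(shape = "circle", center_px = spot$center, radius_px = spot$radius)
  } else {
    list(shape = "polygon", vertices_px = spot$vertices)
  }
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
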