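# Sphere tessellations and facet-density ("Dubai") histograms.
#
# A Dubai plot bins orientation-sphere points into facets of a sphere
# tessellation and draws a radiating bar per facet with length
# proportional to its count. The default tessellation is a subdivided
# icosahedron ("icosphere"): its facets are near-equal in area, avoiding
# the polar over-resolution of a latitude-longitude grid. A lat/lon grid
# is provided for comparability.

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

# Spherical triangle area (steradians) by l'Huilier's theorem.
spherical_triangle_area <- function(a, b, c) {
  ang <- function(u, v) acos(pmin(1, pmax(-1, rowSums(u * v))))
  A <- ang(b, c); B <- ang(a, c); C <- ang(a, b)
  s <- (A + B + C) / 2
  t <- tan(s / 2) * tan((s - A) / 2) * tan((s - B) / 2) * tan((s - C) / 2)
  4 * atan(sqrt(pmax(t, 0)))
}

#' Subdivided-icosahedron sphere tessellation
#'
#' Each of the 20 icosahedral faces is split into `freq^2` triangles on a
#' barycentric grid and projected onto the unit sphere, giving
#' `20 * freq^2` near-equal-area facets (1,280 at the default `freq = 8`).
#'
#' @param freq subdivision frequency (positive integer).
#' @return object of class `sphere_tessellation` with facet `centers`
#'   (F x 3 unit vectors), `areas` (steradians, summing to 4 pi), the facet
#'   corner coordinates, and a `tessellation_id`.
#' @export
icosphere <- function(freq = 8) {
  freq <- as.integer(freq)
  if (freq < 1) parameter_error("freq must be a positive integer")
  ico <- icosahedron()
  V1 <- list(); V2 <- list(); V3 <- list()
  for (fc in seq_len(nrow(ico$faces))) {
    A <- ico$vertices[ico$faces[fc, 1], ]
    B <- ico$vertices[ico$faces[fc, 2], ]
    C <- ico$vertices[ico$faces[fc, 3], ]
    pt <- function(i, j) {
      p <- A + (i / freq) * (B - A) + (j / freq) * (C - A)
      p / sqrt(sum(p^2))
    }
    for (i in 0:(freq - 1)) for (j in 0:(freq - 1 - i)) {
      V1[[length(V1) + 1]] <- pt(i, j)
      V2[[length(V2) + 1]] <- pt(i + 1, j)
      V3[[length(V3) + 1]] <- pt(i, j + 1)
      if (i + j <= freq - 2) {
        V1[[length(V1) + 1]] <- pt(i + 1, j)
        V2[[length(V2) + 1]] <- pt(i + 1, j + 1)
        V3[[length(V3) + 1]] <- pt(i, j + 1)
      }
    }
  }
  v1 <- do.call(rbind, V1); v2 <- do.call(rbind, V2); v3 <- do.call(rbind, V3)
  ctr <- v1 + v2 + v3
  ctr <- ctr / sqrt(rowSums(ctr^2))
  structure(list(
    tessellation_id = sprintf("icosphere_f%d", freq),
    centers = ctr,
    areas = spherical_triangle_area(v1, v2, v3),
    corners = list(v1 = v1, v2 = v2, v3 = v3)),
    class = "sphere_tessellation")
}

#' Latitude-longitude sphere tessellation
#'
#' Rectangular facets between parallels and meridians. Facet areas shrink
#' toward the poles, which biases raw-count density maps; prefer
#' [icosphere()] unless grid comparability is required.
#'
#' @param n_lat number of latitude bands.
#' @param n_lon number of longitude sectors.
#' @return a `sphere_tessellation`.
#' @export
latlon_grid <- function(n_lat = 18, n_lon = 36) {
  lat_edges <- seq(-90, 90, length.out = n_lat + 1)
  lon_edges <- seq(0, 360, length.out = n_lon + 1)
  lat_c <- (lat_edges[-1] + lat_edges[-(n_lat + 1)]) / 2
  lon_c <- (lon_edges[-1] + lon_edges[-(n_lon + 1)]) / 2
  grid <- expand.grid(lon = lon_c, lat = lat_c)
  area_band <- diff(sin(deg2rad(lat_edges))) * (2 * pi / n_lon)
  structure(list(
    tessellation_id = sprintf("latlon_%dx%d", n_lat, n_lon),
    centers = to_sphere(grid$lon, grid$lat),
    areas = rep(area_band, each = n_lon),
    corners = NULL),
    class = "sphere_tessellation")
}

#' @export
print.sphere_tessellation <- function(x, ...) {
  cat(sprintf("<sphere_tessellation> %s: %d facets, area sum %.8f sr\n",
              x$tessellation_id, nrow(x$centers), sum(x$areas)))
  invisible(x)
}

# Nearest-center facet assignment; chunked so the N x F dot-product matrix
# stays small. Ties break to the lowest facet index (max.col "first").
assign_facets <- function(xyz, tess, chunk = 20000L) {
  n <- nrow(xyz)
  out <- integer(n)
  ct <- t(tess$centers)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e] <- max.col(xyz[s:e, , drop = FALSE] %*% ct, ties.method = "first")
  }
  out
}

#' Facet-density histogram on the orientation sphere
#'
#' Assigns every valid sample of an orientation series to the facet whose
#' center it is nearest (greatest dot product; ties to the lowest index)
#' and counts per facet — the data behind a Dubai plot.
#'
#' @param series an `orientation_series`.
#' @param tessellation a `sphere_tessellation`; default `icosphere(8)`.
#' @param density if TRUE the bar-height metric is count/area
#'   (samples per steradian) instead of the raw count.
#' @return object of class `facet_histogram`: `tessellation_id`,
#'   `facet_centers`, `facet_areas`, integer `counts`, `total`,
#'   `heights` (the chosen bar metric) and the `density` flag.
#' @export
dubai_histogram <- function(series, tessellation = icosphere(8),
                            density = FALSE) {
  v <- series$valid & is.finite(series$heading) & is.finite(series$pitch)
  if (!any(v))
    hods_error("no valid samples: cannot build a histogram",
               "hods_empty_histogram")
  xyz <- to_sphere(series$heading[v], series$pitch[v])
  idx <- assign_facets(xyz, tessellation)
  counts <- tabulate(idx, nbins = nrow(tessellation$centers))
  structure(list(
    tessellation_id = tessellation$tessellation_id,
    facet_centers = tessellation$centers,
    facet_areas = tessellation$areas,
    counts = counts,
    total = sum(counts),
    heights = if (density) counts / tessellation$areas else counts,
    density = density),
    class = "facet_histogram")
}

#' @export
print.facet_histogram <- function(x, ...) {
  cat(sprintf("<facet_histogram> %s: %d samples over %d facets (%d occupied)\n",
              x$tessellation_id, x$total, length(x$counts),
              sum(x$counts > 0)))
  invisible(x)
}

#' Write a facet histogram to JSON
#'
#' @param x a `facet_histogram`.
#' @param path output file path.
#' @export
write_facet_histogram <- function(x, path) {
  jsonlite::write_json(
    list(tessellation_id = x$tessellation_id,
         facet_centers = x$facet_centers,
         facet_areas = x$facet_areas,
         counts = x$counts, total = x$total, density = x$density),
    path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
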