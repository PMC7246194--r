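# Rendering the orientation-sphere views: point clouds and trajectories
# on the sphere, Dubai bar histograms, time-radial (expanding-radius)
# plots, and planar heading/pitch panels.
#
# Every render writes a JSON sidecar next to the figure containing the
# exact numeric data drawn, so tests (and downstream analyses) work on
# the data rather than on pixels.

#' Plot specification
#'
#' @param mode one of "sphere_points", "sphere_trajectory", "dubai",
#'   "time_radial", "planar".
#' @param color_by colouring variable: "pitch" (diverging map centred at
#'   level), "angular_speed", "time" or "state".
#' @param radius_map "none" or "linear_time"; only meaningful (and only
#'   allowed) with mode "time_radial", where radius grows linearly from 0
#'   at the start to 1 at the end of the series.
#' @param view_azimuth,view_elevation orthographic viewpoint for sphere
#'   modes, degrees.
#' @return an object of class `plot_spec`.
#' @export
plot_spec <- function(mode = c("sphere_points", "sphere_trajectory",
                               "dubai", "time_radial", "planar"),
                      color_by = c("pitch", "angular_speed", "time", "state"),
                      radius_map = c("none", "linear_time"),
                      view_azimuth = 20, view_elevation = 25) {
  mode <- match.arg(mode)
  color_by <- match.arg(color_by)
  radius_map <- match.arg(radius_map)
  if (radius_map != "none" && mode != "time_radial")
    config_error("radius_map is only compatible with mode 'time_radial'")
  if (mode == "time_radial" && radius_map == "none")
    radius_map <- "linear_time"
  structure(list(mode = mode, color_by = color_by, radius_map = radius_map,
                 view_azimuth = view_azimuth,
                 view_elevation = view_elevation),
            class = "plot_spec")
}

# Orthographic projection of unit vectors for a given viewpoint.
project_ortho <- function(xyz, az, el) {
  a <- deg2rad(az); e <- deg2rad(el)
  right <- c(-sin(a), cos(a), 0)
  up <- c(-cos(a) * sin(e), -sin(a) * sin(e), cos(e))
  fwd <- c(cos(a) * cos(e), sin(a) * cos(e), sin(e))
  data.frame(px = as.numeric(xyz %*% right), py = as.numeric(xyz %*% up),
             front = as.numeric(xyz %*% fwd) >= 0)
}

color_values <- function(series, color_by) {
  switch(color_by,
         pitch = series$pitch,
         angular_speed = angular_speed(series, "yaw"),
         time = series$t,
         state = label_states(series)$labels)
}

render_data <- function(x, spec) {
  if (spec$mode == "dubai") {
    if (!inherits(x, "facet_histogram"))
      config_error("mode 'dubai' needs a facet_histogram")
    occ <- which(x$counts > 0)
    ang <- sphere_to_angles(x$facet_centers[occ, , drop = FALSE])
    return(data.frame(facet = occ, heading = ang$heading, pitch = ang$pitch,
                      count = x$counts[occ],
                      height = x$heights[occ]))
  }
  if (!inherits(x, "orientation_series"))
    config_error(sprintf("mode '%s' needs an orientation_series", spec$mode))
  if (!any(x$valid))
    hods_error("no valid samples to plot", "hods_empty_plot")
  v <- x$valid
  if (spec$mode == "planar") {
    return(data.frame(t = x$t[v], heading = x$heading[v], pitch = x$pitch[v]))
  }
  xyz <- to_sphere(x$heading[v], x$pitch[v])
  pr <- project_ortho(xyz, spec$view_azimuth, spec$view_elevation)
  col <- color_values(x, spec$color_by)
  d <- data.frame(t = x$t[v], heading = x$heading[v], pitch = x$pitch[v],
                  px = pr$px, py = pr$py, front = pr$front,
                  color = col[v])
  if (spec$mode == "time_radial") {
    dur <- diff(range(x$t))
    d$radius <- if (dur > 0) (x$t[v] - x$t[1]) / dur else rep(1, sum(v))
    d$px <- d$px * d$radius
    d$py <- d$py * d$radius
  }
  d
}

graticule_data <- function(az, el) {
  out <- list()
  for (lat in seq(-60, 60, by = 30)) {
    h <- seq(0, 360, by = 5)
    p <- project_ortho(to_sphere(h, rep(lat, length(h))), az, el)
    out[[length(out) + 1]] <- cbind(p, id = paste0("lat", lat))
  }
  for (lon in seq(0, 330, by = 30)) {
    pp <- seq(-90, 90, by = 5)
    p <- project_ortho(to_sphere(rep(lon, length(pp)), pp), az, el)
    out[[length(out) + 1]] <- cbind(p, id = paste0("lon", lon))
  }
  do.call(rbind, out)
}

#' Render an orientation-sphere figure
#'
#' Writes a static figure at `path` and the plotted numbers to a JSON
#' sidecar at `paste0(path, ".json")`. Sphere modes draw a 30-degree
#' graticule with N/E/S/W labels; Dubai mode draws radiating bars with
#' length proportional to the facet metric; time-radial mode spirals the
#' series outward with radius linear in time; planar mode panels heading
#' and pitch against time.
#'
#' @param x an `orientation_series`, or a `facet_histogram` for mode
#'   "dubai".
#' @param spec a [plot_spec()].
#' @param path output figure path (".png" or ".pdf").
#' @return the plotted data, invisibly.
#' @export
render <- function(x, spec = plot_spec(), path) {
  d <- render_data(x, spec)  # validates before any file is written
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(mode = spec$mode, color_by = spec$color_by,
                            radius_map = spec$radius_map, data = d),
                       sidecar, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  gg <- build_figure(d, spec)
  ggplot2::ggsave(path, gg, width = 7, height = 6, dpi = 120)
  invisible(d)
}

build_figure <- function(d, spec) {
  if (spec$mode == "planar") {
    long <- rbind(data.frame(t = d$t, value = d$heading, panel = "heading (deg)"),
                  data.frame(t = d$t, value = d$pitch, panel = "pitch (deg)"))
    return(ggplot2::ggplot(long, ggplot2::aes(x = t, y = value)) +
             ggplot2::geom_line(linewidth = 0.3) +
             ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
             ggplot2::labs(x = "time (s)") +
             ggplot2::theme_minimal())
  }
  if (spec$mode == "dubai") {
    # radiating bars: each occupied facet drawn as a lollipop from the
    # sphere surface outward, orthographic view
    xyz <- to_sphere(d$heading, d$pitch)
    pr <- project_ortho(xyz, 20, 25)
    len <- 0.5 * d$height / max(d$height)
    pt <- project_ortho(xyz * (1 + len), 20, 25)
    seg <- data.frame(x = pr$px, y = pr$py, xend = pt$px, yend = pt$py,
                      front = pr$front)
    return(ggplot2::ggplot() +
             base_sphere_layers() +
             ggplot2::geom_segment(
               data = seg[seg$front, ],
               ggplot2::aes(x = x, y = y, xend = xend, yend = yend),
               colour = "#c0392b", linewidth = 0.8) +
             ggplot2::coord_equal() + ggplot2::theme_void())
  }
  gg <- ggplot2::ggplot() + base_sphere_layers()
  if (spec$mode == "sphere_trajectory") {
    gg <- gg + ggplot2::geom_path(
      data = d[d$front, ], ggplot2::aes(x = px, y = py),
      linewidth = 0.3, colour = "grey40")
  }
  aes_col <- if (is.numeric(d$color)) ggplot2::aes(x = px, y = py,
                                                   colour = color)
  else ggplot2::aes(x = px, y = py, colour = factor(color))
  gg <- gg + ggplot2::geom_point(data = d[d$front, ], aes_col, size = 0.8)
  if (spec$color_by == "pitch" && is.numeric(d$color))
    gg <- gg + ggplot2::scale_colour_gradient2(low = "#2166ac",
                                               mid = "#f7f7f7",
                                               high = "#b2182b",
                                               midpoint = 0,
                                               name = "pitch (deg)")
  gg + ggplot2::coord_equal() + ggplot2::theme_void()
}

base_sphere_layers <- function(az = 20, el = 25) {
  grat <- graticule_data(az, el)
  lab_pts <- to_sphere(c(0, 90, 180, 270), rep(0, 4))
  lab <- cbind(project_ortho(lab_pts, az, el),
               txt = c("N", "E", "S", "W"))
  list(
    ggplot2::geom_path(data = grat[grat$front, ],
                       ggplot2::aes(x = px, y = py, group = id),
                       colour = "grey80", linewidth = 0.2),
    ggplot2::geom_text(data = lab[lab$front, ],
                       ggplot2::aes(x = px * 1.08, y = py * 1.08,
                                    label = txt),
                       size = 3, colour = "grey30"))
}
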