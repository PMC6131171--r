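#' Geometry configuration for Kanizsa stimulus generation
#'
#' All lengths are degrees of visual angle; the coordinate frame is
#' centre-origin with y up. Targets are Pac-Man inducer figures: a subjective
#' contour illusion (SCI) target has every inducer's mouth edges collinear
#' with the implied polygon's edges; a no-SCI target uses the same polygon and
#' inducers but rotates each inducer independently to disrupt collinearity.
#'
#' @param canvas_size Square canvas side, degrees.
#' @param circumradius_mean,circumradius_jitter Vertex distance from centre is
#'   uniform on mean +/- jitter, degrees.
#' @param angular_jitter Uniform jitter (+/- degrees) applied to the regular
#'   angular positions of the vertices.
#' @param inducer_radius Pac-Man disc radius, degrees.
#' @param interior_angle_bounds Named list with elements `"3"` and `"4"`:
#'   `[min, max]` interior-angle bounds in degrees for triangles and
#'   quadrilaterals.
#' @param nosci_rotation_bounds `[min, max]` magnitude in degrees of the
#'   per-inducer rotation used to break collinearity in no-SCI targets.
#' @param primer_segment_length Length of each primer line segment, degrees.
#' @param target_color,primer_color,background Ink colours.
#' @param max_retries Rejection-sampling cap for polygon generation.
#' @return A validated list of class `psicat_geometry_config`.
#' @export
geometry_config <- function(canvas_size = 10,
                            circumradius_mean = 3,
                            circumradius_jitter = 0.5,
                            angular_jitter = 20,
                            inducer_radius = 1,
                            interior_angle_bounds = list(`3` = c(30, 120),
                                                         `4` = c(50, 130)),
                            nosci_rotation_bounds = c(40, 140),
                            primer_segment_length = inducer_radius,
                            target_color = "white",
                            primer_color = "red",
                            background = "black",
                            max_retries = 1000) {
  cfg <- list(canvas_size = canvas_size,
              circumradius_mean = circumradius_mean,
              circumradius_jitter = circumradius_jitter,
              angular_jitter = angular_jitter,
              inducer_radius = inducer_radius,
              interior_angle_bounds = interior_angle_bounds,
              nosci_rotation_bounds = nosci_rotation_bounds,
              primer_segment_length = primer_segment_length,
              target_color = target_color,
              primer_color = primer_color,
              background = background,
              max_retries = max_retries)
  class(cfg) <- "psicat_geometry_config"
  validate_geometry_config(cfg)
  cfg
}

validate_geometry_config <- function(cfg) {
  for (nm in c("3", "4")) {
    b <- cfg$interior_angle_bounds[[nm]]
    if (is.null(b) || length(b) != 2) {
      stop("interior_angle_bounds must have elements '3' and '4' of length 2",
           call. = FALSE)
    }
    if (!(0 < b[1] && b[1] < b[2] && b[2] < 180)) {
      stop("interior angle bounds must satisfy 0 < min < max < 180",
           call. = FALSE)
    }
  }
  rb <- cfg$nosci_rotation_bounds
  if (!(rb[1] > 0 && rb[1] <= rb[2])) {
    stop("no-SCI rotation bounds must satisfy 0 < min <= max", call. = FALSE)
  }
  if (cfg$circumradius_mean <= cfg$circumradius_jitter) {
    stop("circumradius jitter must be smaller than its mean", call. = FALSE)
  }
  # inducers must not overlap: radius below half the smallest possible
  # inter-vertex chord (worst case: 4 vertices, maximal inward jitter)
  min_gap <- 360 / 4 - 2 * cfg$angular_jitter
  if (min_gap <= 0) stop("angular_jitter too large for 4-vertex stimuli",
                         call. = FALSE)
  min_chord <- 2 * (cfg$circumradius_mean - cfg$circumradius_jitter) *
    sin(deg2rad(min_gap / 2))
  if (cfg$inducer_radius >= min_chord / 2) {
    stop("inducer_radius must be below half the minimum inter-vertex distance (",
         signif(min_chord / 2, 3), " deg)", call. = FALSE)
  }
  invisible(cfg)
}

polygon_interior_angles <- function(xy) {
  n <- nrow(xy)
  vapply(seq_len(n), function(i) {
    p <- xy[if (i == 1) n else i - 1, ]
    v <- xy[i, ]
    nx <- xy[if (i == n) 1 else i + 1, ]
    u1 <- p - v
    u2 <- nx - v
    co <- sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))
    rad2deg(acos(pmin(pmax(co, -1), 1)))
  }, numeric(1))
}

polygon_is_convex <- function(xy) {
  n <- nrow(xy)
  cr <- vapply(seq_len(n), function(i) {
    a <- xy[i, ]
    b <- xy[if (i == n) 1 else i + 1, ]
    c <- xy[if (i >= n - 1) i + 2 - n else i + 2, ]
    (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
  }, numeric(1))
  all(cr > 0) || all(cr < 0)
}

#' Generate a constrained irregular polygon
#'
#' Vertices are placed at jittered angular positions on a jittered-radius
#' circle and the candidate is rejected and resampled until every interior
#' angle lies inside the configured bounds and the polygon is convex.
#' Identical `(config, seed)` pairs give identical polygons.
#'
#' @param n_vertices 3 or 4.
#' @param config A [geometry_config()].
#' @param seed Optional integer seed; if `NULL` the current RNG stream is used.
#' @return A list of class `psicat_polygon` with `n_vertices`, `vertices`
#'   (tibble of `x`, `y` in degrees) and `interior_angles` (degrees).
#' @export
generate_polygon <- function(n_vertices, config = geometry_config(),
                             seed = NULL) {
  stopifnot(n_vertices %in% c(3L, 4L))
  bounds <- config$interior_angle_bounds[[as.character(n_vertices)]]
  angle_sum <- (n_vertices - 2) * 180
  if (n_vertices * bounds[1] > angle_sum || n_vertices * bounds[2] < angle_sum) {
    stop("infeasible interior-angle bounds [", bounds[1], ", ", bounds[2],
         "] for n = ", n_vertices, " (angles must sum to ", angle_sum, ")",
         call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  base <- 90 + (seq_len(n_vertices) - 1) * 360 / n_vertices
  for (try in seq_len(config$max_retries)) {
    th <- base + stats::runif(n_vertices, -config$angular_jitter,
                              config$angular_jitter)
    r <- config$circumradius_mean +
      stats::runif(n_vertices, -config$circumradius_jitter,
                   config$circumradius_jitter)
    xy <- cbind(x = r * cos(deg2rad(th)), y = r * sin(deg2rad(th)))
    if (is.unsorted(th %% 360)) next   # keep angular order => simple polygon
    if (!polygon_is_convex(xy)) next
    ang <- polygon_interior_angles(xy)
    if (all(ang >= bounds[1] & ang <= bounds[2])) {
      out <- list(n_vertices = as.integer(n_vertices),
                  vertices = tibble::tibble(x = xy[, 1], y = xy[, 2]),
                  interior_angles = ang)
      class(out) <- "psicat_polygon"
      return(out)
    }
  }
  stop("could not satisfy interior-angle bounds in ", config$max_retries,
       " attempts; relax the configuration", call. = FALSE)
}

# per-vertex directions (degrees) of the two polygon edges leaving vertex i,
# ordered (toward previous, toward next)
vertex_edge_angles <- function(polygon) {
  xy <- as.matrix(polygon$vertices)
  n <- nrow(xy)
  t(vapply(seq_len(n), function(i) {
    p <- xy[if (i == 1) n else i - 1, ]
    v <- xy[i, ]
    nx <- xy[if (i == n) 1 else i + 1, ]
    c(rad2deg(atan2(p[2] - v[2], p[1] - v[1])),
      rad2deg(atan2(nx[2] - v[2], nx[1] - v[1])))
  }, numeric(2)))
}

#' Build an SCI or no-SCI Pac-Man target from a polygon
#'
#' Places one Pac-Man inducer at every vertex: a disc with a wedge (mouth)
#' removed whose opening angle equals the interior angle at that vertex. For
#' the SCI class the mouth edges are exactly collinear with the polygon edges
#' meeting at the vertex; for the no-SCI class each inducer is independently
#' rotated by a magnitude drawn uniformly from the configured bounds with a
#' random sign. Inducer centres and radii are identical across classes, so
#' low-level ink area is matched by construction.
#'
#' @param polygon A [generate_polygon()] result.
#' @param target_class `"SCI"` or `"noSCI"`.
#' @param config A [geometry_config()].
#' @param seed Optional integer seed for the no-SCI rotations.
#' @return A list of class `psicat_target` with `stimulus_id`, `target_class`,
#'   `polygon` and an `inducers` tibble (`vertex`, `cx`, `cy`, `radius`,
#'   `mouth_angle`, `mouth_orientation`, `rotation_offset`, all degrees).
#' @export
make_target <- function(polygon, target_class = c("SCI", "noSCI"),
                        config = geometry_config(), seed = NULL) {
  target_class <- match.arg(target_class)
  if (!is.null(seed)) withr::local_seed(seed)
  ea <- vertex_edge_angles(polygon)
  n <- polygon$n_vertices
  # interior bisector: mean direction of the two unit edge vectors
  bis <- rad2deg(atan2(sin(deg2rad(ea[, 1])) + sin(deg2rad(ea[, 2])),
                       cos(deg2rad(ea[, 1])) + cos(deg2rad(ea[, 2]))))
  offset <- if (target_class == "SCI") {
    rep(0, n)
  } else {
    stats::runif(n, config$nosci_rotation_bounds[1],
                 config$nosci_rotation_bounds[2]) *
      sample(c(-1, 1), n, replace = TRUE)
  }
  inducers <- tibble::tibble(
    vertex = seq_len(n),
    cx = polygon$vertices$x,
    cy = polygon$vertices$y,
    radius = config$inducer_radius,
    mouth_angle = polygon$interior_angles,
    mouth_orientation = (bis + offset) %% 360,
    rotation_offset = offset
  )
  out <- list(stimulus_id = NA_character_,
              target_class = target_class,
              polygon = polygon,
              inducers = inducers)
  out$stimulus_id <- paste0("tgt-", substr(rlang::hash(out[-1]), 1, 12))
  class(out) <- "psicat_target"
  out
}

# realized mouth-edge directions (degrees), two per inducer
mouth_edge_angles <- function(target) {
  with(target$inducers,
       cbind((mouth_orientation - mouth_angle / 2) %% 360,
             (mouth_orientation + mouth_angle / 2) %% 360))
}

#' Measure per-inducer deviation from collinearity
#'
#' Re-measures, from the emitted geometry, the angular deviation between each
#' inducer's realized mouth edges and the polygon edges meeting at its vertex.
#' Zero (to numerical precision) for SCI targets; within the configured no-SCI
#' rotation bounds for no-SCI targets.
#'
#' @param target A [make_target()] result.
#' @return Numeric vector, one absolute deviation (degrees) per vertex.
#' @export
measure_rotation_offsets <- function(target) {
  me <- mouth_edge_angles(target)
  ea <- vertex_edge_angles(target$polygon)
  vapply(seq_len(nrow(me)), function(i) {
    # match edges in the orientation-preserving order and take the common
    # rotation magnitude
    d1 <- ang_diff(me[i, 1], ea[i, 1])
    d2 <- ang_diff(me[i, 1], ea[i, 2])
    min(max(d1, ang_diff(me[i, 2], ea[i, 2])),
        max(d2, ang_diff(me[i, 2], ea[i, 1])))
  }, numeric(1))
}

#' Build a congruent or incongruent line primer for a target
#'
#' A primer is an angle figure: at every vertex, two thin line segments share
#' an endpoint at the vertex. A congruent primer traces the target's own
#' realized mouth edges. An incongruent primer traces the mouth edges of the
#' opposite-class target built from the same polygon (the no-SCI twin of an
#' SCI target and vice versa), so that incongruent primers reinforce the
#' opposite class.
#'
#' @param target A [make_target()] result.
#' @param congruency `"con"` or `"inc"`.
#' @param config A [geometry_config()].
#' @param seed Seed for the opposite-class twin's rotations (incongruent only).
#' @return A list of class `psicat_primer` with `primer_id`, `congruency`,
#'   `source_target_id` and a `segments` tibble (`vertex`, `seg`, `x0`, `y0`,
#'   `x1`, `y1`, `angle`).
#' @export
make_primer <- function(target, congruency = c("con", "inc"),
                        config = geometry_config(), seed = NULL) {
  congruency <- match.arg(congruency)
  source <- if (congruency == "con") {
    target
  } else {
    twin_class <- if (target$target_class == "SCI") "noSCI" else "SCI"
    make_target(target$polygon, twin_class, config, seed = seed)
  }
  me <- mouth_edge_angles(source)
  n <- nrow(me)
  L <- config$primer_segment_length
  segments <- tibble::tibble(
    vertex = rep(seq_len(n), each = 2),
    seg = rep(1:2, times = n),
    angle = as.vector(t(me))
  )
  vx <- target$polygon$vertices$x[segments$vertex]
  vy <- target$polygon$vertices$y[segments$vertex]
  segments$x0 <- vx
  segments$y0 <- vy
  segments$x1 <- vx + L * cos(deg2rad(segments$angle))
  segments$y1 <- vy + L * sin(deg2rad(segments$angle))
  out <- list(primer_id = NA_character_,
              congruency = congruency,
              source_target_id = target$stimulus_id,
              segments = segments)
  out$primer_id <- paste0("pri-", substr(rlang::hash(out[-1]), 1, 12))
  class(out) <- "psicat_primer"
  out
}

#' Measure primer orientation deviation from a target
#'
#' Per vertex, the angular deviation between the primer's realized segment
#' pair and the target's mouth edges (best orientation-preserving matching).
#'
#' @param primer A [make_primer()] result.
#' @param target The target to compare against.
#' @return Numeric vector of deviations (degrees), one per vertex.
#' @export
measure_primer_deviation <- function(primer, target) {
  me <- mouth_edge_angles(target)
  vapply(seq_len(nrow(me)), function(i) {
    segs <- primer$segments[primer$segments$vertex == i, ]
    d1 <- ang_diff(segs$angle[1], me[i, 1])
    d2 <- ang_diff(segs$angle[1], me[i, 2])
    min(max(d1, ang_diff(segs$angle[2], me[i, 2])),
        max(d2, ang_diff(segs$angle[2], me[i, 1])))
  }, numeric(1))
}
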