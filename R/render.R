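#' Rasterize a stimulus to an intensity matrix
#'
#' Deterministic rasterization in the stimulus coordinate frame (degrees of
#' visual angle, centre origin, y up; pixel row 1 is the top of the canvas).
#' Targets paint Pac-Man inducers (disc minus mouth wedge); primers paint thin
#' line segments. With `antialias = FALSE` every pixel is 0 or 1 by a
#' centre-point test; with `antialias = TRUE` a 3x3 supersample is averaged.
#'
#' @param stimulus A `psicat_target` or `psicat_primer`.
#' @param pixels_per_degree Raster resolution, > 0.
#' @param canvas_size Canvas side in degrees.
#' @param antialias Logical.
#' @param line_width Primer line width, degrees.
#' @return Numeric matrix (rows x cols) of ink intensity in `[0, 1]`, with
#'   attributes `ink` (colour name) and `pixels_per_degree`.
#' @export
render_raster <- function(stimulus, pixels_per_degree = 32, canvas_size = 10,
                          antialias = FALSE, line_width = 0.08) {
  if (pixels_per_degree <= 0) stop("pixels_per_degree must be > 0",
                                   call. = FALSE)
  npx <- round(canvas_size * pixels_per_degree)
  sub <- if (antialias) c(-1, 0, 1) / 3 else 0
  img <- matrix(0, npx, npx)
  for (dx in sub) {
    for (dy in sub) {
      px <- ((seq_len(npx) - 0.5 + dx) / pixels_per_degree) - canvas_size / 2
      py <- canvas_size / 2 - ((seq_len(npx) - 0.5 + dy) / pixels_per_degree)
      gx <- matrix(px, npx, npx, byrow = TRUE)
      gy <- matrix(py, npx, npx)
      img <- img + rasterize_ink(stimulus, gx, gy, line_width)
    }
  }
  img <- img / length(sub)^2
  attr(img, "ink") <- if (inherits(stimulus, "psicat_primer")) "red" else "white"
  attr(img, "pixels_per_degree") <- pixels_per_degree
  img
}

rasterize_ink <- function(stimulus, gx, gy, line_width) {
  mask <- matrix(FALSE, nrow(gx), ncol(gx))
  if (inherits(stimulus, "psicat_target")) {
    ind <- stimulus$inducers
    for (i in seq_len(nrow(ind))) {
      dx <- gx - ind$cx[i]
      dy <- gy - ind$cy[i]
      in_disc <- dx^2 + dy^2 <= ind$radius[i]^2
      phi <- rad2deg(atan2(dy, dx))
      in_mouth <- ang_diff(phi, ind$mouth_orientation[i]) <
        ind$mouth_angle[i] / 2
      mask <- mask | (in_disc & !in_mouth)
    }
  } else if (inherits(stimulus, "psicat_primer")) {
    segs <- stimulus$segments
    for (i in seq_len(nrow(segs))) {
      ax <- segs$x0[i]; ay <- segs$y0[i]
      bx <- segs$x1[i]; by <- segs$y1[i]
      vx <- bx - ax; vy <- by - ay
      len2 <- vx^2 + vy^2
      t <- pmin(pmax(((gx - ax) * vx + (gy - ay) * vy) / len2, 0), 1)
      d2 <- (gx - (ax + t * vx))^2 + (gy - (ay + t * vy))^2
      mask <- mask | (d2 <= (line_width / 2)^2)
    }
  } else {
    stop("unsupported stimulus type", call. = FALSE)
  }
  mask * 1
}

#' Write a stimulus raster as PNG
#'
#' White-on-black ink for targets, red-on-black for primers.
#'
#' @inheritParams render_raster
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(stimulus, path, pixels_per_degree = 32,
                               canvas_size = 10, antialias = FALSE) {
  img <- render_raster(stimulus, pixels_per_degree, canvas_size, antialias)
  rgb <- array(0, dim = c(nrow(img), ncol(img), 3))
  if (attr(img, "ink") == "red") {
    rgb[, , 1] <- img
  } else {
    rgb[, , 1] <- img; rgb[, , 2] <- img; rgb[, , 3] <- img
  }
  png::writePNG(rgb, target = path)
  invisible(path)
}

svg_num <- function(x) formatC(x, format = "f", digits = 5)

#' Write a stimulus as SVG
#'
#' Vector form of the same geometry the rasterizer paints: Pac-Man inducers as
#' disc-minus-wedge paths, primers as stroked line segments. Coordinates are
#' degrees of visual angle; the y axis is flipped into SVG screen convention.
#'
#' @inheritParams render_raster
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stimulus_svg <- function(stimulus, path, canvas_size = 10,
                               line_width = 0.08) {
  half <- canvas_size / 2
  header <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="%s %s %s %s">',
            svg_num(-half), svg_num(-half), svg_num(canvas_size),
            svg_num(canvas_size)),
    sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="black"/>',
            svg_num(-half), svg_num(-half), svg_num(canvas_size),
            svg_num(canvas_size)),
    '<g transform="scale(1,-1)">'
  )
  body <- if (inherits(stimulus, "psicat_target")) {
    ind <- stimulus$inducers
    vapply(seq_len(nrow(ind)), function(i) {
      r <- ind$radius[i]
      a1 <- deg2rad(ind$mouth_orientation[i] + ind$mouth_angle[i] / 2)
      a2 <- deg2rad(ind$mouth_orientation[i] - ind$mouth_angle[i] / 2)
      # visible disc spans from a1 counterclockwise round to a2
      sprintf('<path d="M %s %s L %s %s A %s %s 0 1 1 %s %s Z" fill="white"/>',
              svg_num(ind$cx[i]), svg_num(ind$cy[i]),
              svg_num(ind$cx[i] + r * cos(a1)), svg_num(ind$cy[i] + r * sin(a1)),
              svg_num(r), svg_num(r),
              svg_num(ind$cx[i] + r * cos(a2)), svg_num(ind$cy[i] + r * sin(a2)))
    }, character(1))
  } else {
    segs <- stimulus$segments
    vapply(seq_len(nrow(segs)), function(i) {
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="red" stroke-width="%s" stroke-linecap="round"/>',
              svg_num(segs$x0[i]), svg_num(segs$y0[i]),
              svg_num(segs$x1[i]), svg_num(segs$y1[i]), svg_num(line_width))
    }, character(1))
  }
  writeLines(c(header, body, "</g>", "</svg>"), path)
  invisible(path)
}

#' Generate a batch of stimuli with a manifest
#'
#' Builds `n` fresh polygon/target/primer sets (one target and its primer per
#' row of the manifest), writes SVG and/or PNG files, and records a JSON
#' manifest mapping stimulus ids to files, classes, and seeds.
#'
#' @param n Number of target/primer pairs.
#' @param config A [geometry_config()].
#' @param seed Integer seed; the whole batch is a pure function of it.
#' @param outdir Output directory (created if missing).
#' @param formats Subset of `c("svg", "png")`.
#' @param pixels_per_degree Raster resolution for PNG output.
#' @return The manifest as a tibble, invisibly; also written as
#'   `manifest.json` in `outdir`.
#' @export
gen_stimuli <- function(n, config = geometry_config(), seed = 1,
                        outdir = ".", formats = c("svg", "png"),
                        pixels_per_degree = 32) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  # cycle the cells with congruency alternating so small batches cover both
  cells <- condition_cells()[c(1, 5, 2, 6, 3, 7, 4, 8), ]
  rows <- purrr::map(seq_len(n), function(i) {
    cell <- cells[((i - 1) %% nrow(cells)) + 1, ]
    s <- derive_seed(seed, i)
    poly <- generate_polygon(cell$n_vertices, config, seed = s)
    tgt <- make_target(poly, cell$target_class, config,
                       seed = derive_seed(s, 1))
    pri <- make_primer(tgt, cell$congruency, config,
                       seed = derive_seed(s, 2))
    files <- character(0)
    for (stim in list(tgt = tgt, pri = pri)) {
      id <- if (inherits(stim, "psicat_target")) stim$stimulus_id else stim$primer_id
      if ("svg" %in% formats) {
        f <- file.path(outdir, paste0(id, ".svg"))
        write_stimulus_svg(stim, f, config$canvas_size)
        files <- c(files, f)
      }
      if ("png" %in% formats) {
        f <- file.path(outdir, paste0(id, ".png"))
        write_stimulus_png(stim, f, pixels_per_degree, config$canvas_size)
        files <- c(files, f)
      }
    }
    tibble::tibble(index = i, target_id = tgt$stimulus_id,
                   primer_id = pri$primer_id,
                   target_class = cell$target_class,
                   congruency = cell$congruency,
                   n_vertices = cell$n_vertices, seed = s,
                   files = list(files))
  })
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
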