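#' Biosemi-128 montage labels and synthetic scalp positions
#'
#' Returns the 128 Biosemi ABCD channel labels (A1--A32, B1--B32, C1--C32,
#' D1--D32) together with 2-D projected and 3-D unit-sphere coordinates.
#' Labels are the exact Biosemi set; the coordinates are a synthetic
#' approximate layout built in code (anchored so the analysis regions of
#' interest sit in the right scalp neighbourhoods: A1 at the vertex, C19--C21
#' on the anterior midline, A19 centro-parietal, A23 occipital). Positions are
#' used only for topography falloff in the simulator and for plotting, never
#' for inference.
#'
#' @return A tibble with columns `label`, `x`, `y` (2-D head-top projection,
#'   nose up, +y anterior, unit head radius) and `x3`, `y3`, `z3` (unit
#'   sphere).
#' @export
biosemi128_montage <- function() {
  labels <- paste0(rep(c("A", "B", "C", "D"), each = 32), rep(1:32, times = 4))

  # anchor the channels any ROI refers to, plus a few named landmarks
  anchors <- tibble::tribble(
    ~label, ~x,     ~y,
    "A1",    0.00,   0.00,   # vertex (Cz)
    "A2",    0.00,  -0.12,
    "B1",    0.12,   0.00,
    "C1",    0.00,   0.12,
    "D1",   -0.12,   0.00,
    "D15",  -0.12,  -0.10,
    "A19",   0.00,  -0.38,   # Pz
    "A4",   -0.10,  -0.30,
    "A5",   -0.12,  -0.44,
    "A20",   0.12,  -0.44,
    "A32",   0.10,  -0.30,
    "A23",   0.00,  -0.78,   # Oz
    "A15",  -0.14,  -0.72,
    "A22",  -0.08,  -0.64,
    "A24",   0.08,  -0.64,
    "A28",   0.14,  -0.72,
    "C19",   0.07,   0.34,
    "C20",   0.00,   0.42,   # Fz
    "C21",  -0.07,   0.50
  )

  pos <- matrix(NA_real_, nrow = 128, ncol = 2,
                dimnames = list(labels, c("x", "y")))
  pos[anchors$label, ] <- cbind(anchors$x, anchors$y)

  # distribute the remaining channels on concentric rings, deterministic order
  remaining <- labels[!labels %in% anchors$label]
  rings <- list(c(r = 0.25, n = 14), c(r = 0.48, n = 22),
                c(r = 0.68, n = 30), c(r = 0.88, n = 43))
  ring_pts <- purrr::map(rings, function(rg) {
    th <- seq(0, 2 * pi, length.out = rg[["n"]] + 1)[-1] + 0.1
    cbind(x = rg[["r"]] * sin(th), y = rg[["r"]] * cos(th))
  })
  ring_pts <- do.call(rbind, ring_pts)
  stopifnot(nrow(ring_pts) >= length(remaining))
  pos[remaining, ] <- ring_pts[seq_along(remaining), ]

  r <- pmin(sqrt(pos[, 1]^2 + pos[, 2]^2), 1)
  theta <- r * pi / 2           # 0 at vertex, pi/2 at equator
  phi <- atan2(pos[, 2], pos[, 1])
  tibble::tibble(
    label = labels,
    x = pos[, 1], y = pos[, 2],
    x3 = sin(theta) * cos(phi),
    y3 = sin(theta) * sin(phi),
    z3 = cos(theta)
  )
}

#' Reduced 20-channel montage for fast pipelines
#'
#' Subsets the full montage to the 19 channels any analysis region of interest
#' uses, plus one non-ROI control channel (B20). All downstream analyses run
#' identically on the full and reduced montages.
#'
#' @return A tibble, subset of [biosemi128_montage()].
#' @export
reduced_montage <- function() {
  keep <- c(unique(unlist(roi_definitions()$channels)), "B20")
  m <- biosemi128_montage()
  m[match(keep, m$label), ]
}

#' Analysis regions of interest
#'
#' The four scalp regions used by the ERP and spectral analyses: a vertex ROI
#' for P3a, a centro-parietal ROI for P3b, an occipital ROI for visual N1, and
#' a fronto-medial ROI for theta-band dynamics.
#'
#' @return A tibble with columns `roi` and `channels` (list column of labels).
#' @export
roi_definitions <- function() {
  tibble::tibble(
    roi = c("vertex", "parietal", "occipital", "frontomedial"),
    channels = list(
      c("A1", "A2", "B1", "C1", "D1", "D15"),
      c("A19", "A4", "A5", "A20", "A32"),
      c("A23", "A15", "A22", "A24", "A28"),
      c("C19", "C20", "C21")
    )
  )
}

#' Channel labels for one ROI
#' @param roi One of "vertex", "parietal", "occipital", "frontomedial".
#' @return Character vector of channel labels.
#' @export
roi_channels <- function(roi) {
  defs <- roi_definitions()
  i <- match(roi, defs$roi)
  if (is.na(i)) {
    stop("unknown ROI '", roi, "'; expected one of: ",
         paste(defs$roi, collapse = ", "), call. = FALSE)
  }
  defs$channels[[i]]
}
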