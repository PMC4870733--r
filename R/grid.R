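# Calibration grid: four stacked bead plates spanning the imaging volume.

#' Calibration grid specification
#'
#' Four 80 mm square plates stacked 30 mm apart along y (the coil bore), each
#' carrying a centred 4x4 array of 2 mm water beads on a 20 mm pitch. Three
#' additional axis beads on the first two plates break the 4-fold symmetry of
#' the lattice and define the grid axes: plate 0 carries an x-marker 8 mm off
#' the corner bead along -x and a z-marker 6 mm off along -z; plate 1 carries
#' the x-marker only.
#'
#' @param n_plates number of plates.
#' @param beads_per_side beads per row/column (4 gives the 4x4 array).
#' @param bead_spacing lattice pitch, mm.
#' @param plate_spacing distance between adjacent plates, mm.
#' @param bead_diameter bead diameter, mm.
#' @param plate_side plate edge length, mm.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(n_plates = 4, beads_per_side = 4, bead_spacing = 20,
                      plate_spacing = 30, bead_diameter = 2, plate_side = 80) {
  extent <- (beads_per_side - 1) * bead_spacing
  if (extent >= plate_side)
    stop_mrikin("bead array does not fit within the plate", "mrikin_param_error")
  structure(list(n_plates = n_plates, beads_per_side = beads_per_side,
                 bead_spacing = bead_spacing, plate_spacing = plate_spacing,
                 bead_diameter = bead_diameter, plate_side = plate_side),
            class = "grid_spec")
}

# Offsets of the three axis beads relative to the (-,-) corner bead of their
# plate, in the plate plane (x, z), and which plate carries each.
axis_bead_table <- function(spec) {
  data.frame(label = c("AX0", "AZ0", "AX1"),
             plate = c(0L, 0L, 1L),
             dx = c(-8, 0, -8),
             dz = c(0, -6, 0))
}

#' World coordinates of every grid bead
#'
#' The lattice is centred on the plate; plate p lies at y = p * plate_spacing.
#' This labelled table is the "framespec" ground truth used as calibration
#' control points.
#'
#' @param spec a `grid_spec`.
#' @return data.frame with columns `label`, `plate`, `row`, `col`, `x`, `y`,
#'   `z`, `axis_bead`. Rows and columns index the lattice along x and z; the
#'   axis beads carry `row = col = NA`.
#' @export
grid_bead_coordinates <- function(spec = grid_spec()) {
  k <- spec$beads_per_side
  off <- (seq_len(k) - 1 - (k - 1) / 2) * spec$bead_spacing
  out <- list()
  for (p in seq_len(spec$n_plates) - 1L) {
    g <- expand.grid(row = seq_len(k) - 1L, col = seq_len(k) - 1L)
    out[[p + 1]] <- data.frame(
      label = sprintf("P%d_%d%d", p, g$row, g$col),
      plate = p, row = g$row, col = g$col,
      x = off[g$row + 1], y = p * spec$plate_spacing, z = off[g$col + 1],
      axis_bead = FALSE)
  }
  beads <- do.call(rbind, out)
  corner <- c(off[1], off[1])  # (-,-) corner of the lattice
  ax <- axis_bead_table(spec)
  ax_rows <- data.frame(label = ax$label, plate = ax$plate,
                        row = NA_integer_, col = NA_integer_,
                        x = corner[1] + ax$dx,
                        y = ax$plate * spec$plate_spacing,
                        z = corner[2] + ax$dz,
                        axis_bead = TRUE)
  keep <- ax_rows$plate < spec$n_plates
  rbind(beads, ax_rows[keep, ])
}
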