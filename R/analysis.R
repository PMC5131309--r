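# Post-processing metrics: regional percent-volume of thrombus, axial
# burden distribution, wall thrombus thickness, Damkohler diagnostics.
# All metrics are pure functions of their input fields.

#' Percentage of a region's fluid volume occupied by thrombus
#'
#' `100 * sum(phi * V_cell) / (phi_max * sum(V_cell))` over the masked
#' cells: the volume-weighted occupancy of the deposited-platelet bed
#' relative to its packing limit.
#'
#' @param phi volume-fraction matrix (`nx` x `ny`).
#' @param mask logical matrix selecting the region (FLUID cells only).
#' @param phi_max packing limit.
#' @param grid optional [grid2d] used to verify the mask covers only
#'   FLUID cells.
#' @return Percentage in \[0, 100\].
#' @export
regional_thrombus_percent <- function(phi, mask, phi_max, grid = NULL) {
  if (!any(mask)) stop("empty region mask")
  if (!is.null(grid) &&
      any(mask & grid$cell_type != CELL_TYPES[["FLUID"]]))
    stop("mask must cover only FLUID cells")
  100 * sum(phi[mask]) / (phi_max * sum(mask))
}

#' Axial distribution of thrombus burden
#'
#' For every x-column of cells, the percentage of the local fluid
#' volume occupied by thrombus.
#'
#' @param phi volume-fraction matrix.
#' @param grid a [grid2d].
#' @param phi_max packing limit.
#' @return data.frame with `x` (station center, m), `percent`, and
#'   `n_fluid` (fluid cells in the column; `percent` is `NA` where the
#'   column has no fluid).
#' @export
axial_thrombus_distribution <- function(phi, grid, phi_max) {
  fluid <- grid$cell_type == CELL_TYPES[["FLUID"]]
  n_fluid <- rowSums(fluid)
  tot <- rowSums(phi * fluid)
  pct <- ifelse(n_fluid > 0, 100 * tot / (phi_max * pmax(n_fluid, 1)), NA_real_)
  data.frame(x = grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$dx,
             percent = pct, n_fluid = n_fluid)
}

#' Thrombus thickness along a wall
#'
#' At each x station, the contiguous wall-normal extent of cells with
#' `phi >= threshold * phi_max`, measured from the wall (m).
#'
#' @param phi volume-fraction matrix.
#' @param grid a [grid2d].
#' @param wall `"bottom"` or `"top"`.
#' @param threshold fraction of `phi_max` in (0, 1] counting as solid
#'   thrombus.
#' @param phi_max packing limit.
#' @return data.frame with `x` and `thickness` (m).
#' @export
thrombus_thickness_profile <- function(phi, grid, wall = "bottom",
                                       threshold = 0.5, phi_max = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  wall <- match.arg(wall, c("bottom", "top"))
  fluid <- grid$cell_type == CELL_TYPES[["FLUID"]]
  above <- phi >= threshold * phi_max & fluid
  thick <- numeric(grid$nx)
  jseq <- if (wall == "bottom") seq_len(grid$ny) else rev(seq_len(grid$ny))
  for (i in seq_len(grid$nx)) {
    n <- 0L
    started <- FALSE
    for (j in jseq) {
      if (!fluid[i, j]) {
        if (started) break else next    # skip the solid wall slab itself
      }
      started <- TRUE
      if (above[i, j]) n <- n + 1L else break
    }
    thick[i] <- n * grid$dy
  }
  data.frame(x = grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$dx,
             thickness = thick)
}

#' Damkohler number
#'
#' Ratio of reaction to transport rate: `Da = k*L/U` for a bulk
#' (volumetric, 1/s) rate constant, or `Da = k_s*L/D` for a surface
#' (m/s) rate constant against diffusive supply.  Large values mean the
#' species field, not the kinetics, limits deposition -- the regime that
#' justifies compressing reaction time by the chi factor.
#'
#' @param k rate constant (1/s for `kind = "bulk"`, m/s for
#'   `kind = "surface"`).
#' @param L characteristic length (m).
#' @param U characteristic velocity (m/s), for the bulk convention.
#' @param D diffusivity (m^2/s), for the surface convention.
#' @param kind `"bulk"` or `"surface"`.
#' @return Dimensionless Damkohler number.
#' @export
damkohler_number <- function(k, L, U = NULL, D = NULL, kind = "bulk") {
  kind <- match.arg(kind, c("bulk", "surface"))
  stopifnot(k > 0, L > 0)
  if (kind == "bulk") {
    stopifnot(!is.null(U), U > 0)
    k * L / U
  } else {
    stopifnot(!is.null(D), D > 0)
    k * L / D
  }
}

#' Named region masks for a scenario grid
#'
#' Surrogate analogues of the burden-reporting regions: for the crevice
#' channel, `crevice` (the cavity) and `channel`; for the
#' backward-facing step, `recirculation` (downstream of the step, below
#' the inlet-section floor level) and `channel`; for a plain channel,
#' `channel`.  All masks cover only FLUID cells.
#'
#' @param grid a [grid2d] built by one of the geometry presets.
#' @return Named list of logical matrices.
#' @export
region_masks <- function(grid) {
  fluid <- grid$cell_type == CELL_TYPES[["FLUID"]]
  meta <- grid$meta
  if (is.null(meta)) return(list(all = fluid))
  switch(meta$preset,
         crevice_channel = {
           cav <- matrix(FALSE, grid$nx, grid$ny)
           cav[meta$i_cav[1]:meta$i_cav[2], seq_len(meta$ny_cav)] <- TRUE
           cav <- cav & fluid
           list(crevice = cav, channel = fluid & !cav)
         },
         backward_facing_step = {
           rec <- matrix(FALSE, grid$nx, grid$ny)
           rec[(meta$n_step_x + 1L):grid$nx, seq_len(meta$n_step_y)] <- TRUE
           rec <- rec & fluid
           list(recirculation = rec, channel = fluid & !rec)
         },
         list(channel = fluid))
}
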