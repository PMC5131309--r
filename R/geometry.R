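# Structured Cartesian grids with stair-step walls.  Cells are square
# (dx == dy) and indexed [ix, iy] with x increasing streamwise and y
# increasing upward; face normals point out of the FLUID cell; unit depth
# (1 m) out of plane.

#' Cell type codes used in `grid2d` objects
#'
#' Integer codes stored in the `cell_type` matrix of a [grid2d] object:
#' `FLUID = 0`, `SOLID = 1`, `INLET = 2`, `OUTLET = 3`.
#'
#' @format A named integer vector of length 4.
#' @export
CELL_TYPES <- c(FLUID = 0L, SOLID = 1L, INLET = 2L, OUTLET = 3L)

# side order used everywhere a per-side array appears
SIDES <- c("xm", "xp", "ym", "yp")
SIDE_OFFSETS <- matrix(c(-1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L),
                       nrow = 4L, byrow = TRUE,
                       dimnames = list(SIDES, c("di", "dj")))

#' Construct a structured 2D grid
#'
#' Low-level constructor; most users should call one of the geometry
#' presets ([build_channel()], [build_backward_facing_step()],
#' [build_crevice_channel()]) instead.
#'
#' @param cell_type integer matrix of dim `c(nx, ny)` with entries from
#'   [CELL_TYPES].
#' @param dx,dy cell spacing (m), must be positive.
#' @param reactive logical array of dim `c(nx, ny, 4)` flagging reactive
#'   (platelet-adhesive) wall faces per cell side in the order
#'   `xm, xp, ym, yp`; `NULL` means no reactive faces.
#' @param origin numeric length-2, coordinates (m) of the lower-left
#'   corner of cell `[1, 1]`.
#' @return An object of class `grid2d`.
#' @export
grid2d <- function(cell_type, dx, dy, reactive = NULL, origin = c(0, 0)) {
  if (!is.matrix(cell_type) || !is.numeric(cell_type))
    stop("cell_type must be an integer matrix")
  nx <- nrow(cell_type); ny <- ncol(cell_type)
  if (nx < 4L || ny < 4L) stop("grid must be at least 4x4 cells")
  if (!is.numeric(dx) || length(dx) != 1L || !is.finite(dx) || dx <= 0)
    stop("dx must be a positive number")
  if (!is.numeric(dy) || length(dy) != 1L || !is.finite(dy) || dy <= 0)
    stop("dy must be a positive number")
  storage.mode(cell_type) <- "integer"
  if (!all(cell_type %in% CELL_TYPES)) stop("unknown cell type code")
  if (is.null(reactive)) reactive <- array(FALSE, dim = c(nx, ny, 4L))
  if (!identical(dim(reactive), c(nx, ny, 4L)))
    stop("reactive must have dim c(nx, ny, 4)")
  g <- structure(list(nx = nx, ny = ny, dx = dx, dy = dy,
                      cell_type = cell_type,
                      reactive = reactive,
                      origin = as.numeric(origin)),
                 class = "grid2d")
  validate_grid(g)
  g
}

# neighbour cell type with domain boundary treated as SOLID wall
.neighbor_type <- function(ct, ix, iy, side) {
  di <- SIDE_OFFSETS[side, 1L]; dj <- SIDE_OFFSETS[side, 2L]
  i <- ix + di; j <- iy + dj
  nx <- nrow(ct); ny <- ncol(ct)
  out <- rep(CELL_TYPES[["SOLID"]], length(ix))
  ok <- i >= 1L & i <= nx & j >= 1L & j <= ny
  out[ok] <- ct[cbind(i[ok], j[ok])]
  out
}

#' Validate the invariants of a grid
#'
#' Checks the cell-type partition, that reactive flags sit only on wall
#' faces (FLUID--SOLID interfaces or domain boundary), and that in open
#' domains every FLUID cell is 4-connected (through FLUID cells) to at
#' least one INLET and one OUTLET cell.  Closed boxes (no INLET/OUTLET
#' cells at all) are accepted as test domains.
#'
#' @param grid a [grid2d] object.
#' @return `grid`, invisibly; errors if an invariant is violated.
#' @export
validate_grid <- function(grid) {
  ct <- grid$cell_type
  n_in <- sum(ct == CELL_TYPES[["INLET"]])
  n_out <- sum(ct == CELL_TYPES[["OUTLET"]])
  if (xor(n_in > 0L, n_out > 0L))
    stop("grid must have both INLET and OUTLET cells, or neither")
  fluid <- ct == CELL_TYPES[["FLUID"]]
  if (!any(fluid)) stop("grid has no FLUID cells")
  # reactive flags only on wall faces
  idx <- which(fluid, arr.ind = TRUE)
  for (s in 1:4) {
    flagged <- grid$reactive[, , s]
    if (!any(flagged)) next
    fi <- which(flagged, arr.ind = TRUE)
    if (any(ct[fi] != CELL_TYPES[["FLUID"]]))
      stop("reactive faces must belong to FLUID cells")
    nt <- .neighbor_type(ct, fi[, 1L], fi[, 2L], SIDES[s])
    if (any(nt != CELL_TYPES[["SOLID"]]))
      stop("reactive faces must lie on FLUID-SOLID or domain-boundary walls")
  }
  if (n_in > 0L) {
    reach_in <- .flood_from(ct, CELL_TYPES[["INLET"]])
    reach_out <- .flood_from(ct, CELL_TYPES[["OUTLET"]])
    if (any(fluid & !reach_in))
      stop("some FLUID cells are not connected to an INLET")
    if (any(fluid & !reach_out))
      stop("some FLUID cells are not connected to an OUTLET")
  }
  invisible(grid)
}

# flood fill through FLUID cells starting from all cells of type `seed`
.flood_from <- function(ct, seed) {
  nx <- nrow(ct); ny <- ncol(ct)
  reached <- matrix(FALSE, nx, ny)
  fluid <- ct == CELL_TYPES[["FLUID"]]
  frontier <- which(ct == seed)
  while (length(frontier)) {
    i <- (frontier - 1L) %% nx + 1L
    j <- (frontier - 1L) %/% nx + 1L
    nbr <- integer(0)
    for (s in 1:4) {
      ii <- i + SIDE_OFFSETS[s, 1L]; jj <- j + SIDE_OFFSETS[s, 2L]
      ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
      lin <- (jj[ok] - 1L) * nx + ii[ok]
      lin <- lin[fluid[lin] & !reached[lin]]
      nbr <- c(nbr, lin)
    }
    nbr <- unique(nbr)
    reached[nbr] <- TRUE
    frontier <- nbr
  }
  reached
}

#' Straight channel grid
#'
#' Rectangular channel of the given length and height.  The left column
#' is tagged INLET, the right column OUTLET; top and bottom walls are
#' reactive (platelet-adhesive) by default.  Cells are square with
#' `dy = height / n_across`.
#'
#' @param length,height channel dimensions (m).
#' @param n_across number of cells across the channel height (>= 4).
#' @param reactive_walls tag the top/bottom walls as platelet-adhesive.
#' @return A [grid2d].
#' @export
build_channel <- function(length, height, n_across, reactive_walls = TRUE) {
  if (!is.finite(length) || length <= 0) stop("length must be positive")
  if (!is.finite(height) || height <= 0) stop("height must be positive")
  if (n_across < 4L) stop("n_across must be at least 4")
  ny <- as.integer(n_across)
  dy <- height / ny
  dx <- dy
  nx <- max(4L, as.integer(round(length / dx)))
  ct <- matrix(CELL_TYPES[["FLUID"]], nx, ny)
  ct[1L, ] <- CELL_TYPES[["INLET"]]
  ct[nx, ] <- CELL_TYPES[["OUTLET"]]
  reactive <- array(FALSE, dim = c(nx, ny, 4L))
  if (reactive_walls) {
    interior <- 2:(nx - 1L)
    reactive[interior, 1L, 3L] <- TRUE   # bottom wall, side ym
    reactive[interior, ny, 4L] <- TRUE   # top wall, side yp
  }
  g <- grid2d(ct, dx, dy, reactive)
  g$meta <- list(preset = "channel", length = length, height = height)
  g
}

#' Closed rectangular box grid (test domain)
#'
#' All-FLUID box with no INLET or OUTLET cells; used for conservation and
#' energy-decay tests.
#'
#' @param nx,ny cell counts (>= 4).
#' @param dx,dy spacing (m).
#' @return A [grid2d].
#' @export
build_closed_box <- function(nx, ny, dx = 1e-4, dy = dx) {
  ct <- matrix(CELL_TYPES[["FLUID"]], as.integer(nx), as.integer(ny))
  grid2d(ct, dx, dy)
}

#' Backward-facing step grid
#'
#' Inlet section of height `inlet_h` sits above a SOLID block that ends at
#' `step_x`; the sudden expansion to `outlet_h` creates a recirculation
#' zone downstream of the step.  The vertical step face and the bottom
#' wall downstream of the step are reactive.
#'
#' @param inlet_h,outlet_h inlet/outlet section heights (m),
#'   `outlet_h > inlet_h`.
#' @param step_x streamwise position of the step (m), `0 < step_x < length`.
#' @param length domain length (m).
#' @param n_across number of cells across `outlet_h` (>= 4).
#' @return A [grid2d].
#' @export
build_backward_facing_step <- function(inlet_h, outlet_h, step_x, length,
                                       n_across) {
  if (!is.finite(inlet_h) || inlet_h <= 0) stop("inlet_h must be positive")
  if (!is.finite(outlet_h) || outlet_h <= inlet_h)
    stop("outlet_h must exceed inlet_h")
  if (!is.finite(step_x) || step_x <= 0 || step_x >= length)
    stop("step_x must lie strictly inside the domain")
  if (n_across < 4L) stop("n_across must be at least 4")
  ny <- as.integer(n_across)
  dy <- outlet_h / ny
  dx <- dy
  nx <- max(4L, as.integer(round(length / dx)))
  n_step_x <- as.integer(round(step_x / dx))
  n_step_y <- as.integer(round((outlet_h - inlet_h) / dy))
  if (n_step_x < 1L || n_step_x >= nx - 1L) stop("step_x unresolvable on grid")
  if (n_step_y < 1L || n_step_y >= ny) stop("step height unresolvable on grid")
  ct <- matrix(CELL_TYPES[["FLUID"]], nx, ny)
  ct[1:n_step_x, 1:n_step_y] <- CELL_TYPES[["SOLID"]]
  ct[1L, (n_step_y + 1L):ny] <- CELL_TYPES[["INLET"]]
  ct[nx, ] <- CELL_TYPES[["OUTLET"]]
  reactive <- array(FALSE, dim = c(nx, ny, 4L))
  # step face: FLUID cells just downstream of the block, side xm
  reactive[n_step_x + 1L, 1:n_step_y, 1L] <- TRUE
  # bottom wall downstream of the step, side ym
  if (n_step_x + 1L <= nx - 1L)
    reactive[(n_step_x + 1L):(nx - 1L), 1L, 3L] <- TRUE
  g <- grid2d(ct, dx, dy, reactive)
  g$meta <- list(preset = "backward_facing_step", n_step_x = n_step_x,
                 n_step_y = n_step_y)
  g
}

#' Crevice channel grid
#'
#' Straight channel with a rectangular cavity recessed into the lower
#' wall, emulating the stagnant bearing-crevice region of a rotary blood
#' pump.  The cavity walls are reactive; the main channel walls are not,
#' so deposition initiates inside the crevice.
#'
#' @param channel_h main channel height (m).
#' @param crevice_w,crevice_d cavity width and depth (m).
#' @param length domain length (m); the cavity is centered streamwise.
#' @param n_across number of cells across `channel_h` (>= 4).
#' @return A [grid2d].
#' @export
build_crevice_channel <- function(channel_h, crevice_w, crevice_d, length,
                                  n_across) {
  if (!is.finite(channel_h) || channel_h <= 0) stop("channel_h must be positive")
  if (!is.finite(crevice_w) || crevice_w <= 0) stop("crevice_w must be positive")
  if (!is.finite(crevice_d) || crevice_d <= 0) stop("crevice_d must be positive")
  if (crevice_w >= length) stop("crevice wider than the domain")
  if (n_across < 4L) stop("n_across must be at least 4")
  ny_ch <- as.integer(n_across)
  dy <- channel_h / ny_ch
  dx <- dy
  nx <- max(4L, as.integer(round(length / dx)))
  ny_cav <- as.integer(round(crevice_d / dy))
  n_cav_w <- as.integer(round(crevice_w / dx))
  if (ny_cav < 1L) stop("crevice_d unresolvable on grid")
  if (n_cav_w < 1L) stop("crevice_w unresolvable on grid")
  ny <- ny_ch + ny_cav
  i0 <- as.integer(round((nx - n_cav_w) / 2))
  i0 <- max(2L, i0)
  i1 <- i0 + n_cav_w - 1L
  if (i1 >= nx) stop("crevice does not fit in the domain")
  ct <- matrix(CELL_TYPES[["FLUID"]], nx, ny)
  ct[, 1:ny_cav] <- CELL_TYPES[["SOLID"]]           # lower wall slab
  ct[i0:i1, 1:ny_cav] <- CELL_TYPES[["FLUID"]]      # carve the cavity
  ct[1L, (ny_cav + 1L):ny] <- CELL_TYPES[["INLET"]]
  ct[nx, (ny_cav + 1L):ny] <- CELL_TYPES[["OUTLET"]]
  reactive <- array(FALSE, dim = c(nx, ny, 4L))
  reactive[i0, 1:ny_cav, 1L] <- TRUE                # cavity left wall
  reactive[i1, 1:ny_cav, 2L] <- TRUE                # cavity right wall
  reactive[i0:i1, 1L, 3L] <- TRUE                   # cavity floor
  g <- grid2d(ct, dx, dy, reactive)
  g$meta <- list(preset = "crevice_channel", ny_cav = ny_cav,
                 i_cav = c(i0, i1))
  g
}

#' Enumerate wall faces of the fluid region
#'
#' Lists every face of a FLUID cell adjacent to a SOLID cell or the
#' domain boundary, with outward face normal, face area (m^2 per unit
#' depth) and reactive flag.  Faces toward INLET/OUTLET cells are not
#' walls.
#'
#' @param grid a [grid2d].
#' @return A data.frame with columns `ix, iy, side, nx, ny, area,
#'   reactive`, ordered row-major (x fastest) then by side.
#' @export
wall_faces <- function(grid) {
  ct <- grid$cell_type
  fl <- which(ct == CELL_TYPES[["FLUID"]], arr.ind = TRUE)
  out <- vector("list", 4L)
  for (s in 1:4) {
    nt <- .neighbor_type(ct, fl[, 1L], fl[, 2L], SIDES[s])
    w <- nt == CELL_TYPES[["SOLID"]]
    if (!any(w)) next
    area <- if (s <= 2L) grid$dy else grid$dx
    out[[s]] <- data.frame(
      ix = fl[w, 1L], iy = fl[w, 2L], side = SIDES[s],
      nx = SIDE_OFFSETS[s, 1L], ny = SIDE_OFFSETS[s, 2L],
      area = area,
      reactive = grid$reactive[cbind(fl[w, 1L], fl[w, 2L], s)],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(ix = integer(0), iy = integer(0), side = character(0),
                      nx = integer(0), ny = integer(0), area = numeric(0),
                      reactive = logical(0))
  ord <- order(res$iy, res$ix, match(res$side, SIDES))
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Number of FLUID cells
#' @param grid a [grid2d].
#' @return Integer count.
#' @export
n_fluid_cells <- function(grid) sum(grid$cell_type == CELL_TYPES[["FLUID"]])

#' @export
print.grid2d <- function(x, ...) {
  tab <- table(factor(names(CELL_TYPES)[match(x$cell_type, CELL_TYPES)],
                      levels = names(CELL_TYPES)))
  cat(sprintf("grid2d: %d x %d cells, dx = %g m, dy = %g m\n",
              x$nx, x$ny, x$dx, x$dy))
  cat(sprintf("  cells: %s\n",
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  cat(sprintf("  reactive wall faces: %d\n", sum(x$reactive)))
  invisible(x)
}

#' Write a grid or cell fields to a legacy VTK structured-points file
#'
#' ASCII legacy VTK for quick inspection in ParaView.  The cell-type
#' matrix is always written; additional per-cell fields may be supplied
#' as a named list of `nx` by `ny` matrices.
#'
#' @param grid a [grid2d].
#' @param path output file path.
#' @param fields optional named list of numeric matrices of dim
#'   `c(nx, ny)`.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(grid, path, fields = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "hemoclot structured grid",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", grid$nx + 1L, grid$ny + 1L),
               sprintf("ORIGIN %g %g 0", grid$origin[1], grid$origin[2]),
               sprintf("SPACING %g %g 1", grid$dx, grid$dy),
               sprintf("CELL_DATA %d", grid$nx * grid$ny)), con)
  writeLines(c("SCALARS cell_type int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(grid$cell_type), collapse = " "), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    stopifnot(identical(dim(f), c(grid$nx, grid$ny)))
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(format(as.numeric(f), digits = 12), collapse = " "), con)
  }
  invisible(path)
}
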