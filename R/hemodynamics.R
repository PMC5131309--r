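# Incompressible flow with a porous-thrombus momentum sink.
#
# Fractional-step (projection) scheme on a staggered (MAC) arrangement:
# u lives on vertical faces ((nx+1) x ny), v on horizontal faces
# (nx x (ny+1)), p at cell centers.  First-order upwind advection,
# explicit viscous diffusion, and the Darcy drag -C2*f(phi)*v_f treated
# implicitly inside the projection: with b = 1/(1 + dt*C2*f(phi)/rho) the
# corrected face velocity is u = b*(u* - dt/rho * dp/dx), which yields a
# variable-coefficient Poisson equation div(b grad p) and recovers the
# exact steady Darcy-Brinkman balance K*u = -grad p + mu*lapl(u).

#' Fluid-phase parameters
#'
#' @param mu_f dynamic viscosity (Pa s).  Blood treated as Newtonian.
#' @param rho_f0 density of the pure fluid phase (kg/m^3).  The mixture
#'   density is held at `rho_f0` (thrombosed regions are nearly
#'   stagnant, so the momentum effect of the phi-dependence is
#'   negligible at desk scale).
#' @param C2 resistance coefficient of the deposited-platelet bed
#'   (kg/(m^3 s)); multiplies the hindrance function.
#' @param nu_t additive turbulent eddy viscosity (m^2/s); retained as a
#'   hook but 0 for the laminar desk-scale runs.
#' @param div_tol maximum tolerated discrete divergence after a
#'   projection step (1/s).
#' @param max_iters iteration cap for [solve_steady_flow()].
#' @return A list of class `flow_params`.
#' @export
flow_params <- function(mu_f = 3.5e-3, rho_f0 = 1060, C2 = 2e9,
                        nu_t = 0, div_tol = 1e-8, max_iters = 50000L) {
  stopifnot(mu_f > 0, rho_f0 > 0, C2 > 0, nu_t >= 0,
            div_tol > 0, max_iters >= 1)
  structure(list(mu_f = mu_f, rho_f0 = rho_f0, C2 = C2, nu_t = nu_t,
                 div_tol = div_tol, max_iters = as.integer(max_iters)),
            class = "flow_params")
}

#' Hindrance function of the deposited-platelet bed
#'
#' `f(phi) = phi * (1 + 6.5 * phi)`, the drag enhancement of an
#' assemblage of densely packed particles relative to a single particle;
#' monotone increasing on \[0, 1\].
#'
#' @param phi deposited-platelet volume fraction, in \[0, 1\].
#' @return Dimensionless factor, same shape as `phi`.
#' @export
hindrance <- function(phi) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1))
    stop("phi must lie in [0, 1]")
  phi * (1 + 6.5 * phi)
}

#' Isotropic Darcy drag coefficient
#'
#' `C2 * f(phi)`, the coefficient multiplying `(v_f - v_T)` in the
#' momentum sink; `v_T = 0` here (static walls only).
#'
#' @param phi volume fraction in \[0, 1\].
#' @param params a [flow_params()] list.
#' @return Drag coefficient in kg/(m^3 s), same shape as `phi`.
#' @export
drag_coefficient <- function(phi, params = flow_params()) {
  params$C2 * hindrance(phi)
}

# ---- face classification -------------------------------------------------

# Precompute staggered-face types and ghost masks for a grid.
# u_type/v_type: 0 = fixed zero (wall/dead), 1 = projected interior,
# 2 = inlet (fixed), 3 = outlet (projected against p = 0 ghost).
flow_masks <- function(grid) {
  ct <- grid$cell_type
  nx <- grid$nx; ny <- grid$ny
  FL <- CELL_TYPES[["FLUID"]]; SO <- CELL_TYPES[["SOLID"]]
  IN <- CELL_TYPES[["INLET"]]; OU <- CELL_TYPES[["OUTLET"]]
  # pad cell types with SOLID outside the domain
  pad <- matrix(SO, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- ct
  ctL <- pad[1:(nx + 1L), 2:(ny + 1L)]    # cell left of u face i
  ctR <- pad[2:(nx + 2L), 2:(ny + 1L)]    # cell right of u face i
  u_type <- matrix(0L, nx + 1L, ny)
  u_type[ctL == FL & ctR == FL] <- 1L
  u_type[(ctL == IN & ctR == FL) | (ctL == FL & ctR == IN)] <- 2L
  u_type[(ctL == FL & ctR == OU) | (ctL == OU & ctR == FL)] <- 3L
  ctB <- pad[2:(nx + 1L), 1:(ny + 1L)]    # cell below v face j
  ctT <- pad[2:(nx + 1L), 2:(ny + 2L)]    # cell above v face j
  v_type <- matrix(0L, nx, ny + 1L)
  v_type[ctB == FL & ctT == FL] <- 1L
  # ghost-reflection masks for no-slip walls in the tangential stencils:
  # the vertical neighbour u(i, j+1) is a wall ghost when both cells in
  # the row above the u face are SOLID (incl. outside the domain).
  solid_pad <- pad == SO
  sL <- solid_pad[1:(nx + 1L), ]; sR <- solid_pad[2:(nx + 2L), ]
  u_ghost_up <- (sL & sR)[, 3:(ny + 2L)]          # row above face (i,j)
  u_ghost_dn <- (sL & sR)[, 1:ny]                 # row below
  sB <- solid_pad[, 1:(ny + 1L)]; sT <- solid_pad[, 2:(ny + 2L)]
  v_ghost_left <- (sB & sT)[1:nx, ]               # column left of v face
  v_ghost_right <- (sB & sT)[3:(nx + 2L), ]       # column right
  list(u_type = u_type, v_type = v_type,
       u_ghost_up = u_ghost_up, u_ghost_dn = u_ghost_dn,
       v_ghost_left = v_ghost_left, v_ghost_right = v_ghost_right,
       fluid = ct == FL)
}

#' Initialize a flow state
#'
#' Zero velocity and pressure except for the prescribed uniform inlet
#' velocity on inlet faces.
#'
#' @param grid a [grid2d].
#' @param u_in uniform inlet velocity (m/s, along +x).
#' @return A list of class `flow_state` with `u`, `v`, `p` and cached
#'   masks.
#' @export
init_flow <- function(grid, u_in = 0) {
  m <- flow_masks(grid)
  u <- matrix(0, grid$nx + 1L, grid$ny)
  v <- matrix(0, grid$nx, grid$ny + 1L)
  u[m$u_type == 2L] <- u_in
  structure(list(u = u, v = v, p = matrix(0, grid$nx, grid$ny),
                 u_in = u_in, masks = m, div_max = 0),
            class = "flow_state")
}

#' Stable explicit time step for the momentum predictor
#'
#' Combined viscous/advective limit for the explicit part of the
#' fractional-step scheme.
#'
#' @param grid a [grid2d].
#' @param flow a `flow_state`.
#' @param params a [flow_params()].
#' @param safety multiplicative safety factor.
#' @return Time step (s).
#' @export
flow_dt_stable <- function(grid, flow, params, safety = 0.7) {
  nu <- (params$mu_f / params$rho_f0) + params$nu_t
  umax <- max(abs(flow$u), abs(flow$v), abs(flow$u_in), 1e-12)
  dt_visc <- 0.25 / (nu * (1 / grid$dx^2 + 1 / grid$dy^2))
  dt_adv <- 1 / (umax / grid$dx + umax / grid$dy)
  safety * min(dt_visc, dt_adv)
}

# ---- pressure operator ---------------------------------------------------

# Variable-coefficient Poisson operator for the projection, with the
# Darcy factor b = 1/(1 + dt*C2*f(phi)/rho) evaluated on faces.
# Returns cached assembly + Cholesky factor; rebuild when phi or dt
# change.
build_flow_operator <- function(grid, phi, params, dt, masks = NULL) {
  if (is.null(masks)) masks <- flow_masks(grid)
  nx <- grid$nx; ny <- grid$ny
  fluid <- masks$fluid
  M <- sum(fluid)
  cid <- matrix(0L, nx, ny)
  cid[fluid] <- seq_len(M)
  rho <- params$rho_f0
  # face Darcy factors (phi averaged across the face)
  phip <- matrix(0, nx + 2L, ny + 2L)
  phip[2:(nx + 1L), 2:(ny + 1L)] <- phi
  clamp01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }
  phL <- phip[1:(nx + 1L), 2:(ny + 1L)]; phR <- phip[2:(nx + 2L), 2:(ny + 1L)]
  b_u <- 1 / (1 + dt * params$C2 * hindrance(clamp01((phL + phR) / 2)) / rho)
  phB <- phip[2:(nx + 1L), 1:(ny + 1L)]; phT <- phip[2:(nx + 1L), 2:(ny + 2L)]
  b_v <- 1 / (1 + dt * params$C2 * hindrance(clamp01((phB + phT) / 2)) / rho)
  # assemble triplets over the four sides of every fluid cell
  idx <- which(fluid, arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]; c0 <- cid[fluid]
  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  dd <- numeric(M)  # diagonal accumulator
  add_side <- function(di, dj, bf, area, dist) {
    ii <- i + di; jj <- j + dj
    inb <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
    ntype <- matrix(CELL_TYPES[["SOLID"]], 1L, length(i))
    ntype[inb] <- grid$cell_type[cbind(ii[inb], jj[inb])]
    k <- bf * (dt / rho) * area / dist
    isf <- inb & ntype == CELL_TYPES[["FLUID"]]
    if (any(isf)) {
      ti <<- c(ti, c0[isf]); tj <<- c(tj, cid[cbind(ii[isf], jj[isf])])
      tv <<- c(tv, -k[isf])
      dd[c0[isf]] <<- dd[c0[isf]] + k[isf]
    }
    iso <- inb & ntype == CELL_TYPES[["OUTLET"]]
    if (any(iso)) dd[c0[iso]] <<- dd[c0[iso]] + 2 * k[iso]  # p=0 at face
    invisible(NULL)
  }
  add_side(+1L, 0L, b_u[cbind(i + 1L, j)], grid$dy, grid$dx)
  add_side(-1L, 0L, b_u[cbind(i, j)], grid$dy, grid$dx)
  add_side(0L, +1L, b_v[cbind(i, j + 1L)], grid$dx, grid$dy)
  add_side(0L, -1L, b_v[cbind(i, j)], grid$dx, grid$dy)
  has_outlet <- any(grid$cell_type == CELL_TYPES[["OUTLET"]])
  if (!has_outlet) dd[1L] <- dd[1L] + max(dd)  # pin pressure (closed box)
  A <- Matrix::sparseMatrix(i = c(ti, seq_len(M)), j = c(tj, seq_len(M)),
                            x = c(tv, dd), dims = c(M, M))
  list(chol = Matrix::Cholesky(methods::as(A, "symmetricMatrix"), LDL = FALSE),
       cid = cid, b_u = b_u, b_v = b_v, masks = masks, dt = dt,
       has_outlet = has_outlet)
}

# shift helper: value of m[i+di, j+dj] aligned at [i, j], `fill` outside
.shift <- function(m, di, dj, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- max(1L, 1L - di):min(nr, nr - di)
  rj <- max(1L, 1L - dj):min(nc, nc - dj)
  out[ri, rj] <- m[ri + di, rj + dj]
  out
}

# momentum predictor: upwind advection + explicit viscous diffusion.
# Darcy drag is excluded here (applied in the projection).
momentum_predictor <- function(grid, flow, params, dt) {
  m <- flow$masks
  nx <- grid$nx; ny <- grid$ny
  dx <- grid$dx; dy <- grid$dy
  nu <- params$mu_f / params$rho_f0 + params$nu_t
  u <- flow$u; v <- flow$v
  ## --- u faces ---
  u_im <- .shift(u, -1L, 0L); u_ip <- .shift(u, +1L, 0L)
  out_face <- m$u_type == 3L
  u_ip[out_face] <- u[out_face]               # du/dx = 0 across the outlet
  u_jp <- .shift(u, 0L, +1L); u_jm <- .shift(u, 0L, -1L)
  u_jp[m$u_ghost_up] <- -u[m$u_ghost_up]      # no-slip wall ghosts
  u_jm[m$u_ghost_dn] <- -u[m$u_ghost_dn]
  # v averaged to u faces
  v0 <- rbind(matrix(0, 1L, ny), v[, 1:ny, drop = FALSE])
  v1 <- rbind(v[, 1:ny, drop = FALSE], matrix(0, 1L, ny))
  v2 <- rbind(matrix(0, 1L, ny), v[, 2:(ny + 1L), drop = FALSE])
  v3 <- rbind(v[, 2:(ny + 1L), drop = FALSE], matrix(0, 1L, ny))
  vbar <- (v0 + v1 + v2 + v3) / 4
  adv_u <- u * ifelse(u > 0, (u - u_im) / dx, (u_ip - u) / dx) +
    vbar * ifelse(vbar > 0, (u - u_jm) / dy, (u_jp - u) / dy)
  visc_u <- nu * ((u_ip - 2 * u + u_im) / dx^2 + (u_jp - 2 * u + u_jm) / dy^2)
  u_star <- u + dt * (-adv_u + visc_u)
  upd <- m$u_type == 1L | m$u_type == 3L
  u_star[!upd] <- u[!upd]
  ## --- v faces ---
  v_jm <- .shift(v, 0L, -1L); v_jp <- .shift(v, 0L, +1L)
  v_im <- .shift(v, -1L, 0L); v_ip <- .shift(v, +1L, 0L)
  v_im[m$v_ghost_left] <- -v[m$v_ghost_left]
  v_ip[m$v_ghost_right] <- -v[m$v_ghost_right]
  u0 <- cbind(matrix(0, nx, 1L), u[1:nx, , drop = FALSE])
  u1 <- cbind(u[1:nx, , drop = FALSE], matrix(0, nx, 1L))
  u2 <- cbind(matrix(0, nx, 1L), u[2:(nx + 1L), , drop = FALSE])
  u3 <- cbind(u[2:(nx + 1L), , drop = FALSE], matrix(0, nx, 1L))
  ubar <- (u0 + u1 + u2 + u3) / 4
  adv_v <- ubar * ifelse(ubar > 0, (v - v_im) / dx, (v_ip - v) / dx) +
    v * ifelse(v > 0, (v - v_jm) / dy, (v_jp - v) / dy)
  visc_v <- nu * ((v_ip - 2 * v + v_im) / dx^2 + (v_jp - 2 * v + v_jm) / dy^2)
  v_star <- v + dt * (-adv_v + visc_v)
  v_star[m$v_type != 1L] <- v[m$v_type != 1L]
  list(u = u_star, v = v_star)
}

#' Advance the flow by one projection step
#'
#' Momentum predictor (first-order upwind advection, explicit viscous
#' diffusion), pointwise-implicit Darcy sink, then projection onto the
#' divergence-free space.  Inlet faces carry the fixed uniform velocity,
#' the outlet is held at p = 0 Pa, walls are no-slip.
#'
#' @param grid a [grid2d].
#' @param flow a `flow_state` from [init_flow()].
#' @param phi per-cell deposited-platelet volume fraction (matrix
#'   `nx` x `ny`).
#' @param params a [flow_params()].
#' @param dt time step (s); must satisfy the advective and viscous
#'   stability limits (checked).
#' @param ops cached operator from an earlier step with identical
#'   `phi` and `dt` (internal use); rebuilt when `NULL`.
#' @return Updated `flow_state`; `div_max` holds the post-projection
#'   divergence.
#' @export
flow_step <- function(grid, flow, phi, params, dt, ops = NULL) {
  dt_max <- flow_dt_stable(grid, flow, params, safety = 1.0)
  if (dt > dt_max * 1.000001)
    stop(sprintf("dt = %g exceeds stability limit %g s", dt, dt_max))
  if (is.null(ops)) ops <- build_flow_operator(grid, phi, params, dt, flow$masks)
  pred <- momentum_predictor(grid, flow, params, dt)
  st <- project_flow(grid, flow, pred, params, dt, ops)
  if (st$div_max > params$div_tol)
    stop(sprintf("projection failed: max divergence %.3g 1/s exceeds %.3g",
                 st$div_max, params$div_tol))
  st
}

# projection: solve div(b grad p) = div(b u*) / (dt/rho), correct faces
project_flow <- function(grid, flow, pred, params, dt, ops) {
  m <- flow$masks
  nx <- grid$nx; ny <- grid$ny
  dx <- grid$dx; dy <- grid$dy
  rho <- params$rho_f0
  u_s <- pred$u; v_s <- pred$v
  b_u <- ops$b_u; b_v <- ops$b_v
  # effective face fluxes entering the divergence: projected faces get
  # b*u*, fixed faces their held values (inlet u_in, walls 0)
  fu <- u_s * b_u
  fixed_u <- m$u_type == 2L | m$u_type == 0L
  fu[fixed_u] <- flow$u[fixed_u]
  fv <- v_s * b_v
  fv[m$v_type == 0L] <- flow$v[m$v_type == 0L]
  rhs_m <- (fu[2:(nx + 1L), , drop = FALSE] - fu[1:nx, , drop = FALSE]) * dy +
    (fv[, 2:(ny + 1L), drop = FALSE] - fv[, 1:ny, drop = FALSE]) * dx
  rhs <- -rhs_m[m$fluid]                       # A p = -div(b u*)
  if (!ops$has_outlet) rhs <- rhs - mean(rhs)  # compatibility (closed box)
  pv <- as.numeric(Matrix::solve(ops$chol, rhs))
  p <- matrix(0, nx, ny)
  p[m$fluid] <- pv
  # pressure differences across u faces (0 outside fluid; ghost 0 at outlet)
  pL <- matrix(0, nx + 1L, ny); pR <- matrix(0, nx + 1L, ny)
  pL[2:(nx + 1L), ] <- p; pR[1:nx, ] <- p
  gu <- (pR - pL) / dx
  i_out <- which(m$u_type == 3L, arr.ind = TRUE)
  if (nrow(i_out)) {
    # outlet faces: fluid cell on the left, p = 0 at the face itself
    gu[i_out] <- (0 - p[cbind(i_out[, 1L] - 1L, i_out[, 2L])]) / (dx / 2)
  }
  u_new <- b_u * (u_s - (dt / rho) * gu)
  u_new[fixed_u] <- flow$u[fixed_u]
  pB <- matrix(0, nx, ny + 1L); pT <- matrix(0, nx, ny + 1L)
  pB[, 2:(ny + 1L)] <- p; pT[, 1:ny] <- p
  gv <- (pT - pB) / dy
  v_new <- b_v * (v_s - (dt / rho) * gv)
  v_new[m$v_type == 0L] <- flow$v[m$v_type == 0L]
  # post-projection divergence diagnostic (1/s)
  divm <- ((u_new[2:(nx + 1L), , drop = FALSE] - u_new[1:nx, , drop = FALSE]) / dx +
           (v_new[, 2:(ny + 1L), drop = FALSE] - v_new[, 1:ny, drop = FALSE]) / dy)
  div_max <- max(abs(divm[m$fluid]))
  structure(list(u = u_new, v = v_new, p = p, u_in = flow$u_in,
                 masks = m, div_max = div_max),
            class = "flow_state")
}

#' March the flow to steady state
#'
#' Pseudo-time iteration of [flow_step()] at the largest stable step
#' until the per-step velocity change falls below `steady_tol` relative
#' to the velocity scale, or `max_iters` is reached.
#'
#' @param grid a [grid2d].
#' @param phi per-cell volume fraction matrix.
#' @param params a [flow_params()].
#' @param u_in uniform inlet velocity (m/s).
#' @param flow0 optional warm-start `flow_state`.
#' @param steady_tol relative per-step change threshold.
#' @param max_iters iteration cap (default from `params`).
#' @return A converged `flow_state` with attributes `iters` and
#'   `residual`.
#' @export
solve_steady_flow <- function(grid, phi, params = flow_params(), u_in,
                              flow0 = NULL, steady_tol = 1e-9,
                              max_iters = params$max_iters) {
  flow <- if (is.null(flow0)) init_flow(grid, u_in) else flow0
  flow$u[flow$masks$u_type == 2L] <- u_in
  flow$u_in <- u_in
  # conservative safety: peak speeds grow ~1.5-2x above u_in as the
  # profile develops; rechecked periodically below
  dt <- flow_dt_stable(grid, flow, params, safety = 0.35)
  ops <- build_flow_operator(grid, phi, params, dt, flow$masks)
  uscale <- max(abs(u_in), 1e-12)
  res <- Inf; it <- 0L
  while (it < max_iters) {
    it <- it + 1L
    nxt <- flow_step(grid, flow, phi, params, dt, ops)
    res <- max(max(abs(nxt$u - flow$u)), max(abs(nxt$v - flow$v))) / uscale
    flow <- nxt
    if (res <= steady_tol) break
    # velocities may have grown beyond the dt used to build the operator
    if (it %% 50L == 0L) {
      dt_new <- flow_dt_stable(grid, flow, params, safety = 0.35)
      if (dt_new < dt * 0.999) {
        dt <- dt_new
        ops <- build_flow_operator(grid, phi, params, dt, flow$masks)
      }
    }
  }
  attr(flow, "iters") <- it
  attr(flow, "residual") <- res
  flow
}

#' Wall shear stress on wall faces
#'
#' One-sided tangential velocity gradient at every wall face, using a
#' two-point quadratic fit `tau = mu*(9*u1 - u2)/(3*dn)` when two fluid
#' cells are available along the wall normal (exact for a parabolic
#' profile), else the one-point form `2*mu*u1/dn`.  Reported in Pa as a
#' magnitude.
#'
#' @param grid a [grid2d].
#' @param flow a `flow_state`.
#' @param mu_f dynamic viscosity (Pa s).
#' @return The [wall_faces()] data.frame with an extra `tau` column.
#' @export
wall_shear_stress <- function(grid, flow, mu_f = flow_params()$mu_f) {
  wf <- wall_faces(grid)
  if (!nrow(wf)) return(cbind(wf, tau = numeric(0)))
  ct <- grid$cell_type
  u <- flow$u; v <- flow$v
  uc <- (u[1:grid$nx, , drop = FALSE] + u[2:(grid$nx + 1L), , drop = FALSE]) / 2
  vc <- (v[, 1:grid$ny, drop = FALSE] + v[, 2:(grid$ny + 1L), drop = FALSE]) / 2
  tau <- numeric(nrow(wf))
  for (r in seq_len(nrow(wf))) {
    i <- wf$ix[r]; j <- wf$iy[r]; s <- wf$side[r]
    if (s %in% c("ym", "yp")) {
      dn <- grid$dy
      tang <- uc
      di <- 0L; dj <- if (s == "ym") 1L else -1L
    } else {
      dn <- grid$dx
      tang <- vc
      di <- if (s == "xm") 1L else -1L; dj <- 0L
    }
    t1 <- tang[i, j]
    i2 <- i + di; j2 <- j + dj
    two_pt <- i2 >= 1L && i2 <= grid$nx && j2 >= 1L && j2 <= grid$ny &&
      ct[i2, j2] == CELL_TYPES[["FLUID"]]
    tau[r] <- if (two_pt) {
      abs(mu_f * (9 * t1 - tang[i2, j2]) / (3 * dn))
    } else {
      abs(2 * mu_f * t1 / dn)
    }
  }
  wf$tau <- tau
  wf
}

#' Cell-centered shear-stress magnitude
#'
#' `tau = mu * sqrt(2 D:D)` with the rate-of-deformation tensor D built
#' from central differences of the face velocities; wall-adjacent
#' gradients use no-slip ghost values.  Used for shear-driven cleaning
#' and shear activation in the interior of the thrombus region.
#'
#' @param grid a [grid2d].
#' @param flow a `flow_state`.
#' @param mu_f dynamic viscosity (Pa s).
#' @return Matrix `nx` x `ny` of stress magnitudes (Pa); 0 in non-FLUID
#'   cells.
#' @export
cell_shear_stress <- function(grid, flow, mu_f = flow_params()$mu_f) {
  nx <- grid$nx; ny <- grid$ny
  u <- flow$u; v <- flow$v
  dudx <- (u[2:(nx + 1L), , drop = FALSE] - u[1:nx, , drop = FALSE]) / grid$dx
  dvdy <- (v[, 2:(ny + 1L), drop = FALSE] - v[, 1:ny, drop = FALSE]) / grid$dy
  uc <- (u[1:nx, , drop = FALSE] + u[2:(nx + 1L), , drop = FALSE]) / 2
  vc <- (v[, 1:ny, drop = FALSE] + v[, 2:(ny + 1L), drop = FALSE]) / 2
  fluid <- grid$cell_type == CELL_TYPES[["FLUID"]]
  solid <- grid$cell_type == CELL_TYPES[["SOLID"]]
  nonfluid_pad <- function(m) { m[!fluid] <- 0; m }
  uc <- nonfluid_pad(uc); vc <- nonfluid_pad(vc)
  # directional gradient of a cell field: no-slip ghost (-f) across SOLID
  # neighbours and the domain boundary, zero gradient into INLET/OUTLET
  open_nb <- grid$cell_type == CELL_TYPES[["INLET"]] |
    grid$cell_type == CELL_TYPES[["OUTLET"]]
  grad_dir <- function(f, di, dj, d) {
    fp <- .shift(f, di, dj)
    wall <- .shift(matrix(as.numeric(solid), nx, ny), di, dj, fill = 1) > 0.5
    fp[wall] <- -f[wall]
    opn <- .shift(matrix(as.numeric(open_nb), nx, ny), di, dj) > 0.5
    fp[opn] <- f[opn]
    (fp - f) / d
  }
  dudy <- (grad_dir(uc, 0L, 1L, grid$dy) - grad_dir(uc, 0L, -1L, grid$dy)) / 2
  dvdx <- (grad_dir(vc, 1L, 0L, grid$dx) - grad_dir(vc, -1L, 0L, grid$dx)) / 2
  dd <- 2 * dudx^2 + 2 * dvdy^2 + (dudy + dvdx)^2
  tau <- mu_f * sqrt(pmax(dd, 0))
  tau[!fluid] <- 0
  tau
}

#' Volumetric flux through inlet and outlet (m^3/s per unit depth)
#'
#' @param grid a [grid2d].
#' @param flow a `flow_state`.
#' @return List with `inflow` and `outflow` (both positive for
#'   left-to-right flow).
#' @export
flow_balance <- function(grid, flow) {
  m <- flow$masks
  inlet <- m$u_type == 2L
  outlet <- m$u_type == 3L
  list(inflow = sum(flow$u[inlet]) * grid$dy,
       outflow = sum(flow$u[outlet]) * grid$dy)
}
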