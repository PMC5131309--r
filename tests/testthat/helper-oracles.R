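# Independent oracles used across the suite.

# Classic fixed-step RK4 integration of the batch reaction network,
# independent of the package's Rosenbrock integrator.  Negative
# intermediate states are clamped to zero exactly as the reference
# integrator does.
rk4_batch <- function(c0, t_end, params, tau = 0, n = 20000L) {
  h <- t_end / n
  y <- c0
  traj <- matrix(NA_real_, n + 1L, 7L)
  traj[1L, ] <- as.numeric(y)
  f <- function(yy) {
    attributes(yy) <- attributes(c0)
    assemble_sources(yy, tau, params)
  }
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(pmax(y + h / 2 * k1, 0))
    k3 <- f(pmax(y + h / 2 * k2, 0))
    k4 <- f(pmax(y + h * k3, 0))
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    y[y < 0] <- 0
    attributes(y) <- attributes(c0)
    traj[i + 1L, ] <- as.numeric(y)
  }
  traj
}

# Brute-force wall-face enumeration: march over FLUID cells, inspect
# all four neighbours directly from the cell-type matrix.
brute_force_wall_faces <- function(grid) {
  ct <- grid$cell_type
  offs <- list(xm = c(-1L, 0L), xp = c(1L, 0L),
               ym = c(0L, -1L), yp = c(0L, 1L))
  rows <- list()
  for (j in seq_len(grid$ny)) {
    for (i in seq_len(grid$nx)) {
      if (ct[i, j] != CELL_TYPES[["FLUID"]]) next
      for (s in names(offs)) {
        ii <- i + offs[[s]][1L]; jj <- j + offs[[s]][2L]
        outside <- ii < 1L || ii > grid$nx || jj < 1L || jj > grid$ny
        if (outside || ct[ii, jj] == CELL_TYPES[["SOLID"]])
          rows[[length(rows) + 1L]] <- data.frame(ix = i, iy = j, side = s)
      }
    }
  }
  do.call(rbind, rows)
}

# tiny kinetics parameter set that switches every pathway off; used to
# isolate pure transport behaviour in kernel tests
inert_kinetics <- function() {
  kinetics_params(phi_AT = 1e-300, phi_RT = 1e-300, k_cat = 0,
                  beta_TxA2 = 1e-300, lambda_ADP = 1e-300)
}

inert_transport <- function(...) {
  args <- list(k_rpd_b = 1e-300, k_apd_b = 1e-300, k_ra = 1e-300,
               k_aa = 1e-300, k_clean = 1e-300, k_stab = 1e-300)
  over <- list(...)
  args[names(over)] <- over
  do.call(transport_params, args)
}

# random non-negative batch state drawn on the physiological scales
random_batch_state <- function() {
  batch_state(RP = runif(1, 0, 4e14), AP = runif(1, 0, 1e13),
              ADP = runif(1, 0, 6e6), TxA2 = runif(1, 0, 2e6),
              PT = runif(1, 0, 2e-6), T = runif(1, 0, 300),
              AT = runif(1, 0, 4e-6))
}
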