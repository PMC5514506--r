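#' Rasterize agent biomass onto the solute grid
#'
#' Each agent's mass is deposited into its containing grid cell and
#' converted to a concentration (fg per grid-cell volume; with the
#' internal units 1 fg/um^3 = 1 g/L). Living biomass is binned per
#' species ("acidogen", "methanogen"); dead cells contribute to the
#' "dead" grid. The diffusivity mask is `gamma` wherever any biomass
#' (living or dead, including EPS capsules) is present and 1 elsewhere.
#'
#' @param agents agent tibble.
#' @param species species parameter tibble.
#' @param cfg a [world_config].
#' @return list with `biomass` (named list of g/L matrices), `mask`
#'   (diffusivity factor matrix) and `cell` (per-agent linear grid index).
#' @export
rasterize_biomass <- function(agents, species, cfg) {
  n <- cfg$grid_resolution
  h <- grid_spacing(cfg)
  vol <- h^2 * cfg$slice_thickness  # um^3; fg / um^3 == g/L
  if (nrow(agents) > 0 &&
      (any(agents$x < 0 | agents$x > cfg$domain_width |
           agents$y < 0 | agents$y > cfg$domain_height))) {
    rlang::abort("agent outside the simulation domain",
                 class = "granusim_geometry_error")
  }
  ix <- pmin(n, pmax(1L, as.integer(floor(agents$x / h)) + 1L))
  iy <- pmin(n, pmax(1L, as.integer(floor(agents$y / h)) + 1L))
  cell <- (iy - 1L) * n + ix  # linear index, row = x index

  grids <- list()
  groups <- unique(c("acidogen", "methanogen", "dead", agents$species))
  for (g in groups) {
    m <- matrix(0, n, n)
    sel <- agents$species == g
    if (any(sel)) {
      tot <- tapply(agents$mass[sel], cell[sel], sum)
      m[as.integer(names(tot))] <- tot / vol
    }
    grids[[g]] <- m
  }
  occupied <- matrix(0, n, n)
  if (nrow(agents) > 0) {
    totmass <- tapply(agents$mass + agents$capsule, cell, sum)
    occupied[as.integer(names(totmass))] <- totmass
  }
  mask <- matrix(1, n, n)
  mask[occupied > 0] <- cfg$gamma
  list(biomass = grids, mask = mask, cell = cell)
}

# Solver context: caches the node indexing, the off-diagonal triplet
# skeleton and the symbolic Cholesky factorisations (one 5-point pattern
# per boundary mode, fixed for a given grid), so each solve only
# updates numeric values. Dirichlet mode solves the (n-2)^2 interior
# with the boundary ring held at the bulk value; no-flux mode solves all
# n^2 nodes with zero-flux domain edges.
new_field_solver <- function(cfg) {
  n <- cfg$grid_resolution
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  prep <- function(lo, hi, id) {
    I <- rep(lo:hi, times = hi - lo + 1)
    J <- rep(lo:hi, each = hi - lo + 1)
    pre <- lapply(shifts, function(s) {
      Ni <- I + s[1]; Nj <- J + s[2]
      inside <- Ni >= 1 & Ni <= n & Nj >= 1 & Nj <= n
      q <- integer(length(Ni))
      q[inside] <- id[cbind(Ni[inside], Nj[inside])]
      list(center = cbind(I, J),
           nb = cbind(pmin(pmax(Ni, 1L), n), pmin(pmax(Nj, 1L), n)),
           q = q, inside = inside)
    })
    list(I = I, J = J, pre = pre, nun = (hi - lo + 1)^2)
  }
  id_int <- matrix(0L, n, n)
  id_int[2:(n - 1), 2:(n - 1)] <- seq_len((n - 2L)^2)
  id_all <- matrix(seq_len(n * n), n, n)
  env <- new.env(parent = emptyenv())
  env$n <- n
  env$h <- grid_spacing(cfg)
  env$dirichlet <- prep(2L, n - 1L, id_int)
  env$noflux <- prep(1L, n, id_all)
  env$chol <- list()
  env
}

# Assemble and solve  trans*(S - S_old)/1 - div(D grad S) + k S = src.
# D, k, src are n x n matrices; bc is the Dirichlet boundary value
# (ignored in no-flux mode); `trans` is the implicit-Euler mass
# coefficient 1/dt (0 for a steady solve) with previous field `S_old`.
# Returns the full n x n field. The sparse matrix template and its
# value ordering are cached per boundary mode, so repeated solves only
# overwrite numeric slots and refresh the Cholesky factor.
solve_linear_field <- function(solver, D, k, src, bc,
                               boundary = "dirichlet",
                               trans = 0, S_old = NULL) {
  n <- solver$n; h <- solver$h
  lay <- solver[[boundary]]
  nun <- lay$nun
  p <- seq_len(nun)
  center <- cbind(lay$I, lay$J)
  if (is.null(lay$tmpl)) {
    # one-time: lower-triangle triplet skeleton and template matrix
    # whose @x slot maps back to our value order
    lower <- lapply(lay$pre, function(pr) {
      keep <- pr$q > 0L & pr$inside & p > pr$q
      list(keep = keep, i = p[keep], j = pr$q[keep])
    })
    ii <- c(p, unlist(lapply(lower, `[[`, "i")))
    jj <- c(p, unlist(lapply(lower, `[[`, "j")))
    A0 <- Matrix::sparseMatrix(i = ii, j = jj, x = seq_along(ii),
                               dims = c(nun, nun), symmetric = TRUE)
    lay$lower <- lower
    lay$ord <- A0@x
    lay$tmpl <- A0
    assign(boundary, lay, envir = solver)
  }
  diagacc <- numeric(nun)
  b <- src[center]
  if (trans > 0) b <- b + trans * S_old[center]
  offs <- vector("list", 4)
  for (s in seq_len(4)) {
    pr <- lay$pre[[s]]
    g <- 2 * D[pr$center] * D[pr$nb] / (D[pr$center] + D[pr$nb]) / h^2
    if (boundary == "noflux") g[!pr$inside] <- 0  # zero-flux domain edge
    diagacc <- diagacc + g
    offs[[s]] <- -g[lay$lower[[s]]$keep]
    if (boundary == "dirichlet") {
      # neighbours off the interior layout are the bc-valued boundary ring
      ghost <- pr$q == 0L
      if (bc != 0 && any(ghost)) b[ghost] <- b[ghost] + g[ghost] * bc
    }
  }
  diagacc <- diagacc + k[center] + trans
  vals <- c(diagacc, unlist(offs))
  A <- lay$tmpl
  A@x <- vals[lay$ord]
  if (is.null(solver$chol[[boundary]])) {
    solver$chol[[boundary]] <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  } else {
    solver$chol[[boundary]] <- Matrix::update(solver$chol[[boundary]], A)
  }
  sol <- as.numeric(Matrix::solve(solver$chol[[boundary]], b))
  out <- matrix(bc, n, n)
  out[center] <- sol
  out
}

#' Pseudo-steady-state solve for one solute
#'
#' Solves the steady diffusion--reaction balance
#' `div(B(x,y) D grad S) - uptake * S + source = 0` on the grid with a
#' Dirichlet boundary (the bulk value for the fed solute, zero for
#' absorbing/volatile solutes). The net reaction is supplied linearized:
#' `uptake` is a first-order consumption coefficient grid (1/h; e.g. the
#' Monod uptake `mu_max * B /(yield *(Ks + S_prev))` evaluated at the
#' previous iterate) and `source` a production grid (g/(L h)). The
#' harmonic mean of the node diffusivities is used across biofilm/liquid
#' interfaces, which keeps the 5-point operator symmetric positive
#' definite and the solution nonnegative for nonnegative sources.
#'
#' Nonlinear (Monod) kinetics are handled by Picard iteration: pass
#' `reaction`, a function mapping the current field to
#' `list(uptake =, source =)`, and the solve is repeated until the
#' relative change falls below `tol`.
#'
#' @param conc current concentration matrix (initial iterate), g/L.
#' @param solute one-row solute parameter tibble.
#' @param mask diffusivity mask matrix (1 or gamma), see
#'   [rasterize_biomass()].
#' @param cfg a [world_config].
#' @param uptake,source linearized reaction grids (matrices or scalars).
#' @param reaction optional function(conc) -> list(uptake, source) for
#'   Picard iteration.
#' @param tol relative convergence tolerance.
#' @param solver optional solver context (created if missing).
#' @return concentration matrix, g/L.
#' @export
solve_steady_state <- function(conc, solute, mask, cfg,
                               uptake = 0, source = 0, reaction = NULL,
                               tol = cfg$solver_tol, solver = NULL) {
  stopifnot(tol > 0)
  n <- cfg$grid_resolution
  if (is.null(solver)) solver <- new_field_solver(cfg)
  D <- solute$D_liquid * mask
  bc <- if (solute$boundary == "bulk") solute$bulk_value else 0
  mode <- if (solute$boundary == "noflux") "noflux" else "dirichlet"
  expand <- function(m) if (is.matrix(m)) m else matrix(m, n, n)
  if (is.null(reaction)) {
    out <- solve_linear_field(solver, D, expand(uptake), expand(source), bc,
                              boundary = mode)
  } else {
    out <- conc
    for (it in seq_len(cfg$solver_max_iter)) {
      r <- reaction(out)
      new <- solve_linear_field(solver, D, expand(r$uptake),
                                expand(r$source), bc, boundary = mode)
      delta <- max(abs(new - out)) / max(max(abs(new)), 1e-300)
      out <- new
      if (delta < tol) break
    }
    if (delta >= tol) {
      rlang::abort(sprintf(
        "pseudo-steady-state solver did not converge: residual %.3g > %.3g",
        delta, tol), class = "granusim_solver_error")
    }
  }
  neg <- out < 0
  if (any(neg)) out[neg] <- 0  # round-off guard; operator is positivity-preserving
  out
}

#' Discrete diffusion residual / flux divergence
#'
#' Applies the discrete operator `div(B D grad S)` to a field, using the
#' same harmonic-mean face conductances as the solver. With
#' `boundary = "noflux"` the domain-edge faces carry zero flux, so the
#' divergence sums to zero over the grid (discrete mass conservation);
#' with a Dirichlet boundary the boundary ring is held at `bc`.
#'
#' @inheritParams solve_steady_state
#' @param boundary "dirichlet" or "noflux".
#' @param bc Dirichlet boundary value.
#' @return matrix of the same shape as `conc`, g/(L h).
#' @export
flux_divergence <- function(conc, solute, mask, cfg,
                            boundary = c("dirichlet", "noflux"),
                            bc = NULL) {
  boundary <- match.arg(boundary)
  n <- cfg$grid_resolution
  h <- grid_spacing(cfg)
  D <- solute$D_liquid * mask
  if (is.null(bc)) bc <- if (solute$boundary == "bulk") solute$bulk_value else 0
  S <- conc
  if (boundary == "dirichlet") {
    S[1, ] <- bc; S[n, ] <- bc; S[, 1] <- bc; S[, n] <- bc
  }
  out <- matrix(0, n, n)
  face <- function(Da, Db) 2 * Da * Db / (Da + Db)
  # horizontal faces
  gx <- face(D[-n, ], D[-1, ]) / h^2
  fx <- gx * (S[-1, ] - S[-n, ])
  out[-n, ] <- out[-n, ] + fx
  out[-1, ] <- out[-1, ] - fx
  # vertical faces
  gy <- face(D[, -n], D[, -1]) / h^2
  fy <- gy * (S[, -1] - S[, -n])
  out[, -n] <- out[, -n] + fy
  out[, -1] <- out[, -1] - fy
  out
}

# Nodes of the well-mixed bulk liquid: farther than the boundary-layer
# thickness from any biomass-occupied grid cell (Euclidean distance on
# node centres). In the agitated reactor liquid the fed solute is held
# at its bulk value there; gradients exist only inside the biofilm and
# its boundary layer.
far_field_mask <- function(occupied, cfg) {
  L <- cfg$boundary_layer
  if (!is.finite(L)) return(matrix(FALSE, nrow(occupied), ncol(occupied)))
  h <- grid_spacing(cfg)
  rad <- floor(L / h)
  n <- nrow(occupied)
  near <- occupied
  if (any(occupied) && rad > 0) {
    for (di in -rad:rad) {
      for (dj in -rad:rad) {
        if (di == 0 && dj == 0) next
        if ((di^2 + dj^2) * h^2 > L^2) next
        src_i <- max(1, 1 - di):min(n, n - di)
        src_j <- max(1, 1 - dj):min(n, n - dj)
        near[src_i + di, src_j + dj] <-
          near[src_i + di, src_j + dj] | occupied[src_i, src_j]
      }
    }
  }
  !near
}

#' Spatial integrals of the solute fields
#'
#' Integrates each concentration field over the domain (grid-cell volume
#' in litres x g/L). For methane the cumulative production ledger --
#' which includes the mass that has already escaped through the
#' absorbing boundary -- is reported alongside the standing mass.
#'
#' @param state a `world_state`.
#' @return tibble with columns `solute`, `standing_g`, `cumulative_g`.
#' @export
solute_totals <- function(state) {
  cfg <- state$config
  vol <- grid_cell_volume_L(cfg)
  tibble::tibble(
    solute = names(state$fields),
    standing_g = unname(vapply(state$fields, function(m) sum(m) * vol,
                               numeric(1))),
    cumulative_g = ifelse(names(state$fields) == "methane",
                          state$cumulative_ch4 * 1e-15, NA_real_)
  )
}
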