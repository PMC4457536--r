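# Volume-conductor field: quasi-static extracellular potential of a disk
# electrode in a layered resistive sandwich, discretised with a regular
# finite-volume grid and solved by preconditioned conjugate gradients.

#' Layered volume model
#'
#' The default volume is the implant sandwich: a 100 um electrode-carrier
#' chip (1e6 Ohm cm), 300 um of retina (57 Ohm cm) and 300 um of silicone
#' tamponade (1e6 Ohm cm), each 2000 x 2000 um laterally. The first layer
#' extends downward from the chip/retina interface at z = 0 (when more
#' than one layer is given); the remaining layers stack upward. Layers
#' flagged `grounded` have their outer lateral boundaries held at 0 V
#' (the distant return electrode); all other outer faces are insulating.
#'
#' @param layers Data frame with columns `name`, `thickness` (um),
#'   `resistivity` (Ohm cm) and `grounded` (logical).
#' @param edge Lateral edge length in um.
#' @return Object of class `cbc_volume`.
#' @export
volume_model <- function(layers = data.frame(
                           name = c("chip", "retina", "tamponade"),
                           thickness = c(100, 300, 300),
                           resistivity = c(1e6, 57, 1e6),
                           grounded = c(FALSE, TRUE, FALSE)),
                         edge = 2000) {
  stopifnot(is.data.frame(layers),
            all(c("name", "thickness", "resistivity", "grounded") %in%
                  names(layers)),
            all(layers$thickness > 0), all(layers$resistivity > 0),
            edge > 0)
  nl <- nrow(layers)
  z0 <- if (nl > 1) -layers$thickness[1] else 0
  zb <- z0 + cumsum(c(0, layers$thickness))
  layers$z_bottom <- zb[-length(zb)]
  layers$z_top <- zb[-1]
  structure(list(layers = layers, edge = edge), class = "cbc_volume")
}

#' Disk electrode specification
#'
#' A voltage-driven disk electrode on the chip surface at the chip/retina
#' interface (z = 0), extruded `height` um into the retina.
#'
#' @param diameter Disk diameter in um.
#' @param height Electrode height in um (0 = flush disk).
#' @param center Electrode centre (x, y) on the interface, um.
#' @return Object of class `cbc_electrode`.
#' @export
electrode_spec <- function(diameter = 50, height = 10, center = c(0, 0)) {
  stopifnot(diameter > 0, height >= 0, length(center) == 2)
  structure(list(diameter = diameter, height = height, center = center),
            class = "cbc_electrode")
}

#' Analytic potential of an equipotential disk in a homogeneous half-space
#'
#' Oblate-spheroidal closed form for a disk of radius `a` held at `v0` on
#' the boundary of a semi-infinite homogeneous conductor:
#' `V = (2 v0 / pi) asin(2a / (sqrt((r-a)^2+z^2) + sqrt((r+a)^2+z^2)))`.
#' On the axis this reduces to `(2 v0 / pi) atan(a / z)`. Used as the
#' independent oracle for the finite-difference solver.
#'
#' @param r Radial distance(s) from the disk axis, um.
#' @param z Height(s) above the disk plane, um.
#' @param a Disk radius, um.
#' @param v0 Disk potential, V.
#' @return Potential in the units of `v0`.
#' @export
disk_potential_analytic <- function(r, z, a, v0 = 1) {
  q <- 2 * a / (sqrt((r - a)^2 + z^2) + sqrt((r + a)^2 + z^2))
  2 * v0 / pi * asin(pmin(1, q))
}

#' Solve the extracellular potential on a regular grid
#'
#' Discretises `div(sigma grad V) = 0` with a 7-point finite-volume stencil
#' (edge conductances from the layer resistivities; series/parallel
#' averaging at layer interfaces) and solves with Jacobi-preconditioned
#' conjugate gradients. Dirichlet conditions: the electrode nodes at the
#' drive voltage and the grounded layers' outer lateral boundary nodes at
#' 0 V; all remaining outer faces are insulating (natural Neumann).
#'
#' With `outer_bc = "analytic_disk"` (homogeneous volumes only) the outer
#' lateral and top faces are instead held at the closed-form disk potential
#' of [disk_potential_analytic()]; this is the validation configuration in
#' which the discrete solution can be compared against the analytic one.
#'
#' @param volume A [volume_model()].
#' @param electrode An [electrode_spec()].
#' @param drive Electrode voltage in V (the solution scales linearly).
#' @param grid_spacing Grid spacing in um; must divide all layer
#'   thicknesses and half the lateral edge.
#' @param tol Relative residual tolerance of the iterative solver.
#' @param maxit Iteration budget; exceeding it is an error.
#' @param outer_bc `"ground"` (default) or `"analytic_disk"`.
#' @param neumann_layers Optional character vector of layer names treated
#'   as perfect insulators (removed from the domain; their interface
#'   becomes a Neumann boundary). Only extreme layers may be named.
#' @return Object of class `cbc_field` with the grid axes, the potential
#'   array (V), solver diagnostics, and the inputs.
#' @export
solve_potential <- function(volume, electrode, drive = 1,
                            grid_spacing = 10, tol = 1e-8, maxit = 20000L,
                            outer_bc = c("ground", "analytic_disk"),
                            neumann_layers = character(0)) {
  stopifnot(inherits(volume, "cbc_volume"), inherits(electrode, "cbc_electrode"),
            is.finite(drive))
  outer_bc <- match.arg(outer_bc)
  lay <- volume$layers
  if (length(neumann_layers)) {
    keep <- !(lay$name %in% neumann_layers)
    if (!any(keep)) stop("cannot remove all layers")
    if (any(diff(which(keep)) != 1))
      stop("neumann_layers must be extreme (outermost) layers")
    lay <- lay[keep, , drop = FALSE]
  }
  h <- grid_spacing
  if (any(abs(lay$thickness / h - round(lay$thickness / h)) > 1e-9))
    stop("grid_spacing must divide every layer thickness")
  if (abs(volume$edge / 2 / h - round(volume$edge / 2 / h)) > 1e-9)
    stop("grid_spacing must divide half the lateral edge")

  xs <- seq(-volume$edge / 2, volume$edge / 2, by = h)
  ys <- xs
  zs <- seq(min(lay$z_bottom), max(lay$z_top), by = h)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)

  # conductivity of the z-cell between zs[k] and zs[k+1]
  zmid <- (zs[-nz] + zs[-1]) / 2
  sig_cell <- vapply(zmid, function(z) {
    i <- which(z > lay$z_bottom & z < lay$z_top)
    1 / lay$resistivity[i]
  }, numeric(1))
  # finite-volume edge conductances: each face contributes
  # sigma * (face area)/h with quarter-cell weighting, so faces on the
  # domain boundary carry half (or quarter) weight and layer interfaces
  # get the parallel average of the adjacent cells
  sig_lat <- numeric(nz) # sum of half-contributions from the z-cells
  for (k in seq_len(nz)) {
    below <- if (k > 1) sig_cell[k - 1] else 0
    above <- if (k < nz) sig_cell[k] else 0
    sig_lat[k] <- (below + above) / 2
  }
  N <- nx * ny * nz
  igrid <- rep(seq_len(nx), times = ny * nz)
  jgrid <- rep(rep(seq_len(ny), each = nx), nz)
  kgrid <- rep(seq_len(nz), each = nx * ny)
  half_x <- ifelse(igrid == 1 | igrid == nx, 0.5, 1)
  half_y <- ifelse(jgrid == 1 | jgrid == ny, 0.5, 1)
  lat <- sig_lat[kgrid]
  Gx <- lat * half_y
  Gy <- lat * half_x
  Gx[igrid == nx] <- 0
  Gy[jgrid == ny] <- 0
  Gz <- c(rep(sig_cell, each = nx * ny), rep(0, nx * ny)) * half_x * half_y

  # Dirichlet sets
  fixed <- integer(N); fval <- numeric(N)
  xg <- rep(xs, times = ny * nz)
  yg <- rep(rep(ys, each = nx), nz)
  zg <- rep(zs, each = nx * ny)
  a <- electrode$diameter / 2
  r2 <- (xg - electrode$center[1])^2 + (yg - electrode$center[2])^2
  el <- r2 <= a^2 & zg >= 0 & zg <= electrode$height
  fixed[el] <- 1L; fval[el] <- drive

  if (outer_bc == "ground") {
    gz <- lay[lay$grounded, , drop = FALSE]
    if (nrow(gz)) {
      inband <- rep(FALSE, N)
      for (i in seq_len(nrow(gz)))
        inband <- inband | (zg >= gz$z_bottom[i] & zg <= gz$z_top[i])
      onside <- xg %in% range(xs) | yg %in% range(ys)
      sel <- inband & onside & !el
      fixed[sel] <- 1L; fval[sel] <- 0
    }
  } else {
    if (length(unique(lay$resistivity)) != 1)
      stop("analytic_disk boundary requires a homogeneous volume")
    if (min(lay$z_bottom) < 0)
      stop("analytic_disk boundary requires a half-space (z >= 0) volume")
    onface <- (xg %in% range(xs) | yg %in% range(ys) | zg == max(zs)) & !el
    rr <- sqrt((xg - electrode$center[1])^2 + (yg - electrode$center[2])^2)
    fixed[onface] <- 1L
    fval[onface] <- disk_potential_analytic(rr[onface], zg[onface], a, drive)
  }

  sol <- field_cg_cpp(nx, ny, nz, Gx, Gy, Gz, fixed, fval, tol, as.integer(maxit))
  if (drive != 0 && sol$relres > tol && sol$iterations >= maxit)
    stop(sprintf("field solver did not converge: relres %.3g after %d iterations",
                 sol$relres, sol$iterations))
  structure(list(x = xs, y = ys, z = zs,
                 v = array(sol$v, dim = c(nx, ny, nz)),
                 drive = drive, spacing = h,
                 iterations = sol$iterations, relres = sol$relres,
                 volume = volume, electrode = electrode,
                 outer_bc = outer_bc),
            class = "cbc_field")
}

#' @export
print.cbc_field <- function(x, ...) {
  cat(sprintf("<cbc_field> %dx%dx%d grid, h = %g um, drive %g V\n",
              length(x$x), length(x$y), length(x$z), x$spacing, x$drive))
  cat(sprintf("  CG iterations %d, relative residual %.2e\n",
              x$iterations, x$relres))
  invisible(x)
}

#' Sample the potential at arbitrary points
#'
#' Trilinear interpolation from the grid nodes; exact at nodes. Points
#' must lie inside the solved volume.
#'
#' @param field A `cbc_field`.
#' @param points Numeric matrix (n x 3) or data frame with columns x, y, z
#'   in um.
#' @return Numeric vector of potentials (V).
#' @export
sample_potential <- function(field, points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  xs <- field$x; ys <- field$y; zs <- field$z
  if (any(points[, 1] < xs[1] | points[, 1] > xs[length(xs)] |
          points[, 2] < ys[1] | points[, 2] > ys[length(ys)] |
          points[, 3] < zs[1] | points[, 3] > zs[length(zs)]))
    stop("point outside the solved volume")
  h <- field$spacing
  fx <- (points[, 1] - xs[1]) / h
  fy <- (points[, 2] - ys[1]) / h
  fz <- (points[, 3] - zs[1]) / h
  i0 <- pmin(pmax(floor(fx), 0), length(xs) - 2)
  j0 <- pmin(pmax(floor(fy), 0), length(ys) - 2)
  k0 <- pmin(pmax(floor(fz), 0), length(zs) - 2)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  v <- field$v
  g <- function(di, dj, dk) {
    v[cbind(i0 + 1 + di, j0 + 1 + dj, k0 + 1 + dk)]
  }
  (1 - tx) * (1 - ty) * (1 - tz) * g(0, 0, 0) +
    tx * (1 - ty) * (1 - tz) * g(1, 0, 0) +
    (1 - tx) * ty * (1 - tz) * g(0, 1, 0) +
    tx * ty * (1 - tz) * g(1, 1, 0) +
    (1 - tx) * (1 - ty) * tz * g(0, 0, 1) +
    tx * (1 - ty) * tz * g(1, 0, 1) +
    (1 - tx) * ty * tz * g(0, 1, 1) +
    tx * ty * tz * g(1, 1, 1)
}

#' Place a cell in the volume
#'
#' Translates cell-local coordinates into the volume frame: the soma is
#' centred over the electrode in x and y (plus optional shifts) and the
#' lowest compartment (the dendritic tree top facing the implant) sits
#' `tip_distance` um above the interface.
#'
#' @param cell A `cbc_cell`.
#' @param dx,dy,dz Shifts of the cell relative to the standard placement, um.
#' @param tip_distance Distance of the dendritic tip from the interface, um.
#' @param electrode Electrode whose centre defines x = y = 0.
#' @return n x 3 matrix of compartment centres in the volume frame.
#' @export
place_cell <- function(cell, dx = 0, dy = 0, dz = 0, tip_distance = 25,
                       electrode = electrode_spec()) {
  df <- cell$compartments
  soma <- df[df$region == "soma", ]
  cbind(x = df$x - soma$x + electrode$center[1] + dx,
        y = df$y - soma$y + electrode$center[2] + dy,
        z = df$z - min(df$z) + tip_distance + dz)
}

#' Extracellular potential per compartment for a shifted cell
#'
#' Samples the (fixed) field at the compartment centres of a cell shifted
#' by `(dx, dz)` from its standard placement; one pixel of the position
#' maps corresponds to a 2 um shift.
#'
#' @param field A `cbc_field`.
#' @param cell A `cbc_cell`.
#' @param dx,dz Lateral and axial shift in um.
#' @param ... Passed to [place_cell()].
#' @return Potential (V) per compartment.
#' @export
shift_cell <- function(field, cell, dx = 0, dz = 0, ...) {
  sample_potential(field, place_cell(cell, dx = dx, dz = dz,
                                     electrode = field$electrode, ...))
}
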