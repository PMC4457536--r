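# Morphology generation: compartmentalised ON / OFF cone bipolar cell
# geometries. Compartments are cylinders (processes) or a sphere (soma)
# arranged as a tree; the electrode-facing dendrites sit at low z and the
# axon terminal system at high z.

#' Morphology specification
#'
#' Describes how a compartmentalised bipolar-cell geometry is generated:
#' an ordered region layout (dendrite, soma, axon, terminal) stacked along
#' +z away from the electrode plane, compartment counts and branch counts
#' per region, and the seeded depth (y) randomisation. The two packaged
#' specs [on_spec()] and [off_spec()] emulate a rat type-9 ON cell
#' (94 compartments) and a type-3 OFF cell (78 compartments).
#'
#' @param cell_type `"ON_type9"` or `"OFF_type3"`.
#' @param target_compartments Total compartment count the layout must reach.
#' @param soma_diameter Soma diameter in um.
#' @param region_layout Data frame with columns `region` (character:
#'   dendrite/axon/terminal), `z_extent` (um), `n_branches`,
#'   `n_compartments` (total in region), `diameter` (um) and `spread`
#'   (lateral radius of the branch fan, um). The soma is implicit.
#' @param depth_sigma_fraction Standard deviation of the confined normal
#'   depth (y) randomisation, as a fraction of each branch's 2D extent;
#'   draws are truncated at +/- 2 sigma.
#' @param seed Integer seed; morphology generation is deterministic for a
#'   fixed seed.
#' @return Object of class `cbc_spec`.
#' @seealso [build_cell()], [on_spec()], [off_spec()]
#' @export
morphology_spec <- function(cell_type = c("ON_type9", "OFF_type3"),
                            target_compartments,
                            soma_diameter,
                            region_layout,
                            depth_sigma_fraction = 0.15,
                            seed = 1L) {
  cell_type <- match.arg(cell_type)
  stopifnot(is.data.frame(region_layout),
            all(c("region", "z_extent", "n_branches", "n_compartments",
                  "diameter", "spread") %in% names(region_layout)))
  if (!all(region_layout$region %in% c("dendrite", "axon", "terminal")))
    stop("region labels must be dendrite, axon or terminal (soma is implicit)")
  if (target_compartments <= 0) stop("target_compartments must be positive")
  if (soma_diameter <= 0) stop("soma_diameter must be positive")
  structure(list(cell_type = cell_type,
                 target_compartments = as.integer(target_compartments),
                 soma_diameter = soma_diameter,
                 region_layout = region_layout,
                 depth_sigma_fraction = depth_sigma_fraction,
                 seed = as.integer(seed)),
            class = "cbc_spec")
}

#' Packaged ON (type 9) morphology spec: 94 compartments
#'
#' Long-axon ON cone bipolar cell: 36 dendritic compartments on 6 branches,
#' a spherical soma (11 um), a 60 um axon of 34 compartments and 23
#' terminal compartments on 4 branches. Region extents and branch counts
#' are canonical synthetic stand-ins chosen to reproduce the qualitative
#' polarisation pattern of a long perpendicular fibre; they are not traced
#' coordinates.
#'
#' @param seed Integer seed for the depth randomisation.
#' @return A `cbc_spec`.
#' @export
on_spec <- function(seed = 1L) {
  layout <- data.frame(
    region = c("dendrite", "axon", "terminal"),
    z_extent = c(15, 60, 12),
    n_branches = c(6L, 1L, 4L),
    n_compartments = c(36L, 34L, 23L),
    diameter = c(0.9, 1.2, 1.2),
    spread = c(12, 0, 8))
  morphology_spec("ON_type9", 94L, 11, layout, seed = seed)
}

#' Packaged OFF (type 3) morphology spec: 78 compartments
#'
#' Short-axon OFF cone bipolar cell: 30 dendritic compartments on 6
#' branches, a spherical soma (9 um), a 22 um axon of 12 compartments and a
#' wide terminal system of 35 compartments on 5 branches.
#'
#' @param seed Integer seed for the depth randomisation.
#' @return A `cbc_spec`.
#' @export
off_spec <- function(seed = 1L) {
  layout <- data.frame(
    region = c("dendrite", "axon", "terminal"),
    z_extent = c(14, 22, 10),
    n_branches = c(6L, 1L, 5L),
    n_compartments = c(30L, 12L, 35L),
    diameter = c(0.9, 1.2, 1.2),
    spread = c(11, 0, 9))
  morphology_spec("OFF_type3", 78L, 9, layout, seed = seed)
}

#' Per-compartment electrical properties
#'
#' Half axial resistance and membrane capacitance of a compartment. A
#' cylinder of length L and diameter d has half resistance
#' `rho_a * (L/2) / (pi (d/2)^2)`; the spherical soma is treated as a
#' cylinder of length equal to its diameter for the axial path (the cable
#' equations need a finite half-resistance and the sphere has no natural
#' one). Capacitance is the specific membrane capacitance times the surface
#' area (lateral area for cylinders, full area for the sphere).
#'
#' @param length Cylinder length in um (ignored for spheres).
#' @param diameter Diameter in um.
#' @param shape `"cylinder"` or `"sphere"`.
#' @param rho_a Axial resistivity in Ohm cm.
#' @param cm Specific membrane capacitance in uF/cm^2.
#' @return List with `r_half` (kOhm), `capacitance` (uF), `area` (um^2),
#'   `volume` (um^3) and `s_over_v` (1/um).
#' @examples
#' # 10 um x 1 um cylinder at 130 Ohm cm: about 8276 kOhm
#' compartment_electrics(10, 1)$r_half
#' @export
compartment_electrics <- function(length, diameter,
                                  shape = c("cylinder", "sphere"),
                                  rho_a = cbc_constants()$rho_a,
                                  cm = cbc_constants()$cm) {
  shape <- match.arg(shape)
  if (any(diameter <= 0)) stop("diameter must be positive")
  if (shape == "cylinder" && any(length <= 0)) stop("length must be positive")
  r_cm <- diameter / 2 * 1e-4
  if (shape == "sphere") length <- diameter
  l_cm <- length * 1e-4
  r_half <- rho_a * (l_cm / 2) / (pi * r_cm^2) / 1000 # kOhm
  if (shape == "sphere") {
    area <- 4 * pi * (diameter / 2)^2
    volume <- 4 / 3 * pi * (diameter / 2)^3
  } else {
    area <- pi * diameter * length
    volume <- pi * (diameter / 2)^2 * length
  }
  list(r_half = r_half,
       capacitance = cm * area * 1e-8, # uF
       area = area,
       volume = volume,
       s_over_v = area / volume)
}

# confined normal draw: sd sigma, truncated at +/- 2 sigma
.trunc_norm <- function(n, sigma) {
  if (sigma <= 0) return(rep(0, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, 0, sigma)
      if (abs(x) <= 2 * sigma) break
    }
    out[i] <- x
  }
  out
}

# chain of n compartments along the segment p0 -> p1, attached to parent_id
.add_branch <- function(df, p0, p1, n, diameter, region, parent_id) {
  vec <- p1 - p0
  for (k in seq_len(n)) {
    a <- p0 + vec * (k - 1) / n
    b <- p0 + vec * k / n
    ctr <- (a + b) / 2
    el <- compartment_electrics(sqrt(sum(vec^2)) / n, diameter, "cylinder")
    id <- nrow(df) + 1L
    df[id, ] <- list(id, region, "cylinder",
                     ctr[1], ctr[2], ctr[3],
                     a[1], a[2], a[3], b[1], b[2], b[3],
                     sqrt(sum(vec^2)) / n, diameter,
                     el$area, el$volume, el$r_half, el$capacitance,
                     el$s_over_v,
                     if (k == 1) parent_id else id - 1L)
  }
  df
}

.empty_comp_df <- function() {
  data.frame(id = integer(), region = character(), shape = character(),
             x = numeric(), y = numeric(), z = numeric(),
             x0 = numeric(), y0 = numeric(), z0 = numeric(),
             x1 = numeric(), y1 = numeric(), z1 = numeric(),
             length = numeric(), diameter = numeric(),
             area = numeric(), volume = numeric(),
             r_half = numeric(), capacitance = numeric(),
             s_over_v = numeric(), parent = integer(),
             stringsAsFactors = FALSE)
}

#' Build a compartmentalised cell from a morphology spec
#'
#' Generates the 3D compartment tree: dendritic branches fan downward from
#' the soma toward the electrode plane (low z), the axon rises from the
#' soma, and terminal branches fan outward from the axon tip. The lateral
#' (x) layout of branches is deterministic; extent into depth (y) uses a
#' confined normally distributed random variable (sd =
#' `depth_sigma_fraction` x branch 2D extent, truncated at 2 sigma) under
#' the spec seed, so the result is reproducible. Coordinates are in a
#' cell-local frame with the lowest dendritic tip at z = 0; placement
#' relative to the electrode happens at sampling time.
#'
#' @param spec A [morphology_spec()].
#' @return Object of class `cbc_cell`: a compartment table (see
#'   [compartment_electrics()] for the electrical columns) plus the spec.
#' @examples
#' cell <- build_cell(on_spec())
#' nrow(cell$compartments) # 94
#' @export
build_cell <- function(spec) {
  stopifnot(inherits(spec, "cbc_spec"))
  lay <- spec$region_layout
  if (any(lay$n_branches > lay$n_compartments))
    stop("unreachable target: a region has more branches than compartments")
  if (sum(lay$n_compartments) + 1L != spec$target_compartments)
    stop(sprintf(
      "unreachable target count: layout gives %d compartments, spec wants %d",
      sum(lay$n_compartments) + 1L, spec$target_compartments))
  if (!identical(lay$region, c("dendrite", "axon", "terminal")))
    stop("region_layout must list dendrite, axon, terminal in order")

  # seeded but isolated RNG stream
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  dend <- lay[lay$region == "dendrite", ]
  axon <- lay[lay$region == "axon", ]
  term <- lay[lay$region == "terminal", ]
  r_soma <- spec$soma_diameter / 2
  z_soma_bottom <- dend$z_extent
  z_soma_center <- z_soma_bottom + r_soma
  z_axon_base <- z_soma_bottom + spec$soma_diameter
  z_axon_top <- z_axon_base + axon$z_extent
  z_term_top <- z_axon_top + term$z_extent

  df <- .empty_comp_df()
  el <- compartment_electrics(spec$soma_diameter, spec$soma_diameter, "sphere")
  df[1, ] <- list(1L, "soma", "sphere", 0, 0, z_soma_center,
                  0, 0, z_soma_bottom, 0, 0, z_axon_base,
                  spec$soma_diameter, spec$soma_diameter,
                  el$area, el$volume, el$r_half, el$capacitance,
                  el$s_over_v, NA_integer_)

  split_branches <- function(total, nb) {
    base <- total %/% nb
    extra <- total %% nb
    rep(base, nb) + c(rep(1L, extra), rep(0L, nb - extra))
  }

  # dendritic fan: branch b runs from the soma bottom to a tip at z ~ 0
  nb <- dend$n_branches
  per <- split_branches(dend$n_compartments, nb)
  theta <- 2 * pi * (seq_len(nb) - 1) / nb
  radius <- dend$spread * (0.55 + 0.45 * seq_len(nb) / nb)
  for (b in seq_len(nb)) {
    tip_xz <- c(radius[b] * cos(theta[b]), 0)
    ext2d <- sqrt(sum((c(tip_xz[1], 0) - c(0, z_soma_bottom))^2))
    ytip <- .trunc_norm(1, spec$depth_sigma_fraction * ext2d)
    df <- .add_branch(df, c(0, 0, z_soma_bottom),
                      c(tip_xz[1], ytip, 0), per[b],
                      dend$diameter, "dendrite", 1L)
  }

  # axon: straight vertical chain from the soma top
  df <- .add_branch(df, c(0, 0, z_axon_base), c(0, 0, z_axon_top),
                    axon$n_compartments, axon$diameter, "axon", 1L)
  axon_tip_id <- nrow(df)

  # terminal fan from the axon tip
  nb <- term$n_branches
  per <- split_branches(term$n_compartments, nb)
  theta <- 2 * pi * (seq_len(nb) - 1) / nb + pi / nb
  radius <- term$spread * (0.55 + 0.45 * seq_len(nb) / nb)
  for (b in seq_len(nb)) {
    tipx <- radius[b] * cos(theta[b])
    ext2d <- sqrt(tipx^2 + term$z_extent^2)
    ytip <- .trunc_norm(1, spec$depth_sigma_fraction * ext2d)
    df <- .add_branch(df, c(0, 0, z_axon_top),
                      c(tipx, ytip, z_term_top), per[b],
                      term$diameter, "terminal", axon_tip_id)
  }

  # shift so the lowest compartment centre sits at z = 0
  zmin <- min(df$z)
  df$z <- df$z - zmin; df$z0 <- df$z0 - zmin; df$z1 <- df$z1 - zmin

  cell <- structure(list(spec = spec, compartments = df), class = "cbc_cell")
  validate_cell(cell)
  cell
}

#' @export
print.cbc_cell <- function(x, ...) {
  df <- x$compartments
  cat(sprintf("<cbc_cell> %s: %d compartments (%s)\n",
              x$spec$cell_type, nrow(df),
              paste(sprintf("%s %d", names(table(df$region)),
                            as.integer(table(df$region))), collapse = ", ")))
  cat(sprintf("  z extent %.1f um, total membrane area %.1f um^2\n",
              max(df$z1, df$z) - min(df$z0, df$z), sum(df$area)))
  invisible(x)
}

#' @export
summary.cbc_cell <- function(object, ...) {
  df <- object$compartments
  agg <- do.call(rbind, lapply(split(df, df$region), function(d)
    data.frame(region = d$region[1], n = nrow(d),
               area_um2 = sum(d$area), z_min = min(d$z), z_max = max(d$z))))
  rownames(agg) <- NULL
  agg
}

#' @export
plot.cbc_cell <- function(x, ...) {
  df <- x$compartments
  cols <- c(dendrite = "#D55E00", soma = "#009E73",
            axon = "#9467bd", terminal = "#E6C229")
  plot(df$x, df$z, pch = 16, cex = 0.6, col = cols[df$region],
       xlab = "x (um)", ylab = "z (um)", asp = 1,
       main = x$spec$cell_type, ...)
  legend("topright", legend = names(cols), col = cols, pch = 16, cex = 0.8)
  invisible(x)
}

#' Validate the structural invariants of a cell
#'
#' Checks that there is exactly one (spherical) soma at the tree root, that
#' the compartment graph is a connected tree (n - 1 parent edges, parents
#' precede children), and that areas/volumes are consistent with the shape
#' formulas.
#'
#' @param cell A `cbc_cell`.
#' @return The cell, invisibly; errors on violation.
#' @export
validate_cell <- function(cell) {
  df <- cell$compartments
  if (sum(df$region == "soma") != 1L) stop("cell must have exactly one soma")
  if (!is.na(df$parent[1]) || df$region[1] != "soma")
    stop("soma must be the tree root (first compartment)")
  if (any(is.na(df$parent[-1]))) stop("orphan compartments present")
  if (any(df$parent[-1] >= df$id[-1]))
    stop("parents must precede children (Hines ordering)")
  cyl <- df$shape == "cylinder"
  if (any(abs(df$area[cyl] - pi * df$diameter[cyl] * df$length[cyl]) >
          1e-6 * df$area[cyl]))
    stop("cylinder surface areas inconsistent")
  if (any(df$r_half <= 0)) stop("half axial resistances must be positive")
  invisible(cell)
}

#' Rescale the axonal z-extent of a cell
#'
#' Compresses (factor < 1) or elongates (factor > 1) the axonal and
#' terminal portions of the cell along z about the soma centre:
#' `z' = z_soma + factor * (z - z_soma)` for axon and terminal
#' compartments. Lateral coordinates, diameters and the per-compartment
#' electrical properties are left untouched, so the membrane area and
#' compartment count are invariant and only the geometry each compartment
#' samples the extracellular field at changes.
#'
#' @param cell A `cbc_cell`.
#' @param factor Positive scale factor (1 = identity).
#' @return The rescaled `cbc_cell`.
#' @export
scale_axon <- function(cell, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("factor must be a positive scalar")
  df <- cell$compartments
  zs <- df$z[df$region == "soma"]
  sel <- df$region %in% c("axon", "terminal")
  for (col in c("z", "z0", "z1"))
    df[[col]][sel] <- zs + factor * (df[[col]][sel] - zs)
  cell$compartments <- df
  attr(cell, "axon_scale") <- factor
  cell
}

#' Cell z extent (um)
#' @param cell A `cbc_cell`.
#' @return Span of compartment centres along z.
#' @export
cell_z_extent <- function(cell) {
  diff(range(cell$compartments$z))
}

#' Read / write morphology specs as YAML
#'
#' The YAML mirrors the [morphology_spec()] fields; `region_layout` is a
#' list of per-region mappings.
#'
#' @param path YAML file path.
#' @return `read_morphology_yaml`: a `cbc_spec`.
#' @export
read_morphology_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  lay <- do.call(rbind, lapply(cfg$region_layout, as.data.frame))
  morphology_spec(cfg$cell_type, cfg$target_compartments,
                  cfg$soma_diameter, lay,
                  depth_sigma_fraction = cfg$depth_sigma_fraction %||% 0.15,
                  seed = cfg$seed %||% 1L)
}

#' @rdname read_morphology_yaml
#' @param spec A `cbc_spec`.
#' @return `write_morphology_yaml`: `path`, invisibly.
#' @export
write_morphology_yaml <- function(spec, path) {
  lay <- lapply(seq_len(nrow(spec$region_layout)), function(i)
    as.list(spec$region_layout[i, ]))
  yaml::write_yaml(list(cell_type = spec$cell_type,
                        target_compartments = spec$target_compartments,
                        soma_diameter = spec$soma_diameter,
                        region_layout = lay,
                        depth_sigma_fraction = spec$depth_sigma_fraction,
                        seed = spec$seed), path)
  invisible(path)
}
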