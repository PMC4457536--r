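# SWC import/export. Standard 7 columns: sample, type, x, y, z, radius,
# parent. Type codes used here: 1 = soma, 2 = axon, 3 = dendrite,
# 5 = axon terminal (custom). Nodes are written at the distal endpoint of
# each compartment (soma at its centre), so inter-node distances recover
# compartment lengths within unbranched chains; the compartment attached
# to the soma absorbs the soma-attachment offset, as in any SWC
# reconstruction.

.swc_type_codes <- c(soma = 1L, axon = 2L, dendrite = 3L, terminal = 5L)

#' Write a cell to an SWC file
#'
#' @param cell A `cbc_cell`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(cell, path) {
  df <- cell$compartments
  type <- .swc_type_codes[df$region]
  x <- ifelse(df$shape == "sphere", df$x, df$x1)
  y <- ifelse(df$shape == "sphere", df$y, df$y1)
  z <- ifelse(df$shape == "sphere", df$z, df$z1)
  out <- data.frame(sample = df$id, type = type,
                    x = x, y = y, z = z,
                    radius = df$diameter / 2,
                    parent = ifelse(is.na(df$parent), -1L, df$parent))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC export (cbcstim); types: 1 soma, 2 axon, 3 dendrite, 5 terminal", con)
  write.table(format(out, digits = 10, scientific = FALSE, trim = TRUE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cell from an SWC file
#'
#' Rebuilds a compartment tree from a 7-column SWC file. The root must be a
#' soma node (modelled as a sphere of the stored radius); every other node
#' becomes a cylindrical compartment spanning from its parent node (clipped
#' to the soma surface for soma children) to its own coordinate. Files with
#' orphan nodes or cyclic parent links are rejected.
#'
#' @param path SWC file path.
#' @param cell_type Optional cell-type label for the rebuilt cell.
#' @return A `cbc_cell`.
#' @export
read_swc <- function(path, cell_type = "ON_type9") {
  raw <- read.table(path, comment.char = "#",
                    col.names = c("sample", "type", "x", "y", "z",
                                  "radius", "parent"))
  if (nrow(raw) == 0) stop("empty SWC file")
  raw <- raw[order(raw$sample), ]
  id_map <- match(raw$parent, raw$sample)
  root <- which(raw$parent == -1)
  if (length(root) != 1) stop("SWC must contain exactly one root node")
  if (any(is.na(id_map[-root]))) stop("SWC contains orphan nodes")
  # cycle / ordering check: walk each node to the root
  for (i in seq_len(nrow(raw))) {
    seen <- integer(0); j <- i
    while (raw$parent[j] != -1) {
      if (j %in% seen) stop("SWC contains a cycle")
      seen <- c(seen, j)
      j <- id_map[j]
      if (length(seen) > nrow(raw)) stop("SWC contains a cycle")
    }
  }
  if (raw$type[root] != 1) stop("SWC root must be a soma node (type 1)")

  # re-order so parents precede children (keep file order when already valid)
  ok_order <- root == 1 && all(id_map[-root] < seq_len(nrow(raw))[-root])
  if (!ok_order) {
    order_idx <- root
    frontier <- root
    while (length(order_idx) < nrow(raw)) {
      frontier <- setdiff(which(id_map %in% frontier), c(root, order_idx))
      if (length(frontier) == 0) stop("SWC graph is not connected")
      order_idx <- c(order_idx, frontier)
    }
    raw <- raw[order_idx, ]
    id_map <- match(raw$parent, raw$sample)
  }

  region_of <- names(.swc_type_codes)[match(raw$type, .swc_type_codes)]
  if (any(is.na(region_of))) stop("unknown SWC type code")

  df <- .empty_comp_df()
  d_soma <- 2 * raw$radius[1]
  el <- compartment_electrics(d_soma, d_soma, "sphere")
  df[1, ] <- list(1L, "soma", "sphere", raw$x[1], raw$y[1], raw$z[1],
                  raw$x[1], raw$y[1], raw$z[1] - d_soma / 2,
                  raw$x[1], raw$y[1], raw$z[1] + d_soma / 2,
                  d_soma, d_soma, el$area, el$volume, el$r_half,
                  el$capacitance, el$s_over_v, NA_integer_)
  if (nrow(raw) > 1) {
    for (i in 2:nrow(raw)) {
      p <- id_map[i]
      p0 <- c(raw$x[p], raw$y[p], raw$z[p])
      p1 <- c(raw$x[i], raw$y[i], raw$z[i])
      if (p == 1) { # clip to the soma surface along the chord
        vec <- p1 - p0
        len <- sqrt(sum(vec^2))
        if (len > d_soma / 2) p0 <- p0 + vec / len * (d_soma / 2)
      }
      len <- sqrt(sum((p1 - p0)^2))
      if (len <= 0) stop("zero-length SWC segment")
      dia <- 2 * raw$radius[i]
      el <- compartment_electrics(len, dia, "cylinder")
      df[i, ] <- list(as.integer(i), region_of[i], "cylinder",
                      mean(c(p0[1], p1[1])), mean(c(p0[2], p1[2])),
                      mean(c(p0[3], p1[3])),
                      p0[1], p0[2], p0[3], p1[1], p1[2], p1[3],
                      len, dia, el$area, el$volume, el$r_half,
                      el$capacitance, el$s_over_v, as.integer(p))
    }
  }
  spec <- structure(list(cell_type = cell_type,
                         target_compartments = nrow(df),
                         soma_diameter = d_soma,
                         region_layout = NULL,
                         depth_sigma_fraction = NA_real_,
                         seed = NA_integer_),
                    class = "cbc_spec")
  cell <- structure(list(spec = spec, compartments = df), class = "cbc_cell")
  validate_cell(cell)
  cell
}
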