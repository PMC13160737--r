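#' Geometry of one SR element
#'
#' A single sarcoplasmic reticulum element is formalised as a cylinder of
#' radius 15 nm and length 1.8 um (half the sarcomere length), running from
#' the cisternal release face to the mid-sarcomere closed end. Faces are
#' tagged F1 (closed LSR midpoint end), F2 (cisternal CSR release end) and
#' F3 (lateral membrane). The axial coordinate has x = 0 at F2 (CSR) and
#' x = axial_length at F1.
#'
#' @param radius cylinder radius, m (default 1.5e-8).
#' @param axial_length cylinder length, m (default 1.8e-6). A warning is
#'   issued if the aspect ratio `axial_length / radius` falls below 10,
#'   since the 1D axial reduction then becomes questionable.
#' @return An object of class `sr_geometry` with the radius, length, face
#'   areas (`area_F2 = pi r^2`, `area_F3 = 2 pi r L`) and total volume.
#' @examples
#' g <- sr_geometry()
#' g$volume   # 1.2723e-21 m^3
#' @export
sr_geometry <- function(radius = 1.5e-8, axial_length = 1.8e-6) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0,
            is.numeric(axial_length), length(axial_length) == 1L,
            axial_length > 0)
  if (axial_length / radius < 10)
    warning("axial_length/radius < 10: the element is not slender; ",
            "the 1D axial reduction may be inaccurate")
  g <- list(
    radius = radius,
    axial_length = axial_length,
    area_F2 = pi * radius^2,
    area_F3 = 2 * pi * radius * axial_length,
    volume = pi * radius^2 * axial_length,
    face_tags = c(F1 = "closed LSR-midpoint end", F2 = "CSR release end",
                  F3 = "lateral membrane")
  )
  class(g) <- "sr_geometry"
  g
}

#' @export
print.sr_geometry <- function(x, ...) {
  cat(sprintf("SR element cylinder: radius %.3g m, length %.3g m\n",
              x$radius, x$axial_length))
  cat(sprintf("  F2 (CSR) area %.4g m^2, F3 (lateral) area %.4g m^2, ",
              x$area_F2, x$area_F3))
  cat(sprintf("volume %.4g m^3\n", x$volume))
  invisible(x)
}

#' 1D axial finite-volume grid
#'
#' Uniform vertex-centred grid on `[0, axial_length]` with x = 0 at the CSR
#' face (F2) and x = axial_length at the closed LSR end (F1). Node control
#' volumes are `pi r^2 dx` (half-cells at the two ends), so the volumes sum
#' exactly to the cylinder volume.
#'
#' @param geometry an [sr_geometry()] object.
#' @param spacing target node spacing, m (default 1e-8 = 10 nm, the meshing
#'   resolution used throughout); the actual spacing divides the length
#'   exactly.
#' @return An object of class `sr_grid` with `mode = "axial_1d"`, node
#'   coordinates `x`, spacing `h`, control volumes `volumes`, and face tags
#'   per node (`"F2"` at node 1, `"F1"` at the last node, `""` inside; every
#'   node additionally abuts the lateral face F3 in the 1D reduction).
#' @export
axial_grid <- function(geometry = sr_geometry(), spacing = 1e-8) {
  stopifnot(inherits(geometry, "sr_geometry"))
  L <- geometry$axial_length
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0 ||
      spacing > L)
    stop("spacing must lie in (0, axial_length]")
  n_cells <- max(1L, as.integer(round(L / spacing)))
  h <- L / n_cells
  x <- seq(0, L, length.out = n_cells + 1L)
  A <- geometry$area_F2
  vol <- rep(A * h, n_cells + 1L)
  vol[c(1L, n_cells + 1L)] <- A * h / 2
  tags <- rep("", n_cells + 1L)
  tags[1L] <- "F2"; tags[n_cells + 1L] <- "F1"
  g <- list(mode = "axial_1d", geometry = geometry, x = x, h = h,
            n_nodes = n_cells + 1L, volumes = vol, face_tags = tags)
  class(g) <- "sr_grid"
  g
}

#' 2D axisymmetric finite-volume grid
#'
#' Discretises the (r, z) half-plane rectangle `[0, radius] x [0,
#' axial_length]` with the cylindrical measure `2 pi r dr dz`. Radially the
#' grid is cell-centred (ring cells with exact annular volumes); axially it
#' is vertex-centred with the same spacing rule as [axial_grid()], so that
#' in the absence of radial forcing the axial operator coincides with the
#' 1D grid's. Edge tags: z = 0 -> F2, z = axial_length -> F1, r = radius ->
#' F3; the symmetry axis r = 0 carries no tag (natural no-flux).
#'
#' @param geometry an [sr_geometry()] object.
#' @param hmax maximal edge length, m (default 1e-8 = 10 nm); must not
#'   exceed the radius.
#' @return An object of class `sr_grid` with `mode = "axisymmetric_2d"`:
#'   radial cell centres `r`, radial cell edges `r_edges`, axial nodes `z`,
#'   ring cross-section areas `ring_area` (summing to `pi r^2`), the
#'   volume matrix `volumes` (`n_r x n_z`, summing to the cylinder volume),
#'   and spacings `dr`, `hz`.
#' @export
axisymmetric_grid <- function(geometry = sr_geometry(), hmax = 1e-8) {
  stopifnot(inherits(geometry, "sr_geometry"))
  R <- geometry$radius; L <- geometry$axial_length
  if (!is.numeric(hmax) || length(hmax) != 1L || hmax <= 0 || hmax > R)
    stop("hmax must lie in (0, radius]")
  n_r <- max(2L, as.integer(ceiling(R / hmax)))
  dr <- R / n_r
  r_edges <- seq(0, R, length.out = n_r + 1L)
  r <- (r_edges[-1L] + r_edges[-(n_r + 1L)]) / 2
  ring_area <- pi * diff(r_edges^2)            # sums exactly to pi R^2
  n_cells_z <- max(1L, as.integer(round(L / hmax)))
  hz <- L / n_cells_z
  z <- seq(0, L, length.out = n_cells_z + 1L)
  wz <- rep(hz, n_cells_z + 1L)
  wz[c(1L, n_cells_z + 1L)] <- hz / 2
  volumes <- outer(ring_area, wz)
  g <- list(mode = "axisymmetric_2d", geometry = geometry,
            r = r, r_edges = r_edges, z = z, dr = dr, hz = hz,
            n_r = n_r, n_z = n_cells_z + 1L,
            ring_area = ring_area, z_weights = wz, volumes = volumes)
  class(g) <- "sr_grid"
  g
}

#' @export
print.sr_grid <- function(x, ...) {
  if (x$mode == "axial_1d") {
    cat(sprintf("1D axial SR grid: %d nodes, spacing %.3g m\n",
                x$n_nodes, x$h))
  } else {
    cat(sprintf(
      "2D axisymmetric SR grid: %d radial x %d axial nodes (dr %.3g, dz %.3g m)\n",
      x$n_r, x$n_z, x$dr, x$hz))
  }
  invisible(x)
}

#' Export a grid as plain node/element tables
#'
#' @param grid an `sr_grid`.
#' @return A data frame of node coordinates, control volumes and face tags.
#' @export
grid_table <- function(grid) {
  stopifnot(inherits(grid, "sr_grid"))
  if (grid$mode == "axial_1d") {
    data.frame(node = seq_len(grid$n_nodes), x = grid$x,
               volume = grid$volumes, face = grid$face_tags)
  } else {
    idx <- expand.grid(ir = seq_len(grid$n_r), iz = seq_len(grid$n_z))
    face <- character(nrow(idx))
    face[idx$iz == 1L] <- "F2"
    face[idx$iz == grid$n_z] <- "F1"
    outer_ring <- idx$ir == grid$n_r
    face[outer_ring] <- trimws(paste(face[outer_ring], "F3"))
    data.frame(node = seq_len(nrow(idx)), r = grid$r[idx$ir],
               z = grid$z[idx$iz],
               volume = as.vector(grid$volumes), face = face)
  }
}
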