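#' Percent decline of a time series
#'
#' `100 * (value(0) - value(t_end)) / value(0)`, the statistic used to
#' summarise the release-efflux and cisternal free-Ca2+ decays over a
#' simulation window. Invariant under uniform rescaling of the series.
#'
#' @param times sample times, s (must include 0 as the first element).
#' @param values series values at `times`; `values[1]` must be non-zero.
#' @param t_end evaluation time, s (default: last sample). The nearest
#'   sample time is used.
#' @return Percent decline (positive when the series fell).
#' @export
percent_decline <- function(times, values, t_end = max(times)) {
  stopifnot(length(times) == length(values), length(times) >= 2L)
  if (values[1L] == 0) stop("series starts at zero; decline undefined")
  i <- which.min(abs(times - t_end))
  100 * (values[1L] - values[i]) / values[1L]
}

# node values along the axis of a field; for 2D, the cross-section
# area-weighted mean per axial node.
.axial_matrix <- function(field, quantity = c("free", "total")) {
  quantity <- match.arg(quantity)
  m <- if (quantity == "free") free_field(field) else field$total
  if (field$mode == "axial_1d")
    return(list(pos = field$x, mat = m))
  grid <- field$grid
  nr <- grid$n_r; nzn <- grid$n_z
  w <- grid$ring_area / sum(grid$ring_area)
  prof <- matrix(0, nrow(m), nzn)
  for (j in seq_len(nzn))
    prof[, j] <- m[, (j - 1L) * nr + seq_len(nr), drop = FALSE] %*% w
  list(pos = grid$z, mat = prof)
}

#' LSR-minus-CSR free Ca2+ difference
#'
#' Free Ca2+ at the closed LSR-midpoint end (F1) minus free Ca2+ at the
#' cisternal release end (F2) at a given time, reported in uM. Positive
#' while release depletes the cisternal end. Starts at 0 (uniform initial
#' condition).
#'
#' @param field an `sr_field`.
#' @param t evaluation time, s (nearest output sample; default: window
#'   end).
#' @param quantity `"free"` (default) or `"total"`.
#' @return Concentration difference in uM (1 mol m^-3 = 1000 uM).
#' @export
lsr_csr_difference <- function(field, t = max(field$times),
                               quantity = c("free", "total")) {
  stopifnot(inherits(field, "sr_field"))
  ax <- .axial_matrix(field, match.arg(quantity))
  i <- which.min(abs(field$times - t))
  nzn <- length(ax$pos)
  (ax$mat[i, nzn] - ax$mat[i, 1L]) * 1000
}

#' Position-by-time matrix along a sampling line
#'
#' Extracts the exact numeric matrix behind a concentration colour map:
#' rows are positions along the requested line, columns are the output
#' times. Lines: `"axial"` (CSR face to LSR midpoint; cross-section mean
#' for 2D fields) and, for 2D fields, `"radial_F2"` / `"radial_F1"`
#' (across the radius at the cisternal / closed end).
#'
#' @param field an `sr_field`.
#' @param line `"axial"`, `"radial_F2"` or `"radial_F1"`.
#' @param quantity `"free"` or `"total"`.
#' @return A matrix with `dimnames` giving positions (m) and times (s).
#' @export
colormap_matrix <- function(field, line = c("axial", "radial_F2",
                                            "radial_F1"),
                            quantity = c("free", "total")) {
  stopifnot(inherits(field, "sr_field"))
  line <- match.arg(line)
  quantity <- match.arg(quantity)
  if (line == "axial") {
    ax <- .axial_matrix(field, quantity)
    m <- t(ax$mat)
    dimnames(m) <- list(position = signif(ax$pos, 8),
                        time = signif(field$times, 8))
    return(m)
  }
  if (field$mode != "axisymmetric_2d")
    stop("radial lines require an axisymmetric 2D field")
  grid <- field$grid
  nr <- grid$n_r
  vals <- if (quantity == "free") free_field(field) else field$total
  j <- if (line == "radial_F2") 1L else grid$n_z
  cols <- (j - 1L) * nr + seq_len(nr)
  m <- t(vals[, cols, drop = FALSE])
  dimnames(m) <- list(position = signif(grid$r, 8),
                      time = signif(field$times, 8))
  m
}

#' Axial concentration profiles at equally spaced positions
#'
#' Samples the axial line at `n_positions` equally spaced positions
#' (nearest nodes) from the LSR midpoint to the CSR face and returns both
#' free and total position-by-time matrices, the standard reduction behind
#' the multi-trace time-course figures.
#'
#' @param field an `sr_field`.
#' @param n_positions number of sample positions (default 5).
#' @return List with `positions` (m, LSR first), `times`, and matrices
#'   `free`, `total` (position x time).
#' @export
axial_profiles <- function(field, n_positions = 5L) {
  stopifnot(inherits(field, "sr_field"), n_positions >= 2L)
  axf <- .axial_matrix(field, "free")
  axt <- .axial_matrix(field, "total")
  L <- max(axf$pos)
  want <- seq(L, 0, length.out = n_positions)   # LSR -> CSR display order
  idx <- vapply(want, function(p) which.min(abs(axf$pos - p)), integer(1))
  list(positions = axf$pos[idx], times = field$times,
       free = t(axf$mat[, idx, drop = FALSE]),
       total = t(axt$mat[, idx, drop = FALSE]))
}

#' Maximal axial and radial concentration spreads of a 2D run
#'
#' For each output time, the axial spread is the range of the
#' cross-section-mean free Ca2+ along the axis, and the radial spread is
#' the largest within-cross-section range across all axial positions.
#' The maxima over time quantify how one-dimensional the diffusion is.
#'
#' @param field a 2D axisymmetric `sr_field`.
#' @param quantity `"free"` or `"total"`.
#' @return List with `max_axial`, `max_radial` (mol m^-3) and
#'   `log10_ratio`.
#' @export
axial_radial_spread <- function(field, quantity = c("free", "total")) {
  stopifnot(inherits(field, "sr_field"))
  if (field$mode != "axisymmetric_2d")
    stop("spread analysis requires an axisymmetric 2D field")
  quantity <- match.arg(quantity)
  vals <- if (quantity == "free") free_field(field) else field$total
  grid <- field$grid
  nr <- grid$n_r; nzn <- grid$n_z; nt <- nrow(vals)
  ax <- .axial_matrix(field, quantity)$mat
  axial_spread <- apply(ax, 1L, function(v) diff(range(v)))
  radial_spread <- numeric(nt)
  for (j in seq_len(nzn)) {
    block <- vals[, (j - 1L) * nr + seq_len(nr), drop = FALSE]
    rs <- apply(block, 1L, function(v) diff(range(v)))
    radial_spread <- pmax(radial_spread, rs)
  }
  max_ax <- max(axial_spread); max_rad <- max(radial_spread)
  list(max_axial = max_ax, max_radial = max_rad,
       log10_ratio = log10(max_ax / max_rad))
}

#' Headline statistics of one simulation
#'
#' The per-condition summary used throughout: percent declines of the
#' release efflux density and of the cisternal (F2-face) free Ca2+ over
#' the window, and the LSR-minus-CSR free Ca2+ difference at the window
#' end.
#'
#' @param sim an `sr_simulation`.
#' @return A one-row data frame.
#' @export
condition_summary <- function(sim) {
  stopifnot(inherits(sim, "sr_simulation"))
  fl <- sim$fluxes
  fr <- free_field(sim$field)
  csr <- if (sim$field$mode == "axial_1d") fr[, 1L] else {
    grid <- sim$grid
    as.vector(fr[, seq_len(grid$n_r), drop = FALSE] %*% grid$ring_area) /
      sum(grid$ring_area)
  }
  eff_decl <- if (all(fl$efflux_density == 0)) 0 else
    percent_decline(fl$time, fl$efflux_density)
  data.frame(
    duration = sim$config$duration,
    efflux_mode = sim$efflux$mode,
    casq = sim$config$casq_enabled,
    serca = sim$config$serca_enabled,
    efflux_decline_pct = eff_decl,
    csr_free_decline_pct = percent_decline(fl$time, csr),
    lsr_csr_diff_uM = lsr_csr_difference(sim$field)
  )
}
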