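#' Geometric orifice area
#'
#' Approximates the valve orifice as an ellipse from the two free-edge
#' curves projected onto the cross-sectional plane: the major axis is the
#' commissure-to-commissure extent, the minor axis the maximum transverse
#' separation of the two edges, and `GOA = pi/4 * D_major * D_minor`.
#' Returns 0 when the edges overlap or are within `closed_tol` of contact.
#'
#' @param edge1,edge2 ordered m x 3 free-edge point matrices (cm), one per
#'   leaflet (at least 8 points each).
#' @param closed_tol contact tolerance on the transverse separation (cm).
#' @return Orifice area (cm^2), non-negative.
#' @export
geometric_orifice_area <- function(edge1, edge2, closed_tol = 1e-3) {
  edge1 <- node_matrix(edge1); edge2 <- node_matrix(edge2)
  if (nrow(edge1) < 8L || nrow(edge2) < 8L)
    stop("need at least 8 points per free edge")
  all_xy <- rbind(edge1[, 1:2], edge2[, 1:2])
  if (max(apply(all_xy, 2, function(v) diff(range(v)))) < 1e-12) {
    warning("degenerate free-edge projection; returning 0")
    return(0)
  }
  dmaj <- diff(range(all_xy[, 1]))
  ## transverse separation, signed away from the symmetry plane:
  ## edge1 is the +y leaflet, edge2 the -y leaflet (identified by mean y)
  if (mean(edge1[, 2]) < mean(edge2[, 2])) { tmp <- edge1; edge1 <- edge2; edge2 <- tmp }
  dmin <- max(edge1[, 2]) - min(edge2[, 2])
  if (dmin <= closed_tol) return(0)
  pi / 4 * dmaj * dmin
}

#' Lumen mask at a cross-sectional plane
#'
#' Logical nx x ny mask of cells whose centres lie inside the inner wall
#' radius at axial position `plane_z`.
#'
#' @param grid a [fluid_grid].
#' @param params a [geometry_params].
#' @param plane_z axial position (cm).
#' @param box fluid box extents (the vein axis runs through the box
#'   centre).
#' @return Logical matrix (nx x ny).
#' @export
lumen_mask <- function(grid, params, plane_z, box = grid$L) {
  rin <- wall_inner_radius(plane_z, params)
  xc <- (seq_len(grid$n[1]) - 0.5) * grid$h - box[1] / 2
  yc <- (seq_len(grid$n[2]) - 0.5) * grid$h - box[2] / 2
  outer(xc, yc, function(x, y) x^2 + y^2) < rin^2
}

#' Sinus pocket mask
#'
#' Cells inside the bulged sinus pocket: axial position within the sinus
#' window, radial position between the nominal lumen radius and the local
#' inner wall radius.
#'
#' @inheritParams lumen_mask
#' @return Logical 3D array over the fluid cells.
#' @export
sinus_pocket_mask <- function(grid, params, box = grid$L) {
  zw <- sinus_window(params)
  xc <- (seq_len(grid$n[1]) - 0.5) * grid$h - box[1] / 2
  yc <- (seq_len(grid$n[2]) - 0.5) * grid$h - box[2] / 2
  zc <- (seq_len(grid$n[3]) - 0.5) * grid$h
  r2 <- outer(xc, yc, function(x, y) x^2 + y^2)
  R0 <- params$d / 2
  mask <- array(FALSE, grid$n)
  for (k in seq_along(zc)) {
    if (zc[k] <= zw[1] || zc[k] >= zw[2]) next
    rin <- wall_inner_radius(zc[k], params)
    if (rin <= R0 * 1.01) next
    mask[, , k] <- r2 > R0^2 & r2 < rin^2
  }
  mask
}

#' Transvalvular flow rate
#'
#' Volumetric flow rate through a cross-sectional plane:
#' `Q = sum(w * h^2)` over the masked faces nearest `plane_z`.  Positive
#' values are distal-to-proximal (+z) flow.
#'
#' @param state a [fluid_state].
#' @param plane_z axial position of the measurement plane (cm).
#' @param mask logical nx x ny lumen mask (see [lumen_mask]); `NULL`
#'   integrates over the whole cross-section.
#' @return Flow rate (cm^3/s).
#' @export
transvalvular_flow_rate <- function(state, plane_z, mask = NULL) {
  g <- state$grid
  if (plane_z < 0 || plane_z > g$L[3]) stop("plane outside the box")
  k <- round(plane_z / g$h) + 1L
  k <- min(max(k, 1L), dim(state$w)[3])
  wz <- state$w[, , k]
  if (!is.null(mask)) wz <- wz * mask
  sum(wz) * g$h^2
}

#' Stagnant-zone fraction
#'
#' Volume fraction of the masked region where the speed is below the
#' near-stasis threshold (default 1 cm/s), a thrombosis-risk indicator.
#'
#' @param state a [fluid_state].
#' @param mask logical cell mask (e.g. [sinus_pocket_mask]).
#' @param threshold speed threshold (cm/s).
#' @return Fraction in `[0, 1]`.
#' @export
stagnant_fraction <- function(state, mask, threshold = 1) {
  if (!any(mask)) stop("empty mask")
  sp <- cell_speed(state)
  mean(sp[mask] < threshold)
}

## cell-centred speed from face velocities
cell_speed <- function(state) {
  g <- state$grid
  n <- g$n
  if (g$periodic) {
    uc <- (state$u + state$u[c(2:n[1], 1), , ]) / 2
    vc <- (state$v + state$v[, c(2:n[2], 1), ]) / 2
    wc <- (state$w + state$w[, , c(2:n[3], 1)]) / 2
  } else {
    uc <- (state$u[-1, , ] + state$u[-(n[1] + 1), , ]) / 2
    vc <- (state$v[, -1, ] + state$v[, -(n[2] + 1), ]) / 2
    wc <- (state$w[, , -1] + state$w[, , -(n[3] + 1)]) / 2
  }
  sqrt(uc^2 + vc^2 + wc^2)
}

#' Venous wall dilation ratio
#'
#' Mean current diameter of the wall ring nearest `measurement_z` over its
#' reference diameter, `d/d0`.  The plane should cross the plain tube; a
#' warning is issued if it intersects the sinus window.
#'
#' @param mesh a [structural_mesh].
#' @param x current node positions (n x 3, cm).
#' @param measurement_z axial position of the measurement ring (cm).
#' @return Dilation ratio (dimensionless, > 0).
#' @export
dilation_ratio <- function(mesh, x, measurement_z) {
  zw <- sinus_window(mesh$params)
  if (measurement_z > zw[1] && measurement_z < zw[2])
    warning("measurement plane intersects the sinus; d/d0 is defined on ",
            "the plain tube")
  wall_nodes <- unique(as.vector(mesh$elements[mesh$region != "leaflet", ]))
  X <- mesh$nodes[wall_nodes, , drop = FALSE]
  dz <- abs(X[, 3] - measurement_z)
  ring <- wall_nodes[dz < min(dz) + 1e-9 + mesh$resolution / 2]
  Xr <- mesh$nodes[ring, , drop = FALSE]
  xr <- x[ring, , drop = FALSE]
  c0 <- colMeans(Xr[, 1:2, drop = FALSE])
  c1 <- colMeans(xr[, 1:2, drop = FALSE])
  r0 <- mean(sqrt((Xr[, 1] - c0[1])^2 + (Xr[, 2] - c0[2])^2))
  r1 <- mean(sqrt((xr[, 1] - c1[1])^2 + (xr[, 2] - c1[2])^2))
  r1 / r0
}

#' Segment a valve cycle into its four phases
#'
#' Splits one cycle of a geometric-orifice-area trace into opening,
#' equilibrium (fully open), closing and closed phases.  The rising and
#' falling flanks are located between the closed threshold and
#' `open_frac` of the cycle maximum, then extrapolated linearly to the
#' closed level and to the plateau level, which makes the boundaries
#' insensitive to the exact threshold values for trapezoid-like traces.
#'
#' @param time sample times covering one cycle (s).
#' @param goa GOA samples (cm^2).
#' @param closed_area GOA below which the valve counts as closed (cm^2);
#'   default twice the gap area of the trace minimum.
#' @param open_frac fraction of the cycle maximum regarded as fully open.
#' @return A `phase_segmentation`: data frame of phase, start, end,
#'   fraction.
#' @export
segment_phases <- function(time, goa, closed_area = NULL, open_frac = 0.9) {
  stopifnot(length(time) == length(goa), length(goa) >= 8)
  Tc <- diff(range(time)) + mean(diff(time))
  gmax <- max(goa)
  if (gmax - min(goa) < 1e-12 * max(gmax, 1e-12)) {
    open_trace <- gmax > 0
    warning(if (open_trace) "valve never closes; single equilibrium phase"
            else "valve never opens; single closed phase")
    seg <- data.frame(phase = if (open_trace) "equilibrium" else "closed",
                      start = min(time), end = min(time) + Tc, fraction = 1)
    class(seg) <- c("phase_segmentation", class(seg))
    return(seg)
  }
  if (is.null(closed_area))
    closed_area <- min(goa) + 0.02 * (gmax - min(goa))
  if (gmax <= closed_area) {
    warning("valve never opens; single closed phase")
    seg <- data.frame(phase = "closed", start = min(time),
                      end = min(time) + Tc, fraction = 1)
    class(seg) <- c("phase_segmentation", class(seg))
    return(seg)
  }
  open_level <- open_frac * gmax
  if (min(goa) > closed_area || all(goa > closed_area)) {
    warning("valve never closes; single equilibrium phase")
    seg <- data.frame(phase = "equilibrium", start = min(time),
                      end = min(time) + Tc, fraction = 1)
    class(seg) <- c("phase_segmentation", class(seg))
    return(seg)
  }
  cross_up <- function(level) {
    i <- which(goa[-1] >= level & goa[-length(goa)] < level)[1]
    if (is.na(i)) return(NA_real_)
    time[i] + (level - goa[i]) / (goa[i + 1] - goa[i]) * (time[i + 1] - time[i])
  }
  cross_dn <- function(level, after) {
    ok <- which(goa[-1] < level & goa[-length(goa)] >= level &
                time[-length(goa)] >= after)
    if (!length(ok)) return(NA_real_)
    i <- ok[1]
    time[i] + (goa[i] - level) / (goa[i] - goa[i + 1]) * (time[i + 1] - time[i])
  }
  ## rising flank between the closed threshold and the open level,
  ## anchored to the pre-rise baseline
  t_hi_up <- cross_up(open_level)
  if (is.na(t_hi_up)) {
    warning("no opening flank found; single closed phase")
    seg <- data.frame(phase = "closed", start = min(time),
                      end = min(time) + Tc, fraction = 1)
    class(seg) <- c("phase_segmentation", class(seg))
    return(seg)
  }
  base_lo <- min(goa[time <= t_hi_up])
  lvl_lo_up <- base_lo + 0.02 * (gmax - base_lo)
  t_lo_up <- cross_up(max(closed_area, lvl_lo_up))
  slope_up <- (open_level - goa_at(time, goa, t_lo_up)) /
    max(t_hi_up - t_lo_up, 1e-12)
  t_open_start <- t_lo_up - (goa_at(time, goa, t_lo_up) - base_lo) / slope_up
  t_open_end <- t_hi_up + (gmax - open_level) / slope_up
  ## falling flank, anchored to the post-fall baseline
  t_hi_dn <- cross_dn(open_level, after = t_hi_up)
  if (is.na(t_hi_dn)) {
    warning("no closing flank found; opening/equilibrium only")
    t_hi_dn <- max(time)
  }
  floor_dn <- min(goa[time >= t_hi_dn])
  lvl_lo_dn <- floor_dn + 0.02 * (gmax - floor_dn)
  t_lo_dn <- cross_dn(max(closed_area, lvl_lo_dn), after = t_hi_dn)
  if (is.na(t_lo_dn)) t_lo_dn <- max(time)
  slope_dn <- (open_level - goa_at(time, goa, t_lo_dn)) /
    max(t_lo_dn - t_hi_dn, 1e-12)
  t_close_start <- t_hi_dn - (gmax - open_level) / slope_dn
  t_close_end <- t_lo_dn + (goa_at(time, goa, t_lo_dn) - floor_dn) / slope_dn
  t_close_end <- min(t_close_end, max(time))
  t0 <- min(time)
  b <- sort(c(t_open_start, t_open_end, t_close_start, t_close_end))
  seg <- data.frame(
    phase = c("opening", "equilibrium", "closing", "closed"),
    start = b,
    end = c(b[-1], t0 + Tc),
    stringsAsFactors = FALSE)
  ## anything before the opening start belongs to the closed phase
  seg$fraction <- (seg$end - seg$start) / Tc
  seg$fraction[seg$phase == "closed"] <-
    seg$fraction[seg$phase == "closed"] + (b[1] - t0) / Tc
  class(seg) <- c("phase_segmentation", class(seg))
  seg
}

## linear interpolation of the trace at one time
goa_at <- function(time, goa, t) {
  if (is.na(t)) return(NA_real_)
  stats::approx(time, goa, xout = t, rule = 2)$y
}

#' Radial velocity profiles at axial probe stations
#'
#' Samples the speed along the two transverse axes through the vein axis
#' at each axial station and fits a quadratic (Poiseuille-type) profile
#' across the lumen, reporting the fitted peak and R^2.
#'
#' @param state a [fluid_state].
#' @param params a [geometry_params] (for the local lumen radius).
#' @param stations axial positions (cm); defaults to the five standard
#'   fractions (0.08, 0.30, valve plane, 0.70, 0.92) of the box length.
#' @param box fluid box extents.
#' @return List of per-station data frames (`r`, `speed`) with attributes
#'   `r2`, `max_speed`, `z`.
#' @export
axial_velocity_profiles <- function(state, params, stations = NULL,
                                    box = state$grid$L) {
  g <- state$grid
  if (is.null(stations))
    stations <- c(0.08, 0.30, NA, 0.70, 0.92) * box[3]
  stations[is.na(stations)] <- params$valve_z
  if (any(stations < 0 | stations > box[3])) stop("probe outside the box")
  sp <- cell_speed(state)
  xc <- (seq_len(g$n[1]) - 0.5) * g$h - box[1] / 2
  yc <- (seq_len(g$n[2]) - 0.5) * g$h - box[2] / 2
  ic <- which.min(abs(xc)); jc <- which.min(abs(yc))
  out <- lapply(stations, function(z) {
    k <- min(max(round(z / g$h + 0.5), 1L), g$n[3])
    rin <- wall_inner_radius(z, params)
    ## samples along x and y axes through the centre
    selx <- abs(xc) < rin
    sely <- abs(yc) < rin
    r <- c(xc[selx], yc[sely])
    v <- c(sp[selx, jc, k], sp[ic, sely, k])
    fit <- stats::lm(v ~ I(r^2))
    r2 <- summary(fit)$r.squared
    df <- data.frame(r = r, speed = v)
    attr(df, "r2") <- r2
    attr(df, "max_speed") <- max(v)
    attr(df, "fit_peak") <- unname(stats::coef(fit)[1])
    attr(df, "z") <- z
    df
  })
  names(out) <- utils::head(LETTERS, length(out))
  out
}
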