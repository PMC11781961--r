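#' Geometric parameters of the vein--sinus--valve model
#'
#' Dimensions of the idealised bicuspid venous valve geometry (all in cm):
#' a straight vein segment with a bulged valve sinus and two semilunar
#' leaflets whose free edges leave a small initialisation gap `g`.
#' Defaults are the reference dimensions of a typical bovine saphenous
#' vein segment.
#'
#' @param l wall (vein segment) length.
#' @param d luminal diameter.
#' @param tw wall thickness.
#' @param lv valve (leaflet) depth: axial extent of a leaflet.
#' @param tv leaflet thickness.
#' @param ls sinus depth: axial extent of the sinus bulge.
#' @param ts sinus wall thickness.
#' @param sinus_bulge_ratio maximum sinus inner radius over lumen radius,
#'   in (1, 2].  The default 1.3 keeps the bulged sinus clear of the
#'   1 x 1 cm cross-section of the standard fluid box.
#' @param g free-edge gap between the two leaflets; must be < d/10.
#' @param valve_z axial position of the leaflet free-edge plane; default
#'   mid-length.
#' @param sinus_offset fraction of the sinus depth lying distal (below) the
#'   free-edge plane.
#' @param sag belly sag of the leaflet midsurface as a fraction of `lv`
#'   (must be < 0.25 so the leaflet axial extent stays exactly `lv`).
#' @return A validated `geometry_params` object.
#' @export
geometry_params <- function(l = 3.2, d = 0.691, tw = 0.020, lv = 0.500,
                            tv = 0.020, ls = 1.000, ts = 0.015,
                            sinus_bulge_ratio = 1.3, g = 0.01,
                            valve_z = l / 2, sinus_offset = 0.7,
                            sag = 0.2) {
  p <- list(l = l, d = d, tw = tw, lv = lv, tv = tv, ls = ls, ts = ts,
            sinus_bulge_ratio = sinus_bulge_ratio, g = g,
            valve_z = valve_z, sinus_offset = sinus_offset, sag = sag)
  if (any(vapply(p[c("l", "d", "tw", "lv", "tv", "ls", "ts", "g")],
                 function(v) !is.numeric(v) || v <= 0, logical(1))))
    stop("all lengths must be positive")
  if (!(p$lv < p$ls && p$ls < p$l))
    stop("need valve depth < sinus depth < wall length (lv < ls < l)")
  if (p$g >= p$d / 10) stop("free-edge gap g must be < d/10")
  if (p$sinus_bulge_ratio <= 1 || p$sinus_bulge_ratio > 2)
    stop("sinus_bulge_ratio must lie in (1, 2]")
  if (p$sag <= 0 || p$sag >= 0.25) stop("sag must lie in (0, 0.25)")
  zs0 <- p$valve_z - p$sinus_offset * p$ls
  zs1 <- zs0 + p$ls
  if (zs0 <= 0 || zs1 >= p$l)
    stop("sinus window [", signif(zs0, 4), ", ", signif(zs1, 4),
         "] must lie strictly inside (0, l)")
  if (p$valve_z - p$lv <= zs0)
    stop("leaflet attachment would extend below the sinus window")
  class(p) <- "geometry_params"
  p
}

#' @export
print.geometry_params <- function(x, ...) {
  cat("<geometry_params> vein l =", x$l, "cm, lumen d =", x$d,
      "cm, valve depth lv =", x$lv, "cm, sinus depth ls =", x$ls, "cm\n")
  invisible(x)
}

## sinus bulge profile: 0 outside the sinus window, sin^2 bump inside
sinus_bump <- function(z, params) {
  zs0 <- params$valve_z - params$sinus_offset * params$ls
  xi <- (z - zs0) / params$ls
  ifelse(xi > 0 & xi < 1, sin(pi * xi)^2, 0)
}

## inner wall radius and wall thickness as functions of z
wall_inner_radius <- function(z, params) {
  params$d / 2 * (1 + (params$sinus_bulge_ratio - 1) * sinus_bump(z, params))
}
wall_thickness <- function(z, params) {
  params$tw + (params$ts - params$tw) * sinus_bump(z, params)
}

## attachment depth below the free-edge plane at angular position theta
attachment_z <- function(theta, params) {
  params$valve_z - params$lv * abs(sin(theta))
}

#' Leaflet midsurface
#'
#' Parametric midsurface of one semilunar leaflet.  `s` runs along the
#' attachment arc between the two commissures (both on the sinus wall);
#' `t` runs from the attachment curve (`t = 0`, a half-ellipse of depth
#' `lv` on the sinus wall) to the parabolic free edge (`t = 1`).  The free
#' edge lies in the plane `z = valve_z` and bows to a transverse distance
#' `g/2` from the inter-leaflet symmetry plane at its midpoint; the belly
#' sags parabolically below the chord.
#'
#' @param params a [geometry_params].
#' @param s,t surface parameters in `[0, 1]` (vectorised; recycled).
#' @param side `+1` for the leaflet on the `y > 0` side, `-1` for its
#'   mirror image.
#' @return m x 3 matrix of points (cm).
#' @export
leaflet_midsurface <- function(params, s, t, side = 1) {
  if (any(s < -1e-12 | s > 1 + 1e-12) || any(t < -1e-12 | t > 1 + 1e-12))
    stop("surface parameters s, t must lie in [0, 1]")
  m <- max(length(s), length(t))
  s <- rep_len(pmin(pmax(s, 0), 1), m)
  t <- rep_len(pmin(pmax(t, 0), 1), m)
  th <- pi * s                         # angular position along the arc
  za <- attachment_z(th, params)
  ra <- wall_inner_radius(za, params)
  ax <- ra * cos(th)
  ay <- side * ra * sin(th)
  rc <- wall_inner_radius(params$valve_z, params)
  ex <- rc * cos(th)
  ey <- side * (params$g / 2) * sin(th)^2
  ez <- params$valve_z
  ## sqrt(sin) keeps the sag alive near the commissures, which keeps the
  ## commissure transition elements well-shaped (the leaflet would
  ## otherwise be locally flat there); the leaflet axial extent stays lv
  ## for sag < lv/4
  sagz <- params$sag * params$lv * sqrt(sin(th)) * 4 * t * (1 - t)
  cbind(x = (1 - t) * ax + t * ex,
        y = (1 - t) * ay + t * ey,
        z = (1 - t) * za + t * ez - sagz)
}

## Freudenthal (Kuhn) subdivision of a hexahedral cell given its 8 global
## node ids indexed v[x + 2y + 4z + 1] for local binary coords; globally
## conforming on structured grids.
.freudenthal <- matrix(c(
  1, 2, 4, 8,
  1, 2, 6, 8,
  1, 3, 4, 8,
  1, 3, 7, 8,
  1, 5, 6, 8,
  1, 5, 7, 8), ncol = 4, byrow = TRUE)

split_hexes <- function(v8) {
  ## v8: n x 8 matrix of global node ids
  do.call(rbind, lapply(seq_len(nrow(.freudenthal)), function(r)
    v8[, .freudenthal[r, ], drop = FALSE]))
}

## 3-tet split of the prism (A B | C D | E F): triangles (A,C,E), (B,D,F);
## the quad (C,D,F,E) gets diagonal C-F, matching the Freudenthal diagonal
## of an adjacent hex strip.
split_prisms <- function(A, B, C, D, E, F) {
  rbind(cbind(A, B, D, F), cbind(A, C, D, F), cbind(A, C, F, E))
}

## 2-tet split of pyramid (apex; quad (a, b, c, d)) with diagonal a-c
split_pyramids <- function(apex, a, b, c, d) {
  rbind(cbind(apex, a, b, c), cbind(apex, a, c, d))
}

#' Build the conformal structural mesh
#'
#' Generates the reference-configuration tetrahedral mesh of the vein wall,
#' sinus and both leaflets.  The wall/sinus is a structured annular grid
#' (rotationally generated); leaflet attachment curves are snapped onto
#' wall grid nodes so the three regions share nodes along their junctions.
#' Hexahedral/prismatic cells are subdivided into tetrahedra with a
#' globally consistent (Freudenthal) diagonal rule.
#'
#' @param params a [geometry_params].
#' @param resolution target edge length (cm); must not exceed the wall
#'   thickness scale by more than a factor 3 (one element through the
#'   thickness is always used).
#' @return A `structural_mesh` with fields `nodes`, `elements`, `region`,
#'   `fixed`, `free_edges` (list of two ordered node-index vectors),
#'   `params`, `resolution`.
#' @export
build_structural_mesh <- function(params, resolution = 0.05) {
  if (resolution > 3 * params$tw)
    stop("resolution ", resolution, " cm too coarse to resolve the wall ",
         "thickness ", params$tw, " cm (need <= ", 3 * params$tw, ")")
  res <- resolution
  R0 <- params$d / 2
  ## angular grid: multiple of 4 so both commissure and midline columns exist
  ntheta <- max(16L, 4L * ceiling(2 * pi * R0 / res / 4))
  theta <- 2 * pi * (0:(ntheta - 1)) / ntheta
  ## axial grid containing the free-edge plane and the sinus window
  ## boundaries exactly (region tags then do not jitter with resolution)
  zs0g <- params$valve_z - params$sinus_offset * params$ls
  zs1g <- zs0g + params$ls
  seg <- function(a, b) {
    k <- max(2L, round((b - a) / res))
    seq(a, b, length.out = k + 1)
  }
  zgrid <- c(seg(0, zs0g), seg(zs0g, params$valve_z)[-1],
             seg(params$valve_z, zs1g)[-1], seg(zs1g, params$l)[-1])
  nzrow <- length(zgrid)
  ktop <- which.min(abs(zgrid - params$valve_z))
  dz <- params$valve_z / (ktop - 1L)

  ## per-column axial rows with the attachment node snapped in; rows below
  ## and above the attachment are re-spaced uniformly so no sliver layers
  ## appear next to the snapped row
  zcols <- matrix(rep(zgrid, ntheta), nzrow, ntheta)
  katt <- integer(ntheta)
  for (j in seq_len(ntheta)) {
    za <- attachment_z(theta[j], params)
    if (abs(za - params$valve_z) < 1e-12) { katt[j] <- ktop; next }
    k <- which.min(abs(zgrid - za))
    if (k >= ktop) k <- ktop - 1L
    k0 <- which.min(abs(zgrid - zs0g))   # sinus-window start row (fixed)
    if (k <= k0 + 1L) k <- k0 + 2L
    zcols[k0:k, j] <- seq(zs0g, za, length.out = k - k0 + 1L)
    zcols[k:ktop, j] <- seq(za, params$valve_z, length.out = ktop - k + 1L)
    katt[j] <- k
  }

  ## wall nodes: layers 0..nr through the thickness
  nr <- max(1L, round(params$tw / res))
  wall_id <- array(0L, c(nr + 1L, ntheta, nzrow))
  idc <- 0L
  coord <- matrix(0, (nr + 1L) * ntheta * nzrow, 3)
  for (k in seq_len(nzrow)) {
    for (j in seq_len(ntheta)) {
      z <- zcols[k, j]
      rin <- wall_inner_radius(z, params)
      tks <- wall_thickness(z, params)
      for (q in 0:nr) {
        idc <- idc + 1L
        r <- rin + tks * q / nr
        coord[idc, ] <- c(r * cos(theta[j]), r * sin(theta[j]), z)
        wall_id[q + 1L, j, k] <- idc
      }
    }
  }
  nodes <- coord

  ## wall hexes -> tets; local binary axes (x = theta, y = z, z = radial)
  jn <- c(seq_len(ntheta - 1L) + 1L, 1L)  # next column with wrap
  hx <- vector("list", (nzrow - 1L) * nr)
  hcount <- 0L
  for (k in seq_len(nzrow - 1L)) {
    for (q in seq_len(nr)) {
      hcount <- hcount + 1L
      j0 <- seq_len(ntheta); j1 <- jn
      hx[[hcount]] <- cbind(
        wall_id[q, j0, k],     wall_id[q, j1, k],
        wall_id[q, j0, k + 1], wall_id[q, j1, k + 1],
        wall_id[q + 1L, j0, k],     wall_id[q + 1L, j1, k],
        wall_id[q + 1L, j0, k + 1], wall_id[q + 1L, j1, k + 1])
    }
  }
  hex <- do.call(rbind, hx)
  wall_tets <- split_hexes(hex)
  ## region of wall tets: sinus if the element's mean z is inside the window
  zs0 <- params$valve_z - params$sinus_offset * params$ls
  zs1 <- zs0 + params$ls
  zmean_wall <- rowMeans(matrix(nodes[wall_tets, 3], nrow(wall_tets), 4))
  wall_region <- ifelse(zmean_wall > zs0 & zmean_wall < zs1, "sinus", "wall")

  ## Leaflets.  Columns whose attachment-to-free-edge chord is below the
  ## mesh resolution are treated as degenerate (the leaflet surface
  ## pinches onto the wall near the commissures, below what the mesh can
  ## represent); the solid starts at the first column with a resolvable
  ## chord, and the ring count is limited by that chord so rings stay
  ## thicker than the leaflet itself.
  nth2 <- ntheta %/% 2L
  svals_all <- (0:nth2) / nth2
  chord <- sin(pi * svals_all) *
    sqrt(params$lv^2 + (params$d / 2)^2)
  degen <- chord < max(2 * res, 2.5 * params$tv)
  ind <- which(!degen)
  if (length(ind) < 4L)
    stop("resolution too coarse to resolve the leaflets")
  nt <- max(3L, min(ceiling(1.2 * params$lv / res),
                    floor(chord[ind[1]] / (0.8 * params$tv))))
  elems <- list(wall_tets)
  regions <- list(wall_region)
  free_edges <- vector("list", 2)
  for (lf in 1:2) {
    side <- if (lf == 1) 1 else -1
    ## mirrored leaflet walks the wall columns backwards through theta = 0
    jcols <- if (lf == 1) 1:(nth2 + 1L) else c(1L, ntheta:(nth2 + 1L))
    ncol_l <- length(jcols)              # nth2 + 1 columns
    svals <- (seq_len(ncol_l) - 1) / (ncol_l - 1)
    ## attachment (t = 0) nodes are wall inner-surface nodes
    att_id <- vapply(seq_len(ncol_l), function(i)
      wall_id[1L, jcols[i], katt[jcols[i]]], integer(1))
    ## interior rings t_1 .. t_{nt-1}: node pairs (minus, plus);
    ## free edge t = 1: single midsurface nodes
    tvals <- seq(0, 1, length.out = nt + 1L)
    nid_m <- matrix(0L, ncol_l, nt - 1L)  # S- nodes, interior columns only
    nid_p <- matrix(0L, ncol_l, nt - 1L)
    fe_id <- integer(ncol_l)
    newc <- list(); nn <- nrow(nodes)
    eps <- 1e-4
    for (i in seq_len(ncol_l)) {
      si <- svals[i]
      if (degen[i]) { fe_id[i] <- att_id[i]; next }
      mid <- leaflet_midsurface(params, si, tvals, side = side)
      ## numerical surface normal (central differences in s, t)
      dps <- (leaflet_midsurface(params, pmin(si + eps, 1), tvals, side) -
              leaflet_midsurface(params, pmax(si - eps, 0), tvals, side))
      dpt <- (leaflet_midsurface(params, si, pmin(tvals + eps, 1), side) -
              leaflet_midsurface(params, si, pmax(tvals - eps, 0), side))
      nrm <- cbind(dps[, 2] * dpt[, 3] - dps[, 3] * dpt[, 2],
                   dps[, 3] * dpt[, 1] - dps[, 1] * dpt[, 3],
                   dps[, 1] * dpt[, 2] - dps[, 2] * dpt[, 1])
      nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-30)
      flip <- sign(nrm[, 3]); flip[flip == 0] <- 1
      nrm <- nrm * flip                  # orient towards +z
      for (m in 2:nt) {                  # interior rings
        pm <- mid[m, ] - params$tv / 2 * nrm[m, ]
        pp <- mid[m, ] + params$tv / 2 * nrm[m, ]
        newc[[length(newc) + 1L]] <- pm
        nid_m[i, m - 1L] <- nn + length(newc)
        newc[[length(newc) + 1L]] <- pp
        nid_p[i, m - 1L] <- nn + length(newc)
      }
      newc[[length(newc) + 1L]] <- mid[nt + 1L, ]
      fe_id[i] <- nn + length(newc)
    }
    nodes <- rbind(nodes, do.call(rbind, newc))

    ii <- ind[-length(ind)]              # interior s-strips
    tl <- list()
    ## attachment prism strip (t0 -> t1) over interior s-intervals
    tl[[1]] <- split_prisms(att_id[ii], att_id[ii + 1L],
                            nid_m[ii, 1L], nid_m[ii + 1L, 1L],
                            nid_p[ii, 1L], nid_p[ii + 1L, 1L])
    ## interior hex strips between rings m and m+1
    if (nt > 2L) {
      hx <- lapply(seq_len(nt - 2L), function(m)
        cbind(nid_m[ii, m], nid_m[ii + 1L, m],
              nid_m[ii, m + 1L], nid_m[ii + 1L, m + 1L],
              nid_p[ii, m], nid_p[ii + 1L, m],
              nid_p[ii, m + 1L], nid_p[ii + 1L, m + 1L]))
      tl[[2]] <- split_hexes(do.call(rbind, hx))
    }
    ## free-edge prism strip (t_{nt-1} -> t1): apex = free-edge nodes
    tl[[length(tl) + 1L]] <-
      split_prisms(fe_id[ii], fe_id[ii + 1L],
                   nid_m[ii, nt - 1L], nid_m[ii + 1L, nt - 1L],
                   nid_p[ii, nt - 1L], nid_p[ii + 1L, nt - 1L])
    ## The wedge between the commissure point and the first interior
    ## column is intrinsically flat (the leaflet surface pinches onto the
    ## wall there) and is below mesh resolution: it is left unmeshed
    ## rather than filled with degenerate cells.  The free-edge curve
    ## still terminates on the commissure wall nodes.
    lt <- do.call(rbind, tl)
    elems[[length(elems) + 1L]] <- lt
    regions[[length(regions) + 1L]] <- rep("leaflet", nrow(lt))
    ## ordered free-edge curve: the two commissure wall nodes plus the
    ## true free-edge nodes (degenerate trimmed columns sit on the wall
    ## and would corrupt the orifice measurement)
    free_edges[[lf]] <- fe_id[sort(unique(c(1L, ind, ncol_l)))]
  }

  elements <- do.call(rbind, elems)
  region <- unlist(regions)
  dimnames(elements) <- NULL

  ## fix orientation: swap last two vertices of negative-volume tets
  v <- tet_volumes(nodes, elements)
  neg <- v < 0
  if (any(neg))
    elements[neg, 3:4] <- elements[neg, 4:3]
  v <- abs(v)
  if (any(v <= 0))
    stop("degenerate element(s) produced by the mesher: ",
         paste(utils::head(which(v <= 0), 10), collapse = ", "))

  mesh <- list(nodes = nodes, elements = elements, region = region,
               fixed = sort(c(wall_id[, , 1L], wall_id[, , nzrow])),
               free_edges = free_edges,
               params = params, resolution = resolution,
               cache = new.env(parent = emptyenv()))
  class(mesh) <- "structural_mesh"
  mesh
}

tet_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 1], , drop = FALSE]
  e1 <- nodes[elements[, 2], , drop = FALSE] - a
  e2 <- nodes[elements[, 3], , drop = FALSE] - a
  e3 <- nodes[elements[, 4], , drop = FALSE] - a
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
   e2[, 1] * (e1[, 2] * e3[, 3] - e1[, 3] * e3[, 2]) +
   e3[, 1] * (e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2])) / 6
}

#' @export
print.structural_mesh <- function(x, ...) {
  cat("<structural_mesh>", nrow(x$nodes), "nodes,", nrow(x$elements),
      "tetrahedra\n  regions:",
      paste(names(table(x$region)), table(x$region), collapse = ", "),
      "\n")
  invisible(x)
}

#' Mesh quality report
#'
#' Summarises element and node counts, per-region element counts, the
#' volume range and the worst radius-ratio aspect measure.  Fails with a
#' diagnostic listing offending element ids if any element is inverted or
#' degenerate.
#'
#' @param mesh a [structural_mesh].
#' @return List of summary quantities.
#' @export
mesh_quality_report <- function(mesh) {
  v <- tet_volumes(mesh$nodes, mesh$elements)
  if (any(v <= 0))
    stop("inverted element(s): ",
         paste(utils::head(which(v <= 0), 20), collapse = ", "))
  ## aspect measure: longest edge^3 / (6 sqrt(2) vol), 1 for regular tet
  ed <- function(a, b) sqrt(rowSums((mesh$nodes[mesh$elements[, a], ,
                                                drop = FALSE] -
                                     mesh$nodes[mesh$elements[, b], ,
                                                drop = FALSE])^2))
  lmax <- pmax(ed(1, 2), ed(1, 3), ed(1, 4), ed(2, 3), ed(2, 4), ed(3, 4))
  aspect <- lmax^3 / (6 * sqrt(2) * v)
  used <- sort(unique(as.vector(mesh$elements)))
  list(n_elements = nrow(mesh$elements),
       n_nodes = nrow(mesh$nodes),
       n_orphan_nodes = nrow(mesh$nodes) - length(used),
       min_volume = min(v), max_volume = max(v),
       total_volume = sum(v),
       region_counts = table(mesh$region),
       region_volumes = tapply(v, mesh$region, sum),
       worst_aspect = max(aspect))
}
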