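ref_params <- geometry_params()

test_that("geometry parameters are validated", {
  expect_error(geometry_params(lv = 1.2), "lv < ls < l")
  expect_error(geometry_params(g = 0.1), "g must be")
  expect_error(geometry_params(sinus_bulge_ratio = 0.9), "sinus_bulge_ratio")
  expect_error(geometry_params(tw = -0.01), "positive")
})

test_that("leaflet midsurface hits its anchor points", {
  p <- ref_params
  # commissures lie on the sinus wall at the free-edge plane
  for (tt in c(0, 0.5, 1)) {
    pt <- leaflet_midsurface(p, 0, tt)
    expect_equal(sqrt(pt[1]^2 + pt[2]^2),
                 valvefsi:::wall_inner_radius(p$valve_z, p),
                 tolerance = 1e-12)
    expect_equal(unname(pt[, "z"]), p$valve_z, tolerance = 1e-12)
  }
  # free-edge midpoint sits half a gap off the symmetry plane
  mid <- leaflet_midsurface(p, 0.5, 1)
  expect_equal(unname(mid[, "y"]), p$g / 2, tolerance = 1e-12)
  # axial extent of the sampled surface equals the valve depth
  ss <- rep(seq(0, 1, length.out = 101), each = 101)
  tt <- rep(seq(0, 1, length.out = 101), times = 101)
  zs <- leaflet_midsurface(p, ss, tt)[, "z"]
  expect_equal(diff(range(zs)), p$lv, tolerance = 1e-6)
  expect_error(leaflet_midsurface(p, -0.2, 0.5), "0, 1")
})

mesh60 <- build_structural_mesh(ref_params, resolution = 0.06)

test_that("the built mesh honours the printed lumen diameter and gap", {
  nd <- mesh60$nodes
  endring <- nd[abs(nd[, 3]) < 1e-9, ]
  r <- sqrt(endring[, 1]^2 + endring[, 2]^2)
  expect_equal(2 * min(r), 0.691, tolerance = 1e-9)
  # free edges: midpoint transverse separation equals the gap
  fe1 <- nd[mesh60$free_edges[[1]], , drop = FALSE]
  fe2 <- nd[mesh60$free_edges[[2]], , drop = FALSE]
  m1 <- fe1[which.min(abs(fe1[, 1])), ]
  m2 <- fe2[which.min(abs(fe2[, 1])), ]
  expect_equal(unname(m1[2] - m2[2]), ref_params$g, tolerance = 1e-9)
  # the curves never separate by more than the gap at matching stations
  expect_lte(min(abs(fe1[, 2])), ref_params$g / 2 + 1e-9)
})

test_that("region volumes follow thin-shell estimates and refinement", {
  q <- mesh_quality_report(mesh60)
  expect_identical(q$n_orphan_nodes, 0L)
  expect_gt(q$min_volume, 0)
  p <- ref_params
  extent <- p$l - p$ls               # plain tube outside the sinus window
  shell <- pi * p$d * p$tw * extent
  expect_lt(abs(q$region_volumes[["wall"]] - shell) / shell, 0.05)
  # refinement convergence: halving the edge length changes the shell
  # volumes < 1%; the leaflet volume is quantised by its ring count and
  # commissure trim, so it converges more slowly
  fine <- build_structural_mesh(ref_params, resolution = 0.03)
  qf <- mesh_quality_report(fine)
  for (reg in c("wall", "sinus")) {
    rel <- abs(q$region_volumes[[reg]] - qf$region_volumes[[reg]]) /
      qf$region_volumes[[reg]]
    expect_lt(rel, 0.01)
  }
  rel_leaf <- abs(q$region_volumes[["leaflet"]] -
                  qf$region_volumes[["leaflet"]]) /
    qf$region_volumes[["leaflet"]]
  expect_lt(rel_leaf, 0.08)
  # production-like resolution lands within a factor two of a typical
  # 74,294-element reference mesh of this geometry
  expect_gt(qf$n_elements, 74294 / 2)
  expect_lt(qf$n_elements, 74294 * 2)
})

test_that("the mesh is mirror-symmetric about the inter-leaflet plane", {
  nd <- mesh60$nodes
  key <- function(m) paste(round(m[, 1], 9), round(m[, 2], 9),
                           round(m[, 3], 9))
  mirrored <- nd; mirrored[, 2] <- -mirrored[, 2]
  # reflecting across y = 0 permutes the node set
  expect_identical(sort(key(mirrored)), sort(key(nd)))
})

test_that("regions are conformal: junction nodes shared by 2+ regions", {
  leaf_nodes <- unique(as.vector(
    mesh60$elements[mesh60$region == "leaflet", ]))
  wall_nodes <- unique(as.vector(
    mesh60$elements[mesh60$region != "leaflet", ]))
  shared <- intersect(leaf_nodes, wall_nodes)
  # both attachment curves contribute many shared nodes
  expect_gt(length(shared), 20)
  # sinus and wall regions share their ring interfaces
  sin_nodes <- unique(as.vector(mesh60$elements[mesh60$region == "sinus", ]))
  w_only <- unique(as.vector(mesh60$elements[mesh60$region == "wall", ]))
  expect_gt(length(intersect(sin_nodes, w_only)), 20)
})

test_that("quality report counts a single tetrahedron and flags inversion", {
  one <- list(nodes = unit_tet(), elements = matrix(1:4, 1),
              region = "wall", fixed = integer(0),
              free_edges = list(integer(0), integer(0)),
              params = NULL, resolution = 1,
              cache = new.env(parent = emptyenv()))
  class(one) <- "structural_mesh"
  q <- mesh_quality_report(one)
  expect_identical(q$n_elements, 1L)
  expect_equal(q$total_volume, 1 / 6)
  bad <- one
  bad$elements <- matrix(c(1, 2, 4, 3), 1)   # inverted orientation
  expect_error(mesh_quality_report(bad), "inverted element.*1")
})

test_that("a resolution too coarse for the wall thickness is refused", {
  expect_error(build_structural_mesh(ref_params, resolution = 0.1),
               "too coarse")
})
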