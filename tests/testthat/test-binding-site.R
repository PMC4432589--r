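# Binding-site geometry, ring geometry and pocket volume.

test_that("site_geometry reports planted distances exactly", {
  s <- toy_nitrate_site()
  g <- site_geometry(s)
  expect_equal(g$siteA$nh1, 2.70, tolerance = 1e-9)
  expect_equal(g$siteA$nh2, 2.75, tolerance = 1e-9)
  expect_equal(g$siteA$min, 2.70, tolerance = 1e-9)
  expect_equal(g$siteB, 2.40, tolerance = 1e-9)
  expect_equal(g$siteB_network$y263_r305, 3.00, tolerance = 1e-9)
  expect_equal(g$siteB_network$r305_s366, 2.80, tolerance = 1e-9)
  expect_equal(g$siteC, 3.10, tolerance = 1e-9)
  expect_equal(g$ligand_resname, "NO3")

  # distances are invariant under rigid transforms of the whole structure
  set.seed(13)
  g2 <- site_geometry(rigid_transform(s))
  expect_equal(g2$siteA$min, g$siteA$min, tolerance = 1e-9)
  expect_equal(g2$siteB, g$siteB, tolerance = 1e-9)

  # a planted 3.00 A guanidinium-N/ligand-O pair reads back exactly
  g3 <- site_geometry(toy_nitrate_site(d_nh1 = 3.00))
  expect_equal(g3$siteA$nh1, 3.00, tolerance = 1e-9)
})

test_that("apo structures yield NA ligand fields but the protein-only network", {
  s <- toy_nitrate_site()
  apo <- new_structure(s$atoms[s$atoms$resname != "NO3", ], title = "")
  g <- site_geometry(apo)
  expect_true(is.na(g$siteB))
  expect_true(is.na(g$siteC))
  expect_equal(g$siteB_network$y263_r305, 3.00, tolerance = 1e-9)
  expect_true(is.na(g$ligand_resname))
})

test_that("ring_geometry: parallel, perpendicular, and degenerate input", {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- cbind(1.4 * cos(th), 1.4 * sin(th), 0)
  lig_par <- cbind(1.2 * cos(th[c(1, 3, 5)]), 1.2 * sin(th[c(1, 3, 5)]), 3.5)
  rp <- ring_geometry(ring, lig_par)
  expect_equal(rp$dist, 3.5, tolerance = 1e-9)
  expect_equal(rp$angle, 0, tolerance = 1e-9)

  lig_perp <- cbind(1.2 * cos(th[c(1, 3, 5)]), 0, 1.2 * sin(th[c(1, 3, 5)]) + 3.5)
  expect_equal(ring_geometry(ring, lig_perp)$angle, 90, tolerance = 1e-9)

  expect_error(ring_geometry(ring[1:5, ], lig_par), "6 ring atoms")
  expect_error(ring_geometry(ring, lig_par[1:2, ]), ">= 3 atoms")
})

test_that("pocket_volume recovers the analytic cavity within one grid shell", {
  cav <- make_cavity(inner_side = 4, wall_spacing = 0.4)
  p <- pocket_volume(cav$structure, cav$seed_point, spacing = 0.25,
                     probe = 0, bounds = 3)
  shell <- 6 * 4^2 * 0.25          # one voxel layer over the cavity surface
  expect_lt(abs(p$volume - 64), shell)
  expect_false(p$open)
  expect_equal(p$volume, p$n_grid_points * 0.25^3, tolerance = 1e-9)
})

test_that("pocket_volume: probe monotonicity, closure, seed errors, open flag", {
  cav <- make_cavity(4, 0.4)
  vols <- vapply(c(0, 0.7, 1.4, 1.9), function(pr)
    pocket_volume(cav$structure, cav$seed_point, spacing = 0.25, probe = pr,
                  bounds = 3)$volume, 0)
  expect_true(all(diff(vols) <= 0))
  # probe exceeding the cavity half-width: nowhere to sit, volume 0
  expect_equal(pocket_volume(cav$structure, cav$seed_point, spacing = 0.25,
                             probe = 3, bounds = 3)$volume, 0)
  # a seed inside a wall atom's bare vdW sphere is a precondition error
  expect_error(pocket_volume(cav$structure, c(0, 0, 3.7), spacing = 0.25,
                             probe = 0, bounds = 3), "vdW sphere")
  # bounds larger than the shell: the fill escapes and is flagged open
  p_open <- pocket_volume(cav$structure, c(0, 0, 10), spacing = 0.5,
                          probe = 0, bounds = 4)
  expect_true(p_open$open)
})

test_that("flood-fill volume equals direct enumeration on an enclosed cavity", {
  # bounds chosen inside the wall shell so every free voxel belongs to the
  # cavity: direct counting (no connectivity) is then an independent oracle
  cav <- make_cavity(4, 0.4)
  spacing <- 0.4
  p <- pocket_volume(cav$structure, cav$seed_point, spacing = spacing,
                     probe = 0, bounds = 2.8)
  n <- ceiling(2 * 2.8 / spacing)
  g <- -2.8 + (seq_len(n) - 0.5) * spacing
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  wall <- coords(cav$structure)
  r2 <- (1.70)^2
  free <- vapply(seq_len(nrow(pts)), function(i)
    all(colSums((t(wall) - pts[i, ])^2) > r2), TRUE)
  expect_equal(p$n_grid_points, sum(free))
})

test_that("pocket volume converges with grid refinement", {
  cav <- make_cavity(4, 0.4)
  v_coarse <- pocket_volume(cav$structure, cav$seed_point, spacing = 0.5,
                            probe = 0, bounds = 3)$volume
  v_fine <- pocket_volume(cav$structure, cav$seed_point, spacing = 0.25,
                          probe = 0, bounds = 3)$volume
  expect_lt(abs(v_fine - v_coarse) / v_fine, 0.05)
})

test_that("site_compare tabulates both states, deltas, and handles apo", {
  occ <- toy_nitrate_site(d_nh1 = 2.70, d_y263 = 2.40)
  inw <- toy_nitrate_site(d_nh1 = 3.10, d_y263 = 3.90)
  tab <- site_compare(occ, inw, pocket = FALSE)
  row <- function(q) tab[tab$quantity == q, ]
  expect_equal(row("siteA_min")$occluded, 2.70, tolerance = 1e-9)
  expect_equal(row("siteA_min")$inward, 3.10, tolerance = 1e-9)
  expect_equal(row("siteB")$delta, 1.50, tolerance = 1e-9)

  same <- site_compare(occ, occ, pocket = FALSE)
  expect_true(all(same$delta[!is.na(same$delta)] == 0))

  apo <- new_structure(occ$atoms[occ$atoms$resname != "NO3", ], title = "")
  tab_apo <- site_compare(occ, apo, pocket = FALSE)
  expect_true(is.na(tab_apo[tab_apo$quantity == "siteB", "inward"]))
  expect_equal(tab_apo[tab_apo$quantity == "y263_r305", "inward"], 3.00,
               tolerance = 1e-9)
})
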