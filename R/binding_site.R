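# Substrate-binding-site geometry (recognition sites A/B/C, the aromatic
# sandwich) and cavity volume by probe-inflated grid flood fill.

#' Default substrate-site residue table
#'
#' The nitrate site of NarK is formed by F49, R89, F147, N175, Y263, F267,
#' R305 and S366: R89 donates a bidentate salt bridge (site A), Y263/R305/
#' S366 form the hydrogen-bonded network of site B, N175 with F49 forms
#' site C, and F147/F267 sandwich the planar anion.
#'
#' @return named list of residue numbers.
#' @export
default_site_residues <- function() list(
  F49 = 49L, R89 = 89L, F147 = 147L, N175 = 175L, Y263 = 263L,
  F267 = 267L, R305 = 305L, S366 = 366L)

site_atom <- function(s, resseq, atom_names, chains = "all") {
  a <- s$atoms
  keep <- a$resseq == resseq & a$atom %in% atom_names & a$element != "H"
  if (!identical(chains, "all")) keep <- keep & a$chain %in% chains
  which(keep)
}

min_dist <- function(s, ia, ib) {
  if (length(ia) == 0 || length(ib) == 0) return(NA_real_)
  min(pair_distances(s, ia, ib))
}

#' Geometry of the substrate-binding site
#'
#' Measures the recognition-site distances from deposited coordinates:
#' site A, the R89 guanidinium NH1/NH2 to nearest ligand oxygen (separately
#' and as the minimum — the value quoted for the site is this minimum, since
#' deposited descriptions do not name the atom); site B, the minimum Y263
#' hydroxyl to ligand oxygen distance, plus the protein-only network
#' Y263 OH - R305 guanidinium - S366 OG; site C, the N175 side-chain amide
#' to nearest ligand oxygen; and the F147/F267 aromatic sandwich via
#' [ring_geometry()]. With no ligand resolved (apo structures) the ligand
#' distances are `NA` and the protein-only network is still reported.
#'
#' @param s a `tmg_structure`.
#' @param ligand_sel selection resolving the ligand (default residue name
#'   `NO3`; `NO2` is accepted by the same ops, with site C expected absent).
#' @param residues residue-number table, see [default_site_residues()].
#' @param chains chain filter for the protein residues.
#' @return list of class `tmg_site_geometry` with fields `siteA`
#'   (`nh1`, `nh2`, `min`), `siteB`, `siteB_network`, `siteC`, `sandwich`
#'   (per-ring centroid distance and interplanar angle), `ligand_resname`.
#' @export
site_geometry <- function(s, ligand_sel = sel(resnames = "NO3"),
                          residues = default_site_residues(),
                          chains = "all") {
  lig <- resolve(ligand_sel, s, allow_empty = TRUE)
  has_lig <- nrow(lig$keys) > 0
  if (has_lig) {
    lr <- unique(lig$keys[c("chain", "resseq", "resname")])
    if (nrow(lr) > 1) stop("ligand selection resolves to more than one residue")
    ilig_o <- lig$index[s$atoms$element[lig$index] == "O"]
  } else ilig_o <- integer()

  r <- residues
  nh1 <- site_atom(s, r$R89, "NH1", chains)
  nh2 <- site_atom(s, r$R89, "NH2", chains)
  d_nh1 <- min_dist(s, nh1, ilig_o)
  d_nh2 <- min_dist(s, nh2, ilig_o)
  oh263 <- site_atom(s, r$Y263, "OH", chains)
  guan305 <- site_atom(s, r$R305, c("NE", "NH1", "NH2"), chains)
  og366 <- site_atom(s, r$S366, "OG", chains)
  amide175 <- site_atom(s, r$N175, c("ND2", "OD1"), chains)

  sandwich <- lapply(c(F147 = r$F147, F267 = r$F267), function(rr) {
    ring <- site_atom(s, rr, c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), chains)
    if (length(ring) < 6 || !has_lig) return(list(dist = NA_real_, angle = NA_real_))
    ring_geometry(coords(s)[ring, , drop = FALSE],
                  coords(s)[lig$index, , drop = FALSE])
  })

  structure(list(
    siteA = list(nh1 = d_nh1, nh2 = d_nh2,
                 min = suppressWarnings(min(c(d_nh1, d_nh2), na.rm = TRUE))),
    siteB = min_dist(s, oh263, ilig_o),
    siteB_network = list(
      y263_r305 = min_dist(s, oh263, guan305),
      r305_s366 = min_dist(s, guan305, og366)),
    siteC = min_dist(s, amide175, ilig_o),
    sandwich = sandwich,
    ligand_resname = if (has_lig) lr$resname[1] else NA_character_),
    class = "tmg_site_geometry")
}

#' Ring-to-ligand centroid distance and interplanar angle
#'
#' Fits least-squares planes to the ring and the ligand, returns the
#' centroid-centroid distance and the angle between the plane normals folded
#' into [0, 90] degrees (pi-stacking geometry).
#'
#' @param ring_xyz 6 x 3 coordinates of a phenyl ring (CG..CZ).
#' @param ligand_xyz >= 3 x 3 coordinates of a planar ligand.
#' @return list: `dist` (Angstrom), `angle` (degrees).
#' @export
ring_geometry <- function(ring_xyz, ligand_xyz) {
  ring_xyz <- as.matrix(ring_xyz); ligand_xyz <- as.matrix(ligand_xyz)
  if (nrow(ring_xyz) < 6) stop("phenyl ring requires its 6 ring atoms")
  if (nrow(ligand_xyz) < 3) stop("ligand plane requires >= 3 atoms")
  normal_of <- function(m) {
    mc <- sweep(m, 2, colMeans(m))
    svd(mc, nu = 0, nv = 3)$v[, 3]
  }
  n1 <- normal_of(ring_xyz); n2 <- normal_of(ligand_xyz)
  ang <- acos(min(1, abs(sum(n1 * n2)))) * 180 / pi
  list(dist = sqrt(sum((colMeans(ring_xyz) - colMeans(ligand_xyz))^2)),
       angle = ang)
}

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, F = 1.47)

#' Cavity volume by probe-inflated grid flood fill
#'
#' Lays a cubic grid over `bounds`, blocks every grid point within
#' (van der Waals radius + probe) of an occluding heavy atom, and 6-connected
#' flood-fills from the seed point. The volume is the count of filled points
#' times the voxel volume. Waters and ligands are excluded from the
#' occluding set by default, so the pocket they occupy is measured.
#'
#' If the fill reaches the boundary of `bounds` the pocket is open; the
#' truncated volume is returned with `open = TRUE`. A seed inside an atom's
#' bare van der Waals sphere is an error; a seed excluded only by probe
#' inflation yields volume 0 (the probe does not fit anywhere).
#'
#' @param s a `tmg_structure`.
#' @param seed 3-vector seed point (Angstrom), e.g. the ligand centroid.
#' @param spacing grid spacing (default 0.25 A).
#' @param probe probe radius (default 1.4 A, a water).
#' @param bounds half-width of the cubic search box centred on the seed
#'   (default 6 A, i.e. a 12 A cube).
#' @param exclude_resnames residue names removed from the occluding set
#'   (default waters and nitrate/nitrite).
#' @return list of class `tmg_pocket`: `volume` (Angstrom^3),
#'   `n_grid_points`, `spacing`, `probe`, `seed`, `open`.
#' @export
pocket_volume <- function(s, seed, spacing = 0.25, probe = 1.4, bounds = 6,
                          exclude_resnames = c("HOH", "WAT", "NO3", "NO2")) {
  seed <- as.numeric(seed)
  stopifnot(length(seed) == 3, spacing > 0, probe >= 0, bounds > spacing)
  a <- s$atoms
  occ <- !(a$resname %in% exclude_resnames) & a$element != "H"
  ax <- coords(s)[occ, , drop = FALSE]
  rad <- VDW_RADII[a$element[occ]]
  rad[is.na(rad)] <- 1.70

  # bare-sphere seed check
  if (nrow(ax) > 0) {
    d2 <- rowSums(sweep(ax, 2, seed)^2)
    if (any(d2 < rad^2)) stop("seed point lies inside an atom's vdW sphere")
  }

  # voxel centres on a half-offset (midpoint-rule) lattice: no centre falls
  # exactly on a symmetric molecular surface, halving the boundary bias
  n <- as.integer(ceiling(2 * bounds / spacing))
  g1 <- -bounds + (seq_len(n) - 0.5) * spacing
  blocked <- array(FALSE, dim = c(n, n, n))
  rr <- rad + probe
  # mark blocked voxels atom by atom over the local sub-box
  for (k in seq_len(nrow(ax))) {
    ctr <- ax[k, ] - seed
    lo <- pmax(1L, as.integer(ceiling((ctr - rr[k] + bounds) / spacing + 0.5)))
    hi <- pmin(n, as.integer(floor((ctr + rr[k] + bounds) / spacing + 0.5)))
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx2 <- (g1[ix] - ctr[1])^2
    dy2 <- (g1[iy] - ctr[2])^2
    dz2 <- (g1[iz] - ctr[3])^2
    sub <- outer(outer(dx2, dy2, "+"), dz2, "+") <= rr[k]^2
    blocked[ix, iy, iz] <- blocked[ix, iy, iz] | sub
  }

  s0 <- max(1L, min(n, as.integer(round(bounds / spacing + 0.5))))  # seed voxel
  if (blocked[s0, s0, s0]) {
    return(structure(list(volume = 0, n_grid_points = 0L, spacing = spacing,
                          probe = probe, seed = seed, open = FALSE),
                     class = "tmg_pocket"))
  }

  # 6-connected flood fill by frontier dilation on the logical array
  filled <- array(FALSE, dim = dim(blocked))
  filled[s0, s0, s0] <- TRUE
  frontier <- filled
  free <- !blocked
  repeat {
    grown <- array(FALSE, dim = dim(filled))
    grown[-1, , ] <- grown[-1, , ] | frontier[-n, , ]
    grown[-n, , ] <- grown[-n, , ] | frontier[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | frontier[, -n, ]
    grown[, -n, ] <- grown[, -n, ] | frontier[, -1, ]
    grown[, , -1] <- grown[, , -1] | frontier[, , -n]
    grown[, , -n] <- grown[, , -n] | frontier[, , -1]
    frontier <- grown & free & !filled
    if (!any(frontier)) break
    filled <- filled | frontier
  }
  open_pocket <- any(filled[c(1, n), , ]) || any(filled[, c(1, n), ]) ||
    any(filled[, , c(1, n)])
  npts <- sum(filled)
  structure(list(volume = npts * spacing^3, n_grid_points = npts,
                 spacing = spacing, probe = probe, seed = seed,
                 open = open_pocket),
            class = "tmg_pocket")
}

#' @export
print.tmg_pocket <- function(x, ...) {
  cat(sprintf("<tmg_pocket> %.1f A^3 (%d points @ %.2f A, probe %.2f A)%s\n",
              x$volume, x$n_grid_points, x$spacing, x$probe,
              if (x$open) " [open: fill reached bounds]" else ""))
  invisible(x)
}

#' Compare binding-site geometry and pocket volume between two states
#'
#' Tabulates [site_geometry()] distances and, when a seed can be derived
#' from the ligand (or is supplied), [pocket_volume()] for both structures,
#' with their differences. Per-field failures are recorded as `NA` rather
#' than aborting.
#'
#' @param occluded,inward `tmg_structure` objects for the two states.
#' @param ligand_sel ligand selection, as in [site_geometry()].
#' @param pocket logical: also compute pocket volumes (needs a ligand or
#'   explicit seeds).
#' @param seeds optional list of two 3-vectors overriding the ligand-derived
#'   pocket seeds.
#' @param ... passed to [pocket_volume()].
#' @return data.frame: quantity, occluded, inward, delta, unit.
#' @export
site_compare <- function(occluded, inward, ligand_sel = sel(resnames = "NO3"),
                         pocket = TRUE, seeds = NULL, ...) {
  gs <- lapply(list(occluded, inward), function(s)
    tryCatch(site_geometry(s, ligand_sel), error = function(e) NULL))
  grab <- function(g, path) {
    if (is.null(g)) return(NA_real_)
    v <- g
    for (p in path) v <- v[[p]]
    if (is.null(v)) NA_real_ else v
  }
  fields <- list(
    c("siteA", "min"), c("siteA", "nh1"), c("siteA", "nh2"),
    "siteB", c("siteB_network", "y263_r305"), c("siteB_network", "r305_s366"),
    "siteC",
    c("sandwich", "F147", "dist"), c("sandwich", "F267", "dist"),
    c("sandwich", "F147", "angle"), c("sandwich", "F267", "angle"))
  labels <- c("siteA_min", "siteA_nh1", "siteA_nh2", "siteB",
              "y263_r305", "r305_s366", "siteC",
              "sandwich_f147_dist", "sandwich_f267_dist",
              "sandwich_f147_angle", "sandwich_f267_angle")
  units <- c(rep("A", 9), "deg", "deg")
  v_occ <- vapply(fields, grab, 0, g = gs[[1]])
  v_in <- vapply(fields, grab, 0, g = gs[[2]])
  out <- data.frame(quantity = labels, occluded = v_occ, inward = v_in,
                    delta = v_in - v_occ, unit = units,
                    stringsAsFactors = FALSE)
  if (pocket) {
    vols <- mapply(function(s, i) {
      seed <- if (!is.null(seeds)) seeds[[i]] else {
        lig <- resolve(ligand_sel, s, allow_empty = TRUE)
        if (nrow(lig$keys) == 0) return(NA_real_)
        colMeans(lig$coords)
      }
      tryCatch(pocket_volume(s, seed, ...)$volume, error = function(e) NA_real_)
    }, list(occluded, inward), 1:2)
    out <- rbind(out, data.frame(quantity = "pocket_volume",
                                 occluded = vols[1], inward = vols[2],
                                 delta = vols[2] - vols[1], unit = "A^3",
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
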