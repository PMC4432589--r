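# Synthetic-structure generators with known ground truth. Every analysis
# stage has a generator here that plants the quantity the stage measures
# (axis direction, hinge angle, centroid separation, cavity volume, noise
# amplitude, hydrogen-bond geometry), so the whole toolkit is testable
# without downloading coordinates. Fixtures are geometric, not physical: no
# sterics, no Ramachandran validity.

#' Generate an ideal (optionally hinge-bent) alpha helix
#'
#' C-alpha trace with textbook helix parameters: 1.5 A rise per residue,
#' 100 degree twist, 2.3 A C-alpha radius. With `backbone = TRUE` each
#' residue carries N, CA, C, O and CB pseudo-atoms placed on concentric
#' helical curves (geometrically helix-like; adequate for I/O and selection
#' fixtures, not for chemistry). If `bend_angle > 0`, residues beyond
#' `hinge_index` are rotated rigidly by that angle about an axis through the
#' hinge C-alpha perpendicular to the helix axis — an exactly planted hinge.
#'
#' @param n_res residue count (>= 8 when a bend is requested).
#' @param bend_angle planted hinge angle, degrees in [0, 90].
#' @param hinge_index residue position of the hinge (default: middle).
#' @param rise_per_res,twist_per_res,ca_radius helix constants (A, deg, A).
#' @param axis unit 3-vector for the helix direction (default +z).
#' @param chain chain id.
#' @param start_res author number of the first residue.
#' @param backbone emit N/CA/C/O/CB per residue instead of a C-alpha trace.
#' @param resname residue name (default poly-ALA).
#' @return a `tmg_structure`; deterministic (no randomness involved).
#' @export
make_helix <- function(n_res, bend_angle = 0, hinge_index = NULL,
                       rise_per_res = 1.5, twist_per_res = 100,
                       ca_radius = 2.3, axis = c(0, 0, 1), chain = "A",
                       start_res = 1L, backbone = FALSE, resname = "ALA") {
  if (bend_angle < 0 || bend_angle > 90) stop("bend_angle must be in [0, 90]")
  if (bend_angle > 0 && n_res < 8) stop("a hinged helix needs >= 8 residues")
  if (is.null(hinge_index)) hinge_index <- ceiling(n_res / 2)
  th <- (seq_len(n_res) - 1) * twist_per_res * pi / 180
  zz <- (seq_len(n_res) - 1) * rise_per_res
  place <- function(r, phase, dz)
    cbind(r * cos(th + phase), r * sin(th + phase), zz + dz)
  ca <- place(ca_radius, 0, 0)

  if (backbone) {
    atoms_per_res <- list(
      N = place(1.6, -0.5, -0.9), CA = ca, C = place(2.0, 0.5, 0.6),
      O = place(2.2, 0.7, 1.1), CB = place(3.3, -0.1, -0.2))
  } else atoms_per_res <- list(CA = ca)

  if (bend_angle > 0) {
    pivot <- ca[hinge_index, ]
    R <- rotation_about(c(1, 0, 0), bend_angle)  # perpendicular to +z axis
    mv <- seq_len(n_res) > hinge_index
    atoms_per_res <- lapply(atoms_per_res, function(m) {
      m[mv, ] <- sweep(sweep(m[mv, , drop = FALSE], 2, pivot) %*% t(R),
                       2, pivot, "+")
      m
    })
  }
  if (!isTRUE(all.equal(axis, c(0, 0, 1)))) {
    R <- rotation_between(c(0, 0, 1), axis)
    atoms_per_res <- lapply(atoms_per_res, function(m) m %*% t(R))
  }

  nm <- names(atoms_per_res)
  rows <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    xyz <- do.call(rbind, lapply(atoms_per_res, function(m) m[i, ]))
    data.frame(chain = chain, resseq = start_res + i - 1L,
               resname = resname, atom = nm,
               element = substr(nm, 1, 1),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }))
  new_structure(rows, title = "synthetic helix")
}

# rotation matrix: angle degrees about unit axis u (Rodrigues)
rotation_about <- function(u, angle_deg) {
  u <- u / sqrt(sum(u^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# minimal rotation carrying unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    return(rotation_about(v, 180))
  }
  rotation_about(v, atan2(s, cth) * 180 / pi)
}

#' Generate a toy two-bundle transporter with a planted centroid separation
#'
#' Builds two identical helix bundles (chains `A` and `B`) and translates
#' bundle B so that the centroid distance between the two chains' C-alpha
#' sets is exactly `separation` along +x. No clash checking is performed —
#' arbitrary separations, including unphysically small ones, are honoured.
#'
#' @param separation planted centroid distance (A, > 0).
#' @param n_helices helices per bundle.
#' @param n_res residues per helix.
#' @param seed integer seed (helix placement jitter is deterministic given
#'   the seed).
#' @return list: `structure` (a `tmg_structure`), `selA`, `selB` (the
#'   chain selections whose C-alpha centroids realise the separation).
#' @export
make_two_bundle <- function(separation, n_helices = 3, n_res = 20, seed = 1) {
  if (separation <= 0) stop("separation must be positive")
  if (n_helices < 1 || n_res < 4) stop("invalid bundle geometry")
  bundle <- function(chain, start_res) {
    hel <- lapply(seq_len(n_helices), function(h) {
      ang <- 2 * pi * (h - 1) / n_helices
      s <- make_helix(n_res, chain = chain,
                      start_res = start_res + (h - 1L) * n_res)
      xyz <- coords(s) + matrix(rep(4 * c(cos(ang), sin(ang), 0), nrow(s$atoms)),
                                ncol = 3, byrow = TRUE)
      set_coords(s, xyz)
    })
    atoms <- do.call(rbind, lapply(hel, function(s) s$atoms))
    new_structure(atoms, title = "synthetic bundle")
  }
  jitter <- with_seed(seed, stats::runif(3, -1, 1))
  a <- bundle("A", 1L)
  b <- bundle("B", 1L)
  # centre each bundle's CA centroid, then place B at the exact separation
  centre <- function(s) {
    ctr <- colMeans(resolve(sel(atoms = "CA"), s)$coords)
    set_coords(s, sweep(coords(s), 2, ctr))
  }
  a <- centre(a)
  b <- centre(b)
  b <- set_coords(b, sweep(coords(b), 2, c(separation, 0, 0), "+"))
  a <- set_coords(a, sweep(coords(a), 2, jitter, "+"))
  b <- set_coords(b, sweep(coords(b), 2, jitter, "+"))
  list(structure = new_structure(rbind(a$atoms, b$atoms),
                                 title = "synthetic two-bundle"),
       selA = sel(chains = "A", atoms = "CA"),
       selB = sel(chains = "B", atoms = "CA"))
}

#' Generate a hollow cubic cavity of analytic volume
#'
#' Builds a cubic shell of pseudo carbon atoms whose van der Waals surface
#' lies exactly on the faces of an empty cube of side `inner_side` centred
#' at the origin: atom centres sit `r_C = 1.70` A outside each face, on a
#' square lattice of pitch `wall_spacing`. For probe radius 0 the enclosed
#' volume is `inner_side^3` analytically (up to sub-voxel scalloping between
#' lattice atoms, negligible at the default pitch).
#'
#' @param inner_side inner cube side (A).
#' @param wall_spacing lattice pitch of the wall atoms; must be <= 1.2 A so
#'   the wall is probe-tight (larger pitches leak and are rejected).
#' @return list: `structure`, `seed_point` (the cavity centre, origin) and
#'   `volume` (the analytic enclosed volume for probe 0).
#' @export
make_cavity <- function(inner_side = 4, wall_spacing = 0.4) {
  if (wall_spacing > 1.2) stop("wall_spacing > 1.2 A leaks: wall not probe-tight")
  if (inner_side <= 0) stop("inner_side must be positive")
  r_c <- as.numeric(VDW_RADII["C"])
  half <- inner_side / 2
  off <- half + r_c                  # wall-atom centre plane
  g <- seq(-off, off, by = wall_spacing)
  faces <- list()
  for (sgn in c(-1, 1)) {
    gg <- expand.grid(u = g, v = g)
    faces[[length(faces) + 1]] <- cbind(sgn * off, gg$u, gg$v)
    faces[[length(faces) + 1]] <- cbind(gg$u, sgn * off, gg$v)
    faces[[length(faces) + 1]] <- cbind(gg$u, gg$v, sgn * off)
  }
  xyz <- unique(do.call(rbind, faces))
  atoms <- data.frame(chain = "W", resseq = seq_len(nrow(xyz)),
                      resname = "WAL", atom = "C", element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      het = TRUE, stringsAsFactors = FALSE)
  list(structure = new_structure(atoms, title = "synthetic cavity"),
       seed_point = c(0, 0, 0), volume = inner_side^3)
}

#' Generate an interpolation trajectory between two conformations
#'
#' Frame k (k = 0..n-1) is the linear interpolation from `start` to `end`
#' at fraction k/(n-1), optionally restricted to `moving_sel` (atoms outside
#' the moving selection stay at their `start` positions), plus iid Gaussian
#' noise of standard deviation `noise_sigma` per coordinate. Noise is
#' applied after interpolation, never to the endpoint structures themselves.
#' Deterministic given `seed`.
#'
#' @param start,end `tmg_structure` objects sharing one atom roster.
#' @param n_frames frame count (>= 2).
#' @param noise_sigma Gaussian coordinate noise, A (>= 0).
#' @param seed integer RNG seed.
#' @param moving_sel optional [sel()] restricting the interpolated motion.
#' @param times optional frame times (ns).
#' @return a `tmg_trajectory`.
#' @export
make_trajectory <- function(start, end, n_frames = 50, noise_sigma = 0,
                            seed = 1, moving_sel = NULL, times = NULL) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!identical(atom_keys(start$atoms), atom_keys(end$atoms)))
    stop("start and end structures do not share one atom roster")
  x0 <- coords(start); x1 <- coords(end)
  delta <- x1 - x0
  if (!is.null(moving_sel)) {
    keep <- resolve(moving_sel, start)$index
    mask <- rep(0, nrow(x0)); mask[keep] <- 1
    delta <- delta * mask
  }
  frames <- with_seed(seed, lapply(seq_len(n_frames) - 1L, function(k) {
    fr <- x0 + delta * (k / (n_frames - 1L))
    if (noise_sigma > 0)
      fr <- fr + matrix(stats::rnorm(length(fr), 0, noise_sigma), ncol = 3)
    fr
  }))
  new_trajectory(start, frames, times)
}

#' Place atoms verbatim to build a toy interaction site
#'
#' Builds a structure from an explicit atom table — used to plant hydrogen
#' bonds, salt bridges and water bridges at exact distances. Duplicate
#' (chain, residue, atom) keys are rejected.
#'
#' @param atoms data.frame with at least `resseq`, `resname`, `atom`, `x`,
#'   `y`, `z`; optional `chain` (default "A") and `element`.
#' @return a `tmg_structure`.
#' @export
plant_site <- function(atoms) {
  if (!is.data.frame(atoms) || nrow(atoms) == 0)
    stop("plant_site needs a nonempty atom table")
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$het)) atoms$het <- !(atoms$resname %in% standard_residues())
  key <- paste(atoms$chain, atoms$resseq, atoms$atom, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate atom keys in planted site")
  new_structure(atoms, title = "synthetic site")
}
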