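# Shared fixtures and independent oracles. All fixtures are generated in
# code; nothing is read from disk except files the tests write themselves.

# --- independent rigid-fit oracle -------------------------------------------
# Minimum RMSD over proper rotations found numerically: rotation
# parameterised by ZYZ Euler angles, centroids removed (the least-squares
# translation), multi-start Nelder-Mead + BFGS polish. Independent of the
# SVD route used by kabsch_fit().
euler_rot <- function(p) {
  cz1 <- cos(p[1]); sz1 <- sin(p[1])
  cy <- cos(p[2]); sy <- sin(p[2])
  cz2 <- cos(p[3]); sz2 <- sin(p[3])
  Rz1 <- matrix(c(cz1, -sz1, 0, sz1, cz1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz2 <- matrix(c(cz2, -sz2, 0, sz2, cz2, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

brute_force_rmsd <- function(X, Y, n_starts = 12) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  obj <- function(p) {
    R <- euler_rot(p)
    sqrt(mean(rowSums((Yc %*% t(R) - Xc)^2)))
  }
  best <- Inf
  starts <- rbind(c(0, 0, 0),
                  as.matrix(expand.grid(a = c(0.8, 2.4, 4.4),
                                        b = c(0.6, 2.2),
                                        c = c(1.1, 3.9)))[seq_len(n_starts - 1), ])
  for (i in seq_len(nrow(starts))) {
    r0 <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
    r1 <- stats::optim(r0$par, obj, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, r0$value, r1$value)
  }
  best
}

# --- random rigid transforms ------------------------------------------------
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigid_transform <- function(s, R = random_rotation(), t = stats::rnorm(3, 0, 10)) {
  set_coords(s, sweep(coords(s) %*% t(R), 2, t, "+"))
}

# --- planted interaction-site fixtures --------------------------------------
# A toy site with exactly planted polar interactions:
#   - hydrogen bond: SER17 OG -> ALA12 O at 2.80 A
#   - salt bridge: ARG89 NH1/NH2 -> GLU95 OE1/OE2 at 2.70/2.75 A
#   - water bridge: HOH300 O at 2.80 A from ALA40 O and ALA50 O
#   - a distant (> 6 A) ALA60 O that must never be hit
toy_polar_site <- function() {
  plant_site(data.frame(
    resseq = c(12L, 17L, 89L, 89L, 95L, 95L, 40L, 50L, 300L, 60L),
    resname = c("ALA", "SER", "ARG", "ARG", "GLU", "GLU", "ALA", "ALA",
                "HOH", "ALA"),
    atom = c("O", "OG", "NH1", "NH2", "OE1", "OE2", "O", "O", "O", "O"),
    element = c("O", "O", "N", "N", "O", "O", "O", "O", "O", "O"),
    x = c(0, 2.80, 10, 10, 12.70, 12.75, 20, 25.60, 22.80, 40),
    y = c(0, 0, 0, 1.40, 0, 1.40, 0, 0, 0, 0),
    z = 0))
}

# Nitrate site with exactly planted distances. The nitrate is an ideal
# trigonal NO3 (N at the origin, three oxygens at 120 degrees, N-O 1.25 A);
# each protein atom sits along a chosen direction at its planted distance:
#   siteA: R89 NH1 d_nh1 from O1, NH2 d_nh1 + 0.05 from O2 (min = d_nh1)
#   siteB: Y263 OH 2.40 A from O3; OH-R305 NH1 3.00 A; NH1-S366 OG 2.80 A
#   siteC: N175 ND2 3.10 A from O1 (out of plane)
toy_nitrate_site <- function(d_nh1 = 2.70, d_y263 = 2.40) {
  o1 <- c(1.25, 0, 0)
  o2 <- 1.25 * c(cos(2 * pi / 3), sin(2 * pi / 3), 0)
  o3 <- 1.25 * c(cos(4 * pi / 3), sin(4 * pi / 3), 0)
  radial <- function(o, d) o * (1 + d / 1.25)   # extend outward from N
  nh1 <- radial(o1, d_nh1)
  nh2 <- radial(o2, d_nh1 + 0.05)
  oh <- radial(o3, d_y263)
  r305 <- oh + c(0, -3.00, 0)
  og <- r305 + c(0, -2.80, 0)
  nd2 <- o1 + c(0, 0, 3.10)
  xyz <- rbind(nh1, nh2, oh, r305, og, nd2, c(0, 0, 0), o1, o2, o3)
  plant_site(data.frame(
    resseq = c(89L, 89L, 263L, 305L, 366L, 175L, 600L, 600L, 600L, 600L),
    resname = c("ARG", "ARG", "TYR", "ARG", "SER", "ASN",
                "NO3", "NO3", "NO3", "NO3"),
    atom = c("NH1", "NH2", "OH", "NH1", "OG", "ND2", "N", "O1", "O2", "O3"),
    element = c("N", "N", "O", "N", "O", "N", "N", "O", "O", "O"),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}
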