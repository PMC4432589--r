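# Helix axis fitting and hinge bend-angle quantification between
# conformational states.

#' Define a transmembrane helix segment
#'
#' A segment names a helix, its full residue range, the hinge residues
#' (conserved glycines in the NarK case) and the two rigid halves on either
#' side of the hinge. The moving half is the cytosolic half whose
#' reorientation between states is reported as the bend angle.
#'
#' @param name helix label, e.g. `"TM10"`.
#' @param full_range `c(start, end)` residue range of the whole helix.
#' @param hinge integer vector of hinge residue numbers.
#' @param moving_half `c(start, end)` cytosolic-half residue range.
#' @param static_half `c(start, end)` remainder of the helix.
#' @return object of class `tmg_helix_segment`.
#' @export
helix_segment <- function(name, full_range, hinge, moving_half, static_half) {
  overlap <- max(moving_half[1], static_half[1]) <= min(moving_half[2], static_half[2])
  if (overlap) stop("moving and static halves overlap")
  for (h in list(moving_half, static_half))
    if (h[1] < full_range[1] || h[2] > full_range[2])
      stop("half ranges must lie within the full helix range")
  structure(list(name = name, full_range = full_range, hinge = hinge,
                 moving_half = moving_half, static_half = static_half),
            class = "tmg_helix_segment")
}

#' Default NarK helix segment table
#'
#' The hinge glycines are G268 (TM7), G363/G365/G367 (TM10) and
#' G408/G414/G417/G418 (TM11). The moving (cytosolic) halves of TM10 and
#' TM11 reuse the only residue-exact cytosolic ranges published for these
#' helices (T369-L380 and A399-F409, the gate order-parameter ranges); the
#' TM7 cytosolic half runs from the G268 hinge to the helix end. All ranges
#' are plain data and can be edited or replaced.
#'
#' @return named list of [helix_segment()] objects.
#' @export
default_helix_segments <- function() list(
  TM7 = helix_segment("TM7", c(243, 278), hinge = 268,
                      moving_half = c(269, 278), static_half = c(243, 266)),
  TM10 = helix_segment("TM10", c(352, 382), hinge = c(363, 365, 367),
                       moving_half = c(369, 380), static_half = c(352, 362)),
  TM11 = helix_segment("TM11", c(386, 420), hinge = c(408, 414, 417, 418),
                       moving_half = c(399, 409), static_half = c(386, 398)))

#' Fit an axis to an ordered C-alpha run
#'
#' The C-alpha positions are smoothed with a running mean over a short
#' window (default 4 residues, roughly one helical turn) to suppress the
#' helical wobble, then the principal direction of the smoothed points is
#' taken as the axis. The sign is oriented from the N-terminal to the
#' C-terminal end of the segment.
#'
#' @param xyz ordered n x 3 C-alpha coordinates, n >= 4.
#' @param window running-mean window (residues).
#' @return list: `axis` (unit 3-vector), `centroid`, `anisotropy` (ratio of
#'   the first two singular values of the smoothed cloud) and `flat`
#'   (TRUE when anisotropy < 2: the axis direction is poorly determined).
#' @export
fit_helix_axis <- function(xyz, window = 4) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n < 4) stop("at least 4 C-alpha atoms required for an axis fit")
  w <- min(window, n)
  if (w > 1) {
    sm <- matrix(0, n - w + 1, 3)
    for (j in 1:3) {
      cs <- cumsum(c(0, xyz[, j]))
      sm[, j] <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
    }
  } else sm <- xyz
  ctr <- colMeans(sm)
  smc <- sweep(sm, 2, ctr)
  sv <- svd(smc, nu = 0, nv = 3)
  axis <- sv$v[, 1]
  if (sum((sm[nrow(sm), ] - sm[1, ]) * axis) < 0) axis <- -axis
  aniso <- if (sv$d[2] > 1e-12) sv$d[1] / sv$d[2] else Inf
  list(axis = axis / sqrt(sum(axis^2)), centroid = ctr,
       anisotropy = aniso, flat = is.finite(aniso) && aniso < 2)
}

#' Bend angle of a helix half between two conformational states
#'
#' `alt` is superposed onto `ref` over the global-fit selection (default:
#' the N-bundle C-alpha set, residues 1-233, which is structurally invariant
#' between the states being compared), axes are fitted to the moving-half
#' C-alpha run of each state, and the angle between the two oriented axes is
#' returned in degrees. A signed radial-displacement diagnostic
#' (`radial_shift`, Angstrom) reports whether the moving-half centroid moved
#' away from (+) or towards (-) the whole-molecule centroid — the direction
#' language of gate opening — without folding direction into the angle.
#'
#' @param ref,alt `tmg_structure` objects (e.g. occluded and inward-open).
#' @param seg a [helix_segment()].
#' @param global_fit selection used to superpose `alt` onto `ref`.
#' @param chain_map optional chain mapping for the superposition.
#' @param window axis-fit smoothing window, see [fit_helix_axis()].
#' @return list: `helix`, `angle_deg` in [0, 180], `axis_ref`, `axis_alt`,
#'   `n_axis_atoms`, `radial_shift`, `flat` flag.
#' @export
bend_angle <- function(ref, alt, seg,
                       global_fit = sel(ranges = list(c(1, 233)), atoms = "CA"),
                       chain_map = NULL, window = 4) {
  stopifnot(inherits(seg, "tmg_helix_segment"))
  pf <- pair_common_atoms(ref, alt, global_fit, chain_map)
  fit <- kabsch_fit(pf$X, pf$Y)
  alt_fitted <- apply_fit(fit, alt)

  msel <- sel(ranges = list(seg$moving_half), atoms = "CA")
  ca_ref <- resolve(msel, ref)
  ca_alt <- resolve(msel, alt_fitted)
  if (nrow(ca_ref$coords) < 4 || nrow(ca_alt$coords) < 4)
    stop("moving half of ", seg$name, " resolves fewer than 4 C-alpha atoms")
  ax_r <- fit_helix_axis(ca_ref$coords, window)
  ax_a <- fit_helix_axis(ca_alt$coords, window)
  ang <- acos(max(-1, min(1, sum(ax_r$axis * ax_a$axis)))) * 180 / pi

  ctr_all <- colMeans(resolve(sel(atoms = "CA"), ref)$coords)
  radial <- function(p) sqrt(sum((p - ctr_all)^2))
  rshift <- radial(colMeans(ca_alt$coords)) - radial(colMeans(ca_ref$coords))

  list(helix = seg$name, angle_deg = ang,
       axis_ref = ax_r$axis, axis_alt = ax_a$axis,
       n_axis_atoms = nrow(ca_ref$coords),
       radial_shift = rshift, flat = ax_r$flat || ax_a$flat)
}

#' Tabulate bend angles over a set of helix segments
#'
#' Maps [bend_angle()] over the segments; per-segment failures (e.g. a half
#' fully disordered in one state) are recorded in the `status` column rather
#' than aborting the report.
#'
#' @param ref,alt `tmg_structure` objects.
#' @param segments list of [helix_segment()]s (default
#'   [default_helix_segments()]).
#' @param ... passed to [bend_angle()].
#' @return data.frame: helix, angle_deg, radial_shift, n_axis_atoms, hinge,
#'   status (`"ok"`, `"flat"` or `"unresolved"`).
#' @export
bend_report <- function(ref, alt, segments = default_helix_segments(), ...) {
  if (length(segments) == 0)
    return(data.frame(helix = character(), angle_deg = numeric(),
                      radial_shift = numeric(), n_axis_atoms = integer(),
                      hinge = character(), status = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(segments, function(seg) {
    res <- tryCatch(bend_angle(ref, alt, seg, ...), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(helix = seg$name, angle_deg = NA_real_,
                 radial_shift = NA_real_, n_axis_atoms = 0L,
                 hinge = paste(seg$hinge, collapse = ","),
                 status = "unresolved", stringsAsFactors = FALSE)
    } else {
      data.frame(helix = res$helix, angle_deg = res$angle_deg,
                 radial_shift = res$radial_shift,
                 n_axis_atoms = res$n_axis_atoms,
                 hinge = paste(seg$hinge, collapse = ","),
                 status = if (res$flat) "flat" else "ok",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
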