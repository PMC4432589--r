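# Trajectory statistics: RMSD time series, per-residue RMSF, and the
# inter-bundle centroid-distance order parameter.

#' Default centroid-distance selections for the cytoplasmic gate
#'
#' The gate order parameter is the distance between the C-alpha centroids of
#' the cytosolic parts of TM4-TM5 (residues A148 to G171) and of TM10-TM11
#' (T369 to L380 together with A399 to F409).
#'
#' @return list with elements `A` and `B`, both [sel()] objects.
#' @export
default_bundle_selections <- function() list(
  A = sel(ranges = list(c(148, 171)), atoms = "CA"),
  B = sel(ranges = list(c(369, 380), c(399, 409)), atoms = "CA"))

traj_index <- function(traj, selection) resolve(selection, traj$topology)$index

traj_times <- function(traj) {
  if (!is.null(traj$times)) traj$times else seq_along(traj$frames) - 1
}

#' RMSD of each trajectory frame against a reference structure
#'
#' Per frame: the frame is superposed onto the reference over the atoms
#' paired by `fit_sel`, then the RMSD is reported over the `measure_sel`
#' pairs (defaults: both all C-alpha). The reference may be the topology
#' itself or any structure sharing the atom naming.
#'
#' @param traj a `tmg_trajectory`.
#' @param ref reference `tmg_structure` (default: the topology).
#' @param fit_sel,measure_sel selections, as in [rmsd_between()].
#' @param chain_map optional chain mapping reference -> topology.
#' @return data.frame of class `tmg_series`: `time`, `value` (Angstrom).
#' @export
rmsd_series <- function(traj, ref = traj$topology,
                        fit_sel = sel(atoms = "CA"), measure_sel = NULL,
                        chain_map = NULL) {
  if (is.null(measure_sel)) measure_sel <- fit_sel
  pf <- pair_common_atoms(ref, traj$topology, fit_sel, chain_map)
  pm <- pair_common_atoms(ref, traj$topology, measure_sel, chain_map)
  fit_rows <- pf$index_b
  meas_rows <- pm$index_b
  vals <- vapply(traj$frames, function(fr) {
    f <- kabsch_fit(pf$X, fr[fit_rows, , drop = FALSE])
    sqrt(mean(rowSums((apply_fit(f, fr[meas_rows, , drop = FALSE]) - pm$X)^2)))
  }, 0)
  structure(data.frame(time = traj_times(traj), value = vals),
            class = c("tmg_series", "data.frame"), name = "rmsd")
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed over `fit_sel` in two passes: first onto frame 0,
#' then onto the resulting time-mean structure (`reference = "mean"`, the
#' default) or simply onto the first frame (`reference = "first"`). The RMSF
#' of each residue is the root-mean-square deviation of its `measure_sel`
#' atoms from their time-mean positions.
#'
#' @param traj a `tmg_trajectory` with >= 2 frames.
#' @param fit_sel,measure_sel selections (defaults: all C-alpha).
#' @param reference `"mean"` (two-pass, fluctuation about the trajectory
#'   mean) or `"first"` (fluctuation about frame 0 after fitting to it).
#' @return data.frame: `chain`, `resseq`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, fit_sel = sel(atoms = "CA"), measure_sel = NULL,
                 reference = c("mean", "first")) {
  reference <- match.arg(reference)
  if (length(traj$frames) < 2) stop("RMSF requires at least 2 frames")
  if (is.null(measure_sel)) measure_sel <- fit_sel
  fi <- traj_index(traj, fit_sel)
  mi <- traj_index(traj, measure_sel)
  nF <- length(traj$frames)

  align_to <- function(target_fit) {
    lapply(traj$frames, function(fr) {
      f <- kabsch_fit(target_fit, fr[fi, , drop = FALSE])
      apply_fit(f, fr[mi, , drop = FALSE])
    })
  }
  # pass 1: fit to frame 0
  a1 <- lapply(traj$frames, function(fr) {
    f <- kabsch_fit(traj$frames[[1]][fi, , drop = FALSE],
                    fr[fi, , drop = FALSE])
    apply_fit(f, fr)
  })
  if (reference == "mean") {
    mean_all <- Reduce(`+`, a1) / nF
    aligned <- lapply(a1, function(fr) {
      f <- kabsch_fit(mean_all[fi, , drop = FALSE], fr[fi, , drop = FALSE])
      apply_fit(f, fr[mi, , drop = FALSE])
    })
  } else {
    aligned <- lapply(a1, function(fr) fr[mi, , drop = FALSE])
  }
  mean_pos <- Reduce(`+`, aligned) / nF
  dev2 <- Reduce(`+`, lapply(aligned, function(m) rowSums((m - mean_pos)^2))) / nF

  keys <- traj$topology$atoms[mi, c("chain", "resseq"), drop = FALSE]
  grp <- paste(keys$chain, keys$resseq, sep = "\r")
  per_res <- tapply(dev2, grp, mean)
  ord <- unique(grp)
  out <- data.frame(chain = keys$chain[!duplicated(grp)],
                    resseq = keys$resseq[!duplicated(grp)],
                    rmsf = sqrt(as.numeric(per_res[ord])))
  out[order(out$chain, out$resseq), , drop = FALSE]
}

#' Inter-bundle centroid-distance series
#'
#' Per frame: the Euclidean distance between the centroids of the two
#' C-alpha selections. No superposition is applied — this is an internal
#' coordinate, invariant under any per-frame rigid motion, which is what
#' makes it usable as an open/closed order parameter.
#'
#' @param traj a `tmg_trajectory`.
#' @param selA,selB the two selections (defaults:
#'   [default_bundle_selections()]).
#' @param reference_lines optional named numeric vector of crystal-structure
#'   reference distances, attached to the result.
#' @return data.frame of class `tmg_series`: `time`, `value` (Angstrom),
#'   with a `reference_lines` attribute.
#' @export
bundle_distance_series <- function(traj,
                                   selA = default_bundle_selections()$A,
                                   selB = default_bundle_selections()$B,
                                   reference_lines = NULL) {
  ia <- traj_index(traj, selA)
  ib <- traj_index(traj, selB)
  vals <- vapply(traj$frames, function(fr) {
    sqrt(sum((colMeans(fr[ia, , drop = FALSE]) -
                colMeans(fr[ib, , drop = FALSE]))^2))
  }, 0)
  out <- structure(data.frame(time = traj_times(traj), value = vals),
                   class = c("tmg_series", "data.frame"), name = "bundle_distance")
  attr(out, "reference_lines") <- reference_lines
  out
}

#' Centroid-distance reference values from static structures
#'
#' The same centroid computation as [bundle_distance_series()], applied to
#' crystal structures; used as the dashed reference lines against which a
#' trajectory's order parameter is read.
#'
#' @param structs named list of `tmg_structure` objects.
#' @param selA,selB the two selections.
#' @return named numeric vector of distances (Angstrom).
#' @export
crystal_reference_distances <- function(structs,
                                        selA = default_bundle_selections()$A,
                                        selB = default_bundle_selections()$B) {
  vapply(structs, function(s) {
    ca <- colMeans(resolve(selA, s)$coords)
    cb <- colMeans(resolve(selB, s)$coords)
    sqrt(sum((ca - cb)^2))
  }, 0)
}
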