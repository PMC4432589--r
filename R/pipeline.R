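# End-to-end state-comparison pipeline composing the analysis stages, plus
# its configuration table. All residue constants are plain data and can be
# overridden for other MFS transporters.

#' Default pipeline configuration for the NarK state comparison
#'
#' Bundles the residue constants the analyses need: the N-bundle global-fit
#' selection (C-alpha 1-233, the half that does not move between states),
#' the hinge-helix segment table, the gate-layer table, the binding-site
#' residues, the gate order-parameter selections and the ligand residue
#' name.
#'
#' @param ... named overrides of any listed field.
#' @return list of class `tmg_pipeline_config`.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    global_fit = sel(ranges = list(c(1, 233)), atoms = "CA"),
    measure_sel = sel(atoms = "CA"),
    segments = default_helix_segments(),
    layers = default_gate_layers(),
    site_residues = default_site_residues(),
    bundle_selections = default_bundle_selections(),
    ligand_sel = sel(resnames = "NO3"),
    pocket_spacing = 0.25, pocket_probe = 1.4, pocket_bounds = 6,
    chain_map = NULL)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "tmg_pipeline_config"
  cfg
}

#' Run the full occluded vs inward-open state comparison
#'
#' Composes the analysis stages over two (optionally three) structures:
#' whole-molecule C-alpha RMSD after N-bundle superposition, hinge bend
#' angles, gate-layer states of both structures, binding-site geometry and
#' pocket-volume comparison, and the inter-bundle centroid reference
#' distances. The run is deterministic; per-stage failures are caught,
#' recorded in `errors`, and leave `NA` rows rather than aborting.
#'
#' @param occluded,inward `tmg_structure` objects or PDB file paths for the
#'   occluded and inward-open states.
#' @param apo optional apo-state structure or path (adds the apo-vs-bound
#'   RMSD row).
#' @param config a [default_pipeline_config()].
#' @param outdir optional directory: when given, writes `report.json` plus
#'   TSV tables (`bend.tsv`, `gates_*.tsv`, `site.tsv`) into it.
#' @return list of class `tmg_report`: `rmsd` (data.frame), `bend`
#'   (data.frame), `gates` (list of two [gate_state()] results), `site`
#'   (data.frame from [site_compare()]), `reference_distances` (named
#'   numeric), `errors` (character).
#' @export
run_state_comparison <- function(occluded, inward, apo = NULL,
                                 config = default_pipeline_config(),
                                 outdir = NULL) {
  load1 <- function(x) if (inherits(x, "tmg_structure")) x else read_pdb(x)
  occ <- load1(occluded); inw <- load1(inward)
  apo_s <- if (!is.null(apo)) load1(apo) else NULL
  errors <- character()
  note <- function(stage, e) {
    errors[[length(errors) + 1]] <<- paste0(stage, ": ", conditionMessage(e))
    NULL
  }

  rmsd_rows <- list()
  r1 <- tryCatch(rmsd_between(occ, inw, config$measure_sel,
                              chain_map = config$chain_map),
                 error = function(e) note("rmsd occluded-vs-inward", e))
  if (!is.null(r1))
    rmsd_rows$occluded_vs_inward <- data.frame(
      comparison = "occluded_vs_inward", rmsd = r1$rmsd, n_atoms = r1$n_measure)
  if (!is.null(apo_s)) {
    r2 <- tryCatch(rmsd_between(apo_s, inw, config$measure_sel,
                                chain_map = config$chain_map),
                   error = function(e) note("rmsd apo-vs-bound", e))
    if (!is.null(r2))
      rmsd_rows$apo_vs_bound <- data.frame(
        comparison = "apo_vs_bound_inward", rmsd = r2$rmsd,
        n_atoms = r2$n_measure)
  }
  rmsd_tab <- if (length(rmsd_rows)) do.call(rbind, rmsd_rows) else NULL
  if (!is.null(rmsd_tab)) rownames(rmsd_tab) <- NULL

  bend_tab <- tryCatch(
    bend_report(occ, inw, config$segments, global_fit = config$global_fit,
                chain_map = config$chain_map),
    error = function(e) note("bend", e))
  gates <- list(
    occluded = tryCatch(gate_state(occ, config$layers),
                        error = function(e) note("gates occluded", e)),
    inward = tryCatch(gate_state(inw, config$layers),
                      error = function(e) note("gates inward", e)))
  site_tab <- tryCatch(
    site_compare(occ, inw, config$ligand_sel,
                 spacing = config$pocket_spacing, probe = config$pocket_probe,
                 bounds = config$pocket_bounds),
    error = function(e) note("site", e))
  refs <- tryCatch(
    crystal_reference_distances(
      list(occluded = occ, inward = inw),
      config$bundle_selections$A, config$bundle_selections$B),
    error = function(e) note("reference distances", e))

  rep <- structure(list(rmsd = rmsd_tab, bend = bend_tab, gates = gates,
                        site = site_tab, reference_distances = refs,
                        errors = errors),
                   class = "tmg_report")
  if (!is.null(outdir)) write_report(rep, outdir)
  rep
}

#' @export
print.tmg_report <- function(x, ...) {
  cat("== state comparison report ==\n")
  if (!is.null(x$rmsd)) { cat("-- RMSD (A) --\n"); print(x$rmsd) }
  if (!is.null(x$bend)) { cat("-- bend angles (deg) --\n"); print(x$bend) }
  for (nm in names(x$gates)) if (!is.null(x$gates[[nm]])) {
    cat(sprintf("-- gate [%s]: %s --\n", nm, x$gates[[nm]]$state))
    print(x$gates[[nm]]$layers)
  }
  if (!is.null(x$site)) { cat("-- binding site --\n"); print(x$site) }
  if (!is.null(x$reference_distances)) {
    cat("-- centroid reference distances (A) --\n")
    print(x$reference_distances)
  }
  if (length(x$errors)) cat("!! stage errors:", paste(x$errors, collapse = "; "), "\n")
  invisible(x)
}

write_report <- function(rep, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) utils::write.table(
    df, file.path(outdir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(rep$rmsd)) tsv(rep$rmsd, "rmsd.tsv")
  if (!is.null(rep$bend)) tsv(rep$bend, "bend.tsv")
  for (nm in names(rep$gates)) {
    g <- rep$gates[[nm]]
    if (!is.null(g)) {
      tsv(g$layers, paste0("gates_", nm, ".tsv"))
      if (!is.null(g$hits)) tsv(g$hits, paste0("gate_hits_", nm, ".tsv"))
    }
  }
  if (!is.null(rep$site)) tsv(rep$site, "site.tsv")
  payload <- list(
    rmsd = rep$rmsd, bend = rep$bend,
    gate_state = lapply(rep$gates, function(g) if (is.null(g)) NULL else g$state),
    site = rep$site,
    reference_distances = as.list(rep$reference_distances),
    errors = rep$errors)
  jsonlite::write_json(payload, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(outdir)
}
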