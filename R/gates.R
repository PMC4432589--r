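# Cytoplasmic gate-layer contact inventories: hydrophobic contacts,
# heavy-atom hydrogen bonds, water-mediated bridges, and a closed/open call.
#
# Cutoffs are standard crystallographic heuristics: 4.5 A for hydrophobic
# carbon-carbon contacts, 3.5 A heavy-atom donor-acceptor distance for
# hydrogen bonds and for each leg of a water bridge. No angular criterion is
# applied (the structures carry no hydrogens); this is a documented
# limitation, not an option.

MAIN_CHAIN_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Describe a residue group for contact detection
#'
#' @param resseq integer residue numbers.
#' @param scope atom scope per residue: `"any"`, `"side-chain"` or
#'   `"main-chain"` (recycled).
#' @param chains chain filter (default all).
#' @param atoms optional explicit atom-name filter overriding `scope`.
#' @return data.frame group descriptor.
#' @export
residue_group <- function(resseq, scope = "any", chains = "all", atoms = NULL) {
  scope <- match.arg(scope, c("any", "side-chain", "main-chain"))
  data.frame(resseq = as.integer(resseq), scope = scope,
             chains = paste(chains, collapse = ","),
             atoms = if (is.null(atoms)) "" else paste(atoms, collapse = ","),
             stringsAsFactors = FALSE)
}

# resolve a residue_group to atom rows (heavy atoms only, no waters)
resolve_group <- function(group, s) {
  a <- s$atoms
  keep <- a$resseq %in% group$resseq & a$element != "H" &
    !(a$resname %in% c("HOH", "WAT"))
  ch <- strsplit(group$chains[1], ",")[[1]]
  if (!identical(ch, "all")) keep <- keep & a$chain %in% ch
  if (nzchar(group$atoms[1])) {
    keep <- keep & a$atom %in% strsplit(group$atoms[1], ",")[[1]]
  } else if (group$scope[1] == "side-chain") {
    keep <- keep & !(a$atom %in% MAIN_CHAIN_ATOMS)
  } else if (group$scope[1] == "main-chain") {
    keep <- keep & a$atom %in% MAIN_CHAIN_ATOMS
  }
  which(keep)
}

pair_distances <- function(s, ia, ib) {
  xa <- coords(s)[ia, , drop = FALSE]
  xb <- coords(s)[ib, , drop = FALSE]
  # n_a x n_b distance matrix
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(pmax(d2, 0))
}

hit_frame <- function(s, ia, ib, d, kind, water = NA_character_) {
  if (length(ia) == 0)
    return(data.frame(atom_a = character(), atom_b = character(),
                      res_a = integer(), res_b = integer(),
                      distance = numeric(), kind = character(),
                      water = character(), stringsAsFactors = FALSE))
  a <- s$atoms
  lab <- function(i) paste0(a$chain[i], "/", a$resname[i], a$resseq[i],
                            ":", a$atom[i])
  data.frame(atom_a = lab(ia), atom_b = lab(ib),
             res_a = a$resseq[ia], res_b = a$resseq[ib],
             distance = d, kind = rep_len(kind, length(ia)),
             water = rep_len(water, length(ia)),
             stringsAsFactors = FALSE)
}

#' Heavy-atom contacts between two residue groups
#'
#' All heavy-atom pairs (one atom from each group) at or below the cutoff.
#' Symmetric in the two groups.
#'
#' @param s a `tmg_structure`.
#' @param groupA,groupB [residue_group()] descriptors.
#' @param cutoff distance cutoff in Angstrom (default 4.5, the hydrophobic
#'   contact heuristic).
#' @param carbon_only restrict both sides to carbon atoms (strict
#'   hydrophobic-contact definition).
#' @return data.frame of hits: atom labels, residue numbers, distance, kind.
#' @export
find_contacts <- function(s, groupA, groupB, cutoff = 4.5,
                          carbon_only = FALSE) {
  ia <- resolve_group(groupA, s)
  ib <- resolve_group(groupB, s)
  if (carbon_only) {
    ia <- ia[s$atoms$element[ia] == "C"]
    ib <- ib[s$atoms$element[ib] == "C"]
  }
  if (length(ia) == 0 || length(ib) == 0)
    stop("contact group resolves to zero atoms")
  d <- pair_distances(s, ia, ib)
  w <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(w) == 0) return(hit_frame(s, integer(), integer(), numeric(), character()))
  out <- hit_frame(s, ia[w[, 1]], ib[w[, 2]], d[w], "contact")
  out[order(out$distance), , drop = FALSE]
}

#' Heavy-atom hydrogen bonds between donor and acceptor groups
#'
#' Detects donor-acceptor pairs at or below `d_max` where the donor atom is
#' an N, O or S and the acceptor an N or O (heavy-atom criterion; the
#' structures carry no hydrogens, so no angular term is applied).
#'
#' @param s a `tmg_structure`.
#' @param donors,acceptors [residue_group()] descriptors.
#' @param d_max donor-acceptor heavy-atom cutoff (default 3.5 A).
#' @return data.frame of hits as in [find_contacts()].
#' @export
find_hbonds <- function(s, donors, acceptors, d_max = 3.5) {
  ia <- resolve_group(donors, s)
  ib <- resolve_group(acceptors, s)
  ia <- ia[s$atoms$element[ia] %in% c("N", "O", "S")]
  ib <- ib[s$atoms$element[ib] %in% c("N", "O")]
  if (length(ia) == 0 || length(ib) == 0)
    stop("hydrogen-bond group resolves to zero polar atoms")
  d <- pair_distances(s, ia, ib)
  w <- which(d <= d_max, arr.ind = TRUE)
  if (nrow(w) == 0) return(hit_frame(s, integer(), integer(), numeric(), character()))
  out <- hit_frame(s, ia[w[, 1]], ib[w[, 2]], d[w], "hbond")
  out[order(out$distance), , drop = FALSE]
}

#' Water-mediated hydrogen-bond bridges between two groups
#'
#' A bridge is a water whose oxygen lies within `d_max` of at least one
#' hydrogen-bond-capable (N/O) atom in each group. One hit is reported per
#' water, recording the closest partner atom on each side.
#'
#' @param s a `tmg_structure` (waters as residue name `HOH`).
#' @param groupA,groupB [residue_group()] descriptors.
#' @param d_max per-leg cutoff (default 3.5 A).
#' @return data.frame of hits; `distance` is the longer of the two legs and
#'   `water` identifies the bridging water. Empty when the structure has no
#'   waters.
#' @export
find_water_bridges <- function(s, groupA, groupB, d_max = 3.5) {
  a <- s$atoms
  iw <- which(a$resname %in% c("HOH", "WAT") & a$element == "O")
  empty <- hit_frame(s, integer(), integer(), numeric(), character())
  if (length(iw) == 0) return(empty)
  ia <- resolve_group(groupA, s); ia <- ia[a$element[ia] %in% c("N", "O")]
  ib <- resolve_group(groupB, s); ib <- ib[a$element[ib] %in% c("N", "O")]
  if (length(ia) == 0 || length(ib) == 0) return(empty)
  da <- pair_distances(s, iw, ia)
  db <- pair_distances(s, iw, ib)
  rows <- list()
  for (k in seq_along(iw)) {
    ja <- which.min(da[k, ]); jb <- which.min(db[k, ])
    if (da[k, ja] <= d_max && db[k, jb] <= d_max) {
      wlab <- paste0(a$chain[iw[k]], "/HOH", a$resseq[iw[k]])
      rows[[length(rows) + 1]] <-
        hit_frame(s, ia[ja], ib[jb], max(da[k, ja], db[k, jb]),
                  "water_bridge", wlab)
    }
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Specify one gate-layer interaction
#'
#' @param layer layer label (`"C1"`, `"C2"`, `"C3"`).
#' @param group_N,group_C [residue_group()]s on the N- and C-bundle sides.
#' @param kind `"hydrophobic"`, `"hbond"` or `"water_bridge"`.
#' @return object of class `tmg_contact_spec`.
#' @export
contact_spec <- function(layer, group_N, group_C,
                         kind = c("hydrophobic", "hbond", "water_bridge")) {
  kind <- match.arg(kind)
  structure(list(layer = layer, group_N = group_N, group_C = group_C,
                 kind = kind),
            class = "tmg_contact_spec")
}

#' Default NarK cytoplasmic gate-layer table
#'
#' Transcription of the three stacked interaction layers sealing the
#' cytoplasmic pathway in the occluded state: C1, hydrophobic packing of
#' F370/L407 (C bundle) against F147/M151/L167 (N bundle) plus the
#' water-mediated bridge between the A404 and A148 main-chain carbonyls;
#' C2, packing of M382/M396/A400 against F156 and the P159-Q161 backbone,
#' the R378 guanidinium hydrogen bonds to the F158/K160 carbonyls, and the
#' A400 carbonyl to S155 hydroxyl bond; C3, contacts of D392/E393/M396 with
#' the N-terminal loop residues P20/E21.
#'
#' @return list of [contact_spec()] objects.
#' @export
default_gate_layers <- function() list(
  contact_spec("C1", residue_group(c(147, 151, 167), "side-chain"),
               residue_group(c(370, 407), "side-chain"), "hydrophobic"),
  contact_spec("C1", residue_group(148, atoms = "O"),
               residue_group(404, atoms = "O"), "water_bridge"),
  contact_spec("C2", residue_group(c(156), "side-chain"),
               residue_group(c(382, 396, 400), "side-chain"), "hydrophobic"),
  contact_spec("C2", residue_group(159:161, "main-chain"),
               residue_group(c(382, 396, 400), "side-chain"), "hydrophobic"),
  contact_spec("C2", residue_group(c(158, 160), atoms = "O"),
               residue_group(378, atoms = c("NE", "NH1", "NH2")), "hbond"),
  contact_spec("C2", residue_group(155, atoms = "OG"),
               residue_group(400, atoms = "O"), "hbond"),
  contact_spec("C3", residue_group(c(20, 21), "any"),
               residue_group(c(392, 393, 396), "any"), "hydrophobic"))

# evaluate one spec: which listed residue pairs have >= 1 hit
eval_contact_spec <- function(s, spec, cutoffs) {
  hits <- switch(spec$kind,
    hydrophobic = try(find_contacts(s, spec$group_N, spec$group_C,
                                    cutoffs$hydrophobic), silent = TRUE),
    hbond = try(find_hbonds(s, spec$group_C, spec$group_N,
                            cutoffs$hbond), silent = TRUE),
    water_bridge = find_water_bridges(s, spec$group_N, spec$group_C,
                                      cutoffs$water_bridge))
  pairs <- expand.grid(res_N = spec$group_N$resseq, res_C = spec$group_C$resseq)
  if (inherits(hits, "try-error")) {
    pairs$formed <- NA
    return(list(pairs = pairs, hits = NULL, unresolved = TRUE))
  }
  hit_res <- unique(data.frame(
    rn = pmin(hits$res_a, hits$res_b), rc = pmax(hits$res_a, hits$res_b)))
  pairs$formed <- mapply(function(rn, rc)
    any(hit_res$rn == min(rn, rc) & hit_res$rc == max(rn, rc)),
    pairs$res_N, pairs$res_C)
  list(pairs = pairs, hits = hits, unresolved = FALSE)
}

#' Classify the cytoplasmic gate of a structure as closed or open
#'
#' Each layer's specs enumerate residue pairs; a layer counts as formed when
#' at least `formed_frac` of its listed pairs have at least one hit of the
#' required kind. The gate is `"closed"` when every layer is formed,
#' `"open"` otherwise. Layers whose residues do not resolve are flagged
#' unresolved and count as not formed.
#'
#' @param s a `tmg_structure`.
#' @param layer_specs list of [contact_spec()]s (default
#'   [default_gate_layers()]).
#' @param formed_frac fraction of listed pairs needed to call a layer
#'   formed (default 0.5).
#' @param cutoffs named list of distance cutoffs in Angstrom.
#' @return list: `state` (`"closed"`/`"open"`), `layers` (per-layer
#'   data.frame: layer, n_pairs, n_formed, formed, unresolved), `hits`
#'   (all hit rows with a layer column).
#' @export
gate_state <- function(s, layer_specs = default_gate_layers(),
                       formed_frac = 0.5,
                       cutoffs = list(hydrophobic = 4.5, hbond = 3.5,
                                      water_bridge = 3.5)) {
  if (length(layer_specs) == 0) stop("no layer specs given")
  evals <- lapply(layer_specs, eval_contact_spec, s = s, cutoffs = cutoffs)
  layers <- sort(unique(vapply(layer_specs, function(sp) sp$layer, "")))
  rows <- lapply(layers, function(L) {
    ii <- which(vapply(layer_specs, function(sp) sp$layer, "") == L)
    pairs <- do.call(rbind, lapply(evals[ii], function(e) e$pairs))
    unresolved <- any(vapply(evals[ii], function(e) e$unresolved, TRUE))
    n_formed <- sum(pairs$formed, na.rm = TRUE)
    data.frame(layer = L, n_pairs = nrow(pairs), n_formed = n_formed,
               formed = !unresolved && n_formed >= formed_frac * nrow(pairs),
               unresolved = unresolved, stringsAsFactors = FALSE)
  })
  layer_tab <- do.call(rbind, rows)
  hits <- do.call(rbind, lapply(seq_along(evals), function(i) {
    h <- evals[[i]]$hits
    if (is.null(h) || nrow(h) == 0) return(NULL)
    h$layer <- layer_specs[[i]]$layer
    h
  }))
  list(state = if (all(layer_tab$formed)) "closed" else "open",
       layers = layer_tab, hits = hits)
}
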