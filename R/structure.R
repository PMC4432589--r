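# Domain types: Structure, Trajectory, AtomSelection, plus fixed-format PDB I/O.
# No R-side PDB reader ships with the pre-installed stack, so the fixed-column
# ATOM/HETATM/MODEL grammar is implemented here.

ATOM_COLS <- c("chain", "resseq", "icode", "resname", "atom", "altloc",
               "element", "x", "y", "z", "occ", "b", "het")

#' Construct a Structure from an atom table
#'
#' A `tmg_structure` is an ordered atom table: one row per atom with chain id,
#' author residue number (plus insertion code), residue name, PDB atom name,
#' element, coordinates in Angstrom, occupancy, B-factor, alternate-location
#' label and a HETATM flag. Author residue numbering is kept exactly as
#' deposited; residue numbers within a chain need not be contiguous
#' (disordered loops are simply absent).
#'
#' @param atoms data.frame with columns `chain`, `resseq`, `resname`, `atom`,
#'   `x`, `y`, `z` and optionally `icode`, `altloc`, `element`, `occ`, `b`,
#'   `het`. Missing optional columns are filled with defaults.
#' @param model_id integer model number.
#' @param title free-text title.
#' @return object of class `tmg_structure`.
#' @export
new_structure <- function(atoms, model_id = 1L, title = "") {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resseq", "resname", "atom", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$icode)) atoms$icode <- rep("", n)
  if (is.null(atoms$altloc)) atoms$altloc <- rep("", n)
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$atom)
  if (is.null(atoms$occ)) atoms$occ <- rep(1, n)
  if (is.null(atoms$b)) atoms$b <- rep(0, n)
  if (is.null(atoms$het)) atoms$het <- rep(FALSE, n)
  atoms$resseq <- as.integer(atoms$resseq)
  for (cc in c("x", "y", "z", "occ", "b")) atoms[[cc]] <- as.numeric(atoms[[cc]])
  if (n > 0) {
    if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
      stop("non-finite coordinates in atom table")
    if (any(atoms$atom == "")) stop("empty atom names in atom table")
    if (any(atoms$occ < 0 | atoms$occ > 1))
      stop("occupancy outside [0,1]")
  }
  atoms <- atoms[ATOM_COLS]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = as.integer(model_id), title = title),
            class = "tmg_structure")
}

#' @export
print.tmg_structure <- function(x, ...) {
  a <- x$atoms
  nres <- nrow(unique(a[c("chain", "resseq", "icode")]))
  cat(sprintf("<tmg_structure> model %d: %d atoms, %d residues, chains [%s]\n",
              x$model_id, nrow(a), nres,
              paste(sort(unique(a$chain)), collapse = ",")))
  invisible(x)
}

guess_element <- function(atom_names) {
  # First alphabetic character of the stripped atom name, except for
  # two-letter PDB conventions we actually meet (no metals in this domain).
  nm <- toupper(gsub("[^A-Z]", "", toupper(atom_names)))
  el <- substr(nm, 1, 1)
  el[nm == ""] <- "X"
  el
}

#' Read a single model from a PDB file
#'
#' Parses fixed-column `ATOM`/`HETATM` records. HETATM ligand and water
#' records (e.g. `NO3`, `HOH`) are retained with their residue codes.
#' Alternate locations are resolved to a single conformer: the
#' highest-occupancy one, ties broken by the alphabetically first altloc
#' label.
#'
#' @param path PDB file path.
#' @param model integer model number, or `"first"` (default) for the first
#'   MODEL block (or the whole file when no MODEL records are present).
#' @return a [new_structure()] object.
#' @export
read_pdb <- function(path, model = "first") {
  models <- read_pdb_models(path)
  ids <- vapply(models, function(m) m$model_id, integer(1))
  if (identical(model, "first")) {
    pick <- 1L
  } else {
    pick <- match(as.integer(model), ids)
    if (is.na(pick)) stop("model ", model, " absent from ", path,
                          " (has models: ", paste(ids, collapse = ","), ")")
  }
  models[[pick]]
}

# Parse every model of a PDB file into a list of tmg_structure.
read_pdb_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  title <- trimws(paste(substring(lines[rec == "TITLE "], 11), collapse = " "))

  model_no <- integer(length(lines))
  cur <- 0L
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) == 0) {
    model_no[] <- 1L
  } else {
    idx <- 1L
    # assign each line the id of the most recent MODEL record
    mids <- suppressWarnings(as.integer(substr(lines[model_starts], 11, 14)))
    mids[is.na(mids)] <- seq_along(model_starts)[is.na(mids)]
    bounds <- c(model_starts, length(lines) + 1L)
    for (k in seq_along(model_starts))
      model_no[bounds[k]:(bounds[k + 1L] - 1L)] <- mids[k]
  }

  ai <- which(is_atom)
  al <- lines[ai]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(al, from, to)))
    bad <- which(!is.finite(v))
    if (what %in% c("x", "y", "z") && length(bad))
      stop("malformed coordinate field '", what, "' at line ", ai[bad[1]],
           " of ", path)
    v
  }
  atoms <- data.frame(
    chain = substr(al, 22, 22),
    resseq = suppressWarnings(as.integer(substr(al, 23, 26))),
    icode = trimws(substr(al, 27, 27)),
    resname = trimws(substr(al, 18, 20)),
    atom = trimws(substr(al, 13, 16)),
    altloc = trimws(substr(al, 17, 17)),
    element = trimws(substr(al, 77, 78)),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occ = num(55, 60, "occ"), b = num(61, 66, "b"),
    het = substr(al, 1, 6) == "HETATM",
    stringsAsFactors = FALSE)
  bad <- which(is.na(atoms$resseq))
  if (length(bad))
    stop("malformed residue number at line ", ai[bad[1]], " of ", path)
  atoms$element[atoms$element == ""] <- guess_element(atoms$atom[atoms$element == ""])
  atoms$occ[!is.finite(atoms$occ)] <- 1
  atoms$b[!is.finite(atoms$b)] <- 0

  split_ids <- model_no[ai]
  out <- lapply(sort(unique(split_ids)), function(id) {
    a <- resolve_altloc(atoms[split_ids == id, , drop = FALSE])
    new_structure(a, model_id = id, title = title)
  })
  out
}

# Keep one conformer per (chain, resseq, icode, atom): highest occupancy,
# ties to the alphabetically first altloc label.
resolve_altloc <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$atom, sep = "\r")
  ord <- order(key, -atoms$occ, atoms$altloc)
  a <- atoms[ord, , drop = FALSE]
  a <- a[!duplicated(key[ord]), , drop = FALSE]
  # restore original file order
  a[order(match(rownames(a), rownames(atoms))), , drop = FALSE]
}

#' Read a multi-model PDB file as a trajectory
#'
#' Every `MODEL` block must share one atom roster in one order; the first
#' model becomes the topology and each further model one coordinate frame.
#'
#' @param path multi-model PDB file.
#' @param frame_times optional numeric vector of frame times (ns), strictly
#'   increasing, one per model.
#' @return object of class `tmg_trajectory` with fields `topology`
#'   (a [new_structure()]), `frames` (list of n_atoms x 3 matrices) and
#'   `times`.
#' @export
read_multimodel <- function(path, frame_times = NULL) {
  models <- read_pdb_models(path)
  topo <- models[[1]]
  key0 <- atom_keys(topo$atoms)
  frames <- vector("list", length(models))
  for (k in seq_along(models)) {
    a <- models[[k]]$atoms
    if (nrow(a) != nrow(topo$atoms))
      stop("model ", models[[k]]$model_id, " has ", nrow(a),
           " atoms; topology has ", nrow(topo$atoms))
    if (!identical(atom_keys(a), key0))
      stop("model ", models[[k]]$model_id, " atom roster differs from topology")
    frames[[k]] <- coords(models[[k]])
  }
  new_trajectory(topo, frames, frame_times)
}

#' Construct a trajectory from a topology and coordinate frames
#'
#' @param topology a `tmg_structure` giving the atom roster (frame-0 order).
#' @param frames list of n_atoms x 3 coordinate matrices.
#' @param times optional strictly increasing frame times (ns).
#' @return object of class `tmg_trajectory`.
#' @export
new_trajectory <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "tmg_structure"), is.list(frames))
  n <- nrow(topology$atoms)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3)
      stop("frame ", k, " is not a ", n, " x 3 coordinate matrix")
  }
  if (!is.null(times)) {
    if (length(times) != length(frames)) stop("one time per frame required")
    if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  }
  structure(list(topology = topology, frames = frames, times = times),
            class = "tmg_trajectory")
}

#' @export
print.tmg_trajectory <- function(x, ...) {
  cat(sprintf("<tmg_trajectory> %d frames x %d atoms\n",
              length(x$frames), nrow(x$topology$atoms)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `tmg_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

atom_keys <- function(atoms)
  paste(atoms$chain, atoms$resseq, atoms$icode, atoms$atom, sep = "\r")

#' Coordinates of a structure as a matrix
#' @param s a `tmg_structure`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(s) {
  m <- cbind(x = s$atoms$x, y = s$atoms$y, z = s$atoms$z)
  m
}

#' Replace the coordinates of a structure
#' @param s a `tmg_structure`.
#' @param xyz n x 3 matrix congruent with the atom table.
#' @return the modified structure.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms), ncol(xyz) == 3)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Write a structure or trajectory to a PDB file
#'
#' Fixed-column output, coordinates at 3 decimals. A `tmg_trajectory` is
#' written as MODEL/ENDMDL blocks (the multi-model trajectory interchange
#' format).
#'
#' @param s a `tmg_structure` or `tmg_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(s, "tmg_trajectory")) {
    for (k in seq_along(s$frames)) {
      writeLines(sprintf("MODEL     %4d", k), con)
      writeLines(format_atom_lines(set_coords(s$topology, s$frames[[k]])$atoms), con)
      writeLines("ENDMDL", con)
    }
  } else {
    if (nzchar(s$title)) writeLines(sprintf("TITLE     %s", s$title), con)
    writeLines(format_atom_lines(s$atoms), con)
  }
  writeLines("END", con)
  invisible(path)
}

format_atom_lines <- function(a) {
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  nm <- a$atom
  # PDB column 13 alignment: 1-3 char names start in column 14
  nm <- ifelse(nchar(nm) < 4, paste0(" ", nm), nm)
  nm <- formatC(nm, width = -4)
  sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, seq_len(nrow(a)) %% 100000L, nm,
          substr(paste0(a$altloc, " "), 1, 1), a$resname, a$chain,
          a$resseq, substr(paste0(a$icode, " "), 1, 1),
          a$x, a$y, a$z, a$occ, a$b, formatC(a$element, width = 2))
}

#' Declarative atom selection
#'
#' A selection filters a structure by chain, inclusive residue-number ranges,
#' atom names and residue names. Waters and ligands are kept in structures by
#' default but must be named explicitly (`resnames = "NO3"` / `"HOH"`) to be
#' selected; protein selections with `resnames = NULL` exclude waters and
#' ligand HETATM records. Hydrogens are always excluded (crystal structures
#' in this resolution range have none; trajectory dumps may).
#'
#' @param chains character vector of chain ids, or `"all"`.
#' @param ranges list of `c(start, end)` inclusive residue-number ranges, or
#'   a 2-column matrix; empty means all residues. Ranges compare by integer
#'   residue number and include all insertion-code variants.
#' @param atoms character vector of atom names (e.g. `"CA"`), or `"all"`.
#' @param resnames optional residue-name filter (needed to select HETATM
#'   residues such as `NO3` or `HOH`).
#' @return object of class `tmg_selection`.
#' @export
sel <- function(chains = "all", ranges = list(), atoms = "all",
                resnames = NULL) {
  if (is.numeric(ranges)) ranges <- list(ranges)
  if (is.matrix(ranges)) ranges <- lapply(seq_len(nrow(ranges)), function(i) ranges[i, ])
  for (r in ranges) {
    if (length(r) != 2 || r[1] > r[2])
      stop("each range must be c(start, end) with start <= end")
  }
  structure(list(chains = chains, ranges = ranges, atoms = atoms,
                 resnames = resnames),
            class = "tmg_selection")
}

#' @export
print.tmg_selection <- function(x, ...) {
  rg <- if (length(x$ranges)) paste(vapply(x$ranges, function(r)
    paste0(r[1], "-", r[2]), ""), collapse = ",") else "all"
  cat(sprintf("<tmg_selection> chains=%s residues=%s atoms=%s resnames=%s\n",
              paste(x$chains, collapse = ","), rg,
              paste(x$atoms, collapse = ","),
              if (is.null(x$resnames)) "(protein)" else
                paste(x$resnames, collapse = ",")))
  invisible(x)
}

#' Parse a compact selection string
#'
#' Grammar: `"<ranges>:<atoms>"` where ranges is `all` or comma-separated
#' `start-end` spans and atoms is `all` or comma-separated atom names, e.g.
#' `"1-233:CA"` or `"369-380,399-409:CA"`. Used by the command-line tools.
#'
#' @param txt selection string.
#' @param chains chain filter passed through to [sel()].
#' @return a `tmg_selection`.
#' @export
parse_selection <- function(txt, chains = "all") {
  parts <- strsplit(txt, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("selection must look like '1-233:CA' or 'all:CA'")
  ranges <- list()
  if (parts[1] != "all") {
    for (span in strsplit(parts[1], ",", fixed = TRUE)[[1]]) {
      ab <- as.integer(strsplit(span, "-", fixed = TRUE)[[1]])
      if (length(ab) == 1) ab <- c(ab, ab)
      ranges[[length(ranges) + 1]] <- ab
    }
  }
  atoms <- if (parts[2] == "all") "all" else strsplit(parts[2], ",", fixed = TRUE)[[1]]
  sel(chains = chains, ranges = ranges, atoms = atoms)
}

#' Resolve a selection against a structure
#'
#' Returns the matching atoms in ascending (chain, residue number, insertion
#' code, atom name) order — deterministic and idempotent. Residues requested
#' by a range but absent from the model (disordered regions) are skipped
#' silently and counted.
#'
#' @param selection a [sel()] object.
#' @param s a `tmg_structure`.
#' @param allow_empty return an empty resolution instead of erroring when no
#'   atom matches.
#' @return list with `coords` (n x 3), `keys` (atom table rows), `index`
#'   (row indices into `s$atoms`) and `n_skipped` (count of requested
#'   residues absent from the model).
#' @export
resolve <- function(selection, s, allow_empty = FALSE) {
  stopifnot(inherits(selection, "tmg_selection"), inherits(s, "tmg_structure"))
  a <- s$atoms
  keep <- a$element != "H" & a$element != "D"
  if (!identical(selection$chains, "all"))
    keep <- keep & a$chain %in% selection$chains
  if (is.null(selection$resnames)) {
    keep <- keep & !(a$resname %in% c("HOH", "WAT", "DOD")) &
      !(a$het & !(a$resname %in% standard_residues()))
  } else {
    keep <- keep & a$resname %in% selection$resnames
  }
  if (length(selection$ranges)) {
    in_range <- rep(FALSE, nrow(a))
    for (r in selection$ranges)
      in_range <- in_range | (a$resseq >= r[1] & a$resseq <= r[2])
    keep <- keep & in_range
  }
  if (!identical(selection$atoms, "all"))
    keep <- keep & a$atom %in% selection$atoms
  idx <- which(keep)
  ord <- order(a$chain[idx], a$resseq[idx], a$icode[idx], a$atom[idx])
  idx <- idx[ord]
  if (length(idx) == 0 && !allow_empty)
    stop("selection resolves to zero atoms")

  # count requested residues absent from the model
  n_skipped <- 0L
  if (length(selection$ranges)) {
    ch <- if (identical(selection$chains, "all")) unique(a$chain) else selection$chains
    for (cc in ch) {
      present <- unique(a$resseq[a$chain == cc])
      wanted <- unique(unlist(lapply(selection$ranges, function(r) r[1]:r[2])))
      n_skipped <- n_skipped + sum(!(wanted %in% present))
    }
  }
  list(coords = cbind(a$x[idx], a$y[idx], a$z[idx]),
       keys = a[idx, c("chain", "resseq", "icode", "resname", "atom"), drop = FALSE],
       index = idx, n_skipped = n_skipped)
}

standard_residues <- function() c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE")

# shared helper: run code under a seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
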