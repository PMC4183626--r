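#' Construct a molecular system
#'
#' The central container of the package: an ordered atom table, Cartesian
#' coordinates in Angstrom, and (optionally) bonded terms. Force-field
#' parameters (`charge`, `lj_epsilon`, `lj_rmin_half`, `gb_radius`) start as
#' `NA` when a structure is read from PDB and are filled in by
#' [merge_parameters()].
#'
#' @param atoms data frame with columns `serial`, `name`, `resname`, `resid`,
#'   `chain`, `element`; parameter columns `charge`, `lj_epsilon`,
#'   `lj_rmin_half`, `gb_radius` (and optional `gb_screen`) are added as `NA`
#'   if absent. `element` may be `NA` and is then inferred from the first
#'   letter of the atom name.
#' @param xyz numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param bonds data frame `(i, j, kb, b0)`: harmonic bonds,
#'   `kb` in kcal/mol/A^2, `b0` in Angstrom. Indices are row positions in
#'   `atoms`.
#' @param angles data frame `(i, j, k, ktheta, theta0)`: harmonic angles,
#'   `ktheta` in kcal/mol/rad^2, `theta0` in degrees.
#' @param dihedrals data frame `(i, j, k, l, kphi, n, delta)`: cosine
#'   dihedrals `kphi * (1 + cos(n*phi - delta))`, `delta` in degrees.
#' @param scale14 scaling factor applied to 1-4 nonbonded pairs (both
#'   electrostatic and Lennard-Jones); 1-2 and 1-3 pairs are always excluded.
#' @return object of class `molsys`.
#' @export
molecular_system <- function(atoms, xyz,
                             bonds = NULL, angles = NULL, dihedrals = NULL,
                             scale14 = 1.0) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("serial", "name", "resname", "resid", "chain", "element")
  miss <- setdiff(need, names(atoms))
  if ("element" %in% miss) {
    atoms$element <- NA_character_
    miss <- setdiff(miss, "element")
  }
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  for (p in c("charge", "lj_epsilon", "lj_rmin_half", "gb_radius", "gb_screen"))
    if (is.null(atoms[[p]])) atoms[[p]] <- NA_real_
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L)
    stop("xyz must be a numeric N x 3 matrix")
  if (nrow(xyz) != nrow(atoms))
    stop("coordinate rows (", nrow(xyz), ") != atom count (", nrow(atoms), ")")
  if (nrow(atoms) == 0L) stop("empty system: no atoms")
  if (anyDuplicated(atoms$serial))
    stop("atom serial numbers must be unique within a system")
  na_el <- is.na(atoms$element) | atoms$element == ""
  atoms$element[na_el] <- infer_element(atoms$name[na_el])
  if (any(!is.na(atoms$lj_epsilon) & atoms$lj_epsilon < 0))
    stop("lj_epsilon must be >= 0")
  if (any(!is.na(atoms$gb_radius) & atoms$gb_radius <= 0))
    stop("gb_radius must be > 0")
  chk_idx <- function(tbl, cols, what) {
    if (is.null(tbl)) return(NULL)
    tbl <- as.data.frame(tbl)
    idx <- unlist(tbl[cols])
    if (length(idx) && (any(idx < 1L) || any(idx > nrow(atoms))))
      stop(what, " indices out of range")
    tbl
  }
  bonds     <- chk_idx(bonds, c("i", "j"), "bond")
  angles    <- chk_idx(angles, c("i", "j", "k"), "angle")
  dihedrals <- chk_idx(dihedrals, c("i", "j", "k", "l"), "dihedral")
  structure(list(atoms = atoms, xyz = xyz, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, scale14 = scale14),
            class = "molsys")
}

# First alphabetic character of the atom name, upper-cased; digits and primes
# stripped (PDB convention, e.g. "1HG1" -> H, "O3'" -> O).
infer_element <- function(name) {
  el <- sub("^[^A-Za-z]*", "", name)
  toupper(substr(el, 1L, 1L))
}

#' @export
print.molsys <- function(x, ...) {
  cat(sprintf("<molsys> %d atoms, %d residues, %d bonds, %d angles, %d dihedrals\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              NROW(x$bonds), NROW(x$angles), NROW(x$dihedrals)))
  invisible(x)
}

#' Number of atoms in a system
#' @param system a `molsys` object.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Human-readable atom labels ("RES<resid>-NAME")
#' @param system a `molsys` object.
#' @param indices atom indices (default all).
#' @export
atom_labels <- function(system, indices = seq_len(n_atoms(system))) {
  a <- system$atoms
  paste0(a$resname[indices], a$resid[indices], "-", a$name[indices])
}

# ---------------------------------------------------------------------------
# PDB I/O (backed by bio3d)
# ---------------------------------------------------------------------------

# Pre-scan ATOM/HETATM records so malformed coordinate fields are reported
# with their line number (bio3d would silently coerce to NA).
scan_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in '", path, "'")
  for (ln in which(rec)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[ln], 31, 38),
                                         substr(lines[ln], 39, 46),
                                         substr(lines[ln], 47, 54))))
    if (anyNA(xyz))
      stop("malformed PDB record at line ", ln, " of '", path, "'")
  }
  invisible(lines)
}

#' Read a single-structure PDB file
#'
#' Atoms are kept in file order; coordinates are Angstrom. Force-field
#' parameters are unset (`NA`) until [merge_parameters()] is applied. Files
#' with MODEL blocks are read through [read_ensemble()]; this function takes
#' the first model.
#'
#' @param path PDB file.
#' @return a [molecular_system()].
#' @export
read_pdb <- function(path) {
  scan_pdb_records(path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(serial = a$eleno, name = a$elety, resname = a$resid,
                      resid = a$resno, chain = ifelse(is.na(a$chain), "", a$chain),
                      element = NA_character_, stringsAsFactors = FALSE)
  molecular_system(atoms, cbind(a$x, a$y, a$z))
}

#' Write a system (or ensemble) as PDB
#'
#' Single systems give a plain PDB; ensembles give multi-model PDB with one
#' MODEL block per frame.
#'
#' @param x a `molsys` or an `ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "ensemble")) {
    sys <- x$system
    xyz <- do.call(rbind, lapply(x$frames, function(f) as.vector(t(f))))
  } else {
    sys <- x
    xyz <- matrix(as.vector(t(sys$xyz)), nrow = 1L)
  }
  a <- sys$atoms
  bio3d::write.pdb(file = path, xyz = xyz, eleno = a$serial, elety = a$name,
                   resid = a$resname, resno = a$resid,
                   chain = ifelse(a$chain == "", " ", a$chain))
  invisible(path)
}

#' Construct a snapshot ensemble
#'
#' @param system a `molsys` giving the (fixed) topology.
#' @param frames list of N x 3 coordinate matrices, all the same shape.
#' @param time_ps per-frame times in picoseconds, strictly increasing.
#' @return object of class `ensemble`.
#' @export
snapshot_ensemble <- function(system, frames, time_ps = NULL) {
  stopifnot(inherits(system, "molsys"), is.list(frames), length(frames) >= 1L)
  na <- n_atoms(system)
  for (k in seq_along(frames)) {
    frames[[k]] <- as.matrix(frames[[k]])
    if (!identical(dim(frames[[k]]), c(na, 3L)) &&
        !(nrow(frames[[k]]) == na && ncol(frames[[k]]) == 3L))
      stop("frame ", k, " has ", nrow(frames[[k]]), " atoms; topology has ", na,
           " (structural mismatch)")
  }
  if (is.null(time_ps)) time_ps <- as.numeric(seq_along(frames) - 1L)
  if (length(time_ps) != length(frames))
    stop("time_ps length != frame count")
  if (any(diff(time_ps) <= 0)) stop("frame times must be strictly increasing")
  structure(list(system = system, frames = frames, time_ps = time_ps),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d frames x %d atoms, t = %.1f..%.1f ps\n",
              length(x$frames), n_atoms(x$system),
              x$time_ps[1], x$time_ps[length(x$time_ps)]))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble an `ensemble`.
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

#' Read a multi-model PDB file as a snapshot ensemble
#'
#' Topology (atom names, residues) is taken from the first model; per-frame
#' coordinates are aligned by atom order. A single-model file yields a
#' 1-frame ensemble. PDB carries no time axis, so frame times are
#' `0, dt_ps, 2*dt_ps, ...`.
#'
#' @param path multi-model PDB file.
#' @param dt_ps time spacing between frames (picoseconds).
#' @return an `ensemble`.
#' @export
read_ensemble <- function(path, dt_ps = 1.0) {
  lines <- scan_pdb_records(path)
  n_models <- sum(grepl("^MODEL", lines))
  counts <- per_model_atom_counts(lines)
  if (length(unique(counts)) > 1L)
    stop("models differ in atom count (", paste(unique(counts), collapse = ", "),
         "): structural mismatch")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  na <- if (n_models > 1L) counts[1] else nrow(a)
  atoms <- data.frame(serial = a$eleno[seq_len(na)], name = a$elety[seq_len(na)],
                      resname = a$resid[seq_len(na)], resid = a$resno[seq_len(na)],
                      chain = ifelse(is.na(a$chain[seq_len(na)]), "", a$chain[seq_len(na)]),
                      element = NA_character_, stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  frames <- lapply(seq_len(nrow(xyz)), function(k)
    matrix(xyz[k, ], ncol = 3L, byrow = TRUE))
  sys <- molecular_system(atoms, frames[[1L]])
  snapshot_ensemble(sys, frames, time_ps = dt_ps * (seq_along(frames) - 1L))
}

per_model_atom_counts <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(sum(grepl("^(ATOM  |HETATM)", lines)))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    stop("unbalanced MODEL/ENDMDL records")
  vapply(seq_along(starts), function(k)
    sum(grepl("^(ATOM  |HETATM)", lines[starts[k]:ends[k]])), integer(1))
}

# ---------------------------------------------------------------------------
# Parameter merging
# ---------------------------------------------------------------------------

#' Merge force-field parameters into a system
#'
#' Per-atom parameters are looked up by `(residue_name, atom_name)` from a
#' flat table; bonded constants, when connectivity is present but constants
#' are missing, are looked up by atom-name tuples. Lookups must be complete:
#' any unmatched atom is an error naming every offender (no silent defaults).
#'
#' @param system a `molsys`.
#' @param atom_params data frame (or path to a TSV with a header row) with
#'   columns `residue_name`, `atom_name`, `charge`, `lj_epsilon`,
#'   `lj_rmin_half`, `gb_radius` and optionally `gb_screen`. A
#'   `residue_name` of `"*"` is a wildcard matching any residue.
#' @param bond_params,angle_params,dihedral_params optional data frames keyed
#'   by atom-name tuples (`type_i`, `type_j`, ...) supplying `kb, b0` /
#'   `ktheta, theta0` / `kphi, n, delta` for bonded terms whose constants are
#'   `NA` in the system.
#' @return the parameterized `molsys`.
#' @export
merge_parameters <- function(system, atom_params,
                             bond_params = NULL, angle_params = NULL,
                             dihedral_params = NULL) {
  stopifnot(inherits(system, "molsys"))
  if (is.character(atom_params) && length(atom_params) == 1L)
    atom_params <- read.delim(atom_params, stringsAsFactors = FALSE,
                              comment.char = "#")
  p <- as.data.frame(atom_params)
  need <- c("residue_name", "atom_name", "charge", "lj_epsilon",
            "lj_rmin_half", "gb_radius")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("parameter table lacks column(s): ", paste(miss, collapse = ", "))
  a <- system$atoms
  key <- paste(a$resname, a$name, sep = "/")
  idx <- match(key, paste(p$residue_name, p$atom_name, sep = "/"))
  wild <- which(is.na(idx))
  if (length(wild))
    idx[wild] <- match(paste("*", a$name[wild], sep = "/"),
                       paste(p$residue_name, p$atom_name, sep = "/"))
  if (anyNA(idx)) {
    off <- unique(paste0("(", a$resname[is.na(idx)], ", ", a$name[is.na(idx)], ")"))
    stop("no parameters for atom(s): ", paste(off, collapse = ", "))
  }
  a$charge       <- p$charge[idx]
  a$lj_epsilon   <- p$lj_epsilon[idx]
  a$lj_rmin_half <- p$lj_rmin_half[idx]
  a$gb_radius    <- p$gb_radius[idx]
  a$gb_screen    <- if (!is.null(p$gb_screen)) p$gb_screen[idx] else NA_real_
  system$atoms <- a
  lookup_bonded <- function(terms, tbl, keycols, valcols, what) {
    if (is.null(terms) || is.null(tbl)) return(terms)
    tbl <- as.data.frame(tbl)
    tkey <- do.call(paste, c(tbl[paste0("type_", letters[9:(8 + length(keycols))])],
                             sep = "/"))
    names_of <- function(col) a$name[terms[[col]]]
    skey <- do.call(paste, c(lapply(keycols, names_of), sep = "/"))
    m <- match(skey, tkey)
    if (anyNA(m))
      stop("no ", what, " parameters for tuple(s): ",
           paste(unique(skey[is.na(m)]), collapse = ", "))
    for (v in valcols) terms[[v]] <- tbl[[v]][m]
    terms
  }
  system$bonds <- lookup_bonded(system$bonds, bond_params, c("i", "j"),
                                c("kb", "b0"), "bond")
  system$angles <- lookup_bonded(system$angles, angle_params, c("i", "j", "k"),
                                 c("ktheta", "theta0"), "angle")
  system$dihedrals <- lookup_bonded(system$dihedrals, dihedral_params,
                                    c("i", "j", "k", "l"),
                                    c("kphi", "n", "delta"), "dihedral")
  system
}

# ---------------------------------------------------------------------------
# Atom selection mini-grammar and complex partitioning
# ---------------------------------------------------------------------------

#' Select atoms with a small selection grammar
#'
#' Clauses are joined with `and` (intersection). Each clause is one of:
#' \itemize{
#'   \item `chain A B`      -- any of the listed chain ids
#'   \item `resid 3:7 12`   -- residue numbers or `lo:hi` ranges
#'   \item `name CA N`      -- atom names
#'   \item `resname ALA`    -- residue names
#'   \item `backbone`       -- shorthand for `name N CA C O`
#' }
#'
#' @param system a `molsys`.
#' @param spec selection string, e.g. `"chain P and resid 18:24"`.
#' @return integer atom indices (possibly empty).
#' @export
select_atoms <- function(system, spec) {
  stopifnot(inherits(system, "molsys"), is.character(spec), length(spec) == 1L)
  a <- system$atoms
  keep <- rep(TRUE, nrow(a))
  clauses <- strsplit(trimws(spec), "\\s+and\\s+")[[1L]]
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1L]]
    if (!length(tok)) next
    kw <- tolower(tok[1L]); args <- tok[-1L]
    keep <- keep & switch(kw,
      chain = a$chain %in% args,
      name = a$name %in% args,
      resname = a$resname %in% args,
      backbone = a$name %in% c("N", "CA", "C", "O"),
      resid = {
        ids <- unlist(lapply(args, function(s) {
          if (grepl("^-?[0-9]+:-?[0-9]+$", s)) {
            r <- as.integer(strsplit(s, ":")[[1L]]); seq(r[1L], r[2L])
          } else if (grepl("^-?[0-9]+$", s)) as.integer(s)
          else stop("bad resid token '", s, "' in selection '", spec, "'")
        }))
        a$resid %in% ids
      },
      stop("unknown selection keyword '", kw, "' in '", spec, "'")
    )
  }
  which(keep)
}

#' Partition a complex into receptor and ligand atom sets
#'
#' The ligand is chosen by a [select_atoms()] expression; the receptor is the
#' complement (within the full system). Used to score binding as
#' complex minus receptor minus ligand.
#'
#' @param system a `molsys`.
#' @param ligand_spec selection string for the ligand atoms.
#' @return object of class `partition`: list with integer vectors
#'   `receptor` and `ligand`.
#' @export
partition_by_selection <- function(system, ligand_spec) {
  lig <- select_atoms(system, ligand_spec)
  if (!length(lig)) stop("ligand selection '", ligand_spec, "' matches no atoms")
  rec <- setdiff(seq_len(n_atoms(system)), lig)
  complex_partition(rec, lig)
}

#' @rdname partition_by_selection
#' @param receptor,ligand explicit disjoint, non-empty atom index vectors.
#' @export
complex_partition <- function(receptor, ligand) {
  receptor <- sort(unique(as.integer(receptor)))
  ligand <- sort(unique(as.integer(ligand)))
  if (!length(receptor) || !length(ligand))
    stop("receptor and ligand selections must both be non-empty")
  if (length(intersect(receptor, ligand)))
    stop("receptor and ligand selections overlap")
  structure(list(receptor = receptor, ligand = ligand), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> receptor %d atoms, ligand %d atoms\n",
              length(x$receptor), length(x$ligand)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Nonbonded topology: 1-2/1-3 exclusions and scaled 1-4 pairs from bonds
# ---------------------------------------------------------------------------

# Pairs at bond-graph distance 1 or 2 are excluded from nonbonded sums;
# distance-3 pairs are scaled by system$scale14. Returns a list with
# character-keyed sets for O(1) lookup plus the 1-4 pair matrix.
exclusion_info <- function(system) {
  nb <- NROW(system$bonds)
  na <- n_atoms(system)
  adj <- vector("list", na)
  if (nb) {
    for (r in seq_len(nb)) {
      i <- system$bonds$i[r]; j <- system$bonds$j[r]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  excl <- character(0); pair14 <- character(0)
  for (i in seq_len(na)) {
    n1 <- unique(adj[[i]])
    n2 <- unique(unlist(adj[n1]))
    n3 <- unique(unlist(adj[n2]))
    d12 <- setdiff(n1, i)
    d13 <- setdiff(n2, c(i, d12))
    d14 <- setdiff(n3, c(i, d12, d13))
    excl <- c(excl, paste(pmin(i, c(d12, d13)), pmax(i, c(d12, d13))))
    pair14 <- c(pair14, paste(pmin(i, d14), pmax(i, d14)))
  }
  pair14 <- setdiff(unique(pair14), unique(excl))
  list(excluded = unique(excl), scaled14 = pair14, scale14 = system$scale14)
}

# All nonbonded pairs among `indices` with per-pair weights (0 for excluded,
# scale14 for 1-4, 1 otherwise). Returns list(i, j, w) of equal length.
nonbonded_pairs <- function(system, indices = seq_len(n_atoms(system)),
                            excl = exclusion_info(system)) {
  n <- length(indices)
  if (n < 2L) return(list(i = integer(0), j = integer(0), w = numeric(0)))
  cmb <- utils::combn(indices, 2L)
  i <- cmb[1L, ]; j <- cmb[2L, ]
  key <- paste(pmin(i, j), pmax(i, j))
  w <- rep(1.0, length(i))
  w[key %in% excl$scaled14] <- excl$scale14
  w[key %in% excl$excluded] <- 0.0
  keep <- w != 0
  list(i = i[keep], j = j[keep], w = w[keep])
}
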