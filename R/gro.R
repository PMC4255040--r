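#' Read a (multi-frame) GRO coordinate file
#'
#' Parses the fixed-column GROMACS GRO layout: title, atom count, atom lines
#' (`resid resname atomname atomid x y z`, nm), box line. Consecutive frames
#' are concatenated in one file; a `t=` field in the title line is used as the
#' frame time (ns) when present, otherwise frames are numbered 0, 1, 2, ... ns
#' apart. Velocities, if present, are ignored. Only orthorhombic boxes are
#' supported: a box line with non-zero off-diagonal entries raises an error.
#'
#' Molecule ids are rebuilt from the residue column (GRO residue numbers wrap
#' at 100000): a new molecule starts whenever the residue number or name
#' changes between consecutive atom lines.
#'
#' @param path file path.
#' @param topology optional [md_topology()]; by default one is constructed
#'   from the residue/atom names with masses from the built-in tables.
#' @return An [md_trajectory()].
#' @export
read_gro <- function(path, topology = NULL) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric()
  boxes <- list()
  pos <- 1L
  top_cols <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos])) && pos == length(lines)) break
    title <- lines[pos]
    if (pos + 1L > length(lines)) {
      abort(sprintf("line %d: truncated frame (missing atom count)", pos))
    }
    n <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(n) || n < 0) {
      abort(sprintf("line %d: malformed atom count '%s'", pos + 1L,
                    trimws(lines[pos + 1L])))
    }
    atom_first <- pos + 2L
    atom_last <- atom_first + n - 1L
    if (atom_last + 1L > length(lines)) {
      abort(sprintf(
        "line %d: header declares %d atoms but file ends before the box line",
        pos + 1L, n))
    }
    atoms <- lines[atom_first:atom_last]
    bad <- which(nchar(atoms) < 44)
    if (length(bad) > 0) {
      abort(sprintf("line %d: atom line too short for GRO fixed columns",
                    atom_first + bad[1] - 1L))
    }
    x <- suppressWarnings(as.numeric(substr(atoms, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(atoms, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(atoms, 37, 44)))
    if (anyNA(x) || anyNA(y) || anyNA(z)) {
      bad <- which(is.na(x) | is.na(y) | is.na(z))[1]
      abort(sprintf("line %d: unparseable coordinates", atom_first + bad - 1L))
    }
    box_tokens <- strsplit(trimws(lines[atom_last + 1L]), "\\s+")[[1]]
    bv <- suppressWarnings(as.numeric(box_tokens))
    if (length(bv) < 3 || anyNA(bv[1:3])) {
      abort(sprintf("line %d: missing or malformed box line", atom_last + 1L))
    }
    if (length(bv) > 3 && any(abs(bv[-(1:3)]) > 1e-9)) {
      abort("triclinic boxes are not supported (orthorhombic only)")
    }
    if (is.null(top_cols)) {
      top_cols <- list(
        resid = as.integer(substr(atoms, 1, 5)),
        resname = trimws(substr(atoms, 6, 10)),
        atomname = trimws(substr(atoms, 11, 15))
      )
    }
    tm <- regmatches(title, regexpr("t=\\s*[0-9eE+.-]+", title))
    times <- c(times, if (length(tm) == 1) {
      as.numeric(sub("t=\\s*", "", tm))
    } else NA_real_)
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
    boxes[[length(boxes) + 1L]] <- bv[1:3]
    pos <- atom_last + 2L
    # tolerate trailing blank lines
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (length(frames) == 0) abort("no frames found in GRO file")
  if (anyNA(times)) times <- seq_along(frames) - 1
  if (is.null(topology)) {
    new_mol <- c(TRUE, top_cols$resid[-1] != top_cols$resid[-length(top_cols$resid)] |
                   top_cols$resname[-1] != top_cols$resname[-length(top_cols$resname)])
    mol_id <- cumsum(new_mol)
    topology <- md_topology(mol_id, top_cols$resname, top_cols$atomname)
  }
  coords <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  md_trajectory(topology, coords, times, do.call(rbind, boxes))
}

#' Write a trajectory as a (multi-frame) GRO file
#'
#' Coordinates are written with the standard GRO precision of 0.001 nm; the
#' frame time is recorded as `t=` in each title line. Residue and atom numbers
#' wrap at 100000 per the format.
#'
#' @param traj an [md_trajectory()].
#' @param path output path.
#' @param title title string for the frame headers.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path, title = "npbilayer") {
  top <- traj$topology
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, i)
    if (is.vector(m)) m <- matrix(m, 1, 3)
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     top$molecule_id %% 100000L,
                     substr(top$molecule_type, 1, 5),
                     substr(top$site_name, 1, 5),
                     top$site_id %% 100000L,
                     m[, 1], m[, 2], m[, 3])
    writeLines(c(sprintf("%s t= %.6f", title, traj$times[i]),
                 sprintf("%5d", n_sites(traj)),
                 lines,
                 sprintf("%10.5f%10.5f%10.5f", traj$boxes[i, 1],
                         traj$boxes[i, 2], traj$boxes[i, 3])), con)
  }
  invisible(path)
}

#' Export a point set as XYZ or PDB
#'
#' Convenience exporters for nanoparticle coordinates. XYZ is written in
#' Angstrom (the format's convention); PDB likewise.
#'
#' @param coords `n x 3` matrix (nm).
#' @param path output path.
#' @param element element symbol for all atoms.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(coords, path, element = "Au") {
  ang <- coords * 10
  writeLines(c(sprintf("%d", nrow(ang)), "npbilayer",
               sprintf("%-2s %12.6f %12.6f %12.6f", element,
                       ang[, 1], ang[, 2], ang[, 3])), path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
write_pdb <- function(coords, path, element = "AU") {
  ang <- coords * 10
  lines <- sprintf(
    "HETATM%5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(ang)) %% 100000L, substr(element, 1, 4), "NP",
    1L, ang[, 1], ang[, 2], ang[, 3], substr(toupper(element), 1, 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
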