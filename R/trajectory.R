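#' Trajectory container
#'
#' An `md_trajectory` holds an ordered set of coordinate snapshots of a fixed
#' topology in an orthorhombic box. Coordinates are stored as-read in a
#' `n_sites x 3 x n_frames` array (nm); analyses that need whole molecules
#' re-wrap per molecule about its first site. Frame times must be strictly
#' increasing and every coordinate finite.
#'
#' @param topology an [md_topology()].
#' @param coords numeric array `n_sites x 3 x n_frames` (nm). A
#'   `n_sites x 3` matrix is accepted for a single frame.
#' @param times numeric vector of frame times (ns), strictly increasing.
#' @param boxes `n_frames x 3` matrix of box edge lengths (nm); a length-3
#'   vector is recycled to all frames.
#' @return Object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, coords, times, boxes) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  n_frames <- dim(coords)[3]
  if (dim(coords)[1] != nrow(topology)) {
    abort(sprintf("coords has %d sites but topology has %d",
                  dim(coords)[1], nrow(topology)))
  }
  if (length(times) != n_frames) abort("one time stamp per frame required")
  if (n_frames > 1 && any(diff(times) <= 0)) {
    abort("frame times must be strictly increasing")
  }
  if (!all(is.finite(coords))) abort("all coordinates must be finite")
  if (is.vector(boxes) && length(boxes) == 3) {
    boxes <- matrix(boxes, n_frames, 3, byrow = TRUE)
  }
  boxes <- as.matrix(boxes)
  if (nrow(boxes) != n_frames || ncol(boxes) != 3) {
    abort("boxes must be an n_frames x 3 matrix")
  }
  if (any(boxes <= 0)) abort("box edges must be strictly positive")
  structure(
    list(topology = topology, coords = coords,
         times = as.numeric(times), boxes = boxes),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(
    "<md_trajectory> %d sites x %d frames, t = %g..%g ns, box %s nm\n",
    n_sites(x), n_frames(x), x$times[1], x$times[n_frames(x)],
    paste(signif(x$boxes[1, ], 4), collapse = " x ")))
  invisible(x)
}

#' Trajectory accessors
#' @param traj an `md_trajectory`.
#' @return `n_frames()`/`n_sites()` return counts; `frame_coords()` the
#'   `n_sites x 3` coordinate matrix of one frame; `frame_box()` its box edge
#'   lengths.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_sites <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @param i frame index.
#' @export
frame_coords <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' @rdname n_frames
#' @export
frame_box <- function(traj, i) traj$boxes[i, ]

#' Indices of frames within a time window
#'
#' `window = c(t0, t1)` selects frames with `t0 <= t <= t1`; `window = w`
#' (a single number) selects the last `w` ns; `NULL` selects all frames.
#'
#' @param traj an `md_trajectory`.
#' @param window window specification.
#' @return Integer frame indices.
#' @export
window_frames <- function(traj, window = NULL) {
  t <- traj$times
  if (is.null(window)) return(seq_along(t))
  if (length(window) == 1) window <- c(t[length(t)] - window, t[length(t)])
  idx <- which(t >= window[1] - 1e-9 & t <= window[2] + 1e-9)
  if (length(idx) == 0) abort("empty analysis window")
  idx
}

#' Subset a trajectory by frame index
#' @param traj an `md_trajectory`.
#' @param frames integer frame indices (kept in the given order).
#' @return An `md_trajectory`.
#' @export
subset_frames <- function(traj, frames) {
  md_trajectory(traj$topology, traj$coords[, , frames, drop = FALSE],
                traj$times[frames], traj$boxes[frames, , drop = FALSE])
}

#' Render a trajectory as a long tibble
#'
#' One row per site per frame, with topology columns joined on. Intended for
#' plotting and small systems; the array representation remains the working
#' format.
#'
#' @param x an `md_trajectory`.
#' @param frames frame indices to include (default all).
#' @param ... unused.
#' @return A tibble with columns `frame`, `time`, `site_id`, `molecule_id`,
#'   `molecule_type`, `site_name`, `x`, `y`, `z`.
#' @export
tidy.md_trajectory <- function(x, frames = seq_len(n_frames(x)), ...) {
  top <- x$topology
  out <- purrr::map(frames, function(i) {
    m <- frame_coords(x, i)
    tibble(frame = i, time = x$times[i], site_id = top$site_id,
           molecule_id = top$molecule_id, molecule_type = top$molecule_type,
           site_name = top$site_name,
           x = m[, 1], y = m[, 2], z = m[, 3])
  })
  bind_rows(out)
}

#' @export
glance.md_trajectory <- function(x, ...) {
  tibble(
    n_sites = n_sites(x), n_frames = n_frames(x),
    n_molecules = length(unique(x$topology$molecule_id)),
    t_start = x$times[1], t_end = x$times[n_frames(x)],
    lx = x$boxes[1, 1], ly = x$boxes[1, 2], lz = x$boxes[1, 3]
  )
}

#' Read a trajectory file, dispatching on extension
#'
#' Only the (multi-frame) GRO path is implemented; binary trajectory formats
#' (.xtc/.trr) are not supported and raise an explicit error so the failure
#' mode is unambiguous.
#'
#' @param path file path.
#' @param ... passed to the format reader.
#' @return An `md_trajectory`.
#' @export
read_trajectory <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") return(read_gro(path, ...))
  if (ext %in% c("xtc", "trr")) {
    abort(sprintf("binary trajectory format '.%s' is not supported; convert to multi-frame GRO", ext))
  }
  abort(sprintf("unrecognised trajectory extension '.%s'", ext))
}
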