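#' Minimum-image displacement under an orthorhombic box
#'
#' Wraps each component of `b - a` into `[-L/2, +L/2)`. `a` and `b` may be
#' matrices (`n x 3`) or single 3-vectors; they are recycled against each
#' other row-wise.
#'
#' @param a,b positions (nm), 3-vectors or `n x 3` matrices.
#' @param box length-3 box edge vector (nm).
#' @return Displacement(s) with the same shape as the larger input.
#' @export
#' @examples
#' minimum_image_vector(c(0, 0, 0), c(0.9, 0, 0), c(1, 1, 1))  # -0.1 0 0
minimum_image_vector <- function(a, b, box) {
  if (any(box <= 0)) abort("box edges must be positive")
  if (is.vector(a)) a <- matrix(a, ncol = 3)
  if (is.vector(b)) b <- matrix(b, ncol = 3)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), , drop = FALSE]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), , drop = FALSE]
  d <- b - a
  L <- matrix(box, n, 3, byrow = TRUE)
  d <- d - L * floor(d / L + 0.5)
  if (n == 1) as.numeric(d) else d
}

#' Minimum-image distances
#'
#' @inheritParams minimum_image_vector
#' @return Numeric vector of Euclidean distances between paired rows.
#' @export
minimum_image_distance <- function(a, b, box) {
  d <- minimum_image_vector(a, b, box)
  if (is.vector(d)) sqrt(sum(d^2)) else sqrt(rowSums(d^2))
}

# All minimum-image distances between rows of A (n x 3) and rows of B (m x 3),
# returned as an n x m matrix. Used by RDF / contact analyses on modest n*m.
.cross_distances <- function(A, B, box) {
  n <- nrow(A); m <- nrow(B)
  out <- matrix(0, n, m)
  for (k in 1:3) {
    d <- outer(A[, k], B[, k], "-")
    d <- d - box[k] * floor(d / box[k] + 0.5)
    out <- out + d * d
  }
  sqrt(out)
}

#' Wrap coordinates into the primary box `[0, L)`
#'
#' @param coords `n x 3` matrix (nm).
#' @param box length-3 box vector (nm).
#' @return Wrapped `n x 3` matrix.
#' @export
wrap_coords <- function(coords, box) {
  L <- matrix(box, nrow(coords), 3, byrow = TRUE)
  coords - L * floor(coords / L)
}

# Re-wrap each molecule to be whole about its first site: every site is moved
# to its minimum image relative to the molecule's first listed site.
rewrap_molecules <- function(coords, topology, box) {
  first_idx <- match(topology$molecule_id, topology$molecule_id)
  ref <- coords[first_idx, , drop = FALSE]
  ref + minimum_image_vector(ref, coords, box)
}

#' Mass-weighted center of mass of a selection
#'
#' The selection is made whole first: every site is shifted to its minimum
#' image relative to the first selected site, so a molecule straddling the
#' periodic boundary gets a physically sensible center. The result is wrapped
#' back into the primary box.
#'
#' @param traj an `md_trajectory`.
#' @param selection integer site ids (e.g. from [select_sites()]).
#' @param frame frame index.
#' @return Length-3 position (nm).
#' @export
center_of_mass <- function(traj, selection, frame = 1) {
  if (length(selection) == 0) abort("empty selection")
  m <- traj$topology$mass[selection]
  box <- frame_box(traj, frame)
  p <- frame_coords(traj, frame)[selection, , drop = FALSE]
  ref <- p[1, , drop = FALSE]
  whole <- ref[rep(1, nrow(p)), , drop = FALSE] +
    minimum_image_vector(ref, p, box)
  com <- colSums(whole * m) / sum(m)
  com <- com - box * floor(com / box)
  # a CoM within numerical noise of the upper box face is the same point as 0
  as.numeric(ifelse(box - com < 1e-9, 0, com))
}

#' Unwrap periodic jumps to obtain continuous coordinates
#'
#' For each selected site, whenever the displacement between consecutive frames
#' exceeds half the box in any axis, the appropriate multiple of the box vector
#' is added back so the coordinate becomes continuous in time. Required for
#' mean-square-displacement analysis. An inter-frame jump of exactly half a box
#' is ambiguous and raises an error naming the frame.
#'
#' @param traj an `md_trajectory`.
#' @param selection site ids to unwrap (default all).
#' @return Numeric array `length(selection) x 3 x n_frames` of continuous
#'   coordinates (nm).
#' @export
unwrap_positions <- function(traj, selection = seq_len(n_sites(traj))) {
  nf <- n_frames(traj)
  out <- traj$coords[selection, , , drop = FALSE]
  if (nf == 1) return(out)
  shift <- matrix(0, length(selection), 3)
  for (i in 2:nf) {
    box <- frame_box(traj, i)
    d <- traj$coords[selection, , i, drop = TRUE] -
      traj$coords[selection, , i - 1, drop = TRUE]
    if (length(selection) == 1) d <- matrix(d, 1, 3)
    L <- matrix(box, nrow(d), 3, byrow = TRUE)
    amb <- abs(abs(d) - L / 2) < 1e-12
    if (any(amb)) {
      abort(sprintf("ambiguous half-box jump between frames %d and %d", i - 1, i))
    }
    shift <- shift - L * round(d / L)
    out[, , i] <- traj$coords[selection, , i, drop = TRUE] + shift
  }
  out
}
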