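#' Coarse-grained trajectory container
#'
#' A sequence of bead frames sharing one topology and box, stored as a
#' 3D coordinate array for fast histogramming.
#'
#' @param coords array of dim `c(n_frames, n_beads, 3)` (nm), or a list of
#'   [cg_frame()] objects.
#' @param box length-3 box edges (nm).
#' @param types length-`n_beads` character vector of bead types.
#' @param masses optional bead masses (amu).
#' @return An object of class `cg_traj`.
#' @export
cg_traj <- function(coords, box, types, masses = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    frames <- coords
    nb <- nrow(frames[[1L]]$positions)
    arr <- array(0, c(length(frames), nb, 3L))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]$positions
    if (missing(box)) box <- frames[[1L]]$box
    if (missing(types)) types <- frames[[1L]]$types
    if (is.null(masses)) masses <- frames[[1L]]$masses
    coords <- arr
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  structure(list(coords = coords, box = as.numeric(box),
                 types = as.character(types), masses = masses),
            class = "cg_traj")
}

as_cg_traj <- function(frames) {
  if (inherits(frames, "cg_traj")) return(frames)
  if (inherits(frames, "cg_frame")) return(cg_traj(list(frames)))
  if (is.list(frames)) return(cg_traj(frames))
  stop("frames must be a cg_traj, a cg_frame, or a list of cg_frame")
}

#' @export
print.cg_traj <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<cg_traj: %d frames, %d beads, box %.3f x %.3f x %.3f nm>\n",
              d[1], d[2], x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

min_image <- function(d, box) {
  d - sweep(round(sweep(d, 2L, box, `/`)), 2L, box, `*`)
}

#' Radial distribution function between two bead-type sets
#'
#' Histograms minimum-image pair distances between beads of `types_a`
#' and `types_b`, averaged over frames, and normalizes by the
#' homogeneous ideal-gas shell expectation `N_a * rho_b * 4 pi r^2 dr`.
#' The type sets must be identical or disjoint. Excluded (bonded) pairs
#' are skipped. Grid points are bin midpoints, left edges at
#' `0, dx, 2 dx, ...`.
#'
#' @param frames a [cg_traj()] or list of [cg_frame()].
#' @param types_a,types_b character vectors of bead types.
#' @param r_max maximum distance (nm); must not exceed half the shortest
#'   box edge.
#' @param dx bin width (nm), default 0.01.
#' @param exclusions optional 2-column matrix of bead index pairs to skip.
#' @return A [tab_fn()] of kind `"rdf"`.
#' @export
radial_distribution <- function(frames, types_a, types_b, r_max, dx = 0.01,
                                exclusions = NULL) {
  traj <- as_cg_traj(frames)
  box <- traj$box
  if (r_max > min(box) / 2 + 1e-12)
    stop("r_max must not exceed half the shortest box edge")
  ia <- which(traj$types %in% types_a)
  ib <- which(traj$types %in% types_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("no beads of the requested types")
  same <- setequal(ia, ib)
  if (!same && length(intersect(ia, ib)) > 0L)
    stop("type sets must be identical or disjoint")
  nbins <- as.integer(floor(r_max / dx + 1e-9))
  if (nbins < 2L) stop("r_max/dx must give at least 2 bins")
  excl <- if (is.null(exclusions)) matrix(0L, 0L, 2L) else {
    storage.mode(exclusions) <- "integer"
    matrix(exclusions - 1L, ncol = 2L)
  }
  counts <- cpp_pair_histogram(traj$coords, box, ia - 1L, ib - 1L,
                               same, excl, nbins, dx)
  n_frames <- dim(traj$coords)[1]
  npair <- if (same) length(ia) * (length(ia) - 1) / 2 else
    length(ia) * length(ib)
  if (npair == 0) stop("no pairs between the requested type sets")
  r_mid <- (seq_len(nbins) - 0.5) * dx
  ideal <- n_frames * npair * 4 * pi * r_mid^2 * dx / prod(box)
  tab_fn(dx / 2, dx, counts / ideal, "rdf")
}

#' Bond-length distribution
#'
#' Normalized histogram (unit trapezoidal integral) of minimum-image
#' bond lengths over frames.
#'
#' @param frames a [cg_traj()] or list of [cg_frame()].
#' @param bond_pairs 2-column matrix of bonded bead index pairs.
#' @param l_max histogram range (nm).
#' @param dx bin width (nm).
#' @return A [tab_fn()] of kind `"bond_dist"`.
#' @export
bond_distribution <- function(frames, bond_pairs, l_max, dx = 0.002) {
  traj <- as_cg_traj(frames)
  bond_pairs <- matrix(as.integer(bond_pairs), ncol = 2L)
  if (nrow(bond_pairs) == 0L) stop("bond list is empty")
  nbins <- as.integer(floor(l_max / dx + 1e-9))
  counts <- numeric(nbins)
  for (b in seq_len(nrow(bond_pairs))) {
    d <- traj$coords[, bond_pairs[b, 1L], , drop = FALSE] -
         traj$coords[, bond_pairs[b, 2L], , drop = FALSE]
    d <- min_image(matrix(d, ncol = 3L), traj$box)
    l <- sqrt(rowSums(d^2))
    bin <- floor(l / dx) + 1L
    ok <- bin >= 1L & bin <= nbins
    counts <- counts + tabulate(bin[ok], nbins)
  }
  if (sum(counts) == 0) stop("no bond lengths fell inside [0, l_max]")
  tab_normalize(tab_fn(dx / 2, dx, counts, "bond_dist"))
}

#' Angle distribution
#'
#' Normalized histogram of the angle at the middle bead of each triple,
#' computed on minimum-image displacement vectors, on a grid spanning
#' 0 to 180 degrees. Triples with a degenerate (zero-length) arm are
#' skipped; their count is attached as attribute `"skipped"`.
#'
#' @param frames a [cg_traj()] or list of [cg_frame()].
#' @param angle_triples 3-column matrix (i, j, k); the angle is at j.
#' @param dtheta bin width in degrees (default 1).
#' @return A [tab_fn()] of kind `"angle_dist"` on `[0, 180]` degrees.
#' @export
angle_distribution <- function(frames, angle_triples, dtheta = 1) {
  traj <- as_cg_traj(frames)
  angle_triples <- matrix(as.integer(angle_triples), ncol = 3L)
  if (nrow(angle_triples) == 0L) stop("angle list is empty")
  nbins <- as.integer(round(180 / dtheta))
  counts <- numeric(nbins)
  skipped <- 0L
  for (a in seq_len(nrow(angle_triples))) {
    i <- angle_triples[a, 1L]; j <- angle_triples[a, 2L]; k <- angle_triples[a, 3L]
    u <- min_image(matrix(traj$coords[, i, ] - traj$coords[, j, ], ncol = 3L),
                   traj$box)
    v <- min_image(matrix(traj$coords[, k, ] - traj$coords[, j, ], ncol = 3L),
                   traj$box)
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    ok <- nu > 1e-12 & nv > 1e-12
    skipped <- skipped + sum(!ok)
    ct <- pmin(1, pmax(-1, rowSums(u * v)[ok] / (nu[ok] * nv[ok])))
    th <- acos(ct) * 180 / pi
    bin <- pmin(nbins, floor(th / dtheta) + 1L)
    counts <- counts + tabulate(bin, nbins)
  }
  if (sum(counts) == 0) stop("no valid angles measured")
  out <- tab_normalize(tab_fn(dtheta / 2, dtheta, counts, "angle_dist"))
  attr(out, "skipped") <- skipped
  out
}
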