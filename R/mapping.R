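#' All-atom coordinate frame
#'
#' @param positions N x 3 numeric matrix of positions (nm).
#' @param masses length-N positive numeric vector (amu).
#' @param labels length-N character vector of atom names.
#' @param box length-3 positive numeric vector of orthorhombic box edges (nm).
#' @return An object of class `atom_frame`.
#' @export
atom_frame <- function(positions, masses, labels = NULL, box) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an N x 3 matrix")
  n <- nrow(positions)
  masses <- as.numeric(masses)
  if (is.null(labels)) labels <- rep("X", n)
  if (length(masses) != n || length(labels) != n)
    stop("positions, masses and labels must have equal length")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("all masses must be positive and finite")
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be 3 positive edge lengths (nm)")
  structure(list(positions = positions, masses = masses,
                 labels = as.character(labels), box = box),
            class = "atom_frame")
}

#' Bead mapping scheme
#'
#' A partition of atom indices into typed beads. Solvent atoms listed in
#' `solvent_indices` are excluded from mapping entirely (the CG model is
#' implicit-solvent).
#'
#' @param beads list of entries, each `list(type = <string>, atoms = <indices>)`.
#' @param solvent_indices atom indices excluded from mapping.
#' @return An object of class `mapping_scheme`.
#' @export
mapping_scheme <- function(beads, solvent_indices = integer(0)) {
  if (length(beads) == 0L) stop("at least one bead is required")
  for (b in beads) {
    if (is.null(b$type) || is.null(b$atoms) || length(b$atoms) < 1L)
      stop("each bead needs a type and at least one atom index")
  }
  idx <- unlist(lapply(beads, `[[`, "atoms"))
  if (anyDuplicated(idx)) stop("atom indices must be disjoint across beads")
  if (length(intersect(idx, solvent_indices)) > 0L)
    stop("solvent indices cannot also belong to beads")
  structure(list(beads = beads,
                 solvent_indices = as.integer(solvent_indices)),
            class = "mapping_scheme")
}

#' Coarse-grained bead frame
#'
#' @param positions M x 3 numeric matrix of bead positions (nm).
#' @param masses length-M numeric vector (amu).
#' @param types length-M character vector of bead types.
#' @param box length-3 box edges (nm).
#' @return An object of class `cg_frame`.
#' @export
cg_frame <- function(positions, masses, types, box) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an M x 3 matrix")
  m <- nrow(positions)
  if (length(masses) != m || length(types) != m)
    stop("positions, masses and types must agree in length")
  structure(list(positions = positions, masses = as.numeric(masses),
                 types = as.character(types), box = as.numeric(box)),
            class = "cg_frame")
}

#' Mass-weighted center of mass
#'
#' `R = sum(r_i m_i) / sum(m_i)`, invariant under permutation of the
#' inputs. Positions are used as given; unwrap periodic groups first
#' (see [apply_mapping()], which does this automatically).
#'
#' @param positions N x 3 matrix (nm).
#' @param masses length-N positive numeric vector (amu).
#' @return length-3 numeric vector (nm).
#' @export
center_of_mass <- function(positions, masses) {
  positions <- as.matrix(positions)
  if (nrow(positions) == 0L) stop("center_of_mass of an empty group")
  masses <- as.numeric(masses)
  if (length(masses) != nrow(positions))
    stop("positions and masses must have equal length")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("all masses must be positive")
  as.numeric(crossprod(positions, masses)) / sum(masses)
}

# Make a group whole across periodic boundaries: minimum-image unwrap of
# every atom relative to the group's first atom.
unwrap_group <- function(positions, box) {
  ref <- positions[1L, ]
  d <- sweep(positions, 2L, ref)
  shift <- -round(sweep(d, 2L, box, `/`))
  positions + sweep(shift, 2L, box, `*`)
}

#' Map an all-atom frame to coarse-grained beads
#'
#' Each bead takes the center of mass of its member atoms (after
#' minimum-image unwrapping of the group relative to its first atom, so
#' boundary-straddling groups are made whole) and the sum of their
#' masses. Total mapped mass is conserved exactly.
#'
#' @param frame an [atom_frame()].
#' @param scheme a [mapping_scheme()].
#' @return A [cg_frame()] with one bead per scheme entry.
#' @export
apply_mapping <- function(frame, scheme) {
  stopifnot(inherits(frame, "atom_frame"), inherits(scheme, "mapping_scheme"))
  n <- nrow(frame$positions)
  all_idx <- unlist(lapply(scheme$beads, `[[`, "atoms"))
  if (any(all_idx < 1L) || any(all_idx > n) ||
      any(scheme$solvent_indices > n))
    stop("mapping scheme references atom indices outside the frame")
  m <- length(scheme$beads)
  pos <- matrix(0, m, 3L)
  mass <- numeric(m)
  types <- character(m)
  for (k in seq_len(m)) {
    b <- scheme$beads[[k]]
    p <- frame$positions[b$atoms, , drop = FALSE]
    if (nrow(p) > 1L) p <- unwrap_group(p, frame$box)
    pos[k, ] <- center_of_mass(p, frame$masses[b$atoms])
    mass[k] <- sum(frame$masses[b$atoms])
    types[k] <- b$type
  }
  cg_frame(pos, mass, types, frame$box)
}

#' CNT bead mapping: consecutive axial groups
#'
#' Groups the tube's atoms, ordered along the tube axis, into beads of
#' `atoms_per_bead` consecutive atoms each (type `"CNT"`). The reference
#' (5,5) tube at 10 atoms/bead over a 2.93 nm periodic cell gives 24 beads.
#'
#' @param n_atoms total number of CNT atoms.
#' @param atoms_per_bead atoms per bead; must divide `n_atoms` exactly.
#' @param axis_sorted_indices atom indices sorted by tube-axis coordinate;
#'   defaults to `1:n_atoms`.
#' @return A [mapping_scheme()].
#' @export
build_cnt_mapping <- function(n_atoms, atoms_per_bead,
                              axis_sorted_indices = seq_len(n_atoms)) {
  n_atoms <- as.integer(n_atoms); atoms_per_bead <- as.integer(atoms_per_bead)
  if (n_atoms < 1L || atoms_per_bead < 1L)
    stop("atom counts must be positive")
  if (n_atoms %% atoms_per_bead != 0L)
    stop("n_atoms must be an exact multiple of atoms_per_bead")
  if (length(axis_sorted_indices) != n_atoms)
    stop("axis_sorted_indices must list every atom once")
  nb <- n_atoms %/% atoms_per_bead
  beads <- lapply(seq_len(nb), function(k) {
    sel <- axis_sorted_indices[((k - 1L) * atoms_per_bead + 1L):(k * atoms_per_bead)]
    list(type = "CNT", atoms = as.integer(sel))
  })
  mapping_scheme(beads)
}

#' Capped amino-acid mapping: ACE / residue / NH2 beads
#'
#' A capped single amino acid maps to exactly three beads in chain order:
#' the acetyl cap (`ACE`), the whole residue including its side chain
#' (`AA`), and the amine cap (`NH2`). Cap atoms are excluded from the
#' residue bead.
#'
#' @param ace_indices,residue_indices,nh2_indices disjoint non-empty
#'   atom-index groups.
#' @return A [mapping_scheme()] with beads ordered (ACE, AA, NH2).
#' @export
build_peptide_mapping <- function(ace_indices, residue_indices, nh2_indices) {
  groups <- list(ace_indices, residue_indices, nh2_indices)
  if (any(vapply(groups, length, 1L) == 0L))
    stop("all three groups must be non-empty")
  if (anyDuplicated(unlist(groups)))
    stop("ACE, residue and NH2 atom groups must be disjoint")
  mapping_scheme(list(
    list(type = "ACE", atoms = as.integer(ace_indices)),
    list(type = "AA",  atoms = as.integer(residue_indices)),
    list(type = "NH2", atoms = as.integer(nh2_indices))
  ))
}
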