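#' Average residue masses of the 20 standard amino acids (amu)
#'
#' Residue (monomer-unit) masses used for the toy capped-amino-acid
#' geometries; the acetyl cap (CH3CO) weighs 43.045 amu and the amine
#' cap (NH2) 16.023 amu.
#' @export
residue_masses <- c(
  GLY = 57.0519, ALA = 71.0788, SER = 87.0782, PRO = 97.1167,
  VAL = 99.1326, THR = 101.1051, CYS = 103.1388, LEU = 113.1594,
  ILE = 113.1594, ASN = 114.1038, ASP = 115.0886, GLN = 128.1307,
  LYS = 128.1741, GLU = 129.1155, MET = 131.1926, HIS = 137.1411,
  PHE = 147.1766, ARG = 156.1875, TYR = 163.1760, TRP = 186.2132)

#' Armchair carbon-nanotube coordinates spanning a periodic box
#'
#' Builds an (n,n) armchair tube by rolling a graphene strip: all atoms
#' sit at one radius `3 n cc / (2 pi)` from the z axis, in rings of
#' `2n` atoms, two rings per translational cell of length `sqrt(3) cc`.
#' The tube is strained axially (uniformly) so an integer number of
#' cells exactly spans `box_z`; boxes further than 0.1 cells from an
#' integer multiple are rejected as non-commensurate. Atoms are emitted
#' ring by ring, so indices are sorted along the tube axis.
#'
#' @param box_z periodic box length along the tube axis (nm).
#' @param cc_bond carbon-carbon bond length (nm), default 0.142.
#' @param chirality length-2 integer vector `(n, n)`; only armchair
#'   tubes are supported. Default `c(5, 5)`.
#' @param box_xy transverse box edge (nm), default 4.16.
#' @return An [atom_frame()] (carbon mass 12.011, label `"C"`), axis
#'   along z through the box center.
#' @export
generate_cnt_coordinates <- function(box_z = 2.93, cc_bond = 0.142,
                                     chirality = c(5, 5), box_xy = 4.16) {
  if (length(chirality) != 2L || chirality[1] != chirality[2] ||
      chirality[1] < 2)
    stop("only armchair (n,n) chiralities with n >= 2 are supported")
  n <- as.integer(chirality[1])
  cell <- sqrt(3) * cc_bond
  ncell_f <- box_z / cell
  ncells <- round(ncell_f)
  if (ncells < 1L || abs(ncell_f - ncells) > 0.1)
    stop(sprintf(
      "box_z = %g nm is not commensurate with the (n,n) cell %.5f nm", box_z,
      cell))
  cell_eff <- box_z / ncells
  R <- 3 * n * cc_bond / (2 * pi)
  circ <- 3 * n * cc_bond
  # graphene strip: x along circumference, y along the axis
  xs <- as.vector(vapply(seq_len(n) - 1L,
                         function(i) 3 * cc_bond * i + c(0, cc_bond),
                         numeric(2)))
  xs2 <- as.vector(vapply(seq_len(n) - 1L,
                          function(i) 3 * cc_bond * i + c(1.5, 2.5) * cc_bond,
                          numeric(2)))
  pos <- matrix(0, 0L, 3L)
  for (c_i in seq_len(ncells) - 1L) {
    for (ring in 1:2) {
      x <- if (ring == 1) xs else xs2
      z <- (c_i + (ring - 1) * 0.5) * cell_eff
      phi <- 2 * pi * x / circ
      pos <- rbind(pos, cbind(box_xy / 2 + R * cos(phi),
                              box_xy / 2 + R * sin(phi), z))
    }
  }
  atom_frame(pos, rep(12.011, nrow(pos)), rep("C", nrow(pos)),
             c(box_xy, box_xy, box_z))
}

#' Toy capped amino-acid structure and its 3-bead mapping
#'
#' A schematic (mass-correct, shape-coarse) capped residue: three
#' clustered atom groups for the acetyl cap, the residue with its side
#' chain, and the amine cap, with the paired ACE/AA/NH2 mapping. Group
#' masses come from the standard residue-mass table; geometries are not
#' atomistically realistic (closure targets come from the CG engine
#' itself, not from these coordinates).
#'
#' @param residue_name three-letter code of a standard amino acid.
#' @param center position of the ACE group (nm).
#' @param box box edges (nm).
#' @return list with `frame` (an [atom_frame()]) and `scheme` (the
#'   [build_peptide_mapping()] scheme, beads ordered ACE, AA, NH2).
#' @export
generate_capped_residue <- function(residue_name,
                                    center = c(2.08, 2.88, 1.46),
                                    box = c(4.16, 4.16, 2.93)) {
  residue_name <- toupper(residue_name)
  if (!residue_name %in% names(residue_masses))
    stop(sprintf("unknown residue '%s'", residue_name))
  m_res <- residue_masses[[residue_name]]
  spread <- function(ctr, masses) {
    off <- matrix(c(0, 0, 0,  0.08, 0.05, 0,  -0.06, 0.07, 0.04,
                    0.03, -0.08, -0.05), ncol = 3L, byrow = TRUE)
    cbind(ctr[1] + off[seq_along(masses), 1],
          ctr[2] + off[seq_along(masses), 2],
          ctr[3] + off[seq_along(masses), 3])
  }
  ace_m <- c(15.035, 12.011, 15.999)                 # CH3, C, O
  res_m <- m_res * c(0.3, 0.3, 0.2, 0.2)
  nh2_m <- c(14.007, 1.008, 1.008)                   # N, H, H
  step <- c(0.38, 0, 0)
  pos <- rbind(spread(center, ace_m),
               spread(center + step, res_m),
               spread(center + 2 * step, nh2_m))
  frame <- atom_frame(pos, c(ace_m, res_m, nh2_m),
                      c("ACE", "ACE", "ACE", rep("AA", 4), "N", "H", "H"),
                      box)
  scheme <- build_peptide_mapping(1:3, 4:7, 8:10)
  list(frame = frame, scheme = scheme)
}

#' Tabulated 12-6 (Lennard-Jones) potential
#'
#' `U(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6)`, truncated and shifted to
#' zero at `r_cut`. Above `u_cap` the core is replaced by a linear
#' repulsive wall continuing the analytic slope at the capping radius,
#' so tabulated values stay finite on the full grid. The force column is
#' built by central differences ([force_from_potential()]).
#'
#' @param epsilon well depth (kJ/mol); 0 gives the ideal-gas table.
#' @param sigma size parameter (nm).
#' @param x0,dx,n uniform grid (nm); defaults give midpoints of 0.02 nm
#'   bins up to 1.2 nm.
#' @param r_cut truncation radius (nm).
#' @param u_cap wall-linearization threshold (kJ/mol).
#' @return A [potential_table()].
#' @export
lj_table <- function(epsilon, sigma, x0 = 0.01, dx = 0.02, n = 60L,
                     r_cut = 1.0, u_cap = 150) {
  r <- x0 + (seq_len(n) - 1L) * dx
  u_lj <- function(r) 4 * epsilon * ((sigma / r)^12 - (sigma / r)^6)
  shift <- u_lj(r_cut)
  U <- u_lj(r) - shift
  if (epsilon > 0) {
    above <- which(U > u_cap)
    if (length(above)) {
      iw <- max(above) + 1L
      rw <- r[iw]
      dUdr <- 4 * epsilon * (-12 * sigma^12 / rw^13 + 6 * sigma^6 / rw^7)
      U[above] <- U[iw] + dUdr * (r[above] - rw)
    }
  }
  U[r >= r_cut - 1e-12] <- 0
  potential_table(x0, dx, U, r_cut = r_cut)
}

#' Tabulated harmonic potential
#'
#' `U(x) = 0.5 k (x - center)^2`, for bond (nm) and angle (degree)
#' fixture tables; force column by central differences.
#'
#' @param center minimum position (nm or degrees).
#' @param k force constant (kJ/mol per unit squared).
#' @param x0,dx,n uniform grid.
#' @return A [potential_table()] with no cutoff.
#' @export
harmonic_table <- function(center, k, x0, dx, n) {
  x <- x0 + (seq_len(n) - 1L) * dx
  potential_table(x0, dx, 0.5 * k * (x - center)^2)
}

#' Homogeneous LJ bead fluid system
#'
#' `n_beads` identical beads of type `"LJ"` on a perturbed cubic
#' lattice with Maxwell-Boltzmann velocities (drawn from the current
#' RNG state), interacting through a [lj_table()] whose grid matches
#' the RDF estimator's midpoint grid.
#'
#' @param n_beads bead count (default 160, a dense supercritical state
#'   point: reduced density ~0.59, reduced temperature ~1.8 at 330 K).
#' @param box box edges (nm).
#' @param epsilon,sigma LJ parameters (kJ/mol, nm).
#' @param mass bead mass (amu).
#' @param T temperature for the initial velocities (K).
#' @param r_cut cutoff (nm).
#' @param dx RDF/table bin width (nm).
#' @return A [cg_system()].
#' @export
build_lj_fluid <- function(n_beads = 160L, box = c(2.2, 2.2, 2.2),
                           epsilon = 1.5, sigma = 0.34, mass = 72,
                           T = 330, r_cut = 1.0, dx = 0.02) {
  ncell <- ceiling(n_beads^(1 / 3))
  sp <- box / ncell
  g <- expand.grid(x = seq_len(ncell) - 0.5, y = seq_len(ncell) - 0.5,
                   z = seq_len(ncell) - 0.5)
  pos <- as.matrix(g[seq_len(n_beads), ]) * rep(sp, each = n_beads)
  pos <- pos + matrix(stats::runif(3 * n_beads, -0.02, 0.02), n_beads, 3L)
  n_bins <- floor((min(box) / 2) / dx)
  tab <- lj_table(epsilon, sigma, x0 = dx / 2, dx = dx, n = n_bins,
                  r_cut = r_cut)
  masses <- rep(mass, n_beads)
  cg_system(pos, masses, rep("LJ", n_beads), box,
            velocities = maxwell_velocities(masses, T),
            nonbonded = list("LJ-LJ" = tab))
}

#' CNT bead chain plus mobile 3-bead capped peptide
#'
#' The coarse-grained study system: 24 CNT beads (the (5,5) tube mapped
#' at 10 atoms/bead) bonded in a periodic chain along z with harmonic
#' bond and angle tables, and one mobile ACE-AA-NH2 peptide whose AA
#' bead interacts with the CNT beads through a [lj_table()] (the
#' iterated pair); the cap beads feel weaker LJ tables. All
#' intramolecular pairs are excluded or marked non-interacting.
#'
#' @param residue three-letter residue code for the AA bead mass.
#' @param epsilon AA-CNT well depth (kJ/mol); caps get `epsilon/2`.
#' @param sigma LJ size parameter (nm).
#' @param box box edges (nm); default the reference 4.16 x 4.16 x 2.93.
#' @param T temperature for initial peptide velocities (K).
#' @param r_cut cutoff (nm).
#' @param dx RDF/table bin width (nm).
#' @param frozen_cnt freeze the CNT beads (default `FALSE`: mobile).
#' @return A [cg_system()] with types `CNT`, `ACE`, `AA`, `NH2`.
#' @export
build_cnt_peptide_system <- function(residue = "GLY", epsilon = 3.0,
                                     sigma = 0.47,
                                     box = c(4.16, 4.16, 2.93), T = 330,
                                     r_cut = 1.0, dx = 0.01,
                                     frozen_cnt = FALSE) {
  n_cnt <- 24L
  spacing <- box[3] / n_cnt
  cnt_pos <- cbind(box[1] / 2, box[2] / 2, (seq_len(n_cnt) - 1L) * spacing)
  cnt_mass <- rep(10 * 12.011, n_cnt)
  # peptide beads radially offset from the tube axis
  pep <- generate_capped_residue(residue, center = c(box[1] / 2 + 0.9,
                                                     box[2] / 2, box[3] / 2),
                                 box = box)
  pep_cg <- apply_mapping(pep$frame, pep$scheme)
  pos <- rbind(cnt_pos, pep_cg$positions)
  masses <- c(cnt_mass, pep_cg$masses)
  types <- c(rep("CNT", n_cnt), pep_cg$types)
  bond_cnt <- harmonic_table(spacing, 40000, x0 = spacing - 0.06,
                             dx = 0.001, n = 121L)
  angle_cnt <- harmonic_table(180, 0.1, x0 = 0.5, dx = 1, n = 180L)
  bond_pep <- harmonic_table(0.38, 8000, x0 = 0.2, dx = 0.002, n = 181L)
  angle_pep <- harmonic_table(140, 0.02, x0 = 0.5, dx = 1, n = 180L)
  bonds <- c(
    lapply(seq_len(n_cnt), function(i)
      list(i = i, j = if (i < n_cnt) i + 1L else 1L, table = bond_cnt)),
    list(list(i = n_cnt + 1L, j = n_cnt + 2L, table = bond_pep),
         list(i = n_cnt + 2L, j = n_cnt + 3L, table = bond_pep)))
  angles <- c(
    lapply(seq_len(n_cnt), function(i) {
      list(i = if (i > 1L) i - 1L else n_cnt, j = i,
           k = if (i < n_cnt) i + 1L else 1L, table = angle_cnt)
    }),
    list(list(i = n_cnt + 1L, j = n_cnt + 2L, k = n_cnt + 3L,
              table = angle_pep)))
  n_bins <- floor(r_cut * 1.2 / dx)
  lj_pair <- function(eps) lj_table(eps, sigma, x0 = dx / 2, dx = dx,
                                    n = n_bins, r_cut = r_cut)
  nonbonded <- list("AA-CNT" = lj_pair(epsilon),
                    "ACE-CNT" = lj_pair(epsilon / 2),
                    "CNT-NH2" = lj_pair(epsilon / 2),
                    "CNT-CNT" = "none", "AA-AA" = "none",
                    "ACE-ACE" = "none", "NH2-NH2" = "none",
                    "AA-ACE" = "none", "AA-NH2" = "none",
                    "ACE-NH2" = "none")
  vel <- maxwell_velocities(masses, T)
  frozen <- c(rep(frozen_cnt, n_cnt), rep(FALSE, 3L))
  vel[frozen, ] <- 0
  cg_system(pos, masses, types, box, velocities = vel, bonds = bonds,
            angles = angles, nonbonded = nonbonded, frozen = frozen)
}

#' Build a self-consistency (closure) fixture
#'
#' Generates the target distributions with the package's own CG engine
#' under a known ground-truth potential, so the inverse method can be
#' validated end to end: the IBI fit started from the target's PMF must
#' re-reach the target RDF (and recover the ground-truth potential up
#' to statistical noise). Fully replayable from the recorded provenance.
#'
#' @param preset `"fluid"` (homogeneous LJ bead fluid; iterated pair
#'   `LJ-LJ`) or `"cnt-peptide"` (CNT bead chain + capped peptide;
#'   iterated pair `AA-CNT`).
#' @param epsilon,sigma ground-truth LJ parameters (kJ/mol, nm);
#'   `sigma = NULL` picks the preset default (0.34 fluid, 0.47 tube).
#' @param n_mobile bead count for the fluid preset.
#' @param box box edges (nm); `NULL` for the preset default.
#' @param T temperature (K).
#' @param seed RNG seed (initial velocities and thermostat).
#' @param steps target-run length in steps.
#' @param dx RDF bin width (nm); `NULL` for the preset default.
#' @param r_cut cutoff (nm).
#' @param sample_interval frame sampling stride of the target run.
#' @param equilibration_fraction frames discarded before measuring.
#' @return An object of class `closure_fixture`: list with
#'   `ground_truth` (the iterated pair's [potential_table()]), `system`
#'   (a [cg_system()] template), `target` (the target RDF), `dists`
#'   (rdf plus, for the tube preset, bond/angle distributions),
#'   `iterate_pair`, and `provenance`.
#' @export
make_closure_fixture <- function(preset = c("fluid", "cnt-peptide"),
                                 epsilon = 1.5, sigma = NULL,
                                 n_mobile = 160L, box = NULL, T = 330,
                                 seed = 1L, steps = 100000L, dx = NULL,
                                 r_cut = 1.0, sample_interval = 5L,
                                 equilibration_fraction = 0.2) {
  preset <- match.arg(preset)
  set.seed(seed)
  if (preset == "fluid") {
    if (is.null(sigma)) sigma <- 0.34
    if (is.null(box)) box <- c(2.2, 2.2, 2.2)
    if (is.null(dx)) dx <- 0.02
    system <- build_lj_fluid(n_mobile, box, epsilon, sigma, T = T,
                             r_cut = r_cut, dx = dx)
    iterate_pair <- c("LJ", "LJ")
    ground_truth <- system$nonbonded[["LJ-LJ"]]
  } else {
    if (is.null(sigma)) sigma <- 0.47
    if (is.null(box)) box <- c(4.16, 4.16, 2.93)
    if (is.null(dx)) dx <- 0.01
    system <- build_cnt_peptide_system(epsilon = epsilon, sigma = sigma,
                                       box = box, T = T, r_cut = r_cut,
                                       dx = dx)
    iterate_pair <- c("AA", "CNT")
    ground_truth <- system$nonbonded[["AA-CNT"]]
  }
  cfg <- sim_config(n_steps = steps, T_ref = T, r_cut = r_cut,
                    seed = seed, sample_interval = sample_interval)
  run <- run_nvt(system, cfg)
  nf <- dim(run$traj$coords)[1]
  keep <- seq.int(floor(nf * equilibration_fraction) + 1L, nf)
  prod <- cg_traj(run$traj$coords[keep, , , drop = FALSE], system$box,
                  system$types, system$masses)
  r_max <- length(ground_truth$U) * dx
  target <- radial_distribution(prod, iterate_pair[1], iterate_pair[2],
                                r_max, dx, exclusions = system$exclusions)
  dists <- list(rdf = target)
  if (preset == "cnt-peptide") {
    cnt_bonds <- t(vapply(system$bonds[1:24], function(b) c(b$i, b$j),
                          integer(2)))
    cnt_angles <- t(vapply(system$angles[1:24], function(a) c(a$i, a$j, a$k),
                           integer(3)))
    dists$bond <- bond_distribution(prod, cnt_bonds, l_max = 0.3, dx = 0.002)
    dists$angle <- angle_distribution(prod, cnt_angles, dtheta = 1)
  }
  # hand the template back with equilibrated coordinates, so iteration
  # runs start from a well-relaxed configuration
  structure(list(ground_truth = ground_truth, system = run$system,
                 target = target, dists = dists,
                 iterate_pair = iterate_pair,
                 provenance = list(preset = preset, epsilon = epsilon,
                                   sigma = sigma, n_mobile = n_mobile,
                                   box = box, T = T, seed = seed,
                                   steps = steps, dx = dx, r_cut = r_cut,
                                   sample_interval = sample_interval,
                                   equilibration_fraction =
                                     equilibration_fraction)),
            class = "closure_fixture")
}

#' @export
print.closure_fixture <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "<closure_fixture: %s, eps = %g kJ/mol, sigma = %g nm, %d-step target (seed %d)>\n",
    p$preset, p$epsilon, p$sigma, p$steps, p$seed))
  invisible(x)
}

#' Perturb a closure target with sampling-like noise
#'
#' Adds zero-mean Gaussian noise to the target RDF (clipped at zero);
#' bond/angle distributions, when present, are perturbed the same way
#' and renormalized. Used to probe IBI robustness to target noise.
#'
#' @param fixture a `closure_fixture` (or a single [tab_fn()]).
#' @param noise_sd noise standard deviation (per bin).
#' @return a list of perturbed distributions (or a perturbed `tab_fn`).
#' @export
make_noisy_target <- function(fixture, noise_sd) {
  perturb <- function(f) {
    f$values <- pmax(0, f$values + stats::rnorm(length(f$values), 0, noise_sd))
    if (f$kind %in% c("bond_dist", "angle_dist")) f <- tab_normalize(f)
    f
  }
  if (inherits(fixture, "tab_fn")) return(perturb(fixture))
  stopifnot(inherits(fixture, "closure_fixture"))
  lapply(fixture$dists, perturb)
}
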