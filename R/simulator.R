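pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "-")

#' Coarse-grained simulation system
#'
#' Holds bead positions, velocities, masses and types, the orthorhombic
#' box, bonded topology with tabulated bond/angle potentials, the map
#' from unordered type pairs to non-bonded [potential_table()]s, pair
#' exclusions and per-bead freeze flags.
#'
#' Every unordered pair of bead types present in the system must appear
#' in `nonbonded`, either as a `potential_table` or as the string
#' `"none"` (an explicit no-interaction marker). Bonded 1-2 and 1-3
#' pairs are added to the exclusion list automatically.
#'
#' @param positions N x 3 matrix (nm).
#' @param masses length-N positive vector (amu).
#' @param types length-N character vector.
#' @param box length-3 box edges (nm).
#' @param velocities N x 3 matrix (nm/ps); zeros when omitted.
#' @param bonds list of `list(i, j, table)` with a bond
#'   [potential_table()] (x in nm).
#' @param angles list of `list(i, j, k, table)`; angle at bead `j`,
#'   table x in degrees.
#' @param nonbonded named list keyed `"A-B"` (types sorted
#'   alphabetically) of `potential_table` or `"none"`.
#' @param exclusions optional extra 2-column matrix of excluded pairs.
#' @param frozen logical, recycled to length N; frozen beads accumulate
#'   force but never move.
#' @return An object of class `cg_system`.
#' @export
cg_system <- function(positions, masses, types, box, velocities = NULL,
                      bonds = list(), angles = list(), nonbonded = list(),
                      exclusions = NULL, frozen = FALSE) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3L, length(masses) == n, length(types) == n)
  if (any(masses <= 0)) stop("all bead masses must be positive")
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive edges")
  if (is.null(velocities)) velocities <- matrix(0, n, 3L)
  velocities <- as.matrix(velocities)
  stopifnot(nrow(velocities) == n, ncol(velocities) == 3L)
  frozen <- rep_len(as.logical(frozen), n)

  check_idx <- function(i) {
    if (any(i < 1L) || any(i > n)) stop("bead index out of range")
    as.integer(i)
  }
  for (b in bonds) {
    check_idx(c(b$i, b$j))
    if (b$i == b$j) stop("self-bond not allowed")
    if (!inherits(b$table, "potential_table")) stop("bond needs a potential_table")
  }
  for (a in angles) {
    check_idx(c(a$i, a$j, a$k))
    if (anyDuplicated(c(a$i, a$j, a$k))) stop("angle beads must be distinct")
    if (!inherits(a$table, "potential_table")) stop("angle needs a potential_table")
  }
  utypes <- sort(unique(types))
  for (a in utypes) for (b in utypes) {
    if (a <= b) {
      k <- pair_key(a, b)
      v <- nonbonded[[k]]
      if (is.null(v))
        stop(sprintf("type pair '%s' has no non-bonded assignment; ", k),
             "give a potential_table or the marker \"none\"")
      if (!identical(v, "none") && !inherits(v, "potential_table"))
        stop(sprintf("nonbonded[['%s']] must be a potential_table or \"none\"", k))
    }
  }
  excl <- matrix(integer(0), 0L, 2L)
  if (!is.null(exclusions))
    excl <- matrix(as.integer(exclusions), ncol = 2L)
  for (b in bonds) excl <- rbind(excl, c(b$i, b$j))
  for (a in angles) excl <- rbind(excl, c(a$i, a$j), c(a$j, a$k), c(a$i, a$k))
  if (nrow(excl)) {
    excl <- t(apply(excl, 1L, sort))
    excl <- unique(excl)
  }
  structure(list(positions = positions, velocities = velocities,
                 masses = as.numeric(masses), types = as.character(types),
                 box = box, bonds = bonds, angles = angles,
                 nonbonded = nonbonded, exclusions = excl, frozen = frozen),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf(
    "<cg_system: %d beads (%s), %d bonds, %d angles, box %.3f x %.3f x %.3f nm>\n",
    nrow(x$positions), paste(unique(x$types), collapse = ", "),
    length(x$bonds), length(x$angles), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Simulation run configuration
#'
#' @param dt integration time step (ps); default 0.001.
#' @param n_steps number of leapfrog steps; default 100000.
#' @param T_ref thermostat set point (K); default 330.
#' @param thermostat `"vrescale"` (canonical stochastic velocity
#'   rescaling), `"berendsen"`, or `"none"` (NVE).
#' @param tau_T coupling time (ps); default 0.1.
#' @param r_cut non-bonded cutoff (nm); default 1.0.
#' @param seed RNG seed for the stochastic thermostat.
#' @param sample_interval frames are emitted every this many steps.
#' @param remove_com remove mobile-subsystem center-of-mass motion every
#'   step (default `TRUE`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.001, n_steps = 100000L, T_ref = 330,
                       thermostat = c("vrescale", "berendsen", "none"),
                       tau_T = 0.1, r_cut = 1.0, seed = 1L,
                       sample_interval = 10L, remove_com = TRUE) {
  thermostat <- match.arg(thermostat)
  if (!(dt > 0)) stop("dt must be > 0")
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (!(T_ref > 0)) stop("T_ref must be > 0 K")
  if (!(tau_T > 0)) stop("tau_T must be > 0 ps")
  if (!(r_cut > 0)) stop("r_cut must be > 0 nm")
  structure(list(dt = dt, n_steps = as.integer(n_steps), T_ref = T_ref,
                 thermostat = thermostat, tau_T = tau_T, r_cut = r_cut,
                 seed = as.integer(seed),
                 sample_interval = as.integer(sample_interval),
                 remove_com = isTRUE(remove_com)),
            class = "sim_config")
}

# Flatten a cg_system into the argument set of the compiled kernels.
engine_args <- function(system, r_cut) {
  utypes <- sort(unique(system$types))
  type_idx <- match(system$types, utypes) - 1L
  nt <- length(utypes)
  tabs <- list()
  pair_tab <- matrix(-1L, nt, nt)
  as_tab <- function(pt) list(x0 = pt$x0, dx = pt$dx, U = pt$U, F = pt$F)
  for (a in seq_len(nt)) for (b in a:nt) {
    v <- system$nonbonded[[pair_key(utypes[a], utypes[b])]]
    if (inherits(v, "potential_table")) {
      tabs[[length(tabs) + 1L]] <- as_tab(v)
      pair_tab[a, b] <- pair_tab[b, a] <- length(tabs) - 1L
    }
  }
  bond_tabs <- lapply(system$bonds, function(b) as_tab(b$table))
  bonds <- if (length(system$bonds))
    t(vapply(system$bonds, function(b) c(b$i, b$j), integer(2))) - 1L
  else matrix(integer(0), 0L, 2L)
  angle_tabs <- lapply(system$angles, function(a) as_tab(a$table))
  angles <- if (length(system$angles))
    t(vapply(system$angles, function(a) c(a$i, a$j, a$k), integer(3))) - 1L
  else matrix(integer(0), 0L, 3L)
  excl <- if (nrow(system$exclusions)) system$exclusions - 1L
  else matrix(integer(0), 0L, 2L)
  storage.mode(excl) <- "integer"
  list(pos = system$positions, vel = system$velocities,
       mass = system$masses, box = system$box, type_idx = type_idx,
       pair_tab = pair_tab, nb = tabs, r_cut = r_cut, excl = excl,
       bonds = bonds, bond_idx = seq_along(bond_tabs) - 1L,
       bond_tabs = bond_tabs, angles = angles,
       angle_idx = seq_along(angle_tabs) - 1L, angle_tabs = angle_tabs,
       frozen = system$frozen)
}

#' Forces and potential energy of a configuration
#'
#' Pairwise minimum-image non-bonded forces by linear interpolation of
#' the tabulated force column (distances below a table's range clamp to
#' its wall force and are counted), plus tabulated bond and angle
#' forces. Newton's third law holds exactly; frozen beads accumulate
#' force but are never moved by the integrator.
#'
#' @param system a [cg_system()].
#' @param r_cut non-bonded cutoff (nm); default 1.0.
#' @return list with `forces` (N x 3, kJ/(mol nm)), `epot` (kJ/mol) and
#'   `clamped` (count of off-table lookups).
#' @export
compute_forces <- function(system, r_cut = 1.0) {
  a <- engine_args(system, r_cut)
  cpp_compute_forces(a$pos, a$box, a$type_idx, a$pair_tab, a$nb, a$r_cut,
                     a$excl, a$bonds, a$bond_idx, a$bond_tabs, a$angles,
                     a$angle_idx, a$angle_tabs, a$frozen)
}

#' One leapfrog step
#'
#' `v(t+dt/2) = v(t-dt/2) + F/m dt`, then `x(t+dt) = x(t) + v(t+dt/2) dt`,
#' positions wrapped into the box. No thermostat is applied; see
#' [run_nvt()] for thermostatted runs.
#'
#' @param system a [cg_system()].
#' @param config a [sim_config()].
#' @return the updated `cg_system`.
#' @export
leapfrog_step <- function(system, config) {
  f <- compute_forces(system, config$r_cut)$forces
  mob <- !system$frozen
  v <- system$velocities
  v[mob, ] <- v[mob, ] + f[mob, , drop = FALSE] / system$masses[mob] * config$dt
  x <- system$positions
  x[mob, ] <- x[mob, ] + v[mob, , drop = FALSE] * config$dt
  x <- x - sweep(floor(sweep(x, 2L, system$box, `/`)), 2L, system$box, `*`)
  if (any(!is.finite(x)))
    stop("integration blow-up: non-finite coordinate after leapfrog step")
  system$velocities <- v
  system$positions <- x
  system
}

#' Instantaneous kinetic temperature
#'
#' `T = sum(m v^2) / (N_df kB)` with `N_df = 3 * n_mobile - 3` (the
#' center-of-mass motion is removed by the integrator).
#'
#' @param system a [cg_system()].
#' @return temperature in K.
#' @export
instantaneous_temperature <- function(system) {
  mob <- which(!system$frozen)
  if (length(mob) == 0L) stop("no mobile beads")
  ndf <- max(1L, 3L * length(mob) - 3L)
  K <- 0.5 * sum(system$masses[mob] * rowSums(system$velocities[mob, , drop = FALSE]^2))
  2 * K / (ndf * kB)
}

csvr_factor <- function(K, Kbar, ndf, dt, tau) {
  c <- exp(-dt / tau)
  R1 <- stats::rnorm(1)
  sumR2 <- if (ndf > 1) stats::rchisq(1, df = ndf - 1) else 0
  a2 <- c + (1 - c) * Kbar * (R1^2 + sumR2) / (ndf * K) +
    2 * R1 * sqrt(c * (1 - c) * Kbar / (ndf * K))
  sqrt(max(0, a2))
}

#' Canonical stochastic velocity-rescaling (V-rescale) thermostat
#'
#' One application of the stochastic kinetic-energy propagator: the
#' kinetic energy is relaxed toward its canonical expectation with
#' coupling time `tau_T`, and all mobile velocities are scaled by the
#' resulting common factor. Deterministic for a fixed RNG state; in the
#' limit `tau_T -> Inf` velocities are unchanged.
#'
#' @param system a [cg_system()].
#' @param config a [sim_config()] supplying `dt`, `T_ref`, `tau_T`.
#' @return the system with rescaled velocities.
#' @export
vrescale_thermostat <- function(system, config) {
  mob <- which(!system$frozen)
  if (length(mob) == 0L) stop("no mobile beads")
  ndf <- max(1L, 3L * length(mob) - 3L)
  K <- 0.5 * sum(system$masses[mob] * rowSums(system$velocities[mob, , drop = FALSE]^2))
  if (K <= 0) return(system)
  s <- csvr_factor(K, 0.5 * ndf * kB * config$T_ref, ndf, config$dt, config$tau_T)
  system$velocities[mob, ] <- system$velocities[mob, ] * s
  system
}

#' Berendsen weak-coupling thermostat
#'
#' Scales mobile velocities by
#' `lambda = sqrt(1 + (dt/tau_T) (T_ref/T - 1))`.
#'
#' @inheritParams vrescale_thermostat
#' @return the system with rescaled velocities.
#' @export
berendsen_thermostat <- function(system, config) {
  mob <- which(!system$frozen)
  if (length(mob) == 0L) stop("no mobile beads")
  T <- instantaneous_temperature(system)
  if (T <= 0) return(system)
  lambda <- sqrt(max(0, 1 + config$dt / config$tau_T * (config$T_ref / T - 1)))
  system$velocities[mob, ] <- system$velocities[mob, ] * lambda
  system
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Each component is normal with sd `sqrt(kB T / m)`; the mass-weighted
#' mean velocity is removed afterwards when `remove_com` is `TRUE`.
#'
#' @param masses bead masses (amu).
#' @param T temperature (K).
#' @param remove_com remove net momentum (default `TRUE`).
#' @return N x 3 matrix of velocities (nm/ps).
#' @export
maxwell_velocities <- function(masses, T, remove_com = TRUE) {
  n <- length(masses)
  v <- matrix(stats::rnorm(3 * n), n, 3L) * sqrt(thermal_energy(T) / masses)
  if (remove_com && n > 1L)
    v <- sweep(v, 2L, colSums(v * masses) / sum(masses))
  v
}

#' Run NVT (or NVE) coarse-grained molecular dynamics
#'
#' Integrates `n_steps` leapfrog steps with the configured thermostat
#' applied every step and mobile center-of-mass motion removed. Frames
#' are sampled every `sample_interval` steps; instantaneous temperature,
#' potential energy and on-step kinetic energy are recorded every step.
#' Bit-reproducible for a fixed `config$seed`.
#'
#' @param system a [cg_system()].
#' @param config a [sim_config()]; `r_cut` must not exceed half the
#'   shortest box edge.
#' @return An object of class `cg_run`: list with `traj` (a
#'   [cg_traj()]), `T`, `epot`, `kin_onstep` (per-step series), `system`
#'   (final state), `ndf`, `clamped`, and the `config` used.
#' @export
run_nvt <- function(system, config) {
  stopifnot(inherits(system, "cg_system"), inherits(config, "sim_config"))
  if (config$r_cut > min(system$box) / 2 + 1e-12)
    stop("r_cut exceeds half the shortest box edge")
  a <- engine_args(system, config$r_cut)
  th <- match(config$thermostat, c("none", "vrescale", "berendsen")) - 1L
  set.seed(config$seed)
  res <- cpp_run_nvt(a$pos, a$vel, a$mass, a$box, a$type_idx, a$pair_tab,
                     a$nb, a$r_cut, a$excl, a$bonds, a$bond_idx, a$bond_tabs,
                     a$angles, a$angle_idx, a$angle_tabs, a$frozen,
                     config$dt, config$n_steps, config$T_ref, th,
                     config$tau_T, config$sample_interval, config$remove_com,
                     kB)
  system$positions <- res$positions
  system$velocities <- res$velocities
  structure(list(
    traj = cg_traj(res$frames, system$box, system$types, system$masses),
    T = res$T, epot = res$epot, kin_onstep = res$kin_onstep,
    system = system, ndf = res$ndf, clamped = res$clamped, config = config),
    class = "cg_run")
}

#' @export
print.cg_run <- function(x, ...) {
  n <- length(x$T)
  prod_T <- mean(x$T[max(1, floor(n * 0.2)):n])
  cat(sprintf("<cg_run: %d steps of dt = %g ps, %s thermostat>\n",
              n, x$config$dt, x$config$thermostat))
  cat(sprintf("  mean T (last 80%%) = %.2f K, %d sampled frames\n",
              prod_T, dim(x$traj$coords)[1]))
  invisible(x)
}
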