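#' IBI iteration configuration
#'
#' @param max_iters iteration cap (default 100).
#' @param f_tol convergence tolerance on the weighted functional
#'   (default 1e-4, dimensionless with r in nm).
#' @param alpha_coeff linear-correction coefficient in units of `kB T`
#'   (default -0.001, i.e. `alpha = -0.001 kB T`).
#' @param use_linear_correction apply the linear tail correction
#'   `alpha (1 - r/r_cut)` every update (default `TRUE`).
#' @param r_cut non-bonded cutoff (nm), default 1.
#' @param damping factor in (0, 1] on the `kB T ln(g_n/g_target)`
#'   increment (default 0.2); changes the iteration path, not its fixed
#'   point.
#' @param smooth_method,smooth_window smoothing of the update increment
#'   (see [smooth_table()]); `smooth_window = 1` disables.
#' @param sim per-iteration [sim_config()].
#' @param equilibration_fraction fraction of sampled frames discarded
#'   before measuring `g_n` (default 0.2).
#' @param base_seed per-iteration seed is `base_seed + n`.
#' @param iterate_pair length-2 character vector: the bead-type pair
#'   whose non-bonded table is iterated; all other tables stay fixed.
#' @param g_floor bins at or below this are unsampled (default 1e-6).
#' @param cap_kT increment cap in units of `kB T` (default 2), guarding
#'   against runaway walls at unsampled bins.
#' @return An object of class `ibi_config`.
#' @export
ibi_config <- function(max_iters = 100L, f_tol = 1e-4, alpha_coeff = -0.001,
                       use_linear_correction = TRUE, r_cut = 1.0,
                       damping = 0.2, smooth_method = "ma",
                       smooth_window = 5L, sim = sim_config(),
                       equilibration_fraction = 0.2, base_seed = 1L,
                       iterate_pair = c("AA", "CNT"), g_floor = 1e-6,
                       cap_kT = 2) {
  if (!(f_tol > 0)) stop("f_tol must be > 0")
  if (!(damping > 0 && damping <= 1)) stop("damping must be in (0, 1]")
  if (!(equilibration_fraction >= 0 && equilibration_fraction < 1))
    stop("equilibration_fraction must be in [0, 1)")
  stopifnot(inherits(sim, "sim_config"), length(iterate_pair) == 2L)
  structure(list(max_iters = as.integer(max_iters), f_tol = f_tol,
                 alpha_coeff = alpha_coeff,
                 use_linear_correction = isTRUE(use_linear_correction),
                 r_cut = r_cut, damping = damping,
                 smooth_method = smooth_method,
                 smooth_window = as.integer(smooth_window), sim = sim,
                 equilibration_fraction = equilibration_fraction,
                 base_seed = as.integer(base_seed),
                 iterate_pair = as.character(iterate_pair),
                 g_floor = g_floor, cap_kT = cap_kT),
            class = "ibi_config")
}

#' Linear tail correction
#'
#' `dU(r) = alpha (1 - r/r_cut)` for `r <= r_cut`, zero beyond: the
#' ramp equals `alpha` at `r = 0` and vanishes at the cutoff.
#'
#' @param grid a [tab_fn()]/[potential_table()] whose grid to use, or a
#'   numeric vector of r values (uniformly spaced).
#' @param alpha ramp height at r = 0 (kJ/mol); conventionally
#'   `-0.001 * kB * T`.
#' @param r_cut cutoff radius (nm), > 0.
#' @return A [tab_fn()] of kind `"potential"`.
#' @export
linear_correction <- function(grid, alpha, r_cut) {
  if (!(r_cut > 0)) stop("r_cut must be > 0")
  if (inherits(grid, "tab_fn")) {
    x0 <- grid$x0; dx <- grid$dx; x <- tab_grid(grid)
  } else {
    x <- as.numeric(grid)
    dx <- diff(x)
    if (any(abs(dx - dx[1]) > 1e-9)) stop("grid must be uniform")
    x0 <- x[1]; dx <- dx[1]
  }
  v <- ifelse(x <= r_cut, alpha * (1 - x / r_cut), 0)
  tab_fn(x0, dx, v, "potential")
}

#' Weighted RDF mismatch functional
#'
#' `f_target = integral of w(r) (g(r) - g_target(r))^2 dr` with weight
#' `w(r) = exp(-r)` (r in nm), by trapezoidal quadrature on the common
#' grid.
#'
#' @param g,g_target [tab_fn()]s on identical grids.
#' @return the dimensionless functional value.
#' @export
convergence_metric <- function(g, g_target) {
  if (!same_grid(g, g_target)) stop("g and g_target must share one grid")
  x <- tab_grid(g)
  integrand <- exp(-x) * (g$values - g_target$values)^2
  v <- integrand
  g$dx * (sum(v) - (v[1] + v[length(v)]) / 2)
}

#' One IBI potential update
#'
#' `U_{n+1}(r) = U_n(r) + damping * kB T ln(g_n(r)/g_target(r)) + dU(r)`,
#' evaluated where both distributions exceed `g_floor`. Bins where only
#' one side is sampled move by the capped `cap_kT * kB T`; fully
#' unsampled bins are left alone. The increment is smoothed, the linear
#' tail correction added, and the result re-shifted to `U(r_cut) = 0`
#' with its force column rebuilt.
#'
#' @param U_n current [potential_table()].
#' @param g_n,g_target measured and target RDFs on the same grid as `U_n`.
#' @param T temperature (K).
#' @param config an [ibi_config()].
#' @return the updated [potential_table()].
#' @export
ibi_update <- function(U_n, g_n, g_target, T, config) {
  stopifnot(inherits(U_n, "potential_table"), inherits(config, "ibi_config"))
  if (!same_grid(U_n, g_n) || !same_grid(U_n, g_target))
    stop("U_n, g_n and g_target must share one grid")
  kT <- thermal_energy(T)
  x <- tab_grid(U_n)
  vn <- g_n$values > config$g_floor
  vt <- g_target$values > config$g_floor
  incr <- numeric(length(x))
  both <- vn & vt
  incr[both] <- kT * log(g_n$values[both] / g_target$values[both])
  incr[!vn & vt] <- -config$cap_kT * kT
  incr[vn & !vt] <- +config$cap_kT * kT
  incr <- pmin(pmax(incr, -config$cap_kT * kT), config$cap_kT * kT)
  incr <- incr * config$damping
  incr[x > config$r_cut] <- 0
  if (config$smooth_window > 1L)
    incr <- smooth_table(tab_fn(U_n$x0, U_n$dx, incr, "potential"),
                         method = config$smooth_method,
                         window = config$smooth_window)$values
  U <- U_n$U + incr
  if (config$use_linear_correction) {
    dU <- linear_correction(U_n, config$alpha_coeff * kT, config$r_cut)
    U <- U + dU$values
  }
  U <- U - stats::approx(x, U, xout = config$r_cut, rule = 2)$y
  U[x >= config$r_cut - 1e-12] <- 0
  potential_table(U_n$x0, U_n$dx, U, r_core = U_n$r_core,
                  r_cut = config$r_cut)
}

#' Fit a coarse-grained pair potential by Iterative Boltzmann Inversion
#'
#' The central fitting routine. Starting from the potential of mean
#' force of the target RDF (or a supplied initial table), it repeats:
#' run coarse-grained NVT molecular dynamics under the current tables,
#' measure the iterated pair's RDF `g_n`, score the weighted functional
#' `f_target`, stop when `f_target <= f_tol` or the iteration cap is
#' reached, otherwise apply [ibi_update()]. The returned fit reports the
#' best-scoring iteration, not necessarily the last.
#'
#' @param g_target target RDF ([tab_fn()], kind `"rdf"`), on the
#'   midpoint grid produced by [radial_distribution()].
#' @param system_template a [cg_system()] whose `iterate_pair`
#'   non-bonded entry is replaced each iteration.
#' @param config an [ibi_config()].
#' @param initial_U optional starting [potential_table()]; defaults to
#'   `pmf_from_rdf(g_target, ...)`.
#' @param out_dir optional archive directory: per-iteration potential
#'   and RDF tables plus a manifest and f-history log are written there.
#' @param verbose print one progress line per iteration.
#' @return An object of class `ibi_fit`; see [coef.ibi_fit()],
#'   [predict.ibi_fit()], [plot.ibi_fit()], [simulate.ibi_fit()].
#' @export
run_ibi <- function(g_target, system_template, config = ibi_config(),
                    initial_U = NULL, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(g_target, "tab_fn"),
            inherits(system_template, "cg_system"),
            inherits(config, "ibi_config"))
  T <- config$sim$T_ref
  key <- pair_key(config$iterate_pair[1], config$iterate_pair[2])
  if (is.null(system_template$nonbonded[[key]]))
    stop(sprintf("system has no non-bonded slot for iterated pair '%s'", key))
  if (is.null(initial_U))
    initial_U <- pmf_from_rdf(g_target, T, config$r_cut, config$g_floor)
  if (!same_grid(initial_U, g_target))
    stop("initial_U must live on the grid of g_target")
  r_max <- length(g_target$values) * g_target$dx
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  U_n <- initial_U
  iters <- list()
  f_hist <- numeric(0)
  for (n in 0:config$max_iters) {
    sys <- system_template
    sys$nonbonded[[key]] <- U_n
    cfg <- config$sim
    cfg$seed <- config$base_seed + n
    run <- tryCatch(run_nvt(sys, cfg), error = function(e)
      stop(sprintf("IBI aborted at iteration %d: %s", n, conditionMessage(e)),
           call. = FALSE))
    nf <- dim(run$traj$coords)[1]
    keep <- seq.int(floor(nf * config$equilibration_fraction) + 1L, nf)
    prod_traj <- cg_traj(run$traj$coords[keep, , , drop = FALSE],
                         sys$box, sys$types, sys$masses)
    g_n <- radial_distribution(prod_traj, config$iterate_pair[1],
                               config$iterate_pair[2], r_max, g_target$dx,
                               exclusions = sys$exclusions)
    f_n <- convergence_metric(g_n, g_target)
    f_hist <- c(f_hist, f_n)
    prod_steps <- max(1L, floor(length(run$T) * config$equilibration_fraction))
    iters[[n + 1L]] <- list(n = n, f = f_n, seed = cfg$seed, U = U_n, g = g_n,
                            mean_T = mean(run$T[prod_steps:length(run$T)]))
    if (!is.null(out_dir)) {
      d <- file.path(out_dir, sprintf("iter_%03d", n))
      dir.create(d, showWarnings = FALSE)
      write_table(U_n, file.path(d, "potential.dat"))
      write_table(g_n, file.path(d, "rdf.dat"))
    }
    if (verbose)
      message(sprintf("iter %3d  f_target = %.6e  mean T = %.1f K", n, f_n,
                      iters[[n + 1L]]$mean_T))
    if (f_n <= config$f_tol || n == config$max_iters) break
    U_n <- ibi_update(U_n, g_n, g_target, T, config)
  }
  best <- which.min(f_hist)
  fit <- structure(list(
    potential = iters[[best]]$U, rdf = iters[[best]]$g,
    best_iter = best - 1L, f_history = f_hist, iterations = iters,
    g_target = g_target, config = config,
    system_template = system_template, initial_U = initial_U,
    converged = f_hist[length(f_hist)] <= config$f_tol ||
      min(f_hist) <= config$f_tol,
    out_dir = out_dir), class = "ibi_fit")
  if (!is.null(out_dir)) write_manifest(fit, out_dir)
  fit
}

#' @export
print.ibi_fit <- function(x, ...) {
  cat("Iterative Boltzmann Inversion fit\n")
  cat(sprintf("  iterations run : %d (cap %d)\n", length(x$f_history),
              x$config$max_iters + 1L))
  cat(sprintf("  best iteration : %d with f_target = %.6e\n",
              x$best_iter, x$f_history[x$best_iter + 1L]))
  cat(sprintf("  converged      : %s (f_tol = %g)\n",
              if (x$converged) "yes" else "no", x$config$f_tol))
  invisible(x)
}

#' @export
summary.ibi_fit <- function(object, ...) {
  g <- tab_grid(object$potential)
  well <- which.min(object$potential$U)
  out <- list(
    n_iter = length(object$f_history), best_iter = object$best_iter,
    f_best = min(object$f_history), f_initial = object$f_history[1],
    converged = object$converged, well_depth = object$potential$U[well],
    well_position = g[well],
    max_abs_residual = max(abs(stats::residuals(object))))
  class(out) <- "summary.ibi_fit"
  out
}

#' @export
print.summary.ibi_fit <- function(x, ...) {
  cat("IBI fit summary\n")
  cat(sprintf("  iterations: %d, best: %d, converged: %s\n", x$n_iter,
              x$best_iter, if (x$converged) "yes" else "no"))
  cat(sprintf("  f_target: initial %.4e -> best %.4e\n", x$f_initial, x$f_best))
  cat(sprintf("  fitted well: %.3f kJ/mol at r = %.3f nm\n",
              x$well_depth, x$well_position))
  cat(sprintf("  max |g - g_target|: %.4f\n", x$max_abs_residual))
  invisible(x)
}

#' Fitted potential table as a data frame
#' @param object an `ibi_fit`.
#' @param ... unused.
#' @return data.frame with columns `r`, `U` (kJ/mol), `F` (kJ/(mol nm)).
#' @export
coef.ibi_fit <- function(object, ...) {
  data.frame(r = tab_grid(object$potential), U = object$potential$U,
             F = object$potential$F)
}

#' @export
fitted.ibi_fit <- function(object, ...) object$rdf$values

#' RDF residuals of the best iteration
#' @param object an `ibi_fit`.
#' @param ... unused.
#' @return numeric vector `g_best - g_target` on the common grid.
#' @export
residuals.ibi_fit <- function(object, ...) {
  object$rdf$values - object$g_target$values
}

#' Evaluate the fitted potential, force or RDF at new separations
#'
#' @param object an `ibi_fit`.
#' @param r separations (nm); defaults to the fit grid.
#' @param what `"potential"` (kJ/mol), `"force"` (kJ/(mol nm)) or
#'   `"rdf"`.
#' @param ... unused.
#' @return numeric vector of interpolated values.
#' @export
predict.ibi_fit <- function(object, r = NULL,
                            what = c("potential", "force", "rdf"), ...) {
  what <- match.arg(what)
  if (is.null(r)) r <- tab_grid(object$potential)
  src <- switch(what,
    potential = list(x = tab_grid(object$potential), y = object$potential$U),
    force     = list(x = tab_grid(object$potential), y = object$potential$F),
    rdf       = list(x = tab_grid(object$rdf), y = object$rdf$values))
  stats::approx(src$x, src$y, xout = r, rule = 2)$y
}

#' Plot an IBI fit
#'
#' Three base-graphics panels: measured vs target RDF at the best
#' iteration, initial (PMF) vs fitted potential, and the f_target
#' history on a log scale.
#'
#' @param x an `ibi_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ibi_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  r <- tab_grid(x$g_target)
  graphics::plot(r, x$g_target$values, type = "l", lwd = 2, xlab = "r (nm)",
                 ylab = "g(r)", main = "RDF", ...)
  graphics::lines(tab_grid(x$rdf), x$rdf$values, col = 2, lty = 2, lwd = 2)
  graphics::legend("topright", c("target", "best iterate"), col = c(1, 2),
                   lty = c(1, 2), bty = "n")
  rp <- tab_grid(x$potential)
  ok <- x$initial_U$U < 5 * max(abs(x$potential$U[x$potential$U < 0]), 1)
  graphics::plot(rp[ok], x$initial_U$U[ok], type = "l", lwd = 2,
                 xlab = "r (nm)", ylab = "U (kJ/mol)", main = "Potential")
  graphics::lines(rp, x$potential$U, col = 2, lty = 2, lwd = 2)
  graphics::legend("bottomright", c("initial (PMF)", "fitted"),
                   col = c(1, 2), lty = c(1, 2), bty = "n")
  graphics::plot(seq_along(x$f_history) - 1L, x$f_history, log = "y",
                 type = "b", pch = 16, xlab = "iteration",
                 ylab = "f_target", main = "Convergence")
  graphics::abline(h = x$config$f_tol, lty = 3)
  invisible(x)
}

#' Simulate from a fitted IBI potential
#'
#' Runs coarse-grained NVT molecular dynamics with the best-iteration
#' potential installed in the fit's system template.
#'
#' @param object an `ibi_fit`.
#' @param nsim number of independent runs (seeds `seed`, `seed+1`, ...).
#' @param seed base RNG seed (default the fit's `base_seed`).
#' @param n_steps steps per run; default the fit's per-iteration count.
#' @param ... unused.
#' @return a [run_nvt()] result for `nsim = 1`, else a list of them.
#' @export
simulate.ibi_fit <- function(object, nsim = 1, seed = NULL, n_steps = NULL,
                             ...) {
  cfg <- object$config$sim
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(n_steps)) cfg$n_steps <- as.integer(n_steps)
  key <- pair_key(object$config$iterate_pair[1], object$config$iterate_pair[2])
  sys <- object$system_template
  sys$nonbonded[[key]] <- object$potential
  runs <- lapply(seq_len(nsim), function(i) {
    ci <- cfg
    ci$seed <- cfg$seed + i - 1L
    run_nvt(sys, ci)
  })
  if (nsim == 1) runs[[1]] else runs
}
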