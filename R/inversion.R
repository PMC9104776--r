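#' Tabulated potential with force column
#'
#' A uniform-grid potential `U` (kJ/mol) with its force column
#' `F = -dU/dx` (built by central differences when not supplied).
#' Non-bonded tables are truncated and shifted at `r_cut`
#' (`U(r_cut) = 0`, `F(r_cut) = 0`, both identically zero beyond);
#' bonded tables have no cutoff (`r_cut = NA`). `r_core` marks the
#' boundary below which the repulsive wall was linearly extrapolated
#' from the innermost sampled region.
#'
#' @param x0,dx uniform grid as in [tab_fn()].
#' @param U energy values, kJ/mol.
#' @param F force values, kJ/(mol nm) (or per degree for angle tables);
#'   rebuilt from `U` when `NULL`.
#' @param r_core wall-extrapolation boundary (or `NA`).
#' @param r_cut truncation radius (or `NA` for bonded tables).
#' @return An object of class `potential_table`.
#' @export
potential_table <- function(x0, dx, U, F = NULL, r_core = NA_real_,
                            r_cut = NA_real_) {
  if (!(dx > 0)) stop("dx must be > 0")
  U <- as.numeric(U)
  if (any(!is.finite(U))) stop("U must be finite on its grid")
  pt <- structure(list(x0 = x0, dx = dx, U = U, F = NULL, values = U,
                       kind = "potential", r_core = r_core, r_cut = r_cut),
                  class = c("potential_table", "tab_fn"))
  if (is.null(F)) pt <- force_from_potential(pt) else pt$F <- as.numeric(F)
  pt
}

#' @export
print.potential_table <- function(x, ...) {
  g <- tab_grid(x)
  cat(sprintf(
    "<potential_table: %d points on [%.4g, %.4g] (dx = %.4g), r_cut = %s>\n",
    length(x$U), g[1], g[length(g)], x$dx,
    if (is.na(x$r_cut)) "none" else format(x$r_cut)))
  cat(sprintf("  min U = %.4g kJ/mol at x = %.4g\n",
              min(x$U), g[which.min(x$U)]))
  invisible(x)
}

#' @export
as.data.frame.potential_table <- function(x, ...) {
  data.frame(x = tab_grid(x), U = x$U, F = x$F)
}

#' Rebuild the force column of a potential table
#'
#' Central differences `F_i = -(U_{i+1} - U_{i-1})/(2 dx)` on interior
#' points, one-sided differences at the edges. When the table has a
#' cutoff, `F` is zeroed at and beyond it.
#'
#' @param pt a [potential_table()].
#' @return the table with `F` refilled.
#' @export
force_from_potential <- function(pt) {
  stopifnot(inherits(pt, "potential_table"))
  U <- pt$U
  n <- length(U)
  if (n < 3L) stop("need at least 3 points to differentiate")
  F <- numeric(n)
  F[2:(n - 1)] <- -(U[3:n] - U[1:(n - 2)]) / (2 * pt$dx)
  F[1] <- -(U[2] - U[1]) / pt$dx
  F[n] <- -(U[n] - U[n - 1]) / pt$dx
  if (!is.na(pt$r_cut)) F[tab_grid(pt) >= pt$r_cut - 1e-12] <- 0
  pt$F <- F
  pt
}

# Boltzmann inversion shared by the pair/bond/angle variants:
# U = -kT ln P where P > floor; interior gaps interpolated; unsampled
# flanks extended linearly from the two nearest sampled points.
invert_distribution <- function(x, p, kT, g_floor) {
  valid <- which(p > g_floor)
  if (length(valid) == 0L) stop("distribution is zero everywhere: nothing to invert")
  if (length(valid) < 2L) stop("need at least two sampled bins to invert")
  Uv <- -kT * log(p[valid])
  U <- stats::approx(x[valid], Uv, xout = x, rule = 2)$y
  v1 <- valid[1L]; v2 <- valid[2L]
  if (v1 > 1L) {
    slope <- (U[v2] - U[v1]) / (x[v2] - x[v1])
    if (slope >= 0) slope <- -100 * kT  # degenerate inner edge: force a wall
    U[1:(v1 - 1L)] <- U[v1] + slope * (x[1:(v1 - 1L)] - x[v1])
  }
  vn <- valid[length(valid)]; vm <- valid[length(valid) - 1L]
  if (vn < length(x)) {
    slope <- (U[vn] - U[vm]) / (x[vn] - x[vm])
    U[(vn + 1L):length(x)] <- U[vn] + slope * (x[(vn + 1L):length(x)] - x[vn])
  }
  list(U = U, r_core = x[v1])
}

#' Potential of mean force from a radial distribution function
#'
#' `U_PMF(r) = -kB T ln g(r)` where `g > g_floor`. The unsampled core
#' (`g <= g_floor`) is filled by linear extrapolation of the innermost
#' sampled slope, giving a repulsive wall. The result is truncated and
#' shifted so `U(r_cut) = 0` and is identically zero beyond the cutoff.
#'
#' @param g a [tab_fn()] of kind `"rdf"`.
#' @param T temperature (K).
#' @param r_cut cutoff radius (nm), inside the table range.
#' @param g_floor bins at or below this value count as unsampled.
#' @return A [potential_table()] on the same grid as `g`.
#' @export
pmf_from_rdf <- function(g, T, r_cut = 1.0, g_floor = 1e-6) {
  stopifnot(inherits(g, "tab_fn"))
  if (g$kind != "rdf") stop("pmf_from_rdf expects an rdf table")
  x <- tab_grid(g)
  if (r_cut > x[length(x)] + g$dx / 2 || r_cut <= x[1])
    stop("r_cut must lie within the table range")
  kT <- thermal_energy(T)
  inv <- invert_distribution(x, g$values, kT, g_floor)
  U <- inv$U
  U <- U - stats::approx(x, U, xout = r_cut, rule = 2)$y
  U[x >= r_cut - 1e-12] <- 0
  potential_table(g$x0, g$dx, U, r_core = inv$r_core, r_cut = r_cut)
}

#' Bond potential from a bond-length distribution
#'
#' `U_Bond(l) = -kB T ln P(l)`, no Jacobian correction, no cutoff;
#' the minimum of `U` is shifted to zero. Extracted once and never
#' iterated.
#'
#' @param P a [tab_fn()] of kind `"bond_dist"`.
#' @param T temperature (K).
#' @param g_floor unsampled-bin threshold.
#' @return A [potential_table()] with `r_cut = NA`.
#' @export
potential_from_bond_dist <- function(P, T, g_floor = 1e-6) {
  stopifnot(inherits(P, "tab_fn"))
  if (P$kind != "bond_dist") stop("expects a bond_dist table")
  x <- tab_grid(P)
  inv <- invert_distribution(x, P$values, thermal_energy(T), g_floor)
  potential_table(P$x0, P$dx, inv$U - min(inv$U), r_core = inv$r_core)
}

#' Angle potential from an angle distribution
#'
#' `U_Angle(theta) = -kB T ln P(theta)` on the degree grid, no Jacobian
#' correction; minimum shifted to zero.
#'
#' @param P a [tab_fn()] of kind `"angle_dist"`.
#' @param T temperature (K).
#' @param g_floor unsampled-bin threshold.
#' @return A [potential_table()] with `r_cut = NA` (x in degrees).
#' @export
potential_from_angle_dist <- function(P, T, g_floor = 1e-6) {
  stopifnot(inherits(P, "tab_fn"))
  if (P$kind != "angle_dist") stop("expects an angle_dist table")
  x <- tab_grid(P)
  inv <- invert_distribution(x, P$values, thermal_energy(T), g_floor)
  potential_table(P$x0, P$dx, inv$U - min(inv$U), r_core = inv$r_core)
}
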