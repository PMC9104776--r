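#' Uniform-grid tabulated function
#'
#' The common container for every tabulated quantity in the package:
#' radial distribution functions, bond-length and angle distributions,
#' potentials and forces. The grid is uniform: `x_i = x0 + (i-1)*dx`.
#' For histogram-derived kinds the grid points are bin midpoints.
#'
#' @param x0 first grid point.
#' @param dx grid spacing, > 0.
#' @param values numeric vector of function values on the grid.
#' @param kind one of `"rdf"`, `"bond_dist"`, `"angle_dist"`,
#'   `"potential"`, `"force"`.
#' @return An object of class `tab_fn`.
#' @export
tab_fn <- function(x0, dx, values, kind = c("rdf", "bond_dist", "angle_dist",
                                            "potential", "force")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(x0), length(x0) == 1L, is.numeric(dx), length(dx) == 1L)
  if (!(dx > 0)) stop("dx must be > 0")
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a tabulated function needs at least 2 points")
  if (kind %in% c("rdf", "bond_dist", "angle_dist")) {
    if (any(!is.finite(values))) stop("distribution values must be finite")
    if (any(values < 0)) stop("distribution values must be >= 0")
  }
  structure(list(x0 = x0, dx = dx, values = values, kind = kind),
            class = "tab_fn")
}

#' Grid of a tabulated function
#' @param f a `tab_fn` or `potential_table`.
#' @return numeric vector of grid points.
#' @export
tab_grid <- function(f) f$x0 + (seq_along(f$values) - 1L) * f$dx

#' Linear interpolation on a tabulated function
#'
#' Values are clamped to the first/last table value outside the grid.
#'
#' @param f a `tab_fn`.
#' @param x points at which to evaluate.
#' @return numeric vector of interpolated values.
#' @export
tab_interp <- function(f, x) {
  g <- tab_grid(f)
  stats::approx(g, f$values, xout = x, rule = 2)$y
}

#' @export
as.data.frame.tab_fn <- function(x, ...) {
  data.frame(x = tab_grid(x), value = x$values)
}

#' @export
print.tab_fn <- function(x, ...) {
  g <- tab_grid(x)
  cat(sprintf("<tab_fn: %s>  %d points on [%.4g, %.4g], dx = %.4g\n",
              x$kind, length(x$values), g[1], g[length(g)], x$dx))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$values) == length(b$values) &&
    abs(a$x0 - b$x0) < tol && abs(a$dx - b$dx) < tol
}

#' Trapezoidal integral of a tabulated function
#' @param f a `tab_fn`.
#' @return the trapezoidal quadrature of `f` over its grid.
#' @export
tab_integral <- function(f) {
  v <- f$values
  n <- length(v)
  f$dx * (sum(v) - (v[1] + v[n]) / 2)
}

#' Normalize a distribution table to unit trapezoidal integral
#' @param f a `tab_fn` of a distribution kind.
#' @return the rescaled `tab_fn`.
#' @export
tab_normalize <- function(f) {
  tot <- tab_integral(f)
  if (tot <= 0) stop("cannot normalize: non-positive integral")
  f$values <- f$values / tot
  f
}

#' Smooth a tabulated function
#'
#' Centered moving-average smoothing with a shrinking window near the
#' edges, so the endpoint values are preserved exactly. Distribution
#' kinds are clamped at zero after smoothing.
#'
#' @param f a `tab_fn`.
#' @param method `"ma"` (moving average) or `"none"`.
#' @param window odd integer window width (points), `<= length(f$values)`.
#' @return the smoothed `tab_fn` on the same grid.
#' @export
smooth_table <- function(f, method = c("ma", "none"), window = 5L) {
  method <- match.arg(method)
  if (method == "none") return(f)
  n <- length(f$values)
  window <- as.integer(window)
  if (window < 1L || window > n) stop("window must be in [1, length(values)]")
  if (window %% 2L == 0L) stop("window must be odd")
  hw <- (window - 1L) %/% 2L
  v <- f$values
  out <- v
  for (i in seq_len(n)) {
    h <- min(hw, i - 1L, n - i)
    out[i] <- mean(v[(i - h):(i + h)])
  }
  if (f$kind %in% c("rdf", "bond_dist", "angle_dist")) out <- pmax(out, 0)
  f$values <- out
  f
}
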