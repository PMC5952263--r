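#' Parametric transform chains mapping fixed-frame points to moving-frame points
#'
#' A `transform_chain` is an ordered list of component transforms; applying
#' the chain to a point applies the components in list order (the first
#' component acts first). An empty chain is the identity. Components are
#' built with [translation_transform()], [rigid_transform()],
#' [affine_transform()], [bspline_transform()] or [couch_shift_transform()].
#'
#' @param ... component transforms (or a single list of them).
#' @param fixed_frame,moving_frame optional frame labels.
#' @return An object of class `transform_chain`.
#' @export
transform_chain <- function(..., fixed_frame = NULL, moving_frame = NULL) {
  stages <- list(...)
  if (length(stages) == 1 && is.list(stages[[1]]) &&
      (length(stages[[1]]) == 0 || !is.null(stages[[1]][[1]]$kind)) &&
      is.null(stages[[1]]$kind))
    stages <- stages[[1]]
  for (s in stages)
    if (is.null(s$kind)) stop("chain components must be transform stages")
  structure(stages, class = "transform_chain",
            fixed_frame = fixed_frame, moving_frame = moving_frame)
}

#' @export
print.transform_chain <- function(x, ...) {
  if (length(x) == 0) {
    cat("transform_chain: identity (no stages)\n")
    return(invisible(x))
  }
  cat(sprintf("transform_chain with %d stage(s): %s\n", length(x),
              paste(vapply(x, `[[`, "", "kind"), collapse = " -> ")))
  invisible(x)
}

is_transform_chain <- function(x) inherits(x, "transform_chain")

as_chain <- function(x) {
  if (is_transform_chain(x)) x
  else if (is.list(x) && !is.null(x$kind)) transform_chain(list(x))
  else stop("expected a transform_chain or a single transform stage")
}

#' Component transform constructors
#'
#' * `translation_transform(t)`: pure translation by `t` mm.
#' * `couch_shift_transform(shift)`: a translation recorded as a
#'   radiographer couch shift (same mapping as a translation; the kind is
#'   kept so pipelines can report it separately).
#' * `rigid_transform(angles, translation, center)`: rotation by Euler
#'   angles (radians, applied as Rz Ry Rx) about `center`, then translation.
#' * `affine_transform(matrix, translation, center)`: `A (p - c) + c + t`.
#' * `bspline_transform(grid_origin, grid_spacing, grid_dim, coefficients)`:
#'   cubic B-spline free-form deformation; `coefficients` is an array
#'   `grid_dim x 3` (or its flattened vector) of control-point displacements
#'   in mm. Points beyond the control lattice get identity displacement.
#'
#' @param t,shift,translation length-3 displacement (mm).
#' @param angles length-3 Euler angles (radians).
#' @param center rotation centre (mm).
#' @param matrix 3 x 3 linear part.
#' @param grid_origin mm position of control point (0,0,0).
#' @param grid_spacing control-point spacing (mm), scalar or length-3.
#' @param grid_dim integer length-3 control-grid dimensions.
#' @param coefficients control-point displacement coefficients.
#' @return A transform stage usable in [transform_chain()].
#' @name transform_stages
NULL

#' @rdname transform_stages
#' @export
translation_transform <- function(t) {
  list(kind = "translation", params = as.numeric(t))
}

#' @rdname transform_stages
#' @export
couch_shift_transform <- function(shift) {
  stage <- list(kind = "couch_shift", params = as.numeric(shift))
  transform_chain(list(stage))
}

#' @rdname transform_stages
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  list(kind = "rigid", params = c(as.numeric(angles), as.numeric(translation)),
       center = as.numeric(center))
}

#' @rdname transform_stages
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  list(kind = "affine", params = c(as.numeric(matrix), as.numeric(translation)),
       center = as.numeric(center))
}

#' @rdname transform_stages
#' @export
bspline_transform <- function(grid_origin, grid_spacing, grid_dim,
                              coefficients = NULL) {
  grid_dim <- as.integer(grid_dim)
  if (length(grid_spacing) == 1) grid_spacing <- rep(grid_spacing, 3)
  ncoef <- prod(grid_dim) * 3
  if (is.null(coefficients)) coefficients <- numeric(ncoef)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != ncoef)
    stop("coefficients must have length prod(grid_dim) * 3")
  list(kind = "bspline", params = coefficients,
       grid_origin = as.numeric(grid_origin),
       grid_spacing = as.numeric(grid_spacing),
       grid_dim = grid_dim)
}

#' Map mm points through a transform chain
#'
#' Applies the exact composition of the chain's stages. The identity chain
#' returns points unchanged. Points beyond a B-spline stage's control
#' lattice are extended with identity displacement.
#'
#' @param chain a [transform_chain] (or a single stage).
#' @param p n x 3 matrix or length-3 vector of mm points.
#' @return n x 3 matrix of mapped points.
#' @export
transform_point <- function(chain, p) {
  chain <- as_chain(chain)
  p <- to_point_matrix(p)
  if (any(!is.finite(p))) stop("points must be finite")
  if (length(chain) == 0) return(p)
  cpp_apply_chain(p, unclass(chain))
}

#' Concatenate two transform chains
#'
#' The result applies `a` first, then `b`:
#' `transform_point(compose_chains(a, b), p) == transform_point(b,
#' transform_point(a, p))`.
#'
#' @param a,b transform chains.
#' @return A [transform_chain].
#' @export
compose_chains <- function(a, b) {
  a <- as_chain(a); b <- as_chain(b)
  transform_chain(c(unclass(a), unclass(b)),
                  fixed_frame = attr(a, "fixed_frame"),
                  moving_frame = attr(b, "moving_frame"))
}

#' Numerically invert a chain at given points
#'
#' Solves `chain(x) = y` for each row of `y` by fixed-point iteration,
#' which converges for the small, smooth deformations this package deals
#' with. Residuals above `tol` are reported via a warning.
#'
#' @param chain a [transform_chain].
#' @param y n x 3 matrix of moving-frame points.
#' @param max_iter,tol iteration controls.
#' @return n x 3 matrix x with `chain(x)` approximately `y`.
#' @export
invert_chain_points <- function(chain, y, max_iter = 50, tol = 1e-9) {
  chain <- as_chain(chain)
  y <- to_point_matrix(y)
  if (length(chain) == 0) return(y)
  res <- cpp_invert_chain(y, unclass(chain), as.integer(max_iter), tol)
  bad <- sum(res$residual > max(tol, 1e-6))
  if (bad > 0)
    warning(bad, " point(s) did not reach the inversion tolerance")
  res$points
}

#' Serialise a transform chain to structured text (JSON) and back
#'
#' The representation records each stage's kind, parameter vector and (for
#' B-splines) control-grid geometry; round trips are exact.
#'
#' @param chain a [transform_chain].
#' @param path file path.
#' @return `read_transform` returns a [transform_chain].
#' @export
write_transform <- function(chain, path) {
  chain <- as_chain(chain)
  payload <- list(
    format = "corddose-transform-1",
    fixed_frame = attr(chain, "fixed_frame"),
    moving_frame = attr(chain, "moving_frame"),
    stages = lapply(unclass(chain), function(s) {
      s$params <- as.numeric(s$params)
      s
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  if (!identical(payload$format, "corddose-transform-1"))
    stop("not a corddose transform file")
  stages <- lapply(payload$stages, function(s) {
    s$params <- as.numeric(s$params)
    if (!is.null(s$grid_dim)) s$grid_dim <- as.integer(s$grid_dim)
    if (!is.null(s$center)) s$center <- as.numeric(s$center)
    if (!is.null(s$grid_origin)) s$grid_origin <- as.numeric(s$grid_origin)
    if (!is.null(s$grid_spacing)) s$grid_spacing <- as.numeric(s$grid_spacing)
    s
  })
  transform_chain(stages, fixed_frame = payload$fixed_frame,
                  moving_frame = payload$moving_frame)
}

# Control grid that covers [lo, hi] (3-vectors, mm) with cubic support,
# plus a margin of one spacing on each side.
bspline_grid_covering <- function(lo, hi, spacing) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  origin <- lo - 2 * spacing
  dim <- as.integer(ceiling((hi - lo) / spacing) + 5L)
  list(origin = origin, spacing = spacing, dim = dim)
}
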