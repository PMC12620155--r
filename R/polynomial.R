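# Spatial polynomial basis for the smooth per-timepoint phase-error model.

#' Build a 2D polynomial phase basis
#'
#' Constructs the design matrix A whose columns are the monomials
#' x^px * y^py with px + py <= order, evaluated at pixel centers on
#' coordinates normalized to [-1, 1] per axis. The normalization keeps the
#' joint optimization well conditioned; any full-rank reparameterization of
#' the basis yields identical fitted phase fields.
#'
#' @param grid_shape Integer length-2: rows, cols (both > 0).
#' @param order Polynomial order >= 0. Order 2 (6 terms) is the default
#'   used by the reconstruction.
#' @return An object of class `poly_basis`: list with `order`, `design`
#'   (num_voxels x num_terms, column-major voxel order, column 1 = constant),
#'   `exponents` (num_terms x 2 matrix of (px, py)), `grid_shape`.
#' @export
build_basis <- function(grid_shape, order = 2L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop_validation("grid_shape must be two positive integers")
  order <- as.integer(order)
  if (length(order) != 1L || order < 0L)
    stop_validation("order must be a single integer >= 0")
  norm_coord <- function(n) if (n == 1L) 0 else seq(-1, 1, length.out = n)
  x <- norm_coord(grid_shape[1L])                 # along rows
  y <- norm_coord(grid_shape[2L])                 # along cols
  X <- matrix(x, grid_shape[1L], grid_shape[2L])
  Y <- matrix(y, grid_shape[1L], grid_shape[2L], byrow = TRUE)
  expo <- do.call(rbind, lapply(0:order, function(total)
    cbind(px = total - (0:total), py = 0:total)))
  design <- vapply(seq_len(nrow(expo)), function(k)
    as.vector(X^expo[k, 1L] * Y^expo[k, 2L]),
    numeric(prod(grid_shape)))
  structure(list(order = order, design = design, exponents = expo,
                 grid_shape = grid_shape),
            class = "poly_basis")
}

#' Number of polynomial terms
#' @param basis A `poly_basis`.
#' @return Integer: (order+1)(order+2)/2.
#' @export
n_terms <- function(basis) ncol(basis$design)

#' Evaluate a smooth phase field from polynomial coefficients
#'
#' Returns `design %*% coefficients` reshaped to the grid; linear in the
#' coefficients.
#'
#' @param basis A `poly_basis` from [build_basis()].
#' @param coefficients Numeric vector, length = number of terms; radians.
#' @return Matrix (rows x cols) of phase in radians.
#' @export
eval_phase <- function(basis, coefficients) {
  stopifnot(inherits(basis, "poly_basis"))
  if (length(coefficients) != ncol(basis$design))
    stop_validation("coefficient length (", length(coefficients),
                    ") does not match basis terms (", ncol(basis$design), ")")
  matrix(basis$design %*% coefficients,
         basis$grid_shape[1L], basis$grid_shape[2L])
}

# Least-squares projection of a voxel-vector field onto the basis span.
# Returns the coefficient vector.
project_coeffs <- function(basis, field_vec) {
  qr.coef(qr(basis$design), field_vec)
}
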