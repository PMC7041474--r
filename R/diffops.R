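#' Discrete differential operators for the TGV discretization
#'
#' Forward-difference gradient and symmetrized derivative on the voxel grid
#' (unit grid spacing, zero difference at the trailing plane of each axis),
#' together with the divergences realizing their exact negative adjoints:
#' `<grad p, v> = -<p, div_vec v>` and `<symgrad v, w>_W = -<v, div_tens w>`,
#' where the `W` inner product double-counts the off-diagonal tensor slots so
#' that pointwise magnitudes are Frobenius norms of symmetric 3x3 matrices.
#'
#' Vector fields are arrays of shape `(Nx, Ny, Nz, 3)` with components
#' ordered `(x, y, z)`; symmetric tensor fields have shape `(Nx, Ny, Nz, 6)`
#' with components `(xx, yy, zz, xy, xz, yz)`.
#'
#' @param p scalar field, 3D array.
#' @param v vector field, 4D array with 3 components.
#' @param w symmetric tensor field, 4D array with 6 components.
#' @return `grad3()` a vector field; `symgrad3()` a tensor field;
#'   `div_vec3()` a scalar field; `div_tens3()` a vector field.
#' @examples
#' p <- array(rnorm(4 * 4 * 2), dim = c(4, 4, 2))
#' g <- grad3(p)
#' dim(g)
#' @name diffops
NULL

#' @rdname diffops
#' @export
grad3 <- function(p) {
  d <- dim(p)
  stopifnot(length(d) == 3L)
  array(.cpp_grad(as.double(p), d[1], d[2], d[3]), dim = c(d, 3L))
}

#' @rdname diffops
#' @export
symgrad3 <- function(v) {
  d <- dim(v)
  stopifnot(length(d) == 4L, d[4] == 3L)
  array(.cpp_symgrad(as.double(v), d[1], d[2], d[3]), dim = c(d[1:3], 6L))
}

#' @rdname diffops
#' @export
div_vec3 <- function(v) {
  d <- dim(v)
  stopifnot(length(d) == 4L, d[4] == 3L)
  array(.cpp_div_vec(as.double(v), d[1], d[2], d[3]), dim = d[1:3])
}

#' @rdname diffops
#' @export
div_tens3 <- function(w) {
  d <- dim(w)
  stopifnot(length(d) == 4L, d[4] == 6L)
  array(.cpp_div_tens(as.double(w), d[1], d[2], d[3]), dim = c(d[1:3], 3L))
}

# inner products with the W convention (off-diagonals doubled)
dot_vec <- function(a, b) sum(a * b)
dot_tens <- function(a, b) {
  n <- prod(dim(a)[1:3])
  av <- as.double(a); bv <- as.double(b)
  sum(av[seq_len(3 * n)] * bv[seq_len(3 * n)]) +
    2 * sum(av[3 * n + seq_len(3 * n)] * bv[3 * n + seq_len(3 * n)])
}
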