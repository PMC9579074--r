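#' Half-vectorization utilities
#'
#' All asymptotic matrices in the package (`gamma_adf()`,
#' `normal_theory_weight()`, `delta_jacobian()`, `residual_u()`) live in a
#' single shared basis: the lower triangle of a symmetric \eqn{p \times p}
#' matrix stacked column-major ("vech"). These helpers are the one source of
#' truth for that ordering.
#'
#' @param p number of observed variables.
#' @return `vech_index(p)` returns a two-column integer matrix with the (row,
#'   column) subscripts of the \eqn{p^* = p(p+1)/2} vech elements, in order.
#' @keywords internal
vech_index <- function(p) {
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  # which() on a matrix is column-major already; enforce ordering explicitly
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

#' @param m symmetric matrix.
#' @rdname vech_index
#' @keywords internal
vech <- function(m) m[lower.tri(m, diag = TRUE)]

#' @param v vector of length p(p+1)/2.
#' @rdname vech_index
#' @keywords internal
unvech <- function(v, p) {
  m <- matrix(0, p, p)
  m[lower.tri(m, diag = TRUE)] <- v
  m + t(m) - diag(diag(m))
}
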