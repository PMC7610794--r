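# Vectorised operations on fields of 3x3 matrices.
#
# A field of N matrices is stored as an N x 9 numeric matrix with columns in
# row-major order: (1,1),(1,2),(1,3),(2,1),...,(3,3). All ops below are
# elementwise over rows, so a quarter-million Jacobians cost a handful of
# vectorised arithmetic passes rather than an R-level loop.

m3col <- function(i, j) 3L * (i - 1L) + j

m3_identity <- function(n) {
  out <- matrix(0, n, 9L)
  out[, c(1L, 5L, 9L)] <- 1
  out
}

m3_det <- function(A) {
  A[, 1] * (A[, 5] * A[, 9] - A[, 6] * A[, 8]) -
  A[, 2] * (A[, 4] * A[, 9] - A[, 6] * A[, 7]) +
  A[, 3] * (A[, 4] * A[, 8] - A[, 5] * A[, 7])
}

# Adjugate: adj(A) = det(A) * inv(A); cofactor matrix transposed.
m3_adjugate <- function(A) {
  cbind(A[, 5] * A[, 9] - A[, 6] * A[, 8],
        A[, 3] * A[, 8] - A[, 2] * A[, 9],
        A[, 2] * A[, 6] - A[, 3] * A[, 5],
        A[, 6] * A[, 7] - A[, 4] * A[, 9],
        A[, 1] * A[, 9] - A[, 3] * A[, 7],
        A[, 3] * A[, 4] - A[, 1] * A[, 6],
        A[, 4] * A[, 8] - A[, 5] * A[, 7],
        A[, 2] * A[, 7] - A[, 1] * A[, 8],
        A[, 1] * A[, 5] - A[, 2] * A[, 4])
}

m3_inverse <- function(A, det = NULL) {
  if (is.null(det)) det <- m3_det(A)
  m3_adjugate(A) / det
}

m3_transpose <- function(A) A[, c(1L, 4L, 7L, 2L, 5L, 8L, 3L, 6L, 9L), drop = FALSE]

m3_mult <- function(A, B) {
  out <- matrix(0, nrow(A), 9L)
  for (i in 1:3) for (j in 1:3) {
    acc <- 0
    for (k in 1:3) acc <- acc + A[, m3col(i, k)] * B[, m3col(k, j)]
    out[, m3col(i, j)] <- acc
  }
  out
}

m3_frob2 <- function(A) rowSums(A * A)

# Eigenvalues of the symmetric matrices A^T A, descending, by the closed-form
# trigonometric solution for symmetric 3x3 eigenproblems. Returns an N x 3
# matrix. Used for singular values: s_i = sqrt(eig_i(A^T A)).
m3_ata_eigvals <- function(A) {
  S <- m3_mult(m3_transpose(A), A)       # symmetric PSD
  a11 <- S[, 1]; a22 <- S[, 5]; a33 <- S[, 9]
  a12 <- S[, 2]; a13 <- S[, 3]; a23 <- S[, 6]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  n <- length(q)
  e <- matrix(q, n, 3L)
  nz <- p > 1e-300 * pmax(abs(q), 1)
  if (any(nz)) {
    B <- (S[nz, , drop = FALSE] - q[nz] * m3_identity(sum(nz))) / p[nz]
    r <- pmin(pmax(m3_det(B) / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[nz] + 2 * p[nz] * cos(phi)
    e3 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    e[nz, 1] <- e1
    e[nz, 3] <- e3
    e[nz, 2] <- 3 * q[nz] - e1 - e3
  }
  e
}

# Singular values of each matrix, descending (>= 0).
m3_singvals <- function(A) sqrt(pmax(m3_ata_eigvals(A), 0))
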