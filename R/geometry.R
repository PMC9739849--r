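# Mass-weighted least-squares (Kabsch) superposition.
# Finds rotation R and translation t minimizing sum_i m_i |R a_i + t - b_i|^2.
# Returns the rotation, translation, weighted rmsd and the determinant sign
# of the unconstrained optimum (-1 means a reflection would fit better).
kabsch_fit <- function(a, b, masses) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("superposition: coordinate dimension mismatch")
  if (length(masses) != nrow(a)) stop("superposition: mass count mismatch")
  w <- masses / sum(masses)
  coma <- colSums(a * w); comb <- colSums(b * w)
  ac <- sweep(a, 2, coma); bc <- sweep(b, 2, comb)
  M <- t(ac * w) %*% bc
  sv <- La.svd(M)           # M = u %*% diag(d) %*% vt
  d <- sign(det(t(sv$vt) %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- t(sv$vt) %*% diag(c(1, 1, d)) %*% t(sv$u)
  resid <- ac %*% t(R) - bc
  rmsd <- sqrt(sum(w * rowSums(resid^2)))
  list(rotation = R, translation = comb - as.vector(R %*% coma),
       rmsd = rmsd, det_sign = d, com_ref = coma, com_target = comb)
}

# Apply a kabsch_fit to coordinates: rows r -> R r + t
apply_fit <- function(fit, coords) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, -fit$translation)
}

# Orthonormal mass-weighted translation / infinitesimal-rotation vectors
# (Eckart frame), as columns of a 3N x k matrix, k = 6 (5 if linear, 3 for a
# single atom). Coordinates are flattened atom-major (x1 y1 z1 x2 ...).
trans_rot_vectors <- function(geometry, masses) {
  g <- as.matrix(geometry)
  n <- nrow(g)
  m_e <- masses * au_constants$amu_me
  sm <- sqrt(m_e)
  com <- colSums(g * m_e) / sum(m_e)
  gc <- sweep(g, 2, com)
  cols <- list()
  for (a in 1:3) {            # translations
    v <- matrix(0, n, 3); v[, a] <- sm
    cols[[a]] <- as.vector(t(v))
  }
  ex <- diag(3)
  for (a in 1:3) {            # rotations: sqrt(m) * (e_a x (r - com))
    cr <- cbind(ex[a, 2] * gc[, 3] - ex[a, 3] * gc[, 2],
                ex[a, 3] * gc[, 1] - ex[a, 1] * gc[, 3],
                ex[a, 1] * gc[, 2] - ex[a, 2] * gc[, 1]) * sm
    cols[[3 + a]] <- as.vector(t(cr))
  }
  B <- do.call(cbind, cols)
  # Gram-Schmidt, dropping null directions (linear molecule, single atom)
  Q <- NULL
  for (j in seq_len(ncol(B))) {
    v <- B[, j]
    if (!is.null(Q)) v <- v - Q %*% crossprod(Q, v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-10 * sqrt(sum(B[, j]^2) + 1)) Q <- cbind(Q, v / nv)
  }
  Q
}
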