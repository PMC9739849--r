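#' Normal-mode analysis of a Cartesian Hessian
#'
#' Mass-weights the Hessian, projects out the translation and
#' infinitesimal-rotation subspace (Eckart-style explicit projection) and
#' diagonalizes. Roto-translational modes are identified by near-zero
#' eigenvalues of the projected matrix; remaining modes are internal.
#' Negative-curvature internal modes (saddle directions, typical when the
#' Hessian is computed with a cheaper method at a higher-level minimum) carry
#' a negative frequency flag.
#'
#' @param hessian 3N x 3N Cartesian Hessian (Hartree/Bohr^2), atom-major
#'   coordinate order (x1 y1 z1 x2 ...)
#' @param masses per-atom masses (a.m.u.)
#' @param geometry n x 3 coordinates (Bohr) at which the Hessian was taken
#' @param state_label label of the owning electronic state
#' @param zero_tol eigenvalue magnitude (a.u.) below which a projected mode
#'   counts as roto-translational
#' @return object of class `mode_basis`: orthonormal mass-weighted mode
#'   matrix (`vectors`, internal modes sorted by increasing eigenvalue, then
#'   roto-translations), per-mode frequencies `nu` in frequency atomic units
#'   (sign flags curvature), `labels`, raw `eigenvalues`
#' @export
normal_modes <- function(hessian, masses, geometry, state_label = "",
                         zero_tol = 1e-8) {
  H <- as.matrix(hessian)
  n3 <- nrow(H)
  if (ncol(H) != n3 || n3 != 3 * length(masses))
    stop("normal_modes: Hessian dimension does not match atom count")
  if (max(abs(H - t(H))) > 1e-8) stop("normal_modes: non-symmetric Hessian")
  if (any(masses <= 0)) stop("normal_modes: non-positive mass")
  mvec <- rep(masses * au_constants$amu_me, each = 3)
  Fm <- H / sqrt(outer(mvec, mvec))
  TR <- trans_rot_vectors(geometry, masses)
  P <- diag(n3) - TR %*% t(TR)
  Fp <- P %*% Fm %*% P
  Fp <- (Fp + t(Fp)) / 2
  ee <- eigen(Fp, symmetric = TRUE)
  lam <- rev(ee$values)
  vec <- ee$vectors[, rev(seq_len(n3)), drop = FALSE]
  is_tr <- abs(lam) < zero_tol
  if (sum(is_tr) < ncol(TR))
    warning(sprintf(
      "normal_modes: expected %d near-zero eigenvalues, found %d (values: %s)",
      ncol(TR), sum(is_tr),
      paste(signif(lam[order(abs(lam))][seq_len(ncol(TR))], 3), collapse = ", ")))
  ord <- c(which(!is_tr)[order(lam[!is_tr])], which(is_tr))
  lam <- lam[ord]; vec <- vec[, ord, drop = FALSE]
  # deterministic sign: largest-magnitude component positive
  for (j in seq_len(ncol(vec))) {
    k <- which.max(abs(vec[, j]))
    if (vec[k, j] < 0) vec[, j] <- -vec[, j]
  }
  labels <- ifelse(seq_len(n3) > n3 - sum(is_tr), "rototranslation", "internal")
  nu <- ifelse(labels == "rototranslation", 0, eig_to_freq_au(lam))
  structure(list(vectors = vec, nu = nu, labels = labels, eigenvalues = lam,
                 state_label = state_label, masses = as.numeric(masses),
                 geometry = as.matrix(geometry), n_trrot = sum(is_tr)),
            class = "mode_basis")
}

#' @export
print.mode_basis <- function(x, ...) {
  ni <- sum(x$labels != "rototranslation")
  cat(sprintf("Mode basis%s: %d modes (%d internal, %d roto-translational)\n",
              if (nzchar(x$state_label)) paste0(" [", x$state_label, "]") else "",
              length(x$nu), ni, x$n_trrot))
  if (ni > 0) {
    cm1 <- x$nu[x$labels != "rototranslation"] * 2 * pi * au_constants$hartree_cm1
    cat("  internal frequencies (cm^-1):",
        paste(sprintf("%.1f", cm1), collapse = ", "), "\n")
  }
  if (any(x$labels %in% c("quantum", "semiclassical")))
    cat("  partition:", sum(x$labels == "quantum"), "quantum /",
        sum(x$labels == "semiclassical"), "semiclassical\n")
  invisible(x)
}

#' Partition internal modes into quantum and semiclassical at a temperature
#'
#' Internal modes with vibrational quantum h*nu above the thermal energy
#' kB*T are quantum; the rest (including negative-curvature modes) are
#' semiclassical and excluded from the Franck-Condon treatment.
#'
#' @param basis a `mode_basis`
#' @param temperature absolute temperature (K)
#' @return the basis with `labels` set to quantum / semiclassical /
#'   rototranslation
#' @export
classify_modes <- function(basis, temperature) {
  stopifnot(inherits(basis, "mode_basis"), temperature > 0)
  kT <- au_constants$kB * temperature
  hnu <- au_constants$h_au * basis$nu   # photon/vibrational quantum in Eh
  basis$labels <- ifelse(
    basis$labels == "rototranslation", "rototranslation",
    ifelse(hnu > kT, "quantum", "semiclassical"))
  basis$temperature <- temperature
  basis
}

internal_columns <- function(basis) which(basis$labels != "rototranslation")

#' Duschinsky matrix between two mode bases
#'
#' Inner products between the internal (non-roto-translational) mass-weighted
#' mode vectors of two electronic states sharing atoms and masses. For bases
#' spanning the same internal subspace J is orthogonal; near-diagonal J
#' justifies treating modes as shared up to a displaced minimum.
#'
#' @param basis_a,basis_b `mode_basis` objects for the two states
#' @return object of class `mode_match` holding `duschinsky` (J), `J2`, the
#'   internal frequencies and labels of both bases
#' @export
duschinsky <- function(basis_a, basis_b) {
  stopifnot(inherits(basis_a, "mode_basis"), inherits(basis_b, "mode_basis"))
  if (nrow(basis_a$vectors) != nrow(basis_b$vectors))
    stop("duschinsky: dimension mismatch between bases")
  ia <- internal_columns(basis_a); ib <- internal_columns(basis_b)
  J <- t(basis_a$vectors[, ia, drop = FALSE]) %*%
    basis_b$vectors[, ib, drop = FALSE]
  structure(list(duschinsky = J, J2 = J^2,
                 modes_a = ia, modes_b = ib,
                 nu_a = basis_a$nu[ia], nu_b = basis_b$nu[ib],
                 labels_a = basis_a$labels[ia], labels_b = basis_b$labels[ib],
                 state_a = basis_a$state_label, state_b = basis_b$state_label,
                 pairing = NULL),
            class = "mode_match")
}

#' Pair modes across two states by maximal squared Duschinsky elements
#'
#' Solves the assignment problem maximizing the total squared element over
#' pairings (restricted to quantum modes when the bases are classified).
#' Pairs whose squared element falls below `diagonality_threshold` are
#' flagged, not rejected.
#'
#' @param match a `mode_match` from [duschinsky()]
#' @param diagonality_threshold squared-element fraction below which a pair
#'   is flagged
#' @return the match with `pairing` (data.frame mode_a, mode_b, J2, flagged)
#'   and `diagonality_score` (mean paired squared element)
#' @export
match_modes <- function(match, diagonality_threshold = 0.7) {
  stopifnot(inherits(match, "mode_match"))
  qa <- if (any(match$labels_a == "quantum"))
    which(match$labels_a == "quantum") else seq_along(match$labels_a)
  qb <- if (any(match$labels_b == "quantum"))
    which(match$labels_b == "quantum") else seq_along(match$labels_b)
  J2 <- match$J2[qa, qb, drop = FALSE]
  n <- max(nrow(J2), ncol(J2))
  C <- matrix(1, n, n)          # pad rectangular problems with zero overlap
  C[seq_len(nrow(J2)), seq_len(ncol(J2))] <- 1 - J2
  perm <- solve_assignment(C)
  keep <- seq_len(nrow(J2))
  keep <- keep[perm[keep] <= ncol(J2)]
  pair <- data.frame(mode_a = match$modes_a[qa[keep]],
                     mode_b = match$modes_b[qb[perm[keep]]],
                     J2 = J2[cbind(keep, perm[keep])])
  pair$flagged <- pair$J2 < diagonality_threshold
  if (any(pair$flagged))
    warning(sprintf("match_modes: %d pair(s) below diagonality threshold %.2f",
                    sum(pair$flagged), diagonality_threshold))
  match$pairing <- pair
  match$diagonality_score <- mean(pair$J2)
  match$diagonality_threshold <- diagonality_threshold
  match
}

#' @export
print.mode_match <- function(x, ...) {
  cat(sprintf("Duschinsky match %s -> %s: %d x %d internal modes\n",
              x$state_a, x$state_b, nrow(x$J2), ncol(x$J2)))
  if (!is.null(x$pairing))
    cat(sprintf("  %d pairs, mean paired J^2 = %.4f, %d flagged (< %.2f)\n",
                nrow(x$pairing), x$diagonality_score, sum(x$pairing$flagged),
                x$diagonality_threshold))
  invisible(x)
}

#' Per-mode displacements and Huang-Rhys factors between two minima
#'
#' After mass-weighted least-squares superposition of `geom_b` onto
#' `geom_a`, the mass-weighted displacement is projected on each quantum mode
#' of `basis` and converted to the dimensionless normal coordinate
#' (multiplied by sqrt(omega/hbar)); the Huang-Rhys factor is S = delta^2/2.
#'
#' @param geom_a,geom_b n x 3 minimum-energy geometries (Bohr) of the two
#'   electronic states
#' @param basis `mode_basis` whose quantum modes define the projection
#'   (conventionally the final state of the transition)
#' @param masses per-atom masses (a.m.u.)
#' @param rmsd_warn superposition residual (Bohr) above which a warning about
#'   a suspected conformational change is raised
#' @return data.frame with columns mode (column index in `basis`), nu
#'   (frequency a.u.), delta (dimensionless displacement), S; the alignment
#'   rmsd is attached as attribute `rmsd`
#' @export
mode_displacements <- function(geom_a, geom_b, basis, masses,
                               rmsd_warn = 0.5) {
  stopifnot(inherits(basis, "mode_basis"))
  fit <- kabsch_fit(geom_b, geom_a, masses)   # superpose b onto a
  b_al <- apply_fit(fit, geom_b)
  if (fit$rmsd > rmsd_warn)
    warning(sprintf(
      "mode_displacements: alignment rmsd %.3f Bohr above %.3f; conformational change suspected",
      fit$rmsd, rmsd_warn))
  mvec <- rep(masses * au_constants$amu_me, each = 3)
  dmw <- sqrt(mvec) * as.vector(t(b_al - as.matrix(geom_a)))
  idx <- if (any(basis$labels == "quantum")) which(basis$labels == "quantum")
  else which(basis$labels == "internal")
  omega <- au_constants$h_au * basis$nu[idx]    # hbar*omega in Eh; hbar = 1
  dq <- as.vector(crossprod(basis$vectors[, idx, drop = FALSE], dmw))
  delta <- dq * sqrt(pmax(omega, 0))
  out <- data.frame(mode = idx, nu = basis$nu[idx], delta = delta,
                    S = delta^2 / 2)
  attr(out, "rmsd") <- fit$rmsd
  out
}

#' Export a mode table (frequencies and labels, optionally pairing) as TSV
#'
#' @param basis a `mode_basis`
#' @param path output path
#' @return `path`, invisibly
#' @export
export_mode_table <- function(basis, path) {
  stopifnot(inherits(basis, "mode_basis"))
  d <- data.frame(mode = seq_along(basis$nu),
                  nu_au = basis$nu,
                  freq_cm1 = basis$nu * 2 * pi * au_constants$hartree_cm1,
                  label = basis$labels)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
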