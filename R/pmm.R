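#' Electrostatic perturbation of one environment frame
#'
#' Computes the perturbing electric potential at every QC atom and the
#' perturbing electric field at the reference position r0 (the mass-weighted
#' QC centroid) from the environment point charges, under the minimum-image
#' convention when the frame carries a periodic box. An explicit
#' `uniform_field` on the frame adds to the field only (analytic test
#' device).
#'
#' @param frame an `environment_frame`
#' @param masses per-atom QC masses (a.m.u.)
#' @param exclusion_radius charges closer than this (Bohr) to any QC atom
#'   raise an error listing the offenders
#' @param dV state-independent higher-order diagonal term (a.u.); retained
#'   for reporting, cannot affect transition energies
#' @return object of class `pmm_electrostatics` with fields `V` (per-atom
#'   potential, a.u.), `E0` (field 3-vector at r0), `r0`, `dV`
#' @export
perturbation_fields <- function(frame, masses,
                                exclusion_radius = 0.05 / au_constants$bohr_nm,
                                dV = 0) {
  stopifnot(inherits(frame, "environment_frame"))
  qc <- frame$qc_coords
  if (length(masses) != nrow(qc))
    stop("perturbation_fields: mass count != QC atom count")
  m_e <- masses * au_constants$amu_me
  r0 <- colSums(qc * m_e) / sum(m_e)
  nq <- nrow(qc); ne <- nrow(frame$env_coords)
  V <- numeric(nq)
  E0 <- c(0, 0, 0)
  if (ne > 0) {
    q <- frame$env_charges
    offenders <- integer(0)
    for (i in seq_len(nq)) {
      d <- min_image(frame$env_coords - rep(qc[i, ], each = ne), frame$box)
      r <- sqrt(rowSums(d * d))
      offenders <- union(offenders, which(r < exclusion_radius))
      V[i] <- sum(q / r)
    }
    if (length(offenders))
      stop("perturbation_fields: environment charges within exclusion radius of QC: indices ",
           paste(sort(offenders), collapse = ", "))
    d0 <- min_image(sweep(frame$env_coords, 2, r0), frame$box)  # r_e - r0
    r3 <- rowSums(d0 * d0)^1.5
    E0 <- -colSums(d0 * (q / r3))   # sum q (r0 - r_e)/|r0 - r_e|^3
  }
  if (!is.null(frame$uniform_field)) E0 <- E0 + frame$uniform_field
  if (!all(is.finite(V)) || !all(is.finite(E0)))
    stop("perturbation_fields: non-finite electrostatics")
  structure(list(V = V, E0 = E0, r0 = r0, dV = dV),
            class = "pmm_electrostatics")
}

#' Superpose the reference geometry onto frame coordinates
#'
#' Mass-weighted least-squares superposition giving the proper rotation that
#' carries the molecular frame (reference geometry) into the lab frame of
#' the MD snapshot; used to rotate dipole matrix elements.
#'
#' @param ref_geometry n x 3 reference coordinates (Bohr, molecular frame)
#' @param frame_qc_coords n x 3 QC coordinates of the snapshot (Bohr)
#' @param masses per-atom masses (a.m.u.)
#' @return list with `rotation` (3 x 3, det +1), `translation`, `rmsd`
#' @export
align_reference <- function(ref_geometry, frame_qc_coords, masses) {
  fit <- kabsch_fit(ref_geometry, frame_qc_coords, masses)
  if (fit$det_sign < 0)
    stop("align_reference: superposition requires a reflection; chirality mismatch suspected")
  fit[c("rotation", "translation", "rmsd")]
}

#' Build the perturbed electronic Hamiltonian for one frame
#'
#' In the basis of unperturbed electronic eigenstates: diagonal elements are
#' the unperturbed energies plus the charge-potential coupling (QC state
#' charges placed at the frame QC coordinates) plus the state-independent
#' dV; off-diagonal elements couple states through the perturbing field at
#' r0 acting on the (lab-frame-rotated) transition dipoles.
#'
#' @param stateset an `unperturbed_stateset`
#' @param es a `pmm_electrostatics` for the frame
#' @param rotation 3 x 3 molecular-to-lab rotation (default identity)
#' @return real symmetric Hamiltonian matrix (Hartree)
#' @export
build_hamiltonian <- function(stateset, es, rotation = diag(3)) {
  stopifnot(inherits(stateset, "unperturbed_stateset"),
            inherits(es, "pmm_electrostatics"))
  ns <- length(stateset$state_labels)
  if (length(es$V) != ncol(stateset$charges))
    stop("build_hamiltonian: dimension mismatch (atom count)")
  H <- diag(as.vector(stateset$U0 + stateset$charges %*% es$V + es$dV))
  mu_lab <- rotate_dipoles(stateset$dipole_matrix, rotation)
  coup <- -(mu_lab[, , 1] * es$E0[1] + mu_lab[, , 2] * es$E0[2] +
              mu_lab[, , 3] * es$E0[3])
  diag(coup) <- 0
  H <- H + coup
  dimnames(H) <- list(stateset$state_labels, stateset$state_labels)
  (H + t(H)) / 2
}

rotate_dipoles <- function(dip, rotation) {
  ns <- dim(dip)[1]
  flat <- matrix(dip, ns * ns, 3)
  array(flat %*% t(rotation), dim = c(ns, ns, 3))
}

#' Diagonalize a perturbed Hamiltonian and derive per-frame observables
#'
#' Eigenvalues ascending; eigenvector signs fixed so the largest-magnitude
#' component is positive. Transition frequencies nu_i = (E_i - E_0)/h and
#' lab-frame transition dipoles mu_0i = sum_jl c_j0 c_li mu_jl are computed
#' for every excited perturbed state, together with the squared projections
#' on the unperturbed basis.
#'
#' @param H symmetric Hamiltonian from [build_hamiltonian()]
#' @param stateset the `unperturbed_stateset`
#' @param rotation molecular-to-lab rotation used for the dipoles
#' @param degeneracy_tol eigenvalue gap (Hartree) below which states are
#'   flagged degenerate (ordering within the block follows the dominant
#'   unperturbed component)
#' @return object of class `pmm_frame_result` with `energies`,
#'   `eigenvectors`, `projections2`, `trans_freq` (a.u.), `trans_dipole`
#'   (n_excited x 3), `degenerate` flag
#' @export
diagonalize_hamiltonian <- function(H, stateset, rotation = diag(3),
                                    degeneracy_tol = 1e-12) {
  if (max(abs(H - t(H))) > 1e-10) stop("diagonalize: H must be symmetric")
  ns <- nrow(H)
  ee <- eigen(H, symmetric = TRUE)
  vals <- rev(ee$values)
  vecs <- ee$vectors[, rev(seq_len(ns)), drop = FALSE]
  degenerate <- any(diff(vals) < degeneracy_tol)
  if (degenerate) {
    # deterministic ordering within degenerate blocks by dominant component
    blocks <- split(seq_len(ns), cumsum(c(1, diff(vals) >= degeneracy_tol)))
    for (b in blocks) {
      if (length(b) > 1) {
        dom <- apply(abs(vecs[, b, drop = FALSE]), 2, which.max)
        vecs[, b] <- vecs[, b[order(dom)], drop = FALSE]
        vals[b] <- vals[b][order(dom)]
      }
    }
  }
  for (j in seq_len(ns)) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  proj2 <- vecs^2
  dimnames(proj2) <- list(stateset$state_labels, NULL)
  mu_lab <- rotate_dipoles(stateset$dipole_matrix, rotation)
  nex <- ns - 1
  td <- matrix(0, nex, 3)
  c0 <- vecs[, 1]
  for (a in 1:3) {
    tmp <- as.vector(t(c0) %*% mu_lab[, , a] %*% vecs)   # over all states
    td[, a] <- tmp[-1]
  }
  structure(list(energies = vals, eigenvectors = vecs, projections2 = proj2,
                 trans_freq = (vals[-1] - vals[1]) / au_constants$h_au,
                 trans_dipole = td, rotation = rotation,
                 degenerate = degenerate,
                 state_labels = stateset$state_labels),
            class = "pmm_frame_result")
}

#' @export
print.pmm_frame_result <- function(x, ...) {
  cat("Perturbed frame result:", length(x$energies), "states\n")
  for (i in seq_along(x$trans_freq)) {
    cat(sprintf("  excited %d: dE = %.4f eV, |mu|^2 = %.4f a.u.%s\n", i,
                freq_au_to_ev(x$trans_freq[i]), sum(x$trans_dipole[i, ]^2),
                if (!is.null(x$assignment)) paste0(" -> ", x$assignment[i + 1])
                else ""))
  }
  invisible(x)
}

#' Assign perturbed states to unperturbed labels
#'
#' Each perturbed state is labelled by the unperturbed state carrying its
#' largest squared projection when that projection reaches
#' `identity_threshold`; otherwise "mixed". States whose best label is in
#' `dark_labels` become "dark-discard".
#'
#' @param result a `pmm_frame_result`
#' @param identity_threshold minimum squared projection for identification
#' @param dark_labels labels of spectroscopically dark states to discard
#' @return the result with an `assignment` character vector (one entry per
#'   perturbed state)
#' @export
assign_state <- function(result, identity_threshold = 0.8,
                         dark_labels = character()) {
  stopifnot(inherits(result, "pmm_frame_result"))
  p2 <- result$projections2
  lab <- character(ncol(p2))
  for (i in seq_len(ncol(p2))) {
    j <- which.max(p2[, i])
    best <- result$state_labels[j]
    if (best %in% dark_labels) lab[i] <- "dark-discard"
    else if (p2[j, i] >= identity_threshold) lab[i] <- best
    else lab[i] <- "mixed"
  }
  result$assignment <- lab
  result$identity_threshold <- identity_threshold
  result
}
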