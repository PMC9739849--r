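test_that("diatomic normal mode matches the reduced-mass closed form", {
  k <- 0.4; m_amu <- 10
  basis <- normal_modes(diatomic_hessian(k),
                        masses = c(m_amu, m_amu),
                        geometry = rbind(c(0, 0, 0), c(2, 0, 0)))
  internal <- basis$nu[basis$labels == "internal"]
  expect_length(internal, 1)
  expect_equal(basis$n_trrot, 5)  # linear molecule
  omega_expect <- sqrt(2 * k / (m_amu * pmmvib::au_constants$amu_me))
  expect_equal(2 * pi * internal, omega_expect, tolerance = 1e-10)
})

test_that("a single atom yields only roto-translational modes", {
  basis <- normal_modes(matrix(0, 3, 3), masses = 12,
                        geometry = matrix(0, 1, 3))
  expect_true(all(basis$labels == "rototranslation"))
})

test_that("toy Hessian frequencies match a direct dense-eigensolver oracle", {
  ss <- fix_stateset()
  toy <- attr(ss, "toy")
  basis <- normal_modes(ss$hessians[["GS"]], ss$masses, ss$geometries[["GS"]])
  # oracle: direct diagonalization of the projected mass-weighted matrix
  mvec <- rep(ss$masses * au_constants$amu_me, each = 3)
  Fm <- ss$hessians[["GS"]] / sqrt(outer(mvec, mvec))
  TR <- pmmvib:::trans_rot_vectors(ss$geometries[["GS"]], ss$masses)
  P <- diag(nrow(Fm)) - TR %*% t(TR)
  lam <- sort(eigen((P %*% Fm %*% P + t(P %*% Fm %*% P)) / 2,
                    symmetric = TRUE, only.values = TRUE)$values)
  lam_int <- lam[abs(lam) > 1e-8]
  got <- 2 * pi * basis$nu[basis$labels == "internal"]
  expect_equal(got, sqrt(lam_int), tolerance = 1e-10)
  # generator-set quanta are recovered exactly
  expect_equal(sort(got), sort(toy$hw), tolerance = 1e-10)
  # non-symmetric Hessian rejected
  H <- ss$hessians[["GS"]]; H[1, 2] <- H[1, 2] + 1e-3
  expect_error(normal_modes(H, ss$masses, ss$geometries[["GS"]]),
               "non-symmetric")
})

test_that("mode orthonormality and Hessian reconstruction hold", {
  ss <- fix_stateset()
  basis <- normal_modes(ss$hessians[["GS"]], ss$masses, ss$geometries[["GS"]])
  V <- basis$vectors
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
  # reconstruction of the projected mass-weighted Hessian from modes
  mvec <- rep(ss$masses * au_constants$amu_me, each = 3)
  TR <- pmmvib:::trans_rot_vectors(ss$geometries[["GS"]], ss$masses)
  P <- diag(nrow(V)) - TR %*% t(TR)
  Fm <- ss$hessians[["GS"]] / sqrt(outer(mvec, mvec))
  Fp <- P %*% Fm %*% P
  rec <- V %*% (basis$eigenvalues * t(V))
  expect_lt(max(abs(rec - Fp)), 1e-8)
})

test_that("quantum/semiclassical partition follows h*nu vs kB*T", {
  kT <- au_constants$kB * 300
  # diatomic tuned so h*nu = 2 kBT, then 0.5 kBT
  m <- 10
  mk <- function(ratio) {
    omega <- ratio * kT       # hbar*omega = h*nu
    k <- omega^2 * m * au_constants$amu_me / 2
    classify_modes(normal_modes(diatomic_hessian(k), c(m, m),
                                rbind(c(0, 0, 0), c(2, 0, 0))), 300)
  }
  b2 <- mk(2); b05 <- mk(0.5)
  expect_equal(b2$labels[b2$labels != "rototranslation"], "quantum")
  expect_equal(b05$labels[b05$labels != "rototranslation"], "semiclassical")
  # negative-curvature mode is always semiclassical
  bneg <- mk(2)
  bneg$nu[bneg$labels == "quantum"] <- -bneg$nu[bneg$labels == "quantum"]
  bneg$labels[bneg$labels == "quantum"] <- "internal"
  bneg <- classify_modes(bneg, 300)
  expect_equal(bneg$labels[bneg$labels != "rototranslation"], "semiclassical")
})

test_that("Duschinsky matrix is identity for a basis with itself and a
           permutation for permuted columns", {
  ss <- fix_stateset()
  basis <- normal_modes(ss$hessians[["GS"]], ss$masses, ss$geometries[["GS"]])
  m <- duschinsky(basis, basis)
  n <- nrow(m$J2)
  expect_lt(max(abs(m$duschinsky - diag(n))), 1e-10)
  mm <- match_modes(m)
  expect_equal(mm$pairing$mode_a, mm$pairing$mode_b)
  expect_equal(mm$diagonality_score, 1, tolerance = 1e-12)
  # column-permuted copy
  perm <- c(2, 1, seq_len(n)[-(1:2)])
  basis_p <- basis
  ic <- pmmvib:::internal_columns(basis)
  basis_p$vectors[, ic] <- basis$vectors[, ic[perm]]
  basis_p$nu[ic] <- basis$nu[ic[perm]]
  mp <- match_modes(duschinsky(basis, basis_p))
  expect_lt(max(abs(mp$J2 - diag(n)[, perm])), 1e-10)
  expect_equal(mp$pairing$J2, rep(1, n), tolerance = 1e-10)
})

test_that("constructed two-mode rotation gives sin^2 off-diagonals and is
           flagged at 45 degrees", {
  th <- pi / 4
  ss <- make_toy_stateset(toy_spec(n_atoms = 4, n_states = 2,
                                   displacement_scale = 0,
                                   duschinsky_angle = th, seed = 12))
  toy <- attr(ss, "toy")
  bg <- classify_modes(normal_modes(ss$hessians[["GS"]], ss$masses,
                                    ss$geometries[["GS"]]), 300)
  be <- classify_modes(normal_modes(ss$hessians[["Lb"]], ss$masses,
                                    ss$geometries[["GS"]]), 300)
  m <- duschinsky(bg, be)
  p <- toy$pair
  expect_equal(m$J2[p[1], p[2]], sin(th)^2, tolerance = 1e-10)
  expect_equal(m$J2[p[1], p[1]], cos(th)^2, tolerance = 1e-10)
  expect_lt(max(abs(crossprod(m$duschinsky) - diag(nrow(m$J2)))), 1e-6)
  expect_warning(mm <- match_modes(m, diagonality_threshold = 0.7),
                 "below diagonality")
  flagged <- mm$pairing$flagged[mm$pairing$mode_a %in% p]
  expect_true(all(flagged))
})

test_that("optimal assignment agrees with brute-force enumeration", {
  set.seed(31)
  for (rep in 1:5) {
    cost <- matrix(runif(25), 5, 5)
    expect_equal(pmmvib:::solve_assignment(cost), brute_assignment(cost))
  }
})

test_that("mode displacements recover generator targets and vanish for
           rigid motions", {
  ss <- make_toy_stateset(toy_spec(n_atoms = 4, n_states = 2,
                                   displacement_scale = 0.8, seed = 3))
  toy <- attr(ss, "toy")
  be <- classify_modes(normal_modes(ss$hessians[["Lb"]], ss$masses,
                                    ss$geometries[["GS"]]), 300)
  md <- mode_displacements(ss$geometries[["GS"]], ss$geometries[["Lb"]],
                           be, ss$masses)
  expect_equal(md$S[match(toy$disp_modes, md$mode)], 0.8, tolerance = 1e-8)
  expect_lt(max(md$S[!md$mode %in% toy$disp_modes]), 1e-12)
  # identical geometries
  md0 <- mode_displacements(ss$geometries[["GS"]], ss$geometries[["GS"]],
                            be, ss$masses)
  expect_lt(max(abs(md0$delta)), 1e-10)
  # rigid roto-translation of either geometry changes nothing
  R <- rot_z(0.7)
  gb <- ss$geometries[["Lb"]] %*% t(R) + matrix(rep(c(3, -2, 1), each = 4), 4)
  mdr <- mode_displacements(ss$geometries[["GS"]], gb, be, ss$masses)
  expect_equal(mdr$delta, md$delta, tolerance = 1e-8)
})

test_that("diatomic bond elongation matches the reduced-mass displacement
           formula", {
  k <- 0.3; m <- 14; d <- 2.2; dr <- 0.05
  geom_a <- rbind(c(0, 0, 0), c(d, 0, 0))
  geom_b <- rbind(c(0, 0, 0), c(d + dr, 0, 0))
  basis <- classify_modes(normal_modes(diatomic_hessian(k), c(m, m), geom_a),
                          300)
  md <- mode_displacements(geom_a, geom_b, basis, c(m, m))
  mu <- m * au_constants$amu_me / 2
  omega <- sqrt(2 * k / (m * au_constants$amu_me))
  expect_equal(abs(md$delta), dr * sqrt(mu * omega), tolerance = 1e-8)
})

test_that("sum of S*h*nu equals the harmonic reorganization energy", {
  ss <- fix_stateset()
  be <- classify_modes(normal_modes(ss$hessians[["Lb"]], ss$masses,
                                    ss$geometries[["GS"]]), 300)
  md <- mode_displacements(ss$geometries[["GS"]], ss$geometries[["Lb"]],
                           be, ss$masses)
  lam_modes <- sum(md$S * au_constants$h_au * md$nu)
  # oracle: quadratic form of the excited Hessian over the displacement
  dx <- as.vector(t(ss$geometries[["GS"]] - ss$geometries[["Lb"]]))
  lam_direct <- 0.5 * as.numeric(dx %*% ss$hessians[["Lb"]] %*% dx)
  expect_equal(lam_modes, lam_direct, tolerance = 1e-8)
})
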