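test_that("electrostatics reduce to Coulomb sums and the dipole far field", {
  # no charges, no field
  qc <- matrix(c(0, 0, 0), 1, 3)
  es0 <- perturbation_fields(environment_frame(qc), masses = 12)
  expect_equal(es0$V, 0)
  expect_equal(es0$E0, c(0, 0, 0))
  # single unit charge at distance d
  d <- 7
  es1 <- perturbation_fields(
    environment_frame(qc, matrix(c(d, 0, 0), 1, 3), 1), masses = 12)
  expect_equal(es1$V, 1 / d, tolerance = 1e-14)
  expect_equal(es1$E0, c(-1 / d^2, 0, 0), tolerance = 1e-14)
  # +-q pair straddling r0: far field matches the ideal dipole within 1%
  sep <- 0.4; R <- 20 * sep
  env <- rbind(c(R, 0, sep / 2), c(R, 0, -sep / 2))
  esd <- perturbation_fields(environment_frame(qc, env, c(1, -1)),
                             masses = 12)
  p <- c(0, 0, sep)   # dipole moment q*sep along z at distance R on x
  ideal <- (3 * sum(p * c(1, 0, 0)) * c(1, 0, 0) - p) / R^3
  expect_lt(sqrt(sum((esd$E0 - ideal)^2)) / sqrt(sum(ideal^2)), 0.01)
})

test_that("reference alignment recovers constructed rotations and flags
           reflections", {
  ss <- fix_stateset()
  g <- ss$geometries[["GS"]]
  fit0 <- align_reference(g, g, ss$masses)
  expect_lt(max(abs(fit0$rotation - diag(3))), 1e-12)
  expect_lt(fit0$rmsd, 1e-12)
  R <- rot_z(pi / 6)
  fit <- align_reference(g, g %*% t(R), ss$masses)
  expect_lt(max(abs(fit$rotation - R)), 1e-10)
  # mirror image requires a reflection
  gm <- g; gm[, 1] <- -gm[, 1]
  expect_error(align_reference(g, gm, ss$masses), "chirality")
  # thermally distorted fixture: rmsd equals the quaternion-solver oracle
  set.seed(4)
  gt <- (g + matrix(rnorm(length(g), sd = 0.05), nrow(g))) %*%
    t(random_rotation())
  fit2 <- align_reference(g, gt, ss$masses)
  aligned <- pmmvib:::apply_fit(list(rotation = fit2$rotation,
                                     translation = fit2$translation), g)
  expect_equal(fit2$rmsd, horn_rmsd(g, gt, ss$masses), tolerance = 1e-10)
})

test_that("zero perturbation returns the unperturbed states exactly", {
  ss <- fix_stateset()
  fr <- environment_frame(ss$geometries[["GS"]])
  es <- perturbation_fields(fr, ss$masses)
  H <- build_hamiltonian(ss, es, diag(3))
  expect_equal(unname(H), diag(unname(ss$U0)), tolerance = 1e-14)
  res <- diagonalize_hamiltonian(H, ss)
  expect_equal(res$energies, unname(ss$U0), tolerance = 1e-10)
  expect_equal(unname(res$projections2), diag(3), tolerance = 1e-10)
  expect_equal(res$trans_dipole[1, ], ss$dipole_matrix[1, 2, ],
               tolerance = 1e-10)
})

test_that("two-state uniform field reproduces the closed-form avoided
           crossing and dipole mixing", {
  ss <- fix_stateset2()
  for (Ez in c(0.002, 0.005, 0.01)) {
    fr <- make_field_frames(ss, list(c(0, 0, Ez)))[[1]]
    es <- perturbation_fields(fr, ss$masses)
    H <- build_hamiltonian(ss, es, diag(3))
    res <- diagonalize_hamiltonian(H, ss)
    U <- unname(ss$U0); c01 <- -Ez * ss$dipole_matrix[1, 2, 3]
    disc <- sqrt(((U[2] - U[1]) / 2)^2 + c01^2)
    expect_equal(res$energies, c(mean(U) - disc, mean(U) + disc),
                 tolerance = 1e-10)
    # mixing: ground eigenvector component ratio v2/v1 = (E- - U1)/c
    v <- c(1, (res$energies[1] - U[1]) / c01)
    v <- v / sqrt(sum(v^2))
    expect_equal(abs(res$eigenvectors[, 1]), abs(v), tolerance = 1e-10)
    # field-sign reversal leaves eigenvalues unchanged
    fr2 <- make_field_frames(ss, list(c(0, 0, -Ez)))[[1]]
    H2 <- build_hamiltonian(ss, perturbation_fields(fr2, ss$masses), diag(3))
    expect_equal(eigen(H2, only.values = TRUE)$values,
                 eigen(H, only.values = TRUE)$values, tolerance = 1e-12)
  }
})

test_that("a state-independent dV shifts nothing observable", {
  ss <- fix_stateset()
  frames <- fix_frames()
  es <- perturbation_fields(frames[[1]], ss$masses)
  es_dv <- perturbation_fields(frames[[1]], ss$masses, dV = 0.37)
  r1 <- diagonalize_hamiltonian(build_hamiltonian(ss, es), ss)
  r2 <- diagonalize_hamiltonian(build_hamiltonian(ss, es_dv), ss)
  expect_equal(r2$trans_freq, r1$trans_freq, tolerance = 1e-12)
  expect_equal(r2$eigenvectors, r1$eigenvectors, tolerance = 1e-12)
  expect_equal(r2$energies - r1$energies, rep(0.37, 3), tolerance = 1e-12)
})

test_that("rotating the whole frame leaves energies, projections and dipole
           norms invariant", {
  ss <- fix_stateset()
  fr <- fix_frames()[[2]]
  run_one <- function(fr) {
    fit <- align_reference(ss$geometries[["GS"]], fr$qc_coords, ss$masses)
    es <- perturbation_fields(fr, ss$masses)
    diagonalize_hamiltonian(build_hamiltonian(ss, es, fit$rotation), ss,
                            fit$rotation)
  }
  r1 <- run_one(fr)
  set.seed(8)
  R <- random_rotation()
  fr_rot <- environment_frame(fr$qc_coords %*% t(R),
                              fr$env_coords %*% t(R), fr$env_charges,
                              frame_index = fr$frame_index)
  r2 <- run_one(fr_rot)
  expect_equal(r2$energies, r1$energies, tolerance = 1e-10)
  expect_equal(r2$projections2, r1$projections2, tolerance = 1e-10)
  expect_equal(rowSums(r2$trans_dipole^2), rowSums(r1$trans_dipole^2),
               tolerance = 1e-10)
})

test_that("eigenvalues match a characteristic-polynomial oracle and
           projections are unitary", {
  ss <- fix_stateset()
  fr <- fix_frames()[[3]]
  es <- perturbation_fields(fr, ss$masses)
  H <- build_hamiltonian(ss, es)
  res <- diagonalize_hamiltonian(H, ss)
  # oracle: roots of det(H - x I) for the 3x3 case
  cp <- c(-det(H),
          det(H[2:3, 2:3]) + det(H[c(1, 3), c(1, 3)]) + det(H[1:2, 1:2]),
          -sum(diag(H)), 1)
  roots <- sort(Re(polyroot(cp)))
  expect_equal(res$energies, roots, tolerance = 1e-10)
  expect_equal(colSums(res$projections2), rep(1, 3), tolerance = 1e-8)
  # random symmetric H keeps unitarity too
  set.seed(2)
  Hr <- crossprod(matrix(rnorm(9), 3)); Hr <- (Hr + t(Hr)) / 2
  dimnames(Hr) <- dimnames(H)
  rr <- diagonalize_hamiltonian(Hr, ss)
  expect_equal(colSums(rr$projections2), rep(1, 3), tolerance = 1e-8)
})

test_that("state assignment applies the identity threshold and dark-state
           discard", {
  ss <- fix_stateset()
  fake <- function(p2) {
    structure(list(projections2 = matrix(p2, ncol = ncol(p2)),
                   state_labels = c("GS", "Lb", "La")),
              class = "pmm_frame_result")
  }
  r <- fake(matrix(c(0.95, 0.04, 0.01), 3, 1))
  rownames(r$projections2) <- c("GS", "Lb", "La")
  expect_equal(assign_state(r, 0.8)$assignment, "GS")
  r2 <- fake(matrix(c(0.5, 0.5, 0), 3, 1))
  expect_equal(assign_state(r2, 0.8)$assignment, "mixed")
  r3 <- fake(matrix(c(0.05, 0.05, 0.9), 3, 1))
  expect_equal(assign_state(r3, 0.8, dark_labels = "La")$assignment,
               "dark-discard")
})
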