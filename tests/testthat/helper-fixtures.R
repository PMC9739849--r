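# Shared fixtures, built once per test run.

cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, cache)) assign(key, expr, cache)
  get(key, cache)
}

# 3-state toy with mild mixing and displacement
fix_stateset <- function() memo("ss3", make_toy_stateset(
  toy_spec(n_atoms = 4, n_states = 3, displacement_scale = 0.4,
           duschinsky_angle = 0.2, charge_contrast = 0.05, seed = 42)))

fix_frames <- function() memo("fr3", make_solvent_frames(
  fix_stateset(), n_frames = 40, n_waters = 10, seed = 7))

# 2-state toy with zero mixing, for closed-form checks
fix_stateset2 <- function() memo("ss2", make_toy_stateset(
  toy_spec(n_atoms = 3, n_states = 2, displacement_scale = 0.3,
           duschinsky_angle = 0, charge_contrast = 0, seed = 5)))

# diatomic harmonic fixture: spring constant k (a.u.), masses m (a.m.u.),
# atoms separated by d Bohr along x
diatomic_hessian <- function(k, d = 2) {
  H <- matrix(0, 6, 6)
  H[1, 1] <- H[4, 4] <- k
  H[1, 4] <- H[4, 1] <- -k
  H
}

# independent quaternion (Horn) superposition oracle: returns optimal rmsd
horn_rmsd <- function(a, b, masses) {
  w <- masses / sum(masses)
  ac <- sweep(a, 2, colSums(a * w)); bc <- sweep(b, 2, colSums(b * w))
  M <- t(ac * w) %*% bc
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lmax <- max(eigen(K, symmetric = TRUE)$values)
  sq <- sum(w * rowSums(ac^2)) + sum(w * rowSums(bc^2)) - 2 * lmax
  sqrt(max(sq, 0))
}

# rotation matrix about z by angle
rot_z <- function(th) matrix(c(cos(th), sin(th), 0,
                               -sin(th), cos(th), 0, 0, 0, 1), 3, 3)

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# brute-force assignment oracle (minimize) for small n
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- rbind(1)
  if (n > 1) {
    perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ,
                   drop = FALSE]
  }
  best <- which.min(apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)])))
  as.integer(perms[best, ])
}
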