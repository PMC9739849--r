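# run code with a private, restored RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic toy chromophore
#'
#' @param n_atoms number of atoms (>= 2)
#' @param n_states number of electronic states (>= 2, ground first)
#' @param displacement_scale target Huang-Rhys factor(s); a vector is applied
#'   to the first `length(displacement_scale)` quantum modes (ascending
#'   frequency), a scalar to the first quantum mode only
#' @param duschinsky_angle mixing angle (radians, in \[0, pi/4\]) applied
#'   between the two highest-frequency quantum modes of every excited state
#' @param charge_contrast magnitude of the difference between ground- and
#'   excited-state charge sets (e)
#' @param seed RNG seed; identical seeds give identical output
#' @return a validated list of class `toy_spec`
#' @export
toy_spec <- function(n_atoms = 4, n_states = 3, displacement_scale = 0.5,
                     duschinsky_angle = 0, charge_contrast = 0.1, seed = 1L) {
  if (n_atoms < 2) stop("toy_spec: n_atoms must be >= 2")
  if (n_states < 2) stop("toy_spec: n_states must be >= 2")
  if (duschinsky_angle < 0 || duschinsky_angle > pi / 4)
    stop("toy_spec: duschinsky_angle must lie in [0, pi/4]")
  if (any(displacement_scale < 0))
    stop("toy_spec: displacement_scale must be >= 0")
  structure(list(n_atoms = as.integer(n_atoms),
                 n_states = as.integer(n_states),
                 displacement_scale = as.numeric(displacement_scale),
                 duschinsky_angle = duschinsky_angle,
                 charge_contrast = charge_contrast, seed = as.integer(seed)),
            class = "toy_spec")
}

toy_labels <- function(n) {
  base <- c("GS", "Lb", "La", "pisigma")
  if (n <= 4) base[seq_len(n)] else c(base, paste0("S", 4:(n - 1)))[seq_len(n)]
}

#' Generate a synthetic unperturbed state set
#'
#' Builds a toy chromophore whose per-state Hessians share one internal mode
#' frame defined at the ground-state reference geometry: excited states have
#' the same frequencies, a mode pair mixed by exactly `duschinsky_angle`, and
#' minima displaced along their own quantum modes so each targeted mode's
#' Huang-Rhys factor equals `displacement_scale` exactly. Because all
#' Hessians are constructed orthogonal to the ground-state roto-translation
#' space, normal-mode analysis of toy Hessians should use the ground-state
#' geometry for the Eckart projection; the generator's exact targets are
#' attached as attribute `toy` (mode frame, frequencies, per-state S vectors,
#' mixing angle).
#'
#' @param spec a [toy_spec()]
#' @return an `unperturbed_stateset` passing all validators
#' @export
make_toy_stateset <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  with_seed(spec$seed, {
    n <- spec$n_atoms
    ns <- spec$n_states
    mass_table <- c(C = 12.011, N = 14.007, O = 15.999)
    elements <- sample(names(mass_table), n, replace = TRUE)
    masses <- unname(mass_table[elements])
    geom <- matrix(stats::rnorm(3 * n, sd = 1.8), n, 3)
    m_e <- masses * au_constants$amu_me
    geom <- sweep(geom, 2, colSums(geom * m_e) / sum(m_e))
    T0 <- trans_rot_vectors(geom, masses)
    nint <- 3 * n - ncol(T0)
    # internal frame orthogonal to the ground-state roto-translation space
    X <- matrix(stats::rnorm(3 * n * 3 * n), 3 * n)
    Q <- qr.Q(qr(cbind(T0, X)))[, (ncol(T0) + 1):(3 * n), drop = FALSE]
    # vibrational quanta h*nu (Eh): one semiclassical mode when room allows
    if (nint >= 5) hw <- c(5e-4, seq(0.006, 0.016, length.out = nint - 1))
    else hw <- seq(0.007, 0.016, length.out = nint)
    quantum <- hw > au_constants$kB * 300
    nq <- sum(quantum)
    S_target <- spec$displacement_scale
    if (length(S_target) > nq)
      stop("make_toy_stateset: infeasible spec, more displaced modes than quantum modes")
    disp_modes <- which(quantum)[seq_along(S_target)]
    pair <- utils::tail(which(quantum), 2)
    mvec <- rep(m_e, each = 3)
    msqrt <- sqrt(mvec)
    build_hess <- function(V) {
      Hm <- V %*% (hw^2 * t(V))
      H <- Hm * outer(msqrt, msqrt)
      (H + t(H)) / 2
    }
    U0 <- c(0, 0.17 + 0.02 * seq_len(ns - 1) - 0.02)
    qg <- stats::runif(n, -0.3, 0.3); qg <- qg - mean(qg)
    charges <- matrix(0, ns, n)
    charges[1, ] <- qg
    geometries <- vector("list", ns); geometries[[1]] <- geom
    hessians <- vector("list", ns); hessians[[1]] <- build_hess(Q)
    S_states <- vector("list", ns)
    for (s in 2:ns) {
      Ve <- Q
      if (spec$duschinsky_angle > 0 && length(pair) == 2) {
        th <- spec$duschinsky_angle
        Ve[, pair] <- cbind(cos(th) * Q[, pair[1]] + sin(th) * Q[, pair[2]],
                            -sin(th) * Q[, pair[1]] + cos(th) * Q[, pair[2]])
      }
      hessians[[s]] <- build_hess(Ve)
      dq <- numeric(nint)
      dq[disp_modes] <- sqrt(2 * S_target / hw[disp_modes])
      dx <- as.vector(Ve %*% dq) / msqrt
      geometries[[s]] <- geom + matrix(dx, n, 3, byrow = TRUE)
      pat <- stats::runif(n, -1, 1); pat <- pat - mean(pat)
      charges[s, ] <- qg + spec$charge_contrast * pat
      Ssv <- numeric(nint); Ssv[disp_modes] <- S_target
      S_states[[s]] <- Ssv
    }
    dip <- array(0, dim = c(ns, ns, 3))
    for (j in seq_len(ns)) for (l in j:ns) {
      v <- if (j == l) stats::runif(3, -0.5, 0.5) else stats::runif(3, -1, 1)
      if (l == 4 && j == 1) v <- v * 0.01   # dark state: tiny transition dipole
      dip[j, l, ] <- v; dip[l, j, ] <- v
    }
    out <- unperturbed_stateset(toy_labels(ns), U0, charges, dip, geometries,
                                masses, elements, hessians)
    attr(out, "toy") <- list(spec = spec, mode_frame = Q, hw = hw,
                             quantum = quantum, disp_modes = disp_modes,
                             pair = pair, S_states = S_states)
    out
  })
}

#' Generate solvent-like environment frames around a toy chromophore
#'
#' Statistical scenery, not dynamics: each frame jitters the QC around the
#' ground-state reference geometry and scatters neutral three-point charge
#' triads (water-like partials -2q, +q, +q) uniformly in a spherical shell
#' around the QC, with per-frame total environment charge exactly zero.
#'
#' @param stateset the toy `unperturbed_stateset`
#' @param n_frames number of frames
#' @param n_waters triads per frame (0 gives zero-perturbation frames)
#' @param seed RNG seed
#' @param shell inner/outer shell radii around the QC center of mass (Bohr)
#' @param jitter_sd thermal jitter of QC coordinates (Bohr)
#' @return list of `environment_frame` objects
#' @export
make_solvent_frames <- function(stateset, n_frames, n_waters, seed = 1L,
                                shell = c(7, 16), jitter_sd = 0.01) {
  stopifnot(inherits(stateset, "unperturbed_stateset"), n_waters >= 0)
  geom <- stateset$geometries[[1]]
  m_e <- stateset$masses * au_constants$amu_me
  com <- colSums(geom * m_e) / sum(m_e)
  with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      qc <- geom + matrix(stats::rnorm(length(geom), sd = jitter_sd),
                          nrow(geom), 3)
      env <- matrix(0, 0, 3); qch <- numeric(0)
      if (n_waters > 0) {
        opos <- matrix(0, n_waters, 3)
        placed <- 0L; tries <- 0L
        while (placed < n_waters) {
          tries <- tries + 1L
          if (tries > 200L * n_waters)
            stop("make_solvent_frames: shell too small for requested water count")
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          r <- (shell[1]^3 + stats::runif(1) * (shell[2]^3 - shell[1]^3))^(1 / 3)
          p <- com + r * u
          if (placed > 0 &&
              min(rowSums(sweep(opos[seq_len(placed), , drop = FALSE], 2,
                                p)^2)) < 4.5^2) next
          placed <- placed + 1L
          opos[placed, ] <- p
        }
        L <- 1.8089            # O-H bond, Bohr
        half <- 104.52 / 2 * pi / 180
        env <- matrix(0, 3 * n_waters, 3)
        qch <- rep(c(-0.834, 0.417, 0.417), n_waters)
        for (w in seq_len(n_waters)) {
          b1 <- stats::rnorm(3); b1 <- b1 / sqrt(sum(b1^2))
          b2 <- stats::rnorm(3); b2 <- b2 - sum(b2 * b1) * b1
          b2 <- b2 / sqrt(sum(b2^2))
          env[3 * w - 2, ] <- opos[w, ]
          env[3 * w - 1, ] <- opos[w, ] + L * (cos(half) * b1 + sin(half) * b2)
          env[3 * w, ] <- opos[w, ] + L * (cos(half) * b1 - sin(half) * b2)
        }
      }
      environment_frame(qc, env, qch, frame_index = f - 1L)
    })
  })
}

#' Frames carrying an explicit uniform field and no charges
#'
#' One frame per field value, QC fixed at the ground-state reference
#' geometry; supports analytic tests of the perturbed Hamiltonian.
#'
#' @param stateset the `unperturbed_stateset`
#' @param field_values list of 3-vectors, or an m x 3 matrix (a.u.)
#' @return list of `environment_frame` objects
#' @export
make_field_frames <- function(stateset, field_values) {
  stopifnot(inherits(stateset, "unperturbed_stateset"))
  if (is.matrix(field_values))
    field_values <- split(field_values, row(field_values))
  lapply(seq_along(field_values), function(i)
    environment_frame(stateset$geometries[[1]],
                      uniform_field = as.numeric(field_values[[i]]),
                      frame_index = i - 1L))
}
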