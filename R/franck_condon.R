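#' Squared single-mode overlap for a displaced harmonic mode
#'
#' For two identical harmonic modes whose minima differ by a dimensionless
#' displacement with Huang-Rhys factor S, the squared overlap between the
#' vibrational ground state of one and the k-th eigenstate of the other is
#' the Poisson weight exp(-S) S^k / k!.
#'
#' @param S Huang-Rhys factor(s), >= 0
#' @param k vibrational quantum number(s), non-negative integer
#' @return squared overlap, vectorized over the longer argument
#' @export
fc_single_squared <- function(S, k) {
  if (any(S < 0)) stop("fc_single_squared: S must be >= 0")
  if (any(k < 0) || any(k != round(k)))
    stop("fc_single_squared: k must be a non-negative integer")
  n <- max(length(S), length(k))
  S <- rep_len(S, n); k <- rep_len(k, n)
  out <- numeric(n)
  z <- S == 0
  out[z] <- as.numeric(k[z] == 0)
  out[!z] <- exp(-S[!z] + k[!z] * log(S[!z]) - lfactorial(k[!z]))
  out
}

#' Squared multi-mode overlap as a product of single-mode factors
#'
#' The multi-mode squared overlap factorizes over quantum modes; modes with
#' zero excited quanta contribute their ground-ground factor exp(-S).
#'
#' @param S_vector per-quantum-mode Huang-Rhys factors
#' @param quanta excited quanta: either a full integer vector aligned with
#'   `S_vector`, or a named sparse vector whose names are mode indices
#' @return squared overlap
#' @export
fc_product <- function(S_vector, quanta) {
  n <- length(S_vector)
  k <- integer(n)
  sparse_idx <- suppressWarnings(as.integer(names(quanta)))
  if (!is.null(names(quanta)) && !anyNA(sparse_idx)) {
    if (any(sparse_idx < 1) || any(sparse_idx > n))
      stop("fc_product: unknown mode index in quanta")
    k[sparse_idx] <- as.integer(quanta)
  } else {
    if (length(quanta) != n)
      stop("fc_product: quanta must be named or match S_vector length")
    k <- as.integer(quanta)
  }
  prod(fc_single_squared(S_vector, k))
}

#' Enumerate vibronic transitions above a squared-overlap threshold
#'
#' Enumerates every vector of excited quanta over the quantum modes whose
#' squared multi-mode overlap is at least `fc_threshold`, subject to a total
#' quanta cap. Completeness follows from per-mode bound pruning: a partial
#' assignment is abandoned only when even the maximal attainable factors of
#' the remaining modes cannot reach the threshold.
#'
#' @param S_vector per-quantum-mode Huang-Rhys factors
#' @param freqs per-quantum-mode frequencies (a.u.), final electronic state
#' @param fc_threshold minimum squared overlap retained
#' @param max_total_quanta cap on the total number of excited quanta
#' @param max_transitions memory guard: abort (with the projected count) if
#'   the enumeration exceeds this many retained transitions
#' @return object of class `transition_set`: `quanta` (matrix, one row per
#'   transition), `fc2` (descending; ties broken by lexicographic quanta),
#'   `nu0` (frequency offset above the 0-0 line, a.u.), `captured` (sum of
#'   fc2), plus the enumeration controls
#' @export
enumerate_transitions <- function(S_vector, freqs, fc_threshold = 1e-8,
                                  max_total_quanta = 30,
                                  max_transitions = 2e6) {
  if (fc_threshold <= 0 || max_total_quanta <= 0)
    stop("enumerate_transitions: thresholds must be positive")
  n <- length(S_vector)
  if (length(freqs) != n)
    stop("enumerate_transitions: freqs length != S_vector length")
  if (n > 0 && any(freqs <= 0))
    stop("enumerate_transitions: quantum-mode frequencies must be positive")
  if (any(S_vector < 0)) stop("enumerate_transitions: negative Huang-Rhys factor")
  lthr <- log(fc_threshold)
  kmax <- max_total_quanta
  # per-mode log Poisson weights up to kmax
  lp <- lapply(seq_len(n), function(i) {
    S <- S_vector[i]
    if (S == 0) c(0, rep(-Inf, kmax))
    else -S + (0:kmax) * log(S) - lfactorial(0:kmax)
  })
  lmax <- vapply(lp, max, 0)                   # per-mode best factor
  suf <- rev(cumsum(rev(c(lmax, 0))))          # suf[i] = sum of lmax[i..n]
  # iterative cross-product with bound pruning
  quanta <- matrix(0L, 1, 0)
  tot <- 0L
  lfc <- 0
  for (i in seq_len(n)) {
    keepk <- which(lp[[i]] + suf[i + 1] + max(lfc) >= lthr) - 1L
    keepk <- keepk[keepk <= kmax]
    nk <- length(keepk)
    nr <- length(lfc)
    new_lfc <- rep(lfc, times = nk) + rep(lp[[i]][keepk + 1L], each = nr)
    new_tot <- rep(tot, times = nk) + rep(keepk, each = nr)
    ok <- (new_lfc + suf[i + 1] >= lthr) & (new_tot <= kmax)
    if (sum(ok) > max_transitions)
      stop(sprintf(
        "enumerate_transitions: projected transition count %d exceeds cap %d",
        sum(ok), as.integer(max_transitions)))
    quanta <- cbind(quanta[rep(seq_len(nr), times = nk), , drop = FALSE],
                    rep(keepk, each = nr))[ok, , drop = FALSE]
    lfc <- new_lfc[ok]
    tot <- new_tot[ok]
  }
  keep <- lfc >= lthr
  quanta <- quanta[keep, , drop = FALSE]
  fc2 <- exp(lfc[keep])
  nu0 <- if (n > 0) as.vector(quanta %*% freqs) else rep(0, length(fc2))
  ord <- do.call(order, c(list(-fc2),
                          lapply(seq_len(max(n, 1)), function(j)
                            if (n > 0) quanta[, j] else rep(0, length(fc2)))))
  colnames(quanta) <- if (n > 0) paste0("m", seq_len(n)) else NULL
  structure(list(quanta = quanta[ord, , drop = FALSE], fc2 = fc2[ord],
                 nu0 = nu0[ord], captured = sum(fc2),
                 S_vector = S_vector, freqs = freqs,
                 fc_threshold = fc_threshold,
                 max_total_quanta = max_total_quanta),
            class = "transition_set")
}

#' @export
print.transition_set <- function(x, ...) {
  cat(sprintf(
    "Transition set: %d vibronic transitions over %d quantum modes\n",
    length(x$fc2), length(x$S_vector)))
  cat(sprintf("  captured sum of squared overlaps: %.8f (threshold %g, max quanta %d)\n",
              x$captured, x$fc_threshold, x$max_total_quanta))
  invisible(x)
}

#' Export a transition set as TSV
#'
#' Quanta are encoded as "mode:quanta" pairs joined by commas (empty string
#' for the 0-0 transition); offsets are given in cm^-1 and eV.
#'
#' @param tset a `transition_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
export_transitions <- function(tset, path) {
  stopifnot(inherits(tset, "transition_set"))
  qstr <- apply(tset$quanta, 1, function(k) {
    i <- which(k > 0)
    paste(sprintf("%d:%d", i, k[i]), collapse = ",")
  })
  if (length(tset$fc2) == 0) qstr <- character(0)
  d <- data.frame(quanta = qstr, fc2 = tset$fc2,
                  offset_cm1 = tset$nu0 * 2 * pi * au_constants$hartree_cm1,
                  offset_ev = freq_au_to_ev(tset$nu0))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# physicists' Hermite polynomial H_k at points x, by recurrence
hermite_poly <- function(k, x) {
  if (k == 0) return(rep(1, length(x)))
  hm1 <- rep(1, length(x)); h <- 2 * x
  if (k == 1) return(h)
  for (j in 2:k) {
    hn <- 2 * x * h - 2 * (j - 1) * hm1
    hm1 <- h; h <- hn
  }
  h
}

#' Quadrature oracle for the displaced-oscillator squared overlap
#'
#' Numerically integrates the product of the ground eigenfunction of one
#' harmonic oscillator and the k-th eigenfunction of an identical oscillator
#' displaced by d = sqrt(2S), using Gauss-Hermite quadrature, and squares
#' the result. Serves as an independent check of [fc_single_squared()].
#'
#' @param S Huang-Rhys factor
#' @param k vibrational quantum number
#' @param quadrature_points number of Gauss-Hermite nodes (>= 200)
#' @return squared overlap
#' @export
oracle_overlap <- function(S, k, quadrature_points = 200) {
  if (quadrature_points < 200)
    stop("oracle_overlap: need at least 200 quadrature points")
  if (S < 0 || k < 0 || k != round(k)) stop("oracle_overlap: invalid S or k")
  val <- function(npts) {
    gh <- pracma::gaussHermite(npts)
    d <- sqrt(2 * S)
    # integrand chi_0(x) chi_k(x - d); substitute t = x - d/2
    coef <- exp(-d^2 / 4 - 0.5 * (k * log(2) + lfactorial(k))) / sqrt(pi)
    (coef * sum(gh$w * hermite_poly(k, gh$x - d / 2)))^2
  }
  v1 <- val(quadrature_points)
  v2 <- val(2 * quadrature_points)
  if (abs(v2 - v1) > 1e-11 * max(1, abs(v2)))
    stop("oracle_overlap: quadrature not converged across point doubling")
  v2
}
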