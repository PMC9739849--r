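#' Run configuration for the spectroscopy workflows
#'
#' Collects the tunable constants of the pipeline. `bin_width` defaults to
#' `sigma/2`, below the Gaussian resolution, so the binned spectrum is
#' grid-insensitive.
#'
#' @param temperature absolute temperature (K) for the quantum/semiclassical
#'   mode partition
#' @param sigma Gaussian broadening width (frequency a.u.)
#' @param bin_width frequency bin width (a.u.)
#' @param fc_threshold minimum squared vibrational overlap retained
#' @param max_total_quanta cap on total excited quanta per transition
#' @param identity_threshold minimum squared projection identifying a
#'   perturbed state with an unperturbed one
#' @param dark_labels labels of spectroscopically dark states
#' @param exp_00 optional named vector of experimental gas-phase 0-0
#'   energies (eV) keyed by excited-state label; matching transitions are
#'   shifted so their 0-0 line reproduces these values
#' @return a list of class `run_config`
#' @export
run_config <- function(temperature = 300, sigma = 4e-4, bin_width = sigma / 2,
                       fc_threshold = 1e-8, max_total_quanta = 30,
                       identity_threshold = 0.8,
                       dark_labels = "pisigma", exp_00 = NULL) {
  stopifnot(temperature > 0, sigma > 0, bin_width > 0, fc_threshold > 0,
            max_total_quanta > 0, identity_threshold > 0)
  structure(list(temperature = temperature, sigma = sigma,
                 bin_width = bin_width, fc_threshold = fc_threshold,
                 max_total_quanta = max_total_quanta,
                 identity_threshold = identity_threshold,
                 dark_labels = dark_labels, exp_00 = exp_00),
            class = "run_config")
}

# per-frame PMM sweep against a fixed reference geometry
pmm_sweep <- function(stateset, frames, ref_label, config) {
  geom_ref <- stateset$geometries[[ref_label]]
  masses <- stateset$masses
  ns <- length(stateset$state_labels)
  nf <- length(frames)
  nex <- ns - 1
  nu <- matrix(0, nf, nex)
  mu2 <- matrix(0, nf, nex)
  assign_m <- matrix("", nf, nex)
  proj2 <- array(0, dim = c(nf, ns, nex),
                 dimnames = list(NULL, stateset$state_labels, NULL))
  fidx <- integer(nf)
  for (f in seq_len(nf)) {
    fr <- frames[[f]]
    fit <- align_reference(geom_ref, fr$qc_coords, masses)
    es <- perturbation_fields(fr, masses)
    H <- build_hamiltonian(stateset, es, fit$rotation)
    res <- diagonalize_hamiltonian(H, stateset, fit$rotation)
    res <- assign_state(res, config$identity_threshold, config$dark_labels)
    nu[f, ] <- res$trans_freq
    mu2[f, ] <- rowSums(res$trans_dipole^2)
    assign_m[f, ] <- res$assignment[-1]
    proj2[f, , ] <- res$projections2[, -1, drop = FALSE]
    fidx[f] <- fr$frame_index
  }
  list(nu = nu, mu2 = mu2, assignments = assign_m, projections2 = proj2,
       frame_indices = fidx)
}

# classified mode basis for a state, or NULL when no Hessian is available
state_basis <- function(stateset, label, temperature) {
  H <- stateset$hessians[[label]]
  if (is.null(H)) return(NULL)
  classify_modes(normal_modes(H, stateset$masses,
                              stateset$geometries[[label]],
                              state_label = label), temperature)
}

# Huang-Rhys vector, final-state frequencies and 0-0 line for a state pair.
# `final_label` owns the projection basis (excited for absorption, ground
# for emission). Missing Hessians degrade to an electronic-only treatment
# (no quantum modes, pure 0-0).
vibronic_inputs <- function(stateset, excited_label, kind, config) {
  final_label <- if (kind == "absorption") excited_label else "GS"
  basis <- state_basis(stateset, final_label, config$temperature)
  if (is.null(basis)) {
    S <- numeric(0); freqs <- numeric(0)
  } else {
    md <- mode_displacements(stateset$geometries[["GS"]],
                             stateset$geometries[[excited_label]],
                             basis, stateset$masses)
    S <- md$S; freqs <- md$nu
  }
  nu_el0 <- (stateset$U0[[excited_label]] - stateset$U0[["GS"]]) /
    au_constants$h_au
  lambda_nu <- sum(S * freqs)    # reorganization energy / h
  nu_00 <- if (kind == "absorption") nu_el0 - lambda_nu else nu_el0 + lambda_nu
  shift <- 0
  if (!is.null(config$exp_00) && excited_label %in% names(config$exp_00)) {
    shift <- correct_00(nu_00,
                        energy_ev_to_freq_au(config$exp_00[[excited_label]]))
    nu_00 <- nu_00 + shift
  }
  tset <- enumerate_transitions(S, freqs, config$fc_threshold,
                                config$max_total_quanta)
  list(transitions = tset, nu_el0 = nu_el0, nu_00 = nu_00, shift_00 = shift,
       basis = basis)
}

#' Absorption workflow: ground-state ensemble to vibronic spectrum
#'
#' For every frame, builds and diagonalizes the perturbed electronic
#' Hamiltonian at the ground-state reference structure, assigns each
#' perturbed excited state to an unperturbed label, extracts per-label
#' sub-ensembles, constructs their vertical and vibronic spectra, and
#' combines everything with sub-ensemble weights into the total absorption
#' spectrum.
#'
#' @param stateset an `unperturbed_stateset` (ground-state Hessian and
#'   excited-state Hessians enable the vibronic structure)
#' @param frames list of `environment_frame` objects from the ground-state
#'   trajectory
#' @param config a [run_config()]
#' @param excited_labels unperturbed labels to retain as sub-ensembles
#'   (default: all excited states not in `dark_labels`)
#' @return object of class `vibronic_run`
#' @export
run_absorption <- function(stateset, frames, config = run_config(),
                           excited_labels = NULL) {
  stopifnot(inherits(stateset, "unperturbed_stateset"))
  if (length(frames) == 0) stop("run_absorption: no frames")
  labels <- stateset$state_labels
  if (is.null(excited_labels))
    excited_labels <- setdiff(labels[-1], config$dark_labels)
  sweep_res <- pmm_sweep(stateset, frames, "GS", config)
  nex <- ncol(sweep_res$nu)
  spectra <- list(); weights <- numeric(0)
  pieces <- list()
  manifest <- list()
  subens_all <- list()
  for (i in seq_len(nex)) {
    a <- sweep_res$assignments[, i]
    se <- tryCatch(
      extract_subensembles(a, sweep_res$frame_indices, source = "ground-state"),
      error = function(e) NULL)
    disc <- if (is.null(se)) c(mixed = sum(a == "mixed"),
                               dark = sum(a == "dark-discard"))
    else attr(se, "discarded")
    se <- se[names(se) %in% excited_labels]
    other <- length(a) - sum(disc) -
      sum(vapply(se, function(s) length(s$frame_indices), 0))
    if (length(se) > 0) {
      wsum <- sum(vapply(se, `[[`, 0, "weight"))
      for (lab in names(se)) {
        sub <- se[[lab]]
        sub$weight <- sub$weight / wsum
        rows <- which(a == lab)
        band <- bin_vertical(sweep_res$nu[rows, i], sweep_res$mu2[rows, i],
                             config$bin_width, "absorption", config$sigma)
        vin <- vibronic_inputs(stateset, lab, "absorption", config)
        vert <- vertical_spectrum(band)
        vib <- vibronic_spectrum(band, vin$transitions, vin$nu_el0, vin$nu_00)
        key <- sprintf("excited%d_%s", i, lab)
        pieces[[key]] <- list(perturbed_index = i, label = lab,
                              subensemble = sub, band = band,
                              vertical = vert, vibronic = vib,
                              transitions = vin$transitions,
                              nu_el0 = vin$nu_el0, nu_00 = vin$nu_00,
                              shift_00 = vin$shift_00)
        spectra[[key]] <- vib
        weights <- c(weights, sub$weight)
        subens_all[[key]] <- sub
      }
    }
    manifest[[i]] <- data.frame(
      perturbed_index = i, n_frames = length(a),
      retained = sum(!(a %in% c("mixed", "dark-discard")) &
                       a %in% excited_labels),
      mixed = unname(disc["mixed"]), dark = unname(disc["dark"]),
      other = other)
  }
  if (length(spectra) == 0)
    stop("run_absorption: no retained sub-ensembles for any excited state")
  total <- combine_spectra(spectra, weights)
  structure(list(kind = "absorption", config = config,
                 state_labels = labels,
                 sweep = sweep_res, pieces = pieces,
                 subensembles = subens_all,
                 manifest = do.call(rbind, manifest), total = total),
            class = "vibronic_run")
}

#' Emission workflow: excited-state ensemble to vibronic spectrum
#'
#' As [run_absorption()] but over an excited-state trajectory: the
#' reference structure and PMM basis positioning use the tagged unperturbed
#' excited state, frames whose perturbed emitting state is not coherent with
#' the tag are removed (and counted), overlaps connect the excited
#' vibrational ground state to ground-state modes, and the emission
#' frequency factors apply. The exported total is peak-normalized; the raw
#' spectrum is retained.
#'
#' @param stateset an `unperturbed_stateset`
#' @param frames list of `environment_frame` objects from the excited-state
#'   trajectory
#' @param config a [run_config()]
#' @param ensemble_tag unperturbed label that defined the excited-state
#'   force field (e.g. "La")
#' @param emitting_index which perturbed excited state emits (1 = first)
#' @return object of class `vibronic_run`
#' @export
run_emission <- function(stateset, frames, config = run_config(),
                         ensemble_tag, emitting_index = 1L) {
  stopifnot(inherits(stateset, "unperturbed_stateset"),
            ensemble_tag %in% stateset$state_labels[-1])
  if (length(frames) == 0) stop("run_emission: no frames")
  sweep_res <- pmm_sweep(stateset, frames, ensemble_tag, config)
  a <- sweep_res$assignments[, emitting_index]
  rows <- which(a == ensemble_tag)
  if (length(rows) == 0)
    stop("run_emission: empty ensemble, no frame coherent with tag ",
         ensemble_tag)
  band <- bin_vertical(sweep_res$nu[rows, emitting_index],
                       sweep_res$mu2[rows, emitting_index],
                       config$bin_width, "emission", config$sigma)
  vin <- vibronic_inputs(stateset, ensemble_tag, "emission", config)
  vert <- vertical_spectrum(band)
  vib <- vibronic_spectrum(band, vin$transitions, vin$nu_el0, vin$nu_00)
  sub <- structure(list(label = ensemble_tag, source = "excited-state",
                        frame_indices = sweep_res$frame_indices[rows],
                        weight = 1), class = "subensemble")
  key <- sprintf("excited%d_%s", emitting_index, ensemble_tag)
  manifest <- data.frame(
    perturbed_index = emitting_index, n_frames = length(a),
    retained = length(rows), mixed = sum(a == "mixed"),
    dark = sum(a == "dark-discard"),
    other = length(a) - length(rows) - sum(a == "mixed") -
      sum(a == "dark-discard"))
  pieces <- list()
  pieces[[key]] <- list(perturbed_index = emitting_index,
                        label = ensemble_tag, subensemble = sub, band = band,
                        vertical = vert, vibronic = vib,
                        transitions = vin$transitions, nu_el0 = vin$nu_el0,
                        nu_00 = vin$nu_00, shift_00 = vin$shift_00)
  structure(list(kind = "emission", config = config,
                 state_labels = stateset$state_labels, sweep = sweep_res,
                 pieces = pieces, subensembles = stats::setNames(list(sub), key),
                 manifest = manifest, total = vib,
                 total_normalized = normalize_peak(vib)),
            class = "vibronic_run")
}

#' @export
print.vibronic_run <- function(x, ...) {
  cat(sprintf("Vibronic %s run: %d frames, %d sub-ensemble spectra\n",
              x$kind, nrow(x$sweep$nu), length(x$pieces)))
  for (key in names(x$pieces)) {
    p <- x$pieces[[key]]
    cat(sprintf(
      "  %s: weight %.3f, %d transitions (captured %.6f), nu_el %.4g a.u.\n",
      key, p$subensemble$weight, length(p$transitions$fc2),
      p$transitions$captured, p$band$nu_el))
  }
  pk <- x$total$grid[which.max(x$total$intensity)]
  cat(sprintf("  total peak: %.3f eV (%.1f nm)\n", freq_au_to_ev(pk),
              freq_au_to_nm(pk)))
  invisible(x)
}

#' @export
summary.vibronic_run <- function(object, ...) {
  cat("Frame accounting (retained + mixed + dark + other = total):\n")
  print(object$manifest, row.names = FALSE)
  cat("\nMean squared projections per perturbed excited state:\n")
  for (i in seq_len(dim(object$sweep$projections2)[3])) {
    m <- colMeans(object$sweep$projections2[, , i, drop = FALSE][, , 1])
    cat(sprintf("  excited %d: %s\n", i,
                paste(sprintf("%s=%.3f", names(m), m), collapse = " ")))
  }
  invisible(object)
}

#' @export
plot.vibronic_run <- function(x, ...) {
  sp <- if (x$kind == "emission") x$total_normalized else x$total
  plot(sp, main = paste("total", x$kind, "spectrum"), ...)
}

#' Write the spectra and manifest of a run to a directory
#'
#' Emits one TSV per sub-ensemble vibronic spectrum, the total spectrum
#' (peak-normalized for emission), and a plain-text manifest with frame
#' accounting, weights and captured overlap sums.
#'
#' @param run a `vibronic_run`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(run$pieces)) {
    write_spectrum_tsv(run$pieces[[key]]$vibronic,
                       file.path(dir, paste0(key, "_vibronic.tsv")))
    write_spectrum_tsv(run$pieces[[key]]$vertical,
                       file.path(dir, paste0(key, "_vertical.tsv")))
  }
  total <- if (run$kind == "emission") run$total_normalized else run$total
  write_spectrum_tsv(total, file.path(dir, "total.tsv"))
  con <- file(file.path(dir, "manifest.txt"), "w")
  on.exit(close(con))
  writeLines(sprintf("kind=%s", run$kind), con)
  writeLines(sprintf("sigma_au=%.8g bin_width_au=%.8g fc_threshold=%g",
                     run$config$sigma, run$config$bin_width,
                     run$config$fc_threshold), con)
  apply(run$manifest, 1, function(r)
    writeLines(paste(names(r), r, sep = "=", collapse = " "), con))
  for (key in names(run$pieces)) {
    p <- run$pieces[[key]]
    writeLines(sprintf(
      "subensemble=%s weight=%.8f n_frames=%d n_transitions=%d captured=%.10f shift00_au=%.8g",
      key, p$subensemble$weight, length(p$subensemble$frame_indices),
      length(p$transitions$fc2), p$transitions$captured, p$shift_00), con)
  }
  invisible(dir)
}
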