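#' Construct and validate an unperturbed state set
#'
#' The unperturbed (gas-phase) description of the quantum center: one block
#' per electronic eigenstate with its electronic energy, ESP atomic charges,
#' minimum-energy geometry and (optionally) Cartesian Hessian, plus the full
#' electronic dipole matrix between all state pairs, atomic masses and
#' element symbols. Everything is stored in atomic units (Hartree, Bohr, e;
#' masses in a.m.u. as is conventional for Hessian files).
#'
#' @param state_labels character vector of state labels, ground state first
#' @param U0 numeric vector of per-state electronic energies (Hartree),
#'   strictly increasing with the ground state lowest
#' @param charges n_states x n_atoms matrix of partial charges (e)
#' @param dipole_matrix numeric array `c(n_states, n_states, 3)` of dipole
#'   matrix elements (a.u., molecular frame); symmetric per component
#' @param geometries list of n_atoms x 3 coordinate matrices (Bohr), one per
#'   state
#' @param masses per-atom masses (a.m.u.)
#' @param elements per-atom element symbols
#' @param hessians optional list of 3N x 3N Cartesian Hessians
#'   (Hartree/Bohr^2), entries may be NULL
#' @return an object of class `unperturbed_stateset`
#' @export
unperturbed_stateset <- function(state_labels, U0, charges, dipole_matrix,
                                 geometries, masses, elements,
                                 hessians = NULL) {
  ns <- length(state_labels)
  na <- length(masses)
  if (ns < 2) stop("stateset schema error: need at least 2 states")
  if (length(U0) != ns) stop("stateset schema error: U0 length != state count")
  if (any(diff(U0) <= 0))
    stop("stateset schema error: U0 must be strictly increasing (GS lowest)")
  charges <- as.matrix(charges)
  if (!all(dim(charges) == c(ns, na)))
    stop("stateset schema error: atom count mismatch in field 'charges'")
  if (!is.array(dipole_matrix) || !all(dim(dipole_matrix) == c(ns, ns, 3)))
    stop("stateset schema error: dipole_matrix must be n_states x n_states x 3")
  for (a in 1:3) {
    if (max(abs(dipole_matrix[, , a] - t(dipole_matrix[, , a]))) > 1e-10)
      stop("stateset schema error: dipole_matrix not symmetric (component ",
           c("x", "y", "z")[a], ")")
  }
  if (length(geometries) != ns)
    stop("stateset schema error: missing state block in field 'geometries'")
  for (s in seq_len(ns)) {
    g <- as.matrix(geometries[[s]])
    if (!all(dim(g) == c(na, 3)))
      stop("stateset schema error: atom count mismatch in geometry of state ",
           state_labels[s])
    geometries[[s]] <- g
  }
  if (length(elements) != na)
    stop("stateset schema error: atom count mismatch in field 'elements'")
  if (any(masses <= 0)) stop("stateset schema error: non-positive mass")
  if (is.null(hessians)) hessians <- vector("list", ns)
  if (length(hessians) != ns)
    stop("stateset schema error: hessians list length != state count")
  for (s in seq_len(ns)) {
    h <- hessians[[s]]
    if (is.null(h)) next
    h <- as.matrix(h)
    if (!all(dim(h) == c(3 * na, 3 * na)))
      stop("stateset schema error: atom count mismatch in hessian of state ",
           state_labels[s])
    if (max(abs(h - t(h))) > 1e-8)
      stop("stateset schema error: non-symmetric hessian for state ",
           state_labels[s])
    hessians[[s]] <- h
  }
  names(U0) <- state_labels
  rownames(charges) <- state_labels
  names(geometries) <- state_labels
  names(hessians) <- state_labels
  structure(
    list(state_labels = state_labels, U0 = U0, charges = charges,
         dipole_matrix = dipole_matrix, geometries = geometries,
         masses = as.numeric(masses), elements = as.character(elements),
         hessians = hessians),
    class = "unperturbed_stateset")
}

#' @export
print.unperturbed_stateset <- function(x, ...) {
  cat("Unperturbed state set:", length(x$state_labels), "states,",
      length(x$masses), "atoms\n")
  de <- (x$U0 - x$U0[1]) * au_constants$hartree_ev
  for (s in seq_along(x$state_labels)) {
    cat(sprintf("  %-10s U0 = %12.6f Eh  (+%.3f eV)%s\n", x$state_labels[s],
                x$U0[s], de[s],
                if (is.null(x$hessians[[s]])) "" else "  [Hessian]"))
  }
  invisible(x)
}

#' Write an unperturbed state set to a structured text (JSON) file
#'
#' The schema is a single JSON document; see the package vignette for a full
#' description. All numeric fields are written in atomic units.
#'
#' @param stateset an `unperturbed_stateset`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_stateset <- function(stateset, path) {
  doc <- list(
    schema = "pmmvib-stateset-1",
    units = list(energy = "hartree", length = "bohr", charge = "e",
                 mass = "amu"),
    elements = stateset$elements,
    masses = stateset$masses,
    state_labels = as.character(stateset$state_labels),
    states = lapply(seq_along(stateset$state_labels), function(s) {
      list(label = stateset$state_labels[s],
           energy = unname(stateset$U0[s]),
           charges = unname(stateset$charges[s, ]),
           geometry = unname(stateset$geometries[[s]]),
           hessian = if (is.null(stateset$hessians[[s]])) NULL else
             unname(stateset$hessians[[s]]))
    }),
    dipole_matrix = unname(stateset$dipole_matrix))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Read an unperturbed state set from its structured text (JSON) schema
#'
#' Units declared in the file header are converted to atomic units
#' (accepted: energy hartree/ev, length bohr/angstrom/nm).
#'
#' @param path file path
#' @return an `unperturbed_stateset`
#' @export
read_stateset <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (is.null(doc$states)) stop("stateset schema error: missing 'states' block")
  eu <- tolower(doc$units$energy %||% "hartree")
  lu <- tolower(doc$units$length %||% "bohr")
  ef <- switch(eu, hartree = 1, ev = 1 / au_constants$hartree_ev,
               stop("stateset schema error: unknown energy unit ", eu))
  lf <- switch(lu, bohr = 1, angstrom = 0.1 / au_constants$bohr_nm,
               nm = 1 / au_constants$bohr_nm,
               stop("stateset schema error: unknown length unit ", lu))
  states <- doc$states
  # jsonlite may simplify the states list into a data.frame
  get_state <- function(i, field) {
    if (is.data.frame(states)) states[[field]][[i]] else states[[i]][[field]]
  }
  ns <- if (is.data.frame(states)) nrow(states) else length(states)
  labels <- vapply(seq_len(ns), get_state, "", field = "label")
  U0 <- vapply(seq_len(ns), function(i) as.numeric(get_state(i, "energy")), 0)
  charges <- do.call(rbind, lapply(seq_len(ns), get_state, field = "charges"))
  geoms <- lapply(seq_len(ns), function(i)
    as.matrix(get_state(i, "geometry")) * lf)
  hess <- lapply(seq_len(ns), function(i) {
    h <- tryCatch(get_state(i, "hessian"), error = function(e) NULL)
    if (is.null(h) || length(h) == 0 || all(is.na(h))) NULL
    else as.matrix(h) * ef / lf^2
  })
  dm <- doc$dipole_matrix
  dm <- array(as.numeric(dm), dim = c(ns, ns, 3))
  unperturbed_stateset(labels, U0 * ef, charges, dm, geoms,
                       as.numeric(doc$masses), as.character(doc$elements),
                       hess)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct and validate one environment frame
#'
#' A single MD snapshot: quantum-center atomic coordinates plus the
#' environment point charges. An optional explicit `uniform_field` supports
#' analytic tests with no charges present.
#'
#' @param qc_coords n_atoms x 3 QC coordinates (Bohr)
#' @param env_coords m x 3 environment charge coordinates (Bohr); may have
#'   zero rows
#' @param env_charges length-m charge vector (e)
#' @param box optional length-3 orthorhombic box vector (Bohr)
#' @param uniform_field optional explicit uniform electric field (a.u.)
#' @param frame_index integer frame identifier
#' @param exclusion_radius minimum allowed QC-charge distance (Bohr);
#'   default 0.05 nm
#' @return an object of class `environment_frame`
#' @export
environment_frame <- function(qc_coords, env_coords = NULL, env_charges = NULL,
                              box = NULL, uniform_field = NULL,
                              frame_index = 0L,
                              exclusion_radius = 0.05 / au_constants$bohr_nm) {
  qc_coords <- as.matrix(qc_coords)
  if (ncol(qc_coords) != 3) stop("frame error: qc_coords must be n x 3")
  if (is.null(env_coords)) env_coords <- matrix(0, 0, 3)
  env_coords <- as.matrix(env_coords)
  if (nrow(env_coords) > 0 && ncol(env_coords) != 3)
    stop("frame error: env_coords must be m x 3")
  env_charges <- as.numeric(env_charges %||% numeric(0))
  if (length(env_charges) != nrow(env_coords))
    stop("frame error: env_charges length != env_coords rows")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(box <= 0))
      stop("frame error: box must be 3 positive lengths")
    inside <- function(m) all(m >= 0 & m <= rep(box, each = nrow(m)))
    if (nrow(env_coords) > 0 && !inside(env_coords))
      stop("frame error: environment coordinates outside box")
  }
  if (nrow(env_coords) > 0) {
    d2min <- min_dist2_qc_env(qc_coords, env_coords, box)
    if (d2min < exclusion_radius^2)
      stop(sprintf(
        "frame error: environment charge within exclusion radius (min %.4f Bohr < %.4f Bohr) in frame %d",
        sqrt(d2min), exclusion_radius, frame_index))
  }
  if (!is.null(uniform_field)) {
    uniform_field <- as.numeric(uniform_field)
    if (length(uniform_field) != 3) stop("frame error: uniform_field must be a 3-vector")
  }
  structure(list(qc_coords = qc_coords, env_coords = env_coords,
                 env_charges = env_charges, box = box,
                 uniform_field = uniform_field,
                 frame_index = as.integer(frame_index)),
            class = "environment_frame")
}

# minimum-image displacement of rows of b relative to single point a
min_image <- function(d, box) {
  if (is.null(box)) return(d)
  d - rep(box, each = nrow(d)) * round(d / rep(box, each = nrow(d)))
}

min_dist2_qc_env <- function(qc, env, box) {
  mins <- vapply(seq_len(nrow(qc)), function(i) {
    d <- min_image(env - rep(qc[i, ], each = nrow(env)), box)
    min(rowSums(d * d))
  }, 0)
  min(mins)
}

#' @export
print.environment_frame <- function(x, ...) {
  cat(sprintf("Environment frame %d: %d QC atoms, %d point charges%s%s\n",
              x$frame_index, nrow(x$qc_coords), nrow(x$env_coords),
              if (is.null(x$box)) "" else ", periodic box",
              if (is.null(x$uniform_field)) "" else ", explicit field"))
  invisible(x)
}

#' Write environment frames to an extended-XYZ file with a charge column
#'
#' Format, per frame: an atom-count line; a comment line with key=value
#' tokens (`frame_index`, `n_qc`, `units`, optional `box="a b c"`, optional
#' `field="fx fy fz"`); then one line per site `element x y z charge`. QC
#' atoms come first (charge column written as 0), environment charges follow
#' with element symbol `X`.
#'
#' @param frames list of `environment_frame` objects
#' @param path output path
#' @param elements QC element symbols (recycled for every frame)
#' @param units coordinate units to write: "bohr" (default), "nm" or
#'   "angstrom"
#' @return `path`, invisibly
#' @export
write_frames <- function(frames, path, elements = NULL, units = "bohr") {
  lf <- switch(units, bohr = 1, nm = au_constants$bohr_nm,
               angstrom = 10 * au_constants$bohr_nm,
               stop("unknown length unit ", units))
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    nq <- nrow(fr$qc_coords); ne <- nrow(fr$env_coords)
    el <- elements %||% rep("Q", nq)
    hdr <- sprintf("frame_index=%d n_qc=%d units=%s", fr$frame_index, nq, units)
    if (!is.null(fr$box))
      hdr <- paste0(hdr, sprintf(" box=\"%.12g %.12g %.12g\"",
                                 fr$box[1] * lf, fr$box[2] * lf, fr$box[3] * lf))
    if (!is.null(fr$uniform_field))
      hdr <- paste0(hdr, sprintf(" field=\"%.12g %.12g %.12g\"",
                                 fr$uniform_field[1], fr$uniform_field[2],
                                 fr$uniform_field[3]))
    writeLines(as.character(nq + ne), con)
    writeLines(hdr, con)
    xyz <- fr$qc_coords * lf
    writeLines(sprintf("%-3s %.12g %.12g %.12g %.12g", el, xyz[, 1], xyz[, 2],
                       xyz[, 3], rep(0, nq)), con)
    if (ne > 0) {
      exyz <- fr$env_coords * lf
      writeLines(sprintf("%-3s %.12g %.12g %.12g %.12g", rep("X", ne),
                         exyz[, 1], exyz[, 2], exyz[, 3], fr$env_charges), con)
    }
  }
  invisible(path)
}

#' Read environment frames from an extended-XYZ file with a charge column
#'
#' @param path input path (format of [write_frames()])
#' @param stride keep every stride-th frame (in file order), starting with
#'   the first; the returned count is `ceiling(total/stride)`
#' @return list of `environment_frame` objects
#' @export
read_frames <- function(path, stride = 1L) {
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1) stop("stride must be a positive integer")
  lines <- readLines(path)
  frames <- list()
  i <- 1L; rec <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    ntot <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(ntot) || ntot < 1)
      stop("malformed frame record at line ", i, ": bad atom count")
    if (i + 1L + ntot > length(lines))
      stop("malformed frame record at line ", i, ": truncated frame")
    hdr <- parse_kv(lines[i + 1L])
    nq <- as.integer(hdr[["n_qc"]] %||% ntot)
    units <- hdr[["units"]] %||% "bohr"
    lf <- switch(units, bohr = 1, nm = 1 / au_constants$bohr_nm,
                 angstrom = 0.1 / au_constants$bohr_nm,
                 stop("malformed frame record at line ", i + 1L,
                      ": unknown units ", units))
    body <- lines[(i + 2L):(i + 1L + ntot)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(lengths(toks) != 5)
    if (length(bad))
      stop("malformed frame record at line ", i + 1L + bad[1],
           ": expected 5 columns (element x y z charge)")
    num <- matrix(suppressWarnings(as.numeric(unlist(
      lapply(toks, `[`, 2:5)))), ncol = 4, byrow = TRUE)
    if (anyNA(num))
      stop("malformed frame record near line ", i + 2L, ": non-numeric field")
    rec <- rec + 1L
    if ((rec - 1L) %% stride == 0L) {
      box <- if (!is.null(hdr[["box"]]))
        as.numeric(strsplit(hdr[["box"]], "[[:space:]]+")[[1]]) * lf else NULL
      field <- if (!is.null(hdr[["field"]]))
        as.numeric(strsplit(hdr[["field"]], "[[:space:]]+")[[1]]) else NULL
      qc <- num[seq_len(nq), 1:3, drop = FALSE] * lf
      env <- if (ntot > nq) num[(nq + 1L):ntot, 1:3, drop = FALSE] * lf
      else matrix(0, 0, 3)
      qch <- if (ntot > nq) num[(nq + 1L):ntot, 4] else numeric(0)
      fi <- as.integer(hdr[["frame_index"]] %||% (rec - 1L))
      frames[[length(frames) + 1L]] <- environment_frame(
        qc, env, qch, box = box, uniform_field = field, frame_index = fi)
    }
    i <- i + 2L + ntot
  }
  if (length(frames) == 0) stop("empty frame input: no frames in ", path)
  frames
}

parse_kv <- function(line) {
  # key=value tokens; values may be double-quoted
  out <- list()
  rx <- '([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|[^[:space:]]+)'
  m <- gregexpr(rx, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  for (k in seq_along(m)) {
    tok <- substr(line, m[k], m[k] + attr(m, "match.length")[k] - 1)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1)
    val <- substr(tok, eq + 1, nchar(tok))
    out[[key]] <- gsub('^"|"$', "", val)
  }
  out
}

#' Subsample a frames file by a fixed stride
#'
#' @param path_in input extended-XYZ frames file
#' @param path_out output path
#' @param stride keep every stride-th frame
#' @return the number of frames written, invisibly
#' @export
subsample_frames <- function(path_in, path_out, stride) {
  fr <- read_frames(path_in, stride = stride)
  write_frames(fr, path_out)
  invisible(length(fr))
}
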