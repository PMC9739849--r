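#' Extract sub-ensembles from per-frame state assignments
#'
#' Groups frames by the unperturbed label assigned to one perturbed state,
#' applying the discard policy for mixed and dark frames; weights are
#' renormalized over retained frames.
#'
#' @param assignments character vector, one assigned label per frame
#'   (entries "mixed" and "dark-discard" follow the policy)
#' @param frame_indices optional frame identifiers (default sequential)
#' @param discard_mixed,discard_dark drop frames labelled "mixed" /
#'   "dark-discard"
#' @param source trajectory tag recorded on each sub-ensemble
#' @return list of `subensemble` objects (label, frame_indices, weight,
#'   source); attribute `discarded` counts dropped frames by reason
#' @export
extract_subensembles <- function(assignments, frame_indices = NULL,
                                 discard_mixed = TRUE, discard_dark = TRUE,
                                 source = "ground-state") {
  n <- length(assignments)
  if (n == 0) stop("extract_subensembles: no assignments")
  if (is.null(frame_indices)) frame_indices <- seq_len(n) - 1L
  drop <- rep(FALSE, n)
  if (discard_mixed) drop <- drop | assignments == "mixed"
  if (discard_dark) drop <- drop | assignments == "dark-discard"
  kept <- which(!drop)
  if (length(kept) == 0)
    stop("extract_subensembles: empty ensemble, all frames discarded")
  groups <- split(frame_indices[kept], assignments[kept])
  out <- lapply(names(groups), function(lab) {
    structure(list(label = lab, frame_indices = groups[[lab]],
                   weight = length(groups[[lab]]) / length(kept),
                   source = source),
              class = "subensemble")
  })
  names(out) <- names(groups)
  attr(out, "discarded") <- c(mixed = sum(assignments == "mixed" & drop),
                              dark = sum(assignments == "dark-discard" & drop))
  attr(out, "n_total") <- n
  out
}

#' @export
print.subensemble <- function(x, ...) {
  cat(sprintf("Sub-ensemble '%s' (%s): %d frames, weight %.4f\n", x$label,
              x$source, length(x$frame_indices), x$weight))
  invisible(x)
}

#' Projection statistics over an ensemble of frames
#'
#' Per-unperturbed-state means of the squared projections of one perturbed
#' state, and a normalized 2D histogram of a chosen pair of projections on
#' the unit square.
#'
#' @param projections2 frames x unperturbed-states matrix of squared
#'   projections (rows sum to 1)
#' @param pair length-2 vector of column names or indices for the histogram
#' @param nbins histogram bins per axis on [0, 1]
#' @return list with `means` (named vector) and `histogram` (nbins x nbins
#'   matrix summing to 1, breaks attached), `pair`
#' @export
projection_statistics <- function(projections2, pair = NULL, nbins = 25) {
  p2 <- as.matrix(projections2)
  if (nrow(p2) < 1) stop("projection_statistics: need at least one frame")
  means <- colMeans(p2)
  hist2 <- NULL
  if (is.null(pair)) pair <- utils::head(seq_len(ncol(p2)), 2)
  if (length(pair) == 2) {
    br <- seq(0, 1, length.out = nbins + 1)
    ix <- pmin(pmax(findInterval(p2[, pair[1]], br, rightmost.closed = TRUE), 1), nbins)
    iy <- pmin(pmax(findInterval(p2[, pair[2]], br, rightmost.closed = TRUE), 1), nbins)
    hist2 <- matrix(0, nbins, nbins)
    for (k in seq_along(ix)) hist2[ix[k], iy[k]] <- hist2[ix[k], iy[k]] + 1
    hist2 <- hist2 / sum(hist2)
    attr(hist2, "breaks") <- br
  }
  list(means = means, histogram = hist2, pair = pair)
}
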