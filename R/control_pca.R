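#' PCA of control-probe intensities (technical variance)
#'
#' Array control probes capture technical variation only (bisulfite
#' conversion, staining, hybridization, negative controls), so principal
#' components of their raw intensities summarize batch structure without
#' touching biology. PCA is performed with centering but no scaling, on the
#' full set of samples whose scores will be needed (controls and cases
#' jointly by default; fit on controls only and project cases via
#' `fit_ids` if leakage is a concern). The sign of each component is fixed by
#' making the largest-magnitude loading entry positive, so results are
#' reproducible across platforms.
#'
#' @param intensities Numeric matrix, samples x control-probe features
#'   (e.g. 847 probes x 2 channels = 1694 columns on the 450K platform).
#' @param fit_ids Optional character vector of sample ids (rownames) used to
#'   fit the rotation; all samples are always scored.
#' @return Object of class `technical_pca`: list with `scores` (samples x K),
#'   `loadings`, `var_frac` (non-increasing, sums to <= 1), `center`,
#'   `fit_ids`.
#' @export
fit_control_pca <- function(intensities, fit_ids = NULL) {
  if (!is.matrix(intensities) || nrow(intensities) < 2)
    stop("need a samples x features matrix with >= 2 samples")
  if (is.null(rownames(intensities)))
    rownames(intensities) <- paste0("sample", seq_len(nrow(intensities)))
  fit <- if (is.null(fit_ids)) intensities else {
    missing <- setdiff(fit_ids, rownames(intensities))
    if (length(missing) > 0) stop("fit_ids not in matrix: ",
                                  paste(missing, collapse = ", "))
    intensities[fit_ids, , drop = FALSE]
  }
  if (all(apply(fit, 2, stats::sd) == 0)) stop("no variance in control probes")
  pc <- stats::prcomp(fit, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  # deterministic sign: largest-magnitude entry of each loading positive
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2, flip, `*`)
  centered <- sweep(intensities, 2, pc$center, `-`)
  scores <- centered %*% rot
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = rot, var_frac = var_frac,
                 center = pc$center,
                 fit_ids = rownames(fit)),
            class = "technical_pca")
}

#' @export
print.technical_pca <- function(x, ...) {
  cat(sprintf("Control-probe PCA: %d samples, %d components (fit on %d samples)\n",
              nrow(x$scores), ncol(x$scores), length(x$fit_ids)))
  cat("Variance fractions (first 5):",
      paste(sprintf("%.3f", utils::head(x$var_frac, 5)), collapse = " "), "\n")
  invisible(x)
}

#' Choose the number of technical PCs by the scree elbow
#'
#' The elbow is the scree point with the maximum perpendicular distance to the
#' straight line joining the first and last scree points; ties break toward
#' the smaller index (an exactly linear scree yields K = 1). Pass `override`
#' to force a specific K (e.g. 17, the value appropriate for the full 450K
#' blood mega-cohort this methodology was developed on).
#'
#' @param variance_fractions Numeric vector of per-PC variance fractions
#'   (length >= 3).
#' @param override Optional integer forcing the returned K.
#' @return Integer K.
#' @export
choose_n_pcs <- function(variance_fractions, override = NULL) {
  if (!is.null(override)) {
    override <- as.integer(override)
    if (override < 1 || override > length(variance_fractions))
      stop("override outside 1..", length(variance_fractions))
    return(override)
  }
  n <- length(variance_fractions)
  if (n < 3) stop("need >= 3 scree points")
  x <- seq_len(n)
  y <- variance_fractions
  # perpendicular distance from (x_i, y_i) to the chord (1, y1) -- (n, yn)
  dx <- n - 1
  dy <- y[n] - y[1]
  d <- abs(dy * (x - 1) - dx * (y - y[1])) / sqrt(dx^2 + dy^2)
  if (max(d) <= .Machine$double.eps^0.5 * max(1, abs(y[1]))) return(1L)
  which.max(d)                      # which.max already breaks ties low
}
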