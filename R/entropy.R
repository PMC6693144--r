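#' Shannon methylation entropy
#'
#' Per-sample normalized Shannon entropy of beta values:
#' `Entropy = (1 / (N * log2(1/2))) * sum_i [ beta_i*log2(beta_i) +
#' (1-beta_i)*log2(1-beta_i) ]`, i.e. the mean binary entropy across probes.
#' It equals 1 when every beta is 0.5 and 0 when every beta is 0 or 1. Terms
#' with beta exactly 0 or 1 contribute 0 (the `0*log(0) = 0` convention);
#' set `clip` to a small positive value to instead clamp betas into
#' `[clip, 1-clip]` for noisy inputs. Missing betas are excluded per sample
#' and `n_used` reduced accordingly.
#'
#' Entropy is very sensitive to batch effects, especially over small probe
#' sets; compare batches before interpreting differences.
#'
#' @param betas Beta matrix (probes x samples).
#' @param probe_subset Optional character vector restricting the probes used
#'   (e.g. the clock CpG sites).
#' @param clip Optional positive clamp; `NULL` (default) uses the exact
#'   convention.
#' @return data.frame with `sample_id`, `entropy` (in \[0,1\]), `n_used`.
#' @export
shannon_entropy <- function(betas, probe_subset = NULL, clip = NULL) {
  validate_beta_matrix(betas)
  if (!is.null(probe_subset)) {
    probe_subset <- intersect(probe_subset, rownames(betas))
    if (length(probe_subset) == 0) stop("empty probe subset")
    betas <- betas[probe_subset, , drop = FALSE]
  }
  b <- betas
  if (!is.null(clip)) b <- pmin(pmax(b, clip), 1 - clip)
  term <- function(p) ifelse(is.na(p) | p <= 0 | p >= 1, 0, p * log2(p))
  h <- term(b) + term(1 - b)                  # <= 0, -1 at beta = 0.5
  h[is.na(b)] <- NA
  n_used <- colSums(!is.na(b))
  if (any(n_used == 0)) stop("sample with no usable probes for entropy")
  ent <- colSums(h, na.rm = TRUE) / (n_used * log2(0.5))
  data.frame(sample_id = colnames(betas), entropy = as.numeric(ent),
             n_used = as.integer(n_used), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Spearman correlation between entropy and age
#'
#' @param entropy Per-sample values (named by sample id, or a data.frame from
#'   [shannon_entropy()]).
#' @param sheet Sample sheet (see [read_sample_sheet()]).
#' @return list with `rho`, `p`, `n`, and `degenerate` (TRUE when the
#'   correlation is undefined because one variable is constant).
#' @export
entropy_age_correlation <- function(entropy, sheet) {
  v <- as_named_values(entropy, "entropy")
  sheet <- validate_sample_sheet(sheet)
  common <- intersect(names(v), sheet$sample_id)
  if (length(common) < 3) stop("need >= 3 samples")
  age <- sheet$age[match(common, sheet$sample_id)]
  e <- v[common]
  if (stats::sd(e) == 0 || stats::sd(age) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(common),
                degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(age, e, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(common),
       degenerate = FALSE)
}

# Accept either a named vector or a data.frame carrying sample_id + a value
# column; returns a named numeric vector.
as_named_values <- function(x, column) {
  if (is.data.frame(x)) {
    if (!column %in% names(x)) {
      num <- names(x)[vapply(x, is.numeric, logical(1))]
      column <- setdiff(num, c("coverage", "n_used"))[1]
    }
    stats::setNames(x[[column]], x$sample_id)
  } else {
    if (is.null(names(x))) stop("values must be named by sample id")
    x
  }
}
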