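#' Find differentially methylated positions (DMPs)
#'
#' Per-probe ordinary least-squares models of beta values on a covariate
#' design, with the target coefficient's two-sided t-test p-value
#' Bonferroni-corrected over the probes actually tested.
#'
#' * `contrast = "age"`: `beta_i ~ Age + Sex [+ cells] [+ PCs]`, fit on
#'   control samples; the Age coefficient (beta units per year) is extracted.
#'   Probes whose methylation increases with age are labelled `hyper`,
#'   decreasing ones `hypo`.
#' * `contrast = "disease"`: `beta_i ~ Disease_status + Age + Sex [+ cells]
#'   [+ PCs]`, fit on controls plus the cases of `case_label`
#'   (`Disease_status` coded case = 1), extracting the case-shift coefficient
#'   in beta units, so probes hypomethylated in the disorder get negative
#'   coefficients.
#'
#' Probes with zero variance or missing values across the modelled samples
#' are excluded (reported via message); all remaining probes share one QR
#' decomposition, so the scan is fast.
#'
#' @param betas Beta matrix (probes x samples).
#' @param sheet Sample sheet.
#' @param pcs,n_pcs,composition Covariates as in [control_model()].
#' @param contrast `"age"` or `"disease"`.
#' @param case_label Disorder label defining cases for the disease contrast.
#' @param alpha Bonferroni significance level (default 0.01).
#' @return data.frame of class `dmp_table`: `probe_id`, `coef`, `se`, `t`,
#'   `p`, `p_adjusted`, `direction` (`hyper`/`hypo`), `significant`; the
#'   number of probes tested and the contrast are carried as attributes.
#' @export
find_dmps <- function(betas, sheet, pcs = NULL, n_pcs = "auto",
                      composition = NULL, contrast = c("age", "disease"),
                      case_label = NULL, alpha = 0.01) {
  contrast <- match.arg(contrast)
  validate_beta_matrix(betas)
  sheet <- validate_sample_sheet(sheet)
  dat <- build_model_frame(sheet, pcs, n_pcs, composition)
  design_cols <- attr(dat, "design_cols")
  if (contrast == "age") {
    dat <- dat[dat$group == "control", , drop = FALSE]
    target <- "Age"
  } else {
    if (is.null(case_label)) stop("case_label required for the disease contrast")
    dat <- dat[dat$group %in% c("control", case_label), , drop = FALSE]
    if (!any(dat$group == case_label)) stop("no cases with label ", case_label)
    if (!any(dat$group == "control")) stop("no controls present")
    dat$Disease_status <- as.numeric(dat$group == case_label)
    design_cols <- c("Disease_status", design_cols)
    target <- "Disease_status"
  }
  keep <- intersect(colnames(betas), dat$sample_id)
  dat <- dat[match(keep, dat$sample_id), , drop = FALSE]
  Y <- t(betas[, keep, drop = FALSE])          # samples x probes
  X <- cbind(`(Intercept)` = 1, as.matrix(dat[design_cols]))
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("rank-deficient design; check covariates: ",
         paste(design_cols, collapse = ", "))
  usable <- apply(Y, 2, function(v) !anyNA(v) && stats::sd(v) > 0)
  if (any(!usable))
    message(sum(!usable), " probe(s) excluded (zero variance or missing values)")
  Y <- Y[, usable, drop = FALSE]
  if (ncol(Y) == 0) stop("no testable probes")
  coefs <- qr.coef(qrx, Y)                     # p x probes
  res <- Y - X %*% coefs
  df <- nrow(X) - qrx$rank
  if (df < 1) stop("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrx))
  ti <- match(target, colnames(X))
  se <- sqrt(sigma2 * xtx_inv[ti, ti])
  b <- coefs[ti, ]
  tval <- b / se
  p <- 2 * stats::pt(-abs(tval), df)
  out <- data.frame(probe_id = colnames(Y), coef = as.numeric(b),
                    se = as.numeric(se), t = as.numeric(tval),
                    p = as.numeric(p),
                    p_adjusted = pmin(1, p * ncol(Y)),
                    direction = ifelse(b >= 0, "hyper", "hypo"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$p_adjusted < alpha
  attr(out, "contrast") <- contrast
  attr(out, "target") <- target
  attr(out, "n_tested") <- ncol(Y)
  attr(out, "alpha") <- alpha
  class(out) <- c("dmp_table", class(out))
  out
}

#' Intersect aging and disease DMP tables by direction
#'
#' Partitions the shared probe universe by (aging direction x disease
#' direction) among significant probes, plus aging-only, disease-only and
#' neither. The `hypo_hypo` subset (hypomethylated both with age and in the
#' disorder) is the one of main mechanistic interest.
#'
#' @param aging,disease `dmp_table`s over the same probe universe.
#' @return list of class `dmp_intersection` with `counts` (named integer
#'   vector) and `subsets` (named list of probe-id vectors); subsets are
#'   disjoint and their union is the universe.
#' @export
intersect_dmps <- function(aging, disease) {
  ua <- sort(aging$probe_id)
  ud <- sort(disease$probe_id)
  if (!identical(ua, ud)) {
    asym <- c(setdiff(ua, ud), setdiff(ud, ua))
    stop("probe universes differ; asymmetric probes: ",
         paste(utils::head(asym, 10), collapse = ", "))
  }
  lab <- function(tab) {
    out <- stats::setNames(rep("ns", nrow(tab)), tab$probe_id)
    out[tab$probe_id[tab$significant]] <-
      tab$direction[tab$significant]
    out
  }
  la <- lab(aging)[ua]
  ld <- lab(disease)[ua]
  key <- paste(la, ld, sep = "_")
  subset_names <- c(hyper_hyper = "hyper_hyper", hyper_hypo = "hyper_hypo",
                    hypo_hyper = "hypo_hyper", hypo_hypo = "hypo_hypo",
                    aging_hyper_only = "hyper_ns", aging_hypo_only = "hypo_ns",
                    disease_hyper_only = "ns_hyper",
                    disease_hypo_only = "ns_hypo", neither = "ns_ns")
  subsets <- lapply(subset_names, function(k) ua[key == k])
  counts <- vapply(subsets, length, integer(1))
  stopifnot(sum(counts) == length(ua))
  structure(list(counts = counts, subsets = subsets, universe = ua),
            class = "dmp_intersection")
}

#' @export
print.dmp_intersection <- function(x, ...) {
  cat("DMP direction intersection over", length(x$universe), "probes:\n")
  print(x$counts)
  invisible(x)
}

#' Quadratic beta-trajectory models for clock CpG sites
#'
#' For each clock probe, fits `beta_i ~ Age + Age^2 + Sex [+ cells] [+ PCs]`
#' on control samples; the quadratic term accommodates the non-linear
#' relationship between age and methylation at many clock sites. Case
#' deviations (observed minus predicted beta, on the beta scale) are then
#' obtained with [case_deviations()].
#'
#' @param betas Beta matrix restricted to (or containing) the clock probes.
#' @param sheet Sample sheet; controls are the training set.
#' @param clock_probes Character vector of probe ids to model.
#' @param pcs,n_pcs,composition Covariates as in [control_model()].
#' @return Object of class `clock_site_profiles`: coefficient matrix
#'   (probes x terms) plus the design description. A warning is issued with
#'   fewer than 10 training controls.
#' @export
fit_clock_site_profiles <- function(betas, sheet, clock_probes = rownames(betas),
                                    pcs = NULL, n_pcs = "auto",
                                    composition = NULL) {
  validate_beta_matrix(betas)
  sheet <- validate_sample_sheet(sheet)
  probes <- intersect(clock_probes, rownames(betas))
  if (length(probes) == 0) stop("no clock probes present")
  dat <- build_model_frame(sheet, pcs, n_pcs, composition)
  dat$Age2 <- dat$Age^2
  design_cols <- append(attr(dat, "design_cols"), "Age2",
                        after = match("Age", attr(dat, "design_cols")))
  train <- dat[dat$group == "control", , drop = FALSE]
  if (nrow(train) < 10)
    warning("fewer than 10 controls; fitted curves will have wide variance")
  keep <- intersect(colnames(betas), train$sample_id)
  train <- train[match(keep, train$sample_id), , drop = FALSE]
  Y <- t(betas[probes, keep, drop = FALSE])
  X <- cbind(`(Intercept)` = 1, as.matrix(train[design_cols]))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("rank-deficient design for clock-site profiles")
  coefs <- qr.coef(qrx, Y)
  structure(list(coefficients = t(coefs),   # probes x terms
                 terms = colnames(X),
                 design_cols = design_cols,
                 n_pcs = attr(dat, "n_pcs"),
                 with_ccc = !is.null(composition),
                 training_ids = keep),
            class = "clock_site_profiles")
}

#' @rdname fit_clock_site_profiles
#' @param profiles A `clock_site_profiles` fit.
#' @param sample_ids Samples (typically cases) to score; defaults to all
#'   columns of `betas`.
#' @return `case_deviations()` returns a probes x samples matrix of observed
#'   minus predicted betas.
#' @export
case_deviations <- function(profiles, betas, sheet, sample_ids = colnames(betas),
                            pcs = NULL, composition = NULL) {
  stopifnot(inherits(profiles, "clock_site_profiles"))
  dat <- build_model_frame(validate_sample_sheet(sheet), pcs,
                           profiles$n_pcs, composition)
  dat$Age2 <- dat$Age^2
  dat <- dat[match(intersect(sample_ids, dat$sample_id), dat$sample_id), ,
             drop = FALSE]
  miss <- setdiff(profiles$design_cols, names(dat))
  if (length(miss) > 0)
    stop("missing covariate(s): ", paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = 1, as.matrix(dat[profiles$design_cols]))
  pred <- profiles$coefficients %*% t(X)       # probes x samples
  colnames(pred) <- dat$sample_id
  obs <- betas[rownames(profiles$coefficients), dat$sample_id, drop = FALSE]
  obs - pred
}

#' @export
print.clock_site_profiles <- function(x, ...) {
  cat(sprintf("Clock-site quadratic profiles: %d probes, design ~ %s (%d controls)\n",
              nrow(x$coefficients), paste(x$design_cols, collapse = " + "),
              length(x$training_ids)))
  invisible(x)
}
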