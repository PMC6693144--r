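#' Fit a control model and derive per-sample acceleration
#'
#' The central estimator of the package. A linear model of a per-sample
#' response (epigenetic age, entropy, a mitotic score, ...) is fit by least
#' squares on the *control* samples:
#'
#' `response ~ Age + Sex [+ Gran + CD4T + CD8T + B + Mono + NK] [+ PC1..PCK]`
#'
#' Cell proportions enter when `composition` is supplied; technical PCs enter
#' when `pcs` is supplied. Control samples get their residuals as
#' acceleration; every other sample gets `observed - predicted` under the
#' control coefficients (no refitting). The median absolute control residual
#' (MAE) summarizes model calibration.
#'
#' @param response Named numeric vector (sample id -> value), or a data.frame
#'   with `sample_id` plus a value column (e.g. from [evaluate_clock()]).
#' @param sheet Sample sheet; rows with `group == "control"` form the training
#'   set.
#' @param pcs Optional [fit_control_pca()] object, or a samples x K score
#'   matrix with sample ids as rownames.
#' @param n_pcs Number of leading PCs to include when `pcs` is given;
#'   `"auto"` (default) picks the scree elbow via [choose_n_pcs()].
#' @param composition Optional samples x cell-types proportion matrix (e.g. a
#'   `cell_composition`). If proportions sum to one, the last cell-type column
#'   is dropped to keep the design full rank (reported via message).
#' @param response_label Label stored on the result (e.g. `"DNAmAge"`).
#' @param train_age_range Optional `c(min, max)` restricting training
#'   controls to an age window (years).
#' @return Object of class `control_model`: list with the underlying `lm`
#'   fit, `acceleration` (named vector over all scored samples), `mae`,
#'   `coefficients`, `training_ids`, `n_pcs`, `with_ccc`, `response_label`.
#' @export
control_model <- function(response, sheet, pcs = NULL, n_pcs = "auto",
                          composition = NULL, response_label = "response",
                          train_age_range = NULL) {
  sheet <- validate_sample_sheet(sheet)
  y <- as_named_values(response, response_label)
  dat <- build_model_frame(sheet, pcs, n_pcs, composition)
  design_cols <- attr(dat, "design_cols")
  k <- attr(dat, "n_pcs")
  common <- intersect(names(y), dat$sample_id)
  missing_resp <- setdiff(dat$sample_id, names(y))
  dat <- dat[match(common, dat$sample_id), , drop = FALSE]
  dat$.response <- as.numeric(y[common])

  train <- dat$group == "control"
  if (!is.null(train_age_range))
    train <- train & dat$age >= train_age_range[1] & dat$age <= train_age_range[2]
  if (sum(train) < length(design_cols) + 1)
    stop("too few control samples to fit the model")
  if (diff(range(dat$age[train])) <= 0) stop("control ages span zero range")

  fml <- stats::as.formula(paste(".response ~",
                                 paste(design_cols, collapse = " + ")))
  fit <- stats::lm(fml, data = dat[train, , drop = FALSE])
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  pred <- stats::predict(fit, newdata = dat)
  accel <- stats::setNames(dat$.response - pred, dat$sample_id)
  mae <- stats::median(abs(accel[dat$sample_id[train]]))
  structure(list(fit = fit,
                 acceleration = accel,
                 mae = mae,
                 coefficients = stats::coef(fit),
                 training_ids = dat$sample_id[train],
                 design_cols = design_cols,
                 n_pcs = k,
                 with_ccc = !is.null(composition),
                 response_label = response_label,
                 sheet = dat[, c("sample_id", "age", "sex", "batch", "group")],
                 dropped_samples = missing_resp),
            class = "control_model")
}

#' Epigenetic age acceleration (EAA) model
#'
#' Convenience wrapper around [control_model()] with DNAmAge (years) as the
#' response: controls' EAA are the model residuals, cases' EAA is the
#' difference between their DNAmAge and the control-model prediction, and the
#' MAE (median absolute control EAA, in years) measures calibration. Positive
#' EAA means the blood epigenome looks older than expected for the
#' chronological age.
#'
#' @inheritParams control_model
#' @param dnam_age Per-sample epigenetic age in years (named vector or the
#'   data.frame from [evaluate_clock()]).
#' @return Object of class `c("eaa_model", "control_model")`; the
#'   `acceleration` component holds per-sample EAA in years.
#' @export
eaa_model <- function(dnam_age, sheet, pcs = NULL, n_pcs = "auto",
                      composition = NULL, train_age_range = NULL) {
  m <- control_model(dnam_age, sheet, pcs = pcs, n_pcs = n_pcs,
                     composition = composition, response_label = "DNAmAge",
                     train_age_range = train_age_range)
  class(m) <- c("eaa_model", class(m))
  m
}

# Assemble the per-sample model frame: Age, Sex indicator (male = 1), cell
# proportions, PC scores. Returns the data plus design column metadata.
build_model_frame <- function(sheet, pcs, n_pcs, composition) {
  dat <- data.frame(sample_id = sheet$sample_id, age = sheet$age,
                    sex = sheet$sex, batch = sheet$batch, group = sheet$group,
                    stringsAsFactors = FALSE)
  dat$Age <- dat$age
  dat$Sex <- as.numeric(dat$sex == "male")
  design_cols <- c("Age", "Sex")
  if (!is.null(composition)) {
    pm <- if (inherits(composition, "cell_composition") || is.matrix(composition))
      unclass(composition) else as.matrix(composition)
    keep <- intersect(dat$sample_id, rownames(pm))
    if (length(keep) < nrow(dat))
      stop("missing cell composition for sample(s): ",
           paste(utils::head(setdiff(dat$sample_id, keep), 5), collapse = ", "))
    pm <- pm[dat$sample_id, , drop = FALSE]
    if (max(abs(rowSums(pm) - 1)) < 1e-8) {
      message("proportions sum to one; dropping cell type '",
              colnames(pm)[ncol(pm)], "' from the design")
      pm <- pm[, -ncol(pm), drop = FALSE]
    }
    cn <- make.names(colnames(pm))
    dat[cn] <- pm
    design_cols <- c(design_cols, cn)
  }
  k <- 0L
  if (!is.null(pcs)) {
    scores <- if (inherits(pcs, "technical_pca")) pcs$scores else as.matrix(pcs)
    k <- if (identical(n_pcs, "auto")) {
      if (inherits(pcs, "technical_pca")) choose_n_pcs(pcs$var_frac)
      else ncol(scores)
    } else as.integer(n_pcs)
    k <- min(k, ncol(scores))
    miss <- setdiff(dat$sample_id, rownames(scores))
    if (length(miss) > 0)
      stop("missing PC scores for sample(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    sc <- scores[dat$sample_id, seq_len(k), drop = FALSE]
    colnames(sc) <- paste0("PC", seq_len(k))
    dat[colnames(sc)] <- sc
    design_cols <- c(design_cols, colnames(sc))
  }
  attr(dat, "design_cols") <- design_cols
  attr(dat, "n_pcs") <- k
  dat
}

#' @export
print.control_model <- function(x, ...) {
  cat(sprintf("Control model: %s ~ %s\n", x$response_label,
              paste(x$design_cols, collapse = " + ")))
  cat(sprintf("  training controls: %d; scored samples: %d\n",
              length(x$training_ids), length(x$acceleration)))
  cat(sprintf("  MAE (median |control residual|): %.4f\n", x$mae))
  invisible(x)
}

#' @export
summary.control_model <- function(object, ...) {
  s <- summary(object$fit, ...)
  cat(sprintf("Control model for %s (%s cell-composition correction, %d PCs)\n",
              object$response_label, if (object$with_ccc) "with" else "without",
              object$n_pcs))
  cat(sprintf("MAE over %d training controls: %.4f\n\n",
              length(object$training_ids), object$mae))
  print(s$coefficients)
  invisible(s)
}

#' @export
coef.control_model <- function(object, ...) object$coefficients

#' @export
residuals.control_model <- function(object, ...)
  object$acceleration[object$training_ids]

#' Predict the expected response for new samples
#'
#' @param object A `control_model`.
#' @param sheet Sample sheet for the new samples.
#' @param pcs,composition Covariates matching those used at fit time.
#' @param ... Unused.
#' @return Named numeric vector of predictions.
#' @export
predict.control_model <- function(object, sheet = NULL, pcs = NULL,
                                  composition = NULL, ...) {
  if (is.null(sheet)) return(stats::predict(object$fit))
  dat <- build_model_frame(validate_sample_sheet(sheet), pcs,
                           object$n_pcs, composition)
  miss <- setdiff(object$design_cols, names(dat))
  if (length(miss) > 0)
    stop("missing covariate(s) for prediction: ", paste(miss, collapse = ", "))
  stats::setNames(stats::predict(object$fit, newdata = dat), dat$sample_id)
}

#' Extract per-sample acceleration
#'
#' @param object A `control_model` / `eaa_model`.
#' @param groups Optional group labels to restrict to.
#' @return data.frame `sample_id`, `group`, `age`, `acceleration`, `role`
#'   (`"control-residual"` or `"case-prediction-difference"`).
#' @export
acceleration <- function(object, groups = NULL) {
  stopifnot(inherits(object, "control_model"))
  sh <- object$sheet
  out <- data.frame(sample_id = sh$sample_id, group = sh$group, age = sh$age,
                    acceleration = as.numeric(object$acceleration[sh$sample_id]),
                    role = ifelse(sh$sample_id %in% object$training_ids,
                                  "control-residual",
                                  "case-prediction-difference"),
                    stringsAsFactors = FALSE)
  if (!is.null(groups)) out <- out[out$group %in% groups, , drop = FALSE]
  out
}

#' @export
plot.control_model <- function(x, ...) {
  a <- acceleration(x)
  is_ctrl <- a$group == "control"
  graphics::plot(a$age, a$acceleration,
                 col = ifelse(is_ctrl, "grey60", "orange"),
                 pch = 19, cex = 0.6, xlab = "Age (years)",
                 ylab = paste(x$response_label, "acceleration"), ...)
  graphics::abline(h = 0, lty = 2)
  graphics::legend("topleft", legend = c("control", "case"),
                   col = c("grey60", "orange"), pch = 19, bty = "n")
  invisible(x)
}

#' Acceleration model for entropy or mitotic scores
#'
#' Fits the same control-model machinery with the response swapped (e.g.
#' Shannon entropy or pcgtAge instead of DNAmAge), always with cell
#' composition and technical PCs when supplied; case acceleration is
#' observed minus predicted.
#'
#' @inheritParams control_model
#' @return A `control_model` with the requested `response_label`.
#' @export
fit_acceleration <- function(response, sheet, pcs = NULL, n_pcs = "auto",
                             composition = NULL,
                             response_label = "Entropy") {
  control_model(response, sheet, pcs = pcs, n_pcs = n_pcs,
                composition = composition, response_label = response_label)
}
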