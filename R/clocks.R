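#' Horvath-style age transform
#'
#' Epigenetic clocks of the Horvath family are trained on a transformed age
#' scale that is logarithmic before reproductive age (`adult_age`, 20 years in
#' humans) and linear afterwards:
#' `F(age) = log((age + 1) / (adult_age + 1))` for `age <= adult_age`, and
#' `(age - adult_age) / (adult_age + 1)` otherwise. The transform is
#' continuous with a continuous first derivative (`1 / (adult_age + 1)`) at
#' `adult_age`.
#'
#' @param age Chronological age in years (must exceed -1).
#' @param adult_age Anchor age in years (default 20).
#' @return Transformed age (unitless).
#' @export
transform_age <- function(age, adult_age = 20) {
  if (any(age <= -1)) stop("age must be > -1")
  ifelse(age <= adult_age,
         log((age + 1) / (adult_age + 1)),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname transform_age
#' @param t Transformed-age value.
#' @return `inverse_transform_age()` returns age in years.
#' @export
inverse_transform_age <- function(t, adult_age = 20) {
  ifelse(t <= 0,
         exp(t) * (adult_age + 1) - 1,
         t * (adult_age + 1) + adult_age)
}

#' Construct a clock definition
#'
#' A linear epigenetic clock: a raw score `intercept + sum_j w_j * beta_j` is
#' computed from probe betas and mapped to years through the declared
#' transform (`"log-linear"` applies [inverse_transform_age()]; `"identity"`
#' reports the raw score as years directly).
#'
#' @param name Clock name.
#' @param intercept Intercept on the transformed-age scale.
#' @param coefficients Named numeric vector, probe id -> weight.
#' @param transform `"log-linear"` or `"identity"`.
#' @param adult_age Anchor age (years) for the log-linear transform.
#' @return An object of class `clock_definition`.
#' @export
clock_definition <- function(name, intercept, coefficients,
                             transform = c("log-linear", "identity"),
                             adult_age = 20) {
  transform <- match.arg(transform)
  if (is.null(names(coefficients)) || anyDuplicated(names(coefficients)))
    stop("coefficients must be uniquely named by probe id")
  if (transform == "log-linear" && adult_age <= 0)
    stop("adult_age must be positive for the log-linear transform")
  structure(list(name = name, intercept = intercept,
                 coefficients = coefficients, transform = transform,
                 adult_age = adult_age),
            class = "clock_definition")
}

#' @export
print.clock_definition <- function(x, ...) {
  cat(sprintf("Linear epigenetic clock '%s': %d probes, %s transform (adult_age = %g)\n",
              x$name, length(x$coefficients), x$transform, x$adult_age))
  invisible(x)
}

#' Read / write a clock definition file
#'
#' The format is CSV with a metadata header of `#key=value` lines (`name`,
#' `intercept`, `transform`, `adult_age`) followed by `probe_id,coefficient`
#' rows. Published coefficient sets are supplied by the user in this format;
#' the package does not embed them.
#'
#' @param path File path.
#' @return A `clock_definition`.
#' @export
read_clock_definition <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- strsplit(sub("^#", "", l), "=", fixed = TRUE)[[1]]
    meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- utils::read.csv(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  if (!all(c("probe_id", "coefficient") %in% names(body)))
    stop("clock file needs probe_id and coefficient columns")
  coefs <- stats::setNames(as.numeric(body$coefficient),
                           as.character(body$probe_id))
  clock_definition(name = meta$name %||% "unnamed",
                   intercept = as.numeric(meta$intercept %||% 0),
                   coefficients = coefs,
                   transform = meta$transform %||% "log-linear",
                   adult_age = as.numeric(meta$adult_age %||% 20))
}

#' @rdname read_clock_definition
#' @param clock A `clock_definition` to write.
#' @export
write_clock_definition <- function(clock, path) {
  header <- c(sprintf("#name=%s", clock$name),
              sprintf("#intercept=%.17g", clock$intercept),
              sprintf("#transform=%s", clock$transform),
              sprintf("#adult_age=%.17g", clock$adult_age),
              "probe_id,coefficient")
  rows <- sprintf("%s,%.17g", names(clock$coefficients), clock$coefficients)
  writeLines(c(header, rows), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a linear epigenetic clock
#'
#' Computes per-sample DNAmAge: the raw score is `intercept + sum w_j beta_j`
#' over the clock probes found in the matrix, mapped to years via the clock's
#' transform. Under the `"available-only"` policy missing clock probes are
#' skipped (the raw score uses the available subset) and the per-sample probe
#' coverage is reported; a warning is issued whenever coverage is below 1,
#' since missing probes can offset the predictions.
#'
#' @param betas Beta matrix (probes x samples).
#' @param clock A [clock_definition()].
#' @param missing_policy `"available-only"` (default) or `"fail"`.
#' @return data.frame with `sample_id`, `dnam_age` (years), `coverage`.
#' @export
evaluate_clock <- function(betas, clock,
                           missing_policy = c("available-only", "fail")) {
  missing_policy <- match.arg(missing_policy)
  validate_beta_matrix(betas)
  probes <- names(clock$coefficients)
  present <- probes[probes %in% rownames(betas)]
  absent <- setdiff(probes, present)
  if (missing_policy == "fail" && length(absent) > 0)
    stop("missing clock probes: ", paste(absent, collapse = ", "))
  if (length(present) == 0) stop("no clock probes present in beta matrix")
  w <- clock$coefficients[present]
  sub <- betas[present, , drop = FALSE]
  avail <- !is.na(sub)
  raw <- clock$intercept + colSums(sub * w, na.rm = TRUE)
  coverage <- colSums(avail) / length(probes)
  if (any(coverage < 1))
    warning(sprintf("clock '%s': %d/%d samples evaluated with incomplete probe coverage",
                    clock$name, sum(coverage < 1), ncol(betas)))
  age <- if (clock$transform == "log-linear")
    inverse_transform_age(raw, clock$adult_age) else raw
  data.frame(sample_id = colnames(betas), dnam_age = as.numeric(age),
             coverage = as.numeric(coverage), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Mitotic-clock score (pcgtAge)
#'
#' The mitotic clock scores a sample as the unweighted mean beta over a fixed
#' set of Polycomb-group-target promoter probes; higher values track a higher
#' number of lifetime cell divisions in the tissue.
#'
#' @param betas Beta matrix (probes x samples).
#' @param probe_set Character vector of probe ids constituting the score.
#' @return data.frame with `sample_id`, `pcgt_age` (mean beta, in \[0,1\]),
#'   `coverage` (fraction of `probe_set` available).
#' @export
pcgt_age <- function(betas, probe_set) {
  if (length(probe_set) == 0) stop("probe_set is empty")
  validate_beta_matrix(betas)
  present <- intersect(probe_set, rownames(betas))
  if (length(present) == 0)
    stop("no overlap between probe_set and beta matrix")
  sub <- betas[present, , drop = FALSE]
  score <- colMeans(sub, na.rm = TRUE)
  coverage <- colSums(!is.na(sub)) / length(probe_set)
  data.frame(sample_id = colnames(betas), pcgt_age = as.numeric(score),
             coverage = as.numeric(coverage), stringsAsFactors = FALSE,
             row.names = NULL)
}
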