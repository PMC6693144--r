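#' Construct a cell-type reference
#'
#' Mean beta profiles of purified leukocyte populations, used for
#' reference-based deconvolution. Default blood panel labels are Gran, CD4T,
#' CD8T, B, Mono, NK.
#'
#' @param profiles Numeric matrix (probes x cell types) of mean betas in
#'   \[0,1\], with rownames (probe ids) and colnames (cell-type labels).
#' @return Object of class `cell_type_reference` (the validated matrix).
#' @export
cell_type_reference <- function(profiles) {
  if (!is.matrix(profiles) || ncol(profiles) < 2)
    stop("reference needs a matrix with >= 2 cell types")
  if (is.null(rownames(profiles)) || is.null(colnames(profiles)))
    stop("reference needs probe ids (rownames) and cell-type labels (colnames)")
  if (anyDuplicated(rownames(profiles))) stop("duplicate probe ids in reference")
  if (any(profiles < 0 | profiles > 1)) stop("reference betas must lie in [0,1]")
  if (qr(profiles)$rank < ncol(profiles))
    warning("reference profiles are collinear; estimates may be non-unique")
  structure(profiles, class = c("cell_type_reference", "matrix", "array"))
}

#' Estimate cell composition by constrained least squares
#'
#' Reference-based (Houseman-style) deconvolution: for each sample the
#' proportions `p` minimize `||beta - R p||^2` subject to `p >= 0` and the
#' chosen sum constraint. `"sum-le-one"` (the default, matching common
#' implementations) allows the proportions to sum to at most 1;
#' `"sum-to-one"` forces an exact simplex solution. The solver is
#' deterministic: nonnegative least squares for the relaxed problem, and exact
#' active-set enumeration (KKT solve per support) when the sum constraint is
#' binding. Results are independent of probe order.
#'
#' @param betas Beta matrix (probes x samples).
#' @param reference A [cell_type_reference()] (probes x cell types).
#' @param constraint `"sum-le-one"` or `"sum-to-one"`.
#' @return Object of class `cell_composition`: a samples x cell-types matrix
#'   of proportions with attribute `constraint`.
#' @export
estimate_cell_composition <- function(betas, reference,
                                      constraint = c("sum-le-one", "sum-to-one")) {
  constraint <- match.arg(constraint)
  validate_beta_matrix(betas)
  shared <- intersect(rownames(betas), rownames(reference))
  k <- ncol(reference)
  if (length(shared) < k)
    stop(sprintf("only %d probes shared between betas and reference; need >= %d",
                 length(shared), k))
  if (k > 15) stop("active-set enumeration supports at most 15 cell types")
  shared <- sort(shared)            # canonical order: probe-order invariance
  R <- unclass(reference)[shared, , drop = FALSE]
  B <- betas[shared, , drop = FALSE]
  out <- matrix(NA_real_, ncol(B), k,
                dimnames = list(colnames(B), colnames(reference)))
  for (j in seq_len(ncol(B))) {
    y <- B[, j]
    ok <- !is.na(y)
    out[j, ] <- solve_constrained_ls(R[ok, , drop = FALSE], y[ok], constraint)
  }
  structure(out, constraint = constraint,
            class = c("cell_composition", "matrix", "array"))
}

# min ||R p - y||^2 s.t. p >= 0 and (sum-to-one: 1'p = 1 | sum-le-one: 1'p <= 1)
solve_constrained_ls <- function(R, y, constraint) {
  k <- ncol(R)
  if (constraint == "sum-le-one") {
    p <- as.numeric(pracma::lsqnonneg(R, y)$x)
    if (sum(p) <= 1 + 1e-10) return(pmax(p, 0))
  }
  # optimum lies on the simplex face sum(p) = 1: enumerate supports and solve
  # the equality-constrained KKT system on each; keep the feasible minimum.
  best <- NULL
  best_obj <- Inf
  for (size in seq_len(k)) {
    combs <- utils::combn(k, size)
    for (c_i in seq_len(ncol(combs))) {
      S <- combs[, c_i]
      Rs <- R[, S, drop = FALSE]
      G <- crossprod(Rs)
      kkt <- rbind(cbind(2 * G, rep(1, size)), c(rep(1, size), 0))
      rhs <- c(2 * crossprod(Rs, y), 1)
      sol <- tryCatch(solve(kkt, rhs), error = function(e) {
        warning("rank-deficient reference; using minimum-norm solution")
        as.numeric(MASS::ginv(kkt) %*% rhs)
      })
      ps <- sol[seq_len(size)]
      if (any(ps < -1e-9)) next
      obj <- sum((Rs %*% ps - y)^2)
      if (obj < best_obj - 1e-12) {
        best_obj <- obj
        best <- numeric(k)
        best[S] <- pmax(ps, 0)
      }
    }
  }
  if (is.null(best)) stop("no feasible solution found")
  best / max(sum(best), 1)          # exact renormalization of tiny drift
}

#' @export
print.cell_composition <- function(x, ...) {
  cat(sprintf("Cell composition estimates: %d samples x %d cell types (%s)\n",
              nrow(x), ncol(x), attr(x, "constraint")))
  print(utils::head(unclass(x)))
  invisible(x)
}

#' Benchmark deconvolution estimates against known composition
#'
#' Summarizes deviations between estimated and true proportions per cell type
#' and pooled: mean absolute deviation (MAD) and root mean squared error
#' (RMSE). Strategies are compared by pooled RMSE.
#'
#' @param estimates,truth Samples x cell-types matrices with matching
#'   dimnames (e.g. a `cell_composition` and the generator's ground truth).
#' @return list with `per_type` (data.frame: cell_type, mad, rmse) and
#'   `overall` (mad, rmse over all entries).
#' @export
benchmark_deconvolution <- function(estimates, truth) {
  estimates <- unclass(estimates)
  truth <- unclass(truth)
  if (!identical(dim(estimates), dim(truth)) ||
      !identical(colnames(estimates), colnames(truth)) ||
      !identical(rownames(estimates), rownames(truth)))
    stop("estimates and truth must share samples and cell-type labels")
  d <- estimates - truth
  per_type <- data.frame(cell_type = colnames(d),
                         mad = colMeans(abs(d)),
                         rmse = sqrt(colMeans(d^2)),
                         row.names = NULL, stringsAsFactors = FALSE)
  list(per_type = per_type,
       overall = c(mad = mean(abs(d)), rmse = sqrt(mean(d^2))))
}
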