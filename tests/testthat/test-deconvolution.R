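make_ref <- function(k = 2, m = 20, seed = 1) {
  set.seed(seed)
  r <- matrix(runif(m * k, 0.05, 0.95), m, k,
              dimnames = list(sprintf("p%03d", 1:m), paste0("T", 1:k)))
  cell_type_reference(r)
}

test_that("noiseless mixtures are recovered exactly", {
  ref <- make_ref(2)
  y <- unclass(ref) %*% c(0.6, 0.4)
  betas <- make_betas(y, probes = rownames(ref), samples = "mix")
  for (con in c("sum-le-one", "sum-to-one")) {
    est <- estimate_cell_composition(betas, ref, constraint = con)
    expect_lt(max(abs(est[1, ] - c(0.6, 0.4))), 1e-6)
  }
})

test_that("a pure reference column yields a unit vector", {
  ref <- make_ref(3, seed = 2)
  betas <- make_betas(unclass(ref)[, 2, drop = FALSE],
                      probes = rownames(ref), samples = "pure")
  est <- estimate_cell_composition(betas, ref, constraint = "sum-to-one")
  expect_lt(max(abs(est[1, ] - c(0, 1, 0))), 1e-6)
})

test_that("estimates match a 1e-3 grid-search oracle for 2 types", {
  set.seed(7)
  ref <- make_ref(2, seed = 3)
  R <- unclass(ref)
  for (i in 1:4) {
    w <- c(runif(1, 0, 0.7), runif(1, 0, 0.3))
    y <- as.numeric(R %*% w + rnorm(nrow(R), 0, 0.02))
    betas <- make_betas(matrix(pmin(pmax(y, 0), 1)), probes = rownames(ref))
    est <- estimate_cell_composition(betas, ref)
    grid <- oracle_grid_deconv2(R, pmin(pmax(y, 0), 1))
    expect_lt(max(abs(est[1, ] - grid)), 2e-3)
  }
})

test_that("noisy 6-type mixtures beat the truth's objective and stay feasible", {
  b <- simulate_deconv_benchmark(n_samples = 15, noise_sd = 0.01, seed = 4)
  for (con in c("sum-le-one", "sum-to-one")) {
    est <- estimate_cell_composition(b$betas, b$reference, constraint = con)
    expect_true(all(est >= -1e-12))
    if (con == "sum-to-one") expect_equal(unname(rowSums(est)), rep(1, 15))
    else expect_true(all(rowSums(est) <= 1 + 1e-8))
    R <- unclass(b$reference)
    for (j in 1:15) {
      obj_est <- sum((b$betas[, j] - R %*% est[j, ])^2)
      obj_truth <- sum((b$betas[, j] - R %*% b$truth[j, ])^2)
      expect_lte(obj_est, obj_truth + 1e-10)
    }
  }
})

test_that("a probe constant across cell types does not change the estimate", {
  ref <- make_ref(3, seed = 5)
  y <- unclass(ref) %*% c(0.5, 0.3, 0.2)
  betas <- make_betas(y, probes = rownames(ref))
  est1 <- estimate_cell_composition(betas, ref, constraint = "sum-to-one")

  r2 <- rbind(unclass(ref), extra = rep(0.4, 3))
  # the constant probe contributes 0.4 to any simplex mixture
  b2 <- make_betas(rbind(y, extra = 0.4), probes = rownames(r2))
  est2 <- estimate_cell_composition(b2, suppressWarnings(cell_type_reference(r2)),
                                    constraint = "sum-to-one")
  expect_lt(max(abs(est1 - est2)), 1e-8)
})

test_that("degenerate references and probe shortage are reported", {
  r <- matrix(c(0.2, 0.4, 0.2, 0.4), 2, 2,
              dimnames = list(c("p1", "p2"), c("A", "B")))
  expect_warning(cell_type_reference(r), "collinear")
  ref <- make_ref(3, m = 20)
  betas <- make_betas(matrix(0.5, 2, 1), probes = c("p001", "p002"))
  expect_error(estimate_cell_composition(betas, ref), "need >= 3")
})

test_that("benchmark deviations follow the definitions", {
  est <- matrix(0.2, 3, 6, dimnames = list(paste0("s", 1:3), paste0("T", 1:6)))
  b <- benchmark_deconvolution(est, est)
  expect_true(all(b$per_type$mad == 0))
  expect_equal(unname(b$overall["rmse"]), 0)

  # +0.1 on one type, -0.1 on another, one sample: pooled MAD = 0.2/6
  tr <- est; tr[1, 1] <- tr[1, 1] + 0.1; tr[1, 2] <- tr[1, 2] - 0.1
  b2 <- benchmark_deconvolution(est[1, , drop = FALSE], tr[1, , drop = FALSE])
  expect_equal(unname(b2$overall["mad"]), 0.1 * 2 / 6)

  set.seed(6)
  e <- matrix(runif(18), 3, 6, dimnames = dimnames(est))
  e <- e / rowSums(e)
  b3 <- benchmark_deconvolution(e, est)
  expect_equal(unname(b3$overall["rmse"]), sqrt(mean((e - est)^2)))
  expect_error(benchmark_deconvolution(e, est[, 6:1]), "labels")
})
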