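test_that("a response equal to age is fit exactly", {
  sh <- make_sheet(40)
  y <- setNames(sh$age, sh$sample_id)
  m <- control_model(y, sh, response_label = "DNAmAge")
  expect_equal(unname(coef(m)["Age"]), 1, tolerance = 1e-10)
  expect_lt(max(abs(residuals(m))), 1e-10)
  expect_equal(m$mae, 0, tolerance = 1e-10)

  m2 <- control_model(y + 3, sh)
  expect_equal(unname(coef(m2)["(Intercept)"]), 3, tolerance = 1e-10)
  expect_lt(max(abs(residuals(m2))), 1e-10)
})

test_that("control residuals sum to zero and are orthogonal to the design", {
  set.seed(10)
  sh <- make_sheet(80)
  y <- setNames(sh$age + rnorm(80, 0, 3), sh$sample_id)
  pcs <- matrix(rnorm(160), 80, 2, dimnames = list(sh$sample_id, NULL))
  m <- control_model(y, sh, pcs = pcs, n_pcs = 2)
  r <- residuals(m)
  expect_lt(abs(sum(r)), 1e-8 * length(r))
  X <- model.matrix(m$fit)
  expect_lt(max(abs(crossprod(X, r))), 1e-7)
})

test_that("case acceleration is observed minus control-model prediction", {
  set.seed(12)
  n <- 60
  sh <- make_sheet(n)
  sh$group[51:60] <- "DIS"
  y <- setNames(sh$age + rnorm(n, 0, 1), sh$sample_id)
  # construct one case to sit exactly 7.64 years above its prediction
  m0 <- control_model(y, sh)
  pred <- predict(m0, sh)
  y["s051"] <- pred["s051"] + 7.64
  m <- eaa_model(y, sh)
  expect_equal(unname(m$acceleration["s051"]), 7.64, tolerance = 1e-10)
  a <- acceleration(m)
  expect_setequal(a$role[a$group == "DIS"], "case-prediction-difference")
})

test_that("the MAE of an adult cohort with 2-year noise matches the half-normal median", {
  cfg <- simulation_config(n_controls = 500, cases = c(X = 0),
                           age_range = c(20, 55), case_age_range = c(20, 55),
                           batch_offset_sd_years = 0, n_batches = 1,
                           clock_resid_sd_years = 2, seed = 31)
  sim <- simulate_cohort(cfg)
  dn <- evaluate_clock(sim$betas, sim$clock)
  m <- eaa_model(dn, sim$sheet)
  expect_equal(m$mae, 2 * 0.6745, tolerance = 0.15)
})

test_that("sum-to-one compositions drop one cell type with a message", {
  set.seed(13)
  sh <- make_sheet(50)
  comp <- matrix(rgamma(50 * 3, 2), 50, 3,
                 dimnames = list(sh$sample_id, c("Gran", "CD4T", "B")))
  comp <- comp / rowSums(comp)
  y <- setNames(sh$age + rnorm(50), sh$sample_id)
  expect_message(m <- control_model(y, sh, composition = comp),
                 "dropping cell type")
  expect_true(m$with_ccc)
  expect_true(all(c("Gran", "CD4T") %in% names(coef(m))))
  expect_false("B" %in% names(coef(m)))
})

test_that("degenerate designs raise informative errors", {
  sh <- make_sheet(20)
  y <- setNames(sh$age, sh$sample_id)
  pcs <- matrix(rep(sh$age, 2), 20, 2, dimnames = list(sh$sample_id, NULL))
  expect_error(control_model(y, sh, pcs = pcs, n_pcs = 2), "collinear|rank")
  sh2 <- sh; sh2$age <- 30
  expect_error(control_model(setNames(rnorm(20), sh2$sample_id), sh2),
               "zero range")
  pcs3 <- matrix(rnorm(10), 5, 2,
                 dimnames = list(sh$sample_id[1:5], NULL))
  expect_error(control_model(y, sh, pcs = pcs3, n_pcs = 2), "missing PC scores")
})

test_that("acceleration models recover constructed shifts in other responses", {
  set.seed(14)
  n <- 80
  sh <- make_sheet(n)
  sh$group[71:80] <- "DIS"
  ent <- setNames(0.4 + 0.001 * sh$age + rnorm(n, 0, 0.005), sh$sample_id)
  ent[71:80] <- ent[71:80] - 0.05
  m <- fit_acceleration(ent, sh, response_label = "Entropy")
  expect_lt(abs(unname(coef(m)["Age"]) - 0.001), 5e-4)
  med <- median(m$acceleration[sh$sample_id[71:80]])
  expect_lt(abs(med + 0.05), 0.01)
})
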