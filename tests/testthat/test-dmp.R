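make_dmp_cohort <- function(n = 200, seed = 25) {
  set.seed(seed)
  sh <- make_sheet(n, age = runif(n, 0, 55))
  list(sheet = sh)
}

test_that("an exact linear age trend is recovered to numerical precision", {
  co <- make_dmp_cohort()
  n <- nrow(co$sheet)
  b <- rbind(0.3 + 0.005 * co$sheet$age,
             rep(0.5, n),
             0.6 - 0.002 * co$sheet$age)
  bm <- make_betas(b, probes = c("up", "flat", "down"),
                   samples = co$sheet$sample_id)
  expect_message(dt <- find_dmps(bm, co$sheet, contrast = "age"),
                 "excluded")
  expect_false("flat" %in% dt$probe_id)      # zero-variance probe dropped
  expect_equal(dt$coef[dt$probe_id == "up"], 0.005, tolerance = 1e-8)
  expect_equal(dt$direction[dt$probe_id == "up"], "hyper")
  expect_true(dt$significant[dt$probe_id == "up"])
  expect_equal(dt$direction[dt$probe_id == "down"], "hypo")
  expect_equal(attr(dt, "n_tested"), 2)
})

test_that("disease contrasts recover constructed case shifts with sign symmetry", {
  set.seed(26)
  n <- 80
  sh <- make_sheet(n); sh$group[61:80] <- "DIS"
  base <- runif(n, 0.4, 0.6)
  b <- rbind(base - 0.2 * (sh$group == "DIS"),
             runif(n))
  bm <- make_betas(b, probes = c("shift", "noise"), samples = sh$sample_id)
  dt <- find_dmps(bm, sh, contrast = "disease", case_label = "DIS")
  expect_lt(abs(dt$coef[dt$probe_id == "shift"] + 0.2), 0.06)
  expect_equal(dt$direction[dt$probe_id == "shift"], "hypo")

  # swapping the case/control labels flips the coefficient sign only
  sh2 <- sh; sh2$group <- ifelse(sh$group == "DIS", "control", "DIS")
  dt2 <- find_dmps(bm, sh2, contrast = "disease", case_label = "DIS")
  expect_equal(dt2$coef, -dt$coef, tolerance = 1e-10)
  expect_equal(dt2$p, dt$p, tolerance = 1e-10)
})

test_that("Bonferroni adjustment uses the number of probes actually tested", {
  set.seed(27)
  co <- make_dmp_cohort(n = 100, seed = 27)
  b <- matrix(runif(20 * 100), 20, 100)
  b[1, ] <- 0.5                              # excluded
  bm <- make_betas(b, samples = co$sheet$sample_id)
  dt <- suppressMessages(find_dmps(bm, co$sheet, contrast = "age"))
  expect_equal(attr(dt, "n_tested"), 19)
  expect_equal(dt$p_adjusted, pmin(1, dt$p * 19))
})

test_that("direction intersections match brute-force set operations", {
  mk <- function(ids, sig, dir) {
    data.frame(probe_id = ids, coef = ifelse(dir == "hyper", 1, -1),
               se = 1, t = 1, p = 0.5, p_adjusted = 0.5,
               direction = dir, significant = sig, stringsAsFactors = FALSE)
  }
  ids <- paste0("p", 1:6)
  aging <- mk(ids, sig = c(F, T, T, F, T, F),
              dir = c("hyper", "hypo", "hypo", "hyper", "hypo", "hyper"))
  disease <- mk(ids, sig = c(F, T, T, T, F, F),
                dir = c("hypo", "hypo", "hypo", "hypo", "hyper", "hyper"))
  ix <- intersect_dmps(aging, disease)
  expect_equal(sort(ix$subsets$hypo_hypo), c("p2", "p3"))
  expect_equal(sum(ix$counts), 6)
  expect_equal(ix$subsets$disease_hypo_only, "p4")

  # reordering probes leaves counts bit-identical
  perm <- c(4, 2, 6, 1, 3, 5)
  ix2 <- intersect_dmps(aging[perm, ], disease[rev(perm), ])
  expect_identical(ix$counts, ix2$counts)
  expect_identical(lapply(ix$subsets, sort), lapply(ix2$subsets, sort))

  # no disease detections -> all direction intersections empty
  disease0 <- disease; disease0$significant <- FALSE
  ix0 <- intersect_dmps(aging, disease0)
  expect_equal(unname(ix0$counts["hypo_hypo"]), 0L)

  # randomized labels vs an independent set-operation oracle
  set.seed(28)
  ids <- paste0("q", 1:50)
  a <- mk(ids, sig = runif(50) < 0.4,
          dir = sample(c("hyper", "hypo"), 50, TRUE))
  d <- mk(ids, sig = runif(50) < 0.4,
          dir = sample(c("hyper", "hypo"), 50, TRUE))
  ix3 <- intersect_dmps(a, d)
  ah <- ids[a$significant & a$direction == "hypo"]
  dh <- ids[d$significant & d$direction == "hypo"]
  expect_setequal(ix3$subsets$hypo_hypo, intersect(ah, dh))
  expect_error(intersect_dmps(a, d[1:40, ]), "universes differ")
})

test_that("quadratic clock-site profiles recover exact trajectories", {
  co <- make_dmp_cohort(n = 120, seed = 29)
  sh <- co$sheet
  b1 <- 0.2 + 0.01 * sh$age - 0.0001 * sh$age^2
  b2 <- 0.7 - 0.004 * sh$age + 0.00005 * sh$age^2
  bm <- make_betas(rbind(b1, b2), probes = c("cgA", "cgB"),
                   samples = sh$sample_id)
  pr <- fit_clock_site_profiles(bm, sh)
  expect_equal(unname(pr$coefficients["cgA", c("(Intercept)", "Age", "Age2")]),
               c(0.2, 0.01, -0.0001), tolerance = 1e-8)
  # control deviations equal model residuals (zero here)
  dev <- case_deviations(pr, bm, sh)
  expect_lt(max(abs(dev)), 1e-8)
})

test_that("constant case shifts appear as constant deviations", {
  co <- make_dmp_cohort(n = 60, seed = 30)
  sh <- co$sheet
  sh2 <- rbind(sh, data.frame(sample_id = "case1", age = 33, sex = "male",
                              batch = "b1", group = "DIS"))
  b <- rbind(0.3 + 0.002 * sh2$age, 0.5 + 0.001 * sh2$age)
  b[, 61] <- b[, 61] - 0.1
  bm <- make_betas(b, probes = c("cgA", "cgB"), samples = sh2$sample_id)
  pr <- fit_clock_site_profiles(bm, sh2)
  dev <- case_deviations(pr, bm, sh2, sample_ids = "case1")
  expect_equal(unname(dev[, "case1"]), c(-0.1, -0.1), tolerance = 1e-8)
})

test_that("few controls trigger the wide-variance warning", {
  sh <- make_sheet(6)
  bm <- make_betas(matrix(runif(12), 2, 6), samples = sh$sample_id)
  expect_warning(fit_clock_site_profiles(bm, sh), "fewer than 10")
})
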