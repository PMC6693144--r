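test_that("window means follow the per-base definition on designed cases", {
  # constant track covering the whole window
  tr <- validate_signal_track(data.frame(chrom = "chr1", start = 0,
                                         end = 10000, value = 2))
  co <- data.frame(probe_id = "p1", chrom = "chr1", pos = 5000)
  expect_equal(unname(window_mean_signal(tr, co)), 2)

  # value 4 over exactly half the 401 window bases (uncovered bases count 0):
  # window [4800, 5201); cover [4800, 5000) with 4 and pad track extent
  tr2 <- validate_signal_track(data.frame(chrom = "chr1",
                                          start = c(4800, 9000),
                                          end = c(5000, 10000),
                                          value = c(4, 0)))
  expect_equal(unname(window_mean_signal(tr2, co)), 4 * 200 / 401)

  # probe on a chromosome absent from the track -> NA
  co2 <- data.frame(probe_id = "p2", chrom = "chrX", pos = 100)
  expect_true(is.na(window_mean_signal(tr, co2)))
  expect_error(window_mean_signal(tr, co, half_width = 0), "positive")
})

test_that("window means equal the per-base brute force on random tracks", {
  set.seed(32)
  for (i in 1:40) {
    n_iv <- sample(1:15, 1)
    starts <- sort(sample(0:2000, n_iv))
    ends <- starts + sample(1:120, n_iv, replace = TRUE)
    keep <- c(TRUE, starts[-1] >= cummax(ends)[-n_iv])
    tr <- validate_signal_track(data.frame(
      chrom = "chr1", start = starts[keep], end = ends[keep],
      value = round(runif(sum(keep), -3, 3), 2)))
    pos <- sample(0:2200, 3)
    co <- data.frame(probe_id = paste0("p", 1:3), chrom = "chr1", pos = pos)
    hw <- sample(c(50, 200), 1)
    got <- window_mean_signal(tr, co, half_width = hw)
    want <- vapply(pos, oracle_window_mean, numeric(1), track = tr,
                   half_width = hw)
    expect_equal(unname(got), want, tolerance = 1e-9,
                 label = paste("fixture", i))
  }
})

test_that("z-scoring and replicate aggregation follow the scale conventions", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(zscore(rep(2, 5)), "zero standard deviation")
  z <- zscore(c(4, 8, 1, 3))
  expect_equal(aggregate_replicates(cbind(z, z)), z, ignore_attr = TRUE)
  set.seed(33)
  zs <- replicate(3, zscore(rnorm(10)))
  expect_equal(aggregate_replicates(zs), rowMeans(zs))
})

test_that("RNA signal composes window means, log2(1+x) and z-scoring", {
  mk <- function(v) validate_signal_track(
    data.frame(chrom = "chr1", start = 0, end = 10000, value = v))
  co <- data.frame(probe_id = paste0("p", 1:3), chrom = "chr1",
                   pos = c(1000, 5000, 9000))
  r <- rna_signal(mk(3), mk(4), co)
  expect_equal(r$rna, rep(log2(8), 3))            # 3 + 4 summed, log2(1+7)
  expect_true(all(is.na(r$nre)))                  # constant signal: no z-score

  set.seed(34)
  vals <- round(runif(20, 0, 5), 2)
  trp <- validate_signal_track(data.frame(chrom = "chr1",
                                          start = seq(0, 9500, by = 500),
                                          end = seq(500, 10000, by = 500),
                                          value = vals))
  trm <- mk(0.5)
  r2 <- rna_signal(trp, trm, co)
  wp <- window_mean_signal(trp, co); wm <- window_mean_signal(trm, co)
  raw <- log2(1 + wp + wm)
  expect_equal(r2$rna, unname(raw))
  expect_equal(r2$nre, unname((raw - mean(raw)) / sd(raw)))
  expect_error(rna_signal(mk(-1), mk(1), co), "non-negative")
})

test_that("CGI context labels obey the stated distance rules", {
  cgi <- data.frame(chrom = "chr1", start = 10000, end = 11000)
  lab <- function(p) unname(classify_cgi_context(
    data.frame(probe_id = "x", chrom = "chr1", pos = p), cgi))
  expect_equal(lab(10500), "island")
  expect_equal(lab(10000), "island")      # first base of the island
  expect_equal(lab(11000), "shore")       # first base past the half-open end
  expect_equal(lab(11500), "shore")
  expect_equal(lab(13000), "shore")       # d exactly 2000 -> shore
  expect_equal(lab(13500), "shelf")
  expect_equal(lab(15000), "shelf")       # d exactly 4000 -> shelf
  expect_equal(lab(16000), "open-sea")
  expect_equal(lab(9999), "shore")        # upstream side, d = 1
  expect_equal(lab(7900), "shelf")
  expect_equal(lab(5000), "open-sea")
})

test_that("CGI labels partition probes and ignore record order", {
  set.seed(35)
  cgis <- data.frame(chrom = "chr1", start = c(1000, 20000, 21000),
                     end = c(2000, 20500, 22000))
  co <- data.frame(probe_id = paste0("p", 1:50), chrom = "chr1",
                   pos = sample(0:30000, 50))
  l1 <- classify_cgi_context(co, cgis)
  expect_true(all(l1 %in% c("island", "shore", "shelf", "open-sea")))
  l2 <- classify_cgi_context(co, cgis[c(3, 1, 2), ])
  expect_identical(l1, l2)
})

test_that("categorical overlap matches quadratic brute force", {
  set.seed(36)
  iv <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                   start = sample(0:5000, 30))
  iv$end <- iv$start + sample(1:400, 30, replace = TRUE)
  iv <- validate_intervals(iv)
  co <- data.frame(probe_id = paste0("p", 1:80),
                   chrom = sample(c("chr1", "chr2", "chr3"), 80, TRUE),
                   pos = sample(0:5500, 80))
  got <- overlap_categorical(co, iv)
  want <- vapply(seq_len(80), function(i) {
    any(iv$chrom == co$chrom[i] & iv$start <= co$pos[i] & co$pos[i] < iv$end)
  }, logical(1))
  expect_equal(unname(got), want)
})

test_that("Fisher enrichment matches hypergeometric enumeration and fisher.test", {
  u <- paste0("p", 1:1100)
  f <- setNames(rep(FALSE, 1100), u)
  f[1:10] <- TRUE            # 10/100 in subset
  f[101:200] <- TRUE         # 100/1000 in control
  r <- enrichment_test(u[1:100], u, f)
  expect_equal(r$odds_ratio, 1)

  u2 <- paste0("q", 1:20)
  f2 <- setNames(c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8)), u2)
  r2 <- enrichment_test(u2[1:10], u2, f2)
  expect_equal(r2$odds_ratio, 16)
  expect_equal(r2$p, fisher.test(matrix(c(8, 2, 2, 8), 2))$p.value,
               tolerance = 1e-12)

  # all probes carry the feature: Haldane correction, flagged degenerate
  f3 <- setNames(rep(TRUE, 20), u2)
  r3 <- enrichment_test(u2[1:10], u2, f3)
  expect_true(r3$degenerate)
  expect_equal(r3$odds_ratio, 1)

  # table counts always partition the universe
  set.seed(37)
  f4 <- setNames(runif(1100) < 0.3, u)
  r4 <- enrichment_test(sample(u, 200), u, f4, n_tests = 7)
  expect_equal(sum(r4$table), 1100)
  expect_equal(r4$p_adjusted, min(1, r4$p * 7))
  expect_error(enrichment_test(c("p1", "zz"), u, f4), "contained")
})

test_that("Fisher p equals fisher.test across all tables with margins <= 12", {
  for (k in 1:11) for (m in 1:12) for (a in max(0, k - m):min(k, m)) {
    n <- 12
    tab <- c(a, k - a, m - a, n - m - k + a)
    if (any(tab < 0)) next
    u <- paste0("t", seq_len(sum(tab)))
    f <- setNames(rep(c(TRUE, FALSE, TRUE, FALSE), tab), u)
    subset <- u[seq_len(tab[1] + tab[2])]
    r <- enrichment_test(subset, u, f)
    ft <- fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    expect_equal(r$p, ft, tolerance = 1e-9,
                 label = sprintf("table %d/%d/%d/%d", tab[1], tab[2], tab[3], tab[4]))
  }
})

test_that("continuous comparisons report the enumeration p and medians", {
  r <- compare_continuous(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r$p, 0.1)                    # 2 / choose(6,3)
  expect_equal(r$median_subset, 11)
  expect_equal(r$median_control, 2)
  expect_equal(c(r$n_subset, r$n_control), c(3, 3))
  rt <- compare_continuous(rep(5, 4), rep(5, 6))
  expect_true(rt$all_tied)
  expect_equal(rt$p, 1)
})
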