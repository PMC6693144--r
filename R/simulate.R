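#' Configuration for the synthetic methylation cohort generator
#'
#' The generator emulates the statistical structure of a blood 450K-style
#' methylation cohort: clock probes whose betas track the Horvath-transformed
#' age, age-drifting cell-type proportions mixed through a purified-cell
#' reference, batch offsets visible both in epigenetic age and in
#' control-probe intensities, direction-labelled aging and disease DMPs, null
#' probes, and a toy single-chromosome annotation layout (enhancers with
#' designed enrichment of hypomethylated DMPs, gene bodies, CpG islands) with
#' accompanying signal tracks.
#'
#' Defaults follow the structure of the blood cohorts this methodology was
#' designed for: ages 0-55 years, three batches, six leukocyte types
#' (Gran, CD4T, CD8T, B, Mono, NK), a clock residual sd of 2 years, aging
#' DMP slopes of 0.003 beta/year, and a disorder whose cases carry an
#' injected epigenetic age acceleration.
#'
#' @param n_controls Number of healthy control samples.
#' @param cases Named integer vector: disorder label -> number of cases.
#' @param accel_years Named numeric vector: disorder label -> injected
#'   acceleration in years (on the years scale for adult samples; on the
#'   transformed-age scale before `adult_age`).
#' @param age_range Control age range in years (default 0-55).
#' @param case_age_range Case age range (default 20-55, so the injected
#'   acceleration equals the years-scale median EAA exactly).
#' @param n_batches Number of batches; batch offsets on the years scale are
#'   equally spaced with standard deviation `batch_offset_sd_years`.
#' @param batch_offset_sd_years Spread of the batch offsets on epigenetic age
#'   (years; 0 disables beta-side batch effects).
#' @param batch_intensity_sd Spread of the per-batch control-probe intensity
#'   mean vectors (fluorescence units).
#' @param intensity_noise_sd Isotropic noise on control-probe intensities.
#' @param n_control_features Number of control-probe intensity features
#'   (847 probes x 2 channels = 1694 on the real platform; smaller default
#'   for simulation).
#' @param n_clock_probes Number of clock probes.
#' @param clock_resid_sd_years Residual sd of epigenetic age around
#'   chronological age, in years (exact for adults).
#' @param adult_age Anchor age of the age transform (default 20).
#' @param cell_types Cell-type labels.
#' @param base_props Baseline proportions (mid-cohort), summing to 1.
#' @param prop_age_drift Per-type linear drift in proportion per year
#'   (must sum to 0).
#' @param prop_conc Dirichlet concentration controlling proportion noise.
#' @param n_cell_probes Number of cell-type-sensitive probes.
#' @param n_admp_hyper,n_admp_hypo Numbers of aging DMPs gaining / losing
#'   methylation with age.
#' @param admp_slope Aging DMP slope in beta units per year.
#' @param n_disease_hyper,n_disease_hypo Numbers of disease DMPs (the shift
#'   applies to cases of the first disorder in `cases`).
#' @param disease_effect Disease DMP shift in beta units.
#' @param n_null_probes Number of null probes.
#' @param beta_noise_sd Per-probe technical noise sd on betas.
#' @param enhancer_base_rate Probability that a non-hypo probe lies in an
#'   enhancer.
#' @param enhancer_or Designed odds ratio for hypomethylated DMPs lying in
#'   enhancers.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_controls = 300,
                              cases = c(SOTOS = 20),
                              accel_years = c(SOTOS = 7.5),
                              age_range = c(0, 55),
                              case_age_range = c(20, 55),
                              n_batches = 3,
                              batch_offset_sd_years = 3,
                              batch_intensity_sd = 200,
                              intensity_noise_sd = 50,
                              n_control_features = 120,
                              n_clock_probes = 30,
                              clock_resid_sd_years = 2,
                              adult_age = 20,
                              cell_types = c("Gran", "CD4T", "CD8T", "B",
                                             "Mono", "NK"),
                              base_props = c(0.55, 0.15, 0.10, 0.08, 0.07, 0.05),
                              prop_age_drift = c(0.0020, -0.0008, -0.0006,
                                                 -0.0002, -0.0002, -0.0002),
                              prop_conc = 300,
                              n_cell_probes = 60,
                              n_admp_hyper = 60,
                              n_admp_hypo = 60,
                              admp_slope = 0.003,
                              n_disease_hyper = 8,
                              n_disease_hypo = 60,
                              disease_effect = 0.05,
                              n_null_probes = 250,
                              beta_noise_sd = 0.02,
                              enhancer_base_rate = 0.10,
                              enhancer_or = 4,
                              seed = 1) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_controls, cfg$cases, cfg$n_clock_probes, cfg$n_cell_probes,
              cfg$n_admp_hyper, cfg$n_admp_hypo, cfg$n_disease_hyper,
              cfg$n_disease_hypo, cfg$n_null_probes, cfg$n_batches,
              cfg$n_control_features)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$n_controls < 2) stop("need >= 2 controls")
  if (cfg$n_clock_probes < 2) stop("need >= 2 clock probes")
  if (cfg$n_batches < 1) stop("need >= 1 batch")
  if (is.null(names(cfg$cases)) && length(cfg$cases) > 0)
    stop("cases must be a named vector of disorder counts")
  if (!all(names(cfg$cases) %in% c(names(cfg$accel_years), names(cfg$cases)[0])) &&
      length(cfg$cases) > 0) {
    missing <- setdiff(names(cfg$cases), names(cfg$accel_years))
    cfg$accel_years[missing] <- 0
  }
  if (length(cfg$base_props) != length(cfg$cell_types) ||
      length(cfg$prop_age_drift) != length(cfg$cell_types))
    stop("base_props and prop_age_drift must match cell_types in length")
  if (abs(sum(cfg$base_props) - 1) > 1e-8) stop("base_props must sum to 1")
  if (abs(sum(cfg$prop_age_drift)) > 1e-10) stop("prop_age_drift must sum to 0")
  if (diff(cfg$age_range) <= 0 || any(cfg$age_range < 0))
    stop("invalid age_range")
  if (cfg$clock_resid_sd_years < 0 || cfg$beta_noise_sd < 0)
    stop("noise sds must be >= 0")
  if (cfg$enhancer_base_rate <= 0 || cfg$enhancer_base_rate >= 1)
    stop("enhancer_base_rate must be in (0,1)")
  structure(cfg, class = "simulation_config")
}

#' Generate a synthetic methylation cohort with recorded ground truth
#'
#' See [simulation_config()] for the generating model. Clock-probe betas are
#' bounded linear functions of a per-sample transformed-age score (true
#' transformed age + injected acceleration + batch offset + residual noise),
#' with coefficients chosen so that the bundled linear clock definition
#' inverts the construction exactly: with zero noise, zero batch effect and
#' zero acceleration, evaluating the bundled clock returns each sample's
#' chronological age to numerical precision.
#'
#' @param config A [simulation_config()].
#' @return list with components `betas` (probes x samples), `sheet`
#'   (sample sheet), `control_probes` (samples x features intensity matrix),
#'   `intensities` (list `methylated`/`unmethylated`), `coords` (probe
#'   coordinates), `intervals` (list `enhancers`, `gene_bodies`, `cgis`),
#'   `tracks` (list `fc_rep1`, `fc_rep2`, `sur_plus`, `sur_minus`),
#'   `reference` (cell-type reference), `clock` (clock definition), and
#'   `truth` (ground-truth record: proportions, accelerations, probe roles
#'   and effects, batch assignments and offsets).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  aa1 <- cfg$adult_age + 1

  ## ---- samples ----
  n_cases <- sum(cfg$cases)
  n <- cfg$n_controls + n_cases
  sample_id <- sprintf("S%05d", seq_len(n))
  group <- c(rep("control", cfg$n_controls),
             rep(names(cfg$cases), times = cfg$cases))
  age <- numeric(n)
  is_ctrl <- group == "control"
  age[is_ctrl] <- stats::runif(cfg$n_controls, cfg$age_range[1], cfg$age_range[2])
  age[!is_ctrl] <- stats::runif(n_cases, cfg$case_age_range[1],
                                cfg$case_age_range[2])
  sex <- sample(c("male", "female"), n, replace = TRUE)
  batch <- sample(paste0("batch", seq_len(cfg$n_batches)), n, replace = TRUE)

  if (cfg$n_batches > 1 && cfg$batch_offset_sd_years > 0) {
    raw <- seq(-1, 1, length.out = cfg$n_batches)
    batch_offsets <- raw / stats::sd(raw) * cfg$batch_offset_sd_years
  } else batch_offsets <- rep(0, cfg$n_batches)
  names(batch_offsets) <- paste0("batch", seq_len(cfg$n_batches))

  delta <- ifelse(is_ctrl, 0, cfg$accel_years[group])
  delta[is.na(delta)] <- 0

  ## per-sample transformed-age score driving the clock probes
  s <- transform_age(age, cfg$adult_age) +
    (delta + batch_offsets[batch]) / aa1 +
    stats::rnorm(n, 0, cfg$clock_resid_sd_years / aa1)

  ## ---- clock probes: bounded linear trajectories with an exact inverse ----
  w <- stats::runif(cfg$n_clock_probes, 0.03, 0.08) *
    sample(c(-1, 1), cfg$n_clock_probes, replace = TRUE)
  slo <- min(s) - 0.5
  shi <- max(s) + 0.5
  a <- vapply(w, function(wj) {
    lo <- 0.02 - min(wj * slo, wj * shi)
    hi <- 0.98 - max(wj * slo, wj * shi)
    stats::runif(1, lo, hi)
  }, numeric(1))
  clock_betas <- outer(a, rep(1, n)) + outer(w, s)
  cvec <- w / sum(w^2)
  clock <- clock_definition(name = "synthetic-clock",
                            intercept = -sum(cvec * a),
                            coefficients = stats::setNames(cvec, sprintf(
                              "cg%07d", seq_len(cfg$n_clock_probes))),
                            transform = "log-linear",
                            adult_age = cfg$adult_age)

  ## ---- aging DMPs ----
  max_age <- max(cfg$age_range[2], cfg$case_age_range[2])
  noise <- function(nr) matrix(stats::rnorm(nr * n, 0, cfg$beta_noise_sd), nr, n)
  ## aging drift moves betas toward 0.5 (hyper sites start low, hypo sites
  ## start high), the erosion pattern that raises methylome entropy with age
  mk_admp <- function(n_probes, sign) {
    if (n_probes == 0) return(list(b = NULL, slope = numeric(0)))
    span <- cfg$admp_slope * max_age
    base <- if (sign > 0) stats::runif(n_probes, 0.10, min(0.45, 0.90 - span))
            else stats::runif(n_probes, max(0.55, 0.10 + span), 0.90)
    b <- outer(base, rep(1, n)) + sign * cfg$admp_slope * outer(rep(1, n_probes), age)
    list(b = pmin(pmax(b + noise(n_probes), 0), 1),
         slope = rep(sign * cfg$admp_slope, n_probes))
  }
  admp_hyper <- mk_admp(cfg$n_admp_hyper, +1)
  admp_hypo <- mk_admp(cfg$n_admp_hypo, -1)

  ## ---- disease DMPs (cases of the first-named disorder) ----
  disease_label <- if (length(cfg$cases) > 0) names(cfg$cases)[1] else NA
  is_case1 <- !is.na(disease_label) & group == disease_label
  mk_ddmp <- function(n_probes, sign) {
    if (n_probes == 0) return(list(b = NULL, effect = numeric(0)))
    base <- if (sign > 0) stats::runif(n_probes, 0.15, 0.80 - cfg$disease_effect)
            else stats::runif(n_probes, 0.20 + cfg$disease_effect, 0.85)
    shift <- sign * cfg$disease_effect * outer(rep(1, n_probes), as.numeric(is_case1))
    list(b = pmin(pmax(outer(base, rep(1, n)) + shift + noise(n_probes), 0), 1),
         effect = rep(sign * cfg$disease_effect, n_probes))
  }
  dis_hyper <- mk_ddmp(cfg$n_disease_hyper, +1)
  dis_hypo <- mk_ddmp(cfg$n_disease_hypo, -1)

  ## ---- cell-type mixture probes ----
  k <- length(cfg$cell_types)
  ref <- matrix(0.10, cfg$n_cell_probes, k,
                dimnames = list(sprintf("cell%04d", seq_len(cfg$n_cell_probes)),
                                cfg$cell_types))
  sig_type <- rep(seq_len(k), length.out = cfg$n_cell_probes)
  ref[cbind(seq_len(cfg$n_cell_probes), sig_type)] <- 0.85
  ref <- pmin(pmax(ref + matrix(stats::runif(length(ref), -0.05, 0.05),
                                nrow(ref)), 0.02), 0.98)
  mid_age <- mean(cfg$age_range)
  props <- t(vapply(seq_len(n), function(i) {
    m <- pmax(cfg$base_props + cfg$prop_age_drift * (age[i] - mid_age), 0.005)
    g <- stats::rgamma(k, shape = m * cfg$prop_conc, rate = 1)
    g / sum(g)
  }, numeric(k)))
  colnames(props) <- cfg$cell_types
  rownames(props) <- sample_id
  cell_betas <- pmin(pmax(ref %*% t(props) +
                            noise(cfg$n_cell_probes), 0), 1)

  ## ---- null probes ----
  ## null probes follow the bimodal beta distribution of real arrays: most
  ## sites sit near fully unmethylated or fully methylated, a minority between
  null_betas <- if (cfg$n_null_probes > 0) {
    comp <- sample.int(3, cfg$n_null_probes, replace = TRUE,
                       prob = c(0.4, 0.4, 0.2))
    base <- c(stats::runif(cfg$n_null_probes, 0.03, 0.15),
              stats::runif(cfg$n_null_probes, 0.85, 0.97),
              stats::runif(cfg$n_null_probes, 0.30, 0.70)
              )[cfg$n_null_probes * (comp - 1) + seq_len(cfg$n_null_probes)]
    pmin(pmax(outer(base, rep(1, n)) + noise(cfg$n_null_probes), 0), 1)
  } else NULL

  ## ---- assemble beta matrix ----
  roles <- c(rep("clock", cfg$n_clock_probes),
             rep("aDMP-hyper", cfg$n_admp_hyper),
             rep("aDMP-hypo", cfg$n_admp_hypo),
             rep("disease-hyper", cfg$n_disease_hyper),
             rep("disease-hypo", cfg$n_disease_hypo),
             rep("cell", cfg$n_cell_probes),
             rep("null", cfg$n_null_probes))
  betas <- rbind(clock_betas, admp_hyper$b, admp_hypo$b, dis_hyper$b,
                 dis_hypo$b, cell_betas, null_betas)
  n_probes <- nrow(betas)
  probe_id <- sprintf("cg%07d", seq_len(n_probes))
  rownames(betas) <- probe_id
  colnames(betas) <- sample_id
  rownames(ref) <- probe_id[roles == "cell"]
  stopifnot(all(betas >= 0 & betas <= 1))
  effects <- c(rep(NA_real_, cfg$n_clock_probes),
               admp_hyper$slope, admp_hypo$slope,
               dis_hyper$effect, dis_hypo$effect,
               rep(NA_real_, cfg$n_cell_probes + cfg$n_null_probes))

  ## ---- probe coordinates and toy annotation on one synthetic chromosome ----
  pos <- 500L + 1000L * (seq_len(n_probes) - 1L)
  coords <- data.frame(probe_id = probe_id, chrom = "chrS", pos = pos,
                       stringsAsFactors = FALSE)
  hypo <- roles %in% c("aDMP-hypo", "disease-hypo")
  odds0 <- cfg$enhancer_base_rate / (1 - cfg$enhancer_base_rate)
  p1 <- cfg$enhancer_or * odds0 / (1 + cfg$enhancer_or * odds0)
  in_enh <- stats::runif(n_probes) < ifelse(hypo, p1, cfg$enhancer_base_rate)
  enhancers <- data.frame(chrom = "chrS", start = pos[in_enh] - 100L,
                          end = pos[in_enh] + 100L,
                          name = "enhancer", stringsAsFactors = FALSE)
  in_gene <- stats::runif(n_probes) < 0.3
  gene_bodies <- data.frame(chrom = "chrS", start = pos[in_gene] - 300L,
                            end = pos[in_gene] + 300L,
                            name = "gene_body", stringsAsFactors = FALSE)
  island_idx <- seq(1, n_probes, by = 10)
  cgis <- data.frame(chrom = "chrS", start = pos[island_idx] - 250L,
                     end = pos[island_idx] + 250L, name = "CGI",
                     stringsAsFactors = FALSE)

  ## ---- signal tracks (piecewise constant, 500 bp bins) ----
  chrom_len <- 1000L * n_probes + 500L
  bin_start <- seq(0L, chrom_len - 1L, by = 500L)
  bin_end <- pmin(bin_start + 500L, chrom_len)
  nb <- length(bin_start)
  bin_in_gene <- overlap_categorical(
    data.frame(probe_id = paste0("bin", seq_len(nb)), chrom = "chrS",
               pos = bin_start + 250L, stringsAsFactors = FALSE),
    gene_bodies)
  mk_track <- function(values) {
    validate_signal_track(data.frame(chrom = "chrS", start = bin_start,
                                     end = bin_end, value = values,
                                     stringsAsFactors = FALSE))
  }
  fc_rep1 <- mk_track(pmax(stats::rnorm(nb, 1, 0.3) + 1.5 * bin_in_gene, 0))
  fc_rep2 <- mk_track(pmax(stats::rnorm(nb, 1, 0.3) + 1.5 * bin_in_gene, 0))
  sur_plus <- mk_track(stats::rexp(nb, 1) + 2 * bin_in_gene)
  sur_minus <- mk_track(stats::rexp(nb, 1) + 2 * bin_in_gene)

  ## ---- control-probe intensities with batch structure ----
  base_f <- stats::rnorm(cfg$n_control_features, 2000, 100)
  mu <- matrix(stats::rnorm(cfg$n_batches * cfg$n_control_features, 0,
                            cfg$batch_intensity_sd),
               cfg$n_batches, cfg$n_control_features,
               dimnames = list(names(batch_offsets), NULL))
  if (cfg$n_batches == 1) mu[] <- 0
  control_probes <- matrix(stats::rnorm(n * cfg$n_control_features, 0,
                                        cfg$intensity_noise_sd),
                           n, cfg$n_control_features)
  control_probes <- sweep(control_probes, 2, base_f, `+`) + mu[batch, ]
  rownames(control_probes) <- sample_id
  colnames(control_probes) <- sprintf("ctrl%04d", seq_len(cfg$n_control_features))

  ## ---- whole-array intensity pair (for the QC filter) ----
  total <- matrix(stats::rnorm(n_probes * n, 4096, 300), n_probes, n)
  total <- pmax(total, 100)
  meth <- betas * total
  unmeth <- (1 - betas) * total
  dimnames(meth) <- dimnames(unmeth) <- dimnames(betas)

  sheet <- data.frame(sample_id = sample_id, age = age, sex = sex,
                      batch = batch, group = group, stringsAsFactors = FALSE)
  truth <- list(proportions = props,
                accel_years = cfg$accel_years,
                disease_label = disease_label,
                probe_roles = data.frame(probe_id = probe_id, role = roles,
                                         effect = effects,
                                         in_enhancer = in_enh,
                                         stringsAsFactors = FALSE),
                batch_offsets_years = batch_offsets,
                enhancer_rates = c(base = cfg$enhancer_base_rate, hypo = p1),
                clock = clock)
  list(betas = betas, sheet = sheet, control_probes = control_probes,
       intensities = list(methylated = meth, unmethylated = unmeth),
       coords = coords,
       intervals = list(enhancers = enhancers, gene_bodies = gene_bodies,
                        cgis = cgis),
       tracks = list(fc_rep1 = fc_rep1, fc_rep2 = fc_rep2,
                     sur_plus = sur_plus, sur_minus = sur_minus),
       reference = cell_type_reference(ref),
       clock = clock,
       truth = truth,
       config = cfg)
}

#' Generate a deconvolution benchmark
#'
#' Mixtures are exact or noisy convex combinations of reference cell-type
#' profiles with recorded true weights, for benchmarking deconvolution
#' strategies against a known gold standard.
#'
#' @param n_samples Number of mixture samples.
#' @param reference Optional [cell_type_reference()]; by default a synthetic
#'   6-type, 60-probe blood-like reference is built.
#' @param weights Optional samples x types matrix of true weights (rows on the
#'   simplex); by default Dirichlet(1) draws.
#' @param noise_sd Gaussian noise added to the mixtures (0 = exact).
#' @param seed Integer seed.
#' @return list with `betas` (probes x samples), `reference`, `truth`
#'   (samples x types weight matrix).
#' @export
simulate_deconv_benchmark <- function(n_samples = 20, reference = NULL,
                                      weights = NULL, noise_sd = 0.01,
                                      seed = 1) {
  set.seed(seed)
  if (is.null(reference)) {
    k <- 6
    ref <- matrix(0.10, 60, k,
                  dimnames = list(sprintf("cg%07d", seq_len(60)),
                                  c("Gran", "CD4T", "CD8T", "B", "Mono", "NK")))
    ref[cbind(seq_len(60), rep(seq_len(k), length.out = 60))] <- 0.85
    ref <- pmin(pmax(ref + matrix(stats::runif(length(ref), -0.05, 0.05),
                                  nrow(ref)), 0.02), 0.98)
    reference <- cell_type_reference(ref)
  }
  k <- ncol(reference)
  if (k < 2) stop("need >= 2 cell types")
  if (is.null(weights)) {
    g <- matrix(stats::rgamma(n_samples * k, 1, 1), n_samples, k)
    weights <- g / rowSums(g)
  }
  weights <- as.matrix(weights)
  if (ncol(weights) != k) stop("weights must have one column per cell type")
  colnames(weights) <- colnames(reference)
  rownames(weights) <- sprintf("M%04d", seq_len(nrow(weights)))
  mix <- unclass(reference) %*% t(weights)
  if (noise_sd > 0)
    mix <- mix + matrix(stats::rnorm(length(mix), 0, noise_sd), nrow(mix))
  mix <- pmin(pmax(mix, 0), 1)
  colnames(mix) <- rownames(weights)
  list(betas = mix, reference = reference, truth = weights)
}
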