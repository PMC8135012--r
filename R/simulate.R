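# Synthetic methylation-array data generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# ~2k-probe array (desk-scale stand-in for a ~36k mammalian array), cattle
# blood and oocyte cohorts with disjoint and divergent age-related CpG sets,
# lower non-island baseline methylation in oocytes than blood, and an
# optional second species (human blood) sharing the aging signal on the
# relative-age scale. Every dataset ships with a ground-truth table so
# recovery can be tested probe by probe.

#' Simulation configuration
#'
#' Builds the parameter list consumed by [simulate_methylation()] and
#' [simulate_isogenic_pairs()]. Defaults describe a desk-scale array of
#' 2,000 probes measured in 60 cattle blood, 40 cattle oocyte and
#' (optionally) 60 human blood samples, mirroring the composition of the
#' motivating cohorts at roughly 1/18 scale.
#'
#' Per-probe classes: `null` probes carry no age signal; `blood_up`/
#' `blood_down` (`oocyte_up`/`oocyte_down`) drift only in that tissue;
#' `shared` probes drift with the same slope in both tissues; `divergent`
#' probes drift with opposite signs, the structure a divergence classifier
#' must detect. Age signal is linear on the transformed-age scale:
#' `beta = baseline + slope * T(age) + noise`, clipped to \[0, 1\].
#'
#' @param n_probes total number of probes.
#' @param n_blood,n_oocyte cattle sample counts per tissue.
#' @param n_human_blood human blood sample count (0 disables the second
#'   species).
#' @param age_range_cattle,age_range_human sampling ranges for ages (years).
#' @param lifespan named species maximum lifespans in years.
#' @param classes named integer vector of signal-probe counts; remaining
#'   probes are null.
#' @param transform scale of the age signal: `"identity"` (beta drift per
#'   year; single-species use) or `"relative"` (drift per relative-age unit,
#'   shared across species). Default `NULL` picks `"relative"` when human
#'   samples are requested and `"identity"` otherwise.
#' @param slope_range magnitude range for per-probe slopes, in beta units per
#'   transformed-age unit. Default `NULL` picks `c(0.01, 0.03)` per year for
#'   the identity scale and `c(0.25, 0.75)` per relative-age unit for the
#'   relative scale (the latter equals roughly the former times the cattle
#'   lifespan, so the two scales describe comparable cattle-cohort drift).
#' @param noise_sd standard deviation of additive Gaussian noise on the beta
#'   scale.
#' @param island_fraction fraction of probes annotated as CpG-island probes.
#' @param baseline_island baseline beta range for island probes (both
#'   tissues; islands are lowly methylated).
#' @param baseline_blood,baseline_oocyte baseline beta ranges for non-island
#'   probes per tissue; the oocyte range sits strictly below the blood range
#'   so the generated data reproduce the lower non-island methylation of
#'   oocytes.
#' @param promoter_fraction_signal fraction of `blood_up` probes placed in
#'   promoters (makes promoter enrichment detectable).
#' @param promoter_fraction_background promoter rate among all other probes.
#' @param noise_model `"gaussian"` (additive on the beta scale, clipped) or
#'   `"logit"` (additive on the logit scale, never clips).
#' @param seed integer seed; mandatory, every draw flows from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 2000L,
                       n_blood = 60L,
                       n_oocyte = 40L,
                       n_human_blood = 0L,
                       age_range_cattle = c(0.5, 13.3),
                       age_range_human = c(1, 100),
                       lifespan = c(cattle = 38, human = 122.5),
                       classes = c(blood_up = 100L, blood_down = 100L,
                                   oocyte_up = 60L, oocyte_down = 60L,
                                   shared = 40L, divergent = 20L),
                       transform = NULL,
                       slope_range = NULL,
                       noise_sd = 0.02,
                       island_fraction = 0.3,
                       baseline_island = c(0.05, 0.25),
                       baseline_blood = c(0.5, 0.85),
                       baseline_oocyte = c(0.25, 0.6),
                       promoter_fraction_signal = 0.6,
                       promoter_fraction_background = 0.15,
                       noise_model = c("gaussian", "logit"),
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (is.null(transform))
    transform <- if (n_human_blood > 0L) "relative" else "identity"
  transform <- match.arg(transform, c("identity", "relative"))
  if (is.null(slope_range))
    slope_range <- if (transform == "relative") c(0.25, 0.75) else c(0.01, 0.03)
  known <- c("blood_up", "blood_down", "oocyte_up", "oocyte_down",
             "shared", "divergent")
  cls <- stats::setNames(integer(length(known)), known)
  cls[names(classes)] <- as.integer(classes)
  if (any(is.na(match(names(classes), known))))
    stop("unknown probe class: ",
         paste(setdiff(names(classes), known), collapse = ", "))
  if (sum(cls) > n_probes)
    stop("probe class counts exceed n_probes")
  stopifnot(noise_sd >= 0, all(slope_range >= 0), diff(slope_range) >= 0,
            island_fraction >= 0, island_fraction <= 1,
            length(seed) == 1L, is.finite(seed))
  cfg <- list(n_probes = as.integer(n_probes),
              n_blood = as.integer(n_blood),
              n_oocyte = as.integer(n_oocyte),
              n_human_blood = as.integer(n_human_blood),
              age_range_cattle = age_range_cattle,
              age_range_human = age_range_human,
              lifespan = lifespan,
              classes = cls,
              transform = transform,
              slope_range = slope_range,
              noise_sd = noise_sd,
              island_fraction = island_fraction,
              baseline_island = baseline_island,
              baseline_blood = baseline_blood,
              baseline_oocyte = baseline_oocyte,
              promoter_fraction_signal = promoter_fraction_signal,
              promoter_fraction_background = promoter_fraction_background,
              noise_model = noise_model,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# draw per-probe truth (classes, slopes, baselines, island status) and a toy
# annotation manifest consistent with it
.make_truth <- function(cfg) {
  n <- cfg$n_probes
  probe_id <- sprintf("cg%06d", seq_len(n))
  cls <- cfg$classes
  class_lab <- rep("null", n)
  idx <- sample.int(n, sum(cls))
  class_lab[idx] <- rep(names(cls), times = cls)

  island <- sample(c("island", "non_island"), n, replace = TRUE,
                   prob = c(cfg$island_fraction, 1 - cfg$island_fraction))

  mag <- stats::runif(n, cfg$slope_range[1L], cfg$slope_range[2L])
  dir_shared <- sample(c(-1, 1), n, replace = TRUE)
  slope_blood <- numeric(n)
  slope_oocyte <- numeric(n)
  slope_blood[class_lab == "blood_up"] <- mag[class_lab == "blood_up"]
  slope_blood[class_lab == "blood_down"] <- -mag[class_lab == "blood_down"]
  slope_oocyte[class_lab == "oocyte_up"] <- mag[class_lab == "oocyte_up"]
  slope_oocyte[class_lab == "oocyte_down"] <- -mag[class_lab == "oocyte_down"]
  sh <- class_lab == "shared"
  slope_blood[sh] <- dir_shared[sh] * mag[sh]
  slope_oocyte[sh] <- dir_shared[sh] * mag[sh]
  dv <- class_lab == "divergent"
  slope_blood[dv] <- dir_shared[dv] * mag[dv]
  slope_oocyte[dv] <- -dir_shared[dv] * mag[dv]

  base_blood <- ifelse(island == "island",
                       stats::runif(n, cfg$baseline_island[1L], cfg$baseline_island[2L]),
                       stats::runif(n, cfg$baseline_blood[1L], cfg$baseline_blood[2L]))
  base_oocyte <- ifelse(island == "island",
                        stats::runif(n, cfg$baseline_island[1L], cfg$baseline_island[2L]),
                        stats::runif(n, cfg$baseline_oocyte[1L], cfg$baseline_oocyte[2L]))

  # keep the noiseless trajectory inside [0.02, 0.98] over the transformed-age
  # range so clipping stays rare; the baseline is shifted, never the slope
  t_max <- if (cfg$transform == "relative") {
    max(cfg$age_range_cattle[2L] / cfg$lifespan[["cattle"]],
        if (cfg$n_human_blood > 0L)
          cfg$age_range_human[2L] / cfg$lifespan[["human"]] else 0)
  } else cfg$age_range_cattle[2L]
  feas <- function(base, slope) {
    lo <- 0.02 - pmin(0, slope * t_max)
    hi <- 0.98 - pmax(0, slope * t_max)
    pmin(pmax(base, lo), pmax(hi, lo))
  }
  base_blood <- feas(base_blood, slope_blood)
  base_oocyte <- feas(base_oocyte, slope_oocyte)

  truth <- data.frame(probe_id = probe_id,
                      class = class_lab,
                      slope_blood = slope_blood,
                      slope_oocyte = slope_oocyte,
                      baseline_blood = base_blood,
                      baseline_oocyte = base_oocyte,
                      island_status = island,
                      stringsAsFactors = FALSE)
  attr(truth, "transform") <- cfg$transform
  truth
}

# toy genome layout: genes in blocks of 8 probes along 5 chromosomes; a
# configurable share of blood_up probes lands in the promoter window so
# region enrichment is exercisable
.make_annotation <- function(cfg, truth) {
  n <- cfg$n_probes
  gene_idx <- (seq_len(n) - 1L) %/% 8L + 1L
  gene <- sprintf("GENE%04d", gene_idx)
  chrom <- paste0("chr", (gene_idx - 1L) %% 5L + 1L)
  tss <- 100000L + ((gene_idx - 1L) %/% 5L) * 200000L

  p_prom <- ifelse(truth$class == "blood_up",
                   cfg$promoter_fraction_signal,
                   cfg$promoter_fraction_background)
  is_prom <- stats::runif(n) < p_prom
  dist <- integer(n)
  dist[is_prom] <- as.integer(round(stats::runif(sum(is_prom), -10000, 1000)))
  n_out <- sum(!is_prom)
  upstream <- stats::runif(n_out) < 0.3
  d_out <- integer(n_out)
  d_out[upstream] <- as.integer(round(stats::runif(sum(upstream), -60000, -10001)))
  d_out[!upstream] <- as.integer(round(stats::runif(sum(!upstream), 1001, 60000)))
  dist[!is_prom] <- d_out

  region <- character(n)
  region[is_prom] <- "promoter"
  region[!is_prom & dist < PROMOTER_WINDOW[1L]] <- "intergenic_upstream"
  body <- !is_prom & dist > PROMOTER_WINDOW[2L]
  region[body] <- sample(c("five_prime_utr", "exon", "intron",
                           "three_prime_utr", "intergenic_downstream"),
                         sum(body), replace = TRUE,
                         prob = c(0.08, 0.22, 0.4, 0.1, 0.2))

  validate_annotation(data.frame(
    probe_id = truth$probe_id,
    chromosome = chrom,
    position = pmax(tss + dist, 1L),
    nearest_gene = gene,
    distance_to_tss = dist,
    region_class = region,
    island_status = truth$island_status,
    stringsAsFactors = FALSE))
}

# beta = baseline + slope * T(signal_age) + noise, clipped; signal_age may
# include a per-donor acceleration offset
.make_betas <- function(cfg, truth, samples, signal_age) {
  tval <- if (cfg$transform == "relative")
    signal_age / samples$max_lifespan_years else signal_age
  base <- cbind(blood = truth$baseline_blood, oocyte = truth$baseline_oocyte)
  slope <- cbind(blood = truth$slope_blood, oocyte = truth$slope_oocyte)
  ti <- match(samples$tissue, c("blood", "oocyte"))
  mu <- base[, ti, drop = FALSE] +
    slope[, ti, drop = FALSE] * rep(tval, each = nrow(truth))
  n_cell <- length(mu)
  if (cfg$noise_model == "logit") {
    eps <- matrix(stats::rnorm(n_cell, 0, cfg$noise_sd), nrow(truth))
    mu_c <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
    betas <- stats::plogis(stats::qlogis(mu_c) + eps / (mu_c * (1 - mu_c)))
    clipped <- 0
  } else {
    betas <- mu + matrix(stats::rnorm(n_cell, 0, cfg$noise_sd), nrow(truth))
    clipped <- mean(betas < 0 | betas > 1)
    betas <- pmin(pmax(betas, 0), 1)
  }
  dimnames(betas) <- list(truth$probe_id, samples$sample_id)
  attr(betas, "clipped_fraction") <- clipped
  if (clipped > 0.5)
    warning("infeasible configuration: ", round(100 * clipped, 1),
            "% of beta draws fell outside [0,1] and were clipped")
  betas
}

#' Simulate a methylation dataset with ground truth
#'
#' Draws ages uniformly on the configured per-species ranges, generates
#' betas as `baseline + slope * T(age) + noise` clipped to \[0, 1\], and
#' returns the beta matrix together with the sample table, a consistent toy
#' annotation manifest and the per-probe truth table. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param truth optional truth table from a previous run with a compatible
#'   config: reusing it fixes the array (probe classes, slopes, baselines,
#'   annotation) while redrawing samples and noise, the natural way to
#'   simulate independent cohorts measured on the same array.
#' @return list with elements `betas` (probe x sample matrix, with a
#'   `clipped_fraction` attribute), `samples`, `annotation`, `truth`.
#' @examples
#' d <- simulate_methylation(sim_config(n_probes = 100, n_blood = 10,
#'                                      n_oocyte = 10, seed = 7))
#' dim(d$betas)
#' @export
simulate_methylation <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_blood + config$n_oocyte + config$n_human_blood == 0L)
    stop("no samples requested in any tissue")
  set.seed(config$seed)
  if (is.null(truth)) {
    truth <- .make_truth(config)
    annotation <- .make_annotation(config, truth)
  } else {
    stopifnot(nrow(truth) == config$n_probes)
    annotation <- attr(truth, "annotation")
    if (is.null(annotation)) annotation <- .make_annotation(config, truth)
  }
  attr(truth, "annotation") <- annotation

  mk <- function(prefix, n, species, tissue, range, lifespan)
    if (n > 0L) data.frame(
      sample_id = sprintf("%s%03d", prefix, seq_len(n)),
      species = species, tissue = tissue,
      age_years = stats::runif(n, range[1L], range[2L]),
      max_lifespan_years = lifespan,
      donor_id = NA_character_, stringsAsFactors = FALSE)
  samples <- rbind(
    mk("cb", config$n_blood, "cattle", "blood",
       config$age_range_cattle, config$lifespan[["cattle"]]),
    mk("co", config$n_oocyte, "cattle", "oocyte",
       config$age_range_cattle, config$lifespan[["cattle"]]),
    mk("hb", config$n_human_blood, "human", "blood",
       config$age_range_human, config$lifespan[["human"]]))
  samples <- validate_sample_table(samples)

  betas <- .make_betas(config, truth, samples, samples$age_years)
  list(betas = betas, samples = samples, annotation = annotation,
       truth = truth)
}

#' Simulate isogenic blood/oocyte pairs
#'
#' Each donor contributes one blood and one oocyte sample collected at the
#' same age. A latent per-donor age-acceleration offset (years) is added to
#' the age driving the methylation signal — but not to the recorded
#' chronological age — with a configurable cross-tissue correlation `rho`,
#' so recovery of the blood/oocyte acceleration correlation can be tested
#' against a known value.
#'
#' @param config a [sim_config()]; cattle tissue counts are ignored in favor
#'   of `n_donors`.
#' @param n_donors number of donors (each yields 2 samples).
#' @param rho cross-tissue correlation of the latent acceleration offsets.
#' @param accel_sd standard deviation of the acceleration offsets in years.
#' @param truth optional fixed truth table (see [simulate_methylation()]).
#' @return as [simulate_methylation()], plus `accel`: a data.frame of the
#'   latent per-donor offsets for each tissue.
#' @export
simulate_isogenic_pairs <- function(config, n_donors = 40L, rho = 0,
                                    accel_sd = 1.5, truth = NULL) {
  stopifnot(inherits(config, "sim_config"),
            n_donors >= 2L, abs(rho) <= 1, accel_sd >= 0)
  set.seed(config$seed)
  if (is.null(truth)) {
    truth <- .make_truth(config)
    attr(truth, "annotation") <- .make_annotation(config, truth)
  }
  annotation <- attr(truth, "annotation")

  ages <- stats::runif(n_donors, config$age_range_cattle[1L],
                       config$age_range_cattle[2L])
  z1 <- stats::rnorm(n_donors)
  z2 <- stats::rnorm(n_donors)
  a_blood <- accel_sd * z1
  a_oocyte <- accel_sd * (rho * z1 + sqrt(1 - rho^2) * z2)

  donor <- sprintf("donor%03d", seq_len(n_donors))
  samples <- data.frame(
    sample_id = c(sprintf("%s_b", donor), sprintf("%s_o", donor)),
    species = "cattle",
    tissue = rep(c("blood", "oocyte"), each = n_donors),
    age_years = rep(ages, 2L),
    max_lifespan_years = config$lifespan[["cattle"]],
    donor_id = rep(donor, 2L),
    stringsAsFactors = FALSE)
  samples <- validate_sample_table(samples)

  signal_age <- pmax(rep(ages, 2L) + c(a_blood, a_oocyte), 0.05)
  betas <- .make_betas(config, truth, samples, signal_age)
  list(betas = betas, samples = samples, annotation = annotation,
       truth = truth,
       accel = data.frame(donor_id = donor, accel_blood = a_blood,
                          accel_oocyte = a_oocyte,
                          stringsAsFactors = FALSE))
}
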