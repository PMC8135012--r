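# End-to-end orchestration: simulate (or load) a dataset, train and
# cross-validate the panel of clocks, compare age acceleration in isogenic
# pairs, and run the aging EWAS with meta-analysis, divergence and
# enrichment. Produces a machine-readable summary so figures and reports
# regenerate from one JSON.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] describing the dataset to simulate. The
#'   default simulates the full three-cohort design (cattle blood, cattle
#'   oocytes, human blood) with relative-age-shared signal.
#' @param alpha elastic-net mixing parameter for all clocks.
#' @param kfold folds for the dual-species clock CV (single-tissue cattle
#'   clocks use leave-one-out).
#' @param loo_max_n above this cattle sample count, single-tissue clocks
#'   fall back from LOO to k-fold CV to bound compute.
#' @param p_threshold EWAS significance threshold.
#' @param max_per_direction top-CpG cap per direction of change.
#' @param n_donors isogenic donors for the acceleration comparison.
#' @param accel_rho injected cross-tissue acceleration correlation.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(n_human_blood = 60L, seed = 1L),
                            alpha = 0.5, kfold = 10L, loo_max_n = 150L,
                            p_threshold = 1e-4, max_per_direction = 500L,
                            n_donors = 40L, accel_rho = 0,
                            seed = 1L) {
  structure(list(sim = sim, alpha = alpha, kfold = kfold,
                 loo_max_n = loo_max_n, p_threshold = p_threshold,
                 max_per_direction = max_per_direction,
                 n_donors = n_donors, accel_rho = accel_rho,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage_seed <- function(seed, k) (seed * 131L + k) %% 2147483647L

#' Run the full analysis pipeline
#'
#' Stages, mirroring the study design: (1) simulate the dataset;
#' (2) cross-validated single-tissue cattle clocks (blood, oocyte) and the
#' dual-tissue cattle clock, all LOO; (3) dual-species clocks on years and
#' on relative age, 10-fold CV; (4) tissue-transfer check (blood clock
#' applied to oocytes); (5) isogenic blood/oocyte age-acceleration
#' correlation; (6) per-tissue EWAS, Stouffer meta-analysis, top-CpG
#' selection, divergence classes, cross-tissue Z correlation, promoter
#' enrichment, island comparisons. Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, clock files, estimate and
#'   EWAS tables and a `summary.json` are written there.
#' @return list with the dataset, clock estimate tables, evaluations, EWAS
#'   tables and a flat `summary` list of the headline numbers.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  cfg <- config$sim
  cfg$seed <- .stage_seed(seed, 1L)
  if (cfg$n_blood == 0L || cfg$n_oocyte == 0L)
    stop("pipeline requires both cattle tissues in the simulation config")
  dat <- simulate_methylation(cfg)
  betas <- dat$betas; samples <- dat$samples

  is_cattle <- samples$species == "cattle"
  sub <- function(keep) list(b = betas[, keep, drop = FALSE],
                             s = samples[keep, , drop = FALSE])
  cv_single <- function(d, k) {
    if (ncol(d$b) <= config$loo_max_n)
      loo_estimates(d$b, d$s, alpha = config$alpha, seed = k)
    else kfold_estimates(d$b, d$s, k = config$kfold, alpha = config$alpha,
                         seed = k)
  }

  blood <- sub(is_cattle & samples$tissue == "blood")
  oocyte <- sub(is_cattle & samples$tissue == "oocyte")
  cattle <- sub(is_cattle)

  est_blood <- cv_single(blood, .stage_seed(seed, 2L))
  est_oocyte <- cv_single(oocyte, .stage_seed(seed, 3L))
  est_cattle <- cv_single(cattle, .stage_seed(seed, 4L))

  evals <- list(blood_clock = evaluate_clock(est_blood),
                oocyte_clock = evaluate_clock(est_oocyte),
                cattle_dual_tissue = evaluate_clock(est_cattle, by = "tissue"))

  # dual-species clocks (when humans simulated): years and relative age
  est_dual_years <- est_dual_rel <- NULL
  if (cfg$n_human_blood > 0L) {
    est_dual_years <- kfold_estimates(betas, samples, k = config$kfold,
                                      alpha = config$alpha,
                                      seed = .stage_seed(seed, 5L))
    est_dual_rel <- kfold_estimates(betas, samples, k = config$kfold,
                                    transform = age_transform("relative"),
                                    alpha = config$alpha,
                                    seed = .stage_seed(seed, 6L))
    evals$dual_species_years <- evaluate_clock(est_dual_years, by = "species")
    evals$dual_species_relative <-
      evaluate_clock(est_dual_rel, by = "species", units = "relative")
  }

  # tissue transfer: train on blood only, apply to oocytes
  clock_blood <- train_clock(blood$b, blood$s, alpha = config$alpha,
                             seed = .stage_seed(seed, 7L))
  transfer_pred <- predict(clock_blood, oocyte$b, oocyte$s,
                           warn_range = FALSE)
  transfer_r <- if (length(clock_blood$coefficients) &&
                    stats::sd(transfer_pred) > 0)
    stats::cor(oocyte$s$age_years, transfer_pred) else 0

  # isogenic acceleration comparison on an independent cohort, predicted
  # with clocks trained on the main cohort
  iso_cfg <- cfg
  iso_cfg$seed <- .stage_seed(seed, 8L)
  iso <- simulate_isogenic_pairs(iso_cfg, n_donors = config$n_donors,
                                 rho = config$accel_rho, truth = dat$truth)
  clock_oocyte <- train_clock(oocyte$b, oocyte$s, alpha = config$alpha,
                              seed = .stage_seed(seed, 9L))
  iso_est <- function(clock, tissue) {
    keep <- iso$samples$tissue == tissue
    s <- iso$samples[keep, , drop = FALSE]
    data.frame(sample_id = s$sample_id, fold_id = NA_integer_,
               age_years = s$age_years,
               dnam_age_years = predict(clock,
                                        iso$betas[, keep, drop = FALSE],
                                        s, warn_range = FALSE),
               tissue = s$tissue, species = s$species,
               max_lifespan_years = s$max_lifespan_years,
               donor_id = s$donor_id, stringsAsFactors = FALSE)
  }
  accel <- acceleration_correlation(iso_est(clock_blood, "blood"),
                                    iso_est(clock_oocyte, "oocyte"))

  # EWAS per tissue, meta, selection, divergence, enrichment
  ew_blood <- correlation_screen(blood$b, blood$s)
  ew_oocyte <- correlation_screen(oocyte$b, oocyte$s)
  meta <- ewas_meta(ew_blood, ew_oocyte)
  sel_blood <- select_top_cpgs(ew_blood, config$p_threshold,
                               config$max_per_direction)
  sel_oocyte <- select_top_cpgs(ew_oocyte, config$p_threshold,
                                config$max_per_direction)
  sel_meta <- select_top_cpgs(meta, config$p_threshold,
                              config$max_per_direction)
  divergence <- classify_divergent(ew_blood, ew_oocyte, config$p_threshold)
  z_cor <- cross_tissue_z_correlation(ew_blood, ew_oocyte)

  background <- ew_blood$probe_id[!is.na(ew_blood$r)]
  promoters <- dat$annotation$probe_id[
    dat$annotation$region_class == "promoter"]
  enrich_prom <- feature_enrichment(
    intersect(sel_blood$hyper, background), background, promoters)

  island_blood <- island_z_comparison(ew_blood, dat$annotation)
  island_oocyte <- island_z_comparison(ew_oocyte, dat$annotation)
  meth_island <- mean_methylation_by_island(betas[, is_cattle, drop = FALSE],
                                            samples[is_cattle, , drop = FALSE],
                                            dat$annotation)

  pick <- function(ev, group) {
    row <- ev[ev$group == group, , drop = FALSE]
    c(r = row$pearson_r[1L], mae = row$mae[1L])
  }
  summary <- list(
    schema_version = 1L,
    seed = seed,
    n_probes = cfg$n_probes,
    blood_clock_r = unname(pick(evals$blood_clock, "overall")["r"]),
    blood_clock_mae_years = unname(pick(evals$blood_clock, "overall")["mae"]),
    oocyte_clock_r = unname(pick(evals$oocyte_clock, "overall")["r"]),
    oocyte_clock_mae_years = unname(pick(evals$oocyte_clock, "overall")["mae"]),
    dual_tissue_blood_r = unname(pick(evals$cattle_dual_tissue, "blood")["r"]),
    dual_tissue_oocyte_r = unname(pick(evals$cattle_dual_tissue, "oocyte")["r"]),
    transfer_blood_to_oocyte_r = transfer_r,
    accel_correlation_r = accel$r,
    accel_correlation_p = accel$p,
    accel_n_pairs = accel$n_pairs,
    ewas_blood_hyper = length(sel_blood$hyper),
    ewas_blood_hypo = length(sel_blood$hypo),
    ewas_oocyte_hyper = length(sel_oocyte$hyper),
    ewas_oocyte_hypo = length(sel_oocyte$hypo),
    ewas_meta_hyper = length(sel_meta$hyper),
    ewas_meta_hypo = length(sel_meta$hypo),
    n_divergent = sum(divergence$class == "divergent_both"),
    cross_tissue_z_r = z_cor,
    promoter_enrichment_or = enrich_prom$odds_ratio,
    promoter_enrichment_p = enrich_prom$p_value,
    island_z_t_blood = island_blood$t,
    island_z_t_oocyte = island_oocyte$t)
  if (!is.null(est_dual_rel)) {
    summary$dual_species_relative_cattle_r <-
      unname(pick(evals$dual_species_relative, "cattle")["r"])
    summary$dual_species_relative_human_r <-
      unname(pick(evals$dual_species_relative, "human")["r"])
    summary$dual_species_years_cattle_r <-
      unname(pick(evals$dual_species_years, "cattle")["r"])
    summary$dual_species_years_human_r <-
      unname(pick(evals$dual_species_years, "human")["r"])
  }

  result <- list(data = dat,
                 estimates = list(blood = est_blood, oocyte = est_oocyte,
                                  cattle = est_cattle,
                                  dual_years = est_dual_years,
                                  dual_relative = est_dual_rel),
                 clocks = list(blood = clock_blood, oocyte = clock_oocyte),
                 evaluations = evals,
                 acceleration = accel,
                 ewas = list(blood = ew_blood, oocyte = ew_oocyte,
                             meta = meta),
                 selection = list(blood = sel_blood, oocyte = sel_oocyte,
                                  meta = sel_meta),
                 divergence = divergence,
                 enrichment = list(promoter_blood_hyper = enrich_prom),
                 island = list(z_blood = island_blood,
                               z_oocyte = island_oocyte,
                               methylation = meth_island),
                 summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_beta_matrix(betas, file.path(out_dir, "betas.tsv"))
    write_sample_sheet(samples, file.path(out_dir, "samples.tsv"))
    write_annotation(dat$annotation, file.path(out_dir, "annotation.tsv"))
    utils::write.table(dat$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_clock(clock_blood, file.path(out_dir, "clock_blood.tsv"))
    write_clock(clock_oocyte, file.path(out_dir, "clock_oocyte.tsv"))
    write_ewas(ew_blood, file.path(out_dir, "ewas_blood.tsv"))
    write_ewas(ew_oocyte, file.path(out_dir, "ewas_oocyte.tsv"))
    write_ewas(meta, file.path(out_dir, "ewas_meta.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
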