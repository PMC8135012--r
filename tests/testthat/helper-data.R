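# small fixtures built in code

tiny_samples <- function(n, tissue = "blood", species = "cattle",
                         ages = NULL, lifespan = 38, prefix = "s",
                         donor = NA_character_) {
  if (is.null(ages)) ages <- seq(1, 12, length.out = n)
  data.frame(sample_id = sprintf("%s%03d", prefix, seq_len(n)),
             species = species, tissue = tissue, age_years = ages,
             max_lifespan_years = lifespan, donor_id = donor,
             stringsAsFactors = FALSE)
}

tiny_betas <- function(n_probes, sample_ids, values = NULL, seed = 1) {
  set.seed(seed)
  m <- matrix(if (is.null(values)) runif(n_probes * length(sample_ids))
              else values,
              nrow = n_probes, ncol = length(sample_ids))
  dimnames(m) <- list(sprintf("cg%05d", seq_len(n_probes)), sample_ids)
  m
}

tiny_annotation <- function(probe_ids, island = NULL, region = NULL,
                            dist = NULL, gene = "GENE1", chrom = "chr1",
                            tss = 100000L) {
  n <- length(probe_ids)
  if (is.null(dist)) dist <- rep(-5000L, n)
  if (is.null(region))
    region <- ifelse(dist >= -10000 & dist <= 1000, "promoter", "intron")
  if (is.null(island)) island <- rep("non_island", n)
  data.frame(probe_id = probe_ids, chromosome = chrom,
             position = tss + dist, nearest_gene = gene,
             distance_to_tss = dist, region_class = region,
             island_status = island, stringsAsFactors = FALSE)
}

# small simulated dataset reused by several tests
small_sim <- function(seed = 3, noise_sd = 0.02, n_blood = 30L,
                      n_oocyte = 20L, ...) {
  simulate_methylation(sim_config(
    n_probes = 300L, n_blood = n_blood, n_oocyte = n_oocyte,
    classes = c(blood_up = 25L, blood_down = 25L, oocyte_up = 15L,
                oocyte_down = 15L, shared = 10L, divergent = 5L),
    noise_sd = noise_sd, seed = seed, ...))
}
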