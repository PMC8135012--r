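# independent per-probe oracle: scalar statistics from first principles
screen_oracle <- function(b, age) {
  r <- cor(b, age)
  n <- length(age)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(abs(t), n - 2, lower.tail = FALSE)
  z <- sign(r) * qnorm(p / 2, lower.tail = FALSE)
  c(r = r, t = t, p = p, z = z)
}

test_that("screen statistics match the hand-computable example", {
  age <- 1:5
  s <- tiny_samples(5, ages = age)
  b <- matrix(c(2, 1, 4, 3, 5) / 10, nrow = 1,
              dimnames = list("cgA", s$sample_id))
  ew <- correlation_screen(b, s)
  expect_equal(ew$r, 0.8, tolerance = 1e-10)
  expect_equal(ew$t, 0.8 * sqrt(3) / sqrt(1 - 0.64), tolerance = 1e-10)
  o <- screen_oracle(b[1, ], age)
  expect_equal(ew$p, unname(o["p"]), tolerance = 1e-10)
  expect_equal(ew$z, unname(o["z"]), tolerance = 1e-10)
  expect_identical(ew$n, 5L)
})

test_that("screen agrees with the per-probe oracle on random data", {
  set.seed(20)
  n <- 30
  s <- tiny_samples(n, ages = runif(n, 0.5, 13.3))
  b <- tiny_betas(200, s$sample_id, seed = 21)
  b[1:50, ] <- pmin(pmax(b[1:50, ] * 0.1 +
    outer(runif(50, -0.02, 0.02), s$age_years) + 0.4, 0), 1)
  ew <- correlation_screen(b, s)
  for (i in seq_len(nrow(b))) {
    o <- screen_oracle(b[i, ], s$age_years)
    expect_equal(ew$r[i], unname(o["r"]), tolerance = 1e-10)
    expect_equal(ew$t[i], unname(o["t"]), tolerance = 1e-10)
    expect_equal(ew$p[i], unname(o["p"]), tolerance = 1e-10)
    expect_equal(ew$z[i], unname(o["z"]), tolerance = 1e-10)
  }
})

test_that("screen handles perfect correlation and constant probes", {
  s <- tiny_samples(8)
  b <- rbind(cg_perfect = 0.01 * s$age_years,
             cg_flat = rep(0.5, 8),
             cg_anti = 0.9 - 0.01 * s$age_years)
  colnames(b) <- s$sample_id
  expect_message(ew <- correlation_screen(b, s), "1 constant probe")
  expect_equal(ew$r[1], 1)
  expect_gt(ew$p[1], 0)            # underflow-guarded, never exactly 0
  expect_lte(abs(ew$z[1]), 37.1)   # documented |Z| cap
  expect_true(all(is.na(ew[ew$probe_id == "cg_flat", c("r", "p", "z")])))
  expect_equal(ew$r[3], -1)
  expect_equal(ew$z[3], -ew$z[1])
  expect_error(correlation_screen(b[, 1:3], s[1:3, ]), "4 samples")
})

test_that("sign(z) follows sign(r) and p decreases in |t|", {
  set.seed(22)
  s <- tiny_samples(25, ages = runif(25, 1, 13))
  b <- tiny_betas(300, s$sample_id, seed = 23)
  ew <- correlation_screen(b, s)
  nz <- !is.na(ew$r) & ew$r != 0
  expect_true(all(sign(ew$z[nz]) == sign(ew$r[nz])))
  o <- order(abs(ew$t[nz]))
  expect_true(all(diff(ew$p[nz][o]) <= 1e-15))
})

test_that("Stouffer combination obeys its closed forms", {
  expect_equal(stouffer_meta(2, 2), 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(stouffer_meta(1.5, -1.5), 0)
  expect_equal(stouffer_meta(2, 0, weights = c(sqrt(100), sqrt(25))),
               20 / sqrt(125), tolerance = 1e-12)
  set.seed(24)
  for (i in 1:25) {
    z <- rnorm(2); w <- runif(2, 0.1, 5)
    expect_equal(stouffer_meta(z[1], z[2], w),
                 (w[1] * z[1] + w[2] * z[2]) / sqrt(w[1]^2 + w[2]^2),
                 tolerance = 1e-12)
    # symmetric in tissue order under equal weights
    expect_equal(stouffer_meta(z[1], z[2]), stouffer_meta(z[2], z[1]))
  }
  # |z_meta| grows with each |z_i| at fixed signs
  z_grid <- seq(0.5, 5, by = 0.5)
  expect_true(all(diff(stouffer_meta(z_grid, 1)) > 0))
  expect_true(is.na(stouffer_meta(NA, 2)))
})

test_that("meta table joins tissues and propagates undefined probes", {
  d <- small_sim(seed = 25)
  ewb <- correlation_screen(d$betas, d$samples, tissue = "blood")
  ewo <- correlation_screen(d$betas, d$samples, tissue = "oocyte")
  m <- ewas_meta(ewb, ewo)
  expect_equal(m$z_meta, (ewb$z + ewo$z) / sqrt(2), tolerance = 1e-12)
  expect_true(all(c("z_blood", "z_oocyte", "p_meta") %in% names(m)))
  expect_error(ewas_meta(ewb, ewo[1:10, ]), "universes")
})

test_that("top-CpG selection thresholds, caps and tie-breaks deterministically", {
  mk <- function(n, z) data.frame(
    probe_id = sprintf("cg%04d", seq_len(n)), n = 50,
    r = z / 10, t = z, p = 2 * pnorm(abs(z), lower.tail = FALSE), z = z)
  # 600 significant positive probes -> exactly the 500 largest |z|
  z <- seq(4, 10, length.out = 600)
  sel <- select_top_cpgs(mk(600, z))
  expect_length(sel$hyper, 500)
  expect_setequal(sel$hyper, mk(600, z)$probe_id[101:600])
  expect_length(sel$hypo, 0)
  # simple threshold filter
  ew3 <- data.frame(probe_id = c("a", "b", "c"), n = 50, r = 0.5, t = 5,
                    p = c(1e-5, 1e-3, 1e-6), z = c(5, 5, 5.5))
  expect_setequal(select_top_cpgs(ew3)$hyper, c("a", "c"))
  # exact |z| ties break on probe id, stable across calls
  ewt <- data.frame(probe_id = c("cgB", "cgA", "cgC"), n = 50, r = 0.5,
                    t = 5, p = rep(1e-6, 3), z = rep(5, 3))
  s1 <- select_top_cpgs(ewt, max_per_direction = 2L)
  expect_identical(s1$hyper, c("cgA", "cgB"))
  expect_identical(s1, select_top_cpgs(ewt, max_per_direction = 2L))
})

test_that("divergence classes follow the two-tissue significance pattern", {
  mk <- function(z, p, tis) {
    out <- data.frame(probe_id = c("a", "b", "c", "d"), n = 30,
                      r = z / 10, t = z, p = p, z = z)
    attr(out, "tissue") <- tis
    out
  }
  ewb <- mk(c(5, 5, 5, 0.5), c(1e-6, 1e-6, 1e-6, 0.3), "blood")
  ewo <- mk(c(-5, 5, 1, -0.5), c(1e-6, 1e-6, 0.3, 0.4), "oocyte")
  cls <- classify_divergent(ewb, ewo)
  expect_identical(cls$class, c("divergent_both", "concordant_both",
                                "blood_only", "neither"))
  expect_error(classify_divergent(ewb, ewo[1:2, ]), "universes")
})

test_that("divergent probes in synthetic data are recovered", {
  d <- simulate_methylation(sim_config(
    n_probes = 500L, n_blood = 60L, n_oocyte = 60L,
    classes = c(divergent = 20L), slope_range = c(0.02, 0.03), seed = 26L))
  ewb <- correlation_screen(d$betas, d$samples, tissue = "blood")
  ewo <- correlation_screen(d$betas, d$samples, tissue = "oocyte")
  cls <- classify_divergent(ewb, ewo)
  truth_div <- d$truth$probe_id[d$truth$class == "divergent"]
  found <- cls$probe_id[cls$class == "divergent_both"]
  expect_gte(mean(truth_div %in% found), 0.95)
  expect_lte(length(setdiff(found, truth_div)), 2L)
})

test_that("cross-tissue z correlation summarizes shared aging structure", {
  d <- small_sim(seed = 27)
  ewb <- correlation_screen(d$betas, d$samples, tissue = "blood")
  expect_equal(cross_tissue_z_correlation(ewb, ewb), 1)
  neg <- ewb
  neg$z <- -neg$z
  expect_equal(cross_tissue_z_correlation(ewb, neg), -1)
  expect_error(cross_tissue_z_correlation(ewb[1:5, ], ewb[1:5, ]),
               "10 probes")
})

test_that("enrichment counts, odds ratio and hypergeometric p are exact", {
  bg <- sprintf("p%04d", 1:1000)
  feat <- bg[1:100]
  sel <- c(bg[1:10], bg[101:110])  # a=10 of 20 selected are features
  res <- feature_enrichment(sel, bg, feat)
  expect_identical(unname(res$table), c(10L, 10L, 90L, 890L))
  expect_equal(res$odds_ratio, (10 * 890) / (10 * 90))
  # exact upper-tail summation oracle via lchoose
  p_oracle <- sum(exp(lchoose(100, 10:20) + lchoose(900, 20 - (10:20)) -
                      lchoose(1000, 20)))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)

  none <- feature_enrichment(bg[101:105], bg, feat)
  expect_equal(none$odds_ratio, 0)
  expect_equal(none$p_value, 1, tolerance = 1e-12)
  # every selected probe is a feature probe: b = 0, OR degenerates to Inf
  all_in <- feature_enrichment(bg[1:5], bg, feat)
  expect_true(all_in$infinite_or)
  expect_gt(all_in$p_value, 0)
  degen <- feature_enrichment(bg[1:5], bg[1:200], bg[1:5])
  expect_true(degen$infinite_or)
  expect_identical(degen$odds_ratio, Inf)
  expect_gt(degen$p_value, 0)
  expect_error(feature_enrichment("zzz", bg, feat), "subset")
})

test_that("enrichment p is calibrated for uniformly drawn selections", {
  set.seed(28)
  bg <- sprintf("p%04d", 1:500)
  feat <- bg[1:120]
  ps <- replicate(200, feature_enrichment(sample(bg, 40), bg, feat)$p_value)
  # discrete but should not concentrate near 0: few false enrichments
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.35)
})

test_that("island Z comparison detects a shifted stratum and respects the null", {
  set.seed(29)
  n <- 400
  ew <- data.frame(probe_id = sprintf("cg%04d", 1:n), n = 50,
                   r = 0, t = 0, p = 0.5, z = rnorm(n))
  anno <- tiny_annotation(ew$probe_id,
                          island = rep(c("island", "non_island"), n / 2))
  ew$z[anno$island_status == "island"] <-
    ew$z[anno$island_status == "island"] + 1
  res <- island_z_comparison(ew, anno)
  expect_gt(res$t, 5)
  expect_lt(res$p, 1e-6)
  expect_equal(res$mean_island - res$mean_non_island, 1, tolerance = 0.3)

  ew0 <- data.frame(probe_id = c("a", "b", "c", "d", "e", "f"), n = 10,
                    r = 0, t = 0, p = 0.5, z = c(1, 2, 3, 1, 2, 3))
  anno0 <- tiny_annotation(ew0$probe_id,
                           island = rep(c("island", "non_island"), each = 3))
  res0 <- island_z_comparison(ew0, anno0)
  expect_equal(res0$mean_island, res0$mean_non_island)
  expect_equal(res0$t, 0)
  expect_error(island_z_comparison(ew0[c(1, 4, 5, 6), ], anno0), "2 probes")
})

test_that("stratum methylation means are exact on constructed matrices", {
  s <- tiny_samples(4)
  b <- tiny_betas(6, s$sample_id, values = 0.5)
  anno <- tiny_annotation(rownames(b),
                          island = c("island", rep("non_island", 5)))
  ms <- mean_methylation_by_island(b, s, anno)
  expect_true(all(ms$mean_beta == 0.5))
  # single-probe stratum equals that probe's mean
  b["cg00001", ] <- c(0.1, 0.2, 0.3, 0.4)
  ms <- mean_methylation_by_island(b, s, anno)
  expect_equal(ms$mean_beta[ms$island_status == "island"], 0.25)
  expect_identical(ms$n_probes[ms$island_status == "island"], 1L)
})

test_that("gene-neighborhood query applies the flank window", {
  anno <- tiny_annotation(c("cgNear", "cgFar", "cgAt"),
                          dist = c(5000L, 5000L, 5000L))
  anno$nearest_gene <- c("SIRT1", "OTHER", "SIRT1")
  anno$position <- c(200000L, 2500000L, 1000000L)
  anno$distance_to_tss <- anno$position - 995000L  # SIRT1 TSS at 995 kb
  anno$region_class <- ifelse(
    anno$distance_to_tss >= -10000 & anno$distance_to_tss <= 1000,
    "promoter", "intron")
  hits <- cpgs_near_gene(anno, "SIRT1", flank_bp = 1000000L)
  expect_setequal(hits$probe_id, c("cgNear", "cgAt"))
  expect_identical(hits$side[hits$probe_id == "cgNear"], "upstream")
  # flank 0 keeps only probes at the TSS itself
  anno2 <- anno
  anno2$position[3] <- 995000L
  anno2$distance_to_tss <- anno2$position - 995000L
  anno2$region_class <- ifelse(
    anno2$distance_to_tss >= -10000 & anno2$distance_to_tss <= 1000,
    "promoter", "intron")
  h0 <- cpgs_near_gene(anno2, "SIRT1", flank_bp = 0L)
  expect_identical(h0$probe_id, "cgAt")
  expect_identical(h0$side, "at_tss")
  # invariant to probe input order
  sh <- cpgs_near_gene(anno[c(3, 1, 2), ], "SIRT1", flank_bp = 1000000L)
  expect_identical(sh$probe_id, hits$probe_id)
  expect_error(cpgs_near_gene(anno, "SIRT2"), "near miss")
})
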