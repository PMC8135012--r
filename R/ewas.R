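# Epigenome-wide association screen of aging: per-CpG correlation
# statistics per tissue, Stouffer cross-tissue meta-analysis, top-CpG
# selection, divergence classification, and annotation-based enrichment.

# smallest p we report; caps |Z| at qnorm(.P_MIN/2, lower = FALSE) ~ 37.0
.P_MIN <- 1e-300

#' Per-CpG correlation screen against age
#'
#' For every probe, the Pearson correlation `r` of its betas with
#' chronological age (years) across the samples of one tissue, the Student
#' statistic `t = r * sqrt(n-2) / sqrt(1-r^2)`, the two-sided p-value from
#' the t distribution with `n-2` df, and the signed normal-equivalent
#' statistic `Z = sign(r) * qnorm(1 - p/2)`. This is the standard numeric
#' trait screen of the WGCNA tradition, vectorized over probes.
#'
#' P-values are floored at 1e-300, which caps |Z| near 37; probes with
#' constant betas get `NA` statistics (a message reports the count) and are
#' excluded from downstream selection.
#'
#' @param betas beta matrix.
#' @param samples sample table; must reduce to a single tissue, or pass
#'   `tissue` to subset.
#' @param tissue optional tissue to restrict to.
#' @return data.frame (`ewas_table`): `probe_id`, `n`, `r`, `t`, `p`, `z`,
#'   with the tissue recorded in attribute `"tissue"`.
#' @export
correlation_screen <- function(betas, samples, tissue = NULL) {
  betas <- validate_beta_matrix(betas)
  samples <- .align_samples(betas, samples)
  if (!is.null(tissue)) {
    keep <- samples$tissue == tissue
    samples <- samples[keep, , drop = FALSE]
    betas <- betas[, keep, drop = FALSE]
  }
  tis <- unique(samples$tissue)
  if (length(tis) != 1L)
    stop("screen requires a single tissue; found: ",
         paste(tis, collapse = ", "), " (use the `tissue` argument)")
  n <- ncol(betas)
  if (n < 4L) stop("need at least 4 samples per tissue (got ", n, ")")

  age <- samples$age_years
  xc <- age - mean(age)
  bc <- betas - rowMeans(betas)
  ssb <- rowSums(bc^2)
  r <- unname(as.numeric(bc %*% xc) / sqrt(ssb * sum(xc^2)))
  const <- ssb == 0
  if (any(const)) {
    r[const] <- NA_real_
    message(sum(const), " constant probe(s) excluded from the screen")
  }
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2L
  tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[is.infinite(tstat)] <- 0
  p <- pmax(p, .P_MIN)
  z <- sign(r) * stats::qnorm(p / 2, lower.tail = FALSE)
  z[!is.na(r) & r == 0] <- 0

  out <- data.frame(probe_id = rownames(betas), n = n, r = r, t = tstat,
                    p = ifelse(is.na(r), NA_real_, p), z = z,
                    stringsAsFactors = FALSE)
  attr(out, "tissue") <- tis
  class(out) <- c("ewas_table", "data.frame")
  out
}

#' Stouffer combination of two signed Z statistics
#'
#' `z_meta = (w1*z1 + w2*z2) / sqrt(w1^2 + w2^2)`; with the default unit
#' weights this is `(z1 + z2) / sqrt(2)`. Vectorized; `NA` in either input
#' propagates (a probe undefined in one tissue has no meta statistic).
#'
#' @param z1,z2 signed Z statistics.
#' @param weights length-2 positive weights (e.g. `sqrt(n)` per tissue).
#' @return combined Z, same length as the inputs.
#' @examples
#' stouffer_meta(2, 2)    # 2.828427...
#' stouffer_meta(1.5, -1.5) # 0
#' @export
stouffer_meta <- function(z1, z2, weights = c(1, 1)) {
  stopifnot(length(weights) == 2L, all(weights > 0))
  (weights[1L] * z1 + weights[2L] * z2) / sqrt(sum(weights^2))
}

#' Cross-tissue EWAS meta-analysis table
#'
#' Joins two single-tissue screens on their common probe universe and adds
#' Stouffer-combined `z_meta` and the two-sided normal `p_meta`.
#'
#' @param ewas_a,ewas_b [correlation_screen()] tables over the same probes.
#' @param weights `"equal"` or `"sqrt_n"` (weight each tissue by the square
#'   root of its sample size).
#' @return data.frame with per-tissue `z`/`p` columns plus `z_meta`,
#'   `p_meta`.
#' @export
ewas_meta <- function(ewas_a, ewas_b, weights = c("equal", "sqrt_n")) {
  weights <- match.arg(weights)
  if (!setequal(ewas_a$probe_id, ewas_b$probe_id))
    stop("the two EWAS tables cover different probe universes")
  b <- ewas_b[match(ewas_a$probe_id, ewas_b$probe_id), , drop = FALSE]
  w <- if (weights == "sqrt_n") sqrt(c(ewas_a$n[1L], b$n[1L])) else c(1, 1)
  z_meta <- stouffer_meta(ewas_a$z, b$z, w)
  p_meta <- pmax(2 * stats::pnorm(abs(z_meta), lower.tail = FALSE), .P_MIN)
  ta <- attr(ewas_a, "tissue"); tb <- attr(ewas_b, "tissue")
  if (is.null(ta) || is.null(tb) || identical(ta, tb)) { ta <- "a"; tb <- "b" }
  out <- data.frame(probe_id = ewas_a$probe_id, stringsAsFactors = FALSE)
  out[[paste0("z_", ta)]] <- ewas_a$z
  out[[paste0("p_", ta)]] <- ewas_a$p
  out[[paste0("z_", tb)]] <- b$z
  out[[paste0("p_", tb)]] <- b$p
  out$z_meta <- z_meta
  out$p_meta <- ifelse(is.na(z_meta), NA_real_, p_meta)
  out
}

#' Select top age-related CpGs
#'
#' Keeps probes with `p` below the significance threshold, splits them by
#' the sign of `Z` (hypermethylated with age vs hypomethylated), and caps
#' each direction at `max_per_direction`, retaining the largest `|Z|` with a
#' deterministic tie-break on probe id.
#'
#' @param ewas a screen or meta table; statistic columns default to `p`/`z`
#'   (`p_meta`/`z_meta` used automatically for meta tables).
#' @param p_threshold significance threshold (default 1e-4).
#' @param max_per_direction cap per direction (default 500).
#' @return list with character vectors `hyper` and `hypo`.
#' @export
select_top_cpgs <- function(ewas, p_threshold = 1e-4,
                            max_per_direction = 500L) {
  p <- if ("p" %in% names(ewas)) ewas$p else ewas$p_meta
  z <- if ("z" %in% names(ewas)) ewas$z else ewas$z_meta
  if (is.null(p) || is.null(z))
    stop("table has neither p/z nor p_meta/z_meta columns")
  sig <- !is.na(p) & p < p_threshold
  pick <- function(dir_sig) {
    ids <- ewas$probe_id[dir_sig]
    zz <- abs(z[dir_sig])
    ids[order(-zz, ids)][seq_len(min(length(ids), max_per_direction))]
  }
  list(hyper = pick(sig & z > 0), hypo = pick(sig & z < 0))
}

#' Classify cross-tissue aging behavior per CpG
#'
#' A probe is `divergent_both` when significantly age-associated in both
#' tissues with opposite directions of change, `concordant_both` when
#' significant in both with the same direction, `blood_only`/`oocyte_only`
#' (named after the tables' tissues) when significant in one, else
#' `neither`.
#'
#' @param ewas_a,ewas_b single-tissue screens over the same probes.
#' @param p_threshold per-tissue significance threshold.
#' @return data.frame `probe_id`, `class`.
#' @export
classify_divergent <- function(ewas_a, ewas_b, p_threshold = 1e-4) {
  if (!setequal(ewas_a$probe_id, ewas_b$probe_id))
    stop("the two EWAS tables cover different probe universes")
  b <- ewas_b[match(ewas_a$probe_id, ewas_b$probe_id), , drop = FALSE]
  ta <- attr(ewas_a, "tissue"); tb <- attr(ewas_b, "tissue")
  if (is.null(ta)) ta <- "a"
  if (is.null(tb) || identical(tb, ta)) tb <- "b"
  sa <- !is.na(ewas_a$p) & ewas_a$p < p_threshold
  sb <- !is.na(b$p) & b$p < p_threshold
  cls <- rep("neither", nrow(ewas_a))
  cls[sa & !sb] <- paste0(ta, "_only")
  cls[!sa & sb] <- paste0(tb, "_only")
  both <- sa & sb
  cls[both & sign(ewas_a$z) == sign(b$z)] <- "concordant_both"
  cls[both & sign(ewas_a$z) != sign(b$z)] <- "divergent_both"
  data.frame(probe_id = ewas_a$probe_id, class = cls,
             stringsAsFactors = FALSE)
}

#' Correlation of age effects between tissues
#'
#' Pearson correlation of the two tissues' Z statistics across all probes
#' defined in both — the genome-wide summary of how similar the aging
#' methylome is between tissues.
#'
#' @param ewas_a,ewas_b single-tissue screens over the same probes.
#' @return Pearson correlation (scalar).
#' @export
cross_tissue_z_correlation <- function(ewas_a, ewas_b) {
  if (!setequal(ewas_a$probe_id, ewas_b$probe_id))
    stop("the two EWAS tables cover different probe universes")
  b <- ewas_b[match(ewas_a$probe_id, ewas_b$probe_id), , drop = FALSE]
  ok <- !is.na(ewas_a$z) & !is.na(b$z)
  if (sum(ok) < 10L) stop("fewer than 10 probes defined in both tissues")
  stats::cor(ewas_a$z[ok], b$z[ok])
}

#' Feature enrichment of a selected probe set
#'
#' Builds the 2x2 table of a selected probe set against its background for
#' a binary feature (e.g. promoter location), and reports the odds ratio
#' `ad/bc` with the upper-tail hypergeometric probability
#' `P(X >= a)` (population = background, successes = feature probes in the
#' background, draws = selected set).
#'
#' @param selected character vector of selected probe ids (subset of
#'   `background`).
#' @param background character vector of background probe ids.
#' @param feature either a character vector of feature-positive probe ids,
#'   or a one-argument function applied to `annotation` returning a logical
#'   row mask.
#' @param annotation annotation table, required when `feature` is a
#'   function.
#' @return list of class `enrichment_result`: `table` (a,b,c,d),
#'   `odds_ratio` (`Inf` with `infinite_or = TRUE` when `b*c = 0`),
#'   `p_value`.
#' @examples
#' bg <- sprintf("p%03d", 1:100)
#' feat <- bg[1:20]
#' feature_enrichment(bg[1:10], bg, feat)
#' @export
feature_enrichment <- function(selected, background, feature,
                               annotation = NULL) {
  background <- unique(as.character(background))
  selected <- unique(as.character(selected))
  if (!all(selected %in% background))
    stop("selected set is not a subset of the background")
  if (is.function(feature)) {
    if (is.null(annotation))
      stop("`annotation` is required when `feature` is a predicate function")
    feat <- annotation$probe_id[feature(annotation)]
  } else feat <- as.character(feature)
  if (!all(background %in% c(feat, setdiff(background, feat))))
    stop("feature must be defined for all background probes")  # nocov
  is_feat <- background %in% feat
  is_sel <- background %in% selected
  a <- sum(is_feat & is_sel)
  b <- sum(!is_feat & is_sel)
  cc <- sum(is_feat & !is_sel)
  d <- sum(!is_feat & !is_sel)
  infinite_or <- (b * cc) == 0 && a * d > 0
  or <- if (infinite_or) Inf else if (a * d == 0 && b * cc == 0) NaN
        else (a * d) / (b * cc)
  p <- stats::phyper(a - 1L, m = a + cc, n = b + d, k = a + b,
                     lower.tail = FALSE)
  structure(list(table = c(a = a, b = b, c = cc, d = d),
                 odds_ratio = or, infinite_or = infinite_or,
                 p_value = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("2x2 enrichment: a =", x$table["a"], " b =", x$table["b"],
      " c =", x$table["c"], " d =", x$table["d"], "\n")
  cat("odds ratio =", signif(x$odds_ratio, 4L),
      if (x$infinite_or) "(degenerate table)" else "",
      "; hypergeometric p =", format(x$p_value, digits = 3L), "\n")
  invisible(x)
}

#' Compare age-correlation Z by CpG island status
#'
#' Welch two-sample t test of the screen's Z statistics between island and
#' non-island probes — the standard check of whether island CpGs age
#' differently (in blood they typically gain methylation faster).
#'
#' @param ewas a single-tissue screen.
#' @param annotation annotation covering the screened probes.
#' @return list: `mean_island`, `mean_non_island`, `t`, `df`, `p`.
#' @export
island_z_comparison <- function(ewas, annotation) {
  status <- annotation$island_status[match(ewas$probe_id,
                                           annotation$probe_id)]
  z <- ewas$z
  zi <- z[status == "island" & !is.na(z)]
  zn <- z[status == "non_island" & !is.na(z)]
  if (length(zi) < 2L || length(zn) < 2L)
    stop("need at least 2 probes per island stratum")
  tt <- stats::t.test(zi, zn, var.equal = FALSE)
  list(mean_island = mean(zi), mean_non_island = mean(zn),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Mean methylation by tissue and island status
#'
#' Average beta across all probes and samples of each tissue x island-status
#' stratum, with spread summaries — the comparison showing oocytes' lower
#' non-island baseline methylation.
#'
#' @param betas beta matrix.
#' @param samples sample table covering the beta columns.
#' @param annotation annotation covering the beta rows.
#' @return data.frame: `tissue`, `island_status`, `n_probes`, `n_samples`,
#'   `mean_beta`, `sd_beta`.
#' @export
mean_methylation_by_island <- function(betas, samples, annotation) {
  betas <- validate_beta_matrix(betas)
  samples <- .align_samples(betas, samples)
  status <- annotation$island_status[match(rownames(betas),
                                           annotation$probe_id)]
  if (anyNA(status))
    stop("annotation does not cover all probes in the beta matrix")
  out <- list()
  for (tis in unique(samples$tissue)) {
    cols <- samples$tissue == tis
    for (st in intersect(ISLAND_LEVELS, unique(status))) {
      block <- betas[status == st, cols, drop = FALSE]
      if (length(block) == 0L) stop("empty stratum: ", tis, " / ", st)
      out[[paste(tis, st)]] <- data.frame(
        tissue = tis, island_status = st,
        n_probes = nrow(block), n_samples = ncol(block),
        mean_beta = mean(block), sd_beta = stats::sd(as.numeric(block)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' CpG probes near a gene
#'
#' All probes within `flank_bp` of a gene's transcription start site,
#' ordered by genomic position and labeled upstream/downstream. The TSS is
#' taken from `gene_table` (columns `gene`, `chromosome`, `tss`) when
#' supplied, otherwise reconstructed from the annotation rows whose
#' `nearest_gene` is the query (`position - distance_to_tss`).
#'
#' @param annotation annotation table.
#' @param gene gene symbol.
#' @param flank_bp flanking window in bp on each side of the TSS.
#' @param gene_table optional gene coordinate table.
#' @return annotation rows in the window, with `distance_to_gene_tss`
#'   (signed bp) and `side` (`upstream`/`downstream`/`at_tss`) columns.
#' @export
cpgs_near_gene <- function(annotation, gene, flank_bp = 1000000L,
                           gene_table = NULL) {
  annotation <- validate_annotation(annotation)
  if (!is.null(gene_table)) {
    row <- gene_table[gene_table$gene == gene, , drop = FALSE]
    if (nrow(row) == 0L)
      stop("gene '", gene, "' not in gene_table; near misses: ",
           paste(utils::head(agrep(gene, gene_table$gene, value = TRUE), 5L),
                 collapse = ", "))
    chrom <- row$chromosome[1L]; tss <- row$tss[1L]
  } else {
    hits <- annotation[annotation$nearest_gene == gene, , drop = FALSE]
    if (nrow(hits) == 0L)
      stop("gene '", gene, "' not found in annotation; near misses: ",
           paste(utils::head(
             agrep(gene, unique(annotation$nearest_gene), value = TRUE), 5L),
             collapse = ", "))
    chrom <- hits$chromosome[1L]
    tss <- stats::median(hits$position - hits$distance_to_tss)
  }
  win <- annotation$chromosome == chrom &
    abs(annotation$position - tss) <= flank_bp
  out <- annotation[win, , drop = FALSE]
  out$distance_to_gene_tss <- out$position - tss
  out$side <- ifelse(out$distance_to_gene_tss < 0, "upstream",
                     ifelse(out$distance_to_gene_tss > 0, "downstream",
                            "at_tss"))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
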