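# Elastic-net epigenetic clocks: training, cross-validated age estimation,
# accuracy evaluation and age acceleration.
#
# A clock is a sparse linear model of transformed age on probe betas. The
# penalized fit goes through glmnet (the standard engine for methylation
# clocks); penalty strength is chosen by internal 10-fold CV at the minimum
# mean squared error. Predictors are standardized internally by glmnet and
# coefficients are returned on the original beta scale.

new_meth_clock <- function(transform, intercept, coefficients, alpha,
                           lambda, metadata, fitted = NULL) {
  structure(list(transform = transform,
                 intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 alpha = alpha,
                 lambda = lambda,
                 metadata = metadata,
                 fitted = fitted),
            class = "meth_clock")
}

# samples aligned to beta columns, in beta column order
.align_samples <- function(betas, samples) {
  samples <- validate_sample_table(samples)
  miss <- setdiff(colnames(betas), samples$sample_id)
  if (length(miss))
    stop("beta matrix columns not found in sample table: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  samples[match(colnames(betas), samples$sample_id), , drop = FALSE]
}

#' Train an epigenetic clock
#'
#' Fits transformed age on probe betas with a combined L1/L2 (elastic-net)
#' penalty. The penalty strength is selected by internal k-fold
#' cross-validation minimizing squared error; the mixing parameter
#' `alpha` (1 = lasso, 0 = ridge) defaults to 0.5, the convention in the
#' methylation-clock literature.
#'
#' @param betas probe x sample beta matrix (see [validate_beta_matrix()]).
#' @param samples sample table covering all beta columns.
#' @param transform an [age_transform()]; identity for within-species
#'   chronological clocks, relative for dual-species clocks.
#' @param alpha elastic-net mixing parameter in \[0, 1\].
#' @param nfolds folds for internal penalty selection.
#' @param seed integer seed controlling the internal CV fold split.
#' @return an object of class `meth_clock` with the transform, intercept,
#'   the nonzero coefficients (named, original beta scale), the selected
#'   penalty, training metadata, and the in-sample fitted ages in years.
#' @examples
#' d <- simulate_methylation(sim_config(n_probes = 300, n_blood = 30,
#'                                      n_oocyte = 0, seed = 3))
#' cl <- train_clock(d$betas, d$samples)
#' cl
#' @export
train_clock <- function(betas, samples, transform = age_transform("identity"),
                        alpha = 0.5, nfolds = 10L, seed = 1L) {
  betas <- validate_beta_matrix(betas)
  samples <- .align_samples(betas, samples)
  n <- ncol(betas)
  if (n < 10L)
    stop("need at least 10 samples to train a clock (got ", n, ")")
  if (nfolds > n)
    stop("fewer samples (", n, ") than internal CV folds (", nfolds, ")")
  y <- transform_age(transform, samples$age_years,
                     samples$max_lifespan_years)
  if (stats::var(y) == 0)
    stop("transformed age is constant; cannot fit a clock")

  x <- t(betas)
  # internal CV folds are drawn in canonical (sorted sample id) order so the
  # fit does not depend on the column order of the input matrix
  set.seed(seed)
  fid <- sample(rep_len(seq_len(nfolds), n))
  foldid <- integer(n)
  foldid[order(samples$sample_id)] <- fid
  cv <- glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid,
                          standardize = TRUE, family = "gaussian",
                          grouped = n >= 3L * nfolds)
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))
  w <- cf[-1L, 1L]
  w <- w[w != 0]

  clock <- new_meth_clock(
    transform = transform,
    intercept = cf[1L, 1L],
    coefficients = w,
    alpha = alpha,
    lambda = cv$lambda.min,
    metadata = list(
      n_train = n,
      tissues = sort(unique(samples$tissue)),
      species = sort(unique(samples$species)),
      lifespan = stats::setNames(
        as.list(tapply(samples$max_lifespan_years, samples$species, unique)),
        sort(unique(samples$species))),
      nfolds = nfolds,
      seed = seed))
  clock$fitted <- data.frame(
    sample_id = samples$sample_id,
    age_years = samples$age_years,
    dnam_age_years = predict(clock, betas, samples, warn_range = FALSE),
    tissue = samples$tissue,
    species = samples$species,
    stringsAsFactors = FALSE)
  clock
}

#' @export
print.meth_clock <- function(x, ...) {
  cat("Epigenetic clock (elastic net, alpha =", x$alpha, ")\n")
  cat("  transform: ", x$transform$kind, "\n", sep = "")
  cat("  probes with nonzero weight: ", length(x$coefficients), "\n", sep = "")
  cat("  penalty lambda: ", signif(x$lambda, 4L), "\n", sep = "")
  if (!is.null(x$metadata$n_train))
    cat("  trained on ", x$metadata$n_train, " samples (",
        paste(unlist(x$metadata$tissues), collapse = "/"), "; ",
        paste(unlist(x$metadata$species), collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.meth_clock <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
summary.meth_clock <- function(object, ...) {
  out <- list(clock = object,
              evaluation = if (!is.null(object$fitted))
                evaluate_clock(object$fitted) else NULL)
  class(out) <- "summary.meth_clock"
  out
}

#' @export
print.summary.meth_clock <- function(x, ...) {
  print(x$clock)
  if (!is.null(x$evaluation)) {
    cat("In-sample fit (resubstitution; use loo_estimates()/kfold_estimates()",
        "for honest accuracy):\n")
    print(x$evaluation, row.names = FALSE)
  }
  invisible(x)
}

#' Predict DNA methylation age
#'
#' Applies the stored sparse linear model and back-transforms to years. For
#' a relative-age clock the species maximum lifespan is needed to convert
#' relative predictions to years; it is taken from `samples` (matched on
#' beta column names) or from a scalar `max_lifespan`.
#'
#' Predictions are never clipped to the valid age range: an out-of-range
#' DNAm age is a calibration signal, reported as-is with a warning.
#'
#' @param object a `meth_clock`.
#' @param betas beta matrix containing every clock probe (missing probes are
#'   an error; there is no silent imputation).
#' @param samples sample table, required for relative-age clocks.
#' @param max_lifespan scalar lifespan alternative to `samples`.
#' @param warn_range warn on negative predicted ages.
#' @param ... unused.
#' @return named numeric vector of DNAm ages in years, one per beta column.
#' @export
predict.meth_clock <- function(object, betas, samples = NULL,
                               max_lifespan = NULL, warn_range = TRUE, ...) {
  betas <- validate_beta_matrix(betas)
  probes <- names(object$coefficients)
  miss <- setdiff(probes, rownames(betas))
  if (length(miss))
    stop("beta matrix lacks ", length(miss), " clock probe(s): ",
         paste(utils::head(miss, 10L), collapse = ", "))
  lin <- object$intercept +
    as.numeric(crossprod(betas[probes, , drop = FALSE],
                         object$coefficients))
  if (length(probes) == 0L) lin <- rep(object$intercept, ncol(betas))
  if (object$transform$kind == "relative") {
    if (is.null(max_lifespan)) {
      if (is.null(samples))
        stop("relative-age clock needs `samples` (or `max_lifespan`) to ",
             "convert relative age to years")
      samples <- .align_samples(betas, samples)
      max_lifespan <- samples$max_lifespan_years
    }
    years <- untransform_age(object$transform, lin, max_lifespan)
  } else {
    years <- untransform_age(object$transform, lin)
  }
  if (warn_range && any(years < 0))
    warning(sum(years < 0), " predicted DNAm age(s) below 0 years; ",
            "reported unclipped")
  stats::setNames(years, colnames(betas))
}

#' Cross-validation fold assignment
#'
#' Folds are stratified by species x tissue so every fold sees the full
#' design, and balanced so overall fold sizes differ by at most one. With
#' `group_by_donor`, all samples of a donor are assigned to the same fold
#' (required when isogenic samples would otherwise leak across folds).
#'
#' @param samples sample table.
#' @param k number of folds.
#' @param group_by_donor keep donors intact.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k) aligned to `samples` rows.
#' @export
make_folds <- function(samples, k = 10L, group_by_donor = FALSE, seed = 1L) {
  samples <- validate_sample_table(samples)
  n <- nrow(samples)
  if (k > n) stop("more folds (", k, ") than samples (", n, ")")
  set.seed(seed)
  unit <- if (group_by_donor) {
    ifelse(is.na(samples$donor_id) | samples$donor_id == "",
           paste0(".solo.", samples$sample_id), samples$donor_id)
  } else samples$sample_id
  # donors can span tissues, so donor-grouped folds stratify by species only
  stratum <- if (group_by_donor) samples$species
             else paste(samples$species, samples$tissue)
  units <- unique(data.frame(unit = unit, stratum = stratum,
                             stringsAsFactors = FALSE))
  fold_of_unit <- stats::setNames(integer(nrow(units)), units$unit)
  cursor <- 0L
  for (st in unique(units$stratum)) {
    u <- units$unit[units$stratum == st]
    u <- u[sample.int(length(u))]
    fold_of_unit[u] <- (cursor + seq_along(u) - 1L) %% k + 1L
    cursor <- cursor + length(u)
  }
  unname(fold_of_unit[unit])
}

.cv_estimates <- function(betas, samples, fold_id, transform, alpha,
                          nfolds, seed) {
  n <- ncol(betas)
  est <- rep(NA_real_, n)
  for (f in sort(unique(fold_id))) {
    hold <- fold_id == f
    cl <- train_clock(betas[, !hold, drop = FALSE],
                      samples[!hold, , drop = FALSE],
                      transform = transform, alpha = alpha,
                      nfolds = nfolds, seed = seed)
    est[hold] <- predict(cl, betas[, hold, drop = FALSE],
                         samples[hold, , drop = FALSE], warn_range = FALSE)
  }
  data.frame(sample_id = samples$sample_id,
             fold_id = fold_id,
             age_years = samples$age_years,
             dnam_age_years = est,
             tissue = samples$tissue,
             species = samples$species,
             max_lifespan_years = samples$max_lifespan_years,
             donor_id = samples$donor_id,
             stringsAsFactors = FALSE)
}

#' Leave-one-sample-out DNAm age estimates
#'
#' For each sample the entire training procedure — including penalty
#' selection — is rerun without that sample, and its age is predicted by the
#' resulting clock. This is the conservative scheme: nothing about the held
#' out sample influences its own estimate.
#'
#' @inheritParams train_clock
#' @return a data.frame of cross-validated estimates: `sample_id`,
#'   `fold_id`, `age_years`, `dnam_age_years`, `tissue`, `species`,
#'   `max_lifespan_years`, `donor_id`.
#' @export
loo_estimates <- function(betas, samples, transform = age_transform("identity"),
                          alpha = 0.5, nfolds = 10L, seed = 1L) {
  betas <- validate_beta_matrix(betas)
  samples <- .align_samples(betas, samples)
  .cv_estimates(betas, samples, seq_len(ncol(betas)), transform, alpha,
                nfolds, seed)
}

#' k-fold cross-validated DNAm age estimates
#'
#' @inheritParams train_clock
#' @param k number of folds.
#' @param group_by_donor keep all samples of a donor in one fold.
#' @return as [loo_estimates()].
#' @export
kfold_estimates <- function(betas, samples, k = 10L,
                            transform = age_transform("identity"),
                            alpha = 0.5, group_by_donor = FALSE,
                            nfolds = 10L, seed = 1L) {
  betas <- validate_beta_matrix(betas)
  samples <- .align_samples(betas, samples)
  folds <- make_folds(samples, k = k, group_by_donor = group_by_donor,
                      seed = seed)
  .cv_estimates(betas, samples, folds, transform, alpha, nfolds, seed)
}

#' Evaluate clock accuracy
#'
#' Pearson correlation between DNAm age and chronological age, and the
#' median absolute error, overall and per grouping.
#'
#' @param est cross-validated estimates from [loo_estimates()] or
#'   [kfold_estimates()] (or a compatible data.frame).
#' @param by grouping: `"overall"`, `"tissue"`, `"species"`, or
#'   `"species_tissue"`.
#' @param units `"years"` (default) or `"relative"` — the latter divides
#'   both ages by `max_lifespan_years`, the natural error scale for a
#'   relative-age clock.
#' @return data.frame with columns `group`, `n`, `pearson_r`, `mae`. `r` is
#'   `NA` for a group with constant chronological age.
#' @export
evaluate_clock <- function(est, by = c("overall", "tissue", "species",
                                       "species_tissue"),
                           units = c("years", "relative")) {
  by <- match.arg(by)
  units <- match.arg(units)
  age <- est$age_years
  dnam <- est$dnam_age_years
  if (units == "relative") {
    if (is.null(est$max_lifespan_years))
      stop("relative-unit evaluation needs a max_lifespan_years column")
    age <- age / est$max_lifespan_years
    dnam <- dnam / est$max_lifespan_years
  }
  grp <- switch(by,
                overall = rep("overall", nrow(est)),
                tissue = est$tissue,
                species = est$species,
                species_tissue = paste(est$species, est$tissue, sep = "_"))
  out <- lapply(split(seq_along(grp), grp), function(i) {
    if (length(i) < 3L)
      stop("need >=3 samples per evaluated group")
    r <- if (stats::var(age[i]) == 0 || stats::var(dnam[i]) == 0)
      NA_real_ else stats::cor(age[i], dnam[i])
    data.frame(group = grp[i[1L]], n = length(i), pearson_r = r,
               mae = stats::median(abs(dnam[i] - age[i])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Epigenetic age acceleration
#'
#' Residuals from an ordinary least-squares regression of DNAm age on
#' chronological age, fitted within each tissue group. The within-tissue
#' regression removes tissue-specific calibration slope and intercept, so
#' accelerations are comparable across tissues; by construction they are
#' uncorrelated with chronological age. Only cross-validated estimates
#' should be supplied — resubstitution fits understate acceleration.
#'
#' @param est cross-validated estimates (see [loo_estimates()]).
#' @return `est` with an added `acceleration` column (years).
#' @export
age_acceleration <- function(est) {
  stopifnot(all(c("age_years", "dnam_age_years", "tissue") %in% names(est)))
  accel <- rep(NA_real_, nrow(est))
  for (tis in unique(est$tissue)) {
    i <- which(est$tissue == tis)
    if (length(i) < 3L)
      stop("tissue '", tis, "' has <3 samples; cannot define acceleration")
    fit <- stats::lm(dnam_age_years ~ age_years, data = est[i, ])
    accel[i] <- stats::residuals(fit)
  }
  est$acceleration <- accel
  est
}

#' Cross-tissue correlation of age acceleration in isogenic pairs
#'
#' Pairs blood and oocyte samples by donor, computes age acceleration
#' within each tissue, and tests the Pearson correlation of the paired
#' accelerations (two-sided). Also reports per-tissue acceleration
#' summaries (median and IQR).
#'
#' @param est_blood,est_oocyte cross-validated estimates for each tissue,
#'   carrying `donor_id`.
#' @return list with `r`, `p`, `n_pairs`, and `summaries` (per-tissue
#'   median/IQR of acceleration).
#' @export
acceleration_correlation <- function(est_blood, est_oocyte) {
  ab <- age_acceleration(est_blood)
  ao <- age_acceleration(est_oocyte)
  db <- ab$donor_id
  do_ <- ao$donor_id
  if (is.null(db) || is.null(do_) || all(is.na(db)) || all(is.na(do_)))
    stop("both estimate tables need donor_id for pairing")
  common <- intersect(db[!is.na(db)], do_[!is.na(do_)])
  if (length(common) < 3L)
    stop("fewer than 3 donor pairs shared between tissues")
  x <- ab$acceleration[match(common, db)]
  y <- ao$acceleration[match(common, do_)]
  ct <- stats::cor.test(x, y, alternative = "two.sided", method = "pearson")
  summ <- function(v) c(median = stats::median(v),
                        iqr = stats::IQR(v))
  list(r = unname(ct$estimate),
       p = ct$p.value,
       n_pairs = length(common),
       summaries = rbind(blood = summ(x), oocyte = summ(y)))
}
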