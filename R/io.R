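# Typed data model: beta matrices, sample sheets, CpG annotation manifests,
# clock files and EWAS tables, with validating readers and writers.
#
# All delimited files are TSV with a header by default; readers accept
# sep = "," for comma-separated exports. Probe and sample order is preserved
# from file and never assumed sorted.

SPECIES_LEVELS <- c("cattle", "human")
TISSUE_LEVELS <- c("blood", "oocyte", "skin")
REGION_LEVELS <- c("promoter", "five_prime_utr", "exon", "intron",
                   "three_prime_utr", "intergenic_upstream",
                   "intergenic_downstream")
ISLAND_LEVELS <- c("island", "non_island")

# promoter window around the nearest TSS: -10 kb .. +1 kb, signed distance
# with negative = upstream
PROMOTER_WINDOW <- c(-10000L, 1000L)

#' Validate a beta-value matrix
#'
#' A beta matrix is a numeric matrix of methylation fractions with unique
#' probe rownames and unique sample colnames; every entry must lie in
#' \[0, 1\] (a numerical tolerance of 1e-9 is allowed and clamped). Missing
#' values are rejected: the pipeline assumes complete matrices.
#'
#' @param betas numeric matrix, probes x samples.
#' @return the validated (possibly clamped) matrix, invisibly usable.
#' @export
validate_beta_matrix <- function(betas) {
  if (!is.matrix(betas) || !is.numeric(betas))
    stop("beta matrix must be a numeric matrix")
  if (is.null(rownames(betas)) || is.null(colnames(betas)))
    stop("beta matrix must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(betas)))
    stop("duplicate probe ids: ",
         paste(utils::head(unique(rownames(betas)[duplicated(rownames(betas))]), 3L),
               collapse = ", "))
  if (anyDuplicated(colnames(betas)))
    stop("duplicate sample ids: ",
         paste(utils::head(unique(colnames(betas)[duplicated(colnames(betas))]), 3L),
               collapse = ", "))
  if (anyNA(betas)) {
    idx <- which(is.na(betas), arr.ind = TRUE)[1L, ]
    stop("missing beta value at probe ", rownames(betas)[idx[1L]],
         ", sample ", colnames(betas)[idx[2L]])
  }
  tol <- 1e-9
  if (any(betas < -tol) || any(betas > 1 + tol)) {
    idx <- which(betas < -tol | betas > 1 + tol, arr.ind = TRUE)[1L, ]
    stop("beta value out of [0,1] at probe ", rownames(betas)[idx[1L]],
         ", sample ", colnames(betas)[idx[2L]], ": ",
         betas[idx[1L], idx[2L]])
  }
  betas[betas < 0] <- 0
  betas[betas > 1] <- 1
  betas
}

#' Read a beta-value matrix
#'
#' Expects delimited text with a header line; the first column holds probe
#' ids and each remaining column one sample.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return validated numeric matrix, probes x samples.
#' @export
read_beta_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("beta matrix file needs a probe_id column plus >=1 sample column")
  probes <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  # a column that is entirely NA is read as logical; keep it numeric so the
  # missing-value check reports it properly
  vals[] <- lapply(vals, function(x) if (is.logical(x)) as.numeric(x) else x)
  m <- as.matrix(vals)
  if (!is.numeric(m))
    stop("non-numeric beta values in ", path)
  rownames(m) <- probes
  validate_beta_matrix(m)
}

#' Write a beta-value matrix
#'
#' Inverse of [read_beta_matrix()]; values are written with full double
#' precision so read/write round-trips are lossless to float formatting.
#'
#' @param betas validated beta matrix.
#' @param path output path.
#' @param sep field separator.
#' @export
write_beta_matrix <- function(betas, path, sep = "\t") {
  betas <- validate_beta_matrix(betas)
  df <- data.frame(probe_id = rownames(betas),
                   apply(betas, 2L, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(betas))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample table
#'
#' Required columns: `sample_id`, `species`, `tissue`, `age_years`,
#' `max_lifespan_years`; optional `donor_id` linking isogenic samples.
#' Enforced invariants: unique sample ids; positive ages not exceeding the
#' species lifespan; one lifespan per species; samples sharing a donor agree
#' on species and age.
#'
#' @param samples data.frame.
#' @return the validated table with normalized (lower-case) enum columns.
#' @export
validate_sample_table <- function(samples) {
  req <- c("sample_id", "species", "tissue", "age_years", "max_lifespan_years")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         samples$sample_id[duplicated(samples$sample_id)][1L])
  samples$species <- tolower(trimws(as.character(samples$species)))
  samples$tissue <- tolower(trimws(as.character(samples$tissue)))
  bad <- setdiff(unique(samples$species), SPECIES_LEVELS)
  if (length(bad))
    stop("unknown species token(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(samples$tissue), TISSUE_LEVELS)
  if (length(bad))
    stop("unknown tissue token(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(samples$age_years)) || any(samples$age_years <= 0))
    stop("nonpositive or missing age_years for sample: ",
         samples$sample_id[which(!is.finite(samples$age_years) |
                                 samples$age_years <= 0)[1L]])
  if (any(!is.finite(samples$max_lifespan_years)) ||
      any(samples$max_lifespan_years <= 0))
    stop("max_lifespan_years must be positive")
  if (any(samples$age_years > samples$max_lifespan_years))
    stop("age exceeds species maximum lifespan for sample: ",
         samples$sample_id[which(samples$age_years >
                                 samples$max_lifespan_years)[1L]])
  for (sp in unique(samples$species)) {
    ls <- unique(samples$max_lifespan_years[samples$species == sp])
    if (length(ls) > 1L)
      stop("species '", sp, "' carries multiple max lifespans: ",
           paste(ls, collapse = ", "))
  }
  if (!"donor_id" %in% names(samples)) samples$donor_id <- NA_character_
  samples$donor_id <- as.character(samples$donor_id)
  dn <- samples$donor_id[!is.na(samples$donor_id) & samples$donor_id != ""]
  for (d in unique(dn)) {
    rows <- samples[!is.na(samples$donor_id) & samples$donor_id == d, ]
    if (length(unique(rows$species)) > 1L ||
        length(unique(rows$age_years)) > 1L)
      stop("donor '", d, "' linked to samples with differing species or age")
  }
  samples
}

#' Read a sample sheet
#'
#' @param path file path to a delimited sample sheet.
#' @param sep field separator; `NULL` auto-detects tab vs comma from the
#'   header line.
#' @return validated sample table (data.frame).
#' @export
read_sample_sheet <- function(path, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_table(df)
}

#' Write a sample sheet
#' @param samples validated sample table.
#' @param path output path.
#' @param sep field separator.
#' @export
write_sample_sheet <- function(samples, path, sep = "\t") {
  samples <- validate_sample_table(samples)
  utils::write.table(samples, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a CpG annotation manifest
#'
#' Columns: `probe_id`, `chromosome`, `position` (1-based bp),
#' `nearest_gene`, `distance_to_tss` (signed bp, negative = upstream of the
#' TSS), `region_class`, `island_status`. A probe is a promoter probe exactly
#' when its TSS distance lies in the window −10 kb to +1 kb; rows whose
#' `region_class` contradicts that window are kept but flagged with a warning
#' reporting the count.
#'
#' @param annotation data.frame.
#' @return validated annotation table.
#' @export
validate_annotation <- function(annotation) {
  req <- c("probe_id", "chromosome", "position", "nearest_gene",
           "distance_to_tss", "region_class", "island_status")
  miss <- setdiff(req, names(annotation))
  if (length(miss))
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  annotation$probe_id <- as.character(annotation$probe_id)
  if (anyDuplicated(annotation$probe_id))
    stop("duplicate probe_id in annotation: ",
         annotation$probe_id[duplicated(annotation$probe_id)][1L])
  annotation$region_class <- tolower(as.character(annotation$region_class))
  annotation$island_status <- tolower(as.character(annotation$island_status))
  bad <- setdiff(unique(annotation$region_class), REGION_LEVELS)
  if (length(bad))
    stop("unknown region_class token(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(annotation$island_status), ISLAND_LEVELS)
  if (length(bad))
    stop("unknown island_status token(s): ", paste(bad, collapse = ", "))
  if (any(annotation$position < 1L))
    stop("positions must be 1-based positive integers")
  in_window <- annotation$distance_to_tss >= PROMOTER_WINDOW[1L] &
    annotation$distance_to_tss <= PROMOTER_WINDOW[2L]
  inconsistent <- xor(in_window, annotation$region_class == "promoter")
  if (any(inconsistent))
    warning(sum(inconsistent), " probe(s) have region_class inconsistent ",
            "with the promoter window [-10000, +1000] bp (e.g. ",
            annotation$probe_id[which(inconsistent)[1L]], ")")
  annotation
}

#' Read a CpG annotation manifest
#' @param path file path.
#' @param sep field separator.
#' @return validated annotation data.frame.
#' @export
read_annotation <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_annotation(df)
}

#' Write a CpG annotation manifest
#' @param annotation validated annotation table.
#' @param path output path.
#' @param sep field separator.
#' @export
write_annotation <- function(annotation, path, sep = "\t") {
  annotation <- validate_annotation(annotation)
  utils::write.table(annotation, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export annotation probe positions as BED
#'
#' Writes a 4-column BED file (chromosome, 0-based start, 1-based end,
#' probe_id) for use with genome-arithmetic tools.
#'
#' @param annotation validated annotation table.
#' @param path output path.
#' @export
annotation_to_bed <- function(annotation, path) {
  annotation <- validate_annotation(annotation)
  bed <- data.frame(chrom = annotation$chromosome,
                    start = annotation$position - 1L,
                    end = annotation$position,
                    name = annotation$probe_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a clock to a file
#'
#' The clock file is a single text file: a first line `#clock<TAB><JSON>`
#' carrying the transform, intercept and metadata at full precision, then a
#' TSV table of probe ids and coefficient weights. Serialization preserves
#' predictions to better than 1e-12.
#'
#' @param clock a [train_clock()] object.
#' @param path output path.
#' @export
write_clock <- function(clock, path) {
  stopifnot(inherits(clock, "meth_clock"))
  header <- list(
    format_version = 1L,
    transform = clock$transform[!vapply(clock$transform, is.null, TRUE)],
    intercept = clock$intercept,
    alpha = clock$alpha,
    lambda = clock$lambda,
    metadata = clock$metadata
  )
  hjson <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                            null = "null")
  lines <- c(paste0("#clock\t", as.character(hjson)),
             "probe_id\tweight",
             sprintf("%s\t%.17g", names(clock$coefficients),
                     clock$coefficients))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clock from a file
#' @param path a file written by [write_clock()].
#' @return a `meth_clock` object identical in predictions to the one saved.
#' @export
read_clock <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "#clock\t"))
    stop("not a clock file (missing '#clock' header): ", path)
  header <- jsonlite::fromJSON(sub("^#clock\t", "", lines[1L]),
                               simplifyVector = TRUE)
  if (lines[2L] != "probe_id\tweight")
    stop("malformed clock file coefficient table header")
  coefs <- numeric(0)
  if (length(lines) > 2L) {
    tab <- utils::read.table(text = lines[-(1:2)], sep = "\t",
                             col.names = c("probe_id", "weight"),
                             colClasses = c("character", "numeric"))
    coefs <- stats::setNames(tab$weight, tab$probe_id)
  }
  tr <- do.call(age_transform, header$transform)
  new_meth_clock(transform = tr,
                 intercept = header$intercept,
                 coefficients = coefs,
                 alpha = header$alpha,
                 lambda = header$lambda,
                 metadata = header$metadata)
}

#' Write an EWAS table
#' @param ewas data.frame from [correlation_screen()] or [ewas_meta()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_ewas <- function(ewas, path, sep = "\t") {
  df <- ewas
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an EWAS table
#' @param path file written by [write_ewas()].
#' @param sep field separator.
#' @return data.frame with numeric statistic columns restored.
#' @export
read_ewas <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (col in setdiff(names(df), c("probe_id", "tissue", "class")))
    df[[col]] <- as.numeric(df[[col]])
  df
}
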