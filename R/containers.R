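#' Genotype matrix container
#'
#' Samples x variants additive dosage matrix (counts of the alternative
#' allele, 0/1/2) with `NA` for missing genotypes, carrying the per-variant
#' records and sample labels.
#'
#' @param dosage numeric/integer matrix, samples in rows, variants in
#'   columns, entries in \{0,1,2\} or `NA`.
#' @param samples character vector of sample labels (rows).
#' @param variants data frame with at least `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt` (one row per column of `dosage`).
#' @param coding `"additive_NA"` (missing stored as `NA`) or
#'   `"heatmap_minus1"` (missing stored as -1, the convention used for
#'   genotype-distribution heatmaps).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, samples, variants,
                            coding = c("additive_NA", "heatmap_minus1")) {
  coding <- match.arg(coding)
  dosage <- as.matrix(dosage)
  stopifnot(nrow(dosage) == length(samples),
            ncol(dosage) == nrow(variants),
            !anyDuplicated(variants$variant_id))
  vals <- dosage[!is.na(dosage)]
  ok <- if (coding == "additive_NA") vals %in% c(0, 1, 2)
        else vals %in% c(-1, 0, 1, 2)
  if (!all(ok)) stop("dosage entries must be 0/1/2 (missing: NA or -1)")
  dimnames(dosage) <- list(samples, variants$variant_id)
  structure(list(dosage = dosage, samples = samples,
                 variants = as.data.frame(variants), coding = coding),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%s coding), %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage), x$coding,
              100 * mean(if (x$coding == "additive_NA") is.na(x$dosage)
                         else x$dosage == -1)))
  invisible(x)
}

#' @exportS3Method base::dim
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Switch the missing-genotype coding of a genotype matrix
#'
#' `additive_NA` stores missing genotypes as `NA` (the coding used for model
#' fitting, where the tree learner handles missing values natively);
#' `heatmap_minus1` stores them as -1 (the recode used for
#' genotype-distribution heatmaps and hierarchical clustering).
#'
#' @param x a [genotype_matrix].
#' @param coding target coding.
#' @return a [genotype_matrix] in the requested coding.
#' @export
recode_genotypes <- function(x, coding = c("additive_NA", "heatmap_minus1")) {
  coding <- match.arg(coding)
  if (coding == x$coding) return(x)
  d <- x$dosage
  if (coding == "heatmap_minus1") {
    d[is.na(d)] <- if (is.integer(d)) -1L else -1
  } else {
    d[d == -1] <- if (is.integer(d)) NA_integer_ else NA_real_
  }
  genotype_matrix(d, x$samples, x$variants, coding)
}

#' Subset a genotype matrix by variant id or sample
#'
#' @param x a [genotype_matrix].
#' @param variants variant ids (or column indices) to keep; `NULL` keeps all.
#' @param samples sample labels (or row indices) to keep; `NULL` keeps all.
#' @return a [genotype_matrix].
#' @export
subset_genotypes <- function(x, variants = NULL, samples = NULL) {
  vi <- if (is.null(variants)) seq_len(ncol(x$dosage))
        else if (is.character(variants)) {
          m <- match(variants, x$variants$variant_id)
          if (anyNA(m)) stop("unknown variant id(s): ",
                             paste(variants[is.na(m)], collapse = ", "))
          m
        } else variants
  si <- if (is.null(samples)) seq_len(nrow(x$dosage))
        else if (is.character(samples)) {
          m <- match(samples, x$samples)
          if (anyNA(m)) stop("unknown sample(s): ",
                             paste(samples[is.na(m)], collapse = ", "))
          m
        } else samples
  genotype_matrix(x$dosage[si, vi, drop = FALSE], x$samples[si],
                  x$variants[vi, , drop = FALSE], x$coding)
}

#' Trait table container
#'
#' Per-sample binary class labels for one trait.
#'
#' @param sample_id sample labels.
#' @param class integer vector of 0/1 labels (`NA` = excluded).
#' @param trait trait name.
#' @param value optional raw phenotype values the classes were derived from.
#' @return data frame of class `trait_table` with attribute `trait`.
#' @export
trait_table <- function(sample_id, class, trait = "trait", value = NULL) {
  stopifnot(length(sample_id) == length(class),
            all(class %in% c(0L, 1L) | is.na(class)))
  df <- data.frame(sample_id = as.character(sample_id),
                   class = as.integer(class), stringsAsFactors = FALSE)
  if (!is.null(value)) df$value <- value
  structure(df, class = c("trait_table", "data.frame"), trait = trait)
}

# align a trait table to a genotype matrix; drops excluded (NA) samples
align_trait <- function(gm, trait) {
  tt <- trait[!is.na(trait$class) & trait$sample_id %in% gm$samples, ]
  x <- subset_genotypes(gm, samples = tt$sample_id)
  list(x = x$dosage, y = tt$class, samples = tt$sample_id)
}
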