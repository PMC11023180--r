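#' Read a VCF into a genotype matrix and variant table
#'
#' Parses a VCF 4.2 file (via \pkg{vcfR}) into additive dosages: the dosage
#' is the number of alternative alleles in the unphased GT call, with
#' `./.` mapped to missing. INFO metrics used by the GATK-style hard filters
#' (AC, MQ, DP, SOR, QD, FS, MQRankSum, ReadPosRankSum, BaseQRankSum) are
#' carried in the variant table when present.
#'
#' @param path VCF file (plain or bgzipped).
#' @param multiallelic `"error"` (default) rejects records with more than one
#'   alternative allele; `"drop"` removes them with a warning.
#' @return a [genotype_matrix] whose `variants` data frame holds the
#'   per-variant records including INFO metrics.
#' @export
read_vcf <- function(path, multiallelic = c("error", "drop")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF drops to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (!"GT" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID &&
      !grepl("GT", v@gt[1, "FORMAT"]))
    stop("VCF has no GT field")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error")
      stop(sum(multi), " multiallelic record(s); biallelic input required ",
           "(use multiallelic = \"drop\" to remove them)")
    warning("dropping ", sum(multi), " multiallelic record(s)")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # count alt alleles in unphased or phased diploid calls
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  bad <- !is.na(clean) & !clean %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  if (any(bad))
    stop("malformed GT at record(s): ",
         paste(utils::head(which(rowSums(bad) > 0), 5), collapse = ", "))

  vt <- data.frame(variant_id = paste0(fix$CHROM, "_", fix$POS),
                   chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT, n_alt_alleles = 1L,
                   stringsAsFactors = FALSE)
  for (m in c("AC", "MQ", "DP", "SOR", "QD", "FS", "MQRankSum",
              "ReadPosRankSum", "BaseQRankSum")) {
    val <- suppressWarnings(vcfR::extract.info(v, element = m, as.numeric = TRUE))
    if (!is.null(val) && !all(is.na(val))) vt[[m]] <- val
  }
  genotype_matrix(t(dos), samples = colnames(gt), variants = vt)
}

#' Default GATK-style hard-filter expressions
#'
#' The nine INFO-metric thresholds applied after joint genotyping:
#' AC > 10, MQ > 30.0, DP > 1525, DP < 9150, SOR < 3.0, QD > 2.0, FS < 60.0,
#' MQRankSum > -12.5, ReadPosRankSum > -8.0, BaseQRankSum > -12.5.
#'
#' @return character vector of filter expressions.
#' @export
default_hard_filters <- function() {
  c("AC > 10", "MQ > 30.0", "DP > 1525", "DP < 9150", "SOR < 3.0",
    "QD > 2.0", "FS < 60.0", "MQRankSum > -12.5", "ReadPosRankSum > -8.0",
    "BaseQRankSum > -12.5")
}

parse_filter_expr <- function(e) {
  m <- regmatches(e, regexec(
    "^\\s*([A-Za-z][A-Za-z0-9_]*)\\s*([<>])\\s*(-?[0-9.]+)\\s*$", e))[[1]]
  if (length(m) != 4)
    stop("cannot parse filter expression: '", e,
         "' (expected 'metric < value' or 'metric > value')")
  list(metric = m[2], cmp = m[3], value = as.numeric(m[4]))
}

#' Apply hard-filter expressions to a variant table
#'
#' Keeps variants that satisfy every expression (each of the form
#' `metric < value` or `metric > value` on an INFO column) and are
#' biallelic. Input order is preserved.
#'
#' @param variants a variant data frame (e.g. `gm$variants`) or a
#'   [genotype_matrix] (filtered as a whole).
#' @param expressions character vector of expressions; default
#'   [default_hard_filters()]. An empty vector keeps all biallelic variants.
#' @return object of the same kind as `variants`, restricted to passing rows.
#' @export
hard_filter <- function(variants, expressions = default_hard_filters()) {
  if (inherits(variants, "genotype_matrix")) {
    keep <- hard_filter_keep(variants$variants, expressions)
    return(subset_genotypes(variants, variants = which(keep)))
  }
  variants[hard_filter_keep(variants, expressions), , drop = FALSE]
}

hard_filter_keep <- function(vt, expressions) {
  keep <- if ("n_alt_alleles" %in% names(vt)) vt$n_alt_alleles == 1L
          else !grepl(",", vt$alt, fixed = TRUE)
  for (e in expressions) {
    pe <- parse_filter_expr(e)
    if (!pe$metric %in% names(vt))
      stop("filter expression references unknown metric: ", pe$metric)
    val <- vt[[pe$metric]]
    pass <- if (pe$cmp == ">") val > pe$value else val < pe$value
    pass[is.na(pass)] <- FALSE
    keep <- keep & pass
  }
  keep
}

#' Classify a continuous or categorical phenotype into two classes
#'
#' Implements two-class phenotype definitions of the "range" kind (e.g.
#' bolting time 40-120 days = class 0, 156-203 days = class 1) and the
#' "category" kind (e.g. Green = 0, Purple = 1). Samples whose value falls in
#' neither range / matches neither category are excluded (`NA` class), so
#' intermediate phenotypes never receive a label.
#'
#' @param values named vector (names = sample ids) of raw phenotype values,
#'   numeric or character.
#' @param class0,class1 for numeric values, length-2 inclusive ranges
#'   `c(lo, hi)`; for character values, single category labels.
#' @param trait trait name.
#' @return a `trait_table` (see [trait_table()]) with the raw values kept in
#'   column `value`.
#' @export
classify_phenotype <- function(values, class0, class1, trait = "trait") {
  ids <- names(values)
  if (is.null(ids)) ids <- paste0("S", seq_along(values))
  if (is.numeric(values)) {
    stopifnot(length(class0) == 2, length(class1) == 2)
    class0 <- sort(class0); class1 <- sort(class1)
    if (max(class0[1], class1[1]) <= min(class0[2], class1[2]))
      stop("class ranges overlap")
    cls <- rep(NA_integer_, length(values))
    cls[values >= class0[1] & values <= class0[2]] <- 0L
    cls[values >= class1[1] & values <= class1[2]] <- 1L
  } else {
    if (class0 == class1) stop("class categories overlap")
    cls <- rep(NA_integer_, length(values))
    cls[values == class0] <- 0L
    cls[values == class1] <- 1L
  }
  trait_table(ids, cls, trait = trait, value = unname(values))
}

#' Read a phenotype TSV
#'
#' Expects columns `sample_id`, `trait`, and either `class` (already 0/1) or
#' `value` (raw, to be classified with [classify_phenotype()]).
#'
#' @param path TSV path.
#' @param trait trait to extract (default: the only one present).
#' @return a `trait_table` if `class` is present, otherwise a named value
#'   vector.
#' @export
read_phenotypes <- function(path, trait = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("trait" %in% names(df)) {
    if (is.null(trait)) {
      trait <- unique(df$trait)
      if (length(trait) > 1) stop("multiple traits present; specify one")
    }
    df <- df[df$trait == trait, , drop = FALSE]
  } else if (is.null(trait)) trait <- "trait"
  if ("class" %in% names(df))
    trait_table(df$sample_id, df$class, trait = trait)
  else stats::setNames(df$value, df$sample_id)
}

#' Read a sample-to-population map TSV
#'
#' @param path TSV with columns `sample_id` and `population`.
#' @return named character vector, sample id -> population label.
#' @export
read_popmap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "population") %in% names(df)))
  stats::setNames(df$population, df$sample_id)
}
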