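#' Per-population allele frequencies with jackknife blocks
#'
#' Alternative-allele frequencies per population and variant,
#' `sum(dosages) / (2 * n_called)`, with contiguous blocks of `block_size`
#' variants assigned per chromosome for the block jackknife. Variants for
#' which any population has no called genotype are dropped (the F4
#' computation expects complete frequency vectors).
#'
#' @param x a [genotype_matrix].
#' @param popmap named character vector, sample id -> population label (see
#'   [read_popmap()]); every sample of `x` must be mapped.
#' @param block_size jackknife block size in variants (default 500).
#' @return object of class `population_frequencies`: list with `freq`
#'   (populations x variants), `counts` (haploid sample sizes), `blocks`
#'   (per-variant block index), `variant_id`.
#' @export
population_frequencies <- function(x, popmap, block_size = 500) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (!all(x$samples %in% names(popmap)))
    stop("unmapped sample(s): ",
         paste(utils::head(setdiff(x$samples, names(popmap))), collapse = ", "))
  pop <- popmap[x$samples]
  pops <- sort(unique(pop))
  if (any(table(pop) == 0)) stop("empty population")
  d <- x$dosage
  if (x$coding == "heatmap_minus1") d[d == -1] <- NA
  freq <- matrix(NA_real_, length(pops), ncol(d),
                 dimnames = list(pops, colnames(d)))
  counts <- freq
  for (k in seq_along(pops)) {
    dk <- d[pop == pops[k], , drop = FALSE]
    called <- colSums(!is.na(dk))
    counts[k, ] <- 2 * called
    freq[k, ] <- ifelse(called > 0, colSums(dk, na.rm = TRUE) / (2 * called),
                        NA_real_)
  }
  keep <- colSums(counts == 0 | is.na(freq)) == 0
  freq <- freq[, keep, drop = FALSE]
  counts <- counts[, keep, drop = FALSE]
  vt <- x$variants[keep, , drop = FALSE]
  blocks <- unlist(lapply(split(seq_len(nrow(vt)), vt$chrom), function(ix)
    (seq_along(ix) - 1L) %/% block_size + 1L), use.names = FALSE)
  # make block ids globally unique across chromosomes
  chrom_f <- factor(vt$chrom, levels = unique(vt$chrom))
  blocks <- as.integer(interaction(chrom_f, blocks, drop = TRUE, lex.order = TRUE))
  new_population_frequencies(freq, counts, blocks, vt$variant_id)
}

#' Construct a population-frequency object directly
#'
#' Low-level constructor for frequency matrices that do not come from a
#' genotype matrix (e.g. closed-form examples).
#'
#' @param freq populations x variants frequency matrix with rownames.
#' @param counts haploid sample sizes, same shape as `freq` (default 2).
#' @param blocks per-variant jackknife block indices (default one variant
#'   per block).
#' @param variant_id optional variant ids.
#' @return a `population_frequencies` object.
#' @export
new_population_frequencies <- function(freq, counts = NULL, blocks = NULL,
                                       variant_id = NULL) {
  freq <- as.matrix(freq)
  if (is.null(counts)) counts <- matrix(2, nrow(freq), ncol(freq))
  if (is.null(blocks)) blocks <- seq_len(ncol(freq))
  if (is.null(variant_id)) variant_id <- colnames(freq)
  if (is.null(variant_id)) variant_id <- paste0("v", seq_len(ncol(freq)))
  stopifnot(all(freq >= 0 & freq <= 1, na.rm = TRUE),
            length(blocks) == ncol(freq))
  structure(list(freq = freq, counts = counts, blocks = as.integer(blocks),
                 variant_id = variant_id),
            class = "population_frequencies")
}

# weighted delete-one-block jackknife (blocks may differ in size);
# reduces to the standard delete-one jackknife for equal blocks
block_jackknife_se <- function(values, blocks) {
  theta_hat <- mean(values)
  bl <- sort(unique(blocks))
  B <- length(bl)
  if (B < 2) stop("fewer than 2 jackknife blocks; SE undefined")
  m <- vapply(bl, function(b) sum(blocks == b), 0)
  M <- length(values)
  theta_minus <- vapply(bl, function(b) mean(values[blocks != b]), 0)
  h <- M / m
  theta_j <- B * theta_hat - sum((1 - m / M) * theta_minus)
  tau <- h * theta_hat - (h - 1) * theta_minus
  var_j <- mean((tau - theta_j)^2 / (h - 1))
  sqrt(var_j)
}

#' F4 allele-sharing statistic with block-jackknife error
#'
#' `f4 = mean over variants of (p_A - p_B)(p_C - p_D)`, the allele-sharing
#' statistic for the quartet (A, B, C, D) with A the outgroup, B the
#' hypothesised source, C the sister of the target, and D the target
#' population. The standard error comes from a weighted delete-one-block
#' jackknife over contiguous variant blocks, `z = f4 / se`, and the p-value
#' from the two-sided normal tail. A significantly positive value (p < 0.05)
#' indicates allele sharing (gene flow) between B and D; a significantly
#' negative one between B and C.
#'
#' @param freqs a `population_frequencies` object.
#' @param quartet character vector (A, B, C, D) of four distinct population
#'   labels present in `freqs`.
#' @return object of class `f4_result`: `quartet`, `f4`, `se`, `z`, `p`,
#'   `n_variants_used`, `interpretation` ("B-D flow", "B-C flow" or "none").
#' @export
f4 <- function(freqs, quartet) {
  stopifnot(inherits(freqs, "population_frequencies"))
  quartet <- as.character(quartet)
  if (length(quartet) != 4 || anyDuplicated(quartet))
    stop("quartet must name four distinct populations")
  missing_pop <- setdiff(quartet, rownames(freqs$freq))
  if (length(missing_pop))
    stop("unknown population(s): ", paste(missing_pop, collapse = ", "))
  p <- freqs$freq[quartet, , drop = FALSE]
  d <- (p[1, ] - p[2, ]) * (p[3, ] - p[4, ])
  est <- mean(d)
  se <- block_jackknife_se(d, freqs$blocks)
  z <- if (se == 0) 0 else est / se
  pval <- 2 * stats::pnorm(-abs(z))
  interp <- if (pval < 0.05 && est > 0) "B-D flow"
            else if (pval < 0.05 && est < 0) "B-C flow"
            else "none"
  structure(list(quartet = stats::setNames(quartet, c("A", "B", "C", "D")),
                 f4 = est, se = se, z = z, p = pval,
                 n_variants_used = length(d), interpretation = interp),
            class = "f4_result")
}

#' @exportS3Method base::print
print.f4_result <- function(x, ...) {
  cat(sprintf("F4(%s) = %.5f  se %.5f  z %.2f  p %.3g  [%s]\n",
              paste(x$quartet, collapse = ", "), x$f4, x$se, x$z, x$p,
              x$interpretation))
  invisible(x)
}

#' Build F4 quartets from gene-flow hypotheses
#'
#' Constructs one quartet F4(A = outgroup, B, C, D) per hypothesis triple:
#' B the proposed source population, C a sister population of the target,
#' and D the proposed migration target. Hypotheses come from prior knowledge
#' or an admixture-graph analysis; this function evaluates them, it does not
#' infer them. Duplicate triples are dropped with a warning.
#'
#' @param pops available population labels.
#' @param outgroup the outgroup population label (position A).
#' @param hypotheses data frame with columns `source` (B), `sister` (C),
#'   `target` (D).
#' @return data frame of quartets with columns `A`, `B`, `C`, `D`.
#' @export
build_quartets <- function(pops, outgroup, hypotheses) {
  if (!outgroup %in% pops) stop("outgroup not among populations: ", outgroup)
  hy <- as.data.frame(hypotheses)
  if (nrow(hy) == 0)
    return(data.frame(A = character(0), B = character(0), C = character(0),
                      D = character(0)))
  stopifnot(all(c("source", "sister", "target") %in% names(hy)))
  unknown <- setdiff(unique(unlist(hy[c("source", "sister", "target")])), pops)
  if (length(unknown))
    stop("hypothesis references unknown population(s): ",
         paste(unknown, collapse = ", "))
  key <- paste(hy$source, hy$sister, hy$target)
  if (anyDuplicated(key)) {
    warning("dropping ", sum(duplicated(key)), " duplicate hypothesis triple(s)")
    hy <- hy[!duplicated(key), , drop = FALSE]
  }
  data.frame(A = outgroup, B = hy$source, C = hy$sister, D = hy$target,
             stringsAsFactors = FALSE)
}

#' Evaluate F4 for a set of quartets
#'
#' @param freqs a `population_frequencies` object.
#' @param quartets data frame from [build_quartets()].
#' @return data frame: A, B, C, D, f4, se, z, p, n_variants_used,
#'   interpretation.
#' @export
f4_table <- function(freqs, quartets) {
  rows <- lapply(seq_len(nrow(quartets)), function(i) {
    r <- f4(freqs, unlist(quartets[i, c("A", "B", "C", "D")]))
    data.frame(A = r$quartet["A"], B = r$quartet["B"], C = r$quartet["C"],
               D = r$quartet["D"], f4 = r$f4, se = r$se, z = r$z, p = r$p,
               n_variants_used = r$n_variants_used,
               interpretation = r$interpretation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(A = character(0), B = character(0), C = character(0),
                      D = character(0), f4 = numeric(0), se = numeric(0),
                      z = numeric(0), p = numeric(0),
                      n_variants_used = integer(0),
                      interpretation = character(0))
  out
}
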