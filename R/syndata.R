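#' Simulation configuration for a synthetic genotype-phenotype cohort
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' Populations drift from a common ancestor under a Balding-Nichols model,
#' optionally exchange alleles through admixture events, and a binary trait
#' is driven by a small set of planted causal variants through a logistic
#' liability. The defaults define a cohort of 300 accessions and 5000
#' biallelic variants on one chromosome.
#'
#' @param n_samples_per_pop diploid samples per population (default 75).
#' @param n_pops number of populations (default 4).
#' @param n_variants number of biallelic variants (default 5000).
#' @param fst Balding-Nichols drift parameter in (0,1); scalar or one value
#'   per population (default 0.1).
#' @param admixture_events data frame with columns `source`, `target`
#'   (population indices or names "pop1"...) and `alpha` in \[0,1\]: the
#'   target population's allele frequencies become
#'   `alpha * source + (1 - alpha) * target`. Default none.
#' @param n_causal number of causal variants (default 10).
#' @param effect_size log-odds per alternative-allele copy (default 1.5).
#' @param ld_block_size variants per LD block; members of a block are copies
#'   of its first column with per-entry refresh probability `ld_decay`
#'   (default 5).
#' @param ld_decay probability that a copied entry is redrawn from the
#'   population frequency instead of copied (default 0.1).
#' @param missing_rate per-entry missing-genotype probability (default 0.02).
#' @param info_fail_rate fraction of non-causal variants whose synthetic
#'   INFO metrics violate each GATK-style hard-filter expression
#'   (default 0.05).
#' @param n_chrom number of synthetic chromosomes (default 1).
#' @param seed integer seed; every draw of the generator is a deterministic
#'   function of it.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [write_fixture()]
#' @export
sim_config <- function(n_samples_per_pop = 75, n_pops = 4, n_variants = 5000,
                       fst = 0.1, admixture_events = NULL, n_causal = 10,
                       effect_size = 1.5, ld_block_size = 5, ld_decay = 0.1,
                       missing_rate = 0.02, info_fail_rate = 0.05,
                       n_chrom = 1, seed = 1) {
  cfg <- list(n_samples_per_pop = as.integer(n_samples_per_pop),
              n_pops = as.integer(n_pops),
              n_variants = as.integer(n_variants), fst = as.numeric(fst),
              admixture_events = admixture_events,
              n_causal = as.integer(n_causal),
              effect_size = as.numeric(effect_size),
              ld_block_size = as.integer(ld_block_size),
              ld_decay = as.numeric(ld_decay),
              missing_rate = as.numeric(missing_rate),
              info_fail_rate = as.numeric(info_fail_rate),
              n_chrom = as.integer(n_chrom), seed = as.integer(seed))
  counts <- c("n_samples_per_pop", "n_pops", "n_variants", "ld_block_size",
              "n_chrom")
  for (nm in counts)
    if (cfg[[nm]] < 1L) stop("invalid config: ", nm, " must be >= 1")
  if (cfg$n_causal < 0L) stop("invalid config: n_causal must be >= 0")
  if (any(cfg$fst <= 0 | cfg$fst >= 1))
    stop("invalid config: fst must lie in (0, 1)")
  if (!length(cfg$fst) %in% c(1L, cfg$n_pops))
    stop("invalid config: fst must be scalar or one value per population")
  if (cfg$ld_decay < 0 || cfg$ld_decay > 1)
    stop("invalid config: ld_decay must lie in [0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("invalid config: missing_rate must lie in [0, 1)")
  if (cfg$n_causal > cfg$n_variants)
    stop("invalid config: n_causal exceeds n_variants")
  if (!is.null(cfg$admixture_events)) {
    ev <- as.data.frame(cfg$admixture_events)
    stopifnot(all(c("source", "target", "alpha") %in% names(ev)))
    if (any(ev$alpha < 0 | ev$alpha > 1))
      stop("invalid config: admixture alpha must lie in [0, 1]")
    cfg$admixture_events <- ev
  }
  structure(cfg, class = "sim_config")
}

pop_names <- function(config) paste0("pop", seq_len(config$n_pops))

resolve_pop <- function(x, config) {
  if (is.numeric(x)) return(as.integer(x))
  m <- match(x, pop_names(config))
  if (anyNA(m)) stop("unknown population label: ", paste(x[is.na(m)], collapse = ", "))
  m
}

#' Simulate per-population allele frequencies under drift and admixture
#'
#' Ancestral alternative-allele frequencies are drawn uniformly on
#' \[0.05, 0.95\]; each population's frequency is then drawn from a Beta
#' distribution with mean equal to the ancestral frequency p and variance
#' p(1-p)F (the Balding-Nichols model). Configured admixture events are
#' applied in order, replacing the target's frequencies by the
#' alpha-weighted mix of source and target.
#'
#' @param config a [sim_config()].
#' @return list with `ancestral` (length `n_variants`) and `freq`
#'   (`n_pops` x `n_variants` matrix, rows named pop1..popK).
#' @export
simulate_allele_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p_anc <- stats::runif(config$n_variants, 0.05, 0.95)
  fst <- rep_len(config$fst, config$n_pops)
  freq <- matrix(NA_real_, config$n_pops, config$n_variants,
                 dimnames = list(pop_names(config), NULL))
  for (k in seq_len(config$n_pops)) {
    f <- fst[k]
    shape <- (1 - f) / f   # Beta(a, b) with a + b = (1 - F)/F gives var p(1-p)F
    freq[k, ] <- stats::rbeta(config$n_variants, p_anc * shape,
                              (1 - p_anc) * shape)
  }
  if (!is.null(config$admixture_events)) {
    ev <- config$admixture_events
    for (i in seq_len(nrow(ev))) {
      s <- resolve_pop(ev$source[i], config)
      t <- resolve_pop(ev$target[i], config)
      a <- ev$alpha[i]
      freq[t, ] <- a * freq[s, ] + (1 - a) * freq[t, ]
    }
  }
  list(ancestral = p_anc, freq = freq)
}

variant_positions <- function(config) {
  # variants evenly spread over chromosomes, 1 kb apart
  chrom_of <- rep(seq_len(config$n_chrom), length.out = config$n_variants)
  chrom_of <- sort(chrom_of)
  pos <- unlist(lapply(split(seq_along(chrom_of), chrom_of),
                       function(ix) seq_along(ix) * 1000L), use.names = FALSE)
  data.frame(chrom = paste0("chr", chrom_of), pos = pos)
}

#' Simulate genotypes with LD blocks, planted causal variants and missingness
#'
#' Dosages are binomial(2, p) draws from each sample's population frequency.
#' Consecutive variants are grouped into LD blocks of `ld_block_size`; all
#' non-causal members of a block copy the block's first column, each entry
#' independently refreshed from its own frequency with probability
#' `ld_decay`. Causal columns are drawn independently (never copy targets),
#' so recovered proxies can be distinguished from planted truth. A missing
#' mask with rate `missing_rate` is applied to all columns.
#'
#' @param freqs result of [simulate_allele_frequencies()].
#' @param config the same [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix]) and `truth` (list:
#'   `causal_variant_ids`, `effect`, `admixture_events`,
#'   `population_assignments`).
#' @export
simulate_genotypes <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_samples_per_pop * config$n_pops
  p <- config$n_variants
  pop_of <- rep(seq_len(config$n_pops), each = config$n_samples_per_pop)
  samples <- sprintf("S%03d", seq_len(n))
  pf <- freqs$freq[pop_of, , drop = FALSE]          # n x p expanded frequencies
  dosage <- matrix(stats::rbinom(n * p, 2L, pf), n, p)

  causal <- if (config$n_causal > 0L)
    sort(sample.int(p, config$n_causal)) else integer(0)

  if (config$ld_block_size > 1L) {
    block <- (seq_len(p) - 1L) %/% config$ld_block_size + 1L
    for (b in unique(block)) {
      ix <- which(block == b)
      head_ix <- setdiff(ix, causal)[1]             # block seed column
      if (is.na(head_ix)) next
      for (j in setdiff(ix, c(head_ix, causal))) {
        keep <- stats::runif(n) >= config$ld_decay
        dosage[, j] <- ifelse(keep, dosage[, head_ix],
                              stats::rbinom(n, 2L, pf[, j]))
      }
    }
  }

  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * p) < config$missing_rate, n, p)
    dosage[miss] <- NA_integer_
  }

  loc <- variant_positions(config)
  vt <- data.frame(variant_id = paste0(loc$chrom, "_", loc$pos),
                   chrom = loc$chrom, pos = loc$pos,
                   ref = "A", alt = "T", n_alt_alleles = 1L,
                   stringsAsFactors = FALSE)
  alleles <- c("A", "C", "G", "T")
  vt$ref <- sample(alleles, p, replace = TRUE)
  vt$alt <- vapply(vt$ref, function(r) sample(setdiff(alleles, r), 1L), "")

  gm <- genotype_matrix(dosage, samples = samples, variants = vt)
  truth <- list(causal_variant_ids = vt$variant_id[causal],
                effect = config$effect_size,
                admixture_events = config$admixture_events,
                population_assignments = stats::setNames(
                  pop_names(config)[pop_of], samples))
  list(genotypes = gm, truth = truth)
}

#' Simulate a binary trait from planted causal variants
#'
#' The liability of each sample is the sum of `effect_size` times its causal
#' dosages (missing dosages contribute 0); class 1 is drawn with probability
#' `plogis(liability - offset)`, the offset being the median liability so
#' that the marginal class balance stays near 1/2.
#'
#' @param genotypes a [genotype_matrix].
#' @param truth truth record from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @param trait_name label for the trait (default "trait1").
#' @param offset optional explicit liability offset; by default the median
#'   liability, which keeps the marginal class balance near 1/2.
#' @return a `trait_table` data frame (columns `sample_id`, `class`) with
#'   attribute `trait`.
#' @export
simulate_binary_trait <- function(genotypes, truth, config,
                                  trait_name = "trait1", offset = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  d <- genotypes$dosage[, match(truth$causal_variant_ids,
                                genotypes$variants$variant_id),
                        drop = FALSE]
  d[is.na(d)] <- 0
  liab <- as.numeric(d %*% rep(config$effect_size, ncol(d)))
  if (is.null(offset)) offset <- stats::median(liab)
  cls <- as.integer(stats::runif(length(liab)) < stats::plogis(liab - offset))
  trait_table(genotypes$samples, cls, trait = trait_name)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper chaining [simulate_allele_frequencies()],
#' [simulate_genotypes()] and [simulate_binary_trait()].
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `truth`, `trait`, `freqs`.
#' @export
simulate_cohort <- function(config) {
  freqs <- simulate_allele_frequencies(config)
  g <- simulate_genotypes(freqs, config)
  trait <- simulate_binary_trait(g$genotypes, g$truth, config)
  list(genotypes = g$genotypes, truth = g$truth, trait = trait, freqs = freqs)
}

default_info_ranges <- function() {
  # (pass_lo, pass_hi, fail value) per INFO metric, against default_hard_filters()
  list(AC  = c(11, 600, 5),   MQ  = c(40, 60, 25),
       DP  = c(2000, 9000, 1000), SOR = c(0.5, 2.5, 4),
       QD  = c(5, 30, 1),     FS  = c(0, 30, 80),
       MQRankSum = c(-2, 2, -15), ReadPosRankSum = c(-2, 2, -10),
       BaseQRankSum = c(-2, 2, -15))
}

synthetic_info <- function(config, causal_ix) {
  set.seed(config$seed + 3L)
  p <- config$n_variants
  rngs <- default_info_ranges()
  info <- as.data.frame(lapply(rngs, function(r)
    round(stats::runif(p, r[1], r[2]), 2)))
  if (config$info_fail_rate > 0) {
    eligible <- setdiff(seq_len(p), causal_ix)
    for (m in names(rngs)) {
      n_fail <- round(config$info_fail_rate * length(eligible))
      if (n_fail > 0)
        info[sample(eligible, n_fail), m] <- rngs[[m]][3]
    }
  }
  info$AC <- round(info$AC)
  info
}

dosage_to_gt <- function(d) {
  gt <- c("0/0", "0/1", "1/1")[d + 1L]
  gt[is.na(d)] <- "./."
  gt
}

#' Write a synthetic cohort to disk as standard files
#'
#' Emits a VCF 4.2 (unphased GT, synthetic INFO metrics covering the nine
#' GATK-style hard-filter fields), a phenotype TSV, a population TSV, a GFF3
#' with gene/mRNA/exon/CDS models tiled along each chromosome, and a JSON
#' truth file listing the planted causal variants.
#'
#' @param genotypes a [genotype_matrix].
#' @param truth truth record from [simulate_genotypes()].
#' @param config the [sim_config()] used.
#' @param out_dir output directory (created if absent).
#' @param trait optional `trait_table` to write as phenotype TSV.
#' @return invisibly, named character vector of the file paths written.
#' @export
write_fixture <- function(genotypes, truth, config, out_dir, trait = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  vt <- genotypes$variants
  causal_ix <- match(truth$causal_variant_ids, vt$variant_id)
  info <- synthetic_info(config, causal_ix)

  vcf_path <- file.path(out_dir, "cohort.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=chr%d>", seq_len(config$n_chrom)),
           sprintf(paste0("##INFO=<ID=%s,Number=1,Type=Float,",
                          "Description=\"Synthetic %s\">"),
                   names(info), names(info)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", genotypes$samples), collapse = "\t"))
  info_str <- do.call(paste, c(Map(function(nm, v) paste0(nm, "=", v),
                                   names(info), info), sep = ";"))
  gt_body <- apply(genotypes$dosage, 1, dosage_to_gt)   # p x n
  body <- paste(vt$chrom, vt$pos, vt$variant_id, vt$ref, vt$alt, ".", "PASS",
                info_str, "GT",
                apply(gt_body, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), vcf_path)

  pop_path <- file.path(out_dir, "populations.tsv")
  utils::write.table(
    data.frame(sample_id = names(truth$population_assignments),
               population = unname(truth$population_assignments)),
    pop_path, sep = "\t", quote = FALSE, row.names = FALSE)

  paths <- c(vcf = vcf_path, populations = pop_path)

  if (!is.null(trait)) {
    ph_path <- file.path(out_dir, "phenotypes.tsv")
    utils::write.table(
      data.frame(sample_id = trait$sample_id, trait = attr(trait, "trait"),
                 class = trait$class),
      ph_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["phenotypes"] <- ph_path
  }

  gff_path <- file.path(out_dir, "genes.gff3")
  writeLines(tile_genes_gff3(config), gff_path)
  paths["gff3"] <- gff_path

  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(causal_variant_ids = truth$causal_variant_ids,
         effect = truth$effect,
         admixture_events = truth$admixture_events,
         population_assignments = as.list(truth$population_assignments)),
    truth_path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  paths["truth"] <- truth_path
  invisible(paths)
}

# genes of 4 kb (two exons, inner CDS) every 12 kb, alternating strand
tile_genes_gff3 <- function(config) {
  per_chrom <- ceiling(config$n_variants / config$n_chrom)
  chrom_len <- per_chrom * 1000L
  lines <- "##gff-version 3"
  g <- 0L
  for (c_i in seq_len(config$n_chrom)) {
    chrom <- paste0("chr", c_i)
    starts <- seq(2001L, max(chrom_len - 4000L, 2001L), by = 12000L)
    for (s in starts) {
      g <- g + 1L
      id <- sprintf("gene%04d", g)
      strand <- if (g %% 2L == 0L) "-" else "+"
      e1 <- c(s, s + 1199L); e2 <- c(s + 2800L, s + 3999L)
      cds <- c(s + 600L, s + 3399L)
      f <- function(type, st, en, attr)
        paste(chrom, "synthetic", type, st, en, ".", strand, ".", attr,
              sep = "\t")
      lines <- c(lines,
        f("gene", s, s + 3999L, paste0("ID=", id)),
        f("mRNA", s, s + 3999L, paste0("ID=", id, ".1;Parent=", id)),
        f("exon", e1[1], e1[2], paste0("Parent=", id, ".1")),
        f("exon", e2[1], e2[2], paste0("Parent=", id, ".1")),
        f("CDS", max(cds[1], e1[1]), e1[2], paste0("Parent=", id, ".1")),
        f("CDS", e2[1], min(cds[2], e2[2]), paste0("Parent=", id, ".1")))
    }
  }
  lines
}
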