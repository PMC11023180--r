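# small fixtures shared across test files; everything is generated in code

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_samples_per_pop = 15, n_pops = 4, n_variants = 200, n_causal = 5,
         effect_size = 2, ld_block_size = 5, ld_decay = 0.1,
         missing_rate = 0.02, seed = 11),
    list(...))
  do.call(sim_config, args)
}

# genotype matrix straight from a dosage matrix (no missing metadata needed)
gm_from_dosage <- function(d, chrom = "chr1", pos = NULL) {
  p <- ncol(d)
  if (is.null(pos)) pos <- seq_len(p) * 100L
  chrom <- rep_len(chrom, p)
  vt <- data.frame(variant_id = paste0(chrom, "_", pos), chrom = chrom,
                   pos = pos, ref = "A", alt = "T", n_alt_alleles = 1L)
  genotype_matrix(d, samples = sprintf("S%03d", seq_len(nrow(d))),
                  variants = vt)
}

# a separable two-class fixture: one variant fully determines the class
separable_fixture <- function(n = 60, p = 20, seed = 1) {
  set.seed(seed)
  d <- matrix(rbinom(n * p, 2, 0.4), n, p)
  y <- rep(0:1, length.out = n)
  d[, 1] <- y * 2L             # dosage 0 for class 0, 2 for class 1
  list(gm = gm_from_dosage(d), y = y)
}

# fit records with prescribed appearance patterns
fake_fits <- function(appearances, n_fits) {
  lapply(seq_len(n_fits), function(i) {
    ids <- names(appearances)[appearances >= i]
    structure(list(seed = i, accuracy = 0.5,
                   gain_scores = stats::setNames(rep(1, length(ids)), ids)),
              class = "fit_record")
  })
}

# GFF3 with one + strand and one - strand gene, with two exons and a CDS
# spanning part of each exon; returns path and the coordinates used
region_test_gff <- function() {
  path <- tempfile(fileext = ".gff3")
  lines <- c("##gff-version 3",
    # + strand gene: span 1000..5000, exons 1000..1999 and 3500..5000,
    # CDS 1500..1999 and 3500..4500 (so 1000..1499 is utr5, 4501..5000 utr3)
    "chr1\ttest\tgene\t1000\t5000\t.\t+\t.\tID=gplus",
    "chr1\ttest\tmRNA\t1000\t5000\t.\t+\t.\tID=gplus.1;Parent=gplus",
    "chr1\ttest\texon\t1000\t1999\t.\t+\t.\tParent=gplus.1",
    "chr1\ttest\texon\t3500\t5000\t.\t+\t.\tParent=gplus.1",
    "chr1\ttest\tCDS\t1500\t1999\t.\t+\t.\tParent=gplus.1",
    "chr1\ttest\tCDS\t3500\t4500\t.\t+\t.\tParent=gplus.1",
    # - strand gene far away: span 50000..54000, same internal layout, so
    # utr5 is at the high-coordinate end
    "chr1\ttest\tgene\t50000\t54000\t.\t-\t.\tID=gminus",
    "chr1\ttest\tmRNA\t50000\t54000\t.\t-\t.\tID=gminus.1;Parent=gminus",
    "chr1\ttest\texon\t50000\t50999\t.\t-\t.\tParent=gminus.1",
    "chr1\ttest\texon\t52500\t54000\t.\t-\t.\tParent=gminus.1",
    "chr1\ttest\tCDS\t50500\t50999\t.\t-\t.\tParent=gminus.1",
    "chr1\ttest\tCDS\t52500\t53500\t.\t-\t.\tParent=gminus.1")
  writeLines(lines, path)
  path
}

variant_df <- function(chrom, pos) {
  data.frame(variant_id = paste0(chrom, "_", pos), chrom = chrom, pos = pos)
}

# independent brute-force oracle for windowed greedy pruning: walks windows
# along the (single-chromosome) matrix, repeatedly dropping the
# lower-MAF/later-position member of any above-threshold pair
prune_oracle <- function(d, window, step, r2_max) {
  p <- ncol(d)
  keep <- rep(TRUE, p)
  maf <- sapply(seq_len(p), function(j) {
    f <- mean(d[, j], na.rm = TRUE) / 2
    if (is.nan(f)) 0 else min(f, 1 - f)
  })
  mono <- sapply(seq_len(p), function(j) {
    v <- var(d[, j], na.rm = TRUE); is.na(v) || v == 0
  })
  r2 <- function(i, j) {
    ok <- !is.na(d[, i]) & !is.na(d[, j])
    if (sum(ok) < 2) return(0)
    r <- suppressWarnings(cor(d[ok, i], d[ok, j]))
    if (is.na(r)) 0 else r^2
  }
  for (s in seq(1, p, by = step)) {
    win <- s:min(s + window - 1, p)
    repeat {
      active <- win[keep[win] & !mono[win]]
      dropped <- FALSE
      if (length(active) >= 2) {
        for (a in 1:(length(active) - 1)) {
          for (b in (a + 1):length(active)) {
            i <- active[a]; j <- active[b]
            if (!keep[i] || !keep[j]) next
            if (r2(i, j) > r2_max) {
              dr <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j
                    else max(i, j)   # positions are in column order here
              keep[dr] <- FALSE
              dropped <- TRUE
            }
          }
        }
      }
      if (!dropped) break
    }
  }
  which(keep)
}
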