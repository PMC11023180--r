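#' Greedy windowed LD pruning of a genotype matrix
#'
#' Mirrors the behaviour of plink's `--indep-pairwise <window> <step> <r2>`
#' with variant-count windows: within each window of `window` consecutive
#' variants (per chromosome, in position order), every pair of retained
#' variants with squared Pearson correlation of dosages above `r2_max` loses
#' its lower-minor-allele-frequency member (ties drop the later position);
#' the window then advances by `step` variants. r-squared is computed over
#' pairwise-complete samples; pairs with fewer than two complete samples, or
#' involving a monomorphic variant, are treated as r-squared 0.
#'
#' The default `(50, 10, 0.1)` follows the flag as run in variant counts; a
#' kilobase window is available via `window_kb` for the textual
#' "50 kb window, 10 bp step" reading.
#'
#' @param x a [genotype_matrix].
#' @param window window size in variants (default 50).
#' @param step step size in variants (default 10); must not exceed `window`.
#' @param r2_max prune pairs with r-squared strictly above this (default 0.1).
#' @param window_kb optional window size in kilobases; when given, windows
#'   contain all variants within `window_kb` kb of the window's first
#'   variant and `step` is interpreted in variants as before.
#' @return character vector of retained variant ids, in input order.
#' @export
ld_prune <- function(x, window = 50, step = 10, r2_max = 0.1,
                     window_kb = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (step < 1 || window < step) stop("need window >= step >= 1")
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must lie in (0, 1]")
  d <- x$dosage
  if (x$coding == "heatmap_minus1") d[d == -1] <- NA
  vt <- x$variants
  keep <- rep(TRUE, ncol(d))
  maf <- apply(d, 2, function(col) {
    f <- mean(col, na.rm = TRUE) / 2
    if (is.nan(f)) 0 else min(f, 1 - f)
  })
  variance <- apply(d, 2, stats::var, na.rm = TRUE)
  mono <- is.na(variance) | variance == 0

  for (chrom in unique(vt$chrom)) {
    ix <- which(vt$chrom == chrom)
    ix <- ix[order(vt$pos[ix])]
    starts <- seq(1L, length(ix), by = step)
    for (s in starts) {
      win <- if (is.null(window_kb)) {
        ix[s:min(s + window - 1L, length(ix))]
      } else {
        lo <- vt$pos[ix[s]]
        ix[s:length(ix)][vt$pos[ix[s:length(ix)]] <= lo + window_kb * 1000]
      }
      win <- win[keep[win] & !mono[win]]
      if (length(win) < 2) next
      # scan pairs over currently-kept members; a drop immediately removes
      # the variant from further pairs in this and later windows
      for (a in seq_len(length(win) - 1L)) {
        i <- win[a]
        if (!keep[i]) next
        for (b in (a + 1L):length(win)) {
          j <- win[b]
          if (!keep[j]) next
          r2 <- dosage_r2(d[, i], d[, j])
          if (r2 > r2_max) {
            drop <- if (maf[i] < maf[j]) i
                    else if (maf[j] < maf[i]) j
                    else if (vt$pos[i] >= vt$pos[j]) i else j
            keep[drop] <- FALSE
            if (drop == i) break
          }
        }
      }
    }
  }
  vt$variant_id[keep]
}

# squared Pearson correlation over pairwise-complete samples; undefined -> 0
dosage_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(0)
  r <- suppressWarnings(stats::cor(a[ok], b[ok]))
  if (is.na(r)) 0 else r * r
}
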