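#' Expand selected variants to highly correlated companions
#'
#' For each selected (seed) variant, computes the Pearson correlation of its
#' dosages with every other variant of the full (unpruned) matrix over
#' pairwise-complete samples and reports companions whose correlation
#' reaches `r_min` (default 0.97, the "correlated variants" cutoff applied
#' after selection on the pruned set). Companions that are themselves
#' selected are not reported again; zero-variance companions and pairs with
#' fewer than `min_complete` complete samples are skipped.
#'
#' @param selected a `selection_result` (its selected rows are used) or a
#'   character vector of seed variant ids.
#' @param full_matrix the full [genotype_matrix] to search.
#' @param r_min correlation threshold in (0, 1] (default 0.97), applied to
#'   the signed correlation unless `absolute = TRUE`.
#' @param absolute apply the threshold to |r| instead of signed r.
#' @param min_complete minimum pairwise-complete samples per hit
#'   (default 10); hits below it are skipped with a warning.
#' @return data frame of correlation hits: `seed_variant_id`,
#'   `companion_variant_id`, `r`, `n_complete`.
#' @export
expand_selected <- function(selected, full_matrix, r_min = 0.97,
                            absolute = FALSE, min_complete = 10) {
  stopifnot(inherits(full_matrix, "genotype_matrix"))
  if (r_min <= 0 || r_min > 1) stop("r_min must lie in (0, 1]")
  seeds <- if (inherits(selected, "selection_result"))
    selected$variant_id[selected$selected] else as.character(selected)
  d <- full_matrix$dosage
  if (full_matrix$coding == "heatmap_minus1") d[d == -1] <- NA
  miss <- match(seeds, colnames(d))
  if (anyNA(miss))
    stop("selected id(s) absent from full matrix: ",
         paste(seeds[is.na(miss)], collapse = ", "))
  hits <- list()
  obs <- !is.na(d)
  for (s in seeds) {
    r <- suppressWarnings(stats::cor(d[, s], d, use = "pairwise.complete.obs"))
    r <- drop(r)
    n_complete <- colSums(obs & obs[, s])
    score <- if (absolute) abs(r) else r
    cand <- which(!is.na(score) & score >= r_min)
    cand <- setdiff(colnames(d)[cand], c(s, seeds))
    if (length(cand) == 0) next
    low <- n_complete[cand] < min_complete
    if (any(low)) {
      warning("skipping ", sum(low), " hit(s) of ", s, " with fewer than ",
              min_complete, " complete sample pairs")
      cand <- cand[!low]
    }
    if (length(cand))
      hits[[s]] <- data.frame(seed_variant_id = s, companion_variant_id = cand,
                              r = unname(r[cand]),
                              n_complete = unname(n_complete[cand]),
                              stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits)
         else data.frame(seed_variant_id = character(0),
                         companion_variant_id = character(0),
                         r = numeric(0), n_complete = integer(0))
  rownames(out) <- NULL
  out
}
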