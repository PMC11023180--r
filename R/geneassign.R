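#' Read gene models from a GFF3 file
#'
#' Imports gene, mRNA, exon and CDS features (via \pkg{rtracklayer}) and
#' groups exons and CDS by gene through their Parent attributes. UTRs are
#' not required in the file; they are derived as exon minus CDS during
#' annotation.
#'
#' @param path GFF3 file.
#' @return list of class `gene_models` with `GRanges` elements `genes`,
#'   `exons`, `cds`, each carrying a `gene_id` metadata column.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  gene_id <- as.character(genes$ID)
  if (length(genes) == 0) stop("no gene features in ", path)
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = gene_id)

  # transcripts map their Parent gene; exons/CDS map via their transcript
  tx <- gr[type %in% c("mRNA", "transcript")]
  tx_parent <- stats::setNames(vapply(tx$Parent, `[`, "", 1),
                               as.character(tx$ID))
  feature_gene <- function(feat) {
    par <- vapply(feat$Parent, `[`, "", 1)
    gid <- ifelse(par %in% names(tx_parent), unname(tx_parent[par]), par)
    S4Vectors::mcols(feat) <- S4Vectors::DataFrame(gene_id = gid)
    feat[gid %in% gene_id]
  }
  structure(list(genes = genes, exons = feature_gene(gr[type == "exon"]),
                 cds = feature_gene(gr[type == "CDS"])),
            class = "gene_models")
}

REGION_PRIORITY <- c(exon_cds = 1, utr5 = 2, utr3 = 2, intron = 3,
                     upstream = 4, downstream = 4, intergenic = 5)

#' Assign variants to gene regions
#'
#' Classifies each variant position against the gene models: inside an exon
#' overlapping CDS is `exon_cds`; inside an exon 5'/3' of the gene's CDS
#' span (strand-aware) is `utr5`/`utr3`; inside the gene but no exon is
#' `intron`; within `window` bp 5' of the gene's transcription start
#' (strand-aware) is `upstream` and within `window` bp 3' of its end
#' `downstream` (with the distance to the gene); otherwise `intergenic`.
#' A variant hitting several genes reports the highest-priority region
#' (exon_cds > utr > intron > upstream/downstream), ties resolved by the
#' nearest strand-aware gene start. Exon hits in genes without CDS records
#' are reported as `exon_cds`. Variants on chromosomes absent from the gene
#' models are intergenic, with a warning.
#'
#' @param variants data frame with `variant_id`, `chrom`, `pos` (e.g.
#'   `gm$variants` or a `selection_result` joined to it).
#' @param genes a `gene_models` object from [read_gene_models()].
#' @param window up/downstream window in bp (default 5000); `window = 0`
#'   yields only genic/intergenic calls.
#' @return data frame: `variant_id`, `gene_id` (`NA` when intergenic),
#'   `region`, `distance` (bp to gene for up/downstream, otherwise `NA`).
#' @export
annotate_variants <- function(variants, genes, window = 5000) {
  stopifnot(inherits(genes, "gene_models"))
  vt <- as.data.frame(variants)
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(vt)))
  known <- unique(as.character(GenomicRanges::seqnames(genes$genes)))
  if (!all(vt$chrom %in% known))
    warning("variant chromosome(s) absent from gene models: ",
            paste(setdiff(unique(vt$chrom), known), collapse = ", "),
            "; classified intergenic")

  g <- genes$genes
  strand_plus <- as.character(GenomicRanges::strand(g)) != "-"
  g_start <- GenomicRanges::start(g)
  g_end <- GenomicRanges::end(g)
  tss <- ifelse(strand_plus, g_start, g_end)

  out <- data.frame(variant_id = vt$variant_id, gene_id = NA_character_,
                    region = "intergenic", distance = NA_real_,
                    stringsAsFactors = FALSE)
  vgr <- GenomicRanges::GRanges(vt$chrom,
                                IRanges::IRanges(vt$pos, width = 1))
  suppressWarnings({
    hit_gene <- GenomicRanges::findOverlaps(vgr, g)
    near <- GenomicRanges::findOverlaps(
      vgr, GenomicRanges::resize(g, GenomicRanges::width(g) + 2 * window,
                                 fix = "center"))
  })
  cand <- unique(rbind(as.data.frame(hit_gene), as.data.frame(near)))

  classify_one <- function(v_i, g_i) {
    pos <- vt$pos[v_i]
    inside <- pos >= g_start[g_i] && pos <= g_end[g_i]
    gid <- g$gene_id[g_i]
    if (inside) {
      ex <- genes$exons[genes$exons$gene_id == gid]
      in_exon <- length(ex) > 0 &&
        any(pos >= GenomicRanges::start(ex) & pos <= GenomicRanges::end(ex))
      if (!in_exon) return(list(region = "intron", distance = NA_real_))
      cds <- genes$cds[genes$cds$gene_id == gid]
      if (length(cds) == 0) return(list(region = "exon_cds", distance = NA_real_))
      cs <- min(GenomicRanges::start(cds)); ce <- max(GenomicRanges::end(cds))
      if (any(pos >= GenomicRanges::start(cds) & pos <= GenomicRanges::end(cds)))
        return(list(region = "exon_cds", distance = NA_real_))
      five_prime <- if (strand_plus[g_i]) pos < cs else pos > ce
      return(list(region = if (five_prime) "utr5" else "utr3",
                  distance = NA_real_))
    }
    # outside the gene span: up/downstream within the window
    if (window <= 0) return(NULL)
    before <- pos < g_start[g_i]
    dist <- if (before) g_start[g_i] - pos else pos - g_end[g_i]
    if (dist > window) return(NULL)
    upstream <- (before && strand_plus[g_i]) || (!before && !strand_plus[g_i])
    list(region = if (upstream) "upstream" else "downstream", distance = dist)
  }

  for (v_i in unique(cand[[1]])) {
    rows <- cand[cand[[1]] == v_i, 2]
    best <- NULL
    for (g_i in rows) {
      cl <- classify_one(v_i, g_i)
      if (is.null(cl)) next
      cl$gene_id <- g$gene_id[g_i]
      cl$tss_dist <- abs(vt$pos[v_i] - tss[g_i])
      if (is.null(best) ||
          REGION_PRIORITY[cl$region] < REGION_PRIORITY[best$region] ||
          (REGION_PRIORITY[cl$region] == REGION_PRIORITY[best$region] &&
           cl$tss_dist < best$tss_dist))
        best <- cl
    }
    if (!is.null(best)) {
      out$gene_id[v_i] <- best$gene_id
      out$region[v_i] <- best$region
      out$distance[v_i] <- best$distance
    }
  }
  out
}

#' Rank candidate genes by the variants they carry
#'
#' Genes carrying at least one selected or expanded variant, with per-gene
#' variant counts and the regions hit, ordered by decreasing count (ties by
#' gene id).
#'
#' @param annotations output of [annotate_variants()] restricted to the
#'   selected and expanded variants.
#' @return data frame: `gene_id`, `n_variants`, `regions` (comma-separated),
#'   `variant_ids`.
#' @export
candidate_genes <- function(annotations) {
  an <- annotations[!is.na(annotations$gene_id), , drop = FALSE]
  if (nrow(an) == 0)
    return(data.frame(gene_id = character(0), n_variants = integer(0),
                      regions = character(0), variant_ids = character(0)))
  sp <- split(an, an$gene_id)
  out <- data.frame(
    gene_id = names(sp),
    n_variants = vapply(sp, nrow, 0L),
    regions = vapply(sp, function(d)
      paste(sort(unique(d$region)), collapse = ","), ""),
    variant_ids = vapply(sp, function(d)
      paste(d$variant_id, collapse = ","), ""),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_variants, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Row and column orders for a genotype-distribution heatmap
#'
#' Hierarchically clusters accessions (within each phenotype class) and
#' variants of a selected-variant matrix in the -1/0/1/2 heatmap coding,
#' using Euclidean distance and complete linkage with the missing code -1
#' treated as an ordinary value. The returned orders group accessions by
#' class, each class internally ordered by its dendrogram, matching the
#' class-panel layout of genotype-distribution heatmaps.
#'
#' @param x a [genotype_matrix], typically restricted to selected variants;
#'   converted to `heatmap_minus1` coding if needed.
#' @param trait a `trait_table` for the accessions of `x`.
#' @return list: `row_order` (sample labels, class 0 block then class 1),
#'   `col_order` (variant ids), `row_trees` (per-class hclust or NULL),
#'   `col_tree` (hclust or NULL).
#' @export
genotype_heatmap_order <- function(x, trait) {
  stopifnot(inherits(x, "genotype_matrix"))
  x <- recode_genotypes(x, "heatmap_minus1")
  cls <- if (inherits(trait, "trait_table"))
    trait$class[match(x$samples, trait$sample_id)] else as.integer(trait)
  d <- x$dosage

  cluster_order <- function(m) {
    if (nrow(m) < 2) return(list(order = seq_len(nrow(m)), tree = NULL))
    tr <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "complete")
    list(order = tr$order, tree = tr)
  }

  row_order <- character(0); row_trees <- list()
  for (k in sort(unique(cls[!is.na(cls)]))) {
    ix <- which(cls == k)
    co <- cluster_order(d[ix, , drop = FALSE])
    row_order <- c(row_order, x$samples[ix][co$order])
    row_trees[[as.character(k)]] <- co$tree
  }
  col <- if (ncol(d) < 2) list(order = seq_len(ncol(d)), tree = NULL)
         else cluster_order(t(d))
  list(row_order = row_order, col_order = colnames(d)[col$order],
       row_trees = row_trees, col_tree = col$tree)
}
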