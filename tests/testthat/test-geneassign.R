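test_that("all seven region types are recovered on both strands", {
  models <- read_gene_models(region_test_gff())
  # + strand gene spans 1000..5000: exons 1000..1999 / 3500..5000,
  # CDS 1500..1999 / 3500..4500
  plus <- variant_df("chr1", c(
    1700,   # inside CDS            -> exon_cds
    1200,   # exon 5' of CDS        -> utr5
    4800,   # exon 3' of CDS        -> utr3
    2500,   # inside gene, no exon  -> intron
    400,    # 600 bp before start   -> upstream (+)
    5600,   # 600 bp after end      -> downstream (+)
    20000)) # far from everything   -> intergenic
  ann <- annotate_variants(plus, models, window = 5000)
  expect_identical(ann$region, c("exon_cds", "utr5", "utr3", "intron",
                                 "upstream", "downstream", "intergenic"))
  expect_identical(ann$gene_id, c(rep("gplus", 6), NA))
  expect_equal(ann$distance, c(NA, NA, NA, NA, 600, 600, NA))

  # - strand gene spans 50000..54000: utr5 at the high end, upstream beyond
  minus <- variant_df("chr1", c(
    50700,  # inside CDS           -> exon_cds
    53800,  # exon 5' of CDS (high)-> utr5
    50200,  # exon 3' of CDS (low) -> utr3
    51500,  # intron
    54500,  # after end on - strand -> upstream, distance 500
    49500,  # before start          -> downstream, distance 500
    30000)) # intergenic
  ann2 <- annotate_variants(minus, models, window = 5000)
  expect_identical(ann2$region, c("exon_cds", "utr5", "utr3", "intron",
                                  "upstream", "downstream", "intergenic"))
  expect_equal(ann2$distance, c(NA, NA, NA, NA, 500, 500, NA))
})

test_that("window = 0 yields only genic or intergenic calls", {
  models <- read_gene_models(region_test_gff())
  v <- variant_df("chr1", c(400, 1700, 5600, 2500))
  ann <- annotate_variants(v, models, window = 0)
  expect_identical(ann$region, c("intergenic", "exon_cds", "intergenic",
                                 "intron"))
})

test_that("region classification is a partition and flags unknown chromosomes", {
  models <- read_gene_models(region_test_gff())
  set.seed(1)
  v <- variant_df("chr1", sort(sample(1:60000, 200)))
  ann <- annotate_variants(v, models, window = 2000)
  expect_identical(nrow(ann), 200L)
  expect_true(all(ann$region %in% c("upstream", "downstream", "intron",
                                    "exon_cds", "utr5", "utr3", "intergenic")))
  expect_identical(is.na(ann$gene_id), ann$region == "intergenic")

  expect_warning(ann_bad <- annotate_variants(variant_df("chrX", 100), models),
                 "absent from gene models")
  expect_identical(ann_bad$region, "intergenic")
})

test_that("overlapping genes resolve by region priority, ties by nearest start", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr1\tt\tgene\t1000\t4000\t.\t+\t.\tID=gA",
    "chr1\tt\tmRNA\t1000\t4000\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\tt\texon\t1000\t4000\t.\t+\t.\tParent=gA.1",
    "chr1\tt\tCDS\t1000\t4000\t.\t+\t.\tParent=gA.1",
    "chr1\tt\tgene\t3000\t6000\t.\t+\t.\tID=gB",
    "chr1\tt\tmRNA\t3000\t6000\t.\t+\t.\tID=gB.1;Parent=gB"), path)
  models <- read_gene_models(path)
  # 3500 is exon_cds in gA but intron (no exon) in gB -> exon_cds wins
  ann <- annotate_variants(variant_df("chr1", 3500), models)
  expect_identical(ann$region, "exon_cds")
  expect_identical(ann$gene_id, "gA")
  # 4500 is intronic in gB only
  ann2 <- annotate_variants(variant_df("chr1", 4500), models)
  expect_identical(ann2$gene_id, "gB")
  expect_identical(ann2$region, "intron")
})

test_that("candidate genes are counted and ordered; empty annotation gives empty list", {
  ann <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4", "v5"),
    gene_id = c("gB", "gA", "gB", NA, "gC"),
    region = c("intron", "upstream", "utr5", "intergenic", "downstream"),
    distance = NA_real_)
  cand <- candidate_genes(ann)
  expect_identical(cand$gene_id, c("gB", "gA", "gC"))
  expect_identical(cand$n_variants, c(2L, 1L, 1L))
  expect_identical(cand$regions[1], "intron,utr5")
  empty <- candidate_genes(ann[4, ])
  expect_identical(nrow(empty), 0L)
})

test_that("planted causal variants inside genes surface as candidates", {
  cfg <- tiny_config(seed = 70, n_variants = 300, missing_rate = 0)
  co <- simulate_cohort(cfg)
  dirp <- tempfile()
  write_fixture(co$genotypes, co$truth, cfg, dirp, trait = co$trait)
  models <- read_gene_models(file.path(dirp, "genes.gff3"))
  vt <- co$genotypes$variants
  ann <- annotate_variants(vt[vt$variant_id %in% co$truth$causal_variant_ids, ],
                           models)
  cand <- candidate_genes(ann)
  hosted <- unique(ann$gene_id[!is.na(ann$gene_id)])
  expect_setequal(cand$gene_id, hosted)
})

test_that("heatmap clustering groups identical accessions and class blocks", {
  set.seed(2)
  d <- rbind(matrix(0L, 5, 8), matrix(2L, 5, 8))
  d[2, 1] <- 1L; d[8, 3] <- 1L
  d[3, ] <- d[1, ]   # accessions 1 and 3 identical
  gm <- gm_from_dosage(d)
  y <- rep(c(0L, 1L), each = 5)
  ord <- genotype_heatmap_order(gm, y)
  # class-0 block first, then class 1
  expect_identical(sort(ord$row_order[1:5]), sort(gm$samples[1:5]))
  # identical accessions are adjacent within their class dendrogram
  i1 <- match(gm$samples[1], ord$row_order)
  i3 <- match(gm$samples[3], ord$row_order)
  expect_equal(abs(i1 - i3), 1)
  # class 1 carries more alternative alleles over these variants
  expect_gt(mean(d[6:10, ]), mean(d[1:5, ]))
})

test_that("heatmap orders are permutation-invariant up to dendrogram reflection", {
  # distinct pairwise distances so the dendrogram is unique up to reflection
  set.seed(21)
  d <- matrix(rbinom(6 * 80, 2, 0.5), 6, 80)
  stopifnot(!anyDuplicated(round(dist(d)^2)))
  gm <- gm_from_dosage(d)
  y <- rep(0L, 6)
  ord1 <- genotype_heatmap_order(gm, y)
  perm <- sample(6)
  gm2 <- genotype_matrix(d[perm, ], gm$samples[perm], gm$variants)
  ord2 <- genotype_heatmap_order(gm2, y)
  # the sets of adjacent merge pairs agree: compare cophenetic distances
  c1 <- cophenetic(ord1$row_trees[["0"]])
  c2 <- cophenetic(ord2$row_trees[["0"]])
  m1 <- as.matrix(c1)[gm$samples, gm$samples]
  m2 <- as.matrix(c2)[gm$samples, gm$samples]
  expect_equal(m1, m2)
  # degenerate inputs fall back to identity order
  one <- genotype_heatmap_order(subset_genotypes(gm, samples = 1), 0L)
  expect_identical(one$row_order, gm$samples[1])
})
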