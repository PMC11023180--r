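#' Run the full variant-selection and gene-flow analysis
#'
#' Orchestrates the stages end to end: ingest or simulate a cohort, apply
#' the hard filters, LD-prune, tune and resample-fit the boosted classifier,
#' select variants by appearance frequency, validate against the
#' majority-class baseline (accuracy distribution and 5x2cv paired t-test),
#' expand the selection by correlation against the full filtered matrix,
#' annotate variants against the gene models, compute the heatmap
#' clustering orders, and evaluate configured F4 gene-flow hypotheses.
#' When a truth record is available (simulated input), truth-recovery
#' metrics are added: causal recall (counting selected proxies with
#' r-squared > 0.8 to a causal variant), precision, and gene-level recall.
#'
#' @param config a YAML file path or a nested list. Top-level keys:
#'   `seed`; `simulate` (arguments of [sim_config()]) or `input` (paths
#'   `vcf`, `phenotypes`, `populations`, `gff3`, optional `truth`);
#'   `filter` (`expressions`); `prune` (`window`, `step`, `r2_max`);
#'   `select` (`n_fits`, `threshold`, `tuning_budget`); `expand` (`r_min`);
#'   `annotate` (`window`); `f4` (`outgroup`, `block_size`, `hypotheses` =
#'   list of `source`/`sister`/`target` triples); optional `out_dir` where
#'   stage TSVs and `report.json` are written.
#' @return the run report (list), invisibly also written to
#'   `out_dir/report.json` when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  report <- list(config = config, stages = list())

  ## --- ingest or simulate -------------------------------------------------
  if (!is.null(config$input)) {
    inp <- config$input
    gm <- read_vcf(inp$vcf)
    trait <- read_phenotypes(inp$phenotypes)
    popmap <- if (!is.null(inp$populations)) read_popmap(inp$populations)
    models <- if (!is.null(inp$gff3)) read_gene_models(inp$gff3)
    truth <- if (!is.null(inp$truth)) jsonlite::read_json(inp$truth, simplifyVector = TRUE)
    sim_cfg <- NULL
  } else {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    sim_cfg <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(sim_cfg)
    gm <- cohort$genotypes
    trait <- cohort$trait
    truth <- cohort$truth
    popmap <- truth$population_assignments
    if (!is.null(config$out_dir)) {
      write_fixture(gm, truth, sim_cfg, config$out_dir, trait = trait)
      # ingest the written fixture so the run exercises the file formats and
      # the variant table carries the synthetic INFO metrics
      gm <- read_vcf(file.path(config$out_dir, "cohort.vcf"))
      models <- read_gene_models(file.path(config$out_dir, "genes.gff3"))
    } else {
      vt <- gm$variants
      info <- synthetic_info(sim_cfg, match(truth$causal_variant_ids,
                                            vt$variant_id))
      gm$variants <- cbind(vt, info)
      gff <- tempfile(fileext = ".gff3")
      writeLines(tile_genes_gff3(sim_cfg), gff)
      models <- read_gene_models(gff)
    }
  }
  report$stages$ingest <- list(n_samples = length(gm$samples),
                               n_variants = nrow(gm$variants))

  ## --- hard filter ---------------------------------------------------------
  expr <- config$filter$expressions %||% default_hard_filters()
  gm_f <- hard_filter(gm, expr)
  report$stages$filter <- list(n_in = ncol(gm$dosage), n_out = ncol(gm_f$dosage))

  ## --- LD pruning ----------------------------------------------------------
  pr <- config$prune %||% list()
  kept <- ld_prune(gm_f, window = pr$window %||% 50, step = pr$step %||% 10,
                   r2_max = pr$r2_max %||% 0.1)
  gm_p <- subset_genotypes(gm_f, variants = kept)
  report$stages$prune <- list(n_in = ncol(gm_f$dosage), n_out = length(kept))

  ## --- selection -----------------------------------------------------------
  sel_cfg <- config$select %||% list()
  n_fits <- sel_cfg$n_fits %||% 100
  threshold <- sel_cfg$threshold %||% 20
  spec <- tune_model(gm_p, trait, budget = sel_cfg$tuning_budget %||% 100,
                     seed = seed)
  fits <- resample_fit(gm_p, trait, spec, n_fits = n_fits, base_seed = seed)
  sel <- select_variants(fits, threshold = threshold,
                         variant_ids = gm_p$variants$variant_id)
  selected_ids <- sel$variant_id[sel$selected]
  report$stages$select <- list(
    spec = unclass(spec), n_fits = n_fits, threshold = threshold,
    n_selected = length(selected_ids),
    accuracy = as.list(accuracy_distribution(fits)))

  ## --- baseline comparison ------------------------------------------------
  if (isTRUE(config$validate %||% TRUE)) {
    xy <- align_trait(gm_p, trait)
    cv <- cv52_ttest(gm_p, trait, spec, seed = seed)
    report$stages$validate <- list(
      baseline_accuracy = max(mean(xy$y == 1), mean(xy$y == 0)),
      t_statistic = cv$t_statistic, p_value = cv$p_value,
      significant = cv$significant)
  }

  ## --- correlation expansion ----------------------------------------------
  r_min <- config$expand$r_min %||% 0.97
  hits <- expand_selected(selected_ids, gm_f, r_min = r_min)
  expanded_ids <- unique(c(selected_ids, hits$companion_variant_id))
  report$stages$expand <- list(n_selected = length(selected_ids),
                               n_companions = nrow(hits),
                               n_total = length(expanded_ids))

  ## --- gene annotation ----------------------------------------------------
  ann <- heat <- NULL
  if (!is.null(models) && length(expanded_ids)) {
    vt_sel <- gm_f$variants[match(expanded_ids, gm_f$variants$variant_id), ]
    ann <- annotate_variants(vt_sel, models,
                             window = config$annotate$window %||% 5000)
    cand <- candidate_genes(ann)
    report$stages$annotate <- list(
      n_variants = nrow(ann),
      n_gene_associated = sum(!is.na(ann$gene_id)),
      n_candidate_genes = nrow(cand),
      regions = as.list(table(ann$region)))
    heat <- genotype_heatmap_order(
      subset_genotypes(gm_f, variants = selected_ids), trait)
  } else {
    cand <- candidate_genes(data.frame(variant_id = character(0),
                                       gene_id = character(0),
                                       region = character(0)))
  }

  ## --- F4 gene-flow hypotheses --------------------------------------------
  if (!is.null(config$f4) && !is.null(popmap)) {
    f4c <- config$f4
    pf <- population_frequencies(gm_p, unlist(popmap),
                                 block_size = f4c$block_size %||% 500)
    hyp <- do.call(rbind, lapply(f4c$hypotheses, as.data.frame))
    quartets <- build_quartets(rownames(pf$freq), f4c$outgroup, hyp)
    report$stages$f4 <- f4_table(pf, quartets)
  }

  ## --- truth recovery -----------------------------------------------------
  if (!is.null(truth) && length(truth$causal_variant_ids)) {
    report$truth_recovery <- truth_recovery(
      selected_ids, truth$causal_variant_ids, gm_f,
      annotations = ann, candidates = cand)
  }

  report$selection <- sel
  report$expansion <- hits
  if (!is.null(ann)) report$annotations <- ann
  report$candidate_genes <- cand

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(sel, file.path(config$out_dir, "selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep_json <- report
    rep_json$selection <- NULL; rep_json$expansion <- NULL
    rep_json$annotations <- NULL
    jsonlite::write_json(rep_json, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", force = TRUE)
  }
  report
}

#' Truth-recovery metrics for a selection
#'
#' Recall counts a planted causal variant as recovered when it is selected
#' itself or when any selected variant has r-squared > `r2_proxy` with it;
#' precision is the fraction of selected variants that are causal or such
#' proxies; gene recall is the fraction of causal-hosting genes present in
#' the candidate list.
#'
#' @param selected_ids selected variant ids.
#' @param causal_ids planted causal variant ids.
#' @param gm the full [genotype_matrix] (for proxy r-squared).
#' @param annotations optional annotation table (for gene recall).
#' @param candidates optional candidate-gene table.
#' @param r2_proxy proxy threshold (default 0.8).
#' @return list: `recall`, `precision`, `n_selected`, `n_false`, and
#'   `gene_recall` when gene tables are supplied.
#' @export
truth_recovery <- function(selected_ids, causal_ids, gm, annotations = NULL,
                           candidates = NULL, r2_proxy = 0.8) {
  d <- gm$dosage
  if (gm$coding == "heatmap_minus1") d[d == -1] <- NA
  causal_ids <- intersect(causal_ids, colnames(d))
  if (length(selected_ids) == 0) {
    out <- list(recall = 0, precision = NA_real_, n_selected = 0L,
                n_false = 0L)
  } else {
    r2 <- matrix(0, length(selected_ids), length(causal_ids))
    for (j in seq_along(causal_ids))
      for (i in seq_along(selected_ids))
        r2[i, j] <- dosage_r2(d[, selected_ids[i]], d[, causal_ids[j]])
    hit_causal <- colSums(r2 > r2_proxy) > 0 | causal_ids %in% selected_ids
    sel_true <- rowSums(r2 > r2_proxy) > 0 | selected_ids %in% causal_ids
    out <- list(recall = mean(hit_causal), precision = mean(sel_true),
                n_selected = length(selected_ids),
                n_false = sum(!sel_true))
  }
  if (!is.null(annotations) && !is.null(candidates)) {
    causal_genes <- unique(annotations$gene_id[
      annotations$variant_id %in% causal_ids & !is.na(annotations$gene_id)])
    if (length(causal_genes))
      out$gene_recall <- mean(causal_genes %in% candidates$gene_id)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
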