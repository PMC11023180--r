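test_that("drift model has the Balding-Nichols moments", {
  cfg <- sim_config(n_samples_per_pop = 2, n_pops = 2, n_variants = 10000,
                    fst = 0.2, n_causal = 0, seed = 42)
  fr <- simulate_allele_frequencies(cfg)
  # across-variant variance of (p_pop - p_anc) should match p(1-p)*F
  expected <- mean(fr$ancestral * (1 - fr$ancestral)) * 0.2
  for (k in 1:2) {
    observed <- mean((fr$freq[k, ] - fr$ancestral)^2)
    expect_lt(abs(observed - expected) / expected, 0.15)
  }
})

test_that("near-zero drift returns the ancestral frequencies", {
  cfg <- sim_config(n_samples_per_pop = 2, n_pops = 2, n_variants = 500,
                    fst = 1e-9, n_causal = 0, seed = 1)
  fr <- simulate_allele_frequencies(cfg)
  expect_equal(fr$freq[1, ], fr$ancestral, tolerance = 1e-3)
})

test_that("complete admixture replaces the target frequencies", {
  ev <- data.frame(source = "pop1", target = "pop3", alpha = 1)
  cfg <- sim_config(n_samples_per_pop = 2, n_pops = 3, n_variants = 300,
                    admixture_events = ev, n_causal = 0, seed = 2)
  fr <- simulate_allele_frequencies(cfg)
  expect_identical(fr$freq["pop3", ], fr$freq["pop1", ])
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(fst = 0), "fst")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(n_variants = 0), "n_variants")
  expect_error(sim_config(n_causal = -1), "n_causal")
  expect_error(sim_config(admixture_events =
    data.frame(source = 1, target = 2, alpha = 1.2)), "alpha")
})

test_that("fixed allele frequency gives all-alt dosages before masking", {
  cfg <- tiny_config(missing_rate = 0, ld_block_size = 1, n_causal = 0)
  fr <- simulate_allele_frequencies(cfg)
  fr$freq[, 3] <- 1
  g <- simulate_genotypes(fr, cfg)
  expect_true(all(g$genotypes$dosage[, 3] == 2))
})

test_that("zero LD decay copies whole blocks; missing rate is respected", {
  cfg <- sim_config(n_samples_per_pop = 50, n_pops = 2, n_variants = 1000,
                    n_causal = 0, ld_block_size = 5, ld_decay = 0,
                    missing_rate = 0, seed = 5)
  g <- simulate_genotypes(simulate_allele_frequencies(cfg), cfg)
  d <- g$genotypes$dosage
  for (b in c(1, 7, 42)) {
    cols <- (b - 1) * 5 + 1:5
    expect_true(all(d[, cols] == d[, cols[1]]))
    expect_equal(cor(d[, cols[1]], d[, cols[2]])^2, 1)
  }

  cfg2 <- sim_config(n_samples_per_pop = 50, n_pops = 2, n_variants = 1000,
                     n_causal = 0, ld_block_size = 1, missing_rate = 0.1,
                     seed = 6)
  g2 <- simulate_genotypes(simulate_allele_frequencies(cfg2), cfg2)
  expect_lt(abs(mean(is.na(g2$genotypes$dosage)) - 0.1), 0.01)
})

test_that("expected heterozygosity matches 2p(1-p)(1-F)", {
  cfg <- sim_config(n_samples_per_pop = 100, n_pops = 1, n_variants = 10000,
                    fst = 0.2, n_causal = 0, ld_block_size = 1,
                    missing_rate = 0, seed = 9)
  fr <- simulate_allele_frequencies(cfg)
  g <- simulate_genotypes(fr, cfg)
  het <- mean(g$genotypes$dosage == 1)
  expected <- mean(2 * fr$ancestral * (1 - fr$ancestral)) * (1 - 0.2)
  expect_lt(abs(het - expected) / expected, 0.15)
})

test_that("null trait is independent of genotype; strong effect is deterministic", {
  cfg0 <- tiny_config(effect_size = 0, seed = 21)
  co0 <- simulate_cohort(cfg0)
  # association of class with causal dosages should be at chance level
  d <- co0$genotypes$dosage[, match(co0$truth$causal_variant_ids,
                                    co0$genotypes$variants$variant_id)]
  d[is.na(d)] <- 0
  r <- abs(cor(rowSums(d), co0$trait$class))
  expect_lt(r, 0.3)

  cfg1 <- sim_config(n_samples_per_pop = 40, n_pops = 2, n_variants = 50,
                     n_causal = 1, effect_size = 60, ld_block_size = 1,
                     missing_rate = 0, seed = 22)
  fr1 <- simulate_allele_frequencies(cfg1)
  g1 <- simulate_genotypes(fr1, cfg1)
  # with the offset between 0 and one effect unit and a near-infinite effect,
  # class is 1 exactly when the causal dosage is positive
  tt <- simulate_binary_trait(g1$genotypes, g1$truth, cfg1, offset = 30)
  dos <- g1$genotypes$dosage[, g1$truth$causal_variant_ids]
  expect_identical(tt$class, as.integer(dos > 0))
})

test_that("true liability separates classes (AUC > 0.8) at default effect", {
  cfg <- sim_config(n_samples_per_pop = 75, n_pops = 4, n_variants = 500,
                    n_causal = 10, effect_size = 1.5, seed = 33)
  co <- simulate_cohort(cfg)
  d <- co$genotypes$dosage[, match(co$truth$causal_variant_ids,
                                   co$genotypes$variants$variant_id)]
  d[is.na(d)] <- 0
  liab <- rowSums(d) * 1.5
  y <- co$trait$class
  # AUC by the rank-sum identity
  auc <- (mean(rank(liab)[y == 1]) - (sum(y) + 1) / 2) / sum(y == 0)
  expect_gt(auc, 0.8)
})

test_that("class balance stays within the configured band", {
  for (s in 1:5) {
    co <- simulate_cohort(tiny_config(seed = s))
    expect_gte(mean(co$trait$class), 0.35)
    expect_lte(mean(co$trait$class), 0.65)
  }
})

test_that("fixtures are byte-identical under a fixed seed and roundtrip", {
  cfg <- tiny_config(seed = 77)
  co <- simulate_cohort(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture(co$genotypes, co$truth, cfg, d1, trait = co$trait)
  co2 <- simulate_cohort(cfg)
  write_fixture(co2$genotypes, co2$truth, cfg, d2, trait = co2$trait)
  for (f in c("cohort.vcf", "phenotypes.tsv", "populations.tsv",
              "genes.gff3", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  gm <- read_vcf(file.path(d1, "cohort.vcf"))
  expect_identical(unname(gm$dosage), unname(co$genotypes$dosage))

  # GT coding convention and truth bookkeeping
  vcf <- readLines(file.path(d1, "cohort.vcf"))
  body <- vcf[!startsWith(vcf, "#")]
  first <- strsplit(body[1], "\t")[[1]]
  gts <- first[-(1:9)]
  expect_identical(sort(unique(gts[co$genotypes$dosage[, 1] == 1])), "0/1")
  truth <- jsonlite::read_json(file.path(d1, "truth.json"),
                               simplifyVector = TRUE)
  expect_length(truth$causal_variant_ids, cfg$n_causal)
  expect_true(all(truth$causal_variant_ids %in%
                    co$genotypes$variants$variant_id))
})
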