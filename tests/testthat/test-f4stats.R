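test_that("population frequencies equal hand-tallied counts", {
  d <- rbind(c(0L, 1L, 2L),   # pop A
             c(1L, 1L, NA),   # pop A
             c(2L, 0L, 2L),   # pop B
             c(2L, NA, 1L))   # pop B
  gm <- gm_from_dosage(d)
  popmap <- setNames(c("A", "A", "B", "B"), gm$samples)
  pf <- population_frequencies(gm, popmap, block_size = 2)
  expect_equal(unname(pf$freq["A", ]), c((0 + 1) / 4, (1 + 1) / 4, 2 / 2))
  expect_equal(unname(pf$freq["B", ]), c((2 + 2) / 4, 0 / 2, (2 + 1) / 4))
  expect_equal(unname(pf$counts["A", ]), c(4, 4, 2))
  # single het sample -> frequency one half
  gm1 <- gm_from_dosage(matrix(1L, 1, 2))
  pf1 <- population_frequencies(gm1, setNames("solo", gm1$samples),
                                block_size = 1)
  expect_equal(unname(pf1$freq[1, ]), c(0.5, 0.5))
  expect_error(population_frequencies(gm, popmap[1:2]), "unmapped")
})

test_that("variants with an uncalled population are dropped", {
  d <- rbind(c(0L, NA), c(1L, NA), c(2L, 1L), c(0L, 1L))
  gm <- gm_from_dosage(d)
  popmap <- setNames(c("A", "A", "B", "B"), gm$samples)
  pf <- population_frequencies(gm, popmap, block_size = 1)
  expect_identical(pf$variant_id, gm$variants$variant_id[1])
})

test_that("f4 matches the direct arithmetic oracle on the 2-variant example", {
  freq <- rbind(A = c(1, 1), B = c(0, 1), C = c(1, 0), D = c(0, 0))
  pf <- new_population_frequencies(freq)
  r <- f4(pf, c("A", "B", "C", "D"))
  # per-variant products: (1-0)(1-0) = 1 and (1-1)(0-0) = 0 -> mean 0.5
  expect_identical(r$f4, 0.5)
  expect_identical(r$n_variants_used, 2L)
})

test_that("f4 antisymmetries are exact; identical C and D give exactly zero", {
  set.seed(1)
  freq <- matrix(runif(4 * 40), 4, 40,
                 dimnames = list(c("A", "B", "C", "D"), NULL))
  pf <- new_population_frequencies(freq, blocks = rep(1:4, each = 10))
  r <- f4(pf, c("A", "B", "C", "D"))
  expect_identical(f4(pf, c("A", "B", "D", "C"))$f4, -r$f4)
  expect_identical(f4(pf, c("B", "A", "C", "D"))$f4, -r$f4)
  expect_identical(f4(pf, c("A", "B", "D", "C"))$se, r$se)

  freq2 <- freq; freq2["D", ] <- freq2["C", ]
  rownames(freq2) <- c("A", "B", "C", "D")
  pf2 <- new_population_frequencies(freq2, blocks = rep(1:4, each = 10))
  expect_identical(f4(pf2, c("A", "B", "C", "D"))$f4, 0)

  expect_error(f4(pf, c("A", "B", "C", "C")), "distinct")
  expect_error(f4(pf, c("A", "B", "C", "X")), "unknown")
})

test_that("fewer than two jackknife blocks is an error", {
  freq <- matrix(runif(4 * 10), 4, 10,
                 dimnames = list(c("A", "B", "C", "D"), NULL))
  pf <- new_population_frequencies(freq, blocks = rep(1L, 10))
  expect_error(f4(pf, c("A", "B", "C", "D")), "blocks")
})

test_that("weighted jackknife reduces to the standard delete-one form for equal blocks", {
  set.seed(2)
  freq <- matrix(runif(4 * 60), 4, 60,
                 dimnames = list(c("A", "B", "C", "D"), NULL))
  blocks <- rep(1:6, each = 10)
  pf <- new_population_frequencies(freq, blocks = blocks)
  r <- f4(pf, c("A", "B", "C", "D"))
  d <- (freq[1, ] - freq[2, ]) * (freq[3, ] - freq[4, ])
  theta_minus <- sapply(1:6, function(b) mean(d[blocks != b]))
  se_classic <- sqrt((5 / 6) * sum((theta_minus - mean(theta_minus))^2))
  expect_equal(r$se, se_classic, tolerance = 1e-12)
})

test_that("quartets are built from hypothesis triples with the outgroup as A", {
  pops <- c("STE", "IRA", "TUR", "GRE", "GEO", "MAC", "BEL", "US", "AFG",
            "IND", "CHI", "EGY", "ESP")
  hyp <- data.frame(
    source = c("IRA", "TUR", "IRA", "GEO", "BEL", "AFG", "AFG", "IND", "TUR",
               "EGY"),
    sister = c("GRE", "IRA", "TUR", "GRE", "MAC", "CHI", "IND", "AFG", "GRE",
               "TUR"),
    target = c("TUR", "GRE", "GEO", "MAC", "US", "IND", "CHI", "CHI", "EGY",
               "ESP"))
  q <- build_quartets(pops, "STE", hyp)
  expect_identical(nrow(q), 10L)
  expect_true(all(q$A == "STE"))
  expect_identical(q$B, hyp$source)
  expect_identical(q$D, hyp$target)

  expect_identical(nrow(build_quartets(pops, "STE", hyp[0, ])), 0L)
  expect_warning(qd <- build_quartets(pops, "STE", rbind(hyp, hyp[1, ])),
                 "duplicate")
  expect_identical(nrow(qd), 10L)
  expect_error(build_quartets(pops, "XXX", hyp), "outgroup")
  bad <- hyp; bad$target[1] <- "ATLANTIS"
  expect_error(build_quartets(pops, "STE", bad), "unknown population")
})

test_that("an admixture event produces a significantly positive f4 for its quartet", {
  ev <- data.frame(source = "pop2", target = "pop4", alpha = 0.3)
  cfg <- sim_config(n_samples_per_pop = 25, n_pops = 4, n_variants = 5000,
                    fst = 0.1, admixture_events = ev, n_causal = 0,
                    ld_block_size = 1, missing_rate = 0, seed = 91)
  co <- simulate_cohort(cfg)
  pf <- population_frequencies(co$genotypes,
                               co$truth$population_assignments,
                               block_size = 250)
  r <- f4(pf, c("pop1", "pop2", "pop3", "pop4"))
  expect_gt(r$f4, 0)
  expect_lt(r$p, 0.05)
  expect_identical(r$interpretation, "B-D flow")
})
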