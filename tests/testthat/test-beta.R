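gene_at <- function(tss, id = "g1") {
  data.frame(gene_id = id, chrom = "chr1", tss = as.integer(tss),
             stringsAsFactors = FALSE)
}
dmr_at <- function(center, w = 100L) {
  data.frame(chrom = "chr1", start = as.integer(center - w / 2),
             end = as.integer(center + w / 2), stringsAsFactors = FALSE)
}

test_that("regulatory potential matches its closed form", {
  expect_equal(unname(regulatory_potential(gene_at(5e5), dmr_at(5e5))),
               exp(-0.5), tolerance = 1e-12)
  expect_equal(unname(regulatory_potential(gene_at(5e5), dmr_at(5e5 + 5e4))),
               exp(-2.5), tolerance = 1e-12)
  expect_equal(unname(regulatory_potential(gene_at(5e5), dmr_at(5e5 + 1e5))),
               exp(-4.5), tolerance = 1e-12)
  # additivity over DMRs
  both <- rbind(dmr_at(5e5), dmr_at(5e5 + 5e4))
  expect_equal(unname(regulatory_potential(gene_at(5e5), both)),
               exp(-0.5) + exp(-2.5), tolerance = 1e-12)
  # outside the window contributes nothing; off-chromosome too
  expect_equal(unname(regulatory_potential(gene_at(5e5),
                                           dmr_at(5e5 + 1e5 + 51))), 0)
  far <- dmr_at(5e5); far$chrom <- "chr2"
  expect_equal(unname(regulatory_potential(gene_at(5e5), far)), 0)
})

test_that("potential decays monotonically with distance", {
  dist <- seq(0, 1e5, by = 5e3)
  s <- vapply(dist, function(d)
    unname(regulatory_potential(gene_at(2e5), dmr_at(2e5 + d))), 0)
  expect_true(all(diff(s) < 0))
})

test_that("KS function test matches exhaustive small-sample enumeration", {
  # UP occupies ranks {1,2}, NON {3,4,5}: D+ = 1, exact p = 1/C(5,2)
  g <- data.frame(gene_id = letters[1:5], S = c(5, 4, 3, 2, 1),
                  de_class = c("UP", "UP", "NON", "NON", "NON"),
                  stringsAsFactors = FALSE)
  ft <- beta_function_test(g)
  expect_equal(ft$UP$D, 1)
  expect_equal(ft$UP$p, 1 / 10)
  expect_true(is.na(ft$DOWN$D))

  # identical S values -> no separation
  g2 <- g; g2$S <- rep(1, 5)
  ft2 <- beta_function_test(g2)
  expect_equal(ft2$UP$D, 0, tolerance = 1e-12)
  expect_equal(ft2$UP$p, 1)

  # single-gene class still computes a small-sample p
  g3 <- data.frame(gene_id = letters[1:4], S = c(9, 3, 2, 1),
                   de_class = c("UP", "NON", "NON", "NON"),
                   stringsAsFactors = FALSE)
  ft3 <- beta_function_test(g3)
  expect_equal(ft3$UP$D, 1)
  expect_equal(ft3$UP$p, 1 / 4)

  expect_error(beta_function_test(data.frame(
    gene_id = "a", S = 1, de_class = "UP", stringsAsFactors = FALSE)),
    "NON")
})

test_that("KS test is invariant to monotone transforms and tracks ks.test", {
  set.seed(31)
  s <- c(runif(30, 0.5, 1), runif(60, 0, 0.8))
  g <- data.frame(gene_id = paste0("g", 1:90), S = s,
                  de_class = rep(c("UP", "NON"), c(30, 60)),
                  stringsAsFactors = FALSE)
  a <- beta_function_test(g)
  g$S <- log1p(g$S) * 3 + 1   # strictly monotone transform
  b <- beta_function_test(g)
  expect_equal(a$UP$D, b$UP$D, tolerance = 1e-12)
  expect_equal(a$UP$p, b$UP$p, tolerance = 1e-12)
  # tie-free data: D equals ks.test's one-sided statistic
  ks <- suppressWarnings(stats::ks.test(rank(-s)[1:30], rank(-s)[-(1:30)],
                                        alternative = "greater"))
  expect_equal(a$UP$D, unname(ks$statistic), tolerance = 1e-12)
})

test_that("rank products match direct enumeration on a toy table", {
  g <- data.frame(gene_id = c("a", "b", "c", "d"),
                  S = c(10, 8, 8, 1), pvalue = c(0.01, 0.5, 0.001, 0.2),
                  de_class = c("UP", "UP", "DOWN", "DOWN"),
                  stringsAsFactors = FALSE)
  rp <- rank_product_targets(g, cutoff = 1)
  rp <- rp[match(c("a", "b", "c", "d"), rp$gene_id), ]
  # hand enumeration: rank_S = 1, 2.5, 2.5, 4; rank_E = 2, 4, 1, 3
  expect_equal(rp$rank_S, c(1, 2.5, 2.5, 4))
  expect_equal(rp$rank_E, c(2, 4, 1, 3))
  expect_equal(rp$RP, c(1 * 2, 2.5 * 4, 2.5 * 1, 4 * 3) / 16)
  expect_true(all(rp$is_target))  # cutoff 1 returns everything
  # best possible gene scores 1/N^2
  g2 <- g; g2$S <- c(9, 1, 2, 3); g2$pvalue <- c(1e-9, 0.2, 0.3, 0.4)
  rp2 <- rank_product_targets(g2, cutoff = 1)
  expect_equal(rp2$RP[rp2$gene_id == "a"], 1 / 16)
  expect_error(rank_product_targets(g[0, ]), "rank")
  # restricted mode drops non-significant genes from the family
  g$de_class <- c("UP", "NON", "NON", "DOWN")
  rp3 <- rank_product_targets(g, cutoff = 1, de_only = TRUE)
  expect_setequal(rp3$gene_id, c("a", "d"))
})

test_that("near-gene DMR scores are monotone in the window and flag coupling", {
  genes <- data.frame(gene_id = c("u", "n1", "n2"), chrom = "chr1",
                      tss = c(1e5L, 5e5L, 9e5L),
                      de_class = c("DOWN", "NON", "NON"),
                      stringsAsFactors = FALSE)
  dmrs <- rbind(dmr_at(1e5 + 2e4), dmr_at(1e5 - 9e4), dmr_at(95e4))
  a <- dmr_gene_enrichment(genes, dmrs, window = 5e4)
  b <- dmr_gene_enrichment(genes, dmrs, window = 1e5)
  expect_true(all(b$scores$score >= a$scores$score))
  expect_equal(a$scores$score[a$scores$gene_id == "u"], 1)
  expect_equal(b$scores$score[b$scores$gene_id == "u"], 2)

  none <- dmr_gene_enrichment(genes, dmrs[0, ], window = 1e5)
  expect_true(all(none$scores$score == 0))
  expect_equal(none$p_down_vs_non, 1)
  expect_error(dmr_gene_enrichment(genes, dmrs, window = 0), "window")
})

test_that("planted DMR-gene coupling is recovered by the integration chain", {
  cfg <- sim_config(n_cpgs = 20000, n_hyper = 15, n_hypo = 15, seed = 23)
  sim <- simulate_methylome(cfg)
  de <- simulate_expression(cfg, sim$truth)
  res <- call_dmrs(sim$counts, "LF", "HF")
  called <- rbind(res$hyper, res$hypo)
  S <- regulatory_potential(sim$truth$genes, called)
  g <- cbind(sim$truth$genes[c("gene_id", "chrom", "tss")],
             S = unname(S), de[c("pvalue", "de_class")])
  # hyper-DMRs sit near downregulated genes: DOWN class outranks NON
  ft <- beta_function_test(g[g$de_class != "UP", ])
  expect_lt(ft$DOWN$p, 0.01)
  # DOWN genes carry more hyper-DMRs nearby than background genes
  enr <- dmr_gene_enrichment(g, res$hyper)
  expect_lt(enr$p_down_vs_non, 0.05)
  sc <- enr$scores
  expect_gt(mean(sc$score[sc$de_class == "DOWN"]),
            mean(sc$score[sc$de_class == "NON"]))
})
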