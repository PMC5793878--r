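mk_results <- function(p, delta, wcov, pos = NULL) {
  n <- length(p)
  data.frame(chrom = rep("chr1", n),
             pos = if (is.null(pos)) seq(100L, by = 100L, length.out = n)
             else pos,
             p1 = 0.5 - delta / 2, p2 = 0.5 + delta / 2, delta = delta,
             G2 = rep(1, n), d1 = rep(1, n), d2 = rep(1, n),
             G2_adj = rep(1, n), p_value = p,
             weighted_coverage = wcov, stringsAsFactors = FALSE)
}

test_that("site filters apply the printed thresholds with strict inequalities", {
  res <- mk_results(p = c(0.04, 0.04, 0.04, 0.05, 0.04, 0.049),
                    delta = c(0.15, 0.15, 0.10, 0.15, -0.12, 0.101),
                    wcov = c(12, 9.9, 50, 50, 10, 10))
  out <- call_dm_sites(res)
  # hand enumeration: rows 1 (all pass), 5 (hypo at boundary coverage),
  # 6 (just above both strict thresholds); 2 fails coverage, 3 fails the
  # strict delta rule, 4 fails the strict p rule
  expect_equal(out$pos, c(100L, 500L, 600L))
  expect_equal(out$direction, c("hyper", "hypo", "hyper"))
})

test_that("unsorted site input is rejected", {
  res <- mk_results(p = c(0.01, 0.01), delta = c(0.2, 0.2), wcov = c(20, 20),
                    pos = c(200L, 100L))
  expect_error(call_dm_sites(res), "sorted")
  res$direction <- "hyper"
  expect_error(merge_dm_sites(res), "sorted")
})

test_that("merging chains same-direction sites within 5 kb", {
  s <- mk_results(p = rep(0.01, 3), delta = rep(0.2, 3), wcov = rep(20, 3),
                  pos = c(100L, 4000L, 10000L))
  s$direction <- "hyper"
  reg <- merge_dm_sites(s)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$start, c(100L, 10000L))
  expect_equal(reg$end, c(4001L, 10001L))
  expect_equal(reg$n_sites, c(2L, 1L))
  expect_equal(reg$members[[1]], c(100L, 4000L))

  # opposite directions never merge even when adjacent
  s2 <- mk_results(p = rep(0.01, 2), delta = c(0.2, -0.2), wcov = c(20, 20),
                   pos = c(100L, 200L))
  s2$direction <- c("hyper", "hypo")
  reg2 <- merge_dm_sites(s2)
  expect_equal(nrow(reg2), 2L)
  expect_setequal(reg2$direction, c("hyper", "hypo"))

  # chromosome change breaks a chain
  s3 <- mk_results(p = rep(0.01, 2), delta = rep(0.2, 2), wcov = c(20, 20),
                   pos = c(100L, 150L))
  s3$direction <- "hyper"
  s3$chrom <- c("chr1", "chr2")
  expect_equal(nrow(merge_dm_sites(s3[order(s3$chrom, s3$pos), ])), 2L)

  expect_equal(nrow(merge_dm_sites(mk_results(numeric(0), numeric(0),
                                              numeric(0)))), 0L)
})

test_that("region testing aggregates member counts and matches the site oracle", {
  # two member CpGs, one replicate per group, each 8/10 vs 2/10
  pos <- c(100L, 300L, 9000L)
  mat <- toy_matrix(pos, list(
    g1_1 = list(meth = c(8L, 8L, 1L), total = c(10L, 10L, 10L)),
    g2_1 = list(meth = c(2L, 2L, 2L), total = c(10L, 10L, 10L))))
  cand <- data.frame(chrom = "chr1", start = 100L, end = 301L,
                     direction = "hypo", n_sites = 2L,
                     stringsAsFactors = FALSE)
  cand$members <- list(c(100L, 300L))
  reg <- test_regions(cand, mat, "g1", "g2")
  ref <- rslrt_test(16, 20, 4, 20)
  expect_equal(reg$p_value, ref$p_value)
  expect_equal(reg$delta, -0.6)
  expect_true(abs(reg$delta) > 0.30)
  expect_equal(reg$n_dm_cpgs, 2L)
})

test_that("fold change uses the epsilon-guarded proportion ratio", {
  # aggregated p1 = 0.02, p2 = 0.15 -> (0.16/0.03) just above 5
  pos <- c(100L, 200L)
  mat <- toy_matrix(pos, list(
    g1_1 = list(meth = c(1L, 1L), total = c(50L, 50L)),
    g2_1 = list(meth = c(8L, 7L), total = c(50L, 50L))))
  cand <- data.frame(chrom = "chr1", start = 100L, end = 201L,
                     direction = "hyper", n_sites = 2L,
                     stringsAsFactors = FALSE)
  cand$members <- list(c(100L, 200L))
  reg <- test_regions(cand, mat, "g1", "g2")
  expect_equal(reg$fold_change, 0.16 / 0.03, tolerance = 1e-12)
  expect_true(abs(reg$delta) <= 0.30)        # passes only through fold change
  expect_true(reg$fold_change > 5)
})

test_that("BH adjustment over candidates matches the step-up formula", {
  # three regions engineered to give three distinct raw p values
  pos <- c(100L, 200L, 10000L, 10100L, 20000L, 20100L)
  mat <- toy_matrix(pos, list(
    g1_1 = list(meth = c(0L, 0L, 2L, 2L, 4L, 4L),
                total = rep(20L, 6)),
    g2_1 = list(meth = c(18L, 18L, 14L, 14L, 12L, 12L),
                total = rep(20L, 6))))
  sites <- call_dm_sites(site_scan(mat, "g1", "g2", moderate = FALSE))
  cand <- merge_dm_sites(sites)
  expect_equal(nrow(cand), 3L)
  reg <- test_regions(cand, mat, "g1", "g2")
  p <- reg$p_value
  n <- length(p)
  o <- order(p)
  expected <- numeric(n)
  expected[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))  # step-up by hand
  expect_equal(reg$p_adj, pmin(1, expected))
  expect_true(all(reg$p_adj >= reg$p_value))
  # monotone: ordering by p and by p_adj agree up to ties
  expect_equal(order(reg$p_adj), order(reg$p_value))
})

test_that("call_dmrs output is direction-disjoint with non-increasing audit", {
  cfg <- sim_config(n_cpgs = 6000, n_hyper = 5, n_hypo = 5, seed = 9)
  sim <- simulate_methylome(cfg)
  res <- call_dmrs(sim$counts, "LF", "HF")
  expect_s3_class(res, "dmr_result")
  expect_true(all(res$hyper$delta > 0))
  expect_true(all(res$hypo$delta < 0))
  if (nrow(res$hyper) && nrow(res$hypo)) {
    ov <- outer(seq_len(nrow(res$hyper)), seq_len(nrow(res$hypo)),
                function(i, j) pmin(res$hyper$end[i], res$hypo$end[j]) -
                  pmax(res$hyper$start[i], res$hypo$start[j]))
    expect_true(all(ov <= 0))
  }
  a <- res$audit
  expect_lte(a[["n_candidate_regions"]], a[["n_dm_sites"]])
  expect_lte(a[["n_passing"]], a[["n_candidate_regions"]])
  expect_equal(a[["n_passing"]], a[["n_hyper"]] + a[["n_hypo"]])
  # every passing DMR satisfies the printed filters exactly
  pass <- rbind(res$hyper, res$hypo)
  expect_true(all(pass$p_adj < 0.01))
  expect_true(all(abs(pass$delta) > 0.30 | pass$fold_change > 5))
  expect_true(all(pass$n_dm_cpgs >= 2))
})
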