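# Independent oracles and small builders used across the suite.
# These deliberately avoid the package's own code paths.

# brute-force binomial G2: maximize each log-likelihood numerically
g2_brute <- function(m1, t1, m2, t2) {
  ll <- function(p, m, t) {
    out <- 0
    if (m > 0) out <- out + m * log(p)
    if (t - m > 0) out <- out + (t - m) * log(1 - p)
    out
  }
  mx <- function(m, t) {
    if (m == 0) return(0)
    if (m == t) return(0)
    optimize(function(p) ll(p, m, t), c(1e-12, 1 - 1e-12),
             maximum = TRUE, tol = 1e-12)$objective
  }
  2 * (mx(m1, t1) + mx(m2, t2) - mx(m1 + m2, t1 + t2))
}

# naive running-sum ssGSEA, gene by gene
ssgsea_brute <- function(expr, gene_set, alpha = 0.25) {
  rho <- rank(expr, ties.method = "average")
  ord <- order(-expr, names(expr))
  genes <- names(expr)[ord]
  in_set <- genes %in% gene_set
  w_tot <- sum(rho[ord][in_set]^alpha)
  n_out <- sum(!in_set)
  p_in <- 0; p_out <- 0; es <- 0
  for (i in seq_along(genes)) {
    if (in_set[i]) {
      p_in <- p_in + rho[ord][i]^alpha / w_tot
    } else {
      p_out <- p_out + 1 / n_out
    }
    es <- es + (p_in - p_out)
  }
  as.numeric(es)
}

# hand-tabulated two-group log-rank chi-square (observed minus expected)
logrank_brute <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  o_minus_e <- 0; v <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt & e1 == 1); d2 <- sum(t2 == tt & e2 == 1)
    d <- d1 + d2
    e1t <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1t)
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# adjusted Rand index from the contingency table
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# reciprocal-overlap matching of called vs true intervals
reciprocal_overlap <- function(a1, a2, b1, b2) {
  ov <- pmin(a2, b2) - pmax(a1, b1)
  pmin(ov / (a2 - a1), ov / (b2 - b1))
}

dmr_recall_precision <- function(called, truth, min_recip = 0.5) {
  hit_t <- vapply(seq_len(nrow(truth)), function(i)
    any(reciprocal_overlap(called$start, called$end,
                           truth$start[i], truth$end[i]) >= min_recip &
          called$direction == truth$direction[i]), TRUE)
  hit_c <- vapply(seq_len(nrow(called)), function(i)
    any(reciprocal_overlap(truth$start, truth$end,
                           called$start[i], called$end[i]) >= min_recip &
          truth$direction == called$direction[i]), TRUE)
  c(recall = mean(hit_t), precision = mean(hit_c))
}

# build a CpGCountMatrix from explicit per-sample count vectors
toy_matrix <- function(pos, counts, chrom = "chr1") {
  samples <- lapply(counts, function(x)
    data.frame(chrom = chrom, pos = pos, meth = x$meth, total = x$total,
               stringsAsFactors = FALSE))
  design <- data.frame(sample_id = names(counts),
                       group = sub("_[^_]*$", "", names(counts)),
                       stringsAsFactors = FALSE)
  cpg_count_matrix(samples, design)
}

# attach member CpG positions of the simulated truth intervals
truth_with_members <- function(sim) {
  tr <- sim$truth$dmrs
  tr$members <- lapply(seq_len(nrow(tr)), function(i)
    sim$counts$pos[sim$counts$pos >= tr$start[i] &
                     sim$counts$pos < tr$end[i]])
  tr
}
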