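#' Simulation configuration for synthetic WGBS designs
#'
#' Collects every knob of the ground-truthed generator.  Defaults emulate a
#' five-replicate mouse dietary design: a low-fat control group (`LF`), a
#' high-fat obese group (`HF`) and a formerly obese group switched back to
#' the control diet (`FO`), ~30x coverage per CpG and replicate, a bimodal
#' background methylation landscape (lowly methylated regulatory loci around
#' 0.05, highly methylated bulk around 0.85) and beta-binomial replicate
#' noise with intra-group correlation `rho`.
#'
#' Planted hyper-DMRs gain `delta` methylation in `HF` (on a low-mode
#' background, mirroring gains at lowly methylated distal regulatory
#' elements), hypo-DMRs lose `delta` (on a high-mode background).  The `FO`
#' group sits at `LF + r * (HF - LF)` where the retention factor `r` is 1
#' for retained, 0 for lost and 0.5 for intermediate DMRs, drawn by quota
#' from `persistence_fractions`.
#'
#' @param n_cpgs number of CpGs.
#' @param n_replicates replicates per group.
#' @param groups group labels to simulate (subset of `c("LF","HF","FO")`,
#'   in this order).
#' @param mean_coverage,coverage_size negative-binomial coverage mean and
#'   size per CpG/replicate.
#' @param rho beta-binomial overdispersion in `[0, 1)`.
#' @param bg_low,bg_high,bg_weight_high,bg_concentration background mixture:
#'   mode locations, probability of the high mode, and beta concentration
#'   (higher = tighter modes).
#' @param n_hyper,n_hypo numbers of planted DMRs per direction.
#' @param dmr_width length-2 range of planted DMR widths (bp).
#' @param dmr_margin minimum separation between planted DMRs (bp); keep it
#'   above the 5 kb merge distance so neighbours stay distinct.
#' @param min_dmr_cpgs minimum CpGs a planted DMR must contain.
#' @param delta planted methylation shift.
#' @param persistence_fractions named fractions (sum 1) of retained / lost /
#'   intermediate DMRs.
#' @param retention_r retention factor per persistence class.
#' @param mean_spacing,min_spacing CpG spacing (bp).
#' @param n_genes genes placed along the simulated chromosome.
#' @param lfc_effect,lfc_sd,coupling expression simulator: absolute log fold
#'   change of coupled genes, observation noise, and coupling strength
#'   multiplier (0 = null).
#' @param de_background_frac,de_background_lfc fraction of uncoupled genes
#'   planted as (weaker) background differential expression, and their
#'   absolute log fold change; real expression programmes contain many
#'   changes not explained by methylation, and without them the
#'   rank-product target list could never contain non-significant genes.
#' @param seed RNG seed; identical configs reproduce identical data.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cpgs = 50000, n_replicates = 5,
                       groups = c("LF", "HF", "FO"),
                       mean_coverage = 30, coverage_size = 10,
                       rho = 0.05,
                       bg_low = 0.05, bg_high = 0.85,
                       bg_weight_high = 0.5, bg_concentration = 40,
                       n_hyper = 25, n_hypo = 25,
                       dmr_width = c(3000, 8000), dmr_margin = 15000,
                       min_dmr_cpgs = 4, delta = 0.4,
                       persistence_fractions = c(retained = 0.4, lost = 0.3,
                                                 intermediate = 0.3),
                       retention_r = c(retained = 1, lost = 0,
                                       intermediate = 0.5),
                       mean_spacing = 1000, min_spacing = 100,
                       n_genes = 4000, lfc_effect = 2, lfc_sd = 0.3,
                       coupling = 1, de_background_frac = 0.15,
                       de_background_lfc = 1, seed = 1) {
  cfg <- as.list(environment())
  if (n_cpgs < 1 || n_replicates < 1 || mean_coverage <= 0) {
    stop("counts must be positive")
  }
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (abs(sum(persistence_fractions) - 1) > 1e-8) {
    stop("persistence fractions must sum to 1")
  }
  if (!all(groups %in% c("LF", "HF", "FO"))) {
    stop("groups must be a subset of LF, HF, FO")
  }
  if (length(dmr_width) != 2L || dmr_width[1] > dmr_width[2]) {
    stop("dmr_width must be an increasing length-2 range")
  }
  structure(cfg, class = "sim_config")
}

## beta-binomial draws; p entries of exactly 0/1 give deterministic counts
rbetabinom <- function(t, p, rho) {
  n <- length(t)
  if (rho == 0) return(rbinom(n, t, p))
  pp <- numeric(n)
  i <- p > 0 & p < 1
  a <- p[i] * (1 - rho) / rho
  b <- (1 - p[i]) * (1 - rho) / rho
  pp[i] <- rbeta(sum(i), a, b)
  pp[p >= 1] <- 1
  rbinom(n, t, pp)
}

place_dmr_intervals <- function(cfg, pos, genome_size) {
  n_dmr <- cfg$n_hyper + cfg$n_hypo
  if (n_dmr == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  widths <- round(runif(n_dmr, cfg$dmr_width[1], cfg$dmr_width[2]))
  starts <- integer(0)
  ends <- integer(0)
  tries <- 0L
  max_tries <- 500L * n_dmr
  while (length(starts) < n_dmr && tries < max_tries) {
    tries <- tries + 1L
    w <- widths[length(starts) + 1L]
    s <- floor(runif(1, pos[1], genome_size - w))
    e <- s + w
    if (length(starts) &&
        any(s < ends + cfg$dmr_margin & e > starts - cfg$dmr_margin)) next
    if (sum(pos >= s & pos < e) < cfg$min_dmr_cpgs) next
    starts <- c(starts, as.integer(s))
    ends <- c(ends, as.integer(e))
  }
  if (length(starts) < n_dmr) {
    stop("could not place planted DMRs disjointly; ",
         "use fewer or narrower DMRs (or a larger n_cpgs)")
  }
  o <- order(starts)
  data.frame(start = starts[o], end = ends[o])
}

#' Simulate a replicated multi-group methylome with planted DMRs
#'
#' Generates CpG positions along one synthetic chromosome, a shared bimodal
#' background methylation level per CpG, planted hyper-/hypo-DMR intervals
#' with persistence classes, gene models with TSSs, a DMR-to-nearest-gene
#' coupling table, and beta-binomial replicate counts for every configured
#' group.  Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a `CpGCountMatrix`), `truth` (list with
#'   `dmrs`, `genes`, `coupling`, per-CpG true group methylation in
#'   `site_levels`) and `config`.
#' @export
simulate_methylome <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_cpgs
  spacing <- cfg$min_spacing +
    rnbinom(n, mu = cfg$mean_spacing - cfg$min_spacing, size = 2)
  pos <- as.integer(1000 + cumsum(spacing))
  genome_size <- max(pos) + 50000L
  chrom <- rep("chr1", n)

  iv <- place_dmr_intervals(cfg, pos, genome_size)
  n_dmr <- nrow(iv)
  direction <- character(n_dmr)
  if (n_dmr > 0L) {
    direction <- sample(rep(c("hyper", "hypo"), c(cfg$n_hyper, cfg$n_hypo)))
  }
  classes <- names(cfg$persistence_fractions)
  if (n_dmr > 0L) {
    quota <- diff(round(cumsum(c(0, cfg$persistence_fractions)) * n_dmr))
    pclass <- sample(rep(classes, quota))
  } else {
    pclass <- character(0)
  }
  r_dmr <- unname(cfg$retention_r[pclass])

  # background: mixture of two beta modes, shared across groups
  conc <- cfg$bg_concentration
  b_low <- rbeta(n, conc * cfg$bg_low, conc * (1 - cfg$bg_low))
  b_high <- rbeta(n, conc * cfg$bg_high, conc * (1 - cfg$bg_high))
  bg <- ifelse(runif(n) < cfg$bg_weight_high, b_high, b_low)

  dmr_of_site <- rep(NA_integer_, n)
  if (n_dmr > 0L) {
    for (i in seq_len(n_dmr)) {
      j <- which(pos >= iv$start[i] & pos < iv$end[i])
      dmr_of_site[j] <- i
      # plant gains on the low mode, losses on the high mode
      bg[j] <- if (direction[i] == "hyper") b_low[j] else b_high[j]
    }
  }
  p_LF <- bg
  p_HF <- bg
  r_site <- rep(0, n)
  if (n_dmr > 0L) {
    in_dmr <- !is.na(dmr_of_site)
    d_sign <- ifelse(direction[dmr_of_site[in_dmr]] == "hyper", 1, -1)
    p_HF[in_dmr] <- pmin(1, pmax(0, bg[in_dmr] + d_sign * cfg$delta))
    r_site[in_dmr] <- r_dmr[dmr_of_site[in_dmr]]
  }
  p_FO <- p_LF + r_site * (p_HF - p_LF)
  levels <- list(LF = p_LF, HF = p_HF, FO = p_FO)

  ids <- unlist(lapply(cfg$groups, function(g)
    paste0(g, "_", seq_len(cfg$n_replicates))))
  design <- data.frame(sample_id = ids,
                       group = rep(cfg$groups, each = cfg$n_replicates),
                       stringsAsFactors = FALSE)
  meth <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  total <- meth
  for (g in cfg$groups) {
    for (k in seq_len(cfg$n_replicates)) {
      t <- rnbinom(n, mu = cfg$mean_coverage, size = cfg$coverage_size)
      m <- rbetabinom(t, levels[[g]], cfg$rho)
      col <- paste0(g, "_", k)
      total[, col] <- t
      meth[, col] <- m
    }
  }
  counts <- new_cpg_count_matrix(chrom, pos, meth, total, design)

  # gene models along the chromosome
  tss <- sort(as.integer(floor(runif(cfg$n_genes, 0, genome_size))))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("gene_%05d", seq_len(cfg$n_genes)),
    chrom = "chr1",
    start = ifelse(strand == "+", tss, pmax(0L, tss - 999L)),
    end = ifelse(strand == "+", tss + 1000L, tss + 1L),
    strand = strand, tss = tss, stringsAsFactors = FALSE)

  dmrs <- data.frame(dmr_id = sprintf("true_%s_%03d", direction,
                                      seq_len(n_dmr)),
                     chrom = rep("chr1", n_dmr),
                     start = iv$start, end = iv$end,
                     direction = direction,
                     delta = rep(cfg$delta, n_dmr),
                     persistence_class = pclass,
                     r = if (n_dmr) r_dmr else numeric(0),
                     n_cpgs = vapply(seq_len(n_dmr), function(i)
                       sum(!is.na(dmr_of_site) & dmr_of_site == i), 0L),
                     stringsAsFactors = FALSE)

  # couple each planted DMR to its nearest free gene within 100 kb
  coupling <- data.frame(dmr_id = character(), gene_id = character(),
                         direction = character(), stringsAsFactors = FALSE)
  used <- character(0)
  for (i in seq_len(n_dmr)) {
    center <- floor((iv$start[i] + iv$end[i]) / 2)
    dist <- abs(genes$tss - center)
    cand <- order(dist, genes$gene_id)
    cand <- cand[dist[cand] <= 1e5 & !(genes$gene_id[cand] %in% used)]
    if (length(cand) == 0L) next
    g <- genes$gene_id[cand[1L]]
    used <- c(used, g)
    coupling <- rbind(coupling,
                      data.frame(dmr_id = dmrs$dmr_id[i], gene_id = g,
                                 direction = direction[i],
                                 stringsAsFactors = FALSE))
  }

  list(counts = counts,
       truth = list(dmrs = dmrs, genes = genes, coupling = coupling,
                    site_levels = levels, genome_size = genome_size),
       config = cfg)
}

#' Simulate a differential-expression table coupled to planted DMRs
#'
#' Genes coupled to planted hyper-DMRs are biased down (negative log fold
#' change), hypo-coupled genes up, with effect `lfc_effect * coupling`.  A
#' fraction `de_background_frac` of the uncoupled genes is planted as
#' weaker background differential expression (`de_background_lfc`, random
#' sign); the remaining genes are null.  The observed log fold change is
#' the true effect plus Gaussian noise of sd `lfc_sd`; p values are
#' two-sided normal tail probabilities of the observed effect, BH-adjusted.
#' With `coupling = 0` and `de_background_frac = 0` every gene is null and
#' p values are uniform.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` component returned by [simulate_methylome()].
#' @return `data.frame` with `gene_id`, `log2fc`, `pvalue`, `padj`,
#'   `de_class` (`UP` / `DOWN` / `NON` at `padj < 0.05`) and `true_lfc`.
#' @export
simulate_expression <- function(config, truth) {
  if (is.null(truth$coupling)) stop("truth lacks gene coupling")
  set.seed(config$seed + 7919L)
  genes <- truth$genes
  true_lfc <- numeric(nrow(genes))
  i <- match(truth$coupling$gene_id, genes$gene_id)
  sgn <- ifelse(truth$coupling$direction == "hyper", -1, 1)
  true_lfc[i] <- sgn * config$lfc_effect * config$coupling
  free <- setdiff(seq_len(nrow(genes)), i)
  n_bg <- round(config$de_background_frac * length(free))
  if (n_bg > 0L) {
    bg <- sample(free, n_bg)
    true_lfc[bg] <- sample(c(-1, 1), n_bg, replace = TRUE) *
      config$de_background_lfc
  }
  obs <- true_lfc + rnorm(nrow(genes), 0, config$lfc_sd)
  p <- 2 * pnorm(-abs(obs) / config$lfc_sd)
  padj <- p.adjust(p, method = "BH")
  data.frame(gene_id = genes$gene_id, log2fc = obs, pvalue = p, padj = padj,
             de_class = ifelse(padj < 0.05,
                               ifelse(obs > 0, "UP", "DOWN"), "NON"),
             true_lfc = true_lfc, stringsAsFactors = FALSE)
}

#' Simulate an expression matrix and survival cohort driven by a latent score
#'
#' Each sample carries a latent "fatty-acid score" `z ~ N(0,1)` that shifts
#' the expression of the first (driver) gene set by `effect * z` and scales
#' the exponential event rate by `exp(-effect * z)`, so low-score samples
#' have shorter survival.  Censoring times are uniform on
#' `[0, censor_max]`.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param gene_sets named list of gene-id vectors over the simulated genes
#'   (`g_0001`, `g_0002`, ...); the first set is the survival driver.
#' @param effect coupling strength (>= 0 unless `allow_negative`).
#' @param seed RNG seed.
#' @param base_rate baseline exponential event rate.
#' @param censor_max upper bound of the uniform censoring time.
#' @param allow_negative permit a negative (protective-inverted) effect.
#' @return list with `expression` (genes x samples), `clinical`
#'   (`sample_id`, `group`, `time`, `event`) and the latent score `latent`.
#' @export
simulate_survival_cohort <- function(n_samples, n_genes, gene_sets, effect,
                                     seed = 1, base_rate = 0.2,
                                     censor_max = 10,
                                     allow_negative = FALSE) {
  if (n_samples < 1) stop("n_samples must be positive")
  if (n_genes < 1) stop("n_genes must be positive")
  if (effect < 0 && !allow_negative) {
    stop("negative effect disallowed unless allow_negative = TRUE")
  }
  ids <- sprintf("g_%04d", seq_len(n_genes))
  for (nm in names(gene_sets)) {
    if (!all(gene_sets[[nm]] %in% ids)) {
      stop(sprintf("gene set '%s' references genes outside the simulated %d",
                   nm, n_genes))
    }
  }
  set.seed(seed)
  z <- rnorm(n_samples)
  samp <- sprintf("s_%03d", seq_len(n_samples))
  x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(ids, samp))
  if (length(gene_sets) > 0L) {
    driver <- gene_sets[[1L]]
    x[driver, ] <- x[driver, ] +
      matrix(effect * z, length(driver), n_samples, byrow = TRUE)
  }
  rate <- base_rate * exp(-effect * z)
  t_event <- rexp(n_samples, rate)
  t_cens <- runif(n_samples, 0, censor_max)
  clinical <- data.frame(sample_id = samp, group = "case",
                         time = pmin(t_event, t_cens),
                         event = as.integer(t_event <= t_cens),
                         stringsAsFactors = FALSE)
  list(expression = x, clinical = clinical, latent = z)
}
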