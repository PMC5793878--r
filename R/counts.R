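#' Assemble a CpG count matrix from per-sample records
#'
#' Builds the central container of the pipeline: methylated and total read
#' counts at every CpG (rows) for every sample (columns), plus the design
#' table mapping samples to groups.  CpGs are the union of positions seen in
#' any sample; a sample without coverage at a CpG gets `total = 0` there.
#'
#' @param samples named list of record `data.frame`s as returned by
#'   [read_coverage_file()] (columns `chrom`, `pos`, `meth`, `total`);
#'   names are sample ids.
#' @param design `data.frame` with columns `sample_id` and `group`; every
#'   name of `samples` must appear exactly once.
#' @return object of class `CpGCountMatrix`: a list with `chrom`, `pos`
#'   (parallel site vectors, sorted), `meth` and `total` (site x sample
#'   integer matrices) and `design`.
#' @export
cpg_count_matrix <- function(samples, design) {
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("'samples' must be a named list of record data frames")
  }
  if (!all(names(samples) %in% design$sample_id)) {
    stop("every sample must appear in the design table")
  }
  design <- design[match(names(samples), design$sample_id), , drop = FALSE]
  keys <- unique(do.call(rbind, lapply(samples, function(s)
    data.frame(chrom = s$chrom, pos = s$pos, stringsAsFactors = FALSE))))
  keys <- keys[order(keys$chrom, keys$pos), , drop = FALSE]
  rownames(keys) <- NULL
  site_key <- paste(keys$chrom, keys$pos)
  n <- nrow(keys)
  meth <- matrix(0L, n, length(samples),
                 dimnames = list(NULL, names(samples)))
  total <- meth
  for (s in names(samples)) {
    i <- match(paste(samples[[s]]$chrom, samples[[s]]$pos), site_key)
    meth[i, s] <- samples[[s]]$meth
    total[i, s] <- samples[[s]]$total
  }
  new_cpg_count_matrix(keys$chrom, keys$pos, meth, total, design)
}

new_cpg_count_matrix <- function(chrom, pos, meth, total, design) {
  stopifnot(length(chrom) == length(pos), nrow(meth) == length(pos),
            identical(dim(meth), dim(total)))
  structure(list(chrom = chrom, pos = as.integer(pos),
                 meth = meth, total = total, design = design),
            class = "CpGCountMatrix")
}

#' @export
print.CpGCountMatrix <- function(x, ...) {
  cat(sprintf("CpGCountMatrix: %d CpGs x %d samples (%s)\n",
              length(x$pos), ncol(x$meth),
              paste(sprintf("%s: n=%d", names(table(x$design$group)),
                            as.integer(table(x$design$group))),
                    collapse = ", ")))
  invisible(x)
}

#' Number of CpG sites in a count matrix
#' @param mat a `CpGCountMatrix`.
#' @return integer.
#' @export
n_sites <- function(mat) length(mat$pos)

group_columns <- function(mat, group) {
  i <- which(mat$design$group == group)
  if (length(i) == 0L) stop(sprintf("group '%s' not present in design", group))
  i
}

subset_sites <- function(mat, idx) {
  new_cpg_count_matrix(mat$chrom[idx], mat$pos[idx],
                       mat$meth[idx, , drop = FALSE],
                       mat$total[idx, , drop = FALSE], mat$design)
}
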