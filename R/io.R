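#' Read a Bismark-coverage-style CpG count file
#'
#' Parses a whitespace/tab-separated file with columns
#' `chrom, start, end, methylation %, count_methylated, count_unmethylated`
#' into per-CpG count records.  `meth = count_methylated` and
#' `total = count_methylated + count_unmethylated`; the methylation-percent
#' column is ignored (it is redundant with the counts).
#'
#' Records with `total == 0` carry no information and are dropped with a
#' single warning; the number dropped is attached as attribute
#' `"n_zero_dropped"`.
#'
#' @param path file path.
#' @param sample_id optional sample identifier stored as an attribute.
#' @param zero_based logical; `TRUE` (default) treats the start column as
#'   0-based (BED-like).  Set `FALSE` for 1-based dialects; positions are
#'   then shifted down by one so that all internal coordinates are 0-based.
#' @return `data.frame` with columns `chrom`, `pos` (0-based CpG start),
#'   `meth`, `total`, sorted by `(chrom, pos)`.
#' @export
read_coverage_file <- function(path, sample_id = NULL, zero_based = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      meth = integer(), total = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "sample_id") <- sample_id
    attr(out, "n_zero_dropped") <- 0L
    return(out)
  }
  parts <- strsplit(trimws(lines), "[\t ]+")
  nf <- lengths(parts)
  bad <- which(nf < 6L)
  if (length(bad)) {
    stop(sprintf("malformed coverage line %d: expected 6 fields, got %d",
                 bad[1L], nf[bad[1L]]))
  }
  m <- matrix(unlist(lapply(parts, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("malformed coverage line %d: non-numeric %s '%s'",
                   bad[1L], what, m[bad[1L], col]))
    }
    v
  }
  start <- num(2L, "start")
  meth <- num(5L, "methylated count")
  unmeth <- num(6L, "unmethylated count")
  bad <- which(meth < 0 | unmeth < 0)
  if (length(bad)) {
    stop(sprintf("malformed coverage line %d: negative count", bad[1L]))
  }
  pos <- as.integer(if (zero_based) start else start - 1)
  bad <- which(pos < 0)
  if (length(bad)) {
    stop(sprintf("malformed coverage line %d: negative position", bad[1L]))
  }
  total <- as.integer(meth + unmeth)
  drop <- total == 0L
  n_drop <- sum(drop)
  if (n_drop > 0L) {
    warning(sprintf("%d record(s) with zero coverage dropped", n_drop))
  }
  out <- data.frame(chrom = m[, 1L], pos = pos,
                    meth = as.integer(meth), total = total,
                    stringsAsFactors = FALSE)[!drop, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_id") <- sample_id
  attr(out, "n_zero_dropped") <- n_drop
  out
}

#' Write DMRs as BED6
#'
#' Coordinates are 0-based half-open.  `name` is the DMR id (which encodes
#' the direction, e.g. `hyper_001`), `score = -10*log10(p_adj)` rounded and
#' capped at 1000 (`p_adj = 0` maps to 1000), `strand = "."`.
#'
#' @param dmrs `data.frame` with columns `chrom`, `start`, `end`,
#'   `direction`, `p_adj`, and optionally `dmr_id`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (nrow(dmrs) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  ids <- if (!is.null(dmrs$dmr_id)) dmrs$dmr_id else
    paste0(dmrs$direction, "_", seq_len(nrow(dmrs)))
  score <- ifelse(dmrs$p_adj <= 0, 1000,
                  pmin(1000, round(-10 * log10(dmrs$p_adj))))
  bed <- data.frame(dmrs$chrom, dmrs$start, dmrs$end, ids, score, ".",
                    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a DMR BED6 file written by [write_dmr_bed()]
#'
#' The direction is recovered from the id prefix (`hyper_*` / `hypo_*`).
#'
#' @param path BED6 path.
#' @return `data.frame` with `chrom`, `start`, `end`, `dmr_id`, `direction`.
#' @export
read_dmr_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), dmr_id = character(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  m <- matrix(unlist(lapply(f, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  data.frame(chrom = m[, 1L], start = as.integer(m[, 2L]),
             end = as.integer(m[, 3L]), dmr_id = m[, 4L],
             direction = sub("_.*$", "", m[, 4L]),
             stringsAsFactors = FALSE)
}

#' Read gene models from BED6
#'
#' The transcription start site (TSS) is the 5' end on the annotated strand:
#' `start` for `+` genes and `end - 1` for `-` genes (0-based).
#'
#' @param path BED6 path (name column = gene id; strand must be `+` or `-`).
#' @return `data.frame` with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`.
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), tss = integer(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(trimws(lines), "[\t ]+")
  nf <- lengths(f)
  if (any(nf < 6L)) {
    stop(sprintf("gene model line %d: missing strand column (need BED6)",
                 which(nf < 6L)[1L]))
  }
  m <- matrix(unlist(lapply(f, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  strand <- m[, 6L]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("gene model line %d: strand must be '+' or '-', got '%s'",
                 bad[1L], strand[bad[1L]]))
  }
  start <- as.integer(m[, 2L]); end <- as.integer(m[, 3L])
  data.frame(gene_id = m[, 4L], chrom = m[, 1L], start = start, end = end,
             strand = strand,
             tss = ifelse(strand == "+", start, end - 1L),
             stringsAsFactors = FALSE)
}

#' Read gene sets in GMT format
#'
#' Each line is `name <tab> description <tab> member1 <tab> member2 ...`.
#' Duplicate members are removed; a set with fewer than two distinct members
#' is rejected.
#'
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    name <- f[1L]
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) < 2L) {
      stop(sprintf("gene set '%s' has fewer than 2 distinct members", name))
    }
    sets[[name]] <- members
  }
  sets
}

#' Read a differential-expression table
#'
#' Tab-separated with a header; the first four columns are taken as gene id,
#' log fold change, p value and BH-adjusted p value.
#'
#' @param path TSV path.
#' @return `data.frame` with `gene_id`, `log2fc`, `pvalue`, `padj`.
#' @export
read_de_table <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (ncol(d) < 4L) stop("differential-expression table needs >= 4 columns")
  out <- d[, 1:4]
  names(out) <- c("gene_id", "log2fc", "pvalue", "padj")
  out
}

#' Read a clinical table
#'
#' Tab-separated with a header; columns sample id, group, survival time and
#' event flag (1 = event, 0 = censored).
#'
#' @param path TSV path.
#' @return `data.frame` with `sample_id`, `group`, `time`, `event`.
#' @export
read_clinical_table <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (ncol(d) < 4L) stop("clinical table needs >= 4 columns")
  out <- d[, 1:4]
  names(out) <- c("sample_id", "group", "time", "event")
  if (any(out$time < 0)) stop("negative survival time")
  out
}
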