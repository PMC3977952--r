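# File input/output: plain-text counts and bedGraph coverage in; BED, TSV
# and a JSON run report out. bedGraph intervals arrive natively
# plateau-compressed (interval length = weight); gaps are zero coverage.

#' Read a count series from plain text or bedGraph
#'
#' Plain text: one non-negative integer per line. bedGraph: standard
#' 4-column (chrom, start, end, value) with 0-based half-open intervals and
#' integer values; a single chromosome per run (use `chrom` to pick one from
#' a multi-chromosome file). Gaps between intervals are filled with zero
#' coverage; each interval becomes one weighted point, so bedGraph input is
#' already plateau-compressed.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"txt"` or `"bedgraph"`.
#' @param chrom chromosome to extract from a multi-chromosome bedGraph.
#' @return an object of class `count_series`: `values`, `weights` (`NULL`
#'   for txt input), `n`, `chrom`, `offset` (0-based genomic start of the
#'   series, 0 for txt).
#' @export
read_counts <- function(path, format = c("auto", "txt", "bedgraph"),
                        chrom = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg|bedGraph)$", path)) "bedgraph"
              else "txt"
  }
  if (format == "txt") {
    v <- scan(path, what = numeric(), quiet = TRUE)
    if (any(v < 0 | v != round(v)))
      stop("plain-text counts must be non-negative integers")
    return(structure(list(values = v, weights = NULL, n = length(v),
                          chrom = NA_character_, offset = 0L),
                     class = "count_series"))
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  chroms <- as.character(unique(GenomicRanges::seqnames(gr)))
  if (length(chroms) > 1L) {
    if (is.null(chrom))
      stop("multi-chromosome bedGraph: pick one with 'chrom' (found: ",
           paste(chroms, collapse = ", "), ")")
    gr <- gr[GenomicRanges::seqnames(gr) == chrom]
    if (length(gr) == 0L) stop("chromosome '", chrom, "' not in file")
  } else if (!is.null(chrom) && !identical(chrom, chroms)) {
    stop("chromosome '", chrom, "' not in file")
  }
  gr <- GenomicRanges::sort(gr)
  v <- gr$score
  if (any(v < 0 | v != round(v)))
    stop("bedGraph coverage values must be non-negative integers")
  # 1-based inclusive starts/ends of the imported intervals
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  if (any(st[-1L] <= en[-length(en)]))
    stop("overlapping bedGraph intervals")
  values <- numeric(0); weights <- integer(0)
  cur <- st[1L]
  for (i in seq_along(v)) {
    if (st[i] > cur) {                       # zero-fill the gap
      values <- c(values, 0); weights <- c(weights, st[i] - cur)
    }
    values <- c(values, v[i]); weights <- c(weights, en[i] - st[i] + 1L)
    cur <- en[i] + 1L
  }
  # merge adjacent equal values so runs are maximal
  keep <- c(TRUE, diff(values) != 0)
  grp <- cumsum(keep)
  values <- values[keep]
  weights <- as.integer(tapply(weights, grp, sum))
  structure(list(values = values, weights = weights, n = sum(weights),
                 chrom = as.character(chroms[1L]),
                 offset = st[1L] - 1L),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> n = %d%s%s\n", x$n,
              if (!is.null(x$weights))
                sprintf(" (%d weighted points)", length(x$values)) else "",
              if (!is.na(x$chrom)) paste0(", ", x$chrom) else ""))
  invisible(x)
}

#' Write a fitted segmentation to BED, TSV and a JSON report
#'
#' Three files are produced under `prefix`: `<prefix>.bed` (0-based
#' half-open segments, name = segment index, score = fitted mean linearly
#' rescaled to 0-1000 per BED convention), `<prefix>_segments.tsv` (1-based
#' inclusive coordinates with exact fitted values) and `<prefix>_report.json`
#' (configuration, dispersion, per-K costs and criterion values, the
#' selected K and breakpoints for every K).
#'
#' @param fit a [pdp_segment()] result.
#' @param ktab a [select_K()] result for `fit`.
#' @param prefix output path prefix.
#' @param chrom chromosome name for the BED track (default `"chr1"`).
#' @param offset 0-based genomic start of position 1 (default 0).
#' @return (invisibly) named character vector of the files written.
#' @export
write_segments <- function(fit, ktab, prefix, chrom = "chr1", offset = 0L) {
  stopifnot(inherits(fit, "pdp_fit"), inherits(ktab, "criterion_table"))
  K_hat <- attr(ktab, "K_hat")
  tab <- segment_table(fit, K_hat)

  bed_path <- paste0(prefix, ".bed")
  tsv_path <- paste0(prefix, "_segments.tsv")
  json_path <- paste0(prefix, "_report.json")

  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = tab$start + offset,
                              end = tab$end + offset),
    name = paste0("seg", tab$segment),
    score = pmin(1000L, as.integer(round(
      1000 * tab$mean / max(tab$mean, .Machine$double.eps)))))
  rtracklayer::export(gr, bed_path, format = "BED")

  con <- file(tsv_path, "w")
  writeLines(c(
    sprintf("# countseg %s segment table (1-based inclusive coordinates)",
            as.character(utils::packageVersion("countseg"))),
    sprintf("# model=%s phi=%.6g phi_source=%s Kmax=%d criterion=%s K_hat=%d",
            fit$model, fit$phi, fit$phi_source, fit$Kmax,
            attr(ktab, "criterion_name"), K_hat)), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  report <- list(
    tool = "countseg",
    version = as.character(utils::packageVersion("countseg")),
    config = list(model = fit$model, phi = fit$phi,
                  phi_source = fit$phi_source, Kmax = fit$Kmax,
                  compressed = fit$compressed, n = fit$n,
                  n_effective = fit$n_effective,
                  criterion = attr(ktab, "criterion_name"),
                  beta = attr(ktab, "beta")),
    K_hat = K_hat,
    criterion_table = as.data.frame(ktab),
    breakpoints = fit$breakpoints,
    segments = tab)
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")

  invisible(c(bed = bed_path, tsv = tsv_path, json = json_path))
}
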