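#' Coverage-ratio gene copy-number estimate
#'
#' Copy number is estimated as the median read depth over the gene interval
#' divided by the median depth over all nuclear positions pooled. Both the
#' raw ratio and its nearest integer (half away from zero) are reported.
#'
#' @param coverage tibble with `strain`, `chrom`, `depth` (list column of
#'   per-base integer depth vectors, 1-based positions)
#' @param genes tibble of gene intervals: `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive)
#' @return tibble: `strain`, `gene`, `ratio`, `rounded`
#' @export
#' @examples
#' cov <- tibble::tibble(strain = "s1", chrom = "chr01",
#'                       depth = list(rep(50L, 1000)))
#' genes <- tibble::tibble(gene = "g", chrom = "chr01",
#'                         start = 101, end = 200)
#' copy_number(cov, genes)
copy_number <- function(coverage, genes) {
  rows <- list()
  for (st in unique(coverage$strain)) {
    cv <- coverage[coverage$strain == st, ]
    genome_median <- median(unlist(cv$depth))
    if (!is.finite(genome_median) || genome_median <= 0)
      abort(sprintf("strain %s: genome median depth is zero", st))
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      tr <- cv$depth[[match(g$chrom, cv$chrom)]]
      if (is.null(tr)) abort(sprintf("chromosome %s missing", g$chrom))
      if (g$start < 1 || g$end > length(tr) || g$end < g$start)
        abort(sprintf("gene %s: interval outside chromosome", g$gene))
      ratio <- median(tr[g$start:g$end]) / genome_median
      rows[[length(rows) + 1L]] <- tibble(
        strain = st, gene = g$gene, ratio = ratio,
        rounded = as.integer(sign(ratio) * floor(abs(ratio) + 0.5))
      )
    }
  }
  bind_rows(rows)
}

#' Gene intervals from the placed marker catalog
#'
#' @param catalog placed catalog (with `chrom`, `start`, `end`)
#' @param markers markers to keep (default all placed)
#' @return tibble `gene`, `chrom`, `start`, `end`
#' @export
catalog_gene_intervals <- function(catalog, markers = NULL) {
  out <- catalog |>
    filter(!is.na(.data$start)) |>
    select(gene = "marker", "chrom", "start", "end")
  if (!is.null(markers)) out <- filter(out, .data$gene %in% markers)
  out
}

#' Read / write gene intervals as BED
#'
#' BED is 0-based half-open on disk; intervals are converted to and from
#' the package's 1-based inclusive convention.
#'
#' @param genes tibble `gene`, `chrom`, `start`, `end` (1-based inclusive)
#' @param path file path
#' @return `read_bed` returns the genes tibble
#' @export
write_bed <- function(genes, path) {
  utils::write.table(
    data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "gene"),
                         colClasses = c("character", "integer", "integer",
                                        "character"))
  tibble(gene = d$gene, chrom = d$chrom, start = d$start + 1L, end = d$end)
}
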