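#' Generate a synthetic reference genome
#'
#' Builds a random nuclear reference of `n_chrom` chromosomes of equal length
#' with a target GC content. Deterministic for a fixed seed.
#'
#' @param n_chrom number of chromosomes (>= 1)
#' @param chrom_len chromosome length in bp (>= 10,000)
#' @param gc target G+C fraction, strictly between 0 and 1
#' @param seed integer seed
#' @return tibble with columns `chrom`, `seq`
#' @export
#' @examples
#' ref <- make_reference(1, 10000, 0.38, seed = 7)
#' nchar(ref$seq)
make_reference <- function(n_chrom, chrom_len, gc = 0.38, seed = 1) {
  check_scalar_count(n_chrom, "n_chrom", 1)
  check_scalar_count(chrom_len, "chrom_len", 10000)
  if (gc <= 0 || gc >= 1) abort("`gc` must be strictly between 0 and 1")
  withr::with_seed(seed, {
    tibble(
      chrom = sprintf("chr%02d", seq_len(n_chrom)),
      seq   = vapply(seq_len(n_chrom), function(i) random_dna(chrom_len, gc),
                     character(1))
    )
  })
}

#' Default domestication-marker catalog
#'
#' Synthetic stand-ins for the surveyed loci: the aquaporins AQY1/AQY2, the
#' sucrose invertase SUC2, the molasses-resistance gene RTM1, the biotin
#' genes BIO1/BIO6, the alpha-galactosidase MEL, the glucoamylase STA1 with
#' its promoter, and the horizontally acquired wine-strain regions A, B and
#' C. Sequences are random but deterministic for the seed; CDS entries start
#' with ATG and end with a stop codon.
#'
#' @param seed integer seed
#' @return tibble with columns `marker`, `kind` (cds/promoter/region), `seq`,
#'   `length`
#' @export
default_marker_catalog <- function(seed = 101) {
  entries <- tibble(
    marker = c("AQY1", "AQY2", "SUC2", "RTM1", "BIO1", "BIO6",
               "MEL", "STA1", "STA1_promoter",
               "region_A", "region_B", "region_C"),
    kind   = c("cds", "cds", "cds", "cds", "cds", "cds",
               "cds", "cds", "promoter",
               "region", "region", "region"),
    length = c(915L, 870L, 1599L, 900L, 990L, 1098L,
               1413L, 1536L, 2000L,
               3000L, 3000L, 3000L)
  )
  withr::with_seed(seed, {
    entries$seq <- pmap(list(entries$kind, entries$length), function(kind, len) {
      if (kind == "cds") random_cds(len) else random_dna(len)
    }) |> unlist()
  })
  entries
}

#' Place catalog markers at fixed loci on a reference genome
#'
#' Markers are inserted (replacing background sequence, so coordinates are
#' shared by all strains) at evenly spaced loci on chromosome 1, with the
#' STA1 promoter placed immediately upstream of STA1. Returns the modified
#' reference and the placed catalog with 1-based inclusive intervals.
#'
#' @param reference tibble from [make_reference()]
#' @param catalog tibble from [default_marker_catalog()]
#' @return list with `reference` (markers inserted) and `catalog` (with
#'   `chrom`, `start`, `end` columns, 1-based inclusive)
#' @export
place_catalog <- function(reference, catalog) {
  chrom <- reference$chrom[1]
  seqv <- seq_chars(reference$seq[1])
  L <- length(seqv)
  # STA1 promoter must directly precede STA1: fuse them for placement
  sta1 <- catalog[catalog$marker == "STA1", ]
  prom <- catalog[catalog$marker == "STA1_promoter", ]
  units <- catalog[!catalog$marker %in% c("STA1", "STA1_promoter"), ]
  unit_names <- c(units$marker, "STA1_unit")
  unit_seqs <- c(units$seq, paste0(prom$seq, sta1$seq))
  total <- sum(nchar(unit_seqs))
  gap <- (L - total) %/% (length(unit_seqs) + 1)
  if (gap < 500)
    abort("reference too short for the marker catalog; increase chrom_len")
  placed <- vector("list", length(unit_seqs))
  pos <- gap + 1
  for (i in seq_along(unit_seqs)) {
    len <- nchar(unit_seqs[i])
    seqv[pos:(pos + len - 1)] <- seq_chars(unit_seqs[i])
    placed[[i]] <- tibble(marker = unit_names[i], start = pos,
                          end = pos + len - 1)
    pos <- pos + len + gap
  }
  placed <- bind_rows(placed)
  # split the fused STA1 unit back into promoter + CDS intervals
  u <- placed[placed$marker == "STA1_unit", ]
  placed <- placed[placed$marker != "STA1_unit", ]
  placed <- bind_rows(
    placed,
    tibble(marker = "STA1_promoter", start = u$start,
           end = u$start + nchar(prom$seq) - 1),
    tibble(marker = "STA1", start = u$start + nchar(prom$seq), end = u$end)
  )
  placed$chrom <- chrom
  out_cat <- left_join(catalog, placed, by = "marker")
  reference$seq[1] <- chars_seq(seqv)
  list(reference = reference, catalog = out_cat)
}
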