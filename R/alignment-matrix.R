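#' Phred quality score to percent base-call accuracy
#'
#' `100 * (1 - 10^(-q/10))`; Q40 corresponds to 99.99% accuracy, the
#' threshold used for consensus masking.
#'
#' @param q Phred score(s), >= 0
#' @return percent accuracy
#' @export
#' @examples
#' phred_accuracy(40)  # 99.99
phred_accuracy <- function(q) {
  if (any(q < 0)) abort("Phred scores must be >= 0")
  100 * (1 - 10^(-q / 10))
}

VALID_CALLS <- c(DNA_BASES, names(IUPAC_HET))

#' Quality-mask consensus sequences
#'
#' Converts to 'N' every base whose Phred quality is below the threshold
#' (strictly below: a Q40 base is kept at the default threshold), and every
#' character that is neither an unambiguous base nor a two-base IUPAC
#' heterozygous code. Idempotent; rows without quality strings pass through
#' with only the character cleanup.
#'
#' @param consensus tibble with columns `strain`, `chrom`, `seq` and
#'   optionally `qual` (Phred+33 string, same length as `seq`)
#' @param q_threshold masking threshold (default Q40)
#' @return tibble of the same shape with masked `seq`
#' @export
mask_consensus <- function(consensus, q_threshold = 40) {
  has_qual <- "qual" %in% names(consensus)
  consensus$seq <- map_chr(seq_len(nrow(consensus)), function(i) {
    v <- seq_chars(consensus$seq[i])
    keep <- v %in% VALID_CALLS
    if (has_qual && !is.na(consensus$qual[i])) {
      q <- consensus$qual[i]
      if (nchar(q) != length(v))
        abort(sprintf("strain %s %s: seq and qual lengths differ",
                      consensus$strain[i], consensus$chrom[i]))
      keep <- keep & (phred_to_int(q) >= q_threshold)
    }
    v[!keep] <- "N"
    chars_seq(v)
  })
  consensus
}

#' Extract the SNP matrix from a masked consensus panel
#'
#' A column (chrom, pos) is retained iff (i) the fraction of strains with a
#' single unambiguous base (A/C/G/T) at that position is at least
#' `min_unambiguous_fraction` of all strains, and (ii) at least two distinct
#' bases occur among those unambiguous calls. Heterozygous IUPAC codes and
#' 'N' count as ambiguous. The fraction comparison is exact to four decimal
#' places of the threshold (so 6/7 passes at 0.85 without rounding noise).
#'
#' @param consensus masked consensus tibble (`strain`, `chrom`, `seq`)
#' @param min_unambiguous_fraction site-level call-rate threshold
#' @return object of class `snp_matrix`: list with `sites` (tibble `chrom`,
#'   `pos`, 1-based), `alleles` (strains x sites character matrix) and
#'   `strains`
#' @export
extract_snps <- function(consensus, min_unambiguous_fraction = 0.85) {
  if (nrow(consensus) == 0) abort("empty consensus panel")
  strains <- unique(consensus$strain)
  n <- length(strains)
  f4 <- round(min_unambiguous_fraction * 1e4)
  chroms <- unique(consensus$chrom)
  sites <- list(); alle <- list()
  for (ch in chroms) {
    sub <- consensus[consensus$chrom == ch, ]
    sub <- sub[match(strains, sub$strain), ]
    if (anyNA(sub$strain)) abort("all strains must carry every chromosome")
    lens <- nchar(sub$seq)
    if (length(unique(lens)) != 1)
      abort(sprintf("chromosome %s: strains differ in length", ch))
    mat <- do.call(rbind, strsplit(sub$seq, "", fixed = TRUE))
    unamb <- matrix(mat %in% DNA_BASES, nrow = n)
    n_call <- colSums(unamb)
    cand <- which(n_call * 1e4 >= f4 * n & n_call >= 2L)
    if (!length(cand)) next
    poly <- vapply(cand, function(j) {
      calls <- mat[unamb[, j], j]
      length(unique(calls)) >= 2
    }, logical(1))
    keep <- cand[poly]
    if (!length(keep)) next
    sites[[ch]] <- tibble(chrom = ch, pos = keep)
    alle[[ch]] <- mat[, keep, drop = FALSE]
  }
  sites <- bind_rows(sites)
  if (nrow(sites) == 0)
    sites <- tibble(chrom = character(), pos = integer())
  alleles <- do.call(cbind, alle)
  if (is.null(alleles)) alleles <- matrix(character(0), nrow = n)
  rownames(alleles) <- strains
  structure(list(sites = sites, alleles = alleles, strains = strains),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d strains x %d sites\n",
              length(x$strains), nrow(x$sites)))
  invisible(x)
}

#' Concatenate a SNP matrix into a pseudo-alignment
#'
#' One record per strain, one column per retained SNP; ambiguous calls
#' (het codes, 'N') are written as 'N'. The column map records the source
#' coordinate of every alignment column.
#'
#' @param x `snp_matrix`
#' @return list with `alignment` (named character vector of equal-length
#'   strings) and `column_map` (tibble `index`, `chrom`, `pos`)
#' @export
concat_snp_alignment <- function(x) {
  if (nrow(x$sites) == 0) abort("SNP matrix is empty")
  m <- x$alleles
  m[!(m %in% DNA_BASES)] <- "N"
  aln <- apply(m, 1, chars_seq)
  names(aln) <- x$strains
  list(alignment = aln,
       column_map = mutate(x$sites, index = row_number(),
                           .before = "chrom"))
}

#' @exportS3Method generics::tidy
tidy.snp_matrix <- function(x, ...) {
  if (nrow(x$sites) == 0)
    return(tibble(strain = character(), chrom = character(),
                  pos = integer(), allele = character()))
  tibble(
    strain = rep(x$strains, times = nrow(x$sites)),
    chrom = rep(x$sites$chrom, each = length(x$strains)),
    pos = rep(x$sites$pos, each = length(x$strains)),
    allele = as.vector(x$alleles)
  )
}

#' @exportS3Method generics::glance
glance.snp_matrix <- function(x, ...) {
  amb <- mean(!(x$alleles %in% DNA_BASES))
  tibble(n_strains = length(x$strains), n_sites = nrow(x$sites),
         ambiguous_fraction = if (nrow(x$sites)) amb else NA_real_)
}
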