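#' Introduce an inactivating lesion into a gene or promoter sequence
#'
#' Emulates the three lesion classes observed among yeast domestication
#' markers: an in-frame premature stop codon (as in SUC2 of the Olives
#' clade), a frameshift indel, and a promoter deletion (the 1162-bp STA1
#' promoter lesion associated with weak diastase activity).
#'
#' @param gene_seq sequence string; in-frame CDS for `premature_stop` and
#'   `frameshift`, promoter sequence for `promoter_deletion`
#' @param kind one of "premature_stop", "frameshift", "promoter_deletion"
#' @param seed integer seed controlling lesion placement
#' @param deletion_len deletion length in bp (promoter_deletion only)
#' @param indel_len signed indel length for frameshift; absolute value must
#'   not be a multiple of 3 (default +1 insertion ... actually -1 deletion)
#' @return list with `seq` (mutated sequence) and `lesion` (one-row tibble:
#'   `kind`, `pos` 1-based, `len`, `codon` for premature stops)
#' @export
#' @examples
#' cds <- withr::with_seed(1, random_cds(300))
#' les <- apply_lesion(cds, "premature_stop", seed = 2)
#' les$lesion
apply_lesion <- function(gene_seq, kind, seed = 1,
                         deletion_len = 1162L, indel_len = -1L) {
  kind <- match.arg(kind, c("premature_stop", "frameshift",
                            "promoter_deletion"))
  n <- nchar(gene_seq)
  if (kind != "promoter_deletion" && n < 300)
    abort("CDS lesions require a gene of >= 300 bp")
  withr::with_seed(seed, {
    switch(kind,
      premature_stop = {
        n_codon <- n %/% 3
        # strictly internal codon, keep the start codon untouched
        codon <- sample(2:(n_codon - 1), 1)
        pos <- (codon - 1) * 3 + 1
        v <- seq_chars(gene_seq)
        v[pos:(pos + 2)] <- c("T", "A", "A")
        list(seq = chars_seq(v),
             lesion = tibble(kind = "premature_stop", pos = pos, len = 3L,
                             codon = codon))
      },
      frameshift = {
        if (abs(indel_len) %% 3 == 0)
          abort("frameshift indel length must not be a multiple of 3")
        pos <- sample(seq(31, n - 60), 1)
        v <- seq_chars(gene_seq)
        if (indel_len < 0) {
          v <- v[-(pos:(pos - indel_len - 1))]
        } else {
          v <- append(v, sample(DNA_BASES, indel_len, replace = TRUE),
                      after = pos - 1)
        }
        list(seq = chars_seq(v),
             lesion = tibble(kind = "frameshift", pos = pos,
                             len = as.integer(indel_len), codon = NA_integer_))
      },
      promoter_deletion = {
        if (deletion_len >= n)
          abort("deletion longer than (or equal to) the promoter")
        start <- sample(seq_len(n - deletion_len), 1)
        v <- seq_chars(gene_seq)
        v <- v[-(start:(start + deletion_len - 1))]
        list(seq = chars_seq(v),
             lesion = tibble(kind = "promoter_deletion", pos = start,
                             len = as.integer(deletion_len),
                             codon = NA_integer_))
      }
    )
  })
}
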