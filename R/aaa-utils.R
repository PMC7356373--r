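#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols distinct pull n row_number rename
#' @importFrom purrr map map2 pmap map_chr map_int map_dbl map_lgl
#' @importFrom stats median setNames rbinom rpois runif as.dist
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC two-base ambiguity codes used for heterozygous genotype calls
IUPAC_HET <- c(M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT")

#' Encode an unordered base pair as its IUPAC ambiguity code
#' @param a,b single bases (A/C/G/T)
#' @return single IUPAC character; returns the base itself when `a == b`
#' @keywords internal
iupac_encode <- function(a, b) {
  key <- paste0(pmin(a, b), pmax(a, b))
  out <- names(IUPAC_HET)[match(key, IUPAC_HET)]
  ifelse(a == b, a, out)
}

#' Decode an IUPAC heterozygous code into its two bases
#' @param code vector of IUPAC codes
#' @return character matrix with two columns (sorted base pair)
#' @keywords internal
iupac_decode <- function(code) {
  pair <- IUPAC_HET[code]
  if (anyNA(pair)) abort("not a heterozygous IUPAC code")
  cbind(substr(pair, 1, 1), substr(pair, 2, 2))
}

is_het_code <- function(x) x %in% names(IUPAC_HET)

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

chars_seq <- function(v) paste(v, collapse = "")

#' Generate a random DNA string with a target GC content
#' @param n length in bp
#' @param gc target G+C fraction
#' @return character scalar (caller controls the RNG state)
#' @keywords internal
random_dna <- function(n, gc = 0.38) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars_seq(sample(DNA_BASES, n, replace = TRUE, prob = p))
}

gc_fraction <- function(seq) {
  v <- seq_chars(seq)
  v <- v[v %in% DNA_BASES]
  sum(v %in% c("G", "C")) / length(v)
}

# Codon table restricted to what the package needs: stop detection and
# translation of unambiguous codons (ambiguous codons -> "X").
translate_cds <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) abort("CDS length must be a multiple of 3")
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(seq), if.fuzzy.codon = "X"
  )))
  aa
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

codons_of <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n - 2, by = 3), seq(3, n, by = 3))
}

#' Pick a replacement base different from the current one
#' @keywords internal
mutate_base <- function(base) {
  vapply(base, function(b) sample(setdiff(DNA_BASES, b), 1), character(1),
         USE.NAMES = FALSE)
}

#' Substitute bases at random positions, avoiding new in-frame stop codons
#'
#' Used to build diverged but still-translatable gene copies (e.g. the MEL
#' allele reference panel). Mutations landing on a codon that would become a
#' stop are redrawn; positions are sampled without replacement.
#' @param seq in-frame CDS string
#' @param rate per-site substitution probability
#' @return mutated CDS string
#' @keywords internal
mutate_cds <- function(seq, rate) {
  v <- seq_chars(seq)
  n <- length(v)
  n_mut <- rbinom(1, n, rate)
  if (n_mut == 0) return(seq)
  pos <- sample(n, n_mut)
  for (p in pos) {
    old <- v[p]
    for (alt in sample(setdiff(DNA_BASES, old))) {
      v[p] <- alt
      ci <- ((p - 1) %/% 3) * 3 + 1
      codon <- chars_seq(v[ci:(ci + 2)])
      if (ci < n - 2 && codon %in% STOP_CODONS) {
        v[p] <- old  # would truncate the ORF; try another base
      } else {
        break
      }
    }
  }
  chars_seq(v)
}

#' Substitute bases at random positions (no reading-frame constraint)
#' @keywords internal
mutate_dna <- function(seq, rate) {
  v <- seq_chars(seq)
  n_mut <- rbinom(1, length(v), rate)
  if (n_mut == 0) return(seq)
  pos <- sample(length(v), n_mut)
  v[pos] <- mutate_base(v[pos])
  chars_seq(v)
}

#' Build a random intact CDS (ATG ... stop) of the requested length
#' @param len total length, must be a multiple of 3 and >= 9
#' @keywords internal
random_cds <- function(len, gc = 0.40) {
  if (len %% 3 != 0 || len < 9) abort("CDS length must be a multiple of 3, >= 9")
  n_mid <- len / 3 - 2
  body <- character(n_mid)
  for (i in seq_len(n_mid)) {
    repeat {
      codon <- random_dna(3, gc)
      if (!codon %in% STOP_CODONS) break
    }
    body[i] <- codon
  }
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

phred_to_int <- function(qual) utf8ToInt(qual) - 33L

int_to_phred <- function(q) intToUtf8(pmin(q, 93L) + 33L)

check_scalar_count <- function(x, name, min = 1) {
  if (length(x) != 1 || is.na(x) || x < min)
    abort(sprintf("`%s` must be a single value >= %s", name, min))
  invisible(x)
}
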