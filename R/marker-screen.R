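NUC_SUB_MATRIX <- NULL

nuc_sub_matrix <- function() {
  m <- matrix(-1, 5, 5,
              dimnames = list(c(DNA_BASES, "N"), c(DNA_BASES, "N")))
  diag(m) <- 1
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

string_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

align_global_local <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = "global-local", substitutionMatrix = nuc_sub_matrix(),
    gapOpening = 2, gapExtension = 1
  )
}

align_global <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = "global", substitutionMatrix = nuc_sub_matrix(),
    gapOpening = 2, gapExtension = 1
  )
}

# Deletion-friendly scoring for the promoter scan: a kilobase deletion must
# stay one contiguous gap run. Cheap extension keeps a long run cheaper
# than a mismatch wall against non-homologous sequence; the high opening
# cost stops the aligner from fragmenting the run around accidental
# matches in that sequence.
align_deletion_scan <- function(pattern, subject, type) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = type, substitutionMatrix = nuc_sub_matrix(),
    gapOpening = 25, gapExtension = 0.25
  )
}

aligned_strings <- function(aln) {
  list(pattern = as.character(Biostrings::alignedPattern(aln)),
       subject = as.character(Biostrings::alignedSubject(aln)))
}

alignment_identity <- function(pat, sub) {
  vp <- seq_chars(pat); vs <- seq_chars(sub)
  both <- vp != "-" & vs != "-"
  if (!any(both)) return(NA_real_)
  mean(vp[both] == vs[both])
}

#' Locate a marker gene in a strain sequence by k-mer seeding
#'
#' Presence screening without an external aligner: the fraction of the
#' marker's k-mers found exactly in the strain sequence decides the call
#' (>= `present_min` present, < `absent_max` absent, in between partial).
#' When seeds are found, the implied locus is extracted with a margin and
#' the marker is globally aligned against it to report identity and the
#' aligned copy.
#'
#' @param genome strain sequence (single string)
#' @param marker_seq marker reference sequence (length >= k)
#' @param k k-mer size (default 31)
#' @param present_min,absent_max k-mer fraction bands for presence calls
#' @param genome_kmers optional precomputed `string_kmers(genome, k)`
#' @return one-row tibble: `state` ("present", "partial", "absent"),
#'   `kmer_fraction`, `identity`, `start`, `end` (1-based hit interval) and
#'   `alignment` (list of gapped pattern/subject strings)
#' @export
find_marker <- function(genome, marker_seq, k = 31, present_min = 0.5,
                        absent_max = 0.1, genome_kmers = NULL) {
  if (nchar(marker_seq) < k) abort("marker shorter than k")
  mk <- string_kmers(marker_seq, k)
  if (is.null(genome_kmers)) genome_kmers <- string_kmers(genome, k)
  hit_pos <- match(mk, genome_kmers)
  frac <- mean(!is.na(hit_pos))
  state <- if (frac >= present_min) "present"
           else if (frac < absent_max) "absent" else "partial"
  if (all(is.na(hit_pos)) || state == "absent") {
    return(tibble(state = state, kmer_fraction = frac,
                  identity = NA_real_, start = NA_integer_,
                  end = NA_integer_, alignment = list(NULL)))
  }
  idx <- which(!is.na(hit_pos))
  est <- hit_pos[idx] - (idx - 1L)  # implied marker start per seed
  w0 <- max(1L, min(est) - 100L)
  w1 <- min(nchar(genome), max(est) + nchar(marker_seq) + 100L)
  aln <- align_global_local(marker_seq, substr(genome, w0, w1))
  s <- aligned_strings(aln)
  ident <- alignment_identity(s$pattern, s$subject)
  sub_rng <- aln@subject@range
  tibble(state = state, kmer_fraction = frac, identity = ident,
         start = w0 + BiocGenerics::start(sub_rng) - 1L,
         end = w0 + BiocGenerics::end(sub_rng) - 1L,
         alignment = list(s))
}

#' Assess the integrity of an aligned CDS copy
#'
#' Detects the two inactivation classes: frameshifts (an indel within the
#' CDS whose length is not a multiple of 3) and premature stop codons (an
#' in-frame stop strictly before the reference terminal codon).
#'
#' @param alignment list with gapped `pattern` (reference CDS) and
#'   `subject` (strain copy) strings, as produced by [find_marker()]
#' @return list with `state` ("present_intact" or "present_inactivated")
#'   and `lesions` (tibble `kind`, `pos` 1-based on the reference, `len`
#'   signed indel length, `codon`)
#' @export
cds_integrity <- function(alignment) {
  if (is.null(alignment) || is.null(alignment$pattern))
    abort("cds_integrity requires an aligned copy")
  vp <- seq_chars(alignment$pattern)
  vs <- seq_chars(alignment$subject)
  ref_pos <- cumsum(vp != "-")  # reference coordinate per column
  lesions <- list()
  for (who in c("subject", "pattern")) {
    v <- if (who == "subject") vs else vp
    r <- rle(v == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gap_runs <- which(r$values)
    for (g in gap_runs) {
      len <- r$lengths[g]
      if (len %% 3 == 0) next
      pos <- max(1L, ref_pos[starts[g]])
      lesions[[length(lesions) + 1L]] <-
        tibble(kind = "frameshift",
               pos = pos,
               len = if (who == "subject") -as.integer(len)
                     else as.integer(len),
               codon = NA_integer_)
    }
  }
  # premature stop: translate the degapped strain copy when in frame
  copy <- chars_seq(vs[vs != "-"])
  if (nchar(copy) %% 3 == 0 && nchar(copy) >= 6) {
    aa <- translate_cds(copy)
    stops <- which(seq_chars(aa) == "*")
    n_codon <- nchar(aa)
    premature <- stops[stops < n_codon]
    if (length(premature)) {
      cd <- premature[1]
      lesions[[length(lesions) + 1L]] <-
        tibble(kind = "premature_stop", pos = (cd - 1L) * 3L + 1L,
               len = 3L, codon = as.integer(cd))
    }
  }
  lesions <- if (length(lesions)) bind_rows(lesions)
             else tibble(kind = character(), pos = integer(),
                         len = integer(), codon = integer())
  list(state = if (nrow(lesions)) "present_inactivated" else "present_intact",
       lesions = lesions)
}

#' Measure a promoter deletion by alignment
#'
#' Globally aligns the reference promoter against the strain's promoter
#' region and returns the length of the largest contiguous gapped run in
#' the strain sequence (0 when the promoter is intact). The region is
#' located by k-mer seeding when `strain_seq` is long; short inputs (a bare
#' promoter region) are aligned directly.
#'
#' @param strain_seq strain sequence (whole assembly or promoter region)
#' @param promoter_ref reference promoter sequence
#' @param k seeding k-mer size
#' @return deletion length in bp (integer), or `NA` with a warning when the
#'   promoter region cannot be recovered
#' @export
sta1_promoter_scan <- function(strain_seq, promoter_ref, k = 31) {
  Lp <- nchar(promoter_ref)
  if (nchar(strain_seq) <= Lp + 400) {
    s <- aligned_strings(align_deletion_scan(promoter_ref, strain_seq,
                                             "global"))
  } else {
    gk <- string_kmers(strain_seq, k)
    mk <- string_kmers(promoter_ref, k)
    hit <- match(mk, gk)
    idx <- which(!is.na(hit))
    if (!length(idx)) {
      warn("promoter region unrecoverable: no seed k-mers found")
      return(NA_integer_)
    }
    est <- hit[idx] - (idx - 1L)
    w0 <- max(1L, min(est) - 100L)
    w1 <- min(nchar(strain_seq), max(est) + Lp + 100L)
    s <- aligned_strings(align_deletion_scan(promoter_ref,
                                             substr(strain_seq, w0, w1),
                                             "global-local"))
  }
  runs <- gregexpr("-+", s$subject)[[1]]
  if (runs[1] == -1) return(0L)
  as.integer(max(attr(runs, "match.length")))
}

#' Diastase genotype from STA1 state and promoter deletion
#'
#' STA1-positive strains with an intact promoter are called
#' diastase-positive; a promoter deletion attenuates the phenotype.
#'
#' @param sta1_state marker state of STA1
#' @param promoter_deletion deletion length in bp
#' @return "diastase-positive", "weak/negative diastase" or "no STA1"
#' @export
diastase_genotype <- function(sta1_state, promoter_deletion) {
  dplyr::case_when(
    !sta1_state %in% c("present_intact", "present_inactivated") ~ "no STA1",
    promoter_deletion > 0 ~ "weak/negative diastase",
    TRUE ~ "diastase-positive"
  )
}

#' Match aquaporin lesions against known population signatures
#'
#' Aquaporin inactivation arose independently in different populations with
#' distinct lesions; a strain's observed lesion set is matched against a
#' signature table and labelled, or called "novel" when no type matches.
#' Premature stops must match at the codon; frameshifts at the signed
#' length with a positional tolerance (alignment gap placement can slide
#' inside repeats).
#'
#' @param lesions tibble of observed AQY lesions with a `marker` column
#' @param signatures signature table (see [default_aqy_signatures()])
#' @param pos_tol positional tolerance for frameshift matching (bp)
#' @return type label, "novel", or `NA` when no lesions are given
#' @export
aqy_type <- function(lesions, signatures, pos_tol = 15) {
  if (is.null(lesions) || nrow(lesions) == 0) return(NA_character_)
  for (t in unique(signatures$type)) {
    sig <- signatures[signatures$type == t, ]
    if (nrow(sig) != nrow(lesions)) next
    ok <- all(vapply(seq_len(nrow(sig)), function(i) {
      s <- sig[i, ]
      any(lesions$marker == s$marker & lesions$kind == s$kind &
            (if (s$kind == "premature_stop") lesions$codon == s$codon
             else lesions$len == s$len & abs(lesions$pos - s$pos) <= pos_tol))
    }, logical(1)))
    if (ok) return(t)
  }
  "novel"
}

#' Screen a strain panel for all catalog markers
#'
#' Runs [find_marker()] for every strain x marker, refines CDS presence
#' calls with [cds_integrity()], measures the STA1 promoter deletion for
#' STA1-positive strains, and flags divergent alleles (present but identity
#' below `divergent_below`).
#'
#' @param assemblies tibble with `strain`, `chrom`, `seq` (strain genomes;
#'   chromosomes are fused with an N spacer for the k-mer scan)
#' @param catalog placed marker catalog
#' @param k k-mer size
#' @param divergent_below identity threshold for the divergent-allele flag
#' @param mel_panel optional MEL allele reference panel; when given, every
#'   panel reference is used as an additional MEL query and the best hit
#'   kept (divergent allele groups share few exact k-mers with any single
#'   query, mirroring the use of MEL genes from two strains as search
#'   queries)
#' @return tibble: `strain`, `marker`, `state`, `kmer_fraction`,
#'   `identity`, `divergent`, `promoter_deletion` (STA1_promoter rows),
#'   `lesions` and `alignment` (list columns)
#' @export
screen_markers <- function(assemblies, catalog, k = 31,
                           divergent_below = 0.95, mel_panel = NULL) {
  spacer <- chars_seq(rep("N", k))
  strains <- unique(assemblies$strain)
  rows <- list()
  for (st in strains) {
    genome <- paste(assemblies$seq[assemblies$strain == st],
                    collapse = spacer)
    gk <- string_kmers(genome, k)
    sta1_row <- NULL
    for (i in seq_len(nrow(catalog))) {
      m <- catalog$marker[i]
      if (m == "STA1_promoter") next  # handled with STA1 below
      queries <- catalog$seq[i]
      if (m == "MEL" && !is.null(mel_panel))
        queries <- unique(c(queries, mel_panel$seq[!mel_panel$outgroup]))
      hits <- lapply(queries, function(q)
        find_marker(genome, q, k = k, genome_kmers = gk))
      hit <- hits[[which.max(vapply(hits, function(h) h$kmer_fraction,
                                    numeric(1)))]]
      state <- hit$state
      lesions <- tibble(kind = character(), pos = integer(),
                        len = integer(), codon = integer())
      if (catalog$kind[i] == "cds" && state == "present") {
        integ <- cds_integrity(hit$alignment[[1]])
        state <- integ$state
        lesions <- integ$lesions
      } else if (state == "present") {
        state <- "present_intact"
      }
      lesions$marker <- rep(m, nrow(lesions))
      rows[[length(rows) + 1L]] <- tibble(
        strain = st, marker = m, state = state,
        kmer_fraction = hit$kmer_fraction, identity = hit$identity,
        divergent = !is.na(hit$identity) & hit$identity < divergent_below &
          state != "absent",
        promoter_deletion = NA_integer_, lesions = list(lesions),
        alignment = hit$alignment
      )
      if (m == "STA1") sta1_row <- state
    }
    prom_ref <- catalog$seq[catalog$marker == "STA1_promoter"]
    if (!is.null(sta1_row) && sta1_row != "absent") {
      del <- sta1_promoter_scan(genome, prom_ref, k = k)
      prom_state <- if (is.na(del)) "partial"
                    else if (del > 0) "present_deleted" else "present_intact"
    } else {
      del <- NA_integer_
      prom_state <- "absent"
    }
    rows[[length(rows) + 1L]] <- tibble(
      strain = st, marker = "STA1_promoter", state = prom_state,
      kmer_fraction = NA_real_, identity = NA_real_, divergent = FALSE,
      promoter_deletion = del,
      lesions = list(tibble(kind = character(), pos = integer(),
                            len = integer(), codon = integer())),
      alignment = list(NULL)
    )
  }
  bind_rows(rows)
}

#' Aquaporin inactivation-type calls for a screened panel
#'
#' @param calls output of [screen_markers()]
#' @param signatures signature table
#' @return tibble `strain`, `aqy_type` (`NA` when both aquaporins are
#'   intact)
#' @export
aqy_type_calls <- function(calls, signatures = default_aqy_signatures()) {
  aqy <- filter(calls, .data$marker %in% c("AQY1", "AQY2"))
  aqy |>
    group_by(.data$strain) |>
    summarise(aqy_type = {
      les <- bind_rows(.data$lesions)
      aqy_type(les, signatures)
    }, .groups = "drop")
}
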