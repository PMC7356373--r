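# Shared fixtures, memoised so expensive panels are generated once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# default study panel, one strain per preset
shared_panel <- function() memo("panel1", simulate_panel(seed = 1))

# two strains per preset (for clade-recovery tests)
shared_panel2 <- function() {
  memo("panel2", simulate_panel(seed = 2, n_per_preset = 2))
}

shared_calls <- function() {
  memo("calls1", {
    p <- shared_panel()
    screen_markers(p$assemblies, p$catalog, mel_panel = p$mel_panel)
  })
}

shared_catalog <- function() memo("catalog", default_marker_catalog())

shared_mel_panel <- function() {
  memo("melpanel", make_mel_panel(shared_catalog(), seed = 7))
}

rand_dna_str <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# Independent per-column SNP scan used as the oracle for extract_snps:
# straightforward loops, no shared code with the implementation.
brute_force_snps <- function(consensus, min_frac) {
  strains <- unique(consensus$strain)
  out <- list()
  for (ch in unique(consensus$chrom)) {
    sub <- consensus[consensus$chrom == ch, ]
    sub <- sub[match(strains, sub$strain), ]
    L <- nchar(sub$seq[1])
    for (j in seq_len(L)) {
      calls <- substr(sub$seq, j, j)
      unamb <- calls[calls %in% c("A", "C", "G", "T")]
      if (length(unamb) / length(strains) >= min_frac - 1e-12 &&
          length(unique(unamb)) >= 2) {
        out[[length(out) + 1]] <- data.frame(chrom = ch, pos = j)
      }
    }
  }
  if (!length(out)) return(data.frame(chrom = character(), pos = integer()))
  do.call(rbind, out)
}

# random consensus panel with ambiguity and het codes, for oracle tests
random_panel <- function(n_strains, len, seed, p_n = 0.15, p_het = 0.1) {
  withr::with_seed(seed, {
    alphabet <- c("A", "C", "G", "T")
    rows <- lapply(seq_len(n_strains), function(i) {
      v <- sample(alphabet, len, replace = TRUE)
      amb <- runif(len) < p_n
      v[amb] <- "N"
      het <- runif(len) < p_het
      v[het] <- sample(c("M", "R", "W", "S", "Y", "K"), sum(het),
                       replace = TRUE)
      tibble::tibble(strain = sprintf("s%02d", i), chrom = "c1",
                     seq = paste(v, collapse = ""))
    })
    dplyr::bind_rows(rows)
  })
}

# phasing truth: n het sites with two distinct alleles each
random_het_truth <- function(n, seed) {
  withr::with_seed(seed, {
    alphabet <- c("A", "C", "G", "T")
    a0 <- sample(alphabet, n, replace = TRUE)
    a1 <- vapply(a0, function(b) sample(setdiff(alphabet, b), 1), "")
    swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
    tibble::tibble(site = seq_len(n), allele0 = a0, allele1 = a1,
                   hap1 = ifelse(swap, a1, a0),
                   hap2 = ifelse(swap, a0, a1))
  })
}
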