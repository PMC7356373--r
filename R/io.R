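#' Read / write FASTA
#'
#' 60-column FASTA via the standard sequence machinery.
#'
#' @param x named character vector of sequences
#' @param path file path
#' @return `read_fasta` returns a named character vector
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(ss, path, width = 60)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) abort(sprintf("no records in %s", path))
  setNames(as.character(ss), names(ss))
}

#' Write a consensus panel as FASTA plus FASTQ-style quality
#'
#' Consensus sequences go to `<stem>.fasta` (records named
#' `strain|chrom`); quality strings, when present, to `<stem>.fastq`
#' (Phred+33).
#'
#' @param consensus consensus tibble
#' @param stem output path stem
#' @export
write_consensus <- function(consensus, stem) {
  nm <- paste(consensus$strain, consensus$chrom, sep = "|")
  write_fasta(setNames(consensus$seq, nm), paste0(stem, ".fasta"))
  if ("qual" %in% names(consensus) && !anyNA(consensus$qual)) {
    con <- file(paste0(stem, ".fastq"), "w")
    on.exit(close(con))
    for (i in seq_len(nrow(consensus)))
      writeLines(c(paste0("@", nm[i]), consensus$seq[i], "+",
                   consensus$qual[i]), con)
  }
  invisible(stem)
}

#' @rdname write_consensus
#' @param path FASTQ path
#' @export
read_consensus_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) abort(sprintf("truncated FASTQ: %s", path))
  ids <- sub("^@", "", lines[seq(1, length(lines), 4)])
  parts <- strsplit(ids, "|", fixed = TRUE)
  tibble(
    strain = map_chr(parts, 1), chrom = map_chr(parts, 2),
    seq = lines[seq(2, length(lines), 4)],
    qual = lines[seq(4, length(lines), 4)]
  )
}

#' Read / write per-base coverage tracks as TSV
#'
#' Long format: `strain`, `chrom`, `pos` (1-based), `depth`; header line
#' starts with '#'.
#'
#' @param coverage coverage tibble with `depth` list column
#' @param path file path
#' @export
write_coverage <- function(coverage, path) {
  long <- coverage |>
    mutate(pos = map(.data$depth, seq_along)) |>
    tidyr::unnest(c("pos", "depth"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#strain\tchrom\tpos\tdepth", con)
  utils::write.table(long[, c("strain", "chrom", "pos", "depth")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                         col.names = c("strain", "chrom", "pos", "depth"))
  d |>
    as_tibble() |>
    arrange(.data$strain, .data$chrom, .data$pos) |>
    group_by(.data$strain, .data$chrom) |>
    summarise(depth = list(.data$depth), .groups = "drop")
}

#' Write a tab-separated table with a '#'-prefixed header
#' @param x data frame (list columns are dropped with a message)
#' @param path file path
#' @export
write_tsv_table <- function(x, path) {
  is_list <- vapply(x, is.list, logical(1))
  x <- x[!is_list]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(x), collapse = "\t")), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1))
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         comment.char = "#", stringsAsFactors = FALSE)
  names(d) <- strsplit(header, "\t", fixed = TRUE)[[1]]
  as_tibble(d)
}

#' @export
print.domestiscan_panel <- function(x, ...) {
  cat(sprintf(
    "<domestiscan_panel> %d strains, %d chromosome(s) of %s bp (seed %d)\n",
    nrow(x$truth), nrow(x$reference),
    format(nchar(x$reference$seq[1]), big.mark = ","), x$params$seed))
  cat("presets:", paste(unique(x$truth$preset), collapse = ", "), "\n")
  invisible(x)
}

#' Run the full pipeline on a simulated panel
#'
#' Executes simulate -> mask -> SNP matrix -> phasing selection -> tree ->
#' marker screen -> copy number -> MEL typing -> lifestyle classification,
#' and returns every intermediate plus the final per-strain report. Rerun
#' with the same config, the result is byte-identical.
#'
#' @param seed integer seed driving every stochastic stage
#' @param presets preset tibble
#' @param n_per_preset strains per preset
#' @param min_frac SNP-matrix unambiguity fraction (default 0.85)
#' @param q_threshold masking threshold (default Q40)
#' @param min_het_sites phasing selection threshold (default 20,000)
#' @param bootstrap_replicates tree bootstrap replicates
#' @param out_dir optional directory to write report files into
#' @param ... further arguments to [simulate_panel()]
#' @return list with `panel`, `snp`, `alignment`, `tree`, `calls`, `aqy`,
#'   `copy_numbers`, `mel`, `profiles`, `lifestyle`, `report`
#' @export
run_all <- function(seed = 1, presets = default_presets(),
                    n_per_preset = 1, min_frac = 0.85, q_threshold = 40,
                    min_het_sites = 20000, bootstrap_replicates = 100,
                    out_dir = NULL, ...) {
  panel <- simulate_panel(presets, n_per_preset, seed = seed, ...)
  masked <- mask_consensus(panel$consensus, q_threshold)
  snp <- extract_snps(masked, min_frac)
  conc <- concat_snp_alignment(snp)
  selection <- select_for_phasing(masked, min_het_sites, q_threshold)
  ploidy <- flag_het_excess(masked, q_threshold = q_threshold)
  boot <- bootstrap_support(conc$alignment, metric = "p",
                            replicates = bootstrap_replicates, seed = seed)
  calls <- screen_markers(panel$assemblies, panel$catalog,
                          mel_panel = panel$mel_panel)
  aqy <- aqy_type_calls(calls, default_aqy_signatures(panel$catalog))
  cn <- copy_number(panel$coverage,
                    catalog_gene_intervals(panel$catalog, "MEL"))
  mel <- mel_typing(calls, panel$mel_panel)
  niche <- select(panel$truth, "strain", "niche")
  profiles <- profile_panel(calls, aqy, cn, mel, ploidy, niche)
  lifestyle <- classify_lifestyle(profiles)
  report <- profiles |>
    left_join(lifestyle, by = "strain") |>
    left_join(select(panel$truth, "strain", "preset",
                     truth_lifestyle = "lifestyle"), by = "strain")
  res <- list(panel = panel, snp = snp, alignment = conc,
              selection = selection, tree = boot, calls = calls,
              aqy = aqy, copy_numbers = cn, mel = mel,
              profiles = profiles, lifestyle = lifestyle, report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(conc$alignment, file.path(out_dir, "snp_alignment.fasta"))
    write_tsv_table(conc$column_map, file.path(out_dir, "column_map.tsv"))
    write_newick(boot$tree, file.path(out_dir, "tree.nwk"))
    write_tsv_table(cn, file.path(out_dir, "copy_number.tsv"))
    write_tsv_table(select(calls, -"lesions", -"alignment"),
                    file.path(out_dir, "marker_calls.tsv"))
    jsonlite::write_json(
      report, file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  res
}
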