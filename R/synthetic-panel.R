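# Fixed seeds for the shared lesion definitions, so that independently
# constructed signature tables reproduce the exact lesions the generator
# placed (the same inactivation type is shared across populations).
AQY_TYPE_LESIONS <- list(
  wine = list(
    AQY1 = list(kind = "premature_stop", seed = 501L),
    AQY2 = list(kind = "frameshift",     seed = 502L)
  ),
  sake = list(
    AQY1 = list(kind = "frameshift",     seed = 503L),
    AQY2 = list(kind = "premature_stop", seed = 504L)
  ),
  malaysia = list(  # wild high-sugar type; deliberately absent from the
    AQY1 = list(kind = "premature_stop", seed = 505L),  # known-type table
    AQY2 = list(kind = "premature_stop", seed = 506L)
  )
)

SUC2_STOP_SEED <- 601L
STA1_DEL_SEED  <- 603L

#' Construct a population preset
#'
#' A preset bundles the genomic state of one synthetic population: SNP
#' divergence from the reference backbone, genome-wide heterozygous-site
#' count, domestication-marker states, STA1 promoter state, MEL allele group
#' and copy number, and the true lifestyle label used in recovery tests.
#'
#' @param name preset label
#' @param lifestyle truth label: "wild", "domesticated" or "feral"
#' @param niche isolation niche: "arboreal_low_sugar", "high_sugar",
#'   "fermentation" or "unknown"
#' @param snp_divergence substitutions/site from the reference, in (0, 0.05]
#' @param het_sites heterozygous sites per genome (absolute count)
#' @param aqy_type aquaporin inactivation type (`NA` = intact); one of
#'   `names(AQY_TYPE_LESIONS)`
#' @param suc2 "intact" or "premature_stop"
#' @param sta1 "absent" or "present"
#' @param sta1_promoter "intact" or "deletion_1162" (only if STA1 present)
#' @param rtm1,bio "present" or "absent" (BIO covers BIO1 and BIO6)
#' @param mel_group MEL allele group label or `NA` (no MEL gene)
#' @param mel_copies integer vector of per-strain MEL copy numbers, recycled
#'   across the preset's strains; must be 0 exactly when `mel_group` is `NA`
#' @param region_a,region_b,region_c logical presence of the horizontally
#'   acquired regions
#' @return one-row tibble
#' @export
population_preset <- function(name, lifestyle, niche, snp_divergence,
                              het_sites, aqy_type = NA_character_,
                              suc2 = "intact", sta1 = "absent",
                              sta1_promoter = "intact",
                              rtm1 = "absent", bio = "absent",
                              mel_group = NA_character_, mel_copies = 0L,
                              region_a = FALSE, region_b = FALSE,
                              region_c = FALSE) {
  if (snp_divergence <= 0 || snp_divergence > 0.05)
    abort("snp_divergence must be in (0, 0.05]")
  if (het_sites < 0) abort("het_sites must be >= 0")
  if (is.na(mel_group) && any(mel_copies != 0))
    abort("mel_copies must be 0 when mel_group is NA")
  if (!is.na(mel_group) && any(mel_copies < 1))
    abort("mel_copies must be >= 1 when mel_group is set")
  tibble(
    preset = name,
    lifestyle = match.arg(lifestyle, c("wild", "domesticated", "feral")),
    niche = match.arg(niche, c("arboreal_low_sugar", "high_sugar",
                               "fermentation", "unknown")),
    snp_divergence = snp_divergence, het_sites = as.integer(het_sites),
    aqy_type = aqy_type, suc2 = suc2, sta1 = sta1,
    sta1_promoter = sta1_promoter, rtm1 = rtm1, bio = bio,
    mel_group = mel_group, mel_copies = list(as.integer(mel_copies)),
    region_a = region_a, region_b = region_b, region_c = region_c
  )
}

#' Default synthetic study panel
#'
#' Eight populations mirroring the published clade descriptions: wine (all
#' three horizontally acquired regions, wine-type aquaporin inactivation),
#' olives (SUC2 premature stop, European MEL allele at 4-11 copies), two
#' beer-2 presets (STA1-positive with intact vs 1162-bp-deleted promoter,
#' the promoter-deleted one with a >2n heterozygosity excess), sake (RTM1 +
#' BIO1/BIO6, Asian I MEL), a feral arboreal population carrying region B
#' and a wine-type aquaporin lesion, a wild arboreal population with no
#' signatures, and a wild high-sugar population whose aquaporin lesion is of
#' a type private to it.
#'
#' @return tibble of presets, one row per population
#' @export
default_presets <- function() {
  bind_rows(
    population_preset("wine_main", "domesticated", "fermentation",
      snp_divergence = 0.012, het_sites = 2000, aqy_type = "wine",
      region_a = TRUE, region_b = TRUE, region_c = TRUE),
    population_preset("olives", "domesticated", "fermentation",
      snp_divergence = 0.013, het_sites = 2000, aqy_type = "wine",
      suc2 = "premature_stop", mel_group = "European",
      mel_copies = c(4L, 5L, 6L, 10L, 11L)),
    population_preset("beer2_sta1_weak", "domesticated", "fermentation",
      snp_divergence = 0.010, het_sites = 25000, aqy_type = "wine",
      sta1 = "present", sta1_promoter = "deletion_1162",
      rtm1 = "present", bio = "present", region_b = TRUE),
    population_preset("beer2_sta1_active", "domesticated", "fermentation",
      snp_divergence = 0.010, het_sites = 2000, aqy_type = "wine",
      sta1 = "present", sta1_promoter = "intact",
      rtm1 = "present", region_b = TRUE),
    population_preset("sake", "domesticated", "fermentation",
      snp_divergence = 0.015, het_sites = 2000, aqy_type = "sake",
      rtm1 = "present", bio = "present",
      mel_group = "Asian I", mel_copies = 1L),
    population_preset("china_viii_feral", "feral", "arboreal_low_sugar",
      snp_divergence = 0.020, het_sites = 2000, aqy_type = "wine",
      region_b = TRUE),
    population_preset("china_wild", "wild", "arboreal_low_sugar",
      snp_divergence = 0.025, het_sites = 1000),
    population_preset("malaysia_wild", "wild", "high_sugar",
      snp_divergence = 0.022, het_sites = 1000, aqy_type = "malaysia",
      mel_group = "Asian I", mel_copies = 1L)
  )
}

# Lesioned marker copies shared across strains; deterministic via the fixed
# lesion seeds above.
build_marker_variants <- function(catalog) {
  get_seq <- function(m) catalog$seq[catalog$marker == m]
  aqy <- lapply(AQY_TYPE_LESIONS, function(type) {
    lapply(names(type), function(m) {
      l <- type[[m]]
      res <- apply_lesion(get_seq(m), l$kind, seed = l$seed)
      res$lesion$marker <- m
      res
    }) |> setNames(names(type))
  })
  suc2_stop <- apply_lesion(get_seq("SUC2"), "premature_stop",
                            seed = SUC2_STOP_SEED)
  sta1_prom_del <- apply_lesion(get_seq("STA1_promoter"), "promoter_deletion",
                                seed = STA1_DEL_SEED, deletion_len = 1162L)
  list(aqy = aqy, suc2_stop = suc2_stop, sta1_prom_del = sta1_prom_del)
}

#' Known aquaporin inactivation signatures
#'
#' The lesion sets characteristic of domesticated populations, against which
#' [aqy_type()] matches observed lesions. The wild high-sugar type is
#' deliberately not listed: it must come out as "novel".
#'
#' @param catalog marker catalog (for the reference gene sequences)
#' @return tibble with columns `type`, `marker`, `kind`, `pos`, `len`, `codon`
#' @export
default_aqy_signatures <- function(catalog = default_marker_catalog()) {
  mv <- build_marker_variants(catalog)
  known <- c("wine", "sake")
  bind_rows(lapply(known, function(t) {
    bind_rows(lapply(mv$aqy[[t]], function(x) x$lesion)) |>
      mutate(type = t)
  })) |>
    select("type", "marker", "kind", "pos", "len", "codon")
}

#' Simulate a strain panel with truth tables
#'
#' Generates, for every preset x replicate combination: two haplotypes on
#' reference coordinates, an IUPAC-encoded consensus with per-base quality
#' strings, an assembly (the actual strain genome, in which length-changing
#' lesions such as the STA1 promoter deletion are physically present), a
#' per-base coverage track whose depth over the MEL locus scales with the
#' true copy number, and a truth table recording every planted state.
#'
#' @param presets preset tibble (see [population_preset()])
#' @param n_per_preset strains per preset
#' @param seed integer seed; fixed seed gives byte-identical output
#' @param chrom_len reference chromosome length (bp); the default is large
#'   enough that absent-marker loci (zero coverage) stay a small fraction
#'   of nuclear positions, keeping the genome-median depth unbiased
#' @param n_chrom number of chromosomes (markers are placed on chromosome 1)
#' @param gc reference GC fraction
#' @param depth mean sequencing depth for the coverage simulation
#' @param read_len read length used to place coverage-generating reads
#' @param frac_below_q40 fraction of consensus bases given quality < Q40
#' @param catalog marker catalog
#' @param mel_panel MEL allele reference panel (see [make_mel_panel()])
#' @return object of class `domestiscan_panel`: a list with `reference`,
#'   `catalog`, `consensus`, `assemblies`, `haplotypes`, `coverage`,
#'   `truth`, `variants`, `mel_panel`, `params`
#' @export
simulate_panel <- function(presets = default_presets(), n_per_preset = 1,
                           seed = 1, chrom_len = 250000L, n_chrom = 1L,
                           gc = 0.38, depth = 50, read_len = 150L,
                           frac_below_q40 = 0.02,
                           catalog = default_marker_catalog(),
                           mel_panel = NULL) {
  if (nrow(presets) == 0) abort("presets must be non-empty")
  bad <- setdiff(presets$mel_group[!is.na(presets$mel_group)],
                 c("Asian I", "Asian II", "Asian-American", "European",
                   "African I", "African II", "South American"))
  if (length(bad))
    abort(paste("preset references unknown MEL group:", bad[1]))
  ref0 <- make_reference(n_chrom, chrom_len, gc, seed = seed + 7L)
  placed <- place_catalog(ref0, catalog)
  reference <- placed$reference
  catalog <- placed$catalog
  if (is.null(mel_panel))
    mel_panel <- make_mel_panel(catalog, seed = seed + 13L)
  mv <- build_marker_variants(catalog)

  chrom1 <- reference$chrom[1]
  refv <- lapply(reference$seq, seq_chars)
  names(refv) <- reference$chrom
  L1 <- length(refv[[chrom1]])

  # variant-eligible positions: outside marker loci (with margin)
  occupied <- unlist(lapply(seq_len(nrow(catalog)), function(i)
    seq(max(1, catalog$start[i] - 50), min(L1, catalog$end[i] + 50))))
  eligible <- list()
  eligible[[chrom1]] <- setdiff(seq_len(L1), occupied)
  for (ch in setdiff(reference$chrom, chrom1))
    eligible[[ch]] <- seq_along(refv[[ch]])
  genome_len <- sum(nchar(reference$seq))

  mel_iv <- catalog[catalog$marker == "MEL", ]

  withr::with_seed(seed, {
    # per-preset SNP backbones
    backbones <- lapply(seq_len(nrow(presets)), function(i) {
      n_var <- round(presets$snp_divergence[i] * genome_len)
      lapply(reference$chrom, function(ch) {
        share <- length(eligible[[ch]]) / sum(lengths(eligible))
        pos <- sort(sample(eligible[[ch]], round(n_var * share)))
        tibble(chrom = ch, pos = pos,
               ref = refv[[ch]][pos], alt = mutate_base(refv[[ch]][pos]))
      }) |> bind_rows()
    })

    out_cons <- list(); out_asm <- list(); out_hap <- list()
    out_cov <- list(); out_truth <- list(); out_var <- list()
    row <- 0L
    for (i in seq_len(nrow(presets))) {
      p <- presets[i, ]
      copies <- rep(p$mel_copies[[1]], length.out = n_per_preset)
      for (j in seq_len(n_per_preset)) {
        row <- row + 1L
        strain <- sprintf("%s_%d", p$preset, j)
        st <- build_strain(p, strain, copies[j], backbones[[i]], refv,
                           eligible, catalog, mv, mel_panel,
                           frac_below_q40)
        cov <- simulate_coverage(st, refv, catalog, mel_iv,
                                 copies[j], depth, read_len)
        out_cons[[row]] <- st$consensus
        out_asm[[row]] <- st$assembly
        out_hap[[row]] <- st$haplotypes
        out_var[[row]] <- st$variants
        out_cov[[row]] <- cov
        out_truth[[row]] <- mutate(st$truth, mel_copy_number = copies[j])
      }
    }
    structure(list(
      reference = reference, catalog = catalog,
      consensus = bind_rows(out_cons), assemblies = bind_rows(out_asm),
      haplotypes = bind_rows(out_hap), coverage = bind_rows(out_cov),
      truth = bind_rows(out_truth), variants = bind_rows(out_var),
      mel_panel = mel_panel,
      params = list(seed = seed, depth = depth, read_len = read_len,
                    frac_below_q40 = frac_below_q40)
    ), class = "domestiscan_panel")
  })
}

# One strain: haplotypes/consensus/assembly/variants/truth. Runs inside the
# panel's seeded RNG scope.
build_strain <- function(p, strain, mel_cn, backbone, refv, eligible,
                         catalog, mv, mel_panel, frac_below_q40) {
  chrom1 <- names(refv)[1]
  iv <- function(m) {
    r <- catalog[catalog$marker == m, ]
    c(r$start, r$end)
  }
  cat_seq <- function(m) catalog$seq[catalog$marker == m]

  # --- marker plan -----------------------------------------------------
  # each entry: marker, state, cons_seq (ref-coord, same length or NULL->N),
  # asm_seq (may change length)
  plan <- list()
  add <- function(m, state, cons_seq, asm_seq) {
    plan[[m]] <<- list(marker = m, state = state, cons = cons_seq,
                       asm = asm_seq)
  }
  for (rg in c("region_A", "region_B", "region_C")) {
    fld <- tolower(sub("region_", "region_", rg))
    present <- p[[tolower(rg)]]
    if (present) add(rg, "present_intact", cat_seq(rg), cat_seq(rg))
    else add(rg, "absent", NULL, NULL)
  }
  if (is.na(p$aqy_type)) {
    add("AQY1", "present_intact", cat_seq("AQY1"), cat_seq("AQY1"))
    add("AQY2", "present_intact", cat_seq("AQY2"), cat_seq("AQY2"))
  } else {
    les <- mv$aqy[[p$aqy_type]]
    for (m in c("AQY1", "AQY2")) {
      s <- les[[m]]$seq
      # frameshifts change length: consensus keeps the intact allele (the
      # lesion lives in the assembly, where the screen operates)
      cons <- if (nchar(s) == nchar(cat_seq(m))) s else cat_seq(m)
      add(m, "present_inactivated", cons, s)
    }
  }
  if (p$suc2 == "premature_stop")
    add("SUC2", "present_inactivated", mv$suc2_stop$seq, mv$suc2_stop$seq)
  else add("SUC2", "present_intact", cat_seq("SUC2"), cat_seq("SUC2"))
  add("RTM1", if (p$rtm1 == "present") "present_intact" else "absent",
      if (p$rtm1 == "present") cat_seq("RTM1") else NULL,
      if (p$rtm1 == "present") cat_seq("RTM1") else NULL)
  for (m in c("BIO1", "BIO6"))
    add(m, if (p$bio == "present") "present_intact" else "absent",
        if (p$bio == "present") cat_seq(m) else NULL,
        if (p$bio == "present") cat_seq(m) else NULL)
  if (p$sta1 == "present") {
    add("STA1", "present_intact", cat_seq("STA1"), cat_seq("STA1"))
    if (p$sta1_promoter == "deletion_1162")
      add("STA1_promoter", "present_deleted", cat_seq("STA1_promoter"),
          mv$sta1_prom_del$seq)
    else
      add("STA1_promoter", "present_intact", cat_seq("STA1_promoter"),
          cat_seq("STA1_promoter"))
  } else {
    add("STA1", "absent", NULL, NULL)
    add("STA1_promoter", "absent", NULL, NULL)
  }
  if (!is.na(p$mel_group)) {
    grp_ref <- mel_panel$seq[mel_panel$group == p$mel_group][1]
    mel_seq <- mutate_cds(grp_ref, 0.01)
    add("MEL", "present_intact", mel_seq, mel_seq)
  } else add("MEL", "absent", NULL, NULL)

  # --- substitution variants ------------------------------------------
  keep <- runif(nrow(backbone)) < 0.95
  own <- backbone[keep, ]
  n_priv <- round(0.02 * nrow(backbone))
  priv_pool <- setdiff(eligible[[chrom1]], backbone$pos[backbone$chrom == chrom1])
  if (n_priv > 0) {
    pp <- sort(sample(priv_pool, n_priv))
    own <- bind_rows(own, tibble(chrom = chrom1, pos = pp,
                                 ref = refv[[chrom1]][pp],
                                 alt = mutate_base(refv[[chrom1]][pp])))
  }
  own <- arrange(own, .data$chrom, .data$pos)

  het_pool <- setdiff(priv_pool, own$pos[own$chrom == chrom1])
  n_het <- min(p$het_sites, length(het_pool))
  het_pos <- sort(sample(het_pool, n_het))

  # --- haplotype construction (reference coordinates) ------------------
  haps <- list()
  for (ch in names(refv)) {
    h1 <- refv[[ch]]; h2 <- refv[[ch]]
    ovn <- own[own$chrom == ch, ]
    h1[ovn$pos] <- ovn$alt; h2[ovn$pos] <- ovn$alt
    if (ch == chrom1) {
      alt_het <- mutate_base(refv[[ch]][het_pos])
      on_h1 <- runif(n_het) < 0.5
      h1[het_pos[on_h1]] <- alt_het[on_h1]
      h2[het_pos[!on_h1]] <- alt_het[!on_h1]
      # marker loci: substitution-level content on both haplotypes
      for (pl in plan) {
        r <- iv(pl$marker)
        if (is.null(pl$cons)) {
          h1[r[1]:r[2]] <- "N"; h2[r[1]:r[2]] <- "N"
        } else {
          mseq <- seq_chars(pl$cons)
          h1[r[1]:r[2]] <- mseq; h2[r[1]:r[2]] <- mseq
        }
      }
    }
    haps[[ch]] <- list(h1 = h1, h2 = h2)
  }

  # --- consensus + quality --------------------------------------------
  cons_rows <- list(); hap_rows <- list(); var_rows <- list()
  for (ch in names(refv)) {
    h1 <- haps[[ch]]$h1; h2 <- haps[[ch]]$h2
    cons <- ifelse(h1 == h2, h1, iupac_encode(h1, h2))
    qual <- rep(45L, length(cons))
    n_low <- round(frac_below_q40 * length(cons))
    if (n_low > 0) {
      low <- sample(length(cons), n_low)
      qual[low] <- sample(2:39, n_low, replace = TRUE)
    }
    cons_rows[[ch]] <- tibble(strain = strain, chrom = ch,
                              seq = chars_seq(cons),
                              qual = int_to_phred(qual))
    hap_rows[[ch]] <- tibble(strain = strain, chrom = ch,
                             hap = c(1L, 2L),
                             seq = c(chars_seq(h1), chars_seq(h2)))
    d <- which(h1 != refv[[ch]] | h2 != refv[[ch]])
    var_rows[[ch]] <- tibble(strain = strain, chrom = ch, pos = d,
                             ref = refv[[ch]][d], hap1 = h1[d], hap2 = h2[d])
  }

  # --- assembly (length-changing lesions physically applied) -----------
  asm_rows <- list()
  for (ch in names(refv)) {
    if (ch != chrom1) {
      asm_rows[[ch]] <- tibble(strain = strain, chrom = ch,
                               seq = hap_rows[[ch]]$seq[1])
      next
    }
    base <- haps[[ch]]$h1
    edits <- lapply(plan, function(pl) {
      r <- iv(pl$marker)
      repl <- if (is.null(pl$asm)) random_dna(r[2] - r[1] + 1) else pl$asm
      list(start = r[1], end = r[2], repl = repl)
    })
    edits <- edits[order(vapply(edits, `[[`, numeric(1), "start"))]
    pieces <- character(0); cur <- 1
    for (e in edits) {
      if (e$start > cur)
        pieces <- c(pieces, chars_seq(base[cur:(e$start - 1)]))
      pieces <- c(pieces, e$repl)
      cur <- e$end + 1
    }
    if (cur <= length(base))
      pieces <- c(pieces, chars_seq(base[cur:length(base)]))
    asm_rows[[ch]] <- tibble(strain = strain, chrom = ch,
                             seq = paste(pieces, collapse = ""))
  }

  states <- vapply(plan, `[[`, character(1), "state")
  truth <- tibble(
    strain = strain, preset = p$preset, lifestyle = p$lifestyle,
    niche = p$niche, snp_divergence = p$snp_divergence,
    het_sites = n_het,
    ploidy = if (n_het > 20000) ">2n" else "2n",
    aqy_type = p$aqy_type,
    aqy1 = states[["AQY1"]], aqy2 = states[["AQY2"]],
    suc2 = states[["SUC2"]], rtm1 = states[["RTM1"]],
    bio1 = states[["BIO1"]], bio6 = states[["BIO6"]],
    sta1 = states[["STA1"]],
    sta1_promoter_deletion =
      if (p$sta1 == "present" && p$sta1_promoter == "deletion_1162")
        1162L else 0L,
    region_a = states[["region_A"]], region_b = states[["region_B"]],
    region_c = states[["region_C"]],
    mel = states[["MEL"]], mel_group = p$mel_group
  )
  list(consensus = bind_rows(cons_rows), assembly = bind_rows(asm_rows),
       haplotypes = bind_rows(hap_rows), variants = bind_rows(var_rows),
       truth = truth)
}

#' Simulate a coverage track for one gene at a known multiplicity
#'
#' Stand-alone generator for copy-number recovery studies: places reads
#' uniformly at Poisson-distributed count over a genome of `genome_len` bp,
#' boosts depth over the gene interval to `multiplicity` times the genome
#' depth (reads from the extra copies all map onto the single reference
#' locus), and returns a coverage tibble ready for [copy_number()].
#'
#' @param genome_len genome length in bp
#' @param gene_start,gene_end gene interval (1-based inclusive)
#' @param multiplicity true gene copy number (>= 0; 0 = gene absent)
#' @param depth mean genome depth
#' @param read_len read length
#' @param seed integer seed
#' @param strain strain label for the output
#' @return coverage tibble (`strain`, `chrom`, `depth` list column)
#' @export
simulate_gene_coverage <- function(genome_len, gene_start, gene_end,
                                   multiplicity, depth = 50,
                                   read_len = 150L, seed = 1,
                                   strain = "sim") {
  if (gene_end <= gene_start || gene_start < 1 || gene_end > genome_len)
    abort("invalid gene interval")
  withr::with_seed(seed, {
    n_reads <- rpois(1, depth * genome_len / read_len)
    starts <- sample.int(genome_len - read_len + 1L, n_reads, replace = TRUE)
    if (multiplicity == 0) {
      drop <- starts > gene_start - read_len & starts <= gene_end
      starts <- starts[!drop]
    } else if (multiplicity > 1) {
      w0 <- max(1L, gene_start - read_len + 1L)
      w1 <- gene_end
      n_extra <- rpois(1, (multiplicity - 1) * depth * (w1 - w0 + 1L) /
                         read_len)
      starts <- c(starts, sample(w0:w1, n_extra, replace = TRUE))
    }
    tibble(strain = strain, chrom = "chr01",
           depth = list(coverage_from_starts(starts, read_len, genome_len)))
  })
}

MARKER_TRUTH_COLUMN <- c(
  AQY1 = "aqy1", AQY2 = "aqy2", SUC2 = "suc2", RTM1 = "rtm1",
  BIO1 = "bio1", BIO6 = "bio6", STA1 = "sta1", STA1_promoter = "sta1",
  region_A = "region_a", region_B = "region_b", region_C = "region_c",
  MEL = "mel"
)

# Uniform read placement at Poisson-distributed count; depth over the MEL
# locus is boosted to copy_number x genome depth (reads from the extra
# copies all map onto the single reference locus); absent loci get zero
# covering reads. Runs inside the panel's seeded RNG scope.
simulate_coverage <- function(st, refv, catalog, mel_iv, mel_cn, depth,
                              read_len) {
  strain <- st$truth$strain
  chrom1 <- names(refv)[1]
  absent_iv <- catalog[
    vapply(catalog$marker, function(m)
      st$truth[[MARKER_TRUTH_COLUMN[[m]]]] == "absent", logical(1)), ]
  rows <- list()
  for (ch in names(refv)) {
    L <- length(refv[[ch]])
    n_reads <- rpois(1, depth * L / read_len)
    starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
    if (ch == chrom1 && nrow(absent_iv) > 0) {
      drop <- rep(FALSE, length(starts))
      for (k in seq_len(nrow(absent_iv)))
        drop <- drop | (starts > absent_iv$start[k] - read_len &
                          starts <= absent_iv$end[k])
      starts <- starts[!drop]
    }
    if (ch == chrom1 && mel_cn > 1) {
      w0 <- mel_iv$start - read_len + 1L
      w1 <- mel_iv$end
      n_extra <- rpois(1, (mel_cn - 1) * depth * (w1 - w0 + 1L) / read_len)
      starts <- c(starts, sample(w0:w1, n_extra, replace = TRUE))
    }
    cov <- coverage_from_starts(starts, read_len, L)
    rows[[length(rows) + 1L]] <- tibble(strain = strain, chrom = ch,
                                        depth = list(cov))
  }
  bind_rows(rows)
}

coverage_from_starts <- function(starts, read_len, L) {
  d <- integer(L + 1L)
  tab <- tabulate(starts, nbins = L)
  ends <- pmin(starts + read_len, L + 1L)
  tab_end <- tabulate(ends, nbins = L + 1L)
  d[seq_len(L)] <- tab
  d <- d - tab_end
  head(cumsum(d), L)
}
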