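# Seed-controlled generators for panels, catalogues, reads, call sets and
# cohorts. Everything is a pure function of (config, seed): fixed seed gives
# byte-identical output, so planted defects can be checked oracle-exactly.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Defaults emulate a 33-gene amplicon panel sequenced with 2x301 bp
#' paired-end reads: 425 bp amplicons tiling each gene body with 50 bp
#' overlap (ten amplicons per six-exon gene), a 1207-variant known-mutation
#' catalogue with the class mix 87% missense / 4% simple insertions / 8%
#' deletions / 1% complex indels, per-amplicon read yield with occasional
#' total dropout, and forward/reverse reads anchored at opposite amplicon
#' ends so that the centre is covered by both mates and the flanks by one —
#' the geometry that makes mean amplicon coverage mask low flanks.
#'
#' @param seed integer seed; every generator derives its randomness from it.
#' @param n_genes,exons_per_gene,exon_length,intron_length,gene_gap panel
#'   geometry in bases.
#' @param amplicon_length,amplicon_overlap amplicon tiling (overlap must be
#'   smaller than length).
#' @param read_length read length in bases (default 301).
#' @param mean_read_pairs mean read pairs per surviving amplicon.
#' @param dropout_prob probability an amplicon yields no reads at all.
#' @param strand_balance probability a read is forward (anchored at the
#'   amplicon 5' end) rather than reverse (anchored at the 3' end).
#' @param catalogue_size number of catalogue variants.
#' @param class_mix named fractions over variant classes, summing to 1.
#' @param exact_mix if `TRUE` (default) class counts are the
#'   largest-remainder rounding of `catalogue_size * class_mix` (exact,
#'   deterministic); if `FALSE` classes are drawn multinomially.
#' @param splice_site_fraction fraction of variants placed on the
#'   near-intronic side of an exon boundary and classed `splice`.
#' @param pathogenic_fraction fraction of catalogue variants flagged
#'   pathogenic.
#' @param n_decoys decoy calls emitted by [make_callset()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_genes = 33, exons_per_gene = 6,
                       exon_length = 300, intron_length = 400,
                       gene_gap = 10000, amplicon_length = 425,
                       amplicon_overlap = 50, read_length = 301,
                       mean_read_pairs = 40, dropout_prob = 0.02,
                       strand_balance = 0.5, catalogue_size = 1207,
                       class_mix = c(missense = 0.87,
                                     simple_insertion = 0.04,
                                     deletion = 0.08,
                                     complex_indel = 0.01),
                       exact_mix = TRUE, splice_site_fraction = 0,
                       pathogenic_fraction = 0.9, n_decoys = 0) {
  assert_that(amplicon_overlap < amplicon_length,
              "amplicon overlap must be smaller than amplicon length")
  assert_that(abs(sum(class_mix) - 1) < 1e-9, "class_mix must sum to 1")
  assert_that(dropout_prob >= 0 && dropout_prob <= 1 &&
                strand_balance >= 0 && strand_balance <= 1 &&
                splice_site_fraction >= 0 && splice_site_fraction <= 1,
              "probabilities must lie in [0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic panel manifest
#'
#' Genes are laid head-to-tail on one chromosome, each a run of equal
#' exons separated by equal introns; amplicons tile each gene body
#' end-to-end with the configured overlap. Purely geometric, hence
#' trivially deterministic.
#'
#' @param cfg a [sim_config()].
#' @return a [panel_manifest()].
#' @export
make_panel <- function(cfg) {
  span <- cfg$exons_per_gene * cfg$exon_length +
    (cfg$exons_per_gene - 1) * cfg$intron_length
  step <- cfg$amplicon_length - cfg$amplicon_overlap
  n_amp <- ceiling(max(0, span - cfg$amplicon_length) / step) + 1L
  genes <- list(); amps <- list()
  for (g in seq_len(cfg$n_genes)) {
    sym <- sprintf("G%02d", g)
    gstart <- 1000L + (g - 1L) * (span + cfg$gene_gap)
    ex_start <- gstart + (seq_len(cfg$exons_per_gene) - 1L) *
      (cfg$exon_length + cfg$intron_length)
    genes[[g]] <- data.frame(gene = sym, chrom = "chr1", start = ex_start,
                             end = ex_start + cfg$exon_length,
                             exon = seq_len(cfg$exons_per_gene),
                             strand = "+", stringsAsFactors = FALSE)
    astart <- gstart + (seq_len(n_amp) - 1L) * step
    amps[[g]] <- data.frame(amplicon_id = sprintf("%s_amp%02d", sym,
                                                  seq_len(n_amp)),
                            chrom = "chr1", start = astart,
                            end = astart + cfg$amplicon_length, gene = sym,
                            stringsAsFactors = FALSE)
  }
  panel_manifest("synthetic_panel", do.call(rbind, genes),
                 do.call(rbind, amps))
}

# Largest-remainder allocation of n items to fractions (sums exactly to n).
allocate_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

synthetic_alleles <- function(class) {
  switch(class,
         missense = list(ref = "A", alt = "G"),
         nonsense = list(ref = "C", alt = "T"),
         splice = list(ref = "G", alt = "A"),
         simple_insertion = list(ref = "A", alt = "AGCT"),
         deletion = list(ref = "ACGT", alt = "A"),
         complex_indel = list(ref = "AC", alt = "GTT"),
         list(ref = "T", alt = "C"))
}

#' Generate a synthetic known-variant catalogue
#'
#' Variant positions are drawn uniformly without replacement over the
#' exonic footprint (the last base of each gene is excluded so insertion
#' footprints stay on-panel); classes follow the configured mix, by exact
#' largest-remainder allocation when `exact_mix` is set. An optional
#' fraction is placed on the intronic side of exon boundaries and classed
#' `splice`.
#'
#' @param panel a [panel_manifest()] from [make_panel()].
#' @param cfg a [sim_config()].
#' @return a [variant_catalogue()] (positions 1-based).
#' @export
make_catalogue <- function(panel, cfg) {
  if (cfg$catalogue_size == 0) {
    return(variant_catalogue(data.frame(
      variant_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), gene = character(),
      variant_class = character(), pathogenic = logical(),
      stringsAsFactors = FALSE)))
  }
  with_seed(cfg$seed + 1L, {
    ex <- panel$genes
    gene_last <- tapply(ex$end, ex$gene, max)
    pool <- do.call(c, lapply(seq_len(nrow(ex)), function(i) {
      b <- (ex$start[i] + 1L):ex$end[i]          # 1-based base positions
      b[b != gene_last[[ex$gene[i]]]]
    }))
    pool_gene <- do.call(c, lapply(seq_len(nrow(ex)), function(i) {
      b <- (ex$start[i] + 1L):ex$end[i]
      rep(ex$gene[i], sum(b != gene_last[[ex$gene[i]]]))
    }))
    n <- cfg$catalogue_size
    assert_that(n <= length(pool), "catalogue_size exceeds exonic bases")
    n_splice <- round(cfg$splice_site_fraction * n)
    n_mix <- n - n_splice
    idx <- sample(length(pool), n_mix)
    pos <- pool[idx]; gene <- pool_gene[idx]
    counts <- if (cfg$exact_mix) allocate_counts(n_mix, cfg$class_mix) else
      as.integer(stats::rmultinom(1, n_mix, cfg$class_mix))
    classes <- rep(names(cfg$class_mix), counts)
    classes <- classes[sample.int(length(classes))]
    if (n_splice > 0) {
      # donor/acceptor positions: 1-2 bases into the intron
      donors <- ex[ex$exon < cfg$exons_per_gene, , drop = FALSE]
      spos <- donors$end + sample(1:2, nrow(donors), replace = TRUE)
      pick <- sample(nrow(donors), n_splice, replace = n_splice > nrow(donors))
      pos <- c(pos, spos[pick]); gene <- c(gene, donors$gene[pick])
      classes <- c(classes, rep("splice", n_splice))
    }
    al <- lapply(classes, synthetic_alleles)
    variant_catalogue(data.frame(
      variant_id = sprintf("var%04d", seq_along(pos)),
      chrom = "chr1", pos = as.integer(pos),
      ref = vapply(al, `[[`, "", "ref"),
      alt = vapply(al, `[[`, "", "alt"),
      gene = gene, variant_class = classes,
      pathogenic = stats::runif(length(pos)) < cfg$pathogenic_fraction,
      stringsAsFactors = FALSE))
  })
}

#' Simulate aligned reads over a panel
#'
#' Each amplicon first draws total dropout with probability
#' `dropout_prob` (amplicons named in `force_dropout` always drop).
#' Surviving amplicons emit `Poisson(2 * mean_read_pairs)` reads, each
#' forward with probability `strand_balance`. Forward reads start at the
#' amplicon 5' end, reverse reads end at the 3' end; with reads shorter
#' than the amplicon this leaves single-strand flanks and a double-covered
#' centre — the central-overlap artifact. Reads longer than the amplicon
#' are truncated to it.
#'
#' @param panel a [panel_manifest()].
#' @param cfg a [sim_config()].
#' @param force_dropout character vector of amplicon_ids that must drop.
#' @return list with `reads` (data.frame `chrom, pos, cigar, mapq, strand,
#'   qcfail, duplicate`) and `dropped` (amplicon_ids that yielded no
#'   reads).
#' @export
simulate_reads <- function(panel, cfg, force_dropout = character()) {
  with_seed(cfg$seed + 2L, {
    amp <- panel$amplicons
    rl <- min(cfg$read_length, cfg$amplicon_length)
    out <- list(); dropped <- character()
    for (i in seq_len(nrow(amp))) {
      if (amp$amplicon_id[i] %in% force_dropout ||
          stats::runif(1) < cfg$dropout_prob) {
        dropped <- c(dropped, amp$amplicon_id[i])
        next
      }
      n <- stats::rpois(1, 2 * cfg$mean_read_pairs)
      if (n == 0) { dropped <- c(dropped, amp$amplicon_id[i]); next }
      fwd <- stats::runif(n) < cfg$strand_balance
      pos <- ifelse(fwd, amp$start[i], amp$end[i] - rl)
      out[[length(out) + 1L]] <- data.frame(
        chrom = amp$chrom[i], pos = as.integer(pos),
        cigar = sprintf("%dM", rl), mapq = 60L,
        strand = ifelse(fwd, "+", "-"), qcfail = FALSE, duplicate = FALSE,
        stringsAsFactors = FALSE)
    }
    reads <- if (length(out)) do.call(rbind, out) else
      data.frame(chrom = character(), pos = integer(), cigar = character(),
                 mapq = integer(), strand = character(), qcfail = logical(),
                 duplicate = logical(), stringsAsFactors = FALSE)
    list(reads = reads, dropped = dropped)
  })
}

#' Write simulated reads as SAM text
#'
#' Minimal unpaired SAM with `@SQ` headers derived from the manifest
#' footprint; sequences and qualities are `*` placeholders (the depth
#' engine only needs coordinates and CIGAR).
#'
#' @param reads data.frame as produced by [simulate_reads()].
#' @param manifest a [panel_manifest()] (for reference lengths).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_sam <- function(reads, manifest, path) {
  chroms <- unique(manifest$footprint$chrom)
  lens <- vapply(chroms, function(ch)
    as.integer(max(manifest$footprint$end[manifest$footprint$chrom == ch]) +
                 1000), integer(1))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chroms, lens))
  body <- if (nrow(reads)) sprintf(
    "r%06d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
    seq_len(nrow(reads)), ifelse(reads$strand == "-", 16L, 0L), reads$chrom,
    reads$pos + 1L, reads$mapq, reads$cigar) else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

CLASS_TO_CONSEQUENCE <- c(missense = "missense", nonsense = "stop_gained",
                          splice = "splice", simple_insertion = "frameshift",
                          deletion = "frameshift",
                          complex_indel = "frameshift", other = "missense")

#' Generate a synthetic variant call set
#'
#' Planted catalogue variants are emitted with comfortably passing
#' attributes (quality 250, PASS, depth 120, VAF 0.5, no population
#' record, whitelisted consequence mapped from the variant class). Decoys
#' are emitted at off-catalogue positions with attributes drawn from small
#' grids straddling every filter boundary (quality around 100, depth
#' around 30, VAF around 0.20, population frequency around 0.05,
#' consequences on and off the whitelist).
#'
#' @param catalogue a [variant_catalogue()].
#' @param cfg a [sim_config()] (uses `n_decoys` and the seed).
#' @param planted character vector of `variant_id`s to plant (must exist
#'   in the catalogue).
#' @return data.frame of calls as consumed by [filter_calls()].
#' @export
make_callset <- function(catalogue, cfg, planted = character()) {
  missing <- setdiff(planted, catalogue$variant_id)
  assert_that(length(missing) == 0, "planted ids not in catalogue: %s",
              paste(missing, collapse = ", "))
  with_seed(cfg$seed + 3L, {
    p <- catalogue[match(planted, catalogue$variant_id), , drop = FALSE]
    planted_calls <- if (nrow(p)) data.frame(
      chrom = p$chrom, pos = p$pos, ref = p$ref, alt = p$alt, qual = 250,
      filter_status = "PASS", total_depth = 120L, alt_depth = 60L,
      vaf = 0.5, population_freq = NA_real_,
      consequence = unname(CLASS_TO_CONSEQUENCE[p$variant_class]),
      gene = p$gene, source = "planted", stringsAsFactors = FALSE) else NULL
    decoys <- NULL
    if (cfg$n_decoys > 0) {
      n <- cfg$n_decoys
      maxpos <- if (nrow(catalogue)) max(catalogue$pos) else 10000L
      decoys <- data.frame(
        chrom = "chr1",
        pos = maxpos + sample.int(10 * n, n),   # off-catalogue positions
        ref = "A", alt = "T",
        qual = sample(c(90, 99.9, 100, 100.01, 150, 250), n, replace = TRUE),
        filter_status = sample(c("PASS", "q20"), n, replace = TRUE,
                               prob = c(0.8, 0.2)),
        total_depth = sample(c(25L, 30L, 31L, 60L, 120L), n, replace = TRUE),
        vaf = sample(c(0.1, 0.19, 0.2, 0.21, 0.5), n, replace = TRUE),
        population_freq = sample(c(NA, 0.01, 0.049, 0.05, 0.2), n,
                                 replace = TRUE),
        consequence = sample(c(CONSEQUENCE_WHITELIST, "synonymous",
                               "intron", "utr"), n, replace = TRUE),
        gene = "DECOY", source = "decoy", stringsAsFactors = FALSE)
      decoys$alt_depth <- as.integer(round(decoys$vaf * decoys$total_depth))
    }
    out <- rbind(planted_calls, decoys)
    if (is.null(out)) out <- data.frame(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), qual = numeric(), filter_status = character(),
      total_depth = integer(), alt_depth = integer(), vaf = numeric(),
      population_freq = numeric(), consequence = character(),
      gene = character(), source = character(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic cohort outcome vector
#'
#' @param outcome_mix named integer counts over
#'   `confirmed, new_diagnosis, changed_diagnosis, unsolved`.
#' @param seed integer seed (order is shuffled deterministically).
#' @return data.frame `case_id, outcome`.
#' @export
make_cohort <- function(outcome_mix = c(confirmed = 17, new_diagnosis = 2,
                                        changed_diagnosis = 3,
                                        unsolved = 35), seed = 1) {
  bad <- setdiff(names(outcome_mix), COHORT_OUTCOMES)
  assert_that(length(bad) == 0, "unknown outcome class: %s",
              paste(bad, collapse = ", "))
  with_seed(seed + 4L, {
    outcome <- sample(rep(names(outcome_mix), outcome_mix))
    data.frame(case_id = sprintf("case%03d", seq_along(outcome)),
               outcome = outcome, stringsAsFactors = FALSE)
  })
}

#' Materialize a complete synthetic workspace on disk
#'
#' Writes the panel BEDs, catalogue TSV, simulated reads (SAM), the
#' corresponding depth table (bedGraph), a call set TSV and a cohort TSV
#' into a directory, using the dialects the package's own readers consume.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @param force_dropout passed to [simulate_reads()].
#' @return invisibly, a named list of the paths written.
#' @export
write_workspace <- function(cfg, dir, force_dropout = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- make_panel(cfg)
  catalogue <- make_catalogue(panel, cfg)
  sim <- simulate_reads(panel, cfg, force_dropout)
  profile <- compute_depth(sim$reads, panel, sample_id = "sim")
  calls <- make_callset(catalogue, cfg,
                        planted = utils::head(catalogue$variant_id, 5))
  cohort <- make_cohort(seed = cfg$seed)
  paths <- list(
    amplicon_bed = file.path(dir, "amplicons.bed"),
    gene_bed = file.path(dir, "genes.bed"),
    catalogue = file.path(dir, "catalogue.tsv"),
    sam = file.path(dir, "reads.sam"),
    depth = file.path(dir, "depth.bedgraph"),
    calls = file.path(dir, "calls.tsv"),
    cohort = file.path(dir, "cohort.tsv"),
    dropped = file.path(dir, "dropped_amplicons.txt"))
  write_manifest(panel, paths$amplicon_bed, paths$gene_bed)
  write_catalogue(catalogue, paths$catalogue)
  write_sam(sim$reads, panel, paths$sam)
  write_depth_table(profile, paths$depth)
  write_calls(calls, paths$calls)
  utils::write.table(cohort, paths$cohort, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sim$dropped, paths$dropped)
  invisible(paths)
}
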