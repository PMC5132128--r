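# Small in-code fixtures shared across test files.

# A one-gene toy manifest: two amplicons [0,100) and [80,180) on chr1,
# one exon spanning [10,170).
toy_manifest <- function() {
  panel_manifest(
    "toy",
    genes = data.frame(gene = "TG1", chrom = "chr1", start = 10L,
                       end = 170L, exon = 1L, strand = "+",
                       stringsAsFactors = FALSE),
    amplicons = data.frame(amplicon_id = c("a1", "a2"), chrom = "chr1",
                           start = c(0L, 80L), end = c(100L, 180L),
                           gene = "TG1", stringsAsFactors = FALSE))
}

# Uniform-depth profile over a manifest footprint.
uniform_profile <- function(manifest, depth, sample_id = "s") {
  fp <- manifest$footprint
  reads <- do.call(rbind, lapply(seq_len(nrow(fp)), function(i) {
    data.frame(chrom = fp$chrom[i], pos = fp$start[i],
               cigar = sprintf("%dM", fp$end[i] - fp$start[i]),
               mapq = 60L, strand = "+", stringsAsFactors = FALSE)
  }))
  reads <- reads[rep(seq_len(nrow(reads)), each = depth), , drop = FALSE]
  compute_depth(reads, manifest, sample_id = sample_id)
}

# Random reads (simple M-only CIGARs) over a manifest, for oracle tests.
random_reads <- function(manifest, n, seed) {
  withr::with_seed(seed, {
    fp <- manifest$footprint
    i <- sample(nrow(fp), n, replace = TRUE)
    len <- sample(5:40, n, replace = TRUE)
    pos <- vapply(seq_len(n), function(k)
      sample(max(fp$start[i[k]] - 10, 0):(fp$end[i[k]] + 10), 1), 0)
    data.frame(chrom = fp$chrom[i], pos = as.integer(pos),
               cigar = sprintf("%dM", len),
               mapq = sample(0:60, n, replace = TRUE),
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

# Independent brute-force depth oracle: for every footprint base, count
# reads whose expanded covered positions include it. CIGAR expansion here
# enumerates per-base positions read by read, independently of the
# engine's interval accumulation.
brute_force_depth <- function(reads, manifest, min_mapq = 0,
                              count_del = FALSE) {
  fp <- manifest$footprint
  lapply(seq_len(nrow(fp)), function(i) {
    bases <- fp$start[i]:(fp$end[i] - 1L)
    counts <- integer(length(bases))
    for (r in seq_len(nrow(reads))) {
      if (reads$mapq[r] < min_mapq || reads$chrom[r] != fp$chrom[i]) next
      covered <- integer()
      off <- reads$pos[r]
      ops <- regmatches(reads$cigar[r],
                        gregexpr("\\d+[MIDNSHP=X]", reads$cigar[r]))[[1]]
      for (o in ops) {
        len <- as.integer(sub(".$", "", o))
        op <- substr(o, nchar(o), nchar(o))
        if (op %in% c("M", "=", "X")) {
          covered <- c(covered, off:(off + len - 1L)); off <- off + len
        } else if (op == "D") {
          if (count_del) covered <- c(covered, off:(off + len - 1L))
          off <- off + len
        } else if (op == "N") {
          off <- off + len
        }
      }
      counts <- counts + as.integer(bases %in% covered)
    }
    counts
  })
}

# Expand "chrom:pos:ref:alt" keys into a call data.frame.
calls_df <- function(keys) {
  if (length(keys) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[[`, "", 1),
             pos = as.integer(vapply(parts, `[[`, "", 2)),
             ref = vapply(parts, `[[`, "", 3),
             alt = vapply(parts, `[[`, "", 4), stringsAsFactors = FALSE)
}

# A call that passes every default filter rule.
passing_call <- function(...) {
  base <- list(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
               qual = 200, filter_status = "PASS", total_depth = 100L,
               alt_depth = 50L, vaf = 0.5, population_freq = NA_real_,
               consequence = "missense", gene = "TG1")
  mods <- list(...)
  base[names(mods)] <- mods
  as.data.frame(base, stringsAsFactors = FALSE)
}

# Independent re-evaluation of the filter rules, written as one flat
# predicate per call rather than a cascade.
oracle_filter_keep <- function(calls, cfg = filter_config()) {
  vapply(seq_len(nrow(calls)), function(i) {
    c <- calls[i, ]
    vaf <- if (!is.null(c$vaf)) c$vaf else c$alt_depth / c$total_depth
    c$qual > cfg$min_qual &&
      (!cfg$require_pass || c$filter_status == "PASS") &&
      c$total_depth > cfg$min_total_depth &&
      vaf >= cfg$min_vaf &&
      (is.na(c$population_freq) || c$population_freq < cfg$max_pop_freq) &&
      c$consequence %in% cfg$consequence_whitelist
  }, TRUE)
}

# Single-gene panel with the ten-amplicon topology used in coverage
# figures: six 300 bp exons, 400 bp introns, 425 bp amplicons with 50 bp
# overlap.
fig_topology_cfg <- function(seed = 11, mean_read_pairs = 100) {
  sim_config(seed = seed, n_genes = 1, dropout_prob = 0,
             mean_read_pairs = mean_read_pairs, catalogue_size = 0)
}
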