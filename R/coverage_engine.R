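#' Counting options for the depth engine
#'
#' Controls which reads and bases contribute to per-base depth. Defaults
#' match naive pileup of an amplicon aligner's output: duplicates counted
#' (amplicon PCR duplicates are indistinguishable from real coverage),
#' deletion-spanned reference bases not counted, no MAPQ floor.
#'
#' @param min_mapq minimum mapping quality; reads below it are excluded.
#' @param count_deletion_spanned_bases if `TRUE`, reference bases spanned
#'   by a CIGAR `D` operation count towards depth.
#' @param count_duplicates if `FALSE`, reads flagged as duplicates are
#'   excluded.
#' @return list of class `counting_options`.
#' @export
counting_options <- function(min_mapq = 0, count_deletion_spanned_bases = FALSE,
                             count_duplicates = TRUE) {
  assert_that(min_mapq >= 0, "min_mapq must be >= 0")
  structure(list(min_mapq = min_mapq,
                 count_deletion_spanned_bases = count_deletion_spanned_bases,
                 count_duplicates = count_duplicates),
            class = "counting_options")
}

# Parse a SAM CIGAR string into reference-consuming blocks relative to the
# read's leftmost position. M/=/X always count towards depth; D counts only
# when enabled; N consumes reference but never counts; I/S/H/P consume none.
cigar_ref_blocks <- function(cigar, count_del = FALSE) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  assert_that(length(ops) > 0 && sum(nchar(ops)) == nchar(cigar),
              "malformed CIGAR: %s", cigar)
  len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- substr(ops, nchar(ops), nchar(ops))
  off <- 0L
  starts <- integer(); ends <- integer()
  for (i in seq_along(op)) {
    consumes_ref <- op[i] %in% c("M", "=", "X", "D", "N")
    counts <- op[i] %in% c("M", "=", "X") || (op[i] == "D" && count_del)
    if (counts) {
      starts <- c(starts, off)
      ends <- c(ends, off + len[i])
    }
    if (consumes_ref) off <- off + len[i]
  }
  list(starts = starts, ends = ends, ref_span = off)
}

new_depth_profile <- function(sample_id, footprint, depth, fwd = NULL,
                              rev = NULL, options = counting_options(),
                              skipped_reads = 0L) {
  structure(list(sample_id = sample_id, intervals = footprint, depth = depth,
                 fwd = fwd, rev = rev, options = options,
                 skipped_reads = skipped_reads),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  tot <- sum(vapply(x$depth, function(d) sum(as.numeric(d)), 0))
  nb <- interval_width(x$intervals)
  cat(sprintf("depth_profile '%s': %d footprint bp, mean depth %.1f%s\n",
              x$sample_id, nb, if (nb) tot / nb else 0,
              if (!is.null(x$fwd)) ", strand-resolved" else ""))
  invisible(x)
}

# Accumulate interval events into per-footprint-interval depth vectors.
tally_blocks <- function(footprint, blocks) {
  depth <- vector("list", nrow(footprint))
  for (i in seq_len(nrow(footprint))) {
    fs <- footprint$start[i]; fe <- footprint$end[i]
    d <- integer(fe - fs)
    b <- blocks[blocks$chrom == footprint$chrom[i] & blocks$end > fs &
                  blocks$start < fe, , drop = FALSE]
    if (nrow(b)) {
      s <- pmax(b$start, fs) - fs
      e <- pmin(b$end, fe) - fs
      diffv <- integer(fe - fs + 1L)
      for (j in seq_along(s)) {
        diffv[s[j] + 1L] <- diffv[s[j] + 1L] + 1L
        diffv[e[j] + 1L] <- diffv[e[j] + 1L] - 1L
      }
      d <- cumsum(diffv[seq_len(fe - fs)])
    }
    depth[[i]] <- as.integer(d)
  }
  depth
}

#' Compute per-base depth over the panel footprint
#'
#' Depth at a base is the number of retained reads whose aligned
#' (CIGAR-consuming, countable) reference bases include it, restricted to
#' the panel footprint. The result is order-independent in the read stream.
#' Reads on chromosomes absent from the footprint are tallied as skipped,
#' not an error.
#'
#' @param reads data.frame of aligned reads with columns `chrom`, `pos`
#'   (0-based leftmost reference position), `cigar` (SAM CIGAR string),
#'   `mapq`, `strand` (`"+"`/`"-"`), and optional logicals `qcfail` and
#'   `duplicate`.
#' @param manifest a [panel_manifest()] (its footprint defines the region
#'   of interest).
#' @param opts a [counting_options()].
#' @param sample_id sample label stored on the profile.
#' @param strand_resolved if `TRUE`, keep forward/reverse sub-profiles
#'   (they sum to the total exactly).
#' @return A `depth_profile`.
#' @export
compute_depth <- function(reads, manifest, opts = counting_options(),
                          sample_id = "sample", strand_resolved = FALSE) {
  footprint <- manifest$footprint
  assert_that(nrow(footprint) > 0, "manifest footprint is empty")
  reads <- as.data.frame(reads, stringsAsFactors = FALSE)
  if (is.null(reads$qcfail)) reads$qcfail <- rep(FALSE, nrow(reads))
  if (is.null(reads$duplicate)) reads$duplicate <- rep(FALSE, nrow(reads))
  keep <- reads$mapq >= opts$min_mapq & !reads$qcfail
  if (!opts$count_duplicates) keep <- keep & !reads$duplicate
  reads <- reads[keep, , drop = FALSE]
  on_panel <- reads$chrom %in% footprint$chrom
  skipped <- sum(!on_panel)
  reads <- reads[on_panel, , drop = FALSE]

  blocks <- list()
  for (i in seq_len(nrow(reads))) {
    b <- cigar_ref_blocks(reads$cigar[i], opts$count_deletion_spanned_bases)
    assert_that(b$ref_span > 0, "read with no reference-consuming CIGAR ops")
    if (length(b$starts)) {
      blocks[[length(blocks) + 1L]] <-
        data.frame(chrom = reads$chrom[i], start = reads$pos[i] + b$starts,
                   end = reads$pos[i] + b$ends, strand = reads$strand[i],
                   stringsAsFactors = FALSE)
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)

  depth <- tally_blocks(footprint, blocks)
  fwd <- rev <- NULL
  if (strand_resolved) {
    fwd <- tally_blocks(footprint, blocks[blocks$strand == "+", , drop = FALSE])
    rev <- tally_blocks(footprint, blocks[blocks$strand == "-", , drop = FALSE])
  }
  new_depth_profile(sample_id, footprint, depth, fwd, rev, opts,
                    as.integer(skipped))
}

#' Per-base depth over an arbitrary region
#'
#' @param profile a `depth_profile`.
#' @param chrom,start,end region of interest, 0-based half-open.
#' @return integer vector of length `end - start`; bases outside the panel
#'   footprint are `NA`.
#' @export
depth_at <- function(profile, chrom, start, end) {
  assert_that(end > start, "empty query interval")
  out <- rep(NA_integer_, end - start)
  iv <- profile$intervals
  idx <- which(iv$chrom == chrom & iv$end > start & iv$start < end)
  for (i in idx) {
    qs <- max(start, iv$start[i]); qe <- min(end, iv$end[i])
    out[(qs - start + 1L):(qe - start)] <-
      profile$depth[[i]][(qs - iv$start[i] + 1L):(qe - iv$start[i])]
  }
  out
}

#' Load a per-base depth table (bedGraph dialect)
#'
#' Rows are `chrom start end depth`, 0-based half-open. The table is
#' expanded to per-base depth over the manifest footprint; footprint bases
#' absent from the table get depth 0. Overlapping rows with conflicting
#' depths are a validation error.
#'
#' @param path path to the 4-column TSV.
#' @param manifest a [panel_manifest()].
#' @param sample_id sample label.
#' @return A `depth_profile`.
#' @export
load_depth_table <- function(path, manifest, sample_id = "sample") {
  assert_that(file.exists(path), "file not found: %s", path)
  footprint <- manifest$footprint
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  depth <- lapply(seq_len(nrow(footprint)),
                  function(i) integer(footprint$end[i] - footprint$start[i]))
  if (length(lines)) {
    f <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(f, length, 1L) < 4)
    assert_that(length(bad) == 0, "malformed row in %s at line %d", path, bad[1])
    tab <- data.frame(chrom = vapply(f, `[[`, "", 1),
                      start = as.integer(vapply(f, `[[`, "", 2)),
                      end = as.integer(vapply(f, `[[`, "", 3)),
                      depth = as.integer(vapply(f, `[[`, "", 4)),
                      stringsAsFactors = FALSE)
    assert_that(!anyNA(tab$start) && !anyNA(tab$end) && !anyNA(tab$depth),
                "non-numeric field in %s", path)
    for (i in seq_len(nrow(footprint))) {
      fs <- footprint$start[i]; fe <- footprint$end[i]
      rows <- tab[tab$chrom == footprint$chrom[i] & tab$end > fs &
                    tab$start < fe, , drop = FALSE]
      seen <- rep(NA_integer_, fe - fs)
      for (j in seq_len(nrow(rows))) {
        s <- max(rows$start[j], fs) - fs + 1L
        e <- min(rows$end[j], fe) - fs
        idx <- s:e
        clash <- !is.na(seen[idx]) & seen[idx] != rows$depth[j]
        assert_that(!any(clash),
                    "%s: overlapping rows with conflicting depths near %s:%d",
                    path, rows$chrom[j], rows$start[j])
        seen[idx] <- rows$depth[j]
      }
      seen[is.na(seen)] <- 0L
      depth[[i]] <- seen
    }
  }
  new_depth_profile(sample_id, footprint, depth)
}

#' Write a depth profile as a bedGraph-dialect table
#'
#' Runs of equal depth are collapsed into one row; zero-depth runs are
#' omitted (absent bases read back as 0).
#'
#' @param profile a `depth_profile`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_depth_table <- function(profile, path) {
  out <- character()
  iv <- profile$intervals
  for (i in seq_len(nrow(iv))) {
    r <- rle(profile$depth[[i]])
    ends <- iv$start[i] + cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      out <- c(out, paste(iv$chrom[i], starts[keep], ends[keep],
                          r$values[keep], sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Mean depth over one amplicon
#'
#' @param profile a `depth_profile`.
#' @param amplicon a list or one-row data.frame with `chrom`, `start`, `end`.
#' @return arithmetic mean of per-base depth over the amplicon interval.
#' @export
amplicon_mean_coverage <- function(profile, amplicon) {
  d <- depth_at(profile, amplicon$chrom, amplicon$start, amplicon$end)
  assert_that(!anyNA(d), "amplicon extends outside the panel footprint")
  mean(d)
}

#' Per-base pass/fail status of one amplicon
#'
#' An amplicon fails if any base within it is below the minimum depth —
#' the per-base criterion that exposes low-coverage flanks which a
#' mean-coverage check would mask. The threshold is inclusive: depth equal
#' to `min_depth` passes.
#'
#' @param profile a `depth_profile`.
#' @param amplicon a list or one-row data.frame with `chrom`, `start`, `end`.
#' @param min_depth minimum acceptable per-base depth (default 30).
#' @return list with `status` (`"pass"`/`"fail"`), `fraction_pass` (share
#'   of bases at or above threshold), `min_depth_observed` and
#'   `mean_depth`.
#' @export
amplicon_status <- function(profile, amplicon, min_depth = 30) {
  d <- depth_at(profile, amplicon$chrom, amplicon$start, amplicon$end)
  assert_that(!anyNA(d), "amplicon extends outside the panel footprint")
  ok <- d >= min_depth
  list(status = if (all(ok)) "pass" else "fail",
       fraction_pass = mean(ok),
       min_depth_observed = min(d),
       mean_depth = mean(d))
}

#' Read aligned reads from SAM/BAM
#'
#' Thin wrapper over Rsamtools: extracts the fields the depth engine needs
#' and converts positions to the package's 0-based convention. SAM text
#' input is converted to BAM in a temporary file first.
#'
#' @param path path to a `.sam` or `.bam` file.
#' @return data.frame with columns `chrom, pos, cigar, mapq, strand,
#'   qcfail, duplicate`.
#' @export
read_alignments <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop_pc("read_alignments requires the Rsamtools package")
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("rname", "pos", "cigar", "mapq", "flag")))[[1]]
  mapped <- !is.na(res$pos) & !bitwAnd(res$flag, 4L)
  data.frame(chrom = as.character(res$rname)[mapped],
             pos = res$pos[mapped] - 1L,
             cigar = res$cigar[mapped],
             mapq = ifelse(is.na(res$mapq[mapped]), 0L, res$mapq[mapped]),
             strand = ifelse(bitwAnd(res$flag[mapped], 16L) > 0, "-", "+"),
             qcfail = bitwAnd(res$flag[mapped], 512L) > 0,
             duplicate = bitwAnd(res$flag[mapped], 1024L) > 0,
             stringsAsFactors = FALSE)
}
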