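#' Panel, gene and known-variant domain model
#'
#' A panel manifest bundles the gene models (exon structure), the amplicons
#' that tile them, and the derived panel footprint: the exact interval union
#' of all amplicons, i.e. the genomic territory the assay can interrogate.
#' All coordinates inside the package are 0-based half-open; BED input is
#' read as 0-based half-open and catalogue/VCF positions as 1-based.
#'
#' @param name panel name.
#' @param genes data.frame with columns `gene, chrom, start, end, exon,
#'   strand`, one row per exon. Exons of a gene must be non-overlapping,
#'   sorted by start, and on a single chromosome.
#' @param amplicons data.frame with columns `amplicon_id, chrom, start, end,
#'   gene` (gene may be `""` for intergenic amplicons).
#' @return An object of class `panel_manifest` with elements `name`,
#'   `genes`, `amplicons` and `footprint` (reduced interval union).
#' @export
panel_manifest <- function(name, genes, amplicons) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  amplicons <- as.data.frame(amplicons, stringsAsFactors = FALSE)
  if (nrow(genes)) validate_intervals(genes, "gene exon")
  if (nrow(amplicons)) {
    validate_intervals(amplicons, "amplicon")
    dup <- amplicons$amplicon_id[duplicated(amplicons$amplicon_id)]
    assert_that(length(dup) == 0, "duplicate amplicon_id: %s",
                paste(unique(dup), collapse = ", "))
  }
  for (g in unique(genes$gene)) {
    ex <- genes[genes$gene == g, , drop = FALSE]
    assert_that(length(unique(ex$chrom)) == 1,
                "gene %s has exons on multiple chromosomes", g)
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1) {
      assert_that(all(ex$start[-1] >= ex$end[-nrow(ex)]),
                  "gene %s has overlapping exons", g)
    }
  }
  known <- unique(genes$gene)
  amp_genes <- setdiff(unique(amplicons$gene), c("", known))
  assert_that(length(amp_genes) == 0,
              "amplicon references unknown gene(s): %s",
              paste(amp_genes, collapse = ", "))
  structure(list(name = name, genes = genes, amplicons = amplicons,
                 footprint = reduce_intervals(amplicons)),
            class = "panel_manifest")
}

#' @export
print.panel_manifest <- function(x, ...) {
  cat(sprintf("panel_manifest '%s': %d genes, %d amplicons, footprint %d bp on %d interval(s)\n",
              x$name, length(unique(x$genes$gene)), nrow(x$amplicons),
              interval_width(x$footprint), nrow(x$footprint)))
  invisible(x)
}

read_bed_rows <- function(path, min_cols) {
  assert_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) return(NULL)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < min_cols)
  assert_that(length(bad) == 0, "malformed row in %s at line %d (< %d columns)",
              path, bad[1], min_cols)
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(starts) | is.na(ends))
  assert_that(length(bad) == 0, "non-numeric coordinate in %s at line %d",
              path, bad[1])
  list(fields = fields, chrom = vapply(fields, `[[`, "", 1),
       start = starts, end = ends)
}

#' Load a panel manifest from BED files
#'
#' The amplicon BED is standard 4+ column BED (`chrom start end name`).
#' An optional fifth column carries the gene symbol of the amplicon. The
#' gene/exon BED has name fields of the form `SYMBOL|exonN` plus a strand
#' column. BED coordinates are interpreted 0-based half-open, unchanged.
#'
#' @param amplicon_bed path to the amplicon BED file.
#' @param gene_bed path to the gene/exon BED file (optional; `NULL` gives a
#'   manifest with amplicons only).
#' @param name panel name stored on the manifest.
#' @return A [panel_manifest()].
#' @export
load_manifest <- function(amplicon_bed, gene_bed = NULL, name = "panel") {
  amp <- read_bed_rows(amplicon_bed, 4L)
  if (is.null(amp)) {
    amplicons <- data.frame(amplicon_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            gene = character(), stringsAsFactors = FALSE)
  } else {
    gene <- vapply(amp$fields, function(f) if (length(f) >= 5) f[[5]] else "", "")
    amplicons <- data.frame(amplicon_id = vapply(amp$fields, `[[`, "", 4),
                            chrom = amp$chrom, start = amp$start,
                            end = amp$end, gene = gene,
                            stringsAsFactors = FALSE)
  }
  genes <- data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(), exon = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (!is.null(gene_bed)) {
    gb <- read_bed_rows(gene_bed, 4L)
    if (!is.null(gb)) {
      nm <- vapply(gb$fields, `[[`, "", 4)
      parts <- strsplit(nm, "|", fixed = TRUE)
      bad <- which(vapply(parts, length, 1L) != 2)
      assert_that(length(bad) == 0,
                  "malformed gene/exon name in %s at line %d (want SYMBOL|exonN)",
                  gene_bed, bad[1])
      exon <- suppressWarnings(as.integer(sub("^exon", "",
                                              vapply(parts, `[[`, "", 2))))
      assert_that(!anyNA(exon), "malformed exon index in %s", gene_bed)
      strand <- vapply(gb$fields, function(f) if (length(f) >= 6) f[[6]]
                       else if (length(f) >= 5) f[[5]] else "+", "")
      strand[!strand %in% c("+", "-")] <- "+"
      genes <- data.frame(gene = vapply(parts, `[[`, "", 1), chrom = gb$chrom,
                          start = gb$start, end = gb$end, exon = exon,
                          strand = strand, stringsAsFactors = FALSE)
      genes <- genes[order(genes$gene, genes$start), , drop = FALSE]
    }
  }
  m <- panel_manifest(name, genes, amplicons)
  check_chrom_consistency(m)
  m
}

# Exact string matching of chromosome names; a cross-file mismatch such as
# "1" vs "chr1" is reported rather than silently aliased.
check_chrom_consistency <- function(manifest, extra_chroms = character()) {
  chroms <- unique(c(manifest$amplicons$chrom, manifest$genes$chrom,
                     extra_chroms))
  stripped <- sub("^chr", "", chroms)
  clash <- stripped[duplicated(stripped)]
  if (length(clash)) {
    warning(sprintf("chromosome naming mismatch across inputs: %s",
                    paste(unique(chroms[stripped %in% clash]), collapse = ", ")),
            call. = FALSE)
  }
  invisible(chroms)
}

#' Write a manifest back to BED files
#'
#' @param manifest a [panel_manifest()].
#' @param amplicon_bed,gene_bed output paths (either may be `NULL` to skip).
#' @return Invisibly, the manifest.
#' @export
write_manifest <- function(manifest, amplicon_bed = NULL, gene_bed = NULL) {
  if (!is.null(amplicon_bed)) {
    a <- manifest$amplicons
    writeLines(if (nrow(a)) paste(a$chrom, a$start, a$end, a$amplicon_id,
                                  a$gene, sep = "\t") else character(),
               amplicon_bed)
  }
  if (!is.null(gene_bed)) {
    g <- manifest$genes
    writeLines(if (nrow(g)) paste(g$chrom, g$start, g$end,
                                  paste0(g$gene, "|exon", g$exon),
                                  g$strand, sep = "\t") else character(),
               gene_bed)
  }
  invisible(manifest)
}

VARIANT_CLASSES <- c("missense", "nonsense", "splice", "simple_insertion",
                     "deletion", "complex_indel", "other")

CATALOGUE_COLUMNS <- c("variant_id", "chrom", "pos", "ref", "alt", "gene",
                       "variant_class", "pathogenic")

#' Known-variant catalogue
#'
#' A catalogue of known mutations (an HGMD-style extract): one row per
#' variant with 1-based position of the first affected reference base,
#' ref/alt alleles, gene symbol, variant class from a closed vocabulary,
#' and a pathogenicity flag. The class is taken from the annotation source,
#' never re-derived from the alleles.
#'
#' @param variants data.frame with columns `variant_id, chrom, pos, ref,
#'   alt, gene, variant_class, pathogenic`.
#' @return Object of class `variant_catalogue`: the validated data.frame
#'   with an attribute `n_reclassed` counting records whose class was not
#'   in the closed vocabulary and was mapped to `"other"`.
#' @export
variant_catalogue <- function(variants) {
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  missing <- setdiff(CATALOGUE_COLUMNS, names(v))
  assert_that(length(missing) == 0, "catalogue missing column(s): %s",
              paste(missing, collapse = ", "))
  v <- v[CATALOGUE_COLUMNS]
  n_reclassed <- 0L
  if (nrow(v)) {
    assert_that(all(v$pos >= 1), "catalogue pos must be >= 1")
    assert_that(!any(v$ref == v$alt), "catalogue record with ref == alt")
    dup <- v$variant_id[duplicated(v$variant_id)]
    assert_that(length(dup) == 0, "duplicate variant_id: %s",
                paste(unique(dup), collapse = ", "))
    unknown <- !(v$variant_class %in% VARIANT_CLASSES)
    n_reclassed <- sum(unknown)
    if (n_reclassed > 0) {
      warning(sprintf("%d record(s) with unknown variant_class mapped to 'other'",
                      n_reclassed), call. = FALSE)
      v$variant_class[unknown] <- "other"
    }
    v$pathogenic <- as.logical(v$pathogenic)
  }
  structure(v, class = c("variant_catalogue", "data.frame"),
            n_reclassed = n_reclassed)
}

#' Load a known-variant catalogue from TSV
#'
#' Expects a tab-separated file with header columns `variant_id, chrom,
#' pos, ref, alt, gene, variant_class, pathogenic`; `pos` is 1-based.
#' Records with a class outside the closed vocabulary are kept but mapped
#' to `"other"` with a warning (count available via `attr(x,
#' "n_reclassed")`).
#'
#' @param path path to the TSV file.
#' @return A [variant_catalogue()].
#' @export
load_catalogue <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  first <- readLines(path, n = 1)
  if (length(first) == 0) {
    return(variant_catalogue(
      data.frame(variant_id = character(), chrom = character(),
                 pos = integer(), ref = character(), alt = character(),
                 gene = character(), variant_class = character(),
                 pathogenic = logical(), stringsAsFactors = FALSE)))
  }
  v <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(CATALOGUE_COLUMNS, names(v))
  assert_that(length(missing) == 0, "%s: missing column(s): %s", path,
              paste(missing, collapse = ", "))
  v$pos <- as.integer(v$pos)
  assert_that(!anyNA(v$pos), "%s: non-numeric pos", path)
  v$pathogenic <- tolower(v$pathogenic) %in% c("true", "t", "1", "yes")
  variant_catalogue(v)
}

#' Write a catalogue to TSV
#'
#' @param catalogue a [variant_catalogue()].
#' @param path output path.
#' @return Invisibly, the catalogue.
#' @export
write_catalogue <- function(catalogue, path) {
  v <- as.data.frame(catalogue)
  v$pathogenic <- ifelse(v$pathogenic, "true", "false")
  utils::write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(catalogue)
}

#' Genomic footprint of a known variant
#'
#' The footprint is the set of reference bases that must be adequately
#' covered for the variant to be detectable. Substitutions and deletions
#' occupy the reference bases they change: `[pos-1, pos-1+nchar(ref))`
#' 0-based half-open. A pure insertion (ref length 1, alt beginning with
#' ref) changes no reference base, but its junction can only be observed by
#' reads spanning both flanks, so its footprint is the two flanking bases
#' `[pos-1, pos+1)`.
#'
#' @param pos 1-based position of the first affected reference base.
#' @param ref,alt allele strings.
#' @return list with `start`, `end` (0-based half-open).
#' @export
variant_footprint <- function(pos, ref, alt) {
  assert_that(pos >= 1, "pos must be >= 1")
  insertion <- nchar(ref) == 1 && nchar(alt) > 1 && startsWith(alt, ref)
  if (insertion) {
    list(start = pos - 1L, end = pos + 1L)
  } else {
    list(start = pos - 1L, end = pos - 1L + max(1L, nchar(ref)))
  }
}

footprint_table <- function(catalogue) {
  if (nrow(catalogue) == 0) {
    return(cbind(empty_intervals(),
                 data.frame(variant_id = character(), gene = character())))
  }
  fp <- mapply(function(p, r, a) unlist(variant_footprint(p, r, a)),
               catalogue$pos, catalogue$ref, catalogue$alt)
  data.frame(chrom = catalogue$chrom, start = as.integer(fp["start", ]),
             end = as.integer(fp["end", ]), variant_id = catalogue$variant_id,
             gene = catalogue$gene, stringsAsFactors = FALSE)
}

#' Class composition of a catalogue
#'
#' Tallies variants by class and reports the fraction of each, mirroring
#' validation-report statements such as "87% missense, 4% simple
#' insertions, 8% deletions, 1% complex indels".
#'
#' @param catalogue a non-empty [variant_catalogue()].
#' @return data.frame with columns `variant_class, n, fraction`, one row
#'   per class present, fractions summing to 1.
#' @export
catalogue_composition <- function(catalogue) {
  assert_that(nrow(catalogue) > 0, "catalogue is empty")
  tab <- table(catalogue$variant_class)
  out <- data.frame(variant_class = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$fraction <- out$n / sum(out$n)
  out[order(-out$n, out$variant_class), , drop = FALSE]
}
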