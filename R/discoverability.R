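#' Discoverability of a single known variant
#'
#' A known mutation is "discoverable" in a sample when every reference
#' base of its footprint lies inside the panel footprint and carries read
#' depth at or above the threshold — i.e. the assay had enough data at
#' that location to have seen the mutation were it present. The threshold
#' is inclusive: minimum depth exactly equal to it is discoverable.
#'
#' @param profile a `depth_profile`.
#' @param variant one catalogue record (list or one-row data.frame with
#'   `variant_id, chrom, pos, ref, alt`).
#' @param threshold minimum per-base depth (default 30).
#' @return list with `sample_id, variant_id, min_footprint_depth,
#'   discoverable, outside_panel`. `min_footprint_depth` is the minimum
#'   over in-panel footprint bases (`NA` if the footprint lies wholly
#'   outside the panel).
#' @export
variant_discoverable <- function(profile, variant, threshold = 30) {
  fp <- variant_footprint(variant$pos, variant$ref, variant$alt)
  d <- depth_at(profile, variant$chrom, fp$start, fp$end)
  outside <- anyNA(d)
  mind <- if (all(is.na(d))) NA_integer_ else min(d, na.rm = TRUE)
  list(sample_id = profile$sample_id,
       variant_id = variant$variant_id,
       min_footprint_depth = mind,
       discoverable = !outside && mind >= threshold,
       outside_panel = outside)
}

#' Per-variant discoverability table for a whole catalogue
#'
#' @param profile a `depth_profile`.
#' @param catalogue a [variant_catalogue()].
#' @param threshold minimum per-base depth.
#' @return data.frame with one row per catalogue variant: `variant_id,
#'   gene, min_footprint_depth, outside_panel, discoverable`.
#' @export
discoverability_table <- function(profile, catalogue, threshold = 30) {
  rows <- lapply(seq_len(nrow(catalogue)), function(i) {
    r <- variant_discoverable(profile, catalogue[i, ], threshold)
    data.frame(variant_id = r$variant_id, gene = catalogue$gene[i],
               min_footprint_depth = r$min_footprint_depth,
               outside_panel = r$outside_panel,
               discoverable = r$discoverable, stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(), gene = character(),
               min_footprint_depth = integer(), outside_panel = logical(),
               discoverable = logical(), stringsAsFactors = FALSE)
}

summarise_gene <- function(tab, gene, flag_below, include_unassayable) {
  g <- tab[tab$gene == gene, , drop = FALSE]
  n_outside <- sum(g$outside_panel)
  if (!include_unassayable) g <- g[!g$outside_panel, , drop = FALSE]
  n_known <- nrow(g)
  n_disc <- sum(g$discoverable)
  frac <- if (n_known > 0) n_disc / n_known else NA_real_
  data.frame(gene = gene, n_known = n_known, n_discoverable = n_disc,
             fraction = frac,
             flagged = if (is.na(frac)) NA else frac < flag_below,
             n_outside_panel = n_outside, stringsAsFactors = FALSE)
}

#' Per-gene discoverability
#'
#' Fraction of the gene's catalogued mutations that are discoverable in
#' this sample. Genes whose fraction falls below `flag_below` (default
#' 0.90, strict less-than) are flagged as below accepted coverage
#' standards. By default, catalogue variants whose footprint lies outside
#' the panel footprint are excluded from the denominator and counted
#' separately as never-assayable; set `include_unassayable = TRUE` to keep
#' them in the denominator (where they count as non-discoverable).
#'
#' @param profile a `depth_profile`.
#' @param gene gene symbol (assignment of variants to genes comes from the
#'   catalogue's gene column, not positional overlap).
#' @param catalogue a [variant_catalogue()].
#' @param threshold minimum per-base depth.
#' @param flag_below flag fraction threshold (strict `<`).
#' @param include_unassayable see Description.
#' @return one-row data.frame `gene, n_known, n_discoverable, fraction,
#'   flagged, n_outside_panel`, or `NULL` if the catalogue has no variants
#'   for the gene (omitted-gene marker, not an error).
#' @export
gene_discoverability <- function(profile, gene, catalogue, threshold = 30,
                                 flag_below = 0.90,
                                 include_unassayable = FALSE) {
  cat_g <- catalogue[catalogue$gene == gene, , drop = FALSE]
  if (nrow(cat_g) == 0) return(NULL)
  tab <- discoverability_table(profile, cat_g, threshold)
  summarise_gene(tab, gene, flag_below, include_unassayable)
}

#' Sample-level discoverability report
#'
#' One row per catalogued gene plus the sample's overall discoverable
#' fraction, computed over all catalogue variants (total discoverable /
#' total known — not the mean of gene fractions). `repeat_flag` is raised
#' when any gene is flagged, as a machine-readable signal to repeat
#' sequencing or fall back to an orthogonal assay for that gene.
#'
#' @inheritParams gene_discoverability
#' @param manifest the [panel_manifest()] the profile was computed over.
#' @return object of class `sample_report`: list with `sample_id`, `genes`
#'   (per-gene data.frame), `overall_fraction`, `n_known`,
#'   `n_discoverable`, `n_outside_panel`, `repeat_flag`, `threshold`,
#'   `flag_below`.
#' @export
sample_report <- function(profile, manifest, catalogue, threshold = 30,
                          flag_below = 0.90, include_unassayable = FALSE) {
  assert_that(nrow(catalogue) > 0, "catalogue is empty")
  tab <- discoverability_table(profile, catalogue, threshold)
  genes <- unique(catalogue$gene)
  per_gene <- do.call(rbind, lapply(genes, function(g)
    summarise_gene(tab, g, flag_below, include_unassayable)))
  # genes with every variant outside the panel have no assayable denominator
  assayable <- per_gene[per_gene$n_known > 0, , drop = FALSE]
  rownames(assayable) <- NULL
  n_known <- sum(assayable$n_known)
  n_disc <- sum(assayable$n_discoverable)
  structure(list(
    sample_id = profile$sample_id,
    genes = assayable,
    overall_fraction = if (n_known > 0) n_disc / n_known else NA_real_,
    n_known = n_known,
    n_discoverable = n_disc,
    n_outside_panel = sum(tab$outside_panel),
    repeat_flag = any(assayable$flagged, na.rm = TRUE),
    threshold = threshold,
    flag_below = flag_below), class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("sample_report '%s': %d/%d known variants discoverable (%s%%)%s\n",
              x$sample_id, x$n_discoverable, x$n_known,
              percent1(x$overall_fraction),
              if (x$repeat_flag) " [LOW-coverage gene(s) flagged]" else ""))
  invisible(x)
}

#' Run-level summary across samples
#'
#' Five-number summaries (min, lower quartile, median, upper quartile,
#' max; quantile type 7) of the per-gene discoverable fraction across
#' samples, plus per-sample overall fractions with their range.
#'
#' @param reports list of [sample_report()] objects (at least one).
#' @return object of class `run_summary`: list with `per_gene`
#'   (data.frame `gene, min, q1, median, q3, max, n_samples`),
#'   `per_sample` (data.frame `sample_id, overall_fraction`), `range`
#'   (min/max of overall fractions) and `n_samples`.
#' @export
run_summary <- function(reports) {
  assert_that(length(reports) >= 1, "need at least one sample report")
  per_sample <- data.frame(
    sample_id = vapply(reports, function(r) r$sample_id, ""),
    overall_fraction = vapply(reports, function(r) r$overall_fraction, 0),
    stringsAsFactors = FALSE)
  gene_frac <- do.call(rbind, lapply(reports, function(r)
    r$genes[, c("gene", "fraction")]))
  per_gene <- do.call(rbind, lapply(split(gene_frac, gene_frac$gene),
    function(d) {
      q <- stats::quantile(d$fraction, c(0, .25, .5, .75, 1), na.rm = TRUE,
                           names = FALSE, type = 7)
      data.frame(gene = d$gene[1], min = q[1], q1 = q[2], median = q[3],
                 q3 = q[4], max = q[5], n_samples = sum(!is.na(d$fraction)),
                 stringsAsFactors = FALSE)
    }))
  rownames(per_gene) <- NULL
  structure(list(per_gene = per_gene[order(per_gene$gene), , drop = FALSE],
                 per_sample = per_sample,
                 range = range(per_sample$overall_fraction),
                 n_samples = length(reports)),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("run_summary: %d samples, overall discoverability %s%%-%s%%\n",
              x$n_samples, percent1(x$range[1]), percent1(x$range[2])))
  invisible(x)
}

#' Plot-ready coverage track for one gene
#'
#' Pure data for a gene coverage figure: the per-base depth series over
#' the gene's amplicons, each amplicon with its per-base pass/fail status,
#' the threshold line, exon intervals, and one marker per known variant
#' with its discoverability. Rendering is left to the caller.
#'
#' @param profile a `depth_profile`.
#' @param manifest a [panel_manifest()].
#' @param gene gene symbol; amplicons are selected by gene label or by
#'   overlap with the gene's exon span (so flanking intergenic amplicons
#'   appear, as on a real panel).
#' @param catalogue a [variant_catalogue()].
#' @param threshold minimum per-base depth.
#' @return list with `gene`, `depth` (data.frame `chrom, pos, depth`),
#'   `exons`, `amplicons` (with `status`, `fraction_pass`), `threshold`,
#'   `markers` (data.frame `variant_id, pos, discoverable`).
#' @export
gene_coverage_track <- function(profile, manifest, gene, catalogue,
                                threshold = 30) {
  ex <- manifest$genes[manifest$genes$gene == gene, , drop = FALSE]
  span_start <- if (nrow(ex)) min(ex$start) else Inf
  span_end <- if (nrow(ex)) max(ex$end) else -Inf
  amp <- manifest$amplicons
  sel <- amp$gene == gene |
    (nrow(ex) > 0 & amp$chrom %in% ex$chrom[1] & amp$end > span_start &
       amp$start < span_end)
  amp <- amp[sel, , drop = FALSE]
  assert_that(nrow(amp) > 0, "gene %s has no amplicons", gene)
  amp <- amp[order(amp$start), , drop = FALSE]

  status <- lapply(seq_len(nrow(amp)),
                   function(i) amplicon_status(profile, amp[i, ], threshold))
  amp$status <- vapply(status, `[[`, "", "status")
  amp$fraction_pass <- vapply(status, `[[`, 0, "fraction_pass")

  region <- reduce_intervals(amp[, c("chrom", "start", "end")])
  depth <- do.call(rbind, lapply(seq_len(nrow(region)), function(i) {
    pos <- region$start[i]:(region$end[i] - 1L)
    data.frame(chrom = region$chrom[i], pos = pos,
               depth = depth_at(profile, region$chrom[i], region$start[i],
                                region$end[i]),
               stringsAsFactors = FALSE)
  }))

  cat_g <- catalogue[catalogue$gene == gene, , drop = FALSE]
  markers <- do.call(rbind, lapply(seq_len(nrow(cat_g)), function(i) {
    r <- variant_discoverable(profile, cat_g[i, ], threshold)
    data.frame(variant_id = r$variant_id, pos = cat_g$pos[i] - 1L,
               discoverable = r$discoverable, stringsAsFactors = FALSE)
  }))
  if (is.null(markers)) {
    markers <- data.frame(variant_id = character(), pos = integer(),
                          discoverable = logical(), stringsAsFactors = FALSE)
  }
  list(gene = gene, depth = depth, exons = ex, amplicons = amp,
       threshold = threshold, markers = markers)
}

#' Render a report as TSV or JSON
#'
#' The TSV matrix has one row per gene with columns `gene, n_known,
#' n_discoverable, percent_discoverable, flag`; percentages are rendered
#' to one decimal (half away from zero) and the flag column carries the
#' literal `LOW` for genes below the flag threshold. JSON mirrors all
#' report fields. For a `run_summary` the TSV carries the per-gene
#' five-number summary as percentages.
#'
#' @param report a `sample_report` or `run_summary`.
#' @param format `"tsv"` or `"json"`.
#' @param path optional output path; when given, the document is written
#'   there.
#' @return the document as a character scalar, invisibly if `path` given.
#' @export
render_report <- function(report, format = c("tsv", "json"), path = NULL) {
  format <- match.arg(format)
  if (inherits(report, "sample_report")) {
    if (format == "tsv") {
      g <- report$genes
      lines <- c(paste("gene", "n_known", "n_discoverable",
                       "percent_discoverable", "flag", sep = "\t"),
                 if (nrow(g)) paste(g$gene, g$n_known, g$n_discoverable,
                                    percent1(g$fraction),
                                    ifelse(g$flagged, "LOW", ""), sep = "\t"))
      doc <- paste0(paste(lines, collapse = "\n"), "\n")
    } else {
      doc <- as.character(jsonlite::toJSON(list(
        sample_id = report$sample_id,
        threshold = report$threshold,
        flag_below = report$flag_below,
        overall_fraction = report$overall_fraction,
        overall_percent = as.numeric(percent1(report$overall_fraction)),
        n_known = report$n_known,
        n_discoverable = report$n_discoverable,
        n_outside_panel = report$n_outside_panel,
        repeat_flag = report$repeat_flag,
        genes = report$genes), auto_unbox = TRUE, digits = NA, pretty = TRUE))
    }
  } else if (inherits(report, "run_summary")) {
    if (format == "tsv") {
      g <- report$per_gene
      lines <- c(paste("gene", "min", "q1", "median", "q3", "max",
                       "n_samples", sep = "\t"),
                 if (nrow(g)) paste(g$gene, percent1(g$min), percent1(g$q1),
                                    percent1(g$median), percent1(g$q3),
                                    percent1(g$max), g$n_samples, sep = "\t"))
      doc <- paste0(paste(lines, collapse = "\n"), "\n")
    } else {
      doc <- as.character(jsonlite::toJSON(list(
        n_samples = report$n_samples, range = report$range,
        per_gene = report$per_gene, per_sample = report$per_sample),
        auto_unbox = TRUE, digits = NA, pretty = TRUE))
    }
  } else {
    stop_pc("render_report: unsupported report object")
  }
  if (!is.null(path)) {
    writeLines(sub("\n$", "", doc), path)
    return(invisible(doc))
  }
  doc
}

#' Parse a sample-report TSV back into a gene table
#'
#' @param path path to a TSV written by [render_report()].
#' @return data.frame with the gene table; `fraction` is recomputed
#'   exactly as `n_discoverable / n_known`.
#' @export
parse_report_tsv <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(flag = "character"))
  g$flag[is.na(g$flag)] <- ""
  g$fraction <- ifelse(g$n_known > 0, g$n_discoverable / g$n_known, NA_real_)
  g
}

#' Write a gene coverage track as JSON
#'
#' @param track result of [gene_coverage_track()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_track_json <- function(track, path) {
  jsonlite::write_json(track, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
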