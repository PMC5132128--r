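# Internal helpers shared across modules. All genomic intervals inside the
# package are 0-based half-open [start, end); catalogue/VCF positions are
# 1-based on disk and converted on load.

#' @keywords internal
"_PACKAGE"

# Round half away from zero at `digits` decimals (clinical rendering style;
# base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Render a fraction as a percentage string with one decimal, e.g. "85.0".
percent1 <- function(frac) {
  sprintf("%.1f", round_half_up(100 * frac, 1))
}

stop_pc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop_pc(fmt, ...)
  invisible(TRUE)
}

# --- interval algebra on data.frames with columns chrom, start, end ---------

empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

validate_intervals <- function(iv, what = "interval") {
  assert_that(all(c("chrom", "start", "end") %in% names(iv)),
              "%s table must have chrom/start/end columns", what)
  if (nrow(iv) == 0) return(invisible(iv))
  assert_that(all(nzchar(iv$chrom)), "%s has empty chromosome name", what)
  assert_that(all(iv$start >= 0), "%s has negative start", what)
  assert_that(all(iv$end > iv$start), "%s has end <= start", what)
  invisible(iv)
}

#' Merge possibly-overlapping genomic intervals
#'
#' Returns the sorted interval union (no double counting) of a table of
#' 0-based half-open intervals.
#'
#' @param iv data.frame with columns `chrom, start, end`.
#' @return data.frame of disjoint sorted intervals.
#' @export
reduce_intervals <- function(iv) {
  if (nrow(iv) == 0) return(empty_intervals())
  out <- lapply(split(iv, iv$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    start <- d$start[1]; end <- d$end[1]
    starts <- integer(); ends <- integer()
    if (nrow(d) > 1) {
      for (i in 2:nrow(d)) {
        if (d$start[i] <= end) {
          end <- max(end, d$end[i])
        } else {
          starts <- c(starts, start); ends <- c(ends, end)
          start <- d$start[i]; end <- d$end[i]
        }
      }
    }
    data.frame(chrom = d$chrom[1], start = c(starts, start),
               end = c(ends, end), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Total width of an interval set
#'
#' @param iv data.frame with columns `chrom, start, end`.
#' @return total number of bases covered (assuming disjoint intervals).
#' @export
interval_width <- function(iv) sum(iv$end - iv$start)

# Is [start, end) on chrom fully contained in the (reduced) interval set?
interval_contained <- function(iv, chrom, start, end) {
  hit <- iv[iv$chrom == chrom & iv$start <= start & iv$end >= end, , drop = FALSE]
  nrow(hit) > 0
}

# Variant identity key used for concordance and reproducibility.
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
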