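CONSEQUENCE_WHITELIST <- c("missense", "frameshift", "stop_gained",
                           "stop_lost", "initiator_codon",
                           "inframe_insertion", "inframe_deletion", "splice")

#' Clinical variant filter configuration
#'
#' Defaults reproduce a validated clinical filter set for germline panel
#' calls: quality score strictly above 100; caller PASS required; total
#' read depth strictly above 30; variant allele fraction at least 20%
#' (inclusive — germline heterozygotes expect ~50%); population frequency
#' strictly below 5% (calls with no population record pass, since novel
#' variants must survive); and a consequence whitelist of
#' protein/splice-affecting classes.
#'
#' @param min_qual quality floor, strict `>`.
#' @param require_pass require caller `FILTER == "PASS"`.
#' @param min_total_depth total read depth floor, strict `>`.
#' @param min_vaf variant allele fraction floor, inclusive `>=`.
#' @param max_pop_freq population frequency ceiling, strict `<`.
#' @param consequence_whitelist allowed consequence annotations.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_qual = 100, require_pass = TRUE,
                          min_total_depth = 30, min_vaf = 0.20,
                          max_pop_freq = 0.05,
                          consequence_whitelist = CONSEQUENCE_WHITELIST) {
  assert_that(min_qual >= 0 && min_total_depth >= 0 && min_vaf >= 0 &&
                max_pop_freq >= 0, "filter thresholds must be non-negative")
  assert_that(length(consequence_whitelist) > 0,
              "consequence whitelist must be non-empty")
  structure(list(min_qual = min_qual, require_pass = require_pass,
                 min_total_depth = min_total_depth, min_vaf = min_vaf,
                 max_pop_freq = max_pop_freq,
                 consequence_whitelist = consequence_whitelist),
            class = "filter_config")
}

FILTER_RULES <- c("qual", "pass", "depth", "vaf", "pop_freq", "consequence")

# Evaluate each rule for every call; TRUE = passes.
filter_rule_matrix <- function(calls, cfg) {
  vaf <- if (!is.null(calls$vaf)) calls$vaf else
    calls$alt_depth / calls$total_depth
  cbind(
    qual = calls$qual > cfg$min_qual,
    pass = if (cfg$require_pass) calls$filter_status == "PASS" else
      rep(TRUE, nrow(calls)),
    depth = calls$total_depth > cfg$min_total_depth,
    vaf = vaf >= cfg$min_vaf,
    pop_freq = is.na(calls$population_freq) |
      calls$population_freq < cfg$max_pop_freq,
    consequence = calls$consequence %in% cfg$consequence_whitelist)
}

#' Apply the clinical filter cascade
#'
#' Rules are conjunctive, so the kept set does not depend on rule order;
#' the rejection ledger records, for each rejected call, the first rule it
#' failed in the fixed order qual, pass, depth, vaf, pop_freq,
#' consequence.
#'
#' @param calls data.frame of variant calls with columns `chrom, pos, ref,
#'   alt, qual, filter_status, total_depth, alt_depth` (or `vaf`),
#'   `population_freq` (`NA` for unknown), `consequence`, `gene`.
#' @param cfg a [filter_config()].
#' @return list with `kept` (data.frame of surviving calls), `rejected`
#'   (data.frame with a `rejected_by` column), and `ledger` (data.frame
#'   `rule, n_rejected` in cascade order).
#' @export
filter_calls <- function(calls, cfg = filter_config()) {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (nrow(calls) == 0) {
    return(list(kept = calls, rejected = cbind(calls, rejected_by = character()),
                ledger = data.frame(rule = FILTER_RULES,
                                    n_rejected = 0L,
                                    stringsAsFactors = FALSE)))
  }
  ok <- filter_rule_matrix(calls, cfg)
  first_fail <- apply(ok, 1, function(r)
    if (all(r)) NA_character_ else FILTER_RULES[which(!r)[1]])
  kept <- calls[is.na(first_fail), , drop = FALSE]
  rejected <- calls[!is.na(first_fail), , drop = FALSE]
  rejected$rejected_by <- first_fail[!is.na(first_fail)]
  ledger <- data.frame(
    rule = FILTER_RULES,
    n_rejected = vapply(FILTER_RULES, function(r)
      sum(first_fail == r, na.rm = TRUE), 0L),
    stringsAsFactors = FALSE)
  rownames(kept) <- rownames(rejected) <- rownames(ledger) <- NULL
  list(kept = kept, rejected = rejected, ledger = ledger)
}

TIER2_CONSEQUENCES <- c("frameshift", "stop_gained", "stop_lost",
                        "initiator_codon")

# Canonical GT/AG splice: consequence "splice" and, when an intronic offset
# annotation is present, |offset| of 1 or 2. Without the annotation the
# consequence alone decides.
is_canonical_splice <- function(consequence, splice_offset) {
  consequence == "splice" &
    (is.na(splice_offset) | abs(splice_offset) <= 2)
}

#' Assign a reporting tier to one filtered call
#'
#' Three-tier pathogenicity stratification for panel reporting:
#' * Tier 1 — the call exactly matches a catalogue entry validated as
#'   pathogenic, in a gene linked to the patient's phenotype.
#' * Tier 2 — not Tier 1, but the mutation mechanism predicts loss of
#'   function: frameshift, novel stop codon, stop loss, initiator-codon
#'   mutation, or disruption of the canonical GT/AG splice dinucleotides.
#' * Tier 3 — possibly causative: a known-pathogenic variant in a gene
#'   not linked to this phenotype, a predicted cryptic-splice or
#'   transcription effect, or a non-conservative missense with a high
#'   deleteriousness score (consumed as an input annotation, e.g.
#'   SIFT/PolyPhen-style; never computed here).
#' * none — fails all three.
#'
#' @param call one call (list or one-row data.frame) with `chrom, pos,
#'   ref, alt, gene, consequence`, optional `splice_offset`,
#'   `deleterious_score`, `effect_prediction` (one of `"cryptic_splice"`,
#'   `"transcription"`, `"none"`).
#' @param catalogue a [variant_catalogue()].
#' @param phenotype_genes character vector of genes consistent with the
#'   patient's phenotype; `NULL` means all genes are phenotype-linked.
#' @param high_score deleteriousness cut-off for Tier 3 missense
#'   (inclusive, default 0.95).
#' @return list of class `tier_assignment`: `tier` (`1`, `2`, `3` or
#'   `NA`), `rationale` (rule identifier), `unsolved_flag` (set later by
#'   [compound_recessive_check()], `FALSE` here).
#' @export
assign_tier <- function(call, catalogue, phenotype_genes = NULL,
                        high_score = 0.95) {
  key <- variant_key(call$chrom, call$pos, call$ref, call$alt)
  cat_keys <- variant_key(catalogue$chrom, catalogue$pos, catalogue$ref,
                          catalogue$alt)
  hit <- which(cat_keys == key)
  known_pathogenic <- length(hit) > 0 && any(catalogue$pathogenic[hit])
  in_phenotype <- is.null(phenotype_genes) || call$gene %in% phenotype_genes
  splice_offset <- if (!is.null(call$splice_offset)) call$splice_offset else NA
  score <- if (!is.null(call$deleterious_score)) call$deleterious_score else NA
  effect <- if (!is.null(call$effect_prediction)) call$effect_prediction else "none"

  tier <- NA_integer_; rationale <- "no_rule"
  if (known_pathogenic && in_phenotype) {
    tier <- 1L; rationale <- "catalogue_pathogenic_phenotype_gene"
  } else if (call$consequence %in% TIER2_CONSEQUENCES ||
             is_canonical_splice(call$consequence, splice_offset)) {
    tier <- 2L
    rationale <- if (call$consequence %in% TIER2_CONSEQUENCES)
      paste0("mechanism_", call$consequence) else "canonical_splice_gt_ag"
  } else if (known_pathogenic && !in_phenotype) {
    tier <- 3L; rationale <- "pathogenic_in_non_phenotype_gene"
  } else if (!is.na(effect) && effect %in% c("cryptic_splice", "transcription")) {
    tier <- 3L; rationale <- paste0("predicted_", effect)
  } else if (call$consequence == "missense" && !is.na(score) &&
             score >= high_score) {
    tier <- 3L; rationale <- "high_deleteriousness_missense"
  }
  structure(list(tier = tier, rationale = rationale, unsolved_flag = FALSE),
            class = "tier_assignment")
}

#' Compound-recessive caveat check for one case
#'
#' A case carrying exactly one heterozygous Tier-1/2 hit in each of two
#' different autosomal-recessive genes cannot be concluded solved: each
#' variant alone is a carrier state, and pathogenicity of the combination
#' requires functional follow-up. Such cases are marked unsolved. A gene
#' with a homozygous hit, two or more heterozygous hits (compound
#' heterozygote), or a single hit under dominant or X-linked inheritance
#' remains diagnosis-eligible.
#'
#' @param case_calls data.frame with one row per tiered call of the case:
#'   columns `gene`, `tier` (integer or `NA`), `genotype` (`"het"` or
#'   `"hom"`).
#' @param inheritance_map named character vector gene -> inheritance mode
#'   (`"AR"`, `"AD"`, `"XL"`).
#' @return list with `unsolved` (logical), `reason`, and
#'   `eligible_genes` (genes that could support a diagnosis).
#' @export
compound_recessive_check <- function(case_calls, inheritance_map) {
  cc <- as.data.frame(case_calls, stringsAsFactors = FALSE)
  cc <- cc[!is.na(cc$tier) & cc$tier %in% c(1L, 2L), , drop = FALSE]
  if (nrow(cc) == 0) {
    return(list(unsolved = TRUE, reason = "no_reportable_variant",
                eligible_genes = character()))
  }
  modes <- inheritance_map[cc$gene]
  modes[is.na(modes)] <- "AR"
  eligible <- character()
  lone_het_ar <- character()
  for (g in unique(cc$gene)) {
    hits <- cc[cc$gene == g, , drop = FALSE]
    mode <- modes[match(g, cc$gene)]
    if (mode %in% c("AD", "XL")) {
      eligible <- c(eligible, g)
    } else if (any(hits$genotype == "hom") || nrow(hits) >= 2) {
      eligible <- c(eligible, g)  # homozygous or compound heterozygote
    } else {
      lone_het_ar <- c(lone_het_ar, g)
    }
  }
  if (length(eligible) > 0) {
    list(unsolved = FALSE, reason = "diagnosis_eligible",
         eligible_genes = eligible)
  } else if (length(lone_het_ar) >= 2) {
    list(unsolved = TRUE, reason = "co_inherited_recessive_carriers",
         eligible_genes = character())
  } else {
    list(unsolved = TRUE, reason = "single_recessive_carrier",
         eligible_genes = character())
  }
}

COHORT_OUTCOMES <- c("confirmed", "new_diagnosis", "changed_diagnosis",
                     "unsolved")

#' Cohort diagnostic-yield summary
#'
#' Counts outcomes per class and computes the diagnostic yield —
#' (confirmed + new + changed diagnoses) / total — as a percentage
#' rendered to one decimal, half away from zero. An optional stratum
#' column produces a per-working-diagnosis breakdown.
#'
#' @param outcomes data.frame with columns `case_id`, `outcome` (one of
#'   `"confirmed", "new_diagnosis", "changed_diagnosis", "unsolved"`) and
#'   optional `working_diagnosis`.
#' @return list with `counts` (named integer vector), `n`, `n_diagnosed`,
#'   `yield_fraction`, `yield_percent` (one-decimal numeric), and
#'   `by_stratum` (data.frame or `NULL`).
#' @export
cohort_summary <- function(outcomes) {
  outcomes <- as.data.frame(outcomes, stringsAsFactors = FALSE)
  assert_that(nrow(outcomes) > 0, "no outcomes supplied")
  bad <- setdiff(unique(outcomes$outcome), COHORT_OUTCOMES)
  assert_that(length(bad) == 0, "unknown outcome class: %s",
              paste(bad, collapse = ", "))
  counts <- vapply(COHORT_OUTCOMES, function(o)
    sum(outcomes$outcome == o), 0L)
  n <- nrow(outcomes)
  n_diag <- sum(counts[c("confirmed", "new_diagnosis", "changed_diagnosis")])
  by_stratum <- NULL
  if (!is.null(outcomes$working_diagnosis)) {
    by_stratum <- do.call(rbind, lapply(
      split(outcomes, outcomes$working_diagnosis), function(d) {
        nd <- sum(d$outcome != "unsolved")
        data.frame(working_diagnosis = d$working_diagnosis[1], n = nrow(d),
                   n_diagnosed = nd,
                   yield_percent = round_half_up(100 * nd / nrow(d), 1),
                   stringsAsFactors = FALSE)
      }))
    rownames(by_stratum) <- NULL
  }
  list(counts = counts, n = n, n_diagnosed = n_diag,
       yield_fraction = n_diag / n,
       yield_percent = round_half_up(100 * n_diag / n, 1),
       by_stratum = by_stratum)
}

#' Read a variant call set from TSV or VCF
#'
#' TSV input carries the call columns directly. VCF input is read with
#' vcfR; the quality and depth fields come from `QUAL`/`FILTER` and the
#' INFO keys named in `fields` (defaults `DP`, `VAF`, `POPAF`, `CSQ`,
#' `GENE`).
#'
#' @param path path to a `.tsv` or `.vcf` file.
#' @param fields named list mapping the package's call fields to INFO
#'   keys.
#' @return data.frame of calls as expected by [filter_calls()].
#' @export
read_calls <- function(path, fields = list(depth = "DP", vaf = "VAF",
                                           pop_freq = "POPAF",
                                           consequence = "CSQ",
                                           gene = "GENE")) {
  assert_that(file.exists(path), "file not found: %s", path)
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop_pc("reading VCF requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    info_get <- function(key, numeric = TRUE) {
      x <- vcfR::extract.info(v, element = key)
      if (numeric) suppressWarnings(as.numeric(x)) else x
    }
    total_depth <- as.integer(info_get(fields$depth))
    vaf <- info_get(fields$vaf)
    data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
               alt = fix$ALT, qual = as.numeric(fix$QUAL),
               filter_status = fix$FILTER, total_depth = total_depth,
               alt_depth = as.integer(round(vaf * total_depth)),
               vaf = vaf, population_freq = info_get(fields$pop_freq),
               consequence = info_get(fields$consequence, numeric = FALSE),
               gene = info_get(fields$gene, numeric = FALSE),
               stringsAsFactors = FALSE)
  } else {
    calls <- utils::read.delim(path, stringsAsFactors = FALSE)
    num <- intersect(c("pos", "qual", "total_depth", "alt_depth", "vaf",
                       "population_freq"), names(calls))
    for (cn in num) calls[[cn]] <- as.numeric(calls[[cn]])
    calls
  }
}

#' Write a call set to TSV
#'
#' @param calls data.frame of calls.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
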