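test_that("filter boundaries follow the printed inequality directions", {
  cfg <- filter_config()

  # quality strictly greater than 100
  res <- filter_calls(passing_call(qual = 100), cfg)
  expect_equal(nrow(res$kept), 0)
  expect_equal(res$rejected$rejected_by, "qual")
  expect_equal(nrow(filter_calls(passing_call(qual = 100.01), cfg)$kept), 1)

  # caller PASS required
  expect_equal(filter_calls(passing_call(filter_status = "q20"),
                            cfg)$rejected$rejected_by, "pass")

  # depth strictly greater than 30
  expect_equal(filter_calls(passing_call(total_depth = 30L, alt_depth = 15L),
                            cfg)$rejected$rejected_by, "depth")
  expect_equal(nrow(filter_calls(passing_call(total_depth = 31L,
                                              alt_depth = 16L), cfg)$kept), 1)

  # VAF inclusive at 20%
  expect_equal(nrow(filter_calls(passing_call(vaf = 0.20, alt_depth = 20L),
                                 cfg)$kept), 1)
  expect_equal(filter_calls(passing_call(vaf = 0.199), cfg)$rejected$rejected_by,
               "vaf")

  # population frequency strictly below 5%; unknown passes
  expect_equal(filter_calls(passing_call(population_freq = 0.05),
                            cfg)$rejected$rejected_by, "pop_freq")
  expect_equal(nrow(filter_calls(passing_call(population_freq = 0.049),
                                 cfg)$kept), 1)
  expect_equal(nrow(filter_calls(passing_call(population_freq = NA_real_),
                                 cfg)$kept), 1)

  # consequence whitelist
  expect_equal(filter_calls(passing_call(consequence = "synonymous"),
                            cfg)$rejected$rejected_by, "consequence")
  for (cons in cfg$consequence_whitelist) {
    expect_equal(nrow(filter_calls(passing_call(consequence = cons),
                                   cfg)$kept), 1)
  }
})

test_that("random call sets match the brute-force oracle filter", {
  cfg_sim <- sim_config(seed = 37, n_genes = 2, catalogue_size = 30,
                        n_decoys = 500)
  panel <- make_panel(cfg_sim)
  catalogue <- make_catalogue(panel, cfg_sim)
  calls <- make_callset(catalogue, cfg_sim,
                        planted = catalogue$variant_id[1:10])
  res <- filter_calls(calls)
  keep <- oracle_filter_keep(calls)
  expect_equal(nrow(res$kept), sum(keep))
  expect_equal(res$kept[c("chrom", "pos", "qual")],
               calls[keep, c("chrom", "pos", "qual")], ignore_attr = TRUE)
  # the ledger accounts for every rejection exactly once
  expect_equal(sum(res$ledger$n_rejected), sum(!keep))
  # planted calls always survive the default filters
  expect_equal(sum(res$kept$source == "planted"), 10)
})

test_that("tightening any threshold never enlarges the kept set", {
  cfg_sim <- sim_config(seed = 41, catalogue_size = 0, n_decoys = 300)
  calls <- make_callset(variant_catalogue(data.frame(
    variant_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    variant_class = character(), pathogenic = logical())), cfg_sim)
  base_keys <- with(filter_calls(calls)$kept, paste(chrom, pos))
  tighter <- list(filter_config(min_qual = 150),
                  filter_config(min_total_depth = 60),
                  filter_config(min_vaf = 0.3),
                  filter_config(max_pop_freq = 0.01),
                  filter_config(consequence_whitelist = c("missense")))
  for (cfg in tighter) {
    keys <- with(filter_calls(calls, cfg)$kept, paste(chrom, pos))
    expect_true(all(keys %in% base_keys))
  }
})

test_that("kept set is rule-order independent (ledger is not)", {
  cfg_sim <- sim_config(seed = 43, catalogue_size = 0, n_decoys = 200)
  calls <- make_callset(variant_catalogue(data.frame(
    variant_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    variant_class = character(), pathogenic = logical())), cfg_sim)
  res <- filter_calls(calls)
  # conjunctive rules: kept = calls passing each rule independently
  ok <- panelcover:::filter_rule_matrix(calls, filter_config())
  expect_equal(nrow(res$kept), sum(rowSums(!ok) == 0))
})

phenotype_catalogue <- function() {
  variant_catalogue(data.frame(
    variant_id = c("k1", "k2"), chrom = "chr1", pos = c(100L, 300L),
    ref = "A", alt = "G", gene = c("PKLR", "SEC23B"),
    variant_class = "missense", pathogenic = c(TRUE, TRUE),
    stringsAsFactors = FALSE))
}

test_that("tier assignment distinguishes known, mechanistic and possible", {
  cat <- phenotype_catalogue()

  # exact pathogenic catalogue match in a phenotype gene -> Tier 1
  t1 <- assign_tier(list(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                         gene = "PKLR", consequence = "missense"),
                    cat, phenotype_genes = "PKLR")
  expect_equal(t1$tier, 1L)

  # novel stop gain -> Tier 2
  t2 <- assign_tier(list(chrom = "chr1", pos = 999L, ref = "C", alt = "T",
                         gene = "PKLR", consequence = "stop_gained"),
                    cat, phenotype_genes = "PKLR")
  expect_equal(t2$tier, 2L)
  expect_match(t2$rationale, "stop_gained")

  # canonical GT/AG splice offsets
  t2s <- assign_tier(list(chrom = "chr1", pos = 999L, ref = "G", alt = "A",
                          gene = "PKLR", consequence = "splice",
                          splice_offset = 2L), cat, "PKLR")
  expect_equal(t2s$tier, 2L)
  deep <- assign_tier(list(chrom = "chr1", pos = 999L, ref = "G", alt = "A",
                           gene = "PKLR", consequence = "splice",
                           splice_offset = 8L), cat, "PKLR")
  expect_false(identical(deep$tier, 2L))

  # known pathogenic but wrong-phenotype gene -> Tier 3
  t3 <- assign_tier(list(chrom = "chr1", pos = 300L, ref = "A", alt = "G",
                         gene = "SEC23B", consequence = "missense"),
                    cat, phenotype_genes = "PKLR")
  expect_equal(t3$tier, 3L)
  expect_equal(t3$rationale, "pathogenic_in_non_phenotype_gene")

  # high-deleteriousness missense -> Tier 3; low score -> none
  hi <- assign_tier(list(chrom = "chr1", pos = 555L, ref = "A", alt = "C",
                         gene = "PKLR", consequence = "missense",
                         deleterious_score = 0.99), cat, "PKLR")
  expect_equal(hi$tier, 3L)
  lo <- assign_tier(list(chrom = "chr1", pos = 555L, ref = "A", alt = "C",
                         gene = "PKLR", consequence = "missense",
                         deleterious_score = 0.2), cat, "PKLR")
  expect_true(is.na(lo$tier))

  # predicted cryptic splice -> Tier 3
  cs <- assign_tier(list(chrom = "chr1", pos = 555L, ref = "A", alt = "C",
                         gene = "PKLR", consequence = "intron",
                         effect_prediction = "cryptic_splice"), cat, "PKLR")
  expect_equal(cs$tier, 3L)

  # benign synonymous -> none
  none <- assign_tier(list(chrom = "chr1", pos = 777L, ref = "T", alt = "C",
                           gene = "PKLR", consequence = "synonymous"),
                      cat, "PKLR")
  expect_true(is.na(none$tier))

  # pure function: repeated evaluation gives identical assignments
  expect_identical(assign_tier(list(chrom = "chr1", pos = 100L, ref = "A",
                                    alt = "G", gene = "PKLR",
                                    consequence = "missense"), cat, "PKLR"),
                   t1)
})

test_that("compound recessive carriers across two genes stay unsolved", {
  inh <- c(PKLR = "AR", SEC23B = "AR", GATA1 = "XL", RPS19 = "AD")

  two_genes <- data.frame(gene = c("PKLR", "SEC23B"), tier = c(1L, 1L),
                          genotype = "het", stringsAsFactors = FALSE)
  r <- compound_recessive_check(two_genes, inh)
  expect_true(r$unsolved)
  expect_equal(r$reason, "co_inherited_recessive_carriers")

  same_gene <- data.frame(gene = "PKLR", tier = c(1L, 1L),
                          genotype = c("het", "het"))
  r <- compound_recessive_check(same_gene, inh)
  expect_false(r$unsolved)
  expect_equal(r$eligible_genes, "PKLR")

  hom <- data.frame(gene = "SEC23B", tier = 1L, genotype = "hom")
  expect_false(compound_recessive_check(hom, inh)$unsolved)

  ad_single <- data.frame(gene = "RPS19", tier = 2L, genotype = "het")
  expect_false(compound_recessive_check(ad_single, inh)$unsolved)

  lone_carrier <- data.frame(gene = "PKLR", tier = 1L, genotype = "het")
  r <- compound_recessive_check(lone_carrier, inh)
  expect_true(r$unsolved)
  expect_equal(r$reason, "single_recessive_carrier")

  # Tier-3 and untiered hits never rescue a case
  t3_only <- data.frame(gene = "PKLR", tier = 3L, genotype = "het")
  expect_true(compound_recessive_check(t3_only, inh)$unsolved)
})

test_that("cohort summary computes yield to one decimal", {
  cohort <- make_cohort(c(confirmed = 17, new_diagnosis = 2,
                          changed_diagnosis = 3, unsolved = 35), seed = 3)
  expect_equal(nrow(cohort), 57)
  s <- cohort_summary(cohort)
  expect_equal(s$n_diagnosed, 22)
  expect_equal(s$yield_percent, 38.6)
  expect_equal(unname(s$counts),
               c(17L, 2L, 3L, 35L))

  all_unsolved <- make_cohort(c(unsolved = 10), seed = 1)
  expect_equal(cohort_summary(all_unsolved)$yield_percent, 0.0)

  # permutation invariance
  perm <- cohort[withr::with_seed(9, sample(nrow(cohort))), ]
  expect_equal(cohort_summary(perm)$counts, s$counts)

  # random outcome vector equals a tally oracle
  withr::with_seed(11, {
    oc <- sample(c("confirmed", "new_diagnosis", "changed_diagnosis",
                   "unsolved"), 200, replace = TRUE)
    s2 <- cohort_summary(data.frame(case_id = seq_along(oc), outcome = oc))
    expect_equal(unname(s2$counts),
                 unname(vapply(c("confirmed", "new_diagnosis",
                                 "changed_diagnosis", "unsolved"),
                               function(x) sum(oc == x), 0L)))
  })

  expect_error(cohort_summary(data.frame(case_id = 1, outcome = "odd")),
               "unknown outcome")
  expect_error(cohort_summary(data.frame(case_id = character(),
                                         outcome = character())),
               "no outcomes")

  # stratified breakdown sums to the cohort
  cohort$working_diagnosis <- rep(c("CDA", "DBA", "other"), length.out = 57)
  s3 <- cohort_summary(cohort)
  expect_equal(sum(s3$by_stratum$n), 57)
  expect_equal(sum(s3$by_stratum$n_diagnosed), 22)
})

test_that("call sets round-trip through TSV and load from VCF", {
  cfg_sim <- sim_config(seed = 47, n_genes = 2, catalogue_size = 20,
                        n_decoys = 30)
  panel <- make_panel(cfg_sim)
  catalogue <- make_catalogue(panel, cfg_sim)
  calls <- make_callset(catalogue, cfg_sim,
                        planted = catalogue$variant_id[1:5])
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, tsv)
  back <- read_calls(tsv)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$qual, calls$qual)
  expect_equal(filter_calls(back)$ledger, filter_calls(calls)$ledger)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##INFO=<ID=VAF,Number=1,Type=Float,Description="Allele fraction">',
    '##INFO=<ID=POPAF,Number=1,Type=Float,Description="Population AF">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tG\t250\tPASS\tDP=120;VAF=0.5;CSQ=missense;GENE=PKLR",
    "chr1\t200\t.\tC\tT\t100\tPASS\tDP=120;VAF=0.5;POPAF=0.2;CSQ=missense;GENE=PKLR"),
    vcf)
  vc <- read_calls(vcf)
  expect_equal(nrow(vc), 2)
  expect_equal(vc$qual, c(250, 100))
  expect_true(is.na(vc$population_freq[1]))
  res <- filter_calls(vc)
  expect_equal(nrow(res$kept), 1)
  expect_equal(res$rejected$rejected_by, "qual")
})
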