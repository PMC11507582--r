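# Shared fixtures: compact constructors for calls, annotation rows and
# small cohort configs.  Everything is built in code; no stored data.

make_calls <- function(n = 1, sample_id = "S0001", chrom = "chr1",
                       pos = 100L, ref = "A", alt = "T",
                       variant_class = "snp", qual = 60, mapq = 50,
                       depth = 100L, ref_depth = 60L, alt_depth = 40L,
                       gene = "TP53", origin = "planted",
                       decoy_gate = NA_character_) {
  data.frame(sample_id = rep_len(sample_id, n), chrom = rep_len(chrom, n),
             pos = as.integer(rep_len(pos, n)), ref = rep_len(ref, n),
             alt = rep_len(alt, n),
             variant_class = rep_len(variant_class, n),
             qual = rep_len(qual, n), mapq = rep_len(mapq, n),
             depth = as.integer(rep_len(depth, n)),
             ref_depth = as.integer(rep_len(ref_depth, n)),
             alt_depth = as.integer(rep_len(alt_depth, n)),
             gene = rep_len(gene, n), origin = rep_len(origin, n),
             decoy_gate = rep_len(decoy_gate, n), stringsAsFactors = FALSE)
}

ann_row <- function(SAMPLE = "S0001", CHROM = "chr1", POS = 100L,
                    REF = "A", ALT = "T", SYMBOL = "TP53",
                    Consequence = "missense_variant", IMPACT = "MODERATE",
                    Existing_variation = "", CLIN_SIG = "", SIFT = "",
                    PolyPhen = "", MAX_AF = NA_real_, HGVSp = "p.Arg1Gly") {
  data.frame(SAMPLE = SAMPLE, CHROM = CHROM, POS = as.integer(POS),
             REF = REF, ALT = ALT, SYMBOL = SYMBOL,
             Consequence = Consequence, IMPACT = IMPACT,
             Existing_variation = Existing_variation, CLIN_SIG = CLIN_SIG,
             SIFT = SIFT, PolyPhen = PolyPhen, MAX_AF = MAX_AF,
             HGVSp = HGVSp, stringsAsFactors = FALSE)
}

# Random annotation tables for property tests.
random_ann_table <- function(n_variants, max_rows_per_variant = 3) {
  imp <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  sift <- c("", "deleterious", "deleterious_low_confidence", "tolerated",
            "tolerated_low_confidence")
  poly <- c("", "probably_damaging", "possibly_damaging", "benign", "unknown")
  clin <- c("", "pathogenic", "likely_pathogenic", "benign",
            "uncertain_significance", "pathogenic,benign")
  do.call(rbind, lapply(seq_len(n_variants), function(v) {
    k <- sample(seq_len(max_rows_per_variant), 1)
    do.call(rbind, lapply(seq_len(k), function(i) {
      ann_row(POS = 100L + v, SYMBOL = sample(c("TP53", "BRCA1", "KRAS"), 1),
              IMPACT = sample(imp, 1),
              Existing_variation = sample(c("", "rs123", "rs7,COSV9"), 1),
              CLIN_SIG = sample(clin, 1), SIFT = sample(sift, 1),
              PolyPhen = sample(poly, 1),
              MAX_AF = sample(c(NA, 0.004, 0.2, 0.9), 1))
    }))
  }))
}

# Small cohort config used by several suites: tiny null panel world.
small_config <- function(seed = 1L, group_sizes = c(BOT = 20, BOT.V600E = 10,
                                                    lgOvCa = 5, hgOvCa = 30),
                         ...) {
  cohort_config(group_sizes = group_sizes, panel = default_panel("hotspot"),
                seed = seed, ...)
}
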