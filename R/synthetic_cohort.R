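# Seeded synthetic-cohort generator.
#
# Emulates the statistical structure of a four-group ovarian tumor
# cohort (BOT, BOT.V600E, lgOvCa, hgOvCa): per-gene per-group alteration
# frequencies, sub-threshold VAF noise and other single-gate decoy
# calls, low-coverage regions, censored OS/DFS/RFS with planted
# log-hazard-ratios, and binary CR/PS outcomes with planted log-odds
# ratios.  Everything is driven by one integer seed; identical config +
# seed gives byte-identical serialized bundles.

.OV_GROUPS <- c("BOT", "BOT.V600E", "lgOvCa", "hgOvCa")
.OV_STRATA <- c("HIGH_OR_MODERATE", "HIGH", "MODERATE")
.BASES <- c("A", "C", "G", "T")

# Baseline exponential hazards expressed as median times (months).
# Stated-world choices: hgOvCa median OS ~40 mo, borderline tumors
# rarely die or relapse within follow-up, ~20% BOTS recurrence.
.BASE_MEDIANS <- list(
  OS  = c(BOT = 240, BOT.V600E = 240, lgOvCa = 100, hgOvCa = 40),
  RFS = c(BOT = 180, BOT.V600E = 180, lgOvCa = 60,  hgOvCa = 24),
  DFS = c(BOT = 180, BOT.V600E = 180, lgOvCa = 40,  hgOvCa = 18)
)
.BASE_RESPONSE <- c(CR = 0.65, PS = 0.55, microinvasion_or_implants = 0.15)

#' Default planted per-gene alteration frequencies
#'
#' A stated-world frequency table loosely shaped after the qualitative
#' group differences the shipped panels are meant to exhibit (TP53 and
#' BRCA1 high-impact alterations concentrated in hgOvCa, KRAS/NRAS in
#' borderline tumors and low-grade carcinomas, BRAF defining the
#' BOT.V600E group, a moderate-impact background everywhere).  Values
#' are placeholders for a study whose per-gene frequencies are not
#' published numerically; they are fixed here once and not tuned.
#'
#' @param panel An `ov_panel`.
#' @return Data frame with columns `gene`, `group`, `stratum`, `prob`.
#' @export
default_gene_freqs <- function(panel) {
  base <- expand.grid(gene = panel$genes, group = .OV_GROUPS,
                      stringsAsFactors = FALSE)
  baseline <- rbind(
    cbind(base, stratum = "MODERATE", prob = 0.05),
    cbind(base, stratum = "HIGH", prob = 0.02)
  )
  ov <- function(gene, group, stratum, prob) {
    data.frame(gene = gene, group = group, stratum = stratum, prob = prob,
               stringsAsFactors = FALSE)
  }
  overrides <- rbind(
    ov("TP53", "hgOvCa", "HIGH", 0.40),
    ov("TP53", "hgOvCa", "MODERATE", 0.35),
    ov("TP53", c("BOT", "BOT.V600E", "lgOvCa"), "HIGH", 0.01),
    ov("TP53", c("BOT", "BOT.V600E", "lgOvCa"), "MODERATE", 0.03),
    ov("BRCA1", "hgOvCa", "HIGH", 0.30),
    ov("BRCA1", "BOT", "MODERATE", 0.30),
    ov("BRCA2", "BOT", "MODERATE", 0.30),
    ov("BRCA2", "hgOvCa", "MODERATE", 0.12),
    ov("SEM1", "BOT", "MODERATE", 0.50),
    ov("SEM1", c("BOT.V600E", "lgOvCa", "hgOvCa"), "MODERATE", 0.22),
    ov("FANCA", "BOT", "MODERATE", 0.35),
    ov("KRAS", c("BOT", "lgOvCa"), "MODERATE", 0.40),
    ov("KRAS", c("BOT.V600E", "hgOvCa"), "MODERATE", 0.05),
    ov("NRAS", "lgOvCa", "MODERATE", 0.30),
    ov("BRAF", "BOT.V600E", "MODERATE", 1.00),
    ov("BRAF", "BOT", "MODERATE", 0.05)
  )
  overrides <- overrides[overrides$gene %in% panel$genes, , drop = FALSE]
  key <- function(d) paste(d$gene, d$group, d$stratum)
  keep <- !(key(baseline) %in% key(overrides))
  out <- rbind(overrides, baseline[keep, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Synthetic cohort configuration
#'
#' Collects every knob of the generator and validates the invariants
#' (probabilities in \[0, 1\], non-negative group sizes, effect genes
#' inside the panel).  Defaults reproduce the study-like cohort
#' structure: group sizes 53/23/10/139, a ~30% censoring fraction and
#' an expectation of two sub-threshold VAF decoys per sample.
#'
#' @param group_sizes Named integer vector over
#'   `BOT, BOT.V600E, lgOvCa, hgOvCa`.
#' @param panel An `ov_panel` (see [default_panel()]).
#' @param gene_freqs Data frame `gene, group, stratum, prob` of planted
#'   alteration probabilities; `stratum` is `HIGH`, `MODERATE` or
#'   `HIGH_OR_MODERATE` (impact drawn 50/50).
#' @param noise_vaf_rate Expected count per sample of decoy calls with
#'   VAF below 0.10 (Poisson).
#' @param decoy_rate Expected count per sample of each remaining decoy
#'   family (depth, qual, mapq, alt_bases, impact, retention).
#' @param lowcov_region_rate Probability that a sample-region is
#'   simulated with mean depth below 5 reads.
#' @param survival_effects Data frame `gene, endpoint, log_hr` with
#'   endpoint in `OS, DFS, RFS`; `NULL` for none.
#' @param response_effects Data frame `gene, outcome, log_or` with
#'   outcome in `CR, PS, microinvasion_or_implants`; `NULL` for none.
#' @param censoring_rate Expected censored fraction in \[0, 1).
#' @param seed Integer seed fixing every random draw.
#' @return An `ov_cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(BOT = 53, BOT.V600E = 23,
                                          lgOvCa = 10, hgOvCa = 139),
                          panel = default_panel("genes44"),
                          gene_freqs = default_gene_freqs(panel),
                          noise_vaf_rate = 2,
                          decoy_rate = 0.5,
                          lowcov_region_rate = 0.02,
                          survival_effects = NULL,
                          response_effects = NULL,
                          censoring_rate = 0.3,
                          seed = 1L) {
  names(group_sizes) <- sub("^BOT\\.V600E$", "BOT.V600E", names(group_sizes))
  if (!all(names(group_sizes) %in% .OV_GROUPS)) {
    stop("configuration error: unknown group name(s) in 'group_sizes': ",
         paste(setdiff(names(group_sizes), .OV_GROUPS), collapse = ", "))
  }
  sizes <- stats::setNames(rep(0L, 4L), .OV_GROUPS)
  sizes[names(group_sizes)] <- as.integer(group_sizes)
  if (any(sizes < 0)) stop("configuration error: negative group size")
  stopifnot(inherits(panel, "ov_panel"))
  stopifnot(all(c("gene", "group", "stratum", "prob") %in% names(gene_freqs)))
  if (any(gene_freqs$prob < 0 | gene_freqs$prob > 1)) {
    stop("configuration error: gene_freqs probabilities must lie in [0, 1]")
  }
  if (!all(gene_freqs$stratum %in% .OV_STRATA)) {
    stop("configuration error: unknown stratum in gene_freqs")
  }
  if (!all(gene_freqs$gene %in% panel$genes)) {
    stop("configuration error: gene_freqs gene(s) not in panel: ",
         paste(setdiff(gene_freqs$gene, panel$genes), collapse = ", "))
  }
  check_effects <- function(eff, col, what) {
    if (is.null(eff)) return(NULL)
    stopifnot(all(c("gene", col) %in% names(eff)))
    if (!all(eff$gene %in% panel$genes)) {
      stop("configuration error: ", what, " on gene(s) absent from panel: ",
           paste(setdiff(eff$gene, panel$genes), collapse = ", "))
    }
    eff
  }
  survival_effects <- check_effects(survival_effects, "log_hr",
                                    "survival effect")
  if (!is.null(survival_effects) &&
      !all(survival_effects$endpoint %in% c("OS", "DFS", "RFS"))) {
    stop("configuration error: survival endpoint must be OS, DFS or RFS")
  }
  response_effects <- check_effects(response_effects, "log_or",
                                    "response effect")
  if (!is.null(response_effects) &&
      !all(response_effects$outcome %in%
             c("CR", "PS", "microinvasion_or_implants"))) {
    stop("configuration error: response outcome must be CR, PS or ",
         "microinvasion_or_implants")
  }
  stopifnot(noise_vaf_rate >= 0, decoy_rate >= 0,
            lowcov_region_rate >= 0, lowcov_region_rate <= 1,
            censoring_rate >= 0, censoring_rate < 1)
  structure(
    list(group_sizes = sizes, panel = panel, gene_freqs = gene_freqs,
         noise_vaf_rate = noise_vaf_rate, decoy_rate = decoy_rate,
         lowcov_region_rate = lowcov_region_rate,
         survival_effects = survival_effects,
         response_effects = response_effects,
         censoring_rate = censoring_rate, seed = as.integer(seed)),
    class = "ov_cohort_config"
  )
}

# -- internal draw helpers ---------------------------------------------------

.rand_seq <- function(n) {
  vapply(n, function(k) paste(sample(.BASES, k, replace = TRUE),
                              collapse = ""), character(1))
}

.other_base <- function(ref) {
  vapply(ref, function(b) sample(setdiff(.BASES, b), 1L), character(1))
}

# Draw REF/ALT/class for k planted or decoy calls (class mix fixed).
.draw_alleles <- function(k) {
  cls <- sample(c("snp", "indel", "mnp", "other"), k, replace = TRUE,
                prob = c(0.80, 0.12, 0.05, 0.03))
  ref <- character(k); alt <- character(k)
  is_snp <- cls == "snp"
  ref[is_snp] <- sample(.BASES, sum(is_snp), replace = TRUE)
  alt[is_snp] <- .other_base(ref[is_snp])
  is_ind <- cls == "indel"
  if (any(is_ind)) {
    ins <- stats::runif(sum(is_ind)) < 0.3
    len <- sample(1:5, sum(is_ind), replace = TRUE)
    anchor <- sample(.BASES, sum(is_ind), replace = TRUE)
    tail <- .rand_seq(len)
    ref[is_ind] <- ifelse(ins, anchor, paste0(anchor, tail))
    alt[is_ind] <- ifelse(ins, paste0(anchor, tail), anchor)
  }
  is_mnp <- cls == "mnp"
  if (any(is_mnp)) {
    r1 <- sample(.BASES, sum(is_mnp), replace = TRUE)
    r2 <- sample(.BASES, sum(is_mnp), replace = TRUE)
    ref[is_mnp] <- paste0(r1, r2)
    alt[is_mnp] <- paste0(.other_base(r1), .other_base(r2))
  }
  is_oth <- cls == "other"
  if (any(is_oth)) {
    ref[is_oth] <- sample(.BASES, sum(is_oth), replace = TRUE)
    alt[is_oth] <- "<DUP>"
  }
  data.frame(variant_class = cls, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# Evidence fields for retained-eligible calls: VAF in [0.2, 0.9], all
# quality gates passed with margin.
.passing_evidence <- function(k) {
  vaf <- stats::runif(k, 0.20, 0.90)
  depth <- as.integer(round(stats::runif(k, 50, 250)))
  alt_depth <- pmax(2L, as.integer(round(vaf * depth)))
  data.frame(
    qual = round(stats::runif(k, 30, 90), 1),
    mapq = as.integer(round(stats::runif(k, 40, 60))),
    depth = depth,
    ref_depth = depth - alt_depth,
    alt_depth = alt_depth
  )
}

# Annotation retention profile for calls meant to survive the cascade.
.passing_annotation <- function(k) {
  profile <- sample(c("novel", "clinsig", "sift", "allempty", "rareaf"),
                    k, replace = TRUE, prob = c(0.55, 0.15, 0.10, 0.10, 0.10))
  rsid <- sprintf("rs%07d", sample.int(9999999L, k, replace = TRUE))
  data.frame(
    Existing_variation = ifelse(profile == "novel", "", rsid),
    CLIN_SIG = c(novel = "", clinsig = "pathogenic", sift = "benign",
                 allempty = "", rareaf = "benign")[profile],
    SIFT = c(novel = "", clinsig = "", sift = "deleterious",
             allempty = "", rareaf = "tolerated")[profile],
    PolyPhen = c(novel = "", clinsig = "", sift = "benign",
                 allempty = "", rareaf = "benign")[profile],
    MAX_AF = c(novel = NA, clinsig = 0.2, sift = 0.2,
               allempty = 0.3, rareaf = 0.005)[profile],
    stringsAsFactors = FALSE
  )
}

.consequence_for <- function(impact) {
  ifelse(impact == "HIGH",
         sample(c("stop_gained", "frameshift_variant"),
                length(impact), replace = TRUE),
         ifelse(impact == "MODERATE", "missense_variant",
                ifelse(impact == "LOW", "splice_region_variant",
                       "intron_variant")))
}

.hgvsp_for <- function(k) {
  aa <- c("Ala", "Arg", "Asn", "Cys", "Gln", "Glu", "Gly", "Leu", "Lys",
          "Phe", "Ser", "Thr", "Trp", "Tyr", "Val")
  sprintf("p.%s%d%s", sample(aa, k, TRUE), sample.int(900L, k, TRUE),
          sample(c(aa, "Ter"), k, TRUE))
}

# Positions: one random locus inside an unmasked region of the gene for
# that sample.  `avail` is the region table already restricted to the
# sample's unmasked regions.
.place_in_regions <- function(avail, idx) {
  reg <- avail[idx, , drop = FALSE]
  off <- as.integer(floor(stats::runif(nrow(reg)) * (reg$end - reg$start + 1L)))
  list(chrom = reg$chrom, pos = reg$start + off)
}

#' Generate a synthetic cohort bundle
#'
#' Draws the clinical table, planted and decoy variant calls, their
#' functional annotations and the per-sample per-region depth table.
#' Every planted alteration is retained-eligible (VAF at least 0.10,
#' all quality gates passed, impact inside its stratum, annotation
#' satisfying at least one retention rule, region not coverage-masked);
#' every decoy violates exactly one gate and carries that gate's tag.
#' Survival times come from a proportional-hazards model with
#' exponential group baselines and the configured log-hazard-ratios;
#' binary responses from a logistic model with the configured log-odds
#' ratios.  Deterministic given `config$seed`.
#'
#' @param config An `ov_cohort_config` from [cohort_config()].
#' @return An `ov_cohort`: list with data frames `clinical`, `calls`,
#'   `annotations`, `depth`, plus the `panel` and `config`.  `calls`
#'   carries truth columns `gene`, `origin` (`planted`/`decoy`) and
#'   `decoy_gate`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ov_cohort_config"))
  set.seed(config$seed)
  panel <- config$panel
  sizes <- config$group_sizes
  n <- sum(sizes)
  group <- rep(names(sizes), times = sizes)
  sample_id <- sprintf("S%04d", seq_len(max(n, 0L)))

  clinical <- .draw_clinical_base(sample_id, group)

  # depth table + low-coverage mask -----------------------------------------
  reg <- panel$regions
  grid <- data.frame(
    SAMPLE = rep(sample_id, each = nrow(reg)),
    CHROM = rep(reg$chrom, times = length(sample_id)),
    START = rep(reg$start, times = length(sample_id)),
    END = rep(reg$end, times = length(sample_id)),
    GENE = rep(reg$gene, times = length(sample_id)),
    stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$SAMPLE, grid$GENE, grid$START), , drop = FALSE]
  lowcov <- stats::runif(nrow(grid)) < config$lowcov_region_rate
  md <- numeric(nrow(grid))
  md[lowcov] <- round(stats::runif(sum(lowcov), 0, 4.99), 2)
  md[!lowcov] <- round(pmax(5, stats::rnorm(sum(!lowcov), 150, 30)), 2)
  depth_tbl <- cbind(grid, MEAN_DEPTH = md)
  rownames(depth_tbl) <- NULL

  # region availability per sample (unmasked only)
  avail_key <- paste(depth_tbl$SAMPLE[!lowcov], depth_tbl$GENE[!lowcov])
  avail <- data.frame(sample_id = depth_tbl$SAMPLE[!lowcov],
                      gene = depth_tbl$GENE[!lowcov],
                      chrom = depth_tbl$CHROM[!lowcov],
                      start = depth_tbl$START[!lowcov],
                      end = depth_tbl$END[!lowcov],
                      stringsAsFactors = FALSE)

  # planted alterations ------------------------------------------------------
  gf <- config$gene_freqs
  plant <- vector("list", nrow(gf))
  for (i in seq_len(nrow(gf))) {
    ids <- sample_id[group == gf$group[i]]
    if (!length(ids) || gf$prob[i] == 0) next
    hit <- ids[stats::runif(length(ids)) < gf$prob[i]]
    # only placeable where the gene has an unmasked region
    hit <- hit[paste(hit, gf$gene[i]) %in% avail_key]
    if (!length(hit)) next
    plant[[i]] <- data.frame(sample_id = hit, gene = gf$gene[i],
                             stratum = gf$stratum[i],
                             stringsAsFactors = FALSE)
  }
  plant <- do.call(rbind, plant)

  calls <- list(); anns <- list()
  if (!is.null(plant) && nrow(plant)) {
    k <- nrow(plant)
    impact <- ifelse(plant$stratum == "HIGH_OR_MODERATE",
                     sample(c("HIGH", "MODERATE"), k, replace = TRUE),
                     plant$stratum)
    # pick one unmasked region per planted call
    pos <- .place_planted(plant, avail)
    al <- .draw_alleles(k)
    ev <- .passing_evidence(k)
    ann <- .passing_annotation(k)
    calls[["planted"]] <- data.frame(
      sample_id = plant$sample_id, chrom = pos$chrom, pos = pos$pos,
      ref = al$ref, alt = al$alt, variant_class = al$variant_class,
      qual = ev$qual, mapq = ev$mapq, depth = ev$depth,
      ref_depth = ev$ref_depth, alt_depth = ev$alt_depth,
      gene = plant$gene, origin = "planted", decoy_gate = NA_character_,
      stringsAsFactors = FALSE
    )
    anns[["planted"]] <- data.frame(
      SAMPLE = plant$sample_id, CHROM = pos$chrom, POS = pos$pos,
      REF = al$ref, ALT = al$alt, SYMBOL = plant$gene,
      Consequence = .consequence_for(impact), IMPACT = impact,
      Existing_variation = ann$Existing_variation, CLIN_SIG = ann$CLIN_SIG,
      SIFT = ann$SIFT, PolyPhen = ann$PolyPhen, MAX_AF = ann$MAX_AF,
      HGVSp = .hgvsp_for(k), stringsAsFactors = FALSE
    )
    # extra lower-impact transcript rows for ~30% of planted variants,
    # exercising the consolidation step
    extra <- which(stats::runif(k) < 0.3)
    if (length(extra)) {
      e <- anns[["planted"]][extra, , drop = FALSE]
      e$IMPACT <- "MODIFIER"; e$Consequence <- "intron_variant"
      e$SIFT <- ""; e$PolyPhen <- ""; e$HGVSp <- ""
      anns[["extra"]] <- e
    }
  }

  # decoys -------------------------------------------------------------------
  dec <- .draw_decoys(sample_id, avail, config)
  if (!is.null(dec)) {
    calls[["decoy"]] <- dec$calls
    anns[["decoy"]] <- dec$annotations
  }

  calls <- if (length(calls)) do.call(rbind, calls) else .empty_calls()
  anns <- if (length(anns)) do.call(rbind, anns) else .empty_annotations()
  ord <- order(calls$sample_id, calls$chrom, calls$pos, calls$ref, calls$alt)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  ord <- order(anns$SAMPLE, anns$CHROM, anns$POS, anns$REF, anns$ALT,
               anns$IMPACT)
  anns <- anns[ord, , drop = FALSE]
  rownames(anns) <- NULL

  # endpoints ----------------------------------------------------------------
  altered <- .altered_indicator(calls, sample_id)
  clinical <- .draw_responses(clinical, altered, config)
  clinical <- .draw_survival(clinical, altered, config)

  structure(list(clinical = clinical, calls = calls, annotations = anns,
                 depth = depth_tbl, panel = panel, config = config),
            class = "ov_cohort")
}

.place_planted <- function(plant, avail) {
  key <- paste(plant$sample_id, plant$gene)
  akey <- paste(avail$sample_id, avail$gene)
  split_idx <- split(seq_len(nrow(avail)), akey)
  pick <- vapply(key, function(kk) {
    idx <- split_idx[[kk]]
    if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
  }, integer(1))
  .place_in_regions(avail, pick)
}

.empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), variant_class = character(),
             qual = numeric(), mapq = integer(), depth = integer(),
             ref_depth = integer(), alt_depth = integer(), gene = character(),
             origin = character(), decoy_gate = character(),
             stringsAsFactors = FALSE)
}

.empty_annotations <- function() {
  data.frame(SAMPLE = character(), CHROM = character(), POS = integer(),
             REF = character(), ALT = character(), SYMBOL = character(),
             Consequence = character(), IMPACT = character(),
             Existing_variation = character(), CLIN_SIG = character(),
             SIFT = character(), PolyPhen = character(), MAX_AF = numeric(),
             HGVSp = character(), stringsAsFactors = FALSE)
}

# Each decoy family violates exactly one gate so that filter tests can
# attribute removals:
#   VAF       alt/(ref+alt) in [0.02, 0.095], everything else passing
#   depth     DP in 0..4 (AD unaffected; AD and DP are independent)
#   qual      QUAL in [0, 19.9]
#   mapq      MQ in 0..19
#   alt_bases AD alt = 1 with VAF still >= 0.10
#   impact    all QC gates pass, annotation impact LOW/MODIFIER
#   retention all QC gates pass, MODERATE impact, but known + benign +
#             tolerated + common (fails every retention rule)
.draw_decoys <- function(sample_id, avail, config) {
  n <- length(sample_id)
  if (!n || !nrow(avail)) return(NULL)
  fams <- c("VAF", "depth", "qual", "mapq", "alt_bases", "impact", "retention")
  rates <- c(VAF = config$noise_vaf_rate,
             stats::setNames(rep(config$decoy_rate, 6L), fams[-1]))
  counts <- lapply(fams, function(f) stats::rpois(n, rates[[f]]))
  names(counts) <- fams
  tot <- vapply(counts, sum, integer(1))
  if (sum(tot) == 0) return(NULL)
  gate <- rep(fams, times = tot)
  sid <- unlist(lapply(fams, function(f) rep(sample_id, counts[[f]])),
                use.names = FALSE)
  k <- length(sid)
  # place each decoy inside one of its sample's unmasked regions
  split_idx <- split(seq_len(nrow(avail)), avail$sample_id)
  ok <- sid %in% names(split_idx)
  sid <- sid[ok]; gate <- gate[ok]; k <- length(sid)
  if (!k) return(NULL)
  pick <- vapply(sid, function(s) {
    idx <- split_idx[[s]]
    if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
  }, integer(1))
  pos <- .place_in_regions(avail, pick)
  gene <- avail$gene[pick]
  al <- .draw_alleles(k)
  ev <- .passing_evidence(k)

  i <- gate == "VAF"
  if (any(i)) {
    a <- sample(2:3, sum(i), replace = TRUE)
    vaf <- stats::runif(sum(i), 0.02, 0.095)
    r <- as.integer(ceiling(a / vaf)) - a
    ev$alt_depth[i] <- a; ev$ref_depth[i] <- r
    ev$depth[i] <- pmax(ev$depth[i], a + r)
  }
  i <- gate == "depth"
  if (any(i)) ev$depth[i] <- sample(0:4, sum(i), replace = TRUE)
  i <- gate == "qual"
  if (any(i)) ev$qual[i] <- round(stats::runif(sum(i), 0, 19.9), 1)
  i <- gate == "mapq"
  if (any(i)) ev$mapq[i] <- sample(0:19, sum(i), replace = TRUE)
  i <- gate == "alt_bases"
  if (any(i)) {
    ev$alt_depth[i] <- 1L
    ev$ref_depth[i] <- sample(0:8, sum(i), replace = TRUE)  # VAF >= 1/9
  }

  impact <- rep("HIGH", k)
  impact[gate == "impact"] <- sample(c("LOW", "MODIFIER"),
                                     sum(gate == "impact"), replace = TRUE)
  impact[gate == "retention"] <- "MODERATE"
  ann <- .passing_annotation(k)
  # impact decoys keep a passing (novel) annotation; retention decoys
  # fail all five rules
  i <- gate == "impact"
  ann$Existing_variation[i] <- ""
  ann$CLIN_SIG[i] <- ""; ann$SIFT[i] <- ""; ann$PolyPhen[i] <- ""
  ann$MAX_AF[i] <- NA
  i <- gate == "retention"
  ann$Existing_variation[i] <- sprintf("rs%07d",
                                       sample.int(9999999L, sum(i), TRUE))
  ann$CLIN_SIG[i] <- "benign"; ann$SIFT[i] <- "tolerated"
  ann$PolyPhen[i] <- "benign"; ann$MAX_AF[i] <- 0.45

  list(
    calls = data.frame(
      sample_id = sid, chrom = pos$chrom, pos = pos$pos,
      ref = al$ref, alt = al$alt, variant_class = al$variant_class,
      qual = ev$qual, mapq = ev$mapq, depth = ev$depth,
      ref_depth = ev$ref_depth, alt_depth = ev$alt_depth,
      gene = gene, origin = "decoy", decoy_gate = gate,
      stringsAsFactors = FALSE
    ),
    annotations = data.frame(
      SAMPLE = sid, CHROM = pos$chrom, POS = pos$pos,
      REF = al$ref, ALT = al$alt, SYMBOL = gene,
      Consequence = .consequence_for(impact), IMPACT = impact,
      Existing_variation = ann$Existing_variation, CLIN_SIG = ann$CLIN_SIG,
      SIFT = ann$SIFT, PolyPhen = ann$PolyPhen, MAX_AF = ann$MAX_AF,
      HGVSp = .hgvsp_for(k), stringsAsFactors = FALSE
    )
  )
}

.draw_clinical_base <- function(sample_id, group) {
  n <- length(sample_id)
  is_bots <- group %in% c("BOT", "BOT.V600E")
  serous_p <- c(BOT = 0.80, BOT.V600E = 0.80, lgOvCa = 0.90,
                hgOvCa = 0.81)[group]
  histotype <- ifelse(stats::runif(n) < serous_p, "serous", "other")
  age_mean <- ifelse(group == "BOT.V600E", 42, 55)  # V600E patients younger
  age <- round(pmin(95, pmax(18, stats::rnorm(n, age_mean, 12))), 1)
  primary_tumor <- ifelse(is_bots, stats::runif(n) < 0.9, TRUE)
  chemo <- character(n)
  chemo[is_bots] <- ifelse(stats::runif(sum(is_bots)) < 60 / 76, "none",
                           sample(c("PC", "TP"), sum(is_bots), TRUE))
  chemo[!is_bots] <- sample(c("PC", "TP"), sum(!is_bots), TRUE,
                            prob = c(35, 112))
  tp53_accumulation <- ifelse(is_bots, NA, stats::runif(n) < 0.5)
  figo_stage <- integer(n)
  figo_stage[is_bots] <- sample(1:2, sum(is_bots), TRUE, prob = c(0.8, 0.2))
  lg <- group == "lgOvCa"
  figo_stage[lg] <- sample(1:4, sum(lg), TRUE, prob = c(0.2, 0.2, 0.4, 0.2))
  hg <- group == "hgOvCa"
  figo_stage[hg] <- sample(1:4, sum(hg), TRUE,
                           prob = c(0.05, 0.10, 0.55, 0.30))
  residual_tumor <- rep("none", n)  # all BOT patients have none
  residual_tumor[!is_bots] <- sample(c("none", "lt2cm", "ge2cm"),
                                     sum(!is_bots), TRUE,
                                     prob = c(0.40, 0.35, 0.25))
  data.frame(sample_id = sample_id, group = group, histotype = histotype,
             age = age, primary_tumor = primary_tumor, chemo = chemo,
             tp53_accumulation = tp53_accumulation, figo_stage = figo_stage,
             residual_tumor = residual_tumor, stringsAsFactors = FALSE)
}

# 0/1 indicator matrix of planted alterations (any stratum) used to
# apply the configured endpoint effects.
.altered_indicator <- function(calls, sample_id) {
  planted <- calls[calls$origin == "planted", c("sample_id", "gene")]
  function(gene) {
    as.numeric(sample_id %in% planted$sample_id[planted$gene == gene])
  }
}

.draw_responses <- function(clinical, altered, config) {
  n <- nrow(clinical)
  is_bots <- clinical$group %in% c("BOT", "BOT.V600E")
  eff <- config$response_effects
  lp_for <- function(outcome) {
    lp <- rep(stats::qlogis(.BASE_RESPONSE[[outcome]]), n)
    if (!is.null(eff)) {
      for (i in which(eff$outcome == outcome)) {
        lp <- lp + eff$log_or[i] * altered(eff$gene[i])
      }
    }
    lp
  }
  cr <- stats::runif(n) < stats::plogis(lp_for("CR"))
  ps <- stats::runif(n) < stats::plogis(lp_for("PS"))
  mi <- stats::runif(n) < stats::plogis(lp_for("microinvasion_or_implants"))
  clinical$cr <- ifelse(is_bots, NA, cr)
  clinical$ps <- ifelse(is_bots, NA, ps)
  # split the combined borderline-tumor outcome into its two flags
  micro <- logical(n); impl <- logical(n)
  which_mi <- which(is_bots & mi)
  if (length(which_mi)) {
    u <- stats::runif(length(which_mi))
    micro[which_mi] <- u < 0.7
    impl[which_mi] <- u >= 0.3  # overlap keeps both flags realistic
  }
  clinical$microinvasion <- ifelse(is_bots, micro, NA)
  clinical$implants <- ifelse(is_bots, impl, NA)
  clinical
}

.draw_survival <- function(clinical, altered, config) {
  n <- nrow(clinical)
  eff <- config$survival_effects
  cens <- config$censoring_rate
  draw <- function(endpoint) {
    base_rate <- log(2) / .BASE_MEDIANS[[endpoint]][clinical$group]
    lp <- rep(0, n)
    if (!is.null(eff)) {
      for (i in which(eff$endpoint == endpoint)) {
        lp <- lp + eff$log_hr[i] * altered(eff$gene[i])
      }
    }
    te <- stats::rexp(n, base_rate * exp(lp))
    tc <- if (cens > 0) {
      stats::rexp(n, base_rate * cens / (1 - cens))
    } else rep(Inf, n)
    list(time = round(pmin(te, tc), 3), event = te <= tc)
  }
  os <- draw("OS"); rfs <- draw("RFS"); dfs <- draw("DFS")
  clinical$os_time <- os$time; clinical$os_event <- os$event
  clinical$rfs_time <- rfs$time; clinical$rfs_event <- rfs$event
  # DFS only defined for carcinoma patients who achieved CR
  has_dfs <- !is.na(clinical$cr) & clinical$cr
  clinical$dfs_time <- ifelse(has_dfs, dfs$time, NA)
  clinical$dfs_event <- ifelse(has_dfs, dfs$event, NA)
  clinical
}

#' @export
print.ov_cohort <- function(x, ...) {
  cat(sprintf(
    "<ov_cohort> %d samples (%s), %d calls (%d planted / %d decoy), panel %s\n",
    nrow(x$clinical),
    paste(sprintf("%s=%d", names(table(x$clinical$group)),
                  table(x$clinical$group)), collapse = ", "),
    nrow(x$calls), sum(x$calls$origin == "planted"),
    sum(x$calls$origin == "decoy"), x$panel$name))
  invisible(x)
}
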