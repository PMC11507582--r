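# Serialization of cohort bundles.
#
# On-disk layout (all plain text):
#   clinical.csv            one row per patient
#   annotations.tsv         VEP-style annotation table
#   depth.tsv               per-sample per-region mean coverage depths
#   vcf/<sample>.vcf        VCF v4.2, FORMAT GT:DP:AD, INFO MQ (+ truth tags)
#   config.dcf, gene_freqs.tsv, panel_regions.tsv, *_effects.tsv
# Coordinates are 1-based inclusive throughout (VCF convention).

.ANN_COLS <- c("SAMPLE", "CHROM", "POS", "REF", "ALT", "SYMBOL",
               "Consequence", "IMPACT", "Existing_variation", "CLIN_SIG",
               "SIFT", "PolyPhen", "MAX_AF", "HGVSp")

#' Write a cohort bundle to a directory
#'
#' Emits one VCF per sample (with `AD`, `DP` and `MQ` populated), the
#' annotation TSV, the depth TSV, the clinical CSV and the serialized
#' configuration.  [read_bundle()] reproduces the bundle from these
#' files.
#'
#' @param bundle An `ov_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ov_cohort"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2L) != 0L) {
    stop("I/O error: cannot write to directory ", dir)
  }
  dir.create(file.path(dir, "vcf"), showWarnings = FALSE)
  utils::write.csv(bundle$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, na = "")
  .write_tsv(bundle$annotations[, .ANN_COLS, drop = FALSE],
             file.path(dir, "annotations.tsv"))
  .write_tsv(bundle$depth, file.path(dir, "depth.tsv"))
  for (sid in bundle$clinical$sample_id) {
    calls <- bundle$calls[bundle$calls$sample_id == sid, , drop = FALSE]
    .write_vcf(calls, sid, file.path(dir, "vcf", paste0(sid, ".vcf")),
               contigs = unique(bundle$panel$regions$chrom))
  }
  .write_config(bundle$config, dir)
  invisible(dir)
}

#' Read a cohort bundle from a directory
#'
#' @param dir Directory previously written by [write_bundle()].
#' @return An `ov_cohort`.
#' @export
read_bundle <- function(dir) {
  if (!dir.exists(dir)) stop("I/O error: no such directory: ", dir)
  clin_path <- file.path(dir, "clinical.csv")
  if (!file.exists(clin_path)) stop("missing input file: ", clin_path)
  clinical <- utils::read.csv(clin_path, stringsAsFactors = FALSE,
                              colClasses = .CLINICAL_CLASSES)
  ann <- utils::read.delim(file.path(dir, "annotations.tsv"),
                           stringsAsFactors = FALSE,
                           colClasses = .ANN_CLASSES)
  depth <- utils::read.delim(file.path(dir, "depth.tsv"),
                             stringsAsFactors = FALSE,
                             colClasses = .DEPTH_CLASSES)
  calls <- lapply(clinical$sample_id, function(sid) {
    read_vcf_calls(file.path(dir, "vcf", paste0(sid, ".vcf")))
  })
  calls <- if (length(calls)) do.call(rbind, calls) else .empty_calls()
  rownames(calls) <- NULL
  config <- .read_config(dir)
  structure(list(clinical = clinical, calls = calls, annotations = ann,
                 depth = depth, panel = config$panel, config = config),
            class = "ov_cohort")
}

.CLINICAL_CLASSES <- c(
  sample_id = "character", group = "character", histotype = "character",
  age = "numeric", primary_tumor = "logical", chemo = "character",
  tp53_accumulation = "logical", figo_stage = "integer",
  residual_tumor = "character", cr = "logical", ps = "logical",
  microinvasion = "logical", implants = "logical",
  os_time = "numeric", os_event = "logical",
  rfs_time = "numeric", rfs_event = "logical",
  dfs_time = "numeric", dfs_event = "logical"
)

.ANN_CLASSES <- c(
  SAMPLE = "character", CHROM = "character", POS = "integer",
  REF = "character", ALT = "character", SYMBOL = "character",
  Consequence = "character", IMPACT = "character",
  Existing_variation = "character", CLIN_SIG = "character",
  SIFT = "character", PolyPhen = "character", MAX_AF = "numeric",
  HGVSp = "character"
)

.DEPTH_CLASSES <- c(SAMPLE = "character", CHROM = "character",
                    START = "integer", END = "integer", GENE = "character",
                    MEAN_DEPTH = "numeric")

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

.write_vcf <- function(calls, sample_id, path, contigs) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=ovascreen",
    paste0("##contig=<ID=", contigs, ">"),
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##INFO=<ID=MQ,Number=1,Type=Integer,Description=\"Mapping quality\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Panel gene\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Variant class\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"planted or decoy\">",
    "##INFO=<ID=GATE,Number=1,Type=String,Description=\"Violated gate of a decoy call\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t")
  )
  lines <- character(0)
  if (nrow(calls)) {
    info <- sprintf("MQ=%d;GENE=%s;CLASS=%s;ORIGIN=%s",
                    calls$mapq, calls$gene, calls$variant_class, calls$origin)
    has_gate <- !is.na(calls$decoy_gate)
    info[has_gate] <- paste0(info[has_gate], ";GATE=",
                             calls$decoy_gate[has_gate])
    lines <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                   calls$qual, ".", info, "GT:DP:AD",
                   sprintf("0/1:%d:%d,%d", calls$depth, calls$ref_depth,
                           calls$alt_depth),
                   sep = "\t")
  }
  writeLines(c(hdr, lines), path)
}

.info_get <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

.infer_class <- function(ref, alt) {
  ifelse(grepl("^<", alt) | alt == "*", "other",
         ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snp",
                ifelse(nchar(ref) == nchar(alt), "mnp", "indel")))
}

#' Read per-sample variant calls from a VCF file
#'
#' Parses a VCF v4.2 file with `GT:DP:AD` sample data into the
#' `VariantCall` table used by the filters.  Multi-allelic records are
#' split into one row per alternate allele, with `AD` taken per allele.
#'
#' @param path VCF file path.
#' @return Data frame of calls (one row per alternate allele).
#' @export
read_vcf_calls <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  if (!length(hdr_i)) stop("data error: no #CHROM header in ", path)
  hdr <- strsplit(lines[hdr_i[1]], "\t", fixed = TRUE)[[1]]
  sample_id <- if (length(hdr) >= 10L) hdr[10] else NA_character_
  body <- lines[-seq_len(hdr_i[1])]
  body <- body[nzchar(body)]
  if (!length(body)) return(.empty_calls())
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  alt_list <- strsplit(f[, 5], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rep_i <- rep(seq_len(nrow(f)), n_alt)
  alt_k <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  fmt_keys <- strsplit(f[, 9], ":", fixed = TRUE)
  fmt_vals <- strsplit(f[, 10], ":", fixed = TRUE)
  field <- function(i, key) {
    j <- match(key, fmt_keys[[i]])
    if (is.na(j)) NA_character_ else fmt_vals[[i]][j]
  }
  dp <- vapply(seq_len(nrow(f)), field, character(1), key = "DP")
  ad <- strsplit(vapply(seq_len(nrow(f)), field, character(1), key = "AD"),
                 ",", fixed = TRUE)
  info <- f[, 8]
  gate <- .info_get(info, "GATE")
  origin <- .info_get(info, "ORIGIN")
  cls <- .info_get(info, "CLASS")
  out <- data.frame(
    sample_id = rep(sample_id, length(rep_i)),
    chrom = f[rep_i, 1],
    pos = as.integer(f[rep_i, 2]),
    ref = f[rep_i, 4],
    alt = unlist(alt_list, use.names = FALSE),
    variant_class = cls[rep_i],
    qual = as.numeric(f[rep_i, 6]),
    mapq = as.integer(.info_get(info, "MQ"))[rep_i],
    depth = as.integer(dp)[rep_i],
    ref_depth = vapply(rep_i, function(i) as.integer(ad[[i]][1]), integer(1)),
    alt_depth = vapply(seq_along(rep_i), function(j) {
      as.integer(ad[[rep_i[j]]][1L + alt_k[j]])
    }, integer(1)),
    gene = .info_get(info, "GENE")[rep_i],
    origin = origin[rep_i],
    decoy_gate = gate[rep_i],
    stringsAsFactors = FALSE
  )
  miss <- is.na(out$variant_class)
  out$variant_class[miss] <- .infer_class(out$ref[miss], out$alt[miss])
  out
}

.write_config <- function(config, dir) {
  gs <- config$group_sizes
  dcf <- data.frame(
    panel = config$panel$name,
    panel_genes = paste(config$panel$genes, collapse = ","),
    panel_incidental = paste(config$panel$incidental, collapse = ","),
    group_sizes = paste(sprintf("%s=%d", names(gs), gs), collapse = ","),
    noise_vaf_rate = config$noise_vaf_rate,
    decoy_rate = config$decoy_rate,
    lowcov_region_rate = config$lowcov_region_rate,
    censoring_rate = config$censoring_rate,
    seed = config$seed
  )
  write.dcf(dcf, file.path(dir, "config.dcf"))
  .write_tsv(config$gene_freqs, file.path(dir, "gene_freqs.tsv"))
  .write_tsv(config$panel$regions, file.path(dir, "panel_regions.tsv"))
  if (!is.null(config$survival_effects)) {
    .write_tsv(config$survival_effects,
               file.path(dir, "survival_effects.tsv"))
  }
  if (!is.null(config$response_effects)) {
    .write_tsv(config$response_effects,
               file.path(dir, "response_effects.tsv"))
  }
}

.read_config <- function(dir) {
  dcf <- as.list(as.data.frame(read.dcf(file.path(dir, "config.dcf")),
                               stringsAsFactors = FALSE))
  regions <- utils::read.delim(file.path(dir, "panel_regions.tsv"),
                               stringsAsFactors = FALSE,
                               colClasses = c(chrom = "character",
                                              start = "integer",
                                              end = "integer",
                                              gene = "character"))
  genes <- strsplit(dcf$panel_genes, ",", fixed = TRUE)[[1]]
  incidental <- if (nzchar(dcf$panel_incidental)) {
    strsplit(dcf$panel_incidental, ",", fixed = TRUE)[[1]]
  } else character()
  panel <- new_panel(dcf$panel, genes, regions, incidental)
  gs_pairs <- strsplit(strsplit(dcf$group_sizes, ",", fixed = TRUE)[[1]],
                       "=", fixed = TRUE)
  gs <- stats::setNames(
    vapply(gs_pairs, function(p) as.integer(p[2]), integer(1)),
    vapply(gs_pairs, `[`, character(1), 1)
  )
  read_eff <- function(fname, classes) {
    p <- file.path(dir, fname)
    if (!file.exists(p)) return(NULL)
    utils::read.delim(p, stringsAsFactors = FALSE, colClasses = classes)
  }
  cohort_config(
    group_sizes = gs,
    panel = panel,
    gene_freqs = utils::read.delim(file.path(dir, "gene_freqs.tsv"),
                                   stringsAsFactors = FALSE,
                                   colClasses = c(gene = "character",
                                                  group = "character",
                                                  stratum = "character",
                                                  prob = "numeric")),
    noise_vaf_rate = as.numeric(dcf$noise_vaf_rate),
    decoy_rate = as.numeric(dcf$decoy_rate),
    lowcov_region_rate = as.numeric(dcf$lowcov_region_rate),
    survival_effects = read_eff("survival_effects.tsv",
                                c(gene = "character", endpoint = "character",
                                  log_hr = "numeric")),
    response_effects = read_eff("response_effects.tsv",
                                c(gene = "character", outcome = "character",
                                  log_or = "numeric")),
    censoring_rate = as.numeric(dcf$censoring_rate),
    seed = as.integer(dcf$seed)
  )
}
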