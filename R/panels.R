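# Shipped targeted-panel definitions.
#
# Two panels are bundled: a 44-gene hereditary ovarian cancer panel
# (exonic enrichment) and a 37-gene hot-spot panel targeting loci
# frequently mutated in sporadic cancers.  Region coordinates are
# synthetic stand-ins (one or two intervals per gene on a deterministic
# layout); the gene lists are the real panel contents.

.PANEL44_GENES <- c(
  "ATM", "ATR", "ATRX", "BAP1", "BARD1", "BCL2L1", "BLM", "BRCA1",
  "BRCA2", "BRIP1", "CCNE1", "CEBPA", "CHEK1", "CHEK2", "CRNDE",
  "EMSY", "FANCA", "FANCB", "FANCC", "FANCD2", "FANCE", "FANCF",
  "FANCG", "FANCI", "FANCL", "FANCM", "IRX5", "MDM2", "MRE11",
  "MUTYH", "NBN", "PALB2", "PARP1", "PIK3CA", "PRKDC", "PTEN",
  "RAD50", "RAD51B", "RAD51C", "RAD51D", "RAD54L", "RPA1", "SEM1",
  "TP53"
)

.HOTSPOT_GENES <- c(
  "AKT1", "ALK", "APC", "ATM", "BRAF", "BRCA1", "CDKN2A", "CTNNB1",
  "EGFR", "ERBB2", "ESR1", "FBXW7", "FGFR1", "FGFR2", "FGFR3",
  "GNA11", "GNAQ", "GNAS", "HRAS", "IDH1", "IDH2", "JAK2", "KIT",
  "KRAS", "NF1", "NRAS", "NTRK3", "PDGFRA", "PIK3CA", "POLE",
  "PTCH1", "PTEN", "RET", "STK11", "TP53", "TSC1", "TSC2"
)

# Deterministic synthetic region layout: gene i sits on chr((i-1) %% 22 + 1)
# at 1e6 + 5e4 * i.  1-based inclusive coordinates (VCF convention).
.panel_regions <- function(genes, n_regions, exon_len) {
  i <- seq_along(genes)
  chrom <- paste0("chr", ((i - 1L) %% 22L) + 1L)
  base <- 1e6 + 5e4 * i
  out <- do.call(rbind, lapply(seq_len(n_regions), function(k) {
    start <- as.integer(base + (k - 1L) * 2L * exon_len)
    data.frame(
      chrom = chrom,
      start = start,
      end = as.integer(start + exon_len - 1L),
      gene = genes,
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(match(out$gene, genes), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_panel <- function(name, genes, regions, incidental = character()) {
  stopifnot(is.character(genes), !anyDuplicated(genes))
  stopifnot(all(regions$gene %in% genes), all(regions$start <= regions$end))
  structure(
    list(name = name, genes = genes, regions = regions,
         incidental = incidental),
    class = "ov_panel"
  )
}

#' Shipped panel definitions
#'
#' Returns one of the two bundled panel definitions: `"genes44"`, the
#' 44-gene hereditary ovarian cancer panel (two synthetic exonic regions
#' per gene), or `"hotspot"`, the 37-gene hot-spot panel (one region per
#' gene).  Each panel also names its incidentally enriched neighbour
#' gene (`KCNMB3` overlapping *PIK3CA*; `FBXW7-AS1` antisense to
#' *FBXW7*), which downstream reporting flags separately.
#'
#' @param name `"genes44"` or `"hotspot"`.
#' @return An `ov_panel`: list with `name`, `genes` (character),
#'   `regions` (data frame `chrom`, `start`, `end`, `gene`; 1-based
#'   inclusive) and `incidental` (character).
#' @examples
#' length(default_panel("genes44")$genes)  # 44
#' length(default_panel("hotspot")$genes)  # 37
#' @export
default_panel <- function(name = c("genes44", "hotspot")) {
  name <- match.arg(name)
  if (name == "genes44") {
    new_panel("genes44", .PANEL44_GENES,
              .panel_regions(.PANEL44_GENES, n_regions = 2L, exon_len = 400L),
              incidental = "KCNMB3")
  } else {
    new_panel("hotspot", .HOTSPOT_GENES,
              .panel_regions(.HOTSPOT_GENES, n_regions = 1L, exon_len = 150L),
              incidental = "FBXW7-AS1")
  }
}

#' Number of distinct genes across panels
#'
#' @param panels A list of `ov_panel` objects (or a single panel).
#' @return Integer count of distinct gene symbols in the union.
#' @examples
#' panel_union_size(list(default_panel("genes44"), default_panel("hotspot")))
#' @export
panel_union_size <- function(panels) {
  if (inherits(panels, "ov_panel")) panels <- list(panels)
  stopifnot(all(vapply(panels, inherits, logical(1), "ov_panel")))
  length(unique(unlist(lapply(panels, `[[`, "genes"))))
}

#' @export
print.ov_panel <- function(x, ...) {
  cat(sprintf("<ov_panel> %s: %d genes, %d regions\n",
              x$name, length(x$genes), nrow(x$regions)))
  invisible(x)
}
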