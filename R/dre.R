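# Per-gene window assembly, DRE-target pair calling and classification,
# methylation-dynamics categories, and precision against chromatin
# interaction anchors.
#
# Coordinate conventions: positions are 1-based internally. A probe's
# anchor is its interval midpoint; a gene's anchor is its TSS (start on
# "+", end on "-"). Signed probe-TSS distance is measured 5'->3' relative
# to the gene's strand; classification uses |distance| with a closed
# boundary at 2000 bp for promoter vs distal.

#' Build a per-variable genomic annotation
#'
#' @param ids variable identifiers.
#' @param chrom chromosome names.
#' @param pos 1-based anchor position (probe coordinate or gene TSS).
#' @param strand `"+"`/`"-"` for genes, `"*"` otherwise.
#' @param kind `"gene"` or `"probe"` (scalar or per-id).
#' @return A [GenomicRanges::GRanges] with metadata columns `id`, `kind`.
#' @export
variableAnnotation <- function(ids, chrom, pos, strand = "*", kind) {
  if (any(pos < 1)) stop("positions must be >= 1 (1-based)", call. = FALSE)
  if (length(kind) == 1L) kind <- rep(kind, length(ids))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = pos, width = 1L),
                               strand = strand)
  S4Vectors::mcols(gr)$id <- as.character(ids)
  S4Vectors::mcols(gr)$kind <- as.character(kind)
  gr
}

.annoLookup <- function(anno, id, kind = NULL) {
  hit <- S4Vectors::mcols(anno)$id == id
  if (!is.null(kind)) hit <- hit & S4Vectors::mcols(anno)$kind == kind
  w <- which(hit)
  if (!length(w)) return(NULL)
  anno[w[1L]]
}

#' Assemble the analysis window of one target gene
#'
#' Collects the target gene, every annotated gene with TSS within
#' `windowBp` of the target TSS (closed interval), and every probe within
#' the same window, then merges their expression and methylation values
#' over the shared samples into one [OmicsMatrix-class].
#'
#' @param geneId target gene id (must be annotated and present in `expr`).
#' @param anno annotation `GRanges` from [variableAnnotation()] or
#'   [regionsToAnnotation()].
#' @param expr expression [OmicsMatrix-class] (genes x samples).
#' @param meth methylation [OmicsMatrix-class] (probes x samples).
#' @param windowBp half-width of the window around the TSS (default
#'   300000, i.e. +/- 300 kb).
#' @return The merged `OmicsMatrix`, or `NULL` (with a warning) when no
#'   probe falls inside the window.
#' @export
assembleWindow <- function(geneId, anno, expr, meth, windowBp = 300000L) {
  g <- .annoLookup(anno, geneId, "gene")
  if (is.null(g)) stop("gene ", geneId, " not found in annotation",
                       call. = FALSE)
  if (!geneId %in% varIds(expr))
    stop("gene ", geneId, " not found in the expression matrix",
         call. = FALSE)
  tss <- GenomicRanges::start(g)
  chrom <- as.character(GenomicRanges::seqnames(g))
  m <- S4Vectors::mcols(anno)
  same_chrom <- as.character(GenomicRanges::seqnames(anno)) == chrom
  within <- abs(GenomicRanges::start(anno) - tss) <= windowBp
  genes <- unique(m$id[same_chrom & within & m$kind == "gene"])
  probes <- unique(m$id[same_chrom & within & m$kind == "probe"])
  genes <- intersect(c(geneId, genes), varIds(expr))
  probes <- intersect(probes, varIds(meth))
  if (!length(probes)) {
    warning("no probes within ", windowBp, " bp of ", geneId,
            " TSS; gene skipped")
    return(NULL)
  }
  mergeOmics(expr[genes, ], meth[probes, ])
}

.signedDistance <- function(probePos, tss, strand) {
  d <- probePos - tss
  # strand may be scalar while probePos is a vector
  ifelse(rep_len(strand == "-", length(d)), -d, d)
}

#' Call DRE-target pairs for one gene window
#'
#' Runs the PC-algorithm cascade on the merged window matrix; every probe
#' directly connected to the target gene becomes a DRE-target pair with
#' its Pearson correlation, signed TSS distance, promoter/distal class,
#' correlation sign, and (when a DEG table is supplied) the target's
#' regulation direction.
#'
#' @param geneId target gene id.
#' @param merged merged window from [assembleWindow()].
#' @param params a [PcParams-class].
#' @param anno annotation `GRanges` (needed for distances).
#' @param degTable optional data.frame with columns `gene`, `log2FC`,
#'   `adj_p` used only to fill `target_direction` (filter
#'   `|log2FC| > 0.58` and `adj_p < 0.01`).
#' @return data.frame with one row per pair and columns `probe_id`,
#'   `gene_id`, `pcc`, `distance_bp`, `locus_class`, `corr_sign`,
#'   `target_direction`, `mi_bits`, `p_value`. Zero rows when no probe is
#'   directly connected.
#' @export
callDres <- function(geneId, merged, params = pcParams(), anno,
                     degTable = NULL) {
  stopifnot(is(merged, "OmicsMatrix"))
  net <- inferNetwork(merged, params)
  e <- networkEdges(net)
  kinds <- varKinds(merged)
  other <- ifelse(e$node_a == geneId, e$node_b,
                  ifelse(e$node_b == geneId, e$node_a, NA_character_))
  sel <- !is.na(other) & kinds[other] == "methylation"
  if (!any(sel)) return(.emptyDreTable())
  probes <- other[sel]
  g <- .annoLookup(anno, geneId, "gene")
  if (is.null(g)) stop("gene ", geneId, " not found in annotation",
                       call. = FALSE)
  tss <- GenomicRanges::start(g)
  strand <- as.character(GenomicRanges::strand(g))
  vals <- omValues(merged)
  pcc <- vapply(probes, function(p) stats::cor(vals[p, ], vals[geneId, ]),
                numeric(1))
  ppos <- vapply(probes, function(p) {
    a <- .annoLookup(anno, p, "probe")
    if (is.null(a)) stop("probe ", p, " not found in annotation",
                         call. = FALSE)
    GenomicRanges::start(a)
  }, numeric(1))
  out <- data.frame(probe_id = probes, gene_id = geneId, pcc = pcc,
                    distance_bp = .signedDistance(ppos, tss, strand),
                    locus_class = NA_character_, corr_sign = NA_character_,
                    target_direction = NA_character_,
                    mi_bits = e$mi_bits[sel], p_value = e$p_value[sel],
                    stringsAsFactors = FALSE, row.names = NULL)
  classifyDre(out, degTable)
}

.emptyDreTable <- function() {
  data.frame(probe_id = character(), gene_id = character(), pcc = numeric(),
             distance_bp = integer(), locus_class = character(),
             corr_sign = character(), target_direction = character(),
             mi_bits = numeric(), p_value = numeric(),
             stringsAsFactors = FALSE)
}

#' Classify DRE-target pairs
#'
#' Fills `locus_class` (promoter iff `|distance| <= 2000` bp, closed
#' boundary), `corr_sign` (`negative` iff `pcc < 0`; an exact zero is tie-
#' broken to `positive` with a message), and `target_direction` from an
#' optional differential-expression table (`up`/`down` for genes passing
#' `|log2FC| > 0.58` and `adj_p < 0.01`, `NA` otherwise or when no table
#' is given).
#'
#' @param pairs data.frame of DRE-target pairs (needs `pcc`,
#'   `distance_bp`, `gene_id`).
#' @param degTable optional data.frame with `gene`, `log2FC`, `adj_p`.
#' @param promoterBp promoter classification half-width (default 2000).
#' @return The annotated data.frame.
#' @export
classifyDre <- function(pairs, degTable = NULL, promoterBp = 2000L) {
  if (!nrow(pairs)) return(pairs)
  pairs$locus_class <- ifelse(abs(pairs$distance_bp) <= promoterBp,
                              "promoter", "distal")
  if (any(pairs$pcc == 0))
    message("classifyDre: ", sum(pairs$pcc == 0),
            " pair(s) with pcc exactly 0 tie-broken to 'positive'")
  pairs$corr_sign <- ifelse(pairs$pcc < 0, "negative", "positive")
  pairs$target_direction <- NA_character_
  if (!is.null(degTable)) {
    idx <- match(pairs$gene_id, degTable$gene)
    ok <- !is.na(idx) & abs(degTable$log2FC[idx]) > 0.58 &
      degTable$adj_p[idx] < 0.01
    dir <- ifelse(degTable$log2FC[idx] > 0, "up", "down")
    pairs$target_direction <- ifelse(!is.na(idx) & ok, dir, NA_character_)
  }
  pairs
}

#' Call DRE-target pairs for a set of genes
#'
#' Loops [assembleWindow()] and [callDres()] over the target genes;
#' duplicate (probe, gene) pairs arising from overlapping windows are
#' deduplicated keeping the smallest p-value. A probe may legitimately
#' appear in pairs with several genes.
#'
#' @param geneIds character vector of target gene ids.
#' @param anno annotation `GRanges`.
#' @param expr,meth expression and methylation [OmicsMatrix-class].
#' @param params a [PcParams-class].
#' @param windowBp window half-width in bp.
#' @param degTable optional DEG table, see [classifyDre()].
#' @return Combined DRE table (data.frame).
#' @export
callDresForGenes <- function(geneIds, anno, expr, meth,
                             params = pcParams(), windowBp = 300000L,
                             degTable = NULL) {
  tabs <- lapply(geneIds, function(g) {
    merged <- withCallingHandlers(
      assembleWindow(g, anno, expr, meth, windowBp),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(merged)) return(.emptyDreTable())
    callDres(g, merged, params, anno, degTable)
  })
  out <- do.call(rbind, tabs)
  if (!nrow(out)) return(out)
  ord <- order(out$probe_id, out$gene_id, out$p_value)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(out[, c("probe_id", "gene_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify methylation dynamics across disease stages
#'
#' Compares the mean beta difference at initiation (tumor - normal) with
#' the difference at progression (late - early stage). Categories:
#' `reversed` when both deltas exceed the tolerance with opposite signs;
#' otherwise `consistent` when the magnitudes agree within `tol`,
#' `stronger` when the progression change exceeds the initiation change by
#' more than `tol`, and `weaker` when it falls short by more than `tol`.
#'
#' @param deltaInitiation,deltaProgression numeric vectors of mean beta
#'   differences.
#' @param tol tolerance on the beta scale (default 0.05).
#' @param probeIds optional probe identifiers.
#' @return data.frame with `probe_id`, `delta_initiation`,
#'   `delta_progression`, `category`.
#' @export
classifyDynamics <- function(deltaInitiation, deltaProgression, tol = 0.05,
                             probeIds = NULL) {
  stopifnot(length(deltaInitiation) == length(deltaProgression),
            all(is.finite(deltaInitiation)), all(is.finite(deltaProgression)))
  di <- deltaInitiation; dp <- deltaProgression
  reversed <- sign(di) != sign(dp) & abs(di) > tol & abs(dp) > tol
  diffmag <- abs(dp) - abs(di)
  category <- ifelse(reversed, "reversed",
              ifelse(abs(diffmag) <= tol, "consistent",
              ifelse(diffmag > tol, "stronger", "weaker")))
  data.frame(probe_id = if (is.null(probeIds)) NA_character_ else probeIds,
             delta_initiation = di, delta_progression = dp,
             category = category, stringsAsFactors = FALSE)
}

#' Precision of DRE-target pairs against chromatin-interaction anchors
#'
#' Only negatively correlated pairs are evaluated. A pair is confirmed
#' when its probe position falls inside one anchor of an interaction and
#' the target promoter (TSS +/- `promoterBp`) overlaps the mate anchor, in
#' either orientation. The positive predictive value is reported overall
#' and binned by absolute TSS distance.
#'
#' @param pairs DRE table (needs `probe_id`, `gene_id`, `pcc`,
#'   `distance_bp`).
#' @param interactions anchor pairs as returned by
#'   `readRegions(..., format = "bedpe")`: a list with `GRanges` elements
#'   `first` and `second` of equal length.
#' @param anno annotation `GRanges` with probe positions and gene TSS.
#' @param breaks distance-bin breakpoints in bp.
#' @param promoterBp promoter half-width used as the gene-end anchor proxy.
#' @return list with `overall` PPV, `n_confirmed`, `n_pairs`, and a
#'   `by_bin` data.frame.
#' @export
pairPrecision <- function(pairs, interactions, anno,
                          breaks = c(0, 2e3, 2.5e4, 1e5, 3e5, Inf),
                          promoterBp = 2000L) {
  pairs <- pairs[pairs$pcc < 0, , drop = FALSE]
  n <- nrow(pairs)
  empty_int <- is.null(interactions) ||
    length(interactions$first) == 0L
  if (n == 0L || empty_int) {
    if (empty_int) warning("empty interaction set; PPV is 0")
    return(list(overall = 0, n_confirmed = 0L, n_pairs = n,
                by_bin = data.frame(bin = character(), n = integer(),
                                    confirmed = integer(), ppv = numeric())))
  }
  m <- S4Vectors::mcols(anno)
  pidx <- match(pairs$probe_id, m$id)
  gidx <- match(pairs$gene_id, m$id)
  if (anyNA(pidx) || anyNA(gidx))
    stop("pairs reference ids missing from the annotation", call. = FALSE)
  probe_gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(anno)[pidx],
    IRanges::IRanges(GenomicRanges::start(anno)[pidx], width = 1L))
  tss <- GenomicRanges::start(anno)[gidx]
  prom_gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(anno)[gidx],
    IRanges::IRanges(pmax(1L, tss - promoterBp), tss + promoterBp))
  confirmed <- logical(n)
  for (orient in 1:2) {
    g1 <- if (orient == 1L) interactions$first else interactions$second
    g2 <- if (orient == 1L) interactions$second else interactions$first
    hp <- GenomicRanges::findOverlaps(probe_gr, g1)
    hg <- GenomicRanges::findOverlaps(prom_gr, g2)
    key_p <- paste(S4Vectors::queryHits(hp), S4Vectors::subjectHits(hp))
    key_g <- paste(S4Vectors::queryHits(hg), S4Vectors::subjectHits(hg))
    ok <- unique(S4Vectors::queryHits(hp)[key_p %in% key_g])
    confirmed[ok] <- TRUE
  }
  bins <- cut(abs(pairs$distance_bp), breaks = breaks, include.lowest = TRUE)
  by_bin <- data.frame(
    bin = levels(bins),
    n = as.integer(table(bins)),
    confirmed = as.integer(tapply(confirmed, bins, sum, default = 0L)),
    stringsAsFactors = FALSE)
  by_bin$ppv <- ifelse(by_bin$n > 0, by_bin$confirmed / by_bin$n, NA_real_)
  list(overall = sum(confirmed) / n, n_confirmed = sum(confirmed),
       n_pairs = n, by_bin = by_bin)
}
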