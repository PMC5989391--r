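# TF-binding association with DREs, odds-ratio enrichment with confidence
# intervals, hypergeometric category enrichment, and the TF-expression vs
# binding-site-methylation correlation ranking.

#' Associate TF motif hits with DREs
#'
#' A DRE is associated with a TF when the interval probe position +/-
#' `flankBp` (closed on both ends) overlaps at least one motif hit of that
#' TF. Motif hits come from a BED-like `GRanges` with a `tf` metadata
#' column.
#'
#' @param dres DRE table (needs `probe_id`).
#' @param motifHits `GRanges` with a `tf` metadata column, e.g. from
#'   `readRegions(..., format = "bed")` with the name column holding the
#'   TF.
#' @param anno annotation `GRanges` with probe positions.
#' @param flankBp flank half-width (default 250).
#' @return Named list, TF -> character vector of associated probe ids.
#' @export
tfBindingAssociation <- function(dres, motifHits, anno, flankBp = 250L) {
  probes <- unique(dres$probe_id)
  m <- S4Vectors::mcols(anno)
  idx <- match(probes, m$id[m$kind == "probe"])
  pa <- anno[m$kind == "probe"]
  idx <- match(probes, S4Vectors::mcols(pa)$id)
  if (anyNA(idx))
    stop("probes missing from annotation: ",
         paste(probes[is.na(idx)], collapse = ", "), call. = FALSE)
  pchr <- as.character(GenomicRanges::seqnames(pa))[idx]
  hchr <- unique(as.character(GenomicRanges::seqnames(motifHits)))
  if (!length(intersect(unique(pchr), hchr)))
    stop("chromosome names do not match between probes (",
         paste(unique(pchr), collapse = ","), ") and motif hits (",
         paste(hchr, collapse = ","), ")", call. = FALSE)
  pos <- GenomicRanges::start(pa)[idx]
  flanks <- GenomicRanges::GRanges(
    pchr, IRanges::IRanges(pmax(1L, pos - flankBp), pos + flankBp))
  ov <- GenomicRanges::findOverlaps(flanks, motifHits)
  tf <- as.character(S4Vectors::mcols(motifHits)$tf)
  if (is.null(tf)) stop("motifHits needs a 'tf' metadata column",
                        call. = FALSE)
  hit_tf <- tf[S4Vectors::subjectHits(ov)]
  hit_probe <- probes[S4Vectors::queryHits(ov)]
  lapply(split(hit_probe, hit_tf), unique)
}

#' Odds-ratio enrichment of a DRE category for a TF
#'
#' `OR = (a/c) / (b/d)` with the 95% CI
#' `exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`, where `a`/`b` count
#' category DREs with/without the TF site and `c`/`d` count all DREs
#' with/without it. The TF is called enriched when `OR > threshold`.
#'
#' @param a,b,c,d non-negative integer counts (see above). All four must
#'   be positive unless `haldane = TRUE`, which adds 0.5 to every cell.
#' @param threshold enrichment call threshold (default 1.05).
#' @param haldane apply the Haldane continuity correction (+0.5 per cell).
#' @return list with `odds_ratio`, `ci_low`, `ci_high`, `enriched`.
#' @examples
#' oddsRatioEnrichment(30, 70, 100, 900)$odds_ratio  # 3.857143
#' @export
oddsRatioEnrichment <- function(a, b, c, d, threshold = 1.05,
                                haldane = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("counts must be non-negative", call. = FALSE)
  if (a > c || b > d)
    stop("category counts cannot exceed totals (need a <= c, b <= d)",
         call. = FALSE)
  if (any(cells == 0)) {
    if (!haldane)
      stop("zero cell(s): ",
           paste(names(cells)[cells == 0], collapse = ", "),
           "; the OR formula is undefined at zero - set haldane = TRUE ",
           "for a +0.5 continuity correction", call. = FALSE)
    cells <- cells + 0.5
  }
  or <- (cells[["a"]] / cells[["c"]]) / (cells[["b"]] / cells[["d"]])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  list(odds_ratio = or, ci_low = ci[1L], ci_high = ci[2L],
       enriched = or > threshold)
}

#' Hypergeometric enrichment of a category among DREs
#'
#' Upper-tail hypergeometric test `P(X >= x)` with `N` total probes, `K`
#' probes in the category, `n` DREs drawn, and `x` DREs in the category.
#' Fold change is `(x/n) / (K/N)`.
#'
#' @param N,K,n,x integer counts with `K <= N`, `n <= N`,
#'   `x <= min(K, n)`.
#' @return list with `N`, `K`, `n`, `x`, `fold_change`, `p_value`.
#' @examples
#' hypergeometricEnrichment(10, 5, 4, 4)$p_value  # 5/210
#' @export
hypergeometricEnrichment <- function(N, K, n, x) {
  if (K > N || n > N || x > min(K, n) || x < max(0, n - (N - K)) ||
      any(c(N, K, n, x) < 0))
    stop("inconsistent counts: need x <= min(K, n) <= N", call. = FALSE)
  if (n == 0 || K == 0) stop("n and K must be positive", call. = FALSE)
  p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  list(N = N, K = K, n = n, x = x,
       fold_change = (x / n) / (K / N), p_value = p)
}

#' Correlation between TF expression and its binding-site methylation
#'
#' Averages methylation across the TF's associated DRE probes per sample
#' and returns the Pearson correlation with the TF's expression.
#'
#' @param tfExpr numeric expression vector over samples (named by sample).
#' @param dreMeth methylation [OmicsMatrix-class] restricted to the TF's
#'   associated probes (samples matching `tfExpr`).
#' @return list with `pcc` and `mean_methylation` (per-sample average).
#' @export
tfMethylationCorrelation <- function(tfExpr, dreMeth) {
  stopifnot(is(dreMeth, "OmicsMatrix"))
  v <- omValues(dreMeth)
  if (!nrow(v)) stop("no associated DREs", call. = FALSE)
  if (ncol(v) != length(tfExpr))
    stop("sample count mismatch", call. = FALSE)
  avg <- colMeans(v)
  if (stats::sd(avg) == 0)
    stop("average binding-site methylation is constant; ",
         "correlation undefined", call. = FALSE)
  .checkVariable(tfExpr, "TF expression")
  list(pcc = stats::cor(tfExpr, avg), mean_methylation = avg)
}

#' Rank enriched TFs by binding-site methylation correlation
#'
#' For each TF with at least one associated DRE, computes
#' [tfMethylationCorrelation()] and ranks ascending in PCC, so the TFs
#' whose expression most strongly tracks demethylation of their binding
#' sites come first.
#'
#' @param expr expression [OmicsMatrix-class] containing the TF rows.
#' @param meth methylation [OmicsMatrix-class].
#' @param association named list TF -> probe ids from
#'   [tfBindingAssociation()].
#' @return data.frame with columns `tf`, `n_sites`, `pcc`, sorted
#'   ascending by `pcc`.
#' @export
rankTfsByMethylation <- function(expr, meth, association) {
  shared <- intersect(sampleIds(expr), sampleIds(meth))
  rows <- lapply(names(association), function(tf) {
    if (!tf %in% varIds(expr)) return(NULL)
    probes <- intersect(association[[tf]], varIds(meth))
    if (!length(probes)) return(NULL)
    res <- tryCatch(
      tfMethylationCorrelation(omValues(expr)[tf, shared],
                               meth[probes, shared]),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(tf = tf, n_sites = length(probes), pcc = res$pcc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(tf = character(), n_sites = integer(),
                      pcc = numeric()))
  out <- out[order(out$pcc), , drop = FALSE]
  rownames(out) <- NULL
  out
}
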