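# Master regulator analysis: regulon inference by MI with data-processing
# inequality filtering, a ranked differential-expression signature, and a
# two-run rank-based enrichment combined with Fisher's method.

#' Infer the signed regulon of a transcription factor
#'
#' Candidate members are genes whose expression has permutation-significant
#' MI with the TF. The data-processing inequality (DPI) then removes the
#' weakest edge of every fully significant triangle (tf, g1, g2) when it is
#' weaker than `(1 - dpiTolerance)` times the smaller of the other two
#' edges; members whose TF edge is removed leave the regulon. Surviving
#' members are split by the sign of the Spearman correlation between TF
#' and member expression.
#'
#' @param tfId TF gene id, must be a row of `expr`.
#' @param expr expression [OmicsMatrix-class].
#' @param params a [PcParams-class] providing the significance cutoff,
#'   permutation count and seed.
#' @param dpiTolerance DPI tolerance (default 0.1).
#' @return A [Regulon-class].
#' @export
inferRegulon <- function(tfId, expr, params = pcParams(),
                         dpiTolerance = 0.1) {
  stopifnot(is(expr, "OmicsMatrix"))
  if (!tfId %in% varIds(expr))
    stop("TF ", tfId, " not found in the expression matrix", call. = FALSE)
  dat <- t(omValues(expr))
  genes <- setdiff(colnames(dat), tfId)
  md <- miMaxDependent(params@epsilonMax)

  mi_tf <- numeric(length(genes)); p_tf <- numeric(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    res <- .permCore(dat[, tfId], dat[, g], NULL, params@nPerm,
                     .edgeSeed(params@seed, "mi", tfId, g), md)
    mi_tf[i] <- mutualInformation(dat[, tfId], dat[, g], md)$raw_nats
    p_tf[i] <- res$p_value
  }
  members <- genes[p_tf < params@pCutoff]
  names(mi_tf) <- genes
  if (length(members) >= 2L) {
    # pairwise MI among members, with significance, for the DPI triangles
    drop <- character()
    for (i in seq_len(length(members) - 1L)) {
      for (j in seq(i + 1L, length(members))) {
        g1 <- members[i]; g2 <- members[j]
        res <- .permCore(dat[, g1], dat[, g2], NULL, params@nPerm,
                         .edgeSeed(params@seed, "mi", g1, g2), md)
        if (res$p_value >= params@pCutoff) next
        mi_12 <- mutualInformation(dat[, g1], dat[, g2], md)$raw_nats
        tri <- c(tf_g1 = mi_tf[[g1]], tf_g2 = mi_tf[[g2]], g1_g2 = mi_12)
        weakest <- which.min(tri)
        if (tri[weakest] < (1 - dpiTolerance) * min(tri[-weakest])) {
          if (weakest == 1L) drop <- c(drop, g1)
          if (weakest == 2L) drop <- c(drop, g2)
          # weakest == 3: an indirect member-member edge, regulon unchanged
        }
      }
    }
    members <- setdiff(members, drop)
  }
  if (!length(members)) {
    return(new("Regulon", tf = tfId, positiveMembers = character(),
               negativeMembers = character(),
               memberMi = stats::setNames(numeric(), character())))
  }
  rho <- vapply(members, function(g)
    stats::cor(dat[, tfId], dat[, g], method = "spearman"), numeric(1))
  new("Regulon", tf = tfId,
      positiveMembers = members[rho >= 0],
      negativeMembers = members[rho < 0],
      memberMi = mi_tf[members] / log(2))
}

#' Rank a differential-expression signature by t statistic
#'
#' Plumbing only: a per-gene unequal-variance (Welch) two-sample t
#' statistic between the two label groups, sorted descending.
#'
#' @param expr expression [OmicsMatrix-class].
#' @param groupLabels factor/character vector over samples with exactly
#'   two levels; the t statistic is mean(level 2) - mean(level 1) scaled,
#'   so positive values mean higher in the second level.
#' @return data.frame with columns `gene`, `t`, sorted by decreasing `t`.
#' @export
rankSignature <- function(expr, groupLabels) {
  stopifnot(is(expr, "OmicsMatrix"))
  f <- factor(groupLabels)
  if (nlevels(f) != 2L) stop("need exactly two groups", call. = FALSE)
  if (any(table(f) < 3L)) stop("each group needs >= 3 samples",
                               call. = FALSE)
  v <- omValues(expr)
  i1 <- f == levels(f)[1L]; i2 <- f == levels(f)[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(v[, i1, drop = FALSE]); m2 <- rowMeans(v[, i2, drop = FALSE])
  s1 <- apply(v[, i1, drop = FALSE], 1, stats::var)
  s2 <- apply(v[, i2, drop = FALSE], 1, stats::var)
  se <- sqrt(s1 / n1 + s2 / n2)
  if (any(se == 0)) stop("degenerate group: zero variance gene",
                         call. = FALSE)
  t <- (m2 - m1) / se
  out <- data.frame(gene = rownames(v), t = unname(t),
                    stringsAsFactors = FALSE)
  out[order(-out$t), , drop = FALSE]
}

# One-sided enrichment p of a member set within a ranked signature.
# method "ranksum": Mann-Whitney of member t values vs non-members.
# method "ks": one-sided two-sample Kolmogorov-Smirnov.
.sideEnrichment <- function(members, signature, side = c("up", "down"),
                            method = c("ranksum", "ks")) {
  side <- match.arg(side); method <- match.arg(method)
  members <- intersect(members, signature$gene)
  if (!length(members)) return(NA_real_)
  inset <- signature$gene %in% members
  tm <- signature$t[inset]; tn <- signature$t[!inset]
  if (!length(tn)) return(NA_real_)
  alt <- if (side == "up") "greater" else "less"
  if (method == "ranksum") {
    suppressWarnings(stats::wilcox.test(tm, tn, alternative = alt)$p.value)
  } else {
    # ks.test alternative is about the CDF: members shifted up means their
    # CDF lies below the non-members' CDF
    alt_ks <- if (side == "up") "less" else "greater"
    suppressWarnings(stats::ks.test(tm, tn, alternative = alt_ks)$p.value)
  }
}

.fisherCombine <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(list(stat = NA_real_, p = NA_real_))
  p <- pmax(p, .Machine$double.xmin)
  stat <- -2 * sum(log(p))
  list(stat = stat,
       p = stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE))
}

.mraRuns <- function(regulon, signature, method = "ranksum") {
  pos <- positiveMembers(regulon); neg <- negativeMembers(regulon)
  # run 1: regulon(+) from the upregulated side, regulon(-) from the
  # downregulated side; run 2 is the reverse
  r1 <- .fisherCombine(c(.sideEnrichment(pos, signature, "up", method),
                         .sideEnrichment(neg, signature, "down", method)))
  r2 <- .fisherCombine(c(.sideEnrichment(pos, signature, "down", method),
                         .sideEnrichment(neg, signature, "up", method)))
  list(p_run1 = r1$p, p_run2 = r2$p, stat_run1 = r1$stat,
       stat_run2 = r2$stat)
}

.mraDirection <- function(q1, q2, qThreshold) {
  if (is.na(q1) || is.na(q2)) return("ns")
  if (min(q1, q2) >= qThreshold) return("ns")
  if (q1 < q2) "oncogenic" else if (q1 > q2) "tumor_suppressive" else "ns"
}

#' Master regulator call for one regulon
#'
#' Two enrichment runs against a ranked signature: run 1 tests the
#' positive members against the upregulated side and the negative members
#' against the downregulated side; run 2 reverses the sides. Within a run
#' the two side p-values are combined by Fisher's method (`-2 sum(ln p)`
#' against a chi-squared with 4 df). The TF is called oncogenic when run 1
#' is the more significant, tumor-suppressive when run 2 is, provided the
#' better q-value passes `qThreshold`.
#'
#' For a single regulon the q-values equal the run p-values; use
#' [masterRegulatorAnalysis()] to adjust across a set of TFs.
#'
#' @param regulon a [Regulon-class].
#' @param signature ranked signature from [rankSignature()].
#' @param qThreshold significance threshold on the better q-value
#'   (default 0.05).
#' @param method enrichment statistic per side: `"ranksum"`
#'   (Mann-Whitney, default) or `"ks"` (Kolmogorov-Smirnov running-sum
#'   alternative).
#' @return data.frame with one row: `tf`, `q_run1`, `q_run2`, `direction`,
#'   `combined_stat` (Fisher statistic of the winning run).
#' @export
masterRegulatorTest <- function(regulon, signature, qThreshold = 0.05,
                                method = c("ranksum", "ks")) {
  method <- match.arg(method)
  stopifnot(is(regulon, "Regulon"))
  if (!length(positiveMembers(regulon)) &&
      !length(negativeMembers(regulon))) {
    warning("empty regulon for ", regulon@tf, "; call is ns")
    return(data.frame(tf = regulon@tf, q_run1 = NA_real_, q_run2 = NA_real_,
                      direction = "ns", combined_stat = NA_real_,
                      stringsAsFactors = FALSE))
  }
  r <- .mraRuns(regulon, signature, method)
  dir <- .mraDirection(r$p_run1, r$p_run2, qThreshold)
  data.frame(tf = regulon@tf, q_run1 = r$p_run1, q_run2 = r$p_run2,
             direction = dir,
             combined_stat = if (identical(dir, "tumor_suppressive"))
               r$stat_run2 else r$stat_run1,
             stringsAsFactors = FALSE)
}

#' Master regulator analysis over a set of regulons
#'
#' Runs [masterRegulatorTest()] per TF and converts the per-run p-values
#' to q-values by Benjamini-Hochberg across TFs before calling the
#' direction.
#'
#' @param regulons list of [Regulon-class] objects.
#' @param signature ranked signature from [rankSignature()].
#' @param qThreshold threshold on the better q-value (default 0.05).
#' @param method see [masterRegulatorTest()].
#' @return data.frame with columns `tf`, `q_run1`, `q_run2`, `direction`,
#'   `combined_stat`.
#' @export
masterRegulatorAnalysis <- function(regulons, signature, qThreshold = 0.05,
                                    method = c("ranksum", "ks")) {
  method <- match.arg(method)
  runs <- lapply(regulons, function(rg) {
    if (!length(positiveMembers(rg)) && !length(negativeMembers(rg))) {
      warning("empty regulon for ", rg@tf, "; call is ns")
      list(tf = rg@tf, p_run1 = NA_real_, p_run2 = NA_real_,
           stat_run1 = NA_real_, stat_run2 = NA_real_)
    } else {
      c(list(tf = rg@tf), .mraRuns(rg, signature, method))
    }
  })
  p1 <- vapply(runs, `[[`, numeric(1), "p_run1")
  p2 <- vapply(runs, `[[`, numeric(1), "p_run2")
  q1 <- stats::p.adjust(p1, method = "BH")
  q2 <- stats::p.adjust(p2, method = "BH")
  dir <- mapply(.mraDirection, q1, q2,
                MoreArgs = list(qThreshold = qThreshold))
  data.frame(
    tf = vapply(runs, `[[`, character(1), "tf"),
    q_run1 = q1, q_run2 = q2, direction = dir,
    combined_stat = ifelse(dir == "tumor_suppressive",
                           vapply(runs, `[[`, numeric(1), "stat_run2"),
                           vapply(runs, `[[`, numeric(1), "stat_run1")),
    stringsAsFactors = FALSE)
}

#' Write a regulon table as TSV
#'
#' Columns: tf, member, sign, mi_bits.
#' @param regulons list of [Regulon-class] objects (or a single one).
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeRegulonTable <- function(regulons, path) {
  if (is(regulons, "Regulon")) regulons <- list(regulons)
  rows <- lapply(regulons, function(rg) {
    mem <- c(positiveMembers(rg), negativeMembers(rg))
    if (!length(mem)) return(NULL)
    data.frame(tf = rg@tf, member = mem,
               sign = c(rep("+", length(positiveMembers(rg))),
                        rep("-", length(negativeMembers(rg)))),
               mi_bits = unname(rg@memberMi[mem]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(tf = character(), member = character(),
                                      sign = character(), mi_bits = numeric())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
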