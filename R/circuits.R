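# Core regulatory circuitry assembly and the three-node directed motif
# census with randomized-network Z-scores.
#
# Triad encoding: a node triple (i, j, k) maps to a 6-bit code with bits
# (i->j)=1, (j->i)=2, (i->k)=4, (k->i)=8, (j->k)=16, (k->j)=32. The
# canonical form of a triple is the minimum code over the 6 vertex
# permutations; self-loops are ignored. A triple is (weakly) connected iff
# at least two of its three dyads are non-null. Exactly 13 canonical forms
# are connected; they are labelled with the standard triad-census names.

.triadCache <- new.env(parent = emptyenv())

.decodeTriad <- function(code) {
  A <- matrix(FALSE, 3, 3)
  bits <- as.logical(bitwAnd(code, c(1L, 2L, 4L, 8L, 16L, 32L)))
  A[1, 2] <- bits[1]; A[2, 1] <- bits[2]
  A[1, 3] <- bits[3]; A[3, 1] <- bits[4]
  A[2, 3] <- bits[5]; A[3, 2] <- bits[6]
  A
}

.encodeTriad <- function(A) {
  sum(c(1L, 2L, 4L, 8L, 16L, 32L)[c(A[1, 2], A[2, 1], A[1, 3],
                                    A[3, 1], A[2, 3], A[3, 2])])
}

# Standard names of the 13 weakly connected triad classes, keyed by
# canonical code (derived once from exemplar graphs; see tests for the
# cross-check against an independent census).
.triadLabelByCanon <- c(
  "5"  = "021D", "6"  = "021C", "7"  = "111U", "10" = "021U",
  "11" = "111D", "15" = "201",  "21" = "030T", "23" = "120U",
  "25" = "030C", "27" = "120C", "30" = "120D", "31" = "210",
  "63" = "300")

.triadTables <- function() {
  if (!is.null(.triadCache$canon)) return(as.list(.triadCache))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  permMap <- lapply(perms, function(p) {
    vapply(0:63, function(code) {
      A <- .decodeTriad(code)
      .encodeTriad(A[p, p])
    }, integer(1))
  })
  canon <- Reduce(pmin, lapply(permMap, function(m) m))  # min over perms
  ndyad <- vapply(0:63, function(code) {
    A <- .decodeTriad(code)
    sum((A | t(A))[upper.tri(A)])
  }, integer(1))
  connected <- ndyad >= 2L
  classCodes <- sort(unique(canon[connected]))
  stopifnot(length(classCodes) == 13L)
  labels <- unname(.triadLabelByCanon[as.character(classCodes)])
  classId <- integer(64)
  classId[connected] <- match(canon[connected], classCodes)
  .triadCache$canon <- canon
  .triadCache$classId <- classId       # 0 for disconnected codes
  .triadCache$classCodes <- classCodes
  .triadCache$labels <- labels
  as.list(.triadCache)
}

#' The 13 connected three-node motif classes
#'
#' @return data.frame with the canonical 6-bit adjacency code and the
#'   standard triad-census label of each class, in the package's class
#'   order.
#' @export
triadClasses <- function() {
  tt <- .triadTables()
  data.frame(class = seq_len(13L), canonical_code = tt$classCodes,
             label = tt$labels, stringsAsFactors = FALSE)
}

.asAdjacency <- function(x) {
  if (igraph::is_igraph(x)) {
    A <- as.matrix(igraph::as_adjacency_matrix(x)) > 0
  } else {
    x <- as.data.frame(x)
    stopifnot(ncol(x) >= 2L)
    nodes <- sort(unique(c(as.character(x[[1L]]), as.character(x[[2L]]))))
    A <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    A[cbind(match(as.character(x[[1L]]), nodes),
            match(as.character(x[[2L]]), nodes))] <- TRUE
  }
  diag(A) <- FALSE  # census ignores self-loops
  A
}

#' Census of connected three-node directed motifs
#'
#' Enumerates all node triples whose induced subgraph is weakly connected
#' and classifies each by isomorphism into one of the 13 connected triad
#' classes. Mutual (bidirectional) pairs count as mutual dyads; self-loops
#' are ignored.
#'
#' @param x a directed `igraph` graph, or a 2+ column data.frame/matrix of
#'   (from, to) edges.
#' @return Named integer vector of length 13 (class labels as names).
#' @examples
#' triadCensus(data.frame(from = c("A", "A", "B"), to = c("B", "C", "C")))
#' @export
triadCensus <- function(x) {
  tt <- .triadTables()
  A <- .asAdjacency(x)
  counts <- integer(13L)
  n <- nrow(A)
  if (n >= 3L) {
    tr <- utils::combn(n, 3L)
    i <- tr[1L, ]; j <- tr[2L, ]; k <- tr[3L, ]
    code <- A[cbind(i, j)] * 1L + A[cbind(j, i)] * 2L +
      A[cbind(i, k)] * 4L + A[cbind(k, i)] * 8L +
      A[cbind(j, k)] * 16L + A[cbind(k, j)] * 32L
    cls <- tt$classId[code + 1L]
    counts <- tabulate(cls[cls > 0L], nbins = 13L)
  }
  stats::setNames(as.integer(counts), tt$labels)
}

#' Motif enrichment Z-scores against randomized networks
#'
#' Compares the observed motif census with `nRandom` randomizations of the
#' same network. The default null preserves the in- and out-degree
#' sequences exactly (directed double-edge swaps, 10 |E| attempts per
#' replicate); `null = "erdos"` draws same-|V|,|E| Erdos-Renyi graphs
#' instead. `Z = (obs - mean) / sd` per class; classes with zero null
#' variance get `Z = 0` when the observed count equals the null mean and
#' `NA` (with a warning) otherwise. Enrichment is conventionally read at
#' `|Z| > 2`.
#'
#' @param x directed graph as in [triadCensus()], at least 3 nodes.
#' @param nRandom number of randomized networks (default 200, >= 2).
#' @param seed RNG seed; fixed seed gives identical Z-scores on replay.
#' @param null `"degree"` (default) or `"erdos"`.
#' @return A [MotifProfile-class].
#' @export
motifZscores <- function(x, nRandom = 200L, seed = 0L,
                         null = c("degree", "erdos")) {
  null <- match.arg(null)
  if (nRandom < 2L) stop("nRandom must be >= 2", call. = FALSE)
  g <- if (igraph::is_igraph(x)) x else {
    x <- as.data.frame(x)
    igraph::graph_from_data_frame(x[, 1:2], directed = TRUE)
  }
  g <- igraph::simplify(g, remove.loops = TRUE, remove.multiple = TRUE)
  if (igraph::vcount(g) < 3L) stop("network needs >= 3 nodes",
                                   call. = FALSE)
  obs <- triadCensus(g)
  nullCounts <- .withSeed(seed, {
    vapply(seq_len(nRandom), function(r) {
      rg <- if (null == "degree") {
        igraph::rewire(g, igraph::keeping_degseq(
          loops = FALSE, niter = 10L * igraph::ecount(g)))
      } else {
        igraph::sample_gnm(igraph::vcount(g), igraph::ecount(g),
                           directed = TRUE)
      }
      triadCensus(rg)
    }, integer(13L))
  })
  mu <- rowMeans(nullCounts)
  sdv <- apply(nullCounts, 1L, stats::sd)
  z <- (as.numeric(obs) - mu) / sdv
  flat <- sdv == 0
  z[flat & as.numeric(obs) == mu] <- 0
  if (any(flat & as.numeric(obs) != mu)) {
    warning("observed count differs from a zero-variance null for class(es) ",
            paste(names(obs)[flat & as.numeric(obs) != mu], collapse = ", "))
    z[flat & as.numeric(obs) != mu] <- NA_real_
  }
  new("MotifProfile", counts = obs,
      zScores = stats::setNames(z, names(obs)),
      randomMean = stats::setNames(mu, names(obs)),
      randomSd = stats::setNames(sdv, names(obs)),
      nRandom = as.integer(nRandom), nSubgraphs = as.integer(sum(obs)))
}

#' Assemble core regulatory circuitry from SE-overlapping distal DREs
#'
#' A TF `t` gets an auto-regulatory loop when some distal DRE targeting
#' `t` overlaps a super-enhancer and carries `t`'s own motif within
#' `flankBp` of the probe; a cross edge `t1 -> t2` arises when such a DRE
#' of `t2` carries `t1`'s motif. The returned graph is the union of all
#' auto- and cross-regulations, each edge recording its supporting DRE and
#' super-enhancer.
#'
#' @param dres DRE table; rows with `locus_class == "distal"` (when the
#'   column exists) and targets in `tfList` are used.
#' @param seRegions super-enhancer `GRanges` (names or a `name` column
#'   identify each SE).
#' @param motifHits `GRanges` with a `tf` metadata column.
#' @param tfList character vector of TF gene ids.
#' @param anno annotation `GRanges` with probe positions.
#' @param flankBp motif search flank around the probe (default 250).
#' @return A [CrcGraph-class].
#' @export
assembleCrc <- function(dres, seRegions, motifHits, tfList, anno,
                        flankBp = 250L) {
  if (!length(tfList)) stop("tfList is empty", call. = FALSE)
  empty <- function() new("CrcGraph", nodes = character(),
                          edges = data.frame(regulator = character(),
                                             target = character(),
                                             dre = character(),
                                             se = character(),
                                             stringsAsFactors = FALSE),
                          autoLoops = character())
  if (is.null(seRegions) || !length(seRegions)) {
    warning("empty super-enhancer set; CRC graph is empty")
    return(empty())
  }
  if ("locus_class" %in% names(dres))
    dres <- dres[dres$locus_class == "distal", , drop = FALSE]
  dres <- dres[dres$gene_id %in% tfList, , drop = FALSE]
  if (!nrow(dres)) return(empty())
  m <- S4Vectors::mcols(anno)
  pa <- anno[m$kind == "probe"]
  idx <- match(dres$probe_id, S4Vectors::mcols(pa)$id)
  if (anyNA(idx)) stop("DRE probes missing from annotation", call. = FALSE)
  pos <- GenomicRanges::start(pa)[idx]
  chr <- as.character(GenomicRanges::seqnames(pa))[idx]
  probe_gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(pos, width = 1L))
  se_names <- names(seRegions)
  if (is.null(se_names)) se_names <- S4Vectors::mcols(seRegions)$name
  if (is.null(se_names)) se_names <- paste0("SE", seq_along(seRegions))
  ov_se <- GenomicRanges::findOverlaps(probe_gr, seRegions)
  flank_gr <- GenomicRanges::GRanges(
    chr, IRanges::IRanges(pmax(1L, pos - flankBp), pos + flankBp))
  tf_col <- as.character(S4Vectors::mcols(motifHits)$tf)
  ov_mot <- GenomicRanges::findOverlaps(flank_gr, motifHits)
  edges <- list()
  for (h in seq_along(ov_se)) {
    di <- S4Vectors::queryHits(ov_se)[h]
    se <- se_names[S4Vectors::subjectHits(ov_se)[h]]
    regs <- unique(tf_col[S4Vectors::subjectHits(ov_mot)[
      S4Vectors::queryHits(ov_mot) == di]])
    regs <- intersect(regs, tfList)
    if (!length(regs)) next
    edges[[length(edges) + 1L]] <- data.frame(
      regulator = regs, target = dres$gene_id[di],
      dre = dres$probe_id[di], se = se, stringsAsFactors = FALSE)
  }
  if (!length(edges)) return(empty())
  e <- unique(do.call(rbind, edges))
  rownames(e) <- NULL
  new("CrcGraph", nodes = sort(unique(c(e$regulator, e$target))),
      edges = e,
      autoLoops = sort(unique(e$target[e$regulator == e$target])))
}

#' Write a motif profile as TSV
#'
#' Columns: class, count, mean_random, sd_random, z.
#' @param profile a [MotifProfile-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeMotifProfile <- function(profile, path) {
  stopifnot(is(profile, "MotifProfile"))
  out <- data.frame(class = names(profile@counts),
                    count = as.integer(profile@counts),
                    mean_random = profile@randomMean,
                    sd_random = profile@randomSd,
                    z = profile@zScores, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
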