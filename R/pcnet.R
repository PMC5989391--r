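# MI/CMI-based PC-algorithm pruning: start from a complete graph over all
# variables, keep edges whose MI is significant by permutation, then drop
# every edge that loses significance conditional on any single common
# neighbor, and finally remove weak edges below the MI floor (in bits).
#
# Determinism: every permutation test derives its own seed from the master
# seed plus the sorted ids of the variables involved, so the result does
# not depend on variable ordering or edge iteration order. Removals within
# one conditional sweep are deferred to the end of the sweep.

.sortedPair <- function(a, b) {
  sw <- a > b
  cbind(ifelse(sw, b, a), ifelse(sw, a, b))
}

.emptyEdges <- function() {
  data.frame(node_a = character(), node_b = character(),
             mi_nats = numeric(), mi_bits = numeric(),
             normalized_mi = numeric(), p_value = numeric(),
             stringsAsFactors = FALSE)
}

#' Build a complete graph over the variables of an OmicsMatrix
#'
#' All `n(n-1)/2` edges are present with weights unset; the data matrix is
#' attached for the pruning stages.
#'
#' @param om an [OmicsMatrix-class] with at least 2 variables.
#' @return A [RegulatoryNetwork-class].
#' @export
buildCompleteGraph <- function(om) {
  stopifnot(is(om, "OmicsMatrix"))
  ids <- varIds(om)
  if (length(ids) < 2L) stop("need at least 2 variables", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate variable ids", call. = FALSE)
  pairs <- t(utils::combn(sort(ids), 2L))
  edges <- data.frame(node_a = pairs[, 1L], node_b = pairs[, 2L],
                      mi_nats = NA_real_, mi_bits = NA_real_,
                      normalized_mi = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
  new("RegulatoryNetwork",
      nodes = data.frame(id = ids, kind = unname(varKinds(om)),
                         stringsAsFactors = FALSE),
      edges = edges,
      data = t(omValues(om)))
}

#' Score all edges by MI and drop non-significant ones
#'
#' Each edge is scored by [mutualInformation()] and
#' [permutationSignificance()]; edges with `p >= pCutoff` are removed and
#' surviving edges carry their MI and p-value.
#'
#' @param net a [RegulatoryNetwork-class] with data attached.
#' @param params a [PcParams-class].
#' @return The pruned network.
#' @export
pruneByMI <- function(net, params = pcParams()) {
  stopifnot(is(net, "RegulatoryNetwork"), is(params, "PcParams"))
  e <- net@edges
  if (!nrow(e)) return(net)
  dat <- net@data
  md <- miMaxDependent(params@epsilonMax)
  keep <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    a <- e$node_a[i]; b <- e$node_b[i]
    res <- tryCatch(
      .permCore(dat[, a], dat[, b], NULL, params@nPerm,
                .edgeSeed(params@seed, "mi", a, b), md),
      error = function(err) stop("edge ", a, " -- ", b, ": ",
                                 conditionMessage(err), call. = FALSE))
    mi <- mutualInformation(dat[, a], dat[, b], md)
    e$mi_nats[i] <- mi$raw_nats
    e$mi_bits[i] <- mi$raw_bits
    e$normalized_mi[i] <- mi$normalized
    e$p_value[i] <- res$p_value
    keep[i] <- res$p_value < params@pCutoff
  }
  net@edges <- e[keep, , drop = FALSE]
  rownames(net@edges) <- NULL
  net
}

# adjacency list (id -> neighbor ids) from an edge frame
.neighborMap <- function(edges, ids) {
  nb <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(edges))) {
    a <- edges$node_a[i]; b <- edges$node_b[i]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  nb
}

#' Conditional-independence pruning over single common neighbors
#'
#' For each surviving edge (i, j), every common graph neighbor k is tested
#' one at a time with the permutation significance of CMI(i, j | k); if any
#' k renders the edge non-significant (`p >= pCutoff`) the edge is removed.
#' Removals within a sweep are applied after the sweep completes, so the
#' result is independent of edge iteration order. With `iterateCmi = TRUE`
#' in the parameters, sweeps repeat until no edge is removed.
#'
#' @inheritParams pruneByMI
#' @return The pruned network.
#' @export
pruneByCMI <- function(net, params = pcParams()) {
  stopifnot(is(net, "RegulatoryNetwork"), is(params, "PcParams"))
  dat <- net@data
  md <- miMaxDependent(params@epsilonMax)
  repeat {
    e <- net@edges
    if (nrow(e) < 2L) break
    nb <- .neighborMap(e, net@nodes$id)
    drop <- logical(nrow(e))
    for (i in seq_len(nrow(e))) {
      a <- e$node_a[i]; b <- e$node_b[i]
      common <- intersect(nb[[a]], nb[[b]])
      for (k in sort(common)) {
        res <- tryCatch(
          .permCore(dat[, a], dat[, b], dat[, k, drop = FALSE],
                    params@nPerm, .edgeSeed(params@seed, "cmi", a, b, k), md),
          error = function(err) stop("edge ", a, " -- ", b, " | ", k, ": ",
                                     conditionMessage(err), call. = FALSE))
        if (res$p_value >= params@pCutoff) { drop[i] <- TRUE; break }
      }
    }
    net@edges <- e[!drop, , drop = FALSE]
    rownames(net@edges) <- NULL
    if (!params@iterateCmi || !any(drop)) break
  }
  net
}

#' Remove weak edges below the mutual information floor
#'
#' Edges with MI at or below `miFloorBits` (paper rule: keep MI > 0.1 bits)
#' are removed.
#'
#' @inheritParams pruneByMI
#' @return The filtered network.
#' @export
applyMiFloor <- function(net, params = pcParams()) {
  stopifnot(is(net, "RegulatoryNetwork"), is(params, "PcParams"))
  e <- net@edges
  if (nrow(e)) {
    net@edges <- e[!is.na(e$mi_bits) & e$mi_bits > params@miFloorBits, ,
                   drop = FALSE]
    rownames(net@edges) <- NULL
  }
  net
}

#' Infer a direct-connection network by the full PC pruning cascade
#'
#' Composition of [buildCompleteGraph()], [pruneByMI()], [pruneByCMI()] and
#' [applyMiFloor()]. Deterministic for a fixed seed in `params`.
#'
#' @param om an [OmicsMatrix-class] (>= 2 variables; >= 30 samples
#'   recommended).
#' @param params a [PcParams-class].
#' @return A [RegulatoryNetwork-class] whose edges are the retained direct
#'   connections.
#' @examples
#' set.seed(1)
#' m <- rbind(a = rnorm(100), b = rnorm(100))
#' m["b", ] <- m["a", ] + rnorm(100, sd = 0.3)
#' colnames(m) <- paste0("s", 1:100)
#' net <- inferNetwork(OmicsMatrix(m, "expression"), pcParams(seed = 1))
#' networkEdges(net)
#' @export
inferNetwork <- function(om, params = pcParams()) {
  net <- buildCompleteGraph(om)
  net <- pruneByMI(net, params)
  net <- pruneByCMI(net, params)
  net <- applyMiFloor(net, params)
  ord <- order(net@edges$node_a, net@edges$node_b)
  net@edges <- net@edges[ord, , drop = FALSE]
  rownames(net@edges) <- NULL
  net
}

#' Write a network edge list as TSV
#'
#' Columns: node_a, node_b, mi_bits, normalized_mi, p_value.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "RegulatoryNetwork"))
  e <- net@edges[, c("node_a", "node_b", "mi_bits", "normalized_mi",
                     "p_value")]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
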