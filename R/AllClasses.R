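# S4 classes, generics, validity, accessors and show methods for the
# package's central containers.

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

# ---------------------------------------------------------------- OmicsMatrix

#' OmicsMatrix: typed variables-by-samples numeric matrix
#'
#' Holds one block of omics measurements with rows as variables (genes or
#' CpG probes) and columns as samples. Every variable carries a kind tag,
#' either `"expression"` (continuous, unbounded) or `"methylation"`
#' (beta values, constrained to \[0, 1\]). Validity enforces unique row and
#' column names, absence of missing values, and the beta-value range.
#'
#' @slot values numeric matrix, variables x samples, dimnames required.
#' @slot varKind character vector, one of `"expression"`/`"methylation"`
#'   per row.
#' @aliases OmicsMatrix-class
#' @export
setClass("OmicsMatrix",
         representation(values = "matrix", varKind = "character"))

setValidity("OmicsMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have row (variable) and column (sample) names")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicated variable ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicated sample ids")
  }
  if (anyNA(v)) msg <- c(msg, "missing values are not allowed")
  if (length(object@varKind) != nrow(v))
    msg <- c(msg, "varKind length must equal the number of variables")
  if (!all(object@varKind %in% c("expression", "methylation")))
    msg <- c(msg, "varKind entries must be 'expression' or 'methylation'")
  meth <- object@varKind == "methylation"
  if (any(meth) && nrow(v) > 0) {
    mv <- v[meth, , drop = FALSE]
    if (length(mv) && (min(mv) < 0 || max(mv) > 1))
      msg <- c(msg, "methylation beta values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, variables x samples, with dimnames.
#' @param kind `"expression"` or `"methylation"`; either a single value for
#'   the whole block or one value per row.
#' @return An [OmicsMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' om <- OmicsMatrix(m, "expression")
#' varIds(om)
#' @export
OmicsMatrix <- function(values, kind) {
  values <- as.matrix(values)
  if (length(kind) == 1L) kind <- rep(kind, nrow(values))
  new("OmicsMatrix", values = values, varKind = as.character(kind))
}

#' @rdname OmicsMatrix
#' @param object,x an `OmicsMatrix`.
#' @export
setGeneric("omValues", function(x) standardGeneric("omValues"))
#' @rdname OmicsMatrix
#' @export
setGeneric("varIds", function(x) standardGeneric("varIds"))
#' @rdname OmicsMatrix
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname OmicsMatrix
#' @export
setGeneric("varKinds", function(x) standardGeneric("varKinds"))

#' @rdname OmicsMatrix
#' @export
setMethod("omValues", "OmicsMatrix", function(x) x@values)
#' @rdname OmicsMatrix
#' @export
setMethod("varIds", "OmicsMatrix", function(x) rownames(x@values))
#' @rdname OmicsMatrix
#' @export
setMethod("sampleIds", "OmicsMatrix", function(x) colnames(x@values))
#' @rdname OmicsMatrix
#' @export
setMethod("varKinds", "OmicsMatrix", function(x) {
  stats::setNames(x@varKind, rownames(x@values))
})

setMethod("show", "OmicsMatrix", function(object) {
  cat("OmicsMatrix with", nrow(object@values), "variables x",
      ncol(object@values), "samples\n")
  tb <- table(object@varKind)
  cat("  kinds:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
})

#' Subset an OmicsMatrix by variable ids
#' @param i character vector of variable ids (or integer/logical row index).
#' @param j sample ids or index.
#' @param ... ignored.
#' @param drop ignored; the result is always an `OmicsMatrix`.
#' @rdname OmicsMatrix
#' @export
setMethod("[", "OmicsMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  k <- x@varKind
  if (!missing(i)) {
    ii <- if (is.character(i)) match(i, rownames(v)) else seq_len(nrow(v))[i]
    if (anyNA(ii)) stop("unknown variable id(s): ",
                        paste(i[is.na(ii)], collapse = ", "))
    v <- v[ii, , drop = FALSE]; k <- k[ii]
  }
  if (!missing(j)) v <- v[, j, drop = FALSE]
  new("OmicsMatrix", values = v, varKind = k)
})

#' Merge several OmicsMatrix blocks over their shared samples
#'
#' Rows are stacked; samples are intersected (a message reports how many
#' survive). Used to combine the expression and methylation blocks of one
#' genomic window into a single analysis matrix.
#'
#' @param ... `OmicsMatrix` objects.
#' @return A single `OmicsMatrix`.
#' @export
mergeOmics <- function(...) {
  oms <- list(...)
  stopifnot(length(oms) >= 1L)
  shared <- Reduce(intersect, lapply(oms, sampleIds))
  if (length(shared) < 3L)
    stop("fewer than 3 shared samples across matrices", call. = FALSE)
  total <- unique(unlist(lapply(oms, sampleIds)))
  if (length(shared) < length(total))
    message("mergeOmics: keeping ", length(shared), " of ", length(total),
            " samples present in all blocks")
  v <- do.call(rbind, lapply(oms, function(o) o@values[, shared, drop = FALSE]))
  new("OmicsMatrix", values = v,
      varKind = unlist(lapply(oms, function(o) o@varKind), use.names = FALSE))
}

# ------------------------------------------------------------------- PcParams

#' Parameters of the PC-algorithm network pruning
#'
#' @slot pCutoff permutation p-value below which an edge is significant
#'   (default 0.01).
#' @slot miFloorBits minimum mutual information in bits for a retained edge
#'   (default 0.1; edges must exceed this strictly).
#' @slot nPerm number of permutations per significance test (default 100).
#' @slot seed master seed; all per-edge permutation streams derive from it.
#' @slot maxConditioning size of the conditioning set; only order-1
#'   conditioning (single common neighbors) is implemented.
#' @slot iterateCmi logical; re-sweep conditional pruning to a fixed point
#'   instead of a single pass (default FALSE).
#' @slot epsilonMax saturation parameter of the normalization denominator,
#'   see [miMaxDependent()].
#' @aliases PcParams-class
#' @export
setClass("PcParams",
         representation(pCutoff = "numeric", miFloorBits = "numeric",
                        nPerm = "integer", seed = "integer",
                        maxConditioning = "integer", iterateCmi = "logical",
                        epsilonMax = "numeric"))

setValidity("PcParams", function(object) {
  msg <- character()
  if (object@pCutoff <= 0 || object@pCutoff >= 1)
    msg <- c(msg, "pCutoff must lie in (0, 1)")
  if (object@miFloorBits < 0) msg <- c(msg, "miFloorBits must be >= 0")
  if (object@nPerm < 30L) msg <- c(msg, "nPerm must be >= 30")
  if (object@maxConditioning != 1L)
    msg <- c(msg, "only maxConditioning = 1 is supported")
  if (object@epsilonMax <= 0 || object@epsilonMax >= 1)
    msg <- c(msg, "epsilonMax must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname PcParams-class
#' @param pCutoff,miFloorBits,nPerm,seed,maxConditioning,iterateCmi,epsilonMax
#'   see slot documentation.
#' @return A `PcParams` object.
#' @examples
#' pcParams(pCutoff = 0.01, nPerm = 100, seed = 1)
#' @export
pcParams <- function(pCutoff = 0.01, miFloorBits = 0.1, nPerm = 100L,
                     seed = 0L, maxConditioning = 1L, iterateCmi = FALSE,
                     epsilonMax = 1e-6) {
  new("PcParams", pCutoff = pCutoff, miFloorBits = miFloorBits,
      nPerm = as.integer(nPerm), seed = as.integer(seed),
      maxConditioning = as.integer(maxConditioning),
      iterateCmi = iterateCmi, epsilonMax = epsilonMax)
}

setMethod("show", "PcParams", function(object) {
  cat("PcParams: p <", object@pCutoff, "| MI floor", object@miFloorBits,
      "bits |", object@nPerm, "permutations | seed", object@seed, "\n")
})

# --------------------------------------------------------- RegulatoryNetwork

#' Undirected weighted network over genes and probes
#'
#' Product of the PC pruning stages. Edges are unordered id pairs carrying
#' mutual information (nats and bits), the saturation-normalized MI, and
#' the permutation p-value. The samples-by-variables data matrix is kept in
#' the object so successive pruning stages can rescore edges.
#'
#' @slot nodes data.frame with columns `id`, `kind`.
#' @slot edges data.frame with columns `node_a`, `node_b`, `mi_nats`,
#'   `mi_bits`, `normalized_mi`, `p_value`; `node_a < node_b` lexically.
#' @slot data numeric matrix, samples x variables.
#' @aliases RegulatoryNetwork-class
#' @export
setClass("RegulatoryNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        data = "matrixOrNULL"))

setValidity("RegulatoryNetwork", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("node_a", "node_b", "mi_nats", "mi_bits", "normalized_mi",
            "p_value")
  if (!all(need %in% names(e))) msg <- c(msg, "edges lack required columns")
  else if (nrow(e)) {
    if (any(e$node_a == e$node_b)) msg <- c(msg, "self-edges are not allowed")
    if (!all(c(e$node_a, e$node_b) %in% object@nodes$id))
      msg <- c(msg, "edge endpoints must be nodes")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname RegulatoryNetwork-class
#' @param x a `RegulatoryNetwork`.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname RegulatoryNetwork-class
#' @export
setMethod("networkEdges", "RegulatoryNetwork", function(x) x@edges)
#' @rdname RegulatoryNetwork-class
#' @export
setMethod("networkNodes", "RegulatoryNetwork", function(x) x@nodes)

setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
})

# -------------------------------------------------------------------- Regulon

#' Signed regulon of one transcription factor
#'
#' Candidate target genes with significant mutual information to the TF,
#' filtered by the data-processing inequality, and split by the sign of the
#' Spearman correlation between TF and member expression.
#'
#' @slot tf TF gene id.
#' @slot positiveMembers,negativeMembers character vectors of gene ids
#'   (disjoint, neither contains the TF).
#' @slot memberMi named numeric vector, MI in bits per member.
#' @aliases Regulon-class
#' @export
setClass("Regulon",
         representation(tf = "character", positiveMembers = "character",
                        negativeMembers = "character", memberMi = "numeric"))

setValidity("Regulon", function(object) {
  msg <- character()
  if (length(intersect(object@positiveMembers, object@negativeMembers)))
    msg <- c(msg, "positive and negative members must be disjoint")
  if (object@tf %in% c(object@positiveMembers, object@negativeMembers))
    msg <- c(msg, "a TF cannot be a member of its own regulon")
  if (length(msg)) msg else TRUE
})

#' @rdname Regulon-class
#' @param x a `Regulon`.
#' @export
setGeneric("positiveMembers", function(x) standardGeneric("positiveMembers"))
#' @rdname Regulon-class
#' @export
setGeneric("negativeMembers", function(x) standardGeneric("negativeMembers"))
#' @rdname Regulon-class
#' @export
setMethod("positiveMembers", "Regulon", function(x) x@positiveMembers)
#' @rdname Regulon-class
#' @export
setMethod("negativeMembers", "Regulon", function(x) x@negativeMembers)

setMethod("show", "Regulon", function(object) {
  cat("Regulon of", object@tf, ":", length(object@positiveMembers),
      "positive /", length(object@negativeMembers), "negative members\n")
})

# ------------------------------------------------------------------- CrcGraph

#' Core regulatory circuitry graph
#'
#' Directed TF-to-TF regulation edges, each justified by a distal DRE that
#' overlaps a super-enhancer of the target TF and carries the regulator's
#' binding motif within the flank window.
#'
#' @slot nodes TF ids appearing in any edge.
#' @slot edges data.frame with columns `regulator`, `target`, `dre`, `se`.
#' @slot autoLoops TF ids with self-regulation.
#' @aliases CrcGraph-class
#' @export
setClass("CrcGraph",
         representation(nodes = "character", edges = "data.frame",
                        autoLoops = "character"))

#' @rdname CrcGraph-class
#' @param x a `CrcGraph`.
#' @export
setGeneric("crcEdges", function(x) standardGeneric("crcEdges"))
#' @rdname CrcGraph-class
#' @export
setGeneric("crcAutoLoops", function(x) standardGeneric("crcAutoLoops"))
#' @rdname CrcGraph-class
#' @export
setMethod("crcEdges", "CrcGraph", function(x) x@edges)
#' @rdname CrcGraph-class
#' @export
setMethod("crcAutoLoops", "CrcGraph", function(x) x@autoLoops)

setMethod("show", "CrcGraph", function(object) {
  cat("CrcGraph:", length(object@nodes), "TFs,", nrow(object@edges),
      "regulatory edges (", length(object@autoLoops), "auto-loops )\n")
})

# --------------------------------------------------------------- MotifProfile

#' Three-node motif census with randomized-network Z-scores
#'
#' Counts over the 13 weakly connected three-node directed motif classes,
#' with per-class Z-scores against degree-preserving randomizations.
#'
#' @slot counts named integer vector of length 13 (observed census).
#' @slot zScores named numeric vector of length 13.
#' @slot randomMean,randomSd per-class null mean and standard deviation.
#' @slot nRandom number of randomized networks used.
#' @slot nSubgraphs total number of connected triples in the observed graph.
#' @aliases MotifProfile-class
#' @export
setClass("MotifProfile",
         representation(counts = "integer", zScores = "numeric",
                        randomMean = "numeric", randomSd = "numeric",
                        nRandom = "integer", nSubgraphs = "integer"))

#' @rdname MotifProfile-class
#' @param x a `MotifProfile`.
#' @export
setGeneric("motifCounts", function(x) standardGeneric("motifCounts"))
#' @rdname MotifProfile-class
#' @export
setGeneric("motifZ", function(x) standardGeneric("motifZ"))
#' @rdname MotifProfile-class
#' @export
setMethod("motifCounts", "MotifProfile", function(x) x@counts)
#' @rdname MotifProfile-class
#' @export
setMethod("motifZ", "MotifProfile", function(x) x@zScores)

setMethod("show", "MotifProfile", function(object) {
  cat("MotifProfile:", object@nSubgraphs, "connected triples,",
      object@nRandom, "randomizations\n")
  enr <- names(object@zScores)[!is.na(object@zScores) & object@zScores > 2]
  dep <- names(object@zScores)[!is.na(object@zScores) & object@zScores < -2]
  if (length(enr)) cat("  enriched (Z > 2):", paste(enr, collapse = ", "), "\n")
  if (length(dep)) cat("  depleted (Z < -2):", paste(dep, collapse = ", "), "\n")
})
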