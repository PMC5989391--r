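# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# pair of standardized vectors whose *sample* correlation equals r to
# machine precision (Gram-Schmidt construction)
fix_cor_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- as.numeric(scale(rnorm(n)))
  z <- rnorm(n)
  z <- as.numeric(scale(stats::resid(stats::lm(z ~ x))))
  list(x = x, y = r * x + sqrt(1 - r^2) * z)
}

# partial correlation of x and y given z via regression residuals
# (independent oracle for the CMI closed form)
partial_cor_oracle <- function(x, y, z) {
  stats::cor(stats::resid(stats::lm(x ~ z)),
             stats::resid(stats::lm(y ~ z)))
}

# samples-in-columns OmicsMatrix from a named list of vectors
om_from_vectors <- function(..., kind = "expression") {
  vs <- list(...)
  m <- do.call(rbind, vs)
  colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  OmicsMatrix(m, kind)
}

# linear Gaussian chain a -> b -> c
fix_chain <- function(n, seed, noise = 0.6) {
  set.seed(seed)
  a <- rnorm(n)
  b <- a + rnorm(n, sd = noise)
  c <- b + rnorm(n, sd = noise)
  om_from_vectors(a = a, b = b, c = c)
}

# collider a -> c <- b with a, b independent
fix_collider <- function(n, seed, noise = 0.6) {
  set.seed(seed)
  a <- rnorm(n); b <- rnorm(n)
  c <- a + b + rnorm(n, sd = noise)
  om_from_vectors(a = a, b = b, c = c)
}

# star: hub drives 4 leaves
fix_star <- function(n, seed, noise = 0.6) {
  set.seed(seed)
  hub <- rnorm(n)
  leaves <- lapply(1:4, function(i) hub + rnorm(n, sd = noise))
  names(leaves) <- paste0("leaf", 1:4)
  do.call(om_from_vectors, c(list(hub = hub), leaves))
}

edge_keys <- function(net) {
  e <- networkEdges(net)
  sort(paste(e$node_a, e$node_b))
}

# all 64 labeled 3-node digraphs (no self-loops) as adjacency matrices
all_triad_adjacency <- function() {
  lapply(0:63, function(code) {
    A <- matrix(FALSE, 3, 3, dimnames = list(c("a", "b", "c"),
                                             c("a", "b", "c")))
    bits <- as.logical(bitwAnd(code, c(1L, 2L, 4L, 8L, 16L, 32L)))
    A[1, 2] <- bits[1]; A[2, 1] <- bits[2]
    A[1, 3] <- bits[3]; A[3, 1] <- bits[4]
    A[2, 3] <- bits[5]; A[3, 2] <- bits[6]
    A
  })
}

adjacency_to_edges <- function(A) {
  idx <- which(A, arr.ind = TRUE)
  data.frame(from = rownames(A)[idx[, 1]], to = colnames(A)[idx[, 2]],
             stringsAsFactors = FALSE)
}

# small annotation: one gene at 1 Mb plus probes at given offsets
fix_annotation <- function(probe_offsets, gene_id = "geneA",
                           strand = "+", tss = 1000000L) {
  c(variableAnnotation(gene_id, "chr1", tss, strand = strand,
                       kind = "gene"),
    variableAnnotation(sprintf("p%02d", seq_along(probe_offsets)),
                       "chr1", tss + probe_offsets, kind = "probe"))
}
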