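# PC-algorithm pruning: complete graph, MI/CMI stages, MI floor,
# determinism and order robustness.

test_that("the complete graph has n(n-1)/2 edges and rejects bad input", {
  set.seed(1)
  m4 <- matrix(rnorm(40), 4, 10,
               dimnames = list(paste0("v", 1:4), paste0("s", 1:10)))
  expect_equal(nrow(networkEdges(buildCompleteGraph(
    OmicsMatrix(m4, "expression")))), 6L)
  m2 <- m4[1:2, ]
  expect_equal(nrow(networkEdges(buildCompleteGraph(
    OmicsMatrix(m2, "expression")))), 1L)
  m1 <- m4[1, , drop = FALSE]
  expect_error(buildCompleteGraph(OmicsMatrix(m1, "expression")),
               "at least 2")
  mdup <- m4; rownames(mdup) <- c("v1", "v1", "v3", "v4")
  expect_error(OmicsMatrix(mdup, "expression"), "duplicated")
})

test_that("MI pruning keeps dependent and drops independent pairs", {
  removed <- 0L
  for (s in 1:20) {
    set.seed(s)
    om <- om_from_vectors(a = rnorm(500), b = rnorm(500))
    net <- pruneByMI(buildCompleteGraph(om), pcParams(seed = s))
    if (nrow(networkEdges(net)) == 0L) removed <- removed + 1L
  }
  expect_gte(removed, 18L)  # >= 95% nominal under p < 0.01

  set.seed(99)
  x <- rnorm(300)
  om <- om_from_vectors(a = x, b = x + rnorm(300, sd = 0.1))
  net <- pruneByMI(buildCompleteGraph(om), pcParams(seed = 1))
  expect_equal(nrow(networkEdges(net)), 1L)

  # empty in, empty out; degenerate variable reported with edge context
  empty <- net; empty@edges <- empty@edges[0, ]
  expect_equal(nrow(networkEdges(pruneByMI(empty, pcParams()))), 0L)
  mm <- rbind(a = rep(1, 50), b = rnorm(50))
  colnames(mm) <- paste0("s", 1:50)
  expect_error(pruneByMI(buildCompleteGraph(OmicsMatrix(mm, "expression")),
                         pcParams()), "edge a -- b")
})

test_that("conditional pruning removes chain shortcuts but keeps direct
           edges", {
  ok <- 0L
  for (s in 1:20) {
    net <- inferNetwork(fix_chain(1000, seed = s), pcParams(seed = s))
    if (identical(edge_keys(net), c("a b", "b c"))) ok <- ok + 1L
  }
  expect_gte(ok, 18L)

  # collider: a and b marginally independent, both drive c
  ok <- 0L
  for (s in 1:10) {
    net <- inferNetwork(fix_collider(1000, seed = s), pcParams(seed = s))
    if (identical(edge_keys(net), c("a c", "b c"))) ok <- ok + 1L
  }
  expect_gte(ok, 9L)

  # an edge with no common neighbors is untouched by the CMI sweep
  set.seed(5)
  om <- om_from_vectors(a = rnorm(300), b = rnorm(300))
  net <- pruneByMI(buildCompleteGraph(om), pcParams(seed = 5))
  expect_identical(networkEdges(pruneByCMI(net, pcParams(seed = 5))),
                   networkEdges(net))
})

test_that("star systems are recovered and independent sets stay sparse", {
  ok <- 0L
  for (s in 1:10) {
    net <- inferNetwork(fix_star(1000, seed = s), pcParams(seed = s))
    want <- sort(paste("hub", paste0("leaf", 1:4)))
    if (identical(edge_keys(net), want)) ok <- ok + 1L
  }
  expect_gte(ok, 8L)

  # 10 mutually independent variables: about cutoff-rate false positives
  surviving <- integer(10)
  for (s in 1:10) {
    set.seed(s)
    m <- matrix(rnorm(10 * 300), 10, 300,
                dimnames = list(paste0("v", 1:10), paste0("s", 1:300)))
    net <- inferNetwork(OmicsMatrix(m, "expression"), pcParams(seed = s))
    surviving[s] <- nrow(networkEdges(net))
  }
  expect_lte(mean(surviving), 1)
})

test_that("the MI floor removes weak edges only", {
  set.seed(2)
  om <- om_from_vectors(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  net <- buildCompleteGraph(om)
  net@edges <- net@edges[1:2, ]
  net@edges$mi_bits <- c(0.05, 0.25)
  flo <- applyMiFloor(net, pcParams())
  expect_equal(networkEdges(flo)$mi_bits, 0.25)    # 0.05 <= 0.1 removed
  all_kept <- applyMiFloor(net, pcParams(miFloorBits = 0))
  expect_equal(nrow(networkEdges(all_kept)), 2L)
})

test_that("inference is deterministic, order-robust, and monotone across
           stages", {
  om <- fix_chain(400, seed = 42)
  p <- pcParams(seed = 9)
  n1 <- inferNetwork(om, p)
  n2 <- inferNetwork(om, p)
  expect_identical(networkEdges(n1), networkEdges(n2))

  # shuffled variable order gives the same edge set (per-edge seeds are
  # keyed by sorted variable ids)
  om_shuf <- om[c("c", "a", "b"), ]
  n3 <- inferNetwork(om_shuf, p)
  expect_identical(edge_keys(n1), edge_keys(n3))

  # pruning only ever removes edges
  complete <- buildCompleteGraph(om)
  s1 <- pruneByMI(complete, p)
  s2 <- pruneByCMI(s1, p)
  s3 <- applyMiFloor(s2, p)
  expect_true(all(edge_keys(s1) %in% edge_keys(complete)))
  expect_true(all(edge_keys(s2) %in% edge_keys(s1)))
  expect_true(all(edge_keys(s3) %in% edge_keys(s2)))
})

test_that("the retained skeleton matches an exhaustive partial-correlation
           oracle on small Gaussian systems", {
  # oracle: marginal correlation test, then partial-correlation tests
  # conditioning on every single third variable, then the |r| equivalent
  # of the MI floor
  oracle_skeleton <- function(dat, alpha = 0.01, floor_bits = 0.1) {
    r_floor <- sqrt(1 - 2^(-2 * floor_bits))
    ids <- colnames(dat)
    keys <- character()
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq(i + 1, length(ids))) {
        x <- dat[, i]; y <- dat[, j]
        if (stats::cor.test(x, y)$p.value >= alpha) next
        sep <- FALSE
        for (k in setdiff(seq_along(ids), c(i, j))) {
          rp <- partial_cor_oracle(x, y, dat[, k])
          n <- nrow(dat)
          tstat <- rp * sqrt((n - 3) / (1 - rp^2))
          if (2 * pt(-abs(tstat), df = n - 3) >= alpha) { sep <- TRUE; break }
        }
        if (!sep && abs(cor(x, y)) > r_floor)
          keys <- c(keys, paste(sort(c(ids[i], ids[j])), collapse = " "))
      }
    }
    sort(keys)
  }
  agree <- 0L
  for (s in 1:20) {
    om <- fix_chain(600, seed = 100 + s)
    net <- inferNetwork(om, pcParams(seed = s))
    if (identical(edge_keys(net), oracle_skeleton(t(omValues(om)))))
      agree <- agree + 1L
  }
  expect_gte(agree, 18L)
})

test_that("the edge list writer round-trips the edge table", {
  net <- inferNetwork(fix_chain(300, seed = 3), pcParams(seed = 3))
  f <- tempfile(fileext = ".tsv")
  writeEdgeList(net, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back$node_a, networkEdges(net)$node_a)
  expect_equal(back$mi_bits, networkEdges(net)$mi_bits, tolerance = 1e-9)
})
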