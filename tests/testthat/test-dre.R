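# Window assembly, DRE calling, classification, methylation dynamics,
# and precision against interaction anchors.

test_that("window assembly uses a closed +/- window around the TSS", {
  anno <- fix_annotation(c(250000L, 300000L, -300000L, 350000L, -300001L))
  set.seed(1)
  n <- 50
  expr <- om_from_vectors(geneA = rnorm(n))
  bm <- matrix(runif(5 * n), 5, n,
               dimnames = list(sprintf("p%02d", 1:5), sampleIds(expr)))
  meth <- OmicsMatrix(bm, "methylation")
  merged <- assembleWindow("geneA", anno, expr, meth)
  ids <- varIds(merged)
  expect_true(all(c("p01", "p02", "p03") %in% ids))  # boundary included
  expect_false(any(c("p04", "p05") %in% ids))
  # merged column count: target + in-window genes + in-window probes
  expect_equal(length(ids), 1L + 3L)

  expect_error(assembleWindow("nope", anno, expr, meth), "not found")
  far <- fix_annotation(500000L)
  expect_warning(res <- assembleWindow("geneA", far, expr, meth),
                 "no probes")
  expect_null(res)
})

test_that("only the causal probe is called in a confounded scene", {
  # direct: probeD -> target; confounded: latent -> (probeC, geneM) and
  # geneM -> target, so probeC correlates with target only via geneM
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 500
    lat_d <- rnorm(n); lat_c <- rnorm(n)
    probeD <- plogis(1.5 * lat_d)
    probeC <- plogis(1.5 * (lat_c + rnorm(n, sd = 0.2)))
    geneM <- lat_c + rnorm(n, sd = 0.6)
    target <- 0.9 * lat_d + 0.9 * geneM + rnorm(n)
    expr <- om_from_vectors(geneT = target, geneM = geneM)
    meth <- om_from_vectors(probeD = probeD, probeC = probeC,
                            kind = "methylation")
    anno <- c(variableAnnotation(c("geneT", "geneM"), "chr1",
                                 c(1000000L, 1100000L), strand = "+",
                                 kind = "gene"),
              variableAnnotation(c("probeD", "probeC"), "chr1",
                                 c(1050000L, 950000L), kind = "probe"))
    merged <- assembleWindow("geneT", anno, expr, meth)
    calls <- callDres("geneT", merged, pcParams(seed = s), anno)
    if (identical(sort(calls$probe_id), "probeD")) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("a distal probe with a direct effect is called distal; a quiet
           window returns no pairs", {
  set.seed(7)
  n <- 400
  lat <- rnorm(n)
  expr <- om_from_vectors(geneA = 0.9 * lat + rnorm(n))
  meth <- om_from_vectors(p01 = plogis(1.5 * lat),
                          p02 = plogis(rnorm(n)), kind = "methylation")
  anno <- fix_annotation(c(240000L, -10000L))
  merged <- assembleWindow("geneA", anno, expr, meth)
  calls <- callDres("geneA", merged, pcParams(seed = 7), anno)
  expect_true("p01" %in% calls$probe_id)
  expect_equal(calls$locus_class[calls$probe_id == "p01"], "distal")
  expect_equal(calls$distance_bp[calls$probe_id == "p01"], 240000L)

  # pure-noise window: empty table with the full column contract
  expr0 <- om_from_vectors(geneA = rnorm(n))
  merged0 <- assembleWindow("geneA", anno, expr0, meth)
  calls0 <- callDres("geneA", merged0, pcParams(seed = 7), anno)
  expect_equal(nrow(calls0), 0L)
  expect_true(all(c("probe_id", "gene_id", "pcc", "distance_bp",
                    "locus_class", "corr_sign", "target_direction",
                    "mi_bits", "p_value") %in% names(calls0)))
})

test_that("per-probe distances are recomputable from the annotation, also
           with several probes and on the minus strand", {
  set.seed(17)
  n <- 400
  l1 <- rnorm(n); l2 <- rnorm(n)
  expr <- om_from_vectors(geneA = 0.9 * l1 + 0.9 * l2 + rnorm(n))
  meth <- om_from_vectors(p01 = plogis(1.5 * l1), p02 = plogis(1.5 * l2),
                          kind = "methylation")
  offs <- c(236063L, -87275L)
  for (strand in c("+", "-")) {
    anno <- fix_annotation(offs, strand = strand)
    merged <- assembleWindow("geneA", anno, expr, meth)
    calls <- callDres("geneA", merged, pcParams(seed = 17), anno)
    calls <- calls[order(calls$probe_id), ]
    expect_equal(nrow(calls), 2L)
    want <- if (strand == "+") offs else -offs
    expect_equal(calls$distance_bp, want)
  }
})

test_that("pair classification follows the promoter window, correlation
           sign and DEG direction rules", {
  pairs <- data.frame(
    probe_id = paste0("p", 1:4), gene_id = c("g1", "g2", "g1", "g1"),
    pcc = c(0.4, -0.6, 0, -0.2),
    distance_bp = c(1500L, 22595L, -2000L, 2001L),
    locus_class = NA, corr_sign = NA, target_direction = NA,
    mi_bits = 0.3, p_value = 1e-4, stringsAsFactors = FALSE)
  deg <- data.frame(gene = c("g1", "g2"), log2FC = c(1.2, -0.3),
                    adj_p = c(1e-5, 1e-5))
  expect_message(out <- classifyDre(pairs, deg), "tie-broken")
  expect_equal(out$locus_class, c("promoter", "distal", "promoter",
                                  "distal"))
  expect_equal(out$corr_sign, c("positive", "negative", "positive",
                                "negative"))
  # g2 fails the |log2FC| > 0.58 filter -> NA direction
  expect_equal(out$target_direction, c("up", NA, "up", "up"))
})

test_that("methylation dynamics categories follow the delta rules", {
  out <- classifyDynamics(
    deltaInitiation = c(-0.2, 0.2, 0.1, 0.3, 0.15),
    deltaProgression = c(0.15, 0.2, 0.3, 0.1, 0.18),
    tol = 0.05)
  expect_equal(out$category,
               c("reversed", "consistent", "stronger", "weaker",
                 "consistent"))
  expect_error(classifyDynamics(NA_real_, 0.1), "finite|is.finite|TRUE")
})

test_that("duplicate (probe, gene) pairs keep the smallest p-value", {
  set.seed(3)
  n <- 300
  lat <- rnorm(n)
  expr <- om_from_vectors(geneA = 0.9 * lat + rnorm(n))
  meth <- om_from_vectors(p01 = plogis(1.5 * lat), kind = "methylation")
  anno <- fix_annotation(50000L)
  out <- callDresForGenes(c("geneA", "geneA"), anno, expr, meth,
                          pcParams(seed = 3))
  expect_equal(sum(out$probe_id == "p01" & out$gene_id == "geneA"), 1L)
})

test_that("pair precision counts anchor-supported negative pairs, either
           orientation", {
  anno <- c(variableAnnotation(c("gA", "gB"), "chr1",
                               c(1000000L, 2000000L), strand = "+",
                               kind = "gene"),
            variableAnnotation(c("p1", "p2", "p3", "p4"), "chr1",
                               c(1050000L, 1060000L, 2050000L, 2060000L),
                               kind = "probe"))
  pairs <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4"),
    gene_id = c("gA", "gA", "gB", "gB"),
    pcc = c(-0.5, -0.5, -0.5, 0.5),
    distance_bp = c(50000L, 60000L, 50000L, 60000L),
    stringsAsFactors = FALSE)
  # anchors confirm p1-gA (probe in first anchor) and p3-gB (probe in
  # second anchor, i.e. the swapped orientation)
  interactions <- list(
    first = GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(1049000, 1999000), c(1051000, 2001000))),
    second = GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(999000, 2049000), c(1001000, 2051000))))
  res <- pairPrecision(pairs, interactions, anno)
  expect_equal(res$n_pairs, 3L)            # the positive pair is excluded
  expect_equal(res$n_confirmed, 2L)
  expect_equal(res$overall, 2 / 3)

  # every negative pair supported -> PPV 1
  all_in <- list(
    first = GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(1040000, 2040000), c(1070000, 2070000))),
    second = GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(995000, 1995000), c(1005000, 2005000))))
  expect_equal(pairPrecision(pairs, all_in, anno)$overall, 1)

  expect_warning(res0 <- pairPrecision(pairs, list(
    first = GenomicRanges::GRanges(), second = GenomicRanges::GRanges()),
    anno), "empty interaction")
  expect_equal(res0$overall, 0)
})
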