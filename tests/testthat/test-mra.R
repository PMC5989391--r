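# Regulon inference with DPI, ranked signatures, and the two-run master
# regulator call.

make_tf_expr <- function(n_targets = 10, n_noise = 50, n = 300, seed = 1,
                         effect = 1, noise_sd = 0.5) {
  set.seed(seed)
  tf <- rnorm(n)
  vs <- list(TF = tf)
  signs <- rep_len(c(1, -1), n_targets)
  for (j in seq_len(n_targets))
    vs[[sprintf("tg%02d", j)]] <- signs[j] * effect * tf +
      rnorm(n, sd = noise_sd)
  for (j in seq_len(n_noise)) vs[[sprintf("nz%02d", j)]] <- rnorm(n)
  do.call(om_from_vectors, vs)
}

test_that("regulons recover planted targets with few false members and
           the correct signs", {
  ok <- 0L
  for (s in 1:20) {
    expr <- make_tf_expr(seed = s)
    rg <- inferRegulon("TF", expr, pcParams(seed = s))
    mem <- c(positiveMembers(rg), negativeMembers(rg))
    planted <- sprintf("tg%02d", 1:10)
    recovered <- sum(planted %in% mem)
    false_mem <- sum(!mem %in% planted)
    if (recovered >= 9L && false_mem <= 2L) ok <- ok + 1L
  }
  expect_gte(ok, 18L)

  # signs follow the planted Spearman direction
  expr <- make_tf_expr(seed = 4)
  rg <- inferRegulon("TF", expr, pcParams(seed = 4))
  expect_true(all(grepl("tg0[13579]", positiveMembers(rg))
                  [positiveMembers(rg) %in% sprintf("tg%02d", 1:10)]))
  expect_error(inferRegulon("missing", expr), "not found")
})

test_that("DPI excludes chain-mediated members but keeps dominant direct
           edges", {
  excluded <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 300
    tf <- rnorm(n)
    a <- tf + rnorm(n, sd = 0.4)
    b <- a + rnorm(n, sd = 0.4)   # reaches TF only through a
    expr <- om_from_vectors(TF = tf, a = a, b = b)
    rg <- inferRegulon("TF", expr, pcParams(seed = s))
    mem <- c(positiveMembers(rg), negativeMembers(rg))
    if ("a" %in% mem && !"b" %in% mem) excluded <- excluded + 1L
  }
  expect_gte(excluded, 8L)

  # triangle where both TF edges dominate: neither member is removed
  set.seed(11)
  n <- 300
  tf <- rnorm(n)
  a <- tf + rnorm(n, sd = 0.3)
  b <- -tf + rnorm(n, sd = 0.3)
  expr <- om_from_vectors(TF = tf, a = a, b = b)
  rg <- inferRegulon("TF", expr, pcParams(seed = 11))
  expect_setequal(c(positiveMembers(rg), negativeMembers(rg)),
                  c("a", "b"))

  # TF independent of everything: empty regulon
  set.seed(12)
  expr <- om_from_vectors(TF = rnorm(200), x = rnorm(200), y = rnorm(200))
  rg <- inferRegulon("TF", expr, pcParams(seed = 12))
  expect_length(c(positiveMembers(rg), negativeMembers(rg)), 0L)
})

test_that("signature ranking is a Welch t ordering with label
           antisymmetry", {
  set.seed(21)
  n <- 60
  labels <- rep(c("ctrl", "case"), each = n / 2)
  base <- matrix(rnorm(20 * n), 20, n,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("s%03d", 1:n)))
  # levels sort alphabetically, so "ctrl" is the second group and a shift
  # there produces a positive statistic
  base["g01", labels == "ctrl"] <- base["g01", labels == "ctrl"] + 2
  expr <- OmicsMatrix(base, "expression")
  sig <- rankSignature(expr, labels)
  expect_equal(sig$gene[1], "g01")
  expect_gt(sig$t[1], 0)

  # swapping labels negates every statistic
  sig_sw <- rankSignature(expr, ifelse(labels == "ctrl", "case", "ctrl"))
  m <- match(sig$gene, sig_sw$gene)
  expect_equal(sig$t, -sig_sw$t[m], tolerance = 1e-12)

  # identical group values give exactly zero statistics
  same <- cbind(base[, 1:5], base[, 1:5])
  colnames(same) <- sprintf("s%03d", 1:10)
  expect_error(rankSignature(OmicsMatrix(same, "expression"),
                             rep(c("a", "b"), each = 5)), NA)
  tt <- rankSignature(OmicsMatrix(same, "expression"),
                      rep(c("a", "b"), each = 5))
  expect_true(all(tt$t == 0))

  expect_error(rankSignature(expr, rep("one", n)), "two groups")
  expect_error(rankSignature(expr, c("a", "a", "b",
                                     rep("a", n - 3))), ">= 3")
})

make_signature <- function(n_genes = 200, seed = 31) {
  set.seed(seed)
  data.frame(gene = sprintf("g%03d", 1:n_genes),
             t = sort(rnorm(n_genes, sd = 3), decreasing = TRUE),
             stringsAsFactors = FALSE)
}

test_that("constructed regulons are called oncogenic or tumor-suppressive
           with direction antisymmetry", {
  sig <- make_signature()
  onco <- new("Regulon", tf = "TFonc",
              positiveMembers = sig$gene[1:10],
              negativeMembers = sig$gene[191:200],
              memberMi = setNames(rep(0.5, 20),
                                  c(sig$gene[1:10], sig$gene[191:200])))
  call1 <- masterRegulatorTest(onco, sig)
  expect_equal(call1$direction, "oncogenic")
  expect_lt(call1$q_run1, call1$q_run2)

  supp <- new("Regulon", tf = "TFsup",
              positiveMembers = sig$gene[191:200],
              negativeMembers = sig$gene[1:10],
              memberMi = setNames(rep(0.5, 20),
                                  c(sig$gene[191:200], sig$gene[1:10])))
  expect_equal(masterRegulatorTest(supp, sig)$direction,
               "tumor_suppressive")

  # reversing the ranking flips the call
  flipped <- sig
  flipped$t <- -flipped$t
  flipped <- flipped[order(-flipped$t), ]
  expect_equal(masterRegulatorTest(onco, flipped)$direction,
               "tumor_suppressive")
  expect_equal(masterRegulatorTest(supp, flipped)$direction, "oncogenic")

  expect_warning(ns <- masterRegulatorTest(
    new("Regulon", tf = "empty", positiveMembers = character(),
        negativeMembers = character(),
        memberMi = setNames(numeric(), character())), sig), "empty")
  expect_equal(ns$direction, "ns")
})

test_that("random regulons are mostly non-significant and the Fisher
           statistic is reproducible from the side p-values", {
  sig <- make_signature(seed = 41)
  ns_count <- 0L
  for (s in 1:100) {
    set.seed(400 + s)
    mem <- sample(sig$gene, 20)
    rg <- new("Regulon", tf = paste0("tf", s),
              positiveMembers = mem[1:10], negativeMembers = mem[11:20],
              memberMi = setNames(rep(0.3, 20), mem))
    if (masterRegulatorTest(rg, sig)$direction == "ns")
      ns_count <- ns_count + 1L
  }
  expect_gte(ns_count, 90L)

  # independent recomputation of run 1 (rank-sum sides + Fisher)
  onco <- new("Regulon", tf = "TFonc",
              positiveMembers = sig$gene[1:10],
              negativeMembers = sig$gene[191:200],
              memberMi = setNames(rep(0.5, 20),
                                  c(sig$gene[1:10], sig$gene[191:200])))
  call1 <- masterRegulatorTest(onco, sig)
  inset_p <- sig$gene %in% sig$gene[1:10]
  inset_n <- sig$gene %in% sig$gene[191:200]
  p_up <- wilcox.test(sig$t[inset_p], sig$t[!inset_p],
                      alternative = "greater")$p.value
  p_dn <- wilcox.test(sig$t[inset_n], sig$t[!inset_n],
                      alternative = "less")$p.value
  expect_equal(call1$combined_stat, -2 * (log(p_up) + log(p_dn)),
               tolerance = 1e-12)
  expect_equal(call1$q_run1,
               pchisq(-2 * (log(p_up) + log(p_dn)), df = 4,
                      lower.tail = FALSE), tolerance = 1e-12)
})

test_that("BH adjustment across TFs feeds the direction calls", {
  sig <- make_signature(seed = 51)
  onco <- new("Regulon", tf = "TFonc",
              positiveMembers = sig$gene[1:10],
              negativeMembers = sig$gene[191:200],
              memberMi = setNames(rep(0.5, 20),
                                  c(sig$gene[1:10], sig$gene[191:200])))
  set.seed(52)
  mem <- sample(sig$gene, 20)
  rand <- new("Regulon", tf = "TFrand",
              positiveMembers = mem[1:10], negativeMembers = mem[11:20],
              memberMi = setNames(rep(0.3, 20), mem))
  tab <- masterRegulatorAnalysis(list(onco, rand), sig)
  expect_equal(tab$direction[tab$tf == "TFonc"], "oncogenic")
  expect_equal(nrow(tab), 2L)
  # q-values are BH over the per-run p-values
  expect_true(all(tab$q_run1 >= 0 & tab$q_run1 <= 1, na.rm = TRUE))
})
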