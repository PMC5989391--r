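# Seeded generators for synthetic regulatory scenes with known
# direct/indirect structure, TF programs for regulon/CRC analyses, and the
# false discovery rate experiment.
#
# Scene model (latent linear Gaussian): each direct edge j contributes
# effect_size * M_j to the target gene's expression, where M_j is the
# standard-normal methylation latent read out by probe j through a
# logistic squash into (0, 1). Confounder latents correlate probe pairs;
# when mediator gene slots exist (n_genes > 1) a confounder also drives a
# mediator gene that feeds the target, creating an indirect probe-target
# correlation that vanishes conditional on the mediator.

#' Configuration of a synthetic regulatory scene
#'
#' @param nSamples number of samples (default 300).
#' @param nGenes number of genes; gene 1 is the target (default 1).
#' @param nProbes number of CpG probes (default 30).
#' @param nDirectEdges probes with a direct linear effect on the target
#'   (default 3).
#' @param nConfounders confounder latents (default 3); each correlates a
#'   pair of otherwise-null probes and, when a mediator gene slot is
#'   free, drives an indirect probe-target chain through it.
#' @param effectSize direct-edge coefficient relative to the noise scale
#'   (default 0.8).
#' @param noiseSd expression noise standard deviation (default 1).
#' @param windowBp genomic half-window for coordinate placement
#'   (default 300000).
#' @param seed RNG seed.
#' @return A validated `SceneConfig` list.
#' @export
sceneConfig <- function(nSamples = 300L, nGenes = 1L, nProbes = 30L,
                        nDirectEdges = 3L, nConfounders = 3L,
                        effectSize = 0.8, noiseSd = 1,
                        windowBp = 300000L, seed = 1L) {
  cfg <- list(nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
              nProbes = as.integer(nProbes),
              nDirectEdges = as.integer(nDirectEdges),
              nConfounders = as.integer(nConfounders),
              effectSize = effectSize, noiseSd = noiseSd,
              windowBp = as.integer(windowBp), seed = as.integer(seed))
  with(cfg, {
    if (nSamples < 10L || nGenes < 1L || nProbes < 1L)
      stop("counts must be positive (and nSamples >= 10)", call. = FALSE)
    if (nDirectEdges > nProbes)
      stop("nDirectEdges cannot exceed nProbes", call. = FALSE)
    if (2L * nConfounders > nProbes - nDirectEdges)
      stop("not enough probes for the requested confounders", call. = FALSE)
    if (noiseSd <= 0) stop("noiseSd must be positive", call. = FALSE)
  })
  structure(cfg, class = "SceneConfig")
}

#' Simulate a regulatory scene with known ground truth
#'
#' @param config a [sceneConfig()].
#' @return list with elements `expr` and `meth` ([OmicsMatrix-class]),
#'   `annotation` (`GRanges`), and `truth` (list with `direct_edges` and
#'   `indirect_correlations` data.frames).
#' @examples
#' sc <- simulateScene(sceneConfig(nSamples = 50, seed = 7))
#' dim(omValues(sc$meth))
#' @export
simulateScene <- function(config) {
  stopifnot(inherits(config, "SceneConfig"))
  c_ <- config
  .withSeed(c_$seed, {
    n <- c_$nSamples
    samples <- sprintf("s%03d", seq_len(n))
    genes <- sprintf("gene%02d", seq_len(c_$nGenes))
    probes <- sprintf("cg%05d", seq_len(c_$nProbes))
    target <- genes[1L]

    direct <- probes[seq_len(c_$nDirectEdges)]
    # confounders take probe pairs after the direct block
    conf_probes <- if (c_$nConfounders > 0L) {
      matrix(probes[c_$nDirectEdges + seq_len(2L * c_$nConfounders)],
             nrow = 2L)
    } else matrix(character(), nrow = 2L)
    mediator_slots <- min(c_$nConfounders, c_$nGenes - 1L)

    latent <- matrix(stats::rnorm(n * c_$nProbes), n, c_$nProbes,
                     dimnames = list(samples, probes))
    conf_latent <- vector("list", c_$nConfounders)
    for (k in seq_len(c_$nConfounders)) {
      ck <- stats::rnorm(n)
      latent[, conf_probes[1L, k]] <- ck + stats::rnorm(n, sd = 0.3)
      latent[, conf_probes[2L, k]] <- ck + stats::rnorm(n, sd = 0.3)
      conf_latent[[k]] <- ck
    }
    # logistic squash into (0,1); per-probe baseline shifts the midpoint
    intercept <- stats::runif(c_$nProbes, -1, 1)
    beta <- stats::plogis(sweep(1.5 * latent, 2L, intercept, `+`))

    expr <- matrix(stats::rnorm(n * c_$nGenes, sd = c_$noiseSd),
                   n, c_$nGenes, dimnames = list(samples, genes))
    indirect <- data.frame(probe = character(), gene = character(),
                           mediator = character(), stringsAsFactors = FALSE)
    for (k in seq_len(mediator_slots)) {
      med <- genes[1L + k]
      ck <- conf_latent[[k]]
      expr[, med] <- ck + stats::rnorm(n, sd = c_$noiseSd)
      expr[, target] <- expr[, target] +
        c_$effectSize * c_$noiseSd * scale(expr[, med])[, 1L]
      indirect <- rbind(indirect, data.frame(
        probe = conf_probes[, k], gene = target, mediator = med,
        stringsAsFactors = FALSE))
    }
    for (p in direct)
      expr[, target] <- expr[, target] +
        c_$effectSize * c_$noiseSd * latent[, p]

    tss <- 1000000L
    gene_pos <- c(tss, tss + sample.int(2L * c_$windowBp,
                                        c_$nGenes - 1L,
                                        replace = TRUE) - c_$windowBp)
    probe_pos <- tss + sample.int(2L * c_$windowBp, c_$nProbes,
                                  replace = TRUE) - c_$windowBp
    anno <- c(
      variableAnnotation(genes, "chr1", pmax(1L, gene_pos),
                         strand = "+", kind = "gene"),
      variableAnnotation(probes, "chr1", pmax(1L, probe_pos),
                         kind = "probe"))

    list(expr = OmicsMatrix(t(expr), "expression"),
         meth = OmicsMatrix(t(beta), "methylation"),
         annotation = anno,
         truth = list(
           direct_edges = data.frame(probe = direct, gene = target,
                                     stringsAsFactors = FALSE),
           indirect_correlations = indirect))
  })
}

#' Label-shuffled null version of a scene
#'
#' Permutes the sample order of the methylation matrix relative to the
#' expression matrix, destroying all probe-gene dependence while keeping
#' both marginal distributions and the probe-probe correlation structure.
#'
#' @param scene output of [simulateScene()].
#' @param seed seed for the shuffle.
#' @return A scene list with shuffled methylation and empty ground truth.
#' @export
shuffleSceneNull <- function(scene, seed = 0L) {
  v <- omValues(scene$meth)
  perm <- .withSeed(seed, sample.int(ncol(v)))
  v_null <- v[, perm, drop = FALSE]
  colnames(v_null) <- colnames(v)
  out <- scene
  out$meth <- OmicsMatrix(v_null, "methylation")
  out$truth <- list(direct_edges = data.frame(probe = character(),
                                              gene = character()),
                    indirect_correlations =
                      data.frame(probe = character(), gene = character(),
                                 mediator = character()))
  out
}

#' False discovery rate experiment over seeded scenes
#'
#' For each replicate, a scene is simulated and DRE-target pairs are
#' called on (a) the real scene and (b) its sample-label-shuffled null.
#' Per p-value cutoff: `true_calls` are real-scene calls matching the
#' planted direct edges, `false_calls` the remaining real-scene calls,
#' `chance_calls` the null-scene calls, and
#' `fdr = false / (false + true)` aggregated over replicates.
#'
#' @param config scene configuration (replicate r uses seed
#'   `config$seed + 1009 * r`).
#' @param pCutoffs numeric vector of p-value cutoffs (default 0.01).
#' @param nReps number of replicates (default 20, >= 3).
#' @param seed master seed; offsets the per-replicate scene seeds and the
#'   pruning permutation streams.
#' @param params base [PcParams-class]; the cutoff is overridden per row.
#' @return data.frame with columns `cutoff`, `true_calls`, `false_calls`,
#'   `chance_calls`, `fdr`.
#' @export
fdrExperiment <- function(config = sceneConfig(), pCutoffs = 0.01,
                          nReps = 20L, seed = 0L, params = pcParams()) {
  if (nReps < 3L) stop("nReps must be >= 3", call. = FALSE)
  acc <- array(0L, dim = c(length(pCutoffs), 3L),
               dimnames = list(NULL, c("true", "false", "chance")))
  for (r in seq_len(nReps)) {
    cfg <- config
    cfg$seed <- as.integer((config$seed + seed + 1009 * r) %% 2147483647)
    scene <- simulateScene(cfg)
    null <- shuffleSceneNull(scene, seed = cfg$seed + 1L)
    target <- scene$truth$direct_edges$gene[1L]
    if (is.na(target) || is.null(target)) target <- varIds(scene$expr)[1L]
    for (ci in seq_along(pCutoffs)) {
      p <- pcParams(pCutoff = pCutoffs[ci],
                    miFloorBits = params@miFloorBits,
                    nPerm = params@nPerm,
                    seed = cfg$seed, iterateCmi = params@iterateCmi,
                    epsilonMax = params@epsilonMax)
      merged <- assembleWindow(target, scene$annotation, scene$expr,
                               scene$meth, cfg$windowBp)
      calls <- callDres(target, merged, p, scene$annotation)
      truth_key <- paste(scene$truth$direct_edges$probe,
                         scene$truth$direct_edges$gene)
      call_key <- paste(calls$probe_id, calls$gene_id)
      acc[ci, "true"] <- acc[ci, "true"] + sum(call_key %in% truth_key)
      acc[ci, "false"] <- acc[ci, "false"] + sum(!call_key %in% truth_key)
      merged_null <- assembleWindow(target, null$annotation, null$expr,
                                    null$meth, cfg$windowBp)
      chance <- callDres(target, merged_null, p, null$annotation)
      acc[ci, "chance"] <- acc[ci, "chance"] + nrow(chance)
    }
  }
  total <- acc[, "true"] + acc[, "false"]
  data.frame(cutoff = pCutoffs,
             true_calls = acc[, "true"], false_calls = acc[, "false"],
             chance_calls = acc[, "chance"],
             fdr = ifelse(total > 0, acc[, "false"] / total, NA_real_))
}

#' Simulate a TF regulatory program
#'
#' TF expression vectors linearly drive their target sets with mixed
#' signs among noise genes, and matching genomic fixtures (annotation,
#' distal DRE table, motif hits, super-enhancers) are emitted so that
#' [assembleCrc()] recovers the planted fully interconnected loop
#' structure and [inferRegulon()] recovers the planted targets.
#'
#' @param nTfs number of transcription factors.
#' @param targetsPerTf targets driven by each TF.
#' @param nNoiseGenes independent noise genes.
#' @param nSamples number of samples.
#' @param seed RNG seed.
#' @param effectSize regression coefficient of targets on their TF
#'   (default 1).
#' @param noiseSd target noise sd (default 0.5).
#' @return list with `expr` ([OmicsMatrix-class]), `tfList`, `regulons`
#'   (list TF -> data.frame(target, sign)), `dres` (planted distal DRE
#'   table), `annotation`, `motifHits`, `seRegions`.
#' @export
simulateTfProgram <- function(nTfs = 2L, targetsPerTf = 10L,
                              nNoiseGenes = 20L, nSamples = 300L,
                              seed = 1L, effectSize = 1, noiseSd = 0.5) {
  stopifnot(nTfs >= 1L, targetsPerTf >= 1L, nNoiseGenes >= 0L,
            nSamples >= 10L)
  .withSeed(seed, {
    samples <- sprintf("s%03d", seq_len(nSamples))
    tfs <- sprintf("TF%02d", seq_len(nTfs))
    targets <- sprintf("tg%02d_%02d",
                       rep(seq_len(nTfs), each = targetsPerTf),
                       rep(seq_len(targetsPerTf), nTfs))
    noise <- if (nNoiseGenes > 0L) sprintf("nz%03d", seq_len(nNoiseGenes))
             else character()
    expr <- matrix(0, nSamples, nTfs + length(targets) + length(noise),
                   dimnames = list(samples, c(tfs, targets, noise)))
    regulons <- list()
    for (i in seq_len(nTfs)) {
      expr[, tfs[i]] <- stats::rnorm(nSamples)
      idx <- (i - 1L) * targetsPerTf + seq_len(targetsPerTf)
      signs <- rep_len(c(1, -1), targetsPerTf)
      for (j in seq_len(targetsPerTf)) {
        expr[, targets[idx[j]]] <- signs[j] * effectSize * expr[, tfs[i]] +
          stats::rnorm(nSamples, sd = noiseSd)
      }
      regulons[[tfs[i]]] <- data.frame(target = targets[idx], sign = signs,
                                       stringsAsFactors = FALSE)
    }
    for (g in noise) expr[, g] <- stats::rnorm(nSamples)

    # genomic fixtures: each TF gets a TSS, a distal DRE probe 50 kb away
    # inside its own SE; every DRE carries the motifs of all TFs, so the
    # planted circuitry is fully interconnected (all auto + cross loops)
    tss <- 1000000L + (seq_len(nTfs) - 1L) * 1000000L
    probes <- sprintf("cgTF%02d", seq_len(nTfs))
    anno <- c(
      variableAnnotation(tfs, "chr1", tss, strand = "+", kind = "gene"),
      variableAnnotation(probes, "chr1", tss + 50000L, kind = "probe"))
    dres <- data.frame(probe_id = probes, gene_id = tfs, pcc = -0.5,
                       distance_bp = 50000L, locus_class = "distal",
                       corr_sign = "negative",
                       target_direction = NA_character_,
                       mi_bits = 0.5, p_value = 1e-4,
                       stringsAsFactors = FALSE)
    se <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(tss + 40000L, tss + 60000L))
    names(se) <- sprintf("SE%02d", seq_len(nTfs))
    hits <- GenomicRanges::GRanges(
      "chr1",
      IRanges::IRanges(rep(tss + 50000L, each = nTfs) - 10L, width = 20L))
    S4Vectors::mcols(hits)$tf <- rep(tfs, times = nTfs)
    list(expr = OmicsMatrix(t(expr), "expression"),
         tfList = tfs, regulons = regulons, dres = dres,
         annotation = anno, motifHits = hits, seRegions = se)
  })
}
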