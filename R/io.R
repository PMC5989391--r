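# Readers and writers for the on-disk formats: TSV matrices, BED / GFF3 /
# BEDPE regions, DRE tables, and the run configuration.
#
# BED inputs are 0-based half-open and are converted to 1-based inclusive
# internally. BED and BEDPE are parsed here (with line-numbered
# validation); GFF3 goes through rtracklayer.

#' Read an omics matrix from TSV
#'
#' Expects a header row of sample ids and a first column of variable ids.
#' Variables containing any missing value are dropped with a warning.
#'
#' @param path TSV file.
#' @param kind `"expression"` or `"methylation"` (beta range validated).
#' @return An [OmicsMatrix-class].
#' @export
readMatrix <- function(path, kind = c("expression", "methylation")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs an id column plus >= 1 sample",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated variable id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      stop("non-numeric value in column '", names(vals)[j], "', row ",
           if (length(bad)) bad[1L] else "?", call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  has_na <- apply(m, 1L, anyNA)
  if (any(has_na)) {
    warning("dropping ", sum(has_na), " variable(s) with missing values: ",
            paste(utils::head(ids[has_na], 5L), collapse = ", "),
            if (sum(has_na) > 5L) ", ..." else "")
    m <- m[!has_na, , drop = FALSE]
  }
  if (kind == "methylation" && nrow(m) &&
      (min(m) < 0 || max(m) > 1)) {
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)[1L, ]
    stop("methylation beta value out of [0, 1] at variable '",
         rownames(m)[bad[1L]], "'", call. = FALSE)
  }
  OmicsMatrix(m, kind)
}

#' Write an omics matrix as TSV
#' @param om an [OmicsMatrix-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeMatrix <- function(om, path) {
  stopifnot(is(om, "OmicsMatrix"))
  v <- omValues(om)
  df <- data.frame(id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.readBedLike <- function(path, min_cols, label) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (!length(lines)) stop("empty ", label, " file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_cols))
    stop("malformed ", label, " at line ", which(nf < min_cols)[1L],
         ": expected >= ", min_cols, " columns", call. = FALSE)
  fields
}

.bedInterval <- function(chrom, start0, end0, path, line) {
  start0 <- suppressWarnings(as.numeric(start0))
  end0 <- suppressWarnings(as.numeric(end0))
  bad <- which(is.na(start0) | is.na(end0) | start0 >= end0)
  if (length(bad))
    stop("invalid interval (need start < end) at line ", line[bad[1L]],
         " of ", path, call. = FALSE)
  # 0-based half-open -> 1-based inclusive
  IRanges::IRanges(start = start0 + 1, end = end0)
}

#' Read genomic regions
#'
#' * `bed`: 4+ columns; returns a `GRanges` with metadata `name` (4th
#'   column, also exposed as `tf` for motif-hit files), strand from the
#'   6th column when present.
#' * `gff3`: imported with rtracklayer; feature rows of type `gene` are
#'   returned, with `name` from the `Name`/`ID` attribute.
#' * `bedpe`: 6+ columns; returns `list(first =, second =)` of parallel
#'   `GRanges` anchor pairs.
#'
#' Coordinates are converted to 1-based inclusive.
#'
#' @param path input file.
#' @param format one of `"bed"`, `"gff3"`, `"bedpe"`.
#' @return `GRanges` (bed/gff3) or anchor-pair list (bedpe).
#' @export
readRegions <- function(path, format = c("bed", "gff3", "bedpe")) {
  format <- match.arg(format)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    nm <- S4Vectors::mcols(gr)$Name
    if (is.null(nm) || all(is.na(nm))) nm <- S4Vectors::mcols(gr)$ID
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::IRanges(
                                    GenomicRanges::start(gr),
                                    GenomicRanges::end(gr)),
                                  strand = GenomicRanges::strand(gr))
    S4Vectors::mcols(out)$name <- as.character(nm)
    return(out)
  }
  if (format == "bed") {
    fields <- .readBedLike(path, 3L, "BED")
    line <- seq_along(fields)
    chrom <- vapply(fields, `[[`, character(1), 1L)
    ir <- .bedInterval(chrom, vapply(fields, `[[`, character(1), 2L),
                       vapply(fields, `[[`, character(1), 3L), path, line)
    name <- vapply(fields, function(f)
      if (length(f) >= 4L) f[[4L]] else NA_character_, character(1))
    strand <- vapply(fields, function(f)
      if (length(f) >= 6L) f[[6L]] else "*", character(1))
    bad <- which(!strand %in% c("+", "-", ".", "*"))
    if (length(bad))
      stop("unknown strand '", strand[bad[1L]], "' at line ", bad[1L],
           " of ", path, call. = FALSE)
    strand[strand == "."] <- "*"
    gr <- GenomicRanges::GRanges(chrom, ir, strand = strand)
    S4Vectors::mcols(gr)$name <- name
    S4Vectors::mcols(gr)$tf <- name
    return(gr)
  }
  # bedpe
  fields <- .readBedLike(path, 6L, "BEDPE")
  line <- seq_along(fields)
  g <- function(i) vapply(fields, `[[`, character(1), i)
  first <- GenomicRanges::GRanges(
    g(1L), .bedInterval(g(1L), g(2L), g(3L), path, line))
  second <- GenomicRanges::GRanges(
    g(4L), .bedInterval(g(4L), g(5L), g(6L), path, line))
  list(first = first, second = second)
}

#' Convert region GRanges to a per-variable annotation
#'
#' Probes anchor at their interval midpoint (450k probes are single
#' CpGs); genes anchor at the TSS derived from strand (start on `+`, end
#' on `-`; unstranded genes are rejected).
#'
#' @param gr `GRanges` with a `name` metadata column.
#' @param kind `"gene"` or `"probe"`.
#' @return Annotation `GRanges` as from [variableAnnotation()].
#' @export
regionsToAnnotation <- function(gr, kind = c("probe", "gene")) {
  kind <- match.arg(kind)
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm) || anyNA(nm))
    stop("regions need a name column to serve as variable ids",
         call. = FALSE)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (kind == "probe") {
    pos <- floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
    return(variableAnnotation(nm, chrom, pos, kind = "probe"))
  }
  st <- as.character(GenomicRanges::strand(gr))
  if (any(!st %in% c("+", "-")))
    stop("genes need '+' or '-' strand to locate the TSS", call. = FALSE)
  tss <- ifelse(st == "+", GenomicRanges::start(gr),
                GenomicRanges::end(gr))
  variableAnnotation(nm, chrom, tss, strand = st, kind = "gene")
}

#' Write a DRE table as TSV
#' @param dres DRE data.frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeDreTable <- function(dres, path) {
  utils::write.table(dres, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a DRE table written by [writeDreTable()]
#' @param path TSV path.
#' @return data.frame.
#' @export
readDreTable <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Read a run configuration (YAML)
#'
#' Missing keys fall back to the package defaults (window 300 kb,
#' promoter 2 kb, flank 250 bp, p < 0.01, MI floor 0.1 bits, OR > 1.05,
#' 100 permutations, 200 network randomizations, dynamics tolerance
#' 0.05, seed 0). Paths listed under `inputs:` must exist.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Named list of settings.
#' @export
readRunConfig <- function(path = NULL) {
  defaults <- list(window_bp = 300000L, promoter_bp = 2000L,
                   flank_bp = 250L, p_cutoff = 0.01,
                   mi_floor_bits = 0.1, or_threshold = 1.05,
                   n_perm = 100L, n_random = 200L, dynamics_tol = 0.05,
                   seed = 0L, inputs = list())
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(defaults, user)
  for (p in unlist(cfg$inputs)) {
    if (!file.exists(p))
      stop("configured input does not exist: ", p, call. = FALSE)
  }
  cfg
}

#' Write the resolved run configuration next to the outputs
#' @param cfg configuration list.
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
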