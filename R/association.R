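# Enhancer-gene association by TSS window and chromatin-loop anchors,
# plus FPKM expression binning and per-bin association fractions.

#' Construct a table of gene models
#'
#' @param gene_id character, unique stable identifiers.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param tss 0-based TSS coordinate (bp), >= 0.
#' @return a data.frame of class `GeneModels`.
#' @export
gene_models <- function(gene_id, chrom, strand, tss) {
  gene_id <- as.character(gene_id)
  chrom <- as.character(chrom)
  strand <- as.character(strand)
  tss <- as.numeric(tss)
  if (length(chrom) == 1) chrom <- rep(chrom, length(gene_id))
  if (length(strand) == 1) strand <- rep(strand, length(gene_id))
  n <- length(gene_id)
  if (length(chrom) != n || length(strand) != n || length(tss) != n)
    stop("gene_id, chrom, strand, tss must have equal length")
  if (any(duplicated(gene_id))) stop("duplicate gene_ids")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(is.na(tss)) || any(tss < 0)) stop("tss must be >= 0")
  structure(data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                       tss = tss, stringsAsFactors = FALSE),
            class = c("GeneModels", "data.frame"))
}

#' Read gene models from a TSV or BED6 file
#'
#' TSV format: 4 tab-separated columns `gene_id, chrom, strand, tss`
#' (no header). BED6: the TSS is derived from the span and strand
#' (plus strand: span start; minus strand: span end - 1).
#'
#' @param path input file.
#' @param format `"tsv"` or `"bed"`.
#' @return a `GeneModels` data.frame.
#' @export
read_genes <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("gene_id", "chrom", "strand", "tss"))
    gene_models(df$gene_id, df$chrom, df$strand, df$tss)
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 6) stop("BED gene annotation requires 6 columns")
    tss <- ifelse(df[[6]] == "+", df[[2]], df[[3]] - 1)
    gene_models(df[[4]], df[[1]], df[[6]], tss)
  }
}

#' Read chromatin loops from a BEDPE file
#'
#' Expects >= 6 tab-separated columns (chromA, startA, endA, chromB,
#' startB, endB). Anchors must lie on the same chromosome and must not
#' overlap.
#'
#' @param path BEDPE file path.
#' @param sample_id optional specimen label.
#' @return a data.frame of class `ChromatinLoops` with columns `chrom`,
#'   `a_start`, `a_end`, `b_start`, `b_end`, `sample_id`.
#' @export
read_loops <- function(path, sample_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("BEDPE requires >= 6 columns")
  chromatin_loops(df[[1]], df[[2]], df[[3]], df[[5]], df[[6]],
                  chrom_b = df[[4]], sample_id = sample_id)
}

#' Construct chromatin loops
#'
#' @param chrom chromosome of both anchors.
#' @param a_start,a_end,b_start,b_end anchor coordinates (0-based
#'   half-open).
#' @param chrom_b optional second-anchor chromosome; must equal `chrom`.
#' @param sample_id optional specimen label.
#' @return a `ChromatinLoops` data.frame.
#' @export
chromatin_loops <- function(chrom, a_start, a_end, b_start, b_end,
                            chrom_b = NULL, sample_id = NA_character_) {
  chrom <- as.character(chrom)
  if (!is.null(chrom_b) && !all(as.character(chrom_b) == chrom))
    stop("loop anchors must lie on the same chromosome")
  a_start <- as.numeric(a_start); a_end <- as.numeric(a_end)
  b_start <- as.numeric(b_start); b_end <- as.numeric(b_end)
  if (any(a_start >= a_end) || any(b_start >= b_end))
    stop("anchor intervals must have start < end")
  overl <- pmax(a_start, b_start) < pmin(a_end, b_end)
  if (any(overl)) stop("loop anchors must not overlap")
  structure(data.frame(chrom = chrom, a_start = a_start, a_end = a_end,
                       b_start = b_start, b_end = b_end,
                       sample_id = sample_id, stringsAsFactors = FALSE),
            class = c("ChromatinLoops", "data.frame"))
}

#' Bin genes by FPKM expression level
#'
#' Default bins follow the standard active-gene convention: inactive
#' FPKM < 1; low 1 <= FPKM < 5; mid 5 <= FPKM < 15; high FPKM >= 15.
#' Boundary values land in the upper bin. A gene's bin uses its mean FPKM
#' across samples by default.
#'
#' @param table numeric gene x sample matrix of FPKM values (rownames =
#'   gene ids), or a numeric vector named by gene.
#' @param sample_summary `"mean"` (default) or `"per_sample"`.
#' @param thresholds increasing numeric vector of the three bin edges,
#'   default `c(1, 5, 15)`.
#' @return for `"mean"`: a factor named by gene with levels
#'   `inactive < low < mid < high`; for `"per_sample"`: a character matrix
#'   gene x sample.
#' @export
bin_expression <- function(table, sample_summary = c("mean", "per_sample"),
                           thresholds = c(1, 5, 15)) {
  sample_summary <- match.arg(sample_summary)
  stopifnot(length(thresholds) == 3, !is.unsorted(thresholds))
  if (is.vector(table)) table <- matrix(table, ncol = 1,
                                        dimnames = list(names(table), NULL))
  if (is.null(rownames(table))) stop("expression table must have gene rownames")
  if (nrow(table) == 0) stop("expression table is empty")
  if (any(duplicated(rownames(table)))) stop("duplicate gene_ids")
  if (any(table < 0)) stop("FPKM values must be non-negative")
  labs <- c("inactive", "low", "mid", "high")
  bin1 <- function(x) factor(labs[findInterval(x, thresholds) + 1],
                             levels = labs, ordered = TRUE)
  if (sample_summary == "mean") {
    stats::setNames(bin1(rowMeans(table)), rownames(table))
  } else {
    out <- apply(table, 2, function(x) as.character(bin1(x)))
    rownames(out) <- rownames(table)
    out
  }
}

enhancer_ids <- function(set) {
  df <- set$intervals
  sprintf("%s:%s-%s", df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
          format(df$end, scientific = FALSE, trim = TRUE))
}

new_links <- function(enh_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      gene_id = character(), distance = numeric(),
                      evidence = character()) {
  structure(data.frame(enhancer_id = enh_id, chrom = chrom, start = start,
                       end = end, gene_id = gene_id, distance = distance,
                       evidence = evidence, stringsAsFactors = FALSE),
            class = c("EnhancerGeneLinks", "data.frame"))
}

#' Associate enhancers with genes by TSS window
#'
#' Links every (enhancer, gene) pair within `window` bp. With the default
#' `midpoint` anchor the distance is `|enhancer midpoint - TSS|`; with
#' `edge` the distance is 0 when the TSS lies inside the enhancer and the
#' distance to the nearest enhancer edge otherwise. One enhancer may link
#' to many genes and vice versa.
#'
#' @param enhancers canonical `IntervalSet`.
#' @param genes a `GeneModels` data.frame.
#' @param window positive window size in bp (default 100000).
#' @param anchor `"midpoint"` (default) or `"edge"`.
#' @return an `EnhancerGeneLinks` data.frame (columns: enhancer_id,
#'   chrom, start, end, gene_id, distance, evidence = "window").
#' @export
associate_by_window <- function(enhancers, genes, window = 100000,
                                anchor = c("midpoint", "edge")) {
  anchor <- match.arg(anchor)
  check_canonical(enhancers)
  stopifnot(inherits(genes, "GeneModels"))
  if (length(window) != 1 || is.na(window) || window <= 0)
    stop("window must be a positive number of bp")
  edf <- enhancers$intervals
  edf$enh_id <- enhancer_ids(enhancers)
  out <- list()
  for (ch in unique(edf$chrom)) {
    e <- edf[edf$chrom == ch, , drop = FALSE]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0 || nrow(e) == 0) next
    o <- order(g$tss)
    g <- g[o, , drop = FALSE]
    tss <- g$tss
    if (anchor == "midpoint") {
      ref <- (e$start + e$end) / 2
      lo <- ref - window
      hi <- ref + window
    } else {
      lo <- e$start - window
      hi <- (e$end - 1) + window
    }
    i1 <- findInterval(lo - 0.5, tss) + 1
    i2 <- findInterval(hi + 0.5, tss)
    keep <- which(i2 >= i1)
    if (length(keep) == 0) next
    reps <- i2[keep] - i1[keep] + 1
    ei <- rep(keep, reps)
    gi <- unlist(mapply(seq.int, i1[keep], i2[keep], SIMPLIFY = FALSE),
                 use.names = FALSE)
    dist <- if (anchor == "midpoint") {
      abs((e$start[ei] + e$end[ei]) / 2 - tss[gi])
    } else {
      inside <- tss[gi] >= e$start[ei] & tss[gi] < e$end[ei]
      d <- pmin(abs(e$start[ei] - tss[gi]), abs(e$end[ei] - 1 - tss[gi]))
      ifelse(inside, 0, d)
    }
    out[[ch]] <- data.frame(enhancer_id = e$enh_id[ei], chrom = ch,
                            start = e$start[ei], end = e$end[ei],
                            gene_id = g$gene_id[gi], distance = dist,
                            evidence = "window", stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(new_links())
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("EnhancerGeneLinks", "data.frame")
  res
}

#' Associate enhancers with genes through chromatin-loop anchors
#'
#' Links an enhancer to a gene when the enhancer overlaps (>= 1 bp) one
#' loop anchor and the gene TSS lies within the other anchor. Symmetric
#' in the two anchors; an enhancer and TSS sharing a single anchor are
#' *not* linked.
#'
#' @param enhancers canonical `IntervalSet`.
#' @param genes a `GeneModels` data.frame.
#' @param loops a `ChromatinLoops` data.frame.
#' @return an `EnhancerGeneLinks` data.frame with evidence `"loop"`;
#'   distance is |enhancer midpoint - TSS|.
#' @export
associate_by_loop <- function(enhancers, genes, loops) {
  check_canonical(enhancers)
  stopifnot(inherits(genes, "GeneModels"), inherits(loops, "ChromatinLoops"))
  edf <- enhancers$intervals
  eid <- enhancer_ids(enhancers)
  res <- list()
  link_one_way <- function(anc_e_start, anc_e_end, anc_g_start, anc_g_end,
                           ch) {
    ei <- which(edf$chrom == ch & edf$start < anc_e_end &
                  edf$end > anc_e_start)
    gi <- which(genes$chrom == ch & genes$tss >= anc_g_start &
                  genes$tss < anc_g_end)
    if (length(ei) == 0 || length(gi) == 0) return(NULL)
    expand.grid(ei = ei, gi = gi)
  }
  for (k in seq_len(nrow(loops))) {
    ch <- loops$chrom[k]
    pairs <- rbind(
      link_one_way(loops$a_start[k], loops$a_end[k],
                   loops$b_start[k], loops$b_end[k], ch),
      link_one_way(loops$b_start[k], loops$b_end[k],
                   loops$a_start[k], loops$a_end[k], ch)
    )
    if (is.null(pairs) || nrow(pairs) == 0) next
    res[[length(res) + 1]] <- data.frame(
      enhancer_id = eid[pairs$ei], chrom = ch,
      start = edf$start[pairs$ei], end = edf$end[pairs$ei],
      gene_id = genes$gene_id[pairs$gi],
      distance = abs((edf$start[pairs$ei] + edf$end[pairs$ei]) / 2 -
                       genes$tss[pairs$gi]),
      evidence = "loop", stringsAsFactors = FALSE)
  }
  if (length(res) == 0) return(new_links())
  out <- do.call(rbind, res)
  out <- out[!duplicated(out[c("enhancer_id", "gene_id")]), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnhancerGeneLinks", "data.frame")
  out
}

#' Combine window- and loop-evidence links
#'
#' Pairs supported by both sources get evidence `"both"`.
#'
#' @param window_links,loop_links `EnhancerGeneLinks` data.frames.
#' @return a combined `EnhancerGeneLinks` data.frame.
#' @export
combine_evidence <- function(window_links, loop_links) {
  key <- function(df) paste(df$enhancer_id, df$gene_id, sep = "|")
  wk <- key(window_links); lk <- key(loop_links)
  both <- intersect(wk, lk)
  w <- window_links
  w$evidence[wk %in% both] <- "both"
  l <- loop_links[!(lk %in% both), , drop = FALSE]
  out <- rbind(as.data.frame(w), as.data.frame(l))
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnhancerGeneLinks", "data.frame")
  out
}

#' Per-bin enhancer association fractions
#'
#' For each expression bin, the fraction of enhancers with at least one
#' link to a gene of that bin (an enhancer may count toward several bins,
#' so fractions need not sum to 1). Fractions are computed over
#' enhancers, not genes.
#'
#' @param links an `EnhancerGeneLinks` data.frame derived from
#'   `enhancers`.
#' @param enhancers the canonical `IntervalSet` the links came from
#'   (non-empty).
#' @param bins factor/character named by gene_id with levels inactive,
#'   low, mid, high (as from [bin_expression()]).
#' @return a data.frame with columns `bin`, `n_enhancers_linked`,
#'   `fraction`.
#' @export
association_fractions <- function(links, enhancers, bins) {
  check_canonical(enhancers)
  n_enh <- n_intervals(enhancers)
  if (n_enh == 0) stop("enhancer set is empty")
  labs <- c("inactive", "low", "mid", "high")
  gene_bin <- as.character(bins)[match(links$gene_id, names(bins))]
  out <- data.frame(bin = labs, stringsAsFactors = FALSE)
  out$n_enhancers_linked <- vapply(labs, function(b)
    length(unique(links$enhancer_id[!is.na(gene_bin) & gene_bin == b])),
    integer(1))
  out$fraction <- out$n_enhancers_linked / n_enh
  out
}

#' Write enhancer-gene links as TSV
#' @param links an `EnhancerGeneLinks` data.frame.
#' @param path output path.
#' @param gene_bins optional named bin vector appended as a `gene_bin`
#'   column.
#' @return invisibly, `path`.
#' @export
write_links <- function(links, path, gene_bins = NULL) {
  df <- as.data.frame(links)
  if (!is.null(gene_bins))
    df$gene_bin <- as.character(gene_bins)[match(df$gene_id,
                                                 names(gene_bins))]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
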