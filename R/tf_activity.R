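# Gene-signature TF activity scoring (T-scores) and correlation of
# inferred activity with a target gene's expression.

#' Depth-scale a count matrix to a target sequencing depth
#'
#' Each sample's column is multiplied by `target / total_mapped_pairs`,
#' so a sample sequenced to exactly the target depth is unchanged.
#'
#' @param counts numeric gene x sample matrix.
#' @param total_mapped_pairs positive numeric per-sample totals (length =
#'   ncol(counts)).
#' @param target target depth in read pairs (default 56.5 million).
#' @return the scaled matrix (zeros preserved, within-sample order
#'   preserved).
#' @export
scale_counts <- function(counts, total_mapped_pairs, target = 56.5e6) {
  counts <- as.matrix(counts)
  if (length(total_mapped_pairs) != ncol(counts))
    stop("total_mapped_pairs must have one entry per sample")
  if (any(is.na(total_mapped_pairs)) || any(total_mapped_pairs <= 0))
    stop("total mapped pairs must be positive")
  sweep(counts, 2, target / total_mapped_pairs, `*`)
}

#' Filter genes by mean normalized count
#'
#' Keeps genes whose mean normalized count across all samples is
#' strictly greater than 1.
#'
#' @param normalized numeric gene x sample matrix.
#' @return the row-subset matrix.
#' @export
filter_expressed <- function(normalized) {
  normalized <- as.matrix(normalized)
  normalized[rowMeans(normalized) > 1, , drop = FALSE]
}

#' Construct an up/down gene signature
#'
#' @param up_genes genes expected higher when the TF is active
#'   (non-empty).
#' @param down_genes genes expected lower when the TF is active (may be
#'   empty; scoring then contrasts up genes against all non-signature
#'   genes).
#' @param source_note free-text provenance.
#' @return a list of class `GeneSignature`.
#' @export
gene_signature <- function(up_genes, down_genes = character(),
                           source_note = "") {
  up_genes <- as.character(up_genes)
  down_genes <- as.character(down_genes)
  if (length(up_genes) == 0) stop("up_genes must be non-empty")
  if (length(intersect(tolower(up_genes), tolower(down_genes))) > 0)
    stop("up and down gene lists must be disjoint")
  structure(list(up_genes = up_genes, down_genes = down_genes,
                 source_note = source_note),
            class = "GeneSignature")
}

#' Read a signature from a two-column TSV (gene_id, direction)
#' @param path TSV with columns gene_id and direction in \{up, down\}, no
#'   header.
#' @return a `GeneSignature`.
#' @export
read_signature <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("gene_id", "direction"))
  if (!all(df$direction %in% c("up", "down")))
    stop("signature direction must be 'up' or 'down'")
  gene_signature(df$gene_id[df$direction == "up"],
                 df$gene_id[df$direction == "down"],
                 source_note = path)
}

#' Per-sample signature activity T-scores
#'
#' Genes are z-scored across samples (genes with zero variance are
#' dropped with a warning). For each sample the T-score is the Welch
#' two-sample t-statistic comparing that sample's z-scores of the up
#' genes against the down genes (or against all non-signature genes when
#' the signature has no down side). Signature genes are matched
#' case-insensitively, so a mouse-symbol signature scores a human matrix.
#'
#' The exact scoring formula used by signature tools varies; this Welch
#' construction is a documented, pluggable stand-in with the standard
#' properties (swapping up/down negates every score; affine per-gene
#' rescaling leaves scores unchanged).
#'
#' @param expression numeric gene x sample matrix (>= 3 samples), e.g.
#'   FPKM.
#' @param signature a `GeneSignature`.
#' @return a list of class `ActivityScores` with `sample_id`, `t_score`,
#'   and bookkeeping on matched/missing signature genes.
#' @export
compute_tscores <- function(expression, signature) {
  expression <- as.matrix(expression)
  stopifnot(inherits(signature, "GeneSignature"))
  if (ncol(expression) < 3) stop("need >= 3 samples")
  if (is.null(rownames(expression))) stop("expression needs gene rownames")
  mu <- rowMeans(expression)
  sds <- sqrt(rowSums((expression - mu)^2) / (ncol(expression) - 1))
  degenerate <- sds == 0
  genes_lc <- tolower(rownames(expression))
  up_idx <- which(genes_lc %in% tolower(signature$up_genes))
  down_idx <- which(genes_lc %in% tolower(signature$down_genes))
  n_up_missing <- length(signature$up_genes) - length(up_idx)
  n_down_missing <- length(signature$down_genes) - length(down_idx)
  if (any(degenerate[c(up_idx, down_idx)]))
    warning(sum(degenerate[c(up_idx, down_idx)]),
            " signature gene(s) with zero variance dropped")
  up_idx <- setdiff(up_idx, which(degenerate))
  down_idx <- setdiff(down_idx, which(degenerate))
  use_rest <- length(signature$down_genes) == 0
  if (use_rest)
    down_idx <- setdiff(which(!degenerate), up_idx)
  if (length(up_idx) < 2 || length(down_idx) < 2)
    stop(sprintf(paste0("need >= 2 usable genes on each side ",
                        "(up: %d usable, %d missing; down: %d usable, %d missing)"),
                 length(up_idx), n_up_missing, length(down_idx),
                 n_down_missing))
  z <- (expression - mu) / sds
  z[degenerate, ] <- NA
  welch <- function(x, y) {
    nx <- length(x); ny <- length(y)
    (mean(x) - mean(y)) /
      sqrt(stats::var(x) / nx + stats::var(y) / ny)
  }
  t_score <- vapply(seq_len(ncol(z)), function(j)
    welch(z[up_idx, j], z[down_idx, j]), numeric(1))
  structure(list(sample_id = colnames(expression) %||%
                   as.character(seq_len(ncol(expression))),
                 t_score = t_score,
                 n_up_used = length(up_idx),
                 n_down_used = length(down_idx),
                 n_up_missing = n_up_missing,
                 n_down_missing = n_down_missing,
                 down_is_rest = use_rest),
            class = "ActivityScores")
}

#' @export
print.ActivityScores <- function(x, ...) {
  cat(sprintf("ActivityScores: %d sample(s); %d up / %d down signature genes used\n",
              length(x$t_score), x$n_up_used, x$n_down_used))
  print(utils::head(data.frame(sample = x$sample_id, t_score = x$t_score), 6),
        row.names = FALSE)
  invisible(x)
}

#' Pearson correlation of activity scores with a target gene
#'
#' @param scores an `ActivityScores` object or a numeric vector.
#' @param target_expression per-sample numeric values (same order or
#'   matched by names when both are named).
#' @return a list of class `CorrelationResult` with `r`, `n`, `p_value`
#'   (two-sided, t-distributed).
#' @export
correlate_activity <- function(scores, target_expression) {
  x <- if (inherits(scores, "ActivityScores")) {
    stats::setNames(scores$t_score, scores$sample_id)
  } else as.numeric(scores)
  y <- target_expression
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y)))
      stop("sample ids of scores and target expression do not match")
    y <- y[names(x)]
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need n >= 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), n = length(x),
                 p_value = ct$p.value),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, p = %.3g)\n", x$r, x$n, x$p_value))
  invisible(x)
}
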