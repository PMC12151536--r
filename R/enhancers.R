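# Putative-enhancer calling and geometric super-enhancer stitching.

#' Call putative enhancers from two histone-mark tracks
#'
#' Regions positive for both H3K27ac and H3K4me1 are treated as putative
#' active enhancers. Two definitions are supported:
#' \describe{
#'   \item{`double_positive_union` (default)}{merge the two tracks
#'     (gap 0) and keep each union interval containing at least one peak
#'     of *each* mark — the "union peaks" construction.}
#'   \item{`intersection`}{exact base-pair intersection of the tracks.}
#' }
#'
#' @param h3k27ac,h3k4me1 canonical `IntervalSet`s from the same sample.
#' @param mode `"double_positive_union"` or `"intersection"`.
#' @return a canonical `IntervalSet` with attribute `"mode"` recording the
#'   definition used.
#' @export
call_putative_enhancers <- function(h3k27ac, h3k4me1,
                                    mode = c("double_positive_union",
                                             "intersection")) {
  mode <- match.arg(mode)
  check_canonical(h3k27ac); check_canonical(h3k4me1)
  if (n_intervals(h3k27ac) == 0 || n_intervals(h3k4me1) == 0)
    stop("both mark tracks must be non-empty")
  out <- if (mode == "intersection") {
    intersect_regions(h3k27ac, h3k4me1)
  } else {
    gr_a <- as_granges(h3k27ac)
    gr_b <- as_granges(h3k4me1)
    # suppressWarnings: seqlevel-mismatch chatter when the two tracks
    # mention different chromosomes
    union_gr <- GenomicRanges::reduce(suppressWarnings(c(gr_a, gr_b)),
                                      min.gapwidth = 1)
    has_a <- suppressWarnings(
      GenomicRanges::countOverlaps(union_gr, gr_a,
                                   ignore.strand = TRUE)) > 0
    has_b <- suppressWarnings(
      GenomicRanges::countOverlaps(union_gr, gr_b,
                                   ignore.strand = TRUE)) > 0
    granges_to_set(union_gr[has_a & has_b], h3k27ac$sample_id,
                   "putative_enhancer")
  }
  out$sample_id <- h3k27ac$sample_id
  attr(out, "mode") <- mode
  out
}

#' Build a multi-sample enhancer catalog
#'
#' Computes the consensus ("common") enhancer set shared by all samples
#' and per-sample accounting: how many enhancers each specimen carries and
#' what fraction of them overlaps the common set.
#'
#' @param per_sample_enhancers named list of canonical `IntervalSet`s,
#'   one per sample (>= 2 samples, unique names).
#' @return a list of class `EnhancerCatalog` with elements `per_sample`,
#'   `common`, and `counts` (data.frame: sample, n_enhancers, n_common,
#'   fraction_common).
#' @export
build_catalog <- function(per_sample_enhancers) {
  sets <- per_sample_enhancers
  if (!is.list(sets) || length(sets) < 2)
    stop("need at least two samples")
  ids <- names(sets)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(sets, function(s) s$sample_id, character(1))
  if (anyNA(ids) || any(duplicated(ids)))
    stop("sample ids must be present and unique")
  lapply(sets, check_canonical)
  common <- consensus_intervals(sets, min_samples = length(sets))
  counts <- data.frame(
    sample = ids,
    n_enhancers = vapply(sets, n_intervals, integer(1)),
    stringsAsFactors = FALSE
  )
  counts$n_common_overlap <- vapply(sets, function(s) {
    if (n_intervals(s) == 0) return(0L)
    n_intervals(filter_overlapping(s, common))
  }, integer(1))
  counts$fraction_common <- ifelse(counts$n_enhancers > 0,
                                   counts$n_common_overlap / counts$n_enhancers,
                                   NA_real_)
  structure(list(per_sample = sets, common = common, counts = counts,
                 n_common = n_intervals(common)),
            class = "EnhancerCatalog")
}

#' @export
print.EnhancerCatalog <- function(x, ...) {
  cat(sprintf("EnhancerCatalog: %d sample(s), %d common enhancer(s)\n",
              length(x$per_sample), x$n_common))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Call super enhancers by geometric stitching
#'
#' H3K27ac peaks within `stitch_gap` of one another are stitched
#' (bedtools `-d` semantics: gap <= `stitch_gap` merges) and a stitched
#' region strictly longer than `size_threshold` is called a super
#' enhancer. This is the purely geometric rule — deliberately not the
#' ROSE signal-ranking algorithm. Input should be H3K27ac peaks, not
#' double-positive enhancers.
#'
#' @param h3k27ac_peaks canonical `IntervalSet` of H3K27ac peaks.
#' @param stitch_gap maximum gap in bp to stitch across (default 12500).
#' @param size_threshold minimum stitched length in bp, strict
#'   (default 15000).
#' @return a data.frame of class `SuperEnhancerSet` with columns `chrom`,
#'   `start`, `end`, `length`, `n_constituents`, `constituent_bp`, ordered
#'   by (chrom, start).
#' @export
call_super_enhancers <- function(h3k27ac_peaks, stitch_gap = 12500,
                                 size_threshold = 15000) {
  check_canonical(h3k27ac_peaks)
  if (length(stitch_gap) != 1 || is.na(stitch_gap) || stitch_gap <= 0)
    stop("stitch_gap must be a positive integer")
  if (length(size_threshold) != 1 || is.na(size_threshold) ||
      size_threshold <= 0)
    stop("size_threshold must be a positive integer")
  gr <- as_granges(h3k27ac_peaks)
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    length = numeric(), n_constituents = integer(),
                    constituent_bp = numeric(), stringsAsFactors = FALSE)
  if (length(gr) > 0) {
    red <- GenomicRanges::reduce(gr, min.gapwidth = stitch_gap + 1,
                                 with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    widths <- GenomicRanges::width(gr)
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(red)),
      start = GenomicRanges::start(red) - 1,
      end = GenomicRanges::end(red),
      stringsAsFactors = FALSE
    )
    df$length <- df$end - df$start
    df$n_constituents <- lengths(revmap)
    df$constituent_bp <- vapply(revmap, function(i) sum(widths[i]),
                                numeric(1))
    df <- df[df$length > size_threshold, , drop = FALSE]
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
    out <- df
  }
  structure(out,
            class = c("SuperEnhancerSet", "data.frame"),
            sample_id = h3k27ac_peaks$sample_id,
            stitch_gap = stitch_gap, size_threshold = size_threshold)
}

#' Convert a SuperEnhancerSet to an IntervalSet of stitched spans
#' @param ses a `SuperEnhancerSet`.
#' @return a canonical `IntervalSet`.
#' @export
super_enhancer_regions <- function(ses) {
  stopifnot(inherits(ses, "SuperEnhancerSet"))
  interval_set(ses$chrom, ses$start, ses$end,
               sample_id = attr(ses, "sample_id") %||% NA_character_,
               track_label = "super_enhancer", canonical = TRUE)
}

#' Common super enhancers across samples
#'
#' Consensus (all samples) over the per-sample stitched super-enhancer
#' spans.
#'
#' @param per_sample named list of `SuperEnhancerSet`s (>= 2 samples),
#'   each non-empty.
#' @return a canonical `IntervalSet` of common super-enhancer regions.
#' @export
common_super_enhancers <- function(per_sample) {
  if (!is.list(per_sample) || length(per_sample) < 2)
    stop("need at least two samples")
  empty <- vapply(per_sample, function(s) nrow(s) == 0, logical(1))
  if (any(empty))
    stop("sample(s) with no super enhancers: ",
         paste(names(per_sample)[empty], collapse = ", "))
  sets <- lapply(per_sample, super_enhancer_regions)
  consensus_intervals(sets, min_samples = length(sets))
}
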