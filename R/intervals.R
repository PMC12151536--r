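# All coordinates in this package are 0-based half-open (BED convention):
# an interval [start, end) covers bases start .. end-1. Zero-length
# intervals are rejected everywhere.

#' Construct an IntervalSet
#'
#' An `IntervalSet` is the package's substrate for all peak arithmetic: a
#' table of genomic intervals on named chromosomes, optionally labelled
#' with a specimen id and a track (mark/assay) label. Coordinates are
#' 0-based half-open. A set is *canonical* when its intervals are sorted
#' by (chrom, start, end) and no two intervals on the same chromosome
#' overlap or abut; raw sets (e.g. fresh from [read_bed()]) must be passed
#' through [canonicalize()] before set arithmetic.
#'
#' @param chrom character vector of chromosome names (no whitespace), or a
#'   data.frame with columns `chrom`, `start`, `end` (and optionally
#'   `name`, `score`).
#' @param start,end integer vectors, 0-based half-open; `start < end`.
#' @param name optional character labels.
#' @param score optional numeric annotation (e.g. narrowPeak signalValue).
#' @param sample_id,track_label optional specimen / assay labels.
#' @param canonical logical; assert that the intervals are already sorted
#'   and non-overlapping. Checked when `TRUE`.
#' @return An object of class `IntervalSet`.
#' @examples
#' s <- interval_set("chr1", c(0L, 200L), c(100L, 300L))
#' n_intervals(s)
#' @export
interval_set <- function(chrom, start = NULL, end = NULL, name = NULL,
                         score = NULL, sample_id = NA_character_,
                         track_label = NA_character_, canonical = FALSE) {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
    chrom <- df$chrom; start <- df$start; end <- df$end
    if (is.null(name) && !is.null(df$name)) name <- df$name
    if (is.null(score) && !is.null(df$score)) score <- df$score
  }
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) == 1 && length(start) > 1)
    chrom <- rep(chrom, length(start))
  n <- length(chrom)
  if (length(start) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  if (n > 0) {
    if (anyNA(chrom) || anyNA(start) || anyNA(end))
      stop("intervals contain missing values")
    if (any(grepl("[[:space:]]", chrom)))
      stop("chromosome names must not contain whitespace")
    if (any(start < 0))
      stop("interval start must be >= 0")
    bad <- which(start >= end)
    if (length(bad))
      stop(sprintf("zero- or negative-length interval at row %d (start %s >= end %s)",
                   bad[1], format(start[bad[1]], scientific = FALSE),
                   format(end[bad[1]], scientific = FALSE)))
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  df$name <- if (is.null(name)) rep(NA_character_, n) else as.character(name)
  df$score <- if (is.null(score)) rep(NA_real_, n) else as.numeric(score)
  obj <- structure(list(sample_id = sample_id, track_label = track_label,
                        intervals = df, canonical = isTRUE(canonical)),
                   class = "IntervalSet")
  if (isTRUE(canonical) && !is_sorted_disjoint(df))
    stop("intervals are not canonical (sorted, non-overlapping, non-abutting)")
  obj
}

is_sorted_disjoint <- function(df) {
  if (nrow(df) < 2) return(TRUE)
  o <- order(df$chrom, df$start, df$end)
  if (!identical(o, seq_len(nrow(df)))) return(FALSE)
  same <- df$chrom[-1] == df$chrom[-nrow(df)]
  gaps <- df$start[-1] - df$end[-nrow(df)]
  !any(same & gaps <= 0)
}

#' @export
print.IntervalSet <- function(x, ...) {
  cat(sprintf("IntervalSet: %d interval(s) on %d chromosome(s)%s\n",
              nrow(x$intervals), length(unique(x$intervals$chrom)),
              if (x$canonical) " [canonical]" else " [raw]"))
  if (!is.na(x$sample_id)) cat("  sample:", x$sample_id, "\n")
  if (!is.na(x$track_label)) cat("  track: ", x$track_label, "\n")
  if (nrow(x$intervals) > 0)
    print(utils::head(x$intervals, 6), row.names = FALSE)
  invisible(x)
}

#' Number of intervals in a set
#' @param set an `IntervalSet`.
#' @return integer count.
#' @export
n_intervals <- function(set) {
  stopifnot(inherits(set, "IntervalSet"))
  nrow(set$intervals)
}

#' @export
as.data.frame.IntervalSet <- function(x, ...) x$intervals

#' Total bases covered by a canonical set
#' @param set a canonical `IntervalSet`.
#' @return numeric, total covered base pairs.
#' @export
covered_bases <- function(set) {
  check_canonical(set)
  sum(set$intervals$end - set$intervals$start)
}

check_canonical <- function(set, arg = deparse(substitute(set))) {
  if (!inherits(set, "IntervalSet"))
    stop(sprintf("%s must be an IntervalSet", arg))
  if (!set$canonical)
    stop(sprintf("%s must be canonical; call canonicalize() first", arg))
  invisible(set)
}

# GRanges bridge: BED half-open [start,end) <-> 1-based closed [start+1, end]
as_granges <- function(set) {
  df <- set$intervals
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

granges_to_set <- function(gr, sample_id = NA_character_,
                           track_label = NA_character_) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr) - 1
  end <- GenomicRanges::end(gr)
  o <- order(chrom, start, end)
  interval_set(chrom[o], start[o], end[o], sample_id = sample_id,
               track_label = track_label, canonical = TRUE)
}

#' Merge intervals with a gap tolerance (bedtools-style)
#'
#' Joins intervals whose gap (`later.start - earlier.end`) is at most
#' `max_gap`; overlapping and book-ended intervals always join at
#' `max_gap = 0`. This reproduces `bedtools merge -d <max_gap>` semantics
#' and is the stitching primitive for super-enhancer calling.
#'
#' @param set an `IntervalSet` (raw input allowed).
#' @param max_gap non-negative integer, maximum gap in bp to close.
#' @return a canonical `IntervalSet` covering the union of input bases
#'   plus closed gaps; idempotent.
#' @examples
#' s <- interval_set("chr1", c(0, 12600), c(100, 12700))
#' n_intervals(merge_intervals(s, 12500))  # gap 12500 <= 12500: merged
#' @export
merge_intervals <- function(set, max_gap = 0) {
  stopifnot(inherits(set, "IntervalSet"))
  if (length(max_gap) != 1 || is.na(max_gap) || max_gap < 0)
    stop("max_gap must be a single non-negative integer")
  if (nrow(set$intervals) == 0)
    return(interval_set(character(), numeric(), numeric(),
                        sample_id = set$sample_id,
                        track_label = set$track_label, canonical = TRUE))
  gr <- GenomicRanges::reduce(as_granges(set), min.gapwidth = max_gap + 1)
  granges_to_set(gr, set$sample_id, set$track_label)
}

#' Canonicalize a raw IntervalSet
#'
#' Sorts and merges overlapping/abutting intervals (gap tolerance 0).
#' @param set an `IntervalSet`.
#' @return a canonical `IntervalSet`.
#' @export
canonicalize <- function(set) merge_intervals(set, 0)

#' Base-pair intersection of two canonical sets
#'
#' Returns the exact regions covered by both sets (per-base AND), e.g.
#' genomic regions carrying both H3K27ac and H3K4me1 marks.
#'
#' @param a,b canonical `IntervalSet`s.
#' @return a canonical `IntervalSet`.
#' @export
intersect_regions <- function(a, b) {
  check_canonical(a); check_canonical(b)
  # suppressWarnings: GenomicRanges warns when the two sets mention
  # different chromosomes; disjoint chromosome namespaces are legitimate
  # here (exact-name matching, empty result)
  gr <- suppressWarnings(
    GenomicRanges::intersect(as_granges(a), as_granges(b),
                             ignore.strand = TRUE))
  granges_to_set(gr, a$sample_id,
                 paste_tracks(a$track_label, b$track_label))
}

paste_tracks <- function(a, b) {
  if (is.na(a) && is.na(b)) return(NA_character_)
  paste(stats::na.omit(c(a, b)), collapse = "&")
}

#' Keep query intervals overlapping a subject set
#'
#' Returns query intervals (whole, unclipped) that share at least
#' `min_overlap_bp` bases with any subject interval — the primitive behind
#' colocalization of regions with a TF occupancy cistrome.
#'
#' @param query,subject canonical `IntervalSet`s.
#' @param min_overlap_bp minimum shared bases, integer >= 1.
#' @return a canonical `IntervalSet`, subset of `query`.
#' @export
filter_overlapping <- function(query, subject, min_overlap_bp = 1) {
  check_canonical(query); check_canonical(subject)
  if (length(min_overlap_bp) != 1 || is.na(min_overlap_bp) || min_overlap_bp < 1)
    stop("min_overlap_bp must be >= 1")
  if (nrow(query$intervals) == 0) return(query)
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(as_granges(query), as_granges(subject),
                                 minoverlap = min_overlap_bp,
                                 ignore.strand = TRUE))
  keep <- hits > 0
  df <- query$intervals[keep, , drop = FALSE]
  interval_set(df, sample_id = query$sample_id,
               track_label = query$track_label, canonical = TRUE)
}

#' Multi-sample consensus intervals
#'
#' Builds the merged union (gap 0) of all sets, then retains each union
#' interval overlapped (>= 1 bp) by intervals from at least `min_samples`
#' distinct input sets. With `min_samples = 1` this equals the pooled
#' merge. This is how "common" peaks/enhancers across specimens are
#' counted: on the symmetric union, not against a reference sample.
#'
#' @param sets a list of `IntervalSet`s (one per sample).
#' @param min_samples integer in `[1, length(sets)]`.
#' @return a canonical `IntervalSet` of supported union intervals, with a
#'   `support` column attached as attribute `"support"`.
#' @export
consensus_intervals <- function(sets, min_samples) {
  if (!is.list(sets) || length(sets) < 1 || !all(vapply(sets, inherits,
      logical(1), "IntervalSet")))
    stop("sets must be a non-empty list of IntervalSet objects")
  n <- length(sets)
  if (length(min_samples) != 1 || is.na(min_samples) ||
      min_samples < 1 || min_samples > n)
    stop(sprintf("min_samples must be in [1, %d]", n))
  grl <- lapply(sets, as_granges)
  pooled <- suppressWarnings(do.call(c, unname(grl)))
  if (length(pooled) == 0)
    return(interval_set(character(), numeric(), numeric(), canonical = TRUE))
  union_gr <- GenomicRanges::reduce(pooled, min.gapwidth = 1)
  support <- Reduce(`+`, lapply(grl, function(g)
    as.integer(suppressWarnings(
      GenomicRanges::countOverlaps(union_gr, g,
                                   ignore.strand = TRUE)) > 0)))
  keep <- support >= min_samples
  out <- granges_to_set(union_gr[keep])
  attr(out, "support") <- support[keep]
  out
}

#' Overlap fraction of a query set against a subject set
#'
#' @param query,subject canonical `IntervalSet`s; `query` must be
#'   non-empty.
#' @param min_overlap_bp minimum shared bases to count an overlap.
#' @return a list of class `OverlapReport` with `n_query`,
#'   `n_overlapping` and `fraction`.
#' @export
overlap_report <- function(query, subject, min_overlap_bp = 1) {
  check_canonical(query); check_canonical(subject)
  if (nrow(query$intervals) == 0)
    stop("query set is empty; overlap fraction undefined")
  n_hit <- n_intervals(filter_overlapping(query, subject, min_overlap_bp))
  structure(list(n_query = n_intervals(query), n_overlapping = n_hit,
                 fraction = n_hit / n_intervals(query)),
            class = "OverlapReport")
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat(sprintf("OverlapReport: %d / %d query intervals overlap (%.1f%%)\n",
              x$n_overlapping, x$n_query, 100 * x$fraction))
  invisible(x)
}

#' Read a BED-family file
#'
#' Supports BED3, BED6 and ENCODE narrowPeak (10 columns; `signalValue`
#' mapped to `score`). Returns a *raw* set preserving row order; zero- or
#' negative-length intervals are rejected with the offending line number.
#'
#' @param path file path, tab-separated, no header.
#' @param dialect one of `"bed3"`, `"bed6"`, `"narrowPeak"`.
#' @param sample_id,track_label optional labels attached to the set.
#' @return a raw `IntervalSet`.
#' @export
read_bed <- function(path, dialect = c("bed3", "bed6", "narrowPeak"),
                     sample_id = NA_character_, track_label = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(interval_set(character(), numeric(), numeric(),
                        sample_id = sample_id, track_label = track_label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- switch(dialect, bed3 = 3L, bed6 = 6L, narrowPeak = 10L)
  bad <- which(nf < need)
  if (length(bad))
    stop(sprintf("%s: line %d has %d field(s); %s requires >= %d",
                 path, bad[1], nf[bad[1]], dialect, need))
  getcol <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- getcol(1)
  start <- suppressWarnings(as.numeric(getcol(2)))
  end <- suppressWarnings(as.numeric(getcol(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("%s: line %d: coordinates do not parse as integers",
                 path, bad[1]))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("%s: line %d: start >= end (zero-length intervals are forbidden)",
                 path, bad[1]))
  bad <- which(start < 0)
  if (length(bad))
    stop(sprintf("%s: line %d: negative start coordinate", path, bad[1]))
  name <- NULL; score <- NULL
  if (dialect %in% c("bed6", "narrowPeak")) {
    name <- getcol(4)
    name[name == "."] <- NA_character_
  }
  if (dialect == "bed6") {
    s <- getcol(5)
    score <- suppressWarnings(as.numeric(s))
    score[s == "."] <- NA_real_
  } else if (dialect == "narrowPeak") {
    s <- getcol(7)  # signalValue
    score <- suppressWarnings(as.numeric(s))
  }
  interval_set(chrom, start, end, name = name, score = score,
               sample_id = sample_id, track_label = track_label,
               canonical = FALSE)
}

#' Write an IntervalSet as BED
#'
#' Writes BED3 when the set carries no names/scores, BED6 otherwise
#' (missing name/score rendered as `.`/`0` placeholder columns only when
#' needed). Round-trips losslessly through [read_bed()] for bed3/bed6.
#'
#' @param set an `IntervalSet`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(set, path) {
  stopifnot(inherits(set, "IntervalSet"))
  df <- set$intervals
  fmt_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (nrow(df) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (all(is.na(df$name)) && all(is.na(df$score))) {
    lines <- paste(df$chrom, fmt_coord(df$start), fmt_coord(df$end),
                   sep = "\t")
  } else {
    nm <- ifelse(is.na(df$name), ".", df$name)
    sc <- ifelse(is.na(df$score), ".",
                 format(df$score, scientific = FALSE, trim = TRUE))
    lines <- paste(df$chrom, fmt_coord(df$start), fmt_coord(df$end),
                   nm, sc, ".", sep = "\t")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
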