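# Seeded synthetic-data generators. Each generator returns the objects
# the pipeline consumes plus a manifest recording the planted ground
# truth, so every downstream stage has a recovery test that needs no
# external data. Regeneration from (seed, parameters) is bit-identical.

#' Simulate multi-sample peak sets for two histone marks
#'
#' Emulates the three-subject H3K27ac/H3K4me1 structure: `n_shared`
#' peak loci appear in every sample for both marks (with boundary jitter
#' up to `jitter_bp`), so they are double-positive and survive an
#' all-sample consensus; each sample additionally carries
#' `n_private_per_sample` private loci per mark. Loci are laid out on
#' non-overlapping slots so jitter can never fuse distinct loci.
#'
#' @param n_samples number of specimens (default 3).
#' @param n_shared shared (consensus-recoverable, double-positive) loci.
#' @param n_private_per_sample private loci per sample and mark.
#' @param jitter_bp maximum boundary jitter in bp.
#' @param peak_width range of peak widths in bp (min must exceed
#'   `2 * jitter_bp`).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param seed integer RNG seed.
#' @return a list with `h3k27ac` and `h3k4me1` (named lists of canonical
#'   `IntervalSet`s per sample) and `manifest` (planted truth).
#' @export
simulate_peaksets <- function(n_samples = 3, n_shared = 200,
                              n_private_per_sample = 100, jitter_bp = 200,
                              peak_width = c(600, 1600),
                              chrom_lengths = c(chrS1 = 120e6, chrS2 = 90e6),
                              seed = 1) {
  stopifnot(n_samples >= 1, n_shared >= 0, n_private_per_sample >= 0,
            jitter_bp >= 0, peak_width[1] > 2 * jitter_bp + 10)
  pitch <- peak_width[2] + 2 * jitter_bp + 4000  # slot pitch; gap > 0 always
  n_slots <- n_shared + 2 * n_samples * n_private_per_sample
  capacity <- sum(floor((chrom_lengths - 2 * pitch) / pitch))
  if (n_slots > capacity)
    stop("requested peaks do not fit the genome; enlarge chrom_lengths")
  with_seed(seed, {
    # slot coordinates across chromosomes, then shuffled role assignment
    slots <- list()
    remaining <- n_slots
    for (ch in names(chrom_lengths)) {
      cap <- floor((chrom_lengths[[ch]] - 2 * pitch) / pitch)
      take <- min(cap, remaining)
      if (take > 0)
        slots[[ch]] <- data.frame(chrom = ch,
                                  pos = pitch + pitch * (seq_len(take) - 1),
                                  stringsAsFactors = FALSE)
      remaining <- remaining - take
      if (remaining == 0) break
    }
    slots <- do.call(rbind, slots)
    slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
    rownames(slots) <- NULL
    role <- c(rep("shared", n_shared),
              rep(sprintf("private_k27_s%d", seq_len(n_samples)),
                  each = n_private_per_sample),
              rep(sprintf("private_k4_s%d", seq_len(n_samples)),
                  each = n_private_per_sample))
    slots$role <- role
    slots$width <- round(stats::runif(nrow(slots), peak_width[1],
                                      peak_width[2]))
    jit <- function(n) if (jitter_bp > 0)
      round(stats::runif(n, -jitter_bp, jitter_bp)) else rep(0, n)
    sample_ids <- sprintf("S%d", seq_len(n_samples))
    make_track <- function(s, mark) {
      rows <- slots$role == "shared" |
        slots$role == sprintf("private_%s_s%d",
                              if (mark == "h3k27ac") "k27" else "k4", s)
      df <- slots[rows, , drop = FALSE]
      start <- df$pos + jit(nrow(df))
      end <- df$pos + df$width + jit(nrow(df))
      interval_set(df$chrom, start, end, sample_id = sample_ids[s],
                   track_label = if (mark == "h3k27ac") "H3K27ac"
                                 else "H3K4me1") |> canonicalize()
    }
    h3k27ac <- lapply(seq_len(n_samples), make_track, mark = "h3k27ac")
    h3k4me1 <- lapply(seq_len(n_samples), make_track, mark = "h3k4me1")
    names(h3k27ac) <- names(h3k4me1) <- sample_ids
    shared <- slots[slots$role == "shared", c("chrom", "pos", "width")]
    manifest <- list(
      generator = "simulate_peaksets", seed = seed,
      params = list(n_samples = n_samples, n_shared = n_shared,
                    n_private_per_sample = n_private_per_sample,
                    jitter_bp = jitter_bp, peak_width = peak_width),
      shared_loci = shared,
      n_expected_consensus = n_shared,
      n_expected_common_enhancers = n_shared
    )
    list(h3k27ac = h3k27ac, h3k4me1 = h3k4me1, manifest = manifest)
  })
}

# Build one exact-span peak cluster: first peak starts at `origin`, last
# peak ends at origin + span, all intra-cluster gaps <= 12500 (provided
# span <= ~28 kb for the 2-peak layout; a mid peak is inserted for wider
# spans). Returns a data.frame of peaks.
cluster_peaks <- function(origin, span, intra_gap_max) {
  if (span <= 2) stop("cluster span too small")
  w <- ceiling((span - intra_gap_max + 1000) / 2)
  w <- max(w, 500)
  if (2 * w + 1 > span) w <- floor((span - 500) / 2)
  if (w < 1) { w <- floor(span / 3); if (w < 1) w <- 1 }
  gap <- span - 2 * w
  peaks <- data.frame(start = c(origin, origin + span - w),
                      end = c(origin + w, origin + span))
  # split the gap with a middle peak when it would exceed the max,
  # and sometimes anyway for constituent-count variety
  if (gap > intra_gap_max ||
      (gap > 3000 && stats::runif(1) < 0.5)) {
    mid_w <- min(1000, gap - 2)
    mid_s <- origin + w + floor((gap - mid_w) / 2)
    peaks <- rbind(peaks[1, ], data.frame(start = mid_s,
                                          end = mid_s + mid_w),
                   peaks[2, ])
    if (max(peaks$start[-1] - peaks$end[-nrow(peaks)]) > intra_gap_max)
      stop("internal: cluster gap constraint violated")
  }
  peaks
}

#' Simulate a super-enhancer landscape with planted clusters
#'
#' Plants exactly `k_clusters` stitchable clusters (intra-cluster gaps
#' <= `intra_gap_max`, total span drawn from `span_range`) separated by
#' more than `intra_gap_max` from everything else, plus isolated decoy
#' peaks whose stitched span stays at or below `size_threshold`.
#' With the default thresholds, [call_super_enhancers()] recovers exactly
#' the planted clusters with their exact spans.
#'
#' @param k_clusters number of planted clusters (>= 0).
#' @param span_range numeric length-2, cluster span range in bp.
#' @param n_decoys isolated sub-threshold peaks.
#' @param intra_gap_max maximum intra-cluster gap (default 12500).
#' @param inter_gap spacing between elements, must exceed
#'   `intra_gap_max`.
#' @param chrom chromosome name.
#' @param seed integer RNG seed.
#' @return a list with `peaks` (canonical `IntervalSet`) and `manifest`
#'   (with `cluster_spans` data.frame: start, end, span).
#' @export
simulate_super_enhancer_landscape <- function(k_clusters = 5,
                                              span_range = c(15500, 28000),
                                              n_decoys = 20,
                                              intra_gap_max = 12500,
                                              inter_gap = 20000,
                                              chrom = "chrS1", seed = 1) {
  stopifnot(k_clusters >= 0, n_decoys >= 0, inter_gap > intra_gap_max,
            span_range[1] > 1000, span_range[2] >= span_range[1])
  with_seed(seed, {
    kinds <- sample(c(rep("cluster", k_clusters), rep("decoy", n_decoys)))
    cursor <- 10000
    peaks <- list(); spans <- list()
    for (kind in kinds) {
      if (kind == "cluster") {
        span <- round(stats::runif(1, span_range[1], span_range[2]))
        pk <- cluster_peaks(cursor, span, intra_gap_max)
        peaks[[length(peaks) + 1]] <- pk
        spans[[length(spans) + 1]] <- data.frame(start = cursor,
                                                 end = cursor + span,
                                                 span = span)
        cursor <- cursor + span
      } else {
        w <- round(stats::runif(1, 800, 3000))
        peaks[[length(peaks) + 1]] <- data.frame(start = cursor,
                                                 end = cursor + w)
        cursor <- cursor + w
      }
      cursor <- cursor + inter_gap + round(stats::runif(1, 0, 5000))
    }
    pk <- if (length(peaks)) do.call(rbind, peaks) else
      data.frame(start = numeric(), end = numeric())
    set <- interval_set(rep(chrom, nrow(pk)), pk$start, pk$end,
                        sample_id = "sim", track_label = "H3K27ac",
                        canonical = FALSE)
    set <- canonicalize(set)
    manifest <- list(
      generator = "simulate_super_enhancer_landscape", seed = seed,
      params = list(k_clusters = k_clusters, span_range = span_range,
                    n_decoys = n_decoys, intra_gap_max = intra_gap_max,
                    inter_gap = inter_gap, chrom = chrom),
      cluster_spans = if (length(spans)) {
        s <- do.call(rbind, spans); s[order(s$start), , drop = FALSE]
      } else data.frame(start = numeric(), end = numeric(),
                        span = numeric())
    )
    rownames(manifest$cluster_spans) <- NULL
    list(peaks = set, manifest = manifest)
  })
}

#' Simulate expression, gene models and planted enhancer-gene links
#'
#' Builds `n_enhancers` enhancers on a wide grid (pitch greater than
#' twice the window, so a gene planted for one enhancer can never fall
#' into another enhancer's window), then for each expression bin plants
#' genes inside the window of `round(fraction * n_enhancers)` enhancers.
#' FPKM values are drawn log-uniformly within the bin's bounds, with
#' symmetric per-sample jitter so the mean FPKM stays inside the bin.
#' Filler genes live on a separate chromosome with no enhancers.
#'
#' @param n_enhancers number of enhancers (default 540).
#' @param bin_fractions named fractions in `[0, 1]` for bins
#'   `inactive`, `low`, `mid`, `high`.
#' @param window association window in bp (default 100000).
#' @param n_samples expression columns (default 3).
#' @param n_filler unlinked background genes (default 100).
#' @param enhancer_width enhancer width in bp.
#' @param seed integer RNG seed.
#' @return a list with `enhancers` (canonical `IntervalSet`), `genes`
#'   (`GeneModels`), `fpkm` (gene x sample matrix) and `manifest`
#'   (per-bin planted enhancer counts and ids).
#' @export
simulate_expression_and_links <- function(n_enhancers = 540,
                                          bin_fractions = c(inactive = 0.05,
                                                            low = 0.073,
                                                            mid = 0.15,
                                                            high = 0.40),
                                          window = 100000, n_samples = 3,
                                          n_filler = 100,
                                          enhancer_width = 2000, seed = 1) {
  labs <- c("inactive", "low", "mid", "high")
  stopifnot(all(labs %in% names(bin_fractions)),
            all(bin_fractions >= 0 & bin_fractions <= 1),
            n_enhancers >= 1, window > 0, n_samples >= 1)
  bounds <- list(inactive = c(0.02, 0.95), low = c(1.0, 4.9),
                 mid = c(5.0, 14.9), high = c(15.0, 300))
  with_seed(seed, {
    pitch <- 2 * window + enhancer_width + 20000
    start <- pitch * seq_len(n_enhancers)
    enh <- interval_set(rep("chrE1", n_enhancers), start,
                        start + enhancer_width,
                        track_label = "enhancer", canonical = TRUE)
    ids <- enhancer_ids(enh)
    mid_pt <- start + enhancer_width / 2
    genes <- list(); fpkm <- list()
    planted <- list()
    max_off <- window - enhancer_width / 2 - 1000
    for (b in labs) {
      k <- round(bin_fractions[[b]] * n_enhancers)
      planted[[b]] <- list(n = k, enhancer_ids = character())
      if (k == 0) next
      sel <- sort(sample.int(n_enhancers, k))
      planted[[b]]$enhancer_ids <- ids[sel]
      off <- round(stats::runif(k, -max_off, max_off))
      gid <- sprintf("G_%s_%d", toupper(substr(b, 1, 2)), seq_len(k))
      genes[[b]] <- data.frame(gene_id = gid, chrom = "chrE1",
                               strand = sample(c("+", "-"), k, TRUE),
                               tss = pmax(0, mid_pt[sel] + off),
                               stringsAsFactors = FALSE)
      lo <- bounds[[b]][1]; hi <- bounds[[b]][2]
      fpkm[[b]] <- exp(stats::runif(k, log(lo), log(hi)))
    }
    if (n_filler > 0) {
      gid <- sprintf("G_FILL_%d", seq_len(n_filler))
      genes$filler <- data.frame(gene_id = gid, chrom = "chrF1",
                                 strand = sample(c("+", "-"), n_filler,
                                                 TRUE),
                                 tss = 50000 * seq_len(n_filler),
                                 stringsAsFactors = FALSE)
      fpkm$filler <- exp(stats::runif(n_filler, log(0.02), log(300)))
    }
    gdf <- do.call(rbind, genes)
    gm <- gene_models(gdf$gene_id, gdf$chrom, gdf$strand, gdf$tss)
    base <- unlist(fpkm, use.names = FALSE)
    # symmetric multiplicative jitter keeps the mean exactly at `base`
    jit <- seq(-0.08, 0.08, length.out = n_samples)
    mat <- outer(base, 1 + jit)
    rownames(mat) <- gdf$gene_id
    colnames(mat) <- sprintf("S%d", seq_len(n_samples))
    manifest <- list(
      generator = "simulate_expression_and_links", seed = seed,
      params = list(n_enhancers = n_enhancers,
                    bin_fractions = as.list(bin_fractions),
                    window = window, n_samples = n_samples),
      planted = lapply(planted, function(p)
        list(n = p$n, enhancer_ids = p$enhancer_ids)),
      expected_fractions = stats::setNames(
        vapply(labs, function(b) planted[[b]]$n / n_enhancers, numeric(1)),
        labs)
    )
    list(enhancers = enh, genes = gm, fpkm = mat, manifest = manifest)
  })
}

#' Simulate an expression matrix with a planted activity axis
#'
#' Per-sample activity `delta` is standard normal; up-signature genes are
#' shifted by `+delta_scale * delta`, down genes by the negative, plus
#' i.i.d. noise. The target gene is drawn so that its correlation with
#' `delta` is `rho` in expectation.
#'
#' @param n_samples specimens (default 43).
#' @param n_up,n_down signature sizes (default 50 each).
#' @param n_background non-signature genes.
#' @param delta_scale shift per unit activity (FPKM units, default 2).
#' @param noise_sd per-gene noise SD (default 1).
#' @param rho planted target-activity correlation, |rho| < 1
#'   (default 0.47).
#' @param target_gene name of the target gene row.
#' @param seed integer RNG seed.
#' @return a list with `fpkm` (matrix, target gene included),
#'   `signature` (`GeneSignature`), `target_gene`, and `manifest`
#'   (with the planted `delta` vector and `rho`).
#' @export
simulate_activity_correlation <- function(n_samples = 43, n_up = 50,
                                          n_down = 50, n_background = 400,
                                          delta_scale = 2, noise_sd = 1,
                                          rho = 0.47,
                                          target_gene = "TARGETG",
                                          seed = 1) {
  stopifnot(n_samples >= 3, n_up >= 2, n_down >= 2, abs(rho) < 1,
            delta_scale > 0, noise_sd >= 0)
  with_seed(seed, {
    delta <- stats::rnorm(n_samples)
    sid <- sprintf("M%02d", seq_len(n_samples))
    up <- sprintf("SIGUP%d", seq_len(n_up))
    dn <- sprintf("SIGDN%d", seq_len(n_down))
    bg <- sprintf("BG%d", seq_len(n_background))
    mk <- function(genes, dir) {
      mu <- stats::runif(length(genes), 10, 100)
      m <- outer(mu, rep(1, n_samples)) +
        dir * delta_scale * outer(rep(1, length(genes)), delta) +
        matrix(stats::rnorm(length(genes) * n_samples, sd = noise_sd),
               nrow = length(genes), ncol = n_samples)
      rownames(m) <- genes
      m
    }
    mat <- rbind(mk(up, +1), mk(dn, -1), mk(bg, 0))
    tvar <- rho * delta + sqrt(1 - rho^2) * stats::rnorm(n_samples)
    target <- 50 + 5 * tvar
    mat <- rbind(mat, matrix(target, nrow = 1,
                             dimnames = list(target_gene, NULL)))
    mat <- pmax(mat, 0)
    colnames(mat) <- sid
    manifest <- list(generator = "simulate_activity_correlation",
                     seed = seed,
                     params = list(n_samples = n_samples, n_up = n_up,
                                   n_down = n_down,
                                   n_background = n_background,
                                   delta_scale = delta_scale,
                                   noise_sd = noise_sd, rho = rho),
                     delta = stats::setNames(delta, sid), rho = rho)
    list(fpkm = mat,
         signature = gene_signature(up, dn, "planted activity axis"),
         target_gene = target_gene, manifest = manifest)
  })
}

#' Simulate a CRISPRa Perturb-seq dataset
#'
#' Cells are assigned a multiplicity class (`none`/`singlet`/`multiplet`)
#' with the given probabilities; detected gRNAs receive Poisson-shifted
#' counts. Gene counts are negative binomial; each gRNA's planted fold
#' change multiplies its target gene's mean in that gRNA's singlet cells
#' only. The default panel mirrors an 8-guide enhancer screen around one
#' target gene plus a non-targeting control.
#'
#' @param n_cells cells (default 2000).
#' @param grna_targets named character gRNA -> target gene; default an
#'   8-guide panel targeting `PLCL2` plus `NonTargeting`.
#' @param fold_changes named per-gRNA planted fold changes (control 1).
#' @param multiplicity_probs probabilities for classes
#'   none/singlet/multiplet, summing to 1.
#' @param n_genes gene count including the target (default 300).
#' @param nb_size negative-binomial size (inverse dispersion,
#'   default 10).
#' @param control_label non-targeting gRNA id.
#' @param seed integer RNG seed.
#' @return a list with `dataset` (`PerturbDataset`) and `manifest`
#'   (planted classes per cell, per-gRNA fold changes).
#' @export
simulate_perturb <- function(n_cells = 2000,
                             grna_targets = NULL, fold_changes = NULL,
                             multiplicity_probs = c(none = 0.163,
                                                    singlet = 0.567,
                                                    multiplet = 0.270),
                             n_genes = 300, nb_size = 10,
                             control_label = "NonTargeting", seed = 1) {
  stopifnot(abs(sum(multiplicity_probs) - 1) < 1e-9,
            all(multiplicity_probs >= 0), n_cells >= 10, n_genes >= 2)
  if (is.null(grna_targets)) {
    grna_targets <- stats::setNames(rep("PLCL2", 8),
                                    sprintf("PLCL2-%d", 1:8))
    grna_targets[control_label] <- control_label
  }
  grnas <- names(grna_targets)
  if (!(control_label %in% grnas))
    stop("control_label must be in grna_targets")
  if (is.null(fold_changes)) {
    fold_changes <- stats::setNames(
      c(1.8, 1.0, 1.7, 1.0, 3.0, 1.6, 2.0, 2.2, 1.0)[seq_along(grnas)],
      grnas)
    fold_changes[control_label] <- 1.0
  }
  if (!all(grnas %in% names(fold_changes)))
    stop("fold_changes must cover every gRNA")
  with_seed(seed, {
    cells <- sprintf("CELL%05d", seq_len(n_cells))
    cls <- sample(c("none", "singlet", "multiplet"), n_cells,
                  replace = TRUE, prob = multiplicity_probs)
    grna_counts <- matrix(0L, nrow = length(grnas), ncol = n_cells,
                          dimnames = list(grnas, cells))
    cell_grna <- rep(NA_character_, n_cells)
    for (i in seq_len(n_cells)) {
      if (cls[i] == "none") next
      k <- if (cls[i] == "singlet") 1 else
        sample(2:min(3, length(grnas)), 1)
      g <- sample(grnas, k)
      grna_counts[g, i] <- 1L + stats::rpois(k, 15)
      if (k == 1) cell_grna[i] <- g
    }
    target_genes <- setdiff(unique(unname(grna_targets)), control_label)
    other <- sprintf("GENE%04d", seq_len(max(0, n_genes -
                                               length(target_genes))))
    gene_ids <- c(target_genes, other)
    mu <- exp(stats::rnorm(length(gene_ids), log(3), 0.8))
    names(mu) <- gene_ids
    mu[target_genes] <- 5  # moderate baseline so FC is detectable
    expr <- matrix(0L, nrow = length(gene_ids), ncol = n_cells,
                   dimnames = list(gene_ids, cells))
    fc_cell <- matrix(1, nrow = length(gene_ids), ncol = n_cells)
    rownames(fc_cell) <- gene_ids
    sing <- which(!is.na(cell_grna))
    for (i in sing) {
      tg <- grna_targets[[cell_grna[i]]]
      if (tg %in% gene_ids)
        fc_cell[tg, i] <- fold_changes[[cell_grna[i]]]
    }
    for (g in seq_along(gene_ids)) {
      expr[g, ] <- stats::rnbinom(n_cells, size = nb_size,
                                  mu = mu[g] * fc_cell[g, ])
    }
    dataset <- perturb_dataset(grna_counts, expr, grna_targets,
                               control_label)
    manifest <- list(generator = "simulate_perturb", seed = seed,
                     params = list(n_cells = n_cells, n_genes = n_genes,
                                   nb_size = nb_size,
                                   multiplicity_probs =
                                     as.list(multiplicity_probs)),
                     classes = stats::setNames(cls, cells),
                     cell_grna = stats::setNames(cell_grna, cells),
                     fold_changes = as.list(fold_changes),
                     grna_targets = as.list(grna_targets))
    list(dataset = dataset, manifest = manifest)
  })
}

#' Simulate a TF-occupancy cistrome over a region catalog
#'
#' Plants occupancy intervals over an exact fraction of the supplied
#' regions (e.g. 76 of 100 super enhancers), plus unrelated occupancy
#' sites elsewhere, so [colocalize()] recovers the planted percentage
#' exactly.
#'
#' @param regions canonical `IntervalSet`.
#' @param fraction fraction of regions to cover (default 0.76).
#' @param n_extra unrelated occupancy intervals on a separate
#'   chromosome.
#' @param seed integer RNG seed.
#' @return a list with `occupancy` (canonical `IntervalSet`) and
#'   `manifest` (covered region ids, expected percent).
#' @export
simulate_occupancy <- function(regions, fraction = 0.76, n_extra = 50,
                               seed = 1) {
  check_canonical(regions)
  stopifnot(fraction >= 0, fraction <= 1)
  n <- n_intervals(regions)
  k <- round(fraction * n)
  with_seed(seed, {
    sel <- if (k > 0) sort(sample.int(n, k)) else integer()
    df <- regions$intervals[sel, , drop = FALSE]
    occ <- data.frame(chrom = df$chrom,
                      start = floor((df$start + df$end) / 2) - 100,
                      end = floor((df$start + df$end) / 2) + 100)
    if (n_extra > 0) {
      pos <- 5000 * seq_len(n_extra)
      occ <- rbind(occ, data.frame(chrom = "chrOCC", start = pos,
                                   end = pos + 200))
    }
    set <- canonicalize(interval_set(occ$chrom, occ$start, occ$end,
                                     track_label = "occupancy"))
    manifest <- list(generator = "simulate_occupancy", seed = seed,
                     params = list(fraction = fraction, n_extra = n_extra),
                     covered_ids = enhancer_ids(regions)[sel],
                     n_covered = k,
                     expected_percent = round(100 * k / n, 1))
    list(occupancy = set, manifest = manifest)
  })
}
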