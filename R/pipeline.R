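# End-to-end pipeline: config validation, stage orchestration, and a
# deterministic JSON run report.

#' Read a gene x sample expression TSV
#'
#' First column = gene id, remaining columns = samples; tab-separated
#' with a header row.
#' @param path input TSV.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a gene x sample expression TSV
#' @param mat numeric matrix with gene rownames.
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

default_thresholds <- function() {
  list(stitch_gap = 12500, size_threshold = 15000, window = 100000,
       fpkm_bins = c(1, 5, 15), fc_threshold = 1.5, alpha = 0.05,
       target_depth = 56.5e6, min_overlap = 1)
}

default_modes <- function() {
  list(enhancer_mode = "double_positive_union", anchor = "midpoint")
}

#' Validate a pipeline configuration file
#'
#' The config is a single JSON file. Required: `samples`, an array of
#' objects with `id`, `h3k27ac`, `h3k4me1` (BED paths), and `genes` +
#' `fpkm` for association. Optional sections: `loops` (BEDPE),
#' `occupancy` (BED), `activity` (`expression`, `signature`,
#' `target_gene`), `perturb` (MTX paths + `control`), `thresholds`,
#' `modes`, `seed`, `outdir`. Missing thresholds default to the standard
#' constants (stitch gap 12500, size threshold 15000, window 100000,
#' FPKM bins 1/5/15, FC 1.5, alpha 0.05, target depth 56.5e6).
#'
#' @param path JSON config path.
#' @return a validated config list of class `RunConfig`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  known <- c("samples", "genes", "fpkm", "loops", "occupancy", "activity",
             "perturb", "thresholds", "modes", "seed", "outdir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  problems <- character()
  if (is.null(cfg$samples) || length(cfg$samples) < 2)
    problems <- c(problems, "samples: need >= 2 entries")
  th <- utils::modifyList(default_thresholds(),
                          lapply(cfg$thresholds %||% list(), unlist))
  for (k in c("stitch_gap", "size_threshold", "window", "fc_threshold",
              "alpha", "target_depth", "min_overlap")) {
    if (!is.numeric(th[[k]]) || length(th[[k]]) != 1 || th[[k]] <= 0)
      problems <- c(problems, sprintf("thresholds$%s: must be a positive number", k))
  }
  if (length(th$fpkm_bins) != 3 || is.unsorted(th$fpkm_bins))
    problems <- c(problems, "thresholds$fpkm_bins: need 3 increasing values")
  md <- utils::modifyList(default_modes(),
                          lapply(cfg$modes %||% list(), unlist))
  if (!md$enhancer_mode %in% c("double_positive_union", "intersection"))
    problems <- c(problems, "modes$enhancer_mode: invalid")
  if (!md$anchor %in% c("midpoint", "edge"))
    problems <- c(problems, "modes$anchor: invalid")
  need_file <- function(p, label) {
    if (is.null(p)) return(invisible())
    if (!file.exists(p))
      problems <<- c(problems, sprintf("%s: file not found: %s", label, p))
  }
  for (s in cfg$samples) {
    if (is.null(s$id) || is.null(s$h3k27ac) || is.null(s$h3k4me1)) {
      problems <- c(problems, "samples: each entry needs id, h3k27ac, h3k4me1")
      next
    }
    need_file(s$h3k27ac, paste0("samples[", s$id, "]$h3k27ac"))
    need_file(s$h3k4me1, paste0("samples[", s$id, "]$h3k4me1"))
  }
  ids <- vapply(cfg$samples, function(s) s$id %||% NA_character_,
                character(1))
  if (any(duplicated(stats::na.omit(ids))))
    problems <- c(problems, "samples: duplicate sample ids")
  need_file(cfg$genes, "genes")
  need_file(cfg$fpkm, "fpkm")
  need_file(cfg$loops, "loops")
  need_file(cfg$occupancy, "occupancy")
  if (!is.null(cfg$activity)) {
    need_file(cfg$activity$expression, "activity$expression")
    need_file(cfg$activity$signature, "activity$signature")
    if (is.null(cfg$activity$target_gene))
      problems <- c(problems, "activity$target_gene: required")
  }
  if (!is.null(cfg$perturb)) {
    for (k in c("grna_mtx", "expr_mtx", "grna_names", "gene_names",
                "cell_names"))
      need_file(cfg$perturb[[k]], paste0("perturb$", k))
    if (is.null(cfg$perturb$control))
      problems <- c(problems, "perturb$control: required")
  }
  if (length(problems))
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "))
  cfg$thresholds <- th
  cfg$modes <- md
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$outdir <- cfg$outdir %||% "regmap_out"
  structure(cfg, class = "RunConfig")
}

#' Write a config list back to JSON
#' @param config a `RunConfig` (or plain list).
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

round_report <- function(x) {
  if (is.list(x)) return(lapply(x, round_report))
  if (is.numeric(x)) return(signif(x, 10))
  x
}

#' Run the full pipeline from a validated config
#'
#' Stage order: read + canonicalize peak tracks; per-sample putative
#' enhancers and catalog; per-sample super enhancers and their common
#' set; expression binning and window (plus optional loop) association
#' with per-bin fractions for enhancers and super enhancers; optional
#' TF-occupancy colocalization with an enhancer-vs-super-enhancer
#' contrast; optional signature activity + target correlation; optional
#' Perturb-seq activation and differential-expression calls. Writes BED/
#' TSV artifacts plus `report.json` into `config$outdir`; numbers in the
#' report are rounded to 10 significant digits so reruns are
#' byte-identical.
#'
#' @param config a `RunConfig` from [validate_config()], or a path to a
#'   config file.
#' @return the run report, invisibly (a nested list; also serialized to
#'   `outdir/report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "RunConfig"))
  th <- config$thresholds; md <- config$modes
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(...) message(sprintf("[regmap] %s", sprintf(...)))
  # hash a path-normalized copy of the config (basenames only) so the
  # fingerprint is stable across working directories
  strip_paths <- function(x) {
    if (is.list(x)) return(lapply(x, strip_paths))
    if (is.character(x)) return(basename(x))
    x
  }
  report <- list(provenance = list(
    package_version = as.character(utils::packageVersion("regmap")),
    config_hash = content_hash(jsonlite::toJSON(strip_paths(unclass(config)),
                                                auto_unbox = TRUE,
                                                digits = NA)),
    seed = config$seed))

  stage("reading peak tracks for %d samples", length(config$samples))
  ids <- vapply(config$samples, `[[`, character(1), "id")
  k27 <- list(); k4 <- list()
  for (s in config$samples) {
    dialect <- s$dialect %||% "bed3"
    k27[[s$id]] <- canonicalize(read_bed(s$h3k27ac, dialect,
                                         sample_id = s$id,
                                         track_label = "H3K27ac"))
    k4[[s$id]] <- canonicalize(read_bed(s$h3k4me1, dialect,
                                        sample_id = s$id,
                                        track_label = "H3K4me1"))
  }
  report$intervals <- list(per_sample = lapply(ids, function(i)
    list(sample = i, n_h3k27ac = n_intervals(k27[[i]]),
         n_h3k4me1 = n_intervals(k4[[i]]))))

  stage("calling putative enhancers (%s)", md$enhancer_mode)
  enh <- lapply(ids, function(i)
    call_putative_enhancers(k27[[i]], k4[[i]], mode = md$enhancer_mode))
  names(enh) <- ids
  catalog <- build_catalog(enh)
  write_bed(catalog$common, file.path(config$outdir,
                                      "common_enhancers.bed"))
  report$enhancers <- list(mode = md$enhancer_mode,
                           counts = catalog$counts,
                           n_common = catalog$n_common)

  stage("stitching super enhancers (gap %d, size > %d)",
        th$stitch_gap, th$size_threshold)
  ses <- lapply(ids, function(i)
    call_super_enhancers(k27[[i]], th$stitch_gap, th$size_threshold))
  names(ses) <- ids
  common_se <- common_super_enhancers(ses)
  write_bed(common_se, file.path(config$outdir,
                                 "common_super_enhancers.bed"))
  report$super_enhancers <- list(
    per_sample = lapply(ids, function(i)
      list(sample = i, n_super_enhancers = nrow(ses[[i]]))),
    n_common = n_intervals(common_se))

  links_enh <- NULL; bins <- NULL
  if (!is.null(config$genes) && !is.null(config$fpkm)) {
    stage("associating enhancers with genes (window %d, %s anchor)",
          th$window, md$anchor)
    genes <- read_genes(config$genes, format = config$genes_format %||%
                          "tsv")
    fpkm <- read_expression(config$fpkm)
    bins <- bin_expression(fpkm, thresholds = th$fpkm_bins)
    links_enh <- associate_by_window(catalog$common, genes, th$window,
                                     md$anchor)
    links_se <- associate_by_window(common_se, genes, th$window,
                                    md$anchor)
    if (!is.null(config$loops)) {
      loops <- read_loops(config$loops)
      links_enh <- combine_evidence(links_enh,
                                    associate_by_loop(catalog$common,
                                                      genes, loops))
      links_se <- combine_evidence(links_se,
                                   associate_by_loop(common_se, genes,
                                                     loops))
      report$loops <- list(n_loops = nrow(loops))
    }
    write_links(links_enh, file.path(config$outdir, "enhancer_links.tsv"),
                bins)
    write_links(links_se, file.path(config$outdir,
                                    "super_enhancer_links.tsv"), bins)
    report$association <- list(
      bin_counts = as.list(table(bins)),
      enhancer_fractions = association_fractions(links_enh,
                                                 catalog$common, bins),
      super_enhancer_fractions = association_fractions(links_se,
                                                       common_se, bins))
  }

  if (!is.null(config$occupancy)) {
    stage("colocalizing with occupancy cistrome")
    occ <- canonicalize(read_bed(config$occupancy,
                                 config$occupancy_dialect %||% "bed3",
                                 track_label = "occupancy"))
    ce <- colocalize(catalog$common, occ, th$min_overlap, "enhancer")
    cs <- colocalize(common_se, occ, th$min_overlap, "super_enhancer")
    contrast <- colocalization_contrast(cs, ce)
    report$colocalization <- list(
      enhancers = unclass(ce), super_enhancers = unclass(cs),
      contrast = list(percent_difference = contrast$percent_difference,
                      odds_ratio = contrast$odds_ratio,
                      undefined_or = contrast$undefined_or,
                      fisher_p = contrast$fisher_p))
  }

  if (!is.null(config$activity)) {
    stage("computing signature activity scores")
    aexpr <- read_expression(config$activity$expression)
    sig <- read_signature(config$activity$signature)
    scores <- compute_tscores(aexpr, sig)
    tg <- config$activity$target_gene
    if (!(tg %in% rownames(aexpr)))
      stop("activity$target_gene not in expression matrix: ", tg)
    corr <- correlate_activity(scores,
                               stats::setNames(aexpr[tg, ],
                                               colnames(aexpr)))
    utils::write.table(data.frame(sample = scores$sample_id,
                                  t_score = signif(scores$t_score, 10)),
                       file.path(config$outdir, "activity_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$activity <- list(target_gene = tg, r = corr$r, n = corr$n,
                            p_value = corr$p_value,
                            n_up_used = scores$n_up_used,
                            n_down_used = scores$n_down_used)
  }

  if (!is.null(config$perturb)) {
    stage("calling Perturb-seq activation")
    pd <- read_perturb(config$perturb$grna_mtx, config$perturb$expr_mtx,
                       config$perturb$grna_names,
                       config$perturb$gene_names,
                       config$perturb$cell_names,
                       config$perturb$control,
                       grna_targets = read_targets(config$perturb$targets))
    asg <- assign_grnas(pd, min_count = config$perturb$min_count %||% 1)
    sub <- suppressWarnings(filter_singlets(asg, pd))
    calls <- list()
    for (g in setdiff(rownames(pd$grna_counts), pd$control_label)) {
      if (sum(sub$cell_grna == g, na.rm = TRUE) < 3) next
      tg <- pd$grna_targets[[g]]
      ac <- call_activation(sub, g, tg, th$fc_threshold)
      calls[[g]] <- data.frame(grna = g, gene = tg,
                               fold_change = ac$fold_change,
                               activated = ac$activated,
                               n_perturbed = ac$n_perturbed,
                               n_control = ac$n_control,
                               stringsAsFactors = FALSE)
    }
    calls <- do.call(rbind, calls)
    if (!is.null(calls)) {
      rownames(calls) <- NULL
      calls$fold_change <- signif(calls$fold_change, 10)
      utils::write.table(calls,
                         file.path(config$outdir, "perturb_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report$perturb <- list(
      class_fractions = as.list(attr(asg, "class_fractions")),
      n_singlet_cells = sum(asg$multiplicity_class == "singlet"),
      calls = calls)
  }

  report <- round_report(report)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage("report written to %s", file.path(config$outdir, "report.json"))
  invisible(report)
}

read_targets <- function(path) {
  if (is.null(path)) return(NULL)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(df$target, df$grna)
}

#' Write a ready-to-run synthetic fixture (inputs + config)
#'
#' Generates a complete set of pipeline inputs with the synthetic-data
#' module, writes them in the formats the pipeline reads, and returns the
#' path to a validated config. Used by the end-to-end determinism test
#' and the `simulate` CLI subcommand.
#'
#' @param dir output directory.
#' @param seed integer seed driving all generators.
#' @return path to the written config JSON (invisibly, with the
#'   manifests attached as attribute `"manifests"`).
#' @export
write_fixture <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pk <- simulate_peaksets(n_samples = 3, n_shared = 120,
                          n_private_per_sample = 60,
                          jitter_bp = 150, seed = derive_seed(seed, 1))
  samples <- list()
  for (i in seq_along(pk$h3k27ac)) {
    id <- names(pk$h3k27ac)[i]
    p27 <- file.path(dir, sprintf("%s_h3k27ac.bed", id))
    p4 <- file.path(dir, sprintf("%s_h3k4me1.bed", id))
    write_bed(pk$h3k27ac[[id]], p27)
    write_bed(pk$h3k4me1[[id]], p4)
    samples[[i]] <- list(id = id, h3k27ac = p27, h3k4me1 = p4)
  }
  # super-enhancer landscape on its own chromosome, appended to each
  # sample's H3K27ac track: identical clusters in all samples so the
  # common SE set is planted
  se <- simulate_super_enhancer_landscape(k_clusters = 6, chrom = "chrSE",
                                          seed = derive_seed(seed, 2))
  for (i in seq_along(samples)) {
    comb <- canonicalize(interval_set(rbind(
      as.data.frame(pk$h3k27ac[[i]]), as.data.frame(se$peaks))))
    write_bed(comb, samples[[i]]$h3k27ac)
  }
  # genes planted near the shared double-positive loci, bins cycled
  sl <- pk$manifest$shared_loci
  bins_cycle <- rep(c("high", "mid", "low", "inactive"),
                    length.out = nrow(sl))
  bounds <- list(inactive = c(0.05, 0.9), low = c(1.2, 4.5),
                 mid = c(6, 14), high = c(20, 200))
  gdf <- with_seed(derive_seed(seed, 3), data.frame(
    gene_id = sprintf("GENE%03d", seq_len(nrow(sl))),
    chrom = sl$chrom,
    strand = rep(c("+", "-"), length.out = nrow(sl)),
    tss = sl$pos + 30000,
    fpkm = vapply(bins_cycle, function(b)
      round(stats::runif(1, bounds[[b]][1], bounds[[b]][2]), 3),
      numeric(1)),
    stringsAsFactors = FALSE))
  genes_path <- file.path(dir, "genes.tsv")
  utils::write.table(gdf[c("gene_id", "chrom", "strand", "tss")],
                     genes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fpkm_path <- file.path(dir, "fpkm.tsv")
  fpkm_mat <- outer(gdf$fpkm, c(0.95, 1.0, 1.05))
  rownames(fpkm_mat) <- gdf$gene_id
  colnames(fpkm_mat) <- vapply(samples, `[[`, character(1), "id")
  write_expression(fpkm_mat, fpkm_path)
  # a few loops pairing a shared locus with its planted gene's TSS
  nl <- min(5, nrow(sl))
  loops_path <- file.path(dir, "loops.bedpe")
  utils::write.table(data.frame(
    chrom = sl$chrom[seq_len(nl)],
    a_start = sl$pos[seq_len(nl)] - 500,
    a_end = sl$pos[seq_len(nl)] + 2500,
    chrom_b = sl$chrom[seq_len(nl)],
    b_start = gdf$tss[seq_len(nl)] - 1000,
    b_end = gdf$tss[seq_len(nl)] + 1000),
    loops_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  # occupancy: 76% of the planted super enhancers, 20% of the shared
  # double-positive loci (the regular-enhancer consensus)
  occ_se <- simulate_occupancy(super_enhancer_regions(
    call_super_enhancers(se$peaks)), fraction = 0.76,
    seed = derive_seed(seed, 4))
  shared_set <- canonicalize(interval_set(sl$chrom, sl$pos,
                                          sl$pos + sl$width))
  occ_enh <- simulate_occupancy(shared_set, fraction = 0.20, n_extra = 0,
                                seed = derive_seed(seed, 7))
  occ <- canonicalize(interval_set(rbind(
    as.data.frame(occ_se$occupancy), as.data.frame(occ_enh$occupancy))))
  occ_path <- file.path(dir, "occupancy.bed")
  write_bed(occ, occ_path)
  act <- simulate_activity_correlation(seed = derive_seed(seed, 5))
  act_path <- file.path(dir, "activity_fpkm.tsv")
  write_expression(act$fpkm, act_path)
  sig_path <- file.path(dir, "signature.tsv")
  utils::write.table(
    data.frame(gene = c(act$signature$up_genes, act$signature$down_genes),
               dir = c(rep("up", length(act$signature$up_genes)),
                       rep("down", length(act$signature$down_genes)))),
    sig_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  pt <- simulate_perturb(n_cells = 800, n_genes = 60,
                         seed = derive_seed(seed, 6))
  ppaths <- write_perturb(pt$dataset, file.path(dir, "perturb"))
  cfg <- list(
    samples = samples,
    genes = genes_path,
    fpkm = fpkm_path,
    loops = loops_path,
    occupancy = occ_path,
    activity = list(expression = act_path, signature = sig_path,
                    target_gene = act$target_gene),
    perturb = list(grna_mtx = ppaths$grna_mtx,
                   expr_mtx = ppaths$expr_mtx,
                   grna_names = ppaths$grna_names,
                   gene_names = ppaths$gene_names,
                   cell_names = ppaths$cell_names,
                   targets = ppaths$targets,
                   control = pt$dataset$control_label),
    seed = seed,
    outdir = file.path(dir, "out"))
  cfg_path <- file.path(dir, "config.json")
  write_config(cfg, cfg_path)
  out <- cfg_path
  attr(out, "manifests") <- list(peaksets = pk$manifest,
                                 super_enhancers = se$manifest,
                                 occupancy_se = occ_se$manifest,
                                 occupancy_enh = occ_enh$manifest,
                                 activity = act$manifest,
                                 perturb = pt$manifest)
  invisible(out)
}
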