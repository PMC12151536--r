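# CRISPRa Perturb-seq: gRNA-to-cell assignment, multiplicity filtering,
# normalization, target-activation calls, and differential expression
# versus the non-targeting control.

#' Construct a Perturb-seq dataset
#'
#' @param grna_counts integer gRNA x cell matrix (rownames = gRNA ids,
#'   colnames = cell ids).
#' @param expression integer gene x cell matrix sharing the same cell
#'   ids.
#' @param grna_targets named character: gRNA id -> intended target gene
#'   label.
#' @param control_label id of the non-targeting control gRNA (must be a
#'   row of `grna_counts`).
#' @return a list of class `PerturbDataset`.
#' @export
perturb_dataset <- function(grna_counts, expression, grna_targets,
                            control_label) {
  grna_counts <- as.matrix(grna_counts)
  expression <- as.matrix(expression)
  if (is.null(colnames(grna_counts)) || is.null(colnames(expression)))
    stop("both matrices need cell id colnames")
  if (!identical(colnames(grna_counts), colnames(expression)))
    stop("cell ids of gRNA and expression matrices must match")
  if (any(grna_counts < 0) || any(expression < 0))
    stop("counts must be non-negative")
  if (!(control_label %in% rownames(grna_counts)))
    stop("control_label not found among gRNAs")
  missing_t <- setdiff(rownames(grna_counts), names(grna_targets))
  if (length(missing_t))
    stop("gRNAs without a target label: ", paste(missing_t, collapse = ", "))
  structure(list(grna_counts = grna_counts, expression = expression,
                 grna_targets = grna_targets,
                 control_label = control_label,
                 cell_grna = NULL),
            class = "PerturbDataset")
}

#' Assign gRNAs to cells and classify multiplicity
#'
#' A gRNA is detected in a cell when its count is at least `min_count`.
#' Cells are classified `none` (no gRNA), `singlet` (exactly one) or
#' `multiplet` (two or more); the three classes partition the cells.
#'
#' @param grna_counts integer gRNA x cell matrix (or a `PerturbDataset`).
#' @param min_count detection threshold, default 1.
#' @return a data.frame of class `CellAssignments` with columns
#'   `cell_id`, `n_detected`, `multiplicity_class`, `grna` (the single
#'   detected gRNA for singlets, else `NA`); attribute
#'   `"class_fractions"` holds the per-class cell fractions.
#' @export
assign_grnas <- function(grna_counts, min_count = 1) {
  if (inherits(grna_counts, "PerturbDataset"))
    grna_counts <- grna_counts$grna_counts
  grna_counts <- as.matrix(grna_counts)
  if (any(grna_counts < 0)) stop("counts must be non-negative")
  if (length(min_count) != 1 || min_count < 1)
    stop("min_count must be >= 1")
  det <- grna_counts >= min_count
  n_det <- colSums(det)
  cls <- ifelse(n_det == 0, "none", ifelse(n_det == 1, "singlet",
                                           "multiplet"))
  single <- rep(NA_character_, ncol(grna_counts))
  idx <- which(n_det == 1)
  if (length(idx))
    single[idx] <- rownames(grna_counts)[apply(det[, idx, drop = FALSE], 2,
                                               which)]
  out <- data.frame(cell_id = colnames(grna_counts),
                    n_detected = as.integer(n_det),
                    multiplicity_class = cls, grna = single,
                    stringsAsFactors = FALSE)
  fr <- c(none = mean(cls == "none"), singlet = mean(cls == "singlet"),
          multiplet = mean(cls == "multiplet"))
  structure(out, class = c("CellAssignments", "data.frame"),
            class_fractions = fr, min_count = min_count)
}

#' Keep only singlet cells
#'
#' Cells carrying zero or more than one detected gRNA are excluded; the
#' returned dataset carries a per-cell `cell_grna` label. gRNAs left with
#' no singlet cells trigger a warning (they cannot be tested downstream).
#'
#' @param assignments a `CellAssignments` data.frame computed on
#'   `dataset`.
#' @param dataset a `PerturbDataset`.
#' @return the singlet-only `PerturbDataset`.
#' @export
filter_singlets <- function(assignments, dataset) {
  stopifnot(inherits(assignments, "CellAssignments"),
            inherits(dataset, "PerturbDataset"))
  if (!identical(assignments$cell_id, colnames(dataset$grna_counts)))
    stop("assignments were not computed on this dataset")
  keep <- assignments$multiplicity_class == "singlet"
  cells <- assignments$cell_id[keep]
  out <- dataset
  out$grna_counts <- dataset$grna_counts[, cells, drop = FALSE]
  out$expression <- dataset$expression[, cells, drop = FALSE]
  out$cell_grna <- stats::setNames(assignments$grna[keep], cells)
  tab <- table(factor(out$cell_grna, levels = rownames(dataset$grna_counts)))
  zero <- names(tab)[tab == 0]
  if (length(zero))
    warning("gRNA(s) with zero singlet cells excluded from downstream calls: ",
            paste(zero, collapse = ", "))
  out$singlet_counts <- as.integer(tab)
  names(out$singlet_counts) <- names(tab)
  out
}

#' Depth-normalize single-cell expression counts
#'
#' Scales each cell to the median library size, then applies `log1p`.
#' Zero-depth cells are dropped with a warning. A deterministic stand-in
#' for variance-stabilizing normalizations.
#'
#' @param expression integer gene x cell matrix.
#' @return the normalized numeric matrix.
#' @export
normalize_cells <- function(expression) {
  expression <- as.matrix(expression)
  depths <- colSums(expression)
  if (any(depths == 0)) {
    warning(sum(depths == 0), " zero-depth cell(s) dropped")
    expression <- expression[, depths > 0, drop = FALSE]
    depths <- depths[depths > 0]
  }
  if (length(depths) == 0) return(expression)
  med <- stats::median(depths)
  log1p(sweep(expression, 2, med / depths, `*`))
}

arm_cells <- function(dataset, grna_id) {
  if (is.null(dataset$cell_grna))
    stop("dataset is not singlet-filtered; run filter_singlets() first")
  if (!(grna_id %in% rownames(dataset$grna_counts)))
    stop("unknown gRNA: ", grna_id)
  pert <- names(dataset$cell_grna)[dataset$cell_grna == grna_id]
  ctrl <- names(dataset$cell_grna)[dataset$cell_grna ==
                                     dataset$control_label]
  if (length(pert) < 3 || length(ctrl) < 3)
    stop(sprintf("need >= 3 cells per arm (perturbed: %d, control: %d)",
                 length(pert), length(ctrl)))
  list(pert = pert, ctrl = ctrl)
}

#' Call activation of a known target gene by a gRNA
#'
#' Fold change = (mean normalized target expression in the gRNA's singlet
#' cells + eps) / (mean in non-targeting control cells + eps); the gRNA
#' is called activating when the fold change strictly exceeds
#' `fc_threshold`.
#'
#' @param dataset a singlet-filtered `PerturbDataset`.
#' @param grna_id gRNA to test.
#' @param known_target gene id of the intended target.
#' @param fc_threshold strict fold-change threshold (default 1.5).
#' @param eps pseudocount on normalized means (default 1e-9).
#' @return a list of class `ActivationCall` with `grna_id`, `gene_id`,
#'   `fold_change`, `activated`, and per-arm cell counts.
#' @export
call_activation <- function(dataset, grna_id, known_target,
                            fc_threshold = 1.5, eps = 1e-9) {
  stopifnot(inherits(dataset, "PerturbDataset"))
  arms <- arm_cells(dataset, grna_id)
  if (!(known_target %in% rownames(dataset$expression)))
    stop("target gene not in expression matrix: ", known_target)
  norm <- normalize_cells(dataset$expression[, c(arms$pert, arms$ctrl),
                                             drop = FALSE])
  # fold change on the linear depth-normalized scale (expm1 of the
  # log-normalized values), the single-cell marker-finder convention;
  # the log1p scale would attenuate mean ratios
  x <- expm1(norm[known_target, intersect(arms$pert, colnames(norm))])
  y <- expm1(norm[known_target, intersect(arms$ctrl, colnames(norm))])
  fc <- (mean(x) + eps) / (mean(y) + eps)
  structure(list(grna_id = grna_id, gene_id = known_target,
                 fold_change = fc, adjusted_p = NA_real_,
                 activated = fc > fc_threshold,
                 n_perturbed = length(x), n_control = length(y)),
            class = "ActivationCall")
}

#' @export
print.ActivationCall <- function(x, ...) {
  cat(sprintf("%s -> %s: FC = %.3f (%s; %d vs %d cells)\n", x$grna_id,
              x$gene_id, x$fold_change,
              if (x$activated) "activated" else "not activated",
              x$n_perturbed, x$n_control))
  invisible(x)
}

# Vectorized two-sided Wilcoxon rank-sum test with tie correction and
# continuity correction, matching wilcox.test(exact = FALSE,
# correct = TRUE). Rows of `a` and `b` are genes; columns are cells.
rank_sum_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b); N <- n1 + n2
  m <- cbind(a, b)
  p <- numeric(nrow(m)); tied <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    r <- rank(m[i, ])
    W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    nt <- table(r)
    tiecor <- sum(nt^3 - nt)
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - tiecor / (N * (N - 1)))
    if (sigma2 <= 0) { p[i] <- 1; tied[i] <- TRUE; next }
    z <- W - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p[i] <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(p = p, tied = tied)
}

#' Differential expression of a gRNA arm versus control
#'
#' Per gene, a two-sided Wilcoxon rank-sum test of the gRNA's singlet
#' cells versus the non-targeting control cells on depth-normalized
#' expression, with Benjamini-Hochberg adjustment across genes. Hits
#' ("target genes") require fold change > `fc_threshold` AND adjusted
#' p < `alpha`. Genes with all-tied values get p = 1 and a `tied` flag.
#'
#' @param dataset a singlet-filtered `PerturbDataset` with >= 2 genes.
#' @param grna_id gRNA to test (>= 3 cells per arm).
#' @param fc_threshold strict fold-change threshold (default 1.5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param eps pseudocount for fold changes (default 1e-9).
#' @return a data.frame of class `ActivationCalls` ranked by adjusted p
#'   then decreasing |log2 FC|, with columns `gene_id`, `fold_change`,
#'   `log2_fc`, `p_value`, `adjusted_p`, `activated`, `tied`.
#' @export
differential_expression <- function(dataset, grna_id, fc_threshold = 1.5,
                                    alpha = 0.05, eps = 1e-9) {
  stopifnot(inherits(dataset, "PerturbDataset"))
  if (nrow(dataset$expression) < 2) stop("need >= 2 genes")
  arms <- arm_cells(dataset, grna_id)
  norm <- normalize_cells(dataset$expression[, c(arms$pert, arms$ctrl),
                                             drop = FALSE])
  pert <- intersect(arms$pert, colnames(norm))
  ctrl <- intersect(arms$ctrl, colnames(norm))
  if (length(pert) < 3 || length(ctrl) < 3)
    stop("fewer than 3 usable cells per arm after normalization")
  a <- norm[, pert, drop = FALSE]
  b <- norm[, ctrl, drop = FALSE]
  ts <- rank_sum_rows(a, b)
  # test on the log scale, fold change on the linear scale (see
  # call_activation)
  fc <- (rowMeans(expm1(a)) + eps) / (rowMeans(expm1(b)) + eps)
  padj <- stats::p.adjust(ts$p, method = "BH")
  out <- data.frame(gene_id = rownames(norm), fold_change = fc,
                    log2_fc = log2(fc), p_value = ts$p,
                    adjusted_p = padj,
                    activated = fc > fc_threshold & padj < alpha,
                    tied = ts$tied, stringsAsFactors = FALSE)
  out <- out[order(out$adjusted_p, -abs(out$log2_fc)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ActivationCalls", "data.frame"),
            grna_id = grna_id, fc_threshold = fc_threshold, alpha = alpha)
}

#' Read a Perturb-seq dataset from MatrixMarket files with name sidecars
#'
#' @param grna_mtx,expr_mtx MatrixMarket (.mtx) paths for the gRNA x cell
#'   and gene x cell matrices.
#' @param grna_names,gene_names,cell_names plain-text files, one id per
#'   line (cells shared by both matrices).
#' @param grna_targets named character gRNA -> target, or `NULL` to map
#'   each gRNA to itself.
#' @param control_label non-targeting gRNA id.
#' @return a `PerturbDataset`.
#' @export
read_perturb <- function(grna_mtx, expr_mtx, grna_names, gene_names,
                         cell_names, control_label,
                         grna_targets = NULL) {
  g <- as.matrix(Matrix::readMM(grna_mtx))
  e <- as.matrix(Matrix::readMM(expr_mtx))
  rn_g <- readLines(grna_names); rn_e <- readLines(gene_names)
  cells <- readLines(cell_names)
  rownames(g) <- rn_g; colnames(g) <- cells
  rownames(e) <- rn_e; colnames(e) <- cells
  if (is.null(grna_targets))
    grna_targets <- stats::setNames(rn_g, rn_g)
  perturb_dataset(g, e, grna_targets, control_label)
}

#' Write a Perturb-seq dataset as MatrixMarket + sidecars
#' @param dataset a `PerturbDataset`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named list of file paths written.
#' @export
write_perturb <- function(dataset, dir) {
  stopifnot(inherits(dataset, "PerturbDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    grna_mtx = file.path(dir, "grna_counts.mtx"),
    expr_mtx = file.path(dir, "expression.mtx"),
    grna_names = file.path(dir, "grna_names.txt"),
    gene_names = file.path(dir, "gene_names.txt"),
    cell_names = file.path(dir, "cell_names.txt"),
    targets = file.path(dir, "grna_targets.tsv")
  )
  Matrix::writeMM(Matrix::Matrix(dataset$grna_counts, sparse = TRUE),
                  paths$grna_mtx)
  Matrix::writeMM(Matrix::Matrix(dataset$expression, sparse = TRUE),
                  paths$expr_mtx)
  writeLines(rownames(dataset$grna_counts), paths$grna_names)
  writeLines(rownames(dataset$expression), paths$gene_names)
  writeLines(colnames(dataset$expression), paths$cell_names)
  utils::write.table(
    data.frame(grna = names(dataset$grna_targets),
               target = unname(dataset$grna_targets)),
    paths$targets, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
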