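# Perturb-seq: assignment, singlet filtering, normalization,
# activation calls, differential expression.

tiny_dataset <- function() {
  g <- matrix(c(5, 0,   3, 2,  0, 0,  1, 0,  0, 4), nrow = 2,
              dimnames = list(c("gA", "NT"),
                              sprintf("c%d", 1:5)))
  e <- matrix(rpois(50, 5), nrow = 10,
              dimnames = list(sprintf("gene%d", 1:10),
                              sprintf("c%d", 1:5)))
  perturb_dataset(g, e, c(gA = "gene1", NT = "NT"), "NT")
}

test_that("assignment classifies multiplicity and partitions cells", {
  set.seed(1)
  d <- tiny_dataset()
  asg <- assign_grnas(d)
  expect_equal(asg$multiplicity_class,
               c("singlet", "multiplet", "none", "singlet", "singlet"))
  expect_equal(asg$grna, c("gA", NA, NA, "gA", "NT"))
  fr <- attr(asg, "class_fractions")
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["singlet"]), 3 / 5)
  # min_count raises the detection bar
  asg2 <- assign_grnas(d, min_count = 3)
  expect_equal(asg2$multiplicity_class[2], "singlet")
  expect_error(assign_grnas(matrix(-1), min_count = 1), "non-negative")
  expect_error(assign_grnas(d, min_count = 0), "min_count")
})

test_that("filter_singlets keeps singlet cells and warns on empty gRNAs", {
  set.seed(2)
  d <- tiny_dataset()
  asg <- assign_grnas(d)
  sub <- filter_singlets(asg, d)
  expect_equal(ncol(sub$expression), 3)
  expect_equal(unname(sub$cell_grna), c("gA", "gA", "NT"))
  # all-multiplet input -> empty subset with warning about empty gRNAs
  g <- matrix(c(2, 2, 3, 1), nrow = 2,
              dimnames = list(c("gA", "NT"), c("c1", "c2")))
  e <- matrix(rpois(8, 5), nrow = 4,
              dimnames = list(sprintf("gene%d", 1:4), c("c1", "c2")))
  d2 <- perturb_dataset(g, e, c(gA = "gene1", NT = "NT"), "NT")
  expect_warning(sub2 <- filter_singlets(assign_grnas(d2), d2),
                 "zero singlet")
  expect_equal(ncol(sub2$expression), 0)
})

test_that("normalization equalizes library sizes and drops empty cells", {
  m <- matrix(c(1, 2, 3,   2, 4, 6,  0, 0, 0), nrow = 3,
              dimnames = list(sprintf("g%d", 1:3), c("a", "b", "empty")))
  expect_warning(norm <- normalize_cells(m), "zero-depth")
  # proportional cells become identical profiles
  expect_equal(norm[, "a"], norm[, "b"])
  set.seed(4)
  r <- matrix(rpois(500, 8) + 1, nrow = 20,
              dimnames = list(sprintf("g%d", 1:20),
                              sprintf("c%d", 1:25)))
  norm <- normalize_cells(r)
  libs <- colSums(expm1(norm))
  expect_lt(max(libs) - min(libs), 1e-9)
})

test_that("call_activation uses a strict fold-change threshold", {
  set.seed(5)
  ncell <- 40
  g <- rbind(gA = c(rep(2, 20), rep(0, 20)),
             NT = c(rep(0, 20), rep(2, 20)))
  colnames(g) <- sprintf("c%d", 1:ncell)
  e <- matrix(rpois(ncell * 3, 30), nrow = 3,
              dimnames = list(c("tgt", "x", "y"), colnames(g)))
  d <- perturb_dataset(g, e, c(gA = "tgt", NT = "NT"), "NT")
  sub <- filter_singlets(assign_grnas(d), d)
  # keep per-cell depth constant so normalization is a no-op, then
  # plant exact means (the x row compensates the tgt shift)
  e2 <- e; e2[] <- 10
  e2["tgt", 1:20] <- 16; e2["x", 1:20] <- 4
  d2 <- perturb_dataset(g, e2, c(gA = "tgt", NT = "NT"), "NT")
  sub2 <- filter_singlets(assign_grnas(d2), d2)
  ac <- call_activation(sub2, "gA", "tgt")
  expect_equal(ac$fold_change, 16 / 10, tolerance = 1e-9)
  expect_true(ac$activated)
  # FC exactly 1.5 is NOT activation
  e3 <- e2; e3["tgt", 1:20] <- 15; e3["x", 1:20] <- 5
  d3 <- perturb_dataset(g, e3, c(gA = "tgt", NT = "NT"), "NT")
  sub3 <- filter_singlets(assign_grnas(d3), d3)
  ac3 <- call_activation(sub3, "gA", "tgt")
  expect_equal(ac3$fold_change, 1.5, tolerance = 1e-9)
  expect_false(ac3$activated)
  expect_error(call_activation(sub2, "gA", "nope"), "not in expression")
  expect_error(call_activation(d2, "gA", "tgt"), "singlet-filtered")
})

test_that("fold change is invariant to uniform depth rescaling", {
  sim <- simulate_perturb(n_cells = 600, n_genes = 40, seed = 9)
  sub <- suppressWarnings(
    filter_singlets(assign_grnas(sim$dataset), sim$dataset))
  fc1 <- call_activation(sub, "PLCL2-5", "PLCL2")$fold_change
  scaled <- sub
  scaled$expression <- sub$expression * 3
  fc2 <- call_activation(scaled, "PLCL2-5", "PLCL2")$fold_change
  expect_equal(fc1, fc2, tolerance = 1e-9)
})

test_that("rank-sum p-values match wilcox.test and BH matches the
           step-up oracle", {
  set.seed(6)
  a <- matrix(rpois(15 * 8, 4), nrow = 15)
  b <- matrix(rpois(15 * 11, 5), nrow = 15)
  got <- regmap:::rank_sum_rows(a, b)
  ref <- vapply(1:15, function(i)
    stats::wilcox.test(a[i, ], b[i, ], exact = FALSE,
                       correct = TRUE)$p.value, numeric(1))
  expect_equal(got$p, ref, tolerance = 1e-12)
  # all-tied rows get p = 1 and the tied flag
  a2 <- matrix(3, 1, 8); b2 <- matrix(3, 1, 11)
  tied <- regmap:::rank_sum_rows(a2, b2)
  expect_equal(tied$p, 1)
  expect_true(tied$tied)
  for (rep in 1:10) {
    p <- runif(sample(5:50, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p),
                 tolerance = 1e-12)
  }
})

test_that("differential_expression ranks a strong planted target first", {
  sim <- simulate_perturb(n_cells = 1200, n_genes = 120, seed = 12)
  sub <- suppressWarnings(
    filter_singlets(assign_grnas(sim$dataset), sim$dataset))
  de <- differential_expression(sub, "PLCL2-5")   # planted FC 3.0
  expect_equal(de$gene_id[1], "PLCL2")
  expect_true(de$activated[1])
  expect_equal(order(de$adjusted_p), seq_len(nrow(de)))
  # gRNA with planted FC 1.0 should not call its target
  de_null <- differential_expression(sub, "PLCL2-2")
  expect_false(de_null$activated[de_null$gene_id == "PLCL2"])
})

test_that("too few cells per arm is a validation error", {
  g <- rbind(gA = c(2, 2, 0, 0, 0), NT = c(0, 0, 2, 2, 2))
  colnames(g) <- sprintf("c%d", 1:5)
  e <- matrix(rpois(25, 5), nrow = 5,
              dimnames = list(sprintf("gene%d", 1:5), colnames(g)))
  d <- perturb_dataset(g, e, c(gA = "gene1", NT = "NT"), "NT")
  sub <- filter_singlets(assign_grnas(d), d)
  expect_error(differential_expression(sub, "gA"), ">= 3 cells")
  expect_error(call_activation(sub, "gA", "gene1"), ">= 3 cells")
})

test_that("MTX round trip preserves the dataset", {
  sim <- simulate_perturb(n_cells = 80, n_genes = 15, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_perturb(sim$dataset, dir)
  back <- read_perturb(paths$grna_mtx, paths$expr_mtx, paths$grna_names,
                       paths$gene_names, paths$cell_names,
                       "NonTargeting",
                       grna_targets = sim$dataset$grna_targets)
  expect_equal(back$grna_counts, sim$dataset$grna_counts)
  expect_equal(back$expression, sim$dataset$expression)
})
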