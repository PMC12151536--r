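# Colocalization of region catalogs with a TF occupancy cistrome,
# e.g. enhancers / super enhancers vs PGR-occupied regions.

#' Colocalize a region catalog with a TF occupancy set
#'
#' A region is colocalized when it shares at least `min_overlap_bp` bases
#' with any occupancy interval.
#'
#' @param regions canonical, non-empty `IntervalSet` (the catalog).
#' @param occupancy canonical `IntervalSet` (the cistrome).
#' @param min_overlap_bp minimum shared bases (default 1).
#' @param category label for reporting: `"enhancer"`, `"super_enhancer"`
#'   or `"custom"`.
#' @return a list of class `ColocalizationResult` with `category`,
#'   `n_regions`, `n_colocalized`, `percent` (one decimal).
#' @export
colocalize <- function(regions, occupancy, min_overlap_bp = 1,
                       category = c("custom", "enhancer", "super_enhancer")) {
  category <- match.arg(category)
  check_canonical(regions); check_canonical(occupancy)
  if (n_intervals(regions) == 0) stop("regions set is empty")
  rep <- overlap_report(regions, occupancy, min_overlap_bp)
  structure(list(category = category,
                 n_regions = rep$n_query,
                 n_colocalized = rep$n_overlapping,
                 percent = round(100 * rep$fraction, 1)),
            class = "ColocalizationResult")
}

#' @export
print.ColocalizationResult <- function(x, ...) {
  cat(sprintf("Colocalization [%s]: %d / %d regions (%.1f%%)\n",
              x$category, x$n_colocalized, x$n_regions, x$percent))
  invisible(x)
}

#' Contrast two colocalization results
#'
#' Formalizes a percent-vs-percent comparison (e.g. super enhancers vs
#' regular enhancers against the same occupancy set) as a 2x2 table with
#' the sample odds ratio and a Fisher exact p-value. The statistical
#' contrast is an artifact addition on top of the raw percentages.
#'
#' @param a,b `ColocalizationResult`s computed against the same occupancy
#'   set.
#' @return a list of class `ColocalizationContrast` with
#'   `percent_difference` (a - b), `odds_ratio` (sample OR; `NA` with
#'   `undefined_or = TRUE` when a marginal is zero), and
#'   `fisher_p` (two-sided).
#' @export
colocalization_contrast <- function(a, b) {
  stopifnot(inherits(a, "ColocalizationResult"),
            inherits(b, "ColocalizationResult"))
  tab <- matrix(c(a$n_colocalized, a$n_regions - a$n_colocalized,
                  b$n_colocalized, b$n_regions - b$n_colocalized),
                nrow = 2,
                dimnames = list(c("colocalized", "not"),
                                c(a$category, b$category)))
  undefined <- any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
    tab[2, 1] == 0 || tab[1, 2] == 0
  or <- if (tab[2, 1] > 0 && tab[1, 2] > 0)
    (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2]) else NA_real_
  p <- stats::fisher.test(tab)$p.value
  structure(list(table = tab,
                 percent_difference = a$percent - b$percent,
                 odds_ratio = or,
                 undefined_or = undefined || is.na(or),
                 fisher_p = p),
            class = "ColocalizationContrast")
}

#' @export
print.ColocalizationContrast <- function(x, ...) {
  cat(sprintf("Colocalization contrast: delta = %.1f%%, OR = %s, Fisher p = %.3g\n",
              x$percent_difference,
              if (x$undefined_or) "undefined" else sprintf("%.3g", x$odds_ratio),
              x$fisher_p))
  invisible(x)
}
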