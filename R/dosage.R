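#' X-to-autosome fold change of normalized signal
#'
#' The core dosage statistic: the median normalized signal of X-linked
#' features divided by the median of autosomal features on the same
#' allele, within one sample group. By default autosomal features are
#' pooled into a single distribution ("median of all the autosomes"); set
#' `per_chromosome_median = TRUE` to instead take the median of the 19
#' autosomal per-chromosome medians. A two-sided Wilcoxon rank-sum test
#' compares the two feature-level distributions.
#'
#' @param m A normalized `AllelicCountMatrix` (run [normalize_library()]
#'   first and any filters, e.g. [filter_min_allelic_total()]).
#' @param allele One of "mus", "cast", "total".
#' @param group Group label to evaluate; samples in the group are
#'   averaged per feature before taking medians.
#' @param include_escapees Include escapee features on the X side
#'   (default TRUE; they are X-linked genes).
#' @param per_chromosome_median Autosome pooling variant (see above).
#' @return A one-row `data.frame` (a `DosageSummary`): allele, group,
#'   x_median, autosome_median, fold_change, p_value, n_x, n_autosomal.
#' @export
x_autosome_fold <- function(m, allele = c("cast", "mus", "total"), group,
                            include_escapees = TRUE,
                            per_chromosome_median = FALSE) {
  allele <- match.arg(allele)
  layer <- m[[paste0("norm_", allele)]]
  if (is.null(layer)) stop("normalized layer missing: run normalize_library()")
  grp <- resolve_groups(m)
  if (!group %in% grp) stop("unknown group '", group, "'")
  vals <- rowMeans(layer[, grp == group, drop = FALSE], na.rm = TRUE)
  if (!is.null(m$retained) && group %in% colnames(m$retained))
    vals[!m$retained[, group]] <- NA_real_
  ann <- m$annotation
  xf <- intersect(x_features(ann, include_escapees), m$features)
  af <- intersect(autosomal_features(ann), m$features)
  xv <- vals[xf][!is.na(vals[xf])]
  av <- vals[af][!is.na(vals[af])]
  if (length(xv) == 0 || length(av) == 0)
    stop("no X-linked or no autosomal features left after filtering in group '",
         group, "'")
  auto_med <- if (per_chromosome_median) {
    chrom <- ann$chrom[match(names(av), ann$feature_id)]
    stats::median(tapply(av, chrom, stats::median))
  } else {
    stats::median(av)
  }
  x_med <- stats::median(xv)
  rs <- rank_sum_test(xv, av)
  data.frame(allele = allele, group = group,
             x_median = x_med, autosome_median = auto_med,
             fold_change = x_med / auto_med,
             p_value = rs$p_value,
             n_x = length(xv), n_autosomal = length(av),
             stringsAsFactors = FALSE)
}

#' Per-cell X-to-autosome expression ratio
#'
#' For each cell, the median (default; `use_mean = TRUE` for the mean)
#' normalized expression of the chosen X allele over expressed genes is
#' divided by that of autosomal genes. A gene counts as expressed in a
#' cell when its summed allelic reads (Mus + Cast) are > 0 there; the
#' allele-specific value of an expressed gene may still be zero, so a
#' fully silenced X allele yields a ratio of ~0.
#'
#' @param m A normalized `AllelicCountMatrix`.
#' @param allele "mus" or "cast".
#' @param include_escapees Include escapees on the X side.
#' @param use_mean Use the mean instead of the median across genes.
#' @return Named numeric vector of per-cell ratios (`NA`, with a warning,
#'   for cells with no expressed autosomal genes).
#' @export
x_autosome_ratio_per_cell <- function(m, allele = c("mus", "cast"),
                                      include_escapees = TRUE,
                                      use_mean = FALSE) {
  allele <- match.arg(allele)
  layer <- m[[paste0("norm_", allele)]]
  if (is.null(layer)) stop("normalized layer missing: run normalize_library()")
  expressed <- (m$counts_mus + m$counts_cast) > 0
  ann <- m$annotation
  xf <- intersect(x_features(ann, include_escapees), m$features)
  af <- intersect(autosomal_features(ann), m$features)
  center <- if (use_mean) mean else stats::median
  ratios <- vapply(seq_along(m$samples), function(j) {
    ex <- expressed[, j]
    xv <- layer[xf, j][ex[xf]]
    av <- layer[af, j][ex[af]]
    xv <- xv[!is.na(xv)]; av <- av[!is.na(av)]
    if (length(av) == 0) return(NA_real_)
    x_c <- if (length(xv) == 0) 0 else center(xv)
    x_c / center(av)
  }, numeric(1))
  names(ratios) <- m$samples
  if (anyNA(ratios))
    warning(sum(is.na(ratios)), " cell(s) had no expressed autosomal genes")
  ratios
}

#' Chromosome-to-autosome signal ratio along groups
#'
#' For each sample group (in the order given by `group_order`, or order
#' of appearance), the median normalized signal of the chosen
#' chromosome's features divided by the median over all *other*
#' autosomes. When `chrom` is itself an autosome it is excluded from its
#' own denominator, giving the control series expected to sit at ~1.
#'
#' @param m A normalized `AllelicCountMatrix`.
#' @param chrom Chromosome name (e.g. "chrX", "chr7").
#' @param allele "mus", "cast" or "total".
#' @param group_order Optional character vector fixing the group order.
#' @return A `data.frame` with columns group, ratio, n_chrom, n_autosomal.
#' @export
chromosome_autosome_trajectory <- function(m, chrom,
                                           allele = c("cast", "mus", "total"),
                                           group_order = NULL) {
  allele <- match.arg(allele)
  layer <- m[[paste0("norm_", allele)]]
  if (is.null(layer)) stop("normalized layer missing: run normalize_library()")
  if (!chrom %in% m$annotation$chrom)
    stop("unknown chromosome '", chrom, "'")
  grp <- resolve_groups(m)
  glev <- if (is.null(group_order)) unique(grp) else group_order
  if (length(glev) < 2) stop("need >= 2 groups for a trajectory")
  ann <- m$annotation
  cf <- ann$feature_id[ann$chrom == chrom]
  af <- setdiff(autosomal_features(ann), cf)
  cf <- intersect(cf, m$features); af <- intersect(af, m$features)
  out <- lapply(glev, function(g) {
    vals <- rowMeans(layer[, grp == g, drop = FALSE], na.rm = TRUE)
    if (!is.null(m$retained) && g %in% colnames(m$retained))
      vals[!m$retained[, g]] <- NA_real_
    cv <- vals[cf][!is.na(vals[cf])]
    av <- vals[af][!is.na(vals[af])]
    data.frame(group = g,
               ratio = stats::median(cv) / stats::median(av),
               n_chrom = length(cv), n_autosomal = length(av),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify an expression change between two states
#'
#' A gene counts as up- or downregulated when its expression increases or
#' decreases by at least 25% (default), boundary inclusive; otherwise it
#' is stable.
#'
#' @param expr_start,expr_end Expression values (start must be > 0).
#' @param threshold Relative-change threshold (default 0.25).
#' @return "up", "down" or "stable" (vectorized).
#' @export
classify_expression_change <- function(expr_start, expr_end,
                                       threshold = 0.25) {
  if (any(expr_start <= 0)) stop("expr_start must be > 0")
  rel <- expr_end / expr_start
  ifelse(rel >= 1 + threshold, "up",
         ifelse(rel <= 1 - threshold, "down", "stable"))
}

#' Classify allelic expression bias
#'
#' A gene is biasedly expressed towards one allele when the two allelic
#' values differ by at least 25% (default) of the larger one, boundary
#' inclusive; otherwise it is balanced.
#'
#' @param mus_expr,cast_expr Non-negative allelic expression values
#'   (not both zero).
#' @param threshold Relative-difference threshold (default 0.25).
#' @return "mus_biased", "cast_biased" or "balanced" (vectorized).
#' @export
classify_allelic_bias <- function(mus_expr, cast_expr, threshold = 0.25) {
  if (any(mus_expr < 0) || any(cast_expr < 0))
    stop("allelic expression values must be >= 0")
  if (any(mus_expr == 0 & cast_expr == 0))
    stop("both alleles zero: bias undefined")
  diff_rel <- abs(mus_expr - cast_expr) / pmax(mus_expr, cast_expr)
  ifelse(diff_rel >= threshold,
         ifelse(mus_expr > cast_expr, "mus_biased", "cast_biased"),
         "balanced")
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' @param a,b Numeric vectors, each with >= 2 values.
#' @return A list with `statistic` (the Mann-Whitney U for `a`) and
#'   `p_value`.
#' @export
rank_sum_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs >= 2 non-missing values")
  wt <- stats::wilcox.test(a, b, alternative = "two.sided")
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
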