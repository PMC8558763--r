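#' Smooth per-cell values along pseudotime
#'
#' Locally weighted regression (loess) of a per-cell quantity (allelic
#' ratio or normalized expression) on pseudotime, evaluated at `n_grid`
#' equally spaced points spanning the observed pseudotime range. Cells
#' with missing values are dropped before fitting; genes with fewer than
#' `min_cells` informative cells are skipped (return `NULL`, with a
#' message).
#'
#' @param values Per-cell values (may contain `NA`).
#' @param pseudotime Per-cell pseudotime, same length.
#' @param span loess span (default 0.75).
#' @param degree loess polynomial degree (default 2).
#' @param n_grid Number of grid points (default 100).
#' @param min_cells Minimum informative cells (default 20).
#' @param clip01 Clip fitted values into [0, 1] (for allelic-ratio mode).
#' @return A list with `grid` and `fitted` (length `n_grid` each), or
#'   `NULL` if too few cells.
#' @export
fit_pseudotime_curve <- function(values, pseudotime, span = 0.75,
                                 degree = 2, n_grid = 100,
                                 min_cells = 20, clip01 = FALSE) {
  stopifnot(length(values) == length(pseudotime))
  keep <- !is.na(values) & is.finite(pseudotime)
  v <- values[keep]; t <- pseudotime[keep]
  if (length(v) < min_cells || length(unique(t)) < 2) {
    message("skipping curve fit: only ", length(v), " informative cells")
    return(NULL)
  }
  grid <- seq(min(t), max(t), length.out = n_grid)
  fit <- suppressWarnings(
    stats::loess(v ~ t, span = span, degree = degree,
                 family = "gaussian",
                 control = stats::loess.control(surface = "direct")))
  fitted <- as.numeric(stats::predict(fit, newdata = data.frame(t = grid)))
  if (clip01) fitted <- pmin(pmax(fitted, 0), 1)
  list(grid = grid, fitted = fitted)
}

#' Per-gene Xi/Xa allelic-ratio profiles along pseudotime (XCR mode)
#'
#' For every X-linked gene, the per-cell allelic ratio of normalized
#' expression, Mus / (Mus + Cast), is smoothed along pseudotime. Cells
#' where a gene has zero total allelic signal (or is masked missing) are
#' excluded from that gene's fit.
#'
#' @param m A normalized `AllelicCountMatrix` of single cells.
#' @param pseudotime Pseudotime table ([read_pseudotime()] format) or a
#'   named numeric vector over `m$samples`.
#' @param features Genes to profile (default: all chrX features).
#' @inheritParams fit_pseudotime_curve
#' @return A genes x grid matrix of fitted ratios (genes with too few
#'   cells are dropped); the grid is attached as `attr(, "grid")`.
#' @export
xcr_profiles <- function(m, pseudotime, features = NULL, span = 0.75,
                         n_grid = 100, min_cells = 20) {
  pt <- as_pseudotime_vector(pseudotime, m$samples)
  if (is.null(m$norm_mus)) stop("run normalize_library() first")
  if (is.null(features))
    features <- intersect(x_features(m$annotation), m$features)
  profile_matrix(m, features, pt, span, n_grid, min_cells,
                 value_fun = function(i) {
                   nm <- m$norm_mus[i, ]; nc <- m$norm_cast[i, ]
                   tot <- nm + nc
                   ifelse(is.na(tot) | tot == 0, NA_real_, nm / tot)
                 }, clip01 = TRUE)
}

#' Per-gene Xa normalized-expression profiles along pseudotime (XCD mode)
#'
#' Smooths the normalized expression of one allele (default Cast, the Xa
#' in the reprogramming system) along pseudotime per gene, for studying
#' erasure of X upregulation.
#'
#' @inheritParams xcr_profiles
#' @param allele Which allele's normalized expression to profile.
#' @return A genes x grid matrix of fitted normalized expression.
#' @export
xcd_profiles <- function(m, pseudotime, features = NULL,
                         allele = c("cast", "mus"), span = 0.75,
                         n_grid = 100, min_cells = 20) {
  allele <- match.arg(allele)
  pt <- as_pseudotime_vector(pseudotime, m$samples)
  layer <- m[[paste0("norm_", allele)]]
  if (is.null(layer)) stop("run normalize_library() first")
  if (is.null(features))
    features <- intersect(x_features(m$annotation), m$features)
  profile_matrix(m, features, pt, span, n_grid, min_cells,
                 value_fun = function(i) layer[i, ], clip01 = FALSE)
}

as_pseudotime_vector <- function(pseudotime, samples) {
  if (is.data.frame(pseudotime)) {
    pt <- stats::setNames(pseudotime$pseudotime, pseudotime$sample_id)
  } else pt <- pseudotime
  if (!all(samples %in% names(pt)))
    stop("pseudotime missing for samples: ",
         paste(utils::head(setdiff(samples, names(pt)), 5), collapse = ", "))
  pt[samples]
}

profile_matrix <- function(m, features, pt, span, n_grid, min_cells,
                           value_fun, clip01) {
  fits <- lapply(features, function(f) {
    fit_pseudotime_curve(value_fun(f), pt, span = span, n_grid = n_grid,
                         min_cells = min_cells, clip01 = clip01)
  })
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep)) stop("no gene had enough informative cells to profile")
  prof <- do.call(rbind, lapply(fits[keep], `[[`, "fitted"))
  rownames(prof) <- features[keep]
  attr(prof, "grid") <- fits[keep][[1]]$grid
  prof
}

half_reactivation_time <- function(fitted, grid) {
  half <- (fitted[1] + fitted[length(fitted)]) / 2
  idx <- which(fitted >= half)
  if (length(idx) == 0) return(grid[length(grid)])
  grid[min(idx)]
}

run_profile_kmeans <- function(profiles, k, seed, nstart = 25) {
  profiles <- as.matrix(profiles)
  n_distinct <- nrow(unique(profiles))
  if (n_distinct < k)
    stop("only ", n_distinct, " distinct profiles for k = ", k,
         ": the input is degenerate; lower k or check the profiles")
  set.seed(seed)
  kmeans_pp(profiles, k, nstart = nstart)
}

#' Classify X-reactivation kinetics of genes
#'
#' k-means clustering (default k = 5) of the fitted allelic-ratio curves
#' from [xcr_profiles()]. The cluster whose curve already starts in the
#' biallelic band (initial grid ratio >= 0.15) is named "escapee"; the
#' remaining clusters are named early / intermediate / late / very_late
#' in order of their half-reactivation pseudotime (first grid point at or
#' above the midpoint of the curve's start and end values). Names depend
#' only on curve shape, so they are stable under cluster relabeling.
#'
#' @param profiles Genes x grid fitted-ratio matrix (shared grid in
#'   `attr(profiles, "grid")`).
#' @param k Number of clusters (default 5).
#' @param seed Integer RNG seed for the clustering.
#' @param escapee_threshold Initial-ratio threshold naming the escapee
#'   cluster (default 0.15).
#' @return A `data.frame` with feature_id, cluster_id, klass; cluster
#'   centers and half-times attached as attributes "centers" and
#'   "half_times".
#' @export
classify_xcr_kinetics <- function(profiles, k = 5, seed = 1,
                                  escapee_threshold = 0.15) {
  grid <- attr(profiles, "grid")
  if (is.null(grid)) grid <- seq_len(ncol(profiles))
  fit <- run_profile_kmeans(profiles, k, seed)
  centers <- fit$centers
  esc <- centers[, 1] >= escapee_threshold
  if (sum(esc) > 1)
    warning(sum(esc), " clusters start in the biallelic band; ",
            "all named escapee")
  ht <- apply(centers, 1, half_reactivation_time, grid = grid)
  klass_names <- rep(NA_character_, k)
  klass_names[esc] <- "escapee"
  nonesc <- which(!esc)
  ordered_names <- c("early", "intermediate", "late", "very_late")
  if (length(nonesc) > length(ordered_names))
    stop("more than ", length(ordered_names),
         " non-escapee clusters; use k <= 5 for XCR classes")
  klass_names[nonesc[order(ht[nonesc])]] <-
    ordered_names[seq_along(nonesc)]
  out <- data.frame(feature_id = rownames(profiles),
                    cluster_id = unname(fit$cluster),
                    klass = klass_names[fit$cluster],
                    stringsAsFactors = FALSE)
  attr(out, "centers") <- centers
  attr(out, "half_times") <- ht
  out
}

#' Classify Xa expression kinetics of genes (upregulation erasure)
#'
#' k-means clustering (default k = 3) of fitted Xa normalized-expression
#' curves from [xcd_profiles()]. Each cluster is named by comparing its
#' mean curve's start and end with the 25% rule of
#' [classify_expression_change()]: "decreased", "stable" or "increased".
#' Several clusters may share a name (e.g. all stable for flat input).
#'
#' @param profiles Genes x grid fitted-expression matrix.
#' @param k Number of clusters (default 3).
#' @param seed Integer RNG seed.
#' @param threshold Relative-change threshold for naming (default 0.25).
#' @return A `data.frame` with feature_id, cluster_id, klass; centers
#'   attached as `attr(, "centers")`.
#' @export
classify_xcd_kinetics <- function(profiles, k = 3, seed = 1,
                                  threshold = 0.25) {
  fit <- run_profile_kmeans(profiles, k, seed)
  centers <- fit$centers
  klass_names <- vapply(seq_len(k), function(i) {
    ch <- classify_expression_change(max(centers[i, 1], 1e-8),
                                     centers[i, ncol(centers)],
                                     threshold = threshold)
    c(up = "increased", down = "decreased", stable = "stable")[ch]
  }, character(1))
  out <- data.frame(feature_id = rownames(profiles),
                    cluster_id = unname(fit$cluster),
                    klass = unname(klass_names[fit$cluster]),
                    stringsAsFactors = FALSE)
  attr(out, "centers") <- centers
  out
}
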