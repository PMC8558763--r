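#' Allelic ratio
#'
#' Maternal over total allele-assignable reads, `mus / (mus + cast)`:
#' 0 means Cast-exclusive signal, 1 Mus-exclusive, 0.5 perfectly
#' biallelic.
#'
#' @param mus,cast Non-negative read counts (vectorized); their sum must
#'   be > 0.
#' @return Ratio(s) in [0, 1].
#' @export
allelic_ratio <- function(mus, cast) {
  if (any(mus < 0) || any(cast < 0)) stop("counts must be >= 0")
  if (any(mus + cast == 0))
    stop("allelic ratio undefined where mus + cast == 0")
  mus / (mus + cast)
}

#' Classify an allelic accessibility ratio into mono/biallelic states
#'
#' Ratios below 0.15 mean Cast mono-accessibility, ratios above 0.85 Mus
#' mono-accessibility, and the band from 0.15 to 0.85 (both boundaries
#' included) is biallelic.
#'
#' @param ratio Ratio(s) in [0, 1].
#' @return "cast_mono", "biallelic" or "mus_mono" (vectorized).
#' @export
classify_accessibility_state <- function(ratio) {
  if (any(ratio < 0 | ratio > 1 | !is.finite(ratio)))
    stop("ratio must lie in [0, 1]")
  ifelse(ratio < 0.15, "cast_mono",
         ifelse(ratio > 0.85, "mus_mono", "biallelic"))
}

#' Informative-region filter across all timepoints
#'
#' Keeps features whose summed allelic coverage (Mus + Cast over the
#' group's samples) reaches `min_total_per_group` in *every* group, so
#' their allelic-ratio trajectories are defined at all timepoints.
#'
#' @param m An `AllelicCountMatrix`.
#' @param min_total_per_group Minimum summed allelic reads per group
#'   (default 9, inclusive).
#' @param groups Named character vector mapping samples to groups;
#'   defaults to `m$groups`.
#' @return Character vector of retained feature IDs.
#' @export
filter_informative_regions <- function(m, min_total_per_group = 9,
                                       groups = NULL) {
  grp <- resolve_groups(m, groups)
  allelic <- m$counts_mus + m$counts_cast
  ok <- rep(TRUE, nrow(allelic))
  for (g in unique(grp)) {
    gs <- rowSums(allelic[, grp == g, drop = FALSE])
    ok <- ok & (gs >= min_total_per_group) & (gs > 0)
  }
  m$features[ok]
}

#' Per-group allelic-ratio trajectories
#'
#' Sums allelic counts over each group's samples and forms the Mus
#' fraction per feature and group, ordered by `group_order`. Entries with
#' zero allelic coverage in a group are `NA`; use
#' [filter_informative_regions()] first to avoid them.
#'
#' @param m An `AllelicCountMatrix`.
#' @param group_order Character vector fixing the trajectory order
#'   (e.g. d0, d8, d9, d10, d12, iPSC).
#' @param features Optional subset of features.
#' @param groups Named character vector of sample groups; defaults to
#'   `m$groups`.
#' @return Numeric matrix features x groups of allelic ratios.
#' @export
ratio_trajectories <- function(m, group_order, features = NULL,
                               groups = NULL) {
  grp <- resolve_groups(m, groups)
  if (!all(group_order %in% grp))
    stop("groups absent from the matrix: ",
         paste(setdiff(group_order, grp), collapse = ", "))
  if (is.null(features)) features <- m$features
  mus <- m$counts_mus[features, , drop = FALSE]
  cast <- m$counts_cast[features, , drop = FALSE]
  out <- sapply(group_order, function(g) {
    ms <- rowSums(mus[, grp == g, drop = FALSE])
    cs <- rowSums(cast[, grp == g, drop = FALSE])
    ifelse(ms + cs == 0, NA_real_, ms / (ms + cs))
  })
  out <- matrix(out, nrow = length(features),
                dimnames = list(features, group_order))
  out
}

# k-means with k-means++ seeding: `nstart` independent seedings, each
# refined by Lloyd iterations via stats::kmeans, best total
# within-cluster sum of squares wins. Euclidean distance on the raw
# vectors (ratios are bounded and commensurate; no scaling).
kmeans_pp <- function(x, k, nstart = 25, iter.max = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds the number of rows (", n, ")")
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1, ] <- x[sample.int(n, 1), ]
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    if (k > 1) {
      for (j in 2:k) {
        if (all(d2 == 0)) {
          centers[j, ] <- x[sample.int(n, 1), ]
        } else {
          centers[j, ] <- x[sample.int(n, 1, prob = d2), ]
        }
        dj <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
        d2 <- pmin(d2, dj)
      }
    }
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = iter.max,
                    algorithm = "Lloyd")
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Cluster allelic-ratio trajectories by k-means
#'
#' Groups features by the shape of their allelic-ratio trajectory using
#' k-means (k-means++ seeding, 25 restarts, Euclidean distance on the raw
#' ratio vectors). Deterministic given `seed`.
#'
#' @param trajectories Features x timepoints ratio matrix (no missing
#'   values; see [ratio_trajectories()]).
#' @param k Number of clusters (default 10).
#' @param seed Integer RNG seed.
#' @param nstart Number of k-means++ restarts (default 25).
#' @return A `data.frame` with feature_id and cluster_id; the cluster
#'   mean trajectories (k x timepoints) are attached as
#'   `attr(, "centers")`.
#' @export
cluster_ratio_trajectories <- function(trajectories, k = 10, seed = 1,
                                       nstart = 25) {
  trajectories <- as.matrix(trajectories)
  if (anyNA(trajectories))
    stop("trajectories contain missing ratios; filter informative regions first")
  if (k > nrow(trajectories))
    stop("k (", k, ") exceeds the number of features (",
         nrow(trajectories), ")")
  set.seed(seed)
  fit <- kmeans_pp(trajectories, k, nstart = nstart)
  out <- data.frame(feature_id = rownames(trajectories),
                    cluster_id = unname(fit$cluster),
                    stringsAsFactors = FALSE)
  centers <- fit$centers
  colnames(centers) <- colnames(trajectories)
  attr(out, "centers") <- centers
  out
}

#' Name trajectory clusters by their accessibility dynamics
#'
#' Each cluster's mean Mus-ratio trajectory is labeled by the first
#' timepoint at which it leaves the Cast-monoallelic band (ratio >=
#' `opening_threshold`): a cluster opening at d8 is "early", d9
#' "intermediate", d10 "late", d12 "very_late" (a first crossing only at
#' the terminal iPSC point is also called very_late). Clusters already
#' out of the band at the first timepoint are "escapee" (biallelic start)
#' or "mus_mono_to_bi" (Mus-monoallelic start), and clusters that never
#' leave the band are "cast_monoallelic".
#'
#' @param centers Cluster mean trajectories (clusters x timepoints), as
#'   attached by [cluster_ratio_trajectories()]; columns named by
#'   timepoint.
#' @param opening_threshold Lower biallelic band edge (default 0.15).
#' @param timepoint_categories Named map from opening timepoint to
#'   category.
#' @return A `data.frame` with cluster_id, category, opening_timepoint.
#' @export
assign_categories <- function(centers, opening_threshold = 0.15,
                              timepoint_categories = c(
                                d8 = "early", d9 = "intermediate",
                                d10 = "late", d12 = "very_late",
                                iPSC = "very_late")) {
  centers <- as.matrix(centers)
  tps <- colnames(centers)
  out <- lapply(seq_len(nrow(centers)), function(i) {
    tr <- centers[i, ]
    if (tr[1] >= opening_threshold) {
      cat <- if (classify_accessibility_state(min(max(tr[1], 0), 1)) ==
                 "mus_mono") "mus_mono_to_bi" else "escapee"
      return(data.frame(cluster_id = i, category = cat,
                        opening_timepoint = tps[1],
                        stringsAsFactors = FALSE))
    }
    idx <- which(tr >= opening_threshold)
    if (length(idx) == 0)
      return(data.frame(cluster_id = i, category = "cast_monoallelic",
                        opening_timepoint = NA_character_,
                        stringsAsFactors = FALSE))
    tp <- tps[min(idx)]
    cat <- unname(timepoint_categories[tp])
    if (is.na(cat))
      stop("no category mapping for opening timepoint '", tp, "'")
    data.frame(cluster_id = i, category = cat, opening_timepoint = tp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genomic distance to the nearest reference (biallelic) region
#'
#' For each query region, the gap in bp to the closest reference region
#' on the same chromosome (closest-edge convention; 0 for any overlap or
#' adjacency). Regions on chromosomes without any reference region get
#' `NA` with a warning.
#'
#' @param features,reference_biallelic Data frames with columns chrom,
#'   start, end, feature_id (0-based half-open coordinates).
#' @return Named numeric vector of distances (bp) per query feature.
#' @export
distance_to_nearest_biallelic <- function(features, reference_biallelic) {
  as_gr <- function(df) {
    GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
  }
  q <- as_gr(features)
  r <- as_gr(reference_biallelic)
  hits <- GenomicRanges::distanceToNearest(q, r, ignore.strand = TRUE)
  d <- rep(NA_real_, length(q))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  names(d) <- features$feature_id
  if (anyNA(d))
    warning(sum(is.na(d)),
            " region(s) on chromosomes with no reference regions -> NA")
  d
}

#' Estimate chromatin opening time from allelic-ratio trajectories
#'
#' Fits, per feature, a log-linked Gaussian GLM of the allelic ratio on
#' the numeric reprogramming day and reports the day at which the fitted
#' ratio crosses the biallelic threshold (0.15). Features already at or
#' above the threshold at day 0 (fitted) get opening time 0; features
#' whose fitted curve never reaches the threshold within the observed
#' day range (or whose fit fails) are skipped with a message. Class
#' means (enhancer vs promoter etc.) are attached when `reg_class` is
#' given.
#'
#' @param trajectories Features x timepoints ratio matrix.
#' @param days Numeric day per timepoint column (iPSC is conventionally
#'   coded as a late day, e.g. 16).
#' @param reg_class Optional regulatory class per feature (same order as
#'   rows).
#' @param threshold Opening threshold on the ratio scale (default 0.15).
#' @return A `data.frame` with feature_id, opening_time and (if given)
#'   reg_class; per-class mean opening times attached as
#'   `attr(, "class_means")`.
#' @export
estimate_opening_time <- function(trajectories, days, reg_class = NULL,
                                  threshold = 0.15) {
  trajectories <- as.matrix(trajectories)
  stopifnot(length(days) == ncol(trajectories))
  fit_one <- function(y) {
    fit <- tryCatch(
      stats::glm(y ~ days, family = stats::gaussian(link = "log"),
                 mustart = pmax(y, 1e-3)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !fit$converged) return(NA_real_)
    b <- stats::coef(fit)
    if (exp(b[1] + b[2] * min(days)) >= threshold) return(0)
    if (b[2] <= 0) return(NA_real_)
    ot <- (log(threshold) - b[1]) / b[2]
    if (ot > max(days)) return(NA_real_)
    max(ot, 0)
  }
  if (is.null(rownames(trajectories)))
    rownames(trajectories) <- sprintf("feature%03d",
                                      seq_len(nrow(trajectories)))
  ot <- apply(trajectories, 1, fit_one)
  out <- data.frame(feature_id = rownames(trajectories),
                    opening_time = unname(ot), stringsAsFactors = FALSE)
  if (!is.null(reg_class)) out$reg_class <- reg_class
  n_skip <- sum(is.na(ot))
  if (n_skip > 0)
    message(n_skip, " feature(s) skipped (non-convergent or never-opening fit)")
  if (!is.null(reg_class)) {
    cm <- tapply(out$opening_time, out$reg_class, mean, na.rm = TRUE)
    attr(out, "class_means") <- cm
  }
  out
}
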