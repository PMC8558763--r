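#' Library-size normalization of allelic counts
#'
#' Each layer (Mus, Cast, total) is divided by the sample's total library
#' size (column sum of the *total* layer -- allelic layers are scaled by
#' the full library, not the much smaller allelic library), multiplied by
#' `scale` and log(1+x)-transformed. Raw layers are left untouched and
#' re-running simply overwrites the normalized layers. Entries flagged by
#' [apply_missing_convention()] are set to `NA` in the normalized allelic
#' layers so no downstream statistic consumes them as zeros.
#'
#' @param m An `AllelicCountMatrix`.
#' @param scale Scale factor (default 10,000).
#' @param log_base Base of the logarithm (default natural log).
#' @return `m` with `norm_mus`, `norm_cast`, `norm_total` filled in.
#' @export
normalize_library <- function(m, scale = 10000, log_base = exp(1)) {
  validate_allelic_matrix(m)
  lib <- colSums(m$counts_total)
  zero <- m$samples[lib == 0]
  if (length(zero) > 0)
    stop("zero total library size for samples: ",
         paste(zero, collapse = ", "), " -- drop them before normalizing")
  norm1 <- function(x) {
    out <- log1p(sweep(x, 2, lib, "/") * scale) / log(log_base)
    dimnames(out) <- dimnames(x)
    out
  }
  m$norm_mus <- norm1(m$counts_mus)
  m$norm_cast <- norm1(m$counts_cast)
  m$norm_total <- norm1(m$counts_total)
  if (any(m$missing_mask)) {
    m$norm_mus[m$missing_mask] <- NA_real_
    m$norm_cast[m$missing_mask] <- NA_real_
  }
  m
}

#' Minimum allelic coverage filter (per sample group)
#'
#' Within each sample group (timepoint), features whose summed allelic
#' coverage `sum(mus + cast)` over the group's samples falls below
#' `min_total` are masked for that group: the retained/masked status is
#' recorded in a features x groups logical matrix (`m$retained`) and the
#' normalized allelic values of masked (feature, group) contexts are set
#' to `NA`. A feature can therefore be informative at one timepoint and
#' masked at another; cross-timepoint analyses should intersect (see
#' [filter_informative_regions()]).
#'
#' @param m An `AllelicCountMatrix`.
#' @param min_total Minimum summed allelic reads per group (default 10,
#'   inclusive: a sum of exactly `min_total` is retained).
#' @param groups Named character vector mapping samples to groups;
#'   defaults to `m$groups`.
#' @return `m` with `m$retained` set; a per-group retention report is
#'   attached as `attr(m$retained, "report")`.
#' @export
filter_min_allelic_total <- function(m, min_total = 10, groups = NULL) {
  if (min_total < 1) stop("min_total must be >= 1")
  grp <- resolve_groups(m, groups)
  glev <- unique(grp)
  allelic <- m$counts_mus + m$counts_cast
  retained <- sapply(glev, function(g) {
    rowSums(allelic[, grp == g, drop = FALSE]) >= min_total
  })
  dimnames(retained) <- list(m$features, glev)
  m$retained <- retained
  attr(m$retained, "report") <- data.frame(
    group = glev,
    n_retained = colSums(retained),
    n_total = nrow(retained)
  )
  if (!is.null(m$norm_mus)) {
    for (g in glev) {
      cols <- which(grp == g)
      drop <- !retained[, g]
      m$norm_mus[drop, cols] <- NA_real_
      m$norm_cast[drop, cols] <- NA_real_
    }
  }
  m
}

#' SNP coverage filter for genes
#'
#' Allelic quantification of a gene is only trustworthy when enough
#' strain SNPs cover it; genes covered by fewer than `min_snps` SNPs are
#' removed from the matrix entirely.
#'
#' @param m An `AllelicCountMatrix` whose annotation has `snp_count`.
#' @param min_snps Minimum SNP count (default 4, inclusive).
#' @return The filtered `AllelicCountMatrix`.
#' @export
filter_min_snps <- function(m, min_snps = 4) {
  sc <- m$annotation$snp_count[match(m$features, m$annotation$feature_id)]
  if (any(is.na(sc)))
    stop("snp_count missing for: ",
         paste(utils::head(m$features[is.na(sc)], 5), collapse = ", "))
  subset_allelic_matrix(m, features = m$features[sc >= min_snps])
}

#' Flag expressed-but-allelically-uninformative entries
#'
#' Distinguishes true absence of expression from missing allelic
#' information: an entry with total reads but no allele-assignable reads
#' is flagged missing (`NA` downstream), while an entry with no reads at
#' all stays a numeric zero.
#'
#' @param m An `AllelicCountMatrix` with a total layer.
#' @return `m` with `missing_mask` set (and normalized allelic layers
#'   masked to `NA`, if already computed).
#' @export
apply_missing_convention <- function(m) {
  mask <- m$counts_total > 0 & (m$counts_mus + m$counts_cast) == 0
  dimnames(mask) <- dimnames(m$counts_total)
  m$missing_mask <- mask
  if (!is.null(m$norm_mus)) {
    m$norm_mus[mask] <- NA_real_
    m$norm_cast[mask] <- NA_real_
  }
  m
}

#' RPKM normalization of allelic counts
#'
#' Reads per kilobase of feature length per million library reads:
#' `count * 1e9 / (length * library_size)`.
#'
#' @param counts Numeric vector/matrix of raw counts (features in rows).
#' @param gene_lengths Feature lengths in bp (recycled along rows).
#' @param library_sizes Per-sample library sizes (recycled along columns).
#' @return RPKM values with the shape of `counts`.
#' @export
rpkm_normalize <- function(counts, gene_lengths, library_sizes) {
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  if (is.matrix(counts)) {
    sweep(sweep(counts, 1, gene_lengths, "/"), 2, library_sizes, "/") * 1e9
  } else {
    counts * 1e9 / (gene_lengths * library_sizes)
  }
}

#' Feature sets used by X/A statistics
#'
#' `autosomal_features()` returns the autosomal feature IDs of an
#' annotation (guarding against chrX/chrY/chrM leakage: X/A statistics
#' must never include sex or mitochondrial chromosomes in the autosomal
#' pool); `x_features()` returns chrX features, optionally including
#' escapees.
#'
#' @param ann A feature annotation `data.frame`.
#' @return Character vector of feature IDs.
#' @export
autosomal_features <- function(ann) {
  ann$feature_id[ann$category == "autosomal" &
                   !ann$chrom %in% c("chrX", "chrY", "chrM")]
}

#' @rdname autosomal_features
#' @param include_escapees Include escapee features (default TRUE).
#' @export
x_features <- function(ann, include_escapees = TRUE) {
  keep <- ann$chrom == "chrX" &
    ann$category %in% c("x_linked", if (include_escapees) "escapee")
  ann$feature_id[keep]
}
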