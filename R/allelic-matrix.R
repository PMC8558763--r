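#' Allelic count matrix
#'
#' The universal container for allele-resolved count data from a hybrid
#' Mus musculus (129) x Mus castaneus cross: features (ATAC regions or
#' genes) in rows, samples (bulk timepoints or single cells) in columns,
#' with one layer per parental allele plus a non-allelic total layer.
#' Because only reads overlapping strain SNPs can be assigned to an
#' allele, `counts_mus + counts_cast <= counts_total` element-wise.
#'
#' @param counts_mus,counts_cast Non-negative integer matrices of
#'   maternal (Mus) and paternal (Cast) allele read counts, same
#'   dimensions, with feature row names and sample column names.
#' @param annotation A feature annotation `data.frame`; see
#'   [read_feature_annotation()] for the required columns.
#' @param counts_total Optional matrix of total (allele-unassignable
#'   included) counts; defaults to `counts_mus + counts_cast`.
#' @param groups Optional named character vector mapping sample names to
#'   group labels (e.g. isolation timepoints d0..iPSC or clusters C0..C5).
#'
#' @return An object of class `AllelicCountMatrix`: a list with elements
#'   `features`, `samples`, `counts_mus`, `counts_cast`, `counts_total`,
#'   `norm_mus`, `norm_cast`, `norm_total` (NULL until
#'   [normalize_library()] is run), `annotation`, `missing_mask`,
#'   `retained` (NULL until a group-level filter is run) and `groups`.
#' @export
AllelicCountMatrix <- function(counts_mus, counts_cast, annotation,
                               counts_total = NULL, groups = NULL) {
  counts_mus <- as.matrix(counts_mus)
  counts_cast <- as.matrix(counts_cast)
  if (is.null(counts_total)) counts_total <- counts_mus + counts_cast
  counts_total <- as.matrix(counts_total)
  m <- structure(list(
    features = rownames(counts_mus),
    samples = colnames(counts_mus),
    counts_mus = counts_mus,
    counts_cast = counts_cast,
    counts_total = counts_total,
    norm_mus = NULL, norm_cast = NULL, norm_total = NULL,
    annotation = annotation,
    missing_mask = matrix(FALSE, nrow(counts_mus), ncol(counts_mus),
                          dimnames = dimnames(counts_mus)),
    retained = NULL,
    groups = groups
  ), class = "AllelicCountMatrix")
  validate_allelic_matrix(m)
  m
}

#' Validate an AllelicCountMatrix
#'
#' Checks the structural invariants: matching dimensions and dimnames
#' across layers, non-negative integer raw counts, allelic counts bounded
#' by totals, and a one-to-one feature/annotation correspondence (escapee
#' features must lie on chrX).
#'
#' @param m An `AllelicCountMatrix`.
#' @return `m`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_allelic_matrix <- function(m) {
  stopifnot(inherits(m, "AllelicCountMatrix"))
  layers <- list(mus = m$counts_mus, cast = m$counts_cast,
                 total = m$counts_total)
  for (nm in names(layers)) {
    x <- layers[[nm]]
    if (!identical(dim(x), dim(m$counts_mus)))
      stop("layer '", nm, "' has mismatched dimensions")
    if (!identical(rownames(x), m$features))
      stop("layer '", nm, "' has mismatched feature names")
    if (!identical(colnames(x), m$samples))
      stop("layer '", nm, "' has mismatched sample names")
    bad <- which(x < 0 | x != round(x), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("layer '", nm, "' has negative or non-integer counts, e.g. ",
           "feature '", m$features[bad[1, 1]], "' sample '",
           m$samples[bad[1, 2]], "'")
  }
  over <- which(m$counts_mus + m$counts_cast > m$counts_total,
                arr.ind = TRUE)
  if (nrow(over) > 0)
    stop("allelic counts exceed total counts for feature '",
         m$features[over[1, 1]], "' sample '", m$samples[over[1, 2]], "'")
  ann <- m$annotation
  missing_ann <- setdiff(m$features, ann$feature_id)
  if (length(missing_ann) > 0)
    stop("features absent from annotation: ",
         paste(utils::head(missing_ann, 5), collapse = ", "))
  if (anyDuplicated(ann$feature_id))
    stop("duplicated annotation rows for: ",
         ann$feature_id[duplicated(ann$feature_id)][1])
  if (any(ann$start >= ann$end))
    stop("annotation has start >= end for feature '",
         ann$feature_id[which(ann$start >= ann$end)[1]], "'")
  esc_bad <- ann$feature_id[ann$category == "escapee" & ann$chrom != "chrX"]
  if (length(esc_bad) > 0)
    stop("escapee feature not on chrX: '", esc_bad[1], "'")
  if (!is.null(m$groups)) {
    if (!all(m$samples %in% names(m$groups)))
      stop("groups vector does not cover all samples")
  }
  invisible(m)
}

#' @export
dim.AllelicCountMatrix <- function(x) dim(x$counts_mus)

#' @export
print.AllelicCountMatrix <- function(x, ...) {
  cat("AllelicCountMatrix:", nrow(x$counts_mus), "features x",
      ncol(x$counts_mus), "samples\n")
  cat("  chromosomes:",
      paste(sort(unique(x$annotation$chrom)), collapse = " "), "\n")
  cat("  normalized:", if (is.null(x$norm_total)) "no" else "yes", "\n")
  cat("  missing entries:", sum(x$missing_mask), "\n")
  if (!is.null(x$groups))
    cat("  groups:", paste(unique(x$groups), collapse = " "), "\n")
  invisible(x)
}

#' Subset an allelic matrix by features and/or samples
#'
#' All layers, the missing mask and the annotation are subset
#' consistently; normalized layers are preserved (they are per-sample
#' quantities, unaffected by dropping features).
#'
#' @param m An `AllelicCountMatrix`.
#' @param features,samples Character vectors (or logical/integer indices)
#'   of features / samples to keep; `NULL` keeps all.
#' @return The subset `AllelicCountMatrix`.
#' @export
subset_allelic_matrix <- function(m, features = NULL, samples = NULL) {
  if (is.null(features)) features <- m$features
  if (is.null(samples)) samples <- m$samples
  if (is.character(features) &&
      length(bad <- setdiff(features, m$features)) > 0)
    stop("unknown features: ", paste(utils::head(bad, 5), collapse = ", "))
  if (is.character(samples) &&
      length(bad <- setdiff(samples, m$samples)) > 0)
    stop("unknown samples: ", paste(utils::head(bad, 5), collapse = ", "))
  for (layer in c("counts_mus", "counts_cast", "counts_total",
                  "norm_mus", "norm_cast", "norm_total", "missing_mask")) {
    if (!is.null(m[[layer]]))
      m[[layer]] <- m[[layer]][features, samples, drop = FALSE]
  }
  m$features <- rownames(m$counts_mus)
  m$samples <- colnames(m$counts_mus)
  m$annotation <- m$annotation[match(m$features, m$annotation$feature_id), ,
                               drop = FALSE]
  rownames(m$annotation) <- NULL
  if (!is.null(m$retained))
    m$retained <- m$retained[m$features, , drop = FALSE]
  if (!is.null(m$groups)) m$groups <- m$groups[m$samples]
  m
}

read_count_layer <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop("count file '", path, "' needs a feature_id column plus samples")
  x <- as.matrix(tab[, -1, drop = FALSE])
  rownames(x) <- as.character(tab[[1]])
  storage.mode(x) <- "double"
  x
}

#' Read an allelic count matrix from delimited files
#'
#' Count layers are TSV files with features as rows and samples as
#' columns, the first column holding the feature identifier. All layers
#' must share the same feature index and sample header. The annotation is
#' a BED-like TSV (see [read_feature_annotation()]).
#'
#' @param mus_path,cast_path Paths to the Mus / Cast allele count TSVs.
#' @param total_path Optional path to the total (non-allelic) count TSV.
#' @param annotation_path Path to the BED-like feature annotation.
#' @param groups Optional named character vector of sample group labels.
#' @return A validated `AllelicCountMatrix`.
#' @export
read_allelic_matrix <- function(mus_path, cast_path, total_path = NULL,
                                annotation_path, groups = NULL) {
  mus <- read_count_layer(mus_path)
  cast <- read_count_layer(cast_path)
  if (!identical(rownames(mus), rownames(cast)))
    stop("Mus and Cast files disagree on features, first difference: '",
         setdiff(union(rownames(mus), rownames(cast)),
                 intersect(rownames(mus), rownames(cast)))[1], "'")
  if (!identical(colnames(mus), colnames(cast)))
    stop("Mus and Cast files disagree on samples: ",
         paste(setdiff(union(colnames(mus), colnames(cast)),
                       intersect(colnames(mus), colnames(cast))),
               collapse = ", "))
  total <- if (is.null(total_path)) NULL else read_count_layer(total_path)
  if (!is.null(total)) {
    if (!identical(dimnames(total), dimnames(mus)))
      stop("total layer disagrees with allelic layers on features/samples")
  }
  ann <- read_feature_annotation(annotation_path)
  AllelicCountMatrix(mus, cast, ann, counts_total = total, groups = groups)
}

#' Write an allelic count matrix to a directory of delimited files
#'
#' Writes `mus.tsv`, `cast.tsv`, `total.tsv` and `annotation.bed` under
#' `dir`; the inverse of [read_allelic_matrix()] (raw layers round-trip
#' bit-exactly; normalized layers and masks are not serialized).
#'
#' @param m An `AllelicCountMatrix`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_allelic_matrix <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mus = file.path(dir, "mus.tsv"),
             cast = file.path(dir, "cast.tsv"),
             total = file.path(dir, "total.tsv"),
             annotation = file.path(dir, "annotation.bed"))
  write_layer <- function(x, path) {
    out <- data.frame(feature_id = rownames(x), x, check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_layer(m$counts_mus, paths["mus"])
  write_layer(m$counts_cast, paths["cast"])
  write_layer(m$counts_total, paths["total"])
  write_feature_annotation(m$annotation, paths["annotation"])
  invisible(paths)
}

#' Read a BED-like feature annotation
#'
#' Expects a headerless TSV with columns chrom, start, end, feature_id,
#' category, reg_class and optionally snp_count. Coordinates are 0-based
#' half-open (BED convention). `category` is one of autosomal / x_linked /
#' escapee; `reg_class` one of enhancer / promoter / other / unknown.
#'
#' @param path Path to the annotation file.
#' @return A `data.frame` with one row per feature.
#' @export
read_feature_annotation <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!ncol(tab) %in% c(6, 7))
    stop("annotation must have 6 or 7 columns, got ", ncol(tab))
  names(tab) <- c("chrom", "start", "end", "feature_id", "category",
                  "reg_class", if (ncol(tab) == 7) "snp_count")
  if (ncol(tab) == 6) tab$snp_count <- NA_integer_
  bad_cat <- setdiff(unique(tab$category),
                     c("autosomal", "x_linked", "escapee"))
  if (length(bad_cat) > 0)
    stop("unknown feature category: ", paste(bad_cat, collapse = ", "))
  bad_reg <- setdiff(unique(tab$reg_class),
                     c("enhancer", "promoter", "other", "unknown"))
  if (length(bad_reg) > 0)
    stop("unknown reg_class: ", paste(bad_reg, collapse = ", "))
  tab
}

#' @rdname read_feature_annotation
#' @param ann An annotation `data.frame`.
#' @export
write_feature_annotation <- function(ann, path) {
  cols <- c("chrom", "start", "end", "feature_id", "category", "reg_class")
  if (!all(is.na(ann$snp_count))) cols <- c(cols, "snp_count")
  utils::write.table(ann[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a pseudotime axis
#'
#' A 3-column TSV with header `sample_id`, `pseudotime`, `group_label`:
#' one row per sample/cell, pseudotime a finite value >= 0 (inferred
#' upstream, e.g. by a trajectory method -- never inferred here) and a
#' categorical label (isolation timepoint or cluster).
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with columns sample_id, pseudotime, group_label.
#' @export
read_pseudotime <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "pseudotime", "group_label") %in% names(tab)))
  if (anyDuplicated(tab$sample_id))
    stop("duplicated sample_id in pseudotime table")
  if (any(!is.finite(tab$pseudotime)) || any(tab$pseudotime < 0))
    stop("pseudotime values must be finite and >= 0")
  tab
}

#' @rdname read_pseudotime
#' @param pt A pseudotime `data.frame`.
#' @export
write_pseudotime <- function(pt, path) {
  utils::write.table(pt[, c("sample_id", "pseudotime", "group_label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# sample -> group lookup used by the group-aware filters and statistics;
# falls back to the matrix's own groups vector
resolve_groups <- function(m, groups = NULL) {
  if (is.null(groups)) groups <- m$groups
  if (is.null(groups))
    stop("no sample groups: pass `groups` or set them on the matrix")
  if (!all(m$samples %in% names(groups)))
    stop("groups vector missing samples: ",
         paste(setdiff(m$samples, names(groups)), collapse = ", "))
  groups[m$samples]
}
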