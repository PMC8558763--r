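#!/usr/bin/env Rscript
# Allelic-ratio dynamics of X-linked chromatin regions across
# reprogramming: informative-region filtering, k-means trajectory
# clustering into opening categories, distance to pre-existing biallelic
# regions, and GLM-based opening-time estimates for enhancers vs
# promoters.

suppressPackageStartupMessages(library(xdosage))
seed <- 2024
out <- "results/dynamics"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

atac <- simulate_atac_timepoints(atac_config("mef_female"), seed = seed)
m <- atac$matrix
tps <- atac$config$timepoints
ann <- m$annotation

keep <- filter_informative_regions(m, 9)
xk <- intersect(keep, x_features(ann))
message(length(keep), " informative regions (>= 9 allelic reads at every ",
        "timepoint), of which ", length(xk), " X-linked")

tr <- ratio_trajectories(m, tps, features = xk)
utils::write.table(data.frame(feature_id = rownames(tr), tr,
                              check.names = FALSE),
                   file.path(out, "x_ratio_trajectories.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cl <- cluster_ratio_trajectories(tr, k = 10, seed = seed)
cats <- assign_categories(attr(cl, "centers"))
cl$category <- cats$category[match(cl$cluster_id, cats$cluster_id)]
truth <- atac$truth$category[match(cl$feature_id, atac$truth$feature_id)]
agree <- mean(cl$category == truth)
message(sprintf(
  "10 k-means clusters -> 7 categories; %.1f%% of regions match their planted category",
  100 * agree))
print(table(cluster = cats$category))
utils::write.table(cl, file.path(out, "region_categories.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(cluster_id = cats$cluster_id, category = cats$category,
             opening_timepoint = cats$opening_timepoint,
             round(attr(cl, "centers"), 4), check.names = FALSE),
  file.path(out, "cluster_centers.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

# distance from each X region to the nearest day-0 biallelic region
d0_ratio <- ratio_trajectories(m, "d0", features = keep)[, 1]
bi0 <- names(d0_ratio)[classify_accessibility_state(d0_ratio) == "biallelic"]
bi0 <- intersect(bi0, x_features(ann))
qx <- ann[ann$feature_id %in% setdiff(xk, bi0), ]
ref <- ann[ann$feature_id %in% bi0, ]
dist <- distance_to_nearest_biallelic(qx, ref)
by_cat <- tapply(dist, cl$category[match(names(dist), cl$feature_id)],
                 median, na.rm = TRUE)
message("median distance (bp) to nearest day-0 biallelic region, by category:")
print(round(by_cat))
utils::write.table(data.frame(feature_id = names(dist), distance_bp = dist),
                   file.path(out, "distance_to_biallelic.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# opening-time GLM per region, summarized by regulatory class
opening <- estimate_opening_time(
  tr, atac$config$days,
  reg_class = ann$reg_class[match(rownames(tr), ann$feature_id)])
cm <- attr(opening, "class_means")
message("mean estimated opening day by regulatory class:")
print(round(cm, 2))
utils::write.table(opening, file.path(out, "opening_times.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
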