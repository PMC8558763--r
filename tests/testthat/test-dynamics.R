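test_that("allelic ratio and its symmetry hold on valid inputs", {
  expect_equal(allelic_ratio(5, 5), 0.5)
  expect_equal(allelic_ratio(0, 12), 0)
  set.seed(1)
  m <- rpois(50, 8); c <- rpois(50, 8)
  keep <- m + c > 0
  expect_equal(allelic_ratio(m[keep], c[keep]) +
                 allelic_ratio(c[keep], m[keep]),
               rep(1, sum(keep)))
  expect_error(allelic_ratio(0, 0), "undefined")
})

test_that("accessibility states partition [0,1] with biallelic boundaries", {
  expect_equal(classify_accessibility_state(0.5), "biallelic")
  expect_equal(classify_accessibility_state(0.10), "cast_mono")
  expect_equal(classify_accessibility_state(0.15), "biallelic")
  expect_equal(classify_accessibility_state(0.85), "biallelic")
  expect_equal(classify_accessibility_state(0.851), "mus_mono")
  grid <- seq(0, 1, by = 0.001)
  states <- classify_accessibility_state(grid)
  expect_true(all(states %in% c("cast_mono", "biallelic", "mus_mono")))
  expect_error(classify_accessibility_state(1.2), "0, 1")
})

test_that("informative-region filter requires coverage at every timepoint", {
  ids <- c("r1", "r2", "r3")
  samples <- paste0("g", 1:6)
  groups <- setNames(samples, samples)
  # r1: exactly 9 everywhere; r2: one group at 8; r3: zero everywhere
  mus <- named_matrix(c(rep(c(5L, 4L, 0L), 6)), ids, samples)
  cast <- named_matrix(c(rep(c(4L, 4L, 0L), 6)), ids, samples)
  mus["r2", "g3"] <- 4L
  m <- toy_matrix(mus, cast, groups = groups)
  expect_equal(filter_informative_regions(m, 9), "r1")
  expect_setequal(filter_informative_regions(m, 0), c("r1", "r2"))
})

test_that("trajectory k-means recovers planted archetypes deterministically", {
  set.seed(3)
  tr <- rbind(matrix(pmax(rnorm(40 * 6, 0.02, 0.01), 0), 40, 6),
              matrix(rnorm(40 * 6, 0.5, 0.02), 40, 6))
  rownames(tr) <- sprintf("r%02d", 1:80)
  colnames(tr) <- paste0("t", 1:6)
  cl <- cluster_ratio_trajectories(tr, k = 2, seed = 11)
  centers <- attr(cl, "centers")
  expect_equal(unname(sort(rowMeans(centers))), c(0.02, 0.5),
               tolerance = 0.05)
  # perfect membership recovery of the two planted groups
  expect_equal(length(unique(cl$cluster_id[1:40])), 1)
  expect_equal(length(unique(cl$cluster_id[41:80])), 1)
  expect_false(cl$cluster_id[1] == cl$cluster_id[41])
  # identical partition from the same seed
  cl2 <- cluster_ratio_trajectories(tr, k = 2, seed = 11)
  expect_identical(cl$cluster_id, cl2$cluster_id)
  # k = 1 collapses to the grand mean trajectory
  cl1 <- cluster_ratio_trajectories(tr, k = 1, seed = 11)
  expect_equal(as.numeric(attr(cl1, "centers")),
               unname(colMeans(tr)))
  expect_error(cluster_ratio_trajectories(tr, k = 100, seed = 1),
               "exceeds")
  # permutation invariance of the partition (up to relabeling)
  perm <- sample(nrow(tr))
  cl3 <- cluster_ratio_trajectories(tr[perm, ], k = 2, seed = 11)
  agree <- table(cl$cluster_id[perm], cl3$cluster_id)
  expect_equal(sum(apply(agree, 1, max)), nrow(tr))
})

test_that("cluster categories follow the first biallelic crossing", {
  tps <- c("d0", "d8", "d9", "d10", "d12", "iPSC")
  centers <- rbind(
    early = c(0.02, 0.35, 0.40, 0.45, 0.50, 0.50),
    escapee = rep(0.5, 6),
    cast_monoallelic = rep(0.02, 6),
    late = c(0.02, 0.05, 0.10, 0.30, 0.45, 0.50),
    very_late_terminal = c(0.02, 0.03, 0.05, 0.08, 0.10, 0.40),
    mus_mono_to_bi = c(0.95, 0.90, 0.60, 0.50, 0.50, 0.50))
  colnames(centers) <- tps
  cats <- assign_categories(centers)
  expect_equal(cats$category,
               c("early", "escapee", "cast_monoallelic", "late",
                 "very_late", "mus_mono_to_bi"))
  expect_equal(cats$opening_timepoint[1], "d8")
  expect_equal(cats$opening_timepoint[4], "d10")
})

test_that("nearest biallelic-region distances match a brute-force oracle", {
  regions <- data.frame(chrom = "chrX",
                        start = c(1000L, 5000L),
                        end = c(1100L, 5100L),
                        feature_id = c("q1", "q2"))
  ref <- data.frame(chrom = "chrX", start = c(2000L, 1050L),
                    end = c(2100L, 1150L),
                    feature_id = c("b1", "b2"))
  d <- distance_to_nearest_biallelic(regions, ref)
  expect_equal(unname(d["q1"]), 0)      # overlaps b2
  expect_equal(unname(d["q2"]), 2900)   # gap to b1: 5000 - 2100

  set.seed(12)
  qn <- 50; rn <- 30
  q <- data.frame(chrom = sample(c("chr1", "chr2"), qn, TRUE),
                  start = s <- sample.int(1e6, qn),
                  end = s + 200L,
                  feature_id = sprintf("q%02d", 1:qn))
  r <- data.frame(chrom = sample(c("chr1", "chr2"), rn, TRUE),
                  start = s2 <- sample.int(1e6, rn),
                  end = s2 + 200L,
                  feature_id = sprintf("r%02d", 1:rn))
  d <- distance_to_nearest_biallelic(q, r)
  oracle <- vapply(seq_len(qn), function(i) {
    same <- r[r$chrom == q$chrom[i], ]
    gaps <- pmax(same$start - q$end[i], q$start[i] - same$end, 0)
    if (nrow(same) == 0) NA_real_ else min(gaps)
  }, numeric(1))
  expect_equal(unname(d), oracle)

  # chromosome with no reference regions -> NA with warning
  q2 <- rbind(q, data.frame(chrom = "chrY", start = 1L, end = 100L,
                            feature_id = "lonely"))
  expect_warning(d2 <- distance_to_nearest_biallelic(q2, r), "NA")
  expect_true(is.na(d2["lonely"]))
})

test_that("log-linked GLM opening times recover planted crossings", {
  days <- c(0, 8, 9, 10, 12, 16)
  # exactly log-linear trajectory crossing 0.15 at day 9
  b1 <- 0.25
  b0 <- log(0.15) - b1 * 9
  tr <- rbind(planted = pmin(exp(b0 + b1 * days), 1),
              escapee = rep(0.5, 6))
  ot <- estimate_opening_time(tr, days)
  expect_equal(ot$opening_time[1], 9, tolerance = 1e-3)
  expect_equal(ot$opening_time[2], 0)

  # enhancers opening one timepoint before promoters
  mk <- function(cross) pmin(exp((log(0.15) - 0.3 * cross) + 0.3 * days), 1)
  tr2 <- rbind(mk(8), mk(8), mk(8), mk(9), mk(9), mk(9))
  cls <- rep(c("enhancer", "promoter"), each = 3)
  ot2 <- estimate_opening_time(tr2, days, reg_class = cls)
  cm <- attr(ot2, "class_means")
  expect_lt(cm["enhancer"], cm["promoter"])
})
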