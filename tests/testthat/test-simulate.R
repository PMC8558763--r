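test_that("generators are bit-reproducible and validate their configs", {
  a1 <- simulate_atac_timepoints(atac_config("null", n_autosomal = 200,
                                             n_x = 40), seed = 30)
  a2 <- simulate_atac_timepoints(atac_config("null", n_autosomal = 200,
                                             n_x = 40), seed = 30)
  expect_identical(a1$matrix$counts_mus, a2$matrix$counts_mus)
  expect_identical(a1$matrix$counts_total, a2$matrix$counts_total)
  expect_error(atac_config("null", not_a_field = 1), "unknown config")
  expect_error(atac_config("mef_female", xa_fold = -1))

  s1 <- simulate_reprogramming_scrna(
    scrna_config("null", n_cells = 40, n_autosomal = 60, n_x = 20),
    seed = 31)
  s2 <- simulate_reprogramming_scrna(
    scrna_config("null", n_cells = 40, n_autosomal = 60, n_x = 20),
    seed = 31)
  expect_identical(s1$matrix$counts_cast, s2$matrix$counts_cast)
  expect_error(scrna_config("null", nope = 2), "unknown config")
})

test_that("autosomal allelic ratios are symmetric around 0.5", {
  sim <- simulate_atac_timepoints(atac_config("mef_female"), seed = 32)
  m <- sim$matrix
  af <- autosomal_features(m$annotation)
  mus <- rowSums(m$counts_mus[af, ])
  cast <- rowSums(m$counts_cast[af, ])
  expect_lt(abs(mean(allelic_ratio(mus, cast)) - 0.5), 0.01)
})

test_that("the null configurations put X and autosomes on equal footing", {
  sim <- simulate_atac_timepoints(atac_config("null"), seed = 33)
  m <- filter_min_allelic_total(normalize_library(sim$matrix), 10)
  for (al in c("cast", "mus")) {
    fc <- x_autosome_fold(m, al, "d0")
    expect_gt(fc$fold_change, 0.95)
    expect_lt(fc$fold_change, 1.05)
  }
  tr <- chromosome_autosome_trajectory(m, "chrX", "cast",
                                       group_order = sim$config$timepoints)
  expect_true(all(abs(tr$ratio - 1) < 0.05))

  simn <- simulate_reprogramming_scrna(scrna_config("null", n_cells = 80),
                                       seed = 34)
  mn <- normalize_library(apply_missing_convention(simn$matrix))
  r <- x_autosome_ratio_per_cell(mn, "cast")
  expect_lt(abs(median(r) - 1), 0.07)
  xr <- rowSums(mn$counts_mus[x_features(mn$annotation), ])
  xc <- rowSums(mn$counts_cast[x_features(mn$annotation), ])
  expect_lt(abs(mean(allelic_ratio(xr, xc)) - 0.5), 0.02)
})

test_that("ATAC dynamics are recovered end-to-end from planted categories", {
  sim <- simulate_atac_timepoints(atac_config("mef_female"), seed = 35)
  m <- sim$matrix
  keep <- filter_informative_regions(m, 9)
  xk <- intersect(keep, x_features(m$annotation))
  tr <- ratio_trajectories(m, sim$config$timepoints, features = xk)
  cl <- cluster_ratio_trajectories(tr, k = 10, seed = 36)
  cats <- assign_categories(attr(cl, "centers"))
  called <- cats$category[match(cl$cluster_id, cats$cluster_id)]
  truth <- sim$truth$category[match(cl$feature_id,
                                    sim$truth$feature_id)]
  expect_gte(mean(called == truth), 0.9)
  # a planted early region is classified early
  early_ids <- cl$feature_id[truth == "early"]
  expect_gte(mean(called[truth == "early"] == "early"), 0.9)

  # Cast-allele enhancement decays toward 1, Mus ratio rises toward 1
  mm <- filter_min_allelic_total(normalize_library(m), 10)
  traj_c <- chromosome_autosome_trajectory(mm, "chrX", "cast",
                                           group_order = sim$config$timepoints)
  expect_equal(traj_c$ratio[1],
               x_autosome_fold(mm, "cast", "d0")$fold_change,
               tolerance = 1e-8)
  expect_lt(traj_c$ratio[6], traj_c$ratio[1])
  expect_lt(abs(traj_c$ratio[6] - 1), 0.06)
  traj_m <- chromosome_autosome_trajectory(mm, "chrX", "mus",
                                           group_order = sim$config$timepoints)
  expect_gt(traj_m$ratio[6], traj_m$ratio[1])
})

test_that("reprogramming scRNA couples Xi reactivation to pseudotime", {
  sim <- simulate_reprogramming_scrna(scrna_config("reprogramming"),
                                      seed = 37)
  m <- normalize_library(apply_missing_convention(sim$matrix))
  r <- x_autosome_ratio_per_cell(m, "mus")
  pt <- sim$pseudotime$pseudotime
  expect_lt(median(r[pt < 0.15], na.rm = TRUE), 0.1)
  expect_gt(median(r[pt > 0.9], na.rm = TRUE), 0.75)
  # missing-data convention arises naturally from unassignable reads
  expect_gt(sum(m$missing_mask), 0)
})

test_that("simulated marginals match the Poisson-beta pmf (chi-square GoF)", {
  set.seed(38)
  n_genes <- 40; n_cells <- 1000
  pvals <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    kon <- rlnorm(1, log(1), 0.4); koff <- rlnorm(1, log(6), 0.4)
    ksyn <- rlnorm(1, log(100), 0.4)
    x <- rpoisbeta(n_cells, kon, koff, ksyn)
    ub <- max(x)
    p <- poisson_beta_pmf(0:ub, kon, koff, ksyn)
    p <- c(p, max(1 - sum(p), 1e-12))
    obs <- c(tabulate(x + 1, nbins = ub + 1), 0)
    # pool bins to expected counts >= 5
    grp <- c(0, head(cumsum(p * n_cells), -1)) %/% 5
    o <- tapply(obs, grp, sum); e <- tapply(p * n_cells, grp, sum)
    stat <- sum((o - e)^2 / e)
    pvals[i] <- pchisq(stat, df = length(o) - 1, lower.tail = FALSE)
  }
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("XO cells lose one X allele and upregulate the retained one", {
  cfg <- scrna_config("xo_ipsc", n_cells = 300,
                      ksyn_meanlog = log(600))
  sim <- simulate_xo_ipscs(cfg, seed = 39)
  m <- normalize_library(apply_missing_convention(sim$matrix))
  cells <- sim$truth$cells
  xf <- x_features(m$annotation)
  mus_lost <- cells$sample_id[cells$x_state == "XO_mus_lost"]
  expect_true(all(m$counts_mus[xf, mus_lost] == 0))

  # retained-allele X/A ratio in XO cells exceeds either allele's in XX
  r_cast <- x_autosome_ratio_per_cell(m, "cast")
  r_mus <- x_autosome_ratio_per_cell(m, "mus")
  xx <- cells$sample_id[cells$x_state == "XX"]
  expect_gt(median(r_cast[mus_lost]), median(r_cast[xx]))
  expect_gt(median(r_cast[mus_lost]), median(r_mus[xx]))

  # burst comparison on the retained allele recovers the k_on multiplier
  g0 <- sim$truth$xa_kon_multiplier
  counts_xo <- m$counts_cast[xf, mus_lost]
  counts_xx <- m$counts_cast[xf, xx]
  kin_xo <- fit_burst_kinetics(counts_xo, min_cells = 50)
  kin_xx <- fit_burst_kinetics(counts_xx, min_cells = 50)
  conv <- kin_xo$converged & kin_xx$converged
  fold <- median(kin_xo$burst_frequency[conv]) /
    median(kin_xx$burst_frequency[conv])
  expect_lt(abs(fold - g0), 0.2 * g0)
  expect_error(simulate_xo_ipscs(scrna_config("c0_mef")), "xo_fraction")
})
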