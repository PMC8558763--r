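# Synthetic allelic-count generators. They emulate the statistical
# structure the analyses assume -- diploid biallelic autosomes, a
# silenced Xi with escapees, an enhanced/upregulated Xa whose
# enhancement is erased during reprogramming, class-wise Xi reactivation
# schedules, XO cells, telegraph-model counts and allele-unassignable
# reads -- with full ground truth, so every pipeline stage is testable
# without sequencing data.
#
# Enhancement calibration: the Xa enhancement parameter (`xa_fold`) is
# defined on the scale the corresponding statistic is reported on -- the
# fold change of median library-normalized log1p signal (ATAC) or of the
# per-cell median normalized expression (scRNA) of X-linked features
# over autosomal ones. The generators convert that target fold into a
# count-scale multiplier by solving the fold equation on the planted
# expected values (ATAC) or on the planted Poisson-beta count mixture
# (scRNA), so the generative truth *is* the statistic's target value.

open_day_map <- c(early = 8, intermediate = 9, late = 10, very_late = 12)

#' Configuration for the ATAC timepoint simulator
#'
#' @param preset "mef_female" (reprogramming of female MEFs: Xi-Mus,
#'   enhanced Xa-Cast, fold 1.33 at day 0 decaying to 1), "mesc_male"
#'   (a single male mESC group: sole X-Mus enhanced 1.4-fold, no Cast X)
#'   or "null" (no enhancement, no silencing: X statistically
#'   indistinguishable from autosomes).
#' @param ... Named overrides of any config field.
#' @return A list of generator settings (see source for fields).
#' @export
atac_config <- function(preset = c("mef_female", "mesc_male", "null"),
                        ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    timepoints = c("d0", "d8", "d9", "d10", "d12", "iPSC"),
    days = c(0, 8, 9, 10, 12, 16),
    n_samples_per_group = 2,
    n_autosomal = 3000,
    n_x = 300,
    # X-region accessibility dynamics categories and their frequencies
    category_probs = c(early = 0.20, intermediate = 0.15, late = 0.20,
                       very_late = 0.15, escapee = 0.10,
                       mus_mono_to_bi = 0.10, cast_monoallelic = 0.10),
    xa_fold = 1.33,          # target X/A fold of median normalized signal
    xa_allele = "cast",
    male = FALSE,            # male: no Cast X chromosome at all
    # decay of the enhancement during reprogramming (weight in [0,1])
    xa_decay = function(day) stats::plogis(-(day - 11)),
    silenced_level = 0.02,   # accessibility of a closed allele, rel. to open
    mus_mono_open_day = 10,  # when Mus-mono regions gain Cast accessibility
    rate_meanlog = log(300), # per-allele true read rate of a region
    rate_sdlog = 0.6,
    nb_size = 50,            # negative-binomial overdispersion of counts
    assignable_fraction = 0.1, # fraction of reads overlapping strain SNPs
    depth_sdlog = 0.3,       # log-normal library depth variation
    scale = 10000
  )
  if (preset == "mesc_male") {
    cfg$timepoints <- "mESC"; cfg$days <- 0
    cfg$xa_fold <- 1.4; cfg$xa_allele <- "mus"; cfg$male <- TRUE
    cfg$category_probs <- c(escapee = 1)
  } else if (preset == "null") {
    cfg$xa_fold <- 1
    cfg$category_probs <- c(escapee = 1)
  }
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad) > 0) stop("unknown config fields: ",
                            paste(bad, collapse = ", "))
  cfg[names(override)] <- override
  validate_atac_config(cfg)
  cfg
}

validate_atac_config <- function(cfg) {
  stopifnot(length(cfg$timepoints) == length(cfg$days),
            cfg$n_samples_per_group >= 1,
            cfg$n_autosomal > 0, cfg$n_x > 0,
            cfg$xa_fold > 0, cfg$silenced_level >= 0,
            cfg$assignable_fraction > 0, cfg$assignable_fraction <= 1,
            abs(sum(cfg$category_probs) - 1) < 1e-8,
            all(names(cfg$category_probs) %in%
                  c(names(open_day_map), "escapee", "mus_mono_to_bi",
                    "cast_monoallelic")))
  invisible(cfg)
}

sim_annotation <- function(feature_ids, is_x, sim_category) {
  n <- length(feature_ids)
  chrom <- character(n)
  chrom[!is_x] <- paste0("chr", rep_len(1:19, sum(!is_x)))
  chrom[is_x] <- "chrX"
  start <- sample.int(15e7, n, replace = TRUE)
  category <- ifelse(!is_x, "autosomal",
                     ifelse(sim_category == "escapee", "escapee",
                            "x_linked"))
  reg_class <- rep("unknown", n)
  reg_class[is_x] <- sample(c("enhancer", "promoter", "other"), sum(is_x),
                            replace = TRUE, prob = c(0.4, 0.3, 0.3))
  data.frame(feature_id = feature_ids, chrom = chrom, start = start,
             end = start + 500L, category = category,
             reg_class = reg_class, snp_count = NA_integer_,
             stringsAsFactors = FALSE)
}

# Count-scale multiplier g reproducing a target fold of median
# normalized signal, given planted per-allele expected allelic counts.
# `x_allelic` / `a_allelic` are the enhanced-allele expected allelic
# counts of X / autosomal features at multiplier 1; `other_lib` is the
# expected total-layer library contribution that does not scale with g;
# `x_lib_at_1` the contribution that does.
solve_fold_multiplier <- function(target_fold, x_allelic, a_allelic,
                                  other_lib, x_true_at_1, scale) {
  pred <- function(g) {
    lib <- other_lib + g * x_true_at_1
    med_x <- stats::median(log1p(scale * g * x_allelic / lib))
    med_a <- stats::median(log1p(scale * a_allelic / lib))
    med_x / med_a - target_fold
  }
  if (abs(target_fold - 1) < 1e-12) return(1)
  stats::uniroot(pred, c(1e-3, 1e3), tol = 1e-10)$root
}

#' Simulate allele-resolved ATAC-seq counts over reprogramming timepoints
#'
#' Regions x samples allelic count matrices for the timepoint design d0,
#' d8, d9, d10, d12, iPSC (configurable). Autosomal regions are
#' biallelic; X regions follow a planted accessibility-dynamics category:
#' the silenced Mus allele of early/intermediate/late/very_late regions
#' opens at d8/d9/d10/d12, escapees are biallelic throughout,
#' Mus-monoallelic regions gain Cast accessibility mid-course and
#' Cast-monoallelic regions never open on Mus. The active-X allele
#' carries a calibrated enhancement (`xa_fold` on the normalized-median
#' scale) that decays to 1 during reprogramming. True counts are
#' negative-binomial draws; the allelic layers are binomial thinnings
#' (only SNP-overlapping reads are allele-assignable) and the total
#' layer keeps all reads. Bit-reproducible given `seed`.
#'
#' @param config From [atac_config()].
#' @param seed Integer RNG seed.
#' @return A list: `matrix` (`AllelicCountMatrix` with groups set),
#'   `truth` (per-region category, opening day, rate), `xa_multiplier`
#'   (per-timepoint count-scale enhancement) and `config`.
#' @export
simulate_atac_timepoints <- function(config = atac_config(), seed = 1) {
  validate_atac_config(config)
  set.seed(seed)
  cfg <- config
  n_feat <- cfg$n_autosomal + cfg$n_x
  feature_ids <- c(sprintf("regA%04d", seq_len(cfg$n_autosomal)),
                   sprintf("regX%04d", seq_len(cfg$n_x)))
  is_x <- c(rep(FALSE, cfg$n_autosomal), rep(TRUE, cfg$n_x))
  rate <- stats::rlnorm(n_feat, cfg$rate_meanlog, cfg$rate_sdlog)
  category <- rep(NA_character_, n_feat)
  category[is_x] <- sample(names(cfg$category_probs), cfg$n_x,
                           replace = TRUE, prob = cfg$category_probs)
  open_day <- unname(open_day_map[category])

  n_tp <- length(cfg$timepoints)
  # per-feature multipliers for each timepoint, before Xa enhancement
  mult_mus <- matrix(1, n_feat, n_tp)
  mult_cast <- matrix(1, n_feat, n_tp)
  for (j in seq_len(n_tp)) {
    day <- cfg$days[j]
    opened <- !is.na(open_day) & day >= open_day
    cls <- !is.na(category)
    silenced <- cfg$silenced_level
    mm <- rep(1, n_feat)
    mm[cls & category %in% names(open_day_map)] <-
      silenced + (1 - silenced) * opened[cls & category %in%
                                           names(open_day_map)]
    mm[cls & category == "cast_monoallelic"] <- silenced
    mult_mus[, j] <- mm
    mc <- rep(1, n_feat)
    mc[cls & category == "mus_mono_to_bi"] <-
      silenced + (1 - silenced) * (day >= cfg$mus_mono_open_day)
    mult_cast[, j] <- mc
  }
  if (cfg$male) mult_cast[is_x, ] <- 0

  # calibrated enhancement multiplier per timepoint on the active allele;
  # applied to all X regions already accessible on that allele
  enh_layer <- if (cfg$xa_allele == "cast") "cast" else "mus"
  g_tp <- numeric(n_tp)
  af <- cfg$assignable_fraction
  for (j in seq_len(n_tp)) {
    target <- 1 + (cfg$xa_fold - 1) * cfg$xa_decay(cfg$days[j])
    enh_mult <- if (enh_layer == "cast") mult_cast[, j] else mult_mus[, j]
    oth_mult <- if (enh_layer == "cast") mult_mus[, j] else mult_cast[, j]
    x_true_at_1 <- sum(rate[is_x] * enh_mult[is_x])
    other_lib <- sum(rate[is_x] * oth_mult[is_x]) +
      sum(rate[!is_x] * (mult_mus[!is_x, j] + mult_cast[!is_x, j]))
    g_tp[j] <- solve_fold_multiplier(
      target,
      x_allelic = af * rate[is_x] * enh_mult[is_x],
      a_allelic = af * rate[!is_x] * (if (enh_layer == "cast")
        mult_cast[!is_x, j] else mult_mus[!is_x, j]),
      other_lib = other_lib, x_true_at_1 = x_true_at_1,
      scale = cfg$scale)
    if (enh_layer == "cast") {
      mult_cast[is_x, j] <- mult_cast[is_x, j] * g_tp[j]
    } else {
      mult_mus[is_x, j] <- mult_mus[is_x, j] * g_tp[j]
    }
  }

  samples <- as.vector(vapply(cfg$timepoints, function(tp)
    paste0(tp, "_r", seq_len(cfg$n_samples_per_group)),
    character(cfg$n_samples_per_group)))
  groups <- stats::setNames(rep(cfg$timepoints,
                                each = cfg$n_samples_per_group), samples)
  n_s <- length(samples)
  depth <- stats::rlnorm(n_s, 0, cfg$depth_sdlog)
  counts_mus <- counts_cast <- counts_total <-
    matrix(0L, n_feat, n_s, dimnames = list(feature_ids, samples))
  for (s in seq_len(n_s)) {
    j <- match(groups[s], cfg$timepoints)
    t_mus <- stats::rnbinom(n_feat, mu = rate * mult_mus[, j] * depth[s],
                            size = cfg$nb_size)
    t_cast <- stats::rnbinom(n_feat, mu = rate * mult_cast[, j] * depth[s],
                             size = cfg$nb_size)
    counts_mus[, s] <- stats::rbinom(n_feat, t_mus, af)
    counts_cast[, s] <- stats::rbinom(n_feat, t_cast, af)
    counts_total[, s] <- t_mus + t_cast
  }
  ann <- sim_annotation(feature_ids, is_x, category)
  m <- AllelicCountMatrix(counts_mus, counts_cast, ann,
                          counts_total = counts_total, groups = groups)
  truth <- data.frame(feature_id = feature_ids, category = category,
                      opening_day = open_day, rate = rate,
                      stringsAsFactors = FALSE)
  list(matrix = m, truth = truth,
       xa_multiplier = stats::setNames(g_tp, cfg$timepoints),
       config = cfg)
}

#' Configuration for the single-cell RNA reprogramming simulator
#'
#' @param preset "reprogramming" (cells spread over the full pseudotime
#'   axis, Xi reactivating in 5 kinetic classes while the Xa enhancement
#'   decays), "c0_mef" (MEF-like somatic cells only: silenced Xi-Mus,
#'   Xa-Cast upregulated 1.35-fold), "xo_ipsc" (iPSC-stage XX cells plus
#'   XO cells that lost either X, with sole-Xa upregulation) or "null"
#'   (no XCI, no upregulation).
#' @param ... Named overrides of any config field.
#' @return A list of generator settings.
#' @export
scrna_config <- function(preset = c("reprogramming", "c0_mef", "xo_ipsc",
                                    "null"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    n_cells = 300,
    n_autosomal = 800,
    n_x = 150,
    fraction_escapees = 0.15,
    # Xi reactivation pseudotimes per kinetic class (pseudotime in [0,1])
    reactivation_schedule = c(early = 0.30, intermediate = 0.50,
                              late = 0.65, very_late = 0.85),
    react_slope = 0.04,      # logistic slope of the k_on reactivation
    silenced_kon_mult = 0.01, # k_on multiplier of the silenced Xi allele
    xa_fold = 1.35,          # target per-cell X/A ratio of the Xa
    xa_allele = "cast",
    xa_decay = function(t) 1 - stats::plogis((t - 0.6) / 0.05),
    pseudotime_range = c(0, 1),
    xo_fraction = 0,         # fraction of cells having lost one X
    # telegraph-model parameter distributions (read-scale k_syn: counts
    # are sequencing reads, not UMIs)
    kon_meanlog = log(1), kon_sdlog = 0.5,
    koff_meanlog = log(6), koff_sdlog = 0.5,
    ksyn_meanlog = log(9000), ksyn_sdlog = 0.5,
    assignable_fraction = 0.1,
    depth_sdlog = 0.3,
    scale = 10000
  )
  if (preset == "c0_mef") {
    cfg$pseudotime_range <- c(0, 0.02)
    cfg$n_cells <- 200
  } else if (preset == "xo_ipsc") {
    cfg$pseudotime_range <- c(0.98, 1)
    cfg$xo_fraction <- 0.5
    cfg$n_cells <- 200
  } else if (preset == "null") {
    cfg$xa_fold <- 1
    cfg$fraction_escapees <- 1
  }
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad) > 0) stop("unknown config fields: ",
                            paste(bad, collapse = ", "))
  cfg[names(override)] <- override
  stopifnot(cfg$n_cells > 0, cfg$xa_fold > 0,
            cfg$fraction_escapees >= 0, cfg$fraction_escapees <= 1,
            cfg$xo_fraction >= 0, cfg$xo_fraction <= 1,
            all(cfg$reactivation_schedule >= cfg$pseudotime_range[1] |
                  cfg$reactivation_schedule >= 0))
  cfg
}

# Poisson-beta count pmf matrix (rows 0..n_max) for one gene, and the
# conditional distribution of this allele's count given the gene is
# expressed (mus + cast > 0); used by the scRNA enhancement calibration.
pb_pmf_vec <- function(n_max, k_on, k_off, k_syn) {
  poisson_beta_pmf(0:n_max, k_on, k_off, k_syn)
}

# Predicted per-cell median normalized value of one allele over a gene
# set: interpolated median of the expression-conditioned count mixture.
mixture_median <- function(pmf_list, p0_other, weights = NULL) {
  n_max <- max(vapply(pmf_list, length, integer(1))) - 1
  mix <- numeric(n_max + 1)
  wsum <- 0
  for (i in seq_along(pmf_list)) {
    p <- pmf_list[[i]]
    q <- 1 - p[1] * p0_other[i]        # P(expressed)
    if (q <= 0) next
    cond <- p
    cond[1] <- p[1] * (1 - p0_other[i])
    cond <- cond / q
    w <- if (is.null(weights)) q else weights[i]
    mix[seq_along(cond)] <- mix[seq_along(cond)] + w * cond
    wsum <- wsum + w
  }
  mix <- mix / wsum
  cdf <- cumsum(mix)
  n_star <- which(cdf >= 0.5)[1]
  if (is.na(n_star)) return(NA_real_)  # grid too short: caller regrows
  if (n_star == 1) return(0.5 * mix[1])
  (n_star - 2) + (0.5 - cdf[n_star - 1]) / mix[n_star]
}

# Calibrate the Xa k_on multiplier so the per-cell median-normalized
# X/A ratio statistic equals `target` in the somatic (fully enhanced)
# state. Works on the planted Poisson-beta mixtures at reference depth.
solve_xa_kon_multiplier <- function(target, kon, koff, ksyn, is_x,
                                    mus_mult_x, cfg) {
  if (abs(target - 1) < 1e-12) return(1)
  af <- cfg$assignable_fraction
  ks_a <- af * ksyn            # allelic-layer k_syn after thinning
  mean_expr <- function(kon_eff, idx)
    ksyn[idx] * kon_eff / (kon_eff + koff[idx])
  xi <- which(is_x)
  ai <- which(!is_x)
  # pmf grids need only reach the count-mixture median, not the far
  # tail: cap per gene at ~3x the mixture's expected scale (grown on
  # demand by mixture_median's caller if the cdf never reaches 0.5)
  cap_for <- function(means) {
    ceiling(3 * stats::median(means)) + 30
  }
  mix_median_capped <- function(idx, kon_eff, cap, p0_other) {
    repeat {
      pmfs <- lapply(seq_along(idx), function(k) {
        i <- idx[k]
        pb_pmf_vec(min(cap, ceiling(ks_a[i]) + 30), kon_eff[k], koff[i],
                   ks_a[i])
      })
      med <- mixture_median(pmfs, p0_other)
      if (!is.na(med)) return(med)
      cap <- cap * 2
    }
  }
  # only P(0) of the partner allele enters the expressed-gene
  # conditioning: the silenced Mus allele for X genes, the identically
  # distributed second allele for autosomal genes
  p0_mus <- vapply(seq_along(xi), function(k) {
    i <- xi[k]
    poisson_beta_pmf(0L, kon[i] * mus_mult_x[k], koff[i], ks_a[i])
  }, numeric(1))
  p0_auto <- vapply(ai, function(i)
    poisson_beta_pmf(0L, kon[i], koff[i], ks_a[i]), numeric(1))
  # autosomal side is enhancement-independent: compute once
  mean_a <- af * mean_expr(kon[ai], ai)
  med_a_counts <- mix_median_capped(ai, kon[ai], cap_for(mean_a), p0_auto)
  pred <- function(g) {
    mean_x <- af * mean_expr(kon[xi] * g, xi)
    med_x_counts <- mix_median_capped(xi, kon[xi] * g, cap_for(mean_x),
                                      p0_mus)
    lib <- 2 * sum(mean_expr(kon[ai], ai)) +
      sum(mean_expr(kon[xi] * g, xi)) +
      sum(mean_expr(kon[xi] * mus_mult_x, xi))
    v_x <- log1p(cfg$scale * med_x_counts / lib)
    v_a <- log1p(cfg$scale * med_a_counts / lib)
    v_x / v_a - target
  }
  stats::uniroot(pred, c(1, 60), tol = 1e-3, extendInt = "upX")$root
}

#' Simulate allele-resolved single-cell RNA-seq along reprogramming
#'
#' Cells are placed uniformly along pseudotime and labeled C0..C5 by
#' sextile. Per gene and allele, read counts are drawn from the
#' telegraph model (Beta-then-Poisson). The Xi (Mus) allele's k_on is
#' scaled by a logistic reactivation factor centred at the gene's
#' kinetic-class pseudotime; the Xa (Cast) allele's k_on carries a
#' calibrated upregulation multiplier whose effect equals `xa_fold` on
#' the per-cell X/A statistic in the somatic state and decays along
#' pseudotime (`xa_decay`). Escapees are biallelic throughout. Optional
#' XO cells lose all counts (escapees included) from one X allele while
#' the retained allele keeps the full upregulation multiplier.
#' Allele-unassignable reads are modeled by binomial thinning into the
#' total layer. Bit-reproducible given `seed`.
#'
#' @param config From [scrna_config()].
#' @param seed Integer RNG seed.
#' @return A list: `matrix` (`AllelicCountMatrix`, groups = C0..C5),
#'   `pseudotime` (sample_id/pseudotime/group_label table), `truth`
#'   (list with per-gene `genes`, per-cell `cells`, `xa_kon_multiplier`)
#'   and `config`.
#' @export
simulate_reprogramming_scrna <- function(config = scrna_config(),
                                         seed = 1) {
  cfg <- config
  set.seed(seed)
  n_feat <- cfg$n_autosomal + cfg$n_x
  feature_ids <- c(sprintf("geneA%04d", seq_len(cfg$n_autosomal)),
                   sprintf("geneX%04d", seq_len(cfg$n_x)))
  is_x <- c(rep(FALSE, cfg$n_autosomal), rep(TRUE, cfg$n_x))
  kon <- stats::rlnorm(n_feat, cfg$kon_meanlog, cfg$kon_sdlog)
  koff <- stats::rlnorm(n_feat, cfg$koff_meanlog, cfg$koff_sdlog)
  ksyn <- stats::rlnorm(n_feat, cfg$ksyn_meanlog, cfg$ksyn_sdlog)

  klass <- rep(NA_character_, n_feat)
  n_x <- cfg$n_x
  esc <- stats::runif(n_x) < cfg$fraction_escapees
  klass[is_x] <- ifelse(esc, "escapee",
                        sample(names(cfg$reactivation_schedule), n_x,
                               replace = TRUE))
  t_class <- unname(cfg$reactivation_schedule[klass])

  cells <- sprintf("cell%04d", seq_len(cfg$n_cells))
  pt <- stats::runif(cfg$n_cells, cfg$pseudotime_range[1],
                     cfg$pseudotime_range[2])
  cluster <- paste0("C", pmin(floor(pt * 6), 5))
  depth <- stats::rlnorm(cfg$n_cells, 0, cfg$depth_sdlog)
  x_state <- rep("XX", cfg$n_cells)
  if (cfg$xo_fraction > 0) {
    xo <- stats::runif(cfg$n_cells) < cfg$xo_fraction
    x_state[xo] <- sample(c("XO_mus_lost", "XO_cast_lost"), sum(xo),
                          replace = TRUE)
  }

  # Xi (Mus) reactivation multiplier per X gene x cell
  xi_idx <- which(is_x)
  react_mult <- matrix(1, length(xi_idx), cfg$n_cells)
  for (k in seq_along(xi_idx)) {
    if (!is.na(t_class[xi_idx[k]])) {
      react_mult[k, ] <- cfg$silenced_kon_mult +
        (1 - cfg$silenced_kon_mult) *
        stats::plogis((pt - t_class[xi_idx[k]]) / cfg$react_slope)
    }
  }
  # calibrate the somatic-state upregulation multiplier; the somatic
  # Xi state used for calibration is the fully silenced one
  mus_mult_somatic <- ifelse(is.na(t_class[xi_idx]), 1,
                             cfg$silenced_kon_mult)
  g0 <- solve_xa_kon_multiplier(cfg$xa_fold, kon, koff, ksyn, is_x,
                                mus_mult_somatic, cfg)
  xa_mult <- 1 + (g0 - 1) * cfg$xa_decay(pt)   # per cell

  kon_mus <- matrix(kon, n_feat, cfg$n_cells)
  kon_cast <- matrix(kon, n_feat, cfg$n_cells)
  kon_mus[xi_idx, ] <- kon[xi_idx] * react_mult
  kon_cast[xi_idx, ] <- sweep(matrix(kon[xi_idx], length(xi_idx),
                                     cfg$n_cells), 2, xa_mult, "*")
  # XO cells: the retained allele keeps the full upregulation multiplier
  for (j in which(x_state != "XX")) {
    if (x_state[j] == "XO_mus_lost") {
      kon_cast[xi_idx, j] <- kon[xi_idx] * g0
    } else {
      kon_mus[xi_idx, j] <- kon[xi_idx] * g0
    }
  }

  draw_counts <- function(kon_mat) {
    p <- stats::rbeta(length(kon_mat), kon_mat,
                      matrix(koff, n_feat, cfg$n_cells))
    lam <- matrix(ksyn, n_feat, cfg$n_cells) * p
    lam <- sweep(lam, 2, depth, "*")
    matrix(stats::rpois(length(lam), lam), n_feat, cfg$n_cells)
  }
  true_mus <- draw_counts(kon_mus)
  true_cast <- draw_counts(kon_cast)
  # X loss: the lost allele contributes nothing, escapees included
  for (j in which(x_state != "XX")) {
    if (x_state[j] == "XO_mus_lost") true_mus[xi_idx, j] <- 0L
    else if (x_state[j] == "XO_cast_lost") true_cast[xi_idx, j] <- 0L
  }
  af <- cfg$assignable_fraction
  counts_mus <- matrix(stats::rbinom(length(true_mus), true_mus, af),
                       n_feat, cfg$n_cells,
                       dimnames = list(feature_ids, cells))
  counts_cast <- matrix(stats::rbinom(length(true_cast), true_cast, af),
                        n_feat, cfg$n_cells,
                        dimnames = list(feature_ids, cells))
  counts_total <- true_mus + true_cast
  dimnames(counts_total) <- list(feature_ids, cells)

  ann <- sim_annotation(feature_ids, is_x,
                        ifelse(is.na(klass), "none", klass))
  ann$snp_count <- sample(4:60, n_feat, replace = TRUE)
  groups <- stats::setNames(cluster, cells)
  m <- AllelicCountMatrix(counts_mus, counts_cast, ann,
                          counts_total = counts_total, groups = groups)
  ptab <- data.frame(sample_id = cells, pseudotime = pt,
                     group_label = cluster, stringsAsFactors = FALSE)
  truth <- list(
    genes = data.frame(feature_id = feature_ids, klass = klass,
                       t_class = t_class, k_on = kon, k_off = koff,
                       k_syn = ksyn, stringsAsFactors = FALSE),
    cells = data.frame(sample_id = cells, pseudotime = pt,
                       group_label = cluster, depth = depth,
                       x_state = x_state, stringsAsFactors = FALSE),
    xa_kon_multiplier = g0)
  list(matrix = m, pseudotime = ptab, truth = truth, config = cfg)
}

#' Simulate XX and XO iPSCs
#'
#' Thin wrapper over [simulate_reprogramming_scrna()] with the
#' "xo_ipsc" preset: iPSC-stage cells, a configurable fraction of which
#' lost either the Mus or the Cast X chromosome; the sole X allele of XO
#' cells carries the upregulation multiplier.
#'
#' @param config From `scrna_config("xo_ipsc")`.
#' @param seed Integer RNG seed.
#' @return As [simulate_reprogramming_scrna()].
#' @export
simulate_xo_ipscs <- function(config = scrna_config("xo_ipsc"),
                              seed = 1) {
  if (config$xo_fraction <= 0)
    stop("xo_fraction must be > 0 for an XO simulation")
  simulate_reprogramming_scrna(config, seed)
}

#' Simulate telegraph-model counts for a burst-inference experiment
#'
#' Per-gene counts for one allele drawn directly from the Poisson-beta
#' model, with X-linked genes' k_on scaled by `kon_fold_x` (burst
#' frequency) and k_syn by `size_fold_x` (burst size; k_off untouched)
#' relative to autosomal genes drawn from the same parameter
#' distributions. This is the allele-level count matrix a burst-MLE
#' recovery experiment fits directly (no depth variation or thinning, so
#' the planted folds are the exact generative truth).
#'
#' @param n_x,n_autosomal Numbers of X-linked / autosomal genes.
#' @param n_cells Cells per gene.
#' @param kon_fold_x,size_fold_x Multipliers applied to X-linked burst
#'   frequency (k_on) / burst size (k_syn / k_off; applied to k_syn with
#'   k_off untouched).
#' @param kon_meanlog,kon_sdlog,koff_meanlog,koff_sdlog,size_meanlog,size_sdlog
#'   Log-normal distributions of k_on, k_off and burst size shared by
#'   both gene sets; k_syn is derived as size * k_off, so the planted
#'   burst-size fold is exact.
#' @param seed Integer RNG seed.
#' @return A list: `counts` (genes x cells), `annotation` (feature_id,
#'   category), `truth` (per-gene generative parameters).
#' @export
simulate_burst_counts <- function(n_x = 300, n_autosomal = 1500,
                                  n_cells = 1000, kon_fold_x = 1.19,
                                  size_fold_x = 0.82,
                                  kon_meanlog = log(0.8), kon_sdlog = 0.6,
                                  koff_meanlog = log(5), koff_sdlog = 0.6,
                                  size_meanlog = log(24),
                                  size_sdlog = 0.5, seed = 1) {
  set.seed(seed)
  n_feat <- n_autosomal + n_x
  feature_ids <- c(sprintf("geneA%04d", seq_len(n_autosomal)),
                   sprintf("geneX%04d", seq_len(n_x)))
  is_x <- c(rep(FALSE, n_autosomal), rep(TRUE, n_x))
  # gene-level parameters are stratified quantiles of the log-normal
  # (randomly paired across parameters): the planted median fold between
  # the two gene panels is then exact at any panel size, instead of
  # fluctuating with the luck of an i.i.d. draw; count-level randomness
  # is untouched
  strat_lnorm <- function(n, meanlog, sdlog)
    stats::qlnorm(sample(stats::ppoints(n)), meanlog, sdlog)
  both <- function(meanlog, sdlog)
    c(strat_lnorm(n_autosomal, meanlog, sdlog),
      strat_lnorm(n_x, meanlog, sdlog))
  kon <- both(kon_meanlog, kon_sdlog)
  koff <- both(koff_meanlog, koff_sdlog)
  size <- both(size_meanlog, size_sdlog)
  kon[is_x] <- kon[is_x] * kon_fold_x
  size[is_x] <- size[is_x] * size_fold_x
  ksyn <- size * koff
  counts <- t(vapply(seq_len(n_feat), function(i)
    rpoisbeta(n_cells, kon[i], koff[i], ksyn[i]), numeric(n_cells)))
  rownames(counts) <- feature_ids
  colnames(counts) <- sprintf("cell%04d", seq_len(n_cells))
  list(counts = counts,
       annotation = data.frame(feature_id = feature_ids,
                               category = ifelse(is_x, "x_linked",
                                                 "autosomal"),
                               stringsAsFactors = FALSE),
       truth = data.frame(feature_id = feature_ids, k_on = kon,
                          k_off = koff, k_syn = ksyn,
                          burst_size = ksyn / koff,
                          stringsAsFactors = FALSE))
}
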