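# Gauss-Jacobi quadrature for expectations under a Beta(a, b) density:
# nodes/weights for weight (1-x)^alpha (1+x)^beta on [-1,1] via
# Golub-Welsch, mapped to [0,1]. Weights are normalized to sum to 1, so
# sum(w * f(p)) approximates E[f(p)] with p ~ Beta(a, b). Exactness for
# polynomial f makes this accurate for any a, b > 0: the Beta density,
# including its endpoint singularities, is absorbed into the quadrature
# weight.
beta_quadrature <- function(a, b, n_nodes = 50) {
  alpha <- b - 1; beta <- a - 1
  ab <- alpha + beta
  j <- seq_len(n_nodes - 1)
  diag0 <- c((beta - alpha) / (ab + 2),
             (beta^2 - alpha^2) /
               ((2 * j + ab) * (2 * j + ab + 2)))
  off2 <- 4 * j * (j + alpha) * (j + beta) * (j + ab) /
    ((2 * j + ab)^2 * (2 * j + ab + 1) * (2 * j + ab - 1))
  # n=1 term of the general formula is 0/0 when ab = 0 or -1; closed form
  off2[1] <- 4 * (1 + alpha) * (1 + beta) / ((2 + ab)^2 * (3 + ab))
  J <- diag(diag0)
  for (i in j) {
    J[i, i + 1] <- sqrt(off2[i])
    J[i + 1, i] <- sqrt(off2[i])
  }
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  nodes <- (e$values[ord] + 1) / 2
  weights <- (e$vectors[1, ord])^2
  list(nodes = pmin(pmax(nodes, 0), 1), weights = weights / sum(weights))
}

logsumexp_rows <- function(x) {
  mx <- apply(x, 1, max)
  mx + log(rowSums(exp(x - mx)))
}

#' Poisson-beta probability mass function (two-state model, steady state)
#'
#' At steady state of the telegraph model -- a gene switching ON at rate
#' `k_on`, OFF at rate `k_off` (both in units of the mRNA degradation
#' rate) and transcribing at rate `k_syn` while ON -- the mRNA count is a
#' Poisson-beta mixture: `n ~ Poisson(k_syn * p)` with
#' `p ~ Beta(k_on, k_off)`. The mixture is integrated by fixed-order
#' Gauss-Jacobi quadrature over the Beta density with log-domain
#' accumulation; for strongly boundary-singular cases
#' (`k_on` or `k_off` < 0.05) it falls back to adaptive quadrature.
#'
#' @param n Non-negative integer count(s).
#' @param k_on,k_off,k_syn Positive model rates.
#' @param n_nodes Quadrature order (default 50).
#' @param log Return log-probabilities.
#' @return Probabilities (or log-probabilities) for each `n`.
#' @export
poisson_beta_pmf <- function(n, k_on, k_off, k_syn, n_nodes = 50,
                             log = FALSE) {
  if (!all(is.finite(c(k_on, k_off, k_syn))) ||
      any(c(k_on, k_off, k_syn) <= 0))
    stop("k_on, k_off, k_syn must be finite and > 0")
  if (any(n < 0 | n != round(n))) stop("n must be non-negative integers")
  if (min(k_on, k_off) < 0.05) {
    p <- vapply(n, function(ni) {
      stats::integrate(function(p) {
        stats::dbeta(p, k_on, k_off) * stats::dpois(ni, k_syn * p)
      }, 0, 1, rel.tol = 1e-10, abs.tol = 0, subdivisions = 500L,
      stop.on.error = FALSE)$value
    }, numeric(1))
    lp <- base::log(pmax(p, 1e-300))
  } else {
    q <- beta_quadrature(k_on, k_off, n_nodes)
    # rows = counts, cols = nodes
    lmat <- outer(n, q$nodes,
                  function(ni, pj) stats::dpois(ni, k_syn * pj, log = TRUE))
    lmat <- sweep(lmat, 2, base::log(q$weights), "+")
    lp <- logsumexp_rows(lmat)
  }
  if (log) lp else exp(lp)
}

#' Sample from the Poisson-beta (telegraph steady state) distribution
#'
#' Direct Beta-then-Poisson sampling.
#'
#' @param n Number of draws.
#' @inheritParams poisson_beta_pmf
#' @return Integer vector of counts.
#' @export
rpoisbeta <- function(n, k_on, k_off, k_syn) {
  stats::rpois(n, k_syn * stats::rbeta(n, k_on, k_off))
}

# Method-of-moments estimator (Peccoud-Ycart): solves the first three
# factorial moments of the Poisson-beta for (k_on, k_off, k_syn).
# Returns NULL when the moment equations have no admissible solution.
poisson_beta_moments <- function(counts) {
  f1 <- mean(counts)
  f2 <- mean(counts * (counts - 1))
  f3 <- mean(counts * (counts - 1) * (counts - 2))
  if (f1 <= 0 || f2 <= 0 || f3 <= 0) return(NULL)
  r1 <- f1; r2 <- f2 / f1; r3 <- f3 / f2
  denom1 <- r1 * r2 - 2 * r1 * r3 + r2 * r3
  denom2 <- r1 - 2 * r2 + r3
  if (denom1 == 0 || denom2 == 0) return(NULL)
  k_on <- 2 * r1 * (r3 - r2) / denom1
  k_syn <- (2 * r1 * r3 - r1 * r2 - r2 * r3) / denom2
  k_off <- 2 * (r3 - r2) * (r1 - r3) * (r2 - r1) / (denom1 * denom2)
  est <- c(k_on = k_on, k_off = k_off, k_syn = k_syn)
  if (any(!is.finite(est)) || any(est <= 0)) return(NULL)
  est
}

#' Maximum-likelihood fit of two-state burst kinetics for one gene/allele
#'
#' Maximizes the Poisson-beta log-likelihood over (k_on, k_off, k_syn) on
#' the log scale with bounded quasi-Newton (L-BFGS-B), multi-started from
#' the method-of-moments estimate plus two fixed perturbations of it.
#' Burst frequency is k_on and burst size k_syn / k_off, both in units of
#' the mRNA degradation rate. `NA` entries (missing allelic information)
#' are dropped; non-integer values are rounded. The fit is flagged
#' non-converged when the optimizer fails or the optimum sits on a
#' parameter bound.
#'
#' @param counts Per-cell counts for one gene and allele (`NA` =
#'   missing).
#' @param min_cells Minimum non-missing cells to attempt a fit
#'   (default 50).
#' @param bounds List with `k_on`, `k_off` (default c(1e-3, 1e3)) and
#'   `k_syn` (default c(1e-2, 1e4)) bounds.
#' @param n_nodes Quadrature order for the likelihood (default 50).
#' @return A one-row `data.frame` (a `BurstKinetics`): k_on, k_off,
#'   k_syn, burst_frequency, burst_size, converged, n_cells, loglik,
#'   reason.
#' @export
fit_two_state_mle <- function(counts, min_cells = 50,
                              bounds = list(k_on = c(1e-3, 1e3),
                                            k_off = c(1e-3, 1e3),
                                            k_syn = c(1e-2, 1e4)),
                              n_nodes = 50) {
  counts <- round(counts[!is.na(counts)])
  failed <- function(reason) {
    data.frame(k_on = NA_real_, k_off = NA_real_, k_syn = NA_real_,
               burst_frequency = NA_real_, burst_size = NA_real_,
               converged = FALSE, n_cells = length(counts),
               loglik = NA_real_, reason = reason,
               stringsAsFactors = FALSE)
  }
  if (length(counts) < min_cells) return(failed("too_few_cells"))
  if (all(counts == 0)) return(failed("all_zero"))
  tab <- table(counts)
  u <- as.integer(names(tab))
  w <- as.numeric(tab)
  lower <- log(c(bounds$k_on[1], bounds$k_off[1], bounds$k_syn[1]))
  upper <- log(c(bounds$k_on[2], bounds$k_off[2], bounds$k_syn[2]))
  # likelihood always goes through the Gauss-Jacobi rule (valid for any
  # k_on, k_off > 0: the Beta density, singularities included, is the
  # quadrature weight), keeping the objective smooth for the optimizer;
  # the rule is cached across evaluations that only move k_syn (a third
  # of finite-difference gradient steps)
  quad_cache <- list(key = c(NA_real_, NA_real_), q = NULL)
  negll <- function(lpar) {
    par <- exp(lpar)
    if (!identical(quad_cache$key, par[1:2])) {
      quad_cache <<- list(key = par[1:2],
                          q = beta_quadrature(par[1], par[2], n_nodes))
    }
    q <- quad_cache$q
    lmat <- outer(u, q$nodes,
                  function(ni, pj) stats::dpois(ni, par[3] * pj,
                                                log = TRUE))
    lmat <- sweep(lmat, 2, base::log(q$weights), "+")
    v <- -sum(w * logsumexp_rows(lmat))
    if (!is.finite(v)) 1e10 else v
  }
  mom <- poisson_beta_moments(counts)
  if (is.null(mom))
    mom <- c(k_on = 1, k_off = 10,
             k_syn = max(mean(counts) * 11, 1))
  mom <- pmin(pmax(mom, exp(lower) * 1.01), exp(upper) * 0.99)
  starts <- list(mom,
                 pmin(pmax(mom * c(3, 1 / 3, 1), exp(lower) * 1.01),
                      exp(upper) * 0.99),
                 pmin(pmax(mom * c(1 / 3, 3, 1), exp(lower) * 1.01),
                      exp(upper) * 0.99))
  # the moment start is usually in the basin of attraction; the two
  # fixed perturbations are fallbacks for when it is not
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(log(s), negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
    if (!is.null(best) && best$convergence == 0 &&
        all(best$par > lower + 1e-4) && all(best$par < upper - 1e-4))
      break
  }
  if (is.null(best)) return(failed("optimizer_failed"))
  par <- exp(best$par)
  on_bound <- any(best$par <= lower + 1e-4) || any(best$par >= upper - 1e-4)
  data.frame(k_on = par[1], k_off = par[2], k_syn = par[3],
             burst_frequency = par[1], burst_size = par[3] / par[2],
             converged = best$convergence == 0 && !on_bound,
             n_cells = length(counts), loglik = -best$value,
             reason = if (best$convergence == 0 && !on_bound) "ok"
             else if (on_bound) "at_bound" else "no_convergence",
             stringsAsFactors = FALSE)
}

#' Fit burst kinetics for every gene of one allele
#'
#' Applies [fit_two_state_mle()] to each row of a counts matrix (genes x
#' cells), skipping genes with more than `max_missing_frac` missing
#' (masked) cells.
#'
#' @param counts Genes x cells count matrix (`NA` = missing allelic
#'   information per the missing-data convention). Raw allelic counts
#'   are the intended input; normalized values (e.g. RPKM from
#'   [rpkm_normalize()]) are accepted but rounded to integers for the
#'   Poisson likelihood, with a warning, which distorts the count
#'   distribution.
#' @param min_cells,bounds,n_nodes Passed to [fit_two_state_mle()].
#' @param max_missing_frac Skip genes with a larger missing fraction
#'   (default 0.9).
#' @return A `data.frame` with one row per gene (feature_id + the
#'   [fit_two_state_mle()] columns).
#' @export
fit_burst_kinetics <- function(counts, min_cells = 50,
                               bounds = list(k_on = c(1e-3, 1e3),
                                             k_off = c(1e-3, 1e3),
                                             k_syn = c(1e-2, 1e4)),
                               n_nodes = 50, max_missing_frac = 0.9) {
  if (any(counts != round(counts), na.rm = TRUE))
    warning("non-integer values (normalized data?) rounded to integers ",
            "for the Poisson-beta likelihood")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("feature%04d", seq_len(nrow(counts)))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    x <- counts[i, ]
    if (mean(is.na(x)) > max_missing_frac) {
      out <- fit_two_state_mle(numeric(0), min_cells = min_cells)
      out$reason <- "too_many_missing"
    } else {
      out <- fit_two_state_mle(x, min_cells = min_cells, bounds = bounds,
                               n_nodes = n_nodes)
    }
    cbind(feature_id = rownames(counts)[i], out,
          stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare burst kinetics between X-linked and autosomal genes
#'
#' Fold changes of median burst frequency (k_on) and median burst size
#' (k_syn / k_off) of X-linked over autosomal genes, with two-sided
#' Wilcoxon rank-sum p-values. Only converged fits enter the comparison.
#'
#' @param kinetics A `data.frame` from [fit_burst_kinetics()].
#' @param x_features,autosomal_features Feature ID vectors for the two
#'   sides.
#' @param min_converged Minimum converged genes required per side
#'   (default 20).
#' @return A one-row `data.frame` (a `BurstComparison`): fold_frequency,
#'   fold_size, p_frequency, p_size, n_x, n_autosomal.
#' @export
compare_burst <- function(kinetics, x_features, autosomal_features,
                          min_converged = 20) {
  conv <- kinetics[kinetics$converged, ]
  xk <- conv[conv$feature_id %in% x_features, ]
  ak <- conv[conv$feature_id %in% autosomal_features, ]
  if (nrow(xk) < min_converged || nrow(ak) < min_converged)
    stop("too few converged genes: ", nrow(xk), " X-linked, ",
         nrow(ak), " autosomal (need >= ", min_converged, " each)")
  data.frame(
    fold_frequency = stats::median(xk$burst_frequency) /
      stats::median(ak$burst_frequency),
    fold_size = stats::median(xk$burst_size) / stats::median(ak$burst_size),
    p_frequency = rank_sum_test(xk$burst_frequency,
                                ak$burst_frequency)$p_value,
    p_size = rank_sum_test(xk$burst_size, ak$burst_size)$p_value,
    n_x = nrow(xk), n_autosomal = nrow(ak))
}
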