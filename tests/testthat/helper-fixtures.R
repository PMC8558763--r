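# Small in-code fixtures shared across test files.

# annotation for a feature set: autosomal unless listed in x_ids/esc_ids
toy_annotation <- function(ids, x_ids = character(), esc_ids = character(),
                           snp_count = NA_integer_) {
  n <- length(ids)
  chrom <- ifelse(ids %in% c(x_ids, esc_ids), "chrX",
                  paste0("chr", rep_len(1:19, n)))
  start <- seq(1000L, by = 1000L, length.out = n)
  data.frame(feature_id = ids, chrom = chrom, start = start,
             end = start + 500L,
             category = ifelse(ids %in% esc_ids, "escapee",
                               ifelse(ids %in% x_ids, "x_linked",
                                      "autosomal")),
             reg_class = "unknown",
             snp_count = rep_len(snp_count, n),
             stringsAsFactors = FALSE)
}

# matrix with the given mus/cast layers (total defaults to mus + cast)
toy_matrix <- function(mus, cast, total = NULL, x_ids = character(),
                       esc_ids = character(), groups = NULL,
                       snp_count = NA_integer_) {
  AllelicCountMatrix(mus, cast,
                     toy_annotation(rownames(mus), x_ids, esc_ids,
                                    snp_count),
                     counts_total = total, groups = groups)
}

named_matrix <- function(data, ids, samples) {
  matrix(data, nrow = length(ids), dimnames = list(ids, samples))
}

# Poisson counts with per-feature rates; X and autosomal features drawn
# from the same distribution unless x_factor != 1
random_count_matrix <- function(n_autosomal, n_x, n_samples, rate = 30,
                                x_factor = 1, seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("a%04d", seq_len(n_autosomal)),
           sprintf("x%04d", seq_len(n_x)))
  x_ids <- ids[seq_len(n_x) + n_autosomal]
  samples <- sprintf("s%02d", seq_len(n_samples))
  lam <- rlnorm(length(ids), log(rate), 0.5)
  lam[ids %in% x_ids] <- lam[ids %in% x_ids] * x_factor
  mus <- named_matrix(rpois(length(ids) * n_samples, lam), ids, samples)
  cast <- named_matrix(rpois(length(ids) * n_samples, lam), ids, samples)
  toy_matrix(mus, cast, x_ids = x_ids,
             groups = setNames(rep("g1", n_samples), samples))
}
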