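test_that("allelic matrix IO round-trips raw layers bit-exactly", {
  ids <- c("f1", "f2", "f3")
  mus <- named_matrix(c(1L, 0L, 5L, 2L, 3L, 4L), ids, c("s1", "s2"))
  cast <- named_matrix(c(0L, 2L, 1L, 7L, 0L, 9L), ids, c("s1", "s2"))
  m <- toy_matrix(mus, cast, x_ids = "f3")
  expect_identical(dim(m), c(3L, 2L))

  dir <- withr::local_tempdir()
  write_allelic_matrix(m, dir)
  m2 <- read_allelic_matrix(file.path(dir, "mus.tsv"),
                            file.path(dir, "cast.tsv"),
                            file.path(dir, "total.tsv"),
                            file.path(dir, "annotation.bed"))
  expect_equal(m2$counts_mus, m$counts_mus)
  expect_equal(m2$counts_cast, m$counts_cast)
  expect_equal(m2$counts_total, m$counts_total)
  expect_equal(m2$annotation$category, m$annotation$category)
})

test_that("layer mismatches and invalid counts are rejected with names", {
  ids <- c("f1", "f2")
  mus <- named_matrix(0:3, ids, c("s1", "s2"))
  cast_short <- named_matrix(0:1, ids, "s1")
  dir <- withr::local_tempdir()
  utils::write.table(data.frame(feature_id = ids, mus),
                     file.path(dir, "mus.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(feature_id = ids, cast_short),
                     file.path(dir, "cast.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_feature_annotation(toy_annotation(ids),
                           file.path(dir, "ann.bed"))
  expect_error(
    read_allelic_matrix(file.path(dir, "mus.tsv"),
                        file.path(dir, "cast.tsv"),
                        annotation_path = file.path(dir, "ann.bed")),
    "s2")

  expect_error(toy_matrix(named_matrix(c(-1L, 0L, 0L, 0L), ids,
                                       c("s1", "s2")),
                          named_matrix(0L * 0:3, ids, c("s1", "s2"))),
               "negative or non-integer")
  expect_error(toy_matrix(named_matrix(c(0.5, 0, 0, 0), ids,
                                       c("s1", "s2")),
                          named_matrix(0 * 0:3, ids, c("s1", "s2"))),
               "negative or non-integer")
  # allelic counts must not exceed totals
  expect_error(toy_matrix(named_matrix(rep(5L, 4), ids, c("s1", "s2")),
                          named_matrix(rep(5L, 4), ids, c("s1", "s2")),
                          total = named_matrix(rep(7L, 4), ids,
                                               c("s1", "s2"))),
               "exceed total")
  # features missing from the annotation are rejected
  mus2 <- named_matrix(0:3, c("f1", "unknown"), c("s1", "s2"))
  expect_error(
    AllelicCountMatrix(mus2, mus2, toy_annotation(ids)),
    "absent from annotation")
})

test_that("library normalization matches the x10,000 log1p formula", {
  ids <- sprintf("f%d", 1:3)
  # sample s1 has total library 10000; f1 has one read
  mus <- named_matrix(c(1L, 9999L, 0L, 2L, 8L, 0L), ids, c("s1", "s2"))
  cast <- named_matrix(0L * 1:6, ids, c("s1", "s2"))
  m <- normalize_library(toy_matrix(mus, cast))
  expect_equal(m$norm_mus["f1", "s1"], log(2))
  # all-zero feature stays 0 in every normalized layer
  expect_equal(unname(m$norm_mus["f3", ]), c(0, 0))
  expect_equal(unname(m$norm_total["f3", ]), c(0, 0))
  # doubling every count of a sample leaves its normalized values alone
  mus_dbl <- mus; mus_dbl[, "s2"] <- 2L * mus_dbl[, "s2"]
  m2 <- normalize_library(toy_matrix(mus_dbl, cast))
  expect_equal(m2$norm_mus[, "s2"], m$norm_mus[, "s2"])
  # renormalizing overwrites, never compounds
  m3 <- normalize_library(m)
  expect_equal(m3$norm_mus, m$norm_mus)
  # zero-library samples are refused by name
  mus0 <- named_matrix(c(0L, 0L, 0L, 1L, 2L, 3L), ids, c("bad", "ok"))
  cast0 <- named_matrix(rep(0L, 6), ids, c("bad", "ok"))
  expect_error(normalize_library(toy_matrix(mus0, cast0)), "bad")
})

test_that("minimum allelic coverage filter is inclusive and per group", {
  ids <- c("f1", "f2", "f3")
  #      f1: 4+5 = 9 in g1 (dropped), 20 in g2; f2: 5+5 = 10 (kept)
  mus <- named_matrix(c(4L, 5L, 0L, 10L, 5L, 1L), ids, c("s1", "s2"))
  cast <- named_matrix(c(5L, 5L, 0L, 10L, 5L, 0L), ids, c("s1", "s2"))
  groups <- c(s1 = "g1", s2 = "g2")
  m <- filter_min_allelic_total(toy_matrix(mus, cast, groups = groups),
                                min_total = 10)
  expect_false(m$retained["f1", "g1"])
  expect_true(m$retained["f1", "g2"])
  expect_true(m$retained["f2", "g1"])
  expect_false(m$retained["f3", "g1"])
  rep1 <- attr(m$retained, "report")
  expect_equal(rep1$n_retained[rep1$group == "g1"], 1)
  # min_total = 1 keeps every feature with any allelic read
  m1 <- filter_min_allelic_total(toy_matrix(mus, cast, groups = groups),
                                 min_total = 1)
  expect_true(all(m1$retained[c("f1", "f2"), ]))
  expect_error(filter_min_allelic_total(toy_matrix(mus, cast,
                                                   groups = groups), 0),
               "min_total")
})

test_that("SNP filter keeps genes at the threshold and errors on NA", {
  ids <- c("g1", "g2", "g3")
  mus <- named_matrix(rep(1L, 6), ids, c("s1", "s2"))
  m <- toy_matrix(mus, mus, snp_count = c(4L, 3L, 12L))
  expect_setequal(filter_min_snps(m, 4)$features, c("g1", "g3"))
  expect_setequal(filter_min_snps(m, 0)$features, ids)
  m_na <- toy_matrix(mus, mus, snp_count = c(4L, NA, 12L))
  expect_error(filter_min_snps(m_na), "snp_count missing")
})

test_that("missing-data convention separates missing from unexpressed", {
  ids <- c("f1", "f2", "f3")
  mus <- named_matrix(c(0L, 0L, 3L), ids, "s1")
  cast <- named_matrix(c(0L, 0L, 0L), ids, "s1")
  total <- named_matrix(c(7L, 0L, 7L), ids, "s1")
  m <- apply_missing_convention(toy_matrix(mus, cast, total = total))
  expect_true(m$missing_mask["f1", "s1"])   # expressed, no allelic reads
  expect_false(m$missing_mask["f2", "s1"])  # not expressed: numeric 0
  expect_false(m$missing_mask["f3", "s1"])  # has allelic reads
  # masked entries are NA downstream, not zeros
  m <- normalize_library(m)
  expect_true(is.na(m$norm_mus["f1", "s1"]))
  expect_equal(m$norm_mus["f2", "s1"], 0)
})

test_that("masking changes downstream statistics that would read zeros", {
  # a cell where half the X genes are expressed-but-uninformative: if
  # the mask leaked zeros into the normalized layer, the per-cell X
  # median would be dragged down
  ids <- c(sprintf("a%d", 1:4), sprintf("x%d", 1:4))
  x_ids <- sprintf("x%d", 1:4)
  mus <- named_matrix(c(10L, 10L, 10L, 10L, 10L, 10L, 0L, 0L), ids, "c1")
  cast <- named_matrix(rep(0L, 8), ids, "c1")
  total <- named_matrix(c(rep(10L, 6), 40L, 40L), ids, "c1")
  m <- apply_missing_convention(toy_matrix(mus, cast, total = total,
                                           x_ids = x_ids))
  m <- normalize_library(m)
  r <- x_autosome_ratio_per_cell(m, "mus")
  expect_equal(unname(r["c1"]), 1)  # masked x3/x4 must not count as 0
})

test_that("coverage and SNP filters commute", {
  set.seed(42)
  ids <- sprintf("f%02d", 1:40)
  mus <- named_matrix(rpois(80, 6), ids, c("s1", "s2"))
  cast <- named_matrix(rpois(80, 6), ids, c("s1", "s2"))
  groups <- c(s1 = "g1", s2 = "g2")
  m <- toy_matrix(mus, cast, groups = groups,
                  snp_count = sample(2:8, 40, replace = TRUE))
  a <- filter_min_snps(filter_min_allelic_total(m, 10), 4)
  b <- filter_min_allelic_total(filter_min_snps(m, 4), 10)
  expect_identical(a$features, b$features)
  expect_identical(a$retained[a$features, ], b$retained[b$features, ])
})

test_that("pseudotime tables round-trip and are validated", {
  pt <- data.frame(sample_id = c("c1", "c2"), pseudotime = c(0, 2.5),
                   group_label = c("C0", "C1"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pseudotime(pt, path)
  expect_equal(read_pseudotime(path), pt)
  bad <- pt; bad$pseudotime[1] <- -1
  write_pseudotime(bad, path)
  expect_error(read_pseudotime(path), "finite")
})
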