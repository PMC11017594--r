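paired_design <- function(n_subj, groups = rep(0:1, length.out = n_subj)) {
  study_design(data.frame(
    sample_id = c(sprintf("h%d_d0", 1:n_subj), sprintf("h%d_d10", 1:n_subj)),
    subject_id = rep(sprintf("h%d", 1:n_subj), 2),
    group = rep(groups, 2),
    day = rep(c(0L, 10L), each = n_subj)))
}

test_that("median normalisation rescales every feature median to 1", {
  m <- cbind(a = c(2, 4, 6), b = c(10, 20, 30), z = c(0, 0, 0))
  rownames(m) <- c("s1", "s2", "s3")
  out <- suppressMessages(median_normalize(feature_table(m, "intensities")))
  expect_equal(unname(out$values[, "a"]), c(0.5, 1, 1.5))
  expect_equal(apply(out$values[, c("a", "b")], 2, median), c(a = 1, b = 1))
  # zero-median feature untouched and flagged
  expect_equal(unname(out$values[, "z"]), c(0, 0, 0))
  expect_identical(attr(out, "unscaled_features"), "z")
  # idempotence
  out2 <- median_normalize(ft_plain <- feature_table(out$values, "intensities"))
  expect_equal(out2$values, out$values, tolerance = 1e-12)
  expect_error(median_normalize(ft(cbind(a = c(-1, 2)))),
               class = "value_domain_error")
})

test_that("feature removal drops exactly one column and rejects unknown ids", {
  tab <- ft(matrix(1:12, 3, 4))
  out <- remove_feature(tab, "f002")
  expect_identical(feature_ids(out), c("f001", "f003", "f004"))
  expect_identical(sample_ids(out), sample_ids(tab))
  expect_error(remove_feature(out, "f002"), class = "unknown_feature_error")
  err <- tryCatch(remove_feature(tab, "ghost"), error = identity)
  expect_s3_class(err, "unknown_feature_error")
  expect_match(conditionMessage(err), "ghost")
})

test_that("genus aggregation sums member ASVs and conserves sample totals", {
  counts <- matrix(c(5, 1, 0,
                     2, 3, 7,
                     0, 4, 1), nrow = 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"),
                                   c("asv1", "asv2", "asv3")))
  tax <- c(asv1 = "Sarcina", asv2 = "Fibrobacter", asv3 = "Sarcina")
  out <- aggregate_to_genus(feature_table(counts, "counts"), tax)
  expect_identical(sort(feature_ids(out)), c("Fibrobacter", "Sarcina"))
  expect_equal(rowSums(out$values), rowSums(counts))
  expect_equal(unname(out$values[, "Sarcina"]), c(5, 9, 1))
  # all ASVs one genus -> single column of row totals
  one <- aggregate_to_genus(feature_table(counts, "counts"),
                            c(asv1 = "g", asv2 = "g", asv3 = "g"))
  expect_identical(ncol(one$values), 1L)
  expect_equal(unname(one$values[, 1]), unname(rowSums(counts)))
  expect_error(aggregate_to_genus(feature_table(counts, "counts"),
                                  c(asv1 = "g", asv2 = "g")),
               class = "missing_taxonomy_error")
})

test_that("prevalence filter keeps features observed in >= min_samples samples", {
  set.seed(1)
  m <- matrix(0, 36, 3, dimnames = list(sprintf("s%02d", 1:36),
                                        c("in5", "in6", "in36")))
  m[1:5, "in5"] <- 1
  m[1:6, "in6"] <- 1
  m[, "in36"] <- 1
  out <- prevalence_filter(feature_table(m, "counts"), min_samples = 6)
  expect_identical(feature_ids(out), c("in6", "in36")) # 5-sample feature removed
  out1 <- prevalence_filter(feature_table(m, "counts"), min_samples = 1)
  expect_identical(feature_ids(out1), c("in5", "in6", "in36"))
  expect_error(prevalence_filter(feature_table(m, "counts"), min_samples = 37),
               class = "config_error")
})

test_that("relative abundance normalises rows to 1 and flags empty samples", {
  m <- rbind(s1 = c(2, 3, 5), s2 = c(1, 1, 2))
  colnames(m) <- c("a", "b", "c")
  out <- relative_abundance(feature_table(m, "counts"))
  expect_equal(unname(out$values["s1", ]), c(0.2, 0.3, 0.5))
  expect_equal(rowSums(out$values), c(s1 = 1, s2 = 1))
  expect_identical(out$view_kind, "relative_abundance")
  one <- relative_abundance(ft(matrix(c(4, 7), 2, 1), samples = c("s1", "s2")))
  expect_true(all(one$values == 1))
  m0 <- rbind(s1 = c(0, 0), s2 = c(1, 1))
  colnames(m0) <- c("a", "b")
  err <- tryCatch(relative_abundance(feature_table(m0, "counts")), error = identity)
  expect_s3_class(err, "zero_sample_error")
  expect_match(conditionMessage(err), "s1")
})

test_that("paired differencing yields one day10-minus-day0 row per subject", {
  des <- paired_design(4)
  m <- matrix(rnorm(8 * 3), 8, 3,
              dimnames = list(des$sample_id, c("a", "b", "c")))
  m["h1_d0", ] <- c(3, 1, 0)
  m["h1_d10", ] <- c(5, 1, -2)
  out <- paired_difference(feature_table(m), des)
  expect_identical(sample_ids(out), sprintf("h%d", 1:4))
  expect_equal(unname(out$values["h1", ]), c(2, 0, -2))
  expect_identical(out$view_kind, "differences")

  # identical day-0/day-10 rows give an all-zero difference
  m2 <- m
  m2[5:8, ] <- m2[1:4, ]
  expect_true(all(paired_difference(feature_table(m2), des)$values == 0))

  # a subject missing one day is dropped with a message
  m3 <- m[-1, , drop = FALSE] # h1 loses day 0
  expect_message(out3 <- paired_difference(feature_table(m3), des), "h1")
  expect_identical(sample_ids(out3), sprintf("h%d", 2:4))

  expect_error(paired_difference(feature_table(m[1:4, ], ), des),
               class = "pairing_error")
})

test_that("log-CPM has its closed-form values and is depth-invariant", {
  m <- rbind(s1 = c(0, 10), s2 = c(5, 5))
  colnames(m) <- c("a", "b")
  out <- log_cpm(feature_table(m, "counts"))
  expect_identical(out$values["s1", "a"], 0) # zero count -> exactly 0
  expect_equal(out$values["s1", "b"], log2(1e6 + 1)) # count == total
  doubled <- log_cpm(feature_table(2 * m, "counts"))
  expect_equal(doubled$values, out$values, tolerance = 1e-12)
  m0 <- rbind(s1 = c(a = 0, b = 0), s2 = c(a = 1, b = 2))
  expect_error(log_cpm(feature_table(m0, "counts")), class = "zero_sample_error")
})

test_that("column standardization uses the population sd and is idempotent", {
  tab <- ft(cbind(a = c(1, 2, 3), b = c(7, 7, 7)))
  out <- standardize_columns(tab)
  expect_equal(unname(out$values[, "a"]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(unname(out$values[, "b"]), c(0, 0, 0)) # constant -> zeros
  expect_identical(attr(out, "constant_features"), "b")
  again <- standardize_columns(out)
  expect_equal(again$values, out$values, tolerance = 1e-12)
})

test_that("preprocessing invariants hold on random tables", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    p <- sample(5:30, 1)
    counts <- matrix(rpois(n * p, lambda = 2), n, p,
                     dimnames = list(sprintf("s%02d", 1:n), sprintf("f%03d", 1:p)))
    counts[1, 1] <- counts[1, 1] + 1 # ensure no zero-total sample
    tab <- feature_table(counts, "counts")

    genus <- setNames(sample(letters[1:4], p, replace = TRUE), colnames(counts))
    agg <- aggregate_to_genus(tab, genus)
    expect_equal(rowSums(agg$values), rowSums(counts))

    k <- sample(seq_len(n), 1)
    kept <- prevalence_filter(tab, min_samples = k)
    if (n_features(kept) > 0)
      expect_true(all(colSums(kept$values > 0) >= k))

    med <- suppressMessages(median_normalize(tab))
    nz <- apply(counts, 2, median) > 0
    if (any(nz))
      expect_equal(unname(apply(med$values[, nz, drop = FALSE], 2, median)),
                   rep(1, sum(nz)))
  }
})
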