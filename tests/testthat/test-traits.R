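test_that("remobilization index matches hand arithmetic in both variants", {
  # corrected form: 100 * (16.7*100 - 7.7*120) / (16.7*100)
  expect_equal(tnc_remobilized(16.7, 100, 7.7, 120), 100 * 746 / 1670,
               tolerance = 1e-12)
  # as-printed form keeps the heading stem weight in both terms
  expect_equal(tnc_remobilized(16.7, 100, 7.7, 120, as_printed = TRUE),
               100 * 900 / 1670, tolerance = 1e-12)
})

test_that("remobilization spans the natural boundary cases", {
  expect_equal(tnc_remobilized(12, 80, 0, 90), 100)
  expect_equal(tnc_remobilized(10, 50, 10, 50), 0)
  # the two variants coincide exactly when stem weight is unchanged
  expect_equal(tnc_remobilized(14, 70, 6, 70),
               tnc_remobilized(14, 70, 6, 70, as_printed = TRUE))
  # net re-accumulation gives a negative index
  expect_lt(tnc_remobilized(10, 50, 12, 60), 0)
  expect_error(tnc_remobilized(0, 50, 1, 50), "positive")
})

test_that("tnc is the commutative sum of starch and sucrose", {
  expect_equal(tnc(0, 0), 0)
  expect_equal(tnc(10, 6.7), 16.7)
  expect_equal(tnc(3.2, 8.1), tnc(8.1, 3.2))
  expect_error(tnc(-1, 2), ">= 0")
})

test_that("maturity groups split at 120 and 130 days", {
  expect_equal(as.character(maturity_group(c(119, 120, 129, 130))),
               c("Early", "Medium", "Medium", "Late"))
  expect_error(maturity_group(0), "positive")
})

test_that("maturity grouping reproduces a 10/10/13 panel split", {
  durations <- c(seq(104, 119, length.out = 10),
                 seq(120, 129, length.out = 10),
                 seq(130, 141, length.out = 13))
  counts <- table(maturity_group(durations))
  expect_equal(unname(c(counts)), c(10, 10, 13))
})

test_that("correlation matrix matches cor.test and annotates stars", {
  tb <- data.frame(a = c(1, 2, 3, 4, 7), b = c(2, 1, 4, 6, 9))
  cm <- correlation_matrix(tb)
  ct <- cor.test(tb$a, tb$b)
  off <- cm[cm$trait_1 == "a" & cm$trait_2 == "b", ]
  expect_equal(off$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(off$p_value, ct$p.value, tolerance = 1e-12)
  diag_row <- cm[cm$trait_1 == "a" & cm$trait_2 == "a", ]
  expect_equal(diag_row$r, 1)
  collin <- correlation_matrix(data.frame(x = 1:3, y = c(2, 4, 6)))
  expect_equal(collin$r[collin$trait_1 == "x" & collin$trait_2 == "y"], 1)
  expect_equal(collin$stars[collin$trait_1 == "x" & collin$trait_2 == "y"],
               "***")
})

test_that("constant traits and missing values are handled pairwise", {
  tb <- data.frame(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5),
                   c = c(1, NA, 3, 4))
  cm <- correlation_matrix(tb)
  expect_true(is.na(cm$r[cm$trait_1 == "a" & cm$trait_2 == "b"]))
  ac <- cm[cm$trait_1 == "a" & cm$trait_2 == "c", ]
  expect_equal(ac$n, 3)
  expect_false(is.na(ac$r))
})

test_that("contrast selection covers well-separated clusters like the
           exhaustive maximin oracle", {
  set.seed(91)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  tb <- data.frame(
    line = sprintf("g%02d", 1:12),
    t1 = rep(centers[, 1], each = 3) + rnorm(12, 0, 0.3),
    t2 = rep(centers[, 2], each = 3) + rnorm(12, 0, 0.3)
  )
  sel <- select_contrasting(tb, 4, n_clusters = 4)
  got_clusters <- sel$diagnostics$cluster_complete[sel$diagnostics$selected]
  expect_setequal(got_clusters, 1:4)
  # exhaustive maximin over all 4-subsets in the PC plane
  pcs <- as.matrix(sel$diagnostics[c("pc1", "pc2")])
  D <- as.matrix(dist(pcs))
  combos <- utils::combn(12, 4)
  minds <- apply(combos, 2, function(s) min(D[s, s][upper.tri(D[s, s])]))
  best <- max(minds)
  ours <- min(D[sel$diagnostics$selected, sel$diagnostics$selected][
    upper.tri(matrix(0, 4, 4))])
  expect_gt(ours, 0.9 * best)
})

test_that("selecting all lines returns all, duplicates are avoided", {
  tb <- data.frame(line = letters[1:5], t1 = c(1, 1, 5, 9, 9),
                   t2 = c(2, 2, 5, 8, 8))
  all_sel <- select_contrasting(tb, 5)
  expect_setequal(all_sel$selected, letters[1:5])
  three <- select_contrasting(tb, 3, n_clusters = 3)
  # the duplicated pairs (a,b) and (d,e) never both selected
  expect_false(all(c("a", "b") %in% three$selected))
  expect_false(all(c("d", "e") %in% three$selected))
  expect_error(select_contrasting(tb, 3, n_clusters = 9), "n_clusters")
})

test_that("PC variance explained is non-increasing and selection deterministic", {
  set.seed(92)
  tb <- data.frame(line = sprintf("l%d", 1:10),
                   a = rnorm(10), b = rnorm(10), c = rnorm(10))
  s1 <- select_contrasting(tb, 4)
  s2 <- select_contrasting(tb, 4)
  expect_identical(s1$selected, s2$selected)
  expect_gte(s1$variance_explained[1], s1$variance_explained[2])
})
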