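test_that("the 1-D toy example selects the maximin sequence", {
  m <- matrix(c(0, 1, 2, 10), ncol = 1)
  ks <- kennard_stone(m, 3)
  # seed pair {0, 10} (rows 1, 4), then 2 (row 3) by maximin
  expect_setequal(ks$selected[1:2], c(1, 4))
  expect_equal(ks$selected[3], 3)
  expect_equal(ks$remainder, 2)
})

test_that("selection and remainder partition the sample set", {
  set.seed(51)
  m <- matrix(rnorm(40), 10)
  ks <- kennard_stone(m, 9)
  expect_setequal(c(ks$selected, ks$remainder), 1:10)
  expect_length(ks$selected, 9)
})

test_that("kennard-stone matches an exhaustive greedy oracle on small sets", {
  greedy_oracle <- function(X, k) {
    D <- as.matrix(dist(X))
    n <- nrow(X)
    mx <- which(D == max(D), arr.ind = TRUE)
    mx <- mx[mx[, 1] < mx[, 2], , drop = FALSE]
    mx <- mx[order(mx[, 1], mx[, 2]), , drop = FALSE]
    sel <- as.integer(mx[1, ])
    while (length(sel) < k) {
      cand <- setdiff(seq_len(n), sel)
      score <- vapply(cand, function(i) min(D[i, sel]), numeric(1))
      sel <- c(sel, cand[which.max(score)]) # which.max takes lowest index
    }
    sel
  }
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(12 * 3), 12)
    for (k in c(3, 6, 11)) {
      expect_equal(kennard_stone(X, k)$selected, greedy_oracle(X, k),
                   info = sprintf("seed %d k %d", s, k))
    }
  }
})

test_that("selection follows samples under reordering (up to the tie rule)", {
  set.seed(52)
  X <- matrix(rnorm(16), 8)
  rownames(X) <- sprintf("s%d", 1:8)
  perm <- sample(8)
  ks1 <- kennard_stone(X, 4)
  ks2 <- kennard_stone(X[perm, ], 4)
  expect_setequal(ks1$selected, ks2$selected)
})

test_that("duplicate spectra resolve deterministically by lowest index", {
  X <- matrix(c(0, 0, 5, 5, 9), ncol = 1)
  ks <- kennard_stone(X, 3)
  expect_equal(ks$selected[1:2], c(1, 5))
  expect_equal(ks$selected[3], 3)
})

test_that("bad selection sizes are rejected", {
  X <- matrix(rnorm(10), 5)
  expect_error(kennard_stone(X, 1), "n_select")
  expect_error(kennard_stone(X, 5), "n_select")
})
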