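#' Proportion of stem TNC remobilized between heading and maturity
#'
#' Remobilization index from percent TNC by dry weight (`tnc_hd`, `tnc_mt`)
#' and stem dry weights (`stm_hd`, `stm_mt`) at heading and maturity:
#' \deqn{TNC_{RMB} = 100 \times \frac{TNC_{hd} STM_{hd} - TNC_{mt} STM_{mt}}
#'   {TNC_{hd} STM_{hd}}}
#' i.e. the percentage of the heading-stage TNC mass no longer present at
#' maturity. A widely circulated printed form of this index uses the heading
#' stem weight in both numerator terms; `as_printed = TRUE` reproduces that
#' variant exactly. The corrected (maturity stem weight) form is the
#' default. The index is a net difference: it can be negative when TNC is
#' re-accumulated at the end of grain filling.
#'
#' @param tnc_hd,tnc_mt Percent TNC by dry weight at heading / maturity
#'   (`tnc_hd > 0`).
#' @param stm_hd,stm_mt Stem dry weight at heading / maturity
#'   (`stm_hd > 0`).
#' @param as_printed Use the heading stem weight in both numerator terms.
#' @return Percent remobilized (vectorized).
#' @examples
#' tnc_remobilized(16.7, 100, 7.7, 120) # corrected form
#' tnc_remobilized(16.7, 100, 7.7, 120, as_printed = TRUE)
#' @export
tnc_remobilized <- function(tnc_hd, stm_hd, tnc_mt, stm_mt,
                            as_printed = FALSE) {
  assert_that(all(tnc_hd > 0) && all(stm_hd > 0),
              "heading TNC mass must be positive")
  mt_mass <- if (as_printed) tnc_mt * stm_hd else tnc_mt * stm_mt
  100 * (tnc_hd * stm_hd - mt_mass) / (tnc_hd * stm_hd)
}

#' Assign maturity groups from growth duration
#'
#' Early: under 120 days; Medium: 120-129 days; Late: 130 days or more.
#'
#' @param growth_duration_days Positive numeric vector (days from sowing to
#'   maturity).
#' @return Factor with levels Early, Medium, Late.
#' @examples
#' maturity_group(c(119, 120, 129, 130))
#' @export
maturity_group <- function(growth_duration_days) {
  assert_that(all(growth_duration_days > 0, na.rm = TRUE),
              "growth duration must be positive")
  cut(growth_duration_days, breaks = c(0, 120, 130, Inf), right = FALSE,
      labels = c("Early", "Medium", "Late"))
}

#' Pairwise trait correlation matrix with significance stars
#'
#' Pearson correlations over all numeric trait columns with two-sided
#' p-values and the conventional star annotation (* P<0.05, ** P<0.01,
#' *** P<0.001). Missing values are handled pairwise-complete; pairs with a
#' constant column or fewer than 3 complete rows are reported missing.
#'
#' @param table Data frame of line-level trait means (one row per line);
#'   non-numeric columns are ignored.
#' @return Tibble with `trait_1`, `trait_2`, `r`, `p_value`, `stars`, `n`,
#'   one row per unordered pair plus the diagonal.
#' @examples
#' correlation_matrix(data.frame(a = 1:5, b = c(2, 4, 6, 8, 10)))
#' @export
correlation_matrix <- function(table) {
  assert_that(is.data.frame(table), "`table` must be a data frame")
  num <- dplyr::select(as_tibble(table), dplyr::where(is.numeric))
  assert_that(ncol(num) >= 2, "need at least two numeric trait columns")
  traits <- names(num)
  combos <- expand.grid(i = seq_along(traits), j = seq_along(traits))
  combos <- combos[combos$i <= combos$j, ]
  purrr::map_dfr(seq_len(nrow(combos)), function(k) {
    i <- combos$i[k]; j <- combos$j[k]
    x <- num[[i]]; y <- num[[j]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      r <- NA_real_; p <- NA_real_
    } else if (i == j) {
      r <- 1; p <- 0
    } else {
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    tibble(
      trait_1 = traits[i], trait_2 = traits[j], r = r, p_value = p,
      stars = significance_stars(p), n = n
    )
  })
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Select multivariate contrasting lines by PCA and dual-linkage clustering
#'
#' Standardizes the trait columns, computes a correlation-based PCA, cuts
#' complete- and average-linkage Euclidean dendrograms at `n_clusters`, and
#' returns `n_select` lines that (a) spread over distinct joint cluster
#' memberships (the pair of labels from both trees) and (b) maximize pairwise
#' spread in the PC1-PC2 plane by a greedy maximin rule seeded with the most
#' distant pair. Fully deterministic; ties break toward the lower row index.
#'
#' @param table Data frame with a `line` id column (or rownames) and numeric
#'   trait columns.
#' @param n_select Number of lines to select.
#' @param n_clusters Number of clusters to cut each dendrogram into
#'   (default `n_select`).
#' @return List with `selected` (line ids) and `diagnostics`: a tibble of PC
#'   coordinates and both cluster labels per line, plus attribute-free
#'   `variance_explained` for PC1-PC2.
#' @examples
#' tb <- data.frame(line = letters[1:6], t1 = c(0, 0, 5, 5, 10, 10),
#'                  t2 = c(0, 1, 5, 6, 10, 11))
#' select_contrasting(tb, 3)$selected
#' @export
select_contrasting <- function(table, n_select, n_clusters = n_select) {
  assert_that(is.data.frame(table), "`table` must be a data frame")
  tb <- as_tibble(table)
  ids <- if ("line" %in% names(tb)) as.character(tb$line) else
    (rownames(table) %||% as.character(seq_len(nrow(tb))))
  num <- dplyr::select(tb, dplyr::where(is.numeric))
  assert_that(ncol(num) >= 2, "need at least two numeric traits")
  n <- nrow(num)
  assert_that(is_count(n_select, 1L) && n_select <= n,
              "`n_select` must be between 1 and the number of lines")
  assert_that(n_clusters <= n, "`n_clusters` cannot exceed the number of lines")
  X <- scale(as.matrix(num))
  X[is.na(X)] <- 0 # constant traits carry no contrast information
  pca <- prcomp(X, center = FALSE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  pcs <- pca$x[, seq_len(min(2, ncol(pca$x))), drop = FALSE]
  if (ncol(pcs) == 1) pcs <- cbind(pcs, 0)
  d <- dist(X)
  cl_complete <- cutree(hclust(d, method = "complete"), k = n_clusters)
  cl_average <- cutree(hclust(d, method = "average"), k = n_clusters)
  joint <- paste(cl_complete, cl_average, sep = "/")

  if (n_select == n) {
    sel <- seq_len(n)
  } else {
    D <- as.matrix(dist(pcs))
    sel <- integer(0)
    # seed with the most distant pair in the PC plane
    mx <- which(D == max(D), arr.ind = TRUE)
    mx <- mx[order(mx[, 1], mx[, 2]), , drop = FALSE]
    sel <- as.integer(mx[1, 1:2])
    while (length(sel) < n_select) {
      cand <- setdiff(seq_len(n), sel)
      # prefer candidates from joint clusters not yet covered
      fresh <- cand[!(joint[cand] %in% joint[sel])]
      pool <- if (length(fresh) > 0) fresh else cand
      score <- vapply(pool, function(i) min(D[i, sel]), numeric(1))
      sel <- c(sel, pool[which.max(score)])
    }
    sel <- sort(sel)
  }
  diagnostics <- tibble(
    line = ids,
    pc1 = pcs[, 1], pc2 = pcs[, 2],
    cluster_complete = cl_complete, cluster_average = cl_average,
    joint_cluster = joint,
    selected = seq_len(n) %in% sel
  )
  list(
    selected = ids[sel],
    diagnostics = diagnostics,
    variance_explained = ve[seq_len(min(2, length(ve)))]
  )
}

#' PCA biplot of a contrast selection
#'
#' @param selection Result of [select_contrasting()].
#' @return A ggplot of the PC1-PC2 plane with selected lines highlighted.
#' @export
plot_selection <- function(selection) {
  df <- selection$diagnostics
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected,
                                     shape = factor(.data$cluster_complete)),
                        size = 2) +
    ggplot2::geom_text(
      data = df[df$selected, ],
      ggplot2::aes(label = .data$line), vjust = -0.8, size = 3
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * selection$variance_explained[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * selection$variance_explained[2]),
      colour = "selected", shape = "cluster"
    ) +
    ggplot2::theme_minimal()
}
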