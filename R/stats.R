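#' Two-group t test comparison
#'
#' Two-sided t test between two groups of masked voxel/pixel values. Unpaired
#' comparisons use the Welch unequal-variance statistic by default; set
#' `var_equal = TRUE` for the pooled-variance form. Paired comparisons
#' require equal group sizes.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param paired paired test (e.g. before/after ash measurements).
#' @param var_equal pooled-variance unpaired test instead of Welch.
#' @param names character 2-vector of group names for the report.
#' @param alpha significance level (default 0.05).
#' @return one-row data.frame: `group_a`, `group_b`, `test`, `statistic`,
#'   `p`, `p_adj` (`NA`, filled by [bonferroni()] workflows), `significant`.
#' @export
t_test <- function(group_a, group_b, paired = FALSE, var_equal = FALSE,
                   names = c("a", "b"), alpha = 0.05) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("need >= 2 observations per group")
  if (paired && length(group_a) != length(group_b))
    stop("paired test requires equal group sizes")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0)
    stop("degenerate variance in both groups")
  tt <- stats::t.test(group_a, group_b, paired = paired,
                      var.equal = var_equal)
  lbl <- if (paired) "paired t"
         else if (var_equal) "unpaired t (pooled)" else "unpaired t (Welch)"
  data.frame(group_a = names[1], group_b = names[2], test = lbl,
             statistic = unname(tt$statistic), p = tt$p.value,
             p_adj = NA_real_, significant = tt$p.value < alpha)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` for an explicit family size `m`, which must be at
#' least the number of tests supplied.
#'
#' @param p numeric vector of p values.
#' @param m family size (default: number of p values).
#' @return adjusted p values, capped at 1.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) stop("m must be >= number of tests")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Median-based ANOVA (Mood's median test) across ROIs
#'
#' Counts, per group, values above vs at-or-below the grand median and tests
#' the resulting 2 x k contingency table: chi-squared without continuity
#' correction by default, or Fisher's exact test with `exact = TRUE`.
#' `method = "kruskal"` substitutes the Kruskal-Wallis rank test as an
#' alternative reading of a median-based k-group comparison.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param method `"mood"` (default) or `"kruskal"`.
#' @param exact use Fisher's exact test on the median table (Mood only).
#' @param alpha significance level.
#' @return one-row data.frame: `groups`, `test`, `statistic`, `p`, `p_adj`,
#'   `significant`.
#' @export
median_anova <- function(groups, method = c("mood", "kruskal"),
                         exact = FALSE, alpha = 0.05) {
  method <- match.arg(method)
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs n >= 2")
  gname <- paste(names(groups) %||% seq_along(groups), collapse = " vs ")
  if (method == "kruskal") {
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    kt <- stats::kruskal.test(x, g)
    return(data.frame(groups = gname, test = "Kruskal-Wallis",
                      statistic = unname(kt$statistic), p = kt$p.value,
                      p_adj = NA_real_, significant = kt$p.value < alpha))
  }
  all_vals <- unlist(groups, use.names = FALSE)
  med <- stats::median(all_vals)
  above <- vapply(groups, function(g) sum(g > med), integer(1))
  below <- vapply(groups, function(g) sum(g <= med), integer(1))
  if (sum(above) == 0L)
    stop("all values equal the grand median; median test undefined")
  tab <- rbind(above = above, below = below)
  if (exact) {
    ft <- stats::fisher.test(tab)
    data.frame(groups = gname, test = "Mood median (Fisher exact)",
               statistic = NA_real_, p = ft$p.value, p_adj = NA_real_,
               significant = ft$p.value < alpha)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(groups = gname, test = "Mood median (chi-squared)",
               statistic = unname(ct$statistic), p = ct$p.value,
               p_adj = NA_real_, significant = ct$p.value < alpha)
  }
}

#' Assemble the per-tissue summary report
#'
#' Merges segmented mineral statistics with masked elemental-ratio
#' statistics, keyed by tissue name, and flags tissue pairs whose comparison
#' was not significant. Tissues present in one input but not another are
#' listed in the `"missing"` attribute rather than failing.
#'
#' @param segments data.frame with a `tissue` column plus [segment_stats()]
#'   columns (`mean_md`, `sd_md`, `md_min`, `md_max`, `mean_hu`, `n_voxels`).
#' @param ratio_stats optional data.frame with `tissue`, `element_pair`
#'   (e.g. `"Ca/P"`), `mean`, `sd`.
#' @param comparisons optional data.frame of test results (`group_a`,
#'   `group_b`, `p`, and optionally `p_adj`).
#' @param alpha significance level for the indistinguishable-pair flag.
#' @return data.frame of class `tissue_report`, one row per tissue; attrs
#'   `indistinguishable_pairs` (data.frame) and `missing` (character).
#' @export
build_report <- function(segments, ratio_stats = NULL, comparisons = NULL,
                         alpha = 0.05) {
  seg <- as.data.frame(segments)
  if (!"tissue" %in% names(seg)) stop("segments need a `tissue` column")
  rep_tab <- seg
  missing <- character(0)
  if (!is.null(ratio_stats)) {
    rs <- as.data.frame(ratio_stats)
    for (pair in unique(rs$element_pair)) {
      sub <- rs[rs$element_pair == pair, ]
      col <- gsub("/", "_", tolower(pair))
      idx <- match(rep_tab$tissue, sub$tissue)
      rep_tab[[paste0(col, "_mean")]] <- sub$mean[idx]
      rep_tab[[paste0(col, "_sd")]] <- sub$sd[idx]
      missing <- union(missing, setdiff(sub$tissue, rep_tab$tissue))
    }
    missing <- union(missing, setdiff(rep_tab$tissue, rs$tissue))
  }
  pairs <- NULL
  if (!is.null(comparisons)) {
    cmp <- as.data.frame(comparisons)
    pcol <- if ("p_adj" %in% names(cmp) && any(!is.na(cmp$p_adj)))
      ifelse(is.na(cmp$p_adj), cmp$p, cmp$p_adj) else cmp$p
    ns <- cmp[pcol >= alpha, c("group_a", "group_b"), drop = FALSE]
    ns$p <- pcol[pcol >= alpha]
    pairs <- ns
  }
  structure(rep_tab, indistinguishable_pairs = pairs, missing = missing,
            class = c("tissue_report", "data.frame"))
}
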