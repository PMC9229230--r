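#' Pair estimates with reference measurements, excluding listed trees
#'
#' Inner join of a trait table and a ground-reference table on `tree_id`,
#' minus an explicit exclusion list (e.g. a single atypically large tree
#' removed so it does not dominate the correlation).
#'
#' @param traits data.frame with a `tree_id` column and estimate columns.
#' @param reference data.frame with a `tree_id` column and reference columns.
#' @param excluded_ids tree ids to drop (absent ids warn, not error).
#' @return the joined data.frame; attribute `"n"` holds the retained count.
#' @export
exclude_outliers <- function(traits, reference, excluded_ids = integer(0)) {
  missing_ids <- setdiff(excluded_ids, union(traits$tree_id, reference$tree_id))
  if (length(missing_ids)) {
    warning("excluded ids not present: ", paste(missing_ids, collapse = ", "))
  }
  joined <- merge(traits, reference, by = "tree_id",
                  suffixes = c("_est", "_ref"))
  joined <- joined[!(joined$tree_id %in% excluded_ids), , drop = FALSE]
  rownames(joined) <- NULL
  attr(joined, "n") <- nrow(joined)
  joined
}

#' Pearson correlation with significance stars and linear fit
#'
#' Pearson's r with a two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`, starred at the three conventional
#' levels (*** p < 0.001, ** p < 0.01, * p < 0.05; boundary values fall in
#' the less significant class), plus the least-squares slope and intercept
#' of `y ~ x` and `r_squared = r^2`.
#'
#' @param x,y numeric vectors of equal length, n >= 3, nonzero variance.
#' @param label pair label carried into the result.
#' @return one-row data.frame with columns `pair`, `n`, `r`, `p_value`,
#'   `stars`, `slope`, `intercept`, `r_squared`.
#' @export
pearson_with_stars <- function(x, y, label = "") {
  n <- length(x)
  if (length(y) != n) stop_invalid("x and y must have equal length")
  if (n < 3) stop_invalid("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_invalid("zero variance: correlation undefined")
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  slope <- stats::cov(x, y) / stats::var(x)
  data.frame(pair = label, n = n, r = r, p_value = p, stars = star_code(p),
             slope = slope, intercept = mean(y) - slope * mean(x),
             r_squared = r^2, stringsAsFactors = FALSE)
}

star_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Correlation matrix over reference and estimate vectors
#'
#' Computes the full symmetric Pearson matrix over the reference vector and
#' every dataset vector (so estimate-versus-estimate entries, such as the
#' integrated versus single-angle comparison, are included), with matching
#' p-value and star matrices.
#'
#' @param datasets named list of numeric vectors; each must carry names
#'   (tree ids) aligned with `reference`.
#' @param reference named numeric vector of ground-reference values.
#' @param reference_label row/column label for the reference (default
#'   "ground").
#' @return list with matrices `r`, `p`, `stars` and a long-format
#'   data.frame `pairs` of the upper-triangle [pearson_with_stars()] rows.
#' @export
correlation_matrix <- function(datasets, reference, reference_label = "ground") {
  ids <- names(reference)
  if (is.null(ids)) stop_invalid("reference must be named by tree id")
  for (nm in names(datasets)) {
    v <- datasets[[nm]]
    if (is.null(names(v)) || !setequal(names(v), ids)) {
      stop_invalid("dataset '", nm, "' is not aligned with the reference ids")
    }
    datasets[[nm]] <- v[ids]
  }
  all_vec <- c(stats::setNames(list(reference), reference_label), datasets)
  labs <- names(all_vec)
  m <- length(labs)
  r <- p <- matrix(NA_real_, m, m, dimnames = list(labs, labs))
  pairs <- list()
  for (i in seq_len(m)) {
    r[i, i] <- 1; p[i, i] <- 0
    for (j in seq_len(m)[-seq_len(i)]) {
      res <- pearson_with_stars(all_vec[[i]], all_vec[[j]],
                                label = paste(labs[i], "vs", labs[j]))
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p_value
      pairs[[length(pairs) + 1L]] <- res
    }
  }
  stars <- matrix(star_code(p), m, m, dimnames = dimnames(p))
  diag(stars) <- ""
  list(r = r, p = p, stars = stars, pairs = do.call(rbind, pairs))
}

#' Five-number distribution summary
#'
#' Median and quartiles by the inclusive linear-interpolation rule
#' (`quantile(type = 7)`), plus min, max and n — the numbers a violin/box
#' plot displays.
#'
#' @param values numeric vector, n >= 1.
#' @param label summary label.
#' @return one-row data.frame `label, n, min, q1, median, q3, max`.
#' @export
summarize_distribution <- function(values, label = "") {
  if (!length(values)) stop_invalid("empty vector")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(label = label, n = length(values), min = min(values),
             q1 = q[1], median = q[2], q3 = q[3], max = max(values),
             stringsAsFactors = FALSE)
}

#' Write the statistical report
#'
#' Emits `correlations.csv` and `summaries.csv`, plus scatter plots with
#' fitted lines and violin/box plots when plotting succeeds (a plotting
#' failure degrades to CSV-only output with a warning).
#'
#' @param correlations data.frame of [pearson_with_stars()] rows.
#' @param summaries data.frame of [summarize_distribution()] rows.
#' @param paired optional data.frame with columns `pair`, `reference`,
#'   `estimate` for the scatter panels.
#' @param outdir output directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
build_report <- function(correlations, summaries, paired = NULL, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- file.path(outdir, "correlations.csv")
  utils::write.csv(correlations, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(outdir, "summaries.csv")
  utils::write.csv(summaries, f, row.names = FALSE)
  files <- c(files, f)
  plots <- tryCatch({
    written <- character(0)
    if (!is.null(paired) && nrow(paired)) {
      gp <- ggplot2::ggplot(paired, ggplot2::aes(x = reference, y = estimate)) +
        ggplot2::geom_point(size = 1) +
        ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                             linewidth = 0.5, color = "red") +
        ggplot2::facet_wrap(~pair, scales = "free") +
        ggplot2::labs(x = "ground reference", y = "estimate") +
        ggplot2::theme_bw(base_size = 9)
      f <- file.path(outdir, "scatter.png")
      ggplot2::ggsave(f, gp, width = 9, height = 7, dpi = 120)
      written <- c(written, f)
    }
    if (!is.null(paired) && nrow(paired)) {
      first_pair <- paired$pair == paired$pair[1]
      long <- rbind(
        data.frame(group = paired$pair, value = paired$estimate),
        data.frame(group = "ground reference",
                   value = paired$reference[first_pair]))
      gv <- ggplot2::ggplot(long, ggplot2::aes(x = group, y = value)) +
        ggplot2::geom_violin(fill = "grey85") +
        ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
        ggplot2::stat_summary(fun = stats::median, geom = "point",
                              color = "red", size = 1.5) +
        ggplot2::theme_bw(base_size = 9) +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1)) +
        ggplot2::labs(x = NULL, y = "value")
      f <- file.path(outdir, "violin.png")
      ggplot2::ggsave(f, gv, width = 9, height = 5, dpi = 120)
      written <- c(written, f)
    }
    written
  }, error = function(e) {
    warning("plotting failed (", conditionMessage(e), "); CSV output only")
    character(0)
  })
  invisible(c(files, plots))
}
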