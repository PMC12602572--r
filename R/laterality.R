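## Laterality index, hemispheric hypothesis tests with Bonferroni correction
## and signed effect sizes, demographic comparisons, two-cohort concordance.
##
## Sign convention throughout: positive = leftward lateralisation. For the
## paired test, Cohen's d is the standardized mean of L-R differences (d_z);
## for the one-sample LI test it is mean(LI)/sd(LI).

LI_GUARD <- 1e-12

#' Laterality index
#'
#' `LI = (L - R) / (L + R)`: 0 means no lateralisation, positive values
#' leftward and negative values rightward dominance. When `|L + R|` is
#' below 1e-12 the ratio is numerically meaningless and `NA` is returned
#' (this guards z-scored or near-cancelling inputs). Vectorised.
#'
#' @param L,R Metric values from the left and right member of a homologous
#'   region pair.
#' @return `(L - R) / (L + R)`, `NA` where the guard triggers; lies in
#'   `[-1, 1]` whenever `L, R >= 0`.
#' @examples
#' laterality_index(3, 1)   # 0.5
#' laterality_index(1, 3)   # -0.5
#' @export
laterality_index <- function(L, R) {
  den <- L + R
  out <- (L - R) / den
  out[abs(den) < LI_GUARD] <- NA_real_
  out[is.na(L) | is.na(R)] <- NA_real_
  out
}

#' Build a laterality table from node metrics
#'
#' Applies the laterality index per subject, homologous pair and metric.
#' Midline regions are skipped; missing metric values propagate; guard hits
#' (|L+R| ~ 0) become missing.
#'
#' @param metrics Long node-metrics table (`subject`, `roi`, `metric`,
#'   `value`), e.g. from [compute_node_metrics()].
#' @param atlas An `atlas_table`; every paired region must appear in
#'   `metrics`.
#' @return Long data frame of class `laterality_table`: `subject`,
#'   `pair_id`, `metric`, `L`, `R`, `li`.
#' @export
build_laterality_table <- function(metrics, atlas) {
  validate_atlas(atlas)
  pairs <- atlas_pairs(atlas)
  present <- unique(metrics$roi)
  missing_rois <- setdiff(c(pairs$name_left, pairs$name_right), present)
  if (length(missing_rois))
    stop("paired region(s) absent from the metrics table: ",
         paste(missing_rois, collapse = ", "))
  left <- metrics[metrics$roi %in% pairs$name_left, ]
  right <- metrics[metrics$roi %in% pairs$name_right, ]
  left$pair_id <- pairs$pair_id[match(left$roi, pairs$name_left)]
  right$pair_id <- pairs$pair_id[match(right$roi, pairs$name_right)]
  m <- merge(left[, c("subject", "pair_id", "metric", "value")],
             right[, c("subject", "pair_id", "metric", "value")],
             by = c("subject", "pair_id", "metric"),
             suffixes = c("_L", "_R"))
  out <- data.frame(subject = m$subject, pair_id = m$pair_id,
                    metric = m$metric, L = m$value_L, R = m$value_R,
                    li = laterality_index(m$value_L, m$value_R),
                    stringsAsFactors = FALSE)
  out <- out[order(out$metric, out$pair_id, out$subject), ]
  rownames(out) <- NULL
  class(out) <- c("laterality_table", "data.frame")
  out
}

## shared test-result assembly: given per-cell samples, run the t machinery
finish_test <- function(x, pair_id, metric, test, alpha, m) {
  n <- sum(!is.na(x))
  x <- x[!is.na(x)]
  if (n < 3) return(NULL)
  s <- stats::sd(x)
  mu <- mean(x)
  degenerate <- FALSE
  if (s == 0) {
    if (mu == 0) {
      t_stat <- NA_real_; p <- NA_real_; d <- 0; degenerate <- TRUE
    } else {
      t_stat <- sign(mu) * Inf; p <- 0; d <- sign(mu) * Inf
    }
  } else {
    tt <- stats::t.test(x, mu = 0)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
    d <- mu / s
  }
  p_bonf <- if (is.na(p)) NA_real_ else min(1, m * p)
  direction <- if (!is.na(p_bonf) && p_bonf < alpha && !is.na(d) && d != 0) {
    if (d > 0) "left" else "right"
  } else "none"
  data.frame(pair_id = pair_id, metric = metric, test = test,
             t = t_stat, df = n - 1, p = p, p_bonferroni = p_bonf,
             cohens_d = d, direction = direction, n_used = n,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Paired left-right t-tests per region pair and metric
#'
#' For every homologous pair and metric, tests the across-subject L-R
#' differences with a paired t-test; the signed effect size is
#' `d = mean(L - R) / sd(L - R)` (positive = leftward). p-values are
#' Bonferroni-adjusted by `m` (`p_bonf = min(1, m p)`), with `m` defaulting
#' to the total number of atlas regions (132 in the full configuration),
#' mirroring an alpha level divided by the region count.
#'
#' @param metrics Long node-metrics table.
#' @param atlas An `atlas_table`.
#' @param alpha Significance level (default 0.05).
#' @param m Bonferroni divisor; default `nrow(atlas)`.
#' @return Data frame of class `region_test_result` with one row per pair
#'   and metric: `pair_id`, `metric`, `test`, `t`, `df`, `p`,
#'   `p_bonferroni`, `cohens_d`, `direction`, `n_used`, `degenerate`, plus
#'   attributes `m` and `n_pairs`.
#' @export
paired_lr_tests <- function(metrics, atlas, alpha = 0.05, m = NULL) {
  li <- build_laterality_table(metrics, atlas)
  if (is.null(m)) m <- nrow(atlas)
  run_cell_tests(li, diff_col = "paired", alpha = alpha, m = m,
                 test_name = "paired_LR", atlas = atlas)
}

#' One-sample t-tests on the laterality index
#'
#' For every pair and metric, tests whether the subject-level LI values
#' deviate from 0; `d = mean(LI) / sd(LI)`, Bonferroni as in
#' [paired_lr_tests()].
#'
#' @param li A `laterality_table` (or the output of
#'   [build_laterality_table()]).
#' @param atlas An `atlas_table` (used for the default Bonferroni divisor).
#' @param alpha Significance level.
#' @param m Bonferroni divisor; default `nrow(atlas)`.
#' @return A `region_test_result` data frame (see [paired_lr_tests()]).
#' @export
li_one_sample_tests <- function(li, atlas, alpha = 0.05, m = NULL) {
  if (is.null(m)) m <- nrow(atlas)
  run_cell_tests(li, diff_col = "li", alpha = alpha, m = m,
                 test_name = "one_sample_LI", atlas = atlas)
}

run_cell_tests <- function(li, diff_col, alpha, m, test_name, atlas) {
  cells <- unique(li[, c("pair_id", "metric")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- li$pair_id == cells$pair_id[i] & li$metric == cells$metric[i]
    x <- if (diff_col == "paired") li$L[sel] - li$R[sel] else li$li[sel]
    finish_test(x, cells$pair_id[i], cells$metric[i], test_name, alpha, m)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    stop("no pair/metric cell has the minimum of 3 complete subjects")
  rownames(res) <- NULL
  attr(res, "m") <- m
  attr(res, "n_pairs") <- length(unique(res$pair_id))
  attr(res, "alpha") <- alpha
  class(res) <- c("region_test_result", "data.frame")
  res
}

#' Two-cohort direction concordance
#'
#' For each metric, intersects the significantly lateralised pairs of two
#' cohorts (Bonferroni-corrected p by default, uncorrected with
#' `corrected = FALSE`) and reports the fraction of the intersection with
#' the same lateralisation direction, plus the regions that agree in
#' direction across cohorts only via different metrics.
#'
#' @param res_a,res_b `region_test_result` tables from two cohorts sharing
#'   an atlas (the same pair_id space).
#' @param corrected Use Bonferroni-adjusted p-values (default `TRUE`).
#' @param alpha Significance level.
#' @return A list of class `concordance_report`: `per_metric` (data frame
#'   with `metric`, `n_sig_a`, `n_sig_b`, `n_intersection`, `n_same
#'   direction`, `agreement`), `overall_agreement`, `same_direction`
#'   (pair/metric listing) and `direction_only_regions` (pairs concordant in
#'   direction but via different metrics).
#' @export
concordance <- function(res_a, res_b, corrected = TRUE, alpha = 0.05) {
  if (!length(intersect(unique(res_a$pair_id), unique(res_b$pair_id))))
    stop("the two result sets share no region pairs; were they computed ",
         "on the same atlas?")
  pcol <- if (corrected) "p_bonferroni" else "p"
  sig <- function(res) {
    s <- res[!is.na(res[[pcol]]) & res[[pcol]] < alpha &
               res$direction != "none", c("pair_id", "metric", "direction")]
    rownames(s) <- NULL
    s
  }
  sa <- sig(res_a); sb <- sig(res_b)
  metrics <- sort(unique(c(sa$metric, sb$metric)))
  per_metric <- do.call(rbind, lapply(metrics, function(mt) {
    a <- sa[sa$metric == mt, ]; b <- sb[sb$metric == mt, ]
    inter <- merge(a, b, by = c("pair_id", "metric"),
                   suffixes = c("_a", "_b"))
    n_same <- sum(inter$direction_a == inter$direction_b)
    data.frame(metric = mt, n_sig_a = nrow(a), n_sig_b = nrow(b),
               n_intersection = nrow(inter), n_same_direction = n_same,
               agreement = if (nrow(inter)) n_same / nrow(inter)
                           else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_metric))
    per_metric <- data.frame(metric = character(0), n_sig_a = integer(0),
                             n_sig_b = integer(0), n_intersection = integer(0),
                             n_same_direction = integer(0),
                             agreement = numeric(0))
  inter_all <- merge(sa, sb, by = c("pair_id", "metric"),
                     suffixes = c("_a", "_b"))
  same <- inter_all[inter_all$direction_a == inter_all$direction_b, ]
  overall <- if (nrow(inter_all))
    nrow(same) / nrow(inter_all) else NA_real_

  # regions lateralised the same way in both cohorts but in no shared metric
  dir_a <- unique(sa[, c("pair_id", "direction")])
  dir_b <- unique(sb[, c("pair_id", "direction")])
  dir_common <- merge(dir_a, dir_b, by = c("pair_id", "direction"))
  shared_metric_pairs <- unique(inter_all$pair_id)
  dir_only <- sort(setdiff(unique(dir_common$pair_id), shared_metric_pairs))

  structure(list(per_metric = per_metric,
                 overall_agreement = overall,
                 same_direction = same[, c("pair_id", "metric",
                                           "direction_a")],
                 direction_only_regions = dir_only,
                 corrected = corrected, alpha = alpha),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> (",
      if (x$corrected) "Bonferroni-corrected" else "uncorrected",
      ", alpha = ", x$alpha, ")\n", sep = "")
  print(x$per_metric, row.names = FALSE)
  cat("overall direction agreement on the intersection: ",
      format(x$overall_agreement), "\n", sep = "")
  if (length(x$direction_only_regions))
    cat("pairs agreeing in direction via different metrics: ",
        paste(x$direction_only_regions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a concordance report as JSON
#'
#' @param report A `concordance_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "rows")
  invisible(path)
}

#' Compare cohort demographics
#'
#' Continuous variables (age, education, cognitive score) are compared with
#' pooled-variance two-sample t-tests and Cohen's d on the pooled standard
#' deviation; sex distributions with a Pearson chi-square test (no
#' continuity correction) and the phi coefficient.
#'
#' @param a,b Demographics data frames with columns `age`, `sex`,
#'   `education`, `mmse`.
#' @param welch Use Welch's t-test instead of pooled variance.
#' @return Data frame: `variable`, `statistic`, `df`, `p`, `effect_size`.
#' @export
compare_demographics <- function(a, b, welch = FALSE) {
  stopifnot(nrow(a) > 1, nrow(b) > 1)
  cont <- c("age", "education", "mmse")
  rows <- lapply(cont, function(v) {
    tt <- stats::t.test(a[[v]], b[[v]], var.equal = !welch)
    sp <- sqrt(((nrow(a) - 1) * stats::var(a[[v]]) +
                  (nrow(b) - 1) * stats::var(b[[v]])) /
                 (nrow(a) + nrow(b) - 2))
    d <- if (sp == 0) 0 else (mean(a[[v]]) - mean(b[[v]])) / sp
    data.frame(variable = v, statistic = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value, effect_size = d,
               stringsAsFactors = FALSE)
  })
  lev <- sort(union(unique(a$sex), unique(b$sex)))
  tab <- rbind(table(factor(a$sex, levels = lev)),
               table(factor(b$sex, levels = lev)))
  ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  phi <- sqrt(unname(ch$statistic) / sum(tab))
  rows$sex <- data.frame(variable = "sex", statistic = unname(ch$statistic),
                         df = unname(ch$parameter), p = ch$p.value,
                         effect_size = phi, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bar plot of mean laterality per region pair
#'
#' Cohort-mean LI per pair and metric, positive bars = leftward; the visual
#' summary used to compare lateralisation direction across cohorts.
#'
#' @param li A `laterality_table`, or a named list of them (one per cohort).
#' @param metrics Optional metric subset.
#' @return A ggplot object.
#' @export
plot_laterality <- function(li, metrics = NULL) {
  tabs <- if (inherits(li, "laterality_table")) list(cohort = li) else li
  dat <- do.call(rbind, lapply(names(tabs), function(nm) {
    x <- tabs[[nm]]
    if (!is.null(metrics)) x <- x[x$metric %in% metrics, ]
    agg <- stats::aggregate(li ~ pair_id + metric, data = x, FUN = mean,
                            na.rm = TRUE)
    agg$cohort <- nm
    agg
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$pair_id), y = .data$li,
                                    fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "region pair", y = "mean laterality index",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
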