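# Statistical layer: one-way ANOVA with Tukey HSD (Tukey-Kramer at unequal
# n) across the seven groups, two-way single-measure ICC reliability
# (absolute agreement for intra-operator, consistency for inter-operator)
# with 95% F-based confidence intervals, and deterministic report writers.
# All statistics are computed from their mean-square decompositions with
# base distribution functions (pf, ptukey, qf); normality/variance
# pre-checks (Shapiro-Wilk, Levene) are left to stock routines and are not
# part of this layer.

#' One-way analysis of variance
#'
#' `F = MS_between / MS_within` with p from the F distribution.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @return List with `F`, `df_between`, `df_within`, `p`, `ms_between`,
#'   `ms_within`, class `anova_result`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("at least 2 groups required", call. = FALSE)
  }
  n_i <- lengths(groups)
  if (any(n_i < 2)) stop("each group needs >= 2 values", call. = FALSE)
  all_x <- unlist(groups, use.names = FALSE)
  n <- length(all_x)
  k <- length(groups)
  grand <- mean(all_x)
  means <- vapply(groups, mean, 0)
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  df_b <- k - 1L
  df_w <- n - k
  if (ssw == 0 && ssb == 0) {
    stop("undefined statistic: zero between- and within-group variance",
         call. = FALSE)
  }
  msb <- ssb / df_b
  msw <- ssw / df_w
  F_stat <- msb / msw
  structure(list(F = F_stat, df_between = df_b, df_within = df_w,
                 p = stats::pf(F_stat, df_b, df_w, lower.tail = FALSE),
                 ms_between = msb, ms_within = msw),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Tukey HSD multiple comparisons
#'
#' All-pairs comparisons using the studentized range distribution with the
#' pooled within-group mean square; the Tukey-Kramer standard error
#' `sqrt(MSW/2 (1/n_i + 1/n_j))` keeps the test honest at unequal group
#' sizes.
#'
#' @param groups List of numeric vectors, optionally named.
#' @return Data frame with columns `group_i`, `group_j`, `mean_diff`
#'   (mean_j - mean_i, mm in this package's use) and `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  a <- one_way_anova(groups)
  k <- length(groups)
  nms <- names(groups) %||% as.character(seq_len(k))
  n_i <- lengths(groups)
  means <- vapply(groups, mean, 0)
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(a$ms_within / 2 * (1 / n_i[i] + 1 / n_i[j]))
      q <- abs(means[j] - means[i]) / se
      out[[length(out) + 1L]] <- data.frame(
        group_i = nms[i], group_j = nms[j],
        mean_diff = means[j] - means[i],
        p_adj = stats::ptukey(q, nmeans = k, df = a$df_within,
                              lower.tail = FALSE),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Two-way single-measurement intraclass correlation
#'
#' Computes the two-way mean-square decomposition of a complete
#' targets x raters matrix (rows MSR, columns MSC, error MSE) and returns
#' the single-measurement ICC in one of the study's two forms:
#' \itemize{
#'   \item `"consistency"` (two-way random, consistency):
#'     `(MSR - MSE) / (MSR + (k-1) MSE)`
#'   \item `"agreement"` (two-way mixed, absolute agreement):
#'     `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#' }
#' 95% confidence bounds follow the standard F-based derivations for these
#' forms (exact F interval for consistency; the Satterthwaite-style
#' approximation for absolute agreement). The mixed-vs-random model label
#' affects interpretation, not the point-estimate formula.
#'
#' @param mat Numeric matrix, targets (rows) x raters (columns), complete,
#'   >= 2 rows and >= 2 columns.
#' @param type `"agreement"` or `"consistency"`.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `type` and the mean
#'   squares, class `icc_result`.
#' @export
icc_single <- function(mat, type = c("agreement", "consistency"),
                       conf_level = 0.95) {
  type <- match.arg(type)
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("need >= 2 targets and >= 2 raters", call. = FALSE)
  if (anyNA(mat)) stop("matrix must be complete", call. = FALSE)
  if (diff(range(mat)) < 1e-9) {
    stop("undefined statistic: constant matrix", call. = FALSE)
  }
  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0 && msc <= 0 && mse <= 0) {
    stop("undefined statistic: constant matrix", call. = FALSE)
  }
  alpha <- 1 - conf_level
  if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    fl <- f_obs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f_obs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_star <- stats::qf(1 - alpha / 2, n - 1, v)
    lower <- n * (msr - f_star * mse) /
      (f_star * (k * msc + (k * n - k - n) * mse) + n * msr)
    f_star_u <- stats::qf(1 - alpha / 2, v, n - 1)
    upper <- n * (f_star_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_star_u * msr)
    ci <- c(lower, upper)
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2], type = type,
                 msr = msr, msc = msc, mse = mse,
                 n_targets = n, n_raters = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s, single): %.4f [%.4f, %.4f]\n",
              x$type, x$icc, x$ci_low, x$ci_high))
  invisible(x)
}

#' Intra- and inter-operator reliability report
#'
#' Intra-operator: per (group, operator), the matrix of measured inter-jaw
#' distances `D_M` with evaluation pairs as targets and repetitions as
#' raters, two-way mixed absolute-agreement single-measurement ICC.
#' Inter-operator: per group, the per-pair repetition-mean `D_M` with
#' operators as raters, two-way random consistency single-measurement ICC.
#'
#' @param report An `experiment_report` from [run_experiment()] with at
#'   least 2 repetitions and 2 operators.
#' @return List of data frames `intra` (group, operator, icc, ci_low,
#'   ci_high) and `inter` (group, icc, ci_low, ci_high).
#' @export
intra_inter_operator_report <- function(report) {
  cfg <- report$config
  if (cfg$n_repetitions < 2 || cfg$n_operators < 2) {
    stop("reliability requires >= 2 repetitions and >= 2 operators",
         call. = FALSE)
  }
  rec <- report$records
  scheme <- group_scheme()
  groups <- sort(unique(rec$group))

  intra <- list()
  for (g in groups) {
    ev <- evaluation_pairs(scheme, g)
    for (op in seq_len(cfg$n_operators)) {
      sub <- rec[rec$group == g & rec$operator == op, ]
      dm <- matrix(NA_real_, length(ev), cfg$n_repetitions)
      for (r in seq_len(cfg$n_repetitions)) {
        row_r <- sub[sub$repetition == r, ]
        dm[, r] <- row_r$D_M_mm[match(ev, row_r$pair)]
      }
      res <- icc_single(dm, type = "agreement")
      intra[[length(intra) + 1L]] <- data.frame(
        group = g, operator = op, icc = res$icc,
        ci_low = res$ci_low, ci_high = res$ci_high
      )
    }
  }

  inter <- list()
  for (g in groups) {
    ev <- evaluation_pairs(scheme, g)
    dm <- matrix(NA_real_, length(ev), cfg$n_operators)
    for (op in seq_len(cfg$n_operators)) {
      sub <- rec[rec$group == g & rec$operator == op, ]
      means <- tapply(sub$D_M_mm, sub$pair, mean)
      dm[, op] <- means[ev]
    }
    res <- icc_single(dm, type = "consistency")
    inter[[length(inter) + 1L]] <- data.frame(
      group = g, icc = res$icc, ci_low = res$ci_low, ci_high = res$ci_high
    )
  }

  list(intra = do.call(rbind, intra), inter = do.call(rbind, inter))
}

#' Group-level ANOVA and Tukey tables of an experiment
#'
#' One-way ANOVA across the seven groups' per-unit RMSE values, with Tukey
#' HSD all-pairs comparisons, for trueness and for precision.
#'
#' @param report An `experiment_report`.
#' @return List with `anova` (data frame, one row per metric) and `tukey`
#'   (data frame with a `metric` column).
#' @export
experiment_statistics <- function(report) {
  split_metric <- function(df) split(df$rmse_mm, df$group)
  metrics <- list(trueness = split_metric(report$trueness))
  if (nrow(report$precision) > 0) {
    metrics$precision <- split_metric(report$precision)
  }
  anova_rows <- list(); tukey_rows <- list()
  for (m in names(metrics)) {
    a <- one_way_anova(metrics[[m]])
    anova_rows[[m]] <- data.frame(
      metric = m, F = a$F, df_between = a$df_between,
      df_within = a$df_within, p = a$p, stringsAsFactors = FALSE
    )
    tk <- tukey_hsd(metrics[[m]])
    tk <- cbind(metric = m, tk)
    tukey_rows[[m]] <- tk
  }
  list(anova = do.call(rbind, c(anova_rows, list(make.row.names = FALSE))),
       tukey = do.call(rbind, c(tukey_rows, list(make.row.names = FALSE))))
}

#' Write the report tables to disk
#'
#' Writes `summary.csv` (per-group trueness/precision mean and sd),
#' `records.csv` (long per-measurement records), `anova.csv`, `tukey.csv`
#' (7 x 7 adjusted-p matrix with the diagonal marked `NA`), `icc_intra.csv`,
#' `icc_inter.csv` and `report.json` (config, seed and summary bundle).
#' Output is deterministic: re-writing the same report produces byte-identical
#' files.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_report_tables <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    summary = file.path(dir, "summary.csv"),
    records = file.path(dir, "records.csv"),
    anova = file.path(dir, "anova.csv"),
    tukey = file.path(dir, "tukey.csv"),
    icc_intra = file.path(dir, "icc_intra.csv"),
    icc_inter = file.path(dir, "icc_inter.csv"),
    report = file.path(dir, "report.json")
  )
  wr <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  wr(report$summary, paths["summary"])
  wr(report$records, paths["records"])

  st <- experiment_statistics(report)
  wr(st$anova, paths["anova"])
  tk <- st$tukey[st$tukey$metric == "trueness", ]
  groups <- sort(unique(report$records$group))
  pmat <- matrix(NA_real_, length(groups), length(groups),
                 dimnames = list(paste0("group", groups),
                                 paste0("group", groups)))
  for (r in seq_len(nrow(tk))) {
    i <- match(tk$group_i[r], as.character(groups))
    j <- match(tk$group_j[r], as.character(groups))
    pmat[i, j] <- pmat[j, i] <- tk$p_adj[r]
  }
  utils::write.csv(data.frame(group = rownames(pmat), pmat,
                              check.names = FALSE),
                   paths["tukey"], row.names = FALSE, quote = FALSE)

  icc <- intra_inter_operator_report(report)
  wr(icc$intra, paths["icc_intra"])
  wr(icc$inter, paths["icc_inter"])

  cfg <- report$config
  bundle <- list(
    seed = cfg$seed,
    design = list(n_repetitions = cfg$n_repetitions,
                  n_operators = cfg$n_operators,
                  points_per_concave = cfg$points_per_concave,
                  cap_half_angle = cfg$cap_half_angle),
    noise = list(sigma_contact = cfg$noise$sigma_contact,
                 sigma_scan = cfg$noise$sigma_scan,
                 n_probe_repeats = cfg$noise$n_probe_repeats,
                 n_scan_repeats = cfg$noise$n_scan_repeats),
    reference = report$reference,
    summary = report$summary
  )
  jsonlite::write_json(bundle, paths["report"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
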