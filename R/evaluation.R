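# The measurement core of the study: seven reference-point groups, held-out
# inter-jaw pair distances D_R (standard/contact data) and D_M (after
# alignment), their differences, and RMSE trueness/precision per group over
# the repetitions x operators design (ISO 5725-1 framing: trueness =
# closeness to the reference value, precision = closeness of repeated
# measurements to each other).

#' The seven canonical reference-point groups
#'
#' Groups 1-3 use three center-point pairs, groups 4-7 use four:
#' \itemize{
#'   \item group 1: 14-44, 0-0', 24-34
#'   \item group 2: 13-43, 0-0', 23-33
#'   \item group 3: 12-42, 0-0', 22-32
#'   \item group 4: 14-44, 12-42, 22-32, 24-34
#'   \item group 5: 14-44, 11-41, 21-31, 24-34
#'   \item group 6: 13-43, 11-41, 21-31, 23-33
#'   \item group 7: 12-42, 11-41, 21-31, 22-32
#' }
#'
#' @return A `group_scheme`: list of 7 character vectors of maxillary member
#'   labels (mandibular partners via [pair_of()]).
#' @export
group_scheme <- function() {
  structure(list(
    `1` = c("14", "0", "24"),
    `2` = c("13", "0", "23"),
    `3` = c("12", "0", "22"),
    `4` = c("14", "12", "22", "24"),
    `5` = c("14", "11", "21", "24"),
    `6` = c("13", "11", "21", "23"),
    `7` = c("12", "11", "21", "22")
  ), class = "group_scheme")
}

#' @export
print.group_scheme <- function(x, ...) {
  cat("group_scheme: 7 reference-point groups\n")
  for (g in seq_along(x)) {
    cat(sprintf("  group %d: %s\n", g,
                paste(sprintf("%s-%s", x[[g]], pair_of(x[[g]])),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Held-out evaluation pairs of a group
#'
#' The canonical pairs not used as the group's alignment references; the
#' inter-jaw distances of these pairs are what the accuracy evaluation
#' measures.
#'
#' @param scheme A `group_scheme`.
#' @param group Group index in 1..7.
#' @return Character vector of maxillary labels of the evaluation pairs.
#' @export
evaluation_pairs <- function(scheme = group_scheme(), group) {
  key <- as.character(group)
  if (length(key) != 1 || !key %in% names(scheme)) {
    stop("unknown group index: ", group, call. = FALSE)
  }
  setdiff(concave_labels("maxillary"), scheme[[key]])
}

#' Inter-jaw distances of center-point pairs
#'
#' Euclidean distance between each maxillary landmark and its mandibular
#' partner, taking the maxillary coordinates from `max_set` and the
#' mandibular ones from `mand_set`. Order-stable in `pairs`.
#'
#' @param max_set,mand_set `landmark_set`s holding the maxillary and
#'   mandibular coordinates (may be the same object).
#' @param pairs Maxillary labels of the pairs (default: all nine).
#' @return Named numeric vector of distances, mm.
#' @export
pair_distances <- function(max_set, mand_set = max_set,
                           pairs = concave_labels("maxillary")) {
  .check_labels(pairs)
  mand <- pair_of(pairs)
  for (set_name in c("max_set", "mand_set")) {
    set <- get(set_name)
    want <- if (set_name == "max_set") pairs else mand
    miss <- setdiff(want, rownames(set$points))
    if (length(miss)) {
      stop("missing landmark(s) in ", set_name, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  d <- sqrt(rowSums((max_set$points[pairs, , drop = FALSE] -
                       mand_set$points[mand, , drop = FALSE])^2))
  stats::setNames(as.numeric(d), pairs)
}

#' Trueness RMSE of one alignment-evaluation unit
#'
#' Root-mean-square of the differences `D_M - D_R` over the evaluation
#' pairs of one (operator, repetition, group) unit.
#'
#' @param diffs Numeric vector of distance differences, mm.
#' @return RMSE in mm.
#' @export
trueness_rmse <- function(diffs) {
  if (length(diffs) < 1) stop("empty record set", call. = FALSE)
  sqrt(mean(diffs^2))
}

#' Per-repetition precision RMSE
#'
#' For a matrix of measured distances `D_M` (rows = evaluation pairs,
#' columns = repetitions of one operator in one group), the precision RMSE
#' of repetition r is the root-mean-square over pairs of the deviation of
#' `D_M[p, r]` from the pair's across-repetition mean -- the ISO 5725-1
#' repeatability notion with the per-pair mean as the consensus value.
#'
#' @param dm Numeric matrix, pairs x repetitions (>= 2 repetitions).
#' @return Numeric vector, one RMSE (mm) per repetition.
#' @export
precision_rmse <- function(dm) {
  dm <- as.matrix(dm)
  if (ncol(dm) < 2) {
    stop("precision undefined for a single repetition", call. = FALSE)
  }
  dev <- dm - rowMeans(dm)
  sqrt(colMeans(dev^2))
}

#' Run the full in-silico accuracy experiment
#'
#' Executes the whole study design: simulates one contact-measured standard
#' data set; for every (operator, repetition) simulates both jaws' scan
#' sessions and extracts fitted concave centers; for each of the seven
#' groups aligns both jaws onto the standard by the group's reference pairs
#' and measures the held-out pair distances; and aggregates trueness and
#' precision RMSE per group.
#'
#' `D_R` is taken from the simulated contact standard data (the study's
#' reference measurement); set `reference = "nominal"` to use the noiseless
#' nominal layout instead for oracle studies.
#'
#' @param config A `simulation_config`.
#' @param reference `"standard"` (default) or `"nominal"`.
#' @param fixed_radius Optional fixed sphere-fit radius (mm), passed to
#'   [fit_concave_centers()].
#' @return An `experiment_report`: list with `config`, `standard` (the
#'   simulated standard landmark set), `records` (long data frame: operator,
#'   repetition, group, pair, D_R_mm, D_M_mm, diff_mm), `trueness` (data
#'   frame: operator, repetition, group, rmse_mm), `precision` (data frame:
#'   operator, group, repetition, rmse_mm) and `summary` (per group:
#'   trueness_mean/sd, precision_mean/sd, mm).
#' @export
run_experiment <- function(config = simulation_config(),
                           reference = c("standard", "nominal"),
                           fixed_radius = NULL) {
  reference <- match.arg(reference)
  scheme <- group_scheme()
  standard <- simulate_contact_standard(config$layout, config$noise,
                                        seed = config$seed)
  ref_set <- if (reference == "nominal") {
    nominal_landmarks(config$layout)
  } else standard
  d_r_all <- pair_distances(ref_set, ref_set)

  n_op <- config$n_operators
  n_rep <- config$n_repetitions
  n_groups <- length(scheme)
  n_eval <- vapply(seq_len(n_groups),
                   function(g) length(evaluation_pairs(scheme, g)), 1L)
  total <- n_op * n_rep * sum(n_eval)

  rec_operator <- integer(total); rec_repetition <- integer(total)
  rec_group <- integer(total); rec_pair <- character(total)
  rec_dr <- numeric(total); rec_dm <- numeric(total)
  i0 <- 0L
  true_rows <- vector("list", n_op * n_rep * n_groups)
  tr <- 0L

  for (op in seq_len(n_op)) {
    for (rep in seq_len(n_rep)) {
      sess_max <- simulate_scan_session(config, "maxillary", op, rep)
      sess_mand <- simulate_scan_session(config, "mandibular", op, rep)
      fitted_max <- fit_concave_centers(sess_max, fixed_radius = fixed_radius)
      fitted_mand <- fit_concave_centers(sess_mand, fixed_radius = fixed_radius)
      for (g in seq_len(n_groups)) {
        rel <- construct_icp_relation(fitted_max, fitted_mand, standard,
                                      scheme[[g]], group = g)
        ev <- evaluation_pairs(scheme, g)
        d_m <- pair_distances(rel$maxillary, rel$mandibular, ev)
        idx <- i0 + seq_along(ev)
        rec_operator[idx] <- op; rec_repetition[idx] <- rep
        rec_group[idx] <- g; rec_pair[idx] <- ev
        rec_dr[idx] <- d_r_all[ev]; rec_dm[idx] <- d_m
        i0 <- i0 + length(ev)
        tr <- tr + 1L
        true_rows[[tr]] <- data.frame(
          operator = op, repetition = rep, group = g,
          rmse_mm = trueness_rmse(d_m - d_r_all[ev])
        )
      }
    }
  }

  records <- data.frame(
    operator = rec_operator, repetition = rec_repetition, group = rec_group,
    pair = rec_pair, D_R_mm = rec_dr, D_M_mm = rec_dm,
    diff_mm = rec_dm - rec_dr, stringsAsFactors = FALSE
  )
  trueness <- do.call(rbind, true_rows)

  prec_rows <- list()
  if (n_rep >= 2) {
    for (op in seq_len(n_op)) {
      for (g in seq_len(n_groups)) {
        sub <- records[records$operator == op & records$group == g, ]
        dm <- matrix(NA_real_, n_eval[g], n_rep)
        ev <- evaluation_pairs(scheme, g)
        for (r in seq_len(n_rep)) {
          row_r <- sub[sub$repetition == r, ]
          dm[, r] <- row_r$D_M_mm[match(ev, row_r$pair)]
        }
        prec_rows[[length(prec_rows) + 1L]] <- data.frame(
          operator = op, group = g, repetition = seq_len(n_rep),
          rmse_mm = precision_rmse(dm)
        )
      }
    }
  }
  precision <- if (length(prec_rows)) do.call(rbind, prec_rows) else
    data.frame(operator = integer(), group = integer(),
               repetition = integer(), rmse_mm = numeric())

  summary_df <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    tv <- trueness$rmse_mm[trueness$group == g]
    pv <- precision$rmse_mm[precision$group == g]
    data.frame(
      group = g,
      trueness_mean = mean(tv), trueness_sd = stats::sd(tv),
      precision_mean = if (length(pv)) mean(pv) else NA_real_,
      precision_sd = if (length(pv)) stats::sd(pv) else NA_real_
    )
  }))

  structure(list(config = config, standard = standard, reference = reference,
                 records = records, trueness = trueness,
                 precision = precision, summary = summary_df),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf(
    "experiment_report: %d operators x %d repetitions x %d groups (%d units)\n",
    x$config$n_operators, x$config$n_repetitions, 7L, nrow(x$trueness)))
  cat("  per-group accuracy (mm):\n")
  s <- x$summary
  for (g in seq_len(nrow(s))) {
    cat(sprintf("   group %d: trueness %.3f +/- %.3f, precision %.3f +/- %.3f\n",
                s$group[g], s$trueness_mean[g], s$trueness_sd[g],
                s$precision_mean[g], s$precision_sd[g]))
  }
  invisible(x)
}
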