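test_that("one-way ANOVA reproduces the hand-computed example", {
  res <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  # SSB = 1.5, SSW = 4, df (1, 4): F = 1.5 / 1 = 1.5
  expect_equal(res$F, 1.5)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)
  expect_equal(res$p, pf(1.5, 1, 4, lower.tail = FALSE))

  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "undefined")
  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
  expect_error(one_way_anova(list(c(1, 2), 3)), ">= 2 values")
})

test_that("ANOVA matches stats::aov on random group sets", {
  set.seed(51)
  for (i in 1:50) {
    k <- sample(3:7, 1)
    groups <- lapply(seq_len(k), function(g) rnorm(sample(4:12, 1), mean = g / 10))
    mine <- one_way_anova(groups)
    df <- data.frame(y = unlist(groups),
                     g = factor(rep(seq_len(k), lengths(groups))))
    ref <- summary(stats::aov(y ~ g, data = df))[[1]]
    expect_equal(mine$F, ref[["F value"]][1], tolerance = 1e-9)
    expect_equal(mine$p, ref[["Pr(>F)"]][1], tolerance = 1e-9)
  }
})

test_that("ANOVA F is location-invariant and scale-invariant", {
  set.seed(52)
  groups <- lapply(1:4, function(g) rnorm(8, mean = g / 5))
  base <- one_way_anova(groups)
  shifted <- one_way_anova(lapply(groups, `+`, 100))
  scaled <- one_way_anova(lapply(groups, `*`, 7))
  expect_equal(shifted$F, base$F, tolerance = 1e-9)
  expect_equal(scaled$F, base$F, tolerance = 1e-9)
})

test_that("Tukey HSD matches stats::TukeyHSD including unequal n", {
  set.seed(53)
  for (i in 1:20) {
    k <- sample(3:7, 1)
    groups <- lapply(seq_len(k), function(g) rnorm(sample(4:15, 1),
                                                   mean = g / 8))
    names(groups) <- paste0("g", seq_len(k))
    mine <- tukey_hsd(groups)
    df <- data.frame(y = unlist(groups),
                     g = factor(rep(names(groups), lengths(groups))))
    ref <- stats::TukeyHSD(stats::aov(y ~ g, data = df))$g
    for (r in seq_len(nrow(mine))) {
      key <- paste0(mine$group_j[r], "-", mine$group_i[r])
      expect_equal(mine$p_adj[r], ref[key, "p adj"], tolerance = 1e-6)
      expect_equal(mine$mean_diff[r], ref[key, "diff"], tolerance = 1e-9)
    }
  }
})

test_that("Tukey-adjusted p is never below the unadjusted pooled p", {
  set.seed(54)
  for (i in 1:50) {
    groups <- lapply(1:4, function(g) rnorm(6, mean = g / 10))
    names(groups) <- as.character(1:4)
    a <- one_way_anova(groups)
    tk <- tukey_hsd(groups)
    means <- vapply(groups, mean, 0)
    n_i <- lengths(groups)
    for (r in seq_len(nrow(tk))) {
      gi <- tk$group_i[r]; gj <- tk$group_j[r]
      se <- sqrt(a$ms_within * (1 / n_i[gi] + 1 / n_i[gj]))
      p_lsd <- 2 * pt(-abs(means[gj] - means[gi]) / se, a$df_within)
      expect_gte(tk$p_adj[r], p_lsd - 1e-12)
    }
  }
  ident <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(ident$p_adj, rep(1, 3), tolerance = 1e-9)
})

test_that("ICC single-measure forms match hand computation", {
  shift <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2, byrow = TRUE)
  # columns differ by an additive constant: perfect consistency
  expect_equal(icc_single(shift, "consistency")$icc, 1)
  # absolute agreement penalizes the offset: MSR 8, MSC 1.5, MSE 0
  expect_equal(icc_single(shift, "agreement")$icc, 8 / 9, tolerance = 1e-12)

  same <- matrix(c(1, 1, 4, 4, 9, 9), 3, 2, byrow = TRUE)
  expect_equal(icc_single(same, "consistency")$icc, 1)
  expect_equal(icc_single(same, "agreement")$icc, 1)

  expect_error(icc_single(matrix(5, 4, 3)), "constant")
  expect_error(icc_single(matrix(1:4, 1, 4)), ">= 2")
})

test_that("ICC point estimates and CIs match the reference implementation", {
  # reference values computed with pingouin.intraclass_corr (ICC(A,1) and
  # ICC(C,1) rows); CIs as printed by the reference (2 decimals)
  wide <- matrix(c(9.1, 8.8, 9.4, 7.2, 7.0, 7.5, 6.1, 6.3, 6.0,
                   8.5, 8.2, 8.9, 5.0, 5.4, 4.8), 5, 3, byrow = TRUE)
  noisy <- matrix(c(
    10.597673, 10.012303, 11.225013, 11.153889,
    7.966253, 8.709101, 8.247288, 7.318527,
    11.759028, 10.829685, 12.115818, 11.465954,
    11.751726, 11.404479, 12.736908, 11.772959,
    5.7981, 5.851436, 6.470546, 6.35374,
    7.684554, 7.697216, 8.894794, 7.11115,
    9.897111, 9.68604, 10.686866, 11.045961,
    9.287752, 8.779405, 8.790378, 9.82293), 8, 4, byrow = TRUE)

  wa <- icc_single(wide, "agreement")
  expect_equal(wa$icc, 0.9720924732454325, tolerance = 1e-9)
  expect_equal(c(wa$ci_low, wa$ci_high), c(0.88, 1.00), tolerance = 0.005)
  wc <- icc_single(wide, "consistency")
  expect_equal(wc$icc, 0.9691700070738034, tolerance = 1e-9)
  expect_equal(c(wc$ci_low, wc$ci_high), c(0.86, 1.00), tolerance = 0.005)

  na_ <- icc_single(noisy, "agreement")
  expect_equal(na_$icc, 0.9246665140002256, tolerance = 1e-9)
  expect_equal(c(na_$ci_low, na_$ci_high), c(0.79, 0.98), tolerance = 0.005)
  nc <- icc_single(noisy, "consistency")
  expect_equal(nc$icc, 0.9409530476849788, tolerance = 1e-9)
  expect_equal(c(nc$ci_low, nc$ci_high), c(0.84, 0.99), tolerance = 0.005)
})

test_that("ICC mean squares agree with an independent two-way ANOVA", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(4:10, 1); k <- sample(2:5, 1)
    mat <- matrix(rnorm(n * k, mean = rep(rnorm(n, sd = 2), k)), n, k)
    mine <- icc_single(mat, "agreement")
    df <- data.frame(y = as.vector(mat),
                     target = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ target + rater, data = df))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    ref_a <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    ref_c <- (msr - mse) / (msr + (k - 1) * mse)
    expect_equal(mine$icc, ref_a, tolerance = 1e-9)
    expect_equal(icc_single(mat, "consistency")$icc, ref_c, tolerance = 1e-9)
    expect_lte(mine$ci_low, mine$icc)
    expect_gte(mine$ci_high, mine$icc)
    expect_lte(mine$icc, 1)
  }
})

test_that("consistency ICC ignores rater offsets; agreement does not", {
  set.seed(56)
  mat <- matrix(rnorm(24, mean = rep(rnorm(8, sd = 2), 3)), 8, 3)
  offset <- sweep(mat, 2, c(0, 1.5, -2), "+")
  expect_equal(icc_single(offset, "consistency")$icc,
               icc_single(mat, "consistency")$icc, tolerance = 1e-9)
  expect_lt(icc_single(offset, "agreement")$icc,
            icc_single(mat, "agreement")$icc)
})

test_that("operator reliability report has the study's structure", {
  icc <- intra_inter_operator_report(cached_default_report())
  expect_equal(nrow(icc$intra), 7 * 2)
  expect_equal(nrow(icc$inter), 7)
  # under default noise every reported reliability lies in (0, 1]
  expect_true(all(icc$intra$icc > 0 & icc$intra$icc <= 1))
  expect_true(all(icc$inter$icc > 0 & icc$inter$icc <= 1))
  expect_true(all(icc$intra$ci_low <= icc$intra$icc))
  expect_true(all(icc$intra$ci_high >= icc$intra$icc))

  zero_cfg <- simulation_config(
    noise = noise_model(sigma_contact = 0, sigma_scan = 0),
    points_per_concave = 40, operator_subsample_fraction = 1,
    n_repetitions = 2, seed = 57
  )
  zero_rep <- run_experiment(zero_cfg)
  # all D_M identical by construction: reliability is undefined
  expect_error(intra_inter_operator_report(zero_rep), "constant|undefined")
})

test_that("diverging operator subsampling lowers inter-operator ICC", {
  base_icc <- numeric(12); gap_icc <- numeric(12)
  for (s in 1:12) {
    cfg_eq <- simulation_config(points_per_concave = 60, n_repetitions = 3,
                                operator_subsample_fraction = c(0.9, 0.9),
                                seed = 5700 + s)
    cfg_gap <- simulation_config(points_per_concave = 60, n_repetitions = 3,
                                 operator_subsample_fraction = c(0.9, 0.15),
                                 seed = 5700 + s)
    base_icc[s] <- mean(intra_inter_operator_report(
      run_experiment(cfg_eq))$inter$icc)
    gap_icc[s] <- mean(intra_inter_operator_report(
      run_experiment(cfg_gap))$inter$icc)
  }
  expect_lt(mean(gap_icc), mean(base_icc))
})

test_that("report tables are complete, deterministic and round-trip", {
  cfg <- simulation_config(points_per_concave = 40, n_repetitions = 3,
                           seed = 58)
  report <- run_experiment(cfg)
  dir1 <- file.path(tempdir(), "rep1")
  paths <- write_report_tables(report, dir1)
  expect_true(all(file.exists(paths)))

  tukey <- utils::read.csv(paths["tukey"], check.names = FALSE)
  expect_equal(dim(tukey), c(7, 8))
  expect_true(all(is.na(diag(as.matrix(tukey[, -1])))))
  expect_equal(sum(!is.na(as.matrix(tukey[, -1]))), 42)  # 21 pairs mirrored

  intra <- utils::read.csv(paths["icc_intra"])
  expect_equal(nrow(intra), 14)

  back <- utils::read.csv(paths["summary"])
  expect_equal(back$trueness_mean, report$summary$trueness_mean,
               tolerance = 1e-12)

  dir2 <- file.path(tempdir(), "rep2")
  paths2 <- write_report_tables(report, dir2)
  for (f in names(paths)) {
    expect_identical(readLines(paths[[f]]), readLines(paths2[[f]]))
  }

  st <- experiment_statistics(report)
  expect_equal(nrow(st$anova), 2)
  expect_equal(nrow(st$tukey), 42)
  expect_true(all(st$tukey$p_adj >= 0 & st$tukey$p_adj <= 1))
})
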