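test_that("a forest recovers a deterministic step-function signal", {
  climate <- iid_climate(500, seed = 7)
  y <- as.integer(climate$MCMT > stats::median(climate$MCMT)) * 2L
  # all predictors tried per split, so attribution is not diluted by the
  # random candidate draw missing the true driver at the root
  fit <- fit_snp_forest(y, climate, n_trees = 200, seed = 7, mtry = 20)
  expect_gt(fit$oob_r2, 0.8)
  expect_gt(fit$importance[["MCMT"]] / sum(fit$importance), 0.95)
  # the default mtry = p/3 forest still explains the signal
  fit6 <- fit_snp_forest(y, climate, n_trees = 200, seed = 7)
  expect_gt(fit6$oob_r2, 0.8)
  expect_equal(names(which.max(fit6$importance)), "MCMT")
})

test_that("a permutation null centers OOB R^2 at zero", {
  climate <- iid_climate(500, seed = 8)
  set.seed(8)
  y <- sample(rep(0:2, length.out = 500))
  r2 <- vapply(1:20, function(s) {
    fit_snp_forest(y, climate, n_trees = 100, seed = s)$oob_r2
  }, numeric(1))
  expect_lte(mean(r2), 0.02)
})

test_that("degenerate forests are flagged instead of reporting spurious R^2", {
  climate <- iid_climate(60, seed = 9)
  y <- rep(0:2, 20)
  fit <- fit_snp_forest(y, climate, n_trees = 1, seed = 1)
  # one bootstrap leaves ~37% of samples OOB: below the 50% coverage floor
  expect_true(fit$flagged)
  expect_identical(fit$oob_r2, 0)
})

test_that("forest preconditions are enforced", {
  climate <- iid_climate(50, seed = 10)
  expect_error(fit_snp_forest(rep(1L, 50), climate, n_trees = 10),
               "constant dosage")
  expect_error(fit_snp_forest(rep(0:1, 25), climate[1:10, ][rep(1, 50), ],
                              n_trees = 10), NA)  # duplicated climate is fine
  expect_error(fit_snp_forest(c(rep(0:1, 10), rep(NA_integer_, 30)), climate,
                              n_trees = 10), "complete cases")
})

test_that("fits are deterministic given a seed", {
  climate <- iid_climate(200, seed = 12)
  y <- as.integer(climate$EMT > stats::median(climate$EMT)) +
    as.integer(climate$MAP > stats::median(climate$MAP))
  a <- fit_snp_forest(y, climate, n_trees = 50, seed = 31, return_splits = TRUE)
  b <- fit_snp_forest(y, climate, n_trees = 50, seed = 31, return_splits = TRUE)
  expect_identical(a$oob_r2, b$oob_r2)
  expect_identical(a$splits, b$splits)
  c <- fit_snp_forest(y, climate, n_trees = 50, seed = 32)
  expect_false(identical(a$oob_r2, c$oob_r2))
})

test_that("split records are internally consistent", {
  climate <- iid_climate(150, seed = 13)
  y <- as.integer(climate$Eref > stats::median(climate$Eref)) * 2L
  fit <- fit_snp_forest(y, climate, n_trees = 10, seed = 5,
                        return_splits = TRUE)
  expect_true(all(fit$splits$improvement >= 0))
  # per-predictor raw importances equal the summed split improvements
  by_pred <- tapply(fit$splits$improvement, fit$splits$predictor, sum)
  for (v in names(by_pred)) {
    expect_equal(fit$importance[[v]], unname(by_pred[[v]]), tolerance = 1e-12)
  }
  # split values lie inside each predictor's observed range
  for (v in unique(fit$splits$predictor)) {
    vals <- fit$splits$value[fit$splits$predictor == v]
    expect_true(all(vals >= min(climate[[v]]) & vals <= max(climate[[v]])))
  }
})

make_small_model <- function(n = 250, n_cline = 12, n_noise = 12, seed = 21,
                             n_trees = 60) {
  climate <- iid_climate(n, seed = seed)
  set.seed(seed)
  drivers <- rep(c("MCMT", "EMT", "DD_0", "Eref"), length.out = n_cline)
  dos <- matrix(NA_integer_, n, n_cline + n_noise)
  for (j in seq_len(n_cline)) {
    z <- scale(climate[[drivers[j]]])[, 1]
    dos[, j] <- stats::rbinom(n, 2, stats::plogis(2.5 * z))
  }
  for (j in seq_len(n_noise)) {
    dos[, n_cline + j] <- sample(rep(0:2, length.out = n))
  }
  colnames(dos) <- c(sprintf("cline_%02d", seq_len(n_cline)),
                     sprintf("noise_%02d", seq_len(n_noise)))
  g <- genotype_matrix(dos, sample_ids = climate$sample_id)
  list(g = g, climate = climate,
       model = fit_gradient_forest(g, climate, n_trees = n_trees, seed = seed))
}

test_that("gradient forest conserves R^2 across predictor shares", {
  mm <- make_small_model()
  model <- mm$model
  expect_gt(model$n_retained, 0)
  retained <- model$fits$retained
  share_sums <- rowSums(model$shares[retained, , drop = FALSE])
  expect_equal(share_sums,
               stats::setNames(model$fits$oob_r2[retained],
                               model$fits$snp_id[retained]),
               tolerance = 1e-9)
  # overall importances are the mean retained shares
  expect_equal(sum(model$overall_importance),
               sum(model$fits$oob_r2[retained]) / model$n_retained,
               tolerance = 1e-9)
})

test_that("aggregate turnover curves are monotone from zero and total the overall importance", {
  model <- make_small_model()$model
  imp <- overall_importance(model)
  for (v in imp$predictor) {
    tf <- cumulative_importance(model, v)
    expect_equal(tf$cumimp[1], 0)
    expect_true(all(diff(tf$cumimp) >= 0))
    expect_equal(tf$total, imp$importance[imp$predictor == v],
                 tolerance = 1e-9)
  }
  # totals across predictors sum to the summed overall importance
  tot <- sum(vapply(model$turnover, `[[`, numeric(1), "total"))
  expect_equal(tot, sum(model$overall_importance), tolerance = 1e-9)
})

test_that("data densities integrate to one on every predictor", {
  model <- make_small_model()$model
  for (v in names(model$density)) {
    d <- model$density[[v]]
    expect_equal(sum(d$d * (d$upper - d$lower)), 1, tolerance = 1e-9)
  }
})

test_that("retention contrasts clinal against permuted SNPs", {
  mm <- make_small_model(n = 300, n_cline = 30, n_noise = 30, seed = 23,
                         n_trees = 200)
  fits <- mm$model$fits
  cline_rate <- mean(fits$retained[grepl("^cline", fits$snp_id)])
  noise_rate <- mean(fits$retained[grepl("^noise", fits$snp_id)])
  expect_gte(cline_rate, 5 * max(noise_rate, 1 / 30))
})

test_that("a model with no predictive SNPs is an explicit empty result", {
  climate <- iid_climate(120, seed = 29)
  set.seed(29)
  dos <- matrix(sample(rep(0:2, length.out = 120 * 5)), 120, 5,
                dimnames = list(NULL, sprintf("s%d", 1:5)))
  model <- fit_gradient_forest(genotype_matrix(dos,
                                               sample_ids = climate$sample_id),
                               climate, n_trees = 50, seed = 29)
  # permuted dosages should essentially never be predictive; if none are,
  # the model reports an empty retained set rather than erroring
  expect_s3_class(model, "gf_model")
  expect_true(model$n_retained >= 0)
  if (model$n_retained == 0) {
    expect_true(all(model$overall_importance == 0))
    expect_equal(cumulative_importance(model, "MAT")$total, 0)
  }
})

test_that("raw importance density localizes single split events", {
  climate <- iid_climate(100, seed = 31)
  y <- as.integer(climate$PAS > stats::median(climate$PAS)) * 2L
  fit <- fit_snp_forest(y, climate, n_trees = 4, seed = 3, min_node = 25,
                        return_splits = TRUE)
  dens <- raw_importance_density(list(fit), "PAS", weights = 1)
  sp <- fit$splits[fit$splits$predictor == "PAS", ]
  # brute-force tally of the enumerated split list into the same bins
  expected <- rep(0, nrow(dens))
  for (i in seq_len(nrow(sp))) {
    b <- min(max(findInterval(sp$value[i], dens$lower), 1), nrow(dens))
    expected[b] <- expected[b] + sp$improvement[i]
  }
  expect_equal(dens$I, expected, tolerance = 1e-12)
  # additivity: two identical fits double the density before weighting
  dens2 <- raw_importance_density(list(fit, fit), "PAS", weights = c(1, 1))
  expect_equal(dens2$I, dens$I, tolerance = 1e-12)  # mean over fits
})

test_that("standardized importance follows f = I / floored d", {
  # hand-computed 5-bin case
  out <- standardized_importance(c(0, 1, 2, 1, 0), rep(0.2, 5))
  expect_equal(out$f, c(0, 5, 10, 5, 0))
  expect_false(any(out$flagged))
  # uniform d makes f proportional to I
  I <- c(0.3, 0.1, 0.6)
  expect_equal(standardized_importance(I, rep(1 / 3, 3))$f, 3 * I)
  # I proportional to d gives a constant f
  d <- c(0.1, 0.3, 0.6)
  expect_equal(standardized_importance(2 * d, d)$f, rep(2, 3))
  # floored bins are flagged and bounded
  out <- standardized_importance(c(1, 1), c(1, 1e-6), floor = 0.01)
  expect_true(out$flagged[2])
  expect_equal(out$f[2], 1 / 0.01)
  expect_error(standardized_importance(1:3, 1:2), "binnings")
})

test_that("turnover staircases match the brute-force split tally", {
  climate <- iid_climate(40, seed = 37)
  y <- as.integer(climate$MCMT > stats::median(climate$MCMT)) * 2L
  fit <- fit_snp_forest(y, climate, n_trees = 3, seed = 11, min_node = 10,
                        return_splits = TRUE, min_cases = 30)
  expect_lte(nrow(fit$splits), 10)
  for (v in unique(fit$splits$predictor)) {
    tf <- cumulative_importance(fit, v, rescale_to = "none")
    rng <- range(climate[[v]])
    xs <- seq(rng[1] - 0.05 * diff(rng), rng[2] + 0.05 * diff(rng),
              length.out = 100)
    sp <- fit$splits[fit$splits$predictor == v, ]
    expect_equal(predict(tf, xs, rule = "staircase"),
                 split_tally(sp$value, sp$improvement, xs), tolerance = 1e-12)
  }
  # empty importance gives a flat zero function
  tf0 <- cumulative_importance(fit$splits[0, ], "MAT", range = c(0, 1))
  expect_identical(predict(tf0, c(-1, 0.5, 2)), c(0, 0, 0))
  # a single split event is a one-step staircase at the split value
  one <- data.frame(predictor = "MAT", value = 0.4, improvement = 2)
  tf1 <- cumulative_importance(one, "MAT", range = c(0, 1))
  expect_equal(predict(tf1, c(0, 0.39, 0.4, 1), rule = "staircase"),
               c(0, 0, 2, 2))
})

test_that("single-predictor forests put all overall importance on that predictor", {
  set.seed(41)
  n <- 120
  climate <- iid_climate(n, seed = 41)
  for (v in setdiff(climate_variable_names(), "MCMT")) {
    climate[[v]] <- rep(climate[[v]][1], n)  # constants cannot be split on
  }
  y <- stats::rbinom(n, 2, stats::plogis(2 * scale(climate$MCMT)[, 1]))
  g <- genotype_matrix(cbind(only = y), sample_ids = climate$sample_id)
  model <- fit_gradient_forest(g, climate, n_trees = 100, seed = 41)
  expect_equal(model$n_retained, 1)
  imp <- overall_importance(model)
  expect_equal(imp$predictor[1], "MCMT")
  expect_equal(imp$importance[1], model$fits$oob_r2[1], tolerance = 1e-9)
  expect_true(all(imp$importance[-1] == 0))
  # descending order with alphabetical ties (the zero block)
  zero <- imp$predictor[imp$importance == 0]
  expect_identical(zero, sort(zero, method = "radix"))
})

test_that("models serialize to JSON + CSV and back", {
  model <- make_small_model(n = 150, n_cline = 6, n_noise = 4, seed = 43,
                            n_trees = 40)$model
  path <- file.path(withr::local_tempdir(), "model.json")
  write_gf_model(model, path)
  m2 <- read_gf_model(path)
  expect_equal(m2$n_retained, model$n_retained)
  expect_equal(m2$overall_importance, model$overall_importance,
               tolerance = 1e-12)
  xs <- seq(model$ranges["lo", "MCMT"], model$ranges["hi", "MCMT"],
            length.out = 37)
  expect_equal(predict(m2$turnover[["MCMT"]], xs),
               predict(model$turnover[["MCMT"]], xs), tolerance = 1e-12)
  expect_identical(m2$fits$retained, model$fits$retained)
})

test_that("tidy and glance expose the model tables", {
  model <- make_small_model(n = 150, n_cline = 4, n_noise = 2, seed = 47,
                            n_trees = 30)$model
  expect_identical(tidy(model), overall_importance(model))
  expect_equal(nrow(tidy(model, "snps")), 6)
  expect_true(all(c("predictor", "value", "cumulative_importance") %in%
                    names(tidy(model, "turnover"))))
  gl <- glance(model)
  expect_equal(gl$n_input_snps, 6)
  expect_equal(gl$retention_rate, gl$n_retained / 6)
})
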