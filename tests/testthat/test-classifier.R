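test_that("GA configuration is validated", {
  expect_error(ga_config(population_size = 0), "population_size")
  expect_error(ga_config(crossover_rate = 2), "probabilities")
  expect_error(ga_config(elitism = 10, population_size = 5), "elitism")
  expect_error(ga_config(cv_folds = 1), "cv_folds")
  expect_error(ga_config(c_range = c(5, -5)), "bounds")
})

test_that("GA fitness trajectory is non-decreasing and seeded", {
  tab <- toy_feature_table(n = 30, seed = 4)
  opt <- ga_optimize(tab[c("signal", "noise")], tab$label,
                     ga = fast_ga(seed = 3))
  expect_true(all(diff(opt$trajectory) >= 0))
  expect_gte(max(opt$trajectory), opt$trajectory[1])
  opt2 <- ga_optimize(tab[c("signal", "noise")], tab$label,
                      ga = fast_ga(seed = 3))
  expect_identical(opt, opt2)

  # a single-individual, single-generation run returns that individual's
  # cross-validated AUC
  opt1 <- ga_optimize(tab[c("signal", "noise")], tab$label,
                      ga = ga_config(population_size = 1, generations = 1,
                                     cv_folds = 3, seed = 5))
  expect_length(opt1$trajectory, 1L)
  expect_identical(opt1$best$cv_auc, opt1$trajectory[1])

  expect_error(ga_optimize(tab[c("signal", "noise")], tab$label,
                           ga = ga_config(cv_folds = 20, seed = 1)),
               "folds")
})

test_that("the GA finds a separating SVM on easy 2-D data", {
  ok <- vapply(1:3, function(s) {
    set.seed(s)
    n <- 60
    lab <- rep(c("benign", "malignant"), each = n / 2)
    x <- data.frame(a = rnorm(n, ifelse(lab == "malignant", 3, 0)),
                    b = rnorm(n, ifelse(lab == "malignant", -3, 0)))
    opt <- ga_optimize(x, lab, ga = ga_config(population_size = 10,
                                              generations = 10,
                                              cv_folds = 5, seed = s))
    opt$best$cv_auc >= 0.95
  }, logical(1))
  expect_gte(sum(ok), 3)
})

test_that("training is deterministic and separable data is memorized", {
  tab <- toy_feature_table(n = 30, seed = 6)
  tab$signal <- tab$signal + ifelse(tab$label == "malignant", 10, 0)
  fit <- ga_svm(label ~ signal + noise, tab, ga = fast_ga(seed = 2))
  expect_equal(roc_auc(fit$fitted, fit$y)$auc, 1)
  expect_equal(fit$youden_J, 1)
  expect_true(fit$youden_cutoff >= min(fit$fitted) &&
                fit$youden_cutoff <= max(fit$fitted))

  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f1)
  write_model(ga_svm(label ~ signal + noise, tab, ga = fast_ga(seed = 2)),
              f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("prediction is idempotent, row-stable and validates columns", {
  tab <- toy_feature_table(n = 40, seed = 7)
  fit <- ga_svm(label ~ signal + noise, tab, ga = fast_ga(seed = 1))
  # predicting the training rows reproduces the fitted values
  expect_equal(predict(fit, tab), fit$fitted, tolerance = 1e-9)
  # duplicated rows predict identically, independent of companions
  two <- tab[c(5, 5), ]
  p2 <- predict(fit, two)
  expect_identical(p2[1], p2[2])
  expect_equal(p2[1], predict(fit, tab[5, , drop = FALSE]))
  # class calls flip at the Youden cutoff
  cls <- predict(fit, tab, type = "class")
  expect_identical(as.character(cls),
                   ifelse(predict(fit, tab) >= fit$youden_cutoff,
                          "malignant", "benign"))
  expect_error(predict(fit, tab[, c("subject_id", "signal")]), "noise")
})

test_that("a serialized model restores to an identical predictor", {
  tab <- toy_feature_table(n = 30, seed = 8)
  fit <- ga_svm(label ~ signal + noise, tab, ga = fast_ga(seed = 9))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_model(fit, tmp)
  back <- read_model(tmp)
  expect_equal(predict(back, tab), predict(fit, tab), tolerance = 1e-12)
  expect_identical(back$feature_names, fit$feature_names)
  expect_equal(back$youden_cutoff, fit$youden_cutoff)
})

test_that("swapping the class labels complements the predicted values", {
  tab <- toy_feature_table(n = 40, seed = 10)
  ga <- ga_config(population_size = 8, generations = 4, cv_folds = 4,
                  kernels = "linear", seed = 3)
  fit_m <- ga_svm(label ~ signal + noise, tab, ga = ga,
                  positive = "malignant")
  fit_b <- ga_svm(label ~ signal + noise, tab, ga = ga,
                  positive = "benign")
  p_m <- predict(fit_m, tab)
  p_b <- predict(fit_b, tab)
  expect_lt(cor(p_m, p_b), -0.9)
  expect_lt(mean(abs(p_m - (1 - p_b))), 0.15)
})

test_that("model methods expose hyperparameters and diagnostics", {
  tab <- toy_feature_table(n = 30, seed = 11)
  fit <- ga_svm(label ~ signal + noise, tab,
                ga = fast_ga(seed = 1, kernels = "linear"))
  expect_output(print(fit), "GA-tuned SVM")
  expect_output(print(summary(fit)), "Training-set evaluation")
  cf <- coef(fit)
  expect_true("cost" %in% names(cf))
  expect_true(all(c("signal", "noise") %in% names(cf)))
  expect_equal(fitted(fit), fit$fitted)
  expect_equal(residuals(fit),
               as.numeric(tab$label == "malignant") - fit$fitted)
  tmp <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tmp)
  expect_silent(plot(fit))
  grDevices::dev.off()
})

test_that("TCR ablation trains paired models on identical seeds", {
  set.seed(12)
  n <- 40
  lab <- rep(c("benign", "malignant"), each = n / 2)
  tab <- data.frame(subject_id = sprintf("S%d", 1:n), label = lab,
                    shannon = rnorm(n, ifelse(lab == "malignant", -2, 0)),
                    ggn = rbinom(n, 1, 0.4),
                    stringsAsFactors = FALSE)
  attr(tab, "tcr_features") <- "shannon"
  ab <- ablate_tcr_features(tab, c("shannon", "ggn"), ga = fast_ga(seed = 4))
  expect_s3_class(ab$with_tcr, "ga_svm")
  expect_identical(ab$without_tcr$feature_names, "ggn")
  # the with-TCR fit equals a plain train under the same seed
  plain <- ga_svm(label ~ shannon + ggn, tab, ga = fast_ga(seed = 4))
  expect_equal(ab$with_tcr$fitted, plain$fitted)
  expect_identical(ab$with_tcr$kernel, plain$kernel)
  expect_identical(ab$with_tcr$cost, plain$cost)
  # only the TCR feature carries signal here
  expect_gt(roc_auc(ab$with_tcr$fitted, lab)$auc,
            roc_auc(ab$without_tcr$fitted, lab)$auc)
  expect_error(ablate_tcr_features(tab, "shannon", ga = fast_ga()),
               "no features remain")
})
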