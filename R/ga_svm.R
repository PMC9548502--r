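# The nodule classifier: a support-vector machine whose hyperparameters
# (kernel family, cost C, RBF width gamma) are tuned by a genetic algorithm
# maximizing stratified cross-validated AUC, refit on the full training set,
# with a Platt sigmoid mapping decision scores to a bounded predicted value
# and a Youden cutoff for the benign/malignant call.

#' Genetic-algorithm search configuration
#'
#' Controls the hyperparameter search for [ga_svm()]. Individuals encode
#' `log2(C)`, `log2(gamma)` and the kernel family; fitness is the mean
#' stratified cross-validated AUC. The loop uses tournament selection
#' (size 2), uniform crossover, per-gene mutation within the bounds and
#' elitism, so the best fitness never decreases across generations.
#'
#' @param population_size Individuals per generation (default 30).
#' @param generations Number of generations (default 40).
#' @param crossover_rate Probability a mating pair recombines (default 0.8).
#' @param mutation_rate Per-gene mutation probability (default 0.1).
#' @param elitism Individuals copied unchanged into the next generation
#'   (default 2; must be below `population_size`).
#' @param c_range,gamma_range Search bounds on the log2 scale.
#' @param kernels Kernel families searched (subset of `"rbf"`, `"linear"`).
#' @param cv_folds Stratified cross-validation folds for the fitness
#'   (default 5).
#' @param seed Integer seed governing fold assignment and all GA randomness.
#' @return A validated list of class `"ga_config"`.
#' @export
ga_config <- function(population_size = 30L, generations = 40L,
                      crossover_rate = 0.8, mutation_rate = 0.1,
                      elitism = 2L, c_range = c(-5, 15),
                      gamma_range = c(-15, 3),
                      kernels = c("rbf", "linear"), cv_folds = 5L,
                      seed = 1L) {
  cfg <- as.list(environment())
  if (!is_count(cfg$population_size)) stopf("population_size must be >= 1")
  if (!is_count(cfg$generations)) stopf("generations must be >= 1")
  if (!is_prob(cfg$crossover_rate) || !is_prob(cfg$mutation_rate)) {
    stopf("crossover_rate and mutation_rate must be probabilities")
  }
  if (cfg$elitism < 1L || cfg$elitism >= cfg$population_size) {
    if (cfg$population_size > 1L) stopf("elitism must be in [1, population_size)")
    cfg$elitism <- 0L
  }
  for (f in c("c_range", "gamma_range")) {
    r <- cfg[[f]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] >= r[2]) {
      stopf("%s must be two finite increasing bounds", f)
    }
  }
  cfg$kernels <- match.arg(kernels, c("rbf", "linear"), several.ok = TRUE)
  if (!is_count(cfg$cv_folds) || cfg$cv_folds < 2L) {
    stopf("cv_folds must be >= 2")
  }
  structure(cfg, class = "ga_config")
}

# Stratified fold assignment: shuffles within class, deals round-robin.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Decision values oriented so that higher = second level (positive class).
oriented_decision <- function(model, x, positive) {
  pr <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1]][1L]
  if (first == positive) as.numeric(dv) else -as.numeric(dv)
}

svm_fit <- function(x, y, kernel, cost, gamma) {
  suppressWarnings(e1071::svm(
    x = as.matrix(x), y = y,
    kernel = if (kernel == "rbf") "radial" else kernel, cost = cost,
    gamma = if (kernel == "rbf") gamma else 1 / ncol(x),
    scale = FALSE, probability = FALSE
  ))
}

# Mean cross-validated AUC of one hyperparameter triple under fixed folds.
# Per-fold standardization uses the fold's training rows only.
cv_auc <- function(x, y, kernel, cost, gamma, fold, positive) {
  aucs <- c()
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(y[!tr])) < 2L) next
    ctr <- colMeans(x[tr, , drop = FALSE])
    sc <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sc[sc == 0] <- 1
    xt <- scale(x[tr, , drop = FALSE], ctr, sc)
    xv <- scale(x[!tr, , drop = FALSE], ctr, sc)
    m <- svm_fit(xt, y[tr], kernel, cost, gamma)
    dv <- oriented_decision(m, as.matrix(xv), positive)
    aucs <- c(aucs, roc_auc(dv, y[!tr], positive)$auc)
  }
  mean(aucs)
}

decode_individual <- function(ind) {
  list(kernel = ind$kernel, cost = 2^ind$c_log2, gamma = 2^ind$g_log2)
}

#' Genetic-algorithm hyperparameter search for the SVM
#'
#' Runs the GA over (kernel, C, gamma) with mean stratified cross-validated
#' AUC as fitness. Fold assignment is fixed once per call, so every
#' individual is scored on identical folds. Fully reproducible under
#' `ga$seed`.
#'
#' @param x Data frame or matrix of numeric features.
#' @param labels Two-class labels.
#' @param ga A [ga_config()].
#' @param positive Positive-class label (default `"malignant"`).
#' @return List with `best` (kernel, cost, gamma, cv_auc), `trajectory`
#'   (best fitness per generation, non-decreasing) and `folds`.
#' @export
ga_optimize <- function(x, labels, ga = ga_config(),
                        positive = "malignant") {
  stopifnot(inherits(ga, "ga_config"))
  x <- as.matrix(as.data.frame(lapply(as.data.frame(x), as.numeric)))
  y <- as_binary_label(labels, positive)
  if (min(table(y)) < ga$cv_folds) {
    stopf(paste("class with %d members is smaller than cv_folds = %d;",
                "reduce cv_folds"), min(table(y)), ga$cv_folds)
  }

  with_seed(ga$seed, {
    fold <- stratified_folds(y, ga$cv_folds)
    cache <- new.env(parent = emptyenv())
    fitness <- function(ind) {
      key <- sprintf("%s|%.10g|%.10g", ind$kernel, ind$c_log2,
                     if (ind$kernel == "rbf") ind$g_log2 else 0)
      if (!is.null(cache[[key]])) return(cache[[key]])
      par <- decode_individual(ind)
      val <- cv_auc(x, y, par$kernel, par$cost, par$gamma, fold, positive)
      cache[[key]] <- val
      val
    }
    random_individual <- function() {
      list(c_log2 = stats::runif(1, ga$c_range[1], ga$c_range[2]),
           g_log2 = stats::runif(1, ga$gamma_range[1], ga$gamma_range[2]),
           kernel = sample(ga$kernels, 1L))
    }
    mutate <- function(ind) {
      if (stats::runif(1) < ga$mutation_rate) {
        ind$c_log2 <- min(max(ind$c_log2 +
                                stats::rnorm(1, 0, diff(ga$c_range) / 10),
                              ga$c_range[1]), ga$c_range[2])
      }
      if (stats::runif(1) < ga$mutation_rate) {
        ind$g_log2 <- min(max(ind$g_log2 +
                                stats::rnorm(1, 0, diff(ga$gamma_range) / 10),
                              ga$gamma_range[1]), ga$gamma_range[2])
      }
      if (stats::runif(1) < ga$mutation_rate) {
        ind$kernel <- sample(ga$kernels, 1L)
      }
      ind
    }
    crossover <- function(a, b) {
      for (g in c("c_log2", "g_log2", "kernel")) {
        if (stats::runif(1) < 0.5) { tmp <- a[[g]]; a[[g]] <- b[[g]]; b[[g]] <- tmp }
      }
      list(a, b)
    }
    tournament <- function(fit) {
      pick <- sample.int(length(fit), 2L, replace = TRUE)
      pick[which.max(fit[pick])]
    }

    pop <- replicate(ga$population_size, random_individual(),
                     simplify = FALSE)
    fit <- vapply(pop, fitness, numeric(1))
    trajectory <- numeric(ga$generations)
    for (gen in seq_len(ga$generations)) {
      ord <- order(-fit)
      nextpop <- pop[ord[seq_len(min(ga$elitism, length(pop)))]]
      while (length(nextpop) < ga$population_size) {
        pa <- pop[[tournament(fit)]]
        pb <- pop[[tournament(fit)]]
        if (stats::runif(1) < ga$crossover_rate) {
          kids <- crossover(pa, pb)
        } else {
          kids <- list(pa, pb)
        }
        kids <- lapply(kids, mutate)
        nextpop <- c(nextpop, kids)
      }
      pop <- nextpop[seq_len(ga$population_size)]
      fit <- vapply(pop, fitness, numeric(1))
      trajectory[gen] <- max(fit)
    }
    best <- pop[[which.max(fit)]]
    out <- decode_individual(best)
    out$cv_auc <- max(fit)
    list(best = out, trajectory = trajectory, folds = fold)
  })
}

# Kernel matrix between rows of a and rows of b in the standardized space.
kernel_matrix <- function(a, b, kernel, gamma) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (kernel == "linear") return(a %*% t(b))
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  exp(-gamma * pmax(d2, 0))
}

# Self-contained decision function from the stored support-vector expansion.
model_decision <- function(object, xs) {
  k <- kernel_matrix(xs, object$sv, object$kernel, object$gamma)
  object$decision_sign * (as.vector(k %*% object$sv_coefs) - object$rho)
}

#' Fit the GA-tuned SVM nodule classifier
#'
#' The central model of the package. Given a cohort feature table and a
#' formula naming the diagnostic features (e.g.
#' `label ~ ggn + shannon + evenness`), the fit:
#' \enumerate{
#'   \item standardizes the features on the training data (stored for
#'     prediction);
#'   \item tunes the SVM kernel, cost and width by [ga_optimize()]
#'     (mean stratified cross-validated AUC as fitness);
#'   \item refits the SVM with the chosen hyperparameters on all rows;
#'   \item fits a Platt sigmoid on the training decision scores, giving a
#'     bounded predicted value in (0, 1);
#'   \item computes the Youden-optimal cutoff on the training predicted
#'     values (lowest cutoff on ties).
#' }
#' Everything downstream of the seed is deterministic, so refitting with
#' the same data and configuration reproduces the model exactly.
#'
#' @param formula Model formula, response = label column.
#' @param data Feature table (e.g. from [assemble_features()]).
#' @param ga A [ga_config()]; its seed drives all randomness.
#' @param positive Positive-class label (default `"malignant"`).
#' @return Object of class `"ga_svm"` with, among others,
#'   `hyperparameters`, `center`/`scale`, the support-vector expansion,
#'   `platt` coefficients, `youden_cutoff`, the GA `trajectory` and the
#'   training `fitted` values.
#' @seealso [predict.ga_svm()], [ablate_tcr_features()], [write_model()]
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(label = rep(c("benign", "malignant"), each = 20),
#'                 f1 = c(rnorm(20, 0), rnorm(20, 2)),
#'                 f2 = rnorm(40))
#' fit <- ga_svm(label ~ f1 + f2, d,
#'               ga = ga_config(population_size = 6, generations = 3,
#'                              cv_folds = 3, seed = 1))
#' fit
ga_svm <- function(formula, data, ga = ga_config(),
                   positive = "malignant") {
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  y_raw <- stats::model.response(mf)
  features <- attr(stats::terms(mf), "term.labels")
  if (!length(features)) stopf("the model needs at least one feature")
  x <- as.data.frame(lapply(mf[features], as.numeric))
  if (anyNA(x)) stopf("features contain missing values; impute first")
  y <- as_binary_label(y_raw, positive)

  center <- colMeans(x)
  scl <- vapply(x, stats::sd, numeric(1))
  scl[scl == 0] <- 1
  xs <- scale(as.matrix(x), center, scl)

  opt <- ga_optimize(xs, y, ga, positive)
  par <- opt$best
  m <- svm_fit(xs, y, par$kernel, par$cost, par$gamma)

  raw_dec <- as.vector(kernel_matrix(xs, m$SV, par$kernel,
                                     if (par$kernel == "rbf") par$gamma
                                     else 1 / ncol(xs)) %*% m$coefs) - m$rho
  oriented <- oriented_decision(m, xs, positive)
  sign_try <- c(1, -1)
  err <- vapply(sign_try, function(s) max(abs(s * raw_dec - oriented)),
                numeric(1))
  decision_sign <- sign_try[which.min(err)]

  y01 <- as.numeric(y == positive)
  # Platt scaling with smoothed targets (n+1)/(n+2), 1/(n+2): keeps the
  # sigmoid slope finite on separable training data
  n_pos <- sum(y01 == 1)
  n_neg <- sum(y01 == 0)
  t_sm <- ifelse(y01 == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  platt <- tryCatch({
    g <- suppressWarnings(stats::glm(t_sm ~ oriented,
                                     family = stats::binomial()))
    unname(stats::coef(g))
  }, error = function(e) c(0, 1))
  fitted_p <- stats::plogis(platt[1] + platt[2] * oriented)
  yc <- youden_cutoff(fitted_p, y, positive)

  structure(list(
    call = cl, formula = formula, feature_names = features,
    levels = levels(y), positive = positive,
    center = center, scale = scl,
    kernel = par$kernel, cost = par$cost,
    gamma = if (par$kernel == "rbf") par$gamma else 1 / ncol(xs),
    sv = unname(as.matrix(m$SV)), sv_coefs = as.vector(m$coefs),
    rho = m$rho, decision_sign = decision_sign,
    platt = platt, youden_cutoff = yc$cutoff, youden_J = yc$J,
    cv_auc = par$cv_auc, trajectory = opt$trajectory,
    fitted = fitted_p, decision = oriented, y = as.character(y_raw),
    seed = ga$seed, schema_version = 1L
  ), class = "ga_svm")
}

check_newdata <- function(object, newdata) {
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss)) {
    stopf("newdata is missing feature column(s): %s",
          paste(miss, collapse = ", "))
  }
  x <- as.data.frame(lapply(newdata[object$feature_names], as.numeric))
  if (anyNA(x)) stopf("newdata features contain missing values")
  scale(as.matrix(x), object$center, object$scale)
}

#' Predict from a fitted GA-tuned SVM
#'
#' Standardizes `newdata` with the training parameters, evaluates the
#' stored support-vector expansion and maps the decision score through the
#' training Platt sigmoid.
#'
#' @param object A [ga_svm()] fit (possibly restored by [read_model()]).
#' @param newdata Data frame containing the model's feature columns;
#'   defaults to the training data's fitted values.
#' @param type `"response"` (bounded predicted value, default),
#'   `"decision"` (raw SVM decision score) or `"class"` (label at the
#'   Youden cutoff).
#' @param ... Unused.
#' @return Numeric vector, or factor for `type = "class"`.
#' @export
predict.ga_svm <- function(object, newdata = NULL,
                           type = c("response", "decision", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    dec <- object$decision
  } else {
    dec <- model_decision(object, check_newdata(object, newdata))
  }
  p <- stats::plogis(object$platt[1] + object$platt[2] * dec)
  switch(type,
         decision = dec,
         response = p,
         class = factor(ifelse(p >= object$youden_cutoff,
                               object$levels[2L], object$levels[1L]),
                        levels = object$levels))
}

#' @export
fitted.ga_svm <- function(object, ...) object$fitted

#' @export
residuals.ga_svm <- function(object, ...) {
  as.numeric(object$y == object$positive) - object$fitted
}

#' @export
coef.ga_svm <- function(object, ...) {
  out <- c(cost = object$cost,
           gamma = if (object$kernel == "rbf") object$gamma else NA_real_)
  if (object$kernel == "linear") {
    w <- object$decision_sign * drop(t(object$sv) %*% object$sv_coefs)
    names(w) <- object$feature_names
    out <- c(out, w)
  }
  out
}

#' @export
print.ga_svm <- function(x, digits = 3, ...) {
  cat("GA-tuned SVM nodule classifier\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Features: %s\n", paste(x$feature_names, collapse = ", ")))
  cat(sprintf("Kernel %s, C = %.4g%s\n", x$kernel, x$cost,
              if (x$kernel == "rbf") sprintf(", gamma = %.4g", x$gamma)
              else ""))
  cat(sprintf("CV AUC %.*f; Youden cutoff %.*f (J = %.*f)\n",
              digits, x$cv_auc, digits, x$youden_cutoff, digits, x$youden_J))
  invisible(x)
}

#' @export
summary.ga_svm <- function(object, ...) {
  train_eval <- evaluation_report(object$fitted, object$y,
                                  cutoff = object$youden_cutoff,
                                  positive = object$positive)
  structure(list(fit = object, train_eval = train_eval),
            class = "summary.ga_svm")
}

#' @export
print.summary.ga_svm <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("GA trajectory: %d generations, fitness %.*f -> %.*f\n",
              length(x$fit$trajectory), digits, x$fit$trajectory[1],
              digits, max(x$fit$trajectory)))
  cat("Training-set evaluation:\n")
  print(x$train_eval, digits = digits)
  invisible(x)
}

#' Plot a fitted GA-tuned SVM
#'
#' Two base-graphics panels: the GA best-fitness trajectory and the
#' training ROC curve.
#' @param x A [ga_svm()] fit.
#' @param ... Passed to `plot`.
#' @export
plot.ga_svm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(seq_along(x$trajectory), x$trajectory, type = "s",
       xlab = "generation", ylab = "best CV AUC",
       main = "GA trajectory", ...)
  roc <- roc_auc(x$fitted, x$y, x$positive)
  plot(roc$roc_points$fpr, roc$roc_points$tpr, type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("training ROC (AUC %.3f)", roc$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Paired fits with and without the TCR-derived features
#'
#' Trains the classifier twice under identical seeds and fold assignments:
#' once on the supplied feature list, once with every TCR-derived column
#' removed, quantifying how much diagnostic signal the repertoire features
#' contribute.
#'
#' @param table Feature table from [assemble_features()].
#' @param features Character vector of candidate feature columns.
#' @param tcr_features TCR-derived columns; defaults to the table's
#'   `"tcr_features"` attribute.
#' @param ga A [ga_config()].
#' @param positive Positive-class label.
#' @return List of class `"ga_svm_ablation"` with `with_tcr` and
#'   `without_tcr` fits.
#' @export
ablate_tcr_features <- function(table, features,
                                tcr_features = attr(table, "tcr_features"),
                                ga = ga_config(), positive = "malignant") {
  without <- setdiff(features, tcr_features)
  if (!length(without)) {
    stopf("no features remain after removing TCR-derived columns")
  }
  f_with <- stats::reformulate(features, response = "label")
  f_without <- stats::reformulate(without, response = "label")
  structure(list(
    with_tcr = ga_svm(f_with, table, ga = ga, positive = positive),
    without_tcr = ga_svm(f_without, table, ga = ga, positive = positive)
  ), class = "ga_svm_ablation")
}

#' Serialize a fitted model to a JSON artifact
#'
#' Writes every component needed for prediction (features, scaling,
#' support-vector expansion, Platt coefficients, Youden cutoff, GA
#' trajectory) as schema-versioned JSON at full numeric precision; the file
#' round-trips through [read_model()].
#'
#' @param object A [ga_svm()] fit.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(object, path) {
  stopifnot(inherits(object, "ga_svm"))
  payload <- object[c("feature_names", "levels", "positive", "kernel",
                      "cost", "gamma", "sv_coefs", "rho", "decision_sign",
                      "platt", "youden_cutoff", "youden_J", "cv_auc",
                      "trajectory", "fitted", "decision", "y", "seed",
                      "schema_version")]
  payload$center <- as.list(object$center)
  payload$scale <- as.list(object$scale)
  payload$sv <- object$sv
  payload$formula <- deparse(object$formula)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Restore a model written by [write_model()]
#' @param path JSON artifact path.
#' @return A `"ga_svm"` object usable with [predict.ga_svm()].
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$schema_version) || p$schema_version != 1L) {
    stopf("unsupported model schema in %s", path)
  }
  obj <- p
  obj$center <- unlist(p$center)
  obj$scale <- unlist(p$scale)
  obj$sv <- as.matrix(p$sv)
  if (ncol(obj$sv) == 1L && length(p$feature_names) > 1L) {
    obj$sv <- matrix(obj$sv, nrow = length(p$sv_coefs), byrow = TRUE)
  }
  obj$formula <- stats::as.formula(p$formula)
  obj$call <- NULL
  structure(obj, class = "ga_svm")
}
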