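# Exhaustive covariate-subset model search: three classifiers, dual
# cross-validated AUC (leave-one-out and a fixed leave-two-out partition),
# Mason-Graham significance with FDR correction across the run, best-model
# feature frequencies, and precision-weighted aggregation of the logistic
# coefficients over all tested models.

#' Dummy-encode the cohort covariates
#'
#' Reference-level encoding of the categorical covariates with the fixed
#' column layout of the aggregated-coefficient table: continuous columns
#' F1-F5, Age, Ki67, ER, ADC, PgR, PET_SUV, then dummies Grade_3,
#' HER2 (positive vs negative), Shape_I, Shape_O (reference R), Margin_I
#' (reference S), IntEnh_E, IntEnh_O (reference RE), Curve_III (III vs
#' I/II), Type_MC, Type_MF (reference U). Only covariates present in the
#' table are encoded; an unseen categorical level is an error.
#'
#' @param table cohort data.frame (see [generate_cohort()]).
#' @return A list: `x` (numeric design matrix, no intercept), `map` (named
#'   list covariate -> its design column names).
#' @export
encode_dummies <- function(table) {
  cont_order <- c("F1", "F2", "F3", "F4", "F5", "Age", "Ki67", "ER",
                  "ADC", "PgR", "PET_SUV")
  dummy_rules <- list(
    Grade  = list(levels = c("2", "3"),
                  cols = c("Grade_3"), values = list("3")),
    HER2   = list(levels = c("pos", "neg"),
                  cols = c("HER2"), values = list("pos")),
    Shape  = list(levels = c("I", "O", "R"),
                  cols = c("Shape_I", "Shape_O"), values = list("I", "O")),
    Margin = list(levels = c("I", "S"),
                  cols = c("Margin_I"), values = list("I")),
    IntEnh = list(levels = c("E", "O", "RE"),
                  cols = c("IntEnh_E", "IntEnh_O"), values = list("E", "O")),
    Curve  = list(levels = c("I", "II", "III"),
                  cols = c("Curve_III"), values = list("III")),
    Type   = list(levels = c("MC", "MF", "U"),
                  cols = c("Type_MC", "Type_MF"), values = list("MC", "MF")))
  cols <- list(); map <- list()
  for (nm in intersect(cont_order, names(table))) {
    cols[[nm]] <- as.numeric(table[[nm]])
    map[[nm]] <- nm
  }
  for (nm in intersect(names(dummy_rules), names(table))) {
    rule <- dummy_rules[[nm]]
    v <- as.character(table[[nm]])
    bad <- setdiff(unique(v), rule$levels)
    if (length(bad))
      stop("unseen level(s) in ", nm, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (i in seq_along(rule$cols))
      cols[[rule$cols[i]]] <- as.numeric(v == rule$values[[i]])
    map[[nm]] <- rule$cols
  }
  x <- do.call(cbind, cols)
  list(x = x, map = map)
}

#' The five published variable groups
#'
#' `G1` clinical + radiological, `Rad` the five radiomic features, `Hist`
#' the histological covariates, `NoRad = G1 + Hist`, `All = G1 + Rad +
#' Hist`.
#'
#' @return Named list of covariate name vectors.
#' @export
variable_groups <- function() {
  g1 <- c("Age", "ADC", "PET_SUV", "Grade", "Shape", "Margin", "IntEnh",
          "Curve", "Type")
  rad <- paste0("F", 1:5)
  hist <- c("Ki67", "ER", "PgR", "HER2")
  list(G1 = g1, Rad = rad, Hist = hist,
       NoRad = c(g1, hist), All = c(g1, rad, hist))
}

# Fold assignments. "loo" = one subject per fold; "fold2" = one fixed
# seeded random partition into folds of (as far as possible) 2 subjects.
make_folds <- function(n, scheme = c("loo", "fold2"), seed = 1) {
  scheme <- match.arg(scheme)
  if (scheme == "loo") return(seq_len(n))
  K <- ceiling(n / 2)
  with_seed(derive_seed(seed, "fold2"), {
    fold <- integer(n)
    fold[sample.int(n)] <- rep(seq_len(K), each = 2, length.out = n)
    fold
  })
}

subset_design <- function(enc, members, intercept = TRUE) {
  cols <- unlist(enc$map[members], use.names = FALSE)
  x <- enc$x[, cols, drop = FALSE]
  if (intercept) x <- cbind(`(Intercept)` = 1, x)
  x
}

#' Out-of-fold classifier scores
#'
#' Cross-validated continuous scores for one classifier and covariate
#' subset: predicted probability (logistic regression), raw regression
#' output on the 0/1 outcome (linear SVR, with per-fold standardization
#' fitted on the training folds), or positive-class vote fraction (random
#' forest). The leave-one-out scheme has one fold per subject; the
#' leave-two-out scheme uses one fixed seeded partition into folds of two.
#'
#' @param table cohort data.frame with a `pCR` column.
#' @param members covariate names forming the subset.
#' @param classifier `"Logit"`, `"SVR"` or `"RF"`.
#' @param scheme `"loo"` or `"fold2"`.
#' @param seed seed driving the fold partition and the forest.
#' @param hyper list of tuned hyperparameters (`cost`, `ntree`).
#' @param enc optional precomputed [encode_dummies()] result.
#' @return Numeric score vector, one per subject.
#' @export
cv_scores <- function(table, members, classifier = c("Logit", "SVR", "RF"),
                      scheme = c("loo", "fold2"), seed = 1,
                      hyper = list(cost = 1, ntree = 500), enc = NULL) {
  classifier <- match.arg(classifier)
  scheme <- match.arg(scheme)
  enc <- enc %||% encode_dummies(table)
  y <- table$pCR
  n <- length(y)
  fold <- make_folds(n, scheme, seed)
  if (classifier == "Logit") {
    x <- subset_design(enc, members)
    return(as.numeric(logit_cv_scores_cpp(x, y, as.integer(fold))))
  }
  x <- subset_design(enc, members, intercept = FALSE)
  scores <- numeric(n)
  with_seed(derive_seed(seed, paste0("cv-", classifier, "-", scheme)), {
    for (k in unique(fold)) {
      tr <- fold != k; te <- !tr
      if (classifier == "SVR") {
        keep <- apply(x[tr, , drop = FALSE], 2, function(v) var(v) > 0)
        if (!any(keep)) { scores[te] <- mean(y[tr]); next }
        fit <- suppressWarnings(e1071::svm(
          x = x[tr, keep, drop = FALSE], y = y[tr], type = "eps-regression",
          kernel = "linear", cost = hyper$cost, scale = TRUE))
        scores[te] <- predict(fit, x[te, keep, drop = FALSE])
      } else {
        fit <- randomForest::randomForest(
          x = x[tr, , drop = FALSE], y = factor(y[tr], levels = c(0, 1)),
          ntree = hyper$ntree)
        scores[te] <- predict(fit, x[te, , drop = FALSE],
                              type = "prob")[, "1"]
      }
    }
  })
  scores
}

#' Tune the SVR cost / RF tree count on the full-group model
#'
#' Grid search maximizing the leave-one-out AUC of the model containing
#' every covariate of the group; the winning value is then frozen for the
#' entire subset search. Ties go to the smallest grid value.
#'
#' @inheritParams cv_scores
#' @param group covariate names of the full group.
#' @param cost_grid,ntree_grid hyperparameter grids.
#' @return `list(cost =, ntree =)`; logistic regression has none to tune.
#' @export
tune_hyperparameters <- function(table, group,
                                 classifier = c("Logit", "SVR", "RF"),
                                 seed = 1,
                                 cost_grid = 2^seq(-5, 5, by = 2),
                                 ntree_grid = c(100, 250, 500, 1000),
                                 enc = NULL) {
  classifier <- match.arg(classifier)
  enc <- enc %||% encode_dummies(table)
  out <- list(cost = 1, ntree = 500)
  if (classifier == "Logit") return(out)
  grid <- if (classifier == "SVR") sort(unique(cost_grid))
          else sort(unique(ntree_grid))
  perf <- vapply(grid, function(g) {
    h <- if (classifier == "SVR") list(cost = g, ntree = 500)
         else list(cost = 1, ntree = g)
    s <- cv_scores(table, group, classifier, "loo", seed, h, enc)
    auc(s, table$pCR)
  }, numeric(1))
  best <- grid[which.max(perf)]       # which.max takes the first maximum
  if (classifier == "SVR") out$cost <- best else out$ntree <- best
  out
}

#' Evaluate one classifier + covariate subset
#'
#' Dual cross-validated AUC: the mean of the leave-one-out AUC and the
#' fixed leave-two-out AUC. The DeLong confidence interval and the
#' Mason-Graham p-value are computed on the pooled leave-one-out scores
#' (one out-of-fold score per subject); FDR adjustment is deferred to the
#' group-level search.
#'
#' @inheritParams cv_scores
#' @param level confidence level for the AUC interval.
#' @return A list: `auc_loo`, `auc_fold2`, `auc_mean`, `ci`, `p_raw`.
#' @export
evaluate_model <- function(table, members, classifier = "Logit", seed = 1,
                           hyper = list(cost = 1, ntree = 500),
                           level = 0.95, enc = NULL) {
  enc <- enc %||% encode_dummies(table)
  y <- table$pCR
  s_loo <- cv_scores(table, members, classifier, "loo", seed, hyper, enc)
  s_2 <- cv_scores(table, members, classifier, "fold2", seed, hyper, enc)
  a1 <- auc(s_loo, y); a2 <- auc(s_2, y)
  ci <- tryCatch(suppressWarnings(auc_ci(s_loo, y, level)),
                 error = function(e) c(lo = NA_real_, hi = NA_real_))
  list(auc_loo = a1, auc_fold2 = a2, auc_mean = (a1 + a2) / 2,
       ci = ci, p_raw = mason_graham_p(s_loo, y))
}

# Full-data logistic fit of one subset: coefficients and standard errors
# per design column (used for coefficient aggregation).
full_logit_fit <- function(enc, members, y) {
  x <- subset_design(enc, members)
  f <- logit_fit_cpp(x, y)
  nm <- colnames(x)[-1]
  list(m = setNames(as.numeric(f$coefficients[-1]), nm),
       se = setNames(as.numeric(f$se[-1]), nm))
}

#' Aggregate logistic coefficients over many fitted models
#'
#' For each design column j, combines the coefficients of every fit whose
#' subset contains j into a precision-weighted mean. The default follows
#' the published formula `m_j = sum_i(m_ij / s_ij^2) / sum_i(1 / s_ij)`
#' (numerator weights `1/s^2`, denominator `sum 1/s`, a weighted mean of
#' the z-like ratios `m_ij/s_ij`); `aggregation = "inverse_variance"`
#' gives the textbook `sum(m/s^2) / sum(1/s^2)` variant. Values outside
#' \[-1, 1\] are read as relevant positive/negative association with the
#' outcome.
#'
#' @param fits list of fits, each `list(m =, se =)` named per design
#'   column.
#' @param aggregation `"printed"` (default) or `"inverse_variance"`.
#' @return Named vector of aggregated coefficients; columns appearing in
#'   no fit are `NA`.
#' @export
aggregate_coefficients <- function(fits, aggregation = c("printed",
                                                         "inverse_variance")) {
  aggregation <- match.arg(aggregation)
  all_nm <- unique(unlist(lapply(fits, function(f) names(f$m))))
  num <- den <- setNames(numeric(length(all_nm)), all_nm)
  for (f in fits) {
    ok <- is.finite(f$se) & f$se > 0
    nm <- names(f$m)[ok]
    num[nm] <- num[nm] + f$m[ok] / f$se[ok]^2
    den[nm] <- den[nm] + if (aggregation == "printed") 1 / f$se[ok]
                         else 1 / f$se[ok]^2
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Exhaustive covariate-subset search within a variable group
#'
#' Enumerates every non-empty subset of the group's covariates (dummies of
#' a categorical move together), evaluates each with
#' [evaluate_model()], ranks by mean dual-CV AUC, FDR-adjusts the
#' Mason-Graham p-values across the run, and summarizes the six best
#' models: per-covariate inclusion frequency and, from the full-data
#' logistic fits of all tested subsets, the aggregated coefficients. When
#' the subset count exceeds `subset_cap`, a seeded uniform sample of
#' `subset_cap` subsets is evaluated instead and the truncation recorded.
#'
#' @inheritParams cv_scores
#' @param group group name from [variable_groups()] or a character vector
#'   of covariate names.
#' @param subset_cap maximum number of subsets evaluated (default 2^14).
#' @param hyper tuned hyperparameters; `NULL` tunes via
#'   [tune_hyperparameters()] for SVR/RF.
#' @param aggregation coefficient-aggregation variant, see
#'   [aggregate_coefficients()].
#' @return A `search_report`: `group`, `classifier`, `models` (ranked
#'   data.frame), `best6`, `frequency`, `m_agg`, `mean_p_adj_best6`,
#'   `truncated`, `seed`, `hyper`.
#' @export
run_group_search <- function(table, group, classifier = "Logit",
                             subset_cap = 2^14, seed = 1, hyper = NULL,
                             level = 0.95,
                             aggregation = "printed") {
  members <- if (is.character(group) && length(group) == 1 &&
                 group %in% names(variable_groups()))
    variable_groups()[[group]] else group
  group_name <- if (length(group) == 1) group else "custom"
  members <- intersect(members, names(table))
  if (!length(members)) stop("empty variable group", call. = FALSE)
  enc <- encode_dummies(table)
  y <- table$pCR
  if (is.null(hyper))
    hyper <- tune_hyperparameters(table, members, classifier, seed, enc = enc)

  k <- length(members)
  total <- 2^k - 1
  truncated <- total > subset_cap
  ids <- if (truncated)
    with_seed(derive_seed(seed, "subset-sample"),
              sample(seq_len(total), subset_cap))
  else seq_len(total)
  bits <- function(id) members[bitwAnd(id, 2^(seq_len(k) - 1)) > 0]

  rows <- vector("list", length(ids))
  fits <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    mem <- bits(ids[i])
    ev <- evaluate_model(table, mem, classifier, seed, hyper, level, enc)
    rows[[i]] <- data.frame(
      subset = paste(sort(mem), collapse = "+"), size = length(mem),
      auc_loo = ev$auc_loo, auc_fold2 = ev$auc_fold2,
      auc_mean = ev$auc_mean, ci_lo = ev$ci[1], ci_hi = ev$ci[2],
      p_raw = ev$p_raw, stringsAsFactors = FALSE)
    fits[[i]] <- full_logit_fit(enc, mem, y)
  }
  models <- do.call(rbind, rows)
  models$p_adj <- benjamini_hochberg(models$p_raw)
  ord <- order(-models$auc_mean, models$size, models$subset)
  models <- models[ord, ]
  rownames(models) <- NULL
  best6 <- head(models, 6L)
  freq <- vapply(members, function(m)
    mean(vapply(strsplit(best6$subset, "+", fixed = TRUE),
                function(s) m %in% s, logical(1))), numeric(1))
  structure(list(group = group_name, classifier = classifier,
                 models = models, best6 = best6, frequency = freq,
                 m_agg = aggregate_coefficients(fits, aggregation),
                 mean_p_adj_best6 = mean(best6$p_adj),
                 truncated = truncated, n_evaluated = length(ids),
                 seed = seed, hyper = hyper),
            class = "search_report")
}

#' @export
print.search_report <- function(x, ...) {
  cat("search_report:", x$group, "/", x$classifier, "-", x$n_evaluated,
      "subsets", if (x$truncated) "(sampled)" else "(exhaustive)", "\n")
  cat("best model:", x$best6$subset[1],
      sprintf("auc_mean = %.3f", x$best6$auc_mean[1]), "\n")
  cat("mean adjusted p (best 6):",
      format(x$mean_p_adj_best6, digits = 3), "\n")
  invisible(x)
}
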