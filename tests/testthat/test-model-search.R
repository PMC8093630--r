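small_cohort <- function(seed = 7) generate_cohort(synthetic_config(seed = seed))

test_that("dummy encoding reproduces the fixed 21-column layout", {
  coh <- small_cohort()
  enc <- encode_dummies(coh)
  expect_identical(colnames(enc$x),
                   c("F1", "F2", "F3", "F4", "F5", "Age", "Ki67", "ER",
                     "ADC", "PgR", "PET_SUV", "Grade_3", "HER2", "Shape_I",
                     "Shape_O", "Margin_I", "IntEnh_E", "IntEnh_O",
                     "Curve_III", "Type_MC", "Type_MF"))
  expect_equal(ncol(enc$x), 21L)
  # reference levels encode to zero rows
  coh2 <- coh; coh2$Grade <- "2"
  expect_true(all(encode_dummies(coh2)$x[, "Grade_3"] == 0))
  r_rows <- coh$Shape == "R"
  expect_true(all(enc$x[r_rows, c("Shape_I", "Shape_O")] == 0))
  expect_true(all(enc$x[coh$Curve != "III", "Curve_III"] == 0))
  coh3 <- coh; coh3$HER2[1] <- "maybe"
  expect_error(encode_dummies(coh3), "unseen level")
})

test_that("variable groups follow the published definitions", {
  g <- variable_groups()
  expect_setequal(g$G1, c("Age", "ADC", "PET_SUV", "Grade", "Shape", "Margin",
                          "IntEnh", "Curve", "Type"))
  expect_identical(g$Rad, paste0("F", 1:5))
  expect_setequal(g$Hist, c("Ki67", "ER", "PgR", "HER2"))
  expect_setequal(g$NoRad, union(g$G1, g$Hist))
  expect_setequal(g$All, union(g$NoRad, g$Rad))
})

test_that("fold layouts: LOO has one subject per fold, fold2 is a seeded pairing", {
  f1 <- pcrradiomics:::make_folds(60, "loo")
  expect_identical(f1, 1:60)
  f2 <- pcrradiomics:::make_folds(60, "fold2", seed = 3)
  expect_equal(sort(unique(f2)), 1:30)
  expect_true(all(table(f2) == 2))
  expect_identical(f2, pcrradiomics:::make_folds(60, "fold2", seed = 3))
  expect_false(identical(f2, pcrradiomics:::make_folds(60, "fold2", seed = 4)))
})

test_that("logistic CV scores equal a per-fold glm oracle", {
  set.seed(40)
  toy <- data.frame(a = rnorm(10), b = rnorm(10),
                    pCR = rep(c(1, 0), 5))
  # rename to known continuous covariates so the encoder accepts them
  names(toy)[1:2] <- c("Age", "ADC")
  s <- cv_scores(toy, c("Age", "ADC"), "Logit", "loo")
  oracle <- vapply(1:10, function(i) {
    fit <- glm(pCR ~ Age + ADC, data = toy[-i, ], family = binomial())
    unname(predict(fit, toy[i, ], type = "response"))
  }, numeric(1))
  expect_equal(s, oracle, tolerance = 1e-6)
})

test_that("SVR and RF cv scores are deterministic given the seed", {
  coh <- small_cohort()
  for (cl in c("SVR", "RF")) {
    s1 <- cv_scores(coh, c("Ki67", "ER"), cl, "fold2", seed = 5,
                    hyper = list(cost = 1, ntree = 50))
    s2 <- cv_scores(coh, c("Ki67", "ER"), cl, "fold2", seed = 5,
                    hyper = list(cost = 1, ntree = 50))
    expect_identical(s1, s2)
  }
})

test_that("evaluate_model averages the two CV schemes and detects separation", {
  coh <- small_cohort()
  ev <- evaluate_model(coh, c("Ki67", "ER"), "Logit", seed = 2)
  expect_equal(ev$auc_mean, (ev$auc_loo + ev$auc_fold2) / 2)
  expect_true(ev$p_raw > 0 && ev$p_raw <= 1)
  # a perfectly separating covariate drives the AUC to 1
  sep <- coh
  sep$Age <- ifelse(sep$pCR == 1, 100, 10)
  evs <- evaluate_model(sep, "Age", "Logit", seed = 2)
  expect_equal(evs$auc_mean, 1)
})

test_that("null scores give an AUC centred on one half", {
  set.seed(41)
  y <- rep(c(1, 0), c(20, 40))
  aucs <- replicate(200, {
    s <- rnorm(60)
    (auc(s, y) + auc(s, y)) / 2
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("a 3-covariate group search enumerates exactly 7 subsets", {
  coh <- small_cohort()
  r <- run_group_search(coh, c("Age", "Ki67", "ER"), classifier = "Logit",
                        seed = 1)
  expect_equal(nrow(r$models), 7L)
  expect_false(r$truncated)
  # rank list is a permutation of the evaluated subsets
  expect_setequal(r$models$subset,
                  c("Age", "Ki67", "ER", "Age+Ki67", "Age+ER", "ER+Ki67",
                    "Age+ER+Ki67"))
  expect_true(all(diff(r$models$auc_mean) <= 1e-12))
  expect_true(all(r$frequency >= 0 & r$frequency <= 1))
  # frequency definition: covariate in all six best models
  infreq <- vapply(strsplit(r$best6$subset, "+", fixed = TRUE),
                   function(s) "ER" %in% s, logical(1))
  expect_equal(unname(r$frequency["ER"]), mean(infreq))
})

test_that("the subset cap triggers seeded sampling and is reported", {
  coh <- small_cohort()
  r <- run_group_search(coh, "Hist", classifier = "Logit", subset_cap = 5,
                        seed = 9)
  expect_true(r$truncated)
  expect_equal(nrow(r$models), 5L)
  r2 <- run_group_search(coh, "Hist", classifier = "Logit", subset_cap = 5,
                         seed = 9)
  expect_identical(r$models, r2$models)
})

test_that("coefficient aggregation implements the precision-weighted formula", {
  f1 <- list(m = c(Age = 2), se = c(Age = 1))
  expect_equal(aggregate_coefficients(list(f1)), c(Age = 2))
  f2 <- list(m = c(Age = 1), se = c(Age = 1))
  expect_equal(aggregate_coefficients(list(f2, f2)), c(Age = 1))
  # summation oracle on a random collection
  set.seed(42)
  fits <- lapply(1:20, function(i) {
    nm <- sample(c("Age", "ADC", "Ki67"), sample(1:3, 1))
    list(m = setNames(rnorm(length(nm)), nm),
         se = setNames(runif(length(nm), 0.5, 2), nm))
  })
  agg <- aggregate_coefficients(fits)
  for (nm in names(agg)) {
    num <- den <- 0
    for (f in fits) if (nm %in% names(f$m)) {
      num <- num + f$m[[nm]] / f$se[[nm]]^2
      den <- den + 1 / f$se[[nm]]
    }
    expect_equal(unname(agg[nm]), num / den)
  }
  # inverse-variance variant
  f3 <- list(m = c(Age = 2), se = c(Age = 2))
  f4 <- list(m = c(Age = 0), se = c(Age = 1))
  iv <- aggregate_coefficients(list(f3, f4), aggregation = "inverse_variance")
  expect_equal(unname(iv["Age"]), (2 / 4) / (1 / 4 + 1))
  # absent covariate flagged
  agg2 <- aggregate_coefficients(list(list(m = c(Age = 1), se = c(Age = NaN))))
  expect_true(is.na(agg2["Age"]))
})

test_that("hyperparameter tuning freezes the argmax of the full-group LOOCV AUC", {
  coh <- small_cohort()
  h1 <- tune_hyperparameters(coh, c("Ki67", "ER"), "SVR", seed = 1,
                             cost_grid = 0.5)
  expect_equal(h1$cost, 0.5)
  h2 <- tune_hyperparameters(coh, c("Ki67", "ER"), "SVR", seed = 1,
                             cost_grid = c(0.5, 0.5, 2, 2))
  h3 <- tune_hyperparameters(coh, c("Ki67", "ER"), "SVR", seed = 1,
                             cost_grid = c(0.5, 2))
  expect_equal(h2, h3)
  # argmax re-check for RF on a small grid
  h4 <- tune_hyperparameters(coh, c("Ki67", "ER"), "RF", seed = 1,
                             ntree_grid = c(30, 60))
  perf <- vapply(c(30, 60), function(nt) {
    s <- cv_scores(coh, c("Ki67", "ER"), "RF", "loo", seed = 1,
                   hyper = list(cost = 1, ntree = nt))
    auc(s, coh$pCR)
  }, numeric(1))
  expect_equal(h4$ntree, c(30, 60)[which.max(perf)])
})

test_that("search results do not depend on subject order beyond the seeded folds", {
  coh <- small_cohort()
  r1 <- run_group_search(coh, c("Ki67", "ER"), classifier = "Logit", seed = 5)
  perm <- withr::with_seed(1, sample(nrow(coh)))
  # permuting subjects changes fold membership only through the seeded
  # partition; LOO quantities must be identical
  s1 <- cv_scores(coh, c("Ki67", "ER"), "Logit", "loo")
  s2 <- cv_scores(coh[perm, ], c("Ki67", "ER"), "Logit", "loo")
  expect_equal(auc(s1, coh$pCR), auc(s2, coh$pCR[perm]), tolerance = 1e-9)
  expect_equal(sort(r1$models$subset), sort(c("Ki67", "ER", "ER+Ki67")))
})
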