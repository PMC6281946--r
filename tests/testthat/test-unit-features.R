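test_that("standardization centres and scales with sample sd, dropping constants", {
  tab <- data.frame(unit_label = c("m", "m"), duration = c(1, 3),
                    peak_freq = c(5, 5))
  expect_warning(std <- standardize_features(tab), "constant")
  # sample (n-1) sd of {1, 3} is sqrt(2)
  expect_equal(std$duration, c(-1, 1) / sqrt(2))
  expect_false("peak_freq" %in% names(std))
  expect_error(standardize_features(tab[1, ]), "at least 2")
  allc <- data.frame(unit_label = c("m", "m"), duration = c(1, 1))
  expect_error(suppressWarnings(standardize_features(allc)), "constant")
})

test_that("unit-type centroids are per-feature medians", {
  tab <- data.frame(unit_label = rep(c("m", "w"), c(3, 1)),
                    duration = c(0, 0, 10, 5), peak_freq = c(1, 2, 3, 4))
  std <- standardize_features(tab)
  cent <- unit_type_centroids(std)
  expect_equal(rownames(cent), c("m", "w"))
  # median robustness: centre of {0, 0, 10} is 0 (pre-standardization),
  # so the standardized centroid equals the standardized 0
  expect_equal(cent["m", "duration"],
               (0 - mean(tab$duration)) / sd(tab$duration))
  # single-row label: centroid equals that row
  expect_equal(cent["w", ], unlist(std[4, c("duration", "peak_freq")]),
               ignore_attr = TRUE)
})

test_that("substitution costs normalize to [0, 1] with beta scaling", {
  cent <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(c("a", "b", "c"), "f"))
  cm <- substitution_costs(cent, beta = 1)
  expect_s3_class(cm, "cost_matrix")
  expect_equal(cm$costs["a", "b"], 0.5)
  expect_equal(cm$costs["a", "c"], 1.0)
  expect_equal(cm$costs["b", "c"], 0.5)
  expect_equal(diag(cm$costs), c(a = 0, b = 0, c = 0))
  expect_equal(max(cm$costs), 1)
  # beta = 0 collapses to the unweighted analysis
  cm0 <- substitution_costs(cent, beta = 0)
  off <- cm0$costs[upper.tri(cm0$costs)]
  expect_true(all(off == 1))
  # monotone in beta: larger exponent never increases a cost
  cm2 <- substitution_costs(cent, beta = 2)
  expect_true(all(cm2$costs <= cm$costs + 1e-12))
  expect_error(substitution_costs(cent[1, , drop = FALSE]), "at least 2")
  same <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "f"))
  expect_error(substitution_costs(same), "identical")
})

test_that("costs are invariant to feature order and common rescaling", {
  meas <- synthetic_measurements(seed = 5)
  std <- standardize_features(meas)
  cent <- unit_type_centroids(std)
  cm1 <- substitution_costs(cent)
  cm2 <- substitution_costs(cent[, rev(colnames(cent))])
  expect_equal(cm2$costs, cm1$costs)
  cm3 <- substitution_costs(3 * cent + 7)
  expect_equal(cm3$costs, cm1$costs)
})

test_that("classification-tree validation reports root error and agreement", {
  # perfectly separable two-class problem
  tab <- data.frame(unit_label = rep(c("lo", "hi"), each = 20),
                    peak_freq = c(rnorm(20, 100, 5), rnorm(20, 1000, 5)),
                    duration = runif(40, 0.1, 0.5))
  fit <- fit_classification_tree(standardize_features(tab), seed = 1)
  expect_s3_class(fit, "unit_cart")
  expect_equal(fit$agreement, 1.0)
  expect_equal(fit$root_error, 0.5)

  # 90/10 split: trivial-classifier error is the minority share
  tab2 <- data.frame(unit_label = rep(c("a", "b"), c(90, 10)),
                     peak_freq = c(rnorm(90, 100), rnorm(10, 1000)),
                     duration = runif(100))
  fit2 <- fit_classification_tree(standardize_features(tab2), seed = 1)
  expect_equal(fit2$root_error, 0.10)

  # labels permuted at random against the features: cross-validated
  # agreement sits at chance level for 2 balanced classes
  set.seed(2)
  tab3 <- data.frame(unit_label = sample(rep(c("a", "b"), 30)),
                     peak_freq = rep(1, 60), duration = seq_len(60))
  fit3 <- suppressWarnings(
    fit_classification_tree(standardize_features(tab3), seed = 3))
  cv_agreement <- 1 - fit3$cv_error * fit3$root_error
  expect_gt(cv_agreement, 0.5 - 3 * sqrt(0.25 / 60))
  expect_lt(cv_agreement, 0.5 + 3 * sqrt(0.25 / 60))

  # reproducible under a fixed fold seed
  fit_a <- fit_classification_tree(standardize_features(tab2), seed = 9)
  fit_b <- fit_classification_tree(standardize_features(tab2), seed = 9)
  expect_equal(fit_a$cv_error, fit_b$cv_error)

  std <- standardize_features(tab)
  expect_error(fit_classification_tree(std, labels = rep("x", 40)),
               "2 unit classes")
  expect_error(fit_classification_tree(std, k_folds = 100), "exceeds")
})
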