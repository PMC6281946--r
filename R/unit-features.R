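#' Standardize acoustic unit measurements
#'
#' Centres each numeric acoustic feature and scales it to unit variance
#' (sample, n-1, standard deviation) so that features measured in hertz,
#' seconds and counts contribute commensurately to distances between unit
#' types. The named schema covers the ten standard spectrogram measurements
#' (min/max/start/end/peak frequency, bandwidth, frequency range and trend,
#' duration, number of inflections); any extra numeric columns are
#' standardized and carried along, so wider measurement tables also work.
#' Constant features carry no information about unit identity and are
#' dropped with a warning.
#'
#' @param table data.frame of unit measurements: a `unit_label` column plus
#'   numeric feature columns. Identifier columns (`unit_label`,
#'   `population`, `year`, `singer`) are passed through untouched.
#' @return A data.frame with the same identifier columns and standardized
#'   feature columns; the feature names are stored in
#'   `attr(, "feature_cols")`.
#' @export
standardize_features <- function(table) {
  stopifnot(is.data.frame(table))
  if (nrow(table) < 2L) {
    stop("need at least 2 measurements to standardize", call. = FALSE)
  }
  id_cols <- intersect(c("unit_label", "population", "year", "singer"),
                       names(table))
  feat <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], id_cols)
  if (!length(feat)) stop("no numeric feature columns found", call. = FALSE)
  sds <- vapply(table[feat], sd, 0.0)
  const <- sds == 0 | is.na(sds)
  if (all(const)) stop("all feature columns are constant", call. = FALSE)
  if (any(const)) {
    warning("dropping constant feature column(s): ",
            paste(feat[const], collapse = ", "), call. = FALSE)
    feat <- feat[!const]
  }
  out <- table[c(id_cols, feat)]
  for (f in feat) out[[f]] <- (out[[f]] - mean(out[[f]])) / sd(out[[f]])
  attr(out, "feature_cols") <- feat
  out
}

#' Per-unit-type feature centroids
#'
#' Summarises each unit type by the per-feature median of its standardized
#' measurements. The median is robust to the occasional extreme unit that
#' skewed, bounded acoustic measures produce.
#'
#' @param standardized output of [standardize_features()].
#' @return Numeric matrix, one row per unit type (rownames are unit
#'   labels), one column per feature.
#' @export
unit_type_centroids <- function(standardized) {
  feat <- attr(standardized, "feature_cols")
  if (is.null(feat)) {
    stop("input must come from standardize_features()", call. = FALSE)
  }
  labs <- as.character(standardized$unit_label)
  if (any(!nzchar(labs) | is.na(labs))) {
    stop("empty unit label group", call. = FALSE)
  }
  ulabs <- unique(labs)
  cent <- t(vapply(ulabs, function(l) {
    vapply(standardized[labs == l, feat, drop = FALSE], median, 0.0)
  }, numeric(length(feat))))
  dimnames(cent) <- list(ulabs, feat)
  cent
}

#' Derive unit substitution costs from acoustic centroids
#'
#' Substitution costs for the weighted Levenshtein analysis: the Euclidean
#' distance between unit-type centroids in standardized feature space,
#' normalized by the maximum pairwise distance so the most dissimilar pair
#' costs exactly 1 (the indel cost), then raised to the exponent `beta`.
#' `beta = 1` uses the normalized distances directly; `beta = 0` collapses
#' every off-diagonal cost to 1, which reduces the weighted analysis to the
#' unweighted one.
#'
#' @param centroids matrix from [unit_type_centroids()].
#' @param beta nonnegative weighting exponent (default 1).
#' @return An object of class `cost_matrix`: list with `labels`, `costs`
#'   (square symmetric, zero diagonal, entries in \[0, 1\]), `indel_cost`
#'   (fixed 1) and `beta`.
#' @export
substitution_costs <- function(centroids, beta = 1) {
  stopifnot(is.matrix(centroids), is.numeric(beta), length(beta) == 1L,
            beta >= 0)
  if (nrow(centroids) < 2L) stop("need at least 2 centroids", call. = FALSE)
  d <- as.matrix(dist(centroids))
  dmax <- max(d)
  if (dmax == 0) {
    stop("all centroids are identical (maximum pairwise distance is 0)",
         call. = FALSE)
  }
  costs <- (d / dmax)^beta
  diag(costs) <- 0
  structure(list(labels = rownames(centroids), costs = costs,
                 indel_cost = 1, beta = beta),
            class = "cost_matrix")
}

#' @export
print.cost_matrix <- function(x, ...) {
  cat("<cost_matrix> ", length(x$labels), " unit types, beta = ", x$beta,
      ", indel cost = ", x$indel_cost, "\n", sep = "")
  invisible(x)
}

#' Validate manual unit classification with a classification tree
#'
#' Fits a binary recursive-partitioning tree (Gini impurity, via rpart) of
#' manual unit labels on acoustic features, prunes it by cost-complexity
#' with the subtree chosen by k-fold cross-validated error under the 1-SE
#' rule, and reports how well the tree's classes agree with the manual
#' labelling. Two quantities are reported explicitly: the root-node error
#' (the error of the trivial majority-class classifier, i.e. 1 minus the
#' largest class share) and the agreement (fraction of measurements whose
#' predicted class matches the manual label).
#'
#' @param standardized output of [standardize_features()].
#' @param labels manual unit labels; defaults to the `unit_label` column.
#' @param k_folds number of cross-validation folds (default 10).
#' @param seed optional seed fixing the fold assignment.
#' @return An object of class `unit_cart`: list with the pruned `tree`, the
#'   chosen `cp`, `root_error`, `agreement`, cross-validated error
#'   `cv_error` (relative to the root), `n` and `k_folds`.
#' @export
fit_classification_tree <- function(standardized, labels = NULL,
                                    k_folds = 10, seed = NULL) {
  feat <- attr(standardized, "feature_cols")
  if (is.null(feat)) {
    stop("input must come from standardize_features()", call. = FALSE)
  }
  if (is.null(labels)) labels <- standardized$unit_label
  labels <- factor(as.character(labels))
  n <- nrow(standardized)
  if (nlevels(labels) < 2L) {
    stop("need at least 2 unit classes", call. = FALSE)
  }
  if (k_folds > n) {
    stop("k_folds (", k_folds, ") exceeds the number of rows (", n, ")",
         call. = FALSE)
  }
  dat <- standardized[feat]
  dat$.label <- labels
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  fit <- rpart::rpart(.label ~ ., data = dat, method = "class",
                      control = rpart::rpart.control(xval = k_folds,
                                                     cp = 0, minsplit = 2))
  cp_tab <- fit$cptable
  best <- which.min(cp_tab[, "xerror"])
  thresh <- cp_tab[best, "xerror"] + cp_tab[best, "xstd"]  # 1-SE rule
  chosen <- which(cp_tab[, "xerror"] <= thresh)[1]
  pruned <- rpart::prune(fit, cp = cp_tab[chosen, "CP"])
  pred <- predict(pruned, dat, type = "class")
  structure(list(tree = pruned, cp = unname(cp_tab[chosen, "CP"]),
                 root_error = 1 - max(table(labels)) / n,
                 agreement = mean(pred == labels),
                 cv_error = unname(cp_tab[chosen, "xerror"]),
                 n = n, k_folds = k_folds),
            class = "unit_cart")
}

#' @export
print.unit_cart <- function(x, ...) {
  cat("<unit_cart> n = ", x$n, ", ", x$k_folds, "-fold CV\n",
      "  root-node error (trivial classifier): ",
      sprintf("%.4f", x$root_error), "\n",
      "  agreement with manual labels:         ",
      sprintf("%.4f", x$agreement), "\n", sep = "")
  invisible(x)
}

# Restore (or remove) the global RNG state saved before a seeded section.
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
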