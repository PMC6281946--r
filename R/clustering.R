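#' Convert a similarity matrix to a distance matrix
#'
#' Dissimilarity is `100 - similarity`; the diagonal is forced to 0 even
#' when the similarity diagonal carries a self-similarity below 100, since
#' for clustering purposes every singer is at distance 0 from itself.
#'
#' @param m a [similarity_matrix()] (or a plain symmetric percentage
#'   matrix).
#' @return Square numeric distance matrix with the same labels.
#' @export
to_distance <- function(m) {
  vals <- if (inherits(m, "similarity_matrix")) m$values else as.matrix(m)
  if (max(abs(vals - t(vals))) > 1e-9) {
    stop("similarity matrix is not symmetric", call. = FALSE)
  }
  if (min(vals) < -1e-9 || max(vals) > 100 + 1e-9) {
    stop("entries must be in [0, 100]", call. = FALSE)
  }
  d <- 100 - vals
  diag(d) <- 0
  d
}

#' UPGMA dendrogram of a distance matrix
#'
#' Average-linkage (UPGMA) agglomeration: at every step the two clusters
#' with the smallest mean inter-cluster distance merge, at a height equal
#' to that mean. The result is ultrametric -- heights never decrease along
#' a root path. Equidistant candidates are merged lowest-index pair first,
#' which makes the tree deterministic.
#'
#' @param d square symmetric distance matrix with zero diagonal, or a
#'   `dist` object.
#' @return An object of class `song_dendrogram` wrapping the `hclust`
#'   merge tree, with fields `hclust`, `labels`, `dist` and (optionally,
#'   after [bootstrap_support()]) `support`.
#' @export
upgma <- function(d) {
  dm <- as.matrix(d)
  if (any(!is.finite(dm))) stop("non-finite distances", call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-9 || any(abs(diag(dm)) > 1e-9)) {
    stop("need a symmetric matrix with zero diagonal", call. = FALSE)
  }
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("L", seq_len(nrow(dm)))
  }
  hc <- hclust(as.dist(dm), method = "average")
  structure(list(hclust = hc, labels = hc$labels, dist = dm,
                 support = NULL),
            class = "song_dendrogram")
}

#' @export
print.song_dendrogram <- function(x, ...) {
  cat("<song_dendrogram> ", length(x$labels), " leaves, ",
      nrow(x$hclust$merge), " merges",
      if (!is.null(x$support)) " (with AU/BP support)", "\n", sep = "")
  invisible(x)
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic distances (the merge height of each pair's lowest common
#' ancestor). A value of 0.8 or more is conventionally read as the tree
#' representing the distance structure well; an ultrametric input is
#' recovered exactly (CCC = 1).
#'
#' @param tree a [upgma()] dendrogram.
#' @param d the distance matrix the tree should represent; its labels must
#'   match the tree's leaves.
#' @return Correlation in \[-1, 1\].
#' @export
cophenetic_correlation <- function(tree, d) {
  stopifnot(inherits(tree, "song_dendrogram"))
  dm <- as.matrix(d)
  if (nrow(dm) < 3L) {
    stop("cophenetic correlation needs at least 3 leaves", call. = FALSE)
  }
  if (!is.null(rownames(dm))) {
    if (!setequal(rownames(dm), tree$labels)) {
      stop("distance labels do not match tree leaves", call. = FALSE)
    }
    dm <- dm[tree$labels, tree$labels]
  }
  coph <- cophenetic(tree$hclust)
  cor(as.dist(dm), coph)
}

#' Bootstrap configuration
#'
#' @param n_replicates bootstrap replicates per scale (default 1000).
#' @param scales relative resampling sizes r; the default ten values
#'   0.5, 0.6, ..., 1.4 are the standard grid for the multiscale
#'   (approximately unbiased) method.
#' @param seed optional RNG seed for reproducible support values.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_replicates = 1000,
                             scales = seq(0.5, 1.4, by = 0.1),
                             seed = NULL) {
  stopifnot(n_replicates >= 1, all(scales > 0), length(scales) >= 1)
  structure(list(n_replicates = as.integer(n_replicates), scales = scales,
                 seed = seed),
            class = "bootstrap_config")
}

# Leaf-set signature of every internal node of an hclust tree. Nodes are
# identified across bootstrap replicates by leaf-set equality.
node_signatures <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  sig <- character(nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[k, ]
    leaves <- unlist(lapply(kids, function(x)
      if (x < 0) -x else members[[x]]))
    members[[k]] <- leaves
    sig[k] <- paste(sort(hc$labels[leaves]), collapse = "\r")
  }
  sig
}

#' Multiscale (AU) and ordinary (BP) bootstrap support for a UPGMA tree
#'
#' The rows of the similarity matrix are treated as the resampled features
#' while its columns (the singers) are clustered: for each scale r,
#' `n_replicates` resamples of `ceiling(r * n)` rows are drawn with
#' replacement, the singers are reclustered by UPGMA on the Euclidean
#' distance between the resampled columns, and each original internal
#' node's recurrence frequency BP(r) is recorded. BP is reported at r = 1.
#' AU comes from the multiscale fit: `z(r) = qnorm(1 - BP(r))` is fitted by
#' weighted least squares to `v * sqrt(r) + c / sqrt(r)` with
#' binomial-variance weights, and `AU = 100 * (1 - pnorm(v - c))`.
#' Frequencies are clamped to `[1/(B+1), B/(B+1)]` before the probit
#' transform; a node recurring in every replicate at every scale is
#' reported AU = 100 (and one never recurring, AU = 0).
#'
#' The assessed tree is itself built by the same machinery at full size
#' (UPGMA on the Euclidean distance between the columns of
#' `to_distance(m)`), so the full-data tree and the replicate trees are
#' directly comparable.
#'
#' @param m a [similarity_matrix()] with at least 3 singers.
#' @param config a [bootstrap_config()].
#' @return A `song_dendrogram` whose `support` field is a data.frame with
#'   one row per internal node: `node`, `leaves`, `au`, `bp`, and
#'   significance flags `au_sig` (AU > 95) and `bp_sig` (BP > 70) -- the
#'   conventional thresholds, reported as annotations only.
#' @export
bootstrap_support <- function(m, config = bootstrap_config()) {
  stopifnot(inherits(m, "similarity_matrix"),
            inherits(config, "bootstrap_config"))
  X <- to_distance(m)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 singers", call. = FALSE)
  sizes <- as.integer(ceiling(config$scales * n))
  if (any(sizes < 2L)) {
    stop("scale(s) ", paste(config$scales[sizes < 2L], collapse = ", "),
         " resample fewer than 2 rows", call. = FALSE)
  }
  if (!is.null(config$seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(config$seed)
  }
  tree <- upgma(as.matrix(dist(t(X))))
  sig0 <- node_signatures(tree$hclust)
  B <- config$n_replicates
  counts <- matrix(0L, nrow = length(sig0), ncol = length(config$scales))
  for (s in seq_along(config$scales)) {
    for (b in seq_len(B)) {
      rows <- sample.int(n, sizes[s], replace = TRUE)
      hc_b <- hclust(dist(t(X[rows, , drop = FALSE])), method = "average")
      counts[, s] <- counts[, s] + (sig0 %in% node_signatures(hc_b))
    }
  }
  bp_rs <- counts / B
  r_eff <- sizes / n  # the realized scales after ceiling()
  au <- vapply(seq_along(sig0), function(k)
    au_from_multiscale(bp_rs[k, ], r_eff, B), 0.0)
  bp1 <- 100 * bp_rs[, which.min(abs(r_eff - 1))]
  leaves <- gsub("\r", ", ", sig0)
  tree$support <- data.frame(node = seq_along(sig0), leaves = leaves,
                             au = au, bp = bp1,
                             au_sig = au > 95, bp_sig = bp1 > 70,
                             stringsAsFactors = FALSE)
  tree$config <- config
  tree
}

# Probit-domain weighted least squares fit of the multiscale decay curve.
au_from_multiscale <- function(bp, r, B) {
  if (all(bp == 1)) return(100)
  if (all(bp == 0)) return(0)
  p <- pmin(pmax(bp, 1 / (B + 1)), B / (B + 1))
  z <- qnorm(1 - p)
  w <- B * dnorm(z)^2 / (p * (1 - p))  # delta-method binomial weights
  fit <- lm(z ~ 0 + I(sqrt(r)) + I(1 / sqrt(r)), weights = w)
  vc <- coef(fit)
  100 * (1 - pnorm(vc[1] - vc[2]))
}

#' Export a dendrogram as Newick text
#'
#' Merge heights are halved to edge lengths (leaves sit at height 0), so
#' the leaf-to-leaf path length in the tree equals the cophenetic
#' distance. When bootstrap support is present, internal nodes are
#' labelled `"AU/BP"` (rounded to integers). Leaf labels containing
#' Newick metacharacters are quoted.
#'
#' @param tree a `song_dendrogram`.
#' @return A single Newick string (terminated by `;`).
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "song_dendrogram"))
  hc <- tree$hclust
  quote_label <- function(l) {
    if (grepl("[][,;:()'[:space:]]", l)) {
      paste0("'", gsub("'", "''", l), "'")
    } else l
  }
  sup_lab <- if (is.null(tree$support)) rep("", nrow(hc$merge))
  else sprintf("%.0f/%.0f", tree$support$au, tree$support$bp)
  # merge heights are halved to node depths so that the leaf-to-leaf path
  # length in the tree equals the cophenetic distance
  node_height <- hc$height / 2
  render <- function(idx) {
    if (idx < 0) {
      list(text = quote_label(hc$labels[-idx]), height = 0)
    } else {
      kids <- lapply(hc$merge[idx, ], render)
      h <- node_height[idx]
      inner <- paste(vapply(kids, function(k)
        sprintf("%s:%s", k$text, format(h - k$height, digits = 10)),
        ""), collapse = ",")
      list(text = paste0("(", inner, ")", sup_lab[idx]), height = h)
    }
  }
  paste0(render(nrow(hc$merge))$text, ";")
}
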