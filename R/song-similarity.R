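#' Similarity matrices over singers
#'
#' A `similarity_matrix` stores a square symmetric table of percentages
#' over singers, with the singer keys alongside. The diagonal carries
#' self-similarity (how alike the songs one individual sings are) for the
#' LSI kind, and 100 for the Dice kind.
#'
#' @param ids data.frame with columns `population`, `year`, `singer_id`.
#' @param values square numeric matrix of percentages in \[0, 100\].
#' @param kind `"LSI"` or `"Dice"`.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(ids, values, kind = c("LSI", "Dice")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(ids), is.matrix(values),
            nrow(values) == ncol(values), nrow(ids) == nrow(values))
  if (any(!is.finite(values))) stop("non-finite similarity", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-9) {
    stop("similarity matrix is not symmetric", call. = FALSE)
  }
  if (min(values) < -1e-9 || max(values) > 100 + 1e-9) {
    stop("similarities must be percentages in [0, 100]", call. = FALSE)
  }
  lab <- paste(ids$population, ids$year, ids$singer_id, sep = ".")
  dimnames(values) <- list(lab, lab)
  structure(list(ids = ids, values = values, kind = kind),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix> kind = ", x$kind, ", ", nrow(x$values),
      " singers\n", sep = "")
  print(round(x$values, 1))
  invisible(x)
}

#' Average unweighted LSI between two singers' songs
#'
#' Every theme sequence (song cycle) of singer A is compared with every
#' cycle of singer B by unweighted [lsi_similarity()], and the cross-pair
#' mean is returned. Averaging over cycles absorbs the alternations and
#' repeats of themes that individual renditions show.
#'
#' @param A,B singer records (see [corpus_singer()]).
#' @return Percentage in \[0, 100\].
#' @export
singer_pair_lsi <- function(A, B) {
  pairs <- expand.grid(i = seq_along(A$cycles), j = seq_along(B$cycles))
  mean(mapply(function(i, j) lsi_similarity(A$cycles[[i]], B$cycles[[j]]),
              pairs$i, pairs$j))
}

#' Self-similarity of a singer's songs
#'
#' Mean unweighted LSI over all unordered pairs of distinct song cycles.
#' With a single recorded cycle there is nothing to compare and 100 is
#' returned by convention, with a warning.
#'
#' @param A a singer record.
#' @return Percentage in \[0, 100\].
#' @export
self_similarity <- function(A) {
  k <- length(A$cycles)
  if (k < 1L) stop("singer has no cycles", call. = FALSE)
  if (k == 1L) {
    warning("singer ", A$singer_id %||% "?",
            " has a single cycle; self-similarity set to 100 by convention",
            call. = FALSE)
    return(100)
  }
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  mean(mapply(function(i, j) lsi_similarity(A$cycles[[i]], A$cycles[[j]]),
              pairs[, 1], pairs[, 2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Singer-by-singer LSI similarity matrix
#'
#' Off-diagonal entries are [singer_pair_lsi()]; the diagonal carries
#' [self_similarity()].
#'
#' @param corpus a [song_corpus()] with at least 2 singers.
#' @return A [similarity_matrix()] of kind `"LSI"`.
#' @export
lsi_matrix <- function(corpus) {
  stopifnot(inherits(corpus, "song_corpus"))
  s <- corpus$singers
  n <- nrow(s)
  if (n < 2L) stop("need at least 2 singers", call. = FALSE)
  recs <- lapply(seq_len(n), function(i)
    list(singer_id = s$singer_id[i], cycles = s$cycles[[i]]))
  vals <- diag(vapply(recs, function(r)
    suppressWarnings(self_similarity(r)), 0.0))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      vals[i, j] <- vals[j, i] <- singer_pair_lsi(recs[[i]], recs[[j]])
    }
  }
  similarity_matrix(s[c("population", "year", "singer_id")], vals, "LSI")
}

#' Dice's similarity index of two repertoires
#'
#' `SI = 2A / (B + C)` where A is the number of shared types and B, C the
#' repertoire sizes of the two individuals. Sequential information is
#' deliberately ignored: only the presence and sharing of types counts.
#'
#' @param setA,setB character vectors of type labels (duplicates ignored).
#' @return Similarity in \[0, 1\].
#' @examples
#' dice(c("7s", "23", "25", "18E", "24", "6"),
#'      c("7s", "23", "24", "25", "6"))  # 10/11
#' @export
dice <- function(setA, setB) {
  a <- unique(as.character(setA))
  b <- unique(as.character(setB))
  if (length(a) + length(b) == 0L) {
    stop("both repertoires are empty", call. = FALSE)
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Singer-by-singer Dice similarity matrix
#'
#' Pairwise [dice()] (as a percentage) on singer repertoires: at
#' `level = "theme"` the repertoire is the [theme_inventory()] pooled over
#' all cycles; at `level = "phrase"` it is the singer's phrase-type
#' inventory, which must be present in the corpus.
#'
#' @param corpus a [song_corpus()].
#' @param level `"theme"` or `"phrase"`.
#' @return A [similarity_matrix()] of kind `"Dice"` (diagonal 100).
#' @export
dice_matrix <- function(corpus, level = c("theme", "phrase")) {
  level <- match.arg(level)
  stopifnot(inherits(corpus, "song_corpus"))
  s <- corpus$singers
  n <- nrow(s)
  if (n < 2L) stop("need at least 2 singers", call. = FALSE)
  invs <- if (level == "theme") {
    lapply(s$cycles, function(cyc) theme_inventory(list(cycles = cyc)))
  } else {
    if (is.null(s$phrase_inventory)) {
      stop("corpus has no phrase inventories; use level = \"theme\"",
           call. = FALSE)
    }
    s$phrase_inventory
  }
  vals <- diag(100, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      vals[i, j] <- vals[j, i] <- 100 * dice(invs[[i]], invs[[j]])
    }
  }
  similarity_matrix(s[c("population", "year", "singer_id")], vals, "Dice")
}

# Half-up rounding to whole percent (round() would round half to even).
round_half_up <- function(x) floor(x + 0.5)

#' Between-population similarity range in one year
#'
#' Minimum and maximum similarity over all cross-population singer pairs
#' recorded in the given year, rounded half-up to whole percentages --
#' the form in which between-population song-similarity ranges are
#' conventionally reported.
#'
#' @param m a [similarity_matrix()] whose ids span two populations.
#' @param year the year to restrict to.
#' @return Named numeric vector `c(min = , max = )`.
#' @export
between_population_range <- function(m, year) {
  stopifnot(inherits(m, "similarity_matrix"))
  ids <- m$ids
  pops <- unique(ids$population[ids$year == year])
  if (length(pops) < 2L) {
    stop("need both populations recorded in year ", year,
         " (found: ", paste(pops, collapse = ", "), ")", call. = FALSE)
  }
  i <- which(ids$year == year & ids$population == pops[1])
  j <- which(ids$year == year & ids$population == pops[2])
  cross <- m$values[i, j, drop = FALSE]
  c(min = round_half_up(min(cross)), max = round_half_up(max(cross)))
}

#' Write a similarity matrix as labeled CSV
#'
#' The file carries a 3-line comment header (kind, level/extra note, and a
#' checksum of the value block) followed by a labeled square CSV table.
#'
#' @param m a [similarity_matrix()].
#' @param path output path.
#' @param note free-text second header line (e.g. the Dice level).
#' @return `path`, invisibly.
#' @export
write_similarity <- function(m, path, note = "") {
  stopifnot(inherits(m, "similarity_matrix"))
  chk <- sum(m$values) / length(m$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# kind: ", m$kind),
               paste0("# note: ", note),
               paste0("# mean_value: ", format(chk, digits = 12))), con)
  write.csv(as.data.frame(m$values), con, row.names = TRUE)
  invisible(path)
}
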