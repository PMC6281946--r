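# Token sequences are character vectors; before hitting the C++ dynamic
# programme they are encoded as 1-based integer indices, either into the
# cost matrix's label set (weighted) or into the union vocabulary of the
# sequences at hand (unweighted).
encode_seqs <- function(seqs, costs = NULL) {
  seqs <- lapply(seqs, as.character)
  if (!is.null(costs)) {
    stopifnot(inherits(costs, "cost_matrix"))
    vocab <- costs$labels
    enc <- lapply(seqs, function(s) {
      i <- match(s, vocab)
      if (anyNA(i)) {
        stop("token(s) absent from cost matrix: ",
             paste(unique(s[is.na(i)]), collapse = ", "), call. = FALSE)
      }
      i
    })
    list(seqs = enc, cost = costs$costs)
  } else {
    vocab <- unique(unlist(seqs))
    list(seqs = lapply(seqs, function(s) match(s, vocab)), cost = NULL)
  }
}

#' Levenshtein distance between token sequences
#'
#' Minimum total cost of insertions, deletions and substitutions turning
#' one sequence into the other, computed by dynamic programming.
#' Insertions and deletions always cost 1. Without a cost matrix every
#' substitution costs 1 (classic Levenshtein); with one, substituting token
#' i for token j costs `costs$costs[i, j]`, so acoustically similar units
#' are cheap to exchange.
#'
#' @param a,b character vectors of tokens (theme labels or unit labels);
#'   length 0 is allowed.
#' @param costs optional [substitution_costs()] object covering every token
#'   in `a` and `b`.
#' @return Nonnegative number; 0 if and only if `a` and `b` are identical.
#' @examples
#' levenshtein_distance(c("1", "2", "3"), c("1", "3", "2"))  # 2
#' @export
levenshtein_distance <- function(a, b, costs = NULL) {
  enc <- encode_seqs(list(a, b), costs)
  lev_dist_cpp(enc$seqs[[1]], enc$seqs[[2]], enc$cost)
}

#' Levenshtein distance similarity index (LSI)
#'
#' Length-normalized edit similarity between two token sequences, as a
#' percentage: `100 * (1 - LD(a, b) / max(length(a), length(b)))`.
#' Dividing by the longer sequence keeps the index in \[0, 100\], with 100
#' for identical sequences and 0 for unweighted comparison of equal-length
#' sequences over disjoint alphabets.
#'
#' @inheritParams levenshtein_distance
#' @return Percentage in \[0, 100\].
#' @examples
#' lsi_similarity(c("1", "2", "3"), c("1", "3", "2"))  # 33.33
#' @export
lsi_similarity <- function(a, b, costs = NULL) {
  n <- max(length(a), length(b))
  if (n == 0L) stop("both sequences are empty", call. = FALSE)
  if (!is.null(costs) && max(costs$costs) > 2 * costs$indel_cost) {
    stop("cost matrix has substitutions dearer than delete+insert",
         call. = FALSE)
  }
  max(0, 100 * (1 - levenshtein_distance(a, b, costs) / n))
}

# Pairwise LSI matrix over a list of token sequences (shared C++ core).
lsi_pairwise <- function(seqs, costs = NULL) {
  enc <- encode_seqs(seqs, costs)
  d <- lev_pairwise_cpp(enc$seqs, enc$cost)
  len <- vapply(seqs, length, 1L)
  norm <- outer(len, len, pmax)
  if (any(norm == 0 & row(norm) != col(norm))) {
    stop("cannot compare two empty sequences", call. = FALSE)
  }
  norm[norm == 0] <- 1  # only the diagonal of all-empty rows
  sim <- 100 * (1 - d / norm)
  diag(sim) <- 100
  pmax(sim, 0)
}

#' Set-median string of a collection
#'
#' The member of the collection minimizing the summed Levenshtein distance
#' to all members (the set-median; the unrestricted generalized median is
#' NP-hard and not needed here). Ties are broken by shortest length, then
#' by lexicographic token order, so the result does not depend on the
#' input order.
#'
#' @param strings nonempty list of character vectors.
#' @inheritParams levenshtein_distance
#' @return One member of `strings`.
#' @export
median_string <- function(strings, costs = NULL) {
  if (!is.list(strings) || length(strings) == 0L) {
    stop("need a nonempty list of sequences", call. = FALSE)
  }
  if (length(strings) == 1L) return(strings[[1]])
  d <- lev_pairwise_cpp_wrap(strings, costs)
  tot <- rowSums(d)
  cand <- which(tot == min(tot))
  if (length(cand) > 1L) {
    len <- vapply(strings[cand], length, 1L)
    cand <- cand[len == min(len)]
    if (length(cand) > 1L) {
      flat <- vapply(strings[cand], paste, "", collapse = "\r")
      cand <- cand[order(flat)[1]]
    }
  }
  strings[[cand[1]]]
}

lev_pairwise_cpp_wrap <- function(seqs, costs = NULL) {
  enc <- encode_seqs(seqs, costs)
  lev_pairwise_cpp(enc$seqs, enc$cost)
}

#' Group phrase strings into phrase types by weighted LSI
#'
#' The quantitative replacement for judging "similar units in a similar
#' position" by eye: all pairwise weighted LSI values are computed, the
#' phrases are clustered by UPGMA on dissimilarity `100 - LSI`, and the
#' tree is cut at height `100 - cut`. Every resulting cluster is one phrase
#' type. Type ids are integers numbered by first occurrence in the input.
#'
#' @param phrases list of unit-token character vectors, or a phrase table
#'   from [load_fixture()] (its `units` column is used).
#' @param costs a [substitution_costs()] object.
#' @param cut similarity threshold in percent (default 70): phrases in the
#'   same type are at least this similar on average.
#' @return Integer vector of phrase-type ids, one per phrase.
#' @export
group_phrases <- function(phrases, costs, cut = 70) {
  if (inherits(phrases, "phrase_table")) phrases <- phrases$units
  stopifnot(is.list(phrases), length(phrases) >= 1L)
  if (!(cut > 0 && cut <= 100)) stop("cut must be in (0, 100]", call. = FALSE)
  if (length(phrases) == 1L) return(1L)
  sim <- lsi_pairwise(phrases, costs)
  hc <- hclust(as.dist(100 - sim), method = "average")
  raw <- cutree(hc, h = 100 - cut)
  # renumber so type ids follow first occurrence
  ids <- match(raw, unique(raw))
  as.integer(ids)
}
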