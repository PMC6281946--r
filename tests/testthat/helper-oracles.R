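# Independent oracles and fixture builders shared across the test files.

# Memoised recursive edit-distance oracle: a direct transcription of the
# recurrence, independent of the package's dynamic-programming code path.
# `cost` is a labelled square matrix of substitution costs (NULL = 0/1).
lev_oracle <- function(a, b, cost = NULL) {
  la <- length(a)
  lb <- length(b)
  memo <- array(NA_real_, dim = c(la + 1L, lb + 1L))
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- if (i > la) {
      lb - j + 1
    } else if (j > lb) {
      la - i + 1
    } else {
      s <- if (is.null(cost)) as.numeric(a[i] != b[j]) else cost[a[i], b[j]]
      min(rec(i + 1L, j + 1L) + s, rec(i + 1L, j) + 1, rec(i, j + 1L) + 1)
    }
    memo[i, j] <<- v
    v
  }
  rec(1L, 1L)
}

# All token strings over `alphabet` up to length `maxlen`, including the
# empty string.
all_strings <- function(alphabet, maxlen) {
  out <- list(character(0))
  prev <- list(character(0))
  for (l in seq_len(maxlen)) {
    prev <- unlist(lapply(prev, function(s)
      lapply(alphabet, function(ch) c(s, ch))), recursive = FALSE)
    out <- c(out, prev)
  }
  out
}

# Random metric substitution-cost matrix: Euclidean distances between
# random points in the plane, scaled into [0, 1]. Metric by construction.
random_metric_costs <- function(labels) {
  pts <- matrix(runif(2 * length(labels)), ncol = 2)
  d <- as.matrix(dist(pts))
  d <- d / max(d)
  dimnames(d) <- list(labels, labels)
  structure(list(labels = labels, costs = d, indel_cost = 1, beta = 1),
            class = "cost_matrix")
}

# Tiny corpus built in code: populations P1/P2, one year, given cycles.
toy_corpus <- function(cycles_by_singer, populations = NULL, year = 2000) {
  n <- length(cycles_by_singer)
  if (is.null(populations)) populations <- rep("P1", n)
  tab <- data.frame(population = populations, year = year,
                    singer_id = as.character(seq_len(n)),
                    stringsAsFactors = FALSE)
  tab$cycles <- lapply(cycles_by_singer, function(cyc) {
    if (is.character(cyc)) list(cyc) else cyc
  })
  song_corpus(tab)
}

# Synthetic unit-measurement table: `n_per` rows per unit type, features
# drawn around type-specific centres. Column names follow the measurement
# schema; values are plausible magnitudes (Hz, seconds, counts).
synthetic_measurements <- function(types = c("moan", "cry", "croak"),
                                   n_per = 20, noise = 0.05, seed = 1) {
  set.seed(seed)
  centres <- seq(200, by = 400, length.out = length(types))
  rows <- lapply(seq_along(types), function(k) {
    f0 <- centres[k] * exp(rnorm(n_per, 0, noise))
    bw <- 100 + 10 * k + rnorm(n_per, 0, noise * 50)
    data.frame(unit_label = types[k],
               min_freq = f0, max_freq = f0 + bw,
               start_freq = f0 + 0.2 * bw, end_freq = f0 + 0.8 * bw,
               peak_freq = f0 + 0.5 * bw, bandwidth = bw,
               freq_range = f0 / (f0 + bw),
               freq_trend = (f0 + 0.2 * bw) / (f0 + 0.8 * bw),
               duration = 0.2 + 0.05 * k + abs(rnorm(n_per, 0, noise)),
               n_inflections = rpois(n_per, k),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
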