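#' Construct a song corpus
#'
#' A corpus holds one record per singer: population, year, an arbitrary
#' singer id (ids are only meaningful within a population-year; no
#' cross-year identity is implied), and one or more song cycles, each an
#' ordered character vector of theme labels.
#'
#' @param singers data.frame with columns `population`, `year`, `singer_id`
#'   and a list-column `cycles` (each element a list of character vectors,
#'   one per song cycle).
#' @param phrases optional phrase table: data.frame with columns
#'   `population`, `year`, `theme_label` and list-column `units`.
#' @return An object of class `song_corpus`.
#' @export
song_corpus <- function(singers, phrases = NULL) {
  stopifnot(is.data.frame(singers))
  need <- c("population", "year", "singer_id", "cycles")
  miss <- setdiff(need, names(singers))
  if (length(miss)) {
    stop("singers table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(singers$population, singers$year, singers$singer_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (population, year, singer_id) triple(s): ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(singers))) {
    cyc <- singers$cycles[[i]]
    if (!is.list(cyc) || length(cyc) < 1L) {
      stop("singer ", singers$singer_id[i], " (", singers$population[i], " ",
           singers$year[i], ") has no song cycles", call. = FALSE)
    }
    if (any(vapply(cyc, length, 1L) < 1L)) {
      stop("empty song cycle for singer ", singers$singer_id[i], call. = FALSE)
    }
  }
  vocab <- if (!is.null(phrases)) {
    sort(unique(unlist(phrases$units)))
  } else character()
  structure(list(singers = singers, phrases = phrases,
                 unit_vocabulary = vocab),
            class = "song_corpus")
}

#' @export
print.song_corpus <- function(x, ...) {
  s <- x$singers
  cat("<song_corpus> ", nrow(s), " singers, ",
      length(unique(s$year)), " year(s), populations: ",
      paste(sort(unique(s$population)), collapse = ", "), "\n", sep = "")
  if (!is.null(x$phrases)) {
    cat("  phrase table: ", nrow(x$phrases), " phrase strings, ",
        length(x$unit_vocabulary), " unit types\n", sep = "")
  }
  invisible(x)
}

#' Read a transcription CSV into a corpus
#'
#' The transcription schema has one row per theme occurrence with columns
#' `population`, `year`, `singer_id`, `cycle_index`, `position`,
#' `theme_label`. Positions within each (population, year, singer, cycle)
#' must run 1, 2, 3, ... without gaps or duplicates; theme labels must parse
#' (see [parse_theme_label()]). Violations are reported with the offending
#' CSV line numbers.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @return A [song_corpus()].
#' @seealso [write_transcriptions()] for the inverse.
#' @export
parse_transcriptions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("empty transcription file: ", path, call. = FALSE)
  need <- c("population", "year", "singer_id", "cycle_index", "position",
            "theme_label")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("transcription file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- !is_theme_label(df$theme_label)
  if (any(bad)) {
    stop("malformed theme label(s) at line(s) ",
         paste(line[bad], collapse = ", "), ": ",
         paste(unique(df$theme_label[bad]), collapse = ", "), call. = FALSE)
  }
  df$year <- as.integer(df$year)
  df$cycle_index <- as.integer(df$cycle_index)
  df$position <- as.integer(df$position)
  cyc_key <- paste(df$population, df$year, df$singer_id, df$cycle_index,
                   sep = "\r")
  dup <- duplicated(paste(cyc_key, df$position, sep = "\r"))
  if (any(dup)) {
    stop("duplicate (population, year, singer, cycle, position) at line(s) ",
         paste(line[dup], collapse = ", "), call. = FALSE)
  }
  singers <- list()
  for (k in unique(cyc_key)) {
    rows <- df[cyc_key == k, ]
    rows <- rows[order(rows$position), ]
    expect <- seq_len(nrow(rows))
    if (!identical(rows$position, expect)) {
      gap <- setdiff(expect, rows$position)
      stop("position gap in cycle ", rows$cycle_index[1], " of singer ",
           rows$singer_id[1], " (", rows$population[1], " ", rows$year[1],
           "): missing position(s) ", paste(gap, collapse = ", "),
           call. = FALSE)
    }
    skey <- paste(rows$population[1], rows$year[1], rows$singer_id[1],
                  sep = "\r")
    if (is.null(singers[[skey]])) {
      singers[[skey]] <- list(population = rows$population[1],
                              year = rows$year[1],
                              singer_id = rows$singer_id[1],
                              cycles = list())
    }
    singers[[skey]]$cycles[[as.character(rows$cycle_index[1])]] <-
      rows$theme_label
  }
  tab <- data.frame(
    population = vapply(singers, `[[`, "", "population"),
    year = vapply(singers, `[[`, 1L, "year"),
    singer_id = vapply(singers, `[[`, "", "singer_id"),
    stringsAsFactors = FALSE, row.names = NULL)
  tab$cycles <- lapply(singers, function(s) {
    cyc <- s$cycles
    unname(cyc[order(as.integer(names(cyc)))])
  })
  song_corpus(tab)
}

#' Write a corpus back to the transcription CSV schema
#'
#' @param corpus a [song_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transcriptions <- function(corpus, path) {
  stopifnot(inherits(corpus, "song_corpus"))
  s <- corpus$singers
  out <- do.call(rbind, lapply(seq_len(nrow(s)), function(i) {
    do.call(rbind, lapply(seq_along(s$cycles[[i]]), function(ci) {
      th <- s$cycles[[i]][[ci]]
      data.frame(population = s$population[i], year = s$year[i],
                 singer_id = s$singer_id[i], cycle_index = ci,
                 position = seq_along(th), theme_label = th,
                 stringsAsFactors = FALSE)
    }))
  }))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a packaged fixture of the published song tables
#'
#' Two fixtures transcribe the published Gabon/Madagascar song tables:
#' `"table3_themes"` gives the median theme sequence per individual singer
#' (one song cycle per singer, 31 singers, 2001--2005) and returns a
#' [song_corpus()]; `"table2_phrases"` gives the median unit sequence of
#' each phrase type per population and year and returns a phrase table
#' (data.frame with list-column `units`).
#'
#' @param name `"table3_themes"` or `"table2_phrases"`.
#' @return A `song_corpus` or a phrase table, depending on `name`.
#' @examples
#' corpus <- load_fixture("table3_themes")
#' corpus
#' @export
load_fixture <- function(name = c("table3_themes", "table2_phrases")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "whalesong",
                      mustWork = TRUE)
  if (name == "table3_themes") {
    return(parse_transcriptions(path))
  }
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(year = "integer", position = "integer"))
  key <- paste(df$population, df$year, df$theme_label, sep = "\r")
  out <- do.call(rbind, lapply(unique(key), function(k) {
    rows <- df[key == k, ]
    rows <- rows[order(rows$position), ]
    data.frame(population = rows$population[1], year = rows$year[1],
               theme_label = rows$theme_label[1], stringsAsFactors = FALSE)
  }))
  out$units <- lapply(unique(key), function(k) {
    rows <- df[key == k, ]
    check_unit_tokens(rows$unit_label[order(rows$position)])
  })
  class(out) <- c("phrase_table", "data.frame")
  out
}

#' Extract one singer's record from a corpus
#'
#' @param corpus a [song_corpus()].
#' @param population,year,singer_id the singer's key.
#' @return A list with fields `population`, `year`, `singer_id`, `cycles`.
#' @export
corpus_singer <- function(corpus, population, year, singer_id) {
  s <- corpus$singers
  i <- which(s$population == population & s$year == year &
               s$singer_id == as.character(singer_id))
  if (length(i) != 1L) {
    stop("no singer ", singer_id, " in ", population, " ", year,
         call. = FALSE)
  }
  list(population = s$population[i], year = s$year[i],
       singer_id = s$singer_id[i], cycles = s$cycles[[i]])
}

#' Theme inventory of a singer
#'
#' The set of distinct theme labels a singer used across all song cycles
#' (presence/absence repertoire; order and repeats are discarded). This is
#' the input to Dice's similarity index at theme level.
#'
#' @param singer a singer record as returned by [corpus_singer()], or any
#'   list with a `cycles` field of character vectors.
#' @return Character vector of distinct theme labels, sorted.
#' @export
theme_inventory <- function(singer) {
  cyc <- if (is.list(singer) && !is.null(singer$cycles)) singer$cycles
  else singer
  if (length(cyc) < 1L) stop("singer has no cycles", call. = FALSE)
  sort(unique(unlist(cyc)))
}
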