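#' Parse theme labels into core number and suffix
#'
#' Theme labels are a positive integer core with an optional one-letter
#' suffix: `"s"` for shifting themes, `"E"` for an evolved form of an
#' earlier theme, `"c"` as printed in some published tables. Labels are
#' atomic: `"18"` and `"18E"` are different themes, and all comparisons in
#' the package treat them as unrelated symbols.
#'
#' @param x character vector of theme labels, e.g. `c("7s", "18E", "23")`.
#' @return A data.frame with columns `label`, `core` (integer) and `suffix`
#'   (`""` when absent).
#' @examples
#' parse_theme_label(c("7s", "18E", "23"))
#' @export
parse_theme_label <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^([0-9]+)([sEc]?)$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed theme label(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected <positive integer>[s|E|c])", call. = FALSE)
  }
  core <- as.integer(vapply(m, `[`, "", 2L))
  if (any(core < 1L)) {
    stop("theme label core must be a positive integer", call. = FALSE)
  }
  data.frame(label = x, core = core, suffix = vapply(m, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' @rdname parse_theme_label
#' @export
is_theme_label <- function(x) {
  grepl("^[0-9]+[sEc]?$", as.character(x)) & !grepl("^0", as.character(x))
}

# Unit tokens: nonempty, no internal whitespace; "(tn)" train markers are
# part of the token (e.g. "sqk(tn)").
check_unit_tokens <- function(x) {
  x <- as.character(x)
  bad <- !nzchar(x) | grepl("[[:space:]]", x)
  if (any(bad)) {
    stop("invalid unit token(s): ",
         paste(sprintf("'%s'", unique(x[bad])), collapse = ", "),
         call. = FALSE)
  }
  x
}
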