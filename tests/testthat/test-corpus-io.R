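test_that("theme labels parse atomically and reject malformed forms", {
  p <- parse_theme_label(c("7s", "18E", "23", "7c"))
  expect_equal(p$core, c(7L, 18L, 23L, 7L))
  expect_equal(p$suffix, c("s", "E", "", "c"))
  expect_error(parse_theme_label("18x"), "malformed")
  expect_error(parse_theme_label("s7"), "malformed")
  expect_true(all(is_theme_label(c("1", "19s", "23E"))))
  expect_false(is_theme_label("7sE"))
})

test_that("transcription CSVs parse, reject schema violations, and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("population,year,singer_id,cycle_index,position,theme_label",
               "Gabon,2005,8,1,1,7s",
               "Gabon,2005,8,1,2,26",
               "Gabon,2005,8,1,3,24",
               "Gabon,2005,8,1,4,27"), f)
  corpus <- parse_transcriptions(f)
  expect_s3_class(corpus, "song_corpus")
  expect_equal(nrow(corpus$singers), 1L)
  expect_equal(corpus$singers$cycles[[1]][[1]], c("7s", "26", "24", "27"))

  # "18" and "18E" are distinct labels
  writeLines(c("population,year,singer_id,cycle_index,position,theme_label",
               "Gabon,2004,1,1,1,18",
               "Gabon,2004,1,1,2,18E"), f)
  corpus <- parse_transcriptions(f)
  expect_equal(sort(unique(unlist(corpus$singers$cycles))), c("18", "18E"))

  # position gap is named
  writeLines(c("population,year,singer_id,cycle_index,position,theme_label",
               "Gabon,2004,1,1,1,1",
               "Gabon,2004,1,1,2,2",
               "Gabon,2004,1,1,4,3"), f)
  expect_error(parse_transcriptions(f), "missing position\\(s\\) 3")

  # duplicate position carries the line number
  writeLines(c("population,year,singer_id,cycle_index,position,theme_label",
               "Gabon,2004,1,1,1,1",
               "Gabon,2004,1,1,1,2"), f)
  expect_error(parse_transcriptions(f), "line\\(s\\) 3")

  writeLines("population,year,singer_id,cycle_index,position,theme_label", f)
  expect_error(parse_transcriptions(f), "empty")

  # round-trip: write and re-parse the packaged corpus
  corpus <- load_fixture("table3_themes")
  out <- withr::local_tempfile(fileext = ".csv")
  write_transcriptions(corpus, out)
  back <- parse_transcriptions(out)
  expect_equal(back$singers$cycles, corpus$singers$cycles,
               ignore_attr = TRUE)
  expect_setequal(paste(back$singers$population, back$singers$year,
                        back$singers$singer_id),
                  paste(corpus$singers$population, corpus$singers$year,
                        corpus$singers$singer_id))
})

test_that("packaged fixtures are pinned and match the published tables", {
  themes_csv <- system.file("extdata", "table3_themes.csv",
                            package = "whalesong")
  phrases_csv <- system.file("extdata", "table2_phrases.csv",
                             package = "whalesong")
  expect_equal(unname(tools::md5sum(themes_csv)),
               "bcec8931ff8873b2b580879c38729ea9")
  expect_equal(unname(tools::md5sum(phrases_csv)),
               "8b4950928531dabc1c775776c6cfa45d")

  corpus <- load_fixture("table3_themes")
  expect_equal(nrow(corpus$singers), 31L)
  g8 <- corpus_singer(corpus, "Gabon", 2005, "8")
  expect_equal(g8$cycles[[1]], c("7s", "26", "24", "27"))

  ph <- load_fixture("table2_phrases")
  expect_equal(nrow(ph), 67L)
  g5 <- ph$units[[which(ph$population == "Gabon" & ph$year == 2001 &
                          ph$theme_label == "5")]]
  expect_equal(g5, c("mti-sq", "sq", "mti-sq", "sq", "mti-sq", "sq",
                     "mti-sq", "mti-sq", "mti-sq"))
  expect_error(load_fixture("table9"), "arg")
})

test_that("theme_inventory collapses repeats and ignores cycle order", {
  s1 <- list(cycles = list(c("1", "4", "5", "11", "1", "3")))
  expect_equal(theme_inventory(s1), sort(c("1", "3", "4", "5", "11")))
  expect_equal(theme_inventory(list(cycles = list(c("7s", "26", "24", "27")))),
               sort(c("7s", "26", "24", "27")))
  two <- list(cycles = list(c("1", "2"), c("2", "1")))
  one <- list(cycles = list(c("1", "2")))
  expect_equal(theme_inventory(two), theme_inventory(one))
  perm <- list(cycles = rev(two$cycles))
  expect_equal(theme_inventory(perm), theme_inventory(two))
})

test_that("corpus invariants are enforced", {
  tab <- data.frame(population = c("P1", "P1"), year = 2000,
                    singer_id = c("1", "1"), stringsAsFactors = FALSE)
  tab$cycles <- list(list(c("1")), list(c("2")))
  expect_error(song_corpus(tab), "duplicate")
  tab2 <- data.frame(population = "P1", year = 2000, singer_id = "1",
                     stringsAsFactors = FALSE)
  tab2$cycles <- list(list())
  expect_error(song_corpus(tab2), "no song cycles")
})
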