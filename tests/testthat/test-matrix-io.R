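test_that("reading parses states, normalizes minus glyphs, and validates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("language,p1,p2", "L1,+,−", "L2,0,+"), path)
  m <- read_parameter_matrix(path)
  expect_s3_class(m, "parameter_matrix")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unclass(m)["L1", ], c(p1 = "+", p2 = "-"))
  expect_equal(rowSums(unclass(m) == "+"), c(L1 = 1, L2 = 1))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("language,p1,p2", "L1,+,x"), bad)
  expect_error(read_parameter_matrix(bad), "L1.*p2")

  ragged <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("language,p1,p2", "L1,+", "L2,-,+"), ragged)
  expect_error(read_parameter_matrix(ragged), "ragged")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("language,p1,p2", "L1,+,-", "L1,-,+"), dup)
  expect_error(read_parameter_matrix(dup), "duplicate")
})

test_that("write/read round-trips in both orientations", {
  m <- pm(st("+-0?"), st("0+-+"), st("++--"))
  for (orient in c("languages", "parameters")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_parameter_matrix(m, path, orientation = orient)
    back <- read_parameter_matrix(path, orientation = orient)
    expect_identical(unclass(back), unclass(m))
  }
})

test_that("summary counts partition the cells and overlaps are exhaustive", {
  m <- pm(st("+-0?+"), st("0+-++"), st("++-0-"))
  s <- summary(m)
  expect_equal(s$n_cells, 15L)
  expect_equal(s$n_plus + s$n_minus + s$n_null + s$n_unknown, s$n_cells)
  expect_equal(s$n_plus, 7L)
  expect_equal(s$n_null, 3L)
  expect_equal(s$n_unknown, 1L)
  # overlap by hand: AB share p2,p5; AC share p1,p2,p5; BC share p2,p3,p5
  expect_setequal(s$overlap, c(2L, 3L, 3L))

  all_plus <- pm(st("+++"), st("+++"))
  s2 <- summary(all_plus)
  expect_equal(s2$n_null, 0L)
  expect_equal(s2$n_plus, 6L)
  expect_true(all(s2$overlap == 3L))

  # random matrices: the partition identity holds regardless of content
  set.seed(42)
  for (i in 1:5) {
    x <- matrix(sample(c("+", "-", "0", "?"), 60, replace = TRUE), 6, 10,
                dimnames = list(paste0("L", 1:6), paste0("p", 1:10)))
    si <- summary(parameter_matrix(x))
    expect_equal(si$n_plus + si$n_minus + si$n_null + si$n_unknown, 60L)
  }
})

test_that("dependency validation flags exactly the inconsistent cells", {
  m <- pm(st("-+"), st("-0"), st("+-"), st("+0"),
          languages = c("bad_valued", "ok_null", "ok_valued", "bad_null"))
  expect_equal(nrow(validate_dependencies(m, NULL)), 0L)

  deps <- data.frame(param = "p2", requires = "p1", state = "+")
  v <- validate_dependencies(m, deps)
  expect_equal(nrow(v), 2L)
  expect_setequal(v$language, c("bad_valued", "bad_null"))
  expect_equal(v$problem[v$language == "bad_valued"], "valued_but_condition_unmet")
  expect_equal(v$problem[v$language == "bad_null"], "null_but_condition_met")

  # unknown controller state never flags
  m2 <- pm(st("?+"), languages = "L1")
  expect_equal(nrow(validate_dependencies(m2, deps)), 0L)

  expect_error(validate_dependencies(m, data.frame(
    param = "p2", requires = "p9", state = "+")), "unknown")
  cyc <- data.frame(param = c("p1", "p2"), requires = c("p2", "p1"),
                    state = "+")
  expect_error(validate_dependencies(m, cyc), "cyclic")
})

test_that("conjunctive dependencies require every term", {
  m <- pm(st("++-"), st("+--"), st("+-0"),
          languages = c("both_met", "unmet_valued", "unmet_null"))
  deps <- data.frame(param = c("p3", "p3"), requires = c("p1", "p2"),
                     state = c("+", "+"))
  v <- validate_dependencies(m, deps)
  expect_equal(v$language, "unmet_valued")
})

test_that("NEXUS export recodes, is parseable, and round-trips", {
  m <- pm(st("+"), languages = "Solo")
  path <- withr::local_tempfile(fileext = ".nex")
  write_nexus(m, path)
  lines <- readLines(path)
  expect_true(any(grepl("^\\s*Solo +1$", lines)))

  m2 <- pm(st("+-0"), st("-++"), languages = c("L1", "L 2"))
  path2 <- withr::local_tempfile(fileext = ".nex")
  write_nexus(m2, path2)
  txt <- readLines(path2)
  expect_true(any(grepl("NTAX=2 NCHAR=3", txt)))
  mat_lines <- grep("^    ", txt, value = TRUE)
  seqs <- sub("^\\s*\\S+\\s+", "", mat_lines)
  expect_true(all(grepl("^[01?]+$", seqs)))
  expect_true(any(grepl("\\?$", seqs[1]))) # the null cell became missing

  back <- read_nexus_matrix(path2)
  expect_equal(unname(unclass(back)),
               matrix(c("+", "-", "-", "+", "?", "+"), 2, 3))

  # independent parser agrees on content
  via_ape <- ape::read.nexus.data(path2)
  expect_equal(length(via_ape), 2L)
  expect_equal(paste(via_ape[[1]], collapse = ""), "10?")

  empty <- structure(matrix(character(0), 0, 0),
                     class = c("parameter_matrix", "matrix", "array"))
  expect_error(write_nexus(empty, tempfile()), "empty")
})

test_that("packaged Gold-Standard table matches the published structure", {
  gs <- pcm_gold_standard()
  expect_length(gs, 24L)
  expect_length(pcm_gold_standard(exclude = "Altaic"), 23L)
  expect_equal(sort(unique(unlist(gs["IE"]))) |> length(), 39L)
  langs <- pcm_languages()
  expect_equal(nrow(langs), 69L)
  expect_true(all(unlist(gs) %in% langs$name))
  expect_equal(length(unique(langs$family)), 13L)
})
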