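test_that("contact lists parse with correct record and timestamp counts", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("20 A B", "20 A C", "40 B C"), f)
  s <- read_contact_list(f, dialect = "sociopatterns")
  expect_equal(t_count(s), 3L)
  expect_equal(t_max(s), 2L)
  expect_setequal(event_vertices(s), c("A", "B", "C"))
})

test_that("metadata columns and comment lines are ignored", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# a comment", "", "10 A B classX classY"), f)
  s <- read_contact_list(f, dialect = "sociopatterns")
  expect_equal(t_count(s), 1L)
  expect_setequal(event_vertices(s), c("A", "B"))
})

test_that("malformed and empty files raise parse errors naming the line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("20 A B", "20 A"), f)
  expect_error(read_contact_list(f, dialect = "sociopatterns"), "line 2")
  writeLines(c("% only comments"), f)
  expect_error(read_contact_list(f, dialect = "sociopatterns"), "no data")
  writeLines(c("x A B"), f)
  expect_error(read_contact_list(f, dialect = "sociopatterns"), "timestamp")
  expect_error(read_contact_list(file.path(tempdir(), "nope.txt")),
               "not found")
})

test_that("network-repository rows parse as i j [w] t with comment header", {
  f <- withr::local_tempfile(fileext = ".edges")
  writeLines(c("% bip unweighted", "5,12,1082040961", "7,12,2,1082155839"), f)
  s <- read_contact_list(f, dialect = "netrepo_edges")
  expect_equal(t_count(s), 2L)
  expect_equal(s$time, c(1082040961, 1082155839))
  expect_equal(s$weight, c(1, 2))
  expect_setequal(event_vertices(s), c("5", "12", "7"))
})

test_that("generic dialect honours a custom column map", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t3\t100"), f)
  s <- read_contact_list(f, dialect = "generic_tsv",
                         column_map = c(i = 1, j = 2, weight = 3, time = 4))
  expect_equal(s$time, 100)
  expect_equal(s$weight, 3)
})

test_that("self-contacts are kept as single-actor events with a warning", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("10 A A", "20 A B"), f)
  expect_warning(s <- read_contact_list(f), "self-contact")
  expect_equal(t_count(s), 2L)
  expect_true(is.na(s$j[1]))
  expect_setequal(event_vertices(s), c("A", "B"))
})

test_that("events are sorted by time with ties kept in input order", {
  s <- event_stream(data.frame(time = c(30, 10, 30, 10),
                               i = c("C", "A", "D", "B"),
                               j = c("D", "B", "C", "A")))
  expect_equal(s$time, c(10, 10, 30, 30))
  expect_equal(s$i, c("A", "B", "C", "D"))
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("40 B C", "20 A B", "20 A C"), f)
  expect_equal(read_contact_list(f)$time, c(20, 20, 40))
})

test_that("write -> read round-trips the event multiset, t_count and t_max", {
  set.seed(42)
  for (rep in 1:5) {
    s <- random_stream(weighted = rep %% 2 == 0)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_contact_list(s, f)
    s2 <- read_contact_list(f, dialect = "generic_tsv")
    expect_identical(stream_multiset(s2), stream_multiset(s))
    expect_equal(t_count(s2), t_count(s))
    expect_equal(t_max(s2), t_max(s))
  }
})

test_that("t_max equals the brute-force count of distinct times", {
  set.seed(7)
  for (rep in 1:10) {
    s <- random_stream(n_events = sample(5:40, 1))
    seen <- character(0)
    for (t in s$time) seen <- union(seen, as.character(t))
    expect_equal(t_max(s), length(seen))
    expect_lte(t_max(s), t_count(s))
  }
})

test_that("serialising an empty stream is refused", {
  s <- event_stream(data.frame(time = 1, i = "A", j = "B"))
  empty <- s[0, ]
  class(empty) <- class(s)
  attr(empty, "vertices") <- character(0)
  expect_error(write_contact_list(empty, tempfile()), "empty")
  expect_error(event_stream(data.frame(time = numeric(), i = character(),
                                       j = character())),
               "at least one event")
})
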