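test_that("read_ehr_corpus reads back what write_ehr_corpus wrote (both dialects)", {
  corpus <- random_corpus(n = 15, seed = 4)
  code_sets <- function(cp) lapply(cp$records, function(r)
    lapply(r$visits, function(v) sort(cp$vocab[v$codes])))
  for (dialect in c("jsonl", "flat")) {
    path <- withr::local_tempfile()
    write_ehr_corpus(corpus, path, dialect = dialect)
    # visits are code sets; equality is up to the rebuilt vocabulary order
    back <- read_ehr_corpus(path, dialect = dialect)
    expect_equal(code_sets(back), code_sets(corpus))
    expect_equal(vapply(back$records, `[[`, character(1), "pid"),
                 vapply(corpus$records, `[[`, character(1), "pid"))
    expect_equal(lapply(back$records, function(r) topicgru:::visit_labels(r)),
                 lapply(corpus$records, function(r) topicgru:::visit_labels(r)))
    # with the explicit vocabulary the round trip is field-for-field identical
    exact <- read_ehr_corpus(path, dialect = dialect, vocab = corpus$vocab)
    expect_equal(exact$vocab, corpus$vocab)
    if (dialect == "jsonl") expect_equal(exact$records, corpus$records)
  }
  # jsonl also round-trips times exactly
  path <- withr::local_tempfile()
  write_ehr_corpus(corpus, path, "jsonl")
  back <- read_ehr_corpus(path, "jsonl")
  expect_identical(lapply(back$records, function(r) lapply(r$visits, `[[`, "time")),
                   lapply(corpus$records, function(r) lapply(r$visits, `[[`, "time")))
})

test_that("a one-patient file reads back with the right shape", {
  path <- withr::local_tempfile()
  writeLines(c('{"pid":"p1","visits":[{"codes":["A"]},{"codes":["A","B"]}]}'), path)
  corpus <- read_ehr_corpus(path, "jsonl")
  expect_length(corpus$vocab, 2)
  expect_length(corpus$records[[1]]$visits, 2)
  expect_equal(lengths(lapply(corpus$records[[1]]$visits, `[[`, "codes")), c(1L, 2L))
})

test_that("malformed lines and unknown fixed-vocabulary codes raise line-naming errors", {
  path <- withr::local_tempfile()
  writeLines(c('{"pid":"p1","visits":[{"codes":["A"]}]}', "not json at all {"), path)
  expect_error(read_ehr_corpus(path, "jsonl"), "line 2")
  path2 <- withr::local_tempfile()
  writeLines('{"pid":"p1","visits":[{"codes":["Z"]}]}', path2)
  expect_error(read_ehr_corpus(path2, "jsonl", vocab = c("A", "B")), "Z")
  path3 <- withr::local_tempfile()
  writeLines("p1\tbadvisitnocomma", path3)
  expect_error(read_ehr_corpus(path3, "flat"), "line 1")
})

test_that("writing is deterministic and handles empty and optional-field corpora", {
  empty <- ehr_corpus(c("A"), list())
  path <- withr::local_tempfile()
  write_ehr_corpus(empty, path)
  expect_length(read_ehr_corpus(path)$records, 0)

  corpus <- random_corpus(n = 40, seed = 9)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_ehr_corpus(corpus, p1)
  write_ehr_corpus(corpus, p2)
  expect_identical(readLines(p1), readLines(p2))

  # optional fields absent are omitted from the serialization
  bare <- ehr_corpus(c("A"), list(ehr_record("p", list(ehr_visit(1L, label = 0L)))))
  p3 <- withr::local_tempfile()
  write_ehr_corpus(bare, p3)
  expect_false(grepl('"t"|"loc"|"dur"', readLines(p3)))
})

test_that("write to an unwritable path errors", {
  corpus <- tiny_corpus()
  expect_error(write_ehr_corpus(corpus, "/nonexistent-dir/x/y.jsonl"), "writing")
})

test_that("build_labels applies the (discharge, discharge + 30] window", {
  mk <- function(times, locs, durations = NULL) {
    visits <- lapply(seq_along(times), function(i) {
      ehr_visit(1L, time = times[i], loc = locs[i],
                duration = if (is.null(durations)) NULL else durations[i])
    })
    ehr_record("p", visits)
  }
  # single inpatient visit: nothing can follow
  r <- build_labels(mk(0L, "inpatient"))
  expect_equal(r$visits[[1]]$label, 0L)
  expect_true(r$mask)
  # discharge day 10 (admit 10, duration 0): readmit day 40 is 30 days -> 1
  r <- build_labels(mk(c(10L, 40L), c("inpatient", "inpatient")))
  expect_equal(r$visits[[1]]$label, 1L)
  # day 41 is outside the closed right endpoint -> 0
  r <- build_labels(mk(c(10L, 41L), c("inpatient", "inpatient")))
  expect_equal(r$visits[[1]]$label, 0L)
  # duration shifts the anchor to discharge: admit 5 + 5 days -> discharge 10
  r <- build_labels(mk(c(5L, 40L), c("inpatient", "inpatient"), c(5L, 0L)))
  expect_equal(r$visits[[1]]$label, 1L)
  # same-day (not strictly after discharge) does not count
  r <- build_labels(mk(c(10L, 10L), c("inpatient", "inpatient")))
  expect_equal(r$visits[[1]]$label, 0L)
  # outpatient visits are mask-false and never labeled
  r <- build_labels(mk(c(0L, 5L, 20L), c("inpatient", "outpatient", "inpatient")))
  expect_equal(r$mask, c(TRUE, FALSE, TRUE))
  expect_equal(r$visits[[1]]$label, 1L)
  expect_null(r$visits[[2]]$label)
  expect_equal(r$visits[[3]]$label, 0L)
})

test_that("interleaved non-inpatient visits never change an inpatient label", {
  set.seed(31)
  for (i in 1:20) {
    times_in <- sort(sample(0:200, 5))
    base <- ehr_record("p", lapply(times_in, function(t)
      ehr_visit(1L, time = t, loc = "inpatient")))
    lab_base <- topicgru:::visit_labels(build_labels(base))
    # splice outpatient visits at random times
    times_out <- sort(sample(0:200, 4))
    all_times <- c(times_in, times_out)
    all_locs <- c(rep("inpatient", 5), rep("outpatient", 4))
    ord <- order(all_times, all_locs == "outpatient")
    mixed <- ehr_record("p", lapply(seq_along(ord), function(k)
      ehr_visit(1L, time = all_times[ord[k]], loc = all_locs[ord[k]])))
    lab_mixed <- topicgru:::visit_labels(build_labels(mixed))
    expect_equal(lab_mixed[!is.na(lab_mixed)], lab_base[!is.na(lab_base)])
  }
})

test_that("build_labels without timestamps directs to pre-labeled input", {
  r <- ehr_record("p", list(ehr_visit(1L, label = 0L)))
  expect_error(build_labels(r), "pre-labeled")
})

test_that("split_corpus gives exact, disjoint, reproducible patient-level splits", {
  corpus <- random_corpus(n = 50, seed = 2)
  sp <- split_corpus(corpus, c(30, 10, 10), seed = 7)
  expect_equal(unname(table(sp$split)[c("train", "validation", "test")]),
               array(c(30L, 10L, 10L)), ignore_attr = TRUE)
  sp2 <- split_corpus(corpus, c(30, 10, 10), seed = 7)
  expect_identical(sp$split, sp2$split)
  sp3 <- split_corpus(corpus, c(50, 0, 0), seed = 1)
  expect_true(all(sp3$split == "train"))
  expect_error(split_corpus(corpus, c(49, 1, 1)), "exceed")
  for (s in 1:5) {
    spl <- split_corpus(corpus, c(25, 15, 10), seed = s)$split
    expect_equal(sum(!is.na(spl)), 50)  # exhaustive over requested sizes
    expect_equal(as.integer(sort(table(spl))), c(10L, 15L, 25L))
  }
})

test_that("corpus_stats matches hand counts and its arithmetic invariants", {
  st <- corpus_stats(tiny_corpus())
  expect_equal(unclass(st)[c("n_patients", "n_visits", "n_events")],
               list(n_patients = 1L, n_visits = 2L, n_events = 3L))
  expect_equal(st$avg_visits_per_patient, 2)
  expect_equal(st$avg_events_per_patient, 3)
  expect_equal(st$n_unique_codes, 2L)

  st3 <- corpus_stats(three_patient_corpus())
  expect_equal(st3$n_patients, 3L)
  expect_equal(st3$n_visits, 7L)
  expect_equal(st3$n_events, 15L)

  expect_error(corpus_stats(ehr_corpus("A", list())), "empty")

  for (s in 1:10) {
    st <- corpus_stats(random_corpus(n = 10, seed = s))
    expect_equal(st$avg_visits_per_patient, st$n_visits / st$n_patients)
    expect_equal(st$avg_events_per_patient, st$n_events / st$n_patients)
    expect_lte(st$n_unique_codes, 12)
  }
})

test_that("corpus_stats agrees with the de novo generator's own bookkeeping", {
  sim <- simulate_ehr(n_patients = 25, vocab_size = 40, n_topics = 4,
                      mean_visits = 10, mean_codes_per_visit = 3, seed = 5)
  st <- corpus_stats(sim$corpus)
  expect_equal(st$n_visits, sim$truth$n_visits)
  expect_equal(st$n_events, sim$truth$n_events)
  expect_equal(st$n_patients, 25L)
})

test_that("corpus constructor rejects invalid code indices and bad splits", {
  expect_error(ehr_corpus(c("A"), list(
    ehr_record("p", list(ehr_visit(2L, label = 0L))))), "outside the vocabulary")
  expect_error(ehr_corpus(c("A", "A"), list()), "duplicate")
  expect_error(ehr_corpus(c("A"), list(ehr_record("p", list(ehr_visit(1L, label = 0L)))),
                          split = "weird"), "unknown split")
})
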