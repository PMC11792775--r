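test_that("long loader counts participant responses per cue", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_long_tsv(c("p1", "p2", "p1"), c("cat", "cat", "cat"),
                 c("pet", "pet", "dog"), f)
  d <- read_associations(f)
  counts <- moralassoc:::response_counts(d, "cat")
  expect_identical(counts[["pet"]], 2L)
  expect_identical(counts[["dog"]], 1L)
  expect_identical(sum(counts), 3L)
})

test_that("missing-response sentinels are dropped, not counted", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_long_tsv(rep("p1", 5), rep("cat", 5),
                 c("pet", "NA", "Unknown word", "No more responses", "  "), f)
  d <- read_associations(f)
  expect_identical(nrow(d$records), 1L)
  expect_identical(sum(d$counts$n), 1L)
})

test_that("loader errors name the failure", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("participant\tcue", f)  # header only, missing response column
  expect_error(read_associations(f), class = "moralassoc_format_error")
  expect_error(read_associations(f), "response")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("participant\tcue\tresponse", f2)
  expect_error(read_associations(f2), class = "moralassoc_empty_error")
})

test_that("wide rows expand to one record per non-missing slot", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("participant\tcue\tR1\tR2\tR3",
               "p1\tcigarette\tsmoke\tbad\tNA"), f)
  d <- read_associations(f, format = "wide")
  expect_identical(nrow(d$records), 2L)
  expect_setequal(d$records$response, c("smoke", "bad"))
  expect_setequal(d$records$position, c(1L, 2L))
})

test_that("wide file and its long expansion yield identical count matrices", {
  set.seed(42)
  n <- 50
  r <- matrix(sample(c(sprintf("w%02d", 1:15), "NA"), n * 3, replace = TRUE),
              ncol = 3)
  fw <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("participant\tcue\tR1\tR2\tR3",
               sprintf("p%03d\tcue%d\t%s\t%s\t%s", seq_len(n), seq_len(n) %% 4,
                       r[, 1], r[, 2], r[, 3])), fw)
  long <- data.frame(participant = rep(sprintf("p%03d", seq_len(n)), 3),
                     cue = rep(paste0("cue", seq_len(n) %% 4), 3),
                     response = c(r))
  fl <- withr::local_tempfile(fileext = ".tsv")
  write_long_tsv(long$participant, long$cue, long$response, fl)
  dw <- read_associations(fw, format = "wide")
  dl <- read_associations(fl, format = "long")
  expect_identical(dw$counts, dl$counts)
  expect_equal(sum(dw$counts$n), sum(!(c(r) == "NA")))  # <= 3 slots per row
})

test_that("retained record count matches an independent line tally (seed 11)", {
  set.seed(11)
  n <- 1000
  resp <- sample(c(sprintf("w%02d", 1:40), "NA", "Unknown word"), n,
                 replace = TRUE, prob = c(rep(1, 40), 3, 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_long_tsv(sprintf("p%04d", sample.int(200, n, TRUE)),
                 sprintf("q%d", sample.int(10, n, TRUE)), resp, f)
  d <- read_associations(f)
  # independent tally: count non-sentinel lines in the raw file
  lines <- readLines(f)[-1]
  retained <- sum(!grepl("\t(NA|Unknown word)$", lines))
  expect_identical(sum(d$counts$n), retained)
  expect_identical(nrow(d$records), retained)
  # per-cue count conservation
  for (cu in d$cues) {
    expect_identical(sum(moralassoc:::response_counts(d, cu)),
                     sum(d$records$cue == cu))
  }
})

test_that("token normalization lowercases, trims and noun-lemmatizes", {
  expect_identical(normalize_token("Cigarettes"), "cigarette")
  expect_identical(normalize_token("bad"), "bad")
  expect_identical(normalize_token("  Smoke "), "smoke")
  expect_identical(normalize_token("Second   Hand  Smoke"), "second hand smoke")
  expect_identical(normalize_token("Cigarettes", lemmatize = FALSE), "cigarettes")
  expect_identical(lemmatize_noun(c("churches", "glasses", "ladies", "wolves",
                                    "boxes", "children", "bus", "analysis")),
                   c("church", "glass", "lady", "wolf",
                     "box", "child", "bus", "analysis"))
})

test_that("canonical long TSV writer round-trips", {
  d <- make_assoc(c("p1", "p1", "p2"), c("cat", "cat", "dog"),
                  c("pet", "fur", "bone"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_associations(d, f, comment = "seed=99")
  expect_true(startsWith(readLines(f, n = 1), "#"))
  d2 <- read_associations(f)
  expect_identical(d$counts, d2$counts)
})

test_that("response graph counts unordered within-participant pairs", {
  d <- make_assoc(c("p1", "p1", "p1", "p2", "p2"),
                  rep("x", 5), c("a", "b", "c", "a", "b"))
  g <- response_graph(d, "x")
  expect_identical(g$W["a", "b"], 2L)
  expect_identical(g$W["a", "c"], 1L)
  expect_identical(g$W["b", "c"], 1L)
  expect_identical(g$participant_count, 2L)
  expect_error(response_graph(d, "zebra"), class = "moralassoc_missing_cue_error")
})

test_that("single responses leave nodes isolated and duplicates add no self-edge", {
  d <- make_assoc(c("p1", "p2", "p3", "p3"), rep("x", 4),
                  c("a", "b", "c", "c"))
  g <- response_graph(d, "x")
  expect_true(all(g$W == 0L))
  expect_true(all(g$isolated))
  expect_identical(diag(g$W), c(a = 0L, b = 0L, c = 0L))
})

test_that("graph symmetry, zero diagonal and pair totals hold on random data", {
  set.seed(101)
  for (i in 1:100) {
    rd <- random_dataset(n_cues = 2, max_resp = 25, vocab_size = 10)
    cu <- sample(rd$data$cues, 1)
    g <- response_graph(rd$data, cu)
    expect_identical(g$W, t(g$W))
    expect_true(all(diag(g$W) == 0L))
    # brute-force pair enumeration over participants
    rec <- rd$data$records[rd$data$records$cue == cu, ]
    expected_pairs <- sum(vapply(split(rec$response, rec$participant),
                                 function(r) choose(length(unique(r)), 2),
                                 numeric(1)))
    expect_equal(sum(g$W[upper.tri(g$W)]), expected_pairs)
  }
})
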