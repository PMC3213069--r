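test_that("the significance score matches the worked examples", {
  expect_equal(significance_score(2, 4), 0.4)
  expect_equal(significance_score(5, 10), 5 / 11)
  expect_equal(sprintf("%.2f", significance_score(5, 10)), "0.45")
  expect_equal(significance_score(0, 7), 0)
  expect_equal(significance_score(3, 3), 0.75)
  expect_error(significance_score(5, 4), class = "specmatch_logic_error")
  expect_error(significance_score(1, 0), class = "specmatch_logic_error")
  # f1 is the plain fraction
  expect_equal(significance_score(2, 4, fn = "f1"), 0.5)
})

test_that("score bounds and monotonicity hold across the (matched, total) grid", {
  for (total in 1:30) {
    m <- 0:total
    s <- significance_score(m, total)
    expect_true(all(s >= 0 & s < 1))
    expect_true(all(diff(s) > 0))  # strictly increasing in matched
  }
  # equal match fraction, more peaks => strictly larger score
  expect_true(significance_score(5, 10) > significance_score(2, 4))
  expect_true(significance_score(50, 100) > significance_score(5, 10))
})

test_that("peak matching uses an inclusive window, once per library peak", {
  expect_equal(count_matches(1.00, 1.00, 0), list(matched = 1L, coords = 1.00))
  expect_equal(count_matches(1.00, 1.01, 0)$matched, 0L)
  expect_equal(count_matches(1.00, 1.01, 0.01),
               list(matched = 1L, coords = 1.00))
  # two sample peaks in one library window still count once
  expect_equal(count_matches(c(1.00, 2.00), c(1.00, 1.01), 0.01),
               list(matched = 1L, coords = 1.00))
  # strictly outside the window
  expect_equal(count_matches(1.00, 1.01, 0.005)$matched, 0L)
})

test_that("MH1 reproduces the hand-traced toy search", {
  lib <- toy_library()
  res <- search_mh1(c(1.00, 2.00, 3.00), lib, r = 0.5)
  expect_equal(res$metabolite_id, c("A", "B"))
  expect_equal(res$score, c(0.75, 0.5))
  expect_equal(res$rank, 1:2)
  expect_equal(res$matched_coords[[1]], c(1.00, 2.00, 3.00))
  # C is excluded with score 0
  expect_false("C" %in% res$metabolite_id)
})

test_that("MH1 self-recovery, degenerate thresholds, and input errors", {
  set.seed(5)
  lib <- generate_library(12, c(2, 6), overlap_rate = 0, seed = 23)
  for (i in c(1, 5, 12)) {
    res <- search_mh1(lib$peaks[[i]], lib, r = 0.5)
    expect_equal(res$metabolite_id[1], lib$id[i])
    tot <- nrow(lib$peaks[[i]])
    expect_equal(res$score[1], tot / (tot + 1))
  }
  # r = 1 can never be reached (score < 1 always)
  expect_equal(nrow(search_mh1(lib$peaks[[1]], lib, r = 1)), 0L)
  expect_error(search_mh1(numeric(0), lib), class = "specmatch_empty_input")
  expect_error(search_mh1(c(1.00), lib, features = list(solvent = "no-such")),
               class = "specmatch_config_error")
  expect_error(search_config("MH1", tolerance = 0.02),
               class = "specmatch_config_error")
})

test_that("the noise threshold drops sub-eta sample peaks before matching", {
  lib <- toy_library()
  sample <- peak_tbl(c(1.00, 2.00, 3.00), c(10, 0.5, 10))
  res <- search_mh1(sample, lib, eta = 1, r = 0.1)
  expect_equal(res$matched[res$metabolite_id == "A"], 2L)
})

test_that("MH2 windows recapture shifted peaks; tolerance 0 degenerates to MH1", {
  lib <- ref_library(list(metabolite_record("A", peaks = c(1.00, 2.00))))
  shifted <- c(1.01, 2.01)
  expect_equal(search_mh2(shifted, lib, tolerance = 0.01)$score, 2 / 3)
  expect_equal(nrow(search_mh2(shifted, lib, tolerance = 0.005)), 0L)
  expect_equal(nrow(search_mh2(shifted, lib, tolerance = 0)), 0L)
})

test_that("MH2 with tolerance 0 is bit-identical to MH1 on randomized cases", {
  set.seed(77)
  for (rep in 1:60) {
    cs <- random_case()
    r <- runif(1, 0, 0.9)
    a <- search_mh1(cs$sample, cs$lib, r = r)
    b <- search_mh2(cs$sample, cs$lib, r = r)
    attr(a, "config") <- attr(b, "config") <- NULL
    expect_identical(a, b)
  }
})

test_that("MH3 reproduces the hand trace: consumed peaks suppress later hits", {
  lib <- ref_library(list(
    metabolite_record("A", peaks = c(1.00, 2.00)),
    metabolite_record("B", peaks = 1.00)
  ))
  res <- search_mh3(c(1.00, 2.00), lib, r = 0.5)
  expect_equal(res$metabolite_id, "A")
  expect_equal(res$score, 2 / 3)
  # B is a deliberate false negative: its only peak was consumed by A
  expect_false("B" %in% res$metabolite_id)
  expect_equal(attr(res, "unassigned"), numeric(0))
})

test_that("MH3 on disjoint mixtures reports exactly the members", {
  lib <- generate_library(15, c(2, 5), overlap_rate = 0, seed = 31)
  mix <- make_mixture(lib, 4, seed = 8)
  res <- search_mh3(mix$pooled_peaks, lib, r = 0.5)
  expect_setequal(res$metabolite_id, mix$member_ids)
  tot <- vapply(res$metabolite_id,
                function(id) nrow(lib$peaks[[match(id, lib$id)]]), integer(1))
  expect_equal(res$score, tot / (tot + 1), ignore_attr = TRUE)
})

test_that("MH3 terminates on residual peaks and reports them unassigned", {
  lib <- ref_library(list(metabolite_record("A", peaks = c(1.00, 2.00))))
  res <- search_mh3(c(1.00, 2.00, 9.00), lib, r = 0.5)
  expect_equal(res$metabolite_id, "A")
  expect_equal(attr(res, "unassigned"), 9.00)
})

test_that("MH3 enforces mutual exclusion and is contained in MH1's output", {
  set.seed(99)
  for (rep in 1:40) {
    cs <- random_case(k = 8, max_peaks = 6, max_sample = 14)
    m1 <- search_mh1(cs$sample, cs$lib, r = 0.5, max_results = 1000)
    m3 <- search_mh3(cs$sample, cs$lib, r = 0.5, max_results = 1000)
    # pairwise disjoint matched coordinates, all within the sample
    coords <- m3$matched_coords
    all_coords <- unlist(coords)
    expect_equal(anyDuplicated(all_coords), 0L)
    expect_true(all(all_coords %in% cs$sample$ppm))
    # containment: removal can only lower scores
    expect_true(all(m3$metabolite_id %in% m1$metabolite_id))
  }
})

test_that("MH3 equals an independently coded greedy re-simulation", {
  set.seed(123)
  for (rep in 1:40) {
    cs <- random_case(k = 10, max_peaks = 6, max_sample = 16)
    r <- sample(c(0.3, 0.5, 0.7), 1)
    got <- search_mh3(cs$sample, cs$lib, r = r, max_results = 1000)
    want <- oracle_greedy(cs$lib, cs$sample$ppm, r = r)
    expect_identical(got$metabolite_id, want)
  }
})

test_that("MH3 with nonzero tolerance is opt-in and consumes windowed peaks", {
  lib <- ref_library(list(metabolite_record("A", peaks = c(1.00, 2.00)),
                          metabolite_record("B", peaks = 1.02)))
  expect_error(search_mh3(c(1.01, 2.01), lib, tolerance = 0.01),
               class = "specmatch_config_error")
  res <- search_mh3(c(1.01, 2.01), lib, tolerance = 0.01,
                    experimental_drift = TRUE)
  # A matches both shifted peaks and consumes them; B's window (1.02 +/- .01)
  # covered 1.01 too, so B is starved
  expect_equal(res$metabolite_id, "A")
})

test_that("ranking breaks ties by matched count then lexicographic id", {
  scored <- tibble::tibble(
    metabolite_id = c("B", "A", "D", "C"),
    name = metabolite_id,
    score = c(0.5, 0.75, 0.5, 0.5),
    matched = c(3L, 3L, 2L, 2L),
    total = c(5L, 3L, 3L, 3L),
    matched_coords = list(1, 1, 1, 1)
  )
  ranked <- rank_results(scored, max_results = 3)
  expect_equal(ranked$metabolite_id, c("A", "B", "C"))
  expect_equal(ranked$rank, 1:3)
})

test_that("the dispatcher and the per-method functions agree", {
  cs <- list(lib = toy_library(), sample = as_peak_list(c(1, 2, 3)))
  a <- search_library(cs$sample, cs$lib, method = "MH1")
  b <- search_mh1(cs$sample, cs$lib)
  expect_identical(tidy(a), tidy(b))
  expect_equal(glance(a)$method, "MH1")
  expect_equal(glance(a)$n_hits, 2L)
})

test_that("results serialize as a TSV mirroring the search view", {
  res <- search_mh1(c(1, 2, 3), toy_library())
  p <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, p)
  tab <- utils::read.delim(p, colClasses = "character")
  expect_equal(tab$metabolite_id, c("A", "B"))
  expect_equal(tab$score, c("0.75", "0.50"))
  expect_equal(as.numeric(tab$score_full), c(0.75, 0.5))
})
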