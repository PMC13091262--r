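# Independent brute-force reimplementation of the matching rules, used as an
# oracle against the package's scoring path on random small instances.
oracle_scores <- function(results, truths, case_sensitive = TRUE) {
  norm <- function(x) { x <- trimws(x); if (!case_sensitive) tolower(x) else x }
  correct <- extracted <- truth_n <- 0
  s_err <- integer(0); e_err <- integer(0); excluded <- 0
  for (r in results) {
    tr <- truths[[r$dataset_id]]
    pn <- norm(r$records$sbre)
    tn <- norm(tr$sbre)
    pset <- unique(pn)
    correct <- correct + sum(pset %in% tn)
    extracted <- extracted + length(pset)
    truth_n <- truth_n + length(unique(tn))
    for (k in seq_along(pn)) {
      unique_pred <- sum(pn == pn[k]) == 1
      hits <- which(tn == pn[k])
      if (unique_pred && length(hits) == 1) {
        s_err <- c(s_err, r$records$start[k] - tr$start[hits])
        e_err <- c(e_err, r$records$end[k] - tr$end[hits])
      } else excluded <- excluded + 1
    }
  }
  list(precision = if (extracted) correct / extracted else NA_real_,
       recall = if (truth_n) correct / truth_n else NA_real_,
       start_errors = s_err, end_errors = e_err, n_excluded = excluded)
}

test_that("name deduplication returns the set and the duplicated subset", {
  d <- dedupe_names(c("Binding Site A", "Binding Site A", "Structural Motif A"))
  expect_setequal(d$names, c("Binding Site A", "Structural Motif A"))
  expect_identical(d$duplicated, "Binding Site A")

  e <- dedupe_names(character(0))
  expect_length(e$names, 0)
  expect_length(e$duplicated, 0)

  expect_identical(dedupe_names(" Binding Site A")$names, "Binding Site A")
  expect_identical(dedupe_names("Motif a", matcher_config(case_sensitive = FALSE))$names,
                   "motif a")
})

test_that("the single-image worked example scores exactly as computed by hand", {
  truths <- list(img = fixture_truth())
  results <- list(make_result("img", fixture_predictions()))
  m <- matcher_config(case_sensitive = FALSE)

  s <- score_sbre_corpus(results, truths, m)
  expect_identical(s$n_correct, 3L)
  expect_identical(s$n_extracted, 4L)
  expect_identical(s$n_truth, 3L)
  expect_equal(s$precision, 0.75)
  expect_equal(s$recall, 1.0)
  expect_equal(s$f1, 2 * 0.75 / 1.75)

  err <- boundary_errors(results, truths, m)
  expect_identical(err$start_errors, c(-2L, -53L, 10L))
  expect_identical(err$end_errors, c(3L, -47L, 9L))
  expect_identical(err$n_excluded, 1L)

  mae <- boundary_mae(err)
  expect_equal(mae$mae_start, 65 / 3)
  expect_equal(mae$mae_end, 59 / 3)

  # under case-sensitive matching the same predictions all miss
  strict <- score_sbre_corpus(results, truths, matcher_config())
  expect_identical(strict$n_correct, 0L)
})

test_that("degenerate corpora hit the defined edge values", {
  truths <- make_truth_corpus(4)
  perfect <- lapply(names(truths), function(id) make_result(id, truths[[id]]))
  s <- score_sbre_corpus(perfect, truths)
  expect_equal(c(s$precision, s$recall, s$f1), c(1, 1, 1))
  mae <- boundary_mae(boundary_errors(perfect, truths))
  expect_equal(c(mae$mae_start, mae$mae_end), c(0, 0))

  blanks <- lapply(names(truths), function(id)
    make_result(id, msabench:::empty_records(), blank = TRUE, n_attempts = 3L))
  s0 <- score_sbre_corpus(blanks, truths)
  expect_true(is.na(s0$precision))
  expect_equal(s0$recall, 0)
  e0 <- boundary_errors(blanks, truths)
  expect_length(e0$start_errors, 0)
  expect_true(is.na(boundary_mae(e0)$mae_start))

  expect_error(score_sbre_corpus(list(make_result("ghost", fixture_truth())),
                                 truths), "ghost")
})

test_that("duplicated predicted names are excluded from boundary pairing", {
  truths <- list(img = fixture_truth())
  recs <- rbind(fixture_truth()[1, ], fixture_truth()[1, ])
  recs$start[2] <- 45L
  err <- boundary_errors(list(make_result("img", recs)), truths)
  expect_length(err$start_errors, 0)
  expect_identical(err$n_excluded, 2L)

  # reversed boundaries still pair; errors just reflect them
  rev <- fixture_truth()
  tmp <- rev$start; rev$start <- rev$end; rev$end <- tmp
  err2 <- boundary_errors(list(make_result("img", rev)), truths)
  expect_identical(err2$start_errors, fixture_truth()$end - fixture_truth()$start)
  expect_identical(err2$n_excluded, 0L)
})

test_that("histograms conserve counts and align to integer bins", {
  z <- structure(list(start_errors = rep(0L, 5), end_errors = rep(0L, 5),
                      n_excluded = 0L), class = "boundary_errors")
  h <- error_histogram(z, 1)
  expect_identical(sum(h$counts), 10L)
  expect_identical(h$counts[h$counts > 0], 10L)
  expect_equal(h$edges[which(h$counts > 0)], 0)

  mixed <- structure(list(start_errors = c(-60L, -1L, 0L, 2L),
                          end_errors = c(-60L, 0L, 0L, 3L),
                          n_excluded = 0L), class = "boundary_errors")
  h2 <- error_histogram(mixed, 5)
  expect_identical(sum(h2$counts), 8L)
  expect_true(all(h2$edges %% 5 == 0))

  empty <- structure(list(start_errors = integer(0), end_errors = integer(0),
                          n_excluded = 0L), class = "boundary_errors")
  expect_length(error_histogram(empty)$counts, 0)
})

test_that("scores match an exhaustive independent oracle on random instances", {
  pool <- c("Alpha A", "Alpha B", "Beta A", "Gamma A", "Delta A", "Rogue X")
  for (s in 1:60) {
    set.seed(1000 + s)
    n_img <- sample(1:3, 1)
    truths <- list()
    results <- list()
    for (i in seq_len(n_img)) {
      id <- paste0("img", i)
      nt <- sample(1:5, 1)
      truths[[id]] <- data.frame(sbre = sample(pool[1:5], nt),
                                 start = sample.int(150, nt),
                                 end = sample.int(150, nt),
                                 stringsAsFactors = FALSE)
      np <- sample(0:6, 1)
      preds <- data.frame(sbre = sample(pool, np, replace = TRUE),
                          start = sample.int(200, np, replace = TRUE) - 60L,
                          end = sample.int(200, np, replace = TRUE) - 60L,
                          stringsAsFactors = FALSE)
      results[[i]] <- make_result(id, preds)
    }
    got <- score_sbre_corpus(results, truths)
    err <- boundary_errors(results, truths)
    want <- oracle_scores(results, truths)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_identical(sort(err$start_errors), sort(want$start_errors))
    expect_identical(sort(err$end_errors), sort(want$end_errors))
    expect_identical(err$n_excluded, as.integer(want$n_excluded))
  }
})

test_that("reports assemble, print and round-trip through JSON", {
  truths <- list(img = fixture_truth())
  results <- list(make_result("img", fixture_predictions()))
  rep <- build_report(results, truths, matcher_config(case_sensitive = FALSE))
  expect_s3_class(rep, "evaluation_report")
  expect_equal(rep$precision, 0.75)
  expect_equal(rep$mae_start, 65 / 3)
  expect_identical(rep$n_images, 1L)
  expect_identical(sum(rep$histogram$counts), 6L)
  expect_output(print(rep), "precision 0.750")

  path <- file.path(tempdir(), "report.json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$precision, rep$precision)
  expect_equal(back$mae_end, rep$mae_end)
  expect_identical(back$errors$start_errors, rep$errors$start_errors)
  expect_equal(back$histogram$counts, rep$histogram$counts)
})

test_that("simulated-annotator errors recover the analytic mixture", {
  # jitter uniform on {-3..3}: E|J| = 12/7; row shift 0.1 at width 60:
  # E|-60+J| = 60, so MAE -> 0.9*(12/7) + 0.1*60
  truths <- make_truth_corpus(2500, 4L)
  model <- error_model(jitter_halfwidth = 3, p_row_shift = 0.1)
  set.seed(31)
  results <- lapply(names(truths), function(id)
    make_result(id, simulate_annotations(truths[[id]], model)))
  err <- boundary_errors(results, truths)
  n <- length(err$start_errors)
  expect_gte(n, 10000)

  expected <- 0.9 * (12 / 7) + 0.1 * 60
  for (v in list(err$start_errors, err$end_errors)) {
    se <- stats::sd(abs(v)) / sqrt(n)
    expect_lt(abs(mean(abs(v)) - expected), 3 * se)
  }

  # histogram mass in the [-63, -57] band estimates p_row_shift
  h <- error_histogram(err, 1)
  band <- h$edges[-length(h$edges)] >= -63 & h$edges[-length(h$edges)] <= -57
  mass <- sum(h$counts[band]) / sum(h$counts)
  expect_lt(abs(mass - 0.1), 3 * sqrt(0.1 * 0.9 / (2 * n)))
})
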