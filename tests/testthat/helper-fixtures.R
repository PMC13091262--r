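# Shared fixtures: the published worked example (one image, three true
# regions, four predicted records including an improvised name) and small
# constructors used across test files.

fixture_truth <- function() {
  data.frame(sbre = c("Mutation Hotspot A", "Low Conservation A", "Low Conservation B"),
             start = c(39L, 63L, 116L),
             end = c(56L, 75L, 128L),
             stringsAsFactors = FALSE)
}

fixture_predictions <- function() {
  data.frame(sbre = c("Mutation hotspot A", "Low conservation A",
                      "Low conservation B", "Unlabeled region"),
             start = c(37L, 10L, 126L, 111L),
             end = c(59L, 28L, 137L, 119L),
             stringsAsFactors = FALSE)
}

make_result <- function(dataset_id, records, blank = FALSE, n_attempts = 1L) {
  msabench:::annotation_result(dataset_id, records,
                               raw_responses = character(0),
                               n_attempts = n_attempts, blank = blank)
}

# Truth corpora without MSAs, for evaluation-only tests: n_images images of
# n_regions regions each, names unique within an image.
make_truth_corpus <- function(n_images, n_regions = 4L) {
  truths <- lapply(seq_len(n_images), function(i) {
    len <- 16L
    start <- seq.int(10L, by = len + 10L, length.out = n_regions)
    data.frame(sbre = sprintf("Region %s", LETTERS[seq_len(n_regions)]),
               start = start, end = start + len - 1L,
               stringsAsFactors = FALSE)
  })
  names(truths) <- sprintf("img_%04d", seq_len(n_images))
  truths
}
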