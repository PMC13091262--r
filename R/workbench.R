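#' Corpus manifest
#'
#' Reproducibility record for a generated benchmark corpus: the master seed
#' and configuration echo from which every dataset's ground truth can be
#' regenerated bit-for-bit, plus per-dataset seeds and artifact paths.
#'
#' @param corpus_id Corpus identifier.
#' @param master_seed Master RNG seed.
#' @param config Generator configuration echo (\code{generator_config}).
#' @param style Render style echo (\code{render_style}), optional.
#' @param datasets Data frame with \code{dataset_id}, \code{seed} and
#'   optional path columns (\code{alignment_path}, \code{image_path},
#'   \code{ground_truth_path}).
#' @return An object of class \code{corpus_manifest}.
#' @export
corpus_manifest <- function(corpus_id, master_seed, config, datasets,
                            style = NULL) {
  stopifnot(is.data.frame(datasets), "dataset_id" %in% names(datasets))
  if (anyDuplicated(datasets$dataset_id))
    stop("duplicate dataset_id in manifest", call. = FALSE)
  structure(list(corpus_id = corpus_id,
                 master_seed = as.integer(master_seed),
                 config = unclass(config),
                 style = if (!is.null(style)) unclass(style),
                 datasets = datasets),
            class = "corpus_manifest")
}

#' Write a corpus manifest as JSON
#'
#' @param manifest A \code{corpus_manifest}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "corpus_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a corpus manifest from JSON
#'
#' Validates structure and dataset_id uniqueness.
#'
#' @param path Manifest JSON path.
#' @return A \code{corpus_manifest}.
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  for (f in c("corpus_id", "master_seed", "datasets"))
    if (is.null(x[[f]]))
      stop(sprintf("malformed manifest: missing field '%s'", f), call. = FALSE)
  corpus_manifest(x$corpus_id, x$master_seed, x$config, x$datasets,
                  style = x$style)
}

#' Run the full benchmark pipeline
#'
#' Executes generate -> render -> annotate -> evaluate and writes every
#' artifact under \code{output_dir}: aligned FASTA and Stockholm exports,
#' ground-truth TSV sidecars, rendered PNGs, the corpus manifest, a per-image
#' log, and the evaluation report. The \code{"simulated"} and
#' \code{"human-import"} backends are fully offline. One pipeline seed
#' drives three decoupled RNG streams (generation, region colors, simulated
#' annotation), so two runs with identical arguments produce identical
#' reports.
#'
#' @param output_dir Directory for all artifacts (created if needed).
#' @param backend \code{"simulated"} or \code{"human-import"}.
#' @param n_datasets Number of datasets. Default 100.
#' @param config A \code{generator_config}.
#' @param style A \code{render_style}.
#' @param model \code{error_model} for the simulated backend.
#' @param human_tsv Annotation TSV path for the human-import backend; images
#'   absent from the file score as blank results.
#' @param matcher A \code{matcher_config}.
#' @param seed Pipeline seed.
#' @param render Render PNG images (set \code{FALSE} to skip the raster step
#'   when only ground truth and scoring are needed). Default TRUE.
#' @param bin_width Histogram bin width. Default 1.
#' @return List with \code{report} (\code{evaluation_report}),
#'   \code{manifest} (\code{corpus_manifest}), \code{corpus}, \code{results}
#'   and \code{log} (per-image data frame).
#' @export
run_pipeline <- function(output_dir,
                         backend = c("simulated", "human-import"),
                         n_datasets = 100L,
                         config = generator_config(),
                         style = render_style(),
                         model = error_model(),
                         human_tsv = NULL,
                         matcher = matcher_config(),
                         seed = 1L,
                         render = TRUE,
                         bin_width = 1L) {
  backend <- match.arg(backend)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("alignments", "images", "truth"))
    dir.create(file.path(output_dir, sub), showWarnings = FALSE)

  set.seed(seed)
  aux <- sample.int(.Machine$integer.max, 3L)

  corpus <- generate_corpus(n_datasets, config, master_seed = aux[1])
  ids <- names(corpus$datasets)

  set.seed(aux[2])
  paths <- data.frame(dataset_id = ids,
                      seed = corpus$manifest$seed,
                      alignment_path = file.path("alignments", paste0(ids, ".fasta")),
                      image_path = if (render) file.path("images", paste0(ids, ".png"))
                                   else NA_character_,
                      ground_truth_path = file.path("truth", paste0(ids, ".tsv")),
                      stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    d <- corpus$datasets[[i]]
    d$regions <- assign_colors(d$regions, style$palette)
    corpus$datasets[[i]] <- d
    write_alignment_fasta(d$msa, file.path(output_dir, paths$alignment_path[i]))
    write_alignment_stockholm(d$msa,
      file.path(output_dir, "alignments", paste0(ids[i], ".sto")))
    write_ground_truth(d, file.path(output_dir, paths$ground_truth_path[i]))
    if (render)
      render_msa_image(d, style, file.path(output_dir, paths$image_path[i]))
  }

  results <- switch(backend,
    "simulated" = annotate_corpus_simulated(corpus, model, seed = aux[3]),
    "human-import" = {
      if (is.null(human_tsv)) stop("`human_tsv` is required for human-import",
                                   call. = FALSE)
      imported <- import_human_annotations(human_tsv)
      out <- lapply(ids, function(id) {
        if (!is.null(imported[[id]])) imported[[id]]
        else annotation_result(id, empty_records(), character(0), 1L, TRUE)
      })
      stats::setNames(out, ids)
    })

  truths <- corpus_truths(corpus)
  report <- build_report(results, truths, matcher, bin_width)

  log <- do.call(rbind, lapply(ids, function(id) {
    r <- results[[id]]
    err <- boundary_errors(list(r), truths[id], matcher)
    data.frame(dataset_id = id, n_attempts = r$n_attempts, blank = r$blank,
               n_records = nrow(r$records),
               n_matched = length(err$start_errors),
               n_excluded = err$n_excluded,
               n_truth = nrow(truths[[id]]),
               stringsAsFactors = FALSE)
  }))

  manifest <- corpus_manifest(basename(output_dir), aux[1], config, paths,
                              style = style)
  write_manifest(manifest, file.path(output_dir, "manifest.json"))
  utils::write.table(log, file.path(output_dir, "pipeline_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_report(report, file.path(output_dir, "report.json"))

  list(report = report, manifest = manifest, corpus = corpus,
       results = results, log = log)
}
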