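#' The 20 standard amino-acid one-letter codes
#'
#' Ordered alphabet used for parent-sequence synthesis and mutation draws.
#'
#' @return A single string of 20 distinct residue letters.
#' @export
aa_alphabet <- function() "ARNDCQEGHILKMFPSTWYV"

#' Configuration for the synthetic MSA generator
#'
#' Bundles every tunable of the generative process: a random parent sequence
#' of \code{parent_length} residues, \code{n_sequences - 1} child sequences
#' derived by per-site substitution (probability \code{p_mut}) and gap
#' introduction (probability \code{p_gap}), and 2--5 named, non-overlapping
#' annotation regions sampled onto the alignment columns.
#'
#' @param parent_length Residue count of the gap-free parent row. Default 180.
#' @param n_sequences Total rows including the parent. Default 10.
#' @param p_mut Per-site substitution probability for child rows; a
#'   substitution always changes the residue (uniform over the other 19).
#'   Default 0.1.
#' @param p_gap Per-site gap probability for child rows; gaps replace the
#'   residue in place so alignment width never changes. Default 0.05.
#' @param alphabet Ordered residue letters, one string. Default
#'   \code{aa_alphabet()}.
#' @param region_count_range Inclusive integer interval for the number of
#'   regions per dataset. Default \code{c(2, 5)}.
#' @param region_length_range Inclusive integer interval for region length in
#'   columns. Default \code{c(10, 30)}.
#' @param min_inter_region_gap Minimum number of unannotated columns between
#'   consecutive regions. Default 4.
#' @param name_pool Base region names; a suffix letter (A, B, C, ...) is
#'   appended per base name in ascending start order.
#'
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(parent_length = 180L,
                             n_sequences = 10L,
                             p_mut = 0.1,
                             p_gap = 0.05,
                             alphabet = aa_alphabet(),
                             region_count_range = c(2L, 5L),
                             region_length_range = c(10L, 30L),
                             min_inter_region_gap = 4L,
                             name_pool = c("Mutation Hotspot",
                                           "Low Conservation",
                                           "Binding Site",
                                           "Structural Motif")) {
  stopifnot(parent_length >= 0, n_sequences >= 1)
  if (p_mut < 0 || p_mut > 1) stop("`p_mut` must be in [0, 1]", call. = FALSE)
  if (p_gap < 0 || p_gap > 1) stop("`p_gap` must be in [0, 1]", call. = FALSE)
  letters_ <- strsplit(alphabet, "")[[1]]
  if (anyDuplicated(letters_)) stop("`alphabet` letters must be distinct", call. = FALSE)
  region_count_range <- as.integer(region_count_range)
  region_length_range <- as.integer(region_length_range)
  stopifnot(length(region_count_range) == 2, region_count_range[1] <= region_count_range[2],
            region_count_range[1] >= 0,
            length(region_length_range) == 2, region_length_range[1] <= region_length_range[2],
            region_length_range[1] >= 1,
            min_inter_region_gap >= 0, length(name_pool) >= 1)
  structure(list(parent_length = as.integer(parent_length),
                 n_sequences = as.integer(n_sequences),
                 p_mut = p_mut, p_gap = p_gap,
                 alphabet = alphabet,
                 region_count_range = region_count_range,
                 region_length_range = region_length_range,
                 min_inter_region_gap = as.integer(min_inter_region_gap),
                 name_pool = name_pool),
            class = "generator_config")
}

#' Generate a random parent sequence
#'
#' Draws \code{length} residues independently and uniformly with replacement
#' from \code{alphabet}, using the current RNG stream.
#'
#' @param length Residue count.
#' @param alphabet Ordered residue letters (single string).
#' @return A single string of \code{length} residues.
#' @export
generate_parent <- function(length, alphabet = aa_alphabet()) {
  if (length < 0) stop("`length` must be non-negative", call. = FALSE)
  if (nchar(alphabet) == 0) stop("`alphabet` must be non-empty", call. = FALSE)
  if (length == 0) return("")
  letters_ <- strsplit(alphabet, "")[[1]]
  paste(sample(letters_, length, replace = TRUE), collapse = "")
}

#' Derive one child row from a parent sequence
#'
#' Per position, independently: with probability \code{p_gap} the residue is
#' replaced by the gap symbol \code{"-"}; otherwise with probability
#' \code{p_mut} it is substituted by a uniform draw from the 19 residues that
#' differ from the parent residue; otherwise it is copied. Gaps replace
#' residues in place (no insertions), so the child has exactly the parent's
#' length and alignment columns coincide with parent residue indices.
#'
#' @param parent Parent sequence (single gap-free string).
#' @param p_mut Substitution probability per site.
#' @param p_gap Gap probability per site (takes precedence over mutation).
#' @param alphabet Residue letters used for substitution draws.
#' @return A single aligned string over \code{alphabet} plus \code{"-"}.
#' @export
derive_child <- function(parent, p_mut, p_gap, alphabet = aa_alphabet()) {
  if (nchar(parent) == 0) stop("`parent` must be non-empty", call. = FALSE)
  if (p_mut < 0 || p_mut > 1 || p_gap < 0 || p_gap > 1)
    stop("probabilities must be in [0, 1]", call. = FALSE)
  res <- strsplit(parent, "")[[1]]
  n <- length(res)
  letters_ <- strsplit(alphabet, "")[[1]]
  is_gap <- stats::runif(n) < p_gap
  is_mut <- !is_gap & stats::runif(n) < p_mut
  out <- res
  if (any(is_mut)) {
    # substitutions are forced to differ from the parent residue
    for (i in which(is_mut)) out[i] <- sample(setdiff(letters_, res[i]), 1L)
  }
  out[is_gap] <- "-"
  paste(out, collapse = "")
}

#' Build a synthetic MSA
#'
#' Generates the parent row and \code{n_sequences - 1} children under
#' \code{config}. Row 0 (named \code{"parent"}) is gap-free; children are
#' named \code{"child_1"} ... in order.
#'
#' @param config A \code{generator_config}.
#' @return An object of class \code{synthetic_msa}: a named character vector
#'   of aligned rows with attribute \code{n_columns}.
#' @export
build_msa <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  parent <- generate_parent(config$parent_length, config$alphabet)
  rows <- character(config$n_sequences)
  rows[1] <- parent
  if (config$n_sequences > 1) {
    for (k in 2:config$n_sequences)
      rows[k] <- derive_child(parent, config$p_mut, config$p_gap, config$alphabet)
  }
  names(rows) <- c("parent",
                   if (config$n_sequences > 1) paste0("child_", seq_len(config$n_sequences - 1L)))
  structure(rows, n_columns = config$parent_length, class = "synthetic_msa")
}

#' @export
print.synthetic_msa <- function(x, ...) {
  cat(sprintf("synthetic_msa: %d sequences x %d columns\n",
              length(x), attr(x, "n_columns")))
  invisible(x)
}

#' Sample non-overlapping region coordinates
#'
#' Draws a region count uniformly over \code{region_count_range} and a length
#' per region uniformly over \code{region_length_range}, then places start
#' columns by rejection sampling: starts are drawn independently and uniformly
#' in their admissible ranges and the draw is accepted when, after sorting,
#' every pair of consecutive regions is separated by at least
#' \code{min_inter_region_gap} unannotated columns. On 1000 rejected draws the
#' lengths are resampled; after 10 such rounds generation fails. Geometrically
#' infeasible requests (minimum total footprint exceeding \code{n_columns})
#' fail immediately with the violated constraint.
#'
#' @param n_columns Alignment width.
#' @param config A \code{generator_config}.
#' @return A data frame with integer columns \code{start}, \code{end}
#'   (1-based inclusive alignment columns), sorted by \code{start}.
#' @export
sample_regions <- function(n_columns, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cr <- config$region_count_range
  lr <- config$region_length_range
  gap <- config$min_inter_region_gap
  # sample() treats a scalar first argument as 1:n, so guard degenerate ranges
  sample_range <- function(lo, hi, n) {
    if (lo == hi) rep(lo, n) else sample(lo:hi, n, replace = TRUE)
  }
  k <- sample_range(cr[1], cr[2], 1L)
  min_total <- k * lr[1] + gap * max(k - 1L, 0L)
  if (min_total > n_columns)
    stop(sprintf(paste0("cannot place %d regions of minimum length %d with ",
                        "inter-region gap %d in %d columns (needs %d)"),
                 k, lr[1], gap, n_columns, min_total), call. = FALSE)
  for (round in seq_len(10L)) {
    len <- sample_range(lr[1], lr[2], k)
    if (sum(len) + gap * (k - 1L) > n_columns) next
    for (attempt in seq_len(1000L)) {
      start <- vapply(len, function(l) sample.int(n_columns - l + 1L, 1L), integer(1))
      ord <- order(start)
      s <- start[ord]; e <- s + len[ord] - 1L
      if (k < 2L || all(s[-1] - e[-k] - 1L >= gap))
        return(data.frame(start = s, end = e))
    }
  }
  stop(sprintf("region placement failed after bounded resampling (gap >= %d in %d columns)",
               gap, n_columns), call. = FALSE)
}

#' Assign names to sampled regions
#'
#' Each region draws a base name uniformly from \code{name_pool}; a suffix
#' letter is appended per base name in ascending start order (A, B, C, ...).
#' A base name used once still receives suffix "A", so full names are always
#' pairwise distinct within a dataset.
#'
#' @param regions Data frame with \code{start}, \code{end}, sorted by start.
#' @param name_pool Character vector of base names.
#' @return The data frame with an \code{sbre} column prepended.
#' @export
assign_region_names <- function(regions, name_pool) {
  stopifnot(is.data.frame(regions), length(name_pool) >= 1)
  n <- nrow(regions)
  if (n == 0)
    return(cbind(data.frame(sbre = character(0)), regions))
  if (is.unsorted(regions$start)) stop("`regions` must be sorted by start", call. = FALSE)
  base <- sample(name_pool, n, replace = TRUE)
  suffix <- character(n)
  for (b in unique(base)) {
    idx <- which(base == b)
    if (length(idx) > 26L)
      stop(sprintf("more than 26 regions share base name '%s'", b), call. = FALSE)
    suffix[idx] <- LETTERS[seq_along(idx)]
  }
  out <- cbind(data.frame(sbre = paste(base, suffix), stringsAsFactors = FALSE), regions)
  rownames(out) <- NULL
  out
}

#' Generate one complete benchmark dataset
#'
#' Seeds the RNG, builds the MSA, samples and names its ground-truth regions.
#'
#' @param config A \code{generator_config}.
#' @param seed Integer RNG seed for this dataset.
#' @param dataset_id Identifier string; default derived from the seed.
#' @return An object of class \code{msa_dataset}: a list with
#'   \code{dataset_id}, \code{msa}, \code{regions} (data frame \code{sbre},
#'   \code{start}, \code{end}, \code{color}) and \code{seed}.
#' @export
generate_dataset <- function(config = generator_config(), seed = 1L,
                             dataset_id = sprintf("msa_%06d", seed)) {
  set.seed(seed)
  msa <- build_msa(config)
  regions <- sample_regions(attr(msa, "n_columns"), config)
  regions <- assign_region_names(regions, config$name_pool)
  regions$color <- NA_character_
  structure(list(dataset_id = dataset_id, msa = msa,
                 regions = regions, seed = as.integer(seed)),
            class = "msa_dataset")
}

#' @export
print.msa_dataset <- function(x, ...) {
  cat(sprintf("msa_dataset '%s': %d sequences x %d columns, %d regions (seed %d)\n",
              x$dataset_id, length(x$msa), attr(x$msa, "n_columns"),
              nrow(x$regions), x$seed))
  invisible(x)
}

#' Generate a reproducible benchmark corpus
#'
#' Derives one RNG seed per dataset from \code{master_seed} (via a seeded
#' integer draw, so datasets are decoupled but the whole corpus is a pure
#' function of the master seed) and generates each dataset with
#' \code{\link{generate_dataset}}.
#'
#' @param n_datasets Number of datasets.
#' @param config A \code{generator_config}.
#' @param master_seed Integer master seed.
#' @return An object of class \code{msa_corpus}: list with \code{datasets}
#'   (named by dataset_id) and \code{manifest} (data frame of dataset_id and
#'   per-dataset seed).
#' @export
generate_corpus <- function(n_datasets, config = generator_config(), master_seed = 1L) {
  stopifnot(n_datasets >= 1)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, n_datasets)
  ids <- sprintf("msa_%04d", seq_len(n_datasets))
  datasets <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    datasets[[i]] <- tryCatch(
      generate_dataset(config, seeds[i], ids[i]),
      error = function(e) stop(sprintf("dataset %d (%s): %s", i, ids[i],
                                       conditionMessage(e)), call. = FALSE))
  }
  names(datasets) <- ids
  structure(list(datasets = datasets,
                 manifest = data.frame(dataset_id = ids, seed = seeds,
                                       stringsAsFactors = FALSE),
                 master_seed = as.integer(master_seed)),
            class = "msa_corpus")
}

#' Extract the ground-truth region tables of a corpus
#'
#' @param corpus An \code{msa_corpus}.
#' @return Named list (by dataset_id) of region data frames.
#' @export
corpus_truths <- function(corpus) {
  stopifnot(inherits(corpus, "msa_corpus"))
  lapply(corpus$datasets, function(d) d$regions)
}
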