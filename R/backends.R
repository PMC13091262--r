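#' Benchmark prompt text
#'
#' Returns the prompt submitted to a vision-language model together with an
#' MSA image. Two fixed variants exist: \code{"naive"} asks only for the
#' structured list; \code{"strict"} additionally instructs the model to
#' interpolate residue indices between the sparse number ticks, ideally at
#' one-residue resolution. Both demand the answer as a Python list-of-lists
#' assigned to the sentinel key \code{parsed_result}.
#'
#' @param mode \code{"naive"} or \code{"strict"}.
#' @return A single prompt string.
#' @export
build_prompt <- function(mode = c("naive", "strict")) {
  if (length(mode) != 1 || !mode %in% c("naive", "strict"))
    stop("`mode` must be \"naive\" or \"strict\"", call. = FALSE)
  naive <- paste0(
    "This is a figure from a biological paper. Identify any structural region ",
    "defined here. Report the python list of lists as ",
    "parsed_result = [[region_name, region_init, region_end],...]")
  strict <- paste0(
    "This is a figure from a biological paper. Identify any structural region ",
    "defined here. You must extract the residue indexes as precisely as ",
    "possible from the figure, ideally at one-residue resolution. Residue ",
    "indexes are shown at sparse, roughly regular intervals for clarity, so ",
    "you'll need to estimate the actual start and end positions of structural ",
    "regions by interpolating between the visible labels. Report the python ",
    "list of lists as parsed_result = [[region_name, region_init, region_end],...]")
  if (mode == "naive") naive else strict
}

#' Retry policy for annotator queries
#'
#' @param max_attempts Total queries per image before a blank result is
#'   returned. Default 3.
#' @param inter_image_pause Seconds to wait between images (API pacing).
#'   Default 5.
#' @param pre_retry_pause Seconds to wait before each retry. Default 3.
#'   Both pauses can be set to 0, e.g. for offline backends and tests.
#' @return An object of class \code{retry_policy}.
#' @export
retry_policy <- function(max_attempts = 3L, inter_image_pause = 5,
                         pre_retry_pause = 3) {
  stopifnot(max_attempts >= 1, inter_image_pause >= 0, pre_retry_pause >= 0)
  structure(list(max_attempts = as.integer(max_attempts),
                 inter_image_pause = inter_image_pause,
                 pre_retry_pause = pre_retry_pause),
            class = "retry_policy")
}

#' Strip formatting characters from a raw model response
#'
#' Removes Markdown code-fence markers (with or without a language tag),
#' surrounding backticks, and leading/trailing whitespace; inner content is
#' preserved.
#'
#' @param raw Raw response text (single string).
#' @return Cleaned text.
#' @export
strip_formatting <- function(raw) {
  if (length(raw) != 1 || is.na(raw)) return("")
  x <- gsub("```[A-Za-z0-9_+-]*", "", raw)
  x <- trimws(x)
  x <- gsub("^`+|`+$", "", x)
  trimws(x)
}

parse_failure <- function(reason) {
  structure(list(ok = FALSE, reason = reason), class = "parse_outcome")
}
parse_success <- function(value) {
  structure(list(ok = TRUE, value = value), class = "parse_outcome")
}

#' Extract the sentinel payload from a cleaned response
#'
#' Locates the LAST occurrence of the sentinel key followed by \code{=}
#' (whitespace around \code{=} tolerated; responses often restate the output
#' format before the final answer) and returns the balanced bracketed literal
#' that follows. Nesting and quoted strings (with escapes) are respected while
#' balancing.
#'
#' @param cleaned Cleaned response text.
#' @param sentinel Output key string. Default \code{"parsed_result"}.
#' @return A \code{parse_outcome}: on success \code{$value} holds the literal
#'   text; on failure \code{$reason} is \code{"missing_key"} (sentinel absent)
#'   or \code{"syntax"} (no balanced literal after it).
#' @export
extract_payload <- function(cleaned, sentinel = "parsed_result") {
  if (length(cleaned) != 1 || is.na(cleaned)) return(parse_failure("missing_key"))
  pat <- paste0(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", sentinel), "[ \t]*=")
  hits <- gregexpr(pat, cleaned)[[1]]
  if (hits[1] == -1) return(parse_failure("missing_key"))
  last <- hits[length(hits)] + attr(hits, "match.length")[length(hits)]
  rest <- substr(cleaned, last, nchar(cleaned))
  ch <- strsplit(rest, "")[[1]]
  open <- which(ch == "[")
  if (!length(open)) return(parse_failure("syntax"))
  i <- open[1]
  # anything other than whitespace between "=" and "[" is not a literal
  if (i > 1 && grepl("[^ \t\r\n]", paste(ch[seq_len(i - 1)], collapse = "")))
    return(parse_failure("syntax"))
  depth <- 0L; in_str <- FALSE; quote_ch <- ""; escaped <- FALSE
  for (j in i:length(ch)) {
    c_ <- ch[j]
    if (in_str) {
      if (escaped) escaped <- FALSE
      else if (c_ == "\\") escaped <- TRUE
      else if (c_ == quote_ch) in_str <- FALSE
    } else if (c_ == "'" || c_ == '"') {
      in_str <- TRUE; quote_ch <- c_
    } else if (c_ == "[") depth <- depth + 1L
    else if (c_ == "]") {
      depth <- depth - 1L
      if (depth == 0L)
        return(parse_success(paste(ch[i:j], collapse = "")))
    }
  }
  parse_failure("syntax")
}

# Recursive-descent reader for a Python-style nested list literal.
# Interprets ONLY literals (never evaluates anything): nested lists, quoted
# strings with backslash escapes, and bare numeric tokens.
read_py_literal <- function(text) {
  ch <- strsplit(text, "")[[1]]
  n <- length(ch)
  pos <- 1L
  skip_ws <- function() while (pos <= n && ch[pos] %in% c(" ", "\t", "\r", "\n")) pos <<- pos + 1L
  parse_string <- function() {
    q <- ch[pos]; pos <<- pos + 1L
    out <- character(0)
    while (pos <= n) {
      c_ <- ch[pos]
      if (c_ == "\\") {
        if (pos + 1L > n) stop("syntax", call. = FALSE)
        nxt <- ch[pos + 1L]
        out <- c(out, switch(nxt, n = "\n", t = "\t", nxt))
        pos <<- pos + 2L
      } else if (c_ == q) {
        pos <<- pos + 1L
        return(paste(out, collapse = ""))
      } else {
        out <- c(out, c_); pos <<- pos + 1L
      }
    }
    stop("syntax", call. = FALSE)
  }
  parse_bare <- function() {
    start <- pos
    while (pos <= n && !ch[pos] %in% c(",", "]", "[", " ", "\t", "\r", "\n"))
      pos <<- pos + 1L
    if (pos == start) stop("syntax", call. = FALSE)
    tok <- paste(ch[start:(pos - 1L)], collapse = "")
    if (!grepl("^[+-]?[0-9]+(\\.[0-9]+)?$", tok)) stop("syntax", call. = FALSE)
    as.numeric(tok)
  }
  parse_value <- function() {
    skip_ws()
    if (pos > n) stop("syntax", call. = FALSE)
    c_ <- ch[pos]
    if (c_ == "[") parse_list()
    else if (c_ == "'" || c_ == '"') parse_string()
    else parse_bare()
  }
  parse_list <- function() {
    pos <<- pos + 1L   # consume "["
    items <- list()
    skip_ws()
    if (pos <= n && ch[pos] == "]") { pos <<- pos + 1L; return(items) }
    repeat {
      items[[length(items) + 1L]] <- parse_value()
      skip_ws()
      if (pos > n) stop("syntax", call. = FALSE)
      if (ch[pos] == ",") { pos <<- pos + 1L; skip_ws()
        if (pos <= n && ch[pos] == "]") { pos <<- pos + 1L; return(items) } }
      else if (ch[pos] == "]") { pos <<- pos + 1L; return(items) }
      else stop("syntax", call. = FALSE)
    }
  }
  val <- parse_value()
  skip_ws()
  if (pos <= n) stop("syntax", call. = FALSE)
  val
}

#' Parse a bracketed literal into extraction records
#'
#' Interprets the text strictly as a literal list of \code{[name, start,
#' end]} triples; nothing is ever evaluated or executed. Names must be
#' quoted strings; boundaries must be integers or numeric strings (models
#' sometimes quote numbers, so \code{"39"} coerces to 39). Any malformed
#' element fails the whole parse.
#'
#' @param literal Literal text, e.g.
#'   \code{"[['Mutation Hotspot A', 39, 56]]"}.
#' @return A \code{parse_outcome}: on success \code{$value} is a data frame
#'   with columns \code{sbre}, \code{start}, \code{end}; on failure
#'   \code{$reason} is \code{"syntax"} or \code{"schema"}.
#' @export
parse_literal <- function(literal) {
  if (length(literal) != 1 || is.na(literal)) return(parse_failure("syntax"))
  val <- tryCatch(read_py_literal(literal), error = function(e) NULL)
  if (is.null(val)) return(parse_failure("syntax"))
  if (!is.list(val)) return(parse_failure("schema"))
  coerce_int <- function(x) {
    if (is.character(x) && grepl("^[+-]?[0-9]+$", x)) x <- as.numeric(x)
    if (!is.numeric(x) || x != round(x)) return(NA_integer_)
    as.integer(x)
  }
  records <- data.frame(sbre = character(0), start = integer(0), end = integer(0),
                        stringsAsFactors = FALSE)
  for (el in val) {
    if (!is.list(el) || length(el) != 3) return(parse_failure("schema"))
    if (!is.character(el[[1]])) return(parse_failure("schema"))
    s <- coerce_int(el[[2]]); e <- coerce_int(el[[3]])
    if (is.na(s) || is.na(e)) return(parse_failure("schema"))
    records <- rbind(records, data.frame(sbre = el[[1]], start = s, end = e,
                                         stringsAsFactors = FALSE))
  }
  parse_success(records)
}

#' Parse a raw annotator response end to end
#'
#' Strips formatting, extracts the sentinel payload, and reads the literal.
#'
#' @param raw Raw response text.
#' @param sentinel Output key. Default \code{"parsed_result"}.
#' @return A \code{parse_outcome} whose \code{$value} on success is the
#'   record data frame.
#' @export
parse_response <- function(raw, sentinel = "parsed_result") {
  payload <- extract_payload(strip_formatting(raw), sentinel)
  if (!payload$ok) return(payload)
  parse_literal(payload$value)
}

annotation_result <- function(dataset_id, records, raw_responses, n_attempts, blank) {
  structure(list(dataset_id = dataset_id, records = records,
                 raw_responses = raw_responses,
                 n_attempts = as.integer(n_attempts), blank = isTRUE(blank)),
            class = "annotation_result")
}

empty_records <- function() {
  data.frame(sbre = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

#' Query an annotator backend with retries and a blank fallback
#'
#' Calls \code{backend(image, prompt)} up to \code{policy$max_attempts}
#' times. The first response that parses wins; a transport error counts as a
#' failed attempt. If every attempt fails, a blank result is returned with
#' all raw responses retained for audit. \code{pre_retry_pause} seconds are
#' waited before each retry.
#'
#' @param backend A function \code{(image, prompt) -> raw text}.
#' @param image Opaque image handle passed through to the backend
#'   (typically a file path).
#' @param prompt Prompt text, see \code{\link{build_prompt}}.
#' @param policy A \code{retry_policy}.
#' @param parser Response parser; default \code{\link{parse_response}}.
#' @param dataset_id Identifier recorded in the result.
#' @return An \code{annotation_result}.
#' @export
run_backend_with_retries <- function(backend, image, prompt,
                                     policy = retry_policy(),
                                     parser = parse_response,
                                     dataset_id = NA_character_) {
  stopifnot(is.function(backend), inherits(policy, "retry_policy"))
  raws <- character(0)
  for (attempt in seq_len(policy$max_attempts)) {
    if (attempt > 1 && policy$pre_retry_pause > 0)
      Sys.sleep(policy$pre_retry_pause)
    raw <- tryCatch(backend(image, prompt),
                    error = function(e) paste0("<transport error: ",
                                               conditionMessage(e), ">"))
    raws <- c(raws, raw)
    parsed <- parser(raw)
    if (parsed$ok)
      return(annotation_result(dataset_id, parsed$value, raws, attempt, FALSE))
  }
  annotation_result(dataset_id, empty_records(), raws, policy$max_attempts, TRUE)
}

#' Parametric annotator error model
#'
#' Describes the failure modes observed in automated and human annotation of
#' rendered MSA images: missed regions, fabricated regions with improvised
#' names, row-offset boundary shifts of \code{-row_width} (a bar read one
#' wrapped row above its true row), uniform boundary jitter, duplicated
#' records, and single-character name typos.
#'
#' @param p_miss Probability of dropping a true region.
#' @param p_spurious Probability of appending one fabricated region with an
#'   improvised name per dataset.
#' @param p_row_shift Probability that both boundaries of an emitted record
#'   are offset by \code{-row_width}.
#' @param jitter_halfwidth Max absolute boundary jitter; each endpoint gets an
#'   independent uniform integer draw on
#'   \code{[-jitter_halfwidth, +jitter_halfwidth]}.
#' @param p_duplicate Probability of re-emitting a record.
#' @param p_name_typo Probability of corrupting a name by one character.
#' @param row_width Rendered columns per row panel. Default 60.
#' @param spurious_names Improvised-name pool for fabricated regions, disjoint
#'   from the generator's name pool.
#' @return An object of class \code{error_model}.
#' @export
error_model <- function(p_miss = 0, p_spurious = 0, p_row_shift = 0,
                        jitter_halfwidth = 0L, p_duplicate = 0,
                        p_name_typo = 0, row_width = 60L,
                        spurious_names = c("Unlabeled Region", "Unknown")) {
  probs <- c(p_miss, p_spurious, p_row_shift, p_duplicate, p_name_typo)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must be in [0, 1]", call. = FALSE)
  stopifnot(jitter_halfwidth >= 0, row_width >= 1)
  structure(list(p_miss = p_miss, p_spurious = p_spurious,
                 p_row_shift = p_row_shift,
                 jitter_halfwidth = as.integer(jitter_halfwidth),
                 p_duplicate = p_duplicate, p_name_typo = p_name_typo,
                 row_width = as.integer(row_width),
                 spurious_names = spurious_names),
            class = "error_model")
}

corrupt_name <- function(name) {
  chars <- strsplit(name, "")[[1]]
  i <- sample.int(length(chars), 1L)
  repl <- sample(c(letters, LETTERS), 1L)
  while (repl == chars[i]) repl <- sample(c(letters, LETTERS), 1L)
  chars[i] <- repl
  paste(chars, collapse = "")
}

#' Simulate annotator output for one dataset
#'
#' Applies the \code{\link{error_model}} to the ground-truth regions: each
#' true region is independently dropped with \code{p_miss} or emitted with
#' per-endpoint uniform jitter, an optional \code{-row_width} shift of both
#' endpoints, an optional name typo, and an optional duplicate copy; finally,
#' with \code{p_spurious} one fabricated record with an improvised name is
#' appended. An all-zero model reproduces the truth exactly.
#'
#' @param truth Ground-truth region data frame (\code{sbre}, \code{start},
#'   \code{end}).
#' @param model An \code{error_model}.
#' @param n_columns Alignment width used to place fabricated regions.
#' @return A record data frame (\code{sbre}, \code{start}, \code{end}).
#' @export
simulate_annotations <- function(truth, model = error_model(), n_columns = 180L) {
  stopifnot(inherits(model, "error_model"), is.data.frame(truth))
  sbre <- character(0); start <- integer(0); end <- integer(0)
  for (r in seq_len(nrow(truth))) {
    if (stats::runif(1) < model$p_miss) next
    j <- model$jitter_halfwidth
    ds <- if (j > 0) sample(seq.int(-j, j), 1L) else 0L
    de <- if (j > 0) sample(seq.int(-j, j), 1L) else 0L
    s <- truth$start[r] + ds
    e <- truth$end[r] + de
    if (stats::runif(1) < model$p_row_shift) {
      s <- s - model$row_width
      e <- e - model$row_width
    }
    name <- truth$sbre[r]
    if (stats::runif(1) < model$p_name_typo) name <- corrupt_name(name)
    rep_n <- if (stats::runif(1) < model$p_duplicate) 2L else 1L
    sbre <- c(sbre, rep(name, rep_n))
    start <- c(start, rep(as.integer(s), rep_n))
    end <- c(end, rep(as.integer(e), rep_n))
  }
  if (stats::runif(1) < model$p_spurious) {
    len <- sample(5:15, 1L)
    s0 <- sample.int(max(n_columns - len, 1L), 1L)
    sbre <- c(sbre, sample(model$spurious_names, 1L))
    start <- c(start, s0)
    end <- c(end, s0 + len - 1L)
  }
  data.frame(sbre = sbre, start = start, end = end, stringsAsFactors = FALSE)
}

#' Annotate a whole corpus with the simulated annotator
#'
#' @param corpus An \code{msa_corpus}.
#' @param model An \code{error_model}.
#' @param seed RNG seed for the simulated errors.
#' @return Named list of \code{annotation_result}, one per dataset.
#' @export
annotate_corpus_simulated <- function(corpus, model = error_model(), seed = 1L) {
  stopifnot(inherits(corpus, "msa_corpus"))
  set.seed(seed)
  results <- lapply(corpus$datasets, function(d) {
    recs <- simulate_annotations(d$regions, model, attr(d$msa, "n_columns"))
    annotation_result(d$dataset_id, recs,
                      raw_responses = "<simulated>", n_attempts = 1L,
                      blank = FALSE)
  })
  names(results) <- names(corpus$datasets)
  results
}

#' Import human annotations from a TSV file
#'
#' Expects a tab-separated file with header columns \code{image_id},
#' \code{sbre}, \code{start}, \code{end}. Names are whitespace-trimmed and
#' boundaries parsed as integers; a non-integer boundary is reported with its
#' line number. Returns one \code{annotation_result} per distinct
#' \code{image_id} (\code{n_attempts = 1}, \code{blank = FALSE}).
#'
#' @param tsv_path Path to the annotation TSV.
#' @return Named list (by image_id) of \code{annotation_result}.
#' @export
import_human_annotations <- function(tsv_path) {
  df <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("image_id", "sbre", "start", "end")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("annotation file missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0) return(stats::setNames(list(), character(0)))
  bad <- which(!grepl("^[+-]?[0-9]+$", trimws(df$start)) |
               !grepl("^[+-]?[0-9]+$", trimws(df$end)))
  if (length(bad))
    stop(sprintf("non-integer boundary at line %d of %s",
                 bad[1] + 1L, tsv_path), call. = FALSE)
  df$sbre <- trimws(df$sbre)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  ids <- unique(df$image_id)
  results <- lapply(ids, function(id) {
    sub <- df[df$image_id == id, c("sbre", "start", "end"), drop = FALSE]
    rownames(sub) <- NULL
    annotation_result(id, sub, raw_responses = character(0),
                      n_attempts = 1L, blank = FALSE)
  })
  stats::setNames(results, ids)
}
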