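#' Rendering style for annotated MSA images
#'
#' @param wrap_length Alignment columns per rendered row panel. Default 60.
#' @param tick_interval Spacing of the residue-number ticks. Default 10.
#' @param palette Candidate bar/label colors; one is drawn uniformly per
#'   region. Default red, green, blue, orange, purple.
#' @param canvas_width,canvas_height Output raster size in pixels.
#'   Default 1006 x 867.
#' @return An object of class \code{render_style}.
#' @export
render_style <- function(wrap_length = 60L,
                         tick_interval = 10L,
                         palette = c("red", "green", "blue", "orange", "purple"),
                         canvas_width = 1006L,
                         canvas_height = 867L) {
  stopifnot(wrap_length >= 1, tick_interval >= 1, length(palette) >= 1,
            canvas_width >= 1, canvas_height >= 1)
  structure(list(wrap_length = as.integer(wrap_length),
                 tick_interval = as.integer(tick_interval),
                 palette = palette,
                 canvas_width = as.integer(canvas_width),
                 canvas_height = as.integer(canvas_height)),
            class = "render_style")
}

#' Draw a random color per region
#'
#' Each region's color is an independent uniform draw from the palette;
#' collisions between regions are permitted.
#'
#' @param regions Region data frame (\code{sbre}, \code{start}, \code{end}).
#' @param palette Character vector of color names.
#' @return The data frame with its \code{color} column filled.
#' @export
assign_colors <- function(regions, palette = render_style()$palette) {
  stopifnot(is.data.frame(regions), length(palette) >= 1)
  regions$color <- if (nrow(regions)) sample(palette, nrow(regions), replace = TRUE)
                   else character(0)
  regions
}

# Muted per-residue letter colors (Clustal-like grouping); gaps grey.
residue_letter_colors <- function() {
  c(A = "#80a0f0", I = "#80a0f0", L = "#80a0f0", M = "#80a0f0", F = "#80a0f0",
    W = "#80a0f0", V = "#80a0f0", C = "#f08080", K = "#f01505", R = "#f01505",
    E = "#c048c0", D = "#c048c0", N = "#15c015", Q = "#15c015", S = "#15c015",
    T = "#15c015", G = "#f09048", P = "#c0c000", H = "#15a4a4", Y = "#15a4a4",
    "-" = "#aaaaaa")
}

#' Render a dataset as an annotated MSA raster image
#'
#' Draws the alignment wrapped into \code{wrap_length}-column row panels with
#' residue numbers at \code{tick_interval} spacing, and each ground-truth
#' region as a colored bar spanning its columns with its name above in the
#' same color. A region crossing a wrap boundary is split across panels; its
#' name is printed over the first segment only. Output is written as a PNG of
#' exactly \code{canvas_width} x \code{canvas_height} pixels.
#'
#' Regions with no color assigned yet receive one via
#' \code{\link{assign_colors}} using the current RNG stream.
#'
#' @param dataset An \code{msa_dataset}.
#' @param style A \code{render_style}.
#' @param out_path Output PNG path.
#' @return Invisibly, a render record: list with \code{dataset_id},
#'   \code{path}, \code{width}, \code{height}, the style echo, and the
#'   region table with the colors actually drawn.
#' @export
render_msa_image <- function(dataset, style = render_style(),
                             out_path = file.path(tempdir(), paste0(dataset$dataset_id, ".png"))) {
  stopifnot(inherits(dataset, "msa_dataset"), inherits(style, "render_style"))
  msa <- dataset$msa
  n_col <- attr(msa, "n_columns")
  regions <- dataset$regions
  if (nrow(regions) && (is.null(regions$color) || anyNA(regions$color)))
    regions <- assign_colors(regions, style$palette)
  if (nrow(regions) && (any(regions$start < 1) || any(regions$end > n_col)))
    stop("region outside alignment bounds", call. = FALSE)
  if (!dir.exists(dirname(out_path)))
    stop(sprintf("output directory does not exist: %s", dirname(out_path)), call. = FALSE)

  wrap <- style$wrap_length
  n_panels <- ceiling(n_col / wrap)
  n_seq <- length(msa)
  margin <- 8                       # cells reserved for sequence ids
  rows_per_panel <- n_seq + 4       # label + bar + ticks + sequences + spacer
  total_rows <- n_panels * rows_per_panel
  chars <- lapply(msa, function(s) strsplit(s, "")[[1]])
  letter_col <- residue_letter_colors()

  grDevices::png(out_path, width = style$canvas_width, height = style$canvas_height,
                 type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0.2, 0.2, 0.2, 0.2), bg = "white", xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, margin + wrap), ylim = c(total_rows, 0))
  cex_letter <- min(1, 14 / max(n_seq, 10))

  for (p in seq_len(n_panels)) {
    c0 <- (p - 1L) * wrap + 1L
    c1 <- min(p * wrap, n_col)
    y0 <- (p - 1L) * rows_per_panel
    xpos <- function(col) margin + (col - c0) + 0.5

    # residue-number ticks (global 1-based numbering)
    ticks <- seq.int(style$tick_interval, c1, by = style$tick_interval)
    ticks <- ticks[ticks >= c0]
    if (length(ticks))
      graphics::text(xpos(ticks), y0 + 2.5, labels = ticks,
                     cex = 0.65, family = "mono", col = "grey30")

    # sequence ids and letters
    for (j in seq_len(n_seq)) {
      y <- y0 + 2.5 + j
      graphics::text(0.2, y, labels = names(msa)[j], adj = 0,
                     cex = 0.62, family = "mono", col = "grey20")
      seg <- chars[[j]][c0:c1]
      graphics::text(xpos(c0:c1), y, labels = seg, cex = cex_letter,
                     family = "mono", col = letter_col[seg])
    }

    # region bars and names for regions intersecting this panel
    if (nrow(regions)) {
      for (r in seq_len(nrow(regions))) {
        rs <- regions$start[r]; re <- regions$end[r]
        if (re < c0 || rs > c1) next
        xl <- margin + (max(rs, c0) - c0)
        xr <- margin + (min(re, c1) - c0) + 1
        graphics::rect(xl, y0 + 1.25, xr, y0 + 1.85,
                       col = regions$color[r], border = NA)
        if (rs >= c0)   # name only over the first segment
          graphics::text(xl, y0 + 0.55, labels = regions$sbre[r], adj = 0,
                         cex = 0.75, col = regions$color[r])
      }
    }
  }

  invisible(list(dataset_id = dataset$dataset_id, path = out_path,
                 width = style$canvas_width, height = style$canvas_height,
                 style = style, regions = regions))
}

#' Write a ground-truth sidecar TSV
#'
#' One row per region, sorted by start, with header
#' \code{sbre<TAB>start<TAB>end} (1-based inclusive alignment columns).
#' Round-trips losslessly through \code{\link{read_ground_truth}}.
#'
#' @param dataset An \code{msa_dataset} (or a bare region data frame).
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_ground_truth <- function(dataset, path) {
  regions <- if (inherits(dataset, "msa_dataset")) dataset$regions else dataset
  stopifnot(is.data.frame(regions))
  regions <- regions[order(regions$start), c("sbre", "start", "end"), drop = FALSE]
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a ground-truth sidecar TSV
#'
#' @param path TSV with header \code{sbre}, \code{start}, \code{end}.
#' @return Region data frame with integer \code{start}, \code{end}.
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "integer"),
                          quote = "", comment.char = "")
  need <- c("sbre", "start", "end")
  if (!all(need %in% names(df)))
    stop(sprintf("ground-truth file missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")), call. = FALSE)
  df[need]
}

#' Export an alignment as aligned FASTA
#'
#' Gap symbol \code{"-"}; record ids are the MSA row names
#' (\code{parent}, \code{child_1}, ...).
#'
#' @param msa A \code{synthetic_msa}.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_alignment_fasta <- function(msa, path) {
  stopifnot(inherits(msa, "synthetic_msa"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(msa))
    writeLines(c(paste0(">", names(msa)[i]), msa[[i]]), con)
  invisible(path)
}

#' Export an alignment in Stockholm format
#'
#' Minimal single-block Stockholm 1.0 with one line per sequence.
#'
#' @param msa A \code{synthetic_msa}.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_alignment_stockholm <- function(msa, path) {
  stopifnot(inherits(msa, "synthetic_msa"))
  w <- max(nchar(names(msa))) + 2L
  lines <- c("# STOCKHOLM 1.0",
             sprintf(paste0("%-", w, "s%s"), names(msa), unname(msa)),
             "//")
  writeLines(lines, path)
  invisible(path)
}
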