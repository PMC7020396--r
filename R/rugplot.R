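# Rugplots: the running-sum trace of a pathway over gene ranks, with a
# vertical line at the ES peak and hatch marks at the ranks of pathway
# genes. Rendering consumes only the stored running sum and membership; no
# statistic is recomputed here.

#' Build the drawing specification of a pathway rugplot
#'
#' @param fit A `pathway_enrichment` object.
#' @param pathway_id Pathway to plot; defaults to the smallest-p pathway.
#' @return A list of class `rugplot_spec` with `x` (ranks 1..N), `y`
#'   (running-sum values), `peak_x`, `hatch_positions` (ranks of pathway
#'   genes) and `title`.
#' @export
rugplot_spec <- function(fit, pathway_id = NULL) {
  stopifnot(inherits(fit, "pathway_enrichment"))
  if (is.null(pathway_id)) pathway_id <- fit$results$pathway_id[1]
  rs <- fit$running_sums[[pathway_id]]
  if (is.null(rs)) stop(sprintf("pathway '%s' was not scored", pathway_id))
  name <- fit$results$pathway_name[match(pathway_id, fit$results$pathway_id)]
  structure(list(x = seq_along(rs$S), y = rs$S, peak_x = rs$peak_rank,
                 hatch_positions = rs$hit_ranks,
                 title = sprintf("%s (%s)", name, pathway_id)),
            class = "rugplot_spec")
}

#' @noRd
draw_rugplot <- function(spec) {
  graphics::plot(spec$x, spec$y, type = "l", lwd = 2, col = "steelblue4",
                 xlab = "Gene effect rank", ylab = "ES running sum",
                 main = spec$title)
  graphics::abline(h = 0, col = "grey70")
  graphics::abline(v = spec$peak_x, lty = 2, col = "firebrick")
  usr <- graphics::par("usr")
  tick <- 0.04 * (usr[4] - usr[3])
  graphics::segments(spec$hatch_positions, usr[4] - tick,
                     spec$hatch_positions, usr[4], col = "black")
}

#' Render one pathway rugplot to a file or the current device
#'
#' @param fit A `pathway_enrichment` object (or a `rugplot_spec`).
#' @param pathway_id Pathway to plot; defaults to the smallest-p pathway.
#' @param file Output path; when `NULL` the current graphics device is used.
#' @param format `"png"`, `"svg"` or `"pdf"` (used when `file` is given).
#' @param width,height Device size in inches.
#' @return Invisibly, the `rugplot_spec` drawn.
#' @export
plot_rugplot <- function(fit, pathway_id = NULL, file = NULL,
                         format = c("png", "svg", "pdf"),
                         width = 7, height = 5) {
  format <- match.arg(format)
  spec <- if (inherits(fit, "rugplot_spec")) fit else rugplot_spec(fit, pathway_id)
  if (!is.null(file)) {
    switch(format,
      png = grDevices::png(file, width = width, height = height,
                           units = "in", res = 150),
      svg = grDevices::svg(file, width = width, height = height),
      pdf = grDevices::pdf(file, width = width, height = height))
    on.exit(grDevices::dev.off())
  }
  draw_rugplot(spec)
  invisible(spec)
}

#' @rdname plot_rugplot
#' @param x A `pathway_enrichment` object.
#' @param ... Passed to [plot_rugplot()].
#' @export
plot.pathway_enrichment <- function(x, pathway_id = NULL, ...) {
  plot_rugplot(x, pathway_id = pathway_id, ...)
}

#' Long-format rugplot data for serialisation
#'
#' One row per (pathway, rank) with the running-sum value and hit flag, so
#' that the plotting stage can be re-run later without recomputing any
#' statistic.
#'
#' @param fit A `pathway_enrichment` object.
#' @param which Pathway ids to include; default all scored pathways.
#' @return Data frame with columns `pathway_id`, `pathway_name`, `rank`,
#'   `gene_id`, `running_sum`, `hit`, `peak_rank`.
#' @export
rugplot_table <- function(fit, which = NULL) {
  stopifnot(inherits(fit, "pathway_enrichment"))
  ids <- if (is.null(which)) names(fit$running_sums) else which
  if (length(ids) == 0) {
    return(data.frame(pathway_id = character(), pathway_name = character(),
                      rank = integer(), gene_id = character(),
                      running_sum = numeric(), hit = logical(),
                      peak_rank = integer(), stringsAsFactors = FALSE))
  }
  rows <- lapply(ids, function(id) {
    rs <- fit$running_sums[[id]]
    nm <- fit$results$pathway_name[match(id, fit$results$pathway_id)]
    data.frame(pathway_id = id, pathway_name = nm,
               rank = seq_along(rs$S), gene_id = fit$ranked$gene_id,
               running_sum = rs$S,
               hit = seq_along(rs$S) %in% rs$hit_ranks,
               peak_rank = rs$peak_rank, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render rugplots for a set of pathways
#'
#' Accepts either a `pathway_enrichment` fit or a serialised
#' [rugplot_table()] data frame (or the path of one written as TSV), so the
#' plotting stage can be re-run on its own. Files are named
#' `<pathway_id>.<format>` with filename-unsafe characters replaced by `_`.
#'
#' @param x A `pathway_enrichment` object, a [rugplot_table()] data frame,
#'   or the path to one saved as tab-delimited text.
#' @param outdir Output directory (created if needed).
#' @param which Pathway ids to render; default all present in `x`.
#' @param format Image format: `"png"`, `"svg"` or `"pdf"`.
#' @return Invisibly, a character vector of the files written.
#' @export
render_rugplots <- function(x, outdir, which = NULL,
                            format = c("png", "svg", "pdf")) {
  format <- match.arg(format)
  tab <- if (inherits(x, "pathway_enrichment")) {
    rugplot_table(x, which)
  } else if (is.character(x)) {
    utils::read.delim(x, stringsAsFactors = FALSE)
  } else {
    x
  }
  if (!is.null(which)) tab <- tab[tab$pathway_id %in% which, , drop = FALSE]
  if (nrow(tab) == 0) {
    message("no pathways to plot; no files written")
    return(invisible(character(0)))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (id in unique(tab$pathway_id)) {
    d <- tab[tab$pathway_id == id, , drop = FALSE]
    d <- d[order(d$rank), , drop = FALSE]
    spec <- structure(list(x = d$rank, y = d$running_sum,
                           peak_x = d$peak_rank[1],
                           hatch_positions = d$rank[d$hit],
                           title = sprintf("%s (%s)", d$pathway_name[1], id)),
                      class = "rugplot_spec")
    safe <- gsub("[^A-Za-z0-9._-]", "_", id)
    path <- file.path(outdir, paste0(safe, ".", format))
    plot_rugplot(spec, file = path, format = format)
    written <- c(written, path)
  }
  invisible(written)
}
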