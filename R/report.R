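#' Bundle QC summaries for reporting
#'
#' @param summaries List of `qc_summary` objects (at least one; unique
#'   sample ids).
#' @param config Optional list echoed into the report (run parameters).
#' @return Object of class `report_bundle`.
#' @export
report_bundle <- function(summaries, config = list()) {
  if (!length(summaries)) stop("need at least one QC summary", call. = FALSE)
  ids <- vapply(summaries, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s): ", paste(unique(ids[duplicated(ids)]),
                                           collapse = ", "), call. = FALSE)
  }
  structure(list(summaries = summaries, config = config,
                 version = as.character(utils::packageVersion("bsqc"))),
            class = "report_bundle")
}

# Per-sample scalar metric table with a stable column order; NA kept as NA.
bundle_metric_table <- function(bundle) {
  rows <- lapply(bundle$summaries, function(s) {
    as.data.frame(qc_scalar_fields(s), stringsAsFactors = FALSE)
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(cols, names(r))) r[[nm]] <- NA
    r[cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# The sentinel token used for undefined metrics in text output.
NA_TOKEN <- "NA"

#' Render the plain-text QC report
#'
#' A TSV table with one row per sample and all scalar metrics in stable
#' column order. Undefined metrics are rendered as the fixed token `NA`,
#' never as 0. Comment lines (`#`) carry the generation timestamp, toolkit
#' version and configuration echo; everything below them is a pure function
#' of the bundle, so reports from identical bundles are byte-identical
#' outside the comment region.
#'
#' @param bundle A [report_bundle()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
render_text_report <- function(bundle, path) {
  stopifnot(inherits(bundle, "report_bundle"))
  tab <- bundle_metric_table(bundle)
  cells <- vapply(tab, function(col) {
    out <- if (is.double(col)) fmt_num(col) else as.character(col)
    out[is.na(col)] <- NA_TOKEN
    out
  }, character(nrow(tab)))
  if (nrow(tab) == 1L) cells <- matrix(cells, nrow = 1L)
  cfg <- if (length(bundle$config)) {
    jsonlite::toJSON(bundle$config, auto_unbox = TRUE, digits = NA)
  } else "{}"
  lines <- c(
    "# bsqc quality control report",
    paste0("# generated: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("# version: ", bundle$version),
    paste0("# config: ", cfg),
    paste(names(tab), collapse = "\t"),
    apply(cells, 1L, paste, collapse = "\t")
  )
  write_text_lines(lines, path)
}

# Render a base-graphics plot to a base64 PNG data URI for embedding.
plot_data_uri <- function(expr, width = 720, height = 430) {
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp, width = width, height = height, res = 96)
  ok <- tryCatch({
    force(expr)
    TRUE
  }, error = function(e) FALSE, finally = grDevices::dev.off())
  if (!ok || !file.exists(tmp)) return(NULL)
  raw <- readBin(tmp, "raw", file.info(tmp)$size)
  unlink(tmp)
  paste0("data:image/png;base64,", jsonlite::base64_enc(raw))
}

sample_palette <- function(n) {
  grDevices::hcl.colors(max(n, 2L), palette = "Dark 2")[seq_len(n)]
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the self-contained HTML QC report
#'
#' A single HTML file with no external assets or network fetches: a
#' per-sample scalar metric table (cells failing the quality thresholds are
#' highlighted), and embedded figures for the M-bias profiles, saturation
#' curves, methylation value histograms and CpG density histograms, one
#' series per sample. Samples lacking the data for a panel get a placeholder
#' instead of a plot.
#'
#' @param bundle A [report_bundle()].
#' @param path Output path (`.html`).
#' @param flag_thresholds Named list of lower bounds used to highlight
#'   suspect samples; defaults flag conversion rate below 0.98 and mapping
#'   rate below 0.5.
#' @return `path`, invisibly.
#' @export
render_html_report <- function(bundle, path,
                               flag_thresholds = list(conversion_rate = 0.98,
                                                      mapping_rate = 0.5)) {
  stopifnot(inherits(bundle, "report_bundle"))
  tab <- bundle_metric_table(bundle)
  n <- nrow(tab)
  pal <- sample_palette(n)
  ids <- tab$sample_id

  flagged <- function(row) {
    bad <- character()
    cr <- tab$conversion_rate[row]
    if (!is.null(flag_thresholds$conversion_rate) && !is.na(cr) &&
        cr < flag_thresholds$conversion_rate) bad <- c(bad, "conversion_rate")
    mr <- tab$reads_mapped[row] /
      (tab$reads_mapped[row] + tab$reads_unmapped[row])
    if (!is.null(flag_thresholds$mapping_rate) && !is.na(mr) &&
        mr < flag_thresholds$mapping_rate) {
      bad <- c(bad, "reads_mapped")
    }
    bad
  }

  header_cells <- paste0("<th>", html_escape(names(tab)), "</th>",
                         collapse = "")
  body_rows <- vapply(seq_len(n), function(i) {
    bad <- flagged(i)
    cells <- vapply(names(tab), function(nm) {
      v <- tab[[nm]][i]
      txt <- if (is.na(v)) NA_TOKEN else if (is.double(v)) fmt_num(v) else
        as.character(v)
      cls <- if (nm %in% bad) " class=\"flag\"" else ""
      paste0("<td", cls, ">", html_escape(txt), "</td>")
    }, character(1))
    paste0("<tr>", paste(cells, collapse = ""), "</tr>")
  }, character(1))

  panel <- function(title, n_series, uri) {
    if (is.null(uri) || n_series == 0) {
      return(sprintf(
        "<div class=\"panel\" data-series=\"0\"><h2>%s</h2><p class=\"placeholder\">no data available for this metric</p></div>",
        html_escape(title)))
    }
    sprintf(
      "<div class=\"panel\" data-series=\"%d\"><h2>%s</h2><img alt=\"%s\" src=\"%s\"/></div>",
      n_series, html_escape(title), html_escape(title), uri)
  }

  # --- M-bias ---
  mb <- lapply(bundle$summaries, `[[`, "mbias")
  mb_n <- sum(!vapply(mb, is.null, logical(1)))
  mbias_uri <- if (mb_n > 0) plot_data_uri({
    graphics::plot(NULL, xlim = c(0, max(vapply(mb[!vapply(mb, is.null,
                                                           logical(1))],
      function(p) max(vapply(p, function(d) max(d$position), numeric(1))),
      numeric(1)))), ylim = c(0, 1),
      xlab = "position in read (0-based)", ylab = "CpG methylation fraction",
      main = "M-bias")
    for (i in seq_len(n)) {
      p <- mb[[i]]
      if (is.null(p)) next
      for (m in names(p)) {
        d <- p[[m]]
        graphics::lines(d$position, d$fraction, col = pal[i],
                        lty = match(m, c("R1", "R2", "unpaired")))
      }
    }
    graphics::legend("bottomright", legend = ids, col = pal, lty = 1,
                     cex = 0.7, bty = "n")
  }) else NULL

  # --- saturation ---
  sat <- lapply(bundle$summaries, `[[`, "saturation")
  sat_n <- sum(!vapply(sat, is.null, logical(1)))
  sat_uri <- if (sat_n > 0) plot_data_uri({
    ymax <- max(vapply(sat, function(s) max(c(s$covered_cpgs, 1)),
                       numeric(1)))
    graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, ymax * 1.05),
                   xlab = "fraction of reads retained",
                   ylab = "covered CpGs", main = "Downsampling saturation")
    for (i in seq_len(n)) {
      s <- sat[[i]]
      if (is.null(s)) next
      graphics::lines(s$fraction, s$covered_cpgs, col = pal[i], type = "b",
                      pch = 16, cex = 0.6)
    }
    graphics::legend("bottomright", legend = ids, col = pal, lty = 1,
                     cex = 0.7, bty = "n")
  }) else NULL

  # --- methylation histogram ---
  mh <- lapply(bundle$summaries, `[[`, "methylation_histogram")
  mh_n <- sum(vapply(mh, function(h) !is.null(h) && sum(h$count) > 0,
                     logical(1)))
  mh_uri <- if (mh_n > 0) plot_data_uri({
    dens <- lapply(mh, function(h) {
      if (is.null(h) || sum(h$count) == 0) return(NULL)
      h$count / sum(h$count)
    })
    ymax <- max(unlist(dens), 0.01)
    graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, ymax * 1.1),
                   xlab = "methylation (beta)", ylab = "fraction of CpGs",
                   main = "Methylation value distribution")
    for (i in seq_len(n)) {
      if (is.null(dens[[i]])) next
      mid <- (mh[[i]]$lower + mh[[i]]$upper) / 2
      graphics::lines(mid, dens[[i]], col = pal[i], type = "s")
    }
    graphics::legend("top", legend = ids, col = pal, lty = 1, cex = 0.7,
                     bty = "n")
  }) else NULL

  # --- CpG density histogram ---
  dh <- lapply(bundle$summaries, `[[`, "cpg_density_histogram")
  dh_n <- sum(vapply(dh, function(h) !is.null(h) && nrow(h) > 0,
                     logical(1)))
  dh_uri <- if (dh_n > 0) plot_data_uri({
    xmax <- max(unlist(lapply(dh, function(h) h$density)), 1)
    ymax <- max(unlist(lapply(dh, function(h) {
      if (is.null(h) || !nrow(h)) return(0)
      h$count / sum(h$count)
    })), 0.01)
    graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, ymax * 1.1),
                   xlab = sprintf("reference CpGs within the density window"),
                   ylab = "fraction of covered sites",
                   main = "CpG density around covered sites")
    for (i in seq_len(n)) {
      h <- dh[[i]]
      if (is.null(h) || !nrow(h)) next
      graphics::lines(h$density, h$count / sum(h$count), col = pal[i],
                      type = "h")
    }
    graphics::legend("topright", legend = ids, col = pal, lty = 1,
                     cex = 0.7, bty = "n")
  }) else NULL

  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    "<title>bsqc quality control report</title>",
    "<style>",
    "body{font-family:sans-serif;margin:2em;max-width:70em}",
    "table{border-collapse:collapse;font-size:0.85em}",
    "td,th{border:1px solid #bbb;padding:0.3em 0.6em;text-align:right}",
    "th{background:#f0f0f0}",
    "td.flag{background:#ffd6d6;font-weight:bold}",
    ".panel{margin-top:2em}",
    ".placeholder{color:#888;font-style:italic}",
    "</style></head><body>",
    "<h1>bsqc quality control report</h1>",
    sprintf("<p class=\"meta\">generated: %s &middot; version %s &middot; %d sample(s)</p>",
            format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), bundle$version, n),
    "<h2>Per-sample metrics</h2>",
    "<table id=\"metrics\">",
    paste0("<tr>", header_cells, "</tr>"),
    body_rows,
    "</table>",
    panel("M-bias", mb_n, mbias_uri),
    panel("Downsampling saturation", sat_n, sat_uri),
    panel("Methylation value distribution", mh_n, mh_uri),
    panel("CpG density distribution", dh_n, dh_uri),
    "</body></html>"
  )
  write_text_lines(html, path)
}
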