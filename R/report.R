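# Static HTML review gallery: the non-reactive equivalent of the dashboard's
# data display area. Browsable from the filesystem, no server or network.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

REPORT_CSS <- "
body { font-family: sans-serif; margin: 1em 2em; color: #222; }
table { border-collapse: collapse; }
th, td { border: 1px solid #bbb; padding: 3px 8px; font-size: 0.9em; }
th { background: #eee; cursor: pointer; }
.panel { display: inline-block; margin: 4px; vertical-align: top; }
.panel img { border: 1px solid #888; image-rendering: pixelated; }
.placeholder { display: inline-block; margin: 4px; padding: 24px;
  border: 1px dashed #c00; color: #c00; font-size: 0.85em; }
.nav a { margin-right: 1.5em; }
.flag-true { color: #c00; font-weight: bold; }
"

INDEX_JS <- "
function filterRows() {
  var q = document.getElementById('search').value.toLowerCase();
  var rows = document.querySelectorAll('#studies tbody tr');
  rows.forEach(function (r) {
    r.style.display = r.textContent.toLowerCase().indexOf(q) >= 0 ? '' : 'none';
  });
}
function sortBy(k) {
  var tb = document.querySelector('#studies tbody');
  var rows = Array.from(tb.rows);
  var asc = tb.dataset.sort !== String(k) || tb.dataset.asc !== '1';
  rows.sort(function (a, b) {
    var x = a.cells[k].textContent, y = b.cells[k].textContent;
    var nx = parseFloat(x), ny = parseFloat(y);
    var c = (!isNaN(nx) && !isNaN(ny)) ? nx - ny : x.localeCompare(y);
    return asc ? c : -c;
  });
  rows.forEach(function (r) { tb.appendChild(r); });
  tb.dataset.sort = String(k); tb.dataset.asc = asc ? '1' : '0';
}
"

html_page <- function(title, body, js = NULL) {
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">\n<title>",
         html_escape(title), "</title>\n<style>", REPORT_CSS, "</style>\n",
         if (!is.null(js)) paste0("<script>", js, "</script>\n"),
         "</head>\n<body>\n", body, "\n</body></html>\n")
}

#' Report configuration
#' @param panel_order panel kinds in display order on case pages.
#' @param include_scatter draw the measured-vs-reference volume scatter.
#' @param table_columns manifest columns shown on the index (default: all
#'   non-path columns).
#' @return list of class `report_config`.
#' @export
report_config <- function(panel_order = c("annotation", "registration", "csf",
                                          "density", "crosshair"),
                          include_scatter = TRUE,
                          table_columns = NULL) {
  structure(list(panel_order = panel_order, include_scatter = include_scatter,
                 table_columns = table_columns), class = "report_config")
}

#' Measured-vs-reference tumor volume scatter
#'
#' Scatter of segmented versus reference tumor volumes with a dashed
#' identity line indicating agreement; the currently opened case can be
#' highlighted with a distinct marker.
#'
#' @param measured,reference named numeric vectors (cm^3), names = study IDs.
#' @param file output PNG path.
#' @param highlight study ID to highlight, or `NULL`.
#' @param main plot title.
#' @return list with `status` (`"rendered"` / `"skipped"`) and `file`.
#' @export
build_scatter <- function(measured, reference, file, highlight = NULL,
                          main = "Segmented vs reference tumor volume") {
  ids <- intersect(names(measured), names(reference))
  ids <- ids[is.finite(measured[ids]) & is.finite(reference[ids])]
  if (length(ids) == 0) {
    warning("no paired volume values; scatter skipped")
    return(list(status = "skipped", file = file))
  }
  grDevices::png(file, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  lim <- range(0, measured[ids], reference[ids])
  graphics::plot(reference[ids], measured[ids], xlim = lim, ylim = lim,
                 xlab = "reference volume (cm^3)",
                 ylab = "segmented volume (cm^3)",
                 pch = 19, col = "#33557788", main = main)
  graphics::abline(0, 1, lty = 2)
  if (!is.null(highlight) && highlight %in% ids)
    graphics::points(reference[highlight], measured[highlight],
                     pch = 21, cex = 2, lwd = 2, col = "red", bg = "yellow")
  list(status = "rendered", file = file)
}

panel_img_html <- function(panels, rel_dir = "panels") {
  out <- character()
  for (i in seq_len(nrow(panels))) {
    p <- panels[i, ]
    cap <- html_escape(sprintf("%s / %s / %s", p$kind, p$modality, p$plane))
    if (identical(p$status, "rendered")) {
      out <- c(out, sprintf(
        "<div class=\"panel\"><img src=\"%s/%s\" alt=\"%s\"><br><small>%s</small></div>",
        rel_dir, html_escape(basename(p$file)), cap, cap))
    } else {
      out <- c(out, sprintf(
        "<div class=\"placeholder\">missing panel<br>%s<br>(%s)</div>",
        cap, html_escape(p$status)))
    }
  }
  paste(out, collapse = "\n")
}

review_state_html <- function(entry) {
  if (is.null(entry) || nrow(entry) == 0)
    return("<p><em>unreviewed</em></p>")
  q <- vapply(Q_COLUMNS, function(cl) as.character(entry[[cl]][1]), "")
  fl <- vapply(F_COLUMNS, function(cl) entry[[cl]][1] %in% TRUE, TRUE)
  cls <- as.character(classify_combined(entry))
  paste0(
    sprintf("<p>Combined class: <b>%s</b> (reviewer %s, %s)</p>",
            html_escape(cls), html_escape(entry$reviewer[1]),
            html_escape(entry$timestamp[1])),
    "<ul>",
    paste(sprintf("<li>%s: %s</li>", html_escape(sub("^q_", "", Q_COLUMNS)),
                  html_escape(q)), collapse = ""),
    paste(sprintf("<li class=\"%s\">%s: %s</li>",
                  ifelse(fl, "flag-true", ""),
                  html_escape(sub("^f_", "", F_COLUMNS)),
                  ifelse(fl, "set", "-")), collapse = ""),
    "</ul>",
    if (nzchar(entry$comment[1]))
      sprintf("<p>Comment: %s</p>", html_escape(entry$comment[1])) else "")
}

#' Build one case page
#'
#' A self-contained HTML page for one study: its snapshot panels in the
#' configured order (missing panels appear as explicit placeholders), QC
#' metrics, the current review state, and previous/next navigation.
#'
#' @param study_id study identifier.
#' @param panels panel data.frame (from a `snapshot_set` or its JSON sidecar).
#' @param qc_row one-row data.frame of QC values, or `NULL`.
#' @param entry one-row `review_log`, or `NULL` for unreviewed.
#' @param out_dir site output directory.
#' @param prev_id,next_id neighbor case IDs (or `NULL`).
#' @param config a [report_config()].
#' @return path of the written HTML file.
#' @export
build_case_page <- function(study_id, panels, qc_row = NULL, entry = NULL,
                            out_dir, prev_id = NULL, next_id = NULL,
                            config = report_config()) {
  ord <- match(panels$kind, config$panel_order)
  panels <- panels[order(ord, panels$modality, panels$plane), , drop = FALSE]
  nav <- paste0("<p class=\"nav\"><a href=\"index.html\">index</a>",
                if (!is.null(prev_id))
                  sprintf("<a href=\"%s.html\">&larr; %s</a>",
                          html_escape(prev_id), html_escape(prev_id)) else "",
                if (!is.null(next_id))
                  sprintf("<a href=\"%s.html\">%s &rarr;</a>",
                          html_escape(next_id), html_escape(next_id)) else "",
                "</p>")
  qc_html <- if (is.null(qc_row)) "" else paste0(
    "<h2>QC metrics</h2><ul>",
    paste(sprintf("<li>%s: %s</li>", html_escape(names(qc_row)),
                  html_escape(vapply(qc_row, function(v)
                    format(v, digits = 4), ""))), collapse = ""),
    "</ul>")
  body <- paste0("<h1>", html_escape(study_id), "</h1>", nav,
                 "<h2>Review</h2>", review_state_html(entry),
                 qc_html,
                 "<h2>Panels</h2>", panel_img_html(panels), nav)
  file <- file.path(out_dir, paste0(study_id, ".html"))
  writeLines(html_page(study_id, body), file)
  file
}

#' Build the index page
#'
#' The cohort overview: a client-side searchable/sortable table of study
#' ID, non-path manifest data, QC values and the combined review class,
#' each row linking to its case page. Purely static — no server process.
#'
#' @param manifest a `study_manifest`.
#' @param qc_tbl data.frame from [qc_table()], or `NULL`.
#' @param log a `review_log`, or `NULL`.
#' @param out_dir site output directory.
#' @param extra_html HTML fragment inserted above the table (e.g. scatter).
#' @param config a [report_config()].
#' @return path of the written `index.html`.
#' @export
build_index <- function(manifest, qc_tbl = NULL, log = NULL, out_dir,
                        extra_html = "", config = report_config()) {
  df <- as.data.frame(manifest)
  keep <- if (is.null(config$table_columns))
    names(df)[!grepl("^path_", names(df))] else
      intersect(c("study_id", config$table_columns), names(df))
  df <- df[, keep, drop = FALSE]
  if (!is.null(qc_tbl)) df <- merge(df, qc_tbl, by = "study_id",
                                    all.x = TRUE, sort = FALSE)
  cls <- rep("unreviewed", nrow(df))
  if (!is.null(log) && nrow(log)) {
    m <- match(df$study_id, log$study_id)
    cc <- as.character(classify_combined(log))
    cls[!is.na(m)] <- cc[m[!is.na(m)]]
  }
  df$review_class <- cls
  head_html <- paste(sprintf("<th onclick=\"sortBy(%d)\">%s</th>",
                             seq_along(df) - 1L, html_escape(names(df))),
                     collapse = "")
  row_html <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(seq_along(df), function(j) {
      v <- df[i, j]
      v <- if (is.numeric(v)) format(v, digits = 4) else as.character(v)
      if (names(df)[j] == "study_id")
        sprintf("<td><a href=\"%s.html\">%s</a></td>", html_escape(v),
                html_escape(v))
      else sprintf("<td>%s</td>", html_escape(ifelse(is.na(v), "", v)))
    }, "")
    paste0("<tr>", paste(cells, collapse = ""), "</tr>")
  }, "")
  body <- paste0(
    "<h1>Study review index</h1>", extra_html,
    "<p><input id=\"search\" onkeyup=\"filterRows()\" ",
    "placeholder=\"search...\" size=\"40\"></p>",
    "<table id=\"studies\"><thead><tr>", head_html, "</tr></thead><tbody>\n",
    paste(row_html, collapse = "\n"), "\n</tbody></table>")
  file <- file.path(out_dir, "index.html")
  writeLines(html_page("Study review index", body, js = INDEX_JS), file)
  file
}

#' Assemble the full static review site
#'
#' Copies rendered panels into the site, then writes one case page per
#' study plus a searchable index with the volume scatter. The resulting
#' directory tree (HTML + PNG) opens directly from the filesystem.
#'
#' @param manifest a `study_manifest`.
#' @param snapshots_dir directory holding [render_study()] output (panel
#'   PNGs and `*_panels.json` sidecars).
#' @param out_dir site output directory (created).
#' @param log optional `review_log`.
#' @param qcs optional list of `study_qc` objects.
#' @param config a [report_config()].
#' @return `out_dir`, invisibly.
#' @export
build_report <- function(manifest, snapshots_dir, out_dir, log = NULL,
                         qcs = NULL, config = report_config()) {
  dir.create(file.path(out_dir, "panels"), recursive = TRUE, showWarnings = FALSE)
  qc_tbl <- if (!is.null(qcs)) qc_table(qcs) else NULL
  ids <- manifest$study_id
  panel_sets <- list()
  for (id in ids) {
    side <- file.path(snapshots_dir, sprintf("%s_panels.json", id))
    if (!file.exists(side)) {
      panel_sets[[id]] <- data.frame(kind = character(), modality = character(),
                                     plane = character(), slice_index = character(),
                                     file = character(), status = character(),
                                     stringsAsFactors = FALSE)
      next
    }
    ps <- jsonlite::read_json(side, simplifyVector = TRUE)$panels
    ok <- ps$status == "rendered" & file.exists(ps$file)
    file.copy(ps$file[ok], file.path(out_dir, "panels", basename(ps$file[ok])),
              overwrite = TRUE)
    ps$status[ps$status == "rendered" & !file.exists(ps$file)] <- "failed"
    panel_sets[[id]] <- ps
  }
  extra <- ""
  if (isTRUE(config$include_scatter) && "ref_total_cm3" %in% names(manifest) &&
      !is.null(qc_tbl)) {
    measured <- stats::setNames(qc_tbl$tumor_total_cm3, qc_tbl$study_id)
    reference <- stats::setNames(as.numeric(manifest$ref_total_cm3),
                                 manifest$study_id)
    sc <- build_scatter(measured, reference,
                        file.path(out_dir, "panels", "volume_scatter.png"))
    if (sc$status == "rendered") {
      ids2 <- intersect(names(measured), names(reference))
      ids2 <- ids2[is.finite(measured[ids2]) & is.finite(reference[ids2])]
      dev <- abs(measured[ids2] - reference[ids2])
      ord <- ids2[order(dev, decreasing = TRUE)]
      lookup <- paste(sprintf(
        "<tr><td><a href=\"%s.html\">%s</a></td><td>%.2f</td><td>%.2f</td><td>%.2f</td></tr>",
        html_escape(ord), html_escape(ord), measured[ord], reference[ord],
        dev[ord]), collapse = "\n")
      extra <- paste0(
        "<div class=\"panel\"><img src=\"panels/volume_scatter.png\" ",
        "alt=\"volume scatter\"></div>",
        "<details><summary>volume agreement lookup (largest deviation first)",
        "</summary><table><tr><th>study</th><th>measured</th><th>reference",
        "</th><th>|diff|</th></tr>", lookup, "</table></details>")
    }
  }
  for (i in seq_along(ids)) {
    id <- ids[i]
    entry <- if (!is.null(log) && id %in% log$study_id)
      log[log$study_id == id, , drop = FALSE] else NULL
    qc_row <- if (!is.null(qc_tbl) && id %in% qc_tbl$study_id)
      qc_tbl[qc_tbl$study_id == id, -1, drop = FALSE] else NULL
    build_case_page(id, panel_sets[[id]], qc_row = qc_row, entry = entry,
                    out_dir = out_dir,
                    prev_id = if (i > 1) ids[i - 1],
                    next_id = if (i < length(ids)) ids[i + 1],
                    config = config)
  }
  build_index(manifest, qc_tbl, log, out_dir, extra_html = extra, config = config)
  invisible(out_dir)
}
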