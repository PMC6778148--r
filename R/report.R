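# HTML report layer: aggregates clone QC, clustering and selection outputs
# into one self-contained report, plus the run-configuration record that
# makes a run reproducible.

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.html_table <- function(df, caption = NULL) {
  if (is.null(df) || nrow(df) == 0) return("")
  head_row <- paste0("<tr>", paste0("<th>", .html_escape(names(df)),
                                    "</th>", collapse = ""), "</tr>")
  body <- vapply(seq_len(nrow(df)), function(i)
    paste0("<tr>", paste0("<td>",
                          .html_escape(unlist(df[i, ], use.names = FALSE)),
                          "</td>", collapse = ""), "</tr>"), character(1))
  paste0(if (!is.null(caption)) sprintf("<h2>%s</h2>", .html_escape(caption))
         else "",
         "<table border='1' cellpadding='4' cellspacing='0'>",
         head_row, paste(body, collapse = ""), "</table>")
}

#' Render the pipeline HTML report
#'
#' Aggregates the outputs of the clone-QC, clustering and selection steps
#' into a single HTML file: valid/invalid counts with failure reasons, one
#' row per cluster, the ELISA specificity matrix and per-round enrichment.
#' Sections whose input is `NULL` are skipped. Apart from the timestamp
#' line the output is a deterministic function of its inputs.
#'
#' @param file output HTML path.
#' @param qc clone table from [cloneTable()], or `NULL`.
#' @param clusters cluster table from [clusterReport()]`$table`, or `NULL`.
#' @param elisa data.frame of ELISA signals/calls, or `NULL`.
#' @param panning data.frame with per-round titers/enrichment, or `NULL`.
#' @param title report title.
#' @return `file`, invisibly.
#' @export
renderReport <- function(file, qc = NULL, clusters = NULL, elisa = NULL,
                         panning = NULL, title = "Selection report") {
  parts <- c(sprintf("<html><head><title>%s</title></head><body>",
                     .html_escape(title)),
             sprintf("<h1>%s</h1>", .html_escape(title)),
             sprintf("<p class='timestamp'>generated %s</p>",
                     format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  if (!is.null(qc)) {
    counts <- table(factor(qc$status, c("valid", "invalid")))
    parts <- c(parts,
               sprintf("<h2>Clone QC</h2><p>%d reads: %d valid, %d invalid</p>",
                       nrow(qc), counts[["valid"]], counts[["invalid"]]),
               .html_table(qc, "Per-read triage"))
  }
  if (!is.null(clusters))
    parts <- c(parts, .html_table(clusters, "Clusters"))
  if (!is.null(elisa))
    parts <- c(parts, .html_table(elisa, "Phage-ELISA"))
  if (!is.null(panning))
    parts <- c(parts, .html_table(panning, "Panning rounds"))
  parts <- c(parts, "</body></html>")
  writeLines(parts, file)
  invisible(file)
}

#' Resolve and record a run configuration
#'
#' Merges parameter overrides over defaults (override wins), records the
#' resolved values plus the seed, and serializes the result as JSON into
#' the output directory so a run can be reproduced from its artifacts
#' alone.
#'
#' @param outputDir run output directory (created if needed).
#' @param seed integer seed recorded and used by the caller.
#' @param defaults named list of default parameters.
#' @param overrides named list of overriding parameters.
#' @return the resolved configuration (named list), invisibly written to
#'   `outputDir/run-config.json`.
#' @export
resolveRunConfig <- function(outputDir, seed = 1L, defaults = list(),
                             overrides = list()) {
  cfg <- defaults
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg$seed <- as.integer(seed)
  if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
  jsonlite::write_json(cfg, file.path(outputDir, "run-config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  cfg
}
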