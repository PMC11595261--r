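#' Read a GEO Series Matrix file into an expression cohort
#'
#' Parses the tab-separated Series Matrix layout: metadata lines prefixed with
#' `!`, and a probe-by-sample table enclosed between
#' `!series_matrix_table_begin` and `!series_matrix_table_end` whose first row
#' holds sample accessions and first column probe identifiers. Probes are
#' mapped to gene symbols and collapsed to one row per gene.
#'
#' @param path Path to a Series Matrix file (plain text, uncompressed).
#' @param label_map Optional sample-to-label mapping: a named character vector,
#'   a two-column data frame (`sample_id`, `label`), or a path to a JSON file
#'   of `{"sample": "label"}` pairs. Samples absent from the map get label
#'   `"unknown"`. Labels are never guessed from the file's metadata text.
#' @param probe_map Probe-to-gene mapping: a named character vector
#'   (names = probes, values = gene symbols), a two-column data frame
#'   (`probe`, `gene`), or `NULL` when probe identifiers already are gene
#'   symbols. Probes mapping to `NA` or `""` are dropped.
#' @param collapse Collapse method for multi-probe genes, `"mean"` (default)
#'   or `"max_var"`; see [collapse_probes()].
#' @return An expression cohort tibble (see [as_cohort()]). Sample order
#'   follows the file's column order.
#' @export
read_series_matrix <- function(path, label_map = NULL, probe_map = NULL,
                               collapse = c("mean", "max_var")) {
  collapse <- match.arg(collapse)
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(begin) != 1L || length(end) != 1L || end <= begin) {
    stop("not a Series Matrix file: table begin/end delimiters missing in ",
         path, call. = FALSE)
  }
  if (end - begin < 3L) stop("empty Series Matrix table in ", path, call. = FALSE)
  body <- lines[(begin + 1L):(end - 1L)]
  body <- body[nzchar(body)]
  if (length(body) < 2L) stop("empty Series Matrix table in ", path, call. = FALSE)

  header <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- gsub('^"|"$', "", header[-1L])
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  probes <- vapply(rows, function(r) gsub('^"|"$', "", r[[1L]]), character(1))
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(sample_ids))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != length(sample_ids) + 1L) {
      stop("row ", i, " (probe ", probes[i], ") has ", length(r) - 1L,
           " values, expected ", length(sample_ids), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(r[-1L]))
    bad <- which(is.na(v) & !(r[-1L] %in% c("NA", "null", "")))
    if (length(bad)) {
      stop("non-numeric value at table row ", i, ", column ", bad[[1L]] + 1L,
           " (probe ", probes[i], "): '", r[-1L][bad[[1L]]], "'", call. = FALSE)
    }
    vals[i, ] <- v
  }

  probe_tbl <- tibble::as_tibble(as.data.frame(t(vals)))
  names(probe_tbl) <- probes
  probe_tbl <- dplyr::bind_cols(tibble::tibble(sample_id = sample_ids), probe_tbl)

  if (is.null(probe_map)) {
    mapping <- stats::setNames(probes, probes)
  } else {
    mapping <- normalize_probe_map(probe_map)
  }
  out <- collapse_probes(probe_tbl, mapping, method = collapse)
  out$label <- resolve_labels(out$sample_id, label_map)
  as_cohort(out)
}

normalize_probe_map <- function(probe_map) {
  if (is.data.frame(probe_map)) {
    stats::setNames(as.character(probe_map[[2L]]), as.character(probe_map[[1L]]))
  } else if (is.character(probe_map) && !is.null(names(probe_map))) {
    probe_map
  } else {
    stop("probe_map must be a named character vector or two-column data frame",
         call. = FALSE)
  }
}

resolve_labels <- function(sample_ids, label_map) {
  if (is.null(label_map)) return(rep("unknown", length(sample_ids)))
  if (is.character(label_map) && is.null(names(label_map)) &&
      length(label_map) == 1L) {
    label_map <- unlist(jsonlite::read_json(label_map))
  }
  if (is.data.frame(label_map)) {
    label_map <- stats::setNames(as.character(label_map[[2L]]),
                                 as.character(label_map[[1L]]))
  }
  lab <- unname(label_map[sample_ids])
  lab[is.na(lab)] <- "unknown"
  lab
}

#' Collapse probe-level columns to gene symbols
#'
#' Maps probe columns of a probe-level cohort to gene symbols and collapses
#' genes measured by several probes to a single column. Probes whose mapped
#' symbol is missing or blank are dropped, mirroring the removal of
#' unknown/unnamed sequences before differential-expression analysis.
#'
#' @param data A wide tibble with `sample_id` (and optionally `label`) plus one
#'   numeric column per probe.
#' @param mapping Named character vector, names = probe ids, values = gene
#'   symbols (or a two-column `probe`,`gene` data frame).
#' @param method `"mean"` averages the probe columns of a gene;
#'   `"max_var"` keeps the single probe with the largest variance across
#'   samples (ties broken by probe order).
#' @return An expression cohort tibble with one column per gene symbol.
#' @export
collapse_probes <- function(data, mapping, method = c("mean", "max_var")) {
  method <- match.arg(method)
  mapping <- normalize_probe_map(mapping)
  data <- tibble::as_tibble(data)
  probes <- setdiff(names(data), c("sample_id", "label"))
  genes <- unname(mapping[probes])
  keep <- !is.na(genes) & nzchar(genes)
  if (!any(keep)) {
    stop("no probe maps to a non-empty gene symbol; nothing to retain",
         call. = FALSE)
  }
  probes <- probes[keep]
  genes <- genes[keep]

  out <- data[intersect(c("sample_id", "label"), names(data))]
  for (g in unique(genes)) {
    cols <- probes[genes == g]
    if (length(cols) == 1L) {
      out[[g]] <- data[[cols]]
    } else if (method == "mean") {
      out[[g]] <- rowMeans(as.matrix(as.data.frame(data[cols])))
    } else {
      vars <- vapply(cols, function(p) stats::var(data[[p]]), numeric(1))
      out[[g]] <- data[[cols[which.max(vars)]]]
    }
  }
  out
}

#' Write an expression cohort in GEO Series Matrix layout
#'
#' Serializes a cohort as a Series Matrix file (synthetic probe identifiers,
#' one probe per gene unless `probe_ids` says otherwise) so that readers are
#' exercised on realistic bytes. Labels are not stored in the file; keep them
#' in a sidecar JSON written with [write_label_map()].
#'
#' @param data An expression cohort tibble.
#' @param path Output path.
#' @param probe_ids Optional named character vector probe id -> gene symbol
#'   used to emit probe-level rows (several probes may point at one gene, each
#'   receiving that gene's values). Default: one probe named after each gene.
#' @export
write_series_matrix <- function(data, path, probe_ids = NULL) {
  data <- as_cohort(data)
  genes <- cohort_genes(data)
  if (is.null(probe_ids)) probe_ids <- stats::setNames(genes, genes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "!Series_title\t\"synthetic expression cohort\"",
    paste0("!Series_sample_id\t\"", paste(data$sample_id, collapse = " "), "\""),
    "!series_matrix_table_begin"
  ), con)
  writeLines(paste(c("\"ID_REF\"", paste0('"', data$sample_id, '"')),
                   collapse = "\t"), con)
  for (p in names(probe_ids)) {
    vals <- format(data[[probe_ids[[p]]]], digits = 15, trim = TRUE,
                   scientific = FALSE)
    writeLines(paste(c(paste0('"', p, '"'), vals), collapse = "\t"), con)
  }
  writeLines("!series_matrix_table_end", con)
  invisible(path)
}

#' Label maps and marker panels on disk
#'
#' Label maps are JSON objects `{"sample_id": "label"}`; marker panels are
#' JSON objects `{"up": [...], "down": [...]}`.
#'
#' @param data Cohort tibble (label map) or `marker_panel` (panel).
#' @param path File path.
#' @name io_json
NULL

#' @rdname io_json
#' @export
write_label_map <- function(data, path) {
  jsonlite::write_json(as.list(stats::setNames(data$label, data$sample_id)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname io_json
#' @export
read_label_map <- function(path) {
  unlist(jsonlite::read_json(path))
}

#' @rdname io_json
#' @export
write_panel <- function(data, path) {
  stopifnot(inherits(data, "marker_panel"))
  jsonlite::write_json(list(up = data$up, down = data$down), path,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname io_json
#' @export
read_panel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  marker_panel(up = as.character(x$up), down = as.character(x$down))
}

#' Read/write cascade result tables
#'
#' Results are TSV files with columns `sample_id`, `true_label`, `call`,
#' `decided_at_step`; undetermined samples have an empty `decided_at_step`
#' field. The round trip is lossless.
#'
#' @param result A cascade result tibble from [apply_cascade()].
#' @param path File path.
#' @export
write_result_table <- function(result, path) {
  out <- result[c("sample_id", "true_label", "call", "decided_at_step")]
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    true_label = readr::col_character(),
    call = readr::col_character(),
    decided_at_step = readr::col_integer()
  ), na = "", progress = FALSE)
}
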