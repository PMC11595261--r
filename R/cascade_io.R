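#' Read/write cascade configurations
#'
#' Cascades serialize to JSON: one entry per step with the ordered gene
#' list, layout mode, labeled regions (`anchor_a`, `anchor_b`, `r_min`) and,
#' when fitted, the frozen per-gene normalization bounds. The round trip is
#' lossless, so a cascade fitted on one cohort can be applied to another
#' from disk.
#'
#' @param cascade An `rv_cascade`.
#' @param path File path (JSON).
#' @export
write_cascade <- function(cascade, path) {
  steps <- lapply(cascade$steps, function(s) {
    list(
      genes = s$layout$genes,
      mode = s$layout$mode,
      regions = lapply(seq_along(s$regions), function(j) {
        r <- s$regions[[j]]
        list(label = names(s$regions)[j], anchor_a = r$anchor_a,
             anchor_b = r$anchor_b, r_min = r$r_min)
      }),
      normalization = if (is.null(s$normalization)) NULL else
        list(gene = s$normalization$gene, min = s$normalization$min,
             max = s$normalization$max)
    )
  })
  jsonlite::write_json(list(steps = steps), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_cascade
#' @export
read_cascade <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  steps <- lapply(x$steps, function(s) {
    genes <- unlist(s$genes)
    layout <- if (identical(s$mode, "cartesian")) {
      anchor_layout(genes, "cartesian")
    } else {
      anchor_layout(genes)
    }
    regions <- stats::setNames(
      lapply(s$regions, function(r) {
        sector_region(r$anchor_a, r$anchor_b, r$r_min)
      }),
      vapply(s$regions, `[[`, character(1), "label"))
    norm <- NULL
    if (!is.null(s$normalization)) {
      norm <- tibble::tibble(gene = unlist(s$normalization$gene),
                             min = unlist(s$normalization$min),
                             max = unlist(s$normalization$max))
      class(norm) <- c("radviz_norm", class(norm))
    }
    elimination_step(layout, regions, normalization = norm)
  })
  new_cascade(steps)
}

#' Write a DEG table with its thresholds in the header
#'
#' TSV with `#`-prefixed header lines recording the thresholds used, for
#' provenance, followed by the gene, mean_diff, t_mod, p_raw, p_adj,
#' direction columns.
#'
#' @param table DEG tibble from [moderated_t()].
#' @param path Output path.
#' @param thresholds Named list echoed into the header.
#' @export
write_deg_table <- function(table, path, thresholds = list()) {
  hdr <- c("# differential expression table",
           vapply(names(thresholds), function(nm) {
             paste0("# ", nm, " = ", thresholds[[nm]])
           }, character(1)))
  writeLines(hdr, path)
  readr::write_tsv(table, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  readr::read_tsv(path, comment = "#", col_types = readr::cols(
    gene = readr::col_character(),
    direction = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}

#' Write an evaluation report as TSV
#'
#' Mirrors the Selected/Correct presentation per class, followed by
#' `#`-prefixed summary lines (undetermined and false-call counts).
#'
#' @param eval_report A `cascade_eval` from [evaluate()].
#' @param path Output path.
#' @export
write_eval_report <- function(eval_report, path) {
  readr::write_tsv(eval_report$per_class, path)
  cat(sprintf("# undetermined\t%d\n# false_sensitive\t%d\n# false_resistant\t%d\n",
              eval_report$undetermined, eval_report$false_sensitive,
              eval_report$false_resistant),
      file = path, append = TRUE)
  invisible(path)
}
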