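#' Expression cohorts as wide tibbles
#'
#' Throughout the package an expression cohort is an ordinary tibble with one
#' row per sample: a `sample_id` character column, a `label` column in
#' `c("resistant", "sensitive", "unknown")`, and one numeric column per gene
#' symbol. Expression units are whatever the source provides (log2 intensities
#' are typical for microarray series); all downstream math is scale-agnostic.
#'
#' `as_cohort()` validates and normalizes a data frame into this shape;
#' `cohort_genes()` lists the gene columns; `cohort_matrix()` extracts the
#' samples-by-genes numeric matrix (rownames = sample ids).
#'
#' @param data A data frame with `sample_id`, optionally `label`, and numeric
#'   gene columns.
#' @return `as_cohort()` returns the validated tibble; `cohort_genes()` a
#'   character vector; `cohort_matrix()` a numeric matrix.
#' @examples
#' coh <- as_cohort(tibble::tibble(
#'   sample_id = c("s1", "s2"), label = c("resistant", "sensitive"),
#'   GENE1 = c(8.1, 7.9), GENE2 = c(6.2, 6.5)
#' ))
#' cohort_genes(coh)
#' @export
as_cohort <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"sample_id" %in% names(data)) {
    stop("cohort must have a `sample_id` column", call. = FALSE)
  }
  data$sample_id <- as.character(data$sample_id)
  if (anyDuplicated(data$sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(data$sample_id[duplicated(data$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!"label" %in% names(data)) data$label <- "unknown"
  data$label <- as.character(data$label)
  bad <- setdiff(unique(data$label), c("resistant", "sensitive", "unknown"))
  if (length(bad)) {
    stop("labels must be 'resistant', 'sensitive' or 'unknown'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  genes <- setdiff(names(data), c("sample_id", "label"))
  if (anyDuplicated(genes)) {
    stop("duplicate gene columns: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  }
  for (g in genes) {
    if (!is.numeric(data[[g]])) {
      stop("gene column `", g, "` is not numeric", call. = FALSE)
    }
  }
  vals <- as.matrix(data[genes])
  if (length(vals) && any(!is.finite(vals))) {
    drop <- genes[colSums(!is.finite(vals)) > 0]
    warning("dropping ", length(drop), " gene(s) with missing/non-finite values: ",
            paste(utils::head(drop, 5), collapse = ", "),
            if (length(drop) > 5) ", ..." else "", call. = FALSE)
    data <- data[setdiff(names(data), drop)]
  }
  dplyr::relocate(data, "sample_id", "label")
}

#' @rdname as_cohort
#' @export
cohort_genes <- function(data) {
  setdiff(names(data), c("sample_id", "label"))
}

#' @rdname as_cohort
#' @export
cohort_matrix <- function(data) {
  genes <- cohort_genes(data)
  m <- as.matrix(as.data.frame(data[genes]))
  rownames(m) <- data$sample_id
  m
}

check_genes_present <- function(data, genes, context = "cohort") {
  missing <- setdiff(genes, cohort_genes(data))
  if (length(missing)) {
    stop("gene(s) missing from ", context, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
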