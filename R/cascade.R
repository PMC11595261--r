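#' Elimination steps and cascades
#'
#' An elimination step pairs an anchor layout with one sector region and the
#' label it eliminates ("calls"): samples whose projected point falls in the
#' region receive that label and leave the cohort. A final step may carry two
#' labeled regions on one shared layout (one per class), with everything else
#' left "mixed". A cascade is an ordered list of such steps.
#'
#' @param layout An [anchor_layout()].
#' @param region A [sector_region()], or for a dual final step a named list
#'   of regions with names in `c("sensitive", "resistant")`.
#' @param eliminate Label eliminated by the region (ignored when `region` is
#'   a named list).
#' @param normalization Optional `radviz_norm` covering the layout genes;
#'   fitted later via [fit_cascade_normalization()] when absent.
#' @return An `elimination_step`.
#' @export
elimination_step <- function(layout, region, eliminate = NULL,
                             normalization = NULL) {
  if (inherits(region, "sector_region")) {
    if (is.null(eliminate)) stop("eliminate label required", call. = FALSE)
    regions <- stats::setNames(list(region), eliminate)
  } else {
    regions <- region
  }
  labs <- names(regions)
  if (is.null(labs) || !all(labs %in% c("sensitive", "resistant")) ||
      anyDuplicated(labs)) {
    stop("step regions must be named with distinct labels ",
         "'sensitive'/'resistant'", call. = FALSE)
  }
  for (r in regions) region_arc(r, layout)  # validates anchors + adjacency
  if (!is.null(normalization)) {
    missing <- setdiff(layout$genes, normalization$gene)
    if (length(missing)) {
      stop("normalization lacks layout gene(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(layout = layout, regions = regions,
                 normalization = normalization),
            class = "elimination_step")
}

#' @param steps List of [elimination_step()]s; only the last may carry two
#'   labeled regions.
#' @rdname elimination_step
#' @export
new_cascade <- function(steps) {
  if (!length(steps)) stop("a cascade needs at least one step", call. = FALSE)
  n2 <- vapply(steps, function(s) length(s$regions), integer(1))
  if (any(n2[-length(steps)] > 1L)) {
    stop("only the final step may assign both labels", call. = FALSE)
  }
  structure(list(steps = steps), class = "rv_cascade")
}

#' @export
print.rv_cascade <- function(x, ...) {
  cat("<rv_cascade> ", length(x$steps), " step(s)\n", sep = "")
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    rr <- vapply(seq_along(s$regions), function(j) {
      r <- s$regions[[j]]
      paste0(names(s$regions)[j], " in ", r$anchor_a, "–", r$anchor_b)
    }, character(1))
    cat(sprintf("  %d. [%s] %s%s\n", i, paste(s$layout$genes, collapse = ", "),
                paste(rr, collapse = "; "),
                if (is.null(s$normalization)) " (unfitted)" else ""))
  }
  invisible(x)
}

#' Number of steps in a cascade
#' @param cascade An `rv_cascade`.
#' @export
n_steps <- function(cascade) length(cascade$steps)

#' The published four-step FOLFOX-response cascade
#'
#' The fixed eliminative cascade for calling FOLFOX-resistant versus
#' sensitive colorectal-cancer samples from expression of 14 marker genes:
#' step 1 projects TMEM182, MCM9, LRRFIP1 and LAMP1 on the coordinate axes
#' and eliminates sensitive samples in the LAMP1-LRRFIP1 quarter; step 2
#' projects FAM161A, KLHL36 and ETV5 and eliminates resistant samples in the
#' FAM161A-ETV5 arm; step 3 projects RNF168, SRSF11, NCKAP5 and CRTAP and
#' eliminates sensitive samples in the CRTAP-RNF168 quarter; step 4 projects
#' VAMP2, ZBTB49 and RIMBP2, calling sensitive in the VAMP2-RIMBP2 arm and
#' resistant in the RIMBP2-ZBTB49 arm, with the remainder undetermined
#' ("hard to interpret").
#'
#' Normalization bounds are not stored; fit them against a reference cohort
#' with [fit_cascade_normalization()] before applying.
#'
#' @param r_min Dead-zone radius around the origin for every region.
#' @return An `rv_cascade` with 4 steps.
#' @export
published_folfox_cascade <- function(r_min = 0.05) {
  new_cascade(list(
    elimination_step(
      anchor_layout(c("TMEM182", "MCM9", "LRRFIP1", "LAMP1"), "cartesian"),
      sector_region("LAMP1", "LRRFIP1", r_min), eliminate = "sensitive"),
    elimination_step(
      anchor_layout(c("FAM161A", "KLHL36", "ETV5")),
      sector_region("FAM161A", "ETV5", r_min), eliminate = "resistant"),
    elimination_step(
      anchor_layout(c("RNF168", "SRSF11", "NCKAP5", "CRTAP"), "cartesian"),
      sector_region("CRTAP", "RNF168", r_min), eliminate = "sensitive"),
    elimination_step(
      anchor_layout(c("VAMP2", "ZBTB49", "RIMBP2")),
      list(sensitive = sector_region("VAMP2", "RIMBP2", r_min),
           resistant = sector_region("RIMBP2", "ZBTB49", r_min)))
  ))
}

#' All genes used by a cascade
#' @param cascade An `rv_cascade`.
#' @export
cascade_genes <- function(cascade) {
  unique(unlist(lapply(cascade$steps, function(s) s$layout$genes)))
}

#' Fit a cascade's normalization bounds against a reference cohort
#'
#' Fits frozen per-gene min-max bounds for every step on the given cohort.
#'
#' @param data Expression cohort tibble containing all cascade genes.
#' @param cascade An `rv_cascade`.
#' @return The cascade with all step normalizations fitted.
#' @export
fit_cascade_normalization <- function(data, cascade) {
  data <- as_cohort(data)
  check_genes_present(data, cascade_genes(cascade))
  cascade$steps <- lapply(cascade$steps, function(s) {
    s$normalization <- fit_normalization(data, s$layout$genes)
    s
  })
  cascade
}

#' Apply an eliminative cascade to a cohort
#'
#' Runs the steps in order over the not-yet-eliminated samples. A sample
#' whose projected point lies in a step's region receives that region's
#' label and the 1-based step index; samples surviving every step are
#' `undetermined`. When a final step carries two regions and a point sits
#' exactly on their shared boundary, the first region listed wins.
#'
#' @param data Expression cohort tibble containing all cascade genes.
#' @param cascade A fitted `rv_cascade` (see [fit_cascade_normalization()]).
#' @param renormalize If `TRUE`, refit min-max bounds on the samples still in
#'   play at each step instead of using the stored frozen bounds (the
#'   training-time behaviour of interactive visual tools, where the display
#'   is rescaled to the samples on screen).
#' @return A tibble: `sample_id`, `true_label`, `call` in
#'   `c("sensitive", "resistant", "undetermined")`, `decided_at_step`
#'   (`NA` for undetermined samples). Input sample order is preserved.
#' @export
apply_cascade <- function(data, cascade, renormalize = FALSE) {
  data <- as_cohort(data)
  for (i in seq_along(cascade$steps)) {
    missing <- setdiff(cascade$steps[[i]]$layout$genes, cohort_genes(data))
    if (length(missing)) {
      stop("step ", i, " gene(s) missing from cohort: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  n <- nrow(data)
  call <- rep("undetermined", n)
  decided <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  for (i in seq_along(cascade$steps)) {
    if (!length(remaining)) break
    s <- cascade$steps[[i]]
    norm <- if (renormalize) {
      if (length(remaining) < 2L) s$normalization else
        fit_normalization(data[remaining, ], s$layout$genes)
    } else {
      s$normalization
    }
    if (is.null(norm)) {
      stop("step ", i, " has no fitted normalization; run ",
           "fit_cascade_normalization() first", call. = FALSE)
    }
    proj <- project(data[remaining, ], norm, s$layout)
    for (j in seq_along(s$regions)) {
      hit <- in_region(proj, s$regions[[j]], s$layout)
      hit_idx <- remaining[hit]
      hit_idx <- hit_idx[is.na(decided[hit_idx])]
      call[hit_idx] <- names(s$regions)[j]
      decided[hit_idx] <- i
    }
    remaining <- remaining[is.na(decided[remaining])]
  }
  tibble::tibble(sample_id = data$sample_id, true_label = data$label,
                 call = call, decided_at_step = decided)
}

#' Evaluate cascade calls against true labels
#'
#' Tallies, per class, how many samples were selected (called with that
#' label) and how many of those carry the matching true label, with the
#' percentage rounded to integers. Undetermined samples are counted
#' separately and never as correct. `false_sensitive` is the number of truly
#' resistant samples called sensitive (the clinically costly error);
#' `false_resistant` is symmetric.
#'
#' @param result Result tibble from [apply_cascade()]; true labels must be
#'   known for at least one sample.
#' @return A `cascade_eval`: list with `per_class` tibble
#'   (`class`, `selected`, `correct`, `percent`), `undetermined`,
#'   `false_sensitive`, `false_resistant`, `n`. Use [tidy()][tidy.cascade_eval]
#'   / [glance()][glance.cascade_eval] for tibble views.
#' @export
evaluate <- function(result) {
  known <- result$true_label %in% c("sensitive", "resistant")
  if (!any(known)) stop("no sample has a known true label", call. = FALSE)
  res <- result[known, ]
  per_class <- dplyr::bind_rows(lapply(c("sensitive", "resistant"), function(cl) {
    sel <- sum(res$call == cl)
    cor <- sum(res$call == cl & res$true_label == cl)
    tibble::tibble(class = cl, selected = sel, correct = cor,
                   percent = if (sel > 0) round(100 * cor / sel) else NA_real_)
  }))
  structure(list(
    per_class = per_class,
    undetermined = sum(res$call == "undetermined"),
    false_sensitive = sum(res$call == "sensitive" & res$true_label == "resistant"),
    false_resistant = sum(res$call == "resistant" & res$true_label == "sensitive"),
    n = nrow(res)
  ), class = "cascade_eval")
}

#' @export
print.cascade_eval <- function(x, ...) {
  cat("<cascade_eval> n =", x$n, "\n")
  print(x$per_class)
  cat("undetermined:", x$undetermined,
      " false_sensitive:", x$false_sensitive,
      " false_resistant:", x$false_resistant, "\n")
  invisible(x)
}

#' Tidy and glance methods
#'
#' `tidy()` returns the per-class Selected/Correct table; `glance()` a
#' one-row summary with overall accuracy among called samples and the
#' undetermined fraction. For cascades, `tidy()` lists one row per step.
#'
#' @param x A `cascade_eval` or `rv_cascade`.
#' @param ... Unused.
#' @name tidy-methods
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy-methods
#' @export
tidy.cascade_eval <- function(x, ...) x$per_class

#' @rdname tidy-methods
#' @export
glance.cascade_eval <- function(x, ...) {
  called <- sum(x$per_class$selected)
  correct <- sum(x$per_class$correct)
  tibble::tibble(
    n = x$n, called = called, correct = correct,
    pct_correct_called = if (called > 0) 100 * correct / called else NA_real_,
    undetermined = x$undetermined,
    pct_undetermined = 100 * x$undetermined / x$n,
    false_sensitive = x$false_sensitive,
    false_resistant = x$false_resistant
  )
}

#' @rdname tidy-methods
#' @export
tidy.rv_cascade <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$steps), function(i) {
    s <- x$steps[[i]]
    dplyr::bind_rows(lapply(seq_along(s$regions), function(j) {
      r <- s$regions[[j]]
      tibble::tibble(step = i, genes = paste(s$layout$genes, collapse = ","),
                     mode = s$layout$mode, label = names(s$regions)[j],
                     anchor_a = r$anchor_a, anchor_b = r$anchor_b,
                     r_min = r$r_min,
                     fitted = !is.null(s$normalization))
    }))
  }))
}
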