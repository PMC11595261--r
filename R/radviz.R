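#' Circular anchor layouts
#'
#' A layout places k >= 2 gene anchors on the unit circle. `"cartesian"` mode
#' requires exactly four genes and puts them on the coordinate axes at 0, 90,
#' 180 and 270 degrees in listed order; `"equal_spacing"` distributes k genes
#' uniformly starting from `phase` (for three genes the default phase puts
#' anchors at 90, 210 and 330 degrees, the "arm" arrangement).
#'
#' @param genes Ordered character vector of gene symbols (k >= 2, unique).
#' @param mode `"equal_spacing"` or `"cartesian"`.
#' @param phase Rotation offset in radians for `equal_spacing`; default
#'   `pi/2` for k = 3, else 0.
#' @return An `anchor_layout`: list with `genes`, `angles` (radians in
#'   `[0, 2*pi)`), `mode`.
#' @examples
#' anchor_layout(c("TMEM182", "MCM9", "LRRFIP1", "LAMP1"), mode = "cartesian")
#' @export
anchor_layout <- function(genes, mode = c("equal_spacing", "cartesian"),
                          phase = NULL) {
  mode <- match.arg(mode)
  genes <- as.character(genes)
  k <- length(genes)
  if (k < 2L) stop("a layout needs at least two genes", call. = FALSE)
  if (anyDuplicated(genes)) stop("layout genes must be unique", call. = FALSE)
  if (mode == "cartesian") {
    if (k != 4L) stop("cartesian layouts require exactly 4 genes", call. = FALSE)
    angles <- c(0, pi / 2, pi, 3 * pi / 2)
  } else {
    if (is.null(phase)) phase <- if (k == 3L) pi / 2 else 0
    angles <- (2 * pi * (seq_len(k) - 1L) / k + phase) %% (2 * pi)
  }
  structure(list(genes = genes, angles = angles, mode = mode),
            class = "anchor_layout")
}

#' @export
print.anchor_layout <- function(x, ...) {
  cat("<anchor_layout> ", x$mode, "\n", sep = "")
  cat(paste0("  ", x$genes, " @ ", round(x$angles * 180 / pi, 1), "°",
             collapse = "\n"), "\n")
  invisible(x)
}

anchor_positions <- function(layout) {
  cbind(x = cos(layout$angles), y = sin(layout$angles))
}

#' Fit per-gene min-max normalization bounds
#'
#' Learns per-gene `(min, max)` bounds on a reference cohort. The bounds are
#' frozen: projections of new samples reuse them (values outside the training
#' range are clipped), which makes cascade predictions deterministic and
#' single-sample capable. A constant gene gets bounds `(v, v)` and
#' normalizes to weight 0.5 downstream.
#'
#' @param data Expression cohort tibble with >= 2 samples.
#' @param genes Genes to cover (default: all gene columns).
#' @return A `radviz_norm` tibble with columns `gene`, `min`, `max`.
#' @export
fit_normalization <- function(data, genes = cohort_genes(data)) {
  data <- as_cohort(data)
  check_genes_present(data, genes)
  if (nrow(data) < 2L) stop("need at least 2 samples to fit bounds",
                            call. = FALSE)
  m <- cohort_matrix(data)[, genes, drop = FALSE]
  out <- tibble::tibble(gene = genes,
                        min = unname(apply(m, 2, min)),
                        max = unname(apply(m, 2, max)))
  class(out) <- c("radviz_norm", class(out))
  out
}

# samples x genes matrix of weights in [0, 1]; constant genes -> 0.5
normalized_weights <- function(data, model, genes) {
  m <- cohort_matrix(as_cohort(data))[, genes, drop = FALSE]
  idx <- match(genes, model$gene)
  if (anyNA(idx)) {
    stop("normalization model lacks gene(s): ",
         paste(genes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  lo <- model$min[idx]; hi <- model$max[idx]
  rng <- hi - lo
  u <- sweep(sweep(m, 2, lo), 2, ifelse(rng > 0, rng, 1), "/")
  u <- pmin(pmax(u, 0), 1)
  u[, rng == 0] <- 0.5
  u
}

#' Project samples onto a radial layout
#'
#' Places each sample at the spring-force equilibrium of its normalized
#' attribute weights: with weights \eqn{u_i \in [0,1]} and anchor positions
#' \eqn{A_i} on the unit circle, the point is the weighted barycentre
#' \deqn{p = \sum_i u_i A_i / \sum_i u_i,}
#' the unique zero of the spring-force sum \eqn{\sum_i u_i (A_i - p)} when
#' each attribute pulls the point toward its anchor with stiffness
#' proportional to its value (Hooke's law analogy). A sample with all-zero
#' weights sits at the origin.
#'
#' @param data Expression cohort tibble containing the layout genes.
#' @param model A `radviz_norm` from [fit_normalization()] covering the
#'   layout genes.
#' @param layout An [anchor_layout()].
#' @return A `radviz_projection` tibble: `sample_id`, `label`, `x`, `y`,
#'   with the layout attached as attribute `"layout"`.
#' @export
project <- function(data, model, layout) {
  data <- as_cohort(data)
  check_genes_present(data, layout$genes)
  u <- normalized_weights(data, model, layout$genes)
  pts <- equilibrium_points(u, layout)
  out <- tibble::tibble(sample_id = data$sample_id, label = data$label,
                        x = unname(pts[, 1]), y = unname(pts[, 2]))
  attr(out, "layout") <- layout
  class(out) <- c("radviz_projection", class(out))
  out
}

equilibrium_points <- function(u, layout) {
  A <- anchor_positions(layout)
  tot <- rowSums(u)
  p <- (u %*% A)
  nz <- tot > 0
  p[nz, ] <- p[nz, , drop = FALSE] / tot[nz]
  p[!nz, ] <- 0
  colnames(p) <- c("x", "y")
  p
}

#' Numeric spring-equilibrium oracle
#'
#' Independently locates a sample's position by numerically minimizing the
#' total spring energy \eqn{\tfrac12 \sum_i u_i \lVert A_i - p \rVert^2}
#' (BFGS with analytic gradient). Exists as a cross-check for [project()]
#' and is not used by it.
#'
#' @param weights Non-negative numeric weights, one per layout gene; must not
#'   all be zero.
#' @param layout An [anchor_layout()].
#' @return Length-2 numeric `(x, y)`.
#' @export
spring_oracle <- function(weights, layout) {
  if (length(weights) != length(layout$genes)) {
    stop("one weight per layout gene required", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(weights) == 0) stop("all-zero weights have no equilibrium",
                              call. = FALSE)
  A <- anchor_positions(layout)
  energy <- function(p) {
    0.5 * sum(weights * ((A[, 1] - p[1])^2 + (A[, 2] - p[2])^2))
  }
  grad <- function(p) {
    c(-sum(weights * (A[, 1] - p[1])), -sum(weights * (A[, 2] - p[2])))
  }
  fit <- stats::optim(c(0, 0), energy, grad, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 500))
  stats::setNames(fit$par, c("x", "y"))
}

#' Sector regions between adjacent anchors
#'
#' A region is the closed angular sector spanned by two anchors adjacent in
#' the layout (the arc between them containing no other anchor — the
#' "quarter" of a four-anchor layout or "arm" of a three-anchor one),
#' excluding a small disc of radius `r_min` around the origin where samples
#' are maximally ambiguous.
#'
#' @param anchor_a,anchor_b Gene names of the bounding anchors.
#' @param r_min Minimum radius in `[0, 1)`; default 0.05.
#' @return A `sector_region` list.
#' @export
sector_region <- function(anchor_a, anchor_b, r_min = 0.05) {
  if (r_min < 0 || r_min >= 1) stop("r_min must lie in [0, 1)", call. = FALSE)
  structure(list(anchor_a = anchor_a, anchor_b = anchor_b, r_min = r_min),
            class = "sector_region")
}

# closed arc [from, to] going counter-clockwise that contains no other anchor;
# returns c(start, width) with width in (0, 2*pi)
region_arc <- function(region, layout) {
  ia <- match(region$anchor_a, layout$genes)
  ib <- match(region$anchor_b, layout$genes)
  if (is.na(ia) || is.na(ib)) {
    stop("region anchors ", region$anchor_a, "/", region$anchor_b,
         " not in layout", call. = FALSE)
  }
  ta <- layout$angles[ia]; tb <- layout$angles[ib]
  others <- layout$angles[-c(ia, ib)]
  ccw <- (tb - ta) %% (2 * pi)   # width going a -> b counter-clockwise
  inside_ccw <- any(((others - ta) %% (2 * pi)) < ccw &
                    ((others - ta) %% (2 * pi)) > 0)
  if (!inside_ccw) return(c(start = ta, width = ccw))
  cw <- (ta - tb) %% (2 * pi)
  inside_cw <- any(((others - tb) %% (2 * pi)) < cw &
                   ((others - tb) %% (2 * pi)) > 0)
  if (!inside_cw) return(c(start = tb, width = cw))
  stop("anchors ", region$anchor_a, " and ", region$anchor_b,
       " are not adjacent in the layout", call. = FALSE)
}

#' Test points for sector membership
#'
#' A point belongs to a region when its polar angle lies in the closed arc
#' between the region's anchors and its radius is at least `r_min`. Points on
#' an anchor ray belong to both sectors bordered by that anchor (closed
#' arcs); the origin belongs to no region when `r_min > 0`.
#'
#' @param points A two-column matrix/data frame of `(x, y)` or a
#'   `radviz_projection`.
#' @param region A [sector_region()].
#' @param layout An [anchor_layout()]; defaults to the projection's own.
#' @return Logical vector.
#' @export
in_region <- function(points, region, layout = attr(points, "layout")) {
  if (is.null(layout)) stop("layout required", call. = FALSE)
  if (is.data.frame(points)) {
    pts <- cbind(points$x, points$y)
  } else {
    pts <- matrix(points, ncol = 2L)
  }
  arc <- region_arc(region, layout)
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  theta <- atan2(pts[, 2], pts[, 1]) %% (2 * pi)
  rel <- (theta - arc[["start"]]) %% (2 * pi)
  eps <- 1e-12
  in_arc <- rel <= arc[["width"]] + eps | rel >= 2 * pi - eps
  in_arc & r >= region$r_min
}
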