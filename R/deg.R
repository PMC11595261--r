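#' Moderated two-group t-statistics
#'
#' Per-gene comparison of resistant versus sensitive samples. The effect is
#' the difference of group means (`mean_diff = mean(resistant) -
#' mean(sensitive)`, in the units of the input). The per-gene residual
#' variance is the pooled two-sample variance on `d = n1 + n2 - 2` degrees of
#' freedom; with `moderation = "empirical_bayes"` it is shrunk toward a prior
#' variance `s0_sq` on `d0` prior degrees of freedom,
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d),}
#' with `(d0, s0_sq)` estimated by moment matching of `log s^2` across genes
#' (the classical empirical-Bayes estimator for gene-wise variances). The
#' moderated statistic `t_mod = mean_diff / (s_tilde * sqrt(1/n1 + 1/n2))` is
#' referred to a t distribution on `d0 + d` degrees of freedom (`d` when
#' moderation is disabled). Two-sided p-values are Benjamini-Hochberg
#' adjusted.
#'
#' A gene with zero pooled variance and zero mean difference gets
#' `t_mod = 0, p_raw = 1` (an uninformative, not an erroneous, gene).
#'
#' @param data Expression cohort tibble with at least two samples labeled
#'   `resistant` and two labeled `sensitive`; `unknown` samples are ignored.
#' @param moderation `"empirical_bayes"` (default) or `"none"`.
#' @return A tibble with one row per gene: `gene`, `mean_diff`, `t_mod`,
#'   `p_raw`, `p_adj`, `direction` (`"up"` when `mean_diff > 0` else
#'   `"down"`). The fitted shrinkage hyperparameters are attached as
#'   attribute `"moderation"` (a list with `d0`, `s0_sq`, `df_resid`).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_sensitive = 10, n_resistant = 10,
#'                                    seed = 1))
#' head(moderated_t(coh))
#' @export
moderated_t <- function(data, moderation = c("empirical_bayes", "none")) {
  moderation <- match.arg(moderation)
  data <- as_cohort(data)
  m <- cohort_matrix(data)
  res <- data$label == "resistant"
  sen <- data$label == "sensitive"
  n1 <- sum(res); n2 <- sum(sen)
  if (n1 < 2L || n2 < 2L) {
    stop("need at least 2 samples per group (resistant: ", n1,
         ", sensitive: ", n2, ")", call. = FALSE)
  }
  mr <- colMeans(m[res, , drop = FALSE])
  ms <- colMeans(m[sen, , drop = FALSE])
  mean_diff <- mr - ms
  d <- n1 + n2 - 2L
  ss <- (colSums(sweep(m[res, , drop = FALSE], 2, mr)^2) +
         colSums(sweep(m[sen, , drop = FALSE], 2, ms)^2))
  s2 <- ss / d

  if (moderation == "empirical_bayes") {
    mp <- moment_match_variances(s2, d)
    d0 <- mp$d0; s0_sq <- mp$s0_sq
    if (is.finite(d0)) {
      s2_post <- (d0 * s0_sq + d * s2) / (d0 + d)
    } else {
      s2_post <- rep(s0_sq, length(s2))
    }
    df_total <- d0 + d
  } else {
    mp <- list(d0 = 0, s0_sq = NA_real_)
    s2_post <- s2
    df_total <- d
  }

  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, mean_diff / se, ifelse(mean_diff == 0, 0, Inf * sign(mean_diff)))
  p_raw <- if (is.finite(df_total)) {
    2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  } else {
    2 * stats::pnorm(abs(t_mod), lower.tail = FALSE)
  }
  p_raw[se == 0 & mean_diff == 0] <- 1

  out <- tibble::tibble(
    gene = colnames(m),
    mean_diff = unname(mean_diff),
    t_mod = unname(t_mod),
    p_raw = unname(p_raw),
    p_adj = bh_adjust(unname(p_raw)),
    direction = ifelse(mean_diff > 0, "up", "down")
  )
  attr(out, "moderation") <- list(d0 = mp$d0, s0_sq = mp$s0_sq, df_resid = d)
  out
}

# Moment matching of (d0, s0_sq) from gene-wise variances s2 on d df:
# z = log(s2) has E z = log(s0_sq) + digamma(d/2) - log(d/2)
#                       - digamma(d0/2) + log(d0/2)
# and Var z = trigamma(d/2) + trigamma(d0/2). Solve the variance equation for
# d0 by inverting the trigamma function, then back out s0_sq. Excess sample
# variance at or below trigamma(d/2) means no detectable gene-to-gene
# variance heterogeneity: d0 = Inf and every gene shares s0_sq.
moment_match_variances <- function(s2, d) {
  ok <- s2 > 0
  if (sum(ok) < 2L) {
    return(list(d0 = Inf, s0_sq = if (any(ok)) mean(s2[ok]) else mean(s2)))
  }
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  n <- length(e)
  excess <- mean((e - ebar)^2) * n / (n - 1) - trigamma(d / 2)
  if (excess <= 0) {
    # no gene-to-gene variance heterogeneity beyond sampling noise: every
    # gene shares the common variance, estimated by the average s^2
    d0 <- Inf
    s0_sq <- mean(s2[ok])
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton inversion of trigamma on (0, Inf); monotone decreasing target.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values. Thin wrapper
#' around [stats::p.adjust()] that validates the input range.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) && (any(!is.finite(p_values)) ||
                           any(p_values < 0 | p_values > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Primary DEG filter
#'
#' Splits a differential-expression table into up- and downregulated gene
#' sets at the primary thresholds: raw p-value strictly below `p_max` and
#' moderated t strictly above `t_min` (up) or strictly below `-t_min` (down).
#' Blank or missing gene symbols are excluded.
#'
#' @param table A tibble from [moderated_t()].
#' @param p_max Raw p-value threshold (default 0.05, strict).
#' @param t_min Moderated-t magnitude threshold (default 2, strict).
#' @return A list with character vectors `up` and `down`.
#' @export
primary_filter <- function(table, p_max = 0.05, t_min = 2) {
  named <- !is.na(table$gene) & nzchar(table$gene)
  list(
    up = table$gene[named & table$p_raw < p_max & table$t_mod > t_min],
    down = table$gene[named & table$p_raw < p_max & table$t_mod < -t_min]
  )
}

#' Core marker genes shared by three cohorts
#'
#' Triple intersection of the per-cohort up- and downregulated DEG sets; the
#' genes dysregulated in the same direction in every cohort.
#'
#' @param up_sets,down_sets Lists of three character vectors each.
#' @return List with `core_up` and `core_down`.
#' @export
venn_core <- function(up_sets, down_sets) {
  stopifnot(length(up_sets) == 3L, length(down_sets) == 3L)
  list(core_up = Reduce(intersect, up_sets),
       core_down = Reduce(intersect, down_sets))
}

#' Marker panels
#'
#' An ordered set of upregulated and downregulated marker genes (up in
#' treatment-resistant samples means elevated relative to sensitive ones).
#'
#' @param up,down Character vectors of gene symbols; disjoint, no duplicates.
#' @return An object of class `marker_panel`.
#' @export
marker_panel <- function(up = character(), down = character()) {
  up <- as.character(up); down <- as.character(down)
  if (anyDuplicated(up) || anyDuplicated(down)) {
    stop("panel gene lists must not contain duplicates", call. = FALSE)
  }
  if (length(intersect(up, down))) {
    stop("up and down panels overlap: ",
         paste(intersect(up, down), collapse = ", "), call. = FALSE)
  }
  structure(list(up = up, down = down), class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", length(x$up), " up, ", length(x$down), " down\n",
      sep = "")
  if (length(x$up)) cat("  up:   ", paste(x$up, collapse = ", "), "\n", sep = "")
  if (length(x$down)) cat("  down: ", paste(x$down, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extended two-stage marker selection across three cohorts
#'
#' A gene becomes a candidate if it passes the primary filter
#' ([primary_filter()]) in the same direction in at least two of the three
#' cohorts. A candidate is then excluded if, in each remaining cohort, any of
#' the following holds: the mean difference has the opposite sign, the
#' moderated t magnitude is below `t_secondary`, or the raw p-value is at or
#' above `p_secondary` — i.e. survivors must show at least acceptable,
#' same-direction evidence in the cohort where they missed the primary cut.
#' Genes in the triple-intersection core ([venn_core()]) are always included.
#'
#' @param tables List of three DEG tibbles (from [moderated_t()]) over a
#'   shared gene universe; genes absent from any table are ineligible.
#' @param p_max,t_min Primary thresholds, see [primary_filter()].
#' @param t_secondary Secondary t magnitude floor (default 1, strict).
#' @param p_secondary Secondary "acceptable significance" ceiling
#'   (default 0.075, strict).
#' @return A [marker_panel()]; gene order follows the first table.
#' @export
extended_marker_selection <- function(tables, p_max = 0.05, t_min = 2,
                                      t_secondary = 1, p_secondary = 0.075) {
  stopifnot(length(tables) == 3L)
  universes <- lapply(tables, function(t) t$gene)
  shared <- Reduce(intersect, universes)
  if (!length(shared)) {
    stop("the three DEG tables share no genes; cannot cross-reference cohorts",
         call. = FALSE)
  }
  filt <- lapply(tables, primary_filter, p_max = p_max, t_min = t_min)
  core <- venn_core(lapply(filt, `[[`, "up"), lapply(filt, `[[`, "down"))

  rows <- lapply(tables, function(t) {
    t <- t[!is.na(t$gene) & nzchar(t$gene), ]
    stats::setNames(seq_len(nrow(t)), t$gene)
  })
  keep_up <- character(); keep_down <- character()
  for (g in shared) {
    in_up <- vapply(filt, function(f) g %in% f$up, logical(1))
    in_down <- vapply(filt, function(f) g %in% f$down, logical(1))
    dir <- if (sum(in_up) >= 2L) "up" else if (sum(in_down) >= 2L) "down" else next
    hits <- if (dir == "up") in_up else in_down
    sgn <- if (dir == "up") 1 else -1
    ok <- TRUE
    for (i in which(!hits)) {
      row <- tables[[i]][rows[[i]][[g]], ]
      if (sign(row$mean_diff) != sgn || abs(row$t_mod) < t_secondary ||
          row$p_raw >= p_secondary) {
        ok <- FALSE
        break
      }
    }
    if (g %in% core$core_up) { keep_up <- c(keep_up, g); next }
    if (g %in% core$core_down) { keep_down <- c(keep_down, g); next }
    if (ok && dir == "up") keep_up <- c(keep_up, g)
    if (ok && dir == "down") keep_down <- c(keep_down, g)
  }
  order_by_first <- function(genes) genes[order(match(genes, universes[[1L]]))]
  marker_panel(up = order_by_first(unique(keep_up)),
               down = order_by_first(unique(keep_down)))
}

#' Pearson correlation matrix over a marker panel
#'
#' Pairwise Pearson correlations of panel-gene expression across samples,
#' with two-sided p-values from the t transform `t = r sqrt((n-2)/(1-r^2))`
#' on `n - 2` degrees of freedom and significance tiers
#' `*` p < 0.05, `**` p < 0.005, `***` p < 0.001.
#'
#' @param data Expression cohort tibble with at least 3 samples.
#' @param panel A [marker_panel()]; all panel genes must be present.
#' @return List with matrices `r`, `p` and character matrix `stars`
#'   (`""`, `"*"`, `"**"`, `"***"`), genes ordered up panel then down panel.
#'   Zero-variance genes yield `NA` entries with a warning.
#' @export
correlation_matrix <- function(data, panel) {
  data <- as_cohort(data)
  genes <- c(panel$up, panel$down)
  check_genes_present(data, genes)
  n <- nrow(data)
  if (n < 3L) stop("need at least 3 samples for correlation p-values",
                   call. = FALSE)
  m <- cohort_matrix(data)[, genes, drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance gene(s), correlations reported as NA: ",
            paste(genes[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(m))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r)[sds > 0] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[is.infinite(tstat)] <- 0
  diag(p)[sds > 0] <- 0
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.005] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  stars[is.na(p)] <- NA_character_
  list(r = r, p = p, stars = stars)
}
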