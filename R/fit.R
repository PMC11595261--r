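# Purity-constrained exhaustive search over (gene subset, circular ordering,
# sector) candidates. Replaces interactive feature suggestion plus hand-drawn
# elimination regions with an objective criterion: a candidate qualifies when
# the fraction of covered samples carrying the target label (purity) and the
# number covered (coverage) both clear their floors on a random training
# split, and again on the full cohort.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# all distinct circular orderings of a gene subset up to rotation+reflection:
# first gene pinned, (k-1)! permutations of the rest, reflections removed.
circular_orderings <- function(genes) {
  k <- length(genes)
  if (k == 2L) return(list(genes))
  rest <- genes[-1L]
  perms <- all_permutations(rest)
  keep <- vapply(perms, function(p) p[1L] <= p[length(p)], logical(1))
  lapply(perms[keep], function(p) c(genes[1L], p))
}

all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (tail in all_permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], tail)
  }
  out
}

step_layout <- function(genes) {
  if (length(genes) == 4L) anchor_layout(genes, "cartesian")
  else anchor_layout(genes)
}

# membership of points in each of the k sectors of a layout (closed arcs,
# radius >= r_min); returns n x k logical matrix, sector j spans anchors
# j -> j+1 counter-clockwise. `widen` inflates each arc by that angle on
# both ends (used for the margin qualification during search).
sector_membership <- function(pts, layout, r_min, widen = 0) {
  k <- length(layout$angles)
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  theta <- atan2(pts[, 2], pts[, 1]) %% (2 * pi)
  eps <- 1e-12
  out <- matrix(FALSE, nrow(pts), k)
  for (j in seq_len(k)) {
    a <- layout$angles[j]
    b <- layout$angles[if (j == k) 1L else j + 1L]
    width <- (b - a) %% (2 * pi)
    rel <- (theta - (a - widen)) %% (2 * pi)
    out[, j] <- (rel <= width + 2 * widen + eps | rel >= 2 * pi - eps) &
      r >= r_min
  }
  out
}

#' Fit one elimination step by exhaustive sector search
#'
#' Draws a stratified random `train_frac` split of each class, enumerates all
#' gene subsets of size `k` from the candidate pool, all distinct circular
#' orderings (rotations/reflections collapsed), and all adjacent-anchor
#' sectors; keeps candidates whose purity (fraction of covered training
#' samples carrying `target_label`) and coverage (count covered) clear
#' `purity_min` / `coverage_min` on the split, re-verifies both on the full
#' cohort, and returns the verified candidate with maximal full-cohort
#' coverage (ties: higher purity, then lexicographically smallest gene
#' ordering). Four-gene layouts use the Cartesian axes; three-gene layouts
#' the equally spaced arm arrangement.
#'
#' @param data Expression cohort with both classes labeled; `unknown`
#'   samples are ignored during scoring.
#' @param candidate_genes Gene pool (all present in `data`); at most
#'   `max_pool` genes, otherwise an error asks for a pre-ranked pool (e.g.
#'   the top genes by `abs(t_mod)`).
#' @param k Anchors per step, 3 or 4.
#' @param target_label Label the step eliminates.
#' @param purity_min,coverage_min Constraint floors (defaults 1.0 and 3: a
#'   step eliminates homogeneous samples only, and at least 3 of them).
#' @param train_frac Fraction of each class in the random training split.
#' @param r_min Sector dead-zone radius.
#' @param seed Integer seed for the split (optional).
#' @param max_pool Combinatorial cap on the pool size.
#' @param margin Angular margin in radians (default 0, no margin): when
#'   positive, a candidate sector must also keep its purity when inflated by
#'   this angle on both ends, so the chosen region does not sit flush
#'   against opposite-class training samples. [fit_cascade()] enables a 10
#'   degree margin by default.
#' @return An [elimination_step()] with normalization fitted on `data`, or
#'   `NULL` when no candidate satisfies the constraints. The winning
#'   candidate's purity/coverage are attached as attribute `"score"`.
#' @export
fit_step <- function(data, candidate_genes, k, target_label,
                     purity_min = 1, coverage_min = 3, train_frac = 0.7,
                     r_min = 0.05, seed = NULL, max_pool = 12L,
                     margin = 0) {
  data <- as_cohort(data)
  stopifnot(k %in% c(3L, 4L), train_frac > 0, train_frac <= 1)
  check_genes_present(data, candidate_genes)
  if (length(candidate_genes) > max_pool) {
    stop("candidate pool has ", length(candidate_genes), " genes (cap ",
         max_pool, "); pre-rank genes (e.g. by abs(t_mod)) and pass the top ",
         max_pool, call. = FALSE)
  }
  if (k > length(candidate_genes)) {
    stop("k = ", k, " exceeds the candidate pool size", call. = FALSE)
  }
  labeled <- data[data$label %in% c("sensitive", "resistant"), ]
  if (!all(c("sensitive", "resistant") %in% labeled$label)) {
    stop("both classes must be present to fit a step", call. = FALSE)
  }
  train <- with_seed(seed, stratified_split(labeled$label, train_frac))
  best <- search_step(labeled, candidate_genes, k, target_label, purity_min,
                      coverage_min, train, r_min, margin)
  if (is.null(best)) return(NULL)
  step <- elimination_step(
    step_layout(best$genes),
    sector_region(best$anchor_a, best$anchor_b, r_min),
    eliminate = target_label,
    normalization = fit_normalization(labeled, best$genes))
  attr(step, "score") <- best[c("purity", "coverage")]
  step
}

stratified_split <- function(labels, frac) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_take <- max(1L, floor(frac * length(idx)))
    train[sample(idx, n_take)] <- TRUE
  }
  train
}

# core enumeration; returns the best qualifying candidate or NULL
search_step <- function(labeled, pool, k, target_label, purity_min,
                        coverage_min, train, r_min, margin = 0) {
  pool <- sort(pool)
  norm <- fit_normalization(labeled, pool)
  U <- normalized_weights(labeled, norm, pool)
  is_target <- labeled$label == target_label
  subsets <- utils::combn(pool, k, simplify = FALSE)
  best <- NULL
  for (sub in subsets) {
    for (genes in circular_orderings(sub)) {
      layout <- step_layout(genes)
      pts <- equilibrium_points(U[, genes, drop = FALSE], layout)
      mem <- sector_membership(pts, layout, r_min)
      mem_w <- if (margin > 0) sector_membership(pts, layout, r_min, margin)
               else mem
      for (j in seq_len(k)) {
        hit_tr <- mem[train, j]
        cov_tr <- sum(hit_tr)
        if (cov_tr < coverage_min) next
        if (mean(is_target[train][hit_tr]) < purity_min) next
        hit <- mem[, j]
        cov <- sum(hit)
        if (cov < coverage_min) next
        pur <- mean(is_target[hit])
        if (pur < purity_min) next
        if (margin > 0 && mean(is_target[mem_w[, j]]) < purity_min) next
        cand <- list(genes = genes,
                     anchor_a = genes[j],
                     anchor_b = genes[if (j == k) 1L else j + 1L],
                     purity = pur, coverage = cov)
        if (is.null(best) || better_candidate(cand, best)) best <- cand
      }
    }
  }
  best
}

better_candidate <- function(a, b) {
  if (a$coverage != b$coverage) return(a$coverage > b$coverage)
  if (a$purity != b$purity) return(a$purity > b$purity)
  # lexicographic gene-ordering tie-break for bit-stable selection
  ka <- paste(c(a$genes, a$anchor_a, a$anchor_b), collapse = "\r")
  kb <- paste(c(b$genes, b$anchor_a, b$anchor_b), collapse = "\r")
  ka < kb
}

# final dual-region step: one shared layout, the same constrained search run
# for each label; layouts eligible only when both labels find a (distinct)
# qualifying sector, scored by combined coverage.
fit_final_step <- function(data, candidate_genes, k, purity_min = 0.8,
                           coverage_min = 3, train_frac = 0.7, r_min = 0.05,
                           seed = NULL, max_pool = 12L, margin = 0) {
  data <- as_cohort(data)
  check_genes_present(data, candidate_genes)
  if (length(candidate_genes) > max_pool) {
    stop("candidate pool has ", length(candidate_genes), " genes (cap ",
         max_pool, ")", call. = FALSE)
  }
  labeled <- data[data$label %in% c("sensitive", "resistant"), ]
  if (!all(c("sensitive", "resistant") %in% labeled$label)) {
    stop("both classes must be present to fit a step", call. = FALSE)
  }
  train <- with_seed(seed, stratified_split(labeled$label, train_frac))
  pool <- sort(candidate_genes)
  norm <- fit_normalization(labeled, pool)
  U <- normalized_weights(labeled, norm, pool)
  subsets <- utils::combn(pool, k, simplify = FALSE)
  best <- NULL
  best_single <- NULL
  for (sub in subsets) {
    for (genes in circular_orderings(sub)) {
      layout <- step_layout(genes)
      pts <- equilibrium_points(U[, genes, drop = FALSE], layout)
      mem <- sector_membership(pts, layout, r_min)
      mem_w <- if (margin > 0) sector_membership(pts, layout, r_min, margin)
               else mem
      per_label <- lapply(c(sensitive = "sensitive", resistant = "resistant"),
        function(lab) {
          is_t <- labeled$label == lab
          bl <- NULL
          for (j in seq_len(k)) {
            hit_tr <- mem[train, j]
            if (sum(hit_tr) < coverage_min) next
            if (mean(is_t[train][hit_tr]) < purity_min) next
            hit <- mem[, j]
            if (sum(hit) < coverage_min) next
            pur <- mean(is_t[hit])
            if (pur < purity_min) next
            if (margin > 0 && mean(is_t[mem_w[, j]]) < purity_min) next
            cand <- list(genes = genes, anchor_a = genes[j],
                         anchor_b = genes[if (j == k) 1L else j + 1L],
                         purity = pur, coverage = sum(hit), sector = j,
                         label = lab)
            if (is.null(bl) || better_candidate(cand, bl)) bl <- cand
          }
          bl
        })
      for (bl in per_label) {
        if (!is.null(bl) &&
            (is.null(best_single) || better_candidate(bl, best_single))) {
          best_single <- bl
        }
      }
      if (is.null(per_label$sensitive) || is.null(per_label$resistant)) next
      if (per_label$sensitive$sector == per_label$resistant$sector) next
      cand <- list(genes = genes,
                   sens = per_label$sensitive, res = per_label$resistant,
                   coverage = per_label$sensitive$coverage +
                              per_label$resistant$coverage,
                   purity = (per_label$sensitive$purity +
                             per_label$resistant$purity) / 2,
                   anchor_a = per_label$sensitive$anchor_a,
                   anchor_b = per_label$sensitive$anchor_b)
      if (is.null(best) || better_candidate(cand, best)) best <- cand
    }
  }
  if (!is.null(best)) {
    step <- elimination_step(
      step_layout(best$genes),
      list(sensitive = sector_region(best$sens$anchor_a, best$sens$anchor_b,
                                     r_min),
           resistant = sector_region(best$res$anchor_a, best$res$anchor_b,
                                     r_min)),
      normalization = fit_normalization(labeled, best$genes))
    attr(step, "score") <- list(sensitive = best$sens[c("purity", "coverage")],
                                resistant = best$res[c("purity", "coverage")])
    return(step)
  }
  # no layout resolves both classes: fall back to the best single labeled
  # region and leave the other class in the mixed remainder
  if (is.null(best_single)) return(NULL)
  step <- elimination_step(
    step_layout(best_single$genes),
    sector_region(best_single$anchor_a, best_single$anchor_b, r_min),
    eliminate = best_single$label,
    normalization = fit_normalization(labeled, best_single$genes))
  attr(step, "score") <- best_single[c("purity", "coverage")]
  step
}

#' Train an eliminative cascade
#'
#' Greedy stage-wise training: for each schedule entry, [fit_step()] is run
#' on the samples not yet eliminated, the covered samples are removed, and
#' training proceeds to the next entry. A schedule entry with target
#' `"final"` fits a dual-region final step (one region per label on a shared
#' layout, purity floor `final_purity_min`) separating sensitive, resistant
#' and mixed samples. A scheduled step that finds no qualifying candidate is
#' skipped with a warning. Per-step normalization bounds are fitted on the
#' samples in play at that step and frozen into the cascade.
#'
#' @param data Labeled expression cohort.
#' @param panel A [marker_panel()] supplying the candidate genes.
#' @param schedule List of `list(k =, target =)` entries, `target` in
#'   `c("sensitive", "resistant", "final")`. The default mirrors the
#'   published four-step design: eliminate sensitive (4 anchors), eliminate
#'   resistant (3), eliminate sensitive (4), then a dual final step (3).
#' When the available panel genes exceed `max_pool`, the pool for each step
#' is reduced to the top `max_pool` genes ranked by `abs(t_mod)` on the
#' samples still in play, stratified by panel direction (up/down in
#' proportion to the panel's composition), so later steps draw the genes
#' most informative for the leftover subpopulation.
#'
#' @param purity_min,coverage_min,train_frac,r_min,max_pool,margin See
#'   [fit_step()].
#' @param final_purity_min Purity floor for the dual final step; lower than
#'   the elimination floor because the final step is allowed to trade purity
#'   for resolving the leftover, harder samples.
#' @param seed Integer; per-step split seeds are derived as `seed + step`.
#' @param allow_reuse Reuse genes across steps (default `FALSE`; each step
#'   draws from the panel genes not yet used).
#' @return A fitted `rv_cascade`.
#' @export
fit_cascade <- function(data, panel,
                        schedule = list(list(k = 4L, target = "sensitive"),
                                        list(k = 3L, target = "resistant"),
                                        list(k = 4L, target = "sensitive"),
                                        list(k = 3L, target = "final")),
                        purity_min = 1, coverage_min = 3,
                        final_purity_min = 0.8, train_frac = 0.7,
                        r_min = 0.05, seed = NULL, allow_reuse = FALSE,
                        max_pool = 12L, margin = 10 * pi / 180) {
  if (!length(schedule)) stop("schedule must be nonempty", call. = FALSE)
  data <- as_cohort(data)
  panel_genes <- c(panel$up, panel$down)
  check_genes_present(data, panel_genes)
  remaining <- data[data$label %in% c("sensitive", "resistant"), ]
  ranking_fallback <- if (length(panel_genes) > max_pool &&
                          min(table(remaining$label)) >= 2L) {
    moderated_t(remaining)
  } else NULL
  used <- character()
  steps <- list()
  for (i in seq_along(schedule)) {
    entry <- schedule[[i]]
    pool <- if (allow_reuse) panel_genes else setdiff(panel_genes, used)
    if (length(pool) > max_pool) {
      pool <- rank_pool(remaining, panel, pool, max_pool, ranking_fallback)
    }
    step_seed <- if (is.null(seed)) NULL else seed + i
    if (length(pool) < entry$k) {
      warning("step ", i, ": candidate pool exhausted, skipping",
              call. = FALSE)
      next
    }
    step <- if (identical(entry$target, "final")) {
      fit_final_step(remaining, pool, entry$k, purity_min = final_purity_min,
                     coverage_min = coverage_min, train_frac = train_frac,
                     r_min = r_min, seed = step_seed, max_pool = max_pool,
                     margin = margin)
    } else {
      fit_step(remaining, pool, entry$k, entry$target,
               purity_min = purity_min, coverage_min = coverage_min,
               train_frac = train_frac, r_min = r_min, seed = step_seed,
               max_pool = max_pool, margin = margin)
    }
    if (is.null(step)) {
      warning("step ", i, " (target ", entry$target,
              "): no candidate met the purity/coverage floors, skipping",
              call. = FALSE)
      next
    }
    steps[[length(steps) + 1L]] <- step
    used <- union(used, step$layout$genes)
    # eliminate the samples this step calls before fitting the next one
    res <- apply_cascade(remaining, new_cascade(list(step)))
    keep <- res$call == "undetermined"
    remaining <- remaining[keep, ]
    if (!all(c("sensitive", "resistant") %in% remaining$label)) break
  }
  if (!length(steps)) stop("no step could be fitted", call. = FALSE)
  new_cascade(steps)
}

# top max_pool pool genes by abs moderated t on the samples in play,
# stratified by panel direction in proportion to the pool's composition;
# falls back to a pre-computed full-cohort table when a class has run out.
rank_pool <- function(remaining, panel, pool, max_pool, fallback) {
  tab <- if (min(table(factor(remaining$label,
                              c("sensitive", "resistant")))) >= 2L) {
    moderated_t(remaining)
  } else {
    fallback
  }
  if (is.null(tab)) return(sort(pool)[seq_len(min(length(pool), max_pool))])
  up <- intersect(pool, panel$up)
  down <- intersect(pool, panel$down)
  n_up <- min(length(up), ceiling(max_pool * length(up) / length(pool)))
  n_down <- min(length(down), max_pool - n_up)
  ord <- tab$gene[order(-abs(tab$t_mod))]
  c(utils::head(intersect(ord, up), n_up),
    utils::head(intersect(ord, down), n_down))
}
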