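# reference cohort with bounds [0, 1] on every cascade gene, so test samples
# can be written directly as normalized weights
bounds_reference <- function(genes) {
  weights_cohort(rbind(rep(0, length(genes)), rep(1, length(genes))), genes)
}

folfox_sample <- function(genes, loadings, label = "unknown") {
  w <- stats::setNames(rep(0, length(genes)), genes)
  w[names(loadings)] <- loadings
  weights_cohort(rbind(w), genes, labels = label)
}

test_that("the published cascade has the four documented steps", {
  cas <- published_folfox_cascade()
  expect_equal(n_steps(cas), 4L)
  expect_setequal(cas$steps[[1]]$layout$genes,
                  c("TMEM182", "MCM9", "LRRFIP1", "LAMP1"))
  expect_identical(cas$steps[[1]]$layout$mode, "cartesian")
  expect_identical(names(cas$steps[[1]]$regions), "sensitive")
  expect_identical(cas$steps[[2]]$layout$genes,
                   c("FAM161A", "KLHL36", "ETV5"))
  expect_identical(names(cas$steps[[2]]$regions), "resistant")
  expect_setequal(cas$steps[[3]]$layout$genes,
                  c("RNF168", "SRSF11", "NCKAP5", "CRTAP"))
  # final step: two labeled regions sharing the RIMBP2 anchor
  s4 <- cas$steps[[4]]
  expect_setequal(names(s4$regions), c("sensitive", "resistant"))
  shared <- intersect(c(s4$regions$sensitive$anchor_a,
                        s4$regions$sensitive$anchor_b),
                      c(s4$regions$resistant$anchor_a,
                        s4$regions$resistant$anchor_b))
  expect_identical(shared, "RIMBP2")
})

test_that("a sample loading only on LAMP1 and LRRFIP1 is called sensitive at step 1", {
  genes <- cascade_genes(published_folfox_cascade())
  cas <- fit_cascade_normalization(bounds_reference(genes),
                                   published_folfox_cascade())
  smp <- folfox_sample(genes, c(LAMP1 = 0.8, LRRFIP1 = 0.6))
  # the point must lie inside the LAMP1-LRRFIP1 sector per in_region itself
  s1 <- cas$steps[[1]]
  pr <- project(smp, s1$normalization, s1$layout)
  expect_true(in_region(pr, s1$regions$sensitive, s1$layout))
  res <- apply_cascade(smp, cas)
  expect_identical(res$call, "sensitive")
  expect_identical(res$decided_at_step, 1L)
})

test_that("an empty cohort yields an empty result", {
  genes <- cascade_genes(published_folfox_cascade())
  cas <- fit_cascade_normalization(bounds_reference(genes),
                                   published_folfox_cascade())
  res <- apply_cascade(bounds_reference(genes)[0, ], cas)
  expect_equal(nrow(res), 0L)
  expect_named(res, c("sample_id", "true_label", "call", "decided_at_step"))
})

test_that("missing cascade genes are reported with gene and step", {
  spec <- cohort_spec(n_sensitive = 3, n_resistant = 3, n_background = 0,
                      panel = marker_panel(up = c("TMEM182", "MCM9"),
                                           down = c("LRRFIP1", "LAMP1")),
                      seed = 2)
  coh <- generate_cohort(spec)  # lacks RIMBP2 and the rest
  expect_error(apply_cascade(coh, published_folfox_cascade()),
               "step 2.*FAM161A")
})

test_that("calls partition every fuzzed cohort", {
  genes <- cascade_genes(published_folfox_cascade())
  cas <- fit_cascade_normalization(bounds_reference(genes),
                                   published_folfox_cascade())
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(0:40, 1)
    coh <- weights_cohort(matrix(runif(n * length(genes)), ncol = length(genes)),
                          genes,
                          labels = sample(c("sensitive", "resistant"), max(n, 1),
                                          replace = TRUE)[seq_len(n)])
    res <- apply_cascade(coh, cas)
    expect_equal(sum(res$call == "sensitive") + sum(res$call == "resistant") +
                 sum(res$call == "undetermined"), n)
    expect_identical(res$sample_id, coh$sample_id)  # order preserved
    expect_identical(is.na(res$decided_at_step), res$call == "undetermined")
  }
})

test_that("early calls are invariant to edits of later steps", {
  genes <- cascade_genes(published_folfox_cascade())
  ref <- bounds_reference(genes)
  cas <- fit_cascade_normalization(ref, published_folfox_cascade())
  set.seed(21)
  coh <- weights_cohort(matrix(runif(30 * length(genes)), ncol = length(genes)),
                        genes, labels = "sensitive")
  full <- apply_cascade(coh, cas)
  for (k in 1:3) {
    trunc <- new_cascade(cas$steps[seq_len(k)])
    res_k <- apply_cascade(coh, trunc)
    decided_early <- !is.na(full$decided_at_step) & full$decided_at_step <= k
    expect_identical(res_k$call[decided_early], full$call[decided_early])
    expect_identical(res_k$decided_at_step[decided_early],
                     full$decided_at_step[decided_early])
  }
  # swapping the final step for a different rule leaves steps 1-3 alone
  alt <- cas
  alt$steps[[4]] <- elimination_step(
    alt$steps[[4]]$layout,
    sector_region("ZBTB49", "VAMP2", 0.05), eliminate = "resistant",
    normalization = alt$steps[[4]]$normalization)
  res_alt <- apply_cascade(coh, alt)
  early <- !is.na(full$decided_at_step) & full$decided_at_step <= 3
  expect_identical(res_alt$call[early], full$call[early])
})

test_that("with frozen bounds, cohort concatenation equals per-cohort results", {
  genes <- cascade_genes(published_folfox_cascade())
  cas <- fit_cascade_normalization(bounds_reference(genes),
                                   published_folfox_cascade())
  set.seed(31)
  a <- weights_cohort(matrix(runif(10 * length(genes)), ncol = length(genes)),
                      genes)
  b <- weights_cohort(matrix(runif(15 * length(genes)), ncol = length(genes)),
                      genes)
  b$sample_id <- paste0("b", b$sample_id)
  both <- dplyr::bind_rows(a, b)
  res_both <- apply_cascade(both, cas)
  res_sep <- dplyr::bind_rows(apply_cascade(a, cas), apply_cascade(b, cas))
  expect_identical(res_both, res_sep)
})

test_that("unfitted cascades refuse to run", {
  genes <- cascade_genes(published_folfox_cascade())
  coh <- bounds_reference(genes)
  expect_error(apply_cascade(coh, published_folfox_cascade()),
               "no fitted normalization")
})

test_that("evaluation tallies match a brute-force count", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 40
    truth <- sample(c("sensitive", "resistant"), n, replace = TRUE)
    call <- sample(c("sensitive", "resistant", "undetermined"), n,
                   replace = TRUE)
    res <- tibble::tibble(sample_id = as.character(seq_len(n)),
                          true_label = truth, call = call,
                          decided_at_step = ifelse(call == "undetermined",
                                                   NA_integer_, 1L))
    ev <- evaluate(res)
    for (cl in c("sensitive", "resistant")) {
      sel <- 0; cor <- 0
      for (i in seq_len(n)) {
        if (call[i] == cl) sel <- sel + 1
        if (call[i] == cl && truth[i] == cl) cor <- cor + 1
      }
      row <- ev$per_class[ev$per_class$class == cl, ]
      expect_equal(row$selected, sel)
      expect_equal(row$correct, cor)
      expect_equal(row$percent, if (sel > 0) round(100 * cor / sel) else NA_real_)
    }
    expect_equal(ev$false_sensitive,
                 sum(call == "sensitive" & truth == "resistant"))
    expect_equal(ev$false_resistant,
                 sum(call == "resistant" & truth == "sensitive"))
    expect_equal(ev$undetermined, sum(call == "undetermined"))
    g <- glance(ev)
    expect_equal(g$called + g$undetermined, n)
  }
  expect_error(evaluate(tibble::tibble(sample_id = "x", true_label = "unknown",
                                       call = "sensitive",
                                       decided_at_step = 1L)),
               "known true label")
})

test_that("perfect and single-error evaluations behave per definition", {
  res <- tibble::tibble(
    sample_id = as.character(1:6),
    true_label = rep(c("sensitive", "resistant"), 3),
    call = rep(c("sensitive", "resistant"), 3),
    decided_at_step = 1L)
  ev <- evaluate(res)
  expect_equal(ev$per_class$percent, c(100, 100))
  expect_equal(ev$false_sensitive + ev$false_resistant, 0)
  res$call[2] <- "sensitive"  # one resistant sample miscalled sensitive
  ev2 <- evaluate(res)
  expect_equal(ev2$false_sensitive, 1)
  expect_equal(ev2$per_class$percent[1], round(100 * 3 / 4))
})
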