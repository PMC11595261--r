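# direct-formula pooled two-sample t, written independently of moderated_t
pooled_t_oracle <- function(x_res, x_sen) {
  n1 <- nrow(x_res); n2 <- nrow(x_sen)
  md <- colMeans(x_res) - colMeans(x_sen)
  sp2 <- (colSums(sweep(x_res, 2, colMeans(x_res))^2) +
          colSums(sweep(x_sen, 2, colMeans(x_sen))^2)) / (n1 + n2 - 2)
  tt <- md / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * pt(-abs(tt), df = n1 + n2 - 2))
}

test_that("without moderation the statistic equals the classical pooled t", {
  set.seed(91)
  n_gene <- 50
  coh <- weights_cohort(matrix(rnorm(10 * n_gene, mean = 8), nrow = 10),
                        sprintf("g%02d", 1:n_gene),
                        labels = rep(c("resistant", "sensitive"), each = 5))
  tab <- moderated_t(coh, moderation = "none")
  m <- cohort_matrix(coh)
  orc <- pooled_t_oracle(m[1:5, ], m[6:10, ])
  expect_lt(max(abs(tab$t_mod - orc$t)), 1e-10)
  expect_lt(max(abs(tab$p_raw - orc$p)), 1e-12)
  expect_equal(tab$direction, ifelse(tab$mean_diff > 0, "up", "down"))
})

test_that("degenerate genes give t = 0, p = 1 instead of errors", {
  coh <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    label = rep(c("resistant", "sensitive"), each = 3),
    same = rep(5, 6),                    # zero variance, zero difference
    flat = c(2, 2, 2, 2, 2, 2) + c(0, 0, 0, 1, 1, 1) * 0  # identical groups
  )
  for (mod in c("none", "empirical_bayes")) {
    tab <- moderated_t(coh, moderation = mod)
    expect_equal(tab$t_mod, c(0, 0))
    expect_equal(tab$p_raw, c(1, 1))
  }
  expect_error(moderated_t(coh[c(1, 4, 5), ]), "at least 2 samples")
})

test_that("empirical Bayes hyperparameters match an independent moment-matching fit", {
  # heterogeneous per-gene variances so d0 is finite
  set.seed(17)
  n_gene <- 200; n1 <- 4; n2 <- 4
  sd_g <- sqrt(1 / rgamma(n_gene, shape = 4, rate = 4))  # chi-square mixing
  m <- sapply(sd_g, function(s) rnorm(n1 + n2, sd = s))
  coh <- weights_cohort(m, sprintf("g%03d", 1:n_gene),
                        labels = rep(c("resistant", "sensitive"), each = 4))
  tab <- moderated_t(coh)
  got <- attr(tab, "moderation")

  # independent estimator: solve the log-variance moment equations directly
  d <- n1 + n2 - 2
  mm <- cohort_matrix(coh)
  s2 <- (colSums(sweep(mm[1:4, ], 2, colMeans(mm[1:4, ]))^2) +
         colSums(sweep(mm[5:8, ], 2, colMeans(mm[5:8, ]))^2)) / d
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  excess <- var(e) - trigamma(d / 2)
  expect_gt(excess, 0)
  d0_orc <- 2 * uniroot(function(y) trigamma(y) - excess, c(1e-3, 1e3),
                        tol = 1e-12)$root
  s0_orc <- exp(mean(e) + digamma(d0_orc / 2) - log(d0_orc / 2))
  expect_equal(got$d0, d0_orc, tolerance = 1e-6)
  expect_equal(got$s0_sq, s0_orc, tolerance = 1e-6)

  # shrunken statistic follows from the definition
  s2_post <- (got$d0 * got$s0_sq + d * s2) / (got$d0 + d)
  t_orc <- (colMeans(mm[1:4, ]) - colMeans(mm[5:8, ])) /
    sqrt(s2_post * (1 / 4 + 1 / 4))
  expect_lt(max(abs(tab$t_mod - t_orc)), 1e-8)
})

test_that("empirical Bayes moderation agrees with the limma cross-check", {
  skip_if_not_installed("limma")
  set.seed(23)
  spec <- cohort_spec(n_sensitive = 8, n_resistant = 8, n_background = 150,
                      panel = small_panel(), seed = 23)
  coh <- generate_cohort(spec)
  tab <- moderated_t(coh)
  m <- t(cohort_matrix(coh))
  design <- cbind(1, coh$label == "resistant")
  fit <- limma::eBayes(limma::lmFit(m, design))
  idx <- match(tab$gene, rownames(fit$t))
  expect_equal(attr(tab, "moderation")$d0, fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(tab, "moderation")$s0_sq, fit$s2.prior, tolerance = 1e-4)
  expect_lt(max(abs(tab$t_mod - fit$t[idx, 2])), 1e-6)
  # p-value conventions differ only when d0 is infinite (normal reference
  # here vs limma's capped pooled df), so agreement is near-exact
  expect_lt(max(abs(tab$p_raw - fit$p.value[idx, 2])), 5e-4)
})

test_that("shrinkage limits: d0 = 0 is the classical t, d0 = Inf pins s0^2", {
  # identical within-group spreads across genes -> zero excess variance of
  # log s^2 -> the moment estimator returns d0 = Inf and every gene is
  # referred to the common prior variance
  base <- c(-1.2, 0.3, 0.9, -0.7, 1.1, -0.4, 0.2, -0.2)
  m <- outer(base, rep(1, 12)) + matrix(rep(seq(0, 2.2, by = 0.2), each = 8),
                                        nrow = 8)
  coh <- weights_cohort(m, sprintf("g%02d", 1:12),
                        labels = rep(c("resistant", "sensitive"), each = 4))
  eb <- moderated_t(coh)
  mod <- attr(eb, "moderation")
  expect_identical(mod$d0, Inf)
  t_expect <- eb$mean_diff / sqrt(mod$s0_sq * (1 / 4 + 1 / 4))
  expect_lt(max(abs(eb$t_mod - t_expect)), 1e-10)
  # and p-values come from the normal limit
  expect_lt(max(abs(eb$p_raw - 2 * pnorm(-abs(t_expect)))), 1e-12)
})

test_that("BH adjustment reproduces the hand-executed step-up procedure", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.2, -0.1)), "\\[0, 1\\]")

  set.seed(6)
  p <- runif(60)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p) && all(adj <= 1))
  perm <- sample(60)
  expect_equal(bh_adjust(p[perm]), adj[perm])     # permutation invariance
  expect_true(all(bh_adjust(adj) >= adj))         # re-adjusting never decreases
})

test_that("primary filter applies strict thresholds and drops blank symbols", {
  tab <- tibble::tibble(
    gene = c("A", "B", "C", "D", "E", ""),
    mean_diff = c(1, -1, 1, -1, 1, 1),
    t_mod = c(2.5, -2.5, 2.0, -1.9, 3.0, 4.0),
    p_raw = c(0.01, 0.02, 0.01, 0.01, 0.05, 0.001),
    p_adj = 1, direction = "up"
  )
  f <- primary_filter(tab)
  expect_identical(f$up, "A")        # C excluded at t = 2 exactly; E at p = 0.05
  expect_identical(f$down, "B")      # D excluded at |t| < 2
})

test_that("triple-intersection core matches brute-force set arithmetic", {
  expect_equal(venn_core(list(c("A", "B", "C"), c("B", "C"), c("B", "D")),
                         list("X", "Y", "Z")),
               list(core_up = "B", core_down = character()))
  set.seed(12)
  universe <- sprintf("G%03d", 1:100)
  ups <- lapply(1:3, function(i) sample(universe, 40))
  downs <- lapply(1:3, function(i) sample(universe, 40))
  core <- venn_core(ups, downs)
  brute_up <- universe[vapply(universe, function(g)
    all(vapply(ups, function(s) g %in% s, logical(1))), logical(1))]
  expect_setequal(core$core_up, brute_up)
})

test_that("correlation matrix matches the direct covariance formula", {
  set.seed(31)
  pan <- marker_panel(up = c("A", "B", "C"), down = c("D", "E"))
  m <- matrix(rnorm(50), nrow = 10)
  coh <- weights_cohort(m, c("A", "B", "C", "D", "E"))
  cm <- correlation_matrix(coh, pan)
  n <- 10
  for (i in 1:5) for (j in 1:5) {
    xi <- m[, i] - mean(m[, i]); xj <- m[, j] - mean(m[, j])
    r_direct <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    expect_lt(abs(cm$r[i, j] - r_direct), 1e-12)
  }
  expect_equal(unname(diag(cm$r)), rep(1, 5))
  # p-values agree with cor.test and star tiers follow the thresholds
  ct <- cor.test(m[, 1], m[, 2])
  expect_equal(cm$p[1, 2], ct$p.value, tolerance = 1e-12)
  expect_true(all(cm$stars[!is.na(cm$p) & cm$p < 0.001] == "***"))
  expect_true(all(cm$stars[!is.na(cm$p) & cm$p >= 0.05] == ""))

  # exact anti-correlation and self-correlation
  coh2 <- weights_cohort(cbind(1:10, -(1:10), rnorm(10), rnorm(10), rnorm(10)),
                         c("A", "B", "C", "D", "E"))
  cm2 <- correlation_matrix(coh2, pan)
  expect_equal(cm2$r[1, 2], -1)

  # zero-variance gene is NA with warning, not an error
  coh3 <- weights_cohort(cbind(1:10, rep(1, 10), rnorm(10), rnorm(10),
                               rnorm(10)),
                         c("A", "B", "C", "D", "E"))
  expect_warning(cm3 <- correlation_matrix(coh3, pan), "zero-variance")
  expect_true(all(is.na(cm3$r["B", ])))
})
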