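#' Specify a synthetic two-class expression cohort
#'
#' Describes a labeled cohort with the statistical structure the eliminative
#' method assumes: a panel of "up" genes elevated in resistant samples and a
#' "down" panel reduced, positive correlation within each panel and negative
#' correlation across panels, optional resistant-subtype heterogeneity (each
#' subtype over-expresses only its own subset of the up panel, so no single
#' projection step can cover every resistant sample), plus independent
#' background genes.
#'
#' Expression values are on an arbitrary log-like scale centred at 8 with
#' per-gene SD `noise_sd`, echoing microarray log2 intensities; all
#' downstream code is scale-agnostic.
#'
#' @param n_sensitive,n_resistant Sample counts.
#' @param panel A [marker_panel()]; the default mirrors the published
#'   FOLFOX marker panel's composition, 20 up / 10 down synthetic genes.
#' @param effect_size Mean shift for panel genes in resistant samples, in
#'   per-gene SD units (up genes `+effect_size`, down genes `-effect_size`).
#' @param rho_within Within-panel correlation in `[0, 1)`.
#' @param rho_cross Cross-panel correlation in `(-1, 0]`; must not exceed
#'   `rho_within` in magnitude (block factor model).
#' @param n_background Independent unrelated genes.
#' @param subtypes Number of resistant sub-populations; the up panel is
#'   partitioned into `subtypes` disjoint subsets.
#' @param noise_sd Per-gene SD.
#' @param flip_genes Panel genes whose effect sign is flipped (used to plant
#'   discordant decoys in multi-cohort fixtures).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_sensitive = 30, n_resistant = 30,
                        panel = marker_panel(up = sprintf("UPG%02d", 1:20),
                                             down = sprintf("DNG%02d", 1:10)),
                        effect_size = 1.5, rho_within = 0.3,
                        rho_cross = -0.2, n_background = 100, subtypes = 1,
                        noise_sd = 1, flip_genes = character(),
                        seed = NULL) {
  stopifnot(n_sensitive >= 0, n_resistant >= 0, noise_sd > 0, subtypes >= 1)
  if (rho_within < 0 || rho_within >= 1) {
    stop("rho_within must lie in [0, 1)", call. = FALSE)
  }
  if (rho_cross > 0 || rho_cross <= -1) {
    stop("rho_cross must lie in (-1, 0]", call. = FALSE)
  }
  if (abs(rho_cross) > rho_within) {
    stop("panel covariance block is not positive semi-definite: ",
         "|rho_cross| (", abs(rho_cross), ") exceeds rho_within (",
         rho_within, ")", call. = FALSE)
  }
  if (subtypes > length(panel$up)) {
    stop("more subtypes than up-panel genes", call. = FALSE)
  }
  structure(list(n_sensitive = n_sensitive, n_resistant = n_resistant,
                 panel = panel, effect_size = effect_size,
                 rho_within = rho_within, rho_cross = rho_cross,
                 n_background = n_background, subtypes = subtypes,
                 noise_sd = noise_sd, flip_genes = flip_genes, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws the cohort described by a [cohort_spec()]. Panel genes follow a
#' two-factor Gaussian block model: with per-gene SD `s`, a shared latent
#' factor loads `+sqrt(|rho_cross|) s` on up genes and the negative on down
#' genes, and each panel has its own factor carrying the remaining
#' `rho_within - |rho_cross|` covariance — positive semi-definiteness holds
#' by construction. Resistant sample `i` is assigned subtype
#' `((i - 1) mod subtypes) + 1` and shifted by `+effect_size * s` on that
#' subtype's up-gene subset and `-effect_size * s` on every down gene.
#' Background genes are independent noise.
#'
#' @param spec A [cohort_spec()].
#' @return An expression cohort tibble (sensitive samples first); the
#'   resistant subtype assignment is attached as attribute `"subtype"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    up <- spec$panel$up; down <- spec$panel$down
    bg <- if (spec$n_background > 0) sprintf("BG%04d", seq_len(spec$n_background))
          else character()
    genes <- c(up, down, bg)
    n <- spec$n_sensitive + spec$n_resistant
    labels <- rep(c("sensitive", "resistant"),
                  c(spec$n_sensitive, spec$n_resistant))
    subtype <- rep(NA_integer_, n)
    if (spec$n_resistant > 0) {
      subtype[labels == "resistant"] <-
        rep(seq_len(spec$subtypes), length.out = spec$n_resistant)
    }
    s <- spec$noise_sd
    a <- s * sqrt(abs(spec$rho_cross))
    b <- s * sqrt(spec$rho_within - abs(spec$rho_cross))
    resid <- s * sqrt(1 - spec$rho_within)

    # subtype u: which up genes it over-expresses (interleaved partition)
    up_subset <- split(up, rep(seq_len(spec$subtypes), length.out = length(up)))

    m <- matrix(NA_real_, n, length(genes), dimnames = list(NULL, genes))
    sgn <- stats::setNames(rep(1, length(genes)), genes)
    sgn[spec$flip_genes[spec$flip_genes %in% genes]] <- -1
    for (i in seq_len(max(n, 0))) {
      g_shared <- stats::rnorm(1)
      f_up <- stats::rnorm(1)
      f_down <- stats::rnorm(1)
      x_up <- 8 + a * g_shared + b * f_up +
        stats::rnorm(length(up), sd = resid)
      x_down <- 8 - a * g_shared + b * f_down +
        stats::rnorm(length(down), sd = resid)
      if (labels[i] == "resistant") {
        active <- up_subset[[subtype[i]]]
        x_up[up %in% active] <- x_up[up %in% active] +
          spec$effect_size * s * sgn[up[up %in% active]]
        x_down <- x_down - spec$effect_size * s * sgn[down]
      }
      x_bg <- stats::rnorm(length(bg), mean = 8, sd = s)
      m[i, ] <- c(x_up, x_down, x_bg)
    }
    out <- dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("S%03d", seq_len(n)), label = labels),
      tibble::as_tibble(as.data.frame(m))
    )
    out <- as_cohort(out)
    attr(out, "subtype") <- subtype
    out
  })
}

#' Generate three related cohorts sharing one marker panel
#'
#' Produces three independently seeded cohorts from a common spec, with
#' optional per-cohort perturbations (effect and noise multipliers, genes
#' with sign-flipped effects) so cross-cohort concordance and discordance
#' rules can be exercised. Cohort `i` uses seed `spec$seed + 97 * i`.
#'
#' @param spec A [cohort_spec()] with a non-`NULL` seed.
#' @param perturbations List of up to three lists with elements
#'   `effect_mult` (default 1), `noise_mult` (1), `flip_genes`
#'   (`character()`).
#' @return A list of three expression cohort tibbles.
#' @export
generate_triple_cohorts <- function(spec, perturbations = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), !is.null(spec$seed))
  lapply(1:3, function(i) {
    p <- if (!is.null(perturbations) && length(perturbations) >= i)
      perturbations[[i]] else list()
    s <- spec
    s$effect_size <- spec$effect_size * (p$effect_mult %||% 1)
    s$noise_sd <- spec$noise_sd * (p$noise_mult %||% 1)
    s$flip_genes <- as.character(p$flip_genes %||% character())
    s$seed <- spec$seed + 97L * i
    generate_cohort(s)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
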