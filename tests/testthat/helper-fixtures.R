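# shared in-code fixtures

toy_cohort <- function() {
  as_cohort(tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    label = rep(c("resistant", "sensitive"), each = 3),
    G1 = c(9.1, 9.4, 9.0, 7.8, 8.0, 7.9),
    G2 = c(6.0, 6.2, 6.1, 7.5, 7.4, 7.6),
    G3 = c(8.0, 8.1, 7.9, 8.0, 8.1, 7.9)
  ))
}

unit_norm <- function(genes) {
  out <- tibble::tibble(gene = genes, min = 0, max = 1)
  class(out) <- c("radviz_norm", class(out))
  out
}

# weight-matrix cohort: one column per layout gene, values already in [0, 1]
weights_cohort <- function(W, genes, labels = "unknown") {
  df <- tibble::as_tibble(as.data.frame(W))
  names(df) <- genes
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("w%d", seq_len(nrow(W))),
                   label = labels),
    df
  )
}

small_panel <- function() {
  marker_panel(up = sprintf("UPG%02d", 1:8), down = sprintf("DNG%02d", 1:4))
}

# the 14 genes of the published cascade, with their panel directions
folfox_panel_for_tests <- function() {
  marker_panel(
    up = c("TMEM182", "MCM9", "SRSF11", "ETV5", "FAM161A", "RIMBP2",
           "NCKAP5", "ZBTB49"),
    down = c("LRRFIP1", "LAMP1", "KLHL36", "CRTAP", "RNF168", "VAMP2")
  )
}

# hand-constructed DEG-table triple in which every selection and exclusion
# rule fires at least once; expected memberships are enumerable by hand
deg_row <- function(gene, md, t, p) {
  tibble::tibble(gene = gene, mean_diff = md, t_mod = t, p_raw = p,
                 p_adj = pmin(1, p * 4), direction = ifelse(md > 0, "up", "down"))
}

marker_fixture <- function() {
  planted_up <- sprintf("PU%02d", 1:8)
  planted_down <- sprintf("PD%02d", 1:4)
  strong_up <- function() deg_row(planted_up, 1, 3, 0.001)
  strong_down <- function() deg_row(planted_down, -1, -3, 0.001)
  # acceptable-but-not-significant versions for the "remaining" cohort
  accept_up <- function() deg_row(planted_up, 0.4, 1.5, 0.05)
  accept_down <- function() deg_row(planted_down, -0.4, -1.5, 0.05)
  null_row <- function(g) deg_row(g, 0.05, 0.3, 0.8)

  # decoys: primary-pass in two tables, third table fails each rule in turn
  t12 <- function(g, up = TRUE) deg_row(g, ifelse(up, 1, -1),
                                        ifelse(up, 2.6, -2.6), 0.01)
  d_oppo <- deg_row("DOPPO", -0.8, -1.6, 0.02)     # opposite regulation
  d_weak <- deg_row("DWEAK", 0.3, 0.5, 0.02)       # |t| < 1
  d_insig <- deg_row("DINSIG", 0.5, 1.5, 0.08)     # p >= 0.075
  d_oppo_dn <- deg_row("DOPPODN", 0.8, 1.6, 0.02)  # opposite, down candidate
  d_weak_dn <- deg_row("DWEAKDN", -0.3, -0.5, 0.02)
  d_insig_dn <- deg_row("DINSIGDN", -0.5, -1.5, 0.09)
  d_single <- "DSINGLE"                            # significant once only
  d_never <- "DNEVER"

  bg <- sprintf("BG%02d", 1:10)

  tab1 <- dplyr::bind_rows(
    strong_up(), strong_down(),
    t12("DOPPO"), t12("DWEAK"), t12("DINSIG"),
    t12("DOPPODN", up = FALSE), t12("DWEAKDN", up = FALSE),
    t12("DINSIGDN", up = FALSE),
    deg_row(d_single, 1, 2.8, 0.005), null_row(d_never),
    null_row(bg))
  tab2 <- dplyr::bind_rows(
    strong_up(), strong_down(),
    t12("DOPPO"), t12("DWEAK"), t12("DINSIG"),
    t12("DOPPODN", up = FALSE), t12("DWEAKDN", up = FALSE),
    t12("DINSIGDN", up = FALSE),
    null_row(d_single), null_row(d_never),
    null_row(bg))
  # third cohort: planted genes only "acceptable", decoys fail their rule
  tab3 <- dplyr::bind_rows(
    accept_up(), accept_down(),
    d_oppo, d_weak, d_insig, d_oppo_dn, d_weak_dn, d_insig_dn,
    null_row(d_single), null_row(d_never),
    null_row(bg))
  list(tab1, tab2, tab3,
       planted = marker_panel(up = planted_up, down = planted_down))
}

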