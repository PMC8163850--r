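# PLFA marker dynamics, eukaryotic/bacterial grouping, compound-specific
# source partitioning.

plfa_tbl <- function(compound, treatment_id, initial, final, n_rep = 2) {
  grid <- expand.grid(compound = compound, treatment_id = treatment_id,
                      replicate = seq_len(n_rep), stringsAsFactors = FALSE)
  dplyr::bind_rows(
    dplyr::mutate(grid, phase = "initial",
                  conc = initial[cbind(match(compound, rownames(initial)),
                                       match(treatment_id, colnames(initial)))]),
    dplyr::mutate(grid, phase = "final",
                  conc = final[cbind(match(compound, rownames(final)),
                                     match(treatment_id, colnames(final)))]))
}

test_that("concentration change is final minus initial on replicate means", {
  m0 <- matrix(c(5, 5, 1, 1), 2, 2, dimnames = list(c("a15:0", "i15:0"),
                                                    c("T1", "T2")))
  m1 <- matrix(c(5, 8, 4, 1), 2, 2, dimnames = dimnames(m0))
  ch <- plfa_concentration_change(plfa_tbl(rownames(m0), colnames(m0), m0, m1))
  get <- function(cmp, tr) ch$d_conc[ch$compound == cmp & ch$treatment_id == tr]
  expect_equal(get("a15:0", "T1"), 0)
  expect_equal(get("i15:0", "T1"), 3)
  expect_equal(get("a15:0", "T2"), 3)
  expect_equal(get("i15:0", "T2"), 0)
  # a compound absent initially contributes its final concentration
  extra <- dplyr::bind_rows(
    plfa_tbl(rownames(m0), colnames(m0), m0, m1),
    tibble::tibble(compound = "cy-17:0", treatment_id = "T1", replicate = 1,
                   phase = "final", conc = 7))
  ch2 <- plfa_concentration_change(extra)
  expect_equal(ch2$d_conc[ch2$compound == "cy-17:0" & ch2$treatment_id == "T1"], 7)
})

test_that("clustering splits the markers into the expected two groups", {
  ch <- plfa_concentration_change(noisy_study()$measurements$plfa)
  assign <- cluster_markers(ch)
  grp <- setNames(assign$group, assign$compound)
  expect_setequal(names(grp)[grp == "eukaryotic"],
                  c("18:1ω9t/7c", "18:2ω6,9"))
  expect_setequal(names(grp)[grp == "bacterial"],
                  c("i15:0", "a15:0", "cy-17:0", "16:1ω9", "18:1ω9c"))
  expect_equal(attr(assign, "distance"), "1 - Pearson")
})

test_that("clustering is invariant to row order and uniform rescaling", {
  ch <- plfa_concentration_change(noisy_study()$measurements$plfa)
  ref <- cluster_markers(ch)
  set.seed(42)
  for (i in 1:5) {
    perm <- ch[sample(nrow(ch)), ]
    got <- cluster_markers(perm)
    expect_equal(dplyr::arrange(got, compound)$group,
                 dplyr::arrange(ref, compound)$group)
  }
  scaled <- dplyr::mutate(ch, d_conc = d_conc * 1e3)
  expect_equal(dplyr::arrange(cluster_markers(scaled), compound)$group,
               dplyr::arrange(ref, compound)$group)
})

test_that("anticorrelated profiles separate; split anchors are an error", {
  trts <- paste0("T", 1:4)
  up <- c(1, 2, 3, 4); down <- -up
  ch <- tibble::tibble(
    compound = rep(c("18:2ω6,9", "i15:0"), each = 4),
    treatment_id = rep(trts, 2),
    d_conc = c(up, down))
  got <- cluster_markers(ch)
  expect_equal(sort(unique(got$group)), c("bacterial", "eukaryotic"))
  expect_true(got$group[got$compound == "18:2ω6,9"] == "eukaryotic")
  # anchors forced into one cluster -> ambiguous labelling
  bad <- tibble::tibble(
    compound = rep(c("18:2ω6,9", "i15:0", "a15:0"), each = 4),
    treatment_id = rep(trts, 3),
    d_conc = c(up, up * 1.01, down))
  expect_error(cluster_markers(bad), "ambiguous")
})

test_that("group biomass totals are additive", {
  m <- noisy_study()$measurements$plfa
  assign <- cluster_markers(plfa_concentration_change(m))
  gb <- group_biomass(m, assign)
  per_compound <- m |>
    dplyr::group_by(compound, treatment_id, phase) |>
    dplyr::summarise(conc = mean(conc), .groups = "drop")
  expect_equal(sum(gb$conc_total), sum(per_compound$conc), tolerance = 1e-12)
  expect_error(group_biomass(m, assign[-1, ]), "unassigned")
})

test_that("compound-specific partitioning recovers simulator source fractions", {
  study <- nf_study()
  cfg <- sim_config()
  ends <- study_endmembers(cfg)
  m <- study$measurements$plfa
  res <- partition_plfa_carbon(m, ends, mode = "atom")
  tru <- study$plfa_truth <- study$measurements$plfa_truth
  joined <- dplyr::inner_join(
    res, tru, by = c("compound", "treatment_id", "phase"))
  ok <- !joined$no_delta & !is.na(joined$f_daphnia)
  expect_gt(sum(ok), 20)
  expect_equal(joined$pct_daphnia[ok] / 100, joined$f_daphnia[ok],
               tolerance = 1e-10)
  # fractions sum to 100%
  expect_equal(joined$pct_daphnia[ok] + joined$pct_leaf[ok],
               rep(100, sum(ok)))
  # missing isotope values flagged, not fatal
  expect_true(all(is.na(res$pct_daphnia[res$no_delta])))
})

test_that("endmember and midpoint signatures give 100% and 50/50 splits", {
  ends <- natural_ends()
  rec <- tibble::tibble(
    compound = c("i15:0", "i15:0"), treatment_id = "T1",
    phase = c("initial", "final"), replicate = 1, conc = 10,
    delta13C_permil = c(-30, forward_mix(0.5, ends, "delta")$value))
  res <- partition_plfa_carbon(rec, ends, mode = "delta")
  expect_equal(res$pct_daphnia[res$phase == "initial"], 100)
  expect_equal(res$pct_daphnia[res$phase == "final"], 50)
})
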