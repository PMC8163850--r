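# Phospholipid fatty acid (PLFA) biomass markers: concentration dynamics,
# eukaryotic/bacterial grouping by clustering, and compound-specific 13C
# source partitioning. Compound names follow the omega nomenclature; the
# chromatographically inseparable pair 18:1w9t/18:1w7c is one token.

#' Canonical PLFA compound vocabulary
#'
#' The marker set used throughout: two eukaryotic indicators (the fungal/
#' crustacean markers 18:1ω9t/7c and 18:2ω6,9) and five compounds
#' dominated by bacterial membranes (branched i15:0 and a15:0, cyclopropyl
#' cy-17:0, and the less specific 16:1ω9 and 18:1ω9c).
#'
#' @return Named character vector: compound -> nominal group.
#' @export
plfa_vocabulary <- function() {
  c("18:1ω9t/7c" = "eukaryotic",
    "18:2ω6,9"   = "eukaryotic",
    "i15:0"           = "bacterial",
    "a15:0"           = "bacterial",
    "cy-17:0"         = "bacterial",
    "16:1ω9"     = "bacterial",
    "18:1ω9c"    = "bacterial")
}

#' Per-compound concentration change over the incubation
#'
#' Final minus initial concentration per compound and treatment (replicate
#' means). A compound absent in one phase contributes zero for that phase.
#'
#' @param records Data frame with columns `compound`, `treatment_id`,
#'   `replicate`, `phase` ("initial"/"final") and `conc`.
#' @return A tibble with `compound`, `treatment_id`, `d_conc`.
#' @export
plfa_concentration_change <- function(records) {
  need <- c("compound", "treatment_id", "replicate", "phase", "conc")
  stopifnot(all(need %in% names(records)))
  if (!all(records$phase %in% c("initial", "final")))
    stop("phase must be 'initial' or 'final'")
  if (length(unique(records$phase)) < 2L) stop("both phases must be present")
  records |>
    dplyr::group_by(.data$compound, .data$treatment_id, .data$phase) |>
    dplyr::summarise(conc = mean(.data$conc), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "conc",
                       values_fill = 0) |>
    dplyr::mutate(d_conc = .data$final - .data$initial) |>
    dplyr::select("compound", "treatment_id", "d_conc")
}

#' Assign PLFA markers to eukaryotic vs bacterial groups by clustering
#'
#' Hierarchically clusters per-compound concentration-change profiles across
#' treatments (correlation distance 1 - Pearson, average linkage, cut at
#' k = 2) and labels the two clusters deterministically via anchor
#' compounds: the cluster containing the eukaryotic anchors is labelled
#' eukaryotic, the other bacterial. Anchors split across clusters are an
#' error (ambiguous labelling), not a silent guess.
#'
#' @param changes Output of [plfa_concentration_change()] (or any long table
#'   with `compound`, `treatment_id`, `d_conc`).
#' @param euk_anchors,bact_anchors Anchor compounds for deterministic
#'   labelling.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return A tibble `compound`, `group`; attributes `distance`, `linkage`,
#'   `hclust` carry the method metadata.
#' @export
cluster_markers <- function(changes,
                            euk_anchors = "18:2ω6,9",
                            bact_anchors = c("i15:0", "a15:0"),
                            linkage = "average") {
  stopifnot(all(c("compound", "treatment_id", "d_conc") %in% names(changes)))
  wide <- changes |>
    dplyr::arrange(.data$compound, .data$treatment_id) |>
    tidyr::pivot_wider(names_from = "treatment_id", values_from = "d_conc")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$compound
  mat <- mat[order(rownames(mat)), , drop = FALSE]  # order-invariant
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("need at least 2 compounds and 2 treatments to cluster")
  # standardise each profile; 1 - Pearson is scale/location invariant anyway,
  # but degenerate constant profiles are rejected explicitly
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0))
    stop("constant concentration-change profile(s): ",
         paste(rownames(mat)[sds == 0], collapse = ", "))
  z <- t(scale(t(mat)))
  d <- stats::as.dist(1 - stats::cor(t(z)))
  hc <- stats::hclust(d, method = linkage)
  k2 <- stats::cutree(hc, k = 2)

  present_euk <- intersect(euk_anchors, names(k2))
  present_bact <- intersect(bact_anchors, names(k2))
  if (!length(present_euk) || !length(present_bact))
    stop("anchor compounds missing from the data")
  euk_cl <- unique(k2[present_euk])
  bact_cl <- unique(k2[present_bact])
  if (length(euk_cl) > 1L || length(bact_cl) > 1L || euk_cl == bact_cl) {
    stop("anchor compounds split across clusters: labelling ambiguous; ",
         "cluster membership: ",
         paste(sprintf("%s=%d", names(k2), k2), collapse = ", "))
  }
  out <- tibble::tibble(
    compound = names(k2),
    group = ifelse(k2 == euk_cl, "eukaryotic", "bacterial"))
  attr(out, "distance") <- "1 - Pearson"
  attr(out, "linkage") <- linkage
  attr(out, "hclust") <- hc
  out
}

#' Group-level PLFA biomass totals
#'
#' Sums compound concentrations within each marker group per treatment and
#' phase (replicate means first).
#'
#' @param records As in [plfa_concentration_change()].
#' @param assignment Output of [cluster_markers()] (columns `compound`,
#'   `group`).
#' @return A tibble `treatment_id`, `phase`, `group`, `conc_total`.
#' @export
group_biomass <- function(records, assignment) {
  unassigned <- setdiff(unique(records$compound), assignment$compound)
  if (length(unassigned))
    stop("unassigned compound(s): ", paste(unassigned, collapse = ", "))
  records |>
    dplyr::group_by(.data$compound, .data$treatment_id, .data$phase) |>
    dplyr::summarise(conc = mean(.data$conc), .groups = "drop") |>
    dplyr::left_join(assignment, by = "compound") |>
    dplyr::group_by(.data$treatment_id, .data$phase, .data$group) |>
    dplyr::summarise(conc_total = sum(.data$conc), .groups = "drop")
}

#' Compound-specific 13C source partitioning
#'
#' Pools replicate delta-13C values per compound/treatment/phase with a
#' concentration-weighted mean (approximating physical pooling of extracts)
#' and applies the two-source mixing model. Compounds without an isotope
#' value yield NA fractions with a `no_delta` flag rather than an error.
#'
#' @param records As in [plfa_concentration_change()], plus
#'   `delta13C_permil` (may be NA).
#' @param ends [endmembers()].
#' @param mode `"delta"` or `"atom"`.
#' @return A tibble per compound x treatment x phase: pooled `delta13C`,
#'   `pct_daphnia`, `pct_leaf`, `clipped`, `no_delta`.
#' @export
partition_plfa_carbon <- function(records, ends, mode = c("delta", "atom")) {
  mode <- match.arg(mode)
  need <- c("compound", "treatment_id", "phase", "conc", "delta13C_permil")
  stopifnot(all(need %in% names(records)))
  pooled <- records |>
    dplyr::group_by(.data$compound, .data$treatment_id, .data$phase) |>
    dplyr::summarise(
      delta13C = {
        ok <- !is.na(.data$delta13C_permil) & .data$conc > 0
        if (any(ok)) sum(.data$conc[ok] * .data$delta13C_permil[ok]) / sum(.data$conc[ok])
        else NA_real_
      },
      conc_total = sum(.data$conc), .groups = "drop")
  has <- !is.na(pooled$delta13C)
  pooled$pct_daphnia <- NA_real_
  pooled$pct_leaf <- NA_real_
  pooled$clipped <- NA
  if (any(has)) {
    mix <- mix_fraction(pooled$delta13C[has], ends, mode = mode)
    pooled$pct_daphnia[has] <- 100 * mix$f_a
    pooled$pct_leaf[has] <- 100 * mix$f_b
    pooled$clipped[has] <- mix$clipped
  }
  pooled$no_delta <- !has
  pooled$mode <- mode
  pooled
}
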