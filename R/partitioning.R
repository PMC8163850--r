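# Source attribution of CO2 and POC, substrate-normalised mineralisation,
# control baselines (measured and pseudo) and the non-additive
# interactive-effect statistic, plus the carbon mass balance.

#' A bottle treatment scenario
#'
#' @param id Treatment identifier (unique).
#' @param daphnia_mg_l,leaf_mg_l Substrate dry weights, mg l-1 (>= 0).
#' @param community `"complex"` (< 50 um inoculum) or `"bacterial"`
#'   (< 0.8 um).
#' @param n_replicates Number of replicate bottles.
#' @return A one-row tibble.
#' @export
treatment <- function(id, daphnia_mg_l, leaf_mg_l,
                      community = c("complex", "bacterial"), n_replicates = 4) {
  community <- match.arg(community)
  stopifnot(daphnia_mg_l >= 0, leaf_mg_l >= 0, n_replicates >= 1)
  tibble::tibble(treatment_id = id, daphnia_mg_l = daphnia_mg_l,
                 leaf_mg_l = leaf_mg_l, community = community,
                 n_replicates = as.integer(n_replicates))
}

#' Carbon molar mass for a given 13C atom fraction
#'
#' Isotope-weighted molar mass, linear in the atom fraction:
#' M(F) = 12 (1 - F) + 13.00335 F. When the composition is unknown
#' (`atom_fraction = NULL`) the conventional 12.011 g mol-1 is used.
#' A 10 atom% pool shifts the carbon molar mass by roughly 0.8%, which
#' matters for mg-scale budgets of labelled material.
#'
#' @param atom_fraction 13C atom fraction, or NULL.
#' @return Molar mass in g mol-1.
#' @export
molar_mass_c <- function(atom_fraction = NULL) {
  if (is.null(atom_fraction)) return(12.011)
  stopifnot(all(atom_fraction > 0 & atom_fraction < 1))
  12 * (1 - atom_fraction) + 13.00335 * atom_fraction
}

#' @rdname molar_mass_c
#' @param umol Amount in umol C l-1.
#' @export
umol_to_mg_c <- function(umol, atom_fraction = NULL) {
  umol * molar_mass_c(atom_fraction) / 1000
}

partition_two_source <- function(amount, delta, ends, tr, mode, replicate, what) {
  stopifnot(nrow(tr) == 1L, all(amount >= -1e-9))
  n <- length(amount)
  n_delta <- if (inherits(delta, "iso_value")) length(delta$value) else length(delta)
  if (n_delta != n) stop("amount and delta must have equal length")
  if (is.null(replicate)) replicate <- seq_len(n)
  masses <- c(daphnia = tr$daphnia_mg_l, leaf = tr$leaf_mg_l)
  if (all(masses == 0)) stop("treatment has no substrate: nothing to partition")

  if (any(masses == 0)) {
    # single-source control: the mixing model is bypassed, the present
    # source receives the full amount without inversion
    f_a <- rep(as.numeric(masses["daphnia"] > 0), n)
    mix <- tibble::tibble(f_a = f_a, f_b = 1 - f_a, raw_f_a = f_a,
                          clipped = FALSE, out_of_range = FALSE,
                          mode = "bypass_single_source",
                          standard = as_iso(ends$source_a)$standard$name,
                          r13 = as_iso(ends$source_a)$standard$r13)
  } else {
    mix <- mix_fraction(delta, ends, mode = mode)
  }

  per_source <- function(source, f, mass) {
    abs_amt <- amount * f
    per_mg <- if (mass > 0) abs_amt / mass else {
      if (any(abs_amt > 1e-9)) stop(sprintf(
        "nonzero %s attributed to source '%s' with zero substrate mass: normalisation undefined",
        what, source))
      rep(0, n)
    }
    tibble::tibble(treatment_id = tr$treatment_id, replicate = replicate,
                   source = source, f_source = f,
                   abs = abs_amt, per_mg = per_mg,
                   mode = mix$mode, clipped = mix$clipped,
                   out_of_range = mix$out_of_range)
  }
  out <- dplyr::bind_rows(per_source("daphnia", mix$f_a, masses[["daphnia"]]),
                          per_source("leaf", mix$f_b, masses[["leaf"]]))
  names(out)[names(out) == "abs"] <- paste0(what, "_abs")
  names(out)[names(out) == "per_mg"] <- paste0(what, "_per_mg")
  out
}

#' Partition dissolved CO2 between the two carbon sources
#'
#' Applies the two-source mixing model to the delta-13C of respired CO2 and
#' normalises the source-specific concentration by the source's substrate
#' dry weight. Treatment CO2 should be net of the blank/initial baseline
#' (see [net_co2_production()]). Single-source controls bypass the mixing
#' model: their whole signal is attributed to the only source present.
#'
#' @param conc Net CO2 concentration(s), umol C l-1 (one per replicate).
#' @param delta delta-13C of that CO2 (per mill vs V-PDB, or [iso_value()]).
#' @param ends [endmembers()] (A = daphnia, B = leaves).
#' @param tr A one-row treatment table (see [treatment()]).
#' @param mode `"delta"` or `"atom"` (passed to [mix_fraction()]).
#' @param replicate Optional replicate labels.
#' @return A tibble with two rows per observation (source daphnia/leaf):
#'   `f_source`, `co2_abs` (umol C l-1), `co2_per_mg` (umol C l-1 mg-1).
#' @export
partition_co2 <- function(conc, delta, ends, tr, mode = c("delta", "atom"),
                          replicate = NULL) {
  mode <- match.arg(mode)
  partition_two_source(conc, delta, ends, tr, mode, replicate, "co2")
}

#' Partition particulate organic carbon between the two sources
#'
#' Identical model to [partition_co2()] with bulk POC delta-13C in place of
#' the CO2 signature.
#'
#' @param mass POC amount(s) (umol C l-1 or mg C l-1; units carried through).
#' @inheritParams partition_co2
#' @return A tibble with two rows per observation: `f_source`, `poc_abs`,
#'   `poc_per_mg`.
#' @export
partition_poc <- function(mass, delta, ends, tr, mode = c("delta", "atom"),
                          replicate = NULL) {
  mode <- match.arg(mode)
  partition_two_source(mass, delta, ends, tr, mode, replicate, "poc")
}

#' Control baseline for the interactive-effect statistic
#'
#' When the single-source controls contain the same substrate masses as the
#' treatment, the baseline is the measured sum of their CO2 production.
#' Otherwise a pseudocontrol is built from the controls' per-mg
#' mineralisation rates scaled to the treatment's masses.
#'
#' @param tr A one-row treatment table.
#' @param controls A data frame with columns `source` ("daphnia"/"leaf"),
#'   `co2` (production, umol C l-1) and `mass_mg_l` (substrate in the
#'   control bottle).
#' @param mass_tol Relative tolerance for judging masses equal.
#' @return A `control_basis` object with `co2_controls`, `basis`
#'   (`"measured_sum"` or `"per_mg_pseudo"`) and per-source `components`.
#' @export
control_basis <- function(tr, controls, mass_tol = 1e-9) {
  stopifnot(nrow(tr) == 1L, all(c("source", "co2", "mass_mg_l") %in% names(controls)))
  need <- c("daphnia", "leaf")
  if (!all(need %in% controls$source))
    stop("controls must cover both sources (daphnia and leaf)")
  controls <- controls[match(need, controls$source), ]
  if (any(controls$mass_mg_l <= 0)) stop("control substrate masses must be > 0")
  tr_mass <- c(daphnia = tr$daphnia_mg_l, leaf = tr$leaf_mg_l)
  same <- all(abs(tr_mass - controls$mass_mg_l) <=
                mass_tol * pmax(tr_mass, controls$mass_mg_l))
  rate <- controls$co2 / controls$mass_mg_l
  if (same) {
    components <- tibble::tibble(source = need, co2 = controls$co2,
                                 rate_per_mg = rate, mass_applied = controls$mass_mg_l)
    basis <- "measured_sum"
  } else {
    components <- tibble::tibble(source = need, co2 = rate * unname(tr_mass),
                                 rate_per_mg = rate, mass_applied = unname(tr_mass))
    basis <- "per_mg_pseudo"
  }
  total <- sum(components$co2)
  if (total <= 0) stop("control basis must be positive")
  structure(list(treatment_id = tr$treatment_id, basis = basis,
                 co2_controls = total, components = components),
            class = "control_basis")
}

#' @export
print.control_basis <- function(x, ...) {
  cat(sprintf("<control_basis> %s [%s]: %.4g umol C l-1\n",
              x$treatment_id, x$basis, x$co2_controls))
  print(x$components, ...)
  invisible(x)
}

#' Non-additive interactive effect (priming statistic)
#'
#' IE = 100 * (CO2_treatment - CO2_controls) / CO2_controls, the percent
#' excess CO2 production of the mixed-substrate treatment over the sum of
#' its single-source controls (measured or pseudo). Replicate-level IEs are
#' aggregated to mean and sd.
#'
#' @param co2_treatment CO2 production of the treatment, umol C l-1; one
#'   value per replicate.
#' @param basis A [control_basis()].
#' @param treatment_community,control_community Community types; a mismatch
#'   (e.g. a bacterial treatment judged against complex-community controls)
#'   is flagged, not fatal.
#' @return An `ie_result` list: `ie_percent` (per replicate), `ie_mean`,
#'   `ie_sd`, `n`, `co2_treatment_mean`, `basis`, flag
#'   `control_community_mismatch`.
#' @export
interactive_effect <- function(co2_treatment, basis,
                               treatment_community = "complex",
                               control_community = "complex") {
  stopifnot(inherits(basis, "control_basis"), is.numeric(co2_treatment))
  if (basis$co2_controls <= 0) stop("non-positive control basis")
  ie <- 100 * (co2_treatment - basis$co2_controls) / basis$co2_controls
  structure(list(
    treatment_id = basis$treatment_id,
    ie_percent = ie,
    ie_mean = mean(ie),
    ie_sd = if (length(ie) > 1) stats::sd(ie) else NA_real_,
    n = length(ie),
    co2_treatment_mean = mean(co2_treatment),
    basis = basis,
    control_community_mismatch = !identical(treatment_community, control_community)
  ), class = "ie_result")
}

#' @export
print.ie_result <- function(x, ...) {
  cat(sprintf("<ie_result> %s: IE = %.1f%% (sd %.2f, n = %d) vs %s basis %.4g\n",
              x$treatment_id, x$ie_mean, x$ie_sd, x$n,
              x$basis$basis, x$basis$co2_controls))
  if (x$control_community_mismatch)
    cat("  flag: control_community_mismatch\n")
  invisible(x)
}

#' Carbon budget closure
#'
#' Checks that carbon lost from the particulate pool plus consumed DOC is
#' accounted for by respired CO2:
#' residual = initial_poc + doc_consumed - final_poc - co2_c (all mg C l-1).
#' CO2 is converted from umol C l-1 with the isotope-weighted molar mass when
#' its composition is known (see [molar_mass_c()]).
#'
#' @param initial_poc_mg,final_poc_mg POC, mg C l-1.
#' @param co2_umol Respired CO2, umol C l-1.
#' @param doc_consumed_mg DOC consumed over the incubation, mg C l-1.
#' @param co2_atom_fraction Optional 13C atom fraction of the respired CO2.
#' @param flag_fraction Residuals larger than this fraction of initial C are
#'   flagged (default 0.10).
#' @param treatment_id Optional label.
#' @return A tibble with the budget terms, `closure_residual`,
#'   `residual_rel` and `flagged`.
#' @export
mass_balance <- function(initial_poc_mg, final_poc_mg, co2_umol,
                         doc_consumed_mg, co2_atom_fraction = NULL,
                         flag_fraction = 0.10, treatment_id = NA_character_) {
  stopifnot(all(initial_poc_mg >= 0), all(final_poc_mg >= 0),
            all(doc_consumed_mg >= -1e-12))
  co2_mg <- umol_to_mg_c(co2_umol, co2_atom_fraction)
  residual <- initial_poc_mg + doc_consumed_mg - final_poc_mg - co2_mg
  initial_c <- initial_poc_mg + doc_consumed_mg
  rel <- ifelse(initial_c > 0, residual / initial_c, 0)
  tibble::tibble(treatment_id = treatment_id,
                 initial_poc = initial_poc_mg, final_poc = final_poc_mg,
                 co2_c = co2_mg, doc_consumed = doc_consumed_mg,
                 closure_residual = residual, residual_rel = rel,
                 flagged = abs(rel) > flag_fraction)
}

# ---- study-level pipeline --------------------------------------------------

#' Carbon budget of one treatment from measurement tables
#'
#' Assembles [mass_balance()] inputs from the emitted `poc`, `doc` and `co2`
#' tables: replicate-mean initial and final POC (converted to mg C with the
#' isotope-weighted molar mass from the measured delta-13C), DOC consumed,
#' and gross CO2 production with its isotope-mass-balance composition.
#'
#' @param meas A measurement list (see [emit_measurements()] /
#'   [read_measurements()]).
#' @param treatment_id Treatment to balance.
#' @param standard An [iso_standard()].
#' @param flag_fraction Passed to [mass_balance()].
#' @return A one-row [mass_balance()] tibble.
#' @export
budget_from_measurements <- function(meas, treatment_id, standard = vpdb(),
                                     flag_fraction = 0.10) {
  poc <- meas$poc[meas$poc$treatment_id == treatment_id, ]
  doc <- meas$doc[meas$doc$treatment_id == treatment_id, ]
  if (!nrow(poc) || !nrow(doc)) stop("treatment not found: ", treatment_id)
  poc_mg <- function(phase) {
    p <- poc[poc$phase == phase, ]
    umol <- mean(p$poc_umol_l)
    f13 <- if (all(is.na(p$delta13C_permil)) || umol <= 0) NULL
           else mean(delta_to_atom(p$delta13C_permil, standard$r13))
    umol_to_mg_c(umol, f13)
  }
  doc_consumed <- mean(doc$doc_mg_l[doc$day == min(doc$day)]) -
    mean(doc$doc_mg_l[doc$day == max(doc$day)])
  gross <- net_co2_production(meas$co2, blank_id = NULL, standard = standard)
  gross <- gross[gross$treatment_id == treatment_id, ]
  co2_umol <- mean(gross$co2_net)
  co2_f13 <- if (all(is.na(gross$atom_fraction_net))) NULL
             else mean(gross$atom_fraction_net, na.rm = TRUE)
  mass_balance(poc_mg("initial"), poc_mg("final"), co2_umol, doc_consumed,
               co2_atom_fraction = co2_f13, flag_fraction = flag_fraction,
               treatment_id = treatment_id)
}

#' Net CO2 production per bottle, isotope-aware
#'
#' Production is final minus the treatment's mean initial concentration;
#' the blank's mean production is then subtracted. Both subtractions are
#' done by carbon-isotope mass balance (on 12C + 13C amounts), so the
#' returned delta-13C is the signature of the net, source-derived CO2 —
#' the quantity the mixing model expects.
#'
#' @param co2_tbl Data frame with columns `treatment_id`, `replicate`,
#'   `day`, `conc_umol_l`, `delta13C_permil` containing initial-day and
#'   final-day samples.
#' @param blank_id Treatment id of the blank (`NULL` to skip blank
#'   subtraction).
#' @param standard An [iso_standard()].
#' @return A tibble per final replicate: `co2_produced` (gross),
#'   `co2_net` (net of blank), `atom_fraction_net`, `delta13C_net`.
#' @export
net_co2_production <- function(co2_tbl, blank_id = "Blank", standard = vpdb()) {
  need <- c("treatment_id", "replicate", "day", "conc_umol_l", "delta13C_permil")
  stopifnot(all(need %in% names(co2_tbl)))
  d0 <- min(co2_tbl$day); d1 <- max(co2_tbl$day)
  if (d0 == d1) stop("need both initial and final day samples")
  co2_tbl$atoms13 <- co2_tbl$conc_umol_l *
    delta_to_atom(co2_tbl$delta13C_permil, standard$r13)

  init <- co2_tbl |>
    dplyr::filter(.data$day == d0) |>
    dplyr::group_by(.data$treatment_id) |>
    dplyr::summarise(c0 = mean(.data$conc_umol_l), c0_13 = mean(.data$atoms13),
                     .groups = "drop")
  fin <- co2_tbl |>
    dplyr::filter(.data$day == d1) |>
    dplyr::left_join(init, by = "treatment_id") |>
    dplyr::mutate(prod = .data$conc_umol_l - .data$c0,
                  prod13 = .data$atoms13 - .data$c0_13)

  if (!is.null(blank_id) && blank_id %in% fin$treatment_id) {
    bl <- dplyr::filter(fin, .data$treatment_id == blank_id)
    bl_prod <- mean(bl$prod); bl_prod13 <- mean(bl$prod13)
  } else {
    bl_prod <- 0; bl_prod13 <- 0
  }

  fin |>
    dplyr::mutate(
      co2_net = .data$prod - bl_prod,
      net13 = .data$prod13 - bl_prod13,
      atom_fraction_net = ifelse(.data$co2_net > 0, .data$net13 / .data$co2_net,
                                 NA_real_),
      delta13C_net = ifelse(is.na(.data$atom_fraction_net), NA_real_,
                            atom_to_delta(.data$atom_fraction_net, standard$r13))
    ) |>
    dplyr::select("treatment_id", "replicate",
                  co2_produced = "prod", "co2_net",
                  "atom_fraction_net", "delta13C_net")
}

#' Partition net CO2 production for every treatment of a study
#'
#' Runs [net_co2_production()] and then [partition_co2()] per treatment,
#' bypassing the mixing model for single-source controls and skipping the
#' blank.
#'
#' @inheritParams net_co2_production
#' @param design Treatment design table (columns of [treatment()]).
#' @param ends [endmembers()].
#' @param mode `"delta"` or `"atom"`.
#' @return A tibble of [partition_co2()] rows for all treatments.
#' @export
partition_study <- function(co2_tbl, design, ends, mode = c("delta", "atom"),
                            blank_id = "Blank", standard = vpdb()) {
  mode <- match.arg(mode)
  net <- net_co2_production(co2_tbl, blank_id = blank_id, standard = standard)
  out <- list()
  for (id in unique(net$treatment_id)) {
    tr <- design[design$treatment_id == id, ]
    if (nrow(tr) == 0L) stop("treatment missing from design: ", id)
    if (tr$daphnia_mg_l == 0 && tr$leaf_mg_l == 0) next  # blank
    rows <- net[net$treatment_id == id, ]
    out[[id]] <- partition_co2(rows$co2_net, rows$delta13C_net, ends, tr,
                               mode = mode, replicate = rows$replicate)
  }
  dplyr::bind_rows(out)
}

#' Interactive effects for every mixed treatment of a study
#'
#' Builds the control basis from the single-source control bottles
#' (measured sum where the masses match, per-mg pseudocontrol otherwise)
#' and computes the replicate-level IE for each mixed-substrate treatment.
#'
#' @inheritParams partition_study
#' @param daphnia_control,leaf_control Treatment ids of the single-source
#'   controls.
#' @return A tibble per mixed treatment: `ie_mean`, `ie_sd`, `n`, `basis`,
#'   `co2_controls`, `control_community_mismatch`.
#' @export
interactive_effects_study <- function(co2_tbl, design,
                                      daphnia_control = "Daphnia",
                                      leaf_control = "Leaves",
                                      blank_id = "Blank", standard = vpdb()) {
  net <- net_co2_production(co2_tbl, blank_id = blank_id, standard = standard)
  ctrl_mean <- function(id) mean(net$co2_net[net$treatment_id == id])
  dmass <- design$daphnia_mg_l[design$treatment_id == daphnia_control]
  lmass <- design$leaf_mg_l[design$treatment_id == leaf_control]
  if (length(dmass) != 1L || length(lmass) != 1L)
    stop("control treatments not found in design")
  controls <- tibble::tibble(
    source = c("daphnia", "leaf"),
    co2 = c(ctrl_mean(daphnia_control), ctrl_mean(leaf_control)),
    mass_mg_l = c(dmass, lmass))
  ctrl_comm <- design$community[design$treatment_id == daphnia_control]

  mixed <- design[design$daphnia_mg_l > 0 & design$leaf_mg_l > 0, ]
  out <- list()
  for (i in seq_len(nrow(mixed))) {
    tr <- mixed[i, ]
    basis <- control_basis(tr, controls)
    rows <- net[net$treatment_id == tr$treatment_id, ]
    res <- interactive_effect(rows$co2_net, basis,
                              treatment_community = tr$community,
                              control_community = ctrl_comm)
    out[[tr$treatment_id]] <- tibble::tibble(
      treatment_id = tr$treatment_id, ie_mean = res$ie_mean, ie_sd = res$ie_sd,
      n = res$n, co2_controls = basis$co2_controls, basis = basis$basis,
      co2_treatment_mean = res$co2_treatment_mean,
      control_community_mismatch = res$control_community_mismatch)
  }
  dplyr::bind_rows(out)
}
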