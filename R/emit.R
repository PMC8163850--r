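# Measurement emission: maps simulator truth onto the tabular files the
# analysis pipeline reads, adding instrument noise (Gaussian in delta-space,
# multiplicative lognormal on concentrations). Deterministic under one root
# seed fanned out per emitted file.

fan_seed <- function(seed, k) {
  m <- 2147483647
  a <- (as.double(seed) %% m) * 48271  # < 2^53, exact in doubles
  as.integer((a %% m + k) %% m)
}

noisy_conc <- function(x, cv) {
  if (cv == 0) return(x)
  s2 <- log1p(cv^2)
  x * stats::rlnorm(length(x), meanlog = -s2 / 2, sdlog = sqrt(s2))
}

noisy_delta <- function(x, sd) {
  if (sd == 0) return(x)
  x + stats::rnorm(length(x), 0, sd)
}

#' Emit measurement tables from simulator truth
#'
#' Produces the full measurement set of an incubation study from one or
#' more [simulate_incubation()] runs: `design`, `co2` (initial/final
#' dissolved CO2 + delta-13C per replicate), `poc`, `doc`, `plfa`
#' (initial/final compound concentrations with delta-13C where above the
#' detection limit) and `mims` (daily monitoring-bottle ion currents).
#' With both noise terms zero the emitted values equal the truth exactly.
#'
#' @param truths A `sim_truth` or list of them (one per treatment).
#' @param seed Root seed; defaults to the first config's seed. The same
#'   seed yields identical tables.
#' @param noise Noise list overriding the configs'
#'   (`delta_sd_permil`, `conc_cv`); `NULL` uses the config values.
#' @return Named list of tibbles: `design`, `co2`, `poc`, `doc`, `plfa`,
#'   `mims`, `truth` (combined daily series), `plfa_truth`.
#' @export
emit_measurements <- function(truths, seed = NULL, noise = NULL) {
  if (inherits(truths, "sim_truth")) truths <- list(truths)
  cfg1 <- truths[[1]]$config
  if (is.null(seed)) seed <- cfg1$seed
  if (is.null(noise)) noise <- cfg1$noise
  dsd <- noise$delta_sd_permil; cv <- noise$conc_cv

  design <- dplyr::bind_rows(lapply(truths, function(x) x$treatment))
  co2 <- list(); poc <- list(); doc <- list(); plfa <- list(); mims <- list()

  for (j in seq_along(truths)) {
    tru <- truths[[j]]
    cfg <- tru$config
    tr <- tru$treatment
    reps <- seq_len(tr$n_replicates)
    fin <- tru$final
    day0 <- tru$series$day[1]; day1 <- fin$day

    # dissolved CO2: initial bottles see only the background pool
    co2[[j]] <- tibble::tibble(
      treatment_id = tr$treatment_id,
      replicate = rep(reps, 2),
      day = rep(c(day0, day1), each = length(reps)),
      conc_umol_l = c(rep(cfg$co2_bg_umol_l, length(reps)),
                      rep(fin$co2_dissolved, length(reps))),
      delta13C_permil = c(rep(atom_to_delta(cfg$f13_bg), length(reps)),
                          rep(fin$delta13_co2_dissolved, length(reps))),
      temperature_C = cfg$temperature_c)

    ini <- tru$series[1, ]
    poc[[j]] <- tibble::tibble(
      treatment_id = tr$treatment_id,
      replicate = rep(reps, 2),
      phase = rep(c("initial", "final"), each = length(reps)),
      day = rep(c(day0, day1), each = length(reps)),
      poc_umol_l = c(rep(ini$poc, length(reps)), rep(fin$poc, length(reps))),
      delta13C_permil = c(rep(ini$delta13_poc, length(reps)),
                          rep(fin$delta13_poc, length(reps))))

    doc[[j]] <- tibble::tibble(
      treatment_id = tr$treatment_id,
      replicate = rep(reps, 2),
      day = rep(c(day0, day1), each = length(reps)),
      doc_mg_l = c(rep(ini$doc_mg, length(reps)), rep(fin$doc_mg, length(reps))))

    pl <- tru$plfa
    plfa[[j]] <- tibble::tibble(
      treatment_id = pl$treatment_id[rep(seq_len(nrow(pl)), each = length(reps))],
      replicate = rep(reps, times = nrow(pl)),
      phase = pl$phase[rep(seq_len(nrow(pl)), each = length(reps))],
      compound = pl$compound[rep(seq_len(nrow(pl)), each = length(reps))],
      conc = pl$conc_ng_l[rep(seq_len(nrow(pl)), each = length(reps))],
      delta13C_permil = pl$delta13C[rep(seq_len(nrow(pl)), each = length(reps))])

    g <- cfg$mims_gain
    mims[[j]] <- tibble::tibble(
      day = tru$series$day,
      treatment_id = tr$treatment_id,
      i32 = g$g32 * tru$series$o2,
      i40 = g$g40 * cfg$ar_umol_l,
      i44 = g$g44 * tru$series$co2_dissolved_12,
      i45 = g$g44 * tru$series$co2_dissolved_13)
  }

  co2 <- dplyr::bind_rows(co2); poc <- dplyr::bind_rows(poc)
  doc <- dplyr::bind_rows(doc); plfa <- dplyr::bind_rows(plfa)
  mims <- dplyr::bind_rows(mims)

  # one fanned seed per file keeps files independently reproducible
  set.seed(fan_seed(seed, 1L))
  co2$conc_umol_l <- noisy_conc(co2$conc_umol_l, cv)
  co2$delta13C_permil <- noisy_delta(co2$delta13C_permil, dsd)
  set.seed(fan_seed(seed, 2L))
  poc$poc_umol_l <- noisy_conc(poc$poc_umol_l, cv)
  poc$delta13C_permil <- noisy_delta(poc$delta13C_permil, dsd)
  set.seed(fan_seed(seed, 3L))
  doc$doc_mg_l <- noisy_conc(doc$doc_mg_l, cv)
  set.seed(fan_seed(seed, 4L))
  plfa$conc <- noisy_conc(plfa$conc, cv)
  plfa$delta13C_permil <- noisy_delta(plfa$delta13C_permil, dsd)
  plfa$delta13C_permil[plfa$conc < cfg1$plfa_delta_min_ng] <- NA_real_
  set.seed(fan_seed(seed, 5L))
  for (ch in c("i32", "i40", "i44", "i45")) mims[[ch]] <- noisy_conc(mims[[ch]], cv)

  list(design = design, co2 = co2, poc = poc, doc = doc, plfa = plfa,
       mims = mims,
       truth = dplyr::bind_rows(lapply(truths, function(x) x$series)),
       plfa_truth = dplyr::bind_rows(lapply(truths, function(x) x$plfa)))
}

#' Simulate a whole incubation study
#'
#' Runs [simulate_incubation()] for every scenario preset and emits the
#' measurement tables.
#'
#' @param presets Output of [scenario_presets()].
#' @param seed Root seed for measurement noise (also stored in the configs).
#' @param noise `TRUE` for the configured noise, `FALSE` for noise-free
#'   emission, or a noise list.
#' @param dir Optional directory: the tables are also written as CSV
#'   (`design.csv`, `co2.csv`, `poc.csv`, `doc.csv`, `plfa.csv`,
#'   `mims.csv`, `truth.csv`).
#' @return List with `truths` (named `sim_truth` list) and `measurements`
#'   (the [emit_measurements()] list).
#' @export
simulate_study <- function(presets = scenario_presets(), seed = 1L,
                           noise = TRUE, dir = NULL) {
  truths <- lapply(presets, function(p) {
    cfg <- p$config
    cfg$seed <- seed
    simulate_incubation(cfg, p$treatment)
  })
  nz <- if (isTRUE(noise)) NULL
        else if (isFALSE(noise)) list(delta_sd_permil = 0, conc_cv = 0)
        else noise
  meas <- emit_measurements(truths, seed = seed, noise = nz)
  if (!is.null(dir)) write_measurements(meas, dir)
  list(truths = truths, measurements = meas)
}

#' Write / read the measurement tables as CSV
#'
#' @param meas An [emit_measurements()] list.
#' @param dir Directory (created if absent).
#' @return `write_measurements()` returns the file paths invisibly;
#'   `read_measurements()` returns the list of tibbles.
#' @export
write_measurements <- function(meas, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c("design", "co2", "poc", "doc", "plfa", "mims", "truth")
  paths <- file.path(dir, paste0(files, ".csv"))
  for (i in seq_along(files)) readr::write_csv(meas[[files[i]]], paths[i])
  invisible(paths)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(dir) {
  files <- c("design", "co2", "poc", "doc", "plfa", "mims", "truth")
  out <- lapply(files, function(f) {
    p <- file.path(dir, paste0(f, ".csv"))
    if (file.exists(p)) readr::read_csv(p, show_col_types = FALSE) else NULL
  })
  stats::setNames(out, files)
}
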