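# Assay readout simulation: predicted amplicons become gel lanes or melt
# profiles, readouts become per-specimen species calls, cohorts of calls
# become concordance statistics, and dilution series become standard-curve
# fits (slope, efficiency, R^2).

#' Virtual agarose gel
#'
#' Band migration is an affine map of `-log10(length)` normalized to the
#' ladder extremes (longest ladder rung migrates 0, shortest 1), so
#' migration strictly decreases with fragment length. Bands in the same
#' lane closer than `merge_tolerance` nt are annotated as co-migrating.
#'
#' @param lanes Tibble with columns lane, length (one row per band), or a
#'   named list of length vectors.
#' @param ladder Ladder rung lengths in nt.
#' @param merge_tolerance Same-lane bands within this many nt are flagged
#'   co-migrating (default 10).
#' @return A `gel_lanes` tibble: lane, length, migration, co_migrating,
#'   bands sorted by migration within lane; ladder kept as an attribute.
#' @export
virtual_gel <- function(lanes, ladder = c(100, 200, 300, 400, 500, 700, 1000),
                        merge_tolerance = 10) {
  if (!length(ladder)) abort("empty ladder")
  if (is.list(lanes) && !is.data.frame(lanes)) {
    lanes <- purrr::imap(lanes, ~tibble(lane = .y, length = .x)) |> bind_rows()
  }
  lanes <- as_tibble(lanes)
  if (any(lanes$length < 50)) abort("bands shorter than 50 nt do not resolve")
  lo <- -log10(max(ladder))
  hi <- -log10(min(ladder))
  mig <- (-log10(lanes$length) - lo) / (hi - lo)
  out <- lanes |>
    mutate(migration = mig) |>
    group_by(.data$lane) |>
    mutate(co_migrating = purrr::map_lgl(seq_along(.data$length), function(i)
      any(abs(.data$length[-i] - .data$length[i]) <= merge_tolerance))) |>
    ungroup() |>
    arrange(.data$lane, .data$migration)
  attr(out, "ladder") <- sort(ladder)
  class(out) <- c("gel_lanes", class(out))
  out
}

#' @export
autoplot.gel_lanes <- function(object, ...) {
  ladder <- attr(object, "ladder")
  lo <- -log10(max(ladder))
  hi <- -log10(min(ladder))
  ldf <- tibble(lane = "ladder", length = ladder,
                migration = (-log10(ladder) - lo) / (hi - lo))
  df <- bind_rows(ldf, tibble(lane = object$lane, length = object$length,
                              migration = object$migration))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lane, y = .data$migration)) +
    ggplot2::geom_tile(width = 0.6, height = 0.012, fill = "grey15") +
    ggplot2::geom_text(ggplot2::aes(label = .data$length), hjust = -0.4,
                       size = 2.8, data = ldf) +
    ggplot2::scale_y_reverse(limits = c(1.05, -0.05)) +
    ggplot2::labs(x = NULL, y = "relative migration",
                  title = "virtual 2% agarose gel") +
    ggplot2::theme_minimal()
}

melt_grid <- function() seq(60, 95, by = 0.3)

#' Synthetic melt-curve profile
#'
#' The -dF/dT signal is modeled as a sum of unit-height Gaussian peaks
#' centered at each product's predicted Tm, sampled on the instrument
#' acquisition grid (60 to 95 deg C in 0.3 deg C steps). Peaks are then
#' re-detected by a local-maximum scan; for well-separated products the
#' detected Tm agrees with the input within half a grid step (0.15 deg C).
#' Equal-height Gaussians merge into a single maximum when their centers
#' are closer than 2*sigma, which is why melt-mode panels enforce a
#' product-Tm separation floor.
#'
#' @param amplicons Numeric vector of product Tm values, or an amplicon
#'   tibble with a product_tm column.
#' @param peak_sigma Gaussian peak width in deg C (default 0.8).
#' @param min_peak_height Local maxima below this are ignored.
#' @return A `melt_profile`: list with `grid` (tibble temperature, signal),
#'   `peaks` (tibble tm, height) and `sigma`.
#' @export
melt_profile <- function(amplicons, peak_sigma = 0.8,
                         min_peak_height = 0.05) {
  tms <- if (is.data.frame(amplicons)) amplicons$product_tm else amplicons
  tms <- tms[!is.na(tms)]
  grid <- melt_grid()
  if (length(tms) && any(tms <= 60 | tms >= 95)) {
    warn(sprintf("product Tm outside the (60, 95) acquisition window: %s",
                 paste(round(tms[tms <= 60 | tms >= 95], 2), collapse = ", ")))
  }
  signal <- rep(0, length(grid))
  for (tm in tms) {
    signal <- signal + exp(-(grid - tm)^2 / (2 * peak_sigma^2))
  }
  peaks <- detect_melt_peaks(grid, signal, min_peak_height)
  structure(list(grid = tibble(temperature = grid, signal = signal),
                 peaks = peaks, sigma = peak_sigma),
            class = "melt_profile")
}

detect_melt_peaks <- function(grid, signal, min_peak_height = 0.05) {
  n <- length(signal)
  if (n < 3L || all(signal == 0)) return(tibble(tm = double(), height = double()))
  is_peak <- vapply(2:(n - 1L), function(i) {
    signal[i] >= signal[i - 1L] && signal[i] > signal[i + 1L] &&
      signal[i] >= min_peak_height
  }, TRUE)
  idx <- which(is_peak) + 1L
  tibble(tm = grid[idx], height = signal[idx])
}

#' @export
print.melt_profile <- function(x, ...) {
  cat(sprintf("<melt_profile> sigma %.2f; %d peak(s): %s\n", x$sigma,
              nrow(x$peaks), paste(round(x$peaks$tm, 2), collapse = ", ")))
  invisible(x)
}

#' @export
autoplot.melt_profile <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$temperature, y = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::geom_vline(xintercept = object$peaks$tm, linetype = "dashed",
                        colour = "firebrick", linewidth = 0.3) +
    ggplot2::labs(x = "temperature (°C)", y = "-dF/dT (arbitrary)",
                  title = "synthetic melt profile") +
    ggplot2::theme_minimal()
}

#' Call the species of one specimen from an assay readout
#'
#' Gel mode: exactly one observed band within `band_tolerance` nt of
#' exactly one expected amplicon length calls that species; no bands call
#' "no-amplification"; anything else is "ambiguous". Melt mode applies the
#' same logic to melt peaks with `peak_tolerance` deg C against the
#' panel's expected product Tm values.
#'
#' @param observation Numeric band lengths (gel) / peak Tm values (melt),
#'   or a `melt_profile`.
#' @param panel A `primer_panel` with populated expectations.
#' @param band_tolerance Band match tolerance, nt (default 15).
#' @param peak_tolerance Peak match tolerance, deg C (default 0.4).
#' @param specimen_id,declared_species Carried into the returned call.
#' @return One-row tibble: specimen_id, declared_species, called_species,
#'   evidence.
#' @export
call_species <- function(observation, panel, band_tolerance = 15,
                         peak_tolerance = 0.4,
                         specimen_id = NA_character_,
                         declared_species = NA_character_) {
  if (inherits(observation, "melt_profile")) {
    observation <- observation$peaks$tm
  }
  if (panel$mode == "melt") {
    expect <- panel$expected$product_tm
    tol <- peak_tolerance
  } else {
    expect <- panel$expected$length
    tol <- band_tolerance
  }
  species <- panel$expected$species
  observation <- observation[!is.na(observation)]
  call <- "ambiguous"
  evidence <- NA_real_
  if (length(observation) == 0L) {
    call <- "no-amplification"
  } else if (length(observation) == 1L) {
    hit <- which(abs(expect - observation) <= tol)
    if (length(hit) == 1L) {
      call <- species[hit]
      evidence <- observation
    }
  }
  tibble(specimen_id = specimen_id, declared_species = declared_species,
         called_species = call, evidence = evidence)
}

#' Call every specimen from multiplex predictions
#'
#' Groups an amplicon table by template and applies [call_species()] to
#' each specimen's band lengths (gel) or product Tm values (melt).
#' Specimens absent from the amplicon table are called
#' "no-amplification".
#'
#' @param amplicons Output of [simulate_multiplex()].
#' @param panel The `primer_panel` used.
#' @param specimens Tibble id, declared_species covering the cohort
#'   (includes specimens that did not amplify).
#' @param ... Tolerances passed to [call_species()].
#' @return Tibble of calls, one row per specimen.
#' @export
call_specimens <- function(amplicons, panel, specimens, ...) {
  specimens <- as_tibble(specimens)
  purrr::map_dfr(seq_len(nrow(specimens)), function(i) {
    id <- specimens$id[i]
    amps <- amplicons[amplicons$template_id == id, ]
    obs <- if (panel$mode == "melt") amps$product_tm else amps$length
    call_species(obs, panel, specimen_id = id,
                 declared_species = specimens$declared_species[i], ...)
  })
}

#' Concordance statistics for a cohort of assay calls
#'
#' One-vs-rest sensitivity and specificity per panel species, panel-level
#' minima, concordant counts and the ids of discordant specimens. A call
#' is concordant when it equals the declared species, or equals
#' "no-amplification" for declared species outside the panel (the
#' negative-control expectation).
#'
#' @param calls Tibble of calls from [call_specimens()]; every row needs a
#'   declared_species.
#' @param panel_species Character vector of panel species; defaults to the
#'   declared labels seen.
#' @return A `concordance_summary`; `tidy()` gives the per-species
#'   confusion table, `glance()` the panel-level one-row summary.
#' @export
concordance_stats <- function(calls, panel_species = NULL) {
  calls <- as_tibble(calls)
  if (!nrow(calls)) abort("empty call list")
  if (anyNA(calls$declared_species)) {
    abort("every call needs a declared_species")
  }
  panel_species <- sort(panel_species %||%
                          setdiff(unique(calls$declared_species), NA))
  declared <- ifelse(calls$declared_species %in% panel_species,
                     calls$declared_species, "non-target")
  per <- purrr::map_dfr(panel_species, function(sp) {
    tp <- sum(declared == sp & calls$called_species == sp)
    fn <- sum(declared == sp & calls$called_species != sp)
    fp <- sum(declared != sp & calls$called_species == sp)
    tn <- sum(declared != sp & calls$called_species != sp)
    tibble(species = sp, tp = tp, fn = fn, fp = fp, tn = tn,
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
  expected_call <- ifelse(declared == "non-target", "no-amplification",
                          declared)
  concordant <- calls$called_species == expected_call
  structure(list(
    per_species = per,
    n_total = nrow(calls),
    n_concordant = sum(concordant),
    discordant_ids = calls$specimen_id[!concordant],
    min_sensitivity = min(per$sensitivity, na.rm = TRUE),
    min_specificity = min(per$specificity, na.rm = TRUE)),
    class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf(
    "<concordance_summary> %d/%d concordant; min sensitivity %.3f, min specificity %.3f\n",
    x$n_concordant, x$n_total, x$min_sensitivity, x$min_specificity))
  print(x$per_species)
  if (length(x$discordant_ids)) {
    cat("discordant:", paste(x$discordant_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.concordance_summary <- function(x, ...) x$per_species

#' @export
glance.concordance_summary <- function(x, ...) {
  tibble(n_total = x$n_total, n_concordant = x$n_concordant,
         min_sensitivity = x$min_sensitivity,
         min_specificity = x$min_specificity)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(concentration):
#' `efficiency = 10^(-1/slope) - 1`, so the perfect-doubling slope
#' `-1/log10(2) = -3.3219` gives 100% efficiency.
#'
#' @param points Tibble with columns conc (template amount, e.g. ng) and
#'   ct (threshold cycle); at least 3 points spanning at least 2 log10
#'   units of concentration.
#' @return A `standard_curve_fit` with slope, intercept, efficiency,
#'   r_squared; supports `tidy()`, `glance()` and `autoplot()`.
#' @export
fit_standard_curve <- function(points) {
  points <- as_tibble(points)
  if (nrow(points) < 3L) abort("need at least 3 dilution points")
  if (any(points$conc <= 0)) abort("concentrations must be positive")
  span <- diff(range(log10(points$conc)))
  if (span == 0) abort("zero variance in concentration")
  if (span < 2) abort("dilution series must span at least 2 log10 units")
  fit <- lm(ct ~ log10(conc), data = points)
  slope <- unname(coef(fit)[2])
  structure(list(points = points,
                 slope = slope,
                 intercept = unname(coef(fit)[1]),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 model = fit),
            class = "standard_curve_fit")
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<standard_curve_fit> slope %.4f, efficiency %.1f%%, R^2 %.4f (%d points)\n",
    x$slope, 100 * x$efficiency, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' @export
tidy.standard_curve_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "log10(conc)"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.standard_curve_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         efficiency = x$efficiency, r_squared = x$r_squared,
         n = nrow(x$points))
}

#' @export
autoplot.standard_curve_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = log10(.data$conc), y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "log10 concentration", y = "Ct",
                  subtitle = sprintf("slope %.3f, E %.1f%%, R² %.4f",
                                     object$slope, 100 * object$efficiency,
                                     object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Simulate a serial-dilution Ct series
#'
#' Generates Ct values `intercept - slope_true * log10(conc) + N(0, sd)`
#' for a 10-fold dilution ladder, the design used for standard-curve
#' validation (10 ng down to 1 pg).
#'
#' @param concs Concentrations (default `10^(1:-3)`: 10 ng to 1 pg).
#' @param efficiency True amplification efficiency (1 = perfect doubling).
#' @param intercept Ct at 1 unit of template.
#' @param noise_sd Gaussian Ct noise, cycles.
#' @param seed Optional seed.
#' @return Tibble conc, ct.
#' @export
simulate_dilution_series <- function(concs = 10^seq(1, -3),
                                     efficiency = 1, intercept = 30,
                                     noise_sd = 0, seed = NULL) {
  slope_true <- -1 / log10(1 + efficiency)
  gen <- function() {
    tibble(conc = concs,
           ct = intercept + slope_true * log10(concs) +
             stats::rnorm(length(concs), 0, noise_sd))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
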