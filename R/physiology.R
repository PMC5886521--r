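# Formula masses (g/mol, standard atomic weights) and the maximal ethanol
# stoichiometry per mole of substrate under homoethanologenic fermentation:
# each glucose equivalent gives at most 2 ethanol; cellobiose carries two
# glucose units; a pentose gives 5/3 ethanol via the phosphoketolase-free
# stoichiometric maximum.
ETHANOL_MASS <- 46.069
SUBSTRATE_TABLE <- tibble::tibble(
  substrate = c("cellobiose", "glucose", "xylose"),
  formula_mass = c(342.297, 180.156, 150.130),
  mol_ethanol_max = c(4, 2, 5 / 3)
)

#' Theoretical ethanol yield coefficient of a substrate
#'
#' Grams of ethanol per gram of substrate at the stoichiometric maximum:
#' `mol_ethanol_max * 46.069 / formula_mass`. For cellobiose this is
#' 4 x 46.069 / 342.297 = 0.54 g/g (2 dp); full precision is used
#' internally.
#'
#' @param substrate One of `"cellobiose"`, `"glucose"`, `"xylose"`
#'   (vectorized).
#' @return Numeric vector of g ethanol per g substrate.
#' @examples
#' round(theoretical_yield_coeff("cellobiose"), 2)
#' @export
theoretical_yield_coeff <- function(substrate) {
  substrate <- tolower(substrate)
  unknown <- setdiff(unique(substrate), SUBSTRATE_TABLE$substrate)
  if (length(unknown) > 0) {
    abort(sprintf("unknown substrate '%s'; supported: %s.", unknown[1],
                  paste(SUBSTRATE_TABLE$substrate, collapse = ", ")),
          class = "rex_input_error")
  }
  i <- match(substrate, SUBSTRATE_TABLE$substrate)
  SUBSTRATE_TABLE$mol_ethanol_max[i] * ETHANOL_MASS /
    SUBSTRATE_TABLE$formula_mass[i]
}

#' Maximal moles of ethanol per mole of substrate
#'
#' @inheritParams theoretical_yield_coeff
#' @return Numeric vector (2 for glucose: one glucose equivalent can be
#'   converted into at most two ethanol).
#' @export
ethanol_stoichiometry <- function(substrate) {
  theoretical_yield_coeff(substrate)  # validates the name
  SUBSTRATE_TABLE$mol_ethanol_max[match(tolower(substrate),
                                        SUBSTRATE_TABLE$substrate)]
}

#' Percent theoretical ethanol yield of fermentation records
#'
#' Yield is ethanol produced divided by the stoichiometric maximum for the
#' substrate actually consumed:
#' `100 * ethanol / ((substrate_initial - substrate_final) * coeff)`.
#'
#' @param rec Tibble with columns `substrate`, `substrate_initial`,
#'   `substrate_final` and `ethanol` (g/L); other columns pass through.
#' @return `rec` with `consumed`, `coeff_g_per_g`, `percent_theoretical` and
#'   `flag_over_100` appended.
#' @export
percent_theoretical_yield <- function(rec) {
  assert_columns(rec, c("substrate", "substrate_initial", "substrate_final",
                        "ethanol"), "fermentation table")
  if (any(rec$substrate_final > rec$substrate_initial)) {
    abort("substrate_final may not exceed substrate_initial.",
          class = "rex_input_error")
  }
  out <- mutate(rec,
                consumed = .data$substrate_initial - .data$substrate_final,
                coeff_g_per_g = theoretical_yield_coeff(.data$substrate))
  if (any(out$consumed <= 0)) {
    abort("substrate consumed must be positive to express a yield.",
          class = "rex_input_error")
  }
  mutate(out,
         percent_theoretical = 100 * .data$ethanol /
           (.data$consumed * .data$coeff_g_per_g),
         flag_over_100 = .data$percent_theoretical > 100)
}

# closed-form rolling least squares of y on x over every length-`window`
# run of consecutive points; returns slopes and r^2 (r^2 = 1 where the fit
# is exact with zero spread, e.g. a constant series)
rolling_ls <- function(x, y, window) {
  n <- length(x)
  k <- window
  csx <- cumsum(x); csy <- cumsum(y)
  csxx <- cumsum(x * x); csyy <- cumsum(y * y); csxy <- cumsum(x * y)
  win_sum <- function(cs) cs[k:n] - c(0, cs)[1:(n - k + 1)]
  sx <- win_sum(csx); sy <- win_sum(csy)
  sxx <- win_sum(csxx); syy <- win_sum(csyy); sxy <- win_sum(csxy)
  ssxx <- sxx - sx^2 / k
  ssyy <- syy - sy^2 / k
  ssxy <- sxy - sx * sy / k
  slope <- ssxy / ssxx
  ssr <- pmax(ssyy - ssxy^2 / ssxx, 0)
  r2 <- ifelse(ssyy > .Machine$double.eps * pmax(abs(syy), 1),
               1 - ssr / ssyy, 1)
  list(start = seq_len(n - k + 1L), slope = slope, r2 = r2)
}

#' Fit the maximal specific growth rate from an OD600 time series
#'
#' The maximal growth rate is the steepest slope of `ln(OD600)` over all
#' sliding windows of `window` consecutive points whose log-linear fit has
#' `r^2 >= min_r2`; windows containing non-positive OD values are excluded.
#' If no window meets the guard, the slope of the best-fitting window is
#' returned with a warning. The maximum OD is taken from a 3-point running
#' median of the series, which suppresses single-point spikes.
#'
#' @param series Tibble with `time_h` (strictly increasing) and `od600`
#'   columns.
#' @param window Number of points per regression window (default 5).
#' @param min_r2 Goodness-of-fit guard on accepted windows (default 0.98).
#' @return Object of class `growth_fit`: `mu_max` (1/h, floored at 0),
#'   `max_od`, `window_start` (h), `r_squared`, plus the per-window fits.
#' @export
fit_growth <- function(series, window = 5, min_r2 = 0.98) {
  assert_columns(series, c("time_h", "od600"), "OD series")
  t <- series$time_h
  od <- series$od600
  if (any(diff(t) <= 0)) {
    abort("`time_h` must be strictly increasing.", class = "rex_input_error")
  }
  if (any(od < 0)) {
    abort("`od600` must be non-negative.", class = "rex_input_error")
  }
  if (all(od == 0)) {
    abort("all-zero OD series cannot be fitted.", class = "rex_input_error")
  }
  if (length(t) < window) {
    abort(sprintf("need at least %d points for a %d-point window.",
                  window, window), class = "rex_input_error")
  }

  y <- log(od)
  fits <- rolling_ls(t, y, window)
  # a window is usable only if every OD in it is positive
  pos_ok <- od > 0
  cs <- cumsum(pos_ok)
  all_pos <- (cs[window:length(od)] -
                c(0, cs)[1:(length(od) - window + 1)]) == window
  usable <- all_pos & is.finite(fits$slope)
  if (!any(usable)) {
    abort("no usable regression window (too many zero OD values).",
          class = "rex_input_error")
  }
  win <- tibble(
    window_start = t[fits$start[usable]],
    slope = fits$slope[usable],
    r_squared = fits$r2[usable]
  )
  passing <- filter(win, .data$r_squared >= min_r2)
  if (nrow(passing) == 0) {
    warn(sprintf(
      "no window reached r^2 >= %.3g; using the best-fitting window instead.",
      min_r2))
    passing <- win[which.max(win$r_squared), ]
  }
  best <- passing[which.max(passing$slope), ]

  smoothed <- if (length(od) >= 3) runmed(od, 3) else od
  structure(
    list(mu_max = max(best$slope, 0),
         max_od = max(smoothed),
         window_start = best$window_start,
         r_squared = best$r_squared,
         window = window,
         min_r2 = min_r2,
         windows = win,
         series = as_tibble(series[, c("time_h", "od600")])),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> mu_max = ", signif(x$mu_max, 4), " 1/h, max OD600 = ",
      signif(x$max_od, 4), "\n", sep = "")
  cat("  steepest ", x$window, "-point window starts at ",
      signif(x$window_start, 4), " h (r^2 = ", signif(x$r_squared, 4), ")\n",
      sep = "")
  invisible(x)
}

#' @rdname fit_growth
#' @param x,object A `growth_fit` object.
#' @param ... Unused.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) x$windows

#' @rdname fit_growth
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(mu_max = x$mu_max, max_od = x$max_od, window_start = x$window_start,
         r_squared = x$r_squared, window = x$window)
}

#' @rdname fit_growth
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  s <- object$series
  t0 <- object$window_start
  in_win <- s$time_h >= t0 &
    s$time_h <= s$time_h[min(which(s$time_h >= t0)) + object$window - 1]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time_h, y = .data$od600)) +
    ggplot2::geom_point(size = 0.6, colour = "grey40") +
    ggplot2::geom_point(data = s[in_win, ], colour = "firebrick", size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time (h)", y = "OD600 (log scale)",
      title = sprintf("mu_max = %.3g 1/h, max OD = %.3g",
                      object$mu_max, object$max_od)
    ) +
    ggplot2::theme_minimal()
}

#' Fit growth curves for every strain in a long-format OD table
#'
#' @param od_table Tibble with `strain`, `time_h`, `od600`.
#' @inheritParams fit_growth
#' @return Tibble with one row per strain: `strain`, `mu_max`, `max_od`,
#'   `window_start`, `r_squared`.
#' @export
fit_growth_curves <- function(od_table, window = 5, min_r2 = 0.98) {
  assert_columns(od_table, c("strain", "time_h", "od600"), "OD table")
  od_table |>
    group_by(.data$strain) |>
    dplyr::group_modify(function(df, key) {
      glance(fit_growth(df, window = window, min_r2 = min_r2))[
        , c("mu_max", "max_od", "window_start", "r_squared")]
    }) |>
    ungroup()
}

#' Alcohol dehydrogenase specific activity
#'
#' One enzyme unit (U) is the formation of 1 umol of product per minute.
#' From the photometric cofactor signal: rate (umol/min) =
#' `slope * reaction_volume / (extinction_coeff * path_length)`; the
#' specific activity divides by the protein mass in the assay. The slope is
#' the magnitude of the A340 change per minute (cofactor oxidation, a
#' decreasing absorbance, enters as a positive slope).
#'
#' @param assay Tibble with `slope` (delta A340/min), and optionally
#'   `extinction_coeff` (mM^-1 cm^-1, default 6.22 for NADH/NADPH at
#'   340 nm), `path_length` (cm, default 1), `reaction_volume` (mL, default
#'   1), `protein_mass` (mg, required), `cofactor`.
#' @return `assay` with `rate_umol_min` and `specific_activity` (U/mg)
#'   appended.
#' @export
adh_specific_activity <- function(assay) {
  assert_columns(assay, c("slope", "protein_mass"), "ADH assay")
  defaults <- list(extinction_coeff = 6.22, path_length = 1, reaction_volume = 1)
  for (nm in names(defaults)) {
    if (!nm %in% names(assay)) assay[[nm]] <- defaults[[nm]]
  }
  if (any(assay$protein_mass <= 0)) {
    abort("`protein_mass` must be positive.", class = "rex_input_error")
  }
  if (any(assay$extinction_coeff <= 0 | assay$path_length <= 0 |
            assay$reaction_volume <= 0)) {
    abort("extinction coefficient, path length and volume must be positive.",
          class = "rex_input_error")
  }
  mutate(assay,
         rate_umol_min = abs(.data$slope) * .data$reaction_volume /
           (.data$extinction_coeff * .data$path_length),
         specific_activity = .data$rate_umol_min / .data$protein_mass)
}

#' Fit a qPCR standard curve
#'
#' Least-squares line of Cq on log10(copies). The amplification efficiency
#' follows from the slope: `efficiency = 10^(-1/slope) - 1`, so the ideal
#' dilution-series slope of -log2(10) ~ -3.32 per decade gives efficiency 1.
#'
#' @param points Tibble with `copies` (> 0) and `cq` columns; at least two
#'   distinct copy levels.
#' @return Object of class `standard_curve` with `slope` (Cq per decade),
#'   `intercept` (Cq at 1 copy), `efficiency`, `r_squared` and the fitted
#'   points.
#' @export
fit_standard_curve <- function(points) {
  assert_columns(points, c("copies", "cq"), "standards")
  if (any(points$copies <= 0)) {
    abort("`copies` must all be positive.", class = "rex_input_error")
  }
  if (!all(is.finite(points$cq))) {
    abort("`cq` must be finite.", class = "rex_input_error")
  }
  if (length(unique(points$copies)) < 2) {
    abort("at least two distinct copy levels are required.",
          class = "rex_input_error")
  }
  fit <- lm(cq ~ log10(copies), data = points)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) {
    warn("standard-curve slope is non-negative; Cq should fall as copies rise.")
  }
  sst <- sum((points$cq - mean(points$cq))^2)
  ssr <- sum(stats::residuals(fit)^2)
  structure(
    list(slope = slope,
         intercept = unname(coef(fit)[1]),
         efficiency = 10^(-1 / slope) - 1,
         r_squared = if (sst > 0) 1 - ssr / sst else 1,
         points = as_tibble(points[, c("copies", "cq")]),
         fit = fit),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> Cq = ", signif(x$intercept, 5), " ",
      ifelse(x$slope < 0, "-", "+"), " ", signif(abs(x$slope), 5),
      " * log10(copies)\n", sep = "")
  cat("  efficiency = ", signif(x$efficiency, 4), ", r^2 = ",
      signif(x$r_squared, 5), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x,object A `standard_curve` object.
#' @param ... Unused.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_standard_curve
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         efficiency = x$efficiency, r_squared = x$r_squared,
         n = nrow(x$points))
}

#' @rdname fit_standard_curve
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = log10(.data$copies), y = .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10(copies)", y = "Cq",
      title = sprintf("slope %.3f, efficiency %.3f",
                      object$slope, object$efficiency)
    ) +
    ggplot2::theme_minimal()
}

#' Absolute qPCR quantification normalized to a reference gene
#'
#' Copies are recovered from each well through the target's standard curve,
#' `copies = 10^((cq - intercept)/slope)`; replicate wells are averaged on
#' the copy scale (per sample when a `sample` column is present); each
#' target's mean copies are finally expressed as a ratio to the reference
#' target.
#'
#' @param samples Tibble with `target` and `cq` columns and optionally
#'   `sample`.
#' @param curves A single [fit_standard_curve()] object shared by all
#'   targets, or a named list of one per target.
#' @param reference_target Name of the normalizer gene (default `"recA"`).
#' @return Tibble with (optional `sample`,) `target`, `copies` and `ratio`
#'   (copies relative to the reference within the same sample).
#' @export
quantify_and_normalize <- function(samples, curves, reference_target = "recA") {
  assert_columns(samples, c("target", "cq"), "qPCR table")
  if (!reference_target %in% samples$target) {
    abort(sprintf("reference target '%s' is missing from the qPCR table.",
                  reference_target), class = "rex_input_error")
  }
  curve_for <- function(target) {
    if (inherits(curves, "standard_curve")) return(curves)
    if (is.list(curves) && target %in% names(curves)) return(curves[[target]])
    abort(sprintf("no standard curve supplied for target '%s'.", target),
          class = "rex_input_error")
  }
  samples$copies <- purrr::map2_dbl(samples$target, samples$cq, function(tg, cq) {
    cv <- curve_for(tg)
    10^((cq - cv$intercept) / cv$slope)
  })
  grouping <- intersect(c("sample", "target"), names(samples))
  means <- samples |>
    group_by(dplyr::across(dplyr::all_of(grouping))) |>
    summarise(copies = mean(.data$copies), .groups = "drop")
  if ("sample" %in% grouping) {
    means |>
      group_by(.data$sample) |>
      mutate(ratio = .data$copies /
               .data$copies[.data$target == reference_target]) |>
      ungroup()
  } else {
    mutate(means, ratio = .data$copies /
             .data$copies[.data$target == reference_target])
  }
}
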