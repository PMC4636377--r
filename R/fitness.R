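# Selection-coefficient estimation from competition assays: endpoint count
# ratios, count corrections, log-ratio slope fits of fluorescence series,
# and concentration-response comparisons.

#' Selection coefficient from endpoint counts
#'
#' `s = (ln(U_f/R_f) - ln(U_i/R_i)) / T`, the per-generation log-ratio
#' change of the unlabeled strain U against the labeled reference R over
#' `T` generations of reference proliferation. Relative fitness is
#' `1 + s`.
#'
#' @param record A `competition_record` (see [simulate_competition()]) or
#'   any list with `U_i`, `R_i`, `U_f`, `R_f`, `T`.
#' @return List `s`, `fitness`.
#' @export
endpoint_selection <- function(record) {
  cts <- unlist(record[c("U_i", "R_i", "U_f", "R_f")])
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("counts must be positive; add explicit pseudo-counts if a class ",
         "was not observed", call. = FALSE)
  if (record$T <= 0) stop("T must be positive", call. = FALSE)
  s <- (log(record$U_f / record$R_f) - log(record$U_i / record$R_i)) /
    record$T
  list(s = s, fitness = 1 + s)
}

#' Correct competition counts for scoring artefacts
#'
#' Two corrections: (i) a fraction `phi` of labeled reference cells score
#' as non-fluorescent and are mis-counted as unlabeled — reference counts
#' are inflated to `R / (1 - phi)` and the same cells removed from the
#' unlabeled pool; (ii) the fluorescent marker burdens the reference by a
#' per-generation cost `s_m >= 0`, which is added to the raw selection
#' coefficient (the raw estimate under-states the mutant's advantage by
#' the marker cost).
#'
#' @param record A competition record.
#' @param phi Labeled, non-fluorescent fraction in `[0, 1)`.
#' @param s_m Marker cost per generation.
#' @return List `record` (corrected counts), `s_raw`, `s` (corrected),
#'   `fitness`.
#' @export
correct_counts <- function(record, phi = 0, s_m = 0) {
  if (phi < 0 || phi >= 1) stop("phi must be in [0, 1)", call. = FALSE)
  corr <- record
  for (side in c("i", "f")) {
    R <- record[[paste0("R_", side)]]
    U <- record[[paste0("U_", side)]]
    R2 <- R / (1 - phi)
    U2 <- U - (R2 - R)
    if (U2 <= 0)
      stop("correction makes U_", side, " non-positive", call. = FALSE)
    corr[[paste0("R_", side)]] <- R2
    corr[[paste0("U_", side)]] <- U2
  }
  s_raw <- endpoint_selection(corr)$s
  list(record = corr, s_raw = s_raw, s = s_raw + s_m,
       fitness = 1 + s_raw + s_m)
}

#' Background-corrected log fluorescence ratio
#'
#' @param series data.frame with `generation`, `ch1`, `ch2` and optional
#'   `bg1`, `bg2` background columns.
#' @return The series with an `ln_ratio` column (`ln((ch1-bg1)/(ch2-bg2))`).
#' @export
fluorescence_ratio <- function(series) {
  bg1 <- if (is.null(series$bg1)) 0 else series$bg1
  bg2 <- if (is.null(series$bg2)) 0 else series$bg2
  a <- series$ch1 - bg1
  b <- series$ch2 - bg2
  if (any(a <= 0 | b <= 0))
    stop("signals must exceed background", call. = FALSE)
  series$ln_ratio <- log(a / b)
  series
}

# robust slope of ln_ratio ~ generation; IRLS bisquare for >= 4 points,
# ordinary least squares otherwise
fit_slope <- function(generation, ln_ratio) {
  if (length(generation) < 2) stop("need >= 2 time points", call. = FALSE)
  if (length(generation) >= 4) {
    fit <- suppressWarnings(
      MASS::rlm(ln_ratio ~ generation, psi = MASS::psi.bisquare,
                maxit = 100))
    unname(stats::coef(fit)["generation"])
  } else {
    unname(stats::coef(stats::lm(ln_ratio ~ generation))["generation"])
  }
}

#' Selection coefficient from fluorescence time series
#'
#' Per replicate series, the slope of the background-corrected log channel
#' ratio against generations is fitted robustly (iteratively reweighted
#' least squares with bisquare weights; plain least squares below 4
#' points). Series measured in the swapped dye orientation
#' (`orientation = "mutant-in-channel-2"`) have their slopes negated so
#' all replicates estimate the mutant-over-reference coefficient; the
#' slope of a parental-vs-parental control is subtracted to remove marker
#' effects. The estimate is the mean across replicate slopes with its
#' standard error.
#'
#' @param series_list List of series data.frames; each needs `generation`,
#'   either `ln_ratio` or channel columns (see [fluorescence_ratio()]),
#'   and an `orientation` attribute or column (default
#'   `"mutant-in-channel-1"`).
#' @param control Optional control series (same format) whose fitted slope
#'   is subtracted.
#' @return A `selection_estimate` list: `s`, `se`, `n`, `fitness`,
#'   `slopes` (per replicate, orientation-aligned), `control_slope`,
#'   `dye_swap` (TRUE when both orientations are present).
#' @export
slope_fitness <- function(series_list, control = NULL) {
  get_orient <- function(s) {
    o <- attr(s, "orientation")
    if (is.null(o) && !is.null(s$orientation)) o <- s$orientation[1]
    if (is.null(o)) o <- "mutant-in-channel-1"
    o
  }
  prep <- function(s) if (is.null(s$ln_ratio)) fluorescence_ratio(s) else s
  slopes <- vapply(series_list, function(s) {
    sl <- fit_slope(prep(s)$generation, prep(s)$ln_ratio)
    if (get_orient(s) == "mutant-in-channel-2") -sl else sl
  }, numeric(1))
  control_slope <- if (!is.null(control))
    fit_slope(prep(control)$generation, prep(control)$ln_ratio) else 0
  slopes <- slopes - control_slope
  orients <- vapply(series_list, get_orient, "")
  dye_swap <- length(unique(orients)) > 1
  if (!dye_swap && length(series_list) > 1)
    message("all series share one dye orientation (no dye swap)")
  est <- list(
    s = mean(slopes),
    se = if (length(slopes) > 1)
      stats::sd(slopes) / sqrt(length(slopes)) else NA_real_,
    n = length(slopes),
    fitness = 1 + mean(slopes),
    slopes = slopes,
    control_slope = control_slope,
    dye_swap = dye_swap
  )
  class(est) <- "selection_estimate"
  est
}

#' Concentration-response comparison of selection coefficients
#'
#' One-way analysis of variance of replicate selection coefficients across
#' conditions (e.g. ethanol concentrations), plus per-condition Welch
#' t-test contrasts against a reference condition.
#'
#' @param estimates data.frame with columns `condition` and `s` (one row
#'   per replicate).
#' @param reference Reference condition label (default `"0"`).
#' @return List `anova` (`F`, `p`, `df`), `contrasts` (data.frame
#'   `condition`, `mean_diff`, `p`).
#' @export
concentration_response <- function(estimates, reference = "0") {
  stopifnot(all(c("condition", "s") %in% names(estimates)))
  conds <- unique(as.character(estimates$condition))
  if (length(conds) < 2)
    stop("need at least two conditions", call. = FALSE)
  estimates$condition <- factor(estimates$condition)
  if (stats::var(estimates$s) == 0) {
    an <- data.frame(`F value` = c(0, NA), `Pr(>F)` = c(1, NA),
                     Df = c(length(conds) - 1,
                            nrow(estimates) - length(conds)),
                     check.names = FALSE)
  } else {
    fit <- stats::aov(s ~ condition, data = estimates)
    an <- summary(fit)[[1]]
  }
  others <- setdiff(conds, reference)
  contrasts <- do.call(rbind, lapply(others, function(cc) {
    a <- estimates$s[estimates$condition == cc]
    b <- estimates$s[estimates$condition == reference]
    tt <- if (stats::sd(c(a, b)) == 0)
      list(p.value = 1) else stats::t.test(a, b)
    data.frame(condition = cc, mean_diff = mean(a) - mean(b),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  list(
    anova = list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                 df = an[["Df"]]),
    contrasts = contrasts
  )
}
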