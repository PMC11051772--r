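# Batch-culture kinetics: maximal exponential growth rate, stationary-phase
# detection, and per-interval ingestion / clearance / biovolume-specific
# clearance rates for a grazer feeding on a bacterial prey.

#' Construct a grazer-prey culture time series
#'
#' @param times sampling times in hours, strictly increasing. Intervals
#'   outside the conventional 12-24 h flow-cytometry cadence trigger a
#'   warning.
#' @param grazer grazer concentrations (cells mL^-1), one per time.
#' @param prey prey concentrations (cells mL^-1), one per time.
#' @param control_prey optional grazer-free control prey series.
#' @param grazer_biovolume grazer cell biovolume in um^3 (used for
#'   biovolume-specific clearance).
#' @param replicate_id,treatment optional identifiers; `treatment` is a
#'   list such as `list(light = "high", nutrient = "low")`.
#' @return object of class `culture_ts`.
#' @export
culture_time_series <- function(times, grazer, prey, control_prey = NULL,
                                grazer_biovolume = 100,
                                replicate_id = "r1", treatment = list()) {
  stopifnot(length(times) == length(grazer), length(times) == length(prey))
  if (length(times) < 2L) stop("need at least 2 time points")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (any(dt < 12 - 1e-9 | dt > 24 + 1e-9))
    warning("sampling interval(s) outside the conventional 12-24 h range")
  if (any(grazer < 0) || any(prey < 0)) stop("concentrations must be non-negative")
  if (!is.null(control_prey) && length(control_prey) != length(times))
    stop("control_prey must align with times")
  if (grazer_biovolume <= 0) stop("grazer_biovolume must be positive")
  structure(list(times = times, grazer = grazer, prey = prey,
                 control_prey = control_prey,
                 grazer_biovolume = grazer_biovolume,
                 replicate_id = replicate_id, treatment = treatment),
            class = "culture_ts")
}

#' @export
print.culture_ts <- function(x, ...) {
  cat(sprintf("Culture time series '%s': %d time points over %g h\n",
              x$replicate_id, length(x$times), diff(range(x$times))))
  cat(sprintf("  grazer %g -> %g, prey %g -> %g cells/mL%s\n",
              x$grazer[1L], tail(x$grazer, 1L), x$prey[1L], tail(x$prey, 1L),
              if (is.null(x$control_prey)) "" else " (+ grazer-free control)"))
  invisible(x)
}

#' Read culture time series from CSV
#'
#' Expected columns: `time_h,replicate,grazer_per_ml,prey_per_ml` and
#' optionally `control_prey_per_ml,light,nutrient`.
#'
#' @param path path to the CSV.
#' @param grazer_biovolume grazer biovolume in um^3.
#' @return named list of `culture_ts`, one per replicate.
#' @export
read_culture_csv <- function(path, grazer_biovolume = 100) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "replicate", "grazer_per_ml", "prey_per_ml")
  if (!all(need %in% names(df)))
    stop("culture file must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$replicate), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    culture_time_series(
      d$time_h, d$grazer_per_ml, d$prey_per_ml,
      control_prey = if ("control_prey_per_ml" %in% names(d)) d$control_prey_per_ml,
      grazer_biovolume = grazer_biovolume,
      replicate_id = as.character(d$replicate[1L]),
      treatment = list(light = d$light[1L], nutrient = d$nutrient[1L]))
  })
}

#' Maximal exponential growth rate
#'
#' The maximal ordinary-least-squares slope of ln(grazer concentration)
#' versus time over all contiguous windows of at least `window` points.
#' Windows containing zero or negative concentrations are skipped.
#'
#' @param ts a `culture_ts`.
#' @param window window length in points (>= 3).
#' @return list of class `growth_fit`: `mu_max` (h^-1), `mu_max_d` (d^-1),
#'   `window` (index range of the maximal window), `slopes` (one per valid
#'   window).
#' @export
exponential_growth_rate <- function(ts, window = 3L) {
  stopifnot(inherits(ts, "culture_ts"))
  window <- as.integer(window)
  if (window < 3L) stop("window must be at least 3 points")
  n <- length(ts$times)
  if (n < window) stop("fewer observations than the window length")
  slopes <- c(); starts <- c()
  for (i in seq_len(n - window + 1L)) {
    idx <- i:(i + window - 1L)
    g <- ts$grazer[idx]
    if (any(g <= 0)) next
    slopes <- c(slopes, unname(coef(lm(log(g) ~ ts$times[idx]))[2L]))
    starts <- c(starts, i)
  }
  if (!length(slopes))
    stop("no window of ", window, " consecutive positive grazer counts")
  best <- which.max(slopes)
  structure(list(mu_max = slopes[best],
                 mu_max_d = slopes[best] * 24,
                 window = c(starts[best], starts[best] + window - 1L),
                 slopes = slopes),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Maximal exponential growth rate: %.4g h^-1 (%.4g d^-1), points %d-%d\n",
              x$mu_max, x$mu_max_d, x$window[1L], x$window[2L]))
  invisible(x)
}

#' Detect onset of the grazer stationary phase
#'
#' Returns the first observation index from which every subsequent local
#' ln-slope of the grazer series stays below `mu_threshold`. If growth
#' never drops below the threshold the index is the series end, meaning all
#' intervals count as pre-stationary; for a series stationary throughout it
#' is 1.
#'
#' @param ts a `culture_ts`.
#' @param mu_threshold stationary threshold on the local growth rate
#'   (h^-1); the default 0.005 is about a tenth of typical maximal rates.
#' @return integer index into `ts$times`.
#' @export
detect_stationary <- function(ts, mu_threshold = 0.005) {
  stopifnot(inherits(ts, "culture_ts"))
  n <- length(ts$times)
  if (n < 3L) stop("need at least 3 observations")
  g <- pmax(ts$grazer, .Machine$double.xmin)
  s <- diff(log(g)) / diff(ts$times)       # local slope per interval
  below <- s < mu_threshold
  # first index i such that intervals i .. n-1 are all below threshold
  run <- rev(cumprod(rev(below)))          # 1 where the tail is all below
  onset <- which(run == 1)[1L]
  if (is.na(onset)) n else onset
}

#' Ingestion and clearance rates from a culture time series
#'
#' Per sampling interval, the ingestion rate is the prey removed divided by
#' the interval length and the mean grazer concentration,
#' `I = (P_t - P_{t+1}) / (dt * mean(G_t, G_{t+1}))` (prey grazer^-1
#' h^-1); the clearance rate divides ingestion by the mean prey
#' concentration, `C = I / mean(P_t, P_{t+1})` (mL grazer^-1 h^-1); the
#' biovolume-specific clearance is `C * 1e12 / V` body volumes grazer^-1
#' h^-1 (1 mL = 1e12 um^3). Summary means cover only intervals before the
#' grazer's stationary onset, and are reported both with and without
#' negative-ingestion intervals (prey growth exceeding grazing).
#'
#' @param ts a `culture_ts`.
#' @param control_correction subtract the prey's net change observed in the
#'   grazer-free control over the matching interval before computing
#'   removal (requires `control_prey`). Default `FALSE`.
#' @param mu_threshold stationary threshold passed to
#'   [detect_stationary()].
#' @param clip_negative set negative per-interval ingestion to zero rather
#'   than only flagging it. Default `FALSE`.
#' @param window window length for the growth-rate fit.
#' @return object of class `rate_estimates` with the per-interval table
#'   (`intervals`), `mu_max` / `mu_max_d`, `stationary_onset`, means of
#'   ingestion, clearance (mL and nL), and biovolume-specific clearance
#'   over pre-stationary intervals (`mean_*`), and the same means excluding
#'   negative intervals (`mean_*_nonneg`).
#' @export
grazing_rates <- function(ts, control_correction = FALSE,
                          mu_threshold = 0.005, clip_negative = FALSE,
                          window = 3L) {
  stopifnot(inherits(ts, "culture_ts"))
  n <- length(ts$times)
  if (n < 2L) stop("need at least 2 time points")
  if (control_correction && is.null(ts$control_prey))
    stop("control_correction requires a control_prey series")
  dt <- diff(ts$times)
  if (any(dt <= 0)) stop("non-positive sampling interval")
  P0 <- ts$prey[-n]; P1 <- ts$prey[-1L]
  G0 <- ts$grazer[-n]; G1 <- ts$grazer[-1L]
  removal <- P0 - P1
  if (control_correction) {
    C0 <- ts$control_prey[-n]; C1 <- ts$control_prey[-1L]
    # expected prey without grazing follows the control's relative change
    removal <- P0 * (C1 / C0) - P1
  }
  gbar <- (G0 + G1) / 2
  pbar <- (P0 + P1) / 2
  skip <- gbar == 0
  if (any(skip))
    warning("interval(s) with zero grazers skipped: ",
            paste(which(skip), collapse = ", "))
  ingestion <- ifelse(skip, NA_real_, removal / (dt * gbar))
  if (clip_negative) ingestion <- pmax(ingestion, 0)
  clearance <- ifelse(pbar > 0, ingestion / pbar, NA_real_)
  bv <- clearance * 1e12 / ts$grazer_biovolume
  onset <- if (n >= 3L) detect_stationary(ts, mu_threshold) else n
  pre <- seq_len(n - 1L) < onset
  use <- pre & !is.na(ingestion)
  mean_or_na <- function(x, w) if (any(w)) mean(x[w]) else NA_real_
  nonneg <- use & ingestion >= 0
  gr <- tryCatch(exponential_growth_rate(ts, window = window),
                 error = function(e) NULL)
  structure(list(
    intervals = data.frame(t0 = ts$times[-n], t1 = ts$times[-1L],
                           ingestion = ingestion, clearance_ml = clearance,
                           bv_clearance = bv,
                           pre_stationary = pre,
                           negative = !is.na(ingestion) & ingestion < 0),
    mu_max = if (is.null(gr)) NA_real_ else gr$mu_max,
    mu_max_d = if (is.null(gr)) NA_real_ else gr$mu_max_d,
    stationary_onset = onset,
    n_intervals_used = sum(use),
    mean_ingestion = mean_or_na(ingestion, use),
    mean_clearance_ml = mean_or_na(clearance, use),
    mean_clearance_nl = mean_or_na(clearance, use) * 1e6,
    mean_bv_clearance = mean_or_na(bv, use),
    mean_ingestion_nonneg = mean_or_na(ingestion, nonneg),
    mean_clearance_ml_nonneg = mean_or_na(clearance, nonneg),
    grazer_biovolume = ts$grazer_biovolume,
    replicate_id = ts$replicate_id,
    treatment = ts$treatment),
    class = "rate_estimates")
}

#' @export
print.rate_estimates <- function(x, ...) {
  cat(sprintf("Grazing rate estimates ('%s', %d pre-stationary interval(s))\n",
              x$replicate_id, x$n_intervals_used))
  cat(sprintf("  mu_max: %.4g h^-1 (%.4g d^-1)\n", x$mu_max, x$mu_max_d))
  cat(sprintf("  mean ingestion: %.4g prey grazer^-1 h^-1\n", x$mean_ingestion))
  cat(sprintf("  mean clearance: %.4g mL (%.4g nL) grazer^-1 h^-1\n",
              x$mean_clearance_ml, x$mean_clearance_nl))
  cat(sprintf("  biovolume-specific clearance: %.4g body volumes h^-1\n",
              x$mean_bv_clearance))
  if (any(x$intervals$negative))
    cat("  note: negative-ingestion interval(s) present; *_nonneg means exclude them\n")
  invisible(x)
}

#' @export
summary.rate_estimates <- function(object, ...) {
  print(object)
  cat("\nPer-interval rates:\n")
  print(object$intervals, row.names = FALSE)
  invisible(object)
}
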