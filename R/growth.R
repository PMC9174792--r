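## Plate-reader growth-curve handling: blank correction, growth call,
## kinetic metrics, and the two-medium comparison statistics.

#' Construct a well time series
#'
#' @param time time points in hours, strictly increasing, `time[1] >= 0`
#' @param od OD600 readings, same length as `time`, all finite
#' @param well well identifier
#' @param medium medium label (e.g. `"NLDM"`, `"R2A"`)
#' @param isolate isolate label, or `"control"` for uninoculated wells
#' @return object of class `well_series`
#' @export
well_series <- function(time, od, well = "", medium = "", isolate = "") {
  stopifnot(length(time) == length(od), length(time) >= 2)
  if (any(!is.finite(time)) || any(!is.finite(od))) {
    stop_data("well ", well, ": time and od must be finite")
  }
  if (time[1] < 0 || any(diff(time) <= 0)) {
    stop_data("well ", well, ": time must be strictly increasing and >= 0")
  }
  structure(list(time = as.numeric(time), od = as.numeric(od),
                 well = well, medium = medium, isolate = isolate),
            class = "well_series")
}

#' @export
print.well_series <- function(x, ...) {
  cat("<well_series> well=", x$well, " isolate=", x$isolate,
      " medium=", x$medium, " n=", length(x$time),
      " t=[", x$time[1], ",", x$time[length(x$time)], "]h\n", sep = "")
  invisible(x)
}

#' Subtract an uninoculated-medium control from a culture series
#'
#' Pointwise OD difference; culture metadata is preserved. When the two
#' time grids differ the control is linearly interpolated onto the culture
#' grid if `interpolate = TRUE`, otherwise mismatched grids are an error.
#' Negative corrected values are kept (they carry information about blank
#' drift); downstream log-transforms apply their own floor.
#'
#' @param culture,control `well_series` objects
#' @param interpolate allow linear interpolation of the control
#' @return corrected `well_series`
#' @export
blank_correct <- function(culture, control, interpolate = FALSE) {
  stopifnot(inherits(culture, "well_series"), inherits(control, "well_series"))
  if (length(culture$time) == length(control$time) &&
      all(culture$time == control$time)) {
    ctrl_od <- control$od
  } else if (interpolate) {
    if (min(culture$time) < min(control$time) ||
        max(culture$time) > max(control$time)) {
      stop_data("control grid does not span culture grid; cannot interpolate")
    }
    ctrl_od <- stats::approx(control$time, control$od,
                             xout = culture$time)$y
  } else {
    stop_data("time grids differ between culture and control ",
              "(set interpolate = TRUE to interpolate the control)")
  }
  well_series(culture$time, culture$od - ctrl_od,
              well = culture$well, medium = culture$medium,
              isolate = culture$isolate)
}

#' Growth call and kinetic metrics for one well
#'
#' The growth call follows the max-minus-initial rule: `delta_od =
#' max(od) - od[1]`, and the well `grew` when `delta_od >= threshold`
#' (default 0.05; the threshold itself counts as growth). The maximum
#' specific growth rate `mu_max` (per hour) is the steepest slope of a
#' sliding-window linear fit to `log(od)` (window of `window` consecutive
#' points), and the lag is where that tangent line crosses the initial
#' log-OD level. For the log transform only, OD values below `floor` are
#' clipped to `floor`; `delta_od` always uses raw values.
#'
#' @param series a blank-corrected `well_series`
#' @param threshold growth-call threshold on `delta_od` (OD600 units)
#' @param window sliding-window width in points (>= 3) for the rate fit
#' @param floor positive clip value applied before taking logs
#' @param min_od quantification limit: windows containing any OD below
#'   this are excluded from the rate fit, since log-slopes of
#'   blank-corrected readings near zero reflect noise, not growth
#' @return data.frame with one row: `well`, `isolate`, `medium`,
#'   `delta_od`, `grew`, `max_od`, `mu_max`, `lag`; `mu_max`/`lag` are NA
#'   when the series is shorter than the window, and `lag` is NA when the
#'   well did not grow
#' @export
growth_metrics <- function(series, threshold = 0.05, window = 5L,
                           floor = 1e-4, min_od = 0.01) {
  stopifnot(inherits(series, "well_series"), window >= 3, floor > 0)
  od <- series$od
  tt <- series$time
  delta_od <- max(od) - od[1]
  grew <- delta_od >= threshold
  mu_max <- NA_real_
  lag <- NA_real_
  n <- length(od)
  if (n >= window) {
    y <- log(pmax(od, floor))
    best_slope <- -Inf
    best <- NULL
    for (i in seq_len(n - window + 1L)) {
      idx <- i:(i + window - 1L)
      if (any(od[idx] < min_od)) next
      xs <- tt[idx]; ys <- y[idx]
      xc <- xs - mean(xs)
      sxx <- sum(xc^2)
      if (sxx == 0) next
      slope <- sum(xc * ys) / sxx
      if (slope > best_slope) {
        best_slope <- slope
        best <- c(slope = slope, intercept = mean(ys) - slope * mean(xs))
      }
    }
    if (is.finite(best_slope) && best_slope > 0) {
      mu_max <- best_slope
      if (grew) {
        y0 <- log(max(od[1], floor))
        lag <- max(0, (y0 - best[["intercept"]]) / best[["slope"]])
      }
    }
  }
  data.frame(well = series$well, isolate = series$isolate,
             medium = series$medium, delta_od = delta_od, grew = grew,
             max_od = max(od), mu_max = mu_max, lag = lag,
             stringsAsFactors = FALSE)
}

#' Per-isolate comparison of maximum growth between two media
#'
#' For each isolate with replicate maximum-OD measurements in both media,
#' performs a two-sample Welch t-test, reports the log2 ratio of mean
#' maximum OD (`medium_a` over `medium_b`), and adjusts p-values across
#' isolates by the Benjamini-Hochberg step-up rule. Isolates missing one
#' medium or with fewer than 2 replicates per medium are dropped with a
#' warning.
#'
#' @param max_ods data.frame with columns `isolate`, `medium`, `max_od`
#'   (one row per replicate well)
#' @param medium_a,medium_b the two medium labels to compare (numerator /
#'   denominator of the ratio)
#' @return data.frame: `isolate`, `mean_a`, `mean_b`, `log2_ratio`,
#'   `t`, `p`, `q`, `higher_in`
#' @export
compare_media <- function(max_ods, medium_a = "NLDM", medium_b = "R2A") {
  stopifnot(all(c("isolate", "medium", "max_od") %in% names(max_ods)))
  isolates <- unique(max_ods$isolate)
  rows <- list()
  dropped <- character(0)
  for (iso in isolates) {
    a <- max_ods$max_od[max_ods$isolate == iso & max_ods$medium == medium_a]
    b <- max_ods$max_od[max_ods$isolate == iso & max_ods$medium == medium_b]
    if (length(a) < 2 || length(b) < 2) {
      dropped <- c(dropped, iso)
      next
    }
    ma <- mean(a); mb <- mean(b)
    if (stats::var(a) + stats::var(b) == 0) {
      tstat <- 0; p <- if (ma == mb) 1 else 0
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      tstat <- unname(tt$statistic); p <- tt$p.value
    }
    rows[[length(rows) + 1]] <- data.frame(
      isolate = iso, mean_a = ma, mean_b = mb,
      log2_ratio = log2(ma / mb), t = tstat, p = p,
      stringsAsFactors = FALSE)
  }
  if (length(dropped)) {
    warning("excluded isolate(s) lacking >= 2 replicates in both media: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (!length(rows)) {
    stop_data("no isolate has >= 2 replicates in both media")
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$higher_in <- ifelse(out$log2_ratio > 0, medium_a,
                          ifelse(out$log2_ratio < 0, medium_b, "equal"))
  rownames(out) <- NULL
  out
}

#' Read a long-format plate file and its plate map
#'
#' The plate CSV has columns `well`, `time_h`, `od600`; the map TSV has
#' columns `well`, `isolate`, `medium`, `role` (`culture` or `control`).
#'
#' @param plate_csv path to the long-format readings CSV
#' @param map_tsv path to the plate-map TSV
#' @return named list of `well_series`, with map metadata attached
#' @export
read_plate <- function(plate_csv, map_tsv) {
  plate <- utils::read.csv(plate_csv, stringsAsFactors = FALSE)
  need <- c("well", "time_h", "od600")
  if (!all(need %in% names(plate))) {
    stop_data("plate file lacks column(s): ",
              paste(setdiff(need, names(plate)), collapse = ", "))
  }
  map <- read_tsv(map_tsv)
  need_m <- c("well", "isolate", "medium", "role")
  if (!all(need_m %in% names(map))) {
    stop_data("plate map lacks column(s): ",
              paste(setdiff(need_m, names(map)), collapse = ", "))
  }
  bad_role <- setdiff(unique(map$role), c("culture", "control"))
  if (length(bad_role)) {
    stop_data("plate map has unknown role(s): ",
              paste(bad_role, collapse = ", "))
  }
  wells <- lapply(unique(plate$well), function(w) {
    sub <- plate[plate$well == w, ]
    sub <- sub[order(sub$time_h), ]
    meta <- map[map$well == w, ]
    if (nrow(meta) != 1) stop_data("well '", w, "' missing from plate map")
    well_series(sub$time_h, sub$od600, well = w,
                medium = meta$medium,
                isolate = if (meta$role == "control") "control"
                          else meta$isolate)
  })
  names(wells) <- unique(plate$well)
  wells
}

#' Blank-correct and summarise every culture well of a plate
#'
#' Controls are averaged per medium (pointwise mean of all `"control"`
#' wells sharing the medium label) and subtracted from each culture well
#' of that medium before [growth_metrics()] is applied.
#'
#' @param wells named list of `well_series` from [read_plate()]
#' @param ... further arguments passed to [growth_metrics()] (e.g.
#'   `min_od`)
#' @inheritParams growth_metrics
#' @return data.frame of per-well growth summaries
#' @export
plate_growth_summary <- function(wells, threshold = 0.05, window = 5L,
                                 ...) {
  is_ctrl <- vapply(wells, function(w) identical(w$isolate, "control"),
                    logical(1))
  media <- unique(vapply(wells, `[[`, character(1), "medium"))
  ctrl_mean <- list()
  for (m in media) {
    cw <- wells[is_ctrl & vapply(wells, `[[`, character(1), "medium") == m]
    if (!length(cw)) stop_data("no control well for medium '", m, "'")
    tt <- cw[[1]]$time
    for (w in cw) {
      if (!identical(w$time, tt)) {
        stop_data("control wells for medium '", m,
                  "' are on different time grids")
      }
    }
    ctrl_mean[[m]] <- well_series(
      tt, rowMeans(vapply(cw, `[[`, numeric(length(tt)), "od")),
      well = paste0("ctrl-", m), medium = m, isolate = "control")
  }
  res <- lapply(wells[!is_ctrl], function(w) {
    growth_metrics(blank_correct(w, ctrl_mean[[w$medium]],
                                 interpolate = TRUE),
                   threshold = threshold, window = window, ...)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
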