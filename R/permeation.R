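#' Cumulative permeated amount from Franz-cell samples
#'
#' Converts sampled receptor concentrations into cumulative permeated
#' amounts with the standard sampling-and-replacement correction
#' \deqn{Q_n = C_n V_{receptor} + V_{sample} \sum_{i<n} C_i,}
#' which accounts for drug removed in earlier withdrawals. With
#' `v_sample = 0` this reduces to `C_n * v_receptor`. The operation is
#' linear in the concentrations and monotone for non-negative
#' concentrations.
#'
#' @param profile A data frame with columns `time_h` (strictly increasing)
#'   and `conc_ug_ml` (sampled receptor concentration, ug/ml, >= 0).
#' @param v_receptor Receptor chamber volume, ml. Default 15.
#' @param v_sample Withdrawn (and replaced) sample volume, ml. Default 1.
#' @return The input tibble with an added `q_ug` column of cumulative
#'   permeated micrograms.
#' @examples
#' prof <- tibble::tibble(time_h = 1:3, conc_ug_ml = 1)
#' cumulative_from_samples(prof)$q_ug # 15, 16, 17
#' @export
cumulative_from_samples <- function(profile, v_receptor = 15, v_sample = 1) {
  profile <- as_tibble(profile)
  if (!all(c("time_h", "conc_ug_ml") %in% names(profile))) {
    abort("`profile` needs columns `time_h` and `conc_ug_ml`.")
  }
  if (is.unsorted(profile$time_h, strictly = TRUE)) {
    abort("`time_h` must be strictly increasing.")
  }
  if (any(profile$conc_ug_ml < 0)) abort("concentrations must be >= 0.")
  if (v_receptor <= 0 || v_sample < 0) {
    abort("`v_receptor` must be > 0 and `v_sample` >= 0.")
  }
  cc <- profile$conc_ug_ml
  prior <- c(0, cumsum(cc)[-length(cc)])
  mutate(profile, q_ug = cc * v_receptor + v_sample * prior)
}

#' Steady-state flux from a cumulative permeation curve
#'
#' Fits a straight line to the linear portion of cumulative amount Q versus
#' time and reports the slope normalised by the diffusion area,
#' \eqn{J_{ss} = slope / area} (ug/cm^2/h), together with the lag time
#' `-intercept/slope` clipped at zero. By default the linear portion is
#' auto-detected as the contiguous window of at least `min_points` samples
#' maximising the R^2 of the line (ties: more points, then the later
#' window, since steady state is reached late); pass `window` (indices into
#' the profile) to override. Adding a constant to Q changes nothing
#' (slope-based); doubling the area halves the flux.
#'
#' @param profile A data frame with columns `time_h` and `q_ug` (cumulative
#'   permeated ug, non-decreasing).
#' @param area Effective diffusion area, cm^2. Default 0.5.
#' @param window Optional integer indices of the points to fit.
#' @param min_points Minimum window size for auto-detection. Default 3.
#' @return A `flux_fit`: list with `jss` (ug/cm^2/h), `slope` (ug/h),
#'   `intercept`, `lag_h`, `r_squared`, `window`, `area`, `data`.
#' @examples
#' prof <- tibble::tibble(time_h = c(3, 5, 11), q_ug = c(412, 845, 1557))
#' steady_state_flux(prof)$jss
#' @export
steady_state_flux <- function(profile, area = 0.5, window = NULL,
                              min_points = 3) {
  profile <- as_tibble(profile)
  if (!all(c("time_h", "q_ug") %in% names(profile))) {
    abort("`profile` needs columns `time_h` and `q_ug`.")
  }
  if (area <= 0) abort("`area` must be positive (cm^2).")
  np <- nrow(profile)
  if (is.null(window)) {
    if (np < min_points) abort("need at least `min_points` samples.")
    best <- NULL
    for (i in 1:(np - min_points + 1)) {
      for (j in (i + min_points - 1):np) {
        tt <- profile$time_h[i:j]
        qq <- profile$q_ug[i:j]
        if (diff(range(tt)) <= 0) next
        r2 <- window_r2(tt, qq)
        cand <- list(i = i, j = j, r2 = r2)
        if (is.null(best) ||
            r2 > best$r2 + 1e-12 ||
            (abs(r2 - best$r2) <= 1e-12 &&
             (j - i > best$j - best$i ||
              (j - i == best$j - best$i && i > best$i)))) {
          best <- cand
        }
      }
    }
    window <- best$i:best$j
  }
  if (length(window) < 2 ||
      diff(range(profile$time_h[window])) <= 0) {
    abort("degenerate window: zero time span.")
  }
  tt <- profile$time_h[window]
  qq <- profile$q_ug[window]
  fit <- lm(qq ~ tt)
  slope <- coef(fit)[["tt"]]
  intercept <- coef(fit)[["(Intercept)"]]
  if (slope <= 0) warn("non-positive slope: no net permeation in window.")
  lag <- if (slope > 0) max(0, -intercept / slope) else NA_real_
  structure(
    list(jss = slope / area, slope = slope, intercept = intercept,
         lag_h = lag, r_squared = window_r2(tt, qq),
         window = window, area = area, data = profile),
    class = "flux_fit"
  )
}

# R^2 of a straight-line fit, without summary.lm's perfect-fit warning
window_r2 <- function(tt, qq) {
  fit <- lm(qq ~ tt)
  tss <- sum((qq - mean(qq))^2)
  if (tss < 1e-24) return(1)
  max(0, 1 - sum(fit$residuals^2) / tss)
}

#' @export
print.flux_fit <- function(x, ...) {
  cat("<flux_fit> Jss = ", signif(x$jss, 4), " ug/cm^2/h (slope ",
      signif(x$slope, 4), " ug/h over ", length(x$window),
      " points), lag = ", signif(x$lag_h, 3), " h\n", sep = "")
  invisible(x)
}

#' @export
tidy.flux_fit <- function(x, ...) {
  tibble(term = c("jss", "slope", "intercept", "lag_h"),
         estimate = c(x$jss, x$slope, x$intercept, x$lag_h))
}

#' @export
glance.flux_fit <- function(x, ...) {
  tibble(jss = x$jss, slope = x$slope, lag_h = x$lag_h,
         r_squared = x$r_squared, n_window = length(x$window),
         area = x$area)
}

#' @export
autoplot.flux_fit <- function(object, ...) {
  d <- mutate(object$data,
              in_window = dplyr::row_number() %in% object$window)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$q_ug)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_window)) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey50"),
                                 guide = "none") +
    ggplot2::labs(x = "time (h)", y = "cumulative permeated (ug)",
                  title = paste0("Jss = ", signif(object$jss, 4),
                                 " ug/cm2/h"))
}
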