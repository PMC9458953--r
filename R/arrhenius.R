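#' Rate-temperature points for Arrhenius analysis
#'
#' Extracts `(temperature, rate)` pairs from a [stage_summaries()] table
#' (bulk compartment VSRR by default) in the form the fitting functions
#' expect.
#'
#' @param summaries A [stage_summaries()] tibble.
#' @param rate_col Name of the rate column to use.
#' @param compartment Compartment to keep.
#' @return A tibble with `temp_C`, `temp_K`, `rate`.
#' @export
arrhenius_points <- function(summaries, rate_col = "vsrr_mmol_L_h",
                             compartment = "bulk") {
  summaries |>
    dplyr::filter(.data$compartment == .env$compartment) |>
    dplyr::transmute(
      temp_C = .data$temp_C,
      temp_K = celsius_to_kelvin(.data$temp_C),
      rate = .data[[rate_col]]
    )
}

as_rate_points <- function(points) {
  if (!all(c("temp_K", "rate") %in% names(points))) {
    if (all(c("temp_C", "rate") %in% names(points))) {
      points$temp_K <- celsius_to_kelvin(points$temp_C)
    } else {
      abort("`points` needs columns `temp_K` (or `temp_C`) and `rate`.",
        class = "lfcr_schema_error")
    }
  }
  if (!("temp_C" %in% names(points))) points$temp_C <- kelvin_to_celsius(points$temp_K)
  as_tibble(points)[c("temp_C", "temp_K", "rate")]
}

#' Fit one Arrhenius segment
#'
#' Ordinary least squares of `ln(rate)` on inverse absolute temperature.
#' The activation energy is `Ea = -slope * R` with `R = 8.314 J/(K.mol)`.
#' Points with non-positive rates are excluded with a warning (the log is
#' undefined); at least two usable points at distinct temperatures are
#' required. A two-point fit is exact (`R^2 = 1`).
#'
#' @param points Tibble with columns `temp_K` (or `temp_C`) and `rate`
#'   (mmol/L.h).
#' @return An `lfcr_arrhenius_segment`: list with `slope` (K), `intercept`
#'   (`ln(A)`), `Ea` (J/mol), `r_squared`, `n` and the fitted `points`.
#' @examples
#' fit_arrhenius_segment(tibble::tibble(temp_C = c(30, 15), rate = c(0.144, 0.0973)))
#' @export
fit_arrhenius_segment <- function(points) {
  pts <- as_rate_points(points)
  if (any(pts$rate <= 0)) {
    warn(sprintf("Excluding %d point(s) with non-positive rates from the Arrhenius fit.",
                 sum(pts$rate <= 0)))
    pts <- pts[pts$rate > 0, ]
  }
  if (nrow(pts) < 2 || length(unique(pts$temp_K)) < 2) {
    abort("Need at least two usable points at distinct temperatures.",
      class = "lfcr_insufficient_data_error")
  }
  x <- 1 / pts$temp_K
  y <- log(pts$rate)
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot < 1e-300) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      Ea = -unname(coef(fit)[2]) * R_GAS,
      r_squared = r2,
      rss = ss_res,
      n = nrow(pts),
      points = pts
    ),
    class = "lfcr_arrhenius_segment"
  )
}

#' @export
print.lfcr_arrhenius_segment <- function(x, ...) {
  cat(sprintf("<arrhenius segment> Ea = %.2f kJ/mol, R^2 = %.4f, n = %d\n",
              x$Ea / 1000, x$r_squared, x$n))
  invisible(x)
}

#' Critical temperature from two Arrhenius segments
#'
#' Intersection of the two fitted lines in `(1/T, ln k)` space:
#' `1/T* = (intercept_cold - intercept_warm) / (slope_warm - slope_cold)`.
#' The result is symmetric in the segment labels. Near-parallel segments
#' (slope difference below `1e-9` of the larger slope magnitude) raise an
#' error rather than returning a wildly extrapolated temperature.
#'
#' @param warm,cold `lfcr_arrhenius_segment` objects.
#' @return Critical temperature (K).
#' @export
intersect_segments <- function(warm, cold) {
  stopifnot(inherits(warm, "lfcr_arrhenius_segment"),
            inherits(cold, "lfcr_arrhenius_segment"))
  dslope <- warm$slope - cold$slope
  if (abs(dslope) < 1e-9 * max(abs(warm$slope), abs(cold$slope), 1)) {
    abort("Segments are (near-)parallel: no meaningful intersection.",
      class = "lfcr_parallel_error")
  }
  inv_t <- (cold$intercept - warm$intercept) / dslope
  if (inv_t <= 0) {
    abort("Segments intersect at a non-physical (non-positive) temperature.",
      class = "lfcr_parallel_error")
  }
  1 / inv_t
}

#' Segmented Arrhenius fit with critical-temperature estimation
#'
#' Fits `ln(rate)` against `1/T` in one or two segments. In `"fixed"` mode
#' the boundary temperature splits the data the way the study design does:
#' the warm segment uses all points at or above the boundary and the cold
#' segment all points at or below it, with the boundary point shared by
#' both. In `"auto"` mode every contiguous split of the
#' temperature-ordered points with at least two points per segment is
#' scored by pooled residual sum of squares and the minimum is taken, with
#' ties broken towards the warmest boundary. `"single"` fits one segment
#' and reports no critical temperature.
#'
#' @param points Tibble with `temp_K` (or `temp_C`) and `rate` columns.
#' @param mode `"auto"`, `"fixed"` or `"single"`.
#' @param boundary_temp_c Boundary temperature (degC) for `"fixed"` mode;
#'   must equal one of the data temperatures.
#' @return An `lfcr_arrhenius` object with elements `segment_warm`,
#'   `segment_cold` (NULL for single mode), `t_crit_K`, `t_crit_C`, `mode`
#'   and the input `points`. Use [tidy()], [glance()], [predict()] and
#'   [autoplot()] on it.
#' @examples
#' pts <- tibble::tibble(temp_C = c(30, 25, 20, 15, 10),
#'                       rate = c(0.144, 0.127, 0.111, 0.097, 0.060))
#' fit <- arrhenius_fit(pts, mode = "fixed", boundary_temp_c = 15)
#' glance(fit)
#' @export
arrhenius_fit <- function(points, mode = c("auto", "fixed", "single"),
                          boundary_temp_c = NULL) {
  mode <- match.arg(mode)
  pts <- as_rate_points(points)
  usable <- pts[pts$rate > 0, ]
  if (nrow(usable) < nrow(pts) && mode != "single") {
    warn(sprintf("Excluding %d point(s) with non-positive rates from the Arrhenius fit.",
                 nrow(pts) - nrow(usable)))
  }

  if (mode == "single") {
    seg <- fit_arrhenius_segment(pts)
    return(new_arrhenius(seg, NULL, NA_real_, mode, pts))
  }

  if (mode == "fixed") {
    if (is.null(boundary_temp_c)) {
      abort("`boundary_temp_c` is required in fixed mode.", class = "lfcr_config_error")
    }
    if (!any(abs(usable$temp_C - boundary_temp_c) < 1e-9)) {
      abort("Boundary temperature must be one of the data temperatures.",
        class = "lfcr_config_error")
    }
    warm <- fit_arrhenius_segment(usable[usable$temp_C >= boundary_temp_c - 1e-9, ])
    cold <- fit_arrhenius_segment(usable[usable$temp_C <= boundary_temp_c + 1e-9, ])
  } else {
    if (nrow(usable) < 4) {
      abort("Auto mode needs at least four points with positive rates.",
        class = "lfcr_insufficient_data_error")
    }
    ord <- usable[order(-usable$temp_K), ]  # warmest first
    n <- nrow(ord)
    best <- NULL
    for (i in 2:(n - 2)) {
      w <- fit_arrhenius_segment(ord[1:i, ])
      c_ <- fit_arrhenius_segment(ord[(i + 1):n, ])
      rss <- w$rss + c_$rss
      if (is.null(best) || rss < best$rss - 1e-12 * max(1, best$rss)) {
        best <- list(warm = w, cold = c_, rss = rss)
      }
    }
    warm <- best$warm; cold <- best$cold
  }

  t_crit_K <- tryCatch(intersect_segments(warm, cold),
    lfcr_parallel_error = function(e) {
      warn("Segments are (near-)parallel; no critical temperature reported.")
      NA_real_
    }
  )
  coldest_warm <- min(warm$points$temp_K)
  warmest_cold <- max(cold$points$temp_K)
  if (is.finite(t_crit_K) &&
      (t_crit_K > coldest_warm + 1 || t_crit_K < warmest_cold - 1)) {
    warn(sprintf(
      "T_crit (%.1f K) lies outside the boundary region [%.1f, %.1f] K.",
      t_crit_K, warmest_cold, coldest_warm
    ))
  }
  if (cold$Ea < warm$Ea) {
    warn("Cold-segment Ea below warm-segment Ea: no stress response detected.")
  }
  new_arrhenius(warm, cold, t_crit_K, mode, pts)
}

new_arrhenius <- function(warm, cold, t_crit_K, mode, points) {
  structure(
    list(
      segment_warm = warm,
      segment_cold = cold,
      t_crit_K = t_crit_K,
      t_crit_C = kelvin_to_celsius(t_crit_K),
      mode = mode,
      points = points
    ),
    class = "lfcr_arrhenius"
  )
}

#' @export
print.lfcr_arrhenius <- function(x, ...) {
  cat(sprintf("<lfcr_arrhenius> mode = %s\n", x$mode))
  cat(sprintf("  warm: Ea = %.1f kJ/mol, R^2 = %.3f (n = %d)\n",
              x$segment_warm$Ea / 1000, x$segment_warm$r_squared, x$segment_warm$n))
  if (!is.null(x$segment_cold)) {
    cat(sprintf("  cold: Ea = %.1f kJ/mol, R^2 = %.3f (n = %d)\n",
                x$segment_cold$Ea / 1000, x$segment_cold$r_squared, x$segment_cold$n))
    cat(sprintf("  T_crit = %.2f K (%.2f degC)\n", x$t_crit_K, x$t_crit_C))
  }
  invisible(x)
}

#' Predict a rate from a fitted Arrhenius model
#'
#' Evaluates the segment whose temperature range contains the query: the
#' stress (cold) segment below the critical temperature, the warm segment
#' at or above it. A single-segment model uses its one segment everywhere.
#'
#' @param object An `lfcr_arrhenius` model.
#' @param temp_c Temperature(s) in degC.
#' @param ... Unused.
#' @return Predicted rate(s) (mmol/L.h).
#' @export
predict.lfcr_arrhenius <- function(object, temp_c, ...) {
  if (is.null(object$segment_warm)) {
    abort("Model has no fitted segments.", class = "lfcr_state_error")
  }
  t_k <- celsius_to_kelvin(temp_c)
  eval_seg <- function(seg, tk) exp(seg$intercept + seg$slope / tk)
  if (is.null(object$segment_cold) || !is.finite(object$t_crit_K)) {
    return(eval_seg(object$segment_warm, t_k))
  }
  ifelse(t_k >= object$t_crit_K,
         eval_seg(object$segment_warm, t_k),
         eval_seg(object$segment_cold, t_k))
}

#' @describeIn arrhenius_fit Per-segment coefficients as a tibble
#'   (`segment`, `slope_K`, `intercept`, `Ea_kJ_mol`, `r_squared`, `n`).
#' @param x An `lfcr_arrhenius` object.
#' @param ... Unused.
#' @method tidy lfcr_arrhenius
#' @export
tidy.lfcr_arrhenius <- function(x, ...) {
  segs <- list(warm = x$segment_warm)
  if (!is.null(x$segment_cold)) segs$cold <- x$segment_cold
  purrr::imap_dfr(segs, function(s, nm) {
    tibble(
      segment = nm, slope_K = s$slope, intercept = s$intercept,
      Ea_kJ_mol = s$Ea / 1000, r_squared = s$r_squared, n = s$n
    )
  })
}

#' @describeIn arrhenius_fit One-row model summary (`mode`, `t_crit_K`,
#'   `t_crit_C`, `Ea_warm_kJ_mol`, `Ea_cold_kJ_mol`, `pooled_rss`).
#' @method glance lfcr_arrhenius
#' @export
glance.lfcr_arrhenius <- function(x, ...) {
  tibble(
    mode = x$mode,
    t_crit_K = x$t_crit_K,
    t_crit_C = x$t_crit_C,
    Ea_warm_kJ_mol = x$segment_warm$Ea / 1000,
    Ea_cold_kJ_mol = if (is.null(x$segment_cold)) NA_real_ else x$segment_cold$Ea / 1000,
    pooled_rss = x$segment_warm$rss +
      if (is.null(x$segment_cold)) 0 else x$segment_cold$rss
  )
}

#' Plot-ready Arrhenius table
#'
#' The display convention for Arrhenius plots in this field uses a
#' `1000/T` abscissa; regression itself is done on `1/T` in Kelvin.
#'
#' @param x An `lfcr_arrhenius` object.
#' @return Tibble with `temp_C`, `inv_T_1000`, `ln_rate`.
#' @export
arrhenius_plot_table <- function(x) {
  pts <- x$points[x$points$rate > 0, ]
  tibble(
    temp_C = pts$temp_C,
    inv_T_1000 = 1000 / pts$temp_K,
    ln_rate = log(pts$rate)
  )
}

#' @describeIn arrhenius_fit Arrhenius plot (ln rate against 1000/T) with
#'   fitted segments and the critical temperature marked.
#' @param object An `lfcr_arrhenius` object.
#' @method autoplot lfcr_arrhenius
#' @export
autoplot.lfcr_arrhenius <- function(object, ...) {
  tab <- arrhenius_plot_table(object)
  seg_lines <- function(seg, nm) {
    rng <- range(1 / seg$points$temp_K)
    tibble(
      segment = nm,
      inv_T_1000 = 1000 * seq(rng[1], rng[2], length.out = 20),
      ln_rate = seg$intercept + seg$slope * seq(rng[1], rng[2], length.out = 20)
    )
  }
  lines <- seg_lines(object$segment_warm, "warm")
  if (!is.null(object$segment_cold)) {
    lines <- dplyr::bind_rows(lines, seg_lines(object$segment_cold, "cold"))
  }
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$inv_T_1000, y = .data$ln_rate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(
      data = lines,
      ggplot2::aes(colour = .data$segment), linewidth = 0.8
    ) +
    ggplot2::labs(
      x = expression(1000 / T ~ (K^-1)),
      y = expression(ln ~ italic(k) ~ (mmol / L.h)),
      colour = "segment"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$segment_cold) && is.finite(object$t_crit_K)) {
    p <- p + ggplot2::geom_vline(
      xintercept = 1000 / object$t_crit_K, linetype = "dashed", colour = "grey40"
    )
  }
  p
}
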