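#' Enumerate virtual stenting strategies for tandem (serial) lesions
#'
#' With serial lesions a pressure wire cannot apportion the aggregate FFR
#' between the individual stenoses, because the downstream lesion caps the
#' achievable hyperemic flow. Virtually "removing" each stenosis in turn —
#' deploying a virtual stent over it and re-solving — reveals the true
#' contribution of each lesion. This routine solves the untreated baseline
#' and then every non-empty subset of the lesions stented (`2^n - 1`
#' strategies), reporting the vFFR at a distal measurement point for each.
#'
#' @param vessel a `vessel_geometry`.
#' @param lesions list of stent-able intervals with reference diameters:
#'   each a [stent_spec()] (or coercible list `(s_proximal, s_distal,
#'   diameter)`). Intervals must be disjoint; at most `max_lesions`.
#' @param bc,blood boundary conditions and blood properties.
#' @param backend `"reduced"` (default) or `"fvm3d"`.
#' @param s_measure arc length of the distal measurement point (mm);
#'   defaults to the distal end of the vessel.
#' @param s_reference proximal measurement point (mm), default 0.
#' @param max_lesions cap on the strategy explosion (default 6, i.e. at
#'   most 63 solves); raise explicitly for larger enumerations.
#' @param ... further arguments passed to the backend solver.
#' @return an object of class `strategy_report`: a data.frame with one row
#'   per strategy (`strategy`, `n_stented`, `lesions`, `vffr`,
#'   `delta_vs_baseline`), ordered by subset size then lesion position,
#'   with the baseline row first; attributes carry the baseline vFFR.
#' @export
tandem_analysis <- function(vessel, lesions, bc = boundary_conditions(),
                            blood = blood_properties(),
                            backend = c("reduced", "fvm3d"),
                            s_measure = vessel_length(vessel),
                            s_reference = 0,
                            max_lesions = 6L, ...) {
  backend <- match.arg(backend)
  if (length(lesions) < 1L) stop("at least one lesion is required")
  lesions <- lapply(lesions, function(st)
    if (!inherits(st, "stent_spec")) do.call(stent_spec, st) else st)
  n <- length(lesions)
  if (n > max_lesions)
    stop(sprintf("%d lesions exceed the cap of %d (raise 'max_lesions')",
                 n, max_lesions))
  iv <- t(vapply(lesions, function(x) c(x$s_proximal, x$s_distal), numeric(2)))
  ord <- order(iv[, 1])
  if (any(iv[ord, 2][-n] > iv[ord, 1][-1]))
    stop("lesion intervals overlap")

  solve_fun <- function(v, ...) {
    if (backend == "reduced") solve_reduced(v, bc, blood)
    else solve_3d(build_volume_mesh(v, ...), bc, blood)
  }
  vffr_of <- function(v) {
    sol <- solve_fun(v, ...)
    compute_vffr(sol, s_reference, s_measure)$vffr
  }

  baseline <- vffr_of(vessel)

  subsets <- lapply(1:(2^n - 1), function(m) which(bitwAnd(m, 2^(0:(n - 1))) > 0))
  # deterministic order: by subset size, then by lesion positions
  key <- vapply(subsets, function(ss)
    sprintf("%02d-%s", length(ss), paste(sprintf("%02d", ss), collapse = ".")),
    character(1))
  subsets <- subsets[order(key)]

  rows <- lapply(subsets, function(ss) {
    v2 <- deploy_stents(vessel, lesions[ss])
    data.frame(
      strategy = paste0("stent{", paste(ss, collapse = ","), "}"),
      n_stented = length(ss),
      lesions = paste(ss, collapse = ","),
      vffr = vffr_of(v2),
      stringsAsFactors = FALSE
    )
  })
  rep <- rbind(
    data.frame(strategy = "baseline", n_stented = 0L, lesions = "",
               vffr = baseline, stringsAsFactors = FALSE),
    do.call(rbind, rows)
  )
  rep$delta_vs_baseline <- rep$vffr - baseline
  attr(rep, "baseline_vffr") <- baseline
  attr(rep, "s_measure") <- s_measure
  attr(rep, "backend") <- backend
  class(rep) <- c("strategy_report", "data.frame")
  rep
}

#' @export
print.strategy_report <- function(x, ...) {
  cat(sprintf("Tandem-lesion strategy report (%s backend, vFFR at s = %.1f mm)\n",
              attr(x, "backend"), attr(x, "s_measure")))
  df <- as.data.frame(x)
  df$vffr <- sprintf("%.3f", df$vffr)
  df$delta_vs_baseline <- sprintf("%+.3f", df$delta_vs_baseline)
  print(df, row.names = FALSE)
  invisible(x)
}

.check_ffr_pairs <- function(mffr, vffr, n_min = 1L) {
  if (length(mffr) != length(vffr)) stop("mFFR and vFFR must be paired")
  if (length(mffr) < n_min) stop(sprintf("need at least %d pairs", n_min))
  if (any(mffr <= 0 | mffr > 1 | vffr <= 0 | vffr > 1))
    stop("FFR values must lie in (0, 1]")
  invisible(NULL)
}

#' Bland-Altman agreement between measured and virtual FFR
#'
#' Differences `d_i = mFFR_i - vFFR_i`; the bias is their mean, and the
#' limits of agreement are drawn at 2 sample standard deviations above and
#' below the bias.
#'
#' @param mffr,vffr paired FFR values in (0, 1], n >= 2.
#' @return an object of class `bland_altman`: list with `bias`, `sd`,
#'   `limits` (length-2, bias -/+ 2 sd), `n`, and `data` (a data.frame of
#'   pair means vs differences for plotting).
#' @export
bland_altman <- function(mffr, vffr) {
  .check_ffr_pairs(mffr, vffr, n_min = 2L)
  d <- mffr - vffr
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(
    bias = bias, sd = s,
    limits = c(lower = bias - 2 * s, upper = bias + 2 * s),
    n = length(d),
    data = data.frame(mean = (mffr + vffr) / 2, difference = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %+.4f, SD %.4f, limits [%.4f, %.4f]\n",
              x$n, x$bias, x$sd, x$limits[1], x$limits[2]))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$data$mean, x$data$difference,
                 xlab = "mean of mFFR and vFFR", ylab = "mFFR - vFFR",
                 main = "Bland-Altman", ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = x$limits, lty = 2, col = "deeppink")
  invisible(x)
}

#' Diagnostic accuracy of vFFR against the 0.80 ischemia threshold
#'
#' The positive (ischemic) class is `mFFR <= threshold`, and the test calls
#' a vessel positive when `vFFR <= threshold`; the boundary value 0.80 is
#' classified positive. Ratios with zero denominators are returned as `NA`
#' with `undefined` flags rather than silently 0.
#'
#' @param mffr,vffr paired FFR values in (0, 1].
#' @param threshold ischemia threshold, default 0.80.
#' @return an object of class `diagnostic_accuracy`: confusion counts
#'   (`tp`, `fp`, `tn`, `fn`), `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy` (all proportions in `[0, 1]` or `NA`), plus an `undefined`
#'   character vector naming any metric with a zero denominator.
#' @export
diagnostic_accuracy <- function(mffr, vffr, threshold = 0.80) {
  .check_ffr_pairs(mffr, vffr, n_min = 1L)
  truth <- mffr <= threshold
  test <- vffr <= threshold
  tp <- sum(truth & test); fn <- sum(truth & !test)
  tn <- sum(!truth & !test); fp <- sum(!truth & test)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  res <- list(
    tp = tp, fp = fp, tn = tn, fn = fn, n = length(mffr),
    threshold = threshold,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = (tp + tn) / length(mffr)
  )
  res$undefined <- names(which(vapply(
    res[c("sensitivity", "specificity", "ppv", "npv")], is.na, logical(1))))
  structure(res, class = "diagnostic_accuracy")
}

#' @export
print.diagnostic_accuracy <- function(x, ...) {
  cat(sprintf("Diagnostic accuracy vs threshold %.2f (n = %d)\n",
              x$threshold, x$n))
  cat(sprintf("  confusion: TP %d  FN %d  TN %d  FP %d\n",
              x$tp, x$fn, x$tn, x$fp))
  pc <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("  sensitivity %s, specificity %s, PPV %s, NPV %s, accuracy %s\n",
              pc(x$sensitivity), pc(x$specificity), pc(x$ppv), pc(x$npv),
              pc(x$accuracy)))
  invisible(x)
}

#' Correlation between measured and virtual FFR
#'
#' Pearson product-moment correlation, plus the slope of a least-squares
#' line constrained through the origin (the conventional way these paired
#' physiology readings are displayed).
#'
#' @param mffr,vffr paired FFR values in (0, 1], n >= 3, with non-zero
#'   variance in both coordinates.
#' @return list with `r` (Pearson), `slope_through_origin`, and `n`.
#'   `r` is `NA` with a warning if either coordinate has zero variance.
#' @export
ffr_correlation <- function(mffr, vffr) {
  .check_ffr_pairs(mffr, vffr, n_min = 3L)
  if (stats::sd(mffr) == 0 || stats::sd(vffr) == 0) {
    warning("zero variance in one coordinate; correlation undefined")
    r <- NA_real_
  } else {
    r <- stats::cor(mffr, vffr)
  }
  list(r = r,
       slope_through_origin = sum(mffr * vffr) / sum(mffr^2),
       n = length(mffr))
}
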