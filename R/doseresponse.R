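# Dose-response pipeline: concentration grid, QC cascade, log-logistic
# fitting with LL4 -> LL3 -> LL2 fallback, pharmacodynamic summaries
# (absolute IC50, EC50, AUC, scaled AUC), delta-method relative potency,
# and responder classification with ROC evaluation.
#
# Model: f(x) = c + (d - c) / (1 + exp(b * (ln x - ln e)))
# LL3 fixes c = 0; LL2 fixes c = 0 and d = 1.

#' Default prediction grid: 32 geometric concentrations, 1e-3 to 300 uM
#'
#' @return Numeric vector of 32 strictly increasing concentrations with a
#'   constant ratio between consecutive points; endpoints exactly 1e-3 and
#'   300.
#' @export
default_grid <- function() {
  g <- exp(seq(log(1e-3), log(300), length.out = 32L))
  g[1L] <- 1e-3; g[32L] <- 300
  g
}

#' Quality-control pruning of a dose-response series
#'
#' Recursively drops the largest-concentration point while any of the four
#' largest-concentration viabilities exceeds the viability at the fifth
#' largest remaining concentration by at least `rise_threshold` (an absolute
#' rise in viability units by default; `relative = TRUE` reads it as a
#' fraction of the reference). A minimum of `min_points` points must remain,
#' and the series must dip to `floor` or below for a curve to be fit at all.
#'
#' @param concentrations Positive concentrations (uM).
#' @param viabilities Paired viabilities.
#' @param rise_threshold Rise that triggers dropping the top point.
#' @param min_points Minimum points required after pruning.
#' @param floor Maximum allowed minimum viability ("no response" gate).
#' @param relative Interpret `rise_threshold` relative to the reference
#'   viability instead of absolutely.
#' @return List `kept` (indices into the input, concentration-ascending) and
#'   `qc_status`: `"ok"`, `"reject_too_few"`, or `"reject_no_response"`.
#' @export
qc_prune <- function(concentrations, viabilities, rise_threshold = 0.2,
                     min_points = 16L, floor = 0.4, relative = FALSE) {
  stopifnot(length(concentrations) == length(viabilities),
            all(concentrations > 0))
  ord <- order(concentrations)
  kept <- ord
  repeat {
    n <- length(kept)
    if (n < 5L) return(list(kept = integer(0), qc_status = "reject_too_few"))
    ref <- viabilities[kept[n - 4L]]
    top4 <- viabilities[kept[(n - 3L):n]]
    lim <- if (relative) ref * (1 + rise_threshold) else ref + rise_threshold
    if (any(top4 >= lim)) kept <- kept[-n] else break
  }
  if (length(kept) < min_points)
    return(list(kept = kept, qc_status = "reject_too_few"))
  if (min(viabilities[kept]) > floor)
    return(list(kept = kept, qc_status = "reject_no_response"))
  list(kept = kept, qc_status = "ok")
}

ll_predict <- function(b, c, d, loge, x) c + (d - c) / (1 + exp(b * (log(x) - loge)))

#' Evaluate a fitted log-logistic curve
#'
#' @param fit A `filmsens_ll_fit`.
#' @param x Concentrations (uM).
#' @return Predicted viabilities.
#' @export
predict_curve <- function(fit, x) {
  stopifnot(inherits(fit, "filmsens_ll_fit"))
  ll_predict(fit$b, fit$c, fit$d, log(fit$e), x)
}

fit_family <- function(conc, viab, family) {
  lx <- log(conc)
  dat <- data.frame(lx = lx, v = viab)
  lo_all <- c(b = 0.1, c = -0.1, d = 0.4, loge = log(1e-5))
  hi_all <- c(b = 20, c = 0.6, d = 2, loge = log(3e4))
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  # start e near the concentration whose viability is closest to midway
  d0 <- clip(max(viab), 0.4, 2)
  c0 <- clip(min(viab), -0.1, 0.6)
  loge0 <- lx[which.min(abs(viab - (d0 + c0) / 2))]
  loge0 <- clip(loge0, log(1e-5), log(3e4))
  form <- switch(family,
    LL4 = v ~ c + (d - c) / (1 + exp(b * (lx - loge))),
    LL3 = v ~ d / (1 + exp(b * (lx - loge))),
    LL2 = v ~ 1 / (1 + exp(b * (lx - loge))))
  start <- switch(family,
    LL4 = list(b = 1, c = c0, d = d0, loge = loge0),
    LL3 = list(b = 1, d = d0, loge = loge0),
    LL2 = list(b = 1, loge = loge0))
  keep <- names(start)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      lower = lo_all[keep], upper = hi_all[keep],
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (any(!is.finite(cf)) || is.null(vc) || any(!is.finite(vc))) return(NULL)
  b <- cf[["b"]]
  c_ <- if ("c" %in% keep) cf[["c"]] else 0
  d_ <- if ("d" %in% keep) cf[["d"]] else 1
  structure(list(family = family, b = b, c = c_, d = d_,
                 e = exp(cf[["loge"]]), loge = cf[["loge"]],
                 vcov = vc, n_points = length(viab), status = "ok"),
            class = "filmsens_ll_fit")
}

#' Fit a log-logistic dose-response curve with LL4/LL3/LL2 fallback
#'
#' Attempts a 4-parameter log-logistic fit (bounded Levenberg-Marquardt on
#' (b, c, d, ln e)); on failure falls back to the 3-parameter (c = 0) and
#' then the 2-parameter (c = 0, d = 1) family. The family actually used is
#' recorded, as is the covariance of the final fit.
#'
#' @param concentrations,viabilities QC-passing paired series.
#' @return A `filmsens_ll_fit` with fields `family, b, c, d, e, loge, vcov,
#'   n_points, status`; `status = "failed"` when the whole cascade fails.
#' @export
fit_curve <- function(concentrations, viabilities) {
  ord <- order(concentrations)
  conc <- concentrations[ord]; viab <- viabilities[ord]
  if (length(unique(viab)) <= 1L)
    return(structure(list(family = NA_character_, b = NA_real_, c = NA_real_,
                          d = NA_real_, e = NA_real_, loge = NA_real_,
                          vcov = NULL, n_points = length(viab),
                          status = "failed"),
                     class = "filmsens_ll_fit"))
  for (family in c("LL4", "LL3", "LL2")) {
    fit <- fit_family(conc, viab, family)
    if (!is.null(fit)) return(fit)
  }
  structure(list(family = NA_character_, b = NA_real_, c = NA_real_,
                 d = NA_real_, e = NA_real_, loge = NA_real_, vcov = NULL,
                 n_points = length(viab), status = "failed"),
            class = "filmsens_ll_fit")
}

#' Filter fitted curves on parameter determinacy and EC50 range
#'
#' Removes fits with non-finite parameters or covariance ("undetermined")
#' and fits whose EC50 falls outside `[lo, hi]` uM.
#'
#' @param fits List of `filmsens_ll_fit`.
#' @param lo,hi EC50 bounds in uM.
#' @return List `kept` (sublist of valid fits), `kept_idx`, and `reasons`
#'   (character per input fit: `"ok"`, `"undetermined"`, `"filtered_ec50"`,
#'   or `"failed"`).
#' @export
filter_fits <- function(fits, lo = 1e-3, hi = 300) {
  reasons <- vapply(fits, function(f) {
    if (!inherits(f, "filmsens_ll_fit") || identical(f$status, "failed"))
      return("failed")
    pars <- c(f$b, f$c, f$d, f$e)
    if (any(!is.finite(pars)) || is.null(f$vcov) || any(!is.finite(f$vcov)) ||
        any(diag(f$vcov) < 0))
      return("undetermined")
    if (f$e < lo || f$e > hi) return("filtered_ec50")
    "ok"
  }, "")
  keep <- which(reasons == "ok")
  list(kept = fits[keep], kept_idx = keep, reasons = reasons)
}

#' Absolute IC50: concentration at 50% viability
#'
#' Closed form `e * ((d - 0.5) / (0.5 - c))^(1/b)`; defined iff 0.5 lies
#' strictly between the lower and upper limits of the fitted curve, otherwise
#' `NA` (the curve never crosses 50% viability).
#'
#' @param fit A `filmsens_ll_fit` with `status == "ok"`.
#' @return Concentration in uM, or `NA_real_`.
#' @export
ic50_abs <- function(fit) {
  stopifnot(inherits(fit, "filmsens_ll_fit"))
  if (!identical(fit$status, "ok")) return(NA_real_)
  lo <- min(fit$c, fit$d); hi <- max(fit$c, fit$d)
  if (!(lo < 0.5 && 0.5 < hi)) return(NA_real_)
  fit$e * ((fit$d - 0.5) / (0.5 - fit$c))^(1 / fit$b)
}

#' Dose-response AUC with per-drug min-max scaling
#'
#' Averages ensemble prediction columns pointwise, integrates viability over
#' log10 concentration by the trapezoid rule, and scales each sample's AUC to
#' \[0, 1\] within its drug (minimum AUC maps to 0 = most sensitive). Drugs
#' with a single sample get `NA` scaled values; drugs whose AUCs are all
#' identical get 0.5, both flagged.
#'
#' @param predictions Data.frame with `compound_id`, `cell_line_id`,
#'   `concentration_uM`, and one or more `pred_*` columns (or `viability`).
#' @return Data.frame, one row per (compound, sample): `auc`, `scaled_auc`,
#'   `flag`.
#' @export
auc_and_scale <- function(predictions) {
  pred_cols <- grep("^pred_", names(predictions), value = TRUE)
  if (!length(pred_cols)) pred_cols <- "viability"
  v <- rowMeans(predictions[, pred_cols, drop = FALSE])
  lx <- log10(predictions$concentration_uM)
  trapz <- function(x, y) {
    o <- order(x); x <- x[o]; y <- y[o]
    sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
  }
  key <- interaction(predictions$compound_id, predictions$cell_line_id,
                     drop = TRUE, sep = "\r")
  idx <- split(seq_along(v), key)
  per <- data.frame(do.call(rbind, strsplit(names(idx), "\r", fixed = TRUE)))
  names(per) <- c("compound_id", "cell_line_id")
  per$auc <- vapply(idx, function(i) trapz(lx[i], v[i]), numeric(1L))
  per$scaled_auc <- NA_real_
  per$flag <- "ok"
  for (i in split(seq_len(nrow(per)), per$compound_id)) {
    a <- per$auc[i]
    if (length(i) == 1L) {
      per$flag[i] <- "single_sample"
    } else if (max(a) - min(a) < 1e-12) {
      per$scaled_auc[i] <- 0.5
      per$flag[i] <- "degenerate_range"
    } else {
      per$scaled_auc[i] <- (a - min(a)) / (max(a) - min(a))
    }
  }
  rownames(per) <- NULL
  per
}

#' Relative potency at the median effective dose (ED50)
#'
#' Tests the ED50 ratio e_A / e_B against 1 with a delta-method standard
#' error derived from each fit's covariance, and a two-sided t test with
#' `df = n_A + n_B - (p_A + p_B)`.
#'
#' @param fitA,fitB `filmsens_ll_fit` objects with finite covariances.
#' @return List `ed50_ratio`, `se`, `t_value`, `p_value`, `df`.
#' @export
compare_ed50 <- function(fitA, fitB) {
  for (f in list(fitA, fitB)) {
    if (!inherits(f, "filmsens_ll_fit") || !identical(f$status, "ok") ||
        is.null(f$vcov) || any(!is.finite(f$vcov)) ||
        !is.finite(f$vcov["loge", "loge"]) || f$vcov["loge", "loge"] <= 0)
      stop_filmsens("both fits need status ok and a finite, positive-definite covariance",
                    class = "filmsens_comparison_error")
  }
  r <- fitA$e / fitB$e
  var_logr <- fitA$vcov["loge", "loge"] + fitB$vcov["loge", "loge"]
  se <- r * sqrt(var_logr)                       # delta method on log-scale
  df <- fitA$n_points + fitB$n_points - (nrow(fitA$vcov) + nrow(fitB$vcov))
  t_value <- (r - 1) / se
  list(ed50_ratio = r, se = se, t_value = t_value,
       p_value = 2 * stats::pt(-abs(t_value), df = df), df = df)
}

#' Responder classification and ROC evaluation of scaled AUCs
#'
#' Lower scaled AUC means more sensitive, so a sample is classified as a
#' responder when its score falls below the threshold. The auROC equals the
#' Mann-Whitney concordant-pair statistic. When `groups` is given, per-group
#' ROC curves are computed and the macro-average auROC reported.
#'
#' @param scores Scaled AUC per sample.
#' @param outcomes Binary outcomes (1 = responder).
#' @param threshold Decision threshold; defaults to the score maximizing
#'   Youden's J on these data.
#' @param groups Optional factor (e.g. drug) for macro-averaging.
#' @return List `threshold`, `classifications`, `confusion` (tp/fp/fn/tn),
#'   `roc` (data.frame of points), `auroc`, and with groups `per_group` and
#'   `macro_auroc`.
#' @export
classify_and_roc <- function(scores, outcomes, threshold = NULL, groups = NULL) {
  stopifnot(length(scores) == length(outcomes))
  outcomes <- as.integer(outcomes)
  if (length(unique(outcomes)) < 2L)
    stop_filmsens("ROC is undefined with one-class outcomes",
                  class = "filmsens_roc_error")
  roc_obj <- pROC::roc(response = outcomes, predictor = scores,
                       levels = c(0L, 1L), direction = ">", quiet = TRUE)
  if (is.null(threshold)) {
    yj <- pROC::coords(roc_obj, "best", best.method = "youden",
                       transpose = FALSE)
    threshold <- yj$threshold[1L]
  }
  cls <- as.integer(scores < threshold)
  confusion <- c(tp = sum(cls == 1L & outcomes == 1L),
                 fp = sum(cls == 1L & outcomes == 0L),
                 fn = sum(cls == 0L & outcomes == 1L),
                 tn = sum(cls == 0L & outcomes == 0L))
  out <- list(threshold = threshold, classifications = cls,
              confusion = confusion,
              roc = data.frame(specificity = roc_obj$specificities,
                               sensitivity = roc_obj$sensitivities),
              auroc = as.numeric(pROC::auc(roc_obj)))
  if (!is.null(groups)) {
    per <- vapply(split(seq_along(scores), groups), function(i) {
      if (length(unique(outcomes[i])) < 2L) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(outcomes[i], scores[i],
                                     levels = c(0L, 1L), direction = ">",
                                     quiet = TRUE)))
    }, numeric(1L))
    out$per_group <- per
    out$macro_auroc <- mean(per, na.rm = TRUE)
  }
  out
}

#' Full pharmacodynamic summary of a prediction table
#'
#' Runs the QC cascade, fits the log-logistic cascade on pooled ensemble
#' replicates, applies the EC50/determinacy filter, and derives IC50 and
#' (scaled) AUC per (compound, cell line) pair.
#'
#' @param predictions Data.frame with `compound_id`, `cell_line_id`,
#'   `concentration_uM`, and `pred_*` (or `viability`) columns.
#' @param rise_threshold,min_points,floor QC parameters, see [qc_prune()].
#' @param ec50_lo,ec50_hi EC50 filter bounds (uM).
#' @param pool Either `"replicates"` (pool ensemble columns as replicate
#'   observations for one fit, the default) or `"mean"` (fit the pointwise
#'   ensemble mean).
#' @return Data.frame, one row per pair: `family,b,c,d,e,ic50,auc,scaled_auc,
#'   qc_status`, plus a `fits` attribute holding the fit objects.
#' @export
pharmacodynamics <- function(predictions, rise_threshold = 0.2,
                             min_points = 16L, floor = 0.4,
                             ec50_lo = 1e-3, ec50_hi = 300,
                             pool = c("replicates", "mean")) {
  pool <- match.arg(pool)
  pred_cols <- grep("^pred_", names(predictions), value = TRUE)
  if (!length(pred_cols)) pred_cols <- "viability"
  vmean <- rowMeans(predictions[, pred_cols, drop = FALSE])
  key <- paste(predictions$compound_id, predictions$cell_line_id, sep = "\r")
  groups <- split(seq_len(nrow(predictions)), key)
  fits <- list()
  rows <- lapply(names(groups), function(k) {
    i <- groups[[k]]
    conc <- predictions$concentration_uM[i]
    qc <- qc_prune(conc, vmean[i], rise_threshold, min_points, floor)
    ids <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    base <- data.frame(compound_id = ids[1L], cell_line_id = ids[2L],
                       family = NA_character_, b = NA_real_, c = NA_real_,
                       d = NA_real_, e = NA_real_, ic50 = NA_real_,
                       qc_status = qc$qc_status)
    if (qc$qc_status != "ok") return(base)
    ik <- i[qc$kept]
    if (pool == "replicates" && length(pred_cols) > 1L) {
      cc <- rep(predictions$concentration_uM[ik], times = length(pred_cols))
      vv <- unlist(predictions[ik, pred_cols], use.names = FALSE)
    } else {
      cc <- predictions$concentration_uM[ik]; vv <- vmean[ik]
    }
    fit <- fit_curve(cc, vv)
    fl <- filter_fits(list(fit), ec50_lo, ec50_hi)
    if (fl$reasons[1L] != "ok") {
      base$qc_status <- if (fl$reasons[1L] == "filtered_ec50")
        "filtered_ec50" else "fit_failed"
      return(base)
    }
    fits[[k]] <<- fit
    data.frame(compound_id = ids[1L], cell_line_id = ids[2L],
               family = fit$family, b = fit$b, c = fit$c, d = fit$d,
               e = fit$e, ic50 = ic50_abs(fit), qc_status = "ok")
  })
  out <- do.call(rbind, rows)
  aucs <- auc_and_scale(predictions)
  out <- merge(out, aucs, by = c("compound_id", "cell_line_id"),
               all.x = TRUE, sort = FALSE)
  attr(out, "fits") <- fits
  out
}
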