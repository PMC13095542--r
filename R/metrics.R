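# Evaluation statistics and experiment drivers.

#' Relative root-mean-square error in percent
#'
#' RMSE of range-normalised values: both vectors are mapped through
#' `(y - lo) / (hi - lo)` over the parameter's sampling range before the
#' plain RMSE, and the result is reported in percent.  This matches the
#' convention of quoting per-parameter errors as percentages of the
#' sampled range.
#'
#' @param y_true,y_pred numeric vectors.
#' @param lo,hi sampling range bounds (`hi > lo`).
#' @return percentage (scalar).
#' @export
relative_rmse <- function(y_true, y_pred, lo, hi) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1)
  if (!(hi > lo)) stop("zero-width range")
  yt <- (y_true - lo) / (hi - lo)
  yp <- (y_pred - lo) / (hi - lo)
  100 * sqrt(mean((yt - yp)^2))
}

#' Euclidean distance and normalised mean Euclidean distance
#'
#' `ED = sum_i sqrt((x_gt,i - x_pred,i)^2 + (y_gt,i - y_pred,i)^2)` over
#' matched point sequences; `nMED = ED / (N (max(y_gt) - min(y_gt)))`.
#' On a shared time grid the x-differences vanish, and nMED reduces to
#' the mean absolute error normalised by the ground-truth range.
#'
#' @param y_gt,y_pred ordinate sequences (equal length).
#' @param x_gt,x_pred abscissae; default shared grid.
#' @return `euclidean_distance`: ED; `nmed`: the dimensionless nMED.
#' @export
euclidean_distance <- function(y_gt, y_pred, x_gt = seq_along(y_gt),
                               x_pred = x_gt) {
  stopifnot(length(y_gt) == length(y_pred),
            length(x_gt) == length(x_pred))
  sum(sqrt((x_gt - x_pred)^2 + (y_gt - y_pred)^2))
}

#' @rdname euclidean_distance
#' @export
nmed <- function(y_gt, y_pred, x_gt = seq_along(y_gt), x_pred = x_gt) {
  rng <- max(y_gt) - min(y_gt)
  if (rng <= 0) stop("flat ground-truth curve: zero range")
  euclidean_distance(y_gt, y_pred, x_gt, x_pred) / (length(y_gt) * rng)
}

#' Least-squares regression of predictions on ground truth
#'
#' Fits `y_pred ~ y_true` (predictions on the ordinate, as in the
#' diagnostic scatter plots) and reports slope, intercept and R-squared.
#'
#' @param y_true,y_pred numeric vectors, `n >= 2`.
#' @return list with `slope`, `intercept`, `r2`.
#' @export
regression_slope_r2 <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  vx <- stats::var(y_true)
  if (vx == 0) stop("degenerate abscissa")
  slope <- stats::cov(y_true, y_pred) / vx
  intercept <- mean(y_pred) - slope * mean(y_true)
  ss_res <- sum((y_pred - intercept - slope * y_true)^2)
  ss_tot <- sum((y_pred - mean(y_pred))^2)
  list(slope = slope, intercept = intercept,
       r2 = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot)
}

# simulate one label row to steady state and return the three comparison
# waveforms (AP / PAP / PCWP over one cycle on a fixed grid)
simulate_indicator_waveforms <- function(labels, T, TBV,
                                         solver = solver_config(t_end = 30),
                                         n_wave = 256) {
  p <- circulation_params(T = T, TBV = TBV)
  for (nm in names(labels)) p <- set_param(p, nm, labels[[nm]])
  r <- simulate_lpm(p, solver)
  w <- detect_steady_state(r)
  list(AP = resample_cycle(r$time, r$pressures[, AP_NODE], w$t0, T, n_wave),
       PAP = resample_cycle(r$time, r$pressures[, PAP_NODE], w$t0, T,
                            n_wave),
       PCWP = resample_cycle(r$time, r$pressures[, "PVN"], w$t0, T, n_wave))
}

#' Evaluate a trained estimator on the test split
#'
#' Computes per-parameter relative RMSE and regression diagnostics on the
#' held-out test records, then re-simulates the predicted parameter sets
#' of a subset of samples and quantifies waveform agreement (nMED of AP,
#' PAP and PCWP against ground-truth re-simulations).  The three best and
#' three worst samples by mean nMED are showcased.
#'
#' @param est a `trained_estimator`.
#' @param dataset the originating `lpm_dataset`.
#' @param n_resim how many test samples to re-simulate for waveform
#'   agreement (a deterministic evenly spaced subset; full re-simulation
#'   of every test record is unnecessary for the best/worst summary).
#' @return object of class `evaluation_report` with `per_parameter`
#'   (data.frame: parameter, rmse_pct, slope, r2), `nmed` (data.frame per
#'   re-simulated sample and indicator), `best3`, `worst3` (row indices
#'   into `nmed`), and `failures`.
#' @export
evaluate_test_set <- function(est, dataset, n_resim = 24) {
  te <- dataset_rows(dataset, "test")
  pred <- predict_parameters(est, dataset, rows = te)
  truth <- dataset$labels[te, colnames(pred), drop = FALSE]
  rz <- est$ranges
  per <- do.call(rbind, lapply(colnames(pred), function(nm) {
    fit <- regression_slope_r2(truth[, nm], pred[, nm])
    data.frame(parameter = nm,
               rmse_pct = relative_rmse(truth[, nm], pred[, nm],
                                        rz$lo[[nm]], rz$hi[[nm]]),
               slope = fit$slope, r2 = fit$r2)
  }))
  sub <- te[unique(round(seq(1, length(te),
                             length.out = min(n_resim, length(te)))))]
  rows <- list(); fails <- list()
  for (i in sub) {
    sc <- dataset$scalars[i, ]
    gt <- tryCatch(simulate_indicator_waveforms(
      as.list(dataset$labels[i, ]), sc[["T"]], sc[["TBV"]]),
      error = function(e) e)
    pr_lab <- predict_parameters(est, dataset, rows = i)[1, ]
    pr <- tryCatch(simulate_indicator_waveforms(
      as.list(pr_lab), sc[["T"]], sc[["TBV"]]), error = function(e) e)
    if (inherits(gt, "error") || inherits(pr, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        row = i, message = conditionMessage(
          if (inherits(gt, "error")) gt else pr))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      row = i,
      AP = nmed(gt$AP, pr$AP), PAP = nmed(gt$PAP, pr$PAP),
      PCWP = nmed(gt$PCWP, pr$PCWP))
  }
  nm_tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(row = integer(), AP = numeric(), PAP = numeric(),
               PCWP = numeric())
  nm_tab$mean <- rowMeans(nm_tab[, c("AP", "PAP", "PCWP"), drop = FALSE])
  ord <- order(nm_tab$mean)
  structure(list(per_parameter = per, nmed = nm_tab,
                 best3 = utils::head(ord, 3), worst3 = utils::tail(ord, 3),
                 failures = if (length(fails)) do.call(rbind, fails) else
                   data.frame(row = integer(), message = character())),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Per-parameter test performance:\n")
  print(transform(x$per_parameter, rmse_pct = round(rmse_pct, 2),
                  slope = round(slope, 3), r2 = round(r2, 3)))
  if (nrow(x$nmed)) {
    sel <- x$nmed[c(x$best3, x$worst3), ]
    cat("Showcased best-3 / worst-3 samples, nMED (%):\n")
    print(transform(sel, AP = round(100 * AP, 3),
                    PAP = round(100 * PAP, 3),
                    PCWP = round(100 * PCWP, 3),
                    mean = round(100 * mean, 3)))
  }
  invisible(x)
}

#' Learning-curve experiment
#'
#' Re-trains the estimator on nested subsets of the training split and
#' reports the mean test error per size, averaged over seeds.
#'
#' @param dataset an `lpm_dataset`.
#' @param sizes training-set sizes (each at most the train-split size).
#' @param seeds integer vector of training seeds.
#' @param spec,config forwarded to [train_estimator()].
#' @return data.frame with `size`, `seed`, `mean_rmse_pct` and the
#'   per-size mean across seeds as attribute `"summary"`.
#' @export
training_size_curve <- function(dataset, sizes, seeds = 1L,
                                spec = network_spec(),
                                config = training_config()) {
  tr <- dataset_rows(dataset, "train")
  stopifnot(all(sizes <= length(tr)), all(sizes >= 1))
  rows <- list()
  for (s in seeds) for (n in sizes) {
    sub <- dataset
    drop <- tr[-seq_len(n)]   # nested subsets: first n train rows
    keep <- setdiff(seq_len(nrow(dataset$labels)), drop)
    for (f in c("q_lv", "q_rv", "ap", "scalars", "labels"))
      sub[[f]] <- dataset[[f]][keep, , drop = FALSE]
    sub$split <- dataset$split[keep]
    cfg <- config; cfg$seed <- as.integer(s)
    est <- train_estimator(sub, spec, cfg)
    rep <- evaluate_test_set(est, sub, n_resim = 0)
    rows[[length(rows) + 1L]] <- data.frame(
      size = n, seed = s, mean_rmse_pct = mean(rep$per_parameter$rmse_pct))
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- stats::aggregate(mean_rmse_pct ~ size, out, mean)
  out
}
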