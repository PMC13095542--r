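# Hierarchical estimator: two waveform networks predict ventricular
# end-systolic pressures, an exact elastance bridge converts them to peak
# elastances, and a third network maps arterial pressure + bridged
# elastances + blood volume to the circulation parameters.

#' End-systolic elastance bridge
#'
#' `Emax = Pes / (Ves - V0)`, exact; the physics constraint linking the
#' network-predicted end-systolic pressure to a model parameter.
#'
#' @param Pes end-systolic pressure (mmHg).
#' @param Ves end-systolic volume (mL), must exceed `V0`.
#' @param V0 zero-pressure volume (mL).
#' @return peak elastance (mmHg/mL).
#' @export
emax_bridge <- function(Pes, Ves, V0) {
  if (any(Ves <= V0)) stop("non-physiological: Ves must exceed V0")
  Pes / (Ves - V0)
}

# ---- normalisation ---------------------------------------------------------

fit_normalizer <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  list(mean = m, sd = s)
}
norm_apply <- function(nz, x) (x - nz$mean) / nz$sd
norm_invert <- function(nz, x) x * nz$sd + nz$mean

# affine [lo, hi] -> [0, 1] map per target parameter
range_normalizer <- function(spec_table, names) {
  tab <- spec_table[match(names, spec_table$parameter), ]
  list(lo = stats::setNames(tab$lower, names),
       hi = stats::setNames(tab$upper, names))
}
range_apply <- function(rz, Y) sweep(sweep(Y, 2, rz$lo[colnames(Y)]), 2,
                                     (rz$hi - rz$lo)[colnames(Y)], "/")
range_invert <- function(rz, Yn) sweep(sweep(Yn, 2,
                                             (rz$hi - rz$lo)[colnames(Yn)],
                                             "*"), 2, rz$lo[colnames(Yn)],
                                       "+")

# assemble the (B, 2, L) signal array: normalised waveform + time ramp 0..T
signal_array <- function(wave_mat, T_vec, nz_wave, T_scale) {
  B <- nrow(wave_mat); L <- ncol(wave_mat)
  X <- array(0, c(B, 2, L))
  X[, 1, ] <- norm_apply(nz_wave, wave_mat)
  X[, 2, ] <- outer(T_vec / T_scale, seq(0, 1, length.out = L))
  X
}

dataset_rows <- function(dataset, split) which(dataset$split == split)

# ---- training --------------------------------------------------------------

#' Train the hierarchical estimator
#'
#' Network A maps the left outflow-tract flow waveform plus LV EDV/ESV to
#' the LV end-systolic pressure; network B is the right-sided analogue;
#' network C maps the arterial-pressure waveform plus bridged peak
#' elastances and total blood volume to the circulation parameters.
#' All three share the architecture of [network_spec()] (independent
#' weights), train with mean-squared-error and Adam at the published
#' learning rate, and keep the best-validation checkpoint.  Network C is
#' trained with ground-truth elastance inputs (teacher forcing) and
#' evaluated end-to-end so that upstream error accumulation is measured.
#'
#' @param dataset an `lpm_dataset`.
#' @param spec a [network_spec()] sizing template (output dims are set per
#'   network); the default follows the published architecture.
#' @param config a [training_config()].
#' @param verbose print per-network validation losses.
#' @return object of class `trained_estimator`.
#' @export
train_estimator <- function(dataset, spec = network_spec(),
                            config = training_config(), verbose = FALSE) {
  L <- ncol(dataset$ap)
  tr <- dataset_rows(dataset, "train"); va <- dataset_rows(dataset, "val")
  circ <- setdiff(colnames(dataset$labels), c("Emax_LV", "Emax_RV"))
  sp_tab <- dataset$provenance$spec$table
  rz <- range_normalizer(sp_tab, colnames(dataset$labels))
  T_scale <- max(sp_tab$upper[sp_tab$parameter == "T"], 1)

  nz <- list(q_lv = fit_normalizer(dataset$q_lv[tr, ]),
             q_rv = fit_normalizer(dataset$q_rv[tr, ]),
             ap = fit_normalizer(dataset$ap[tr, ]),
             sc_a = apply(dataset$scalars[tr, c("LV_EDV", "LV_ESV")], 2,
                          fit_normalizer),
             sc_b = apply(dataset$scalars[tr, c("RV_EDV", "RV_ESV")], 2,
                          fit_normalizer),
             pes_lv = fit_normalizer(dataset$scalars[tr, "Pes_lv"]),
             pes_rv = fit_normalizer(dataset$scalars[tr, "Pes_rv"]),
             tbv = fit_normalizer(dataset$scalars[tr, "TBV"]))

  sc_mat <- function(cols, nzs, rows) {
    m <- dataset$scalars[rows, cols, drop = FALSE]
    for (j in seq_along(cols)) m[, j] <- norm_apply(nzs[[j]], m[, j])
    m
  }
  train_one <- function(wave, nz_wave, sc_cols, nz_sc, y, nz_y, out_dim,
                        tag) {
    Xt <- signal_array(wave[tr, , drop = FALSE],
                       dataset$scalars[tr, "T"], nz_wave, T_scale)
    Xv <- signal_array(wave[va, , drop = FALSE],
                       dataset$scalars[va, "T"], nz_wave, T_scale)
    St <- sc_mat(sc_cols, nz_sc, tr); Sv <- sc_mat(sc_cols, nz_sc, va)
    model <- build_network(network_spec(spec$channels, spec$mlp_hidden,
                                        spec$head, out_dim),
                           L, length(sc_cols), seed = config$seed)
    fit <- nn_train(model, Xt, St, y(tr), Xv, Sv, y(va), config)
    if (verbose)
      message(sprintf("  NN %s: val MSE %.4g (epoch %d)", tag,
                      fit$val_loss, fit$best_epoch))
    fit
  }

  fit_a <- train_one(dataset$q_lv, nz$q_lv, c("LV_EDV", "LV_ESV"), nz$sc_a,
                     function(r) cbind(norm_apply(nz$pes_lv,
                                                  dataset$scalars[r, "Pes_lv"])),
                     nz$pes_lv, 1, "A")
  fit_b <- train_one(dataset$q_rv, nz$q_rv, c("RV_EDV", "RV_ESV"), nz$sc_b,
                     function(r) cbind(norm_apply(nz$pes_rv,
                                                  dataset$scalars[r, "Pes_rv"])),
                     nz$pes_rv, 1, "B")

  # NN C: scalar inputs Emax_LV, Emax_RV (range-normalised, teacher forced)
  # and TBV; targets = circulation parameters (range-normalised)
  emax_n <- range_apply(rz, dataset$labels[, c("Emax_LV", "Emax_RV"),
                                           drop = FALSE])
  c_in <- function(r) cbind(emax_n[r, , drop = FALSE],
                            norm_apply(nz$tbv, dataset$scalars[r, "TBV"]))
  Yc <- range_apply(rz, dataset$labels[, circ, drop = FALSE])
  Xt <- signal_array(dataset$ap[tr, , drop = FALSE],
                     dataset$scalars[tr, "T"], nz$ap, T_scale)
  Xv <- signal_array(dataset$ap[va, , drop = FALSE],
                     dataset$scalars[va, "T"], nz$ap, T_scale)
  model_c <- build_network(network_spec(spec$channels, spec$mlp_hidden,
                                        spec$head, length(circ)),
                           L, 3L, seed = config$seed + 1L)
  fit_c <- nn_train(model_c, Xt, c_in(tr), Yc[tr, , drop = FALSE],
                    Xv, c_in(va), Yc[va, , drop = FALSE], config)
  if (verbose)
    message(sprintf("  NN C: val MSE %.4g (epoch %d)", fit_c$val_loss,
                    fit_c$best_epoch))

  structure(list(nn_a = fit_a$model, nn_b = fit_b$model,
                 nn_c = fit_c$model,
                 history = list(A = fit_a$history, B = fit_b$history,
                                C = fit_c$history),
                 normalizers = nz, ranges = rz, circ_names = circ,
                 T_scale = T_scale, input_len = L,
                 V0 = c(LV = 5, RV = 10),
                 config = config, spec = spec),
            class = "trained_estimator")
}

# predict Pes for a batch of records via network A or B
predict_pes <- function(est, wave, T_vec, edv, esv, side = c("lv", "rv")) {
  side <- match.arg(side)
  nz <- est$normalizers
  nz_wave <- if (side == "lv") nz$q_lv else nz$q_rv
  nz_sc <- if (side == "lv") nz$sc_a else nz$sc_b
  nz_p <- if (side == "lv") nz$pes_lv else nz$pes_rv
  net <- if (side == "lv") est$nn_a else est$nn_b
  X <- signal_array(wave, T_vec, nz_wave, est$T_scale)
  S <- cbind(norm_apply(nz_sc[[1]], edv), norm_apply(nz_sc[[2]], esv))
  norm_invert(nz_p, nn_forward(net, X, S)[, 1])
}

#' Predict the eight model parameters for feature records
#'
#' Runs the full hierarchy on a batch of records: networks A/B produce the
#' end-systolic pressures, the exact bridge converts them to peak
#' elastances using the measured end-systolic volumes and the default
#' zero-pressure volumes (LV 5 mL, RV 10 mL), and network C produces the
#' circulation parameters.
#'
#' @param est a `trained_estimator`.
#' @param dataset an `lpm_dataset` (or compatible record container).
#' @param rows record indices (default all).
#' @param teacher_emax optional matrix of ground-truth `Emax_LV`/`Emax_RV`
#'   to bypass networks A/B (teacher forcing).
#' @return matrix of predicted labels (rows x parameters) on natural
#'   scales.
#' @export
predict_parameters <- function(est, dataset, rows = NULL,
                               teacher_emax = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(dataset$ap))
  sc <- dataset$scalars[rows, , drop = FALSE]
  if (is.null(teacher_emax)) {
    pes_lv <- predict_pes(est, dataset$q_lv[rows, , drop = FALSE],
                          sc[, "T"], sc[, "LV_EDV"], sc[, "LV_ESV"], "lv")
    pes_rv <- predict_pes(est, dataset$q_rv[rows, , drop = FALSE],
                          sc[, "T"], sc[, "RV_EDV"], sc[, "RV_ESV"], "rv")
    emax <- cbind(
      Emax_LV = emax_bridge(pes_lv, sc[, "LV_ESV"], est$V0[["LV"]]),
      Emax_RV = emax_bridge(pes_rv, sc[, "RV_ESV"], est$V0[["RV"]]))
  } else emax <- teacher_emax
  emax_n <- range_apply(est$ranges, emax)
  X <- signal_array(dataset$ap[rows, , drop = FALSE], sc[, "T"],
                    est$normalizers$ap, est$T_scale)
  S <- cbind(emax_n, norm_apply(est$normalizers$tbv, sc[, "TBV"]))
  Yn <- nn_forward(est$nn_c, X, S)
  colnames(Yn) <- est$circ_names
  out <- cbind(emax, range_invert(est$ranges, Yn))
  colnames(out) <- c("Emax_LV", "Emax_RV", est$circ_names)
  out
}

#' Assemble a patient-specific parameter set from one record
#'
#' @param est a `trained_estimator`.
#' @param dataset record container.
#' @param row record index.
#' @param pump optional [pump_model()] to attach afterwards.
#' @param speed pump speed (rpm).
#' @return a [circulation_params()] with the record's `T` and `TBV`
#'   (pass-through, never predicted), the predicted elastances and
#'   circulation parameters, and package defaults elsewhere.
#' @export
predict_patient_parameters <- function(est, dataset, row, pump = NULL,
                                       speed = 0) {
  pred <- predict_parameters(est, dataset, rows = row)
  sc <- dataset$scalars[row, ]
  p <- circulation_params(T = sc[["T"]], TBV = sc[["TBV"]], pump = pump,
                          speed = speed)
  for (nm in colnames(pred)) p <- set_param(p, nm, pred[1, nm])
  p
}

#' Train the non-hierarchical ablation baseline
#'
#' A single dual-branch network fed the union of the hierarchy's raw
#' inputs (all three waveforms plus the ventricular volumes and blood
#' volume) that predicts all eight parameters directly, trained with the
#' same protocol; used only for the ablation comparison.
#'
#' @inheritParams train_estimator
#' @return object of class `flat_estimator`.
#' @export
flat_baseline <- function(dataset, spec = network_spec(),
                          config = training_config(), verbose = FALSE) {
  L <- ncol(dataset$ap)
  tr <- dataset_rows(dataset, "train"); va <- dataset_rows(dataset, "val")
  sp_tab <- dataset$provenance$spec$table
  rz <- range_normalizer(sp_tab, colnames(dataset$labels))
  T_scale <- max(sp_tab$upper[sp_tab$parameter == "T"], 1)
  nz <- list(q_lv = fit_normalizer(dataset$q_lv[tr, ]),
             q_rv = fit_normalizer(dataset$q_rv[tr, ]),
             ap = fit_normalizer(dataset$ap[tr, ]),
             sc = apply(dataset$scalars[tr, c("LV_EDV", "LV_ESV", "RV_EDV",
                                              "RV_ESV", "TBV")], 2,
                        fit_normalizer))
  mk_X <- function(rows) {
    B <- length(rows)
    X <- array(0, c(B, 4, L))
    X[, 1, ] <- norm_apply(nz$q_lv, dataset$q_lv[rows, , drop = FALSE])
    X[, 2, ] <- norm_apply(nz$q_rv, dataset$q_rv[rows, , drop = FALSE])
    X[, 3, ] <- norm_apply(nz$ap, dataset$ap[rows, , drop = FALSE])
    X[, 4, ] <- outer(dataset$scalars[rows, "T"] / T_scale,
                      seq(0, 1, length.out = L))
    X
  }
  mk_S <- function(rows) {
    cols <- c("LV_EDV", "LV_ESV", "RV_EDV", "RV_ESV", "TBV")
    m <- dataset$scalars[rows, cols, drop = FALSE]
    for (j in seq_along(cols)) m[, j] <- norm_apply(nz$sc[[j]], m[, j])
    m
  }
  Y <- range_apply(rz, dataset$labels)
  ch <- spec$channels; ch[1] <- 4L
  model <- build_network(network_spec(ch, spec$mlp_hidden, spec$head,
                                      ncol(Y)), L, 5L, seed = config$seed)
  fit <- nn_train(model, mk_X(tr), mk_S(tr), Y[tr, , drop = FALSE],
                  mk_X(va), mk_S(va), Y[va, , drop = FALSE], config)
  if (verbose)
    message(sprintf("  flat baseline: val MSE %.4g (epoch %d)",
                    fit$val_loss, fit$best_epoch))
  structure(list(model = fit$model, normalizers = nz, ranges = rz,
                 label_names = colnames(dataset$labels), T_scale = T_scale,
                 history = fit$history, mk_X = mk_X, mk_S = mk_S),
            class = "flat_estimator")
}

#' Predict with the flat baseline
#'
#' @param est a `flat_estimator`.
#' @param dataset record container (must be the same layout used in
#'   training).
#' @param rows record indices.
#' @return matrix of predicted labels on natural scales.
#' @export
predict_flat <- function(est, dataset, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(dataset$ap))
  L <- ncol(dataset$ap)
  nz <- est$normalizers
  B <- length(rows)
  X <- array(0, c(B, 4, L))
  X[, 1, ] <- norm_apply(nz$q_lv, dataset$q_lv[rows, , drop = FALSE])
  X[, 2, ] <- norm_apply(nz$q_rv, dataset$q_rv[rows, , drop = FALSE])
  X[, 3, ] <- norm_apply(nz$ap, dataset$ap[rows, , drop = FALSE])
  X[, 4, ] <- outer(dataset$scalars[rows, "T"] / est$T_scale,
                    seq(0, 1, length.out = L))
  cols <- c("LV_EDV", "LV_ESV", "RV_EDV", "RV_ESV", "TBV")
  S <- dataset$scalars[rows, cols, drop = FALSE]
  for (j in seq_along(cols)) S[, j] <- norm_apply(nz$sc[[j]], S[, j])
  Yn <- nn_forward(est$model, X, S)
  colnames(Yn) <- est$label_names
  range_invert(est$ranges, Yn)
}
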