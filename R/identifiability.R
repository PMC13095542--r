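# Sensitivity-based model identifiability analysis.
#
# A "sensitivity model" couples a parameter vector theta to a matrix of
# target-index time series h_j(t_i) over one steady cycle (rows = the N
# observation times, columns = the M target indices).  The traditional
# sensitivity function (TSF) ranks parameters by dimensionless local
# sensitivity; the generalized sensitivity function (GSF) distributes the
# Fisher information of each parameter over the cycle and exposes
# correlated (non-identifiable) pairs through anti- or co-varying
# increments.

#' Build a sensitivity model from an index function
#'
#' @param fn function mapping a named parameter vector to an N x M matrix
#'   of index time series (equal row counts for all parameters).
#' @param theta0 named numeric baseline parameter vector.
#' @param times the N observation times (s).
#' @param index_names names of the M target indices.
#' @param sigma_frac per-index noise scale as a fraction of the baseline
#'   cycle range of that index (the GSF weights; rankings and correlations
#'   are insensitive to a common rescaling).
#' @return an object of class `sensitivity_model` with the baseline
#'   response `h0` and noise scales `sigma` attached.
#' @export
sensitivity_model <- function(fn, theta0, times, index_names,
                              sigma_frac = 0.05) {
  stopifnot(is.function(fn), !is.null(names(theta0)))
  h0 <- fn(theta0)
  stopifnot(nrow(h0) == length(times), ncol(h0) == length(index_names))
  rng <- apply(h0, 2, function(y) diff(range(y)))
  sigma <- sigma_frac * pmax(rng, 1e-12)
  structure(list(fn = fn, theta0 = theta0, times = times,
                 index_names = index_names, h0 = h0, sigma = sigma),
            class = "sensitivity_model")
}

#' Sensitivity model for the full closed-loop circulation
#'
#' Target indices over one steady cycle of the native (pump-off)
#' circulation: the systemic forward-flow waveform (whose cycle mean is
#' cardiac output), the arterial-pressure waveform at the systemic-artery
#' node, and the pulmonary-artery pressure waveform at the proximal
#' pulmonary node (the same measurement sites used by
#' [compute_indicators()]).
#'
#' @param params baseline [circulation_params()] (pump is detached).
#' @param param_names flat parameter names to analyse; defaults to the
#'   full systemic + pulmonary set of [circulation_parameter_names()].
#' @param N samples per cycle.
#' @param solver a [solver_config()].
#' @inheritParams sensitivity_model
#' @return a `sensitivity_model`.
#' @export
lpm_sensitivity_model <- function(params = circulation_params(),
                                  param_names = circulation_parameter_names(),
                                  N = 81, solver = solver_config(),
                                  sigma_frac = 0.05) {
  params$pump <- NULL
  theta0 <- vapply(param_names, function(nm) get_param(params, nm), 0)
  times <- params$T * (seq_len(N) - 1) / (N - 1)
  fn <- function(theta) {
    p <- params
    for (nm in names(theta)) p <- set_param(p, nm, theta[[nm]])
    r <- simulate_lpm(p, solver)
    w <- detect_steady_state(r)
    grid <- w$t0 + times
    cbind(
      CO  = resample_at(r$time, r$flows[, "AV"], grid),
      AP  = resample_at(r$time, r$pressures[, AP_NODE], grid),
      PAP = resample_at(r$time, r$pressures[, PAP_NODE], grid))
  }
  sensitivity_model(fn, theta0, times, c("CO", "AP", "PAP"), sigma_frac)
}

resample_at <- function(t, y, grid) {
  stats::approx(t, y, xout = pmin(grid, max(t)), rule = 2)$y
}

#' Central finite-difference index gradients
#'
#' One pair of perturbed steady-state evaluations per parameter, with a
#' relative step sized to balance solver noise against truncation error.
#'
#' @param model a `sensitivity_model`.
#' @param rel_step relative perturbation of each baseline value.
#' @return 3-d array `grad[time, index, parameter]` of raw sensitivities
#'   `s_ij = dh_i/dtheta_j`.
#' @export
finite_diff_gradients <- function(model, rel_step = 0.01) {
  th <- model$theta0
  P <- length(th)
  grad <- array(NA_real_,
                c(length(model$times), length(model$index_names), P),
                dimnames = list(NULL, model$index_names, names(th)))
  for (k in seq_len(P)) {
    dk <- rel_step * abs(th[k])
    if (dk == 0) dk <- rel_step
    up <- th; up[k] <- th[k] + dk
    dn <- th; dn[k] <- th[k] - dk
    h_up <- tryCatch(model$fn(up), error = function(e)
      stop("perturbed simulation failed for ", names(th)[k], " (+): ",
           conditionMessage(e)))
    h_dn <- tryCatch(model$fn(dn), error = function(e)
      stop("perturbed simulation failed for ", names(th)[k], " (-): ",
           conditionMessage(e)))
    grad[, , k] <- (h_up - h_dn) / (2 * dk)
  }
  grad
}

#' Traditional sensitivity functions and ranking
#'
#' Dimensionless sensitivities `S_ij(t) = (theta_j / h_i,r) dh_i/dtheta_j`
#' with the baseline values as parameter references and the cycle mean of
#' `|h_i|` as index reference (guarded by the index range when that mean
#' is negligible).  The aggregate score per parameter sums, over indices,
#' the cycle-mean `|S_ij|` normalised to the largest parameter within each
#' index; the ranking is descending in this score.
#'
#' @param model a `sensitivity_model`.
#' @param grad optional precomputed [finite_diff_gradients()] array.
#' @param rel_step finite-difference step, forwarded.
#' @return list of class `tsf_result` with `S` (array), `aggregate`
#'   (named scores) and `ranking` (parameter names, descending).
#' @export
tsf <- function(model, grad = NULL, rel_step = 0.01) {
  if (is.null(grad)) grad <- finite_diff_gradients(model, rel_step)
  th <- model$theta0
  h_ref <- apply(abs(model$h0), 2, mean)
  rng <- apply(model$h0, 2, function(y) diff(range(y)))
  h_ref <- ifelse(h_ref < 1e-9 * pmax(rng, 1e-12), pmax(rng, 1e-12), h_ref)
  S <- grad
  for (k in seq_along(th))
    S[, , k] <- sweep(matrix(grad[, , k], ncol = length(h_ref)), 2,
                      th[k] / h_ref, "*")
  per_index <- apply(abs(S), c(2, 3), mean)        # M x P
  norm <- sweep(per_index, 1, apply(per_index, 1, max), "/")
  aggregate <- colSums(norm)
  structure(list(S = S, per_index = per_index, aggregate = aggregate,
                 ranking = names(sort(aggregate, decreasing = TRUE))),
            class = "tsf_result")
}

#' Fisher information matrix from index gradients
#'
#' `F = sum_i sum_j sigma_j^-2 grad_theta h_j(t_i) grad_theta h_j(t_i)^T`,
#' symmetric positive semi-definite by construction; near rank deficiency
#' signals structural non-identifiability.
#'
#' @param grad array from [finite_diff_gradients()].
#' @param sigma per-index noise scales.
#' @return the P x P matrix with attribute `"rank"`.
#' @export
fim <- function(grad, sigma) {
  P <- dim(grad)[3]
  F <- matrix(0, P, P, dimnames = list(dimnames(grad)[[3]],
                                       dimnames(grad)[[3]]))
  for (j in seq_len(dim(grad)[2])) {
    G <- matrix(grad[, j, ], ncol = P)            # N x P
    F <- F + crossprod(G) / sigma[j]^2
  }
  F <- (F + t(F)) / 2
  ev <- eigen(F, symmetric = TRUE, only.values = TRUE)$values
  attr(F, "rank") <- sum(ev > max(ev) * 1e-10)
  F
}

#' Generalized sensitivity functions
#'
#' Cumulative information curves
#' `g_k(t_n) = sum_{i<=n} sum_j sigma_j^-2 [F^-1 grad h_j(t_i)]_k [grad h_j(t_i)]_k`
#' rising from 0 to a terminal value of exactly 1 for every parameter
#' whenever the Fisher matrix is invertible.  Pairwise Pearson
#' correlations of the increment series expose redundant parameter pairs.
#'
#' @param model a `sensitivity_model`.
#' @param param_names subset of parameters to analyse (default: all).
#' @param grad optional precomputed gradient array (subset is taken).
#' @param rel_step finite-difference step, forwarded.
#' @return list of class `gsf_result` with `g` (N x P matrix of curves),
#'   `increments`, `increment_correlation`, `F`, and `singular` flag.
#' @export
gsf <- function(model, param_names = names(model$theta0), grad = NULL,
                rel_step = 0.01) {
  if (is.null(grad)) grad <- finite_diff_gradients(model, rel_step)
  grad <- grad[, , param_names, drop = FALSE]
  F <- fim(grad, model$sigma)
  P <- length(param_names)
  singular <- attr(F, "rank") < P
  Finv <- if (!singular) {
    tryCatch(solve(F), error = function(e) NULL)
  } else NULL
  if (is.null(Finv)) {
    singular <- TRUE
    warning("Fisher matrix numerically singular; using pseudo-inverse")
    s <- svd(F)
    pos <- s$d > max(s$d) * 1e-10
    Finv <- s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  }
  N <- dim(grad)[1]
  contrib <- matrix(0, N, P, dimnames = list(NULL, param_names))
  for (j in seq_len(dim(grad)[2])) {
    G <- matrix(grad[, j, ], ncol = P)            # N x P
    contrib <- contrib + (G %*% Finv) * G / model$sigma[j]^2
  }
  g <- apply(contrib, 2, cumsum)
  inc <- contrib[-1, , drop = FALSE]
  structure(list(g = g, times = model$times, increments = inc,
                 increment_correlation = suppressWarnings(stats::cor(inc)),
                 F = F, singular = singular),
            class = "gsf_result")
}

#' Flag correlated parameter pairs from GSF increments
#'
#' Pairs whose increment series correlate beyond `threshold` in absolute
#' value are flagged; within each pair the member with the lower aggregate
#' TSF score is marked for exclusion.
#'
#' @param gsf_res a `gsf_result`.
#' @param tsf_res a `tsf_result` (supplies the aggregate scores).
#' @param threshold absolute correlation threshold.
#' @return data.frame with columns `a`, `b`, `correlation`, `exclude`.
#' @export
correlation_screen <- function(gsf_res, tsf_res, threshold = 0.9) {
  C <- gsf_res$increment_correlation
  nm <- colnames(C)
  out <- list()
  for (a in seq_along(nm)) for (b in seq_along(nm)) {
    if (b <= a) next
    if (is.finite(C[a, b]) && abs(C[a, b]) > threshold) {
      agg <- tsf_res$aggregate[c(nm[a], nm[b])]
      out[[length(out) + 1L]] <- data.frame(
        a = nm[a], b = nm[b], correlation = C[a, b],
        exclude = names(which.min(agg)))
    }
  }
  if (!length(out))
    return(data.frame(a = character(), b = character(),
                      correlation = numeric(), exclude = character()))
  do.call(rbind, out)
}

#' Two-stage estimable-parameter selection
#'
#' Stage one ranks all candidate parameters by aggregate TSF and keeps the
#' top `N`.  Stage two screens those candidates with the GSF iteratively:
#' while the increment series of some pair correlate beyond `threshold` in
#' absolute value, the lower-TSF member of the worst pair is excluded and
#' the GSF recomputed; if no pair is flagged but the Fisher matrix is
#' still numerically rank-deficient, the lowest-TSF parameter loading on
#' the null space is excluded.  Recomputing after each exclusion matters
#' because a nearly singular information matrix smears apparent
#' correlations across the whole candidate set.  The procedure is
#' deterministic given the model, step, noise scales and threshold.
#'
#' @param model a `sensitivity_model`.
#' @param N number of TSF candidates to keep.
#' @param threshold correlation threshold for the GSF screen.
#' @param rel_step finite-difference step.
#' @return list of class `selection_report` with `candidates`, `flagged`
#'   (one row per exclusion), `excluded`, `selected`, plus the underlying
#'   `tsf` and final `gsf` results.
#' @export
select_parameters <- function(model, N = 10, threshold = 0.9,
                              rel_step = 0.01) {
  grad <- finite_diff_gradients(model, rel_step)
  t_res <- tsf(model, grad = grad)
  candidates <- utils::head(t_res$ranking, N)
  cur <- candidates
  log <- list()
  repeat {
    g_res <- suppressWarnings(gsf(model, param_names = cur, grad = grad))
    C <- abs(g_res$increment_correlation)
    diag(C) <- 0
    if (length(cur) > 1L && max(C, na.rm = TRUE) > threshold) {
      ij <- which(C == max(C, na.rm = TRUE), arr.ind = TRUE)[1, ]
      pair <- colnames(C)[ij]
      drop <- pair[which.min(t_res$aggregate[pair])]
      log[[length(log) + 1L]] <- data.frame(
        a = pair[1], b = pair[2],
        correlation = g_res$increment_correlation[ij[1], ij[2]],
        reason = "correlated", exclude = drop)
    } else if (g_res$singular && length(cur) > 1L) {
      es <- eigen(g_res$F, symmetric = TRUE)
      null_load <- abs(es$vectors[, length(cur)])
      members <- cur[null_load > 0.5 / sqrt(length(cur))]
      if (!length(members)) members <- cur
      drop <- members[which.min(t_res$aggregate[members])]
      log[[length(log) + 1L]] <- data.frame(
        a = drop, b = NA_character_, correlation = NA_real_,
        reason = "rank-deficient", exclude = drop)
    } else break
    cur <- setdiff(cur, drop)
  }
  flagged <- if (length(log)) do.call(rbind, log) else
    data.frame(a = character(), b = character(), correlation = numeric(),
               reason = character(), exclude = character())
  structure(list(candidates = candidates, flagged = flagged,
                 excluded = setdiff(candidates, cur), selected = cur,
                 tsf = t_res, gsf = g_res),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("TSF candidates:", paste(x$candidates, collapse = ", "), "\n")
  if (nrow(x$flagged))
    for (i in seq_len(nrow(x$flagged)))
      cat(sprintf("  %s -> exclude %s (%s%s)\n",
                  x$flagged$reason[i], x$flagged$exclude[i],
                  ifelse(is.na(x$flagged$b[i]), "",
                         paste0(x$flagged$a[i], " ~ ", x$flagged$b[i], ", ")),
                  ifelse(is.na(x$flagged$correlation[i]), "null space",
                         sprintf("r = %+.2f", x$flagged$correlation[i]))))
  cat("Selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

# ---- demonstration fixtures ------------------------------------------------

#' Windkessel demonstration circuits for the GSF method
#'
#' `rcr_fixture()` is the classic proximal-resistance / compliance /
#' distal-resistance circuit driven by a periodic inlet pressure (period
#' 0.8 s) with a grounded outlet and the inlet flow waveform as target
#' index.  `rcrr_fixture()` splits the distal resistor into two series
#' halves whose sum preserves the original value; the split node carries a
#' tiny parasitic compliance (`C_mid`) so the Fisher matrix remains
#' (barely) invertible, mirroring the physical reading of a split
#' transmission segment.  The split renders the pair structurally
#' non-identifiable from inlet flow alone: their GSF increments are
#' anti-correlated.
#'
#' @param R2,C1,R3 element values (defaults: a typical systemic
#'   windkessel); all qualitative conclusions hold across a wide sweep.
#' @param T driving period (s).
#' @param N observation points per cycle.
#' @param split fractional share of the distal resistance assigned to the
#'   first half after the split.
#' @param C_mid parasitic compliance at the split node (mL/mmHg).
#' @return a `sensitivity_model`.
#' @export
rcr_fixture <- function(R2 = 0.05, C1 = 1.0, R3 = 1.0, T = 0.8, N = 81) {
  theta0 <- c(R2 = R2, C1 = C1, R3 = R3)
  times <- T * (seq_len(N) - 1) / (N - 1)
  fn <- function(theta) {
    sim <- simulate_windkessel(theta[["R2"]], theta[["C1"]],
                               c(theta[["R3"]]), C_mid = NULL, T = T)
    matrix(resample_at(sim$t, sim$q_in, sim$t0 + times),
           ncol = 1, dimnames = list(NULL, "Q_in"))
  }
  sensitivity_model(fn, theta0, times, "Q_in")
}

#' @rdname rcr_fixture
#' @export
rcrr_fixture <- function(R2 = 0.05, C1 = 1.0, R3 = 1.0, T = 0.8, N = 81,
                         split = 0.5, C_mid = 0.05) {
  theta0 <- c(R2 = R2, C1 = C1, R3 = split * R3, R4 = (1 - split) * R3)
  times <- T * (seq_len(N) - 1) / (N - 1)
  fn <- function(theta) {
    sim <- simulate_windkessel(theta[["R2"]], theta[["C1"]],
                               c(theta[["R3"]], theta[["R4"]]),
                               C_mid = C_mid, T = T)
    matrix(resample_at(sim$t, sim$q_in, sim$t0 + times),
           ncol = 1, dimnames = list(NULL, "Q_in"))
  }
  sensitivity_model(fn, theta0, times, "Q_in")
}

#' Periodic inlet pressure used by the windkessel fixtures
#'
#' A smooth systolic pulse (half-sine over 35% of the period) on an 80
#' mmHg baseline.
#'
#' @param t time (s), vectorised.
#' @param T period (s).
#' @return pressure (mmHg).
#' @export
windkessel_inlet_pressure <- function(t, T = 0.8) {
  tau <- (t / T) %% 1
  80 + 40 * ifelse(tau < 0.35, sin(pi * tau / 0.35), 0)
}

# RK4 integration of the (single- or two-state) windkessel to a periodic
# state; returns the final-cycle inlet flow.
simulate_windkessel <- function(R2, C1, R_dist, C_mid = NULL, T = 0.8,
                                cycles = 12, dt = 1e-3) {
  two <- !is.null(C_mid) && length(R_dist) == 2
  rhs <- function(t, y) {
    Pin <- windkessel_inlet_pressure(t, T)
    if (!two) {
      q_in <- (Pin - y[1]) / R2
      (q_in - y[1] / R_dist[1]) / C1
    } else {
      q_in <- (Pin - y[1]) / R2
      q_mid <- (y[1] - y[2]) / R_dist[1]
      c((q_in - q_mid) / C1, (q_mid - y[2] / R_dist[2]) / C_mid)
    }
  }
  y <- if (two) c(80, 40) else 80
  t_end <- cycles * T
  nstep <- ceiling(t_end / dt)
  h <- t_end / nstep
  ts <- numeric(nstep + 1); P1 <- matrix(0, nstep + 1, length(y))
  P1[1, ] <- y
  for (s in seq_len(nstep)) {
    t <- (s - 1) * h
    k1 <- rhs(t, y); k2 <- rhs(t + h / 2, y + h / 2 * k1)
    k3 <- rhs(t + h / 2, y + h / 2 * k2); k4 <- rhs(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    ts[s + 1] <- s * h; P1[s + 1, ] <- y
  }
  q_in <- (windkessel_inlet_pressure(ts, T) - P1[, 1]) / R2
  list(t = ts, q_in = q_in, t0 = (cycles - 1) * T)
}
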