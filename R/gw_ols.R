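#' Local weighted least squares
#'
#' Solves one geographically weighted calibration: \eqn{\hat\beta =
#' (X^\top W X)^{-1} X^\top W y} with diagonal weights `w`. Also returns the
#' covariance factor \eqn{C = (X^\top W X)^{-1} X^\top W} (as the derived
#' pieces needed downstream) and, when `focal` is given, the focal row of the
#' hat matrix \eqn{s_i = x_i^\top C}.
#'
#' @param X Design matrix including the intercept column.
#' @param y Response vector.
#' @param w Nonnegative weight vector.
#' @param focal Optional row index of the focal location in `X`.
#' @return List with `beta`, `xtwx_inv` (the \eqn{(X^\top W X)^{-1}} factor),
#'   and `hat_row` (`NULL` unless `focal` given).
#' @export
fit_local_wls <- function(X, y, w, focal = NULL) {
  X <- as.matrix(X)
  if (sum(w > 0) < ncol(X)) {
    abort_singular("Fewer positively weighted points than coefficients.")
  }
  A <- crossprod(X, X * w)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    abort_singular(paste0(
      "Singular local design",
      if (!is.null(focal)) paste0(" at location index ", focal), "."))
  }
  a_inv <- chol2inv(ch)
  beta <- drop(a_inv %*% crossprod(X, w * y))
  names(beta) <- colnames(X)
  hat_row <- NULL
  if (!is.null(focal)) {
    hat_row <- drop((X %*% (a_inv %*% X[focal, ])) * w)
  }
  list(beta = beta, xtwx_inv = a_inv, hat_row = hat_row)
}

# Core GW-OLS sweep. `level` controls how much hat-matrix information is
# assembled: "diag" (enough for AICc/ENP) or "full" (adds tr(S'S) and
# per-location SE factors, needed for inference).
gwols_engine <- function(X, y, coords, kernel, level = c("full", "diag"),
                         on_singular = c("error", "drop")) {
  level <- match.arg(level)
  on_singular <- match.arg(on_singular)
  n <- nrow(X)
  p_model <- ncol(X)
  D <- pairwise_distances(coords)
  bw <- kernel_bandwidths(coords, kernel)
  beta <- matrix(NA_real_, n, p_model, dimnames = list(NULL, colnames(X)))
  se_factor <- matrix(NA_real_, n, p_model)
  hat_diag <- numeric(n)
  tr_sts <- 0
  yhat <- numeric(n)
  local_r2 <- numeric(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    w <- kernel_row_weights(D, i, kernel, bw)
    idx <- which(w > 0)
    if (length(idx) < p_model) {
      if (on_singular == "drop") { flagged[i] <- TRUE; next }
      abort_singular(sprintf("Location %d has %d positively weighted points (< %d).",
                             i, length(idx), p_model))
    }
    Xi <- X[idx, , drop = FALSE]
    wi <- w[idx]
    yi <- y[idx]
    A <- crossprod(Xi, Xi * wi)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) {
      if (on_singular == "drop") { flagged[i] <- TRUE; next }
      abort_singular(sprintf("Singular local design at location %d.", i))
    }
    a_inv <- chol2inv(ch)
    b <- drop(a_inv %*% crossprod(Xi, wi * yi))
    beta[i, ] <- b
    xi <- X[i, ]
    yhat[i] <- sum(xi * b)
    hat_diag[i] <- drop(crossprod(xi, a_inv %*% xi))
    if (level == "full") {
      s_row <- drop(Xi %*% (a_inv %*% xi)) * wi
      tr_sts <- tr_sts + sum(s_row^2)
      B <- crossprod(Xi, Xi * wi^2)
      se_factor[i, ] <- diag(a_inv %*% B %*% a_inv)
    }
    fit_res <- yi - drop(Xi %*% b)
    rss_w <- sum(wi * fit_res^2)
    mw <- sum(wi * yi) / sum(wi)
    tss_w <- sum(wi * (yi - mw)^2)
    local_r2[i] <- if (tss_w > 0) 1 - rss_w / tss_w else NA_real_
  }
  ok <- !flagged
  resid <- y - yhat
  resid[flagged] <- NA_real_
  list(beta = beta, se_factor = se_factor, hat_diag = hat_diag,
       tr_s = sum(hat_diag[ok]), tr_sts = tr_sts,
       yhat = yhat, resid = resid, local_r2 = local_r2,
       flagged = flagged, rss = sum(resid[ok]^2), n = n, p_model = p_model)
}

gwols_design <- function(frame) {
  check_regression_size(frame)
  X <- cbind(`(Intercept)` = 1, area_predictors(frame))
  list(X = X, y = area_outcome(frame), coords = area_coords(frame))
}

# Corrected AIC for a GW regression, in the convention that penalizes by the
# hat-matrix trace: AICc = 2n log(sigma_hat) + n log(2 pi)
#   + n (n + tr S) / (n - 2 - tr S), sigma_hat^2 = RSS / n.
aicc_from_fit <- function(rss, n, tr_s) {
  if (tr_s >= n - 2) {
    abort_config("Ill-conditioned bandwidth: tr(S) >= n - 2.")
  }
  sigma_hat <- sqrt(rss / n)
  2 * n * log(sigma_hat) + n * log(2 * pi) + n * (n + tr_s) / (n - 2 - tr_s)
}

aic_from_fit <- function(rss, n, tr_s) {
  2 * n * log(sqrt(rss / n)) + n * log(2 * pi) + n + tr_s
}

#' AICc of a GW-OLS fit at a given bandwidth
#'
#' Evaluates the bandwidth-selection objective: the corrected Akaike
#' information criterion of the full geographically weighted fit, with the
#' effective number of parameters taken as the trace of the hat matrix.
#'
#' @param frame An [as_area_frame()].
#' @param kernel A [kernel_spec()] with its bandwidth set.
#' @return A single numeric AICc value.
#' @export
gwols_aicc <- function(frame, kernel) {
  d <- gwols_design(frame)
  eng <- gwols_engine(d$X, d$y, d$coords, kernel, level = "diag")
  aicc_from_fit(eng$rss, eng$n, eng$tr_s)
}

#' Select an adaptive bandwidth by AICc
#'
#' Chooses the neighbor count k minimizing the GW-OLS AICc, either over an
#' explicit candidate grid or by golden-section search over `[lower, upper]`
#' (which assumes the AICc profile is unimodal in k, the standard working
#' assumption for GW regression). The evaluation trace is returned for
#' inspection.
#'
#' @param frame An [as_area_frame()].
#' @param family Kernel family (default bi-square).
#' @param candidates Optional integer vector of k values (grid mode).
#' @param method `"golden"` or `"grid"` (forced to grid when `candidates`
#'   given).
#' @param lower,upper Golden-section search range; defaults `p + 3` and `n`.
#' @return A list with `bandwidth` (selected k), `aicc`, and `trace`
#'   (tibble of evaluated `k`, `aicc`).
#' @export
select_bandwidth <- function(frame, family = "bisquare", candidates = NULL,
                             method = c("golden", "grid"),
                             lower = NULL, upper = NULL) {
  method <- match.arg(method)
  n <- nrow(frame)
  p <- length(predictor_names(frame))
  if (!is.null(candidates)) method <- "grid"
  evaluated <- new.env(parent = emptyenv())
  eval_k <- function(k) {
    key <- as.character(k)
    if (!is.null(evaluated[[key]])) return(evaluated[[key]])
    val <- gwols_aicc(frame, kernel_spec(family, adaptive = TRUE,
                                         bandwidth = k))
    evaluated[[key]] <- val
    val
  }
  if (method == "grid") {
    if (is.null(candidates) || length(candidates) == 0) {
      abort_config("Empty candidate set.")
    }
    aiccs <- vapply(candidates, eval_k, numeric(1))
    best <- which.min(aiccs)
    trace <- tibble::tibble(k = as.integer(candidates), aicc = aiccs)
    return(list(bandwidth = as.integer(candidates[best]),
                aicc = aiccs[best], trace = trace))
  }
  lo <- as.integer(lower %||% (p + 3))
  hi <- as.integer(upper %||% n)
  if (lo >= hi) abort_config("Invalid golden-section range.")
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- round(b - phi * (b - a))
  x2 <- round(a + phi * (b - a))
  f1 <- eval_k(x1); f2 <- eval_k(x2)
  while (b - a > 2) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- round(b - phi * (b - a))
      if (x1 == x2) x1 <- max(a, x2 - 1L)
      f1 <- eval_k(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- round(a + phi * (b - a))
      if (x2 == x1) x2 <- min(b, x1 + 1L)
      f2 <- eval_k(x2)
    }
  }
  ks <- seq(a, b)
  aiccs <- vapply(ks, eval_k, numeric(1))
  best_k <- ks[which.min(aiccs)]
  all_k <- sort(as.integer(ls(evaluated)))
  trace <- tibble::tibble(k = all_k,
                          aicc = vapply(as.character(all_k),
                                        function(k) evaluated[[k]],
                                        numeric(1)))
  list(bandwidth = as.integer(best_k), aicc = min(aiccs), trace = trace)
}

#' Fit a geographically weighted OLS regression
#'
#' Calibrates a weighted least-squares regression at every location using
#' kernel weights centred there, yielding location-specific coefficients,
#' standard errors, pseudo-t statistics, raw and dependent-test adjusted
#' p-values, and local weighted R-squared. Global diagnostics follow the GW
#' regression conventions: the effective number of parameters (ENP) is the
#' trace of the hat matrix, pseudo-t degrees of freedom are `n - ENP`, the
#' residual variance for standard errors is
#' `RSS / (n - 2 tr(S) + tr(S'S))`, and model selection uses the corrected
#' AIC penalized by `tr(S)`.
#'
#' @param frame An [as_area_frame()].
#' @param kernel A [kernel_spec()]; if its bandwidth is `NULL`, an adaptive
#'   bandwidth is selected by golden-section AICc search.
#' @param on_singular `"error"` (default) aborts naming the offending
#'   location; `"drop"` flags it and continues.
#' @return A `gwols_fit` object; see [tidy.gwols_fit()], [glance.gwols_fit()],
#'   [coef_quartiles()] and [predict.gwols_fit()].
#' @export
fit_gwols <- function(frame, kernel = kernel_spec("bisquare", adaptive = TRUE,
                                                  bandwidth = NULL),
                      on_singular = c("error", "drop")) {
  on_singular <- match.arg(on_singular)
  selection <- NULL
  if (is.null(kernel$bandwidth)) {
    selection <- select_bandwidth(frame, family = kernel$family)
    kernel <- kernel_spec(kernel$family, adaptive = TRUE,
                          bandwidth = selection$bandwidth)
  }
  d <- gwols_design(frame)
  eng <- gwols_engine(d$X, d$y, d$coords, kernel, level = "full",
                      on_singular = on_singular)
  n <- eng$n
  p_model <- eng$p_model
  enp <- eng$tr_s
  sigma2_se <- eng$rss / (n - 2 * eng$tr_s + eng$tr_sts)
  se <- sqrt(sigma2_se * eng$se_factor)
  tval <- eng$beta / se
  df <- n - enp
  p_raw <- 2 * pt(-abs(tval), df = df)
  p_adj <- adjusted_p_values(tval, enp, p_model, n)
  y <- d$y
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - eng$rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - enp)
  coef_names <- colnames(d$X)
  local <- tibble::tibble(id = area_ids(frame))
  for (j in seq_len(p_model)) {
    nm <- if (j == 1) "intercept" else coef_names[j]
    local[[paste0("beta_", nm)]] <- eng$beta[, j]
    local[[paste0("se_", nm)]] <- se[, j]
    local[[paste0("t_", nm)]] <- tval[, j]
    local[[paste0("p_", nm)]] <- p_raw[, j]
    local[[paste0("p_adj_", nm)]] <- p_adj[, j]
  }
  local$local_r2 <- eng$local_r2
  local$leverage <- eng$hat_diag
  local$residual <- eng$resid
  structure(list(
    local = local,
    global = list(aicc = aicc_from_fit(eng$rss, n, enp),
                  aic = aic_from_fit(eng$rss, n, enp),
                  enp = enp, rss = eng$rss, r2 = r2, adj_r2 = adj_r2,
                  sigma2 = sigma2_se, df = df, n = n),
    beta = eng$beta, se = se, t = tval, p_raw = p_raw, p_adj = p_adj,
    kernel = kernel, selection = selection, coef_names = coef_names,
    frame = frame, flagged = eng$flagged
  ), class = "gwols_fit")
}

#' Dependent-test adjusted p-values for GW-OLS pseudo-t statistics
#'
#' Local coefficient tests in a GW regression are correlated across
#' locations; the dependent-test Bonferroni-style adjustment treats each
#' coefficient surface as carrying `m = ENP / p_model` effective tests and
#' reports `p_adj = min(1, p_raw * m)`, where ENP is the effective number of
#' parameters (hat-matrix trace) and `p_model` the number of coefficients per
#' local fit. In the global limit (`ENP = p_model`) the adjustment vanishes.
#'
#' @param t_values Matrix (or vector) of pseudo-t statistics.
#' @param enp Effective number of parameters (>= `p_model`).
#' @param p_model Number of coefficients in each local fit.
#' @param n Number of observations (degrees of freedom are `n - enp`).
#' @return Adjusted p-values, same shape as `t_values`; always >= the raw
#'   two-sided p-values and capped at 1.
#' @export
adjusted_p_values <- function(t_values, enp, p_model, n) {
  if (enp < p_model - 1e-8) {
    abort_config("ENP < number of model coefficients; inconsistent inputs.")
  }
  p_raw <- 2 * pt(-abs(t_values), df = n - enp)
  p_adj <- p_raw * (enp / p_model)
  p_adj[p_adj > 1] <- 1
  p_adj
}

#' Local variance inflation factors
#'
#' Screens a GW regression for local collinearity: at each location, each
#' predictor is regressed on the others using the focal kernel weights, and
#' `VIF = 1 / (1 - R2_w)`. Values above `1e6` are flagged infinite. The
#' conventional trouble threshold is VIF > 10.
#'
#' @param frame An [as_area_frame()] with at least two predictors.
#' @param kernel A [kernel_spec()] with bandwidth set.
#' @return A tibble with `id` and one `vif_<predictor>` column per predictor.
#' @export
local_vif <- function(frame, kernel) {
  X <- area_predictors(frame)
  p <- ncol(X)
  if (p < 2) abort_config("Local VIFs require at least two predictors.")
  coords <- area_coords(frame)
  D <- pairwise_distances(coords)
  bw <- kernel_bandwidths(coords, kernel)
  n <- nrow(X)
  vif <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  cap <- 1e6
  for (i in seq_len(n)) {
    w <- kernel_row_weights(D, i, kernel, bw)
    idx <- which(w > 0)
    wi <- w[idx]
    for (j in seq_len(p)) {
      Z <- cbind(1, X[idx, -j, drop = FALSE])
      xj <- X[idx, j]
      fitb <- tryCatch(
        fit_local_wls(Z, xj, wi)$beta,
        gwareal_error_singular = function(e) NULL)
      if (is.null(fitb)) { vif[i, j] <- Inf; next }
      res <- xj - drop(Z %*% fitb)
      rss_w <- sum(wi * res^2)
      mw <- sum(wi * xj) / sum(wi)
      tss_w <- sum(wi * (xj - mw)^2)
      r2w <- if (tss_w > 0) 1 - rss_w / tss_w else 1
      v <- if (r2w >= 1) Inf else 1 / (1 - r2w)
      vif[i, j] <- if (is.finite(v) && v > cap) Inf else v
    }
  }
  out <- tibble::tibble(id = area_ids(frame))
  for (j in seq_len(p)) out[[paste0("vif_", colnames(X)[j])]] <- vif[, j]
  out
}

#' Predict from a GW-OLS fit at new locations
#'
#' Calibrates a fresh local weighted regression at each new location's
#' coordinates using the *training* data and the fitted kernel/bandwidth,
#' then evaluates the new predictor row against those local coefficients.
#'
#' @param object A [fit_gwols()] result.
#' @param newdata A data frame with the coordinate and predictor columns of
#'   the training frame.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.gwols_fit <- function(object, newdata, ...) {
  frame <- object$frame
  roles <- gw_roles(frame)
  miss <- setdiff(c(roles$coords, roles$predictors), names(newdata))
  if (length(miss) > 0) {
    abort_schema(paste0("newdata lacks column(s): ", paste(miss, collapse = ", ")))
  }
  X_tr <- cbind(1, area_predictors(frame))
  y_tr <- area_outcome(frame)
  coords_tr <- area_coords(frame)
  p_model <- ncol(X_tr)
  kernel <- object$kernel
  new_coords <- as.matrix(newdata[, roles$coords])
  X_new <- cbind(1, as.matrix(newdata[, roles$predictors]))
  n_new <- nrow(new_coords)
  preds <- numeric(n_new)
  for (i in seq_len(n_new)) {
    d <- sqrt((coords_tr[, 1] - new_coords[i, 1])^2 +
                (coords_tr[, 2] - new_coords[i, 2])^2)
    b <- if (kernel$adaptive) {
      k_eff <- min(kernel$bandwidth, length(d))
      sort(d, method = "radix")[k_eff]
    } else kernel$bandwidth
    w <- kernel_weights(d, b, kernel$family)
    w[d == 0] <- 1
    if (sum(w > 0) < p_model + 1) {
      abort_validation(sprintf(
        "New location %d has too few positively weighted training points.", i))
    }
    beta <- fit_local_wls(X_tr, y_tr, w)$beta
    preds[i] <- sum(X_new[i, ] * beta)
  }
  preds
}

#' Quartile summary of local coefficients
#'
#' Summarizes each local coefficient surface by its minimum, quartiles and
#' maximum — the conventional compact display for a GW regression
#' coefficient table.
#'
#' @param fit A [fit_gwols()] result.
#' @return A tibble with one row per coefficient: `term, min, q1, median,
#'   q3, max`.
#' @export
coef_quartiles <- function(fit) {
  stopifnot(inherits(fit, "gwols_fit"))
  purrr::map_dfr(seq_along(fit$coef_names), function(j) {
    q <- quantile(fit$beta[, j], c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
    tibble::tibble(term = fit$coef_names[j], min = q[[1]], q1 = q[[2]],
                   median = q[[3]], q3 = q[[4]], max = q[[5]])
  })
}

#' @describeIn fit_gwols Long per-location coefficient table (one row per
#'   location x term) with estimates, standard errors, pseudo-t and raw and
#'   adjusted p-values.
#' @param x,object A `gwols_fit`.
#' @param ... Unused.
#' @export
tidy.gwols_fit <- function(x, ...) {
  ids <- x$local$id
  purrr::map_dfr(seq_along(x$coef_names), function(j) {
    tibble::tibble(id = ids, term = x$coef_names[j],
                   estimate = x$beta[, j], std.error = x$se[, j],
                   statistic = x$t[, j], p.value = x$p_raw[, j],
                   p.adjusted = x$p_adj[, j])
  })
}

#' @describeIn fit_gwols One-row global summary (AICc, AIC, ENP, R2,
#'   adjusted R2, bandwidth).
#' @export
glance.gwols_fit <- function(x, ...) {
  tibble::tibble(aicc = x$global$aicc, aic = x$global$aic,
                 enp = x$global$enp, r.squared = x$global$r2,
                 adj.r.squared = x$global$adj_r2, rss = x$global$rss,
                 n = x$global$n, bandwidth = x$kernel$bandwidth,
                 kernel = x$kernel$family)
}

#' @export
print.gwols_fit <- function(x, ...) {
  cat("Geographically weighted OLS fit\n")
  cat(sprintf("  n = %d, kernel = %s, %s bandwidth = %s\n", x$global$n,
              x$kernel$family,
              if (x$kernel$adaptive) "adaptive" else "fixed",
              format(x$kernel$bandwidth)))
  cat(sprintf("  ENP = %.2f, AICc = %.2f, R2 = %.3f, adj. R2 = %.3f\n",
              x$global$enp, x$global$aicc, x$global$r2, x$global$adj_r2))
  cat("Local coefficient quartiles:\n")
  print(as.data.frame(coef_quartiles(x)), row.names = FALSE, digits = 4)
  invisible(x)
}
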