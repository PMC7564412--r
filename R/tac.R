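#' Time-activity-curve models
#'
#' Organ kinetics are modelled with one of two fixed functional forms:
#'
#' * `monoexp`: f(t) = A0 * exp(-lambda * t) — organs whose uptake is maximal
#'   at the first sacrifice and then clears (blood, liver, kidneys, spleen,
#'   lungs, heart, brain, muscle, bone).
#' * `biexp`: f(t) = A1 * (exp(-lambda1 * t) - exp(-lambda2 * t)),
#'   lambda2 > lambda1 — organs that accumulate activity before clearing
#'   (gut, skin, stomach, which take up free halide after dehalogenation);
#'   f(0) = 0 and the curve peaks at log(lambda2/lambda1)/(lambda2 - lambda1).
#'
#' Both integrate analytically over [0, Inf): A0/lambda for `monoexp` and
#' A1 * (1/lambda1 - 1/lambda2) for `biexp`. When fitted on the
#' decay-UNcorrected scale these areas are time-integrated activities per
#' gram, the quantity dosimetry consumes.
#'
#' @name tac_models
NULL

tac_check_params <- function(model, params) {
  model <- match.arg(model, c("monoexp", "biexp"))
  need <- if (model == "monoexp") c("A0", "lambda") else
    c("A1", "lambda1", "lambda2")
  if (is.null(names(params)) || !all(need %in% names(params))) {
    # accept positional vectors of the right length
    if (length(params) != length(need)) {
      stop(model, " expects parameters ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    names(params) <- need
  }
  params <- params[need]
  if (any(!is.finite(params)) || any(params <= 0)) {
    stop("all ", model, " parameters must be positive and finite",
         call. = FALSE)
  }
  if (model == "biexp" && params[["lambda2"]] <= params[["lambda1"]]) {
    stop("biexp requires lambda2 > lambda1 (so f(t) >= 0)", call. = FALSE)
  }
  params
}

#' Evaluate a time-activity-curve model
#'
#' @param model `"monoexp"` or `"biexp"`.
#' @param params Named parameter vector: `A0`, `lambda` (monoexp) or `A1`,
#'   `lambda1`, `lambda2` (biexp, with `lambda2 > lambda1`).
#' @param t Times in hours, >= 0.
#' @return Model values (%ID/g scale).
#' @export
tac_eval <- function(model, params, t) {
  params <- tac_check_params(model, params)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be finite and non-negative", call. = FALSE)
  }
  if (model == "monoexp") {
    params[["A0"]] * exp(-params[["lambda"]] * t)
  } else {
    params[["A1"]] * (exp(-params[["lambda1"]] * t) -
                        exp(-params[["lambda2"]] * t))
  }
}

#' Analytic area under a fitted time-activity curve
#'
#' Integral of the model over t in [0, Inf): `A0/lambda` for `monoexp`,
#' `A1 * (1/lambda1 - 1/lambda2)` for `biexp`. On the decay-uncorrected
#' scale this is the time-integrated activity per gram, in %ID.h/g.
#'
#' @inheritParams tac_eval
#' @return Area in %ID.h/g.
#' @export
tac_auc <- function(model, params) {
  params <- tac_check_params(model, params)
  if (model == "monoexp") {
    params[["A0"]] / params[["lambda"]]
  } else {
    params[["A1"]] * (1 / params[["lambda1"]] - 1 / params[["lambda2"]])
  }
}

#' Peak time of the bi-exponential model
#'
#' @param params Named vector with `lambda1`, `lambda2` (`lambda2 > lambda1`).
#' @return Time of the curve maximum, log(lambda2/lambda1)/(lambda2-lambda1).
#' @export
biexp_peak_time <- function(params) {
  params <- tac_check_params("biexp", c(A1 = 1, params[c("lambda1", "lambda2")]))
  l1 <- params[["lambda1"]]; l2 <- params[["lambda2"]]
  log(l2 / l1) / (l2 - l1)
}

# deterministic starting values (no randomness): monoexp from a log-linear
# regression of the positive values; biexp from a coarse grid over
# (lambda1, lambda2/lambda1) with A1 set by matching the observed peak
tac_init <- function(model, t, y) {
  if (model == "monoexp") {
    pos <- y > 0
    if (sum(pos) >= 2L) {
      fit <- stats::lm(log(y[pos]) ~ t[pos])
      A0 <- exp(stats::coef(fit)[[1L]])
      lam <- max(-stats::coef(fit)[[2L]], 1e-4)
    } else {
      A0 <- max(y, 1e-3); lam <- 0.1
    }
    c(A0 = A0, lambda = lam)
  } else {
    peak_v <- max(y)
    tail_i <- t >= stats::median(t) & y > 0
    lam1_tail <- if (sum(tail_i) >= 2L) {
      max(-stats::coef(stats::lm(log(y[tail_i]) ~ t[tail_i]))[[2L]], 1e-3)
    } else 0.1
    best <- NULL
    for (l1 in unique(c(lam1_tail, 0.05, 0.15))) {
      for (ratio in c(5, 10, 50)) {
        l2 <- l1 * ratio
        tp <- log(ratio) / (l2 - l1)
        shape_peak <- exp(-l1 * tp) - exp(-l2 * tp)
        A1 <- peak_v / shape_peak
        sse <- sum((y - tac_eval("biexp",
                                 c(A1 = A1, lambda1 = l1, lambda2 = l2),
                                 t))^2)
        if (is.null(best) || sse < best$sse) {
          best <- list(sse = sse, par = c(A1 = A1, lambda1 = l1, lambda2 = l2))
        }
      }
    }
    best$par
  }
}

#' Fit a time-activity-curve model by least squares
#'
#' Levenberg-Marquardt least squares (via \pkg{minpack.lm}) with box
#' constraints keeping every parameter in (1e-6, 1e4). The bi-exponential
#' constraint `lambda2 > lambda1` is enforced structurally by fitting
#' `delta = lambda2 - lambda1 > 0`. Starting values are deterministic
#' (log-linear regression for `monoexp`; a coarse shape grid for `biexp`),
#' so identical inputs give identical fits.
#'
#' Non-convergence or an unusable covariance is reported through
#' `converged = FALSE` on the returned object, not as an error.
#'
#' @param t,y Timepoints (hours) and measured values (same length; `y >= 0`).
#' @param model `"monoexp"` or `"biexp"`.
#' @param init Optional named starting values (natural parametrisation).
#' @param weights Optional least-squares weights (default unweighted).
#' @param lower,upper Box constraints applied to every parameter.
#' @return A `tac_fit`: list with `model`, `estimates` (natural
#'   parametrisation), `covariance` (natural scale), `auc`, `rmse`,
#'   `n_points`, `converged`.
#' @export
fit_tac <- function(t, y, model = c("monoexp", "biexp"), init = NULL,
                    weights = NULL, lower = 1e-6, upper = 1e4) {
  model <- match.arg(model)
  stopifnot(length(t) == length(y))
  if (any(!is.finite(t)) || any(!is.finite(y)) || any(t < 0) || any(y < 0)) {
    stop("times and values must be finite and non-negative", call. = FALSE)
  }
  npar <- if (model == "monoexp") 2L else 3L
  if (length(unique(t)) < npar) {
    stop("need at least ", npar, " distinct timepoints to fit a ", model,
         call. = FALSE)
  }
  ord <- order(t)                       # canonical order: fits are
  t <- t[ord]; y <- y[ord]              # invariant to input ordering
  if (!is.null(weights)) weights <- weights[ord] else weights <- rep(1, length(y))

  if (is.null(init)) init <- tac_init(model, t, y)
  clamp <- function(p) pmin(pmax(p, lower * 1.01), upper * 0.99)
  if (model == "monoexp") {
    start <- as.list(clamp(c(A0 = unname(init[["A0"]]),
                             lambda = unname(init[["lambda"]]))))
    form <- y ~ A0 * exp(-lambda * t)
    lo <- c(A0 = lower, lambda = lower); hi <- c(A0 = upper, lambda = upper)
  } else {
    init <- tac_check_params("biexp", init)
    start <- as.list(clamp(c(A1 = unname(init[["A1"]]),
                             lambda1 = unname(init[["lambda1"]]),
                             delta = unname(init[["lambda2"]] -
                                              init[["lambda1"]]))))
    form <- y ~ A1 * (exp(-lambda1 * t) - exp(-(lambda1 + delta) * t))
    lo <- c(A1 = lower, lambda1 = lower, delta = lower)
    hi <- c(A1 = upper, lambda1 = upper, delta = upper)
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(t = t, y = y), start = start,
                      weights = weights, lower = lo, upper = hi,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )

  if (inherits(fit, "error")) {
    return(structure(list(model = model, estimates = NULL, covariance = NULL,
                          auc = NA_real_, rmse = NA_real_,
                          n_points = length(y), converged = FALSE,
                          message = conditionMessage(fit),
                          data = data.frame(t = t, y = y)),
                     class = "tac_fit"))
  }

  est_raw <- stats::coef(fit)
  vc_raw <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (model == "monoexp") {
    estimates <- est_raw[c("A0", "lambda")]
    covariance <- if (!is.null(vc_raw)) vc_raw[c("A0", "lambda"),
                                               c("A0", "lambda")] else NULL
  } else {
    estimates <- c(A1 = unname(est_raw[["A1"]]),
                   lambda1 = unname(est_raw[["lambda1"]]),
                   lambda2 = unname(est_raw[["lambda1"]] + est_raw[["delta"]]))
    if (!is.null(vc_raw)) {
      # (A1, l1, delta) -> (A1, l1, l2 = l1 + delta)
      J <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 1, 1))
      covariance <- J %*% vc_raw[c("A1", "lambda1", "delta"),
                                 c("A1", "lambda1", "delta")] %*% t(J)
      dimnames(covariance) <- list(names(estimates), names(estimates))
    } else covariance <- NULL
  }
  if (!is.null(covariance)) {
    covariance <- (covariance + t(covariance)) / 2  # enforce exact symmetry
  }
  ok_cov <- !is.null(covariance) && all(is.finite(covariance))
  resid <- y - tac_eval(model, estimates, t)
  structure(list(model = model,
                 estimates = estimates,
                 covariance = if (ok_cov) covariance else NULL,
                 auc = tac_auc(model, estimates),
                 rmse = sqrt(mean(resid^2)),
                 n_points = length(y),
                 converged = isTRUE(fit$convInfo$isConv) ||
                   inherits(fit, "nls"),
                 message = NULL,
                 data = data.frame(t = t, y = y)),
            class = "tac_fit")
}

#' @export
print.tac_fit <- function(x, ...) {
  cat(sprintf("<tac_fit> %s, %d points, %s\n", x$model, x$n_points,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (!is.null(x$estimates)) {
    print(round(x$estimates, 6))
    cat(sprintf("  AUC = %.4g %%ID.h/g, RMSE = %.4g\n", x$auc, x$rmse))
  }
  invisible(x)
}

#' Organ-to-model assignment
#'
#' The study design assigns each organ its model a priori: mono-exponential
#' for blood, flat bone, femur, muscle, liver, kidneys, lungs, spleen, brain
#' and heart; bi-exponential for the gut (intestine), skin and stomach.
#'
#' @return Named character vector mapping organ label to model id.
#' @export
default_organ_models <- function() {
  c(blood = "monoexp", flat_bone = "monoexp", femur = "monoexp",
    muscle = "monoexp", liver = "monoexp", kidneys = "monoexp",
    lungs = "monoexp", spleen = "monoexp", brain = "monoexp",
    heart = "monoexp",
    gut = "biexp", intestine = "biexp", skin = "biexp", stomach = "biexp")
}

#' Pick the model for an organ
#'
#' @param organ Organ label (case-insensitive; spaces become underscores).
#' @param mapping Named organ -> model vector, default
#'   [default_organ_models()].
#' @param unknown Policy for unmapped organs: `"error"` (default),
#'   `"monoexp"` or `"biexp"`.
#' @return `"monoexp"` or `"biexp"`.
#' @export
choose_model <- function(organ, mapping = default_organ_models(),
                         unknown = c("error", "monoexp", "biexp")) {
  unknown <- match.arg(unknown)
  key <- gsub("[ -]+", "_", tolower(trimws(organ)))
  if (key %in% names(mapping)) return(unname(mapping[[key]]))
  if (unknown == "error") {
    stop("no model assignment for organ '", organ, "'", call. = FALSE)
  }
  unknown
}
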