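#' Local-energy-deposition absorbed dose
#'
#' Alpha particles travel ~70 um in soft tissue, so all alpha energy emitted
#' inside an organ is assumed absorbed there (MIRD local deposition). The
#' absorbed dose per unit injected activity then follows from the
#' time-integrated activity per gram (the area under the decay-UNcorrected
#' time-activity curve) and the branching-weighted alpha energy per decay:
#'
#'   D \[Gy/MBq\] = (AUC/100) \[ID.h/g\] x 3.6e9 \[decays/(MBq.h)\]
#'                x E \[MeV\] x 1.602e-13 \[J/MeV\] x 1e3 \[g/kg\]
#'
#' Because %ID/g is already a per-mass quantity, no organ-mass table enters:
#' multiplying a whole-organ time-integrated activity by the tissue mass and
#' dividing by that same mass (the whole-organ %ID route) gives the identical
#' dose, which [dose_from_whole_organ()] makes explicit.
#'
#' @name dosimetry
NULL

# decays per MBq.h times J/MeV times g/kg, divided by the %ID scale factor
dose_conversion <- 3.6e9 * 1.602176634e-13 * 1e3 / 100

#' Absorbed dose per unit injected activity
#'
#' @param auc Time-integrated activity per gram, %ID.h/g, from a
#'   decay-uncorrected time-activity curve. Must be >= 0.
#' @param energy Mean alpha energy per decay, MeV (> 0); 6.79 MeV for the
#'   211At chain.
#' @return Absorbed dose in Gy per MBq injected; linear in both arguments.
#' @examples
#' dose_per_unit_activity(100, 6.79) # 3.916 Gy/MBq
#' @export
dose_per_unit_activity <- function(auc, energy) {
  if (any(!is.finite(auc)) || any(auc < 0)) {
    stop("'auc' must be finite and >= 0 (%ID.h/g)", call. = FALSE)
  }
  if (any(!is.finite(energy)) || any(energy <= 0)) {
    stop("'energy' must be finite and > 0 (MeV)", call. = FALSE)
  }
  auc * energy * dose_conversion
}

#' Dose via the whole-organ (%ID + mass) route
#'
#' Same dose as [dose_per_unit_activity()], computed from a whole-organ
#' time-integrated activity (%ID.h) and the organ mass: the mass enters the
#' energy total and the per-mass normalisation and cancels exactly.
#'
#' @param auc_whole Whole-organ time-integrated activity, %ID.h.
#' @param mass_g Organ mass in grams (> 0).
#' @inheritParams dose_per_unit_activity
#' @return Absorbed dose in Gy/MBq.
#' @export
dose_from_whole_organ <- function(auc_whole, mass_g, energy) {
  if (any(!is.finite(mass_g)) || any(mass_g <= 0)) {
    stop("'mass_g' must be finite and > 0", call. = FALSE)
  }
  # total decays scale with auc_whole; dividing the deposited energy by the
  # organ mass recovers the per-gram AUC, so mass cancels out of the dose
  dose_per_unit_activity(auc_whole / mass_g, energy)
}

#' Dose at a given injected activity
#'
#' @param dose_per_mbq Dose coefficient, Gy/MBq.
#' @param injected_mbq Injected activity, MBq (>= 0).
#' @param digits Rounding applied to the report value (`NULL` = none;
#'   study reports use 1 decimal).
#' @return Absorbed dose in Gy.
#' @examples
#' dose_at_activity(8.2, 0.740, digits = 1) # spleen at 740 kBq: 6.1 Gy
#' @export
dose_at_activity <- function(dose_per_mbq, injected_mbq, digits = NULL) {
  if (any(!is.finite(injected_mbq)) || any(injected_mbq < 0)) {
    stop("'injected_mbq' must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(dose_per_mbq)) || any(dose_per_mbq < 0)) {
    stop("'dose_per_mbq' must be finite and >= 0", call. = FALSE)
  }
  d <- dose_per_mbq * injected_mbq
  if (!is.null(digits)) d <- round(d, digits)
  d
}

#' Relative-biological-effectiveness weighting
#'
#' Multiplies an absorbed dose by an RBE factor (4-5 is the usual range for
#' alpha particles relative to photons) to give a photon-equivalent dose,
#' Gy(RBE).
#'
#' @param dose Absorbed dose, Gy.
#' @param rbe RBE factor (> 0).
#' @return RBE-weighted dose, Gy(RBE).
#' @export
apply_rbe <- function(dose, rbe) {
  if (any(!is.finite(rbe)) || any(rbe <= 0)) {
    stop("'rbe' must be finite and > 0", call. = FALSE)
  }
  dose * rbe
}

# gradient of the analytic AUC with respect to the natural parameters
auc_gradient <- function(model, params) {
  params <- tac_check_params(model, params)
  if (model == "monoexp") {
    c(A0 = 1 / params[["lambda"]],
      lambda = -params[["A0"]] / params[["lambda"]]^2)
  } else {
    c(A1 = 1 / params[["lambda1"]] - 1 / params[["lambda2"]],
      lambda1 = -params[["A1"]] / params[["lambda1"]]^2,
      lambda2 = params[["A1"]] / params[["lambda2"]]^2)
  }
}

#' Standard error of the dose coefficient
#'
#' Two routes from a fitted time-activity curve to an SE on Gy/MBq:
#'
#' * `"delta"` — first-order propagation of the fit's parameter covariance
#'   through the gradient of the analytic AUC, then through the linear
#'   AUC -> dose map.
#' * `"bootstrap"` — seeded residual bootstrap: per-point residuals are
#'   resampled with replacement, added back to the fitted curve (floored at
#'   0), the model refitted and the dose recomputed; the SE is the SD over
#'   replicates.
#'
#' A fit whose covariance is unavailable or singular falls back from delta
#' to bootstrap with a warning.
#'
#' @param fit A converged `tac_fit`.
#' @param energy Mean alpha energy per decay, MeV.
#' @param method `"delta"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap resampling.
#' @return SE of the dose coefficient, Gy/MBq.
#' @export
dose_uncertainty <- function(fit, energy, method = c("delta", "bootstrap"),
                             n_boot = 2000, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "tac_fit"))
  if (!isTRUE(fit$converged)) {
    stop("cannot propagate uncertainty from a non-converged fit",
         call. = FALSE)
  }
  if (method == "delta") {
    vc <- fit$covariance
    if (is.null(vc) || any(!is.finite(vc))) {
      warning("unusable covariance; falling back to bootstrap SE",
              call. = FALSE)
      return(dose_uncertainty(fit, energy, "bootstrap", n_boot, seed))
    }
    g <- auc_gradient(fit$model, fit$estimates)
    var_auc <- drop(t(g) %*% vc %*% g)
    var_auc <- max(var_auc, 0)
    return(sqrt(var_auc) * energy * dose_conversion)
  }
  # residual bootstrap
  t_obs <- fit$data$t
  fitted <- tac_eval(fit$model, fit$estimates, t_obs)
  resid <- fit$data$y - fitted
  doses <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      y_star <- pmax(fitted + sample(resid, length(resid), replace = TRUE), 0)
      f <- fit_tac(t_obs, y_star, fit$model, init = fit$estimates)
      if (isTRUE(f$converged)) dose_per_unit_activity(f$auc, energy)
      else NA_real_
    }, numeric(1))
  })
  stats::sd(doses, na.rm = TRUE)
}

# evaluate `expr` under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Per-organ dose table from a biodistribution study
#'
#' The full dosimetry pipeline: convert the table to the decay-uncorrected
#' scale, fit each organ's assigned model, integrate analytically, and
#' convert the time-integrated activity to Gy/MBq with the chain's
#' branching-weighted alpha energy. Whole-organ (%ID) records — the
#' neck/thyroid — are excluded from per-gram dosimetry. Organs whose fit
#' fails are kept in the table with `converged = FALSE` rather than
#' aborting the run.
#'
#' @param table A `biodist_table`.
#' @param chain A `nuclide_chain` (default: shipped 211At chain).
#' @param mapping Organ -> model map (default [default_organ_models()]).
#' @param fit_means Fit per-timepoint means (default, one curve per organ
#'   from group means) or all individual animal points.
#' @param se_method `"delta"` or `"bootstrap"` (see [dose_uncertainty()]).
#' @param n_boot,seed Bootstrap controls.
#' @param unknown Policy for organs absent from `mapping`
#'   (see [choose_model()]).
#' @return A `dose_table` data.frame: `organ`, `model`, `converged`,
#'   `auc`, `dose_gy_per_mbq`, `se_gy_per_mbq`; attributes `energy_mev`,
#'   `nuclide`, `injected_mbq`.
#' @export
build_dose_table <- function(table, chain = read_nuclide_chain(),
                             mapping = default_organ_models(),
                             fit_means = TRUE,
                             se_method = c("delta", "bootstrap"),
                             n_boot = 2000, seed = 1,
                             unknown = "error") {
  se_method <- match.arg(se_method)
  validate_biodist(table)
  stopifnot(inherits(chain, "nuclide_chain"))
  energy <- mean_alpha_energy_per_decay(chain)
  lambda <- decay_constant(chain$half_life)

  whole <- table$unit == "percent_id"
  if (any(whole)) {
    message("excluding whole-organ (%ID) records from per-gram dosimetry: ",
            paste(unique(table$organ[whole]), collapse = ", "))
    table <- new_biodist_table(table[!whole, , drop = FALSE],
                               injected_mbq = attr(table, "injected_mbq"),
                               nuclide = attr(table, "nuclide"),
                               study = attr(table, "study"))
  }
  table <- set_decay_correction(table, lambda, target = FALSE)

  organs <- sort(unique(table$organ))
  rows <- lapply(organs, function(org) {
    sub <- table[table$organ == org, , drop = FALSE]
    if (fit_means) {
      agg <- stats::aggregate(value ~ time_h, data = sub, FUN = mean)
      t_fit <- agg$time_h; y_fit <- agg$value
    } else {
      t_fit <- sub$time_h; y_fit <- sub$value
    }
    model <- choose_model(org, mapping, unknown = unknown)
    fit <- fit_tac(t_fit, y_fit, model)
    if (isTRUE(fit$converged)) {
      dose <- dose_per_unit_activity(fit$auc, energy)
      se <- tryCatch(
        dose_uncertainty(fit, energy, se_method, n_boot = n_boot, seed = seed),
        error = function(e) NA_real_)
    } else {
      message("fit failed for organ '", org, "': ", fit$message)
      dose <- NA_real_; se <- NA_real_
    }
    data.frame(organ = org, model = model, converged = isTRUE(fit$converged),
               auc = fit$auc, dose_gy_per_mbq = dose, se_gy_per_mbq = se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, energy_mev = energy, nuclide = chain$parent,
            injected_mbq = attr(table, "injected_mbq"),
            class = c("dose_table", "data.frame"))
}

#' @export
print.dose_table <- function(x, digits = 1, ...) {
  cat(sprintf("<dose_table> %s, %.2f MeV/decay, %d organs\n",
              attr(x, "nuclide"), attr(x, "energy_mev"), nrow(x)))
  df <- as.data.frame(x)
  df$dose_gy_per_mbq <- round(df$dose_gy_per_mbq, digits)
  df$se_gy_per_mbq <- round(df$se_gy_per_mbq, digits)
  df$auc <- signif(df$auc, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
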