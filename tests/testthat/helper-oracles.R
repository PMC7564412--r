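# Independent oracles used across the suite.

# adaptive quadrature of a TAC over [0, T] plus the analytic tail of the
# slowest exponential beyond T (integrate() cannot reach Inf reliably for
# spiky biexp shapes, so the tail is closed-form)
quadrature_auc <- function(model, params, T_split = 500) {
  head <- stats::integrate(function(tt) tac_eval(model, params, tt),
                           0, T_split, rel.tol = 1e-10,
                           subdivisions = 500L)$value
  tail <- if (model == "monoexp") {
    params[["A0"]] * exp(-params[["lambda"]] * T_split) / params[["lambda"]]
  } else {
    params[["A1"]] * (exp(-params[["lambda1"]] * T_split) / params[["lambda1"]] -
                        exp(-params[["lambda2"]] * T_split) / params[["lambda2"]])
  }
  head + tail
}

# log-rank chi-square computed directly from the O-E / hypergeometric
# variance definition, independent of the package's implementation
oracle_logrank_chisq <- function(time, event, grp) {
  etimes <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (tt in etimes) {
    at <- time >= tt
    n <- sum(at); n1 <- sum(at & grp == 1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# small synthetic survival records used by several tests
six_record_example <- function() {
  data.frame(time = c(5, 8, 8, 12, 20, 25), event = c(0, 1, 1, 0, 1, 0))
}

make_biodist_df <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  defaults <- list(unit = "percent_id_per_gram", decay_corrected = TRUE)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  df
}

study_tps <- c(0.25, 1, 4, 7, 14, 21)
cv15_sdlog <- sqrt(log(1 + 0.15^2))
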