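#' Fit two-sample Mendelian randomization estimators
#'
#' The central fitting function: runs the requested causal-effect estimators
#' on a harmonized exposure/outcome pair set and returns a classed model
#' object. The inverse-variance weighted estimate is the primary method;
#' MR-Egger, weighted median, simple median, and weighted mode are reported
#' for concordance. For a binary outcome, estimates are additionally
#' expressed as odds ratios with 95% confidence intervals.
#'
#' @param hset A `harmonized_set` (see [harmonize()] or
#'   [as_harmonized_set()]).
#' @param methods Character vector from `"ivw"`, `"egger"`,
#'   `"weighted_median"`, `"simple_median"`, `"weighted_mode"`. Methods
#'   whose instrument-count requirement is not met are dropped with a
#'   message.
#' @param binary_outcome If `TRUE`, betas are interpreted as log odds ratios
#'   and OR columns are added.
#' @param ivw_mode Passed to [mr_ivw()].
#' @param n_boot,seed Bootstrap settings for the median and mode estimators;
#'   `seed` is required when any bootstrap method is requested.
#' @param bandwidth_phi Bandwidth multiplier for [mr_weighted_mode()].
#' @return An object of class `mr_fit` with components `estimates`
#'   (a data.frame: method, n_snps, beta, se, pvalue, and OR columns when
#'   binary), `egger` (the full [mr_egger()] result, when fitted), `data`
#'   (the harmonized set), and `call`. Methods: `print`, `summary`, `coef`,
#'   `confint`.
#' @export
#' @examples
#' h <- as_harmonized_set(data.frame(
#'   variant_id = paste0("rs", 1:5),
#'   beta_exposure = c(0.10, 0.12, 0.09, 0.11, 0.13),
#'   se_exposure = rep(0.01, 5),
#'   beta_outcome = c(0.031, 0.035, 0.026, 0.034, 0.040),
#'   se_outcome = rep(0.01, 5)))
#' fit <- mr_fit(h, seed = 1, n_boot = 100)
#' coef(fit)
mr_fit <- function(hset,
                   methods = c("ivw", "egger", "weighted_median",
                               "simple_median", "weighted_mode"),
                   binary_outcome = TRUE,
                   ivw_mode = c("random_multiplicative", "fixed"),
                   n_boot = 1000, seed = NULL, bandwidth_phi = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  ivw_mode <- match.arg(ivw_mode)
  k <- nrow(hset)
  if (k < 1) stop_domain("harmonized set is empty")
  needs3 <- c("egger", "weighted_median", "simple_median", "weighted_mode")
  if (k < 3 && any(methods %in% needs3)) {
    dropped <- intersect(methods, needs3)
    message("fewer than 3 instruments: dropping ",
            paste(dropped, collapse = ", "))
    methods <- setdiff(methods, dropped)
  }
  ests <- list()
  egger <- NULL
  for (m in methods) {
    ests[[m]] <- switch(m,
      ivw = mr_ivw(hset, mode = ivw_mode),
      egger = {
        egger <- mr_egger(hset)
        egger$slope
      },
      weighted_median = mr_weighted_median(hset, n_boot, seed),
      simple_median = mr_simple_median(hset, n_boot, seed),
      weighted_mode = mr_weighted_mode(hset, bandwidth_phi, n_boot, seed))
  }
  rows <- lapply(ests, function(e) {
    row <- data.frame(method = e$method, n_snps = e$n_snps, beta = e$beta,
                      se = e$se, pvalue = e$pvalue, stringsAsFactors = FALSE)
    if (binary_outcome && e$se > 0) {
      or <- to_odds_ratio(e$beta, e$se)
      row$or <- or$or_value; row$or_lci95 <- or$or_lci
      row$or_uci95 <- or$or_uci
    }
    row
  })
  estimates <- do.call(rbind, rows)
  if (!is.null(egger)) {
    irow <- data.frame(method = "egger_intercept",
                       n_snps = egger$intercept$n_snps,
                       beta = egger$intercept$beta, se = egger$intercept$se,
                       pvalue = egger$intercept$pvalue,
                       stringsAsFactors = FALSE)
    if (binary_outcome) { irow$or <- NA; irow$or_lci95 <- NA; irow$or_uci95 <- NA }
    estimates <- rbind(estimates, irow)
  }
  rownames(estimates) <- NULL
  structure(list(estimates = estimates, egger = egger, data = hset,
                 binary_outcome = binary_outcome, n_boot = n_boot,
                 seed = seed, call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit: %s -> %s (%d instruments)\n",
              attr(x$data, "exposure_name"), attr(x$data, "outcome_name"),
              nrow(x$data)))
  print(format(x$estimates, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$estimates
  if (!missing(parm)) est <- est[est$method %in% parm, , drop = FALSE]
  out <- cbind(est$beta - z * est$se, est$beta + z * est$se)
  dimnames(out) <- list(est$method,
                        sprintf("%g %%", c((1 - level) / 2,
                                           1 - (1 - level) / 2) * 100))
  out
}

#' @export
summary.mr_fit <- function(object, ...) {
  sens <- NULL
  if (nrow(object$data) >= 2)
    sens <- cochran_q(object$data)
  structure(list(fit = object, q = sens), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$q))
    cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g\n",
                x$q$q_stat, x$q$q_df, x$q$q_pvalue))
  if (!is.null(x$fit$egger))
    cat(sprintf("Egger intercept = %.4g (p = %.3g), I2_GX = %.3f\n",
                x$fit$egger$intercept$beta, x$fit$egger$intercept$pvalue,
                x$fit$egger$i2_gx))
  invisible(x)
}
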