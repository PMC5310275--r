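#' Branch-model fits
#'
#' Container for one codeml branch-model fit: the null model (H0) assigns a
#' single dN/dS ratio (omega) to the whole tree; the alternative (H1)
#' assigns independent omegas to the marked branches.
#'
#' @param label `"H0"` or `"H1"`.
#' @param log_likelihood the fit's log-likelihood.
#' @param omegas numeric vector of dN/dS ratios (length 1 for H0, 2 or more
#'   for H1).
#' @return list of class `branch_model_fit`.
#' @export
branch_model_fit <- function(label, log_likelihood, omegas) {
  if (!is.numeric(log_likelihood) || length(log_likelihood) != 1L ||
      is.na(log_likelihood)) {
    stopf("log_likelihood must be a single number")
  }
  if (length(omegas) > 0L && any(omegas < 0, na.rm = TRUE)) {
    stopf("omega (dN/dS) values must be >= 0")
  }
  structure(list(label = label, log_likelihood = log_likelihood,
                 omegas = as.numeric(omegas)),
            class = "branch_model_fit")
}

#' Branch-model likelihood-ratio test
#'
#' Computes the LRT statistic `2 * (l_alt - l_null)` and its upper-tail
#' chi-square probability with `df` degrees of freedom (the number of extra
#' omega parameters in the alternative). The alternative nests the null, so
#' `l_alt >= l_null` up to a small optimizer tolerance; a larger deficit
#' signals a failed codeml optimization upstream and is an error. The
#' p-value is kept at full precision internally; round only for display.
#'
#' @param null,alt [branch_model_fit()] objects, or bare log-likelihood
#'   numbers.
#' @param df degrees of freedom (>= 1). Given as an explicit argument rather
#'   than inferred; a warning is emitted when fits are supplied and their
#'   omega counts disagree with `df`.
#' @param tol tolerance for `l_alt < l_null` (optimizer noise).
#' @return list of class `lrt_result` with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(null, alt, df = 1L, tol = 1e-6) {
  l0 <- if (inherits(null, "branch_model_fit")) null$log_likelihood else null
  l1 <- if (inherits(alt, "branch_model_fit")) alt$log_likelihood else alt
  if (!is.numeric(l0) || !is.numeric(l1)) {
    stopf("log-likelihoods must be numeric")
  }
  if (df < 1) stopf("df must be >= 1")
  if (inherits(null, "branch_model_fit") && inherits(alt, "branch_model_fit")) {
    extra <- length(alt$omegas) - length(null$omegas)
    if (extra <= 0) {
      stopf("the alternative must have more omega parameters than the null")
    }
    if (extra != df) {
      warnf("df = %d disagrees with the extra omega count (%d)", df, extra)
    }
  }
  if (l1 < l0 - tol) {
    stopf(paste("alternative log-likelihood (%.6f) is below the null (%.6f):",
                "the nested optimization failed upstream"), l1, l0)
  }
  stat <- max(0, 2 * (l1 - l0))
  structure(list(statistic = stat, df = as.integer(df),
                 p_value = stats::pchisq(stat, df = df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: 2*delta(lnL) = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, signif(x$p_value, 4)))
  invisible(x)
}

#' Extract a branch-model fit from a codeml main-result file
#'
#' Scans a codeml output text file for the `lnL` line
#' (`lnL(ntime: .. np: ..): <value> ...`) and for omega estimates, either a
#' one-ratio line (`omega (dN/dS) = <value>`) or a branch-model line
#' (`w (dN/dS) for branches:  <w0> <w1> ...`).
#'
#' @param path path to a codeml result file.
#' @param label model label stored in the fit (default from omega count:
#'   `"H0"` for one ratio, `"H1"` otherwise).
#' @return a [branch_model_fit()].
#' @export
read_codeml_lnl <- function(path, label = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lnl_line <- grep("lnL", lines, value = TRUE)
  if (length(lnl_line) == 0L) stopf("%s: no 'lnL' line found", path)
  m <- regmatches(lnl_line[1L],
                  regexec("lnL.*:\\s*(-?[0-9]+\\.?[0-9]*)", lnl_line[1L]))[[1L]]
  if (length(m) != 2L) stopf("%s: could not parse the 'lnL' line", path)
  lnl <- as.numeric(m[2L])
  omegas <- numeric(0)
  br <- grep("w \\(dN/dS\\) for branches", lines, value = TRUE)
  if (length(br) > 0L) {
    nums <- regmatches(br[1L], gregexpr("[0-9]+\\.[0-9]+", br[1L]))[[1L]]
    omegas <- as.numeric(nums)
  } else {
    om <- grep("omega \\(dN/dS\\)", lines, value = TRUE)
    if (length(om) > 0L) {
      m2 <- regmatches(om[1L],
                       regexec("=\\s*(-?[0-9]+\\.?[0-9]*)", om[1L]))[[1L]]
      if (length(m2) == 2L) omegas <- as.numeric(m2[2L])
    }
  }
  branch_model_fit(label %||% if (length(omegas) <= 1L) "H0" else "H1",
                   lnl, omegas)
}
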