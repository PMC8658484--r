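#' BCPNN prior hyperparameters
#'
#' The Bayesian Confidence Propagation Neural Network (BCPNN) information
#' component shrinks the crude log2 observed/expected reporting ratio with
#' Dirichlet-style priors on the cell and margin probabilities. The
#' hyperparameters used here are the classic choice: `gamma11 = 1` on the
#' joint cell, `alpha1 = beta1 = 1` on the two margins, and `alpha = beta =
#' 2` on the grand total. The joint-cell prior scale `gamma` is not free: it
#' is recomputed for every contingency table as
#' `gamma11 * (N++ + alpha) * (N++ + beta) / ((N1+ + alpha1) * (N+1 +
#' beta1))`, which centres the prior on independence of drug and event.
#'
#' @param gamma11 Prior count added to the joint cell N11. Default 1.
#' @param alpha1 Prior count added to the drug margin N1+. Default 1.
#' @param beta1 Prior count added to the event margin N+1. Default 1.
#' @param alpha,beta Prior counts added to the grand total N++. Default 2.
#'
#' @return An object of class `bcpnn_prior`: a named list of the five
#'   hyperparameters.
#' @examples
#' bcpnn_prior()
#' @export
bcpnn_prior <- function(gamma11 = 1, alpha1 = 1, beta1 = 1,
                        alpha = 2, beta = 2) {
  p <- list(gamma11 = gamma11, alpha1 = alpha1, beta1 = beta1,
            alpha = alpha, beta = beta)
  bad <- !vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                   is.finite(x) && x > 0, logical(1))
  if (any(bad))
    stop("all prior hyperparameters must be single positive numbers; bad: ",
         paste(names(p)[bad], collapse = ", "))
  structure(p, class = "bcpnn_prior")
}

#' @export
print.bcpnn_prior <- function(x, ...) {
  cat("BCPNN prior: gamma11 =", x$gamma11,
      ", alpha1 =", x$alpha1, ", beta1 =", x$beta1,
      ", alpha =", x$alpha, ", beta =", x$beta, "\n")
  cat("gamma is table-dependent:",
      "gamma11 (N+++alpha)(N+++beta) / ((N1++alpha1)(N+1+beta1))\n")
  invisible(x)
}

# table-coupled joint-cell prior scale (log scale for stability)
.bcpnn_log_gamma <- function(n1plus, nplus1, nplusplus, prior) {
  log(prior$gamma11) +
    log(nplusplus + prior$alpha) + log(nplusplus + prior$beta) -
    log(n1plus + prior$alpha1) - log(nplus1 + prior$beta1)
}

.check_counts <- function(n11, n1plus, nplus1, nplusplus) {
  if (any(!is.finite(n11)) || any(!is.finite(n1plus)) ||
      any(!is.finite(nplus1)) || any(!is.finite(nplusplus)))
    stop("all counts must be finite")
  if (any(n11 < 0) || any(n1plus < 0) || any(nplus1 < 0) ||
      any(nplusplus <= 0))
    stop("counts must be non-negative and nplusplus positive")
  if (any(n11 > n1plus) || any(n11 > nplus1))
    stop("inconsistent counts: n11 exceeds a margin")
  if (any(n1plus > nplusplus) || any(nplus1 > nplusplus))
    stop("inconsistent counts: a margin exceeds nplusplus")
}

#' Expectation of the information component
#'
#' Posterior expectation of the information component in bits:
#' `log2[(N11 + gamma11)(N++ + alpha)(N++ + beta) /
#' ((N++ + gamma)(N1+ + alpha1)(N+1 + beta1))]`,
#' with `gamma` the table-coupled prior scale described in
#' [bcpnn_prior()]. The priors keep every factor positive, so the value is
#' finite for any valid table, including `n11 = 0`.
#'
#' All four count arguments are vectorized and recycled to a common length.
#'
#' @param n11 Cases reporting both the drug (group) and the event.
#' @param n1plus Cases reporting the drug (group); the drug margin N1+.
#' @param nplus1 Cases reporting the event; the event margin N+1.
#' @param nplusplus Total cases in the database, N++.
#' @param prior A [bcpnn_prior()].
#'
#' @return Numeric vector of IC expectations, in bits (log2 units).
#' @examples
#' expectation_ic(86, 771, 10802, 534287)
#' @seealso [variance_ic()], [bcpnn()]
#' @export
expectation_ic <- function(n11, n1plus, nplus1, nplusplus,
                           prior = bcpnn_prior()) {
  .check_counts(n11, n1plus, nplus1, nplusplus)
  log_gamma <- .bcpnn_log_gamma(n1plus, nplus1, nplusplus, prior)
  num <- log(n11 + prior$gamma11) +
    log(nplusplus + prior$alpha) + log(nplusplus + prior$beta)
  den <- log(nplusplus + exp(log_gamma)) +
    log(n1plus + prior$alpha1) + log(nplus1 + prior$beta1)
  (num - den) / log(2)
}

#' Variance of the information component
#'
#' Posterior variance of the information component in bits squared:
#' `(1/ln 2)^2 * [ (N++ - N11 + gamma - gamma11) /
#' ((N11 + gamma11)(1 + N++ + gamma)) +
#' (N++ - N1+ + alpha - alpha1) / ((N1+ + alpha1)(1 + N++ + alpha)) +
#' (N++ - N+1 + beta - beta1) / ((N+1 + beta1)(1 + N++ + beta)) ]`,
#' strictly positive for every valid table.
#'
#' @inheritParams expectation_ic
#' @return Numeric vector of IC variances, in bits^2.
#' @examples
#' variance_ic(86, 771, 10802, 534287)
#' @export
variance_ic <- function(n11, n1plus, nplus1, nplusplus,
                        prior = bcpnn_prior()) {
  .check_counts(n11, n1plus, nplus1, nplusplus)
  g <- exp(.bcpnn_log_gamma(n1plus, nplus1, nplusplus, prior))
  t1 <- (nplusplus - n11 + g - prior$gamma11) /
    ((n11 + prior$gamma11) * (1 + nplusplus + g))
  t2 <- (nplusplus - n1plus + prior$alpha - prior$alpha1) /
    ((n1plus + prior$alpha1) * (1 + nplusplus + prior$alpha))
  t3 <- (nplusplus - nplus1 + prior$beta - prior$beta1) /
    ((nplus1 + prior$beta1) * (1 + nplusplus + prior$beta))
  (t1 + t2 + t3) / log(2)^2
}

#' 95 percent credible interval for the information component
#'
#' The interval is the conventional `E(IC) +- 2 sqrt(V(IC))` — exactly two
#' posterior standard deviations, not 1.96.
#'
#' @param e_ic IC expectation(s), bits.
#' @param v_ic IC variance(s), bits^2; must be non-negative.
#' @return A two-column matrix with columns `ic025` and `ic975`.
#' @examples
#' credible_interval(2.39, 0.0268)
#' @export
credible_interval <- function(e_ic, v_ic) {
  if (any(v_ic < 0)) stop("v_ic must be non-negative")
  hw <- 2 * sqrt(v_ic)
  cbind(ic025 = e_ic - hw, ic975 = e_ic + hw)
}

#' Classify a drug-event pair from its credible bounds
#'
#' A pair is a `signal` when the lower credible bound IC025 exceeds 0, an
#' `inverse` signal when the upper bound IC975 is below 0, and `none`
#' otherwise.
#'
#' @param ic025,ic975 Lower and upper credible bounds, bits.
#' @return Character vector in `c("signal", "inverse", "none")`.
#' @examples
#' classify_ic(c(2.19, -0.75, -0.10), c(2.65, -0.17, 2.20))
#' @export
classify_ic <- function(ic025, ic975) {
  if (any(ic025 > ic975)) stop("ic025 must not exceed ic975")
  ifelse(ic025 > 0, "signal", ifelse(ic975 < 0, "inverse", "none"))
}

#' Score drug-event contingency tables with the BCPNN information component
#'
#' The central estimator of the package. Takes one or more case-based 2x2
#' contingency tables — as raw counts or as [count_table()] objects — and
#' returns the IC expectation, variance, 95 percent credible interval
#' (`E +- 2 sqrt(V)`) and signal classification for each.
#'
#' @param x Either numeric `n11` counts (with the three margin arguments
#'   supplied), a `contingency_table`, or a list of `contingency_table`s.
#' @param ... Passed to methods.
#' @return An object of class `bcpnn`: a data frame with one row per table
#'   and columns `group`, `n11`, `n1plus`, `nplus1`, `nplusplus`, `e_ic`,
#'   `v_ic`, `ic025`, `ic975`, `classification`.
#' @examples
#' fit <- bcpnn(c(enalapril = 86, imidapril = 48), n1plus = c(771, 291),
#'              nplus1 = 10802, nplusplus = 534287)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
bcpnn <- function(x, ...) UseMethod("bcpnn")

#' @rdname bcpnn
#' @inheritParams expectation_ic
#' @param labels Optional group labels; defaults to `names(x)`.
#' @export
bcpnn.default <- function(x, n1plus, nplus1, nplusplus,
                          prior = bcpnn_prior(), labels = NULL, ...) {
  n11 <- x
  k <- max(length(n11), length(n1plus), length(nplus1), length(nplusplus))
  if (is.null(labels)) labels <- names(n11)
  if (is.null(labels)) labels <- if (k == 1L) "table" else paste0("table", seq_len(k))
  n11 <- rep_len(n11, k); n1plus <- rep_len(n1plus, k)
  nplus1 <- rep_len(nplus1, k); nplusplus <- rep_len(nplusplus, k)
  e <- expectation_ic(n11, n1plus, nplus1, nplusplus, prior)
  v <- variance_ic(n11, n1plus, nplus1, nplusplus, prior)
  ci <- credible_interval(e, v)
  out <- data.frame(group = rep_len(labels, k),
                    n11 = n11, n1plus = n1plus,
                    nplus1 = nplus1, nplusplus = nplusplus,
                    e_ic = e, v_ic = v,
                    ic025 = ci[, "ic025"], ic975 = ci[, "ic975"],
                    classification = classify_ic(ci[, "ic025"], ci[, "ic975"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("bcpnn", "data.frame"), prior = prior)
}

#' @rdname bcpnn
#' @export
bcpnn.contingency_table <- function(x, prior = bcpnn_prior(), ...) {
  bcpnn.default(stats::setNames(x$n11, x$group), n1plus = x$n1plus,
                nplus1 = x$nplus1, nplusplus = x$nplusplus, prior = prior)
}

#' @rdname bcpnn
#' @export
bcpnn.list <- function(x, prior = bcpnn_prior(), ...) {
  fits <- lapply(x, bcpnn, prior = prior)
  out <- do.call(rbind, lapply(fits, as.data.frame))
  row.names(out) <- NULL
  structure(out, class = c("bcpnn", "data.frame"), prior = prior)
}

#' @export
print.bcpnn <- function(x, digits = 2, dash_zero_n11 = FALSE, ...) {
  cat("BCPNN information-component scores (", nrow(x), " table",
      if (nrow(x) != 1) "s", ")\n", sep = "")
  df <- format_ic_table(x, digits = digits, dash_zero_n11 = dash_zero_n11)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.bcpnn <- function(object, ...) {
  cl <- table(factor(object$classification,
                     levels = c("signal", "none", "inverse")))
  cat("BCPNN scores for", nrow(object), "drug-event tables\n")
  cat("  signals (IC025 > 0): ", cl[["signal"]], "\n")
  cat("  inverse (IC975 < 0): ", cl[["inverse"]], "\n")
  cat("  no signal:           ", cl[["none"]], "\n")
  invisible(object)
}

#' @export
coef.bcpnn <- function(object, ...) {
  stats::setNames(object$e_ic, object$group)
}

#' @export
confint.bcpnn <- function(object, parm, level = 0.95, ...) {
  if (!missing(level) && !isTRUE(all.equal(level, 0.95)))
    stop("only the E +- 2 sqrt(V) 95% interval is defined for BCPNN scores")
  m <- cbind(ic025 = object$ic025, ic975 = object$ic975)
  rownames(m) <- object$group
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
as.data.frame.bcpnn <- function(x, ...) {
  class(x) <- "data.frame"
  x
}

#' Render a scored table the way published signal tables print
#'
#' Formats IC and CI to a fixed number of decimals and marks signals with
#' `*` and inverse signals with a dagger. Rows with `n11 = 0` can be
#' rendered as an em-dash instead of their (still computed and stored)
#' values; published tables differ on this, so it is a renderer option, not
#' a property of the statistic.
#'
#' @param fit A [bcpnn()] object.
#' @param digits Decimals for IC and CI. Default 2.
#' @param dash_zero_n11 Render rows with `n11 = 0` as an em-dash.
#' @return A data frame with columns `group`, `n11`, `n1plus`, `ic`.
#' @export
format_ic_table <- function(fit, digits = 2, dash_zero_n11 = FALSE) {
  fmt <- function(z) formatC(round_half_up(z, digits), format = "f",
                             digits = digits)
  mark <- c(signal = " *", inverse = " †", none = "")
  ic <- paste0(fmt(fit$e_ic), mark[fit$classification],
               " (", fmt(fit$ic025), " to ", fmt(fit$ic975), ")")
  if (dash_zero_n11) ic[fit$n11 == 0] <- "―"
  data.frame(group = fit$group, n11 = fit$n11, n1plus = fit$n1plus,
             ic = ic, stringsAsFactors = FALSE)
}

#' Reporting odds ratio comparator
#'
#' The ROR `(N11 N00) / (N10 N01)` with a 95 percent Wald interval
#' `exp(ln ROR +- 1.96 sqrt(1/N11 + 1/N10 + 1/N01 + 1/N00))`. Unlike the
#' shrunk IC, the ROR is undefined (NA) when a denominator cell is zero,
#' and its interval is undefined when any cell is zero — the instability at
#' small counts that motivates the BCPNN.
#'
#' @param n11,n10,n01,n00 The four cells of the 2x2 table, or a
#'   `contingency_table` as `n11` with the others missing.
#' @return A data frame with columns `ror`, `ci_low`, `ci_high`.
#' @examples
#' ror(20, 80, 100, 900)
#' @export
ror <- function(n11, n10, n01, n00) {
  if (inherits(n11, "contingency_table")) {
    tab <- n11
    return(ror(tab$n11, tab$n10, tab$n01, tab$n00))
  }
  if (any(c(n11, n10, n01, n00) < 0)) stop("cells must be non-negative")
  est <- ifelse(n10 > 0 & n01 > 0, (n11 * n00) / (n10 * n01), NA_real_)
  ok <- n11 > 0 & n10 > 0 & n01 > 0 & n00 > 0
  se <- ifelse(ok, sqrt(1 / n11 + 1 / n10 + 1 / n01 + 1 / n00), NA_real_)
  data.frame(ror = est,
             ci_low = exp(log(est) - 1.96 * se),
             ci_high = exp(log(est) + 1.96 * se))
}

#' Recover an unpublished event margin from published IC values
#'
#' Published disproportionality tables usually print the per-drug cell N11,
#' the drug margin N1+ and the database total N++, but not the event margin
#' N+1 (the total number of cases with the event). Given rows of
#' `(n11, n1plus, published IC)` that share one database, this routine
#' recovers the integer N+1 by exhaustive grid search, minimizing the sum
#' of squared deviations between [expectation_ic()] and the published
#' values. Ties break toward the smaller margin.
#'
#' @param n11,n1plus Per-row counts.
#' @param ic Published IC values for the same rows, bits.
#' @param nplusplus The database total N++.
#' @param search_range Integer range searched, default `c(1, 50000)`.
#' @param prior A [bcpnn_prior()].
#' @return A list of class `margin_calibration`: `nplus1` (the recovered
#'   integer margin), `sse`, `rms` (root-mean-square residual in bits), and
#'   `n_rows`. A minimum on the range boundary triggers a warning.
#' @examples
#' e <- expectation_ic(c(9, 2), c(50, 40), 300, 10000)
#' calibrate_margin(c(9, 2), c(50, 40), e, 10000)$nplus1
#' @export
calibrate_margin <- function(n11, n1plus, ic, nplusplus,
                             search_range = c(1, 50000),
                             prior = bcpnn_prior()) {
  stopifnot(length(n11) == length(n1plus), length(n11) == length(ic),
            length(n11) >= 1)
  grid <- seq.int(max(search_range[1], max(n11)), search_range[2])
  if (!length(grid)) stop("search_range excludes all valid margins")
  sse <- vapply(grid, function(m) {
    sum((expectation_ic(n11, n1plus, m, nplusplus, prior) - ic)^2)
  }, numeric(1))
  i <- which.min(sse)  # which.min takes the first, i.e. smallest, on ties
  if (i == 1L || i == length(grid))
    warning("calibration minimum lies on the search-range boundary; ",
            "widen search_range")
  structure(list(nplus1 = grid[i], sse = sse[i],
                 rms = sqrt(sse[i] / length(n11)), n_rows = length(n11)),
            class = "margin_calibration")
}

#' @export
print.margin_calibration <- function(x, ...) {
  cat("Calibrated event margin N+1 =", x$nplus1,
      "from", x$n_rows, "published rows",
      sprintf("(RMS residual %.4f bits)\n", x$rms))
  invisible(x)
}
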