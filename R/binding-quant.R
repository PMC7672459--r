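# Quantitative binding formulas: two-population EMSA isotherm fit,
# delta-delta-Ct qPCR enrichment, and pull-down enrichment normalisation.

#' Two-population binding isotherm
#'
#' Fractional bound DNA at free probe concentration X under a 1:1
#' stoichiometry with two G4 subpopulations:
#' `Y = F1 * X / (Kd1 + X) + (1 - F1) * X / (Kd2 + X)`.
#'
#' @param X Free probe concentration(s), molar, non-negative.
#' @param kd1,kd2 Dissociation constants (molar, > 0).
#' @param f1 Fraction of the subpopulation associated with `kd1`, in
#'   \[0, 1\].
#' @return Fractional bound values in \[0, 1).
#' @examples
#' predict_bound(5e-9, kd1 = 5e-9, kd2 = 5e-9, f1 = 1)  # half saturation
#' @export
predict_bound <- function(X, kd1, kd2 = kd1, f1 = 1) {
  if (any(X < 0)) stop("negative probe concentration")
  f1 * X / (kd1 + X) + (1 - f1) * X / (kd2 + X)
}

.two_site_rss <- function(par, x, y) {
  # par = (f1, log10 kd1, log10 kd2)
  yy <- predict_bound(x, 10^par[2], 10^par[3], par[1])
  sum((y - yy)^2)
}

#' Fit the two-population EMSA binding model
#'
#' Nonlinear least squares of the [predict_bound()] isotherm from a grid of
#' start points (F1 in 0.25/0.5/0.75, Kds log-spaced over the observed X
#' range), keeping the best-RSS solution.  Kds are canonically ordered
#' (`kd1 <= kd2`).  When the two Kds coincide within 0.05 log10 units, or
#' `kd2` exceeds 1 M, the fit is flagged degenerate and a single-Kd
#' (one-site) model is refit and reported.
#'
#' @param x Free probe concentrations (molar, >= 0, strictly ascending, >= 4
#'   points).
#' @param y Fractional bound values; values outside \[0, 1\] are clipped
#'   with a warning flag.
#' @param kd_bounds Kd search bounds in molar (default `c(1e-12, 10)`).
#' @param f1_starts Start grid for F1.
#' @return Object of class `binding_fit`: `kd1`, `kd2`, `f1`, `rss`,
#'   `degenerate`, `clipped`.
#' @export
fit_two_site <- function(x, y, kd_bounds = c(1e-12, 10),
                         f1_starts = c(0.25, 0.5, 0.75)) {
  if (length(x) != length(y) || length(x) < 4L) stop("need >= 4 titration points")
  if (is.unsorted(x, strictly = TRUE)) stop("X must be strictly ascending")
  if (any(x < 0)) stop("negative probe concentration")
  clipped <- any(y < 0 | y > 1)
  if (clipped) {
    warning("Y values clipped to [0, 1]")
    y <- pmin(pmax(y, 0), 1)
  }
  if (all(y == 0)) stop("all-zero fractional bound data")
  lb <- log10(kd_bounds[1]); ub <- log10(kd_bounds[2])
  lx <- log10(x[x > 0])
  kq <- unname(quantile(lx, c(0.2, 0.5, 0.8)))
  kd_pairs <- list(c(kq[1], kq[2]), c(kq[1], kq[3]), c(kq[2], kq[3]),
                   c(kq[2], kq[2]))
  best <- NULL
  for (f1 in f1_starts) for (kp in kd_pairs) {
    fit <- try(optim(c(f1, kp[1], kp[2]), .two_site_rss, x = x, y = y,
                     method = "L-BFGS-B",
                     lower = c(0, lb, lb), upper = c(1, ub, ub),
                     control = list(factr = 1e3, maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("two-site fit failed from every start point")
  p <- best$par
  kd <- sort(c(10^p[2], 10^p[3]))
  f1 <- if (p[2] <= p[3]) p[1] else 1 - p[1]
  degenerate <- abs(log10(kd[2]) - log10(kd[1])) < 0.05 || kd[2] > 1
  if (degenerate) {
    one <- optim(log10(pmin(kd[1], kd_bounds[2])), function(lk)
      sum((y - predict_bound(x, 10^lk, 10^lk, 1))^2),
      method = "Brent", lower = lb, upper = ub)
    kd <- rep(10^one$par, 2L)
    f1 <- 1
    rss <- one$value
  } else {
    rss <- best$value
  }
  structure(list(kd1 = kd[1], kd2 = kd[2], f1 = f1, rss = rss,
                 degenerate = degenerate, clipped = clipped),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("binding_fit (one site): Kd = %.3g M, RSS = %.3g\n", x$kd1, x$rss))
  } else {
    cat(sprintf("binding_fit: Kd1 = %.3g M (F1 = %.2f), Kd2 = %.3g M, RSS = %.3g\n",
                x$kd1, x$f1, x$kd2, x$rss))
  }
  invisible(x)
}

#' ChIP-qPCR fold enrichment by double delta Ct
#'
#' Enrichment of a target locus in the ChIP sample relative to input, each
#' calibrated against a PQS-negative reference region:
#' `fold = efficiency ^ -((ct_chip_target - ct_chip_ref) -
#' (ct_input_target - ct_input_ref))`.
#'
#' @param q List or data frame row with `ct_chip_target`, `ct_chip_ref`,
#'   `ct_input_target`, `ct_input_ref` (finite positive cycle numbers).
#' @param efficiency Amplification efficiency per cycle, in (1, 2\]
#'   (default 2, classic delta-delta-Ct).
#' @return Fold enrichment.
#' @export
ddct_enrichment <- function(q, efficiency = 2.0) {
  if (efficiency <= 1 || efficiency > 2) stop("efficiency must be in (1, 2]")
  cts <- unlist(q[c("ct_chip_target", "ct_chip_ref", "ct_input_target", "ct_input_ref")])
  if (any(!is.finite(cts)) || any(cts <= 0)) stop("Ct values must be finite and positive")
  ddct <- (q$ct_chip_target - q$ct_chip_ref) - (q$ct_input_target - q$ct_input_ref)
  efficiency^(-ddct)
}

#' Pull-down enrichment with internal-control calibration
#'
#' Quantities of the target and internal-reference amplicons in the
#' pull-down are calibrated against the same ratio in the input, then
#' normalised to the equivalent ratio of the mutant-motif (template strand)
#' condition.
#'
#' @param q_target_pulldown,q_ref_pulldown,q_target_input,q_ref_input
#'   Positive DNA quantities.
#' @param normalizer The same double ratio computed for the normalising
#'   condition (default 1).
#' @return Fold enrichment.
#' @export
pulldown_enrichment <- function(q_target_pulldown, q_ref_pulldown,
                                q_target_input, q_ref_input, normalizer = 1) {
  qs <- c(q_target_pulldown, q_ref_pulldown, q_target_input, q_ref_input, normalizer)
  if (any(qs == 0)) stop("zero quantity in pull-down enrichment")
  ((q_target_pulldown / q_ref_pulldown) / (q_target_input / q_ref_input)) / normalizer
}
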