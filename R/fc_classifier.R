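# Fold-change distribution thresholding: floor-binned log2FC histogram,
# Gaussian/Lorentzian peak fit, center +/- width gene categorization.

GENE_CATEGORIES <- c("increased", "decreased", "unchanged", "not_significant")

#' Floor-binned log2 fold-change histogram
#'
#' Each finite value is rounded down (toward minus infinity) to the nearest
#' multiple of `bin_width` and equal values are summed; -0.01 therefore lands
#' in bin -0.1, not 0. Non-finite values are dropped and counted.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param bin_width Bin width (default 0.1).
#' @return A data.frame of class `"fc_histogram"` with columns `bin_left`
#'   (floor edge) and `count`, sorted by bin, plus attributes `bin_width` and
#'   `n_dropped`.
#' @export
build_histogram <- function(log2fc, bin_width = 0.1) {
  stopifnot(is.numeric(bin_width), length(bin_width) == 1L, bin_width > 0)
  keep <- is.finite(log2fc)
  n_dropped <- sum(!keep)
  x <- log2fc[keep]
  if (!length(x))
    stop("no finite log2 fold changes to bin")
  if (n_dropped)
    message("build_histogram: dropped ", n_dropped, " non-finite value(s)")
  # small forgiveness term so values that are exact bin edges up to floating
  # error (0.3 stored as 0.29999...) land in their own bin
  idx <- floor(x / bin_width + 1e-9)
  tab <- table(idx)
  h <- data.frame(bin_left = round(as.numeric(names(tab)) * bin_width, 10L),
                  count = as.integer(tab))
  h <- h[order(h$bin_left), , drop = FALSE]
  rownames(h) <- NULL
  structure(h, class = c("fc_histogram", "data.frame"),
            bin_width = bin_width, n_dropped = n_dropped)
}

gaussian_peak <- function(x, A, mu, w) A * exp(-(x - mu)^2 / (2 * w^2))
lorentzian_peak <- function(x, A, mu, w) A * w^2 / ((x - mu)^2 + w^2)

#' Fit a Gaussian or Lorentzian peak to a fold-change histogram
#'
#' Nonlinear least squares (Levenberg-Marquardt) of bin count against bin
#' center (`bin_left + bin_width/2`) for
#' `A * exp(-(x - mu)^2 / (2 * sigma^2))` (Gaussian) or
#' `A * gamma^2 / ((x - mu)^2 + gamma^2)` (Lorentzian, `gamma` =
#' half-width at half-maximum). Initialization is deterministic: the modal bin
#' center for `mu`, the modal count for `A`, and the half-maximum span for the
#' width.
#'
#' @param h Histogram from [build_histogram()], with at least 5 occupied bins.
#' @param model `"gaussian"` or `"lorentzian"`.
#' @return A list of class `"fc_fit"` with elements `model`, `center`, `width`,
#'   `amplitude`, `sse`, `converged`. On optimizer failure `converged` is FALSE
#'   and the parameters are NA; the caller decides policy.
#' @export
fit_distribution <- function(h, model = c("gaussian", "lorentzian")) {
  model <- match.arg(model)
  stopifnot(inherits(h, "fc_histogram"))
  if (nrow(h) < 5L)
    stop("need at least 5 occupied bins to fit a peak")
  bw <- attr(h, "bin_width")
  x <- h$bin_left + bw / 2
  y <- as.numeric(h$count)

  imax <- which.max(y)
  A0 <- y[imax]
  mu0 <- x[imax]
  above <- x[y >= A0 / 2]
  fwhm0 <- max(diff(range(above)), bw)
  w0 <- if (model == "gaussian") fwhm0 / (2 * sqrt(2 * log(2))) else fwhm0 / 2
  w0 <- max(w0, bw / 2)

  peak <- if (model == "gaussian") gaussian_peak else lorentzian_peak
  # raw Levenberg-Marquardt interface: unlike the nls wrapper it does not
  # break down when the residuals reach exactly zero (noiseless histograms)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A = A0, mu = mu0, w = w0),
      fn = function(par) y - peak(x, par[["A"]], par[["mu"]], par[["w"]]),
      lower = c(1e-12, -Inf, 1e-9),
      control = minpack.lm::nls.lm.control(
        ftol = 1e-12, ptol = 1e-12, maxiter = 1000, maxfev = 10000)),
    error = function(e) NULL)
  # info codes 1:3 = ftol/ptol convergence, 4 = gradient orthogonality
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    return(structure(list(model = model, center = NA_real_, width = NA_real_,
                          amplitude = NA_real_, sse = NA_real_,
                          converged = FALSE, histogram = h),
                     class = "fc_fit"))
  }
  cf <- fit$par
  structure(list(model = model, center = unname(cf[["mu"]]),
                 width = abs(unname(cf[["w"]])), amplitude = unname(cf[["A"]]),
                 sse = fit$deviance, converged = TRUE, histogram = h),
            class = "fc_fit")
}

#' @export
print.fc_fit <- function(x, ...) {
  cat(sprintf("%s peak fit: center = %.4f, width = %.4f, amplitude = %.1f, sse = %.3g (%s)\n",
              x$model, x$center, x$width, x$amplitude, x$sse,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Select the better-fitting peak model
#'
#' Fits both the Gaussian and the Lorentzian peak and returns the converged fit
#' with the smaller residual sum of squares; if only one converges, that one.
#' Both candidate fits are attached as attribute `"candidates"`.
#'
#' @param h Histogram from [build_histogram()].
#' @param model `"auto"` for selection by residual sum of squares, or force
#'   `"gaussian"` / `"lorentzian"`.
#' @return An `"fc_fit"` object.
#' @export
select_model <- function(h, model = c("auto", "gaussian", "lorentzian")) {
  model <- match.arg(model)
  if (model != "auto")
    return(fit_distribution(h, model))
  fg <- fit_distribution(h, "gaussian")
  fl <- fit_distribution(h, "lorentzian")
  if (!fg$converged && !fl$converged)
    stop("neither peak model converged; choose fit_model explicitly ",
         "in the run configuration")
  pick <- if (!fl$converged) fg
          else if (!fg$converged) fl
          else if (fg$sse <= fl$sse) fg else fl
  attr(pick, "candidates") <- list(gaussian = fg, lorentzian = fl)
  pick
}

#' Categorize genes against fitted distribution thresholds
#'
#' Genes with `padj >= alpha` are `not_significant`. Significant genes are
#' `increased` when `log2fc > center + width`, `decreased` when
#' `log2fc < center - width`, and `unchanged` otherwise (boundary equality is
#' `unchanged`). When a Lorentzian fit is used, its half-width at half-maximum
#' plays the role of the width (a Lorentzian has no finite standard deviation);
#' this substitution is reported with a message.
#'
#' @param de DE table (see [de_test()] / [read_de_table()]).
#' @param fit Converged `"fc_fit"` object.
#' @param alpha Significance gate on `padj` (default 0.05).
#' @return A data.frame with columns `gene_id`, `log2fc`, `padj`, `category`
#'   (factor with levels increased, decreased, unchanged, not_significant).
#' @export
classify_genes <- function(de, fit, alpha = 0.05) {
  de <- validate_de_table(de)
  stopifnot(inherits(fit, "fc_fit"))
  if (!isTRUE(fit$converged))
    stop("distribution fit did not converge; cannot classify")
  stopifnot(alpha > 0, alpha < 1)
  if (fit$model == "lorentzian")
    message("classify_genes: using Lorentzian half-width at half-maximum ",
            "in place of a standard deviation for the thresholds")
  lo <- fit$center - fit$width
  hi <- fit$center + fit$width
  cat <- ifelse(de$padj >= alpha, "not_significant",
         ifelse(de$log2fc > hi, "increased",
         ifelse(de$log2fc < lo, "decreased", "unchanged")))
  data.frame(gene_id = de$gene_id, log2fc = de$log2fc, padj = de$padj,
             category = factor(cat, levels = GENE_CATEGORIES),
             stringsAsFactors = FALSE)
}

#' Plot a fold-change histogram with its fitted peak
#'
#' @param x An `"fc_fit"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fc_fit <- function(x, ...) {
  h <- x$histogram
  bw <- attr(h, "bin_width")
  xc <- h$bin_left + bw / 2
  graphics::plot(xc, h$count, type = "h", lwd = 3, col = "grey60",
                 xlab = "log2 fold change", ylab = "genes per bin", ...)
  if (isTRUE(x$converged)) {
    xs <- seq(min(xc), max(xc), length.out = 400L)
    f <- if (x$model == "gaussian") gaussian_peak else lorentzian_peak
    graphics::lines(xs, f(xs, x$amplitude, x$center, x$width), col = "red3",
                    lwd = 2)
    graphics::abline(v = x$center + c(-1, 1) * x$width, lty = 2)
  }
  invisible(x)
}
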