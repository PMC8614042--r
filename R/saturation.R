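#' Bin expressed multi-exon genes by expression rank
#'
#' Genes passing the mode's expression rule are sorted by increasing
#' expression (ties broken by gene_id for determinism) and grouped into
#' consecutive bins of exactly `bin_size` genes; a trailing partial bin is
#' dropped so per-bin variance stays comparable. ASP and ASL are computed per
#' bin.
#'
#' @param records Per-gene record table (see [gene_splicing_records()]).
#' @param bin_size Genes per bin (the analysis uses 100 and 500).
#' @param mode Counting mode, as in [species_asp()].
#' @param fpkm_threshold Expression threshold for isoform/event modes.
#' @return A `bin_series` data.frame (bin_index, mean_expression, asp, asl,
#'   n_genes) with attributes `bin_size` and `mode`.
#' @export
bin_genes_by_expression <- function(records, bin_size,
                                    mode = c("junction", "isoform", "event"),
                                    fpkm_threshold = 0.1) {
  mode <- match.arg(mode)
  stopifnot(bin_size >= 1)
  denom <- .asp_denominator(records, mode, fpkm_threshold)
  r <- records[denom, , drop = FALSE]
  r <- r[order(r$expression, r$gene_id), , drop = FALSE]
  n_bins <- nrow(r) %/% bin_size
  if (n_bins < 2L)
    stop("fewer than 2 full bins (", nrow(r), " genes, bin size ",
         bin_size, ")")
  r <- r[seq_len(n_bins * bin_size), , drop = FALSE]
  bin <- rep(seq_len(n_bins), each = bin_size)
  spliced <- switch(mode,
    junction = r$n_clusters >= 1L,
    isoform = r$n_isoforms > 1L,
    event = r$n_events > 1L)
  lvl <- switch(mode,
    junction = r$entropy_asl,
    isoform = r$n_isoforms,
    event = r$n_events)
  out <- data.frame(
    bin_index = seq_len(n_bins),
    mean_expression = as.numeric(rowsum(r$expression, bin)[, 1]) / bin_size,
    asp = as.numeric(rowsum(as.numeric(spliced), bin)[, 1]) / bin_size,
    asl = as.numeric(rowsum(as.numeric(lvl), bin)[, 1]) / bin_size,
    n_genes = bin_size)
  attr(out, "bin_size") <- bin_size
  attr(out, "mode") <- mode
  class(out) <- c("bin_series", "data.frame")
  out
}

#' Fit the logistic saturation curve to a bin series
#'
#' Per-bin ASP or ASL is modelled as a logistic function of expression rank,
#' F(x) = alpha / (1 + exp((xmid - x) / scal)), fitted by bounded nonlinear
#' least squares. The upper asymptote alpha is the depth-corrected (predicted)
#' ASP/ASL. By default x is the bin index; the log mean expression of the bin
#' can be used instead.
#'
#' Starting values come from the data (alpha at 1.05 times the maximum
#' response, xmid at the first bin reaching half of that, scal from the x
#' interquartile spread). alpha is bounded to (0, 1.5\] for ASP (a
#' proportion) and (0, Inf) for ASL; scal is bounded positive so the fitted
#' curve is monotone non-decreasing. A perfectly flat response is fitted as
#' the constant model alpha = mean(response). On optimizer failure the fit is
#' returned with `converged = FALSE` and fitted values from the starting
#' parameters, so the plateau-based estimate remains available.
#'
#' @param series A `bin_series`.
#' @param response `"asp"` or `"asl"`.
#' @param x_scale `"index"` (default) or `"log_expression"`.
#' @return A `saturation_fit` object with elements alpha, xmid, scal,
#'   converged, fitted_values, x, observed, response.
#' @export
fit_saturation_curve <- function(series, response = c("asp", "asl"),
                                 x_scale = c("index", "log_expression")) {
  response <- match.arg(response)
  x_scale <- match.arg(x_scale)
  stopifnot(inherits(series, "bin_series"))
  if (nrow(series) < 4L) stop("need at least 4 bins to fit")
  y <- series[[response]]
  x <- if (x_scale == "index") as.numeric(series$bin_index)
       else log(series$mean_expression)

  new_fit <- function(alpha, xmid, scal, converged, fitted) {
    structure(list(alpha = alpha, xmid = xmid, scal = scal,
                   converged = converged, fitted_values = fitted,
                   x = x, observed = y, response = response,
                   x_scale = x_scale),
              class = "saturation_fit")
  }
  if (diff(range(y)) < 1e-12)  # degenerate flat response
    return(new_fit(mean(y), -Inf, 1, TRUE, rep(mean(y), length(y))))

  alpha0 <- max(y) * 1.05
  xmid0 <- x[which(y >= alpha0 / 2)[1]]
  if (is.na(xmid0)) xmid0 <- stats::median(x)
  scal0 <- max(diff(stats::quantile(x, c(0.25, 0.75))) / 4, 1e-3)
  upper_alpha <- if (response == "asp") 1.5 else Inf
  start <- c(alpha = min(alpha0, upper_alpha), xmid = xmid0, scal = scal0)

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ alpha / (1 + exp((xmid - x) / scal)),
                      data = data.frame(x = x, y = y),
                      start = as.list(start),
                      lower = c(1e-9, -Inf, 1e-9),
                      upper = c(upper_alpha, Inf, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    f0 <- start["alpha"] / (1 + exp((start["xmid"] - x) / start["scal"]))
    return(new_fit(unname(start["alpha"]), unname(start["xmid"]),
                   unname(start["scal"]), FALSE, unname(f0)))
  }
  cf <- stats::coef(fit)
  new_fit(unname(cf["alpha"]), unname(cf["xmid"]), unname(cf["scal"]),
          isTRUE(fit$convInfo$isConv), as.numeric(stats::fitted(fit)))
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf(paste0("saturation_fit (%s ~ logistic(%s)): alpha = %.4f, ",
                     "xmid = %.3f, scal = %.3f, converged = %s\n"),
              x$response, x$x_scale, x$alpha, x$xmid, x$scal, x$converged))
  invisible(x)
}

#' @export
coef.saturation_fit <- function(object, ...) {
  c(alpha = object$alpha, xmid = object$xmid, scal = object$scal)
}

#' @export
predict.saturation_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.list(newdata)) newdata$x else newdata
  object$alpha / (1 + exp((object$xmid - x) / object$scal))
}

#' @export
residuals.saturation_fit <- function(object, ...) {
  object$observed - object$fitted_values
}

#' @export
plot.saturation_fit <- function(x, ...) {
  graphics::plot(x$x, x$observed, xlab = x$x_scale, ylab = x$response,
                 pch = 19, ...)
  o <- order(x$x)
  graphics::lines(x$x[o], x$fitted_values[o], col = "red")
  graphics::abline(h = x$alpha, lty = 2, col = "grey40")
  invisible(x)
}

#' Plateau-based saturation estimate
#'
#' Plateau bins are those whose fitted value differs from the previous bin's
#' fitted value by less than `tol` (the first bin is compared forward to the
#' second). Because a logistic is flat at both tails, plateau bins are
#' additionally required to lie beyond the fitted midpoint, so the plateau
#' captures the upper asymptote rather than the undetected low-expression
#' tail. The plateau mean is the mean of the OBSERVED responses over plateau
#' bins; sequencing depth is called saturated when at least
#' `min_plateau_bins` bins lie on the plateau.
#'
#' @param fit A `saturation_fit`.
#' @param series Optional `bin_series` the fit came from (only used for
#'   consistency checks).
#' @param tol Absolute successive-difference threshold (default 1e-4).
#' @param min_plateau_bins Bins required to call saturation (default 4).
#' @return A `saturation_estimate` list: pasp_or_pasl (the fitted asymptote
#'   alpha), plateau_mean, n_plateau_bins, saturated, plateau_bins (logical).
#' @export
plateau_estimate <- function(fit, series = NULL, tol = 1e-4,
                             min_plateau_bins = 4) {
  stopifnot(inherits(fit, "saturation_fit"))
  f <- fit$fitted_values
  d <- abs(diff(f))
  plateau <- c(d[1] < tol, d < tol)  # first bin compared forward
  plateau <- plateau & fit$x > fit$xmid  # upper-asymptote side only
  n <- sum(plateau)
  structure(list(
    pasp_or_pasl = fit$alpha,
    plateau_mean = if (n) mean(fit$observed[plateau]) else NA_real_,
    n_plateau_bins = n,
    saturated = n >= min_plateau_bins,
    plateau_bins = plateau), class = "saturation_estimate")
}

#' @export
print.saturation_estimate <- function(x, ...) {
  cat(sprintf(paste0("saturation_estimate: asymptote %.4f, plateau mean %.4f",
                     " over %d bins (saturated: %s)\n"),
              x$pasp_or_pasl, x$plateau_mean, x$n_plateau_bins, x$saturated))
  invisible(x)
}

#' One-call depth-corrected ASP/ASL estimate
#'
#' Bins the records, fits the logistic saturation curve and extracts both the
#' asymptote and the plateau mean. The headline estimate is the fitted
#' asymptote when the optimizer converged, falling back to the plateau mean
#' (or the raw maximum bin response if no plateau exists).
#'
#' @inheritParams bin_genes_by_expression
#' @param response `"asp"` or `"asl"`.
#' @param tol Plateau tolerance (default 1e-4).
#' @return List: estimate, fit (`saturation_fit`), plateau
#'   (`saturation_estimate`), series (`bin_series`).
#' @export
estimate_splicing_saturation <- function(records, bin_size = 100,
                                         response = c("asp", "asl"),
                                         mode = "junction",
                                         fpkm_threshold = 0.1, tol = 1e-4) {
  response <- match.arg(response)
  series <- bin_genes_by_expression(records, bin_size, mode, fpkm_threshold)
  fit <- fit_saturation_curve(series, response)
  pl <- plateau_estimate(fit, series, tol)
  est <- if (fit$converged) fit$alpha
         else if (!is.na(pl$plateau_mean)) pl$plateau_mean
         else max(fit$observed)
  list(estimate = est, fit = fit, plateau = pl, series = series)
}

#' Bin-size robustness scan
#'
#' Recomputes the depth-corrected ASP/ASL estimate at a ladder of bin sizes
#' (default 50 to 500 in steps of 50) and reports the sample standard
#' deviation across sizes, per species. When a cross-species complexity
#' trait is supplied, also reports the SD across bin sizes of the Spearman
#' correlation between the per-species estimates and the trait.
#'
#' @param records_list Named list (by species) of per-gene record tables.
#' @param sizes Bin sizes to scan (default `seq(50, 500, by = 50)`).
#' @param trait Optional named numeric vector of a per-species complexity
#'   trait (e.g. cell type number), names matching `records_list`.
#' @param response `"asp"` or `"asl"`.
#' @param mode Counting mode.
#' @return List: `estimates` (species x size matrix), `sd_estimate` (named
#'   per-species SD), `rho` (per-size Spearman correlations, if `trait`),
#'   `sd_rho`.
#' @export
binsize_robustness <- function(records_list, sizes = seq(50, 500, by = 50),
                               trait = NULL, response = "asp",
                               mode = "junction") {
  species <- names(records_list)
  est <- matrix(NA_real_, length(species), length(sizes),
                dimnames = list(species, as.character(sizes)))
  for (s in species) {
    for (k in seq_along(sizes)) {
      e <- tryCatch(
        estimate_splicing_saturation(records_list[[s]], sizes[k],
                                     response, mode)$estimate,
        error = function(err) {
          warning("species ", s, ", bin size ", sizes[k], " skipped: ",
                  conditionMessage(err))
          NA_real_
        })
      est[s, k] <- e
    }
  }
  sd_est <- apply(est, 1, stats::sd, na.rm = TRUE)
  rho <- sd_rho <- NULL
  if (!is.null(trait)) {
    tr <- trait[species]
    rho <- apply(est, 2, function(col) {
      ok <- !is.na(col)
      if (sum(ok) < 4) return(NA_real_)
      stats::cor(col[ok], tr[ok], method = "spearman")
    })
    sd_rho <- stats::sd(rho, na.rm = TRUE)
  }
  list(estimates = est, sd_estimate = sd_est, rho = rho, sd_rho = sd_rho)
}
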