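.correlation_result <- function(method, estimate, p_value, n,
                                adj_r2 = NA_real_, lambda_hat = NA_real_) {
  structure(list(method = method, estimate = estimate, adj_r2 = adj_r2,
                 p_value = p_value, lambda_hat = lambda_hat, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s: estimate = %.4f, p = %.4g, n = %d", x$method,
              x$estimate, x$p_value, x$n))
  if (!is.na(x$adj_r2)) cat(sprintf(", adj R2 = %.4f", x$adj_r2))
  if (!is.na(x$lambda_hat)) cat(sprintf(", lambda = %.4f", x$lambda_hat))
  cat("\n")
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t approximation on n - 2 degrees of freedom (the usual choice at the
#' sample sizes of cross-species trait tables).
#'
#' @param x,y Equal-length numeric vectors; pairs with missing values are
#'   dropped (pairwise deletion).
#' @return A `correlation_result` (method "spearman").
#' @export
spearman_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  .correlation_result("spearman", unname(ct$estimate), ct$p.value, n)
}

#' Partial Spearman correlation
#'
#' Rank correlation between x and y controlling for z, via the recursive
#' (first-order partial) correlation formula applied to the three pairwise
#' Spearman coefficients; p-value from the t approximation on n - 3 degrees
#' of freedom.
#'
#' @param x,y,z Equal-length numeric vectors.
#' @return A `correlation_result` (method "partial_spearman").
#' @export
partial_spearman <- function(x, y, z) {
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete triples")
  rxy <- stats::cor(x, y, method = "spearman")
  rxz <- stats::cor(x, z, method = "spearman")
  ryz <- stats::cor(y, z, method = "spearman")
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("degenerate control variable: |rho| with z is 1")
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  tstat <- r * sqrt((n - 3) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 3)
  .correlation_result("partial_spearman", r, p, n)
}

#' Ordinary least squares regression of y on x
#'
#' @param x,y Equal-length numeric vectors.
#' @return A `correlation_result` (method "linreg") with the slope as
#'   estimate, the slope's t-test p-value, and the adjusted R-squared.
#' @export
linear_regression <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("zero variance in predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  .correlation_result("linreg", unname(stats::coef(fit)[2]),
                      sm$coefficients[2, 4], n,
                      adj_r2 = sm$adj.r.squared)
}

## Pagel's lambda transform of a Brownian covariance: scale off-diagonals,
## keep the diagonal.
.lambda_vcv <- function(C, lambda) {
  V <- lambda * C
  diag(V) <- diag(C)
  V
}

## Profile log-likelihood of the GLS model y = X b + e, e ~ N(0, sigma2 V)
.gls_profile <- function(X, y, V) {
  n <- nrow(X)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  Xi <- backsolve(ch, X, transpose = TRUE)
  yi <- backsolve(ch, y, transpose = TRUE)
  fit <- stats::lm.fit(Xi, yi)
  e <- fit$residuals
  rss <- sum(e^2)
  sigma2 <- rss / n
  logdet <- 2 * sum(log(diag(ch)))
  loglik <- -n / 2 * log(2 * pi * sigma2) - logdet / 2 - n / 2
  list(loglik = loglik, beta = fit$coefficients, sigma2 = sigma2,
       rss = rss, chol = ch, Xw = Xi, yw = yi)
}

#' Phylogenetic generalized least squares with ML Pagel's lambda
#'
#' GLS regression whose residual covariance is the Brownian-motion
#' phylogenetic covariance (shared root-to-MRCA path lengths) with
#' off-diagonal entries scaled by Pagel's lambda. lambda is estimated by
#' maximising the multivariate-normal log-likelihood over \[0, 1\]
#' (bounded scalar optimisation, tolerance 1e-6), or held fixed via the
#' `lambda` argument. With lambda = 0 on an ultrametric tree the fit reduces
#' to ordinary least squares.
#'
#' @param formula Model formula, e.g. `asp ~ ctn`.
#' @param data data.frame of species traits; species are identified by
#'   `data$species` if present, otherwise by rownames.
#' @param tree A rooted `phylo` tree with branch lengths; pruned to the
#'   species in `data`. Species present in the data but missing from the
#'   tree raise an error naming the offenders.
#' @param lambda Optional fixed lambda in \[0, 1\]; NULL (default) estimates
#'   it by maximum likelihood.
#' @return A `pgls` object: coefficients, se, t, p_value (per coefficient),
#'   lambda, logLik, adj_r2, n, residuals, fitted.
#' @export
pgls_fit <- function(formula, data, tree, lambda = NULL) {
  stopifnot(inherits(tree, "phylo"))
  sp <- if (!is.null(data$species)) as.character(data$species)
        else rownames(data)
  if (!length(sp)) stop("no species in data")
  if (is.null(sp) || anyDuplicated(sp))
    stop("data must identify unique species via a 'species' column or rownames")
  missing_sp <- setdiff(sp, tree$tip.label)
  if (length(missing_sp))
    stop("species missing from tree: ", paste(missing_sp, collapse = ", "))
  tree <- ape::keep.tip(tree, sp)
  C <- ape::vcv(tree)[sp, sp]

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  if (n < ncol(X) + 2) stop("too few species for PGLS")

  ll_of <- function(l) .gls_profile(X, y, .lambda_vcv(C, l))$loglik
  if (is.null(lambda)) {
    opt <- stats::optimize(ll_of, c(0, 1), maximum = TRUE, tol = 1e-6)
    ## the optimum can sit on a boundary optimize() never quite reaches
    cand <- c(opt$maximum, 0, 1)
    lambda <- cand[which.max(vapply(cand, ll_of, numeric(1)))]
  }
  V <- .lambda_vcv(C, lambda)
  g <- .gls_profile(X, y, V)
  if (!is.finite(g$loglik)) stop("singular phylogenetic covariance")
  p <- ncol(X)
  df <- n - p
  sigma2_reml <- g$rss / df
  XtX_inv <- chol2inv(chol(crossprod(g$Xw)))
  se <- sqrt(diag(XtX_inv) * sigma2_reml)
  tval <- g$beta / se
  pval <- 2 * stats::pt(-abs(tval), df = df)

  ## GLS R2 against the V-weighted intercept-only model
  g0 <- .gls_profile(X[, 1, drop = FALSE], y, V)
  r2 <- 1 - g$rss / g0$rss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df
  fitted <- drop(X %*% g$beta)
  structure(list(coefficients = g$beta, se = se, t = tval, p_value = pval,
                 lambda = lambda, logLik = g$loglik, sigma2 = g$sigma2,
                 adj_r2 = adj_r2, n = n, residuals = y - fitted,
                 fitted = fitted, formula = formula,
                 call = match.call()), class = "pgls")
}

#' @export
print.pgls <- function(x, ...) {
  cat("PGLS (Pagel's lambda =", format(x$lambda, digits = 4), "):\n")
  print(data.frame(estimate = x$coefficients, se = x$se, t = x$t,
                   p = x$p_value))
  cat(sprintf("n = %d, adj R2 = %.4f, logLik = %.3f\n",
              x$n, x$adj_r2, x$logLik))
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
residuals.pgls <- function(object, ...) object$residuals

#' @export
summary.pgls <- function(object, ...) {
  out <- list(
    coefficients = cbind(Estimate = object$coefficients,
                         `Std. Error` = object$se,
                         `t value` = object$t,
                         `Pr(>|t|)` = object$p_value),
    lambda = object$lambda, adj_r2 = object$adj_r2,
    logLik = object$logLik, n = object$n)
  class(out) <- "summary.pgls"
  out
}

#' @export
print.summary.pgls <- function(x, ...) {
  stats::printCoefmat(x$coefficients)
  cat(sprintf("lambda = %.4f, n = %d, adj R2 = %.4f, logLik = %.3f\n",
              x$lambda, x$n, x$adj_r2, x$logLik))
  invisible(x)
}

#' As a convenience: PGLS slope/p for a response-predictor pair
#' @keywords internal
.pgls_pair <- function(traits, response, predictor, tree) {
  f <- stats::as.formula(paste(response, "~", predictor))
  fit <- pgls_fit(f, traits, tree)
  .correlation_result("pgls", unname(fit$coefficients[2]),
                      unname(fit$p_value[2]), fit$n,
                      adj_r2 = fit$adj_r2, lambda_hat = fit$lambda)
}

#' Wilcoxon rank-sum W contrast between two groups
#'
#' W is the Mann-Whitney statistic: the rank sum of `group_a` in the pooled
#' ranking minus n_a (n_a + 1) / 2. The p-value uses the normal
#' approximation with tie correction.
#'
#' @param group_a,group_b Numeric vectors of values (e.g. expression
#'   quantiles of one pathway versus the others).
#' @return List with `W` and `p`.
#' @export
wilcoxon_w <- function(group_a, group_b) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = FALSE, correct = FALSE))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Chi-square test of pathway gene counts against genome totals
#'
#' Pearson chi-square (no continuity correction) on the 2 x S contingency
#' table of pathway genes versus remaining genes per species, testing whether
#' pathway representation varies across species beyond their genome sizes.
#'
#' @param pathway_counts Per-species pathway gene counts.
#' @param genome_totals Per-species total gene counts (>= pathway counts).
#' @return List with `chi2`, `p`, `df`, and `low_expected` (TRUE when any
#'   expected cell is below 1, attached as a warning flag).
#' @export
chisq_pathway_counts <- function(pathway_counts, genome_totals) {
  stopifnot(length(pathway_counts) == length(genome_totals),
            length(pathway_counts) >= 2,
            all(genome_totals >= pathway_counts))
  tab <- rbind(pathway = pathway_counts,
               rest = genome_totals - pathway_counts)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  low <- any(ct$expected < 1)
  if (low) warning("expected cell count below 1: chi-square unreliable")
  list(chi2 = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter), low_expected = low)
}

#' Relative cell-type-number difference
#'
#' diff(a, b) / max(a, b): the absolute difference scaled by the larger
#' value, ranging from 0 (equal) to just under 1.
#'
#' @param a,b Positive cell type numbers (vectorised).
#' @return Values in \[0, 1\].
#' @export
ctn_difference <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("cell type numbers must be positive")
  abs(a - b) / pmax(a, b)
}

#' Fractional-rank quantile transform
#'
#' Maps values to r / n where r is the average rank (ties averaged); larger
#' quantiles represent higher values and the transform is order-preserving.
#'
#' @param values Numeric vector (length >= 1).
#' @return Quantiles in (0, 1\].
#' @export
quantile_transform <- function(values) {
  stopifnot(length(values) >= 1)
  rank(values, ties.method = "average") / length(values)
}

#' Filter KEGG Orthologs significant for a genomic feature
#'
#' Retains a KO when its Spearman correlation with organism complexity
#' strictly exceeds `rho_cutoff` AND its PGLS p-value is strictly below
#' `p_cutoff`. KOs with a missing result are skipped with a warning.
#'
#' @param ko_results data.frame with columns `ko`, `rho` (Spearman) and
#'   `pgls_p`.
#' @param rho_cutoff Strict lower bound on rho (default 0.4).
#' @param p_cutoff Strict upper bound on the PGLS p-value (default 0.05).
#' @return Character vector of retained KO ids.
#' @export
filter_significant_kos <- function(ko_results, rho_cutoff = 0.4,
                                   p_cutoff = 0.05) {
  stopifnot(all(c("ko", "rho", "pgls_p") %in% names(ko_results)))
  miss <- is.na(ko_results$rho) | is.na(ko_results$pgls_p)
  if (any(miss))
    warning(sum(miss), " KO(s) skipped for missing results")
  keep <- !miss & ko_results$rho > rho_cutoff & ko_results$pgls_p < p_cutoff
  ko_results$ko[keep]
}
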