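# Maximum-likelihood models of continuous trait evolution on a calibrated
# tree: stasis (white noise, ignoring the tree), Brownian motion, and BM with
# a directional trend. Within-taxon measurement error enters as sd^2 added to
# the covariance diagonal. BM/trend likelihoods profile the mean parameters
# by generalised least squares and optimise the step variance in one
# dimension on the log scale.

#' Brownian-motion covariance of a calibrated tree
#'
#' `C[i, j]` is the duration (Myr) from the root to the most recent common
#' ancestor of tips i and j; the diagonal holds root-to-tip durations.
#'
#' @param timetree a `time_tree`
#' @param tips optional subset of tip labels
#' @return a symmetric matrix of shared-path durations
#' @export
phylo_vcv <- function(timetree, tips = NULL) {
  phy <- timetree$phy
  if (!is.null(tips)) {
    tips <- normalise_label(tips)
    miss <- setdiff(tips, phy$tip.label)
    if (length(miss)) stop("tip(s) not in tree: ", paste(miss, collapse = ", "))
    phy <- ape::keep.tip(phy, tips)
  }
  ape::vcv.phylo(phy)
}

new_trait_fit <- function(model, k, estimates, logLik, n, degenerate = FALSE) {
  structure(list(model = model, k = k, estimates = estimates,
                 logLik = logLik, n = n, aicc = aicc_value(logLik, k, n),
                 degenerate = degenerate),
            class = "trait_model_fit")
}

#' @export
print.trait_model_fit <- function(x, ...) {
  cat("<trait_model_fit> ", x$model, ": lnL = ",
      format(x$logLik, digits = 6), ", AICc = ",
      format(x$aicc, digits = 6), "\n  ", sep = "")
  cat(paste(names(x$estimates), "=",
            format(unlist(x$estimates), digits = 4), collapse = "; "), "\n")
  invisible(x)
}

#' Fit the stasis (white-noise) model
#'
#' Tip values are i.i.d. normal around a single mean with variance
#' `trait_variance + measurement_sd^2`; the tree is ignored (2 parameters).
#' With a common measurement sd the ML mean is the arithmetic mean and the
#' variance has a closed form; per-tip sds are handled by profiling the mean
#' and optimising the variance numerically.
#'
#' @param data tibble with `taxon` and `value` columns (or a named numeric)
#' @param measurement_sd within-taxon measurement standard deviation, same
#'   units as the trait; scalar or one value per tip
#' @return a `trait_model_fit` with estimates `trait_mean`, `trait_variance`
#' @export
fit_stasis <- function(data, measurement_sd = 0) {
  y <- trait_values(data)
  n <- length(y)
  if (n < 3) stop("stasis fit needs at least 3 tips")
  sdv <- rep(measurement_sd, length.out = n)
  if (length(unique(sdv)) == 1) {
    m <- mean(y)
    tau2 <- mean((y - m)^2)
    v <- max(0, tau2 - sdv[1]^2)
    total <- v + sdv[1]^2
    if (total == 0)
      return(new_trait_fit("stasis", 2L,
                           list(trait_mean = m, trait_variance = 0),
                           Inf, n, degenerate = TRUE))
    ll <- -0.5 * (n * log(2 * pi * total) + sum((y - m)^2) / total)
    return(new_trait_fit("stasis", 2L,
                         list(trait_mean = m, trait_variance = v), ll, n))
  }
  nll <- function(lv) {
    v <- exp(lv)
    w <- 1 / (v + sdv^2)
    m <- sum(w * y) / sum(w)
    0.5 * (n * log(2 * pi) + sum(log(v + sdv^2)) + sum(w * (y - m)^2))
  }
  vy <- stats::var(y)
  opt <- stats::optimize(nll, c(log(vy * 1e-8 + 1e-12), log(vy * 1e4 + 1)),
                         tol = 1e-10)
  v <- exp(opt$minimum)
  w <- 1 / (v + sdv^2)
  m <- sum(w * y) / sum(w)
  new_trait_fit("stasis", 2L, list(trait_mean = m, trait_variance = v),
                -opt$objective, n)
}

trait_values <- function(data) {
  if (is.numeric(data) && !is.null(names(data))) return(data)
  y <- data$value
  names(y) <- normalise_label(data$taxon)
  if (any(!is.finite(y))) stop("trait values must be finite")
  y
}

# profiled GLS log-likelihood machinery shared by BM and trend
gls_profile_fit <- function(C, y, X, sdv) {
  n <- length(y)
  loglik_at <- function(s2) {
    V <- s2 * C
    diag(V) <- diag(V) + sdv^2
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -1e10))
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    beta <- solve(XtVi %*% X, XtVi %*% y)
    r <- y - X %*% beta
    ll <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
                    drop(crossprod(r, Vi %*% r)))
    list(ll = ll, beta = drop(beta))
  }
  vy <- stats::var(y) / mean(diag(C))
  opt <- stats::optimize(function(ls2) -loglik_at(exp(ls2))$ll,
                         c(log(vy * 1e-8 + 1e-15), log(vy * 1e6 + 1)),
                         tol = 1e-10)
  s2 <- exp(opt$minimum)
  at <- loglik_at(s2)
  if (at$ll <= -1e9)
    stop("singular trait covariance (duplicate-age cherry with zero ",
         "measurement sd?)")
  list(s2 = s2, beta = at$beta, logLik = at$ll)
}

#' Fit the Brownian-motion model
#'
#' Multivariate normal with mean vector equal to the root state and
#' covariance `step_variance * C + measurement_sd^2 * I`, where `C` is the
#' shared-path matrix from [phylo_vcv()]. The root state is profiled by GLS;
#' the step variance (trait units^2 per Myr) is optimised on the log scale.
#'
#' @param timetree a `time_tree`
#' @param data tibble with `taxon` and `value`
#' @param measurement_sd scalar or per-tip measurement sd
#' @return a `trait_model_fit` with estimates `root_state`, `step_variance`
#' @export
fit_bm <- function(timetree, data, measurement_sd = 0) {
  y <- trait_values(data)
  C <- phylo_vcv(timetree, names(y))
  sdv <- rep(measurement_sd, length.out = length(y))
  idx <- match(rownames(C), names(y))
  y <- y[idx]; sdv <- sdv[idx]
  fit <- gls_profile_fit(C, y, matrix(1, length(y), 1), sdv)
  new_trait_fit("bm", 2L,
                list(root_state = fit$beta[1], step_variance = fit$s2),
                fit$logLik, length(y))
}

#' Fit the Brownian-motion-plus-trend model
#'
#' As [fit_bm()], with mean vector `root_state + step_mean * depth(tip)`
#' (depth = root-to-tip duration). The step mean (trait units per Myr) is
#' only identifiable on a non-ultrametric tree — tips at a single common age
#' give a constant depth column and the fit is refused.
#'
#' @inheritParams fit_bm
#' @return a `trait_model_fit` with estimates `root_state`, `step_mean`,
#'   `step_variance`
#' @export
fit_trend <- function(timetree, data, measurement_sd = 0) {
  y <- trait_values(data)
  C <- phylo_vcv(timetree, names(y))
  sdv <- rep(measurement_sd, length.out = length(y))
  idx <- match(rownames(C), names(y))
  y <- y[idx]; sdv <- sdv[idx]
  depth <- diag(C)
  if (stats::sd(depth) < 1e-9 * max(depth, 1))
    stop("tree is ultrametric: trend step mean is unidentifiable")
  X <- cbind(1, depth)
  fit <- gls_profile_fit(C, y, X, sdv)
  new_trait_fit("trend", 3L,
                list(root_state = fit$beta[1], step_mean = fit$beta[2],
                     step_variance = fit$s2),
                fit$logLik, length(y))
}

aicc_value <- function(logLik, k, n) {
  if (n <= k + 1) return(NA_real_)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Small-sample Akaike information criterion
#' @param fit a `trait_model_fit`
#' @param n number of tips (defaults to the fit's own)
#' @return AICc value
#' @export
aicc <- function(fit, n = fit$n) {
  if (n <= fit$k + 1)
    stop("AICc undefined: n must exceed k + 1 (n = ", n, ", k = ", fit$k, ")")
  aicc_value(fit$logLik, fit$k, n)
}

#' Akaike weights over a set of fits
#' @param fits list of `trait_model_fit`
#' @return named numeric weights summing to 1
#' @export
akaike_weights <- function(fits) {
  a <- vapply(fits, function(f) f$aicc, 0)
  d <- a - min(a)
  w <- exp(-0.5 * d)
  w <- w / sum(w)
  names(w) <- vapply(fits, function(f) f$model, "")
  w
}

#' Fit and compare all three trait models
#'
#' Fits stasis, BM and BM+trend to the same data, optionally on the natural
#' log scale, and attaches AICc Akaike weights. On the log scale the
#' measurement sd is transported per tip by the delta method
#' (`sd_log = sd / value`): a single raw-scale sd cannot be correct on the
#' log scale across a wide body-size range.
#'
#' @param timetree a `time_tree`
#' @param data tibble with `taxon` and `value`; rows with missing values are
#'   dropped
#' @param measurement_sd raw-scale measurement sd (scalar or per tip)
#' @param transform `"none"` or `"ln"`
#' @return a `trait_model_set`: list of fits plus `weights`, `transform`, `n`
#' @export
fit_all <- function(timetree, data, measurement_sd = 0,
                    transform = c("none", "ln")) {
  transform <- match.arg(transform)
  y <- trait_values(data)
  y <- y[!is.na(y)]
  y <- y[names(y) %in% timetree$phy$tip.label]
  if (length(y) < 4) stop("need at least 4 usable tips")
  sdv <- rep(measurement_sd, length.out = length(y))
  if (transform == "ln") {
    sdv <- sdv / y
    y <- log(y)
  }
  dat <- tibble::tibble(taxon = names(y), value = unname(y))
  fits <- list(stasis = fit_stasis(dat, sdv),
               bm = fit_bm(timetree, dat, sdv),
               trend = fit_trend(timetree, dat, sdv))
  structure(list(fits = fits, weights = akaike_weights(fits),
                 transform = transform, n = length(y)),
            class = "trait_model_set")
}

#' @export
print.trait_model_set <- function(x, ...) {
  print(glance(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single trait-model fit
#' @param x a `trait_model_fit`
#' @param ... ignored
#' @return tibble of terms and estimates
#' @export
tidy.trait_model_fit <- function(x, ...) {
  tibble::tibble(model = x$model, term = names(x$estimates),
                 estimate = unlist(x$estimates))
}

#' Tidy a trait-model comparison
#' @param x a `trait_model_set`
#' @param ... ignored
#' @return tibble of per-model parameter estimates
#' @export
tidy.trait_model_set <- function(x, ...) {
  purrr::map_dfr(x$fits, tidy)
}

#' One-row-per-model summary of a trait-model comparison
#' @param x a `trait_model_set`
#' @param ... ignored
#' @return tibble: `model`, `k`, `logLik`, `aicc`, `delta_aicc`, `weight`
#' @export
glance.trait_model_set <- function(x, ...) {
  a <- vapply(x$fits, function(f) f$aicc, 0)
  tibble::tibble(model = names(x$fits),
                 k = vapply(x$fits, function(f) f$k, 0L),
                 logLik = vapply(x$fits, function(f) f$logLik, 0),
                 aicc = a, delta_aicc = a - min(a),
                 weight = unname(x$weights))
}
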