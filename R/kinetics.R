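#' Fit first-order cleavage kinetics
#'
#' Fits the plateau-approach model
#' `F(t) = F_max - (F_max - F0) exp(-K_obs t)` to pooled replicate time
#' series by bounded nonlinear least squares, with a delta-method 95%
#' confidence band. (The model approaches `F_max` with rate `K_obs > 0`;
#' a growing-exponential sign convention would diverge.)
#'
#' @param series Data frame with columns `time_min` and `fraction_cleaved`
#'   (and optionally `replicate`); replicates are pooled under a constant
#'   error model.
#' @param init Optional named list/vector with starting values `k_obs`,
#'   `f_max`, `f0`. Defaults: `f0 = min F`, `f_max = max F`, `k_obs` from a
#'   log-linear fit of `F_max - F(t)`.
#' @return Object of class `cleavage_fit`: the fitted model plus `coef`
#'   (tibble), `mse`, `band` (per-time fit with 95% limits) and `n_points`.
#' @export
fit_cleavage <- function(series, init = NULL) {
  series <- tibble::as_tibble(series)
  if (!all(c("time_min", "fraction_cleaved") %in% names(series))) {
    stop("series needs columns time_min and fraction_cleaved", call. = FALSE)
  }
  t <- series$time_min
  f <- series$fraction_cleaved
  if (any(t < 0)) stop("negative times", call. = FALSE)
  if (any(f < 0 | f > 1)) {
    stop("fraction_cleaved outside [0, 1]", call. = FALSE)
  }
  if ("replicate" %in% names(series)) {
    split_t <- split(t, series$replicate)
    if (any(vapply(split_t, is.unsorted, logical(1), strictly = TRUE))) {
      stop("times must be strictly increasing within a replicate",
           call. = FALSE)
    }
  }
  if (length(unique(t)) < 3) {
    stop("need at least 3 distinct time points", call. = FALSE)
  }
  if (diff(range(f)) < 1e-12) {
    stop("degenerate data: fraction_cleaved is constant", call. = FALSE)
  }
  if (is.null(init)) {
    f0 <- min(f)
    fmax <- max(f)
    resid0 <- pmax(fmax - f, 1e-6)
    sl <- stats::coef(stats::lm(log(resid0) ~ t))[2]
    init <- list(k_obs = max(-unname(sl), 1e-4), f_max = fmax, f0 = f0)
  }
  model_at <- function(par, tp) {
    par[["f_max"]] - (par[["f_max"]] - par[["f0"]]) *
      exp(-par[["k_obs"]] * tp)
  }
  jac_at <- function(par, tp) {
    e <- exp(-par[["k_obs"]] * tp)
    cbind(k_obs = (par[["f_max"]] - par[["f0"]]) * tp * e,
          f_max = 1 - e,
          f0 = e)
  }
  start <- unlist(init)[c("k_obs", "f_max", "f0")]
  # nls.lm rather than nlsLM: the latter's post-fit model construction
  # rejects perfect (zero-residual) fits as singular
  fit <- minpack.lm::nls.lm(
    par = start,
    lower = c(k_obs = 0, f_max = 0, f0 = 0),
    upper = c(k_obs = Inf, f_max = 1, f0 = 1),
    fn = function(par) f - model_at(as.list(par), t),
    jac = function(par) -jac_at(as.list(par), t),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- fit$par
  if (est[["f0"]] > est[["f_max"]] + 1e-8) {
    stop("fit violates F0 <= F_max; data are inconsistent with the model",
         call. = FALSE)
  }
  rss <- sum(fit$fvec^2)
  n <- length(f)
  sigma2 <- rss / max(n - 3, 1)
  jtj <- crossprod(jac_at(as.list(est), t))
  vc <- sigma2 * tryCatch(solve(jtj), error = function(e) MASS::ginv(jtj))
  dimnames(vc) <- list(names(est), names(est))
  se <- sqrt(pmax(diag(vc), 0))
  tt <- sort(unique(t))
  grad <- function(tp) {
    e <- exp(-est[["k_obs"]] * tp)
    c(k_obs = (est[["f_max"]] - est[["f0"]]) * tp * e,
      f_max = 1 - e,
      f0 = e)
  }
  fit_at <- function(tp) {
    est[["f_max"]] - (est[["f_max"]] - est[["f0"]]) * exp(-est[["k_obs"]] * tp)
  }
  band <- purrr::map_dfr(tt, function(tp) {
    g <- grad(tp)
    sd <- sqrt(drop(t(g) %*% vc %*% g))
    mid <- fit_at(tp)
    tibble::tibble(time_min = tp, fit = mid,
                   lower = mid - 1.96 * sd, upper = mid + 1.96 * sd)
  })
  structure(
    list(
      model = fit,
      data = series,
      coef = tibble::tibble(term = names(est), estimate = unname(est),
                            std_error = unname(se)),
      k_obs = est[["k_obs"]],
      f_max = est[["f_max"]],
      f0 = est[["f0"]],
      mse = rss / n,
      rss = rss,
      band = band,
      n_points = n
    ),
    class = "cleavage_fit"
  )
}

#' @export
print.cleavage_fit <- function(x, ...) {
  cat("<cleavage_fit> K_obs =", signif(x$k_obs, 4), "/min | F_max =",
      signif(x$f_max, 4), "| F0 =", signif(x$f0, 4), "| MSE =",
      signif(x$mse, 4), "| n =", x$n_points, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cleavage fit
#'
#' @param x A [fit_cleavage()] object.
#' @param ... Unused.
#' @return One row per parameter with estimate, standard error and Wald 95%
#'   confidence limits.
#' @export
tidy.cleavage_fit <- function(x, ...) {
  dplyr::mutate(
    x$coef,
    statistic = .data$estimate / .data$std_error,
    conf_low = .data$estimate - 1.96 * .data$std_error,
    conf_high = .data$estimate + 1.96 * .data$std_error
  )
}

#' Glance at a cleavage fit
#'
#' @inheritParams tidy.cleavage_fit
#' @return One-row tibble with the parameter estimates and fit summaries.
#' @export
glance.cleavage_fit <- function(x, ...) {
  tibble::tibble(
    k_obs = x$k_obs, f_max = x$f_max, f0 = x$f0,
    mse = x$mse, rss = x$rss, n = x$n_points,
    df_residual = x$n_points - 3L,
    converged = isTRUE(x$model$info %in% 1:4)
  )
}

#' Pearson correlation with explicit degeneracy errors
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return Sample correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson(1:3, c(3, 2, 1))
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Correlate cleavage rates against every measure column
#'
#' Joins rates and measures by `id` and reports the Pearson correlation of
#' `k_obs` with each numeric measure column, ordered by decreasing absolute
#' correlation. Zero-variance measures are flagged in `note` with a missing
#' correlation rather than silently propagating `NaN`.
#'
#' @param rates Data frame with columns `id`, `k_obs`.
#' @param measures Data frame with column `id` and numeric measure columns.
#' @return Tibble with columns `measure`, `r`, `n`, `note`.
#' @export
correlation_table <- function(rates, measures) {
  if (!setequal(rates$id, measures$id)) {
    stop("candidate ids do not match between rates and measures",
         call. = FALSE)
  }
  measures <- tibble::as_tibble(measures)
  measures <- measures[, setdiff(names(measures), "k_obs")]
  joined <- dplyr::inner_join(tibble::as_tibble(rates)[, c("id", "k_obs")],
                              measures, by = "id")
  cols <- setdiff(names(joined)[vapply(joined, is.numeric, logical(1))],
                  c("k_obs"))
  rows <- purrr::map_dfr(cols, function(col) {
    v <- joined[[col]]
    if (any(is.na(v))) {
      return(tibble::tibble(measure = col, r = NA_real_, n = sum(!is.na(v)),
                            note = "missing values"))
    }
    if (stats::sd(v) == 0) {
      return(tibble::tibble(measure = col, r = NA_real_, n = length(v),
                            note = "zero variance"))
    }
    tibble::tibble(measure = col, r = pearson(joined$k_obs, v),
                   n = length(v), note = "")
  })
  dplyr::arrange(rows, dplyr::desc(abs(.data$r)))
}
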