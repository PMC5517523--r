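#' Kinetic models of diribonucleotide synthesis
#'
#' Three rate laws describe primase product formation over time:
#' \describe{
#'   \item{`linear`}{multiple-turnover steady state,
#'     \eqn{y = k_{cat} t}: product per enzyme accumulates at the
#'     steady-state rate constant \eqn{k_{cat}} (1/s).}
#'   \item{`burst`}{pre-steady-state burst,
#'     \eqn{y = A (1 - e^{-k_{burst} t}) + k_{cat} t}: a rapid first
#'     turnover of amplitude \eqn{A} (product per enzyme) at rate
#'     \eqn{k_{burst}}, limited thereafter by a slow post-chemistry step at
#'     \eqn{k_{cat}}. Biphasic traces of this shape indicate that product
#'     release, not chemistry, limits the steady state.}
#'   \item{`single_exponential`}{single-turnover,
#'     \eqn{y = A (1 - e^{-k_{obs} t})}: the fraction of substrate
#'     converted approaches amplitude \eqn{A} at the observed rate
#'     \eqn{k_{obs}}, isolating the chemical step.}
#' }
#'
#' @param kind One of `"linear"`, `"burst"`, `"single_exponential"`.
#' @param parameters Named list/vector: `k_cat` for linear; `A`,
#'   `k_burst`, `k_cat` for burst; `A`, `k_obs` for single_exponential.
#'   Rates are in 1/s and must be positive; amplitudes are dimensionless
#'   and non-negative.
#' @param times Numeric vector of time points (seconds).
#' @return Numeric vector of the noise-free response.
#' @export
kinetic_response <- function(kind = c("linear", "burst", "single_exponential"),
                             parameters, times) {
  kind <- match.arg(kind)
  p <- as.list(parameters)
  check_rates(kind, p)
  switch(kind,
    linear = p$k_cat * times,
    burst = p$A * (1 - exp(-p$k_burst * times)) + p$k_cat * times,
    single_exponential = p$A * (1 - exp(-p$k_obs * times))
  )
}

kinetic_param_names <- function(kind) {
  switch(kind,
    linear = "k_cat",
    burst = c("A", "k_burst", "k_cat"),
    single_exponential = c("A", "k_obs")
  )
}

check_rates <- function(kind, p) {
  need <- kinetic_param_names(kind)
  missing <- setdiff(need, names(p))
  if (length(missing) > 0) {
    abort(paste0(kind, " model needs parameter(s): ",
      paste(missing, collapse = ", ")))
  }
  rates <- intersect(c("k_cat", "k_burst", "k_obs"), need)
  for (r in rates) {
    if (!is.finite(p[[r]]) || p[[r]] <= 0) {
      abort(paste0("rate constant ", r, " must be positive"))
    }
  }
  if ("A" %in% need && (!is.finite(p$A) || p$A < 0)) {
    abort("amplitude A must be non-negative")
  }
  invisible(TRUE)
}

#' Simulate a kinetics trace
#'
#' Evaluates a kinetic model (see [kinetic_response()]) on a time grid and
#' adds i.i.d. Gaussian noise, producing a trace like a quench-flow
#' time course.
#'
#' @inheritParams kinetic_response
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param seed Optional integer seed (the caller's RNG state is
#'   untouched).
#' @param condition Optional text label (e.g. `"Mg-like"`, `"Mn-like"`).
#' @return A tibble of class `"kinetics_trace"` with columns `time`
#'   (seconds, strictly increasing) and `response`, and attributes
#'   `kind`, `parameters`, `condition`.
#' @examples
#' simulate_trace("burst", list(A = 0.8, k_burst = 20, k_cat = 0.5),
#'   times = seq(0, 2, by = 0.05), noise_sd = 0.02, seed = 1
#' )
#' @export
simulate_trace <- function(kind, parameters, times, noise_sd = 0,
                           seed = NULL, condition = NA_character_) {
  stopifnot(is.numeric(times), all(is.finite(times)), all(times >= 0),
    !is.unsorted(times, strictly = TRUE), noise_sd >= 0)
  y <- kinetic_response(kind, parameters, times)
  if (noise_sd > 0) {
    y <- y + with_seed_maybe(seed, rnorm(length(times), 0, noise_sd))
  }
  out <- tibble::tibble(time = as.numeric(times), response = y)
  structure(out,
    class = c("kinetics_trace", class(out)),
    kind = kind, parameters = as.list(parameters), condition = condition
  )
}

#' Fit a kinetic model to a trace by least squares
#'
#' Ordinary (unweighted) least squares. The linear model is solved
#' exactly by regression through the origin; burst and single-exponential
#' models are fit by Levenberg-Marquardt ([minpack.lm::nlsLM()]) with
#' rates bounded below by zero. Standard errors come from the local
#' curvature at the optimum. Default starting values are derived from the
#' data: the slope of the late points gives \eqn{k_{cat}}, the intercept
#' of the late-time linear extrapolation gives the burst amplitude, and
#' the reciprocal time-to-half-amplitude gives the rate.
#'
#' @param trace Data frame with `time` and `response` columns.
#' @param kind Model to fit (see [kinetic_response()]).
#' @param start Optional named starting values (otherwise derived from the
#'   data).
#' @return An object of class `"kinetic_fit"`: list with `kind`,
#'   `parameters` (named estimates), `se` (1-SE per parameter),
#'   `residual_norm` (root sum of squared residuals), `fitted`, `data`.
#' @examples
#' tr <- simulate_trace("linear", list(k_cat = 4), times = seq(0.01, 1, 0.01))
#' fit_trace(tr, "linear")$parameters
#' @export
fit_trace <- function(trace, kind = c("linear", "burst", "single_exponential"),
                      start = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(trace), all(c("time", "response") %in% names(trace)))
  t <- trace$time
  y <- trace$response
  np <- length(kinetic_param_names(kind))
  if (length(t) < np + 1) {
    abort(paste0("need at least ", np + 1, " points to fit a ", kind,
      " model"))
  }
  if (kind == "linear") {
    m <- lm(y ~ 0 + t)
    est <- c(k_cat = unname(coef(m)))
    se <- c(k_cat = unname(sqrt(diag(vcov_safe(m)))))
    fitted <- unname(stats::fitted(m))
  } else {
    start <- start %||% default_start(kind, t, y)
    lower <- setNames(rep(1e-12, np), kinetic_param_names(kind))
    lower["A"] <- 0
    fml <- switch(kind,
      burst = y ~ A * (1 - exp(-k_burst * t)) + k_cat * t,
      single_exponential = y ~ A * (1 - exp(-k_obs * t))
    )
    m <- tryCatch(
      minpack.lm::nlsLM(
        fml,
        data = data.frame(t = t, y = y),
        start = as.list(start[kinetic_param_names(kind)]),
        lower = lower[kinetic_param_names(kind)],
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
          ptol = 1e-14)
      ),
      error = function(e) {
        abort(paste0(
          "nonlinear fit of the ", kind, " model did not converge: ",
          conditionMessage(e), " (starting values: ",
          paste(sprintf("%s=%.4g", names(start), unlist(start)),
            collapse = ", "
          ), ")"
        ))
      }
    )
    est <- coef(m)
    se <- sqrt(diag(vcov_safe(m)))
    fitted <- unname(predict(m))
  }
  res <- y - fitted
  structure(
    list(
      kind = kind, parameters = est, se = se,
      residual_norm = sqrt(sum(res^2)), fitted = fitted,
      data = tibble::tibble(time = t, response = y)
    ),
    class = "kinetic_fit"
  )
}

# vcov of a zero-residual fit can be NaN (0/0); report exact fits as SE 0.
vcov_safe <- function(m) {
  v <- tryCatch(suppressWarnings(stats::vcov(m)), error = function(e) NULL)
  if (is.null(v) || anyNA(v)) {
    p <- length(coef(m))
    v <- matrix(0, p, p)
  }
  v
}

default_start <- function(kind, t, y) {
  late <- t >= stats::quantile(t, 2 / 3)
  if (sum(late) < 2) late <- rank(t) > length(t) - 2
  lin <- lm(y[late] ~ t[late])
  kcat0 <- max(coef(lin)[2], 1e-6)
  A0 <- max(coef(lin)[1], max(y) / 2, 1e-6)
  if (kind == "single_exponential") {
    A0 <- max(y[length(y)], max(y) * 0.9, 1e-6)
    t_half <- t[which(y >= A0 / 2)[1]]
    if (is.na(t_half) || t_half <= 0) t_half <- stats::median(t)
    return(c(A = A0, k_obs = log(2) / t_half))
  }
  yb <- y - kcat0 * t
  t_half <- t[which(yb >= A0 / 2)[1]]
  if (is.na(t_half) || t_half <= 0) t_half <- max(min(t[t > 0]), 1e-3)
  c(A = A0, k_burst = log(2) / t_half, k_cat = kcat0)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic fit:", x$kind, "model\n")
  print(tidy(x))
  cat(sprintf("residual norm: %.4g\n", x$residual_norm))
  invisible(x)
}

#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$parameters),
    estimate = unname(x$parameters),
    std.error = unname(x$se[names(x$parameters)])
  )
}

#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    model = x$kind,
    n = nrow(x$data),
    residual_norm = x$residual_norm
  )
}

#' Choose between linear and burst kinetics for a trace
#'
#' Fits both the linear steady-state and the pre-steady-state burst model.
#' The burst model is preferred only when it actually reduces the residual
#' norm and its amplitude estimate is significant (\eqn{A > 2\,SE_A});
#' otherwise the nested linear model wins. Both fits are returned so the
#' call can be inspected.
#'
#' @param trace Data frame with `time` and `response`.
#' @return A list of class `"kinetic_comparison"`: `preferred`
#'   (`"linear"` or `"burst"`), `linear`, `burst` (both `"kinetic_fit"`s,
#'   `burst` may be `NULL` if its fit failed).
#' @export
compare_models <- function(trace) {
  lin <- fit_trace(trace, "linear")
  bur <- tryCatch(fit_trace(trace, "burst"), error = function(e) NULL)
  preferred <- "linear"
  if (!is.null(bur)) {
    a <- bur$parameters[["A"]]
    se_a <- bur$se[["A"]]
    significant <- a > 0 && (se_a == 0 || a > 2 * se_a)
    if (bur$residual_norm < lin$residual_norm && significant) {
      preferred <- "burst"
    }
  }
  structure(list(preferred = preferred, linear = lin, burst = bur),
    class = "kinetic_comparison"
  )
}

#' @export
print.kinetic_comparison <- function(x, ...) {
  cat("Preferred kinetic model:", x$preferred, "\n")
  cat(sprintf("  linear residual norm: %.4g\n", x$linear$residual_norm))
  if (!is.null(x$burst)) {
    cat(sprintf("  burst  residual norm: %.4g (A = %.4g +/- %.4g)\n",
      x$burst$residual_norm, x$burst$parameters[["A"]],
      x$burst$se[["A"]]))
  }
  invisible(x)
}

#' Read and write kinetics traces as delimited text
#'
#' Two-column (`time`, `response`) tab-delimited text with a header row.
#'
#' @param trace Data frame with `time` and `response`.
#' @param file Path.
#' @return `write_trace()` returns `file` invisibly; `read_trace()` the
#'   tibble.
#' @export
write_trace <- function(trace, file) {
  readr::write_tsv(trace[, c("time", "response")], file)
  invisible(file)
}

#' @rdname write_trace
#' @export
read_trace <- function(file) {
  tr <- readr::read_tsv(file, col_types = "dd", progress = FALSE)
  names(tr)[1:2] <- c("time", "response")
  tr
}

#' Export a kinetic fit as JSON
#'
#' @param fit A `"kinetic_fit"`.
#' @param file Path.
#' @return `file`, invisibly.
#' @export
write_kinetic_fit <- function(fit, file) {
  stopifnot(inherits(fit, "kinetic_fit"))
  jsonlite::write_json(
    list(
      schema = "metallosite-kinfit/1", model = fit$kind,
      parameters = as.list(fit$parameters), se = as.list(fit$se),
      residual_norm = fit$residual_norm
    ),
    file, auto_unbox = TRUE, digits = NA
  )
  invisible(file)
}
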