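#' Dual-angle merit functions and thickness optimization
#'
#' Two scalar objectives measure the squared discrepancy between a
#' stack's transmittance and a target curve, summed over a normal and an
#' oblique incidence angle so that a single design satisfies both:
#'
#' * **Merit 1** uses the unpolarized transmittance at the oblique angle:
#'   `(1/N) sum_l [ (T^{theta0}_l - T^tgt_l)^2 + (T^{theta1}_l - T^tgt_l)^2 ]`
#'   with `T = (T_s + T_p)/2` at each angle.
#' * **Merit 2** penalizes the two oblique polarizations independently:
#'   `(1/N) sum_l [ (T^{theta0}_l - T^tgt_l)^2 + (T_p^{theta1}_l - T^tgt_l)^2
#'    + (T_s^{theta1}_l - T^tgt_l)^2 ]`.
#'
#' A `normal_only` variant, `(1/N) sum (T^{theta0} - T^tgt)^2`, is the
#' single-angle baseline that wide-angle designs are compared against.
#'
#' @name merit
NULL

merit_variants <- c("merit1", "merit2", "normal_only")

#' Merit configuration
#'
#' @param variant One of `"merit1"`, `"merit2"`, `"normal_only"`.
#' @param theta0 Normal incidence angle, radians (0).
#' @param theta1 Oblique incidence angle, radians (default 20 degrees).
#' @param grid Wavelength grid, nm.
#' @return List of class `merit_config`.
#' @export
merit_config <- function(variant = "merit1", theta0 = 0,
                         theta1 = 20 * pi / 180, grid = default_grid()) {
  variant <- match.arg(variant, merit_variants)
  if (variant != "normal_only" && isTRUE(all.equal(theta0, theta1))) {
    stop("theta0 and theta1 must differ", call. = FALSE)
  }
  validate_grid(grid)
  structure(list(variant = variant, theta0 = theta0, theta1 = theta1,
                 grid = grid),
            class = "merit_config")
}

check_target_grid <- function(target, config) {
  if (nrow(target) != length(config$grid) ||
      max(abs(target$wavelength - config$grid)) > 1e-9) {
    stop("target curve is not on the configured wavelength grid",
         call. = FALSE)
  }
  pmin(pmax(target$value, 0), 1)
}

# value (and optionally thickness gradient) of any merit variant;
# `target` is one curve used at both angles, or list(t0 = , t1 = ) with
# per-angle curves (recovery experiments against a known stack's spectra)
merit_eval <- function(stack, target, config, gradient = FALSE) {
  if (is.list(target) && !is.data.frame(target) && !is.null(target$t0)) {
    tt0 <- check_target_grid(target$t0, config)
    tt1 <- check_target_grid(target$t1, config)
  } else {
    tt0 <- tt1 <- check_target_grid(target, config)
  }
  tt <- tt0
  N <- length(config$grid)
  L <- n_layers(stack)
  g0s <- tmm_engine(stack, config$theta0, config$grid, "s", gradient)
  # at theta0 (normal by default) s = p, but keep the general form
  g0p <- tmm_engine(stack, config$theta0, config$grid, "p", gradient)
  T0 <- (g0s$T + g0p$T) / 2
  e0 <- T0 - tt
  value <- sum(e0^2)
  grad <- if (gradient) numeric(L) else NULL
  if (gradient && L > 0L) {
    dT0 <- (g0s$dT + g0p$dT) / 2
    grad <- as.numeric(crossprod(dT0, 2 * e0))
  }
  if (config$variant != "normal_only") {
    g1s <- tmm_engine(stack, config$theta1, config$grid, "s", gradient)
    g1p <- tmm_engine(stack, config$theta1, config$grid, "p", gradient)
    if (config$variant == "merit1") {
      T1 <- (g1s$T + g1p$T) / 2
      e1 <- T1 - tt1
      value <- value + sum(e1^2)
      if (gradient && L > 0L) {
        dT1 <- (g1s$dT + g1p$dT) / 2
        grad <- grad + as.numeric(crossprod(dT1, 2 * e1))
      }
    } else {
      es <- g1s$T - tt1
      ep <- g1p$T - tt1
      value <- value + sum(es^2) + sum(ep^2)
      if (gradient && L > 0L) {
        grad <- grad + as.numeric(crossprod(g1s$dT, 2 * es)) +
          as.numeric(crossprod(g1p$dT, 2 * ep))
      }
    }
  }
  list(value = value / N, gradient = if (gradient) grad / N else NULL)
}

#' Merit 1: dual-angle objective with unpolarized oblique transmittance
#'
#' @param stack A [layer_stack()].
#' @param target Target curve on the configured grid ([spectral_curve()]).
#' @param config A [merit_config()] (its `variant` field is ignored).
#' @return Scalar merit value.
#' @export
merit1 <- function(stack, target, config = merit_config()) {
  config$variant <- "merit1"
  merit_eval(stack, target, config)$value
}

#' Merit 2: dual-angle objective with per-polarization oblique terms
#'
#' @inheritParams merit1
#' @return Scalar merit value.
#' @export
merit2 <- function(stack, target, config = merit_config()) {
  config$variant <- "merit2"
  merit_eval(stack, target, config)$value
}

#' Thickness gradient of a merit function
#'
#' @inheritParams merit1
#' @param config A [merit_config()]; its `variant` selects the objective.
#' @return Numeric gradient vector, one entry per inner layer (1/nm).
#' @export
merit_gradient <- function(stack, target, config = merit_config()) {
  merit_eval(stack, target, config, gradient = TRUE)$gradient
}

#' Seeded initial thickness vectors
#'
#' @param num_layers Number of inner layers.
#' @param strategy `"quarter_wave"` (optical thickness lambda_ref/4 for the
#'   alternating 2.3/1.46 structure, plus seeded jitter) or
#'   `"uniform_random"`.
#' @param seed Integer seed; same seed gives the identical vector.
#' @param lambda_ref Reference wavelength for quarter-wave layers, nm.
#' @param jitter_nm Half-width of the uniform jitter added to quarter-wave
#'   thicknesses, nm.
#' @param lo,hi Bounds for `uniform_random`, nm.
#' @param n_high,n_low Alternating indices used by `quarter_wave`.
#' @return Numeric thickness vector, nm.
#' @export
initialize_design <- function(num_layers,
                              strategy = c("quarter_wave", "uniform_random"),
                              seed = 1L, lambda_ref = 550, jitter_nm = 0,
                              lo = 20, hi = 300, n_high = 2.3, n_low = 1.46) {
  strategy <- match.arg(strategy)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  if (strategy == "quarter_wave") {
    idx <- rep(c(n_high, n_low), length.out = num_layers)
    d <- lambda_ref / (4 * idx)
    if (jitter_nm > 0) {
      d <- pmax(d + stats::runif(num_layers, -jitter_nm, jitter_nm), 0)
    }
    d
  } else {
    stats::runif(num_layers, lo, hi)
  }
}

#' Optimize layer thicknesses against a target curve
#'
#' Bounded quasi-Newton (L-BFGS-B) minimization of the selected merit
#' function over the inner-layer thicknesses, using the exact analytic
#' gradient. Thicknesses are constrained to `[bounds[1], bounds[2]]` nm
#' with a non-negative lower edge. Optional random restarts keep the
#' best-of-k result by final merit.
#'
#' @param initial Initial thickness vector, nm (or a [layer_stack()] whose
#'   thicknesses are used; its indices define the stack).
#' @param target Target [spectral_curve()] on `config$grid`, or
#'   `list(t0 = , t1 = )` with separate normal/oblique target curves (used
#'   for recovery experiments against a known stack's own spectra).
#' @param config A [merit_config()].
#' @param stack Stack template giving indices and surrounding media; if
#'   `initial` is a `layer_stack` this defaults to it.
#' @param bounds Length-2 numeric, thickness bounds in nm.
#' @param max_iter Maximum L-BFGS-B iterations.
#' @param seed Integer seed (used for restart perturbations; the base run
#'   is deterministic given `initial`).
#' @param restarts Number of additional randomly perturbed starts.
#' @param restart_jitter_nm Half-width of the uniform restart perturbation.
#' @return An object of class `filter_design`: the optimized stack, merit
#'   trace, final merit, convergence flag and seed.
#' @export
optimize_thicknesses <- function(initial, target, config = merit_config(),
                                 stack = NULL, bounds = c(0, 1000),
                                 max_iter = 500, seed = 1L, restarts = 0L,
                                 restart_jitter_nm = 15) {
  if (inherits(initial, "layer_stack")) {
    if (is.null(stack)) stack <- initial
    initial <- initial$thickness
  }
  if (is.null(stack)) {
    stack <- alternating_stack(initial)
  }
  if (length(initial) != n_layers(stack)) {
    stop("initial thickness length does not match the stack", call. = FALSE)
  }
  if (bounds[1] < 0) stop("lower thickness bound must be >= 0", call. = FALSE)
  initial <- pmin(pmax(initial, bounds[1]), bounds[2])

  run_one <- function(par0) {
    trace_env <- new.env()
    trace_env$values <- numeric(0)
    fn <- function(d) {
      v <- merit_eval(set_thickness(stack, d), target, config)$value
      if (!is.finite(v)) {
        stop("non-finite merit during line search (thicknesses: ",
             paste(signif(d, 4), collapse = ", "), ")", call. = FALSE)
      }
      trace_env$values <- c(trace_env$values, v)
      v
    }
    gr <- function(d) {
      merit_eval(set_thickness(stack, d), target, config,
                 gradient = TRUE)$gradient
    }
    fit <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                        lower = bounds[1], upper = bounds[2],
                        control = list(maxit = max_iter, factr = 4.5e5,
                                       pgtol = 1e-8))
    list(par = fit$par, value = fit$value, convergence = fit$convergence,
         trace = cummin(trace_env$values))
  }

  best <- run_one(initial)
  if (restarts > 0L) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    for (k in seq_len(restarts)) {
      par0 <- pmin(pmax(initial +
                          stats::runif(length(initial), -restart_jitter_nm,
                                       restart_jitter_nm),
                        bounds[1]), bounds[2])
      cand <- run_one(par0)
      if (cand$value < best$value) best <- cand
    }
  }

  structure(list(stack = set_thickness(stack, best$par),
                 thicknesses = best$par,
                 merit_trace = best$trace,
                 final_merit = best$value,
                 converged = best$convergence == 0L,
                 variant = config$variant,
                 config = config,
                 seed = as.integer(seed)),
            class = "filter_design")
}

#' @export
print.filter_design <- function(x, ...) {
  cat(sprintf(
    "<filter_design> %s | %d layers | final merit %.3e | %s after %d evals\n",
    x$variant, length(x$thicknesses), x$final_merit,
    if (x$converged) "converged" else "stopped", length(x$merit_trace)))
  invisible(x)
}

#' Tidy method for optimized designs: one row per layer
#' @param x A `filter_design`.
#' @param ... Unused.
#' @return Tibble with `layer`, `index`, `thickness_nm`.
#' @export
tidy.filter_design <- function(x, ...) tidy(x$stack)

#' Glance method for optimized designs: one-row summary
#' @param x A `filter_design`.
#' @param ... Unused.
#' @return One-row tibble with the merit variant, final merit, evaluation
#'   count, convergence flag and seed.
#' @importFrom generics glance
#' @export
glance.filter_design <- function(x, ...) {
  tibble::tibble(variant = x$variant,
                 n_layers = length(x$thicknesses),
                 final_merit = x$final_merit,
                 n_evaluations = length(x$merit_trace),
                 converged = x$converged,
                 seed = x$seed)
}

#' @export
autoplot.filter_design <- function(object, ...) {
  df <- tibble::tibble(evaluation = seq_along(object$merit_trace),
                       merit = object$merit_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$evaluation, .data$merit)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "function evaluation (running best)", y = "merit")
}

# seed helpers: set a temporary seed and restore global RNG state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
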