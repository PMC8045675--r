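#' Instantaneous reaction rates of the activator-inhibitor model
#'
#' Evaluates the right-hand side of the well-mixed model at a state
#' `(a, i)`. The knockdown factor `params$f_knockdown` multiplies total
#' activator production (basal plus autocatalytic). A small regularization
#' `i + 1e-12` keeps the autocatalytic term finite at `i = 0`; at `a = 0`
#' the activator derivative is exactly `f * sigma_a`, so non-negative
#' states cannot cross zero.
#'
#' @param a Activator concentration (>= 0).
#' @param i Inhibitor concentration (>= 0).
#' @param params A [network_params()] object.
#' @return A named numeric vector `c(da_dt = ..., di_dt = ...)`.
#' @examples
#' p <- network_params(n_coop = 2)
#' mbw_rhs(1, 1, p)  # (0, 0): symmetric steady state
#' @export
mbw_rhs <- function(a, i, params) {
  stopifnot(inherits(params, "network_params"))
  if (!is.numeric(a) || !is.numeric(i) || anyNA(a) || anyNA(i) ||
      any(!is.finite(a)) || any(!is.finite(i))) {
    stop("state (a, i) must be finite numeric; got a = ", deparse(a),
         ", i = ", deparse(i), call. = FALSE)
  }
  p <- params
  ireg <- i + 1e-12
  da <- p$f_knockdown *
    (p$sigma_a + p$rho_a * a^2 / ((1 + p$kappa * a^2) * ireg)) -
    p$mu_a * a
  di <- p$sigma_i + p$rho_i * a^p$n_coop - p$mu_i * i
  c(da_dt = da, di_dt = di)
}

#' Jacobian of the well-mixed model at a state
#'
#' @inheritParams mbw_rhs
#' @return A 2x2 numeric matrix, rows/columns ordered `(a, i)`.
#' @export
mbw_jacobian <- function(a, i, params) {
  stopifnot(inherits(params, "network_params"))
  p <- params
  ireg <- i + 1e-12
  s <- 1 + p$kappa * a^2
  j11 <- p$f_knockdown * p$rho_a * 2 * a / (s^2 * ireg) - p$mu_a
  j12 <- -p$f_knockdown * p$rho_a * a^2 / (s * ireg^2)
  j21 <- if (a == 0 && p$n_coop > 1) 0 else p$rho_i * p$n_coop * a^(p$n_coop - 1)
  j22 <- -p$mu_i
  matrix(c(j11, j12, j21, j22), nrow = 2, byrow = TRUE,
         dimnames = list(c("a", "i"), c("a", "i")))
}

# inhibitor nullcline: i at which di/dt = 0 for given a
i_nullcline <- function(a, p) (p$sigma_i + p$rho_i * a^p$n_coop) / p$mu_i

# activator balance along the inhibitor nullcline; roots are homogeneous
# steady states
g_on_nullcline <- function(a, p) {
  i <- i_nullcline(a, p)
  p$f_knockdown *
    (p$sigma_a + p$rho_a * a^2 / ((1 + p$kappa * a^2) * (i + 1e-12))) -
    p$mu_a * a
}

#' Homogeneous steady state of the activator-inhibitor model
#'
#' Solves for steady states by reducing the system to a one-dimensional
#' root problem along the inhibitor nullcline, scanning a wide logarithmic
#' grid of activator levels for sign changes and polishing each bracket
#' with [stats::uniroot()]. Among the positive roots the *largest stable*
#' one is returned (the pigmented high branch); when no positive root
#' exists the trivial state `(0, sigma_i / mu_i)` is reported with
#' `trivial_only = TRUE` rather than raising an error.
#'
#' @param params A [network_params()] object. The stored `f_knockdown` is
#'   part of the model: steady states under knockdown are obtained by
#'   setting it below 1 (see [knockdown_foldchange()]).
#' @param tol Absolute residual tolerance on the reaction rates at the
#'   returned root.
#' @return A one-row tibble with columns `a_star`, `i_star`,
#'   `trivial_only` (no positive root found), `stable` (trace < 0 and
#'   det > 0 of the well-mixed Jacobian), and `residual` (max absolute
#'   reaction rate at the root).
#' @examples
#' p <- network_params(n_coop = 2)          # closed form: (1, 1)
#' steady_state(p)
#' steady_state(update_params(p, f_knockdown = 0.5))  # (0.5, 0.25)
#' @export
steady_state <- function(params, tol = 1e-10) {
  stopifnot(inherits(params, "network_params"))
  p <- params

  # characteristic activator scale from the kappa = 0, sigma = 0 closed form
  scale_guess <- (p$f_knockdown * p$rho_a * p$mu_i /
                    (p$mu_a * p$rho_i))^(1 / max(p$n_coop - 1, 0.5))
  if (!is.finite(scale_guess) || scale_guess <= 0) scale_guess <- 1

  a_grid <- scale_guess * 10^seq(-8, 8, length.out = 801)
  g_vals <- vapply(a_grid, g_on_nullcline, numeric(1), p = p)

  roots <- numeric(0)
  sgn <- sign(g_vals)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (j in flips) {
    r <- stats::uniroot(g_on_nullcline, lower = a_grid[j],
                        upper = a_grid[j + 1], p = p, tol = 1e-14)
    roots <- c(roots, r$root)
  }
  exact <- a_grid[g_vals == 0 & a_grid > 0]
  roots <- sort(unique(c(roots, exact)))
  roots <- roots[roots > 0]

  if (length(roots) == 0) {
    i0 <- p$sigma_i / p$mu_i
    return(tibble::tibble(
      a_star = 0, i_star = i0, trivial_only = TRUE,
      stable = NA, residual = 0
    ))
  }

  is_stable <- vapply(roots, function(a) {
    J <- mbw_jacobian(a, i_nullcline(a, p), p)
    sum(diag(J)) < 0 && det(J) > 0
  }, logical(1))

  a_star <- if (any(is_stable)) max(roots[is_stable]) else max(roots)
  i_star <- i_nullcline(a_star, p)
  res <- max(abs(mbw_rhs(a_star, i_star, p)))
  if (res > tol * max(1, a_star)) {
    warning("steady-state residual ", format(res), " exceeds tolerance")
  }
  tibble::tibble(
    a_star = a_star, i_star = i_star, trivial_only = FALSE,
    stable = is_stable[match(a_star, roots)], residual = res
  )
}

#' Fold change of activator and inhibitor under an RNAi knockdown
#'
#' Compares the positive steady state at knockdown factor `f` with the
#' wild-type baseline (`f = 1`) and reports fold-*downs*
#' `FC_x = x*(f = 1) / x*(f)`. In the `sigma = 0`, `kappa = 0` limit these
#' obey the closed form `FC_i = FC_a^n_coop`, so any cooperativity above 1
#' amplifies a modest activator knockdown into a larger inhibitor
#' collapse. If the perturbed system loses its positive state entirely the
#' fold-downs are reported as `Inf` and `collapsed = TRUE` — the
#' pattern/pigment-loss regime.
#'
#' @param params A [network_params()] object; its own `f_knockdown` is
#'   ignored (baseline is always `f = 1`).
#' @param f Knockdown factor(s) in (0, 1]; vectorized.
#' @return A tibble with one row per `f`: `f`, `a_star`, `i_star`, `FC_a`,
#'   `FC_i`, `amplification` (`FC_i / FC_a`), `collapsed`.
#' @examples
#' p <- network_params(n_coop = 2)
#' knockdown_foldchange(p, f = c(1, 1/3))  # FC_a = 3 gives FC_i = 9
#' @export
knockdown_foldchange <- function(params, f) {
  stopifnot(inherits(params, "network_params"),
            is.numeric(f), all(f > 0), all(f <= 1))
  base <- steady_state(update_params(params, f_knockdown = 1))
  if (isTRUE(base$trivial_only)) {
    stop("baseline (f = 1) system has no positive steady state; ",
         "fold changes are undefined", call. = FALSE)
  }
  purrr::map_dfr(f, function(fj) {
    st <- steady_state(update_params(params, f_knockdown = fj))
    if (isTRUE(st$trivial_only) || st$a_star <= 0) {
      tibble::tibble(f = fj, a_star = 0, i_star = st$i_star,
                     FC_a = Inf, FC_i = Inf, amplification = NA_real_,
                     collapsed = TRUE)
    } else {
      fca <- base$a_star / st$a_star
      fci <- base$i_star / st$i_star
      tibble::tibble(f = fj, a_star = st$a_star, i_star = st$i_star,
                     FC_a = fca, FC_i = fci, amplification = fci / fca,
                     collapsed = FALSE)
    }
  })
}

#' Integrate the well-mixed model in time
#'
#' Wraps [deSolve::lsoda()] with relative tolerance `1e-8`. Output is
#' clamped at zero (the model cannot cross zero analytically; the solver
#' may undershoot by rounding).
#'
#' @param params A [network_params()] object.
#' @param init Named numeric `c(a = ..., i = ...)`, both >= 0.
#' @param t_end Final time (> 0).
#' @param dt Output time step (> 0, <= `t_end`).
#' @return A tibble with columns `t`, `a`, `i`.
#' @export
integrate_ode <- function(params, init = c(a = 0.1, i = 0.1),
                          t_end = 50, dt = 0.1) {
  stopifnot(inherits(params, "network_params"))
  if (!(dt > 0) || t_end < dt) {
    stop("need dt > 0 and t_end >= dt; got dt = ", dt,
         ", t_end = ", t_end, call. = FALSE)
  }
  if (anyNA(init) || any(!is.finite(init)) || any(init < 0)) {
    stop("init must be finite and non-negative", call. = FALSE)
  }
  a0 <- if (!is.null(names(init))) init[["a"]] else init[[1]]
  i0 <- if (!is.null(names(init))) init[["i"]] else init[[2]]
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::lsoda(
    y = c(a = a0, i = i0), times = times,
    func = function(t, y, parms) {
      r <- mbw_rhs(max(y[["a"]], 0), max(y[["i"]], 0), parms)
      list(unname(r))
    },
    parms = params, rtol = 1e-8, atol = 1e-12
  )
  if (anyNA(sol) || any(!is.finite(sol))) {
    stop("integration produced non-finite values; the state diverged. ",
         "Try a smaller dt (used dt = ", dt, ") or check parameters.",
         call. = FALSE)
  }
  tibble::tibble(t = sol[, "time"],
                 a = pmax(sol[, "a"], 0),
                 i = pmax(sol[, "i"], 0))
}

#' Linear (Turing) stability analysis of the homogeneous steady state
#'
#' Linearizes the reaction-diffusion system about the homogeneous positive
#' steady state and evaluates the dispersion relation: for each wavenumber
#' `k` the growth rate is the largest real part of the eigenvalues of
#' `J - k^2 diag(D_a, D_i)`. The state is Turing-unstable when it is
#' stable to uniform perturbations (`trace(J) < 0`, `det(J) > 0`) yet some
#' `k > 0` grows.
#'
#' @param params A [network_params()] object with diffusivities set.
#' @param k_grid Numeric vector of wavenumbers (>= 0) to evaluate.
#' @return A `stability_report` object: list with `a_star`, `i_star`,
#'   `trivial_only`, `jacobian`, `trace_J`, `det_J`, `dispersion` (tibble
#'   of `k`, `growth_rate`), `turing_unstable`, `k_max`. Use
#'   [generics::tidy()] for the dispersion table, [generics::glance()] for
#'   the one-row summary, and [ggplot2::autoplot()] to plot.
#' @export
linear_stability <- function(params, k_grid = seq(0, 3, length.out = 301)) {
  stopifnot(inherits(params, "network_params"),
            is.numeric(k_grid), all(k_grid >= 0))
  st <- steady_state(params)
  if (isTRUE(st$trivial_only)) {
    rep <- list(a_star = st$a_star, i_star = st$i_star, trivial_only = TRUE,
                jacobian = NULL, trace_J = NA_real_, det_J = NA_real_,
                dispersion = NULL, turing_unstable = FALSE, k_max = NULL)
    return(structure(rep, class = "stability_report"))
  }
  J <- mbw_jacobian(st$a_star, st$i_star, params)
  growth <- vapply(k_grid, function(k) {
    M <- J - k^2 * diag(c(params$D_a, params$D_i))
    max(Re(eigen(M, only.values = TRUE)$values))
  }, numeric(1))
  disp <- tibble::tibble(k = k_grid, growth_rate = growth)
  tr <- sum(diag(J)); dt_ <- det(J)
  pos_k <- disp$k > 0
  turing <- tr < 0 && dt_ > 0 && any(pos_k) && max(disp$growth_rate[pos_k]) > 0
  k_max <- if (turing) {
    disp$k[pos_k][which.max(disp$growth_rate[pos_k])]
  } else NULL
  structure(
    list(a_star = st$a_star, i_star = st$i_star, trivial_only = FALSE,
         jacobian = J, trace_J = tr, det_J = dt_, dispersion = disp,
         turing_unstable = turing, k_max = k_max),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  if (x$trivial_only) {
    cat("  trivial-only steady state (a* = 0); no dispersion computed\n")
    return(invisible(x))
  }
  cat(sprintf("  steady state: a* = %.6g, i* = %.6g\n", x$a_star, x$i_star))
  cat(sprintf("  trace(J) = %.6g, det(J) = %.6g\n", x$trace_J, x$det_J))
  cat(sprintf("  turing_unstable: %s", x$turing_unstable))
  if (!is.null(x$k_max)) cat(sprintf(" (k_max = %.4g)", x$k_max))
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the dispersion relation of a stability report
#'
#' @param x A `stability_report`.
#' @param ... Unused.
#' @return A tibble with columns `k` and `growth_rate` (empty when only
#'   the trivial state exists).
#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) {
  if (is.null(x$dispersion)) {
    return(tibble::tibble(k = numeric(0), growth_rate = numeric(0)))
  }
  x$dispersion
}

#' One-row summary of a stability report
#'
#' @param x A `stability_report`.
#' @param ... Unused.
#' @return A one-row tibble: `a_star`, `i_star`, `trivial_only`,
#'   `trace_J`, `det_J`, `turing_unstable`, `k_max`, `max_growth_rate`.
#' @method glance stability_report
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(
    a_star = x$a_star, i_star = x$i_star, trivial_only = x$trivial_only,
    trace_J = x$trace_J, det_J = x$det_J,
    turing_unstable = x$turing_unstable,
    k_max = if (is.null(x$k_max)) NA_real_ else x$k_max,
    max_growth_rate = if (is.null(x$dispersion)) NA_real_ else
      max(x$dispersion$growth_rate[x$dispersion$k > 0], -Inf)
  )
}

#' Plot a dispersion relation
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot of growth rate against wavenumber with the zero line
#'   and, when Turing-unstable, the fastest-growing mode marked.
#' @method autoplot stability_report
#' @export
autoplot.stability_report <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$growth_rate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavenumber k", y = "max Re growth rate",
                  title = if (object$turing_unstable)
                    "Turing-unstable dispersion relation" else
                      "Dispersion relation (no Turing instability)")
  if (!is.null(object$k_max)) {
    p <- p + ggplot2::geom_vline(xintercept = object$k_max,
                                 colour = "purple", linetype = "dotted")
  }
  p
}

#' Write a stability report's dispersion relation to CSV
#'
#' @param report A `stability_report`.
#' @param path Output CSV path (columns `k`, `growth_rate`).
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(report, path) {
  utils::write.csv(as.data.frame(tidy(report)), path, row.names = FALSE)
  invisible(path)
}
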