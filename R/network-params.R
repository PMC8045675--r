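#' Kinetic parameters of the minimal MBW activator-inhibitor model
#'
#' Constructs and validates the parameter set of the two-species
#' activator-inhibitor model used throughout the package. The activator `a`
#' stands for the MBW activation complex (proxied by the R2R3 MYB
#' *MYB5a/NEGAN* transcript); the inhibitor `i` stands for the R3 MYB
#' repressor (*RTO*), which is itself transcriptionally activated by the
#' complex and represses it by sequestering the bHLH partner.
#'
#' The dynamics are
#' \deqn{da/dt = f \, (\sigma_a + \rho_a a^2 / ((1 + \kappa a^2)\, i)) - \mu_a a}
#' \deqn{di/dt = \sigma_i + \rho_i a^{n} - \mu_i i}
#' a Gierer-Meinhardt-type system with saturation \eqn{\kappa}, basal
#' production \eqn{\sigma}, cooperativity \eqn{n} of activator-driven
#' inhibitor production, and an RNAi knockdown factor \eqn{f \in (0,1]}
#' multiplying *total* activator production (RNAi destroys the transcript,
#' upstream of both the basal and the autocatalytic route).
#'
#' @param sigma_a Basal activator production rate (concentration/time, >= 0).
#' @param sigma_i Basal inhibitor production rate (>= 0).
#' @param rho_a Autocatalytic activator production coefficient (> 0).
#' @param rho_i Activator-driven inhibitor production coefficient (> 0).
#' @param mu_a Activator decay rate (> 0).
#' @param mu_i Inhibitor decay rate (> 0).
#' @param kappa Activator saturation constant (>= 0); `kappa = 0` recovers
#'   the unsaturated model with a closed-form steady state.
#' @param n_coop Cooperativity exponent of activator-driven inhibitor
#'   production (>= 1).
#' @param D_a Activator diffusivity (>= 0), used by the spatial simulator.
#' @param D_i Inhibitor diffusivity (>= 0).
#' @param f_knockdown Multiplicative RNAi factor on total activator
#'   production, in (0, 1]; 1 is wild type.
#'
#' @return An object of class `network_params` (a named list).
#' @examples
#' p <- network_params(rho_a = 1, rho_i = 1, mu_a = 1, mu_i = 1, n_coop = 2)
#' mbw_rhs(a = 1, i = 1, params = p)
#' @export
network_params <- function(sigma_a = 0, sigma_i = 0,
                           rho_a = 1, rho_i = 1,
                           mu_a = 1, mu_i = 1,
                           kappa = 0, n_coop = 2,
                           D_a = 0, D_i = 0,
                           f_knockdown = 1) {
  p <- list(
    sigma_a = sigma_a, sigma_i = sigma_i,
    rho_a = rho_a, rho_i = rho_i,
    mu_a = mu_a, mu_i = mu_i,
    kappa = kappa, n_coop = n_coop,
    D_a = D_a, D_i = D_i,
    f_knockdown = f_knockdown
  )
  validate_network_params(p)
  structure(p, class = "network_params")
}

validate_network_params <- function(p) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("`", nm, "` must be a single finite number, got ",
           deparse(x), call. = FALSE)
    }
  }
  for (nm in names(p)) num1(p[[nm]], nm)
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(p$sigma_a >= 0, "`sigma_a` must be >= 0")
  chk(p$sigma_i >= 0, "`sigma_i` must be >= 0")
  chk(p$rho_a > 0, "`rho_a` must be > 0")
  chk(p$rho_i > 0, "`rho_i` must be > 0")
  chk(p$mu_a > 0, "`mu_a` must be > 0")
  chk(p$mu_i > 0, "`mu_i` must be > 0")
  chk(p$kappa >= 0, "`kappa` must be >= 0")
  chk(p$n_coop >= 1, "`n_coop` must be >= 1")
  chk(p$D_a >= 0, "`D_a` must be >= 0")
  chk(p$D_i >= 0, "`D_i` must be >= 0")
  chk(p$f_knockdown > 0 && p$f_knockdown <= 1,
      "`f_knockdown` must lie in (0, 1]")
  invisible(p)
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params>\n")
  vals <- unlist(x)
  cat(paste0("  ", format(names(vals)), " = ", format(vals, digits = 6)),
      sep = "\n")
  invisible(x)
}

#' Coerce a parameter set to a one-row tibble
#'
#' @param x A `network_params` object.
#' @param ... Unused.
#' @return A one-row tibble with one column per parameter.
#' @method as_tibble network_params
#' @export
as_tibble.network_params <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Replace fields of a parameter set
#'
#' Returns a copy of `params` with the named fields replaced and the result
#' re-validated. Convenient for knockdown scans and presets.
#'
#' @param params A `network_params` object.
#' @param ... Named scalar replacements, e.g. `f_knockdown = 0.5`.
#' @return A `network_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "network_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown) > 0) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(params)
  p[names(repl)] <- repl
  validate_network_params(p)
  structure(p, class = "network_params")
}

#' Read network parameters from a configuration file
#'
#' Reads the flat `network:` section of a YAML configuration file (keys
#' exactly as the arguments of [network_params()]); missing keys take their
#' defaults, unknown keys are rejected.
#'
#' @param path Path to a YAML file with a top-level `network` section (or a
#'   flat file whose top level *is* the section).
#' @return A `network_params` object.
#' @export
read_network_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$network)) cfg <- cfg$network
  known <- names(formals(network_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown key(s) in [network] config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(network_params, cfg)
}

#' Write network parameters to a configuration file
#'
#' @param params A `network_params` object.
#' @param path Output path; written as YAML with a `network` section.
#' @return `path`, invisibly.
#' @export
write_network_params <- function(params, path) {
  stopifnot(inherits(params, "network_params"))
  yaml::write_yaml(list(network = unclass(params)), path)
  invisible(path)
}
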