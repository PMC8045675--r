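#' Two-zone petal domain for reaction-diffusion simulation
#'
#' Builds a rectangular grid split into a proximal nectar-guide zone and a
#' distal lobe zone, mirroring the dissection of *Mimulus* petals into
#' nectar guide versus lobe. Rows run proximal (row 1) to distal.
#'
#' @param nrow,ncol Grid dimensions (default 96 x 64).
#' @param h Grid spacing, length per cell (> 0; default 0.5).
#' @param guide_fraction Fraction of proximal rows assigned to the nectar
#'   guide (default 1/3); both zones must be non-empty.
#' @return A `petal_layout` object: list with `nrow`, `ncol`, `h`,
#'   `zone` (character matrix of `"nectar_guide"`/`"lobe"`), and
#'   `boundary = "no_flux"`.
#' @export
petal_layout <- function(nrow = 96, ncol = 64, h = 0.5,
                         guide_fraction = 1 / 3) {
  stopifnot(nrow >= 2, ncol >= 1, h > 0,
            guide_fraction > 0, guide_fraction < 1)
  n_guide <- round(nrow * guide_fraction)
  if (n_guide < 1 || n_guide >= nrow) {
    stop("both zones must be non-empty; got ", n_guide,
         " guide rows of ", nrow, call. = FALSE)
  }
  zone <- matrix("lobe", nrow, ncol)
  zone[seq_len(n_guide), ] <- "nectar_guide"
  structure(list(nrow = nrow, ncol = ncol, h = h, zone = zone,
                 boundary = "no_flux"),
            class = "petal_layout")
}

#' One-dimensional domain for dispersion-relation validation
#'
#' A single-row periodicity-free line of cells (all labelled `lobe`),
#' used to compare simulated pattern wavelengths against the
#' linear-stability prediction without zone structure.
#'
#' @param n Number of cells.
#' @param h Grid spacing.
#' @return A `petal_layout` with one row and no nectar-guide zone.
#' @export
line_layout <- function(n = 256, h = 0.5) {
  stopifnot(n >= 8, h > 0)
  structure(list(nrow = 1L, ncol = as.integer(n), h = h,
                 zone = matrix("lobe", 1L, n), boundary = "no_flux"),
            class = "petal_layout")
}

#' @export
print.petal_layout <- function(x, ...) {
  cat(sprintf("<petal_layout> %d x %d cells, h = %g, %d nectar-guide rows\n",
              x$nrow, x$ncol, x$h, sum(x$zone[, 1] == "nectar_guide")))
  invisible(x)
}

#' Reaction-diffusion parameter fixture for the petal model
#'
#' The shipped parameter set used by the genotype presets: a monostable
#' activator-inhibitor system whose unique steady-state branch passes
#' through a Turing-unstable band as the basal activator drive `sigma_a`
#' rises. Below the band the petal stays uniformly unpigmented, inside it
#' spots form, above it pigmentation is solid.
#'
#' @param sigma_a Basal activator production (zone-dependent in presets).
#' @param f_knockdown RNAi knockdown factor.
#' @return A [network_params()] object.
#' @export
petal_params <- function(sigma_a = 0.18, f_knockdown = 1) {
  network_params(sigma_a = sigma_a, sigma_i = 0.8,
                 rho_a = 0.8, rho_i = 1, mu_a = 1, mu_i = 2,
                 kappa = 0.3, n_coop = 2,
                 D_a = 0.01, D_i = 6,
                 f_knockdown = f_knockdown)
}

#' Genotype presets for the petal phenotype series
#'
#' Per-zone basal activator drives and a global knockdown factor for the
#' five modelled genotypes: yellow-flowered *M. l. luteus* (spotted nectar
#' guide, unpigmented lobe), solid-purple *M. l. variegatus*, their
#' spotted-lobe F1 hybrid, and strong/partial RNAi knockdowns of the
#' variegatus background. The lobe drive is ordered
#' luteus < F1 < variegatus; the F1 is modelled as an intermediate lobe
#' drive without committing to a cis- versus trans-dosage mechanism.
#'
#' @param name Optional preset name; with `NULL` all presets are returned.
#' @return A tibble with columns `name`, `sigma_a_guide`, `sigma_a_lobe`,
#'   `f_knockdown`.
#' @export
genotype_presets <- function(name = NULL) {
  tbl <- tibble::tribble(
    ~name,          ~sigma_a_guide, ~sigma_a_lobe, ~f_knockdown,
    "luteus",       0.18,           0.05,          1,
    "F1",           0.18,           0.15,          1,
    "variegatus",   0.18,           0.30,          1,
    "rnai_partial", 0.18,           0.30,          0.85,
    "rnai_strong",  0.18,           0.30,          0.15
  )
  if (is.null(name)) return(tbl)
  out <- tbl[tbl$name %in% name, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("unknown genotype preset: ", paste(name, collapse = ", "),
         "; available: ", paste(tbl$name, collapse = ", "), call. = FALSE)
  }
  out
}

# 5-point Laplacian with no-flux (reflecting) boundaries via edge
# replication; sums to zero over the grid up to rounding
laplacian_noflux <- function(M, h) {
  nr <- nrow(M); nc <- ncol(M)
  up    <- M[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- M[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  left  <- M[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- M[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  (up + down + left + right - 4 * M) / h^2
}

# largest dt admitted by the explicit scheme
rd_stability_bound <- function(params, h) {
  dmax <- max(params$D_a, params$D_i)
  if (dmax == 0) return(Inf)
  h^2 / (4 * dmax)
}

#' Simulate reaction-diffusion patterning on the petal domain
#'
#' Explicit forward-Euler integration of the activator-inhibitor model
#' with a 5-point Laplacian and no-flux boundaries. The time step must
#' satisfy the explicit-scheme stability bound
#' `dt <= h^2 / (4 max(D_a, D_i))`; violations are rejected with the
#' computed bound. The initial condition is the per-zone homogeneous
#' steady state (a small positive constant when only the trivial state
#' exists) plus seeded uniform noise.
#'
#' @param params A [network_params()] object; `sigma_a` and `f_knockdown`
#'   are overridden per zone/globally when a `preset` row is given.
#' @param layout A [petal_layout()].
#' @param preset A one-row tibble as returned by [genotype_presets()], or
#'   `NULL` to use `params` uniformly.
#' @param t_end Total simulated time.
#' @param dt Time step; default 90% of the stability bound.
#' @param noise_amplitude Relative amplitude of the uniform initial noise
#'   (fraction of each field's mean; default 0.05).
#' @param seed Integer seed for the initial noise (required: patterning is
#'   a symmetry-breaking process and must be reproducible).
#' @return A `grid_field` object: list with matrices `a` and `i`, time
#'   `t`, the `layout`, the effective `params`, `preset_name`, and `seed`.
#' @export
integrate_rd <- function(params, layout = petal_layout(), preset = NULL,
                         t_end = 150, dt = NULL, noise_amplitude = 0.05,
                         seed) {
  stopifnot(inherits(params, "network_params"),
            inherits(layout, "petal_layout"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)

  bound <- rd_stability_bound(params, layout$h)
  if (is.null(dt)) dt <- 0.9 * bound
  if (dt > bound) {
    stop(sprintf(
      "dt = %g violates the explicit-scheme stability bound %g = h^2/(4 max(D_a, D_i))",
      dt, bound), call. = FALSE)
  }
  stopifnot(dt > 0, t_end >= dt)

  guide <- layout$zone == "nectar_guide"
  if (!is.null(preset)) {
    stopifnot(nrow(preset) == 1)
    params <- update_params(params, f_knockdown = preset$f_knockdown)
    sig_a <- matrix(preset$sigma_a_lobe, layout$nrow, layout$ncol)
    sig_a[guide] <- preset$sigma_a_guide
    zone_sigmas <- c(preset$sigma_a_guide, preset$sigma_a_lobe)
  } else {
    sig_a <- matrix(params$sigma_a, layout$nrow, layout$ncol)
    zone_sigmas <- c(params$sigma_a, params$sigma_a)
  }

  # per-zone homogeneous steady state as initial condition
  a0 <- matrix(0, layout$nrow, layout$ncol)
  i0 <- matrix(0, layout$nrow, layout$ncol)
  for (z in seq_along(zone_sigmas)) {
    st <- steady_state(update_params(params, sigma_a = zone_sigmas[z]))
    av <- if (st$trivial_only || st$a_star <= 0) 0.01 else st$a_star
    iv <- if (st$i_star <= 0) 0.01 else st$i_star
    mask <- if (z == 1) guide else !guide
    a0[mask] <- av
    i0[mask] <- iv
  }
  set.seed(seed)
  a0 <- a0 * (1 + noise_amplitude * stats::runif(length(a0), -1, 1))
  i0 <- i0 * (1 + noise_amplitude * stats::runif(length(i0), -1, 1))

  p <- params
  eps <- 1e-12
  n_steps <- ceiling(t_end / dt)
  a <- a0; i <- i0
  for (s in seq_len(n_steps)) {
    auto <- p$rho_a * a^2 / ((1 + p$kappa * a^2) * (i + eps))
    ra <- p$f_knockdown * (sig_a + auto) - p$mu_a * a +
      p$D_a * laplacian_noflux(a, layout$h)
    ri <- p$sigma_i + p$rho_i * a^p$n_coop - p$mu_i * i +
      p$D_i * laplacian_noflux(i, layout$h)
    a <- pmax(a + dt * ra, 0)
    i <- pmax(i + dt * ri, 0)
    if (s %% 200L == 0L && (anyNA(a) || any(!is.finite(a)))) {
      stop("non-finite field at t = ", s * dt,
           "; dt = ", dt, " is too large for these parameters ",
           "(reaction stiffness); try dt <= ", signif(bound / 4, 3),
           call. = FALSE)
    }
  }
  if (anyNA(a) || anyNA(i) || any(!is.finite(a)) || any(!is.finite(i))) {
    stop("non-finite field at t_end; reduce dt (used ", dt, ")",
         call. = FALSE)
  }
  structure(
    list(a = a, i = i, t = n_steps * dt, layout = layout, params = p,
         preset_name = if (is.null(preset)) NA_character_ else preset$name,
         seed = seed),
    class = "grid_field"
  )
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %d x %d at t = %g (preset: %s, seed %d)\n",
              nrow(x$a), ncol(x$a), x$t, x$preset_name, x$seed))
  cat(sprintf("  activator range [%.4g, %.4g]\n", min(x$a), max(x$a)))
  invisible(x)
}

#' Coerce a simulated field to a long tibble
#'
#' @param x A `grid_field`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y` (lengths), `zone`,
#'   `a`, `i`.
#' @method as_tibble grid_field
#' @export
as_tibble.grid_field <- function(x, ...) {
  nr <- nrow(x$a); nc <- ncol(x$a)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = (rep(seq_len(nc), each = nr) - 0.5) * x$layout$h,
    y = (rep(seq_len(nr), times = nc) - 0.5) * x$layout$h,
    zone = as.vector(x$layout$zone),
    a = as.vector(x$a),
    i = as.vector(x$i)
  )
}

#' Plot a simulated petal field
#'
#' @param object A `grid_field`.
#' @param species `"a"` (activator, default) or `"i"` (inhibitor).
#' @param ... Unused.
#' @return A ggplot raster of the chosen concentration field with the
#'   nectar-guide/lobe boundary drawn.
#' @method autoplot grid_field
#' @export
autoplot.grid_field <- function(object, species = c("a", "i"), ...) {
  species <- match.arg(species)
  d <- as_tibble(object)
  n_guide <- sum(object$layout$zone[, 1] == "nectar_guide")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data[[species]])) +
    ggplot2::geom_raster() +
    ggplot2::geom_hline(yintercept = n_guide * object$layout$h,
                        colour = "white", linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = if (species == "a") "activator" else "inhibitor",
                  title = sprintf("preset %s, t = %g",
                                  object$preset_name, object$t))
}

# connected components (4-connectivity) of a logical matrix, via igraph
count_components <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(list(n = 0L, centroids = NULL))
  nr <- nrow(mask)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  id <- seq_along(idx)
  key <- function(r, c) (c - 1L) * nr + r
  lut <- integer(nr * ncol(mask)); lut[idx] <- id
  edges <- integer(0)
  right <- which(cols < ncol(mask) & mask[key(rows, cols + 1L)])
  down <- which(rows < nr & mask[key(rows + 1L, cols)])
  if (length(right) > 0) {
    edges <- c(edges, rbind(id[right], lut[key(rows[right], cols[right] + 1L)]))
  }
  if (length(down) > 0) {
    edges <- c(edges, rbind(id[down], lut[key(rows[down] + 1L, cols[down])]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(id) - igraph::vcount(g)))
  comp <- igraph::components(g)
  cent <- vapply(seq_len(comp$no), function(cc) {
    m <- comp$membership == cc
    c(mean(rows[m]), mean(cols[m]))
  }, numeric(2))
  list(n = comp$no, centroids = t(cent))
}

#' Summarize a simulated field into a phenotype call
#'
#' Thresholds the activator field at the midpoint of its domain-wide
#' (min, max) range (unless the field is near-constant or an explicit
#' `threshold` is given), then summarizes each zone and the whole domain.
#' A zone is classified `spotted` when its spatial coefficient of
#' variation is at least `cv_tol` *and* it contains at least one
#' supra-threshold connected component (4-connectivity); otherwise it is
#' `uniform_low` or `uniform_high` according to whether its mean activator
#' level clears `uniform_cutoff`. `spot_count` is reported as 0 for
#' uniform calls so that spots are counted only where a pattern exists.
#'
#' @param field A `grid_field`.
#' @param layout A [petal_layout()]; defaults to the field's own.
#' @param threshold Pigmentation threshold on the activator field;
#'   `NULL` (default) uses the domain midpoint rule.
#' @param cv_tol Spatial-CV tolerance separating uniform from patterned
#'   fields (default 0.05).
#' @param uniform_cutoff Mean activator level separating unpigmented from
#'   pigmented uniform fields, in concentration units of the model
#'   (default 0.5; the shipped fixture's steady states sit near 0.05-0.25
#'   when unpigmented and 0.9-1.2 when solidly pigmented).
#' @param margin_cells Rows excluded on each side of the zone boundary
#'   when summarizing a single zone (default 4), mimicking the dissection
#'   margin between lobe and nectar guide: the inhibitor's diffusion range
#'   creates a gradient of a few cells that belongs to neither zone's
#'   interior phenotype. The whole-domain summary uses every cell.
#' @return A tibble with one row per zone plus `"whole"`: `zone`,
#'   `classification`, `pigmented_area_fraction` (supra-threshold fraction
#'   for spotted fields, 0/1 for uniform calls), `spot_count`,
#'   `mean_spot_spacing` (length units; `NA` unless spotted), `spatial_cv`,
#'   `mean_a`, `threshold`.
#' @export
summarize_pattern <- function(field, layout = field$layout,
                              threshold = NULL, cv_tol = 0.05,
                              uniform_cutoff = 0.5, margin_cells = 4) {
  stopifnot(inherits(field, "grid_field") || is.matrix(field))
  a <- if (is.matrix(field)) field else field$a
  if (anyNA(a) || any(!is.finite(a))) {
    stop("field contains non-finite values", call. = FALSE)
  }
  rng <- range(a)
  near_constant <- diff(rng) < 1e-8 * max(1, abs(rng[2]))
  if (is.null(threshold)) {
    threshold <- if (near_constant) Inf else mean(rng)
  }

  guide_rows <- which(apply(layout$zone == "nectar_guide", 1, any))
  boundary_rows <- integer(0)
  if (length(guide_rows) > 0 && length(guide_rows) < nrow(a)) {
    b <- max(guide_rows)  # last proximal guide row
    boundary_rows <- intersect(seq(b - margin_cells + 1, b + margin_cells),
                               seq_len(nrow(a)))
  }

  zone_summary <- function(mask_cells, zone_name, trim_margin) {
    if (trim_margin && length(boundary_rows) > 0) {
      mask_cells[boundary_rows, ] <- FALSE
    }
    if (!any(mask_cells)) return(NULL)
    vals <- a[mask_cells]
    m <- mean(vals)
    cv <- if (m > 0) stats::sd(vals) / m else 0
    supra <- matrix(FALSE, nrow(a), ncol(a))
    supra[mask_cells] <- a[mask_cells] >= threshold
    comp <- count_components(supra)
    area <- mean(a[mask_cells] >= threshold)
    spotted <- cv >= cv_tol && comp$n > 0 && area < 1
    cls <- if (spotted) "spotted" else
      if (m >= uniform_cutoff) "uniform_high" else "uniform_low"
    spacing <- NA_real_
    if (spotted && comp$n >= 2) {
      d <- as.matrix(stats::dist(comp$centroids)) * layout$h
      diag(d) <- Inf
      spacing <- mean(apply(d, 1, min))
    }
    tibble::tibble(
      zone = zone_name, classification = cls,
      pigmented_area_fraction = if (cls == "spotted") area else
        as.numeric(cls == "uniform_high"),
      spot_count = if (spotted) comp$n else 0L,
      mean_spot_spacing = spacing,
      spatial_cv = cv, mean_a = m, threshold = threshold
    )
  }

  dplyr::bind_rows(
    zone_summary(layout$zone == "nectar_guide", "nectar_guide", TRUE),
    zone_summary(layout$zone == "lobe", "lobe", TRUE),
    zone_summary(matrix(TRUE, nrow(a), ncol(a)), "whole", FALSE)
  )
}

#' Simulate and summarize the genotype phenotype series
#'
#' Runs [integrate_rd()] for each genotype preset on a shared layout and
#' parameter base, and summarizes each result. The qualitative series
#' mirrors the cross: luteus (spotted guide, plain lobe), F1 (spotted
#' lobe), variegatus (solid lobe), and RNAi knockdowns of variegatus
#' (partial spotting, then complete loss).
#'
#' @param params Base [network_params()] (e.g. [petal_params()]).
#' @param layout A [petal_layout()].
#' @param presets Preset tibble, default [genotype_presets()].
#' @param seed Integer seed, shared across genotypes.
#' @param t_end,noise_amplitude Passed to [integrate_rd()].
#' @param keep_fields Keep the simulated `grid_field`s as an attribute
#'   `fields` (default `FALSE`).
#' @return A tibble of per-zone [summarize_pattern()] rows with a leading
#'   `genotype` column, ordered as in `presets`.
#' @export
genotype_series <- function(params = petal_params(),
                            layout = petal_layout(),
                            presets = genotype_presets(), seed,
                            t_end = 150, noise_amplitude = 0.05,
                            keep_fields = FALSE) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  fields <- vector("list", nrow(presets))
  out <- purrr::map_dfr(seq_len(nrow(presets)), function(j) {
    fld <- integrate_rd(params, layout, preset = presets[j, ],
                        t_end = t_end, noise_amplitude = noise_amplitude,
                        seed = seed)
    fields[[j]] <<- fld
    dplyr::mutate(summarize_pattern(fld),
                  genotype = presets$name[j], .before = 1)
  })
  if (keep_fields) attr(out, "fields") <- fields
  out
}

#' Plot a phenotype series as a faceted raster panel
#'
#' @param params,layout,presets,seed,t_end,noise_amplitude As in
#'   [genotype_series()].
#' @return A ggplot faceting the activator field by genotype.
#' @export
plot_genotype_series <- function(params = petal_params(),
                                 layout = petal_layout(),
                                 presets = genotype_presets(), seed,
                                 t_end = 150, noise_amplitude = 0.05) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  d <- purrr::map_dfr(seq_len(nrow(presets)), function(j) {
    fld <- integrate_rd(params, layout, preset = presets[j, ],
                        t_end = t_end, noise_amplitude = noise_amplitude,
                        seed = seed)
    dplyr::mutate(as_tibble(fld), genotype = presets$name[j])
  })
  d$genotype <- factor(d$genotype, levels = presets$name)
  n_guide <- sum(layout$zone[, 1] == "nectar_guide")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$a)) +
    ggplot2::geom_raster() +
    ggplot2::geom_hline(yintercept = n_guide * layout$h,
                        colour = "white", linewidth = 0.3) +
    ggplot2::facet_wrap(~genotype, nrow = 1) +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "activator")
}

#' Write a simulated field as delimited text
#'
#' One file per species, row-major numeric matrix with a `#`-prefixed
#' header comment recording shape, spacing and time.
#'
#' @param field A `grid_field`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_grid_field <- function(field, dir, prefix = "field") {
  stopifnot(inherits(field, "grid_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sp in c("a", "i")) {
    path <- file.path(dir, sprintf("%s_%s.txt", prefix, sp))
    hdr <- sprintf("# %d %d h=%g t=%g species=%s", nrow(field[[sp]]),
                   ncol(field[[sp]]), field$layout$h, field$t, sp)
    writeLines(hdr, path)
    utils::write.table(field[[sp]], path, append = TRUE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Dominant pattern wavelength of a 1D field by Fourier analysis
#'
#' For a single-row (or single-column) domain, returns the wavelength of
#' the largest-magnitude nonzero Fourier mode of the mean-centred
#' activator profile, in length units. Used to compare simulated patterns
#' with the linear-stability prediction `2*pi/k_max`.
#'
#' @param field A `grid_field` simulated on a 1D layout.
#' @return The dominant wavelength (length units).
#' @export
dominant_wavelength <- function(field) {
  a <- field$a
  prof <- if (nrow(a) == 1L) as.vector(a) else if (ncol(a) == 1L) {
    as.vector(a)
  } else {
    stop("dominant_wavelength expects a 1D domain", call. = FALSE)
  }
  n <- length(prof)
  sp <- Mod(stats::fft(prof - mean(prof)))[2:floor(n / 2)]
  m <- which.max(sp)  # mode index m corresponds to frequency m / (n*h)
  n * field$layout$h / m
}
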