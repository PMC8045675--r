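#' Compare knockdown-model predictions with DE-estimated regulator folds
#'
#' Matches the activator-inhibitor model to the observed activator
#' knockdown by solving for the knockdown factor `f` at which the model's
#' steady-state activator fold-down equals the DE estimate for the
#' targeted MYB, then reports the model's predicted inhibitor fold-down
#' (`FC_i = FC_a^n_coop` in the unsaturated no-basal limit) next to the
#' observed repressor folds. The amplification ratio `FC_i / FC_a`
#' quantifies how a modest activator knockdown produces a much larger
#' repressor collapse.
#'
#' @param reg_table A tibble from [regulator_table()] (or any table with
#'   `subrole` and `fold_down` columns).
#' @param params A [network_params()] object for the prediction (default:
#'   unsaturated, no-basal model with `n_coop = 2`).
#' @param null_fold_tol Observed folds all within `null_fold_tol` of 1
#'   flag the report as having no knockdown signal (default 1.2).
#' @return A list of class `model_de_comparison`: `matched_f`,
#'   `predicted` (one-row tibble `FC_a`, `FC_i`, `amplification`),
#'   `observed` (the regulator table), `no_knockdown_signal`.
#' @export
compare_model_to_de <- function(reg_table,
                                params = network_params(n_coop = 2),
                                null_fold_tol = 1.2) {
  stopifnot(is.data.frame(reg_table),
            all(c("subrole", "fold_down") %in% names(reg_table)),
            inherits(params, "network_params"))
  fc_obs <- reg_table$fold_down[reg_table$subrole == "MYB5a"]
  folds <- reg_table$fold_down[!is.na(reg_table$fold_down)]
  no_signal <- length(folds) == 0 ||
    all(abs(log(folds)) < log(null_fold_tol))

  matched_f <- NA_real_
  predicted <- tibble::tibble(FC_a = NA_real_, FC_i = NA_real_,
                              amplification = NA_real_)
  if (!no_signal && length(fc_obs) == 1 && !is.na(fc_obs) && fc_obs > 1) {
    # solve FC_a(f) = fc_obs on log scale; FC_a is decreasing in f
    obj <- function(lf) {
      log(knockdown_foldchange(params, exp(lf))$FC_a) - log(fc_obs)
    }
    sol <- stats::uniroot(obj, lower = log(1e-6), upper = log(1),
                          tol = 1e-12)
    matched_f <- exp(sol$root)
    kd <- knockdown_foldchange(params, matched_f)
    predicted <- tibble::tibble(FC_a = kd$FC_a, FC_i = kd$FC_i,
                                amplification = kd$FC_i / kd$FC_a)
  }
  structure(
    list(matched_f = matched_f, predicted = predicted,
         observed = reg_table, no_knockdown_signal = no_signal,
         n_coop = params$n_coop),
    class = "model_de_comparison"
  )
}

#' @export
print.model_de_comparison <- function(x, ...) {
  cat("<model_de_comparison>\n")
  if (x$no_knockdown_signal) {
    cat("  no knockdown signal: all observed regulator folds ~ 1\n")
  }
  if (!is.na(x$matched_f)) {
    cat(sprintf("  matched f = %.4g (activator fold-down %.3g)\n",
                x$matched_f, x$predicted$FC_a))
    cat(sprintf("  predicted inhibitor fold-down %.3g (amplification %.3g, n_coop = %g)\n",
                x$predicted$FC_i, x$predicted$amplification, x$n_coop))
  }
  obs <- x$observed[!is.na(x$observed$fold_down), ]
  if (nrow(obs) > 0) {
    cat("  observed fold-downs: ",
        paste(sprintf("%s=%.3g", obs$subrole, obs$fold_down),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Scan steady-state fold changes over knockdown levels
#'
#' @param params A [network_params()] object.
#' @param f_values Knockdown factors in (0, 1].
#' @return The [knockdown_foldchange()] tibble over `f_values`.
#' @export
knockdown_scan <- function(params = network_params(n_coop = 2),
                           f_values = seq(0.1, 1, by = 0.1)) {
  knockdown_foldchange(params, f_values)
}

#' Default pipeline configuration
#'
#' @return A nested list with per-module sections (`network`, `counts`,
#'   `de`) and the stage list, suitable for [write_run_config()].
#' @export
default_run_config <- function() {
  list(
    stages = c("generate-counts", "run-de", "compare"),
    network = unclass(network_params(n_coop = 2)),
    counts = list(preset = "fig5c", n_per_group = 3, alpha = 0.05,
                  n_background = 2000),
    de = list(shrink_weight = 0.3, pseudocount = 0.5,
              lfc_threshold = 1, sig_level = 0.05)
  )
}

#' Read and validate a pipeline configuration file
#'
#' Unknown top-level keys or unknown keys inside a known section are
#' rejected by name; the configuration round-trips losslessly through
#' [write_run_config()].
#'
#' @param path YAML file path.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ref <- default_run_config()
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (sec in intersect(names(cfg), c("network", "counts", "de"))) {
    bad <- setdiff(names(cfg[[sec]]), names(ref[[sec]]))
    if (length(bad) > 0) {
      stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  utils::modifyList(ref, cfg)
}

#' Write a pipeline configuration file
#'
#' @param config A configuration list (see [default_run_config()]).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full synthetic pipeline: counts, DE, summaries, model check
#'
#' Chains panel construction, count generation, the DE stage, the
#' pathway and regulator summaries, and the model-versus-DE comparison,
#' under one seed. With `out_dir` set, every table is written as
#' delimited text together with the effective configuration, the seed,
#' and a manifest of MD5 checksums; identical configuration and seed give
#' identical manifests.
#'
#' @param seed Integer seed (required; the only source of randomness).
#' @param config Configuration list, default [default_run_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A list of class `pipeline_run`: `panel`, `counts`, `de`,
#'   `pathway`, `regulators`, `comparison`, `manifest` (tibble of `file`,
#'   `md5`; empty when nothing is written), `seed`, `config`.
#' @export
run_full_pipeline <- function(seed, config = default_run_config(),
                              out_dir = NULL) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  cc <- config$counts
  preset <- switch(cc$preset,
                   fig5c = effect_preset_fig5c(),
                   null = effect_preset_null(),
                   stop("unknown counts preset: ", cc$preset, call. = FALSE))
  panel <- build_panel(preset, n_background = cc$n_background)
  cm <- generate_counts(panel, n_per_group = cc$n_per_group,
                        alpha = cc$alpha, seed = seed)
  de <- run_de(cm, shrink_weight = config$de$shrink_weight,
               pseudocount = config$de$pseudocount,
               lfc_threshold = config$de$lfc_threshold,
               sig_level = config$de$sig_level)
  pathway <- pathway_summary(de, panel)
  regs <- regulator_table(de, panel)
  net <- do.call(network_params, config$network)
  comparison <- compare_model_to_de(regs, params = net)

  manifest <- tibble::tibble(file = character(0), md5 = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- write_count_matrix(cm, out_dir)
    p_de <- file.path(out_dir, "de_result.csv")
    write_de_result(de, p_de)
    p_pw <- file.path(out_dir, "pathway_summary.csv")
    utils::write.csv(as.data.frame(pathway), p_pw, row.names = FALSE)
    p_reg <- file.path(out_dir, "regulator_table.csv")
    utils::write.csv(as.data.frame(regs), p_reg, row.names = FALSE)
    p_cfg <- file.path(out_dir, "run_config.yaml")
    write_run_config(c(config, list(seed = seed)), p_cfg)
    files <- c(unname(paths), p_de, p_pw, p_reg, p_cfg)
    manifest <- tibble::tibble(file = basename(files),
                               md5 = unname(tools::md5sum(files)))
    utils::write.csv(as.data.frame(manifest),
                     file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  structure(
    list(panel = panel, counts = cm, de = de, pathway = pathway,
         regulators = regs, comparison = comparison, manifest = manifest,
         seed = seed, config = config),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> seed %d, preset %s\n", x$seed,
              x$config$counts$preset))
  g <- glance(x$de)
  cat(sprintf("  %d genes, %d significant (%d down, %d up)\n",
              g$n_genes, g$n_significant, g$n_sig_down, g$n_sig_up))
  print(x$comparison)
  invisible(x)
}
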