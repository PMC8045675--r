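#' Effect-size preset for the wild-type versus RNAi petal experiment
#'
#' True fold changes planted in the synthetic count matrix, structured
#' after the knockdown response of the anthocyanin network: the targeted
#' R2R3 MYB activator is 3-fold down, its bHLH and WD40 partners 2.5-fold
#' down (midpoint of the observed two- to threefold range), and the two R3
#' MYB repressor homeologs collapse 19- and 29-fold — the signature
#' amplification of the activator-inhibitor feedback. Late biosynthetic
#' genes (DFR, ANS, UF3GT) are coordinately down (default 4-fold); early
#' biosynthetic genes (CHS, CHI, F3H) get a mix of up, down, and no
#' change. The assignment of 19 versus 29 to the two repressor copies is
#' arbitrary. LBG/EBG folds are qualitative choices, not measured values.
#'
#' @param regulator_folds Named fold-downs for the six regulator subroles.
#' @param lbg_fold Fold-down applied to every LBG copy.
#' @param ebg_folds Linear fold *changes* cycled across the copies of each
#'   EBG class (values > 1 are up-regulated).
#' @return An `effect_preset` list.
#' @export
effect_preset_fig5c <- function(regulator_folds = c(MYB5a = 3, bHLH1 = 2.5,
                                                    bHLH2 = 2.5, WD40a = 2.5,
                                                    RTO1 = 19, RTO2 = 29),
                                lbg_fold = 4,
                                ebg_folds = c(1.5, 1 / 1.5, 1)) {
  stopifnot(all(regulator_folds > 0), lbg_fold > 0, all(ebg_folds > 0))
  need <- c("MYB5a", "bHLH1", "bHLH2", "WD40a", "RTO1", "RTO2")
  if (!setequal(names(regulator_folds), need)) {
    stop("regulator_folds must name exactly: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(list(regulator_folds = regulator_folds, lbg_fold = lbg_fold,
                 ebg_folds = ebg_folds, name = "fig5c"),
            class = "effect_preset")
}

#' Null effect preset (no differential expression)
#'
#' All true fold changes equal 1; used for FDR-control simulations.
#' @return An `effect_preset` list.
#' @export
effect_preset_null <- function() {
  structure(list(regulator_folds = c(MYB5a = 1, bHLH1 = 1, bHLH2 = 1,
                                     WD40a = 1, RTO1 = 1, RTO2 = 1),
                 lbg_fold = 1, ebg_folds = 1, name = "null"),
            class = "effect_preset")
}

#' Build the gene panel for synthetic count generation
#'
#' Assembles a tibble of genes with roles (regulator, EBG, LBG,
#' background), per-copy true fold changes from an effect preset, gene
#' lengths, and baseline expression. The default enzyme panel has 30
#' genes across the six core cyanidin-pathway enzyme classes, with the
#' early classes enriched in copy number beyond the two homeologs
#' expected in a tetraploid (CHS 7, CHI 6, F3H 5, DFR 4, ANS 4, UF3GT 4 —
#' only the total of 30 and the EBG enrichment are constrained; the split
#' is a documented choice). Baselines and lengths are drawn with the
#' panel's own seed, so the panel is deterministic given its
#' configuration.
#'
#' @param preset An `effect_preset` (default [effect_preset_fig5c()]).
#' @param enzyme_copies Named copy numbers of the six enzyme classes.
#' @param n_background Number of null background genes (default 2000).
#' @param named_baseline Log-normal median of baseline expression for
#'   named (regulator/enzyme) genes, in expected counts at unit depth.
#' @param background_baseline_range Log-uniform range of background
#'   baselines.
#' @param length_range Uniform range of gene lengths in bases.
#' @param seed Integer seed for baseline/length draws.
#' @return A tibble of class `gene_panel`: `gene_id`, `role`, `subrole`,
#'   `copy`, `length`, `baseline`, `true_fc` (RNAi/wild-type mean ratio),
#'   `fold_down` (wild-type/RNAi, the scale fold-downs are reported on).
#' @export
build_panel <- function(preset = effect_preset_fig5c(),
                        enzyme_copies = c(CHS = 7, CHI = 6, F3H = 5,
                                          DFR = 4, ANS = 4, UF3GT = 4),
                        n_background = 2000,
                        named_baseline = 1000,
                        background_baseline_range = c(10, 1000),
                        length_range = c(500, 5000),
                        seed = 1234) {
  stopifnot(inherits(preset, "effect_preset"),
            all(enzyme_copies >= 1), n_background >= 0,
            named_baseline > 0, all(background_baseline_range > 0),
            all(length_range > 0))
  ebg_classes <- c("CHS", "CHI", "F3H")
  lbg_classes <- c("DFR", "ANS", "UF3GT")
  if (!setequal(names(enzyme_copies), c(ebg_classes, lbg_classes))) {
    stop("enzyme_copies must name the six classes: ",
         paste(c(ebg_classes, lbg_classes), collapse = ", "), call. = FALSE)
  }

  reg <- tibble::tibble(
    subrole = names(preset$regulator_folds),
    role = "regulator", copy = 1L,
    true_fc = unname(1 / preset$regulator_folds)
  )

  enz <- purrr::map_dfr(names(enzyme_copies), function(cl) {
    k <- enzyme_copies[[cl]]
    is_ebg <- cl %in% ebg_classes
    fc <- if (is_ebg) {
      rep_len(preset$ebg_folds, k)
    } else {
      rep(1 / preset$lbg_fold, k)
    }
    tibble::tibble(subrole = cl, role = if (is_ebg) "EBG" else "LBG",
                   copy = seq_len(k), true_fc = fc)
  })

  bg <- if (n_background > 0) {
    tibble::tibble(subrole = "background", role = "background",
                   copy = seq_len(n_background), true_fc = 1)
  } else NULL

  panel <- dplyr::bind_rows(reg, enz, bg)
  panel$gene_id <- ifelse(
    panel$role %in% c("regulator"), panel$subrole,
    ifelse(panel$role == "background",
           sprintf("bg_%04d", panel$copy),
           sprintf("%s_%d", panel$subrole, panel$copy)))

  set.seed(seed)
  n_named <- sum(panel$role != "background")
  panel$baseline <- NA_real_
  panel$baseline[panel$role != "background"] <-
    stats::rlnorm(n_named, log(named_baseline), 0.3)
  if (n_background > 0) {
    lb <- log(background_baseline_range)
    panel$baseline[panel$role == "background"] <-
      exp(stats::runif(n_background, lb[1], lb[2]))
  }
  panel$length <- round(stats::runif(nrow(panel),
                                     length_range[1], length_range[2]))
  panel$fold_down <- 1 / panel$true_fc

  out <- panel[, c("gene_id", "role", "subrole", "copy", "length",
                   "baseline", "true_fc", "fold_down")]
  class(out) <- c("gene_panel", class(out))
  out
}

#' Generate a synthetic wild-type versus RNAi count matrix
#'
#' Draws negative-binomial counts with mean
#' `mu = depth_s * baseline_g * true_fc_g^[s in rnai]` and variance
#' `mu + alpha * mu^2`; `alpha = 0` degenerates to Poisson. This emulates
#' the downstream product of a small-replicate petal RNA-seq experiment
#' (3 wild-type versus 3 RNAi libraries by default) without any read-level
#' simulation.
#'
#' @param panel A `gene_panel` from [build_panel()].
#' @param n_per_group Replicates per group (>= 2; default 3).
#' @param depths Per-sample depth factors (length `2 * n_per_group`), or
#'   `NULL` to draw them log-normally around 1 (sdlog 0.1).
#' @param alpha Negative-binomial dispersion (>= 0; default 0.05).
#' @param seed Integer seed (required).
#' @return A `count_matrix` object: list with integer matrix `counts`
#'   (genes x samples), tibble `samples` (`sample`, `group`, `depth`),
#'   the `panel`, and the generator settings.
#' @export
generate_counts <- function(panel, n_per_group = 3, depths = NULL,
                            alpha = 0.05, seed) {
  stopifnot(inherits(panel, "gene_panel"), n_per_group >= 2, alpha >= 0)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n_s <- 2L * n_per_group
  set.seed(seed)
  if (is.null(depths)) {
    depths <- stats::rlnorm(n_s, 0, 0.1)
  }
  stopifnot(length(depths) == n_s, all(depths > 0))
  groups <- rep(c("wild_type", "rnai"), each = n_per_group)
  sample_ids <- paste0(rep(c("wt", "rnai"), each = n_per_group),
                       rep(seq_len(n_per_group), 2))

  fc_exp <- outer(panel$true_fc, as.integer(groups == "rnai"), `^`)
  mu <- panel$baseline * fc_exp * rep(depths, each = nrow(panel))
  if (any(mu > 1e12)) {
    stop("expected counts exceed 1e12; reduce baselines or depths",
         call. = FALSE)
  }
  counts <- if (alpha == 0) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
  }
  counts <- matrix(as.integer(counts), nrow = nrow(panel),
                   dimnames = list(panel$gene_id, sample_ids))
  structure(
    list(counts = counts,
         samples = tibble::tibble(sample = sample_ids, group = groups,
                                  depth = depths),
         panel = panel, alpha = alpha, seed = seed),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%s), alpha = %g, seed %d\n",
              nrow(x$counts), ncol(x$counts),
              paste(table(x$samples$group), collapse = " vs "),
              x$alpha, x$seed))
  invisible(x)
}

#' Coerce a count matrix to a long tibble
#'
#' @param x A `count_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample`, `group`, `count`.
#' @method as_tibble count_matrix
#' @export
as_tibble.count_matrix <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(rownames(x$counts), times = ncol(x$counts)),
    sample = rep(colnames(x$counts), each = nrow(x$counts)),
    group = rep(x$samples$group, each = nrow(x$counts)),
    count = as.vector(x$counts)
  )
}

#' Write a count matrix and its companions as delimited text
#'
#' Writes the counts as TSV (first column `gene_id`, header row of sample
#' ids), the sample-group table and the panel truth table as CSV.
#'
#' @param cm A `count_matrix`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"counts"`).
#' @return Named character vector of written paths, invisibly.
#' @export
write_count_matrix <- function(cm, dir, prefix = "counts") {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_counts <- file.path(dir, paste0(prefix, ".tsv"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  utils::write.table(df, p_counts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_groups <- file.path(dir, paste0(prefix, "_groups.csv"))
  utils::write.csv(as.data.frame(cm$samples), p_groups, row.names = FALSE)
  p_panel <- file.path(dir, paste0(prefix, "_panel.csv"))
  utils::write.csv(as.data.frame(cm$panel), p_panel, row.names = FALSE)
  invisible(c(counts = p_counts, groups = p_groups, panel = p_panel))
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' Also accepts user-supplied equivalents: a TSV whose first column is the
#' gene id and whose remaining columns are integer counts, plus a CSV with
#' `sample` and `group` columns.
#'
#' @param counts_path Path to the counts TSV.
#' @param groups_path Path to the sample-group CSV.
#' @param panel_path Optional path to a panel truth CSV.
#' @return A `count_matrix` object (panel `NULL` when not supplied).
#' @export
read_count_matrix <- function(counts_path, groups_path, panel_path = NULL) {
  df <- utils::read.delim(counts_path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df[[1]]
  samples <- tibble::as_tibble(utils::read.csv(groups_path))
  if (!all(c("sample", "group") %in% names(samples))) {
    stop("groups file must have `sample` and `group` columns", call. = FALSE)
  }
  samples <- samples[match(colnames(counts), samples$sample), ]
  if (anyNA(samples$sample)) {
    stop("sample ids in groups file do not match count columns",
         call. = FALSE)
  }
  panel <- NULL
  if (!is.null(panel_path)) {
    panel <- tibble::as_tibble(utils::read.csv(panel_path))
    class(panel) <- c("gene_panel", class(panel))
  }
  structure(list(counts = counts, samples = samples, panel = panel,
                 alpha = NA_real_, seed = NA_integer_),
            class = "count_matrix")
}
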