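#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across genes of the
#' ratio of its count to the gene's geometric mean over samples, computed
#' on genes with nonzero counts in every sample and rescaled to unit
#' geometric mean. When no gene is nonzero everywhere, falls back to
#' total-count ratios with a warning. Size factors are scale-equivariant:
#' multiplying one sample's counts by `c` multiplies its factor by `c`.
#'
#' @param counts A `count_matrix` or an integer matrix (genes x samples).
#' @return A named numeric vector of positive per-sample factors with
#'   unit geometric mean.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  stopifnot(is.matrix(m), all(m >= 0))
  keep <- rowSums(m == 0) == 0
  if (!any(keep)) {
    warning("no gene has nonzero counts in all samples; ",
            "falling back to total-count ratios")
    sf <- colSums(m)
    sf <- sf / exp(mean(log(sf)))
    return(sf)
  }
  lm_ <- log(m[keep, , drop = FALSE])
  gm <- rowMeans(lm_)
  sf <- apply(lm_, 2, function(col) exp(stats::median(col - gm)))
  sf / exp(mean(log(sf)))
}

#' Per-gene negative-binomial dispersion with shrinkage
#'
#' Method-of-moments dispersion on size-factor-normalized counts, pooled
#' over groups (each contributing `n_g - 1` degrees of freedom), then
#' shrunk toward the panel-wide mean dispersion with a fixed weight —
#' small-replicate designs cannot estimate a per-gene dispersion stably,
#' and shrinking toward the ensemble mean reduces false positives. The
#' raw estimate solves `var = mean + alpha * mean^2` and is floored at 0.
#'
#' @param counts A `count_matrix` or integer matrix.
#' @param groups Group labels per sample (two levels, each with >= 2
#'   samples); taken from the object when a `count_matrix` is given.
#' @param sf Size factors, default [size_factors()] of `counts`.
#' @param shrink_weight Weight on the panel mean (default 0.3).
#' @return A tibble: `gene_id`, `alpha_raw`, `alpha_shrunk`. All-zero
#'   genes get `NA` (they are excluded from testing).
#' @export
estimate_dispersion <- function(counts, groups = NULL, sf = NULL,
                                shrink_weight = 0.3) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (is.null(groups) && inherits(counts, "count_matrix")) {
    groups <- counts$samples$group
  }
  stopifnot(is.matrix(m), length(groups) == ncol(m),
            shrink_weight >= 0, shrink_weight <= 1)
  tab <- table(groups)
  if (length(tab) != 2 || any(tab < 2)) {
    stop("need two groups with >= 2 samples each; got ",
         paste(names(tab), tab, sep = "=", collapse = ", "), call. = FALSE)
  }
  if (is.null(sf)) sf <- size_factors(m)
  y <- sweep(m, 2, sf, `/`)

  lv <- levels(factor(groups))
  num <- matrix(0, nrow(m), 2)  # (var - mean) * df,  mean^2 * df
  den <- matrix(0, nrow(m), 2)
  alpha_raw <- rep(0, nrow(m))
  wnum <- rep(0, nrow(m)); wden <- rep(0, nrow(m))
  for (g in lv) {
    yg <- y[, groups == g, drop = FALSE]
    ng <- ncol(yg)
    mg <- rowMeans(yg)
    vg <- apply(yg, 1, stats::var)
    ok <- mg > 0
    wnum[ok] <- wnum[ok] + (vg[ok] - mg[ok]) * (ng - 1)
    wden[ok] <- wden[ok] + mg[ok]^2 * (ng - 1)
  }
  alpha_raw <- ifelse(wden > 0, pmax(wnum / wden, 0), NA_real_)
  all_zero <- rowSums(m) == 0
  alpha_raw[all_zero] <- NA_real_
  panel_mean <- mean(alpha_raw, na.rm = TRUE)
  alpha_shrunk <- (1 - shrink_weight) * alpha_raw + shrink_weight * panel_mean
  tibble::tibble(gene_id = rownames(m) %||% as.character(seq_len(nrow(m))),
                 alpha_raw = alpha_raw, alpha_shrunk = alpha_shrunk)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wald tests for differential expression between two groups
#'
#' Estimates the log2 fold change (RNAi versus wild type) as the log
#' ratio of size-factor-normalized group means with a pseudocount, with a
#' delta-method standard error from the negative-binomial variance
#' `mu + alpha mu^2`, a standard-normal reference for the Wald statistic,
#' Benjamini-Hochberg adjustment, and the significance rule
#' `|log2FC| >= lfc_threshold` and `padj < sig_level`.
#'
#' @param counts A `count_matrix` or integer matrix.
#' @param groups Group labels (`"wild_type"`/`"rnai"`, or any two levels
#'   with the reference given by `reference`).
#' @param sf Size factors; computed when `NULL`.
#' @param alphas Per-gene dispersions (vector or the tibble from
#'   [estimate_dispersion()], using `alpha_shrunk`); estimated when
#'   `NULL`.
#' @param reference Reference (denominator) group, default `"wild_type"`.
#' @param pseudocount Added to both normalized group means before the log
#'   ratio whenever either mean falls below it (default 0.5). Well-covered
#'   genes use the pure ratio, which keeps log2 fold changes exactly
#'   invariant to rescaling any sample's column; the pseudocount only
#'   guards the zero/near-zero case.
#' @param lfc_threshold,sig_level Significance rule defaults: absolute
#'   log2 fold change at least 1 and BH-adjusted p below 0.05.
#' @return A `de_result` tibble: `gene_id`, `base_mean`, `log2fc`, `se`,
#'   `stat`, `p_value`, `padj`, `significant`. All-zero genes and genes
#'   with degenerate (zero) standard error get `NA` p-values and are
#'   never called significant.
#' @export
wald_test <- function(counts, groups = NULL, sf = NULL, alphas = NULL,
                      reference = "wild_type", pseudocount = 0.5,
                      lfc_threshold = 1, sig_level = 0.05) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (is.null(groups) && inherits(counts, "count_matrix")) {
    groups <- counts$samples$group
  }
  stopifnot(is.matrix(m), length(groups) == ncol(m))
  if (!reference %in% groups) {
    stop("reference group '", reference, "' not present", call. = FALSE)
  }
  if (is.null(sf)) sf <- size_factors(m)
  if (is.null(alphas)) alphas <- estimate_dispersion(m, groups, sf)
  if (is.data.frame(alphas)) alphas <- alphas$alpha_shrunk
  stopifnot(length(alphas) == nrow(m))

  y <- sweep(m, 2, sf, `/`)
  other <- setdiff(unique(groups), reference)
  if (length(other) != 1) stop("need exactly two groups", call. = FALSE)
  y_ref <- y[, groups == reference, drop = FALSE]
  y_alt <- y[, groups == other, drop = FALSE]
  n_ref <- ncol(y_ref); n_alt <- ncol(y_alt)
  m_ref <- rowMeans(y_ref); m_alt <- rowMeans(y_alt)

  pc <- ifelse(pmin(m_ref, m_alt) < pseudocount, pseudocount, 0)
  log2fc <- log2((m_alt + pc) / (m_ref + pc))
  # delta method: var(log2 mean) = var(mean) / ((mean + pc) ln2)^2,
  # var(mean) = (mu + alpha mu^2) / n at the group mean
  v_ref <- (m_ref + alphas * m_ref^2) / n_ref
  v_alt <- (m_alt + alphas * m_alt^2) / n_alt
  se <- sqrt(v_ref / (m_ref + pc)^2 +
               v_alt / (m_alt + pc)^2) / log(2)

  stat <- ifelse(se > 0, log2fc / se, NA_real_)
  p <- 2 * stats::pnorm(-abs(stat))
  all_zero <- rowSums(m) == 0
  p[all_zero | is.na(alphas)] <- NA_real_
  padj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  padj[ok] <- stats::p.adjust(p[ok], method = "BH")
  sig <- !is.na(padj) & abs(log2fc) >= lfc_threshold & padj < sig_level

  out <- tibble::tibble(
    gene_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    base_mean = rowMeans(y), log2fc = log2fc, se = se, stat = stat,
    p_value = p, padj = padj, significant = sig
  )
  class(out) <- c("de_result", class(out))
  attr(out, "lfc_threshold") <- lfc_threshold
  attr(out, "sig_level") <- sig_level
  out
}

#' Run the full differential-expression stage
#'
#' Convenience wrapper chaining [size_factors()],
#' [estimate_dispersion()] and [wald_test()] on a `count_matrix` or a
#' matrix plus group labels.
#'
#' @inheritParams wald_test
#' @param shrink_weight Passed to [estimate_dispersion()].
#' @param ... Passed to [wald_test()].
#' @return A `de_result` tibble (see [wald_test()]).
#' @export
run_de <- function(counts, groups = NULL, shrink_weight = 0.3, ...) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (is.null(groups) && inherits(counts, "count_matrix")) {
    groups <- counts$samples$group
  }
  sf <- size_factors(m)
  disp <- estimate_dispersion(m, groups, sf, shrink_weight = shrink_weight)
  wald_test(m, groups, sf = sf, alphas = disp, ...)
}

#' Tidy a DE result (identity; columns are already one row per gene)
#' @param x A `de_result`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "de_result")
  out
}

#' One-row summary of a DE result
#' @param x A `de_result`.
#' @param ... Unused.
#' @return A one-row tibble: gene counts, significant up/down counts and
#'   the thresholds used.
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x), n_tested = sum(!is.na(x$p_value)),
    n_significant = sum(x$significant),
    n_sig_down = sum(x$significant & x$log2fc < 0),
    n_sig_up = sum(x$significant & x$log2fc > 0),
    lfc_threshold = attr(x, "lfc_threshold"),
    sig_level = attr(x, "sig_level")
  )
}

#' Volcano plot of a DE result
#'
#' @param object A `de_result`.
#' @param ... Unused.
#' @return A ggplot of log2 fold change against -log10 adjusted p, with
#'   significant genes highlighted.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$padj), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(pmax(.data$padj, 1e-300)),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "purple3")) +
    ggplot2::labs(x = "log2 fold change (RNAi vs wild type)",
                  y = "-log10 adjusted p", colour = "significant")
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count * 1e9 / (length_bases * total counts of the sample)`.
#'
#' @param counts A `count_matrix` or integer matrix.
#' @param gene_lengths Gene lengths in bases (> 0); taken from the panel
#'   when a `count_matrix` with a panel is given.
#' @return A numeric matrix of the same shape as the counts.
#' @export
rpkm <- function(counts, gene_lengths = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (is.null(gene_lengths) && inherits(counts, "count_matrix") &&
      !is.null(counts$panel)) {
    gene_lengths <- counts$panel$length
  }
  stopifnot(is.matrix(m), length(gene_lengths) == nrow(m),
            all(gene_lengths > 0))
  depth <- colSums(m)
  if (any(depth == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(m)[depth == 0], collapse = ", "), call. = FALSE)
  }
  sweep(m * 1e9 / gene_lengths, 2, depth, `/`)
}

#' Per-enzyme-class response summary (EBG/LBG dichotomy)
#'
#' Tallies significant up/down calls per enzyme class and calls each
#' class either coordinately down (every copy significantly down — the
#' LBG signature under activator knockdown) or mixed (the EBG signature).
#'
#' @param de A `de_result`.
#' @param panel A `gene_panel` mapping genes to enzyme classes.
#' @return A tibble: `subrole` (enzyme class), `role`, `copies_tested`,
#'   `copies_down`, `copies_up`, `all_copies_down`, `dichotomy_call`
#'   (`"LBG-like coordinate-down"` or `"EBG-like mixed"`).
#' @export
pathway_summary <- function(de, panel) {
  stopifnot(inherits(de, "de_result"), inherits(panel, "gene_panel"))
  classes <- c("CHS", "CHI", "F3H", "DFR", "ANS", "UF3GT")
  enz <- panel[panel$subrole %in% classes, c("gene_id", "role", "subrole")]
  missing <- setdiff(classes, unique(enz$subrole))
  if (length(missing) > 0) {
    warning("enzyme class(es) absent from panel: ",
            paste(missing, collapse = ", "))
  }
  d <- dplyr::inner_join(enz, tidy(de), by = "gene_id")
  out <- d |>
    dplyr::group_by(.data$subrole, .data$role) |>
    dplyr::summarise(
      copies_tested = dplyr::n(),
      copies_down = sum(.data$significant & .data$log2fc < 0),
      copies_up = sum(.data$significant & .data$log2fc > 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      all_copies_down = .data$copies_down == .data$copies_tested,
      dichotomy_call = ifelse(.data$all_copies_down,
                              "LBG-like coordinate-down", "EBG-like mixed")
    )
  out$subrole <- factor(out$subrole,
                        levels = intersect(classes, out$subrole))
  dplyr::arrange(out, .data$subrole)
}

#' Regulator fold-change table
#'
#' Extracts the six regulator subroles from a DE result and reports the
#' estimated linear fold-down (wild type over RNAi; values below 1 mean
#' up-regulation) with the adjusted p-value. Subroles missing from the DE
#' table get `NA` rows.
#'
#' @param de A `de_result`.
#' @param panel A `gene_panel`.
#' @return A tibble: `subrole`, `gene_id`, `log2fc`, `fold_down`
#'   (`2^-log2fc`), `padj`, `significant`, `true_fold_down` (from the
#'   panel, for recovery checks).
#' @export
regulator_table <- function(de, panel) {
  stopifnot(inherits(de, "de_result"), inherits(panel, "gene_panel"))
  subroles <- c("MYB5a", "bHLH1", "bHLH2", "WD40a", "RTO1", "RTO2")
  reg <- panel[panel$role == "regulator", ]
  base <- tibble::tibble(subrole = subroles)
  d <- dplyr::left_join(base, reg[, c("subrole", "gene_id", "fold_down")],
                        by = "subrole")
  d <- dplyr::left_join(d, tidy(de)[, c("gene_id", "log2fc", "padj",
                                        "significant")],
                        by = "gene_id")
  tibble::tibble(
    subrole = d$subrole, gene_id = d$gene_id, log2fc = d$log2fc,
    fold_down = 2^(-d$log2fc), padj = d$padj,
    significant = d$significant, true_fold_down = d$fold_down
  )
}

#' Exact binomial test of a Mendelian segregation ratio
#'
#' For `n_offspring` plants of which `n_dominant` show the dominant
#' phenotype, computes the binomial pmf under a hypothesized `r:1` ratio
#' (success probability `r / (r + 1)`), the modal count, and the exact
#' two-sided p-value by the minimum-likelihood convention (sum of
#' probabilities of all outcomes at most as likely as the observed one,
#' with the same relative tolerance used by [stats::binom.test()]).
#'
#' @param n_offspring Number of offspring scored (>= 1).
#' @param n_dominant Observed dominant-phenotype count.
#' @param ratio Hypothesized ratio `r` in `r:1` (default 3).
#' @return A `segregation_test` list: `pmf` (tibble `k`, `prob`),
#'   `modal_count`, `p_value`, `expected`, plus the inputs. `tidy()`
#'   returns the pmf; `glance()` the one-row summary.
#' @examples
#' segregation_binomial(8, 6, ratio = 3)  # 6 of 8 is the modal outcome
#' @export
segregation_binomial <- function(n_offspring, n_dominant, ratio = 3) {
  stopifnot(n_offspring >= 1, n_dominant >= 0, n_dominant <= n_offspring)
  if (!is.numeric(ratio) || length(ratio) != 1 || !is.finite(ratio) ||
      ratio <= 0) {
    stop("ratio must be a single positive number r (for r:1)",
         call. = FALSE)
  }
  pr <- ratio / (ratio + 1)
  k <- 0:n_offspring
  pmf <- stats::dbinom(k, n_offspring, pr)
  obs <- pmf[n_dominant + 1]
  p <- sum(pmf[pmf <= obs * (1 + 1e-7)])
  structure(
    list(pmf = tibble::tibble(k = k, prob = pmf),
         modal_count = k[which.max(pmf)],
         p_value = min(p, 1),
         expected = n_offspring * pr,
         n_offspring = n_offspring, n_dominant = n_dominant,
         ratio = ratio),
    class = "segregation_test"
  )
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf("<segregation_test> %d of %d dominant under %g:1 (expected %.2f)\n",
              x$n_dominant, x$n_offspring, x$ratio, x$expected))
  cat(sprintf("  modal count %d, exact two-sided p = %.4g\n",
              x$modal_count, x$p_value))
  invisible(x)
}

#' @param x A `segregation_test`.
#' @param ... Unused.
#' @rdname segregation_binomial
#' @method tidy segregation_test
#' @export
tidy.segregation_test <- function(x, ...) x$pmf

#' @rdname segregation_binomial
#' @method glance segregation_test
#' @export
glance.segregation_test <- function(x, ...) {
  tibble::tibble(n_offspring = x$n_offspring, n_dominant = x$n_dominant,
                 ratio = x$ratio, expected = x$expected,
                 modal_count = x$modal_count, p_value = x$p_value)
}

#' Write a DE result as a comma-separated table
#'
#' @param de A `de_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(de, path) {
  utils::write.csv(as.data.frame(tidy(de)), path, row.names = FALSE)
  invisible(path)
}
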