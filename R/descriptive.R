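#' Lesion-versus-pancreas feature testing (volcano statistics)
#'
#' Per feature: a two-sided Mann-Whitney U test between the lesion and
#' pancreas columns (unpaired; a paired Wilcoxon signed-rank variant is
#' available behind `paired = TRUE`), Cohen's d with the pancreas-mean minus
#' lesion-mean sign convention (pooled SD, n1 + n2 - 2 denominator), and
#' BH-FDR across all tested features. Features lesions score higher on thus
#' get negative d.
#'
#' @param lesion,pancreas Feature tables (one row per patient).
#' @param features Feature columns to test (default: shared feature
#'   columns; features missing in one table are skipped with a warning).
#' @param paired Use the paired signed-rank test instead (default FALSE).
#' @param alpha FDR significance threshold (default 0.05).
#' @return Tibble: `feature`, `cohens_d`, `p`, `q`, `significant`.
#' @export
lesion_vs_pancreas <- function(lesion, pancreas, features = NULL,
                               paired = FALSE, alpha = 0.05) {
  fl <- feature_columns(lesion); fp <- feature_columns(pancreas)
  if (is.null(features)) features <- union(fl, fp)
  missing <- features[!(features %in% fl & features %in% fp)]
  if (length(missing) > 0) {
    warning(sprintf("feature(s) missing in one table, skipped: %s",
                    paste(missing, collapse = ", ")), call. = FALSE)
    features <- setdiff(features, missing)
  }
  rows <- lapply(features, function(f) {
    x <- lesion[[f]]; yv <- pancreas[[f]]
    x <- x[!is.na(x)]; yv <- yv[!is.na(yv)]
    n1 <- length(x); n2 <- length(yv)
    sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(yv)) /
                 (n1 + n2 - 2))
    d <- if (sp > 0) (mean(yv) - mean(x)) / sp else 0
    p <- suppressWarnings(
      if (paired) {
        stats::wilcox.test(lesion[[f]], pancreas[[f]], paired = TRUE,
                           exact = FALSE)$p.value
      } else {
        stats::wilcox.test(x, yv, exact = FALSE)$p.value
      }
    )
    if (is.na(p)) p <- 1  # all-tied comparison
    tibble::tibble(feature = f, cohens_d = d, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  out
}

#' Radiomic-clinical Spearman correlation map
#'
#' Spearman rank correlation (average ranks for ties) of every feature x
#' clinical-variable pair, with BH-FDR control across the full grid. Cells
#' with a constant column or fewer than `min_pairs` complete pairs are
#' flagged rather than raising an error.
#'
#' @param features Feature table (one row per patient).
#' @param clinical Tibble of clinical variables aligned on `patient_id`.
#' @param feature_cols,clinical_cols Column selections (defaults: all
#'   numeric feature / clinical columns).
#' @param min_pairs Minimum complete pairs per cell (default 5).
#' @param alpha FDR threshold (default 0.05).
#' @return Tibble: `feature`, `clinical_var`, `rho`, `p`, `q`,
#'   `significant`, `degenerate`.
#' @export
radiomic_clinical_correlations <- function(features, clinical,
                                           feature_cols = NULL,
                                           clinical_cols = NULL,
                                           min_pairs = 5, alpha = 0.05) {
  if (is.null(feature_cols)) feature_cols <- feature_columns(features)
  if (is.null(clinical_cols)) {
    clinical_cols <- setdiff(
      names(clinical)[vapply(clinical, is.numeric, logical(1))], "patient_id")
  }
  d <- dplyr::inner_join(features, clinical, by = "patient_id",
                         suffix = c("", ".clin"))
  grid <- expand.grid(feature = feature_cols, clinical_var = clinical_cols,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    x <- d[[grid$feature[r]]]; yv <- d[[grid$clinical_var[r]]]
    ok <- !is.na(x) & !is.na(yv)
    degenerate <- sum(ok) < min_pairs ||
      length(unique(x[ok])) < 2 || length(unique(yv[ok])) < 2
    if (degenerate) {
      return(tibble::tibble(feature = grid$feature[r],
                            clinical_var = grid$clinical_var[r],
                            rho = NA_real_, p = NA_real_, degenerate = TRUE))
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], yv[ok], method = "spearman", exact = FALSE)
    )
    tibble::tibble(feature = grid$feature[r],
                   clinical_var = grid$clinical_var[r],
                   rho = unname(ct$estimate), p = ct$p.value,
                   degenerate = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$q) & out$q < alpha
  out[, c("feature", "clinical_var", "rho", "p", "q", "significant",
          "degenerate")]
}

#' Nonparametric group comparison
#'
#' Two groups: two-sided Mann-Whitney U; three or more: Kruskal-Wallis.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @return The p-value.
#' @export
group_comparisons <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok], exclude = NULL)
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2 || any(table(groups) == 0)) {
    stop("need >= 2 nonempty groups", call. = FALSE)
  }
  if (k == 2) {
    p <- suppressWarnings(stats::wilcox.test(values ~ groups,
                                             exact = FALSE)$p.value)
  } else {
    p <- suppressWarnings(stats::kruskal.test(values, groups)$p.value)
  }
  if (is.na(p)) p <- 1  # fully tied data
  p
}

#' Volcano plot of lesion-versus-pancreas statistics
#'
#' @param volcano Result of [lesion_vs_pancreas()].
#' @return A ggplot of Cohen's d versus -log10(p), significant features
#'   highlighted.
#' @export
plot_volcano <- function(volcano) {
  ggplot2::ggplot(volcano,
                  ggplot2::aes(.data$cohens_d, -log10(.data$p),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2,
                        colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Cohen's d (pancreas - lesion)",
                  y = expression(-log[10](p)), colour = "FDR q < 0.05") +
    ggplot2::theme_minimal()
}
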