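#' Print a digenic scan summary
#'
#' @param x A `"digenic_scan"` object.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @exportS3Method base::print
print.digenic_scan <- function(x, ...) {
  cat("<digenic_scan>\n")
  funnel <- paste(sprintf("%s=%d", x$stage_counts$stage,
                          x$stage_counts$n), collapse = " > ")
  cat("  funnel:", funnel, "\n")
  n <- nrow(x$pairs)
  cat(sprintf("  %d candidate pair(s)\n", n))
  if (n > 0) {
    top <- x$pairs[1, ]
    cat(sprintf("  top: %s (%s) x %s (%s), score %.3f\n",
                top$gene_a, top$origin_a, top$gene_b, top$origin_b,
                top$score))
  }
  invisible(x)
}

#' Tidy a digenic scan into its ranked candidate pairs
#'
#' @param x A `"digenic_scan"` object.
#' @param ... Unused.
#' @return The report-shaped CandidatePair tibble (one row per pair).
#' @exportS3Method
tidy.digenic_scan <- function(x, ...) {
  report_table(x$pairs)
}

#' One-row summary of a digenic scan
#'
#' @param x A `"digenic_scan"` object.
#' @param ... Unused.
#' @return One-row tibble with the funnel counts (`n_input`,
#'   `n_autosomal`, `n_region`, `n_rarity`, `n_deleterious`,
#'   `n_shared_monoallelic`, `n_pairs`, `n_geneset`, `n_ranked`) and
#'   `top_pair`.
#' @exportS3Method
glance.digenic_scan <- function(x, ...) {
  counts <- setNames(as.list(x$stage_counts$n),
                     paste0("n_", x$stage_counts$stage))
  counts$top_pair <- if (nrow(x$pairs) > 0) {
    paste(x$pairs$gene_a[1], x$pairs$gene_b[1], sep = "-")
  } else {
    NA_character_
  }
  tibble::as_tibble(counts)
}

#' Funnel plot of a digenic scan
#'
#' Bar chart of the number of variants (then pairs) surviving each pipeline
#' stage, in stage order.
#'
#' @param object A `"digenic_scan"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.digenic_scan <- function(object, ...) {
  df <- object$stage_counts
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n,
                                   fill = .data$unit)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4,
                       size = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "surviving (log scale)",
                  title = "Digenic prioritization funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
}

#' Candidate-pair score plot
#'
#' @param scan A `"digenic_scan"` object with at least one candidate pair.
#' @return A ggplot object (ranked pairs vs score).
#' @export
plot_candidate_pairs <- function(scan) {
  stopifnot(inherits(scan, "digenic_scan"))
  df <- scan$pairs
  if (nrow(df) == 0) abort("no candidate pairs to plot")
  df$label <- paste(df$gene_a, df$gene_b, sep = " × ")
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$label, -.data$rank), y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "rank score",
                  title = "Trans digenic candidate pairs") +
    ggplot2::theme_minimal()
}

#' Print a simulated family exome summary
#'
#' @param x A `"family_sim"` object.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @exportS3Method base::print
print.family_sim <- function(x, ...) {
  cat("<family_sim>\n")
  cat(sprintf("  %d variants x %d samples (seed %d)\n",
              nrow(x$variants), nrow(x$pedigree), x$config$seed))
  if (!is.null(x$truth$gene_a)) {
    cat(sprintf("  planted pair: %s (maternal) x %s (paternal)\n",
                x$truth$gene_a, x$truth$gene_b))
  }
  invisible(x)
}

#' Tidy a simulated family exome into its variant table
#'
#' @param x A `"family_sim"` object.
#' @param ... Unused.
#' @return The variant tibble with true allele frequencies and a `planted`
#'   flag.
#' @exportS3Method
tidy.family_sim <- function(x, ...) {
  v <- x$variants
  planted <- if (!is.null(x$truth$variant_a)) {
    c(x$truth$variant_a, x$truth$variant_b)
  } else {
    character(0)
  }
  v$planted <- v$variant_id %in% planted
  v
}

#' One-row summary of a simulated family exome
#'
#' @param x A `"family_sim"` object.
#' @param ... Unused.
#' @return One-row tibble: `n_variants`, `n_samples`, `n_affected`,
#'   `planted_pair`, `seed`.
#' @exportS3Method
glance.family_sim <- function(x, ...) {
  tibble::tibble(
    n_variants = nrow(x$variants),
    n_samples = nrow(x$pedigree),
    n_affected = sum(x$pedigree$affected),
    planted_pair = if (!is.null(x$truth$gene_a)) {
      paste(x$truth$gene_a, x$truth$gene_b, sep = "-")
    } else {
      NA_character_
    },
    seed = x$config$seed
  )
}

#' Allele-frequency spectrum plot of a simulation
#'
#' Histogram of the true background allele frequencies (log10 scale) with
#' the planted variants marked; visualizes what the rarity filter operates
#' on.
#'
#' @param object A `"family_sim"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.family_sim <- function(object, ...) {
  v <- tidy.family_sim(object)
  p <- ggplot2::ggplot(v[!v$planted, ],
                       ggplot2::aes(x = .data$af)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "true allele frequency (log10)", y = "variants",
                  title = "Simulated allele-frequency spectrum") +
    ggplot2::theme_minimal()
  if (any(v$planted)) {
    p <- p + ggplot2::geom_vline(
      data = v[v$planted, ],
      ggplot2::aes(xintercept = .data$af),
      colour = "firebrick", linetype = "dashed")
  }
  p
}
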