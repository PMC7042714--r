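#' Plot peptide traces of one protein
#'
#' Peptide-level elution chromatograms, one line per peptide, faceted by
#' condition and replicate.
#'
#' @param traces A [sec_traces()] object.
#' @param protein Protein id to plot.
#' @return A ggplot object.
#' @export
plot_protein_traces <- function(traces, protein) {
  sel <- traces[traces$protein_id == protein, ]
  if (nrow(sel) == 0) abort(paste0("no traces for protein '", protein, "'"))
  long <- traces_to_long(sel)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$fraction, y = .data$intensity,
    colour = .data$peptide_id, group = .data$peptide_id
  )) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$replicate),
      cols = ggplot2::vars(.data$condition)
    ) +
    ggplot2::labs(x = "SEC fraction", y = "MS intensity", title = protein) +
    ggplot2::theme_minimal()
}

#' Plot protein-level elution profiles
#'
#' Replicate-mean top-2 protein chromatograms per condition, optionally with
#' detected feature ranges shaded.
#'
#' @param protein_traces A [protein_quant_top2()] result.
#' @param protein Protein id.
#' @param features Optional `sec_features` tibble; this protein's feature
#'   ranges are shaded.
#' @return A ggplot object.
#' @export
plot_protein_profile <- function(protein_traces, protein, features = NULL) {
  sel <- protein_traces[protein_traces$protein_id == protein, ]
  if (nrow(sel) == 0) abort(paste0("no profile for protein '", protein, "'"))
  m <- rowsum(sel$intensity, sel$condition)
  cnt <- rowsum(rep(1, nrow(sel)), sel$condition)
  m <- m / cnt[, 1]
  long <- tibble::tibble(
    condition = rep(rownames(m), each = ncol(m)),
    fraction = rep(seq_len(ncol(m)), nrow(m)),
    intensity = as.vector(t(m))
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$fraction, y = .data$intensity, colour = .data$condition
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "SEC fraction", y = "mean MS intensity",
                  title = protein) +
    ggplot2::theme_minimal()
  if (!is.null(features)) {
    f <- features[features$protein_id == protein, ]
    if (nrow(f) > 0) {
      p <- p + ggplot2::geom_rect(
        data = f,
        ggplot2::aes(xmin = .data$left, xmax = .data$right),
        ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "grey40",
        inherit.aes = FALSE
      )
    }
  }
  p
}

#' Volcano plot of differential results
#'
#' @param results A `sec_diff` tibble (per feature or representative).
#' @param alpha,min_fc Cutoff lines; default to the values stored on the
#'   object.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, alpha = NULL, min_fc = NULL) {
  alpha <- alpha %||% attr(results, "alpha") %||% 0.01
  min_fc <- min_fc %||% attr(results, "min_fc") %||% 1.5
  df <- tibble::as_tibble(results)
  df$neglog_p <- -log10(pmax(df$pBHadj, .Machine$double.xmin))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$median_log2_fc, y = .data$neglog_p,
    colour = .data$is_significant
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(min_fc),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "median log2 fold change",
                  y = "-log10 adjusted p-value", colour = "significant") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sec_diff <- function(object, ...) plot_volcano(object, ...)

#' @export
autoplot.sec_traces <- function(object, ...) {
  runs <- run_table(object)
  key <- paste(object$condition, object$replicate, sep = "\r")
  long <- purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    rows <- key == paste(runs$condition[i], runs$replicate[i], sep = "\r")
    tibble::tibble(
      condition = runs$condition[i], replicate = runs$replicate[i],
      fraction = seq_len(n_fractions(object)),
      total = colSums(object$intensity[rows, , drop = FALSE])
    )
  })
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$fraction, y = .data$total, colour = .data$condition,
    group = interaction(.data$condition, .data$replicate)
  )) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "SEC fraction", y = "total MS intensity") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sec_calibration <- function(object, ...) {
  st <- object$standards
  grid <- tibble::tibble(
    apex_fraction = seq(min(st$apex_fraction), max(st$apex_fraction),
                        length.out = 100)
  )
  grid$mw_kda <- apparent_mw(object, grid$apex_fraction)
  ggplot2::ggplot(st, ggplot2::aes(.data$apex_fraction, .data$mw_kda)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "apex fraction", y = "MW (kDa)") +
    ggplot2::theme_minimal()
}
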