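#' Extract feature-summed peptide intensities
#'
#' For every feature and every peptide of the feature's protein, the
#' intensity summed over the feature's fraction range `[left, right]`
#' (inclusive) is returned for each run of the design. The full
#' peptide x condition x replicate grid is emitted, with 0 for runs in which
#' the peptide was not observed, so downstream imputation and paired testing
#' see every cell. Testing is meant to run on minimally processed
#' (normalized-only) traces so that the raw replicate variability enters the
#' test.
#'
#' @param traces A [sec_traces()] object (normalized).
#' @param features A [detect_protein_features()] result (or any tibble with
#'   `protein_id`, `feature_id`, `left`, `right`, `apex`).
#' @param design A [sec_design()].
#' @return A tibble with one row per (feature, peptide, condition,
#'   replicate) and column `value`.
#' @export
extract_feature_values <- function(traces, features, design) {
  nf <- n_fractions(traces)
  if (any(features$left < 1 | features$right > nf)) {
    abort("feature boundaries outside the fraction range")
  }
  rows_by_prot <- split(seq_len(nrow(traces)), traces$protein_id)
  grid <- run_table(design)
  out <- purrr::pmap_dfr(
    features[c("protein_id", "feature_id", "left", "right")],
    function(protein_id, feature_id, left, right) {
      rows <- rows_by_prot[[protein_id]]
      if (is.null(rows)) return(NULL)
      sums <- rowSums(traces$intensity[rows, left:right, drop = FALSE])
      obs <- tibble::tibble(
        peptide_id = traces$peptide_id[rows],
        condition = traces$condition[rows],
        replicate = traces$replicate[rows],
        value = sums
      )
      full <- tidyr::expand_grid(
        peptide_id = unique(obs$peptide_id), grid
      )
      full <- dplyr::left_join(full, obs,
                               by = c("peptide_id", "condition", "replicate"))
      full$value[is.na(full$value)] <- 0
      dplyr::bind_cols(
        tibble::tibble(protein_id = protein_id, feature_id = feature_id),
        full
      )
    }
  )
  out
}

# deterministic per-key sub-seed below 2^31 (rolling string hash)
hash_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 1073741789
  as.integer((h + seed) %% .Machine$integer.max)
}

#' Impute zero cells for differential testing
#'
#' Zeros among the feature-summed intensities are replaced by draws from
#' `Uniform(0, Q)` where `Q` is the `percentile`-th percentile of all
#' nonzero feature-summed values in the data set (a dataset-wide pool keeps
#' the floor stable for small features). Draws are sub-seeded per cell from
#' `seed` and the cell's identity, so the imputation is reproducible and
#' independent of row order.
#'
#' @param values An [extract_feature_values()] result.
#' @param percentile Percentile (0-100) of the nonzero pool (default 5).
#' @param seed Integer seed.
#' @return `values` with zeros replaced and a logical `imputed` column.
#' @export
impute_test_missing <- function(values, percentile = 5, seed = 1) {
  pool <- values$value[values$value > 0]
  if (length(pool) == 0) abort("no nonzero values to anchor imputation")
  q <- unname(quantile(pool, percentile / 100))
  zero <- which(values$value == 0)
  values$imputed <- FALSE
  if (length(zero) > 0) {
    keys <- paste(values$protein_id[zero], values$feature_id[zero],
                  values$peptide_id[zero], values$condition[zero],
                  values$replicate[zero], sep = "|")
    draws <- vapply(keys, function(k) {
      set.seed(hash_seed(seed, k))
      runif(1, 0, q)
    }, numeric(1), USE.NAMES = FALSE)
    values$value[zero] <- draws
    values$imputed[zero] <- TRUE
  }
  values
}

#' Paired t-tests on peptide feature intensities
#'
#' Per (feature, peptide), intensities are log2 transformed and the two
#' conditions compared with a two-sided paired t-test across replicates
#' (pairing by replicate index). The log2 fold change is the mean paired
#' difference, second condition minus first. When the paired differences
#' have zero variance the p-value is set to the smallest positive double
#' and the test flagged `degenerate`.
#'
#' @param values An [impute_test_missing()] result (all values > 0).
#' @param design A [sec_design()]; `design$conditions[1]` is the reference.
#' @return A tibble with one row per (feature, peptide): `log2_fc`,
#'   `t_statistic`, `df`, `p_value`, `degenerate`.
#' @export
peptide_t_test <- function(values, design) {
  if (any(values$value <= 0)) {
    abort("values must be positive (run impute_test_missing first)")
  }
  if (length(design$replicates) < 2) {
    abort("paired test needs >= 2 replicates")
  }
  c1 <- design$conditions[1]
  c2 <- design$conditions[2]
  wide <- tidyr::pivot_wider(
    dplyr::mutate(values, value = log2(.data$value)),
    id_cols = c("protein_id", "feature_id", "peptide_id", "replicate"),
    names_from = "condition", values_from = "value"
  )
  if (anyNA(wide[[c1]]) || anyNA(wide[[c2]])) {
    abort("incomplete replicate pairing across conditions")
  }
  wide$diff <- wide[[c2]] - wide[[c1]]
  out <- dplyr::summarise(
    dplyr::group_by(wide, .data$protein_id, .data$feature_id,
                    .data$peptide_id),
    n_rep = dplyr::n(),
    log2_fc = mean(.data$diff),
    sd_diff = sd(.data$diff),
    .groups = "drop"
  )
  out$degenerate <- out$sd_diff == 0
  se <- out$sd_diff / sqrt(out$n_rep)
  out$t_statistic <- ifelse(out$degenerate,
                            ifelse(out$log2_fc == 0, 0, Inf * sign(out$log2_fc)),
                            out$log2_fc / se)
  out$df <- out$n_rep - 1
  out$p_value <- ifelse(
    out$degenerate,
    ifelse(out$log2_fc == 0, 1, .Machine$double.xmin),
    2 * pt(-abs(out$t_statistic), out$df)
  )
  out$p_value <- pmax(out$p_value, .Machine$double.xmin)
  dplyr::select(out, -"sd_diff")
}

#' Order-statistic (beta) aggregate of p-values
#'
#' The k-th smallest of n independent Uniform(0,1) p-values follows a
#' Beta(k, n - k + 1) law; its CDF at the observed k-th order statistic is
#' therefore itself a valid p-value. Used to collapse the peptide-level
#' tests of a protein feature into one protein-level p-value, robust to a
#' minority of discordant peptides.
#'
#' @param p Numeric vector of p-values.
#' @param k Order statistic used (default `ceiling(length(p) / 2)`, the
#'   median position).
#' @return A single p-value.
#' @export
beta_order_pvalue <- function(p, k = ceiling(length(p) / 2)) {
  n <- length(p)
  if (n == 0) abort("no p-values to aggregate")
  pbeta(sort(p)[k], k, n - k + 1)
}

#' Aggregate peptide tests to protein-feature results
#'
#' Per (protein, feature): the median peptide log2 fold change is reported,
#' and the peptide p-values are collapsed with [beta_order_pvalue()] at
#' `k = ceiling(n / 2)`. Two aggregation schemes are available:
#' \describe{
#'   \item{`"plain"`}{(default) the two-sided peptide p-values are
#'     aggregated directly; exactly uniform under the null for any n.}
#'   \item{`"adjusted"`}{fold-change directed: each two-sided peptide p is
#'     first converted to a one-sided p toward the protein's median fold
#'     change direction (`p/2` when the peptide agrees in sign, `1 - p/2`
#'     otherwise), aggregated, and the result re-two-sided as
#'     `2 * min(B, 1 - B)` capped at 1. Rewards directional concordance;
#'     exactly calibrated for odd n, slightly conservative near p = 1 for
#'     even n.}
#' }
#'
#' @param peptide_stats A [peptide_t_test()] result.
#' @param direction `"plain"` or `"adjusted"`.
#' @return A tibble with one row per (protein, feature): `n_peptides`, `k`,
#'   `median_log2_fc`, `p_protein`.
#' @export
aggregate_protein <- function(peptide_stats,
                              direction = c("plain", "adjusted")) {
  direction <- match.arg(direction)
  if (nrow(peptide_stats) == 0) abort("no peptide statistics to aggregate")
  agg_one <- function(p, fc) {
    n <- length(p)
    k <- ceiling(n / 2)
    if (direction == "plain") {
      pp <- beta_order_pvalue(p, k)
    } else {
      d <- sign(median(fc))
      if (d == 0) d <- 1
      q <- ifelse(sign(fc) == d, p / 2, 1 - p / 2)
      b <- beta_order_pvalue(q, k)
      pp <- min(2 * min(b, 1 - b), 1)
    }
    tibble::tibble(n_peptides = n, k = k, median_log2_fc = median(fc),
                   p_protein = max(pp, .Machine$double.xmin))
  }
  out <- dplyr::reframe(
    dplyr::group_by(peptide_stats, .data$protein_id, .data$feature_id),
    agg_one(.data$p_value, .data$log2_fc)
  )
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH adjustment over one family of tests (all
#' protein-feature tests of an experiment).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values (`pBHadj`), same length.
#' @export
adjust_bh <- function(p) p.adjust(p, method = "BH")

#' Select one representative feature result per protein
#'
#' The feature with the lowest `pBHadj` represents the protein; ties are
#' broken by largest absolute median log2 fold change, then lowest apex
#' fraction.
#'
#' @param results A per-feature differential result tibble (with `pBHadj`,
#'   `median_log2_fc` and, if available, `apex`).
#' @return One row per protein.
#' @export
select_representative <- function(results) {
  if (!"apex" %in% names(results)) results$apex <- NA_integer_
  out <- dplyr::arrange(results, .data$pBHadj,
                        dplyr::desc(abs(.data$median_log2_fc)), .data$apex)
  out <- dplyr::slice_head(dplyr::group_by(out, .data$protein_id), n = 1)
  dplyr::ungroup(out)
}

#' SEC-localized differential association testing
#'
#' The full per-feature differential pipeline: feature-range extraction of
#' peptide intensities, 5th-percentile uniform imputation of missing cells,
#' paired peptide-level t-tests, order-statistic aggregation to
#' protein-feature p-values, BH adjustment across all protein-feature tests,
#' and significance calls at `pBHadj <= alpha` and
#' `|median log2 FC| >= log2(min_fc)`.
#'
#' @param traces Normalized [sec_traces()].
#' @param features [detect_protein_features()] result (optionally with
#'   assembly states from [assign_assembly_state()]).
#' @param design A [sec_design()].
#' @param alpha BH-adjusted significance cutoff (default 0.01).
#' @param min_fc Minimum linear fold change (default 1.5).
#' @param seed Integer seed for the imputation draws.
#' @param direction Aggregation scheme, see [aggregate_protein()].
#' @param percentile Imputation percentile, see [impute_test_missing()].
#' @return A `sec_diff` tibble, one row per (protein, feature):
#'   `median_log2_fc`, `p_protein`, `pBHadj`, `is_significant`, plus the
#'   feature's apex/boundaries/assembly state.
#' @export
test_differential <- function(traces, features, design, alpha = 0.01,
                              min_fc = 1.5, seed = 1,
                              direction = c("plain", "adjusted"),
                              percentile = 5) {
  direction <- match.arg(direction)
  vals <- extract_feature_values(traces, features, design)
  vals <- impute_test_missing(vals, percentile = percentile, seed = seed)
  stats <- peptide_t_test(vals, design)
  res <- aggregate_protein(stats, direction = direction)
  res$pBHadj <- adjust_bh(res$p_protein)
  res$is_significant <- res$pBHadj <= alpha &
    abs(res$median_log2_fc) >= log2(min_fc)
  keep <- intersect(
    c("feature_id", "apex", "left", "right", "apparent_mw_kda",
      "monomer_mw_kda", "assembly_state"),
    names(features)
  )
  res <- dplyr::left_join(res, features[c("feature_id", setdiff(keep, "feature_id"))],
                          by = "feature_id")
  attr(res, "alpha") <- alpha
  attr(res, "min_fc") <- min_fc
  class(res) <- unique(c("sec_diff", class(res)))
  res
}

#' Differential testing of total protein abundance
#'
#' The identical statistical pipeline as [test_differential()] applied to
#' peptide intensities summed across *all* fractions, i.e. ignoring the SEC
#' dimension. Comparing the two separates abundance changes from mass
#' redistribution between elution states: a pure redistribution with
#' conserved total is significant in one or more feature tests but not
#' here.
#'
#' @inheritParams test_differential
#' @param min_peptides Proteins with fewer peptides are skipped (default 2).
#' @return A `sec_diff` tibble with one row per protein (`feature_id`
#'   `"total"`).
#' @export
total_abundance_test <- function(traces, design, alpha = 0.01, min_fc = 1.5,
                                 seed = 1, direction = c("plain", "adjusted"),
                                 percentile = 5, min_peptides = 2) {
  direction <- match.arg(direction)
  nf <- n_fractions(traces)
  prots <- unique(traces$protein_id[!traces$decoy])
  n_pep <- vapply(
    split(traces$peptide_id[!traces$decoy], traces$protein_id[!traces$decoy]),
    function(x) length(unique(x)), integer(1)
  )
  prots <- prots[n_pep[prots] >= min_peptides]
  pseudo <- tibble::tibble(
    protein_id = prots,
    feature_id = paste0(prots, "_total"),
    left = 1L, right = nf, apex = NA_integer_
  )
  res <- test_differential(
    traces[!traces$decoy, ], pseudo, design, alpha = alpha, min_fc = min_fc,
    seed = seed, direction = direction, percentile = percentile
  )
  res$feature_id <- "total"
  res
}

#' Rank proteins by combined evidence
#'
#' Proteins are ranked by `log10(pBHadj)` ascending and by absolute median
#' log2 fold change descending; the rank-sum of the two (equal weights) is
#' the combined score, sorted ascending (rank 1 = strongest change). Rank
#' ties in the sum are broken by lower `pBHadj`.
#'
#' @param results A per-protein result tibble (e.g. from
#'   [select_representative()]).
#' @return `results` with columns `rank_p`, `rank_fc`, `rank_sum`, `rank`,
#'   sorted by `rank`.
#' @export
rank_sum_score <- function(results) {
  out <- results
  out$rank_p <- rank(log10(out$pBHadj), ties.method = "average")
  out$rank_fc <- rank(-abs(out$median_log2_fc), ties.method = "average")
  out$rank_sum <- out$rank_p + out$rank_fc
  out <- dplyr::arrange(out, .data$rank_sum, .data$pBHadj)
  out$rank <- seq_len(nrow(out))
  out
}
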