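#' Classify significant SEC changes
#'
#' Significant protein changes are sorted into four categories:
#' \enumerate{
#'   \item one significant feature, in the assembled range (a single
#'     complex-bound form changes);
#'   \item one significant feature, in the monomeric range;
#'   \item two or more significant features with similar fold changes
#'     (`log10(deltaFC) <= 1`);
#'   \item two or more significant features with dissimilar fold changes
#'     (`log10(deltaFC) > 1`).
#' }
#' `deltaFC` is the ratio of the largest to the smallest linear fold change
#' (second condition over first) among the protein's significant features,
#' so `delta_fc_log10 >= 0` and the measure is invariant to swapping the
#' condition labels.
#'
#' @param results A per-feature `sec_diff` tibble with `is_significant` and
#'   `assembly_state` columns.
#' @param delta_cutoff Class 3/4 boundary on `log10(deltaFC)` (default 1).
#' @return A tibble with one row per protein that has at least one
#'   significant feature: `class` (1-4), `n_significant_features`,
#'   `delta_fc_log10` (NA for single-feature proteins).
#' @export
classify_changes <- function(results, delta_cutoff = 1) {
  if (!"assembly_state" %in% names(results)) {
    abort("results need an `assembly_state` column (assign_assembly_state)")
  }
  sig <- results[results$is_significant, ]
  if (nrow(sig) == 0) {
    return(tibble::tibble(protein_id = character(), class = integer(),
                          n_significant_features = integer(),
                          delta_fc_log10 = numeric()))
  }
  per_prot <- function(df) {
    n <- nrow(df)
    if (n == 1) {
      cls <- switch(df$assembly_state,
                    assembled = 1L, monomeric = 2L, NA_integer_)
      return(tibble::tibble(class = cls, n_significant_features = 1L,
                            delta_fc_log10 = NA_real_))
    }
    lin <- 2^df$median_log2_fc
    delta <- abs(log10(max(lin) / min(lin)))
    tibble::tibble(
      class = if (delta <= delta_cutoff) 3L else 4L,
      n_significant_features = n,
      delta_fc_log10 = delta
    )
  }
  out <- dplyr::reframe(dplyr::group_by(sig, .data$protein_id),
                        per_prot(dplyr::pick(dplyr::everything())))
  out
}

#' Infer complex remodeling from complex priors
#'
#' A prior complex (e.g. a CORUM entry) is called *remodeling* when at least
#' `min_shifting` of its subunits show a significant SEC shift in the
#' assembled range. Monomer-range changes never count toward the threshold:
#' they carry no information on the complex-bound pool. Complexes with fewer
#' than 2 subunits detected in the experiment are not called (covered =
#' FALSE).
#'
#' @param results A per-feature `sec_diff` tibble with `is_significant` and
#'   `assembly_state`.
#' @param priors Long complex table (`complex_id`, optionally
#'   `complex_name`, `protein_id`), e.g. from [read_complexes()].
#' @param min_shifting Minimum number of shifting assembled subunits
#'   (default 2).
#' @return A tibble with one row per complex: `n_subunits`,
#'   `n_subunits_detected`, `n_subunits_shifting_assembled`, `covered`,
#'   `is_remodeling`, `shift_completeness`, `mean_subunit_shift_score`
#'   (mean -log10 pBHadj of the detected subunits' best features;
#'   display only).
#' @export
infer_complex_remodeling <- function(results, priors, min_shifting = 2) {
  priors <- tibble::as_tibble(priors)
  detected <- unique(results$protein_id)
  shifting <- unique(results$protein_id[
    results$is_significant & results$assembly_state == "assembled"
  ])
  best <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(results), .data$protein_id),
    score = max(-log10(pmax(.data$pBHadj, .Machine$double.xmin))),
    .groups = "drop"
  )
  per_cx <- dplyr::summarise(
    dplyr::group_by(priors, .data$complex_id),
    complex_name = if ("complex_name" %in% names(priors))
      dplyr::first(.data$complex_name) else dplyr::first(.data$complex_id),
    n_subunits = dplyr::n_distinct(.data$protein_id),
    n_subunits_detected = sum(unique(.data$protein_id) %in% detected),
    n_subunits_shifting_assembled = sum(unique(.data$protein_id) %in% shifting),
    mean_subunit_shift_score = mean(
      best$score[match(intersect(unique(.data$protein_id), detected),
                       best$protein_id)]
    ),
    .groups = "drop"
  )
  per_cx$covered <- per_cx$n_subunits_detected >= 2
  per_cx$is_remodeling <- ifelse(
    per_cx$covered,
    per_cx$n_subunits_shifting_assembled >= min_shifting,
    NA
  )
  per_cx$shift_completeness <- ifelse(
    per_cx$n_subunits_detected > 0,
    per_cx$n_subunits_shifting_assembled / per_cx$n_subunits_detected,
    NA_real_
  )
  per_cx
}

#' Windowed co-elution candidate search
#'
#' Nominates candidate interaction partners of a target protein from local
#' profile similarity: the Pearson correlation of every protein's
#' condition-specific replicate-mean elution trace with the target's trace,
#' restricted to a fraction window (e.g. a sub-complex peak). The
#' window-summed intensity of each candidate is reported alongside for
#' stoichiometric plausibility screening; the target itself is included as
#' rank-1 anchor (r = 1).
#'
#' @param protein_traces A [protein_quant_top2()] result.
#' @param target Target protein id; must have nonzero signal in the window.
#' @param window Integer vector of fractions (length >= 3), e.g. `21:27`.
#' @param condition Condition id whose replicate-mean traces are used.
#' @return A tibble sorted by correlation (descending): `protein_id`,
#'   `correlation`, `window_intensity`, `rank`.
#' @export
local_coelution_search <- function(protein_traces, target, window, condition) {
  window <- as.integer(window)
  if (length(window) < 3) abort("window must span at least 3 fractions")
  nf <- n_fractions(protein_traces)
  if (min(window) < 1 || max(window) > nf) {
    abort("window outside the fraction range")
  }
  sel <- protein_traces[protein_traces$condition == condition, ]
  if (nrow(sel) == 0) abort(paste0("no traces for condition '", condition, "'"))
  m <- rowsum(sel$intensity, sel$protein_id, reorder = TRUE)
  cnt <- rowsum(rep(1, nrow(sel)), sel$protein_id, reorder = TRUE)
  m <- m / cnt[, 1]
  if (!target %in% rownames(m)) abort(paste0("unknown target '", target, "'"))
  tw <- m[target, window]
  if (sum(tw) <= 0) abort("target has no signal in the window")
  w <- m[, window, drop = FALSE]
  r <- suppressWarnings(apply(w, 1, cor, y = tw))
  out <- tibble::tibble(
    protein_id = rownames(m),
    correlation = unname(r),
    window_intensity = unname(rowSums(w))
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$correlation))
  out$rank <- seq_len(nrow(out))
  out
}
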