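#' Configuration for the synthetic SEC experiment generator
#'
#' Defaults emulate the statistical structure of a two-condition,
#' triplicate SEC-SWATH-MS experiment: 65 fractions, proteins eluting in
#' 1-5 Gaussian peaks with 2-40 co-eluting sibling peptides, lognormal
#' peptide response factors spanning a large dynamic range, multiplicative
#' measurement noise, detection-limit missingness, spike-in standard
#' peptides with per-run scale distortions, and decoy proteins assembled
#' from reshuffled peptide sets.
#'
#' @param n_proteins Number of target proteins.
#' @param n_fractions Number of SEC fractions (default 65).
#' @param peptides_per_protein Integer range, peptides per protein
#'   (default 2-40).
#' @param peaks_per_protein Integer range, elution peaks per protein
#'   (default 1-5).
#' @param peak_sigma Range of Gaussian peak widths in fractions
#'   (default 1-2).
#' @param response_sdlog Lognormal sd of fixed per-peptide response factors
#'   (default 1; a peptide's ionization efficiency is a property of the
#'   peptide, so responses do not vary across runs).
#' @param noise_cv Multiplicative lognormal measurement noise CV
#'   (default 0.2).
#' @param detection_limit Intensity floor; values below it are reported as 0
#'   (default 1e4, inducing preferential dropout of low signals).
#' @param mcar_rate Additional missing-completely-at-random dropout
#'   probability (default 0).
#' @param conditions Two condition ids.
#' @param n_replicates Replicates per condition (default 3).
#' @param base_amount_meanlog,base_amount_sdlog Lognormal protein amount
#'   distribution (defaults log(1e6) and 1).
#' @param frac_abundance_change Fraction of proteins with a uniform
#'   abundance change in condition 2.
#' @param abundance_fold Fold change applied to those proteins (default 4).
#' @param frac_redistribution Fraction of proteins with mass redistribution
#'   between their first and last peak (total conserved).
#' @param redistribution_moved Fraction of the first peak's amplitude moved
#'   (default 0.5).
#' @param frac_peak_gain Fraction of proteins gaining a new peak in
#'   condition 2.
#' @param gain_amplitude Amplitude of the gained peak relative to the
#'   protein amount (default 0.5).
#' @param decoy_fraction Decoy proteins emitted, as a fraction of
#'   `n_proteins` (default 0.1).
#' @param n_standard_peptides Spike-in standard peptides (default 5).
#' @param standard_intensity Flat per-fraction standard intensity
#'   (default 1e6).
#' @param run_scale_sdlog Lognormal sd of per-run global scale distortions
#'   (default 0.2; exercised and removed by normalization).
#' @param complex_fraction Fraction of proteins grouped into synthetic
#'   complexes whose subunits share their first (assembled) peak
#'   (default 0).
#' @param complex_size Integer range of complex sizes (default 2-5).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 100,
                       n_fractions = 65,
                       peptides_per_protein = c(2, 40),
                       peaks_per_protein = c(1, 5),
                       peak_sigma = c(1, 2),
                       response_sdlog = 1,
                       noise_cv = 0.2,
                       detection_limit = 1e4,
                       mcar_rate = 0,
                       conditions = c("control", "treatment"),
                       n_replicates = 3,
                       base_amount_meanlog = log(1e6),
                       base_amount_sdlog = 1,
                       frac_abundance_change = 0,
                       abundance_fold = 4,
                       frac_redistribution = 0,
                       redistribution_moved = 0.5,
                       frac_peak_gain = 0,
                       gain_amplitude = 0.5,
                       decoy_fraction = 0.1,
                       n_standard_peptides = 5,
                       standard_intensity = 1e6,
                       run_scale_sdlog = 0.2,
                       complex_fraction = 0,
                       complex_size = c(2, 5),
                       seed = 1) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(
      n_proteins >= 1, n_fractions >= 10,
      peptides_per_protein[1] >= 2, peaks_per_protein[1] >= 1,
      all(peak_sigma > 0), response_sdlog >= 0, noise_cv >= 0,
      detection_limit >= 0, mcar_rate >= 0, mcar_rate <= 1,
      length(conditions) == 2, n_replicates >= 2,
      frac_abundance_change >= 0, frac_redistribution >= 0,
      frac_peak_gain >= 0,
      frac_abundance_change + frac_redistribution + frac_peak_gain <= 1,
      abundance_fold > 0, redistribution_moved >= 0, redistribution_moved <= 1,
      decoy_fraction >= 0, complex_fraction >= 0, complex_fraction <= 1
    )
  })
  structure(cfg, class = "sim_config")
}

# apexes in [lo, hi] with pairwise separation >= min_sep
draw_apexes <- function(n, lo, hi, min_sep = 6) {
  for (i in 1:200) {
    a <- sort(runif(n, lo, hi))
    if (n == 1 || min(diff(a)) >= min_sep) return(a)
  }
  # fall back to an evenly spaced grid with jitter
  g <- seq(lo, hi, length.out = n)
  g + runif(n, -1, 1)
}

#' Simulate a synthetic SEC-SWATH-like experiment
#'
#' Generates peptide-level fractionation traces with full ground truth.
#' Peptide intensity at fraction f is the sum over the protein's peaks of
#' `amplitude x response x exp(-(f - apex)^2 / (2 sigma^2))`, multiplied by
#' per-cell lognormal noise (mean 1) and a per-run scale distortion, and
#' zeroed below the detection limit. Condition effects act on protein peak
#' amplitudes only. Calibration standards are emitted on an exact
#' log-linear MW grid so the calibration fit recovers the generating map
#' exactly.
#'
#' @param config A [sim_config()].
#' @return A list: `traces` ([sec_traces()] incl. standard and decoys),
#'   `design` ([sec_design()]), `standards` (calibration table),
#'   `annotation` (monomer MW table), `complexes` (long prior table, may be
#'   empty) and `truth` (list of `proteins`, `peaks`, `complexes` tibbles).
#' @export
simulate_sec_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  nf <- cfg$n_fractions
  fr <- seq_len(nf)

  # exact log-linear calibration covering ~5 MDa .. 10 kDa
  slope <- -log(500) / (nf - 1)
  intercept <- log(5000) - slope
  std_frac <- round(seq(0.08, 0.85, length.out = 6) * nf)
  standards <- tibble::tibble(
    protein = paste0("CAL_STD_", seq_along(std_frac)),
    mw_kda = exp(intercept + slope * std_frac),
    apex_fraction = std_frac
  )
  mw_at <- function(f) exp(intercept + slope * f)

  prot_ids <- sprintf("P%04d", seq_len(cfg$n_proteins))
  n_pep <- sample(cfg$peptides_per_protein[1]:cfg$peptides_per_protein[2],
                  cfg$n_proteins, replace = TRUE)
  n_peak <- sample(cfg$peaks_per_protein[1]:cfg$peaks_per_protein[2],
                   cfg$n_proteins, replace = TRUE)

  # effect assignment
  n_ab <- round(cfg$frac_abundance_change * cfg$n_proteins)
  n_rd <- round(cfg$frac_redistribution * cfg$n_proteins)
  n_pg <- round(cfg$frac_peak_gain * cfg$n_proteins)
  shuffled <- sample(cfg$n_proteins)
  effect <- rep("none", cfg$n_proteins)
  effect[shuffled[seq_len(n_ab)]] <- "abundance_change"
  effect[shuffled[n_ab + seq_len(n_rd)]] <- "redistribution"
  effect[shuffled[n_ab + n_rd + seq_len(n_pg)]] <- "peak_gain"
  n_peak[effect == "redistribution"] <- pmax(n_peak[effect == "redistribution"], 2)

  # synthetic complexes: subunits share their first (largest-MW) peak
  complex_of <- rep(NA_character_, cfg$n_proteins)
  if (cfg$complex_fraction > 0) {
    pool <- sample(cfg$n_proteins, round(cfg$complex_fraction * cfg$n_proteins))
    ci <- 0
    while (length(pool) >= cfg$complex_size[1]) {
      sz <- min(sample(cfg$complex_size[1]:cfg$complex_size[2], 1),
                length(pool))
      ci <- ci + 1
      complex_of[pool[seq_len(sz)]] <- sprintf("CPX%03d", ci)
      pool <- pool[-seq_len(sz)]
    }
  }

  amount <- rlnorm(cfg$n_proteins, cfg$base_amount_meanlog,
                   cfg$base_amount_sdlog)
  noise_sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  runs <- tidyr::expand_grid(condition = cfg$conditions,
                             replicate = seq_len(cfg$n_replicates))
  run_factor <- if (cfg$run_scale_sdlog > 0) {
    rlnorm(nrow(runs), 0, cfg$run_scale_sdlog)
  } else {
    rep(1, nrow(runs))
  }

  # shared apex per complex (drawn once per complex)
  cx_ids <- unique(stats::na.omit(complex_of))
  cx_apex <- setNames(runif(length(cx_ids), 8, 25), cx_ids)

  peaks_list <- vector("list", cfg$n_proteins)
  prot_rows <- vector("list", cfg$n_proteins)
  entry_keys <- vector("list", cfg$n_proteins)
  entry_mat <- vector("list", cfg$n_proteins)
  pep_counter <- 0

  for (i in seq_len(cfg$n_proteins)) {
    np <- n_peak[i]
    apex <- draw_apexes(np, 8, nf - 6)
    if (!is.na(complex_of[i])) apex[1] <- cx_apex[complex_of[i]]
    sigma <- runif(np, cfg$peak_sigma[1], cfg$peak_sigma[2])
    w <- runif(np, 0.5, 1)
    a1 <- amount[i] * w / sum(w)
    # monomer MW: half the proteins elute their last peak as the monomer,
    # the rest are fully assembled (monomer would elute later)
    monomeric_last <- runif(1) < 0.5 && is.na(complex_of[i])
    mono_frac <- if (monomeric_last) apex[np] else apex[np] + runif(1, 8, 15)
    monomer_mw <- mw_at(mono_frac)

    a2 <- a1
    gain <- NULL
    if (effect[i] == "abundance_change") {
      a2 <- a1 * cfg$abundance_fold
    } else if (effect[i] == "redistribution") {
      moved <- cfg$redistribution_moved * a1[1]
      a2[1] <- a1[1] - moved
      a2[np] <- a1[np] + moved
    } else if (effect[i] == "peak_gain") {
      for (k in 1:100) {
        cand <- runif(1, 8, nf - 6)
        if (all(abs(cand - apex) >= 6)) break
      }
      gain <- list(apex = cand, sigma = runif(1, cfg$peak_sigma[1],
                                              cfg$peak_sigma[2]),
                   amp = cfg$gain_amplitude * amount[i])
    }

    apex_all <- c(apex, if (!is.null(gain)) gain$apex)
    sigma_all <- c(sigma, if (!is.null(gain)) gain$sigma)
    amp1 <- c(a1, if (!is.null(gain)) 0)
    amp2 <- c(a2, if (!is.null(gain)) gain$amp)
    peaks_list[[i]] <- tibble::tibble(
      protein_id = prot_ids[i], peak = seq_along(apex_all),
      apex = apex_all, sigma = sigma_all,
      amplitude_1 = amp1, amplitude_2 = amp2,
      assembled = mw_at(apex_all) >= 2 * monomer_mw
    )
    prot_rows[[i]] <- tibble::tibble(
      protein_id = prot_ids[i], n_peptides = n_pep[i],
      n_peaks = length(apex_all),
      monomer_mw_kda = monomer_mw, effect = effect[i],
      complex_id = complex_of[i]
    )

    # noiseless protein shape per condition
    g <- exp(-outer(fr, apex_all, function(f, a) (f - a)^2) /
               rep(2 * sigma_all^2, each = nf))
    shape1 <- drop(g %*% amp1)
    shape2 <- drop(g %*% amp2)

    resp <- rlnorm(n_pep[i], 0, cfg$response_sdlog)
    pep_ids <- sprintf("pep_%s_%02d", prot_ids[i], seq_len(n_pep[i]))
    pep_counter <- pep_counter + n_pep[i]

    base <- rbind(outer(resp, shape1), outer(resp, shape2))  # 2*np x nf
    keys <- tidyr::expand_grid(
      condition = cfg$conditions, peptide_id = pep_ids,
      replicate = seq_len(cfg$n_replicates)
    )
    # rows of base per (condition, peptide): replicate adds noise + scale
    bi <- match(paste(keys$condition, keys$peptide_id),
                paste(rep(cfg$conditions, each = n_pep[i]),
                      rep(pep_ids, 2)))
    m <- base[bi, , drop = FALSE]
    rf <- run_factor[match(paste(keys$condition, keys$replicate),
                           paste(runs$condition, runs$replicate))]
    noise <- matrix(
      rlnorm(length(m), -noise_sdlog^2 / 2, noise_sdlog),
      nrow = nrow(m)
    )
    m <- m * noise * rf
    entry_keys[[i]] <- tibble::tibble(
      peptide_id = keys$peptide_id, protein_id = prot_ids[i],
      condition = keys$condition, replicate = as.integer(keys$replicate),
      decoy = FALSE
    )
    entry_mat[[i]] <- m
  }

  keys <- dplyr::bind_rows(entry_keys)
  m <- do.call(rbind, entry_mat)

  # spike-in standard: flat traces, scaled by the same run distortions
  std_resp <- rlnorm(cfg$n_standard_peptides, 0, cfg$response_sdlog / 2)
  std_keys <- tidyr::expand_grid(
    peptide_id = sprintf("pep_STANDARD_%02d", seq_len(cfg$n_standard_peptides)),
    condition = cfg$conditions, replicate = seq_len(cfg$n_replicates)
  )
  std_rf <- run_factor[match(paste(std_keys$condition, std_keys$replicate),
                             paste(runs$condition, runs$replicate))]
  std_base <- cfg$standard_intensity *
    std_resp[match(std_keys$peptide_id, unique(std_keys$peptide_id))]
  std_m <- matrix(
    rlnorm(nrow(std_keys) * nf, -noise_sdlog^2 / 2, noise_sdlog),
    nrow = nrow(std_keys)
  ) * std_base * std_rf
  keys <- dplyr::bind_rows(keys, tibble::tibble(
    peptide_id = std_keys$peptide_id, protein_id = "STANDARD",
    condition = std_keys$condition, replicate = as.integer(std_keys$replicate),
    decoy = FALSE
  ))
  m <- rbind(m, std_m)

  # decoy proteins: reshuffled peptide sets drawn from distinct targets
  n_decoy <- round(cfg$decoy_fraction * cfg$n_proteins)
  if (n_decoy > 0) {
    target_peps <- unique(keys$peptide_id[keys$protein_id != "STANDARD"])
    pep_prot <- keys$protein_id[match(target_peps, keys$peptide_id)]
    dk <- list()
    dm <- list()
    for (d in seq_len(n_decoy)) {
      sz <- sample(cfg$peptides_per_protein[1]:cfg$peptides_per_protein[2], 1)
      donors <- sample(unique(pep_prot), min(sz, length(unique(pep_prot))))
      picked <- vapply(donors, function(pr) {
        sample(target_peps[pep_prot == pr], 1)
      }, "")
      rows <- which(keys$peptide_id %in% picked)
      kk <- keys[rows, ]
      kk$peptide_id <- paste0("DECOY", d, "_", kk$peptide_id)
      kk$protein_id <- sprintf("DECOY_P%04d", d)
      kk$decoy <- TRUE
      dk[[d]] <- kk
      dm[[d]] <- m[rows, , drop = FALSE]
    }
    keys <- dplyr::bind_rows(keys, dplyr::bind_rows(dk))
    m <- rbind(m, do.call(rbind, dm))
  }

  # detection limit + optional MCAR dropout
  m[m < cfg$detection_limit] <- 0
  if (cfg$mcar_rate > 0) {
    drop_mask <- matrix(runif(length(m)) < cfg$mcar_rate, nrow = nrow(m))
    m[drop_mask] <- 0
  }

  keys$intensity <- m
  traces <- validate_sec_traces(new_sec_traces(keys))

  design <- sec_design(cfg$conditions, seq_len(cfg$n_replicates),
                       standard_protein = "STANDARD", n_fractions = nf)

  peaks <- dplyr::bind_rows(peaks_list)
  peaks$true_log2_fc <- log2(pmax(peaks$amplitude_2, .Machine$double.xmin) /
                               pmax(peaks$amplitude_1, .Machine$double.xmin))
  proteins <- dplyr::bind_rows(prot_rows)
  proteins$true_class <- true_class_of(peaks)[proteins$protein_id]

  truth_cx <- NULL
  if (any(!is.na(proteins$complex_id))) {
    shifting <- dplyr::summarise(
      dplyr::group_by(peaks, .data$protein_id),
      shift = any(.data$assembled & abs(.data$true_log2_fc) >= log2(1.5)),
      .groups = "drop"
    )
    truth_cx <- dplyr::summarise(
      dplyr::group_by(proteins[!is.na(proteins$complex_id), ],
                      .data$complex_id),
      n_subunits = dplyr::n(),
      n_shifting = sum(shifting$shift[match(.data$protein_id,
                                            shifting$protein_id)]),
      is_remodeling = .data$n_shifting >= 2,
      .groups = "drop"
    )
  }

  complexes <- proteins[!is.na(proteins$complex_id),
                        c("complex_id", "protein_id")]
  complexes$complex_name <- complexes$complex_id

  annotation <- proteins[c("protein_id", "monomer_mw_kda")]

  list(
    traces = traces,
    design = design,
    standards = standards,
    annotation = annotation,
    complexes = complexes,
    calibration = list(intercept = intercept, slope = slope),
    truth = list(proteins = proteins, peaks = peaks, complexes = truth_cx)
  )
}

# truth classification by the same four-category rules, applied to planted peaks:
# changed peaks are those with a true fold change of at least 1.5
true_class_of <- function(peaks, min_fc = 1.5, delta_cutoff = 1) {
  changed <- peaks[abs(peaks$true_log2_fc) >= log2(min_fc), ]
  cls <- vapply(split(seq_len(nrow(changed)), changed$protein_id),
                function(rows) {
    if (length(rows) == 1) {
      if (changed$assembled[rows]) 1L else 2L
    } else {
      lin <- 2^changed$true_log2_fc[rows]
      if (abs(log10(max(lin) / min(lin))) <= delta_cutoff) 3L else 4L
    }
  }, integer(1))
  cls
}

#' Compare pipeline output against simulation ground truth
#'
#' @param truth The `truth` element of [simulate_sec_experiment()] output.
#' @param diff_results Per-protein representative differential results
#'   (from [select_representative()] applied to [test_differential()]).
#' @param features Optional [detect_protein_features()] result for apex
#'   localization error.
#' @param classes Optional [classify_changes()] result.
#' @param remodeling Optional [infer_complex_remodeling()] result.
#' @return A list with `shift_detection` (sensitivity, FDP, counts),
#'   optionally `apex_error` (per detected feature, distance to nearest
#'   planted peak), `class_confusion` and `remodeling_confusion` tibbles.
#' @export
summarize_performance <- function(truth, diff_results, features = NULL,
                                  classes = NULL, remodeling = NULL) {
  tp <- truth$proteins
  common <- intersect(tp$protein_id, diff_results$protein_id)
  if (length(common) == 0) abort("no shared protein ids between truth and results")
  res <- diff_results[diff_results$protein_id %in% common, ]
  is_pos <- setNames(tp$effect != "none", tp$protein_id)[res$protein_id]
  pred <- res$is_significant
  out <- list(shift_detection = tibble::tibble(
    n_tested = nrow(res),
    n_true_changed = sum(is_pos),
    n_called = sum(pred),
    tp = sum(pred & is_pos),
    fp = sum(pred & !is_pos),
    sensitivity = ifelse(sum(is_pos) > 0, sum(pred & is_pos) / sum(is_pos),
                         NA_real_),
    fdp = ifelse(sum(pred) > 0, sum(pred & !is_pos) / sum(pred), 0)
  ))
  if (!is.null(features)) {
    pk <- truth$peaks
    err <- purrr::map_dbl(seq_len(nrow(features)), function(i) {
      ap <- pk$apex[pk$protein_id == features$protein_id[i]]
      if (length(ap) == 0) return(NA_real_)
      min(abs(ap - features$apex[i]))
    })
    out$apex_error <- tibble::tibble(
      protein_id = features$protein_id, feature_id = features$feature_id,
      apex = features$apex, error = err
    )
  }
  if (!is.null(classes)) {
    cc <- dplyr::inner_join(classes,
                            tp[c("protein_id", "true_class")],
                            by = "protein_id")
    out$class_confusion <- dplyr::count(cc, .data$true_class, .data$class)
  }
  if (!is.null(remodeling) && !is.null(truth$complexes)) {
    rc <- dplyr::inner_join(remodeling, truth$complexes,
                            by = "complex_id",
                            suffix = c("", "_true"))
    out$remodeling_confusion <- dplyr::count(
      rc, truth = .data$is_remodeling_true, called = .data$is_remodeling
    )
  }
  out
}

#' Write a simulated experiment to a directory of plain-text files
#'
#' Writes `traces.tsv`, `design.yaml`, `standards.tsv`, `annotation.tsv`,
#' `complexes.tsv` (if any) and `truth.json`.
#'
#' @param sim A [simulate_sec_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_traces(sim$traces, file.path(dir, "traces.tsv"))
  write_design(sim$design, file.path(dir, "design.yaml"))
  readr::write_tsv(sim$standards, file.path(dir, "standards.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$annotation, file.path(dir, "annotation.tsv"),
                   progress = FALSE)
  if (nrow(sim$complexes) > 0) {
    wide <- dplyr::summarise(
      dplyr::group_by(sim$complexes, .data$complex_id, .data$complex_name),
      subunits = paste(.data$protein_id, collapse = ";"), .groups = "drop"
    )
    readr::write_tsv(wide, file.path(dir, "complexes.tsv"), progress = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      lapply(sim$truth, function(x) if (is.null(x)) NULL else x),
      file.path(dir, "truth.json"), dataframe = "rows", na = "null"
    )
  }
  invisible(dir)
}
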