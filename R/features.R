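#' Integrate traces into one master set
#'
#' For global ("master map") feature detection the condition/replicate
#' structure is collapsed: per peptide, replicate traces are averaged within
#' each condition and the two condition means are summed, yielding one trace
#' per peptide that carries signal from every elution state populated in
#' either condition.
#'
#' @param traces A preprocessed [sec_traces()] object.
#' @return A `sec_master_traces` tibble: `peptide_id`, `protein_id`, `decoy`
#'   and matrix column `intensity` (one row per peptide).
#' @export
integrate_traces <- function(traces) {
  grp <- paste(traces$peptide_id, traces$condition, sep = "\r")
  cnt <- rowsum(rep(1L, nrow(traces)), grp)
  s <- rowsum(traces$intensity, grp, reorder = TRUE)
  avg <- s / cnt[match(rownames(s), rownames(cnt)), 1]
  pep <- vapply(strsplit(rownames(avg), "\r", fixed = TRUE), `[`, "", 1)
  m <- rowsum(avg, pep, reorder = TRUE)
  peps <- dplyr::distinct(
    tibble::as_tibble(traces[c("peptide_id", "protein_id", "decoy")])
  )
  out <- tibble::tibble(
    peptide_id = rownames(m),
    protein_id = peps$protein_id[match(rownames(m), peps$peptide_id)],
    decoy = peps$decoy[match(rownames(m), peps$peptide_id)]
  )
  rownames(m) <- NULL
  out$intensity <- m
  class(out) <- unique(c("sec_master_traces", class(out)))
  out
}

# centered moving average, window 3, edges shortened
smooth_ma3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  out <- (c(v[-1], 0) + v + c(0, v[-n]))
  den <- c(2, rep(3, n - 2), 2)
  out / den
}

# local maxima indices of a vector (strictly above left neighbour, at least
# equal to right neighbour, so a flat plateau reports its leftmost point);
# boundaries count as -Inf outside
local_maxima <- function(v) {
  n <- length(v)
  if (n == 1) return(if (v[1] > 0) 1L else integer(0))
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  which(v > left & v >= right)
}

local_minima <- function(v) local_maxima(-v)

# peak detection on one protein's peptide matrix (rows = peptides)
detect_features_one <- function(mat, noise_floor = 0.01, merge_overlap = 0.5) {
  npep <- nrow(mat)
  sm <- t(apply(mat, 1, smooth_ma3))
  consensus <- colSums(sm)
  cmax <- max(consensus)
  if (cmax <= 0) return(NULL)
  floor_i <- noise_floor * cmax
  apexes <- local_maxima(consensus)
  apexes <- apexes[consensus[apexes] > floor_i]
  if (length(apexes) == 0) return(NULL)
  nf <- length(consensus)
  mins <- local_minima(consensus)
  bounds <- lapply(apexes, function(a) {
    l <- mins[mins < a]
    l <- if (length(l) > 0) max(l) else 1L
    r <- mins[mins > a]
    r <- if (length(r) > 0) min(r) else nf
    c(l, r)
  })
  feats <- tibble::tibble(
    apex = apexes,
    left = vapply(bounds, `[`, 0L, 1),
    right = vapply(bounds, `[`, 0L, 2)
  )
  # merge candidates whose ranges overlap by > merge_overlap of the smaller
  # peak's width; tie-break toward fewer, wider features
  feats <- feats[order(feats$apex), ]
  repeat {
    if (nrow(feats) < 2) break
    merged <- FALSE
    for (i in seq_len(nrow(feats) - 1)) {
      ov <- min(feats$right[i], feats$right[i + 1]) -
        max(feats$left[i], feats$left[i + 1]) + 1
      w <- min(feats$right[i] - feats$left[i],
               feats$right[i + 1] - feats$left[i + 1]) + 1
      if (ov > merge_overlap * w) {
        keep <- if (consensus[feats$apex[i]] >= consensus[feats$apex[i + 1]])
          feats$apex[i] else feats$apex[i + 1]
        feats$apex[i] <- keep
        feats$left[i] <- min(feats$left[i], feats$left[i + 1])
        feats$right[i] <- max(feats$right[i], feats$right[i + 1])
        feats <- feats[-(i + 1), ]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  # peptide participation: a peptide participates when one of its own local
  # maxima (above its own 1% floor) falls inside the feature range
  pep_max <- lapply(seq_len(npep), function(i) {
    mm <- local_maxima(sm[i, ])
    mm[sm[i, mm] > noise_floor * max(sm[i, ])]
  })
  out <- purrr::pmap_dfr(feats, function(apex, left, right) {
    part <- which(vapply(pep_max, function(mx) any(mx >= left & mx <= right),
                         logical(1)))
    if (length(part) < 2) return(NULL)
    w <- mat[part, left:right, drop = FALSE]
    cc <- suppressWarnings(cor(t(w)))
    cc[!is.finite(cc)] <- 0
    score_cor <- mean(cc[upper.tri(cc)])
    participation <- length(part) / npep
    tibble::tibble(
      apex = as.integer(apex), left = as.integer(left),
      right = as.integer(right),
      n_participating = length(part), n_peptides_total = npep,
      participation = participation,
      mean_correlation = score_cor,
      coelution_score = score_cor * participation,
      peptide_ids = list(rownames(mat)[part])
    )
  })
  if (nrow(out) == 0) NULL else out
}

score_features_set <- function(master, noise_floor, merge_overlap) {
  split_rows <- split(seq_len(nrow(master)), master$protein_id)
  res <- purrr::imap_dfr(split_rows, function(rows, prot) {
    if (length(rows) < 2) return(NULL)
    mat <- master$intensity[rows, , drop = FALSE]
    rownames(mat) <- master$peptide_id[rows]
    f <- detect_features_one(mat, noise_floor, merge_overlap)
    if (is.null(f)) return(NULL)
    dplyr::bind_cols(tibble::tibble(protein_id = prot), f)
  })
  res
}

#' Detect protein elution features on the master map
#'
#' Per protein, peptide traces are smoothed (moving average, window 3) and
#' summed into a consensus trace; local maxima of the consensus above a
#' noise floor (1% of the consensus maximum) are candidate apexes, bounded
#' by the nearest flanking local minima (or the fraction limits). A peptide
#' participates in a feature when one of its own local maxima lies within
#' the feature boundaries. The co-elution score is the mean pairwise Pearson
#' correlation of participating peptides across the feature range, weighted
#' by the fraction of the protein's peptides that participate. The same
#' procedure on decoy proteins (peptides randomly reassigned to pseudo
#' proteins preserving the per-protein peptide-count distribution) yields
#' the null score distribution, from which a monotone q-value is computed
#' per score as `#decoy features >= s / #target features >= s`.
#'
#' @param master A [integrate_traces()] result. Rows flagged `decoy` are
#'   ignored; decoys are regenerated internally (seeded).
#' @param q_cutoff q-value cutoff for reported features (default 0.05).
#' @param seed Integer seed for the decoy peptide reassignment.
#' @param noise_floor Candidate-apex floor as a fraction of the consensus
#'   maximum (default 0.01).
#' @param merge_overlap Merge two candidate peaks when their ranges overlap
#'   by more than this fraction of the smaller width (default 0.5).
#' @return A `sec_features` tibble: `protein_id`, `feature_id`, `apex`,
#'   `left`, `right` (inclusive), participation and score columns, and
#'   `qvalue`. Features with fewer than 2 participating peptides are never
#'   reported.
#' @export
detect_protein_features <- function(master, q_cutoff = 0.05, seed = 1,
                                    noise_floor = 0.01, merge_overlap = 0.5) {
  targets <- master[!master$decoy, ]
  if (nrow(targets) == 0) abort("no target peptides in master traces")
  tf <- score_features_set(targets, noise_floor, merge_overlap)

  decoys <- targets
  set.seed(seed)
  decoys$protein_id <- sample(decoys$protein_id)
  decoys$peptide_id <- paste0("DECOY_", decoys$peptide_id)
  df <- score_features_set(decoys, noise_floor, merge_overlap)

  if (nrow(tf) == 0) {
    return(empty_features())
  }
  ds <- sort(df$coelution_score, decreasing = TRUE)
  ord <- order(tf$coelution_score, decreasing = TRUE)
  n_dec_ge <- findInterval(-tf$coelution_score[ord], -ds)
  fdr <- n_dec_ge / seq_along(ord)
  qv <- rev(cummin(rev(pmin(fdr, 1))))
  tf$qvalue <- NA_real_
  tf$qvalue[ord] <- qv
  tf <- tf[tf$qvalue <= q_cutoff, ]
  tf <- dplyr::arrange(tf, .data$protein_id, .data$apex)
  tf <- dplyr::mutate(
    dplyr::group_by(tf, .data$protein_id),
    feature_id = paste0(.data$protein_id, "_F", dplyr::row_number())
  )
  tf <- dplyr::ungroup(tf)
  tf <- dplyr::relocate(tf, "protein_id", "feature_id")
  class(tf) <- unique(c("sec_features", class(tf)))
  tf
}

empty_features <- function() {
  out <- tibble::tibble(
    protein_id = character(), feature_id = character(), apex = integer(),
    left = integer(), right = integer(), n_participating = integer(),
    n_peptides_total = integer(), participation = numeric(),
    mean_correlation = numeric(), coelution_score = numeric(),
    peptide_ids = list(), qvalue = numeric()
  )
  class(out) <- unique(c("sec_features", class(out)))
  out
}

#' Assign assembled/monomeric state to elution features
#'
#' A feature is called `assembled` when the apparent MW at its apex is at
#' least `factor` times the sequence-predicted monomer MW (boundary
#' inclusive), else `monomeric`. Features of proteins without an annotated
#' monomer MW are labelled `unknown`.
#'
#' @param features A [detect_protein_features()] result.
#' @param annotation Tibble with `protein_id`, `monomer_mw_kda`.
#' @param calibration A [fit_calibration()] result.
#' @param factor Assembled-call threshold on apparent/monomer MW (default 2).
#' @return `features` with columns `apparent_mw_kda`, `monomer_mw_kda`,
#'   `assembly_state` added.
#' @export
assign_assembly_state <- function(features, annotation, calibration,
                                  factor = 2) {
  out <- dplyr::left_join(
    features,
    dplyr::select(tibble::as_tibble(annotation), "protein_id",
                  "monomer_mw_kda"),
    by = "protein_id"
  )
  out$apparent_mw_kda <- apparent_mw(calibration, out$apex)
  out$assembly_state <- dplyr::case_when(
    is.na(out$monomer_mw_kda) ~ "unknown",
    out$apparent_mw_kda >= factor * out$monomer_mw_kda ~ "assembled",
    TRUE ~ "monomeric"
  )
  if (any(out$assembly_state == "unknown")) {
    inform(paste0(sum(out$assembly_state == "unknown"),
                  " feature(s) without monomer MW annotation -> 'unknown'"))
  }
  class(out) <- unique(c("sec_features", class(out)))
  out
}

#' Write / read a feature table
#' @param features A `sec_features` tibble.
#' @param path File path.
#' @return The features (invisibly for write).
#' @export
write_features <- function(features, path) {
  out <- dplyr::select(features, -dplyr::any_of("peptide_ids"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(features)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- unique(c("sec_features", class(out)))
  out
}
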