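#' Scale runs to the spike-in standard
#'
#' Each run (condition x replicate) is multiplied by a single factor so that
#' the total signal of the spike-in standard peptides is identical across
#' runs; the reference level is the median of the per-run standard totals.
#' This compensates global run-to-run intensity drift (e.g. declining MS
#' response over a large fraction series).
#'
#' @param traces A [sec_traces()] object.
#' @param design A [sec_design()] whose `standard_protein` identifies the
#'   spike-in; every run must contain at least one standard peptide with
#'   nonzero total signal.
#' @return The scaled `sec_traces`, with the per-run factors attached as
#'   attribute `"scale_factors"` (see [scale_factors()]).
#' @export
normalize_to_standard <- function(traces, design) {
  std_prot <- design$standard_protein
  if (is.null(std_prot)) abort("design has no `standard_protein`")
  is_std <- traces$protein_id == std_prot
  if (!any(is_std)) abort(paste0("no peptides of standard '", std_prot, "'"))
  runs <- run_table(traces)
  run_key <- paste(traces$condition, traces$replicate, sep = "\r")
  runs$key <- paste(runs$condition, runs$replicate, sep = "\r")
  std_tot <- vapply(runs$key, function(k) {
    sum(traces$intensity[is_std & run_key == k, , drop = FALSE])
  }, numeric(1))
  if (any(std_tot <= 0)) {
    bad <- runs[which(std_tot <= 0)[1], ]
    abort(paste0("run ", bad$condition, "/replicate ", bad$replicate,
                 " has zero standard signal"))
  }
  ref <- median(std_tot)
  factor <- ref / std_tot
  m <- traces$intensity * factor[match(run_key, runs$key)]
  out <- traces
  out$intensity <- m
  attr(out, "scale_factors") <- tibble::tibble(
    condition = runs$condition, replicate = runs$replicate,
    standard_total = unname(std_tot), factor = unname(factor)
  )
  out
}

#' Per-run normalization factors of the last [normalize_to_standard()] call
#' @param traces A `sec_traces` returned by [normalize_to_standard()].
#' @return A tibble with one row per run.
#' @export
scale_factors <- function(traces) attr(traces, "scale_factors")

#' Smooth per-fraction total intensities
#'
#' Within each run, the total MS intensity per fraction is fit with a cubic
#' smoothing spline over fraction number (smoothing level by generalized
#' cross-validation) and every fraction is rescaled by
#' `spline value / observed total`. Within-fraction peptide proportions are
#' untouched; only the fraction-to-fraction envelope is smoothed, removing
#' single-injection artifacts.
#'
#' @param traces A [sec_traces()] object (normalized).
#' @return The rescaled `sec_traces`.
#' @export
smooth_total_intensity <- function(traces) {
  runs <- run_table(traces)
  run_key <- paste(traces$condition, traces$replicate, sep = "\r")
  m <- traces$intensity
  fr <- seq_len(ncol(m))
  warned <- FALSE
  for (k in paste(runs$condition, runs$replicate, sep = "\r")) {
    rows <- which(run_key == k)
    if (length(rows) == 0) next
    tot <- colSums(m[rows, , drop = FALSE])
    pos <- tot > 0
    if (sum(pos) < 4) next
    fit <- smooth.spline(fr[pos], tot[pos])
    sf <- rep(1, length(fr))
    sf[pos] <- pmax(predict(fit, fr[pos])$y, 0) / tot[pos]
    if (any(!pos) && !warned) {
      warn("fractions with zero total intensity left unscaled")
      warned <- TRUE
    }
    m[rows, ] <- sweep(m[rows, , drop = FALSE], 2, sf, `*`)
  }
  out <- traces
  out$intensity <- m
  out
}

# impute internal zero gaps of one trace by a natural cubic spline through
# its nonzero points; a gap qualifies when the nonzero runs immediately left
# and right of it are both at least `min_flank` long
impute_trace <- function(v, min_flank = 2) {
  nz <- v > 0
  if (sum(nz) < 2) return(v)
  first <- which(nz)[1]
  last <- which(nz)[sum(nz)]
  if (all(nz[first:last])) return(v)
  r <- rle(nz)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  fill <- integer(0)
  for (j in seq_along(r$lengths)) {
    if (r$values[j]) next
    if (j == 1 || j == length(r$lengths)) next    # leading/trailing zeros
    if (r$lengths[j - 1] >= min_flank && r$lengths[j + 1] >= min_flank) {
      fill <- c(fill, starts[j]:ends[j])
    }
  }
  if (length(fill) == 0) return(v)
  xs <- which(nz)
  v[fill] <- pmax(spline(xs, v[xs], xout = fill, method = "natural")$y, 0)
  v
}

#' Impute internal detection gaps by spline interpolation
#'
#' Internal zero stretches flanked on both sides by at least `min_flank`
#' consecutive nonzero fractions are replaced by a natural cubic spline
#' interpolation through the trace's nonzero points, floored at 0. Observed
#' (nonzero) values and leading/trailing zeros are never modified. The
#' operation is idempotent.
#'
#' @param traces A [sec_traces()] object.
#' @param min_flank Minimum length of the flanking nonzero runs (default 2).
#' @return The imputed `sec_traces`.
#' @export
impute_missing <- function(traces, min_flank = 2) {
  m <- traces$intensity
  for (i in seq_len(nrow(m))) {
    m[i, ] <- impute_trace(m[i, ], min_flank = min_flank)
  }
  out <- traces
  out$intensity <- m
  out
}

#' Remove short identification stretches
#'
#' Nonzero runs shorter than `min_run` consecutive fractions are set to 0
#' (isolated identifications are unreliable in co-fractionation data). Run
#' entries left entirely zero are dropped.
#'
#' @param traces A [sec_traces()] object.
#' @param min_run Minimum run length kept (default 3; a run of exactly
#'   `min_run` is kept).
#' @return The filtered `sec_traces`.
#' @export
filter_consecutive <- function(traces, min_run = 3) {
  m <- traces$intensity
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    nz <- v > 0
    if (!any(nz)) next
    r <- rle(nz)
    if (!any(r$values & r$lengths < min_run)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values & r$lengths < min_run)) {
      v[starts[j]:ends[j]] <- 0
    }
    m[i, ] <- v
  }
  out <- traces
  out$intensity <- m
  keep <- rowSums(m) > 0
  out <- out[keep, ]
  new_sec_traces(out)
}

#' Filter peptides by average sibling peptide correlation
#'
#' For each peptide, `spc` is the mean Pearson correlation of its
#' run-concatenated fractionation profile with those of its sibling peptides
#' (other peptides of the same protein). Peptides with `spc` below a cutoff
#' are removed; the cutoff is chosen as the smallest value on a scanned grid
#' at which the decoy rate among surviving protein entries
#' (decoy proteins passing / target proteins passing) is at or below
#' `target_decoy_rate`. Proteins left with fewer than 2 peptides are
#' dropped entirely.
#'
#' @param traces A [sec_traces()] containing decoy proteins (`decoy == TRUE`)
#'   for calibration of the cutoff.
#' @param target_decoy_rate Decoy-rate target (default 0.03).
#' @param grid Cutoff grid scanned in ascending order (default
#'   `seq(0.28, 0.34, by = 0.01)`).
#' @return The filtered `sec_traces` with a [filter_report()] attached.
#' @export
sibling_correlation_filter <- function(traces, target_decoy_rate = 0.03,
                                       grid = seq(0.28, 0.34, by = 0.01)) {
  runs <- run_table(traces)
  nf <- n_fractions(traces)
  peps <- dplyr::distinct(
    tibble::as_tibble(traces[c("peptide_id", "protein_id", "decoy")])
  )
  # run-concatenated profile per peptide (zeros for runs without an entry)
  wide <- matrix(0, nrow = nrow(peps), ncol = nf * nrow(runs))
  row_of <- setNames(seq_len(nrow(peps)), peps$peptide_id)
  run_of <- setNames(seq_len(nrow(runs)),
                     paste(runs$condition, runs$replicate, sep = "\r"))
  blk <- run_of[paste(traces$condition, traces$replicate, sep = "\r")]
  wide[cbind(
    rep(row_of[traces$peptide_id], each = nf),
    rep((blk - 1) * nf, each = nf) + seq_len(nf)
  )] <- as.vector(t(traces$intensity))
  spc <- rep(NA_real_, nrow(peps))
  for (rows in split(seq_len(nrow(peps)), peps$protein_id)) {
    if (length(rows) < 2) next
    cc <- suppressWarnings(cor(t(wide[rows, , drop = FALSE])))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- NA
    spc[rows] <- rowMeans(cc, na.rm = TRUE)
  }
  grid <- sort(grid)
  rate_at <- function(cut) {
    keep <- !is.na(spc) & spc >= cut
    prot <- peps[keep, ]
    counts <- table(prot$protein_id)
    ok <- names(counts)[counts >= 2]
    dec <- peps$decoy[match(ok, peps$protein_id)]
    c(n_target = sum(!dec), n_decoy = sum(dec))
  }
  chosen <- NULL
  warned <- FALSE
  for (cut in grid) {
    ct <- rate_at(cut)
    rate <- if (ct["n_target"] > 0) ct["n_decoy"] / ct["n_target"] else Inf
    if (rate <= target_decoy_rate) {
      chosen <- cut
      break
    }
  }
  if (is.null(chosen)) {
    chosen <- max(grid)
    warned <- TRUE
    warn(sprintf(
      "no cutoff on the grid reaches decoy rate <= %g; using most stringent (%g)",
      target_decoy_rate, chosen
    ))
  }
  ct <- rate_at(chosen)
  keep_pep <- peps$peptide_id[!is.na(spc) & spc >= chosen]
  out <- traces[traces$peptide_id %in% keep_pep, ]
  # drop proteins left with < 2 peptides
  pp <- dplyr::distinct(tibble::as_tibble(out[c("peptide_id", "protein_id")]))
  n_per <- table(pp$protein_id)
  out <- out[out$protein_id %in% names(n_per)[n_per >= 2], ]
  out <- new_sec_traces(out)
  attr(out, "filter_report") <- structure(
    list(
      spc_cutoff = chosen,
      n_target_proteins_pass = unname(ct["n_target"]),
      n_decoy_proteins_pass = unname(ct["n_decoy"]),
      decoy_rate = unname(ct["n_decoy"] / ct["n_target"]),
      target_not_reached = warned,
      spc = tibble::tibble(peptide_id = peps$peptide_id,
                           protein_id = peps$protein_id,
                           decoy = peps$decoy, spc = spc)
    ),
    class = "sec_filter_report"
  )
  out
}

#' Report of the last [sibling_correlation_filter()] call
#' @param traces A `sec_traces` returned by [sibling_correlation_filter()].
#' @return A `sec_filter_report` list: chosen `spc_cutoff`, pass counts,
#'   `decoy_rate`, and the per-peptide `spc` table.
#' @export
filter_report <- function(traces) attr(traces, "filter_report")

#' @export
print.sec_filter_report <- function(x, ...) {
  cat(sprintf(
    "<filter report> spc cutoff %.2f | %d targets, %d decoys pass | decoy rate %.3f%s\n",
    x$spc_cutoff, x$n_target_proteins_pass, x$n_decoy_proteins_pass,
    x$decoy_rate, if (x$target_not_reached) " (target rate not reached)" else ""
  ))
  invisible(x)
}

#' Target-decoy protein FDR with correction for absent targets
#'
#' The naive target-decoy FDR overestimates errors when many library targets
#' are genuinely absent from the sample. The corrected estimate scales the
#' decoy count by `pi_A`, the estimated fraction of absent targets:
#' `pi_A = (library_size - n_detected) / library_size` and
#' `FDR = n_decoys_pass * pi_A / n_detected`.
#'
#' @param library_size Number of target proteins queryable in the library.
#' @param n_detected Number of target proteins passing all filters (> 0).
#' @param n_decoys_pass Number of decoy entries passing the same filters.
#' @return A one-row tibble: `library_size`, `n_detected`, `n_decoys_pass`,
#'   `decoy_rate`, `pi_a`, `fdr`.
#' @export
#' @examples
#' estimate_protein_fdr(5916, 5044, 135)
estimate_protein_fdr <- function(library_size, n_detected, n_decoys_pass) {
  if (n_detected <= 0) abort("n_detected must be > 0")
  if (n_detected > library_size) abort("n_detected exceeds library_size")
  if (min(library_size, n_decoys_pass) < 0) abort("counts must be >= 0")
  pi_a <- (library_size - n_detected) / library_size
  tibble::tibble(
    library_size = library_size, n_detected = n_detected,
    n_decoys_pass = n_decoys_pass,
    decoy_rate = n_decoys_pass / n_detected,
    pi_a = pi_a,
    fdr = n_decoys_pass * pi_a / n_detected
  )
}

#' Protein quantification from the top-2 peptides
#'
#' Per protein, the two peptides with the highest cumulative intensity
#' (summed over all fractions and runs) are selected once, and their traces
#' are summed within each run. Fixing the peptide pair across runs prevents
#' run-dependent peptide switching from creating artifactual differences.
#' Ties at rank 2 are broken by lexicographic peptide id.
#'
#' @param traces A filtered [sec_traces()] object.
#' @return A `sec_protein_traces` tibble: `protein_id`, `condition`,
#'   `replicate`, `decoy` and matrix column `intensity`. Proteins with fewer
#'   than 2 peptides are excluded (with a message).
#' @export
protein_quant_top2 <- function(traces) {
  peps <- dplyr::distinct(
    tibble::as_tibble(traces[c("peptide_id", "protein_id", "decoy")])
  )
  tot <- rowsum(rowSums(traces$intensity), traces$peptide_id)
  peps$total <- tot[match(peps$peptide_id, rownames(tot)), 1]
  peps$total[is.na(peps$total)] <- 0
  peps <- dplyr::arrange(peps, .data$protein_id, dplyr::desc(.data$total),
                         .data$peptide_id)
  top2 <- dplyr::slice_head(dplyr::group_by(peps, .data$protein_id), n = 2)
  n_per <- dplyr::count(top2, .data$protein_id)
  dropped <- n_per$protein_id[n_per$n < 2]
  if (length(dropped) > 0) {
    inform(paste0(length(dropped),
                  " protein(s) with < 2 peptides excluded from quantification"))
  }
  top2 <- dplyr::ungroup(top2)
  top2 <- top2[!top2$protein_id %in% dropped, ]
  sel <- traces[traces$peptide_id %in% top2$peptide_id, ]
  grp <- paste(sel$protein_id, sel$condition, sel$replicate, sep = "\r")
  m <- rowsum(sel$intensity, grp, reorder = TRUE)
  parts <- strsplit(rownames(m), "\r", fixed = TRUE)
  out <- tibble::tibble(
    protein_id = vapply(parts, `[`, "", 1),
    condition = vapply(parts, `[`, "", 2),
    replicate = as.integer(vapply(parts, `[`, "", 3)),
    decoy = peps$decoy[match(vapply(parts, `[`, "", 1), peps$protein_id)]
  )
  rownames(m) <- NULL
  out$intensity <- m
  class(out) <- unique(c("sec_protein_traces", class(out)))
  out
}
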