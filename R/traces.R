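#' Peptide co-fractionation traces
#'
#' `sec_traces` is the central data container of the package: a tibble with
#' one row per (peptide, condition, replicate) run entry and a matrix column
#' `intensity` whose columns are the SEC fractions (1-based, contiguous).
#' An intensity of 0 encodes "not detected"; true measured zeros are not
#' distinguishable from missing values, matching the behaviour of targeted
#' DIA extraction upstream.
#'
#' @param data A data frame with columns `peptide_id`, `protein_id`,
#'   `condition`, `replicate`, `decoy` and a numeric matrix column
#'   `intensity` (one column per fraction), or the long columns `fraction`
#'   and `intensity` (one row per observed fraction).
#' @param n_fractions Total number of fractions. Required when `data` is in
#'   long format and the largest observed fraction understates the design.
#'
#' @return A `sec_traces` tibble.
#' @export
sec_traces <- function(data, n_fractions = NULL) {
  if (!is.matrix(data[["intensity"]])) {
    return(traces_from_long(data, n_fractions))
  }
  out <- tibble::as_tibble(data)
  validate_sec_traces(new_sec_traces(out))
}

new_sec_traces <- function(df) {
  class(df) <- unique(c("sec_traces", class(tibble::tibble())))
  df
}

validate_sec_traces <- function(x) {
  need <- c("peptide_id", "protein_id", "condition", "replicate", "decoy",
            "intensity")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("sec_traces is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  m <- x$intensity
  if (!is.matrix(m) || !is.numeric(m)) {
    abort("`intensity` must be a numeric matrix column (rows x fractions)")
  }
  if (nrow(x) > 0) {
    if (anyNA(m) || any(!is.finite(m))) {
      abort("intensities must be finite and non-missing")
    }
    if (any(m < 0)) abort("intensities must be >= 0")
    key <- paste(x$peptide_id, x$condition, x$replicate, sep = "\r")
    if (anyDuplicated(key)) {
      abort("duplicate (peptide, condition, replicate) entries")
    }
    p2p <- unique(x[, c("peptide_id", "protein_id")])
    if (anyDuplicated(p2p$peptide_id)) {
      bad <- p2p$peptide_id[duplicated(p2p$peptide_id)][1]
      abort(paste0("peptide mapped to more than one protein: ", bad))
    }
  }
  x
}

traces_from_long <- function(data, n_fractions = NULL) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0 && is.null(n_fractions)) {
    abort("empty long table needs an explicit `n_fractions`")
  }
  nf <- n_fractions %||% max(data$fraction)
  if (nrow(data) > 0) {
    fr <- data$fraction
    if (any(fr < 1 | fr != round(fr))) abort("fractions must be integers >= 1")
    if (any(fr > nf)) abort("fraction index exceeds `n_fractions`")
  }
  if (!"decoy" %in% names(data)) data$decoy <- FALSE
  keys <- dplyr::distinct(
    data, .data$peptide_id, .data$protein_id, .data$condition,
    .data$replicate, decoy = as.logical(.data$decoy)
  )
  m <- matrix(0, nrow = nrow(keys), ncol = nf)
  if (nrow(data) > 0) {
    row_of <- stats::setNames(
      seq_len(nrow(keys)),
      paste(keys$peptide_id, keys$condition, keys$replicate, sep = "\r")
    )
    i <- row_of[paste(data$peptide_id, data$condition, data$replicate,
                      sep = "\r")]
    # precursor rows sharing a peptide/fraction are summed
    idx <- cbind(i, data$fraction)
    agg <- rowsum(data$intensity, group = paste(i, data$fraction), reorder = FALSE)
    first <- !duplicated(paste(i, data$fraction))
    m[idx[first, , drop = FALSE]] <- agg[, 1]
  }
  keys$intensity <- m
  validate_sec_traces(new_sec_traces(keys))
}

#' Number of fractions of a traces object
#' @param x A `sec_traces` (or protein-level traces) object.
#' @return Integer count of SEC fractions.
#' @export
n_fractions <- function(x) ncol(x$intensity)

#' @export
print.sec_traces <- function(x, ...) {
  cat(sprintf(
    "<sec_traces> %d run entries | %d peptides | %d proteins | %d fractions\n",
    nrow(x), dplyr::n_distinct(x$peptide_id),
    dplyr::n_distinct(x$protein_id), n_fractions(x)
  ))
  NextMethod()
}

#' Read a long-format peptide quantification table
#'
#' Reads a tab-separated table with columns `peptide_id`, `protein_id`,
#' `condition`, `replicate`, `fraction`, `intensity`, `decoy` (0/1), the
#' shape produced by targeted DIA extraction and alignment. Rows sharing the
#' same peptide, run and fraction (precursor charge states) are summed;
#' fraction/run combinations absent from the file are 0.
#'
#' @param path Path to the TSV file.
#' @param design A [sec_design()] describing conditions and replicates;
#'   rows with conditions or replicates not in the design are an error.
#' @param n_fractions Number of fractions; defaults to the design's
#'   `n_fractions` if set, else the largest observed fraction.
#' @return A [sec_traces()] object.
#' @export
read_traces <- function(path, design = NULL, n_fractions = NULL) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      peptide_id = readr::col_character(),
      protein_id = readr::col_character(),
      condition = readr::col_character(),
      replicate = readr::col_integer(),
      fraction = readr::col_integer(),
      intensity = readr::col_character(),
      decoy = readr::col_integer()
    ),
    progress = FALSE
  )
  need <- c("peptide_id", "protein_id", "condition", "replicate", "fraction",
            "intensity", "decoy")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("trace table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ints <- suppressWarnings(as.numeric(raw$intensity))
  bad <- which(is.na(ints) & !is.na(raw$intensity))
  if (length(bad) > 0) {
    abort(paste0("non-numeric intensity at data row ", bad[1], ": '",
                 raw$intensity[bad[1]], "'"))
  }
  if (anyNA(ints) && nrow(raw) > 0) abort("missing intensity values")
  raw$intensity <- ints
  if (!is.null(design)) {
    bad_cond <- setdiff(unique(raw$condition), design$conditions)
    if (length(bad_cond) > 0) {
      abort(paste0("unknown condition(s): ", paste(bad_cond, collapse = ", ")))
    }
    bad_rep <- setdiff(unique(raw$replicate), design$replicates)
    if (length(bad_rep) > 0) {
      abort(paste0("unknown replicate(s): ", paste(bad_rep, collapse = ", ")))
    }
    n_fractions <- n_fractions %||% design$n_fractions
  }
  raw$decoy <- as.logical(raw$decoy)
  traces_from_long(raw, n_fractions = n_fractions %||%
                     (if (nrow(raw) > 0) max(raw$fraction) else 1L))
}

#' Write traces to a long-format TSV
#'
#' Writes the nonzero intensities in the long format read by
#' [read_traces()]. Run entries whose trace is entirely zero are written as
#' a single zero-intensity row so the entry set round-trips.
#'
#' @param traces A [sec_traces()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  long <- traces_to_long(traces, keep_zero_entry = TRUE)
  long$decoy <- as.integer(long$decoy)
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}

traces_to_long <- function(traces, keep_zero_entry = FALSE) {
  m <- traces$intensity
  nz <- which(m > 0, arr.ind = TRUE)
  out <- tibble::tibble(
    peptide_id = traces$peptide_id[nz[, 1]],
    protein_id = traces$protein_id[nz[, 1]],
    condition = traces$condition[nz[, 1]],
    replicate = traces$replicate[nz[, 1]],
    fraction = as.integer(nz[, 2]),
    intensity = m[nz],
    decoy = traces$decoy[nz[, 1]]
  )
  if (keep_zero_entry) {
    empty <- which(rowSums(m) == 0)
    if (length(empty) > 0) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        peptide_id = traces$peptide_id[empty],
        protein_id = traces$protein_id[empty],
        condition = traces$condition[empty],
        replicate = traces$replicate[empty],
        fraction = 1L,
        intensity = 0,
        decoy = traces$decoy[empty]
      ))
    }
  }
  dplyr::arrange(out, .data$peptide_id, .data$condition, .data$replicate,
                 .data$fraction)
}

#' Experimental design of a two-condition SEC experiment
#'
#' @param conditions Character vector of exactly two condition ids, ordered;
#'   fold changes are reported as `conditions[2]` over `conditions[1]`.
#' @param replicates Integer vector of replicate indices shared by both
#'   conditions; replicates are paired across conditions by index (the paired
#'   t-test requirement).
#' @param standard_protein Protein id of the spike-in standard; its peptides
#'   drive run normalization.
#' @param n_fractions Optional number of SEC fractions collected.
#' @return A `sec_design` list.
#' @export
sec_design <- function(conditions, replicates = 1:3, standard_protein = NULL,
                       n_fractions = NULL) {
  if (length(conditions) != 2) {
    abort("differential testing requires exactly 2 conditions")
  }
  replicates <- as.integer(replicates)
  if (length(replicates) < 1) abort("at least one replicate is required")
  structure(
    list(conditions = as.character(conditions), replicates = replicates,
         standard_protein = standard_protein, n_fractions = n_fractions),
    class = "sec_design"
  )
}

#' @export
print.sec_design <- function(x, ...) {
  cat("<sec_design>\n  conditions: ", paste(x$conditions, collapse = ", "),
      "\n  replicates: ", paste(x$replicates, collapse = ", "),
      "\n  standard:   ", x$standard_protein %||% "<none>", "\n", sep = "")
  invisible(x)
}

#' Read / write an experimental design YAML file
#'
#' The YAML file lists `conditions` (2), `replicates`, the spike-in
#' `standard_protein` and optionally `n_fractions`.
#'
#' @param path File path.
#' @return [read_design()] returns a [sec_design()].
#' @export
read_design <- function(path) {
  y <- yaml::read_yaml(path)
  sec_design(
    conditions = y$conditions,
    replicates = y$replicates %||% 1:3,
    standard_protein = y$standard_protein,
    n_fractions = y$n_fractions
  )
}

#' @rdname read_design
#' @param design A [sec_design()].
#' @export
write_design <- function(design, path) {
  yaml::write_yaml(
    list(conditions = design$conditions,
         replicates = as.integer(design$replicates),
         standard_protein = design$standard_protein,
         n_fractions = design$n_fractions),
    path
  )
  invisible(path)
}

#' Read a protein annotation table
#'
#' TSV with columns `protein_id`, `monomer_mw_kda` (sequence-predicted
#' monomer molecular weight in kDa).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_annotation <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    monomer_mw_kda = readr::col_double()
  ), progress = FALSE)
  if (any(out$monomer_mw_kda <= 0)) abort("monomer MW must be > 0")
  out
}

#' Read a complex prior table (CORUM-style)
#'
#' TSV with columns `complex_id`, `complex_name`, `subunits`
#' (semicolon-separated protein ids) and optionally `go_terms`. Returned in
#' long form with one row per (complex, subunit).
#'
#' @param path File path.
#' @return A tibble with columns `complex_id`, `complex_name`, `protein_id`.
#' @export
read_complexes <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  out <- tidyr::separate_rows(raw, "subunits", sep = ";")
  out <- dplyr::rename(out, protein_id = "subunits")
  out <- dplyr::distinct(out, .data$complex_id, .data$protein_id,
                         .keep_all = TRUE)
  dplyr::select(out, "complex_id", dplyr::any_of(c("complex_name")),
                "protein_id", dplyr::any_of("go_terms"))
}

# internal: stable run key ordering (condition-major, replicate-minor)
run_table <- function(traces_or_design) {
  if (inherits(traces_or_design, "sec_design")) {
    d <- traces_or_design
    tidyr::expand_grid(condition = d$conditions, replicate = d$replicates)
  } else {
    dplyr::arrange(
      dplyr::distinct(tibble::as_tibble(traces_or_design[c("condition",
                                                           "replicate")])),
      .data$condition, .data$replicate
    )
  }
}
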