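# build a sec_traces object from per-run trace vectors:
# traces_list is a named list peptide_id -> list(protein, runs) where runs is
# a list of condition -> list of replicate vectors
make_traces <- function(vectors, protein_of, conditions = c("c1", "c2"),
                        replicates = 1, decoy_of = NULL) {
  rows <- list()
  for (pep in names(vectors)) {
    v <- vectors[[pep]]
    for (cond in conditions) {
      for (rep in replicates) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          peptide_id = pep, protein_id = protein_of[[pep]],
          condition = cond, replicate = as.integer(rep),
          decoy = if (is.null(decoy_of)) FALSE else
            isTRUE(decoy_of[[protein_of[[pep]]]])
        )
      }
    }
  }
  keys <- dplyr::bind_rows(rows)
  keys$intensity <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    vectors[[keys$peptide_id[i]]]
  }))
  secshift::sec_traces(keys)
}

make_design <- function(conditions = c("c1", "c2"), replicates = 1:3,
                        standard_protein = NULL, n_fractions = NULL) {
  secshift::sec_design(conditions, replicates, standard_protein, n_fractions)
}

gaussian_trace <- function(nf, apex, sigma, amplitude = 1) {
  f <- seq_len(nf)
  amplitude * exp(-(f - apex)^2 / (2 * sigma^2))
}

# two-point log-linear calibration through (fraction 10, 1000 kDa) and
# (fraction 30, 10 kDa)
two_point_calibration <- function() {
  secshift::fit_calibration(tibble::tibble(
    protein = c("s1", "s2"), mw_kda = c(1000, 10), apex_fraction = c(10, 30)
  ))
}

# a feature table row for tests that bypass detection
feature_row <- function(protein_id, feature_id, left, right,
                        apex = NA_integer_, assembly_state = NULL) {
  out <- tibble::tibble(protein_id = protein_id, feature_id = feature_id,
                        left = as.integer(left), right = as.integer(right),
                        apex = as.integer(apex))
  if (!is.null(assembly_state)) out$assembly_state <- assembly_state
  out
}
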