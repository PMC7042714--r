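test_that("normalization equalizes standard totals, scaling the outlier run", {
  nf <- 10
  std <- c(rep(100, nf))
  vecs <- list(std_pep = std, pepA = gaussian_trace(nf, 5, 1, 1000))
  tr <- make_traces(vecs, list(std_pep = "STD", pepA = "P1"),
                    conditions = c("c1", "c2"), replicates = 1:3)
  # double every intensity of run (c1, 1): its standard total is 2x the rest
  hot <- tr$condition == "c1" & tr$replicate == 1
  tr$intensity[hot, ] <- tr$intensity[hot, ] * 2
  d <- make_design(standard_protein = "STD")
  out <- normalize_to_standard(tr, d)
  sf <- scale_factors(out)
  expect_equal(sf$factor[sf$condition == "c1" & sf$replicate == 1], 0.5)
  expect_equal(sort(unique(round(sf$factor[-(1)], 9))), 1)
  # defining property: per-run standard totals equal after scaling
  std_rows <- out$protein_id == "STD"
  totals <- rowSums(out$intensity[std_rows, , drop = FALSE])
  expect_lt(diff(range(totals)) / mean(totals), 1e-9)
})

test_that("normalization is the identity when runs agree, errors on dead runs", {
  nf <- 8
  vecs <- list(s = rep(10, nf), a = gaussian_trace(nf, 4, 1))
  tr <- make_traces(vecs, list(s = "STD", a = "P1"), replicates = 1:2)
  d <- make_design(replicates = 1:2, standard_protein = "STD")
  out <- normalize_to_standard(tr, d)
  expect_equal(out$intensity, tr$intensity, ignore_attr = TRUE)
  expect_true(all(scale_factors(out)$factor == 1))

  tr$intensity[tr$protein_id == "STD" & tr$condition == "c2" &
                 tr$replicate == 2, ] <- 0
  expect_error(normalize_to_standard(tr, d), "zero standard signal")
})

test_that("total-intensity smoothing is near-identity on smooth totals and preserves proportions", {
  nf <- 65
  f <- seq_len(nf)
  total <- 0.02 * (f - 30)^3 + 1.5 * (f - 10)^2 + 4000  # exact cubic
  vecs <- list(a = 0.7 * total, b = 0.3 * total)
  tr <- make_traces(vecs, list(a = "P1", b = "P1"), replicates = 1)
  out <- smooth_total_intensity(tr)
  expect_lt(max(abs(out$intensity / tr$intensity - 1)), 1e-6)

  # a single spiked fraction is scaled toward the spline; ratios preserved
  spiked <- vecs
  spiked$a[20] <- spiked$a[20] * 10
  spiked$b[20] <- spiked$b[20] * 10
  tr2 <- make_traces(spiked, list(a = "P1", b = "P1"), replicates = 1)
  out2 <- smooth_total_intensity(tr2)
  a2 <- out2$intensity[out2$peptide_id == "a" & out2$condition == "c1", ]
  b2 <- out2$intensity[out2$peptide_id == "b" & out2$condition == "c1", ]
  expect_lt(a2[20], spiked$a[20])                 # spike pulled down
  expect_equal(a2 / b2, rep(0.7 / 0.3, nf), tolerance = 1e-12)
})

test_that("gap imputation matches an independent natural-spline solution", {
  v <- c(4, 8, 0, 6, 3)
  tr <- make_traces(list(a = v, b = v), list(a = "P1", b = "P1"),
                    replicates = 1)
  out <- impute_missing(tr)
  got <- out$intensity[1, ]
  expect_equal(got[-3], v[-3])                    # observed values untouched
  expect_gt(got[3], 0)
  expect_true(is.finite(got[3]))
  # independent oracle: natural cubic spline through {(1,4),(2,8),(4,6),(5,3)}
  # built from the defining linear system (second derivative 0 at the ends)
  x <- c(1, 2, 4, 5); y <- c(4, 8, 6, 3)
  h <- diff(x)
  A <- matrix(0, 2, 2); rhs <- numeric(2)
  # interior second-derivative equations for knots 2 and 3
  A[1, ] <- c(2 * (h[1] + h[2]), h[2])
  rhs[1] <- 6 * ((y[3] - y[2]) / h[2] - (y[2] - y[1]) / h[1])
  A[2, ] <- c(h[2], 2 * (h[2] + h[3]))
  rhs[2] <- 6 * ((y[4] - y[3]) / h[3] - (y[3] - y[2]) / h[2])
  m <- c(0, solve(A, rhs), 0)                     # M1..M4
  i <- 2; t <- 3                                   # evaluate on [x2, x3] at 3
  dx1 <- t - x[i]; dx2 <- x[i + 1] - t
  oracle <- (m[i] * dx2^3 + m[i + 1] * dx1^3) / (6 * h[i]) +
    (y[i] / h[i] - m[i] * h[i] / 6) * dx2 +
    (y[i + 1] / h[i] - m[i + 1] * h[i] / 6) * dx1
  expect_equal(got[3], max(oracle, 0), tolerance = 1e-9)
})

test_that("imputation respects boundary rules and is idempotent", {
  vecs <- list(
    lead = c(0, 0, 5, 6, 7),        # leading zeros: not flanked, untouched
    trail = c(5, 6, 7, 0, 0),
    none = c(1, 2, 3, 4, 5),
    short_flank = c(4, 0, 6, 7, 8)  # left flank run length 1: untouched
  )
  tr <- make_traces(vecs, list(lead = "P1", trail = "P1", none = "P1",
                               short_flank = "P1"), replicates = 1)
  out <- impute_missing(tr)
  expect_equal(out$intensity, tr$intensity, ignore_attr = TRUE)

  set.seed(3)
  v <- c(2, 4, 6, 0, 0, 5, 4, 3, 0, 2, 2, 0, 0)
  tr2 <- make_traces(list(a = v, b = v), list(a = "P2", b = "P2"),
                     replicates = 1)
  once <- impute_missing(tr2)
  twice <- impute_missing(once)
  expect_identical(once$intensity, twice$intensity)
  expect_equal(once$intensity[1, v > 0], v[v > 0])   # nonzero never modified
})

test_that("consecutive-run filter removes short stretches and is idempotent", {
  vecs <- list(
    a = c(0, 0, 5, 0, 0, 3, 4, 6, 0),   # 5 is a singleton -> removed
    b = c(1, 2, 3),
    c = c(1, 0, 2)                       # all-isolated -> dropped entirely
  )
  tr <- make_traces(vecs["a"], list(a = "P1"), replicates = 1)
  out <- filter_consecutive(tr)
  expect_equal(out$intensity[1, ], c(0, 0, 0, 0, 0, 3, 4, 6, 0),
               ignore_attr = TRUE)

  tr3 <- make_traces(vecs["b"], list(b = "P1"), replicates = 1)
  expect_equal(filter_consecutive(tr3)$intensity[1, ], c(1, 2, 3),
               ignore_attr = TRUE)

  tr4 <- make_traces(vecs["c"], list(c = "P1"), replicates = 1)
  expect_equal(nrow(filter_consecutive(tr4)), 0)

  # property: after filtering, no nonzero run is shorter than min_run
  set.seed(11)
  for (i in 1:20) {
    v <- rbinom(30, 1, 0.5) * runif(30, 1, 10)
    tr5 <- make_traces(list(p = v, q = v), list(p = "PX", q = "PX"),
                       replicates = 1)
    f1 <- filter_consecutive(tr5)
    if (nrow(f1) == 0) next
    runs <- rle(f1$intensity[1, ] > 0)
    expect_true(all(runs$lengths[runs$values] >= 3))
    expect_identical(filter_consecutive(f1)$intensity, f1$intensity)
  }
})

test_that("sibling correlation keeps concordant peptides and drops outliers", {
  nf <- 20
  shape <- gaussian_trace(nf, 10, 2, 100)
  vecs <- list(
    p1 = shape, p2 = 2 * shape, p3 = 0.5 * shape,
    bad = max(shape) - shape + 1               # anti-correlated mirror
  )
  tr <- make_traces(vecs, list(p1 = "P1", p2 = "P1", p3 = "P1", bad = "P1"),
                    replicates = 1)
  out <- sibling_correlation_filter(tr, grid = seq(0.28, 0.34, 0.01))
  rep <- filter_report(out)
  spc <- rep$spc
  expect_true(all(spc$spc[spc$peptide_id %in% c("p1", "p2", "p3")] > 0.3))
  expect_lt(spc$spc[spc$peptide_id == "bad"], 0)
  expect_false("bad" %in% out$peptide_id)
  expect_true(all(c("p1", "p2", "p3") %in% out$peptide_id))
})

test_that("spc cutoff is selected by a brute-force-verifiable decoy scan", {
  set.seed(21)
  nf <- 30
  n_prot <- 40
  vecs <- list(); prot <- list(); decoy <- list()
  for (i in seq_len(n_prot)) {
    pid <- sprintf("T%02d", i)
    shape <- gaussian_trace(nf, runif(1, 6, 24), runif(1, 1.5, 2.5), 1000)
    for (j in 1:3) {
      pep <- sprintf("%s_p%d", pid, j)
      vecs[[pep]] <- shape * rlnorm(1, 0, 0.5) * rlnorm(nf, 0, 0.2)
      prot[[pep]] <- pid
    }
    decoy[[pid]] <- FALSE
  }
  for (i in seq_len(8)) {       # decoys: unrelated shapes grouped together
    pid <- sprintf("D%02d", i)
    for (j in 1:3) {
      pep <- sprintf("%s_p%d", pid, j)
      vecs[[pep]] <- gaussian_trace(nf, runif(1, 6, 24), runif(1, 1, 3), 1000) *
        rlnorm(nf, 0, 0.3)
      prot[[pep]] <- pid
    }
    decoy[[pid]] <- TRUE
  }
  tr <- make_traces(vecs, prot, replicates = 1, decoy_of = decoy)
  out <- sibling_correlation_filter(tr, target_decoy_rate = 0.03)
  rep <- filter_report(out)
  expect_lte(rep$decoy_rate, 0.03)

  # brute-force oracle over the same grid on the reported spc values
  spc <- rep$spc
  oracle_cut <- NA
  for (cut in seq(0.28, 0.34, 0.01)) {
    keep <- spc[!is.na(spc$spc) & spc$spc >= cut, ]
    cnt <- table(keep$protein_id)
    ok <- names(cnt)[cnt >= 2]
    dec <- spc$decoy[match(ok, spc$protein_id)]
    if (sum(!dec) > 0 && sum(dec) / sum(!dec) <= 0.03) { oracle_cut <- cut; break }
  }
  expect_equal(rep$spc_cutoff, oracle_cut)
})

test_that("spc filter retains true peptides and removes shuffled decoys", {
  set.seed(31)
  nf <- 65
  n_pep <- 6
  vecs <- list(); prot <- list(); decoy <- list()
  pool <- list()
  for (i in seq_len(60)) {
    pid <- sprintf("T%02d", i)
    shape <- gaussian_trace(nf, runif(1, 8, 55), runif(1, 1, 2), 1e4)
    for (j in seq_len(n_pep)) {
      pep <- sprintf("%s_p%d", pid, j)
      v <- shape * rlnorm(1, 0, 0.8) * rlnorm(nf, 0, sqrt(log(1 + 0.2^2)))
      vecs[[pep]] <- v
      prot[[pep]] <- pid
      pool[[length(pool) + 1]] <- v
    }
    decoy[[pid]] <- FALSE
  }
  shuffled <- sample(pool)
  for (i in seq_len(15)) {      # decoy proteins from reshuffled peptide pool
    pid <- sprintf("D%02d", i)
    for (j in seq_len(n_pep)) {
      pep <- sprintf("%s_p%d", pid, j)
      vecs[[pep]] <- shuffled[[(i - 1) * n_pep + j]]
      prot[[pep]] <- pid
    }
    decoy[[pid]] <- TRUE
  }
  tr <- make_traces(vecs, prot, replicates = 1, decoy_of = decoy)
  out <- sibling_correlation_filter(tr)
  spc <- filter_report(out)$spc
  true_peps <- spc$peptide_id[!spc$decoy]
  kept_true <- mean(true_peps %in% out$peptide_id)
  decoy_peps <- spc$peptide_id[spc$decoy]
  removed_decoy <- mean(!decoy_peps %in% out$peptide_id)
  expect_gt(kept_true, 0.95)
  expect_gt(removed_decoy, 0.90)
})

test_that("pi_A-corrected target-decoy FDR follows the defining identities", {
  r <- estimate_protein_fdr(200, 100, 10)
  expect_equal(r$pi_a, 0.5)
  expect_equal(r$fdr, 0.05)
  expect_equal(estimate_protein_fdr(100, 80, 0)$fdr, 0)
  expect_error(estimate_protein_fdr(100, 0, 5), "n_detected")
  expect_error(estimate_protein_fdr(100, 120, 5), "exceeds")
  # identity: fdr = decoys * pi_a / detected
  r2 <- estimate_protein_fdr(5916, 5044, 135)
  expect_equal(r2$fdr, r2$n_decoys_pass * r2$pi_a / r2$n_detected)
})

test_that("top-2 quantification ranks peptides once, globally, with stable ties", {
  nf <- 6
  vecs <- list(
    big = rep(100 / nf, nf), mid = rep(50 / nf, nf), small = rep(10 / nf, nf)
  )
  tr <- make_traces(vecs, list(big = "P1", mid = "P1", small = "P1"),
                    replicates = 1:2)
  pt <- protein_quant_top2(tr)
  expect_equal(unique(pt$protein_id), "P1")
  expect_equal(pt$intensity[1, ], vecs$big + vecs$mid, ignore_attr = TRUE)

  # exactly two peptides: their sum
  tr2 <- make_traces(vecs[c("big", "mid")], list(big = "P2", mid = "P2"),
                     replicates = 1)
  pt2 <- protein_quant_top2(tr2)
  expect_equal(pt2$intensity[1, ], vecs$big + vecs$mid, ignore_attr = TRUE)

  # tie for 2nd place resolved lexicographically
  vecs3 <- list(zz = rep(5, nf), aa = rep(2, nf), bb = rep(2, nf))
  tr3 <- make_traces(vecs3, list(zz = "P3", aa = "P3", bb = "P3"),
                     replicates = 1)
  pt3 <- protein_quant_top2(tr3)
  expect_equal(pt3$intensity[1, ], vecs3$zz + vecs3$aa, ignore_attr = TRUE)

  # single-peptide proteins are excluded
  tr4 <- make_traces(list(only = rep(1, nf)), list(only = "P4"),
                     replicates = 1)
  expect_message(pt4 <- protein_quant_top2(tr4), "excluded")
  expect_equal(nrow(pt4), 0)
})
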