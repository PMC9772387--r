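test_that("the sigmoidal penalty has the stated midpoint, limits, and values", {
  p <- scoring_params()
  expect_identical(penalty(p$B, p), 0.5)
  expect_lt(penalty(0, p), 1e-30)
  # independent numerical evaluation of 1 - 1/(1 + exp(1.88 * (40 - 38)))
  expect_equal(penalty(40, p), 0.9772, tolerance = 1e-4)
})

test_that("the penalty is bounded in (0,1) and monotone in the deviation", {
  p <- scoring_params()
  # the sigmoid approaches 1 beyond machine precision near d = B + 36/A; test
  # strict bounds and strict monotonicity on the representable range, and
  # the closed bounds with weak monotonicity everywhere
  grid <- seq(0, p$B + 32 / p$A, length.out = 1000)
  v <- penalty(grid, p)
  expect_true(all(v > 0 & v < 1))
  expect_true(all(diff(v) > 0))
  wide <- penalty(seq(0, 1000, length.out = 1000), p)
  expect_true(all(wide >= 0 & wide <= 1))
  expect_true(all(diff(wide) >= 0))
})

test_that("residue deviations are absolute by default and signed on request", {
  expect_equal(residue_deviation(50, 50), 0)
  expect_equal(residue_deviation(80, 46.27), 33.73)
  expect_equal(residue_deviation(10, 48), 38)
  expect_equal(residue_deviation(10, 48, mode = "signed"), -38)
})

# build a labeling table whose experimental changes sit at chosen offsets
# from the model-implied predictions
labeling_at_offsets <- function(structure, spec, offsets,
                                calib = calibration_model()) {
  res <- structure_residues(structure)
  res <- res[seq_along(offsets), ]
  d <- interface_distances(structure, spec, res)
  change <- predict_modification_change(d, calib) + offsets
  data.frame(complex_id = "toy", chain = res$chain,
             residue_number = res$resno, residue_name = res$resid,
             measure_kind = "rate", M_unbound = 1,
             M_bound = 1 - change / 100,
             modification_change = change, stringsAsFactors = FALSE)
}

test_that("the raw score term sums per-residue penalties over mapped residues", {
  s <- make_toy_complex(8, seed = 4)
  ps <- parse_partner_spec("A_B", s)
  p <- scoring_params()

  # all deviations exactly at the midpoint -> raw = 0.5 * n
  lab_b <- labeling_at_offsets(s, ps, rep(p$B, 5))
  term <- cl_score_term_raw(s, ps, lab_b, params = p)
  expect_equal(term$raw, 0.5 * 5, tolerance = 1e-12)
  expect_identical(term$n_scored, 5L)
  expect_identical(term$n_skipped, 0L)

  # a model reproducing the experimental changes exactly -> raw ~ 0
  lab_0 <- labeling_at_offsets(s, ps, rep(0, 6))
  expect_lt(cl_score_term_raw(s, ps, lab_0, params = p)$raw, 1e-20)

  # deviations {0, B, 100} -> 0 + 0.5 + ~1
  lab_3 <- labeling_at_offsets(s, ps, c(0, p$B, 100))
  expect_equal(cl_score_term_raw(s, ps, lab_3, params = p)$raw, 1.5,
               tolerance = 1e-3)

  # unmapped labeled residues are skipped and counted
  lab_skip <- lab_0
  lab_skip$residue_number[1] <- 999L
  term_skip <- cl_score_term_raw(s, ps, lab_skip, params = p)
  expect_identical(term_skip$n_skipped, 1L)
  expect_identical(term_skip$n_scored, 5L)

  lab_none <- lab_0
  lab_none$residue_number <- 900L + seq_len(nrow(lab_none))
  expect_error(cl_score_term_raw(s, ps, lab_none, params = p),
               "cannot be scored")
})

test_that("adding a residue never decreases the raw term, and larger deviations increase it", {
  s <- make_toy_complex(8, seed = 5)
  ps <- parse_partner_spec("A_B", s)
  set.seed(5)
  offs <- runif(8, 0, 60)
  raw_small <- cl_score_term_raw(s, ps, labeling_at_offsets(s, ps, offs))$raw
  raw_more <- cl_score_term_raw(s, ps,
                                labeling_at_offsets(s, ps, c(offs, 20)))$raw
  expect_gte(raw_more, raw_small)
  raw_big <- cl_score_term_raw(s, ps, labeling_at_offsets(s, ps, offs + 5))$raw
  expect_gt(raw_big, raw_small)
})

test_that("normalization divides by the set maximum with a degenerate all-zero rule", {
  expect_equal(normalize_over_set(c(2, 4)), c(0.5, 1.0))
  expect_equal(normalize_over_set(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(normalize_over_set(7), 1.0)
  expect_error(normalize_over_set(c(1, -2)), "negative")
  # ranking-relevant values are invariant to scaling all raw scores
  set.seed(8)
  raw <- runif(10)
  expect_equal(normalize_over_set(raw * 13.7), normalize_over_set(raw),
               tolerance = 1e-12)
})

test_that("combined score adds the weighted normalized term to the interface energy", {
  expect_equal(combined_score(-30, 0.4), -4)
  expect_equal(combined_score(-17.3, 0), -17.3)
  expect_equal(scoring_params()$weight, 65)
  expect_error(combined_score(-30, 1.2), "\\[0, 1\\]")
})

test_that("rescore_ensemble ranks deterministically and reduces to the energy baseline", {
  sc <- make_scenario(seed = 6, n_decoys = 12)
  scores <- suppressWarnings(rescore_ensemble(sc$models, sc$isc, sc$spec,
                                              sc$labeling, sc$calib,
                                              sc$params))
  expect_identical(sort(scores$rank), seq_len(nrow(scores)))
  expect_equal(max(scores$cl_norm), 1)
  expect_equal(scores$cl_score, scores$isc + 65 * scores$cl_norm)
  # the near-native pose agrees best with the labeling data
  best_cl <- scores$model_id[which.min(scores$cl_raw)]
  expect_lt(sc$rmsd[best_cl], 2)

  # weight 0 reduces the ordering to the interface energy alone
  p0 <- scoring_params(weight = 0)
  scores0 <- suppressWarnings(rescore_ensemble(sc$models, sc$isc, sc$spec,
                                               sc$labeling, sc$calib, p0))
  isc_order <- scores0$model_id[order(scores0$isc, scores0$model_id)]
  expect_identical(scores0$model_id, isc_order)

  # identical models with different energies rank by energy
  two <- list(m1 = sc$models[[1]], m2 = sc$models[[1]])
  two$m1$model_id <- "m1"; two$m2$model_id <- "m2"
  isc2 <- data.frame(model_id = c("m1", "m2"), isc = c(-10, -20))
  r2 <- rescore_ensemble(two, isc2, sc$spec, sc$labeling, sc$calib, sc$params)
  expect_identical(r2$model_id[r2$rank == 1], "m2")

  # byte-identical determinism end to end
  f1 <- tempfile(); f2 <- tempfile()
  write_score_table(scores, f1, sc$params, sc$calib)
  write_score_table(suppressWarnings(
    rescore_ensemble(sc$models, sc$isc, sc$spec, sc$labeling, sc$calib,
                     sc$params)), f2, sc$params, sc$calib)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("ensembles with missing scores or mixed chain layouts are rejected", {
  sc <- make_scenario(seed = 7, n_decoys = 5)
  isc_short <- sc$isc[-1, ]
  expect_error(suppressWarnings(
    rescore_ensemble(sc$models, isc_short, sc$spec, sc$labeling)),
    "no interface score")

  mixed <- sc$models
  odd <- mixed[[2]]$atoms
  odd$chain[odd$chain == "B"] <- "C"
  mixed[[2]] <- clrescore:::new_structure(mixed[[2]]$model_id, odd)
  expect_error(suppressWarnings(
    rescore_ensemble(mixed, sc$isc, sc$spec, sc$labeling)),
    "chain layouts")
})

test_that("isc and score tables round-trip through their readers", {
  df <- data.frame(model_id = c("a", "b"), isc = c(-31.5, -28))
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_isc_table(f), df)
  writeLines("model_id\tscore", f)
  expect_error(read_isc_table(f), "columns model_id and isc")
})
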