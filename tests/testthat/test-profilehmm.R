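test_that("profile frequencies follow the weighted pseudocount formula", {
  aln <- msa(c(a = "A", b = "A", c = "A"))
  p <- build_profile(aln, pseudocount_weight = 1e-9)
  expect_equal(unname(p$columns[1, "A"]), 1, tolerance = 1e-6)
  # two-row column with Laplace weight and uniform background:
  # equal sequence weights 1 each, f(A) = (1 + 1 * 1/20) / (2 + 1)
  aln2 <- msa(c(a = "A", b = "C"))
  p2 <- build_profile(aln2, pseudocount_weight = 1,
                      background = rep(1 / 20, 20))
  expect_equal(unname(p2$columns[1, "A"]), (1 + 0.05) / 3)
  expect_equal(unname(p2$columns[1, "C"]), (1 + 0.05) / 3)
  expect_equal(unname(p2$columns[1, "D"]), 0.05 / 3)
  expect_equal(unname(rowSums(p2$columns)), 1, tolerance = 1e-9)
  expect_true(all(p2$columns > 0))
})

test_that("match columns exclude gap-majority columns", {
  aln <- msa(c(a = "AC-D", b = "AC-D", c = "A--D", d = "A-CD"))
  p <- build_profile(aln)
  # col2 has 50% gaps (>= 0.5 drops), col3 75%
  expect_equal(p$match_col_map, c(1L, 4L))
  expect_error(build_profile(msa(c(a = "A-", b = "-A"))), "match columns")
})

test_that("profile-sequence scores equal brute-force path enumeration", {
  set.seed(31)
  for (rep in 1:12) {
    C <- sample(2:5, 1); L <- sample(2:7, 1)
    p <- random_profile(C)
    if (rep %% 3 == 0) p$masked_columns <- sample(C, sample(C, 1))
    s <- paste(sample(AA20_T, L, TRUE), collapse = "")
    E <- famforge:::emission_matrix(p)
    S <- famforge:::seq_score_matrix(p, s, E)
    expect_equal(score_sequence(p, s)$bit_score, bf_local_affine(S),
                 tolerance = 1e-9)
  }
})

test_that("consensus optimality and masking contract hold", {
  set.seed(8)
  p <- random_profile(8, conc = 0.2)
  cons <- profile_consensus(p)
  s0 <- score_sequence(p, cons)$bit_score
  ch <- strsplit(cons, "")[[1]]
  for (pos in c(1, 4, 8)) {
    mut <- ch
    mut[pos] <- setdiff(AA20_T, ch[pos])[1]
    expect_lte(score_sequence(p, paste(mut, collapse = ""))$bit_score, s0)
  }
  p$masked_columns <- 1:8
  for (s in c(cons, "MKTAYIAK"))
    expect_equal(score_sequence(p, s)$bit_score, 0)
})

test_that("masking never helps sequences whose only signal is the motif", {
  # motif-only decoys: master consensus zipper windows pasted into uniform
  # random background
  spec <- synthetic_family_spec(n_subfamilies = 1, members_per_subfamily = 10,
                                inter_sub_divergence = 0, seed = 13)
  g <- generate_superfamily(spec)
  aln <- g$truth$alignment
  prof <- build_profile(aln, id = "m")
  cols <- zipper_mask_columns(aln)
  masked <- mask_profile(prof, cols)
  cons <- strsplit(profile_consensus(prof), "")[[1]]
  zwin <- match(cols, prof$match_col_map)
  set.seed(9)
  for (rep in 1:10) {
    bgseq <- sample(AA20_T, 120, TRUE)
    ins <- sample(1:80, 1)
    motif_only <- paste(c(bgseq[1:ins], cons[zwin],
                          bgseq[(ins + 1):120]), collapse = "")
    expect_lte(score_sequence(masked, motif_only)$bit_score,
               score_sequence(prof, motif_only)$bit_score)
  }
})

test_that("Gumbel fitting recovers known parameters within 10%", {
  set.seed(17)
  mu <- 12; beta <- 3
  x <- mu - beta * log(-log(runif(1000)))
  fit <- famforge:::fit_gumbel(x)
  expect_lt(abs(fit$mu - mu) / mu, 0.1)
  expect_lt(abs(fit$beta - beta) / beta, 0.1)
})

test_that("calibration is reproducible, monotone and guards degeneracy", {
  spec <- synthetic_family_spec(n_subfamilies = 1, members_per_subfamily = 6,
                                inter_sub_divergence = 0, seed = 19)
  aln <- generate_superfamily(spec)$truth$alignment
  p <- build_profile(aln, id = "m")
  c1 <- calibrate(p, 150, 100, seed = 4)
  c2 <- calibrate(p, 150, 100, seed = 4)
  expect_identical(c1$calibration, c2$calibration)
  sc <- seq(5, 80, by = 5)
  ev <- e_value(c1, sc, 500)
  expect_true(all(diff(ev) < 0))
  expect_true(all(ev >= 0))
  expect_error(calibrate(p, 50, 100), ">= 100")
  pm <- p; pm$masked_columns <- seq_len(nrow(p$columns))
  expect_error(calibrate(pm, 150, 100, seed = 1), "degenerate")
  expect_error(e_value(p, 10, 500), "not calibrated")
})

test_that("database search recovers the profile's own members at e <= 1", {
  spec <- synthetic_family_spec(n_subfamilies = 1, members_per_subfamily = 8,
                                inter_sub_divergence = 0,
                                intra_sub_divergence = 0.5, seed = 23)
  g <- generate_superfamily(spec)
  p <- calibrate(build_profile(g$truth$alignment, id = "fam"), 200,
                 median(nchar(g$records$residues)), seed = 2)
  db <- rbind(g$records, generate_background(50, 3))
  class(db) <- c("protein_db", "data.frame")
  hits <- search_db(p, db, 1.0)
  expect_true(all(g$records$id %in% hits$target_id))
  expect_equal(nrow(search_db(p, db, 0)), 0)
  expect_identical(search_db(p, db, 1.0), hits)
  expect_error(search_db(build_profile(g$truth$alignment), db), "calibrated")
})

test_that("profile serialization round-trips including calibration and mask", {
  spec <- synthetic_family_spec(n_subfamilies = 1, members_per_subfamily = 5,
                                seed = 29)
  aln <- generate_superfamily(spec)$truth$alignment
  p <- calibrate(build_profile(aln, id = "roundtrip"), 150, 120, seed = 6)
  p <- mask_profile(p, zipper_mask_columns(aln))
  f <- withr::local_tempfile(fileext = ".prof")
  write_profile(p, f)
  q <- read_profile(f)
  expect_equal(q$id, p$id)
  expect_equal(q$columns, p$columns, tolerance = 1e-12)
  expect_equal(q$background, p$background, tolerance = 1e-12)
  expect_equal(q$masked_columns, p$masked_columns)
  expect_equal(q$match_col_map, p$match_col_map)
  expect_equal(q$calibration$lambda, p$calibration$lambda, tolerance = 1e-12)
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  expect_equal(score_sequence(q, s)$bit_score,
               score_sequence(p, s)$bit_score, tolerance = 1e-9)
})
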