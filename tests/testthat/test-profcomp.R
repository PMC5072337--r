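test_that("profile-profile scores equal brute-force column alignment", {
  set.seed(43)
  for (rep in 1:10) {
    q <- random_profile(sample(2:4, 1))
    m <- random_profile(sample(2:4, 1))
    if (rep %% 3 == 0)
      m$masked_columns <- sample(nrow(m$columns), 1)
    odds <- sweep(m$columns, 2, m$background, "/")
    S <- log2(q$columns %*% t(odds))
    if (length(m$masked_columns)) S[, m$masked_columns] <- 0
    expect_equal(align_profiles(q, m)$raw_score, bf_local_affine(S),
                 tolerance = 1e-9)
  }
})

test_that("self-alignment beats column permutations of the same profile", {
  set.seed(47)
  p <- random_profile(10, conc = 0.3)
  self <- align_profiles(p, p)$raw_score
  for (rep in 1:5) {
    q <- p
    q$columns <- p$columns[sample(10), , drop = FALSE]
    expect_lte(align_profiles(q, p)$raw_score, self + 1e-9)
  }
})

test_that("profiles concentrated on disjoint residues score nothing", {
  mk <- function(res) {
    cols <- matrix(0.1 / 19, 3, 20, dimnames = list(NULL, AA20_T))
    for (j in 1:3) cols[j, res[j]] <- 0.9 + 0.1 / 19
    cols <- cols / rowSums(cols)
    structure(list(id = "x", columns = cols,
                   background = setNames(rep(1 / 20, 20), AA20_T),
                   match_mask = rep(TRUE, 3), match_col_map = 1:3,
                   masked_columns = integer(0), calibration = NULL),
              class = "position_profile")
  }
  q <- mk(c("A", "C", "D")); m <- mk(c("E", "F", "G"))
  odds <- sweep(m$columns, 2, m$background, "/")
  S <- log2(q$columns %*% t(odds))
  expect_true(all(S < 0))  # the co-emission bound, verified numerically
  expect_equal(align_profiles(q, m)$raw_score, 0)
})

test_that("logistic calibration is monotone and recovers a known link", {
  set.seed(53)
  b0 <- -6; b1 <- 0.4
  errs <- replicate(10, {
    s <- runif(200, 5, 25)  # scores concentrated around the transition
    y <- rbinom(200, 1, plogis(b0 + b1 * s))
    fit <- famforge:::fit_logistic(s, y)
    c(abs(fit$intercept - b0) / abs(b0), abs(fit$slope - b1) / b1)
  })
  expect_lt(median(errs[1, ]), 0.15)
  expect_lt(median(errs[2, ]), 0.15)
  s <- runif(200, 0, 40)
  fit <- famforge:::fit_logistic(s, rbinom(200, 1, plogis(b0 + b1 * s)))
  probs <- plogis(fit$intercept + fit$slope * seq(0, 40, 2))
  expect_true(all(diff(probs) >= 0))
  expect_error(famforge:::fit_logistic(rep(3, 10), rep(0:1, 5)), "degenerate")
})

test_that("zipper columns are detected from clean and noisy alignments", {
  aln <- msa(setNames(rep("GLLLGVVVG", 4), paste0("s", 1:4)))
  expect_equal(detect_zipper_columns(aln), c(1, 5, 9))
  noG <- msa(setNames(rep("LLLLVVVVA", 4), paste0("s", 1:4)))
  expect_equal(detect_zipper_columns(noG), integer(0))
  expect_equal(zipper_mask_columns(aln), 1:9)
  expect_equal(zipper_mask_columns(aln, expand = FALSE), c(1, 5, 9))
})

test_that("zipper detection is sensitive and specific on generated families", {
  hits <- replicate(30, {
    spec <- synthetic_family_spec(n_subfamilies = 1,
                                  members_per_subfamily = 12,
                                  inter_sub_divergence = 0,
                                  seed = sample.int(1e6, 1))
    g <- generate_superfamily(spec)
    got <- detect_zipper_columns(g$truth$alignment)
    truth <- g$truth$zipper_columns
    c(sens = mean(truth %in% got),
      fpr = length(setdiff(got, truth)) /
        (g$truth$alignment$n_cols - length(truth)))
  })
  expect_gte(mean(hits["sens", ]), 0.9)
  expect_lte(mean(hits["fpr", ]), 0.05)
})

test_that("masked validation separates members from zipper decoys", {
  spec <- synthetic_family_spec(n_subfamilies = 2, members_per_subfamily = 12,
                                seed = 59)
  g <- generate_superfamily(spec)
  rows1 <- g$truth$alignment$rows[grepl("^sf01", names(g$truth$alignment$rows))]
  aln <- msa(rows1)
  masked <- mask_profile(build_profile(aln, id = "master"),
                         zipper_mask_columns(aln))
  dec <- generate_decoys(20, 61, length = 240)
  decp <- lapply(seq_len(nrow(dec)), function(i) single_seq_profile(dec[i, ]))
  truep <- lapply(seq_along(rows1), function(i)
    single_seq_profile(ungap(rows1[i]), id = paste0("t", i)))
  mm <- calibrate_probability(masked, decp, truep)
  # median separation on fresh examples
  dec2 <- generate_decoys(10, 67, length = 240)
  p_dec <- vapply(seq_len(nrow(dec2)), function(i)
    validate_candidate(single_seq_profile(dec2[i, ]), mm)$score$masked_probability, 0)
  rows2 <- g$truth$alignment$rows[grepl("^sf02", names(g$truth$alignment$rows))]
  p_true <- vapply(seq_along(rows2), function(i)
    validate_candidate(single_seq_profile(ungap(rows2[i]), id = "q"),
                       mm)$score$masked_probability, 0)
  expect_gt(median(p_true), median(p_dec))
  # self-comparison accepts at the top of the probability map
  self <- validate_candidate(mm, mm)
  expect_true(self$accepted)
  expect_gte(self$score$masked_probability, 0.99)
  expect_error(validate_candidate(decp[[1]], masked), "probability map")
})

test_that("a fully masked master accepts nothing", {
  spec <- synthetic_family_spec(n_subfamilies = 1, members_per_subfamily = 10,
                                seed = 71)
  g <- generate_superfamily(spec)
  aln <- g$truth$alignment
  masked <- mask_profile(build_profile(aln, id = "m"),
                         zipper_mask_columns(aln))
  rows <- ungap(aln$rows)
  truep <- lapply(seq_along(rows), function(i)
    single_seq_profile(rows[i], id = paste0("t", i)))
  dec <- generate_decoys(20, 73, length = 240)
  decp <- lapply(seq_len(nrow(dec)), function(i) single_seq_profile(dec[i, ]))
  mm <- calibrate_probability(masked, decp, truep)
  all_masked <- mm
  all_masked$masked_columns <- seq_len(nrow(mm$columns))
  for (i in 1:5) {
    v <- validate_candidate(truep[[i]], all_masked)
    expect_false(v$accepted)
  }
})
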