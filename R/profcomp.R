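#' Align two position profiles (profile-profile comparison)
#'
#' Local dynamic-programming alignment of query columns against master
#' columns. The column-pair score is the co-emission log-odds against the
#' master's background, `log2( sum_a q_i(a) m_j(a) / bg_m(a) )` in bits.
#' Masked master columns score 0 against everything; gap costs match the
#' sequence-profile search (open 4 bits, extend 0.25 bits).
#'
#' @param q query `position_profile`.
#' @param m master `position_profile` (its `masked_columns` are honored).
#' @return a list with `raw_score` (bits) and `pairs` (matched column pairs,
#'   query column then master column).
#' @export
align_profiles <- function(q, m) {
  stopifnot(inherits(q, "position_profile"), inherits(m, "position_profile"))
  odds <- sweep(m$columns, 2, m$background, "/")
  S <- log2(q$columns %*% t(odds))
  if (length(m$masked_columns) > 0) S[, m$masked_columns] <- 0
  r <- .sw_affine(S, 4, 0.25)
  list(raw_score = r$score, pairs = r$pairs,
       q_start = r$q_start, q_end = r$q_end,
       m_start = r$r_start, m_end = r$r_end)
}

#' Build a single-sequence query profile
#'
#' One-row profiles put candidate sequences on the same profile-profile
#' score scale as the labeled calibration sets.
#'
#' @param seq residue string or single-row `protein_db`.
#' @param id profile id (defaults to the record id when available).
#' @param pseudocount_weight passed to [build_profile()].
#' @return a `position_profile`.
#' @export
single_seq_profile <- function(seq, id = NULL, pseudocount_weight = 1) {
  if (is.data.frame(seq) && is.null(id)) id <- seq$id[1]
  residues <- as_residues(seq)
  if (is.null(id)) id <- "query"
  build_profile(msa(setNames(residues, id)),
                pseudocount_weight = pseudocount_weight, id = id)
}

# Two-parameter logistic fit of P(homolog) as a function of raw score, by
# maximum likelihood. Completely separated inputs converge to a steep
# step between the two classes, which is the intended behavior for
# thresholding.
#' @noRd
fit_logistic <- function(scores, labels) {
  if (length(unique(scores)) == 1)
    stop("degenerate calibration input: all scores equal")
  df <- data.frame(y = as.integer(labels), s = scores)
  fit <- suppressWarnings(glm(y ~ s, family = binomial(), data = df,
                              control = list(maxit = 100)))
  co <- coef(fit)
  list(intercept = unname(co[1]), slope = unname(co[2]))
}

#' Calibrate the probability map of a master profile
#'
#' Fits a two-parameter logistic of the profile-profile raw score to
#' labeled examples: decoy profiles (score should not reach homolog levels)
#' and true profiles (known members). Scores are computed against the master
#' as-is, so mask the master first if validation will use the masked master.
#'
#' @param master `position_profile` to attach the map to.
#' @param decoy_profiles list of `position_profile` labeled non-homolog.
#' @param true_profiles list of `position_profile` labeled homolog.
#' @return the master with a `prob_map` element.
#' @export
calibrate_probability <- function(master, decoy_profiles, true_profiles) {
  if (length(decoy_profiles) < 2 || length(true_profiles) < 2)
    stop("need at least 2 decoy and 2 true profiles (20+ recommended)")
  sc_d <- vapply(decoy_profiles, function(p) align_profiles(p, master)$raw_score, 0)
  sc_t <- vapply(true_profiles, function(p) align_profiles(p, master)$raw_score, 0)
  master$prob_map <- fit_logistic(c(sc_d, sc_t),
                                  c(rep(0L, length(sc_d)), rep(1L, length(sc_t))))
  master
}

#' Map a raw profile-profile score to a calibrated probability
#' @param master profile carrying a `prob_map`.
#' @param score raw score(s) in bits.
#' @return probability in \[0, 1\], monotone non-decreasing in `score`.
#' @export
score_probability <- function(master, score) {
  if (is.null(master$prob_map)) stop("master has no probability map")
  plogis(master$prob_map$intercept + master$prob_map$slope * score)
}

# Zipper anchor triples on the match columns of an alignment. Works in
# ungapped consensus coordinates (= match-column index). An anchor triple is
# (c, c2, c3) with c2 in c+4+/-1, c3 in c+8+/-2, all three columns having a
# glycine fraction >= g_fraction among non-gap residues.
#' @noRd
zipper_triples <- function(aln, g_fraction = 0.7, match_mask = NULL) {
  m <- msa_matrix(aln)
  if (is.null(match_mask)) match_mask <- colMeans(m == "-") < 0.5
  mc <- which(match_mask)
  mm <- m[, mc, drop = FALSE]
  non_gap <- colSums(mm != "-")
  gfrac <- ifelse(non_gap > 0, colSums(mm == "G") / pmax(non_gap, 1), 0)
  pass <- gfrac >= g_fraction
  triples <- NULL
  K <- length(mc)
  for (c1 in which(pass)) {
    for (c2 in (c1 + 3):(c1 + 5)) {
      if (c2 > K || !pass[c2]) next
      for (c3 in (c1 + 6):(c1 + 10)) {
        if (c3 > K || c3 <= c2 || !pass[c3]) next
        triples <- rbind(triples, c(c1, c2, c3))
      }
    }
  }
  list(triples = triples, match_cols = mc)
}

#' Detect glycine-zipper columns in an alignment
#'
#' A match column anchors a zipper when at least `g_fraction` of its non-gap
#' residues are glycine and two further glycine-rich match columns follow at
#' ungapped-consensus spacings 4 (+/-1) and 8 (+/-2) — the GxxxGxxxG helix
#' packing motif with tolerance for alignment jitter.
#'
#' @param aln an `msa`.
#' @param g_fraction minimum glycine fraction per column (default 0.7).
#' @param match_mask optional logical match-column mask to use instead of
#'   the default gap-fraction rule.
#' @return sorted integer vector of alignment columns (the anchor glycine
#'   columns of all detected triples); empty when nothing is found.
#' @export
detect_zipper_columns <- function(aln, g_fraction = 0.7, match_mask = NULL) {
  zt <- zipper_triples(aln, g_fraction, match_mask)
  if (is.null(zt$triples)) return(integer(0))
  sort(unique(zt$match_cols[as.vector(zt$triples)]))
}

#' Alignment columns to mask for zipper-blind validation
#'
#' Returns the detected anchor columns plus, when `expand = TRUE` (the
#' default), every match column between the first and last anchor of each
#' triple, so the whole 9-column motif window is silenced rather than just
#' the glycines.
#'
#' @inheritParams detect_zipper_columns
#' @param expand also mask the columns between the anchors of a triple.
#' @return sorted integer vector of alignment columns.
#' @export
zipper_mask_columns <- function(aln, g_fraction = 0.7, match_mask = NULL,
                                expand = TRUE) {
  zt <- zipper_triples(aln, g_fraction, match_mask)
  if (is.null(zt$triples)) return(integer(0))
  cons <- integer(0)
  for (r in seq_len(nrow(zt$triples))) {
    tr <- zt$triples[r, ]
    cons <- c(cons, if (expand) tr[1]:tr[3] else tr)
  }
  sort(unique(zt$match_cols[unique(cons)]))
}

#' Mask profile columns by alignment column index
#'
#' Masking forces the emission contribution of a column to zero (background)
#' without deleting it, so coordinates stay comparable.
#'
#' @param profile a `position_profile`.
#' @param alignment_columns integer columns of the source alignment.
#' @return the profile with `masked_columns` set (profile-column indices).
#' @export
mask_profile <- function(profile, alignment_columns) {
  idx <- match(alignment_columns, profile$match_col_map)
  profile$masked_columns <- sort(unique(idx[!is.na(idx)]))
  profile
}

#' Validate a candidate profile against a masked master
#'
#' Computes the calibrated probability of the candidate against the master
#' with its zipper columns masked; the candidate is accepted only if that
#' masked probability reaches the threshold, so similarity that is carried
#' purely by the glycine-zipper motif does not survive. The unmasked
#' probability and the motif contribution (unmasked minus masked raw score)
#' are reported alongside.
#'
#' @param candidate_profile query `position_profile` (typically from
#'   [single_seq_profile()]).
#' @param master masked, probability-calibrated `position_profile`.
#' @param threshold acceptance probability (default 0.9).
#' @return a list with `accepted` and `score`, the latter a one-row data
#'   frame (`candidate_id`, `raw_score`, `probability`, `masked_probability`,
#'   `motif_contribution`, `accepted`).
#' @export
validate_candidate <- function(candidate_profile, master, threshold = 0.9) {
  if (is.null(master$prob_map)) stop("master has no probability map")
  masked <- align_profiles(candidate_profile, master)
  unmasked_master <- master
  unmasked_master$masked_columns <- integer(0)
  unmasked <- align_profiles(candidate_profile, unmasked_master)
  p_masked <- score_probability(master, masked$raw_score)
  p_unmasked <- score_probability(master, unmasked$raw_score)
  accepted <- p_masked >= threshold
  score <- data.frame(candidate_id = candidate_profile$id,
                      raw_score = unmasked$raw_score,
                      probability = p_unmasked,
                      masked_probability = p_masked,
                      motif_contribution = unmasked$raw_score - masked$raw_score,
                      accepted = accepted, stringsAsFactors = FALSE)
  list(accepted = accepted, score = score)
}
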