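#' Build a position profile from an alignment
#'
#' Match columns are alignment columns with less than 50% gap characters.
#' Per-column residue frequencies are position-based (Henikoff) weighted
#' counts with background-proportional pseudocounts:
#' `f = (weighted counts + w * bg) / (total weight + w)`.
#' The background is the overall residue composition of the source
#' alignment, floored at 1e-4 and renormalized. `X` residues carry no count
#' and score as background everywhere.
#'
#' @param aln an `msa`.
#' @param pseudocount_weight positive pseudocount mass `w` (default 1).
#' @param background optional length-20 background to use instead of the
#'   alignment composition (named by residue or in [AA20] order).
#' @param match_mask optional logical vector over source columns overriding
#'   the gap-fraction rule (used to pin a fixed master column frame).
#' @param weighting `"henikoff"` (position-based, the default) or `"equal"`
#'   sequence weights; equal weights make per-column frequencies a plain
#'   pseudocounted average, for which adding one row moves any frequency by
#'   at most `1/(rows + 1)`.
#' @param id profile identifier (default: derived from row ids).
#' @return an object of class `position_profile` with elements `columns`
#'   (C x 20 frequency matrix), `background`, `match_mask`, `match_col_map`
#'   (source column of each profile column), `masked_columns` (profile
#'   columns scored as background) and `calibration`.
#' @export
build_profile <- function(aln, pseudocount_weight = 1, background = NULL,
                          match_mask = NULL,
                          weighting = c("henikoff", "equal"), id = NULL) {
  stopifnot(inherits(aln, "msa"))
  weighting <- match.arg(weighting)
  if (pseudocount_weight <= 0) stop("pseudocount_weight must be positive")
  m <- msa_matrix(aln)
  if (is.null(match_mask)) {
    gap_frac <- colMeans(m == "-")
    match_mask <- gap_frac < 0.5
  }
  if (!any(match_mask)) stop("alignment has zero match columns")
  if (is.null(background)) {
    res <- m[m %in% AA20]
    cnt <- table(factor(res, levels = AA20))
    background <- pmax(as.numeric(cnt) / max(1, sum(cnt)), 1e-4)
    background <- background / sum(background)
  } else {
    if (!is.null(names(background))) background <- background[AA20]
    background <- as.numeric(background) / sum(background)
  }
  names(background) <- AA20
  mm <- m[, match_mask, drop = FALSE]
  w <- if (weighting == "henikoff") henikoff_weights(mm)
       else rep(1, nrow(mm))
  C <- ncol(mm)
  cols <- matrix(0, C, 20, dimnames = list(NULL, AA20))
  for (j in seq_len(C)) {
    obs <- mm[, j]
    keep <- obs %in% AA20
    wc <- tapply(w[keep], factor(obs[keep], levels = AA20), sum)
    wc[is.na(wc)] <- 0
    tot <- sum(w[keep])
    cols[j, ] <- (wc + pseudocount_weight * background) /
      (tot + pseudocount_weight)
  }
  if (is.null(id))
    id <- paste0("profile_", substr(paste(names(aln$rows), collapse = "|"), 1, 8))
  structure(list(id = id, columns = cols, background = background,
                 match_mask = match_mask,
                 match_col_map = which(match_mask),
                 masked_columns = integer(0), calibration = NULL),
            class = "position_profile")
}

# Position-based sequence weights (Henikoff & Henikoff 1994) over match
# columns: in each column every distinct residue shares 1/r, split equally
# among the sequences carrying it. Gaps and X contribute nothing. Weights
# are normalized to mean 1.
#' @noRd
henikoff_weights <- function(mm) {
  n <- nrow(mm)
  w <- rep(0, n)
  for (j in seq_len(ncol(mm))) {
    obs <- mm[, j]
    keep <- obs %in% AA20
    if (!any(keep)) next
    tab <- table(obs[keep])
    r <- length(tab)
    w[keep] <- w[keep] + 1 / (r * as.numeric(tab[obs[keep]]))
  }
  if (all(w == 0)) w <- rep(1, n)
  w * n / sum(w)
}

#' @export
print.position_profile <- function(x, ...) {
  cat(sprintf("<position_profile '%s': %d columns, %d masked, %s>\n",
              x$id, nrow(x$columns), length(x$masked_columns),
              if (is.null(x$calibration)) "uncalibrated"
              else sprintf("lambda=%.3f mu=%.2f", x$calibration$lambda,
                           x$calibration$mu)))
  invisible(x)
}

# Emission log-odds matrix: profile columns x allowed residues (bits).
# Masked columns and 'X' score 0 (background).
#' @noRd
emission_matrix <- function(profile) {
  E <- log2(sweep(profile$columns, 2, profile$background, "/"))
  E <- cbind(E, X = 0)
  if (length(profile$masked_columns) > 0)
    E[profile$masked_columns, ] <- 0
  E
}

# Query-by-profile score matrix for the DP (rows = query residues).
#' @noRd
seq_score_matrix <- function(profile, residues, E = emission_matrix(profile)) {
  idx <- match(str_to_chars(residues), colnames(E))
  t(E)[idx, , drop = FALSE]
}

#' Score a sequence against a position profile
#'
#' Best local alignment of the sequence to the profile columns by dynamic
#' programming with affine gap costs (open 4 bits, extend 0.25 bits per
#' additional position). Emission scores are `log2(freq/background)` in
#' bits; masked columns and `X` residues contribute 0.
#'
#' @param profile a `position_profile`.
#' @param seq residue string or single-row `protein_db`.
#' @return a list with `bit_score`, `env_start`/`env_end` (1-based inclusive
#'   envelope on the sequence; 0/0 when the best score is 0), `col_start`/
#'   `col_end` (profile column envelope) and `pairs` (matched
#'   residue-position/column pairs).
#' @export
score_sequence <- function(profile, seq) {
  residues <- as_residues(seq)
  S <- seq_score_matrix(profile, residues)
  r <- .sw_affine(S, 4, 0.25)
  list(bit_score = r$score, env_start = r$q_start, env_end = r$q_end,
       col_start = r$r_start, col_end = r$r_end, pairs = r$pairs)
}

#' Calibrate a profile's score distribution
#'
#' Scores `n_shuffles` i.i.d. random sequences drawn from the profile
#' background and fits a Gumbel (type-I extreme value) distribution to the
#' resulting local-alignment scores by maximum likelihood. The fitted
#' `(lambda, mu)` give e-values via
#' `E = db_size * P(S >= s) = db_size * (1 - exp(-exp(-lambda (s - mu))))`.
#'
#' @param profile a `position_profile`.
#' @param n_shuffles number of random sequences (>= 100).
#' @param target_len length of each random sequence (typically the median
#'   database sequence length).
#' @param seed integer seed.
#' @return the profile with `calibration = list(lambda, mu, ...)` attached.
#' @export
calibrate <- function(profile, n_shuffles = 500, target_len = 250, seed = 1) {
  if (n_shuffles < 100) stop("n_shuffles must be >= 100")
  E <- emission_matrix(profile)
  scores <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      s <- paste(sample(AA20, target_len, replace = TRUE,
                        prob = profile$background), collapse = "")
      .sw_affine_score(seq_score_matrix(profile, s, E), 4, 0.25)
    }, 0)
  })
  if (sd(scores) == 0)
    stop("degenerate score distribution: all calibration scores equal")
  fit <- fit_gumbel(scores)
  profile$calibration <- list(lambda = 1 / fit$beta, mu = fit$mu,
                              n_shuffles = n_shuffles,
                              target_len = target_len, seed = seed)
  profile
}

# Maximum-likelihood Gumbel fit, moment-initialized.
#' @noRd
fit_gumbel <- function(x) {
  beta0 <- sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.57721566 * beta0
  nll <- function(p) {
    mu <- p[1]; beta <- exp(p[2])
    z <- (x - mu) / beta
    length(x) * log(beta) + sum(z + exp(-z))
  }
  opt <- optim(c(mu0, log(beta0)), nll, method = "Nelder-Mead")
  list(mu = opt$par[1], beta = exp(opt$par[2]))
}

#' E-value of a bit score under a calibrated profile
#'
#' @param profile calibrated `position_profile`.
#' @param score bit score(s).
#' @param db_size number of sequences searched.
#' @return expected number of equal-or-better scores among `db_size`
#'   unrelated sequences.
#' @export
e_value <- function(profile, score, db_size) {
  if (is.null(profile$calibration)) stop("profile is not calibrated")
  lam <- profile$calibration$lambda
  mu <- profile$calibration$mu
  tail <- exp(-lam * (score - mu))
  db_size * (-expm1(-tail))
}

#' Search a sequence database with a calibrated profile
#'
#' @param profile calibrated `position_profile`.
#' @param db a `protein_db`.
#' @param e_cutoff keep hits with e-value at or below this (default 1, the
#'   deliberately shallow first-pass cutoff; candidates are vetted later by
#'   masked profile-profile validation).
#' @return a data frame of hits (`profile_id`, `target_id`, `bit_score`,
#'   `e_value`, `env_start`, `env_end`), sorted by ascending e-value then
#'   target id. The database size for the e-value is `nrow(db)`.
#' @export
search_db <- function(profile, db, e_cutoff = 1.0) {
  if (is.null(profile$calibration)) stop("profile is not calibrated")
  E <- emission_matrix(profile)
  n <- nrow(db)
  res <- lapply(seq_len(n), function(i) {
    r <- .sw_affine(seq_score_matrix(profile, db$residues[i], E), 4, 0.25)
    c(score = r$score, s = r$q_start, e = r$q_end)
  })
  res <- do.call(rbind, res)
  ev <- e_value(profile, res[, "score"], n)
  keep <- which(ev <= e_cutoff)
  hits <- data.frame(profile_id = rep(profile$id, length(keep)),
                     target_id = db$id[keep],
                     bit_score = res[keep, "score"], e_value = ev[keep],
                     env_start = as.integer(res[keep, "s"]),
                     env_end = as.integer(res[keep, "e"]),
                     stringsAsFactors = FALSE)
  hits[order(hits$e_value, hits$target_id), , drop = FALSE]
}

#' Consensus sequence of a profile (highest-frequency residue per column)
#' @param profile a `position_profile`.
#' @return residue string.
#' @export
profile_consensus <- function(profile) {
  paste(AA20[max.col(profile$columns, ties.method = "first")], collapse = "")
}

#' Write a profile in the package's plain-text format
#'
#' Header lines (`id`, `ncols`, `background`, `match_col_map`, `masked`,
#' `calibration`) followed by one `col` line of 20 frequencies per profile
#' column.
#'
#' @param profile a `position_profile`; @param path output file.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w"); on.exit(close(con))
  num <- function(x) paste(formatC(x, digits = 15, format = "g"), collapse = " ")
  writeLines(c("# famforge profile v1",
               paste("id", profile$id),
               paste("ncols", nrow(profile$columns)),
               paste("background", num(profile$background)),
               paste("match_col_map", paste(profile$match_col_map, collapse = " ")),
               paste("masked", paste(profile$masked_columns, collapse = " ")),
               paste("calibration",
                     if (is.null(profile$calibration)) "none"
                     else num(c(profile$calibration$lambda,
                                profile$calibration$mu)))), con)
  for (j in seq_len(nrow(profile$columns)))
    writeLines(paste("col", num(profile$columns[j, ])), con)
  invisible(path)
}

#' Read a profile written by [write_profile()]
#' @param path input file.
#' @return a `position_profile`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# famforge profile", lines[1]))
    stop("not a famforge profile file: ", path)
  fields <- strsplit(lines[-1], " ")
  key <- vapply(fields, `[`, "", 1)
  val <- lapply(fields, `[`, -1)
  get1 <- function(k) val[[which(key == k)[1]]]
  id <- paste(get1("id"), collapse = " ")
  bg <- setNames(as.numeric(get1("background")), AA20)
  map <- as.integer(get1("match_col_map"))
  masked_raw <- get1("masked")
  masked <- if (length(masked_raw) == 0 || all(masked_raw == "")) integer(0)
            else as.integer(masked_raw)
  cal_raw <- get1("calibration")
  cal <- if (identical(cal_raw, "none")) NULL
         else list(lambda = as.numeric(cal_raw[1]), mu = as.numeric(cal_raw[2]))
  cols <- do.call(rbind, lapply(val[key == "col"], as.numeric))
  colnames(cols) <- AA20
  mask <- rep(FALSE, max(map))
  mask[map] <- TRUE
  structure(list(id = id, columns = cols, background = bg,
                 match_mask = mask, match_col_map = map,
                 masked_columns = masked, calibration = cal),
            class = "position_profile")
}
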