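# PROSITE-style patterns as anchored regular expressions. 'x' matches any
# allowed residue including 'X'.
PRAT_PATTERN <- "[GA]..[FY].{10}R.{3}D.{6}[GAS]G.{3}G"
PRAT_LEN <- 31L
ZIPPER_PATTERN <- "G...G...G"
ZIPPER_LEN <- 9L

# All (possibly overlapping) match start positions of a fixed-length
# pattern, via a zero-width lookahead.
#' @noRd
scan_pattern <- function(residues, pattern, width, name) {
  starts <- gregexpr(sprintf("(?=%s)", pattern), residues, perl = TRUE)[[1]]
  if (starts[1] == -1) {
    return(data.frame(motif_name = character(0), start = integer(0),
                      end = integer(0), matched_span = character(0),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(starts)
  data.frame(motif_name = name, start = starts, end = starts + width - 1L,
             matched_span = substring(residues, starts, starts + width - 1L),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for the PRAT motif
#'
#' The 31-position preprotein and amino-acid transporter (PRAT) pattern
#' `[GA]-x-x-[FY]-x(10)-R-x(3)-D-x(6)-[GAS]-G-x(3)-G`. All overlapping
#' windows are reported in left-to-right order; `x` matches any residue
#' including `X`. Coordinates are 1-based inclusive.
#'
#' @param seq residue string or single-row `protein_db`.
#' @return data frame of matches (`motif_name`, `start`, `end`,
#'   `matched_span`).
#' @export
scan_prat <- function(seq) {
  scan_pattern(as_residues(seq), PRAT_PATTERN, PRAT_LEN, "PRAT")
}

#' Scan a sequence for glycine zippers (GxxxGxxxG)
#'
#' @inheritParams scan_prat
#' @return data frame of 9-residue matches with glycines at offsets 0, 4
#'   and 8.
#' @export
scan_zipper <- function(seq) {
  scan_pattern(as_residues(seq), ZIPPER_PATTERN, ZIPPER_LEN, "GLY_ZIPPER")
}

#' Predict transmembrane segments by sliding-window hydropathy
#'
#' Computes the Kyte-Doolittle window mean over every full window of odd
#' width; a residue is called hydrophobic when it lies inside at least one
#' window whose mean exceeds the threshold (the classic reading of a
#' hydropathy peak: the whole window is the candidate membrane span).
#' Maximal hydrophobic runs separated by at most `merge_gap` residues are
#' merged, and runs shorter than `min_tm_len` are dropped.
#'
#' @param seq residue string or single-row `protein_db`; `X` scores 0.
#' @param window odd window width (default 19).
#' @param threshold window-mean hydropathy threshold (default 1.6).
#' @param min_tm_len minimum reported segment length (default 15).
#' @param merge_gap merge segments separated by at most this many residues
#'   (default 3).
#' @return data frame of segments (`start`, `end` 1-based inclusive,
#'   `mean_hydropathy`), non-overlapping and sorted; zero rows (with
#'   attribute `too_short = TRUE` and a warning) when the sequence is
#'   shorter than the window.
#' @export
predict_tm <- function(seq, window = 19, threshold = 1.6, min_tm_len = 15,
                       merge_gap = 3) {
  if (window %% 2 == 0) stop("window must be odd")
  residues <- as_residues(seq)
  L <- nchar(residues)
  empty <- data.frame(start = integer(0), end = integer(0),
                      mean_hydropathy = numeric(0))
  if (L < window) {
    warning("sequence shorter than hydropathy window; no prediction")
    attr(empty, "too_short") <- TRUE
    return(empty)
  }
  h <- KD_SCALE[str_to_chars(residues)]
  wm <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  centers <- which(!is.na(wm) & wm > threshold)
  mark <- rep(FALSE, L)
  half <- (window - 1L) %/% 2L
  for (c in centers) mark[max(1L, c - half):min(L, c + half)] <- TRUE
  if (!any(mark)) return(empty)
  runs <- rle(mark)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- cbind(starts[runs$values], ends[runs$values])
  # merge runs separated by short hydrophilic gaps
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) {
    for (r in 2:nrow(seg)) {
      last <- nrow(merged)
      if (seg[r, 1] - merged[last, 2] - 1L <= merge_gap)
        merged[last, 2] <- seg[r, 2]
      else merged <- rbind(merged, seg[r, , drop = FALSE])
    }
  }
  keep <- (merged[, 2] - merged[, 1] + 1L) >= min_tm_len
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) == 0) return(empty)
  data.frame(start = merged[, 1], end = merged[, 2],
             mean_hydropathy = vapply(seq_len(nrow(merged)), function(r)
               mean(h[merged[r, 1]:merged[r, 2]]), 0))
}

#' Split a validated homolog into its family domains
#'
#' Scores the sequence against the calibrated family profile, records the
#' best envelope, hard-masks it with `X`, and rescores. When the second
#' envelope also reaches the e-value cutoff and overlaps the first by fewer
#' than 10 residues, the protein carries two linked family domains (the
#' tandem, Tmem135-like case), reported in N-to-C order. TM-architecture
#' flags come from [predict_tm()]: `two_tm_only` when exactly two TM
#' segments are predicted, `extra_cterm_tm` when a TM segment lies entirely
#' after the last domain envelope.
#'
#' @param seq residue string or single-row `protein_db`.
#' @param family_profile calibrated `position_profile`.
#' @param e_cutoff e-value cutoff for a domain envelope (default 1).
#' @param db_size database size fixing the e-value scale (default 1000).
#' @param ... passed to [predict_tm()].
#' @return a list of class `domain_architecture`: `record_id`,
#'   `n_tim17_domains` (1 or 2), `domain_envelopes` (n x 2 matrix, 1-based
#'   inclusive), `tm_segments` (data frame), `flags` (character vector).
#' @export
split_tandem <- function(seq, family_profile, e_cutoff = 1.0, db_size = 1000,
                         ...) {
  if (is.null(family_profile$calibration))
    stop("family profile is not calibrated")
  residues <- as_residues(seq)
  rid <- if (is.data.frame(seq)) seq$id[1] else "query"
  s1 <- score_sequence(family_profile, residues)
  if (s1$bit_score <= 0 ||
      e_value(family_profile, s1$bit_score, db_size) > e_cutoff)
    stop("no family domain envelope passes e <= ", e_cutoff,
         " for record ", rid)
  env <- matrix(c(s1$env_start, s1$env_end), 1, 2)
  masked <- str_to_chars(residues)
  masked[s1$env_start:s1$env_end] <- "X"
  s2 <- score_sequence(family_profile, paste(masked, collapse = ""))
  n_dom <- 1L
  if (s2$bit_score > 0 &&
      e_value(family_profile, s2$bit_score, db_size) <= e_cutoff) {
    overlap <- min(s1$env_end, s2$env_end) - max(s1$env_start, s2$env_start) + 1L
    if (overlap < 10L) {
      env <- rbind(env, c(s2$env_start, s2$env_end))
      env <- env[order(env[, 1]), , drop = FALSE]
      n_dom <- 2L
    }
  }
  tm <- suppressWarnings(predict_tm(residues, ...))
  flags <- character(0)
  if (nrow(tm) == 2) flags <- c(flags, "two_tm_only")
  if (nrow(tm) > 0 && any(tm$start > env[nrow(env), 2]))
    flags <- c(flags, "extra_cterm_tm")
  structure(list(record_id = rid, n_tim17_domains = n_dom,
                 domain_envelopes = env, tm_segments = tm, flags = flags),
            class = "domain_architecture")
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat(sprintf("<domain_architecture %s: %d domain(s), %d TM segment(s)%s>\n",
              x$record_id, x$n_tim17_domains, nrow(x$tm_segments),
              if (length(x$flags)) paste0(", flags: ",
                                          paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Scan a record table for motifs, as a TSV-ready table
#' @param records a `protein_db`.
#' @param motif `"PRAT"` or `"GLY_ZIPPER"`.
#' @return data frame `record_id`, `motif`, `start`, `end`, `span`.
#' @export
scan_records <- function(records, motif = c("PRAT", "GLY_ZIPPER")) {
  motif <- match.arg(motif)
  f <- if (motif == "PRAT") scan_prat else scan_zipper
  out <- lapply(seq_len(nrow(records)), function(i) {
    m <- f(records$residues[i])
    if (nrow(m) == 0) return(NULL)
    data.frame(record_id = records$id[i], motif = m$motif_name,
               start = m$start, end = m$end, span = m$matched_span,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(record_id = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      span = character(0), stringsAsFactors = FALSE)
  out
}
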