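#' Pairwise sequence identity under global alignment
#'
#' Globally aligns two sequences under BLOSUM62 with affine gap costs
#' (open 11, extend 1) and reports the fraction of identical aligned pairs
#' over the length of the shorter sequence, so a fragment of a family member
#' still scores high against the full-length protein.
#'
#' @param a,b residue strings or single-row `protein_db` rows.
#' @return identity fraction in \[0, 1\]; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b) {
  a <- as_residues(a); b <- as_residues(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global", scoreOnly = FALSE)
  p <- str_to_chars(as.character(Biostrings::alignedPattern(pa)))
  s <- str_to_chars(as.character(Biostrings::alignedSubject(pa)))
  n_ident <- sum(p == s & p != "-")
  n_ident / min(nchar(a), nchar(b))
}

# Identity of one query against several representatives in a single
# vectorized alignment call.
#' @noRd
identity_to_reps <- function(query, reps) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(rep(query, length(reps))),
    Biostrings::AAStringSet(reps),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  p <- as.character(Biostrings::alignedPattern(pa))
  s <- as.character(Biostrings::alignedSubject(pa))
  vapply(seq_along(reps), function(i) {
    pc <- str_to_chars(p[i]); sc <- str_to_chars(s[i])
    sum(pc == sc & pc != "-") / min(nchar(query), nchar(reps[i]))
  }, 0)
}

#' @noRd
as_residues <- function(x) {
  if (is.data.frame(x)) x$residues[1] else as.character(x)
}

#' Greedy identity clustering
#'
#' Records are sorted by descending length (ties broken by ascending id) and
#' each record joins the first existing cluster whose representative it
#' matches at or above the identity threshold, otherwise it founds a new
#' cluster. Representatives are therefore the longest members, and any two
#' representatives are below the threshold to each other.
#'
#' @param records a `protein_db`.
#' @param threshold identity fraction in (0, 1\].
#' @return a list of clusters, each a list with `representative_id`,
#'   `member_ids` and `threshold`.
#' @export
greedy_cluster <- function(records, threshold = 0.4) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (is.null(records) || nrow(records) == 0) return(list())
  ord <- order(-nchar(records$residues), records$id)
  records <- records[ord, , drop = FALSE]
  reps_id <- character(0); reps_seq <- character(0)
  members <- list()
  for (i in seq_len(nrow(records))) {
    joined <- FALSE
    if (length(reps_id) > 0) {
      ids <- identity_to_reps(records$residues[i], reps_seq)
      hit <- which(ids >= threshold)
      if (length(hit) > 0) {
        k <- hit[1]
        members[[k]] <- c(members[[k]], records$id[i])
        joined <- TRUE
      }
    }
    if (!joined) {
      reps_id <- c(reps_id, records$id[i])
      reps_seq <- c(reps_seq, records$residues[i])
      members[[length(reps_id)]] <- records$id[i]
    }
  }
  lapply(seq_along(reps_id), function(k)
    list(representative_id = reps_id[k], member_ids = members[[k]],
         threshold = threshold))
}

#' Write clusters as TSV
#'
#' Columns: `cluster_id`, `representative_id`, `member_id`.
#' @param clusters output of [greedy_cluster()].
#' @param path output file.
#' @export
write_clusters <- function(clusters, path) {
  rows <- do.call(rbind, lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    data.frame(cluster_id = sprintf("cluster%03d", k),
               representative_id = cl$representative_id,
               member_id = cl$member_ids, stringsAsFactors = FALSE)
  }))
  write_tsv(rows, path)
}
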