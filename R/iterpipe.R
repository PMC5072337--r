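#' Parameters for the iterative family-expansion loop
#'
#' Defaults follow the published search protocol: clustering at 40%
#' identity, a deliberately shallow e <= 1 search cutoff, and a 0.9
#' calibrated-probability threshold for masked profile-profile validation,
#' for at most 10 iterations.
#'
#' @param id_threshold greedy clustering identity threshold.
#' @param e_cutoff search e-value cutoff.
#' @param prob_threshold masked validation probability threshold.
#' @param pseudocount_weight profile pseudocount mass.
#' @param n_shuffles random sequences per profile calibration.
#' @param n_calib_decoys zipper decoys generated per iteration for the
#'   probability calibration (composition-shuffled master rows are added on
#'   top, one per row used).
#' @param n_calib_true maximum master rows used as true calibration
#'   profiles (each also contributes one simulated remote homolog).
#' @param calib_divergence substitution depth (expected substitutions/site)
#'   of the simulated remote homologs that anchor the low end of the
#'   positive calibration class; the validation should still accept family
#'   members out to roughly this divergence.
#' @param g_fraction glycine fraction for zipper column detection.
#' @param pin_seed_master validate against the original seed master instead
#'   of the evolving master.
#' @param rng_seed integer seed driving every stochastic step.
#' @return a named list.
#' @export
pipeline_params <- function(id_threshold = 0.40, e_cutoff = 1.0,
                            prob_threshold = 0.9, pseudocount_weight = 1,
                            n_shuffles = 300, n_calib_decoys = 25,
                            n_calib_true = 40, calib_divergence = 1.5,
                            g_fraction = 0.7,
                            pin_seed_master = FALSE, rng_seed = 1) {
  list(id_threshold = id_threshold, e_cutoff = e_cutoff,
       prob_threshold = prob_threshold,
       pseudocount_weight = pseudocount_weight, n_shuffles = n_shuffles,
       n_calib_decoys = n_calib_decoys, n_calib_true = n_calib_true,
       calib_divergence = calib_divergence,
       g_fraction = g_fraction, pin_seed_master = pin_seed_master,
       rng_seed = as.integer(rng_seed))
}

#' Initialize the iteration state from a seed alignment
#'
#' The seed alignment pins the master column frame for the whole run: match
#' columns are the seed columns with under 50% gaps, and attached sequences
#' never add new master columns.
#'
#' @param seed_aln an `msa` with at least 2 rows.
#' @return an object of class `iteration_state`.
#' @export
init_state <- function(seed_aln) {
  stopifnot(inherits(seed_aln, "msa"))
  if (length(seed_aln$rows) < 2) stop("seed alignment needs >= 2 rows")
  m <- msa_matrix(seed_aln)
  match_mask <- colMeans(m == "-") < 0.5
  records <- protein_records(names(seed_aln$rows), ungap(seed_aln$rows))
  structure(list(iteration = 0L, homolog_ids = names(seed_aln$rows),
                 master = seed_aln, seed_master = seed_aln,
                 records = records, match_mask = match_mask,
                 insertions = list(),
                 log = data.frame(iteration = integer(0),
                                  n_homologs = integer(0),
                                  n_clusters = integer(0),
                                  n_candidates = integer(0),
                                  n_added = integer(0),
                                  n_rejected = integer(0))),
            class = "iteration_state")
}

#' @export
print.iteration_state <- function(x, ...) {
  cat(sprintf("<iteration_state: iteration %d, %d homologs, master %dx%d>\n",
              x$iteration, length(x$homolog_ids), length(x$master$rows),
              x$master$n_cols))
  invisible(x)
}

#' Attach a sequence to the master alignment
#'
#' The sequence is aligned to the master profile's match columns via the
#' local-alignment traceback; matched residues are placed in the
#' corresponding master columns and residues falling into insert states are
#' recorded as per-row insertion annotations rather than new columns, so the
#' master column count never changes.
#'
#' @param master the master `msa`.
#' @param new_seq a single-row `protein_db` (or named residue string).
#' @param master_profile `position_profile` built from `master` (unmasked).
#' @return the master with one added row; the attached row's insertions are
#'   kept in `attr(, "insertions")`.
#' @export
attach_to_master <- function(master, new_seq, master_profile) {
  if (is.data.frame(new_seq)) {
    id <- new_seq$id[1]; residues <- new_seq$residues[1]
  } else {
    id <- names(new_seq)[1]; residues <- as.character(new_seq)[1]
    if (is.null(id)) stop("new sequence must carry an id")
  }
  if (id %in% names(master$rows))
    stop("sequence id already present in master: ", id)
  sc <- score_sequence(master_profile, residues)
  if (nrow(sc$pairs) == 0)
    stop("sequence does not align to the master profile: ", id)
  row <- rep("-", master$n_cols)
  chars <- str_to_chars(residues)
  mcols <- master_profile$match_col_map[sc$pairs[, 2]]
  row[mcols] <- chars[sc$pairs[, 1]]
  ins_pos <- setdiff(seq(sc$env_start, sc$env_end), sc$pairs[, 1])
  rows <- c(master$rows, setNames(paste(row, collapse = ""), id))
  out <- msa(rows)
  ins <- attr(master, "insertions")
  if (is.null(ins)) ins <- list()
  ins[[id]] <- chars[ins_pos]
  attr(out, "insertions") <- ins
  out
}

# Build the masked, probability-calibrated master profile for validation.
# Positive examples: the master's own rows plus simulated remote homologs of
# those rows (Poisson substitution at depth `calib_divergence`), so the
# logistic boundary sits at the family's expected divergence horizon rather
# than at near-identity. Negatives: generated glycine-zipper random proteins
# plus composition-shuffled master rows, so the boundary also hugs the
# non-homolog score range.
#' @noRd
calibrated_masked_master <- function(aln, match_mask, params, iter_seed) {
  prof <- build_profile(aln, params$pseudocount_weight,
                        match_mask = match_mask, id = "master")
  mask_cols <- zipper_mask_columns(aln, params$g_fraction,
                                   match_mask = match_mask, expand = TRUE)
  masked <- mask_profile(prof, mask_cols)
  rows <- ungap(aln$rows)
  pick <- if (length(rows) > params$n_calib_true)
    rows[round(seq(1, length(rows), length.out = params$n_calib_true))]
  else rows
  remote <- with_seed(derive_seed(iter_seed, 6), {
    vapply(pick, function(s) {
      ch <- str_to_chars(s)
      paste(evolve_branch(ch, params$calib_divergence,
                          rate = rep(1, length(ch)),
                          loop_mask = rep(FALSE, length(ch))), collapse = "")
    }, "")
  })
  true_seqs <- c(pick, remote)
  true_prof <- lapply(seq_along(true_seqs), function(i)
    single_seq_profile(true_seqs[i], id = paste0("true", i)))
  med_len <- as.integer(median(nchar(rows)))
  dec <- generate_decoys(params$n_calib_decoys, derive_seed(iter_seed, 7),
                         length = max(27L, med_len))
  shuf <- with_seed(derive_seed(iter_seed, 8), {
    vapply(pick, function(s)
      paste(sample(str_to_chars(s)), collapse = ""), "")
  })
  decoy_prof <- c(
    lapply(seq_len(nrow(dec)), function(i) single_seq_profile(dec[i, ])),
    lapply(seq_along(shuf), function(i)
      single_seq_profile(shuf[i], id = paste0("shuf", i))))
  list(masked = calibrate_probability(masked, decoy_prof, true_prof),
       unmasked = prof)
}

#' Run one iteration of the family-expansion loop
#'
#' Clusters the current homolog set at the identity threshold, builds and
#' calibrates a search profile per cluster (from the members' master rows),
#' searches the database at the e-value cutoff, validates every new hit
#' against the masked master at the probability threshold, and attaches
#' accepted hits to the master alignment.
#'
#' @param state an `iteration_state`.
#' @param db a `protein_db` database.
#' @param params a [pipeline_params()] list.
#' @return the advanced `iteration_state`; element `validation` holds the
#'   per-candidate validation report of this iteration.
#' @export
run_iteration <- function(state, db, params = pipeline_params()) {
  stopifnot(inherits(state, "iteration_state"))
  if (length(state$homolog_ids) == 0) stop("empty homolog set")
  iter <- state$iteration + 1L
  iter_seed <- derive_seed(params$rng_seed, iter)

  clusters <- greedy_cluster(state$records, params$id_threshold)
  mm_src <- if (params$pin_seed_master) state$seed_master else state$master
  mm_mask <- if (params$pin_seed_master)
    colMeans(msa_matrix(state$seed_master) == "-") < 0.5 else state$match_mask
  cm <- calibrated_masked_master(mm_src, mm_mask, params, iter_seed)
  master_profile <- build_profile(state$master, params$pseudocount_weight,
                                  match_mask = state$match_mask, id = "master")
  med_len <- as.integer(median(nchar(db$residues)))

  cand_hits <- list()
  for (k in seq_along(clusters)) {
    ids <- clusters[[k]]$member_ids
    claln <- msa(state$master$rows[ids])
    prof <- build_profile(claln, params$pseudocount_weight,
                          id = sprintf("iter%d_cluster%d", iter, k))
    prof <- calibrate(prof, params$n_shuffles, med_len,
                      seed = derive_seed(iter_seed, k))
    hits <- search_db(prof, db, params$e_cutoff)
    cand_hits[[k]] <- hits[!(hits$target_id %in% state$homolog_ids), ,
                           drop = FALSE]
  }
  cand <- do.call(rbind, cand_hits)
  cand_ids <- sort(unique(cand$target_id))

  reports <- list(); added <- character(0)
  master <- state$master
  for (cid in cand_ids) {
    rec <- db[db$id == cid, , drop = FALSE]
    v <- validate_candidate(single_seq_profile(rec), cm$masked,
                            params$prob_threshold)
    reports[[cid]] <- v$score
    if (v$accepted) {
      master <- attach_to_master(master, rec, master_profile)
      added <- c(added, cid)
    }
  }
  state$master <- master
  state$homolog_ids <- c(state$homolog_ids, added)
  if (length(added) > 0) {
    add_rec <- db[match(added, db$id), , drop = FALSE]
    state$records <- rbind(state$records, add_rec)
    class(state$records) <- c("protein_db", "data.frame")
  }
  state$iteration <- iter
  state$validation <- if (length(reports)) do.call(rbind, reports) else NULL
  state$log <- rbind(state$log, data.frame(
    iteration = iter, n_homologs = length(state$homolog_ids),
    n_clusters = length(clusters), n_candidates = length(cand_ids),
    n_added = length(added), n_rejected = length(cand_ids) - length(added)))
  state
}

#' Run the full iterative family expansion
#'
#' Repeats [run_iteration()] until the iteration cap or a fixed point (an
#' iteration that adds no sequences); on a finite database the loop always
#' reaches a fixed point because the homolog set grows monotonically.
#'
#' @param seed_aln seed `msa` (>= 2 rows) of trusted family members.
#' @param db a `protein_db` database to expand into.
#' @param n_iter iteration cap (default 10).
#' @param params a [pipeline_params()] list.
#' @return the final `iteration_state`.
#' @export
run_pipeline <- function(seed_aln, db, n_iter = 10,
                         params = pipeline_params()) {
  state <- init_state(seed_aln)
  for (i in seq_len(n_iter)) {
    state <- run_iteration(state, db, params)
    if (state$log$n_added[nrow(state$log)] == 0) break
  }
  state
}

#' Split tandem proteins and attach their domains to the master
#'
#' Runs [split_tandem()] on each record; every detected family domain is
#' excised and attached to the master alignment as its own row, labeled
#' `id#N` (and `id#C` for the C-terminal domain of a two-domain protein), so
#' tandem proteins contribute one tree leaf per domain.
#'
#' @param master the master `msa`.
#' @param tandems a `protein_db` of candidate tandem records.
#' @param family_profile calibrated `position_profile` of the family
#'   (typically built from `master`).
#' @param ... passed to [split_tandem()].
#' @return the master with the domain rows attached.
#' @export
attach_tandem_domains <- function(master, tandems, family_profile, ...) {
  for (i in seq_len(nrow(tandems))) {
    arch <- split_tandem(tandems[i, , drop = FALSE], family_profile, ...)
    tags <- if (arch$n_tim17_domains == 2) c("#N", "#C") else "#N"
    for (d in seq_len(arch$n_tim17_domains)) {
      dom <- substr(tandems$residues[i], arch$domain_envelopes[d, 1],
                    arch$domain_envelopes[d, 2])
      master <- attach_to_master(
        master, setNames(dom, paste0(tandems$id[i], tags[d])),
        family_profile)
    }
  }
  master
}

#' Write the pipeline outputs of a run
#'
#' Emits `homologs.fasta`, `master_alignment.afa`, `iterations.tsv` and
#' (when present) `validation.tsv` into `out_dir`.
#'
#' @param state a finished `iteration_state`.
#' @param out_dir output directory (created if needed).
#' @export
write_pipeline_outputs <- function(state, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(state$records, file.path(out_dir, "homologs.fasta"))
  write_alignment(state$master, file.path(out_dir, "master_alignment.afa"))
  write_tsv(state$log, file.path(out_dir, "iterations.tsv"))
  if (!is.null(state$validation))
    write_tsv(state$validation, file.path(out_dir, "validation.tsv"))
  invisible(out_dir)
}
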