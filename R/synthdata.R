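#' Specification for a synthetic membrane-protein superfamily
#'
#' The generator emulates a polytopic inner-membrane family: an ancestor of
#' alternating hydrophilic loops and hydrophobic transmembrane (TM) helices,
#' glycine-zipper (GxxxGxxxG) motifs inside the helices, and one positively
#' plus one negatively charged conserved site in the loop between helices 2
#' and 3. Subfamilies diverge from a common root; members diverge within
#' each subfamily along a random coalescent tree. Zipper glycines and the
#' charged sites evolve at one tenth of the background substitution rate.
#'
#' @param n_subfamilies number of subfamilies.
#' @param members_per_subfamily members (tips) per subfamily.
#' @param n_tm_helices number of TM helices (default 4).
#' @param tm_len helix length in residues (default 20).
#' @param loop_len loop length in residues (default 25).
#' @param zippers_per_helix glycine zippers overlaid per helix (default 1).
#' @param inter_sub_divergence expected substitutions/site between subfamily
#'   ancestors (default 1.0).
#' @param intra_sub_divergence expected substitutions/site between the two
#'   most divergent members of a subfamily; every member sits at
#'   `intra_sub_divergence / 2` from its subfamily ancestor (default 0.3).
#' @param seed integer seed; the same spec and seed give byte-identical
#'   output.
#' @return a list of class `synthetic_family_spec`.
#' @export
synthetic_family_spec <- function(n_subfamilies = 3, members_per_subfamily = 20,
                                  n_tm_helices = 4, tm_len = 20, loop_len = 25,
                                  zippers_per_helix = 1,
                                  inter_sub_divergence = 1.0,
                                  intra_sub_divergence = 0.3, seed = 1) {
  spec <- list(n_subfamilies = n_subfamilies,
               members_per_subfamily = members_per_subfamily,
               n_tm_helices = n_tm_helices, tm_len = tm_len,
               loop_len = loop_len, zippers_per_helix = zippers_per_helix,
               inter_sub_divergence = inter_sub_divergence,
               intra_sub_divergence = intra_sub_divergence,
               seed = as.integer(seed))
  counts <- c("n_subfamilies", "members_per_subfamily", "n_tm_helices",
              "tm_len", "loop_len")
  for (f in counts) if (spec[[f]] < 1) stop(f, " must be >= 1")
  if (spec$zippers_per_helix < 0) stop("zippers_per_helix must be >= 0")
  if (spec$inter_sub_divergence < 0 || spec$intra_sub_divergence < 0)
    stop("divergences must be >= 0")
  if (spec$zippers_per_helix >= 1 && spec$tm_len < 9 * spec$zippers_per_helix)
    stop("tm_len too short to fit ", spec$zippers_per_helix,
         " glycine zipper(s): needs >= ", 9 * spec$zippers_per_helix)
  class(spec) <- "synthetic_family_spec"
  spec
}

# Sample residues for helix / loop segments.
#' @noRd
sample_hydrophobic <- function(n) {
  sample(names(HYDROPHOBIC_WEIGHTS), n, replace = TRUE,
         prob = HYDROPHOBIC_WEIGHTS)
}
#' @noRd
sample_hydrophilic <- function(n) sample(HYDROPHILIC_SET, n, replace = TRUE)

# Build the ancestral architecture. Returns chars, per-site rate factors,
# loop mask, zipper glycine positions (1-based ancestor columns).
#' @noRd
build_ancestor <- function(spec) {
  chars <- character(0)
  loop_mask <- logical(0)
  zipper_pos <- integer(0)
  tm_bounds <- NULL
  add_loop <- function(n) {
    chars <<- c(chars, sample_hydrophilic(n))
    loop_mask <<- c(loop_mask, rep(TRUE, n))
  }
  add_loop(spec$loop_len)
  pos_site <- neg_site <- NA_integer_
  for (h in seq_len(spec$n_tm_helices)) {
    start <- length(chars) + 1L
    # A designed membrane span must actually be hydrophobic enough to
    # insert: resample until the helix (zipper included) averages >= 2.2 on
    # the Kyte-Doolittle scale, comfortably above the classic 1.6 window
    # threshold.
    for (try in 1:200) {
      helix <- sample_hydrophobic(spec$tm_len)
      if (spec$zippers_per_helix >= 1) {
        # each zipper is a 9-residue insertion into the middle of the
        # helix: glycines at offsets 0, 4, 8, hydrophobic x positions
        z <- spec$zippers_per_helix
        mid <- spec$tm_len %/% 2
        for (k in seq_len(z)) {
          zip <- sample_hydrophobic(9L)
          zip[c(1L, 5L, 9L)] <- "G"
          helix <- append(helix, zip, after = mid + (k - 1L) * 9L)
        }
      }
      if (mean(KD_SCALE[helix]) >= 2.2) break
    }
    if (spec$zippers_per_helix >= 1) {
      mid <- spec$tm_len %/% 2
      for (k in seq_len(spec$zippers_per_helix)) {
        off <- mid + (k - 1L) * 9L
        zipper_pos <- c(zipper_pos, start - 1L + off + c(1L, 5L, 9L))
      }
    }
    chars <- c(chars, helix)
    loop_mask <- c(loop_mask, rep(FALSE, length(helix)))
    tm_bounds <- rbind(tm_bounds, c(start, start + length(helix) - 1L))
    if (h == 2L) {
      # conserved charged pair in the loop between helices 2 and 3
      lp <- length(chars)
      pos_site <- lp + max(1L, spec$loop_len %/% 3L)
      neg_site <- lp + max(2L, (2L * spec$loop_len) %/% 3L)
    }
    add_loop(spec$loop_len)
  }
  charged <- integer(0)
  if (!is.na(pos_site)) {
    chars[pos_site] <- "K"
    chars[neg_site] <- "D"
    charged <- c(pos_site, neg_site)
  }
  rate <- rep(1, length(chars))
  rate[c(zipper_pos, charged)] <- 0.1
  list(chars = chars, rate = rate, loop_mask = loop_mask,
       zipper_pos = sort(zipper_pos), charged = charged,
       tm_bounds = tm_bounds)
}

# Evolve a character vector along a branch of length t (expected
# substitutions/site at rate factor 1). Substitutions are uniform among the
# 19 alternatives; deletions occur in loops at 0.1x the substitution rate
# and are irreversible ('-').
#' @noRd
evolve_branch <- function(chars, t, rate, loop_mask) {
  alive <- chars != "-"
  n_events <- rpois(length(chars), t * rate * alive)
  for (i in which(n_events > 0 & alive)) {
    cur <- chars[i]
    for (k in seq_len(n_events[i])) cur <- sample(setdiff(AA20, cur), 1)
    chars[i] <- cur
  }
  del <- rpois(length(chars), t * rate * 0.1 * loop_mask * alive) > 0
  chars[del] <- "-"
  chars
}

# Evolve an ancestor along an ape tree (edge lengths = divergence); returns
# a tips x sites character matrix, rownames = tip labels.
#' @noRd
evolve_along_tree <- function(tree, anc, rate, loop_mask) {
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  seqs[[root]] <- anc
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; chl <- edges[e, 2]
    seqs[[chl]] <- evolve_branch(seqs[[par]], lens[e], rate, loop_mask)
  }
  out <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(out) <- tree$tip.label
  out
}

# Random ultrametric within-subfamily tree with tip depth d/2.
#' @noRd
subfamily_tree <- function(n, labels, depth) {
  if (n == 1) {
    tr <- ape::read.tree(text = sprintf("(%s:%f);", labels, depth))
    return(tr)
  }
  tr <- ape::rcoal(n, tip.label = labels)
  h <- max(ape::node.depth.edgelength(tr))
  if (h > 0) tr$edge.length <- tr$edge.length * depth / h
  tr
}

#' Generate a synthetic superfamily with known truth
#'
#' @param spec a [synthetic_family_spec()].
#' @return a list with `records` (a `protein_db`) and `truth`, where `truth`
#'   contains the label table, the true tree (`phylo`), the true alignment
#'   (`msa`, ancestor column frame with deletions as gaps), the 1-based
#'   zipper glycine columns, and the TM helix column ranges.
#' @export
generate_superfamily <- function(spec) {
  stopifnot(inherits(spec, "synthetic_family_spec"))
  with_seed(spec$seed, {
    anc <- build_ancestor(spec)
    sub_labels <- sprintf("sf%02d", seq_len(spec$n_subfamilies))
    rows <- list(); trees <- character(0)
    for (k in seq_len(spec$n_subfamilies)) {
      sub_anc <- evolve_branch(anc$chars, spec$inter_sub_divergence / 2,
                               anc$rate, loop_mask = rep(FALSE, length(anc$chars)))
      tips <- sprintf("%s_m%03d", sub_labels[k],
                      seq_len(spec$members_per_subfamily))
      tr <- subfamily_tree(spec$members_per_subfamily, tips,
                           spec$intra_sub_divergence / 2)
      mat <- evolve_along_tree(tr, sub_anc, anc$rate, anc$loop_mask)
      for (tip in rownames(mat)) rows[[tip]] <- paste(mat[tip, ], collapse = "")
      nwk <- ape::write.tree(tr)
      trees <- c(trees, sprintf("%s:%f", sub(";$", "", nwk),
                                spec$inter_sub_divergence / 2))
    }
    full_nwk <- if (length(trees) == 1) paste0(trees, ";") else
      sprintf("(%s);", paste(trees, collapse = ","))
    truth_tree <- ape::read.tree(text = full_nwk)
    aln <- msa(unlist(rows))
    ids <- names(aln$rows)
    labels <- data.frame(
      record_id = ids,
      proteome_id = NA_character_,
      label = sub("_m\\d+$", "", ids),
      subfamily = sub("_m\\d+$", "", ids),
      stringsAsFactors = FALSE)
    records <- protein_records(ids, ungap(aln$rows))
    truth <- structure(list(labels = labels, tree = truth_tree,
                            alignment = aln,
                            zipper_columns = anc$zipper_pos,
                            charged_columns = anc$charged,
                            tm_bounds = anc$tm_bounds,
                            tandem_sources = NULL),
                       class = "synthetic_truth")
    list(records = records, truth = truth)
  })
}

#' Generate glycine-zipper decoy proteins
#'
#' Decoys are i.i.d.-uniform random proteins carrying 2-4 exact GxxxGxxxG
#' motifs and no other shared structure; they model compositional
#' confounders that share only the zipper with a genuine membrane family.
#'
#' @param n number of decoys.
#' @param seed integer seed.
#' @param length decoy length in residues.
#' @return a `protein_db` with ids `decoy_###`.
#' @export
generate_decoys <- function(n, seed, length = 205) {
  if (n < 1) stop("n must be >= 1")
  if (length < 27) stop("decoy length must be >= 27 to fit 3 zippers")
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      chars <- sample(AA20, length, replace = TRUE)
      k <- sample(2:4, 1)
      starts <- integer(0)
      avail <- seq_len(length - 8L)
      for (z in seq_len(k)) {
        ok <- avail[vapply(avail, function(s)
          all(abs(s - starts) >= 9L), TRUE)]
        if (!length(ok)) break
        s <- if (length(ok) == 1) ok else sample(ok, 1)
        starts <- c(starts, s)
      }
      for (s in starts) chars[s + c(0L, 4L, 8L)] <- "G"
      paste(chars, collapse = "")
    }, "")
    protein_records(sprintf("decoy_%03d", seq_len(n)), seqs)
  })
}

#' Generate tandem two-domain proteins from family members
#'
#' Each tandem is the concatenation of two distinct family members joined by
#' a random hydrophilic linker of 10-30 residues, emulating proteins that
#' carry two linked family domains.
#'
#' @param records family member `protein_db` (>= 2 rows).
#' @param seed integer seed.
#' @param n number of tandems (default: half the number of inputs).
#' @return a `protein_db` with ids `tandem_###`; attribute `sources` is a
#'   data frame with the N- and C-terminal source ids and linker length.
#' @export
generate_tandem <- function(records, seed, n = NULL) {
  if (nrow(records) < 2) stop("need >= 2 family records to build tandems")
  if (is.null(n)) n <- max(1L, nrow(records) %/% 2L)
  with_seed(seed, {
    src <- data.frame(id = character(0), n_source = character(0),
                      c_source = character(0), linker_len = integer(0),
                      stringsAsFactors = FALSE)
    seqs <- character(n)
    for (i in seq_len(n)) {
      pick <- sample(nrow(records), 2)
      ll <- sample(10:30, 1)
      linker <- paste(sample_hydrophilic(ll), collapse = "")
      seqs[i] <- paste0(records$residues[pick[1]], linker,
                        records$residues[pick[2]])
      src <- rbind(src, data.frame(id = sprintf("tandem_%03d", i),
                                   n_source = records$id[pick[1]],
                                   c_source = records$id[pick[2]],
                                   linker_len = ll, stringsAsFactors = FALSE))
    }
    out <- protein_records(src$id, seqs)
    attr(out, "sources") <- src
    out
  })
}

#' Generate random background proteins
#'
#' @param n count; @param seed integer seed.
#' @param len_range inclusive length range sampled uniformly.
#' @return a `protein_db` with ids `bg_####`.
#' @export
generate_background <- function(n, seed, len_range = c(150, 350)) {
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, {
    lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE), collapse = ""), "")
    protein_records(sprintf("bg_%04d", seq_len(n)), seqs)
  })
}

#' Default benchmark configuration
#'
#' Three proteomes, each carrying 20 members of each of 3 subfamilies, 20
#' zipper decoys and 200 background proteins.
#'
#' @param ... overrides for any field.
#' @return a named list.
#' @export
benchmark_config <- function(...) {
  cfg <- list(n_proteomes = 3, n_subfamilies = 3, members_per_subfamily = 20,
              decoys_per_proteome = 20, background_per_proteome = 200,
              n_tandem = 0, seed = 1,
              n_tm_helices = 4, tm_len = 20, loop_len = 25,
              zippers_per_helix = 1, inter_sub_divergence = 1.0,
              intra_sub_divergence = 0.3)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Generate a benchmark database of proteome FASTA files with truth
#'
#' Family members are distributed round-robin over the proteomes so each
#' proteome carries `members_per_subfamily` members of every subfamily.
#'
#' @param config a [benchmark_config()] list.
#' @param out_dir output directory (one FASTA per proteome plus
#'   `truth.tsv`, `truth_alignment.afa`, `truth_tree.nwk`); `NULL` skips
#'   writing.
#' @param force overwrite a non-empty `out_dir`.
#' @return (invisibly) a list with `records` (all proteomes combined) and
#'   `truth`.
#' @export
generate_benchmark <- function(config = benchmark_config(), out_dir = NULL,
                               force = FALSE) {
  cfg <- config
  spec <- synthetic_family_spec(
    n_subfamilies = cfg$n_subfamilies,
    members_per_subfamily = cfg$members_per_subfamily * cfg$n_proteomes,
    n_tm_helices = cfg$n_tm_helices, tm_len = cfg$tm_len,
    loop_len = cfg$loop_len, zippers_per_helix = cfg$zippers_per_helix,
    inter_sub_divergence = cfg$inter_sub_divergence,
    intra_sub_divergence = cfg$intra_sub_divergence,
    seed = derive_seed(cfg$seed, 1))
  fam <- generate_superfamily(spec)
  records <- fam$records
  truth <- fam$truth
  # round-robin proteome assignment of family members within each subfamily
  member_idx <- as.integer(sub("^sf\\d+_m", "", records$id))
  prot_of <- ((member_idx - 1L) %% cfg$n_proteomes) + 1L
  records$proteome_id <- sprintf("proteome%d", prot_of)

  all_records <- records
  if (cfg$n_tandem > 0) {
    tand <- generate_tandem(records, derive_seed(cfg$seed, 2),
                            n = cfg$n_tandem)
    truth$tandem_sources <- attr(tand, "sources")
    tand$proteome_id <- sprintf("proteome%d",
                                ((seq_len(nrow(tand)) - 1L) %% cfg$n_proteomes) + 1L)
    all_records <- rbind(all_records, tand)
  }
  for (p in seq_len(cfg$n_proteomes)) {
    if (cfg$decoys_per_proteome > 0) {
      dec <- generate_decoys(cfg$decoys_per_proteome,
                             derive_seed(cfg$seed, 3, p))
      dec$id <- sprintf("p%d_%s", p, dec$id)
      dec$proteome_id <- sprintf("proteome%d", p)
      all_records <- rbind(all_records, dec)
    }
    if (cfg$background_per_proteome > 0) {
      bg <- generate_background(cfg$background_per_proteome,
                                derive_seed(cfg$seed, 4, p))
      bg$id <- sprintf("p%d_%s", p, bg$id)
      bg$proteome_id <- sprintf("proteome%d", p)
      all_records <- rbind(all_records, bg)
    }
  }
  class(all_records) <- c("protein_db", "data.frame")
  lab <- function(id) {
    ifelse(grepl("^sf", id), sub("_m\\d+$", "", id),
           ifelse(grepl("^tandem", id), "tandem",
                  ifelse(grepl("decoy", id), "decoy", "background")))
  }
  truth$labels <- data.frame(
    record_id = all_records$id,
    proteome_id = all_records$proteome_id,
    label = ifelse(grepl("^sf", all_records$id), "subfamily",
                   lab(all_records$id)),
    subfamily = ifelse(grepl("^sf", all_records$id),
                       sub("_m\\d+$", "", all_records$id), ""),
    stringsAsFactors = FALSE)
  truth$labels$label[truth$labels$label == "subfamily"] <-
    truth$labels$subfamily[truth$labels$label == "subfamily"]

  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
      stop("output directory exists and is non-empty: ", out_dir,
           " (use force = TRUE to overwrite)")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (p in unique(all_records$proteome_id)) {
      sub_df <- all_records[all_records$proteome_id == p, , drop = FALSE]
      write_fasta(sub_df, file.path(out_dir, paste0(p, ".fasta")))
    }
    write_tsv(truth$labels, file.path(out_dir, "truth.tsv"))
    write_alignment(truth$alignment,
                    file.path(out_dir, "truth_alignment.afa"))
    write_newick(truth$tree, file.path(out_dir, "truth_tree.nwk"))
    writeLines(as.character(truth$zipper_columns),
               file.path(out_dir, "truth_zipper_columns.txt"))
  }
  invisible(list(records = all_records, truth = truth))
}
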