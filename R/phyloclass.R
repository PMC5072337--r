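#' Trim an alignment by column gap fraction
#'
#' Keeps columns whose gap fraction does not exceed `max_gap_fraction` and
#' returns the old-to-new column map so column annotations (e.g. zipper
#' masks) can be carried over.
#'
#' @param aln an `msa`.
#' @param max_gap_fraction maximum allowed gap fraction per column
#'   (default 0.5).
#' @return a list with `alignment` (trimmed `msa`) and `kept_columns`
#'   (original indices of the surviving columns, in order).
#' @export
trim_alignment <- function(aln, max_gap_fraction = 0.5) {
  stopifnot(inherits(aln, "msa"))
  m <- msa_matrix(aln)
  keep <- which(colMeans(m == "-") <= max_gap_fraction)
  if (length(keep) == 0) stop("trimming removed every column")
  rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  list(alignment = msa(setNames(rows, names(aln$rows))), kept_columns = keep)
}

#' Poisson-corrected pairwise distance matrix
#'
#' For each pair, the p-distance is computed over mutually ungapped columns
#' and corrected as `d = -ln(1 - p)` (Poisson model), capped at 5
#' substitutions/site when `p >= 1 - exp(-5)`.
#'
#' @param aln an `msa` with at least 3 rows (typically trimmed first).
#' @param min_shared minimum shared ungapped columns per pair (default 10).
#' @return a symmetric matrix of substitutions/site with zero diagonal.
#' @export
distance_matrix <- function(aln, min_shared = 10) {
  stopifnot(inherits(aln, "msa"))
  n <- length(aln$rows)
  if (n < 3) stop("need >= 3 rows for a distance matrix")
  m <- msa_matrix(aln)
  gap <- m == "-"
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  d_max <- 5
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !gap[i, ] & !gap[j, ]
      ns <- sum(shared)
      if (ns < min_shared)
        stop(sprintf("pair %s / %s shares only %d ungapped columns (< %d)",
                     rownames(m)[i], rownames(m)[j], ns, min_shared))
      p <- sum(m[i, shared] != m[j, shared]) / ns
      d <- if (p >= 1 - exp(-d_max)) d_max else -log(1 - p)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Canonical neighbor joining on a symmetric distance matrix; negative
#' branch lengths are floored at zero and the deficit is moved to the
#' adjacent branch so path lengths through the node are preserved as far as
#' possible.
#'
#' @param dist symmetric distance matrix with labeled rows.
#' @return an unrooted binary [ape::phylo] tree.
#' @export
build_nj <- function(dist) {
  if (nrow(dist) < 3) stop("need >= 3 taxa")
  if (!isSymmetric(unname(dist), tol = 1e-8))
    stop("distance matrix is not symmetric")
  tree <- ape::nj(as.dist(dist))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    node <- tree$edge[e, 1]
    sib <- which(tree$edge[, 1] == node & seq_along(tree$edge.length) != e)
    tree$edge.length[e] <- 0
    if (length(sib) > 0)
      tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + deficit
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Assign subfamily labels to tree leaves by reference-anchored clades
#'
#' The tree is midpoint-rooted (solely to define nested clades). For each
#' leaf, the smallest clade containing the leaf and at least one reference
#' leaf supplies the label: the majority reference label of that clade, with
#' support equal to that label's fraction among the clade's reference
#' leaves. Leaves whose smallest informative clade is mixed below the 0.75
#' majority threshold are reported `unclassified`. Reference leaves keep
#' their own label with support 1.
#'
#' @param tree an unrooted [ape::phylo] tree.
#' @param reference_labels named character vector, leaf id -> subfamily.
#' @param majority majority threshold (default 0.75).
#' @return data frame (`leaf_id`, `subfamily`, `support`), one row per leaf.
#' @export
assign_subfamilies <- function(tree, reference_labels, majority = 0.75) {
  if (length(reference_labels) == 0) stop("empty reference set")
  missing_ref <- setdiff(names(reference_labels), tree$tip.label)
  if (length(missing_ref) > 0)
    stop("reference leaves not in tree: ", paste(missing_ref, collapse = ", "))
  rooted <- phangorn::midpoint(tree)
  ntip <- length(rooted$tip.label)
  ref_idx <- match(names(reference_labels), rooted$tip.label)
  anc <- phangorn::Ancestors(rooted, seq_len(ntip), "all")
  out <- lapply(seq_len(ntip), function(tip) {
    id <- rooted$tip.label[tip]
    if (id %in% names(reference_labels)) {
      return(data.frame(leaf_id = id,
                        subfamily = unname(reference_labels[id]),
                        support = 1, stringsAsFactors = FALSE))
    }
    for (node in anc[[tip]]) {
      tips <- phangorn::Descendants(rooted, node, "tips")[[1]]
      refs <- intersect(tips, ref_idx)
      if (length(refs) > 0) {
        labs <- reference_labels[match(refs, ref_idx)]
        tab <- sort(table(labs), decreasing = TRUE)
        frac <- as.numeric(tab[1]) / length(labs)
        lab <- if (frac >= majority) names(tab)[1] else "unclassified"
        return(data.frame(leaf_id = id, subfamily = lab, support = frac,
                          stringsAsFactors = FALSE))
      }
    }
    data.frame(leaf_id = id, subfamily = "unclassified", support = 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Proteome-by-subfamily presence/absence matrix
#'
#' A cell is present when at least one record of the proteome is assigned to
#' the subfamily. Tandem leaves (`id#N` / `id#C`) credit the proteome of
#' their source record. Proteomes with no assigned record still appear as
#' all-absent rows.
#'
#' @param assignments output of [assign_subfamilies()].
#' @param proteome_map named character vector, record id -> proteome id
#'   (ids without the `#N`/`#C` suffix).
#' @return an integer 0/1 matrix, rows = proteomes (sorted), columns =
#'   subfamilies (sorted, `unclassified` excluded).
#' @export
presence_absence <- function(assignments, proteome_map) {
  base_id <- sub("#[NC]$", "", assignments$leaf_id)
  unknown <- setdiff(base_id, names(proteome_map))
  if (length(unknown) > 0)
    stop("leaf with unknown proteome: ", paste(head(unknown, 3), collapse = ", "))
  prot <- proteome_map[base_id]
  subfams <- sort(unique(assignments$subfamily[assignments$subfamily !=
                                                 "unclassified"]))
  prots <- sort(unique(unname(proteome_map)))
  mat <- matrix(0L, length(prots), length(subfams),
                dimnames = list(prots, subfams))
  keep <- assignments$subfamily != "unclassified"
  for (i in which(keep)) mat[prot[i], assignments$subfamily[i]] <- 1L
  mat
}

#' Write a presence/absence matrix as TSV
#' @param mat output of [presence_absence()].
#' @param path output file.
#' @export
write_presence_absence <- function(mat, path) {
  df <- data.frame(proteome_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
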