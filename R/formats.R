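#' Construct a validated table of protein records
#'
#' The package's sequence container is a plain `data.frame` with columns
#' `id`, `description`, `residues`, `proteome_id` and `group_label`, one row
#' per protein. Residues are uppercase over the 20 canonical amino acids
#' plus `X` (unknown, scored as background throughout).
#'
#' @param id character vector of unique record identifiers.
#' @param residues character vector of residue strings.
#' @param description free-text descriptions (recycled).
#' @param proteome_id proteome of origin (recycled).
#' @param group_label optional taxon/supergroup tag (recycled).
#' @return a `data.frame` of class `protein_db`.
#' @export
protein_records <- function(id, residues, description = "",
                            proteome_id = NA_character_,
                            group_label = NA_character_) {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    stop("id and residues must have equal length")
  dup <- id[duplicated(id)]
  if (length(dup) > 0)
    stop("duplicate record id: ", dup[1])
  if (any(nchar(residues) == 0))
    stop("empty residue string for record: ", id[which(nchar(residues) == 0)[1]])
  bad <- regexpr(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), residues)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal residue character '%s' at position %d in record %s",
                 substr(residues[i], bad[i], bad[i]), bad[i], id[i]))
  }
  df <- data.frame(id = id, description = rep_len(description, length(id)),
                   residues = residues,
                   proteome_id = rep_len(proteome_id, length(id)),
                   group_label = rep_len(group_label, length(id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("protein_db", "data.frame")
  df
}

#' Read a protein FASTA file into a record table
#'
#' Residues are uppercased and a single trailing `*` (stop) is stripped.
#' The proteome identifier defaults to the file stem.
#'
#' @param path FASTA file.
#' @param proteome_id override for the proteome identifier.
#' @return a `protein_db` data frame.
#' @export
read_fasta <- function(path, proteome_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1)
  desc <- sub("^\\S+\\s*", "", headers)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  if (is.null(proteome_id))
    proteome_id <- sub("\\.[^.]*$", "", basename(path))
  protein_records(ids, seqs, description = desc, proteome_id = proteome_id)
}

#' Write records as FASTA
#'
#' @param records a `protein_db` data frame.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  hdr <- ifelse(is.na(records$description) | records$description == "",
                records$id, paste(records$id, records$description))
  writeLines(paste0(">", hdr, "\n", records$residues), path, sep = "\n")
  invisible(path)
}

#' Construct a multiple sequence alignment
#'
#' Rows are equal-length aligned strings over residues plus `-`.
#'
#' @param rows named character vector, names are record ids.
#' @return an object of class `msa` with elements `rows` and `n_cols`.
#' @export
msa <- function(rows) {
  if (is.null(names(rows)) || any(names(rows) == ""))
    stop("alignment rows must be named by record id")
  if (anyDuplicated(names(rows)))
    stop("duplicate row id: ", names(rows)[duplicated(names(rows))][1])
  rows <- setNames(toupper(as.character(rows)), names(rows))
  lens <- nchar(rows)
  if (length(unique(lens)) > 1) {
    ragged <- names(rows)[lens != lens[1]]
    stop("ragged alignment rows: ", paste(ragged, collapse = ", "))
  }
  bad <- regexpr(sprintf("[^-%s]", paste(AA_ALLOWED, collapse = "")), rows)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal character at column %d of row %s", bad[i],
                 names(rows)[i]))
  }
  ungapped <- gsub("-", "", rows, fixed = TRUE)
  if (any(nchar(ungapped) == 0))
    stop("all-gap row: ", names(rows)[nchar(ungapped) == 0][1])
  structure(list(rows = rows, n_cols = unname(lens[1])), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa: %d rows x %d columns>\n", length(x$rows), x$n_cols))
  invisible(x)
}

#' Read an alignment from aligned FASTA or Stockholm
#'
#' The format is inferred from the first non-blank line (`# STOCKHOLM` vs
#' `>`); Stockholm support is read-only.
#'
#' @param path input file.
#' @return an `msa` object.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty alignment file: ", path)
  if (grepl("^# STOCKHOLM", first)) return(read_stockholm(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty alignment file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  msa(setNames(as.character(set), ids))
}

# Minimal Stockholm 1.0 reader: sequence lines "name seq", '#' markup
# ignored, '//' terminates; wrapped alignments are concatenated by name.
#' @noRd
read_stockholm <- function(path) {
  lines <- readLines(path)
  acc <- list()
  for (ln in lines) {
    if (grepl("^//", ln)) break
    if (grepl("^#", ln) || grepl("^\\s*$", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2)
      stop("malformed Stockholm sequence line: ", ln)
    nm <- parts[1]
    seq <- chartr(".", "-", parts[2])
    acc[[nm]] <- paste0(if (is.null(acc[[nm]])) "" else acc[[nm]], seq)
  }
  if (length(acc) == 0) stop("no sequences in Stockholm file: ", path)
  msa(unlist(acc))
}

#' Write an alignment as aligned FASTA
#'
#' Unwrapped (one sequence line per record) so that read/write round-trips
#' are byte-stable.
#'
#' @param aln an `msa`.
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "msa"))
  writeLines(paste0(">", names(aln$rows), "\n", aln$rows), path)
  invisible(path)
}

#' Write a phylogenetic tree in Newick format
#'
#' Leaf labels containing whitespace are single-quoted. All leaves must be
#' labeled.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (any(is.na(labs) | labs == ""))
    stop("tree has unlabeled leaves")
  # ape rewrites whitespace in labels, so route labels needing quotes
  # through placeholder tokens and re-inject them single-quoted
  needs_quote <- which(grepl("\\s", labs))
  tokens <- sprintf("QLBL%dQ", needs_quote)
  tree$tip.label[needs_quote] <- tokens
  nwk <- ape::write.tree(tree)
  for (k in seq_along(needs_quote))
    nwk <- sub(tokens[k], paste0("'", labs[needs_quote[k]], "'"), nwk,
               fixed = TRUE)
  writeLines(nwk, path)
  invisible(path)
}

#' Drop gaps from an aligned row
#' @param x aligned string(s).
#' @return ungapped residue string(s).
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Convert an alignment to a character matrix (rows x columns)
#' @noRd
msa_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(m) <- names(aln$rows)
  m
}
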