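# Independent brute-force oracles. These deliberately avoid the package's
# dynamic-programming code paths: they enumerate alignments / windows
# directly and are only usable at tiny problem sizes.

AA20_T <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Maximum local-alignment score over an arbitrary position-pair score
# matrix by exhaustive path enumeration. The state machine matches the
# package's: paths start and end on a match cell; between consecutive match
# cells the path may skip rows OR columns (never both), at affine cost
# open + (len-1) * ext; the empty alignment scores 0.
bf_local_affine <- function(S, go = 4, ge = 0.25) {
  n <- nrow(S); m <- ncol(S)
  best <- 0
  rec <- function(i, j, cur) {
    cur <- cur + S[i, j]
    if (cur > best) best <<- cur
    if (i < n) {
      for (di in seq_len(n - i)) {
        gap_i <- if (di > 1) go + (di - 2) * ge else 0
        if (j < m) rec(i + di, j + 1, cur - gap_i)
      }
    }
    if (j < m && i < n) {
      for (dj in seq_len(m - j)) {
        if (dj > 1) rec(i + 1, j + dj, cur - (go + (dj - 2) * ge))
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m)) rec(i, j, 0)
  unname(best)
}

# Exhaustive global affine alignment of two residue strings under a
# substitution matrix, Biostrings cost convention: a gap of length L costs
# open + L * ext (first gap residue open + ext). Returns the optimal score
# and the identity counts attainable by optimal alignments.
bf_global_align <- function(a, b, submat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  best <- -Inf; idents <- integer(0)
  rec <- function(i, j, sc, prev, ident) {
    if (i > na && j > nb) {
      if (sc > best + 1e-9) { best <<- sc; idents <<- ident }
      else if (abs(sc - best) < 1e-9) idents <<- unique(c(idents, ident))
      return()
    }
    if (i <= na && j <= nb)
      rec(i + 1, j + 1, sc + submat[A[i], B[j]], "M",
          ident + (A[i] == B[j]))
    if (i <= na)
      rec(i + 1, j, sc - (if (prev == "I") ext else open + ext), "I", ident)
    if (j <= nb)
      rec(i, j + 1, sc - (if (prev == "D") ext else open + ext), "D", ident)
  }
  rec(1, 1, 0, "S", 0)
  list(score = best, identities = idents)
}

# Naive window-by-window PROSITE pattern checker. pattern is a list of
# allowed-character vectors (NULL = any residue).
bf_scan_windows <- function(residues, pattern) {
  ch <- strsplit(residues, "")[[1]]
  w <- length(pattern)
  hits <- integer(0)
  if (length(ch) < w) return(hits)
  for (s in seq_len(length(ch) - w + 1)) {
    ok <- TRUE
    for (p in seq_len(w)) {
      allowed <- pattern[[p]]
      if (!is.null(allowed) && !(ch[s + p - 1] %in% allowed)) {
        ok <- FALSE; break
      }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

prat_pattern_list <- function() {
  pat <- vector("list", 31)
  pat[[1]] <- c("G", "A"); pat[[4]] <- c("F", "Y"); pat[[15]] <- "R"
  pat[[19]] <- "D"; pat[[26]] <- c("G", "A", "S"); pat[[27]] <- "G"
  pat[[31]] <- "G"
  pat
}

zipper_pattern_list <- function() {
  pat <- vector("list", 9)
  pat[[1]] <- "G"; pat[[5]] <- "G"; pat[[9]] <- "G"
  pat
}

# Random additive distance matrix from a random binary tree with strictly
# positive branch lengths; returns the matrix and the generating tree.
random_additive_matrix <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(k) runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  list(dist = D[ord, ord], tree = tr)
}

# Least-squares fit of a 4-taxon quartet topology: for each of the 3
# topologies, solve the 5 branch lengths by ordinary least squares against
# the 6 pairwise distances and return the topology index with minimal
# residual. Taxa order: t1 t2 t3 t4; topology 1 = (12|34), 2 = (13|24),
# 3 = (14|23).
bf_quartet_topology <- function(D) {
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  d <- apply(pairs, 1, function(p) D[p[1], p[2]])
  res <- sapply(1:3, function(topo) {
    grp <- switch(topo, list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                  list(c(1, 4), c(2, 3)))
    # design matrix over branches e1..e4 (terminal) + internal e5
    X <- t(apply(pairs, 1, function(p) {
      row <- rep(0, 5)
      row[p[1]] <- 1; row[p[2]] <- 1
      same <- (all(p %in% grp[[1]])) || (all(p %in% grp[[2]]))
      if (!same) row[5] <- 1
      row
    }))
    fit <- lm.fit(X, d)
    sum(fit$residuals^2)
  })
  which.min(res)
}

# Topology index of a 4-leaf tree in the bf_quartet_topology encoding:
# 1 = (12|34), 2 = (13|24), 3 = (14|23), leaves in `labs` order.
quartet_topology_of <- function(tree, labs) {
  tr <- ape::unroot(tree)
  tr$edge.length <- rep(1, nrow(tr$edge))
  nd <- ape::cophenetic.phylo(tr)
  sib <- labs[-1][which.min(nd[labs[1], labs[-1]])]
  match(sib, labs[-1])
}

# Monte-Carlo oracle for the generator's substitution process: probability
# that two lineages separated by total path length t (rate factor f) show
# the same residue at a site, under Poisson substitutions uniform among the
# 19 alternatives.
bf_site_identity <- function(t, rate_factor = 1, n_sites = 20000) {
  evolve1 <- function(ch, lam) {
    k <- rpois(length(ch), lam)
    for (i in which(k > 0)) {
      cur <- ch[i]
      for (e in seq_len(k[i])) cur <- sample(setdiff(AA20_T, cur), 1)
      ch[i] <- cur
    }
    ch
  }
  anc <- sample(AA20_T, n_sites, replace = TRUE)
  a <- evolve1(anc, t / 2 * rate_factor)
  b <- evolve1(anc, t / 2 * rate_factor)
  mean(a == b)
}

random_protein <- function(n, min_len = 30, max_len = 60) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  protein_records(sprintf("r%03d", seq_len(n)),
                  vapply(lens, function(L)
                    paste(sample(AA20_T, L, TRUE), collapse = ""), ""))
}

# A tiny random profile: C columns of Dirichlet-ish frequencies.
random_profile <- function(n_cols, seed_cols = NULL, conc = 0.5) {
  cols <- t(vapply(seq_len(n_cols), function(j) {
    x <- rgamma(20, conc)
    x / sum(x)
  }, numeric(20)))
  colnames(cols) <- AA20_T
  structure(list(id = "rand", columns = cols,
                 background = setNames(rep(1 / 20, 20), AA20_T),
                 match_mask = rep(TRUE, n_cols),
                 match_col_map = seq_len(n_cols),
                 masked_columns = integer(0), calibration = NULL),
            class = "position_profile")
}
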