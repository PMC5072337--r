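#' @useDynLib famforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median optim plogis rpois runif setNames glm binomial
#'   coef predict sd
#' @importFrom utils write.table read.table head tail
NULL

# The 20 canonical amino acids, alphabetical one-letter order.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residues allowed in a ProteinRecord ('X' = unknown, scores as background).
AA_ALLOWED <- c(AA20, "X")

# Kyte-Doolittle hydropathy scale; 'X' is neutral.
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

# Hydrophobic sampling weights used by the synthetic generator; the
# complementary hydrophilic set is sampled uniformly.
HYDROPHOBIC_WEIGHTS <- c(L = 25, I = 15, V = 15, F = 10, A = 15, M = 5, G = 15)
HYDROPHILIC_SET <- setdiff(AA20, names(HYDROPHOBIC_WEIGHTS))

#' Split a residue string into a character vector
#' @noRd
str_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Derive a reproducible child seed from a base seed and integer tags.
#'
#' Keeps all derived seeds positive and below 2^31 so they are valid R
#' integer seeds.
#' @noRd
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  s <- 0
  for (t in tags) s <- (s * 69069 + as.double(t) + 1) %% 2147483647
  as.integer(s) + 1L
}

#' Run an expression with a temporary RNG seed, restoring the RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Write a data frame as a plain TSV with header, no quoting.
#' @noRd
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = "character")
}
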