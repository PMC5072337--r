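test_that("zero divergence yields identical full-length members", {
  spec <- synthetic_family_spec(n_subfamilies = 2, members_per_subfamily = 4,
                                inter_sub_divergence = 0,
                                intra_sub_divergence = 0, seed = 2)
  g <- generate_superfamily(spec)
  expect_equal(length(unique(g$records$residues)), 1)
  expect_false(any(grepl("-", g$truth$alignment$rows, fixed = TRUE)))
})

test_that("generation is byte-deterministic in spec + seed", {
  spec <- synthetic_family_spec(n_subfamilies = 2, members_per_subfamily = 3,
                                seed = 9)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(generate_superfamily(spec)$records, f1)
  write_fasta(generate_superfamily(spec)$records, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("spec validation rejects impossible zipper geometry", {
  expect_error(synthetic_family_spec(tm_len = 8, zippers_per_helix = 1),
               "zipper")
  expect_error(synthetic_family_spec(intra_sub_divergence = -1), "divergence")
  expect_error(synthetic_family_spec(members_per_subfamily = 0), ">= 1")
})

test_that("truth zipper columns carry glycines inside TM helices", {
  spec <- synthetic_family_spec(n_subfamilies = 1, members_per_subfamily = 5,
                                inter_sub_divergence = 0,
                                intra_sub_divergence = 0, seed = 4)
  g <- generate_superfamily(spec)
  anc <- strsplit(g$records$residues[1], "")[[1]]
  expect_true(all(anc[g$truth$zipper_columns] == "G"))
  tb <- g$truth$tm_bounds
  inside <- vapply(g$truth$zipper_columns, function(z)
    any(z >= tb[, 1] & z <= tb[, 2]), TRUE)
  expect_true(all(inside))
})

test_that("observed intra-subfamily identity matches a Monte-Carlo oracle", {
  # two-member subfamilies put the pair at exactly the stated divergence
  d <- 0.3
  spec0 <- synthetic_family_spec(n_subfamilies = 1, members_per_subfamily = 2,
                                 inter_sub_divergence = 0,
                                 intra_sub_divergence = d, seed = 1)
  obs <- vapply(1:50, function(r) {
    spec <- synthetic_family_spec(n_subfamilies = 1, members_per_subfamily = 2,
                                  inter_sub_divergence = 0,
                                  intra_sub_divergence = d, seed = 1000 + r)
    g <- generate_superfamily(spec)
    a <- strsplit(g$truth$alignment$rows[[1]], "")[[1]]
    b <- strsplit(g$truth$alignment$rows[[2]], "")[[1]]
    ok <- a != "-" & b != "-"
    mean(a[ok] == b[ok])
  }, 0)
  # oracle: site-level simulation with the generator's conserved-site mix
  g0 <- generate_superfamily(spec0)
  L <- g0$truth$alignment$n_cols
  f_cons <- (length(g0$truth$zipper_columns) + 2) / L
  set.seed(77)
  expected <- (1 - f_cons) * bf_site_identity(d, 1) +
    f_cons * bf_site_identity(d, 0.1)
  expect_lt(abs(mean(obs) - expected), 0.02)
})

test_that("decoys carry zippers but only background-level identity", {
  dec <- generate_decoys(20, seed = 6)
  n_zip <- vapply(seq_len(nrow(dec)), function(i)
    nrow(scan_zipper(dec$residues[i])), 0L)
  expect_true(all(n_zip >= 2))
  expect_equal(nrow(generate_decoys(1, seed = 2)), 1)
  expect_error(generate_decoys(0, seed = 1), ">= 1")
  # positional identity against family members outside zipper columns is at
  # the background expectation for a uniform decoy (1/20), by direct count
  spec <- synthetic_family_spec(n_subfamilies = 1, members_per_subfamily = 20,
                                inter_sub_divergence = 0, seed = 8)
  g <- generate_superfamily(spec)
  keep <- setdiff(seq_len(nchar(g$records$residues[1])),
                  g$truth$zipper_columns)
  idents <- vapply(1:20, function(i) {
    a <- strsplit(dec$residues[i], "")[[1]]
    b <- strsplit(g$records$residues[i], "")[[1]]
    pos <- keep[keep <= min(length(a), length(b))]
    mean(a[pos] == b[pos])
  }, 0)
  expect_lt(abs(mean(idents) - 0.05), 0.02)
})

test_that("tandem records concatenate two members with a reproducible linker", {
  spec <- synthetic_family_spec(n_subfamilies = 1, members_per_subfamily = 6,
                                seed = 3)
  g <- generate_superfamily(spec)
  t1 <- generate_tandem(g$records, seed = 5, n = 4)
  src <- attr(t1, "sources")
  for (i in 1:4) {
    la <- nchar(g$records$residues[g$records$id == src$n_source[i]])
    lb <- nchar(g$records$residues[g$records$id == src$c_source[i]])
    expect_equal(nchar(t1$residues[i]), la + lb + src$linker_len[i])
    expect_true(startsWith(t1$residues[i],
                           g$records$residues[g$records$id == src$n_source[i]]))
  }
  t2 <- generate_tandem(g$records, seed = 5, n = 4)
  expect_identical(t1$residues, t2$residues)
  expect_error(generate_tandem(g$records[1, , drop = FALSE], seed = 1),
               ">= 2")
})

test_that("benchmark directories have partitioning truth and are reproducible", {
  cfg <- benchmark_config(members_per_subfamily = 10, seed = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  res <- generate_benchmark(cfg, out_dir = file.path(d1, "bench"))
  expect_equal(nrow(res$records), 3 * (30 + 20 + 200))
  expect_equal(nrow(res$truth$labels), 750)
  expect_false(anyDuplicated(res$truth$labels$record_id) > 0)
  expect_setequal(res$truth$labels$record_id, res$records$id)
  generate_benchmark(cfg, out_dir = file.path(d2, "bench"))
  for (f in list.files(file.path(d1, "bench"))) {
    expect_identical(readLines(file.path(d1, "bench", f)),
                     readLines(file.path(d2, "bench", f)), label = f)
  }
  expect_error(generate_benchmark(cfg, out_dir = file.path(d1, "bench")),
               "force")
})

test_that("zipper positions are retained more often than typical positions", {
  spec <- synthetic_family_spec(n_subfamilies = 1, members_per_subfamily = 30,
                                inter_sub_divergence = 0, seed = 12)
  g <- generate_superfamily(spec)
  m <- do.call(rbind, strsplit(g$truth$alignment$rows, ""))
  modal <- function(col) names(sort(table(col[col != "-"]), decreasing = TRUE))[1]
  retained <- function(cols) {
    vapply(cols, function(j) mean(m[, j] == modal(m[, j])), 0)
  }
  zc <- g$truth$zipper_columns
  set.seed(5)
  other <- sample(setdiff(seq_len(ncol(m)), c(zc, g$truth$charged_columns)),
                  100)
  expect_gt(mean(retained(zc)), mean(retained(other)))
})
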