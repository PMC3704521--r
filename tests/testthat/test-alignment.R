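test_that("alignment construction validates shape and normalizes case", {
  aln <- dna_alignment(c(s1 = "acgtacgtnn", s2 = "ACGT-CGTAA"))
  expect_equal(ncol(aln), 10)
  expect_equal(unname(unclass(aln)[1, 1:4]), c("A", "C", "G", "T"))
  expect_error(dna_alignment(c(s1 = "ACGT", s2 = "ACG")), "ragged.*s2")
  expect_error(dna_alignment(c("ACGT", "ACGT")), "labels")
})

test_that("FASTA and NEXUS round-trips are exact", {
  set.seed(21)
  aln <- rand_alignment(12, 200, p_gap = 0.03, p_amb = 0.02)
  for (fmt in c("fasta", "nexus")) {
    f <- withr::local_tempfile()
    write_alignment(aln, f, format = fmt)
    back <- read_alignment(f)
    expect_setequal(rownames(back), rownames(aln))
    expect_identical(unclass(back)[rownames(aln), ], unclass(aln)[, ])
  }
})

test_that("indel-column pruning keeps exactly the gap-free columns", {
  aln <- dna_alignment(c(a = "AAC", b = "A-C"))
  pr <- prune_indel_columns(aln)
  expect_equal(pr$column_map, c(1L, 3L))
  expect_equal(ncol(pr$alignment), 2)

  gap_free <- dna_alignment(c(a = "ACGT", b = "ACGA"))
  expect_equal(prune_indel_columns(gap_free)$column_map, 1:4)

  set.seed(5)
  r <- rand_alignment(8, 300, p_gap = 0.05)
  pr <- prune_indel_columns(r)
  brute <- which(vapply(seq_len(300), function(k)
    !any(unclass(r)[, k] == "-"), logical(1)))
  expect_equal(pr$column_map, brute)
  expect_warning(prune_indel_columns(dna_alignment(c(a = "-", b = "A"))),
                 "empty")
})

test_that("Jukes-Cantor distance matches its closed form and contracts", {
  expect_equal(jc_distance("ACGT", "ACGT"), 0)
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("C", 10), rep("A", 90)), collapse = "")
  expect_equal(jc_distance(s1, s2), -0.75 * log(1 - 0.4 / 3),
               tolerance = 1e-12)
  expect_equal(jc_distance(s1, s2), 0.107326, tolerance = 5e-6)
  # singularity at p >= 3/4
  s3 <- paste(c(rep("C", 75), rep("A", 25)), collapse = "")
  expect_true(is.na(jc_distance(s1, s3)))
  # ambiguity and gaps are missing, not mismatches
  expect_equal(jc_distance("ARG-", "AAGT"), 0)
  expect_true(is.na(jc_distance("NNNN", "ACGT")))
})

test_that("jc properties: symmetry, zero iff identical, d >= p", {
  set.seed(9)
  for (rep in 1:50) {
    a <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
    b <- a
    flip <- sample(60, sample(0:30, 1))
    b[flip] <- sample(c("A", "C", "G", "T"), length(flip), replace = TRUE)
    d1 <- jc_distance(a, b)
    expect_identical(d1, jc_distance(b, a))
    p <- mean(a != b)
    if (!is.na(d1)) {
      expect_gte(d1 + 1e-12, p)
      if (p == 0) expect_equal(d1, 0)
      if (d1 == 0) expect_equal(p, 0)
    }
  }
})

test_that("jc_matrix agrees with an independent implementation", {
  set.seed(31)
  tr <- rand_dated_tree(6)
  aln <- evolve_jc(tr, length = 500, rate = 0.02)
  m <- jc_matrix(aln)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 6))
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(
    lapply(seq_len(nrow(aln)), function(i) tolower(unclass(aln)[i, ])) |>
      stats::setNames(rownames(aln))), model = "JC69",
    pairwise.deletion = TRUE))
  expect_equal(m[rownames(ref), colnames(ref)], ref, tolerance = 1e-9)
})

test_that("distance concordance behaves on identical, perturbed and published matrices", {
  set.seed(13)
  m <- jc_matrix(evolve_jc(rand_dated_tree(5), length = 200, rate = 0.02))
  same <- distance_concordance(m, m, rownames(m))
  expect_equal(same$max_abs_diff, 0)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$n_pairs, 10)

  eps <- 0.005
  pert <- m + matrix(runif(25, -eps, eps), 5, 5) * (1 - diag(5))
  pert <- (pert + t(pert)) / 2
  dimnames(pert) <- dimnames(m)
  expect_lte(distance_concordance(m, pert, rownames(m))$max_abs_diff,
             2 * eps)
  expect_error(distance_concordance(m, m, rownames(m)[1:2]),
               "three")

  tab <- nrpa2_copy_distances()
  conc <- distance_concordance(tab$a, tab$b, rownames(tab$a))
  expect_lt(conc$max_abs_diff, 0.03)
  expect_equal(conc$n_pairs, 10)
})

test_that("site statistics match an explicit per-column classifier", {
  allsame <- dna_alignment(stats::setNames(rep("ACGTACGTAC", 4),
                                           paste0("s", 1:4)))
  st <- alignment_stats(allsame)
  expect_equal(st$n_constant, 10)
  expect_equal(st$n_parsimony_informative, 0)

  aln <- dna_alignment(c(s1 = "AA", s2 = "AA", s3 = "CA", s4 = "CC"))
  st <- alignment_stats(aln)
  # col 1: A,A,C,C -> informative; col 2: A,A,A,C -> neither
  expect_equal(st$n_parsimony_informative, 1)
  expect_equal(st$n_constant, 0)

  set.seed(17)
  for (rep in 1:20) {
    r <- rand_alignment(12, 120, p_gap = 0.04, p_amb = 0.04)
    st <- alignment_stats(r)
    or <- oracle_alignment_stats(r)
    expect_equal(st$n_parsimony_informative, or$n_parsimony_informative)
    expect_equal(st$n_constant, or$n_constant)
    expect_lte(st$n_constant + st$n_parsimony_informative, st$n_columns)
  }
})
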