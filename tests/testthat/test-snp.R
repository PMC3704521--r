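mk_aln <- function(...) dna_alignment(c(...))

test_that("diagnostic sites are the fixed, differing, unambiguous columns", {
  aln <- mk_aln(a1 = "ACGT", a2 = "ACGT", b1 = "ACCT", b2 = "ACCT")
  sites <- find_diagnostic_sites(aln, c("a1", "a2"), c("b1", "b2"))
  expect_equal(sites$column, 3)
  expect_equal(sites$state_a, "G")
  expect_equal(sites$state_b, "C")

  # identical references: no sites
  expect_equal(nrow(find_diagnostic_sites(aln, "a1", "a2")), 0)
  # polymorphic or ambiguous reference columns are not diagnostic
  aln2 <- mk_aln(a1 = "AG", a2 = "AC", b1 = "TT", b2 = "TT")
  expect_equal(nrow(find_diagnostic_sites(aln2, c("a1", "a2"),
                                          c("b1", "b2"))), 1)
  expect_error(find_diagnostic_sites(aln, character(0), "b1"), "non-empty")
  # symmetric up to swapping roles
  s_ab <- find_diagnostic_sites(aln, c("a1", "a2"), c("b1", "b2"))
  s_ba <- find_diagnostic_sites(aln, c("b1", "b2"), c("a1", "a2"))
  expect_equal(s_ab$column, s_ba$column)
  expect_equal(s_ab$state_a, s_ba$state_b)
})

test_that("query classification follows the per-site call rules", {
  aln <- mk_aln(ra = "AAAAAAAAAA", rb = "CCCCCCCCCC", q = "AAAAAAAAAA")
  sites <- find_diagnostic_sites(aln, "ra", "rb")
  expect_equal(nrow(sites), 10)

  r_a <- classify_query("AAAAAAAAAA", sites)
  expect_equal(r_a$class, "A")
  expect_equal(r_a$n_match_a, 10)
  r_b <- classify_query("CCCCCCCCCC", sites)
  expect_equal(r_b$class, "B")

  # IUPAC codes covering both states at every site -> BOTH
  r_het <- classify_query(paste(rep("M", 10), collapse = ""), sites)
  expect_equal(r_het$class, "BOTH")
  expect_equal(r_het$n_match_both, 10)

  # 9 a-sites + 1 b-site: lone contradiction reported, class kept
  r_lone <- classify_query("AAAAAAAAAC", sites)
  expect_equal(r_lone$class, "A")
  expect_equal(r_lone$n_other_clade_diagnostic, 1)

  # substantial mixture without ambiguity -> MOSAIC
  r_mix <- classify_query("AAAAACCCCC", sites)
  expect_equal(r_mix$class, "MOSAIC")

  # missing data is uninformative, never a mismatch
  r_miss <- classify_query("NNNN-?NNNN", sites)
  expect_equal(r_miss$class, "NEITHER")
  expect_equal(r_miss$n_missing, 10)

  # accounting identity
  for (r in list(r_a, r_het, r_lone, r_mix, r_miss))
    expect_equal(r$n_match_a + r$n_match_b + r$n_match_both +
                   r$n_other + r$n_missing, r$n_sites_compared)
  expect_error(classify_query("AA", sites), "shorter")
})

test_that("polymorphic queries split into the two component haplotypes", {
  set.seed(47)
  ref_a <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  ref_b <- ref_a
  ref_b[sample(60, 12)] <- sample(c("A", "C", "G", "T"), 12, replace = TRUE)
  aln <- dna_alignment(rbind(ra = ref_a, rb = ref_b))
  sites <- find_diagnostic_sites(aln, "ra", "rb")
  het <- superpose_iupac(ref_a, ref_b)
  sp <- split_polymorphic(het, sites)
  expect_equal(sp$haplotype_a[sites$column], ref_a[sites$column])
  expect_equal(sp$haplotype_b[sites$column], ref_b[sites$column])
  # re-superposing reproduces the query at diagnostic columns
  resup <- superpose_iupac(sp$haplotype_a, sp$haplotype_b)
  expect_equal(resup[sites$column], het[sites$column])

  # unresolvable diagnostic state is carried through and flagged
  if (nrow(sites) >= 2) {
    odd <- het
    third <- setdiff(c("A", "C", "G", "T"),
                     c(sites$state_a[1], sites$state_b[1]))[1]
    odd[sites$column[1]] <- third
    sp2 <- split_polymorphic(odd, sites)
    expect_equal(sp2$unresolved, sites$column[1])
    expect_equal(sp2$haplotype_a[sites$column[1]], third)
  }
  expect_error(split_polymorphic(ref_a, sites), "BOTH")
})

test_that("the summary table counts BOTH rows in both reference columns", {
  sites <- find_diagnostic_sites(
    mk_aln(ra = "AAAAAAAAAA", rb = "CCCCCCCCCC"), "ra", "rb")
  reports <- rbind(
    classify_query("AAAAAAAAAA", sites, "g1_1"),
    classify_query("AAAAAAAAAA", sites, "g1_2"),
    classify_query("AAAAAAAAAA", sites, "g1_3"),
    classify_query("MMMMMMMMMM", sites, "g1_4"),
    classify_query("MMMMMMMMMM", sites, "g1_5"),
    classify_query("MMMMMMMMMM", sites, "g2_1"),
    classify_query("MMMMMMMMMM", sites, "g2_2"))
  groups <- c(g1_1 = "G1", g1_2 = "G1", g1_3 = "G1", g1_4 = "G1",
              g1_5 = "G1", g2_1 = "G2", g2_2 = "G2")
  tab <- tabulate_report(reports, groups)$table
  g1 <- tab[tab$group == "G1", ]
  expect_equal(unname(unlist(g1[c("A", "B", "C")])), c(5, 5, 2))
  # an all-BOTH group has A = B = C
  g2 <- tab[tab$group == "G2", ]
  expect_equal(unname(unlist(g2[c("A", "B", "C")])), c(2, 2, 2))
  # footnote annotations list contradictory sequences
  r_lone <- classify_query("AAAAAAAAAC", sites, "odd")
  ann <- tabulate_report(rbind(reports, r_lone), groups)$annotations
  expect_equal(ann$label, "odd")
  expect_equal(ann$n_other_clade_diagnostic, 1)
  # empty report set -> zero rows, not an error
  empty <- tabulate_report(reports[0, , drop = FALSE], groups)
  expect_true(all(c("G1", "G2") %in% empty$table$group))
  expect_true(all(empty$table$A == 0))
})

test_that("simulated two-clade alignments yield the brute-force site count", {
  set.seed(53)
  for (rep in 1:10) {
    tr <- read_tree(text = "((a1:0.5,a2:0.5):4.5,(b1:0.5,b2:0.5):4.5);")
    aln <- evolve_jc(tr, length = 300, rate = 0.02)
    sites <- find_diagnostic_sites(aln, c("a1", "a2"), c("b1", "b2"))
    mat <- unclass(aln)
    brute <- sum(vapply(seq_len(300), function(k) {
      ua <- unique(mat[c("a1", "a2"), k]); ub <- unique(mat[c("b1", "b2"), k])
      length(ua) == 1 && length(ub) == 1 && ua != ub &&
        ua %in% c("A", "C", "G", "T") && ub %in% c("A", "C", "G", "T")
    }, logical(1)))
    expect_equal(nrow(sites), brute)
    expect_true(all(diff(sites$column) > 0))
    if (nrow(sites) > 0) {
      expect_equal(classify_query(mat["a1", ], sites)$class, "A")
      expect_equal(classify_query(mat["b1", ], sites)$class, "B")
    }
  }
})
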