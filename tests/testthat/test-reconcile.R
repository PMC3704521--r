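tree_of <- function(nwk) read_tree(text = nwk)

test_that("congruent single-copy gene trees reconcile at zero cost", {
  sp <- tree_of("((A:1,B:1):1,C:2);")
  gene <- tree_of("((A:1,B:1):1,C:2);")
  rec <- lca_map(gene, sp, c(A = "A", B = "B", C = "C"))
  expect_equal(count_duplications(rec)$n_duplications, 0)
  expect_equal(count_losses(rec)$n_losses, 0)
  # natural isomorphism: each gene node maps to the same-aged species node
  expect_equal(sp$ages[rec$map], gene$ages)
})

test_that("hand-evaluable discordant cases give the known counts", {
  sp <- tree_of("((A:1,B:1):1,C:2);")
  gene <- tree_of("((A:1,C:1):1,B:2);")
  rec <- lca_map(gene, sp, c(A = "A", B = "B", C = "C"))
  root_s <- n_tips(sp) + 1L
  expect_equal(unname(rec$map[mrca_node(gene, c("A", "C"))]), root_s)
  expect_equal(unname(rec$map[mrca_node(gene, c("A", "B"))]), root_s)
  expect_equal(count_duplications(rec)$n_duplications, 1)
  expect_equal(count_losses(rec)$n_losses, 3)

  sp2 <- tree_of("(A:1,B:1);")
  gene2 <- tree_of("((A1:1,B1:1):1,(A2:1,B2:1):1);")
  rec2 <- lca_map(gene2, sp2,
                  c(A1 = "A", B1 = "B", A2 = "A", B2 = "B"))
  expect_true(all(rec2$map[(n_tips(gene2) + 1L):7] == 3L))
  expect_equal(count_duplications(rec2)$n_duplications, 1)
  expect_equal(count_losses(rec2)$n_losses, 0)
})

test_that("polytomies and incomplete assignments are rejected", {
  sp <- tree_of("((A:1,B:1):1,C:2);")
  expect_warning(read_tree(text = "(A:1,B:1,C:1);"), "multifurcation")
  expect_error(lca_map(suppressWarnings(tree_of("(A:1,B:1,C:1);")), sp,
                       c(A = "A", B = "B", C = "C")), "polytomy")
  expect_error(lca_map(tree_of("((A:1,B:1):1,C:2);"), sp,
                       c(A = "A", B = "B")), "unassigned")
  expect_error(lca_map(tree_of("((A:1,B:1):1,C:2);"), sp,
                       c(A = "A", B = "B", C = "Z")), "absent")
})

test_that("reconciliation equals the leaf-set-containment oracle on random cases", {
  set.seed(23)
  sp <- tree_of("(((A:1,B:1):1,C:2):1,D:3);")
  species_labels <- c("A", "B", "C", "D")
  skip_if_not_installed("phangorn")
  for (n in 3:5) {
    shapes <- phangorn::allTrees(n, rooted = TRUE)
    shapes <- shapes[sample(length(shapes), min(8, length(shapes)))]
    for (shape in shapes) {
      for (rep in 1:6) {
        assn <- sample(species_labels, n, replace = TRUE)
        shape$tip.label <- paste0("g", seq_len(n))
        leaf_sp <- stats::setNames(assn, shape$tip.label)
        got <- pkg_reconcile(shape, sp$phylo, leaf_sp)
        want <- oracle_reconcile(shape, sp$phylo, leaf_sp)
        expect_equal(got, want)
      }
    }
  }
})

test_that("counts are invariant under child order and consistent relabeling", {
  sp <- tree_of("(((A:1,B:1):1,C:2):1,D:3);")
  gene <- tree_of("(((A:1,C:1):1,(B:0.5,D:0.5):1.5):1,B2:3);")
  assn <- c(A = "A", C = "C", B = "B", D = "D", B2 = "B")
  rec <- lca_map(gene, sp, assn)
  base <- list(count_duplications(rec)$n_duplications,
               count_losses(rec)$n_losses)
  # rotate children (ape::rotate swaps child order, same topology)
  rot <- gene
  rot$phylo <- ape::rotate(gene$phylo, n_tips(gene) + 1L)
  rec_rot <- lca_map(dated_tree(rot$phylo), sp, assn)
  expect_equal(list(count_duplications(rec_rot)$n_duplications,
                    count_losses(rec_rot)$n_losses), base)
  # consistent relabeling of species
  relab <- c(A = "W", B = "X", C = "Y", D = "Z")
  sp2 <- sp; sp2$phylo$tip.label <- unname(relab[sp$phylo$tip.label])
  rec2 <- lca_map(gene, dated_tree(sp2$phylo),
                  stats::setNames(relab[assn], names(assn)))
  expect_equal(list(count_duplications(rec2)$n_duplications,
                    count_losses(rec2)$n_losses), base)
})

test_that("the focal-copy protocol reconciles against the pruned species tree", {
  # species (((P1,P2),P3),X),O with one focal copy F hosted in P1, sister to X
  gene <- tree_of(
    "((((P1:1,P2:1):1,P3:2):1,(F:2.5,X:2.5):0.5):1,O:4);")
  rec <- reconcile_focal(gene, focal = "F", hosts = c(F = "P1"))
  expect_setequal(tip_labels(rec$lca_map$species),
                  c("P1", "P2", "P3", "X", "O"))
  want <- oracle_reconcile(gene$phylo,
                           prune_leaves(gene, "F")$phylo,
                           c(P1 = "P1", P2 = "P2", P3 = "P3", X = "X",
                             O = "O", F = "P1"))
  expect_equal(rec$n_duplications, want$n_duplications)
  expect_equal(rec$n_losses, want$n_losses)

  # empty focal set on a congruent tree: zero cost
  congr <- tree_of("((A:1,B:1):1,C:2);")
  rec0 <- reconcile_focal(congr, focal = character(0))
  expect_equal(rec0$n_duplications, 0)
  expect_equal(rec0$n_losses, 0)

  expect_error(reconcile_focal(gene, focal = "F", hosts = c(F = "NOPE")),
               "absent")
})

test_that("grafting a copy sister to its host's copy adds exactly one duplication", {
  # the cherry (X, F) maps to species(X); it is a duplication, and both of
  # its pendant edges contribute zero losses, so dup+loss rises by one
  set.seed(29)
  for (rep in 1:10) {
    sp <- rand_dated_tree(6, labels = LETTERS[1:6])
    gene <- rand_dated_tree(6, labels = LETTERS[1:6])
    assn <- stats::setNames(LETTERS[1:6], LETTERS[1:6])
    r0 <- lca_map(gene, sp, assn)
    cost0 <- count_duplications(r0)$n_duplications +
      count_losses(r0)$n_losses
    host <- sample(LETTERS[1:6], 1)
    grafted <- read_tree(text = sub(paste0("\\b", host, ":"),
                                    paste0("(", host, ":0.001,XX:0.001):"),
                                    write_tree(gene)))
    # the grafted tree is no longer ultrametric at XX; reconciliation is
    # topology-only, so an undated tree is fine
    r1 <- lca_map(dated_tree(grafted$phylo), sp,
                  c(assn, c(XX = host)))
    cost1 <- count_duplications(r1)$n_duplications +
      count_losses(r1)$n_losses
    expect_equal(cost1, cost0 + 1)
  }
})
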