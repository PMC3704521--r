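test_that("species trees realize the configured backbone and are reproducible", {
  cfg <- scenario_config()
  set.seed(77)
  sp <- sim_species_tree(cfg)
  meta <- attr(sp, "species_meta")
  expect_equal(n_tips(sp), 20)
  expect_equal(sort(unique(meta$section)), c("A1", "A2", "B1", "B2"))
  root_age <- sp$ages[n_tips(sp) + 1L]
  expect_gte(root_age, 9); expect_lte(root_age, 13)
  # every node older than its children, leaves contemporaneous at 0
  expect_true(all(sp$ages[1:20] == 0))
  par <- sp$phylo$edge[, 1]; kid <- sp$phylo$edge[, 2]
  expect_true(all(sp$ages[par] >= sp$ages[kid] - 1e-9))
  # determinism
  set.seed(123); a <- write_tree(sim_species_tree(cfg))
  set.seed(123); b <- write_tree(sim_species_tree(cfg))
  expect_identical(a, b)
})

test_that("coalescence excess over the split age has mean theta", {
  sp <- read_tree(text = "(X:5,Y:5);")
  samples <- data.frame(label = c("x", "y"), species = c("X", "Y"),
                        group = "main")
  theta <- 0.8
  set.seed(83)
  excess <- replicate(400, {
    g <- sim_msc(sp, samples, theta)
    g$ages[3] - 5
  })
  se <- stats::sd(excess) / sqrt(length(excess))
  expect_lt(abs(mean(excess) - theta), 3 * se)
  expect_true(all(excess > 0))
})

test_that("gene trees respect species divergence times for primary copies", {
  cfg <- scenario_config()
  for (seed in 1:5) {
    ds <- simulate_dataset("introgression", cfg, seed = seed)
    sp <- ds$species_tree; g <- ds$gene_tree
    main <- ds$assignment[!ds$assignment$focal, ]
    idx <- sample(nrow(main), 6)
    for (i in idx[-1]) {
      pair <- main$leaf[c(idx[1], i)]
      sp_pair <- main$species[c(idx[1], i)]
      g_age <- g$ages[mrca_node(g, pair)]
      s_age <- sp$ages[mrca_node(sp, sp_pair)]
      expect_gte(g_age, s_age - 1e-9)
    }
    # focal copies coalesce with the donor section after the event age,
    # well below the subgenus split
    focal <- ds$assignment$leaf[ds$assignment$focal]
    donor <- ds$assignment$leaf[grepl("^B1_", ds$assignment$species) &
                                  !ds$assignment$focal]
    join <- g$ages[mrca_node(g, c(focal[1], donor[1]))]
    expect_gte(join, ds$truth$event_age - 1e-9)
    expect_lt(join, ds$truth$split_age)
  }
})

test_that("duplication-loss datasets attach focal copies above the split", {
  cfg <- scenario_config()
  for (seed in 11:14) {
    ds <- simulate_dataset("duplication_loss", cfg, seed = seed)
    g <- ds$gene_tree
    focal <- ds$assignment$leaf[ds$assignment$focal]
    other <- setdiff(tip_labels(g), focal)
    join <- g$ages[mrca_node(g, c(focal[1], other[1]))]
    expect_gte(join, ds$truth$duplication_age - 1e-9)
    expect_gte(length(focal), cfg$min_carriers)
    # the pipeline's reconciliation must demand at least one duplication
    rep <- run_analysis(dataset = ds)
    expect_gte(rep$stages$reconciliation$n_duplications, 1)
  }
})

test_that("sequence evolution is exact Jukes-Cantor along branches", {
  tr <- read_tree(text = "(A:1,B:1);")
  set.seed(97)
  frozen <- evolve_jc(tr, length = 50, rate = 0)
  expect_identical(unclass(frozen)["A", ], unclass(frozen)["B", ])
  # mean estimated distance over replicates matches the path length
  t_branch <- 0.05  # per-branch, path length 0.1 substitutions/site
  dists <- replicate(300, {
    a <- evolve_jc(read_tree(text = "(A:1,B:1);"), length = 400,
                   rate = t_branch)
    jc_distance(unclass(a)["A", ], unclass(a)["B", ])
  })
  se <- stats::sd(dists) / sqrt(length(dists))
  expect_lt(abs(mean(dists) - 0.1), 3 * se)
  # determinism under a fixed seed
  set.seed(5); x <- evolve_jc(tr, 30, 0.1)
  set.seed(5); y <- evolve_jc(tr, 30, 0.1)
  expect_identical(unclass(x), unclass(y))
})

test_that("HPD emulation brackets node ages at the requested width", {
  tr <- read_tree(text = "((A:1,B:1):4,C:5);")
  degenerate <- attach_hpd(tr, 0)
  v <- mrca_node(degenerate, c("A", "B"))
  expect_equal(unname(degenerate$hpd[v, ]), c(1, 1))
  wide <- attach_hpd(tr, 0.2)
  expect_equal(unname(wide$hpd[v, ]), c(0.8, 1.2))
  expect_equal(unname(wide$hpd[4, ]), c(4, 6))
  expect_error(attach_hpd(tr, 1), "half_width")
  # jitter keeps parent midpoints at or above child midpoints
  set.seed(101)
  big <- rand_dated_tree(15)
  jit <- attach_hpd(big, 0.1, jitter_sd = 0.05)
  par <- jit$phylo$edge[, 1]; kid <- jit$phylo$edge[, 2]
  mid <- rowMeans(jit$hpd)
  internal <- kid > n_tips(jit)
  expect_true(all(mid[par[internal]] >= mid[kid[internal]] - 1e-9))
})

test_that("datasets are bit-reproducible from (cfg, seed)", {
  cfg <- scenario_config()
  for (sc in c("introgression", "duplication_loss", "ils")) {
    d1 <- simulate_dataset(sc, cfg, seed = 4242)
    d2 <- simulate_dataset(sc, cfg, seed = 4242)
    expect_identical(write_tree(d1$gene_tree, format = "nexus"),
                     write_tree(d2$gene_tree, format = "nexus"))
    expect_identical(unclass(d1$alignment), unclass(d2$alignment))
    expect_identical(d1$truth, d2$truth)
  }
})
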