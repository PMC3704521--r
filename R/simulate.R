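# Synthetic-data generator.
#
# Emulates the study design end to end: a two-subgenus species tree whose
# subgenera split in the 9-13 Ma window, sections nested within each
# subgenus (Yule topology within sections), gene trees under the
# multispecies coalescent, and three competing histories for a set of
# focal extra gene copies --
#   introgression:      the focal copies' lineages are carried by recipient
#                       species but transfer into the donor section at the
#                       hybridization age (2.9-6.0 Ma window), well after
#                       the subgenus split;
#   duplication_loss:   a single gene duplication predating the subgenus
#                       split, the duplicate copy then descending the
#                       species tree with exponential per-branch losses so
#                       that it survives in only a few species;
#   ils:                deep coalescence only, via a large coalescent
#                       parameter, with extra alleles sampled from the
#                       recipient species.
# Sequences evolve along the gene tree under Jukes-Cantor, and node-age
# uncertainty is emulated by symmetric relative-width HPD intervals.

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults encode the study conditions: a 9-13 Ma subgenus split, an
#' introgression window of 2.9-6.0 Ma, two sections per subgenus with five
#' species each and one sampled copy per species, and Jukes-Cantor sequence
#' evolution.
#'
#' @param n_species_per_section Species per section.
#' @param sections Named list: subgenus name -> character vector of section
#'   names (two subgenera; the first is the recipient side, the second the
#'   donor side).
#' @param split_age_range Subgenus split age drawn uniformly from this
#'   interval (Ma).
#' @param subgenus_crown_frac,section_crown_frac Crown ages of each
#'   subgenus and section as fractions of the split age.
#' @param recipient_section,donor_section Section names hosting the focal
#'   copies and donating them.
#' @param n_recipients Number of recipient species carrying a focal copy
#'   under the introgression and ils scenarios.
#' @param event_age_range Introgression age drawn uniformly from this
#'   interval (Ma); must lie below `split_age_range[1]`.
#' @param duplication_age_factor Duplication age as a multiple of the split
#'   age (> 1: the duplication predates the split).
#' @param loss_rate Per-branch exponential loss rate (1/Ma) for the
#'   duplicate copy.
#' @param min_carriers Minimum surviving duplicate copies (resimulated up
#'   to `max_retries` times).
#' @param theta Coalescent time-scale parameter in Ma (mean waiting time to
#'   coalescence for two lineages sharing a branch).
#' @param theta_ils Coalescent parameter for the deep-coalescence scenario.
#' @param seq_length,subst_rate Alignment columns and substitution rate
#'   (substitutions/site/Ma) for Jukes-Cantor sequence evolution.
#' @param hpd_half_width Relative half-width of the emulated HPD intervals.
#' @param max_retries Resimulation cap for the loss process.
#' @return Named list of settings.
#' @export
scenario_config <- function(n_species_per_section = 5L,
                            sections = list(A = c("A1", "A2"),
                                            B = c("B1", "B2")),
                            split_age_range = c(9, 13),
                            subgenus_crown_frac = 0.75,
                            section_crown_frac = 0.45,
                            recipient_section = "A1",
                            donor_section = "B1",
                            n_recipients = 3L,
                            event_age_range = c(2.9, 6.0),
                            duplication_age_factor = 1.25,
                            loss_rate = 0.12,
                            min_carriers = 3L,
                            theta = 0.3,
                            theta_ils = 6,
                            seq_length = 1000L,
                            subst_rate = 0.004,
                            hpd_half_width = 0.1,
                            max_retries = 50L) {
  stopifnot(length(sections) == 2L, n_species_per_section >= 1L,
            split_age_range[1] <= split_age_range[2],
            subgenus_crown_frac < 1, section_crown_frac < subgenus_crown_frac,
            event_age_range[2] < split_age_range[1],
            duplication_age_factor > 1,
            loss_rate >= 0, theta > 0, theta_ils > 0,
            seq_length >= 1L, subst_rate >= 0,
            hpd_half_width >= 0, hpd_half_width < 1)
  as.list(environment())
}

# Yule-topology ultrametric subtree as a Newick fragment (no trailing ';'),
# crown scaled to `crown_age`; single species become a bare label.
yule_fragment <- function(labels, crown_age) {
  n <- length(labels)
  if (n == 1L) return(labels)
  phy <- ape::rphylo(n, birth = 1, death = 0)
  depth <- max(node_depths(phy)[seq_len(n)])
  phy$edge.length <- phy$edge.length * crown_age / depth
  phy$tip.label <- labels
  sub(";$", "", ape::write.tree(phy))
}

#' Simulate a two-subgenus species tree
#'
#' Ultrametric: the root is the subgenus split (age drawn from the
#' configured interval), each subgenus crown and section crown sit at fixed
#' fractions of the split age, and within-section topologies are
#' Yule-sampled.
#'
#' @param cfg A [scenario_config()].
#' @return A `dated_tree` with attribute `species_meta` (data frame:
#'   `species`, `subgenus`, `section`).
#' @export
sim_species_tree <- function(cfg = scenario_config()) {
  split_age <- stats::runif(1, cfg$split_age_range[1], cfg$split_age_range[2])
  sub_crown <- cfg$subgenus_crown_frac * split_age
  sec_crown <- cfg$section_crown_frac * split_age
  meta <- list()
  sub_frags <- character(0)
  for (sg in names(cfg$sections)) {
    secs <- cfg$sections[[sg]]
    sec_frags <- character(0)
    for (sec in secs) {
      labels <- sprintf("%s_s%02d", sec, seq_len(cfg$n_species_per_section))
      meta[[length(meta) + 1L]] <-
        data.frame(species = labels, subgenus = sg, section = sec)
      frag <- yule_fragment(labels, sec_crown)
      stem <- if (length(secs) == 1L) split_age - sec_crown
              else sub_crown - sec_crown
      sec_frags <- c(sec_frags, paste0(frag, ":", fmt_num(stem)))
    }
    sub_frag <- if (length(sec_frags) == 1L) sec_frags
                else paste0("(", paste(sec_frags, collapse = ","), ")",
                            ":", fmt_num(split_age - sub_crown))
    sub_frags <- c(sub_frags, sub_frag)
  }
  tree <- read_tree(text = paste0("(", paste(sub_frags, collapse = ","),
                                  ");"))
  attr(tree, "species_meta") <- do.call(rbind, meta)
  tree
}

#' Multispecies-coalescent gene tree, optionally with a lineage transfer
#'
#' Lineages are carried by species-tree branches and coalesce pairwise at
#' rate `choose(k,2)/theta` within each branch; at a species divergence the
#' surviving lineages of the two descendant branches join the parent
#' branch; above the root, coalescence continues until one lineage
#' remains.  Lineages of group `"focal"` coalesce only among themselves
#' (they are a separate gene copy) until the `transfer` age, at which point
#' they move to the destination branch and join the main pool -- the
#' introgression event when the destination is a contemporary branch of
#' the donor clade, or the gene-duplication point when it is above the
#' root.
#'
#' @param species Dated, ultrametric species tree.
#' @param samples Data frame with columns `label`, `species` and `group`
#'   (`"main"` or `"focal"`).
#' @param theta Coalescent parameter in Ma.
#' @param transfer `NULL`, or `list(age =, dest =)` with `dest` a
#'   species-tree node id whose branch (or the root branch) contains `age`.
#' @return A `dated_tree` (ultrametric, leaf ages 0).
#' @export
sim_msc <- function(species, samples, theta, transfer = NULL) {
  stopifnot(!is.null(species$ages))
  phy <- species$phylo
  ntip_s <- length(phy$tip.label)
  ages_s <- species$ages
  n_samp <- nrow(samples)
  if (any(samples$group == "focal") && is.null(transfer))
    stop("focal lineages need a transfer event to rejoin the main pool")
  nodes <- vector("list", 2L * n_samp)
  for (i in seq_len(n_samp))
    nodes[[i]] <- list(label = samples$label[i], age = 0, children = NULL)
  n_nodes <- n_samp
  lin_node <- seq_len(n_samp)
  lin_branch <- match(samples$species, phy$tip.label)
  if (anyNA(lin_branch))
    stop("sample species absent from species tree: ",
         paste(unique(samples$species[is.na(lin_branch)]), collapse = ", "))
  lin_group <- as.character(samples$group)

  ev <- data.frame(age = ages_s[(ntip_s + 1L):(ntip_s + phy$Nnode)],
                   type = "speciation",
                   node = (ntip_s + 1L):(ntip_s + phy$Nnode))
  if (!is.null(transfer))
    ev <- rbind(ev, data.frame(age = transfer$age, type = "transfer",
                               node = transfer$dest))
  ev <- ev[order(ev$age), , drop = FALSE]

  coalesce_until <- function(t_from, t_to) {
    done <- character(0)
    repeat {
      keys <- paste0(lin_branch, "|", lin_group)
      cand <- setdiff(names(which(table(keys) >= 2L)), done)
      if (length(cand) == 0L) break
      key <- cand[1L]
      t <- t_from
      repeat {
        keys <- paste0(lin_branch, "|", lin_group)
        idx <- which(keys == key)
        k <- length(idx)
        if (k < 2L) break
        t <- t + stats::rexp(1L, rate = k * (k - 1) / 2 / theta)
        if (t >= t_to) break
        pick <- sample(idx, 2L)
        n_nodes <<- n_nodes + 1L
        nodes[[n_nodes]] <<- list(label = NA_character_, age = t,
                                  children = lin_node[pick])
        lin_node[pick[1L]] <<- n_nodes
        lin_node <<- lin_node[-pick[2L]]
        lin_branch <<- lin_branch[-pick[2L]]
        lin_group <<- lin_group[-pick[2L]]
      }
      done <- c(done, key)
    }
  }

  ch_s <- children_list(phy)
  t_now <- 0
  for (i in seq_len(nrow(ev))) {
    coalesce_until(t_now, ev$age[i])
    t_now <- ev$age[i]
    if (ev$type[i] == "speciation") {
      kids <- ch_s[[ev$node[i]]]
      lin_branch[lin_branch %in% kids] <- ev$node[i]
    } else {
      lin_branch[lin_group == "focal"] <- ev$node[i]
      lin_group[lin_group == "focal"] <- "main"
    }
  }
  coalesce_until(t_now, Inf)
  if (length(lin_node) != 1L)
    stop("internal error: lineages failed to coalesce to a single root")

  nwk <- function(v) {
    nd <- nodes[[v]]
    if (is.null(nd$children)) return(quote_label(nd$label))
    paste0("(", paste(vapply(nd$children, function(c0)
      paste0(nwk(c0), ":", fmt_num(nd$age - nodes[[c0]]$age)),
      character(1)), collapse = ","), ")")
  }
  read_tree(text = paste0(nwk(lin_node), ";"))
}

# The focal copies are carried by a *clade* of recipient species (they
# emulate a species group that inherited the introgressed copy from a
# common ancestor).  Pick the proper clade inside the recipient section
# whose size is closest to the configured n_recipients, preferring the
# younger clade on ties; with one species requested (or a two-species
# section) a single species is returned.
recipient_clade <- function(species, meta, cfg) {
  sect_sp <- meta$species[meta$section == cfg$recipient_section]
  if (cfg$n_recipients <= 1L || length(sect_sp) <= 2L)
    return(sect_sp[1L])
  phy <- species$phylo
  ntip <- length(phy$tip.label)
  sets <- vector("list", ntip + phy$Nnode)
  for (v in seq_len(ntip)) sets[[v]] <- phy$tip.label[v]
  post <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in seq_len(nrow(post)))
    sets[[post[i, 1]]] <- c(sets[[post[i, 1]]], sets[[post[i, 2]]])
  crown <- mrca_node(species, sect_sp)
  cand <- which(vapply(seq_along(sets), function(v)
    v > ntip && v != crown && all(sets[[v]] %in% sect_sp), logical(1)))
  if (length(cand) == 0L) return(sect_sp[1L])
  score <- abs(lengths(sets[cand]) - cfg$n_recipients)
  best <- cand[score == min(score)]
  best <- best[which.min(species$ages[best])]
  sets[[best]]
}

# species-tree branch (node id) containing time `age` on the path from
# leaf `tip_label` to the root
branch_at_age <- function(species, tip_label, age) {
  par <- parent_vector(species$phylo)
  v <- match(tip_label, tip_labels(species))
  if (is.na(v)) stop("unknown species: ", tip_label)
  while (par[v] != 0L && species$ages[par[v]] <= age) v <- par[v]
  v
}

# exponential per-branch loss process for a copy entering at the root;
# returns the surviving tip labels and the number of loss events
simulate_losses <- function(species, loss_rate) {
  phy <- species$phylo
  ch <- children_list(phy)
  ntip <- length(phy$tip.label)
  ages <- species$ages
  present <- logical(ntip + phy$Nnode)
  n_lost <- 0L
  recurse <- function(v) {
    present[v] <<- TRUE
    for (c0 in ch[[v]]) {
      len <- ages[v] - ages[c0]
      if (stats::runif(1) < exp(-loss_rate * len)) recurse(c0)
      else n_lost <<- n_lost + 1L
    }
  }
  recurse(ntip + 1L)
  list(carriers = phy$tip.label[present[seq_len(ntip)]], n_lost = n_lost)
}

#' Simulate a gene tree under a chosen history of the focal copies
#'
#' One copy (`<species>_a`) is sampled from every species; focal extra
#' copies (`<species>_b`) are added according to the scenario (see
#' [scenario_config()] and [sim_msc()]).
#'
#' @param species Species tree from [sim_species_tree()].
#' @param cfg A [scenario_config()].
#' @param scenario `"introgression"`, `"duplication_loss"` or `"ils"`.
#' @return List with `tree` (dated gene tree), `assignment` (data frame:
#'   `leaf`, `species`, `focal`) and `truth` (event parameters).
#' @export
sim_gene_tree <- function(species, cfg = scenario_config(),
                          scenario = c("introgression", "duplication_loss",
                                       "ils")) {
  scenario <- match.arg(scenario)
  meta <- attr(species, "species_meta")
  if (is.null(meta)) stop("species tree lacks the species_meta attribute")
  split_age <- species$ages[n_tips(species) + 1L]
  main <- data.frame(label = paste0(meta$species, "_a"),
                     species = meta$species, group = "main")
  recipients <- recipient_clade(species, meta, cfg)
  theta <- cfg$theta
  transfer <- NULL
  truth <- list(scenario = scenario, split_age = split_age)

  if (scenario == "introgression") {
    # A single gene lineage is transferred into the common ancestor of the
    # recipient species, and the transferred copy must nest *within* the
    # donor section's diversification (the defining observation of the
    # scenario), so the event age is drawn inside the window bounded below
    # by the recipients' MRCA age and above by the donor section's crown.
    donor_species <- meta$species[meta$section == cfg$donor_section]
    donor_crown <- species$ages[mrca_node(species, donor_species)]
    recip_mrca <- if (length(recipients) > 1L)
      species$ages[mrca_node(species, recipients)] else 0
    lo <- max(cfg$event_age_range[1], recip_mrca)
    hi <- min(cfg$event_age_range[2], donor_crown)
    if (lo >= hi)
      stop("no feasible introgression age: recipient MRCA (", round(lo, 2),
           " Ma) reaches the donor section crown (", round(hi, 2), " Ma)")
    event_age <- stats::runif(1, lo, hi)
    stopifnot(event_age < split_age)
    donor_sp <- donor_species[1L]
    transfer <- list(age = event_age,
                     dest = branch_at_age(species, donor_sp, event_age))
    focal <- data.frame(label = paste0(recipients, "_b"),
                        species = recipients, group = "focal")
    truth$event_age <- event_age
  } else if (scenario == "duplication_loss") {
    dup_age <- cfg$duplication_age_factor * split_age
    carriers <- NULL
    for (try in seq_len(cfg$max_retries)) {
      sim <- simulate_losses(species, cfg$loss_rate)
      if (length(sim$carriers) >= cfg$min_carriers) { carriers <- sim; break }
    }
    if (is.null(carriers))
      stop("duplicate copy went extinct in every resimulation; ",
           "lower loss_rate or min_carriers")
    transfer <- list(age = dup_age, dest = n_tips(species) + 1L)
    focal <- data.frame(label = paste0(carriers$carriers, "_b"),
                        species = carriers$carriers, group = "focal")
    truth$duplication_age <- dup_age
    truth$n_losses_true <- carriers$n_lost
    truth$carriers <- carriers$carriers
  } else {
    theta <- cfg$theta_ils
    focal <- data.frame(label = paste0(recipients, "_b"),
                        species = recipients, group = "main")
  }
  samples <- rbind(main, focal)
  tree <- sim_msc(species, samples, theta, transfer)
  assignment <- data.frame(leaf = samples$label, species = samples$species,
                           focal = samples$label %in%
                             paste0(c(recipients,
                                      if (scenario == "duplication_loss")
                                        truth$carriers), "_b"))
  list(tree = tree, assignment = assignment, truth = truth)
}

#' Evolve an alignment along a dated tree under Jukes-Cantor
#'
#' The root sequence is uniform over A/C/G/T; along each branch every site
#' changes with probability `(3/4)(1 - exp(-(4/3) rate t))` to a uniformly
#' chosen different base (the exact Jukes-Cantor transition for a branch of
#' duration `t`).
#'
#' @param tree A `dated_tree` (node ages, or branch lengths for undated
#'   trees, supply the durations).
#' @param length Alignment columns.
#' @param rate Substitutions per site per Ma.
#' @return A [dna_alignment()] with one row per leaf.
#' @export
evolve_jc <- function(tree, length = 1000L, rate = 0.004) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  n_all <- ntip + phy$Nnode
  seqs <- matrix(0L, n_all, length)
  root <- ntip + 1L
  seqs[root, ] <- sample.int(4L, length, replace = TRUE)
  ed <- ape::reorder.phylo(phy, "cladewise")
  durations <- if (!is.null(tree$ages)) {
    tree$ages[ed$edge[, 1]] - tree$ages[ed$edge[, 2]]
  } else if (!is.null(ed$edge.length)) {
    ed$edge.length
  } else stop("tree has neither ages nor branch lengths")
  for (i in seq_len(nrow(ed$edge))) {
    p <- ed$edge[i, 1]; c0 <- ed$edge[i, 2]
    pc <- 0.75 * (1 - exp(-4 * rate * durations[i] / 3))
    s <- seqs[p, ]
    hit <- which(stats::runif(length) < pc)
    if (length(hit))
      s[hit] <- 1L + (s[hit] - 1L + sample.int(3L, length(hit),
                                               replace = TRUE)) %% 4L
    seqs[c0, ] <- s
  }
  mat <- matrix(DNA_BASES[seqs[seq_len(ntip), , drop = FALSE]], ntip, length)
  rownames(mat) <- phy$tip.label
  dna_alignment(mat)
}

#' Attach emulated HPD intervals to a dated tree
#'
#' Every internal node receives a symmetric relative-width interval
#' `[age (1 - w), age (1 + w)]`, optionally jittered multiplicatively;
#' jittered interval midpoints are capped at the parent's midpoint so the
#' parent-older-than-child ordering of midpoints is preserved.
#'
#' @param tree A `dated_tree` with ages.
#' @param half_width Relative half-width `w` in `[0, 1)`.
#' @param jitter_sd Standard deviation of the lognormal midpoint jitter
#'   (0 = none).
#' @return The tree with its `hpd` matrix filled on internal nodes.
#' @export
attach_hpd <- function(tree, half_width = 0.1, jitter_sd = 0) {
  if (half_width >= 1 || half_width < 0)
    stop("half_width must be in [0, 1)")
  stopifnot(!is.null(tree$ages))
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  n_all <- ntip + phy$Nnode
  centers <- tree$ages
  if (jitter_sd > 0) {
    par <- parent_vector(phy)
    ed <- ape::reorder.phylo(phy, "cladewise")$edge
    centers[ntip + 1L] <- centers[ntip + 1L] *
      exp(stats::rnorm(1, 0, jitter_sd))
    for (i in seq_len(nrow(ed))) {
      v <- ed[i, 2]
      if (v <= ntip) next
      centers[v] <- min(centers[v] * exp(stats::rnorm(1, 0, jitter_sd)),
                        centers[ed[i, 1]])
    }
  }
  hpd <- tree$hpd
  for (v in (ntip + 1L):n_all)
    hpd[v, ] <- centers[v] * c(1 - half_width, 1 + half_width)
  dated_tree(phy, ages = tree$ages, hpd = hpd, support = tree$support)
}

#' Simulate a complete labelled dataset
#'
#' Species tree, gene tree with HPD intervals, Jukes-Cantor alignment and
#' leaf assignment under one of the three competing histories, fully
#' reproducible from `(cfg, seed)`.
#'
#' @param scenario `"introgression"`, `"duplication_loss"` or `"ils"`.
#' @param cfg A [scenario_config()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Object of class `labeled_dataset`: list with `scenario`,
#'   `species_tree`, `gene_tree`, `alignment`, `assignment`, `truth`,
#'   `cfg`, `seed`.
#' @export
simulate_dataset <- function(scenario = c("introgression",
                                          "duplication_loss", "ils"),
                             cfg = scenario_config(), seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  species <- sim_species_tree(cfg)
  g <- sim_gene_tree(species, cfg, scenario)
  gene <- attach_hpd(g$tree, cfg$hpd_half_width)
  aln <- evolve_jc(gene, length = cfg$seq_length, rate = cfg$subst_rate)
  structure(list(scenario = scenario, species_tree = species,
                 gene_tree = gene, alignment = aln,
                 assignment = g$assignment, truth = g$truth,
                 cfg = cfg, seed = seed),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", x$scenario, "scenario,",
      nrow(x$assignment), "gene copies,",
      sum(x$assignment$focal), "focal\n")
  invisible(x)
}

#' Node designations (c, d, e) for a simulated dataset
#'
#' * `c` -- MRCA of the recipient section's primary copies,
#' * `d` -- MRCA of the donor section's copies together with the focal
#'   copies (the divergence origin of the focal copies),
#' * `e` -- MRCA of the recipient subgenus's primary copies.
#'
#' @param ds A `labeled_dataset`.
#' @return Named integer vector usable with [evaluate_hypotheses()].
#' @export
dataset_designations <- function(ds) {
  meta <- attr(ds$species_tree, "species_meta")
  asg <- ds$assignment
  cfg <- ds$cfg
  sp_section <- stats::setNames(meta$section, meta$species)
  sp_subgenus <- stats::setNames(meta$subgenus, meta$species)
  recipient_subgenus <- sp_subgenus[[
    meta$species[meta$section == cfg$recipient_section][1L]]]
  main <- asg$leaf[!asg$focal]
  focal <- asg$leaf[asg$focal]
  c_leaves <- main[sp_section[asg$species[!asg$focal]] ==
                     cfg$recipient_section]
  d_leaves <- c(asg$leaf[sp_section[asg$species] == cfg$donor_section],
                focal)
  e_leaves <- main[sp_subgenus[asg$species[!asg$focal]] ==
                     recipient_subgenus]
  designate_nodes(ds$gene_tree,
                  list(c = c_leaves, d = d_leaves, e = e_leaves))
}
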