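# Fixture builders and independent brute-force oracles.  The oracles
# deliberately avoid the package's own algorithms: reconciliation is
# re-derived from leaf-set containment, site statistics from explicit
# per-column state tables, and primer scans from a direct window filter.

# random ultrametric dated tree with n leaves (coalescent shape)
rand_dated_tree <- function(n, labels = paste0("t", seq_len(n))) {
  phy <- ape::rcoal(n, tip.label = labels)
  read_tree(text = ape::write.tree(phy))
}

# random alignment with optional gaps and ambiguity codes
rand_alignment <- function(n_seq, n_col, p_gap = 0, p_amb = 0,
                           labels = sprintf("s%02d", seq_len(n_seq))) {
  pool <- c("A", "C", "G", "T")
  mat <- matrix(sample(pool, n_seq * n_col, replace = TRUE), n_seq, n_col)
  if (p_gap > 0) {
    hit <- runif(n_seq * n_col) < p_gap
    mat[hit] <- "-"
  }
  if (p_amb > 0) {
    amb <- c("R", "Y", "S", "W", "K", "M", "N", "?")
    hit <- runif(n_seq * n_col) < p_amb
    mat[hit] <- sample(amb, sum(hit), replace = TRUE)
  }
  rownames(mat) <- labels
  dna_alignment(mat)
}

## --------------------------------------------------------------------------
## reconciliation oracle: leaf-set containment, no LCA walk-ups

# species-tree node tip-label sets
oracle_tipsets <- function(phylo) {
  ntip <- length(phylo$tip.label)
  n_all <- ntip + phylo$Nnode
  sets <- vector("list", n_all)
  for (v in seq_len(ntip)) sets[[v]] <- phylo$tip.label[v]
  ed <- ape::reorder.phylo(phylo, "postorder")$edge
  for (i in seq_len(nrow(ed)))
    sets[[ed[i, 1]]] <- union(sets[[ed[i, 1]]], sets[[ed[i, 2]]])
  sets
}

# brute-force duplication/loss counts for a gene tree on a species tree
oracle_reconcile <- function(gene_phylo, species_phylo, leaf_species) {
  g_ntip <- length(gene_phylo$tip.label)
  g_all <- g_ntip + gene_phylo$Nnode
  g_sets <- oracle_tipsets(gene_phylo)
  s_sets <- oracle_tipsets(species_phylo)
  s_sizes <- lengths(s_sets)
  # species cluster of each gene node
  clusters <- lapply(g_sets, function(labs)
    unique(unname(leaf_species[labs])))
  # map = smallest species node containing the cluster
  map <- integer(g_all)
  for (v in seq_len(g_all)) {
    containing <- which(vapply(s_sets, function(s)
      all(clusters[[v]] %in% s), logical(1)))
    map[v] <- containing[which.min(s_sizes[containing])]
  }
  # ancestors of a species node via containment (proper superset or self)
  anc_count <- function(x) sum(vapply(seq_along(s_sets), function(z)
    all(s_sets[[x]] %in% s_sets[[z]]), logical(1)))
  ch <- list()
  for (i in seq_len(nrow(gene_phylo$edge))) {
    p <- gene_phylo$edge[i, 1]
    ch[[as.character(p)]] <- c(ch[[as.character(p)]],
                               gene_phylo$edge[i, 2])
  }
  n_dup <- 0L; n_loss <- 0L
  for (v in (g_ntip + 1L):g_all) {
    kids <- ch[[as.character(v)]]
    is_dup <- any(map[kids] == map[v])
    if (is_dup) n_dup <- n_dup + 1L
    for (c0 in kids) {
      k <- anc_count(map[c0]) - anc_count(map[v])
      # k ancestors separate the two maps; path edges = k
      n_loss <- n_loss + if (is_dup) k else max(k - 1L, 0L)
    }
  }
  list(n_duplications = n_dup, n_losses = n_loss)
}

# run the package reconciliation from plain phylo objects
pkg_reconcile <- function(gene_phylo, species_phylo, leaf_species) {
  gene <- dated_tree(gene_phylo)
  species <- dated_tree(species_phylo)
  rec <- lca_map(gene, species, leaf_species)
  list(n_duplications = count_duplications(rec)$n_duplications,
       n_losses = count_losses(rec)$n_losses)
}

## --------------------------------------------------------------------------
## site-statistics oracle: explicit per-column classification

oracle_alignment_stats <- function(aln) {
  mat <- unclass(aln)
  bases <- c("A", "C", "G", "T")
  n_const <- 0L; n_pi <- 0L
  for (k in seq_len(ncol(mat))) {
    counts <- vapply(bases, function(b) sum(mat[, k] == b), integer(1))
    present <- counts[counts > 0L]
    if (length(present) == 1L) n_const <- n_const + 1L
    if (sum(present >= 2L) >= 2L) n_pi <- n_pi + 1L
  }
  list(n_parsimony_informative = n_pi, n_constant = n_const)
}

## --------------------------------------------------------------------------
## primer-scan oracle: direct window filter, written against the stated
## rules rather than the implementation

oracle_primer_scan <- function(aln, target, offtarget, min_len, max_len,
                               min_mm = c(forward = 1L, reverse = 2L)) {
  mat <- unclass(aln)
  nc <- ncol(mat)
  mm <- function(off, tgt) {
    if (off == tgt) return(FALSE)
    if (off %in% c("-", "?")) return(TRUE)
    sets <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                 W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                 B = c("C", "G", "T"), D = c("A", "G", "T"),
                 H = c("A", "C", "T"), V = c("A", "C", "G"),
                 N = c("A", "C", "G", "T"))
    s <- sets[[off]]
    if (is.null(s)) return(TRUE)
    !(tgt %in% s)
  }
  out <- list()
  for (len in min_len:min(max_len, nc)) for (start in 1:(nc - len + 1L)) {
    win <- start:(start + len - 1L)
    cols_ok <- vapply(win, function(k) {
      u <- unique(mat[target, k])
      length(u) == 1L && u %in% c("A", "C", "G", "T")
    }, logical(1))
    if (!all(cols_ok)) next
    cons <- vapply(win, function(k) mat[target[1], k], character(1))
    for (orient in c("forward", "reverse")) {
      term <- if (orient == "forward") rev(utils::tail(win, 3))
              else utils::head(win, 3)
      pass <- TRUE
      for (r in offtarget) {
        hits <- vapply(term, function(k)
          mm(mat[r, k], cons[match(k, win)]), logical(1))
        if (!hits[1] || sum(hits) < min_mm[[orient]]) { pass <- FALSE; break }
      }
      if (pass) out[[length(out) + 1L]] <-
          data.frame(orientation = orient, start = start,
                     end = start + len - 1L)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(orientation = character(0), start = integer(0),
                  end = integer(0))
}

# IUPAC superposition of two sequences (used to build heterozygotes)
superpose_iupac <- function(a, b) {
  codes <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  out <- a
  for (k in seq_along(a)) {
    if (a[k] != b[k]) {
      key <- paste(sort(c(a[k], b[k])), collapse = "")
      out[k] <- if (key %in% names(codes)) codes[[key]] else "N"
    }
  }
  out
}
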