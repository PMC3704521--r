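# Parsimony gene-tree/species-tree reconciliation under LCA mapping.
#
# Each gene-tree node is mapped to the least common ancestor (in the
# species tree) of the species hosting its descendant gene copies.  This is
# the unique reconciliation minimizing duplications.  A gene internal node
# v is a duplication iff map(v) equals map(c) for at least one child c.
# Losses along the gene edge (v, c) amount to k species-tree edges on the
# path map(v) -> map(c) when v is a duplication, and k - 1 (never below 0)
# otherwise.

# precomputed species-tree index
species_index <- function(species) {
  phy <- species$phylo
  par <- parent_vector(phy)
  n_all <- length(phy$tip.label) + phy$Nnode
  depth <- integer(n_all)
  root <- length(phy$tip.label) + 1L
  # BFS/cladewise: parents before children
  ed <- ape::reorder.phylo(phy, "cladewise")$edge
  for (i in seq_len(nrow(ed))) depth[ed[i, 2]] <- depth[ed[i, 1]] + 1L
  list(parent = par, depth = depth, root = root,
       tip_id = stats::setNames(seq_along(phy$tip.label), phy$tip.label))
}

lca_pair <- function(idx, u, v) {
  while (u != v) {
    if (idx$depth[u] >= idx$depth[v]) u <- idx$parent[u]
    else v <- idx$parent[v]
  }
  u
}

check_binary <- function(tree, what) {
  ch <- children_list(tree$phylo)
  sizes <- lengths(ch)
  bad <- which(sizes > 2L)
  if (length(bad))
    stop(what, " tree has a polytomy at node ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

normalize_assignment <- function(assignment) {
  if (is.data.frame(assignment))
    assignment <- stats::setNames(as.character(assignment[[2]]),
                                  as.character(assignment[[1]]))
  if (is.null(names(assignment)))
    stop("assignment must map gene leaf labels to species leaf labels")
  assignment
}

#' LCA mapping of a gene tree onto a species tree
#'
#' @param gene,species Rooted binary `dated_tree`s (polytomies are
#'   rejected).
#' @param assignment Named character vector (or two-column data frame)
#'   mapping every gene-tree leaf label to a species-tree leaf label.
#' @return Object of class `lca_map`: list with `map` (integer vector,
#'   gene node id -> species node id), plus the inputs.
#' @export
lca_map <- function(gene, species, assignment) {
  check_binary(gene, "gene")
  check_binary(species, "species")
  assignment <- normalize_assignment(assignment)
  g_labs <- tip_labels(gene)
  missing <- setdiff(g_labs, names(assignment))
  if (length(missing))
    stop("unassigned gene leaf/leaves: ", paste(missing, collapse = ", "))
  idx <- species_index(species)
  sp_of <- assignment[g_labs]
  unknown <- setdiff(sp_of, names(idx$tip_id))
  if (length(unknown))
    stop("assignment names species absent from the species tree: ",
         paste(unknown, collapse = ", "))
  phy <- gene$phylo
  ntip <- length(g_labs)
  n_all <- ntip + phy$Nnode
  map <- integer(n_all)
  map[seq_len(ntip)] <- idx$tip_id[sp_of]
  post <- ape::reorder.phylo(phy, "postorder")$edge
  # postorder: children are mapped before their parent is visited
  for (i in seq_len(nrow(post))) {
    p <- post[i, 1]; c0 <- post[i, 2]
    map[p] <- if (map[p] == 0L) map[c0] else lca_pair(idx, map[p], map[c0])
  }
  structure(list(map = map, gene = gene, species = species,
                 assignment = assignment, species_idx = idx),
            class = "lca_map")
}

#' Count duplications under an LCA mapping
#'
#' @param rec An `lca_map`.
#' @return List with `n_duplications` and `duplication_nodes` (gene node
#'   ids).
#' @export
count_duplications <- function(rec) {
  stopifnot(inherits(rec, "lca_map"))
  ch <- children_list(rec$gene$phylo)
  ntip <- n_tips(rec$gene)
  dup <- integer(0)
  for (v in (ntip + 1L):(ntip + rec$gene$phylo$Nnode)) {
    if (any(rec$map[ch[[v]]] == rec$map[v])) dup <- c(dup, v)
  }
  list(n_duplications = length(dup), duplication_nodes = dup)
}

#' Count losses under an LCA mapping
#'
#' @param rec An `lca_map`.
#' @return List with `n_losses` and `loss_edges` (data frame of gene edges
#'   and the losses they contribute).
#' @export
count_losses <- function(rec) {
  stopifnot(inherits(rec, "lca_map"))
  dup_nodes <- count_duplications(rec)$duplication_nodes
  ch <- children_list(rec$gene$phylo)
  ntip <- n_tips(rec$gene)
  idx <- rec$species_idx
  rows <- list()
  total <- 0L
  for (v in (ntip + 1L):(ntip + rec$gene$phylo$Nnode)) {
    is_dup <- v %in% dup_nodes
    for (c0 in ch[[v]]) {
      k <- idx$depth[rec$map[c0]] - idx$depth[rec$map[v]]
      l <- if (is_dup) k else max(k - 1L, 0L)
      if (l > 0L) rows[[length(rows) + 1L]] <-
          data.frame(node = v, child = c0, n_losses = l)
      total <- total + l
    }
  }
  loss_edges <- if (length(rows)) do.call(rbind, rows)
                else data.frame(node = integer(0), child = integer(0),
                                n_losses = integer(0))
  list(n_losses = total, loss_edges = loss_edges)
}

#' Reconcile a gene tree carrying focal extra copies
#'
#' Implements the focal-copy protocol: the species tree is the gene-taxon
#' tree with the focal (extra-copy) leaves removed, every non-focal gene
#' leaf is assigned to the species leaf of the same name, and each focal
#' leaf is assigned to its host species.  The resulting duplication and
#' loss counts measure only what a duplication/loss history would need in
#' order to accommodate the focal copies.
#'
#' @param gene Rooted binary `dated_tree`.
#' @param species Species tree, or `NULL` to derive it by pruning the focal
#'   leaves from `gene`.
#' @param focal Character vector of focal gene-leaf labels (may be empty).
#' @param hosts Named character vector mapping each focal leaf to its host
#'   species-tree leaf.
#' @return Object of class `reconciliation`: list with `n_duplications`,
#'   `n_losses`, `duplication_nodes`, `loss_edges` and the `lca_map`.
#' @export
reconcile_focal <- function(gene, species = NULL, focal = character(0),
                            hosts = NULL) {
  g_labs <- tip_labels(gene)
  unknown <- setdiff(focal, g_labs)
  if (length(unknown))
    stop("focal label(s) not in gene tree: ", paste(unknown, collapse = ", "))
  if (is.null(species)) species <- prune_leaves(gene, focal)
  assignment <- stats::setNames(setdiff(g_labs, focal),
                                setdiff(g_labs, focal))
  if (length(focal)) {
    if (is.null(hosts) || !all(focal %in% names(hosts)))
      stop("every focal leaf needs a host species in 'hosts'")
    sp_labs <- tip_labels(species)
    bad <- setdiff(hosts[focal], sp_labs)
    if (length(bad))
      stop("host species absent from species tree: ",
           paste(bad, collapse = ", "))
    assignment <- c(assignment, stats::setNames(hosts[focal], focal))
  }
  rec <- lca_map(gene, species, assignment)
  dups <- count_duplications(rec)
  losses <- count_losses(rec)
  structure(list(n_duplications = dups$n_duplications,
                 n_losses = losses$n_losses,
                 duplication_nodes = dups$duplication_nodes,
                 loss_edges = losses$loss_edges,
                 lca_map = rec),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("reconciliation:", x$n_duplications, "duplication(s),",
      x$n_losses, "loss(es)\n")
  invisible(x)
}
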