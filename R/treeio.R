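# Rooted dated trees: the data model shared by all analysis steps.
#
# A dated_tree wraps an ape "phylo" object and attaches, per node (ape
# numbering: tips 1..n, internals n+1..n+Nnode, root = n+1):
#   ages    -- node age in Ma (0 at the tips of an ultrametric tree),
#              or NULL for undated trees,
#   hpd     -- a (n + Nnode) x 2 matrix of 95% HPD age intervals (NA where
#              absent),
#   support -- posterior probability in [0, 1] (NA where absent).

#' Construct a dated tree
#'
#' Bundles an [ape::phylo] tree with node ages (Ma), optional 95% HPD age
#' intervals and optional posterior support, and validates the result.
#'
#' @param phylo A rooted tree of class `phylo`.
#' @param ages Numeric vector of node ages in Ma, one per node in ape
#'   numbering (tips first), or `NULL` for an undated tree.
#' @param hpd Two-column matrix of HPD lower/upper bounds per node, or `NULL`.
#' @param support Numeric vector of posterior probabilities per node, or `NULL`.
#' @return An object of class `dated_tree`.
#' @export
dated_tree <- function(phylo, ages = NULL, hpd = NULL, support = NULL) {
  if (!inherits(phylo, "phylo")) stop("'phylo' must be an ape \"phylo\" tree")
  n_all <- length(phylo$tip.label) + phylo$Nnode
  if (anyDuplicated(phylo$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phylo$tip.label[duplicated(phylo$tip.label)]),
               collapse = ", "))
  if (!is.null(ages)) {
    stopifnot(length(ages) == n_all)
    if (any(is.finite(ages) & ages < -1e-9))
      stop("node ages must be non-negative")
    ages <- pmax(ages, 0)
    par <- parent_vector(phylo)
    for (v in seq_len(n_all)) {
      p <- par[v]
      if (p > 0L && is.finite(ages[p]) && is.finite(ages[v]) &&
          ages[p] < ages[v] - 1e-6)
        stop("node ", v, " is older (", ages[v], " Ma) than its parent (",
             ages[p], " Ma)")
    }
  }
  if (!is.null(hpd)) {
    hpd <- as.matrix(hpd)
    stopifnot(nrow(hpd) == n_all, ncol(hpd) == 2)
    bad <- which(!is.na(hpd[, 1]) & !is.na(hpd[, 2]) & hpd[, 1] > hpd[, 2])
    if (length(bad))
      stop("HPD interval with lower > upper at node(s) ",
           paste(bad, collapse = ", "))
    if (any(hpd < -1e-9, na.rm = TRUE))
      stop("HPD bounds must be non-negative")
  } else {
    hpd <- matrix(NA_real_, n_all, 2)
  }
  if (is.null(support)) support <- rep(NA_real_, n_all)
  structure(list(phylo = phylo, ages = ages, hpd = hpd, support = support),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  nt <- length(x$phylo$tip.label)
  cat("dated_tree:", nt, "leaves,", x$phylo$Nnode, "internal nodes\n")
  if (!is.null(x$ages))
    cat("  root age:", format(x$ages[nt + 1L], digits = 6), "Ma\n")
  else cat("  undated (no node ages)\n")
  n_hpd <- sum(!is.na(x$hpd[, 1]))
  if (n_hpd > 0) cat("  HPD intervals on", n_hpd, "node(s)\n")
  invisible(x)
}

#' Leaf labels of a dated tree
#' @param tree A `dated_tree`.
#' @return Character vector of leaf labels.
#' @export
tip_labels <- function(tree) tree$phylo$tip.label

#' Number of leaves
#' @param tree A `dated_tree`.
#' @return Integer.
#' @export
n_tips <- function(tree) length(tree$phylo$tip.label)

# parent of each node (0 at the root), ape numbering
parent_vector <- function(phylo) {
  n_all <- length(phylo$tip.label) + phylo$Nnode
  par <- integer(n_all)
  par[phylo$edge[, 2]] <- phylo$edge[, 1]
  par
}

# children list per node
children_list <- function(phylo) {
  n_all <- length(phylo$tip.label) + phylo$Nnode
  ch <- vector("list", n_all)
  for (i in seq_len(nrow(phylo$edge)))
    ch[[phylo$edge[i, 1]]] <- c(ch[[phylo$edge[i, 1]]], phylo$edge[i, 2])
  ch
}

#' Most recent common ancestor of a set of leaves
#'
#' @param tree A `dated_tree`.
#' @param labels Character vector of leaf labels (length >= 1).
#' @return Node id (ape numbering).
#' @export
mrca_node <- function(tree, labels) {
  idx <- match(labels, tip_labels(tree))
  if (anyNA(idx))
    stop("unknown leaf label(s): ", paste(labels[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree$phylo, idx)
}

#' Designate named nodes by leaf sets
#'
#' Internal nodes of interest (the "a" through "e" style designations used
#' in relative-age arguments) are supplied by the caller as the MRCA of two
#' or more named leaves; they are never inferred.
#'
#' @param tree A `dated_tree`.
#' @param spec Named list; each element a character vector of leaf labels
#'   whose MRCA carries that designation.
#' @return Named integer vector of node ids.
#' @export
designate_nodes <- function(tree, spec) {
  stopifnot(is.list(spec), !is.null(names(spec)))
  vapply(spec, function(labs) as.integer(mrca_node(tree, labs)), integer(1))
}

#' Read a node-designation file
#'
#' Two whitespace/tab-separated columns: designation letter and a
#' comma-separated list of leaf labels whose MRCA it names.
#'
#' @param file Path.
#' @return Named list of character vectors, usable with [designate_nodes()].
#' @export
read_designations <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (length(parts) < 2) stop("malformed designation line: ", ln)
    out[[parts[1]]] <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
  }
  out
}

## ---------------------------------------------------------------------------
## Newick / NEXUS parsing (comment-aware; keeps BEAST/FigTree annotations)

# Recursive-descent Newick parser that retains bracketed node comments.
# Returns a phylo plus per-node comment strings.
parse_newick_annotated <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n_ch <- length(chars)
  i <- 1L
  parent <- integer(0)
  label <- character(0)
  brlen <- numeric(0)
  comment <- character(0)

  perr <- function(msg) stop("Newick parse error at position ", i, ": ", msg,
                             call. = FALSE)
  peek <- function() if (i <= n_ch) chars[i] else ""
  skip_ws <- function() {
    while (i <= n_ch && grepl("^[ \t\r\n]$", chars[i])) i <<- i + 1L
  }
  new_node <- function(p) {
    parent[length(parent) + 1L] <<- p
    label[length(label) + 1L] <<- NA_character_
    brlen[length(brlen) + 1L] <<- NA_real_
    comment[length(comment) + 1L] <<- ""
    length(parent)
  }
  read_comment <- function() {
    start <- i
    depth <- 0L
    repeat {
      if (i > n_ch) { i <<- start; perr("unterminated comment '['") }
      if (chars[i] == "[") depth <- depth + 1L
      if (chars[i] == "]") {
        depth <- depth - 1L
        if (depth == 0L) break
      }
      i <<- i + 1L
    }
    out <- paste(chars[(start + 1L):(i - 1L)], collapse = "")
    i <<- i + 1L
    out
  }
  read_bare <- function() {
    start <- i
    while (i <= n_ch && !grepl("^[][(),:; \t\r\n]$", chars[i]))
      i <<- i + 1L
    if (i == start) perr("expected a token")
    paste(chars[start:(i - 1L)], collapse = "")
  }
  read_quoted <- function() {
    i <<- i + 1L  # opening quote
    out <- character(0)
    repeat {
      if (i > n_ch) perr("unterminated quoted label")
      if (chars[i] == "'") {
        if (i + 1L <= n_ch && chars[i + 1L] == "'") {  # escaped quote
          out <- c(out, "'"); i <<- i + 2L
        } else { i <<- i + 1L; break }
      } else { out <- c(out, chars[i]); i <<- i + 1L }
    }
    paste(out, collapse = "")
  }

  parse_subtree <- function(p) {
    skip_ws()
    node <- new_node(p)
    if (peek() == "(") {
      repeat {
        i <<- i + 1L  # consume '(' or ','
        parse_subtree(node)
        skip_ws()
        if (peek() == ",") next
        if (peek() == ")") { i <<- i + 1L; break }
        perr("expected ',' or ')'")
      }
    }
    # label / comments / branch length, in flexible order
    have_label <- FALSE
    repeat {
      skip_ws()
      c0 <- peek()
      if (c0 == "[") {
        comment[node] <<- paste0(comment[node], read_comment())
      } else if (c0 == "'") {
        if (have_label) perr("two labels on one node")
        label[node] <<- read_quoted(); have_label <- TRUE
      } else if (c0 == ":") {
        i <<- i + 1L
        skip_ws()
        while (peek() == "[")
          comment[node] <<- paste0(comment[node], read_comment())
        skip_ws()
        tok <- read_bare()
        val <- suppressWarnings(as.numeric(tok))
        if (is.na(val)) perr(paste0("invalid branch length '", tok, "'"))
        brlen[node] <<- val
      } else if (c0 %in% c(",", ")", ";", "")) {
        break
      } else {
        if (have_label) perr("unexpected token")
        label[node] <<- read_bare(); have_label <- TRUE
      }
    }
    node
  }

  skip_ws()
  while (peek() == "[") read_comment()  # leading [&R] style rooting comment
  skip_ws()
  if (peek() == "") perr("empty tree string")
  parse_subtree(0L)
  skip_ws()
  if (peek() != ";") perr("expected terminating ';'")

  n_nodes <- length(parent)
  n_children <- tabulate(parent, nbins = n_nodes)
  is_tip <- n_children == 0L
  if (any(n_children == 1L))
    stop("unary internal node(s) are not supported")
  ntip <- sum(is_tip)
  if (ntip < 2L) stop("a tree needs at least two leaves")
  if (any(is.na(label[is_tip])))
    stop("unlabeled leaf in tree")
  if (anyDuplicated(label[is_tip]))
    stop("duplicate leaf labels: ",
         paste(unique(label[is_tip][duplicated(label[is_tip])]),
               collapse = ", "))
  root <- which(parent == 0L)
  if (n_children[root] > 2L)
    warning("basal multifurcation: treating the tree as rooted at it")

  # renumber: tips 1..ntip (in encounter order), internals in preorder
  new_id <- integer(n_nodes)
  new_id[is_tip] <- seq_len(ntip)
  internals <- which(!is_tip)
  # preorder over internals (parse order is already parent-before-child)
  new_id[internals] <- ntip + seq_along(internals)
  nonroot <- which(parent > 0L)
  edge <- cbind(new_id[parent[nonroot]], new_id[nonroot])
  phy <- list(edge = edge,
              tip.label = label[is_tip][order(new_id[is_tip])],
              Nnode = n_nodes - ntip)
  lens <- brlen[nonroot]
  if (all(!is.na(lens))) {
    phy$edge.length <- lens
  } else if (any(!is.na(lens))) {
    stop("branch lengths present on some edges but missing on others")
  }
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  cmt <- character(ntip + phy$Nnode)
  cmt[new_id] <- comment
  list(phylo = phy, comments = cmt)
}

# Pull an HPD interval out of a BEAST/FigTree node comment.  Both the
# `height_95%_HPD={lo,hi}` and `height_95_HPD={lo,hi}` key dialects are
# accepted; the first matching key wins.
parse_hpd_comment <- function(comment) {
  for (key in c("height_95%_HPD", "height_95_HPD")) {
    pat <- paste0(gsub("%", "%", key, fixed = TRUE),
                  "=\\{([-0-9.eE+]+)\\s*,\\s*([-0-9.eE+]+)\\}")
    m <- regmatches(comment, regexec(pat, comment, fixed = FALSE))[[1]]
    if (length(m) == 3) {
      iv <- as.numeric(m[2:3])
      if (anyNA(iv)) stop("unreadable HPD annotation: ", comment)
      if (iv[1] > iv[2])
        stop("HPD annotation with lower > upper: ", comment)
      return(iv)
    }
  }
  NULL
}

parse_support_comment <- function(comment) {
  m <- regmatches(comment,
                  regexec("posterior=([0-9.eE+-]+)", comment))[[1]]
  if (length(m) == 2) as.numeric(m[2]) else NA_real_
}

# node depths (root-to-node path length); NULL if no branch lengths
node_depths <- function(phylo) {
  if (is.null(phylo$edge.length)) return(NULL)
  n_all <- length(phylo$tip.label) + phylo$Nnode
  depth <- rep(NA_real_, n_all)
  root <- length(phylo$tip.label) + 1L
  depth[root] <- 0
  # cladewise order visits parents before children
  ed <- ape::reorder.phylo(phylo, "cladewise")
  for (i in seq_len(nrow(ed$edge)))
    depth[ed$edge[i, 2]] <- depth[ed$edge[i, 1]] + ed$edge.length[i]
  depth
}

# Convert branch lengths to node ages when the tree is leaf-contemporaneous
# (all leaf depths equal within tol); otherwise NULL (undated).
depths_to_ages <- function(phylo, tol = 1e-6) {
  depth <- node_depths(phylo)
  if (is.null(depth)) return(NULL)
  ntip <- length(phylo$tip.label)
  leaf_d <- depth[seq_len(ntip)]
  if (max(leaf_d) - min(leaf_d) > tol) return(NULL)
  ages <- pmax(max(leaf_d) - depth, 0)
  ages[seq_len(ntip)] <- 0  # snap float jitter on contemporaneous leaves
  ages
}

#' Read a rooted tree from Newick or NEXUS
#'
#' NEXUS input may carry FigTree/BEAST-style bracketed node comments; node
#' height 95% HPD annotations (`height_95%_HPD={lo,hi}` or
#' `height_95_HPD={lo,hi}`) become per-node HPD intervals and `posterior=`
#' becomes node support.  Branch lengths are converted to node ages when the
#' tree is ultrametric (all leaves contemporaneous, tolerance 1e-6);
#' otherwise the tree is kept undated.
#'
#' @param file Path to a tree file, or `NULL` when `text` is given.
#' @param text Literal tree text (alternative to `file`).
#' @param format `"auto"`, `"newick"` or `"nexus"`.
#' @return A [dated_tree()].
#' @export
read_tree <- function(file = NULL, text = NULL,
                      format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (is.null(text)) {
    if (is.null(file)) stop("give either 'file' or 'text'")
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  if (format == "auto") {
    format <- if (grepl("^\\s*#NEXUS", text, ignore.case = TRUE))
      "nexus" else "newick"
  }
  if (format == "nexus") {
    parsed <- parse_nexus_tree(text)
  } else {
    parsed <- parse_newick_annotated(text)
  }
  phy <- parsed$phylo
  n_all <- length(phy$tip.label) + phy$Nnode
  hpd <- matrix(NA_real_, n_all, 2)
  support <- rep(NA_real_, n_all)
  for (v in seq_len(n_all)) {
    if (nzchar(parsed$comments[v])) {
      iv <- parse_hpd_comment(parsed$comments[v])
      if (!is.null(iv)) hpd[v, ] <- iv
      support[v] <- parse_support_comment(parsed$comments[v])
    }
  }
  ages <- depths_to_ages(phy)
  dated_tree(phy, ages = ages, hpd = hpd, support = support)
}

# Extract the first tree statement (with comments) from a NEXUS TREES block
# and apply its TRANSLATE table.
parse_nexus_tree <- function(text) {
  block <- regmatches(text, regexpr("(?is)begin\\s+trees\\s*;.*?\\bend\\s*;",
                                    text, perl = TRUE))
  if (length(block) == 0 || !nzchar(block))
    stop("no TREES block found in NEXUS input")
  block <- block[[1]]
  trans <- NULL
  tm <- regmatches(block,
                   regexpr("(?is)\\btranslate\\b(.*?);", block, perl = TRUE))
  if (length(tm) && nzchar(tm)) {
    body <- sub("(?is)^\\s*translate\\b", "", tm[[1]], perl = TRUE)
    body <- sub(";\\s*$", "", body)
    entries <- strsplit(body, ",")[[1]]
    trans <- list()
    for (e in entries) {
      e <- trimws(e)
      if (!nzchar(e)) next
      mm <- regmatches(e, regexec("^(\\S+)\\s+(.*)$", e))[[1]]
      if (length(mm) != 3) stop("malformed TRANSLATE entry: ", e)
      lab <- trimws(mm[3])
      lab <- gsub("^'(.*)'$", "\\1", lab)
      trans[[mm[2]]] <- lab
    }
  }
  tpos <- regexpr("(?is)\\btree\\s+\\S+\\s*=", block, perl = TRUE)
  if (tpos < 0) stop("no tree statement found in TREES block")
  rest <- substr(block, tpos + attr(tpos, "match.length"), nchar(block))
  # terminate at the first ';' outside brackets/quotes
  ch <- strsplit(rest, "", fixed = TRUE)[[1]]
  depth <- 0L; inq <- FALSE; endpos <- NA_integer_
  for (k in seq_along(ch)) {
    if (inq) { if (ch[k] == "'") inq <- FALSE; next }
    if (ch[k] == "'") inq <- TRUE
    else if (ch[k] == "[") depth <- depth + 1L
    else if (ch[k] == "]") depth <- depth - 1L
    else if (ch[k] == ";" && depth == 0L) { endpos <- k; break }
  }
  if (is.na(endpos)) stop("unterminated tree statement in TREES block")
  newick <- substr(rest, 1, endpos)
  parsed <- parse_newick_annotated(newick)
  if (!is.null(trans)) {
    labs <- parsed$phylo$tip.label
    hit <- labs %in% names(trans)
    labs[hit] <- unlist(trans[labs[hit]])
    if (anyDuplicated(labs))
      stop("duplicate leaf labels after TRANSLATE")
    parsed$phylo$tip.label <- labs
  }
  parsed
}

## ---------------------------------------------------------------------------
## Writing

quote_label <- function(lab) {
  if (grepl("[][(),:;' \t]", lab))
    paste0("'", gsub("'", "''", lab), "'") else lab
}

fmt_num <- function(x) sprintf("%.15g", x)

# Newick text; annotate=TRUE emits FigTree-style node comments.
build_newick <- function(tree, annotate = FALSE) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  ch <- children_list(phy)
  ages <- tree$ages
  par <- parent_vector(phy)
  elen <- function(v) {
    p <- par[v]
    if (p == 0L) return(NA_real_)
    if (!is.null(ages)) return(ages[p] - ages[v])
    if (!is.null(phy$edge.length)) {
      k <- which(phy$edge[, 2] == v)
      return(phy$edge.length[k])
    }
    NA_real_
  }
  node_comment <- function(v) {
    if (!annotate) return("")
    parts <- character(0)
    if (!is.na(tree$hpd[v, 1]))
      parts <- c(parts, paste0("height_95%_HPD={", fmt_num(tree$hpd[v, 1]),
                               ",", fmt_num(tree$hpd[v, 2]), "}"))
    if (!is.na(tree$support[v]))
      parts <- c(parts, paste0("posterior=", fmt_num(tree$support[v])))
    if (length(parts)) paste0("[&", paste(parts, collapse = ","), "]") else ""
  }
  rec <- function(v) {
    core <- if (v <= ntip) {
      quote_label(phy$tip.label[v])
    } else {
      paste0("(", paste(vapply(ch[[v]], rec, character(1)), collapse = ","),
             ")")
    }
    out <- paste0(core, node_comment(v))
    len <- elen(v)
    if (!is.na(len)) out <- paste0(out, ":", fmt_num(len))
    out
  }
  paste0(rec(ntip + 1L), ";")
}

#' Write a tree to Newick or NEXUS
#'
#' NEXUS output carries FigTree-style node comments with any HPD interval
#' (`height_95%_HPD={lo,hi}`) and posterior support present on the tree, so
#' that `read_tree(write_tree(t))` round-trips annotations.
#'
#' @param tree A `dated_tree`.
#' @param file Path, or `NULL` to return the text.
#' @param format `"newick"` or `"nexus"`.
#' @return The tree text, invisibly when written to a file.
#' @export
write_tree <- function(tree, file = NULL, format = c("newick", "nexus")) {
  format <- match.arg(format)
  txt <- if (format == "newick") {
    build_newick(tree, annotate = FALSE)
  } else {
    paste0("#NEXUS\nbegin trees;\n\ttree TREE1 = [&R] ",
           build_newick(tree, annotate = TRUE), "\nend;\n")
  }
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Prune leaves from a dated tree
#'
#' Removes the given leaves, suppresses the resulting unary nodes, and
#' carries node ages, HPD intervals and support over to the surviving nodes
#' (matched as MRCAs of their retained leaf sets, so ages are unchanged).
#'
#' @param tree A `dated_tree`.
#' @param labels Leaf labels to remove; must be a proper subset of the
#'   leaves (an empty set returns the tree unchanged).
#' @return A `dated_tree` on the complement leaf set.
#' @export
prune_leaves <- function(tree, labels) {
  labels <- unique(labels)
  if (length(labels) == 0L) return(tree)
  labs <- tip_labels(tree)
  unknown <- setdiff(labels, labs)
  if (length(unknown))
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(labs, labels)
  if (length(keep) < 2L)
    stop("pruning would leave fewer than two leaves")
  new_phy <- ape::drop.tip(tree$phylo, labels, collapse.singles = TRUE)
  n_new <- length(new_phy$tip.label) + new_phy$Nnode
  ages <- if (is.null(tree$ages)) NULL else rep(NA_real_, n_new)
  hpd <- matrix(NA_real_, n_new, 2)
  support <- rep(NA_real_, n_new)
  ch <- children_list(new_phy)
  ntip_new <- length(new_phy$tip.label)
  # leaf descendant labels per new node
  desc <- vector("list", n_new)
  ord <- ape::reorder.phylo(new_phy, "postorder")$edge
  for (v in seq_len(ntip_new)) desc[[v]] <- new_phy$tip.label[v]
  for (i in seq_len(nrow(ord)))
    desc[[ord[i, 1]]] <- c(desc[[ord[i, 1]]], desc[[ord[i, 2]]])
  for (v in seq_len(n_new)) {
    old <- mrca_node(tree, desc[[v]])
    if (!is.null(ages)) ages[v] <- tree$ages[old]
    hpd[v, ] <- tree$hpd[old, ]
    support[v] <- tree$support[old]
  }
  dated_tree(new_phy, ages = ages, hpd = hpd, support = support)
}
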