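#' Annotated time-tree
#'
#' An `annotated_tree` couples a rooted `ape` `phylo` topology whose branch
#' lengths are in Myr with a per-node annotation table: posterior node age
#' (Ma), the node rate median (substitutions/site/Myr), posterior
#' probability, and, for simulator output, the true rate of the branch
#' subtending each node. Ages increase into the past with tips at 0, the
#' "Node ages" convention of FigTree. Node ages are always derived from the
#' branch lengths (max path to a descendant leaf), so the same code path
#' serves simulated trees and external files; a `height` annotation that
#' disagrees beyond tolerance triggers a warning and is overridden.
#'
#' Node numbering follows the `ape` convention (tips `1..n`, root `n+1`) and
#' is canonicalized to the order a newick reader assigns (tips in
#' left-to-right order, internal nodes in preorder), which makes
#' parse/write round trips the identity.
#'
#' @param phy A rooted `phylo` object with branch lengths in Myr.
#' @param node_data Optional data frame with a `node` column and any of
#'   `rate_median`, `posterior`, `branch_rate`, plus a list column `extra`
#'   of verbatim unknown annotations.
#' @param ultra_tol Relative tolerance for the ultrametricity check.
#' @return An object of class `"annotated_tree"` with elements `phy` and
#'   `node_data` (one row per node, ages filled in).
#' @export
annotated_tree <- function(phy, node_data = NULL, ultra_tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length))
    stop("annotated_tree requires branch lengths (in Myr)")
  if (!ape::is.rooted(phy))
    stop("annotated_tree requires a rooted tree")
  canon <- .canonicalize_phylo(phy)
  phy <- canon$phy
  n_node <- ape::Ntip(phy) + phy$Nnode
  nd <- data.frame(node = seq_len(n_node), stringsAsFactors = FALSE)
  nd$label <- .node_labels(phy)
  nd$age_ma <- .compute_ages(phy, ultra_tol = ultra_tol)
  nd$rate_median <- NA_real_
  nd$posterior <- NA_real_
  nd$branch_rate <- NA_real_
  nd$extra <- rep(list(NULL), n_node)
  if (!is.null(node_data)) {
    stopifnot("node" %in% names(node_data))
    idx <- canon$map[node_data$node]
    for (col in c("rate_median", "posterior", "branch_rate"))
      if (col %in% names(node_data)) nd[[col]][idx] <- node_data[[col]]
    if ("extra" %in% names(node_data)) nd$extra[idx] <- node_data$extra
    if ("height" %in% names(node_data)) {
      h <- node_data[["height"]]
      ok <- !is.na(h)
      if (any(ok)) {
        rel <- abs(h[ok] - nd$age_ma[idx][ok]) /
          pmax(abs(nd$age_ma[idx][ok]), 1)
        if (any(rel > 1e-6))
          warning("'height' annotations disagree with branch-length-derived ",
                  "ages at ", sum(rel > 1e-6),
                  " node(s); branch-length-derived ages are used")
      }
    }
  }
  structure(list(phy = phy, node_data = nd), class = "annotated_tree")
}

# Renumber so tips appear 1..n in left-to-right (newick) order and internal
# nodes in preorder; returns the renumbered phylo and old->new node map.
.canonicalize_phylo <- function(phy) {
  phy <- stats::reorder(phy, "cladewise")
  n <- ape::Ntip(phy)
  n_node <- n + phy$Nnode
  old_int <- unique(phy$edge[, 1L])             # preorder, root first
  old_tip <- phy$edge[phy$edge[, 2L] <= n, 2L]  # left-to-right
  map <- integer(n_node)
  map[old_tip] <- seq_len(n)
  map[old_int] <- n + seq_along(old_int)
  new_phy <- phy
  new_phy$edge <- matrix(as.integer(map[phy$edge]), ncol = 2L)
  new_phy$tip.label <- phy$tip.label[order(map[seq_len(n)])]
  if (!is.null(phy$node.label))
    new_phy$node.label <- phy$node.label[order(map[(n + 1L):n_node])]
  attr(new_phy, "order") <- "cladewise"
  list(phy = new_phy, map = map)
}

.node_labels <- function(phy) {
  n <- ape::Ntip(phy)
  lab <- character(n + phy$Nnode)
  lab[seq_len(n)] <- phy$tip.label
  internal <- if (!is.null(phy$node.label)) phy$node.label else character(phy$Nnode)
  internal[is.na(internal) | !nzchar(internal)] <-
    paste0("node", which(is.na(internal) | !nzchar(internal)) + n)
  lab[(n + 1L):(n + phy$Nnode)] <- internal
  lab
}

# Ages by the max-path-to-descendant-leaf convention (tips exactly 0);
# warns when root-to-tip depths are unequal beyond tolerance.
.compute_ages <- function(phy, ultra_tol = 1e-6) {
  n <- ape::Ntip(phy)
  n_node <- n + phy$Nnode
  age <- numeric(n_node)
  edge <- phy$edge
  len <- phy$edge.length
  # postorder: children before parents
  po <- rev(seq_len(nrow(edge)))
  for (i in po) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    age[p] <- max(age[p], age[ch] + len[i])
  }
  depth <- ape::node.depth.edgelength(phy)
  tip_depth <- depth[seq_len(n)]
  if (diff(range(tip_depth)) > ultra_tol * max(tip_depth, 1))
    warning("tree is not ultrametric within tolerance; node ages follow the ",
            "max-path-to-leaf convention")
  age
}

#' Node ages of an annotated tree
#'
#' @param tree An [annotated_tree].
#' @return Numeric vector of ages in Ma indexed by node number.
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "annotated_tree"))
  tree$node_data$age_ma
}

#' Coerce to phylo
#' @param x An [annotated_tree] or `phylo`.
#' @return The underlying `phylo` object.
#' @export
as_phylo <- function(x) {
  if (inherits(x, "annotated_tree")) x$phy
  else if (inherits(x, "phylo")) x
  else stop("cannot coerce object of class '", class(x)[1L], "' to phylo")
}

#' @export
print.annotated_tree <- function(x, ...) {
  n <- ape::Ntip(x$phy)
  cat(sprintf("Annotated time-tree: %d tips, %d internal nodes, root age %.4g Ma\n",
              n, x$phy$Nnode, max(x$node_data$age_ma)))
  n_rate <- sum(!is.na(x$node_data$rate_median))
  n_post <- sum(!is.na(x$node_data$posterior))
  cat(sprintf("  annotations: rate_median at %d node(s), posterior at %d node(s)\n",
              n_rate, n_post))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Parsing: newick with [&key=value,...] metadata comments, bare or inside a
## NEXUS TREES block with an optional TRANSLATE table.
## ---------------------------------------------------------------------------

#' Parse an annotated NEXUS or newick tree
#'
#' Reads the tree dialect produced by Bayesian dating software and viewed in
#' FigTree: newick with `[&key=value,...]` metadata comments attached to the
#' node or branch token they follow, optionally wrapped in a NEXUS `TREES`
#' block with a taxon `TRANSLATE` table. Keys `posterior`, `rate_median`
#' (synonym `rate`), and `branch_rate` populate the node table; all other
#' keys are preserved verbatim. Node ages are computed from branch lengths.
#'
#' @param text A single string, or a character vector of lines, containing
#'   either a NEXUS file or a bare newick string.
#' @param tree_index Which tree to take when the file holds several
#'   (default the first; MCC summary files carry one tree).
#' @return An [annotated_tree].
#' @export
parse_annotated_nexus <- function(text, tree_index = 1L) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  stopifnot(is.character(text), length(text) == 1L)
  if (grepl("^\\s*#NEXUS", text, ignore.case = TRUE)) {
    parsed <- .nexus_extract_trees(text)
    if (tree_index > length(parsed$trees))
      stop("tree_index ", tree_index, " out of range: file has ",
           length(parsed$trees), " tree(s)")
    newick <- parsed$trees[[tree_index]]
    translate <- parsed$translate
  } else {
    newick <- text
    translate <- NULL
  }
  .parse_newick_annotated(newick, translate = translate)
}

# Extracts tree strings and the translate table from a NEXUS TREES block.
.nexus_extract_trees <- function(text) {
  # strip newlines for token scanning but keep content
  block <- regmatches(text, regexpr("(?is)begin\\s+trees\\s*;.*?end\\s*;",
                                    text, perl = TRUE))
  if (length(block) == 0L) stop("no TREES block found in NEXUS input")
  block <- block[[1L]]
  translate <- NULL
  tr <- regmatches(block, regexpr("(?is)translate\\s.*?;", block, perl = TRUE))
  if (length(tr) == 1L) {
    body <- sub("(?is)^translate\\s", "", sub(";$", "", tr[[1L]]), perl = TRUE)
    entries <- strsplit(body, ",")[[1L]]
    entries <- trimws(entries)
    entries <- entries[nzchar(entries)]
    keys <- sub("^(\\S+)\\s+.*$", "\\1", entries)
    vals <- sub("^\\S+\\s+", "", entries)
    vals <- gsub("^'|'$", "", vals)
    translate <- stats::setNames(vals, keys)
  }
  # tree statements: `tree NAME = [&R] (...);` — take text between '=' and ';'
  stmts <- regmatches(block,
                      gregexpr("(?is)\\btree\\s+[^=]+=[^;]+;", block, perl = TRUE))[[1L]]
  if (length(stmts) == 0L) stop("TREES block contains no tree statements")
  trees <- vapply(stmts, function(s) {
    s <- sub("(?is)^\\s*tree\\s+[^=]+=\\s*", "", s, perl = TRUE)
    # drop a leading rooting comment like [&R]
    s <- sub("^\\s*\\[&[RU]\\]\\s*", "", s)
    s
  }, character(1), USE.NAMES = FALSE)
  list(trees = trees, translate = translate)
}

# Recursive-descent parser for newick with metadata comments.
.parse_newick_annotated <- function(newick, translate = NULL) {
  chars <- strsplit(newick, "", fixed = TRUE)[[1L]]
  env <- new.env(parent = emptyenv())
  env$chars <- chars
  env$i <- 1L
  env$n <- length(chars)

  peek <- function() if (env$i <= env$n) env$chars[env$i] else ""
  advance <- function() env$i <- env$i + 1L
  skip_ws <- function() {
    while (env$i <= env$n && grepl("^\\s$", env$chars[env$i])) advance()
  }
  read_comments <- function() {
    out <- character(0)
    repeat {
      skip_ws()
      if (peek() != "[") return(out)
      advance()
      start <- env$i
      while (env$i <= env$n && env$chars[env$i] != "]") advance()
      if (env$i > env$n) stop("unbalanced '[' in metadata comment")
      out <- c(out, paste(env$chars[start:(env$i - 1L)], collapse = ""))
      advance()
    }
  }
  read_label <- function() {
    skip_ws()
    if (peek() == "'") {
      advance()
      start <- env$i
      while (env$i <= env$n && env$chars[env$i] != "'") advance()
      if (env$i > env$n) stop("unterminated quoted label")
      lab <- paste(env$chars[start:(env$i - 1L)], collapse = "")
      advance()
      return(lab)
    }
    start <- env$i
    while (env$i <= env$n &&
           !grepl("^[\\s(),:;\\[\\]]$", env$chars[env$i], perl = TRUE))
      advance()
    if (env$i == start) return("")
    paste(chars[start:(env$i - 1L)], collapse = "")
  }
  read_number <- function() {
    skip_ws()
    start <- env$i
    while (env$i <= env$n &&
           grepl("^[0-9eE+.\\-]$", env$chars[env$i], perl = TRUE))
      advance()
    if (env$i == start) stop("expected a branch length at position ", env$i)
    as.numeric(paste(chars[start:(env$i - 1L)], collapse = ""))
  }

  parse_node <- function() {
    skip_ws()
    node <- list(children = list(), label = "", length = NA_real_,
                 comments = character(0))
    if (peek() == "(") {
      advance()
      node$children <- list(parse_node())
      skip_ws()
      while (peek() == ",") {
        advance()
        node$children <- c(node$children, list(parse_node()))
        skip_ws()
      }
      if (peek() != ")") stop("unbalanced parentheses in newick string")
      advance()
      node$label <- read_label()
    } else {
      node$label <- read_label()
      if (!nzchar(node$label)) stop("expected a taxon label at position ", env$i)
    }
    node$comments <- c(node$comments, read_comments())
    skip_ws()
    if (peek() == ":") {
      advance()
      node$comments <- c(node$comments, read_comments())
      node$length <- read_number()
      node$comments <- c(node$comments, read_comments())
    }
    node
  }

  root <- parse_node()
  skip_ws()
  if (peek() != ";")
    stop("newick string must end with ';' (found '", peek(), "')")

  # flatten to phylo, numbering tips left-to-right and internals in preorder
  n_tips <- local({
    count <- function(nd) {
      if (length(nd$children) == 0L) 1L
      else sum(vapply(nd$children, count, integer(1)))
    }
    count(root)
  })
  if (n_tips < 2L) stop("tree must have at least two tips")
  state <- new.env(parent = emptyenv())
  state$tipc <- 0L
  state$intc <- 0L
  state$edges <- list()
  state$edge_len <- numeric(0)
  state$tip_label <- character(n_tips)
  state$node_label <- character(0)
  state$annot <- list()

  walk <- function(nd) {
    if (length(nd$children) == 0L) {
      state$tipc <- state$tipc + 1L
      num <- state$tipc
      state$tip_label[num] <- nd$label
    } else {
      state$intc <- state$intc + 1L
      num <- n_tips + state$intc
      state$node_label[state$intc] <- nd$label
    }
    state$annot[[num]] <- .parse_metadata(nd$comments)
    for (ch in nd$children) {
      # reserve the edge slot before recursing so edges come out cladewise
      # (parent edge precedes its child's subtree edges)
      ei <- length(state$edges) + 1L
      state$edges[[ei]] <- c(num, NA_integer_)
      state$edge_len[ei] <- if (is.na(ch$length)) 0 else ch$length
      state$edges[[ei]][2L] <- walk(ch)
    }
    num
  }
  walk(root)

  edge_mat <- do.call(rbind, state$edges)
  storage.mode(edge_mat) <- "integer"
  phy <- structure(list(
    edge = edge_mat,
    edge.length = state$edge_len,
    tip.label = unname(state$tip_label),
    Nnode = state$intc,
    node.label = state$node_label
  ), class = "phylo", order = "cladewise")
  if (!is.null(translate)) {
    miss <- setdiff(phy$tip.label, names(translate))
    if (length(miss) > 0L)
      stop("taxa missing from TRANSLATE table: ", paste(miss, collapse = ", "))
    phy$tip.label <- unname(translate[phy$tip.label])
  }
  if (all(!nzchar(phy$node.label))) phy$node.label <- NULL

  n_node <- n_tips + state$intc
  nd <- data.frame(node = seq_len(n_node))
  nd$rate_median <- NA_real_
  nd$posterior <- NA_real_
  nd$branch_rate <- NA_real_
  nd$height <- NA_real_
  nd$extra <- rep(list(NULL), n_node)
  for (v in seq_len(n_node)) {
    ann <- state$annot[[v]]
    if (is.null(ann) || length(ann) == 0L) next
    keys <- names(ann)
    for (k in keys) {
      val <- ann[[k]]
      if (k %in% c("rate_median", "rate")) {
        nd$rate_median[v] <- suppressWarnings(as.numeric(val))
      } else if (k == "posterior") {
        nd$posterior[v] <- suppressWarnings(as.numeric(val))
      } else if (k == "branch_rate") {
        nd$branch_rate[v] <- suppressWarnings(as.numeric(val))
      } else if (k == "height") {
        nd$height[v] <- suppressWarnings(as.numeric(val))
        nd$extra[[v]] <- c(nd$extra[[v]], stats::setNames(val, k))
      } else {
        nd$extra[[v]] <- c(nd$extra[[v]], stats::setNames(val, k))
      }
    }
  }
  annotated_tree(phy, node_data = nd)
}

# Splits "&key=val,key={a,b},..." into a named character vector of raw values;
# commas inside braces or quotes do not split.
.parse_metadata <- function(comments) {
  out <- character(0)
  for (com in comments) {
    s <- sub("^\\s*&", "", com)
    if (!nzchar(s)) next
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    depth <- 0L
    in_quote <- FALSE
    field_start <- 1L
    fields <- character(0)
    for (i in seq_along(chars)) {
      ch <- chars[i]
      if (ch == '"') in_quote <- !in_quote
      else if (!in_quote && ch == "{") depth <- depth + 1L
      else if (!in_quote && ch == "}") depth <- depth - 1L
      else if (!in_quote && depth == 0L && ch == ",") {
        fields <- c(fields, paste(chars[field_start:(i - 1L)], collapse = ""))
        field_start <- i + 1L
      }
    }
    if (field_start <= length(chars))
      fields <- c(fields, paste(chars[field_start:length(chars)], collapse = ""))
    for (f in fields) {
      eq <- regexpr("=", f, fixed = TRUE)
      if (eq < 0) next
      key <- trimws(substr(f, 1L, eq - 1L))
      val <- trimws(substr(f, eq + 1L, nchar(f)))
      out[key] <- val
    }
  }
  as.list(out)
}

## ---------------------------------------------------------------------------
## Writing
## ---------------------------------------------------------------------------

# 17 significant digits: doubles survive a write/parse cycle exactly
.fmt_num <- function(x) sprintf("%.17g", x)

#' Write an annotated tree as NEXUS
#'
#' Serializes an [annotated_tree] to a NEXUS file in the metadata-comment
#' dialect read by [parse_annotated_nexus()] (and by FigTree). Output is
#' deterministic — fixed node ordering, annotation keys sorted, numbers at
#' 10 significant digits — so write/parse/write is idempotent.
#'
#' @param tree An [annotated_tree].
#' @param path Output path; if `NULL`, the lines are returned invisibly
#'   without writing.
#' @return Invisibly, the character vector of file lines.
#' @export
write_annotated_nexus <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "annotated_tree"))
  phy <- tree$phy
  nd <- tree$node_data
  n <- ape::Ntip(phy)

  children_of <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])

  node_comment <- function(v) {
    ann <- character(0)
    if (!is.na(nd$posterior[v])) ann["posterior"] <- .fmt_num(nd$posterior[v])
    if (!is.na(nd$rate_median[v])) ann["rate_median"] <- .fmt_num(nd$rate_median[v])
    if (!is.na(nd$branch_rate[v])) ann["branch_rate"] <- .fmt_num(nd$branch_rate[v])
    ex <- nd$extra[[v]]
    if (!is.null(ex) && length(ex) > 0L)
      ann[names(ex)] <- unlist(ex)
    if (length(ann) == 0L) return("")
    ann <- ann[order(names(ann), method = "radix")]
    paste0("[&", paste(names(ann), unlist(ann), sep = "=", collapse = ","), "]")
  }

  build <- function(v, edge_idx) {
    if (v <= n) {
      core <- as.character(v)  # translate-table key
    } else {
      kids <- children_of[[as.character(v)]]
      core <- paste0("(", paste(vapply(kids, function(ei)
        build(phy$edge[ei, 2L], ei), character(1)), collapse = ","), ")")
    }
    s <- paste0(core, node_comment(v))
    if (!is.na(edge_idx))
      s <- paste0(s, ":", .fmt_num(phy$edge.length[edge_idx]))
    s
  }
  newick <- paste0(build(n + 1L, NA_integer_), ";")

  quote_taxon <- function(x)
    ifelse(grepl("[\\s(),:;\\[\\]']", x, perl = TRUE),
           paste0("'", x, "'"), x)
  translate <- paste0("\t\t", seq_len(n), " ", quote_taxon(phy$tip.label),
                      c(rep(",", n - 1L), ""))
  lines <- c(
    "#NEXUS",
    "Begin trees;",
    "\tTranslate",
    translate,
    "\t\t;",
    paste0("tree TREE1 = [&R] ", newick),
    "End;"
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Per-node table of ages, rates, and posteriors
#'
#' Flattens an annotated tree into one record per node: the node label, its
#' age in Ma, the rate median in substitutions/site/Myr, and the posterior
#' probability. Internal nodes only by default; rows are sorted by age
#' descending with ties broken by node label.
#'
#' @param tree An [annotated_tree].
#' @param include_tips Also emit leaf rows (age 0).
#' @return A data frame with columns `node_id`, `age_ma`, `rate_median`,
#'   `posterior`, `is_leaf`.
#' @export
node_table <- function(tree, include_tips = FALSE) {
  stopifnot(inherits(tree, "annotated_tree"))
  nd <- tree$node_data
  n <- ape::Ntip(tree$phy)
  is_leaf <- nd$node <= n
  keep <- if (include_tips) rep(TRUE, nrow(nd)) else !is_leaf
  out <- data.frame(node_id = nd$label[keep],
                    age_ma = nd$age_ma[keep],
                    rate_median = nd$rate_median[keep],
                    posterior = nd$posterior[keep],
                    is_leaf = is_leaf[keep],
                    stringsAsFactors = FALSE)
  ord <- order(-out$age_ma, out$node_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a node table as TSV
#'
#' @param tab A data frame from [node_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_node_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
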