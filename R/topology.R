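# Residue tokens accepted on topology nodes and the composition class each
# one collapses to. MS1 cannot distinguish hexose identities, so Gal/Man/Glc
# all count as hex; identity is only meaningful to motif matching and
# exoglycosidase rules.
NODE_CLASS <- c(Gal = "hex", Man = "hex", Glc = "hex", Hex = "hex",
                GlcNAc = "hexnac", GalNAc = "hexnac", HexNAc = "hexnac",
                Fuc = "dhex", dHex = "dhex",
                NeuAc = "neuac", NeuGc = "neugc", KDN = "kdn")

#' Glycan topology
#'
#' A rooted tree of monosaccharide residues. The root is the reducing-end
#' residue (HexNAc for N-glycans); every other node carries the anomeric
#' configuration (`"a"`, `"b"` or `"?"`) of the bond to its parent.
#' Topologies are written and parsed in an IUPAC-condensed-style linear
#' code, non-reducing end first, with branches in square brackets:
#'
#' ```
#' NeuAc(a-)Gal(b-)GlcNAc(b-)Man(a-)[Man(a-)]Man(b-)GlcNAc(b-)GlcNAc
#' Gal(a-)[Gal(b-)]Gal(b-)GlcNAc
#' ```
#'
#' Linkage positions may be given (`(a2-3)`) but are optional and ignored
#' by matching; the package reasons over anomericity only.
#'
#' @param s a topology string.
#' @return an object of class `glycan_topology`: a data.frame with columns
#'   `id`, `parent` (NA for the root), `residue`, `anomer`.
#' @examples
#' t <- parse_glycan("Gal(a-)[Gal(b-)]Gal(b-)GlcNAc")
#' composition_of(t)
#' format(t)
#' @export
parse_glycan <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  s <- gsub("\\s", "", s)
  if (!nzchar(s)) stop("empty topology string")
  nodes <- new.env(parent = emptyenv())
  nodes$df <- data.frame(id = integer(), parent = integer(),
                         residue = character(), anomer = character(),
                         stringsAsFactors = FALSE)
  add_node <- function(residue, anomer) {
    id <- nrow(nodes$df) + 1L
    nodes$df[id, ] <- list(id, NA_integer_, residue, anomer)
    id
  }
  # split a chain at top bracket level into tokens: "[...]" or "Res(link)?"
  tokenize <- function(x) {
    toks <- character(); depth <- 0L; start <- 1L; i <- 1L
    n <- nchar(x)
    while (i <= n) {
      ch <- substr(x, i, i)
      if (ch == "[") {
        if (depth == 0L && i > start)
          stop("malformed topology near position ", i, " in: ", x)
        if (depth == 0L) start <- i
        depth <- depth + 1L
      } else if (ch == "]") {
        depth <- depth - 1L
        if (depth < 0L) stop("unbalanced ']' in topology: ", x)
        if (depth == 0L) { toks <- c(toks, substr(x, start, i)); start <- i + 1L }
      } else if (depth == 0L && ch == ")") {
        toks <- c(toks, substr(x, start, i)); start <- i + 1L
      }
      i <- i + 1L
    }
    if (depth != 0L) stop("unbalanced '[' in topology: ", x)
    if (start <= n) toks <- c(toks, substr(x, start, n))
    toks[nzchar(toks)]
  }
  # parse a chain; returns id of its reducing-most node. `anchor`: ids of
  # pending branch roots waiting to attach to the next residue.
  parse_chain <- function(x) {
    toks <- tokenize(x)
    left <- NA_integer_   # subtree already read (non-reducing side)
    pending <- integer()
    for (t in toks) {
      if (startsWith(t, "[")) {
        pending <- c(pending, parse_chain(substr(t, 2, nchar(t) - 1L)))
      } else {
        m <- regmatches(t, regexec(
          "^([A-Za-z]+)(\\(([ab?])([0-9?]*)-([0-9?]*)\\))?$", t))[[1]]
        if (!length(m)) stop("cannot parse residue token: ", t)
        residue <- m[2]
        if (!residue %in% names(NODE_CLASS))
          stop("unknown residue kind '", residue, "' in topology: ", s)
        anomer <- if (nzchar(m[3])) m[4] else "?"
        id <- add_node(residue, anomer)
        for (child in c(if (!is.na(left)) left, pending))
          nodes$df$parent[child] <- id
        left <- id; pending <- integer()
      }
    }
    if (length(pending)) stop("branch with no parent residue in: ", x)
    if (is.na(left)) stop("empty chain in topology: ", x)
    left
  }
  root <- parse_chain(s)
  df <- nodes$df
  df$anomer[df$id == root] <- "?"   # root has no bond to a parent
  structure(df, class = c("glycan_topology", "data.frame"), root = root)
}

topo_root <- function(topo) attr(topo, "root")

topo_children <- function(topo, id) topo$id[!is.na(topo$parent) & topo$parent == id]

topo_leaves <- function(topo) setdiff(topo$id, topo$parent[!is.na(topo$parent)])

#' @rdname parse_glycan
#' @param x a `glycan_topology`.
#' @param ... unused.
#' @export
format.glycan_topology <- function(x, ...) {
  ser <- function(id, edge) {
    kids <- topo_children(x, id)
    link <- if (is.na(edge)) "" else paste0("(", x$anomer[x$id == id], "-)")
    if (!length(kids)) return(paste0(x$residue[x$id == id], link))
    inline <- ser(kids[1], id)
    branches <- vapply(kids[-1], function(k) paste0("[", ser(k, id), "]"), "")
    paste0(inline, paste(branches, collapse = ""),
           x$residue[x$id == id], link)
  }
  ser(topo_root(x), NA)
}

#' @export
print.glycan_topology <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Collapse a topology to its monosaccharide composition
#'
#' Node identities are erased to the residue classes observable at MS1:
#' Gal/Man/Glc map to hex, GlcNAc/GalNAc to hexnac, Fuc to dhex.
#'
#' @param topology a `glycan_topology`.
#' @return a [glycan_composition()].
#' @export
composition_of <- function(topology) {
  stopifnot(inherits(topology, "glycan_topology"))
  unknown <- setdiff(topology$residue, names(NODE_CLASS))
  if (length(unknown))
    stop("unknown residue kind on node: ", paste(unknown, collapse = ", "))
  cls <- NODE_CLASS[topology$residue]
  counts <- table(factor(cls, levels = COMP_KINDS))
  do.call(glycan_composition, as.list(as.integer(counts)) |>
            stats::setNames(COMP_KINDS))
}

# subtree rooted at `id`, as a new glycan_topology
topo_subtree <- function(topo, id) {
  keep <- id
  frontier <- id
  while (length(frontier)) {
    kids <- topo$id[!is.na(topo$parent) & topo$parent %in% frontier]
    keep <- c(keep, kids)
    frontier <- kids
  }
  df <- topo[topo$id %in% keep, , drop = FALSE]
  df$parent[df$id == id] <- NA_integer_
  # reindex ids 1..n preserving order
  map <- stats::setNames(seq_len(nrow(df)), df$id)
  newdf <- data.frame(id = unname(map[as.character(df$id)]),
                      parent = ifelse(is.na(df$parent), NA_integer_,
                                      unname(map[as.character(df$parent)])),
                      residue = df$residue, anomer = df$anomer,
                      stringsAsFactors = FALSE)
  newdf$anomer[is.na(newdf$parent)] <- "?"
  structure(newdf, class = c("glycan_topology", "data.frame"),
            root = unname(map[as.character(id)]))
}

# remove a set of node ids (must be leaves or whole subtrees) from topology
topo_drop <- function(topo, ids) {
  df <- topo[!(topo$id %in% ids), , drop = FALSE]
  if (!nrow(df)) stop("cannot remove every node of a topology")
  map <- stats::setNames(seq_len(nrow(df)), df$id)
  newdf <- data.frame(id = unname(map[as.character(df$id)]),
                      parent = ifelse(is.na(df$parent), NA_integer_,
                                      unname(map[as.character(df$parent)])),
                      residue = df$residue, anomer = df$anomer,
                      stringsAsFactors = FALSE)
  structure(newdf, class = c("glycan_topology", "data.frame"),
            root = unname(map[as.character(topo_root(topo))]))
}
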