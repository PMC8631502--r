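#' Terminal epitope motifs
#'
#' A motif is a small topology pattern matched against the terminal
#' (non-reducing) region of a glycan. Matching rules:
#'
#' * residues match by class, with generic tokens (`Hex`, `HexNAc`, `dHex`)
#'   acting as wildcards within their class;
#' * a pattern anomer of `"?"` matches any configuration, a specified
#'   anomer must match exactly;
#' * pattern leaves must land on topology leaves (the occurrence is
#'   terminal) and the children of every matched pattern node must
#'   correspond one-to-one to the children of the matched topology node,
#'   so a sialylated branch cannot satisfy an unsialylated pattern;
#' * motifs flagged `root_extendable` relax the one-to-one rule at the
#'   pattern root (used for core fucose, whose anchor residue carries the
#'   rest of the glycan); motifs flagged `anchor_root` must match at the
#'   reducing-end residue of the whole glycan.
#'
#' @param name motif name.
#' @param pattern topology string or `glycan_topology`.
#' @param anchor_root must the match sit on the glycan's reducing end?
#' @param root_extendable may the matched root carry extra substituents?
#' @return an object of class `epitope_motif`.
#' @export
epitope_motif <- function(name, pattern, anchor_root = FALSE,
                          root_extendable = FALSE) {
  if (is.character(pattern)) pattern <- parse_glycan(pattern)
  stopifnot(inherits(pattern, "glycan_topology"))
  structure(list(name = name, pattern = pattern, anchor_root = anchor_root,
                 root_extendable = root_extendable),
            class = "epitope_motif")
}

#' @export
print.epitope_motif <- function(x, ...) {
  cat("<epitope_motif>", x$name, ":", format(x$pattern), "\n")
  invisible(x)
}

#' Built-in motif library
#'
#' The species-signature motifs of teleost and chondrostrean fish serum
#' N-glycans:
#'
#' * `disa` -- the NeuAc-NeuAc di-sialic-acid cap;
#' * `salmonid_cap` -- a singly sialylated terminal galactose (NeuAc-Gal);
#' * `sturgeon_cap` -- the Gala(Galb)Galb-HexNAc tetrasaccharide;
#' * `catfish_cap` -- NeuAc branched on the inner Gal of
#'   GalbGalb-HexNAc;
#' * `gg_cap` -- the nonsialylated GalbGalb-HexNAc trisaccharide;
#' * `core_fucose` -- fucose on the reducing-end HexNAc.
#'
#' @return named list of [epitope_motif()] objects.
#' @export
motif_library <- function() {
  list(
    disa         = epitope_motif("disa", "NeuAc(?-)NeuAc"),
    salmonid_cap = epitope_motif("salmonid_cap", "NeuAc(?-)Gal"),
    sturgeon_cap = epitope_motif("sturgeon_cap",
                                 "Gal(a-)[Gal(b-)]Gal(b-)HexNAc"),
    catfish_cap  = epitope_motif("catfish_cap",
                                 "NeuAc(?-)[Gal(b-)]Gal(b-)HexNAc"),
    gg_cap       = epitope_motif("gg_cap", "Gal(b-)Gal(b-)HexNAc"),
    core_fucose  = epitope_motif("core_fucose", "Fuc(?-)HexNAc",
                                 anchor_root = TRUE, root_extendable = TRUE)
  )
}

# does pattern residue p match topology residue t?
.res_match <- function(p, t) {
  if (NODE_CLASS[[p]] != NODE_CLASS[[t]]) return(FALSE)
  p == t || p %in% c("Hex", "HexNAc", "dHex") || t %in% c("Hex", "HexNAc", "dHex")
}

.anomer_match <- function(p, t) p == "?" || p == t

# try to match pattern subtree (pid) at topology node (tid)
.match_at <- function(pat, pid, topo, tid, extendable) {
  if (!.res_match(pat$residue[pat$id == pid], topo$residue[topo$id == tid]))
    return(FALSE)
  pkids <- topo_children(pat, pid)
  tkids <- topo_children(topo, tid)
  if (!length(pkids)) return(length(tkids) == 0L)  # pattern leaf -> topo leaf
  if (!extendable && length(tkids) != length(pkids)) return(FALSE)
  if (length(tkids) < length(pkids)) return(FALSE)
  # injective assignment of pattern children onto topology children
  assign_kids <- function(pk, avail) {
    if (!length(pk)) return(TRUE)
    for (tk in avail) {
      if (.anomer_match(pat$anomer[pat$id == pk[1]],
                        topo$anomer[topo$id == tk]) &&
          .match_at(pat, pk[1], topo, tk, FALSE)) {
        if (assign_kids(pk[-1], setdiff(avail, tk))) return(TRUE)
      }
    }
    FALSE
  }
  assign_kids(pkids, tkids)
}

#' Find terminal occurrences of a motif in a topology
#'
#' @param topology a `glycan_topology`.
#' @param motif an [epitope_motif()], or a name from [motif_library()].
#' @return integer vector of topology node ids at which the motif root
#'   matches (empty when the motif is absent).
#' @examples
#' t <- parse_glycan("Gal(a-)[Gal(b-)]Gal(b-)GlcNAc")
#' match_motif(t, "sturgeon_cap")
#' match_motif(t, "disa")
#' @export
match_motif <- function(topology, motif) {
  stopifnot(inherits(topology, "glycan_topology"))
  if (is.character(motif)) {
    lib <- motif_library()
    if (!motif %in% names(lib)) stop("unknown motif name: ", motif)
    motif <- lib[[motif]]
  }
  stopifnot(inherits(motif, "epitope_motif"))
  candidates <- if (motif$anchor_root) topo_root(topology) else topology$id
  hits <- candidates[vapply(candidates, function(tid)
    .match_at(motif$pattern, topo_root(motif$pattern), topology, tid,
              motif$root_extendable), logical(1))]
  as.integer(hits)
}
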