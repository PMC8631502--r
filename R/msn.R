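#' Predict MSn fragments of a topology
#'
#' Generates singly charged sodiated B-type ions for every terminal
#' subtree (one glycosidic cleavage, fully methylated fragment) and their
#' sequential neutral-loss products (each further terminal-residue loss
#' adds one unmethylated scar, -14.01565 Da relative to the intact
#' B-ion). The input topology itself is treated as a B-type precursor --
#' the situation in MS3/MS4 of an isolated signature ion -- so its own
#' sequential-loss products are predicted too (the intact precursor is
#' not). These ion families carry all the topology information used to
#' discriminate branched from linear epitopes at ion-trap resolution;
#' Y-type and cross-ring ions are not predicted.
#'
#' @param topology a `glycan_topology` (at most 30 residues).
#' @param max_losses cap on sequential neutral losses per B-ion
#'   (default Inf = enumerate all).
#' @return data.frame `mz`, `composition`, `scars`, `losses`, unique by
#'   (composition, scars), sorted by m/z. A single-residue topology
#'   yields zero rows (no glycosidic bond to cleave).
#' @examples
#' epi <- parse_glycan("NeuAc(a-)[Gal(b-)]Gal(b-)GlcNAc")
#' predict_fragments(epi)  # contains 1051.50 (B) and 676.32 (NeuAc loss)
#' @export
predict_fragments <- function(topology, max_losses = Inf) {
  stopifnot(inherits(topology, "glycan_topology"))
  if (nrow(topology) > 30)
    stop("fragment prediction is limited to topologies of <= 30 residues")
  seen <- new.env(parent = emptyenv())
  out <- list()
  emit <- function(comp, scars, losses) {
    key <- paste(format(comp), scars)
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    out[[length(out) + 1]] <<- data.frame(
      mz = b_fragment_mz(comp, n_scars = scars),
      composition = format(comp), scars = scars, losses = losses,
      stringsAsFactors = FALSE)
  }
  walk_losses <- function(sub, scars, losses, emit_self = TRUE) {
    if (emit_self) emit(composition_of(sub), scars, losses)
    if (losses >= max_losses || nrow(sub) <= 1) return(invisible())
    for (leaf in setdiff(topo_leaves(sub), topo_root(sub)))
      walk_losses(topo_drop(sub, leaf), scars + 1L, losses + 1L)
  }
  # B-ions of every proper subtree, plus their sequential losses
  for (id in setdiff(topology$id, topo_root(topology)))
    walk_losses(topo_subtree(topology, id), 0L, 0L)
  # a multi-residue topology is itself a B-type ion (released from its
  # carrier by one cleavage, as when MSn isolates a signature ion), so it
  # and its sequential-loss products are predicted; a single residue has
  # no glycosidic bond and yields nothing
  walk_losses(topology, 0L, 0L, emit_self = nrow(topology) > 1)
  if (!length(out))
    return(data.frame(mz = numeric(), composition = character(),
                      scars = integer(), losses = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$mz), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Score candidate topologies against an observed fragment list
#'
#' For each candidate, predicted fragments within `tolerance` of an
#' observed m/z count as matched; the score is the number of matched
#' predictions minus `penalty` times the number of observed peaks no
#' prediction explains. Ranking is deterministic: score (descending),
#' then fewer predicted fragments (parsimony), then input order. The
#' discriminating fragments between the top two candidates are reported.
#'
#' @param candidates named list of `glycan_topology` objects (or topology
#'   strings).
#' @param observed_mz numeric vector of observed fragment m/z.
#' @param tolerance match tolerance in m/z (default 0.3, nominal-mass
#'   ion-trap fragments).
#' @param penalty weight of unexplained observed peaks (default 0.5).
#' @param max_losses passed to [predict_fragments()].
#' @return data.frame `candidate`, `score`, `matched`, `unexplained`,
#'   `n_predicted`, best first; attribute `"discriminating"` holds the
#'   m/z predicted by the winner but not the runner-up (and vice versa);
#'   attribute `"all_zero"` flags an unranked all-zero-score result.
#' @export
score_topologies <- function(candidates, observed_mz, tolerance = 0.3,
                             penalty = 0.5, max_losses = Inf) {
  stopifnot(length(candidates) >= 1)
  if (is.null(names(candidates)))
    names(candidates) <- paste0("candidate", seq_along(candidates))
  preds <- lapply(candidates, function(cand) {
    if (is.character(cand)) cand <- parse_glycan(cand)
    predict_fragments(cand, max_losses = max_losses)$mz
  })
  rows <- lapply(names(preds), function(nm) {
    p <- preds[[nm]]
    matched <- sum(vapply(p, function(m) any(abs(observed_mz - m) <= tolerance),
                          logical(1)))
    explained <- vapply(observed_mz, function(o)
      any(abs(p - o) <= tolerance), logical(1))
    data.frame(candidate = nm, score = matched - penalty * sum(!explained),
               matched = matched, unexplained = sum(!explained),
               n_predicted = length(p), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  all_zero <- all(res$score <= 0)
  if (!all_zero)
    res <- res[order(-res$score, res$n_predicted,
                     seq_len(nrow(res))), , drop = FALSE]
  rownames(res) <- NULL
  disc <- NULL
  if (nrow(res) >= 2) {
    a <- preds[[res$candidate[1]]]; b <- preds[[res$candidate[2]]]
    only_a <- a[vapply(a, function(m) all(abs(b - m) > tolerance), logical(1))]
    only_b <- b[vapply(b, function(m) all(abs(a - m) > tolerance), logical(1))]
    disc <- list(top_only = only_a, runner_up_only = only_b)
  }
  structure(res, discriminating = disc, all_zero = all_zero)
}

#' Count di-sialic-acid (NeuAc-NeuAc) units from a composition
#'
#' For complex-type N-glycans the antenna count is estimated as
#' `hexnac - 2` (two core GlcNAc); any sialic acids beyond one per
#' antenna must pair up as NeuAc-NeuAc caps, so the di-SA unit count is
#' `max(0, neuac - antennae)`. Topology-level counts (via
#' [match_motif()]) override this heuristic when a topology is known.
#'
#' @param comp a composition (object or string).
#' @return integer di-SA count, or `NA` with attribute `reason` for
#'   high-mannose/hybrid compositions (hexnac < 4), where the antenna
#'   heuristic does not apply.
#' @examples
#' detect_disa("NeuAc3Hex5HexNAc4")  # 1
#' @export
detect_disa <- function(comp) {
  comp <- as_composition(comp)
  if (comp[["hexnac"]] < 4)
    return(structure(NA_integer_,
                     reason = "not applicable: high-mannose or hybrid composition"))
  antennae <- comp[["hexnac"]] - 2L
  as.integer(max(0L, comp[["neuac"]] - antennae))
}

#' Read / write MGF fragment lists
#'
#' Minimal MGF (Mascot generic format) support for direct-infusion MSn
#' fragment lists: `BEGIN IONS` blocks with `TITLE`, `PEPMASS`, `CHARGE`
#' headers and `m/z intensity` rows. Stage and precursor metadata are
#' carried in the TITLE field as `stage=MSn`.
#'
#' @param path MGF file.
#' @return list of spectra, each a list with `title`, `stage`, `pepmass`,
#'   `charge`, `fragments` (data.frame `mz`, `intensity`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list(); cur <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (ln == "BEGIN IONS") {
      cur <- list(title = "", stage = NA_integer_, pepmass = NA_real_,
                  charge = NA_integer_, fragments = list())
    } else if (ln == "END IONS") {
      if (is.null(cur)) stop("MGF parse error at line ", i, ": stray END IONS")
      fr <- if (length(cur$fragments)) do.call(rbind, cur$fragments) else
        data.frame(mz = numeric(), intensity = numeric())
      cur$fragments <- fr
      spectra[[length(spectra) + 1]] <- cur
      cur <- NULL
    } else if (is.null(cur)) {
      next  # header comments outside blocks
    } else if (grepl("^TITLE=", ln)) {
      cur$title <- sub("^TITLE=", "", ln)
      m <- regmatches(ln, regexec("stage=MS([0-9]+)", ln))[[1]]
      if (length(m)) cur$stage <- as.integer(m[2])
    } else if (grepl("^PEPMASS=", ln)) {
      cur$pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), " ")[[1]][1])
    } else if (grepl("^CHARGE=", ln)) {
      cur$charge <- as.integer(gsub("[^0-9]", "", ln))
    } else if (grepl("^[0-9]", ln)) {
      xs <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
      if (length(xs) < 1 || anyNA(xs))
        stop("MGF parse error at line ", i, ": ", lines[i])
      cur$fragments[[length(cur$fragments) + 1]] <-
        data.frame(mz = xs[1], intensity = if (length(xs) > 1) xs[2] else 1)
    }
  }
  if (!is.null(cur)) stop("MGF ends inside an unterminated IONS block")
  spectra
}

#' @rdname read_mgf
#' @param spectra list of spectra as returned by [read_mgf()] or built by
#'   [generate_msn()].
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    title <- sp$title
    if (!is.na(sp$stage) && !grepl("stage=", title))
      title <- paste0(title, " stage=MS", sp$stage)
    writeLines(paste0("TITLE=", title), con)
    if (!is.na(sp$pepmass)) writeLines(paste0("PEPMASS=", sp$pepmass), con)
    if (!is.na(sp$charge)) writeLines(paste0("CHARGE=", sp$charge, "+"), con)
    if (nrow(sp$fragments))
      writeLines(sprintf("%.5f %.3f", sp$fragments$mz,
                         sp$fragments$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}
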