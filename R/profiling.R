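#' Structural-feature prevalence of a glycan profile
#'
#' Expresses the major structural features as a percent of the total
#' profile:
#'
#' * `disa_pct` -- abundance carrying at least one NeuAc-NeuAc unit
#'   ([detect_disa()] heuristic; topology annotations override when
#'   present);
#' * `core_fucose_pct` -- abundance with `dhex >= 1` (attributed to the
#'   chitobiose core; antenna fucose is indistinguishable at MS1 and this
#'   caveat is carried in the output);
#' * `high_mannose_pct` -- abundance with `hexnac == 2`;
#' * `sialylated_pct` -- abundance with any sialic acid (NeuAc, and by
#'   default also NeuGc/KDN, configurable);
#' * a sialylation-degree histogram `sia0_pct`, `sia1_pct`, ...;
#' * an O-acetyl-count histogram (native mode only; `NA` otherwise).
#'
#' @param profile a `glycan_profile`.
#' @param count_neugc_kdn count NeuGc/KDN as sialylation? (default TRUE)
#' @return data.frame `feature`, `value` (percent of total profile, or NA
#'   for not-applicable features).
#' @export
feature_prevalence <- function(profile, count_neugc_kdn = TRUE) {
  stopifnot(inherits(profile, "glycan_profile"))
  tab <- profile$table
  empty <- !nrow(tab)
  comps <- if (empty) list() else lapply(tab$composition, as_composition)
  ab <- if (empty) numeric() else tab$rel_abundance
  pct <- function(flag) if (empty) 0 else sum(ab[flag])
  sia <- vapply(comps, function(c)
    c[["neuac"]] + if (count_neugc_kdn) c[["neugc"]] + c[["kdn"]] else 0L,
    numeric(1))
  disa <- vapply(comps, function(c) {
    d <- detect_disa(c)
    !is.na(d) && d > 0
  }, logical(1))
  rows <- data.frame(
    feature = c("disa_pct", "core_fucose_pct", "high_mannose_pct",
                "sialylated_pct"),
    value = c(pct(disa),
              pct(vapply(comps, function(c) c[["dhex"]] >= 1, logical(1))),
              pct(vapply(comps, function(c) c[["hexnac"]] == 2, logical(1))),
              pct(sia > 0)))
  max_sia <- if (empty) 0 else max(sia)
  for (s in 0:max(4, max_sia))
    rows[nrow(rows) + 1, ] <- list(sprintf("sia%d_pct", s), pct(sia == s))
  if (identical(profile$mode, "native")) {
    oac <- vapply(comps, function(c) c[["oacetyl"]], numeric(1))
    for (n in 0:max(0, if (empty) 0 else max(oac)))
      rows[nrow(rows) + 1, ] <- list(sprintf("oacetyl%d_pct", n), pct(oac == n))
  } else {
    rows[nrow(rows) + 1, ] <- list("oacetyl0_pct", NA_real_)
  }
  rows
}

#' O-acetylation ladder of a native-mode profile
#'
#' Groups native-mode assignments that differ only in O-acetyl count into
#' a +n x 42.01057 Da ladder on a base composition, and reports the
#' largest n observed. Permethylated profiles are an error, since
#' permethylation removes O-acetylation.
#'
#' @param profile a native-mode `glycan_profile`.
#' @param base_composition the O-acetyl-free composition of interest
#'   (object or string); `NULL` tabulates all bases.
#' @return data.frame `base`, `oacetyl`, `rel_abundance`; attribute
#'   `"max_oacetyl"` holds the largest count observed.
#' @export
oacetyl_ladder <- function(profile, base_composition = NULL) {
  stopifnot(inherits(profile, "glycan_profile"))
  if (!identical(profile$mode, "native"))
    stop("O-acetyl ladders exist only in native mode: ",
         "permethylation removes O-acetylation")
  tab <- profile$table
  if (!nrow(tab))
    return(structure(data.frame(base = character(), oacetyl = integer(),
                                rel_abundance = numeric()), max_oacetyl = 0L))
  comps <- lapply(tab$composition, as_composition)
  strip <- function(c) { c[["oacetyl"]] <- 0L
    do.call(glycan_composition, c(as.list(unclass(c)), list(oacetyl_cap = Inf))) }
  base <- vapply(comps, function(c) format(strip(c)), "")
  oac <- vapply(comps, function(c) c[["oacetyl"]], integer(1))
  res <- data.frame(base = base, oacetyl = oac,
                    rel_abundance = tab$rel_abundance)
  if (!is.null(base_composition)) {
    want <- format(as_composition(base_composition))
    res <- res[res$base == want, , drop = FALSE]
  }
  res <- res[order(res$base, res$oacetyl), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, max_oacetyl = if (nrow(res)) max(res$oacetyl) else 0L)
}

#' Compare glycan profiles across species
#'
#' Tabulates feature prevalences per profile into a species x feature
#' matrix, averaging biological replicates (same species label) with a
#' per-feature SD, and flags the species-characteristic signature motifs
#' when topology annotations are present in the profile tables
#' (`topology` column): the di-SA cap for salmonids, the
#' Gala(Galb)Galb-HexNAc cap for sturgeon, and the NeuAc-branched
#' GalbGalb-HexNAc cap for catfish.
#'
#' @param profiles list of `glycan_profile` objects.
#' @return list: `features` (data.frame, one row per species, feature
#'   columns; `_sd` columns when replicates were averaged), `motifs`
#'   (data.frame of motif flags per species, `NA` when no topologies are
#'   annotated).
#' @export
compare_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  labels <- vapply(seq_along(profiles), function(i) {
    s <- profiles[[i]]$species
    if (is.na(s)) paste0("profile", i) else s
  }, "")
  feats <- lapply(profiles, feature_prevalence)
  fnames <- unique(unlist(lapply(feats, function(f) f$feature)))
  wide <- do.call(rbind, lapply(feats, function(f)
    stats::setNames(f$value[match(fnames, f$feature)], fnames)))
  sig_motifs <- c("disa", "sturgeon_cap", "catfish_cap")
  motif_flags <- do.call(rbind, lapply(profiles, function(p) {
    tab <- p$table
    if (!nrow(tab) || !"topology" %in% names(tab))
      return(stats::setNames(rep(NA, length(sig_motifs)), sig_motifs))
    vapply(sig_motifs, function(m)
      any(vapply(tab$topology[!is.na(tab$topology)], function(s)
        length(match_motif(parse_glycan(s), m)) > 0, logical(1))), logical(1))
  }))
  out_feat <- list(); out_motif <- list()
  for (sp in unique(labels)) {
    rows <- which(labels == sp)
    mu <- colMeans(wide[rows, , drop = FALSE])
    rec <- data.frame(species = sp, t(mu), check.names = FALSE)
    if (length(rows) > 1) {
      sdv <- apply(wide[rows, , drop = FALSE], 2, stats::sd)
      names(sdv) <- paste0(names(sdv), "_sd")
      rec <- cbind(rec, t(sdv))
    }
    out_feat[[sp]] <- rec
    mf <- motif_flags[rows, , drop = FALSE]
    out_motif[[sp]] <- data.frame(species = sp,
                                  t(apply(mf, 2, function(x)
                                    if (all(is.na(x))) NA else any(x %in% TRUE))),
                                  check.names = FALSE)
  }
  merge_rows <- function(lst) {
    cols <- unique(unlist(lapply(lst, names)))
    do.call(rbind, lapply(lst, function(d) {
      d[setdiff(cols, names(d))] <- NA; d[cols]
    }))
  }
  list(features = merge_rows(out_feat), motifs = merge_rows(out_motif))
}
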