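#' Exoglycosidase digest rules
#'
#' A rule names the terminal residue an enzyme removes (residue kind plus
#' anomeric configuration) and the branch substituents on the parent that
#' block removal. The built-in enzymes are the two galactosidases used to
#' sequence the fish terminal epitopes:
#'
#' * `alpha_galactosidase()` removes terminal alpha-Gal (green coffee
#'   bean); no blockers are known for it here.
#' * `beta_galactosidase()` removes terminal beta-Gal (A. oryzae), but not
#'   when the parent residue carries a branching NeuAc (the sialylated
#'   catfish epitope is resistant) or a branching alpha-Gal (the inner
#'   beta-Gals of the sturgeon cap stay blocked until the alpha branch is
#'   removed -- the reason alpha is digested first).
#'
#' @param enzyme display name.
#' @param residue removable terminal residue kind.
#' @param anomer required anomeric configuration (`"a"`/`"b"`).
#' @param blocked_by list of `c(residue =, anomer =)` branch patterns on
#'   the parent that protect the terminal residue (`"?"` anomer matches
#'   any).
#' @return object of class `digest_rule`.
#' @export
digest_rule <- function(enzyme, residue, anomer, blocked_by = list()) {
  structure(list(enzyme = enzyme, residue = residue, anomer = anomer,
                 blocked_by = blocked_by), class = "digest_rule")
}

#' @rdname digest_rule
#' @export
alpha_galactosidase <- function() {
  digest_rule("alpha-galactosidase", "Gal", "a")
}

#' @rdname digest_rule
#' @export
beta_galactosidase <- function() {
  digest_rule("beta-galactosidase", "Gal", "b",
              blocked_by = list(c(residue = "NeuAc", anomer = "?"),
                                c(residue = "Gal", anomer = "a")))
}

# leaves removable by `rule` in the current topology
.eligible_leaves <- function(topo, rule) {
  leaves <- topo_leaves(topo)
  ok <- vapply(leaves, function(id) {
    row <- topo[topo$id == id, ]
    if (row$residue != rule$residue || row$anomer != rule$anomer)
      return(FALSE)
    if (is.na(row$parent)) return(FALSE)  # never digest the reducing end away
    sibs <- setdiff(topo_children(topo, row$parent), id)
    for (b in rule$blocked_by) {
      hit <- vapply(sibs, function(s) {
        srow <- topo[topo$id == s, ]
        srow$residue == b[["residue"]] &&
          (b[["anomer"]] == "?" || srow$anomer == b[["anomer"]])
      }, logical(1))
      if (any(hit)) return(FALSE)
    }
    TRUE
  }, logical(1))
  leaves[ok]
}

#' Apply one exoglycosidase to a topology
#'
#' Removes eligible terminal residues: a residue is eligible when it is a
#' leaf, matches the rule's residue kind and anomericity, and no blocking
#' branch sits on its parent. `exhaustive = TRUE` repeats passes until no
#' eligible residue remains; otherwise a single pass is made (eligibility
#' evaluated before any removal).
#'
#' @param topology a `glycan_topology`.
#' @param rule a [digest_rule()].
#' @param exhaustive digest to completion? (default TRUE)
#' @param site_prob per-site removal probability, for simulating partial
#'   digestion of sterically hindered structures (default 1 =
#'   deterministic complete digestion).
#' @return list with `topology` (the product) and `removed` (count).
#' @examples
#' t <- parse_glycan("Gal(a-)[Gal(b-)]Gal(b-)GlcNAc")
#' apply_enzyme(t, alpha_galactosidase())$removed  # 1
#' @export
apply_enzyme <- function(topology, rule, exhaustive = TRUE, site_prob = 1) {
  stopifnot(inherits(topology, "glycan_topology"),
            inherits(rule, "digest_rule"))
  removed <- 0L
  repeat {
    el <- .eligible_leaves(topology, rule)
    if (site_prob < 1 && length(el))
      el <- el[stats::runif(length(el)) < site_prob]
    if (!length(el)) break
    topology <- topo_drop(topology, el)
    removed <- removed + length(el)
    if (!exhaustive) break
  }
  list(topology = topology, removed = removed)
}

#' Sequential exoglycosidase digestion
#'
#' Applies each enzyme exhaustively in the given order, recording the
#' intermediate topology and removal count per step. Order matters:
#' digesting beta before alpha on the sturgeon cap removes fewer residues
#' because the inner beta-Gals are blocked until the alpha branch is gone.
#'
#' @param topology starting `glycan_topology`.
#' @param rules list of [digest_rule()]s, applied in order.
#' @param site_prob passed to [apply_enzyme()].
#' @return list with `final` topology, `steps` data.frame (`enzyme`,
#'   `removed`, `topology` string after the step).
#' @export
sequential_digest <- function(topology, rules, site_prob = 1) {
  steps <- data.frame(enzyme = character(), removed = integer(),
                      topology = character(), stringsAsFactors = FALSE)
  for (rule in rules) {
    res <- apply_enzyme(topology, rule, exhaustive = TRUE,
                        site_prob = site_prob)
    topology <- res$topology
    steps[nrow(steps) + 1, ] <- list(rule$enzyme, res$removed,
                                     format(topology))
  }
  list(final = topology, steps = steps)
}

#' Interpret a composition shift across a digestion experiment
#'
#' Compares assigned compositions before and after enzyme treatment and
#' reports whether the difference is consistent with the enzyme's
#' specificity (galactosidases remove Hex only). With an expected loss
#' from a structural template, smaller observed losses are flagged as
#' partial digestion (steric interference) and larger ones as
#' inconsistent.
#'
#' @param comp_before,comp_after assigned compositions (objects or
#'   strings).
#' @param rule the [digest_rule()] used.
#' @param expected_loss optional template-predicted residue loss.
#' @return list: `removed` (named count difference), `n_removed`,
#'   `consistent`, `resistant`, `partial`, `note`.
#' @export
interpret_shift <- function(comp_before, comp_after, rule,
                            expected_loss = NULL) {
  a <- unclass(as_composition(comp_before))
  b <- unclass(as_composition(comp_after))
  diff <- a - b
  target <- NODE_CLASS[[rule$residue]]
  others <- setdiff(COMP_KINDS, target)
  consistent <- diff[[target]] >= 0 && all(diff[others] == 0)
  n <- diff[[target]]
  resistant <- all(diff == 0)
  partial <- FALSE
  note <- if (resistant) "0 removed, resistant"
  else if (!consistent) {
    lost <- names(diff)[diff != 0 & names(diff) %in% others]
    paste0("inconsistent: loss of ", paste(lost, collapse = "+"),
           " not attributable to ", rule$enzyme)
  } else sprintf("%d %s-%s removed, consistent", n, rule$anomer, rule$residue)
  if (consistent && !is.null(expected_loss)) {
    if (n > expected_loss) {
      consistent <- FALSE
      note <- sprintf("inconsistent: %d removed but template predicts %d",
                      n, expected_loss)
    } else if (n < expected_loss && n > 0) {
      partial <- TRUE
      note <- sprintf("partial digestion: %d of %d expected sites cleaved",
                      n, expected_loss)
    } else if (n == 0 && expected_loss > 0) {
      note <- "0 removed, resistant"
    }
  }
  list(removed = diff, n_removed = unname(n), consistent = consistent,
       resistant = resistant, partial = partial, note = note)
}
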