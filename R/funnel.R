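# Enumeration of historical substitutions along a branch between two
# reconstructed ancestors and the three-stage prioritization funnel:
# (1) posterior-probability filter, (2) conservation across the full
# alignment or within either daughter lineage, (3) structural triage.

#' Enumerate substitutions between two ancestral profiles
#'
#' One record per alignment column, present in both gap masks, where the
#' parent and child MAP states differ. Positions are reported in the
#' descendant's ungapped residue numbering via the coordinate map.
#'
#' @param parent_profile,child_profile \code{ancestral_profile}s over the
#'   same alignment.
#' @param parent_mask,child_mask \code{gap_mask}s for the two nodes.
#' @param coord_map \code{coordinate_map} giving descendant residue
#'   numbering; columns absent from the map fall back to \code{NA}.
#' @return A data.frame of substitution records: \code{column},
#'   \code{position}, parent/child MAP and second-best states with their
#'   PPs.
#' @export
enumerate_substitutions <- function(parent_profile, child_profile,
                                    parent_mask, child_mask,
                                    coord_map = NULL) {
  if (parent_profile$n_sites != child_profile$n_sites) {
    stop("profiles cover different numbers of columns")
  }
  check_profile_mask(parent_profile, parent_mask)
  check_profile_mask(child_profile, child_mask)
  both <- parent_mask$present & child_mask$present
  diff <- both & parent_profile$map_state != child_profile$map_state
  cols <- which(diff)
  pos <- if (is.null(coord_map)) {
    # descendant numbering among the child-present columns
    cumsum(child_mask$present)[cols]
  } else {
    coord_map$col_to_res[cols]
  }
  data.frame(
    column = cols,
    position = as.integer(pos),
    parent_state = parent_profile$map_state[cols],
    parent_pp = parent_profile$map_pp[cols],
    parent_alt = parent_profile$alt_state[cols],
    parent_alt_pp = parent_profile$alt_pp[cols],
    child_state = child_profile$map_state[cols],
    child_pp = child_profile$map_pp[cols],
    child_alt = child_profile$alt_state[cols],
    child_alt_pp = child_profile$alt_pp[cols],
    stringsAsFactors = FALSE
  )
}

#' Posterior-probability classification of one substitution
#'
#' A substitution is a \code{true_substitution} when the MAP state carries
#' PP > 0.8 at both nodes. When one node has MAP PP < 0.8 but its
#' alternative state (PP > 0.2) differs from the MAP state at the other
#' node, the substitution cannot be explained away as a reconstruction
#' artifact and is \code{ambiguous_included}. Everything else (including
#' exact threshold equality) is \code{excluded}.
#'
#' @param record One-row data.frame (or list) with fields
#'   \code{parent_pp}, \code{child_pp}, \code{parent_alt},
#'   \code{parent_alt_pp}, \code{child_alt}, \code{child_alt_pp},
#'   \code{parent_state}, \code{child_state}.
#' @param pp_true MAP-PP threshold for a confident state (default 0.8).
#' @param pp_alt Alternative-state PP threshold (default 0.2).
#' @return One of \code{"true_substitution"}, \code{"ambiguous_included"},
#'   \code{"excluded"}.
#' @export
classify_by_pp <- function(record, pp_true = 0.8, pp_alt = 0.2) {
  if (record$parent_pp > pp_true && record$child_pp > pp_true) {
    return("true_substitution")
  }
  # one node weakly reconstructed: include when its credible alternative
  # is not simply the other node's MAP state
  if (record$parent_pp < pp_true &&
      record$parent_alt_pp > pp_alt &&
      record$parent_alt != record$child_state) {
    return("ambiguous_included")
  }
  if (record$child_pp < pp_true &&
      record$child_alt_pp > pp_alt &&
      record$child_alt != record$parent_state) {
    return("ambiguous_included")
  }
  "excluded"
}

#' Per-column conservation profile over a clade
#'
#' Modal residue, its frequency, and Shannon entropy (bits) per alignment
#' column over a subset of sequences, gaps excluded from counts. A column
#' is labeled conserved when the modal frequency is at least
#' \code{threshold}; columns with only gaps are undefined and labeled not
#' conserved.
#'
#' @param alignment An \code{\link{aa_alignment}}.
#' @param clade_ids Non-empty subset of \code{alignment$ids}.
#' @param threshold Modal-frequency cutoff (default 0.8, inclusive).
#' @return A data.frame: \code{column}, \code{modal_state},
#'   \code{modal_freq}, \code{entropy}, \code{conserved}.
#' @export
conservation_profile <- function(alignment, clade_ids, threshold = 0.8) {
  if (length(clade_ids) == 0) stop("empty clade")
  if (!all(clade_ids %in% alignment$ids)) {
    stop("clade ids not in alignment: ",
         paste(setdiff(clade_ids, alignment$ids), collapse = ", "))
  }
  sub <- alignment$matrix[clade_ids, , drop = FALSE]
  n_sites <- ncol(sub)
  modal_state <- character(n_sites)
  modal_freq <- numeric(n_sites)
  entropy <- numeric(n_sites)
  for (s in seq_len(n_sites)) {
    col <- sub[, s]
    col <- col[col %in% AA20]
    if (length(col) == 0) {
      modal_state[s] <- NA_character_
      modal_freq[s] <- NA_real_
      entropy[s] <- NA_real_
      next
    }
    tab <- table(col)
    p <- as.numeric(tab) / length(col)
    m <- which.max(tab)
    modal_state[s] <- names(tab)[m]
    modal_freq[s] <- p[m]
    entropy[s] <- -sum(p * log2(p))
  }
  data.frame(
    column = seq_len(n_sites),
    modal_state = modal_state,
    modal_freq = modal_freq,
    entropy = entropy,
    conserved = !is.na(modal_freq) & modal_freq >= threshold,
    stringsAsFactors = FALSE
  )
}

conservation_label <- function(column, cons_all, cons_sn, cons_bv) {
  ifelse(cons_all$conserved[column], "conserved_all",
  ifelse(cons_sn$conserved[column], "conserved_SN_lineage",
  ifelse(cons_bv$conserved[column], "conserved_BV_lineage",
         "not_conserved")))
}

#' Apply the three-stage substitution-prioritization funnel
#'
#' Stage 1 keeps records classified \code{true_substitution} or
#' \code{ambiguous_included} by \code{\link{classify_by_pp}}. Stage 2 keeps
#' records whose column is conserved across the whole alignment or within
#' either lineage. Stage 3 attaches the structural category and
#' surface/core location from the annotation table and drops records that
#' are both on the surface and in no annotated functional environment
#' (category \code{other}) — residues likely playing no role. Every drop is
#' recorded with its failing stage.
#'
#' @param records Output of \code{\link{enumerate_substitutions}}.
#' @param conservation_all,conservation_sn,conservation_bv
#'   \code{\link{conservation_profile}}s over the full alignment and the
#'   two daughter lineages.
#' @param annotations \code{\link{read_annotations}} table in the same
#'   residue numbering as \code{records$position}.
#' @param pp_true,pp_alt Thresholds passed to \code{classify_by_pp}.
#' @return List: \code{records} (survivors with \code{pp_class},
#'   \code{conservation}, \code{category}, \code{location}),
#'   \code{dropped} (with \code{drop_stage}), \code{counts} (named vector:
#'   listed, pp_filtered, conserved, structural).
#' @export
apply_funnel <- function(records, conservation_all, conservation_sn,
                         conservation_bv, annotations,
                         pp_true = 0.8, pp_alt = 0.2) {
  if (nrow(records) == 0) {
    return(list(records = records, dropped = records,
                counts = c(listed = 0, pp_filtered = 0, conserved = 0,
                           structural = 0)))
  }
  records$pp_class <- vapply(seq_len(nrow(records)), function(i) {
    classify_by_pp(records[i, ], pp_true, pp_alt)
  }, character(1))
  records$conservation <- conservation_label(records$column,
                                             conservation_all,
                                             conservation_sn,
                                             conservation_bv)
  idx <- match(records$position, annotations$position)
  records$category <- annotations$category[idx]
  records$location <- annotations$location[idx]
  records$domain <- annotations$domain[idx]

  stage1 <- records$pp_class %in% c("true_substitution", "ambiguous_included")
  stage2 <- stage1 & records$conservation != "not_conserved"
  unannotated <- stage2 & is.na(records$category)
  if (any(unannotated)) {
    warning("missing annotation for surviving positions: ",
            paste(records$position[unannotated], collapse = ", "),
            "; retained unclassified")
  }
  stage3 <- stage2 & (is.na(records$category) |
                      !(records$location == "surface" &
                        records$category == "other"))

  drop_stage <- rep(NA_character_, nrow(records))
  drop_stage[!stage1] <- "pp_filter"
  drop_stage[stage1 & !stage2] <- "conservation"
  drop_stage[stage2 & !stage3] <- "structural"
  dropped <- records[!stage3, , drop = FALSE]
  dropped$drop_stage <- drop_stage[!stage3]

  list(records = records[stage3, , drop = FALSE],
       dropped = dropped,
       counts = c(listed = nrow(records),
                  pp_filtered = sum(stage1),
                  conserved = sum(stage2),
                  structural = sum(stage3)))
}

#' Compose nested mutant sets from funnel survivors
#'
#' The 4x set contains the active-site survivors; 12x adds the
#' next-priority structural environments (tunnel, FAD-proximal, first
#' NADPH shell); 16x contains all survivors. Nesting 4x within 12x within 16x
#' holds by construction and is asserted. Explicit user-defined subsets
#' (e.g. a 4'x reduced set given as residue positions) are validated
#' against the survivors.
#'
#' @param records Survivor records from \code{\link{apply_funnel}} with
#'   \code{position} and \code{category}.
#' @param extra_sets Named list of integer vectors of residue positions.
#' @return Named list of sorted position vectors: \code{"4x"},
#'   \code{"12x"}, \code{"16x"}, plus any extra sets.
#' @export
compose_mutant_sets <- function(records, extra_sets = list()) {
  pos <- records$position
  set4 <- sort(pos[!is.na(records$category) &
                   records$category == "active_site"])
  next_priority <- c("tunnel", "FAD_proximal", "NADPH_shell1")
  set12 <- sort(unique(c(set4, pos[!is.na(records$category) &
                                   records$category %in% next_priority])))
  set16 <- sort(unique(pos))
  stopifnot(all(set4 %in% set12), all(set12 %in% set16))
  out <- list("4x" = set4, "12x" = set12, "16x" = set16)
  for (nm in names(extra_sets)) {
    want <- sort(as.integer(extra_sets[[nm]]))
    missing <- setdiff(want, set16)
    if (length(missing)) {
      stop("set '", nm, "' references positions absent from survivors: ",
           paste(missing, collapse = ", "))
    }
    out[[nm]] <- want
  }
  out
}
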