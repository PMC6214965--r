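#' Assign fusion groups from instrumented levels
#'
#' Gives every distinct (UIV, LIV) pair — the uppermost and lowermost
#' instrumented vertebrae — its own group number, so that patients fused
#' over the same levels share a group. Groups are numbered 1..G in
#' anatomical order of (UIV, LIV); the numbering is deterministic.
#'
#' @param fusions A `fusion_assignment` data frame (see [read_fusions()]).
#' @return Object of class `fusion_groups`: list with `table` (data frame
#'   group, uiv, liv, n) and `assignment` (data frame patient_id, group,
#'   uiv, liv).
#' @export
assign_fusion_groups <- function(fusions) {
  fusions <- as.data.frame(fusions)
  if (nrow(fusions) == 0L) {
    return(structure(list(
      table = data.frame(group = integer(), uiv = character(),
                         liv = character(), n = integer(),
                         stringsAsFactors = FALSE),
      assignment = data.frame(patient_id = character(), group = integer(),
                              uiv = character(), liv = character(),
                              stringsAsFactors = FALSE)),
      class = "fusion_groups"))
  }
  key <- paste(fusions$uiv, fusions$liv, sep = "-")
  uq <- !duplicated(key)
  tab <- data.frame(uiv = fusions$uiv[uq], liv = fusions$liv[uq],
                    stringsAsFactors = FALSE)
  ord <- order(.vert_index(tab$uiv), .vert_index(tab$liv))
  tab <- tab[ord, , drop = FALSE]
  tab$group <- seq_len(nrow(tab))
  grp <- tab$group[match(key, paste(tab$uiv, tab$liv, sep = "-"))]
  tab$n <- as.vector(table(factor(grp, levels = tab$group)))
  structure(list(
    table = tab[, c("group", "uiv", "liv", "n")],
    assignment = data.frame(patient_id = fusions$patient_id, group = grp,
                            uiv = fusions$uiv, liv = fusions$liv,
                            stringsAsFactors = FALSE)),
    class = "fusion_groups")
}

#' @export
print.fusion_groups <- function(x, ...) {
  cat(sprintf("<fusion_groups> %d groups, %d patients\n",
              nrow(x$table), nrow(x$assignment)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Exclude undersized fusion groups
#'
#' Removes the patients of every fusion group with fewer than `min_n`
#' members and renumbers the remaining groups contiguously, preserving their
#' order. Mirrors the exclusion of rare fusion levels before path analysis.
#'
#' @param groups A `fusion_groups` object.
#' @param min_n Minimum group size to keep (default 3).
#' @return List with `kept` (a renumbered `fusion_groups` of retained
#'   patients), `removed_patients` (character vector) and `removed_groups`
#'   (data frame of the dropped rows with their original numbering).
#' @export
filter_small_groups <- function(groups, min_n = 3L) {
  stopifnot(inherits(groups, "fusion_groups"))
  if (min_n < 1L) stop("min_n must be >= 1")
  keep <- groups$table$n >= min_n
  if (!any(keep)) stop("all fusion groups are smaller than min_n = ", min_n)
  kept_tab <- groups$table[keep, , drop = FALSE]
  removed_tab <- groups$table[!keep, , drop = FALSE]
  renum <- setNames(seq_len(nrow(kept_tab)), kept_tab$group)
  asg <- groups$assignment
  in_kept <- asg$group %in% kept_tab$group
  removed_patients <- asg$patient_id[!in_kept]
  asg <- asg[in_kept, , drop = FALSE]
  asg$group <- as.integer(renum[as.character(asg$group)])
  kept_tab$group <- seq_len(nrow(kept_tab))
  rownames(asg) <- rownames(kept_tab) <- NULL
  list(kept = structure(list(table = kept_tab, assignment = asg),
                        class = "fusion_groups"),
       removed_patients = removed_patients,
       removed_groups = removed_tab)
}

#' Build treatment paths
#'
#' Combines each patient's pre-operative cluster (PO_i), early
#' post-operative cluster (EP_j) and fusion group (F_m) into the three-level
#' treatment path "PO\{i\}-EP\{j\}-F\{m\}". A path is a pure function of the
#' triple, so patients with identical triples share the path.
#'
#' @param po_labels,ep_labels Integer cluster labels named by patient id.
#' @param groups A `fusion_groups` object covering the included patients.
#' @return Data frame of class `treatment_paths`: patient_id, po, ep,
#'   fusion_group, path.
#' @export
build_paths <- function(po_labels, ep_labels, groups) {
  stopifnot(inherits(groups, "fusion_groups"))
  asg <- groups$assignment
  ids <- asg$patient_id
  miss_po <- ids[!ids %in% names(po_labels)]
  if (length(miss_po)) stop("no PO cluster label for patient '", miss_po[1L], "'")
  miss_ep <- ids[!ids %in% names(ep_labels)]
  if (length(miss_ep)) stop("no EP cluster label for patient '", miss_ep[1L], "'")
  po <- as.integer(po_labels[ids])
  ep <- as.integer(ep_labels[ids])
  out <- data.frame(patient_id = ids, po = po, ep = ep,
                    fusion_group = asg$group,
                    path = sprintf("PO%d-EP%d-F%d", po, ep, asg$group),
                    stringsAsFactors = FALSE)
  class(out) <- c("treatment_paths", "data.frame")
  out
}

#' Merge fusion groups with equivalent outcomes
#'
#' Within each (PO cluster, EP cluster) stratum, fusion groups whose
#' patients have the same modal two-year outcome cluster are unioned into a
#' single path and their counts added; the merged fusion label lists the
#' member groups in ascending order (e.g. `"F2,6"`). Groups with different
#' modal outcomes stay separate. Total patient count is preserved. Modal
#' ties are broken toward the lower outcome index.
#'
#' @param paths A `treatment_paths` data frame (see [build_paths()]).
#' @param y2_labels Integer two-year cluster labels named by patient id.
#' @return The paths data frame with `fusion_label` and `path` replaced by
#'   their merged versions.
#' @export
merge_equivalent_fusion_groups <- function(paths, y2_labels) {
  stopifnot(inherits(paths, "treatment_paths"))
  ids <- paths$patient_id
  miss <- ids[!ids %in% names(y2_labels)]
  if (length(miss)) stop("no 2Y cluster label for patient '", miss[1L], "'")
  y2 <- as.integer(y2_labels[ids])
  strata <- split(seq_len(nrow(paths)), paste(paths$po, paths$ep, sep = "."))
  fusion_label <- character(nrow(paths))
  for (idx in strata) {
    modal_of <- vapply(split(y2[idx], paths$fusion_group[idx]), function(v) {
      tt <- tabulate(v)
      which.max(tt)   # ties toward the lower outcome index
    }, integer(1L))
    # union the member groups that share a modal outcome
    for (g in names(modal_of)) {
      members <- names(modal_of)[modal_of == modal_of[[g]]]
      lab <- paste(sort(as.integer(members)), collapse = ",")
      fusion_label[idx][paths$fusion_group[idx] == as.integer(g)] <- lab
    }
  }
  paths$fusion_label <- fusion_label
  paths$path <- sprintf("PO%d-EP%d-F%s", paths$po, paths$ep, fusion_label)
  paths
}
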