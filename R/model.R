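#' Fit the spinal-curve classification and outcome model
#'
#' End-to-end pipeline for a surgical AIS cohort observed at three
#' timepoints (pre-operative PO, early post-operative EP, two-year Y2) plus
#' a non-scoliotic control group:
#'
#' 1. every spine is isotropically scaled to unit height and resampled at
#'    the control-derived z-template ([scale_isotropic()],
#'    [build_control_template()], [resample_at_template()]);
#' 2. fusion groups are formed from the instrumented levels and undersized
#'    groups excluded ([assign_fusion_groups()], [filter_small_groups()]);
#' 3. the retained patients' curves are clustered at each timepoint by
#'    K-means with silhouette-selected k ([select_k()]);
#' 4. treatment paths PO_i-EP_j-F_m are built, fusion groups with
#'    equivalent modal outcomes merged, and the path-outcome contingency,
#'    per-path concordance and a multinomial-regression likelihood-ratio
#'    test computed ([build_paths()], [merge_equivalent_fusion_groups()],
#'    [path_outcome_table()], [concordance()], [fit_multinomial()]).
#'
#' @param landmarks Long-format landmark table (data frame or CSV path; see
#'   [read_landmarks()]) with PO/EP/Y2 rows for the patients and CONTROL
#'   rows for the control spines (controls may instead be supplied via
#'   `template`).
#' @param fusions Fusion table (data frame or CSV path; see
#'   [read_fusions()]).
#' @param config A [spinepath_config()].
#' @param template Optional pre-built `control_template`; required if
#'   `landmarks` contains no CONTROL spines.
#' @return Object of class `spinepath`. Components include `template`,
#'   `clusters` (per-timepoint [select_k()] results), `features`
#'   (per-timepoint matrices), `fusion_groups`, `removed_patients`,
#'   `paths` (merged treatment paths), `outcome_table`, `triple_table`
#'   (unmerged, used for empirical prediction), `concordance`, `fit` (the
#'   multinomial LR fit) and `config`.
#' @seealso [predict.spinepath()], [summary.spinepath()],
#'   [plot.spinepath()], [simulate.spinepath()]
#' @export
spinepath <- function(landmarks, fusions, config = spinepath_config(),
                      template = NULL) {
  stopifnot(inherits(config, "spinepath_config"))
  spines <- if (is.list(landmarks) && !is.data.frame(landmarks)) landmarks
            else read_landmarks(landmarks)
  fus <- if (inherits(fusions, "fusion_assignment")) fusions
         else read_fusions(fusions)
  tps <- vapply(spines, function(s) s$timepoint, character(1L))
  if (is.null(template)) {
    ctrl <- spines[tps == "CONTROL"]
    if (length(ctrl) == 0L)
      stop("no CONTROL spines and no template supplied")
    template <- build_control_template(lapply(ctrl, scale_isotropic))
  }

  groups <- assign_fusion_groups(fus)
  filt <- filter_small_groups(groups, config$min_group_n)
  included <- filt$kept$assignment$patient_id

  features <- list()
  clusters <- list()
  labels <- list()
  for (tp in c("PO", "EP", "Y2")) {
    sp <- spines[tps == tp]
    sp <- sp[vapply(sp, function(s) s$patient_id %in% included, logical(1L))]
    if (length(sp) == 0L) stop("no ", tp, " spines among included patients")
    curves <- normalize_spines(sp, template)
    X <- curve_features(curves)
    sel <- select_k(X, config$k_range, restarts = config$restarts,
                    seed = config$seed)
    features[[tp]] <- X
    clusters[[tp]] <- sel
    labels[[tp]] <- sel$model$labels
  }

  paths <- build_paths(labels$PO, labels$EP, filt$kept)
  triple_table <- path_outcome_table(paths, labels$Y2)
  merged <- merge_equivalent_fusion_groups(paths, labels$Y2)
  outcome_table <- path_outcome_table(merged, labels$Y2)
  conc <- concordance(outcome_table, config$min_path_n)
  fit <- fit_multinomial(paths$po, paths$ep, paths$fusion_group,
                         labels$Y2[paths$patient_id],
                         encoding = config$encoding)

  structure(list(template = template, features = features,
                 clusters = clusters, labels = labels,
                 fusion_groups = filt$kept,
                 removed_patients = filt$removed_patients,
                 removed_groups = filt$removed_groups,
                 paths = merged, triple_table = triple_table,
                 outcome_table = outcome_table, concordance = conc,
                 fit = fit, config = config, call = match.call()),
            class = "spinepath")
}

#' @export
print.spinepath <- function(x, ...) {
  ks <- vapply(x$clusters, `[[`, integer(1L), "k")
  cat("Spinal-curve classification and outcome model\n")
  cat(sprintf("  patients included: %d (removed by fusion-group filter: %d)\n",
              length(x$labels$PO), length(x$removed_patients)))
  cat(sprintf("  clusters (silhouette-selected): PO %d, EP %d, 2Y %d\n",
              ks["PO"], ks["EP"], ks["Y2"]))
  cat(sprintf("  fusion groups: %d; treatment paths (merged): %d\n",
              nrow(x$fusion_groups$table), nrow(x$outcome_table)))
  cat(sprintf("  concordance: %d paths with >= %d patients cover %d/%d patients (%d%%)\n",
              x$concordance$n_paths, x$config$min_path_n,
              x$concordance$patients_covered, x$concordance$total_patients,
              x$concordance$coverage_percent))
  cat(sprintf("  LR test (%s encoding): chi-square = %.2f, df = %d, p = %.3g\n",
              x$fit$encoding, x$fit$lr$chi_square, x$fit$lr$df,
              x$fit$lr$p_value))
  invisible(x)
}

#' Summarize a fitted spinepath model
#'
#' @param object A `spinepath` fit.
#' @param ... Unused.
#' @return Object of class `summary.spinepath` printing cluster sizes and
#'   silhouettes per timepoint, the fusion-group table, the path-outcome
#'   contingency table, per-path concordance and the LR test.
#' @export
summary.spinepath <- function(object, ...) {
  structure(list(fit = object), class = "summary.spinepath")
}

#' @export
print.summary.spinepath <- function(x, ...) {
  ob <- x$fit
  print(ob)
  cat("\nSilhouette by candidate k:\n")
  for (tp in names(ob$clusters)) {
    sil <- ob$clusters[[tp]]$silhouettes
    cat(sprintf("  %-3s %s\n", tp,
                paste(sprintf("k=%s: %.3f", names(sil), sil), collapse = "  ")))
    cat(sprintf("      cluster sizes: %s\n",
                paste(ob$clusters[[tp]]$model$sizes, collapse = "/")))
  }
  cat("\nFusion groups (after exclusion):\n")
  print(ob$fusion_groups$table, row.names = FALSE)
  cat("\nPath-outcome table (merged):\n")
  print(unclass(ob$outcome_table))
  cat("\nPer-path concordance (paths with >=", ob$config$min_path_n,
      "patients):\n")
  print(ob$concordance$per_path, row.names = FALSE)
  invisible(x)
}

#' Predict two-year outcomes from a fitted spinepath model
#'
#' @param object A `spinepath` fit.
#' @param newdata Data frame with columns `po`, `ep`, `fusion_group`
#'   (cluster and group indices as in the fit). Defaults to the fitted
#'   patients' own triples.
#' @param method `"empirical"` (modal outcome of the observed triple; an
#'   unseen triple yields an explicit no-data result) or `"model"` (argmax
#'   probability from the multinomial fit).
#' @param ... Unused.
#' @return Data frame with `path`, `outcome`, `status`
#'   (see [predict_outcome()]).
#' @export
predict.spinepath <- function(object, newdata = NULL,
                              method = c("empirical", "model"), ...) {
  method <- match.arg(method)
  if (is.null(newdata)) {
    p <- object$paths
    newdata <- data.frame(po = p$po, ep = p$ep, fusion_group = p$fusion_group)
  }
  if (method == "empirical") {
    key <- sprintf("PO%d-EP%d-F%d", newdata$po, newdata$ep,
                   newdata$fusion_group)
    predict_outcome(key, object$triple_table)
  } else {
    predict_outcome(newdata, object$fit)
  }
}

#' @export
coef.spinepath <- function(object, ...) object$fit$coefficients

#' Residual feature distances of a fitted spinepath model
#'
#' @param object A `spinepath` fit.
#' @param timepoint `"PO"`, `"EP"` or `"Y2"`.
#' @param ... Unused.
#' @return Matrix of per-patient residuals (feature vector minus assigned
#'   cluster center).
#' @export
residuals.spinepath <- function(object, timepoint = "PO", ...) {
  timepoint <- match.arg(timepoint, c("PO", "EP", "Y2"))
  X <- object$features[[timepoint]]
  m <- object$clusters[[timepoint]]$model
  X - m$centers[m$labels, , drop = FALSE]
}

#' Plot fitted cluster-center curves
#'
#' Frontal (x vs z) and sagittal (y vs z) projections of the cluster-center
#' curves at each timepoint, one panel per timepoint and plane.
#'
#' @param x A `spinepath` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.spinepath <- function(x, ...) {
  tz <- unclass(x$template)
  op <- graphics::par(mfrow = c(2L, 3L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (plane in c("frontal", "sagittal")) {
    col_idx <- if (plane == "frontal") 1:17 else 18:34
    for (tp in c("PO", "EP", "Y2")) {
      cen <- x$clusters[[tp]]$model$centers[, col_idx, drop = FALSE]
      graphics::matplot(t(cen), tz, type = "l", lty = 1L, lwd = 2L,
                        xlab = if (plane == "frontal") "x (unit height)" else "y (unit height)",
                        ylab = "z (unit height)",
                        main = sprintf("%s centers, %s", tp, plane), ...)
    }
  }
  invisible(x)
}

#' Simulate cohorts from a fitted spinepath model
#'
#' Draws synthetic cohorts whose cluster templates are the fitted cluster
#' centers and whose noise SD is the root-mean-square residual of the fit,
#' using the fitted cluster-membership frequencies, fusion-level
#' frequencies, and the fitted modal path-to-outcome map.
#'
#' @param object A `spinepath` fit.
#' @param nsim Number of cohorts (default 1).
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of `synthetic_cohort` objects (length `nsim`), or a single
#'   cohort when `nsim = 1`.
#' @export
simulate.spinepath <- function(object, nsim = 1L, seed = NULL, ...) {
  tz <- unclass(object$template)
  tpl_from_center <- function(cen) {
    # represent a fitted center directly as interpolating lobes is not
    # needed: build a degenerate template whose evaluation reproduces the
    # center by linear interpolation over z
    list(shift = 0, frontal = list(), sagittal = list(),
         center_x = cen[1:17], center_y = cen[18:34], z = tz)
  }
  # noise: pooled residual SD per coordinate across timepoints
  res <- do.call(rbind, lapply(c("PO", "EP", "Y2"), function(tp)
    residuals.spinepath(object, tp)))
  noise <- sd(as.vector(res))
  sim_one <- function(sd_seed) {
    spec <- cohort_spec(
      seed = sd_seed,
      fusion_table = data.frame(uiv = object$fusion_groups$table$uiv,
                                liv = object$fusion_groups$table$liv,
                                n = object$fusion_groups$table$n,
                                stringsAsFactors = FALSE),
      po_probs = object$clusters$PO$model$sizes / length(object$labels$PO),
      ep_probs = object$clusters$EP$model$sizes / length(object$labels$EP),
      templates = list(
        PO = lapply(seq_len(object$clusters$PO$k), function(i)
          tpl_from_center(object$clusters$PO$model$centers[i, ])),
        EP = lapply(seq_len(object$clusters$EP$k), function(i)
          tpl_from_center(object$clusters$EP$model$centers[i, ])),
        Y2 = lapply(seq_len(object$clusters$Y2$k), function(i)
          tpl_from_center(object$clusters$Y2$model$centers[i, ])),
        CONTROL = default_templates()$CONTROL),
      noise_sd = noise,
      outcome_map = .fitted_outcome_map(object),
      fidelity = max(min(mean(object$concordance$per_path$fraction), 1), 1e-6))
    generate_cohort(spec)
  }
  seeds <- if (is.null(seed)) sample.int(2^30, nsim) else seed + seq_len(nsim) - 1L
  out <- lapply(seeds, sim_one)
  if (nsim == 1L) out[[1L]] else out
}

# modal path -> outcome map from the fitted triple table, completed with a
# fixed fill rule for unseen triples
.fitted_outcome_map <- function(object) {
  tab <- object$fusion_groups$table
  p <- object$paths
  y2 <- object$labels$Y2[p$patient_id]
  n_y2 <- object$clusters$Y2$k
  grid <- expand.grid(po = seq_len(object$clusters$PO$k),
                      ep = seq_len(object$clusters$EP$k),
                      g = tab$group, KEEP.OUT.ATTRS = FALSE)
  modal <- mapply(function(po, ep, g) {
    v <- y2[p$po == po & p$ep == ep & p$fusion_group == g]
    if (length(v) == 0L) return(NA_integer_)
    which.max(tabulate(v, nbins = n_y2))
  }, grid$po, grid$ep, grid$g)
  fill <- is.na(modal)
  modal[fill] <- ((grid$po[fill] + grid$ep[fill] + grid$g[fill]) %% n_y2) + 1L
  data.frame(po = grid$po, ep = grid$ep, uiv = tab$uiv[match(grid$g, tab$group)],
             liv = tab$liv[match(grid$g, tab$group)], y2 = as.integer(modal),
             stringsAsFactors = FALSE)
}
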