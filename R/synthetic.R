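# Gaussian lobe in normalized height z (1 = T1, 0 = L5)
.lobe <- function(z, center, amp, width) amp * exp(-((z - center)^2) / (2 * width^2))

.eval_template <- function(tpl, z) {
  if (!is.null(tpl$center_x)) {
    # tabulated template (e.g. a fitted cluster center): interpolate in z
    return(list(x = approx(tpl$z, tpl$center_x, xout = z, rule = 2)$y,
                y = approx(tpl$z, tpl$center_y, xout = z, rule = 2)$y))
  }
  x <- rep(tpl$shift %||% 0, length(z))
  for (lb in tpl$frontal %||% list()) x <- x + .lobe(z, lb[1L], lb[2L], lb[3L])
  y <- rep(tpl$y_offset %||% 0, length(z))
  for (lb in tpl$sagittal %||% list()) y <- y + .lobe(z, lb[1L], lb[2L], lb[3L])
  list(x = x, y = y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default shape templates for the synthetic cohort
#'
#' Cluster template curves in normalized (unit-height) coordinates. Each
#' template is a lateral shift plus Gaussian lobes in z for the frontal
#' x(z) profile and kyphosis/lordosis lobes for the sagittal y(z) profile
#' (y negative = posterior). The three pre-operative (PO) templates encode
#' qualitatively distinct right-thoracic morphologies: a balanced
#' hypokyphotic curve, a laterally shifted (unbalanced) curve with a larger
#' main thoracic lobe, and an S-shaped curve with proximal kyphosis and a
#' strong lumbar counter-lobe. The early post-operative (EP) and two-year
#' (Y2) templates carry reduced frontal amplitudes (post-correction shapes)
#' and differ mainly in lateral shift and kyphosis. The control template is
#' planar (x = 0) with only sagittal curvature.
#'
#' @return Named list with elements `PO` (3 templates), `EP` (2),
#'   `Y2` (3) and `CONTROL` (1 template).
#' @export
default_templates <- function() {
  list(
    PO = list(
      list(shift = 0,
           frontal = list(c(0.55, 0.18, 0.14), c(0.15, -0.03, 0.08)),
           sagittal = list(c(0.70, -0.02, 0.16), c(0.12, 0.05, 0.09))),
      list(shift = 0.10,
           frontal = list(c(0.55, 0.24, 0.13), c(0.12, -0.08, 0.08)),
           sagittal = list(c(0.68, -0.055, 0.16), c(0.10, 0.05, 0.08))),
      list(shift = 0,
           frontal = list(c(0.60, 0.08, 0.12), c(0.88, -0.10, 0.07),
                          c(0.18, -0.16, 0.09)),
           sagittal = list(c(0.62, -0.08, 0.14), c(0.92, -0.08, 0.06),
                           c(0.15, 0.07, 0.09)))),
    EP = list(
      list(shift = 0.07,
           frontal = list(c(0.55, 0.06, 0.13)),
           sagittal = list(c(0.70, -0.02, 0.16), c(0.12, 0.02, 0.09))),
      list(shift = 0,
           frontal = list(c(0.60, 0.05, 0.12), c(0.18, -0.04, 0.09)),
           sagittal = list(c(0.65, -0.06, 0.15), c(0.92, -0.04, 0.06),
                           c(0.15, 0.05, 0.09)))),
    Y2 = list(
      list(shift = 0.07, y_offset = -0.08,
           frontal = list(c(0.55, 0.05, 0.13)),
           sagittal = list(c(0.65, -0.12, 0.17), c(0.12, 0.05, 0.09))),
      list(shift = 0,
           frontal = list(c(0.55, 0.04, 0.13)),
           sagittal = list(c(0.68, -0.07, 0.16), c(0.92, -0.07, 0.06),
                           c(0.15, 0.09, 0.09))),
      list(shift = -0.13,
           frontal = list(c(0.60, 0.16, 0.12)),
           sagittal = list(c(0.70, -0.01, 0.16), c(0.12, 0.02, 0.09)))),
    CONTROL = list(
      list(shift = 0,
           frontal = list(),
           sagittal = list(c(0.70, -0.07, 0.16), c(0.12, 0.05, 0.09))))
  )
}

#' Noise-free feature vector of a template
#'
#' Evaluates a shape template at 17 equally spaced normalized z-levels and
#' returns the 34-element clustering feature vector `c(x, y)` of the
#' resulting noise-free curve. Useful for checking template separation.
#'
#' @param tpl One template from [default_templates()].
#' @return Numeric vector of length 34.
#' @export
template_features <- function(tpl) {
  z <- seq(1, 0, length.out = 17L)
  xy <- .eval_template(tpl, z)
  c(xy$x, xy$y)
}

#' Reference fusion-level frequencies
#'
#' The distinct fusion levels (UIV, LIV) and their patient counts observed
#' in a reference cohort of 67 surgically treated right-thoracic AIS
#' patients: 8 distinct levels, two of which (2 and 1 patients) fall below
#' the minimum group size of 3.
#'
#' @return Data frame with columns `group`, `uiv`, `liv`, `n`.
#' @export
reference_fusion_levels <- function() {
  read.csv(system.file("extdata", "fusion_levels.csv", package = "spinepath",
                       mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Reference path-outcome counts
#'
#' The printed treatment-path by two-year-outcome contingency counts of the
#' reference cohort: 17 paths over 64 included patients, with merged fusion
#' labels where equivalent fusion groups were unioned.
#'
#' @return A [path_outcome_table] with 17 rows; attribute `meta` holds the
#'   per-path PO cluster, EP cluster and fusion label.
#' @export
reference_path_outcomes <- function() {
  df <- read.csv(system.file("extdata", "path_outcomes.csv",
                             package = "spinepath", mustWork = TRUE),
                 stringsAsFactors = FALSE, colClasses = list(fusion = "character"))
  tab <- as_path_outcome_table(df[, c("y2_1", "y2_2", "y2_3")],
                               sprintf("PO%d-EP%d-F%s", df$po, df$ep, df$fusion))
  attr(tab, "meta") <- df[, c("po", "ep", "fusion")]
  tab
}

#' Default planted path-to-outcome map
#'
#' Deterministic map from (PO cluster, EP cluster, fusion level) to the
#' planted two-year outcome cluster used by the synthetic generator. Where
#' the reference cohort's path table determines a modal outcome for a
#' (PO, EP, fusion) combination the map follows it; the remaining
#' combinations are filled by a fixed rule so every triple has a planted
#' outcome.
#'
#' @return Data frame with columns `po`, `ep`, `uiv`, `liv`, `y2`.
#' @export
default_outcome_map <- function() {
  lv <- reference_fusion_levels()
  # modal outcomes implied by the reference path table, keyed by the
  # reference group numbering 1..6 (G-number -> uiv/liv via lv)
  known <- rbind(
    data.frame(po = 1, ep = 1, g = c(2, 6, 3, 5), y2 = c(1, 1, 3, 3)),
    data.frame(po = 1, ep = 2, g = c(1, 2, 3, 4, 6), y2 = c(2, 2, 3, 3, 1)),
    data.frame(po = 2, ep = 1, g = c(1, 2, 3, 4, 5, 6), y2 = c(1, 1, 1, 3, 2, 2)),
    data.frame(po = 2, ep = 2, g = c(2, 4, 5), y2 = c(1, 2, 3)),
    data.frame(po = 3, ep = 1, g = c(1, 3, 4, 6), y2 = c(1, 2, 3, 1)))
  grid <- expand.grid(po = 1:3, ep = 1:2, g = seq_len(nrow(lv)),
                      KEEP.OUT.ATTRS = FALSE)
  key <- function(d) paste(d$po, d$ep, d$g)
  y2 <- known$y2[match(key(grid), key(known))]
  fill <- is.na(y2)
  y2[fill] <- ((grid$po[fill] + grid$ep[fill] + grid$g[fill]) %% 3L) + 1L
  data.frame(po = grid$po, ep = grid$ep,
             uiv = lv$uiv[grid$g], liv = lv$liv[grid$g],
             y2 = as.integer(y2), stringsAsFactors = FALSE)
}

#' Specify a synthetic cohort
#'
#' Parameters of the synthetic scoliotic cohort generator. Defaults mirror
#' the reference study conditions: 67 scoliotic patients whose fusion
#' levels follow the reference frequencies (including the two undersized
#' levels), 20 non-scoliotic controls, three pre-operative / two early
#' post-operative / three two-year shape clusters with membership
#' probabilities proportional to the reference cluster sizes, coordinate
#' noise of SD 0.02 in unit-height scale, and a planted path-to-outcome map
#' followed with fidelity `fidelity` (otherwise a different outcome cluster
#' is drawn uniformly).
#'
#' @param seed Integer seed for full reproducibility.
#' @param n_controls Number of control spines (default 20).
#' @param fusion_table Data frame `uiv`, `liv`, `n` of fusion levels and
#'   their patient counts (default: reference frequencies, 67 patients).
#' @param po_probs,ep_probs Cluster membership probabilities at PO and EP.
#' @param templates Shape templates (see [default_templates()]).
#' @param noise_sd Gaussian noise SD added to x and y, in unit-height
#'   scale (default 0.02).
#' @param height_range Range (mm) from which each spine's height is drawn
#'   uniformly (default 380-480).
#' @param outcome_map Planted map (see [default_outcome_map()]).
#' @param fidelity Probability that a patient's realized two-year cluster
#'   equals the planted one (default 0.85, in (0, 1]).
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(seed = 20181102L,
                        n_controls = 20L,
                        fusion_table = NULL,
                        po_probs = c(24, 21, 19) / 64,
                        ep_probs = c(41, 23) / 64,
                        templates = default_templates(),
                        noise_sd = 0.02,
                        height_range = c(380, 480),
                        outcome_map = default_outcome_map(),
                        fidelity = 0.85) {
  if (is.null(fusion_table)) {
    lv <- reference_fusion_levels()
    fusion_table <- lv[, c("uiv", "liv", "n")]
  }
  stopifnot(all(fusion_table$n > 0), noise_sd >= 0,
            fidelity > 0, fidelity <= 1,
            length(po_probs) == length(templates$PO),
            length(ep_probs) == length(templates$EP),
            abs(sum(po_probs) - 1) < 1e-8, abs(sum(ep_probs) - 1) < 1e-8,
            height_range[1L] > 0, height_range[2L] >= height_range[1L])
  structure(list(seed = as.integer(seed), n_controls = as.integer(n_controls),
                 fusion_table = fusion_table, po_probs = po_probs,
                 ep_probs = ep_probs, templates = templates,
                 noise_sd = noise_sd, height_range = height_range,
                 outcome_map = outcome_map, fidelity = fidelity),
            class = "cohort_spec")
}

# build one spine from a template: equally spaced z over a sampled height,
# template x,y scaled isotropically to that height, Gaussian noise on x,y
.spine_from_template <- function(tpl, patient_id, timepoint, height,
                                 noise_sd) {
  z <- seq(1, 0, length.out = 17L)
  xy <- .eval_template(tpl, z)
  x <- (xy$x + rnorm(17L, 0, noise_sd)) * height
  y <- (xy$y + rnorm(17L, 0, noise_sd)) * height
  centroid_spine(patient_id, timepoint, cbind(x = x, y = y, z = z * height))
}

#' Generate one control spine
#'
#' A non-scoliotic spine: x identically zero up to noise, sagittal
#' curvature from the control template (thoracic kyphosis and lumbar
#' lordosis lobes), z equally spaced over a height drawn from
#' `height_range`. Noise is added to x and y only, so z is always strictly
#' decreasing.
#'
#' @param spec A `cohort_spec`.
#' @param patient_id Identifier for the generated spine.
#' @return A `centroid_spine` with timepoint `"CONTROL"`.
#' @export
generate_control <- function(spec, patient_id = "C01") {
  stopifnot(inherits(spec, "cohort_spec"))
  h <- runif(1L, spec$height_range[1L], spec$height_range[2L])
  .spine_from_template(spec$templates$CONTROL[[1L]], patient_id, "CONTROL",
                       h, spec$noise_sd)
}

#' Generate one scoliotic spine
#'
#' Draws a spine from the given cluster's template at the given timepoint:
#' frontal profile as a sum of smooth lobes plus the cluster's lateral
#' shift, sagittal profile from the cluster's kyphosis/lordosis lobes,
#' Gaussian noise of SD `noise_sd` (unit-height scale) on x and y.
#'
#' @param spec A `cohort_spec`.
#' @param cluster_id Cluster index within the timepoint's template list.
#' @param timepoint `"PO"`, `"EP"` or `"Y2"`.
#' @param patient_id Identifier for the generated spine.
#' @return A `centroid_spine`.
#' @export
generate_scoliotic <- function(spec, cluster_id, timepoint,
                               patient_id = "P01") {
  stopifnot(inherits(spec, "cohort_spec"))
  timepoint <- match.arg(timepoint, c("PO", "EP", "Y2"))
  tpls <- spec$templates[[timepoint]]
  if (cluster_id < 1L || cluster_id > length(tpls))
    stop("cluster_id out of range for timepoint ", timepoint)
  h <- runif(1L, spec$height_range[1L], spec$height_range[2L])
  .spine_from_template(tpls[[cluster_id]], patient_id, timepoint, h,
                       spec$noise_sd)
}

#' Generate a full synthetic cohort
#'
#' For each scoliotic patient: the PO cluster and EP cluster are sampled
#' from the spec's membership probabilities, the fusion level is fixed by
#' the spec's frequency table, the planted two-year outcome is looked up in
#' the outcome map and followed with probability `fidelity` (otherwise a
#' different cluster is drawn uniformly), and the PO/EP/Y2 spines are
#' generated from the corresponding templates. Controls are generated from
#' the control template. Fully reproducible from `spec$seed`.
#'
#' @param spec A `cohort_spec`.
#' @return List of class `synthetic_cohort`: `landmarks` (long-format data
#'   frame including controls), `fusions` (patient_id, uiv, liv), `truth`
#'   (per-patient PO/EP/Y2 clusters, planted outcome, fusion level) and
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(spec$seed, {
    ft <- spec$fusion_table
    n <- sum(ft$n)
    ids <- sprintf("P%03d", seq_len(n))
    lvl <- rep(seq_len(nrow(ft)), ft$n)
    po <- sample.int(length(spec$po_probs), n, replace = TRUE,
                     prob = spec$po_probs)
    ep <- sample.int(length(spec$ep_probs), n, replace = TRUE,
                     prob = spec$ep_probs)
    map <- spec$outcome_map
    mk <- paste(map$po, map$ep, map$uiv, map$liv)
    planted <- map$y2[match(paste(po, ep, ft$uiv[lvl], ft$liv[lvl]), mk)]
    if (anyNA(planted)) stop("outcome map does not cover every (po, ep, fusion) triple")
    n_y2 <- length(spec$templates$Y2)
    flip <- runif(n) > spec$fidelity
    y2 <- planted
    y2[flip] <- vapply(planted[flip], function(p)
      sample(setdiff(seq_len(n_y2), p), 1L), integer(1L))
    spines <- vector("list", 3L * n + spec$n_controls)
    j <- 0L
    for (i in seq_len(n)) {
      spines[[j + 1L]] <- generate_scoliotic(spec, po[i], "PO", ids[i])
      spines[[j + 2L]] <- generate_scoliotic(spec, ep[i], "EP", ids[i])
      spines[[j + 3L]] <- generate_scoliotic(spec, y2[i], "Y2", ids[i])
      j <- j + 3L
    }
    for (c in seq_len(spec$n_controls))
      spines[[j + c]] <- generate_control(spec, sprintf("C%03d", c))
    truth <- data.frame(patient_id = ids, po = po, ep = ep, y2 = y2,
                        planted_y2 = planted, uiv = ft$uiv[lvl],
                        liv = ft$liv[lvl], stringsAsFactors = FALSE)
    structure(list(landmarks = spines_to_data_frame(spines),
                   fusions = truth[, c("patient_id", "uiv", "liv")],
                   truth = truth, spec = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d controls, fidelity %.2f, seed %d\n",
              nrow(x$truth), x$spec$n_controls, x$spec$fidelity, x$spec$seed))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits `landmarks.csv`, `fusions.csv` and `truth.csv` into `dir`.
#' Landmark coordinates are written at full precision so the same seed
#' yields byte-identical files.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lm <- cohort$landmarks
  for (col in c("x_mm", "y_mm", "z_mm")) lm[[col]] <- sprintf("%.17g", lm[[col]])
  write.csv(lm, file.path(dir, "landmarks.csv"), row.names = FALSE, quote = FALSE)
  write.csv(cohort$fusions, file.path(dir, "fusions.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}
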