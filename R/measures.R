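#' Tangent-angle curve measure
#'
#' Centroid-curve surrogate for the clinical Cobb angle: the curve is
#' projected onto the frontal (x, z) or sagittal (y, z) plane, the tangent
#' direction is estimated at every vertebra in the span (central
#' differences, one-sided at the span ends) and the absolute angle between
#' the maximal and minimal tangent directions is returned, in degrees.
#' The measure is invariant to rigid translation and isotropic scaling.
#'
#' @param curve A `centroid_spine`, `scaled_spine` or `normalized_curve`.
#' @param plane `"frontal"` or `"sagittal"`.
#' @param span Character vector `c(from, to)` of vertebral labels bounding
#'   the span (inclusive, cranial first); must contain at least 3
#'   vertebrae.
#' @return Angle in degrees (nonnegative).
#' @export
tangent_angle_measure <- function(curve, plane = c("frontal", "sagittal"),
                                  span = c("T1", "L5")) {
  plane <- match.arg(plane)
  if (inherits(curve, "normalized_curve")) {
    v <- if (plane == "frontal") curve$x else curve$y
    z <- curve$z
  } else if (inherits(curve, "centroid_spine")) {
    v <- curve$coords[, if (plane == "frontal") "x" else "y"]
    z <- curve$coords[, "z"]
  } else stop("unsupported curve object")
  i1 <- .vert_index(span[1L]); i2 <- .vert_index(span[2L])
  if (is.na(i1) || is.na(i2) || i1 >= i2) stop("invalid span")
  idx <- i1:i2
  if (length(idx) < 3L) stop("span must contain at least 3 vertebrae")
  v <- v[idx]; z <- z[idx]
  m <- length(idx)
  slope <- numeric(m)
  slope[1L] <- (v[2L] - v[1L]) / (z[2L] - z[1L])
  slope[m] <- (v[m] - v[m - 1L]) / (z[m] - z[m - 1L])
  if (m > 2L)
    slope[2:(m - 1L)] <- (v[3:m] - v[1:(m - 2L)]) / (z[3:m] - z[1:(m - 2L)])
  ang <- atan(slope) * 180 / pi   # tangent direction relative to vertical
  abs(max(ang) - min(ang))
}

#' Frontal and sagittal balance offsets
#'
#' Horizontal offset of T1 relative to L5: `x(T1) - x(L5)` in the coronal
#' plane (frontal balance) and `y(T1) - y(L5)` in the sagittal plane
#' (sagittal balance), in the input units. Invariant to rigid translation.
#'
#' @param spine A `centroid_spine` (or scaled spine / normalized curve).
#' @return Named numeric vector `c(frontal, sagittal)`.
#' @export
balance_offsets <- function(spine) {
  if (inherits(spine, "normalized_curve"))
    return(c(frontal = unname(spine$x["T1"] - spine$x["L5"]),
             sagittal = unname(spine$y["T1"] - spine$y["L5"])))
  stopifnot(inherits(spine, "centroid_spine"))
  c(frontal = unname(spine$coords["T1", "x"] - spine$coords["L5", "x"]),
    sagittal = unname(spine$coords["T1", "y"] - spine$coords["L5", "y"]))
}

#' Standard curve measurement set
#'
#' The centroid-curve surrogates reported per patient/timepoint: frontal
#' tangent angles for the proximal thoracic (T1-T6), main thoracic (T5-T12)
#' and lumbar (T12-L5) regions; sagittal tangent angles for T1-T12 and
#' T4-T12 thoracic kyphosis and L1-L5 lumbar lordosis (centroids end at L5,
#' so the lordosis span stops there); and the frontal/sagittal balance
#' offsets. These approximate, on the centroid curve, the clinical frontal
#' Cobb angles, kyphosis/lordosis angles and balance measurements taken
#' from radiographs; image-only quantities (apical rotations, pelvic
#' parameters) are not computed and can be carried as pass-through columns.
#'
#' @param curve A `centroid_spine` or `normalized_curve`.
#' @return Named numeric vector with elements `ptc`, `mtc`, `lc`,
#'   `tk_t1t12`, `tk_t4t12`, `ll`, `fb`, `sb`.
#' @export
spine_measures <- function(curve) {
  bal <- balance_offsets(curve)
  c(ptc = tangent_angle_measure(curve, "frontal", c("T1", "T6")),
    mtc = tangent_angle_measure(curve, "frontal", c("T5", "T12")),
    lc = tangent_angle_measure(curve, "frontal", c("T12", "L5")),
    tk_t1t12 = tangent_angle_measure(curve, "sagittal", c("T1", "T12")),
    tk_t4t12 = tangent_angle_measure(curve, "sagittal", c("T4", "T12")),
    ll = tangent_angle_measure(curve, "sagittal", c("L1", "L5")),
    fb = unname(bal["frontal"]),
    sb = unname(bal["sagittal"]))
}

#' Dunn's rank-based post-hoc test
#'
#' Pairwise z-tests on mean ranks after a Kruskal-Wallis omnibus test, with
#' the usual tie correction. P-values are unadjusted by default; a
#' multiplicity adjustment can be requested via `p_adjust`
#' (see [stats::p.adjust()]).
#'
#' @param x Numeric response vector.
#' @param g Grouping vector (coercible to factor).
#' @param p_adjust Adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return Data frame with columns `group1`, `group2`, `z`, `p_value`.
#' @export
dunn_test <- function(x, g, p_adjust = "none") {
  g <- factor(g)
  stopifnot(length(x) == length(g), nlevels(g) >= 2L)
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  pairs <- utils::combn(levels(g), 2L)
  z <- apply(pairs, 2L, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[p[1L]] + 1 / ns[p[2L]]))
    (rbar[p[1L]] - rbar[p[2L]]) / se
  })
  p <- stats::p.adjust(2 * pnorm(abs(z), lower.tail = FALSE), method = p_adjust)
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             z = as.numeric(z), p_value = as.numeric(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Between-cluster comparison of curve measurements
#'
#' For each measurement variable: Shapiro-Wilk normality is tested within
#' every cluster at level `alpha`; if all clusters pass, a one-way ANOVA
#' with Tukey HSD post-hoc is used, otherwise Kruskal-Wallis with Dunn's
#' post-hoc. Exactly one omnibus test is run per variable.
#'
#' @param measures Data frame or matrix of measurements, one row per
#'   patient, one column per variable.
#' @param labels Cluster labels, one per row of `measures`; at least two
#'   clusters with at least `min_n` patients each.
#' @param alpha Significance level (default 0.05).
#' @param min_n Minimum cluster size (default 3).
#' @param p_adjust Multiplicity adjustment for Dunn's test (default
#'   `"none"`).
#' @return Object of class `cluster_comparison`: named list per variable
#'   with `normal` (all clusters pass Shapiro-Wilk), `test` (`"anova"` or
#'   `"kruskal"`), `statistic`, `p_value`, `significant`, and `pairwise`
#'   (data frame of post-hoc comparisons with a `significant` flag at
#'   `alpha`).
#' @export
compare_clusters <- function(measures, labels, alpha = 0.05, min_n = 3L,
                             p_adjust = "none") {
  measures <- as.data.frame(measures)
  g <- factor(labels)
  stopifnot(nrow(measures) == length(g))
  if (nlevels(g) < 2L) stop("need at least two clusters")
  if (any(table(g) < min_n))
    stop("every cluster must have at least ", min_n, " patients")
  out <- lapply(measures, function(x) {
    sw_p <- vapply(split(x, g), function(v) {
      if (length(unique(v)) < 3L) return(0)  # constant: treat as non-normal
      shapiro.test(v)$p.value
    }, numeric(1L))
    normal <- all(sw_p > alpha)
    if (normal) {
      fit <- aov(x ~ g)
      an <- summary(fit)[[1L]]
      stat <- an[["F value"]][1L]
      p <- an[["Pr(>F)"]][1L]
      tk <- TukeyHSD(fit)$g
      pw <- data.frame(
        group1 = sub("-.*", "", rownames(tk)),
        group2 = sub(".*-", "", rownames(tk)),
        estimate = tk[, "diff"], p_value = tk[, "p adj"],
        row.names = NULL, stringsAsFactors = FALSE)
      test <- "anova"
    } else {
      kw <- kruskal.test(x, g)
      stat <- unname(kw$statistic)
      p <- kw$p.value
      pw <- dunn_test(x, g, p_adjust = p_adjust)
      names(pw)[names(pw) == "z"] <- "estimate"
      test <- "kruskal"
    }
    pw$significant <- pw$p_value < alpha
    list(normal = normal, shapiro_p = sw_p, test = test, statistic = stat,
         p_value = p, significant = is.finite(p) && p < alpha,
         pairwise = pw)
  })
  structure(out, class = "cluster_comparison", alpha = alpha)
}

#' @export
print.cluster_comparison <- function(x, ...) {
  cat("<cluster_comparison> alpha =", attr(x, "alpha"), "\n")
  for (v in names(x)) {
    cat(sprintf("  %-10s %-8s stat = %8.3f  p = %.4f%s\n", v, x[[v]]$test,
                x[[v]]$statistic, x[[v]]$p_value,
                if (isTRUE(x[[v]]$significant)) " *" else ""))
  }
  invisible(x)
}

#' Cluster summary table of curve measurements
#'
#' Per-cluster mean and standard deviation of every measurement variable,
#' with the omnibus p-value from [compare_clusters()].
#'
#' @inheritParams compare_clusters
#' @return Data frame: variable, one `mean_sd` column per cluster, test
#'   used, omnibus p-value.
#' @export
measure_summary_table <- function(measures, labels, alpha = 0.05,
                                  min_n = 3L) {
  measures <- as.data.frame(measures)
  g <- factor(labels)
  cmp <- compare_clusters(measures, labels, alpha = alpha, min_n = min_n)
  rows <- lapply(names(measures), function(v) {
    ms <- vapply(split(measures[[v]], g), function(x)
      sprintf("%.1f ± %.1f", mean(x), sd(x)), character(1L))
    cbind(data.frame(variable = v, stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(ms, paste0("cluster", levels(g)))),
                        stringsAsFactors = FALSE),
          data.frame(test = cmp[[v]]$test, p_value = cmp[[v]]$p_value,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
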