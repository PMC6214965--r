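#' @useDynLib spinepath, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx aov dist kruskal.test pchisq pnorm qbinom rnorm
#'   runif sd setNames shapiro.test TukeyHSD predict coef simulate residuals
#'   complete.cases
#' @importFrom utils read.csv write.csv
NULL

#' Vertebral labels in anatomical order
#'
#' The 17 vertebral levels carried by every spinal curve, cranial to caudal:
#' the twelve thoracic vertebrae T1--T12 followed by the five lumbar
#' vertebrae L1--L5.
#'
#' @return Character vector of length 17.
#' @export
#' @examples
#' vertebral_labels()
vertebral_labels <- function() {
  c(paste0("T", 1:12), paste0("L", 1:5))
}

.VERTEBRAE <- c(paste0("T", 1:12), paste0("L", 1:5))
.TIMEPOINTS <- c("PO", "EP", "Y2", "CONTROL")

# index of a vertebral label in anatomical (cranial-to-caudal) order
.vert_index <- function(label) match(label, .VERTEBRAE)

#' Construct a vertebral-centroid spine
#'
#' A `centroid_spine` holds one patient/timepoint's 17 vertebral-body
#' centroids (T1--L5) in millimetres. Axis convention: x is frontal-lateral
#' (+ toward the patient's left), y is sagittal (+ anterior), z is vertical
#' (+ cranial). z must be strictly decreasing from T1 down to L5.
#'
#' @param patient_id Patient identifier (scalar character).
#' @param timepoint One of `"PO"` (pre-operative), `"EP"` (early
#'   post-operative), `"Y2"` (two-year follow-up), `"CONTROL"`.
#' @param coords Numeric 17 x 3 matrix of centroid coordinates in mm, rows in
#'   anatomical order T1..L5, columns x, y, z.
#' @return An object of class `centroid_spine`.
#' @export
centroid_spine <- function(patient_id, timepoint, coords) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  timepoint <- match.arg(timepoint, .TIMEPOINTS)
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || nrow(coords) != 17L || ncol(coords) != 3L)
    stop("coords must be a numeric 17 x 3 matrix (T1..L5 x x,y,z)")
  dimnames(coords) <- list(.VERTEBRAE, c("x", "y", "z"))
  obj <- structure(
    list(patient_id = patient_id, timepoint = timepoint,
         vertebrae = .VERTEBRAE, coords = coords),
    class = "centroid_spine")
  validate_spine(obj)
  obj
}

#' Validate a centroid spine
#'
#' Checks the structural invariants: exactly 17 vertebrae in fixed anatomical
#' order, finite coordinates, and z strictly decreasing from T1 to L5.
#'
#' @param spine A `centroid_spine`.
#' @return The spine, invisibly; errors if an invariant fails.
#' @export
validate_spine <- function(spine) {
  if (!inherits(spine, "centroid_spine")) stop("not a centroid_spine")
  who <- sprintf("patient '%s' timepoint '%s'", spine$patient_id, spine$timepoint)
  if (!identical(spine$vertebrae, .VERTEBRAE))
    stop("vertebrae out of order or incomplete for ", who)
  if (!all(is.finite(spine$coords)))
    stop("non-finite coordinates for ", who)
  z <- spine$coords[, "z"]
  bad <- which(diff(z) >= 0)
  if (length(bad))
    stop(sprintf("z not strictly decreasing at %s (between %s and %s)",
                 who, .VERTEBRAE[bad[1L]], .VERTEBRAE[bad[1L] + 1L]))
  invisible(spine)
}

#' @export
print.centroid_spine <- function(x, ...) {
  cat(sprintf("<centroid_spine> patient %s, timepoint %s, height %.1f mm\n",
              x$patient_id, x$timepoint,
              x$coords["T1", "z"] - x$coords["L5", "z"]))
  invisible(x)
}

#' Read vertebral-centroid landmarks
#'
#' Reads a long-format landmark table (one row per vertebra) into a list of
#' [centroid_spine] objects, one per (patient, timepoint). Required columns:
#' `patient_id`, `timepoint`, `vertebra`, `x_mm`, `y_mm`, `z_mm`. Timepoint
#' tokens must be one of PO, EP, Y2, CONTROL; every spine must carry all 17
#' vertebrae T1..L5 exactly once with strictly decreasing z.
#'
#' @param x Path to a CSV file, or a data frame already in that layout.
#' @return Named list of `centroid_spine` objects; names are
#'   `"<patient_id>.<timepoint>"`.
#' @export
read_landmarks <- function(x) {
  df <- if (is.character(x)) {
    if (!file.exists(x)) stop("file not found: ", x)
    read.csv(x, stringsAsFactors = FALSE)
  } else as.data.frame(x)
  need <- c("patient_id", "timepoint", "vertebra", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad_tp <- setdiff(unique(df$timepoint), .TIMEPOINTS)
  if (length(bad_tp))
    stop("unknown timepoint token(s): ", paste(bad_tp, collapse = ", "))
  bad_v <- setdiff(unique(df$vertebra), .VERTEBRAE)
  if (length(bad_v))
    stop("unknown vertebra label(s): ", paste(bad_v, collapse = ", "))
  key <- paste(df$patient_id, df$timepoint, sep = ".")
  out <- lapply(split(df, factor(key, levels = unique(key))), function(g) {
    who <- sprintf("patient '%s' timepoint '%s'", g$patient_id[1L], g$timepoint[1L])
    if (anyDuplicated(g$vertebra))
      stop("duplicate vertebra ", g$vertebra[duplicated(g$vertebra)][1L],
           " for ", who)
    missing_v <- setdiff(.VERTEBRAE, g$vertebra)
    if (length(missing_v))
      stop("missing vertebra ", missing_v[1L], " for ", who)
    g <- g[order(.vert_index(g$vertebra)), ]
    centroid_spine(as.character(g$patient_id[1L]), g$timepoint[1L],
                   cbind(x = g$x_mm, y = g$y_mm, z = g$z_mm))
  })
  out
}

#' Write vertebral-centroid landmarks
#'
#' Inverse of [read_landmarks()]: writes a list of spines as a long-format
#' CSV with full numeric precision so that write-then-read round-trips
#' bit-exactly.
#'
#' @param spines List of `centroid_spine` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(spines, path) {
  df <- spines_to_data_frame(spines)
  # full precision so read_landmarks() reproduces coordinates bit-exactly
  df$x_mm <- sprintf("%.17g", df$x_mm)
  df$y_mm <- sprintf("%.17g", df$y_mm)
  df$z_mm <- sprintf("%.17g", df$z_mm)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flatten spines to a long-format data frame
#'
#' @param spines List of `centroid_spine` objects.
#' @return Data frame with columns patient_id, timepoint, vertebra, x_mm,
#'   y_mm, z_mm.
#' @export
spines_to_data_frame <- function(spines) {
  if (inherits(spines, "centroid_spine")) spines <- list(spines)
  do.call(rbind, lapply(spines, function(s) {
    data.frame(patient_id = s$patient_id, timepoint = s$timepoint,
               vertebra = s$vertebrae,
               x_mm = s$coords[, "x"], y_mm = s$coords[, "y"],
               z_mm = s$coords[, "z"], row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

#' Read fusion-level assignments
#'
#' Reads per-patient instrumented levels: the upper (UIV) and lower (LIV)
#' instrumented vertebrae. The UIV must be strictly cranial to the LIV in
#' the T1..L5 ordering.
#'
#' @param x Path to a CSV with columns `patient_id`, `uiv`, `liv`, or a data
#'   frame in that layout.
#' @return Data frame of class `fusion_assignment` with validated columns
#'   patient_id, uiv, liv.
#' @export
read_fusions <- function(x) {
  df <- if (is.character(x)) {
    if (!file.exists(x)) stop("file not found: ", x)
    read.csv(x, stringsAsFactors = FALSE)
  } else as.data.frame(x)
  need <- c("patient_id", "uiv", "liv")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  for (col in c("uiv", "liv")) {
    bad <- setdiff(unique(df[[col]]), .VERTEBRAE)
    if (length(bad))
      stop("unknown vertebral label in ", col, ": ", paste(bad, collapse = ", "))
  }
  inverted <- .vert_index(df$uiv) >= .vert_index(df$liv)
  if (any(inverted))
    stop("uiv not cranial to liv for patient '",
         df$patient_id[which(inverted)[1L]], "'")
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id: ", df$patient_id[duplicated(df$patient_id)][1L])
  class(df) <- c("fusion_assignment", "data.frame")
  df[, need]
}

#' Pipeline configuration
#'
#' Tunable settings shared across the fitting pipeline.
#'
#' @param k_range Candidate numbers of clusters searched by silhouette
#'   (default 2:6).
#' @param restarts K-means++ restarts per k (default 100).
#' @param seed Integer seed making clustering reproducible
#'   (default 20181102).
#' @param min_group_n Minimum fusion-group size; smaller groups are excluded
#'   (default 3).
#' @param min_path_n Minimum path size for concordance reporting (default 3,
#'   i.e. "more than two patients").
#' @param alpha Significance level for all tests (default 0.05).
#' @param encoding Multinomial-regression encoding: `"main"` for the three
#'   nominal main effects PO + EP + F, or `"saturated"` for a single
#'   path factor.
#' @return A list of class `spinepath_config`.
#' @export
spinepath_config <- function(k_range = 2:6, restarts = 100L, seed = 20181102L,
                             min_group_n = 3L, min_path_n = 3L, alpha = 0.05,
                             encoding = c("main", "saturated")) {
  encoding <- match.arg(encoding)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L || any(k_range < 2L))
    stop("k_range must contain integers >= 2")
  if (min_group_n < 1L) stop("min_group_n must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(k_range = k_range, restarts = as.integer(restarts),
                 seed = as.integer(seed), min_group_n = as.integer(min_group_n),
                 min_path_n = as.integer(min_path_n), alpha = alpha,
                 encoding = encoding),
            class = "spinepath_config")
}

# evaluate code under a temporary RNG seed, restoring the caller's stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
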