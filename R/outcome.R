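#' Cross-tabulate treatment paths against two-year outcomes
#'
#' Counts, for every treatment path, how many of its patients fall in each
#' two-year outcome cluster. Row sums are the path sizes and the grand total
#' is the number of included patients.
#'
#' @param paths A `treatment_paths` data frame (see [build_paths()] or
#'   [merge_equivalent_fusion_groups()]).
#' @param y2_labels Integer two-year cluster labels named by patient id.
#' @return Integer matrix of class `path_outcome_table`; rows are path
#'   strings (in first-appearance order), columns `2Y1..2YK`.
#' @export
path_outcome_table <- function(paths, y2_labels) {
  stopifnot(inherits(paths, "treatment_paths"))
  ids <- paths$patient_id
  miss <- ids[!ids %in% names(y2_labels)]
  if (length(miss)) stop("no 2Y cluster label for patient '", miss[1L], "'")
  y2 <- as.integer(y2_labels[ids])
  ks <- sort(unique(y2))
  tab <- table(factor(paths$path, levels = unique(paths$path)),
               factor(y2, levels = seq_len(max(ks))))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab),
                              paste0("2Y", seq_len(ncol(tab)))))
  structure(m, class = c("path_outcome_table", class(m)))
}

#' Assemble a path-outcome table from printed counts
#'
#' Builds a `path_outcome_table` directly from per-path outcome counts
#' (e.g. a published contingency table) rather than from patient-level
#' labels.
#'
#' @param counts Numeric matrix or data frame of nonnegative integers, one
#'   row per path, one column per outcome cluster.
#' @param path_names Character vector of path strings (rownames).
#' @return A `path_outcome_table`.
#' @export
as_path_outcome_table <- function(counts, path_names = rownames(counts)) {
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  storage.mode(m) <- "integer"
  if (is.null(path_names)) stop("path names are required")
  dimnames(m) <- list(path_names, paste0("2Y", seq_len(ncol(m))))
  structure(m, class = c("path_outcome_table", class(m)))
}

#' Per-path concordance and cohort coverage
#'
#' For every path with at least `min_path_n` patients, reports the modal
#' ("majority") two-year outcome cluster and the fraction of the path's
#' patients in it; coverage is the share of all included patients that
#' belong to such qualifying paths. Percentages are also reported rounded to
#' the nearest integer. Modal ties are broken toward the lower cluster
#' index.
#'
#' @param table A `path_outcome_table`.
#' @param min_path_n Minimum path size to qualify (default 3, i.e. more
#'   than two patients).
#' @return List with `per_path` (data frame: path, n, majority, fraction,
#'   percent), `n_paths` (qualifying), `patients_covered`, `total_patients`,
#'   `coverage` and `coverage_percent`.
#' @export
concordance <- function(table, min_path_n = 3L) {
  stopifnot(inherits(table, "path_outcome_table"))
  n_path <- rowSums(table)
  total <- sum(table)
  qual <- which(n_path >= min_path_n)
  per_path <- data.frame(
    path = rownames(table)[qual],
    n = as.integer(n_path[qual]),
    majority = apply(table[qual, , drop = FALSE], 1L, which.max),
    fraction = apply(table[qual, , drop = FALSE], 1L, max) / n_path[qual],
    row.names = NULL, stringsAsFactors = FALSE)
  per_path$percent <- round(100 * per_path$fraction)
  covered <- sum(n_path[qual])
  list(per_path = per_path,
       n_paths = length(qual),
       patients_covered = as.integer(covered),
       total_patients = as.integer(total),
       coverage = covered / total,
       coverage_percent = round(100 * covered / total))
}

# multinomial log-likelihood of a counts matrix at its saturated (per-row
# proportions) MLE, and at the intercept-only (pooled proportions) MLE
.loglik_saturated <- function(m) {
  p <- m / pmax(rowSums(m), 1)
  sum(m[m > 0] * log(p[m > 0]))
}
.loglik_null <- function(m) {
  cs <- colSums(m)
  n <- sum(cs)
  sum(cs[cs > 0] * log(cs[cs > 0] / n))
}

#' Multinomial regression of the two-year outcome on the treatment path
#'
#' Fits a multinomial logistic model predicting the two-year outcome
#' cluster 2Y_k from the treatment-path components and tests it against the
#' intercept-only model with a likelihood-ratio (LR) chi-square.
#'
#' Two encodings are available. `"main"` enters PO cluster, EP cluster and
#' fusion group as three nominal main-effect factors (fitted with
#' [nnet::multinom()]). `"saturated"` enters the full path as a single
#' factor; its maximum-likelihood fit is closed-form (the fitted outcome
#' probabilities of a path are its observed outcome proportions), so the LR
#' statistic equals the contingency G-statistic of the path-by-outcome
#' table, and zero cells (complete separation) are handled exactly rather
#' than by divergent iteration; separated coefficients are reported as
#' infinite and flagged. In both encodings
#' `df = (non-intercept coefficients per equation) * (K - 1)`.
#'
#' @param po,ep,fusion_group Per-patient path components (integer vectors).
#' @param y2 Per-patient two-year outcome cluster (integer vector, at least
#'   two distinct values).
#' @param encoding `"main"` (default) or `"saturated"`.
#' @return Object of class `path_multinom`: list with `encoding`, `model`
#'   (the `multinom` fit, or the per-path probability table when
#'   saturated), `coefficients`, `lr` (list `chi_square`, `df`, `p_value`)
#'   and `separation` (logical flag).
#' @export
fit_multinomial <- function(po, ep, fusion_group, y2,
                            encoding = c("main", "saturated")) {
  encoding <- match.arg(encoding)
  n <- length(y2)
  stopifnot(length(po) == n, length(ep) == n, length(fusion_group) == n)
  y2 <- factor(y2)
  K <- nlevels(y2)
  if (K < 2L) stop("need at least two outcome categories")
  if (any(table(y2) == 0L)) stop("empty outcome category")

  if (encoding == "saturated") {
    path <- factor(paste(po, ep, fusion_group, sep = "-"))
    m <- as.matrix(table(path, y2))
    chi <- 2 * (.loglik_saturated(m) - .loglik_null(m))
    df <- (nlevels(path) - 1L) * (K - 1L)
    probs <- m / rowSums(m)
    # baseline-category logits; zero cells give -Inf (separation)
    coefs <- log(probs[, -1L, drop = FALSE] / probs[, 1L])
    separation <- any(!is.finite(coefs))
    lr <- list(chi_square = chi, df = df,
               p_value = pchisq(chi, df, lower.tail = FALSE))
    return(structure(list(encoding = encoding, model = probs,
                          coefficients = coefs, lr = lr,
                          separation = separation),
                     class = "path_multinom"))
  }

  dat <- data.frame(y2 = y2, po = factor(po), ep = factor(ep),
                    fg = factor(fusion_group))
  fit <- nnet::multinom(y2 ~ po + ep + fg, data = dat, trace = FALSE,
                        maxit = 500, reltol = 1e-12)
  fit0 <- nnet::multinom(y2 ~ 1, data = dat, trace = FALSE)
  chi <- fit0$deviance - fit$deviance
  p_per_eq <- length(fit$coefnames) - 1L   # non-intercept coefficients
  df <- p_per_eq * (K - 1L)
  separation <- any(abs(coef(fit)) > 15)
  lr <- list(chi_square = chi, df = df,
             p_value = pchisq(chi, df, lower.tail = FALSE))
  structure(list(encoding = encoding, model = fit,
                 coefficients = coef(fit), lr = lr,
                 separation = separation,
                 xlevels = lapply(dat[c("po", "ep", "fg")], levels)),
            class = "path_multinom")
}

#' @export
print.path_multinom <- function(x, ...) {
  cat(sprintf("<path_multinom> encoding = %s; LR chi-square = %.3f, df = %d, p = %.3g%s\n",
              x$encoding, x$lr$chi_square, x$lr$df, x$lr$p_value,
              if (x$separation) " [separation flagged]" else ""))
  invisible(x)
}

#' Predict the two-year outcome of a treatment path
#'
#' Empirical mode looks a path up in a fitted [path_outcome_table] and
#' returns its modal outcome cluster; a path never seen in training yields
#' an explicit no-data result (`NA` with status `"no-data"`), not a guess.
#' Model mode returns the argmax predicted probability from a
#' [fit_multinomial()] fit. Modal/probability ties are broken toward the
#' lower cluster index and flagged as ambiguous.
#'
#' @param paths Character vector of path strings (empirical mode) or a data
#'   frame with columns po, ep, fusion_group (model mode).
#' @param object A `path_outcome_table` (empirical) or `path_multinom`
#'   (model).
#' @return Data frame with columns `path`, `outcome` (integer or NA) and
#'   `status` (`"ok"`, `"ambiguous"` or `"no-data"`).
#' @export
predict_outcome <- function(paths, object) {
  if (inherits(object, "path_outcome_table")) {
    stopifnot(is.character(paths))
    out <- lapply(paths, function(p) {
      if (!p %in% rownames(object))
        return(list(outcome = NA_integer_, status = "no-data"))
      row <- object[p, ]
      top <- which(row == max(row))
      list(outcome = top[1L],
           status = if (length(top) > 1L) "ambiguous" else "ok")
    })
    return(data.frame(path = paths,
                      outcome = vapply(out, `[[`, integer(1L), "outcome"),
                      status = vapply(out, `[[`, character(1L), "status"),
                      stringsAsFactors = FALSE))
  }
  if (inherits(object, "path_multinom")) {
    stopifnot(is.data.frame(paths))
    if (object$encoding == "saturated") {
      key <- paste(paths$po, paths$ep, paths$fusion_group, sep = "-")
      probs <- object$model
      out <- lapply(key, function(kk) {
        if (!kk %in% rownames(probs))
          return(list(outcome = NA_integer_, status = "no-data"))
        row <- probs[kk, ]
        top <- which(row == max(row))
        list(outcome = top[1L],
             status = if (length(top) > 1L) "ambiguous" else "ok")
      })
      return(data.frame(path = sprintf("PO%s-EP%s-F%s", paths$po, paths$ep,
                                       paths$fusion_group),
                        outcome = vapply(out, `[[`, integer(1L), "outcome"),
                        status = vapply(out, `[[`, character(1L), "status"),
                        stringsAsFactors = FALSE))
    }
    xl <- object$xlevels
    nd <- data.frame(po = factor(paths$po, levels = xl$po),
                     ep = factor(paths$ep, levels = xl$ep),
                     fg = factor(paths$fusion_group, levels = xl$fg))
    seen <- stats::complete.cases(nd)
    outcome <- rep(NA_integer_, nrow(nd))
    status <- rep("no-data", nrow(nd))
    if (any(seen)) {
      pr <- predict(object$model, newdata = nd[seen, , drop = FALSE],
                    type = "probs")
      if (is.null(dim(pr))) pr <- matrix(pr, nrow = sum(seen))
      outcome[seen] <- as.integer(apply(pr, 1L, which.max))
      ties <- apply(pr, 1L, function(r) sum(r == max(r)) > 1L)
      status[seen] <- ifelse(ties, "ambiguous", "ok")
    }
    return(data.frame(path = sprintf("PO%s-EP%s-F%s", paths$po, paths$ep,
                                     paths$fusion_group),
                      outcome = outcome, status = status,
                      stringsAsFactors = FALSE))
  }
  stop("object must be a path_outcome_table or path_multinom")
}
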