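# Classification and statistics: Fisher LDA, diagnostic metrics, pooled
# Student's t-tests and p-value heatmap, covariance confidence ellipses,
# blind validation, and the SAXS power-law (mass fractal dimension) fit.

#' Donor-level fingerprint cohort
#'
#' One 2-D fingerprint (starting position mm, levitating area) per donor,
#' with a class label. Replicates must be averaged before building a cohort.
#'
#' @param points Numeric matrix (n x 2) or data frame with two numeric
#'   columns.
#' @param labels Character vector of class names (e.g. `"NOP"`, `"PDAC"`).
#' @param donor_ids Unique donor identifiers; default `d1..dn`.
#' @return Object of class `maglev_cohort`.
#' @export
maglev_cohort <- function(points, labels, donor_ids = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) == length(labels))
  if (is.null(donor_ids)) donor_ids <- paste0("d", seq_len(nrow(points)))
  if (anyDuplicated(donor_ids)) stop("donor_ids must be unique")
  dimnames(points) <- list(NULL,
                           c("starting_position_mm", "levitating_area"))
  structure(list(points = points, labels = as.character(labels),
                 donor_ids = as.character(donor_ids)),
            class = "maglev_cohort")
}

#' @export
as.data.frame.maglev_cohort <- function(x, ...) {
  data.frame(donor_id = x$donor_ids, class = x$labels, x$points,
             row.names = NULL)
}

#' @export
print.maglev_cohort <- function(x, ...) {
  cat("MagLev cohort:", nrow(x$points), "donors;",
      paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a cohort to a subset of classes
#'
#' @param cohort A [maglev_cohort()].
#' @param classes Class labels to keep.
#' @return A [maglev_cohort()].
#' @export
subset_cohort <- function(cohort, classes) {
  keep <- cohort$labels %in% classes
  maglev_cohort(cohort$points[keep, , drop = FALSE], cohort$labels[keep],
                cohort$donor_ids[keep])
}

#' Fit Fisher linear discriminant between a negative and a positive class
#'
#' Classic two-class Fisher LDA with equal priors and pooled covariance:
#' `w = S_pooled^{-1} (mu_pos - mu_neg)`, with the decision threshold at the
#' projected midpoint of the class means. A numerically singular pooled
#' covariance is ridge-regularized (`eps = 1e-8 * trace`) with a warning.
#'
#' @param cohort A [maglev_cohort()] containing (at least) both classes.
#' @param positive_class Label of the positive (disease) class.
#' @param negative_class Label of the negative class (default `"NOP"`).
#' @return Object of class `maglev_lda`: `weights`, `threshold`,
#'   `class_means`, `pooled_cov`, `classes` (negative, positive),
#'   `training_donors`.
#' @export
lda_fit <- function(cohort, positive_class, negative_class = "NOP") {
  cohort <- subset_cohort(cohort, c(negative_class, positive_class))
  x0 <- cohort$points[cohort$labels == negative_class, , drop = FALSE]
  x1 <- cohort$points[cohort$labels == positive_class, , drop = FALSE]
  n0 <- nrow(x0); n1 <- nrow(x1)
  if (n0 < 2 || n1 < 2) stop("need at least 2 donors per class")
  S <- ((n0 - 1) * stats::cov(x0) + (n1 - 1) * stats::cov(x1)) / (n0 + n1 - 2)
  if (rcond(S) < 1e-12) {
    warning("singular pooled covariance; applying ridge regularization")
    S <- S + diag(1e-8 * sum(diag(S)), 2)
  }
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  w <- solve(S, mu1 - mu0)
  structure(list(weights = w,
                 threshold = sum(w * (mu0 + mu1)) / 2,
                 class_means = rbind(negative = mu0, positive = mu1),
                 pooled_cov = S,
                 classes = c(negative_class, positive_class),
                 training_donors = cohort$donor_ids),
            class = "maglev_lda")
}

#' Classify fingerprints with a fitted LDA model
#'
#' Labels each point by the side of the decision line `w . x = threshold`
#' it falls on; points exactly on the line go to the negative class.
#'
#' @param model A [lda_fit()] result.
#' @param points n x 2 matrix of fingerprints.
#' @param true_labels Optional true class labels; when given, confusion
#'   counts are tallied (the model's negative class is the test negative).
#' @return List with `labels` and, if `true_labels` given, `confusion`
#'   (a `confusion_counts`).
#' @export
lda_classify <- function(model, points, true_labels = NULL) {
  points <- as.matrix(points)
  score <- unname(drop(points %*% model$weights)) - model$threshold
  labels <- ifelse(score > 0, model$classes[2], model$classes[1])
  out <- list(labels = labels, score = score)
  if (!is.null(true_labels)) {
    pos <- model$classes[2]; neg <- model$classes[1]
    stopifnot(all(true_labels %in% model$classes))
    out$confusion <- confusion_counts(
      tn = sum(true_labels == neg & labels == neg),
      fp = sum(true_labels == neg & labels == pos),
      fn = sum(true_labels == pos & labels == neg),
      tp = sum(true_labels == pos & labels == pos))
  }
  out
}

#' Confusion counts (negative class = NOP)
#'
#' @param tn,fp,fn,tp Non-negative integer counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tn, fp, fn, tp) {
  stopifnot(tn >= 0, fp >= 0, fn >= 0, tp >= 0)
  structure(list(tn = tn, fp = fp, fn = fn, tp = tp),
            class = "confusion_counts")
}

#' Diagnostic test metrics
#'
#' Specificity = TN / (TN + FP) (correctly classified negatives over all
#' negatives), sensitivity = TP / (TP + FN), accuracy = (TN + TP) / total.
#' A metric with a zero denominator is returned as `NA` and listed in the
#' `undefined` field rather than propagating NaN.
#'
#' @param confusion A [confusion_counts()].
#' @return List with `specificity`, `sensitivity`, `accuracy` (proportions
#'   in `[0, 1]`) and `undefined` (character vector).
#' @export
classification_metrics <- function(confusion) {
  stopifnot(inherits(confusion, "confusion_counts"))
  n_neg <- confusion$tn + confusion$fp
  n_pos <- confusion$tp + confusion$fn
  total <- n_neg + n_pos
  undef <- character(0)
  spec <- if (n_neg > 0) confusion$tn / n_neg else {
    undef <- c(undef, "specificity"); NA_real_ }
  sens <- if (n_pos > 0) confusion$tp / n_pos else {
    undef <- c(undef, "sensitivity"); NA_real_ }
  acc <- if (total > 0) (confusion$tn + confusion$tp) / total else {
    undef <- c(undef, "accuracy"); NA_real_ }
  list(specificity = spec, sensitivity = sens, accuracy = acc,
       undefined = undef)
}

#' Two-sample pooled-variance Student's t-test
#'
#' Classic two-tailed Student's t with pooled variance (not Welch), as used
#' for comparing starting-position distributions between donor classes.
#' Degenerate inputs (zero pooled variance) give p = 1 for equal means and
#' p = 0, flagged, for unequal means.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  dm <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (dm == 0) return(list(t = 0, p = 1, df = df, degenerate = TRUE))
    return(list(t = sign(dm) * Inf, p = 0, df = df, degenerate = TRUE))
  }
  t <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df, degenerate = FALSE)
}

#' Pairwise p-value matrix across donor classes
#'
#' Pooled Student's t-test on one fingerprint feature for every unordered
#' pair of classes; symmetric with a unit diagonal (the heatmap input).
#'
#' @param cohort A [maglev_cohort()].
#' @param feature Column to compare (default `"starting_position_mm"`).
#' @return Symmetric numeric matrix of p-values, classes as dimnames.
#' @export
pairwise_pvalue_matrix <- function(cohort, feature = "starting_position_mm") {
  classes <- unique(cohort$labels)
  if (length(classes) < 2) stop("need at least 2 classes")
  x <- cohort$points[, feature]
  m <- diag(1, length(classes))
  dimnames(m) <- list(classes, classes)
  for (i in seq_along(classes)[-length(classes)])
    for (j in (i + 1):length(classes)) {
      p <- student_t(x[cohort$labels == classes[i]],
                     x[cohort$labels == classes[j]])$p
      m[i, j] <- m[j, i] <- p
    }
  m
}

#' Covariance confidence ellipse of a 2-D point cloud
#'
#' Mean-centred ellipse whose boundary is the chi-square(2 dof) quantile of
#' the Mahalanobis distance under the sample covariance: for bivariate
#' normal data it covers `level` of the mass asymptotically.
#'
#' @param points n x 2 matrix, n >= 3.
#' @param level Coverage probability in (0, 1); default 0.95.
#' @return Object of class `maglev_ellipse`: `center`, `cov`, `semi_axes`
#'   (major, minor), `orientation` (radians of the major axis),
#'   `level`, `r2` (squared Mahalanobis radius), `degenerate` flag.
#' @export
confidence_ellipse <- function(points, level = 0.95) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 3, ncol(points) == 2, level > 0, level < 1)
  ctr <- colMeans(points)
  S <- stats::cov(points)
  e <- eigen(S, symmetric = TRUE)
  r2 <- stats::qchisq(level, df = 2)
  degenerate <- e$values[2] <= 1e-12 * max(e$values[1], 1e-300)
  structure(list(center = ctr, cov = S,
                 semi_axes = sqrt(pmax(e$values, 0) * r2),
                 orientation = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                 level = level, r2 = r2, degenerate = degenerate),
            class = "maglev_ellipse")
}

#' Test which points fall inside a confidence ellipse
#'
#' @param ellipse A [confidence_ellipse()].
#' @param points n x 2 matrix.
#' @return Logical vector.
#' @export
in_ellipse <- function(ellipse, points) {
  stats::mahalanobis(as.matrix(points), ellipse$center, ellipse$cov) <=
    ellipse$r2
}

#' Ellipse boundary coordinates (for plotting)
#'
#' @param ellipse A [confidence_ellipse()].
#' @param n Number of boundary points.
#' @return n x 2 matrix of boundary coordinates.
#' @export
ellipse_boundary <- function(ellipse, n = 181) {
  th <- seq(0, 2 * pi, length.out = n)
  u <- rbind(ellipse$semi_axes[1] * cos(th), ellipse$semi_axes[2] * sin(th))
  phi <- ellipse$orientation
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  t(R %*% u + ellipse$center)
}

#' Blind validation of a fitted model on a held-out cohort
#'
#' Applies the model to donors that were not used for training (enforced by
#' donor id) and reports confusion counts and metrics, with a provenance
#' record binding a hash of the model to a hash of the holdout.
#'
#' @param model A [lda_fit()] result.
#' @param holdout A [maglev_cohort()] of unseen donors.
#' @return List with `confusion`, `metrics`, `labels`, `provenance`.
#' @export
blind_validation <- function(model, holdout) {
  overlap <- intersect(model$training_donors, holdout$donor_ids)
  if (length(overlap))
    stop("protocol violation: holdout shares donors with training set: ",
         paste(overlap, collapse = ", "))
  holdout <- subset_cohort(holdout, model$classes)
  res <- lda_classify(model, holdout$points, holdout$labels)
  list(confusion = res$confusion,
       metrics = classification_metrics(res$confusion),
       labels = res$labels,
       provenance = list(
         model_hash = fnv1a_hash(c(model$weights, model$threshold)),
         holdout_hash = fnv1a_hash(c(as.vector(holdout$points),
                                     holdout$donor_ids))))
}

#' Power-law exponent of a SAXS curve (mass fractal dimension)
#'
#' Least-squares straight-line fit of log I versus log q; the mass fractal
#' dimension is the negated slope, `I(q) ~ q^-D`. D near 2 indicates
#' sheet-like (two-dimensional) scatterers such as graphene oxide.
#'
#' @param q Scattering vector values (1/nm), positive.
#' @param intensity Scattered intensities, positive, same length as `q`.
#' @return List with `D`, `se` (standard error of D), `intercept`
#'   (log amplitude), `n`.
#' @export
powerlaw_exponent <- function(q, intensity) {
  stopifnot(length(q) == length(intensity))
  if (length(q) < 5) stop("need at least 5 points")
  if (any(q <= 0) || any(intensity <= 0))
    stop("q and intensity must be strictly positive")
  fit <- stats::lm(log(intensity) ~ log(q))
  # noiseless power laws are valid input; silence the perfect-fit warning
  cf <- suppressWarnings(summary(fit))$coefficients
  list(D = -unname(cf[2, 1]), se = unname(cf[2, 2]),
       intercept = unname(cf[1, 1]), n = length(q))
}

# Polynomial rolling hash of a vector's text rendering; used only for
# provenance records, not for cryptographic purposes. Arithmetic stays
# below 2^53 so the result is exact in doubles.
fnv1a_hash <- function(x) {
  s <- paste(format(x, digits = 17), collapse = "|")
  bytes <- utf8ToInt(s)
  h <- 216613626
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
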