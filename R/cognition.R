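#' Assemble a cognitive test table
#'
#' Keeps complete cases only (rows with any missing value are dropped before
#' analysis, with a message) and checks that every column varies.
#'
#' @param scores Numeric matrix or data.frame, subjects x 13 tests.
#' @param test_names Optional column names (default taken from `scores` or
#'   [cognitive_battery()]).
#' @return Object of class `cognitive_table` (a numeric matrix).
#' @export
cognitive_table <- function(scores, test_names = NULL) {
  scores <- as.matrix(scores)
  if (!is.numeric(scores)) stop("cognitive scores must be numeric")
  if (!is.null(test_names)) {
    if (length(test_names) != ncol(scores)) {
      stop("'test_names' length must match the number of columns")
    }
    colnames(scores) <- test_names
  }
  if (is.null(colnames(scores))) {
    if (ncol(scores) == 13L) colnames(scores) <- cognitive_battery()
    else colnames(scores) <- sprintf("test_%02d", seq_len(ncol(scores)))
  }
  complete <- stats::complete.cases(scores)
  if (!all(complete)) {
    message(sprintf("dropping %d incomplete case(s); %d remain",
                    sum(!complete), sum(complete)))
    scores <- scores[complete, , drop = FALSE]
  }
  sds <- apply(scores, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant column(s): %s",
                 paste(colnames(scores)[sds == 0], collapse = ", ")))
  }
  structure(scores, class = c("cognitive_table", "matrix", "array"))
}

#' Z-score every column of a cognitive table
#'
#' Centres each column to mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator). Constant columns raise a named error.
#'
#' @param table A [cognitive_table()] or numeric matrix.
#' @return Matrix of the same shape with standardized columns.
#' @export
zscore_columns <- function(table) {
  x <- unclass(as.matrix(table))
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("cannot z-score constant column(s): %s",
                 paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Principal component analysis of the z-scored battery
#'
#' Eigen-decomposition of the standardized test scores via [stats::prcomp()].
#' Components are ordered by explained variance; each loading column is
#' sign-flipped so that its largest-magnitude coefficient is positive (the
#' sign of a principal axis is otherwise arbitrary).
#'
#' @param table Z-scored subjects x tests matrix (see [zscore_columns()]);
#'   needs more subjects than tests.
#' @return Object of class `cognitive_components`: `loadings` (tests x m),
#'   `variance_fraction`, `scores` (subjects x m), `sdev`, plus
#'   `n_retained` / `domain_labels` slots filled by [find_elbow()] /
#'   [label_components()].
#' @export
run_pca <- function(table) {
  x <- unclass(as.matrix(table))
  if (nrow(x) <= ncol(x)) stop("PCA requires more subjects than variables")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (any(ev < .Machine$double.eps * max(ev) * nrow(x))) {
    warning("rank-deficient input: trailing components have zero variance")
  }
  # sign convention: largest |loading| positive per component
  flip <- apply(pc$rotation, 2L, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  structure(
    list(loadings = loadings,
         variance_fraction = ev / sum(ev),
         scores = scores,
         sdev = pc$sdev,
         n_retained = NA_integer_,
         domain_labels = NULL),
    class = "cognitive_components")
}

#' @export
print.cognitive_components <- function(x, ...) {
  cat(sprintf("PCA of %d variables: first fractions %s\n",
              ncol(x$loadings),
              paste(sprintf("%.1f%%", 100 * utils::head(x$variance_fraction, 4)),
                    collapse = ", ")))
  if (!is.na(x$n_retained)) {
    cat(sprintf("  retained components: %d (%s)\n", x$n_retained,
                paste(x$domain_labels %||% "unlabeled", collapse = ", ")))
  }
  invisible(x)
}

#' Elbow of a scree curve by maximal distance to the chord
#'
#' Draws the line from the first to the last observation of the curve and
#' returns the 1-based index of the observation with maximal perpendicular
#' distance to that line; ties go to the smallest index. Applied to the
#' explained-variance scree, this picks the number of components to retain.
#'
#' @param curve Numeric vector (>= 3 points) of ordered positive values.
#' @return Integer index of the elbow.
#' @examples
#' find_elbow(c(10, 1, 0.9))  # 2
#' @export
find_elbow <- function(curve) {
  y <- as.numeric(curve)
  n <- length(y)
  if (n < 3L) stop("elbow detection needs at least 3 points")
  x <- seq_len(n)
  dx <- n - 1
  dy <- y[n] - y[1]
  # perpendicular distance from (x_i, y_i) to the chord through the ends
  d <- abs(dy * (x - 1) - dx * (y - y[1])) / sqrt(dx^2 + dy^2)
  which.max(d)  # which.max returns the first maximum -> smallest index
}

#' Label retained components by cognitive domain
#'
#' For each retained component and each candidate category of size k, counts
#' how many of the component's k largest-|loading| tests belong to that
#' category; the component is labeled with the category attaining the
#' highest coverage fraction. A tie raises an error prompting a manual
#' label.
#'
#' @param components A `cognitive_components` with `n_retained` set.
#' @param test_category_map Named character vector mapping every test to a
#'   category (default [cognitive_category_map()]).
#' @return Character vector of labels, also stored in the returned object's
#'   `domain_labels` by [cognitive_pca()].
#' @export
label_components <- function(components,
                             test_category_map = cognitive_category_map()) {
  stopifnot(inherits(components, "cognitive_components"))
  if (is.na(components$n_retained)) {
    stop("retained components must be selected before labeling")
  }
  tests <- rownames(components$loadings)
  unmapped <- setdiff(tests, names(test_category_map))
  if (length(unmapped)) {
    stop(sprintf("unmapped test name(s): %s", paste(unmapped, collapse = ", ")))
  }
  cats <- split(names(test_category_map), test_category_map)
  vapply(seq_len(components$n_retained), function(j) {
    lo <- abs(components$loadings[, j])
    frac <- vapply(cats, function(members) {
      k <- length(members)
      top_k <- names(sort(lo, decreasing = TRUE))[seq_len(k)]
      mean(top_k %in% members)
    }, numeric(1))
    best <- which(frac == max(frac))
    if (length(best) > 1L) {
      stop(sprintf(
        "component %d ties between categories %s; label it manually",
        j, paste(names(frac)[best], collapse = ", ")))
    }
    names(frac)[best]
  }, character(1))
}

#' Full cognitive scoring stage
#'
#' Complete-case filtering, z-scoring, PCA, elbow-based component retention
#' and domain labeling in one call.
#'
#' @param scores Subjects x 13 matrix or data.frame of raw test scores.
#' @param test_category_map Passed to [label_components()].
#' @return A `cognitive_components` object with `n_retained` and
#'   `domain_labels` filled in and `scores` restricted to the retained
#'   components available via `retained_scores`.
#' @export
cognitive_pca <- function(scores, test_category_map = cognitive_category_map()) {
  tab <- cognitive_table(scores)
  z <- zscore_columns(tab)
  comp <- run_pca(z)
  comp$n_retained <- find_elbow(100 * comp$variance_fraction)
  comp$domain_labels <- tryCatch(
    label_components(comp, test_category_map),
    error = function(e) {
      # category ties stop label_components; the pipeline can proceed with
      # placeholder labels and leave the call to the analyst
      warning(conditionMessage(e), call. = FALSE)
      sprintf("unresolved_%d", seq_len(comp$n_retained))
    })
  comp$retained_scores <- comp$scores[, seq_len(comp$n_retained), drop = FALSE]
  colnames(comp$retained_scores) <-
    sprintf("PC%d", seq_len(comp$n_retained))
  comp
}
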