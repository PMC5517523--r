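#' Within- and between-class scatter matrices
#'
#' For a two-class feature table, computes the class means, the per-class
#' scatter matrices \eqn{S_c = \sum_j (x_j - \mu_c)(x_j - \mu_c)^T}, the
#' within-class scatter \eqn{S_P = S_1 + S_2} and the rank-one
#' between-class scatter \eqn{S_B = (\mu_1 - \mu_2)(\mu_1 - \mu_2)^T}.
#' These are the two quadratic forms whose ratio the Fisher discriminant
#' maximises: \eqn{S_B} measures how far apart the projected class centres
#' are, \eqn{S_P} how spread-out each projected cluster is.
#'
#' @param features Data frame with a `label` column (exactly two distinct
#'   values among `classes`) and numeric feature columns; `site_id` is
#'   ignored if present.
#' @param classes Ordered pair of class labels; the first is "class 1".
#'   Defaults to the sorted unique labels.
#' @return An object of class `"lda_scatter"`: a list with `S1`, `S2`,
#'   `S_P`, `S_B` (p x p matrices), `mu1`, `mu2`, `n1`, `n2`, `classes`,
#'   `feature_names`.
#' @examples
#' corpus <- generate_gaussian_corpus(n_per_class = 50, p = 4, seed = 1)
#' sc <- lda_scatter(corpus$features)
#' all(abs(sc$S_B - t(sc$S_B)) < 1e-12)
#' @export
lda_scatter <- function(features, classes = NULL) {
  xy <- split_features(features, classes)
  if (nrow(xy$X1) < 2 || nrow(xy$X2) < 2) {
    abort("each class needs at least 2 samples to form scatter matrices")
  }
  mu1 <- colMeans(xy$X1)
  mu2 <- colMeans(xy$X2)
  S1 <- crossprod(sweep(xy$X1, 2, mu1))
  S2 <- crossprod(sweep(xy$X2, 2, mu2))
  d <- mu1 - mu2
  structure(
    list(
      S1 = S1, S2 = S2, S_P = S1 + S2, S_B = tcrossprod(d),
      mu1 = mu1, mu2 = mu2, n1 = nrow(xy$X1), n2 = nrow(xy$X2),
      classes = xy$classes, feature_names = colnames(xy$X1)
    ),
    class = "lda_scatter"
  )
}

# Split a labelled feature table into two numeric matrices, preserving the
# column order of the input.
split_features <- function(features, classes = NULL) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  num <- setdiff(
    names(features)[vapply(features, is.numeric, logical(1))],
    c("residue_seq", "serial")
  )
  if (length(num) == 0) abort("no numeric feature columns found")
  labs <- as.character(features$label)
  classes <- classes %||% sort(unique(labs))
  if (length(classes) != 2) {
    abort("exactly two classes are required")
  }
  keep <- labs %in% classes
  X <- as.matrix(features[keep, num, drop = FALSE])
  labs <- labs[keep]
  list(
    X1 = X[labs == classes[1], , drop = FALSE],
    X2 = X[labs == classes[2], , drop = FALSE],
    classes = classes
  )
}

#' Fisher score of a projection direction
#'
#' The criterion \eqn{J(w) = (w^T S_B w) / (w^T S_P w)}: the ratio of
#' between-class to within-class scatter of the data projected onto `w`.
#' Scale-invariant in `w`; the discriminant direction is its maximiser.
#'
#' @param w Numeric direction vector.
#' @param scatter An `"lda_scatter"` object.
#' @return The scalar score.
#' @export
fisher_score <- function(w, scatter) {
  stopifnot(inherits(scatter, "lda_scatter"),
    length(w) == nrow(scatter$S_P))
  denom <- drop(crossprod(w, scatter$S_P %*% w))
  if (!is.finite(denom) || denom <= 0) {
    abort("Fisher score undefined: w lies in the null space of S_P")
  }
  drop(crossprod(w, scatter$S_B %*% w)) / denom
}

#' Fit a Fisher linear discriminant for metal-class separation
#'
#' Computes the closed-form discriminant direction
#' \eqn{w^* = S_P^{-1} (\mu_1 - \mu_2)}, normalised to unit Euclidean
#' length, with sign fixed so that the second listed class (by default the
#' Mn-like class) has the larger mean projection. The decision threshold is
#' the midpoint of the projected class means,
#' \eqn{\tau = \langle w^*, (\mu_1 + \mu_2)/2 \rangle}, which makes the
#' "closer projected centre" rule identical to the test
#' \eqn{\langle w^*, b \rangle \le \tau}. Projected class means and the
#' pooled projected standard deviation are stored for posterior
#' computation.
#'
#' @param features Labelled feature data frame (see [lda_scatter()]).
#' @param classes Ordered pair of labels; second class projects higher.
#' @param standardize Centre/scale features before fitting (off by
#'   default; the stored centre/scale is re-applied at prediction).
#' @param ridge Stabilise the \eqn{S_P} solve with a small ridge
#'   \eqn{\epsilon I}, \eqn{\epsilon = 10^{-8}\,\mathrm{tr}(S_P)/p}
#'   (default `TRUE`); with `ridge = FALSE` a singular \eqn{S_P} is an
#'   error reporting the reciprocal condition estimate.
#' @return An object of class `"lda_fit"` with elements `w` (unit
#'   discriminant vector, named by feature), `tau`, `classes`, `mu_proj`
#'   (projected class means, named by class), `sigma_pooled` (pooled
#'   projected SD), `n_per_class`, `feature_sd` (training SDs, for
#'   importance scaling), `center`/`scale` (if standardised), and
#'   `ridge_eps`.
#' @examples
#' corpus <- generate_gaussian_corpus(n_per_class = 100, delta = 2, seed = 2)
#' fit <- fit_lda(corpus$features)
#' glance(fit)
#' @export
fit_lda <- function(features, classes = NULL, standardize = FALSE,
                    ridge = TRUE) {
  xy <- split_features(features, classes)
  X <- rbind(xy$X1, xy$X2)
  center <- scale_ <- NULL
  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, sd)
    scale_[scale_ == 0] <- 1
    xy$X1 <- sweep(sweep(xy$X1, 2, center), 2, scale_, "/")
    xy$X2 <- sweep(sweep(xy$X2, 2, center), 2, scale_, "/")
  }
  sc <- lda_scatter_from_split(xy)
  fit_lda_from_scatter(sc,
    center = center, scale = scale_,
    feature_sd = apply(X, 2, sd), ridge = ridge
  )
}

lda_scatter_from_split <- function(xy) {
  lda_scatter(
    tibble::as_tibble(rbind(xy$X1, xy$X2)) |>
      dplyr::mutate(label = rep(xy$classes, c(nrow(xy$X1), nrow(xy$X2)))),
    classes = xy$classes
  )
}

# Core solve shared by fit_lda() and the leave-one-out refits.
fit_lda_from_scatter <- function(sc, center = NULL, scale = NULL,
                                 feature_sd = NULL, ridge = TRUE) {
  p <- nrow(sc$S_P)
  d <- sc$mu1 - sc$mu2
  if (sqrt(sum(d^2)) < 1e-12 * (1 + sqrt(sum(sc$mu1^2)))) {
    abort("degenerate training data: the class means coincide")
  }
  S <- sc$S_P
  eps <- 0
  if (ridge) {
    eps <- 1e-8 * sum(diag(S)) / p
    S <- S + diag(eps, p)
  } else {
    rc <- rcond(S)
    if (rc < .Machine$double.eps * 100) {
      abort(paste0(
        "within-class scatter is numerically singular ",
        "(reciprocal condition ", format(rc, digits = 3),
        "); enable ridge = TRUE"
      ))
    }
  }
  w <- drop(solve(S, d))
  w <- w / sqrt(sum(w^2))
  m1 <- drop(crossprod(w, sc$mu1))
  m2 <- drop(crossprod(w, sc$mu2))
  # Sign convention: the second listed class projects higher.
  if (m2 < m1) {
    w <- -w
    m1 <- -m1
    m2 <- -m2
  }
  names(w) <- sc$feature_names
  sigma2 <- drop(crossprod(w, sc$S_P %*% w)) / (sc$n1 + sc$n2 - 2)
  structure(
    list(
      w = w, tau = (m1 + m2) / 2, classes = sc$classes,
      mu_proj = setNames(c(m1, m2), sc$classes),
      sigma_pooled = sqrt(max(sigma2, 0)),
      n_per_class = setNames(c(sc$n1, sc$n2), sc$classes),
      feature_sd = feature_sd, center = center, scale = scale,
      ridge_eps = eps, schema = FEATURE_SCHEMA_VERSION
    ),
    class = "lda_fit"
  )
}

#' @export
print.lda_fit <- function(x, ...) {
  cat("Fisher linear discriminant (", paste(x$classes, collapse = " vs "),
    ")\n",
    sep = ""
  )
  cat("  features: ", length(x$w), "   n = ",
    paste(x$n_per_class, collapse = " + "), "\n",
    sep = ""
  )
  cat("  projected means: ",
    paste(sprintf("%s = %.4g", names(x$mu_proj), x$mu_proj),
      collapse = ", "
    ), "\n",
    sep = ""
  )
  cat(sprintf("  tau = %.4g, pooled SD = %.4g\n", x$tau, x$sigma_pooled))
  invisible(x)
}

#' Project feature vectors onto the discriminant axis
#'
#' Returns \eqn{\langle w^*, b\rangle} for each row, after applying any
#' centre/scale stored at fit time.
#'
#' @param fit An `"lda_fit"`.
#' @param features Data frame containing the fit's feature columns, or a
#'   numeric matrix/vector in schema order.
#' @return Numeric vector of projections.
#' @export
project_lda <- function(fit, features) {
  X <- as_feature_matrix(fit, features)
  if (!is.null(fit$center)) {
    X <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  }
  drop(X %*% fit$w)
}

as_feature_matrix <- function(fit, features) {
  p <- length(fit$w)
  if (is.data.frame(features)) {
    missing <- setdiff(names(fit$w), names(features))
    if (length(missing) > 0) {
      abort(paste0(
        "feature columns absent from new data: ",
        paste(head(missing, 5), collapse = ", ")
      ))
    }
    X <- as.matrix(features[, names(fit$w), drop = FALSE])
  } else {
    X <- if (is.matrix(features)) features else matrix(features, nrow = 1)
    if (ncol(X) != p) {
      abort(paste0(
        "expected ", p, " feature columns, got ", ncol(X)
      ))
    }
  }
  X
}

#' Classify sites and assign posterior metal probabilities
#'
#' Projects each site onto the discriminant axis and labels it by the
#' nearer projected class mean (equivalently, by which side of \eqn{\tau}
#' the projection falls). Posterior probabilities come from equal-prior
#' one-dimensional Gaussian class-conditionals on the projection axis with
#' class-specific means and the pooled training variance, so they are
#' monotone in the signed distance \eqn{\langle w^*, b\rangle - \tau}.
#' Sites whose posterior is within `ambiguity` of 1/2 are reported with the
#' dual label `"A/B"` (mirroring how borderline metallo-sites are reported
#' as "Mg(II)/Mn(II)"); an exact tie with `ambiguity = 0` is `"ambiguous"`.
#'
#' @param object An `"lda_fit"`.
#' @param new_data Feature data frame (or matrix in schema order).
#' @param ambiguity Half-width of the dual-call posterior band (default
#'   0.05, i.e. posteriors in \[0.45, 0.55\] are dual-labelled).
#' @param ... Unused.
#' @return A tibble with `site_id` (if present in `new_data`),
#'   `projection`, one posterior column per class
#'   (`posterior_<class>`), and `call`.
#' @export
predict.lda_fit <- function(object, new_data, ambiguity = 0.05, ...) {
  proj <- project_lda(object, new_data)
  post <- posterior_lda(object, proj)
  cls <- object$classes
  call <- ifelse(post[, 2] > 0.5, cls[2], cls[1])
  dual <- abs(post[, 2] - 0.5) <= ambiguity
  call[dual] <- if (ambiguity > 0) paste(cls, collapse = "/") else "ambiguous"
  call[post[, 2] == 0.5 & ambiguity == 0] <- "ambiguous"
  out <- tibble::tibble(
    projection = unname(proj),
    "posterior_{cls[1]}" := unname(post[, 1]),
    "posterior_{cls[2]}" := unname(post[, 2]),
    call = unname(call)
  )
  if (is.data.frame(new_data) && "site_id" %in% names(new_data)) {
    out <- dplyr::bind_cols(
      tibble::tibble(site_id = new_data$site_id), out
    )
  }
  out
}

# Equal-prior Gaussian class-conditionals with pooled variance reduce to a
# logistic in the projection: log-odds(class2) = Delta * (proj - tau) / sigma^2.
posterior_lda <- function(fit, proj) {
  if (!is.finite(fit$sigma_pooled) || fit$sigma_pooled <= 0) {
    abort("degenerate pooled projected variance; posteriors undefined")
  }
  delta <- unname(fit$mu_proj[2] - fit$mu_proj[1])
  p2 <- plogis(delta * (proj - fit$tau) / fit$sigma_pooled^2)
  cbind(1 - p2, p2)
}

#' @rdname predict.lda_fit
#' @param fit An `"lda_fit"`.
#' @param features Feature data frame or matrix.
#' @export
classify_sites <- function(fit, features, ambiguity = 0.05) {
  predict(fit, features, ambiguity = ambiguity)
}

#' Leave-one-out cross-validation of the discriminant
#'
#' For every sample the model is refit on the remaining \eqn{n - 1}
#' points and the held-out sample is classified; the tally is returned as
#' a confusion matrix with predictions in rows and true classes in
#' columns, plus per-class accuracies. Scatter matrices are downdated per
#' held-out sample rather than recomputed, so the full LOO sweep costs one
#' \eqn{p \times p} solve per sample. A refit that is degenerate (e.g.
#' coincident means after removal) marks that sample unpredictable and
#' excludes it from the counts with a warning.
#'
#' @param features Labelled feature data frame.
#' @param classes,standardize,ridge As in [fit_lda()]. Standardisation,
#'   when requested, is refit inside every fold.
#' @param ambiguity Dual-call band passed to prediction; dual-labelled
#'   samples count toward the class with the larger posterior.
#' @return An object of class `"lda_loo"`: list with `predictions` (tibble:
#'   `site_id`, `label`, `prediction`, `projection`, posteriors),
#'   `confusion` (2 x 2 matrix, rows = predicted, cols = true),
#'   `per_class_accuracy`, `classes`, `n_unpredictable`.
#' @examples
#' corpus <- generate_gaussian_corpus(n_per_class = 30, delta = 3, seed = 3)
#' cv <- loo_lda(corpus$features)
#' glance(cv)
#' @export
loo_lda <- function(features, classes = NULL, standardize = FALSE,
                    ridge = TRUE, ambiguity = 0.05) {
  xy <- split_features(features, classes)
  if (nrow(xy$X1) < 3 || nrow(xy$X2) < 3) {
    abort("leave-one-out needs at least 3 samples per class")
  }
  cls <- xy$classes
  X <- rbind(xy$X1, xy$X2)
  labs <- rep(cls, c(nrow(xy$X1), nrow(xy$X2)))
  # map back to input row order for reporting
  keep <- as.character(features$label) %in% cls
  ids <- if ("site_id" %in% names(features)) {
    features$site_id[keep]
  } else {
    paste0("sample_", seq_len(nrow(features)))[keep]
  }
  ord <- order(match(as.character(features$label)[keep], cls))
  ids <- ids[ord]

  n <- nrow(X)
  pred <- character(n)
  proj <- post2 <- rep(NA_real_, n)
  fnames <- colnames(X)
  # Per-class sufficient statistics; removing one sample is a rank-one
  # downdate of its class's crossproduct, so each fold costs one p x p solve.
  in1 <- labs == cls[1]
  stats_by <- lapply(list(X[in1, , drop = FALSE], X[!in1, , drop = FALSE]),
    function(Xc) list(n = nrow(Xc), s = colSums(Xc), C = crossprod(Xc))
  )
  for (i in seq_len(n)) {
    ci <- if (in1[i]) 1L else 2L
    oi <- 3L - ci
    xi <- X[i, ]
    held <- stats_by[[ci]]
    oth <- stats_by[[oi]]
    nh <- held$n - 1
    sh <- held$s - xi
    muh <- sh / nh
    Sh <- held$C - tcrossprod(xi) - nh * tcrossprod(muh)
    muo <- oth$s / oth$n
    So <- oth$C - oth$n * tcrossprod(muo)
    mus <- if (ci == 1L) list(muh, muo) else list(muo, muh)
    Ss <- if (ci == 1L) list(Sh, So) else list(So, Sh)
    sc_i <- structure(
      list(
        S1 = Ss[[1]], S2 = Ss[[2]], S_P = Ss[[1]] + Ss[[2]],
        S_B = tcrossprod(mus[[1]] - mus[[2]]),
        mu1 = mus[[1]], mu2 = mus[[2]],
        n1 = if (ci == 1L) nh else oth$n,
        n2 = if (ci == 1L) oth$n else nh,
        classes = cls, feature_names = fnames
      ),
      class = "lda_scatter"
    )
    fit_i <- tryCatch(
      if (standardize) {
        df <- tibble::as_tibble(X[-i, , drop = FALSE])
        df$label <- labs[-i]
        fit_lda(df, classes = cls, standardize = TRUE, ridge = ridge)
      } else {
        fit_lda_from_scatter(sc_i, ridge = ridge)
      },
      error = function(e) NULL
    )
    if (is.null(fit_i)) {
      pred[i] <- NA_character_
      next
    }
    pr <- predict(fit_i, matrix(xi, nrow = 1), ambiguity = 0)
    proj[i] <- pr$projection
    post2[i] <- pr[[paste0("posterior_", cls[2])]]
    pred[i] <- if (post2[i] > 0.5) cls[2] else cls[1]
  }
  bad <- is.na(pred)
  if (any(bad)) {
    warn(paste0(sum(bad), " sample(s) unpredictable (degenerate refit); ",
      "excluded from the confusion matrix"))
  }
  conf <- table(
    predicted = factor(pred[!bad], levels = cls),
    true = factor(labs[!bad], levels = cls)
  )
  conf <- unclass(conf)
  acc <- diag(conf) / pmax(colSums(conf), 1)
  predictions <- tibble::tibble(
    site_id = ids, label = labs, prediction = pred,
    projection = proj,
    "posterior_{cls[1]}" := 1 - post2,
    "posterior_{cls[2]}" := post2
  )
  structure(
    list(
      predictions = predictions, confusion = conf,
      per_class_accuracy = setNames(as.numeric(acc), cls),
      classes = cls, n_unpredictable = sum(bad)
    ),
    class = "lda_loo"
  )
}

#' @export
print.lda_loo <- function(x, ...) {
  cat("Leave-one-out cross-validation (rows = predicted, cols = true)\n")
  print(x$confusion)
  cat(
    "per-class accuracy: ",
    paste(sprintf("%s %.1f%%", names(x$per_class_accuracy),
      100 * x$per_class_accuracy
    ), collapse = ", "), "\n"
  )
  invisible(x)
}

#' Rank features by their contribution to the discriminant
#'
#' The entries of \eqn{w^*} with large absolute value dominate the
#' projection \eqn{\langle w^*, b\rangle} and hence the classification; the
#' sign of an entry says which class typically has larger values of that
#' feature (positive entries favour the higher-projecting second class).
#' Because raw features live on different scales, weights are by default
#' rescaled to the standardised scale (multiplied by the training-set SD of
#' each feature) before ranking, unless the model was already fit on
#' standardised features. Entries below `neutral_frac` of the largest
#' absolute weight are flagged neutral — features whose distribution is
#' essentially the same around either metal.
#'
#' @param fit An `"lda_fit"`.
#' @param standardize Rescale weights by training feature SDs (default
#'   `TRUE`; ignored when the fit itself was standardised).
#' @param neutral_frac Neutrality threshold as a fraction of the maximum
#'   absolute weight (default 0.05).
#' @return A tibble `feature`, `weight`, `favored_class`, `neutral`,
#'   `rank`, sorted by decreasing `abs(weight)`.
#' @export
lda_importance <- function(fit, standardize = TRUE, neutral_frac = 0.05) {
  stopifnot(inherits(fit, "lda_fit"))
  w <- fit$w
  if (standardize && is.null(fit$center) && !is.null(fit$feature_sd)) {
    w <- w * fit$feature_sd
  }
  tibble::tibble(
    feature = names(fit$w),
    weight = unname(w),
    favored_class = unname(ifelse(w >= 0, fit$classes[2], fit$classes[1])),
    neutral = unname(abs(w) < neutral_frac * max(abs(w)))
  ) |>
    dplyr::arrange(dplyr::desc(abs(.data$weight))) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' @export
tidy.lda_fit <- function(x, ...) {
  tibble::tibble(
    feature = names(x$w),
    weight = unname(x$w)
  )
}

#' @export
glance.lda_fit <- function(x, ...) {
  tibble::tibble(
    n = sum(x$n_per_class),
    p = length(x$w),
    tau = x$tau,
    separation = unname(diff(x$mu_proj)),
    sigma_pooled = x$sigma_pooled,
    ridge_eps = x$ridge_eps,
    standardized = !is.null(x$center)
  )
}

#' @export
tidy.lda_loo <- function(x, ...) x$predictions

#' @export
glance.lda_loo <- function(x, ...) {
  conf <- x$confusion
  tibble::tibble(
    n = sum(conf),
    accuracy = sum(diag(conf)) / sum(conf),
    "accuracy_{x$classes[1]}" := x$per_class_accuracy[1],
    "accuracy_{x$classes[2]}" := x$per_class_accuracy[2],
    n_unpredictable = x$n_unpredictable
  )
}

#' Serialise a fitted discriminant as versioned JSON
#'
#' @param fit An `"lda_fit"`.
#' @param file Path.
#' @return `file` invisibly; `read_lda_model()` returns the `"lda_fit"`.
#' @export
write_lda_model <- function(fit, file) {
  stopifnot(inherits(fit, "lda_fit"))
  payload <- list(
    schema = "metallosite-lda/1",
    feature_schema = fit$schema,
    classes = fit$classes,
    feature_names = names(fit$w),
    w_star = unname(fit$w),
    tau = fit$tau,
    mu_proj = unname(fit$mu_proj),
    sigma_pooled = fit$sigma_pooled,
    n_per_class = unname(fit$n_per_class),
    feature_sd = unname(fit$feature_sd),
    center = unname(fit$center),
    scale = unname(fit$scale),
    ridge_eps = fit$ridge_eps
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(file)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(j$schema, "metallosite-lda/1")) {
    abort(paste0("unrecognised model schema: ", j$schema))
  }
  structure(
    list(
      w = setNames(as.numeric(j$w_star), j$feature_names),
      tau = j$tau, classes = j$classes,
      mu_proj = setNames(as.numeric(j$mu_proj), j$classes),
      sigma_pooled = j$sigma_pooled,
      n_per_class = setNames(as.integer(j$n_per_class), j$classes),
      feature_sd = if (is.null(j$feature_sd)) NULL else as.numeric(j$feature_sd),
      center = if (is.null(j$center)) NULL else as.numeric(j$center),
      scale = if (is.null(j$scale)) NULL else as.numeric(j$scale),
      ridge_eps = j$ridge_eps, schema = j$feature_schema
    ),
    class = "lda_fit"
  )
}
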