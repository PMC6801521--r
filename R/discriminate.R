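# Feature assembly, ROC-AUC screening at the 0.75 threshold, the KNN
# classifier used to call VUS, and an SVM comparison model.

#' The 22 candidate feature columns
#'
#' Column names of the full feature table: ingested thermodynamic values
#' (`folding_ddg`, `binding_dddg`, kcal/mol), conservation (`ecs`),
#' trajectory statistics (`avg_rmsd`, `rmsd_change`, `rmsf_*`,
#' `cum_rmsf_*`, Angstrom), hydrogen-bond counts, crystallographic
#' B-factor, relative solvent accessibility, and residue-property deltas.
#'
#' @export
FEATURE_NAMES <- c(
  "folding_ddg", "binding_dddg", "ecs",
  "avg_rmsd", "rmsd_change",
  "rmsf_mut", "rmsf_wt", "rmsf_change",
  "cum_rmsf_mut", "cum_rmsf_wt", "cum_rmsf_change",
  "hbond_mut", "hbond_wt", "hbond_change",
  "bfactor_wt",
  "rsasa_mut", "rsasa_wt", "rsasa_change",
  "property_distance", "size_change", "charge_change", "polarity_change"
)

#' Features used by the production classifier
#'
#' Folding free-energy change (entered as its absolute value), evolutionary
#' conservation score, and the wild-type-residue RMSF.
#'
#' @export
CLASSIFIER_FEATURES <- c("folding_ddg", "ecs", "rmsf_wt")

# Feature transforms applied before ranking/distance computation. Folding
# ddG acts on both tails (strong stabilization or destabilization both
# disrupt function), so it enters as a magnitude.
feature_matrix <- function(df, features) {
  missing <- setdiff(features, names(df))
  if (length(missing)) {
    stop("feature table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, features, drop = FALSE])
  if ("folding_ddg" %in% features) {
    m[, "folding_ddg"] <- abs(m[, "folding_ddg"])
  }
  storage.mode(m) <- "double"
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("missing/non-finite feature value: variant row ", bad[1, 1],
         ", column '", features[bad[1, 2]], "'", call. = FALSE)
  }
  m
}

#' Assemble a per-variant feature table from computed and ingested sources
#'
#' Joins a curated variant table with any number of feature sources. A
#' source keyed by `position` alone (e.g. a conservation profile, an RMSF
#' profile, or per-residue structure features) contributes its columns by
#' position; a source keyed by (`position`, `wt_aa`, `mut_aa`) or by
#' `hgvs_p` (e.g. an ingested folding ddG table) contributes by variant
#' identity.
#'
#' @param variants data frame with `hgvs_p` (and optionally a `class`
#'   column) or a parsed variant record table.
#' @param sources named list of data frames as described above.
#' @param features character vector of required feature columns; an error
#'   names any variant/column left unresolved.
#' @return Data frame: identity columns, `class` (if present), and the
#'   requested features; class `feature_table`.
#' @export
assemble_features <- function(variants, sources,
                              features = CLASSIFIER_FEATURES) {
  df <- if (is.null(variants$position)) as_variant_records(variants) else
    variants
  for (nm in names(sources)) {
    src <- sources[[nm]]
    if (all(c("position", "wt_aa", "mut_aa") %in% names(src))) {
      key <- variant_key(df); skey <- variant_key(src)
      idx <- match(key, skey)
    } else if ("hgvs_p" %in% names(src)) {
      idx <- match(df$hgvs_p, src$hgvs_p)
    } else if ("position" %in% names(src)) {
      idx <- match(df$position, src$position)
    } else {
      stop("source '", nm, "' has no recognizable key column", call. = FALSE)
    }
    add <- setdiff(names(src), c("position", "wt_aa", "mut_aa", "hgvs_p",
                                 "gene", "ref_aa", "chain", "resname"))
    for (col in add) df[[col]] <- src[[col]][idx]
  }
  missing <- setdiff(features, names(df))
  if (length(missing)) {
    stop("no source provided feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in features) {
    bad <- which(is.na(df[[col]]))
    if (length(bad)) {
      stop("variant ", df$hgvs_p[bad[1L]], " missing feature '", col, "'",
           call. = FALSE)
    }
  }
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Rank-based ROC AUC of one feature
#'
#' The probability that a randomly chosen pathogenic value exceeds a
#' randomly chosen benign value, ties counted one half (the Mann-Whitney
#' statistic scaled to `[0, 1]`).
#'
#' @param values numeric feature values.
#' @param labels vector with levels `"pathogenic"` (positive class) and
#'   `"benign"`.
#' @return AUC in `[0, 1]` (unoriented).
#' @export
compute_auc <- function(values, labels) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  pos <- labels == "pathogenic"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(values)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Oriented AUC table across features
#'
#' Computes the rank-based AUC for each feature and orients it to be at
#' least 0.5: features where the benign class ranks higher are negated
#' (orientation `"negated"`); `folding_ddg` is screened on its absolute
#' value (orientation `"absolute"`), since pathogenic free-energy changes
#' lie on both tails.
#'
#' @param table a feature table with a `class` column restricted to
#'   pathogenic/benign rows.
#' @param features feature columns to screen (default: all present among
#'   [FEATURE_NAMES]).
#' @return Data frame `feature`, `auc` (oriented), `orientation`; class
#'   `auc_table`, sorted by decreasing AUC.
#' @export
auc_table <- function(table, features = intersect(FEATURE_NAMES,
                                                  names(table))) {
  labels <- table$class
  rows <- lapply(features, function(f) {
    v <- table[[f]]
    orientation <- "as_is"
    if (f == "folding_ddg") {
      v <- abs(v)
      orientation <- "absolute"
    }
    a <- compute_auc(v, labels)
    if (a < 0.5) {
      a <- 1 - a
      orientation <- if (orientation == "absolute") "absolute_negated" else
        "negated"
    }
    data.frame(feature = f, auc = a, orientation = orientation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("auc_table", "data.frame")
  out
}

#' Select discriminating features by AUC threshold
#'
#' @param auc_tab an `auc_table` (or any data frame with `feature` and
#'   `auc` columns).
#' @param threshold minimum oriented AUC, exclusive (default 0.75).
#' @return Character vector of feature names in decreasing AUC order
#'   (possibly empty).
#' @export
select_features <- function(auc_tab, threshold = 0.75) {
  sel <- auc_tab[auc_tab$auc > threshold, , drop = FALSE]
  sel$feature[order(-sel$auc)]
}

#' Reproducible train/test split of the labeled rows
#'
#' @param table labeled feature table (pathogenic/benign rows).
#' @param n_train,n_test partition sizes; must sum to `nrow(table)`.
#' @param seed integer seed.
#' @param stratified allocate within each class proportionally (default
#'   `TRUE`).
#' @return List with `train` and `test` data frames.
#' @export
split_train_test <- function(table, n_train = 52L, n_test = 23L,
                             seed = 1L, stratified = TRUE) {
  n <- nrow(table)
  if (n_train + n_test != n) {
    stop("n_train + n_test (", n_train + n_test,
         ") must equal the number of labeled rows (", n, ")", call. = FALSE)
  }
  idx <- with_seed(seed, {
    if (stratified) {
      classes <- split(seq_len(n), as.character(table$class))
      sizes <- vapply(classes, length, integer(1))
      take <- round(n_train * sizes / n)
      # fix rounding so the total is exactly n_train
      while (sum(take) > n_train) take[which.max(take)] <-
          take[which.max(take)] - 1L
      while (sum(take) < n_train) take[which.min(take)] <-
          take[which.min(take)] + 1L
      unlist(lapply(seq_along(classes), function(i) {
        sample(classes[[i]], take[i])
      }), use.names = FALSE)
    } else {
      sample(n, n_train)
    }
  })
  list(train = table[sort(idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Fit a k-nearest-neighbor classifier
#'
#' Features are z-score standardized with training-set statistics;
#' prediction is by majority vote among the `k` nearest training rows in
#' standardized Euclidean space, with inverse-distance weighting breaking
#' vote ties. `folding_ddg`, when included, enters as its absolute value.
#'
#' @param train labeled feature table.
#' @param k number of neighbors (default 6); must not exceed the training
#'   size.
#' @param features feature columns (default [CLASSIFIER_FEATURES]).
#' @return Object of class `knn_model`.
#' @export
knn_fit <- function(train, k = 6L, features = CLASSIFIER_FEATURES) {
  m <- feature_matrix(train, features)
  if (k > nrow(m)) {
    stop("k (", k, ") exceeds training size (", nrow(m), ")", call. = FALSE)
  }
  mu <- colMeans(m)
  sigma <- apply(m, 2, stats::sd)
  sigma[sigma == 0] <- 1
  structure(list(k = as.integer(k), features = features,
                 center = mu, scale = sigma,
                 x = sweep(sweep(m, 2, mu), 2, sigma, `/`),
                 labels = as.character(train$class)),
            class = "knn_model")
}

#' @export
print.knn_model <- function(x, ...) {
  cat("KNN model: k =", x$k, "on", paste(x$features, collapse = ", "),
      "|", nrow(x$x), "training rows\n")
  invisible(x)
}

#' Predict with a KNN model
#'
#' @param object a `knn_model`.
#' @param newdata feature table of query rows.
#' @param details return a data frame with per-class weighted votes and the
#'   nearest-neighbor distance alongside the label (default `FALSE`).
#' @param ... unused.
#' @return Character vector of predicted labels, or a data frame when
#'   `details = TRUE`.
#' @export
predict.knn_model <- function(object, newdata, details = FALSE, ...) {
  q <- feature_matrix(newdata, object$features)
  q <- sweep(sweep(q, 2, object$center), 2, object$scale, `/`)
  classes <- sort(unique(object$labels))
  out <- lapply(seq_len(nrow(q)), function(i) {
    d <- sqrt(colSums((t(object$x) - q[i, ])^2))
    nb <- order(d)[seq_len(object$k)]
    votes <- table(factor(object$labels[nb], levels = classes))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      w <- 1 / pmax(d[nb], 1e-12)
      wv <- tapply(w, factor(object$labels[nb], levels = classes), sum,
                   default = 0)
      top <- names(wv)[which.max(wv)]
    }
    list(label = top[1L], votes = as.integer(votes),
         min_dist = min(d))
  })
  labels <- vapply(out, `[[`, character(1), "label")
  if (!details) return(labels)
  votes <- do.call(rbind, lapply(out, `[[`, "votes"))
  colnames(votes) <- paste0("votes_", classes)
  data.frame(predicted = labels, votes,
             nn_dist = vapply(out, `[[`, numeric(1), "min_dist"))
}

#' Classification accuracy on a labeled test set
#'
#' @param model a fitted `knn_model` (or `svm` model from [svm_fit()]).
#' @param test labeled feature table.
#' @return Fraction of correct predictions in `[0, 1]`.
#' @export
evaluate_model <- function(model, test) {
  if (!nrow(test)) stop("empty test set", call. = FALSE)
  pred <- if (inherits(model, "knn_model")) predict(model, test) else {
    as.character(predict(model, feature_matrix(test,
                                               attr(model, "msh2_features"))))
  }
  mean(pred == as.character(test$class))
}

#' Tune k over a grid by test-set accuracy
#'
#' @param train,test labeled feature tables.
#' @param k_grid candidate k values (default 1..10).
#' @param features feature columns.
#' @return Data frame `k`, `accuracy`, sorted by the input grid.
#' @export
tune_knn <- function(train, test, k_grid = 1:10,
                     features = CLASSIFIER_FEATURES) {
  acc <- vapply(k_grid, function(k) {
    evaluate_model(knn_fit(train, k = k, features = features), test)
  }, numeric(1))
  data.frame(k = k_grid, accuracy = acc)
}

#' Fit a soft-margin SVM comparison model
#'
#' Thin wrapper over [e1071::svm()] with a small grid search over `cost`
#' and `gamma`; reported alongside KNN for comparison only.
#'
#' @param train labeled feature table.
#' @param features feature columns.
#' @param kernel one of `"linear"`, `"polynomial"`, `"radial"`,
#'   `"sigmoid"`.
#' @param cost_grid,gamma_grid grids searched by cross-validation on the
#'   training rows.
#' @return A fitted `svm` model carrying its feature set as an attribute.
#' @export
svm_fit <- function(train, features = CLASSIFIER_FEATURES,
                    kernel = c("linear", "polynomial", "radial", "sigmoid"),
                    cost_grid = c(0.1, 1, 10),
                    gamma_grid = c(0.1, 0.5, 1)) {
  kernel <- match.arg(kernel)
  y <- factor(as.character(train$class))
  if (nlevels(droplevels(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  x <- feature_matrix(train, features)
  tuned <- e1071::tune.svm(x, y, kernel = kernel,
                           cost = cost_grid,
                           gamma = if (kernel == "linear") 0.5 else gamma_grid)
  fit <- tuned$best.model
  attr(fit, "msh2_features") <- features
  fit
}

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
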