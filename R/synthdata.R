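#' Draw Gaussian cluster parameters for the synthetic sensory environment
#'
#' Each class of sensory experience is a cluster of points in feature space
#' (3-D by default).  Cluster means are drawn per coordinate from a normal
#' distribution centred at 0.5; each covariance matrix is built as
#' `0.04 * I + 0.01 * xi` with the entries of `xi` standard normal, then
#' symmetrised and projected onto the positive-semidefinite cone (negative
#' eigenvalues clipped to zero) so every emitted matrix is a valid
#' covariance.
#'
#' @param n_classes Number of clusters (one per class).
#' @param n_features Dimensionality of the feature space (3 for the
#'   synthetic task).
#' @param seed Integer seed; the same seed always yields the same clusters.
#' @param mean_center,mean_spread Centre and spread of the normal from which
#'   cluster-mean coordinates are drawn.  `mean_spread` is read as a
#'   variance by default (the standard `N(mu, sigma^2)` notation); set
#'   `spread_is_sd = TRUE` to read it as a standard deviation.  The
#'   variance reading is the default because the tighter sd reading packs
#'   the ten clusters so closely that even the Bayes-optimal classifier
#'   stays near 50% accuracy, far below what trained networks reach on
#'   this task.
#' @param spread_is_sd Interpretation flag for `mean_spread`.
#'
#' @return A tibble with one row per class: `label` (0-based class id),
#'   `mean` (list column of length-`n_features` vectors) and `covariance`
#'   (list column of symmetric PSD matrices).
#' @export
#' @examples
#' sample_cluster_params(n_classes = 3, seed = 1)
sample_cluster_params <- function(n_classes, n_features = 3L, seed = 1L,
                                  mean_center = 0.5, mean_spread = 0.2,
                                  spread_is_sd = FALSE) {
  if (!is.numeric(n_classes) || length(n_classes) != 1L || n_classes < 1)
    stop("`n_classes` must be a positive integer", call. = FALSE)
  n_classes <- as.integer(n_classes)
  sd_mean <- if (spread_is_sd) mean_spread else sqrt(mean_spread)
  set.seed(as.integer(seed))
  rows <- purrr::map(seq_len(n_classes) - 1L, function(lab) {
    m <- stats::rnorm(n_features, mean = mean_center, sd = sd_mean)
    xi <- matrix(stats::rnorm(n_features^2), n_features, n_features)
    cv <- 0.04 * diag(n_features) + 0.01 * xi
    cv <- (cv + t(cv)) / 2
    es <- eigen(cv, symmetric = TRUE)
    cv <- es$vectors %*% diag(pmax(es$values, 0), n_features) %*% t(es$vectors)
    cv <- (cv + t(cv)) / 2
    tibble::tibble(label = lab, mean = list(m), covariance = list(cv))
  })
  dplyr::bind_rows(rows)
}

#' Generate a labelled dataset from cluster parameters
#'
#' Samples are assigned to classes as evenly as possible (counts differ by
#' at most one), then each sample's features are drawn from its cluster's
#' multivariate normal distribution.  The per-class quota is filled in a
#' seeded random presentation order, mirroring an environment that presents
#' experiences from randomly chosen clusters.
#'
#' @param params Tibble of cluster parameters from [sample_cluster_params()].
#' @param n_samples Total number of samples to draw.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `sample_id`, feature columns `f1 ... fD`,
#'   and `label`.
#' @export
generate_dataset <- function(params, n_samples, seed = 1L) {
  if (!is.data.frame(params) || nrow(params) == 0L)
    stop("`params` must be a non-empty cluster-parameter tibble", call. = FALSE)
  if (n_samples < 0) stop("`n_samples` must be >= 0", call. = FALSE)
  n_samples <- as.integer(n_samples)
  n_classes <- nrow(params)
  d <- length(params$mean[[1L]])
  feat_names <- paste0("f", seq_len(d))
  if (n_samples == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      c(list(integer(0)), rep(list(numeric(0)), d), list(integer(0))),
      c("sample_id", feat_names, "label")))
    return(out)
  }
  set.seed(as.integer(seed))
  # balanced labels (counts differ by <= 1), shuffled presentation order
  base <- rep(params$label, length.out = n_samples)
  labels <- sample(base)
  feats <- matrix(NA_real_, n_samples, d)
  for (j in seq_len(n_classes)) {
    idx <- which(labels == params$label[j])
    if (!length(idx)) next
    feats[idx, ] <- rmvnorm_chol(length(idx), params$mean[[j]],
                                 params$covariance[[j]])
  }
  out <- tibble::as_tibble(feats, .name_repair = ~feat_names)
  dplyr::bind_cols(tibble::tibble(sample_id = seq_len(n_samples)), out,
                   tibble::tibble(label = labels))
}

# multivariate normal draws via the (possibly rank-deficient) eigen factor
rmvnorm_chol <- function(n, mean, sigma) {
  d <- length(mean)
  es <- eigen(sigma, symmetric = TRUE)
  rt <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), d)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% t(rt), 2, mean, `+`)
}

#' Split a dataset into training and test portions
#'
#' @param samples Dataset tibble from [generate_dataset()].
#' @param n_test Number of rows to hold out.
#' @param seed Integer seed for the shuffle.
#' @return A list with tibbles `train` and `test`.
#' @export
split_dataset <- function(samples, n_test, seed = 1L) {
  stopifnot(n_test >= 0, n_test <= nrow(samples))
  set.seed(as.integer(seed))
  idx <- sample(nrow(samples), n_test)
  list(train = samples[setdiff(seq_len(nrow(samples)), idx), ],
       test = samples[idx, ])
}

#' Write / read a dataset as delimited text
#'
#' One sample per line, comma-separated feature values followed by the
#' integer label; a `#`-prefixed header records the feature count and class
#' count so files are self-describing and diff-able.
#'
#' @param samples Dataset tibble.
#' @param path File path.
#' @param n_classes Number of classes recorded in the header (defaults to
#'   `max(label) + 1`).
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a dataset tibble.
#' @export
write_dataset <- function(samples, path, n_classes = NULL) {
  feat_cols <- grep("^f[0-9]+$", names(samples), value = TRUE)
  if (is.null(n_classes))
    n_classes <- if (nrow(samples)) max(samples$label) + 1L else 0L
  header <- sprintf("# n_features=%d n_classes=%d", length(feat_cols),
                    n_classes)
  body <- if (nrow(samples)) {
    feats <- as.matrix(samples[feat_cols])
    apply(cbind(format(feats, digits = 17, trim = TRUE, scientific = TRUE),
                samples$label), 1, paste, collapse = ",")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#"))
    stop("missing '#' header line in ", path, call. = FALSE)
  hd <- as.integer(sub(".*n_features=([0-9]+).*", "\\1", lines[1L]))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  feat_names <- paste0("f", seq_len(hd))
  if (!length(body)) {
    return(tibble::as_tibble(stats::setNames(
      c(list(integer(0)), rep(list(numeric(0)), hd), list(integer(0))),
      c("sample_id", feat_names, "label"))))
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != hd + 1L)
      stop("line ", i + 1L, ": expected ", hd + 1L, " fields, got ",
           length(parts[[i]]), call. = FALSE)
    vals <- suppressWarnings(as.numeric(parts[[i]]))
    if (anyNA(vals))
      stop("line ", i + 1L, ": non-numeric field in '", body[i], "'",
           call. = FALSE)
  }
  mat <- do.call(rbind, lapply(parts, as.numeric))
  out <- tibble::as_tibble(mat[, seq_len(hd), drop = FALSE],
                           .name_repair = ~feat_names)
  dplyr::bind_cols(tibble::tibble(sample_id = seq_len(nrow(mat))), out,
                   tibble::tibble(label = as.integer(mat[, hd + 1L])))
}

# feature matrix (n x D) from a dataset tibble
feature_matrix <- function(samples) {
  feat_cols <- grep("^f[0-9]+$", names(samples), value = TRUE)
  as.matrix(samples[feat_cols])
}
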