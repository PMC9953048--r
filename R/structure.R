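.units_matrix <- function(units) {
  if (is.data.frame(units)) {
    pars <- intersect(facial_parameters(), names(units))
    if (length(pars)) units <- units[, pars, drop = FALSE]
  }
  x <- as.matrix(units)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("unit matrix contains missing values", call. = FALSE)
  x
}

#' PCA of the facial-parameter landscape with variable contributions
#'
#' Principal component analysis of the unit table. Because the seven
#' parameters mix degrees and dimensionless ratios, variables are
#' standardized (the decomposition is of the correlation matrix). The
#' contribution of variable j to component k is the squared unit-norm
#' loading expressed in percent, so each component's contributions sum
#' to 100.
#'
#' @param units Unit table (data frame with the seven parameter columns)
#'   or a plain numeric matrix.
#' @param scale. Standardize variables (decompose the correlation matrix,
#'   the default) or not (covariance matrix, in which case variables with
#'   large numeric ranges dominate).
#' @return List of class `fm_pca`: `eigenvalues`, `variance_pct`,
#'   `contributions_pct` (variable x component, percent), `loadings`
#'   (correlation-scaled), `scores`.
#' @export
pca_contributions <- function(units, scale. = TRUE) {
  x <- .units_matrix(units)
  if (nrow(x) <= ncol(x)) stop("need more rows than variables")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  z <- scale(x, center = TRUE, scale = scale.)
  e <- eigen(if (scale.) stats::cor(x) else stats::cov(x),
             symmetric = TRUE)
  ev <- pmax(e$values, 0)
  v <- e$vectors
  # fix sign for reproducibility: largest-magnitude loading positive
  for (k in seq_len(ncol(v))) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) v[, k] <- -v[, k]
  }
  contrib <- 100 * v^2
  dimnames(contrib) <- list(colnames(x), paste0("PC", seq_along(ev)))
  loadings <- sweep(v, 2, sqrt(ev), `*`)
  dimnames(loadings) <- dimnames(contrib)
  scores <- z %*% v
  colnames(scores) <- colnames(contrib)
  structure(list(eigenvalues = ev,
                 variance_pct = 100 * ev / sum(ev),
                 contributions_pct = contrib,
                 loadings = loadings, scores = scores),
            class = "fm_pca")
}

#' @export
print.fm_pca <- function(x, ...) {
  cat("PCA of", length(x$eigenvalues), "facial parameters\n")
  print(data.frame(eigenvalue = round(x$eigenvalues, 4),
                   variance_pct = round(x$variance_pct, 2)))
  invisible(x)
}

#' Horn's parallel analysis for component retention
#'
#' Compares the observed correlation-matrix eigenvalues with those of
#' Monte-Carlo datasets of independent standard normal deviates of the
#' same dimensions. Each observed eigenvalue is adjusted by the sampling
#' bias of the corresponding random eigenvalue,
#' adjusted_k = observed_k - (reference_k - 1), and the leading run of
#' components with adjusted eigenvalue > 1 is retained (retention stops
#' at the first component that fails, since later components explain
#' less variance than an already-rejected one). The reference is, by default, a
#' high centile (0.99) of the Monte-Carlo eigenvalue distribution: under
#' an independent-noise null the top observed eigenvalue fluctuates
#' around the Monte-Carlo mean, so a mean reference would retain a
#' spurious first component in about half of all datasets, while a
#' high-centile reference keeps that false-retention rate at
#' 1 - centile. `adjustment = "mean"` gives the classical mean-bias
#' variant.
#'
#' @param units Unit table or numeric matrix.
#' @param n_iter Number of Monte-Carlo datasets (>= 100).
#' @param seed Integer seed; the analysis is fully reproducible.
#' @param adjustment `"centile"` (default) or `"mean"`.
#' @param centile Centile used when `adjustment = "centile"`.
#' @return List of class `fm_parallel`: `observed`, `random_mean`,
#'   `random_reference` (the values subtracted), `adjusted`,
#'   `n_retained`, `n_iter`, `adjustment`, `centile`, `seed`.
#' @export
horn_parallel <- function(units, n_iter = 1000, seed = 1,
                          adjustment = c("centile", "mean"),
                          centile = 0.99) {
  adjustment <- match.arg(adjustment)
  x <- .units_matrix(units)
  if (n_iter < 100) stop("n_iter must be >= 100")
  n <- nrow(x); p <- ncol(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  obs <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  draws <- .with_seed(seed, {
    out <- matrix(NA_real_, n_iter, p)
    for (i in seq_len(n_iter)) {
      r <- matrix(stats::rnorm(n * p), n, p)
      out[i, ] <- eigen(stats::cor(r), symmetric = TRUE,
                        only.values = TRUE)$values
    }
    out
  })
  rnd_mean <- colMeans(draws)
  ref <- if (adjustment == "mean") rnd_mean
         else apply(draws, 2, stats::quantile, probs = centile,
                    names = FALSE)
  adj <- obs - (ref - 1)
  first_fail <- match(FALSE, adj > 1)
  n_ret <- if (is.na(first_fail)) p else first_fail - 1L
  structure(list(observed = obs, random_mean = rnd_mean,
                 random_reference = ref, adjusted = adj,
                 n_retained = as.integer(n_ret), n_iter = n_iter,
                 adjustment = adjustment,
                 centile = if (adjustment == "centile") centile else NA,
                 seed = seed),
            class = "fm_parallel")
}

#' @export
print.fm_parallel <- function(x, ...) {
  cat("Horn's parallel analysis (", x$n_iter, " Monte-Carlo datasets, ",
      x$adjustment, " reference)\n", sep = "")
  print(data.frame(observed = round(x$observed, 4),
                   reference = round(x$random_reference, 4),
                   adjusted = round(x$adjusted, 4)))
  cat("components retained (adjusted eigenvalue > 1):", x$n_retained, "\n")
  invisible(x)
}

# evaluate expr under a local RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' 2-D UMAP embedding of stimulus units
#'
#' Uniform manifold approximation and projection of the unit table into
#' two dimensions, run directly on the absolute measured values (no
#' standardization) with Euclidean distances, 15 neighbors and a minimum
#' distance of 0.1 by default. Note that on raw values, variables with
#' larger numeric ranges (angles in degrees) dominate the Euclidean
#' metric; this is recorded in the result metadata.
#'
#' @param units Unit table or numeric matrix.
#' @param n_neighbors,min_dist,metric UMAP hyperparameters.
#' @param seed Integer seed; identical seeds give identical coordinates.
#' @return List of class `fm_embedding`: `coords` (n x 2 matrix),
#'   `hyperparameters`, `seed`, `note`.
#' @export
embed_units <- function(units, n_neighbors = 15, min_dist = 0.1,
                        metric = "euclidean", seed = 1) {
  x <- .units_matrix(units)
  if (nrow(x) <= n_neighbors) {
    stop("need more rows (", nrow(x), ") than n_neighbors (",
         n_neighbors, ")", call. = FALSE)
  }
  coords <- .with_seed(seed, uwot::umap(
    x, n_neighbors = n_neighbors, min_dist = min_dist, metric = metric,
    n_components = 2, n_threads = 1, n_sgd_threads = 0, batch = FALSE))
  colnames(coords) <- c("umap1", "umap2")
  structure(list(coords = coords,
                 hyperparameters = list(metric = metric,
                                        n_neighbors = n_neighbors,
                                        min_dist = min_dist),
                 seed = seed,
                 note = paste("embedding computed on raw absolute values;",
                              "variables with larger numeric range",
                              "dominate the euclidean metric")),
            class = "fm_embedding")
}

#' @export
print.fm_embedding <- function(x, ...) {
  h <- x$hyperparameters
  cat("UMAP embedding of", nrow(x$coords), "units",
      sprintf("(metric=%s, n_neighbors=%d, min_dist=%g, seed=%d)\n",
              h$metric, h$n_neighbors, h$min_dist, x$seed))
  invisible(x)
}
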