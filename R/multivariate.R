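# Cross grouping and characterisation: standardized PCA, Ward hierarchical
# clustering on component scores, v-test category description of clusters,
# and trait correlation matrices with significance.

# Coerce a dataset / trait table to a numeric crosses-by-traits matrix with
# cross labels as row names.
trait_matrix <- function(x, traits = NULL) {
  if (inherits(x, "kola_dataset")) x <- x$traits
  if (is.data.frame(x) && "cross_label" %in% names(x)) {
    traits <- traits %||%
      intersect(c(TRAIT_PCT_COLUMNS, TRAIT_COLUMNS), names(x))
    m <- as.matrix(x[, traits, drop = FALSE])
    rownames(m) <- x$cross_label
    m
  } else {
    as.matrix(x)
  }
}

#' Standardized principal component analysis
#'
#' Centres every trait and scales it to unit variance, then eigendecomposes
#' the correlation matrix. Missing cells are mean-imputed with a warning;
#' zero-variance traits are dropped with a warning. Component signs follow a
#' deterministic convention: the largest-magnitude loading of each component
#' is made positive.
#'
#' @param table crosses-by-traits matrix, trait data.frame, or
#'   \code{kola_dataset} (at least 3 crosses, 2 traits).
#' @param traits optional trait column selection.
#' @return list of class \code{"kola_pca"}: \code{scores} (crosses x
#'   components), \code{loadings} (traits x components), \code{explained_pct}
#'   (sums to 100), \code{data} (the standardized matrix).
#' @export
pca_standardized <- function(table, traits = NULL) {
  m <- trait_matrix(table, traits)
  if (nrow(m) < 3L) {
    stop_kola("need at least 3 crosses for PCA", class = "kola_validation_error")
  }
  if (anyNA(m)) {
    warning("missing trait cells mean-imputed before PCA")
    for (j in seq_len(ncol(m))) {
      v <- m[, j]
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      m[, j] <- v
    }
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance trait(s) dropped: ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) < 2L) {
    stop_kola("need at least 2 traits with variance",
              class = "kola_validation_error")
  }
  z <- scale(m)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x
  loadings <- pc$rotation
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  ev <- pc$sdev^2
  structure(
    list(scores = scores, loadings = loadings,
         explained_pct = 100 * ev / sum(ev),
         data = z),
    class = "kola_pca"
  )
}

#' @export
print.kola_pca <- function(x, ...) {
  cat("Standardized PCA: ", nrow(x$scores), " crosses, ",
      nrow(x$loadings), " traits\n", sep = "")
  ex <- x$explained_pct
  cat("  explained %: ",
      paste(sprintf("PC%d=%.1f", seq_len(min(5, length(ex))),
                    ex[seq_len(min(5, length(ex)))]), collapse = ", "),
      if (length(ex) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Within-cluster inertia (sum of squared distances to cluster centroids).
within_inertia <- function(scores, assignment) {
  sum(vapply(split(seq_len(nrow(scores)), assignment), function(idx) {
    s <- scores[idx, , drop = FALSE]
    centroid <- colMeans(s)
    sum(sweep(s, 2, centroid)^2)
  }, 0))
}

#' Ward clustering on principal component scores
#'
#' Agglomerates the crosses by Ward's criterion on the Euclidean distances of
#' the component scores that reach \code{retain_pct} cumulative explained
#' variance. When \code{k = "auto"} the number of clusters is chosen over
#' \code{k_range} as the partition whose creation produced the largest
#' relative loss of within-cluster inertia over the previous partition, ties
#' broken toward fewer clusters.
#'
#' @param pca a \code{kola_pca} (or anything [pca_standardized()] accepts).
#' @param k number of clusters, or \code{"auto"}.
#' @param retain_pct cumulative explained variance (\%) retained before
#'   clustering.
#' @param k_range candidate cluster counts searched under \code{k = "auto"}.
#' @return list of class \code{"kola_clusters"}: \code{assignments} (named
#'   integer vector), \code{k}, \code{merge_heights}, \code{hclust},
#'   \code{n_components}, \code{within_inertia}, and \code{category_stats}
#'   from [describe_clusters()] when trait data are recoverable.
#' @export
hcpc_cluster <- function(pca, k = "auto", retain_pct = 80, k_range = 3:6) {
  if (!inherits(pca, "kola_pca")) pca <- pca_standardized(pca)
  n <- nrow(pca$scores)
  ncomp <- max(1L, which(cumsum(pca$explained_pct) >= retain_pct - 1e-9)[1])
  if (is.na(ncomp)) ncomp <- ncol(pca$scores)
  s <- pca$scores[, seq_len(ncomp), drop = FALSE]
  hc <- stats::hclust(stats::dist(s), method = "ward.D2")

  if (identical(k, "auto")) {
    ks <- k_range[k_range >= 2 & k_range < n]
    if (!length(ks)) {
      stop_kola("no feasible k in k_range", class = "kola_validation_error")
    }
    w <- vapply(c(min(ks) - 1L, ks), function(kk) {
      if (kk < 1L) return(within_inertia(s, rep(1L, n)))
      within_inertia(s, stats::cutree(hc, kk))
    }, 0)
    # relative inertia loss when moving from k-1 to k clusters
    prev <- w[-length(w)]
    rel_loss <- ifelse(prev > 0, (prev - w[-1]) / prev, 0)
    k <- ks[which.max(rel_loss)]  # which.max takes the first (smallest k) tie
  }
  k <- as.integer(k)
  if (k > n) {
    stop_kola("k exceeds the number of crosses", class = "kola_validation_error")
  }
  assignments <- stats::cutree(hc, k)
  names(assignments) <- rownames(pca$scores)
  stats <- tryCatch(
    describe_clusters(assignments, pca$data * attr(pca$data, "scaled:scale")[
      col(pca$data)] + attr(pca$data, "scaled:center")[col(pca$data)]),
    error = function(e) NULL
  )
  structure(
    list(assignments = assignments, k = k, merge_heights = hc$height,
         hclust = hc, n_components = ncomp,
         within_inertia = within_inertia(s, assignments),
         category_stats = stats),
    class = "kola_clusters"
  )
}

#' @export
print.kola_clusters <- function(x, ...) {
  cat("Ward clustering on ", x$n_components, " component(s): k = ", x$k, "\n",
      sep = "")
  print(table(cluster = x$assignments))
  if (!is.null(x$category_stats)) {
    sig <- x$category_stats[x$category_stats$significant, ]
    cat(nrow(sig), "significant cluster/trait category deviations (see $category_stats)\n")
  }
  invisible(x)
}

#' Characterise clusters by trait category means (v-test)
#'
#' For each cluster and trait, the v statistic standardises the difference
#' between the cluster's category mean and the overall mean:
#' \deqn{v = (\bar x_c - \bar x) / \sqrt{(s^2 / n_c) (N - n_c)/(N - 1)}}
#' where \eqn{s^2} is the overall (population, denominator N) variance of the
#' trait, \eqn{n_c} the cluster size and N the number of crosses. Large |v|
#' means the cluster's mean deviates more than expected for a random subset
#' of its size; a two-sided normal p-value is attached and flagged at the
#' \code{sig_level} reporting threshold.
#'
#' @param assignments named integer vector of cluster ids (1..k).
#' @param table crosses-by-traits matrix or trait data.frame, rows in the same
#'   order as \code{assignments}.
#' @param sig_level flagging threshold for the \code{significant} column.
#' @return data.frame: \code{cluster}, \code{trait}, \code{n},
#'   \code{category_mean}, \code{overall_mean}, \code{category_sd},
#'   \code{v}, \code{p_value}, \code{significant}.
#' @export
describe_clusters <- function(assignments, table, sig_level = 0.001) {
  m <- trait_matrix(table)
  if (length(assignments) != nrow(m)) {
    stop_kola("assignments and table disagree on the number of crosses",
              class = "kola_validation_error")
  }
  ks <- sort(unique(assignments))
  if (length(ks) < 2L) {
    stop_kola("need at least 2 clusters to describe",
              class = "kola_validation_error")
  }
  N <- nrow(m)
  rows <- list()
  for (k in ks) {
    idx <- which(assignments == k)
    nc <- length(idx)
    for (j in seq_len(ncol(m))) {
      x <- m[, j]
      ok <- !is.na(x)
      mean_all <- mean(x[ok])
      var_all <- mean((x[ok] - mean_all)^2)  # population variance
      mean_c <- mean(x[intersect(idx, which(ok))])
      v <- if (nc == N || var_all == 0) NA_real_ else
        (mean_c - mean_all) /
          sqrt((var_all / nc) * (N - nc) / (N - 1))
      p <- if (is.na(v)) NA_real_ else 2 * stats::pnorm(-abs(v))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = k, trait = colnames(m)[j], n = nc,
        category_mean = mean_c, overall_mean = mean_all,
        category_sd = stats::sd(m[idx, j]),
        v = v, p_value = p,
        significant = !is.na(p) & p < sig_level,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trait correlation matrix with significance
#'
#' Pearson correlations over pairwise-complete observations, with
#' t-distributed p-values. Pairs with fewer than 3 complete observations are
#' reported as missing.
#'
#' @param table crosses-by-traits matrix, trait data.frame or
#'   \code{kola_dataset}.
#' @param traits optional trait selection.
#' @return list of class \code{"kola_corr"}: \code{r}, \code{p_values},
#'   \code{n_pairs} (all traits x traits).
#' @export
correlation_matrix <- function(table, traits = NULL) {
  m <- trait_matrix(table, traits)
  p <- ncol(m)
  r <- diag(1, p)
  pv <- matrix(NA_real_, p, p)
  np <- matrix(0L, p, p)
  diag(pv) <- 0
  dimnames(r) <- dimnames(pv) <- dimnames(np) <- list(colnames(m), colnames(m))
  diag(np) <- colSums(!is.na(m))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      n <- sum(ok)
      np[i, j] <- np[j, i] <- n
      if (n < 3L || stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) {
        r[i, j] <- r[j, i] <- NA_real_
        next
      }
      rij <- stats::cor(m[ok, i], m[ok, j])
      r[i, j] <- r[j, i] <- rij
      pv[i, j] <- pv[j, i] <- if (abs(rij) >= 1) 0 else {
        tstat <- rij * sqrt((n - 2) / (1 - rij^2))
        2 * stats::pt(-abs(tstat), df = n - 2)
      }
    }
  }
  structure(list(r = r, p_values = pv, n_pairs = np), class = "kola_corr")
}

# Significance stars at the conventional thresholds.
corr_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**",
                                     ifelse(p < 0.05, "*", ""))))
}

#' @export
print.kola_corr <- function(x, digits = 2, ...) {
  cat("Trait correlations (Pearson, pairwise-complete; * p<0.05 ** p<0.01 *** p<0.001)\n")
  txt <- matrix(paste0(format(round(x$r, digits)), corr_stars(x$p_values)),
                nrow(x$r), dimnames = dimnames(x$r))
  txt[upper.tri(txt)] <- ""
  print(txt, quote = FALSE)
  invisible(x)
}
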