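# Yield-component and nut-quality summaries: outturn, per-cross trait
# summaries, and group tests (one-way ANOVA or Kruskal-Wallis with
# compact-letter pairwise groupings).

#' Nut outturn percentage
#'
#' Outturn is the peeled nut weight as a percentage of the unpeeled (fresh)
#' nut weight. With zero unpeeled weight the ratio is undefined and \code{NA}
#' is returned; a peeled weight exceeding the unpeeled weight is a data error.
#'
#' @param weight_peeled,weight_unpeeled weights in grams (vectorised).
#' @return numeric percentage.
#' @examples
#' outturn_percent(61.7, 88.7)  # 69.56
#' @export
outturn_percent <- function(weight_peeled, weight_unpeeled) {
  if (any(weight_peeled < 0 | weight_unpeeled < 0, na.rm = TRUE)) {
    stop_kola("weights must be non-negative", class = "kola_validation_error")
  }
  if (any(weight_peeled > weight_unpeeled, na.rm = TRUE)) {
    stop_kola("weight_peeled exceeds weight_unpeeled",
              class = "kola_validation_error")
  }
  ifelse(weight_unpeeled == 0, NA_real_,
         100 * weight_peeled / weight_unpeeled)
}

#' Per-cross trait summaries
#'
#' Mean, standard error of the mean and n for every cross and trait, missing
#' values excluded per trait. With a single observation the SE is undefined
#' and reported as \code{NA} (not 0); a cross whose values are all missing
#' for a trait is kept with \code{n = 0}.
#'
#' @param records trait data.frame (multiple rows per cross allowed) or a
#'   \code{kola_dataset}.
#' @param traits trait columns to summarise; defaults to all recognised trait
#'   columns present.
#' @return data.frame: \code{cross_label}, \code{trait}, \code{mean},
#'   \code{se}, \code{n}.
#' @export
summarize_traits <- function(records, traits = NULL) {
  if (inherits(records, "kola_dataset")) records <- records$traits
  traits <- traits %||%
    intersect(c(TRAIT_COLUMNS, TRAIT_PCT_COLUMNS), names(records))
  key <- vapply(records$cross_label, cross_key, "")
  groups <- split(seq_len(nrow(records)), factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(groups, function(idx) {
    lab <- records$cross_label[idx[1]]
    do.call(rbind, lapply(traits, function(tr) {
      v <- records[[tr]][idx]
      v <- v[!is.na(v)]
      n <- length(v)
      data.frame(cross_label = lab, trait = tr,
                 mean = if (n) mean(v) else NA_real_,
                 se = if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_,
                 n = n, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Pooled per-trait summary across crosses
#'
#' Mirrors the single SE row printed under trial trait tables: for each trait,
#' the mean over crosses and the standard error of that mean.
#'
#' @inheritParams summarize_traits
#' @return data.frame: \code{trait}, \code{mean}, \code{se}, \code{n}.
#' @export
trait_table_summary <- function(records, traits = NULL) {
  if (inherits(records, "kola_dataset")) records <- records$traits
  traits <- traits %||%
    intersect(c(TRAIT_COLUMNS, TRAIT_PCT_COLUMNS), names(records))
  out <- do.call(rbind, lapply(traits, function(tr) {
    v <- records[[tr]]
    v <- v[!is.na(v)]
    data.frame(trait = tr, mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)), n = length(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Group test on a trait with letter groupings
#'
#' Fits a one-way ANOVA of the trait on the grouping factor. If the ANOVA
#' residuals fail a Shapiro-Wilk normality check at the 0.05 level the test
#' switches to Kruskal-Wallis (and says so). When the global test is
#' significant at \code{alpha}, pairwise comparisons produce compact-letter
#' groupings: LSD tests on the pooled ANOVA mean square, or Dunn-style
#' rank-mean comparisons after Kruskal-Wallis. Groups sharing a letter are
#' not significantly different at \code{alpha}.
#'
#' @param values numeric trait values, or a trait data.frame /
#'   \code{kola_dataset} together with \code{trait}.
#' @param groups grouping factor (e.g. cross type or cross label). When
#'   \code{values} is a table, defaults to the cross type.
#' @param trait trait column name when \code{values} is a table.
#' @param alpha significance level for the global test and the pairwise
#'   letters.
#' @return list of class \code{"kola_group_test"}: \code{method} (which test
#'   ran), \code{statistic}, \code{df}, \code{p_value}, \code{means},
#'   \code{letters}, \code{lsd} (LSD at equal n, when ANOVA ran),
#'   \code{degenerate} flag.
#' @export
trait_group_test <- function(values, groups = NULL, trait = NULL,
                             alpha = 0.05) {
  if (inherits(values, "kola_dataset")) values <- values$traits
  if (is.data.frame(values)) {
    stopifnot(!is.null(trait))
    groups <- groups %||% cross_types(values$cross_label)
    values <- values[[trait]]
  }
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  g <- factor(groups[keep])
  if (nlevels(g) < 2L) {
    stop_kola("need at least two groups", class = "kola_validation_error")
  }
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)

  if (all(tapply(values, g, stats::var) %in% c(0, NA)) &&
      stats::var(values) == 0) {
    # every observation identical: exact tie
    return(structure(
      list(method = "anova", statistic = 0, df = c(nlevels(g) - 1L,
                                                   length(values) - nlevels(g)),
           p_value = 1, means = means,
           letters = stats::setNames(rep("a", nlevels(g)), levels(g)),
           lsd = 0, degenerate = TRUE),
      class = "kola_group_test"
    ))
  }

  fit <- stats::aov(values ~ g)
  res <- stats::residuals(fit)
  normal <- TRUE
  if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0) {
    normal <- stats::shapiro.test(res)$p.value >= 0.05
  }

  if (normal) {
    tab <- summary(fit)[[1]]
    statistic <- tab[["F value"]][1]
    df <- c(tab[["Df"]][1], tab[["Df"]][2])
    p_value <- tab[["Pr(>F)"]][1]
    mse <- tab[["Mean Sq"]][2]
    different <- outer(seq_len(nlevels(g)), seq_len(nlevels(g)),
                       Vectorize(function(i, j) {
                         sed <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
                         tcrit <- stats::qt(1 - alpha / 2, df[2])
                         abs(means[i] - means[j]) > tcrit * sed
                       }))
    lsd <- stats::qt(1 - alpha / 2, df[2]) * sqrt(mse * 2 / mean(ns))
    method <- "anova"
  } else {
    kw <- stats::kruskal.test(values, g)
    statistic <- unname(kw$statistic)
    df <- unname(kw$parameter)
    p_value <- kw$p.value
    # Dunn-style pairwise z-tests on mean ranks, tie-corrected
    r <- rank(values)
    rmeans <- tapply(r, g, mean)
    N <- length(values)
    ties <- table(values)
    tiecor <- 1 - sum(ties^3 - ties) / (N^3 - N)
    different <- outer(seq_len(nlevels(g)), seq_len(nlevels(g)),
                       Vectorize(function(i, j) {
                         sed <- sqrt(tiecor * (N * (N + 1) / 12) *
                                       (1 / ns[i] + 1 / ns[j]))
                         z <- abs(rmeans[i] - rmeans[j]) / sed
                         2 * stats::pnorm(-z) < alpha
                       }))
    lsd <- NA_real_
    method <- "kruskal-wallis"
  }
  if (p_value >= alpha) different[] <- FALSE
  diag(different) <- FALSE
  dimnames(different) <- list(levels(g), levels(g))
  letters <- cld_letters(!different, order(means, decreasing = TRUE))

  structure(
    list(method = method, statistic = statistic, df = df, p_value = p_value,
         means = means, letters = letters, lsd = lsd,
         degenerate = FALSE, pairwise_different = different),
    class = "kola_group_test"
  )
}

# Compact letter display. `same` is a symmetric logical matrix: TRUE where
# the pair is NOT significantly different. Letters are assigned from the
# maximal cliques of that graph (ordered by the supplied group order, best
# mean first), which makes letter sharing exactly equivalent to pairwise
# non-difference.
cld_letters <- function(same, order = seq_len(nrow(same))) {
  n <- nrow(same)
  diag(same) <- TRUE
  cliques <- list()
  bron_kerbosch <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      cliques[[length(cliques) + 1L]] <<- R
      return(invisible())
    }
    while (length(P)) {
      v <- P[1]
      nb <- setdiff(which(same[v, ]), v)
      bron_kerbosch(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- P[-1]
      X <- c(X, v)
    }
  }
  bron_kerbosch(integer(0), seq_len(n), integer(0))
  # order cliques by the best-ranked member they contain
  rank_of <- match(seq_len(n), order)
  cliques <- cliques[order(vapply(cliques, function(cl) min(rank_of[cl]), 0))]
  letts <- rep("", n)
  for (k in seq_along(cliques)) {
    sym <- if (k <= 26) letters[k] else paste0(letters[(k - 1) %% 26 + 1], k)
    letts[cliques[[k]]] <- paste0(letts[cliques[[k]]], sym)
  }
  stats::setNames(letts, rownames(same))
}

#' @export
print.kola_group_test <- function(x, ...) {
  cat("Group test (", x$method, ")\n", sep = "")
  cat(sprintf("  statistic = %.4g, df = %s, p = %.3g%s\n",
              x$statistic, paste(x$df, collapse = ", "), x$p_value,
              if (x$degenerate) "  [degenerate: all values tied]" else ""))
  tab <- data.frame(group = names(x$means), mean = as.numeric(x$means),
                    letters = x$letters[names(x$means)])
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}
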