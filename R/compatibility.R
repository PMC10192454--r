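# Sexual-compatibility quantification: pod-set / pseudo-pod-set percentages,
# the 0-5 compatibility class scale, cross-type contrasts on success/failure
# counts, and compatibility-class distribution tests.

COMPAT_CLASS_NAMES <- c("incompatible", "very low", "low", "moderate",
                        "high", "very high")

#' Pod set and pseudo-pod set percentages
#'
#' Pod set is the proportion of hand-pollinated flowers that develop into true
#' pods, expressed as a percentage; pseudo-pod set is the analogous proportion
#' of pseudo-pods (fruit-like structures without viable fertilisation).
#' With zero flowers pollinated the ratio is undefined and \code{NA} is
#' returned (never 0).
#'
#' @param n_pod,n_pseudo,n_pollinated non-negative integer counts (vectorised).
#' @return numeric percentage in \code{[0, 100]}, \code{NA} where
#'   \code{n_pollinated == 0}.
#' @examples
#' pod_set_percent(7, 20)   # 35
#' @export
pod_set_percent <- function(n_pod, n_pollinated) {
  if (!is_count(n_pod[!is.na(n_pod)]) ||
      !is_count(n_pollinated[!is.na(n_pollinated)])) {
    stop_kola("counts must be non-negative integers",
              class = "kola_validation_error")
  }
  if (any(n_pod > n_pollinated, na.rm = TRUE)) {
    stop_kola("n_pod exceeds n_pollinated", class = "kola_validation_error")
  }
  ifelse(n_pollinated == 0, NA_real_, 100 * n_pod / n_pollinated)
}

#' @rdname pod_set_percent
#' @export
pseudo_pod_set_percent <- function(n_pseudo, n_pollinated) {
  pod_set_percent(n_pseudo, n_pollinated)
}

#' The 0-5 compatibility class scale
#'
#' Crosses are categorised from their pod set percentage: 0 (no pod set at
#' all), 1 (up to 20\%), 2 (20-40\%), 3 (40-60\%), 4 (60-80\%) and 5
#' (80-100\%), named incompatible, very low, low, moderate, high and very
#' high compatible. Classes above 0 use half-open intervals
#' \eqn{(20(k-1), 20k]}, so the upper bound of each band belongs to it
#' (100\% is class 5) and every value in \eqn{[0, 100]} maps to exactly one
#' class.
#'
#' @param pod_set_pct numeric vector of pod-set percentages in \code{[0, 100]}.
#' @return integer vector of classes 0-5 (\code{NA} propagated). The class
#'   names are available as \code{compatibility_class_name()}.
#' @examples
#' compatibility_class(c(0, 13.7, 21.3, 48.7, 97))  # 0 1 2 3 5
#' @export
compatibility_class <- function(pod_set_pct) {
  x <- pod_set_pct
  ok <- is.na(x) | (x >= 0 & x <= 100)
  if (!all(ok)) {
    stop_kola("pod set percentage outside [0, 100]",
              class = "kola_domain_error")
  }
  as.integer(ifelse(is.na(x), NA, ifelse(x == 0, 0L, ceiling(x / 20))))
}

#' @rdname compatibility_class
#' @export
compatibility_class_name <- function(pod_set_pct) {
  COMPAT_CLASS_NAMES[compatibility_class(pod_set_pct) + 1L]
}

#' Per-cross compatibility summary
#'
#' Aggregates pollination records to one row per cross: total flowers
#' pollinated, pod set and pseudo-pod set percentages, compatibility class
#' and class name, and cross type. By default replicate counts are pooled
#' before forming the percentage; \code{aggregate = "mean"} instead averages
#' the per-replicate percentages (both conventions occur in trial reports).
#'
#' A trait table that carries printed \code{pod_set} / \code{pseudo_pod_set}
#' percentages but no raw counts (such as the packaged fixtures) is accepted
#' directly: the percentages are taken as given and counts reported as
#' \code{NA}.
#'
#' @param x a \code{kola_dataset}, a pollination data.frame, or a trait
#'   data.frame with percentage columns.
#' @param aggregate \code{"pooled"} (default) or \code{"mean"}.
#' @return data.frame of class \code{"kola_compat"}.
#' @export
compatibility_summary <- function(x, aggregate = c("pooled", "mean")) {
  aggregate <- match.arg(aggregate)
  if (inherits(x, "kola_dataset")) {
    x <- if (!is.null(x$pollinations)) x$pollinations else x$traits
  }
  schema <- attr(x, "schema") %||%
    if ("n_pollinated" %in% names(x)) "pollination" else "trait"
  if (schema == "pollination") {
    split_rows <- split(seq_len(nrow(x)),
                        factor(vapply(x$cross_label, cross_key, ""),
                               levels = unique(vapply(x$cross_label,
                                                      cross_key, ""))))
    rows <- lapply(split_rows, function(idx) {
      d <- x[idx, ]
      if (aggregate == "pooled") {
        ps <- pod_set_percent(sum(d$n_pod), sum(d$n_pollinated))
        psp <- pseudo_pod_set_percent(sum(d$n_pseudo), sum(d$n_pollinated))
      } else {
        ps <- mean(pod_set_percent(d$n_pod, d$n_pollinated), na.rm = TRUE)
        psp <- mean(pseudo_pod_set_percent(d$n_pseudo, d$n_pollinated),
                    na.rm = TRUE)
      }
      data.frame(cross_label = d$cross_label[1],
                 n_pollinated_total = sum(d$n_pollinated),
                 pod_set_pct = ps, pseudo_pod_set_pct = psp,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    if (!"pod_set" %in% names(x)) {
      stop_kola("trait table has no pod_set column to summarise",
                class = "kola_schema_error")
    }
    out <- data.frame(cross_label = x$cross_label,
                      n_pollinated_total = NA_integer_,
                      pod_set_pct = x$pod_set,
                      pseudo_pod_set_pct = x$pseudo_pod_set %||% NA_real_,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out$compat_class <- compatibility_class(out$pod_set_pct)
  out$class_name <- compatibility_class_name(out$pod_set_pct)
  out$cross_type <- cross_types(out$cross_label)
  attr(out, "aggregate") <- aggregate
  class(out) <- c("kola_compat", "data.frame")
  out
}

#' @export
print.kola_compat <- function(x, ...) {
  cat("Compatibility summary (", nrow(x), " crosses, ",
      attr(x, "aggregate"), " replicate aggregation)\n\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Binomial GLM contrast of pod set between two cross types
#'
#' Organises the pollination counts as success/failure events per cross and
#' fits a binomial generalised linear model (logit link, iteratively
#' reweighted least squares) of outcome probability on the cross-type factor.
#' Reported is the likelihood-ratio deviance of the cross-type term against
#' the intercept-only model (1 df) with its chi-square p-value, plus pooled
#' percentages per type.
#'
#' Under complete separation (one type all-success or all-failure) the Wald
#' output of the GLM is degenerate; the statistic is then computed directly
#' as the likelihood-ratio G of the pooled 2x2 table (which the GLM deviance
#' equals in regular cases) and the result is flagged.
#'
#' @param records pollination data.frame (or \code{kola_dataset}).
#' @param groups character(2), the two cross types to contrast (e.g.
#'   \code{c("DCC", "DCS")}). Defaults to the two types present.
#' @param outcome \code{"pod"} or \code{"pseudo"}.
#' @return list of class \code{"kola_contrast"}: \code{groups},
#'   \code{statistic}, \code{df}, \code{p_value}, \code{group_pct},
#'   \code{separation}.
#' @export
cross_type_podset_test <- function(records, groups = NULL,
                                   outcome = c("pod", "pseudo")) {
  outcome <- match.arg(outcome)
  if (inherits(records, "kola_dataset")) records <- records$pollinations
  type <- cross_types(records$cross_label)
  if (is.null(groups)) {
    groups <- sort(unique(type))
    if (length(groups) != 2L) {
      stop_kola("need exactly two cross types (got ",
                paste(groups, collapse = ", "), "); pass `groups`",
                class = "kola_contrast_error")
    }
  }
  keep <- type %in% groups
  records <- records[keep, ]
  type <- factor(type[keep], levels = groups)
  if (any(table(type) == 0) ||
      any(tapply(records$n_pollinated, type, sum) == 0)) {
    stop_kola("a contrast group has no pollinations",
              class = "kola_contrast_error")
  }
  success <- if (outcome == "pod") records$n_pod else records$n_pseudo
  failure <- records$n_pollinated - success

  # per-cross rows (one success/failure pair per cross, replicates pooled)
  key <- vapply(records$cross_label, cross_key, "")
  s <- tapply(success, key, sum)
  f <- tapply(failure, key, sum)
  g <- factor(tapply(as.character(type), key, `[`, 1L), levels = groups)

  pooled_s <- tapply(s, g, sum)
  pooled_n <- tapply(s + f, g, sum)
  group_pct <- 100 * pooled_s / pooled_n
  separation <- any(pooled_s == 0) || any(pooled_s == pooled_n)

  if (!separation) {
    fit <- stats::glm(cbind(s, f) ~ g, family = stats::binomial())
    null <- stats::glm(cbind(s, f) ~ 1, family = stats::binomial())
    statistic <- as.numeric(null$deviance - fit$deviance)
  } else {
    # LRT of the pooled 2x2 table (penalised-fallback note: the pooled G is
    # finite even when group proportions hit 0 or 1)
    statistic <- g2_2x2(pooled_s, pooled_n - pooled_s)
  }
  statistic <- max(statistic, 0)
  structure(
    list(groups = groups, outcome = outcome, statistic = statistic, df = 1L,
         p_value = stats::pchisq(statistic, df = 1L, lower.tail = FALSE),
         group_pct = stats::setNames(as.numeric(group_pct), groups),
         separation = separation),
    class = "kola_contrast"
  )
}

# Likelihood-ratio G statistic of a 2x2 success/failure table, with 0*log(0)
# taken as 0.
g2_2x2 <- function(s, f) {
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  n <- s + f
  # 2 * (per-group binomial loglik at group MLEs - pooled loglik)
  2 * (sum(xlogx(s)) + sum(xlogx(f)) - sum(xlogx(n)) -
         (xlogx(sum(s)) + xlogx(sum(f)) - xlogx(sum(n))))
}

#' @export
print.kola_contrast <- function(x, ...) {
  cat("Binomial GLM contrast (", x$outcome, " set): ",
      paste(x$groups, collapse = " vs "), "\n", sep = "")
  cat(sprintf("  group %%: %s\n",
              paste(sprintf("%s=%.1f", names(x$group_pct), x$group_pct),
                    collapse = ", ")))
  cat(sprintf("  LR deviance = %.4g on %d df, p = %.3g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$separation) "  [complete separation; pooled-table LRT]"
              else ""))
  invisible(x)
}

#' Distribution of compatibility classes
#'
#' Chi-square goodness-of-fit of the observed class counts against a uniform
#' distribution over classes 0-5 (5 df), plus Holm-adjusted pairwise
#' comparisons of the class proportions.
#'
#' @param classes integer vector of per-cross compatibility classes (0-5).
#' @return list of class \code{"kola_classdist"}: \code{counts},
#'   \code{statistic}, \code{df}, \code{p_value}, and \code{pairwise} (a
#'   data.frame of class pairs with raw and Holm-adjusted p-values).
#' @export
class_distribution_test <- function(classes) {
  classes <- classes[!is.na(classes)]
  if (!length(classes)) {
    stop_kola("no classes supplied", class = "kola_validation_error")
  }
  if (!all(classes %in% 0:5)) {
    stop_kola("classes must be integers 0-5", class = "kola_domain_error")
  }
  counts <- table(factor(classes, levels = 0:5))
  n <- sum(counts)
  gof <- suppressWarnings(stats::chisq.test(counts, p = rep(1 / 6, 6)))
  pairs <- utils::combn(0:5, 2)
  pw <- data.frame(class_a = pairs[1, ], class_b = pairs[2, ])
  pw$p_raw <- apply(pairs, 2, function(cl) {
    xa <- counts[[as.character(cl[1])]]
    xb <- counts[[as.character(cl[2])]]
    if (xa == xb) return(1)
    suppressWarnings(stats::prop.test(c(xa, xb), c(n, n))$p.value)
  })
  pw$p_holm <- stats::p.adjust(pw$p_raw, method = "holm")
  structure(
    list(counts = counts, statistic = unname(gof$statistic),
         df = unname(gof$parameter), p_value = gof$p.value, pairwise = pw),
    class = "kola_classdist"
  )
}

#' @export
print.kola_classdist <- function(x, ...) {
  cat("Compatibility class distribution\n")
  print(x$counts)
  cat(sprintf("chi-square = %.4g, df = %d, p = %.3g (vs uniform over 0-5)\n",
              x$statistic, x$df, x$p_value))
  sig <- x$pairwise[x$pairwise$p_holm < 0.05, ]
  cat("pairwise (Holm) significant pairs:",
      if (nrow(sig)) paste(sig$class_a, sig$class_b, sep = "-", collapse = ", ")
      else "none", "\n")
  invisible(x)
}
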