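# Mid-parent heterosis, heterobeltiosis and economic heterosis for single and
# double hybrid crosses, with pedigree-aware parent and reference lookup.
#
# All three statistics are percent deviations of the hybrid (F1) value from a
# reference: the mean of the two parents' self-cross values (mid-parent
# heterosis, MPH), the better parent's self-cross value (heterobeltiosis,
# BPH), or a recommended standard variety (economic heterosis, ECH). For a
# single cross A x B the parents' values are the selfs A x A and B x B; for a
# double cross (A x B) x (C x D) the parents are the two F1 entities and
# their values the double-selfs (A x B) x (A x B) and (C x D) x (C x D).

#' Mid-parent value
#'
#' Arithmetic mean of the two parental self-cross values.
#'
#' @param p1,p2 parental trait values (vectorised).
#' @return numeric; \code{NA} when either parent is missing.
#' @export
mid_parent_value <- function(p1, p2) {
  (p1 + p2) / 2
}

#' Mid-parent (relative) heterosis
#'
#' Percent deviation of the hybrid value from the mid-parent value:
#' \eqn{100 (F1 - MP) / MP}. Undefined (NA) when the mid-parent value is
#' zero — infinite heterosis is never reported as a numeric sentinel.
#'
#' @param f1 hybrid cross value.
#' @param p1,p2 parental self-cross values.
#' @return percentage (vectorised).
#' @examples
#' mid_parent_heterosis(30, 10, 20)  # 100
#' @export
mid_parent_heterosis <- function(f1, p1, p2) {
  mp <- mid_parent_value(p1, p2)
  if (any(mp < 0, na.rm = TRUE)) {
    stop_kola("negative mid-parent value", class = "kola_domain_error")
  }
  ifelse(is.na(mp) | mp == 0, NA_real_, 100 * (f1 - mp) / mp)
}

#' Heterobeltiosis (better-parent heterosis)
#'
#' Percent deviation of the hybrid from the better (larger-valued) parent:
#' \eqn{100 (F1 - BP) / BP} with \eqn{BP = \max(P1, P2)}. All traits scored
#' here (pod set, outturn, brix) are larger-is-better, so the better parent
#' is the one with the larger value. Undefined (NA) when the better parent's
#' value is zero.
#'
#' @inheritParams mid_parent_heterosis
#' @return percentage (vectorised).
#' @export
heterobeltiosis <- function(f1, p1, p2) {
  bp <- pmax(p1, p2)
  ifelse(is.na(bp) | bp == 0, NA_real_, 100 * (f1 - bp) / bp)
}

#' Economic heterosis
#'
#' Percent deviation of the hybrid from a recommended standard variety:
#' \eqn{100 (F1 - S) / S}. Undefined (NA) for a non-positive standard value.
#'
#' @param f1 hybrid cross value.
#' @param standard the standard variety's value for the same trait.
#' @return percentage (vectorised).
#' @export
economic_heterosis <- function(f1, standard) {
  ifelse(is.na(standard) | standard <= 0, NA_real_,
         100 * (f1 - standard) / standard)
}

# Per-cross value table for the scored traits: pod set (from the pollination
# records or a percentage column) joined with trait-table traits.
cross_value_table <- function(dataset,
                              traits = c("pod_set", "outturn", "brix"),
                              aggregate = "pooled") {
  stopifnot(inherits(dataset, "kola_dataset"))
  labels <- dataset_labels(dataset)
  keys <- vapply(labels, cross_key, "")
  out <- data.frame(cross_label = labels, stringsAsFactors = FALSE)
  if ("pod_set" %in% traits) {
    cs <- compatibility_summary(dataset, aggregate = aggregate)
    out$pod_set <- cs$pod_set_pct[match(keys,
                                        vapply(cs$cross_label, cross_key, ""))]
  }
  tr <- dataset$traits
  if (!is.null(tr)) {
    tk <- vapply(tr$cross_label, cross_key, "")
    for (t in setdiff(traits, "pod_set")) {
      if (t %in% names(tr)) out[[t]] <- tr[[t]][match(keys, tk)]
    }
  }
  missing <- setdiff(traits, names(out))
  for (t in missing) out[[t]] <- NA_real_
  out
}

#' Heterosis table for the hybrid crosses of a dataset
#'
#' Scores every hybrid cross (SCC or DCC) in the dataset for the requested
#' traits. Parent values are looked up as the corresponding self-crosses
#' recorded in the same dataset; the two standard-variety references are
#' looked up by label (defaults are the two recommended kola varieties
#' GX1/46 x GX1/16 and JX1/5 x JX1/9) unless explicit per-trait values are
#' supplied. Self-crosses are skipped (their heterosis is 0 by construction).
#' Crosses whose parent selfs are absent from the dataset get \code{NA}
#' statistics with the missing label recorded in the provenance columns.
#'
#' @param dataset a \code{kola_dataset} (e.g. from a simulated trial or read
#'   tables).
#' @param traits traits to score; \code{"pod_set"} is computed from the
#'   pollination counts (or a printed percentage column), the others from the
#'   trait table.
#' @param standard1,standard2 labels of the two standard varieties, or
#'   \code{NA} to skip economic heterosis against that standard.
#' @param standard_values optional named list
#'   \code{list(standard1 = c(trait = value, ...), standard2 = ...)}
#'   overriding dataset lookup.
#' @param aggregate replicate aggregation mode for pod set.
#' @return data.frame of class \code{"kola_heterosis"} with one row per
#'   hybrid cross and trait: \code{f1}, \code{p1}, \code{p2}, \code{mid_parent},
#'   \code{mph_pct}, \code{bph_pct}, \code{ech1_pct}, \code{ech2_pct} and
#'   provenance columns naming the parent/reference records used.
#' @export
compute_heterosis_table <- function(dataset,
                                    traits = c("pod_set", "outturn", "brix"),
                                    standard1 = "GX1/46 × GX1/16",
                                    standard2 = "JX1/5 × JX1/9",
                                    standard_values = NULL,
                                    aggregate = "pooled") {
  values <- cross_value_table(dataset, traits, aggregate)
  keys <- vapply(values$cross_label, cross_key, "")
  types <- cross_types(values$cross_label)

  lookup_cross <- function(label) {
    if (is.null(label) || is.na(label)) return(NULL)
    i <- match(cross_key(label), keys)
    if (is.na(i)) NULL else values[i, ]
  }
  std <- list(standard1 = NULL, standard2 = NULL)
  for (s in names(std)) {
    lab <- get(s)
    if (!is.null(standard_values) && !is.null(standard_values[[s]])) {
      std[[s]] <- list(values = standard_values[[s]], label = lab %||% s)
    } else if (!is.null(lab) && !is.na(lab)) {
      row <- lookup_cross(lab)
      if (!is.null(row)) {
        std[[s]] <- list(values = unlist(row[traits]), label = lab)
      }
    }
  }

  self_label <- function(entity) {
    lab <- entity_label(entity)
    paste(lab, lab, sep = " × ")
  }

  hybrids <- which(types %in% c("SCC", "DCC"))
  rows <- list()
  for (i in hybrids) {
    spec <- parse_cross_label(values$cross_label[i])
    p1_lab <- self_label(spec$female)
    p2_lab <- self_label(spec$male)
    p1_row <- lookup_cross(p1_lab)
    p2_row <- lookup_cross(p2_lab)
    for (t in traits) {
      f1 <- values[[t]][i]
      p1 <- if (is.null(p1_row)) NA_real_ else p1_row[[t]]
      p2 <- if (is.null(p2_row)) NA_real_ else p2_row[[t]]
      mp <- mid_parent_value(p1, p2)
      rows[[length(rows) + 1L]] <- data.frame(
        cross_label = values$cross_label[i], cross_type = types[i], trait = t,
        f1 = f1, p1 = p1, p2 = p2, mid_parent = mp,
        mph_pct = if (!is.na(mp) && mp > 0 && !is.na(f1))
          mid_parent_heterosis(f1, p1, p2) else NA_real_,
        bph_pct = if (!anyNA(c(p1, p2, f1)) && max(p1, p2) > 0)
          heterobeltiosis(f1, p1, p2) else NA_real_,
        ech1_pct = if (!is.null(std$standard1) && !is.na(f1))
          economic_heterosis(f1, std$standard1$values[[t]]) else NA_real_,
        ech2_pct = if (!is.null(std$standard2) && !is.na(f1))
          economic_heterosis(f1, std$standard2$values[[t]]) else NA_real_,
        p1_source = if (is.null(p1_row)) NA_character_ else p1_lab,
        p2_source = if (is.null(p2_row)) NA_character_ else p2_lab,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cross_label = character(0), cross_type = character(0),
               trait = character(0), f1 = numeric(0), p1 = numeric(0),
               p2 = numeric(0), mid_parent = numeric(0), mph_pct = numeric(0),
               bph_pct = numeric(0), ech1_pct = numeric(0),
               ech2_pct = numeric(0), p1_source = character(0),
               p2_source = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "standards") <- lapply(std, function(s) s$label)
  class(out) <- c("kola_heterosis", "data.frame")
  out
}

#' @export
print.kola_heterosis <- function(x, ...) {
  cat("Heterosis table: ", length(unique(x$cross_label)), " hybrid crosses x ",
      length(unique(x$trait)), " trait(s)\n", sep = "")
  std <- attr(x, "standards")
  if (!is.null(std$standard1) || !is.null(std$standard2)) {
    cat("  standards: ", paste(unlist(std), collapse = "; "), "\n", sep = "")
  }
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4,
                   row.names = FALSE)
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}
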