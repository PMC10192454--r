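# Reading, validating and writing crossing-trial tables.

POLLINATION_COLUMNS <- c("cross_label", "replicate", "n_pollinated",
                         "n_pod", "n_pseudo", "n_dropped")

TRAIT_COLUMNS <- c("number_of_pods", "pod_weight", "pod_length", "pod_width",
                   "nuts_per_pod", "nut_length", "nut_width",
                   "weight_unpeeled", "weight_peeled", "outturn",
                   "brix", "potential_alcohol", "firmness")

# Percentages that may ride along in a trait table (printed tables report
# per-cross pod set / pseudo-pod set but not the raw counts behind them).
TRAIT_PCT_COLUMNS <- c("pod_set", "pseudo_pod_set")

#' Read a pollination or trait table
#'
#' Reads a delimited text file (comma or tab separated, auto-detected from the
#' extension unless \code{sep} is given) holding either per-cross-per-replicate
#' pollination counts or per-cross trait measurements, validates it, and
#' returns a typed data frame.
#'
#' A pollination table needs columns \code{cross_label}, \code{replicate},
#' \code{n_pollinated}, \code{n_pod}, \code{n_pseudo}, \code{n_dropped}; every
#' count must be a non-negative integer and pods + pseudo-pods + dropped
#' flowers can not exceed the flowers pollinated. A trait table needs
#' \code{cross_label} plus at least one recognised trait column (see
#' \code{kolacross:::TRAIT_COLUMNS}); unknown extra columns are preserved.
#'
#' @param path file path.
#' @param schema \code{"pollination"} or \code{"trait"}.
#' @param sep field separator; \code{NULL} auto-detects (\code{.tsv}/\code{.txt}
#'   read as tab, anything else as comma).
#' @return data.frame carrying attributes \code{schema} and \code{source_rows}
#'   (original file row numbers, for error provenance).
#' @export
read_cross_table <- function(path, schema = c("pollination", "trait"),
                             sep = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    stop_kola("file not found: ", path, class = "kola_io_error")
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", strip.white = TRUE,
                           comment.char = "", quote = "\"",
                           fileEncoding = "UTF-8")
  validate_cross_table(raw, schema, source = path)
}

validate_cross_table <- function(df, schema, source = "<data>") {
  required <- if (schema == "pollination") POLLINATION_COLUMNS else "cross_label"
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_kola("table ", source, " lacks required column(s): ",
              paste(missing, collapse = ", "), class = "kola_schema_error")
  }
  numeric_cols <- if (schema == "pollination") {
    setdiff(POLLINATION_COLUMNS, "cross_label")
  } else {
    known <- intersect(c(TRAIT_COLUMNS, TRAIT_PCT_COLUMNS), names(df))
    if (!length(known)) {
      stop_kola("trait table ", source, " has no recognised trait column",
                class = "kola_schema_error")
    }
    known
  }
  rows <- seq_len(nrow(df))
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & nzchar(df[[col]]) & is.na(vals))
    if (length(bad)) {
      stop_kola("unparseable numeric value in column ", sQuote(col),
                " of ", source, " at row(s) ", paste(bad, collapse = ", "),
                class = "kola_parse_error")
    }
    df[[col]] <- vals
  }
  # labels must parse under the pedigree grammar
  for (i in rows) parse_cross_label(df$cross_label[i])
  if (schema == "pollination") {
    counts <- df[, c("n_pollinated", "n_pod", "n_pseudo", "n_dropped")]
    bad <- which(apply(counts, 1L, function(r) {
      any(is.na(r)) || any(r < 0) || any(r != round(r)) ||
        sum(r[-1]) > r[1]
    }))
    if (length(bad)) {
      stop_kola("invalid pollination counts (negative, non-integer, or ",
                "pods + pseudo-pods + dropped > pollinated) in ", source,
                " at row(s) ", paste(bad, collapse = ", "),
                class = "kola_validation_error")
    }
  } else {
    if (all(c("weight_peeled", "weight_unpeeled") %in% names(df))) {
      bad <- which(!is.na(df$weight_peeled) & !is.na(df$weight_unpeeled) &
                     df$weight_peeled > df$weight_unpeeled + 1e-9)
      if (length(bad)) {
        stop_kola("weight_peeled exceeds weight_unpeeled in ", source,
                  " at row(s) ", paste(bad, collapse = ", "),
                  class = "kola_validation_error")
      }
    }
    if ("outturn" %in% names(df)) {
      bad <- which(!is.na(df$outturn) & (df$outturn < 0 | df$outturn > 100))
      if (length(bad)) {
        stop_kola("outturn outside [0, 100] in ", source, " at row(s) ",
                  paste(bad, collapse = ", "), class = "kola_validation_error")
      }
    }
  }
  attr(df, "schema") <- schema
  attr(df, "source_rows") <- rows
  df
}

#' Assemble a crossing-trial dataset
#'
#' Bundles a pollination table and/or a trait table into a single dataset
#' object. Trait rows whose cross does not appear among the pollination
#' crosses are flagged as orphans (attribute \code{orphan_traits}), not
#' rejected: printed tables often carry per-cross percentages without the raw
#' counts.
#'
#' @param pollinations pollination data.frame (may be \code{NULL}).
#' @param traits trait data.frame (may be \code{NULL}).
#' @param metadata optional named list (genebank label, year range, ...).
#' @return object of class \code{"kola_dataset"}.
#' @export
kola_dataset <- function(pollinations = NULL, traits = NULL, metadata = list()) {
  if (is.null(pollinations) && is.null(traits)) {
    stop_kola("a dataset needs at least one of pollinations/traits",
              class = "kola_validation_error")
  }
  if (!is.null(pollinations) && is.null(attr(pollinations, "schema"))) {
    pollinations <- validate_cross_table(pollinations, "pollination")
  }
  if (!is.null(traits) && is.null(attr(traits, "schema"))) {
    traits <- validate_cross_table(traits, "trait")
  }
  orphans <- character(0)
  if (!is.null(pollinations) && !is.null(traits)) {
    pk <- vapply(pollinations$cross_label, cross_key, "")
    tk <- vapply(traits$cross_label, cross_key, "")
    orphans <- unique(traits$cross_label[!tk %in% pk])
  }
  structure(
    list(pollinations = pollinations, traits = traits, metadata = metadata),
    orphan_traits = orphans,
    class = "kola_dataset"
  )
}

#' @export
print.kola_dataset <- function(x, ...) {
  np <- if (is.null(x$pollinations)) 0L else nrow(x$pollinations)
  nt <- if (is.null(x$traits)) 0L else nrow(x$traits)
  labels <- dataset_labels(x)
  cat("<kola_dataset> ", length(labels), " crosses; ",
      np, " pollination record(s), ", nt, " trait record(s)\n", sep = "")
  if (length(attr(x, "orphan_traits"))) {
    cat("  orphan trait crosses: ",
        paste(attr(x, "orphan_traits"), collapse = ", "), "\n", sep = "")
  }
  md <- x$metadata
  if (length(md)) {
    cat("  metadata: ", paste(names(md), unlist(md), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# All distinct cross labels in dataset order (pollinations first).
dataset_labels <- function(dataset) {
  labs <- c(
    if (!is.null(dataset$pollinations)) dataset$pollinations$cross_label,
    if (!is.null(dataset$traits)) dataset$traits$cross_label
  )
  labs[!duplicated(vapply(labs, cross_key, ""))]
}

#' Write a dataset to delimited files or JSON
#'
#' \code{write_cross_dataset} writes the pollination and trait tables as CSV
#' next to each other; \code{dataset_to_json} serialises the whole dataset
#' (tables plus metadata) as a single JSON document. Both round-trip through
#' [read_cross_table()] / [jsonlite::fromJSON].
#'
#' @param dataset a \code{kola_dataset}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_cross_dataset <- function(dataset, dir, prefix = "dataset") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(dataset$pollinations)) {
    p <- file.path(dir, paste0(prefix, "_pollinations.csv"))
    utils::write.csv(dataset$pollinations, p, row.names = FALSE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  if (!is.null(dataset$traits)) {
    p <- file.path(dir, paste0(prefix, "_traits.csv"))
    utils::write.csv(dataset$traits, p, row.names = FALSE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_cross_dataset
#' @export
dataset_to_json <- function(dataset) {
  jsonlite::toJSON(
    list(
      metadata = dataset$metadata,
      pollinations = dataset$pollinations,
      traits = dataset$traits
    ),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null"
  )
}

#' Load a packaged in-print trait table
#'
#' Two self-cross trait tables are shipped with the package, transcribed
#' value-for-value from print (one decimal, never recomputed): the 28 GX1
#' single-genotype self-crosses and the 27 MX2 self-crosses, each with per-cross
#' pod set and pseudo-pod set percentages alongside pod/nut yield and quality
#' traits.
#'
#' @param name \code{"gx1_self"} or \code{"mx2_self"}.
#' @return a trait data.frame (schema \code{"trait"}) with a \code{pod_set} and
#'   \code{pseudo_pod_set} column; GX1 rows also carry the printed row codes.
#' @examples
#' gx1 <- kola_fixture("gx1_self")
#' range(gx1$pod_set)  # 1.9 to 54.3
#' @export
kola_fixture <- function(name = c("gx1_self", "mx2_self")) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stop_kola("unknown fixture ", sQuote(name[1]),
              "; available: gx1_self, mx2_self", class = "kola_lookup_error")
  })
  file <- switch(name,
                 gx1_self = "table1_gx1_self.csv",
                 mx2_self = "table2_mx2_self.csv")
  path <- system.file("extdata", file, package = "kolacross", mustWork = TRUE)
  read_cross_table(path, schema = "trait")
}
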