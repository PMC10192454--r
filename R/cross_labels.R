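#' Parse a kola cross pedigree label
#'
#' Cross labels name the female and male sides of a controlled pollination,
#' separated by the multiplication sign. Two ID tokens denote a single cross
#' between genotypes (\code{"JX1/90 × JX1/51"}); four tokens denote a
#' double hybrid cross, i.e. a cross between two F1 hybrid trees, written as
#' the four grandparental genotypes (\code{"B1/11 × B1/71 × B1/157
#' × B1/149"}): the first two IDs form the female hybrid entity, the last
#' two the male hybrid entity.
#'
#' Both \code{"×"} (with or without surrounding whitespace) and a
#' free-standing \code{"x"}/\code{"X"} (whitespace on both sides) are accepted
#' as separators, since published pedigrees mix the two. Genotype IDs may
#' contain an internal space (\code{"JB 32"}) or no genebank prefix at all
#' (\code{"A1"}, \code{"Club"}).
#'
#' @param text a single character string, the cross label.
#' @return An object of class \code{"cross_spec"}: a list with elements
#'   \code{label} (the original text), \code{female} and \code{male}, each an
#'   entity list with \code{kind} (\code{"genotype"} or \code{"hybrid-pair"})
#'   and \code{members} (1 or 2 genotype ID strings).
#' @examples
#' parse_cross_label("JX1/90 × JX1/51")
#' parse_cross_label("B1/11 x B1/71 x B1/157 x B1/149")
#' @seealso [classify_cross_type()], [genotype_id()]
#' @export
parse_cross_label <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop_kola("cross label must be a single character string",
              class = "kola_parse_error")
  }
  tokens <- strsplit(text, "\\s*×\\s*|\\s+[xX]\\s+")[[1]]
  tokens <- squash_ws(tokens)
  if (any(!nzchar(tokens))) {
    stop_kola("empty genotype token in cross label ", sQuote(text),
              class = "kola_parse_error")
  }
  n <- length(tokens)
  if (!n %in% c(2L, 4L)) {
    stop_kola("cross label ", sQuote(text), " has ", n,
              " genotype token(s); expected 2 (single cross) or 4 (double cross)",
              class = "kola_parse_error")
  }
  mk_entity <- function(members) {
    list(kind = if (length(members) == 2L) "hybrid-pair" else "genotype",
         members = members)
  }
  spec <- if (n == 2L) {
    list(label = text, female = mk_entity(tokens[1]), male = mk_entity(tokens[2]))
  } else {
    list(label = text, female = mk_entity(tokens[1:2]), male = mk_entity(tokens[3:4]))
  }
  class(spec) <- "cross_spec"
  spec
}

#' Split a genotype ID into genebank and accession
#'
#' IDs of the form \code{"JX1/90"} carry an explicit genebank prefix before the
#' slash; bare IDs such as \code{"A1"} or \code{"JB 32"} (common in the MX2
#' collection) have no prefix and the whole token is the accession.
#'
#' @param id character vector of genotype ID strings.
#' @return data.frame with columns \code{genebank} (\code{""} when absent) and
#'   \code{accession}.
#' @export
genotype_id <- function(id) {
  id <- squash_ws(id)
  if (any(!nzchar(id))) {
    stop_kola("genotype ID must be non-empty", class = "kola_parse_error")
  }
  has_slash <- grepl("/", id, fixed = TRUE)
  genebank <- ifelse(has_slash, sub("/.*$", "", id), "")
  accession <- ifelse(has_slash, sub("^[^/]*/", "", id), id)
  if (any(!nzchar(accession)) || any(has_slash & !nzchar(genebank))) {
    stop_kola("malformed genotype ID: ", paste(sQuote(id), collapse = ", "),
              class = "kola_parse_error")
  }
  data.frame(genebank = genebank, accession = accession,
             stringsAsFactors = FALSE)
}

# Canonical comparison key for a genotype ID: case-folded, internal whitespace
# removed, so "JB 1" and "JB1" (both spellings occur in print) compare equal.
canonical_id <- function(id) {
  toupper(gsub("\\s+", "", id))
}

canonical_entity <- function(entity) {
  paste(sort(canonical_id(entity$members)), collapse = "|")
}

entity_label <- function(entity) {
  paste(entity$members, collapse = " × ")
}

#' @export
format.cross_spec <- function(x, ...) {
  paste(entity_label(x$female), entity_label(x$male), sep = " × ")
}

#' @export
print.cross_spec <- function(x, ...) {
  cat("<cross_spec> ", format(x), "  [", classify_cross_type(x), "]\n", sep = "")
  invisible(x)
}

#' Canonical rendering of a cross label
#'
#' Reparses and renders a label (or \code{cross_spec}) with normalized
#' \code{" × "} separators. Rendering round-trips through
#' [parse_cross_label()].
#'
#' @param x a cross label string or a \code{cross_spec}.
#' @return character string.
#' @export
cross_label <- function(x) {
  if (!inherits(x, "cross_spec")) x <- parse_cross_label(x)
  format(x)
}

# Key used for dataset joins. The female/male direction of a cross is
# meaningful and preserved; member order *within* a hybrid-pair entity is not
# (an F1 tree is the same tree whichever way its parents are listed), so
# entity members are sorted.
cross_key <- function(x) {
  if (!inherits(x, "cross_spec")) x <- parse_cross_label(x)
  paste(canonical_entity(x$female), canonical_entity(x$male), sep = " x ")
}

#' Classify a cross as self or hybrid, single or double
#'
#' Single crosses (genotype \eqn{\times} genotype) are \code{"SCS"} when female
#' and male are the same genotype (a self-pollination) and \code{"SCC"}
#' otherwise. Double crosses (hybrid-pair \eqn{\times} hybrid-pair) are
#' \code{"DCS"} when the two parental pairs are the same unordered set of
#' genotypes and \code{"DCC"} otherwise. Selfing direction is meaningless, so
#' pair comparison ignores member order.
#'
#' @param spec a \code{cross_spec} (or a label string, parsed on the fly).
#' @return one of \code{"SCS"}, \code{"SCC"}, \code{"DCS"}, \code{"DCC"}.
#' @examples
#' classify_cross_type("JX1/11 × JX1/11")  # SCS
#' classify_cross_type("JX1/90 × JX1/51")  # SCC
#' @export
classify_cross_type <- function(spec) {
  if (!inherits(spec, "cross_spec")) spec <- parse_cross_label(spec)
  if (spec$female$kind != spec$male$kind) {
    stop_kola("cross ", sQuote(spec$label),
              " mixes a genotype with a hybrid pair; not a supported design",
              class = "kola_classify_error")
  }
  same <- identical(canonical_entity(spec$female), canonical_entity(spec$male))
  if (spec$female$kind == "genotype") {
    if (same) "SCS" else "SCC"
  } else {
    if (same) "DCS" else "DCC"
  }
}

# Vectorized cross-type over a character vector of labels.
cross_types <- function(labels) {
  vapply(labels, function(l) classify_cross_type(parse_cross_label(l)), "",
         USE.NAMES = FALSE)
}
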