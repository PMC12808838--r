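# Acuity rule sets
#
# A rule set is an ordered list of predicates over daily intervention flags,
# mapping each infant care-day to one of three dependency categories:
# intensive care (IC), high-dependency care (HDC) or special care (SC).
# Evaluation is strictly top-down, first match wins, and unmatched days fall
# through to the default category (SC). The contested clinical content — which
# interventions imply which category — is data, not code: it ships as an
# editable YAML document and the default table is a reconstruction of the
# three-level BAPM category definitions for the register's named
# interventions.
#
# The "adapted" toggle implements the parenteral-nutrition adjustment: under
# the original scheme, parenteral nutrition without any respiratory support
# implies intensive care; the adapted scheme classifies those days as
# high-dependency care instead, to avoid inflating acuity (and thereby
# deflating provision ratios) for infants most of whom do not need intensive
# care. The two schemes differ on exactly that set of days.

#' Load and validate an acuity rule set
#'
#' Reads a YAML rule document (vocabulary, ordered rules, weights) and returns
#' a validated rule set. Each rule has an `id`, a `category`, optional
#' `all_of` / `any_of` / `none_of` flag lists, and optionally an
#' `adapted_category` that replaces `category` when `adapted = TRUE`.
#' After the toggle is applied, rules are stably re-ordered so that all IC
#' rules precede all HDC rules (severity-monotone evaluation order).
#'
#' Validation rejects: flags not declared in the vocabulary, categories
#' outside IC/HDC/SC, rule orders that cannot be made severity-monotone, and
#' weights that are not strictly decreasing IC > HDC > SC within (0, 1].
#'
#' @param path Path to a YAML rule document. Defaults to the packaged
#'   reconstructed rule table.
#' @param adapted Use the adapted parenteral-nutrition handling (default TRUE).
#' @return An object of class `acuity_ruleset`.
#' @export
#' @examples
#' rs <- load_ruleset(adapted = TRUE)
#' rs$weights
load_ruleset <- function(path = NULL, adapted = TRUE) {
  path <- path %||% system.file("extdata", "acuity_rules.yaml",
                                package = "acuitybench", mustWork = TRUE)
  if (!file.exists(path)) stop("rule file not found: ", path)
  doc <- yaml::read_yaml(path)
  ruleset_from_list(doc, adapted = adapted, source = path)
}

#' Default rule set
#'
#' Convenience wrapper around [load_ruleset()] for the packaged rule table.
#'
#' @inheritParams load_ruleset
#' @return An `acuity_ruleset`.
#' @export
default_ruleset <- function(adapted = TRUE) load_ruleset(NULL, adapted = adapted)

# Build + validate a ruleset from a parsed document.
ruleset_from_list <- function(doc, adapted, source = "<in-memory>") {
  for (field in c("vocabulary", "rules", "weights")) {
    if (is.null(doc[[field]])) stop("rule document missing field: ", field)
  }
  vocabulary <- as.character(unlist(doc$vocabulary))
  if (anyDuplicated(vocabulary)) stop("duplicate names in vocabulary")

  rules <- lapply(doc$rules, function(r) {
    if (is.null(r$id) || is.null(r$category)) {
      stop("every rule needs an 'id' and a 'category'")
    }
    category <- if (adapted && !is.null(r$adapted_category)) {
      r$adapted_category
    } else {
      r$category
    }
    if (!category %in% ACUITY_LEVELS) {
      stop("rule '", r$id, "': unknown category '", category, "'")
    }
    flags <- unique(unlist(r[c("all_of", "any_of", "none_of")]))
    unknown <- setdiff(flags, vocabulary)
    if (length(unknown)) {
      stop("rule '", r$id, "' references undeclared flag(s): ",
           paste(unknown, collapse = ", "))
    }
    if (length(flags) == 0) stop("rule '", r$id, "' has no predicate")
    list(id = as.character(r$id), category = category,
         all_of = as.character(r$all_of %||% character()),
         any_of = as.character(r$any_of %||% character()),
         none_of = as.character(r$none_of %||% character()))
  })

  # Stable severity sort: IC rules first, then HDC, then any SC rules. This
  # preserves relative order within a category and guarantees the
  # severity-monotone evaluation order the first-match semantics rely on.
  sev <- match(vapply(rules, `[[`, "", "category"), ACUITY_LEVELS)
  rules <- rules[order(sev)]

  default_category <- doc$default_category %||% "SC"
  if (!default_category %in% ACUITY_LEVELS) {
    stop("unknown default category: ", default_category)
  }

  weights <- unlist(doc$weights)[ACUITY_LEVELS]
  if (anyNA(weights)) stop("weights must be given for IC, HDC and SC")
  if (!(weights[["IC"]] > weights[["HDC"]] && weights[["HDC"]] > weights[["SC"]])) {
    stop("weights must be strictly decreasing IC > HDC > SC, got ",
         paste(sprintf("%s=%g", names(weights), weights), collapse = ", "))
  }
  if (any(weights <= 0) || any(weights > 1)) stop("weights must lie in (0, 1]")

  structure(
    list(vocabulary = vocabulary, rules = rules,
         default_category = default_category, weights = weights,
         adapted = isTRUE(adapted), source = source,
         source_hash = rlang::hash(list(doc, adapted))),
    class = "acuity_ruleset"
  )
}

#' @export
print.acuity_ruleset <- function(x, ...) {
  cat("<acuity_ruleset> (", if (x$adapted) "adapted" else "original",
      " scheme, hash ", substr(x$source_hash, 1, 8), ")\n", sep = "")
  cat("  vocabulary:", length(x$vocabulary), "interventions\n")
  for (r in x$rules) {
    pred <- c(
      if (length(r$all_of)) paste0("all_of{", paste(r$all_of, collapse = ","), "}"),
      if (length(r$any_of)) paste0("any_of{", paste(r$any_of, collapse = ","), "}"),
      if (length(r$none_of)) paste0("none_of{", paste(r$none_of, collapse = ","), "}")
    )
    cat(sprintf("  %-20s -> %-3s  %s\n", r$id, r$category,
                paste(pred, collapse = " & ")))
  }
  cat("  default ->", x$default_category, "\n")
  cat("  weights:", paste(sprintf("%s=%.2f", names(x$weights), x$weights),
                          collapse = " "), "\n")
  invisible(x)
}

#' Acuity weights of a rule set
#'
#' @param ruleset An `acuity_ruleset` (default: packaged adapted rules).
#' @return Named numeric vector `c(IC=, HDC=, SC=)`.
#' @export
acuity_weights <- function(ruleset = default_ruleset()) ruleset$weights
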