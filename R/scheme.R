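#' Define the substrate category scheme
#'
#' A category scheme names the coral prey categories (the genera a corallivore
#' actually bites, plus a pooled "other coral" group) and the non-coral
#' substrate categories recorded by a point-intercept survey. Every table read
#' or generated by the package is validated against a scheme, and all
#' availability and selectivity computations are indexed by its prey labels.
#'
#' Matching of labels in data files is case-insensitive and ignores surrounding
#' whitespace. Unknown labels are never silently regrouped: to fold, say, a
#' rare genus into the other-coral category, pass it through `aliases`.
#'
#' @param prey_categories Character vector of coral prey labels, in display
#'   order. The last entries typically include the pooled other-coral label.
#' @param substrate_categories Character vector of non-coral substrate labels.
#' @param other_coral_label Single label (must be in `prey_categories`) into
#'   which rare or unidentified scleractinians are pooled.
#' @param aliases Named character vector mapping raw data labels to scheme
#'   labels, e.g. `c(Leptoria = "OtherCoral")`. Matching of alias keys is also
#'   case-insensitive.
#' @return An object of class `category_scheme`.
#' @examples
#' sch <- default_scheme()
#' sch$prey_categories
#' @export
category_scheme <- function(prey_categories,
                            substrate_categories,
                            other_coral_label = prey_categories[length(prey_categories)],
                            aliases = character()) {
  prey_categories <- as.character(prey_categories)
  substrate_categories <- as.character(substrate_categories)
  labs <- c(prey_categories, substrate_categories)
  if (any(!nzchar(trimws(labs)))) {
    rlang::abort("Category labels must be non-empty.")
  }
  if (anyDuplicated(tolower(trimws(labs)))) {
    rlang::abort("Prey and substrate labels must be unique and disjoint (case-insensitive).")
  }
  if (!other_coral_label %in% prey_categories) {
    rlang::abort("`other_coral_label` must be one of `prey_categories`.")
  }
  if (length(aliases)) {
    if (is.null(names(aliases)) || any(!nzchar(names(aliases)))) {
      rlang::abort("`aliases` must be a named character vector (raw label -> scheme label).")
    }
    bad <- setdiff(tolower(trimws(aliases)), tolower(labs))
    if (length(bad)) {
      rlang::abort(paste0("Alias targets not in scheme: ", paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(
      prey_categories = prey_categories,
      substrate_categories = substrate_categories,
      other_coral_label = other_coral_label,
      aliases = aliases
    ),
    class = "category_scheme"
  )
}

#' Default seven-prey / six-substrate category scheme
#'
#' Seven coral prey categories (six genera fed on most frequently, plus a
#' pooled `OtherCoral` group for rare and unidentified scleractinians) and six
#' non-coral substrate categories, the standard scheme for shallow reef-flat
#' photoquadrat surveys.
#'
#' @param aliases Optional alias map, as in [category_scheme()].
#' @return A `category_scheme`.
#' @export
default_scheme <- function(aliases = character()) {
  category_scheme(
    prey_categories = c(
      "Acropora", "Pocillopora", "Porites", "Fungia",
      "Galaxea", "Montipora", "OtherCoral"
    ),
    substrate_categories = c(
      "soft coral", "sponge", "macroalgae", "sand", "rubble", "rock"
    ),
    other_coral_label = "OtherCoral",
    aliases = aliases
  )
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("<category_scheme>\n")
  cat("  prey:     ", paste(x$prey_categories, collapse = ", "), "\n")
  cat("  substrate:", paste(x$substrate_categories, collapse = ", "), "\n")
  cat("  other coral pooled as:", x$other_coral_label, "\n")
  if (length(x$aliases)) {
    cat("  aliases:  ", paste(names(x$aliases), "->", x$aliases, collapse = "; "), "\n")
  }
  invisible(x)
}

#' All labels of a scheme
#' @param scheme A `category_scheme`.
#' @return Character vector of prey then substrate labels.
#' @export
scheme_labels <- function(scheme) {
  c(scheme$prey_categories, scheme$substrate_categories)
}

# Map raw labels onto scheme labels: trim, case-fold, apply aliases.
# Returns the canonical label, or NA for labels the scheme does not know.
normalise_categories <- function(x, scheme) {
  key <- tolower(trimws(as.character(x)))
  if (length(scheme$aliases)) {
    akey <- tolower(trimws(names(scheme$aliases)))
    hit <- match(key, akey)
    key[!is.na(hit)] <- tolower(trimws(scheme$aliases[hit[!is.na(hit)]]))
  }
  labs <- scheme_labels(scheme)
  labs[match(key, tolower(labs))]
}

#' Is a label a coral prey category?
#' @param x Character vector of (already canonical) labels.
#' @param scheme A `category_scheme`.
#' @return Logical vector.
#' @export
is_prey_category <- function(x, scheme) {
  x %in% scheme$prey_categories
}
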