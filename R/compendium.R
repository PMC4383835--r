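#' Load and validate an activity-MET compendium
#'
#' A compendium maps each diary activity code to a human-readable label, a
#' behaviour category, a free subcategory tag, and an intensity in metabolic
#' equivalents (MET). Valid categories are `household`, `transportation`,
#' `work`, `leisure_sports` and `uncategorized`; the last holds activities
#' such as sleep and personal care that count toward total MET but never
#' toward the four behaviour-category totals. MET values must lie in
#' `[0.9, 18]` — 0.9 is the conventional sleeping intensity and 18 the upper
#' end of compendium values for vigorous sport.
#'
#' @param source path to a CSV file with header
#'   `code,label,category,subcategory,met`.
#' @return an object of class `compendium`: a validated data frame with the
#'   five columns above, one row per activity.
#' @seealso [default_compendium()] for the packaged 91-activity fixture,
#'   [lookup_activity()], [write_compendium()].
#' @export
#' @examples
#' comp <- default_compendium()
#' nrow(comp)
#' lookup_activity(comp, "SLEEP")
load_compendium <- function(source) {
  if (!file.exists(source)) {
    stop("compendium file not found: ", source, call. = FALSE)
  }
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        colClasses = c(code = "character"))
  required <- c("code", "label", "category", "subcategory", "met")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("compendium is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  new_compendium(df[required], version = basename(source))
}

new_compendium <- function(df, version = "unversioned") {
  validate_compendium(df)
  structure(df, class = c("compendium", "data.frame"), version = version)
}

validate_compendium <- function(df) {
  dup <- df$code[duplicated(df$code)]
  if (length(dup) > 0) {
    stop("duplicate activity code(s) in compendium: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_cat <- setdiff(unique(df$category), CATEGORIES)
  if (length(bad_cat) > 0) {
    stop("unknown category value(s): ", paste(bad_cat, collapse = ", "),
         "; expected one of ", paste(CATEGORIES, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$met) || anyNA(df$met)) {
    stop("met column must be numeric with no missing values", call. = FALSE)
  }
  out_of_range <- df$code[df$met < 0.9 | df$met > 18.0]
  if (length(out_of_range) > 0) {
    stop("MET outside [0.9, 18.0] for code(s): ",
         paste(out_of_range, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' The packaged default compendium
#'
#' Returns the compendium shipped with the package: 91 activities across the
#' four behaviour categories plus four uncategorized activities (sleeping at
#' MET 0.9, personal care, eating, bathing). The activity list and MET
#' assignments follow the conventions of the Ainsworth compendium of physical
#' activities; the menu is a synthetic stand-in constructed so that every
#' subcategory used by the scoring decomposition (commuting by foot, transit
#' and car, the four work intensities, sport/exercise, cooking, cleaning,
#' childcare, cycling for transport, car washing/gardening, sleep, personal
#' care) is represented.
#'
#' @return a `compendium` object with 95 rows.
#' @export
default_compendium <- function() {
  path <- system.file("extdata", "compendium_91.csv", package = "metdiary")
  comp <- load_compendium(path)
  attr(comp, "version") <- "metdiary-91-v1"
  comp
}

#' Look up one activity by code
#'
#' @param compendium a `compendium` object.
#' @param code a single activity code.
#' @return a list with elements `code`, `label`, `category`, `subcategory`,
#'   `met`.
#' @export
lookup_activity <- function(compendium, code) {
  stopifnot(inherits(compendium, "compendium"), length(code) == 1L)
  i <- match(code, compendium$code)
  if (is.na(i)) {
    stop("unknown activity code: ", code, call. = FALSE)
  }
  as.list(compendium[i, , drop = FALSE])
}

#' Write a compendium back to CSV
#'
#' Inverse of [load_compendium()]: `load_compendium(write_compendium(x, f))`
#' reproduces `x` column for column.
#'
#' @param compendium a `compendium` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_compendium <- function(compendium, path) {
  stopifnot(inherits(compendium, "compendium"))
  utils::write.csv(as.data.frame(compendium), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.compendium <- function(x, ...) {
  tab <- table(factor(x$category, levels = CATEGORIES))
  cat("<compendium> ", nrow(x), " activities (version ",
      attr(x, "version") %||% "unversioned", ")\n", sep = "")
  for (cat_name in names(tab)) {
    cat("  ", format(cat_name, width = 16), tab[[cat_name]], "\n", sep = "")
  }
  invisible(x)
}

# fast vectorised resolution used by the scorer: codes -> row indices
compendium_index <- function(compendium, codes) {
  idx <- match(codes, compendium$code)
  bad <- !is.na(codes) & is.na(idx)
  if (any(bad)) {
    stop("unknown activity code(s): ",
         paste(unique(codes[bad]), collapse = ", "), call. = FALSE)
  }
  idx
}
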