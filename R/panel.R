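# Panel registry: load, validate and query the antibody panel.
#
# A panel catalog is a tibble with one row per entry:
#   name        short antibody identifier, exactly as printed in the panel file
#   category    functional-category label (file order is preserved)
#   is_overlap  TRUE for cross-listed references that point, by exact name, at
#               a primary (non-overlap) entry in another category
#   source_tag  opaque vendor/footnote marker (not interpreted)
#   description optional free text
# with attributes `categories` (ordered labels) and `housekeeping_category`.

PANEL_COLS <- c("name", "category", "is_overlap", "source_tag", "description")

#' Path of the packaged antibody panel
#'
#' The packaged panel describes 218 primary antibodies in 20 functional
#' categories plus 73 overlap (cross-listed) references; its comment header
#' carries the transcription changelog.
#'
#' @return Path to the installed TSV panel file.
#' @export
packaged_panel_path <- function() {
  system.file("extdata", "antibody_panel.tsv", package = "iphplc", mustWork = TRUE)
}

#' Load and validate an antibody panel catalog
#'
#' Reads a panel file (TSV with columns `name`, `category`, `is_overlap`,
#' `source_tag`, `description`, or a JSON array of objects with the same
#' fields), validates it, and returns a panel catalog. Validation enforces:
#' non-empty names, uniqueness of (name, category, is_overlap), and that every
#' overlap reference resolves by exact name to exactly one primary entry in
#' another category.
#'
#' @param path Panel file (`.tsv`/`.txt` or `.json`). Defaults to the
#'   packaged panel.
#' @param housekeeping_category Label of the housekeeping category. `NULL`
#'   (default) auto-detects a single category whose label contains
#'   "housekeeping" (case-insensitive), if any.
#' @return A tibble of class `ip_panel`; entries preserve file order.
#' @seealso [category_counts()], [write_panel()], [panel_entries()]
#' @examples
#' panel <- load_panel()
#' sum(!panel$is_overlap) # 218
#' @export
load_panel <- function(path = packaged_panel_path(), housekeeping_category = NULL) {
  if (!file.exists(path)) stop_iphplc("panel file does not exist: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path)
    if (length(raw) == 0) stop_iphplc("panel file is empty: %s", path)
    entries <- tibble::as_tibble(raw)
    for (col in PANEL_COLS) {
      if (!col %in% names(entries)) entries[[col]] <- NA_character_
    }
    entries <- entries[PANEL_COLS]
  } else {
    # comment lines are stripped by hand: "#" is also a legitimate
    # source_tag value, so readr's comment= would truncate those rows
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[!grepl("^\\s*#", lines)]
    if (length(lines) == 0) stop_iphplc("panel file is empty: %s", path)
    entries <- readr::read_tsv(
      I(paste(lines, collapse = "\n")),
      col_types = readr::cols(
        name = readr::col_character(),
        category = readr::col_character(),
        is_overlap = readr::col_logical(),
        source_tag = readr::col_character(),
        description = readr::col_character()
      ),
      progress = FALSE
    )
  }
  if (nrow(entries) == 0) stop_iphplc("panel file contains no entries: %s", path)
  new_panel(entries, housekeeping_category = housekeeping_category)
}

#' Construct a panel catalog from a data frame
#'
#' @param entries Data frame with columns `name`, `category`, `is_overlap`,
#'   and optionally `source_tag`, `description`.
#' @inheritParams load_panel
#' @return A validated `ip_panel` tibble.
#' @export
new_panel <- function(entries, housekeeping_category = NULL) {
  entries <- tibble::as_tibble(entries)
  for (col in c("source_tag", "description")) {
    if (!col %in% names(entries)) entries[[col]] <- NA_character_
  }
  missing <- setdiff(c("name", "category", "is_overlap"), names(entries))
  if (length(missing) > 0) {
    stop_iphplc("panel is missing column(s): %s", paste(missing, collapse = ", "))
  }
  entries <- entries[PANEL_COLS]
  entries$is_overlap <- as.logical(entries$is_overlap)
  validate_panel_entries(entries)

  categories <- unique(entries$category)
  if (is.null(housekeeping_category)) {
    hk <- grep("housekeeping", categories, ignore.case = TRUE, value = TRUE)
    housekeeping_category <- if (length(hk) == 1) hk else NA_character_
  } else if (!housekeeping_category %in% categories) {
    stop_iphplc("housekeeping category %s not present in panel", housekeeping_category)
  }

  structure(
    entries,
    class = c("ip_panel", class(tibble::tibble())),
    categories = categories,
    housekeeping_category = housekeeping_category
  )
}

validate_panel_entries <- function(entries) {
  bad <- which(is.na(entries$name) | !nzchar(entries$name))
  if (length(bad) > 0) stop_iphplc("panel row %d has an empty antibody name", bad[1])
  bad <- which(is.na(entries$category) | !nzchar(entries$category))
  if (length(bad) > 0) stop_iphplc("panel row %d has an empty category", bad[1])
  bad <- which(is.na(entries$is_overlap))
  if (length(bad) > 0) stop_iphplc("panel row %d has a malformed is_overlap flag", bad[1])

  key <- paste(entries$name, entries$category, entries$is_overlap, sep = "\x1f")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop_iphplc(
      "duplicate panel entry at row %d: %s in category %s",
      dup[1], entries$name[dup[1]], entries$category[dup[1]]
    )
  }

  primaries <- entries$name[!entries$is_overlap]
  overlap_rows <- which(entries$is_overlap)
  for (i in overlap_rows) {
    n_hits <- sum(primaries == entries$name[i])
    if (n_hits != 1L) {
      stop_iphplc(
        "overlap reference at row %d (%s, category %s) resolves to %d primary entries; expected exactly 1",
        i, entries$name[i], entries$category[i], n_hits
      )
    }
  }
  invisible(entries)
}

#' @export
print.ip_panel <- function(x, ...) {
  cat(sprintf(
    "<ip_panel> %d primary antibodies + %d overlap references in %d categories\n",
    sum(!x$is_overlap), sum(x$is_overlap), length(attr(x, "categories"))
  ))
  NextMethod()
}

#' Primary and overlap counts per category
#'
#' @param panel An `ip_panel` catalog.
#' @return Tibble with columns `category`, `n_primary`, `n_overlap`, in panel
#'   order.
#' @examples
#' counts <- category_counts(load_panel())
#' counts[counts$category == "RAS signaling", ] # 22 primaries, 0 overlaps
#' @export
category_counts <- function(panel) {
  stopifnot(inherits(panel, "ip_panel"))
  panel |>
    dplyr::mutate(category = factor(.data$category, levels = attr(panel, "categories"))) |>
    dplyr::group_by(category = .data$category) |>
    dplyr::summarise(
      n_primary = sum(!.data$is_overlap),
      n_overlap = sum(.data$is_overlap),
      .groups = "drop"
    ) |>
    dplyr::mutate(category = as.character(.data$category))
}

#' Entries of one category, with overlap references resolved
#'
#' Returns the category's primary entries followed by its overlap references;
#' each overlap row carries the category in which its primary measurement
#' lives (`resolved_category`).
#'
#' @inheritParams category_counts
#' @param category Category label.
#' @return Tibble `name`, `is_overlap`, `resolved_category`.
#' @export
panel_entries <- function(panel, category) {
  stopifnot(inherits(panel, "ip_panel"))
  if (!category %in% attr(panel, "categories")) {
    stop_iphplc("unknown panel category: %s", category)
  }
  rows <- panel[panel$category == category, ]
  primary_cat <- setNames(
    panel$category[!panel$is_overlap],
    panel$name[!panel$is_overlap]
  )
  tibble::tibble(
    name = rows$name,
    is_overlap = rows$is_overlap,
    resolved_category = ifelse(rows$is_overlap, unname(primary_cat[rows$name]), category)
  )
}

#' Housekeeping antibodies of a panel
#'
#' @inheritParams category_counts
#' @return Character vector of primary antibody names in the panel's
#'   housekeeping category (empty if the panel has none).
#' @export
panel_housekeeping <- function(panel) {
  stopifnot(inherits(panel, "ip_panel"))
  hk_cat <- attr(panel, "housekeeping_category")
  if (is.na(hk_cat)) return(character(0))
  panel$name[panel$category == hk_cat & !panel$is_overlap]
}

#' Write a panel catalog
#'
#' Writes TSV (or JSON when `path` ends in `.json`) readable by
#' [load_panel()]; `load_panel(write_panel(panel, path))` reproduces the
#' catalog exactly.
#'
#' @inheritParams category_counts
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "ip_panel"))
  df <- tibble::as_tibble(panel)[PANEL_COLS]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null", auto_unbox = TRUE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}
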