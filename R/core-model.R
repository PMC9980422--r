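#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Canonical nutrient-profile column names, all per common reference mass
# (100 g or 100 mL): energy in kcal, sodium in mg, the rest in g.
PROFILE_FIELDS <- c(
  "energy_kcal", "carb_g", "protein_g", "fat_g",
  "satfat_g", "sugar_g", "fiber_g", "sodium_mg"
)

PRODUCT_FIELDS <- c(
  "product_id", "subcategory", "brand", "name", "blocking_group",
  PROFILE_FIELDS
)

REFERENCE_FIELDS <- c("food_id", "name", "blocking_group", PROFILE_FIELDS)

#' Nutrient profile column names
#'
#' The eight canonical nutrient-profile columns carried by both product
#' and reference tables: `energy_kcal`, `carb_g`, `protein_g`, `fat_g`,
#' `satfat_g`, `sugar_g`, `fiber_g`, `sodium_mg`. All values are per a
#' common reference mass (conventionally 100 g / 100 mL); the package
#' never rescales, so inputs must already share that basis. A missing
#' value is encoded as `NA` and is tracked explicitly, never coerced
#' to zero.
#'
#' @return Character vector of column names.
#' @export
profile_fields <- function() PROFILE_FIELDS

#' Convert grams of salt to milligrams of sodium
#'
#' Branded-product tables often report salt rather than sodium; the
#' conversion used throughout is `sodium_mg = salt_g * 393`.
#'
#' @param salt_g Non-negative finite numeric vector, grams of salt.
#' @return Milligrams of sodium.
#' @examples
#' salt_to_sodium(1)   # 393
#' salt_to_sodium(2.5) # 982.5
#' @export
salt_to_sodium <- function(salt_g) {
  if (!is.numeric(salt_g)) abort_validation("`salt_g` must be numeric.")
  bad <- !is.na(salt_g) & (!is.finite(salt_g) | salt_g < 0)
  if (any(bad)) {
    abort_validation("`salt_g` must be non-negative and finite.")
  }
  salt_g * 393
}

# Parse a character column as locale-independent numerics (period decimal
# separator, no thousands separators). Empty strings and "NA" are missing.
parse_numeric_column <- function(x, column, rows_label = "row") {
  x <- trimws(as.character(x))
  missing <- is.na(x) | x == "" | x == "NA"
  out <- rep(NA_real_, length(x))
  ok <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x[!missing])
  if (!all(ok)) {
    bad_row <- which(!missing)[which(!ok)[1]]
    abort_validation(sprintf(
      "Column `%s`, %s %d: cannot parse \"%s\" as a number.",
      column, rows_label, bad_row, x[!missing][which(!ok)[1]]
    ))
  }
  out[!missing] <- as.numeric(x[!missing])
  neg <- !is.na(out) & out < 0
  if (any(neg)) {
    abort_validation(sprintf(
      "Column `%s`, %s %d: negative value %s not allowed.",
      column, rows_label, which(neg)[1], out[which(neg)[1]]
    ))
  }
  out
}

map_get <- function(map, key) {
  if (!is.null(map) && key %in% names(map)) map[[key]] else NULL
}

resolve_columns <- function(raw, wanted, column_map, what) {
  src <- vapply(wanted, function(w) map_get(column_map, w) %||% w, character(1))
  missing <- setdiff(src, names(raw))
  if (length(missing)) {
    abort_schema(sprintf(
      "%s file is missing required column(s): %s.",
      what, paste0("`", missing, "`", collapse = ", ")
    ))
  }
  stats::setNames(src, wanted)
}

read_delim_chr <- function(path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
}

#' Read a product table
#'
#' Reads a CSV/TSV of branded products (header row, UTF-8) into the
#' canonical product tibble. Each row carries an id, subcategory, brand,
#' blocking group and a nutrient profile; the display `name` defaults to
#' `"subcategory, brand"` unless the file supplies a `name` column.
#' Sodium may arrive either as a `sodium_mg` column or as a `salt_g`
#' column converted via [salt_to_sodium()] (`salt_column = TRUE`).
#' Eligibility for algorithmic matching is computed on load: a product is
#' eligible iff its energy is strictly positive and none of the required
#' profile fields is missing (see [screen_eligibility()]).
#'
#' @param path Path to a CSV (or `.tsv`) file with a header row.
#' @param column_map Optional named character vector mapping canonical
#'   column names (see [profile_fields()]; plus `product_id`,
#'   `subcategory`, `brand`, `blocking_group`, and optionally `name` /
#'   `salt_g`) to the file's column names. Unmapped names are looked up
#'   verbatim.
#' @param salt_column If `TRUE` the file carries `salt_g` (grams of salt)
#'   instead of `sodium_mg`; exactly one of the two representations must
#'   be declared per table.
#' @param required_fields Profile fields whose absence makes a product
#'   ineligible; defaults to all eight.
#' @return A tibble with the canonical product columns plus `eligible`
#'   and `exclusion_reason`.
#' @export
load_products <- function(path, column_map = NULL, salt_column = FALSE,
                          required_fields = profile_fields()) {
  raw <- read_delim_chr(path)
  id_cols <- c("product_id", "subcategory", "brand", "blocking_group")
  nutrient_cols <- setdiff(PROFILE_FIELDS, "sodium_mg")
  sodium_src <- if (salt_column) "salt_g" else "sodium_mg"
  src <- resolve_columns(raw, c(id_cols, nutrient_cols, sodium_src),
                         column_map, "Product")

  out <- tibble(
    product_id = as.character(raw[[src[["product_id"]]]]),
    subcategory = as.character(raw[[src[["subcategory"]]]]),
    brand = as.character(raw[[src[["brand"]]]]),
    blocking_group = as.character(raw[[src[["blocking_group"]]]])
  )
  name_src <- map_get(column_map, "name") %||% "name"
  out$name <- if (name_src %in% names(raw)) {
    as.character(raw[[name_src]])
  } else {
    paste(out$subcategory, out$brand, sep = ", ")
  }
  for (col in nutrient_cols) {
    out[[col]] <- parse_numeric_column(raw[[src[[col]]]], src[[col]])
  }
  out$sodium_mg <- if (salt_column) {
    salt_to_sodium(parse_numeric_column(raw[[src[["salt_g"]]]], src[["salt_g"]]))
  } else {
    parse_numeric_column(raw[[src[["sodium_mg"]]]], src[["sodium_mg"]])
  }

  dup <- unique(out$product_id[duplicated(out$product_id)])
  if (length(dup)) {
    abort_integrity(sprintf(
      "Duplicate product_id(s): %s.", paste(dup, collapse = ", ")
    ))
  }
  out <- out[c(PRODUCT_FIELDS)]
  screened <- screen_eligibility(out, required_fields = required_fields)
  screened$products
}

#' Read a reference food table
#'
#' As [load_products()] but for the reference food-composition side:
#' columns `food_id`, `name`, `blocking_group` and the nutrient profile.
#' No eligibility screening and no salt conversion is applied.
#'
#' @inheritParams load_products
#' @param group_vocabulary Optional character vector of allowed blocking
#'   groups; rows using a group outside it raise a validation error.
#' @return A tibble with the canonical reference columns.
#' @export
load_reference <- function(path, column_map = NULL, group_vocabulary = NULL) {
  raw <- read_delim_chr(path)
  src <- resolve_columns(raw, c("food_id", "name", "blocking_group", PROFILE_FIELDS),
                         column_map, "Reference")
  out <- tibble(
    food_id = as.character(raw[[src[["food_id"]]]]),
    name = as.character(raw[[src[["name"]]]]),
    blocking_group = as.character(raw[[src[["blocking_group"]]]])
  )
  for (col in PROFILE_FIELDS) {
    out[[col]] <- parse_numeric_column(raw[[src[[col]]]], src[[col]])
  }
  dup <- unique(out$food_id[duplicated(out$food_id)])
  if (length(dup)) {
    abort_integrity(sprintf(
      "Duplicate food_id(s): %s.", paste(dup, collapse = ", ")
    ))
  }
  if (!is.null(group_vocabulary)) {
    unknown <- setdiff(out$blocking_group, group_vocabulary)
    if (length(unknown)) {
      abort_validation(sprintf(
        "Reference rows use blocking group(s) outside the vocabulary: %s.",
        paste(unknown, collapse = ", ")
      ))
    }
  }
  out
}

#' Partition products into eligible and excluded
#'
#' Products cannot be run through the nutrient filters when their energy
#' is zero (the nutrient-share filters divide by energy) or when a
#' required profile field is missing; such products are routed directly
#' to manual matching. The partition is exhaustive and disjoint, and the
#' exclusion reason is one of `"zero_energy"` (energy recorded as 0) or
#' `"missing_nutrient"` (any required field, including energy itself,
#' absent).
#'
#' @param products Product tibble (from [load_products()] or built in
#'   code with the canonical columns).
#' @param required_fields Profile fields that must be present; defaults
#'   to all eight. Use [schedule_required_fields()] to derive the subset
#'   an actual sift schedule needs.
#' @return A list with elements `products` (input plus refreshed
#'   `eligible` / `exclusion_reason` columns), `eligible`, and `excluded`.
#' @export
screen_eligibility <- function(products, required_fields = profile_fields()) {
  required_fields <- union("energy_kcal", required_fields)
  miss <- rep(FALSE, nrow(products))
  for (col in required_fields) miss <- miss | is.na(products[[col]])
  zero_energy <- !is.na(products$energy_kcal) & products$energy_kcal == 0
  products$eligible <- !zero_energy & !miss
  products$exclusion_reason <- dplyr::case_when(
    zero_energy ~ "zero_energy",
    miss ~ "missing_nutrient",
    .default = NA_character_
  )
  list(
    products = products,
    eligible = products[products$eligible, , drop = FALSE],
    excluded = products[!products$eligible, , drop = FALSE]
  )
}

#' Bundle product and reference tables into a linkage dataset
#'
#' Validates that both tables use only blocking groups from a shared
#' vocabulary (by default the union of groups present) and returns the
#' container consumed by [run_schedule()] and [threshold_sweep()].
#'
#' @param products Product tibble.
#' @param reference Reference food tibble.
#' @param group_vocabulary Optional character vector of allowed blocking
#'   groups.
#' @return An object of class `linkage_dataset`.
#' @export
linkage_dataset <- function(products, reference, group_vocabulary = NULL) {
  used <- unique(c(products$blocking_group, reference$blocking_group))
  vocab <- group_vocabulary %||% used
  unknown <- setdiff(used, vocab)
  if (length(unknown)) {
    abort_validation(sprintf(
      "Blocking group(s) not in vocabulary: %s.", paste(unknown, collapse = ", ")
    ))
  }
  if (anyDuplicated(reference$food_id)) {
    abort_integrity("Duplicate food_id in reference table.")
  }
  if (anyDuplicated(products$product_id)) {
    abort_integrity("Duplicate product_id in product table.")
  }
  structure(
    list(products = products, reference = reference, group_vocabulary = vocab),
    class = "linkage_dataset"
  )
}

#' @export
print.linkage_dataset <- function(x, ...) {
  cat(sprintf(
    "<linkage_dataset> %d products, %d reference foods, %d blocking groups\n",
    nrow(x$products), nrow(x$reference), length(x$group_vocabulary)
  ))
  invisible(x)
}

#' Write a linkage dataset to CSV files
#'
#' Writes `products.csv` and `reference.csv` under `dir`, including the
#' `eligible` / `exclusion_reason` columns on the product side. The
#' written pair round-trips through [load_products()] /
#' [load_reference()].
#'
#' @param dataset A [linkage_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dataset$products, file.path(dir, "products.csv"), na = "")
  readr::write_csv(dataset$reference, file.path(dir, "reference.csv"), na = "")
  invisible(dir)
}
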