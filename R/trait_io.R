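#' Construct a trait table
#'
#' A trait table holds one row per species with a taxonomic group label, adult
#' body mass (grams), and any number of life-history trait columns.  All trait
#' values and body masses must be strictly positive, because every downstream
#' criterion works on the log10 scale; non-positive or non-numeric cells are
#' stored as missing.  Each trait column carries a declared unit string.
#'
#' @param df data.frame with columns `species`, `group`, `body_mass`, plus one
#'   column per trait.
#' @param traits character vector of trait column names.
#' @param units named character vector of unit strings; must cover
#'   `body_mass` and every trait.
#' @return An object of class `trait_table` (a data.frame).
#' @export
trait_table <- function(df, traits, units) {
  stopifnot(is.data.frame(df), all(c("species", "group", "body_mass") %in% names(df)))
  missing_cols <- setdiff(traits, names(df))
  if (length(missing_cols))
    stop("trait columns not in data: ", paste(missing_cols, collapse = ", "))
  df$species <- clean_species(df$species)
  dup <- df$species[duplicated(df$species)]
  if (length(dup))
    stop("duplicate species name(s): ", paste(unique(dup), collapse = ", "))
  need_units <- c("body_mass", traits)
  if (!all(need_units %in% names(units)))
    stop("units missing for: ",
         paste(setdiff(need_units, names(units)), collapse = ", "))
  for (col in c("body_mass", traits)) df[[col]] <- positive_or_na(df[[col]], col)
  rownames(df) <- NULL
  structure(df, traits = traits, units = units[need_units],
            class = c("trait_table", "data.frame"))
}

# species names are matched exactly after trimming and collapsing whitespace
clean_species <- function(x) gsub("[[:space:]]+", " ", trimws(as.character(x)))

positive_or_na <- function(x, col) {
  x <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & x <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive value(s) in '", col,
            "' set to missing (log10 undefined)", call. = FALSE)
    x[bad] <- NA_real_
  }
  x
}

#' Read a species trait table from delimited text
#'
#' Reads a CSV/TSV file (UTF-8, header row) and maps its columns onto the
#' trait-table schema.  Cells that are empty, `"NA"`, non-numeric, or
#' non-positive are recorded as missing with a warning; the row count of the
#' input is preserved.  Duplicate species names are a hard error.
#'
#' @param path file path; `.tsv`/`.txt` are read tab-delimited, otherwise
#'   comma-delimited (override with `sep`).
#' @param schema list with elements `species`, `group` (optional), `body_mass`,
#'   `traits` (named character vector, output-name = input-column), and
#'   `units` (named character vector over body_mass and traits).
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path, schema, sep = NULL) {
  stopifnot(file.exists(path))
  if (is.null(sep)) sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, na.strings = c("", "NA"),
                           check.names = FALSE, comment.char = "")
  if (is.null(schema$species) || !schema$species %in% names(raw))
    stop("species column '", schema$species, "' not found in ", path)
  if (length(schema$traits) < 1) stop("schema must name at least one trait column")
  missing_in <- setdiff(unname(schema$traits), names(raw))
  if (length(missing_in))
    stop("trait column(s) not found: ", paste(missing_in, collapse = ", "))
  df <- data.frame(species = raw[[schema$species]], stringsAsFactors = FALSE)
  df$group <- if (!is.null(schema$group) && schema$group %in% names(raw))
    as.character(raw[[schema$group]]) else NA_character_
  df$body_mass <- if (!is.null(schema$body_mass) && schema$body_mass %in% names(raw))
    raw[[schema$body_mass]] else NA_real_
  for (out in names(schema$traits)) df[[out]] <- raw[[schema$traits[[out]]]]
  units <- schema$units
  if (is.null(units)) {
    units <- stats::setNames(rep("unspecified", length(schema$traits) + 1),
                             c("body_mass", names(schema$traits)))
  }
  trait_table(df, traits = names(schema$traits), units = units)
}

#' Write a trait table back to delimited text
#'
#' Inverse of [read_trait_table()]: values and missingness round-trip exactly
#' (missing cells are written as `NA`).
#'
#' @param table a [trait_table()].
#' @param path output path; `.tsv` writes tab-delimited.
#' @export
write_trait_table <- function(table, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(as.data.frame(table), path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Average recorded minimum/maximum trait pairs into a single column
#'
#' Databases often list a trait as a min/max range; analyses use the
#' arithmetic mean of the two.  Where only one of the pair is present that
#' value is carried over; where both are missing the result is missing.  A
#' recorded minimum exceeding its maximum draws a warning but the mean is
#' still taken (the mean is order-insensitive), so the operation is
#' idempotent.
#'
#' @param table a [trait_table()].
#' @param pairs list of `c(min = , max = , out = )` character triples; the
#'   min/max columns must exist as plain columns of `table`.
#' @param units named character vector of units for the new output columns;
#'   defaults to the unit of the min column when available.
#' @return The table with the output columns appended to its trait set.
#' @export
harmonize_min_max <- function(table, pairs, units = NULL) {
  df <- as.data.frame(table)
  traits <- attr(table, "traits")
  unit_map <- attr(table, "units")
  for (p in pairs) {
    stopifnot(all(c("min", "max", "out") %in% names(p)))
    if (!all(c(p[["min"]], p[["max"]]) %in% names(df)))
      stop("min/max columns not found: ", p[["min"]], ", ", p[["max"]])
    lo <- suppressWarnings(as.numeric(df[[p[["min"]]]]))
    hi <- suppressWarnings(as.numeric(df[[p[["max"]]]]))
    inverted <- !is.na(lo) & !is.na(hi) & lo > hi
    if (any(inverted))
      warning(sum(inverted), " row(s) with min > max for '", p[["out"]],
              "'; mean taken anyway", call. = FALSE)
    out <- rowMeans(cbind(lo, hi), na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    df[[p[["out"]]]] <- out
    traits <- union(traits, p[["out"]])
    u <- if (!is.null(units) && p[["out"]] %in% names(units)) units[[p[["out"]]]]
         else if (p[["min"]] %in% names(unit_map)) unit_map[[p[["min"]]]]
         else "unspecified"
    unit_map[p[["out"]]] <- u
  }
  trait_table(df, traits = traits, units = unit_map)
}

#' Define an analysis group
#'
#' An analysis group pools one or more taxonomic labels (e.g. all amphibians
#' = Anura + Caudata + Gymnophiona) under a single name.
#'
#' @param name group label used in reports.
#' @param member_groups non-empty character vector of taxonomic labels.
#' @export
group_spec <- function(name, member_groups) {
  stopifnot(is.character(name), length(member_groups) >= 1)
  structure(list(name = name, member_groups = unique(member_groups)),
            class = "group_spec")
}

#' Subset a trait table to an analysis group
#'
#' @param table a [trait_table()].
#' @param spec a [group_spec()].
#' @return The rows whose `group` is one of the spec's members; an empty
#'   result is allowed (with a warning).
#' @export
subset_group <- function(table, spec) {
  stopifnot(inherits(spec, "group_spec"))
  keep <- table$group %in% spec$member_groups
  if (!any(keep))
    warning("group '", spec$name, "' matches no rows", call. = FALSE)
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  trait_table(out, traits = attr(table, "traits"), units = attr(table, "units"))
}

#' Complete log10 (body mass, trait) pairs for regression
#'
#' Returns, in table order, the species that have both body mass and the
#' requested trait recorded, with both on the log10 scale.  Fewer than three
#' complete pairs are flagged as an insufficient sample; downstream
#' regressions refuse flagged input.
#'
#' @param table a [trait_table()].
#' @param trait trait name.
#' @return list with `x` (log10 body mass), `y` (log10 trait), `species`,
#'   `n`, and `insufficient`.
#' @export
paired_log10 <- function(table, trait) {
  if (!trait %in% attr(table, "traits")) stop("unknown trait: ", trait)
  ok <- !is.na(table$body_mass) & !is.na(table[[trait]])
  out <- list(x = log10(table$body_mass[ok]), y = log10(table[[trait]][ok]),
              species = table$species[ok], n = sum(ok),
              insufficient = sum(ok) < 3)
  class(out) <- "paired_log10"
  out
}
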