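#' Internal standard specification
#'
#' The GC-MS internal standard spiked into every vial. Analyte peak areas
#' are scaled to the standard's peak area for relative quantification. The
#' default reflects 10 uL of a 0.04 uL/mL 3-nonanone solution (4e-4 uL of
#' analyte; at a density of 0.821 g/mL this is 0.3284 ug) added to 5 g of
#' fruit powder. The density is an assumption — the amount is therefore a
#' parameter, not a constant.
#'
#' @param name compound name of the standard.
#' @param amount_ug micrograms of standard added per vial.
#' @param sample_mass_g grams of sample in the vial.
#' @return An object of class `internal_standard`.
#' @export
internal_standard <- function(name = "3-nonanone", amount_ug = 0.3284,
                              sample_mass_g = 5) {
  if (amount_ug <= 0) stop("amount_ug must be positive")
  if (sample_mass_g <= 0) stop("sample_mass_g must be positive")
  structure(list(name = name, amount_ug = amount_ug,
                 sample_mass_g = sample_mass_g),
            class = "internal_standard")
}

chem_classes <- c("ester", "alcohol", "aldehyde", "ketone", "alkane", "other")

check_compound_table <- function(table, need_conc = FALSE) {
  need <- c("sample_id", "compound", "class", "area")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("compound table missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(table$class), chem_classes)
  if (length(bad))
    stop("unknown chemical class label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(chem_classes, collapse = ", "), ")")
  if (need_conc && is.null(table$concentration))
    stop("compound table is not quantified: run relative_quantify() first")
  invisible(table)
}

#' Internal-standard relative quantification
#'
#' Converts peak areas to concentrations by scaling each analyte's area to
#' the internal standard's area in the same sample:
#' `conc_i = (area_i / area_IS) * amount_IS / sample_mass`, expressed in
#' ug/kg. The internal-standard rows themselves receive no concentration and
#' are excluded from downstream totals.
#'
#' @param table compound table: `data.frame` with columns `sample_id`,
#'   `compound`, `class`, `area`.
#' @param is_spec an [internal_standard()].
#' @return The table with a `concentration` column (ug/kg) and an
#'   `is_standard` flag.
#' @export
relative_quantify <- function(table, is_spec = internal_standard()) {
  check_compound_table(table)
  is_row <- table$compound == is_spec$name
  per_sample <- split(seq_len(nrow(table)), table$sample_id)
  area_is <- rep(NA_real_, nrow(table))
  for (sid in names(per_sample)) {
    idx <- per_sample[[sid]]
    k <- idx[is_row[idx]]
    if (length(k) != 1L)
      stop("sample ", sid, ": expected exactly one internal-standard row ('",
           is_spec$name, "'), found ", length(k))
    if (table$area[k] <= 0)
      stop("sample ", sid, ": internal-standard peak area must be positive")
    area_is[idx] <- table$area[k]
  }
  conc <- table$area / area_is * is_spec$amount_ug / is_spec$sample_mass_g * 1000
  table$concentration <- ifelse(is_row, NA_real_, conc)
  table$is_standard <- is_row
  table
}

#' Per-sample chemical-group totals
#'
#' Sums quantified compound concentrations per sample and chemical class.
#' Internal-standard rows and class `"other"` (compounds that resist
#' classification) are excluded; classes absent from a sample total zero.
#'
#' @param table quantified compound table from [relative_quantify()].
#' @return `data.frame` of class `group_totals`: `sample_id` plus one column
#'   per class (`ester`, `alcohol`, `aldehyde`, `ketone`, `alkane`), ug/kg.
#' @export
group_totals <- function(table) {
  check_compound_table(table, need_conc = TRUE)
  keep <- !isTRUE_vec(table$is_standard) & table$class != "other"
  tab <- table[keep, , drop = FALSE]
  ids <- unique(table$sample_id)
  classes <- setdiff(chem_classes, "other")
  out <- data.frame(sample_id = ids)
  for (cl in classes) {
    sums <- tapply(tab$concentration[tab$class == cl],
                   factor(tab$sample_id[tab$class == cl], levels = ids), sum)
    v <- as.numeric(sums)
    v[is.na(v)] <- 0
    out[[cl]] <- v
  }
  class(out) <- c("group_totals", "data.frame")
  out
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' Assign chemical classes from a mapping
#'
#' Fills or overrides the `class` column of a compound table from a
#' compound-name to class mapping, so users can extend the built-in
#' vocabulary assignments. Compounds absent from the mapping keep their
#' existing class, or `"other"` if they had none.
#'
#' @param table compound table (`sample_id`, `compound`, `area`, optionally
#'   `class`).
#' @param mapping named character vector (`compound name -> class`), or a
#'   path to a JSON file holding one object of the same shape.
#' @return The table with its `class` column updated.
#' @export
assign_classes <- function(table, mapping) {
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping))
    mapping <- unlist(jsonlite::read_json(mapping, simplifyVector = TRUE))
  bad <- setdiff(unique(mapping), chem_classes)
  if (length(bad))
    stop("mapping contains unknown class label(s): ", paste(bad, collapse = ", "))
  if (is.null(table$class)) table$class <- "other"
  hit <- table$compound %in% names(mapping)
  table$class[hit] <- unname(mapping[table$compound[hit]])
  table
}

#' Extract a regression target vector
#'
#' Returns the per-sample values of one modelling target — either a chemical
#' group total (from [group_totals()] output) or a single compound's
#' concentration (from a quantified compound table) — aligned to a requested
#' sample order.
#'
#' @param x a `group_totals` data.frame or a quantified compound table.
#' @param target class name (e.g. `"alcohol"`) or compound name.
#' @param sample_ids sample order to align to; defaults to the order in `x`.
#' @return Named numeric vector of concentrations (ug/kg); single compounds
#'   absent from a sample contribute 0.
#' @export
target_vector <- function(x, target, sample_ids = NULL) {
  if (inherits(x, "group_totals")) {
    if (is.null(sample_ids)) sample_ids <- x$sample_id
    if (!target %in% names(x))
      stop("unknown target '", target, "'; available: ",
           paste(setdiff(names(x), "sample_id"), collapse = ", "))
    i <- match(sample_ids, x$sample_id)
    if (anyNA(i)) stop("unknown sample ids requested")
    stats::setNames(x[[target]][i], sample_ids)
  } else {
    check_compound_table(x, need_conc = TRUE)
    if (is.null(sample_ids)) sample_ids <- unique(x$sample_id)
    hit <- x[x$compound == target & !isTRUE_vec(x$is_standard), , drop = FALSE]
    if (!nrow(hit)) {
      cand <- sort(unique(x$compound[!isTRUE_vec(x$is_standard)]))
      stop("unknown target '", target, "'; available compounds: ",
           paste(utils::head(cand, 20), collapse = ", "),
           if (length(cand) > 20) ", ..." else "")
    }
    v <- stats::setNames(rep(0, length(sample_ids)), sample_ids)
    j <- match(hit$sample_id, sample_ids)
    v[j[!is.na(j)]] <- hit$concentration[!is.na(j)]
    v
  }
}
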