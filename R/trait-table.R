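#' Construct and validate a shoot-level trait table
#'
#' A trait table holds one row per sampled shoot with four identifier columns
#' (`species`, `block`, `plot`, `diversity`), one column per configured trait,
#' and `shoot_biomass`. Plots are nested in blocks: a plot label may appear in
#' one block only. `diversity` must be `"monoculture"` or `"mixture"`. Trait
#' values are checked against their physical bounds (angles within 0-180
#' degrees, mass fractions within 0-1, all other traits non-negative); `NA`
#' marks a missing measurement and is allowed everywhere.
#'
#' @param data A data frame with the identifier columns and trait columns.
#' @param config A `trait_config`; defaults to [default_trait_config()].
#' @return The validated data frame with class `trait_table` and the
#'   configuration attached as attribute `trait_config`.
#' @export
trait_table <- function(data, config = default_trait_config()) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(id_columns(), config$trait), names(data))
  if (length(missing_cols) > 0L) {
    stop("trait table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in id_columns()) data[[col]] <- as.character(data[[col]])
  bad_div <- setdiff(unique(data$diversity[!is.na(data$diversity)]), diversity_levels())
  if (length(bad_div) > 0L || anyNA(data$diversity)) {
    stop("diversity must be one of: ", paste(diversity_levels(), collapse = ", "),
         call. = FALSE)
  }
  # plot nested in block
  pb <- unique(data[, c("plot", "block")])
  dup <- pb$plot[duplicated(pb$plot)]
  if (length(dup) > 0L) {
    stop("plot label(s) appear in more than one block: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(config))) {
    tr <- config$trait[i]
    x <- data[[tr]]
    if (!is.numeric(x)) {
      xs <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(xs) & x != "NA" & x != "")
      if (length(bad) > 0L) {
        stop("unparseable numeric value for trait '", tr, "' at row ", bad[1L],
             call. = FALSE)
      }
      x <- xs
      data[[tr]] <- x
    }
    out <- which(!is.na(x) & (x < config$lower[i] | x > config$upper[i]))
    if (length(out) > 0L) {
      stop("trait '", tr, "' outside [", config$lower[i], ", ", config$upper[i],
           "] at row ", out[1L], " (value ", x[out[1L]], ")", call. = FALSE)
    }
  }
  canonical <- c(id_columns(), config$trait)
  extras <- setdiff(names(data), canonical)
  data <- data[, c(canonical, extras), drop = FALSE]
  attr(data, "trait_config") <- config
  class(data) <- c("trait_table", "data.frame")
  data
}

#' Retrieve the trait configuration attached to a table
#' @param table A `trait_table` or `standardized_table`.
#' @return The attached `trait_config`.
#' @export
trait_config_of <- function(table) {
  cfg <- attr(table, "trait_config")
  if (is.null(cfg)) cfg <- default_trait_config()
  cfg
}

#' Read a shoot-level trait table from delimited text
#'
#' Reads a comma- or tab-separated file with one header row. The delimiter is
#' auto-detected from the header (comma tried first) unless given explicitly.
#' Required columns are the four identifiers plus every configured trait;
#' unknown columns are preserved unchanged after the canonical ones. Row order
#' is preserved. Validation (bounds, nesting, diversity levels) is as in
#' [trait_table()].
#'
#' @param path Path to a delimited text file.
#' @param config A `trait_config`.
#' @param delim Optional explicit delimiter (`","` or `"\t"`); overrides
#'   auto-detection.
#' @return A validated `trait_table`.
#' @export
read_trait_table <- function(path, config = default_trait_config(), delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl(",", header, fixed = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA, na.strings = c("NA", ""))
  trait_table(raw, config = config)
}

#' Write a trait table to delimited text
#'
#' Serializes canonical columns first (identifiers, traits in configuration
#' order, biomass), then any extra columns. Numeric values are written with
#' full double precision so that a read back through [read_trait_table()]
#' reproduces the table exactly.
#'
#' @param table A `trait_table`.
#' @param path Output file path.
#' @param delim Field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path, delim = ",") {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1L))
  for (col in names(df)[num]) {
    df[[col]] <- vapply(df[[col]], function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = TRUE)
    }, character(1L))
  }
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = TRUE,
                     na = "NA")
  invisible(path)
}

#' Midpoints of the six field angle categories
#'
#' Angles of shoot axes and leaf blades recorded in the field on a six-level
#' ordinal scale (0-30, 31-60, 61-90, 91-120, 121-150, 151-180 degrees
#' deviation from an ascending vertical) are coded by their interval
#' midpoints: 15, 45, 75, 105, 135, 165 degrees.
#'
#' @param category Integer vector with values in 1..6.
#' @return Numeric vector of midpoint angles in degrees.
#' @export
angle_category_midpoint <- function(category) {
  if (any(!is.na(category) & (category < 1 | category > 6 | category != round(category)))) {
    stop("angle category must be an integer in 1..6", call. = FALSE)
  }
  c(15, 45, 75, 105, 135, 165)[category]
}

#' Derive extreme-value traits from per-segment observations
#'
#' Shoots are divided into up to three vertical segments (Q1: 0-25%, Q2:
#' 25-75%, Q3: >75% of surrounding canopy height). Maximum and minimum leaf
#' angles are the largest and smallest of the per-segment average angles;
#' maximum and minimum specific leaf area are the largest and smallest SLA
#' values observed in any segment. Segments without observations are skipped;
#' if no segment has data for a quantity its derived traits are `NA`.
#'
#' @param leaf_angles Named list (names among `"Q1"`, `"Q2"`, `"Q3"`) of
#'   numeric vectors of leaf-blade angles (degrees); may be `NULL`.
#' @param sla Named list of numeric vectors of specific leaf area values
#'   (mm2 mg-1) per segment; may be `NULL`.
#' @return Named list with `leaf_angle_max`, `leaf_angle_min`, `sla_max`,
#'   `sla_min` (each `NA` when underived).
#' @export
#' @examples
#' derive_extrema_traits(
#'   leaf_angles = list(Q1 = c(30, 50), Q2 = 70, Q3 = c(90, 110)),
#'   sla = list(Q1 = 18, Q3 = 25.5)
#' )
derive_extrema_traits <- function(leaf_angles = NULL, sla = NULL) {
  seg_ok <- function(lst) {
    if (is.null(lst)) return(list())
    lst <- lst[vapply(lst, function(v) length(v) > 0L && any(!is.na(v)), logical(1L))]
    lst
  }
  angles <- seg_ok(leaf_angles)
  slas <- seg_ok(sla)
  out <- list(leaf_angle_max = NA_real_, leaf_angle_min = NA_real_,
              sla_max = NA_real_, sla_min = NA_real_)
  if (length(angles) > 0L) {
    seg_means <- vapply(angles, function(v) mean(v, na.rm = TRUE), numeric(1L))
    out$leaf_angle_max <- max(seg_means)
    out$leaf_angle_min <- min(seg_means)
  }
  if (length(slas) > 0L) {
    vals <- unlist(slas, use.names = FALSE)
    vals <- vals[!is.na(vals)]
    out$sla_max <- max(vals)
    out$sla_min <- min(vals)
  }
  out
}

#' @export
print.trait_table <- function(x, ...) {
  cfg <- trait_config_of(x)
  cells <- unique(as.data.frame(x)[, c("species", "diversity")])
  cat("Shoot-level trait table: ", nrow(x), " shoots, ",
      length(unique(x$species)), " species, ",
      nrow(cells), " species x diversity cells, ",
      sum(cfg$group != "performance"), " traits + shoot biomass\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}
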