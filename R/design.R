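#' Spatial-scale categories of the nested sampling design
#'
#' The sampling design is a five-level nested hierarchy: clones within a
#' fruiting body (micrometre scale), fruiting bodies within a soil core
#' (millimetre), cores within a transect (centimetre), transects within a
#' site (metre), and sites within the landscape (kilometre).
#'
#' @return A data frame with columns `name` (scale label, ordered factor)
#'   and `rank` (integer 0-4, increasing with distance).
#' @export
#' @examples
#' scale_categories()
scale_categories <- function() {
  data.frame(
    name = factor(SCALE_LEVELS, levels = SCALE_LEVELS, ordered = TRUE),
    rank = 0:4
  )
}

SCALE_LEVELS <- c("micrometre", "millimetre", "centimetre", "metre", "kilometre")

scale_factor <- function(x) {
  factor(x, levels = SCALE_LEVELS, ordered = TRUE)
}

ISOLATE_ID_RE <- "^([A-Z]+)([0-9]+)\\.([0-9]+)\\.([0-9]+)([A-Z])$"

#' Parse nested isolate identifiers
#'
#' Isolate names encode the full hierarchical address: an uppercase site
#' label, then transect, soil core and fruiting-body numbers separated by
#' dots, then a single clone letter. For example `"KF3.2.8A"` is clone A of
#' fruiting body 8 in core 2 of transect 3 at site KF.
#'
#' @param ids Character vector of isolate identifiers.
#' @return A data frame with columns `isolate_id`, `site`, `transect`,
#'   `core`, `fruiting_body` (integers) and `clone` (letter).
#' @seealso [format_isolate_id()] for the inverse.
#' @export
#' @examples
#' parse_isolate_id(c("KF3.2.8A", "GH3.5.2A"))
parse_isolate_id <- function(ids) {
  stopifnot(is.character(ids), length(ids) >= 1L)
  bad <- !grepl(ISOLATE_ID_RE, ids)
  if (any(bad)) {
    stop("malformed isolate id(s): ", paste(sQuote(ids[bad]), collapse = ", "),
         " (expected SITE<transect>.<core>.<fruiting_body><CLONE LETTER>,",
         " e.g. \"KF3.2.8A\")", call. = FALSE)
  }
  m <- regmatches(ids, regexec(ISOLATE_ID_RE, ids))
  m <- do.call(rbind, m)
  data.frame(
    isolate_id = ids,
    site = m[, 2L],
    transect = as.integer(m[, 3L]),
    core = as.integer(m[, 4L]),
    fruiting_body = as.integer(m[, 5L]),
    clone = m[, 6L]
  )
}

#' Format hierarchical addresses back into isolate identifiers
#'
#' @param address A data frame with columns `site`, `transect`, `core`,
#'   `fruiting_body`, `clone` (as produced by [parse_isolate_id()]).
#' @return Character vector of identifiers; `format_isolate_id(parse_isolate_id(x))`
#'   reproduces `x` exactly.
#' @export
format_isolate_id <- function(address) {
  need <- c("site", "transect", "core", "fruiting_body", "clone")
  miss <- setdiff(need, names(address))
  if (length(miss)) stop("address is missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(address$transect >= 1), all(address$core >= 1),
            all(address$fruiting_body >= 1),
            all(address$clone %in% LETTERS))
  paste0(address$site, address$transect, ".", address$core, ".",
         address$fruiting_body, address$clone)
}

#' Build a sample sheet from bare isolate identifiers
#'
#' @param ids Character vector of isolate identifiers.
#' @return Sample-sheet data frame (one row per isolate).
#' @export
sample_sheet_from_ids <- function(ids) {
  if (anyDuplicated(ids)) {
    stop("duplicated isolate id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  parse_isolate_id(ids)
}

#' Read or write a sample sheet
#'
#' Tab-separated, columns `isolate_id`, `site`, `transect`, `core`,
#' `fruiting_body`, `clone`; `#`-prefixed lines are metadata comments.
#'
#' @param path File path.
#' @param sheet Sample-sheet data frame.
#' @return `read_sample_sheet()` returns the sample-sheet data frame;
#'   `write_sample_sheet()` returns `path` invisibly.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("isolate_id", "site", "transect", "core", "fruiting_body", "clone")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet is missing column(s): ",
                         paste(miss, collapse = ", "))
  # cross-validate the sheet against the ids it claims to describe
  chk <- format_isolate_id(sheet)
  bad <- chk != sheet$isolate_id
  if (any(bad)) stop("sample sheet rows inconsistent with their isolate_id: ",
                     paste(sheet$isolate_id[bad], collapse = ", "))
  sheet
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify an isolate pair into its spatial-scale category
#'
#' The category is that of the deepest hierarchical level at which the two
#' addresses differ: same fruiting body gives micrometre; same core but
#' different fruiting bodies, millimetre; same transect but different cores,
#' centimetre; same site but different transects, metre; different sites,
#' kilometre.
#'
#' @param a,b Isolate identifiers (character) or single-row address data
#'   frames. Vectors are matched element-wise.
#' @return Ordered factor of scale categories (see [scale_categories()]).
#' @export
#' @examples
#' pair_scale("KF3.2.8A", "KF3.2.8B")  # micrometre
#' pair_scale("GH2.1.1A", "MC3.1.1A")  # kilometre
pair_scale <- function(a, b) {
  if (is.character(a)) a <- parse_isolate_id(a)
  if (is.character(b)) b <- parse_isolate_id(b)
  if (nrow(a) != nrow(b)) stop("a and b must have the same length")
  same_site <- a$site == b$site
  same_tr <- same_site & a$transect == b$transect
  same_core <- same_tr & a$core == b$core
  same_fb <- same_core & a$fruiting_body == b$fruiting_body
  self <- same_fb & a$clone == b$clone
  if (any(self)) {
    stop("self-pair (identical address): ",
         paste(format_isolate_id(a[self, , drop = FALSE]), collapse = ", "))
  }
  out <- rep("kilometre", nrow(a))
  out[same_site] <- "metre"
  out[same_tr] <- "centimetre"
  out[same_core] <- "millimetre"
  out[same_fb] <- "micrometre"
  scale_factor(out)
}

#' Representative distance geometry of the nested design
#'
#' Inter-isolate distances at the two smallest scales are inferred from the
#' sampled structures: isolates are assumed maximally separated by one third
#' of the relevant diameter (fruiting body for the micrometre scale, soil
#' core for the millimetre scale). The centimetre, metre and kilometre
#' representative distances are field-measurement constants.
#'
#' @param fruiting_body_diameter Average fruiting-body diameter in metres
#'   (default 100 micrometres).
#' @param core_diameter Soil-core diameter in metres (default 0.9 cm).
#' @param centimetre_distance,metre_distance,kilometre_distance
#'   Representative distances in metres for the three larger scales.
#' @return Object of class `scale_geometry`.
#' @export
scale_geometry <- function(fruiting_body_diameter = 100e-6,
                           core_diameter = 0.009,
                           centimetre_distance = 0.036,
                           metre_distance = 18,
                           kilometre_distance = 11000) {
  g <- list(
    fruiting_body_diameter = fruiting_body_diameter,
    core_diameter = core_diameter,
    centimetre_distance = centimetre_distance,
    metre_distance = metre_distance,
    kilometre_distance = kilometre_distance
  )
  bad <- !vapply(g, function(x) is.numeric(x) && length(x) == 1L &&
                   is.finite(x) && x > 0, logical(1))
  if (any(bad)) {
    stop("scale geometry lengths must be strictly positive: ",
         paste(names(g)[bad], collapse = ", "))
  }
  structure(g, class = "scale_geometry")
}

#' Read a scale geometry from a key/value config file
#'
#' YAML with keys named as the [scale_geometry()] arguments, values in metres.
#'
#' @param path File path.
#' @return Object of class `scale_geometry`.
#' @export
read_scale_geometry <- function(path) {
  do.call(scale_geometry, yaml::read_yaml(path))
}

#' Representative metric distance of a spatial-scale category
#'
#' Micrometre and millimetre distances are one third of the fruiting-body
#' and soil-core diameters respectively; centimetre, metre and kilometre
#' distances are the configured constants. Values are rounded to two
#' significant figures for reporting (the convention used for the design's
#' published distances, e.g. 0.000033 m for the micrometre scale).
#'
#' @param category Scale name(s) (`"micrometre"` ... `"kilometre"`).
#' @param geometry A [scale_geometry()].
#' @param digits Significant figures for the returned value; `NULL` for the
#'   exact quotient.
#' @return Numeric vector of distances in metres, strictly increasing in
#'   scale rank.
#' @export
#' @examples
#' scale_distance("micrometre")  # 3.3e-05
#' scale_distance(scale_categories()$name)
scale_distance <- function(category, geometry = scale_geometry(), digits = 2L) {
  stopifnot(inherits(geometry, "scale_geometry"))
  category <- as.character(category)
  bad <- !category %in% SCALE_LEVELS
  if (any(bad)) stop("unknown scale category: ",
                     paste(unique(category[bad]), collapse = ", "))
  d <- c(
    micrometre = geometry$fruiting_body_diameter / 3,
    millimetre = geometry$core_diameter / 3,
    centimetre = geometry$centimetre_distance,
    metre = geometry$metre_distance,
    kilometre = geometry$kilometre_distance
  )
  if (!is.null(digits)) d <- signif(d, digits)
  if (any(diff(d) <= 0)) {
    stop("scale distances are not strictly increasing in rank; ",
         "check the geometry")
  }
  unname(d[category])
}
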