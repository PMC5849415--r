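#' Intracortical microstimulation (ICMS) map
#'
#' A motor map is a set of cortical penetration sites on a 500 um grid, each
#' classified by the movement evoked at threshold current (0-200 uA), or
#' `"none"` for unresponsive sites.
#'
#' @param sites Data frame with columns `x_um`, `y_um`, `category`,
#'   `threshold_ua`.
#' @param spacing_um Grid spacing in micrometres (default 500).
#' @return An object of class `icms_map`.
#' @export
icms_map <- function(sites, spacing_um = 500) {
  need <- c("x_um", "y_um", "category", "threshold_ua")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("ICMS map missing column(s): ", paste(miss, collapse = ", "))
  cats <- c("vibrissae", "neck", "jaw", "digit", "wrist", "elbow", "shoulder",
            "hindlimb", "trunk", "none")
  bad <- setdiff(unique(sites$category), cats)
  if (length(bad)) stop("unknown movement category: ", paste(bad, collapse = ", "))
  if (any(sites$x_um %% spacing_um != 0 | sites$y_um %% spacing_um != 0)) {
    stop("site coordinates must lie on the ", spacing_um, " um lattice")
  }
  if (anyDuplicated(sites[, c("x_um", "y_um")])) stop("duplicate site coordinates")
  if (any(sites$threshold_ua < 0 | sites$threshold_ua > 200, na.rm = TRUE)) {
    stop("movement thresholds must lie in [0, 200] uA")
  }
  structure(list(sites = sites, spacing_um = spacing_um), class = "icms_map")
}

#' Cortical area per movement category
#'
#' Each responsive site represents `(spacing/1000)^2` mm-squared of cortex
#' (0.25 mm^2 at the standard 500 um spacing); category area is that unit
#' times the site count. Unresponsive (`"none"`) sites contribute nothing.
#'
#' @param map An [icms_map()] or a site data frame.
#' @return Named numeric vector of areas (mm^2) per category present, plus
#'   `"total"`.
#' @examples
#' m <- icms_map(data.frame(x_um = c(0, 500), y_um = 0,
#'                          category = c("digit", "wrist"), threshold_ua = 60))
#' icms_area_by_category(m)
#' @export
icms_area_by_category <- function(map) {
  if (!inherits(map, "icms_map")) map <- icms_map(map)
  unit_mm2 <- (map$spacing_um / 1000)^2
  resp <- map$sites[map$sites$category != "none", ]
  if (nrow(resp) == 0L) return(c(total = 0))
  tab <- table(resp$category)
  out <- unit_mm2 * as.numeric(tab)
  names(out) <- names(tab)
  c(out, total = sum(out))
}

#' Mean movement threshold per category
#'
#' @param map An [icms_map()] or a site data frame.
#' @return Named numeric vector: arithmetic mean threshold (uA) per
#'   responsive category present in the map.
#' @export
movement_threshold_stats <- function(map) {
  if (!inherits(map, "icms_map")) map <- icms_map(map)
  resp <- map$sites[map$sites$category != "none", ]
  if (nrow(resp) == 0L) return(stats::setNames(numeric(0), character(0)))
  vapply(split(resp$threshold_ua, resp$category, drop = TRUE), mean, numeric(1))
}

#' Normalize transsynaptic tracer counts
#'
#' Labeled-neuron counts in cortex (layer 5), red nucleus and C3/C4
#' propriospinal neurons are normalized within animal to the number of
#' putative spinal motor neurons, controlling for injection efficacy.
#'
#' @param counts Named list or data-frame row with non-negative integer
#'   counts `cortex_layer5`, `red_nucleus`, `propriospinal_C3C4`,
#'   `spinal_motor_neurons`.
#' @return Named numeric vector of ratios for the three non-spinal regions.
#' @examples
#' normalize_prv_counts(list(cortex_layer5 = 200, red_nucleus = 50,
#'                           propriospinal_C3C4 = 120,
#'                           spinal_motor_neurons = 400))
#' @export
normalize_prv_counts <- function(counts) {
  need <- c("cortex_layer5", "red_nucleus", "propriospinal_C3C4",
            "spinal_motor_neurons")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("missing count(s): ", paste(miss, collapse = ", "))
  v <- vapply(need, function(k) as.numeric(counts[[k]]), numeric(1))
  if (any(v < 0)) stop("counts must be non-negative")
  denom <- v["spinal_motor_neurons"]
  if (denom <= 0) stop("spinal motor neuron count must be positive for normalization")
  c(cortex_layer5 = unname(v["cortex_layer5"] / denom),
    red_nucleus = unname(v["red_nucleus"] / denom),
    propriospinal_C3C4 = unname(v["propriospinal_C3C4"] / denom))
}

#' Percent spared tissue
#'
#' Lesion extent expressed as spared gray/white matter area on the lesioned
#' side as a percentage of a within-animal reference area (the contralateral
#' hemicord for unilateral injuries; unlesioned rostral/caudal segments for
#' bilateral ones — reference selection is an input, not computed here).
#'
#' @param lesioned_area,reference_area Areas in any consistent unit;
#'   `reference_area` must be positive.
#' @return Percentage (0 means fully lost, 100 fully spared).
#' @examples
#' percent_spared(30, 120)  # 25
#' @export
percent_spared <- function(lesioned_area, reference_area) {
  if (any(reference_area <= 0)) stop("reference area must be positive")
  if (any(lesioned_area < 0)) stop("areas must be non-negative")
  100 * lesioned_area / reference_area
}

#' Read an ICMS map CSV
#'
#' Dialect: header `x_um,y_um,category,threshold_ua`.
#'
#' @param path File path.
#' @return An [icms_map()].
#' @export
read_icms_map <- function(path) {
  icms_map(utils::read.csv(path, stringsAsFactors = FALSE))
}
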